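{
  "tau": 10,
  "w_SG": 2.56,
  "w_GS": 3.22,
  "w_CC": 2.75,
  "w_CS": 6.6,
  "w_GG": 0.9,
  "C": 277.94,
  "Str": 40.51,
  "M_S": 300,
  "B_S": 10,
  "M_G": 400,
  "B_G": 20,
  "M_E": 72.444444444444,
  "B_E": 10.257565981468,
  "M_I": 211.740740740741,
  "B_I": 4.37037037037,
  "T": 8,
  "comment": "Reference point values; the four cortical sigmoid constants (M_E, B_E, M_I, B_I) are the packaged calibration: grid search over the admissible ranges matching the reference minimal critical delay 3.6807 ms, polished by bisection on B_E. Regenerate with calibrate_cortex()."
}
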