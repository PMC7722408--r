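# bgresonance

Delay-induced beta oscillations in a cortex–STN–GPe firing-rate loop model:
Hopf-bifurcation analysis, normal-form classification, and delay-equation
simulation.

## The problem

Exaggerated beta-band (13–30 Hz) oscillations in the basal ganglia are a
hallmark of Parkinson's disease. A compact dynamical explanation treats the
motor circuit as four interacting mean-field populations — subthalamic
nucleus `S`, external globus pallidus `G`, and cortical excitatory/inhibitory
pairs `E`/`I` — whose firing rates relax toward sigmoid functions of their
delayed synaptic inputs:

    τ S' = F_S(w_CS·E(t−T) − w_GS·G(t−T)) − S
    τ G' = F_G(w_SG·S(t−T) − w_GG·G(t−T) − Str) − G
    τ E' = F_E(C − w_CC·I(t−T)) − E
    τ I' = F_I(w_CC·E(t−T)) − I

with `F_X(u) = M_X / (1 + ((M_X−B_X)/B_X)·exp(−4u/M_X))` and a common
transmission delay `T`. As `T` grows the equilibrium ("healthy state") loses
stability in a Hopf bifurcation and a beta-band limit cycle
("Parkinsonian state") appears. The package answers, analytically and by
simulation: *at which delay, at which frequency, through which loop, and
with what kind of bifurcation.*

For whom: computational neuroscientists and dynamical-systems practitioners
who need a complete, tested delay-Hopf pipeline for this model family —
equilibrium, delayed linearization, critical delays for both feedback loops,
transversality, Routh–Hurwitz zero-delay stability, center-manifold normal
form (`c1(0)`, `μ2`, `β2`, `T2`), Euler delay-equation simulation, and one-
and two-parameter bifurcation scans.

## Worked example

```r
library(bgresonance)

p <- bg_params()          # reference constants + calibrated cortical completion
rep <- hopf_report(p, normal_form = TRUE)
rep
#> <hopf_report>
#>   Hopf at T0 = 3.6807 ms
#>   omega0 = 0.17553 rad/ms (f0 = 27.937 Hz), loop 1 (STN-GPe)
#>   Re(dlambda/dT) = 0.01346 at the crossing
#>   H1=TRUE H2=TRUE H3=TRUE
#> <bg_normal_form>
#>   c1(0) = -8.41445e-05 -6.75213e-05i
#>   mu2 = 0.0062513 (supercritical), beta2 = -0.00016829 (orbit stable),
#>   T2 = 0.00029016 (period increasing)
```

Reading this: the equilibrium survives until the transmission delay reaches
`T0 = 3.6807` ms, where a conjugate eigenvalue pair crosses the imaginary
axis at `f0 = 27.9` Hz — a beta-band instability carried by the STN–GPe loop
(`loop 1`), not the cortical loop. The crossing is transversal
(`Re dλ/dT > 0`: stability is lost as the delay grows) and the equilibrium
is stable at zero delay (`H3`), so the delay itself is the destabilizing
parameter. The normal form classifies the bifurcation: `mu2 > 0`
(supercritical — the oscillation grows continuously from zero amplitude),
`beta2 < 0` (the emerging limit cycle is stable), `T2 > 0` (its period
lengthens as the delay increases).

Simulating past the critical delay shows the mature attractor:

```r
tr <- simulate_bg(bg_params(T = 8), duration = 2500)
summarize_attractor(tr)
#>   kind        amplitude frequency band  freq_spectral freq_flagged
#> 1 oscillation     167.3     17.27 beta           17.6        FALSE
autoplot(tr)    # firing-rate time series, one line per population
```

Scans chain the same machinery along a parameter grid, carrying each point's
final state into the next and overlaying the analytic onset:

```r
sc <- ramp_scan(bg_params(), "T", seq(1, 10, length.out = 200))
attr(sc, "analytic_critical")   # 3.6807
autoplot(sc)                    # bifurcation diagram with onset line
```

`hopf_boundary_2d()` maps stability over two parameters (e.g. `w_SG` vs
`w_CS`, or `w_CS` vs `T` with alpha/beta/gamma band labels), and
`frequency_profile()` tracks the oscillation frequency along the delay axis.
`calibrate_cortex()` reproduces the packaged completion of the four
cortical sigmoid constants from scratch; `generate_fixtures()` draws seeded
admissible parameter sets. A thin command-line front end with `analyze`,
`simulate`, `scan1d` and `freq-profile` subcommands is installed under
`inst/cli/bgresonance`.

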