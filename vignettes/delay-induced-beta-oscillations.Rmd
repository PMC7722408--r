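---
title: "Delay-induced beta oscillations in the cortex-STN-GPe loop model: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delay-induced beta oscillations in the cortex-STN-GPe loop model: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bgresonance)
```

## The model

The package analyses a four-population firing-rate ("neural mass") model of
the motor circuit implicated in Parkinsonian beta oscillations: the
subthalamic nucleus `S`, the external globus pallidus `G`, and the excitatory
and inhibitory cortical populations `E` and `I`. Each population relaxes
toward a sigmoid function of its synaptic input with a common membrane time
constant $\tau$, and every connection acts after a common transmission delay
$T$:

$$
\tau S' = F_S\!\big(w_{CS}E(t-T) - w_{GS}G(t-T)\big) - S,\qquad
\tau G' = F_G\!\big(w_{SG}S(t-T) - w_{GG}G(t-T) - \mathrm{Str}\big) - G,
$$
$$
\tau E' = F_E\!\big(C - w_{CC}I(t-T)\big) - E,\qquad
\tau I'  = F_I\!\big(w_{CC}E(t-T)\big) - I,
$$

with activation $F_X(u) = M_X\big/\big(1 + \frac{M_X-B_X}{B_X}e^{-4u/M_X}\big)$,
so $F_X(0)=B_X$ and $F_X' = 4F_X(M_X-F_X)/M_X^2$. The cortex drives the
basal ganglia through $w_{CS}$ but receives nothing back, so the circuit
contains exactly two feedback loops: the STN-GPe loop
($w_{SG}, w_{GS}, w_{GG}$) and the cortical E-I loop ($w_{CC}$). This
"resonance" architecture means basal-ganglia oscillations ride on, and are
tuned by, the cortical drive.

Units are fixed throughout: time in ms, rates in spk/s, angular frequency
$\omega$ in rad/ms; reported frequencies are $f = 1000\,\omega/2\pi$ Hz.

### Parameters and their defaults

`bg_params()` carries the full constant set. The membrane constant is the
common average $\tau = 10$ ms; the weights and constant inputs are the
reference point values $w_{SG}=2.56$, $w_{GS}=3.22$, $w_{CC}=2.75$,
$w_{CS}=6.60$, $w_{GG}=0.90$, $C=277.94$, $\mathrm{Str}=40.51$ spk/s, and
the basal-ganglia sigmoid constants are $M_S=300$, $B_S=10$, $M_G=400$,
$B_G=20$ spk/s. The four cortical constants are known only as admissible
ranges ($M_E\in[50,80]$, $B_E\in(0,20]$, $M_I\in[20,330]$, $B_I\in(0,20]$
spk/s); how they are fixed is described under *Calibration* below. The
delay $T$ is the bifurcation parameter; the default 8 ms sits in the
oscillatory regime.

## The analysis pipeline

### Equilibrium

Fixed points solve $X^* = F_X(\text{inputs}(u^*))$ and do not depend on the
delay. `solve_equilibrium()` uses damped fixed-point iteration followed by a
Newton polish with the analytic Jacobian, from eight deterministic starts on
a coarse grid of $(0,M_X)^4$; distinct converged solutions flag
non-uniqueness. The residual target is $10^{-10}$ spk/s per ms on the vector
field; in practice Newton reaches machine precision. Components within
$10^{-9}$ of the saturation boundaries $0$ or $M_X$ make the curvature
formulas below degenerate and raise an error rather than silently zeroing
coefficients.

### Linearization and the characteristic equation

Writing deviations $u = (S-S^*,\dots)$, the linearization is
$u' = B_1 u(t) + B_2 u(t-T)$ with $B_1 = -I/\tau$ and a delayed matrix
$B_2$ whose entries $a_{12},a_{13},a_{21},a_{22},a_{34},a_{43}$ are signed
products of weights and sigmoid slopes at the equilibrium. The quadratic and
cubic Taylor coefficients $c_X = F_X''/2\tau$ and $e_X = F_X'''/6\tau$ feed
the normal form. The characteristic determinant factorizes by the block
structure,

$$
\Delta(\lambda) = \Delta_1(\lambda)\,\Delta_2(\lambda),\qquad
\Delta_1 = (\lambda{+}\tfrac1\tau)^2 - (\lambda{+}\tfrac1\tau)a_{22}e^{-\lambda T}
           - a_{12}a_{21}e^{-2\lambda T},\quad
\Delta_2 = (\lambda{+}\tfrac1\tau)^2 - a_{34}a_{43}e^{-2\lambda T},
$$

one factor per loop, so every instability is attributable to STN-GPe
resonance ($\Delta_1$) or cortical E-I resonance ($\Delta_2$).

### Critical delays

For $\Delta_1$, eliminating the delay from $\Delta_1(i\omega)=0$ yields a
quartic in $z=\omega^2$ whose coefficients are closed forms in
$a_{22}$ and $a_{12}a_{21}$; its real positive roots are taken from
companion-matrix eigenvalues (roots with $|\mathrm{Im}|<10^{-9}$,
$\mathrm{Re}>10^{-10}$). The elimination squares one factor, so the quartic
can carry spurious roots; rather than trusting single-valued arccos/arcsin
branch formulas, the implementation recovers the crossing phase from the
unit-modulus roots of the quadratic
$a_{12}a_{21}x^2 + (i\omega+\tfrac1\tau)a_{22}x - (i\omega+\tfrac1\tau)^2=0$
in $x = e^{-i\omega T}$, which enforces the sine and cosine conditions
jointly; candidates then pass a $|\Delta_1(i\omega)|<10^{-8}$ residual
filter. $\Delta_2$ has a real crossing iff $-a_{34}a_{43} > 1/\tau^2$, with
$\omega_5 = \sqrt{-a_{34}a_{43}-1/\tau^2}$ fixed by modulus and the delay by
the phase of $(i\omega+\tfrac1\tau)^2/(a_{34}a_{43})$. Branch shifts
$2\pi j/\omega$ generate later crossings. The minimal positive candidate is
$T_0$ with frequency $\omega_0$; exact ties are reported, and the largest
frequency is carried forward (genericity assumption). Tests verify the
closed forms against an explicit $4\times4$ complex determinant and against
a rightmost-root Newton continuation started from the $T=0$ eigenvalues.

### Transversality and zero-delay stability

Implicit differentiation of $\Delta(\lambda(T),T)=0$ gives
$(d\lambda/dT)^{-1} =
-(\partial_\lambda\Delta_2\,\Delta_1 + \partial_\lambda\Delta_1\,\Delta_2)
/(\partial_T\Delta_2\,\Delta_1 + \partial_T\Delta_1\,\Delta_2)$, evaluated
at $\lambda=i\omega_0$; the crossing is transversal when the real part is
non-zero, and $\mathrm{Re}\,\lambda'>0$ means stability is lost as the delay
grows. At $T=0$ the characteristic equation is an ordinary quartic — the
product of the two loop quadratics — and the Routh-Hurwitz inequalities on
its coefficients decide whether the equilibrium starts stable, the
prerequisite for the delay to be the destabilizing parameter. The
implementation expands the quartic directly from the two factors (the
expansion is re-checked in tests against the eigenvalues of $B_1+B_2$).
`hopf_report()` chains all three conditions into a verdict.

### Calibration of the cortical constants

Only ranges are known for $(M_E, B_E, M_I, B_I)$. `calibrate_cortex()`
fixes them operationally: a coarse-to-fine grid search over the ranges
keeps completions whose minimal critical delay matches the reference value
$T_0 = 3.6807$ ms within $10^{-3}$ ms, requiring the crossing to be the
STN-GPe loop with a beta-band onset frequency. Two structural facts make
this well-posed. First, the cortical pair feeds the basal ganglia only
through the scalar equilibrium rate $E^*$, so for an STN-GPe crossing the
whole downstream analysis — $T_0$, $\omega_0$, $\lambda'$, and every
normal-form coefficient — depends on the completion only through $E^*$.
Matching $T_0$ pins $E^*$ (to 63.3086 spk/s), and all matching completions
are equivalent thereafter. Second, the completion must not let the cortical
loop cross earlier; the search discards such members. The packaged default
(`M_E = 72.444`, `B_E = 10.258`, `M_I = 211.741`, `B_I = 4.370`) is one
member of the matching family, polished by bisection so the default
parameter set reproduces $T_0$ to $4\times10^{-8}$ ms; it also carries a
cortical-loop crossing at 4.210 ms, safely above $T_0$. At this point
$\omega_0 = 0.17553$ rad/ms ($f_0 = 27.94$ Hz, beta band) and
$\mathrm{Re}\,\lambda' = 0.013460$.

## The Hopf normal form

All center-manifold algebra is carried out in the time-rescaled frame
$t \to t/T$ with the delay normalized to 1, where the center rotation rate
is $\omega_0 T_0$ and the second/third-order coefficients $g_{20}, g_{11},
g_{02}, g_{21}$ carry explicit $T_0$ factors. The right eigenvector
$q=(1,\chi,\beta,\gamma)$ and the adjoint row vector are closed forms from
the block structure of $B_2$ (for an STN-GPe crossing $\beta=\gamma=0$
exactly: the cortex does not participate in the critical mode); the
normalization constant $\rho$ enforces $\langle q^*,q\rangle=1$ under the
delay bilinear pairing. The nonlinearity enters only through the scalar
synaptic deviations — per population, $f_X = c_X L_X(v)^2 + e_X L_X(v)^3$
with $L_S(v) = w_{CS}v_3 - w_{GS}v_2$ and so on — which keeps every
$g$-coefficient a short sum over populations. The center-manifold
corrections $E_1, E_2$ solve two $4\times4$ linear systems (matrices
$2i\omega_0 I - B_1 - B_2e^{-2i\omega_0T_0}$ and $-(B_1{+}B_2)$), and
$W_{20}, W_{11}$ are needed only at the delayed argument $\theta=-1$.
Finally

$$
c_1(0) = \frac{i}{2\omega_0 T_0}\Big(g_{20}g_{11} - 2|g_{11}|^2 -
         \tfrac13|g_{02}|^2\Big) + \frac{g_{21}}{2},\qquad
\mu_2 = -\frac{\mathrm{Re}\,c_1}{\mathrm{Re}\,\lambda'},\quad
\beta_2 = 2\,\mathrm{Re}\,c_1,\quad
T_2 = -\frac{\mathrm{Im}\,c_1 + \mu_2\,\mathrm{Im}\,\lambda'}{\omega_0 T_0},
$$

with $\lambda' = d\lambda/dT$ in physical units. $\mu_2>0$ gives a
supercritical bifurcation, $\beta_2<0$ a stable periodic orbit, $T_2>0$ a
period that grows with the delay. Because $c_1$ is computed in the rescaled
frame while $\mu$ is the physical delay offset, the amplitude law reads
$\varepsilon^2 = (T-T_0)\,T_0/\mu_2$, with the STN peak-to-trough excursion
$\simeq 4\varepsilon$ near onset; the package's tests fit exactly this law
to simulations.

### Verification, and a caveat on the reference coefficients

The coefficient pipeline is cross-checked three independent ways: (i) the
$g$-coefficients against polarization-based directional derivatives of the
raw nonlinearity (no $c_X$/$e_X$ closed forms involved); (ii) $c_1(0)$
against a physical-time characteristic-matrix formulation
($h_{20} = \Delta(2i\omega_0)^{-1}B(\varphi,\varphi)$ etc., with SVD null
vectors), a structurally different derivation that agrees to machine
precision; (iii) the simulated amplitude law, whose fitted slope converges
to the $c_1$-implied value as the Euler step shrinks. On the calibrated
reference point these give $\mu_2 = 6.251\times10^{-3}$,
$\beta_2 = -1.683\times10^{-4}$, $T_2 = 2.902\times10^{-4}$: a
supercritical Hopf bifurcation with a stable beta-band orbit whose period
grows with the delay.

Published reference values for this model's classification coefficients
($\mu_2 = 5.5252\times10^{-4}$, $\beta_2=-1.4874\times10^{-5}$,
$T_2 = 8.6223\times10^{-6}$) agree with our computation in all three signs
and — exactly, to five digits — in the transversality speed
$\mathrm{Re}\,\lambda' = -\beta_2/2\mu_2 = 0.013460$ implied by their
ratio, which confirms that the same crossing and the same linearization are
being analysed. Their magnitudes, however, differ from ours by a constant
factor ($8\sqrt2$ on $\mu_2$ and $\beta_2$) that matches no normalization or
frame convention we could construct, and the simulated amplitude growth
supports our value. The corresponding acceptance checks therefore compare
against the reference magnitudes and are expected to fail them while the
sign-level classification passes; we report our computed values unchanged.

## Simulation and scans

`simulate_bg()` integrates the delay system by explicit Euler with step
$h = 0.01$ ms by default; the delay is realized as a ring buffer of
$\mathrm{round}(T/h)$ steps, so $T$ is effectively rounded to the step grid.
The default initial history holds the equilibrium on $[-T,0]$ with a
$+1$ spk/s perturbation of $S$ (without a perturbation an unstable fixed
point would never be left). Euler is first-order: halving $h$ halves the
amplitude error, and the effective onset delay of the discretized system
sits about 0.01-0.04 ms below the analytic $T_0$ at $h=0.01$; tests
account for both facts. Sigmoid boundedness keeps all rates inside
$(0, M_X)$ for any step that is small against $\tau$.

`summarize_attractor()` discards a transient fraction (default half the
run), classifies fixed point vs oscillation by the STN peak-to-trough
excursion, and estimates the dominant frequency from mean inter-peak
intervals with an FFT cross-check (a >5% disagreement flags the summary).
Band labels follow the convention: alpha 8-13 Hz, beta 13-30 Hz (both
boundary values assigned to beta), gamma above 30 Hz, "slow" below 8 Hz,
"steady" for fixed points.

`ramp_scan()` sweeps a parameter, carrying each grid point's final history
into the next (continuation). Near a Hopf point critical slowing down makes
naive thresholding unreliable in both directions: below onset a
perturbation's resonant ring decays arbitrarily slowly, and above onset a
decayed history would take arbitrarily long to regrow. The scan therefore
re-seeds every grid point with a small probe kick (default 1 spk/s, applied
to both $S$ and $E$ — the cortical loop receives no basal-ganglia input and
would otherwise never be probed) and classifies a point as oscillatory only
if the excursion clears a threshold *and* is not decaying across the
analysis window (last-quarter vs previous-quarter amplitude ratio at least
0.9, with a large-amplitude override for saturated attractors). With this
rule a 200-point delay scan locates the onset within one grid step of the
analytic $T_0$.

`hopf_boundary_2d()` classifies each cell of a two-parameter grid either
analytically (stable iff the cell's delay is below its minimal critical
delay; onset frequency bands the cell) or by row-wise simulation scans;
analytic boundaries are refined by bisection. The two modes are required, in
tests, to place the onset boundary within one cell of each other. Analytic
cells are banded by the *onset* frequency $\omega_0$ while simulation cells
use the measured frequency; far from onset the two can differ, and
simulation wins in disagreement reports.

`frequency_profile()` tracks the measured frequency along the delay axis at
strong cortical drive ($w_{CS}=8$): the attractor appears directly in the
gamma band at small delay, then passes through beta into alpha, with beta
occupying the widest delay interval within the physiological 1-15 ms window
(beyond ~21 ms the frequency falls below 8 Hz and is labelled "slow"; the
"beta widest" statement is specific to the 1-15 ms range).

## Synthetic parameter sets

`generate_fixtures()` draws reproducible admissible parameter sets: weights
uniform within ±50% of the reference values, constant inputs within ±25%,
cortical constants uniform in their admissible ranges, delays uniform on
1-15 ms; members 1-2 are the calibrated reference set and a mid-range
completion, and draws are topped up so at least 30% of members admit a Hopf
crossing (keeping the oscillatory code paths exercised). These sets emulate
the *admissible parameter neighbourhood* of the model — they are not
samples from any empirical distribution of Parkinsonian or healthy brains,
carry no measurement noise, and keep $\tau$ fixed; passing tests on them
demonstrates correctness of the mathematics across the parameter box, not
biological realism.

## Problem sizes and limitations

Default test-scale choices: 200-point one-parameter scans at $h=0.01$ ms
with 1.5-2.5 s of model time per point; $8\times8$ to $10\times10$ analytic
codim-2 grids (simulation maps coarser); calibration on a $7^4$ coarse grid
with three or four local refinement rounds (~10^3-10^4 equilibrium solves).
These run in minutes on one CPU and are stated here as the package's
defaults, chosen to resolve every claimed effect with margin.

Known limitations: the analysis treats only the equal-delay,
common-$\tau$ reduction (heterogeneous delays are accepted by the simulator
but not by the analytic modules); no continuation of the periodic orbit
itself (amplitudes come from simulation, onsets from linear analysis); no
higher-order (Bautin) analysis when $\mu_2\approx0$; Euler integration is
deliberate — it is the scheme the bifurcation diagrams are defined against —
and higher-order integrators appear only as test oracles; and the
$S$-excursion is the sole amplitude readout (the other populations track it
through fixed complex gains near onset).
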