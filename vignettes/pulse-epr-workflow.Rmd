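---
title: "Models and methods behind the pentaepr pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the pentaepr pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pentaepr)
```

pentaepr analyses the two pulse-EPR experiments that together resolve the
in-membrane architecture of spin-labelled oligomeric channels: DEER/PELDOR
for nanometre inter-label distances and three-pulse ESEEM for deuterium
(solvent) accessibility of the labelled site.  This vignette records the
models, the tunable parameters, the numerical choices, and the places
where the design was genuinely open — in more detail than the function
reference.

## The DEER forward model

A frozen, isotropically oriented sample of complexes carrying nitroxide
labels produces the dipolar signal

$$V(t) = B(t)\,\Big[(1-\lambda) + \lambda \int K(t,r)\,P(r)\,dr\Big],$$

where $\lambda$ is the modulation depth (fraction of the echo modulated
by intra-complex coupling), $P(r)$ the distance distribution, and
$B(t) = \exp(-k\,t^{d/3})$ the intermolecular background from the
homogeneous ($d = 3$) spin bath; membrane-confined samples can be given
fractional $d$.  The kernel is the powder average

$$K(t,r) = \int_0^1 \cos\!\big[\omega_{dd}(r)\,(1-3x^2)\,t\big]\,dx,
\qquad \omega_{dd} = \frac{2\pi D}{r^3},$$

with $D \approx 52.04$ MHz nm$^3$ computed from CODATA constants
(`dipolar_constant()`), evaluated in closed form through Fresnel
integrals.  For phases $\omega t < 10^{-4}$ the Fresnel expression loses
accuracy to cancellation, so a fourth-order Taylor series is used there;
the crossover keeps the kernel within $10^{-6}$ of dense quadrature
everywhere (this is asserted in the test suite).

## Distance recovery

Inversion of $V \mapsto P$ is ill-posed; we solve the non-negative
Tikhonov problem

$$\min_{p \ge 0}\;\big\|(1-\lambda) + \lambda K p - F\big\|^2
  + \alpha^2 \|L_2 p\|^2$$

with $L_2$ the second-difference operator, using a Lawson–Hanson
active-set solver written for this package (the stacked system
$[\lambda K;\ \alpha L_2]$ has full column rank, so the optimum is unique
and is cross-checked in the tests against an independent
coordinate-descent solver run to $10^{-13}$).

Choices worth recording:

* **Modulation depth.** $\lambda$ is fitted by an inner 1-D golden-section
  search (tolerance $10^{-3}$) on the full regularized objective rather
  than read from the long-time plateau of $F$, because short traces never
  reach the plateau.  Since the non-negative solution carries an
  arbitrary total mass, the *reported* depth is the scale-invariant
  $\lambda \Sigma p / ((1-\lambda) + \lambda \Sigma p)$.
* **Form-factor normalization.** The background is fitted to the trace
  tail, so its amplitude absorbs the $(1-\lambda)$ plateau; the raw
  quotient $V/\hat B$ therefore starts near $1/(1-\lambda)$.
  `form_factor()` renormalizes by the $t = 0$ value, restoring the
  conventional signal that decays from 1 towards $1-\lambda$.
* **Regularization parameter.** Published workflows rarely state their
  $\alpha$ rule, so the package exposes one explicitly: the L-curve corner (maximum
  Menger curvature of log-residual vs log-penalty over a 12-point
  log-spaced grid, $\lambda$ held fixed across the grid).  Two degenerate
  regimes are handled explicitly: a collapsed penalty range falls back to
  the median $\alpha$ with a warning, and a residual that is insensitive
  to $\alpha$ (log-range $< 0.05$, the signature of a trace with no
  recoverable dipolar signal) returns the $3/4$-grid $\alpha$, because
  smoothing is free when the fit does not resist it.
* **Rising backgrounds.** Tail fits occasionally minimize the RMSD with
  $k < 0$ (a rising background) when the dipolar oscillation is
  incompletely sampled.  These fits are admitted when
  `allow_unphysical = TRUE` (the default in `validate()`, matching the
  practice of keeping the best-RMSD fit for the full trace) and flagged
  on the returned object.

## The validation ensemble

A recovered $P(r)$ is only as good as the background correction.
`validate()` re-runs the inversion over a grid of background starting
points (default 16 steps spanning 5–80 % of the trace) with
`trials_per_step = 50` noise perturbations each — 800 trials in total.
The added noise has sd equal to `noise_scale` (default 0.5, i.e. "50 %
noise") times the trace noise estimated from smoothing-spline residuals;
whether such a perturbation should instead be scaled to the signal
amplitude is genuinely ambiguous, so the reference point is recorded in
the configuration (`validation$noise_reference`).  Trials whose fit RMSD
exceeds 1.15 times the best are discarded; ties at exactly the cut are
kept ($\le$, not $<$).  The kept trials are summarized pointwise as
mean ± 2σ, the lower band clamped at zero.  $\alpha$ is selected once on
the clean trace and held fixed across trials so the ensemble spread
reflects background and noise, not regularization churn.  The
single-trace analysis reported alongside uses the starting point that
minimizes the clean-trace RMSD over the same grid.

Multispin ghost peaks in $>$2-spin complexes are suppressed by *power
scaling*: `power_scale()` raises the form factor to $1/(n-1)$ (0.25 for
a pentamer), clipping non-positive values at $10^{-3}$ with a warning.

`reliability_ranges()` maps the evolution window to the largest distance
at which the shape, width and mean of $P(r)$ are trustworthy, using the
customary constants 5, 6 and 7 nm at $t_{max} = 2$ µs; every boundary
scales as $t_{max}^{1/3}$ because the dipolar frequency scales as
$r^{-3}$.

## The ESEEM chain

A three-pulse sequence $\pi/2-\tau-\pi/2-T-\pi/2-\tau$-echo modulates the
stimulated echo with the frequencies of nearby nuclei.  In the
weak-coupling limit used throughout (degenerate nuclear frequency in both
electron manifolds) one nucleus contributes

$$E(T) = 1 - \tfrac{k}{2}\,(1-\cos\omega\tau)\,(1-\cos\omega(\tau+T)),$$

so at $\omega\tau = 2\pi m$ the nucleus is *blind*: `blind_spot_tau()`
returns $\tau = 2/\nu_H \approx 139$ ns at X-band, which kills the matrix
proton signal while the deuterium line at $\nu_D \approx 2.2$ MHz
survives.  The same expression is used for $^1$H and an effective $^2$H
line, with the $I = 1$ deuterium enhancement absorbed into the amplitude
$k$ — only *relative* accessibility is ever interpreted, so a full
spin-Hamiltonian treatment (quadrupole, hyperfine anisotropy) is out of
scope.

The analysis chain mirrors the standard protocol: fit a stretched
exponential $A\exp[-(T/\tau_d)^\beta]$ to the echo decay (initialized
from a log–log linearization; $\beta$ bounded in $[0.05, 2]$, a flat
trace pins $\beta$ at the lower bound with a warning); normalize as
$(V-f)/f$, which retains the modulation-depth information and is exactly
scale-invariant in $A$; apodize with a Hamming window; zero-fill to twice
the next power of two; Fourier transform; apply the zero-order phase that
minimizes the imaginary power over 0.5–8 MHz (closed form, 180°
ambiguity resolved towards positive absorption); and read the absolute
spectrum at the deuterium Larmor frequency computed from the recorded
field.  The readout takes the maximum within one frequency bin of the
nominal $\nu_D$ to tolerate small field-calibration errors — line
positions in practice can sit visibly off the nominal Larmor value, so
the position is treated as data-driven within that guard band.  The
error is the RMSD of the imaginary part over a signal-free band
(3.5–8 MHz by default, between the $^2$H and $^1$H lines); whether the
"imaginary RMSD" should be taken in the time or the frequency domain is
ambiguous, and the choice is recorded in the configuration.

Two properties of this chain matter for interpretation.  First, because
the decay fit absorbs the constant part of the modulation, the measured
amplitude is $a/(1-a)$ for a programmed amplitude $a$ — *superlinear* in
$k$.  Relative changes are therefore faithful only in the small-$k$
regime ($k \lesssim 0.15$; at $k = 0.3$ a programmed +30 % change reads
as roughly +40 %).  Second, dividing by the decay amplifies late-time
noise as $1/f(T)$, which the Hamming taper only partly offsets; traces
should not extend far beyond $\tau_d$.

## The synthetic-data generator

The generator exists so that every stage is testable without downloads,
and its defaults are the conditions the tests and the acceptance script
run under:

* **Geometry**: C$_5$ ring of label sites, radius 2.5 nm (giving
  D$_1$ = 2.94 nm and D$_2$ = 4.76 nm, the working range of Q-band DEER
  on a pentameric channel), optional isotropic Gaussian jitter.  A
  regular pentamer forces D$_2$/D$_1 = 2\cos 36° = 1.618$ at any radius.
* **DEER**: modulation depth 0.3 and Gaussian noise of 1 % of $V(0)$
  (the source data do not state their values; these are typical for
  Q-band nitroxide measurements and are configurable), background rate
  0.05 µs$^{-1}$, $d = 3$.  Round-trip analyses use $t_{max} = 5$ µs
  (417 points at 12 ns), about 2.4 dipolar periods of D$_2$, so the tail
  fit is unbiased; the ensemble checks use a deliberately short 150-point,
  3 µs trace on a 30-bin grid to exercise the protocol at realistic cost.
* **ESEEM**: $T$ incremented in 12 ns steps (300 points), $\tau$ on the
  proton blind spot, stimulated-echo decay $\tau_d = 8$ µs, $\beta = 1.2$
  (the 3-pulse echo decays on the T$_1$/spectral-diffusion timescale at
  80 K, much slower than the phase-memory time relevant to 2-pulse
  experiments), $^2$H amplitude 0.3 and $^1$H amplitude 0.2 by default.
  Noise is additive Gaussian on the real channel with independent noise
  of the same sd on the imaginary channel.

What the generator does *not* emulate — and hence what green tests do
not certify about real data: orientation selection and finite excitation
bandwidth in DEER, nuclear-frequency splitting and quadrupole structure
in ESEEM, baseline drifts and phase noise of real spectrometers, and
conformational heterogeneity beyond Gaussian site jitter.

## The accessible-volume label model

`attach_label()` approximates an MTSSL rotamer search by its end result:
the cloud of sterically allowed label midpoints.  Candidates are drawn
uniformly from a 0.4–1.0 nm shell around C$\beta$ (C$\alpha$ for
glycine) — roughly the reach of the MTSSL linker — and rejected within
the clash cutoff of any heavy atom outside the labelled residue.
"Tight" van der Waals restraints map to a 0.25 nm cutoff and "loose" to
0.20 nm; these constants are a documented approximation, since the exact
restraint radii of rotamer-search tools are not published.  Sampling
directions live in a residue-local backbone frame, which makes clouds
exactly equivariant under rigid motions of the structure (a property the
tests assert).  Only midpoint statistics feed the distance
distributions; side-chain dihedral preferences are not modelled, which
mainly *widens* predicted distributions relative to rotamer libraries.

Pair histograms use mass-preserving linear binning (each distance splits
its weight between the two flanking grid nodes), which preserves the
distribution mean exactly and keeps on-node distances single-bin deltas.
`oligomer_predicted_distributions()` pools nearest- and
next-nearest-neighbour pairs with one unit of weight per pair — 5 + 5
for a pentamer, hence the 1:1 area expectation.  Peak analysis uses
*topographic prominence* (height above the key saddle) rather than a
bare height threshold, which makes the D$_1$/D$_2$ readout robust to
Monte-Carlo wiggle in histogram densities; peaks closer than two grid
steps are merged, the taller surviving.

## Problem sizes and tolerances used by the shipped checks

The package's own end-to-end checks run the full validation protocol
(16 × 50 = 800 trials) on the 150-point trace, the noiseless round trip
on the 417-point trace with the 131-bin default grid, solver-vs-oracle
agreement on 30-bin instances at $10^{-6}$, kernel-vs-quadrature at
$10^{-6}$, and the accessibility chain at 1 % noise over 10 seeds with a
programmed +30 % change asserted within ±5 points on the 10-seed mean
(the ±3-point residual of that comparison is the documented small-$k$
nonlinearity, not noise).  All random draws take explicit seeds; no
function touches the global RNG state.

## Known limitations

* Tail-based background fitting is biased when the evolution window is
  short relative to the longest dipolar period; the validation ensemble
  quantifies but does not remove this bias (no iterative
  background/foreground refinement is attempted).
* The L-curve corner is a heuristic; for heavily oversmoothed or
  undersampled traces the selected $\alpha$ should be inspected via the
  curve attached to the return value.
* ESEEM accessibility is a *relative* quantity; absolute water counts
  would need calibration standards and a spin-physics model beyond the
  weak-coupling limit.
* The label model knows nothing about induced fit or label–lipid
  interactions; treat predicted widths as lower bounds on fidelity, not
  on physics.
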