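# pentaepr

Pulse-EPR distance and accessibility analysis for spin-labelled
oligomeric membrane channels.

Pentameric mechanosensitive channels such as MscL are studied in lipid
nanodisks by attaching a nitroxide (MTSSL/R1) label to an engineered
cysteine on each subunit and running two pulsed-EPR experiments:
**DEER/PELDOR**, whose dipolar modulation encodes the inter-label
distance distribution P(r), and **three-pulse ESEEM**, whose deuterium
modulation reports how solvent-exposed the labelled site is.  A C5
pentamer has exactly two inter-subunit distances, nearest-neighbour D1
and next-nearest D2, with D2/D1 = 2 cos 36° = 1.618 — so the ratio of
recovered distance peaks is a built-in consistency check on the oligomer,
and percent changes of the deuterium peak between detergent and nanodisk
preparations localize a site relative to the lipid bilayer.

This package implements the complete computational workflow for both
experiments, for spectroscopists who have the time traces and want
defensible distributions and accessibilities:

* the powder-averaged dipolar kernel
  K(t, r) = ∫₀¹ cos[(2πD/r³)(1 − 3x²) t] dx (D from CODATA constants),
* background correction V(t) → F(t) with stretched-exponential
  intermolecular models, including flagged "unphysical" rising fits,
* non-negative Tikhonov inversion
  min‖(1−λ) + λKp − F‖² + α²‖L₂p‖², p ≥ 0, with the modulation depth λ
  fitted internally and α selected on the L-curve,
* the 800-trial validation ensemble (16 background start points × 50
  noise trials, 15 % RMSD filter, mean ± 2σ bands),
* power scaling F → F^(1/(n−1)) to suppress multispin ghost peaks,
* the full 3pESEEM chain: stretched-exponential normalization, Hamming
  apodization, zero-filling, FFT, zero-order phase correction, readout
  at the deuterium Larmor frequency, imaginary-RMSD errors and percent
  changes between conditions,
* an accessible-volume spin-label model that predicts P(r) from a PDB
  structure and a D1/D2 peak analysis,
* a forward simulator of pentameric nitroxide spin systems (DEER and
  ESEEM) so every stage is testable without instrument data,
* plain-text trace/distribution formats, YAML configuration and a
  subcommand CLI that writes reproducibility manifests.

## Worked example

Simulate a pentamer with label ring radius 2.5 nm, recover its distance
distribution through the full pipeline, and check the pentamer ratio:

```r
library(pentaepr)

r_grid <- default_r_grid()                      # 1.5-8 nm, 0.05 nm steps
truth  <- geometry_to_distribution(
  make_cn_geometry(5, ring_radius = 2.5), r_grid, width_sd = 0.1)
trace  <- simulate_deer(truth,
  deer_params(mod_depth = 0.3, noise_sd = 0.01,
              time_axis = seq(0, 5, by = 0.012)), seed = 1)

bg     <- fit_background(trace, fit_start = 1/3)
ff     <- form_factor(trace, bg)
kernel <- build_kernel(trace$t, r_grid)
alpha  <- select_alpha(ff, kernel)
inv    <- tikhonov_invert(ff, kernel, alpha)
detect_peaks(inv$pr)
#> <peak_report> 2 peak(s) at 2.95, 4.75 nm
#>   D2/D1 = 1.610 (pentamer-consistent: TRUE)
```

The two recovered modes sit on the grid points nearest the true pentagon
distances (2.939 and 4.755 nm) and their ratio matches the symmetric
pentamer value 1.62 to the stated precision;
`print(inv)` additionally reports the fitted modulation depth
(`mod depth = 0.298` against the programmed 0.3).  The stability of such
a distribution under background-correction choices is quantified by
`validate(trace)`, which runs the 800-trial ensemble and returns
pointwise mean ± 2σ envelopes.

Deuterium accessibility of two conditions of the same site, and their
percent change:

```r
nd  <- simulate_3peseem(eseem_params(couplings = list(
         list(nucleus = "2H", k = 0.13, freq = NULL),
         list(nucleus = "1H", k = 0.20, freq = NULL))), seed = 101)
ddm <- simulate_3peseem(eseem_params(couplings = list(
         list(nucleus = "2H", k = 0.10, freq = NULL),
         list(nucleus = "1H", k = 0.20, freq = NULL))), seed = 202)
percent_change(eseem_accessibility(nd), eseem_accessibility(ddm))
#> <accessibility_change> +34.5 % +/- 3.7
```

The interpulse delay defaults to the proton blind spot
`blind_spot_tau(9.5, 2.006)` ≈ 138.8 ns (the customary "~140 ns"), which
suppresses the matrix ¹H line while the ²H line at ≈2.21 MHz survives.

The same steps are available from a shell:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "pentaepr.R", package = "pentaepr"))')
Rscript "$CLI" simulate-deer --seed 1 --out-dir run/
Rscript "$CLI" invert --input run/deer_trace.txt --out-dir run/
Rscript "$CLI" validate --input run/deer_trace.txt --out-dir run/
```

Every run writes a `manifest.json` (config snapshot, seed, input MD5
hashes, package version) so it can be reproduced exactly.

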