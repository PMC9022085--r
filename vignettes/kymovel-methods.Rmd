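---
title: "Line-scan RBC velocimetry: models, simulator and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Line-scan RBC velocimetry: models, simulator and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kymovel)
```

## The measurement and its geometry

A line-scan acquisition sweeps a scan point at velocity
$V_{scan} = P_x F_p$ along a segment of $N_{PxLineVessel}$ pixels inside a
vessel (optionally followed by $N_{PxLineOutVessel}$ pixels outside it, used
for calcium or diameter monitoring), then spends a fraction
$\gamma_{flyback}$ of the line time returning. The line period is

$$T_{line} = (1+\gamma_{flyback})\,N_{PxLineVessel} / (F_p\,\gamma_{vessel}),$$

with $\gamma_{vessel}$ the in-vessel fraction of the line. Because the
galvanometer has inertia $J$ and torque $\tau$, the first and last
$N_{crop} = P_x F_p^2 J/(f\tau)$ pixels of each segment are scanned off the
target velocity; images are cropped by the truncated integer form of
$N_{crop}$ before analysis and the constant-velocity fraction
$\beta = 1 - 2N_{crop}/N_{PxLineVessel}$ enters all model equations in its
continuous form. Sub-pixel $N_{crop}$ therefore crops nothing, which matches
the practical observation that under common settings ($J/\tau \lesssim
8\times10^{-8}\,\mathrm{s^2}$, $F_p \le 200$ kHz) no cropping is needed.

An RBC moving at real speed $v$ is swept by the scan point at relative speed
$V_{scan} \mp v$, so its dark shadow appears stretched (scanning with the
flow, $\varepsilon=+1$) or compressed (against it, $\varepsilon=-1$). In
terms of the *apparent* velocity $V_{RBCapp}$ — the streak slope actually
read from the image — the apparent diameter is exactly

$$D_{RBCapp} = D_{RBC}\,(1 + \varepsilon\,V_{RBCapp}/V_{scan}).$$

All package interfaces use strict SI internally and accept µm / kHz / mm/s
at the constructor boundary, converting once.

## The three estimators and their error models

**Angle.** Candidate integer streak spans $k = N_{scan/RBC}$ define per-line
shears of $\beta N/k$ pixels; the winning shear maximizes the contrast
(variance) of the time-averaged column profile of the sheared image, and the
estimate $V = \beta\gamma_{vessel}P_xF_p/((1+\gamma_{flyback})k)$ is exact on
that lattice. One line of uncertainty on $k$ gives the relative error
$1/(k-1)$, which rises with velocity; the planner conditions bound the
maximal measurable velocity at error level $P$ and the implied minimum pixel
count and pixel size.

The variance of the sheared column profile must be corrected for sampling
noise: a large shear scatters pixels into near-singleton canvas columns whose
means fluctuate by $\sigma^2/n_c$, which would always win the contrast
comparison. The score therefore subtracts the pooled within-column variance
(a one-way ANOVA decomposition), so a shear that merely scatters pixels
scores approximately zero. Exact score ties break toward the lowest velocity
(largest $k$). Vertical stripes (stationary RBCs) leave the unsheared
baseline unbeaten and return a flagged zero-velocity estimate.

**LSPIV.** Every line pair $(i, i+N_{Tline})$ is mean-subtracted and
cross-correlated in the frequency domain with zero-padding to twice the
segment length (making the circular correlation linear); correlograms are
averaged over all pairs and the integer lag of the global maximum is
$N_{mov}$, signed by flow direction. No sub-pixel interpolation is applied:
the estimate lives on the $N_{mov}$ lattice, matching the one-pixel error
model $\Delta V/V = \gamma_{vessel} V_{scan} /
((1+\gamma_{flyback})N_{Tline}N_{PxLineVessel}V)$, which falls with velocity,
pixel count and $N_{Tline}$. Detection failure is declared when the
energy-normalized correlogram peak does not exceed five times the white-noise
null scale $1/\sqrt{N\,n_{pairs}}$; a scale computed from the correlogram's
own spread is *not* used, because healthy correlograms of correlated RBC
trains carry broad structure that inflates it and produces false failures.

**Fourier.** Moving streaks concentrate spectral power on the ridge
$f_T = V f_x$ of the 2-D power spectrum (in the quadrant pair whose
orientation gives the direction). For each positive temporal frequency the
spatial-frequency expectancy $f_{x0}(f_T)$ is computed with power weights —
the per-row density around the ridge is the squared sinc of the
constant-velocity segment window, whose standard deviation is
$\sigma_x \approx 1/(2P_x\pi\sqrt{N/2 - P_xF_p^2J/(f\tau)})$ — and the
relation $f_{x0} = (1/V) f_T$ is fit by weighted least squares through the
origin and inverted. Three numerical choices matter and were selected for
accuracy on ground-truth renders, not for any particular test outcome:

* *Windowed expectancy.* The raw expectancy over the full half-band is badly
  biased: squared-sinc tails integrate over a band that is asymmetric around
  the ridge. The expectancy is restricted to $\pm 1.5\sigma_x$ (about the
  main lobe) around the ridge, on a signed frequency coordinate that
  continues across $f_x = 0$ so windows near zero frequency never truncate.
  Wider windows re-admit the tail bias (and, with defocused RBCs, power
  leaked along $f_T$ from truncated streaks); narrower ones quantize the
  expectancy.
* *Ridge tracking.* Windows are centered on the row peak in a first pass and
  re-centered on the fitted ridge in two refinement passes; rows where the
  ridge crosses a null of the shadow form factor otherwise lock onto
  off-ridge power.
* *Fit orientation.* The noisy quantity is $f_{x0}$; regressing it on the
  exact regressor $f_T$ and inverting the slope avoids the regression
  dilution (systematic underestimate of $V$) that the opposite orientation
  suffers. The opposite orientation remains available
  (`fit_orientation = "ft_on_fx"`). A fit with intercept was evaluated and
  rejected: under heavy noise the intercept trades off against the slope and
  destabilizes the estimate.

The predicted relative error $1/(\pi\sqrt{N/2 - P_xF_p^2J/(f\tau)} - 1)$ is
independent of velocity; the minimum measurable velocity
$2\gamma_{vessel}V_{scan}/((1+\gamma_{flyback})N)$ comes from temporal-axis
pixelation of the spectrum.

## The synthetic generator: what it emulates, and what not

`simulate_linescan()` renders dark top-hat shadows of diameter $D_{RBC}$
(default 6 µm) on bright plasma. RBC centers are laid out with flat random
gaps on $[0, 2D_{RBC}(1-H_t)/H_t]$, so expected linear coverage equals the
tube hematocrit ($H_t$, default 0.35, the average of published cortical and
olfactory-bulb values) with no overlaps. Every pixel is sampled at its own
absolute time $rT_{line} + x/F_p$; cells advance at the real velocity
$v = V_{RBCapp}V_{scan}/(V_{scan}+\varepsilon V_{RBCapp})$ derived from the
requested apparent velocity, so the streak slope equals $V_{RBCapp}$ exactly
and $D_{RBCapp}$ emerges from the geometry rather than being painted in.
Flyback is dead time during which cells keep moving. White noise is uniform
with peak-to-peak amplitude `noise_ratio` (default 1.5) times the
shadow/plasma contrast. Defocused RBCs (cells drifting out of the scanned
line) are visible only during a random sub-window of their transit — two
uniform draws within the transit, sorted — and are otherwise rendered as
plasma; the disappearance is abrupt, not a gradual fade, because the fade
profile of real defocusing is not constrained by anything this package can
check. Default intensities are plasma 200 / RBC 50 on the 16-bit scale,
arbitrary but fixed for reproducibility.

The generator deliberately omits: pulsatile or radially-varying velocity,
RBC deformation and rouleaux, smooth shadow profiles (a Gaussian-blur option
can be layered on by filtering the rendered image), scanner-acceleration
artifacts (the validation regimes all have $N_{crop}\approx 0$), and shot
noise statistics. A green closed-loop test therefore establishes that the
estimators and error models are mutually consistent under the stated noise
and defocus model — not that they are robust to every artifact of real
microscope data.

## Validation protocols

`run_validation()` reproduces the published protocol: 1.2 s renders, inertia
crop, 3×3 median filter (the default kernel; the filter choice is exposed),
0.1 s sections with the first and last discarded, per-section relative error
$(\hat V - V)/V$, and the per-image maximum of the ten absolute errors.
`closed_loop_conditions()` pins one model-feasible setting per algorithm
(angle: $P_x$ = 1 µm, $F_p$ = 200 kHz, $N$ = 100, $v$ = 10 mm/s; LSPIV:
$P_x$ = 0.5 µm, $N$ = 100, $N_{Tline}$ = 5, $v$ = 3 mm/s; Fourier: same scan,
$v$ = 3 mm/s). `defocus_conditions()` crosses defocus fractions 0–100% with
all three algorithms at $v$ = 5.33 mm/s, $N$ = 120, $P_x$ = 0.8 µm,
$F_p$ = 400 kHz, retrograde scanning; its $N_{Tline}$ is the smallest integer
satisfying the minimum-velocity pixel bound at those settings (which is 4;
the target velocity then sits within 0.1% of the $N_{mov}=12$ lattice
point). Twenty seeds per condition are used by default; replicate counts are
a package choice, since single realizations per condition would make the
verdict a coin flip.

## Degenerate inputs and conventions

Zero velocity renders vertical stripes: the angle estimator reports "no
streaks" (flagged zero), LSPIV returns the zero-lag peak, and the spectral
estimator returns a flagged zero when nothing survives zeroing the
zero-frequency axes. Fewer than three usable temporal frequencies (after
discarding rows carrying only numerical leakage) raise a sparse-spectrum
error; a flat correlogram raises a correlation-failure error. The validation
harness records such failures per section instead of propagating them.
Section boundaries are half-open, indices 0-based in the geometry and
1-based in R containers, and remainder lines after the last full section are
discarded.

## Known limitations and boundary behavior

* The planner evaluates the printed inequality system literally. On default
  grids its venule panel shows a thin boundary sliver (five cells at the
  largest pixel sizes, $N$ = 56–65, retrograde, 200 kHz) where a large
  $N_{Tline}$ makes LSPIV feasible down to 2 mm/s while the spectral
  minimum-velocity bound still excludes the Fourier algorithm; the
  figure-level claim that the Fourier region contains the LSPIV region holds
  everywhere else. This is a property of the inequalities near their
  boundary, not of the estimators.
* The capillary preset uses 0.1–1 mm/s; 2 mm/s appears as an upper bound for
  capillaries in some descriptions, and can be requested explicitly via
  `vessel_profile("capillary", 0.1, 2)`.
* LSPIV feasibility requires one $N_{Tline}$ valid across the whole velocity
  range, matching how an experimenter fixes it at analysis time.
* The angle error model assumes integer streak spans; the `k_grid` argument
  of `estimate_angle()` admits a finer grid, but estimates then leave the
  lattice the error model describes.
* The spectral error model ignores noise (it models pixelation only), and
  its velocity-independent error prediction interacts with the
  minimum-velocity bound near that boundary; both are reported and no
  blending between them is invented.
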