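# kymovel

Red blood cell (RBC) velocimetry from laser line-scan (kymograph) images.

## The problem

Laser scanning microscopes measure blood velocity by scanning a single line
along a vessel axis over and over. Stacking the scanned lines produces a
space–time (XT) image in which every unlabeled RBC, moving through the
fluorescent plasma, leaves an oblique dark streak; the streak slope encodes
the *apparent* RBC velocity V<sub>RBCapp</sub>. Three image-processing
algorithms are in routine use to read that slope:

* **Angle** — shear the image until the streaks are horizontal; a streak that
  spans N<sub>scan/RBC</sub> lines gives
  V = β·γ<sub>vessel</sub>·P<sub>x</sub>·F<sub>p</sub> /
  ((1+γ<sub>flyback</sub>)·N<sub>scan/RBC</sub>), a discrete velocity lattice
  with relative pixelation error 1/(N<sub>scan/RBC</sub>−1);
* **LSPIV** — cross-correlate line pairs separated by N<sub>Tline</sub>
  periods; the integer peak lag N<sub>mov</sub> gives
  V = γ<sub>vessel</sub>·N<sub>mov</sub>·V<sub>scan</sub> /
  ((1+γ<sub>flyback</sub>)·N<sub>Tline</sub>·N<sub>PxLineVessel</sub>), with
  relative error equal to one lattice step (N<sub>mov</sub> = 1);
* **Fourier** — in the 2-D power spectrum the streaks form a ridge
  f<sub>T</sub> = V·f<sub>x</sub>; regressing the per-temporal-frequency
  spatial-frequency expectancy on f<sub>T</sub> gives a continuous estimate
  with relative error ≈ 1/(π·√(N/2 − P<sub>x</sub>F<sub>p</sub>²J/(fτ)) − 1).

Each algorithm is accurate only in a specific region of the scanning
parameter space (pixel size, pixel clock, pixels per line, scan direction,
velocity range). `kymovel` implements the three estimators, the closed-form
pixelation error models that predict when each is trustworthy, a planner
that maps the feasible (P<sub>x</sub>, N<sub>PxLineVessel</sub>) region for
typical vessels (arteriole, venule, capillary), and a synthetic kymograph
generator (tube hematocrit, RBC defocusing, white noise, flyback dead time)
used to validate the whole chain against known ground truth.

## Worked example

```r
library(kymovel)

cfg  <- scan_config(px_size_um = 0.5, pixel_clock_khz = 200, n_px_vessel = 100)
flow <- flow_config(v_app_mms = 3, hematocrit = 0.35, noise_ratio = 1.5)

img      <- simulate_linescan(cfg, flow, duration = 1.2, seed = 1)
sections <- preprocess_linescan(img)   # crop, 3x3 median, 0.1 s sections
sapply(sections, function(s) estimate_lspiv(s, n_tline = 5)$v_app * 1e3)
#>  [1] 2.933 2.933 2.933 2.933 2.933 2.933 2.933 2.933 2.933 2.933
sapply(sections, function(s) estimate_fourier(s)$v_app * 1e3)
#>  [1] 3.027 3.049 3.011 2.966 3.044 3.003 2.949 3.016 3.050 2.969
```

The LSPIV estimate sits on its velocity lattice (2.933 mm/s is the
N<sub>mov</sub> = 22 point; the true 3 mm/s lies between the 22 and 23
points, a 2.2% pixelation error, within the 4.4% the error model predicts
for N<sub>Tline</sub> = 5). The Fourier estimate is continuous and lands
within its predicted 4.7%. The models say when to trust this:

```r
lspiv_bounds(cfg, p_pct = 10, v_target = 3e-3, n_tline = 5)
#> <error_budget: lspiv> FEASIBLE at P = 10% for v = 3 mm/s
#>   predicted relative error: 0.0444
#>   measurable range: 1.333 .. 4.965 mm/s
#>   min n_px_vessel: 71   min px: 0 um
#>   admissible n_tline: 1 .. 11

recommend(vessel_profile("capillary"), scan_config(0.5, 200, 100, 100, direction = -1))$ranking
#>   algorithm    area
#> 1     angle 0.77500
#> 2     lspiv 0.29500
#> 3   fourier 0.17375
```

For a capillary, the angle algorithm covers the largest share of the
scanning parameter space, as expected for low velocities.

## Command line

```sh
inst/exec/kymovel simulate --v-mms 5.33 --n-px 120 --px-um 0.8 --fp-khz 400 --seed 1 --out out/
inst/exec/kymovel estimate --input out/linescan.tif --algorithm lspiv --ntline 4 --out est/
inst/exec/kymovel plan     --vessel capillary --fp-khz 200 --direction retro --error-pct 10 --out plan.csv
inst/exec/kymovel validate --protocol defocus --seeds 20 --out validation.csv
```

Images travel as 16-bit grayscale TIFF (rows = time) with a JSON sidecar
carrying the scan configuration and, for synthetic data, the ground truth.

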