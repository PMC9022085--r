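# Shared fixtures and independent oracles. All fixtures are built in code.

# Config with an explicit lumped inertia term J/(f*tau) in s^2/m, as the
# model-equation worked examples state it.
cfg_jft <- function(px_um, fp_khz, n_px, jft = 0, n_out = 0, gamma_flyback = 0.5,
                    direction = 1L) {
  f_m <- 4.5e-3
  scan_config(px_size_um = px_um, pixel_clock_khz = fp_khz, n_px_vessel = n_px,
              n_px_out_vessel = n_out, gamma_flyback = gamma_flyback,
              inertia_ratio_s2 = jft * f_m, focal_length_mm = f_m * 1e3,
              direction = direction)
}

# Noiseless render convenience (exact streak geometry, no defocus).
render_clean <- function(cfg, v_mms, duration = 0.2, seed = 42,
                         intra_line_sampling = TRUE, d_rbc_um = 6,
                         hematocrit = 0.35) {
  flow <- flow_config(v_mms, d_rbc_um = d_rbc_um, hematocrit = hematocrit,
                      noise_ratio = 0)
  simulate_linescan(cfg, flow, duration = duration, seed = seed,
                    intra_line_sampling = intra_line_sampling)
}

# Brute-force spatial-domain cross-correlation oracle: pair-averaged linear
# correlogram and its argmax lag, computed by direct summation.
bf_lspiv_peak <- function(seg, n_tline) {
  seg <- seg - rowMeans(seg)
  nr <- nrow(seg); w <- ncol(seg)
  lags <- -(w - 1):(w - 1)
  cc <- vapply(lags, function(lag) {
    tot <- 0
    for (i in seq_len(nr - n_tline)) {
      a <- seg[i, ]; b <- seg[i + n_tline, ]
      xs <- seq_len(w)
      keep <- xs + lag >= 1 & xs + lag <= w
      tot <- tot + sum(a[keep] * b[xs[keep] + lag])
    }
    tot / (nr - n_tline)
  }, numeric(1))
  lags[which.max(cc)]
}

# Run lengths of dark pixels in one row (shadow width oracle).
dark_runs <- function(row, thresh) {
  r <- rle(row < thresh)
  r$lengths[r$values]
}
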