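#' @title Velocity estimators for line-scan images
#' @description
#' Three independent estimators of the apparent RBC velocity of a
#' (pre-processed) line-scan section: streak-angle by shear alignment, LSPIV
#' by averaged per-line-pair cross-correlation, and 2-D Fourier spectral-slope
#' regression. All return a signed velocity: positive when streaks advance
#' toward increasing column index over time, negative otherwise (so flipping
#' the scan direction flips the sign). All consume only the vessel-segment
#' columns.
#' @name estimators
NULL

velocity_estimate <- function(v_app, algorithm, params = list(),
                              section_index = NULL, ok = TRUE) {
  structure(
    list(v_app = v_app, algorithm = algorithm, params = params,
         section_index = section_index, ok = ok),
    class = "velocity_estimate"
  )
}

#' @export
print.velocity_estimate <- function(x, ...) {
  cat(sprintf("<velocity_estimate: %s> v_app = %.4g mm/s%s\n",
              x$algorithm, x$v_app * 1e3,
              if (!x$ok) " (no streaks detected)" else ""))
  invisible(x)
}

#' Streak-angle velocity estimate by shear alignment
#'
#' Applies candidate shear transforms to the image until RBC streaks are
#' vertical in the sheared frame: for each candidate integer streak span `k`
#' (lines per RBC transit) the per-line column shift is `width / k` pixels,
#' and alignment is scored as the count-weighted variance of the time-averaged
#' column profile of the sheared image. The arg-max candidate gives the
#' velocity `width * px / (k * t_line)`, which lies on the discrete
#' angle-algorithm lattice by construction. Both flow directions are tried;
#' exact score ties are broken toward the lowest velocity.
#'
#' If no candidate scores above the unsheared baseline (vertical stripes,
#' e.g. stationary RBCs), the estimate is 0 with `ok = FALSE`.
#'
#' @param img A cropped [linescan_image()] with at least 2 lines.
#' @param k_grid Optional numeric vector of candidate streak spans; defaults
#'   to the integers `2:(n_rows - 1)` that the pixelation error model assumes.
#'   A finer grid gives sub-line resolution outside that model.
#' @return A [velocity_estimate()].
#' @export
estimate_angle <- function(img, k_grid = NULL) {
  seg <- vessel_segment(img)
  nr <- nrow(seg)
  if (nr < 2) {
    stop(kymovel_condition("kymovel_domain_error", "need at least 2 lines"))
  }
  w <- ncol(seg)
  ks <- if (is.null(k_grid)) seq(2, nr - 1) else sort(k_grid, decreasing = TRUE)
  # order by increasing |velocity| (decreasing k), positive direction first,
  # so the first maximum is the lowest-velocity tie
  cand <- data.frame(
    k = rep(rev(sort(ks)), each = 2),
    sign = rep(c(1, -1), length(ks))
  )
  shifts <- cand$sign * w / cand$k
  scores <- shear_scores(seg, c(0, shifts))
  baseline <- scores[1]
  scores <- scores[-1]
  best <- which.max(scores)
  if (scores[best] <= baseline) {
    return(velocity_estimate(0, "angle",
                             params = list(n_scan_per_rbc = NA_integer_,
                                           baseline_score = baseline),
                             section_index = img$section_index, ok = FALSE))
  }
  k <- cand$k[best]
  # a streak advancing +d pixels per line is aligned by shifting row r by -d*r,
  # so the velocity sign is opposite to the winning shift sign
  v <- -cand$sign[best] * w * img$cfg$px_size / (k * img$t_line)
  velocity_estimate(v, "angle",
                    params = list(n_scan_per_rbc = k,
                                  score = scores[best],
                                  baseline_score = baseline),
                    section_index = img$section_index)
}

#' LSPIV velocity estimate by averaged cross-correlation
#'
#' For every line pair `(i, i + n_tline)` the mean-subtracted intensity
#' profiles are cross-correlated in the frequency domain with zero-padding to
#' twice the segment length (suppressing wrap-around); the correlograms are
#' averaged over all pairs in the section and the integer lag of the global
#' maximum gives the displacement `n_mov` in pixels (its sign, the flow
#' direction). The velocity `n_mov * px / (n_tline * t_line)` lies on the
#' LSPIV lattice by construction; no sub-pixel interpolation is applied,
#' matching the one-pixel error model.
#'
#' @param img A [linescan_image()] with more rows than `n_tline`.
#' @param n_tline Line separation between correlated rows (default 1).
#' @param check_validity Warn when the segment is shorter than the
#'   two-apparent-shadow minimum at default RBC diameter and hematocrit.
#' @return A [velocity_estimate()].
#' @export
estimate_lspiv <- function(img, n_tline = 1, check_validity = TRUE) {
  seg <- vessel_segment(img)
  nr <- nrow(seg)
  w <- ncol(seg)
  n_tline <- as.integer(n_tline)
  if (n_tline < 1 || nr <= n_tline) {
    stop(kymovel_condition(
      "kymovel_domain_error",
      sprintf("need n_tline >= 1 and more than n_tline = %d rows (have %d)", n_tline, nr)
    ))
  }
  seg <- seg - rowMeans(seg)
  padded <- cbind(seg, matrix(0, nr, w))
  ft <- stats::mvfft(t(padded)) # columns = lines, length 2w
  a <- ft[, seq_len(nr - n_tline), drop = FALSE]
  b <- ft[, seq_len(nr - n_tline) + n_tline, drop = FALSE]
  cross <- rowMeans(Conj(a) * b)
  cc <- Re(stats::fft(cross, inverse = TRUE)) / (2 * w)
  # index m (0-based) carries lag m for m < w, lag m - 2w for m > w
  lags <- c(0:(w - 1), NA, -((w - 1):1))
  valid <- !is.na(lags)
  cc_valid <- cc[valid]
  lag_valid <- lags[valid]
  peak <- which.max(cc_valid)
  # flatness test: the correlogram of real streaks carries broad structure of
  # its own, so a scale taken from the correlogram itself is unreliable.
  # Normalize the peak by the row energies; under the white-noise null each
  # normalized bin has SD 1/sqrt(w * n_pairs), and the peak must clear 5 of
  # those.
  n_pairs <- nr - n_tline
  e_a <- mean(rowSums(seg[seq_len(n_pairs), , drop = FALSE]^2))
  e_b <- mean(rowSums(seg[seq_len(n_pairs) + n_tline, , drop = FALSE]^2))
  rho_peak <- cc_valid[peak] / sqrt(e_a * e_b)
  if (!is.finite(rho_peak) || rho_peak <= 5 / sqrt(w * n_pairs)) {
    stop(kymovel_condition(
      "kymovel_correlation_failed",
      "normalized correlogram peak below the white-noise detection level: correlation failed"
    ))
  }
  n_mov <- lag_valid[peak]
  v <- n_mov * img$cfg$px_size / (n_tline * img$t_line)
  if (check_validity) {
    n_req <- .em_min_n_two_shadows(img$cfg$px_size, img$cfg$pixel_clock,
                                   j_over_ftau(img$cfg), img$cfg$direction,
                                   abs(v), 6e-6, 0.35)
    if (w < n_req) {
      warning(sprintf(
        "vessel segment (%d px) shorter than the two-shadow minimum (%.0f px at default D_RBC/Ht): LSPIV may be unreliable",
        w, n_req))
    }
  }
  velocity_estimate(v, "lspiv",
                    params = list(n_mov = n_mov, n_tline = n_tline,
                                  peak = cc_valid[peak]),
                    section_index = img$section_index)
}

#' Fourier spectral-slope velocity estimate
#'
#' Computes the power spectrum (squared modulus of the 2-D discrete Fourier
#' transform) of the mean-subtracted vessel segment, zeroes the
#' zero-frequency axes, and picks the dominant diagonal quadrant pair (whose
#' orientation gives the flow direction). For each positive temporal
#' frequency `f_T` the expectancy `f_x0(f_T)` of the spatial frequency is
#' computed power-weighted within a window of about 1.5 squared-sinc
#' standard deviations (the main lobe) around the spectral ridge, on a signed frequency
#' coordinate that continues across `f_x = 0` so windows never truncate (raw
#' full-band expectancies are badly biased by the squared-sinc tails over the
#' asymmetric band). The window is centered on the row peak in a first pass
#' and re-centered on the fitted ridge in two refinement passes, which keeps
#' rows near the shadow form-factor nulls from locking onto off-ridge power.
#' The relation `f_x0 = (1/V) * f_T` is fit by weighted least squares through
#' the origin and inverted; regressing the noisy expectancy on the exact
#' temporal frequency avoids the attenuation (regression-dilution) the
#' opposite orientation suffers, which is why it is the default. The slope
#' `V` is the apparent velocity (continuous-valued, unlike the two lattice
#' estimators).
#'
#' @param img A cropped [linescan_image()].
#' @param check_validity Warn when the segment is shorter than the
#'   error-model minimum pixel count.
#' @param fit_orientation `"fx_on_ft"` (default; regress `f_x0` on `f_T` and
#'   invert) or `"ft_on_fx"` (regress `f_T` on `f_x0` directly).
#' @return A [velocity_estimate()].
#' @export
estimate_fourier <- function(img, check_validity = TRUE,
                             fit_orientation = c("fx_on_ft", "ft_on_fx")) {
  fit_orientation <- match.arg(fit_orientation)
  seg <- vessel_segment(img)
  nr <- nrow(seg)
  w <- ncol(seg)
  if (nr < 8 || w < 4) {
    stop(kymovel_condition("kymovel_domain_error", "image too small for spectral estimation"))
  }
  total_before <- sum((seg - mean(seg))^2)
  m <- Mod(stats::fft(seg - mean(seg)))^2
  m[1, ] <- 0 # f_T = 0 axis
  m[, 1] <- 0 # f_x = 0 axis
  if (sum(m) <= 1e-12 * max(total_before, 1)) {
    # vertical stripes or empty image: documented zero-velocity convention
    return(velocity_estimate(0, "fourier",
                             params = list(n_freqs = 0L),
                             section_index = img$section_index, ok = FALSE))
  }
  f_t <- dft_freqs(nr) / (nr * img$t_line)
  f_x <- dft_freqs(w) / (w * img$cfg$px_size)
  pos_t <- which(f_t > 0)
  pos_x <- which(f_x > 0)
  neg_x <- which(f_x < 0)
  # motion toward +x concentrates energy where f_x and f_T have opposite signs
  e_opposite <- sum(m[pos_t, neg_x])
  e_same <- sum(m[pos_t, pos_x])
  sign_v <- if (e_opposite >= e_same) 1 else -1
  # signed ridge coordinate: the signal ridge sits at xi = f_T / |V| > 0 and
  # continues smoothly across f_x = 0, so expectancy windows never truncate
  xi <- -sign_v * f_x
  ord <- order(xi)
  xi_s <- xi[ord]
  dbin <- 1 / (w * img$cfg$px_size)
  # expectancy window: +-1.5 sigma_x of the squared-sinc density (about the
  # main lobe), in bins; wider windows mix in off-ridge power whose
  # form-factor tilt biases the expectancy, narrower ones quantize it
  sigma_bins <- w / (2 * pi * sqrt(max(w / 2, 2)))
  halfwin <- max(2L, ceiling(1.5 * sigma_bins))

  # collect per-row expectancies; windows centered on the row peak (pass 1)
  # or on the ridge predicted by a previous fit (later passes), which keeps
  # rows near the shadow form-factor nulls from locking onto off-ridge power
  collect <- function(v_pred) {
    fx0 <- numeric(0); ft_i <- numeric(0); w_i <- numeric(0)
    for (i in pos_t) {
      row <- m[i, ord]
      if (is.na(v_pred)) {
        on_signal <- which(xi_s > 0)
        pk <- on_signal[which.max(row[on_signal])]
      } else {
        ctr <- f_t[i] / v_pred
        pk <- which.min(abs(xi_s - ctr))
        if (abs(xi_s[pk] - ctr) > dbin) next # ridge beyond Nyquist
      }
      win <- max(1, pk - halfwin):min(length(row), pk + halfwin)
      s <- sum(row[win])
      if (s > 0) {
        fx0 <- c(fx0, sum(xi_s[win] * row[win]) / s)
        ft_i <- c(ft_i, f_t[i])
        w_i <- c(w_i, s)
      }
    }
    # rows carrying only numerical leakage are not usable temporal frequencies
    keep <- w_i > 1e-9 * max(w_i, 0)
    list(fx0 = fx0[keep], ft = ft_i[keep], w = w_i[keep])
  }
  fit_v <- function(d) {
    if (fit_orientation == "fx_on_ft") {
      sum(d$w * d$ft^2) / sum(d$w * d$ft * d$fx0)
    } else {
      sum(d$w * d$ft * d$fx0) / sum(d$w * d$fx0^2)
    }
  }
  d <- collect(NA)
  if (length(d$ft) < 3) {
    stop(kymovel_condition(
      "kymovel_sparse_spectrum",
      sprintf("only %d usable temporal frequencies: spectrum too sparse", length(d$ft))
    ))
  }
  v <- fit_v(d)
  for (pass in 1:2) {
    if (!is.finite(v) || v <= 0) break
    d2 <- collect(v)
    if (length(d2$ft) >= 3) {
      v <- fit_v(d2)
      d <- d2
    }
  }
  if (!is.finite(v)) {
    stop(kymovel_condition(
      "kymovel_sparse_spectrum", "spectral fit degenerate: no usable ridge"
    ))
  }
  if (check_validity) {
    n_req <- .em_ft_min_n_err(img$cfg$px_size, img$cfg$pixel_clock,
                              j_over_ftau(img$cfg), 10)
    if (w < n_req) {
      warning(sprintf(
        "vessel segment (%d px) below the spectral error-model minimum (%.0f px at P = 10%%)",
        w, n_req))
    }
  }
  velocity_estimate(sign_v * v, "fourier",
                    params = list(n_freqs = length(d$ft),
                                  fit_weights_total = sum(d$w)),
                    section_index = img$section_index)
}

# Signed DFT bin indices: 0, 1, ..., floor(n/2), -(ceil(n/2)-1), ..., -1
dft_freqs <- function(n) {
  k <- 0:(n - 1)
  ifelse(k <= n / 2, k, k - n)
}

#' Estimate velocity with a chosen algorithm
#'
#' Thin dispatcher over [estimate_angle()], [estimate_lspiv()] and
#' [estimate_fourier()].
#'
#' @param img A [linescan_image()].
#' @param algorithm One of `"angle"`, `"lspiv"`, `"fourier"`.
#' @param n_tline Line separation for LSPIV.
#' @param ... Passed to the selected estimator.
#' @return A [velocity_estimate()].
#' @export
estimate_velocity <- function(img, algorithm = c("angle", "lspiv", "fourier"),
                              n_tline = 1, ...) {
  algorithm <- match.arg(algorithm)
  switch(algorithm,
         angle = estimate_angle(img, ...),
         lspiv = estimate_lspiv(img, n_tline = n_tline, ...),
         fourier = estimate_fourier(img, ...))
}
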