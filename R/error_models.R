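#' @title Analytic error models for the three velocimetry algorithms
#' @description
#' Closed-form predictions of each algorithm's velocity lattice, pixelation
#' relative error, and minimum/maximum measurable velocity, together with the
#' pixel-count feasibility conditions used by the scanning-parameter planner.
#' All velocities are in m/s and error levels `p_pct` in percent at this
#' interface; fractions are returned as plain numbers (0.1 = 10%).
#' @name error_models
NULL

# ---- internal numeric forms (vectorized; arguments in SI units) -------------
# px: pixel size m; fp: pixel clock Hz; n: N_PxLineVessel; gv: gamma_vessel;
# gf: gamma_flyback; jft: J/(f*tau) s^2/m; eps: scan direction +-1.

.em_beta <- function(px, fp, n, jft) 1 - 2 * px * fp^2 * jft / n

.em_angle_v <- function(px, fp, n, gv, gf, jft, k) {
  .em_beta(px, fp, n, jft) * gv * px * fp / ((1 + gf) * k)
}

.em_angle_relerr_v <- function(px, fp, n, gv, gf, jft, v) {
  den <- .em_beta(px, fp, n, jft) * gv * px * fp - (1 + gf) * v
  ifelse(den > 0, (1 + gf) * v / den, Inf)
}

.em_angle_vmax <- function(px, fp, n, gv, gf, jft, p_pct) {
  .em_beta(px, fp, n, jft) * gv * px * fp / ((1 + 100 / p_pct) * (1 + gf))
}

# Minimum N_PxLineVessel for the angle algorithm at error level p_pct and
# target velocity v (planner form of the beta > threshold condition).
.em_angle_min_n <- function(px, fp, gv, gf, jft, p_pct, v) {
  den <- gv * px * fp - (1 + 100 / p_pct) * (1 + gf) * v
  ifelse(den > 0, 2 * gv * px^2 * fp^3 * jft / den, Inf)
}

# Minimum pixel size for the angle algorithm (inertia-free condition).
.em_angle_min_px <- function(fp, gv, gf, p_pct, v) {
  (1 + 100 / p_pct) * (1 + gf) * v / (gv * fp)
}

.em_lspiv_v <- function(px, fp, n, gv, gf, n_mov, n_tline) {
  gv * n_mov * px * fp / ((1 + gf) * n_tline * n)
}

.em_lspiv_relerr <- function(px, fp, n, gv, gf, n_tline, v) {
  ifelse(v > 0, .em_lspiv_v(px, fp, n, gv, gf, 1, n_tline) / v, Inf)
}

.em_lspiv_vmin <- function(px, fp, n, gv, gf, n_tline, p_pct) {
  100 * gv * px * fp / (p_pct * (1 + gf) * n_tline * n)
}

# Minimum N so the constant-velocity segment holds two apparent shadows and
# the plasma between them at hematocrit ht (shared by LSPIV and Fourier).
.em_min_n_two_shadows <- function(px, fp, jft, eps, v, d_rbc, ht) {
  2 * d_rbc / (ht * px) * (1 + eps * v / (px * fp)) + 2 * px * fp^2 * jft
}

.em_lspiv_vmax <- function(px, fp, n, gv, gf, jft, eps, n_tline, d_rbc) {
  num <- gv * px * (n * px * fp - 2 * px^2 * fp^3 * jft - 2 * d_rbc * fp)
  den <- 2 * (1 + gf) * px * n_tline * n + 2 * eps * gv * d_rbc
  ifelse(den <= 0, Inf, pmax(num / den, 0))
}

# Minimum N so the segment fits two shadows plus their motion over n_tline
# lines at velocity v.
.em_lspiv_min_n_motion <- function(px, fp, gv, gf, jft, eps, n_tline, v, d_rbc) {
  num <- 2 * gv * d_rbc * (px * fp + eps * v) + 2 * gv * px^3 * fp^3 * jft
  den <- gv * px^2 * fp - 2 * (1 + gf) * n_tline * px * v
  ifelse(den > 0, num / den, Inf)
}

.em_ntline_max <- function(px, fp, gv, gf, v) {
  gv * px * fp / (2 * (1 + gf) * v)
}

# Minimum N so v is at or above the LSPIV p_pct minimum velocity.
.em_lspiv_min_n_vmin <- function(px, fp, gv, gf, p_pct, n_tline, v) {
  100 * gv * px * fp / ((1 + gf) * p_pct * n_tline * v)
}

.em_ft_sigma_x <- function(px, fp, n, jft) {
  rad <- n / 2 - px * fp^2 * jft
  ifelse(rad > 0, 1 / (2 * px * pi * sqrt(rad)), NaN)
}

.em_ft_relerr <- function(px, fp, n, jft) {
  rad <- n / 2 - px * fp^2 * jft
  den <- pi * sqrt(pmax(rad, 0)) - 1
  ifelse(rad > 0 & den > 0, 1 / den, Inf)
}

.em_ft_min_n_err <- function(px, fp, jft, p_pct) {
  2 * (((100 + p_pct) / (pi * p_pct))^2 + px * fp^2 * jft)
}

.em_ft_vmin <- function(px, fp, n, gv, gf) {
  2 * gv * px * fp / ((1 + gf) * n)
}

# Minimum N so v is at or above the Fourier minimum velocity.
.em_ft_min_n_vmin <- function(px, fp, gv, gf, v) {
  2 * gv * px * fp / ((1 + gf) * v)
}

# ---- exported cfg-based interface -------------------------------------------

#' Velocity lattice of the angle algorithm
#'
#' The apparent velocity corresponding to a streak spanning `n_scan_per_rbc`
#' lines: `beta * gamma_vessel * px * fp / ((1 + gamma_flyback) * k)`. Because
#' `k` is an integer, the angle estimator can only return these discrete
#' values.
#'
#' @param cfg A [scan_config()].
#' @param n_scan_per_rbc Integer streak span in lines (k >= 1); vectorized.
#' @return Velocity, m/s.
#' @export
angle_velocity <- function(cfg, n_scan_per_rbc) {
  if (any(n_scan_per_rbc < 1)) {
    stop(kymovel_condition("kymovel_domain_error", "n_scan_per_rbc must be >= 1"))
  }
  beta_constant_fraction(cfg) # validates beta > 0
  .em_angle_v(cfg$px_size, cfg$pixel_clock, cfg$n_px_vessel, gamma_vessel(cfg),
              cfg$gamma_flyback, j_over_ftau(cfg), n_scan_per_rbc)
}

#' Relative pixelation error of the angle algorithm
#'
#' One-line uncertainty on the streak span gives a relative error of
#' `1 / (k - 1)`; the velocity-parameterized form is algebraically identical
#' on lattice points. Supply exactly one of `v_app` or `n_scan_per_rbc`.
#'
#' @param cfg A [scan_config()].
#' @param v_app Apparent velocity, m/s.
#' @param n_scan_per_rbc Integer streak span (>= 2).
#' @return Relative error as a fraction.
#' @export
angle_relative_error <- function(cfg, v_app = NULL, n_scan_per_rbc = NULL) {
  if (is.null(v_app) == is.null(n_scan_per_rbc)) {
    stop(kymovel_condition(
      "kymovel_domain_error", "supply exactly one of v_app or n_scan_per_rbc"
    ))
  }
  if (!is.null(n_scan_per_rbc)) {
    if (any(n_scan_per_rbc < 2)) {
      stop(kymovel_condition(
        "kymovel_domain_error",
        "angle relative error is undefined for n_scan_per_rbc < 2"
      ))
    }
    return(1 / (n_scan_per_rbc - 1))
  }
  beta_constant_fraction(cfg)
  err <- .em_angle_relerr_v(cfg$px_size, cfg$pixel_clock, cfg$n_px_vessel,
                            gamma_vessel(cfg), cfg$gamma_flyback,
                            j_over_ftau(cfg), v_app)
  if (any(!is.finite(err))) {
    stop(kymovel_condition(
      "kymovel_domain_error",
      "v_app at or above the k = 1 lattice point: relative error undefined"
    ))
  }
  err
}

#' Feasibility budget for the angle algorithm
#'
#' Collects the maximal measurable velocity at error level `p_pct`, the
#' minimum vessel pixel count, and the minimum pixel size for measuring
#' `v_target`, plus a feasibility verdict for the supplied configuration.
#'
#' @param cfg A [scan_config()].
#' @param p_pct Tolerated relative error, percent (0 < p < 100).
#' @param v_target Velocity to be measured, m/s.
#' @return An object of class `error_budget`.
#' @export
angle_bounds <- function(cfg, p_pct, v_target) {
  check_p(p_pct)
  gv <- gamma_vessel(cfg); gf <- cfg$gamma_flyback; jft <- j_over_ftau(cfg)
  v_max <- .em_angle_vmax(cfg$px_size, cfg$pixel_clock, cfg$n_px_vessel, gv, gf, jft, p_pct)
  min_n <- .em_angle_min_n(cfg$px_size, cfg$pixel_clock, gv, gf, jft, p_pct, v_target)
  min_px <- .em_angle_min_px(cfg$pixel_clock, gv, gf, p_pct, v_target)
  rel <- .em_angle_relerr_v(cfg$px_size, cfg$pixel_clock, cfg$n_px_vessel, gv, gf, jft, v_target)
  feasible <- is.finite(min_n) && cfg$n_px_vessel >= ceiling(min_n) &&
    cfg$px_size >= min_px && v_target <= v_max
  error_budget("angle", rel_error = rel, v_min = 0, v_max = v_max,
               min_n_px_vessel = ceiling_or_inf(min_n), min_px_size = min_px,
               feasible = feasible, p_pct = p_pct, v_target = v_target)
}

#' Velocity lattice of the LSPIV algorithm
#'
#' Velocity for an integer correlogram peak lag `n_mov` between lines
#' separated by `n_tline` line periods.
#'
#' @param cfg A [scan_config()].
#' @param n_mov Integer displacement in pixels (>= 0); vectorized.
#' @param n_tline Line separation (>= 1).
#' @return Velocity, m/s.
#' @export
lspiv_velocity <- function(cfg, n_mov, n_tline = 1) {
  if (any(n_tline < 1) || any(n_mov < 0)) {
    stop(kymovel_condition("kymovel_domain_error", "need n_tline >= 1 and n_mov >= 0"))
  }
  .em_lspiv_v(cfg$px_size, cfg$pixel_clock, cfg$n_px_vessel, gamma_vessel(cfg),
              cfg$gamma_flyback, n_mov, n_tline)
}

#' Relative pixelation error of the LSPIV algorithm
#'
#' One-pixel uncertainty on the correlogram peak, relative to the measured
#' velocity: decreases with velocity, `n_tline` and the pixel count.
#'
#' @inheritParams lspiv_velocity
#' @param v_app Apparent velocity, m/s (> 0).
#' @return Relative error as a fraction (Inf flagged at `v_app = 0`).
#' @export
lspiv_relative_error <- function(cfg, v_app, n_tline = 1) {
  .em_lspiv_relerr(cfg$px_size, cfg$pixel_clock, cfg$n_px_vessel,
                   gamma_vessel(cfg), cfg$gamma_flyback, n_tline, v_app)
}

#' Feasibility budget for the LSPIV algorithm
#'
#' Collects the minimum measurable velocity at error level `p_pct`, the
#' maximum trackable velocity, the pixel-count requirements (two apparent
#' shadows at the tube hematocrit; two shadows plus motion over `n_tline`
#' lines; the minimum-velocity condition), the admissible `n_tline` interval,
#' and a feasibility verdict for `v_target`.
#'
#' @inheritParams angle_bounds
#' @param n_tline Line separation used at analysis time.
#' @param d_rbc RBC diameter, meters.
#' @param hematocrit Tube hematocrit in (0, 1).
#' @return An object of class `error_budget`.
#' @export
lspiv_bounds <- function(cfg, p_pct, v_target, n_tline = 1,
                         d_rbc = 6e-6, hematocrit = 0.35) {
  check_p(p_pct)
  px <- cfg$px_size; fp <- cfg$pixel_clock; n <- cfg$n_px_vessel
  gv <- gamma_vessel(cfg); gf <- cfg$gamma_flyback
  jft <- j_over_ftau(cfg); eps <- cfg$direction
  v_min <- .em_lspiv_vmin(px, fp, n, gv, gf, n_tline, p_pct)
  v_max <- .em_lspiv_vmax(px, fp, n, gv, gf, jft, eps, n_tline, d_rbc)
  n12 <- .em_min_n_two_shadows(px, fp, jft, eps, v_target, d_rbc, hematocrit)
  n14 <- .em_lspiv_min_n_motion(px, fp, gv, gf, jft, eps, n_tline, v_target, d_rbc)
  n23 <- .em_lspiv_min_n_vmin(px, fp, gv, gf, p_pct, n_tline, v_target)
  nt_max <- floor(.em_ntline_max(px, fp, gv, gf, v_target))
  min_n <- max(n12, n14, n23)
  rel <- .em_lspiv_relerr(px, fp, n, gv, gf, n_tline, v_target)
  feasible <- is.finite(min_n) && n >= ceiling(min_n) &&
    v_target >= v_min && v_target <= v_max &&
    n_tline >= 1 && n_tline <= nt_max
  error_budget("lspiv", rel_error = rel, v_min = v_min, v_max = v_max,
               min_n_px_vessel = ceiling_or_inf(min_n), min_px_size = 0,
               n_tline_range = c(1, nt_max), feasible = feasible,
               p_pct = p_pct, v_target = v_target,
               details = list(n_two_shadows = ceiling_or_inf(n12),
                              n_motion = ceiling_or_inf(n14),
                              n_vmin = ceiling_or_inf(n23),
                              n_tline = n_tline))
}

#' Spatial-frequency spread of the Fourier spectrum
#'
#' Standard deviation of the per-temporal-frequency spatial-frequency
#' distribution (a squared-sinc density of width set by the constant-velocity
#' segment length): `1 / (2 px pi sqrt(N/2 - px fp^2 J/(f tau)))`.
#'
#' @param cfg A [scan_config()].
#' @return Spatial frequency, 1/m.
#' @export
ft_sigma_x <- function(cfg) {
  s <- .em_ft_sigma_x(cfg$px_size, cfg$pixel_clock, cfg$n_px_vessel, j_over_ftau(cfg))
  if (!is.finite(s)) {
    stop(kymovel_condition(
      "kymovel_config_error",
      "N/2 <= Px Fp^2 J/(f tau): no constant-velocity pixels left for the spectrum"
    ))
  }
  s
}

#' Relative error of the Fourier-transform algorithm
#'
#' `1 / (pi * sqrt(N/2 - px fp^2 J/(f tau)) - 1)`; independent of the
#' velocity itself.
#'
#' @param cfg A [scan_config()].
#' @return Relative error as a fraction.
#' @export
ft_relative_error <- function(cfg) {
  err <- .em_ft_relerr(cfg$px_size, cfg$pixel_clock, cfg$n_px_vessel, j_over_ftau(cfg))
  if (!is.finite(err)) {
    stop(kymovel_condition(
      "kymovel_config_error",
      "configuration infeasible for the Fourier error model (denominator <= 0)"
    ))
  }
  err
}

#' Feasibility budget for the Fourier-transform algorithm
#'
#' Collects the pixel-count requirements (two apparent shadows at the tube
#' hematocrit; the error-level condition; the minimum-velocity condition),
#' the minimum measurable velocity, and a feasibility verdict.
#'
#' @inheritParams lspiv_bounds
#' @return An object of class `error_budget`.
#' @export
ft_bounds <- function(cfg, p_pct, v_target, d_rbc = 6e-6, hematocrit = 0.35) {
  check_p(p_pct)
  px <- cfg$px_size; fp <- cfg$pixel_clock; n <- cfg$n_px_vessel
  gv <- gamma_vessel(cfg); gf <- cfg$gamma_flyback
  jft <- j_over_ftau(cfg); eps <- cfg$direction
  n15 <- .em_min_n_two_shadows(px, fp, jft, eps, v_target, d_rbc, hematocrit)
  n19 <- .em_ft_min_n_err(px, fp, jft, p_pct)
  n24 <- .em_ft_min_n_vmin(px, fp, gv, gf, v_target)
  v_min <- .em_ft_vmin(px, fp, n, gv, gf)
  rel <- .em_ft_relerr(px, fp, n, jft)
  min_n <- max(n15, n19, n24)
  feasible <- is.finite(min_n) && n >= ceiling(min_n) && v_target >= v_min
  error_budget("fourier", rel_error = rel, v_min = v_min, v_max = Inf,
               min_n_px_vessel = ceiling_or_inf(min_n), min_px_size = 0,
               feasible = feasible, p_pct = p_pct, v_target = v_target,
               details = list(n_two_shadows = ceiling_or_inf(n15),
                              n_error_level = ceiling_or_inf(n19),
                              n_vmin = ceiling_or_inf(n24)))
}

# ---- error budget container -------------------------------------------------

error_budget <- function(algorithm, rel_error, v_min, v_max, min_n_px_vessel,
                         min_px_size, feasible, p_pct, v_target,
                         n_tline_range = NULL, details = list()) {
  structure(
    list(algorithm = algorithm, rel_error = rel_error, v_min = v_min,
         v_max = v_max, min_n_px_vessel = min_n_px_vessel,
         min_px_size = min_px_size, n_tline_range = n_tline_range,
         feasible = isTRUE(feasible), p_pct = p_pct, v_target = v_target,
         details = details),
    class = "error_budget"
  )
}

#' @export
print.error_budget <- function(x, ...) {
  cat(sprintf("<error_budget: %s> %s at P = %g%% for v = %.4g mm/s\n",
              x$algorithm, if (x$feasible) "FEASIBLE" else "infeasible",
              x$p_pct, x$v_target * 1e3))
  cat(sprintf("  predicted relative error: %.3g\n", x$rel_error))
  cat(sprintf("  measurable range: %.4g .. %.4g mm/s\n", x$v_min * 1e3, x$v_max * 1e3))
  cat(sprintf("  min n_px_vessel: %s   min px: %.3g um\n",
              format(x$min_n_px_vessel), x$min_px_size * 1e6))
  if (!is.null(x$n_tline_range)) {
    cat(sprintf("  admissible n_tline: %d .. %d\n",
                x$n_tline_range[1], x$n_tline_range[2]))
  }
  invisible(x)
}

error_budget_to_list <- function(x) {
  out <- x[c("algorithm", "rel_error", "v_min", "v_max", "min_n_px_vessel",
             "min_px_size", "feasible", "p_pct", "v_target")]
  out$n_tline_range <- x$n_tline_range
  out$details <- x$details
  out
}

check_p <- function(p_pct) {
  if (!is.finite(p_pct) || p_pct <= 0 || p_pct >= 100) {
    stop(kymovel_condition("kymovel_domain_error", "p_pct must be in (0, 100)"))
  }
  invisible(p_pct)
}

ceiling_or_inf <- function(x) if (is.finite(x)) ceiling(x) else Inf
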