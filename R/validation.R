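#' Signed relative velocity error
#'
#' `(v_est - v_true) / v_true`.
#'
#' @param v_est Estimated velocity (same units as `v_true`).
#' @param v_true True velocity, > 0.
#' @return Signed fraction.
#' @export
relative_error <- function(v_est, v_true) {
  if (any(v_true <= 0)) {
    stop(kymovel_condition("kymovel_domain_error", "v_true must be > 0"))
  }
  (v_est - v_true) / v_true
}

#' Closed-loop validation of the estimators on synthetic line-scans
#'
#' For each condition and seed: simulate a line-scan of known apparent
#' velocity, pre-process it (inertia crop, median filter, split into
#' sections with first and last dropped), estimate the velocity of every
#' section, and record the per-section relative errors, their maximum
#' absolute value, the model-predicted error and the model feasibility
#' verdict. Estimator failures on a section are recorded (as `NA` errors),
#' never raised.
#'
#' @param conditions A list of conditions; each a list with elements `cfg`
#'   ([scan_config()]), `flow` ([flow_config()]), `algorithm` (`"angle"`,
#'   `"lspiv"` or `"fourier"`), optional `n_tline` (LSPIV) and `label`.
#' @param seeds Integer vector of simulation seeds (one record per seed).
#' @param duration Image duration, seconds (default 1.2).
#' @param section_duration Section length, seconds (default 0.1).
#' @param kernel Median-filter kernel (default 3x3).
#' @param p_pct Error level for the feasibility annotation, percent.
#' @return A data.frame with one row per (condition, seed); the per-section
#'   signed errors are in the list-column `section_errors`.
#' @export
run_validation <- function(conditions, seeds = 1:20, duration = 1.2,
                           section_duration = 0.1, kernel = c(3, 3),
                           p_pct = 10) {
  records <- lapply(conditions, function(cond) {
    cfg <- cond$cfg
    flow <- cond$flow
    algorithm <- cond$algorithm
    n_tline <- cond$n_tline %||% 1L
    budget <- switch(algorithm,
      angle = angle_bounds(cfg, p_pct, flow$v_app),
      lspiv = lspiv_bounds(cfg, p_pct, flow$v_app, n_tline = n_tline,
                           d_rbc = flow$d_rbc, hematocrit = flow$hematocrit),
      fourier = ft_bounds(cfg, p_pct, flow$v_app, d_rbc = flow$d_rbc,
                          hematocrit = flow$hematocrit)
    )
    per_seed <- lapply(seeds, function(seed) {
      img <- simulate_linescan(cfg, flow, duration = duration, seed = seed)
      sections <- preprocess_linescan(img, kernel = kernel,
                                      section_duration = section_duration,
                                      drop_edges = TRUE)
      errs <- vapply(sections, function(sec) {
        est <- tryCatch(
          suppressWarnings(
            estimate_velocity(sec, algorithm, n_tline = n_tline)
          ),
          kymovel_error = function(e) NULL
        )
        if (is.null(est)) NA_real_ else relative_error(abs(est$v_app), flow$v_app)
      }, numeric(1))
      data.frame(
        label = cond$label %||% algorithm,
        algorithm = algorithm,
        seed = seed,
        v_true_mms = flow$v_app * 1e3,
        px_um = cfg$px_size * 1e6,
        fp_khz = cfg$pixel_clock / 1e3,
        n_px_vessel = cfg$n_px_vessel,
        direction = cfg$direction,
        n_tline = n_tline,
        defocus_fraction = flow$defocus_fraction,
        n_sections = length(errs),
        n_failed = sum(is.na(errs)),
        max_abs_rel_error = if (all(is.na(errs))) NA_real_ else max(abs(errs), na.rm = TRUE),
        predicted_rel_error = budget$rel_error,
        model_feasible = budget$feasible,
        pass = NA, # filled below
        stringsAsFactors = FALSE
      ) -> rec
      rec$section_errors <- I(list(errs))
      rec
    })
    do.call(rbind, per_seed)
  })
  out <- do.call(rbind, records)
  out$pass <- !is.na(out$max_abs_rel_error) & out$n_failed == 0 &
    out$max_abs_rel_error <= p_pct / 100
  out
}

#' Closed-loop conditions satisfying each algorithm's validity region
#'
#' Three acquisition settings, one per algorithm, chosen so each algorithm's
#' model inequalities hold at a 10% error level: angle at Px = 1 um,
#' Fp = 200 kHz, N = 100, v = 10 mm/s; LSPIV at Px = 0.5 um, Fp = 200 kHz,
#' N = 100, N_Tline = 5, v = 3 mm/s; Fourier at Px = 0.5 um, Fp = 200 kHz,
#' N = 100, v = 3 mm/s. Hematocrit 0.35, noise ratio 1.5, flyback 0.5,
#' anterograde scanning, whole line in the vessel.
#'
#' @return A list of conditions for [run_validation()].
#' @export
closed_loop_conditions <- function() {
  list(
    list(label = "angle",
         algorithm = "angle",
         cfg = scan_config(px_size_um = 1, pixel_clock_khz = 200, n_px_vessel = 100),
         flow = flow_config(v_app_mms = 10)),
    list(label = "lspiv",
         algorithm = "lspiv",
         n_tline = 5L,
         cfg = scan_config(px_size_um = 0.5, pixel_clock_khz = 200, n_px_vessel = 100),
         flow = flow_config(v_app_mms = 3)),
    list(label = "fourier",
         algorithm = "fourier",
         cfg = scan_config(px_size_um = 0.5, pixel_clock_khz = 200, n_px_vessel = 100),
         flow = flow_config(v_app_mms = 3))
  )
}

#' Defocus-robustness conditions
#'
#' Small-vessel acquisition settings (v = 5.33 mm/s, N = 120, Px = 0.8 um,
#' Fp = 400 kHz, retrograde scanning, whole line in vessel) at which all
#' three algorithms are model-feasible below 10% error, crossed with
#' increasing fractions of defocused RBCs. The LSPIV line separation is the
#' smallest integer `n_tline` satisfying the minimum-velocity pixel-count
#' bound at these settings.
#'
#' @param defocus_fractions Fractions of defocused RBCs (default
#'   `c(0, 0.25, 0.5, 0.75, 1)`).
#' @param algorithms Algorithms to run (default all three).
#' @return A list of conditions for [run_validation()].
#' @export
defocus_conditions <- function(defocus_fractions = c(0, 0.25, 0.5, 0.75, 1),
                               algorithms = c("angle", "lspiv", "fourier")) {
  cfg <- scan_config(px_size_um = 0.8, pixel_clock_khz = 400, n_px_vessel = 120,
                     direction = -1L)
  v <- 5.33e-3
  n_tline <- defocus_n_tline(cfg, v)
  conds <- list()
  for (df in defocus_fractions) {
    flow <- flow_config(v_app_mms = v * 1e3, defocus_fraction = df)
    for (alg in algorithms) {
      conds[[length(conds) + 1]] <- list(
        label = sprintf("%s_defocus%.2f", alg, df),
        algorithm = alg,
        n_tline = if (alg == "lspiv") n_tline else 1L,
        cfg = cfg,
        flow = flow
      )
    }
  }
  conds
}

# Smallest integer n_tline for which the minimum-velocity pixel-count bound
# and the n_tline ceiling both hold at velocity v.
defocus_n_tline <- function(cfg, v, p_pct = 10) {
  nt_cap <- floor(.em_ntline_max(cfg$px_size, cfg$pixel_clock,
                                 gamma_vessel(cfg), cfg$gamma_flyback, v))
  for (nt in seq_len(max(nt_cap, 1))) {
    b <- lspiv_bounds(cfg, p_pct, v, n_tline = nt)
    if (b$feasible) return(nt)
  }
  stop(kymovel_condition(
    "kymovel_config_error", "no feasible n_tline at these settings"
  ))
}
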