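#' Vessel velocity profile
#'
#' Named apparent-velocity range for a vessel type. Presets: `"arteriole"`
#' (parenchymal/pial arteriole, 8--12 mm/s), `"venule"` (venule or
#' precapillary arteriole, 2--4 mm/s), `"capillary"` (0.1--1 mm/s).
#'
#' @param name Preset name, or any label when the range is given explicitly.
#' @param v_low_mms,v_high_mms Velocity range, mm/s; optional for presets.
#' @return An object of class `vessel_profile`.
#' @export
vessel_profile <- function(name, v_low_mms = NULL, v_high_mms = NULL) {
  presets <- list(
    arteriole = c(8, 12),
    venule = c(2, 4),
    capillary = c(0.1, 1)
  )
  if (is.null(v_low_mms) || is.null(v_high_mms)) {
    if (!name %in% names(presets)) {
      stop(kymovel_condition(
        "kymovel_config_error",
        sprintf("unknown vessel preset '%s'; supply v_low_mms and v_high_mms", name)
      ))
    }
    v_low_mms <- presets[[name]][1]
    v_high_mms <- presets[[name]][2]
  }
  if (!(v_low_mms >= 0 && v_low_mms < v_high_mms)) {
    stop(kymovel_condition("kymovel_config_error", "need 0 <= v_low < v_high"))
  }
  structure(list(name = name, v_low = v_low_mms * 1e-3, v_high = v_high_mms * 1e-3),
            class = "vessel_profile")
}

#' @export
print.vessel_profile <- function(x, ...) {
  cat(sprintf("<vessel_profile: %s> %.3g .. %.3g mm/s\n",
              x$name, x$v_low * 1e3, x$v_high * 1e3))
  invisible(x)
}

#' Scanning-parameter feasibility map
#'
#' Evaluates, over a grid of pixel sizes and vessel pixel counts, which of the
#' three algorithms can measure every velocity of a vessel profile with a
#' relative error below `p_pct`. A cell admits:
#' * **angle** when the pixel-count and pixel-size planner conditions hold
#'   and the top of the velocity range stays below the angle maximum velocity;
#' * **lspiv** when a single integer `n_tline` simultaneously satisfies the
#'   two-shadow, shadow-plus-motion and minimum-velocity pixel-count bounds
#'   and keeps the whole range inside `[v_min, v_max]`;
#' * **fourier** when the two-shadow, error-level and minimum-velocity
#'   pixel-count bounds hold at the bottom of the range.
#'
#' Fixed parameters (pixel clock, gamma fractions, direction, inertia, RBC
#' diameter, hematocrit) come from `cfg_template` and the `d_rbc` /
#' `hematocrit` arguments; `gamma_vessel` is held at the template's value as
#' the pixel count varies.
#'
#' @param profile A [vessel_profile()].
#' @param cfg_template A [scan_config()] carrying the fixed parameters (its
#'   `px_size` and `n_px_vessel` are ignored).
#' @param p_pct Error level, percent (default 10).
#' @param px_grid_um Pixel-size grid, micrometers (default 40 log-spaced
#'   points over the experimental 0.1--1 um range).
#' @param n_grid Vessel pixel-count grid (default 60 log-spaced counts over
#'   10--1000).
#' @param d_rbc RBC diameter, meters.
#' @param hematocrit Tube hematocrit.
#' @return An object of class `feasibility_map`: grids plus one logical
#'   matrix (`px` by `n`) per algorithm.
#' @export
feasibility_map <- function(profile, cfg_template, p_pct = 10,
                            px_grid_um = exp(seq(log(0.1), log(1), length.out = 40)),
                            n_grid = unique(round(exp(seq(log(10), log(1000), length.out = 60)))),
                            d_rbc = 6e-6, hematocrit = 0.35) {
  stopifnot(inherits(profile, "vessel_profile"))
  validate_scan_config(cfg_template)
  check_p(p_pct)
  if (length(px_grid_um) == 0 || length(n_grid) == 0) {
    stop(kymovel_condition("kymovel_config_error", "grids must be non-empty"))
  }
  px_grid <- sort(px_grid_um) * 1e-6
  n_grid <- sort(as.integer(n_grid))
  fp <- cfg_template$pixel_clock
  gv <- gamma_vessel(cfg_template)
  gf <- cfg_template$gamma_flyback
  jft <- j_over_ftau(cfg_template)
  eps <- cfg_template$direction
  vl <- profile$v_low
  vh <- profile$v_high

  np <- length(px_grid); nn <- length(n_grid)
  angle_ok <- matrix(FALSE, np, nn)
  lspiv_ok <- matrix(FALSE, np, nn)
  ft_ok <- matrix(FALSE, np, nn)
  lspiv_nt <- matrix(NA_integer_, np, nn)

  for (i in seq_len(np)) {
    px <- px_grid[i]
    # conditions varying only with px (worst case over the velocity range)
    a_min_n <- .em_angle_min_n(px, fp, gv, gf, jft, p_pct, vh)
    a_min_px <- .em_angle_min_px(fp, gv, gf, p_pct, vh)
    n12_worst <- max(.em_min_n_two_shadows(px, fp, jft, eps, vl, d_rbc, hematocrit),
                     .em_min_n_two_shadows(px, fp, jft, eps, vh, d_rbc, hematocrit))
    n19 <- .em_ft_min_n_err(px, fp, jft, p_pct)
    n24 <- .em_ft_min_n_vmin(px, fp, gv, gf, vl)
    nt_cap <- floor(.em_ntline_max(px, fp, gv, gf, vh))
    for (j in seq_len(nn)) {
      n <- n_grid[j]
      beta_pos <- .em_beta(px, fp, n, jft) > 0
      if (!beta_pos) next
      # angle
      angle_ok[i, j] <- is.finite(a_min_n) && n >= ceiling(a_min_n) &&
        px >= a_min_px &&
        vh <= .em_angle_vmax(px, fp, n, gv, gf, jft, p_pct)
      # fourier
      ft_ok[i, j] <- n >= ceiling(max(n12_worst, n19, n24)) &&
        vl >= .em_ft_vmin(px, fp, n, gv, gf)
      # lspiv: one n_tline valid across the whole range
      if (nt_cap >= 1) {
        for (nt in seq_len(nt_cap)) {
          n14_worst <- max(.em_lspiv_min_n_motion(px, fp, gv, gf, jft, eps, nt, vl, d_rbc),
                           .em_lspiv_min_n_motion(px, fp, gv, gf, jft, eps, nt, vh, d_rbc))
          n23 <- .em_lspiv_min_n_vmin(px, fp, gv, gf, p_pct, nt, vl)
          need_n <- max(n12_worst, n14_worst, n23)
          if (!is.finite(need_n) || n < ceiling(need_n)) next
          if (vl < .em_lspiv_vmin(px, fp, n, gv, gf, nt, p_pct)) next
          if (vh > .em_lspiv_vmax(px, fp, n, gv, gf, jft, eps, nt, d_rbc)) next
          lspiv_ok[i, j] <- TRUE
          lspiv_nt[i, j] <- nt
          break
        }
      }
    }
  }
  structure(
    list(profile = profile, px_grid = px_grid, n_grid = n_grid,
         angle = angle_ok, lspiv = lspiv_ok, fourier = ft_ok,
         lspiv_n_tline = lspiv_nt,
         params = list(pixel_clock = fp, gamma_vessel = gv, gamma_flyback = gf,
                       j_over_ftau = jft, direction = eps, p_pct = p_pct,
                       d_rbc = d_rbc, hematocrit = hematocrit)),
    class = "feasibility_map"
  )
}

#' @export
print.feasibility_map <- function(x, ...) {
  frac <- function(m) mean(m)
  cat(sprintf("<feasibility_map> %s, P = %g%%, Fp = %g kHz, %s scan\n",
              x$profile$name, x$params$p_pct, x$params$pixel_clock / 1e3,
              if (x$params$direction > 0) "anterograde" else "retrograde"))
  cat(sprintf("  grid %d px sizes x %d pixel counts\n",
              length(x$px_grid), length(x$n_grid)))
  cat(sprintf("  feasible fraction: angle %.2f | lspiv %.2f | fourier %.2f | none %.2f\n",
              frac(x$angle), frac(x$lspiv), frac(x$fourier),
              mean(!(x$angle | x$lspiv | x$fourier))))
  invisible(x)
}

#' Convert a feasibility map to a long data.frame
#'
#' One row per grid cell with unit-suffixed columns and one boolean column
#' per algorithm, ready for CSV export.
#'
#' @param map A [feasibility_map()].
#' @return A data.frame.
#' @export
feasibility_grid <- function(map) {
  cells <- expand.grid(px_um = map$px_grid * 1e6, n_px_vessel = map$n_grid,
                       KEEP.OUT.ATTRS = FALSE)
  cells$angle <- as.vector(map$angle)
  cells$lspiv <- as.vector(map$lspiv)
  cells$fourier <- as.vector(map$fourier)
  cells$lspiv_n_tline <- as.vector(map$lspiv_n_tline)
  cells
}

#' Recommend an algorithm and scanning parameters for a vessel
#'
#' Ranks the algorithms by their feasible area on the map and proposes a
#' concrete `(px, n_px_vessel, n_tline)` cell maximizing the margin to the
#' feasibility boundary (the most isolated feasible cell, by grid distance to
#' the nearest infeasible cell of the top algorithm).
#'
#' @inheritParams feasibility_map
#' @param ... Passed to [feasibility_map()].
#' @return A list with `ranking` (data.frame of algorithms and feasible-area
#'   fractions), `suggestion` (list or `NULL`), and the `map`.
#' @export
recommend <- function(profile, cfg_template, p_pct = 10, ...) {
  map <- feasibility_map(profile, cfg_template, p_pct, ...)
  areas <- c(angle = mean(map$angle), lspiv = mean(map$lspiv),
             fourier = mean(map$fourier))
  areas <- areas[areas > 0]
  if (length(areas) == 0) {
    return(list(ranking = data.frame(algorithm = character(0), area = numeric(0)),
                suggestion = NULL, map = map,
                verdict = "no algorithm is feasible on this grid"))
  }
  areas <- sort(areas, decreasing = TRUE)
  top <- names(areas)[1]
  feas <- map[[top]]
  # margin: Chebyshev grid distance to the nearest infeasible cell
  dist <- matrix(0L, nrow(feas), ncol(feas))
  best <- c(NA_integer_, NA_integer_); best_d <- -1L
  for (i in seq_len(nrow(feas))) {
    for (j in seq_len(ncol(feas))) {
      if (!feas[i, j]) next
      d <- 0L
      repeat {
        d <- d + 1L
        ii <- max(1, i - d):min(nrow(feas), i + d)
        jj <- max(1, j - d):min(ncol(feas), j + d)
        ring <- feas[ii, jj, drop = FALSE]
        if (!all(ring) || (length(ii) < 2 * d + 1 && length(jj) < 2 * d + 1)) break
      }
      if (d > best_d) { best_d <- d; best <- c(i, j) }
    }
  }
  suggestion <- list(
    algorithm = top,
    px_um = map$px_grid[best[1]] * 1e6,
    n_px_vessel = map$n_grid[best[2]],
    n_tline = if (top == "lspiv") map$lspiv_n_tline[best[1], best[2]] else NA_integer_
  )
  list(ranking = data.frame(algorithm = names(areas), area = as.numeric(areas),
                            row.names = NULL),
       suggestion = suggestion, map = map, verdict = top)
}
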