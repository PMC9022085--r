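#' @title Synthetic line-scan generation
#' @description
#' The generator emulates line-scan acquisition of dark RBC shadows flowing on
#' bright plasma at a constant apparent velocity. RBC centers are laid out on
#' a 1-D flow axis with flat (uniform) random inter-cell gaps whose mean is
#' chosen so that the expected linear coverage equals the tube hematocrit.
#' Every pixel of the rendered image is sampled at its own absolute
#' acquisition time (`row * T_line + column / pixel_clock`), so the apparent
#' shadow stretching/compression `D_RBCapp = D_RBC (1 + direction *
#' v_app / v_scan)` emerges from the scanning geometry rather than being
#' hard-coded. The flyback interval is dead time during which RBCs keep
#' moving but no pixels are recorded.
#' @name synthetic_linescan
NULL

# Run code with a locally-seeded RNG, restoring the caller's stream after.
# seed = NULL draws from the current stream (used when an orchestrator has
# already seeded it).
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a random RBC train
#'
#' Places RBC centers along a 1-D flow axis with inter-cell gaps drawn from a
#' flat distribution on `[0, 2 * d_rbc * (1 - Ht) / Ht]`, so that the expected
#' fraction of the axis covered by shadows equals the tube hematocrit and no
#' two shadows overlap.
#'
#' @param flow A [flow_config()] (uses `d_rbc` and `hematocrit`).
#' @param axis_length Length of the flow axis to populate, meters. Must be at
#'   least `10 * d_rbc / hematocrit` so the realization carries enough cells.
#' @param seed Integer seed, or `NULL` to draw from the current RNG stream.
#' @param origin Coordinate of the start of the axis, meters (default 0).
#'
#' @return An object of class `rbc_train`: a list with `center` (strictly
#'   increasing, meters), `d_rbc`, and per-cell defocus fields (all unset
#'   until [apply_defocus()] is called).
#' @export
make_rbc_train <- function(flow, axis_length, seed = flow$seed, origin = 0) {
  validate_flow_config(flow)
  d <- flow$d_rbc
  ht <- flow$hematocrit
  if (axis_length < 10 * d / ht) {
    stop(kymovel_condition(
      "kymovel_domain_error",
      sprintf("axis_length %.3g m too short: need at least 10*d_rbc/Ht = %.3g m",
              axis_length, 10 * d / ht)
    ))
  }
  gap_max <- 2 * d * (1 - ht) / ht
  with_local_seed(seed, {
    # Expected per-cell pitch is d + gap_max/2 = d/ht; draw a safety margin.
    n_guess <- ceiling(axis_length / (d / ht) * 1.5) + 20
    repeat {
      gaps <- stats::runif(n_guess, min = 0, max = gap_max)
      # center_i = origin + sum_{j<=i}(gap_j) + (i - 1/2) * d
      centers <- origin + cumsum(gaps) + (seq_len(n_guess) - 0.5) * d
      if (centers[n_guess] > origin + axis_length + d) break
      n_guess <- n_guess * 2
    }
    centers <- centers[centers <= origin + axis_length + d]
    structure(
      list(
        center = centers,
        d_rbc = d,
        defocused = rep(FALSE, length(centers)),
        entry_time = rep(NA_real_, length(centers)),
        exit_time = rep(NA_real_, length(centers))
      ),
      class = "rbc_train"
    )
  })
}

#' @export
print.rbc_train <- function(x, ...) {
  cat(sprintf("<rbc_train> %d cells, d_rbc = %.3g um, %d defocused\n",
              length(x$center), x$d_rbc * 1e6, sum(x$defocused)))
  invisible(x)
}

# Fraction of [from, to] covered by shadows; Monte-Carlo check target for Ht.
train_coverage <- function(train, from, to) {
  lo <- pmax(train$center - train$d_rbc / 2, from)
  hi <- pmin(train$center + train$d_rbc / 2, to)
  sum(pmax(hi - lo, 0)) / (to - from)
}

#' Flag a fraction of RBCs as defocused
#'
#' Defocused RBCs drift in or out of the scanned line: each flagged cell is
#' rendered only during a random visibility window and appears as plasma
#' outside it. Cells are flagged independently with probability
#' `defocus_fraction`. When `cfg` and `flow` are supplied the visibility
#' window is drawn uniformly *within the cell's transit through the scanned
#' segment* (two uniform draws, sorted); otherwise it is drawn within
#' `[0, duration]`.
#'
#' @param train An [make_rbc_train()] output.
#' @param defocus_fraction Fraction of RBCs to flag, in [0, 1].
#' @param duration Image duration, seconds.
#' @param seed Integer seed or `NULL` for the current RNG stream.
#' @param cfg,flow Optional [scan_config()] / [flow_config()] used to compute
#'   per-cell transit windows.
#' @return A new `rbc_train` with defocus flags and windows set.
#' @export
apply_defocus <- function(train, defocus_fraction, duration, seed = NULL,
                          cfg = NULL, flow = NULL) {
  if (defocus_fraction < 0 || defocus_fraction > 1) {
    stop(kymovel_condition("kymovel_domain_error", "defocus_fraction must be in [0, 1]"))
  }
  if (defocus_fraction == 0) return(train)
  n <- length(train$center)
  with_local_seed(seed, {
    flagged <- stats::runif(n) < defocus_fraction
    t_in <- rep(0, n)
    t_out <- rep(duration, n)
    if (!is.null(cfg) && !is.null(flow)) {
      vr <- real_velocity(cfg, flow)
      eps <- cfg$direction
      seg_len <- cfg$n_px_vessel * cfg$px_size
      half <- train$d_rbc / 2
      if (vr > 0) {
        if (eps > 0) {
          t_in <- (-half - train$center) / vr
          t_out <- (seg_len + half - train$center) / vr
        } else {
          t_in <- (train$center - seg_len - half) / vr
          t_out <- (train$center + half) / vr
        }
      }
      t_in <- pmax(t_in, 0)
      t_out <- pmin(t_out, duration)
      bad <- t_out <= t_in # never visible: any window works
      t_in[bad] <- 0
      t_out[bad] <- duration
    }
    w1 <- stats::runif(n, t_in, t_out)
    w2 <- stats::runif(n, t_in, t_out)
    train$defocused <- flagged
    train$entry_time <- ifelse(flagged, pmin(w1, w2), NA_real_)
    train$exit_time <- ifelse(flagged, pmax(w1, w2), NA_real_)
    train
  })
}

# Real RBC velocity along the scan axis that produces the requested apparent
# streak velocity: v_real = v_app * v_scan / (v_scan + eps * v_app).
real_velocity <- function(cfg, flow) {
  vs <- scan_velocity(cfg)
  eps <- cfg$direction
  if (eps < 0 && flow$v_app >= vs) {
    stop(kymovel_condition(
      "kymovel_domain_error",
      "retrograde apparent velocity >= scan velocity: shadow geometry undefined"
    ))
  }
  flow$v_app * vs / (vs + eps * flow$v_app)
}

#' Render a noiseless line-scan image from an RBC train
#'
#' Each pixel `(row, col)` of the vessel segment is sampled at absolute time
#' `row * T_line + col / pixel_clock` with the RBC train advanced accordingly;
#' it takes `rbc_level` if the scan point falls inside a (visible) RBC shadow
#' and `plasma_level` otherwise. Out-of-vessel columns are uniform plasma.
#'
#' @param train An [make_rbc_train()] output covering the coordinate range the
#'   scan will sweep (a warning is issued otherwise).
#' @param cfg A [scan_config()].
#' @param flow A [flow_config()]; `v_app` is the ground-truth apparent
#'   velocity of the rendered streaks.
#' @param duration Image duration, seconds (>= 3 line periods).
#' @param intra_line_sampling If `TRUE` (default) pixels within a line are
#'   sampled at distinct times, which is what produces the apparent-diameter
#'   stretching; `FALSE` samples a whole line at its start time.
#' @return A [linescan_image()] with the ground truth attached.
#' @export
render_linescan <- function(train, cfg, flow, duration,
                            intra_line_sampling = TRUE) {
  validate_scan_config(cfg)
  validate_flow_config(flow)
  t_line <- line_period(cfg)
  if (duration < 3 * t_line) {
    stop(kymovel_condition(
      "kymovel_domain_error",
      sprintf("duration %.3g s shorter than 3 line periods (%.3g s)", duration, 3 * t_line)
    ))
  }
  n_rows <- floor(duration / t_line)
  w <- cfg$n_px_vessel
  eps <- cfg$direction
  v_real <- real_velocity(cfg, flow)

  col_pos <- (seq_len(w) - 1) * cfg$px_size
  col_dt <- if (intra_line_sampling) (seq_len(w) - 1) / cfg$pixel_clock else rep(0, w)
  row_t <- (seq_len(n_rows) - 1) * t_line
  # time and flow-frame coordinate of every vessel pixel
  t_abs <- outer(row_t, col_dt, `+`)
  u <- matrix(col_pos, n_rows, w, byrow = TRUE) - eps * v_real * t_abs

  rng <- range(u)
  half <- train$d_rbc / 2
  if (length(train$center) == 0 ||
      min(train$center) - half > rng[1] || max(train$center) + half < rng[2]) {
    warning("RBC train does not cover the full coordinate range swept by the scan; ",
            "uncovered regions render as plasma")
  }

  bounds <- as.vector(rbind(train$center - half, train$center + half))
  idx <- findInterval(as.vector(u), bounds)
  inside <- idx %% 2L == 1L
  if (any(train$defocused)) {
    cell <- (idx + 1L) %/% 2L
    cell[!inside] <- 1L # placeholder, masked below
    visible <- !train$defocused[cell] |
      (as.vector(t_abs) >= train$entry_time[cell] &
         as.vector(t_abs) <= train$exit_time[cell])
    visible[is.na(visible)] <- TRUE
    inside <- inside & visible
  }

  vess <- matrix(flow$plasma_level, n_rows, w)
  vess[matrix(inside, n_rows, w)] <- flow$rbc_level
  img <- if (cfg$n_px_out_vessel > 0) {
    cbind(vess, matrix(flow$plasma_level, n_rows, cfg$n_px_out_vessel))
  } else {
    vess
  }
  linescan_image(img, cfg, flow = flow, t_line = t_line)
}

#' Add white noise to a line-scan image
#'
#' Adds zero-mean white noise drawn uniformly from `[-a/2, +a/2]` with
#' peak-to-peak amplitude `a = noise_ratio * (plasma_level - rbc_level)`,
#' independently per pixel.
#'
#' @param img A [linescan_image()] carrying its ground-truth [flow_config()]
#'   (needed for the contrast).
#' @param noise_ratio Amplitude ratio; defaults to the image's flow setting.
#' @param seed Integer seed or `NULL` for the current RNG stream.
#' @return A new [linescan_image()].
#' @export
add_noise <- function(img, noise_ratio = NULL, seed = NULL) {
  if (is.null(img$flow)) {
    stop(kymovel_condition(
      "kymovel_config_error",
      "add_noise needs the image's flow_config to know the shadow/plasma contrast"
    ))
  }
  if (is.null(noise_ratio)) noise_ratio <- img$flow$noise_ratio
  if (noise_ratio < 0) {
    stop(kymovel_condition("kymovel_domain_error", "noise_ratio must be >= 0"))
  }
  if (noise_ratio == 0) return(img)
  a <- noise_ratio * (img$flow$plasma_level - img$flow$rbc_level)
  with_local_seed(seed, {
    img$data <- img$data + matrix(stats::runif(length(img$data), -a / 2, a / 2),
                                  nrow(img$data), ncol(img$data))
    img
  })
}

#' Simulate a complete synthetic line-scan
#'
#' Convenience pipeline: builds an RBC train long enough to cover the swept
#' coordinate range, applies defocusing, renders the image and adds noise.
#' All randomness is drawn from a single stream seeded by `seed`, so a fixed
#' seed reproduces the image bit for bit.
#'
#' @param cfg A [scan_config()].
#' @param flow A [flow_config()].
#' @param duration Image duration, seconds (default 1.2 s as in the
#'   validation protocol).
#' @param seed Integer seed; defaults to `flow$seed`.
#' @inheritParams render_linescan
#' @return A [linescan_image()].
#' @export
simulate_linescan <- function(cfg, flow, duration = 1.2, seed = flow$seed,
                              intra_line_sampling = TRUE) {
  validate_scan_config(cfg)
  validate_flow_config(flow)
  v_real <- real_velocity(cfg, flow)
  seg_len <- cfg$n_px_vessel * cfg$px_size
  travel <- v_real * duration
  # margin beyond the swept range on both sides: must exceed the largest
  # possible cell pitch (d + gap_max) so truncation of the train cannot leave
  # an uncovered edge
  margin <- 4 * flow$d_rbc / flow$hematocrit
  origin <- (if (cfg$direction > 0) -travel else 0) - margin
  span <- travel + seg_len + 2 * margin
  span <- max(span, 10 * flow$d_rbc / flow$hematocrit)
  with_local_seed(seed, {
    train <- make_rbc_train(flow, axis_length = span, seed = NULL, origin = origin)
    if (flow$defocus_fraction > 0) {
      train <- apply_defocus(train, flow$defocus_fraction, duration,
                             seed = NULL, cfg = cfg, flow = flow)
    }
    img <- render_linescan(train, cfg, flow, duration,
                           intra_line_sampling = intra_line_sampling)
    if (flow$noise_ratio > 0) img <- add_noise(img, seed = NULL)
    img
  })
}
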