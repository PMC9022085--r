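#' Scanner / acquisition configuration
#'
#' Bundles every parameter of a line-scan acquisition: pixel size, pixel clock,
#' number of pixels inside and outside the vessel, flyback dead-time fraction,
#' galvanometer inertia-to-torque ratio, objective focal length and the scan
#' direction relative to RBC flow. All fields are stored in strict SI units
#' (m, Hz, s^2); the constructor accepts the units experimenters actually use
#' (micrometers, kilohertz, millimeters) and converts once at this boundary.
#'
#' @param px_size_um Pixel size along the scanned line, micrometers.
#' @param pixel_clock_khz Pixel acquisition frequency, kilohertz.
#' @param n_px_vessel Number of pixels of the segment inside the vessel.
#' @param n_px_out_vessel Number of pixels of the segment outside the vessel
#'   (used e.g. for calcium or diameter monitoring); 0 for a plain line.
#' @param gamma_flyback Fraction of the line time spent flying back to the
#'   line start (dead time); default 0.5 as for typical galvanometer systems.
#' @param inertia_ratio_s2 Rotor inertia over torque J/tau, seconds^2.
#'   Default 3.7e-8 s^2 (Cambridge Technology 8315 galvanometers).
#' @param focal_length_mm Objective focal length, millimeters. High-NA water
#'   immersion objectives range from 2 to 15 mm; default 4.5 mm.
#' @param direction +1 when scanning in the same direction as the RBC flow
#'   (anterograde), -1 when scanning against it (retrograde).
#'
#' @return An object of class `scan_config`.
#' @examples
#' cfg <- scan_config(px_size_um = 0.5, pixel_clock_khz = 200, n_px_vessel = 100)
#' line_period(cfg)
#' @export
scan_config <- function(px_size_um,
                        pixel_clock_khz,
                        n_px_vessel,
                        n_px_out_vessel = 0,
                        gamma_flyback = 0.5,
                        inertia_ratio_s2 = 3.7e-8,
                        focal_length_mm = 4.5,
                        direction = 1L) {
  cfg <- structure(
    list(
      px_size = as.numeric(px_size_um) * 1e-6,
      pixel_clock = as.numeric(pixel_clock_khz) * 1e3,
      n_px_vessel = as.integer(n_px_vessel),
      n_px_out_vessel = as.integer(n_px_out_vessel),
      gamma_flyback = as.numeric(gamma_flyback),
      inertia_ratio = as.numeric(inertia_ratio_s2),
      focal_length = as.numeric(focal_length_mm) * 1e-3,
      direction = as.integer(direction)
    ),
    class = "scan_config"
  )
  validate_scan_config(cfg)
  cfg
}

validate_scan_config <- function(cfg) {
  stop_cfg <- function(msg) {
    stop(kymovel_condition("kymovel_config_error", msg))
  }
  if (!is.finite(cfg$px_size) || cfg$px_size <= 0) stop_cfg("px_size must be > 0")
  if (!is.finite(cfg$pixel_clock) || cfg$pixel_clock <= 0) stop_cfg("pixel_clock must be > 0")
  if (is.na(cfg$n_px_vessel) || cfg$n_px_vessel < 1) stop_cfg("n_px_vessel must be >= 1")
  if (is.na(cfg$n_px_out_vessel) || cfg$n_px_out_vessel < 0) stop_cfg("n_px_out_vessel must be >= 0")
  if (!is.finite(cfg$gamma_flyback) || cfg$gamma_flyback < 0) stop_cfg("gamma_flyback must be >= 0")
  if (!is.finite(cfg$inertia_ratio) || cfg$inertia_ratio < 0) stop_cfg("inertia_ratio must be >= 0")
  if (!is.finite(cfg$focal_length) || cfg$focal_length <= 0) stop_cfg("focal_length must be > 0")
  if (!(cfg$direction %in% c(-1L, 1L))) stop_cfg("direction must be +1 or -1")
  invisible(cfg)
}

#' @export
print.scan_config <- function(x, ...) {
  cat("<scan_config>\n")
  cat(sprintf("  px_size        : %.3g um\n", x$px_size * 1e6))
  cat(sprintf("  pixel_clock    : %.4g kHz\n", x$pixel_clock / 1e3))
  cat(sprintf("  n_px_vessel    : %d (+%d out of vessel)\n",
              x$n_px_vessel, x$n_px_out_vessel))
  cat(sprintf("  gamma_flyback  : %.3g   gamma_vessel: %.3g\n",
              x$gamma_flyback, gamma_vessel(x)))
  cat(sprintf("  J/tau          : %.3g s^2   f: %.3g mm\n",
              x$inertia_ratio, x$focal_length * 1e3))
  cat(sprintf("  direction      : %+d (%s)\n", x$direction,
              if (x$direction > 0) "anterograde" else "retrograde"))
  cat(sprintf("  v_scan         : %.4g mm/s   T_line: %.4g ms\n",
              scan_velocity(x) * 1e3, line_period(x) * 1e3))
  invisible(x)
}

#' Fraction of the scanned line inside the vessel
#'
#' `gamma_vessel = n_px_vessel / (n_px_vessel + n_px_out_vessel)`, in (0, 1].
#'
#' @param cfg A [scan_config()].
#' @return Dimensionless fraction.
#' @export
gamma_vessel <- function(cfg) {
  cfg$n_px_vessel / (cfg$n_px_vessel + cfg$n_px_out_vessel)
}

#' Target scanning velocity
#'
#' The product of pixel size and pixel clock, m/s.
#'
#' @param cfg A [scan_config()].
#' @return Velocity, m/s.
#' @export
scan_velocity <- function(cfg) {
  cfg$px_size * cfg$pixel_clock
}

# J/(f*tau), s^2/m: the lumped inertia term entering every model equation.
j_over_ftau <- function(cfg) {
  cfg$inertia_ratio / cfg$focal_length
}

#' Line period
#'
#' Time from the beginning of one scanned line to the beginning of the next,
#' including the flyback dead time:
#' `T_line = (1 + gamma_flyback) * n_px_vessel / (pixel_clock * gamma_vessel)`.
#'
#' @param cfg A [scan_config()].
#' @return Duration in seconds, strictly positive.
#' @examples
#' cfg <- scan_config(0.5, 200, 50)
#' line_period(cfg) # 3.75e-4 s
#' @export
line_period <- function(cfg) {
  validate_scan_config(cfg)
  (1 + cfg$gamma_flyback) * cfg$n_px_vessel / (cfg$pixel_clock * gamma_vessel(cfg))
}

#' Number of edge pixels affected by scanner inertia
#'
#' At each end of a scanned segment the galvanometer accelerates or brakes and
#' the instantaneous scan velocity is not the target one. The affected extent
#' is `N_crop = px_size * pixel_clock^2 * J / (f * tau)` pixels on each edge.
#' The continuous value is used in all model equations; the integer form used
#' for physical image cropping truncates, so sub-pixel extents crop nothing
#' (in many practical conditions `N_crop` is identically zero).
#'
#' @param cfg A [scan_config()].
#' @param integer If `TRUE`, return the truncated count used for cropping.
#' @return Pixel count (continuous by default), >= 0.
#' @examples
#' cfg <- scan_config(1, 1000, 2000, inertia_ratio_s2 = 5e-4 * 4.5e-3)
#' n_crop(cfg) # 500
#' @export
n_crop <- function(cfg, integer = FALSE) {
  validate_scan_config(cfg)
  val <- cfg$px_size * cfg$pixel_clock^2 * j_over_ftau(cfg)
  if (integer) floor(val + 1e-9) else val
}

#' Fraction of the vessel segment scanned at constant velocity
#'
#' `beta = 1 - 2 * N_crop / n_px_vessel` using the continuous `N_crop`.
#' A configuration with `beta <= 0` never reaches its target scan velocity
#' and is unusable.
#'
#' @param cfg A [scan_config()].
#' @return Fraction in (0, 1].
#' @export
beta_constant_fraction <- function(cfg) {
  beta <- 1 - 2 * n_crop(cfg) / cfg$n_px_vessel
  if (beta <= 0) {
    stop(kymovel_condition(
      "kymovel_config_error",
      sprintf("beta = %.3g <= 0: the whole line is consumed by scanner acceleration", beta)
    ))
  }
  beta
}

#' Apparent RBC shadow diameter
#'
#' The shadow left by an RBC in a line-scan image is stretched when scanning
#' with the flow and compressed when scanning against it:
#' `D_RBCapp = d_rbc * (1 + direction * v_app / v_scan)`.
#'
#' @param cfg A [scan_config()].
#' @param v_app Apparent RBC velocity, m/s (unsigned).
#' @param d_rbc RBC diameter, meters (default 6 um).
#' @return Apparent diameter in meters, > 0.
#' @export
apparent_rbc_diameter <- function(cfg, v_app, d_rbc = 6e-6) {
  validate_scan_config(cfg)
  if (any(v_app < 0)) {
    stop(kymovel_condition("kymovel_domain_error", "v_app must be >= 0"))
  }
  d_app <- d_rbc * (1 + cfg$direction * v_app / scan_velocity(cfg))
  if (any(d_app <= 0)) {
    stop(kymovel_condition(
      "kymovel_domain_error",
      "apparent shadow diameter <= 0: retrograde apparent velocity exceeds the scan velocity"
    ))
  }
  d_app
}

# Structured condition helper shared by the whole package.
kymovel_condition <- function(class, msg, call = sys.call(-1)) {
  structure(
    class = c(class, "kymovel_error", "error", "condition"),
    list(message = msg, call = call)
  )
}

#' Serialize a scan configuration to a JSON string
#'
#' Keys are unit-suffixed, matching the sidecar convention
#' (`px_size_um`, `pixel_clock_khz`, ...).
#'
#' @param cfg A [scan_config()].
#' @return A JSON string.
#' @export
scan_config_to_json <- function(cfg) {
  validate_scan_config(cfg)
  jsonlite::toJSON(scan_config_to_list(cfg), auto_unbox = TRUE, digits = NA)
}

scan_config_to_list <- function(cfg) {
  list(
    px_size_um = cfg$px_size * 1e6,
    pixel_clock_khz = cfg$pixel_clock / 1e3,
    n_px_vessel = cfg$n_px_vessel,
    n_px_out_vessel = cfg$n_px_out_vessel,
    gamma_flyback = cfg$gamma_flyback,
    inertia_ratio_s2 = cfg$inertia_ratio,
    focal_length_mm = cfg$focal_length * 1e3,
    direction = cfg$direction
  )
}

#' Deserialize a scan configuration from JSON
#'
#' @param json A JSON string or a parsed list with unit-suffixed keys.
#' @return A [scan_config()].
#' @export
scan_config_from_json <- function(json) {
  x <- if (is.character(json)) jsonlite::fromJSON(json) else json
  required <- c("px_size_um", "pixel_clock_khz", "n_px_vessel")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    stop(kymovel_condition(
      "kymovel_config_error",
      paste0("scan config is missing required fields: ", paste(missing, collapse = ", "))
    ))
  }
  scan_config(
    px_size_um = x$px_size_um,
    pixel_clock_khz = x$pixel_clock_khz,
    n_px_vessel = x$n_px_vessel,
    n_px_out_vessel = x$n_px_out_vessel %||% 0,
    gamma_flyback = x$gamma_flyback %||% 0.5,
    inertia_ratio_s2 = x$inertia_ratio_s2 %||% 3.7e-8,
    focal_length_mm = x$focal_length_mm %||% 4.5,
    direction = x$direction %||% 1L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
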