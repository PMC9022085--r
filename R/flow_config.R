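#' Flow / ground-truth configuration for the synthetic generator
#'
#' Describes the simulated blood flow: the constant apparent RBC velocity, the
#' RBC diameter, the tube hematocrit setting the shadow density, the fraction
#' of defocused RBCs, the white-noise amplitude relative to the shadow/plasma
#' contrast, and the two intensity levels of the rendered image.
#'
#' @param v_app_mms Apparent RBC velocity in the image, mm/s (unsigned; the
#'   sign of the streak slope comes from the scan direction).
#' @param d_rbc_um RBC diameter, micrometers (default 6).
#' @param hematocrit Tube hematocrit H_t, the fraction of the vessel axis
#'   covered by RBCs; default 0.35 (average of published cortical and
#'   olfactory-bulb values).
#' @param defocus_fraction Fraction of RBCs that drift in or out of the
#'   scanned line and are therefore only intermittently visible; default 0.
#' @param noise_ratio Peak-to-peak amplitude of the additive white noise,
#'   expressed as a multiple of `plasma_level - rbc_level`; default 1.5.
#' @param plasma_level,rbc_level Intensities of plasma ("white") and RBC
#'   shadow ("black") pixels on a 16-bit scale. Plasma must be brighter.
#' @param seed Optional integer seed making the whole simulation
#'   deterministic.
#'
#' @return An object of class `flow_config`.
#' @export
flow_config <- function(v_app_mms,
                        d_rbc_um = 6,
                        hematocrit = 0.35,
                        defocus_fraction = 0,
                        noise_ratio = 1.5,
                        plasma_level = 200,
                        rbc_level = 50,
                        seed = NULL) {
  flow <- structure(
    list(
      v_app = as.numeric(v_app_mms) * 1e-3,
      d_rbc = as.numeric(d_rbc_um) * 1e-6,
      hematocrit = as.numeric(hematocrit),
      defocus_fraction = as.numeric(defocus_fraction),
      noise_ratio = as.numeric(noise_ratio),
      plasma_level = as.numeric(plasma_level),
      rbc_level = as.numeric(rbc_level),
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "flow_config"
  )
  validate_flow_config(flow)
  flow
}

validate_flow_config <- function(flow) {
  stop_cfg <- function(msg) stop(kymovel_condition("kymovel_config_error", msg))
  if (!is.finite(flow$v_app) || flow$v_app < 0) stop_cfg("v_app must be >= 0")
  if (!is.finite(flow$d_rbc) || flow$d_rbc <= 0) stop_cfg("d_rbc must be > 0")
  if (!is.finite(flow$hematocrit) || flow$hematocrit <= 0 || flow$hematocrit >= 1) {
    stop_cfg("hematocrit must be in (0, 1)")
  }
  if (flow$defocus_fraction < 0 || flow$defocus_fraction > 1) {
    stop_cfg("defocus_fraction must be in [0, 1]")
  }
  if (flow$noise_ratio < 0) stop_cfg("noise_ratio must be >= 0")
  if (flow$plasma_level <= flow$rbc_level) stop_cfg("plasma_level must exceed rbc_level")
  invisible(flow)
}

#' @export
print.flow_config <- function(x, ...) {
  cat("<flow_config>\n")
  cat(sprintf("  v_app      : %.4g mm/s\n", x$v_app * 1e3))
  cat(sprintf("  d_rbc      : %.3g um   hematocrit: %.2f\n", x$d_rbc * 1e6, x$hematocrit))
  cat(sprintf("  defocus    : %.0f%%   noise ratio: %.2g\n",
              100 * x$defocus_fraction, x$noise_ratio))
  cat(sprintf("  intensities: plasma %.4g / rbc %.4g\n", x$plasma_level, x$rbc_level))
  if (!is.null(x$seed)) cat(sprintf("  seed       : %d\n", x$seed))
  invisible(x)
}

flow_config_to_list <- function(flow) {
  list(
    v_app_mms = flow$v_app * 1e3,
    d_rbc_um = flow$d_rbc * 1e6,
    hematocrit = flow$hematocrit,
    defocus_fraction = flow$defocus_fraction,
    noise_ratio = flow$noise_ratio,
    plasma_level = flow$plasma_level,
    rbc_level = flow$rbc_level,
    seed = flow$seed
  )
}

flow_config_from_list <- function(x) {
  flow_config(
    v_app_mms = x$v_app_mms,
    d_rbc_um = x$d_rbc_um %||% 6,
    hematocrit = x$hematocrit %||% 0.35,
    defocus_fraction = x$defocus_fraction %||% 0,
    noise_ratio = x$noise_ratio %||% 1.5,
    plasma_level = x$plasma_level %||% 200,
    rbc_level = x$rbc_level %||% 50,
    seed = x$seed
  )
}
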