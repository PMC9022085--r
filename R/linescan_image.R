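#' Line-scan (kymograph) image container
#'
#' A 2-D intensity grid in which rows index successive scanned lines (time
#' increases downward) and columns index position along the scanned segment:
#' the in-vessel segment comes first, followed by any out-of-vessel segment.
#' The image carries its acquisition [scan_config()], the line period at
#' acquisition time (`t_line`, which stays fixed even when the attached
#' config is later narrowed by cropping) and, for synthetic images, the
#' ground-truth [flow_config()].
#'
#' @param data Numeric matrix of intensities (rows = time).
#' @param cfg The [scan_config()] used to acquire or render the image.
#' @param flow Optional ground-truth [flow_config()].
#' @param t_line Line period in seconds; defaults to `line_period(cfg)`.
#' @param cropped Whether inertia cropping has already been applied.
#' @param section_index Optional index when the image is a 0.1 s section.
#'
#' @return An object of class `linescan_image`.
#' @export
linescan_image <- function(data, cfg, flow = NULL, t_line = line_period(cfg),
                           cropped = FALSE, section_index = NULL) {
  validate_scan_config(cfg)
  if (!is.matrix(data) || !is.numeric(data)) {
    stop(kymovel_condition("kymovel_config_error", "data must be a numeric matrix"))
  }
  if (ncol(data) != cfg$n_px_vessel + cfg$n_px_out_vessel) {
    stop(kymovel_condition(
      "kymovel_config_error",
      sprintf("image has %d columns but config expects %d (vessel) + %d (out)",
              ncol(data), cfg$n_px_vessel, cfg$n_px_out_vessel)
    ))
  }
  if (nrow(data) < 1) {
    stop(kymovel_condition("kymovel_config_error", "image must have at least one line"))
  }
  if (!all(is.finite(data))) {
    stop(kymovel_condition("kymovel_config_error", "image intensities must be finite"))
  }
  structure(
    list(data = data, cfg = cfg, flow = flow, t_line = as.numeric(t_line),
         cropped = isTRUE(cropped), section_index = section_index),
    class = "linescan_image"
  )
}

#' @export
print.linescan_image <- function(x, ...) {
  cat(sprintf("<linescan_image> %d lines x %d px (%d in vessel), T_line = %.4g ms, %.4g s total\n",
              nrow(x$data), ncol(x$data), x$cfg$n_px_vessel, x$t_line * 1e3,
              nrow(x$data) * x$t_line))
  if (!is.null(x$flow)) {
    cat(sprintf("  ground truth: v_app = %.4g mm/s\n", x$flow$v_app * 1e3))
  }
  invisible(x)
}

#' @export
dim.linescan_image <- function(x) dim(x$data)

# Columns of the in-vessel segment only (the part carrying RBC signal).
vessel_segment <- function(img) {
  img$data[, seq_len(img$cfg$n_px_vessel), drop = FALSE]
}
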