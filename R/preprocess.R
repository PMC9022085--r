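#' Crop scanner-acceleration edges from a line-scan image
#'
#' Removes `n_crop(cfg, integer = TRUE)` pixels from each edge of the vessel segment,
#' where the galvanometer has not yet reached (or is leaving) its target scan
#' velocity. The attached config is updated: `n_px_vessel` shrinks and the
#' inertia term is zeroed, since the cropped image is entirely scanned at
#' constant velocity (`beta = 1`). The image's `t_line` is unchanged --- it
#' was fixed at acquisition time. The operation is idempotent.
#'
#' @param img A [linescan_image()].
#' @return A cropped [linescan_image()].
#' @export
crop_edges <- function(img) {
  nc_px <- n_crop(img$cfg, integer = TRUE)
  if (nc_px == 0) {
    img$cropped <- TRUE
    return(img)
  }
  w <- img$cfg$n_px_vessel
  if (nc_px >= w / 2) {
    stop(kymovel_condition(
      "kymovel_config_error",
      sprintf("cropping %d pixels per edge would consume the whole %d-pixel vessel segment",
              nc_px, w)
    ))
  }
  keep_vessel <- seq(nc_px + 1, w - nc_px)
  keep <- c(keep_vessel, seq_len(img$cfg$n_px_out_vessel) + w)
  cfg <- img$cfg
  cfg$n_px_vessel <- as.integer(w - 2 * nc_px)
  cfg$inertia_ratio <- 0 # remaining pixels are constant-velocity: beta = 1
  linescan_image(img$data[, keep, drop = FALSE], cfg, flow = img$flow,
                 t_line = img$t_line, cropped = TRUE,
                 section_index = img$section_index)
}

#' Median-filter a line-scan image
#'
#' 2-D median filtering reduces the additive noise without altering the shape
#' of RBC shadow edges. Edges are handled by reflection; the image shape is
#' unchanged.
#'
#' @param img A [linescan_image()].
#' @param kernel Integer vector `c(rows, cols)` of odd kernel dimensions;
#'   default `c(3, 3)`.
#' @return A filtered [linescan_image()].
#' @export
denoise_median <- function(img, kernel = c(3, 3)) {
  kernel <- as.integer(kernel)
  if (length(kernel) != 2 || any(kernel < 1) || any(kernel %% 2 == 0)) {
    stop(kymovel_condition(
      "kymovel_config_error", "kernel dimensions must be odd integers >= 1"
    ))
  }
  if (all(kernel == 1L)) return(img)
  img$data <- median_filter_2d(img$data, kernel[1], kernel[2])
  img
}

#' Split a line-scan image into fixed-duration sections
#'
#' Cuts the image into consecutive, non-overlapping sections of
#' `floor(section_duration / t_line)` lines each (remainder lines are
#' discarded). With `drop_edges = TRUE` the first and last sections are
#' removed to avoid edge effects, following the 1.2 s / 0.1 s validation
#' protocol which retains ten sections.
#'
#' @param img A [linescan_image()].
#' @param section_duration Section length, seconds (default 0.1).
#' @param drop_edges Drop the first and last sections (default `TRUE`).
#' @return A list of [linescan_image()] sections with `section_index` set
#'   (1-based index within the *full* sequence, before dropping).
#' @export
split_sections <- function(img, section_duration = 0.1, drop_edges = TRUE) {
  lines_per <- floor(section_duration / img$t_line)
  if (lines_per < 1) {
    stop(kymovel_condition(
      "kymovel_domain_error",
      "section_duration is shorter than one line period"
    ))
  }
  n_full <- floor(nrow(img$data) / lines_per)
  keep <- if (drop_edges) {
    if (n_full > 2) 2:(n_full - 1) else integer(0)
  } else {
    seq_len(n_full)
  }
  if (length(keep) == 0) {
    stop(kymovel_condition(
      "kymovel_domain_error",
      sprintf("image too short: %d full sections%s", n_full,
              if (drop_edges) " before dropping first/last" else "")
    ))
  }
  lapply(keep, function(k) {
    rows <- ((k - 1) * lines_per + 1):(k * lines_per)
    linescan_image(img$data[rows, , drop = FALSE], img$cfg, flow = img$flow,
                   t_line = img$t_line, cropped = img$cropped, section_index = k)
  })
}

#' Standard pre-processing pipeline
#'
#' Crop inertia-affected edges, median-filter, then split into sections.
#'
#' @inheritParams split_sections
#' @inheritParams denoise_median
#' @return A list of pre-processed [linescan_image()] sections.
#' @export
preprocess_linescan <- function(img, kernel = c(3, 3), section_duration = 0.1,
                                drop_edges = TRUE) {
  img <- crop_edges(img)
  img <- denoise_median(img, kernel)
  split_sections(img, section_duration, drop_edges)
}
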