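#' @title Line-scan image files: grayscale TIFF plus JSON sidecar
#' @description
#' Images travel as single-page grayscale TIFF (rows = time, row 0 = first
#' scanned line) with a JSON sidecar of the same basename carrying the scan
#' configuration, the ground-truth flow configuration when known, and the
#' line period. The package includes a self-contained baseline TIFF codec
#' (uncompressed, single sample per pixel, 8 or 16 bit) because no TIFF
#' library ships with the supported R stack; anything richer (RGB,
#' compression, tiles) raises a structured unsupported-format error.
#' @name cli_io
NULL

# ---- minimal baseline TIFF --------------------------------------------------

tiff_write_gray16 <- function(data, path) {
  if (any(!is.finite(data))) {
    stop(kymovel_condition("kymovel_io_error", "non-finite intensities cannot be written"))
  }
  rounded <- round(data)
  if (any(rounded < 0) || any(rounded > 65535)) {
    stop(kymovel_condition(
      "kymovel_io_error",
      sprintf("intensities outside the 16-bit range [0, 65535] (found %.6g .. %.6g); refusing to clip",
              min(data), max(data))
    ))
  }
  nr <- nrow(data); nc <- ncol(data)
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  data_offset <- 8L
  n_bytes <- nr * nc * 2L
  ifd_offset <- data_offset + n_bytes
  writeBin(charToRaw("II"), con)
  w2(42L)
  w4(ifd_offset)
  # pixel data, row-major
  w2(as.vector(t(rounded)))
  # IFD: 10 entries
  entry <- function(tag, type, count, value) { w2(tag); w2(type); w4(count); w4(value) }
  w2(10L)
  entry(256L, 4L, 1L, nc)          # ImageWidth
  entry(257L, 4L, 1L, nr)          # ImageLength
  entry(258L, 3L, 1L, 16L)         # BitsPerSample
  entry(259L, 3L, 1L, 1L)          # Compression: none
  entry(262L, 3L, 1L, 1L)          # Photometric: BlackIsZero
  entry(273L, 4L, 1L, data_offset) # StripOffsets
  entry(277L, 3L, 1L, 1L)          # SamplesPerPixel
  entry(278L, 4L, 1L, nr)          # RowsPerStrip
  entry(279L, 4L, 1L, n_bytes)     # StripByteCounts
  entry(339L, 3L, 1L, 1L)          # SampleFormat: unsigned integer
  w4(0L)                           # no next IFD
  invisible(path)
}

tiff_read_gray <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8) stop(kymovel_condition("kymovel_io_error", "truncated TIFF"))
  order_tag <- rawToChar(raw[1:2])
  endian <- if (order_tag == "II") "little" else if (order_tag == "MM") "big" else {
    stop(kymovel_condition("kymovel_io_error", "not a TIFF file (bad byte-order mark)"))
  }
  rd <- function(off, size, n = 1, signed = TRUE) {
    readBin(raw[(off + 1):(off + size * n)], "integer", n = n, size = size,
            endian = endian, signed = if (size <= 2) signed else TRUE)
  }
  if (rd(2, 2, signed = FALSE) != 42) {
    stop(kymovel_condition("kymovel_io_error", "not a TIFF file (bad magic number)"))
  }
  ifd <- rd(4, 4)
  n_entries <- rd(ifd, 2, signed = FALSE)
  tags <- list()
  for (e in seq_len(n_entries)) {
    off <- ifd + 2 + (e - 1) * 12
    tag <- rd(off, 2, signed = FALSE)
    type <- rd(off + 2, 2, signed = FALSE)
    count <- rd(off + 4, 4)
    size <- c(1, 1, 2, 4)[type] # BYTE, ASCII, SHORT, LONG
    if (is.na(size)) next
    vals <- if (size * count <= 4) {
      rd(off + 8, size, count, signed = FALSE)
    } else {
      rd(rd(off + 8, 4), size, count, signed = FALSE)
    }
    tags[[as.character(tag)]] <- vals
  }
  need <- function(tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) {
      if (is.null(default)) {
        stop(kymovel_condition("kymovel_io_error", sprintf("TIFF missing tag %d", tag)))
      }
      default
    } else v
  }
  width <- need(256); height <- need(257)
  bits <- need(258, 8)
  if (need(259, 1) != 1) {
    stop(kymovel_condition("kymovel_io_error", "unsupported format: compressed TIFF"))
  }
  if (need(277, 1) != 1 || length(bits) != 1) {
    stop(kymovel_condition(
      "kymovel_io_error", "unsupported format: RGB / multi-channel TIFF"
    ))
  }
  if (!bits %in% c(8, 16)) {
    stop(kymovel_condition("kymovel_io_error", sprintf("unsupported bit depth %d", bits)))
  }
  offs <- need(273)
  counts <- need(279, width * height * bits / 8)
  px <- integer(0)
  for (s in seq_along(offs)) {
    n_px <- counts[s] / (bits / 8)
    px <- c(px, rd(offs[s], bits / 8, n_px, signed = FALSE))
  }
  if (length(px) != width * height) {
    stop(kymovel_condition("kymovel_io_error", "TIFF pixel data length mismatch"))
  }
  matrix(px, nrow = height, ncol = width, byrow = TRUE)
}

# ---- sidecar + public read/write -------------------------------------------

sidecar_path <- function(path) sub("\\.tiff?$", ".json", path, ignore.case = TRUE)

#' Write a line-scan image as TIFF + JSON sidecar
#'
#' Writes a 16-bit grayscale TIFF (intensities rounded to integers; values
#' outside 0..65535 raise an error rather than being clipped) and a sidecar
#' JSON with the scan configuration, ground truth (when present) and line
#' period.
#'
#' @param img A [linescan_image()].
#' @param path Output TIFF path (`.tif`); the sidecar replaces the extension
#'   with `.json`.
#' @return `path`, invisibly.
#' @export
write_linescan <- function(img, path) {
  tiff_write_gray16(img$data, path)
  sidecar <- list(
    scan = scan_config_to_list(img$cfg),
    t_line_s = img$t_line,
    cropped = img$cropped,
    section_index = img$section_index
  )
  if (!is.null(img$flow)) sidecar$flow <- flow_config_to_list(img$flow)
  jsonlite::write_json(sidecar, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a line-scan image from TIFF + JSON sidecar
#'
#' Orientation is fixed as time-down: TIFF row 0 is the first scanned line.
#' The scan configuration comes from the sidecar when present, otherwise from
#' `cfg`; with neither, an error lists the required fields.
#'
#' @param path TIFF path.
#' @param cfg Optional [scan_config()] overriding / replacing the sidecar.
#' @return A [linescan_image()].
#' @export
read_linescan <- function(path, cfg = NULL) {
  data <- tiff_read_gray(path)
  sc_path <- sidecar_path(path)
  flow <- NULL; t_line <- NULL; cropped <- FALSE; section_index <- NULL
  if (is.null(cfg)) {
    if (!file.exists(sc_path)) {
      stop(kymovel_condition(
        "kymovel_io_error",
        paste0("no sidecar JSON and no scan config supplied; required fields: ",
               "px_size_um, pixel_clock_khz, n_px_vessel ",
               "(optional: n_px_out_vessel, gamma_flyback, inertia_ratio_s2, ",
               "focal_length_mm, direction)")
      ))
    }
    sidecar <- jsonlite::fromJSON(sc_path)
    cfg <- scan_config_from_json(sidecar$scan)
    if (!is.null(sidecar$flow)) flow <- flow_config_from_list(sidecar$flow)
    t_line <- sidecar$t_line_s
    cropped <- isTRUE(sidecar$cropped)
    section_index <- sidecar$section_index
  }
  linescan_image(data + 0, cfg, flow = flow,
                 t_line = t_line %||% line_period(cfg),
                 cropped = cropped, section_index = section_index)
}

# ---- run manifest -----------------------------------------------------------

#' Write a run manifest
#'
#' Records tool version, command, resolved configuration, seeds and
#' input/output paths of a batch run in `manifest.json` inside `dir`.
#'
#' @param dir Output directory.
#' @param command Command name.
#' @param config Named list of resolved parameters.
#' @param seeds Integer seeds used.
#' @param inputs,outputs Character vectors of paths.
#' @return The manifest path, invisibly.
#' @export
write_run_manifest <- function(dir, command, config = list(), seeds = integer(0),
                               inputs = character(0), outputs = character(0)) {
  manifest <- list(
    tool = "kymovel",
    version = as.character(utils::packageVersion("kymovel")),
    command = command,
    config = config,
    seeds = seeds,
    inputs = inputs,
    outputs = outputs,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a run manifest
#' @param dir Directory containing `manifest.json`.
#' @return The manifest as a list.
#' @export
read_run_manifest <- function(dir) {
  jsonlite::fromJSON(file.path(dir, "manifest.json"))
}
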