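#' @title Calibrated multichannel images
#' @name calibrated-image
#' @description
#' A `CalibratedImage` bundles one or more single-channel 2D intensity
#' grids with a physical pixel calibration and a declared bit depth.
#' Channels are keyed by their biological role: the DNA counterstain
#' (used for nucleus segmentation) is mandatory; the euchromatin mark
#' H3K4me3, the heterochromatin mark H3K9me3 and cohesin are optional.
NULL

#' Recognised channel roles
#'
#' The DNA counterstain (e.g. DAPI) defines nucleus masks; the three
#' label roles carry the signals that are quantified per nucleus.
#'
#' @return Character vector of valid role names. `"dna"` is mandatory
#'   in every [CalibratedImage()]; `"h3k4me3"` (euchromatin),
#'   `"h3k9me3"` (heterochromatin) and `"cohesin"` are each optional.
#' @export
channel_roles <- function() c("dna", "h3k4me3", "h3k9me3", "cohesin")

#' Construct a calibrated multichannel image
#'
#' @param channels Named list of integer matrices, one per channel role
#'   (see [channel_roles()]). All matrices must share dimensions and the
#'   `"dna"` role must be present.
#' @param pixel_edge_nm Physical edge length of one pixel in nanometres
#'   (default 25.88). Pixels are assumed square; anisotropic
#'   calibrations are not supported.
#' @param bit_depth Declared acquisition bit depth; intensities must lie
#'   in `[0, 2^bit_depth - 1]`. Default 12 (range 0--4095), the typical
#'   confocal detector range even when files are stored in 16-bit
#'   containers.
#' @param source_id Opaque identifier for provenance (defaults to
#'   `"image"`).
#'
#' @return An object of class `CalibratedImage`: a list with elements
#'   `channels`, `pixel_edge_nm`, `bit_depth`, `source_id`.
#' @export
CalibratedImage <- function(channels, pixel_edge_nm = 25.88,
                            bit_depth = 12L, source_id = "image") {
  if (!is.list(channels) || is.null(names(channels)) ||
      any(!nzchar(names(channels)))) {
    stop("`channels` must be a named list of matrices", call. = FALSE)
  }
  bad <- setdiff(names(channels), channel_roles())
  if (length(bad)) {
    stop("unknown channel role(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(names(channels))) {
    stop("each channel role may appear at most once", call. = FALSE)
  }
  if (!"dna" %in% names(channels)) {
    stop("a 'dna' counterstain channel is mandatory", call. = FALSE)
  }
  dims <- lapply(channels, dim)
  if (any(vapply(channels, function(m) !is.matrix(m) || !is.numeric(m),
                 logical(1)))) {
    stop("every channel must be a numeric matrix", call. = FALSE)
  }
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1) {
    stop("all channels must share identical dimensions", call. = FALSE)
  }
  if (!is.numeric(pixel_edge_nm) || length(pixel_edge_nm) != 1 ||
      !is.finite(pixel_edge_nm) || pixel_edge_nm <= 0) {
    stop("`pixel_edge_nm` must be a single positive number", call. = FALSE)
  }
  bit_depth <- as.integer(bit_depth)
  if (is.na(bit_depth) || bit_depth < 1 || bit_depth > 16) {
    stop("`bit_depth` must be an integer in 1..16", call. = FALSE)
  }
  ceiling_i <- 2^bit_depth - 1
  for (role in names(channels)) {
    m <- channels[[role]]
    if (anyNA(m)) stop("channel '", role, "' contains NA", call. = FALSE)
    if (min(m) < 0 || max(m) > ceiling_i) {
      stop("channel '", role, "' has intensities outside [0, ",
           ceiling_i, "]", call. = FALSE)
    }
    storage.mode(channels[[role]]) <- "integer"
  }
  structure(
    list(channels = channels, pixel_edge_nm = pixel_edge_nm,
         bit_depth = bit_depth, source_id = as.character(source_id)),
    class = "CalibratedImage"
  )
}

#' @export
print.CalibratedImage <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat("<CalibratedImage> ", x$source_id, ": ", d[1], " x ", d[2],
      " px, ", x$pixel_edge_nm, " nm/px, ", x$bit_depth, "-bit\n",
      "  channels: ", paste(names(x$channels), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' @export
dim.CalibratedImage <- function(x) dim(x$channels[[1]])

#' Maximum representable intensity of an image
#' @param image A [CalibratedImage()].
#' @return `2^bit_depth - 1`.
#' @export
max_intensity <- function(image) 2^image$bit_depth - 1

#' Read a calibrated multichannel TIFF image
#'
#' Reads one multi-page TIFF (or several single-channel TIFFs) into a
#' [CalibratedImage()]. Channel roles are assigned by explicit
#' configuration, never inferred from TIFF metadata, because metadata
#' dialects vary between acquisition systems.
#'
#' @param path Either a single file path (pages addressed by
#'   `channel_map`) or a named character vector of per-role file paths
#'   (names are roles, values are paths; `channel_map` is then ignored).
#' @param channel_map Named integer vector mapping roles to page
#'   numbers, e.g. `c(dna = 1, cohesin = 2)`. Required for multi-page
#'   input.
#' @param pixel_edge_nm,bit_depth,source_id Passed to
#'   [CalibratedImage()]. Intensities above the declared bit-depth
#'   ceiling raise an error; they are never clamped.
#'
#' @return A [CalibratedImage()].
#' @export
read_multichannel_image <- function(path, channel_map = NULL,
                                    pixel_edge_nm = 25.88, bit_depth = 12L,
                                    source_id = NULL) {
  chans <- list()
  if (length(path) > 1 || !is.null(names(path))) {
    if (is.null(names(path)) || any(!nzchar(names(path)))) {
      stop("multiple paths must be named by channel role", call. = FALSE)
    }
    for (role in names(path)) {
      if (!file.exists(path[[role]])) {
        stop("file not found: ", path[[role]], call. = FALSE)
      }
      chans[[role]] <- read_tiff_page(path[[role]], 1L)
    }
    if (is.null(source_id)) source_id <- basename(path[[1]])
  } else {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    if (is.null(channel_map) || is.null(names(channel_map))) {
      stop("`channel_map` (role -> page) is required for multi-page input",
           call. = FALSE)
    }
    pages <- tiff::readTIFF(path, as.is = TRUE, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    for (role in names(channel_map)) {
      p <- as.integer(channel_map[[role]])
      if (p < 1 || p > length(pages)) {
        stop("channel_map page ", p, " out of range (file has ",
             length(pages), " pages)", call. = FALSE)
      }
      chans[[role]] <- as_grey_matrix(pages[[p]])
    }
    if (is.null(source_id)) source_id <- basename(path)
  }
  CalibratedImage(chans, pixel_edge_nm = pixel_edge_nm,
                  bit_depth = bit_depth, source_id = source_id)
}

read_tiff_page <- function(path, page) {
  x <- tiff::readTIFF(path, as.is = TRUE, all = FALSE)
  as_grey_matrix(x)
}

as_grey_matrix <- function(x) {
  if (length(dim(x)) == 3) {
    if (dim(x)[3] == 1) x <- x[, , 1] else {
      stop("multi-sample (colour) TIFF pages are not supported; ",
           "supply one grey page per channel", call. = FALSE)
    }
  }
  storage.mode(x) <- "integer"
  x
}

#' Write a calibrated image as a multi-page 16-bit TIFF
#'
#' Pages are written in the order of `image$channels`; the returned
#' channel map records the page of each role so the file can be read
#' back with [read_multichannel_image()].
#'
#' @param image A [CalibratedImage()].
#' @param path Output file path.
#' @return Invisibly, the named page map used.
#' @export
write_multichannel_tiff <- function(image, path) {
  stopifnot(inherits(image, "CalibratedImage"))
  pages <- lapply(image$channels, function(m) m / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(stats::setNames(seq_along(pages), names(image$channels)))
}

#' Physical area of one pixel
#'
#' @param pixel_edge_nm Pixel edge length in nanometres; must be
#'   positive.
#' @return Pixel area in nm^2 (`pixel_edge_nm^2`). At the default
#'   confocal calibration of 25.88 nm per pixel edge this is
#'   669.77 nm^2 (to 2 decimal places).
#' @export
pixel_area_nm2 <- function(pixel_edge_nm) {
  if (!is.numeric(pixel_edge_nm) || any(!is.finite(pixel_edge_nm)) ||
      any(pixel_edge_nm <= 0)) {
    stop("`pixel_edge_nm` must be positive", call. = FALSE)
  }
  pixel_edge_nm^2
}

#' Convert a pixel count to an area in square micrometres
#'
#' @param n_pixels Non-negative pixel count(s).
#' @param pixel_edge_nm Pixel edge length in nanometres.
#' @return `n_pixels * pixel_edge_nm^2 / 1e6`, in um^2.
#' @export
pixels_to_um2 <- function(n_pixels, pixel_edge_nm) {
  if (any(n_pixels < 0)) stop("`n_pixels` must be non-negative", call. = FALSE)
  n_pixels * pixel_area_nm2(pixel_edge_nm) / 1e6
}
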