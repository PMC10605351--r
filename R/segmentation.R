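#' @title Nucleus segmentation from the DNA counterstain
#' @name nucleus-segmentation
#' @description
#' Nucleus masks are derived from the DNA counterstain channel by a
#' global automatic threshold (Otsu), hole filling and connected-
#' component labeling. Quality control is rule-based and every
#' exclusion carries an explicit reason: `BORDER` (component touches
#' the image edge, so the nucleus is incomplete), `TOO_SMALL`
#' (sub-nuclear debris below a minimum area) or `TOO_WEAK` (label
#' signal too faint for reliable quantification). Touching nuclei are
#' not split: the analysis targets isolated nuclei in low-background
#' fields, and merged objects should be excluded upstream.
NULL

qc_reasons <- c("PASS", "BORDER", "TOO_SMALL", "TOO_WEAK")

#' Segment nuclei from a DNA-counterstain channel
#'
#' Foreground is determined by Otsu's threshold on the channel
#' histogram, holes are filled, and connected components are labeled
#' under 8-connectivity. Components touching the image border are
#' flagged `BORDER`; components smaller than `min_area_um2` are flagged
#' `TOO_SMALL`; the rest `PASS`.
#'
#' @param dna_channel Integer matrix of counterstain intensities.
#' @param min_area_um2 Minimum nucleus area in um^2 (default 20);
#'   smaller components are retained in the label map but flagged
#'   `TOO_SMALL`.
#' @param pixel_edge_nm Pixel calibration in nm (default 25.88).
#' @param bit_depth Declared bit depth of the channel (default 12).
#' @param connectivity Component connectivity, 4 or 8 (default 8).
#'
#' @return An object of class `NucleusMaskSet`: list with `label_map`
#'   (integer matrix, 0 = background), `nuclei` (data frame of
#'   per-nucleus records: `label`, `pixel_count`, bounding box,
#'   `touches_border`, `qc_pass`, `qc_reason`), `pixel_edge_nm` and
#'   `otsu_threshold`. A constant image yields an empty mask set.
#' @export
segment_nuclei <- function(dna_channel, min_area_um2 = 20,
                           pixel_edge_nm = 25.88, bit_depth = 12L,
                           connectivity = 8) {
  if (!is.matrix(dna_channel) || !length(dna_channel)) {
    stop("`dna_channel` must be a nonempty matrix", call. = FALSE)
  }
  maxI <- 2^as.integer(bit_depth) - 1
  rng <- range(dna_channel)
  if (rng[1] == rng[2]) {
    return(new_mask_set(matrix(0L, nrow(dna_channel), ncol(dna_channel)),
                        pixel_edge_nm, NA_real_))
  }
  thr <- EBImage::otsu(dna_channel / maxI, range = c(0, 1),
                       levels = maxI + 1L) * maxI
  fg <- dna_channel > thr
  fg <- EBImage::fillHull(fg * 1L) > 0
  lm <- label_components(fg, connectivity = connectivity)
  ms <- new_mask_set(lm, pixel_edge_nm, thr)
  if (nrow(ms$nuclei)) {
    area <- pixels_to_um2(ms$nuclei$pixel_count, pixel_edge_nm)
    reason <- ifelse(ms$nuclei$touches_border, "BORDER",
                     ifelse(area < min_area_um2, "TOO_SMALL", "PASS"))
    ms$nuclei$qc_reason <- reason
    ms$nuclei$qc_pass <- reason == "PASS"
    ms$nuclei$area_um2 <- area
  }
  ms
}

new_mask_set <- function(label_map, pixel_edge_nm, otsu_threshold) {
  rec <- component_records(label_map)
  rec$qc_reason <- rep("PASS", nrow(rec))
  rec$qc_pass <- rep(TRUE, nrow(rec))
  rec$area_um2 <- pixels_to_um2(rec$pixel_count, pixel_edge_nm)
  structure(list(label_map = label_map, nuclei = rec,
                 pixel_edge_nm = pixel_edge_nm,
                 otsu_threshold = otsu_threshold),
            class = "NucleusMaskSet")
}

#' @export
print.NucleusMaskSet <- function(x, ...) {
  cat("<NucleusMaskSet> ", nrow(x$nuclei), " nuclei (",
      sum(x$nuclei$qc_pass), " pass QC), Otsu threshold ",
      format(x$otsu_threshold, digits = 5), "\n", sep = "")
  invisible(x)
}

#' Logical mask of one nucleus
#' @param masks A `NucleusMaskSet`.
#' @param label Nucleus label.
#' @return Logical matrix, `TRUE` on the nucleus pixels.
#' @export
nucleus_mask <- function(masks, label) {
  stopifnot(inherits(masks, "NucleusMaskSet"))
  if (!label %in% masks$nuclei$label) {
    stop("no nucleus with label ", label, call. = FALSE)
  }
  masks$label_map == label
}

#' Eliminate extranuclear background from label channels
#'
#' Sets every label-channel intensity outside all nucleus masks to 0;
#' the DNA channel and all within-mask pixels are left unchanged. This
#' restricts all downstream quantification to nuclear signal.
#'
#' @param image A [CalibratedImage()].
#' @param masks A `NucleusMaskSet` with the same dimensions.
#' @return A [CalibratedImage()] with background-free label channels.
#' @export
mask_background <- function(image, masks) {
  stopifnot(inherits(image, "CalibratedImage"),
            inherits(masks, "NucleusMaskSet"))
  if (!identical(dim(image), dim(masks$label_map))) {
    stop("image and mask dimensions differ", call. = FALSE)
  }
  outside <- masks$label_map == 0L
  for (role in setdiff(names(image$channels), "dna")) {
    ch <- image$channels[[role]]
    ch[outside] <- 0L
    image$channels[[role]] <- ch
  }
  image
}

#' Flag nuclei whose label signal is too weak
#'
#' Nuclei whose within-mask mean intensity of `channel` falls below
#' `min_mean_intensity` are flagged `TOO_WEAK` (only nuclei currently
#' passing QC are re-flagged). The default threshold of 0 disables the
#' filter; any nonzero value used should be reported alongside results.
#'
#' @param channel Integer matrix of a label channel.
#' @param masks A `NucleusMaskSet`.
#' @param min_mean_intensity Minimum acceptable within-mask mean.
#' @return The updated `NucleusMaskSet`.
#' @export
flag_weak_signal <- function(channel, masks, min_mean_intensity = 0) {
  stopifnot(inherits(masks, "NucleusMaskSet"))
  if (min_mean_intensity <= 0 || !nrow(masks$nuclei)) return(masks)
  for (i in which(masks$nuclei$qc_pass)) {
    lab <- masks$nuclei$label[i]
    m <- mean(channel[masks$label_map == lab])
    if (m < min_mean_intensity) {
      masks$nuclei$qc_reason[i] <- "TOO_WEAK"
      masks$nuclei$qc_pass[i] <- FALSE
    }
  }
  masks
}
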