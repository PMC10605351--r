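#' @title Per-nucleus size and signal amount
#' @name signal-quantification
#' @description
#' For each nucleus the pipeline reports its area (um^2) and, per label
#' channel, the within-mask mean intensity and the signal "amount":
#' mean intensity times the nucleus size in pixels, i.e. the integrated
#' within-mask intensity in arbitrary units x pixels. No background is
#' subtracted inside the mask and no cross-image normalisation is
#' applied; amounts are comparable across images only when slides were
#' labeled and imaged under identical conditions.
NULL

#' Nucleus area in square micrometres
#'
#' @param mask Logical matrix (nonempty) of nucleus pixels.
#' @param pixel_edge_nm Pixel calibration in nm.
#' @return Area in um^2.
#' @export
nucleus_area_um2 <- function(mask, pixel_edge_nm) {
  n <- sum(mask != 0)
  if (n == 0) stop("empty nucleus mask", call. = FALSE)
  pixels_to_um2(n, pixel_edge_nm)
}

#' Mean intensity and amount of a channel within a nucleus
#'
#' @param channel Intensity matrix.
#' @param mask Logical matrix (nonempty) of nucleus pixels, same
#'   dimensions as `channel`.
#' @return List with `mean_intensity` (arithmetic within-mask mean) and
#'   `amount` (`mean_intensity * pixel_count`, identical to the
#'   integrated within-mask intensity).
#' @export
channel_amount <- function(channel, mask) {
  if (!identical(dim(channel), dim(mask))) {
    stop("channel and mask dimensions differ", call. = FALSE)
  }
  keep <- mask != 0
  n <- sum(keep)
  if (n == 0) stop("empty nucleus mask", call. = FALSE)
  m <- mean(channel[keep])
  list(mean_intensity = m, amount = m * n)
}

#' Per-nucleus metrics table
#'
#' Computes, for every QC-passing nucleus, its pixel count and area and
#' for each label channel the mean intensity, the amount
#' (intensity x pixels) and a convenience amount in intensity x um^2.
#'
#' @param image A [CalibratedImage()] (background-masked or not; only
#'   within-mask pixels enter the metrics).
#' @param masks A `NucleusMaskSet` for the same image.
#' @param channels Label channel roles to quantify; defaults to every
#'   non-DNA channel present.
#' @return Data frame with one row per passing nucleus: `nucleus_label`,
#'   `pixel_count`, `area_um2`, then per channel `mean_<role>`,
#'   `amount_<role>`, `amount_um2_<role>`.
#' @export
quantify_nuclei <- function(image, masks,
                            channels = setdiff(names(image$channels), "dna")) {
  stopifnot(inherits(image, "CalibratedImage"),
            inherits(masks, "NucleusMaskSet"))
  rec <- masks$nuclei[masks$nuclei$qc_pass, , drop = FALSE]
  out <- data.frame(nucleus_label = rec$label,
                    pixel_count = rec$pixel_count,
                    area_um2 = pixels_to_um2(rec$pixel_count,
                                             masks$pixel_edge_nm))
  for (role in channels) {
    ch <- image$channels[[role]]
    if (is.null(ch)) stop("image has no channel '", role, "'", call. = FALSE)
    means <- amounts <- numeric(nrow(rec))
    for (i in seq_len(nrow(rec))) {
      ca <- channel_amount(ch, masks$label_map == rec$label[i])
      means[i] <- ca$mean_intensity
      amounts[i] <- ca$amount
    }
    out[[paste0("mean_", role)]] <- means
    out[[paste0("amount_", role)]] <- amounts
    out[[paste0("amount_um2_", role)]] <-
      means * pixels_to_um2(rec$pixel_count, masks$pixel_edge_nm)
  }
  out
}
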