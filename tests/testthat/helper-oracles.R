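# Independent oracles used across tests. These deliberately share no
# code with the package implementation.

# Stack-based flood fill labeling; labels assigned in column-major scan
# order (same ordering convention the package documents), so label maps
# are directly comparable.
flood_label <- function(mask, connectivity = 8) {
  mask <- mask != 0
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(0L, nr, nc)
  if (connectivity == 8) {
    dr <- c(-1, -1, -1, 0, 0, 1, 1, 1)
    dc <- c(-1, 0, 1, -1, 1, -1, 0, 1)
  } else {
    dr <- c(-1, 1, 0, 0)
    dc <- c(0, 0, -1, 1)
  }
  lab <- 0L
  stack_r <- integer(nr * nc); stack_c <- integer(nr * nc)
  for (ci in seq_len(nc)) {
    for (ri in seq_len(nr)) {
      if (!mask[ri, ci] || out[ri, ci] > 0L) next
      lab <- lab + 1L
      top <- 1L; stack_r[1] <- ri; stack_c[1] <- ci
      out[ri, ci] <- lab
      while (top > 0L) {
        r <- stack_r[top]; c <- stack_c[top]; top <- top - 1L
        for (k in seq_along(dr)) {
          r2 <- r + dr[k]; c2 <- c + dc[k]
          if (r2 >= 1L && r2 <= nr && c2 >= 1L && c2 <= nc &&
              mask[r2, c2] && out[r2, c2] == 0L) {
            out[r2, c2] <- lab
            top <- top + 1L
            stack_r[top] <- r2; stack_c[top] <- c2
          }
        }
      }
    }
  }
  out
}

# A disk-shaped logical mask centred in an h x w frame.
disk_mask <- function(h, w, center, radius) {
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  (rr - center[1])^2 + (cc - center[2])^2 <= radius^2
}

# Random field of non-overlapping cone-profile spots over a flat floor.
# Every level set of a cone is a disk, so the image's above-threshold
# component count is provably non-increasing in the threshold.
random_cone_field <- function(h, w, n_cones, base_r, peak, floor_lvl) {
  ch <- matrix(floor_lvl, h, w)
  centers <- matrix(NA_real_, 0, 2)
  placed <- 0
  attempts <- 0
  while (placed < n_cones && attempts < 500 * n_cones) {
    attempts <- attempts + 1
    ctr <- c(runif(1, base_r + 1, h - base_r), runif(1, base_r + 1, w - base_r))
    if (nrow(centers) &&
        any(sqrt((centers[, 1] - ctr[1])^2 +
                 (centers[, 2] - ctr[2])^2) < 2 * base_r + 2)) next
    centers <- rbind(centers, ctr)
    placed <- placed + 1
    rr <- matrix(seq_len(h), h, w)
    cc <- matrix(seq_len(w), h, w, byrow = TRUE)
    d <- sqrt((rr - ctr[1])^2 + (cc - ctr[2])^2)
    cone <- pmax(0, 1 - d / base_r) * (peak - floor_lvl) + floor_lvl
    ch <- pmax(ch, cone)
  }
  m <- round(ch)
  storage.mode(m) <- "integer"
  m
}

# A high-SNR single-nucleus scene with a given planted granule count.
highsnr_scene <- function(n_granules, seed) {
  generate_scene(scene_preset(
    "highsnr", seed = seed,
    channels = list(cohesin = list(diffuse_level = 800,
                                   granule_count = n_granules,
                                   granule_radius_px = c(2.3, 2.6),
                                   granule_amplitude = 1800,
                                   noise_sd = 40))))
}
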