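test_that("within-mask histograms conserve counts and bin correctly", {
  mask <- matrix(TRUE, 10, 10)
  h <- build_histogram(matrix(100L, 10, 10), mask)
  expect_equal(sum(h$counts > 0), 1)
  expect_equal(sum(h$counts), 100)

  two <- matrix(c(rep(1000L, 50), rep(3000L, 50)), 10, 10)
  h2 <- build_histogram(two, mask)
  expect_equal(sort(h2$counts[h2$counts > 0]), c(50, 50))

  set.seed(41)
  ch <- matrix(sample(0:4095, 400, TRUE), 20, 20)
  m <- matrix(runif(400) < 0.5, 20, 20)
  expect_equal(sum(build_histogram(ch, m)$counts), sum(m))
  expect_error(build_histogram(ch, matrix(FALSE, 20, 20)), "empty")
})

test_that("smoothing recovers the two modes of a balanced mixture", {
  set.seed(42)
  binw <- 4096 / 256
  for (rep in 1:10) {
    v <- round(c(rnorm(5000, 800, 60), rnorm(5000, 2600, 60)))
    mask <- matrix(TRUE, 100, 100)
    h <- build_histogram(matrix(as.integer(v), 100, 100), mask)
    bt <- smooth_to_bimodal(h)
    expect_true(bt$bimodal)
    expect_lte(abs(bt$mode_lo - 800), binw)
    expect_lte(abs(bt$mode_hi - 2600), binw)
    expect_lte(abs(bt$threshold - 1700), binw)
    # brute-force check of the stopping state: both reported modes are
    # strict local maxima of the smoothed vector, separated by a valley
    # below half the smaller mode
    s <- bt$smoothed
    i_lo <- which.min(abs(h$mids - bt$mode_lo))
    i_hi <- which.min(abs(h$mids - bt$mode_hi))
    for (i in c(i_lo, i_hi)) {
      expect_true(s[i] > s[i - 1] && s[i] > s[i + 1])
    }
    expect_lte(min(s[i_lo:i_hi]), 0.5 * min(s[i_lo], s[i_hi]))
  }
})

test_that("a unimodal histogram never yields a threshold", {
  set.seed(43)
  for (rep in 1:10) {
    v <- round(rnorm(8000, 1500, 80))
    mask <- matrix(TRUE, 80, 100)
    bt <- smooth_to_bimodal(build_histogram(matrix(as.integer(v), 80, 100),
                                            mask))
    expect_false(bt$bimodal)
    expect_true(is.na(bt$threshold))
  }
  # degenerate: everything in one bin
  flat <- smooth_to_bimodal(build_histogram(matrix(7L, 5, 5),
                                            matrix(TRUE, 5, 5)))
  expect_false(flat$bimodal)
})

test_that("an already-bimodal histogram needs no smoothing passes", {
  counts <- rep(0, 256)
  counts[50] <- 400; counts[163] <- 300
  bt <- smooth_to_bimodal(counts)
  expect_true(bt$bimodal)
  expect_equal(bt$smoothing_passes, 0)
  expect_equal(bt$mode_lo, 50)
  expect_equal(bt$mode_hi, 163)
})

test_that("the threshold is the exact midpoint of the two modes", {
  expect_equal(compute_threshold(100, 200), 150)
  expect_equal(compute_threshold(0, 4095), 2047.5)
  expect_error(compute_threshold(200, 100), "strictly less")
  expect_error(compute_threshold(5, 5), "strictly less")
  set.seed(44)
  for (rep in 1:200) {
    j <- runif(1, 0, 2000); k <- j + runif(1, 1, 2000)
    c <- runif(1, -50, 50)
    expect_equal(compute_threshold(j, k), 0.5 * (j + k))
    expect_equal(compute_threshold(j + c, k + c),
                 compute_threshold(j, k) + c)
  }
})

test_that("granule pixel selection is strictly greater-than", {
  ch <- matrix(as.integer(c(999, 1000, 1001, 0)), 2, 2)
  mask <- matrix(TRUE, 2, 2)
  sel <- select_granule_pixels(ch, mask, 1000)
  expect_identical(as.vector(sel), c(FALSE, FALSE, TRUE, FALSE))
  expect_false(any(select_granule_pixels(ch, mask, 4095)))
  expect_true(all(select_granule_pixels(ch, mask, -1) == mask))
  # masked-out pixels are never selected
  m2 <- mask; m2[1, ] <- FALSE
  expect_false(any(select_granule_pixels(ch, m2, -1)[1, ]))
})

test_that("median refinement removes isolated pixels, keeps blocks", {
  mask <- matrix(TRUE, 9, 9)
  ch <- matrix(100L, 9, 9)
  ch[5, 5] <- 3000L  # isolated bright pixel
  sel <- select_granule_pixels(ch, mask, 1000)
  expect_equal(sum(sel), 1)
  ref <- median_refine(ch, sel, mask, 1000, window = 3)
  # hand oracle: median of the 9-neighbourhood of (5,5) is 100 < t
  expect_equal(sum(ref), 0)

  blk <- matrix(100L, 11, 11)
  blk[4:8, 4:8] <- 3000L  # 5 x 5 block, larger than the window
  sel2 <- select_granule_pixels(blk, mask <- matrix(TRUE, 11, 11), 1000)
  ref2 <- median_refine(blk, sel2, mask, 1000, window = 3)
  expect_true(all(ref2[5:7, 5:7]))  # interior certainly retained

  # constant image: filter is the identity
  const <- matrix(500L, 7, 7)
  m <- matrix(TRUE, 7, 7)
  expect_equal(masked_median_filter(const, m), const + 0)
  expect_error(masked_median_filter(const, m, window = 4), "odd")
})

test_that("the median filter never looks outside the mask", {
  set.seed(45)
  ch <- matrix(sample(0:4095, 225, TRUE), 15, 15)
  mask <- disk_mask(15, 15, c(8, 8), 5)
  base <- masked_median_filter(ch, mask)
  pert <- ch
  pert[!mask] <- sample(0:4095, sum(!mask), TRUE)
  expect_identical(masked_median_filter(pert, mask)[mask], base[mask])
  # hand oracle at a boundary pixel
  idx <- which(mask, arr.ind = TRUE)
  p <- idx[which.min(idx[, 1]), , drop = FALSE]  # topmost mask pixel
  win_r <- max(1, p[1] - 1):min(15, p[1] + 1)
  win_c <- max(1, p[2] - 1):min(15, p[2] + 1)
  vals <- ch[win_r, win_c][mask[win_r, win_c]]
  expect_equal(base[p], median(vals))
})

test_that("granule labeling matches the flood-fill oracle", {
  set.seed(46)
  for (rep in 1:20) {
    g <- matrix(runif(64 * 64) < 0.35, 64, 64)
    for (conn in c(4, 8)) {
      expect_identical(label_components(g, conn), flood_label(g, conn))
    }
  }
})

test_that("granules below the minimum size are discarded", {
  ch <- matrix(100L, 12, 12)
  sel <- matrix(FALSE, 12, 12)
  # plus-shaped 5-px blob and a second one, disjoint
  sel[3, 3] <- sel[2, 3] <- sel[4, 3] <- sel[3, 2] <- sel[3, 4] <- TRUE
  sel[9, 9] <- sel[8, 9] <- sel[10, 9] <- sel[9, 8] <- sel[9, 10] <- TRUE
  gs <- label_granules(sel, ch, min_size_px = 5)
  expect_equal(nrow(gs$granules), 2)
  expect_equal(gs$granules$pixel_count, c(5L, 5L))

  four <- matrix(FALSE, 8, 8); four[3:4, 3:4] <- TRUE
  expect_equal(nrow(label_granules(four, ch[1:8, 1:8],
                                   min_size_px = 5)$granules), 0)
  expect_equal(nrow(label_granules(four, ch[1:8, 1:8],
                                   min_size_px = 4)$granules), 1)
})

test_that("connectivity controls diagonal merging exactly as labeled", {
  sel <- matrix(FALSE, 12, 12)
  sel[2:4, 2:4] <- TRUE       # 9-px block
  sel[5:7, 5:7] <- TRUE       # second block, touching only diagonally
  ch <- matrix(1000L, 12, 12)
  g8 <- label_granules(sel, ch, connectivity = 8, min_size_px = 5)
  g4 <- label_granules(sel, ch, connectivity = 4, min_size_px = 5)
  expect_equal(nrow(g8$granules), 1)
  expect_equal(nrow(g4$granules), 2)
  expect_identical(label_components(sel, 8), flood_label(sel, 8))
  expect_identical(label_components(sel, 4), flood_label(sel, 4))
})

test_that("granule mean intensities come from the original image", {
  ch <- matrix(100L, 10, 10)
  sel <- matrix(FALSE, 10, 10)
  sel[3:5, 3:5] <- TRUE
  ch[3:5, 3:5] <- 2000L
  ch[4, 4] <- 3000L
  gs <- label_granules(sel, ch, min_size_px = 5)
  expect_equal(gs$granules$mean_intensity, (8 * 2000 + 3000) / 9)
  expect_equal(gs$granules$centroid_row, 4)
  expect_equal(gs$granules$centroid_col, 4)
})

test_that("granularity summary pools pixels, not granules", {
  # granules of sizes 5 and 15 with uniform intensities 1000 and 3000:
  # the pixel-weighted pooled mean is 2500, not the granule mean 2000
  ch <- matrix(0L, 20, 20)
  sel <- matrix(FALSE, 20, 20)
  sel[3, 3:7] <- TRUE;  ch[3, 3:7] <- 1000L           # 5 px
  sel[10:12, 10:14] <- TRUE; ch[10:12, 10:14] <- 3000L # 15 px
  gs <- label_granules(sel, ch, min_size_px = 5)
  sm <- summarize_granularity(gs, ch)
  expect_equal(sm$n_granules, 2)
  expect_equal(sm$mean_area_px, 10)
  expect_equal(sm$pixelwise_mean_intensity, 2500)
  expect_equal(sm$granulewise_mean_intensity, 2000)

  single <- label_granules(sel & (ch == 1000L), ch, min_size_px = 5)
  sm1 <- summarize_granularity(single, ch)
  expect_equal(sm1$pixelwise_mean_intensity,
               single$granules$mean_intensity)

  none <- label_granules(matrix(FALSE, 5, 5), matrix(0L, 5, 5))
  sm0 <- summarize_granularity(none, matrix(0L, 5, 5))
  expect_equal(sm0$n_granules, 0)
  expect_true(is.na(sm0$mean_area_px))
  expect_true(is.na(sm0$pixelwise_mean_intensity))
})

test_that("granule count is monotone in min_size_px and threshold", {
  # random scenes of non-overlapping cone-profile granules: level sets
  # are nested disks, so counts must fall as either knob rises
  set.seed(47)
  for (rep in 1:5) {
    ch <- random_cone_field(72, 72, n_cones = 8, base_r = 5,
                            peak = 3500, floor_lvl = 300)
    mask <- matrix(TRUE, 72, 72)
    counts_s <- vapply(c(1, 3, 5, 9, 15, 40), function(ms) {
      sel <- select_granule_pixels(ch, mask, 1200)
      nrow(label_granules(sel, ch, min_size_px = ms)$granules)
    }, numeric(1))
    expect_true(all(diff(counts_s) <= 0))
    counts_t <- vapply(c(600, 1200, 1800, 2400, 3000, 3600, 4095),
                       function(t) {
      sel <- select_granule_pixels(ch, mask, t)
      nrow(label_granules(sel, ch, min_size_px = 5)$granules)
    }, numeric(1))
    expect_true(all(diff(counts_t) <= 0))
    expect_equal(counts_t[7], 0)
  }
})
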