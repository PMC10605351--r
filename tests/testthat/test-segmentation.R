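test_that("a single bright disk is segmented to its planted area", {
  set.seed(21)
  h <- 128; w <- 128
  bg <- matrix(round(rnorm(h * w, 100, 5)), h, w)
  dm <- disk_mask(h, w, c(64, 64), 40)
  img <- bg
  img[dm] <- round(rnorm(sum(dm), 3000, 5))
  storage.mode(img) <- "integer"

  masks <- segment_nuclei(img, min_area_um2 = 0, pixel_edge_nm = 1000)
  expect_equal(nrow(masks$nuclei), 1)
  expect_equal(masks$nuclei$qc_reason, "PASS")
  # brute-force oracle: threshold at the known intensity midpoint
  oracle_count <- sum(img > 1550)
  expect_lt(abs(masks$nuclei$pixel_count - oracle_count) / oracle_count, 0.03)
})

test_that("degenerate and border cases follow the stated rules", {
  blank <- matrix(0L, 32, 32)
  expect_equal(nrow(segment_nuclei(blank)$nuclei), 0)
  flat <- matrix(1234L, 32, 32)
  expect_equal(nrow(segment_nuclei(flat)$nuclei), 0)

  set.seed(22)
  h <- 96; w <- 96
  img <- matrix(round(rnorm(h * w, 100, 5)), h, w)
  dm <- disk_mask(h, w, c(3, 48), 20)  # intersects the top edge
  img[dm] <- 3000L
  storage.mode(img) <- "integer"
  masks <- segment_nuclei(img, min_area_um2 = 0, pixel_edge_nm = 1000)
  expect_equal(nrow(masks$nuclei), 1)
  expect_equal(masks$nuclei$qc_reason, "BORDER")
  expect_false(masks$nuclei$qc_pass)
})

test_that("small components are flagged TOO_SMALL, not dropped", {
  set.seed(23)
  h <- 128; w <- 128
  img <- matrix(round(rnorm(h * w, 100, 5)), h, w)
  img[disk_mask(h, w, c(40, 40), 25)] <- 3000L
  img[disk_mask(h, w, c(100, 100), 3)] <- 3000L
  storage.mode(img) <- "integer"
  # 1000 nm pixels: the small disk is ~29 px = 29 um2 < 50
  masks <- segment_nuclei(img, min_area_um2 = 50, pixel_edge_nm = 1000)
  expect_equal(nrow(masks$nuclei), 2)
  expect_setequal(masks$nuclei$qc_reason, c("PASS", "TOO_SMALL"))
  # labels and records stay bijective
  expect_setequal(unique(as.vector(masks$label_map[masks$label_map > 0])),
                  masks$nuclei$label)
})

test_that("holes inside nuclei are filled", {
  set.seed(24)
  h <- 96; w <- 96
  img <- matrix(round(rnorm(h * w, 100, 5)), h, w)
  dm <- disk_mask(h, w, c(48, 48), 30)
  img[dm] <- 3000L
  hole <- disk_mask(h, w, c(48, 48), 5)
  img[hole] <- 100L
  storage.mode(img) <- "integer"
  masks <- segment_nuclei(img, min_area_um2 = 0, pixel_edge_nm = 1000)
  expect_equal(nrow(masks$nuclei), 1)
  expect_true(all(masks$label_map[hole] == masks$nuclei$label))
})

test_that("recovered nucleus count equals planted count on clean scenes", {
  for (seed in 1:5) {
    sc <- generate_scene(scene_preset("paperlike", seed = seed))
    masks <- segment_nuclei(sc$image$channels$dna,
                            pixel_edge_nm = sc$image$pixel_edge_nm)
    expect_equal(nrow(masks$nuclei), nrow(sc$truth$nuclei))
    # per-nucleus pixel sets recovered to within 2%
    got <- sort(masks$nuclei$pixel_count)
    want <- sort(sc$truth$nuclei$pixel_count)
    expect_true(all(abs(got - want) / want < 0.02))
  }
})

test_that("mask_background zeroes label channels outside nuclei only", {
  sc <- generate_scene(scene_preset("highsnr", seed = 9))
  masks <- segment_nuclei(sc$image$channels$dna,
                          pixel_edge_nm = sc$image$pixel_edge_nm)
  clean <- mask_background(sc$image, masks)
  outside <- masks$label_map == 0
  expect_true(all(clean$channels$cohesin[outside] == 0))
  expect_identical(clean$channels$cohesin[!outside],
                   sc$image$channels$cohesin[!outside])
  expect_identical(clean$channels$dna, sc$image$channels$dna)

  empty <- segment_nuclei(matrix(0L, 256, 256))
  empty$pixel_edge_nm <- sc$image$pixel_edge_nm
  allzero <- mask_background(sc$image, empty)
  expect_true(all(allzero$channels$cohesin == 0))

  bad <- segment_nuclei(matrix(0L, 16, 16))
  expect_error(mask_background(sc$image, bad), "dimensions")
})

test_that("weak-signal flagging follows the mean-intensity rule", {
  sc <- generate_scene(scene_preset("highsnr", seed = 10))
  masks <- segment_nuclei(sc$image$channels$dna,
                          pixel_edge_nm = sc$image$pixel_edge_nm)
  ch <- sc$image$channels$cohesin
  lab <- masks$nuclei$label[1]
  m <- mean(ch[masks$label_map == lab])

  keep <- flag_weak_signal(ch, masks, min_mean_intensity = m - 1)
  expect_true(keep$nuclei$qc_pass[1])
  drop <- flag_weak_signal(ch, masks, min_mean_intensity = m + 1)
  expect_equal(drop$nuclei$qc_reason[1], "TOO_WEAK")
  off <- flag_weak_signal(ch, masks, min_mean_intensity = 0)
  expect_identical(off$nuclei, masks$nuclei)
})

test_that("per-nucleus metrics ignore pixels outside the nucleus mask", {
  sc <- generate_scene(scene_preset("highsnr", seed = 12))
  masks <- segment_nuclei(sc$image$channels$dna,
                          pixel_edge_nm = sc$image$pixel_edge_nm)
  img <- mask_background(sc$image, masks)
  base_met <- quantify_nuclei(img, masks)
  base_gran <- analyze_granularity(img, masks, "cohesin")

  set.seed(99)
  outside_idx <- which(masks$label_map == 0)
  for (rep in 1:3) {
    pert <- img
    hit <- sample(outside_idx, 500)
    ch <- pert$channels$cohesin
    ch[hit] <- sample(0:4095, 500, TRUE)
    pert$channels$cohesin <- ch
    expect_identical(quantify_nuclei(pert, masks), base_met)
    pg <- analyze_granularity(pert, masks, "cohesin")
    expect_identical(pg$summary, base_gran$summary)
    expect_identical(pg$granules, base_gran$granules)
  }
})
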