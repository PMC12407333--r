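test_that("illumination correction zeroes a constant image", {
  img <- matrix(37, 128, 128)
  out <- correct_illumination(img, block_size = 32)
  expect_lt(max(abs(out)), 1e-6)
})

test_that("illumination correction removes a planar gradient", {
  x <- matrix(rep(seq(0, 100, length.out = 128), each = 128), 128, 128)
  out <- correct_illumination(x, block_size = 32, poly_order = 1)
  expect_lt(max(out), 0.01 * 100)
})

test_that("illumination correction preserves sparse bright spots", {
  nr <- 256
  x <- matrix(rep(seq(0, 50, length.out = nr), each = nr), nr, nr)
  spots <- rbind(c(40, 40), c(40, 200), c(200, 40), c(200, 200), c(128, 128))
  spot_sum <- 0
  for (i in seq_len(nrow(spots))) {
    rr <- spots[i, 1] + (-3:3)
    cc <- spots[i, 2] + (-3:3)
    x[rr, cc] <- x[rr, cc] + 500
    spot_sum <- spot_sum + 500 * 49
  }
  out <- correct_illumination(x, block_size = 64, poly_order = 1)
  got <- 0
  for (i in seq_len(nrow(spots))) {
    rr <- spots[i, 1] + (-3:3)
    cc <- spots[i, 2] + (-3:3)
    got <- got + sum(out[rr, cc])
  }
  expect_lt(abs(got - spot_sum) / spot_sum, 0.05)
})

test_that("illumination correction rejects undersized images and orders", {
  expect_error(correct_illumination(matrix(0, 16, 16), block_size = 32),
               "smaller than a single block")
  expect_error(correct_illumination(matrix(0, 64, 64), poly_order = 7),
               "poly_order")
})

test_that("rolling ball zeroes a constant image", {
  out <- rolling_ball_subtract(matrix(12, 64, 64), radius = 10)
  expect_lt(max(abs(out)), 1e-9)
})

test_that("rolling ball preserves an isolated bright disk", {
  img <- matrix(0, 128, 128)
  center <- c(64, 64)
  for (r in -6:6) for (c in -6:6) {
    if (r^2 + c^2 <= 36) img[64 + r, 64 + c] <- 100
  }
  disk_sum <- sum(img)
  out <- rolling_ball_subtract(img, radius = 20)
  expect_lt(abs(sum(out) - disk_sum) / disk_sum, 0.05)
})

test_that("rolling ball removes a slowly varying background", {
  x <- matrix(rep(seq(0, 40, length.out = 256), each = 256), 256, 256)
  out <- rolling_ball_subtract(x, radius = 25)
  expect_lt(max(out), 0.02 * 40)
})

test_that("rolling ball rejects a radius beyond the image extent", {
  expect_error(rolling_ball_subtract(matrix(0, 32, 32), radius = 20),
               "exceeds the image extent")
})

test_that("segmentation recovers separated nuclei with high IoU", {
  fx <- run_seg_fixture(seed = 21, n = 20)
  mask <- fx$mask
  expect_equal(max(mask), 20)
  expect_true(all(fx$match$iou >= 0.7))
})

test_that("blank images yield empty masks, not errors", {
  expect_equal(max(segment_nuclei(matrix(0, 64, 64))), 0)
})

test_that("watershed splits a touching doublet with clear necking", {
  img <- matrix(0, 96, 96)
  for (r in 1:96) for (c in 1:96) {
    d1 <- sqrt((r - 48)^2 + (c - 36)^2)
    d2 <- sqrt((r - 48)^2 + (c - 60)^2)
    if (d1 <= 13 || d2 <= 13) img[r, c] <- 100
  }
  mask <- segment_nuclei(img, min_area = 50)
  expect_equal(max(mask), 2)
})

test_that("measurement integrates intensity over the mask region only", {
  mask <- matrix(0L, 16, 16)
  mask[3:4, 3:7] <- 1L # 10 pixels
  ch <- list(dna = matrix(1, 16, 16))
  out <- measure_nuclei(mask, ch)
  expect_equal(out$dna, 10)
  expect_equal(out$area, 10)
})

test_that("measured integrated DNA tracks truth linearly at low noise", {
  fx <- run_seg_fixture(seed = 22, n = 50)
  m <- fx$meas[!is.na(fx$meas$truth_label), ]
  fit <- stats::lm(m$dna ~ m$dna.truth)
  expect_gt(summary(fit)$r.squared, 0.99)
})

test_that("an empty mask gives an empty measurement table", {
  out <- measure_nuclei(matrix(0L, 8, 8), list(dna = matrix(1, 8, 8)))
  expect_equal(nrow(out), 0)
})

test_that("channel shape mismatches are rejected", {
  expect_error(measure_nuclei(matrix(0L, 8, 8), list(dna = matrix(1, 4, 4))),
               "shape")
})

test_that("segmentation and measurement conserve photons", {
  fx <- run_seg_fixture(seed = 21, n = 20)
  corrected_total <- sum(fx$img$channels$dna)
  expect_lte(sum(fx$meas$dna), corrected_total)
})
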