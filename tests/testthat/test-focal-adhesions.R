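test_that("background subtraction removes flat and ramp backgrounds", {
  flat <- intensity_image(matrix(0.4, 80, 80), 0.1)
  out <- subtract_background(flat, 10)
  expect_true(all(unclass(out) == 0))

  # small bright disk on a linear ramp
  nr <- 120
  ramp <- matrix(rep(seq(0, 0.3, length.out = nr), each = nr), nr, nr)
  g <- expand.grid(r = 1:nr, c = 1:nr)
  disk <- matrix((g$r - 60)^2 + (g$c - 60)^2 <= 6^2, nr, nr)
  img <- intensity_image(ramp + 0.5 * disk, 0.1)
  sub <- subtract_background(img, 25)
  expect_gt(max(unclass(sub)[disk]), 0.9 * 0.5)              # peak kept
  # ramp removed in the interior (morphological boundary effects are
  # confined to within one structuring element of the border)
  interior <- matrix(FALSE, nr, nr)
  interior[26:(nr - 25), 26:(nr - 25)] <- TRUE
  expect_lt(max(unclass(sub)[interior & !disk]), 0.05 * 0.3)
  expect_true(all(unclass(sub) >= 0))

  expect_error(subtract_background(flat, 200), "exceeds")
})

test_that("8-bit conversion before or after subtraction gives the same mask", {
  mask <- make_cell_mask(c(260, 260), c(110, 80), 0.1)
  img <- generate_fa_image(mask, 6, function(n) runif(n, 5, 8), seed = 3)
  to8 <- function(im) intensity_image(round(unclass(im) * 255) / 255,
                                      pixel_size(im))
  m1 <- segment_fas(subtract_background(to8(img$marker), 30))
  m2 <- segment_fas(to8(subtract_background(img$marker, 30)))
  expect_equal(unclass(m1) > 0, unclass(m2) > 0)
})

test_that("FA segmentation recovers counts and applies the minimum size", {
  mask <- make_cell_mask(c(300, 300), c(120, 95), 0.1)

  # blank channel: flat background with isolated hot pixels (salt noise);
  # every thresholded speck falls below the minimum size
  blank <- matrix(0.05, 300, 300)
  blank[with_seed(2, sample(9e4, 40))] <- 0.6
  expect_equal(max(segment_fas(intensity_image(blank, 0.1))), 0L)
  expect_error(segment_fas(intensity_image(matrix(0.2, 50, 50), 0.1)),
               "zero intensity range")

  ten <- generate_fa_image(mask, 10, function(n) runif(n, 5, 9), seed = 11)
  expect_equal(max(segment_fas(ten$marker)), 10L)

  strad <- generate_fa_image(mask, 9, seq(2.2, 6.5, length.out = 9),
                             seed = 13)
  kept <- segment_fas(strad$marker)
  expect_equal(max(kept), sum(strad$truth$area_um2 >= 4.14))
})

test_that("raising the minimum size never increases the count", {
  mask <- make_cell_mask(c(300, 300), c(120, 95), 0.1)
  img <- generate_fa_image(mask, 8, seq(2.5, 8, length.out = 8), seed = 7)
  cuts <- c(0, 2, 4.14, 6, 9)
  counts <- vapply(cuts, function(ct)
    max(segment_fas(img$marker, min_fa_area_um2 = ct)), integer(1))
  expect_true(all(diff(counts) <= 0L))
})

test_that("FA statistics follow the count / cell-area definition", {
  mask <- make_cell_mask(c(300, 300), c(120, 95), 0.1)
  img <- generate_fa_image(mask, 10, function(n) runif(n, 5, 9), seed = 4)
  st <- fa_statistics(segment_fas(img$marker), img$actin)
  expect_equal(st$fa_count, 10L)
  expect_equal(st$density_per_um2, st$fa_count / st$cell_area_um2)
  expect_lt(abs(st$cell_area_um2 - sum(unclass(mask)) * 0.01) /
              (sum(unclass(mask)) * 0.01), 0.02)
  expect_lt(abs(mean(st$fa_areas_um2) - mean(img$truth$area_um2)) /
              mean(img$truth$area_um2), 0.10)

  none <- fa_statistics(labeled_mask(matrix(0L, 300, 300), 0.1), img$actin)
  expect_equal(none$fa_count, 0L)
  expect_equal(none$density_per_um2, 0)
})

test_that("adhesions outside the cell footprint are not counted", {
  ps <- 0.1
  marker <- matrix(0.05, 240, 240)
  g <- expand.grid(r = 1:240, c = 1:240)
  inblob <- matrix((g$r - 120)^2 + (g$c - 120)^2 <= 12^2, 240, 240)
  outblob <- matrix((g$r - 30)^2 + (g$c - 220)^2 <= 12^2, 240, 240)
  marker[inblob | outblob] <- 0.9
  actin <- matrix(0.05, 240, 240)
  actin[matrix((g$r - 120)^2 + (g$c - 120)^2 <= 80^2, 240, 240)] <- 0.8
  st <- fa_statistics(segment_fas(intensity_image(marker, ps)),
                      intensity_image(actin, ps))
  expect_equal(st$fa_count, 1L)
})

test_that("density is invariant to 2x upsampling within 5%", {
  mask <- make_cell_mask(c(220, 220), c(90, 70), 0.2)
  img <- generate_fa_image(mask, 8, function(n) runif(n, 6, 10), seed = 6)
  st1 <- fa_statistics(segment_fas(img$marker), img$actin)
  up <- function(im) intensity_image(
    unclass(im)[rep(seq_len(nrow(im)), each = 2),
                rep(seq_len(ncol(im)), each = 2)], pixel_size(im) / 2)
  st2 <- fa_statistics(segment_fas(up(img$marker)), up(img$actin))
  expect_lt(abs(st2$density_per_um2 - st1$density_per_um2) /
              st1$density_per_um2, 0.05)
})
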