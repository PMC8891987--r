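test_that("segmentation handles empty, constant and disk images", {
  ps <- 0.5
  blank <- intensity_image(matrix(0.1, 64, 64) +
                             matrix(runif(64 * 64, 0, 1e-3), 64), ps)
  lab <- segment_particles(blank, threshold_method = 0.5)
  expect_equal(max(lab), 0L)

  expect_error(segment_particles(intensity_image(matrix(0.3, 16, 16), ps)),
               "zero intensity range")

  out <- generate_particle_image(list(shape_disk(c(40, 40), 20)),
                                 c(96, 96), ps, seed = 1)
  lab <- segment_particles(out$image)
  expect_equal(max(lab), 1L)
  expect_lt(abs(sum(lab == 1L) - pi * 400) / (pi * 400), 0.02)
})

test_that("fill-holes recovers the full disk area of an annulus", {
  ring <- matrix(0.1, 80, 80)
  g <- expand.grid(r = 1:80, c = 1:80)
  d2 <- (g$r - 40.5)^2 + (g$c - 40.5)^2
  ring[d2 <= 25^2 & d2 >= 12^2] <- 0.9
  img <- intensity_image(ring, 0.5)
  filled <- segment_particles(img, fill_holes = TRUE)
  open <- segment_particles(img, fill_holes = FALSE)
  expect_equal(sum(filled == 1L), sum(d2 <= 25^2))
  expect_equal(sum(open == 1L), sum(d2 <= 25^2 & d2 >= 12^2))
})

test_that("border-touching particles are excluded on request", {
  img <- matrix(0.1, 60, 60)
  img[1:12, 20:32] <- 0.9          # touches top border
  img[30:42, 20:32] <- 0.9         # interior
  img <- intensity_image(img, 0.5)
  expect_equal(max(segment_particles(img, exclude_border = TRUE)), 1L)
  expect_equal(max(segment_particles(img, exclude_border = FALSE)), 2L)
})

test_that("labeling is 8-connected", {
  img <- matrix(0.1, 20, 20)
  img[cbind(5:10, 5:10)] <- 0.9    # a purely diagonal chain
  lab <- segment_particles(intensity_image(img, 1), fill_holes = FALSE,
                           exclude_border = FALSE)
  expect_equal(max(lab), 1L)
})

test_that("Crofton perimeter matches the independent multi-direction oracle", {
  # frozen values from an independent Crofton implementation
  g <- expand.grid(r = 1:64, c = 1:64)
  disk <- matrix((g$r - 0.5 - 31.7)^2 + (g$c - 0.5 - 30.2)^2 <= 20.3^2,
                 64, 64)
  expect_equal(crofton_perimeter(disk), 127.4837, tolerance = 1e-6)
  s <- paste0("0000000000000000000000000000000000000100000000000000010000000000",
              "0001111111111000000111111111100000011111111110000001111111111000",
              "0001111111111000000111111111100000011111111110000001111111111000",
              "0000000000110000000000000001000000000000000000000000000000000000")
  m <- matrix(strsplit(s, "")[[1]] == "1", 16, 16, byrow = TRUE)
  expect_equal(crofton_perimeter(m), 37.82709, tolerance = 1e-6)
  # and it is close to the analytic circumference of a digital circle
  expect_lt(abs(crofton_perimeter(disk) - 2 * pi * 20.3) / (2 * pi * 20.3),
            0.01)
})

test_that("descriptors recover the analytic geometry of canonical shapes", {
  disk <- render_measure(shape_disk(c(60, 60), 25))$rec
  expect_gte(disk$circularity, 0.95)
  expect_lt(abs(disk$inv_aspect_ratio - 1), 0.02)
  expect_lt(abs(disk$solidity - 1), 0.02)

  ell <- render_measure(shape_ellipse(c(64, 64), c(40, 20), 0.7))$rec
  expect_lt(abs(ell$inv_aspect_ratio - 0.5), 0.03)

  v <- star_vertices(c(64, 64), 5, 45, 18, phase = 0.3)
  star <- render_measure(shape_polygon(v))$rec
  hull <- v[grDevices::chull(v), ]
  expect_lt(abs(star$solidity - shoelace(v) / shoelace(hull)), 0.05)
  hull_rec <- render_measure(shape_polygon(hull))$rec
  expect_lt(abs(hull_rec$solidity - 1), 0.02)
})

test_that("descriptors are scale-equivariant and rotation-robust", {
  out <- generate_particle_image(list(shape_ellipse(c(64, 64), c(36, 18))),
                                 c(128, 128), 0.5, seed = 1)
  lab <- segment_particles(out$image)
  r1 <- shape_descriptors(lab)
  lab2 <- labeled_mask(matrix(as.integer(lab), nrow(lab)), pixel_size = 1.0)
  r2 <- shape_descriptors(lab2)
  expect_equal(r2$area_um2, 4 * r1$area_um2)
  expect_equal(r2$circularity, r1$circularity)
  expect_equal(r2$inv_aspect_ratio, r1$inv_aspect_ratio)
  expect_equal(r2$solidity, r1$solidity)

  angles <- seq(0, pi, length.out = 9)[1:8]
  recs <- do.call(rbind, lapply(angles, function(a)
    render_measure(shape_ellipse(c(64, 64), c(36, 18), a))$rec))
  expect_lt(diff(range(recs$inv_aspect_ratio)), 0.05)
  expect_lt(diff(range(recs$circularity)), 0.05)
  expect_lt(diff(range(recs$solidity)), 0.05)
})

test_that("the particle filter applies the area and circularity bounds", {
  rec <- data.frame(label = 1:3, area_px2 = c(100, 500, 2000),
                    circularity = 0.9)
  kept <- filter_particles(rec)
  expect_equal(kept$area_px2, 500)

  rec2 <- data.frame(label = 1L, area_px2 = 500, circularity = 0.5)
  expect_equal(nrow(filter_particles(rec2)), 0L)

  empty <- rec[0, ]
  expect_equal(nrow(filter_particles(empty)), 0L)

  expect_error(filter_particles(rec, area_range_px2 = c(10, 5)))
})
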