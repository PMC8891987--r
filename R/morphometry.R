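#' Segment bright particles from a grayscale image
#'
#' ImageJ-style particle segmentation: global auto-threshold, optional
#' hole filling, 8-connected component labeling, optional removal of
#' components touching the image border. Bright-on-dark foreground is
#' assumed (phase-contrast images of suspended cells/beads after
#' brightness/contrast maximization behave this way once thresholded).
#'
#' @param image an [intensity_image()].
#' @param threshold_method `"otsu"` (default), `"isodata"` (ImageJ's
#'   default intermeans variant), or a single numeric threshold in
#'   intensity units.
#' @param fill_holes fill enclosed background holes inside particles
#'   (ImageJ "Fill Holes").
#' @param exclude_border drop particles touching the image edge; partial
#'   particles bias area downward.
#' @return a [labeled_mask()] with labels 1..K in raster order.
#' @export
segment_particles <- function(image, threshold_method = "otsu",
                              fill_holes = TRUE, exclude_border = TRUE) {
  stopifnot(inherits(image, "intensity_image"))
  v <- unclass(image)
  if (diff(range(v)) <= 0)
    stop("image has zero intensity range; no threshold exists")
  th <- .auto_threshold(v, threshold_method)
  bin <- v > th
  if (fill_holes)
    bin <- EBImage::fillHull(bin) > 0
  lab <- .label8(bin)
  if (exclude_border && max(lab) > 0L) {
    edge <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    edge <- edge[edge > 0L]
    if (length(edge)) lab[lab %in% edge] <- 0L
  }
  labeled_mask(.relabel(lab), pixel_size(image))
}

.auto_threshold <- function(v, method) {
  if (is.numeric(method)) return(method)
  method <- match.arg(method, c("otsu", "isodata"))
  if (method == "otsu") {
    rng <- range(v)
    as.numeric(EBImage::otsu(EBImage::Image(v), range = rng, levels = 256L))
  } else {
    # iterative intermeans (IsoData): t = mean of class means, to convergence
    t0 <- mean(range(v))
    repeat {
      lo <- v[v <= t0]; hi <- v[v > t0]
      if (!length(lo) || !length(hi)) break
      t1 <- (mean(lo) + mean(hi)) / 2
      if (abs(t1 - t0) < 1e-8 * diff(range(v))) { t0 <- t1; break }
      t0 <- t1
    }
    t0
  }
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so merge labels
# that touch diagonally with a union-find over the label adjacency graph.
.label8 <- function(bin) {
  lab <- EBImage::bwlabel(bin)
  lab <- matrix(as.integer(round(lab)), nrow(bin), ncol(bin))
  k <- max(lab)
  if (k <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]      # down-right diagonal pairs
  a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]     # down-left diagonal pairs
  sel1 <- a1 > 0L & b1 > 0L & a1 != b1
  sel2 <- a2 > 0L & b2 > 0L & a2 != b2
  pairs <- unique(rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2])))
  if (nrow(pairs)) {
    parent <- seq_len(k)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (p in seq_len(nrow(pairs))) {
      ra <- find(pairs[p, 1]); rb <- find(pairs[p, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
    root <- vapply(seq_len(k), find, integer(1))
    lab[lab > 0L] <- root[lab[lab > 0L]]
  }
  lab
}

# relabel to contiguous 1..K in raster (first-appearance) order
.relabel <- function(lab) {
  u <- unique(lab[lab > 0L])
  if (!length(u)) return(lab)
  map <- integer(max(u)); map[u] <- seq_along(u)
  lab[lab > 0L] <- map[lab[lab > 0L]]
  lab
}

#' Crofton perimeter of a binary region
#'
#' Multi-direction (0, 45, 90, 135 degrees) chord-counting estimate from
#' the Cauchy-Crofton formula, P = (pi/4) \[C0 + C90 + (C45 + C135)/sqrt(2)\],
#' where C is the number of boundary chords met by scan lines in each
#' direction. Unbiased for smooth convex shapes; naive boundary-pixel
#' counting would overestimate the perimeter of a digital circle by ~27%
#' and push its circularity down to ~0.8.
#'
#' @param bin logical matrix (one region or several; chords are additive).
#' @return perimeter in pixel units.
#' @export
crofton_perimeter <- function(bin) {
  m <- bin > 0
  m <- rbind(FALSE, cbind(FALSE, m, FALSE), FALSE)
  nr <- nrow(m); nc <- ncol(m)
  c0 <- sum(m[, -1] & !m[, -nc])       # chord starts scanning along rows
  c90 <- sum(m[-1, ] & !m[-nr, ])
  c45 <- sum(m[-1, -1] & !m[-nr, -nc])
  c135 <- sum(m[-1, -nc] & !m[-nr, -1])
  (pi / 4) * (c0 + c90 + (c45 + c135) / sqrt(2))
}

#' Shape descriptors of labeled particles
#'
#' Per particle: area (pixel count, and um^2 via the calibration),
#' Crofton perimeter, circularity 4*pi*A/P^2 (clipped at 1: digitization
#' can push it slightly above), inverse aspect ratio = minor/major axis of
#' the moment-equivalent ellipse (ImageJ "Fit Ellipse" convention, from
#' second-order central moments with the 1/12 unit-pixel term), solidity =
#' area / convex-hull area (hull of the pixel centers; digitization can
#' push the ratio marginally above 1, so it is clipped there), and
#' equivalent diameter sqrt(4A/pi).
#'
#' @param mask a [labeled_mask()] with at least one label.
#' @return data.frame with one row per label: label, area_px2, area_um2,
#'   perimeter_um, circularity, inv_aspect_ratio, solidity,
#'   equiv_diameter_um, centroid_x_px, centroid_y_px.
#' @export
shape_descriptors <- function(mask) {
  stopifnot(inherits(mask, "labeled_mask"))
  ps <- pixel_size(mask)
  k <- max(mask)
  if (k < 1L) stop("mask contains no particles")
  out <- vector("list", k)
  for (lb in seq_len(k)) {
    px <- which(unclass(mask) == lb, arr.ind = TRUE)
    n <- nrow(px)
    # crop to bounding box for the perimeter scan
    rr <- range(px[, 1]); cc <- range(px[, 2])
    sub <- matrix(FALSE, rr[2] - rr[1] + 1L, cc[2] - cc[1] + 1L)
    sub[cbind(px[, 1] - rr[1] + 1L, px[, 2] - cc[1] + 1L)] <- TRUE
    P <- crofton_perimeter(sub)
    x <- px[, 2] - 0.5; y <- px[, 1] - 0.5
    xc <- mean(x); yc <- mean(y)
    mu20 <- mean((x - xc)^2) + 1 / 12
    mu02 <- mean((y - yc)^2) + 1 / 12
    mu11 <- mean((x - xc) * (y - yc))
    iar <- .moment_iar(mu20, mu02, mu11)
    hull_area <- .convex_hull_area(cbind(x, y))
    A <- n
    out[[lb]] <- data.frame(
      label = lb,
      area_px2 = A,
      area_um2 = A * ps^2,
      perimeter_um = P * ps,
      circularity = min(4 * pi * A / P^2, 1),
      inv_aspect_ratio = iar,
      solidity = min(A / hull_area, 1),
      equiv_diameter_um = sqrt(4 * A * ps^2 / pi),
      centroid_x_px = xc,
      centroid_y_px = yc)
  }
  do.call(rbind, out)
}

#' ImageJ-style particle filter on area and circularity
#'
#' Retains particles whose pixel area and circularity both fall inside the
#' given closed intervals. Defaults reproduce the suspended-cell/bead
#' analysis settings of 300-1,250 px^2 with circularity 0.65-1, which
#' exclude debris and multi-cell aggregates. Input order is preserved.
#'
#' @param records data.frame from [shape_descriptors()].
#' @param area_range_px2 closed interval for area_px2.
#' @param circularity_range closed interval for circularity.
#' @return the retained subset of `records` (possibly empty).
#' @export
filter_particles <- function(records, area_range_px2 = c(300, 1250),
                             circularity_range = c(0.65, 1)) {
  stopifnot(length(area_range_px2) == 2L, length(circularity_range) == 2L,
            area_range_px2[1] <= area_range_px2[2],
            circularity_range[1] <= circularity_range[2])
  if (!nrow(records)) return(records)
  keep <- records$area_px2 >= area_range_px2[1] &
    records$area_px2 <= area_range_px2[2] &
    records$circularity >= circularity_range[1] &
    records$circularity <= circularity_range[2]
  records[keep, , drop = FALSE]
}

#' Write a shape-descriptor table to CSV
#'
#' @param records data.frame from [shape_descriptors()].
#' @param path CSV path.
#' @export
write_shape_records_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}
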