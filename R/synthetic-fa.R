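#' Simulate a two-channel focal-adhesion image with ground truth
#'
#' Places `n_fas` disk-shaped adhesion spots inside a cell mask without
#' overlap and renders two channels: a marker channel (e.g. PY-paxillin or
#' phospho-FAK) containing only the spots, and an actin channel filling the
#' whole cell mask. Ground-truth spot areas are the rendered pixel counts
#' times the pixel area, so they are exact for the analysis chain.
#'
#' @param cell_mask a [binary_mask()] defining the cell footprint.
#' @param n_fas number of adhesion spots (>= 0).
#' @param fa_areas_um2 either a numeric vector of length `n_fas` with the
#'   target spot areas (um^2), or a function `f(n)` drawing `n` areas.
#' @param seed integer seed (placement and, if a function, area draws).
#' @param min_area_um2 reference cutoff recorded in the truth table
#'   (`below_min` flags spots whose rendered area falls below it);
#'   defaults to the conventional 4.14 um^2 minimum adhesion size.
#' @param max_tries placement attempts per spot before giving up.
#' @return list with `marker` and `actin` ([intensity_image()]s) and
#'   `truth` data.frame (id, center_x_px, center_y_px, area_px2, area_um2,
#'   below_min).
#' @export
generate_fa_image <- function(cell_mask, n_fas, fa_areas_um2,
                              seed = 1L, min_area_um2 = 4.14,
                              max_tries = 200L) {
  stopifnot(inherits(cell_mask, "binary_mask"), n_fas >= 0L)
  ps <- pixel_size(cell_mask)
  nr <- nrow(cell_mask); nc <- ncol(cell_mask)
  if (n_fas == 0L) {
    marker <- intensity_image(matrix(0.05, nr, nc), ps)
    actin <- intensity_image(matrix(ifelse(unclass(cell_mask), 0.8, 0.05),
                                    nr, nc), ps)
    truth <- data.frame(id = integer(0), center_x_px = numeric(0),
                        center_y_px = numeric(0), area_px2 = numeric(0),
                        area_um2 = numeric(0), below_min = logical(0))
    return(list(marker = marker, actin = actin, truth = truth))
  }
  areas <- if (is.function(fa_areas_um2))
    with_seed(seed, fa_areas_um2(n_fas)) else as.numeric(fa_areas_um2)
  if (length(areas) != n_fas || any(areas <= 0))
    stop("need ", n_fas, " positive spot areas")
  radii <- sqrt(areas / pi) / ps                       # px
  inside <- which(unclass(cell_mask), arr.ind = TRUE)
  placed <- with_seed(seed + 1L, {
    ord <- order(radii, decreasing = TRUE)   # big spots first: easier packing
    cx <- numeric(0); cy <- numeric(0); cr <- numeric(0)
    for (i in ord) {
      r <- radii[i]
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        p <- inside[sample.int(nrow(inside), 1L), ]
        x <- p[2] - 0.5; y <- p[1] - 0.5
        rr <- ceiling(r)
        if (p[1] - rr < 1 || p[1] + rr > nr || p[2] - rr < 1 || p[2] + rr > nc)
          next
        sub <- cell_mask[(p[1] - rr):(p[1] + rr), (p[2] - rr):(p[2] + rr)]
        if (!all(sub)) next                  # spot must lie fully in the cell
        if (length(cx) && any(sqrt((cx - x)^2 + (cy - y)^2) < r + cr + 2))
          next                               # 2 px clearance between spots
        cx <- c(cx, x); cy <- c(cy, y); cr <- c(cr, r); ok <- TRUE; break
      }
      if (!ok) stop("cell mask too small to place ", n_fas,
                    " non-overlapping adhesions")
    }
    data.frame(id = ord, cx = cx, cy = cy, r = cr)
  })
  placed <- placed[order(placed$id), ]
  marker <- matrix(0.05, nr, nc)
  truth <- data.frame(id = seq_len(n_fas), center_x_px = placed$cx,
                      center_y_px = placed$cy, area_px2 = NA_real_,
                      area_um2 = NA_real_, below_min = NA)
  for (i in seq_len(n_fas)) {
    m <- .rasterize_shape(shape_disk(c(placed$cx[i], placed$cy[i]),
                                     placed$r[i]), c(nr, nc))
    marker[m] <- 0.9
    truth$area_px2[i] <- sum(m)
    truth$area_um2[i] <- sum(m) * ps^2
  }
  truth$below_min <- truth$area_um2 < min_area_um2
  actin <- matrix(0.05, nr, nc)
  actin[unclass(cell_mask)] <- 0.8
  list(marker = intensity_image(marker, ps),
       actin = intensity_image(actin, ps),
       truth = truth)
}

#' Elliptical synthetic cell mask
#'
#' Convenience footprint for focal-adhesion simulations.
#'
#' @param image_shape (rows, cols) px.
#' @param center (x, y) px; defaults to the image center.
#' @param semi_axes (major, minor) semi-axes, px.
#' @param pixel_size um/px.
#' @return a [binary_mask()].
#' @export
make_cell_mask <- function(image_shape, semi_axes, pixel_size,
                           center = rev(image_shape) / 2) {
  m <- .rasterize_shape(shape_ellipse(center, semi_axes), image_shape)
  binary_mask(m, pixel_size)
}
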