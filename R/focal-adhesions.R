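#' Background subtraction by morphological opening
#'
#' Estimates the smooth background as the grayscale opening of the image
#' by a disc structuring element of the given radius and subtracts it
#' (white top-hat). Features smaller than the disc survive; slowly varying
#' background (uneven illumination, cytoplasmic haze) is removed. A 50 px
#' radius is the conventional setting for focal-adhesion channels.
#'
#' @param image an [intensity_image()].
#' @param radius_px structuring-element radius in pixels (>= 1); must not
#'   exceed both image dimensions.
#' @return background-subtracted [intensity_image()], non-negative.
#' @export
subtract_background <- function(image, radius_px = 50L) {
  stopifnot(inherits(image, "intensity_image"), radius_px >= 1)
  nr <- nrow(image); nc <- ncol(image)
  if (radius_px > nr && radius_px > nc)
    stop("background radius exceeds both image dimensions")
  size <- 2L * as.integer(radius_px) + 1L
  brush <- EBImage::makeBrush(size, shape = "disc")
  v <- unclass(image); attributes(v) <- list(dim = dim(v))
  out <- EBImage::whiteTopHat(v, brush)
  out <- pmax(as.matrix(EBImage::imageData(out)), 0)
  intensity_image(out, pixel_size(image))
}

#' Segment focal adhesions from a background-subtracted marker channel
#'
#' Auto-threshold (Otsu by default, or IsoData, or a fixed numeric value),
#' 8-connected labeling, then removal of components smaller than the
#' minimum adhesion size — by default 4.14 um^2, the conventional floor
#' that keeps diffraction-limited background staining out of the count.
#'
#' @param marker background-subtracted marker-channel [intensity_image()]
#'   (PY-paxillin or phospho-FAK).
#' @param min_fa_area_um2 minimum adhesion area retained, um^2.
#' @param threshold_method as in [segment_particles()].
#' @return a [labeled_mask()] of adhesions, labels contiguous 1..K.
#' @export
segment_fas <- function(marker, min_fa_area_um2 = 4.14,
                        threshold_method = "otsu") {
  stopifnot(inherits(marker, "intensity_image"), min_fa_area_um2 >= 0)
  ps <- pixel_size(marker)
  v <- unclass(marker)
  if (diff(range(v)) <= 0)
    stop("marker channel has zero intensity range; no threshold exists")
  th <- .auto_threshold(v, threshold_method)
  lab <- .label8(v > th)
  if (max(lab) > 0L) {
    areas <- tabulate(lab[lab > 0L]) * ps^2
    drop <- which(areas < min_fa_area_um2)
    if (length(drop)) lab[lab %in% drop] <- 0L
  }
  labeled_mask(.relabel(lab), ps)
}

#' Per-cell focal-adhesion statistics
#'
#' Cell area comes from the actin channel: auto-threshold, keep the
#' largest 8-connected component, fill holes. An adhesion is assigned to
#' the cell iff its centroid lies inside that mask (density is a per-cell
#' quantity, so adhesions outside the footprint are not counted).
#' Density = count / cell area.
#'
#' @param fa_mask adhesion [labeled_mask()] from [segment_fas()].
#' @param actin actin-channel [intensity_image()], same geometry.
#' @param threshold_method actin threshold method.
#' @return list of class `fa_stats`: fa_count, fa_areas_um2 (of counted
#'   adhesions), mean_fa_area_um2, cell_area_um2, density_per_um2.
#' @export
fa_statistics <- function(fa_mask, actin, threshold_method = "otsu") {
  stopifnot(inherits(fa_mask, "labeled_mask"),
            inherits(actin, "intensity_image"),
            all(dim(fa_mask) == dim(actin)))
  ps <- pixel_size(fa_mask)
  v <- unclass(actin)
  if (diff(range(v)) <= 0) stop("actin channel has zero intensity range")
  th <- .auto_threshold(v, threshold_method)
  lab <- .label8(v > th)
  if (max(lab) < 1L) stop("no cell region found in actin channel")
  counts <- tabulate(lab[lab > 0L])
  cell <- lab == which.max(counts)
  cell <- EBImage::fillHull(cell) > 0
  cell_area <- sum(cell) * ps^2
  if (cell_area <= 0) stop("zero cell area")
  k <- max(fa_mask)
  keep_areas <- numeric(0)
  if (k > 0L) {
    m <- unclass(fa_mask)
    for (lb in seq_len(k)) {
      px <- which(m == lb, arr.ind = TRUE)
      cen <- round(colMeans(px))            # centroid in (row, col)
      if (cell[cen[1], cen[2]])
        keep_areas <- c(keep_areas, nrow(px) * ps^2)
    }
  }
  structure(list(fa_count = length(keep_areas),
                 fa_areas_um2 = keep_areas,
                 mean_fa_area_um2 = if (length(keep_areas))
                   mean(keep_areas) else NA_real_,
                 cell_area_um2 = cell_area,
                 density_per_um2 = length(keep_areas) / cell_area),
            class = "fa_stats")
}

#' @export
print.fa_stats <- function(x, ...) {
  cat(sprintf(
    "FA stats: %d adhesions, cell area %.1f um^2, density %.4g /um^2\n",
    x$fa_count, x$cell_area_um2, x$density_per_um2))
  invisible(x)
}
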