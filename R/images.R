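#' Calibrated image containers
#'
#' Images travel through the pipeline as plain numeric/logical/integer
#' matrices carrying a `pixel_size` attribute (micrometres per pixel).
#' Three thin S3 classes mark the segmentation stages: `intensity_image`
#' (grayscale data), `binary_mask` (logical foreground) and `labeled_mask`
#' (integer labels, 0 = background, k = particle k, labels contiguous 1..K).
#'
#' @param data a matrix (numeric for intensities, logical for masks,
#'   integer for labels) with at least 2 rows and 2 columns.
#' @param pixel_size pixel size in micrometres per pixel; must be > 0.
#' @return the matrix with `pixel_size` attribute and stage class attached.
#' @examples
#' img <- intensity_image(matrix(runif(100), 10, 10), pixel_size = 0.5)
#' pixel_size(img)
#' @export
intensity_image <- function(data, pixel_size) {
  stopifnot(is.matrix(data), is.numeric(data))
  .check_calibration(data, pixel_size)
  structure(data, pixel_size = pixel_size,
            class = c("intensity_image", "matrix", "array"))
}

#' @rdname intensity_image
#' @export
binary_mask <- function(data, pixel_size) {
  stopifnot(is.matrix(data), is.logical(data))
  .check_calibration(data, pixel_size)
  structure(data, pixel_size = pixel_size,
            class = c("binary_mask", "matrix", "array"))
}

#' @rdname intensity_image
#' @export
labeled_mask <- function(data, pixel_size) {
  stopifnot(is.matrix(data))
  storage.mode(data) <- "integer"
  .check_calibration(data, pixel_size)
  k <- max(data)
  if (k > 0L && !identical(sort(unique(data[data > 0L])), seq_len(k)))
    stop("labels must be contiguous 1..K")
  structure(data, pixel_size = pixel_size,
            class = c("labeled_mask", "matrix", "array"))
}

#' @rdname intensity_image
#' @param x an image object.
#' @export
pixel_size <- function(x) {
  ps <- attr(x, "pixel_size")
  if (is.null(ps)) stop("object carries no pixel_size calibration")
  ps
}

.check_calibration <- function(data, pixel_size) {
  if (nrow(data) < 2L || ncol(data) < 2L)
    stop("image must be at least 2x2 pixels")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L ||
      !is.finite(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be a single positive number (um/px)")
  invisible(TRUE)
}

#' Read and write calibrated single-channel TIFF images
#'
#' Images are stored as 16-bit single-channel TIFF; the pixel size (um/px)
#' is recorded in a JSON sidecar (`<file>.json`) because baseline TIFF has
#' no reliable calibration tag. Intensities are clipped to \[0, 1\] on write
#' and scaled to the 16-bit range by the TIFF writer.
#'
#' @param image an [intensity_image()].
#' @param path output path (`.tif`).
#' @return `write_calibrated_tiff` returns `path` invisibly;
#'   `read_calibrated_tiff` returns an [intensity_image()].
#' @export
write_calibrated_tiff <- function(image, path) {
  ps <- pixel_size(image)
  m <- pmin(pmax(unclass(image), 0), 1)
  attributes(m) <- list(dim = dim(m))
  tiff::writeTIFF(m, path, bits.per.sample = 16L)
  jsonlite::write_json(list(pixel_size_um = ps), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibrated_tiff
#' @export
read_calibrated_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  meta <- jsonlite::read_json(paste0(path, ".json"))
  intensity_image(m, pixel_size = meta$pixel_size_um)
}
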