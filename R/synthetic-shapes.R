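#' Analytic shape specifications for synthetic particle images
#'
#' A shape spec describes one particle (bead or cell silhouette) by its
#' analytic geometry, in pixel units. The rasterizer marks a pixel as
#' foreground iff its *center* lies inside the analytic shape (no
#' anti-aliasing), so ground-truth areas are reproducible as pixel counts
#' up to discretization.
#'
#' Coordinates: x runs along matrix columns, y along rows; the pixel in
#' row r, column c has its center at (c - 0.5, r - 0.5).
#'
#' @param center numeric length-2, (x, y) center in pixels.
#' @param radius disk radius in pixels (> 0).
#' @param semi_axes numeric length-2, (major, minor) semi-axes in pixels.
#' @param orientation rotation of the shape, radians (counter-clockwise).
#' @param n_spikes number of star points (>= 3).
#' @param outer_radius,inner_radius star tip and notch radii in pixels.
#' @param vertices two-column matrix of polygon vertices (x, y) in pixels,
#'   in order, not self-intersecting.
#' @return an object of class `shape_spec`.
#' @seealso [generate_particle_image()]
#' @export
shape_disk <- function(center, radius) {
  stopifnot(length(center) == 2L, radius > 0)
  structure(list(kind = "disk", center = as.numeric(center),
                 radius = as.numeric(radius)), class = "shape_spec")
}

#' @rdname shape_disk
#' @export
shape_ellipse <- function(center, semi_axes, orientation = 0) {
  stopifnot(length(center) == 2L, length(semi_axes) == 2L, all(semi_axes > 0))
  a <- max(semi_axes); b <- min(semi_axes)
  structure(list(kind = "ellipse", center = as.numeric(center),
                 a = a, b = b, orientation = as.numeric(orientation)),
            class = "shape_spec")
}

#' @rdname shape_disk
#' @export
shape_star <- function(center, n_spikes, outer_radius, inner_radius,
                       orientation = 0) {
  stopifnot(n_spikes >= 3L, outer_radius > inner_radius, inner_radius > 0)
  k <- 2L * as.integer(n_spikes)
  ang <- orientation + seq(0, 2 * pi, length.out = k + 1L)[-(k + 1L)]
  rad <- rep(c(outer_radius, inner_radius), n_spikes)
  v <- cbind(center[1] + rad * cos(ang), center[2] + rad * sin(ang))
  structure(list(kind = "star", center = as.numeric(center),
                 vertices = v, n_spikes = as.integer(n_spikes),
                 outer_radius = outer_radius, inner_radius = inner_radius),
            class = "shape_spec")
}

#' @rdname shape_disk
#' @export
shape_polygon <- function(vertices) {
  vertices <- as.matrix(vertices)
  stopifnot(ncol(vertices) == 2L, nrow(vertices) >= 3L)
  structure(list(kind = "polygon",
                 center = colMeans(vertices), vertices = vertices),
            class = "shape_spec")
}

# ---- analytic geometry ------------------------------------------------------

.shoelace_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

.polygon_perimeter <- function(v) {
  d <- v - v[c(2:nrow(v), 1L), , drop = FALSE]
  sum(sqrt(rowSums(d^2)))
}

# per-area central second moments of a simple polygon (Green's theorem)
.polygon_moments <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  A <- sum(cr) / 2
  cx <- sum((x + xn) * cr) / (6 * A)
  cy <- sum((y + yn) * cr) / (6 * A)
  iyy <- sum(cr * (x^2 + x * xn + xn^2)) / 12            # integral x^2 dA
  ixx <- sum(cr * (y^2 + y * yn + yn^2)) / 12            # integral y^2 dA
  ixy <- sum(cr * (x * yn + 2 * x * y + 2 * xn * yn + xn * y)) / 24
  s <- sign(A)
  list(area = abs(A),
       mu20 = (s * iyy) / abs(A) - cx^2,
       mu02 = (s * ixx) / abs(A) - cy^2,
       mu11 = (s * ixy) / abs(A) - cx * cy)
}

# minor/major axis ratio from a 2x2 second-moment matrix
.moment_iar <- function(mu20, mu02, mu11) {
  tr <- (mu20 + mu02) / 2
  dd <- sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
  lmax <- tr + dd; lmin <- tr - dd
  if (lmax <= 0) return(1)
  sqrt(max(lmin, 0) / lmax)
}

.convex_hull_area <- function(v) {
  h <- grDevices::chull(v)
  abs(.shoelace_area(v[h, , drop = FALSE]))
}

# Ramanujan's second approximation; relative error < 1e-6 for b/a >= 1/3
.ellipse_perimeter <- function(a, b) {
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

#' Analytic (ground-truth) descriptors of a shape spec
#'
#' Computed from the generating geometry, never from a rendered image:
#' area, perimeter, circularity 4*pi*A/P^2, inverse aspect ratio
#' (minor/major axis of the moment-equivalent ellipse), solidity
#' (area / convex-hull area) and equivalent diameter sqrt(4A/pi).
#'
#' @param spec a [shape_disk()] / [shape_ellipse()] / [shape_star()] /
#'   [shape_polygon()] object.
#' @param pixel_size um/px used to convert to physical units.
#' @return one-row data.frame of descriptors (areas in um^2, lengths in um,
#'   ratios dimensionless).
#' @export
shape_truth <- function(spec, pixel_size) {
  stopifnot(inherits(spec, "shape_spec"), pixel_size > 0)
  if (spec$kind == "disk") {
    A <- pi * spec$radius^2; P <- 2 * pi * spec$radius
    iar <- 1; sol <- 1
  } else if (spec$kind == "ellipse") {
    A <- pi * spec$a * spec$b
    P <- .ellipse_perimeter(spec$a, spec$b)
    iar <- spec$b / spec$a; sol <- 1
  } else {
    v <- spec$vertices
    A <- abs(.shoelace_area(v))
    P <- .polygon_perimeter(v)
    m <- .polygon_moments(v)
    iar <- .moment_iar(m$mu20, m$mu02, m$mu11)
    sol <- min(A / .convex_hull_area(v), 1)
  }
  data.frame(kind = spec$kind,
             center_x_px = spec$center[1], center_y_px = spec$center[2],
             area_px2 = A,
             area_um2 = A * pixel_size^2,
             perimeter_um = P * pixel_size,
             circularity = min(4 * pi * A / P^2, 1),
             inv_aspect_ratio = iar,
             solidity = sol,
             equiv_diameter_um = sqrt(4 * A * pixel_size^2 / pi))
}

# ---- rasterization ----------------------------------------------------------

# logical matrix over the full frame; pixel center inclusion rule
.rasterize_shape <- function(spec, image_shape) {
  nr <- image_shape[1]; nc <- image_shape[2]
  xs <- seq_len(nc) - 0.5
  ys <- seq_len(nr) - 0.5
  X <- matrix(xs, nr, nc, byrow = TRUE)
  Y <- matrix(ys, nr, nc)
  if (spec$kind == "disk") {
    (X - spec$center[1])^2 + (Y - spec$center[2])^2 <= spec$radius^2
  } else if (spec$kind == "ellipse") {
    ct <- cos(spec$orientation); st <- sin(spec$orientation)
    u <- ct * (X - spec$center[1]) + st * (Y - spec$center[2])
    w <- -st * (X - spec$center[1]) + ct * (Y - spec$center[2])
    (u / spec$a)^2 + (w / spec$b)^2 <= 1
  } else {
    m <- matrix(.points_in_polygon(as.vector(X), as.vector(Y), spec$vertices),
                nr, nc)
    m
  }
}

# even-odd ray-crossing test, vectorized over query points
.points_in_polygon <- function(px, py, v) {
  n <- nrow(v)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1]; yi <- v[i, 2]; xj <- v[j, 1]; yj <- v[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

.shape_extent <- function(spec) {
  if (spec$kind == "disk") {
    c(spec$center[1] - spec$radius, spec$center[1] + spec$radius,
      spec$center[2] - spec$radius, spec$center[2] + spec$radius)
  } else if (spec$kind == "ellipse") {
    ct <- cos(spec$orientation); st <- sin(spec$orientation)
    hx <- sqrt((spec$a * ct)^2 + (spec$b * st)^2)
    hy <- sqrt((spec$a * st)^2 + (spec$b * ct)^2)
    c(spec$center[1] - hx, spec$center[1] + hx,
      spec$center[2] - hy, spec$center[2] + hy)
  } else {
    c(range(spec$vertices[, 1]), range(spec$vertices[, 2]))
  }
}

#' Render a synthetic particle image with exact ground truth
#'
#' Draws each shape as bright foreground on a dark background (no
#' anti-aliasing: a pixel is foreground iff its center lies inside the
#' analytic shape), optionally adds Gaussian intensity noise, and returns
#' the image together with a ground-truth table computed from the
#' generating geometry (one row per shape, in input order).
#'
#' @param specs list of [shape_disk()]-family specs; may be empty.
#' @param image_shape integer length-2, (rows, cols) in pixels.
#' @param pixel_size um/px calibration.
#' @param noise_sd standard deviation of additive Gaussian intensity noise
#'   (image intensities live in \[0, 1\]; foreground 0.9, background 0.1).
#' @param seed integer seed; the RNG state is restored on exit.
#' @param fg,bg foreground/background intensity levels.
#' @return list with `image` (an [intensity_image()]) and `truth`
#'   (data.frame with columns id, kind, centers, area_px2, area_um2,
#'   perimeter_um, circularity, inv_aspect_ratio, solidity,
#'   equiv_diameter_um).
#' @examples
#' out <- generate_particle_image(list(shape_disk(c(32, 32), 20)),
#'                                image_shape = c(64, 64),
#'                                pixel_size = 0.5, seed = 1)
#' out$truth$equiv_diameter_um  # 20 um
#' @export
generate_particle_image <- function(specs, image_shape, pixel_size,
                                    noise_sd = 0, seed = 1L,
                                    fg = 0.9, bg = 0.1) {
  stopifnot(length(image_shape) == 2L, all(image_shape >= 2L),
            pixel_size > 0, noise_sd >= 0, bg < fg)
  nr <- as.integer(image_shape[1]); nc <- as.integer(image_shape[2])
  fgmask <- matrix(FALSE, nr, nc)
  truth <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    spec <- specs[[i]]
    stopifnot(inherits(spec, "shape_spec"))
    ext <- .shape_extent(spec)
    if (ext[1] < 0 || ext[2] > nc || ext[3] < 0 || ext[4] > nr)
      stop("shape ", i, " extends outside the image frame")
    m <- .rasterize_shape(spec, c(nr, nc))
    if (any(m & fgmask))
      stop("shape ", i, " overlaps a previously placed shape")
    fgmask <- fgmask | m
    truth[[i]] <- cbind(id = i, shape_truth(spec, pixel_size))
  }
  img <- matrix(bg, nr, nc)
  img[fgmask] <- fg
  if (noise_sd > 0) {
    img <- with_seed(seed, img + matrix(stats::rnorm(nr * nc, 0, noise_sd),
                                        nr, nc))
    img <- pmin(pmax(img, 0), 1)
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    cbind(id = integer(0), shape_truth(shape_disk(c(1, 1), 1), 1)[0, ])
  list(image = intensity_image(img, pixel_size), truth = truth)
}

#' Synthetic field of calibration beads
#'
#' Emulates a suspended-microsphere calibration image: `n` non-overlapping
#' disks whose diameters are drawn from a normal distribution truncated at
#' zero (physical positivity), placed on a jittered grid so overlap is
#' impossible by construction. The default diameter distribution,
#' 9.94 +/- 1.01 um, matches a manufacturer-certified 10-um bead batch.
#'
#' @param n number of beads.
#' @param diameter_mean_um,diameter_sd_um generating normal distribution of
#'   bead diameters, um.
#' @param pixel_size um/px.
#' @param noise_sd Gaussian intensity noise sd.
#' @param seed integer seed (diameters, placement jitter and noise).
#' @return as [generate_particle_image()]; the truth table additionally has
#'   a `diameter_um` column with the drawn (true) diameters.
#' @export
generate_bead_image <- function(n, diameter_mean_um = 9.94,
                                diameter_sd_um = 1.01, pixel_size = 0.3,
                                noise_sd = 0, seed = 1L) {
  stopifnot(n >= 1L, diameter_mean_um > 0, diameter_sd_um >= 0)
  placed <- with_seed(seed, {
    d <- stats::rnorm(n, diameter_mean_um, diameter_sd_um)
    while (any(d <= 0))                       # truncate at 0
      d[d <= 0] <- stats::rnorm(sum(d <= 0), diameter_mean_um, diameter_sd_um)
    r_px <- d / 2 / pixel_size
    cell <- ceiling(2 * max(r_px)) + 8L       # grid pitch: no overlap possible
    ncg <- ceiling(sqrt(n))
    nrg <- ceiling(n / ncg)
    idx <- seq_len(n) - 1L
    gx <- (idx %% ncg) * cell + cell / 2
    gy <- (idx %/% ncg) * cell + cell / 2
    jit <- (cell / 2 - r_px - 2)              # keep inside own grid cell
    cx <- gx + stats::runif(n, -1, 1) * jit
    cy <- gy + stats::runif(n, -1, 1) * jit
    list(d = d, r_px = r_px, cx = cx, cy = cy,
         shape = c(nrg * cell, ncg * cell))
  })
  specs <- lapply(seq_len(n), function(i)
    shape_disk(c(placed$cx[i], placed$cy[i]), placed$r_px[i]))
  out <- generate_particle_image(specs, image_shape = placed$shape,
                                 pixel_size = pixel_size,
                                 noise_sd = noise_sd, seed = seed + 1L)
  out$truth$diameter_um <- placed$d
  out
}

#' Evaluate code with a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the previous RNG state so
#' generators are deterministic without clobbering the caller's stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
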