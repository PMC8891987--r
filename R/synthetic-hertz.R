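#' Simulate a Hertzian AFM force-indentation curve
#'
#' Force is zero before the contact point and follows the spherical-tip
#' Hertz law F = (4/3) (E / (1 - nu^2)) sqrt(r) delta^(3/2) beyond it,
#' with delta = z - contact_point, plus additive Gaussian force noise.
#' All quantities are in SI units (m, N, Pa).
#'
#' @param E Young's modulus, Pa (> 0).
#' @param nu Poisson's ratio (0 <= nu < 0.5); 0.45 is the standard
#'   assumption for live cells.
#' @param r tip radius of curvature, m (> 0); ~30 nm for sharp
#'   silicon-nitride tips.
#' @param contact_point z position of tip-sample contact, m.
#' @param z_grid monotonic increasing vector of z positions, m (z increases
#'   into the sample, so indentation is z - contact_point).
#' @param noise_sd Gaussian force noise sd, N (10 pN = 1e-11 N is typical).
#' @param seed integer seed; RNG state restored on exit.
#' @return data.frame with columns z_m, force_N; attributes record the
#'   generating parameters.
#' @examples
#' z <- seq(-1e-6, 1e-6, length.out = 200)
#' fc <- generate_hertz_curve(E = 1000, nu = 0.45, r = 30e-9,
#'                            contact_point = 0, z_grid = z,
#'                            noise_sd = 0, seed = 1)
#' @export
generate_hertz_curve <- function(E, nu, r, contact_point, z_grid,
                                 noise_sd = 0, seed = 1L) {
  stopifnot(E > 0, nu >= 0, nu < 0.5, r > 0, noise_sd >= 0)
  if (length(z_grid) < 2L || any(diff(z_grid) <= 0))
    stop("z_grid must be strictly increasing")
  delta <- pmax(z_grid - contact_point, 0)
  f <- hertz_force(E, nu, r, delta)
  if (noise_sd > 0)
    f <- f + with_seed(seed, stats::rnorm(length(f), 0, noise_sd))
  structure(data.frame(z_m = z_grid, force_N = f),
            E_true = E, nu = nu, r = r, contact_point = contact_point,
            noise_sd = noise_sd)
}

#' Simulate a force map: a grid of Hertz curves over one cell
#'
#' Mimics a 100-curve force map acquired on a single cell; each curve gets
#' an independent noise realization (seed fans out by curve index).
#'
#' @inheritParams generate_hertz_curve
#' @param n_curves number of curves in the map (default 100).
#' @param cell_id identifier carried through aggregation.
#' @return object of class `force_map`: list with `curves` (list of force
#'   curves) and `cell_id`.
#' @export
generate_force_map <- function(n_curves = 100L, E, nu = 0.45, r = 30e-9,
                               contact_point = 0, z_grid, noise_sd = 0,
                               seed = 1L, cell_id = "cell1") {
  stopifnot(n_curves >= 1L)
  curves <- lapply(seq_len(n_curves), function(i)
    generate_hertz_curve(E, nu, r, contact_point, z_grid,
                         noise_sd = noise_sd, seed = seed + i - 1L))
  structure(list(curves = curves, cell_id = cell_id), class = "force_map")
}

#' Read and write force curves
#'
#' Two-column CSV (z_m, force_N), SI units.
#'
#' @param curve data.frame with columns z_m, force_N.
#' @param path CSV path.
#' @export
write_force_curve_csv <- function(curve, path) {
  stopifnot(all(c("z_m", "force_N") %in% names(curve)))
  utils::write.csv(curve[c("z_m", "force_N")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_force_curve_csv
#' @export
read_force_curve_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("z_m", "force_N") %in% names(df)))
    stop("force curve CSV must have columns z_m, force_N")
  df[c("z_m", "force_N")]
}
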