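#' Hertz contact force for a spherical tip
#'
#' F = (4/3) (E / (1 - nu^2)) sqrt(r) delta^(3/2): the paraboloidal-tip
#' Hertz law relating indentation depth to force for a tip of radius `r`
#' on an elastic half-space of Young's modulus `E` and Poisson's ratio
#' `nu`. Monotone increasing in both delta and E.
#'
#' @param E Young's modulus, Pa (> 0).
#' @param nu Poisson's ratio, 0 <= nu < 0.5.
#' @param r tip radius, m (> 0).
#' @param delta indentation depth(s), m (>= 0).
#' @return force in N, same length as `delta`.
#' @examples
#' hertz_force(E = 1000, nu = 0.45, r = 30e-9, delta = 500e-9)  # ~1.02e-10 N
#' @export
hertz_force <- function(E, nu, r, delta) {
  stopifnot(E > 0, nu >= 0, nu < 0.5, r > 0)
  if (any(delta < 0)) stop("indentation delta must be >= 0")
  (4 / 3) * (E / (1 - nu^2)) * sqrt(r) * delta^1.5
}

#' Fit the Hertz model to an AFM force curve
#'
#' Joint estimation of Young's modulus E, contact point z0 and force
#' baseline b by Levenberg-Marquardt least squares of
#' F(z) = b + hertz_force(E, nu, r, max(z - z0, 0)). The contact point is
#' a free parameter rather than pre-detected by thresholding, which would
#' bias E on soft samples. Curves must contain a pre-contact baseline and
#' a post-contact rise; a flat curve raises a no-contact error.
#'
#' For raw deflection-vs-piezo data, convert first with
#' [force_curve_from_deflection()], which applies F = k d and the
#' indentation correction z - d.
#'
#' @param curve data.frame with columns z_m (monotonic increasing
#'   approach, >= 20 samples) and force_N.
#' @param nu Poisson's ratio (default 0.45, the standard live-cell
#'   assumption).
#' @param r tip radius, m (default 30 nm).
#' @param max_force optional trigger force, N: samples above it are
#'   excluded from the fit (emulates a fixed trigger point, e.g. 1.35 nN).
#' @param baseline_fraction fraction of the leading samples used to
#'   initialize the baseline and noise estimates.
#' @return list of class `hertz_fit`: E (Pa), contact_point (m),
#'   baseline (N), rss, converged.
#' @export
fit_hertz <- function(curve, nu = 0.45, r = 30e-9, max_force = Inf,
                      baseline_fraction = 0.2) {
  stopifnot(is.data.frame(curve),
            all(c("z_m", "force_N") %in% names(curve)))
  z <- curve$z_m; f <- curve$force_N
  if (length(z) < 20L) stop("force curve needs at least 20 samples")
  if (any(diff(z) <= 0)) stop("z_m must be strictly increasing")
  keep <- f <= max_force
  z <- z[keep]; f <- f[keep]
  if (length(z) < 20L) stop("fewer than 20 samples below the trigger force")
  nb <- max(5L, floor(baseline_fraction * length(z)))
  b0 <- stats::median(f[seq_len(nb)])
  noise <- stats::sd(f[seq_len(nb)])
  rise <- max(f) - b0
  if (!is.finite(rise) || rise <= max(5 * noise, 1e-15))
    stop("no detectable contact: curve is flat within noise")
  # initial contact point: first sustained crossing of baseline + threshold
  thr <- b0 + max(5 * noise, 0.02 * rise)
  i0 <- which(f > thr)[1]
  if (is.na(i0)) stop("no detectable contact: curve never leaves baseline")
  z00 <- z[max(i0 - 1L, 1L)]
  zmax <- z[length(z)]
  k0 <- (f[length(f)] - b0) / max(zmax - z00, .Machine$double.eps)^1.5
  fit <- tryCatch(
    minpack.lm::nlsLM(f ~ b + k * pmax(z - z0, 0)^1.5,
                      start = list(b = b0, k = max(k0, 1e-12), z0 = z00),
                      lower = c(b = -Inf, k = 0, z0 = min(z)),
                      upper = c(b = Inf, k = Inf, z0 = max(z)),
                      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(E = NA_real_, contact_point = NA_real_,
                          baseline = NA_real_, rss = NA_real_,
                          converged = FALSE), class = "hertz_fit"))
  }
  cf <- stats::coef(fit)
  E <- unname(cf["k"]) * 3 * (1 - nu^2) / (4 * sqrt(r))
  structure(list(E = E, contact_point = unname(cf["z0"]),
                 baseline = unname(cf["b"]),
                 rss = sum(stats::residuals(fit)^2),
                 converged = fit$convInfo$isConv && E > 0),
            class = "hertz_fit")
}

#' Convert a deflection-vs-piezo curve to force-vs-indentation-axis form
#'
#' Applies Hooke's law F = k_spring d and the standard tip-sample
#' separation correction: the sample is indented by the piezo travel minus
#' the cantilever deflection, so the effective z axis is z - d.
#'
#' @param z piezo z positions, m (monotonic increasing approach).
#' @param deflection cantilever deflection, m.
#' @param spring_constant cantilever spring constant, N/m (~0.02 for soft
#'   bio levers).
#' @return data.frame (z_m, force_N) suitable for [fit_hertz()].
#' @export
force_curve_from_deflection <- function(z, deflection, spring_constant) {
  stopifnot(length(z) == length(deflection), spring_constant > 0)
  data.frame(z_m = z - deflection, force_N = spring_constant * deflection)
}

#' Aggregate a force map to a per-cell Young's modulus
#'
#' Fits every curve in the map and summarizes the converged per-curve
#' moduli with the given statistic (default median, robust to
#' glass-proximity stiffening and bad curves; mean available). A 100-curve
#' map over a few um^2 is the typical per-cell acquisition.
#'
#' @param map a `force_map` from [generate_force_map()], or a list of
#'   force-curve data.frames.
#' @param summary `"median"` or `"mean"`.
#' @inheritParams fit_hertz
#' @return list of class `cell_modulus`: E (Pa), n_curves, n_converged,
#'   frac_nonconverged, per_curve_E (numeric vector with NA where a fit
#'   failed), cell_id.
#' @export
aggregate_force_map <- function(map, summary = c("median", "mean"),
                                nu = 0.45, r = 30e-9, max_force = Inf) {
  summary <- match.arg(summary)
  curves <- if (inherits(map, "force_map")) map$curves else map
  cell_id <- if (inherits(map, "force_map")) map$cell_id else NA_character_
  if (!length(curves)) stop("force map contains no curves")
  fits <- lapply(curves, function(cv)
    tryCatch(fit_hertz(cv, nu = nu, r = r, max_force = max_force),
             error = function(e) list(E = NA_real_, converged = FALSE)))
  e <- vapply(fits, function(ft)
    if (isTRUE(ft$converged)) ft$E else NA_real_, numeric(1))
  if (!any(is.finite(e)))
    stop("no curve in the map produced a converged Hertz fit")
  stat <- if (summary == "median") stats::median else mean
  structure(list(E = stat(e[is.finite(e)]),
                 n_curves = length(curves),
                 n_converged = sum(is.finite(e)),
                 frac_nonconverged = mean(!is.finite(e)),
                 per_curve_E = e,
                 cell_id = cell_id),
            class = "cell_modulus")
}

#' @export
print.hertz_fit <- function(x, ...) {
  cat(sprintf("Hertz fit: E = %.4g Pa, contact at %.3g m (%s)\n",
              x$E, x$contact_point,
              if (isTRUE(x$converged)) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
print.cell_modulus <- function(x, ...) {
  cat(sprintf("Per-cell modulus: E = %.4g Pa (%d/%d curves converged)\n",
              x$E, x$n_converged, x$n_curves))
  invisible(x)
}
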