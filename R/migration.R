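#' Path-based migration speed of a tracked cell
#'
#' Total path length divided by elapsed time at the native sampling
#' (equivalently, mean frame-to-frame displacement over the frame
#' interval). A zigzag track with the same step lengths as a straight one
#' reports the same speed.
#'
#' @param traj data.frame with columns t_min, x_um, y_um for one track
#'   (strictly increasing t).
#' @return speed in um/min.
#' @export
compute_speed <- function(traj) {
  .check_traj(traj, min_samples = 2L)
  dx <- diff(traj$x_um); dy <- diff(traj$y_um)
  sum(sqrt(dx^2 + dy^2)) / (traj$t_min[nrow(traj)] - traj$t_min[1])
}

#' Time-averaged mean squared displacement
#'
#' For each lag k*dt up to `max_lag_fraction` of the track duration, the
#' MSD is the average squared Euclidean displacement over all overlapping
#' ordered pairs of samples separated by that lag (N - k pairs for an
#' N-sample track).
#'
#' @param traj single-track data.frame (t_min, x_um, y_um), uniformly
#'   sampled.
#' @param max_lag_fraction largest lag as a fraction of track duration;
#'   default 0.5 because long-lag estimates average few pairs and are
#'   noise-dominated.
#' @return data.frame of class `msd_curve`: lag_min, msd_um2, n_pairs.
#' @export
compute_msd <- function(traj, max_lag_fraction = 0.5) {
  .check_traj(traj, min_samples = 3L)
  stopifnot(max_lag_fraction > 0, max_lag_fraction <= 1)
  n <- nrow(traj)
  dt <- (traj$t_min[n] - traj$t_min[1]) / (n - 1)
  kmax <- max(1L, floor(max_lag_fraction * (n - 1)))
  x <- traj$x_um; y <- traj$y_um
  out <- data.frame(lag_min = seq_len(kmax) * dt,
                    msd_um2 = NA_real_, n_pairs = NA_integer_)
  for (k in seq_len(kmax)) {
    dx <- x[(k + 1):n] - x[1:(n - k)]
    dy <- y[(k + 1):n] - y[1:(n - k)]
    out$msd_um2[k] <- mean(dx^2 + dy^2)
    out$n_pairs[k] <- n - k
  }
  class(out) <- c("msd_curve", "data.frame")
  out
}

#' Average MSD curves over an ensemble of tracks
#'
#' Lag-wise weighted mean (weights = pair counts) over per-track MSD
#' curves; lags present in any track are kept with summed pair counts.
#'
#' @param trajs data.frame of stacked tracks with a `track_id` column, or
#'   list of single-track data.frames.
#' @inheritParams compute_msd
#' @return an `msd_curve` data.frame.
#' @export
ensemble_msd <- function(trajs, max_lag_fraction = 0.5) {
  if (is.data.frame(trajs))
    trajs <- split(trajs, trajs$track_id)
  curves <- lapply(trajs, compute_msd, max_lag_fraction = max_lag_fraction)
  all_lags <- sort(unique(unlist(lapply(curves, `[[`, "lag_min"))))
  msd <- numeric(length(all_lags)); np <- numeric(length(all_lags))
  for (cv in curves) {
    i <- match(round(cv$lag_min, 9), round(all_lags, 9))
    msd[i] <- msd[i] + cv$msd_um2 * cv$n_pairs
    np[i] <- np[i] + cv$n_pairs
  }
  out <- data.frame(lag_min = all_lags, msd_um2 = msd / np,
                    n_pairs = as.integer(np))
  class(out) <- c("msd_curve", "data.frame")
  out
}

#' Fit the persistent-random-walk (Fuerth) model to an MSD curve
#'
#' Weighted nonlinear least squares of MSD(t) = 4 D \[t - tau (1 -
#' exp(-t/tau))\] over (D, tau) with positivity constraints
#' (Levenberg-Marquardt). Initial values: D from the slope of the last
#' quartile of lags divided by 4 (the diffusive limit), tau from the first
#' lag spacing. The default `"relative"` weighting (1/MSD^2, i.e. fitting
#' relative errors, equivalent to a log-MSD fit) keeps the short-lag
#' ballistic regime — where the curvature that identifies tau lives — from
#' being swamped by the large absolute long-lag values; absolute
#' (`"unit"`), pair-count (`"pairs"`) and inverse-pair-count
#' (`"inverse-pairs"`) weights are available.
#'
#' @param msd an `msd_curve` from [compute_msd()] or [ensemble_msd()] with
#'   at least 4 lags.
#' @param weighting residual weighting scheme; see Details.
#' @return list of class `prw_fit`: D (um^2/min), tau (min), rss,
#'   converged (logical).
#' @export
fit_prw <- function(msd, weighting = c("relative", "unit", "pairs",
                                       "inverse-pairs")) {
  weighting <- match.arg(weighting)
  stopifnot(is.data.frame(msd),
            all(c("lag_min", "msd_um2", "n_pairs") %in% names(msd)))
  if (nrow(msd) < 4L) stop("need at least 4 lags to fit the PRW model")
  if (all(msd$msd_um2 <= 0)) stop("degenerate input: MSD identically zero")
  t <- msd$lag_min; y <- msd$msd_um2
  w <- switch(weighting,
              relative = 1 / pmax(y, .Machine$double.eps)^2,
              unit = rep(1, length(y)),
              pairs = msd$n_pairs,
              "inverse-pairs" = 1 / msd$n_pairs)
  iq <- t >= stats::quantile(t, 0.75)
  slope <- stats::coef(stats::lm(y[iq] ~ t[iq]))[2]
  d0 <- max(slope / 4, y[length(y)] / (4 * t[length(t)]), 1e-8)
  tau0 <- t[1]
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ 4 * D * (t - tau * (1 - exp(-t / tau))),
                      start = list(D = d0, tau = tau0),
                      lower = c(D = 0, tau = 1e-6),
                      weights = w,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(D = NA_real_, tau = NA_real_, rss = NA_real_,
                          converged = FALSE), class = "prw_fit"))
  }
  cf <- stats::coef(fit)
  structure(list(D = unname(cf["D"]), tau = unname(cf["tau"]),
                 rss = sum(w * stats::residuals(fit)^2),
                 converged = fit$convInfo$isConv),
            class = "prw_fit")
}

#' Chemotactic index of a trajectory
#'
#' Net displacement projected on the gradient axis divided by total path
#' length; bounded in \[-1, 1\]. 1 for a straight run up the gradient, 0
#' for motion perpendicular to it or for any closed loop.
#'
#' @param traj single-track data.frame (t_min, x_um, y_um).
#' @param gradient_axis length-2 vector pointing up the gradient
#'   (normalized internally); default +x.
#' @return dimensionless index in \[-1, 1\].
#' @export
chemotactic_index <- function(traj, gradient_axis = c(1, 0)) {
  .check_traj(traj, min_samples = 2L)
  stopifnot(length(gradient_axis) == 2L)
  nv <- sqrt(sum(gradient_axis^2))
  if (nv <= 0) stop("gradient_axis must be non-zero")
  u <- gradient_axis / nv
  dx <- diff(traj$x_um); dy <- diff(traj$y_um)
  path <- sum(sqrt(dx^2 + dy^2))
  if (path <= 0) stop("zero path length: chemotactic index undefined")
  n <- nrow(traj)
  net <- c(traj$x_um[n] - traj$x_um[1], traj$y_um[n] - traj$y_um[1])
  sum(net * u) / path
}

.check_traj <- function(traj, min_samples) {
  stopifnot(is.data.frame(traj),
            all(c("t_min", "x_um", "y_um") %in% names(traj)))
  if (nrow(traj) < min_samples)
    stop("trajectory needs at least ", min_samples, " samples")
  dts <- diff(traj$t_min)
  if (any(dts <= 0)) stop("t_min must be strictly increasing")
  if (nrow(traj) >= 3L && diff(range(dts)) > 1e-6 * mean(dts))
    stop("trajectory must be uniformly sampled")
  invisible(TRUE)
}

#' @export
print.prw_fit <- function(x, ...) {
  cat(sprintf("PRW fit: D = %.4g um^2/min, tau = %.4g min (%s, rss = %.3g)\n",
              x$D, x$tau,
              if (isTRUE(x$converged)) "converged" else "NOT converged",
              x$rss))
  invisible(x)
}
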