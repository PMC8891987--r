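#' Fuerth mean-squared displacement of a 2D persistent random walk
#'
#' MSD(t) = 4 D \[t - tau (1 - exp(-t/tau))\]: ballistic (2D/tau) t^2 at
#' short lags, diffusive 4 D t at long lags.
#'
#' @param t time lag(s), min.
#' @param D diffusion coefficient, um^2/min.
#' @param tau persistence time, min.
#' @return MSD in um^2, same length as `t`.
#' @export
furth_msd <- function(t, D, tau) {
  stopifnot(D >= 0, tau > 0)
  4 * D * (t - tau * (1 - exp(-t / tau)))
}

#' Simulate a 2D persistent-random-walk cell trajectory
#'
#' Positions follow the integral of a 2D Ornstein-Uhlenbeck velocity
#' process with persistence time `tau` and stationary per-component
#' velocity variance D/tau, so the ensemble MSD is exactly the Fuerth form
#' [furth_msd()] at every lag. The update is the exact joint Gaussian
#' transition of (position, velocity) over one step (decay factor
#' exp(-dt/tau)), not an Euler scheme, so no step-size bias is introduced
#' at any `dt`. The initial velocity is drawn from the stationary
#' distribution.
#'
#' @param D diffusion coefficient, um^2/min (>= 0; 0 gives a stationary
#'   track).
#' @param tau persistence time, min (> 0).
#' @param dt sampling interval, min (> 0); 5 min is typical for time-lapse
#'   migration assays.
#' @param n_steps number of steps; the trajectory has `n_steps + 1` samples.
#' @param seed integer seed; RNG state restored on exit.
#' @param track_id identifier stored in the output.
#' @return data.frame with columns track_id, frame (0-based), t_min, x_um,
#'   y_um.
#' @examples
#' tr <- generate_prw_trajectory(D = 10, tau = 5, dt = 5, n_steps = 20, seed = 1)
#' @export
generate_prw_trajectory <- function(D, tau, dt, n_steps, seed = 1L,
                                    track_id = 1L) {
  if (!is.numeric(D) || D < 0) stop("D must be >= 0")
  if (!is.numeric(tau) || tau <= 0) stop("tau must be > 0")
  if (!is.numeric(dt) || dt <= 0) stop("dt must be > 0")
  stopifnot(n_steps >= 1L)
  n <- as.integer(n_steps)
  if (D == 0) {
    return(data.frame(track_id = track_id, frame = 0:n,
                      t_min = (0:n) * dt, x_um = 0, y_um = 0))
  }
  beta <- 1 / tau
  a <- exp(-beta * dt)
  s2 <- D / tau                              # stationary velocity variance
  var_v <- s2 * (1 - a^2)
  var_x <- (s2 / beta^2) * (2 * beta * dt - 3 + 4 * a - a^2)
  cov_xv <- (s2 / beta) * (1 - a)^2
  # Cholesky of the 2x2 (x, v) innovation covariance
  l11 <- sqrt(var_x)
  l21 <- cov_xv / l11
  l22 <- sqrt(max(var_v - l21^2, 0))
  xy <- with_seed(seed, {
    v <- matrix(stats::rnorm(2, 0, sqrt(s2)), 1)   # stationary start
    pos <- matrix(0, n + 1L, 2)
    z1 <- matrix(stats::rnorm(2 * n), n, 2)
    z2 <- matrix(stats::rnorm(2 * n), n, 2)
    for (k in seq_len(n)) {
      dx <- v * (1 - a) / beta + l11 * z1[k, ]
      pos[k + 1L, ] <- pos[k, ] + dx
      v <- a * v + l21 * z1[k, ] + l22 * z2[k, ]
    }
    pos
  })
  data.frame(track_id = track_id, frame = 0:n, t_min = (0:n) * dt,
             x_um = xy[, 1], y_um = xy[, 2])
}

#' Simulate an ensemble of persistent-random-walk trajectories
#'
#' @inheritParams generate_prw_trajectory
#' @param n_tracks number of independent trajectories; track `i` uses seed
#'   `seed + i - 1` and track_id `i`.
#' @return data.frame stacking all trajectories.
#' @export
generate_prw_ensemble <- function(n_tracks, D, tau, dt, n_steps, seed = 1L) {
  stopifnot(n_tracks >= 1L)
  do.call(rbind, lapply(seq_len(n_tracks), function(i)
    generate_prw_trajectory(D, tau, dt, n_steps, seed = seed + i - 1L,
                            track_id = i)))
}

#' Read and write trajectory tables
#'
#' Plain CSV with header `track_id, frame, t_min, x_um, y_um`.
#'
#' @param traj trajectory data.frame (one or many tracks).
#' @param path CSV path.
#' @export
write_trajectory_csv <- function(traj, path) {
  cols <- c("track_id", "frame", "t_min", "x_um", "y_um")
  stopifnot(all(cols %in% names(traj)))
  utils::write.csv(traj[cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path)
  cols <- c("track_id", "frame", "t_min", "x_um", "y_um")
  if (!all(cols %in% names(df)))
    stop("trajectory CSV must have columns: ", paste(cols, collapse = ", "))
  df[cols]
}
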