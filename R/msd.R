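#' Time-averaged mean squared displacement
#'
#' MSD over time origins at lag \eqn{n\Delta t}:
#' \deqn{MSD(n\Delta t) = \frac{1}{N-n} \sum_{i=0}^{N-n-1} |x_{i+n} - x_i|^2}
#' computed for lags \eqn{n = 1 \dots n_{max}}.  By convention the MSD at
#' lag 0 is 0 and is not stored.  Lags beyond N/4 average over few time
#' origins and are noise-dominated, hence the default cutoff.
#'
#' @param traj a [trajectory()] with uniform time step and N >= 3.
#' @param n_max largest lag index; default `floor(N/4)` (at least 1).
#' @return object of class `"msd_curve"`: list with `lags` (time units) and
#'   `values` (length^2), plus the `dt` and `n_points` used.
#' @examples
#' tr <- trajectory(0:49)           # ballistic line: MSD(n) = n^2
#' msd <- msd_time_averaged(tr)
#' anomalous_exponent(msd)          # exactly 2
#' @export
msd_time_averaged <- function(traj, n_max = NULL) {
  n <- n_points(traj)
  if (n < 3L) stop("time-averaged MSD needs at least 3 points")
  dt <- traj_dt(traj)
  if (is.null(n_max)) n_max <- max(1L, n %/% 4L)
  n_max <- as.integer(n_max)
  if (n_max < 1L || n_max > n - 1L)
    stop("'n_max' must be between 1 and N-1")
  p <- traj$positions
  vals <- vapply(seq_len(n_max), function(lag) {
    d <- p[(1L + lag):n, , drop = FALSE] - p[1L:(n - lag), , drop = FALSE]
    mean(.rowSums(d * d, n - lag, ncol(p)))
  }, numeric(1))
  structure(list(lags = seq_len(n_max) * dt, values = vals,
                 dt = dt, n_points = n),
            class = "msd_curve")
}

#' Ensemble mean squared displacement
#'
#' Averages the squared displacement from each trajectory's own origin over
#' an ensemble: \eqn{MSD(t_n) = \langle |x_n - x_0|^2 \rangle_{traj}}.
#' All trajectories must share the same uniform time step; curves are
#' truncated to the shortest trajectory.
#'
#' @param trajs non-empty list of [trajectory()] objects.
#' @return an `"msd_curve"` (lags `dt, 2 dt, ...`).
#' @export
msd_ensemble <- function(trajs) {
  if (!is.list(trajs) || length(trajs) == 0L)
    stop("'trajs' must be a non-empty list of trajectories")
  dts <- vapply(trajs, traj_dt, numeric(1))
  dt <- dts[1L]
  if (any(abs(dts - dt) > 1e-9 * dt))
    stop("all trajectories must share the same time step")
  n <- min(vapply(trajs, n_points, integer(1)))
  if (n < 2L) stop("trajectories too short for an ensemble MSD")
  sq <- vapply(trajs, function(tr) {
    p <- tr$positions
    d <- p[2L:n, , drop = FALSE] -
      matrix(p[1L, ], n - 1L, ncol(p), byrow = TRUE)
    .rowSums(d * d, n - 1L, ncol(p))
  }, numeric(n - 1L))
  structure(list(lags = seq_len(n - 1L) * dt,
                 values = rowMeans(matrix(sq, nrow = n - 1L)),
                 dt = dt, n_points = n),
            class = "msd_curve")
}

#' @export
print.msd_curve <- function(x, ...) {
  cat(sprintf("<msd_curve: %d lags, dt = %g, MSD(dt) = %.4g>\n",
              length(x$lags), x$dt, x$values[1L]))
  invisible(x)
}

#' @export
plot.msd_curve <- function(x, log = "xy", ...) {
  graphics::plot(x$lags, x$values, log = log, xlab = "lag",
                 ylab = "MSD", type = "b", pch = 16, cex = 0.6, ...)
  invisible(x)
}

#' Anomalous diffusion exponent
#'
#' Least-squares slope of log MSD versus log lag.  For MSD
#' \eqn{\propto \tau^\alpha}: \eqn{\alpha = 1} is normal diffusion,
#' \eqn{\alpha < 1} sub-diffusion, \eqn{\alpha > 1} super-diffusion and
#' \eqn{\alpha = 2} ballistic motion.
#'
#' @param msd an `"msd_curve"` with at least 3 lags, all values positive.
#' @return the fitted exponent (dimensionless).
#' @export
anomalous_exponent <- function(msd) {
  if (!inherits(msd, "msd_curve")) stop("'msd' must be an msd_curve")
  if (length(msd$lags) < 3L)
    stop("anomalous exponent fit needs at least 3 lag points")
  if (any(msd$values <= 0))
    stop("MSD has non-positive values (constant trajectory?); ",
         "log-log fit undefined")
  lx <- log(msd$lags)
  ly <- log(msd$values)
  sum((lx - mean(lx)) * (ly - mean(ly))) / sum((lx - mean(lx))^2)
}

#' MSD ratio
#'
#' \eqn{\kappa = MSD(n_1)/MSD(n_2) - n_1/n_2}.  Zero for a linear
#' (normal-diffusive) MSD, negative for super-diffusion, positive for a
#' confined plateau.
#'
#' @param msd an `"msd_curve"`.
#' @param n1,n2 lag indices with `n1 < n2`, both within the curve.  Defaults
#'   `n1 = 1`, `n2 = floor(n_max/2)` (at least 2).
#' @return the dimensionless ratio statistic.
#' @export
msd_ratio <- function(msd, n1 = 1L, n2 = NULL) {
  if (!inherits(msd, "msd_curve")) stop("'msd' must be an msd_curve")
  nmax <- length(msd$lags)
  if (is.null(n2)) n2 <- max(2L, nmax %/% 2L)
  n1 <- as.integer(n1); n2 <- as.integer(n2)
  if (n1 < 1L || n2 > nmax || n1 >= n2)
    stop("need 1 <= n1 < n2 <= ", nmax)
  if (msd$values[n2] == 0) stop("MSD(n2) is zero; ratio undefined")
  msd$values[n1] / msd$values[n2] - n1 / n2
}
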