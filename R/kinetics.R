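#' Finite-difference velocity series
#'
#' \eqn{v_i = (x_{i+1} - x_i)/\Delta t} on a uniform time grid.
#'
#' @param traj a [trajectory()] with uniform time step.
#' @return an (N-1) x d numeric matrix of velocities (length/time).
#' @export
velocity_series <- function(traj) {
  dt <- traj_dt(traj)
  p <- traj$positions
  n <- nrow(p)
  (p[2L:n, , drop = FALSE] - p[1L:(n - 1L), , drop = FALSE]) / dt
}

#' Mean speed
#'
#' Mean Euclidean norm of the finite-difference velocities.
#'
#' @inheritParams velocity_series
#' @return mean speed (length/time), >= 0.
#' @export
mean_speed <- function(traj) {
  v <- velocity_series(traj)
  mean(sqrt(.rowSums(v * v, nrow(v), ncol(v))))
}

#' Velocity autocorrelation function
#'
#' Time-averaged correlation of the finite-difference velocities,
#' \deqn{C(n\Delta t) = \frac{1}{M-n} \sum_{i} v_i \cdot v_{i+n}, \qquad
#'       M = N - 1,}
#' for lags \eqn{n = 0 \dots n_{max}}.  When `normalize = TRUE` the curve is
#' divided by \eqn{C(0)} so that the zero-lag value is 1; this requires a
#' non-degenerate (moving) trajectory.  For a Brownian walk the increments
#' are independent and the normalized VACF vanishes for all \eqn{n \ge 1};
#' persistent motion keeps it positive, reversal makes it negative.
#'
#' @param traj a [trajectory()] with uniform time step and N >= 3.
#' @param n_max largest lag index; default `floor(M/4)` (at least 1).
#' @param normalize divide by the zero-lag value (default `TRUE`).
#' @return object of class `"vacf_curve"`: list with `lags` (starting at 0),
#'   `values`, `c0` (the unnormalized zero-lag value) and `dt`.
#' @export
vacf <- function(traj, n_max = NULL, normalize = TRUE) {
  dt <- traj_dt(traj)
  v <- velocity_series(traj)
  m <- nrow(v)
  if (m < 2L) stop("VACF needs at least 3 trajectory points")
  if (is.null(n_max)) n_max <- max(1L, m %/% 4L)
  n_max <- as.integer(n_max)
  if (n_max < 1L || n_max > m - 1L) stop("'n_max' must be between 1 and M-1")
  vals <- vapply(0L:n_max, function(lag) {
    a <- v[1L:(m - lag), , drop = FALSE]
    b <- v[(1L + lag):m, , drop = FALSE]
    mean(.rowSums(a * b, m - lag, ncol(v)))
  }, numeric(1))
  c0 <- vals[1L]
  if (normalize) {
    if (c0 <= 0) stop("zero-lag VACF is zero (constant trajectory); ",
                      "cannot normalize")
    vals <- vals / c0
  }
  structure(list(lags = (0L:n_max) * dt, values = vals, c0 = c0, dt = dt,
                 normalized = normalize),
            class = "vacf_curve")
}

#' @export
print.vacf_curve <- function(x, ...) {
  cat(sprintf("<vacf_curve: %d lags, dt = %g, %s, C(dt) = %.4g>\n",
              length(x$lags) - 1L, x$dt,
              if (x$normalized) "normalized" else "unnormalized",
              x$values[2L]))
  invisible(x)
}

#' @export
plot.vacf_curve <- function(x, ...) {
  graphics::plot(x$lags, x$values, type = "h", xlab = "lag",
                 ylab = if (x$normalized) "VACF (normalized)" else "VACF", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Green-Kubo diffusion coefficient
#'
#' Estimates the diffusivity from the time integral of the unnormalized
#' velocity autocorrelation function,
#' \deqn{D_{GK} = \frac{1}{d} \int_0^{t_c} \langle v(0)\cdot v(t)\rangle\,dt,}
#' by trapezoidal quadrature.  The cutoff \eqn{t_c} is the first zero
#' crossing of the VACF (the integral's noisy tail past the crossing
#' carries no signal for diffusive motion), or the largest computed lag if
#' the VACF never crosses zero.  A constant trajectory has zero VACF and
#' returns 0.
#'
#' For a discrete random walk with per-dimension step variance
#' \eqn{2 D \Delta t}, \eqn{C(0) = 2 d D / \Delta t} and the lag-1 trapezoid
#' recovers \eqn{D_{GK} \approx D}.
#'
#' @inheritParams vacf
#' @return the Green-Kubo diffusivity (length^2/time).
#' @export
green_kubo_diffusivity <- function(traj, n_max = NULL) {
  cv <- vacf(traj, n_max = n_max, normalize = FALSE)
  vals <- cv$values
  if (vals[1L] <= 0) return(0)
  crossings <- which(vals[-1L] <= 0)
  k <- if (length(crossings)) crossings[1L] + 1L else length(vals)
  dt <- cv$dt
  integral <- sum((vals[1L:(k - 1L)] + vals[2L:k]) / 2) * dt
  integral / n_dims(traj)
}

#' Dominant Fourier frequency
#'
#' Computes the discrete power spectrum of each mean-subtracted coordinate
#' (rectangular window), sums the spectra over dimensions and returns the
#' frequency of the strongest bin excluding zero frequency.  Returns 0 when
#' the total non-zero-bin power is negligible (relative threshold 1e-12),
#' i.e. for a constant trajectory.  Oscillatory or stepping motion shows up
#' as a sharp peak; free diffusion puts most power in the lowest bins.
#'
#' @param traj a [trajectory()] with uniform time step and N >= 4.
#' @return the dominant frequency (1/time units), >= 0.
#' @export
dominant_frequency <- function(traj) {
  dt <- traj_dt(traj)
  n <- n_points(traj)
  if (n < 4L) stop("Fourier analysis needs at least 4 points")
  x <- sweep(traj$positions, 2L, colMeans(traj$positions))
  power <- rowSums(vapply(seq_len(ncol(x)), function(j) {
    Mod(stats::fft(x[, j]))^2
  }, numeric(n)))
  keep <- 2L:(n %/% 2L + 1L)            # positive frequencies, zero excluded
  total <- sum(x * x) * n               # Parseval: total spectral power
  if (total <= 0 || sum(power[keep]) <= 1e-12 * total) return(0)
  freqs <- (keep - 1L) / (n * dt)
  freqs[which.max(power[keep])]
}
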