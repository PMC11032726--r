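step_lengths <- function(traj) {
  p <- traj$positions
  n <- nrow(p)
  d <- p[2L:n, , drop = FALSE] - p[1L:(n - 1L), , drop = FALSE]
  sqrt(.rowSums(d * d, n - 1L, ncol(p)))
}

net_displacement <- function(traj) {
  p <- traj$positions
  sqrt(sum((p[nrow(p), ] - p[1L, ])^2))
}

## Exact diameter of the visited point set.  O(N^2) pairwise distances are
## computed in fixed-size blocks so memory stays bounded; in 1-D and 2-D
## cheaper exact shortcuts (range, convex hull) apply.
max_extent <- function(positions) {
  n <- nrow(positions)
  d <- ncol(positions)
  if (d == 1L) return(diff(range(positions[, 1L])))
  if (d == 2L && n > 16L) {
    hull <- grDevices::chull(positions[, 1L], positions[, 2L])
    positions <- positions[hull, , drop = FALSE]
    n <- nrow(positions)
  }
  block <- 512L
  best <- 0
  starts <- seq(1L, n, by = block)
  for (a in starts) {
    ia <- a:min(a + block - 1L, n)
    pa <- positions[ia, , drop = FALSE]
    for (b in starts[starts >= a]) {
      ib <- b:min(b + block - 1L, n)
      pb <- positions[ib, , drop = FALSE]
      cross <- tcrossprod(pa, pb)
      sq <- outer(.rowSums(pa * pa, nrow(pa), d),
                  .rowSums(pb * pb, nrow(pb), d), "+") - 2 * cross
      best <- max(best, max(sq))
    }
  }
  sqrt(max(best, 0))
}

#' Katz fractal dimension
#'
#' Path-complexity measure
#' \deqn{D = \frac{\ln n}{\ln n + \ln(e/L)}}
#' with \eqn{n = N - 1} steps, total path length
#' \eqn{L = \sum_i |x_{i+1} - x_i|} and maximal extent
#' \eqn{e = \max_{i,j} |x_i - x_j|}.  A straight line gives 1; larger values
#' indicate increasingly space-filling paths.  In the degenerate case
#' \eqn{e/L = 1/n} the denominator vanishes and `Inf` is returned as a
#' sentinel (the pipeline imputes it; see [train_classifier()]).
#'
#' @param traj a [trajectory()] with positive path length.
#' @return the fractal dimension (dimensionless), possibly `Inf`.
#' @export
fractal_dimension <- function(traj) {
  n <- n_points(traj) - 1L
  L <- sum(step_lengths(traj))
  if (L <= 0) stop("zero path length; fractal dimension undefined")
  e <- max_extent(traj$positions)
  if (e <= 0) stop("zero spatial extent; fractal dimension undefined")
  denom <- log(n) + log(e / L)
  if (abs(denom) < 1e-12) return(Inf)
  log(n) / denom
}

#' Straightness
#'
#' Net-displacement-to-path-length ratio
#' \eqn{S = |x_{N-1} - x_0| / \sum_i |x_i - x_{i-1}|} in \[0, 1\]:
#' 1 for a monotone straight line, 0 for a closed loop.
#'
#' @param traj a [trajectory()] with positive path length.
#' @return straightness in \[0, 1\].
#' @export
straightness <- function(traj) {
  L <- sum(step_lengths(traj))
  if (L <= 0) stop("zero path length; straightness undefined")
  net_displacement(traj) / L
}

#' Efficiency
#'
#' Squared form of the net-displacement ratio,
#' \deqn{E = \frac{|x_{N-1} - x_0|^2}{(N-1)\sum_i |x_i - x_{i-1}|^2},}
#' in \[0, 1\]: 1 for a constant-step straight line, ~1/N for a random
#' walk, 0 for a closed loop.
#'
#' @param traj a [trajectory()] with positive path length.
#' @return efficiency in \[0, 1\].
#' @export
efficiency <- function(traj) {
  s2 <- sum(step_lengths(traj)^2)
  if (s2 <= 0) stop("zero path length; efficiency undefined")
  net_displacement(traj)^2 / ((n_points(traj) - 1L) * s2)
}

#' Trappedness
#'
#' Probability-like score that the trajectory is confined, from the
#' short-time diffusivity \eqn{D_0}, the duration
#' \eqn{t = (N-1)\Delta t} and the confinement radius estimate
#' \eqn{r_0} (half the maximal extent):
#' \deqn{P = 1 - \exp\!\left(0.2048 - 0.25117\, \frac{D_0 t}{r_0^2}\right),}
#' clamped to \[0, 1\].  \eqn{D_0} comes from a two-point fit to the first
#' two MSD lags, \eqn{D_0 = (MSD(2\Delta t) - MSD(\Delta t))/(2 d \Delta t)}.
#' Free motion explores far beyond \eqn{r_0} and drives the score towards 1
#' slowly from the duration term; genuinely confined motion has a large
#' \eqn{D_0 t / r_0^2} and scores near 1, while short ballistic paths score 0.
#'
#' @param traj a [trajectory()] with uniform time step.
#' @param msd optional precomputed [msd_time_averaged()] curve with at
#'   least 2 lags.
#' @return trappedness in \[0, 1\].
#' @seealso [trappedness_score()] for the closed form on
#'   \eqn{(D_0, t, r_0)}.
#' @export
trappedness <- function(traj, msd = NULL) {
  if (is.null(msd) || length(msd$lags) < 2L)
    msd <- msd_time_averaged(traj, n_max = 2L)
  dt <- traj_dt(traj)
  d <- n_dims(traj)
  D0 <- (msd$values[2L] - msd$values[1L]) / (2 * d * (msd$lags[2L] - msd$lags[1L]))
  r0 <- max_extent(traj$positions) / 2
  if (r0 <= 0) stop("zero spatial extent; trappedness undefined")
  trappedness_score(D0, (n_points(traj) - 1L) * dt, r0)
}

#' @param D0 short-time diffusivity (length^2/time).
#' @param t_total trajectory duration (time).
#' @param r0 confinement radius estimate (length), > 0.
#' @rdname trappedness
#' @export
trappedness_score <- function(D0, t_total, r0) {
  if (r0 <= 0) stop("'r0' must be positive")
  p <- 1 - exp(0.2048 - 0.25117 * (D0 * t_total) / r0^2)
  min(max(p, 0), 1)
}

#' Gaussianity
#'
#' Excess of the fourth displacement moment relative to the Gaussian
#' expectation at a reference lag \eqn{n^*} (default the first, best-sampled
#' lag):
#' \deqn{g = \frac{\langle r^4 \rangle}{(1 + 2/d)\,\langle r^2 \rangle^2} - 1,}
#' with time-averaged moments over all displacement origins.  Zero for
#' normal diffusion in any dimension; negative for narrow (e.g.
#' constant-modulus) displacement distributions; positive for heavy tails.
#'
#' @param traj a [trajectory()] with uniform time step.
#' @param lag reference lag index \eqn{n^*} (default 1).
#' @return the gaussianity (dimensionless).
#' @export
gaussianity <- function(traj, lag = 1L) {
  traj_dt(traj)
  n <- n_points(traj)
  lag <- as.integer(lag)
  if (lag < 1L || lag > n - 1L) stop("'lag' must be between 1 and N-1")
  p <- traj$positions
  d <- p[(1L + lag):n, , drop = FALSE] - p[1L:(n - lag), , drop = FALSE]
  r2 <- .rowSums(d * d, n - lag, ncol(p))
  m2 <- mean(r2)
  if (m2 <= 0) stop("zero mean squared displacement; gaussianity undefined")
  mean(r2^2) / ((1 + 2 / ncol(p)) * m2^2) - 1
}
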