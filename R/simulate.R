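## Evaluate `code` under a temporary RNG state seeded with `seed`,
## restoring the caller's stream afterwards.  seed = NULL leaves the RNG
## untouched (non-reproducible draw from the ambient stream).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## Deterministic per-coordinate sub-seed derived from one master seed, so a
## d-dimensional simulation shares its first coordinates with the
## lower-dimensional one at the same seed.
coord_seed <- function(seed, j) {
  as.integer((as.double(seed %% 2147483647L) * 1009 + j * 101) %% 2147483629)
}

check_sim_args <- function(n_points, dt, dim, D, allow_zero_D = FALSE) {
  if (!is.numeric(n_points) || length(n_points) != 1L || n_points < 2L)
    stop("'n_points' must be a single integer >= 2")
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("'dt' must be a single positive number")
  if (!dim %in% 1:3) stop("'dim' must be 1, 2 or 3")
  if (!is.numeric(D) || length(D) != 1L || D < 0 ||
      (!allow_zero_D && D == 0))
    stop("'D' must be a single positive diffusivity")
  invisible(TRUE)
}

## Gaussian increment matrix (n-1) x dim with per-dimension variance
## 2 D dt, drawn per coordinate from derived sub-streams.
gaussian_steps <- function(n_points, dt, dim, D, seed) {
  m <- n_points - 1L
  sd <- sqrt(2 * D * dt)
  steps <- matrix(0, m, dim)
  for (j in seq_len(dim)) {
    steps[, j] <- if (is.null(seed)) stats::rnorm(m, sd = sd)
    else with_seed(coord_seed(seed, j), stats::rnorm(m, sd = sd))
  }
  steps
}

#' Simulate normal (Brownian) diffusion
#'
#' Discrete random walk \eqn{x_{n+1} = x_n + \xi_n} started at the origin,
#' with i.i.d. zero-mean Gaussian steps of variance \eqn{2 D \Delta t} per
#' dimension, so the ensemble MSD is \eqn{2 d D t} (anomalous exponent 1).
#'
#' @param n_points number of trajectory points N (>= 2).
#' @param dt time step (time units), > 0.
#' @param dim spatial dimension, 1-3.
#' @param D diffusion coefficient (length^2/time), > 0.
#' @param seed integer master seed; identical seeds give identical
#'   trajectories (per-coordinate sub-streams are derived from it).
#'   `NULL` draws from the ambient RNG stream.
#' @param id optional trajectory label.
#' @return a [trajectory()].
#' @export
simulate_normal <- function(n_points, dt = 1, dim = 2, D = 1, seed = NULL,
                            id = NULL) {
  check_sim_args(n_points, dt, dim, D)
  steps <- gaussian_steps(n_points, dt, dim, D, seed)
  pos <- rbind(0, apply(steps, 2L, cumsum))
  trajectory(matrix(pos, ncol = dim), dt = dt, id = id)
}

## Cache of Cholesky factors of the unit-diffusivity fBm covariance,
## keyed by (alpha, n_points, dt).  The factorization is the costly part
## (O(n^3)); with the cache an ensemble at fixed parameters costs O(n^2)
## per trajectory.
.fbm_cache <- new.env(parent = emptyenv())

fbm_chol <- function(alpha, n_points, dt) {
  key <- paste(format(alpha, digits = 15), n_points, format(dt, digits = 15),
               sep = "|")
  hit <- .fbm_cache[[key]]
  if (!is.null(hit)) return(hit)
  t_grid <- seq_len(n_points - 1L) * dt
  Sigma <- outer(t_grid, t_grid, function(s, t)
    s^alpha + t^alpha - abs(t - s)^alpha)
  L <- tryCatch(chol(Sigma), error = function(e) {
    jitter <- 1e-10 * max(diag(Sigma))
    tryCatch(chol(Sigma + diag(jitter, nrow(Sigma))),
             error = function(e2)
               stop("fBm covariance is numerically not positive definite ",
                    "even after jitter (alpha = ", alpha, ")", call. = FALSE))
  })
  .fbm_cache[[key]] <- L
  L
}

#' Simulate anomalous diffusion (fractional Brownian motion)
#'
#' Each coordinate is exact fractional Brownian motion with Hurst exponent
#' \eqn{H = \alpha/2}, sampled from the covariance
#' \deqn{\mathrm{Cov}(x_s, x_t) = D(|s|^\alpha + |t|^\alpha - |t-s|^\alpha)}
#' via Cholesky factorization, so the ensemble MSD is exactly
#' \eqn{2 d D t^\alpha}.  \eqn{\alpha = 1} reduces to normal diffusion
#' (independent increments); \eqn{\alpha < 1} gives anti-persistent
#' sub-diffusive motion, \eqn{\alpha > 1} persistent super-diffusive
#' motion.  Exact sampling is O(N^3) for the first draw at given
#' (alpha, N, dt) and O(N^2) afterwards (the factor is cached), which is
#' ample at desk scale (N up to a few thousand).
#'
#' @inheritParams simulate_normal
#' @param alpha anomalous exponent in (0, 2].
#' @return a [trajectory()].
#' @export
simulate_anomalous <- function(n_points, dt = 1, dim = 2, D = 1, alpha = 0.5,
                               seed = NULL, id = NULL) {
  check_sim_args(n_points, dt, dim, D)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 2)
    stop("'alpha' must be in (0, 2]")
  L <- fbm_chol(alpha, n_points, dt)
  m <- n_points - 1L
  pos <- matrix(0, n_points, dim)
  for (j in seq_len(dim)) {
    z <- if (is.null(seed)) stats::rnorm(m)
    else with_seed(coord_seed(seed, j), stats::rnorm(m))
    pos[2L:n_points, j] <- sqrt(D) * drop(crossprod(L, z))
  }
  trajectory(pos, dt = dt, id = id)
}

## Fold a radius r into [0, R] by specular reflection at the sphere |x| = R
## (negative values mean passing through the origin: same radius, direction
## handled by the sign of the scale factor).
reflect_radius <- function(r, R) {
  while (r > R || r < -R) {
    if (r > R) r <- 2 * R - r else r <- -2 * R - r
  }
  r
}

#' Simulate confined diffusion
#'
#' Brownian proposal steps as in [simulate_normal()]; any step leaving the
#' sphere \eqn{|x| \le R} centred at the origin is reflected specularly in
#' the radial coordinate, so all output points satisfy \eqn{|x| \le R}.
#' The time-averaged MSD plateaus near the confinement scale, giving the
#' sub-diffusive training class.
#'
#' @inheritParams simulate_normal
#' @param radius confinement radius R (length units), > 0.
#' @return a [trajectory()] with all points inside the sphere.
#' @export
simulate_confined <- function(n_points, dt = 1, dim = 2, D = 1, radius = 1,
                              seed = NULL, id = NULL) {
  check_sim_args(n_points, dt, dim, D)
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0)
    stop("'radius' must be a single positive number")
  steps <- gaussian_steps(n_points, dt, dim, D, seed)
  pos <- matrix(0, n_points, dim)
  for (i in seq_len(n_points - 1L)) {
    y <- pos[i, ] + steps[i, ]
    r <- sqrt(sum(y^2))
    if (r > radius) y <- y * (reflect_radius(r, radius) / r)
    pos[i + 1L, ] <- y
  }
  trajectory(pos, dt = dt, id = id)
}

#' Simulate directed motion
#'
#' Drift plus Brownian noise, \eqn{x_{n+1} = x_n + v\Delta t + \xi_n}, the
#' super-diffusive training class (anomalous exponent approaching 2 when
#' the Peclet number \eqn{|v|^2 T / (2 d D)} is large).  `D = 0` is
#' accepted and gives the pure-drift straight line (the ballistic limit).
#'
#' @inheritParams simulate_normal
#' @param velocity drift velocity: a scalar (drift along the first axis) or
#'   a length-`dim` vector; must be nonzero (use [simulate_normal()] for
#'   zero drift).
#' @return a [trajectory()].
#' @export
simulate_directed <- function(n_points, dt = 1, dim = 2, D = 1,
                              velocity = 1, seed = NULL, id = NULL) {
  check_sim_args(n_points, dt, dim, D, allow_zero_D = TRUE)
  if (length(velocity) == 1L) velocity <- c(velocity, rep(0, dim - 1L))
  if (length(velocity) != dim)
    stop("'velocity' must be a scalar or a vector of length ", dim)
  if (sum(velocity^2) == 0)
    stop("zero drift velocity: use simulate_normal() for undirected motion")
  steps <- gaussian_steps(n_points, dt, dim, D, seed) +
    matrix(velocity * dt, n_points - 1L, dim, byrow = TRUE)
  pos <- rbind(0, apply(steps, 2L, cumsum))
  trajectory(matrix(pos, ncol = dim), dt = dt, id = id)
}

#' Simulate one trajectory by mode name
#'
#' Dispatcher over the four diffusion-mode engines of [diffusion_modes()].
#'
#' @param mode one of `"normal"`, `"anomalous"`, `"confined"`, `"directed"`.
#' @param ... passed to the engine (`n_points`, `dt`, `dim`, `D`, `seed`,
#'   `id`, and the mode-specific `alpha`, `radius` or `velocity`).
#' @return a [trajectory()].
#' @export
simulate_trajectory <- function(mode, ...) {
  switch(match.arg(mode, names(diffusion_modes())),
         normal = simulate_normal(...),
         anomalous = simulate_anomalous(...),
         confined = simulate_confined(...),
         directed = simulate_directed(...))
}

#' Generate a labelled synthetic trajectory set
#'
#' The training-data generator of the classification workflow: a balanced
#' set with `n_per_class` trajectories per diffusion mode, labelled by the
#' fixed mode-to-label map of [diffusion_modes()] (confined ->
#' subdiffusion, normal -> normal, directed -> superdiffusion, fractional
#' Brownian motion with `alpha != 1` -> anomalous).  Per-trajectory seeds
#' are drawn deterministically from the master seed, so two runs with the
#' same arguments are identical.
#'
#' Defaults define a clearly separated parameter regime at unit
#' diffusivity: strong confinement (`radius^2` far below the free-range
#' scale `2 D N dt`), persistent fBm (`alpha = 1.5`), and drift at Peclet
#' number ~16 (`|v|^2 N dt / (2 d D)`).
#'
#' @param n_per_class trajectories per mode (default 100).
#' @param n_points points per trajectory (default 250).
#' @param dt time step (default 1).
#' @param dim spatial dimension (default 2).
#' @param D diffusivity for every engine (default 1).
#' @param alpha fBm exponent for the anomalous class (default 1.5).
#' @param radius confinement radius for the subdiffusive class (default 2).
#' @param velocity drift speed for the superdiffusive class (default 0.5).
#' @param seed master seed (default 1).
#' @return list with `trajectories` (list of [trajectory()]) and `labels`
#'   (character vector drawn from [diffusion_modes()]).
#' @export
generate_labeled_set <- function(n_per_class = 100, n_points = 250, dt = 1,
                                 dim = 2, D = 1, alpha = 1.5, radius = 2,
                                 velocity = 0.5, seed = 1) {
  if (n_per_class < 1L) stop("'n_per_class' must be >= 1")
  modes <- names(diffusion_modes())
  seeds <- with_seed(seed,
                     sample.int(2147483646L, n_per_class * length(modes)))
  trajs <- vector("list", n_per_class * length(modes))
  labels <- character(length(trajs))
  k <- 0L
  for (mode in modes) {
    for (i in seq_len(n_per_class)) {
      k <- k + 1L
      id <- sprintf("%s_%03d", mode, i)
      trajs[[k]] <- switch(mode,
        confined = simulate_confined(n_points, dt, dim, D, radius = radius,
                                     seed = seeds[k], id = id),
        normal = simulate_normal(n_points, dt, dim, D, seed = seeds[k],
                                 id = id),
        directed = simulate_directed(n_points, dt, dim, D,
                                     velocity = velocity, seed = seeds[k],
                                     id = id),
        anomalous = simulate_anomalous(n_points, dt, dim, D, alpha = alpha,
                                       seed = seeds[k], id = id))
      labels[k] <- unname(diffusion_modes()[mode])
    }
  }
  list(trajectories = trajs, labels = labels)
}
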