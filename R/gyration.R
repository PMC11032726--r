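#' Gyration tensor of a trajectory
#'
#' The covariance matrix of the visited positions,
#' \deqn{T_{ab} = \frac{1}{N} \sum_i (x_{i,a} - \bar x_a)(x_{i,b} - \bar x_b),}
#' whose eigenvalues \eqn{\lambda_1 \ge \dots \ge \lambda_d \ge 0} describe
#' the spatial extent and shape of the trajectory's footprint.  Eigenvectors
#' follow a fixed sign convention (first non-negligible component positive)
#' so results are reproducible across platforms.
#'
#' @param traj a [trajectory()].
#' @return object of class `"gyration_spectrum"`: list with `tensor`
#'   (d x d, length^2), `values` (eigenvalues, descending) and `vectors`
#'   (orthonormal columns).
#' @export
gyration_tensor <- function(traj) {
  p <- traj$positions
  centred <- sweep(p, 2L, colMeans(p))
  tensor <- crossprod(centred) / nrow(p)
  eig <- eigen(tensor, symmetric = TRUE)
  vec <- eig$vectors
  for (j in seq_len(ncol(vec))) {
    nz <- which(abs(vec[, j]) > 1e-12)
    if (length(nz) && vec[nz[1L], j] < 0) vec[, j] <- -vec[, j]
  }
  structure(list(tensor = tensor,
                 values = pmax(eig$values, 0),
                 vectors = vec),
            class = "gyration_spectrum")
}

#' @export
print.gyration_spectrum <- function(x, ...) {
  cat(sprintf("<gyration_spectrum: d = %d, eigenvalues = %s, Rg = %.4g>\n",
              length(x$values),
              paste(signif(x$values, 4), collapse = ", "),
              gyration_radius(x)))
  invisible(x)
}

as_gyration <- function(x) {
  if (inherits(x, "gyration_spectrum")) x
  else if (inherits(x, "trajectory")) gyration_tensor(x)
  else stop("expected a trajectory or gyration_spectrum")
}

#' Radius of gyration
#'
#' \eqn{R_g = \sqrt{\sum_i \lambda_i}}: the root of the trace of the
#' gyration tensor, i.e. the RMS distance of the points from their centroid.
#'
#' @param x a [trajectory()] or a [gyration_tensor()] spectrum.
#' @return the radius of gyration (length units), >= 0.
#' @export
gyration_radius <- function(x) {
  sqrt(sum(as_gyration(x)$values))
}

#' Gyration asymmetry
#'
#' Elongation of the trajectory cloud from the top two eigenvalues:
#' \deqn{a = -\ln\!\left(1 - \frac{(\lambda_1-\lambda_2)^2}
#'   {2(\lambda_1+\lambda_2)^2}\right).}
#' Zero for an isotropic footprint, \eqn{-\ln(1/2) \approx 0.693} in the
#' collinear limit.  In 3-D the planar definition is applied to
#' \eqn{(\lambda_1, \lambda_2)}.
#'
#' @inheritParams gyration_radius
#' @return the asymmetry, >= 0.
#' @export
asymmetry <- function(x) {
  s <- as_gyration(x)
  l1 <- s$values[1L]
  l2 <- if (length(s$values) >= 2L) s$values[2L] else 0
  if (l1 + l2 <= 0) stop("all-zero gyration spectrum; asymmetry undefined")
  -log(1 - (l1 - l2)^2 / (2 * (l1 + l2)^2))
}

#' Gyration anisotropy
#'
#' Bounded shape descriptor \eqn{\kappa^2 \in [0, 1]}: 0 for an isotropic
#' footprint, 1 for a collinear one.  In 2-D
#' \eqn{\kappa^2 = (\lambda_1-\lambda_2)^2/(\lambda_1+\lambda_2)^2}; in 3-D
#' \eqn{\kappa^2 = 1 - 3(\lambda_1\lambda_2 + \lambda_2\lambda_3 +
#' \lambda_3\lambda_1)/(\lambda_1+\lambda_2+\lambda_3)^2}.  A 1-D
#' trajectory is collinear by construction, so returns 1.
#'
#' @inheritParams gyration_radius
#' @return anisotropy in \[0, 1\].
#' @export
anisotropy <- function(x) {
  s <- as_gyration(x)
  l <- s$values
  if (sum(l) <= 0) stop("all-zero gyration spectrum; anisotropy undefined")
  if (length(l) == 1L) return(1)
  if (length(l) == 2L) return((l[1L] - l[2L])^2 / (l[1L] + l[2L])^2)
  1 - 3 * (l[1L] * l[2L] + l[2L] * l[3L] + l[3L] * l[1L]) / sum(l)^2
}

#' Kurtosis of the dominant projection
#'
#' Projects the positions onto the leading eigenvector of the gyration
#' tensor and returns the fourth standardized moment \eqn{m_4/m_2^2} of the
#' projected values: 3 for a Gaussian cloud, 1 for points alternating
#' between two values, large for heavy-tailed excursions.
#'
#' @param traj a [trajectory()].
#' @param spectrum optionally, a precomputed [gyration_tensor()] result.
#' @return the kurtosis (dimensionless).
#' @export
projection_kurtosis <- function(traj, spectrum = NULL) {
  if (is.null(spectrum)) spectrum <- gyration_tensor(traj)
  proj <- drop(traj$positions %*% spectrum$vectors[, 1L])
  proj <- proj - mean(proj)
  m2 <- mean(proj^2)
  if (m2 <= 0) stop("zero variance along the dominant axis; kurtosis undefined")
  mean(proj^4) / m2^2
}
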