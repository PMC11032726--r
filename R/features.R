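#' Compute the full 17-descriptor feature vector
#'
#' Runs every descriptor in the package on one trajectory and returns the
#' named vector of [feature_names()] (alphabetical, fixed order — the
#' stable column contract for feature tables).  Besides the individual
#' descriptors, three summary entries are derived from the MSD and VACF:
#' `msd_slope_diffusivity` \eqn{= MSD(\Delta t)/(2 d \Delta t)} (the
#' classical short-lag slope estimate of the diffusion coefficient),
#' `vacf_first_lag` (the normalized VACF at lag \eqn{\Delta t}) and
#' `msd_at_quarter_lag` (the time-averaged MSD at lag index
#' \eqn{\lfloor n_{max}/2 \rfloor} with \eqn{n_{max} = \lfloor N/4
#' \rfloor}, i.e. around one eighth of the trajectory duration).
#'
#' Any failure in a constituent descriptor (e.g. the log-log exponent fit
#' on a constant trajectory) is re-raised with the feature name attached,
#' so batch callers can report which feature failed.
#'
#' @param traj a [trajectory()] with uniform time step and N >= 16 (needed
#'   for a 3-point exponent fit at the default lag cutoff N/4).
#' @return named numeric vector with exactly 17 entries.
#' @examples
#' tr <- simulate_normal(n_points = 128, seed = 1)
#' round(trajectory_features(tr), 3)
#' @export
trajectory_features <- function(traj) {
  if (!inherits(traj, "trajectory")) stop("'traj' must be a trajectory")
  n <- n_points(traj)
  if (n < 16L)
    stop("feature extraction needs at least 16 points (got ", n,
         "): the exponent fit requires >= 3 lags below N/4")
  d <- n_dims(traj)
  dt <- traj_dt(traj)
  feat <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(name, ": ", conditionMessage(e), call. = FALSE))
  }
  msd <- feat("msd", msd_time_averaged(traj))
  gyr <- feat("gyration", gyration_tensor(traj))
  cv <- feat("vacf_first_lag", vacf(traj, normalize = TRUE))
  n_quarter <- max(1L, length(msd$lags) %/% 2L)
  out <- c(
    alpha                 = feat("alpha", anomalous_exponent(msd)),
    anisotropy            = feat("anisotropy", anisotropy(gyr)),
    asymmetry             = feat("asymmetry", asymmetry(gyr)),
    d_greenkubo           = feat("d_greenkubo", green_kubo_diffusivity(traj)),
    dominant_frequency    = feat("dominant_frequency", dominant_frequency(traj)),
    efficiency            = feat("efficiency", efficiency(traj)),
    fractal_dim           = feat("fractal_dim", fractal_dimension(traj)),
    gaussianity           = feat("gaussianity", gaussianity(traj)),
    gyration_radius       = feat("gyration_radius", gyration_radius(gyr)),
    kurtosis              = feat("kurtosis", projection_kurtosis(traj, gyr)),
    mean_speed            = feat("mean_speed", mean_speed(traj)),
    msd_at_quarter_lag    = msd$values[n_quarter],
    msd_ratio             = feat("msd_ratio", msd_ratio(msd)),
    msd_slope_diffusivity = msd$values[1L] / (2 * d * msd$lags[1L]),
    straightness          = feat("straightness", straightness(traj)),
    trappedness           = feat("trappedness", trappedness(traj, msd)),
    vacf_first_lag        = cv$values[2L]
  )
  stopifnot(identical(names(out), feature_names()))
  out
}
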