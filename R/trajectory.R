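#' Construct a trajectory
#'
#' A trajectory is an ordered sequence of positions \eqn{x_n} sampled at
#' strictly increasing times \eqn{t_n}.  It is the universal input object of
#' the package: every descriptor, simulator and pipeline step consumes or
#' produces trajectories.
#'
#' Geometric descriptors (straightness, gyration tensor, fractal dimension,
#' ...) accept arbitrary strictly increasing time grids.  Kinematic
#' descriptors based on lag averaging (MSD, VACF, Fourier spectrum) require a
#' uniform time step and raise an error otherwise; see [traj_dt()].
#'
#' @param positions numeric vector (1-D) or N x d matrix, d in 1..3, in
#'   length units.  Row i is the position at `times[i]`.
#' @param times numeric vector of length N, strictly increasing, in time
#'   units.  Defaults to `0, dt, 2*dt, ...`.
#' @param dt time step used to build `times` when `times` is `NULL`.
#' @param id optional text label carried through feature tables.
#' @return An object of class `"trajectory"`: a list with elements `times`
#'   (length N), `positions` (N x d matrix) and `id`.
#' @examples
#' tr <- trajectory(cbind(0:9, (0:9)^2))
#' tr
#' @seealso [read_trajectory_csv()], [trajectory_features()]
#' @export
trajectory <- function(positions, times = NULL, dt = 1, id = NULL) {
  if (is.null(dim(positions))) positions <- matrix(positions, ncol = 1L)
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  n <- nrow(positions)
  d <- ncol(positions)
  if (n < 2L) stop("a trajectory needs at least 2 points, got ", n)
  if (d < 1L || d > 3L) stop("spatial dimension must be 1, 2 or 3, got ", d)
  if (anyNA(positions) || any(!is.finite(positions)))
    stop("positions contain missing or non-finite values (imputation is not supported)")
  if (is.null(times)) {
    if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
      stop("'dt' must be a single positive number")
    times <- seq(0, by = dt, length.out = n)
  }
  times <- as.numeric(times)
  if (length(times) != n)
    stop("'times' has length ", length(times), " but there are ", n, " positions")
  if (anyNA(times) || any(!is.finite(times)))
    stop("times contain missing or non-finite values")
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing")
  structure(list(times = times, positions = positions,
                 id = if (is.null(id)) NULL else as.character(id)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory%s: %d points, %d-D, t in [%g, %g]>\n",
              if (is.null(x$id)) "" else paste0(" ", x$id),
              n_points(x), n_dims(x), x$times[1L], x$times[n_points(x)]))
  invisible(x)
}

#' Trajectory dimensions
#'
#' @param traj a [trajectory()].
#' @return `n_points()` the number N of sampled points; `n_dims()` the
#'   spatial dimension d.
#' @export
n_points <- function(traj) nrow(traj$positions)

#' @rdname n_points
#' @export
n_dims <- function(traj) ncol(traj$positions)

#' Uniform time step of a trajectory
#'
#' Lag-based descriptors (MSD by lag, VACF, Fourier spectrum) are only
#' defined on a uniform time grid.  `traj_dt()` returns the common step and
#' fails loudly on irregular grids; `has_uniform_dt()` is the predicate.
#'
#' @param traj a [trajectory()].
#' @param rel_tol relative tolerance on the spread of successive time
#'   differences (default 1e-9).
#' @return the scalar time step.
#' @export
traj_dt <- function(traj, rel_tol = 1e-9) {
  dts <- diff(traj$times)
  m <- mean(dts)
  if ((max(dts) - min(dts)) > rel_tol * abs(m))
    stop("trajectory is not uniformly sampled in time; ",
         "lag-based descriptors require a constant time step")
  m
}

#' @rdname traj_dt
#' @export
has_uniform_dt <- function(traj, rel_tol = 1e-9) {
  dts <- diff(traj$times)
  (max(dts) - min(dts)) <= rel_tol * abs(mean(dts))
}

#' @export
plot.trajectory <- function(x, ...) {
  p <- x$positions
  if (ncol(p) == 1L) {
    graphics::plot(x$times, p[, 1L], type = "l", xlab = "time",
                   ylab = "position", main = x$id, ...)
  } else {
    graphics::plot(p[, 1L], p[, 2L], type = "l", asp = 1, xlab = "x",
                   ylab = "y", main = x$id, ...)
    graphics::points(p[1L, 1L], p[1L, 2L], pch = 16)
  }
  invisible(x)
}

## ---- CSV I/O ---------------------------------------------------------------

#' Read a trajectory from a CSV file
#'
#' Expects a header row with one time column and 1-3 coordinate columns.
#' Default column names are `t` for time and (in order) `x`, `y`, `z` for
#' the coordinates; any other dialect is handled by naming the columns
#' explicitly.
#'
#' @param path path to a CSV file (comma separator, `.` decimal).
#' @param time_col name of the time column (default `"t"`).
#' @param coord_cols character vector of coordinate column names in axis
#'   order, or `NULL` to use whichever of `x`, `y`, `z` are present.
#' @param id optional trajectory label; defaults to the file name.
#' @return a [trajectory()].
#' @export
read_trajectory_csv <- function(path, time_col = "t", coord_cols = NULL,
                                id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, header = TRUE, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  nms <- names(raw)
  if (anyDuplicated(nms))
    stop("duplicate column names in ", path, ": ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  if (!time_col %in% nms)
    stop("time column '", time_col, "' not found in ", path,
         " (columns: ", paste(nms, collapse = ", "), ")")
  if (is.null(coord_cols)) {
    coord_cols <- intersect(c("x", "y", "z"), nms)
    if (length(coord_cols) == 0L)
      stop("no coordinate columns found in ", path,
           "; expected some of x, y, z or an explicit 'coord_cols'")
  } else if (!all(coord_cols %in% nms)) {
    stop("coordinate column(s) not found in ", path, ": ",
         paste(setdiff(coord_cols, nms), collapse = ", "))
  }
  as_num <- function(col, what) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop("non-numeric value in column '", col, "' at data row ", bad[1L],
           " of ", path)
    v
  }
  times <- as_num(time_col)
  pos <- vapply(coord_cols, as_num, numeric(nrow(raw)))
  if (nrow(raw) < 2L)
    stop("degenerate trajectory in ", path, ": fewer than 2 rows")
  trajectory(matrix(pos, ncol = length(coord_cols),
                    dimnames = list(NULL, coord_cols)),
             times = times,
             id = if (is.null(id)) basename(path) else id)
}

#' Write a trajectory to CSV
#'
#' Columns are `t` then `x`(, `y`, `z`) so the file round-trips through
#' [read_trajectory_csv()] with the default dialect.
#'
#' @param traj a [trajectory()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  d <- n_dims(traj)
  df <- data.frame(t = traj$times, traj$positions)
  names(df) <- c("t", c("x", "y", "z")[seq_len(d)])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## ---- LAMMPS-style YAML dumps ----------------------------------------------

#' Read trajectories from a LAMMPS-style YAML dump
#'
#' Parses a stream of per-timestep YAML documents of the minimal form
#' produced by `dump ... yaml` in molecular-dynamics codes:
#' ```
#' ---
#' timestep: 0
#' keywords: [id, x, y]
#' data:
#'   - [1, 0.0, 0.0]
#'   - [2, 1.0, 0.5]
#' ...
#' ```
#' One trajectory is built per particle id, with frames ordered by timestep
#' and the timestep number used as the time coordinate.  Particles missing
#' from any frame are dropped with a warning.  Coordinates are taken as-is
#' (no periodic-image unwrapping).
#'
#' @param path path to the YAML dump.
#' @return named list of [trajectory()] objects, one per particle id.
#' @export
read_lammps_yaml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  sep <- grepl("^---\\s*$", lines) | grepl("^\\.\\.\\.\\s*$", lines)
  grp <- cumsum(grepl("^---\\s*$", lines))
  docs <- split(lines[!sep], grp[!sep])
  docs <- Filter(function(x) any(nzchar(trimws(x))), docs)
  if (length(docs) == 0L) stop("no YAML documents found in ", path)
  frames <- lapply(docs, function(txt) {
    doc <- tryCatch(yaml::yaml.load(paste(txt, collapse = "\n")),
                    error = function(e)
                      stop("malformed YAML in ", path, ": ",
                           conditionMessage(e), call. = FALSE))
    if (is.null(doc$timestep) || is.null(doc$keywords) || is.null(doc$data))
      stop("frame in ", path,
           " lacks required keys (timestep, keywords, data)")
    kw <- as.character(unlist(doc$keywords))
    if (!"id" %in% kw) stop("frame in ", path, " has no 'id' keyword")
    coord_kw <- setdiff(kw, "id")
    if (length(coord_kw) < 1L || length(coord_kw) > 3L)
      stop("frame in ", path, " must carry 1-3 coordinate columns, got ",
           length(coord_kw))
    rows <- doc$data
    mat <- do.call(rbind, lapply(rows, function(r) as.numeric(unlist(r))))
    if (ncol(mat) != length(kw))
      stop("data row width does not match keywords in ", path)
    colnames(mat) <- kw
    list(timestep = as.numeric(doc$timestep), coords = coord_kw, mat = mat)
  })
  coord_sets <- unique(lapply(frames, `[[`, "coords"))
  if (length(coord_sets) != 1L)
    stop("inconsistent coordinate columns across frames in ", path)
  coords <- coord_sets[[1L]]
  ord <- order(vapply(frames, `[[`, numeric(1), "timestep"))
  frames <- frames[ord]
  ids_per_frame <- lapply(frames, function(f) f$mat[, "id"])
  keep <- Reduce(intersect, ids_per_frame)
  all_ids <- sort(unique(unlist(ids_per_frame)))
  dropped <- setdiff(all_ids, keep)
  if (length(dropped))
    warning("dropping particle id(s) missing from some frames: ",
            paste(dropped, collapse = ", "))
  if (length(keep) == 0L) stop("no particle id present in every frame of ", path)
  times <- vapply(frames, `[[`, numeric(1), "timestep")
  out <- lapply(sort(keep), function(pid) {
    pos <- t(vapply(frames, function(f) {
      f$mat[match(pid, f$mat[, "id"]), coords]
    }, numeric(length(coords))))
    colnames(pos) <- coords
    trajectory(pos, times = times, id = paste0("particle_", format(pid)))
  })
  names(out) <- paste0("particle_", format(sort(keep)))
  out
}

## ---- feature tables --------------------------------------------------------

#' The canonical feature names
#'
#' The fixed, alphabetically ordered set of 17 descriptor names produced by
#' [trajectory_features()] and expected in every feature table.  The names
#' are the public contract of the package:
#'
#' | name | meaning | units |
#' |---|---|---|
#' | `alpha` | anomalous diffusion exponent (MSD ~ lag^alpha) | - |
#' | `anisotropy` | gyration anisotropy \eqn{\kappa^2} in \[0,1\] | - |
#' | `asymmetry` | gyration asymmetry (log form), >= 0 | - |
#' | `d_greenkubo` | Green-Kubo diffusivity from the VACF integral | length^2/time |
#' | `dominant_frequency` | dominant nonzero Fourier frequency | 1/time |
#' | `efficiency` | squared net displacement / (N-1) sum squared steps | - |
#' | `fractal_dim` | Katz fractal dimension of the path | - |
#' | `gaussianity` | excess of 4th displacement moment vs Gaussian | - |
#' | `gyration_radius` | radius of gyration | length |
#' | `kurtosis` | 4th standardized moment of the dominant projection | - |
#' | `mean_speed` | mean finite-difference speed | length/time |
#' | `msd_at_quarter_lag` | time-averaged MSD at lag floor(n_max/2) | length^2 |
#' | `msd_ratio` | MSD(n1)/MSD(n2) - n1/n2 | - |
#' | `msd_slope_diffusivity` | MSD(dt)/(2 d dt) | length^2/time |
#' | `straightness` | net displacement / path length | - |
#' | `trappedness` | confinement probability score in \[0,1\] | - |
#' | `vacf_first_lag` | normalized velocity autocorrelation at lag dt | - |
#'
#' @return character vector of length 17.
#' @export
feature_names <- function() {
  c("alpha", "anisotropy", "asymmetry", "d_greenkubo", "dominant_frequency",
    "efficiency", "fractal_dim", "gaussianity", "gyration_radius",
    "kurtosis", "mean_speed", "msd_at_quarter_lag", "msd_ratio",
    "msd_slope_diffusivity", "straightness", "trappedness",
    "vacf_first_lag")
}

#' Diffusion-mode label vocabulary
#'
#' The four class labels and their generating simulation engines: confined
#' motion is the sub-diffusive generator, free Brownian motion the normal
#' one, drift plus noise the super-diffusive one, and fractional Brownian
#' motion (Hurst exponent away from 1/2) the anomalous one.
#'
#' @return named character vector mapping mode (`confined`, `normal`,
#'   `directed`, `anomalous`) to label (`subdiffusion`, `normal`,
#'   `superdiffusion`, `anomalous`).
#' @export
diffusion_modes <- function() {
  c(confined = "subdiffusion", normal = "normal",
    directed = "superdiffusion", anomalous = "anomalous")
}

validate_feature_table <- function(table) {
  if (!is.data.frame(table) || nrow(table) == 0L)
    stop("feature table must be a non-empty data frame")
  missing <- setdiff(feature_names(), names(table))
  if (length(missing))
    stop("feature table lacks required feature column(s): ",
         paste(missing, collapse = ", "))
  if ("label" %in% names(table)) {
    lab <- table$label
    if (anyNA(lab))
      stop("labels must be present for all rows or absent entirely")
    bad <- setdiff(unique(as.character(lab)), unname(diffusion_modes()))
    if (length(bad))
      stop("unknown label(s): ", paste(bad, collapse = ", "),
           "; allowed: ", paste(diffusion_modes(), collapse = ", "))
  }
  invisible(table)
}

#' Write / read a feature table
#'
#' A feature table has one row per trajectory with columns `id`, the 17
#' feature names of [feature_names()], and optionally `label` (all rows
#' labelled or none).  Values are written in full precision so the file
#' round-trips through `read_feature_table()`.
#'
#' @param table data frame as produced by [build_feature_table()].
#' @param path CSV file path.
#' @return `write_feature_table()` returns `path` invisibly;
#'   `read_feature_table()` returns the data frame.
#' @export
write_feature_table <- function(table, path) {
  validate_feature_table(table)
  cols <- c("id", feature_names(), intersect("label", names(table)))
  if (!"id" %in% names(table)) table$id <- as.character(seq_len(nrow(table)))
  out <- table[, cols, drop = FALSE]
  for (f in feature_names()) out[[f]] <- sprintf("%.17g", out[[f]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                         stringsAsFactors = FALSE)
  for (f in feature_names())
    if (f %in% names(tab)) tab[[f]] <- as.numeric(tab[[f]])
  validate_feature_table(tab)
  tab
}
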