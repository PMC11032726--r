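test_that("trajectory constructor enforces the data-model invariants", {
  tr <- trajectory(cbind(0:3, c(0, 1, 4, 9)), dt = 0.5, id = "p1")
  expect_s3_class(tr, "trajectory")
  expect_equal(n_points(tr), 4L)
  expect_equal(n_dims(tr), 2L)
  expect_equal(tr$times, c(0, 0.5, 1, 1.5))
  expect_equal(tr$id, "p1")

  expect_error(trajectory(1), "at least 2 points")
  expect_error(trajectory(matrix(1, 2, 4)), "dimension must be 1, 2 or 3")
  expect_error(trajectory(c(0, NA, 2)), "missing")
  expect_error(trajectory(0:2, times = c(0, 0, 1)), "strictly increasing")
  expect_error(trajectory(0:2, times = c(2, 1, 0)), "strictly increasing")
  expect_error(trajectory(0:2, times = c(0, 1)), "length")
})

test_that("uniform time-step detection respects the relative tolerance", {
  expect_equal(traj_dt(trajectory(0:9, dt = 0.1)), 0.1)
  irregular <- trajectory(0:3, times = c(0, 1, 2, 3.5))
  expect_false(has_uniform_dt(irregular))
  expect_error(traj_dt(irregular), "not uniformly sampled")
  # tiny jitter below 1e-9 relative spread passes
  jitter <- trajectory(0:2, times = c(0, 1, 2 + 2e-10))
  expect_true(has_uniform_dt(jitter))
})

test_that("read_trajectory_csv handles the default and mapped dialects", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t,x", "0,0", "1,1", "2,2"), p)
  tr <- read_trajectory_csv(p)
  expect_equal(tr$times, c(0, 1, 2))
  expect_equal(unname(tr$positions[, 1]), c(0, 1, 2))
  expect_equal(n_dims(tr), 1L)

  writeLines(c("t,x,y,z", "0,0,1,2", "1,1,2,3", "2,2,3,4", "3,3,4,5"), p)
  tr3 <- read_trajectory_csv(p)
  expect_equal(n_dims(tr3), 3L)
  expect_equal(n_points(tr3), 4L)

  # column-mapping config overrides the default names
  writeLines(c("frame,posx,posy", "0,0,0", "1,1,0.5"), p)
  trm <- read_trajectory_csv(p, time_col = "frame",
                             coord_cols = c("posx", "posy"))
  expect_equal(unname(trm$positions[2, ]), c(1, 0.5))
})

test_that("read_trajectory_csv rejects malformed input with located errors", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t,x", "0,0", "0,1"), p)
  expect_error(read_trajectory_csv(p), "strictly increasing")
  writeLines(c("time,x", "0,0", "1,1"), p)
  expect_error(read_trajectory_csv(p), "time column 't' not found")
  writeLines(c("t,x", "0,0", "1,abc", "2,2"), p)
  expect_error(read_trajectory_csv(p), "row 2")
  writeLines(c("t,x", "0,0"), p)
  expect_error(read_trajectory_csv(p), "fewer than 2 rows")
  expect_error(read_trajectory_csv(file.path(tempdir(), "nope.csv")),
               "file not found")
})

test_that("trajectory CSV write -> read round-trips to 1e-12", {
  p <- withr::local_tempfile(fileext = ".csv")
  set.seed(42)
  tr <- trajectory(matrix(rnorm(60), ncol = 3), dt = exp(1) / 7)
  write_trajectory_csv(tr, p)
  back <- read_trajectory_csv(p)
  expect_equal(back$times, tr$times, tolerance = 1e-12)
  expect_equal(unname(back$positions), unname(tr$positions),
               tolerance = 1e-12)
})

test_that("read_lammps_yaml builds one trajectory per persistent particle", {
  p <- withr::local_tempfile(fileext = ".yaml")
  write_lammps_fixture(p, list(
    list(timestep = 0, keywords = c("id", "x", "y"),
         rows = list(c(1, 0.0, 0.0), c(2, 1.0, 0.5))),
    list(timestep = 10, keywords = c("id", "x", "y"),
         rows = list(c(2, 1.5, 0.75), c(1, 0.25, -0.5)))))
  trajs <- read_lammps_yaml(p)
  expect_length(trajs, 2L)
  expect_equal(n_points(trajs[[1]]), 2L)
  expect_equal(trajs[[1]]$times, c(0, 10))
  # rows are matched by id, not file order
  expect_equal(unname(trajs[["particle_1"]]$positions[2, ]), c(0.25, -0.5))
  expect_equal(unname(trajs[["particle_2"]]$positions[1, ]), c(1.0, 0.5))
})

test_that("read_lammps_yaml drops transient particles and flags bad frames", {
  p <- withr::local_tempfile(fileext = ".yaml")
  write_lammps_fixture(p, list(
    list(timestep = 0, keywords = c("id", "x", "y"),
         rows = list(c(1, 0, 0), c(2, 1, 1))),
    list(timestep = 1, keywords = c("id", "x", "y"),
         rows = list(c(1, 0.5, 0.5)))))
  expect_warning(trajs <- read_lammps_yaml(p), "missing from some frames")
  expect_length(trajs, 1L)
  expect_equal(names(trajs), "particle_1")

  write_lammps_fixture(p, list(
    list(timestep = 0, keywords = c("id", "x", "y", "z"),
         rows = list(c(1, 0, 0, 0), c(2, 1, 1, 1))),
    list(timestep = 1, keywords = c("id", "x", "y"),
         rows = list(c(1, 0, 0), c(2, 1, 1)))))
  expect_error(read_lammps_yaml(p), "inconsistent coordinate columns")

  writeLines(c("---", "timestep: [unclosed"), p)
  expect_error(read_lammps_yaml(p), "malformed YAML|lacks required keys")
})

test_that("feature tables round-trip through CSV and validate labels", {
  sim <- generate_labeled_set(n_per_class = 1, n_points = 64, seed = 4)
  tab <- build_feature_table(sim)
  expect_equal(nrow(tab), 4L)

  p <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tab, p)
  back <- read_feature_table(p)
  expect_equal(nrow(back), 2L + 2L)
  for (f in feature_names())
    expect_equal(back[[f]], tab[[f]], tolerance = 1e-14, label = f)
  expect_equal(back$label, tab$label)

  # labels must be all-present or all-absent
  mixed <- tab
  mixed$label[2] <- NA
  expect_error(write_feature_table(mixed, p), "all rows")
  # unknown labels rejected
  bad <- tab
  bad$label[1] <- "ballistic"
  expect_error(write_feature_table(bad, p), "unknown label")
  expect_error(write_feature_table(tab[0, ], p), "non-empty")
  # unlabeled tables are fine
  unl <- tab
  unl$label <- NULL
  write_feature_table(unl, p)
  expect_false("label" %in% names(read_feature_table(p)))
})
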