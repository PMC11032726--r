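test_that("gyration tensor matches hand-computed spectra", {
  # repeated single point: zero tensor
  still <- gyration_tensor(trajectory(matrix(1, 5, 2)))
  expect_equal(still$values, c(0, 0))
  expect_equal(still$tensor, matrix(0, 2, 2), ignore_attr = TRUE)

  # two points (0,0), (2,0): T = [[1,0],[0,0]]
  two <- gyration_tensor(trajectory(rbind(c(0, 0), c(2, 0))))
  expect_equal(two$tensor, rbind(c(1, 0), c(0, 0)), ignore_attr = TRUE)
  expect_equal(two$values, c(1, 0))

  # unit-square corners: T = 0.25 I
  sq <- gyration_tensor(staple_path())
  expect_equal(sq$tensor, diag(0.25, 2), ignore_attr = TRUE)
  expect_equal(sq$values, c(0.25, 0.25))

  # spectrum invariants: PSD, trace identity, orthonormal eigenvectors
  set.seed(3)
  g <- gyration_tensor(trajectory(matrix(rnorm(90), ncol = 3)))
  expect_true(all(g$values >= 0))
  expect_true(all(diff(g$values) <= 0))
  expect_equal(sum(diag(g$tensor)), sum(g$values), tolerance = 1e-12)
  expect_equal(crossprod(g$vectors), diag(3), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("gyration radius, asymmetry and anisotropy match hand arithmetic", {
  two <- gyration_tensor(trajectory(rbind(c(0, 0), c(2, 0))))
  sq <- gyration_tensor(staple_path())

  expect_equal(gyration_radius(sq), sqrt(0.5), tolerance = 1e-12)
  expect_equal(gyration_radius(two), 1, tolerance = 1e-12)
  expect_equal(gyration_radius(trajectory(matrix(1, 5, 2))), 0)

  # isotropic: a = 0, kappa^2 = 0; collinear: a = log 2, kappa^2 = 1
  expect_equal(asymmetry(sq), 0, tolerance = 1e-12)
  expect_equal(anisotropy(sq), 0, tolerance = 1e-12)
  expect_equal(asymmetry(two), log(2), tolerance = 1e-12)
  expect_equal(anisotropy(two), 1, tolerance = 1e-12)

  # lambda = (3, 1)
  s31 <- structure(list(values = c(3, 1), vectors = diag(2),
                        tensor = diag(c(3, 1))),
                   class = "gyration_spectrum")
  expect_equal(asymmetry(s31), -log(1 - 4 / 32), tolerance = 1e-12)
  expect_equal(anisotropy(s31), 0.25, tolerance = 1e-12)

  # 3-D anisotropy: isotropic 0, collinear 1
  iso3 <- structure(list(values = c(2, 2, 2)), class = "gyration_spectrum")
  col3 <- structure(list(values = c(5, 0, 0)), class = "gyration_spectrum")
  expect_equal(anisotropy(iso3), 0, tolerance = 1e-12)
  expect_equal(anisotropy(col3), 1, tolerance = 1e-12)

  still <- gyration_tensor(trajectory(matrix(1, 5, 2)))
  expect_error(asymmetry(still), "all-zero")
  expect_error(anisotropy(still), "all-zero")
})

test_that("projection kurtosis: two-point, Gaussian and degenerate cases", {
  # alternating between two values: m4 = m2^2
  alt <- trajectory(rep(c(0, 1), 10), dt = 1)
  expect_equal(projection_kurtosis(alt), 1, tolerance = 1e-12)

  set.seed(123)
  gauss <- trajectory(rnorm(1e4), dt = 1)
  expect_equal(projection_kurtosis(gauss), 3, tolerance = 0.2 / 3)

  expect_error(projection_kurtosis(trajectory(matrix(2, 6, 2))),
               "zero variance")
})

test_that("Katz fractal dimension: line, staple and degenerate zigzag", {
  expect_equal(fractal_dimension(line_traj(20)), 1, tolerance = 1e-12)

  # (0,0)->(1,0)->(1,1)->(0,1): n=3, L=3, e=sqrt(2)
  expect_equal(fractal_dimension(staple_path()),
               log(3) / (log(3) + log(sqrt(2) / 3)), tolerance = 1e-12)

  # zigzag [0,1,0]: e/L = 1/n exactly -> +Inf sentinel
  expect_identical(fractal_dimension(trajectory(c(0, 1, 0))), Inf)

  expect_error(fractal_dimension(trajectory(rep(0, 5))), "zero path length")
})

test_that("straightness and efficiency match closed forms", {
  expect_equal(straightness(line_traj(25)), 1, tolerance = 1e-12)
  expect_equal(efficiency(line_traj(25)), 1, tolerance = 1e-12)

  loop <- trajectory(c(0, 1, 0))
  expect_equal(straightness(loop), 0)
  expect_equal(efficiency(loop), 0)

  expect_equal(straightness(l_path()), sqrt(2) / 2, tolerance = 1e-12)
  expect_equal(efficiency(l_path()), 0.5, tolerance = 1e-12)

  expect_error(straightness(trajectory(rep(1, 4))), "zero path length")
  expect_error(efficiency(trajectory(rep(1, 4))), "zero path length")
})

test_that("trappedness: clamp boundary, saturation and confinement ranking", {
  # argument exactly zero at x = c1/c2: P = 0 at the clamp boundary
  x0 <- 0.2048 / 0.25117
  expect_equal(trappedness_score(x0, 1, 1), 0)
  # saturation: P -> 1 as the argument grows
  expect_equal(trappedness_score(1e6, 1, 1), 1, tolerance = 1e-9)
  # below the boundary the raw score is negative -> clamped to 0
  expect_equal(trappedness_score(0, 1, 1), 0)
  expect_error(trappedness_score(1, 1, 0), "positive")

  # confined motion scores higher than directed motion at matched n
  conf <- vapply(1:10, function(s)
    trappedness(simulate_confined(200, radius = 1, D = 1, seed = s)),
    numeric(1))
  dir <- vapply(1:10, function(s)
    trappedness(simulate_directed(200, velocity = 1, D = 0.1, seed = s)),
    numeric(1))
  expect_gt(mean(conf), mean(dir))
  expect_true(all(conf >= 0 & conf <= 1))
  expect_true(all(dir >= 0 & dir <= 1))
})

test_that("gaussianity: constant-modulus, Brownian and degenerate cases", {
  # all lag-1 displacements of equal magnitude in 2-D: g = 1/2 - 1
  expect_equal(gaussianity(diag_traj(20)), -0.5, tolerance = 1e-12)

  # 1-D constant modulus: g = 1/3 - 1
  expect_equal(gaussianity(line_traj(20)), -2 / 3, tolerance = 1e-12)

  # Brownian displacements are Gaussian: <r^4> = 2 <r^2>^2 in 2-D
  expect_equal(gaussianity(simulate_normal(1e4, seed = 21)), 0,
               tolerance = 0.1)

  expect_error(gaussianity(trajectory(rep(0, 6))), "zero mean squared")
})
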