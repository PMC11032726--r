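test_that("simulators are deterministic in the seed and validate specs", {
  a <- simulate_normal(200, seed = 5)
  b <- simulate_normal(200, seed = 5)
  expect_identical(a$positions, b$positions)
  expect_false(identical(a$positions, simulate_normal(200, seed = 6)$positions))

  for (sim in list(function(s) simulate_anomalous(50, alpha = 0.7, seed = s),
                   function(s) simulate_confined(50, radius = 1, seed = s),
                   function(s) simulate_directed(50, velocity = 1, seed = s)))
    expect_identical(sim(9)$positions, sim(9)$positions)

  # seeding does not disturb the caller's RNG stream
  set.seed(1); before <- .Random.seed
  invisible(simulate_normal(50, seed = 123))
  expect_identical(.Random.seed, before)

  expect_error(simulate_normal(1), "n_points")
  expect_error(simulate_normal(10, dt = 0), "dt")
  expect_error(simulate_normal(10, D = 0), "diffusivity")
  expect_error(simulate_normal(10, dim = 4), "dim")
  expect_error(simulate_anomalous(10, alpha = 0), "alpha")
  expect_error(simulate_anomalous(10, alpha = 2.5), "alpha")
  expect_error(simulate_confined(10, radius = -1), "radius")
  expect_error(simulate_directed(10, velocity = 0), "zero drift")
  expect_error(simulate_trajectory("levy"), "arg")
})

test_that("Brownian steps have variance 2 D dt per dimension", {
  tr <- simulate_normal(1e4, D = 1, dt = 1, dim = 2, seed = 2)
  steps <- apply(tr$positions, 2, diff)
  expect_equal(var(steps[, 1]), 2, tolerance = 0.05)
  expect_equal(var(steps[, 2]), 2, tolerance = 0.05)
  expect_equal(mean(steps), 0, tolerance = 0.05)
  expect_equal(unname(tr$positions[1, ]), c(0, 0))

  # dt and D enter through the step variance
  tr2 <- simulate_normal(5e3, D = 0.25, dt = 2, dim = 1, seed = 3)
  expect_equal(var(diff(tr2$positions[, 1])), 2 * 0.25 * 2, tolerance = 0.1)
})

test_that("fBm generator hits the target law", {
  # alpha = 1 reduces to independent increments
  corr1 <- vapply(1:50, function(s) {
    v <- diff(simulate_anomalous(500, dim = 1, alpha = 1, seed = s)$positions[, 1])
    stats::cor(v[-length(v)], v[-1])
  }, numeric(1))
  expect_lt(abs(mean(corr1)), 0.05)

  # increment autocorrelation matches the fBm closed form 2^(alpha-1) - 1
  rho <- vapply(1:50, function(s) {
    v <- diff(simulate_anomalous(500, dim = 1, alpha = 1.5, seed = s)$positions[, 1])
    stats::cor(v[-length(v)], v[-1])
  }, numeric(1))
  expect_equal(mean(rho), 2^0.5 - 1, tolerance = 0.1)

  # ensemble variance at time t equals 2 D t^alpha per dimension
  xs <- vapply(1:400, function(s)
    simulate_anomalous(33, dim = 1, alpha = 0.5, D = 1, seed = s)$positions[33, 1],
    numeric(1))
  expect_equal(var(xs), 2 * 32^0.5, tolerance = 0.15)

  # alpha = 1 fBm and the Brownian engine give matching MSD(1) populations
  m_fbm <- vapply(1:50, function(s)
    msd_time_averaged(simulate_anomalous(250, alpha = 1, seed = s))$values[1],
    numeric(1))
  m_bm <- vapply(1:50, function(s)
    msd_time_averaged(simulate_normal(250, seed = 1000 + s))$values[1],
    numeric(1))
  expect_gt(stats::wilcox.test(m_fbm, m_bm)$p.value, 0.01)
})

test_that("confined walks stay inside the sphere and plateau", {
  tr <- simulate_confined(2000, radius = 2, D = 1, dim = 2, seed = 8)
  expect_true(all(sqrt(rowSums(tr$positions^2)) <= 2 + 1e-12))

  msd <- msd_time_averaged(tr)
  expect_lt(msd$values[length(msd$values)], 2 * 2^2 + 0.5)

  # 3-D stays confined too
  tr3 <- simulate_confined(500, radius = 1.5, D = 1, dim = 3, seed = 9)
  expect_true(all(sqrt(rowSums(tr3$positions^2)) <= 1.5 + 1e-12))
})

test_that("directed motion: ballistic limit and drift recovery", {
  # D -> 0: exact straight line
  pure <- simulate_directed(100, D = 0, velocity = 0.7, seed = 1)
  expect_equal(straightness(pure), 1, tolerance = 1e-12)
  expect_equal(unname(pure$positions[100, ]), c(99 * 0.7, 0),
               tolerance = 1e-10)

  # mean end-to-end displacement ~ v (N-1) dt
  ends <- vapply(1:100, function(s)
    simulate_directed(200, D = 1, velocity = 0.5, seed = s)$positions[200, 1],
    numeric(1))
  expected <- 0.5 * 199
  se <- sqrt(2 * 199 / 100)   # sd of the end point / sqrt(n_seeds)
  expect_lt(abs(mean(ends) - expected), 3 * se)
})

test_that("generate_labeled_set is balanced, labelled and reproducible", {
  set1 <- generate_labeled_set(n_per_class = 5, n_points = 40, seed = 11)
  expect_length(set1$trajectories, 20L)
  expect_equal(unname(table(set1$labels)[unname(diffusion_modes())]),
               rep(5L, 4), ignore_attr = TRUE)
  expect_setequal(unique(set1$labels), unname(diffusion_modes()))

  set2 <- generate_labeled_set(n_per_class = 5, n_points = 40, seed = 11)
  expect_identical(lapply(set1$trajectories, `[[`, "positions"),
                   lapply(set2$trajectories, `[[`, "positions"))

  # one spec per mode
  four <- generate_labeled_set(n_per_class = 1, n_points = 40, seed = 2)
  expect_length(four$trajectories, 4L)
  expect_identical(sort(unique(four$labels)), sort(unname(diffusion_modes())))
})
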