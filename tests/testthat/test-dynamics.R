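test_that("single angular and position updates match hand evaluation", {
  expect_identical(step_orientation(1.0, Dr = 0, dt = 0.1, 0.7), 1.0)
  expect_equal(step_orientation(0, Dr = 2, dt = 0.1, 0.3), 0.6,
               tolerance = 1e-12)
  p <- motility_params(alpha = 0.25, dt = 0.1)
  # pure advection along the heading
  expect_equal(step_position(pi / 2, p, 0, 0), c(0, 0.1), tolerance = 1e-12)
  # hand evaluation with noise
  expect_equal(step_position(0, p, 0.1, 0), c(0.125, 0), tolerance = 1e-12)
  # noise-free magnitude is (Fm/gamma_s) * dt at any heading
  p0 <- motility_params(alpha = 0, dt = 0.1)
  for (th in c(0, 0.3, 2, 5)) {
    expect_equal(sqrt(sum(step_position(th, p0, 0, 0)^2)), 0.1,
                 tolerance = 1e-12)
  }
})

test_that("closed-form increment magnitude agrees with the step norm", {
  expect_equal(increment_magnitude(1.3, 0, 0, alpha = 0.25, dt = 0.1), 0.1)
  expect_equal(increment_magnitude(0, 0.1, 0, alpha = 0.25, dt = 0.1), 0.125)
  # perfect cancellation: dt + alpha*dWx = 0.1 - 0.1
  expect_equal(increment_magnitude(0, -0.4, 0, alpha = 0.25, dt = 0.1), 0)
  # brute-force cross-validation against the norm of the step vector
  set.seed(31)
  th <- runif(1e4, -10, 10)
  wx <- rnorm(1e4); wy <- rnorm(1e4)
  p <- motility_params(alpha = 0.25, dt = 0.1)
  norms <- vapply(seq_len(1e4), function(i)
    sqrt(sum(step_position(th[i], p, wx[i], wy[i])^2)), numeric(1))
  expect_lt(max(abs(norms - increment_magnitude(th, wx, wy, 0.25, 0.1))),
            1e-12)
})

test_that("parameter validation rejects degenerate configurations", {
  expect_error(motility_params(n_steps = 0))
  expect_error(motility_params(dt = -0.1))
  expect_error(motility_params(alpha = -1))
  expect_error(motility_params(Fm = 0))
  expect_warning(motility_params(H = 0.3), "H < 0.5")
})

test_that("deterministic runs advect straight to the reference ring", {
  p <- motility_params(Dr = 0, alpha = 0)
  tr <- run_simulation(p, seed = 1, theta0 = 0.8)
  fin <- tr$positions[1001, ]
  expect_equal(sqrt(sum(fin^2)), 100, tolerance = 1e-9)
  # along the initial heading
  expect_equal(atan2(fin[2], fin[1]), 0.8, tolerance = 1e-12)
  expect_equal(unname(tr$thetas), rep(0.8, 1001))
  expect_equal(persistence_factor(tr), 1, tolerance = 1e-12)
  ang <- fbmigrate:::turning_angles(tr)
  expect_lt(max(ang), 1e-6)
})

test_that("with alpha = 0 every increment is (Fm/gamma_s)*dt at any Dr", {
  for (Dr in c(0, 0.1, 10)) {
    tr <- run_simulation(motility_params(Dr = Dr, alpha = 0), seed = 3)
    inc <- sqrt(rowSums(tr$step_vectors^2))
    expect_lt(max(abs(inc - 0.1)), 1e-12)
    expect_equal(trajectory_stats(tr)$total_distance, 100, tolerance = 1e-9)
  }
  # strong reorientation shrinks displacement but not path length
  s <- trajectory_stats(run_simulation(motility_params(Dr = 10, alpha = 0),
                                       seed = 4))
  expect_lt(s$displacement, 30)
  expect_equal(s$total_distance, 100, tolerance = 1e-9)
  # Fm/gamma_s != 1 is honored in full
  tr2 <- run_simulation(motility_params(Fm = 3, gamma_s = 2, Dr = 1,
                                        alpha = 0, n_steps = 100), seed = 5)
  expect_lt(max(abs(sqrt(rowSums(tr2$step_vectors^2)) - 0.15)), 1e-12)
})

test_that("trajectories are bit-reproducible and internally consistent", {
  p <- motility_params(Dr = 1, H = 0.75)
  a <- run_simulation(p, seed = 9)
  b <- run_simulation(p, seed = 9)
  expect_identical(a, b)
  expect_true(any(run_simulation(p, seed = 10)$positions != a$positions))
  # length consistency and origin seeding
  expect_identical(a$positions[1, ], c(0, 0))
  expect_identical(nrow(a$positions), 1001L)
  expect_identical(length(a$thetas), 1001L)
  expect_identical(nrow(a$step_vectors), 1000L)
  # positions accumulate the step vectors
  expect_equal(diff(a$positions), unname(a$step_vectors), tolerance = 1e-12)
})

test_that("heading variance follows the rotational diffusion law", {
  n_rep <- 400
  Dr <- 1
  T_end <- 20
  dth <- vapply(seq_len(n_rep), function(i) {
    tr <- run_simulation(motility_params(Dr = Dr, alpha = 0, n_steps = 200),
                         seed = 600 + i)
    tr$thetas[201] - tr$thetas[1]
  }, numeric(1))
  v <- var(dth)
  expected <- 2 * Dr * T_end
  se <- expected * sqrt(2 / (n_rep - 1))
  expect_lt(abs(v - expected), 4 * se)
})
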