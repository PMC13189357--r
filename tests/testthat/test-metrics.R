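test_that("persistence factor matches hand geometry and stays in [0, 1]", {
  expect_equal(persistence_factor(cbind(0:10, 0)), 1)
  out_back <- cbind(c(0:5, 4:0), 0)
  expect_equal(persistence_factor(out_back), 0)
  # L-path, two equal legs at a right angle: sqrt(2)L / 2L
  L <- 3
  expect_equal(persistence_factor(cbind(c(0, L, L), c(0, 0, L))),
               sqrt(2) / 2, tolerance = 1e-12)
  # single step: PF = 1 regardless of direction
  expect_equal(persistence_factor(cbind(c(0, -2), c(0, 5))), 1)
  # degenerate zero-length path: defined as 0, with a warning
  expect_warning(pf0 <- persistence_factor(matrix(0, 4, 2)), "zero total")
  expect_identical(pf0, 0)
  expect_error(persistence_factor(matrix(0, 1, 2)), "at least one step")
  # bound holds on arbitrary random walks
  for (pos in random_walk_positions(30, 200, seed = 1)) {
    pf <- persistence_factor(pos)
    expect_true(pf >= 0 && pf <= 1)
  }
})

test_that("relative turning angle matches the law-of-cosines worked cases", {
  expect_equal(relative_turning_angle(c(0, 0), c(1, 0), c(2, 0)), 0)
  expect_equal(relative_turning_angle(c(0, 0), c(1, 0), c(0, 0)), pi)
  expect_equal(relative_turning_angle(c(0, 0), c(1, 0), c(1, 1)), pi / 2,
               tolerance = 1e-12)
  expect_error(relative_turning_angle(c(0, 0), c(0, 0), c(1, 1)),
               "degenerate")
})

test_that("turning angle agrees with the direct step-vector angle oracle", {
  set.seed(17)
  pts <- matrix(rnorm(9e4), ncol = 9)
  direct <- vapply(seq_len(nrow(pts)), function(i) {
    s1 <- pts[i, 4:5] - pts[i, 1:2]
    s2 <- pts[i, 7:8] - pts[i, 4:5]
    acos(min(1, max(-1, sum(s1 * s2) / sqrt(sum(s1^2) * sum(s2^2)))))
  }, numeric(1))
  via_eq <- vapply(seq_len(nrow(pts)), function(i) {
    relative_turning_angle(pts[i, 1:2], pts[i, 4:5], pts[i, 7:8])
  }, numeric(1))
  expect_lt(max(abs(direct - via_eq)), 1e-9)
  expect_true(all(via_eq >= 0 & via_eq <= pi))
})

test_that("vectorised turning angles skip degenerate triples", {
  pos <- cbind(c(0, 1, 1, 2, 2), c(0, 0, 0, 0, 1))  # one repeated point
  ang <- fbmigrate:::turning_angles(pos)
  expect_identical(attr(ang, "skipped"), 2L)
  expect_length(ang, 1L)
})

test_that("trajectory summaries aggregate the per-step quantities", {
  tr <- run_simulation(motility_params(Dr = 0, alpha = 0), seed = 1)
  s <- trajectory_stats(tr)
  expect_equal(s$total_distance, 100, tolerance = 1e-9)
  expect_equal(s$displacement, 100, tolerance = 1e-9)
  expect_equal(s$pf, 1, tolerance = 1e-12)
  expect_equal(s$mean_increment, 0.1, tolerance = 1e-12)
  expect_equal(s$mean_rel_angle, 0, tolerance = 1e-6)
  expect_identical(s$initial_alignment, 0)
  # triangle inequality on stochastic runs
  for (i in 1:20) {
    ss <- trajectory_stats(
      run_simulation(motility_params(Dr = 1, H = 0.75, n_steps = 200),
                     seed = 40 + i))
    expect_lte(ss$displacement, ss$total_distance)
    expect_true(ss$pf >= 0 && ss$pf <= 1)
  }
})

test_that("initial alignment is the alpha-scaled cosine projection", {
  pos <- cbind(0:2, 0)
  # noise parallel / antiparallel / perpendicular to the heading
  expect_equal(initial_alignment(fake_trajectory(pos,
    noise = cbind(c(2, 0), c(0, 0)), theta0 = 0)), 0.25)
  expect_equal(initial_alignment(fake_trajectory(pos,
    noise = cbind(c(-2, 0), c(0, 0)), theta0 = 0)), -0.25)
  expect_equal(initial_alignment(fake_trajectory(pos,
    noise = cbind(c(0, 0), c(3, 0)), theta0 = 0)), 0, tolerance = 1e-12)
  # zero noise vector and alpha = 0 both give 0
  expect_identical(initial_alignment(fake_trajectory(pos)), 0)
  expect_identical(initial_alignment(fake_trajectory(pos,
    noise = cbind(c(1, 0), c(0, 0)), alpha = 0)), 0)
  # bounded in [-alpha, alpha] on simulated runs
  al <- vapply(1:30, function(i) initial_alignment(
    run_simulation(motility_params(Dr = 1, H = 0.99, n_steps = 50),
                   seed = 70 + i)), numeric(1))
  expect_true(all(abs(al) <= 0.25 + 1e-12))
})

test_that("ensemble MSD reduces to known closed forms", {
  dets <- run_ensemble(motility_params(Dr = 0, alpha = 0), 10, base_seed = 0)
  m <- ensemble_msd(dets)
  expect_identical(m$values[1], 0)
  expect_equal(m$values, m$times^2, tolerance = 1e-9)       # ballistic: t^2
  expect_equal(m$values[length(m$values)], 1e4, tolerance = 1e-6)
  # degenerate average over a single trajectory
  tr <- run_simulation(motility_params(Dr = 1, H = 0.5, n_steps = 100),
                       seed = 5)
  m1 <- ensemble_msd(list(tr), sample_size = 1)
  expect_equal(m1$values, rowSums(tr$positions^2), tolerance = 1e-12)
  # subsampling is seeded and mismatched grids are rejected
  sub <- ensemble_msd(dets, sample_size = 4, seed = 2)
  expect_identical(sub$replicate_ids,
                   ensemble_msd(dets, sample_size = 4, seed = 2)$replicate_ids)
  short <- run_simulation(motility_params(Dr = 0, alpha = 0, n_steps = 50),
                          seed = 1)
  expect_error(ensemble_msd(c(dets, list(short))), "time grid")
})

test_that("MSD exponent fitting recovers exact power laws", {
  tt <- seq(0, 100, by = 0.1)
  ballistic <- structure(list(times = tt, values = tt^2, sample_size = 1L,
                              replicate_ids = 1L), class = "msd_curve")
  diffusive <- structure(list(times = tt, values = 3.7 * tt, sample_size = 1L,
                              replicate_ids = 1L), class = "msd_curve")
  expect_equal(msd_scaling_exponent(ballistic), 2, tolerance = 1e-9)
  expect_equal(msd_scaling_exponent(diffusive), 1, tolerance = 1e-9)
  expect_equal(msd_scaling_exponent(diffusive, fit_window = c(1, 10)), 1,
               tolerance = 1e-9)
  expect_error(msd_scaling_exponent(ballistic, fit_window = c(99.85, 100)),
               "fewer than 3")
  expect_identical(classify_diffusion(2), "superdiffusive")
  expect_identical(classify_diffusion(1.02), "diffusive")
  expect_identical(classify_diffusion(0.6), "subdiffusive")
})
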