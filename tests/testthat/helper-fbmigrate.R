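# Shared fixtures, built in code.

# n_paths random-walk position paths (rows = successive positions), used as
# arbitrary trajectories for persistence-factor bounds.
random_walk_positions <- function(n_steps, n_paths, seed) {
  set.seed(seed)
  lapply(seq_len(n_paths), function(i) {
    apply(matrix(rnorm(2 * n_steps), n_steps, 2), 2, cumsum)
  })
}

# A minimal hand-built trajectory object with prescribed noise and heading,
# for exercising metrics on known geometry.
fake_trajectory <- function(positions, noise = NULL, theta0 = 0,
                            alpha = 0.25, dt = 0.1) {
  n <- nrow(positions) - 1L
  if (is.null(noise)) noise <- matrix(0, n, 2L)
  structure(
    list(times = seq(0, by = dt, length.out = n + 1L),
         positions = positions,
         thetas = rep(theta0, n + 1L),
         step_vectors = diff(positions),
         noise = noise,
         params = motility_params(alpha = alpha, dt = dt, n_steps = n),
         taxis = NULL, seed = NA_integer_, replicate_id = 1L),
    class = "cell_trajectory")
}

run_ensemble <- function(params, n_rep, base_seed, taxis = NULL) {
  lapply(seq_len(n_rep), function(i) {
    if (is.null(taxis)) {
      run_simulation(params, seed = base_seed + i, replicate_id = i)
    } else {
      run_taxis_simulation(params, taxis, seed = base_seed + i,
                           replicate_id = i)
    }
  })
}
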