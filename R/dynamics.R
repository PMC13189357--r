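#' Motility model parameters
#'
#' Bundles all scalar parameters of the single-cell equations of motion: a
#' self-propelled particle of motile force \code{Fm} along its heading,
#' opposed by substrate friction \code{gamma_s}, with correlated (fBm)
#' translational noise of magnitude \code{alpha} and Hurst index \code{H},
#' and rotational diffusion \code{Dr} acting on the heading angle. The
#' defaults reproduce the reference protocol: 1000 timesteps of size
#' \code{dt = 0.1} (100 time units), \code{Fm = gamma_s = 1},
#' \code{alpha = 0.25}, white angular noise (\code{Htheta = 0.5}), and noise
#' series initialised from N(0, \code{init_noise_var}).
#'
#' @param Fm motile force magnitude (> 0).
#' @param gamma_s substrate friction coefficient (> 0).
#' @param alpha translational noise magnitude (>= 0).
#' @param Dr rotational diffusion coefficient (>= 0).
#' @param H Hurst index of the translational noise, in (0, 1). Values below
#'   0.5 (anti-persistent) are allowed but flagged with a warning.
#' @param Htheta Hurst index of the angular noise; 0.5 (white noise) in all
#'   preset analyses.
#' @param dt timestep (> 0).
#' @param n_steps number of steps (>= 1).
#' @param init_noise_var how each noise series is initialised. \code{NULL}
#'   (default): the series is an exact fGn draw, whose first increment has
#'   the marginal law N(0, dt^(2H)) — at the reference protocol
#'   (\code{dt = 0.1}, \code{H = Htheta = 0.5}) that is exactly N(0, 0.1).
#'   A numeric value instead splices a N(0, \code{init_noise_var}) draw in as
#'   the first increment, with the remaining increments following the exact
#'   conditional fGn law given that value; for H near 1 this visibly inflates
#'   ensemble spread (see the methods vignette), so it is not the default.
#' @return An object of class \code{motility_params}.
#' @examples
#' motility_params(Dr = 1, H = 0.75)
#' @export
motility_params <- function(Fm = 1, gamma_s = 1, alpha = 0.25, Dr = 0,
                            H = 0.5, Htheta = 0.5, dt = 0.1,
                            n_steps = 1000L, init_noise_var = NULL) {
  stopifnot(is.numeric(Fm), length(Fm) == 1L, Fm > 0,
            is.numeric(gamma_s), length(gamma_s) == 1L, gamma_s > 0,
            is.numeric(alpha), length(alpha) == 1L, alpha >= 0,
            is.numeric(Dr), length(Dr) == 1L, Dr >= 0,
            is.numeric(dt), length(dt) == 1L, dt > 0,
            is.numeric(n_steps), length(n_steps) == 1L, n_steps >= 1,
            n_steps == round(n_steps),
            is.null(init_noise_var) ||
              (is.numeric(init_noise_var) && length(init_noise_var) == 1L &&
                 init_noise_var >= 0))
  check_hurst(H, warn_below_half = TRUE)
  check_hurst(Htheta)
  structure(
    list(Fm = Fm, gamma_s = gamma_s, alpha = alpha, Dr = Dr, H = H,
         Htheta = Htheta, dt = dt, n_steps = as.integer(n_steps),
         init_noise_var = init_noise_var),
    class = "motility_params")
}

#' @export
print.motility_params <- function(x, ...) {
  cat("Single-cell motility parameters\n")
  cat(sprintf("  Fm = %g, gamma_s = %g (speed %g)\n",
              x$Fm, x$gamma_s, x$Fm / x$gamma_s))
  cat(sprintf("  alpha = %g, H = %g | Dr = %g, Htheta = %g\n",
              x$alpha, x$H, x$Dr, x$Htheta))
  cat(sprintf("  dt = %g, n_steps = %d (horizon %g time units)\n",
              x$dt, x$n_steps, x$dt * x$n_steps))
  invisible(x)
}

#' Single angular update
#'
#' One Euler step of the orientation equation
#' \eqn{d\theta/dt = \sqrt{2 D_r}\, dW/dt}: the heading receives
#' \code{sqrt(2 * Dr) * angular_increment}, where the increment is a noise
#' increment over one timestep (variance \code{dt} for white angular noise).
#' \code{Dr = 0} leaves the heading unchanged.
#'
#' @param theta current heading (radians, unwrapped).
#' @param Dr rotational diffusion coefficient (>= 0).
#' @param dt timestep (unused in the update itself; kept for signature
#'   symmetry and validation).
#' @param angular_increment the stochastic increment for this step.
#' @return Updated heading in radians (never wrapped).
#' @export
step_orientation <- function(theta, Dr, dt, angular_increment) {
  stopifnot(Dr >= 0, dt > 0)
  theta + sqrt(2 * Dr) * angular_increment
}

#' Single position update
#'
#' One step of the equation of motion
#' \eqn{F_m \hat{p} = \gamma_s\, dx/dt - \alpha\, dW^H/dt}: the displacement
#' is \code{(Fm/gamma_s) * (cos(theta), sin(theta)) * dt +
#' (alpha/gamma_s) * (dWx, dWy)}. The heading must already be updated for
#' this step (the angular solution is fed into the equation of motion).
#'
#' @param theta heading for this step (radians).
#' @param params a \code{\link{motility_params}} object.
#' @param dWx,dWy translational noise increments for this step.
#' @return Length-2 displacement vector.
#' @seealso \code{\link{increment_magnitude}} for the closed-form magnitude
#'   under the \code{Fm = gamma_s = 1} convention.
#' @export
step_position <- function(theta, params, dWx, dWy) {
  with(params,
       (Fm / gamma_s) * c(cos(theta), sin(theta)) * dt +
         (alpha / gamma_s) * c(dWx, dWy))
}

#' Closed-form per-step displacement magnitude
#'
#' Magnitude of a single displacement under the \code{Fm = gamma_s = 1}
#' convention:
#' \deqn{|\Delta x| = \sqrt{\Delta t^2 + 2\alpha\Delta t(\cos\theta\,
#' \Delta W_x + \sin\theta\, \Delta W_y) + \alpha^2(\Delta W_x^2 +
#' \Delta W_y^2)}.}
#' Algebraically identical to the Euclidean norm of
#' \code{\link{step_position}} with unit force and friction; the radicand is
#' a perfect squared norm and cannot be negative.
#'
#' @param theta heading (radians). Vectorised with \code{dWx}, \code{dWy}.
#' @param dWx,dWy translational noise increments.
#' @param alpha noise magnitude (>= 0).
#' @param dt timestep (> 0).
#' @return Non-negative displacement magnitude(s).
#' @examples
#' increment_magnitude(0, 0.1, 0, alpha = 0.25, dt = 0.1)  # 0.125
#' @export
increment_magnitude <- function(theta, dWx, dWy, alpha, dt) {
  stopifnot(alpha >= 0, dt > 0)
  rad <- dt^2 + 2 * alpha * dt * (cos(theta) * dWx + sin(theta) * dWy) +
    alpha^2 * (dWx^2 + dWy^2)
  rad[rad < 0] <- 0  # roundoff guard; algebraically a perfect norm
  sqrt(rad)
}

# Per-replicate noise generation. One master seed spawns three independent
# substreams (noise-x, noise-y, angular) so replicates are reproducible and
# mutually independent. init_var = NULL: exact unconditional fGn (first
# increment has its marginal law N(0, dt^(2H))). Numeric init_var: a
# N(0, init_var) draw is spliced in as the first increment and the series
# continues with the exact conditional fGn law given that value.
generate_noise_series <- function(n, H, dt, seed, init_var = NULL) {
  set.seed(seed)
  if (is.null(init_var)) return(fbm_increments(n, H, dt)$values)
  first <- stats::rnorm(1L, sd = sqrt(init_var))
  fgn_conditional_on_first(n, H, dt, first)
}

# Shared simulation engine; taxis = NULL gives the unguided model. The
# unguided path (and f_tax = 0) is fully vectorised; with active guidance the
# heading update depends on the current position, so steps are sequential.
# Both paths accumulate positions by the same sequential additions, so
# f_tax = 0 reproduces the unguided trajectory bit for bit under one seed.
simulate_engine <- function(params, seed, theta0, taxis = NULL,
                            replicate_id = 1L) {
  p <- params
  n <- p$n_steps
  set.seed(seed)
  theta0_drawn <- if (identical(theta0, "random")) {
    stats::runif(1L, 0, 2 * pi)
  } else {
    stopifnot(is.numeric(theta0), length(theta0) == 1L, is.finite(theta0))
    theta0
  }
  sub <- sample.int(.Machine$integer.max - 1L, 3L)
  if (p$alpha > 0) {
    dWx <- generate_noise_series(n, p$H, p$dt, sub[1L], p$init_noise_var)
    dWy <- generate_noise_series(n, p$H, p$dt, sub[2L], p$init_noise_var)
  } else {
    dWx <- dWy <- numeric(n)
  }
  dtheta <- if (p$Dr > 0) {
    sqrt(2 * p$Dr) *
      generate_noise_series(n, p$Htheta, p$dt, sub[3L], p$init_noise_var)
  } else {
    numeric(n)
  }

  guided <- !is.null(taxis) && taxis$f_tax > 0
  speed <- p$Fm / p$gamma_s
  if (!guided) {
    theta <- theta0_drawn + cumsum(dtheta)
    sx <- speed * cos(theta) * p$dt + (p$alpha / p$gamma_s) * dWx
    sy <- speed * sin(theta) * p$dt + (p$alpha / p$gamma_s) * dWy
    pos <- cbind(c(0, cumsum(sx)), c(0, cumsum(sy)))
  } else {
    theta <- numeric(n)
    sx <- numeric(n)
    sy <- numeric(n)
    pos <- matrix(0, n + 1L, 2L)
    th <- theta0_drawn
    for (k in seq_len(n)) {
      th <- th + dtheta[k]
      th <- th + taxis_angular_term(pos[k, ], th, taxis) * p$dt
      theta[k] <- th
      sx[k] <- speed * cos(th) * p$dt + (p$alpha / p$gamma_s) * dWx[k]
      sy[k] <- speed * sin(th) * p$dt + (p$alpha / p$gamma_s) * dWy[k]
      pos[k + 1L, ] <- pos[k, ] + c(sx[k], sy[k])
    }
  }

  structure(
    list(times = seq(0, by = p$dt, length.out = n + 1L),
         positions = pos,
         thetas = c(theta0_drawn, theta),
         step_vectors = cbind(sx, sy, deparse.level = 0),
         noise = cbind(dWx, dWy, deparse.level = 0),
         params = p, taxis = taxis,
         seed = seed, replicate_id = as.integer(replicate_id)),
    class = "cell_trajectory")
}

#' Simulate one cell trajectory
#'
#' Integrates the coupled heading/position equations over the full horizon.
#' Per step: (1) the heading receives its stochastic angular increment;
#' (2) the pre-generated fBm translational increments for the step are
#' fetched; (3) the displacement is computed from the updated heading and the
#' noise; (4) the position is updated. The whole translational noise series
#' is synthesised up front (exact fBm synthesis is a whole-path operation)
#' and consumed stepwise. Cells start at the origin.
#'
#' @param params a \code{\link{motility_params}} object.
#' @param seed integer master seed; the run is bit-reproducible given
#'   identical arguments.
#' @param theta0 initial heading in radians, or \code{"random"} for a uniform
#'   draw on [0, 2*pi).
#' @param replicate_id integer label carried into summaries and CSV output.
#' @return An object of class \code{cell_trajectory}: list with \code{times}
#'   (length \code{n_steps + 1}), \code{positions} ((\code{n_steps + 1}) x 2,
#'   first row the origin), \code{thetas} (unwrapped headings),
#'   \code{step_vectors} (\code{n_steps} x 2), \code{noise} (the fBm
#'   increment pairs), \code{params}, \code{seed}, \code{replicate_id}.
#' @examples
#' p <- motility_params(Dr = 0, alpha = 0)
#' tr <- run_simulation(p, seed = 1)
#' sqrt(sum(tr$positions[1001, ]^2))  # 100: the deterministic reference ring
#' @export
run_simulation <- function(params, seed, theta0 = "random",
                           replicate_id = 1L) {
  stopifnot(inherits(params, "motility_params"))
  simulate_engine(params, seed, theta0, taxis = NULL,
                  replicate_id = replicate_id)
}

#' @export
print.cell_trajectory <- function(x, ...) {
  n <- x$params$n_steps
  fin <- x$positions[n + 1L, ]
  cat(sprintf("Cell trajectory: %d steps, dt = %g (T = %g)\n",
              n, x$params$dt, n * x$params$dt))
  cat(sprintf("  H = %g, Dr = %g, alpha = %g%s\n",
              x$params$H, x$params$Dr, x$params$alpha,
              if (!is.null(x$taxis)) sprintf(", f_tax = %g", x$taxis$f_tax)
              else ""))
  cat(sprintf("  final position (%.3f, %.3f), displacement %.3f\n",
              fin[1], fin[2], sqrt(sum(fin^2))))
  invisible(x)
}
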