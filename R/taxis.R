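#' Taxis (directional guidance) parameters
#'
#' A minimal guidance cue: a fixed organizing center exerts an angular
#' correction proportional to the angle between the cell's heading and the
#' direction toward the center. The default center sits at distance 100 from
#' the origin, on the reference ring traced by the deterministic model, in
#' the third quadrant: \code{x_org = (-100/sqrt(2), -100/sqrt(2))}.
#'
#' @param f_tax attraction strength (>= 0); the preset analyses use
#'   0.01, 0.1 and 1.
#' @param x_org length-2 position of the organizing center.
#' @return An object of class \code{taxis_params}.
#' @examples
#' taxis_params(f_tax = 0.1)
#' @export
taxis_params <- function(f_tax = 0.1,
                         x_org = c(-100 / sqrt(2), -100 / sqrt(2))) {
  stopifnot(is.numeric(f_tax), length(f_tax) == 1L, is.finite(f_tax),
            f_tax >= 0,
            is.numeric(x_org), length(x_org) == 2L, all(is.finite(x_org)))
  structure(list(f_tax = f_tax, x_org = as.numeric(x_org)),
            class = "taxis_params")
}

#' @export
print.taxis_params <- function(x, ...) {
  cat(sprintf("Taxis: f_tax = %g, organizing center (%.4f, %.4f), |x_org| = %.4f\n",
              x$f_tax, x$x_org[1], x$x_org[2], sqrt(sum(x$x_org^2))))
  invisible(x)
}

#' Angular guidance term
#'
#' Rate of heading correction toward the organizing center: magnitude
#' \code{f_tax * acos(v_org . p_hat / |v_org|)} (the unsigned angle between
#' the heading and the target direction \code{v_org = x_org - position}),
#' signed so that applying the term rotates the heading toward the target
#' (positive = counter-clockwise, via the planar cross/dot construction).
#' At the target itself no direction is defined and the term is 0; exact
#' anti-alignment is an unstable equilibrium and is left uncorrected.
#'
#' @param position current length-2 position.
#' @param theta current heading (radians).
#' @param taxis a \code{\link{taxis_params}} object.
#' @return Signed angular rate (radians per unit time).
#' @examples
#' tx <- taxis_params(f_tax = 1, x_org = c(100, 0))
#' taxis_angular_term(c(0, 0), 0, tx)        # aligned: 0
#' taxis_angular_term(c(0, 0), pi / 2, tx)   # perpendicular: -pi/2 (turn cw)
#' @export
taxis_angular_term <- function(position, theta, taxis) {
  v <- taxis$x_org - position
  if (v[1L] == 0 && v[2L] == 0) return(0)
  p <- c(cos(theta), sin(theta))
  nv <- sqrt(sum(v^2))
  cosang <- (v[1L] * p[1L] + v[2L] * p[2L]) / nv
  cosang <- min(1, max(-1, cosang))       # clamp against roundoff
  cross <- p[1L] * v[2L] - p[2L] * v[1L]  # >0: target counter-clockwise
  taxis$f_tax * acos(cosang) * sign(cross)
}

#' Simulate one guided cell trajectory
#'
#' Identical to \code{\link{run_simulation}} except that each heading update
#' adds the guidance correction \code{taxis_angular_term(...) * dt} after the
#' stochastic angular increment. The position update is unchanged, so with
#' \code{alpha = 0} the total distance traveled is unaffected by taxis.
#' With \code{f_tax = 0} the trajectory is bit-identical to the unguided
#' model under the same seed.
#'
#' @inheritParams run_simulation
#' @param taxis a \code{\link{taxis_params}} object.
#' @return A \code{cell_trajectory} (with the taxis parameters attached).
#' @examples
#' p <- motility_params(Dr = 0.1, alpha = 0)
#' tr <- run_taxis_simulation(p, taxis_params(f_tax = 1), seed = 1)
#' final_distance_to_target(tr)
#' @export
run_taxis_simulation <- function(params, taxis, seed, theta0 = "random",
                                 replicate_id = 1L) {
  stopifnot(inherits(params, "motility_params"),
            inherits(taxis, "taxis_params"))
  simulate_engine(params, seed, theta0, taxis = taxis,
                  replicate_id = replicate_id)
}

#' Final distance to the organizing center
#'
#' @param trajectory a \code{cell_trajectory} from
#'   \code{\link{run_taxis_simulation}} (or any trajectory, with an explicit
#'   \code{x_org}).
#' @param x_org target position; defaults to the trajectory's own taxis
#'   target.
#' @return Euclidean distance from the final position to \code{x_org}.
#' @export
final_distance_to_target <- function(trajectory, x_org = NULL) {
  stopifnot(inherits(trajectory, "cell_trajectory"))
  if (is.null(x_org)) {
    if (is.null(trajectory$taxis)) {
      stop("trajectory has no taxis target; supply 'x_org'", call. = FALSE)
    }
    x_org <- trajectory$taxis$x_org
  }
  fin <- trajectory$positions[nrow(trajectory$positions), ]
  sqrt(sum((fin - x_org)^2))
}
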