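positions_of <- function(trajectory) {
  if (inherits(trajectory, "cell_trajectory")) return(trajectory$positions)
  if (is.matrix(trajectory) && ncol(trajectory) == 2L) return(trajectory)
  stop("expected a 'cell_trajectory' or an (n+1) x 2 positions matrix",
       call. = FALSE)
}

#' Persistence factor
#'
#' Ratio of net displacement to total path length,
#' \deqn{PF = \frac{\|x_f - x_0\|}{\sum_i \|x_{i+1} - x_i\|},}
#' constrained to [0, 1]: 1 is a perfectly straight trajectory, values near 0
#' a space-filling wander. A path of zero total length has no defined
#' direction; PF is returned as 0 with a warning (this cannot arise under the
#' model, whose increments are positive almost surely, but arbitrary CSV
#' input must be handled).
#'
#' @param trajectory a \code{cell_trajectory} or an (n+1) x 2 positions
#'   matrix (rows = successive positions).
#' @return PF in [0, 1].
#' @examples
#' persistence_factor(cbind(0:10, 0))                 # straight: 1
#' persistence_factor(cbind(c(0, 1, 1), c(0, 0, 1)))  # L-path: sqrt(2)/2
#' @export
persistence_factor <- function(trajectory) {
  pos <- positions_of(trajectory)
  if (nrow(pos) < 2L) stop("trajectory needs at least one step", call. = FALSE)
  steps <- diff(pos)
  total <- sum(sqrt(rowSums(steps^2)))
  if (total == 0) {
    warning("zero total distance; persistence factor undefined, returning 0",
            call. = FALSE)
    return(0)
  }
  sqrt(sum((pos[nrow(pos), ] - pos[1L, ])^2)) / total
}

#' Relative turning angle
#'
#' Angle between successive step directions from three consecutive positions,
#' via the law of cosines:
#' \deqn{\theta_R = \pi - \arccos\!\big((a^2 + b^2 - c^2) / (2ab)\big)}
#' with \code{a = |x2 - x1|}, \code{b = |x3 - x2|}, \code{c = |x3 - x1|}.
#' Ranges over [0, pi]: 0 for collinear forward motion, pi for a direction
#' reversal. The arccos argument is clamped to [-1, 1] against roundoff.
#'
#' @param x1,x2,x3 length-2 positions of three consecutive points.
#' @return Angle in radians in [0, pi]; \code{NA} (with a warning suppressed
#'   at the caller's discretion) is never returned — degenerate triples with
#'   a repeated point (\code{a == 0} or \code{b == 0}) raise an error, so the
#'   caller may skip them.
#' @examples
#' relative_turning_angle(c(0, 0), c(1, 0), c(2, 0))  # 0
#' relative_turning_angle(c(0, 0), c(1, 0), c(0, 0))  # pi
#' relative_turning_angle(c(0, 0), c(1, 0), c(1, 1))  # pi/2
#' @export
relative_turning_angle <- function(x1, x2, x3) {
  a <- sqrt(sum((x2 - x1)^2))
  b <- sqrt(sum((x3 - x2)^2))
  if (a == 0 || b == 0) {
    stop("degenerate triple: repeated consecutive points", call. = FALSE)
  }
  cc <- sum((x3 - x1)^2)
  arg <- (a^2 + b^2 - cc) / (2 * a * b)
  pi - acos(min(1, max(-1, arg)))
}

# Vectorised turning angles over all consecutive triples of a path.
# Degenerate triples (zero-length step) are skipped; their count is attached.
turning_angles <- function(trajectory) {
  pos <- positions_of(trajectory)
  if (nrow(pos) < 3L) {
    return(structure(numeric(0), skipped = 0L))
  }
  s <- diff(pos)
  a2 <- rowSums(s^2)
  n <- nrow(s)
  a <- sqrt(a2[-n])
  b <- sqrt(a2[-1L])
  ok <- a > 0 & b > 0
  d13 <- pos[-(1:2), , drop = FALSE] - pos[seq_len(n - 1L), , drop = FALSE]
  cc <- rowSums(d13^2)
  arg <- (a2[-n] + a2[-1L] - cc) / (2 * a * b)
  arg <- pmin(1, pmax(-1, arg))
  structure(pi - acos(arg[ok]), skipped = sum(!ok))
}

#' Initial alignment of noise and heading
#'
#' Projection of the first translational-noise increment onto the initial
#' heading, scaled by the noise magnitude:
#' \code{alpha * cos(angle between (dWx[1], dWy[1]) and p_hat(theta0))},
#' bounded in [-alpha, alpha] by construction. With \code{alpha = 0} (or a
#' zero first noise vector) the alignment is 0.
#'
#' @param trajectory a \code{cell_trajectory}.
#' @return Alignment value in [-alpha, alpha].
#' @export
initial_alignment <- function(trajectory) {
  stopifnot(inherits(trajectory, "cell_trajectory"))
  alpha <- trajectory$params$alpha
  w <- trajectory$noise[1L, ]
  nw <- sqrt(sum(w^2))
  if (alpha == 0 || nw == 0) return(0)
  th0 <- trajectory$thetas[1L]
  alpha * (w[1L] * cos(th0) + w[2L] * sin(th0)) / nw
}

#' Per-trajectory summary statistics
#'
#' Aggregates the trajectory-level quantities of the analysis suite: total
#' distance traveled (sum of increments), net displacement, persistence
#' factor, mean increment magnitude, mean relative turning angle (over all
#' consecutive triples; degenerate triples skipped), initial alignment, and
#' the final position. For guided trajectories the final distance to the
#' organizing center is appended.
#'
#' @param trajectory a \code{cell_trajectory}.
#' @return One-row \code{data.frame} with columns \code{replicate},
#'   \code{total_distance}, \code{displacement}, \code{pf},
#'   \code{mean_increment}, \code{mean_rel_angle}, \code{initial_alignment},
#'   \code{final_x}, \code{final_y} and, when taxis is present,
#'   \code{final_distance_to_target}.
#' @examples
#' tr <- run_simulation(motility_params(Dr = 0, alpha = 0), seed = 1)
#' trajectory_stats(tr)
#' @export
trajectory_stats <- function(trajectory) {
  stopifnot(inherits(trajectory, "cell_trajectory"))
  pos <- trajectory$positions
  inc <- sqrt(rowSums(trajectory$step_vectors^2))
  ang <- turning_angles(trajectory)
  fin <- pos[nrow(pos), ]
  out <- data.frame(
    replicate = trajectory$replicate_id,
    total_distance = sum(inc),
    displacement = sqrt(sum((fin - pos[1L, ])^2)),
    pf = persistence_factor(trajectory),
    mean_increment = mean(inc),
    mean_rel_angle = if (length(ang)) mean(ang) else NA_real_,
    initial_alignment = initial_alignment(trajectory),
    final_x = fin[1L],
    final_y = fin[2L])
  if (!is.null(trajectory$taxis)) {
    out$final_distance_to_target <- final_distance_to_target(trajectory)
  }
  out
}

#' Ensemble mean squared displacement
#'
#' Ensemble (not time-averaged) MSD over a seeded random subsample of N
#' trajectories: \deqn{MSD(t) = \frac{1}{N}\sum_i \|x_i(t) - x_0\|^2,} with
#' all cells seeded at the origin (\code{x0 = 0}). Subsampling at N of 50,
#' 100 and 200 (25-100% of the reference ensemble) probes the stability of
#' the curve.
#'
#' @param trajectories list of \code{cell_trajectory} objects sharing one
#'   time grid.
#' @param sample_size number of trajectories to average (<= length of the
#'   list); \code{NULL} uses all of them.
#' @param seed integer seed for the subsample draw (ignored when all
#'   trajectories are used).
#' @return An object of class \code{msd_curve}: list with \code{times},
#'   \code{values} (\code{values[1] == 0} at t = 0), \code{sample_size} and
#'   \code{replicate_ids} (indices used).
#' @export
ensemble_msd <- function(trajectories, sample_size = NULL, seed = NULL) {
  stopifnot(is.list(trajectories), length(trajectories) >= 1L,
            all(vapply(trajectories, inherits, TRUE, "cell_trajectory")))
  times <- trajectories[[1L]]$times
  same <- vapply(trajectories, function(tr) {
    length(tr$times) == length(times) && all(tr$times == times)
  }, TRUE)
  if (!all(same)) stop("trajectories must share one time grid", call. = FALSE)
  n_avail <- length(trajectories)
  if (is.null(sample_size)) sample_size <- n_avail
  stopifnot(sample_size >= 1L, sample_size <= n_avail)
  idx <- if (sample_size < n_avail) {
    if (!is.null(seed)) set.seed(seed)
    sort(sample.int(n_avail, sample_size))
  } else {
    seq_len(n_avail)
  }
  sq <- vapply(trajectories[idx],
               function(tr) rowSums(tr$positions^2),
               numeric(length(times)))
  structure(list(times = times,
                 values = rowMeans(sq),
                 sample_size = as.integer(sample_size),
                 replicate_ids = idx),
            class = "msd_curve")
}

#' @export
print.msd_curve <- function(x, ...) {
  cat(sprintf("Ensemble MSD: N = %d, %d time points, T = %g\n",
              x$sample_size, length(x$times), max(x$times)))
  cat(sprintf("  MSD(T) = %.4g\n", x$values[length(x$values)]))
  invisible(x)
}

#' MSD power-law scaling exponent
#'
#' Least-squares slope of log(MSD) versus log(t) over a fit window,
#' classifying the diffusion regime: slope 2 is ballistic, 1 diffusive,
#' above 1 superdiffusive, below 1 subdiffusive. The default window is the
#' last decade of observation times (t in [T/10, T]), excluding the early
#' advective transient.
#'
#' @param curve an \code{msd_curve}.
#' @param fit_window length-2 numeric \code{c(t0, t1)}; default last decade.
#' @return The fitted exponent (slope).
#' @examples
#' trs <- lapply(1:20, function(i)
#'   run_simulation(motility_params(Dr = 0, alpha = 0), seed = i))
#' msd_scaling_exponent(ensemble_msd(trs))  # 2: ballistic
#' @export
msd_scaling_exponent <- function(curve, fit_window = NULL) {
  stopifnot(inherits(curve, "msd_curve"))
  tt <- curve$times
  if (is.null(fit_window)) fit_window <- c(max(tt) / 10, max(tt))
  stopifnot(is.numeric(fit_window), length(fit_window) == 2L,
            fit_window[1L] < fit_window[2L])
  keep <- tt >= fit_window[1L] & tt <= fit_window[2L] & tt > 0
  if (sum(keep) < 3L) stop("fit window contains fewer than 3 points",
                           call. = FALSE)
  if (any(curve$values[keep] <= 0)) {
    stop("MSD values in the fit window must be positive", call. = FALSE)
  }
  fit <- stats::lm(log(curve$values[keep]) ~ log(tt[keep]))
  unname(stats::coef(fit)[2L])
}

#' Classify a diffusion regime from an MSD exponent
#'
#' @param exponent fitted MSD scaling exponent.
#' @param tol half-width of the band treated as ordinary diffusion.
#' @return One of \code{"subdiffusive"}, \code{"diffusive"},
#'   \code{"superdiffusive"}.
#' @export
classify_diffusion <- function(exponent, tol = 0.1) {
  if (exponent < 1 - tol) "subdiffusive"
  else if (exponent > 1 + tol) "superdiffusive"
  else "diffusive"
}
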