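#' Fractional Brownian motion covariance
#'
#' Closed-form covariance of fractional Brownian motion (fBm) with Hurst
#' index \code{H}: \deqn{Cov(W_H(t), W_H(s)) = \tfrac{1}{2}(t^{2H} + s^{2H} -
#' |t-s|^{2H}).} This is the analytic oracle against which the synthesis
#' routines are validated.
#'
#' @param t,s non-negative times (vectorised, recycled).
#' @param H Hurst index in (0, 1).
#' @return Numeric vector of covariances.
#' @examples
#' fbm_covariance(2, 1, H = 0.75)
#' fbm_covariance(2, 1, H = 0.5)  # = min(t, s), the Wiener covariance
#' @export
fbm_covariance <- function(t, s, H) {
  check_hurst(H)
  if (any(t < 0) || any(s < 0)) {
    stop("'t' and 's' must be non-negative", call. = FALSE)
  }
  0.5 * (t^(2 * H) + s^(2 * H) - abs(t - s)^(2 * H))
}

#' @keywords internal
check_hurst <- function(H, warn_below_half = FALSE) {
  if (!is.numeric(H) || length(H) != 1L || !is.finite(H) || H <= 0 || H >= 1) {
    stop("Hurst index 'H' must be a single number in (0, 1)", call. = FALSE)
  }
  if (warn_below_half && H < 0.5) {
    warning("H < 0.5 gives negatively correlated (anti-persistent) increments; ",
            "the migration model is studied for H >= 0.5 only", call. = FALSE)
  }
  invisible(H)
}

# Autocovariance of fractional Gaussian noise (the increment process of fBm
# on a grid with spacing dt) at integer lags k: per-step variance dt^(2H).
fgn_autocov <- function(k, H, dt) {
  0.5 * dt^(2 * H) *
    (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
}

# Eigenvalues of the circulant embedding of the fGn covariance (size 2n).
dh_eigenvalues <- function(n, H, dt) {
  g <- fgn_autocov(0:n, H, dt)
  Re(stats::fft(c(g, g[n:2])))
}

# Davies-Harte sampling of fGn: exact synthesis via circulant embedding.
# Returns an n x n_paths matrix of increments. Eigenvalues must be
# non-negative; the caller falls back to Hosking otherwise.
dh_sample <- function(n, H, dt, n_paths, ev) {
  m <- 2L * n
  v0 <- stats::rnorm(n_paths)
  vn <- stats::rnorm(n_paths)
  a <- matrix(stats::rnorm((n - 1L) * n_paths), n - 1L, n_paths)
  b <- matrix(stats::rnorm((n - 1L) * n_paths), n - 1L, n_paths)
  z <- matrix(0 + 0i, m, n_paths)
  z[1L, ] <- sqrt(ev[1L]) * v0
  z[n + 1L, ] <- sqrt(ev[n + 1L]) * vn
  mid <- sqrt(ev[2:n] / 2) * (a + 1i * b)
  z[2:n, ] <- mid
  z[m:(n + 2L), ] <- Conj(mid)
  Re(stats::mvfft(z))[1:n, , drop = FALSE] / sqrt(m)
}

# Hosking (Durbin-Levinson) sampling of fGn: exact, O(n^2), sequential.
# z is an n x n_paths matrix of standard normals (innovations).
hosking_sample <- function(n, H, dt, z) {
  z <- as.matrix(z)
  g <- fgn_autocov(0:(n - 1L), H, dt)
  x <- matrix(0, n, ncol(z))
  v <- g[1L]
  x[1L, ] <- sqrt(v) * z[1L, ]
  phi <- numeric(0)
  for (k in seq_len(n - 1L)) {
    if (k == 1L) {
      phi_k <- g[2L] / g[1L]
      phi <- phi_k
    } else {
      phi_k <- (g[k + 1L] - sum(phi * g[k:2])) / v
      phi <- c(phi - phi_k * rev(phi), phi_k)
    }
    v <- v * (1 - phi_k^2)
    if (v < 0) v <- 0  # guard against roundoff at extreme H
    x[k + 1L, ] <- drop(phi %*% x[k:1, , drop = FALSE]) + sqrt(v) * z[k + 1L, ]
  }
  x
}

#' Generate fractional Brownian motion increments
#'
#' Exact synthesis of fractional Gaussian noise — the stationary increment
#' process of fBm restricted to a uniform grid with spacing \code{dt}. Each
#' increment is centred Gaussian with variance \code{dt^(2H)}; the cumulative
#' sums form a zero-mean Gaussian path whose covariance on the grid is
#' \code{\link{fbm_covariance}}. Synthesis uses the Davies-Harte circulant
#' embedding (O(n log n)); if the embedding is not non-negative definite it
#' falls back to the Hosking recursion (exact, O(n^2)).
#'
#' For \code{H = 0.5} the increments are i.i.d. Wiener increments of variance
#' \code{dt}; for \code{H > 0.5} disjoint increments are positively
#' correlated (persistent).
#'
#' @param n number of increments (>= 1).
#' @param H Hurst index in (0, 1).
#' @param dt grid spacing (> 0).
#' @param seed integer seed; identical \code{(n, H, dt, seed)} gives
#'   bit-identical output.
#' @param n_paths number of independent series to draw.
#' @param method \code{"davies-harte"} (default, with automatic fallback) or
#'   \code{"hosking"}.
#' @return An object of class \code{fbm_series}: list with \code{values}
#'   (length-\code{n} vector, or \code{n x n_paths} matrix when
#'   \code{n_paths > 1}), \code{H}, \code{dt}, \code{n}, \code{seed} and
#'   \code{method}.
#' @examples
#' s <- fbm_increments(1000, H = 0.75, dt = 0.1, seed = 1)
#' var(s$values)          # close to 0.1^1.5
#' w <- cumsum(s$values)  # an fBm path on the grid
#' @export
fbm_increments <- function(n, H, dt = 1, seed = NULL, n_paths = 1L,
                           method = c("davies-harte", "hosking")) {
  method <- match.arg(method)
  check_hurst(H)
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    stop("'n' must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) {
    stop("'dt' must be a positive number", call. = FALSE)
  }
  n <- as.integer(n)
  n_paths <- as.integer(n_paths)
  if (!is.null(seed)) set.seed(seed)
  if (n == 1L) {
    x <- matrix(stats::rnorm(n_paths, sd = dt^H), 1L, n_paths)
  } else if (method == "hosking") {
    x <- hosking_sample(n, H, dt, matrix(stats::rnorm(n * n_paths), n, n_paths))
  } else {
    ev <- dh_eigenvalues(n, H, dt)
    if (any(ev < 0)) {
      x <- hosking_sample(n, H, dt, matrix(stats::rnorm(n * n_paths), n, n_paths))
      method <- "hosking"
    } else {
      x <- dh_sample(n, H, dt, n_paths, ev)
    }
  }
  structure(
    list(values = if (n_paths == 1L) drop(x) else x,
         H = H, dt = dt, n = n, n_paths = n_paths,
         seed = seed, method = method),
    class = "fbm_series")
}

#' @export
print.fbm_series <- function(x, ...) {
  cat(sprintf("fBm increment series: n = %d, H = %g, dt = %g (%s)\n",
              x$n, x$H, x$dt, x$method))
  cat(sprintf("  %d path(s); per-step sd = %g\n", x$n_paths, x$dt^x$H))
  invisible(x)
}

# Increments with a prescribed first value: the remaining n-1 increments are
# drawn from the exact conditional law of fGn given the first one. Gaussian
# conditioning on one coordinate leaves the conditional covariance free of
# the observed value, so an unconditional Davies-Harte draw Y can be
# corrected to X_k = Y_k + (x1 - Y_1) * gamma(k-1)/gamma(0).
# This is how the model initialises each noise series from ~N(0, var0).
fgn_conditional_on_first <- function(n, H, dt, first) {
  if (n == 1L) return(first)
  y <- fbm_increments(n, H, dt)$values
  r <- fgn_autocov(0:(n - 1L), H, dt) / fgn_autocov(0L, H, dt)
  x <- y + (first - y[1L]) * r
  x[1L] <- first
  x
}
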