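fmt17 <- function(x) sprintf("%.17g", x)

#' Write a trajectory to CSV
#'
#' Interchange format for the metrics tooling: columns
#' \code{replicate,step,t,x,y,theta} (header mandatory), floats at 17
#' significant digits so the round trip is exact. A JSON sidecar
#' (\code{<path>.json}) records the full parameter set and seed (plus
#' \code{f_tax} and \code{x_org} for guided runs).
#'
#' @param trajectory a \code{cell_trajectory}.
#' @param path output CSV path.
#' @param sidecar write the JSON parameter sidecar (default TRUE).
#' @return \code{path}, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path, sidecar = TRUE) {
  stopifnot(inherits(trajectory, "cell_trajectory"))
  n <- nrow(trajectory$positions)
  df <- data.frame(
    replicate = trajectory$replicate_id,
    step = 0:(n - 1L),
    t = fmt17(trajectory$times),
    x = fmt17(trajectory$positions[, 1L]),
    y = fmt17(trajectory$positions[, 2L]),
    theta = fmt17(trajectory$thetas))
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  if (sidecar) {
    meta <- c(unclass(trajectory$params),
              list(seed = trajectory$seed,
                   replicate_id = trajectory$replicate_id,
                   theta0 = trajectory$thetas[1L]))
    if (!is.null(trajectory$taxis)) {
      meta$f_tax <- trajectory$taxis$f_tax
      meta$x_org <- trajectory$taxis$x_org
    }
    jsonlite::write_json(meta, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a trajectory CSV
#'
#' Rebuilds a \code{cell_trajectory} from the CSV written by
#' \code{\link{write_trajectory_csv}}. Step vectors are recomputed as
#' position differences; the parameter sidecar is used when present (noise
#' increments are not stored in the CSV, so \code{initial_alignment} of a
#' re-read trajectory is 0).
#'
#' @param path CSV path.
#' @return A \code{cell_trajectory}.
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("replicate", "step", "t", "x", "y", "theta")
  if (!all(need %in% names(df))) {
    stop("malformed trajectory CSV: expected columns ",
         paste(need, collapse = ","), call. = FALSE)
  }
  df <- df[order(df$step), ]
  n <- nrow(df) - 1L
  if (n < 1L) stop("trajectory CSV has no steps", call. = FALSE)
  params <- NULL
  taxis <- NULL
  seed <- NA_integer_
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    inv <- meta$init_noise_var
    if (length(inv) == 0) inv <- NULL  # JSON null round-trips as empty
    params <- motility_params(
      Fm = meta$Fm, gamma_s = meta$gamma_s, alpha = meta$alpha,
      Dr = meta$Dr, H = meta$H, Htheta = meta$Htheta, dt = meta$dt,
      n_steps = meta$n_steps, init_noise_var = inv)
    if (!is.null(meta$f_tax)) {
      taxis <- taxis_params(f_tax = meta$f_tax, x_org = meta$x_org)
    }
    seed <- meta$seed
  } else {
    dt <- df$t[2L] - df$t[1L]
    params <- motility_params(dt = dt, n_steps = n)
  }
  pos <- cbind(df$x, df$y)
  structure(
    list(times = df$t, positions = pos, thetas = df$theta,
         step_vectors = diff(pos), noise = matrix(0, n, 2L),
         params = params, taxis = taxis, seed = seed,
         replicate_id = as.integer(df$replicate[1L])),
    class = "cell_trajectory")
}

#' Write an ensemble summary CSV
#'
#' One row per replicate with the \code{\link{trajectory_stats}} columns;
#' floats at 17 significant digits for exact round trips.
#'
#' @param stats data.frame of row-bound \code{trajectory_stats}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_summary_csv <- function(stats, path) {
  out <- stats
  num <- vapply(out, is.double, TRUE)
  out[num] <- lapply(out[num], fmt17)
  utils::write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an MSD curve to CSV
#'
#' Columns \code{t,msd,N}.
#'
#' @param curve an \code{msd_curve}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_msd_csv <- function(curve, path) {
  stopifnot(inherits(curve, "msd_curve"))
  df <- data.frame(t = fmt17(curve$times), msd = fmt17(curve$values),
                   N = curve$sample_size)
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
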