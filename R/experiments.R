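#' Experiment grid definition
#'
#' A sweep over noise-correlation rows and rotational-diffusion columns
#' (optionally crossed with taxis strengths), with a replicate count and a
#' base seed. Rows are the \code{alpha = 0} control plus one row per Hurst
#' index; columns are the \code{Dr} values.
#'
#' @param H_values Hurst indices for the correlated-noise rows.
#' @param Dr_values rotational diffusion coefficients (columns).
#' @param alpha translational noise magnitude for the H rows (the control row
#'   always uses \code{alpha = 0}).
#' @param f_tax_values taxis strengths; empty for the unguided grid.
#' @param x_org organizing-center position (used when \code{f_tax_values} is
#'   non-empty).
#' @param n_replicates replicates per parameter cell.
#' @param base_seed integer; replicate seeds derive deterministically from
#'   (base_seed, cell, replicate), so results are independent of execution
#'   order.
#' @param dt,n_steps timestep and horizon passed to every cell.
#' @param include_control add the \code{alpha = 0} row (default TRUE).
#' @return An object of class \code{experiment_grid} whose \code{cells}
#'   element is a data.frame with one row per parameter cell.
#' @seealso \code{\link{main_grid}}, \code{\link{taxis_grid}} for the preset
#'   grids; \code{\link{run_grid}} to execute.
#' @export
experiment_grid <- function(H_values = c(0.5, 0.75, 0.99),
                            Dr_values = c(0, 0.1, 1, 10),
                            alpha = 0.25,
                            f_tax_values = numeric(0),
                            x_org = c(-100 / sqrt(2), -100 / sqrt(2)),
                            n_replicates = 200L,
                            base_seed = 1L,
                            dt = 0.1, n_steps = 1000L,
                            include_control = TRUE) {
  stopifnot(length(H_values) >= 1L || include_control,
            all(Dr_values >= 0), alpha >= 0,
            all(f_tax_values >= 0),
            n_replicates >= 1L, n_steps >= 1L, dt > 0)
  for (h in H_values) check_hurst(h)
  rows <- data.frame(H = c(if (include_control) 0.5, H_values),
                     alpha = c(if (include_control) 0, rep(alpha, length(H_values))),
                     row_label = c(if (include_control) "alpha0",
                                   paste0("H", H_values)))
  ft <- if (length(f_tax_values)) f_tax_values else NA_real_
  cells <- expand.grid(row = seq_len(nrow(rows)), Dr = Dr_values,
                       f_tax = ft, KEEP.OUT.ATTRS = FALSE)
  cells <- data.frame(H = rows$H[cells$row], alpha = rows$alpha[cells$row],
                      row_label = rows$row_label[cells$row],
                      Dr = cells$Dr, f_tax = cells$f_tax,
                      stringsAsFactors = FALSE)
  cells$cell <- seq_len(nrow(cells))
  cells$label <- sprintf("%s_Dr%g%s", cells$row_label, cells$Dr,
                         ifelse(is.na(cells$f_tax), "",
                                sprintf("_ftax%g", cells$f_tax)))
  structure(
    list(cells = cells, n_replicates = as.integer(n_replicates),
         base_seed = as.integer(base_seed), dt = dt,
         n_steps = as.integer(n_steps), x_org = as.numeric(x_org)),
    class = "experiment_grid")
}

#' @export
print.experiment_grid <- function(x, ...) {
  cat(sprintf("Experiment grid: %d cells x %d replicates (base seed %d)\n",
              nrow(x$cells), x$n_replicates, x$base_seed))
  cat(sprintf("  %d steps of dt = %g per trajectory\n", x$n_steps, x$dt))
  if (!all(is.na(x$cells$f_tax))) {
    cat(sprintf("  taxis: f_tax in {%s}, x_org = (%.4f, %.4f)\n",
                paste(sort(unique(x$cells$f_tax)), collapse = ", "),
                x$x_org[1], x$x_org[2]))
  }
  invisible(x)
}

#' Preset: main (unguided) grid
#'
#' The alpha = 0 control row plus H in {0.5, 0.75, 0.99} against
#' Dr in {0, 0.1, 1, 10} — 16 parameter cells, 200 replicates each, 1000
#' steps of dt = 0.1.
#'
#' @param n_replicates,n_steps,base_seed scale-down knobs; defaults are the
#'   reference protocol.
#' @return An \code{experiment_grid}.
#' @export
main_grid <- function(n_replicates = 200L, n_steps = 1000L, base_seed = 1L) {
  experiment_grid(n_replicates = n_replicates, n_steps = n_steps,
                  base_seed = base_seed)
}

#' Preset: taxis grid
#'
#' The main grid crossed with f_tax in {0.01, 0.1, 1} (48 cells), 100
#' replicates each, organizing center at distance 100 from the origin.
#'
#' @inheritParams main_grid
#' @return An \code{experiment_grid}.
#' @export
taxis_grid <- function(n_replicates = 100L, n_steps = 1000L, base_seed = 1L) {
  experiment_grid(f_tax_values = c(0.01, 0.1, 1),
                  n_replicates = n_replicates, n_steps = n_steps,
                  base_seed = base_seed)
}

# Deterministic replicate seed: a fixed arithmetic function of (base_seed,
# cell, replicate), kept below 2^31 and independent of execution order.
replicate_seed <- function(base_seed, cell, rep) {
  as.integer((as.double(base_seed) + 999983 * as.double(cell) +
                7919 * as.double(rep)) %% (.Machine$integer.max - 1)) + 1L
}

run_cell <- function(grid, cell_row) {
  p <- motility_params(alpha = cell_row$alpha, Dr = cell_row$Dr,
                       H = cell_row$H, dt = grid$dt, n_steps = grid$n_steps)
  tx <- if (!is.na(cell_row$f_tax)) {
    taxis_params(f_tax = cell_row$f_tax, x_org = grid$x_org)
  }
  lapply(seq_len(grid$n_replicates), function(r) {
    s <- replicate_seed(grid$base_seed, cell_row$cell, r)
    if (is.null(tx)) {
      run_simulation(p, seed = s, replicate_id = r)
    } else {
      run_taxis_simulation(p, tx, seed = s, replicate_id = r)
    }
  })
}

#' Run an experiment grid
#'
#' Executes every parameter cell: per cell, \code{n_replicates} independent
#' trajectories, a per-replicate summary CSV
#' (\code{summary_<label>.csv}), an ensemble MSD CSV
#' (\code{msd_<label>.csv}, all replicates), and one \code{manifest.json}
#' recording parameters, seeds and package version. Reruns with the same
#' \code{base_seed} are byte-identical; existing outputs require
#' \code{overwrite = TRUE}.
#'
#' @param grid an \code{\link{experiment_grid}}.
#' @param output_dir writable output directory (created if absent).
#' @param overwrite replace existing outputs (default FALSE: error).
#' @param msd_sample_sizes sample sizes for additional subsampled MSD curves
#'   (values larger than the replicate count are skipped).
#' @return Invisibly, a named list of per-cell summary data.frames.
#' @export
run_grid <- function(grid, output_dir, overwrite = FALSE,
                     msd_sample_sizes = integer(0)) {
  stopifnot(inherits(grid, "experiment_grid"))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(output_dir, "manifest.json")
  if (file.exists(manifest_path) && !overwrite) {
    stop("output directory already holds a run; use overwrite = TRUE",
         call. = FALSE)
  }
  res <- list()
  for (i in seq_len(nrow(grid$cells))) {
    row <- grid$cells[i, ]
    trs <- run_cell(grid, row)
    stats <- do.call(rbind, lapply(trs, trajectory_stats))
    write_summary_csv(stats, file.path(output_dir,
                                       sprintf("summary_%s.csv", row$label)))
    write_msd_csv(ensemble_msd(trs),
                  file.path(output_dir, sprintf("msd_%s.csv", row$label)))
    for (nn in msd_sample_sizes) {
      if (nn < grid$n_replicates) {
        write_msd_csv(
          ensemble_msd(trs, sample_size = nn, seed = grid$base_seed + nn),
          file.path(output_dir, sprintf("msd_%s_N%d.csv", row$label, nn)))
      }
    }
    res[[row$label]] <- stats
  }
  manifest <- list(
    package = "fbmigrate",
    version = as.character(utils::packageVersion("fbmigrate")),
    base_seed = grid$base_seed,
    n_replicates = grid$n_replicates,
    n_steps = grid$n_steps, dt = grid$dt,
    x_org = grid$x_org,
    cells = grid$cells)
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(res)
}

#' Summarise a grid run
#'
#' Reads the per-replicate summary CSVs of a \code{\link{run_grid}} output
#' directory and returns per-cell means, variances and quartiles of the
#' trajectory statistics (the quantities shown as violin distributions in
#' the ensemble analyses).
#'
#' @param results_dir directory produced by \code{\link{run_grid}}.
#' @return data.frame with one row per (cell, statistic).
#' @export
summarize_grid <- function(results_dir) {
  files <- list.files(results_dir, pattern = "^summary_.*\\.csv$",
                      full.names = TRUE)
  if (!length(files)) stop("no summary CSVs found in ", results_dir,
                           call. = FALSE)
  out <- list()
  for (f in files) {
    df <- tryCatch(utils::read.csv(f), error = function(e) {
      warning("malformed summary CSV skipped: ", f, call. = FALSE)
      NULL
    })
    if (is.null(df)) next
    label <- sub("^summary_(.*)\\.csv$", "\\1", basename(f))
    vars <- intersect(c("pf", "total_distance", "displacement",
                        "mean_increment", "mean_rel_angle",
                        "final_distance_to_target"), names(df))
    for (v in vars) {
      x <- df[[v]]
      q <- stats::quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE)
      out[[length(out) + 1L]] <- data.frame(
        cell = label, statistic = v, n = length(x),
        mean = mean(x, na.rm = TRUE), var = stats::var(x),
        q25 = q[[1L]], median = q[[2L]], q75 = q[[3L]])
    }
  }
  do.call(rbind, out)
}
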