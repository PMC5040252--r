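#' Read an xCELLigence-style Cell-Index table
#'
#' Expects the layout of the instrument exports: first column time (hours),
#' second the mean Cell Index of a quadruplicate experiment, optional third
#' its standard deviation. CSV is read natively; `.xlsx`/`.xls` sheets are
#' read through readxl when installed. Rows with non-numeric time are
#' dropped with a message.
#'
#' @param path CSV or XLSX file.
#' @param sheet sheet name or index for XLSX input.
#' @param label optional label (defaults to file/sheet name).
#' @return An object of class `rtca_table`: list with `label`, `data`
#'   (data frame `time_h`, `ci_mean`, optional `ci_sd`) and `has_sd`.
#' @export
read_rtca_table <- function(path, sheet = 1, label = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("read_rtca_table: reading '", path, "' needs the readxl package",
           call. = FALSE)
    }
    raw <- as.data.frame(readxl::read_excel(path, sheet = sheet,
                                            col_names = TRUE))
    src <- paste0(basename(path), "#", sheet)
  } else {
    raw <- utils::read.csv(path, header = TRUE)
    src <- basename(path)
  }
  if (ncol(raw) < 2) {
    stop("read_rtca_table: '", src, "' has fewer than two columns",
         call. = FALSE)
  }
  num <- function(col) suppressWarnings(as.numeric(col))
  t <- num(raw[[1]])
  v <- num(raw[[2]])
  keep <- is.finite(t) & is.finite(v)
  dropped <- sum(!keep)
  if (dropped > 0) {
    message("read_rtca_table: dropped ", dropped, " non-numeric row(s) from ",
            src)
  }
  if (!any(keep)) {
    stop("read_rtca_table: no numeric rows in '", src, "'", call. = FALSE)
  }
  df <- data.frame(time_h = t[keep], ci_mean = v[keep])
  has_sd <- ncol(raw) >= 3
  if (has_sd) {
    s <- num(raw[[3]])[keep]
    if (all(is.finite(s))) df$ci_sd <- s else has_sd <- FALSE
  }
  ord <- order(df$time_h)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  structure(list(label = label %||% src, data = df, has_sd = has_sd),
            class = "rtca_table")
}

#' Write a Cell-Index table as CSV
#'
#' Columns `time_h`, `ci_mean` and, when present, `ci_sd`.
#'
#' @param table an `rtca_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_rtca_table <- function(table, path) {
  stopifnot(inherits(table, "rtca_table"))
  utils::write.csv(table$data, path, row.names = FALSE)
  invisible(path)
}

#' Average independent replicate experiments
#'
#' Pointwise mean across tables on the first table's time grid restricted
#' to the common overlap, with the other tables linearly interpolated onto
#' it. The SD column of the result is the standard deviation of the
#' per-experiment means (zero for a single table). Permutation of the
#' inputs only changes the reference grid choice insofar as grids differ.
#'
#' @param tables list of `rtca_table` objects (>= 1).
#' @return A [ci_curve()] with the averaged Cell Index and its SD.
#' @export
average_replicates <- function(tables) {
  if (inherits(tables, "rtca_table")) tables <- list(tables)
  stopifnot(length(tables) >= 1,
            all(vapply(tables, inherits, logical(1), "rtca_table")))
  lo <- max(vapply(tables, function(tb) min(tb$data$time_h), numeric(1)))
  hi <- min(vapply(tables, function(tb) max(tb$data$time_h), numeric(1)))
  if (lo > hi) {
    stop("average_replicates: tables have disjoint time ranges", call. = FALSE)
  }
  grid <- tables[[1]]$data$time_h
  grid <- grid[grid >= lo - 1e-12 & grid <= hi + 1e-12]
  vals <- vapply(tables, function(tb) {
    stats::approx(tb$data$time_h, tb$data$ci_mean, xout = grid)$y
  }, numeric(length(grid)))
  vals <- matrix(vals, nrow = length(grid))
  m <- rowMeans(vals)
  s <- if (ncol(vals) > 1) apply(vals, 1, stats::sd) else rep(0, length(grid))
  ci_curve(grid, m, sd = s,
           label = paste0("mean of ", length(tables), " experiment(s)"))
}

#' Generate synthetic assay exports
#'
#' Stands in for the instrument's raw exports so the whole pipeline is
#' testable offline: runs the forward model, converts the lower-chamber
#' cell number to Cell Index, samples it at the recording cadence and adds
#' independent additive Gaussian noise per replicate. Each experiment is
#' emitted as the mean of its replicates with their standard deviation,
#' exactly in the export layout read by [read_rtca_table()].
#'
#' @param params,geometry,ic,settings forward-model inputs
#'   (see [simulate_assay()]).
#' @param map a [cell_index_map()] converting cells to Cell Index.
#' @param noise_sd Gaussian noise SD on the Cell Index of each replicate.
#' @param n_replicates replicates per experiment (quadruplicate by default).
#' @param n_experiments independent experiments.
#' @param seed RNG seed; fixed seed gives identical output.
#' @param cadence recording cadence, h (default 0.25).
#' @return List of `n_experiments` objects of class `rtca_table`.
#' @export
synthesize_experiment <- function(params, geometry = assay_geometry(),
                                  ic = preset_initial_conditions(),
                                  settings = simulation_settings(),
                                  map = cell_index_map(1e-4),
                                  noise_sd = 0.05, n_replicates = 4,
                                  n_experiments = 3, seed = 1,
                                  cadence = 0.25) {
  stopifnot(noise_sd >= 0, n_replicates >= 1, n_experiments >= 1)
  settings$output_interval <- min(settings$output_interval, cadence)
  res <- simulate_assay(params, geometry, ic, settings)
  grid <- seq(0, settings$t_end, by = cadence)
  ci <- map$a * stats::approx(res$times, res$n_lower, xout = grid)$y + map$b
  set.seed(seed)
  lapply(seq_len(n_experiments), function(e) {
    reps <- matrix(stats::rnorm(length(grid) * n_replicates, 0, noise_sd),
                   nrow = length(grid))
    reps <- reps + ci
    df <- data.frame(time_h = grid,
                     ci_mean = rowMeans(reps),
                     ci_sd = if (n_replicates > 1) {
                       apply(reps, 1, stats::sd)
                     } else {
                       rep(0, length(grid))
                     })
    structure(list(label = sprintf("synthetic_exp%d", e), data = df,
                   has_sd = TRUE),
              class = "rtca_table")
  })
}

#' Convert an averaged table to a curve
#'
#' @param table an `rtca_table`.
#' @return A [ci_curve()].
#' @export
as_ci_curve <- function(table) {
  stopifnot(inherits(table, "rtca_table"))
  ci_curve(table$data$time_h, table$data$ci_mean,
           sd = if (table$has_sd) table$data$ci_sd else NULL,
           label = table$label)
}
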