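# File formats: delimited-text matrices (comma or whitespace), TSV region
# tables with a header, YAML/JSON run configuration. Region indices are
# 1-based in all files.

read_matrix_file <- function(path) {
  if (!file.exists(path))
    pfic_error("pfic_io_error", "file not found: %s", path)
  first <- readLines(path, n = 1)
  sep <- if (grepl(",", first)) "," else ""
  m <- as.matrix(read.table(path, sep = sep, header = FALSE,
                            colClasses = "numeric"))
  dimnames(m) <- NULL
  m
}

#' Read a structural connectome from delimited text
#'
#' Reads a square SC matrix (comma- or whitespace-delimited) and a sidecar
#' region table (TSV with header; columns `name` and `hemisphere`, optional
#' `x`, `y`, `z` unit-sphere centroids, `network`, `sa_rank`). Near-symmetric
#' matrices (max asymmetry at most `1e-8`) are symmetrized by averaging with
#' the transpose; larger asymmetries are an error.
#'
#' @param path Path to the SC matrix file.
#' @param region_table_path Path to the region table (TSV). If `NULL`,
#'   default region names are used.
#' @return A validated [connectome()].
#' @export
read_connectome <- function(path, region_table_path = NULL) {
  m <- read_matrix_file(path)
  if (nrow(m) != ncol(m))
    pfic_error("pfic_io_error", "SC matrix is not square (%d x %d)",
               nrow(m), ncol(m))
  if (any(m < 0))
    pfic_error("pfic_invalid_connectome", "negative connectivity in %s", path)
  asym <- max(abs(m - t(m)))
  if (asym > 1e-8)
    pfic_error("pfic_invalid_connectome",
               "asymmetry %.3g exceeds tolerance 1e-8", asym)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  tab <- NULL
  if (!is.null(region_table_path)) {
    tab <- read.table(region_table_path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
    if (nrow(tab) != nrow(m))
      pfic_error("pfic_io_error",
                 "region table has %d rows but SC has %d regions",
                 nrow(tab), nrow(m))
  }
  centroids <- if (!is.null(tab) && all(c("x", "y", "z") %in% names(tab)))
    as.matrix(tab[, c("x", "y", "z")])
  connectome(m,
             region_names = tab$name,
             hemisphere = tab$hemisphere,
             centroids = centroids,
             network_label = tab$network,
             sa_rank = tab$sa_rank)
}

#' Write a connectome to delimited text
#'
#' Inverse of [read_connectome()]: writes the SC matrix as tab-delimited
#' text and (optionally) the region table as TSV with header.
#'
#' @param conn A [connectome()].
#' @param path Output path for the SC matrix.
#' @param region_table_path Optional output path for the region table.
#' @return `conn`, invisibly.
#' @export
write_connectome <- function(conn, path, region_table_path = NULL) {
  write.table(conn$sc, path, sep = "\t", row.names = FALSE,
              col.names = FALSE)
  if (!is.null(region_table_path)) {
    tab <- data.frame(name = conn$region_names, hemisphere = conn$hemisphere)
    if (!is.null(conn$centroids)) {
      tab$x <- conn$centroids[, 1]; tab$y <- conn$centroids[, 2]
      tab$z <- conn$centroids[, 3]
    }
    if (!is.null(conn$network_label)) tab$network <- conn$network_label
    if (!is.null(conn$sa_rank)) tab$sa_rank <- conn$sa_rank
    write.table(tab, region_table_path, sep = "\t", row.names = FALSE,
                quote = FALSE)
  }
  invisible(conn)
}

#' Read a BOLD time series from delimited text
#'
#' @param path Delimited-text matrix, frames x regions.
#' @param tr_seconds Repetition time (s).
#' @return A [bold_timeseries()]; non-finite values are an error.
#' @export
read_timeseries <- function(path, tr_seconds) {
  m <- read_matrix_file(path)
  if (!all(is.finite(m)))
    pfic_error("pfic_invalid_timeseries",
               "non-finite values in time series file %s", path)
  bold_timeseries(m, tr_seconds)
}

#' Write a BOLD time series to delimited text
#' @param ts A [bold_timeseries()].
#' @param path Output path.
#' @return `ts`, invisibly.
#' @export
write_timeseries <- function(ts, path) {
  write.table(format(ts$data, digits = 17), path, sep = "\t",
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(ts)
}

#' Run configuration
#'
#' Numerical and protocol settings for simulation and fitting. Defaults:
#' 1 ms integration step, 60 s burn-in, 300 s duration, 3 Hz excitatory
#' firing-rate target with acceptance bounds 2.7-3.3 Hz, 500-candidate
#' budget with top-10 selection, and a penalty cost of 10 for rejected
#' candidates.
#'
#' @param dt_s Integration step (s).
#' @param burn_in_s Discarded initial transient (s); must be < `duration_s`.
#' @param duration_s Total simulated time (s).
#' @param target_hz Excitatory firing-rate set-point (Hz).
#' @param rate_bounds_hz Closed acceptance bounds (Hz) for regional mean
#'   excitatory rates; must bracket `target_hz`.
#' @param candidate_budget Number of candidates evaluated by the search.
#' @param top_k Candidates carried from validation to test.
#' @param seeds Named integer seeds for the train/validation/test phases.
#' @param bounds Per-quantity `(min, max)` search bounds (list with entries
#'   `w_ee`, `w_ei`, `sigma`, `g`).
#' @param penalty Cost assigned to invalid candidates.
#' @param bold_drop_frames Initial BOLD frames discarded as hemodynamic
#'   transient; `NULL` (default) discards ~30 s worth of frames at the
#'   target's TR.
#' @return An object of class `run_config`.
#' @export
run_config <- function(dt_s = 0.001, burn_in_s = 60, duration_s = 300,
                       target_hz = 3.0, rate_bounds_hz = c(2.7, 3.3),
                       candidate_budget = 500, top_k = 10,
                       seeds = c(train = 1L, validation = 2L, test = 3L),
                       bounds = default_bounds(), penalty = 10,
                       bold_drop_frames = NULL) {
  if (dt_s <= 0)
    pfic_error("pfic_invalid_config", "dt_s must be positive")
  if (burn_in_s >= duration_s)
    pfic_error("pfic_invalid_config", "burn_in_s must be below duration_s")
  if (length(rate_bounds_hz) != 2 ||
      !(rate_bounds_hz[1] < target_hz && target_hz < rate_bounds_hz[2]))
    pfic_error("pfic_invalid_config",
               "rate bounds must satisfy lower < target < upper")
  if (top_k > candidate_budget)
    pfic_error("pfic_invalid_config", "top_k cannot exceed candidate_budget")
  structure(list(dt_s = dt_s, burn_in_s = burn_in_s, duration_s = duration_s,
                 target_hz = target_hz, rate_bounds_hz = rate_bounds_hz,
                 candidate_budget = as.integer(candidate_budget),
                 top_k = as.integer(top_k), seeds = seeds, bounds = bounds,
                 penalty = penalty,
                 bold_drop_frames = if (!is.null(bold_drop_frames))
                   as.integer(bold_drop_frames)),
            class = "run_config")
}

#' Load a run configuration from YAML or JSON
#'
#' Absent keys take the [run_config()] defaults; unknown keys produce a
#' warning (not an error); invariants are validated after merging.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` configuration file, or
#'   `NULL` for pure defaults.
#' @return A validated [run_config()].
#' @export
load_config <- function(path = NULL) {
  if (is.null(path)) return(run_config())
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  raw <- raw %||% list()
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    warning(sprintf("ignoring unknown config keys: %s",
                    paste(unknown, collapse = ", ")))
  args <- raw[intersect(names(raw), known)]
  if (!is.null(args$bounds))
    args$bounds <- modifyList(default_bounds(), lapply(args$bounds, unlist))
  if (!is.null(args$seeds)) args$seeds <- unlist(args$seeds)
  do.call(run_config, args)
}
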