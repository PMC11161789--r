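#' Construct and validate a connectome
#'
#' A connectome couples the regional neural-mass models: a square, symmetric,
#' nonnegative structural connectivity (SC) matrix with zero diagonal, plus
#' per-region metadata (names, hemisphere, optional unit-sphere centroids,
#' optional resting-state network labels 1-7 and sensorimotor-association
#' axis ranks).
#'
#' @param sc Square numeric matrix of nonnegative connection strengths
#'   (arbitrary units); must be symmetric within `1e-10` with a zero
#'   diagonal.
#' @param region_names Character vector of region names (default `r1..rn`).
#' @param hemisphere Per-region label in `c("L", "R")`.
#' @param centroids Optional n x 3 matrix of unit-sphere coordinates.
#' @param network_label Optional per-region integer in 1..7.
#' @param sa_rank Optional per-region integer rank along the
#'   sensorimotor-association axis.
#' @return An object of class `connectome`.
#' @export
connectome <- function(sc, region_names = NULL, hemisphere = NULL,
                       centroids = NULL, network_label = NULL,
                       sa_rank = NULL) {
  sc <- as.matrix(sc)
  n <- nrow(sc)
  if (ncol(sc) != n)
    pfic_error("pfic_invalid_connectome", "SC matrix must be square")
  if (!all(is.finite(sc)))
    pfic_error("pfic_invalid_connectome", "SC contains non-finite entries")
  if (any(sc < 0))
    pfic_error("pfic_invalid_connectome",
               "negative connectivity entries are not allowed")
  if (max(abs(sc - t(sc))) > 1e-10)
    pfic_error("pfic_invalid_connectome", "SC must be symmetric within 1e-10")
  if (any(diag(sc) != 0))
    pfic_error("pfic_invalid_connectome", "SC diagonal must be exactly zero")
  region_names <- region_names %||% paste0("r", seq_len(n))
  hemisphere <- hemisphere %||% rep(c("L", "R"), length.out = n)
  chk_len <- function(v, what) {
    if (!is.null(v) && NROW(v) != n)
      pfic_error("pfic_invalid_connectome",
                 "%s must have one entry per region (%d)", what, n)
  }
  chk_len(region_names, "region_names"); chk_len(hemisphere, "hemisphere")
  chk_len(centroids, "centroids"); chk_len(network_label, "network_label")
  chk_len(sa_rank, "sa_rank")
  if (!all(hemisphere %in% c("L", "R")))
    pfic_error("pfic_invalid_connectome", "hemisphere labels must be L or R")
  if (!is.null(network_label) && !all(network_label %in% 1:7))
    pfic_error("pfic_invalid_connectome", "network labels must be in 1..7")
  dimnames(sc) <- list(region_names, region_names)
  structure(list(n_regions = n, sc = sc, region_names = region_names,
                 hemisphere = hemisphere, centroids = centroids,
                 network_label = network_label, sa_rank = sa_rank),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("<connectome> %d regions (%d L / %d R), SC density %.2f\n",
              x$n_regions, sum(x$hemisphere == "L"),
              sum(x$hemisphere == "R"),
              mean(x$sc[upper.tri(x$sc)] > 0)))
  invisible(x)
}

#' Regional annotation maps
#'
#' Per-region cortical annotation maps used by the pFIC parameterization:
#' a T1w/T2w myelin proxy, the principal functional-connectivity gradient,
#' and any number of extra named annotation maps (e.g. receptor density).
#'
#' @param myelin,gradient Numeric per-region vectors (unitless).
#' @param ... Additional named per-region numeric annotation maps.
#' @return An object of class `regional_maps`.
#' @export
regional_maps <- function(myelin, gradient, ...) {
  extra <- list(...)
  n <- length(myelin)
  maps <- c(list(myelin = myelin, gradient = gradient), extra)
  for (nm in names(maps)) {
    v <- maps[[nm]]
    if (!is.numeric(v) || length(v) != n || anyNA(v) || !all(is.finite(v)))
      pfic_error("pfic_invalid_maps",
                 "map '%s' must be finite, complete, length %d", nm, n)
  }
  structure(list(n_regions = n, maps = maps), class = "regional_maps")
}

#' BOLD time series container
#'
#' @param data Numeric matrix, frames x regions; all values finite.
#' @param tr_seconds Repetition time (s).
#' @return An object of class `bold_timeseries`.
#' @export
bold_timeseries <- function(data, tr_seconds) {
  data <- as.matrix(data)
  if (nrow(data) < 2)
    pfic_error("pfic_invalid_timeseries", "need at least 2 frames")
  if (!all(is.finite(data)))
    pfic_error("pfic_invalid_timeseries", "non-finite values in time series")
  if (!is.numeric(tr_seconds) || tr_seconds <= 0)
    pfic_error("pfic_invalid_timeseries", "tr_seconds must be positive")
  structure(list(data = data, n_frames = nrow(data), n_regions = ncol(data),
                 tr_seconds = tr_seconds), class = "bold_timeseries")
}

#' Empirical fitting target
#'
#' Bundles the observables a model candidate is scored against: the static
#' FC matrix, the pooled upper-triangular FCD-entry distribution, the FCD
#' window length, frame count and TR, and the ROI coverage mask (regions
#' with insufficient coverage are excluded from all cost computations).
#'
#' @param fc Square correlation matrix (symmetric, unit diagonal, entries in
#'   `[-1, 1]`).
#' @param fcd_entries Numeric vector of pooled upper-triangular FCD values.
#' @param window_frames Sliding-window length in frames (< `n_frames`).
#' @param n_frames Number of frames per run.
#' @param tr_seconds Repetition time (s).
#' @param roi_mask Logical per-region vector; `TRUE` = region enters the
#'   cost. Default all `TRUE`.
#' @return An object of class `fit_target`.
#' @export
fit_target <- function(fc, fcd_entries, window_frames, n_frames, tr_seconds,
                       roi_mask = NULL) {
  fc <- as.matrix(fc)
  n <- nrow(fc)
  if (ncol(fc) != n || max(abs(fc - t(fc))) > 1e-8)
    pfic_error("pfic_invalid_target", "FC must be square and symmetric")
  if (max(abs(diag(fc) - 1)) > 1e-8)
    pfic_error("pfic_invalid_target", "FC diagonal must be 1")
  if (any(abs(fc) > 1 + 1e-12))
    pfic_error("pfic_invalid_target", "FC entries must lie in [-1, 1]")
  if (length(fcd_entries) < 1 || anyNA(fcd_entries))
    pfic_error("pfic_invalid_target", "fcd_entries must be non-empty, no NA")
  if (window_frames >= n_frames)
    pfic_error("pfic_invalid_target",
               "window_frames must be smaller than n_frames")
  roi_mask <- roi_mask %||% rep(TRUE, n)
  if (length(roi_mask) != n || !is.logical(roi_mask))
    pfic_error("pfic_invalid_target", "roi_mask must be logical, length %d", n)
  structure(list(fc = fc, fcd_entries = as.numeric(fcd_entries),
                 window_frames = as.integer(window_frames),
                 n_frames = as.integer(n_frames), tr_seconds = tr_seconds,
                 roi_mask = roi_mask), class = "fit_target")
}

#' Regional synaptic parameters
#'
#' Regional synaptic strengths of the FIC model: excitatory recurrence
#' `w_EE`, excitatory-to-inhibitory `w_EI`, inhibitory feedback `w_IE`
#' (usually left unset and solved by [calibrate_fic()]), the noise amplitude
#' `sigma`, and the global coupling scalar `G`. The inhibitory recurrence
#' `w_II` is fixed to one by convention.
#'
#' @param w_ee,w_ei,sigma Positive per-region numeric vectors.
#' @param g Global SC scaling constant, `>= 0`.
#' @param w_ie Optional per-region positive vector; `NULL` until calibrated.
#' @return An object of class `regional_parameters`.
#' @export
regional_parameters <- function(w_ee, w_ei, sigma, g, w_ie = NULL) {
  n <- length(w_ee)
  chk <- function(v, what, strict = TRUE) {
    if (length(v) != n || !all(is.finite(v)) || any(if (strict) v <= 0 else v < 0))
      pfic_error("pfic_invalid_parameters",
                 "%s must be finite, positive, length %d", what, n)
  }
  chk(w_ee, "w_ee"); chk(w_ei, "w_ei"); chk(sigma, "sigma", strict = FALSE)
  if (!is.null(w_ie)) chk(w_ie, "w_ie")
  if (!is.numeric(g) || length(g) != 1 || !is.finite(g) || g < 0)
    pfic_error("pfic_invalid_parameters", "g must be a nonnegative scalar")
  structure(list(n_regions = n, w_ee = w_ee, w_ei = w_ei, w_ie = w_ie,
                 w_ii = rep(1, n), sigma = sigma, g = g),
            class = "regional_parameters")
}
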