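# Observables: BOLD forward model, static FC, sliding-window FCD, the
# composite model-fit cost (1 - r) + d + KS, and the regional E/I ratio.

#' Balloon-Windkessel BOLD forward model
#'
#' Integrates the hemodynamic states (vasodilatory signal z, inflow f,
#' venous volume v, deoxyhemoglobin q) per region from rest
#' (`z = 0, f = v = q = 1`) driven by the supplied synaptic activity, and
#' samples BOLD every TR. An initial transient can be discarded.
#'
#' @param s_e Synaptic activity matrix, steps x regions, at resolution
#'   `dt_s` (burn-in already trimmed).
#' @param dt_s Neural integration step (s); must divide `tr_s` within 1e-9.
#' @param tr_s BOLD sampling interval (s).
#' @param constants A [hemodynamic_constants()].
#' @param drop_frames Initial BOLD frames discarded as transient.
#' @return A [bold_timeseries()].
#' @export
balloon_windkessel <- function(s_e, dt_s, tr_s,
                               constants = hemodynamic_constants(),
                               drop_frames = 0L) {
  tr_steps <- tr_s / dt_s
  if (abs(tr_steps - round(tr_steps)) > 1e-9)
    pfic_error("pfic_invalid_config", "dt must divide tr within 1e-9")
  out <- tryCatch(
    cpp_balloon_windkessel(as.matrix(s_e), dt_s,
                           as.integer(round(tr_steps)), constants),
    error = function(e) pfic_error("pfic_simulation_error", "%s",
                                   conditionMessage(e)))
  b <- out$bold
  if (drop_frames > 0) b <- b[-seq_len(drop_frames), , drop = FALSE]
  bold_timeseries(b, tr_s)
}

#' Static functional connectivity
#'
#' Region-by-region Pearson correlation matrix of the BOLD time series,
#' restricted to unmasked regions.
#'
#' @param ts A [bold_timeseries()] (or plain frames x regions matrix).
#' @param roi_mask Optional logical mask; masked-out regions are dropped.
#' @return Symmetric correlation matrix with unit diagonal over the
#'   retained regions.
#' @export
static_fc <- function(ts, roi_mask = NULL) {
  X <- if (inherits(ts, "bold_timeseries")) ts$data else as.matrix(ts)
  if (!is.null(roi_mask)) X <- X[, roi_mask, drop = FALSE]
  if (nrow(X) < 2)
    pfic_error("pfic_invalid_input", "need at least 2 frames")
  sds <- apply(X, 2, sd)
  if (any(sds < 1e-15))
    pfic_error("pfic_zero_variance", "zero-variance region(s): %s",
               paste(which(sds < 1e-15), collapse = ", "))
  fc <- cor(X)
  dimnames(fc) <- NULL
  fc
}

#' Functional connectivity dynamics matrix
#'
#' Sliding-window FC (stride 1 frame): window t covers frames
#' `[t, t + window_frames)`; the upper-triangular FC vectors of all windows
#' are correlated pairwise (Pearson), yielding a `W x W` FCD matrix with
#' `W = frames - window_frames + 1` windows. A 1200-frame series with
#' 83-frame windows gives 1118 windows.
#'
#' @param ts A [bold_timeseries()] (or matrix).
#' @param window_frames Window length in frames, `< frames`.
#' @param roi_mask Optional logical region mask.
#' @return List with `fcd` (window-by-window correlation matrix) and
#'   `n_windows`.
#' @export
fcd_matrix <- function(ts, window_frames, roi_mask = NULL) {
  X <- if (inherits(ts, "bold_timeseries")) ts$data else as.matrix(ts)
  if (!is.null(roi_mask)) X <- X[, roi_mask, drop = FALSE]
  n_frames <- nrow(X)
  if (window_frames >= n_frames)
    pfic_error("pfic_invalid_input",
               "window (%d frames) must be shorter than the series (%d)",
               window_frames, n_frames)
  n_win <- n_frames - window_frames + 1L
  p <- ncol(X)
  ut <- upper.tri(matrix(0, p, p))
  # windowed covariances from prefix sums: one pass over frames instead of
  # one cor() call per window
  iu_pairs <- which(ut, arr.ind = TRUE)
  cross <- X[, iu_pairs[, 1], drop = FALSE] * X[, iu_pairs[, 2], drop = FALSE]
  csum <- function(m) apply(m, 2, cumsum)
  c_x <- csum(X); c_x2 <- csum(X^2); c_xy <- csum(cross)
  wsum <- function(cm) {
    lead <- cm[window_frames:n_frames, , drop = FALSE]
    lag <- rbind(0, cm[seq_len(n_frames - window_frames), , drop = FALSE])
    lead - lag
  }
  sx <- wsum(c_x); sx2 <- wsum(c_x2); sxy <- wsum(c_xy)
  w <- window_frames
  var_w <- sx2 / w - (sx / w)^2
  if (any(var_w < 1e-24))
    pfic_error("pfic_zero_variance",
               "zero-variance region within a sliding window")
  cov_w <- sxy / w - (sx[, iu_pairs[, 1]] / w) * (sx[, iu_pairs[, 2]] / w)
  W <- t(cov_w / sqrt(var_w[, iu_pairs[, 1]] * var_w[, iu_pairs[, 2]]))
  fcd <- cor(W)
  list(fcd = fcd, n_windows = n_win)
}

#' Pooled upper-triangular FCD entries
#'
#' Convenience extractor used to build [fit_target()] distributions: the
#' upper-triangular entries of one or more FCD matrices pooled into a
#' single vector.
#'
#' @param ... FCD matrices or results of [fcd_matrix()].
#' @return Numeric vector of pooled entries.
#' @export
fcd_entries <- function(...) {
  unlist(lapply(list(...), function(f) {
    m <- if (is.list(f)) f$fcd else f
    m[upper.tri(m)]
  }), use.names = FALSE)
}

#' FC agreement (Fisher-z Pearson correlation)
#'
#' Pearson correlation between the Fisher z-transformed (atanh)
#' upper-triangular entries of two FC matrices; entries with `|value| = 1`
#' are clipped to `1 - 1e-7` in magnitude first.
#'
#' @param fc_sim,fc_emp Square FC matrices of identical shape.
#' @param roi_mask Optional logical mask applied to both (only when the
#'   matrices still span all regions).
#' @return Correlation `r` in `[-1, 1]`.
#' @export
fc_agreement <- function(fc_sim, fc_emp, roi_mask = NULL) {
  if (!all(dim(fc_sim) == dim(fc_emp)))
    pfic_error("pfic_invalid_input", "FC shape mismatch")
  if (!is.null(roi_mask)) {
    fc_sim <- fc_sim[roi_mask, roi_mask, drop = FALSE]
    fc_emp <- fc_emp[roi_mask, roi_mask, drop = FALSE]
  }
  ut <- upper.tri(fc_sim)
  if (sum(ut) < 3)
    pfic_error("pfic_invalid_input", "fewer than 3 unmasked region pairs")
  clipz <- function(x) atanh(pmin(pmax(x, -(1 - 1e-7)), 1 - 1e-7))
  cor(clipz(fc_sim[ut]), clipz(fc_emp[ut]))
}

#' Absolute difference of mean FC
#'
#' `d = |mean(upper-tri fc_emp) - mean(upper-tri fc_sim)|` on raw
#' (untransformed) correlations.
#'
#' @inheritParams fc_agreement
#' @return Nonnegative scalar `d`.
#' @export
fc_mean_diff <- function(fc_sim, fc_emp, roi_mask = NULL) {
  if (!all(dim(fc_sim) == dim(fc_emp)))
    pfic_error("pfic_invalid_input", "FC shape mismatch")
  if (!is.null(roi_mask)) {
    fc_sim <- fc_sim[roi_mask, roi_mask, drop = FALSE]
    fc_emp <- fc_emp[roi_mask, roi_mask, drop = FALSE]
  }
  ut <- upper.tri(fc_sim)
  abs(mean(fc_emp[ut]) - mean(fc_sim[ut]))
}

#' Two-sample Kolmogorov-Smirnov distance
#'
#' Maximum distance between the empirical cumulative distribution functions
#' of two samples; no temporal correspondence between the samples is
#' assumed.
#'
#' @param entries_a,entries_b Non-empty numeric samples.
#' @return KS statistic in `[0, 1]`.
#' @export
ks_distance <- function(entries_a, entries_b) {
  if (length(entries_a) < 1 || length(entries_b) < 1)
    pfic_error("pfic_invalid_input", "empty sample")
  unname(suppressWarnings(ks.test(entries_a, entries_b)$statistic))
}

#' Composite model-fit cost
#'
#' `total = (1 - r) + d + KS` for candidates passing the firing-rate
#' validity gate; invalid candidates receive the penalty constant.
#'
#' @param r FC agreement (Pearson correlation on Fisher-z entries).
#' @param d Absolute FC mean difference.
#' @param ks KS distance between FCD-entry distributions.
#' @param valid Logical validity flag (firing-rate check passed).
#' @param penalty Cost assigned when `valid` is `FALSE` (default 10).
#' @param reason Optional character reason code for invalid candidates.
#' @return An object of class `cost_breakdown` with fields `r`, `d`, `ks`,
#'   `total`, `valid`.
#' @export
total_cost <- function(r, d, ks, valid = TRUE, penalty = 10,
                       reason = NULL) {
  if (isTRUE(valid)) {
    if (r < -1 || r > 1 || d < 0 || ks < 0 || ks > 1)
      pfic_error("pfic_invalid_input", "cost components out of range")
    total <- (1 - r) + d + ks
  } else {
    total <- penalty
  }
  structure(list(r = if (isTRUE(valid)) r else NA_real_,
                 d = if (isTRUE(valid)) d else NA_real_,
                 ks = if (isTRUE(valid)) ks else NA_real_,
                 total = total, valid = isTRUE(valid),
                 reason = reason), class = "cost_breakdown")
}

#' @export
print.cost_breakdown <- function(x, ...) {
  if (x$valid)
    cat(sprintf("<cost> total %.3f  (r = %.3f, d = %.3f, KS = %.3f)\n",
                x$total, x$r, x$d, x$ks))
  else
    cat(sprintf("<cost> invalid (penalty %.1f)%s\n", x$total,
                if (!is.null(x$reason)) paste0(" [", x$reason, "]") else ""))
  invisible(x)
}

#' Regional excitation-inhibition ratio
#'
#' The model-derived E/I marker: per region, the ratio of the temporal
#' average of the excitatory gating variable to that of the inhibitory one,
#' `EI_i = mean_t(S_E,i) / mean_t(S_I,i)`, with the cortical mean taken
#' over unmasked regions.
#'
#' @param result A [sim_result()].
#' @param roi_mask Optional logical mask for the cortical mean (regional
#'   values are reported for all regions).
#' @param provenance Optional identifier stored with the map.
#' @return An object of class `ei_map` with fields `regional_ei`,
#'   `cortical_mean`, `roi_mask`, `provenance`.
#' @export
ei_ratio <- function(result, roi_mask = NULL, provenance = NULL) {
  mSE <- result$mean_s_e; mSI <- result$mean_s_i
  if (any(mSI <= 0))
    pfic_error("pfic_invalid_input", "zero mean inhibitory gating")
  ei <- mSE / mSI
  roi_mask <- roi_mask %||% rep(TRUE, length(ei))
  structure(list(regional_ei = ei, cortical_mean = mean(ei[roi_mask]),
                 roi_mask = roi_mask,
                 provenance = provenance %||%
                   list(seed = result$seed, dt_s = result$dt_s)),
            class = "ei_map")
}

#' @export
print.ei_map <- function(x, ...) {
  cat(sprintf("<ei_map> %d regions, cortical mean E/I = %.3f\n",
              length(x$regional_ei), x$cortical_mean))
  invisible(x)
}
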