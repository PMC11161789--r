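# The pFIC parameterization: regional synaptic parameters (w_EE, w_EI,
# sigma) expressed as linear combinations of cortical annotation maps
# (T1w/T2w myelin proxy and principal FC gradient), plus the global
# coupling G. The two-map scheme has 3 x 3 = 9 linear coefficients and G,
# i.e. 10 search dimensions; single-map controls have 7 and the spatially
# homogeneous control has 4.

#' Default search bounds for expanded regional parameters
#'
#' Bounds keep candidates inside the dynamical regime where feedback
#' inhibition control is solvable: excitatory recurrence in `[1, 6]`,
#' excitatory-to-inhibitory coupling in `[1, 5]`, noise amplitude in
#' `[0.003, 0.01]`, global coupling in `[0, 3]`. Beyond an excitatory
#' recurrence of about 5-6 (at global coupling near 1) the network's
#' collective mode destabilizes and no ~3 Hz baseline state exists, so
#' the excitatory bound is kept below that transition. The noise floor
#' keeps the model in the noise-driven regime it is meant to describe:
#' near-deterministic candidates (noise an order of magnitude smaller)
#' reproduce static FC spuriously through pure structural coupling while
#' their fluctuation dynamics are degenerate.
#'
#' @return Named list of `(min, max)` pairs.
#' @export
default_bounds <- function() {
  list(w_ee = c(1, 6), w_ei = c(1, 5), sigma = c(0.003, 0.01), g = c(0, 3))
}

#' Parameterization scheme
#'
#' @param variant One of `"both_maps"` (myelin + gradient),
#'   `"gradient_only"`, `"myelin_only"`, `"homogeneous"`.
#' @param normalization `"zscore"` (maps standardized across regions before
#'   expansion) or `"none"`.
#' @param bounds Per-quantity search bounds, see [default_bounds()].
#' @return An object of class `parameterization_scheme`.
#' @export
parameterization_scheme <- function(variant = c("both_maps", "gradient_only",
                                                "myelin_only", "homogeneous"),
                                    normalization = c("zscore", "none"),
                                    bounds = default_bounds()) {
  variant <- match.arg(variant)
  normalization <- match.arg(normalization)
  maps_used <- switch(variant,
                      both_maps = c("myelin", "gradient"),
                      gradient_only = "gradient",
                      myelin_only = "myelin",
                      homogeneous = character(0))
  structure(list(variant = variant, normalization = normalization,
                 maps_used = maps_used, bounds = bounds),
            class = "parameterization_scheme")
}

#' Number of free search dimensions of a scheme
#'
#' Three linear coefficient sets (for w_EE, w_EI, sigma), each with one
#' intercept plus one coefficient per map, plus the global coupling G:
#' 10 for the two-map scheme, 7 for single-map schemes, 4 for the
#' homogeneous control.
#'
#' @param scheme A [parameterization_scheme()].
#' @return Integer dimension count.
#' @export
count_free_parameters <- function(scheme) {
  3L * (1L + length(scheme$maps_used)) + 1L
}

#' Names of the entries of a parameter vector under a scheme
#' @param scheme A [parameterization_scheme()].
#' @return Character vector, length [count_free_parameters()].
#' @export
parameter_vector_names <- function(scheme) {
  qty <- c("w_ee", "w_ei", "sigma")
  nms <- unlist(lapply(qty, function(q)
    c(paste0(q, "_b0"),
      paste0(q, "_b_", scheme$maps_used, recycle0 = TRUE))))
  c(nms, "g")
}

#' Standardize regional annotation maps
#'
#' In `"zscore"` mode each map is centered and scaled to unit standard
#' deviation across (unmasked) regions; constant maps are an error.
#'
#' @param maps A [regional_maps()].
#' @param mode `"zscore"` or `"none"`.
#' @param roi_mask Optional logical mask; statistics are computed over
#'   unmasked regions only (all regions are still transformed).
#' @return A [regional_maps()] with transformed maps.
#' @export
normalize_maps <- function(maps, mode = c("zscore", "none"), roi_mask = NULL) {
  mode <- match.arg(mode)
  if (mode == "none") return(maps)
  roi_mask <- roi_mask %||% rep(TRUE, maps$n_regions)
  out <- lapply(maps$maps, function(v) {
    mu <- mean(v[roi_mask]); s <- sd(v[roi_mask])
    if (!is.finite(s) || s < 1e-12)
      pfic_error("pfic_invalid_maps", "cannot z-score a constant map")
    (v - mu) / s
  })
  do.call(regional_maps, out)
}

#' Expand a low-dimensional parameter vector into regional parameters
#'
#' Applies the linear pFIC parameterization: for each quantity q in
#' \{w_EE, w_EI, sigma\}, `q_i = b0 + sum_m b_m * map_m[i]`, followed by
#' clipping into the scheme bounds. The inhibitory feedback weight `w_IE`
#' is left unset (solved later by [calibrate_fic()]); G is passed through
#' and clipped likewise.
#'
#' @param vec Numeric vector of length [count_free_parameters()], ordered
#'   as [parameter_vector_names()].
#' @param maps A [regional_maps()] (ignored for the homogeneous scheme);
#'   normalized according to the scheme before expansion.
#' @param scheme A [parameterization_scheme()].
#' @return A [regional_parameters()] with `w_ie = NULL`; attribute
#'   `"clipped"` is `TRUE` when any expanded value hit a bound.
#' @export
expand_parameters <- function(vec, maps, scheme) {
  p <- count_free_parameters(scheme)
  if (length(vec) != p)
    pfic_error("pfic_invalid_parameters",
               "parameter vector has length %d, scheme needs %d",
               length(vec), p)
  if (!all(is.finite(vec)))
    pfic_error("pfic_invalid_parameters", "non-finite parameter vector")
  nmaps <- length(scheme$maps_used)
  if (nmaps > 0) {
    maps <- normalize_maps(maps, scheme$normalization)
    M <- cbind(1, do.call(cbind, maps$maps[scheme$maps_used]))
    n <- maps$n_regions
  } else {
    if (!missing(maps) && !is.null(maps)) n <- maps$n_regions
    else pfic_error("pfic_invalid_parameters",
                    "homogeneous scheme still needs maps for n_regions")
    M <- matrix(1, n, 1)
  }
  k <- 1L + nmaps
  clipped <- FALSE
  clip <- function(x, b) {
    out <- pmin(pmax(x, b[1]), b[2])
    if (any(out != x)) clipped <<- TRUE
    out
  }
  vals <- lapply(seq_len(3), function(j) {
    beta <- vec[((j - 1L) * k + 1L):(j * k)]
    drop(M %*% beta)
  })
  if (!all(vapply(vals, function(v) all(is.finite(v)), logical(1))))
    pfic_error("pfic_invalid_parameters", "non-finite expanded parameters")
  b <- scheme$bounds
  out <- regional_parameters(w_ee = clip(vals[[1]], b$w_ee),
                             w_ei = clip(vals[[2]], b$w_ei),
                             sigma = clip(vals[[3]], b$sigma),
                             g = clip(vec[p], b$g))
  attr(out, "clipped") <- clipped
  out
}

#' Lower and upper search-space bounds for a scheme's coefficient vector
#'
#' Intercepts are bounded by the quantity bounds; map coefficients by
#' plus/minus half the quantity range (on z-scored maps); G by its own
#' bounds.
#'
#' @param scheme A [parameterization_scheme()].
#' @return List with numeric vectors `lower` and `upper`.
#' @export
scheme_search_bounds <- function(scheme) {
  b <- scheme$bounds
  k <- 1L + length(scheme$maps_used)
  lo <- hi <- numeric(0)
  for (q in c("w_ee", "w_ei", "sigma")) {
    r <- b[[q]]
    half <- (r[2] - r[1]) / 2
    lo <- c(lo, r[1], rep(-half, k - 1L))
    hi <- c(hi, r[2], rep(half, k - 1L))
  }
  list(lower = c(lo, b$g[1]), upper = c(hi, b$g[2]))
}

#' Default initial search vector for a scheme
#'
#' Intercepts at the midpoints of the quantity bounds, all map coefficients
#' zero, G = 1.
#'
#' @param scheme A [parameterization_scheme()].
#' @return Named numeric vector.
#' @export
initial_vector <- function(scheme) {
  b <- scheme$bounds
  k <- 1L + length(scheme$maps_used)
  v <- unlist(lapply(c("w_ee", "w_ei", "sigma"), function(q)
    c(mean(b[[q]]), rep(0, k - 1L))))
  v <- c(v, 1)
  setNames(v, parameter_vector_names(scheme))
}
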