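# Group-level statistics: age-bin construction, E/I-age regression,
# matched-performance contrasts, FDR correction, spatial spin tests,
# network summaries, permutation group tests, and covariate residualization.

#' Divide subjects into contiguous age groups with validation splits
#'
#' Subjects are sorted by age and divided into `n_groups` contiguous
#' groups of near-equal size (the first `n %% n_groups` groups take the
#' extra member). Within each group a fixed number of subjects is randomly
#' assigned to the validation set, the rest to training; the assignment is
#' reproducible by seed.
#'
#' @param subjects Data frame with columns `subject_id` and `age`.
#' @param n_groups Number of age groups (`<= nrow(subjects)`).
#' @param val_count Subjects per group assigned to validation (default 15);
#'   must be below the smallest group size.
#' @param seed Integer seed.
#' @return List of groups, each with `group_id`, `mean_age`, `members`
#'   (row indices), `train`, `validation`.
#' @export
bin_by_age <- function(subjects, n_groups, val_count = 15L, seed = 1L) {
  n <- nrow(subjects)
  if (n_groups > n)
    pfic_error("pfic_invalid_input", "more groups than subjects")
  if (anyDuplicated(subjects$subject_id))
    pfic_error("pfic_invalid_input", "duplicate subject ids")
  if (any(subjects$age <= 0))
    pfic_error("pfic_invalid_input", "ages must be positive")
  ord <- order(subjects$age)
  base <- n %/% n_groups
  extra <- n %% n_groups
  sizes <- rep(base, n_groups) + c(rep(1L, extra), rep(0L, n_groups - extra))
  if (val_count >= min(sizes))
    pfic_error("pfic_invalid_input",
               "validation count %d must be below the smallest group size %d",
               val_count, min(sizes))
  stops <- cumsum(sizes)
  starts <- c(1L, head(stops, -1L) + 1L)
  set.seed(seed)
  lapply(seq_len(n_groups), function(g) {
    members <- ord[starts[g]:stops[g]]
    val <- sort(sample(members, val_count))
    list(group_id = g, mean_age = mean(subjects$age[members]),
         members = members, train = setdiff(members, val),
         validation = val)
  })
}

#' Form age-matched high- and low-performance groups
#'
#' Splits subjects at the median of the performance score, divides each
#' half into `n_pairs` contiguous age-sorted groups, and pairs each high
#' group with the low group of nearest mean age (greedy, closest pairs
#' first). Reports the per-pair mean-age difference.
#'
#' @param subjects Data frame with `subject_id`, `age`, `performance`.
#' @param n_pairs Number of matched group pairs per side.
#' @param group_size Optional fixed group size; default divides each half
#'   evenly (sizes differing by at most one).
#' @return List of pairs, each with `high`, `low` (member row indices),
#'   `high_mean_age`, `low_mean_age`, `age_difference`.
#' @export
match_performance_groups <- function(subjects, n_pairs, group_size = NULL) {
  if (anyNA(subjects$performance) || anyNA(subjects$age))
    pfic_error("pfic_invalid_input", "performance and age must be complete")
  hi <- which(subjects$performance > median(subjects$performance))
  lo <- setdiff(seq_len(nrow(subjects)), hi)
  split_groups <- function(ids) {
    ids <- ids[order(subjects$age[ids])]
    n <- length(ids)
    if (!is.null(group_size)) {
      if (n_pairs * group_size > n)
        pfic_error("pfic_invalid_input", "insufficient subjects for %d groups of %d",
                   n_pairs, group_size)
      ids <- ids[seq_len(n_pairs * group_size)]
      n <- length(ids)
    }
    base <- n %/% n_pairs; extra <- n %% n_pairs
    sizes <- rep(base, n_pairs) + c(rep(1L, extra), rep(0L, n_pairs - extra))
    stops <- cumsum(sizes); starts <- c(1L, head(stops, -1L) + 1L)
    lapply(seq_len(n_pairs), function(g) ids[starts[g]:stops[g]])
  }
  hi_groups <- split_groups(hi)
  lo_groups <- split_groups(lo)
  hi_ages <- vapply(hi_groups, function(m) mean(subjects$age[m]), numeric(1))
  lo_ages <- vapply(lo_groups, function(m) mean(subjects$age[m]), numeric(1))
  # greedy pairing: repeatedly match the globally closest unmatched pair
  pairs <- vector("list", n_pairs)
  cost <- abs(outer(hi_ages, lo_ages, "-"))
  for (p in seq_len(n_pairs)) {
    k <- arrayInd(which.min(cost), dim(cost))
    i <- k[1]; j <- k[2]
    pairs[[p]] <- list(high = hi_groups[[i]], low = lo_groups[[j]],
                       high_mean_age = hi_ages[i], low_mean_age = lo_ages[j],
                       age_difference = abs(hi_ages[i] - lo_ages[j]))
    cost[i, ] <- Inf; cost[, j] <- Inf
  }
  pairs[order(vapply(pairs, function(p) p$high_mean_age, numeric(1)))]
}

#' Regress regional E/I ratio on group age
#'
#' Ordinary least squares of each region's E/I ratio on group mean age
#' (one point per group), plus the same regression for the cortical mean.
#' Two-sided p-values come from the slope t-statistic.
#'
#' @param mean_ages Numeric vector of group mean ages (years), length
#'   `>= 3`.
#' @param ei Matrix groups x regions of E/I estimates, or a list of
#'   `ei_map` objects.
#' @return List with `regional` (data.frame: slope, r, p per region) and
#'   `cortical` (slope, r, p for the cortical-mean E/I).
#' @export
ei_age_regression <- function(mean_ages, ei) {
  if (is.list(ei) && !is.matrix(ei))
    ei <- do.call(rbind, lapply(ei, function(m) m$regional_ei))
  if (length(mean_ages) != nrow(ei))
    pfic_error("pfic_invalid_input", "one age per group required")
  if (length(mean_ages) < 3)
    pfic_error("pfic_invalid_input", "need at least 3 groups")
  if (sd(mean_ages) < 1e-12)
    pfic_error("pfic_invalid_input", "constant age predictor")
  fit_one <- function(y) {
    fit <- lm(y ~ mean_ages)
    s <- summary(fit)$coefficients
    c(slope = unname(coef(fit)[2]), r = unname(cor(mean_ages, y)),
      p = if (nrow(s) > 1) unname(s[2, 4]) else NA_real_)
  }
  regional <- as.data.frame(t(apply(ei, 2, fit_one)))
  cortical <- fit_one(rowMeans(ei))
  list(regional = regional, cortical = as.list(cortical))
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' Step-up BH procedure at level `q`; also returns the adjusted p-values
#' from [stats::p.adjust()].
#'
#' @param pvals P-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return List with `reject` (logical), `adjusted`, `n_rejected`.
#' @export
fdr_correct <- function(pvals, q = 0.05) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE) || anyNA(pvals))
    pfic_error("pfic_invalid_input", "p-values must be in [0, 1], no NA")
  adj <- p.adjust(pvals, method = "BH")
  reject <- adj <= q
  list(reject = reject, adjusted = adj, n_rejected = sum(reject))
}

#' Paired contrast of regional E/I maps across matched group pairs
#'
#' Paired differences (high minus low) per region across matched pairs:
#' effect size is the paired Cohen's d (mean difference over the sd of
#' differences), significance the two-sided paired t-test. The cortical
#' means are contrasted likewise.
#'
#' @param high,low Equal-length lists of `ei_map` objects (or matrices
#'   pairs x regions), one entry per matched pair.
#' @return List with `regional` (data.frame: mean_diff, d, t, p),
#'   `cortical` (list: mean_diff, d, t, p), `n_pairs`, and
#'   `degenerate` (regions whose difference sd is zero; their d is
#'   signed infinity).
#' @export
paired_contrast <- function(high, low) {
  as_mat <- function(x) if (is.matrix(x)) x else
    do.call(rbind, lapply(x, function(m) m$regional_ei))
  H <- as_mat(high); L <- as_mat(low)
  if (!all(dim(H) == dim(L)))
    pfic_error("pfic_invalid_input", "high/low lists must pair up")
  if (nrow(H) < 2)
    pfic_error("pfic_invalid_input", "need at least 2 pairs")
  D <- H - L
  one <- function(dd) {
    m <- mean(dd); s <- sd(dd)
    if (s < 1e-15) {
      d_eff <- if (m == 0) 0 else sign(m) * Inf
      return(c(mean_diff = m, d = d_eff, t = d_eff,
               p = if (m == 0) 1 else 0))
    }
    tt <- t.test(dd)
    c(mean_diff = m, d = m / s, t = unname(tt$statistic),
      p = tt$p.value)
  }
  regional <- as.data.frame(t(apply(D, 2, one)))
  cortical <- as.list(one(rowMeans(H) - rowMeans(L)))
  list(regional = regional, cortical = cortical, n_pairs = nrow(D),
       degenerate = which(!is.finite(regional$d)))
}

# one random 3D rotation matrix (uniform via QR of a Gaussian matrix)
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# one-to-one greedy nearest-centroid assignment after rotating the
# centroids; preserves the multiset of map values
spin_permutation <- function(centroids, hemisphere) {
  perm <- integer(nrow(centroids))
  R_left <- random_rotation()
  M <- diag(c(-1, 1, 1))              # mirror across the midline plane
  R_right <- M %*% R_left %*% M
  for (h in c("L", "R")) {
    idx <- which(hemisphere == h)
    R <- if (h == "L") R_left else R_right
    rot <- centroids[idx, , drop = FALSE] %*% t(R)
    cost <- acos(pmin(pmax(tcrossprod(rot, centroids[idx, , drop = FALSE]),
                           -1), 1))
    assigned <- integer(length(idx))
    for (k in seq_along(idx)) {
      kk <- arrayInd(which.min(cost), dim(cost))
      assigned[kk[1]] <- kk[2]
      cost[kk[1], ] <- Inf; cost[, kk[2]] <- Inf
    }
    perm[idx] <- idx[assigned]
  }
  perm
}

#' Spatial spin test for map-to-map correlation
#'
#' Tests the correlation between two regional maps against a null that
#' preserves spatial autocorrelation: parcel centroids are rotated by a
#' random 3D rotation (mirrored across hemispheres), regions are
#' reassigned by one-to-one greedy nearest-centroid matching, and the
#' correlation is recomputed for each of `n_perm` rotations. The p-value
#' is `(1 + #(|null| >= |observed|)) / (1 + n_perm)` (two-tailed).
#'
#' @param map_a,map_b Numeric per-region vectors (complete).
#' @param centroids n x 3 unit-sphere centroid matrix.
#' @param hemisphere Per-region `"L"`/`"R"` labels.
#' @param n_perm Number of rotations (default 1000).
#' @param seed Integer seed.
#' @param method `"pearson"` or `"spearman"`.
#' @return List with `observed`, `p`, `null` (the null correlations).
#' @export
spin_test <- function(map_a, map_b, centroids, hemisphere, n_perm = 1000L,
                      seed = 1L, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (is.null(centroids))
    pfic_error("pfic_invalid_input", "centroids are required for spin test")
  if (anyNA(map_a) || anyNA(map_b))
    pfic_error("pfic_invalid_input", "maps must be complete")
  observed <- cor(map_a, map_b, method = method)
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i) {
    perm <- spin_permutation(centroids, hemisphere)
    cor(map_a[perm], map_b, method = method)
  }, numeric(1))
  p <- (1 + sum(abs(null) >= abs(observed))) / (1 + n_perm)
  list(observed = observed, p = p, null = null)
}

#' Per-network summary of a regional map
#'
#' @param map Numeric per-region vector.
#' @param network_label Integer labels 1-7, one per region, no NA.
#' @return List with `values` (per-network value lists), `summary`
#'   (data.frame: network, n, median, q25, q75, mean).
#' @export
network_summary <- function(map, network_label) {
  if (anyNA(network_label) || length(network_label) != length(map))
    pfic_error("pfic_invalid_input", "every region needs a network label")
  values <- split(map, factor(network_label, levels = sort(unique(network_label))))
  summary <- do.call(rbind, lapply(names(values), function(k) {
    v <- values[[k]]
    data.frame(network = as.integer(k), n = length(v),
               median = median(v), q25 = quantile(v, 0.25, names = FALSE),
               q75 = quantile(v, 0.75, names = FALSE), mean = mean(v))
  }))
  list(values = values, summary = summary)
}

#' Permutation test of a group difference in regional E/I
#'
#' The observed statistic is the regional E/I difference between the two
#' labeled groups as returned by the estimator. The null is built by
#' permuting the group labels (preserving group sizes) and re-running the
#' estimator; `p = (1 + #(|null| >= |observed|)) / (1 + n_perm)` per
#' region.
#'
#' @param subjects Subject table (data.frame).
#' @param labels Binary group labels (0/1), one per subject.
#' @param ei_estimator Function `(subjects_subset) -> regional E/I vector`;
#'   must be deterministic given its input.
#' @param n_perm Number of permutations (`>= 1`).
#' @param seed Integer seed.
#' @return List with `observed` (per-region difference, group 1 minus
#'   group 0), `p` (per-region), `null` (matrix n_perm x regions).
#' @export
permutation_group_test <- function(subjects, labels, ei_estimator,
                                   n_perm = 999L, seed = 1L) {
  if (n_perm < 1)
    pfic_error("pfic_invalid_input", "n_perm must be at least 1")
  labels <- as.integer(labels)
  stat <- function(lab) {
    ei_estimator(subjects[lab == 1L, , drop = FALSE]) -
      ei_estimator(subjects[lab == 0L, , drop = FALSE])
  }
  observed <- stat(labels)
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i) stat(sample(labels)),
                 numeric(length(observed)))
  null <- if (is.matrix(null)) t(null) else matrix(null, ncol = 1)
  p <- (1 + colSums(abs(null) >= matrix(abs(observed), n_perm,
                                        length(observed), byrow = TRUE))) /
    (1 + n_perm)
  list(observed = observed, p = p, null = null)
}

#' Residualize group-level values on a covariate
#'
#' OLS residuals of `values` on `covariate` plus intercept (e.g. removing
#' mean framewise displacement from group E/I estimates). Residuals have
#' zero mean and zero correlation with the covariate.
#'
#' @param values Numeric vector (or matrix with one column per region).
#' @param covariate Numeric vector, same length, non-constant.
#' @return Residuals with the same shape as `values`.
#' @export
covariate_residualize <- function(values, covariate) {
  v <- as.matrix(values)
  if (nrow(v) != length(covariate))
    pfic_error("pfic_invalid_input", "lengths differ")
  if (nrow(v) < 3)
    pfic_error("pfic_invalid_input", "need at least 3 points")
  if (sd(covariate) < 1e-12)
    pfic_error("pfic_invalid_input", "constant covariate")
  res <- residuals(lm(v ~ covariate))
  if (is.matrix(values)) unname(res) else unname(drop(res))
}
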