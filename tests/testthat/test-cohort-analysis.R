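# Group construction, regressions, FDR, contrasts, spin and permutation
# tests, residualization.

fake_subjects <- function(n, seed = 1, age_perf_cor = 0) {
  set.seed(seed)
  age <- runif(n, 8, 23)
  perf <- age_perf_cor * scale(age)[, 1] + rnorm(n)
  data.frame(subject_id = sprintf("s%04d", seq_len(n)), age = age,
             motion = runif(n, 0.05, 0.3), performance = perf)
}

test_that("age binning reproduces the 885-subject design and is seeded", {
  subj <- fake_subjects(885)
  groups <- bin_by_age(subj, 29, val_count = 15, seed = 3)
  sizes <- vapply(groups, function(g) length(g$members), integer(1))
  expect_true(all(sizes %in% c(30, 31)))
  expect_equal(sum(sizes == 31), 15)
  expect_equal(sum(sizes == 30), 14)
  expect_equal(sum(sizes), 885)
  # groups are contiguous in age
  ages <- vapply(groups, function(g) g$mean_age, numeric(1))
  expect_true(all(diff(ages) > 0))
  # validation splits have the fixed size and are reproducible
  expect_true(all(vapply(groups, function(g) length(g$validation),
                         integer(1)) == 15))
  groups2 <- bin_by_age(subj, 29, val_count = 15, seed = 3)
  expect_identical(groups, groups2)
  groups3 <- bin_by_age(subj, 29, val_count = 15, seed = 4)
  expect_false(identical(groups, groups3))

  # boundary: as many groups as subjects gives singletons
  tiny <- fake_subjects(29)
  singles <- bin_by_age(tiny, 29, val_count = 0, seed = 1)
  expect_true(all(vapply(singles, function(g) length(g$members),
                         integer(1)) == 1))
  expect_error(bin_by_age(tiny, 29, val_count = 15),
               class = "pfic_invalid_input")
})

test_that("performance matching yields age-matched pairs at the design
           counts", {
  subj <- fake_subjects(885, seed = 2, age_perf_cor = 0)
  pairs <- match_performance_groups(subj, 14)
  expect_length(pairs, 14)
  sizes <- unlist(lapply(pairs, function(p) c(length(p$high),
                                              length(p$low))))
  expect_true(all(sizes %in% c(31, 32)))
  # with age independent of performance the matching is tight
  expect_true(all(vapply(pairs, function(p) p$age_difference,
                         numeric(1)) < 0.5))

  # perfectly age-stratified toy input matches exactly
  toy <- data.frame(subject_id = sprintf("t%02d", 1:8),
                    age = rep(c(10, 12, 14, 16), 2),
                    performance = rep(c(-1, 1), each = 4))
  tp <- match_performance_groups(toy, 4)
  expect_true(all(vapply(tp, function(p) p$age_difference,
                         numeric(1)) == 0))
})

test_that("E/I-age regression recovers injected slopes and calibrates under
           permutation", {
  n_groups <- 29
  ages <- seq(9, 22, length.out = n_groups)
  # noiseless: exact recovery
  ei <- outer(rep(1, n_groups), rep(3, 8)) - 0.01 * ages
  fit <- ei_age_regression(ages, ei)
  expect_equal(fit$regional$slope, rep(-0.01, 8), tolerance = 1e-10)
  expect_equal(fit$regional$r, rep(-1, 8), tolerance = 1e-10)
  expect_equal(fit$cortical$slope, -0.01, tolerance = 1e-10)

  # noisy Monte-Carlo: slope sign recovered almost always
  set.seed(8)
  range_y <- diff(range(-0.01 * ages))
  hits <- mean(replicate(200, {
    y <- 3 - 0.01 * ages + rnorm(n_groups, sd = 0.2 * range_y)
    coef(lm(y ~ ages))[2] < 0
  }))
  expect_gte(hits, 0.95)

  # permuted ages: p approximately uniform, |r| small on average
  ps <- replicate(200, {
    y <- 3 - 0.01 * ages + rnorm(n_groups, sd = 0.2 * range_y)
    ei_age_regression(sample(ages), matrix(y))$cortical$p
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)

  expect_error(ei_age_regression(rep(10, 5), matrix(rnorm(5))),
               class = "pfic_invalid_input")
})

test_that("BH correction matches hand-computed thresholds", {
  out <- fdr_correct(c(0.01, 0.02, 0.03, 0.5), q = 0.05)
  # thresholds i/m * q = 0.0125, 0.025, 0.0375, 0.05
  expect_equal(out$n_rejected, 3)
  expect_equal(out$reject, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(fdr_correct(rep(1, 10))$n_rejected, 0)
  expect_true(fdr_correct(0.04, q = 0.05)$reject)
  expect_error(fdr_correct(c(0.5, 1.2)), class = "pfic_invalid_input")
})

test_that("paired contrasts report Cohen's d with degenerate guards", {
  set.seed(4)
  H <- matrix(rnorm(14 * 10, mean = 3), 14, 10)
  same <- paired_contrast(H, H)
  expect_equal(same$regional$d, rep(0, 10))
  expect_equal(same$regional$p, rep(1, 10))

  const <- paired_contrast(H + 0.3, H)
  expect_true(all(const$regional$d == Inf))
  expect_equal(const$degenerate, 1:10)

  L <- H - matrix(rnorm(140, 0.2, 0.1), 14, 10)
  out <- paired_contrast(H, L)
  dd <- H - L
  expect_equal(out$regional$d, colMeans(dd) / apply(dd, 2, sd),
               tolerance = 1e-12)
  expect_error(paired_contrast(H[1, , drop = FALSE], L[1, , drop = FALSE]),
               class = "pfic_invalid_input")
})

test_that("matched-pair simulations recover a rank-graded effect map", {
  fs <- fixture_spec(n_regions = 20, cohort_size = 200,
                     group_effect_sd = 0.05, subject_noise_sd = 0.05)
  set.seed(10)
  hits <- replicate(100, {
    fs$seed <- sample.int(1e6, 1)
    coh <- make_synthetic_cohort(fs)
    pairs <- match_performance_groups(coh$subjects, 7)
    Hm <- do.call(rbind, lapply(pairs, function(p)
      colMeans(coh$subject_ei[p$high, , drop = FALSE])))
    Lm <- do.call(rbind, lapply(pairs, function(p)
      colMeans(coh$subject_ei[p$low, , drop = FALSE])))
    # effect profile is graded negative along S-A rank, so the d map of
    # (low - high) increases along the rank
    d_map <- paired_contrast(Lm, Hm)$regional$d
    cor(d_map, coh$sa_rank, method = "spearman") > 0
  })
  expect_gte(mean(hits), 0.95)
})

test_that("spin permutations preserve values and detect self-correlation", {
  parc <- make_parcellation(68, seed = 2)
  maps <- make_synthetic_maps(parc, seed = 2)
  m <- maps$maps$myelin
  set.seed(12)
  perm <- pfic:::spin_permutation(parc$centroids, parc$hemisphere)
  expect_setequal(m[perm], m)          # relabeling invariant
  expect_setequal(perm, seq_along(m))  # one-to-one

  st <- spin_test(m, m, parc$centroids, parc$hemisphere, n_perm = 199,
                  seed = 1)
  expect_equal(st$observed, 1)
  expect_lt(st$p, 0.05)
  expect_true(all(st$null > 0 | st$null <= 1))

  st2 <- spin_test(m, m, parc$centroids, parc$hemisphere, n_perm = 199,
                   seed = 1)
  expect_identical(st$null, st2$null)
  expect_error(spin_test(m, m, NULL, parc$hemisphere),
               class = "pfic_invalid_input")
})

test_that("network summaries partition the regions", {
  labels <- rep(1:7, length.out = 21)
  const <- network_summary(rep(2.5, 21), labels)
  expect_true(all(const$summary$median == 2.5))
  idx <- network_summary(as.numeric(labels), labels)
  expect_equal(idx$summary$median, as.numeric(1:7))
  expect_equal(sort(unname(unlist(idx$values))), sort(as.numeric(labels)))
  expect_error(network_summary(rnorm(3), c(1, NA, 2)),
               class = "pfic_invalid_input")
})

test_that("permutation group tests calibrate and detect injected effects", {
  subj <- fake_subjects(60, seed = 6)
  labels <- rep(c(0L, 1L), 30)
  const_est <- function(s) c(1.5, 2.0)
  out <- permutation_group_test(subj, labels, const_est, n_perm = 99,
                                seed = 1)
  expect_equal(out$p, c(1, 1))

  # injected mean difference in a covariate is detected
  subj$covar <- rnorm(60) + 2 * labels
  mean_est <- function(s) mean(s$covar)
  out2 <- permutation_group_test(subj, labels, mean_est, n_perm = 199,
                                 seed = 1)
  expect_lte(out2$p, 0.01)

  # exchangeable null: p approximately uniform across replicates
  set.seed(7)
  ps <- replicate(150, {
    subj$covar <- rnorm(60)
    permutation_group_test(subj, labels, mean_est, n_perm = 39,
                           seed = sample.int(1e6, 1))$p
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
  expect_true(all(ps > 0 & ps <= 1))
})

test_that("covariate residualization is orthogonal and centered", {
  set.seed(13)
  cov <- rnorm(29)
  vals <- 0.5 * cov + rnorm(29)
  res <- covariate_residualize(vals, cov)
  expect_lt(abs(mean(res)), 1e-10)
  expect_lt(abs(sum(res * cov)), 1e-10)

  expect_lt(max(abs(covariate_residualize(2 * cov, cov))), 1e-10)

  orth <- rnorm(29)
  cc <- cov - mean(cov)
  orth <- orth - cc * sum(orth * cc) / sum(cc^2)
  expect_equal(covariate_residualize(orth, cov), orth - mean(orth),
               tolerance = 1e-8)
  expect_error(covariate_residualize(vals, rep(1, 29)),
               class = "pfic_invalid_input")
})
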