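# BOLD forward model, FC/FCD observables, cost combiner, E/I ratio.

test_that("hemodynamics relax to rest and respond monotonically", {
  dt <- 0.01
  # constant drive: BOLD converges to a constant
  s_e <- matrix(0.15, 6000, 3)
  b <- balloon_windkessel(s_e, dt, tr_s = 1)
  tail_frames <- b$data[round(0.8 * nrow(b$data)):nrow(b$data), ]
  expect_lt(max(apply(tail_frames, 2, var)), 1e-10)

  # zero drive: states relax to (f, v, q) = 1
  out <- pfic:::cpp_balloon_windkessel(matrix(0, 6000, 2), dt, 100L,
                                       hemodynamic_constants())
  expect_lt(max(abs(c(out$f, out$v, out$q) - 1)), 1e-6)

  # doubling a constant drive moves steady-state BOLD in one direction
  b1 <- balloon_windkessel(matrix(0.1, 6000, 3), dt, 1)
  b2 <- balloon_windkessel(matrix(0.2, 6000, 3), dt, 1)
  diffs <- b2$data[nrow(b2$data), ] - b1$data[nrow(b1$data), ]
  expect_true(all(diffs > 0) || all(diffs < 0))
})

test_that("static FC matches a two-pass correlation oracle and flags
           degenerate input", {
  x <- rnorm(100)
  ts <- bold_timeseries(cbind(x, x, -x), 1)
  fc <- static_fc(ts)
  expect_equal(fc[1, 2], 1)
  expect_equal(fc[1, 3], -1)

  set.seed(5)
  X <- matrix(rnorm(500), 100, 5)
  # hand-rolled covariance / outer-sd oracle
  Xc <- sweep(X, 2, colMeans(X))
  cv <- crossprod(Xc) / (nrow(X) - 1)
  sds <- sqrt(diag(cv))
  oracle <- cv / tcrossprod(sds)
  expect_equal(static_fc(bold_timeseries(X, 1)), oracle, tolerance = 1e-12)

  X[, 2] <- 1
  expect_error(static_fc(bold_timeseries(X, 1)),
               class = "pfic_zero_variance")
})

test_that("FCD windows slide at stride one with the documented count", {
  set.seed(1)
  ts <- bold_timeseries(matrix(rnorm(50 * 6), 50, 6), 1)
  out <- fcd_matrix(ts, 10)
  expect_equal(out$n_windows, 41)
  expect_equal(dim(out$fcd), c(41, 41))
  expect_equal(diag(out$fcd), rep(1, 41))
  expect_lt(max(abs(out$fcd - t(out$fcd))), 1e-12)

  # boundary: window = frames - 1 gives a 2 x 2 FCD
  out2 <- fcd_matrix(ts, 49)
  expect_equal(out2$n_windows, 2)
  expect_equal(dim(out2$fcd), c(2, 2))

  expect_error(fcd_matrix(ts, 50), class = "pfic_invalid_input")

  # periodic block structure reappears at lags equal to the period
  block <- matrix(rnorm(20 * 6), 20, 6)
  per <- bold_timeseries(do.call(rbind, rep(list(block), 4)), 1)
  f <- fcd_matrix(per, 10)$fcd
  lag20 <- f[cbind(seq_len(nrow(f) - 20), seq_len(nrow(f) - 20) + 20)]
  expect_true(all(lag20 > 0.9))
})

test_that("FC agreement uses Fisher z and the mean difference stays raw", {
  set.seed(2)
  X <- matrix(rnorm(200 * 6), 200, 6)
  fc1 <- static_fc(bold_timeseries(X, 1))
  fc2 <- static_fc(bold_timeseries(X + rnorm(length(X)), 1))
  expect_equal(fc_agreement(fc1, fc1), 1.0)
  neg <- -fc2; diag(neg) <- 1
  expect_equal(fc_agreement(fc2, neg), -1.0)

  # two-pass oracle on the z-transformed upper triangles
  ut <- upper.tri(fc1)
  z <- function(v) atanh(pmin(pmax(v, -(1 - 1e-7)), 1 - 1e-7))
  a <- z(fc1[ut]); b <- z(fc2[ut])
  oracle <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(fc_agreement(fc1, fc2), oracle, tolerance = 1e-12)

  expect_equal(fc_mean_diff(fc1, fc1), 0)
  c1 <- matrix(0.5, 4, 4); diag(c1) <- 1
  c2 <- matrix(0.3, 4, 4); diag(c2) <- 1
  expect_equal(fc_mean_diff(c2, c1), 0.2)
  perm <- c(3, 1, 4, 2)
  expect_equal(fc_mean_diff(c2[perm, perm], c1[perm, perm]),
               fc_mean_diff(c2, c1))
})

test_that("KS distance equals the brute-force ECDF enumeration", {
  expect_equal(ks_distance(c(0.1, 0.5, 0.9), c(0.1, 0.5, 0.9)), 0)
  expect_equal(ks_distance(c(0.1, 0.2), c(0.8, 0.9)), 1)

  brute <- function(a, b) {
    grid <- sort(unique(c(a, b)))
    max(abs(vapply(grid, function(g) mean(a <= g) - mean(b <= g),
                   numeric(1))))
  }
  expect_equal(ks_distance(c(0.1, 0.2, 0.3), c(0.2, 0.3, 0.4)), 1 / 3)
  expect_equal(brute(c(0.1, 0.2, 0.3), c(0.2, 0.3, 0.4)), 1 / 3)
  set.seed(3)
  for (i in 1:5) {
    a <- runif(40, -1, 1); b <- rnorm(25, 0.2, 0.4)
    expect_equal(ks_distance(a, b), brute(a, b), tolerance = 1e-12)
    expect_equal(ks_distance(a, b), ks_distance(b, a))
  }
  expect_error(ks_distance(numeric(0), 1), class = "pfic_invalid_input")
})

test_that("the cost combiner follows (1 - r) + d + KS with penalty for
           invalid candidates and is monotone", {
  expect_equal(total_cost(1, 0, 0)$total, 0)
  expect_equal(total_cost(0.71, 0.11, 0.18)$total, 0.58, tolerance = 1e-12)
  inv <- total_cost(NA, NA, NA, valid = FALSE)
  expect_equal(inv$total, 10)
  expect_false(inv$valid)

  base <- total_cost(0.5, 0.1, 0.2)$total
  expect_gt(total_cost(0.4, 0.1, 0.2)$total, base)
  expect_gt(total_cost(0.5, 0.2, 0.2)$total, base)
  expect_gt(total_cost(0.5, 0.1, 0.3)$total, base)
  expect_error(total_cost(1.5, 0, 0), class = "pfic_invalid_input")
})

test_that("E/I ratio is the ratio of gating time means, with masking and
           stationarity invariance", {
  n <- 6
  res <- sim_result(s_e = matrix(0.15, 50, n), s_i = matrix(0.30, 50, n))
  ei <- ei_ratio(res)
  expect_equal(ei$regional_ei, rep(0.5, n))
  expect_equal(ei$cortical_mean, 0.5)

  vals <- seq(0.1, 0.6, length.out = n)
  res2 <- sim_result(s_e = matrix(vals, 50, n, byrow = TRUE),
                     s_i = matrix(0.2, 50, n))
  mask <- c(rep(TRUE, 3), rep(FALSE, 3))
  expect_equal(ei_ratio(res2, mask)$cortical_mean, mean(vals[1:3] / 0.2))

  # retained-sample count does not matter for stationary input
  res3 <- sim_result(s_e = matrix(vals, 500, n, byrow = TRUE),
                     s_i = matrix(0.2, 500, n))
  expect_equal(ei_ratio(res3)$regional_ei, ei_ratio(res2)$regional_ei)

  expect_error(ei_ratio(sim_result(s_e = matrix(0.1, 5, 2),
                                   s_i = matrix(0, 5, 2))),
               class = "pfic_invalid_input")
})
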