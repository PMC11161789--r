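# CMA-ES search, candidate evaluation gate, and the selection protocol.

test_that("CMA-ES minimizes the 10-D sphere and records every candidate", {
  sphere <- function(v, i) sum(v^2)
  prot <- fit_protocol(candidate_budget = 500L, top_k = 10L,
                       population = 8L, sigma0 = 0.2,
                       polish_fraction = 0, seed = 1L)
  rec <- cmaes_search(rep(1, 10), rep(-5, 10), rep(5, 10), sphere, prot)
  expect_length(rec, 500)
  best <- min(vapply(rec, function(r) r$training_cost$total, numeric(1)))
  expect_lt(best, 1e-2)

  # with a longer budget the optimizer closes in on the analytic optimum
  prot2 <- fit_protocol(2000L, 10L, population = 10L, sigma0 = 0.3,
                        polish_fraction = 0, seed = 1L)
  rec2 <- cmaes_search(rep(3, 10), rep(-5, 10), rep(5, 10), sphere, prot2)
  best2 <- min(vapply(rec2, function(r) r$training_cost$total, numeric(1)))
  expect_lt(best2, 1e-6)

  # deterministic under the protocol seed
  rec3 <- cmaes_search(rep(1, 10), rep(-5, 10), rep(5, 10), sphere, prot)
  expect_equal(vapply(rec, function(r) r$training_cost$total, numeric(1)),
               vapply(rec3, function(r) r$training_cost$total, numeric(1)))

  # budget 250 (the per-condition protocol) is honored exactly
  rec4 <- cmaes_search(rep(1, 10), rep(-5, 10), rep(5, 10), sphere,
                       fit_protocol(250L, 1L, population = 16L, seed = 2L))
  expect_length(rec4, 250)
})

test_that("the search aborts when every candidate stays invalid", {
  always_invalid <- function(v, i) total_cost(NA, NA, NA, valid = FALSE)
  expect_error(
    cmaes_search(rep(0, 4), rep(-1, 4), rep(1, 4), always_invalid,
                 fit_protocol(200L, 1L, population = 8L, seed = 1L)),
    class = "pfic_search_degenerate")
})

test_that("top-k selection ranks by validation cost with deterministic
           tie-breaks and order invariance", {
  mk_rec <- function(i, train) structure(
    list(vector = c(i, 0), training_cost = total_cost(1 - train, 0, 0),
         index = i, generation = 1L), class = "candidate_record")
  recs <- lapply(1:6, function(i) mk_rec(i, train = i / 10))
  val_lookup <- c(0.5, 0.2, 0.9, 0.2, 0.1, 0.7)
  evaluator <- function(vec) total_cost(1 - val_lookup[vec[1]], 0, 0)

  top1 <- select_top_k(recs, 1, evaluator)
  expect_equal(top1[[1]]$index, 5)

  full <- select_top_k(recs, 6, evaluator)
  expect_setequal(vapply(full, function(r) r$index, numeric(1)), 1:6)
  # tie between candidates 2 and 4 broken by training cost (2 has lower)
  ranks <- vapply(full, function(r) r$index, numeric(1))
  expect_lt(which(ranks == 2), which(ranks == 4))

  shuffled <- select_top_k(recs[c(4, 1, 6, 3, 2, 5)], 3, evaluator)
  expect_equal(vapply(shuffled, function(r) r$index, numeric(1)),
               vapply(select_top_k(recs, 3, evaluator),
                      function(r) r$index, numeric(1)))

  # fewer than k valid candidates returns all valid with a warning
  ev2 <- function(vec) if (vec[1] <= 2) total_cost(0.5, 0.1, 0.1) else
    total_cost(NA, NA, NA, valid = FALSE)
  expect_warning(kept <- select_top_k(recs, 4, ev2), "valid")
  expect_length(kept, 2)
})

test_that("generalization summaries recombine linearly", {
  mk_rec <- function(i) structure(
    list(vector = i, training_cost = total_cost(0.5, 0.1, 0.1),
         index = i, generation = 1L), class = "candidate_record")
  rs <- c(0.70, 0.72, 0.71); ds <- c(0.10, 0.12, 0.11)
  kss <- c(0.17, 0.19, 0.18)
  evaluator <- function(vec) total_cost(rs[vec], ds[vec], kss[vec])
  out <- evaluate_generalization(lapply(1:3, mk_rec), evaluator)
  s <- out$summary
  expect_equal(s$total[["mean"]],
               (1 - s$r[["mean"]]) + s$d[["mean"]] + s$ks[["mean"]],
               tolerance = 1e-12)
  expect_equal(s$r[["mean"]], 0.71, tolerance = 1e-12)
  expect_equal(s$total[["mean"]], 0.58, tolerance = 1e-12)

  single <- evaluate_generalization(list(mk_rec(1)),
                                    function(vec) total_cost(0.7, 0.1, 0.2))
  expect_equal(single$summary$total[["sd"]], 0)
})

test_that("candidate evaluation gates on firing rates and reports reasons", {
  conn <- small_connectome()
  maps <- small_maps()
  scheme <- parameterization_scheme()
  set.seed(21)
  X <- matrix(rnorm(80 * 12), 80, 12)
  target <- fit_target(static_fc(bold_timeseries(X, 0.72)),
                       fcd_entries(fcd_matrix(bold_timeseries(X, 0.72), 20)),
                       window_frames = 20, n_frames = 80, tr_seconds = 0.72)
  run <- run_config(dt_s = 0.002, burn_in_s = 5, duration_s = 100,
                    bold_drop_frames = 5L)
  cb <- evaluate_candidate(initial_vector(scheme), maps, scheme, conn,
                           target, run, seed = 5L)
  expect_s3_class(cb, "cost_breakdown")
  expect_true(cb$valid)
  expect_true(cb$total >= 0)

  # reproducibility: same vector, same seeds, identical breakdown
  cb2 <- evaluate_candidate(initial_vector(scheme), maps, scheme, conn,
                            target, run, seed = 5L)
  expect_equal(cb, cb2)

  # an unattainably tight gate turns the candidate into a penalty case
  tight <- run_config(dt_s = 0.002, burn_in_s = 5, duration_s = 100,
                      rate_bounds_hz = c(2.999, 3.001),
                      bold_drop_frames = 5L)
  cb3 <- evaluate_candidate(initial_vector(scheme), maps, scheme, conn,
                            target, tight, seed = 5L)
  expect_false(cb3$valid)
  expect_equal(cb3$total, 10)
  expect_equal(cb3$reason, "firing_rate")

  # a candidate that cannot be calibrated is rejected with its reason
  v_bad <- initial_vector(scheme)
  v_bad["w_ee_b0"] <- 6; v_bad["g"] <- 3
  cb4 <- evaluate_candidate(v_bad, maps, scheme, conn, target, run,
                            seed = 5L)
  expect_false(cb4$valid)
  expect_true(cb4$reason %in% c("calibration", "firing_rate"))
})
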