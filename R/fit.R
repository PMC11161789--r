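# Candidate evaluation and the train/validation/test selection protocol.

#' Evaluate a candidate coefficient vector against a fit target
#'
#' Runs the full forward pipeline: expand the vector into regional
#' parameters, calibrate feedback inhibition, integrate the stochastic
#' model for the target's scan duration (plus burn-in and hemodynamic
#' transient), gate on the firing-rate acceptance bounds, convert to BOLD,
#' compute FC and FCD restricted to the target's ROI mask, and combine the
#' cost components. Candidates that fail calibration or the firing-rate
#' gate receive the penalty cost with `valid = FALSE` and a reason code.
#'
#' @param vec Coefficient vector (length matching `scheme`).
#' @param maps A [regional_maps()].
#' @param scheme A [parameterization_scheme()].
#' @param conn A [connectome()].
#' @param target A [fit_target()].
#' @param run A [run_config()].
#' @param seed Simulation seed (one fixed seed per protocol phase).
#' @param constants,hemo Model constants.
#' @return A [total_cost()] breakdown.
#' @export
evaluate_candidate <- function(vec, maps, scheme, conn, target, run, seed,
                               constants = neural_constants(),
                               hemo = hemodynamic_constants()) {
  pars <- tryCatch(expand_parameters(vec, maps, scheme),
                   error = function(e) NULL)
  if (is.null(pars))
    return(total_cost(NA, NA, NA, valid = FALSE, penalty = run$penalty,
                      reason = "expansion"))
  cal <- tryCatch(
    calibrate_fic(pars, conn, constants, target_hz = run$target_hz,
                  dt_s = run$dt_s),
    error = function(e) NULL)
  if (is.null(cal)) {
    cb <- total_cost(NA, NA, NA, valid = FALSE, penalty = run$penalty,
                     reason = "calibration")
    attr(cb, "violation") <- 1e3 # ranks below every firing-rate failure
    return(cb)
  }
  drop_frames <- run$bold_drop_frames %||%
    as.integer(ceiling(30 / target$tr_seconds))
  duration <- run$burn_in_s +
    (target$n_frames + drop_frames) * target$tr_seconds
  sim <- tryCatch(
    simulate_fic(cal, conn, constants, duration_s = duration,
                 dt_s = run$dt_s, burn_in_s = run$burn_in_s, seed = seed,
                 tr_s = target$tr_seconds, hemo = hemo),
    error = function(e) NULL)
  if (is.null(sim) || is.null(sim$bold))
    return(total_cost(NA, NA, NA, valid = FALSE, penalty = run$penalty,
                      reason = "simulation"))
  gate <- check_firing_rates(sim, run$rate_bounds_hz)
  if (!gate$ok) {
    cb <- total_cost(NA, NA, NA, valid = FALSE, penalty = run$penalty,
                     reason = "firing_rate")
    # graded infeasibility (worst regional deviation from the band, Hz):
    # lets the search rank rejected candidates among themselves
    attr(cb, "violation") <- max(pmax(gate$means - run$rate_bounds_hz[2],
                                      run$rate_bounds_hz[1] - gate$means))
    return(cb)
  }
  bold <- bold_timeseries(
    sim$bold$data[-seq_len(drop_frames), , drop = FALSE],
    target$tr_seconds)
  res <- tryCatch({
    fc_sim <- static_fc(bold, target$roi_mask)
    fcd_sim <- fcd_matrix(bold, target$window_frames, target$roi_mask)
    fc_emp <- target$fc[target$roi_mask, target$roi_mask, drop = FALSE]
    r <- fc_agreement(fc_sim, fc_emp)
    d <- fc_mean_diff(fc_sim, fc_emp)
    ks <- ks_distance(fcd_entries(fcd_sim), target$fcd_entries)
    total_cost(r, d, ks, valid = TRUE, penalty = run$penalty)
  }, error = function(e) total_cost(NA, NA, NA, valid = FALSE,
                                    penalty = run$penalty,
                                    reason = "observables"))
  res
}

#' Rank candidates on a validation target and keep the best k
#'
#' Evaluates every record with the supplied validation evaluator, sorts
#' ascending by validation total cost (ties broken by training cost, then
#' by candidate index), and returns the first `k`. The ranking is
#' invariant to the input ordering of the records.
#'
#' @param records List of candidate records from [cmaes_search()].
#' @param k Number of candidates to keep.
#' @param evaluator Function `(vector) -> cost_breakdown` on the
#'   validation target (fixed validation seed).
#' @param skip_invalid Candidates already invalid on training keep their
#'   penalty cost without re-simulation (they can never rank); set `FALSE`
#'   to force re-evaluation.
#' @return Ranked sublist of records, each with `validation_cost` added.
#' @export
select_top_k <- function(records, k, evaluator, skip_invalid = TRUE) {
  if (length(records) == 0 || k < 1)
    pfic_error("pfic_invalid_input", "need non-empty records and k >= 1")
  records <- lapply(records, function(rec) {
    rec$validation_cost <-
      if (skip_invalid && !isTRUE(rec$training_cost$valid) &&
          !is.na(rec$training_cost$total))
        rec$training_cost
      else evaluator(rec$vector)
    rec
  })
  val <- vapply(records, function(r) r$validation_cost$total, numeric(1))
  trn <- vapply(records, function(r) r$training_cost$total, numeric(1))
  idx <- vapply(records, function(r) r$index, numeric(1))
  ord <- order(val, trn, idx)
  valid <- vapply(records, function(r) isTRUE(r$validation_cost$valid),
                  logical(1))
  if (sum(valid) < k) {
    warning(sprintf("only %d of %d candidates valid on validation; returning all valid",
                    sum(valid), length(records)))
    ord <- ord[valid[ord]]
    return(records[ord])
  }
  records[ord[seq_len(k)]]
}

#' Evaluate selected candidates on the test target
#'
#' @param selected Records from [select_top_k()].
#' @param evaluator Function `(vector) -> cost_breakdown` on the test
#'   target (fixed test seed).
#' @return List with `records` (each gaining `test_cost`) and `summary`
#'   (mean and sd of r, d, KS and total across valid test evaluations).
#' @export
evaluate_generalization <- function(selected, evaluator) {
  if (length(selected) == 0)
    pfic_error("pfic_invalid_input", "no selected candidates")
  selected <- lapply(selected, function(rec) {
    rec$test_cost <- evaluator(rec$vector)
    rec
  })
  comp <- function(f) vapply(selected, function(r) r$test_cost[[f]],
                             numeric(1))
  valid <- vapply(selected, function(r) isTRUE(r$test_cost$valid),
                  logical(1))
  summ <- lapply(c(r = "r", d = "d", ks = "ks", total = "total"),
                 function(f) {
                   x <- comp(f)[valid]
                   c(mean = mean(x), sd = if (length(x) > 1) sd(x) else 0)
                 })
  list(records = selected, summary = summ, n_valid = sum(valid))
}

#' Fit the pFIC model with the full selection protocol
#'
#' Runs CMA-ES on the training target, re-evaluates every recorded
#' candidate on the validation target, keeps the top k, and scores them on
#' the test target — the train/validation/test protocol of the method.
#' Each phase uses its own fixed simulation seed from `run$seeds`.
#'
#' @param conn A [connectome()].
#' @param maps A [regional_maps()].
#' @param scheme A [parameterization_scheme()].
#' @param targets Named list of [fit_target()]s: `train`, `validation`,
#'   and optionally `test`.
#' @param run A [run_config()].
#' @param protocol A [fit_protocol()].
#' @param constants,hemo Model constants.
#' @param verbose Print per-generation progress.
#' @return List with `records`, `selected`, `generalization` (NULL when no
#'   test target), and the inputs used.
#' @export
fit_pfic <- function(conn, maps, scheme, targets, run = run_config(),
                     protocol = fit_protocol(),
                     constants = neural_constants(),
                     hemo = hemodynamic_constants(), verbose = FALSE) {
  if (!all(c("train", "validation") %in% names(targets)))
    pfic_error("pfic_invalid_input", "targets must include train and validation")
  sb <- scheme_search_bounds(scheme)
  seeds <- vapply(run$seeds, as.integer, integer(1))
  mk_eval <- function(target, seed) function(vec, ...)
    evaluate_candidate(vec, maps, scheme, conn, target, run, seed,
                       constants, hemo)
  train_eval <- mk_eval(targets$train, seeds[["train"]])
  objective <- function(vec, idx) {
    cb <- train_eval(vec)
    if (verbose && idx %% protocol$population == 0)
      message(sprintf("candidate %d: cost %.3f%s", idx, cb$total,
                      if (!cb$valid) " (invalid)" else ""))
    cb
  }
  records <- cmaes_search(initial_vector(scheme), sb$lower, sb$upper,
                          objective, protocol)
  pool <- records
  if (is.finite(protocol$validation_pool) &&
      protocol$validation_pool < length(records)) {
    trn <- vapply(records, function(r) r$training_cost$total, numeric(1))
    pool <- records[order(trn)[seq_len(protocol$validation_pool)]]
  }
  selected <- select_top_k(pool, protocol$top_k,
                           mk_eval(targets$validation,
                                   seeds[["validation"]]))
  generalization <- NULL
  if (!is.null(targets$test))
    generalization <- evaluate_generalization(
      selected, mk_eval(targets$test, seeds[["test"]]))
  list(records = records, selected = selected,
       generalization = generalization, scheme = scheme, run = run,
       protocol = protocol)
}
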