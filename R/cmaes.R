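# Covariance matrix adaptation evolution strategy (CMA-ES), the
# derivative-free optimizer used to fit the pFIC coefficient vector.
# Standard (mu/mu_w, lambda) formulation with rank-one and rank-mu
# covariance updates and cumulative step-size adaptation; box constraints
# are handled by projecting sampled candidates onto the feasible box
# before evaluation.

#' Fit protocol settings
#'
#' @param candidate_budget Total number of candidate evaluations recorded
#'   (e.g. 500 for the main protocol, 250 for the per-group protocols).
#' @param top_k Candidates carried from validation to test (10 or 1).
#' @param population CMA-ES population size per generation.
#' @param sigma0 Initial global step size, as a fraction of each
#'   coordinate's bound range (diagonal scaling).
#' @param restart_after Generations with relative improvement of the best
#'   cost below 0.1% before the strategy restarts from a fresh random mean
#'   (all evaluated candidates stay recorded); `Inf` (default) disables
#'   restarts.
#' @param validation_pool Number of best-training candidates re-evaluated
#'   on the validation target during selection; `Inf` (default) evaluates
#'   every recorded candidate. A finite pool (e.g. 50) is a desk-scale
#'   shortcut: candidates far down the training ranking essentially never
#'   win the validation ranking.
#' @param polish_fraction Fraction of the budget reserved for an
#'   exploitation phase: the strategy restarts from the best candidate
#'   found so far with a third of the initial step size and a reset
#'   covariance. 0 disables the phase.
#' @param seed Integer seed for the search.
#' @return An object of class `fit_protocol`.
#' @export
fit_protocol <- function(candidate_budget = 500L, top_k = 10L,
                         population = 8L, sigma0 = 0.2,
                         restart_after = Inf, validation_pool = Inf,
                         polish_fraction = 0.4, seed = 1L) {
  if (top_k > candidate_budget)
    pfic_error("pfic_invalid_config", "top_k cannot exceed candidate_budget")
  if (candidate_budget < population)
    pfic_error("pfic_invalid_config", "budget must cover one generation")
  structure(list(candidate_budget = as.integer(candidate_budget),
                 top_k = as.integer(top_k),
                 population = as.integer(population), sigma0 = sigma0,
                 restart_after = restart_after,
                 validation_pool = validation_pool,
                 polish_fraction = polish_fraction,
                 seed = as.integer(seed)), class = "fit_protocol")
}

#' CMA-ES search over a bounded parameter space
#'
#' Minimizes `objective` over the box `[lower, upper]`, recording every
#' evaluated candidate until the budget is exhausted. The objective must
#' return either a plain number or a [total_cost()] breakdown; penalty
#' (invalid) evaluations participate in ranking like any other value.
#' When the best cost stops improving for `protocol$restart_after`
#' generations the strategy restarts from a fresh random mean with the
#' initial step size (the budget keeps counting and every candidate stays
#' recorded), which guards against stagnation in deceptive or
#' penalty-flat regions. Deterministic given `protocol$seed`.
#'
#' @param initial Numeric start vector (length d).
#' @param lower,upper Box constraints (length d).
#' @param objective Function `(vector, index) -> cost_breakdown | numeric`.
#' @param protocol A [fit_protocol()].
#' @return List of candidate records (class `candidate_record`): fields
#'   `vector`, `training_cost`, `index`, `generation`.
#' @export
cmaes_search <- function(initial, lower, upper, objective,
                         protocol = fit_protocol()) {
  d <- length(initial)
  stopifnot(length(lower) == d, length(upper) == d)
  lam <- protocol$population
  mu <- floor(lam / 2)
  # active CMA: positive weights for the better half, negative for the rest
  w_raw <- log((lam + 1) / 2) - log(seq_len(lam))
  w_pos <- w_raw[seq_len(mu)] / sum(w_raw[seq_len(mu)])
  mu_eff <- 1 / sum(w_pos^2)
  neg <- w_raw[(mu + 1):lam]
  mu_eff_neg <- sum(neg)^2 / sum(neg^2)
  cc <- (4 + mu_eff / d) / (d + 4 + 2 * mu_eff / d)
  cs <- (mu_eff + 2) / (d + mu_eff + 5)
  c1 <- 2 / ((d + 1.3)^2 + mu_eff)
  cmu <- min(1 - c1, 2 * (mu_eff - 2 + 1 / mu_eff) / ((d + 2)^2 + mu_eff))
  a_neg <- min(1 + c1 / cmu, 1 + 2 * mu_eff_neg / (mu_eff + 2),
               (1 - c1 - cmu) / (d * cmu))
  w_neg <- a_neg * neg / sum(abs(neg))
  w_all <- c(w_pos, w_neg)
  damps <- 1 + 2 * max(0, sqrt((mu_eff - 1) / (d + 1)) - 1) + cs
  chiN <- sqrt(d) * (1 - 1 / (4 * d) + 1 / (21 * d^2))

  scales <- (upper - lower)          # diagonal coordinate scaling
  scales[scales <= 0] <- 1
  m <- (initial - lower) / scales    # search in scaled coordinates
  m[!is.finite(m)] <- 0.5
  sigma <- protocol$sigma0
  C <- diag(d); pc <- ps <- numeric(d)
  eigen_C <- eigen(C, symmetric = TRUE)

  set.seed(protocol$seed)
  records <- vector("list", protocol$candidate_budget)
  idx <- 0L
  gen <- 0L
  consecutive_invalid <- 0L
  best_so_far <- Inf
  best_x <- m
  stagnant_gens <- 0L
  polish_at <- if ((protocol$polish_fraction %||% 0) > 0)
    ceiling((1 - protocol$polish_fraction) * protocol$candidate_budget)
  else Inf
  polished <- FALSE
  while (idx < protocol$candidate_budget) {
    if (!polished && idx >= polish_at) {
      # exploitation phase: contract around the best candidate so far
      m <- best_x
      sigma <- protocol$sigma0 / 3
      C <- diag(d); pc <- ps <- numeric(d)
      eigen_C <- eigen(C, symmetric = TRUE)
      stagnant_gens <- 0L
      polished <- TRUE
    }
    gen <- gen + 1L
    n_this <- min(lam, protocol$candidate_budget - idx)
    B <- eigen_C$vectors
    D <- sqrt(pmax(eigen_C$values, 1e-20))
    Z <- matrix(rnorm(d * lam), d, lam)
    Y <- B %*% (D * Z)                       # N(0, C) samples
    X <- m + sigma * Y                       # scaled coordinates
    Xc <- pmin(pmax(X, 0), 1)                # project into the box
    fitness <- numeric(lam)
    gen_valid <- FALSE
    for (k in seq_len(min(n_this, lam))) {
      vec <- lower + Xc[, k] * scales
      idx <- idx + 1L
      res <- objective(vec, idx)
      if (inherits(res, "cost_breakdown")) {
        cb <- res
        # penalty evaluations are ranked internally by their infeasibility
        # measure when one is attached; the recorded cost stays flat
        fitness[k] <- res$total + (attr(res, "violation") %||% 0)
        if (res$valid) gen_valid <- TRUE
      } else { # plain numeric objective (e.g. surrogate smoke tests)
        cb <- structure(list(r = NA_real_, d = NA_real_, ks = NA_real_,
                             total = res, valid = is.finite(res),
                             reason = NULL), class = "cost_breakdown")
        fitness[k] <- res
        if (is.finite(res)) gen_valid <- TRUE
      }
      records[[idx]] <- structure(
        list(vector = vec, training_cost = cb, index = idx,
             generation = gen), class = "candidate_record")
      if (idx >= protocol$candidate_budget) break
    }
    if (!gen_valid) {
      consecutive_invalid <- consecutive_invalid + 1L
      if (consecutive_invalid >= 3L)
        pfic_error("pfic_search_degenerate",
                   "all candidates invalid for 3 consecutive generations")
    } else consecutive_invalid <- 0L
    if (idx >= protocol$candidate_budget) break
    k_eval <- seq_len(min(n_this, lam))
    gen_best <- min(fitness[k_eval])
    if (gen_best < best_so_far) best_x <- Xc[, k_eval[which.min(fitness[k_eval])]]
    rel_impr <- (best_so_far - min(best_so_far, gen_best)) /
      max(abs(best_so_far), 1e-12)
    best_so_far <- min(best_so_far, gen_best)
    if (is.finite(rel_impr) && rel_impr >= 1e-3) stagnant_gens <- 0L
    else stagnant_gens <- stagnant_gens + 1L
    if (stagnant_gens >= protocol$restart_after) {
      # stagnation restart: fresh random mean, reset strategy state
      m <- runif(d)
      sigma <- protocol$sigma0
      C <- diag(d); pc <- ps <- numeric(d)
      eigen_C <- eigen(C, symmetric = TRUE)
      stagnant_gens <- 0L
      next
    }
    ord <- order(fitness)
    sel <- ord[seq_len(mu)]
    y_w <- drop(Y[, sel, drop = FALSE] %*% w_pos)
    m_new <- m + sigma * y_w
    m_new <- pmin(pmax(m_new, 0), 1)
    # cumulative step-size adaptation
    Cinv_sqrt <- function(y) B %*% ((1 / D) * crossprod(B, y))
    ps <- (1 - cs) * ps + sqrt(cs * (2 - cs) * mu_eff) *
      drop(Cinv_sqrt(y_w))
    hsig <- as.numeric(sqrt(sum(ps^2)) /
                         sqrt(1 - (1 - cs)^(2 * gen)) / chiN <
                         1.4 + 2 / (d + 1))
    pc <- (1 - cc) * pc + hsig * sqrt(cc * (2 - cc) * mu_eff) * y_w
    rank_mu <- matrix(0, d, d)
    for (j in seq_len(lam)) {
      yj <- Y[, ord[j]]
      wj <- w_all[j]
      if (wj < 0) # keep negative updates positive-definite-safe
        wj <- wj * d / max(sum(drop(Cinv_sqrt(yj))^2), 1e-12)
      rank_mu <- rank_mu + wj * tcrossprod(yj)
    }
    C <- (1 - c1 - cmu * sum(w_all)) * C +
      c1 * (tcrossprod(pc) + (1 - hsig) * cc * (2 - cc) * C) +
      cmu * rank_mu
    sigma <- sigma * exp((cs / damps) * (sqrt(sum(ps^2)) / chiN - 1))
    sigma <- min(sigma, 1)
    m <- m_new
    C <- (C + t(C)) / 2
    eigen_C <- eigen(C, symmetric = TRUE)
  }
  records[seq_len(idx)]
}
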