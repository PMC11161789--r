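# The FIC neural-mass model: two populations (excitatory, inhibitory) per
# region, coupled across regions through the SC matrix (excitatory gating
# only). Regional currents:
#   I_E,i = W_E*I0 + w_EE,i*J*S_E,i + G*J*sum_j C_ij*S_E,j - w_IE,i*S_I,i
#   I_I,i = W_I*I0 + w_EI,i*J*S_E,i - w_II*S_I,i           (w_II = 1)
# Gating dynamics:
#   dS_E/dt = -S_E/tau_E + (1 - S_E)*gamma*r_E
#   dS_I/dt = -S_I/tau_I + r_I
# with r = H(I) the sigmoidal frequency-current curve of each population.

#' Population frequency-current transfer function
#'
#' `H(x) = (a*x - b) / (1 - exp(-d*(a*x - b)))`, evaluated elementwise.
#' The singularity at `a*x = b` is removable with limit `1/d`.
#'
#' @param current Numeric vector of input currents (nA); must be finite.
#' @param population `"E"` or `"I"` — selects the population's constants.
#' @param constants A [neural_constants()].
#' @return Firing rates (Hz), strictly positive and finite.
#' @export
transfer_function <- function(current, population = c("E", "I"),
                              constants = neural_constants()) {
  population <- match.arg(population)
  if (!all(is.finite(current)))
    pfic_error("pfic_invalid_input", "non-finite input current")
  out <- if (population == "E")
    cpp_transfer(current, constants$a_e, constants$b_e, constants$d_e)
  else
    cpp_transfer(current, constants$a_i, constants$b_i, constants$d_i)
  drop(out)
}

#' Deterministic drift of the gating equations
#'
#' Evaluates the noise-free right-hand side of the coupled gating equations
#' at a given state, together with the instantaneous population firing
#' rates. Long-range input reaches excitatory populations only.
#'
#' @param s_e,s_i Gating state vectors (length `n_regions`).
#' @param params A [regional_parameters()] with `w_ie` set.
#' @param conn A [connectome()].
#' @param constants A [neural_constants()].
#' @return List with `ds_e`, `ds_i` (1/s) and `r_e`, `r_i` (Hz).
#' @export
synaptic_drift <- function(s_e, s_i, params, conn,
                           constants = neural_constants()) {
  n <- conn$n_regions
  if (length(s_e) != n || length(s_i) != n || params$n_regions != n)
    pfic_error("pfic_invalid_input",
               "state/parameter dimensions must match the connectome (%d)", n)
  if (is.null(params$w_ie))
    pfic_error("pfic_invalid_parameters", "w_ie is unset; calibrate first")
  out <- cpp_drift(conn$sc, params$w_ee, params$w_ei, params$w_ie,
                   params$g, constants, s_e, s_i)
  lapply(out, drop)
}

#' Simulation result container
#'
#' Holds subsampled retained trajectories of the gating variables and
#' firing rates, full-resolution post-burn-in time means, and (optionally)
#' the simulated BOLD signal.
#'
#' @param s_e,s_i,r_e,r_i Matrices, retained steps x regions.
#' @param mean_s_e,mean_s_i,mean_r_e,mean_r_i Per-region time means over
#'   all post-burn-in steps (computed from the retained matrices when
#'   omitted).
#' @param dt_s Integration step (s).
#' @param burn_in_steps Number of discarded steps.
#' @param seed RNG seed used.
#' @param record_stride Subsampling stride of the retained matrices.
#' @param bold Optional [bold_timeseries()].
#' @return An object of class `sim_result`.
#' @export
sim_result <- function(s_e, s_i, r_e = NULL, r_i = NULL,
                       mean_s_e = NULL, mean_s_i = NULL,
                       mean_r_e = NULL, mean_r_i = NULL,
                       dt_s = NA_real_, burn_in_steps = 0L, seed = NA_integer_,
                       record_stride = 1L, bold = NULL) {
  if (nrow(s_e) < 1)
    pfic_error("pfic_invalid_input", "no retained steps")
  structure(list(
    s_e = s_e, s_i = s_i, r_e = r_e, r_i = r_i,
    mean_s_e = mean_s_e %||% colMeans(s_e),
    mean_s_i = mean_s_i %||% colMeans(s_i),
    mean_r_e = mean_r_e %||% (if (!is.null(r_e)) colMeans(r_e)),
    mean_r_i = mean_r_i %||% (if (!is.null(r_i)) colMeans(r_i)),
    dt_s = dt_s, burn_in_steps = burn_in_steps, seed = seed,
    record_stride = record_stride, bold = bold), class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf(
    "<sim_result> %d regions, %d retained samples (stride %d, dt %.4g s)\n",
    ncol(x$s_e), nrow(x$s_e), x$record_stride, x$dt_s))
  cat(sprintf("  mean r_E across regions: %.3f Hz\n", mean(x$mean_r_e)))
  invisible(x)
}

#' Stochastic integration of the FIC model
#'
#' Euler-Maruyama integration of the coupled gating equations with additive
#' regional noise (`S <- S + drift*dt + sigma*sqrt(dt)*N(0,1)`, independent
#' per region and population), state clamped to `[0, 1]` after every step.
#' Burn-in steps are discarded from all retained outputs; time means are
#' accumulated at full resolution over the post-burn-in interval. When
#' `tr_s` is given the Balloon-Windkessel model is integrated in-loop at
#' the neural step and BOLD is sampled every TR after the burn-in.
#'
#' @param params A [regional_parameters()] with `w_ie` set.
#' @param conn A [connectome()].
#' @param constants A [neural_constants()].
#' @param duration_s Total simulated time (s), burn-in included.
#' @param dt_s Step (s); must satisfy `dt_s <= tau_i / 5`.
#' @param burn_in_s Discarded transient (s), `< duration_s`.
#' @param seed Integer RNG seed; identical seeds give identical results.
#' @param with_noise Set `FALSE` for a noise-free (deterministic) run.
#' @param tr_s Optional BOLD sampling interval (s); must be a multiple of
#'   `dt_s` within `1e-9`.
#' @param hemo A [hemodynamic_constants()].
#' @param record_stride Retained-trajectory subsampling stride; default
#'   caps retained samples near 4000.
#' @param init_s_e,init_s_i Initial gating state (scalar or per-region).
#' @return A [sim_result()].
#' @export
simulate_fic <- function(params, conn, constants = neural_constants(),
                         duration_s = 300, dt_s = 0.001, burn_in_s = 60,
                         seed = 1L, with_noise = TRUE, tr_s = NULL,
                         hemo = hemodynamic_constants(),
                         record_stride = NULL,
                         init_s_e = 0.1, init_s_i = 0.1) {
  n <- conn$n_regions
  if (params$n_regions != n)
    pfic_error("pfic_invalid_input", "parameters do not match connectome")
  if (is.null(params$w_ie))
    pfic_error("pfic_invalid_parameters", "w_ie is unset; calibrate first")
  if (dt_s > constants$tau_i / 5 + 1e-12)
    pfic_error("pfic_invalid_config",
               "dt too large for stability: need dt <= tau_i/5 = %.4g s",
               constants$tau_i / 5)
  if (burn_in_s >= duration_s)
    pfic_error("pfic_invalid_config", "duration must exceed burn-in")
  n_steps <- round(duration_s / dt_s)
  burn_steps <- round(burn_in_s / dt_s)
  tr_steps <- 0L
  do_bold <- !is.null(tr_s)
  bw_stride <- 1L
  if (do_bold) {
    tr_steps <- tr_s / dt_s
    if (abs(tr_steps - round(tr_steps)) > 1e-9)
      pfic_error("pfic_invalid_config", "dt must divide tr within 1e-9")
    tr_steps <- as.integer(round(tr_steps))
    # hemodynamic substep ~10 ms (must divide the TR step count)
    bw_stride <- max(1L, as.integer(round(0.01 / dt_s)))
    while (bw_stride > 1L && tr_steps %% bw_stride != 0L)
      bw_stride <- bw_stride - 1L
  }
  record_stride <- record_stride %||%
    max(1L, as.integer(ceiling((n_steps - burn_steps) / 4000)))
  sE0 <- rep_len(init_s_e, n); sI0 <- rep_len(init_s_i, n)
  raw <- tryCatch(
    cpp_integrate(conn$sc, params$w_ee, params$w_ei, params$w_ie,
                  params$sigma, params$g, constants, dt_s,
                  as.integer(n_steps), as.integer(burn_steps),
                  as.integer(record_stride), isTRUE(with_noise),
                  do_bold, hemo, tr_steps, bw_stride, as.integer(seed),
                  sE0, sI0),
    error = function(e) pfic_error("pfic_simulation_error", "%s",
                                   conditionMessage(e)))
  bold <- NULL
  if (do_bold && nrow(raw$bold) >= 2) bold <- bold_timeseries(raw$bold, tr_s)
  sim_result(raw$s_e, raw$s_i, raw$r_e, raw$r_i,
             raw$mean_s_e, raw$mean_s_i, raw$mean_r_e, raw$mean_r_i,
             dt_s = dt_s, burn_in_steps = burn_steps, seed = seed,
             record_stride = record_stride, bold = bold)
}

# Inverse of the transfer function at a target rate: solves H(y) = rate for
# y = a*x - b by root bracketing (H is strictly increasing in y).
transfer_inverse_y <- function(rate, d) {
  f <- function(y) ifelse(abs(d * y) < 1e-8, (1 + d * y / 2) / d,
                          y / (1 - exp(-d * y))) - rate
  stats::uniroot(f, c(-200, 200), tol = 1e-12)$root
}

# Noise-free inhibitory fixed point given total non-S_I inhibitory input c:
# solves S_I = tau_I * H_I(c - S_I) on [0, 1].
solve_si_fixed_point <- function(c_in, constants) {
  g <- function(s) constants$tau_i *
    cpp_transfer(c_in - s, constants$a_i, constants$b_i, constants$d_i) - s
  stats::uniroot(g, c(0, 1), tol = 1e-12)$root
}

# Analytic first guess for the calibrated w_IE: assumes every region sits at
# the target-rate fixed point and solves the current-balance equation. When
# the region is bistable this overestimates the weight needed for the
# attractor reached from the standard initial state, so it serves as an
# upper starting point for the iterative calibration.
fic_initial_guess <- function(params, conn, constants, target_hz) {
  gam <- constants$gamma; tauE <- constants$tau_e
  sE <- gam * target_hz * tauE / (1 + gam * target_hz * tauE)
  yI <- transfer_inverse_y(target_hz, constants$d_e)
  iE <- (constants$b_e + yI) / constants$a_e
  coup <- params$g * constants$j_coupling * drop(conn$sc %*% rep(sE, conn$n_regions))
  cI <- constants$w_i * constants$i0 +
    params$w_ei * constants$j_coupling * sE
  sI <- vapply(cI, solve_si_fixed_point, numeric(1), constants = constants)
  wIE <- (constants$w_e * constants$i0 +
            params$w_ee * constants$j_coupling * sE + coup - iE) / sI
  list(w_ie = pmax(wIE, 0.05), s_e = rep(sE, conn$n_regions), s_i = sI)
}

#' Feedback inhibition control calibration
#'
#' Solves for the regional inhibitory feedback weights `w_IE` that hold
#' every region's noise-free time-averaged excitatory firing rate at the
#' target (around 3 Hz). Starting from an analytic fixed-point guess, the
#' noise-free system is integrated for a calibration horizon from the
#' standard initial state (so the calibrated rate belongs to the attractor
#' a simulation actually reaches), the rate is averaged over the trailing
#' segment, and `w_IE <- max(w_min, w_IE + eta * (rate - target))` is
#' iterated until the worst regional error is within tolerance. The
#' per-region gain is halved whenever the rate error changes sign, which
#' stabilizes the update where the rate is a steep function of the weight.
#'
#' @param params A [regional_parameters()] (`w_ie` ignored/unset).
#' @param conn A [connectome()].
#' @param constants A [neural_constants()].
#' @param target_hz Firing-rate set-point (Hz), default 3.
#' @param tol_hz Convergence tolerance (Hz), default 0.1.
#' @param max_iter Iteration cap; exceeding it raises a
#'   `pfic_calibration_failure` error (the candidate is unfittable).
#' @param dt_s Integration step (s).
#' @param horizon_s,avg_s Calibration horizon and trailing averaging
#'   window (s).
#' @param eta Initial update gain (per Hz of rate error).
#' @param w_min Lower bound on `w_IE`.
#' @param init_s_e,init_s_i Standard initial gating state for each
#'   calibration integration.
#' @return A [regional_parameters()] with `w_ie` set; attribute
#'   `"diagnostics"` holds iterations and final per-region rates.
#' @export
calibrate_fic <- function(params, conn, constants = neural_constants(),
                          target_hz = 3.0, tol_hz = 0.1, max_iter = 50L,
                          dt_s = 0.001, horizon_s = 10, avg_s = 5,
                          eta = 0.05, w_min = 0.05,
                          init_s_e = 0.1, init_s_i = 0.1) {
  if (target_hz <= 0)
    pfic_error("pfic_invalid_config", "target rate must be positive")
  n <- conn$n_regions
  init <- fic_initial_guess(params, conn, constants, target_hz)
  out <- tryCatch(
    cpp_calibrate_fic(conn$sc, params$w_ee, params$w_ei, params$g, constants,
                      dt_s, as.integer(round(horizon_s / dt_s)),
                      as.integer(round(avg_s / dt_s)), target_hz, tol_hz,
                      as.integer(max_iter), eta, w_min,
                      init$w_ie, rep_len(init_s_e, n), rep_len(init_s_i, n)),
    error = function(e) pfic_error("pfic_calibration_failure", "%s",
                                   conditionMessage(e)))
  if (!out$converged)
    pfic_error("pfic_calibration_failure",
               "FIC calibration did not converge within %d iterations (max error %.3f Hz)",
               max_iter, max(abs(out$rates - target_hz)))
  res <- regional_parameters(params$w_ee, params$w_ei, params$sigma,
                             params$g, w_ie = out$w_ie)
  attr(res, "diagnostics") <- list(iterations = out$iterations,
                                   rates = out$rates,
                                   final_s_e = out$final_s_e,
                                   final_s_i = out$final_s_i)
  res
}

#' Check regional firing rates against acceptance bounds
#'
#' @param result A [sim_result()].
#' @param bounds_hz Closed acceptance interval, default `c(2.7, 3.3)` Hz.
#' @return List with `ok` (TRUE iff every regional time-mean excitatory
#'   rate lies within the bounds) and `means` (per-region means, Hz).
#' @export
check_firing_rates <- function(result, bounds_hz = c(2.7, 3.3)) {
  m <- result$mean_r_e
  if (is.null(m))
    pfic_error("pfic_invalid_input", "result carries no firing rates")
  list(ok = all(m >= bounds_hz[1] & m <= bounds_hz[2]), means = m)
}
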