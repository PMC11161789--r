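# Transfer function, drift, stochastic integration and FIC calibration.

test_that("transfer function matches direct evaluation and its limits", {
  nc <- neural_constants()
  # removable singularity: H(b/a) = 1/d
  expect_equal(transfer_function(nc$b_e / nc$a_e, "E", nc), 1 / nc$d_e,
               tolerance = 1e-10)
  expect_equal(1 / nc$d_e, 6.25)
  # independent direct evaluation of H at a generic current
  oracle <- function(x, a, b, d) (a * x - b) / (1 - exp(-d * (a * x - b)))
  for (x in c(0.2, 0.3, 0.382, 0.45)) {
    expect_equal(transfer_function(x, "E", nc), oracle(x, 310, 125, 0.16),
                 tolerance = 1e-12)
    expect_equal(transfer_function(x, "I", nc), oracle(x, 615, 177, 0.087),
                 tolerance = 1e-12)
  }
  expect_equal(transfer_function(0.382, "E", nc), 3.52689, tolerance = 1e-4)
  # asymptote: H -> a*x - b for large drive
  x_hi <- (100 + nc$b_e) / nc$a_e
  expect_lt(abs(transfer_function(x_hi, "E", nc) - 100) / 100, 1e-6)
  # continuity across the removable singularity (perturbation of 1e-9 in
  # the effective drive a*x - b)
  for (eps in c(-1e-9, 1e-9)) {
    x <- (nc$b_e + eps) / nc$a_e
    expect_lt(abs(transfer_function(x, "E", nc) - 1 / nc$d_e),
              1e-6 / nc$d_e)
  }
  expect_error(transfer_function(NaN, "E", nc), class = "pfic_invalid_input")
})

test_that("drift is symmetric for identical uncoupled regions and zero at a
           solved fixed point", {
  n <- 5
  conn <- connectome(matrix(0, n, n))
  p <- regional_parameters(rep(2.5, n), rep(3, n), rep(0.005, n), g = 0,
                           w_ie = rep(1.5, n))
  dr <- synaptic_drift(rep(0.2, n), rep(0.1, n), p, conn)
  expect_true(all(abs(dr$ds_e - dr$ds_e[1]) < 1e-14))
  expect_true(all(abs(dr$ds_i - dr$ds_i[1]) < 1e-14))

  # independent fixed point: root-solve the 2-equation isolated system
  nc <- neural_constants()
  w_ee <- 2.5; w_ei <- 3; w_ie <- 1.5
  fp <- function(s) {
    ie <- nc$w_e * nc$i0 + w_ee * nc$j_coupling * s[1] - w_ie * s[2]
    ii <- nc$w_i * nc$i0 + w_ei * nc$j_coupling * s[1] - s[2]
    re <- transfer_function(ie, "E", nc)
    ri <- transfer_function(ii, "I", nc)
    c(-s[1] / nc$tau_e + (1 - s[1]) * nc$gamma * re,
      -s[2] / nc$tau_i + ri)
  }
  # damped fixed-point iteration as an independent solver
  s <- c(0.15, 0.05)
  for (i in 1:4000) s <- s + 0.002 * fp(s)
  expect_lt(max(abs(fp(s))), 1e-8)
  conn1 <- single_region()
  p1 <- regional_parameters(w_ee, w_ei, 0.005, g = 0, w_ie = w_ie)
  dr1 <- synaptic_drift(s[1], s[2], p1, conn1)
  expect_lt(max(abs(c(dr1$ds_e, dr1$ds_i))), 1e-8)

  # more feedback inhibition strictly lowers the excitatory rate
  r_lo <- synaptic_drift(0.2, 0.1,
                         regional_parameters(2.5, 3, 0.005, 0, w_ie = 1),
                         conn1)$r_e
  r_hi <- synaptic_drift(0.2, 0.1,
                         regional_parameters(2.5, 3, 0.005, 0, w_ie = 2),
                         conn1)$r_e
  expect_lt(r_hi, r_lo)
})

test_that("integration is deterministic, keeps gating in [0, 1], and holds
           noise-free fixed points", {
  conn <- small_connectome()
  cal <- small_calibrated()
  s1 <- simulate_fic(cal, conn, duration_s = 20, burn_in_s = 5, seed = 42,
                     dt_s = 0.002)
  s2 <- simulate_fic(cal, conn, duration_s = 20, burn_in_s = 5, seed = 42,
                     dt_s = 0.002)
  expect_identical(s1$s_e, s2$s_e)
  expect_identical(s1$r_i, s2$r_i)
  s3 <- simulate_fic(cal, conn, duration_s = 20, burn_in_s = 5, seed = 43,
                     dt_s = 0.002)
  expect_false(identical(s1$s_e, s3$s_e))

  # gating bounds over random parameter draws
  set.seed(9)
  for (i in 1:5) {
    p <- regional_parameters(runif(12, 1, 4), runif(12, 1, 5),
                             runif(12, 5e-4, 0.01), g = runif(1, 0, 2),
                             w_ie = runif(12, 0.5, 3))
    s <- simulate_fic(p, conn, duration_s = 5, burn_in_s = 1, seed = i,
                      dt_s = 0.002)
    expect_true(all(s$s_e >= 0 & s$s_e <= 1))
    expect_true(all(s$s_i >= 0 & s$s_i <= 1))
    expect_true(all(is.finite(s$r_e)) && all(s$r_e >= 0))
  }

  # noise-free run settled at its attractor stays there
  settle <- simulate_fic(cal, conn, duration_s = 30, burn_in_s = 25,
                         seed = 1, with_noise = FALSE, dt_s = 0.002)
  expect_lt(max(apply(settle$s_e, 2, var)), 1e-10)

  expect_error(simulate_fic(cal, conn, duration_s = 10, burn_in_s = 1,
                            dt_s = 0.05), class = "pfic_invalid_config")
})

test_that("noise-free trajectories converge at first order in dt", {
  conn <- single_region()
  p <- regional_parameters(2.5, 3, 0.005, g = 0, w_ie = 1.5)
  final_state <- function(dt) {
    s <- simulate_fic(p, conn, duration_s = 2, burn_in_s = 2 - dt,
                      dt_s = dt, seed = 1, with_noise = FALSE,
                      record_stride = 1)
    c(s$s_e[nrow(s$s_e), 1], s$s_i[nrow(s$s_i), 1])
  }
  dts <- c(0.002, 0.001, 0.0005, 0.00025)
  ref <- final_state(0.00003125)
  errs <- vapply(dts, function(dt) max(abs(final_state(dt) - ref)),
                 numeric(1))
  order_fit <- coef(lm(log(errs) ~ log(dts)))[2]
  expect_gt(order_fit, 0.9)
})

test_that("FIC calibration matches the single-region bisection oracle and
           is monotone in recurrent strength", {
  conn1 <- single_region()
  w_ies <- vapply(c(1.8, 2.5, 3.2), function(w_ee) {
    p <- regional_parameters(w_ee, 3, 0.005, g = 0)
    cal <- calibrate_fic(p, conn1, dt_s = 0.002)
    # calibrated weight reproduces the 3 Hz noise-free rate
    expect_lt(abs(cold_rate(cal$w_ie, w_ee) - 3), 0.1)
    # and agrees with the independent bisection oracle
    w_bis <- bisect_w_ie(3, w_ee)
    expect_lt(abs(cold_rate(w_bis, w_ee) - cold_rate(cal$w_ie, w_ee)), 0.2)
    cal$w_ie
  }, numeric(1))
  expect_true(all(diff(w_ies) > 0))
})

test_that("firing-rate gate applies closed bounds and the relaxed setting
           admits more candidates", {
  fake <- function(means) sim_result(
    s_e = matrix(0.2, 2, length(means)), s_i = matrix(0.1, 2, length(means)),
    mean_r_e = means)
  expect_true(check_firing_rates(fake(rep(3, 5)), c(2.7, 3.3))$ok)
  expect_false(check_firing_rates(fake(c(rep(3, 4), 3.4)), c(2.7, 3.3))$ok)
  borderline <- fake(c(2.6, 3, 3.45))
  expect_false(check_firing_rates(borderline, c(2.7, 3.3))$ok)
  expect_true(check_firing_rates(borderline, c(2.5, 3.5))$ok)
})
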