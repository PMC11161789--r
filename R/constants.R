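#' Neural-mass model constants
#'
#' Fixed biophysical constants of the two-population (excitatory/inhibitory)
#' mean-field reduction used by the FIC model. Defaults follow the canonical
#' feedback-inhibition-control parameter set: sigmoidal frequency-current
#' gains/thresholds/curvatures for both populations, gating time constants,
#' the NMDA-like gating rate constant, the synaptic coupling scale, and the
#' background current with its per-population scaling.
#'
#' @param a_e,b_e,d_e Excitatory gain (1/(nA s)), threshold (Hz) and
#'   curvature (s) of the frequency-current curve.
#' @param a_i,b_i,d_i Inhibitory analogues.
#' @param tau_e,tau_i Gating time constants (s); `tau_i < tau_e`.
#' @param gamma Gating rate constant (unitless).
#' @param j_coupling Synaptic coupling scale J (nA).
#' @param i0 Background current (nA).
#' @param w_e,w_i Background current scaling for the two populations.
#' @return An object of class `neural_constants` (named list).
#' @export
neural_constants <- function(a_e = 310, b_e = 125, d_e = 0.16,
                             a_i = 615, b_i = 177, d_i = 0.087,
                             tau_e = 0.1, tau_i = 0.01, gamma = 0.641,
                             j_coupling = 0.15, i0 = 0.382,
                             w_e = 1.0, w_i = 0.7) {
  x <- list(a_e = a_e, b_e = b_e, d_e = d_e, a_i = a_i, b_i = b_i, d_i = d_i,
            tau_e = tau_e, tau_i = tau_i, gamma = gamma,
            j_coupling = j_coupling, i0 = i0, w_e = w_e, w_i = w_i)
  if (any(vapply(x, function(v) !is.numeric(v) || length(v) != 1 || v <= 0,
                 logical(1))))
    pfic_error("pfic_invalid_constants",
               "all neural constants must be positive scalars")
  if (tau_i >= tau_e)
    pfic_error("pfic_invalid_constants", "tau_i must be smaller than tau_e")
  structure(x, class = "neural_constants")
}

#' Balloon-Windkessel hemodynamic constants
#'
#' Parameters of the hemodynamic forward model converting synaptic activity
#' into BOLD signal: vasodilatory signal decay, flow autoregulation, venous
#' transit time, vessel stiffness exponent, resting oxygen extraction,
#' resting venous blood volume fraction, and the three BOLD readout
#' coefficients.
#'
#' @param kappa Signal decay rate (1/s).
#' @param gamma_h Autoregulatory feedback rate (1/s).
#' @param tau_h Venous transit time (s).
#' @param alpha Grubb stiffness exponent, in (0, 1).
#' @param rho Resting oxygen extraction fraction.
#' @param v0 Resting venous blood volume fraction.
#' @param k1,k2,k3 BOLD readout coefficients; defaults `7*rho`, 2,
#'   `2*rho - 0.2`.
#' @return An object of class `hemodynamic_constants`.
#' @export
hemodynamic_constants <- function(kappa = 0.65, gamma_h = 0.41, tau_h = 0.98,
                                  alpha = 0.32, rho = 0.34, v0 = 0.02,
                                  k1 = 7 * rho, k2 = 2, k3 = 2 * rho - 0.2) {
  if (alpha <= 0 || alpha >= 1)
    pfic_error("pfic_invalid_constants", "alpha must lie in (0, 1)")
  pos <- c(kappa = kappa, gamma_h = gamma_h, tau_h = tau_h, rho = rho,
           v0 = v0, k1 = k1, k2 = k2)
  if (any(pos <= 0))
    pfic_error("pfic_invalid_constants",
               "hemodynamic constants (except k3) must be positive")
  structure(list(kappa = kappa, gamma_h = gamma_h, tau_h = tau_h,
                 alpha = alpha, rho = rho, v0 = v0,
                 k1 = k1, k2 = k2, k3 = k3),
            class = "hemodynamic_constants")
}
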