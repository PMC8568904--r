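#' @useDynLib pmfm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

pmfm_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "pmfm_error")))
}

#' Mean-field model constants
#'
#' Fixed synaptic and gain constants of the reduced mean-field population
#' model. Defaults are the standard values for the reduced spiking-network
#' model of a cortical region: synaptic coupling `J` = 0.2609 nA, transfer
#' gain `a` = 270 n/C, threshold `b` = 108 Hz, curvature `d` = 0.154 s,
#' kinetic rate `r_kin` = 0.641 and synaptic time constant `tau_s` = 0.1 s.
#'
#' @param J synaptic coupling (nA)
#' @param a transfer-function gain (n/C)
#' @param b transfer-function threshold (Hz)
#' @param d transfer-function curvature (s)
#' @param r_kin kinetic rate (dimensionless)
#' @param tau_s synaptic time constant (s)
#' @return an object of class `mfm_constants`
#' @export
mfm_constants <- function(J = 0.2609, a = 270, b = 108, d = 0.154,
                          r_kin = 0.641, tau_s = 0.1) {
  vals <- c(J = J, a = a, b = b, d = d, r_kin = r_kin, tau_s = tau_s)
  if (!all(is.finite(vals)) || any(vals <= 0))
    pmfm_stop("all model constants must be finite and strictly positive",
              "pmfm_invalid_input")
  structure(as.list(vals), class = "mfm_constants")
}

#' Balloon-Windkessel haemodynamic constants
#'
#' Constants of the nonlinear balloon haemodynamic model at 3T: signal decay
#' `kappa` (s^-1), flow feedback `gamma` (s^-1), transit time `tau` (s),
#' vessel stiffness `alpha`, resting oxygen extraction `rho`, resting blood
#' volume fraction `V0`, and the 3T BOLD signal coefficients `k1`, `k2`, `k3`
#' (defaults k1 = 4.3 * nu0 * rho * TE with nu0 = 28.265 * 3 s^-1 and
#' TE = 0.0331 s; k2 = epsilon * r0 * rho * TE with epsilon = 0.47 and
#' r0 = 110 s^-1; k3 = 1 - epsilon).
#'
#' @param kappa vasodilatory signal decay rate (s^-1)
#' @param gamma flow-dependent feedback rate (s^-1)
#' @param tau haemodynamic transit time (s)
#' @param alpha Grubb vessel stiffness exponent
#' @param rho resting oxygen extraction fraction
#' @param V0 resting blood volume fraction
#' @param k1,k2,k3 BOLD signal coefficients (3T)
#' @return an object of class `hemo_constants`
#' @export
hemo_constants <- function(kappa = 0.65, gamma = 0.41, tau = 0.98,
                           alpha = 0.32, rho = 0.34, V0 = 0.02,
                           k1 = 4.3 * 28.265 * 3 * 0.34 * 0.0331,
                           k2 = 0.47 * 110 * 0.34 * 0.0331,
                           k3 = 1 - 0.47) {
  vals <- c(kappa = kappa, gamma = gamma, tau = tau, alpha = alpha,
            rho = rho, V0 = V0, k1 = k1, k2 = k2, k3 = k3)
  if (!all(is.finite(vals)))
    pmfm_stop("haemodynamic constants must be finite", "pmfm_invalid_input")
  structure(as.list(vals), class = "hemo_constants")
}

#' Simulation configuration
#'
#' Integration and sampling protocol of a simulated resting-state run:
#' Euler step `dt` (default 10 ms), total simulated duration `t_total`
#' (default 16.4 min), discarded burn-in prefix `t_burn` (default 2 min) and
#' BOLD sampling period `tr` (default 0.72 s). With the defaults the output
#' has (16.4 - 2) * 60 / 0.72 = 1200 frames.
#'
#' Noise enters the Euler update as `sigma_i * xi` per step under the
#' default `noise_scaling = "step"` (the convention under which the model's
#' documented noise-amplitude range produces multi-stable switching), or as
#' `sigma_i * sqrt(dt) * xi` under `"sqrt_dt"` (the SDE-consistent
#' Euler-Maruyama convention); see the methods vignette for the trade-off.
#'
#' @param dt integrator step (s)
#' @param t_total simulated duration (s)
#' @param t_burn discarded prefix (s)
#' @param tr output sampling period (s); must be an integer multiple of `dt`
#' @param seed RNG seed for the run (integer or NULL)
#' @param noise_scaling `"step"` or `"sqrt_dt"` (see Details)
#' @return an object of class `sim_config`
#' @export
sim_config <- function(dt = 0.01, t_total = 16.4 * 60, t_burn = 2 * 60,
                       tr = 0.72, seed = NULL,
                       noise_scaling = c("step", "sqrt_dt")) {
  noise_scaling <- match.arg(noise_scaling)
  if (!is.finite(dt) || dt <= 0)
    pmfm_stop("dt must be > 0", "pmfm_invalid_config")
  ratio <- tr / dt
  if (abs(ratio - round(ratio)) > 1e-8)
    pmfm_stop("tr must be an integer multiple of dt", "pmfm_invalid_config")
  if (t_burn >= t_total)
    pmfm_stop("t_burn must be smaller than t_total", "pmfm_invalid_config")
  structure(list(dt = dt, t_total = t_total, t_burn = t_burn, tr = tr,
                 seed = seed, noise_scaling = noise_scaling),
            class = "sim_config")
}

#' Structural connectome
#'
#' A nonnegative, symmetric coupling matrix with zero diagonal describing
#' anatomical connection strengths between cortical regions.
#'
#' @param C N x N numeric matrix of coupling weights
#' @param region_ids optional character vector of N region labels
#' @return an object of class `connectome`
#' @export
connectome <- function(C, region_ids = NULL) {
  C <- as.matrix(C)
  if (nrow(C) != ncol(C) || nrow(C) < 2)
    pmfm_stop("connectome must be a square matrix with N >= 2", "pmfm_shape_error")
  if (!all(is.finite(C)) || any(C < 0))
    pmfm_stop("connectome weights must be finite and nonnegative",
              "pmfm_validation_error")
  if (any(abs(diag(C)) > 1e-12))
    pmfm_stop("connectome diagonal must be zero", "pmfm_validation_error")
  if (max(abs(C - t(C))) > 1e-9)
    pmfm_stop("connectome must be symmetric (tolerance 1e-9)",
              "pmfm_validation_error")
  if (is.null(region_ids)) region_ids <- paste0("R", seq_len(nrow(C)))
  if (length(region_ids) != nrow(C))
    pmfm_stop("region_ids length must match matrix size", "pmfm_shape_error")
  dimnames(C) <- list(region_ids, region_ids)
  structure(list(C = C, region_ids = as.character(region_ids)),
            class = "connectome")
}

#' Regional spatial map
#'
#' One value per cortical region, ordered like the connectome; used for the
#' myelin-like and FC-gradient-like maps that parameterise the model, and for
#' any derived map fed to the spatial statistics.
#'
#' @param values numeric vector, one value per region
#' @param name map label
#' @param region_ids optional region labels
#' @return an object of class `spatial_map`
#' @export
spatial_map <- function(values, name = "map", region_ids = NULL) {
  values <- as.numeric(values)
  if (!all(is.finite(values)))
    pmfm_stop("spatial map values must be finite", "pmfm_invalid_input")
  if (is.null(region_ids)) region_ids <- paste0("R", seq_along(values))
  structure(list(values = values, name = name,
                 region_ids = as.character(region_ids)),
            class = "spatial_map")
}

#' Linear map coefficients of the parametric mean-field model
#'
#' The 10 free quantities of the model: for each regional parameter family
#' (recurrent strength w, external input I, noise amplitude sigma) a myelin
#' weight `a_*`, a gradient weight `b_*` and an offset `c_*`, plus the global
#' coupling scale `G`.
#'
#' @param a_w,b_w,c_w coefficients of the recurrent-strength map
#' @param a_I,b_I,c_I coefficients of the external-input map
#' @param a_sigma,b_sigma,c_sigma coefficients of the noise-amplitude map
#' @param G global coupling scale (>= 0)
#' @return an object of class `linear_coefficients` (named numeric of length 10)
#' @export
linear_coefficients <- function(a_w = 0, b_w = 0, c_w = 0.5,
                                a_I = 0, b_I = 0, c_I = 0.3,
                                a_sigma = 0, b_sigma = 0, c_sigma = 0.005,
                                G = 0) {
  x <- c(a_w = a_w, b_w = b_w, c_w = c_w, a_I = a_I, b_I = b_I, c_I = c_I,
         a_sigma = a_sigma, b_sigma = b_sigma, c_sigma = c_sigma, G = G)
  if (length(x) != 10 || !all(is.finite(x)))
    pmfm_stop("exactly 10 finite coefficients are required", "pmfm_invalid_input")
  if (G < 0) pmfm_stop("G must be nonnegative", "pmfm_invalid_input")
  structure(x, class = "linear_coefficients")
}

coef_names <- c("a_w", "b_w", "c_w", "a_I", "b_I", "c_I",
                "a_sigma", "b_sigma", "c_sigma", "G")

#' Coerce a numeric vector to linear coefficients
#' @param x numeric vector of length 10 (order a_w, b_w, c_w, a_I, b_I, c_I,
#'   a_sigma, b_sigma, c_sigma, G)
#' @return a `linear_coefficients` object
#' @export
as_linear_coefficients <- function(x) {
  if (inherits(x, "linear_coefficients")) return(x)
  x <- as.numeric(x)
  if (length(x) != 10)
    pmfm_stop("coefficient vector must have length 10", "pmfm_invalid_input")
  do.call(linear_coefficients, as.list(stats::setNames(x, coef_names)))
}

#' Regional circuit parameters
#'
#' Per-region recurrent strength w, external input current I (nA) and noise
#' amplitude sigma (nA), plus the global coupling scale G. Regional w and
#' sigma must be strictly positive; violations raise an infeasible-parameters
#' error (condition class `pmfm_infeasible_error`) that the fitting layer
#' converts to a sentinel cost.
#'
#' @param w numeric vector of recurrent strengths
#' @param I numeric vector of external input currents (nA)
#' @param sigma numeric vector of noise amplitudes (nA)
#' @param G global coupling scale
#' @return an object of class `regional_parameters`
#' @export
regional_parameters <- function(w, I, sigma, G) {
  n <- length(w)
  if (length(I) != n || length(sigma) != n)
    pmfm_stop("w, I and sigma must have equal length", "pmfm_shape_error")
  if (!all(is.finite(c(w, I, sigma, G))))
    pmfm_stop("regional parameters must be finite", "pmfm_invalid_input")
  if (any(w <= 0) || any(sigma <= 0))
    pmfm_stop("infeasible regional parameters: w and sigma must be strictly positive",
              "pmfm_infeasible_error")
  structure(list(w = w, I = I, sigma = sigma, G = G),
            class = "regional_parameters")
}

#' BOLD time series container
#'
#' @param B N x T numeric matrix of BOLD values (regions in rows)
#' @param tr sampling period (s)
#' @param region_ids optional region labels
#' @return an object of class `bold_timeseries`
#' @export
bold_timeseries <- function(B, tr, region_ids = NULL) {
  B <- as.matrix(B)
  if (ncol(B) < 2) pmfm_stop("BOLD must have at least 2 frames", "pmfm_shape_error")
  if (!all(is.finite(B)))
    pmfm_stop("BOLD entries must be finite", "pmfm_invalid_input")
  if (is.null(region_ids)) region_ids <- paste0("R", seq_len(nrow(B)))
  rownames(B) <- region_ids
  structure(list(B = B, tr = tr, region_ids = as.character(region_ids)),
            class = "bold_timeseries")
}

#' Neural trajectory container
#'
#' Synaptic gating values at integrator resolution; all entries lie in
#' \[0, 1\].
#'
#' @param S N x K numeric matrix of gating values
#' @param dt integrator step (s)
#' @return an object of class `neural_trajectory`
#' @export
neural_trajectory <- function(S, dt) {
  S <- as.matrix(S)
  if (min(S) < 0 || max(S) > 1)
    pmfm_stop("gating values must lie in [0, 1]", "pmfm_validation_error")
  structure(list(S = S, dt = dt), class = "neural_trajectory")
}
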