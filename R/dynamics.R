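#' Population transfer function
#'
#' Firing-rate response H(x) = (a x - b) / (1 - exp(-d (a x - b))) of a
#' cortical population to total input current x (nA). H is strictly positive,
#' strictly increasing and continuous through the removable singularity at
#' a x = b, where H = 1/d. For large inputs H approaches the linear branch
#' a x - b.
#'
#' @param x input current (nA); vectorised
#' @param constants an [mfm_constants()] object
#' @return firing rate(s) in Hz
#' @export
transfer_function <- function(x, constants = mfm_constants()) {
  if (!all(is.finite(x)))
    pmfm_stop("input current must be finite", "pmfm_invalid_input")
  u <- constants$a * x - constants$b
  du <- constants$d * u
  out <- ifelse(abs(du) < 1e-8, 1 / constants$d, u / (1 - exp(-du)))
  as.numeric(out)
}

#' Build regional parameters from map coefficients
#'
#' Expands the 10 linear coefficients into per-region circuit parameters:
#' w_i = a_w Mye_i + b_w Grad_i + c_w, and likewise for I_i and sigma_i;
#' G is copied through. Raises an infeasible-parameters error (condition
#' class `pmfm_infeasible_error`) if any resulting w_i or sigma_i is
#' non-positive.
#'
#' @param coeffs a [linear_coefficients()] object
#' @param myelin a [spatial_map()] (myelin-like anatomical gradient)
#' @param gradient a [spatial_map()] (principal FC gradient)
#' @return a [regional_parameters()] object
#' @export
build_regional_parameters <- function(coeffs, myelin, gradient) {
  coeffs <- as_linear_coefficients(coeffs)
  m <- myelin$values
  g <- gradient$values
  if (length(m) != length(g))
    pmfm_stop("myelin and gradient maps must have equal length", "pmfm_shape_error")
  cf <- unclass(coeffs)
  regional_parameters(
    w = cf["a_w"] * m + cf["b_w"] * g + cf["c_w"],
    I = cf["a_I"] * m + cf["b_I"] * g + cf["c_I"],
    sigma = cf["a_sigma"] * m + cf["b_sigma"] * g + cf["c_sigma"],
    G = cf[["G"]]
  )
}

#' Integrate the coupled mean-field equations
#'
#' Euler-Maruyama integration of the stochastic mean-field equations on the
#' connectome: dS_i = \[-S_i/tau_s + r (1 - S_i) H(x_i)\] dt +
#' sigma_i sqrt(dt) xi, with total input x_i = w_i J S_i +
#' G J sum_j C_ij S_j + I_i and i.i.d. standard Gaussian noise xi per region
#' and step. The gating variable is clamped to \[0, 1\] after every step.
#' Initial state is Uniform(0,1) per region drawn from the run seed (or the
#' supplied `init`).
#'
#' @param params a [regional_parameters()] object
#' @param sc a [connectome()] object
#' @param constants an [mfm_constants()] object
#' @param config a [sim_config()] object; `config$seed`, when non-NULL, makes
#'   the run reproducible
#' @param init optional initial gating vector in \[0, 1\]
#' @param perturbation optional list with elements `start_step`, `n_iter`,
#'   `regions` (1-based), `factor`, `s_max`, `s_min` describing an amplitude
#'   perturbation applied during integration (see
#'   [run_perturbation_experiment()])
#' @return a [neural_trajectory()] with one column per integrator step
#' @export
integrate_mfm <- function(params, sc, constants = mfm_constants(),
                          config = sim_config(), init = NULL,
                          perturbation = NULL) {
  N <- nrow(sc$C)
  if (length(params$w) != N)
    pmfm_stop("parameter and connectome dimensions disagree", "pmfm_shape_error")
  n_steps <- round(config$t_total / config$dt)
  if (!is.null(config$seed)) set.seed(config$seed)
  if (is.null(init)) init <- stats::runif(N)
  if (length(init) != N || any(init < 0) || any(init > 1))
    pmfm_stop("init must be N values in [0, 1]", "pmfm_invalid_input")
  if (is.null(perturbation)) {
    pert <- list(start_step = 0L, n_iter = 0L, regions = integer(0),
                 factor = 0, s_max = 1, s_min = 0)
  } else {
    pert <- perturbation
    if (any(pert$regions < 1L) || any(pert$regions > N))
      pmfm_stop("perturbation regions out of range", "pmfm_invalid_input")
  }
  noise_scale <- if (identical(config$noise_scaling, "sqrt_dt"))
    sqrt(config$dt) else 1
  S <- integrate_mfm_cpp(params$w, params$I, params$sigma, params$G, sc$C,
                         constants$J, constants$a, constants$b, constants$d,
                         constants$r_kin, constants$tau_s,
                         config$dt, as.integer(n_steps), init, noise_scale,
                         as.integer(pert$start_step), as.integer(pert$n_iter),
                         as.integer(pert$regions) - 1L, pert$factor,
                         pert$s_max, pert$s_min)
  neural_trajectory(S, config$dt)
}

#' Balloon-Windkessel haemodynamic forward model
#'
#' Converts a neural trajectory into BOLD at integrator resolution through
#' the nonlinear balloon model: a vasodilatory signal s, blood inflow f,
#' venous volume v and deoxyhaemoglobin content q evolve per region, driven
#' by the gating variable, from the resting state s = 0, f = v = q = 1.
#' Integration is Euler at the same dt and fully deterministic given the
#' input.
#'
#' @param neural a [neural_trajectory()] object
#' @param hemo an [hemo_constants()] object
#' @param dt integrator step (s); defaults to the trajectory's own
#' @return N x K matrix of BOLD values (percent signal change scale)
#' @export
balloon_windkessel <- function(neural, hemo = hemo_constants(), dt = neural$dt) {
  if (!all(is.finite(neural$S)))
    pmfm_stop("neural input must be finite", "pmfm_invalid_input")
  balloon_windkessel_cpp(neural$S, dt, hemo$kappa, hemo$gamma, hemo$tau,
                         hemo$alpha, hemo$rho, hemo$V0, hemo$k1, hemo$k2,
                         hemo$k3)
}

#' Simulate a BOLD run from map coefficients
#'
#' Full forward model: builds regional parameters from the coefficients and
#' the two spatial maps, integrates the stochastic mean-field equations,
#' applies the Balloon-Windkessel model, discards the first `t_burn` seconds
#' and keeps one instantaneous sample every `tr` seconds. With the default
#' protocol (16.4 min simulated, 2 min burn-in, TR 0.72 s) the output has
#' 1200 frames.
#'
#' @inheritParams integrate_mfm
#' @param coeffs a [linear_coefficients()] object
#' @param myelin,gradient [spatial_map()] objects sharing the connectome's
#'   region ordering
#' @param hemo an [hemo_constants()] object
#' @param return_neural if TRUE, attach the neural trajectory as attribute
#'   `"neural"` (used by the perturbation experiment)
#' @return a [bold_timeseries()] object
#' @export
simulate_bold <- function(coeffs, sc, myelin, gradient,
                          constants = mfm_constants(),
                          hemo = hemo_constants(), config = sim_config(),
                          perturbation = NULL, return_neural = FALSE) {
  params <- build_regional_parameters(coeffs, myelin, gradient)
  neural <- integrate_mfm(params, sc, constants, config,
                          perturbation = perturbation)
  bold_full <- balloon_windkessel(neural, hemo, config$dt)
  idx <- bold_frame_steps(config)
  out <- bold_timeseries(bold_full[, idx, drop = FALSE], tr = config$tr,
                         region_ids = sc$region_ids)
  if (return_neural) attr(out, "neural") <- neural
  out
}

# Integrator step indices at which BOLD frames are sampled: frame k sits at
# time t_burn + k * tr, k = 1 .. (t_total - t_burn) / tr.
bold_frame_steps <- function(config) {
  n_frames <- floor((config$t_total - config$t_burn) / config$tr + 1e-9)
  round((config$t_burn + seq_len(n_frames) * config$tr) / config$dt)
}
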