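#' Fitting targets
#'
#' Bundles the observables a model is fitted against: a target static FC
#' matrix, a target FCD pdf, and the structural connectome and spatial maps
#' the simulations run on.
#'
#' @param fc_target N x N static FC matrix
#' @param fcd_pdf_target an [fcd_pdf()] object
#' @param sc a [connectome()]
#' @param myelin,gradient [spatial_map()] objects
#' @return an object of class `fit_targets`
#' @export
fit_targets <- function(fc_target, fcd_pdf_target, sc, myelin, gradient) {
  N <- nrow(sc$C)
  if (!all(dim(fc_target) == c(N, N)) || length(myelin$values) != N ||
      length(gradient$values) != N)
    pmfm_stop("targets must share the connectome's region count", "pmfm_shape_error")
  structure(list(fc_target = fc_target, fcd_pdf_target = fcd_pdf_target,
                 sc = sc, myelin = myelin, gradient = gradient),
            class = "fit_targets")
}

# evaluate expr without disturbing the caller's RNG stream
preserve_rng <- function(expr) {
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old, envir = .GlobalEnv))
  }
  expr
}

#' Evaluate one candidate parameter set
#'
#' Runs `n_sims` seeded simulations of the model under the candidate
#' coefficients, averages the simulated static FCs entrywise and the
#' simulated FCD pdfs, and scores them against the targets with
#' [fit_cost()]. Candidates yielding infeasible regional parameters (any
#' w_i <= 0 or sigma_i <= 0), or whose simulation diverges, receive the
#' sentinel cost 3.0 without further simulation. The simulation seeds are
#' `seed + 0:(n_sims-1)`, so identical calls are identical.
#'
#' @param coeffs a [linear_coefficients()] object (or length-10 numeric)
#' @param targets a [fit_targets()] object
#' @param n_sims number of simulations averaged per evaluation
#' @param seed base seed of the per-simulation seed schedule
#' @param config a [sim_config()] (its own seed field is ignored)
#' @param window FCD window length in frames
#' @param n_bins FCD pdf bin count
#' @param constants,hemo model constants
#' @param weight_fc,weight_fcd cost weights
#' @return list with `r`, `ks`, `cost` (`r`/`ks` are NA for sentinel costs)
#' @export
evaluate_candidate <- function(coeffs, targets, n_sims = 3, seed = 1,
                               config = sim_config(), window = 83,
                               n_bins = 200, constants = mfm_constants(),
                               hemo = hemo_constants(), weight_fc = 1,
                               weight_fcd = 1) {
  if (n_sims < 1) pmfm_stop("n_sims must be >= 1", "pmfm_invalid_input")
  coeffs <- as_linear_coefficients(coeffs)
  sentinel <- list(r = NA_real_, ks = NA_real_, cost = 3.0)
  params <- tryCatch(
    build_regional_parameters(coeffs, targets$myelin, targets$gradient),
    pmfm_infeasible_error = function(e) NULL)
  if (is.null(params)) return(sentinel)
  res <- preserve_rng(tryCatch({
    fcs <- vector("list", n_sims)
    pdfs <- vector("list", n_sims)
    for (k in seq_len(n_sims)) {
      cfg <- config
      cfg$seed <- seed + k - 1
      bold <- simulate_bold(coeffs, targets$sc, targets$myelin,
                            targets$gradient, constants, hemo, cfg)
      fcs[[k]] <- static_fc(bold)
      pdfs[[k]] <- fcd_pdf(sliding_window_fcd(bold, window = window), n_bins)
    }
    fc_mean <- Reduce(`+`, fcs) / n_sims
    diag(fc_mean) <- 1
    fit_cost(fc_mean, targets$fc_target, average_fcd_pdf(pdfs),
             targets$fcd_pdf_target, weight_fc, weight_fcd)
  }, pmfm_error = function(e) NULL, error = function(e) NULL))
  if (is.null(res)) return(sentinel)
  res
}

#' Default coefficient bounds for the fit
#'
#' Box constraints for the 10 coefficients, derived from the regional value
#' ranges w in (0, 10), I in (0, 1), sigma in (0.0005, 0.05) and G in
#' (0, 8): each family's offset `c_*` gets the value range, its map slopes
#' `a_*`/`b_*` a symmetric half-range (the maps are z-scored, so slopes of
#' that size already span the value range).
#'
#' @return list with numeric vectors `lower` and `upper` of length 10
#' @export
default_coef_bounds <- function() {
  # value ranges: w in (0,10), I in (0,1), sigma in (0.0005,0.05), G in (0,8);
  # offsets c_* get the value range, slopes a_*/b_* a symmetric half-range
  # (maps are z-scored, so slopes of this size span the value range)
  list(
    lower = c(a_w = -5, b_w = -5, c_w = 0,
              a_I = -0.5, b_I = -0.5, c_I = 0,
              a_sigma = -0.025, b_sigma = -0.025, c_sigma = 0.0005,
              G = 0),
    upper = c(a_w = 5, b_w = 5, c_w = 10,
              a_I = 0.5, b_I = 0.5, c_I = 1,
              a_sigma = 0.025, b_sigma = 0.025, c_sigma = 0.05,
              G = 8))
}

#' Fit the parametric mean-field model with CMA-ES
#'
#' Estimates the 10 linear map coefficients by minimising the combined FC +
#' FCD cost against the targets. The first CMA-ES restart is initialised at
#' the canonical homogeneous working point (w = 1, I = 0.3 nA,
#' sigma = 0.01 nA, G = 1); further restarts start from independent uniform
#' draws within the bounds. Each restart runs `iterations` generations;
#' every evaluated candidate is logged. Simulation noise is variance-reduced
#' by a fixed per-candidate seed schedule (common random numbers across
#' candidates).
#'
#' @param targets a [fit_targets()] object
#' @param iterations CMA-ES generations per restart
#' @param restarts independent restarts
#' @param seed master seed governing initialisation, sampling and the
#'   simulation seed schedule
#' @param bounds list with numeric `lower` and `upper` of length 10; default
#'   [default_coef_bounds()]
#' @param n_sims simulations averaged per candidate evaluation
#' @param lambda CMA-ES population size (default 4 + floor(3 log 10) = 10)
#' @param sigma0_frac initial step size as a fraction of each bound range
#' @inheritParams evaluate_candidate
#' @return an object of class `pmfm_fit`; see [coef.pmfm_fit()],
#'   [simulate.pmfm_fit()], [predict.pmfm_fit()], [plot.pmfm_fit()]
#' @export
fit_pmfm <- function(targets, iterations = 64, restarts = 2, seed = 1,
                     bounds = default_coef_bounds(), n_sims = 3,
                     lambda = NULL, sigma0_frac = 0.2,
                     config = sim_config(), window = 83, n_bins = 200,
                     constants = mfm_constants(), hemo = hemo_constants(),
                     weight_fc = 1, weight_fcd = 1) {
  if (iterations < 1) pmfm_stop("iterations must be >= 1", "pmfm_invalid_input")
  lower <- bounds$lower; upper <- bounds$upper
  stopifnot(length(lower) == 10, length(upper) == 10)
  objective <- function(x) {
    evaluate_candidate(x, targets, n_sims = n_sims, seed = seed,
                       config = config, window = window, n_bins = n_bins,
                       constants = constants, hemo = hemo,
                       weight_fc = weight_fc, weight_fcd = weight_fcd)$cost
  }
  # restart 1 starts from the canonical homogeneous working point (w = 1,
  # I = 0.3 nA, sigma = 0.01 nA, G = 1); later restarts draw uniformly
  x0_canonical <- pmin(pmax(c(0, 0, 1, 0, 0, 0.3, 0, 0, 0.01, 1), lower), upper)
  all_logs <- vector("list", restarts)
  best_cost <- Inf; best_x <- NULL
  for (rs in seq_len(restarts)) {
    set.seed(seed + 1000L * rs)
    x0 <- if (rs == 1) x0_canonical else
      lower + stats::runif(10) * (upper - lower)
    res <- cma_es(objective, x0 = x0, sigma0 = sigma0_frac * (upper - lower),
                  lower = lower, upper = upper, lambda = lambda,
                  iterations = iterations, seed = NULL)
    lg <- res$log
    names(lg)[1:10] <- coef_names
    lg$restart <- rs
    all_logs[[rs]] <- lg
    if (res$best_cost < best_cost) {
      best_cost <- res$best_cost
      best_x <- res$best_x
    }
  }
  candidates <- do.call(rbind, all_logs)
  names(candidates)[names(candidates) == "cost"] <- "train_cost"
  if (all(candidates$train_cost >= 3.0))
    pmfm_stop("all evaluated candidates were infeasible", "pmfm_fit_failure")
  coeffs <- as_linear_coefficients(best_x)
  best_score <- evaluate_candidate(coeffs, targets, n_sims = n_sims,
                                   seed = seed, config = config,
                                   window = window, n_bins = n_bins,
                                   constants = constants, hemo = hemo,
                                   weight_fc = weight_fc, weight_fcd = weight_fcd)
  structure(list(coefficients = coeffs, best_cost = best_cost,
                 best_score = best_score, candidates = candidates,
                 targets = targets, config = config, window = window,
                 n_bins = n_bins, n_sims = n_sims, seed = seed,
                 bounds = bounds, constants = constants, hemo = hemo,
                 weight_fc = weight_fc, weight_fcd = weight_fcd,
                 call = match.call()),
            class = "pmfm_fit")
}

# concatenated z-scored (w, I, sigma) regional maps of a candidate,
# the similarity coordinates used by the diversity rule
candidate_map_vector <- function(coeffs, myelin, gradient) {
  p <- build_regional_parameters(coeffs, myelin, gradient)
  zs <- function(v) if (stats::sd(v) > 0) (v - mean(v)) / stats::sd(v) else v * 0
  c(zs(p$w), zs(p$I), zs(p$sigma))
}

#' Select top diverse candidates on validation targets
#'
#' Re-scores candidates on validation targets, then greedily selects by
#' ascending validation cost, skipping any candidate whose concatenated
#' z-scored regional (w, I, sigma) maps correlate at or above
#' `similarity_threshold` with any already-selected candidate's maps.
#' Returns at most `k` candidates (fewer, with a warning, if diversity
#' exhausts the pool). To keep re-scoring affordable only the
#' `max_rescored` feasible candidates with the lowest training cost are
#' re-scored.
#'
#' @param fit a `pmfm_fit` object (or its `candidates` data.frame)
#' @param validation a [fit_targets()] object
#' @param k number of candidates to select
#' @param similarity_threshold map-correlation cutoff (default 0.98)
#' @param max_rescored cap on candidates re-scored on the validation targets
#' @inheritParams evaluate_candidate
#' @return data.frame of selected candidates: coefficients,
#'   `validation_cost`, `train_cost`, selection `rank`
#' @export
select_top_diverse <- function(fit, validation, k = 10,
                               similarity_threshold = 0.98,
                               max_rescored = 100, n_sims = 3, seed = 1,
                               config = sim_config(), window = 83,
                               n_bins = 200, constants = mfm_constants(),
                               hemo = hemo_constants(), weight_fc = 1,
                               weight_fcd = 1) {
  cand <- if (inherits(fit, "pmfm_fit")) fit$candidates else fit
  cand <- cand[is.finite(cand$train_cost) & cand$train_cost < 3.0, , drop = FALSE]
  if (nrow(cand) == 0)
    pmfm_stop("no feasible candidates to select from", "pmfm_fit_failure")
  cand <- unique(cand[, c(coef_names, "train_cost")])
  cand <- cand[order(cand$train_cost), , drop = FALSE]
  cand <- utils::head(cand, max_rescored)
  cand$validation_cost <- vapply(seq_len(nrow(cand)), function(i) {
    evaluate_candidate(as.numeric(cand[i, coef_names]), validation,
                       n_sims = n_sims, seed = seed, config = config,
                       window = window, n_bins = n_bins,
                       constants = constants, hemo = hemo,
                       weight_fc = weight_fc, weight_fcd = weight_fcd)$cost
  }, numeric(1))
  cand <- cand[order(cand$validation_cost), , drop = FALSE]
  selected <- integer(0)
  maps <- list()
  for (i in seq_len(nrow(cand))) {
    v <- candidate_map_vector(as.numeric(cand[i, coef_names]),
                              validation$myelin, validation$gradient)
    dup <- any(vapply(maps, function(m) {
      if (stats::sd(v) == 0 || stats::sd(m) == 0) return(TRUE)
      stats::cor(v, m) >= similarity_threshold
    }, logical(1)))
    if (!dup) {
      selected <- c(selected, i)
      maps[[length(maps) + 1]] <- v
    }
    if (length(selected) == k) break
  }
  if (length(selected) < k)
    warning(sprintf("diversity rule exhausted the pool: %d of %d selected",
                    length(selected), k))
  out <- cand[selected, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' @export
print.pmfm_fit <- function(x, ...) {
  cat("Parametric mean-field model fit (CMA-ES)\n")
  cat(sprintf("  regions: %d   candidates evaluated: %d\n",
              nrow(x$targets$sc$C), nrow(x$candidates)))
  cat(sprintf("  best training cost: %.4f  (r = %.3f, KS = %.3f)\n",
              x$best_cost, x$best_score$r, x$best_score$ks))
  cat("  coefficients:\n")
  print(round(unclass(x$coefficients), 5))
  invisible(x)
}

#' @export
summary.pmfm_fit <- function(object, ...) {
  cand <- object$candidates
  feasible <- cand$train_cost < 3.0
  by_iter <- tapply(cand$train_cost, cand$iteration, min)
  out <- list(best_cost = object$best_cost, best_score = object$best_score,
              coefficients = object$coefficients,
              n_candidates = nrow(cand), n_feasible = sum(feasible),
              best_by_iteration = by_iter)
  class(out) <- "summary.pmfm_fit"
  out
}

#' @export
print.summary.pmfm_fit <- function(x, ...) {
  cat("pMFM fit summary\n")
  cat(sprintf("  candidates: %d (%d feasible)\n", x$n_candidates, x$n_feasible))
  cat(sprintf("  best cost %.4f = (1 - %.3f) + %.3f\n",
              x$best_cost, x$best_score$r, x$best_score$ks))
  cat("  coefficients:\n")
  print(round(unclass(x$coefficients), 5))
  invisible(x)
}

#' Extract fitted coefficients
#' @param object a `pmfm_fit` object
#' @param ... unused
#' @return named numeric vector of the 10 coefficients
#' @export
coef.pmfm_fit <- function(object, ...) unclass(object$coefficients)

#' Regional parameters implied by a fit
#'
#' Expands the fitted coefficients into per-region circuit parameters on the
#' fitted (or new) spatial maps.
#'
#' @param object a `pmfm_fit` object
#' @param myelin,gradient optional replacement maps
#' @param ... unused
#' @return data.frame with columns region, w, I, sigma
#' @export
predict.pmfm_fit <- function(object, myelin = object$targets$myelin,
                             gradient = object$targets$gradient, ...) {
  p <- build_regional_parameters(object$coefficients, myelin, gradient)
  data.frame(region = myelin$region_ids, w = p$w, I = p$I, sigma = p$sigma)
}

#' Simulate BOLD runs from a fitted model
#'
#' @param object a `pmfm_fit` object
#' @param nsim number of independent runs
#' @param seed base seed; run k uses seed + k - 1
#' @param ... unused
#' @return list of [bold_timeseries()] objects
#' @export
simulate.pmfm_fit <- function(object, nsim = 1, seed = 1, ...) {
  lapply(seq_len(nsim), function(k) {
    cfg <- object$config
    cfg$seed <- seed + k - 1
    simulate_bold(object$coefficients, object$targets$sc,
                  object$targets$myelin, object$targets$gradient,
                  object$constants, object$hemo, cfg)
  })
}

#' Plot CMA-ES convergence
#'
#' Best-so-far training cost per generation, one line per restart.
#'
#' @param x a `pmfm_fit` object
#' @param ... passed to [graphics::plot()]
#' @export
plot.pmfm_fit <- function(x, ...) {
  cand <- x$candidates
  restarts <- sort(unique(cand$restart))
  traces <- lapply(restarts, function(rs) {
    cc <- cand[cand$restart == rs, ]
    cummin(tapply(cc$train_cost, cc$iteration, min))
  })
  ylim <- range(unlist(traces))
  graphics::plot(NA, xlim = c(1, max(cand$iteration)), ylim = ylim,
                 xlab = "generation", ylab = "best-so-far cost", ...)
  for (i in seq_along(traces))
    graphics::lines(seq_along(traces[[i]]), traces[[i]], col = i)
  graphics::legend("topright", legend = paste("restart", restarts),
                   col = seq_along(restarts), lty = 1, bty = "n")
  invisible(x)
}
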