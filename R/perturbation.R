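#' Perturbation experiment configuration
#'
#' Settings of the causal state-switching experiment: amplitude push
#' fraction `factor` (default 0.8), number of perturbed integrator steps
#' `n_iter` (default 72, one TR at dt = 10 ms and TR = 0.72 s), the
#' FCD-mean threshold below which a window counts as incoherent (default
#' 0.6), and the minimum incoherent segment length in frames (default 200).
#'
#' @param factor push fraction in (0, 1]
#' @param n_iter perturbed integrator steps (>= 1)
#' @param fcd_mean_threshold incoherence cutoff on the FCD mean
#' @param min_segment minimum segment length (frames)
#' @return an object of class `perturbation_config`
#' @export
perturbation_config <- function(factor = 0.8, n_iter = 72,
                                fcd_mean_threshold = 0.6, min_segment = 200) {
  if (factor < 0 || factor > 1)
    pmfm_stop("factor must lie in [0, 1]", "pmfm_invalid_input")
  if (n_iter < 1) pmfm_stop("n_iter must be >= 1", "pmfm_invalid_input")
  structure(list(factor = factor, n_iter = n_iter,
                 fcd_mean_threshold = fcd_mean_threshold,
                 min_segment = min_segment),
            class = "perturbation_config")
}

#' Find incoherent segments of an FCD mean time course
#'
#' Maximal runs of consecutive windows whose FCD mean lies below the
#' threshold, kept only if at least `min_segment` windows long. Segments are
#' half-open frame intervals \[start, end).
#'
#' @param fcd_mean numeric vector of per-window FCD means
#' @param config a [perturbation_config()]
#' @return data.frame with columns `start`, `end` (half-open, 1-based) and
#'   `length`; zero rows if no qualifying segment exists
#' @export
find_incoherent_segments <- function(fcd_mean, config = perturbation_config()) {
  low <- fcd_mean < config$fcd_mean_threshold
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= config$min_segment
  data.frame(start = starts[keep], end = ends[keep] + 1L,
             length = r$lengths[keep])
}

# amplitude push applied to a gating value given segment extrema:
# below the midpoint -> towards s_max, above -> towards s_min
perturb_gating <- function(s, factor, s_max, s_min) {
  mid <- (s_max + s_min) / 2
  ifelse(s < mid, s + factor * (s_max - s), s - factor * (s - s_min))
}

#' Causal perturbation experiment
#'
#' For each trial: simulate a run, locate the first incoherent FCD segment
#' (at least `min_segment` frames below the FCD-mean threshold), then re-run
#' the identical simulation (same seed, hence same noise stream) with an
#' amplitude perturbation applied to the target regions' synaptic gating
#' variables for `n_iter` integrator steps starting at the segment
#' midpoint. The push rule moves a region's gating value towards the
#' segment's maximum when it is below the (max + min)/2 midpoint and towards
#' the minimum otherwise, with step fraction `factor`; the extrema are taken
#' over all regions within the located segment of the unperturbed run.
#' Reported per trial are the mean FCD mean over the segment windows before
#' the perturbation onset (`pre`) and over post-onset windows (`post`),
#' both from the perturbed run's FCD.
#'
#' @param coeffs a [linear_coefficients()] object
#' @param sc a [connectome()]
#' @param myelin,gradient [spatial_map()] objects
#' @param target_regions integer vector of perturbed region indices
#' @param config a [perturbation_config()]
#' @param n_trials number of trials attempted
#' @param seed base seed; trial k simulates with seed + k - 1
#' @param sim_config a [sim_config()]
#' @param window FCD window length (frames)
#' @param constants,hemo model constants
#' @return data.frame with one row per successful trial: `trial`, `pre`,
#'   `post`, `delta` = post - pre; skipped trials (no qualifying segment)
#'   are recorded in the `"skipped"` attribute
#' @export
run_perturbation_experiment <- function(coeffs, sc, myelin, gradient,
                                        target_regions,
                                        config = perturbation_config(),
                                        n_trials = 30, seed = 1,
                                        sim_config = pmfm::sim_config(),
                                        window = 83,
                                        constants = mfm_constants(),
                                        hemo = hemo_constants()) {
  if (length(target_regions) == 0)
    pmfm_stop("target_regions must be nonempty", "pmfm_invalid_input")
  N <- nrow(sc$C)
  if (any(target_regions < 1) || any(target_regions > N))
    pmfm_stop("target_regions out of range", "pmfm_invalid_input")
  rows <- list(); skipped <- integer(0)
  for (trial in seq_len(n_trials)) {
    cfg <- sim_config
    cfg$seed <- seed + trial - 1
    base <- simulate_bold(coeffs, sc, myelin, gradient, constants, hemo, cfg,
                          return_neural = TRUE)
    fm <- fcd_mean_timecourse(sliding_window_fcd(base, window = window))
    segs <- find_incoherent_segments(fm, config)
    if (nrow(segs) == 0) { skipped <- c(skipped, trial); next }
    seg <- segs[1, ]
    # frame -> integrator step mapping (frame k sampled at t_burn + k tr)
    steps <- bold_frame_steps(cfg)
    seg_steps <- steps[seg$start]:steps[seg$end - 1L]
    S_seg <- attr(base, "neural")$S[, seg_steps, drop = FALSE]
    s_max <- max(S_seg); s_min <- min(S_seg)
    mid_frame <- seg$start + (seg$end - seg$start) %/% 2
    pert <- list(start_step = steps[mid_frame], n_iter = config$n_iter,
                 regions = as.integer(target_regions), factor = config$factor,
                 s_max = s_max, s_min = s_min)
    pb <- simulate_bold(coeffs, sc, myelin, gradient, constants, hemo, cfg,
                        perturbation = pert)
    fmp <- fcd_mean_timecourse(sliding_window_fcd(pb, window = window))
    # windows are indexed by their start frame; pre = windows wholly before
    # the perturbation onset inside the segment, post = windows starting at
    # or after onset within the segment span
    W <- length(fmp)
    pre_idx <- seg$start:max(seg$start, mid_frame - window)
    post_idx <- mid_frame:min(W, seg$end - 1L)
    rows[[length(rows) + 1]] <- data.frame(
      trial = trial, pre = mean(fmp[pre_idx]), post = mean(fmp[post_idx]))
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(trial = integer(0), pre = numeric(0), post = numeric(0))
  out$delta <- out$post - out$pre
  attr(out, "skipped") <- skipped
  out
}
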