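#' Static functional connectivity
#'
#' Pearson correlation matrix of the regional BOLD time courses over the
#' whole run.
#'
#' @param bold a [bold_timeseries()] object
#' @return an N x N correlation matrix with region labels
#' @export
static_fc <- function(bold) {
  B <- bold$B
  if (ncol(B) < 3) pmfm_stop("need at least 3 frames", "pmfm_shape_error")
  sds <- apply(B, 1, stats::sd)
  if (any(sds == 0))
    pmfm_stop(sprintf("degenerate (constant) time course in region(s): %s",
                      paste(bold$region_ids[sds == 0], collapse = ", ")),
              "pmfm_degenerate_signal")
  fc <- stats::cor(t(B))
  dimnames(fc) <- list(bold$region_ids, bold$region_ids)
  fc
}

# strictly-upper-triangle vectorization shared by FC/FCD code
upper_tri_vec <- function(M) M[upper.tri(M, diag = FALSE)]

#' Sliding-window functional connectivity dynamics (FCD)
#'
#' Computes an FC matrix within each sliding window of `window` frames
#' (default 83 frames, i.e. about 60 s at TR 0.72 s), vectorises the
#' strictly-upper-triangular entries, and correlates the vectorised window
#' FCs with each other. With stride 1 a T-frame run yields
#' W = T - window + 1 windows (1200 frames -> 1118 windows).
#'
#' @param bold a [bold_timeseries()] object
#' @param window window length in frames
#' @param stride window step in frames
#' @return an object of class `fcd_matrix`: list with the W x W matrix
#'   `values`, `window_length` and `stride`
#' @export
sliding_window_fcd <- function(bold, window = 83, stride = 1) {
  B <- bold$B
  T_len <- ncol(B)
  if (window < 3) pmfm_stop("window must be at least 3 frames", "pmfm_invalid_window")
  if (T_len < window)
    pmfm_stop("run shorter than one window", "pmfm_invalid_window")
  starts <- seq(1, T_len - window + 1, by = stride)
  # sliding second-moment matrices by rank-1 updates: entering/leaving frames
  # adjust crossprod(B_w) and the frame sums in O(N^2) per shift
  N <- nrow(B)
  ut <- upper.tri(matrix(0, N, N))
  vecs <- matrix(NA_real_, N * (N - 1) / 2, length(starts))
  Bw <- B[, 1:window, drop = FALSE]
  cp <- tcrossprod(Bw)
  sums <- rowSums(Bw)
  win_cor <- function(cp, sums) {
    cov_w <- cp / window - tcrossprod(sums / window)
    sd_w <- sqrt(pmax(diag(cov_w), 0))
    cov_w / tcrossprod(sd_w)
  }
  col_i <- 1L
  vecs[, 1L] <- win_cor(cp, sums)[ut]
  pos <- 1L
  for (s in starts[-1]) {
    while (pos < s) {
      out_f <- B[, pos]; in_f <- B[, pos + window]
      cp <- cp - tcrossprod(out_f) + tcrossprod(in_f)
      sums <- sums - out_f + in_f
      pos <- pos + 1L
    }
    col_i <- col_i + 1L
    vecs[, col_i] <- win_cor(cp, sums)[ut]
  }
  if (length(starts) == 1) {
    fcd <- matrix(1, 1, 1)
  } else {
    # column-standardise then crossprod (equivalent to cor, BLAS-backed)
    vs <- scale(vecs)
    fcd <- crossprod(vs) / (nrow(vecs) - 1)
    fcd[fcd > 1] <- 1; fcd[fcd < -1] <- -1
    diag(fcd) <- 1
    dimnames(fcd) <- NULL
  }
  structure(list(values = fcd, window_length = window, stride = stride),
            class = "fcd_matrix")
}

#' Agreement between two static FC matrices
#'
#' Fisher z-transforms the strictly-upper-triangular entries of both
#' matrices and returns their Pearson correlation r.
#'
#' @param fc_sim,fc_emp N x N correlation matrices
#' @return correlation r in \[-1, 1\]
#' @export
fc_agreement <- function(fc_sim, fc_emp) {
  if (!all(dim(fc_sim) == dim(fc_emp)))
    pmfm_stop("FC matrices must share dimensions", "pmfm_shape_error")
  a <- upper_tri_vec(fc_sim)
  b <- upper_tri_vec(fc_emp)
  if (any(abs(c(a, b)) >= 1))
    pmfm_stop("off-diagonal FC entries must lie strictly inside (-1, 1) for the z-transform",
              "pmfm_ztransform_domain")
  stats::cor(atanh(a), atanh(b))
}

#' Kolmogorov-Smirnov distance
#'
#' Supremum distance between two cumulative distribution functions. Inputs
#' may be raw numeric samples (empirical CDFs) or [fcd_pdf()] objects on a
#' common bin grid (cumulative-sum CDFs evaluated at bin edges).
#'
#' @param a,b numeric samples or `fcd_pdf` objects (both of the same kind)
#' @return KS statistic in \[0, 1\]
#' @export
ks_distance <- function(a, b) {
  if (inherits(a, "fcd_pdf") && inherits(b, "fcd_pdf")) {
    if (length(a$mass) != length(b$mass) ||
        max(abs(a$bin_edges - b$bin_edges)) > 1e-12)
      pmfm_stop("pdfs must share a common bin grid", "pmfm_shape_error")
    return(max(abs(cumsum(a$mass) - cumsum(b$mass))))
  }
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0 || length(b) == 0)
    pmfm_stop("samples must be nonempty", "pmfm_invalid_input")
  z <- sort(unique(c(a, b)))
  Fa <- vapply(z, function(t) mean(a <= t), numeric(1))
  Fb <- vapply(z, function(t) mean(b <= t), numeric(1))
  max(abs(Fa - Fb))
}

#' Normalised histogram of FCD entries
#'
#' Collapses the strictly-upper-triangular entries of an FCD matrix into a
#' histogram on a fixed grid over \[-1, 1\] and normalises the masses to sum
#' to one.
#'
#' @param fcd an `fcd_matrix` object (or plain correlation matrix)
#' @param n_bins number of uniform bins on \[-1, 1\]
#' @return an object of class `fcd_pdf` with `bin_edges` (length n_bins + 1),
#'   `mass` (length n_bins) and `bin_centers`
#' @export
fcd_pdf <- function(fcd, n_bins = 200) {
  vals <- if (inherits(fcd, "fcd_matrix")) upper_tri_vec(fcd$values) else upper_tri_vec(as.matrix(fcd))
  if (length(vals) == 0)
    pmfm_stop("FCD has no off-diagonal entries", "pmfm_invalid_input")
  edges <- seq(-1, 1, length.out = n_bins + 1)
  idx <- pmin(pmax(findInterval(vals, edges, rightmost.closed = TRUE), 1L), n_bins)
  mass <- tabulate(idx, nbins = n_bins) / length(vals)
  structure(list(bin_edges = edges, mass = mass,
                 bin_centers = (edges[-1] + edges[-length(edges)]) / 2),
            class = "fcd_pdf")
}

#' Average several FCD pdfs
#'
#' FCD matrices from different runs have no temporal correspondence and
#' cannot be averaged directly; their normalised histograms can. Returns the
#' arithmetic mean of the per-run pdfs (still summing to one).
#'
#' @param pdfs list of [fcd_pdf()] objects (or of `fcd_matrix` objects, which
#'   are converted first)
#' @param n_bins bin count used when converting matrices
#' @return an `fcd_pdf` object
#' @export
average_fcd_pdf <- function(pdfs, n_bins = 200) {
  if (length(pdfs) == 0) pmfm_stop("need at least one pdf", "pmfm_invalid_input")
  pdfs <- lapply(pdfs, function(p) if (inherits(p, "fcd_pdf")) p else fcd_pdf(p, n_bins))
  edges <- pdfs[[1]]$bin_edges
  for (p in pdfs)
    if (length(p$bin_edges) != length(edges) || max(abs(p$bin_edges - edges)) > 1e-12)
      pmfm_stop("pdfs must share a common bin grid", "pmfm_shape_error")
  mass <- Reduce(`+`, lapply(pdfs, `[[`, "mass")) / length(pdfs)
  structure(list(bin_edges = edges, mass = mass,
                 bin_centers = pdfs[[1]]$bin_centers),
            class = "fcd_pdf")
}

#' Model-fit cost
#'
#' Overall disagreement between simulated and target observables:
#' weight_fc * (1 - r) + weight_fcd * KS, where r is the FC agreement
#' ([fc_agreement()]) and KS the FCD distribution distance
#' ([ks_distance()]). With the default unit weights the cost lies in
#' \[0, 3\]. Setting `weight_fcd = 0` fits static FC only.
#'
#' @param fc_sim,fc_emp static FC matrices
#' @param fcd_sim_pdf,fcd_emp_pdf [fcd_pdf()] objects
#' @param weight_fc,weight_fcd nonnegative cost weights
#' @return list with elements `r`, `ks` and `cost`
#' @export
fit_cost <- function(fc_sim, fc_emp, fcd_sim_pdf, fcd_emp_pdf,
                     weight_fc = 1, weight_fcd = 1) {
  if (weight_fc < 0 || weight_fcd < 0)
    pmfm_stop("cost weights must be nonnegative", "pmfm_invalid_input")
  r <- fc_agreement(fc_sim, fc_emp)
  ks <- ks_distance(fcd_sim_pdf, fcd_emp_pdf)
  list(r = r, ks = ks, cost = weight_fc * (1 - r) + weight_fcd * ks)
}

#' FCD mean time course
#'
#' Per-window average similarity of a window's FC pattern to all other
#' windows: row means of the FCD matrix, excluding the unit diagonal by
#' default.
#'
#' @param fcd an `fcd_matrix` object or plain W x W matrix
#' @param exclude_diagonal drop the self-correlation from each row mean
#' @return numeric vector of length W
#' @export
fcd_mean_timecourse <- function(fcd, exclude_diagonal = TRUE) {
  M <- if (inherits(fcd, "fcd_matrix")) fcd$values else as.matrix(fcd)
  W <- nrow(M)
  if (W < 2) pmfm_stop("FCD must have at least 2 windows", "pmfm_shape_error")
  if (exclude_diagonal) {
    (rowSums(M) - diag(M)) / (W - 1)
  } else {
    rowMeans(M)
  }
}

#' Sliding-window standard deviation (SW-STD)
#'
#' Standard deviation of each region's BOLD signal within each sliding
#' window, using the same windowing as [sliding_window_fcd()]. The default
#' convention is the population standard deviation (divide by n).
#'
#' @param bold a [bold_timeseries()] object
#' @param window window length in frames
#' @param stride window step in frames
#' @param type `"population"` (divide by n) or `"sample"` (divide by n - 1)
#' @return N x W matrix of window standard deviations
#' @export
sliding_window_std <- function(bold, window = 83, stride = 1,
                               type = c("population", "sample")) {
  type <- match.arg(type)
  B <- bold$B
  if (window < 2) pmfm_stop("window must be at least 2 frames", "pmfm_invalid_window")
  T_len <- ncol(B)
  if (T_len < window) pmfm_stop("run shorter than one window", "pmfm_invalid_window")
  starts <- seq(1, T_len - window + 1, by = stride)
  out <- vapply(starts, function(s) {
    Wb <- B[, s:(s + window - 1), drop = FALSE]
    sdv <- apply(Wb, 1, stats::sd)
    if (type == "population") sdv <- sdv * sqrt((window - 1) / window)
    sdv
  }, numeric(nrow(B)))
  matrix(out, nrow = nrow(B), dimnames = list(bold$region_ids, NULL))
}

#' Classify windows into coherent and incoherent states
#'
#' Fits a two-component univariate Gaussian mixture (EM, via mclust) to the
#' FCD mean time course, thresholds at the cross-over point of the two
#' weighted component densities between their means, labels windows above
#' the threshold "coherent" (high FCD mean) and below "incoherent", and
#' reports dwell times as maximal constant-label run lengths. When the two
#' component densities do not cross between the means the midpoint of the
#' means is used and a warning is issued.
#'
#' @param fcd_mean numeric vector (length >= 20) of per-window FCD means
#' @return list of class `state_labels` with `threshold`, `labels` (factor
#'   with levels incoherent/coherent), `dwell_times` (list with numeric
#'   vectors `incoherent` and `coherent`), and `mixture` (means, sds,
#'   weights)
#' @export
classify_states <- function(fcd_mean) {
  x <- as.numeric(fcd_mean)
  if (length(x) < 20)
    pmfm_stop("need at least 20 windows to fit the mixture", "pmfm_invalid_input")
  if (stats::sd(x) < 1e-12)
    pmfm_stop("degenerate (constant) FCD mean", "pmfm_invalid_input")
  # EM for a 2-component unequal-variance univariate mixture (mclust),
  # deterministically initialised by a median split
  z0 <- cbind(as.numeric(x <= stats::median(x)), as.numeric(x > stats::median(x)))
  fit <- mclust::meV(data = x, z = z0)
  if (is.null(fit$parameters) || anyNA(fit$parameters$mean) ||
      !is.finite(fit$loglik))
    pmfm_stop("mixture fit failed to converge", "pmfm_fit_failure")
  mu <- as.numeric(fit$parameters$mean)
  sdv <- sqrt(as.numeric(fit$parameters$variance$sigmasq))
  if (length(sdv) == 1) sdv <- rep(sdv, 2)
  wts <- as.numeric(fit$parameters$pro)
  ord <- order(mu)
  mu <- mu[ord]; sdv <- sdv[ord]; wts <- wts[ord]
  dens_diff <- function(t) wts[1] * stats::dnorm(t, mu[1], sdv[1]) -
    wts[2] * stats::dnorm(t, mu[2], sdv[2])
  threshold <- NA_real_
  if (mu[2] - mu[1] > 1e-10 &&
      sign(dens_diff(mu[1] + 1e-12)) != sign(dens_diff(mu[2] - 1e-12))) {
    threshold <- stats::uniroot(dens_diff, c(mu[1], mu[2]), tol = 1e-10)$root
  }
  if (!is.finite(threshold)) {
    warning("component densities do not cross between the means; using their midpoint")
    threshold <- mean(mu)
  }
  labels <- factor(ifelse(x > threshold, "coherent", "incoherent"),
                   levels = c("incoherent", "coherent"))
  runs <- rle(as.character(labels))
  dwell <- split(runs$lengths, runs$values)
  structure(list(threshold = threshold, labels = labels,
                 dwell_times = list(
                   incoherent = as.numeric(dwell[["incoherent"]] %||% numeric(0)),
                   coherent = as.numeric(dwell[["coherent"]] %||% numeric(0))),
                 mixture = list(means = mu, sds = sdv, weights = wts)),
            class = "state_labels")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Regional FCD-STD correlation map
#'
#' Per-region Pearson correlation between the first-order forward difference
#' of the FCD mean time course and the first-order forward difference of the
#' region's SW-STD time course. Regions whose difference series has zero
#' variance get NA (flagged in the `"undefined"` attribute).
#'
#' @param fcd_mean numeric vector of length W
#' @param sw_std N x W matrix from [sliding_window_std()]
#' @return numeric vector of N correlations (attribute `"undefined"` marks
#'   zero-variance regions)
#' @export
fcd_std_correlation_map <- function(fcd_mean, sw_std) {
  if (length(fcd_mean) != ncol(sw_std))
    pmfm_stop("window counts disagree", "pmfm_shape_error")
  dfm <- diff(fcd_mean)
  dsw <- t(diff(t(sw_std)))
  undefined <- apply(dsw, 1, stats::sd) == 0 | stats::sd(dfm) == 0
  out <- rep(NA_real_, nrow(sw_std))
  out[!undefined] <- apply(dsw[!undefined, , drop = FALSE], 1,
                           function(v) stats::cor(v, dfm))
  names(out) <- rownames(sw_std)
  attr(out, "undefined") <- which(undefined)
  out
}

#' Permutation null for FCD-STD correlations
#'
#' Observed statistic: per-region FCD-STD correlation averaged across runs.
#' Null: FCD-mean time courses are re-paired with SW-STD matrices from
#' randomly permuted runs, correlations recomputed and averaged, yielding
#' one null value per region per permutation. p-values use the add-one
#' estimator p = (1 + #\{null >= observed\}) / (1 + n_perm) and are FDR
#' corrected across regions (Benjamini-Hochberg).
#'
#' @param runs list of runs, each a list with elements `fcd_mean` (length W)
#'   and `sw_std` (N x W)
#' @param n_perm number of permutations (>= 1)
#' @param seed RNG seed
#' @return list with `observed` (per-region mean correlations), `null`
#'   (n_perm x N matrix), `p` (per-region p-values) and `q` (BH-adjusted)
#' @export
permutation_null_fcd_std <- function(runs, n_perm = 1000, seed = NULL) {
  if (length(runs) < 2) pmfm_stop("need at least 2 runs", "pmfm_invalid_input")
  if (n_perm < 1) pmfm_stop("n_perm must be >= 1", "pmfm_invalid_input")
  if (!is.null(seed)) set.seed(seed)
  R <- length(runs)
  region_cor <- function(fm, sw) fcd_std_correlation_map(fm, sw)
  obs_mat <- vapply(runs, function(r) region_cor(r$fcd_mean, r$sw_std),
                    numeric(nrow(runs[[1]]$sw_std)))
  observed <- rowMeans(obs_mat)
  null <- matrix(NA_real_, n_perm, length(observed))
  for (p in seq_len(n_perm)) {
    perm <- sample.int(R)
    nm <- vapply(seq_len(R), function(k)
      region_cor(runs[[k]]$fcd_mean, runs[[perm[k]]]$sw_std),
      numeric(length(observed)))
    null[p, ] <- rowMeans(nm)
  }
  pvals <- vapply(seq_along(observed), function(i)
    (1 + sum(null[, i] >= observed[i])) / (1 + n_perm), numeric(1))
  names(pvals) <- names(observed)
  list(observed = observed, null = null, p = pvals,
       q = stats::p.adjust(pvals, method = "BH"))
}
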