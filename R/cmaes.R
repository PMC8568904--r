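#' Covariance matrix adaptation evolution strategy (CMA-ES)
#'
#' Derivative-free stochastic minimiser in the standard (mu/mu_w, lambda)
#' formulation: rank-based recombination weights, cumulative step-size
#' adaptation, rank-one and rank-mu covariance updates. Candidates sampled
#' outside the box constraints are clipped to the bounds before evaluation.
#' Every evaluated candidate is logged.
#'
#' @param fn objective taking a numeric vector, returning a scalar cost
#' @param x0 initial mean (length n)
#' @param sigma0 initial step size, either scalar or per-coordinate; a
#'   per-coordinate sigma0 is handled by rescaling coordinates internally
#' @param lower,upper box bounds (length n)
#' @param lambda population size; default 4 + floor(3 log n)
#' @param iterations number of generations
#' @param seed RNG seed (NULL leaves the RNG state alone)
#' @return list with `best_x`, `best_cost`, and `log`, a data.frame with one
#'   row per evaluated candidate (coordinates x1..xn, cost, iteration)
#' @export
cma_es <- function(fn, x0, sigma0, lower, upper, lambda = NULL,
                   iterations = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(x0)
  if (length(sigma0) == 1) sigma0 <- rep(sigma0, n)
  # work in coordinates scaled by sigma0 so a single global step size applies
  scale <- sigma0
  to_raw <- function(y) y * scale
  lo <- lower / scale; hi <- upper / scale
  if (is.null(lambda)) lambda <- 4 + floor(3 * log(n))
  mu <- floor(lambda / 2)
  wts <- log(mu + 0.5) - log(seq_len(mu))
  wts <- wts / sum(wts)
  mueff <- 1 / sum(wts^2)
  cc <- (4 + mueff / n) / (n + 4 + 2 * mueff / n)
  cs <- (mueff + 2) / (n + mueff + 5)
  c1 <- 2 / ((n + 1.3)^2 + mueff)
  cmu <- min(1 - c1, 2 * (mueff - 2 + 1 / mueff) / ((n + 2)^2 + mueff))
  damps <- 1 + 2 * max(0, sqrt((mueff - 1) / (n + 1)) - 1) + cs
  chiN <- sqrt(n) * (1 - 1 / (4 * n) + 1 / (21 * n^2))

  xmean <- x0 / scale
  sigma <- 1
  pc <- ps <- rep(0, n)
  C <- diag(n)
  eig <- list(values = rep(1, n), vectors = diag(n))
  best_cost <- Inf
  best_x <- to_raw(xmean)
  log_x <- matrix(NA_real_, lambda * iterations, n)
  log_cost <- numeric(lambda * iterations)
  log_iter <- integer(lambda * iterations)
  row <- 0L

  for (it in seq_len(iterations)) {
    invsq <- eig$vectors %*% (t(eig$vectors) / sqrt(eig$values))
    Z <- matrix(stats::rnorm(n * lambda), n, lambda)
    Y <- eig$vectors %*% (sqrt(eig$values) * Z)         # ~ N(0, C)
    X <- xmean + sigma * Y
    Xc <- pmin(pmax(X, lo), hi)                          # box clip
    # Hansen-style boundary handling: evaluate the clipped point, add a
    # quadratic penalty on the repair distance (in the scaled coordinates)
    penalty <- colSums((X - Xc)^2)
    raw_costs <- apply(Xc, 2, function(y) fn(to_raw(y)))
    costs <- raw_costs + penalty
    for (k in seq_len(lambda)) {
      row <- row + 1L
      log_x[row, ] <- to_raw(Xc[, k])
      log_cost[row] <- raw_costs[k]
      log_iter[row] <- it
    }
    if (min(raw_costs) < best_cost) {
      best_cost <- min(raw_costs)
      best_x <- to_raw(Xc[, which.min(raw_costs)])
    }
    ord <- order(costs)
    sel <- ord[seq_len(mu)]
    xold <- xmean
    xmean <- drop(Xc[, sel, drop = FALSE] %*% wts)
    yw <- (xmean - xold) / sigma
    ps <- (1 - cs) * ps + sqrt(cs * (2 - cs) * mueff) * drop(invsq %*% yw)
    hsig <- as.numeric(sqrt(sum(ps^2)) /
      sqrt(1 - (1 - cs)^(2 * it)) / chiN < 1.4 + 2 / (n + 1))
    pc <- (1 - cc) * pc + hsig * sqrt(cc * (2 - cc) * mueff) * yw
    Ysel <- (Xc[, sel, drop = FALSE] - xold) / sigma
    C <- (1 - c1 - cmu) * C +
      c1 * (tcrossprod(pc) + (1 - hsig) * cc * (2 - cc) * C) +
      cmu * Ysel %*% (wts * t(Ysel))
    sigma <- sigma * exp((cs / damps) * (sqrt(sum(ps^2)) / chiN - 1))
    C <- (C + t(C)) / 2
    eig <- eigen(C, symmetric = TRUE)
    eig$values <- pmax(eig$values, 1e-14)
  }
  list(best_x = best_x, best_cost = best_cost,
       log = data.frame(log_x[seq_len(row), , drop = FALSE],
                        cost = log_cost[seq_len(row)],
                        iteration = log_iter[seq_len(row)]))
}
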