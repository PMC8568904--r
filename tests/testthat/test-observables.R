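test_that("static FC matches a direct correlation oracle and flags constants", {
  b <- toy_bold(3, 5, seed = 1)
  fc <- static_fc(b)
  expect_equal(fc, cor(t(b$B)), ignore_attr = TRUE)
  expect_equal(diag(fc), rep(1, 3), ignore_attr = TRUE)
  # identical and negated time courses
  x <- sin(seq_len(50))
  b2 <- bold_timeseries(rbind(x, x, -x), tr = 0.72)
  fc2 <- static_fc(b2)
  expect_equal(fc2[1, 2], 1)
  expect_equal(fc2[1, 3], -1)
  bc <- bold_timeseries(rbind(x, rep(2, 50)), tr = 0.72)
  expect_pmfm_error(static_fc(bc), "pmfm_degenerate_signal")
})

test_that("sliding-window FCD has the correct window arithmetic", {
  b <- toy_bold(4, 100)
  fcd <- sliding_window_fcd(b, window = 43)
  expect_equal(nrow(fcd$values), 100 - 43 + 1)  # 58 windows
  expect_equal(fcd$values, t(fcd$values))
  expect_equal(diag(fcd$values), rep(1, 58))
  expect_true(all(abs(fcd$values) <= 1 + 1e-12))
  # single window: trivially [[1]]
  b1 <- toy_bold(4, 43)
  expect_equal(sliding_window_fcd(b1, window = 43)$values, matrix(1, 1, 1))
  expect_pmfm_error(sliding_window_fcd(b, window = 2), "pmfm_invalid_window")
})

test_that("sliding FCD equals the direct per-window correlation computation", {
  b <- toy_bold(6, 150, seed = 77)
  fcd <- sliding_window_fcd(b, window = 30)
  # independent direct oracle: cor() per window, then correlate vectors
  starts <- 1:(150 - 30 + 1)
  vecs <- sapply(starts, function(s) {
    M <- cor(t(b$B[, s:(s + 29)]))
    M[upper.tri(M)]
  })
  expect_equal(fcd$values, cor(vecs), tolerance = 1e-9)
})

test_that("window count invariant W = T - window + 1 holds across sizes", {
  for (T_len in c(60, 90, 140)) for (win in c(20, 43)) {
    b <- toy_bold(3, T_len, seed = T_len + win)
    expect_equal(nrow(sliding_window_fcd(b, window = win)$values),
                 T_len - win + 1)
  }
})

test_that("FC agreement is the correlation of z-transformed upper triangles", {
  mk_fc <- function(v) { M <- diag(3); M[upper.tri(M)] <- v
                         M[lower.tri(M)] <- t(M)[lower.tri(M)]; M }
  A <- mk_fc(c(0, 0.5, -0.5)); B <- mk_fc(c(0, -0.5, 0.5))
  expect_equal(fc_agreement(A, A), 1)
  expect_equal(fc_agreement(A, B), -1)
  set.seed(9)
  v1 <- runif(6, -0.8, 0.8); v2 <- runif(6, -0.8, 0.8)
  mk4 <- function(v) { M <- diag(4); M[upper.tri(M)] <- v
                       M[lower.tri(M)] <- t(M)[lower.tri(M)]; M }
  expect_equal(fc_agreement(mk4(v1), mk4(v2)), cor(atanh(v1), atanh(v2)),
               tolerance = 1e-12)
  C <- mk_fc(c(1, 0.5, -0.5))
  expect_pmfm_error(fc_agreement(C, A), "pmfm_ztransform_domain")
})

test_that("KS distance matches hand cases and the two-sample ECDF oracle", {
  expect_equal(ks_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(ks_distance(c(0, 0), c(1, 1)), 1)
  expect_equal(ks_distance(c(0, 1), c(0.5, 0.5)), 0.5)
  # oracle equivalence: stats::ks.test statistic on 100 seeded pairs, n <= 20
  set.seed(123)
  for (k in 1:100) {
    n1 <- sample(2:20, 1); n2 <- sample(2:20, 1)
    a <- round(rnorm(n1), 2); b <- round(rnorm(n2), 2)
    expect_equal(ks_distance(a, b),
                 unname(suppressWarnings(ks.test(a, b))$statistic),
                 tolerance = 1e-12)
  }
  expect_pmfm_error(ks_distance(numeric(0), 1), "pmfm_invalid_input")
})

test_that("FCD pdfs are normalised histograms and average correctly", {
  b <- toy_bold(4, 120)
  fcd <- sliding_window_fcd(b, window = 43)
  p <- fcd_pdf(fcd)
  expect_equal(sum(p$mass), 1, tolerance = 1e-12)
  expect_true(all(p$mass >= 0))
  expect_equal(length(p$mass), 200)
  # averaging: one pdf is itself; identical pdfs average to themselves
  expect_equal(average_fcd_pdf(list(p))$mass, p$mass)
  expect_equal(average_fcd_pdf(list(p, p))$mass, p$mass)
  # distinct concentrated masses average to 0.5 / 0.5
  m1 <- matrix(c(1, 0.105, 0.105, 1), 2)
  m2 <- matrix(c(1, -0.555, -0.555, 1), 2)
  pa <- average_fcd_pdf(list(fcd_pdf(m1), fcd_pdf(m2)))
  expect_equal(sort(pa$mass[pa$mass > 0]), c(0.5, 0.5))
  p20 <- fcd_pdf(fcd, n_bins = 100)
  expect_pmfm_error(average_fcd_pdf(list(p, p20)), "pmfm_shape_error")
  expect_equal(ks_distance(p, p), 0)
})

test_that("the combined cost is weight_fc (1 - r) + weight_fcd KS", {
  b <- toy_bold(4, 120)
  fc <- static_fc(b)
  p <- fcd_pdf(sliding_window_fcd(b, window = 43))
  self <- fit_cost(fc, fc, p, p)
  expect_equal(self$cost, 0)
  expect_equal(self$r, 1)
  expect_equal(self$ks, 0)
  # printed test-set means: r = 0.66, KS = 0.12 -> cost 0.46
  expect_equal((1 - 0.66) + 0.12, 0.46, tolerance = 1e-12)
  expect_pmfm_error(fit_cost(fc, fc, p, p, weight_fc = -1), "pmfm_invalid_input")
  # FC-only fitting: weight_fcd = 0 drops the KS term
  expect_equal(fit_cost(fc, fc, p, p, weight_fcd = 0)$cost, 0)
})

test_that("FCD mean time course averages rows without the diagonal", {
  expect_equal(fcd_mean_timecourse(matrix(1, 5, 5)), rep(1, 5))
  m2 <- matrix(c(1, 0.4, 0.4, 1), 2)
  expect_equal(fcd_mean_timecourse(m2), c(0.4, 0.4))
  m3 <- diag(3); m3[1, 2] <- m3[2, 1] <- 0.2
  m3[1, 3] <- m3[3, 1] <- 0.4; m3[2, 3] <- m3[3, 2] <- 0.6
  expect_equal(fcd_mean_timecourse(m3), c(0.3, 0.4, 0.5))
  # diagonal included on request
  expect_equal(fcd_mean_timecourse(m2, exclude_diagonal = FALSE), c(0.7, 0.7))
})

test_that("sliding-window standard deviation follows the stated convention", {
  B <- rbind(rep(2, 10), 1:10)
  b <- bold_timeseries(B, tr = 0.72)
  sw <- sliding_window_std(b, window = 3)
  expect_equal(dim(sw), c(2, 8))
  expect_equal(sw[1, ], rep(0, 8))
  # population convention: sd of (1,2,3) with divisor n
  expect_equal(sw[2, 1], sqrt(2 / 3), ignore_attr = TRUE)
  expect_equal(sliding_window_std(b, window = 3, type = "sample")[2, 1],
               sd(1:3), ignore_attr = TRUE)
  expect_true(all(sw >= 0))
})

test_that("state classification recovers a planted two-Gaussian mixture", {
  set.seed(7)
  truth <- rep(c(0, 1), each = 500)
  x <- ifelse(truth == 1, rnorm(1000, 0.8, 0.05), rnorm(1000, 0.3, 0.05))
  st <- classify_states(x)
  expect_equal(sort(st$mixture$means), c(0.3, 0.8), tolerance = 0.02)
  expect_equal(st$threshold, 0.55, tolerance = 0.03)
  misclass <- mean((st$labels == "coherent") != (truth == 1))
  expect_lt(misclass, 0.02)
  expect_pmfm_error(classify_states(rep(0.5, 30)), "pmfm_invalid_input")
  expect_pmfm_error(classify_states(x[1:10]), "pmfm_invalid_input")
})

test_that("dwell times are maximal constant-label run lengths", {
  set.seed(8)
  pattern <- c(rep(0.3, 2), rep(0.8, 3), 0.3, rep(0.8, 8), rep(0.3, 10))
  x <- pattern + rnorm(length(pattern), 0, 0.02)
  st <- classify_states(x)
  expect_equal(st$dwell_times$incoherent, c(2, 1, 10))
  expect_equal(st$dwell_times$coherent, c(3, 8))
})

test_that("FCD-STD correlation map works on aligned and degenerate inputs", {
  set.seed(11)
  W <- 1000
  fm <- cumsum(rnorm(W)) / 10
  sw <- rbind(fm, -fm, rnorm(W), rep(1, W))
  cm <- fcd_std_correlation_map(fm, sw)
  expect_equal(cm[[1]], 1)
  expect_equal(cm[[2]], -1)
  expect_lt(abs(cm[[3]]), 0.1)       # independent white noise
  expect_true(is.na(cm[[4]]))        # zero-variance difference series
  expect_equal(attr(cm, "undefined"), 4L, ignore_attr = TRUE)
  expect_pmfm_error(fcd_std_correlation_map(fm[1:10], sw), "pmfm_shape_error")
})

test_that("permutation null detects planted FCD-STD coupling with FDR control", {
  set.seed(21)
  n_runs <- 6; W <- 300; N <- 10
  runs <- lapply(seq_len(n_runs), function(r) {
    fm <- as.numeric(stats::filter(rnorm(W), rep(1/5, 5), circular = TRUE))
    sw <- matrix(rnorm(N * W), N, W)
    for (i in 1:5) sw[i, ] <- fm + rnorm(W, 0, 0.4)  # coupled half
    list(fcd_mean = fm, sw_std = sw)
  })
  res <- permutation_null_fcd_std(runs, n_perm = 1000, seed = 5)
  expect_equal(dim(res$null), c(1000, N))
  expect_true(all(res$q[1:5] < 0.05))
  expect_true(all(res$q[6:10] > 0.05))
  expect_true(all(res$p > 0 & res$p <= 1))
  # identical runs: every permutation reproduces the observed statistic
  same <- list(runs[[1]], runs[[1]])
  res2 <- permutation_null_fcd_std(same, n_perm = 20, seed = 1)
  expect_equal(apply(res2$null, 2, max), res2$observed, tolerance = 1e-12)
  expect_pmfm_error(permutation_null_fcd_std(runs[1], 10), "pmfm_invalid_input")
})
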