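test_that("transfer function handles the removable singularity and limits", {
  cst <- mfm_constants()
  # at a x = b the limit is 1/d
  expect_equal(transfer_function(cst$b / cst$a), 1 / cst$d, tolerance = 1e-10)
  # far above threshold the denominator is ~1: H(1) ~ a - b = 162
  expect_equal(transfer_function(1), 162, tolerance = 1e-8)
  # below threshold: direct high-precision evaluation of (a x - b)/(1 - e^{-d(a x - b)})
  expect_equal(transfer_function(0), -108 / (1 - exp(0.154 * 108)),
               tolerance = 1e-12)
  expect_equal(transfer_function(0), 6.46e-6, tolerance = 1e-2)
  expect_pmfm_error(transfer_function(NaN), "pmfm_invalid_input")
})

test_that("transfer function is positive, strictly increasing, and linear at infinity", {
  cst <- mfm_constants()
  x <- seq(-1, 2, by = 0.001)
  H <- transfer_function(x)
  expect_true(all(H > 0))
  expect_true(all(diff(H) > 0))
  # approach to the linear branch is governed by exp(-d u): ~1e-4 by u = 60
  # and below 1e-6 once u >= 90
  rel_err <- function(u_min) {
    x_hi <- x[cst$a * x - cst$b >= u_min]
    max(abs(transfer_function(x_hi) - (cst$a * x_hi - cst$b)) /
          (cst$a * x_hi - cst$b))
  }
  expect_lt(rel_err(60), 1e-4)
  expect_lt(rel_err(90), 1e-6)
})

test_that("regional parameters are linear in the maps and reject infeasible values", {
  m <- spatial_map(c(1, 2, 3)); g <- spatial_map(c(0.5, 0, -0.5))
  p <- build_regional_parameters(
    linear_coefficients(c_w = 0.5, c_I = 0.3, c_sigma = 0.01, G = 0), m, g)
  expect_equal(p$w, rep(0.5, 3))
  expect_equal(p$I, rep(0.3, 3))
  expect_equal(p$sigma, rep(0.01, 3))
  p2 <- build_regional_parameters(
    linear_coefficients(a_w = 1, c_w = 0, c_I = 0.3, c_sigma = 0.01, G = 2), m, g)
  expect_equal(p2$w, c(1, 2, 3))
  expect_equal(p2$G, 2)
  # sigma identically zero is infeasible
  expect_pmfm_error(
    build_regional_parameters(
      linear_coefficients(c_w = 0.5, c_I = 0.3, c_sigma = 0, G = 0), m, g),
    "pmfm_infeasible_error")
  # map length mismatch
  expect_pmfm_error(
    build_regional_parameters(linear_coefficients(), m, spatial_map(c(1, 2))),
    "pmfm_shape_error")
})

test_that("noiseless trajectories converge to the drift fixed point (root-finder oracle)", {
  cst <- mfm_constants()
  cfg <- sim_config(t_total = 30, t_burn = 1, tr = 0.1, seed = 1)
  # x fixed at 0.4 nA: w ~ 0, G = 0, I = 0.4
  p <- regional_parameters(w = rep(1e-14, 2), I = rep(0.4, 2),
                           sigma = rep(1e-14, 2), G = 0)
  p$sigma <- rep(0, 2)
  traj <- integrate_mfm(p, tiny_sc(), config = cfg)
  terminal <- traj$S[, ncol(traj$S)]
  drift <- function(S, I) -S / cst$tau_s +
    cst$r_kin * (1 - S) * transfer_function(I)
  s_star <- uniroot(drift, c(0, 1), I = 0.4, tol = 1e-14)$root
  expect_equal(terminal, rep(s_star, 2), tolerance = 1e-6)
  expect_equal(s_star, 0.2939, tolerance = 1e-3)
  # closed form: S* = r tau H / (1 + r tau H)
  H <- transfer_function(0.4)
  expect_equal(s_star, cst$r_kin * cst$tau_s * H / (1 + cst$r_kin * cst$tau_s * H),
               tolerance = 1e-10)
  # residual drift at the terminal state is numerically zero
  expect_lt(max(abs(drift(terminal, 0.4))), 1e-8)
  # I = 0: S decays to the tiny fixed point set by H(0)
  p0 <- p; p0$I <- rep(0, 2)
  traj0 <- integrate_mfm(p0, tiny_sc(), config = cfg)
  s0 <- uniroot(drift, c(0, 1), I = 0, tol = 1e-16)$root
  expect_equal(traj0$S[1, ncol(traj0$S)], s0, tolerance = 1e-6)
  expect_equal(s0, 4.1e-7, tolerance = 5e-2)
})

test_that("halving dt leaves the noiseless terminal state nearly unchanged", {
  p <- regional_parameters(w = rep(0.8, 2), I = rep(0.32, 2),
                           sigma = rep(1e-14, 2), G = 0)
  p$sigma <- rep(0, 2)
  term <- sapply(c(0.01, 0.005), function(dt) {
    cfg <- sim_config(dt = dt, t_total = 30, t_burn = 1, tr = 0.1, seed = 1)
    traj <- integrate_mfm(p, tiny_sc(), config = cfg)
    traj$S[1, ncol(traj$S)]
  })
  expect_lt(abs(term[1] - term[2]), 1e-4)
})

test_that("gating stays in [0,1] and runs are seed-deterministic", {
  sc <- small_sc(); maps <- small_maps()
  co <- linear_coefficients(c_w = 1, c_I = 0.3, c_sigma = 0.05, G = 0.5)
  p <- build_regional_parameters(co, maps$myelin, maps$gradient)
  for (seed in 1:3) {
    traj <- integrate_mfm(p, sc, config = short_config(seed = seed))
    expect_gte(min(traj$S), 0)
    expect_lte(max(traj$S), 1)
  }
  t1 <- integrate_mfm(p, sc, config = short_config(seed = 7))
  t2 <- integrate_mfm(p, sc, config = short_config(seed = 7))
  expect_identical(t1$S, t2$S)
  expect_pmfm_error(integrate_mfm(p, tiny_sc(), config = short_config()),
                    "pmfm_shape_error")
})

test_that("balloon model rests at baseline and treats regions independently", {
  # zero drive from the resting state: BOLD flat at 0
  S0 <- neural_trajectory(matrix(0, 2, 500), dt = 0.01)
  bold <- balloon_windkessel(S0)
  expect_equal(max(abs(bold)), 0)
  # identical neural input in two regions -> identical BOLD
  drive <- matrix(rep(0.2 + 0.1 * sin(seq_len(1000) / 50), each = 2), 2, 1000,
                  byrow = FALSE)
  drive <- neural_trajectory(matrix(drive[1, ], 2, 1000, byrow = TRUE), 0.01)
  b2 <- balloon_windkessel(drive)
  expect_equal(b2[1, ], b2[2, ])
})

# independent R-side Euler integration of the balloon model at a finer step,
# zero-order hold on the neural input
bw_oracle <- function(S, dt, refine = 10, h = hemo_constants()) {
  dtf <- dt / refine
  s <- 0; f <- 1; v <- 1; q <- 1
  out <- numeric(length(S))
  for (i in seq_along(S)) {
    for (j in seq_len(refine)) {
      vfl <- v^(1 / h$alpha)
      Ef <- 1 - (1 - h$rho)^(1 / f)
      ds <- S[i] - h$kappa * s - h$gamma * (f - 1)
      df <- s
      dv <- (f - vfl) / h$tau
      dq <- (f * Ef / h$rho - vfl * q / v) / h$tau
      s <- s + dtf * ds; f <- f + dtf * df
      v <- v + dtf * dv; q <- q + dtf * dq
    }
    out[i] <- 100 * h$V0 / h$rho *
      (h$k1 * (1 - q) + h$k2 * (1 - q / v) + h$k3 * (1 - v))
  }
  out
}

test_that("balloon model matches a fine-step oracle and relaxes after a boxcar", {
  dt <- 0.01
  n <- 6000  # 60 s
  S <- rep(0, n); S[500:572] <- 0.3  # brief boxcar bump in the gating drive
  bold <- balloon_windkessel(neural_trajectory(matrix(S, 1), dt))[1, ]
  peak <- max(abs(bold))
  expect_gt(peak, 0)
  # excursion returns to within 1% of its peak amplitude by the end
  expect_lt(abs(bold[n]), 0.01 * peak)
  # independent same-step oracle: implementation equivalence to float order
  same <- bw_oracle(S, dt, refine = 1)
  expect_lt(max(abs(bold - same)), 1e-10 * max(1, peak))
  # step-halving convergence: refining the integration tenfold moves the
  # solution by well under 1% of the excursion
  fine <- bw_oracle(S, dt, refine = 10)
  expect_lt(max(abs(bold - fine)), 0.01 * peak)
})

test_that("full BOLD pipeline yields the protocol frame count and reproducibility", {
  sc <- small_sc(); maps <- small_maps()
  co <- linear_coefficients(c_w = 0.8, c_I = 0.3, c_sigma = 0.03, G = 0.5)
  cfg <- short_config(seed = 5)
  b <- simulate_bold(co, sc, maps$myelin, maps$gradient, config = cfg)
  expect_equal(ncol(b$B), floor((cfg$t_total - cfg$t_burn) / cfg$tr))
  b2 <- simulate_bold(co, sc, maps$myelin, maps$gradient, config = cfg)
  expect_identical(b$B, b2$B)
  expect_pmfm_error(sim_config(tr = 0.725), "pmfm_invalid_config")
  expect_pmfm_error(sim_config(t_burn = 1000, t_total = 900), "pmfm_invalid_config")
})

test_that("default protocol arithmetic gives 1200 frames and 72 steps per TR", {
  cfg <- sim_config()
  expect_equal(floor((cfg$t_total - cfg$t_burn) / cfg$tr), 1200)
  expect_equal(cfg$tr / cfg$dt, 72)
})
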