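test_that("CMA-ES minimises a smooth bowl and logs every candidate", {
  sphere <- function(x) sum((x - c(1, -2, 0.5))^2)
  res <- cma_es(sphere, x0 = rep(0, 3), sigma0 = 0.5,
                lower = rep(-5, 3), upper = rep(5, 3),
                iterations = 60, seed = 2)
  expect_lt(res$best_cost, 1e-4)
  expect_equal(res$best_x, c(1, -2, 0.5), tolerance = 0.05)
  lambda <- 4 + floor(3 * log(3))
  expect_equal(nrow(res$log), 60 * lambda)
  # determinism
  res2 <- cma_es(sphere, x0 = rep(0, 3), sigma0 = 0.5,
                 lower = rep(-5, 3), upper = rep(5, 3),
                 iterations = 60, seed = 2)
  expect_identical(res$log, res2$log)
  # bounds respected
  expect_true(all(as.matrix(res$log[, 1:3]) >= -5 &
                  as.matrix(res$log[, 1:3]) <= 5))
})

test_that("candidate evaluation is seeded, averaged, and sentinels infeasibility", {
  sc <- small_sc(8, seed = 5); maps <- small_maps(8, seed = 5)
  co <- linear_coefficients(c_w = 0.8, c_I = 0.3, c_sigma = 0.03, G = 0.5)
  tg <- generate_ground_truth(co, synthetic_spec(8, seed = 5),
                              config = short_config(), n_sims = 2, seed = 31,
                              window = 43)
  ev1 <- evaluate_candidate(co, tg, n_sims = 2, seed = 31,
                            config = short_config(), window = 43)
  ev2 <- evaluate_candidate(co, tg, n_sims = 2, seed = 31,
                            config = short_config(), window = 43)
  expect_identical(ev1, ev2)
  # evaluating the generating coefficients with the generating seeds is exact
  expect_equal(ev1$cost, 0, tolerance = 1e-10)
  # infeasible coefficients: sentinel cost without simulation
  bad <- linear_coefficients(c_w = 0.8, c_I = 0.3, c_sigma = -0.01, G = 0)
  evb <- evaluate_candidate(bad, tg, n_sims = 1, seed = 1,
                            config = short_config(), window = 43)
  expect_equal(evb$cost, 3.0)
  expect_true(is.na(evb$r))
  expect_pmfm_error(evaluate_candidate(co, tg, n_sims = 0), "pmfm_invalid_input")
})

test_that("self-consistency: generating coefficients score below the cost floor", {
  co <- linear_coefficients(c_w = 0.8, c_I = 0.3, c_sigma = 0.03, G = 0.5)
  cfg <- sim_config(t_total = 7 * 60, t_burn = 60)
  tg <- generate_ground_truth(co, synthetic_spec(8, seed = 5),
                              config = cfg, n_sims = 3, seed = 31,
                              window = 43)
  # different simulation seeds than the targets: residual cost is finite
  # sampling noise only
  ev <- evaluate_candidate(co, tg, n_sims = 3, seed = 77,
                           config = cfg, window = 43)
  expect_lt(ev$cost, 0.3)
})

test_that("fit bookkeeping counts restarts x iterations x population", {
  co <- linear_coefficients(c_w = 0.8, c_I = 0.3, c_sigma = 0.03, G = 0.5)
  tg <- generate_ground_truth(co, synthetic_spec(6, seed = 9),
                              config = short_config(t_total = 60, t_burn = 10),
                              n_sims = 1, seed = 3, window = 20)
  fit <- fit_pmfm(tg, iterations = 3, restarts = 2, seed = 4, n_sims = 1,
                  lambda = 5, sigma0_frac = 0.05,
                  config = short_config(t_total = 60, t_burn = 10),
                  window = 20)
  expect_s3_class(fit, "pmfm_fit")
  expect_equal(nrow(fit$candidates), 2 * 3 * 5)
  expect_true(all(c(pmfm:::coef_names, "train_cost", "iteration", "restart")
                  %in% names(fit$candidates)))
  # determinism of the whole fit
  fit2 <- fit_pmfm(tg, iterations = 3, restarts = 2, seed = 4, n_sims = 1,
                   lambda = 5, sigma0_frac = 0.05,
                   config = short_config(t_total = 60, t_burn = 10),
                   window = 20)
  expect_identical(fit$candidates, fit2$candidates)
  expect_equal(coef(fit), coef(fit2))
  # methods run
  expect_output(print(fit), "best training cost")
  expect_output(print(summary(fit)), "candidates")
  pr <- predict(fit)
  expect_equal(nrow(pr), 6)
  expect_true(all(pr$w > 0) && all(pr$sigma > 0))
  sims <- simulate(fit, nsim = 2, seed = 9)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "bold_timeseries")
})

test_that("diversity selection skips near-duplicate parameter maps", {
  sc <- small_sc(8, seed = 5); maps <- small_maps(8, seed = 5)
  co <- linear_coefficients(c_w = 0.8, c_I = 0.3, c_sigma = 0.03, G = 0.5)
  tg <- generate_ground_truth(co, synthetic_spec(8, seed = 5),
                              config = short_config(), n_sims = 1, seed = 31,
                              window = 43)
  base <- c(a_w = 0.2, b_w = 0, c_w = 0.8, a_I = 0, b_I = 0, c_I = 0.3,
            a_sigma = 0, b_sigma = 0, c_sigma = 0.03, G = 0.5)
  # pool: best; a near-duplicate of the best (tiny offset change only);
  # and a differently-shaped candidate
  dup <- base; dup["c_w"] <- 0.81
  other <- base; other["a_w"] <- -0.3; other["b_w"] <- 0.4
  pool <- as.data.frame(rbind(base, dup, other))
  pool$train_cost <- c(0.10, 0.11, 0.30)
  sel <- suppressWarnings(
    select_top_diverse(pool, tg, k = 2, n_sims = 1, seed = 31,
                       config = short_config(), window = 43))
  expect_equal(nrow(sel), 2)
  # the near-duplicate is skipped: selected maps differ in shape
  expect_equal(sort(sel$a_w), sort(c(0.2, -0.3)))
  # exact duplicates collapse to a single selection
  pool2 <- as.data.frame(rbind(base, base, base))
  pool2$train_cost <- c(0.1, 0.1, 0.1)
  sel2 <- suppressWarnings(
    select_top_diverse(pool2, tg, k = 3, n_sims = 1, seed = 31,
                       config = short_config(), window = 43))
  expect_equal(nrow(sel2), 1)
  # greedy order: first selected has the lowest validation cost
  expect_equal(sel$validation_cost, sort(sel$validation_cost))
})
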