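test_that("the expected unconditional association follows the closed form", {
  expect_equal(true_alpha1(growth_params(), outcome_params()), 0.54)
  expect_equal(true_alpha1(growth_params(rho_u01 = 0), outcome_params()), 0.5)
  expect_equal(true_alpha1(growth_params(sigma_u1 = 0), outcome_params()),
               0.5)
  expect_error(true_alpha1(growth_params(sigma_u0 = 0), outcome_params()),
               "positive")
})

test_that("relative bias and coverage summaries behave on edge cases", {
  rb <- relative_bias(rep(2, 10), 2)
  expect_equal(rb$bias_pct, 0)
  expect_equal(relative_bias(rep(1.08 * 2, 5), 2)$bias_pct, 8)
  expect_error(relative_bias(1:3, 0), "zero")

  expect_equal(coverage(rnorm(20), rep(1e6, 20), 0)$coverage_pct, 100)
  expect_equal(coverage(rep(1, 20), rep(1e-12, 20), 0)$coverage_pct, 0)
  expect_error(coverage(1:3, c(1, -1, 1), 0))
})

test_that("a correctly specified oracle regression attains nominal coverage", {
  # regress the outcome on the true random effects: classical OLS theory
  # applies exactly, so bias ~ 0 and 1.96-SE coverage ~ 95%
  est3 <- se3 <- est4 <- se4 <- numeric(200)
  sched <- draw_age_schedule(n_individuals = 300, seed = 80)
  for (r in 1:200) {
    dat <- simulate_trajectories(sched, growth_params(), outcome_params(),
                                 seed = derive_seed(80, "oracle", r))
    s <- summary(lm(dat$bp ~ dat$true_u0 + dat$true_u1))$coefficients
    est3[r] <- s[2, 1]; se3[r] <- s[2, 2]
    est4[r] <- s[3, 1]; se4[r] <- s[3, 2]
  }
  rb <- relative_bias(est4, 2)
  expect_lt(abs(rb$bias_pct), 3 * rb$mc_se)
  cv <- coverage(est4, se4, 2)
  expect_lt(abs(cv$coverage_pct - 95), 3 * cv$mc_se + 1e-9)
  cv3 <- coverage(est3, se3, 0.5)
  expect_lt(abs(cv3$coverage_pct - 95), 3 * cv3$mc_se + 1e-9)
})

test_that("scenario runner emits a well-formed table for all methods", {
  scn <- scenario("baseline", n_individuals = 60, n_replicates = 2,
                  master_seed = 3)
  res <- run_scenario(scn)
  expect_s3_class(res, "scenario_result")
  expect_setequal(unique(res$method),
                  c("simple", "ols", "mlm_shrunken", "mlm_inflated",
                    "bvm_inflated", "sem"))
  expect_setequal(unique(res$parameter), c("alpha1", "alpha4"))
  expect_true(all(res$coverage_pct >= 0 & res$coverage_pct <= 100))
  expect_true(all(res$n_converged <= res$n_replicates))
  expect_error(run_scenario(scn, methods = "psychic"), "unknown method")
})

test_that("scenario results are reproducible and reportable", {
  scn <- scenario("sigma_ebp", grid = c(9, 11), n_individuals = 80,
                  n_replicates = 3, master_seed = 5)
  r1 <- run_scenario(scn, methods = c("simple", "ols"))
  r2 <- run_scenario(scn, methods = c("simple", "ols"))
  expect_equal(as.data.frame(r1), as.data.frame(r2))
  expect_equal(unique(r1$grid_value), c(9, 11))

  dir <- file.path(tempdir(), "jg-report")
  paths <- report(r1, dir)
  expect_true(all(file.exists(paths)))
  back <- read.csv(file.path(dir, "scenario_results.csv"))
  expect_equal(back$rel_bias_pct, r1$rel_bias_pct, tolerance = 1e-12)
})

test_that("method ordering and bias signs at baseline match theory", {
  scn <- scenario("baseline", n_replicates = 150, master_seed = 42)
  res <- run_scenario(scn, methods = c("simple", "ols", "mlm_shrunken",
                                       "mlm_inflated", "bvm_inflated"))
  b <- function(m, p) res$rel_bias_pct[res$method == m & res$parameter == p]
  # birth-length association: attenuation orders the two-stage methods,
  # shrunken residuals bias away from the null, joint model is least biased
  expect_lt(b("simple", "alpha1"), 0)
  expect_lt(b("ols", "alpha1"), 0)
  expect_gt(b("mlm_shrunken", "alpha1"), 0)
  expect_gt(abs(b("simple", "alpha1")), abs(b("ols", "alpha1")))
  expect_gt(abs(b("ols", "alpha1")), abs(b("mlm_shrunken", "alpha1")))
  expect_gt(abs(b("mlm_shrunken", "alpha1")), abs(b("mlm_inflated", "alpha1")))
  expect_lt(abs(b("bvm_inflated", "alpha1")), 10)
  # growth-rate association: inflation biases toward the null, more than
  # shrinkage; per-individual OLS biases away from the null at baseline
  expect_lt(b("mlm_inflated", "alpha4"), 0)
  expect_gt(abs(b("mlm_inflated", "alpha4")), abs(b("mlm_shrunken", "alpha4")))
  expect_gt(b("ols", "alpha4"), 0)
})

test_that("growth-rate bias of the coupled methods crosses zero along the correlation sweep", {
  scn <- scenario("rho_u01", grid = c(-0.4, 0.1, 0.6), n_individuals = 1000,
                  n_replicates = 120, master_seed = 9)
  res <- run_scenario(scn, methods = c("simple", "ols"))
  for (m in c("simple", "ols")) {
    bias <- res$rel_bias_pct[res$method == m & res$parameter == "alpha4"]
    expect_equal(order(bias), 1:3)  # monotone increasing in rho
    expect_lt(bias[1], 0)
    expect_gt(bias[3], 0)
  }
})
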