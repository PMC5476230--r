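test_that("univariate ML fit agrees with an independent mixed-model fitter", {
  skip_if_not_installed("lme4")
  dat <- make_data(J = 200, seed = 14)
  fit <- fit_univariate_lmm(dat)
  expect_true(fit$converged)

  long <- data.frame(id = rep(seq_len(200), 5),
                     age = as.vector(dat$ages),
                     h = as.vector(dat$heights))
  lf <- lme4::lmer(h ~ age + (age | id), data = long, REML = FALSE)
  expect_equal(fit$loglik, as.numeric(logLik(lf)), tolerance = 1e-4)
  expect_equal(unname(fit$fixed), unname(lme4::fixef(lf)), tolerance = 1e-4)
  # reported loglik matches the independent R evaluator at the fitted params
  expect_equal(fit$loglik,
               r_loglik(dat, fit$fixed, fit$omega, fit$sigma_eh),
               tolerance = 1e-6)
})

test_that("fixed effects equal the brute-force GLS estimator at the fitted covariance", {
  dat <- make_data(J = 40, seed = 20)
  fit <- fit_univariate_lmm(dat)
  # assemble the full block covariance and solve the GLS normal equations
  XtVX <- matrix(0, 2, 2); XtVy <- numeric(2)
  for (j in 1:40) {
    Z <- cbind(1, dat$ages[j, ])
    V <- Z %*% fit$omega %*% t(Z) + fit$sigma_eh^2 * diag(5)
    W <- solve(V)
    XtVX <- XtVX + t(Z) %*% W %*% Z
    XtVy <- XtVy + t(Z) %*% W %*% dat$heights[j, ]
  }
  expect_equal(unname(fit$fixed), drop(solve(XtVX, XtVy)), tolerance = 1e-8)
})

test_that("BLUPs equal Henderson mixed-model-equation solutions", {
  dat <- make_data(J = 20, seed = 31)
  fit <- fit_univariate_lmm(dat)
  mme <- mme_blups(dat, fit$omega, fit$sigma_eh)
  # the MME jointly solve for beta and u; both must agree with the fit
  expect_equal(unname(fit$fixed), mme$beta, tolerance = 1e-8)
  res <- blup_residuals(fit, dat)
  expect_equal(unname(res$u_hat), unname(mme$u), tolerance = 1e-8)
})

test_that("BLUPs shrink and respect the degenerate limits", {
  dat <- make_data(J = 400, seed = 8)
  fit <- fit_univariate_lmm(dat)
  res <- blup_residuals(fit, dat)
  expect_false(res$inflated)
  expect_lt(var(res$u_hat[, 1]), fit$omega[1, 1])
  expect_lt(var(res$u_hat[, 2]), fit$omega[2, 2])

  # zero random-effect covariance: all residuals exactly zero
  fit0 <- fit
  fit0$omega <- matrix(0, 2, 2, dimnames = dimnames(fit$omega))
  expect_equal(max(abs(blup_residuals(fit0, dat)$u_hat)), 0)

  # vanishing measurement error: BLUPs approach per-individual OLS deviations
  gsmall <- growth_params(sigma_eh = 1e-3)
  dsmall <- make_data(J = 60, seed = 12, growth = gsmall)
  fsmall <- fit_univariate_lmm(dsmall)
  rsmall <- blup_residuals(fsmall, dsmall)
  ols <- ols_summaries(dsmall)
  expect_equal(rsmall$u_hat[, 1], ols$b_hat - fsmall$fixed[[1]],
               tolerance = 1e-2, ignore_attr = TRUE)
  expect_equal(rsmall$u_hat[, 2], ols$g_hat - fsmall$fixed[[2]],
               tolerance = 1e-2, ignore_attr = TRUE)
})

test_that("re-inflation calibrates the sample covariance exactly", {
  dat <- make_data(J = 300, seed = 18)
  fit <- fit_univariate_lmm(dat)
  res <- blup_residuals(fit, dat)
  infl <- inflate_residuals(res, fit$omega)
  expect_true(infl$inflated)
  expect_equal(cov_j(infl$u_hat), unname(fit$omega), tolerance = 1e-10,
               ignore_attr = TRUE)
  # lower orientation: inflated intercept residual is a pure positive
  # rescaling of the shrunken one
  c0 <- res$u_hat[, 1] - mean(res$u_hat[, 1])
  c1 <- infl$u_hat[, 1] - mean(infl$u_hat[, 1])
  expect_equal(sd(c1 / c0), 0, tolerance = 1e-8)
  expect_gt(mean(c1 / c0), 0)
  # upper orientation calibrates too but mixes the slope in
  influ <- inflate_residuals(res, fit$omega, orientation = "upper")
  expect_equal(cov_j(influ$u_hat), unname(fit$omega), tolerance = 1e-10,
               ignore_attr = TRUE)
  cu <- influ$u_hat[, 1] - mean(influ$u_hat[, 1])
  expect_gt(sd(cu / c0), 1e-3)

  # inflating residuals already at the target is the identity map
  same <- inflate_residuals(res, cov_j(res$u_hat))
  expect_equal(same$u_hat, res$u_hat, tolerance = 1e-10)
  expect_error(inflate_residuals(infl, fit$omega), "already inflated")
})

test_that("hand-worked inflation: diag(4,1) residuals to identity target", {
  u <- cbind(c(2, -2, 2, -2), c(1, 1, -1, -1))  # cov_J = diag(4, 1)
  res <- structure(list(u_hat = u, inflated = FALSE,
                        reference_cov = diag(c(4, 1)), type = "univariate"),
                   class = "residual_set")
  infl <- inflate_residuals(res, diag(2))
  expect_equal(infl$u_hat, cbind(0.5 * u[, 1], u[, 2]),
               ignore_attr = TRUE)
})

test_that("bivariate fit estimates the joint covariance structure", {
  # independence case: outcome unrelated to growth
  o0 <- outcome_params(alpha3 = 0, alpha4 = 0)
  d0 <- make_data(J = 600, seed = 25, outcome = o0)
  f0 <- fit_bivariate_lmm(d0)
  expect_true(f0$converged)
  expect_lt(abs(f0$omega[1, 3]), 3 * 2.5 * 10 / sqrt(600))
  expect_lt(abs(f0$omega[2, 3]), 3 * 0.5 * 10 / sqrt(600))

  # moment recovery of the conditional effects on a baseline dataset
  dat <- make_data(J = 1000, seed = 26)
  fit <- fit_bivariate_lmm(dat)
  a <- alpha_from_omega(fit$omega)
  expect_lt(abs(a[["alpha3"]] - 0.5), 0.5)
  expect_lt(abs(a[["alpha4"]] - 2.0), 1.5)
  # its loglik matches the independent R evaluator
  expect_equal(fit$loglik,
               r_loglik(dat, fit$fixed, fit$omega, fit$sigma_eh),
               tolerance = 1e-6)
})

test_that("joint likelihood factorises when outcome cross-covariances vanish", {
  dat <- make_data(J = 80, seed = 33)
  ufit <- fit_univariate_lmm(dat)
  sBP2 <- mean((dat$bp - mean(dat$bp))^2)
  omega3 <- rbind(cbind(ufit$omega, 0), c(0, 0, sBP2))
  ll_joint <- lmm_loglik(dat, c(ufit$fixed, mean(dat$bp)), omega3,
                         ufit$sigma_eh)
  ll_bp <- sum(dnorm(dat$bp, mean(dat$bp), sqrt(sBP2), log = TRUE))
  expect_equal(ll_joint, ufit$loglik + ll_bp, tolerance = 1e-8)
})

test_that("moment recovery from the analytic joint covariance is exact", {
  g <- growth_params(); o <- outcome_params()
  Om2 <- omega_u(g)
  cross <- Om2 %*% c(o$alpha3, o$alpha4)
  sBP2 <- drop(t(c(o$alpha3, o$alpha4)) %*% Om2 %*% c(o$alpha3, o$alpha4)) +
    o$sigma_ebp^2
  Om3 <- rbind(cbind(Om2, cross), c(cross, sBP2))
  a <- alpha_from_omega(Om3)
  expect_equal(unname(a), c(0.54, 0.5, 2.0), tolerance = 1e-12)

  expect_equal(unname(alpha_from_omega(rbind(cbind(Om2, 0), c(0, 0, 9)))),
               c(0, 0, 0))
  Omd <- diag(c(4, 0.25, 9)); Omd[1, 3] <- Omd[3, 1] <- 1
  Omd[2, 3] <- Omd[3, 2] <- 0.3
  expect_equal(alpha_from_omega(Omd)[["alpha3"]], 1 / 4)
  expect_equal(alpha_from_omega(Omd)[["alpha4"]], 0.3 / 0.25)
})

test_that("estimates add fixed effects to residuals, with method labels", {
  dat <- make_data(J = 50, seed = 40)
  fit <- fit_univariate_lmm(dat)
  res <- blup_residuals(fit, dat)
  zero <- res; zero$u_hat[] <- 0
  est0 <- estimates_from_residuals(fit, zero)
  expect_equal(est0$b_hat, rep(fit$fixed[[1]], 50))
  expect_equal(est0$g_hat, rep(fit$fixed[[2]], 50))
  expect_equal(est0$method, "mlm_shrunken")
  infl <- inflate_residuals(res, fit$omega)
  expect_equal(estimates_from_residuals(fit, infl)$method, "mlm_inflated")

  bfit <- fit_bivariate_lmm(dat)
  bres <- inflate_residuals(blup_residuals(bfit, dat), bfit$omega)
  best <- estimates_from_residuals(bfit, bres)
  expect_equal(best$method, "bvm_inflated")
  expect_gt(cor(best$bp_hat, dat$bp), 0.9)
})

test_that("mean fitted covariance tracks the truth over replicates", {
  sched <- draw_age_schedule(n_individuals = 300, seed = 61)
  Om <- omega_u(growth_params())
  oms <- array(NA_real_, c(200, 2, 2))
  for (r in 1:200) {
    dat <- simulate_trajectories(sched, growth_params(), outcome_params(),
                                 seed = derive_seed(61, "rec", r))
    oms[r, , ] <- fit_univariate_lmm(dat)$omega
  }
  for (i in 1:2) for (k in 1:2) {
    mc_se <- sd(oms[, i, k]) / sqrt(200)
    expect_lt(abs(mean(oms[, i, k]) - Om[i, k]), 3 * mc_se + 1e-8)
  }
})

test_that("fit summaries serialise to JSON and back", {
  dat <- make_data(J = 40, seed = 90)
  fit <- fit_univariate_lmm(dat)
  js <- jsonlite::fromJSON(fit_summary_json(fit))
  expect_equal(js$fixed$beta0, fit$fixed[["beta0"]])
  expect_equal(unlist(js$omega[1, ]), unname(fit$omega[1, ]),
               ignore_attr = TRUE)
  expect_true(js$converged)
  sem <- fit_sem_conditional(dat)
  js2 <- jsonlite::fromJSON(fit_summary_json(sem))
  expect_equal(js2$alpha4, sem$alpha4)
})
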