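test_that("individual-ages SEM is the bivariate joint model in disguise", {
  dat <- make_data(J = 150, seed = 52)
  bfit <- fit_bivariate_lmm(dat)
  direct <- fit_sem_conditional(dat, "individual_ages", engine = "direct")
  expect_true(direct$converged)
  expect_equal(direct$loglik, bfit$loglik, tolerance = 1e-4)
  a <- alpha_from_omega(bfit$omega)
  expect_equal(direct$alpha3, a[["alpha3"]], tolerance = 1e-3)
  expect_equal(direct$alpha4, a[["alpha4"]], tolerance = 1e-3)

  # the reparameterisation engine reports the same fit, with delta-method
  # SEs close to the direct observed-information SEs
  rep_fit <- fit_sem_conditional(dat, "individual_ages")
  expect_equal(rep_fit$loglik, direct$loglik, tolerance = 1e-4)
  expect_equal(rep_fit$alpha4, direct$alpha4, tolerance = 1e-3)
  expect_equal(rep_fit$alpha4_se, direct$alpha4_se, tolerance = 0.05)
})

test_that("unconditional refit matches the plug-in transform", {
  dat <- make_data(J = 400, seed = 53)
  cf <- fit_sem_conditional(dat)
  uf <- fit_sem_unconditional(dat)
  expect_equal(uf$alpha1, alpha1_from_sem(cf), tolerance = 1e-8)
  expect_equal(uf$loglik, cf$loglik, tolerance = 1e-6)
  expect_true(is.finite(uf$alpha1_se) && uf$alpha1_se > 0)

  # the direct unconditional optimisation agrees (same likelihood manifold)
  ud <- fit_sem_unconditional(dat, "individual_ages", engine = "direct")
  expect_equal(ud$alpha1, uf$alpha1, tolerance = 5e-3)
})

test_that("null outcome coefficients are recovered as null", {
  o0 <- outcome_params(alpha3 = 0, alpha4 = 0)
  dat <- make_data(J = 500, seed = 54, outcome = o0)
  cf <- fit_sem_conditional(dat)
  expect_lt(abs(cf$alpha3 / cf$alpha3_se), 3.5)
  expect_lt(abs(cf$alpha4 / cf$alpha4_se), 3.5)
})

test_that("fixed mean-age loadings agree with individual ages when there is no jitter", {
  dat <- make_data(J = 400, seed = 55, age_sds = rep(0, 5))
  ind <- fit_sem_conditional(dat, "individual_ages")
  # identical models once the residual structure matches: pooled residual
  # variance, loadings at the (degenerate) observed ages
  fix <- fit_sem_conditional(dat, "fixed_mean_ages",
                             residual_variances = "pooled")
  expect_true(fix$converged)
  expect_equal(fix$loglik, ind$loglik, tolerance = 1e-4)
  expect_equal(fix$alpha4, ind$alpha4, tolerance = 1e-3)
  expect_equal(fix$alpha3, ind$alpha3, tolerance = 1e-3)
  # freeing the per-occasion residual variances can only raise the
  # likelihood, and on a balanced design only marginally shifts the fit
  free <- fit_sem_conditional(dat, "fixed_mean_ages")
  expect_gte(free$loglik, fix$loglik - 1e-6)
  expect_equal(free$alpha4, ind$alpha4, tolerance = 0.2)
})

test_that("the unconditional transform reproduces the closed-form arithmetic", {
  fake <- structure(list(
    model = "conditional", alpha3 = 0.5, alpha4 = 2.0,
    latent_cov = matrix(c(2.5^2, 0.1 * 2.5 * 0.5,
                          0.1 * 2.5 * 0.5, 0.5^2), 2, 2)),
    class = "sem_fit")
  expect_equal(alpha1_from_sem(fake), 0.54)
  fake$alpha4 <- 0
  expect_equal(alpha1_from_sem(fake), 0.5)
  fake$alpha4 <- 2
  fake$latent_cov[1, 2] <- fake$latent_cov[2, 1] <- 0
  expect_equal(alpha1_from_sem(fake), 0.5)
})

test_that("fixed-loadings growth-rate coefficient is sensitive to the age draw", {
  # fit the moment likelihood to the *population* moments implied by a
  # realised age schedule: the resulting pseudo-true coefficient depends on
  # the empirical jitter covariances of that draw, scaled by the squared
  # mean growth rate, so it shifts materially from draw to draw even though
  # sampling noise has been removed entirely
  g <- growth_params(sigma_u1 = 0.2); o <- outcome_params()
  Om <- omega_u(g)
  plim_alpha4 <- function(age_seed) {
    sched <- draw_age_schedule(n_individuals = 1000, seed = age_seed)
    A <- sched$ages; J <- nrow(A)
    Ey <- matrix(0, J, 6); Cw <- matrix(0, 6, 6)
    for (j in seq_len(J)) {
      L <- rbind(cbind(1, A[j, ]), c(o$alpha3, o$alpha4))
      Ey[j, ] <- c(g$beta0 + g$beta1 * A[j, ], o$gamma0)
      Cw <- Cw + L %*% Om %*% t(L)
    }
    Cw <- Cw / J + diag(c(rep(g$sigma_eh^2, 5), o$sigma_ebp^2))
    Spop <- Cw + cov_j(Ey)
    nll <- jointgrowth:::.sem_nll_moments(sched$mean_ages, 1000,
                                          colMeans(Ey), Spop, "conditional")
    dat0 <- simulate_trajectories(sched, g, o, seed = 1)
    th0 <- unname(jointgrowth:::.sem_start(dat0, "conditional", TRUE))
    opt <- nlminb(th0, nll, control = list(iter.max = 2000,
                                           eval.max = 5000,
                                           rel.tol = 1e-14))
    jointgrowth:::.sem_natural(opt$par, "conditional")$a4
  }
  a4 <- vapply(c(1, 9, 13), plim_alpha4, numeric(1))
  expect_gt(max(a4) - min(a4), 0.1)      # > 5% of the true value 2.0
  expect_gt(max(abs(a4 - 2)) / 2, 0.1)   # some draws biased beyond 10%
})
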