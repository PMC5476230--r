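# Shared fixtures and independent oracle implementations used across tests.
# The oracles deliberately avoid the package's compiled code paths: plain R
# loops, dense linear algebra, and textbook formulas.

make_data <- function(J = 200, seed = 1, growth = growth_params(),
                      outcome = outcome_params(),
                      age_sds = c(0.025, 0.5, 0.5, 0.5, 0.5)) {
  sched <- draw_age_schedule(age_sds = age_sds, n_individuals = J,
                             seed = derive_seed(seed, "ages"))
  simulate_trajectories(sched, growth, outcome,
                        seed = derive_seed(seed, "data"))
}

# per-individual design matrices for the univariate / bivariate models
design_of <- function(ages_row, joint) {
  Z <- cbind(1, ages_row)
  if (!joint) return(Z)
  rbind(cbind(Z, 0), c(0, 0, 1))
}

# independent marginal Gaussian log-likelihood (R loop, dense algebra)
r_loglik <- function(data, beta, omega, sigma_eh) {
  joint <- length(beta) == 3
  J <- nrow(data$ages); I <- ncol(data$ages)
  ll <- 0
  for (j in seq_len(J)) {
    A <- design_of(data$ages[j, ], joint)
    y <- if (joint) c(data$heights[j, ], data$bp[j]) else data$heights[j, ]
    V <- A %*% omega %*% t(A)
    diag(V)[seq_len(I)] <- diag(V)[seq_len(I)] + sigma_eh^2
    ll <- ll + mvtnorm_logdens(y, drop(A %*% beta), V)
  }
  ll
}

mvtnorm_logdens <- function(y, mu, V) {
  ch <- chol(V)
  z <- backsolve(ch, y - mu, transpose = TRUE)
  -0.5 * (length(y) * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(z^2))
}

# Henderson mixed-model-equation BLUPs for the univariate growth model:
# a genuinely different route to the random-effect predictions (one big
# sparse-free dense solve over all individuals simultaneously)
mme_blups <- function(data, omega, sigma_eh) {
  J <- nrow(data$ages); I <- ncol(data$ages)
  X <- do.call(rbind, lapply(seq_len(J), function(j) cbind(1, data$ages[j, ])))
  Z <- matrix(0, J * I, 2 * J)
  for (j in seq_len(J))
    Z[(j - 1) * I + seq_len(I), (j - 1) * 2 + 1:2] <- cbind(1, data$ages[j, ])
  y <- as.vector(t(data$heights))
  s2 <- sigma_eh^2
  Oinv <- solve(omega)
  G <- kronecker(diag(J), Oinv)
  lhs <- rbind(cbind(crossprod(X) / s2, crossprod(X, Z) / s2),
               cbind(crossprod(Z, X) / s2, crossprod(Z) / s2 + G))
  rhs <- c(crossprod(X, y), crossprod(Z, y)) / s2
  sol <- solve(lhs, rhs)
  list(beta = sol[1:2],
       u = matrix(sol[-(1:2)], J, 2, byrow = TRUE))
}

# denominator-J sample covariance of mean-centred columns
cov_j <- function(m) {
  mc <- sweep(m, 2, colMeans(m))
  crossprod(mc) / nrow(m)
}
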