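# Maximum-likelihood mixed models fitted by Fisher scoring on the variance
# scale (equivalent to IGLS for Gaussian multilevel models), with a compiled
# core. The bivariate model stacks the five height rows and the outcome row
# per individual; the outcome row has no occasion-level residual, its
# variance living entirely inside the 3x3 random-effect covariance.

# Moment-based starting values from per-individual OLS summaries.
.start_values <- function(data, joint) {
  est <- ols_summaries(data)
  m <- if (joint) cbind(est$b_hat, est$g_hat, data$bp)
       else cbind(est$b_hat, est$g_hat)
  Omega0 <- cov(m)
  # pooled residual variance around the per-individual lines
  fitted <- est$b_hat + est$g_hat * data$ages
  rss <- sum((data$heights - fitted)^2)
  df <- n_individuals(data) * (n_occasions(data) - 2L)
  sige2_0 <- max(rss / max(df, 1L), 1e-6)
  list(Omega0 = Omega0, sige2_0 = sige2_0)
}

# vech ordering used by the compiled core: column-major lower triangle,
# (1,1),(2,1),...,(q,1),(2,2),... ; the variance-parameter vector appends
# the occasion residual variance sige2 as its last entry
.vech_pairs <- function(q) {
  do.call(rbind, lapply(seq_len(q), function(b)
    cbind(a = seq(b, q), b = b)))
}

.omega_from_theta <- function(theta, q) {
  pairs <- .vech_pairs(q)
  O <- matrix(0, q, q)
  for (k in seq_len(nrow(pairs))) {
    O[pairs[k, 1], pairs[k, 2]] <- theta[k]
    O[pairs[k, 2], pairs[k, 1]] <- theta[k]
  }
  O
}

# central-difference jacobian of a vector-valued function
.num_jacobian <- function(f, x, eps = 1e-5) {
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x))
  for (k in seq_along(x)) {
    h <- eps * max(abs(x[k]), 1)
    xp <- x; xp[k] <- x[k] + h
    xm <- x; xm[k] <- x[k] - h
    J[, k] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

.lmm_names <- function(joint) {
  if (joint) list(fixed = c("beta0", "beta1", "beta2"),
                  re = c("u0", "u1", "u_bp"))
  else list(fixed = c("beta0", "beta1"), re = c("u0", "u1"))
}

.fit_lmm <- function(data, joint, start = NULL, max_iter = 500,
                     tol = 1e-9) {
  stopifnot(inherits(data, "trajectory_data"))
  if (n_individuals(data) < 10) stop("need at least 10 individuals")
  if (n_occasions(data) < 2) stop("need at least 2 occasions")
  if (joint && is.null(data$bp)) stop("joint model needs an outcome vector")
  if (is.null(start)) start <- .start_values(data, joint)
  bp <- if (joint) data$bp else numeric(0)

  fit <- cpp_fit_lmm(data$ages, data$heights, bp, joint,
                     start$Omega0, start$sige2_0, max_iter, tol)

  nm <- .lmm_names(joint)
  omega <- fit$omega
  dimnames(omega) <- list(nm$re, nm$re)
  # boundary estimates can leave Omega indefinite; project for downstream use
  ev <- eigen(omega, symmetric = TRUE)
  if (min(ev$values) < -1e-8 * max(abs(ev$values))) {
    warning("random-effect covariance estimate indefinite; projected to PSD")
    vals <- pmax(ev$values, 0)
    omega <- ev$vectors %*% (vals * t(ev$vectors))
    dimnames(omega) <- list(nm$re, nm$re)
  }

  structure(list(
    type = if (joint) "bivariate" else "univariate",
    fixed = setNames(as.numeric(fit$beta), nm$fixed),
    fixed_se = setNames(sqrt(diag(fit$beta_cov)), nm$fixed),
    fixed_vcov = fit$beta_cov,
    omega = omega,
    sigma_eh = sqrt(max(fit$sige2, 0)),
    theta = as.numeric(fit$theta),
    theta_info = fit$theta_info,
    loglik = fit$loglik,
    converged = fit$converged,
    n_iter = fit$n_iter), class = "lmm_fit")
}

#' Fit the univariate growth multilevel model
#'
#' Maximum-likelihood fit of the random-intercept/random-slope model for
#' height on age, with marginal per-individual covariance
#' \eqn{Z_j \Omega Z_j' + \sigma_{eh}^2 I}. Estimation is Fisher scoring on
#' the variance parameters alternated with generalised least squares for the
#' fixed effects (the IGLS scheme, which yields the ML solution for Gaussian
#' models), with step-halving and a relative log-likelihood convergence
#' tolerance of `tol`.
#'
#' @param data a `trajectory_data` object.
#' @param start optional list with `Omega0` (2x2) and `sige2_0` starting
#'   values; by default derived from per-individual OLS moments.
#' @param max_iter maximum scoring iterations.
#' @param tol relative log-likelihood change declaring convergence.
#' @return An object of class `lmm_fit` with elements `fixed`, `fixed_se`,
#'   `omega`, `sigma_eh`, `loglik`, `converged`, `n_iter`.
#' @seealso [fit_bivariate_lmm()], [blup_residuals()]
#' @export
fit_univariate_lmm <- function(data, start = NULL, max_iter = 500,
                               tol = 1e-9) {
  .fit_lmm(data, joint = FALSE, start = start, max_iter = max_iter, tol = tol)
}

#' Fit the bivariate joint growth-outcome multilevel model
#'
#' Joint maximum likelihood for the stacked response (heights plus the distal
#' outcome). The growth part is identical to [fit_univariate_lmm()]; the
#' outcome contributes one extra row per individual whose residual variance
#' and covariances with the growth random effects are estimated inside a 3x3
#' random-effect covariance (the outcome row has no occasion-level residual).
#'
#' @inheritParams fit_univariate_lmm
#' @return An `lmm_fit` with a 3x3 `omega` and a third fixed effect `beta2`
#'   (the outcome mean).
#' @export
fit_bivariate_lmm <- function(data, start = NULL, max_iter = 500,
                              tol = 1e-9) {
  .fit_lmm(data, joint = TRUE, start = start, max_iter = max_iter, tol = tol)
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("%s growth model (ML via Fisher scoring)\n",
              if (x$type == "bivariate") "Bivariate joint" else "Univariate"))
  cat(sprintf("  converged: %s in %d iterations, loglik %.4f\n",
              x$converged, x$n_iter, x$loglik))
  cat("  fixed effects:\n")
  print(round(rbind(estimate = x$fixed, se = x$fixed_se), 4))
  cat("  random-effect covariance:\n")
  print(round(x$omega, 4))
  cat(sprintf("  sigma_eh = %.4f\n", x$sigma_eh))
  invisible(x)
}

#' Evaluate the marginal log-likelihood at fixed parameters
#'
#' Mainly useful for constrained evaluations, e.g. verifying that the
#' bivariate likelihood with all outcome cross-covariances set to zero
#' factorises into the univariate growth likelihood plus an independent
#' Gaussian likelihood for the outcome.
#'
#' @param data a `trajectory_data` object.
#' @param beta fixed-effect vector (length 2, or 3 for the joint model).
#' @param omega random-effect covariance (2x2 or 3x3).
#' @param sigma_eh occasion-level residual SD.
#' @return The log-likelihood value.
#' @export
lmm_loglik <- function(data, beta, omega, sigma_eh) {
  joint <- length(beta) == 3L
  bp <- if (joint) data$bp else numeric(0)
  cpp_lmm_loglik(data$ages, data$heights, bp, joint, as.numeric(beta),
                 omega, sigma_eh^2)
}

#' Serialise a model fit as JSON
#'
#' Writes the interchange summary of a mixed-model or SEM fit — fixed
#' effects or structural coefficients with standard errors, covariance
#' entries, residual SDs, log-likelihood and convergence status — as JSON.
#'
#' @param fit an `lmm_fit` or `sem_fit` object.
#' @param path optional file path; if omitted the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
fit_summary_json <- function(fit, path = NULL) {
  x <- if (inherits(fit, "lmm_fit")) {
    list(model = paste0(fit$type, "_lmm"),
         fixed = as.list(fit$fixed), fixed_se = as.list(fit$fixed_se),
         omega = fit$omega, sigma_eh = fit$sigma_eh,
         loglik = fit$loglik, converged = fit$converged,
         n_iter = fit$n_iter)
  } else if (inherits(fit, "sem_fit")) {
    keep <- intersect(c("model", "loadings_mode", "engine", "alpha0",
                        "alpha0_se", "alpha1", "alpha1_se", "alpha2",
                        "alpha2_se", "alpha3", "alpha3_se", "alpha4",
                        "alpha4_se", "latent_means", "sigma_e1",
                        "sigma_e2", "loglik", "converged"), names(fit))
    c(fit[keep], list(latent_cov = fit$latent_cov))
  } else stop("unsupported fit object")
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Recover association coefficients from the joint covariance matrix
#'
#' Moment-based recovery of the conditional coefficients and of the
#' unconditional birth-length association from the 3x3 random-effect
#' covariance of the bivariate model: with growth block \eqn{\Omega_{22}} and
#' outcome cross-covariances \eqn{(\sigma_{u0BP}, \sigma_{u1BP})},
#' \eqn{(\alpha_3, \alpha_4)' = \Omega_{22}^{-1}(\sigma_{u0BP},
#' \sigma_{u1BP})'} and \eqn{\alpha_1 = \sigma_{u0BP} / \sigma_{u0}^2}.
#'
#' @param omega a 3x3 covariance over (intercept, slope, outcome) deviations.
#' @return Named numeric vector `c(alpha1, alpha3, alpha4)`.
#' @export
alpha_from_omega <- function(omega) {
  stopifnot(is.matrix(omega), all(dim(omega) == c(3, 3)))
  g <- omega[1:2, 1:2]
  if (abs(det(g)) < 1e-12 * max(abs(g), 1)^2)
    stop("growth block of omega is singular")
  a34 <- solve(g, omega[1:2, 3])
  c(alpha1 = omega[1, 3] / omega[1, 1],
    alpha3 = a34[[1]], alpha4 = a34[[2]])
}
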