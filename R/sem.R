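# Latent growth curve SEM: measurement model H_i = B + t_i G + e1_i with
# loadings fixed at the occasion target ages (default) or at each
# individual's observed ages, and structural model
#   conditional:    BP = a2 + a3 B + a4 G + e2
#   unconditional:  BP = a0 + a1 B + e2, cov(e2, G) free
# Both are fitted by direct maximisation of the implied 6-dimensional
# Gaussian marginal likelihood; with fixed loadings this depends on the data
# only through the sample mean and covariance. The unconditional structural
# model is an exact reparameterisation of the conditional one (the free
# residual covariance absorbs the growth-rate path), so it attains the same
# likelihood while reading off the total birth-length effect and its SE
# directly.

# implied mean/covariance of (H_1..H_I, BP) for conditional-form parameters;
# se1 is the vector of occasion measurement-residual SDs (length 1 recycled)
.sem_implied <- function(tvec, muB, muG, a2, a3, a4, psi, se1, se2) {
  I <- length(tvec)
  Lam <- rbind(cbind(1, tvec), c(a3, a4))
  mu <- c(muB + tvec * muG, a2 + a3 * muB + a4 * muG)
  Sig <- Lam %*% psi %*% t(Lam) + diag(c(rep_len(se1^2, I), se2^2))
  list(mu = mu, Sig = Sig)
}

.psi_from_lc <- function(lc) {
  L <- matrix(c(exp(lc[1]), lc[2], 0, exp(lc[3])), 2, 2)
  tcrossprod(L)
}

# map working parameter vector -> conditional-form natural parameters
# conditional:   th = (muB, muG, a2, a3, a4, lc x3, log se2, log se1 ...)
# unconditional: th = (muB, muG, a0, a1, lc x3, c_perp, log sw, log se1 ...)
# The measurement-residual block (entries 10+) is a single log SD when
# residual variances are pooled, or one log SD per occasion when free.
.sem_natural <- function(th, model) {
  psi <- .psi_from_lc(th[if (model == "conditional") 6:8 else 5:7])
  se1 <- exp(th[10:length(th)])
  if (model == "conditional") {
    list(muB = th[1], muG = th[2], a2 = th[3], a3 = th[4], a4 = th[5],
         psi = psi, se1 = se1, se2 = exp(th[9]))
  } else {
    c_perp <- th[8]
    list(muB = th[1], muG = th[2], a2 = th[3],
         a3 = th[4] - c_perp * psi[1, 2] / psi[1, 1], a4 = c_perp,
         psi = psi, se1 = se1, se2 = exp(th[9]),
         alpha1 = th[4])
  }
}

# negative log-likelihood factories ------------------------------------------

.sem_nll_moments <- function(tvec, n, ybar, S, model) {
  I <- length(tvec)
  konst <- (I + 1) * log(2 * pi)
  function(th) {
    p <- .sem_natural(th, model)
    im <- .sem_implied(tvec, p$muB, p$muG, p$a2, p$a3, p$a4, p$psi,
                       p$se1, p$se2)
    ch <- tryCatch(chol(im$Sig), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    logdet <- 2 * sum(log(diag(ch)))
    Sinv <- chol2inv(ch)
    delta <- ybar - im$mu
    0.5 * n * (konst + logdet + sum(Sinv * S) +
                 drop(crossprod(delta, Sinv %*% delta)))
  }
}

.sem_nll_individual <- function(ages, heights, bp, model) {
  J <- nrow(ages); I <- ncol(ages)
  y <- cbind(heights, bp)
  konst <- (I + 1) * log(2 * pi)
  function(th) {
    p <- .sem_natural(th, model)
    nll <- 0.5 * J * konst
    for (j in seq_len(J)) {
      im <- .sem_implied(ages[j, ], p$muB, p$muG, p$a2, p$a3, p$a4, p$psi,
                         p$se1, p$se2)
      ch <- tryCatch(chol(im$Sig), error = function(e) NULL)
      if (is.null(ch)) return(1e10)
      z <- backsolve(ch, y[j, ] - im$mu, transpose = TRUE)
      nll <- nll + 0.5 * (2 * sum(log(diag(ch))) + sum(z^2))
    }
    nll
  }
}

.sem_start <- function(data, model, free_theta) {
  est <- ols_summaries(data)
  b <- est$b_hat; g <- est$g_hat
  psi0 <- cov(cbind(b, g)) * 0.9
  lc <- t(chol(psi0))
  se1 <- if (free_theta) {
    # per-occasion residual SD around lines evaluated at the target ages
    dev <- data$heights - (b + outer(g, data$mean_ages))
    pmax(apply(dev, 2, sd), 0.05)
  } else {
    fitted <- b + g * data$ages
    sqrt(max(mean((data$heights - fitted)^2), 1e-4))
  }
  if (model == "conditional") {
    cf <- .ols_coefficients(cbind(b, g), data$bp)
    c(mean(b), mean(g), cf$coef[1], cf$coef[2], cf$coef[3],
      log(lc[1, 1]), lc[2, 1], log(lc[2, 2]), log(cf$sigma), log(se1))
  } else {
    cf1 <- .ols_coefficients(cbind(b), data$bp)
    cf2 <- .ols_coefficients(cbind(b, g), data$bp)
    c(mean(b), mean(g), cf1$coef[1], cf1$coef[2],
      log(lc[1, 1]), lc[2, 1], log(lc[2, 2]),
      cf2$coef[3], log(cf2$sigma), log(se1))
  }
}

# Individual-ages SEM via the bivariate-MLM reparameterisation: identical
# likelihood, structural coefficients transformed from the 3x3 random-effect
# covariance, SEs by the delta method on the inverse Fisher information.
.sem_reparam <- function(data, model, fit = NULL) {
  if (is.null(fit)) fit <- fit_bivariate_lmm(data)
  Om <- fit$omega
  psi <- Om[1:2, 1:2]
  a34 <- solve(psi, Om[1:2, 3])
  vtheta <- tryCatch(solve(fit$theta_info), error = function(e) NULL)
  dfun <- if (model == "conditional") {
    function(th) {
      O <- .omega_from_theta(th, 3)
      a <- solve(O[1:2, 1:2], O[1:2, 3])
      c(a[1], a[2])
    }
  } else {
    function(th) {
      O <- .omega_from_theta(th, 3)
      O[1, 3] / O[1, 1]
    }
  }
  vc <- if (is.null(vtheta)) NULL else {
    Jc <- .num_jacobian(dfun, fit$theta)
    Jc %*% vtheta %*% t(Jc)
  }
  se_k <- function(k) {
    if (is.null(vc) || !is.finite(vc[k, k]) || vc[k, k] < 0) NA_real_
    else sqrt(vc[k, k])
  }
  # structural intercept: beta and theta blocks are information-orthogonal
  icpt_se <- function(w, grad_theta) {
    v <- drop(t(w) %*% fit$fixed_vcov %*% w)
    if (!is.null(vtheta))
      v <- v + drop(t(grad_theta) %*% vtheta %*% grad_theta)
    if (is.finite(v) && v >= 0) sqrt(v) else NA_real_
  }

  out <- list(
    model = model, loadings_mode = "individual_ages",
    engine = "reparam",
    latent_means = c(birth_length = fit$fixed[[1]],
                     growth_rate = fit$fixed[[2]]),
    latent_cov = matrix(psi, 2, 2,
                        dimnames = list(c("B", "G"), c("B", "G"))),
    sigma_e1 = fit$sigma_eh,
    loglik = fit$loglik, converged = fit$converged,
    lmm_fit = fit)
  if (model == "conditional") {
    out$alpha3 <- a34[[1]]; out$alpha4 <- a34[[2]]
    out$alpha2 <- fit$fixed[[3]] - a34[[1]] * fit$fixed[[1]] -
      a34[[2]] * fit$fixed[[2]]
    out$alpha3_se <- se_k(1); out$alpha4_se <- se_k(2)
    ga <- if (is.null(vtheta)) NULL else .num_jacobian(dfun, fit$theta)
    out$alpha2_se <- if (is.null(ga)) NA_real_ else
      icpt_se(c(-a34[[1]], -a34[[2]], 1),
              -fit$fixed[[1]] * ga[1, ] - fit$fixed[[2]] * ga[2, ])
    out$sigma_e2 <- sqrt(max(Om[3, 3] - sum(Om[1:2, 3] * a34), 0))
  } else {
    a1 <- Om[1, 3] / Om[1, 1]
    out$alpha1 <- a1
    out$alpha0 <- fit$fixed[[3]] - a1 * fit$fixed[[1]]
    out$alpha1_se <- se_k(1)
    ga <- if (is.null(vtheta)) NULL else .num_jacobian(dfun, fit$theta)
    out$alpha0_se <- if (is.null(ga)) NA_real_ else
      icpt_se(c(-a1, 0, 1), -fit$fixed[[1]] * drop(ga))
    out$sigma_e2 <- sqrt(max(Om[3, 3] - a1^2 * Om[1, 1], 0))
  }
  structure(out, class = "sem_fit")
}

.fit_sem <- function(data, loadings_mode, model, engine = "auto",
                     residual_variances = "auto") {
  stopifnot(inherits(data, "trajectory_data"))
  loadings_mode <- match.arg(loadings_mode,
                             c("individual_ages", "fixed_mean_ages"))
  engine <- match.arg(engine, c("auto", "reparam", "direct"))
  residual_variances <- match.arg(residual_variances,
                                  c("auto", "free", "pooled"))
  if (loadings_mode == "individual_ages" && engine != "direct")
    return(.sem_reparam(data, model))
  J <- n_individuals(data)
  free_theta <- if (residual_variances == "auto")
    loadings_mode == "fixed_mean_ages"
  else residual_variances == "free"
  if (loadings_mode == "fixed_mean_ages") {
    tvec <- data$mean_ages
    y <- cbind(data$heights, data$bp)
    ybar <- colMeans(y)
    S <- crossprod(sweep(y, 2, ybar)) / J
    nll <- .sem_nll_moments(tvec, J, ybar, S, model)
  } else {
    nll <- .sem_nll_individual(data$ages, data$heights, data$bp, model)
  }

  th0 <- unname(.sem_start(data, model, free_theta))
  opt <- nlminb(th0, nll, control = list(iter.max = 500, eval.max = 2000,
                                         rel.tol = 1e-12))
  # polish: restart once from the optimum; treat a stationary restart as
  # converged even when nlminb's last step triggers a false-convergence code
  opt2 <- nlminb(opt$par, nll, control = list(iter.max = 200,
                                              eval.max = 1000,
                                              rel.tol = 1e-12))
  stationary <- abs(opt2$objective - opt$objective) <
    1e-7 * (abs(opt$objective) + 1)
  if (opt2$objective <= opt$objective) opt <- opt2
  th <- unname(opt$par)
  converged <- is.finite(opt$objective) &&
    (opt$convergence == 0 || stationary)

  H <- tryCatch(optimHess(th, nll), error = function(e) NULL)
  vc <- if (!is.null(H))
    tryCatch(solve(H), error = function(e) NULL) else NULL
  se_of <- function(k) {
    if (is.null(vc)) return(NA_real_)
    v <- vc[k, k]
    if (!is.finite(v) || v < 0) NA_real_ else sqrt(v)
  }

  p <- .sem_natural(th, model)
  fit <- list(
    model = model,
    loadings_mode = loadings_mode,
    engine = if (loadings_mode == "fixed_mean_ages") "moments" else
      "direct",
    latent_means = c(birth_length = p$muB, growth_rate = p$muG),
    latent_cov = matrix(p$psi, 2, 2,
                        dimnames = list(c("B", "G"), c("B", "G"))),
    sigma_e1 = p$se1, sigma_e2 = p$se2,
    loglik = -opt$objective, converged = converged)
  if (model == "conditional") {
    fit$alpha2 <- p$a2; fit$alpha3 <- p$a3; fit$alpha4 <- p$a4
    fit$alpha2_se <- se_of(3); fit$alpha3_se <- se_of(4)
    fit$alpha4_se <- se_of(5)
  } else {
    fit$alpha0 <- p$a2
    fit$alpha1 <- p$alpha1
    fit$alpha0_se <- se_of(3); fit$alpha1_se <- se_of(4)
  }
  structure(fit, class = "sem_fit")
}

#' Fit the conditional latent growth curve SEM
#'
#' Latent factors for birth length and growth rate with loadings
#' \eqn{\lambda_{0i} = 1} and \eqn{\lambda_{1i}} equal to each individual's
#' observed measurement ages (`"individual_ages"`, the default, following
#' the measurement model's definition of the slope loadings) or fixed at the
#' occasion target ages (`"fixed_mean_ages"`). With individual ages the
#' model is an exact reparameterisation of the bivariate joint multilevel
#' model: by default it is fitted through that model's scoring algorithm and
#' the structural coefficients and their standard errors are recovered by
#' the delta method from the inverse Fisher information
#' (`engine = "reparam"`); `engine = "direct"` instead maximises the SEM
#' parameterisation itself (slower; useful to verify the equivalence). With
#' fixed loadings the implied 6-dimensional Gaussian likelihood depends on
#' the data only through its first two moments and is maximised directly;
#' the measurement residual variances are then free per occasion (usual
#' latent growth curve practice, and necessary when measurement ages are
#' jittered, since the growth-times-jitter term inflates each occasion's
#' residual variance differently). Note that with jittered ages the
#' fixed-loadings model is misspecified and its growth-rate coefficient is
#' sensitive to the realised age draw.
#'
#' @param data a `trajectory_data` object (complete design).
#' @param loadings_mode `"individual_ages"` or `"fixed_mean_ages"`.
#' @param engine `"auto"` (reparameterisation for individual ages, moment
#'   likelihood for fixed loadings), `"reparam"`, or `"direct"`.
#' @param residual_variances `"auto"` (free per occasion with fixed
#'   loadings, pooled otherwise), `"free"`, or `"pooled"`.
#' @return An object of class `sem_fit` with structural coefficients
#'   `alpha2`, `alpha3`, `alpha4` (and SEs), `latent_means`, `latent_cov`,
#'   residual SDs, `loglik` and a convergence flag.
#' @export
fit_sem_conditional <- function(data, loadings_mode = "individual_ages",
                                engine = "auto",
                                residual_variances = "auto") {
  .fit_sem(data, loadings_mode, "conditional", engine, residual_variances)
}

#' Fit the unconditional latent growth curve SEM
#'
#' Refits the SEM with the structural model regressing the outcome on the
#' birth-length factor alone, freeing the covariance between the structural
#' residual and the growth-rate factor so that the coefficient is the total
#' (unconditional) birth-length effect. This specification attains the same
#' likelihood as the conditional model and reads off `alpha1` with a direct
#' standard error.
#'
#' @inheritParams fit_sem_conditional
#' @return An `sem_fit` with `alpha0`, `alpha1` and SEs.
#' @seealso [alpha1_from_sem()] for the plug-in transform of the conditional
#'   fit (no SE).
#' @export
fit_sem_unconditional <- function(data, loadings_mode = "individual_ages",
                                  engine = "auto",
                                  residual_variances = "auto") {
  .fit_sem(data, loadings_mode, "unconditional", engine,
           residual_variances)
}

#' Unconditional association from a conditional SEM fit
#'
#' Plug-in transform \eqn{\alpha_1 = \alpha_3 + \alpha_4\, \psi_{12} /
#' \psi_{11}} (equivalently \eqn{\alpha_3 + \alpha_4 r\,\sigma_{u1} /
#' \sigma_{u0}}) of the fitted conditional parameters. Carries no standard
#' error; refitting with [fit_sem_unconditional()] is the SE-bearing route.
#'
#' @param fit a converged conditional `sem_fit`.
#' @return The implied unconditional birth-length association.
#' @export
alpha1_from_sem <- function(fit) {
  stopifnot(inherits(fit, "sem_fit"))
  if (fit$model != "conditional")
    stop("alpha1_from_sem expects a conditional fit")
  if (fit$latent_cov[1, 1] <= 0)
    stop("zero birth-length variance; alpha1 undefined")
  fit$alpha3 + fit$alpha4 * fit$latent_cov[1, 2] / fit$latent_cov[1, 1]
}

#' @export
print.sem_fit <- function(x, ...) {
  cat(sprintf("Latent growth SEM (%s, %s loadings)\n", x$model,
              x$loadings_mode))
  cat(sprintf("  converged: %s, loglik %.4f\n", x$converged, x$loglik))
  if (x$model == "conditional")
    cat(sprintf("  alpha3 = %.4f (SE %.4f), alpha4 = %.4f (SE %.4f)\n",
                x$alpha3, x$alpha3_se, x$alpha4, x$alpha4_se))
  else
    cat(sprintf("  alpha1 = %.4f (SE %.4f)\n", x$alpha1, x$alpha1_se))
  invisible(x)
}
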