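# Second-stage outcome regressions and the non-parametric cluster bootstrap.

# closed-form OLS with intercept: classical coefficients, SEs, residual SD
.ols_coefficients <- function(X, y) {
  X1 <- cbind(1, X)
  n <- nrow(X1); p <- ncol(X1)
  XtX <- crossprod(X1)
  if (rcond(XtX) < 1e-12) stop("singular design in second-stage regression")
  XtX_inv <- solve(XtX)
  cf <- drop(XtX_inv %*% crossprod(X1, y))
  res <- y - drop(X1 %*% cf)
  s2 <- sum(res^2) / (n - p)
  list(coef = cf, se = sqrt(diag(XtX_inv) * s2), sigma = sqrt(s2))
}

.assoc_row <- function(parameter, estimate, se, method,
                       ci_kind = "wald", ci = NULL) {
  if (is.null(ci)) ci <- estimate + c(-1.96, 1.96) * se
  data.frame(parameter = parameter, estimate = estimate, se = se,
             ci_low = ci[1], ci_high = ci[2], method = method,
             ci_kind = ci_kind, stringsAsFactors = FALSE)
}

#' Second-stage outcome regressions
#'
#' Relates first-stage individual estimates to the outcome with two ordinary
#' least-squares regressions: the outcome on estimated birth length alone
#' (total, unconditional association `alpha1`) and on estimated birth length
#' and growth rate together (conditional associations `alpha3`, `alpha4`).
#' Classical OLS standard errors and Wald 95% intervals (+/- 1.96 SE) are
#' reported; these ignore first-stage estimation uncertainty, which is
#' exactly the behaviour whose consequences the scenario engine measures.
#' `alpha3` is computed and stored but is not a headline quantity (its
#' interpretation suffers from the reversal paradox).
#'
#' @param estimates an `individual_estimates` object.
#' @param outcome per-individual outcome vector, aligned with the estimates.
#'   For the joint-model pipeline this is the model-estimated outcome.
#' @return A data.frame of class `association_estimates` with one row per
#'   parameter (`alpha1`, `alpha3`, `alpha4`): estimate, SE, Wald CI, method
#'   label.
#' @export
second_stage <- function(estimates, outcome) {
  stopifnot(inherits(estimates, "individual_estimates"),
            length(outcome) == length(estimates$b_hat))
  m1 <- .ols_coefficients(cbind(estimates$b_hat), outcome)
  m2 <- .ols_coefficients(cbind(estimates$b_hat, estimates$g_hat), outcome)
  out <- rbind(
    .assoc_row("alpha1", m1$coef[2], m1$se[2], estimates$method),
    .assoc_row("alpha3", m2$coef[2], m2$se[2], estimates$method),
    .assoc_row("alpha4", m2$coef[3], m2$se[3], estimates$method))
  class(out) <- c("association_estimates", "data.frame")
  out
}

# One pass of the full joint-model pipeline: bivariate fit, BLUPs,
# simultaneous re-inflation, second stage on the estimated outcome.
# Returns NULL when any step fails (non-convergence, singular calibration).
.bvm_pipeline <- function(data, start = NULL, fit = NULL) {
  if (is.null(fit))
    fit <- tryCatch(fit_bivariate_lmm(data, start = start),
                    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(fit) || !fit$converged) return(NULL)
  res <- tryCatch({
    shr <- blup_residuals(fit, data)
    infl <- inflate_residuals(shr, fit$omega)
    est <- estimates_from_residuals(fit, infl)
    second_stage(est, est$bp_hat)
  }, error = function(e) NULL)
  if (is.null(res)) return(NULL)
  attr(res, "fit") <- fit
  res
}

#' Cluster bootstrap for the joint-model associations
#'
#' Non-parametric bootstrap that resamples individuals with replacement and
#' reruns the complete bivariate pipeline (joint fit, BLUPs, simultaneous
#' re-inflation, second-stage regressions on the estimated outcome) on every
#' resample. The bootstrap SE is the SD of the resampled estimates; both
#' normal-approximation intervals (point estimate +/- 1.96 bootstrap SE) and
#' empirical 2.5/97.5 percentile intervals (type-7 quantiles) are returned
#' for `alpha1` and `alpha4`.
#'
#' @param data a `trajectory_data` object.
#' @param n_boot number of bootstrap resamples (>= 50).
#' @param seed integer seed; resampling is deterministic given the seed.
#' @return A data.frame of class `association_estimates` with rows for each
#'   parameter x CI kind; attribute `boot_estimates` holds the resampled
#'   estimates, attribute `n_failed` the count of failed resamples. Errors
#'   if more than 10% of resamples fail.
#' @export
bootstrap_joint <- function(data, n_boot = 1000, seed = 1) {
  stopifnot(inherits(data, "trajectory_data"), n_boot >= 50)
  J <- n_individuals(data)

  point <- .bvm_pipeline(data)
  if (is.null(point)) stop("joint-model pipeline failed on the full data")
  fit0 <- attr(point, "fit")
  warm <- list(Omega0 = fit0$omega, sige2_0 = fit0$sigma_eh^2)

  boot <- matrix(NA_real_, n_boot, 2,
                 dimnames = list(NULL, c("alpha1", "alpha4")))
  set.seed(derive_seed(seed, "bootstrap"))
  idx_all <- matrix(sample.int(J, J * n_boot, replace = TRUE), n_boot, J)
  for (b in seq_len(n_boot)) {
    res <- .bvm_pipeline(subset_individuals(data, idx_all[b, ]),
                         start = warm)
    if (!is.null(res))
      boot[b, ] <- res$estimate[match(c("alpha1", "alpha4"),
                                      res$parameter)]
  }
  n_failed <- sum(is.na(boot[, 1]))
  if (n_failed > 0.1 * n_boot)
    stop(sprintf("bootstrap unstable: %d of %d resamples failed",
                 n_failed, n_boot))

  rows <- list()
  for (par in c("alpha1", "alpha4")) {
    est <- point$estimate[match(par, point$parameter)]
    bs <- boot[, par]
    se <- sd(bs, na.rm = TRUE)
    rows[[length(rows) + 1L]] <- .assoc_row(
      par, est, se, "bvm_inflated", "bootstrap_normal")
    rows[[length(rows) + 1L]] <- .assoc_row(
      par, est, se, "bvm_inflated", "bootstrap_percentile",
      ci = unname(quantile(bs, c(0.025, 0.975), na.rm = TRUE)))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("association_estimates", "data.frame")
  attr(out, "boot_estimates") <- boot
  attr(out, "n_failed") <- n_failed
  out
}
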