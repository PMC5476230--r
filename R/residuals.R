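#' Shrunken (BLUP) residuals of a fitted mixed model
#'
#' Computes the best linear unbiased predictors of the individual random
#' effects, \eqn{\hat u_j = \hat\Omega Z_j' V_j^{-1}(y_j - X_j\hat\beta)}.
#' BLUPs are precision-weighted compromises between an individual's own data
#' and the population mean, so their sample variance is smaller than the
#' model-estimated random-effect variance (shrinkage).
#'
#' @param fit an `lmm_fit` from [fit_univariate_lmm()] or
#'   [fit_bivariate_lmm()].
#' @param data the `trajectory_data` the model was fitted to.
#' @return An object of class `residual_set`: matrix `u_hat` (individuals x
#'   2 or 3), flag `inflated = FALSE`, and `reference_cov` set to the fitted
#'   covariance.
#' @export
blup_residuals <- function(fit, data) {
  stopifnot(inherits(fit, "lmm_fit"), inherits(data, "trajectory_data"))
  joint <- fit$type == "bivariate"
  bp <- if (joint) data$bp else numeric(0)
  u <- cpp_blups(data$ages, data$heights, bp, joint, fit$fixed, fit$omega,
                 fit$sigma_eh^2)
  colnames(u) <- colnames(fit$omega)
  structure(list(u_hat = u, inflated = FALSE, reference_cov = fit$omega,
                 type = fit$type),
            class = "residual_set")
}

#' @export
print.residual_set <- function(x, ...) {
  cat(sprintf("Residual set: %d individuals x %d components (%s)\n",
              nrow(x$u_hat), ncol(x$u_hat),
              if (x$inflated) "re-inflated" else "shrunken"))
  invisible(x)
}

# lower-triangular factor L with L L' = m; optionally the "reverse" factor
# (upper triangular U with U U' = m), used for the alternative orientation
.left_chol <- function(m, orientation = "lower") {
  if (orientation == "lower") return(t(chol(m)))
  k <- nrow(m)
  rev_idx <- k:1
  t(chol(m[rev_idx, rev_idx]))[rev_idx, rev_idx]  # upper, U U' = m
}

#' Re-inflate shrunken residuals to a target covariance
#'
#' Linearly transforms mean-centred shrunken residuals so that their sample
#' covariance (denominator `J`) equals `target_cov` exactly, then re-adds the
#' residual means: \eqn{u^* = T(u - \bar u) + \bar u} with
#' \eqn{T = L_{\Omega} L_S^{-1}}, where \eqn{L_\Omega} and \eqn{L_S} are the
#' lower-triangular Cholesky factors of the target and of the sample
#' covariance. With lower factors the first (birth-length) component of the
#' inflated residuals is a pure positive rescaling of the shrunken one; the
#' `"upper"` orientation (reverse Cholesky) instead mixes components into the
#' first coordinate and is provided for contrast experiments.
#'
#' @param res a `residual_set` with `inflated = FALSE`.
#' @param target_cov symmetric positive-definite target covariance, same
#'   order as the residual vectors (typically the model's fitted `omega`).
#' @param orientation `"lower"` (default) or `"upper"` Cholesky orientation.
#' @return A `residual_set` with `inflated = TRUE` and `reference_cov` set to
#'   `target_cov`.
#' @export
inflate_residuals <- function(res, target_cov, orientation = c("lower",
                                                               "upper")) {
  stopifnot(inherits(res, "residual_set"))
  orientation <- match.arg(orientation)
  if (res$inflated) stop("residuals are already inflated")
  k <- ncol(res$u_hat)
  stopifnot(is.matrix(target_cov), all(dim(target_cov) == k))

  u <- res$u_hat
  centre <- colMeans(u)
  uc <- sweep(u, 2, centre)
  S <- crossprod(uc) / nrow(uc)
  L_S <- tryCatch(.left_chol(S, orientation), error = function(e)
    stop("sample covariance of residuals is singular; cannot calibrate"))
  L_T <- .left_chol(target_cov, orientation)
  Tm <- L_T %*% solve(L_S)
  u_new <- sweep(uc %*% t(Tm), 2, centre, `+`)
  colnames(u_new) <- colnames(u)

  structure(list(u_hat = u_new, inflated = TRUE, reference_cov = target_cov,
                 type = res$type),
            class = "residual_set")
}

#' Individual estimates from model residuals
#'
#' Adds the fixed-effect estimates to the (shrunken or re-inflated)
#' residuals: birth length `beta0 + u0`, growth rate `beta1 + u1`, and for
#' the bivariate model the estimated outcome `beta2 + u2`. The method label
#' records the fit type and whether the residuals were re-inflated.
#'
#' @param fit the `lmm_fit` the residuals came from.
#' @param res a `residual_set` of matching order.
#' @return An `individual_estimates` object.
#' @export
estimates_from_residuals <- function(fit, res) {
  stopifnot(inherits(fit, "lmm_fit"), inherits(res, "residual_set"))
  joint <- fit$type == "bivariate"
  if (ncol(res$u_hat) != length(fit$fixed))
    stop("residual order does not match fit")
  method <- if (joint) {
    if (res$inflated) "bvm_inflated" else stop(
      "joint-model estimates are defined for re-inflated residuals")
  } else if (res$inflated) "mlm_inflated" else "mlm_shrunken"
  individual_estimates(
    method,
    b_hat = fit$fixed[[1]] + res$u_hat[, 1],
    g_hat = fit$fixed[[2]] + res$u_hat[, 2],
    bp_hat = if (joint) fit$fixed[[3]] + res$u_hat[, 3] else NULL)
}
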