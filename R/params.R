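#' True parameters of the linear growth model
#'
#' Bundles the fixed effects and variance components of the
#' random-intercept/random-slope height model
#' \deqn{H_{ij} = \beta_0 + u_{0j} + (\beta_1 + u_{1j})\,Age_{ij} + e_{hij},}
#' with \eqn{(u_{0j}, u_{1j}) \sim N(0, \Omega_u)} and
#' \eqn{e_{hij} \sim N(0, \sigma_{eh}^2)} i.i.d. across occasions.
#' Defaults are the baseline conditions of the package's simulation study:
#' mean birth length 50 cm, growth rate 9 cm/y, SDs 2.5 cm and 0.5 cm/y for
#' the random intercept and slope, correlation 0.1, and occasion-level
#' residual SD 2 cm.
#'
#' @param beta0 population mean birth length (cm).
#' @param beta1 population mean linear growth rate (cm/y).
#' @param sigma_u0 SD of individual birth-length deviations (cm).
#' @param sigma_u1 SD of individual growth-rate deviations (cm/y).
#' @param rho_u01 correlation between intercept and slope deviations.
#' @param sigma_eh occasion-level residual SD of height (cm).
#' @return An object of class `growth_params`.
#' @seealso [outcome_params()], [simulate_trajectories()]
#' @examples
#' growth_params()
#' growth_params(sigma_u1 = 0.2)
#' @export
growth_params <- function(beta0 = 50, beta1 = 9, sigma_u0 = 2.5,
                          sigma_u1 = 0.5, rho_u01 = 0.1, sigma_eh = 2.0) {
  stopifnot(sigma_u0 >= 0, sigma_u1 >= 0, sigma_eh >= 0,
            abs(rho_u01) <= 1, is.finite(beta0), is.finite(beta1))
  structure(list(beta0 = beta0, beta1 = beta1, sigma_u0 = sigma_u0,
                 sigma_u1 = sigma_u1, rho_u01 = rho_u01, sigma_eh = sigma_eh),
            class = "growth_params")
}

#' True parameters of the distal outcome model
#'
#' Parameters of the outcome equation
#' \deqn{BP_j = \gamma_0 + \alpha_3 u_{0j} + \alpha_4 u_{1j} + e_{BPj},}
#' linking the individual growth random effects to a single later outcome
#' (systolic blood pressure in the motivating application). `alpha3` and
#' `alpha4` are conditional effects: the effect of a 1 cm higher birth length
#' (respectively 1 cm/y faster growth) with the other deviation held fixed.
#'
#' @param gamma0 population mean outcome (mmHg).
#' @param alpha3 conditional effect of birth-length deviation (mmHg per cm).
#' @param alpha4 conditional effect of growth-rate deviation (mmHg per cm/y).
#' @param sigma_ebp outcome residual SD (mmHg).
#' @return An object of class `outcome_params`.
#' @examples
#' outcome_params()
#' @export
outcome_params <- function(gamma0 = 120, alpha3 = 0.5, alpha4 = 2.0,
                           sigma_ebp = 10) {
  stopifnot(sigma_ebp >= 0, is.finite(gamma0), is.finite(alpha3),
            is.finite(alpha4))
  structure(list(gamma0 = gamma0, alpha3 = alpha3, alpha4 = alpha4,
                 sigma_ebp = sigma_ebp),
            class = "outcome_params")
}

#' Random-effect covariance matrix implied by growth parameters
#'
#' @param growth a [growth_params()] object.
#' @return The 2x2 covariance of `(u0, u1)`.
#' @examples
#' omega_u(growth_params())
#' @export
omega_u <- function(growth) {
  stopifnot(inherits(growth, "growth_params"))
  s01 <- growth$rho_u01 * growth$sigma_u0 * growth$sigma_u1
  matrix(c(growth$sigma_u0^2, s01, s01, growth$sigma_u1^2), 2, 2,
         dimnames = list(c("u0", "u1"), c("u0", "u1")))
}

#' @export
print.growth_params <- function(x, ...) {
  cat("Growth model parameters\n")
  cat(sprintf("  beta0 = %g cm, beta1 = %g cm/y\n", x$beta0, x$beta1))
  cat(sprintf("  sigma_u0 = %g, sigma_u1 = %g, rho_u01 = %g, sigma_eh = %g\n",
              x$sigma_u0, x$sigma_u1, x$rho_u01, x$sigma_eh))
  invisible(x)
}

#' @export
print.outcome_params <- function(x, ...) {
  cat("Outcome model parameters\n")
  cat(sprintf("  gamma0 = %g mmHg, alpha3 = %g, alpha4 = %g, sigma_ebp = %g\n",
              x$gamma0, x$alpha3, x$alpha4, x$sigma_ebp))
  invisible(x)
}
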