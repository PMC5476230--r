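#' Draw a measurement-age schedule
#'
#' Draws realised measurement ages for every individual: occasion `i` ages are
#' independent normal with mean `mean_ages[i]` and SD `age_sds[i]`, with no
#' covariance between occasions. Individuals whose drawn ages are not strictly
#' increasing are redrawn in full, which preserves the per-occasion marginal
#' distributions (rather than sorting, which would not). The default schedule
#' emulates a cohort measured at birth and at about 2.5, 5, 7.5 and 10 years,
#' with the birth measurement tightly timed (SD 0.025 y, i.e. about 95% of
#' individuals measured within +/- 2 weeks of birth) and later measurements
#' jittered with SD 0.5 y.
#'
#' @param mean_ages strictly increasing occasion mean ages (years).
#' @param age_sds per-occasion SD of measurement age (years), non-negative.
#' @param n_individuals number of individuals.
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return An object of class `age_schedule`: list with `mean_ages`,
#'   `age_sds` and the realised `ages` matrix (individuals x occasions).
#' @examples
#' sched <- draw_age_schedule(n_individuals = 100, seed = 1)
#' colMeans(sched$ages)
#' @export
draw_age_schedule <- function(mean_ages = c(0, 2.5, 5, 7.5, 10),
                              age_sds = c(0.025, 0.5, 0.5, 0.5, 0.5),
                              n_individuals = 1000, seed = 1) {
  if (length(mean_ages) != length(age_sds))
    stop("mean_ages and age_sds must have the same length")
  if (any(diff(mean_ages) <= 0))
    stop("mean_ages must be strictly increasing")
  if (any(age_sds < 0)) stop("age_sds must be non-negative")
  stopifnot(n_individuals >= 1)

  I <- length(mean_ages)
  set.seed(derive_seed(seed, "age-schedule"))
  draw <- function(n) {
    matrix(rnorm(n * I, mean = rep(mean_ages, each = n),
                 sd = rep(age_sds, each = n)), n, I)
  }
  ages <- draw(n_individuals)
  for (round in seq_len(1000)) {
    bad <- which(apply(ages, 1, function(a) any(diff(a) <= 0)))
    if (length(bad) == 0L) break
    ages[bad, ] <- draw(length(bad))
  }
  if (any(apply(ages, 1, function(a) any(diff(a) <= 0))))
    stop("could not draw monotone age schedules; SDs too large for spacing")

  structure(list(mean_ages = mean_ages, age_sds = age_sds, ages = ages),
            class = "age_schedule")
}

#' @export
print.age_schedule <- function(x, ...) {
  cat(sprintf("Age schedule: %d individuals x %d occasions\n",
              nrow(x$ages), ncol(x$ages)))
  cat("  mean ages:", paste(x$mean_ages, collapse = ", "), "y\n")
  cat("  age SDs:  ", paste(x$age_sds, collapse = ", "), "y\n")
  invisible(x)
}

#' Simulate growth trajectories and a distal outcome
#'
#' Generates heights from the random-intercept/random-slope model and the
#' outcome from its linear model in the individual random effects:
#' \deqn{H_{ij} = \beta_0 + u_{0j} + (\beta_1 + u_{1j}) Age_{ij} + e_{hij},
#'   \quad BP_j = \gamma_0 + \alpha_3 u_{0j} + \alpha_4 u_{1j} + e_{BPj}.}
#' The random effects, height residuals and outcome residuals are drawn from
#' separate derived seed streams, so changing (say) the outcome residual SD
#' leaves the simulated heights untouched.
#'
#' @param schedule an [draw_age_schedule()] result (ages are taken as fixed).
#' @param growth a [growth_params()] object.
#' @param outcome an [outcome_params()] object.
#' @param seed integer seed.
#' @return An object of class `trajectory_data`: matrices `ages`, `heights`
#'   (individuals x occasions), vector `bp`, the realised random effects
#'   `true_u0`, `true_u1` (kept for validation), and the schedule's
#'   `mean_ages`.
#' @examples
#' sched <- draw_age_schedule(n_individuals = 50, seed = 1)
#' dat <- simulate_trajectories(sched, growth_params(), outcome_params(),
#'                              seed = 2)
#' str(dat$heights)
#' @export
simulate_trajectories <- function(schedule, growth = growth_params(),
                                  outcome = outcome_params(), seed = 1) {
  stopifnot(inherits(schedule, "age_schedule"),
            inherits(growth, "growth_params"),
            inherits(outcome, "outcome_params"))
  J <- nrow(schedule$ages)

  # bivariate normal random effects via the correlation construction,
  # which degrades gracefully to zero-variance cases
  set.seed(derive_seed(seed, "random-effects"))
  z1 <- rnorm(J); z2 <- rnorm(J)
  u0 <- growth$sigma_u0 * z1
  u1 <- growth$sigma_u1 * (growth$rho_u01 * z1 +
                             sqrt(1 - growth$rho_u01^2) * z2)

  set.seed(derive_seed(seed, "height-residuals"))
  eh <- matrix(rnorm(length(schedule$ages), sd = growth$sigma_eh),
               nrow = J)

  set.seed(derive_seed(seed, "outcome-residuals"))
  ebp <- rnorm(J, sd = outcome$sigma_ebp)

  heights <- (growth$beta0 + u0) + (growth$beta1 + u1) * schedule$ages + eh
  bp <- outcome$gamma0 + outcome$alpha3 * u0 + outcome$alpha4 * u1 + ebp

  structure(list(ages = schedule$ages, heights = heights, bp = bp,
                 true_u0 = u0, true_u1 = u1,
                 mean_ages = schedule$mean_ages),
            class = "trajectory_data")
}

#' @export
print.trajectory_data <- function(x, ...) {
  cat(sprintf("Trajectory data: %d individuals x %d occasions + 1 outcome\n",
              nrow(x$ages), ncol(x$ages)))
  invisible(x)
}

n_individuals <- function(data) nrow(data$ages)
n_occasions <- function(data) ncol(data$ages)

#' Subset individuals of a trajectory dataset
#'
#' Used by the cluster bootstrap: `idx` may repeat individuals.
#'
#' @param data a `trajectory_data` object.
#' @param idx integer vector of individual indices (repeats allowed).
#' @return A `trajectory_data` with the selected rows.
#' @export
subset_individuals <- function(data, idx) {
  structure(list(ages = data$ages[idx, , drop = FALSE],
                 heights = data$heights[idx, , drop = FALSE],
                 bp = data$bp[idx],
                 true_u0 = data$true_u0[idx], true_u1 = data$true_u1[idx],
                 mean_ages = data$mean_ages),
            class = "trajectory_data")
}
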