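# Scenario definitions, the Monte-Carlo replication engine, and the
# bias/coverage summary statistics.

.scenario_grids <- list(
  baseline  = NA_real_,
  sigma_u0  = c(1.5, 2.0, 2.5, 3.0, 3.5),
  sigma_u1  = seq(0.2, 1.0, by = 0.1),
  sigma_eh  = c(0.1, 1, 2, 3, 4, 5),
  rho_u01   = c(-0.6, -0.4, -0.2, -0.1, 0, 0.1, 0.2, 0.4, 0.6),
  sigma_ebp = c(8, 9, 10, 11, 12))

.all_methods <- c("simple", "ols", "mlm_shrunken", "mlm_inflated",
                  "bvm_inflated", "sem")

#' Define an experimental scenario
#'
#' A scenario varies one generating parameter over a grid while holding the
#' others at the baseline defaults (`sigma_u0` 2.5, `sigma_u1` 0.5,
#' `sigma_eh` 2.0, `sigma_ebp` 10, `rho_u01` 0.1; fixed effects 50, 9, mean
#' outcome 120, conditional effects 0.5 and 2.0). The default grids are the
#' standard sweeps of the simulation study; `"baseline"` is the single
#' all-defaults condition.
#'
#' @param name one of `"baseline"`, `"sigma_u0"`, `"sigma_u1"`,
#'   `"sigma_eh"`, `"rho_u01"`, `"sigma_ebp"`.
#' @param grid optional numeric vector overriding the default grid for the
#'   varied parameter.
#' @param n_individuals cohort size per replicate.
#' @param n_replicates Monte-Carlo replicates per grid value.
#' @param master_seed master seed; every replicate's seed is derived from
#'   `(master_seed, scenario, grid index, replicate index)` so any single
#'   replicate can be reconstructed in isolation.
#' @param redraw_ages if `FALSE` (default) a single age-schedule draw is
#'   reused for all replicates; if `TRUE` the schedule is redrawn per
#'   replicate.
#' @return An object of class `scenario`.
#' @export
scenario <- function(name, grid = NULL, n_individuals = 1000,
                     n_replicates = 1000, master_seed = 1,
                     redraw_ages = FALSE) {
  name <- match.arg(name, names(.scenario_grids))
  if (is.null(grid)) grid <- .scenario_grids[[name]]
  stopifnot(n_individuals >= 10, n_replicates >= 1)
  structure(list(name = name, grid = grid, n_individuals = n_individuals,
                 n_replicates = n_replicates, master_seed = master_seed,
                 redraw_ages = redraw_ages),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("Scenario '%s': J = %d, %d replicates, master seed %d\n",
              x$name, x$n_individuals, x$n_replicates, x$master_seed))
  if (!all(is.na(x$grid)))
    cat("  grid:", paste(x$grid, collapse = ", "), "\n")
  invisible(x)
}

# parameter objects for one grid value of a scenario
.scenario_params <- function(name, value) {
  growth <- growth_params()
  outcome <- outcome_params()
  if (name != "baseline") {
    if (name == "sigma_ebp") outcome$sigma_ebp <- value
    else growth[[name]] <- value
  }
  list(growth = growth, outcome = outcome)
}

#' Expected unconditional birth-length association
#'
#' The total effect of a birth-length deviation on the outcome implied by
#' the generating model, marginal over growth rate:
#' \eqn{\alpha_1 = \alpha_3 + \alpha_4\,\rho_{u01}\,\sigma_{u1} /
#' \sigma_{u0}}. Used as the truth against which the estimated
#' unconditional association is judged.
#'
#' @param growth a [growth_params()] object (needs `sigma_u0 > 0`).
#' @param outcome an [outcome_params()] object.
#' @return The unconditional association (mmHg per cm).
#' @examples
#' true_alpha1(growth_params(), outcome_params())  # 0.54 at the defaults
#' @export
true_alpha1 <- function(growth, outcome) {
  stopifnot(inherits(growth, "growth_params"),
            inherits(outcome, "outcome_params"))
  if (growth$sigma_u0 <= 0) stop("sigma_u0 must be positive")
  outcome$alpha3 + outcome$alpha4 *
    growth$rho_u01 * growth$sigma_u1 / growth$sigma_u0
}

#' Mean relative bias of a set of estimates
#'
#' Mean over replicates of \eqn{(\hat\alpha - \alpha)/\alpha}, in percent,
#' with its Monte-Carlo standard error.
#'
#' @param estimates numeric vector of replicate estimates.
#' @param truth true parameter value (non-zero).
#' @return List with `bias_pct` and `mc_se`.
#' @export
relative_bias <- function(estimates, truth) {
  if (truth == 0) stop("relative bias undefined for zero truth")
  rb <- (estimates - truth) / truth * 100
  list(bias_pct = mean(rb), mc_se = sd(rb) / sqrt(length(rb)))
}

#' Empirical coverage of 1.96-SE confidence intervals
#'
#' Percentage of replicates in which `|estimate - truth| <= 1.96 * se`,
#' with the binomial Monte-Carlo standard error.
#'
#' @param estimates numeric vector of replicate estimates.
#' @param ses matching vector of standard errors (positive).
#' @param truth true parameter value.
#' @return List with `coverage_pct` and `mc_se`.
#' @export
coverage <- function(estimates, ses, truth) {
  stopifnot(length(estimates) == length(ses), all(ses > 0))
  hit <- abs(estimates - truth) <= 1.96 * ses
  p <- mean(hit)
  list(coverage_pct = p * 100,
       mc_se = sqrt(p * (1 - p) / length(hit)) * 100)
}

# estimates/SEs of alpha1 and alpha4 for each requested method on one
# simulated dataset; returns a list of rows, NULL entries for failures
.replicate_estimates <- function(data, methods) {
  out <- list()
  grab <- function(tab, method) {
    i1 <- match("alpha1", tab$parameter); i4 <- match("alpha4", tab$parameter)
    list(method = method,
         alpha1 = tab$estimate[i1], alpha1_se = tab$se[i1],
         alpha4 = tab$estimate[i4], alpha4_se = tab$se[i4])
  }
  safely <- function(expr) tryCatch(expr, error = function(e) NULL,
                                    warning = function(w) NULL)

  if ("simple" %in% methods)
    out$simple <- safely(grab(second_stage(simple_summaries(data), data$bp),
                              "simple"))
  if ("ols" %in% methods)
    out$ols <- safely(grab(second_stage(ols_summaries(data), data$bp),
                           "ols"))
  if (any(c("mlm_shrunken", "mlm_inflated") %in% methods)) {
    fit <- safely(fit_univariate_lmm(data))
    if (!is.null(fit) && fit$converged) {
      shr <- safely(blup_residuals(fit, data))
      if ("mlm_shrunken" %in% methods && !is.null(shr))
        out$mlm_shrunken <- safely(grab(second_stage(
          estimates_from_residuals(fit, shr), data$bp), "mlm_shrunken"))
      if ("mlm_inflated" %in% methods && !is.null(shr))
        out$mlm_inflated <- safely(grab(second_stage(
          estimates_from_residuals(fit, inflate_residuals(shr, fit$omega)),
          data$bp), "mlm_inflated"))
    }
  }
  if (any(c("bvm_inflated", "sem") %in% methods)) {
    bfit <- safely(fit_bivariate_lmm(data))
    if (!is.null(bfit) && bfit$converged) {
      if ("bvm_inflated" %in% methods) {
        res <- .bvm_pipeline(data, fit = bfit)
        if (!is.null(res)) out$bvm_inflated <- grab(res, "bvm_inflated")
      }
      if ("sem" %in% methods) {
        out$sem <- safely({
          cf <- .sem_reparam(data, "conditional", fit = bfit)
          uf <- .sem_reparam(data, "unconditional", fit = bfit)
          if (!cf$converged || !uf$converged ||
              !is.finite(cf$alpha4_se) || !is.finite(uf$alpha1_se)) NULL
          else list(method = "sem",
                    alpha1 = uf$alpha1, alpha1_se = uf$alpha1_se,
                    alpha4 = cf$alpha4, alpha4_se = cf$alpha4_se)
        })
      }
    }
  }
  out[methods[methods %in% names(out)]]
}

#' Run a Monte-Carlo scenario
#'
#' For every grid value and replicate: simulate a cohort, run each requested
#' method's first stage, run the second-stage regressions (or read the SEM
#' coefficients directly), and record estimates, standard errors and
#' 1.96-SE interval coverage against the generating truth. Replicates where
#' a method fails to converge are excluded from that method's summaries and
#' counted. Fully reproducible from the scenario's master seed.
#'
#' @param scn a [scenario()] object.
#' @param methods subset of `c("simple", "ols", "mlm_shrunken",
#'   "mlm_inflated", "bvm_inflated", "sem")`.
#' @param keep_estimates if `TRUE`, attach the per-replicate estimates as
#'   attribute `estimates`.
#' @param verbose print progress per grid value.
#' @return A data.frame of class `scenario_result`: one row per grid value x
#'   method x parameter with relative bias (%), coverage (%), their
#'   Monte-Carlo SEs, and the converged replicate count.
#' @export
run_scenario <- function(scn, methods = .all_methods,
                         keep_estimates = FALSE, verbose = FALSE) {
  stopifnot(inherits(scn, "scenario"))
  bad <- setdiff(methods, .all_methods)
  if (length(bad)) stop("unknown method(s): ", paste(bad, collapse = ", "))

  grid <- scn$grid
  rows <- list()
  raw <- list()
  shared_schedule <- NULL
  if (!scn$redraw_ages)
    shared_schedule <- draw_age_schedule(
      n_individuals = scn$n_individuals,
      seed = derive_seed(scn$master_seed, "ages"))

  for (gi in seq_along(grid)) {
    gv <- grid[gi]
    pars <- .scenario_params(scn$name, gv)
    truth <- c(alpha1 = true_alpha1(pars$growth, pars$outcome),
               alpha4 = pars$outcome$alpha4)
    if (verbose)
      message(sprintf("scenario %s, grid value %s", scn$name,
                      format(gv)))

    est <- array(NA_real_, dim = c(scn$n_replicates, length(methods), 4),
                 dimnames = list(NULL, methods,
                                 c("alpha1", "alpha1_se",
                                   "alpha4", "alpha4_se")))
    for (r in seq_len(scn$n_replicates)) {
      sched <- if (scn$redraw_ages)
        draw_age_schedule(n_individuals = scn$n_individuals,
                          seed = derive_seed(scn$master_seed, "ages",
                                             scn$name, gi, r))
      else shared_schedule
      data <- simulate_trajectories(
        sched, pars$growth, pars$outcome,
        seed = derive_seed(scn$master_seed, scn$name, gi, r))
      reps <- .replicate_estimates(data, methods)
      for (m in names(reps))
        if (!is.null(reps[[m]]))
          est[r, m, ] <- c(reps[[m]]$alpha1, reps[[m]]$alpha1_se,
                           reps[[m]]$alpha4, reps[[m]]$alpha4_se)
    }
    if (keep_estimates) raw[[paste(scn$name, gi, sep = ":")]] <- est

    for (m in methods) {
      ok <- which(!is.na(est[, m, "alpha1"]))
      if (length(ok) == 0) next
      for (par in c("alpha1", "alpha4")) {
        e <- est[ok, m, par]; s <- est[ok, m, paste0(par, "_se")]
        rb <- relative_bias(e, truth[[par]])
        cv <- coverage(e, s, truth[[par]])
        rows[[length(rows) + 1L]] <- data.frame(
          scenario = scn$name, grid_value = gv, method = m,
          parameter = par, truth = truth[[par]],
          rel_bias_pct = rb$bias_pct, mc_se_bias = rb$mc_se,
          coverage_pct = cv$coverage_pct, mc_se_cov = cv$mc_se,
          n_converged = length(ok), n_replicates = scn$n_replicates,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("scenario_result", "data.frame")
  if (keep_estimates) attr(out, "estimates") <- raw
  out
}

#' @export
print.scenario_result <- function(x, digits = 2, ...) {
  cat("Scenario results (relative bias % / coverage %)\n")
  d <- as.data.frame(x)
  d$rel_bias_pct <- round(d$rel_bias_pct, digits)
  d$coverage_pct <- round(d$coverage_pct, digits)
  d$mc_se_bias <- round(d$mc_se_bias, digits)
  d$mc_se_cov <- round(d$mc_se_cov, digits)
  d$truth <- round(d$truth, 4)
  print(d, row.names = FALSE)
  invisible(x)
}

#' Bootstrap coverage study for the joint-model pipeline
#'
#' Repeats, over independent baseline-scenario replicates: simulate a
#' cohort, compute the joint-model point estimates, bootstrap their SEs by
#' resampling individuals, and check whether the normal-approximation and
#' percentile intervals cover the generating truths.
#'
#' @param n_replicates outer Monte-Carlo replicates.
#' @param n_boot bootstrap resamples per replicate.
#' @param n_individuals cohort size.
#' @param master_seed master seed.
#' @param growth,outcome generating parameters (baseline defaults).
#' @param verbose print progress every 25 replicates.
#' @return A data.frame with coverage (%) and Monte-Carlo SE per parameter
#'   (`alpha1`, `alpha4`) and CI kind (`bootstrap_normal`,
#'   `bootstrap_percentile`), plus the mean relative bias of the point
#'   estimates.
#' @export
run_bootstrap_study <- function(n_replicates = 200, n_boot = 200,
                                n_individuals = 1000, master_seed = 1,
                                growth = growth_params(),
                                outcome = outcome_params(),
                                verbose = FALSE) {
  truth <- c(alpha1 = true_alpha1(growth, outcome),
             alpha4 = outcome$alpha4)
  sched <- draw_age_schedule(n_individuals = n_individuals,
                             seed = derive_seed(master_seed, "ages"))
  recs <- list()
  for (r in seq_len(n_replicates)) {
    data <- simulate_trajectories(
      sched, growth, outcome,
      seed = derive_seed(master_seed, "boot-study", r))
    tab <- tryCatch(bootstrap_joint(data, n_boot = n_boot,
                                    seed = derive_seed(master_seed,
                                                       "boot-seeds", r)),
                    error = function(e) NULL)
    if (is.null(tab)) next
    tab$replicate <- r
    recs[[length(recs) + 1L]] <- as.data.frame(tab)
    if (verbose && r %% 25 == 0)
      message(sprintf("bootstrap study: %d / %d replicates", r,
                      n_replicates))
  }
  all <- do.call(rbind, recs)
  rows <- list()
  for (par in c("alpha1", "alpha4")) {
    for (kind in c("bootstrap_normal", "bootstrap_percentile")) {
      d <- all[all$parameter == par & all$ci_kind == kind, ]
      hit <- d$ci_low <= truth[[par]] & truth[[par]] <= d$ci_high
      p <- mean(hit)
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = par, ci_kind = kind,
        coverage_pct = p * 100,
        mc_se_cov = sqrt(p * (1 - p) / length(hit)) * 100,
        rel_bias_pct = relative_bias(d$estimate, truth[[par]])$bias_pct,
        n_converged = nrow(d), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Write scenario results to disk
#'
#' Writes a tidy CSV of the combined results and a human-readable summary
#' (bias and coverage against the grid value, per method and parameter).
#'
#' @param results a `scenario_result` (or list of them, row-bound).
#' @param dir output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
report <- function(results, dir) {
  if (inherits(results, "scenario_result")) results <- list(results)
  stopifnot(length(results) >= 1)
  all <- do.call(rbind, lapply(results, as.data.frame))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  csv <- file.path(dir, "scenario_results.csv")
  write.csv(all, csv, row.names = FALSE)

  txt <- file.path(dir, "scenario_summary.txt")
  con <- file(txt, "w")
  on.exit(close(con))
  for (scn in unique(all$scenario)) {
    d <- all[all$scenario == scn, ]
    writeLines(sprintf("== scenario: %s ==", scn), con)
    for (par in unique(d$parameter)) {
      writeLines(sprintf("-- %s (truth varies with grid) --", par), con)
      dp <- d[d$parameter == par, ]
      tab <- sprintf("  %-14s grid=%-6s bias%%=%7.2f (SE %4.2f)  cov%%=%6.1f (SE %3.1f)  n=%d",
                     dp$method, format(dp$grid_value), dp$rel_bias_pct,
                     dp$mc_se_bias, dp$coverage_pct, dp$mc_se_cov,
                     dp$n_converged)
      writeLines(tab, con)
    }
    writeLines("", con)
  }
  invisible(c(csv, txt))
}
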