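#' Construct an individual-estimates object
#'
#' Per-individual estimated birth length `b_hat` (cm) and growth rate `g_hat`
#' (cm/y), tagged with the first-stage method that produced them. The joint
#' model additionally carries an estimated outcome `bp_hat`.
#'
#' @param method one of `"simple"`, `"ols"`, `"mlm_shrunken"`,
#'   `"mlm_inflated"`, `"bvm_inflated"`.
#' @param b_hat,g_hat numeric vectors, one entry per individual.
#' @param bp_hat optional estimated outcome vector (joint model only).
#' @return An object of class `individual_estimates`.
#' @export
individual_estimates <- function(method, b_hat, g_hat, bp_hat = NULL) {
  method <- match.arg(method, c("simple", "ols", "mlm_shrunken",
                                "mlm_inflated", "bvm_inflated"))
  stopifnot(length(b_hat) == length(g_hat),
            is.null(bp_hat) || length(bp_hat) == length(b_hat))
  structure(list(method = method, b_hat = as.numeric(b_hat),
                 g_hat = as.numeric(g_hat),
                 bp_hat = if (is.null(bp_hat)) NULL else as.numeric(bp_hat)),
            class = "individual_estimates")
}

#' @export
print.individual_estimates <- function(x, ...) {
  cat(sprintf("Individual estimates (%s): %d individuals%s\n", x$method,
              length(x$b_hat),
              if (is.null(x$bp_hat)) "" else ", with estimated outcome"))
  invisible(x)
}

#' @export
as.data.frame.individual_estimates <- function(x, ...) {
  d <- data.frame(id = seq_along(x$b_hat), method = x$method,
                  b_hat = x$b_hat, g_hat = x$g_hat)
  if (!is.null(x$bp_hat)) d$bp_hat <- x$bp_hat
  d
}

#' Two-point (simple) trajectory summaries
#'
#' First-stage estimator that takes the first observed height as the birth
#' length and the rise over run between the last and first occasions as the
#' growth rate; intermediate occasions are ignored. Because the first height
#' carries its full measurement error, the variance of `b_hat` exceeds the
#' true birth-length variance, and the difference construction induces
#' mathematical coupling between `b_hat` and `g_hat`.
#'
#' @param data a `trajectory_data` object with at least two occasions.
#' @return An `individual_estimates` object with method `"simple"`.
#' @export
simple_summaries <- function(data) {
  stopifnot(inherits(data, "trajectory_data"))
  I <- n_occasions(data)
  if (I < 2) stop("need at least two occasions")
  elapsed <- data$ages[, I] - data$ages[, 1]
  if (any(elapsed <= 0))
    stop("zero or negative elapsed time for individual(s): ",
         paste(which(elapsed <= 0), collapse = ", "))
  individual_estimates(
    "simple",
    b_hat = data$heights[, 1],
    g_hat = (data$heights[, I] - data$heights[, 1]) / elapsed)
}

#' Per-individual least-squares trajectory summaries
#'
#' Fits a separate straight line of height on age to each individual by
#' ordinary least squares (closed-form normal equations; two parameters per
#' individual) and uses the intercept and slope as the birth-length and
#' growth-rate estimates. Sampling error of the per-individual fits inflates
#' the between-individual variance of both estimates relative to the truth.
#'
#' @param data a `trajectory_data` object with at least two distinct ages per
#'   individual.
#' @return An `individual_estimates` object with method `"ols"`.
#' @export
ols_summaries <- function(data) {
  stopifnot(inherits(data, "trajectory_data"))
  if (n_occasions(data) < 2) stop("need at least two occasions")
  a_bar <- rowMeans(data$ages)
  h_bar <- rowMeans(data$heights)
  a_c <- data$ages - a_bar
  sxx <- rowSums(a_c^2)
  if (any(sxx == 0))
    stop("all ages identical for individual(s): ",
         paste(which(sxx == 0), collapse = ", "))
  slope <- rowSums(a_c * data$heights) / sxx
  individual_estimates("ols",
                       b_hat = h_bar - slope * a_bar,
                       g_hat = slope)
}
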