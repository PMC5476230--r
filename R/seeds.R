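#' Derive a reproducible child seed from a master seed
#'
#' Folds a master seed together with an arbitrary sequence of labels (scenario
#' names, grid indices, replicate numbers, stream tags) into a deterministic
#' integer seed, using a multiplicative congruential hash over the labels'
#' character codes. Distinct label paths map to effectively independent
#' streams, so redrawing one component of a simulation (for example the age
#' schedule) never perturbs the draws of another.
#'
#' @param master integer master seed.
#' @param ... labels (coerced to character) identifying the stream.
#' @return An integer in `[1, 2147483629]`, usable with [set.seed()].
#' @examples
#' derive_seed(1, "ages")
#' derive_seed(1, "baseline", 2, 17)
#' @export
derive_seed <- function(master, ...) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  m <- 2147483629
  h <- abs(as.double(master)) %% m
  labels <- paste(vapply(list(...), function(x)
    paste(as.character(x), collapse = ","), character(1)), collapse = "|")
  for (v in utf8ToInt(labels)) h <- (h * 48271 + v) %% m
  as.integer(h) + 1L
}
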