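#' Write trajectory data to long-format CSV files
#'
#' Writes two UTF-8 CSVs: a long trajectory table with columns
#' `id,occasion,age,height` (occasion 1-based) and a per-individual outcome
#' table with columns `id,bp`.
#'
#' @param data a `trajectory_data` object.
#' @param traj_path path for the trajectory CSV.
#' @param outcome_path path for the outcome CSV.
#' @return Invisibly, the two paths.
#' @seealso [read_long_csv()]
#' @export
write_long_csv <- function(data, traj_path, outcome_path) {
  stopifnot(inherits(data, "trajectory_data"))
  J <- n_individuals(data); I <- n_occasions(data)
  long <- data.frame(
    id = rep(seq_len(J), each = I),
    occasion = rep(seq_len(I), times = J),
    age = as.vector(t(data$ages)),
    height = as.vector(t(data$heights)))
  write.csv(long, traj_path, row.names = FALSE, quote = FALSE)
  write.csv(data.frame(id = seq_len(J), bp = data$bp), outcome_path,
            row.names = FALSE, quote = FALSE)
  invisible(c(traj_path, outcome_path))
}

#' Read trajectory data from long-format CSV files
#'
#' Inverse of [write_long_csv()]. Validates that every individual has the
#' same, complete set of occasions, that `(id, occasion)` pairs are unique,
#' that ages are strictly increasing within each individual, and that every
#' individual has exactly one outcome value.
#'
#' @param traj_path path of the trajectory CSV (`id,occasion,age,height`).
#' @param outcome_path path of the outcome CSV (`id,bp`).
#' @return A `trajectory_data` object (with no true random effects).
#' @export
read_long_csv <- function(traj_path, outcome_path) {
  long <- read.csv(traj_path)
  need <- c("id", "occasion", "age", "height")
  if (!all(need %in% names(long)))
    stop("trajectory file must have columns id, occasion, age, height")
  out <- read.csv(outcome_path)
  if (!all(c("id", "bp") %in% names(out)))
    stop("outcome file must have columns id, bp")

  if (anyDuplicated(long[c("id", "occasion")]))
    stop("duplicate (id, occasion) rows in trajectory file")
  ids <- sort(unique(long$id))
  occ <- sort(unique(long$occasion))
  if (nrow(long) != length(ids) * length(occ))
    stop("unbalanced design: every individual needs every occasion")

  long <- long[order(long$id, long$occasion), ]
  J <- length(ids); I <- length(occ)
  ages <- matrix(long$age, nrow = J, ncol = I, byrow = TRUE)
  heights <- matrix(long$height, nrow = J, ncol = I, byrow = TRUE)

  bad <- which(apply(ages, 1, function(a) any(diff(a) <= 0)))
  if (length(bad))
    stop("non-monotone ages within individual(s): ",
         paste(ids[bad], collapse = ", "))

  miss <- setdiff(ids, out$id)
  if (length(miss))
    stop("missing outcome for individual(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(out$id)) stop("duplicate ids in outcome file")
  bp <- out$bp[match(ids, out$id)]

  structure(list(ages = ages, heights = heights, bp = bp,
                 true_u0 = NULL, true_u1 = NULL,
                 mean_ages = colMeans(ages)),
            class = "trajectory_data")
}
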