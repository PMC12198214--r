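#' Risk set at a time point
#'
#' Indices of subjects still under observation at \code{at_time}, i.e.
#' \eqn{R(t) = \{i : t_i \ge t\}}, in original row order.
#'
#' @param dataset a \code{\link{survival_dataset}}.
#' @param at_time finite time point.
#' @return Integer vector of subject indices (possibly empty).
#' @export
risk_set <- function(dataset, at_time) {
  stopifnot(inherits(dataset, "survival_dataset"), is.finite(at_time))
  which(dataset$time >= at_time)
}

#' Evaluation-time grid for binned stacking
#'
#' Splits \code{(0, t_max]} into \code{n_bins} equally spaced evaluation
#' times \eqn{j \cdot t_{max} / B}, \eqn{j = 1..B}.
#'
#' @param t_max positive largest observation time (shared across parties,
#'   see \code{\link{global_max_time}}).
#' @param n_bins number of time bins, at least 1.
#' @return Object of class \code{bin_spec}: strictly increasing numeric
#'   vector \code{times} of length \code{n_bins}.
#' @export
make_bins <- function(t_max, n_bins) {
  if (!is.finite(t_max) || t_max <= 0)
    stop("'t_max' must be a positive finite time", call. = FALSE)
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 1L)
    stop("'n_bins' must be >= 1", call. = FALSE)
  structure(list(times = seq_len(n_bins) * (t_max / n_bins)),
            class = "bin_spec")
}

#' Shared maximum observation time
#'
#' Collaborative max over the parties' local maximum times; each party
#' contributes a single scalar, so no individual record is disclosed beyond
#' the largest time.
#'
#' @param local_max_times numeric vector, one local maximum per party.
#' @return The global maximum time.
#' @export
global_max_time <- function(local_max_times) {
  if (length(local_max_times) == 0L)
    stop("no parties supplied", call. = FALSE)
  max(as.numeric(local_max_times))
}

new_stacked_dataset <- function(X, y, n_covariates, n_indicators,
                                source_rows, bin_times = NULL,
                                dropped_bins = integer(0)) {
  structure(list(X = X, y = y, column_names = colnames(X),
                 n_covariates = n_covariates, n_indicators = n_indicators,
                 source_rows = source_rows, bin_times = bin_times,
                 dropped_bins = dropped_bins),
            class = "stacked_dataset")
}

#' @export
print.stacked_dataset <- function(x, ...) {
  cat(sprintf(
    "Stacked dataset: %d rows = %d covariate + %d risk-indicator columns; %d positive targets\n",
    nrow(x$X), x$n_covariates, x$n_indicators, sum(x$y)))
  if (length(x$dropped_bins))
    cat("  dropped empty bins:", paste(x$dropped_bins, collapse = ", "), "\n")
  invisible(x)
}

#' Exact survival stacking
#'
#' Transforms a right-censored dataset into a classification dataset with one
#' risk-set block per distinct failure time: every member of the risk set
#' \eqn{R(t)} contributes a row replicating its covariates with the
#' corresponding risk indicator set to 1, and the target is 1 exactly for the
#' subject(s) failing at that time. Logistic regression on the result
#' approximates the Cox partial-likelihood fit.
#'
#' @param dataset a \code{\link{survival_dataset}} with at least one failure.
#' @return A \code{stacked_dataset}: dense matrix \code{X} (covariate block
#'   then indicator block, indicator columns labelled \code{__risk_<j>}),
#'   logical target \code{y}, and \code{source_rows} mapping each stacked row
#'   back to its subject.
#' @examples
#' d <- survival_dataset(matrix(c(1, 0, 1), ncol = 1,
#'                              dimnames = list(NULL, "x")),
#'                       time = c(0, 1, 2), event = c(1, 0, 1))
#' s <- stack_exact(d)
#' cbind(s$X, y = s$y)
#' @export
stack_exact <- function(dataset) {
  stopifnot(inherits(dataset, "survival_dataset"))
  if (!any(dataset$event))
    stop("cannot stack: dataset contains no failures", call. = FALSE)
  ft <- sort(unique(dataset$time[dataset$event]))
  members <- lapply(ft, function(tt) which(dataset$time >= tt))
  rows <- unlist(members)
  sizes <- lengths(members)
  B <- length(ft)
  p <- ncol(dataset$covariates)
  block <- rep(seq_len(B), sizes)
  ind <- matrix(0, length(rows), B,
                dimnames = list(NULL, paste0("__risk_", seq_len(B))))
  ind[cbind(seq_along(rows), block)] <- 1
  X <- cbind(dataset$covariates[rows, , drop = FALSE], ind)
  y <- dataset$event[rows] & dataset$time[rows] == ft[block]
  new_stacked_dataset(X, y, p, B, rows, bin_times = ft)
}

#' Time-binned survival stacking
#'
#' Like \code{\link{stack_exact}} but on a fixed evaluation grid: for bin
#' \eqn{j} with interval \eqn{(b_{j-1}, b_j]} (where \eqn{b_0 = 0}), every
#' subject at risk at the interval's lower edge contributes a row, and the
#' target is 1 for subjects failing inside the interval (a failure at exactly
#' time 0 is assigned to the first bin). Bins whose risk set is empty are
#' dropped and recorded in \code{dropped_bins}.
#'
#' @param dataset a \code{\link{survival_dataset}}; at least one failure must
#'   fall at or before the last bin time.
#' @param bins a \code{\link{make_bins}} grid.
#' @param drop_empty drop the indicator columns of bins whose risk set is
#'   empty (the default, for standalone use). Set \code{FALSE} when several
#'   parties stack against a shared grid: every party then keeps all
#'   \code{length(bins$times)} columns so the shards stay aligned, and a
#'   locally empty bin simply contributes no rows.
#' @return A \code{stacked_dataset}; indicator column \code{__risk_<j>}
#'   corresponds to the j-th bin of \code{bins}. Bins with an empty risk set
#'   are listed in \code{dropped_bins} (and their columns removed when
#'   \code{drop_empty}).
#' @export
stack_binned <- function(dataset, bins, drop_empty = TRUE) {
  stopifnot(inherits(dataset, "survival_dataset"), inherits(bins, "bin_spec"))
  upper <- bins$times
  B <- length(upper)
  lower <- c(0, upper[-B])
  if (!any(dataset$event & dataset$time <= upper[B]))
    stop("no failure falls inside the bin grid", call. = FALSE)
  p <- ncol(dataset$covariates)
  members <- lapply(lower, function(lo) which(dataset$time >= lo))
  empty <- which(lengths(members) == 0L)
  keep <- if (drop_empty) setdiff(seq_len(B), empty) else seq_len(B)
  members <- members[keep]
  rows <- unlist(members)
  block <- rep(seq_along(keep), lengths(members))
  ind <- matrix(0, length(rows), length(keep),
                dimnames = list(NULL, paste0("__risk_", keep)))
  ind[cbind(seq_along(rows), block)] <- 1
  X <- cbind(dataset$covariates[rows, , drop = FALSE], ind)
  lo_r <- lower[keep][block]
  hi_r <- upper[keep][block]
  y <- dataset$event[rows] &
    (dataset$time[rows] > lo_r | dataset$time[rows] == 0) &
    dataset$time[rows] <= hi_r
  new_stacked_dataset(X, y, p, length(keep), rows,
                      bin_times = upper[keep],
                      dropped_bins = empty)
}

#' Export a stacked dataset to CSV
#'
#' Writes the classification matrix (covariate and indicator columns) plus a
#' 0/1 \code{y} column, mainly for inspection.
#'
#' @param stacked a \code{stacked_dataset}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_stacked_csv <- function(stacked, path) {
  stopifnot(inherits(stacked, "stacked_dataset"))
  df <- as.data.frame(stacked$X)
  df$y <- as.integer(stacked$y)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
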