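#' Right-censored survival dataset
#'
#' Container for one party's (or a pooled) right-censored survival sample:
#' a numeric covariate matrix, an observed time per subject, and an event
#' indicator (\code{TRUE} = failure observed, \code{FALSE} = censored).
#'
#' @param covariates numeric matrix (n x p) of covariate values, or a
#'   data frame coercible to one. Column names are used as covariate names;
#'   unnamed columns are labelled \code{z1, z2, ...}.
#' @param time numeric vector of n nonnegative observed times.
#' @param event logical (or 0/1) vector of n event indicators.
#'
#' @return An object of class \code{survival_dataset} with elements
#'   \code{covariates}, \code{covariate_names}, \code{time}, \code{event}.
#' @examples
#' d <- survival_dataset(matrix(c(1, 0, 1), ncol = 1,
#'                              dimnames = list(NULL, "x")),
#'                       time = c(0, 1, 2), event = c(1, 0, 1))
#' d
#' @export
survival_dataset <- function(covariates, time, event) {
  if (is.data.frame(covariates)) covariates <- as.matrix(covariates)
  if (!is.matrix(covariates) || !is.numeric(covariates))
    stop("'covariates' must be a numeric matrix", call. = FALSE)
  n <- nrow(covariates)
  p <- ncol(covariates)
  if (n < 1L || p < 1L)
    stop("need at least one subject and one covariate", call. = FALSE)
  if (is.null(colnames(covariates)))
    colnames(covariates) <- paste0("z", seq_len(p))
  nm <- colnames(covariates)
  if (anyDuplicated(nm))
    stop("covariate names must be unique", call. = FALSE)
  if (any(grepl("^__risk_", nm)) || "(intercept)" %in% nm)
    stop("covariate names may not use reserved labels ('__risk_*', '(intercept)')",
         call. = FALSE)
  time <- as.numeric(time)
  if (length(time) != n || anyNA(time) || any(!is.finite(time)) || any(time < 0))
    stop("'time' must be n finite nonnegative values", call. = FALSE)
  if (is.numeric(event)) {
    if (!all(event %in% c(0, 1)))
      stop("'event' values must be 0 or 1", call. = FALSE)
    event <- event == 1
  }
  if (!is.logical(event) || length(event) != n || anyNA(event))
    stop("'event' must be n logical values", call. = FALSE)
  structure(list(covariates = covariates, covariate_names = nm,
                 time = time, event = event),
            class = "survival_dataset")
}

#' @export
print.survival_dataset <- function(x, ...) {
  cat(sprintf("Survival dataset: %d subjects, %d covariates (%s)\n",
              length(x$time), length(x$covariate_names),
              paste(x$covariate_names, collapse = ", ")))
  cat(sprintf("  failures: %d, censored: %d, time range [%g, %g]\n",
              sum(x$event), sum(!x$event), min(x$time), max(x$time)))
  invisible(x)
}

#' @export
as.data.frame.survival_dataset <- function(x, ...) {
  out <- as.data.frame(x$covariates)
  out$time <- x$time
  out$event <- as.integer(x$event)
  out
}

n_subjects <- function(x) length(x$time)

#' Read a survival dataset from CSV
#'
#' Reads a delimited text file with one row per subject, validating the time
#' and event columns and returning a \code{\link{survival_dataset}} in the
#' file's row order.
#'
#' @param path path to a delimited text file with a header row.
#' @param time_col name of the observed-time column.
#' @param event_col name of the 0/1 event-indicator column.
#' @param covariate_cols character vector of covariate column names, or
#'   \code{"all-others"} (default) to use every remaining column.
#' @param delimiter field separator, comma by default.
#' @return A \code{\link{survival_dataset}}.
#' @export
read_survival_csv <- function(path, time_col = "time", event_col = "event",
                              covariate_cols = "all-others", delimiter = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L)
    stop("no data rows in ", path, call. = FALSE)
  for (col in c(time_col, event_col))
    if (!col %in% names(df))
      stop(sprintf("column '%s' not found in %s", col, path), call. = FALSE)
  if (identical(covariate_cols, "all-others"))
    covariate_cols <- setdiff(names(df), c(time_col, event_col))
  missing_cov <- setdiff(covariate_cols, names(df))
  if (length(missing_cov))
    stop("covariate column(s) not found: ", paste(missing_cov, collapse = ", "),
         call. = FALSE)
  for (col in covariate_cols) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1L]
      stop(sprintf("non-numeric covariate value in column '%s', row %d",
                   col, if (is.na(bad)) 1L else bad), call. = FALSE)
    }
  }
  ev <- df[[event_col]]
  bad <- which(!(ev %in% c(0, 1)))
  if (length(bad))
    stop(sprintf("event value outside {0,1} in column '%s', row %d",
                 event_col, bad[1L]), call. = FALSE)
  tm <- df[[time_col]]
  if (!is.numeric(tm))
    stop(sprintf("time column '%s' is not numeric", time_col), call. = FALSE)
  bad <- which(tm < 0)
  if (length(bad))
    stop(sprintf("negative time in column '%s', row %d", time_col, bad[1L]),
         call. = FALSE)
  survival_dataset(as.matrix(df[covariate_cols]), tm, ev)
}

#' Write a survival dataset to CSV
#'
#' Inverse of \code{\link{read_survival_csv}}: covariate columns followed by
#' \code{time} and \code{event} (0/1).
#'
#' @param dataset a \code{\link{survival_dataset}}.
#' @param path output file path.
#' @param delimiter field separator.
#' @return \code{path}, invisibly.
#' @export
write_survival_csv <- function(dataset, path, delimiter = ",") {
  stopifnot(inherits(dataset, "survival_dataset"))
  utils::write.table(as.data.frame(dataset), path, sep = delimiter,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Simulate proportional-hazards survival data
#'
#' Draws covariates i.i.d. standard normal and event times from the hazard
#' \eqn{\lambda(t|Z) = \lambda_0 e^{\beta Z}} with a constant baseline
#' \eqn{\lambda_0}, i.e. latent failure times are exponential with rate
#' \code{baseline_rate * exp(beta . Z)}. Censoring times are independent
#' exponentials with rate \code{censoring_rate} (no censoring when 0).
#'
#' @param n number of subjects.
#' @param beta numeric vector of true log-hazard-ratio coefficients; names
#'   become covariate names.
#' @param baseline_rate positive constant baseline hazard \eqn{\lambda_0}.
#' @param censoring_rate nonnegative rate of the independent exponential
#'   censoring distribution.
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return A \code{\link{survival_dataset}}.
#' @examples
#' d <- simulate_cox_data(200, beta = c(a = 0.5, b = -0.5), seed = 1)
#' mean(d$event)
#' @export
simulate_cox_data <- function(n, beta, baseline_rate = 0.1,
                              censoring_rate = 0.1, seed = 1L) {
  if (n < 1L) stop("'n' must be >= 1", call. = FALSE)
  if (baseline_rate <= 0) stop("'baseline_rate' must be positive", call. = FALSE)
  if (censoring_rate < 0) stop("'censoring_rate' must be >= 0", call. = FALSE)
  beta <- as.numeric_named(beta)
  p <- length(beta)
  local_seed(seed)
  Z <- matrix(stats::rnorm(n * p), nrow = n,
              dimnames = list(NULL, names(beta)))
  rate <- baseline_rate * exp(drop(Z %*% beta))
  Ti <- stats::rexp(n, rate)
  if (censoring_rate > 0) {
    Ci <- stats::rexp(n, censoring_rate)
  } else {
    Ci <- rep(Inf, n)
  }
  survival_dataset(Z, pmin(Ti, Ci), Ti <= Ci)
}

# coerce a coefficient vector to named numeric, inventing z1..zp when unnamed
as.numeric_named <- function(beta) {
  nm <- names(beta)
  beta <- as.numeric(beta)
  if (any(!is.finite(beta))) stop("coefficients must be finite", call. = FALSE)
  names(beta) <- if (is.null(nm)) paste0("z", seq_along(beta)) else nm
  beta
}

# seed the caller's RNG for the rest of its scope, restoring the caller's
# stream on exit
local_seed <- function(seed, envir = parent.frame()) {
  withr::local_seed(as.integer(seed), .local_envir = envir)
  invisible(NULL)
}
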