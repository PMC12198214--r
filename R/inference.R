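#' Standard errors from an information matrix
#'
#' Square roots of the diagonal of the inverse observed information. A
#' singular information triggers the same escalating-ridge fallback as the
#' Newton solver; if that fails the offending column is named.
#'
#' @param information symmetric information matrix (aggregated Hessian at
#'   the optimum).
#' @return Positive standard error per coefficient.
#' @export
standard_errors <- function(information) {
  stopifnot(is.matrix(information), nrow(information) == ncol(information))
  inv <- tryCatch(solve_spd(information, diag(nrow(information))),
                  error = function(e) NULL)
  if (is.null(inv)) {
    culprit <- which.min(diag(information))
    nm <- colnames(information)[culprit]
    stop("information matrix singular; check column ",
         if (is.null(nm)) culprit else nm, call. = FALSE)
  }
  se <- sqrt(pmax(diag(inv), 0))
  names(se) <- colnames(information)
  se
}

#' Wald coefficient table
#'
#' Per-coefficient estimate, standard error (from the total Hessian at the
#' optimum), Wald z = estimate/SE and two-sided normal p-value. Covariate
#' rows are labelled \code{block = "covariate"}; risk-indicator (and
#' intercept) rows are nuisance terms playing the role of a discretized
#' log-baseline hazard and are never compared to Cox coefficients. No
#' multiple-testing adjustment is applied.
#'
#' @param fit a \code{federated_fit}.
#' @param allow_unconverged set \code{TRUE} to table a fit that hit its
#'   iteration cap.
#' @return Data frame of class \code{coefficient_table} with columns
#'   \code{name}, \code{block}, \code{estimate}, \code{std_error},
#'   \code{wald_z}, \code{p_value}.
#' @export
wald_table <- function(fit, allow_unconverged = FALSE) {
  stopifnot(inherits(fit, "federated_fit"))
  if (!fit$converged && !allow_unconverged)
    stop("fit did not converge; pass allow_unconverged = TRUE to table anyway",
         call. = FALSE)
  se <- standard_errors(fit$information)
  est <- fit$beta
  z <- ifelse(se > 0, est / se, NA_real_)
  blocks <- rep("indicator", length(est))
  blocks[covariate_idx(fit)] <- "covariate"
  if (fit$has_intercept) blocks[1L] <- "intercept"
  out <- data.frame(name = names(est), block = blocks,
                    estimate = unname(est), std_error = unname(se),
                    wald_z = unname(z),
                    p_value = unname(2 * stats::pnorm(-abs(z))),
                    stringsAsFactors = FALSE)
  class(out) <- c("coefficient_table", "data.frame")
  out
}

#' Covariate-block view of a coefficient table
#'
#' Restricts a \code{\link{wald_table}} to its covariate rows, in the
#' original covariate order. These are the log-hazard-ratio approximations
#' compared against reference Cox fits throughout.
#'
#' @param table a \code{coefficient_table}, or a \code{federated_fit}
#'   (tabled first, allowing non-convergence).
#' @return The covariate rows as a \code{coefficient_table}.
#' @export
cox_view <- function(table) {
  if (inherits(table, "federated_fit"))
    table <- wald_table(table, allow_unconverged = TRUE)
  stopifnot(inherits(table, "coefficient_table"))
  out <- table[table$block == "covariate", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a coefficient table to CSV
#'
#' @param table a \code{coefficient_table}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_coefficient_csv <- function(table, path) {
  stopifnot(inherits(table, "coefficient_table"))
  utils::write.table(table, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
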