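#' Centralized Cox partial-likelihood fit (internal reference)
#'
#' Newton-Raphson maximization of the Cox partial likelihood with Breslow
#' handling of ties. This is the package's centralized reference model: the
#' federated stacked-logistic pipeline is benchmarked against it, and the
#' Schoenfeld machinery uses it for score-identity checks. It is not part of
#' the federated protocol itself.
#'
#' Convergence is declared when the score max-norm drops below \code{tol};
#' steps that decrease the partial log-likelihood are halved (up to 30 times).
#'
#' @param dataset a \code{\link{survival_dataset}} with at least one failure.
#' @param tol convergence tolerance on the score max-norm.
#' @param max_iter maximum Newton iterations.
#' @return Object of class \code{cox_oracle_fit}: \code{beta} (named),
#'   \code{se}, \code{vcov}, \code{loglik}, \code{score_norm},
#'   \code{iterations}, \code{converged}.
#' @examples
#' d <- simulate_cox_data(500, beta = c(x = 0.7), seed = 3)
#' fit_cox_oracle(d)
#' @export
fit_cox_oracle <- function(dataset, tol = 1e-8, max_iter = 100L) {
  stopifnot(inherits(dataset, "survival_dataset"))
  if (!any(dataset$event))
    stop("cannot fit: dataset contains no failures", call. = FALSE)
  Z <- dataset$covariates
  p <- ncol(Z)
  for (j in seq_len(p)) {
    if (diff(range(Z[, j])) == 0)
      stop("covariate '", colnames(Z)[j], "' is constant; not identifiable",
           call. = FALSE)
  }
  beta <- rep(0, p)
  ll <- cox_partial(dataset, beta)
  for (it in seq_len(max_iter)) {
    sc <- cox_score_info(dataset, beta)
    if (max(abs(sc$score)) <= tol) {
      return(cox_oracle_result(dataset, beta, sc, ll, it - 1L, TRUE))
    }
    step <- solve_spd(sc$info, sc$score)
    new_beta <- beta + step
    new_ll <- cox_partial(dataset, new_beta)
    halvings <- 0L
    while ((!is.finite(new_ll) || new_ll < ll) && halvings < 30L) {
      step <- step / 2
      new_beta <- beta + step
      new_ll <- cox_partial(dataset, new_beta)
      halvings <- halvings + 1L
    }
    beta <- new_beta
    ll <- new_ll
  }
  sc <- cox_score_info(dataset, beta)
  if (max(abs(sc$score)) > tol)
    stop(sprintf(
      "Cox oracle did not converge in %d iterations (score max-norm %.3e)",
      max_iter, max(abs(sc$score))), call. = FALSE)
  cox_oracle_result(dataset, beta, sc, ll, max_iter, TRUE)
}

cox_oracle_result <- function(dataset, beta, sc, ll, iterations, converged) {
  vc <- solve_spd(sc$info, diag(length(beta)))
  names(beta) <- dataset$covariate_names
  se <- sqrt(diag(vc))
  names(se) <- names(beta)
  structure(list(beta = beta, se = se, vcov = vc, loglik = ll,
                 score_norm = max(abs(sc$score)), iterations = iterations,
                 converged = converged),
            class = "cox_oracle_fit")
}

#' @export
print.cox_oracle_fit <- function(x, ...) {
  cat("Cox partial-likelihood fit (Breslow ties)\n")
  print(round(cbind(coef = x$beta, se = x$se, z = x$beta / x$se), 4))
  cat(sprintf("loglik %.4f, %d iterations, score max-norm %.2e\n",
              x$loglik, x$iterations, x$score_norm))
  invisible(x)
}

# Breslow partial log-likelihood. Risk sums are accumulated from the largest
# time down so each failure reads its denominator in O(1).
cox_partial <- function(dataset, beta) {
  ord <- order(dataset$time, decreasing = TRUE)
  t_s <- dataset$time[ord]
  d_s <- dataset$event[ord]
  eta <- drop(dataset$covariates[ord, , drop = FALSE] %*% beta)
  w <- exp(eta)
  cs <- cumsum(w)
  # position of the last subject with time >= t_s[i] (ties included)
  last_ge <- last_tie_index(t_s)
  sum(eta[d_s]) - sum(log(cs[last_ge][d_s]))
}

# score vector and observed information of the Breslow partial likelihood
cox_score_info <- function(dataset, beta) {
  Z <- dataset$covariates
  p <- ncol(Z)
  ord <- order(dataset$time, decreasing = TRUE)
  t_s <- dataset$time[ord]
  d_s <- dataset$event[ord]
  Zs <- Z[ord, , drop = FALSE]
  w <- exp(drop(Zs %*% beta))
  last_ge <- last_tie_index(t_s)
  S0 <- cumsum(w)[last_ge]
  S1 <- apply(Zs * w, 2L, cumsum)
  if (p == 1L) S1 <- matrix(S1, ncol = 1L)
  S1 <- S1[last_ge, , drop = FALSE]
  score <- colSums(Zs[d_s, , drop = FALSE]) - colSums(S1[d_s, , drop = FALSE] / S0[d_s])
  info <- matrix(0, p, p)
  for (a in seq_len(p)) {
    for (b in a:p) {
      S2ab <- cumsum(Zs[, a] * Zs[, b] * w)[last_ge]
      v <- sum(S2ab[d_s] / S0[d_s] -
                 S1[d_s, a] * S1[d_s, b] / S0[d_s]^2)
      info[a, b] <- v
      info[b, a] <- v
    }
  }
  list(score = score, info = info)
}

# for times sorted decreasing, index of the last entry tied with position i
last_tie_index <- function(t_sorted_desc) {
  n <- length(t_sorted_desc)
  idx <- seq_len(n)
  r <- rle(t_sorted_desc)
  rep(cumsum(r$lengths), r$lengths)
}

# SPD solve with escalating ridge, shared by the oracle and newton_step
solve_spd <- function(A, b, ridge0 = 1e-8, max_attempts = 10L) {
  A <- (A + t(A)) / 2
  res <- tryCatch(chol(A), error = function(e) NULL)
  attempt <- 0L
  ridge <- ridge0
  while (is.null(res) && attempt < max_attempts) {
    res <- tryCatch(chol(A + ridge * diag(nrow(A))), error = function(e) NULL)
    ridge <- ridge * 2
    attempt <- attempt + 1L
  }
  if (is.null(res))
    stop("matrix not positive definite after ridge attempts", call. = FALSE)
  backsolve(res, forwardsolve(t(res), b))
}
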