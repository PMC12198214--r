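#' Server-side optimizer state
#'
#' Step rules applied by the aggregation server to the combined gradient
#' (and, for \code{"newton"}, the combined Hessian). Default hyperparameters
#' and iteration budgets follow the conventions used throughout the
#' experiments: first-order methods run with \code{lr = 0.001} (momentum
#' factor 0.9, Adam betas 0.9/0.999), Newton runs at most 25 rounds with a
#' tight gradient tolerance.
#'
#' @param kind one of \code{"gd"}, \code{"momentum"}, \code{"adam"},
#'   \code{"newton"}.
#' @param lr step size \eqn{\eta} (ignored by newton).
#' @param momentum momentum factor in [0,1) (momentum only).
#' @param adam_beta1,adam_beta2 Adam moment decay rates in [0,1).
#' @param max_iter iteration cap; defaults per kind (gd/momentum 100000,
#'   adam 50000, newton 25).
#' @param tol convergence tolerance on the aggregated-gradient max-norm;
#'   defaults to 1e-8 for newton and 1e-5 for first-order rules.
#' @return An \code{optimizer_state} list; pass to \code{\link{fit_federated}}.
#' @examples
#' optimizer("newton")
#' optimizer("adam", lr = 0.001)
#' @export
optimizer <- function(kind = c("newton", "gd", "momentum", "adam"),
                      lr = 0.001, momentum = 0.9,
                      adam_beta1 = 0.9, adam_beta2 = 0.999,
                      max_iter = NULL, tol = NULL) {
  kind <- match.arg(kind)
  if (lr <= 0) stop("'lr' must be positive", call. = FALSE)
  if (momentum < 0 || momentum >= 1) stop("'momentum' must be in [0,1)", call. = FALSE)
  if (any(c(adam_beta1, adam_beta2) < 0) || any(c(adam_beta1, adam_beta2) >= 1))
    stop("adam betas must be in [0,1)", call. = FALSE)
  if (is.null(max_iter))
    max_iter <- switch(kind, gd = 100000L, momentum = 100000L,
                       adam = 50000L, newton = 25L)
  if (is.null(tol))
    tol <- if (kind == "newton") 1e-8 else 1e-5
  structure(list(kind = kind, step_size = lr, momentum_factor = momentum,
                 adam_betas = c(adam_beta1, adam_beta2),
                 moment1 = NULL, moment2 = NULL, velocity = NULL,
                 step_count = 0L, max_iter = as.integer(max_iter), tol = tol),
            class = "optimizer_state")
}

#' @export
print.optimizer_state <- function(x, ...) {
  cat(sprintf("Optimizer '%s' (step %d)", x$kind, x$step_count))
  if (x$kind != "newton") cat(sprintf(", lr = %g", x$step_size))
  if (x$kind == "momentum") cat(sprintf(", v = %g", x$momentum_factor))
  if (x$kind == "adam")
    cat(sprintf(", betas = (%g, %g)", x$adam_betas[1], x$adam_betas[2]))
  cat(sprintf(", max_iter = %d, tol = %g\n", x$max_iter, x$tol))
  invisible(x)
}

check_grad <- function(gradient) {
  if (any(!is.finite(gradient)))
    stop("non-finite gradient entry", call. = FALSE)
}

init_vec <- function(v, n) if (is.null(v)) rep(0, n) else v

#' Plain gradient-descent step
#'
#' \code{beta - lr * gradient}.
#'
#' @param state an \code{\link{optimizer}} state.
#' @param beta current coefficient vector.
#' @param gradient aggregated gradient of the same length.
#' @return List with \code{beta} (updated vector) and \code{state}.
#' @export
gd_step <- function(state, beta, gradient) {
  check_grad(gradient)
  stopifnot(length(beta) == length(gradient))
  state$step_count <- state$step_count + 1L
  list(beta = beta - state$step_size * gradient, state = state)
}

#' Classical momentum step
#'
#' velocity <- v * velocity + gradient; beta <- beta - lr * velocity.
#'
#' @inheritParams gd_step
#' @return List with \code{beta} and updated \code{state} (velocity carried).
#' @export
momentum_step <- function(state, beta, gradient) {
  check_grad(gradient)
  stopifnot(length(beta) == length(gradient))
  vel <- init_vec(state$velocity, length(beta))
  vel <- state$momentum_factor * vel + gradient
  state$velocity <- vel
  state$step_count <- state$step_count + 1L
  list(beta = beta - state$step_size * vel, state = state)
}

#' Adam step
#'
#' Standard Adam with bias-corrected first and second moments and
#' \code{eps = 1e-8}.
#'
#' @inheritParams gd_step
#' @param eps denominator stabilizer.
#' @return List with \code{beta} and updated \code{state} (moments carried).
#' @export
adam_step <- function(state, beta, gradient, eps = 1e-8) {
  check_grad(gradient)
  stopifnot(length(beta) == length(gradient))
  m <- init_vec(state$moment1, length(beta))
  v <- init_vec(state$moment2, length(beta))
  b1 <- state$adam_betas[1]
  b2 <- state$adam_betas[2]
  t_ <- state$step_count + 1L
  m <- b1 * m + (1 - b1) * gradient
  v <- b2 * v + (1 - b2) * gradient^2
  m_hat <- m / (1 - b1^t_)
  v_hat <- v / (1 - b2^t_)
  state$moment1 <- m
  state$moment2 <- v
  state$step_count <- t_
  list(beta = beta - state$step_size * m_hat / (sqrt(v_hat) + eps),
       state = state)
}

#' Newton-Raphson step
#'
#' \code{beta - solve(hessian, gradient)} via a Cholesky (SPD) factorization;
#' on factorization failure a ridge of 1e-8 is added to the diagonal and
#' doubled until the factorization succeeds (at most 10 attempts).
#'
#' @param beta current coefficient vector.
#' @param gradient aggregated gradient.
#' @param hessian symmetric aggregated Hessian.
#' @return Updated coefficient vector.
#' @export
newton_step <- function(beta, gradient, hessian) {
  check_grad(gradient)
  stopifnot(length(beta) == length(gradient),
            is.matrix(hessian),
            nrow(hessian) == length(beta), ncol(hessian) == length(beta))
  beta - drop(solve_spd(hessian, gradient))
}
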