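#' One party's stacked shard
#'
#' Wraps a locally stacked dataset as a federation client. All shards in one
#' federation must share the same column layout (same covariate order and the
#' same bin grid), which \code{\link{fit_federated}} verifies before round 1.
#'
#' @param stacked a \code{stacked_dataset} produced locally by the party.
#' @param party_id label for the party.
#' @return A \code{client_shard}.
#' @export
client_shard <- function(stacked, party_id = "party") {
  stopifnot(inherits(stacked, "stacked_dataset"))
  structure(list(party_id = party_id, stacked = stacked,
                 n_rows = nrow(stacked$X)),
            class = "client_shard")
}

#' Logistic success probabilities
#'
#' \eqn{\sigma(X\beta)} rowwise, numerically stable over the full double
#' range of the linear predictor.
#'
#' @param X feature matrix.
#' @param beta coefficient vector, \code{ncol(X)} long.
#' @return Probability per row, in (0,1).
#' @export
predict_prob <- function(X, beta) {
  stopifnot(ncol(X) == length(beta))
  stats::plogis(drop(X %*% beta))
}

shard_matrix <- function(shard) {
  if (inherits(shard, "client_shard")) shard$stacked$X else shard$X
}
shard_target <- function(shard) {
  s <- if (inherits(shard, "client_shard")) shard$stacked else shard
  as.numeric(s$y)
}

#' Local negative log-likelihood
#'
#' Cross-entropy of the shard's targets under coefficients \code{beta};
#' probabilities are clipped to \code{[1e-12, 1 - 1e-12]} before the logs.
#'
#' @param shard a \code{\link{client_shard}} (or a \code{stacked_dataset}).
#' @param beta coefficient vector.
#' @return Nonnegative scalar loss.
#' @export
local_loss <- function(shard, beta) {
  X <- shard_matrix(shard)
  y <- shard_target(shard)
  pr <- pmin(pmax(predict_prob(X, beta), 1e-12), 1 - 1e-12)
  -sum(y * log(pr) + (1 - y) * log(1 - pr))
}

#' Local gradient of the negative log-likelihood
#'
#' \eqn{\nabla L_k(\beta) = \sum_i (y'_i - y_i) X_i}, the exact gradient of
#' \code{\link{local_loss}}.
#'
#' @inheritParams local_loss
#' @return Numeric vector of length \code{ncol(X)}.
#' @export
local_gradient <- function(shard, beta) {
  X <- shard_matrix(shard)
  y <- shard_target(shard)
  drop(crossprod(X, predict_prob(X, beta) - y))
}

#' Local Hessian of the negative log-likelihood
#'
#' \eqn{X^T D X} with \eqn{D = diag(y'(1-y'))}; symmetric positive
#' semidefinite.
#'
#' @inheritParams local_loss
#' @return Square matrix of dimension \code{ncol(X)}.
#' @export
local_hessian <- function(shard, beta) {
  X <- shard_matrix(shard)
  w <- predict_prob(X, beta)
  w <- w * (1 - w)
  crossprod(X, X * w)
}

#' Size-weighted aggregation
#'
#' The server's combination rule: \eqn{\sum_k (n_k / n) v_k} with
#' \eqn{n = \sum_k n_k}, applied elementwise to per-party vectors or
#' matrices of identical shape.
#'
#' @param values list of per-party numeric vectors or matrices.
#' @param sizes positive per-party row counts \eqn{n_k}.
#' @return The combined value, same shape as each element of \code{values}.
#' @export
aggregate_updates <- function(values, sizes) {
  if (length(values) != length(sizes) || length(values) == 0L)
    stop("'values' and 'sizes' must be nonempty and matched", call. = FALSE)
  if (any(sizes <= 0)) stop("sizes must be positive", call. = FALSE)
  dims <- lapply(values, dim)
  lens <- lengths(values)
  if (length(unique(lens)) != 1L || length(unique(dims)) != 1L)
    stop("shape mismatch across parties", call. = FALSE)
  w <- sizes / sum(sizes)
  out <- values[[1L]] * w[1L]
  for (k in seq_along(values)[-1L]) out <- out + values[[k]] * w[k]
  out
}

# In-process client: answers typed requests with coefficient-dimension
# payloads only (gradient/hessian/loss/meta) -- never raw rows. The local
# update a client shares is its per-row MEAN gradient (and Hessian), so the
# server's size-weighted average reproduces the pooled mean exactly. A
# networked transport can replace this closure without touching the server
# loop.
make_client <- function(X, y, party_id) {
  force(X); force(y)
  shard <- list(X = X, y = y)
  nk <- nrow(X)
  function(msg) {
    switch(msg$type,
           meta = list(n_rows = nk, columns = colnames(X),
                       party_id = party_id),
           gradient = local_gradient(shard, msg$beta) / nk,
           hessian = local_hessian(shard, msg$beta) / nk,
           loss = local_loss(shard, msg$beta),
           stop("unknown message type: ", msg$type, call. = FALSE))
  }
}

#' Federated logistic regression on stacked shards
#'
#' Server loop of the federation: broadcast the current coefficients, collect
#' each party's local gradient (and Hessian for the Newton rule), combine,
#' step, and repeat until the aggregated-gradient max-norm falls below the
#' optimizer's tolerance or its iteration cap is reached. Starts from
#' \eqn{\beta^{(0)} = 0}.
#'
#' With \code{optimizer("newton")} the server solves against the summed
#' (total) gradient and Hessian, which makes the fit exactly equal to the
#' pooled single-party fit for any partition of the data. First-order rules
#' step against the size-weighted mean gradient by default
#' (\code{gradient_scale = "mean"}), so the learning rate is per-row;
#' \code{"sum"} uses the total gradient instead.
#'
#' An optional ridge penalty \code{penalty/2 * ||beta||^2} (never applied to
#' the intercept) and an optional intercept column are available; both are
#' off by default. The combination \code{intercept = TRUE, penalty = 1}
#' matches the defaults of common regularized logistic solvers and is used
#' by the table-reproduction harnesses.
#'
#' @param shards list of \code{\link{client_shard}}s with identical columns.
#' @param optimizer an \code{\link{optimizer}} state; Newton by default.
#' @param intercept prepend a shared intercept column.
#' @param penalty ridge weight \eqn{\lambda \ge 0} on non-intercept terms.
#' @param gradient_scale \code{"mean"} or \code{"sum"} for first-order rules.
#' @param loss_every record the total loss every this many rounds (the final
#'   round is always recorded); raise it for long first-order runs.
#' @return Object of class \code{federated_fit}: \code{beta} (named),
#'   \code{rounds}, \code{converged}, \code{final_gradient_norm},
#'   \code{loss_history}, \code{information} (total Hessian at the optimum,
#'   including the penalty), block bookkeeping, and \code{n_total}.
#' @examples
#' d <- simulate_cox_data(300, beta = c(x = 0.5), seed = 2)
#' s <- stack_binned(d, make_bins(max(d$time), 10))
#' fit <- fit_federated(list(client_shard(s)))
#' cox_view(wald_table(fit))
#' @export
fit_federated <- function(shards, optimizer = fedcox::optimizer("newton"),
                          intercept = FALSE, penalty = 0,
                          gradient_scale = c("mean", "sum"),
                          loss_every = 1L) {
  gradient_scale <- match.arg(gradient_scale)
  if (length(shards) == 0L) stop("need at least one shard", call. = FALSE)
  if (!all(vapply(shards, inherits, TRUE, "client_shard")))
    stop("'shards' must be a list of client_shard objects", call. = FALSE)
  if (penalty < 0) stop("'penalty' must be >= 0", call. = FALSE)
  cols <- lapply(shards, function(s) s$stacked$column_names)
  if (length(unique(cols)) != 1L)
    stop("shard column layouts differ; all parties must stack on the same bins",
         call. = FALSE)
  p <- shards[[1L]]$stacked$n_covariates
  B <- shards[[1L]]$stacked$n_indicators
  clients <- lapply(shards, function(s) {
    X <- s$stacked$X
    if (intercept)
      X <- cbind(`(intercept)` = 1, X)
    make_client(X, as.numeric(s$stacked$y), s$party_id)
  })
  meta <- lapply(clients, function(cl) cl(list(type = "meta")))
  sizes <- vapply(meta, `[[`, 0, "n_rows")
  n <- sum(sizes)
  d <- length(meta[[1L]]$columns)
  col_names <- meta[[1L]]$columns
  pen <- rep(penalty, d)
  if (intercept) pen[1L] <- 0

  beta <- rep(0, d)
  opt <- optimizer
  loss_history <- numeric(0)
  total_loss <- function(beta) {
    sum(vapply(clients, function(cl) cl(list(type = "loss", beta = beta)), 0)) +
      0.5 * sum(pen * beta^2)
  }
  converged <- FALSE
  grad_norm <- NA_real_
  rounds <- 0L
  for (r in seq_len(opt$max_iter)) {
    grads <- lapply(clients, function(cl) cl(list(type = "gradient", beta = beta)))
    mean_grad <- aggregate_updates(grads, sizes)
    if (opt$kind == "newton" || gradient_scale == "sum") {
      g <- n * mean_grad + pen * beta
    } else {
      g <- mean_grad + pen * beta / n
    }
    grad_norm <- max(abs(g))
    if ((r %% loss_every) == 0L) loss_history <- c(loss_history, total_loss(beta))
    if (grad_norm <= opt$tol) { converged <- TRUE; rounds <- r - 1L; break }
    if (opt$kind == "newton") {
      hess <- lapply(clients, function(cl) cl(list(type = "hessian", beta = beta)))
      H <- n * aggregate_updates(hess, sizes) + diag(pen, d)
      beta <- newton_step(beta, g, H)
      opt$step_count <- opt$step_count + 1L
    } else {
      stepped <- switch(opt$kind,
                        gd = gd_step(opt, beta, g),
                        momentum = momentum_step(opt, beta, g),
                        adam = adam_step(opt, beta, g))
      beta <- stepped$beta
      opt <- stepped$state
    }
    rounds <- r
  }
  hess <- lapply(clients, function(cl) cl(list(type = "hessian", beta = beta)))
  information <- n * aggregate_updates(hess, sizes) + diag(pen, d)
  final_loss <- total_loss(beta)
  if (!length(loss_history) || loss_history[length(loss_history)] != final_loss)
    loss_history <- c(loss_history, final_loss)
  names(beta) <- col_names
  structure(list(beta = beta, rounds = rounds, converged = converged,
                 final_gradient_norm = grad_norm,
                 loss_history = loss_history,
                 information = information,
                 n_covariates = p, n_indicators = B,
                 has_intercept = intercept, penalty = penalty,
                 column_names = col_names, n_total = n,
                 optimizer_kind = opt$kind),
            class = "federated_fit")
}

#' @export
print.federated_fit <- function(x, ...) {
  cat(sprintf(
    "Federated stacked-logistic fit (%s): %d covariates + %d risk indicators%s\n",
    x$optimizer_kind, x$n_covariates, x$n_indicators,
    if (x$has_intercept) " + intercept" else ""))
  cat(sprintf("  %d rounds, converged: %s, final gradient max-norm %.3e\n",
              x$rounds, x$converged, x$final_gradient_norm))
  cv <- x$beta[covariate_idx(x)]
  print(round(cv, 4))
  invisible(x)
}

covariate_idx <- function(fit) {
  seq_len(fit$n_covariates) + if (fit$has_intercept) 1L else 0L
}

#' Serialize a federated fit to JSON
#'
#' Writes the coefficient table (name, estimate), round count, convergence
#' flag, and final gradient norm.
#'
#' @param fit a \code{federated_fit}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "federated_fit"))
  obj <- list(coefficients = data.frame(name = names(fit$beta),
                                        estimate = unname(fit$beta)),
              rounds = fit$rounds, converged = fit$converged,
              final_gradient_norm = fit$final_gradient_norm,
              optimizer = fit$optimizer_kind)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
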