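shard_from <- function(X, y) {
  client_shard(fedcox:::new_stacked_dataset(
    structure(X, dimnames = list(NULL, paste0("c", seq_len(ncol(X))))),
    y, ncol(X), 0L, seq_len(nrow(X))))
}

test_that("predicted probabilities match the logistic formula and stay stable", {
  set.seed(3)
  X <- matrix(stats::rnorm(30), 10, 3)
  beta <- c(0.2, -1, 0.5)
  expect_equal(predict_prob(X, beta),
               1 / (1 + exp(-drop(X %*% beta))), tolerance = 1e-12)
  expect_equal(predict_prob(X, c(0, 0, 0)), rep(0.5, 10))
  big <- matrix(c(700, -700), 2, 1)
  pr <- predict_prob(big, 1)
  expect_true(all(is.finite(pr)) && pr[1] > 1 - 1e-12 && pr[2] < 1e-12)
})

test_that("local loss matches closed forms and a hand-computed 3-row shard", {
  X <- rbind(c(1, 0), c(0, 1), c(1, 1))
  y <- c(TRUE, FALSE, TRUE)
  sh <- shard_from(X, y)
  expect_equal(local_loss(sh, c(0, 0)), 3 * log(2))
  beta <- c(0.5, -0.25)
  pr <- 1 / (1 + exp(-drop(X %*% beta)))
  expect_equal(local_loss(sh, beta),
               -sum(y * log(pr) + (1 - y) * log(1 - pr)), tolerance = 1e-12)
  # near-perfect predictions: loss ~ 0
  expect_lt(local_loss(shard_from(rbind(1, -1) * 50, c(TRUE, FALSE)), 1), 1e-10)
})

test_that("local gradient is the exact derivative of the local loss", {
  set.seed(9)
  X <- matrix(stats::rnorm(40), 10, 4)
  y <- stats::runif(10) < 0.4
  sh <- shard_from(X, y)
  beta <- stats::rnorm(4, sd = 0.5)
  g <- local_gradient(sh, beta)
  h <- 1e-6
  for (j in 1:4) {
    e <- numeric(4); e[j] <- h
    fd <- (local_loss(sh, beta + e) - local_loss(sh, beta - e)) / (2 * h)
    expect_equal(g[j], fd, tolerance = 1e-6, ignore_attr = TRUE)
  }
  # stationarity at a centralized optimum (reference logistic fit)
  glm_fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))
  expect_lt(max(abs(local_gradient(sh, glm_fit$coefficients))), 1e-6)
  # y' == y everywhere gives a zero gradient
  expect_equal(local_gradient(shard_from(rbind(1, -1) * 60, c(TRUE, FALSE)), 1),
               c(0), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("local hessian matches sigma(0) closed form, finite differences, PSD", {
  set.seed(10)
  X <- matrix(stats::rnorm(12), 6, 2)
  y <- c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE)
  sh <- shard_from(X, y)
  expect_equal(local_hessian(sh, c(0, 0)), crossprod(X) / 4,
               tolerance = 1e-12, ignore_attr = TRUE)
  beta <- c(0.3, -0.6)
  H <- local_hessian(sh, beta)
  h <- 1e-5
  for (j in 1:2) {
    e <- numeric(2); e[j] <- h
    fd <- (local_gradient(sh, beta + e) - local_gradient(sh, beta - e)) / (2 * h)
    expect_equal(H[, j], fd, tolerance = 1e-4, ignore_attr = TRUE)
  }
  expect_true(all(eigen(H, symmetric = TRUE)$values >= -1e-10))
})

test_that("aggregation is the size-weighted mean and satisfies pooling", {
  expect_equal(aggregate_updates(list(c(1, 2)), 5), c(1, 2))
  expect_equal(aggregate_updates(list(c(1, 2), c(3, 4)), c(7, 7)), c(2, 3))
  expect_error(aggregate_updates(list(c(1, 2), c(1, 2, 3)), c(1, 1)),
               "shape mismatch")

  set.seed(12)
  X <- matrix(stats::rnorm(120), 30, 4)
  y <- stats::runif(30) < 0.5
  beta <- stats::rnorm(4, sd = 0.3)
  # clients share per-row mean gradients; the size-weighted average of
  # those reproduces the pooled mean gradient exactly
  pooled <- local_gradient(shard_from(X, y), beta)
  for (parts in list(c(10, 20), c(5, 5, 20), c(1, 29))) {
    idx <- split(seq_len(30), rep(seq_along(parts), parts))
    grads <- lapply(idx, function(i)
      local_gradient(shard_from(X[i, , drop = FALSE], y[i]), beta) / length(i))
    expect_equal(aggregate_updates(grads, parts), pooled / 30,
                 tolerance = 1e-12)
  }
})

test_that("single-shard newton equals the centralized logistic fit", {
  d <- random_dataset(120, 2, seed = 33)
  s <- stack_binned(d, make_bins(max(d$time), 5))
  fit <- fit_federated(list(client_shard(s)))
  glm_fit <- suppressWarnings(
    stats::glm.fit(s$X, as.numeric(s$y), family = stats::binomial(),
                   control = stats::glm.control(maxit = 200, epsilon = 1e-12)))
  expect_true(fit$converged)
  # compare only identified coefficients: a bin without any failure drives
  # its indicator to -Inf in both fits, at solver-dependent speed
  bin_events <- tapply(as.numeric(s$y),
                       max.col(s$X[, -seq_len(2), drop = FALSE]), sum)
  identified <- c(rep(TRUE, 2), bin_events > 0)
  expect_equal(unname(fit$beta[identified]),
               unname(glm_fit$coefficients[identified]), tolerance = 1e-8)
  # loss never ends above its start
  expect_lte(fit$loss_history[length(fit$loss_history)], fit$loss_history[1])
})

test_that("newton fits are invariant to how the stacked rows are partitioned", {
  d <- random_dataset(80, 3, seed = 44)
  s <- stack_binned(d, make_bins(max(d$time), 8))
  m <- nrow(s$X)
  set.seed(1)
  ref <- fit_federated(list(client_shard(s)))$beta
  for (k in 2:4) {
    grp <- sample(rep(seq_len(k), length.out = m))
    shards <- lapply(seq_len(k), function(g)
      client_shard(stacked_subset(s, which(grp == g))))
    got <- fit_federated(shards)$beta
    expect_equal(got, ref, tolerance = 1e-6)
  }
})

test_that("separable stacked data still yields finite coefficients", {
  # the worked example is separable: probabilities saturate, the gradient
  # vanishes, and the round cap bounds the drift of the indicator block
  s <- stack_exact(worked_dataset())
  fit <- fit_federated(list(client_shard(s)))
  expect_true(all(is.finite(fit$beta)))
  expect_lte(fit$rounds, optimizer("newton")$max_iter)
})

test_that("column layout mismatches are rejected before round 1", {
  d <- random_dataset(40, 2, seed = 51)
  s1 <- stack_binned(d, make_bins(max(d$time), 4))
  s2 <- stack_binned(d, make_bins(max(d$time), 6))
  expect_error(fit_federated(list(client_shard(s1), client_shard(s2))),
               "column layouts differ")
})

test_that("client payloads expose only aggregates, never raw rows", {
  d <- random_dataset(25, 2, seed = 60)
  s <- stack_binned(d, make_bins(max(d$time), 3))
  cl <- fedcox:::make_client(s$X, as.numeric(s$y), "p1")
  beta <- rep(0.1, ncol(s$X))
  meta <- cl(list(type = "meta"))
  expect_named(meta, c("n_rows", "columns", "party_id"))
  g <- cl(list(type = "gradient", beta = beta))
  H <- cl(list(type = "hessian", beta = beta))
  l <- cl(list(type = "loss", beta = beta))
  expect_length(g, ncol(s$X))
  expect_equal(dim(H), c(ncol(s$X), ncol(s$X)))
  expect_length(l, 1)
  expect_error(cl(list(type = "rows")), "unknown message")
})
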