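test_that("time perturbation is deterministic, order-preserving, tie-breaking", {
  d <- random_dataset(50, 2, seed = 81)
  p1 <- perturb_times(d, seed = 5)
  p2 <- perturb_times(d, seed = 5)
  expect_identical(p1, p2)
  expect_true(all(diff(p1$time) > 0))
  # vanishing scale preserves the ranking of already-distinct times
  tiny <- perturb_times(d, scale = 1e-9 * diff(range(d$time)), seed = 6)
  expect_equal(order(tiny$time), order(sort(d$time)))
  expect_equal(tiny$original_time, sort(d$time))

  tied <- survival_dataset(matrix(1:6, ncol = 1), rep(c(1, 2), 3),
                           rep(1, 6))
  pt <- perturb_times(tied, seed = 7)
  expect_false(anyDuplicated(pt$time) > 0)
})

test_that("failure-time sharing merges and conserves the parties' failures", {
  mk <- function(times, ev) survival_dataset(matrix(seq_along(times), ncol = 1),
                                             times, ev)
  parties <- list(mk(c(1.1, 3.0), c(1, 0)), mk(c(2.2, 0.5), c(1, 1)))
  expect_equal(share_failure_times(parties), c(0.5, 1.1, 2.2))
  expect_equal(share_failure_times(parties[1]), 1.1)
  expect_length(share_failure_times(parties),
                sum(vapply(parties, function(d) sum(d$event), 0)))
  dup <- list(mk(1.1, 1), mk(1.1, 1))
  expect_error(share_failure_times(dup), "duplicate")
})

test_that("party precomputation matches its definitions on edge cases", {
  # single subject holding its own failure, beta = 0
  one <- survival_dataset(matrix(c(2, -1), 1, dimnames = list(NULL, c("u", "v"))),
                          3.5, 1)
  pc <- schoenfeld_precompute(one, c(0, 0), f = 3.5)
  expect_equal(pc$hazards, 1)
  expect_equal(unname(pc$HV), 1)
  expect_equal(unname(pc$WV), matrix(c(2, -1), 1), ignore_attr = TRUE)
  expect_equal(unname(pc$CV), matrix(c(2, -1), 1), ignore_attr = TRUE)

  # no subjects at risk beyond the party's last time: HV = 0 from then on
  pc2 <- schoenfeld_precompute(one, c(0.1, -0.2), f = c(3.5, 9, 10))
  expect_equal(unname(pc2$HV[2:3]), c(0, 0))
  expect_equal(unname(pc2$CV[2:3, ]), matrix(0, 2, 2))
})

test_that("precomputed risk sums equal a nested-loop brute force", {
  d <- perturb_times(random_dataset(15, 3, seed = 83), seed = 9)
  beta <- c(0.4, -0.3, 0.1)
  f <- sort(d$time[d$event])
  pc <- schoenfeld_precompute(d, beta, f)
  H <- exp(drop(d$covariates %*% beta))
  for (i in seq_along(f)) {
    at <- which(d$time >= f[i])
    expect_equal(pc$HV[i], sum(H[at]), tolerance = 1e-12)
    expect_equal(pc$WV[i, ], colSums(d$covariates[at, , drop = FALSE] * H[at]),
                 tolerance = 1e-12)
  }
  # HV is nonincreasing along sorted failure times
  expect_true(all(diff(pc$HV) <= 0))
})

test_that("combining one party reproduces the centralized oracle exactly", {
  d <- perturb_times(random_dataset(30, 2, seed = 84), seed = 11)
  beta <- c(0.3, -0.2)
  f <- d$time[d$event]
  pc <- schoenfeld_precompute(d, beta, sort(f))
  got <- schoenfeld_combine(list(pc))
  want <- schoenfeld_oracle(d, beta)
  expect_equal(got$residuals, want$residuals, tolerance = 1e-12)
  expect_equal(got$total_hazard, want$total_hazard, tolerance = 1e-12)

  # a 1-subject population is its own risk set: zero residual
  solo <- survival_dataset(matrix(c(1.5, 2), 1), 4, 1)
  res <- schoenfeld_combine(list(schoenfeld_precompute(solo, c(0.2, 0.1), 4)))
  expect_equal(unname(res$residuals), matrix(0, 1, 2))
})

test_that("the distributed protocol equals the pooled oracle for any split", {
  pooled <- perturb_times(random_dataset(30, 2, seed = 85), seed = 13)
  beta <- c(0.5, -0.5)
  f <- sort(pooled$time[pooled$event])
  want <- schoenfeld_oracle(pooled, beta)
  set.seed(2)
  for (k in 2:4) {
    grp <- sample(rep(seq_len(k), length.out = 30))
    parties <- lapply(seq_len(k), function(g) {
      idx <- which(grp == g)
      survival_dataset(pooled$covariates[idx, , drop = FALSE],
                       pooled$time[idx], pooled$event[idx])
    })
    pcs <- lapply(parties, schoenfeld_precompute, beta = beta, f = f)
    got <- schoenfeld_combine(pcs)
    expect_lt(max(abs(got$residuals - want$residuals)), 1e-10)
  }
})

test_that("oracle residuals: unweighted mean at beta = 0, hand computation", {
  d <- survival_dataset(matrix(c(1, 4, 7), ncol = 1, dimnames = list(NULL, "x")),
                        c(1, 2, 3), c(1, 1, 0))
  res <- schoenfeld_oracle(d, 0)
  # failure 1: risk {1,2,3}, mean 4; failure 2: risk {2,3}, mean 5.5
  expect_equal(unname(res$residuals[, 1]), c(1 - 4, 4 - 5.5))

  tied <- survival_dataset(matrix(1:2, ncol = 1), c(1, 1), c(1, 1))
  expect_error(schoenfeld_oracle(tied, 0), "perturb")
})

test_that("oracle matches survival's Schoenfeld residuals at the Cox MLE", {
  skip_if_not_installed("survival")
  d <- perturb_times(simulate_cox_data(400, c(a = 0.6, b = -0.3), seed = 86),
                     seed = 15)
  df <- as.data.frame(d)
  cfit <- survival::coxph(survival::Surv(time, event) ~ a + b, data = df,
                          ties = "breslow")
  want <- stats::residuals(cfit, type = "schoenfeld")
  got <- schoenfeld_oracle(d, stats::coef(cfit))
  expect_equal(unname(got$residuals), unname(want), tolerance = 1e-6)

  # score identity: residual columns sum to ~0 at the partial-likelihood MLE
  own <- fit_cox_oracle(d)
  at_mle <- schoenfeld_oracle(d, own$beta)
  expect_true(all(abs(colSums(at_mle$residuals)) < 1e-6))
})

test_that("a residual row depends only on subjects still at risk", {
  d <- perturb_times(random_dataset(25, 2, seed = 87), seed = 17)
  beta <- c(0.2, 0.4)
  base <- schoenfeld_oracle(d, beta)
  # mutate the covariates of the earliest censored subject
  victim <- which(!d$event)[which.min(d$time[!d$event])]
  d2 <- d
  d2$covariates[victim, ] <- d2$covariates[victim, ] + 100
  after <- schoenfeld_oracle(d2, beta)
  unaffected <- base$failure_times > d$time[victim]
  expect_equal(base$residuals[unaffected, ], after$residuals[unaffected, ],
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(base$residuals[!unaffected, ],
                                after$residuals[!unaffected, ])))
})

test_that("end-to-end protocol run is deterministic and oracle-consistent", {
  d <- simulate_cox_data(120, c(a = 0.5, b = -0.2), seed = 88)
  beta <- fit_cox_oracle(d)$beta
  parties <- split_uniform(d, 3, seed = 19)
  r1 <- fed_schoenfeld(parties, beta, seed = 23)
  r2 <- fed_schoenfeld(parties, beta, seed = 23)
  expect_identical(r1, r2)
  expect_length(r1$failure_times, sum(d$event))
  expect_equal(sort(r1$original_failure_times), sort(d$time[d$event]),
               tolerance = 1e-9)
  # single party equals the oracle on its own perturbation
  solo <- fed_schoenfeld(list(d), beta, seed = 29)
  pd <- perturb_times(d, seed = 29 + 7919L + 1L)
  expect_equal(solo$residuals, schoenfeld_oracle(pd, beta)$residuals,
               tolerance = 1e-12)
})

test_that("lowess smoothing recovers flat and linear structure", {
  x <- sort(stats::runif(200, 0, 10))
  expect_equal(lowess_smooth(x, rep(0, 200))$y, rep(0, 200))
  expect_equal(lowess_smooth(x, rep(2.5, 200))$y, rep(2.5, 200),
               tolerance = 1e-12)
  set.seed(31)
  y <- 1.5 * x + stats::rnorm(200, sd = 0.1)
  sm <- lowess_smooth(x, y)
  slope <- stats::coef(stats::lm(sm$y ~ sm$x))[2]
  expect_lt(abs(slope - 1.5) / 1.5, 0.1)
  expect_error(lowess_smooth(c(1, 2), c(0, 0)), "at least 3")
})

test_that("diagnostic plots are written per covariate", {
  d <- simulate_cox_data(80, c(a = 0.4), seed = 90)
  res <- fed_schoenfeld(list(d), fit_cox_oracle(d)$beta, seed = 3)
  png_path <- withr::local_tempfile(fileext = ".png")
  plot_schoenfeld(res, "a", file = png_path)
  expect_gt(file.size(png_path), 0)
  csv_path <- withr::local_tempfile(fileext = ".csv")
  write_schoenfeld_csv(res, csv_path)
  back <- utils::read.csv(csv_path)
  expect_equal(nrow(back), length(res$failure_times))
  expect_true("original_failure_time" %in% names(back))
})
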