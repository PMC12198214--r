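#' Manhattan (L1) distance between coefficient vectors
#'
#' The accuracy-loss measure: \eqn{\sum_i |\beta_i - \beta^*_i|} against a
#' reference model's coefficients.
#'
#' @param beta_a,beta_b equal-length numeric vectors.
#' @return Nonnegative scalar.
#' @export
manhattan_distance <- function(beta_a, beta_b) {
  if (length(beta_a) != length(beta_b))
    stop("coefficient vectors differ in length", call. = FALSE)
  sum(abs(beta_a - beta_b))
}

#' Euclidean (L2) distance between coefficient vectors
#'
#' @inheritParams manhattan_distance
#' @return Nonnegative scalar.
#' @export
euclidean_distance <- function(beta_a, beta_b) {
  if (length(beta_a) != length(beta_b))
    stop("coefficient vectors differ in length", call. = FALSE)
  sqrt(sum((beta_a - beta_b)^2))
}

#' Uniform random split into parties
#'
#' Permutes the subjects and deals them into \code{n_parties} shards whose
#' sizes differ by at most one. Deterministic given \code{seed}.
#'
#' @param dataset a \code{\link{survival_dataset}}.
#' @param n_parties number of shards, between 1 and n.
#' @param seed integer seed.
#' @return List of \code{\link{survival_dataset}}s.
#' @export
split_uniform <- function(dataset, n_parties, seed = 1L) {
  stopifnot(inherits(dataset, "survival_dataset"))
  n <- n_subjects(dataset)
  n_parties <- as.integer(n_parties)
  if (n_parties < 1L || n_parties > n)
    stop("'n_parties' must be between 1 and n", call. = FALSE)
  local_seed(seed)
  perm <- sample.int(n)
  sizes <- rep(n %/% n_parties, n_parties)
  extra <- n %% n_parties
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, ends[-n_parties] + 1L)
  lapply(seq_len(n_parties), function(k) {
    idx <- perm[starts[k]:ends[k]]
    survival_dataset(dataset$covariates[idx, , drop = FALSE],
                     dataset$time[idx], dataset$event[idx])
  })
}

# central stacked fit at a given bin count; returns covariate estimates
central_stacked_fit <- function(dataset, n_bins, optimizer, intercept, penalty) {
  bins <- make_bins(max(dataset$time), n_bins)
  s <- stack_binned(dataset, bins)
  fit <- fit_federated(list(client_shard(s)), optimizer = optimizer,
                       intercept = intercept, penalty = penalty)
  stats::setNames(cox_view(fit)$estimate, dataset$covariate_names)
}

#' Bin-count sweep against a reference Cox fit
#'
#' For each bin count, fits the stacked logistic model centrally (one
#' party) and records its covariate coefficients and the Euclidean distance
#' to a reference Cox fit. By default the reference is the internal
#' \code{\link{fit_cox_oracle}}; pass \code{reference} to benchmark against
#' an externally obtained coefficient vector instead.
#'
#' The default solver configuration (intercept plus ridge penalty 1) is the
#' one used for all table-style benchmarks; see the package vignette.
#'
#' @param dataset a \code{\link{survival_dataset}}.
#' @param bin_counts integer vector of bin counts to sweep.
#' @param optimizer an \code{\link{optimizer}}; Newton by default.
#' @param reference optional named reference coefficient vector.
#' @param intercept,penalty solver configuration for the stacked fits.
#' @return Object of class \code{experiment_report}: data frame \code{rows}
#'   with \code{n_bins}, one column per covariate, \code{distance} and
#'   \code{error}, plus the \code{reference} used.
#' @export
run_bins_sweep <- function(dataset, bin_counts,
                           optimizer = fedcox::optimizer("newton"),
                           reference = NULL,
                           intercept = TRUE, penalty = 1) {
  stopifnot(inherits(dataset, "survival_dataset"))
  if (is.null(reference)) reference <- fit_cox_oracle(dataset)$beta
  rows <- lapply(bin_counts, function(B) {
    est <- tryCatch(
      central_stacked_fit(dataset, B, optimizer, intercept, penalty),
      error = function(e) e)
    if (inherits(est, "error")) {
      out <- as.data.frame(as.list(stats::setNames(
        rep(NA_real_, length(reference)), names(reference))))
      out <- cbind(data.frame(n_bins = B), out,
                   data.frame(distance = NA_real_,
                              error = conditionMessage(est)))
    } else {
      out <- cbind(data.frame(n_bins = B), as.data.frame(as.list(est)),
                   data.frame(distance = euclidean_distance(est, reference),
                              error = NA_character_))
    }
    out
  })
  structure(list(design = "bins_sweep", rows = do.call(rbind, rows),
                 reference = reference),
            class = "experiment_report")
}

#' Federated versus individually trained models
#'
#' The partition experiment: for each repetition and each party count, split
#' the dataset uniformly at random, fit one federated stacked model over all
#' shards (bins on the collaborative maximum time) and one Cox model per
#' shard, and record each model's Manhattan distance ("accuracy loss") to
#' the central Cox reference fit on the pooled data. The individual loss of
#' a repetition is the mean over its parties; shards whose Cox fit fails
#' (e.g. monotone likelihood on a small shard) are excluded and counted.
#'
#' @param dataset a \code{\link{survival_dataset}}.
#' @param n_parties integer vector of party counts.
#' @param repetitions splits per party count.
#' @param n_bins bins for the federated stacked fits.
#' @param seed integer seed; repetition r uses derived seed \code{seed + r}.
#' @param optimizer an \code{\link{optimizer}}; Newton by default.
#' @param intercept,penalty solver configuration for the federated fits.
#' @return An \code{experiment_report}: \code{rows} with one record per
#'   (repetition, n_parties) holding \code{federated_loss},
#'   \code{individual_loss}, \code{n_failed_individual}; \code{summary} with
#'   per-party-count averages; \code{per_party_losses} retaining every
#'   individual party's loss.
#' @export
run_federated_vs_individual <- function(dataset, n_parties = 2:5,
                                        repetitions = 10L, n_bins = 25L,
                                        seed = 1L,
                                        optimizer = fedcox::optimizer("newton"),
                                        intercept = TRUE, penalty = 1) {
  stopifnot(inherits(dataset, "survival_dataset"))
  reference <- fit_cox_oracle(dataset)$beta
  records <- list()
  per_party <- list()
  for (np in n_parties) {
    for (r in seq_len(repetitions)) {
      split_seed <- as.integer(seed) + 1000L * match(np, n_parties) + r
      shards_data <- split_uniform(dataset, np, seed = split_seed)
      t_max <- global_max_time(vapply(shards_data, function(d) max(d$time), 0))
      bins <- make_bins(t_max, n_bins)
      shards <- lapply(seq_along(shards_data), function(k)
        client_shard(stack_binned(shards_data[[k]], bins, drop_empty = FALSE),
                     party_id = paste0("party", k)))
      fed <- fit_federated(shards, optimizer = optimizer,
                           intercept = intercept, penalty = penalty)
      fed_loss <- manhattan_distance(cox_view(fed)$estimate, reference)
      ind <- vapply(shards_data, function(d) {
        fit <- tryCatch(fit_cox_oracle(d), error = function(e) NULL)
        if (is.null(fit)) NA_real_ else manhattan_distance(fit$beta, reference)
      }, 0)
      records[[length(records) + 1L]] <- data.frame(
        n_parties = np, repetition = r, seed = split_seed,
        federated_loss = fed_loss,
        individual_loss = mean(ind, na.rm = TRUE),
        n_failed_individual = sum(is.na(ind)))
      per_party[[length(per_party) + 1L]] <- data.frame(
        n_parties = np, repetition = r, party = seq_len(np),
        individual_loss = ind)
    }
  }
  rows <- do.call(rbind, records)
  summary <- do.call(rbind, lapply(unique(rows$n_parties), function(np) {
    sub <- rows[rows$n_parties == np, ]
    data.frame(n_parties = np,
               federated_loss = mean(sub$federated_loss),
               individual_loss = mean(sub$individual_loss),
               n_failed_individual = sum(sub$n_failed_individual))
  }))
  structure(list(design = "federated_vs_individual", rows = rows,
                 summary = summary,
                 per_party_losses = do.call(rbind, per_party),
                 reference = reference),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("Experiment report: %s (%d rows)\n", x$design, nrow(x$rows)))
  if (!is.null(x$summary)) print(x$summary) else print(utils::head(x$rows))
  invisible(x)
}

#' Write an experiment report to CSV/JSON
#'
#' The row table goes to \code{<stem>.csv} (and the summary, when present,
#' to \code{<stem>_summary.csv}); the full report to \code{<stem>.json}.
#'
#' @param report an \code{experiment_report}.
#' @param stem output path without extension.
#' @return The paths written, invisibly.
#' @export
write_report <- function(report, stem) {
  stopifnot(inherits(report, "experiment_report"))
  paths <- paste0(stem, ".csv")
  utils::write.table(report$rows, paths, sep = ",", row.names = FALSE,
                     quote = FALSE)
  if (!is.null(report$summary)) {
    p2 <- paste0(stem, "_summary.csv")
    utils::write.table(report$summary, p2, sep = ",", row.names = FALSE,
                       quote = FALSE)
    paths <- c(paths, p2)
  }
  pj <- paste0(stem, ".json")
  jsonlite::write_json(report[setdiff(names(report), "reference")], pj,
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(c(paths, pj))
}
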