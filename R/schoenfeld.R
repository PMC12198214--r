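#' Perturb event times to break ties
#'
#' Protocol preprocessing: adds an independent Uniform(0, scale) value to
#' every event time so that all times in the federation become distinct,
#' then sorts the party's rows by the perturbed time. The draw is
#' deterministic given \code{seed}; if duplicates survive (scale too coarse
#' for the data's resolution) the draw is retried up to 100 times before
#' erroring.
#'
#' @param dataset a \code{\link{survival_dataset}}.
#' @param scale upper bound of the uniform perturbation; default
#'   \code{1e-6 * diff(range(time))} (or \code{1e-6} for degenerate ranges).
#' @param seed integer seed.
#' @return A \code{\link{survival_dataset}} sorted by perturbed time, with
#'   an extra element \code{original_time} holding the unperturbed times in
#'   the same (sorted) row order.
#' @export
perturb_times <- function(dataset, scale = NULL, seed = 1L) {
  stopifnot(inherits(dataset, "survival_dataset"))
  if (is.null(scale)) {
    rng <- diff(range(dataset$time))
    scale <- if (rng > 0) 1e-6 * rng else 1e-6
  }
  if (scale <= 0) stop("'scale' must be positive", call. = FALSE)
  local_seed(seed)
  n <- length(dataset$time)
  for (attempt in seq_len(100L)) {
    tt <- dataset$time + stats::runif(n, 0, scale)
    if (!anyDuplicated(tt)) {
      ord <- order(tt)
      out <- survival_dataset(dataset$covariates[ord, , drop = FALSE],
                              tt[ord], dataset$event[ord])
      out$original_time <- dataset$time[ord]
      return(out)
    }
  }
  stop("duplicate times persist after 100 perturbation retries; increase 'scale'",
       call. = FALSE)
}

#' Pool the parties' failure times
#'
#' Protocol step 2: the sorted union of all parties' (perturbed) failure
#' times. These times are disclosed by design -- the residuals must be
#' plotted against them.
#'
#' @param parties list of perturbed \code{\link{survival_dataset}}s.
#' @return Sorted numeric vector of the K global failure times.
#' @export
share_failure_times <- function(parties) {
  if (length(parties) == 0L) stop("no parties supplied", call. = FALSE)
  f <- unlist(lapply(parties, function(d) d$time[d$event]))
  if (anyDuplicated(f))
    stop("duplicate failure times across parties; re-perturb with other seeds",
         call. = FALSE)
  sort(f)
}

#' One party's Schoenfeld precomputation
#'
#' Protocol step 3. With model coefficients \eqn{\beta} the party computes,
#' for each of its subjects, the hazard \eqn{H_i = \exp(C_i \beta)} and the
#' weights \eqn{W_{ij} = C_{ij} H_i}; then, for every global failure time
#' \eqn{f_i}, the at-risk sums \eqn{HV_i = \sum_{k: t_k \ge f_i} H_k} and
#' \eqn{WV_{ij} = \sum_{k: t_k \ge f_i} W_{kj}} over its own subjects, and
#' \eqn{CV_{i\cdot}} equal to the covariates of its subject failing at
#' \eqn{f_i} when that failure is the party's own, else a zero row.
#'
#' @param party_data the party's perturbed \code{\link{survival_dataset}}.
#' @param beta covariate coefficients (typically the covariate block of the
#'   federated fit, see \code{\link{cox_view}}).
#' @param f sorted global failure times from
#'   \code{\link{share_failure_times}}.
#' @return A \code{party_precomp} with elements \code{hazards},
#'   \code{weights}, \code{own_failures}, \code{HV} (K), \code{WV} and
#'   \code{CV} (K x p), and \code{f}.
#' @export
schoenfeld_precompute <- function(party_data, beta, f) {
  stopifnot(inherits(party_data, "survival_dataset"))
  beta <- as.numeric(beta)
  Z <- party_data$covariates
  p <- ncol(Z)
  if (length(beta) != p)
    stop("'beta' must have one entry per covariate", call. = FALSE)
  if (is.unsorted(f, strictly = TRUE))
    stop("'f' must be strictly increasing", call. = FALSE)
  K <- length(f)
  tt <- party_data$time
  H <- exp(drop(Z %*% beta))
  W <- Z * H
  ord <- order(tt)
  ts <- tt[ord]
  # count of local subjects with t < f_i: findInterval counts t <= f_i,
  # minus one when f_i coincides with a local time (the party's own failure)
  n_le <- findInterval(f, ts)
  own_hit <- f %in% ts
  n_lt <- n_le - own_hit
  csH <- c(0, cumsum(H[ord]))
  HV <- csH[length(csH)] - csH[n_lt + 1L]
  WV <- matrix(0, K, p, dimnames = list(NULL, colnames(Z)))
  for (j in seq_len(p)) {
    csW <- c(0, cumsum(W[ord, j]))
    WV[, j] <- csW[length(csW)] - csW[n_lt + 1L]
  }
  own_f <- tt[party_data$event]
  CV <- matrix(0, K, p, dimnames = list(NULL, colnames(Z)))
  fi_own <- which(f %in% own_f)
  for (i in fi_own) {
    k <- which(tt == f[i])
    if (length(k) != 1L || !party_data$event[k])
      stop(sprintf("bookkeeping error: failure time %g claimed but not held",
                   f[i]), call. = FALSE)
    CV[i, ] <- Z[k, ]
  }
  structure(list(party_id = attr(party_data, "party_id"),
                 perturbed_times = tt, hazards = H, weights = W,
                 own_failures = sort(own_f), HV = HV, WV = WV, CV = CV,
                 f = f, covariate_names = colnames(Z)),
            class = "party_precomp")
}

#' Combine party precomputations into Schoenfeld residuals
#'
#' Protocol step 4 (the step the secure aggregation would run over secret
#' shares; here the same message flow with plaintext sums): entrywise totals
#' \eqn{TH_i = \sum_p HV_i}, \eqn{TW_{ij} = \sum_p WV_{ij}},
#' \eqn{TC_{ij} = \sum_p CV_{ij}}, then the expected covariate
#' \eqn{EC_{ij} = TW_{ij}/TH_i} and residual \eqn{SR_{ij} = TC_{ij} - EC_{ij}}.
#'
#' @param precomps list of \code{party_precomp}s built against the same
#'   failure-time vector and covariate order.
#' @return Object of class \code{schoenfeld_result}: \code{failure_times},
#'   \code{total_hazard}, \code{total_weight}, \code{observed},
#'   \code{expected}, \code{residuals}, \code{covariate_names}.
#' @export
schoenfeld_combine <- function(precomps) {
  if (length(precomps) == 0L) stop("no precomputations supplied", call. = FALSE)
  if (!all(vapply(precomps, inherits, TRUE, "party_precomp")))
    stop("'precomps' must be party_precomp objects", call. = FALSE)
  f <- precomps[[1L]]$f
  nm <- precomps[[1L]]$covariate_names
  for (pc in precomps[-1L]) {
    if (!identical(pc$f, f) || !identical(pc$covariate_names, nm))
      stop("precomputations disagree on failure times or covariates",
           call. = FALSE)
  }
  TH <- Reduce(`+`, lapply(precomps, `[[`, "HV"))
  TW <- Reduce(`+`, lapply(precomps, `[[`, "WV"))
  TC <- Reduce(`+`, lapply(precomps, `[[`, "CV"))
  if (any(TH <= 0))
    stop("zero total hazard at a failure time: inconsistent risk bookkeeping",
         call. = FALSE)
  EC <- TW / TH
  structure(list(failure_times = f, total_hazard = TH, total_weight = TW,
                 observed = TC, expected = EC, residuals = TC - EC,
                 covariate_names = nm),
            class = "schoenfeld_result")
}

#' @export
print.schoenfeld_result <- function(x, ...) {
  cat(sprintf("Schoenfeld residuals: %d failures x %d covariates (%s)\n",
              length(x$failure_times), length(x$covariate_names),
              paste(x$covariate_names, collapse = ", ")))
  cat("per-covariate residual sums:",
      paste(sprintf("%.4g", colSums(x$residuals)), collapse = ", "), "\n")
  invisible(x)
}

#' Centralized Schoenfeld residuals (textbook reference)
#'
#' Direct computation on pooled data with distinct event times: at each
#' failure, the failing subject's covariates minus the hazard-weighted mean
#' covariate over the risk set,
#' \eqn{SR_i = C_i - \sum_{k \in R(t_i)} C_k e^{C_k\beta} / \sum_{k \in R(t_i)} e^{C_k\beta}}.
#' Used as the test reference for the distributed protocol.
#'
#' @param pooled a \code{\link{survival_dataset}} with distinct event times
#'   (perturb first if necessary).
#' @param beta covariate coefficients.
#' @return A \code{schoenfeld_result}.
#' @export
schoenfeld_oracle <- function(pooled, beta) {
  stopifnot(inherits(pooled, "survival_dataset"))
  if (anyDuplicated(pooled$time))
    stop("tied event times; apply perturb_times() first", call. = FALSE)
  beta <- as.numeric(beta)
  Z <- pooled$covariates
  if (length(beta) != ncol(Z))
    stop("'beta' must have one entry per covariate", call. = FALSE)
  f <- sort(pooled$time[pooled$event])
  K <- length(f)
  p <- ncol(Z)
  r <- exp(drop(Z %*% beta))
  TH <- numeric(K)
  TW <- matrix(0, K, p, dimnames = list(NULL, colnames(Z)))
  TC <- matrix(0, K, p, dimnames = list(NULL, colnames(Z)))
  for (i in seq_len(K)) {
    at_risk <- pooled$time >= f[i]
    TH[i] <- sum(r[at_risk])
    TW[i, ] <- colSums(Z[at_risk, , drop = FALSE] * r[at_risk])
    TC[i, ] <- Z[pooled$time == f[i], ]
  }
  EC <- TW / TH
  structure(list(failure_times = f, total_hazard = TH, total_weight = TW,
                 observed = TC, expected = EC, residuals = TC - EC,
                 covariate_names = colnames(Z)),
            class = "schoenfeld_result")
}

#' Distributed Schoenfeld residuals, end to end
#'
#' Runs the four protocol steps over a list of party datasets: perturb each
#' party's times (re-perturbing all parties with fresh derived seeds if a
#' cross-party collision occurs), share failure times, precompute per party,
#' and combine.
#'
#' @param datasets list of \code{\link{survival_dataset}}s, one per party.
#' @param beta covariate coefficients shared by all parties.
#' @param scale perturbation scale; default derived from the pooled time
#'   range as in \code{\link{perturb_times}}.
#' @param seed integer seed driving all perturbations.
#' @return A \code{schoenfeld_result} with an extra element
#'   \code{original_failure_times}: the unperturbed time of each failure, in
#'   the same order as \code{failure_times}.
#' @export
fed_schoenfeld <- function(datasets, beta, scale = NULL, seed = 1L) {
  if (length(datasets) == 0L) stop("no parties supplied", call. = FALSE)
  if (is.null(scale)) {
    rng <- range(unlist(lapply(datasets, `[[`, "time")))
    scale <- if (diff(rng) > 0) 1e-6 * diff(rng) else 1e-6
  }
  for (attempt in seq_len(100L)) {
    perturbed <- lapply(seq_along(datasets), function(k)
      perturb_times(datasets[[k]], scale = scale,
                    seed = as.integer(seed) + 7919L * attempt + k))
    f <- tryCatch(share_failure_times(perturbed), error = function(e) NULL)
    if (!is.null(f)) {
      precomps <- lapply(perturbed, schoenfeld_precompute, beta = beta, f = f)
      out <- schoenfeld_combine(precomps)
      orig <- unlist(lapply(perturbed, function(d) {
        stats::setNames(d$original_time[d$event], NULL)[order(d$time[d$event])]
      }))
      pert <- unlist(lapply(perturbed, function(d) sort(d$time[d$event])))
      out$original_failure_times <- orig[match(out$failure_times, pert)]
      return(out)
    }
  }
  stop("cross-party duplicate failure times persist; increase 'scale'",
       call. = FALSE)
}

#' LOWESS smooth of a residual series
#'
#' Locally weighted scatterplot smoothing of one covariate's residuals
#' against failure time, for the diagnostic plot.
#'
#' @param failure_times K sorted times (K >= 3).
#' @param residuals K residual values for one covariate.
#' @param fraction smoother span in (0, 1]; default 2/3.
#' @return List with components \code{x} and \code{y} (the smoothed curve).
#' @export
lowess_smooth <- function(failure_times, residuals, fraction = 2/3) {
  if (length(failure_times) < 3L)
    stop("need at least 3 failures to smooth", call. = FALSE)
  if (fraction <= 0 || fraction > 1)
    stop("'fraction' must be in (0, 1]", call. = FALSE)
  stats::lowess(failure_times, residuals, f = fraction)
}

#' Residual-versus-time diagnostic plot
#'
#' Scatter of one covariate's Schoenfeld residuals over failure time with a
#' LOWESS line and a zero reference; a flat line supports the proportional
#' hazards assumption for that covariate.
#'
#' @param result a \code{schoenfeld_result}.
#' @param covariate covariate name (or index).
#' @param file optional output path ending in \code{.png} or \code{.svg};
#'   when \code{NULL} the current device is used.
#' @param fraction LOWESS span.
#' @return \code{file} (or \code{NULL}), invisibly.
#' @export
plot_schoenfeld <- function(result, covariate, file = NULL, fraction = 2/3) {
  stopifnot(inherits(result, "schoenfeld_result"))
  if (is.numeric(covariate)) covariate <- result$covariate_names[covariate]
  if (!covariate %in% result$covariate_names)
    stop("unknown covariate: ", covariate, call. = FALSE)
  if (!is.null(file)) {
    if (grepl("\\.png$", file)) {
      grDevices::png(file, width = 800, height = 500)
    } else if (grepl("\\.svg$", file)) {
      grDevices::svg(file, width = 8, height = 5)
    } else stop("'file' must end in .png or .svg", call. = FALSE)
    on.exit(grDevices::dev.off())
  }
  y <- result$residuals[, covariate]
  graphics::plot(result$failure_times, y, pch = 20,
                 col = "grey40", xlab = "failure time",
                 ylab = sprintf("Schoenfeld residual (%s)", covariate))
  graphics::abline(h = 0, lty = 2)
  sm <- lowess_smooth(result$failure_times, y, fraction)
  graphics::lines(sm, col = "firebrick", lwd = 2)
  invisible(file)
}

#' Write Schoenfeld residuals to CSV
#'
#' Columns: \code{failure_time} (perturbed), \code{original_failure_time}
#' when available, then one residual column per covariate.
#'
#' @param result a \code{schoenfeld_result}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_schoenfeld_csv <- function(result, path) {
  stopifnot(inherits(result, "schoenfeld_result"))
  df <- data.frame(failure_time = result$failure_times)
  if (!is.null(result$original_failure_times))
    df$original_failure_time <- result$original_failure_times
  df <- cbind(df, as.data.frame(result$residuals))
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
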