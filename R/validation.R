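# Model validation: nonparametric bootstrap (subjects as the resampling
# unit) and (prediction-corrected) visual predictive checks.

#' Nonparametric bootstrap of a population PK fit
#'
#' Resamples subjects with replacement, refits the model to each resample
#' (warm-started at the original estimates, single start by default), and
#' summarizes the estimates over the converged resamples: mean, SD, CV%,
#' median and the empirical 2.5th/97.5th percentiles. Failed refits are
#' dropped and counted; if more than 20% fail the result carries a prominent
#' warning flag (and a warning is emitted).
#'
#' @param data A `pk_dataset`.
#' @param spec A [model_spec()].
#' @param n_resamples Number of bootstrap resamples (>= 1). Default 1000.
#' @param seed Seed for the resampling; the whole bootstrap is reproducible
#'   from it. Default 1.
#' @param fit_args Extra arguments for [fit_pk()] applied to the original fit
#'   and every refit (default single start, no SEs).
#' @param indices Optional list of subject-index vectors, one per resample,
#'   overriding the random resampling (each a vector of positions into the
#'   unique subject IDs, with replacement). Useful for forcing an identity
#'   resample in tests.
#' @return An object of class `pk_bootstrap`: `summary` (one row per
#'   parameter: original estimate, bootstrap mean, sd, cv_pct, median, ci_lo,
#'   ci_hi), `estimates` (resample x parameter matrix over converged
#'   resamples), `n_resamples`, `n_failed`, `high_failure` flag, `fit` (the
#'   original fit) and `seed`.
#' @export
bootstrap_pk <- function(data, spec, n_resamples = 1000, seed = 1,
                         fit_args = list(), indices = NULL) {
  if (n_resamples < 1) stop("'n_resamples' must be >= 1")
  data <- pk_dataset(as.data.frame(data))
  ids <- unique(data$ID)
  n <- length(ids)
  if (!is.null(indices)) {
    if (length(indices) != n_resamples)
      stop("'indices' must have one element per resample")
    lapply(indices, function(ix) {
      if (any(ix < 1 | ix > n)) stop("resample index out of range")
    })
  }
  fit_args <- utils::modifyList(list(n_starts = 1, se = FALSE), fit_args)
  fit0 <- do.call(fit_pk, c(list(spec = spec, data = data), fit_args))

  set.seed(seed)
  draws <- if (is.null(indices))
    lapply(seq_len(n_resamples), function(r) sample.int(n, n, replace = TRUE))
  else indices

  resample_data <- function(ix) {
    parts <- lapply(seq_along(ix), function(j) {
      d <- data[data$ID == ids[ix[j]], , drop = FALSE]
      d$ID <- j
      d
    })
    pk_dataset(do.call(rbind, parts))
  }

  par_names <- fit0$estimates$parameter
  est <- matrix(NA_real_, n_resamples, length(par_names),
                dimnames = list(NULL, par_names))
  n_failed <- 0L
  for (r in seq_len(n_resamples)) {
    f <- tryCatch(
      do.call(fit_pk, c(list(spec = spec, data = resample_data(draws[[r]]),
                             start = fit0$par), fit_args)),
      error = function(e) NULL)
    if (is.null(f)) { n_failed <- n_failed + 1L; next }
    est[r, ] <- f$estimates$estimate
  }
  est <- est[stats::complete.cases(est), , drop = FALSE]
  if (nrow(est) == 0) stop("all bootstrap refits failed")
  high_failure <- n_failed > 0.2 * n_resamples
  if (high_failure)
    warning(sprintf("%d of %d bootstrap refits failed (> 20%%); summaries unreliable",
                    n_failed, n_resamples))
  qs <- apply(est, 2, stats::quantile, probs = c(0.025, 0.5, 0.975),
              names = FALSE)
  summary <- data.frame(
    parameter = par_names,
    original = fit0$estimates$estimate,
    mean = colMeans(est),
    sd = apply(est, 2, stats::sd),
    median = qs[2, ], ci_lo = qs[1, ], ci_hi = qs[3, ],
    row.names = NULL)
  summary$cv_pct <- 100 * summary$sd / abs(summary$mean)
  summary <- summary[, c("parameter", "original", "mean", "sd", "cv_pct",
                         "median", "ci_lo", "ci_hi")]
  structure(list(summary = summary, estimates = est,
                 n_resamples = n_resamples, n_failed = n_failed,
                 high_failure = high_failure, fit = fit0, seed = seed),
            class = "pk_bootstrap")
}

#' @export
print.pk_bootstrap <- function(x, ...) {
  cat(sprintf("Bootstrap: %d resamples, %d failed refits%s\n",
              x$n_resamples, x$n_failed,
              if (x$high_failure) "  ** >20% failures: unreliable **" else ""))
  s <- x$summary
  s[, -1] <- signif(s[, -1], 4)
  print(s, row.names = FALSE)
  invisible(x)
}

#' Write a bootstrap summary as CSV
#' @param boot A `pk_bootstrap`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bootstrap_summary <- function(boot, path) {
  utils::write.csv(boot$summary, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Simulate n_sim replicate observation vectors under a fitted model with the
# design (dosing, times, covariates) held at the observed values. Returns an
# n_obs x n_sim matrix.
simulate_from_fit <- function(fit, n_sim, seed = 1) {
  design <- fit$design
  spec <- fit$spec
  p <- unpack_params(fit$par, spec)
  typ <- row_typicals(design, p, spec)
  set.seed(seed)
  out <- matrix(NA_real_, design$n_obs, n_sim)
  for (r in seq_len(n_sim)) {
    ev <- if (spec$re_v)
      exp(stats::rnorm(design$n_subj, 0, sqrt(p$omega2_v))) else
        rep(1, design$n_subj)
    ecl <- if (spec$re_cl)
      exp(stats::rnorm(design$n_subj, 0, sqrt(p$omega2_cl))) else
        rep(1, design$n_subj)
    f <- conc_and_jac(design, typ$V * ev[design$subj],
                      typ$CL * ecl[design$subj], p$ka, jac = FALSE)$f
    w <- resid_var(f, p, spec)
    out[, r] <- f + stats::rnorm(design$n_obs, 0, sqrt(w))
  }
  out
}

# Bin observation rows by time-after-dose deciles with a minimum count per
# bin; undersized bins are merged into their left neighbor (logged via
# message()).
vpc_bins <- function(tad, n_bins = 10, min_per_bin = 10) {
  br <- unique(stats::quantile(tad, probs = seq(0, 1, length.out = n_bins + 1),
                               names = FALSE))
  bin <- findInterval(tad, br, rightmost.closed = TRUE, all.inside = TRUE)
  # merge undersized bins leftwards (the first bin merges rightwards)
  repeat {
    cnt <- table(factor(bin, levels = sort(unique(bin))))
    small <- names(cnt)[cnt < min_per_bin]
    if (length(small) == 0 || length(cnt) == 1) break
    b <- as.integer(small[1])
    lv <- sort(unique(bin))
    tgt <- if (b == lv[1]) lv[2] else max(lv[lv < b])
    message(sprintf("VPC: merging bin %d (n = %d) into bin %d",
                    b, cnt[small[1]], tgt))
    bin[bin == b] <- tgt
  }
  match(bin, sort(unique(bin)))   # relabel 1..K
}

#' Visual predictive check
#'
#' Simulates `n_sim` replicates of the dataset under the fitted model (design,
#' dosing and covariates held at their observed values), bins observations by
#' time-after-dose deciles (minimum 10 observations per bin; undersized bins
#' merged into a neighbor), and compares the observed 5th/50th/95th
#' percentiles per bin against the 90% confidence band of the corresponding
#' simulated percentiles. With `prediction_corrected = TRUE` (default, the
#' pcVPC variant) observations and simulations are first rescaled by
#' `median(PRED in bin) / PRED` to remove covariate- and dose-driven
#' heterogeneity within a bin.
#'
#' @param fit A converged `pk_fit`.
#' @param n_sim Number of simulation replicates. Default 1000.
#' @param n_bins Target number of TAD bins. Default 10.
#' @param min_per_bin Minimum observations per bin. Default 10.
#' @param prediction_corrected Apply prediction correction? Default TRUE.
#' @param seed Simulation seed. Default 1.
#' @param probs Percentiles to check. Default `c(0.05, 0.5, 0.95)`.
#' @return An object of class `pk_vpc`: `table` with one row per bin x
#'   percentile (`bin`, `tad_lo`, `tad_mid`, `tad_hi`, `n`, `prob`,
#'   `observed`, `band_lo`, `band_hi`, `sim_median`), plus
#'   `prediction_corrected`, `n_sim` and `seed`.
#' @export
vpc_pk <- function(fit, n_sim = 1000, n_bins = 10, min_per_bin = 10,
                   prediction_corrected = TRUE, seed = 1,
                   probs = c(0.05, 0.5, 0.95)) {
  design <- fit$design
  sims <- simulate_from_fit(fit, n_sim, seed = seed)
  obs <- design$dv
  bin <- vpc_bins(design$tad, n_bins = n_bins, min_per_bin = min_per_bin)
  if (prediction_corrected) {
    fp <- fit_predictions(fit)
    pred <- pmax(fp$pred, .Machine$double.eps)
    med_pred <- stats::ave(pred, bin, FUN = stats::median)
    corr <- med_pred / pred
    obs <- obs * corr
    sims <- sims * corr
  }
  bins <- sort(unique(bin))
  rows <- list()
  for (b in bins) {
    sel <- bin == b
    obs_q <- stats::quantile(obs[sel], probs = probs, names = FALSE)
    # per-replicate percentiles of the simulated data in this bin
    sim_q <- apply(sims[sel, , drop = FALSE], 2, stats::quantile,
                   probs = probs, names = FALSE)
    if (is.null(dim(sim_q))) sim_q <- matrix(sim_q, nrow = length(probs))
    band <- apply(sim_q, 1, stats::quantile, probs = c(0.05, 0.5, 0.95),
                  names = FALSE)
    rows[[length(rows) + 1]] <- data.frame(
      bin = b, tad_lo = min(design$tad[sel]),
      tad_mid = stats::median(design$tad[sel]),
      tad_hi = max(design$tad[sel]), n = sum(sel),
      prob = probs, observed = obs_q,
      band_lo = band[1, ], sim_median = band[2, ], band_hi = band[3, ])
  }
  tab <- do.call(rbind, rows)
  structure(list(table = tab, prediction_corrected = prediction_corrected,
                 n_sim = n_sim, seed = seed), class = "pk_vpc")
}

#' @export
print.pk_vpc <- function(x, ...) {
  cat(sprintf("VPC: %d simulations, %s, %d bins\n", x$n_sim,
              if (x$prediction_corrected) "prediction-corrected" else "raw",
              length(unique(x$table$bin))))
  t <- x$table
  t[, -(1:1)] <- signif(t[, -(1:1)], 4)
  print(t, row.names = FALSE)
  invisible(x)
}

#' Fraction of observed VPC percentile points inside their simulation bands
#' @param vpc A `pk_vpc`.
#' @return Numeric scalar in [0, 1].
#' @export
vpc_coverage <- function(vpc) {
  t <- vpc$table
  mean(t$observed >= t$band_lo & t$observed <= t$band_hi)
}

#' Write a VPC table as CSV
#' @param vpc A `pk_vpc`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vpc_table <- function(vpc, path) {
  utils::write.csv(vpc$table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
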