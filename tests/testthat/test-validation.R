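# Bootstrap and VPC: identity resamples, reproducibility, band invariants,
# and detection of a deliberately misspecified model.

test_that("identity resamples reproduce the original estimates", {
  coh <- fx("cohort19")
  spec <- model_spec(effects = c("vrc_v", "vrc_cl", "crea_v"))
  idx <- replicate(3, seq_len(19), simplify = FALSE)
  boot <- bootstrap_pk(coh$data, spec, n_resamples = 3, indices = idx,
                       fit_args = list(control = list(rel.tol = 1e-8)))
  expect_identical(boot$n_failed, 0L)
  # each refit solves the same problem warm-started at its solution
  for (r in 1:3)
    expect_equal(unname(boot$estimates[r, ]),
                 boot$summary$original, tolerance = 1e-4)
})

test_that("the bootstrap is reproducible from its seed and validates input", {
  coh <- fx("cohort19")
  spec <- model_spec(effects = c("vrc_v", "vrc_cl", "crea_v"))
  b1 <- bootstrap_pk(coh$data, spec, n_resamples = 3, seed = 5,
                     fit_args = list(control = list(rel.tol = 1e-6)))
  b2 <- bootstrap_pk(coh$data, spec, n_resamples = 3, seed = 5,
                     fit_args = list(control = list(rel.tol = 1e-6)))
  expect_identical(b1$estimates, b2$estimates)
  expect_equal(colnames(b1$summary),
               c("parameter", "original", "mean", "sd", "cv_pct", "median",
                 "ci_lo", "ci_hi"))
  expect_true(all(b1$summary$ci_lo <= b1$summary$ci_hi))

  expect_error(bootstrap_pk(coh$data, spec, n_resamples = 0), "'n_resamples'")
  expect_error(bootstrap_pk(coh$data, spec, n_resamples = 2,
                            indices = list(1:19)), "one element per resample")
  expect_error(bootstrap_pk(coh$data, spec, n_resamples = 1,
                            indices = list(c(1, 99))), "out of range")

  path <- withr::local_tempfile(fileext = ".csv")
  write_bootstrap_summary(b1, path)
  expect_equal(utils::read.csv(path)$parameter, b1$summary$parameter)
})

test_that("VPC table satisfies its structural invariants", {
  fit <- fx("fit19")
  vpc <- vpc_pk(fit, n_sim = 200, seed = 3)
  t <- vpc$table
  expect_equal(colnames(t),
               c("bin", "tad_lo", "tad_mid", "tad_hi", "n", "prob",
                 "observed", "band_lo", "sim_median", "band_hi"))
  # every observation is in exactly one bin
  expect_equal(sum(t$n[!duplicated(t$bin)]), fit$n_obs)
  expect_true(all(t$n[!duplicated(t$bin)] >= 10))
  # bands are ordered and percentiles increase with the probability level
  expect_true(all(t$band_lo <= t$sim_median & t$sim_median <= t$band_hi))
  for (b in unique(t$bin)) {
    tb <- t[t$bin == b, ]
    expect_true(all(diff(tb$observed[order(tb$prob)]) >= 0))
    expect_true(all(diff(tb$sim_median[order(tb$prob)]) >= 0))
  }
  # bins tile the TAD axis in order
  lo <- t$tad_lo[!duplicated(t$bin)]
  expect_true(all(diff(lo) > 0))
  expect_true(vpc_coverage(vpc) >= 0 && vpc_coverage(vpc) <= 1)

  # reproducibility
  vpc2 <- vpc_pk(fit, n_sim = 200, seed = 3)
  expect_identical(vpc$table, vpc2$table)

  path <- withr::local_tempfile(fileext = ".csv")
  write_vpc_table(vpc, path)
  expect_equal(nrow(utils::read.csv(path)), nrow(t))
})

test_that("a well-specified model has high VPC coverage, a corrupted one low", {
  fit <- fx("fit19")
  good <- vpc_coverage(vpc_pk(fit, n_sim = 200, seed = 3))
  # corrupt the fitted clearance by a factor 3: simulations now concentrate
  # far below the observations and the observed percentiles leave the bands
  bad_fit <- fit
  bad_fit$par["lCL"] <- bad_fit$par["lCL"] + log(3)
  bad <- vpc_coverage(vpc_pk(bad_fit, n_sim = 200, seed = 3))
  expect_gt(good, 0.6)
  # the additive residual SD (~3.5 ng/mL) is large relative to the trough
  # level, so even a 3x clearance error leaves some percentile points inside
  # their bands; require a clear drop, not total separation
  expect_lt(bad, 0.6)
  expect_gt(good - bad, 0.2)
})

test_that("raw and prediction-corrected VPC differ but share the binning", {
  fit <- fx("fit19")
  v_pc <- vpc_pk(fit, n_sim = 100, seed = 4, prediction_corrected = TRUE)
  v_raw <- vpc_pk(fit, n_sim = 100, seed = 4, prediction_corrected = FALSE)
  expect_identical(v_pc$table$bin, v_raw$table$bin)
  expect_identical(v_pc$table$n, v_raw$table$n)
  expect_false(isTRUE(all.equal(v_pc$table$observed, v_raw$table$observed)))
})

test_that("undersized bins are merged with a message", {
  tad <- c(seq(0.1, 1, length.out = 30), rep(5, 3))
  expect_message(bins <- tacropk:::vpc_bins(tad, n_bins = 2, min_per_bin = 20),
                 "merging bin")
  expect_equal(length(unique(bins)), 1L)
})

test_that("simulated replicates have the model's dispersion", {
  fit <- fx("fit19")
  sims <- tacropk:::simulate_from_fit(fit, n_sim = 400, seed = 9)
  expect_equal(dim(sims), c(fit$n_obs, 400L))
  # per-observation simulation means track the population prediction within
  # the lognormal-IIV inflation; crude sanity bound only
  pred <- tacropk:::fit_predictions(fit)$pred
  expect_gt(cor(rowMeans(sims), pred), 0.98)
})
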