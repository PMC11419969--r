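# Synthetic cohort generator: reproducibility, study-like structure,
# covariate marginals and the recovery-experiment report contract.

test_that("cohorts are bit-reproducible from the seed", {
  c1 <- generate_cohort(10, seed = 5)
  c2 <- generate_cohort(10, seed = 5)
  expect_identical(as.data.frame(c1$data), as.data.frame(c2$data))
  c3 <- generate_cohort(10, seed = 6)
  expect_false(identical(as.data.frame(c1$data), as.data.frame(c3$data)))
})

test_that("default cohorts have the study-like shape", {
  coh <- generate_cohort(seed = 1)
  expect_s3_class(coh$data, "pk_dataset")
  expect_equal(length(unique(coh$data$ID)), 19)
  # observation total close to the 167 of the emulated study
  for (s in 1:5) {
    n_obs <- n_observations(generate_cohort(seed = s)$data)
    expect_gte(n_obs, 150)
    expect_lte(n_obs, 185)
  }
  per_subj <- table(coh$data$ID[coh$data$EVID == 0])
  expect_true(all(per_subj >= 2))
  # q12h dosing at 0.25 mg increments
  doses <- coh$data[coh$data$EVID == 1, ]
  expect_true(all(abs(doses$AMT * 4 - round(doses$AMT * 4)) < 1e-9))
  expect_true(all(diff(doses$TIME[doses$ID == 1]) == 12))
})

test_that("genotype columns are emitted but have no generating effect", {
  coh <- generate_cohort(12, seed = 8)
  expect_true(all(c("CYP3A5", "CYP2C19") %in% colnames(coh$data)))
  expect_true(all(coh$data$CYP3A5 %in% c("*1/*1", "*1/*3", "*3/*3")))
  expect_true(all(coh$data$CYP2C19 %in% c("NM", "IM", "PM")))
  # constant within subject
  for (col in c("CYP3A5", "CYP2C19"))
    expect_true(all(tapply(coh$data[[col]], coh$data$ID,
                           function(x) length(unique(x))) == 1))
  # no generating effect: the truth object carries no genotype parameter and
  # concentrations are fully determined by dose, etas and CVRC/CREA
  expect_false(any(grepl("cyp", tolower(names(unlist(coh$truth))))))
})

test_that("the titration hook varies the dose schedule without other changes", {
  halve <- function(subject, day, dose_mg) if (day >= 8) dose_mg / 2 else dose_mg
  c0 <- generate_cohort(6, seed = 13)
  c1 <- generate_cohort(6, seed = 13, titration = halve)
  d1 <- c1$data[c1$data$EVID == 1 & c1$data$ID == 1, ]
  base <- c0$truth$subjects[[1]]$dose_mg
  expect_equal(d1$AMT[d1$TIME < 24 * 7], rep(base, sum(d1$TIME < 24 * 7)))
  expect_equal(unique(d1$AMT[d1$TIME >= 24 * 7]),
               round(base / 2 / 0.25) * 0.25)
  expect_true(c1$truth$settings$titrated)
  expect_equal(c1$truth$subjects[[1]]$dose_schedule, d1$AMT)
  # an identity hook reproduces the static path (same RNG stream, same
  # kinetics up to the linearity refactoring of the superposition)
  cid <- generate_cohort(6, seed = 13, titration = function(s, d, m) m)
  expect_equal(cid$data$DV, c0$data$DV, tolerance = 1e-12)
  # sampling times and covariates are untouched by the hook
  expect_identical(c1$data$TIME, c0$data$TIME)
  expect_identical(c1$data$CVRC, c0$data$CVRC)
  expect_error(generate_cohort(4, titration = function(s, d, m) -1),
               "non-negative")
  expect_error(generate_cohort(4, titration = 3), "function")
})

test_that("generated datasets pass validation across 100 seeds", {
  # pk_dataset() runs the full event-record validation inside the generator;
  # a smaller cohort keeps this sweep fast without changing the code path
  for (s in 1:100)
    expect_s3_class(generate_cohort(5, seed = s)$data, "pk_dataset")
})

test_that("generated covariates reproduce the observed marginals", {
  coh <- generate_cohort(400, seed = 2)
  obs <- coh$data[coh$data$EVID == 0, ]
  # zero-inflated voriconazole: median 0, upper quartile ~0.5, capped at 3.38
  expect_equal(median(obs$CVRC), 0)
  q3 <- quantile(obs$CVRC, 0.75, names = FALSE)
  expect_gt(q3, 0.2)
  expect_lt(q3, 1.2)
  expect_lte(max(obs$CVRC), 3.38)
  # every subject has both on- and off-episode visits identified by truth
  ep <- vapply(coh$truth$subjects, function(s) s$vrc_episode[1], 0)
  expect_true(all(ep >= 1 & ep <= 15))
  # creatinine lognormal around 237
  med_crea <- median(obs$CREA)
  expect_gt(med_crea, 237 * 0.75)
  expect_lt(med_crea, 237 / 0.75)
  # per-subject dose median near 3 mg
  dose <- vapply(coh$truth$subjects, function(s) s$dose_mg, 0)
  expect_gt(median(dose), 2)
  expect_lt(median(dose), 4)
})

test_that("the truth object regenerates its cohort and serializes", {
  coh <- generate_cohort(6, seed = 9)
  tr <- coh$truth
  expect_s3_class(tr, "cohort_truth")
  expect_equal(tr$seed, 9)
  expect_length(tr$subjects, 6)
  # observed DV = true concentration + residual, so they correlate strongly
  s1 <- tr$subjects[[1]]
  dv1 <- coh$data$DV[coh$data$ID == 1 & coh$data$EVID == 0]
  expect_equal(length(s1$true_conc), length(dv1))
  expect_lt(max(abs(dv1 - s1$true_conc)), 5 * tr$ranef$sigma_add)

  path <- withr::local_tempfile(fileext = ".json")
  write_cohort_truth(tr, path)
  j <- jsonlite::fromJSON(path)
  expect_equal(j$seed, 9)
  expect_equal(j$typical$v_f, 2690)
})

test_that("truncation clamps negatives and counts them", {
  t0 <- final_model_parameters()
  t0$ranef <- random_effect_spec(0.02, 0.16, 30)  # huge noise forces negatives
  coh <- generate_cohort(10, truth = t0, seed = 3, truncate = TRUE)
  expect_true(all(coh$data$DV[coh$data$EVID == 0] >= 0))
  expect_gt(coh$truth$n_truncated, 0)
})

test_that("generator validates its arguments", {
  expect_error(generate_cohort(1), "'n_subjects'")
  expect_error(generate_cohort(5, mean_obs = 100), "infeasible")
})

test_that("recovery_experiment tabulates per-replicate estimation error", {
  rec <- recovery_experiment(
    n_subjects = 10, n_replicates = 2, seed = 50,
    fit_args = list(n_starts = 1, se = FALSE,
                    control = list(rel.tol = 1e-5)))
  expect_s3_class(rec, "pk_recovery")
  expect_identical(rec$n_failed, 0L)
  r <- rec$report
  expect_setequal(unique(r$replicate), 1:2)
  expect_setequal(unique(r$parameter),
                  c("tvV", "tvCL", "theta_VRC_V", "theta_VRC_CL",
                    "theta_CREA_V", "omega2_V", "omega2_CL", "sigma_add"))
  expect_equal(r$error, r$estimate - r$true)
  expect_equal(r$rel_error, r$error / r$true)
  s <- rec$summary
  expect_true(all(c("median_abs_rel_error", "bias", "rmse") %in% colnames(s)))
  expect_true(all(is.finite(s$rmse)))
  expect_output(print(rec), "Parameter recovery")
  expect_error(recovery_experiment(n_replicates = 0), "'n_replicates'")
})
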