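# Monte Carlo trough simulation, PTA, dose recommendation, heatmaps and the
# reference-table calibration utilities.

truth <- final_model_parameters()

test_that("simulate_troughs draws reproducible IIV-only troughs", {
  s1 <- simulate_troughs(truth, day3_regimen(3), n = 300, seed = 8)
  s2 <- simulate_troughs(truth, day3_regimen(3), n = 300, seed = 8)
  expect_identical(s1$sample, s2$sample)
  expect_length(s1$sample, 300)
  expect_equal(s1$mean, mean(s1$sample))
  expect_equal(s1$sd, sd(s1$sample))
  expect_true(all(s1$sample > 0))
  # residual error is excluded: with zero IIV the sample is deterministic
  t0 <- truth
  t0$ranef <- random_effect_spec(0, 0, 3.5)
  s0 <- simulate_troughs(t0, day3_regimen(3), n = 50, seed = 8)
  expect_equal(unname(diff(range(s0$sample))), 0)
  expect_equal(s0$sample[1],
               pk_concentration(truth$typical, day3_regimen(3), 72))
  expect_error(simulate_troughs(truth, n = 0), "'n'")
  expect_error(simulate_troughs(truth, n = 10, eta = matrix(0, 3, 2)),
               "n x 2")
})

test_that("zero dose yields zero troughs and zero PTA", {
  s <- simulate_troughs(truth, day3_regimen(0), n = 20, seed = 1)
  expect_equal(s$sample, rep(0, 20))
  pt <- pta_table(truth, doses = c(0, 3), c_vrc = 0, n = 50, seed = 1)
  expect_equal(pt$table$pta[pt$table$dose_mg == 0], 0)
})

test_that("common random numbers make dose scaling exact", {
  set.seed(99)
  eta <- cbind(rnorm(400, 0, sqrt(0.02)), rnorm(400, 0, sqrt(0.16)))
  s1 <- simulate_troughs(truth, day3_regimen(1), n = 400, eta = eta)
  s2 <- simulate_troughs(truth, day3_regimen(2), n = 400, eta = eta)
  s55 <- simulate_troughs(truth, day3_regimen(5.5), n = 400, eta = eta)
  s05 <- simulate_troughs(truth, day3_regimen(0.5), n = 400, eta = eta)
  expect_equal(s2$sample, 2 * s1$sample, tolerance = 1e-12)
  expect_equal(s2$mean / s1$mean, 2, tolerance = 1e-12)
  expect_equal(s55$mean / s05$mean, 11, tolerance = 1e-12)
})

test_that("pta computes the closed-interval attainment percentage", {
  expect_equal(pta(c(4, 6, 7, 12)), 50)
  expect_equal(pta(c(5, 10), 5, 10), 100)   # closed interval
  expect_equal(pta(1:4 / 10), 0)
  s <- simulate_troughs(truth, day3_regimen(3), n = 100, seed = 1)
  expect_equal(pta(s), pta(s$sample))
  expect_error(pta(numeric(0)), "non-empty")
  expect_error(pta(c(6, 7), lo = 10, hi = 5), "'lo'")
})

test_that("pta_table sweeps one covariate with shared random numbers", {
  pt <- pta_table(truth, doses = c(1, 3), c_vrc = c(0, 2), n = 300, seed = 2)
  t <- pt$table
  expect_equal(nrow(t), 4)
  expect_equal(colnames(t), c("covariate", "level", "dose_mg", "mean_trough",
                              "sd_trough", "pta", "recommended"))
  expect_true(all(t$covariate == "c_vrc"))
  expect_equal(t$recommended, t$pta >= 70)
  # voriconazole inhibits clearance: same dose, higher C_VRC, higher trough
  expect_gt(t$mean_trough[t$level == 2 & t$dose_mg == 3],
            t$mean_trough[t$level == 0 & t$dose_mg == 3])
  # CRN dose linearity within a level
  expect_equal(t$mean_trough[t$level == 0 & t$dose_mg == 3],
               3 * t$mean_trough[t$level == 0 & t$dose_mg == 1],
               tolerance = 1e-12)
  # reproducible
  pt2 <- pta_table(truth, doses = c(1, 3), c_vrc = c(0, 2), n = 300, seed = 2)
  expect_identical(t, pt2$table)
  # creatinine sweep flips the swept covariate
  ptc <- pta_table(truth, doses = 3, c_vrc = 0, crea = c(100, 400), n = 50)
  expect_true(all(ptc$table$covariate == "crea"))
  expect_error(pta_table(truth, c_vrc = c(0, 1), crea = c(100, 200)),
               "not both")
  expect_error(pta_table(truth, doses = c(-1, 2)), "'doses'")
})

test_that("recommend_dose returns minimal attaining doses per level", {
  pt <- pta_table(truth, doses = seq(0.5, 5.5, 0.5), c_vrc = c(0, 5),
                  n = 500, seed = 4)
  rec <- recommend_dose(pt, threshold = 70)
  expect_equal(rec$level, c(0, 5))
  for (i in 1:2) {
    lev_rows <- pt$table[pt$table$level == rec$level[i], ]
    ok <- lev_rows$dose_mg[lev_rows$pta >= 70]
    expect_equal(rec$min_dose[i], if (length(ok)) min(ok) else NA_real_)
    expect_equal(rec$best_pta[i], max(lev_rows$pta))
  }
  # an unattainable threshold gives an empty set, not an error
  rec100 <- recommend_dose(pt, threshold = 100)
  expect_true(all(is.na(rec100$min_dose)) || any(pt$table$pta == 100))
  expect_error(recommend_dose(pt, threshold = 0), "'threshold'")
  expect_error(recommend_dose(pt, threshold = 101), "'threshold'")
})

test_that("heatmap matrix round trips losslessly", {
  pt <- pta_table(truth, doses = c(1, 2, 3), c_vrc = c(0, 1), n = 100,
                  seed = 5)
  m <- heatmap_table(pt)
  expect_equal(dim(m), c(2L, 3L))
  expect_equal(attr(m, "covariate"), "c_vrc")
  long <- pta_from_heatmap(m)
  expect_equal(long$pta, pt$table$pta)
  expect_equal(long$level, pt$table$level)
  expect_equal(long$dose_mg, pt$table$dose_mg)

  path <- withr::local_tempfile(fileext = ".csv")
  write_heatmap(m, path)
  m2 <- read_heatmap(path)
  expect_equal(as.vector(m2), as.vector(m))
  expect_equal(rownames(m2), rownames(m))
  expect_equal(colnames(m2), colnames(m))
})

test_that("pta_from_summary matches the moment-matched lognormal", {
  # printed cell checked in the acceptance suite; here the mechanism
  expect_equal(pta_from_summary(7, 0), 100)     # degenerate: inside range
  expect_equal(pta_from_summary(12, 0), 0)      # degenerate: outside
  p <- pta_from_summary(6.77, 1.72, n = 2e4, seed = 2)
  expect_gt(p, 75)
  expect_lt(p, 88)
  expect_error(pta_from_summary(-1, 1), "'mean'")
})

test_that("packaged reference tables load with the published anchor cells", {
  rv <- reference_troughs("c_vrc")
  expect_equal(sort(unique(rv$dose_mg)), seq(0.5, 5.5, by = 0.5))
  expect_equal(length(unique(rv$c_vrc)), 15)
  expect_equal(rv$mean_trough[rv$c_vrc == 5 & rv$dose_mg == 1.5], 6.77)
  expect_equal(rv$sd_trough[rv$c_vrc == 5 & rv$dose_mg == 1.5], 1.72)

  rc <- reference_troughs("crea")
  expect_equal(rc$mean_trough[rc$crea == 40 & rc$dose_mg == 5], 5.87)
  expect_equal(rc$sd_trough[rc$crea == 40 & rc$dose_mg == 5], 1.21)
  expect_true(all(rv$mean_trough > 0) && all(rc$mean_trough > 0))
})

test_that("covariate-family calibration reports per-family deviations", {
  cal <- calibrate_covariate_family("c_vrc", grid = seq(-0.6, 0, by = 0.05))
  s <- cal$summary
  expect_setequal(s$family, c("exponential", "power_shift", "power_centered"))
  expect_true(all(is.finite(s$rmse_log_ratio) & s$rmse_log_ratio >= 0))
  expect_true(all(s$max_abs_log_error >= s$rmse_log_ratio))
  expect_true(all(cal$detail$printed_ratio > 0 & cal$detail$model_ratio > 0))

  cal_c <- calibrate_covariate_family("crea", grid = seq(-0.8, 0, by = 0.05))
  expect_equal(cal_c$summary$family, "power")
  expect_true(is.na(cal_c$summary$theta_cl))
  expect_true(is.finite(cal_c$summary$rmse_log_ratio))
})

test_that("compare_to_reference quantifies the printed-table deviation", {
  ref <- reference_troughs("c_vrc")
  ref <- ref[ref$c_vrc %in% c(0, 5) & ref$dose_mg %in% c(1.5, 3), ]
  cmp <- compare_to_reference(truth, "c_vrc", reference = ref, n = 200,
                              seed = 1)
  expect_equal(nrow(cmp$cells), 4)
  expect_true(all(is.finite(cmp$cells$ratio) & cmp$cells$ratio > 0))
  expect_true(is.finite(cmp$summary$median_abs_log_ratio))
  expect_gte(cmp$summary$max_abs_log_ratio, cmp$summary$median_abs_log_ratio)
  expect_output(print(cmp), "median")
})
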