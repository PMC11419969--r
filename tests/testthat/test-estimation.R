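# Laplace marginal likelihood: degenerate closed forms, dense-quadrature
# oracle, invariances, determinism, information criteria and shrinkage.

test_that("without random effects the OFV is the exact Gaussian -2 loglik", {
  truth <- final_model_parameters()
  truth$ranef <- random_effect_spec(0, 0, 3.5)
  coh <- generate_cohort(6, truth = truth, seed = 21)
  spec <- model_spec(effects = c("vrc_v", "vrc_cl", "crea_v"),
                     re_v = FALSE, re_cl = FALSE)
  sigma <- 2.8
  par <- pack_params(spec, tvV = 2500, tvCL = 40,
                     theta = c(vrc_v = -0.2, vrc_cl = -0.28, crea_v = -0.4),
                     sigma_a = sigma)
  ofv <- neg2_marginal_loglik(spec, par, coh$data)

  # independent evaluation: per-observation prediction through the public
  # structural API, then the Gaussian -2 log likelihood
  obs <- coh$data[coh$data$EVID == 0, ]
  expected <- 0
  for (i in seq_len(nrow(obs))) {
    sub <- coh$data[coh$data$ID == obs$ID[i] & coh$data$EVID == 1, ]
    adj <- apply_covariates(structural_params(8.39, 2500, 40),
                            covariate_effects(-0.2, -0.28, -0.4),
                            subject_covariates(obs$CVRC[i], obs$CREA[i]))
    reg <- dosing_regimen(sub$AMT[1], tau_h = 12,
                          n_doses = sum(sub$TIME <= obs$TIME[i]))
    f <- pk_concentration(adj, reg, obs$TIME[i])
    expected <- expected - 2 * dnorm(obs$DV[i], f, sigma, log = TRUE)
  }
  expect_equal(as.numeric(ofv), expected, tolerance = 1e-9)
})

test_that("Laplace OFV is within 0.5 of dense Gauss-Legendre quadrature", {
  coh <- generate_cohort(4, seed = 7, mean_obs = 5)
  spec <- model_spec(effects = c("vrc_v", "vrc_cl", "crea_v"))
  for (par in list(
    pack_params(spec, 2690, 42.87,
                theta = c(vrc_v = -0.2, vrc_cl = -0.28, crea_v = -0.4),
                omega2_v = 0.02, omega2_cl = 0.16, sigma_a = 3.5),
    pack_params(spec, 3500, 30, theta = c(vrc_v = -0.1),
                omega2_v = 0.05, omega2_cl = 0.3, sigma_a = 2.5))) {
    lap <- as.numeric(neg2_marginal_loglik(spec, par, coh$data))
    quad <- quad_ofv(spec, par, coh$data)
    expect_lt(abs(lap - quad), 0.5)
  }
})

test_that("OFV is invariant to subject relabelling and row order", {
  coh <- generate_cohort(6, seed = 9)
  spec <- model_spec(effects = "vrc_cl")
  par <- pack_params(spec, 2690, 42.87, theta = c(vrc_cl = -0.28))
  ofv1 <- as.numeric(neg2_marginal_loglik(spec, par, coh$data))

  d2 <- as.data.frame(coh$data)
  d2$ID <- 100 - d2$ID                      # relabel
  d2 <- d2[order(d2$ID, d2$TIME, -d2$EVID), ]   # reorder subjects
  ofv2 <- as.numeric(neg2_marginal_loglik(spec, par, pk_dataset(d2)))
  expect_equal(ofv1, ofv2, tolerance = 1e-10)
})

test_that("OFV is invariant to a common time shift of one subject", {
  coh <- generate_cohort(5, seed = 12)
  spec <- model_spec()
  par <- pack_params(spec, 2690, 42.87)
  ofv1 <- as.numeric(neg2_marginal_loglik(spec, par, coh$data))
  d2 <- as.data.frame(coh$data)
  d2$TIME[d2$ID == 3] <- d2$TIME[d2$ID == 3] + 24  # same history, new clock
  ofv2 <- as.numeric(neg2_marginal_loglik(spec, par, pk_dataset(d2)))
  expect_equal(ofv1, ofv2, tolerance = 1e-10)
})

test_that("OFV evaluation is deterministic and carries diagnostics", {
  coh <- generate_cohort(5, seed = 14)
  spec <- model_spec()
  par <- pack_params(spec, 2690, 42.87)
  o1 <- neg2_marginal_loglik(spec, par, coh$data)
  o2 <- neg2_marginal_loglik(spec, par, coh$data)
  expect_identical(as.numeric(o1), as.numeric(o2))
  expect_equal(dim(attr(o1, "etas")), c(5L, 2L))
  expect_true(all(attr(o1, "converged")))
  expect_identical(attr(o1, "n_failed"), 0L)
})

test_that("the Gauss-Newton Hessian variant stays close to the exact one", {
  coh <- generate_cohort(5, seed = 15)
  spec <- model_spec(effects = "crea_v")
  par <- pack_params(spec, 2690, 42.87, theta = c(crea_v = -0.4))
  exact <- as.numeric(neg2_marginal_loglik(spec, par, coh$data,
                                           hessian = "exact"))
  gn <- as.numeric(neg2_marginal_loglik(spec, par, coh$data, hessian = "gn"))
  expect_lt(abs(exact - gn), 1.0)
  expect_false(identical(exact, gn))
})

test_that("information criteria implement their definitions and validate", {
  expect_equal(aic(990.2152, 7), 1004.2152)
  expect_equal(bic(990.2152, 7, 167), 990.2152 + 7 * log(167))
  expect_error(aic(100, -1), "'k'")
  expect_error(bic(100, 2, 0), "'n_obs'")
})

test_that("shrinkage implements the SD-ratio definition", {
  set.seed(4)
  e <- rnorm(200, 0, 0.3)
  expect_equal(shrinkage(e, 0.09), 100 * (1 - sd(e) / 0.3))
  expect_equal(shrinkage(c(0.1, -0.1), 0.01), 100 * (1 - sd(c(0.1, -0.1)) / 0.1))
  expect_error(shrinkage(0.1, 0.01), "at least 2")
  expect_error(shrinkage(e, 0), "omega2")
})

test_that("the generating parameters beat a doubled clearance on OFV", {
  coh <- fx("cohort19")
  spec <- model_spec(effects = c("vrc_v", "vrc_cl", "crea_v"))
  th <- c(vrc_v = -0.2, vrc_cl = -0.28, crea_v = -0.4)
  at_truth <- as.numeric(neg2_marginal_loglik(
    spec, pack_params(spec, 2690, 42.87, theta = th,
                      omega2_v = 0.02, omega2_cl = 0.16, sigma_a = 3.5),
    coh$data))
  cl_doubled <- as.numeric(neg2_marginal_loglik(
    spec, pack_params(spec, 2690, 2 * 42.87, theta = th,
                      omega2_v = 0.02, omega2_cl = 0.16, sigma_a = 3.5),
    coh$data))
  expect_lt(at_truth, cl_doubled)
})
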