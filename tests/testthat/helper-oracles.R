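# Independent numerical oracles for the test suite.
#
# - ode_conc(): concentrations from the one-compartment oral ODE system
#   (gut + central compartment) solved numerically with deSolve, independent
#   of the closed-form superposition code under test.
# - quad_ofv(): -2 log marginal likelihood by dense Gauss-Legendre
#   quadrature over the two random effects, independent of the Laplace
#   approximation machinery under test (concentrations via the already
#   ODE-verified closed form, likelihood assembled from scratch).

ode_conc <- function(params, regimen, times) {
  rhs <- function(t, y, p) list(c(-p$ka * y[1], p$ka * y[1] - p$ke * y[2]))
  td <- dose_times(regimen)
  events <- data.frame(var = "gut", time = td, value = regimen$dose_mg,
                       method = "add")
  p <- list(ka = params$ka, ke = params$cl_f / params$v_f)
  grid <- sort(unique(c(0, td, times)))
  sol <- deSolve::lsoda(c(gut = 0, central = 0), grid, rhs, p,
                        events = list(data = events),
                        rtol = 1e-11, atol = 1e-13)
  conc <- 1000 * sol[, "central"] / params$v_f
  conc[match(times, sol[, "time"])]
}

# Dense-quadrature OFV for a spec with both random effects and additive
# residual error. Per subject, the marginal likelihood integral over
# eta = (eta_V, eta_CL) is evaluated by nested adaptive quadrature
# (stats::integrate), with the integrand rescaled by its maximum over a
# coarse grid to avoid underflow. `width` bounds the integration box in
# random-effect SDs.
quad_ofv <- function(spec, par, data, width = 8) {
  stopifnot(spec$re_v, spec$re_cl, spec$residual == "additive")
  tv_v <- exp(par[["lV"]])
  tv_cl <- exp(par[["lCL"]])
  ka <- if (is.na(spec$ka_fixed)) exp(par[["lKa"]]) else spec$ka_fixed
  th <- function(key) {
    nm <- paste0("th_", key)
    if (nm %in% names(par)) par[[nm]] else 0
  }
  sv <- sqrt(exp(par[["lo2_v"]]))
  scl <- sqrt(exp(par[["lo2_cl"]]))
  sig <- exp(par[["lsig_a"]])

  cvrc_fac <- function(x, theta) {
    switch(spec$vrc_form,
           exponential = exp(theta * x),
           power_shift = (x + 1)^theta,
           power_centered = (x / 0.5)^theta)
  }

  total <- 0
  for (id in unique(data$ID)) {
    d <- data[data$ID == id, , drop = FALSE]
    obs <- d[d$EVID == 0, , drop = FALSE]
    doses <- d[d$EVID == 1 & !is.na(d$AMT) & d$AMT > 0, , drop = FALSE]
    fv <- cvrc_fac(obs$CVRC, th("vrc_v")) *
      (obs$CREA / spec$crea_ref)^th("crea_v")
    fcl <- cvrc_fac(obs$CVRC, th("vrc_cl")) *
      (obs$CREA / spec$crea_ref)^th("crea_cl")
    loglik <- function(ev, ecl) {
      f <- numeric(nrow(obs))
      for (j in seq_len(nrow(obs))) {
        v <- tv_v * fv[j] * exp(ev)
        cl <- tv_cl * fcl[j] * exp(ecl)
        ke <- cl / v
        dt <- obs$TIME[j] - doses$TIME
        dt <- dt[dt >= 0]
        amt <- doses$AMT[obs$TIME[j] - doses$TIME >= 0]
        f[j] <- sum(1000 * amt * ka / (v * (ka - ke)) *
                      (exp(-ke * dt) - exp(-ka * dt)))
      }
      sum(stats::dnorm(obs$DV, f, sig, log = TRUE))
    }
    ljoint <- function(ev, ecl) {
      loglik(ev, ecl) + stats::dnorm(ev, 0, sv, log = TRUE) +
        stats::dnorm(ecl, 0, scl, log = TRUE)
    }
    # underflow guard: offset by the coarse-grid maximum of the log joint
    grid_v <- sv * seq(-width, width, length.out = 41)
    grid_cl <- scl * seq(-width, width, length.out = 41)
    C <- max(outer(grid_v, grid_cl, Vectorize(ljoint)))
    inner <- function(ev) {
      stats::integrate(function(ecl_vec)
                         vapply(ecl_vec,
                                function(ecl) exp(ljoint(ev, ecl) - C), 0),
                       lower = -width * scl, upper = width * scl,
                       rel.tol = 1e-9, abs.tol = 0)$value
    }
    I <- stats::integrate(function(ev_vec) vapply(ev_vec, inner, 0),
                          lower = -width * sv, upper = width * sv,
                          rel.tol = 1e-8, abs.tol = 0)$value
    total <- total - 2 * (C + log(I))
  }
  total
}

# Shared fixtures, computed once per test run (testthat sources helpers into
# an environment that persists across test files).
fx <- local({
  cache <- new.env(parent = emptyenv())
  function(name) {
    if (!is.null(cache[[name]])) return(cache[[name]])
    cache[[name]] <- switch(name,
      cohort19 = generate_cohort(19, seed = 11),
      fit19 = fit_pk(model_spec(effects = c("vrc_v", "vrc_cl", "crea_v")),
                     fx("cohort19")$data, n_starts = 2, se = TRUE,
                     control = list(rel.tol = 1e-6)),
      stop("unknown fixture: ", name))
    cache[[name]]
  }
})

# Minimal hand-written valid event dataset (2 subjects, q12h dosing).
toy_df <- function() {
  data.frame(
    ID = c(1, 1, 1, 2, 2, 2),
    TIME = c(0, 12, 13, 0, 12, 23.5),
    AMT = c(3, 3, NA, 2, 2, NA),
    DV = c(NA, NA, 6.1, NA, NA, 4.2),
    EVID = c(1L, 1L, 0L, 1L, 1L, 0L),
    CVRC = c(0, 0, 0.8, 0, 0, 0),
    CREA = c(237, 237, 250, 200, 200, 210))
}
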