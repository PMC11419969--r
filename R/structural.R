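# One-compartment oral model with first-order absorption and elimination,
# evaluated in closed form by superposition over the dosing history.

# Single place where mg/L is converted to ng/mL (dose mg, V/F in L).
MGL_TO_NGML <- 1000

# Relative tolerance below which ka and ke are treated as coincident and the
# analytic limit of the absorption term is used instead.
KA_KE_REL_TOL <- 1e-8

#' Structural pharmacokinetic parameters
#'
#' Typical (or individual) parameters of the one-compartment oral model:
#' first-order absorption rate constant `ka` (1/h), apparent volume of
#' distribution `v_f` (V/F, litres) and apparent oral clearance `cl_f`
#' (CL/F, L/h). The elimination rate constant is `ke = cl_f / v_f`.
#'
#' @param ka Absorption rate constant, 1/h. Strictly positive.
#' @param v_f Apparent volume of distribution V/F, L. Strictly positive.
#' @param cl_f Apparent oral clearance CL/F, L/h. Strictly positive.
#' @return An object of class `pk_params`.
#' @examples
#' structural_params(ka = 8.39, v_f = 2690, cl_f = 42.87)
#' @export
structural_params <- function(ka, v_f, cl_f) {
  stopifnot(is.numeric(ka), is.numeric(v_f), is.numeric(cl_f),
            length(ka) == 1, length(v_f) == 1, length(cl_f) == 1)
  if (!is.finite(ka) || ka <= 0) stop("'ka' must be strictly positive")
  if (!is.finite(v_f) || v_f <= 0) stop("'v_f' must be strictly positive")
  if (!is.finite(cl_f) || cl_f <= 0) stop("'cl_f' must be strictly positive")
  structure(list(ka = ka, v_f = v_f, cl_f = cl_f), class = "pk_params")
}

#' @export
print.pk_params <- function(x, ...) {
  cat(sprintf("One-compartment oral PK parameters:\n  Ka   %.4g 1/h\n  V/F  %.4g L\n  CL/F %.4g L/h  (ke = %.4g 1/h)\n",
              x$ka, x$v_f, x$cl_f, x$cl_f / x$v_f))
  invisible(x)
}

#' Multiple-dose regimen
#'
#' @param dose_mg Dose per administration, mg (>= 0).
#' @param tau_h Inter-dose interval, h (> 0). Default 12 (q12h dosing).
#' @param n_doses Number of administrations (>= 1).
#' @param t_first Clock time of the first dose, h. Default 0.
#' @return An object of class `pk_regimen`.
#' @export
dosing_regimen <- function(dose_mg, tau_h = 12, n_doses = 1, t_first = 0) {
  stopifnot(length(dose_mg) == 1, length(tau_h) == 1,
            length(n_doses) == 1, length(t_first) == 1)
  if (!is.finite(dose_mg) || dose_mg < 0) stop("'dose_mg' must be >= 0")
  if (!is.finite(tau_h) || tau_h <= 0) stop("'tau_h' must be > 0")
  if (!is.finite(n_doses) || n_doses < 1 || n_doses != round(n_doses))
    stop("'n_doses' must be an integer >= 1")
  structure(list(dose_mg = dose_mg, tau_h = tau_h,
                 n_doses = as.integer(n_doses), t_first = t_first),
            class = "pk_regimen")
}

#' Dose times of a regimen
#' @param regimen A `pk_regimen`.
#' @return Numeric vector of administration times, h.
#' @export
dose_times <- function(regimen) {
  regimen$t_first + (seq_len(regimen$n_doses) - 1) * regimen$tau_h
}

# Concentration increment (ng/mL) of unit analysis: per-dose first-order
# absorption term for elapsed times dt >= 0 (vector), amount amt (mg).
# Handles the ka ~ ke degeneracy by its analytic limit amt*ka*dt*exp(-ka*dt)/V.
dose_term <- function(amt, ka, v_f, ke, dt) {
  out <- numeric(length(dt))
  pos <- dt >= 0
  if (!any(pos)) return(out)
  d <- dt[pos]
  if (abs(ka - ke) < KA_KE_REL_TOL * ka) {
    out[pos] <- MGL_TO_NGML * amt * ka * d * exp(-ka * d) / v_f
  } else {
    out[pos] <- MGL_TO_NGML * amt * ka / (v_f * (ka - ke)) *
      (exp(-ke * d) - exp(-ka * d))
  }
  out
}

#' Predicted concentration under a multiple-dose regimen
#'
#' Closed-form concentration (ng/mL) of the one-compartment oral model,
#' superposed over every dose administered at or before `t`. With dose in mg
#' and V/F in litres the model concentration is in mg/L; it is returned as
#' ng/mL (factor 1000).
#'
#' @param params A `pk_params` object (or list with ka, v_f, cl_f).
#' @param regimen A `pk_regimen` object.
#' @param t Time(s) since the clock origin, h (>= 0 returns the profile;
#'   values before the first dose return 0).
#' @return Numeric vector of concentrations, ng/mL (never negative).
#' @examples
#' p <- structural_params(8.39, 2690, 42.87)
#' r <- dosing_regimen(dose_mg = 3, tau_h = 12, n_doses = 6)
#' pk_concentration(p, r, t = 72)  # day-3 trough
#' @export
pk_concentration <- function(params, regimen, t) {
  stopifnot(is.numeric(t))
  if (any(t < 0)) stop("'t' must be non-negative")
  if (regimen$dose_mg == 0) return(numeric(length(t)))
  ke <- params$cl_f / params$v_f
  td <- dose_times(regimen)
  out <- numeric(length(t))
  for (tk in td) {
    out <- out + dose_term(regimen$dose_mg, params$ka, params$v_f, ke, t - tk)
  }
  pmax(out, 0)
}

#' Steady-state trough concentration
#'
#' Geometric-series closed form of the pre-dose (trough) concentration at
#' steady state under a fixed-interval regimen.
#'
#' @inheritParams pk_concentration
#' @return Steady-state trough, ng/mL.
#' @export
steady_state_trough <- function(params, regimen) {
  ke <- params$cl_f / params$v_f
  ka <- params$ka
  tau <- regimen$tau_h
  if (abs(ka - ke) < KA_KE_REL_TOL * ka)
    stop("steady-state trough closed form is degenerate at ka == ke")
  acc <- function(k) exp(-k * tau) / (1 - exp(-k * tau))
  MGL_TO_NGML * regimen$dose_mg * ka / (params$v_f * (ka - ke)) *
    (acc(ke) - acc(ka))
}

#' Individual parameters from log-scale random effects
#'
#' Applies lognormal inter-individual variability:
#' `V/F_i = V/F * exp(eta_v)`, `CL/F_i = CL/F * exp(eta_cl)`. `ka` is shared.
#' Because the random effects have median 0, the median individual parameter
#' equals the typical value.
#'
#' @param typical A `pk_params` of (covariate-adjusted) typical values.
#' @param eta_v,eta_cl Log-scale random effects.
#' @return A `pk_params` of individual parameters.
#' @export
individual_params <- function(typical, eta_v = 0, eta_cl = 0) {
  structural_params(ka = typical$ka,
                    v_f = typical$v_f * exp(eta_v),
                    cl_f = typical$cl_f * exp(eta_cl))
}

#' Simulated observation under additive residual error
#'
#' `observed = conc_true + eps`, `eps ~ N(0, sigma_add^2)`. Negative simulated
#' observations are retained by default (the additive Gaussian model implies
#' them and the estimator tolerates them); set `truncate = TRUE` to clamp at
#' zero (the result then carries a `truncated` attribute with the count).
#'
#' @param conc_true True concentration(s), ng/mL (>= 0).
#' @param sigma_add Additive residual SD, ng/mL (> 0).
#' @param truncate Clamp negative draws to zero? Default FALSE.
#' @return Observed concentration(s), ng/mL. Uses the current RNG stream;
#'   seed the session (or the calling generator) for reproducibility.
#' @export
predict_observation <- function(conc_true, sigma_add, truncate = FALSE) {
  if (any(conc_true < 0)) stop("'conc_true' must be non-negative")
  if (!is.finite(sigma_add) || sigma_add <= 0) stop("'sigma_add' must be > 0")
  obs <- conc_true + stats::rnorm(length(conc_true), 0, sigma_add)
  if (truncate) {
    n_neg <- sum(obs < 0)
    obs <- pmax(obs, 0)
    attr(obs, "truncated") <- n_neg
  }
  obs
}
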