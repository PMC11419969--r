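# Covariate scaling of the typical parameters. Voriconazole concentration
# (C_VRC, ug/mL) acts on both CL/F and V/F; serum creatinine (CREA, umol/L)
# acts on V/F in the default (final) model. The C_VRC functional family is
# pluggable because a pure power law is undefined at the observed median
# C_VRC = 0.

COVARIATE_FORMS <- c("exponential", "power_shift", "power_centered")

#' Covariate effect coefficients
#'
#' Holds the covariate submodel of the final population model: exponents /
#' slopes of voriconazole concentration (C_VRC) on V/F and CL/F, and of serum
#' creatinine (CREA) on V/F (optionally CL/F), together with the CREA
#' normalization constant and the functional family used for C_VRC.
#'
#' Families for the C_VRC factor (value `x`, coefficient `theta`):
#' \describe{
#'   \item{exponential}{`exp(theta * x)` — defined on the whole domain
#'     including `x = 0`; the package default.}
#'   \item{power_shift}{`(x + 1)^theta` — shifted power law, defined at 0.}
#'   \item{power_centered}{`(x / ref)^theta` with `ref = 0.5` ug/mL — a pure
#'     power law, undefined at `x = 0`; offered for calibration probing only.}
#' }
#' The CREA factor is always the centered power `(CREA / crea_ref)^theta`.
#'
#' @param theta_vrc_v Coefficient of C_VRC on V/F (final model: -0.20).
#' @param theta_vrc_cl Coefficient of C_VRC on CL/F (final model: -0.28).
#' @param theta_crea_v Exponent of CREA on V/F (final model: -0.40).
#' @param theta_crea_cl Exponent of CREA on CL/F (default 0; the covariate map
#'   is configurable).
#' @param crea_ref CREA normalization constant, umol/L (default 237, the
#'   study-population median).
#' @param form C_VRC functional family; one of
#'   `"exponential"`, `"power_shift"`, `"power_centered"`.
#' @return An object of class `pk_cov_effects`.
#' @export
covariate_effects <- function(theta_vrc_v = 0, theta_vrc_cl = 0,
                              theta_crea_v = 0, theta_crea_cl = 0,
                              crea_ref = 237, form = "exponential") {
  form <- match.arg(form, COVARIATE_FORMS)
  if (!is.finite(crea_ref) || crea_ref <= 0) stop("'crea_ref' must be > 0")
  structure(list(theta_vrc_v = theta_vrc_v, theta_vrc_cl = theta_vrc_cl,
                 theta_crea_v = theta_crea_v, theta_crea_cl = theta_crea_cl,
                 crea_ref = crea_ref, form = form),
            class = "pk_cov_effects")
}

#' Subject covariates
#'
#' @param c_vrc Voriconazole concentration, ug/mL (>= 0).
#' @param crea Serum creatinine, umol/L (> 0).
#' @return An object of class `pk_covariates`.
#' @export
subject_covariates <- function(c_vrc = 0, crea = 237) {
  if (any(!is.finite(c_vrc)) || any(c_vrc < 0)) stop("'c_vrc' must be >= 0")
  if (any(!is.finite(crea)) || any(crea <= 0)) stop("'crea' must be > 0")
  structure(list(c_vrc = c_vrc, crea = crea), class = "pk_covariates")
}

# Multiplicative covariate factor for one covariate value / coefficient.
# Vectorized over `value`.
covariate_factor <- function(value, theta, form, ref = 0.5) {
  switch(form,
         exponential = exp(theta * value),
         power_shift = (value + 1)^theta,
         power_centered = {
           if (any(value <= 0))
             stop("'power_centered' family is undefined at covariate <= 0")
           (value / ref)^theta
         },
         stop("unknown covariate form: ", form))
}

#' Covariate-adjusted typical parameters
#'
#' With the default exponential-C_VRC / centered-power-CREA family:
#' `CL/F = tvCL * exp(theta_vrc_cl * C_VRC) * (CREA/crea_ref)^theta_crea_cl`,
#' `V/F = tvV * exp(theta_vrc_v * C_VRC) * (CREA/crea_ref)^theta_crea_v`,
#' `ka` unchanged. At the reference covariates (C_VRC = 0, CREA = crea_ref)
#' the typical values are returned unchanged.
#'
#' @param typical A `pk_params` of typical values.
#' @param effects A `pk_cov_effects`.
#' @param cov A `pk_covariates` (scalar covariate values).
#' @return A `pk_params` of covariate-adjusted typical values.
#' @examples
#' tv <- structural_params(8.39, 2690, 42.87)
#' eff <- covariate_effects(theta_vrc_v = -0.20, theta_vrc_cl = -0.28,
#'                          theta_crea_v = -0.40)
#' apply_covariates(tv, eff, subject_covariates(c_vrc = 1, crea = 237))
#' @export
apply_covariates <- function(typical, effects, cov) {
  if (any(cov$crea <= 0)) stop("'crea' must be > 0")
  fv <- covariate_factor(cov$c_vrc, effects$theta_vrc_v, effects$form) *
    (cov$crea / effects$crea_ref)^effects$theta_crea_v
  fcl <- covariate_factor(cov$c_vrc, effects$theta_vrc_cl, effects$form) *
    (cov$crea / effects$crea_ref)^effects$theta_crea_cl
  structural_params(ka = typical$ka,
                    v_f = typical$v_f * fv,
                    cl_f = typical$cl_f * fcl)
}

#' Inter-individual and residual variability specification
#'
#' @param omega2_v Variance of the log-scale random effect on V/F (>= 0).
#' @param omega2_cl Variance of the log-scale random effect on CL/F (>= 0).
#' @param sigma_add Additive residual SD, ng/mL (> 0).
#' @return An object of class `pk_ranef_spec`.
#' @export
random_effect_spec <- function(omega2_v = 0.02, omega2_cl = 0.16,
                               sigma_add = 3.50) {
  if (!is.finite(omega2_v) || omega2_v < 0) stop("'omega2_v' must be >= 0")
  if (!is.finite(omega2_cl) || omega2_cl < 0) stop("'omega2_cl' must be >= 0")
  if (!is.finite(sigma_add) || sigma_add <= 0) stop("'sigma_add' must be > 0")
  structure(list(omega2_v = omega2_v, omega2_cl = omega2_cl,
                 sigma_add = sigma_add), class = "pk_ranef_spec")
}

#' Final-model parameter set of the reference analysis
#'
#' Convenience bundle of the published final population estimates: typical
#' structural values (Ka fixed at 8.39 1/h, V/F 2690 L, CL/F 42.87 L/h),
#' covariate coefficients (C_VRC on V/F -0.20, C_VRC on CL/F -0.28, CREA on
#' V/F -0.40, CREA centered at 237 umol/L), inter-individual variances
#' (omega2_V 0.02, omega2_CL 0.16) and additive residual SD 3.50 ng/mL.
#'
#' @param form C_VRC covariate family (default `"exponential"`).
#' @return A list with elements `typical` (`pk_params`), `effects`
#'   (`pk_cov_effects`) and `ranef` (`pk_ranef_spec`).
#' @export
final_model_parameters <- function(form = "exponential") {
  list(typical = structural_params(ka = 8.39, v_f = 2690, cl_f = 42.87),
       effects = covariate_effects(theta_vrc_v = -0.20, theta_vrc_cl = -0.28,
                                   theta_crea_v = -0.40, crea_ref = 237,
                                   form = form),
       ranef = random_effect_spec(omega2_v = 0.02, omega2_cl = 0.16,
                                  sigma_add = 3.50))
}
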