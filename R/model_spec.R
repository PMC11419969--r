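# Model specification: which parameters are fixed, which covariate effects
# are in the model, the residual-error family and the random-effect
# structure.

PK_EFFECT_NAMES <- c("vrc_v", "vrc_cl", "crea_v", "crea_cl")
PK_RESIDUAL_FAMILIES <- c("additive", "proportional", "combined")

#' Population model specification
#'
#' Defines the estimable model: one-compartment oral structural family with
#' `ka` fixed (default 8.39 1/h) or estimated, a set of covariate effects
#' drawn from `{vrc_v, vrc_cl, crea_v, crea_cl}` (covariate `vrc` = C_VRC,
#' `crea` = CREA; target parameter `v` = V/F, `cl` = CL/F), a residual-error
#' family, and lognormal random effects on V/F and/or CL/F.
#'
#' @param ka_fixed Value at which the absorption rate constant is fixed
#'   (default 8.39 1/h); `NA` to estimate it.
#' @param effects Character vector of covariate-effect names to include
#'   (subset of `c("vrc_v", "vrc_cl", "crea_v", "crea_cl")`).
#' @param residual Residual-error family: `"additive"` (the selected study
#'   model), `"proportional"` or `"combined"`.
#' @param re_v,re_cl Include a random effect on V/F resp. CL/F?
#' @param crea_ref CREA normalization constant, umol/L.
#' @param vrc_form C_VRC covariate family (see [covariate_effects()]).
#' @return An object of class `pk_model_spec`.
#' @examples
#' # Final study model
#' model_spec(effects = c("vrc_v", "vrc_cl", "crea_v"))
#' @export
model_spec <- function(ka_fixed = 8.39,
                       effects = character(0),
                       residual = "additive",
                       re_v = TRUE, re_cl = TRUE,
                       crea_ref = 237,
                       vrc_form = "exponential") {
  residual <- match.arg(residual, PK_RESIDUAL_FAMILIES)
  vrc_form <- match.arg(vrc_form, COVARIATE_FORMS)
  effects <- unique(as.character(effects))
  bad <- setdiff(effects, PK_EFFECT_NAMES)
  if (length(bad) > 0)
    stop("unknown covariate effect(s): ", paste(bad, collapse = ", "))
  if (!is.na(ka_fixed) && (!is.finite(ka_fixed) || ka_fixed <= 0))
    stop("'ka_fixed' must be > 0 (or NA to estimate ka)")
  if (!is.finite(crea_ref) || crea_ref <= 0) stop("'crea_ref' must be > 0")
  structure(list(ka_fixed = ka_fixed, effects = effects, residual = residual,
                 re_v = isTRUE(re_v), re_cl = isTRUE(re_cl),
                 crea_ref = crea_ref, vrc_form = vrc_form),
            class = "pk_model_spec")
}

#' @export
print.pk_model_spec <- function(x, ...) {
  cat("One-compartment oral PopPK model specification\n")
  cat(sprintf("  ka: %s\n", if (is.na(x$ka_fixed)) "estimated"
              else sprintf("fixed at %.4g 1/h", x$ka_fixed)))
  cat(sprintf("  covariate effects: %s (C_VRC family: %s, CREA ref %.4g)\n",
              if (length(x$effects)) paste(x$effects, collapse = ", ")
              else "(none)", x$vrc_form, x$crea_ref))
  cat(sprintf("  residual: %s; random effects: %s\n", x$residual,
              paste(c("V/F", "CL/F")[c(x$re_v, x$re_cl)], collapse = ", ")))
  invisible(x)
}

# Names of the free (estimated) parameters of a spec, on the transformed
# (unconstrained/log) scale used by the optimizer.
free_param_names <- function(spec) {
  nm <- c("lV", "lCL")
  if (is.na(spec$ka_fixed)) nm <- c(nm, "lKa")
  if (length(spec$effects) > 0) nm <- c(nm, paste0("th_", spec$effects))
  if (spec$re_v) nm <- c(nm, "lo2_v")
  if (spec$re_cl) nm <- c(nm, "lo2_cl")
  nm <- c(nm, switch(spec$residual,
                     additive = "lsig_a",
                     proportional = "lsig_p",
                     combined = c("lsig_a", "lsig_p")))
  nm
}

# Default starting values (transformed scale). Structural starts are the
# base-model typical values; thetas start at 0.
default_start <- function(spec, data = NULL) {
  nm <- free_param_names(spec)
  st <- numeric(length(nm))
  names(st) <- nm
  st["lV"] <- log(5291)
  st["lCL"] <- log(32.14)
  if ("lKa" %in% nm) st["lKa"] <- log(8.39)
  st[grep("^th_", nm)] <- 0
  if ("lo2_v" %in% nm) st["lo2_v"] <- log(0.1)
  if ("lo2_cl" %in% nm) st["lo2_cl"] <- log(0.1)
  sig0 <- if (!is.null(data)) max(stats::sd(data$DV[data$EVID == 0]) / 2, 0.5)
          else 3.5
  if ("lsig_a" %in% nm) st["lsig_a"] <- log(sig0)
  if ("lsig_p" %in% nm) st["lsig_p"] <- log(0.2)
  st
}

# Box constraints on the transformed scale.
param_bounds <- function(spec) {
  nm <- free_param_names(spec)
  lo <- stats::setNames(rep(-Inf, length(nm)), nm)
  hi <- stats::setNames(rep(Inf, length(nm)), nm)
  lo["lV"] <- log(1);      hi["lV"] <- log(1e7)
  lo["lCL"] <- log(1e-2);  hi["lCL"] <- log(1e5)
  if ("lKa" %in% nm) { lo["lKa"] <- log(1e-2); hi["lKa"] <- log(100) }
  th <- grep("^th_", nm)
  lo[th] <- -5; hi[th] <- 5
  for (k in c("lo2_v", "lo2_cl"))
    if (k %in% nm) { lo[k] <- log(1e-6); hi[k] <- log(10) }
  for (k in c("lsig_a", "lsig_p"))
    if (k %in% nm) { lo[k] <- log(1e-6); hi[k] <- log(1e4) }
  list(lower = lo, upper = hi)
}

#' Pack natural-scale parameters into the transformed vector of a spec
#'
#' Inverse of the internal unpacking: builds the named transformed parameter
#' vector (`lV = log tvV`, thetas untransformed, `lo2_* = log omega2`,
#' `lsig_* = log sigma`) that the estimation functions accept. Useful for
#' evaluating the objective at known (e.g. generating) values.
#'
#' @param spec A [model_spec()].
#' @param tvV,tvCL Typical V/F (L) and CL/F (L/h).
#' @param ka Absorption rate constant (used only when the spec estimates ka).
#' @param theta Named numeric vector of covariate coefficients, names among
#'   `vrc_v, vrc_cl, crea_v, crea_cl` (defaults 0).
#' @param omega2_v,omega2_cl Random-effect variances.
#' @param sigma_a,sigma_p Residual SDs (additive ng/mL, proportional
#'   fraction).
#' @return Named numeric vector on the transformed scale.
#' @export
pack_params <- function(spec, tvV, tvCL, ka = 8.39, theta = numeric(0),
                        omega2_v = 0.02, omega2_cl = 0.16,
                        sigma_a = 3.5, sigma_p = 0.2) {
  nm <- free_param_names(spec)
  par <- stats::setNames(numeric(length(nm)), nm)
  par["lV"] <- log(tvV)
  par["lCL"] <- log(tvCL)
  if ("lKa" %in% nm) par["lKa"] <- log(ka)
  for (e in spec$effects) {
    key <- paste0("th_", e)
    par[key] <- if (e %in% names(theta)) theta[[e]] else 0
  }
  if ("lo2_v" %in% nm) par["lo2_v"] <- log(omega2_v)
  if ("lo2_cl" %in% nm) par["lo2_cl"] <- log(omega2_cl)
  if ("lsig_a" %in% nm) par["lsig_a"] <- log(sigma_a)
  if ("lsig_p" %in% nm) par["lsig_p"] <- log(sigma_p)
  par
}

# Unpack a transformed parameter vector into natural-scale components.
unpack_params <- function(par, spec) {
  gv <- function(key, default = 0) if (key %in% names(par)) par[[key]] else default
  list(
    tvV = exp(par[["lV"]]),
    tvCL = exp(par[["lCL"]]),
    ka = if (is.na(spec$ka_fixed)) exp(par[["lKa"]]) else spec$ka_fixed,
    th_vrc_v = gv("th_vrc_v"),
    th_vrc_cl = gv("th_vrc_cl"),
    th_crea_v = gv("th_crea_v"),
    th_crea_cl = gv("th_crea_cl"),
    omega2_v = if (spec$re_v) exp(par[["lo2_v"]]) else 0,
    omega2_cl = if (spec$re_cl) exp(par[["lo2_cl"]]) else 0,
    sigma_a = if ("lsig_a" %in% names(par)) exp(par[["lsig_a"]]) else 0,
    sigma_p = if ("lsig_p" %in% names(par)) exp(par[["lsig_p"]]) else 0)
}
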