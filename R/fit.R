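# Outer maximum-likelihood fit: minimize the Laplace OFV over the free
# parameters, with multi-start guarding against local minima, standard errors
# from the observed information at the optimum, EBEs, shrinkage and CWRES.

#' Fit a population PK model
#'
#' Minimizes the Laplace objective ([neg2_marginal_loglik()]) over the free
#' parameters of `spec` with `nlminb` under box constraints (positivity via
#' log transforms; covariate coefficients bounded in [-5, 5]). Standard
#' errors come from the observed-information matrix at the optimum
#' (`2 * solve(hessian(OFV))` on the transformed scale, delta method back to
#' the natural scale); a singular information matrix yields `NA` standard
#' errors with the fit still returned.
#'
#' @param spec A [model_spec()].
#' @param data A `pk_dataset`.
#' @param start Optional named start vector on the transformed scale (see
#'   [pack_params()]); defaults to base-model typical values.
#' @param n_starts Number of starts; starts beyond the first jitter the
#'   start multiplicatively by up to +/-50% (log-scale parameters) and
#'   +/-0.3 (covariate coefficients). Default 5.
#' @param seed Seed for the start jitter (the only stochastic element;
#'   identical data, start and seed give a bit-identical fit). Default 100.
#' @param se Compute standard errors? (Skipping them speeds up bootstrap
#'   refits.) Default TRUE.
#' @param hessian Inner Laplace Hessian method, `"exact"` or `"gn"`.
#' @param control Passed to [stats::nlminb()] (default
#'   `list(rel.tol = 1e-8, iter.max = 300)`).
#' @return An object of class `pk_fit`: natural-scale estimate table
#'   (estimate, SE, CV%, 95% CI), `ofv`, `loglik`, `aic`, `bic`, `k`,
#'   `n_obs`, per-subject EBEs, shrinkage (%), convergence diagnostics, the
#'   transformed optimum (`par`), and the spec/data needed by the
#'   diagnostics functions.
#' @export
fit_pk <- function(spec, data, start = NULL, n_starts = 5, seed = 100,
                   se = TRUE, hessian = "exact", control = NULL) {
  data <- pk_dataset(as.data.frame(data))
  design <- build_design(data, spec)
  nm <- free_param_names(spec)
  st0 <- default_start(spec, data)
  if (!is.null(start)) {
    common <- intersect(names(start), nm)
    st0[common] <- start[common]
  }
  bounds <- param_bounds(spec)
  ctrl <- utils::modifyList(list(rel.tol = 1e-8, iter.max = 300,
                                 eval.max = 1000), as.list(control))
  starts <- list(st0)
  if (n_starts > 1) {
    rng <- local({ set.seed(seed); lapply(seq_len(n_starts - 1), function(i) {
      jit <- st0
      is_th <- grepl("^th_", nm)
      jit[!is_th] <- jit[!is_th] + log(stats::runif(sum(!is_th), 0.5, 1.5))
      jit[is_th] <- jit[is_th] + stats::runif(sum(is_th), -0.3, 0.3)
      pmin(pmax(jit, bounds$lower), bounds$upper)
    }) })
    starts <- c(starts, rng)
  }
  eta_cache <- new.env(parent = emptyenv())
  eta_cache$eta <- NULL
  obj <- function(par) {
    names(par) <- nm
    v <- tryCatch(
      ofv_engine(design, spec, par, hessian = hessian,
                 eta_start = eta_cache$eta),
      error = function(e) NULL)
    if (is.null(v) || !is.finite(v)) return(1e12)
    eta_cache$eta <- attr(v, "etas")
    as.numeric(v)
  }
  best <- NULL
  conv_msgs <- character(0)
  for (s in starts) {
    eta_cache$eta <- NULL
    res <- tryCatch(
      stats::nlminb(s, obj, lower = bounds$lower, upper = bounds$upper,
                    control = ctrl),
      error = function(e) NULL)
    if (is.null(res)) next
    conv_msgs <- c(conv_msgs, res$message)
    if (is.null(best) || res$objective < best$objective) best <- res
  }
  if (is.null(best)) stop("all starts failed in fit_pk()")
  par <- stats::setNames(best$par, nm)
  final <- ofv_engine(design, spec, par, hessian = hessian)
  ofv <- as.numeric(final)
  k <- length(nm)
  n_obs <- design$n_obs

  # standard errors: observed information on the transformed scale
  vcov_t <- NULL
  se_t <- rep(NA_real_, k)
  if (se) {
    H <- tryCatch(stats::optimHess(par, obj), error = function(e) NULL)
    if (!is.null(H)) {
      vc <- tryCatch(2 * solve(H), error = function(e) NULL)
      if (!is.null(vc) && all(is.finite(diag(vc))) && all(diag(vc) > 0)) {
        vcov_t <- vc
        se_t <- sqrt(diag(vc))
      }
    }
    if (is.null(vcov_t))
      warning("information matrix singular or not positive definite; SEs unavailable")
  }

  est <- natural_estimates(par, se_t, nm)
  p <- unpack_params(par, spec)
  ebes <- attr(final, "etas")
  shr <- c()
  if (spec$re_v)
    shr["eta_v"] <- shrinkage(ebes[, "eta_v"], p$omega2_v)
  if (spec$re_cl)
    shr["eta_cl"] <- shrinkage(ebes[, "eta_cl"], p$omega2_cl)

  structure(list(
    spec = spec, data = data, design = design, par = par,
    estimates = est, vcov_transformed = vcov_t,
    ofv = ofv, loglik = -ofv / 2, k = k, n_obs = n_obs,
    aic = aic(ofv, k), bic = bic(ofv, k, n_obs),
    ebes = ebes, shrinkage = shr,
    convergence = list(code = best$convergence, message = best$message,
                       n_inner_failed = attr(final, "n_failed"),
                       n_starts = length(starts)),
    hessian_method = hessian), class = "pk_fit")
}

# Natural-scale estimate table from transformed optimum and SEs.
natural_estimates <- function(par, se_t, nm) {
  natural_name <- c(lV = "tvV", lCL = "tvCL", lKa = "tvKa",
                    lo2_v = "omega2_V", lo2_cl = "omega2_CL",
                    lsig_a = "sigma_add", lsig_p = "sigma_prop",
                    th_vrc_v = "theta_VRC_V", th_vrc_cl = "theta_VRC_CL",
                    th_crea_v = "theta_CREA_V", th_crea_cl = "theta_CREA_CL")
  z <- stats::qnorm(0.975)
  rows <- lapply(seq_along(nm), function(i) {
    key <- nm[i]
    if (grepl("^th_", key)) {
      est <- par[[key]]; s <- se_t[i]
      lo <- est - z * s; hi <- est + z * s
    } else {
      est <- exp(par[[key]]); s <- est * se_t[i]   # delta method
      lo <- exp(par[[key]] - z * se_t[i]); hi <- exp(par[[key]] + z * se_t[i])
    }
    data.frame(parameter = unname(natural_name[key]), estimate = est,
               se = s, cv_pct = 100 * s / abs(est),
               ci_lo = lo, ci_hi = hi, row.names = NULL)
  })
  do.call(rbind, rows)
}

#' @export
print.pk_fit <- function(x, ...) {
  cat(sprintf("PopPK fit: %d subjects, %d observations\n",
              x$design$n_subj, x$n_obs))
  cat(sprintf("  OFV %.4f | AIC %.4f | BIC %.4f (k = %d)\n",
              x$ofv, x$aic, x$bic, x$k))
  est <- x$estimates
  est[, -1] <- signif(est[, -1], 4)
  print(est, row.names = FALSE)
  if (length(x$shrinkage) > 0)
    cat("  shrinkage (%):",
        paste(sprintf("%s %.1f", names(x$shrinkage), x$shrinkage),
              collapse = ", "), "\n")
  invisible(x)
}

#' Extract a named natural-scale coefficient from a fit
#' @param fit A `pk_fit`.
#' @param parameter Name in the estimate table (e.g. `"tvCL"`,
#'   `"theta_VRC_CL"`).
#' @return The estimate (numeric scalar).
#' @export
coef_pk <- function(fit, parameter) {
  i <- match(parameter, fit$estimates$parameter)
  if (is.na(i)) stop("no such parameter: ", parameter)
  fit$estimates$estimate[i]
}

# Population (eta = 0) and individual (eta = EBE) predictions per
# observation row, plus the per-row random-effect Jacobian at the EBEs.
fit_predictions <- function(fit) {
  spec <- fit$spec
  design <- fit$design
  p <- unpack_params(fit$par, spec)
  typ <- row_typicals(design, p, spec)
  pred <- conc_and_jac(design, typ$V, typ$CL, p$ka, jac = FALSE)$f
  re <- colnames(fit$ebes)
  if (length(re) > 0) {
    ev <- exp(fit$ebes)
    mv <- if ("eta_v" %in% re) ev[design$subj, match("eta_v", re)] else 1
    mcl <- if ("eta_cl" %in% re) ev[design$subj, match("eta_cl", re)] else 1
    cj <- conc_and_jac(design, typ$V * mv, typ$CL * mcl, p$ka)
  } else {
    cj <- conc_and_jac(design, typ$V, typ$CL, p$ka)
  }
  list(pred = pred, ipred = cj$f, cj = cj, p = p, design = design, re = re)
}

#' Conditional weighted residuals (CWRES)
#'
#' FOCE-type conditional weighted residuals: the model is linearized around
#' the empirical Bayes estimates, `y ~ f(eta_hat) + J (eta - eta_hat) + eps`,
#' so the approximate marginal mean is `f(eta_hat) - J eta_hat` and the
#' marginal covariance is `J Omega J' + W`; the residual vector is
#' standardized by the Cholesky factor of that covariance per subject. For a
#' model without random effects this reduces exactly to `(DV - PRED) / sigma`.
#'
#' @param fit A converged `pk_fit`.
#' @return Numeric vector of CWRES, one per observation row (ordered as the
#'   observation records of the dataset).
#' @export
cwres <- function(fit) {
  fp <- fit_predictions(fit)
  design <- fp$design
  w <- resid_var(fp$cj$f, fp$p, fit$spec)
  re <- fp$re
  d <- length(re)
  out <- numeric(design$n_obs)
  if (d == 0) return((design$dv - fp$pred) / sqrt(w))
  o2 <- c(eta_v = fp$p$omega2_v, eta_cl = fp$p$omega2_cl)[re]
  Omega <- diag(o2, d)
  for (s in seq_len(design$n_subj)) {
    rows <- which(design$subj == s)
    J <- cbind(if ("eta_v" %in% re) fp$cj$jV[rows],
               if ("eta_cl" %in% re) fp$cj$jCL[rows])
    mu <- fp$cj$f[rows] - J %*% fit$ebes[s, ]
    Cov <- J %*% Omega %*% t(J) + diag(w[rows], length(rows))
    L <- tryCatch(chol(Cov), error = function(e)
      stop("non-invertible marginal covariance for subject ",
           design$ids[s]))
    out[rows] <- backsolve(t(L), design$dv[rows] - mu, upper.tri = FALSE)
  }
  out
}

#' Goodness-of-fit tables
#'
#' Tidy per-observation table sufficient to draw the standard diagnostic
#' panels: observed DV against population (PRED, eta = 0) and individual
#' (IPRED, eta = EBE) predictions, and CWRES against IPRED and time after
#' dose (TAD = observation time minus most recent prior dose time).
#'
#' @param fit A converged `pk_fit`.
#' @return A data.frame with columns
#'   `ID, TIME, TAD, DV, PRED, IPRED, CWRES`.
#' @export
gof_tables <- function(fit) {
  fp <- fit_predictions(fit)
  design <- fp$design
  data.frame(ID = design$ids[design$subj], TIME = design$time,
             TAD = design$tad, DV = design$dv,
             PRED = fp$pred, IPRED = fp$ipred, CWRES = cwres(fit))
}
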