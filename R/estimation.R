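# Marginal-likelihood machinery: per-subject Laplace approximation of the
# integral over the random effects eta = (eta_V, eta_CL), with a vectorized
# Gauss-Newton inner mode search using analytic Jacobians of the closed-form
# concentration with respect to the random effects.

# ---------------------------------------------------------------------------
# Design: flattened per-observation dose-history matrices so that one call
# evaluates every observation of every subject at once.

build_design <- function(data, spec) {
  data <- pk_dataset(as.data.frame(data))
  ids <- unique(data$ID)
  n_subj <- length(ids)
  obs <- data[data$EVID == 0, , drop = FALSE]
  n_obs <- nrow(obs)
  subj <- match(obs$ID, ids)
  dose_list <- vector("list", n_subj)
  uniform <- logical(n_subj)
  for (s in seq_len(n_subj)) {
    rows <- data$ID == ids[s] & data$EVID == 1 & data$AMT > 0
    tt <- data$TIME[rows]; aa <- data$AMT[rows]
    dose_list[[s]] <- list(time = tt, amt = aa)
    # uniform regimen: equal amounts on an equally spaced grid (the study
    # design); enables the geometric-series fast path
    uniform[s] <- length(tt) > 0 && max(abs(aa - aa[1])) < 1e-12 &&
      (length(tt) <= 2 || max(abs(diff(diff(tt)))) < 1e-9)
  }
  # fast-path rows: dmin (time since most recent dose), tau, n doses <= obs
  uni_rows <- which(uniform[subj])
  u_dmin <- u_tau <- u_amt <- numeric(length(uni_rows))
  u_n <- integer(length(uni_rows))
  tad <- rep(Inf, n_obs)
  for (k in seq_along(uni_rows)) {
    i <- uni_rows[k]
    d <- dose_list[[subj[i]]]
    n_k <- sum(d$time <= obs$TIME[i])
    if (n_k == 0) { u_n[k] <- 0L; next }
    u_n[k] <- n_k
    u_amt[k] <- d$amt[1]
    u_tau[k] <- if (length(d$time) > 1) d$time[2] - d$time[1] else 1
    u_dmin[k] <- obs$TIME[i] - d$time[n_k]
    tad[i] <- u_dmin[k]
  }
  gen_rows <- setdiff(seq_len(n_obs), uni_rows)
  DT <- AMT <- NULL
  if (length(gen_rows) > 0) {
    dmax <- max(vapply(dose_list[unique(subj[gen_rows])],
                       function(d) length(d$time), 0L))
    DT <- matrix(0, length(gen_rows), max(dmax, 1))
    AMT <- matrix(0, length(gen_rows), max(dmax, 1))
    for (k in seq_along(gen_rows)) {
      i <- gen_rows[k]
      d <- dose_list[[subj[i]]]
      dt <- obs$TIME[i] - d$time
      keep <- dt >= 0
      m <- sum(keep)
      if (m > 0) {
        DT[k, seq_len(m)] <- dt[keep]
        AMT[k, seq_len(m)] <- d$amt[keep]
        tad[i] <- min(dt[keep])
      }
    }
  }
  list(ids = ids, n_subj = n_subj, n_obs = n_obs, subj = subj,
       dv = obs$DV, cvrc = obs$CVRC, crea = obs$CREA,
       time = obs$TIME, tad = tad,
       uni_rows = uni_rows, u_dmin = u_dmin, u_tau = u_tau, u_amt = u_amt,
       u_n = u_n, gen_rows = gen_rows, DT = DT, AMT = AMT,
       obs_rows = which(data$EVID == 0))
}

# Geometric-series accumulation for a uniform regimen: value and ke
# derivative of G(ke) = sum_{i=0}^{n-1} exp(-ke (dmin + tau i)), computed
# stably with expm1. Returns list(G, dG).
geo_accum <- function(ke, dmin, tau, n) {
  A <- exp(-ke * dmin)
  x_exp <- ke * tau
  P <- -expm1(-x_exp * n)
  Q <- -expm1(-x_exp)
  G <- A * P / Q
  # dG/dke = -dmin G + A (P'Q - PQ')/Q^2 ; near ke -> 0 use the mean-lag limit
  Pp <- tau * n * exp(-x_exp * n)
  Qp <- tau * exp(-x_exp)
  dG <- -dmin * G + A * (Pp * Q - P * Qp) / Q^2
  small <- which(x_exp * n < 1e-5)
  if (length(small) > 0) {
    G[small] <- A[small] * n[small]
    dG[small] <- -G[small] * (dmin[small] + tau[small] * (n[small] - 1) / 2)
  }
  list(G = G, dG = dG)
}

# Covariate-adjusted typical V/F and CL/F per observation row.
row_typicals <- function(design, p, spec) {
  fv <- rep(1, design$n_obs)
  fcl <- rep(1, design$n_obs)
  if ("vrc_v" %in% spec$effects)
    fv <- fv * covariate_factor(design$cvrc, p$th_vrc_v, spec$vrc_form)
  if ("vrc_cl" %in% spec$effects)
    fcl <- fcl * covariate_factor(design$cvrc, p$th_vrc_cl, spec$vrc_form)
  if ("crea_v" %in% spec$effects)
    fv <- fv * (design$crea / spec$crea_ref)^p$th_crea_v
  if ("crea_cl" %in% spec$effects)
    fcl <- fcl * (design$crea / spec$crea_ref)^p$th_crea_cl
  list(V = p$tvV * fv, CL = p$tvCL * fcl)
}

# Concentration and its Jacobian w.r.t. (eta_V, eta_CL) for every observation
# row, given per-row individual V and CL. Uniform-regimen rows use the stable
# geometric-series accumulation; remaining rows use explicit per-dose
# superposition matrices. Returns f (ng/mL), jV = df/d eta_V,
# jCL = df/d eta_CL.
conc_and_jac <- function(design, V, CL, ka, jac = TRUE) {
  ke <- CL / V
  # guard the ka == ke degeneracy with a continuous nudge
  deg <- which(abs(ka - ke) < 1e-8 * ka)
  if (length(deg) > 0) ke[deg] <- ka * (1 - 1e-8)
  n <- design$n_obs
  f <- numeric(n)
  g <- if (jac) numeric(n) else NULL   # df/d ke
  ur <- design$uni_rows
  if (length(ur) > 0) {
    keu <- ke[ur]
    live <- design$u_n > 0
    gk <- geo_accum(keu, design$u_dmin, design$u_tau, design$u_n)
    ga <- geo_accum(rep(ka, length(ur)), design$u_dmin, design$u_tau,
                    design$u_n)
    S1 <- design$u_amt * gk$G * live
    S2 <- design$u_amt * ga$G * live
    B <- MGL_TO_NGML * ka / (V[ur] * (ka - keu))
    f[ur] <- B * (S1 - S2)
    if (jac) {
      T1 <- -design$u_amt * gk$dG * live
      g[ur] <- f[ur] / (ka - keu) - B * T1
    }
  }
  gr <- design$gen_rows
  if (length(gr) > 0) {
    keg <- ke[gr]
    E1 <- exp(-design$DT * keg)        # column-major recycling: row-wise ke
    E2 <- exp(-ka * design$DT)
    W1 <- design$AMT * E1
    S1 <- rowSums(W1)
    S2 <- rowSums(design$AMT * E2)
    B <- MGL_TO_NGML * ka / (V[gr] * (ka - keg))
    f[gr] <- B * (S1 - S2)
    if (jac) {
      T1 <- rowSums(W1 * design$DT)
      g[gr] <- f[gr] / (ka - keg) - B * T1
    }
  }
  if (!jac) return(list(f = f))
  list(f = f,
       jV = -f - ke * g,               # df/d eta_V  (V_i = V * e^eta_V)
       jCL = ke * g)                   # df/d eta_CL
}

# Residual variance per observation row and its derivative factor w.r.t. f.
resid_var <- function(f, p, spec) {
  switch(spec$residual,
         additive = rep(p$sigma_a^2, length(f)),
         proportional = pmax((p$sigma_p * f)^2, 1e-12),
         combined = p$sigma_a^2 + (p$sigma_p * f)^2)
}

# Evaluate f, residuals, variances, per-subject m, gradient for a given eta
# matrix (n_subj x d). Shared workhorse for the inner solver and Hessian.
# One rowsum pass aggregates both the objective and gradient contributions.
eval_state <- function(design, typ, ka, p, spec, eta, oinv, ld_omega,
                       need_grad = TRUE) {
  d <- ncol(eta)
  cols <- colnames(eta)
  if (d > 0) {
    ev <- exp(eta)
    mv <- if ("eta_v" %in% cols) ev[design$subj, match("eta_v", cols)] else 1
    mcl <- if ("eta_cl" %in% cols) ev[design$subj, match("eta_cl", cols)]
           else 1
  } else mv <- mcl <- 1
  V <- typ$V * mv
  CL <- typ$CL * mcl
  cj <- conc_and_jac(design, V, CL, ka, jac = need_grad && d > 0)
  r <- design$dv - cj$f
  w <- resid_var(cj$f, p, spec)
  contrib <- r^2 / w + log(2 * pi * w)
  if (need_grad && d > 0) {
    # d/d eta of sum r^2/w + log w:
    #   -2 r J / w  + w'(1/w - r^2/w^2),  w' = 2 sigma_p^2 f J (prop/combined)
    wp_fac <- if (spec$residual == "additive") NULL else 2 * p$sigma_p^2 * cj$f
    gcols <- lapply(seq_len(d), function(k) {
      J <- if (cols[k] == "eta_v") cj$jV else cj$jCL
      gk <- -2 * r * J / w
      if (!is.null(wp_fac)) gk <- gk + (wp_fac * J) * (1 / w - r^2 / w^2)
      gk
    })
    agg <- rowsum(cbind(contrib, do.call(cbind, gcols)), design$subj,
                  reorder = TRUE)
    grad <- agg[, -1, drop = FALSE] + 2 * eta %*% oinv
  } else {
    agg <- rowsum(contrib, design$subj, reorder = TRUE)
    grad <- NULL
  }
  prior <- if (d > 0)
    rowSums((eta %*% oinv) * eta) + ld_omega + d * log(2 * pi)
  else 0
  m <- agg[, 1] + prior
  out <- list(cj = cj, r = r, w = w, m = as.vector(m))
  if (!is.null(grad)) out$grad <- grad
  out
}

# Vectorized inner Gauss-Newton search for the per-subject mode of m(eta).
# Returns list(eta, m, state, converged (logical per subject)).
inner_modes <- function(design, typ, ka, p, spec, oinv, ld_omega,
                        eta_start = NULL, max_iter = 40L, tol = 1e-8) {
  re <- c(if (spec$re_v) "eta_v", if (spec$re_cl) "eta_cl")
  d <- length(re)
  if (d == 0) {
    eta <- matrix(0, design$n_subj, 0)
    st <- eval_state(design, typ, ka, p, spec, eta, oinv, 0, need_grad = FALSE)
    return(list(eta = eta, m = st$m, state = st,
                converged = rep(TRUE, design$n_subj)))
  }
  eta <- if (is.null(eta_start)) matrix(0, design$n_subj, d) else eta_start
  colnames(eta) <- re
  st <- eval_state(design, typ, ka, p, spec, eta, oinv, ld_omega)
  converged <- rep(FALSE, design$n_subj)
  for (it in seq_len(max_iter)) {
    # GN metric A = J' W^-1 J + Omega^-1 per subject; step = A^-1 (-grad/2)
    Js <- lapply(re, function(k) if (k == "eta_v") st$cj$jV else st$cj$jCL)
    A <- array(0, c(design$n_subj, d, d))
    pairs <- which(upper.tri(diag(d), diag = TRUE), arr.ind = TRUE)
    xcols <- vapply(seq_len(nrow(pairs)), function(q)
      Js[[pairs[q, 1]]] * Js[[pairs[q, 2]]] / st$w,
      numeric(design$n_obs))
    s <- rowsum(xcols, design$subj, reorder = TRUE)
    for (q in seq_len(nrow(pairs))) {
      i <- pairs[q, 1]; j <- pairs[q, 2]
      A[, i, j] <- A[, j, i] <- s[, q] + oinv[i, j]
    }
    b <- -0.5 * st$grad
    delta <- matrix(0, design$n_subj, d)
    if (d == 1) {
      delta[, 1] <- b[, 1] / pmax(A[, 1, 1], 1e-12)
    } else {
      det <- A[, 1, 1] * A[, 2, 2] - A[, 1, 2]^2
      det <- ifelse(abs(det) < 1e-12, 1e-12, det)
      delta[, 1] <- (A[, 2, 2] * b[, 1] - A[, 1, 2] * b[, 2]) / det
      delta[, 2] <- (A[, 1, 1] * b[, 2] - A[, 1, 2] * b[, 1]) / det
    }
    step_len <- sqrt(rowSums(delta^2))
    converged <- converged | step_len < tol
    if (all(converged)) break
    m_old <- st$m
    m_tol <- 1e-8 * (abs(m_old) + 1)   # acceptance slack: rounding-level
    step <- as.numeric(!converged)
    accepted <- converged               # converged subjects do not move
    eta_new <- eta
    st_full <- NULL
    for (ls in 1:12) {
      cand <- eta + delta * step
      colnames(cand) <- re
      # first trial carries the gradient so a clean full-step acceptance
      # (the common case) needs no re-evaluation
      st_c <- eval_state(design, typ, ka, p, spec, cand, oinv, ld_omega,
                         need_grad = (ls == 1))
      better <- st_c$m <= m_old + m_tol
      take <- better & !accepted
      if (any(take)) eta_new[take, ] <- cand[take, , drop = FALSE]
      accepted <- accepted | better
      if (ls == 1 && all(accepted)) st_full <- st_c
      if (all(accepted)) break
      step[!accepted] <- step[!accepted] / 2
    }
    colnames(eta_new) <- re
    # a subject failing every halving of a tiny step is at its mode up to
    # numerical noise; count it converged
    converged <- converged | (!accepted & step_len < 1e-5)
    st <- if (!is.null(st_full)) st_full
          else eval_state(design, typ, ka, p, spec, eta_new, oinv, ld_omega)
    eta <- eta_new
    if (all(converged)) break
  }
  # fallback for stragglers: damped true-Newton per subject (Hessian by
  # forward differences of the analytic gradient), updating only the
  # unconverged rows; robust where the Gauss-Newton metric is a poor
  # curvature model (large-residual subjects)
  if (!all(converged)) {
    lam <- rep(1e-2, design$n_subj)
    h_fd <- 1e-4
    for (it2 in seq_len(40L)) {
      bad <- which(!converged)
      if (length(bad) == 0) break
      H <- array(0, c(design$n_subj, d, d))
      for (k in seq_len(d)) {
        ep <- eta; ep[, k] <- ep[, k] + h_fd
        colnames(ep) <- re
        gp <- eval_state(design, typ, ka, p, spec, ep, oinv, ld_omega)$grad
        H[, , k] <- (gp - st$grad) / h_fd
      }
      if (d == 2) {
        off <- (H[, 1, 2] + H[, 2, 1]) / 2
        H[, 1, 2] <- H[, 2, 1] <- off
      }
      g <- st$grad
      delta <- matrix(0, design$n_subj, d)
      dec <- numeric(design$n_subj)
      if (d == 1) {
        A11 <- pmax(H[, 1, 1], 1e-10) + lam
        delta[, 1] <- -g[, 1] / A11
        dec <- 0.5 * g[, 1]^2 / A11
      } else {
        A11 <- H[, 1, 1] + lam; A22 <- H[, 2, 2] + lam; A12 <- H[, 1, 2]
        det <- A11 * A22 - A12^2
        ok <- A11 > 0 & det > 0
        det[!ok] <- 1; A11[!ok] <- 1; A22[!ok] <- 1; A12[!ok] <- 0
        delta[, 1] <- -(A22 * g[, 1] - A12 * g[, 2]) / det
        delta[, 2] <- -(A11 * g[, 2] - A12 * g[, 1]) / det
        delta[!ok, ] <- -0.05 * g[!ok, , drop = FALSE] /
          sqrt(rowSums(g[!ok, , drop = FALSE]^2) + 1e-12)  # gradient descent
        dec <- -0.5 * rowSums(delta * g)
      }
      cand <- eta
      cand[bad, ] <- eta[bad, , drop = FALSE] + delta[bad, , drop = FALSE]
      colnames(cand) <- re
      st_c <- eval_state(design, typ, ka, p, spec, cand, oinv, ld_omega)
      slack <- 1e-11 * (abs(st$m) + 1)
      improved <- st_c$m <= st$m + slack
      acc <- bad[improved[bad]]
      rej <- bad[!improved[bad]]
      lam[acc] <- lam[acc] / 3
      lam[rej] <- lam[rej] * 10
      if (length(acc) > 0) {
        eta[acc, ] <- cand[acc, , drop = FALSE]
        st <- if (length(rej) == 0) st_c
              else eval_state(design, typ, ka, p, spec, eta, oinv, ld_omega)
      }
      # scale-free convergence: the Newton decrement is the predicted
      # objective decrease; rounding level means we are at the mode
      converged <- converged |
        (abs(dec) < 1e-9 * (abs(st$m) + 1) & lam < 1)
    }
  }
  # final safeguard: a small gradient marks the mode even if the step
  # bookkeeping did not
  if (!all(converged) && !is.null(st$grad)) {
    gnorm <- sqrt(rowSums(st$grad^2))
    converged <- converged | gnorm < 1e-4 * (abs(st$m) + 1)
  }
  list(eta = eta, m = st$m, state = st, converged = converged)
}

# Per-subject Hessian of m(eta) at the mode: central finite differences of
# the analytic gradient (exact Laplace), with a Gauss-Newton fallback when
# the numeric Hessian is not positive definite.
inner_hessians <- function(design, typ, ka, p, spec, eta, oinv, ld_omega,
                           method = c("exact", "gn"), h = 1e-4) {
  method <- match.arg(method)
  d <- ncol(eta)
  re <- colnames(eta)
  n <- design$n_subj
  H <- array(0, c(n, d, d))
  st0 <- eval_state(design, typ, ka, p, spec, eta, oinv, ld_omega)
  gn <- function() {
    Js <- lapply(re, function(k) if (k == "eta_v") st0$cj$jV else st0$cj$jCL)
    G <- array(0, c(n, d, d))
    pairs <- which(upper.tri(diag(d), diag = TRUE), arr.ind = TRUE)
    xcols <- vapply(seq_len(nrow(pairs)), function(q)
      Js[[pairs[q, 1]]] * Js[[pairs[q, 2]]] / st0$w,
      numeric(design$n_obs))
    s <- rowsum(xcols, design$subj, reorder = TRUE)
    for (q in seq_len(nrow(pairs))) {
      i <- pairs[q, 1]; j <- pairs[q, 2]
      G[, i, j] <- G[, j, i] <- 2 * (s[, q] + oinv[i, j])
    }
    G
  }
  if (method == "gn") return(gn())
  # forward differences of the analytic gradient (the gradient at the mode is
  # ~0, so the forward scheme loses no meaningful accuracy in the log-det)
  g0 <- st0$grad
  for (k in seq_len(d)) {
    ep <- eta; ep[, k] <- ep[, k] + h
    colnames(ep) <- re
    gp <- eval_state(design, typ, ka, p, spec, ep, oinv, ld_omega)$grad
    H[, , k] <- (gp - g0) / h
  }
  # symmetrize
  for (i in seq_len(d)) for (j in seq_len(d))
    if (i < j) H[, i, j] <- H[, j, i] <- (H[, i, j] + H[, j, i]) / 2
  # positive-definiteness check; fall back to GN rows where it fails
  bad <- rep(FALSE, n)
  if (d == 1) bad <- H[, 1, 1] <= 0
  if (d == 2) bad <- H[, 1, 1] <= 0 |
    (H[, 1, 1] * H[, 2, 2] - H[, 1, 2]^2) <= 0
  if (any(bad)) {
    G <- gn()
    for (i in which(bad)) H[i, , ] <- G[i, , ]
  }
  H
}

# Objective-inflation penalty per non-converged subject.
INNER_FAIL_PENALTY <- 1e7

#' Laplace objective function value (-2 log marginal likelihood)
#'
#' Computes the objective function value (OFV) of the nonlinear mixed-effects
#' model for a given parameter set: per subject, the joint log density of the
#' data and the random effects is maximized over `eta = (eta_V, eta_CL)`
#' (vectorized Gauss-Newton with analytic Jacobians) and the marginal
#' integral is approximated by the Laplace method using the exact (finite
#' difference of the analytic gradient) Hessian at the mode. Subject
#' contributions are summed and multiplied by -2. Deterministic given data
#' and parameters.
#'
#' @param spec A [model_spec()].
#' @param par Named transformed parameter vector (see [free_param_names()]),
#'   or a natural-scale list accepted by [pack_params()].
#' @param data A `pk_dataset` (or a prebuilt design from the fitting
#'   machinery).
#' @param hessian Inner Hessian method: `"exact"` (default; true Laplace) or
#'   `"gn"` (Gauss-Newton / FOCE-type expected information).
#' @param eta_start Optional warm-start matrix of random-effect modes.
#' @return The OFV (numeric scalar) with attributes `etas` (per-subject
#'   modes), `converged` (per-subject logical) and `n_failed`. Non-converged
#'   inner problems inflate the objective by a large penalty and raise a
#'   warning; they are never silently dropped.
#' @export
neg2_marginal_loglik <- function(spec, par, data, hessian = "exact",
                                 eta_start = NULL) {
  design <- if (is.list(data) && !is.null(data$uni_rows)) data
            else build_design(data, spec)
  ofv_engine(design, spec, par, hessian = hessian, eta_start = eta_start,
             warn = TRUE)
}

ofv_engine <- function(design, spec, par, hessian = "exact",
                       eta_start = NULL, warn = FALSE) {
  p <- unpack_params(par, spec)
  typ <- row_typicals(design, p, spec)
  re <- c(if (spec$re_v) "eta_v", if (spec$re_cl) "eta_cl")
  d <- length(re)
  if (d > 0) {
    o2 <- c(eta_v = p$omega2_v, eta_cl = p$omega2_cl)[re]
    oinv <- diag(1 / o2, d)
    ld_omega <- sum(log(o2))
  } else {
    oinv <- matrix(0, 0, 0); ld_omega <- 0
  }
  im <- inner_modes(design, typ, p$ka, p, spec, oinv, ld_omega,
                    eta_start = eta_start)
  ofv_i <- im$m
  if (d > 0) {
    H <- inner_hessians(design, typ, p$ka, p, spec, im$eta, oinv, ld_omega,
                        method = hessian)
    ld_h <- if (d == 1) log(0.5 * H[, 1, 1]) else
      log(0.25 * pmax(H[, 1, 1] * H[, 2, 2] - H[, 1, 2]^2, 1e-300))
    ofv_i <- ofv_i - d * log(2 * pi) + ld_h
  }
  n_failed <- sum(!im$converged)
  if (n_failed > 0) {
    ofv_i[!im$converged] <- ofv_i[!im$converged] + INNER_FAIL_PENALTY
    if (warn)
      warning(sprintf("inner mode search failed for %d subject(s); objective inflated",
                      n_failed))
  }
  structure(sum(ofv_i), etas = im$eta, converged = im$converged,
            n_failed = n_failed, per_subject = ofv_i)
}

#' Akaike information criterion from an OFV
#'
#' `AIC = OFV + 2k`, where `k` is the number of estimated parameters (fixed
#' parameters such as a frozen `ka` are excluded).
#'
#' @param ofv Objective function value (-2 log likelihood).
#' @param k Number of estimated parameters (>= 0).
#' @return AIC.
#' @export
aic <- function(ofv, k) {
  if (k < 0) stop("'k' must be >= 0")
  ofv + 2 * k
}

#' Bayesian information criterion from an OFV
#'
#' `BIC = OFV + k * log(n_obs)` with `n_obs` the number of observation
#' records.
#'
#' @inheritParams aic
#' @param n_obs Number of observation records (>= 1).
#' @return BIC.
#' @export
bic <- function(ofv, k, n_obs) {
  if (k < 0) stop("'k' must be >= 0")
  if (n_obs < 1) stop("'n_obs' must be >= 1")
  ofv + k * log(n_obs)
}

#' Eta shrinkage
#'
#' `100 * (1 - SD(eta_hat) / sqrt(omega2))`, using the sample SD (n - 1
#' denominator). Values below 20% are conventionally deemed acceptable.
#'
#' @param ebes Vector of empirical Bayes estimates for one random effect.
#' @param omega2 The corresponding population variance (> 0).
#' @return Shrinkage, percent.
#' @export
shrinkage <- function(ebes, omega2) {
  if (length(ebes) < 2) stop("shrinkage needs at least 2 subjects")
  if (!is.finite(omega2) || omega2 <= 0)
    stop("shrinkage is undefined for omega2 <= 0")
  100 * (1 - stats::sd(ebes) / sqrt(omega2))
}
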