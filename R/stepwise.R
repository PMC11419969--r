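# Stepwise covariate selection on the objective function value: forward
# inclusion (delta OFV > 6.635, i.e. p <= 0.01 on 1 df) followed by backward
# elimination with the more stringent delta OFV > 10.828 (p < 0.001).

#' Stepwise covariate selection
#'
#' Forward phase: at each step every remaining candidate effect is added to
#' the current model and refitted; the candidate with the largest OFV drop is
#' included if that drop exceeds `forward_dofv`. Backward phase: each
#' included candidate is removed in turn; the effect whose removal raises the
#' OFV least is eliminated while that rise is below `backward_dofv`. Ties are
#' broken by candidate declaration order. Candidate fits are warm-started
#' from the incumbent model's estimates (single start). A failing candidate
#' fit is skipped with a warning, never fatal.
#'
#' @param base A [model_spec()] without the candidate effects.
#' @param candidates Character vector of candidate effect names (subset of
#'   `c("vrc_v", "vrc_cl", "crea_v", "crea_cl")`), in declaration order.
#' @param data A `pk_dataset`.
#' @param forward_dofv Forward inclusion threshold (default 6.635).
#' @param backward_dofv Backward elimination threshold (default 10.828).
#' @param fit_args List of extra arguments passed to [fit_pk()] for every
#'   fit (e.g. `control`); `n_starts` defaults to 1 here because every fit is
#'   warm-started.
#' @return A list of class `pk_selection`: `spec` (final [model_spec()]),
#'   `fit` (final `pk_fit`), `selected` (effect names in inclusion order) and
#'   `trace` (data.frame of every evaluated step with its delta OFV and
#'   action).
#' @export
stepwise_select <- function(base, candidates, data,
                            forward_dofv = 6.635, backward_dofv = 10.828,
                            fit_args = list()) {
  candidates <- as.character(candidates)
  if (length(candidates) == 0) stop("'candidates' must be non-empty")
  bad <- setdiff(candidates, PK_EFFECT_NAMES)
  if (length(bad) > 0)
    stop("unknown candidate effect(s): ", paste(bad, collapse = ", "))
  data <- pk_dataset(as.data.frame(data))
  fit_args <- utils::modifyList(list(n_starts = 1, se = FALSE), fit_args)

  do_fit <- function(spec, start) {
    args <- c(list(spec = spec, data = data, start = start), fit_args)
    tryCatch(do.call(fit_pk, args), error = function(e) {
      warning("candidate fit failed (", conditionMessage(e), "); skipped")
      NULL
    })
  }
  with_effects <- function(effs) {
    model_spec(ka_fixed = base$ka_fixed, effects = effs,
               residual = base$residual, re_v = base$re_v,
               re_cl = base$re_cl, crea_ref = base$crea_ref,
               vrc_form = base$vrc_form)
  }

  trace <- data.frame(step = integer(0), phase = character(0),
                      candidate = character(0), ofv = numeric(0),
                      delta_ofv = numeric(0), action = character(0))
  log_step <- function(step, phase, cand, ofv, dofv, action) {
    trace <<- rbind(trace, data.frame(step = step, phase = phase,
                                      candidate = cand, ofv = ofv,
                                      delta_ofv = dofv, action = action))
  }

  current <- do_fit(with_effects(character(0)), start = NULL)
  if (is.null(current)) stop("base model fit failed")
  included <- character(0)
  step <- 0L
  log_step(step, "base", "(none)", current$ofv, NA, "start")

  # forward inclusion
  repeat {
    remaining <- setdiff(candidates, included)
    if (length(remaining) == 0) break
    step <- step + 1L
    cand_fits <- list()
    for (eff in remaining) {
      f <- do_fit(with_effects(c(included, eff)), start = current$par)
      if (is.null(f)) next
      dofv <- current$ofv - f$ofv
      log_step(step, "forward", eff, f$ofv, dofv, "evaluated")
      cand_fits[[eff]] <- f
    }
    if (length(cand_fits) == 0) break
    drops <- vapply(cand_fits, function(f) current$ofv - f$ofv, 0)
    best <- names(drops)[which.max(drops)]   # declaration order breaks ties
    if (drops[[best]] > forward_dofv) {
      included <- c(included, best)
      current <- cand_fits[[best]]
      log_step(step, "forward", best, current$ofv, drops[[best]], "included")
    } else break
  }

  # backward elimination
  repeat {
    if (length(included) == 0) break
    step <- step + 1L
    rises <- c()
    red_fits <- list()
    for (eff in included) {
      f <- do_fit(with_effects(setdiff(included, eff)), start = current$par)
      if (is.null(f)) next
      rise <- f$ofv - current$ofv
      log_step(step, "backward", eff, f$ofv, rise, "evaluated")
      rises[eff] <- rise
      red_fits[[eff]] <- f
    }
    if (length(rises) == 0) break
    worst <- names(rises)[which.min(rises)]
    if (rises[[worst]] < backward_dofv) {
      included <- setdiff(included, worst)
      current <- red_fits[[worst]]
      log_step(step, "backward", worst, current$ofv, rises[[worst]],
               "removed")
    } else break
  }

  # final fit with standard errors
  final_spec <- with_effects(included)
  final_args <- utils::modifyList(fit_args, list(se = TRUE))
  final <- do.call(fit_pk, c(list(spec = final_spec, data = data,
                                  start = current$par), final_args))
  structure(list(spec = final_spec, fit = final, selected = included,
                 trace = trace), class = "pk_selection")
}

#' @export
print.pk_selection <- function(x, ...) {
  cat("Stepwise covariate selection\n  selected:",
      if (length(x$selected)) paste(x$selected, collapse = ", ")
      else "(none)", "\n")
  print(x$trace, row.names = FALSE)
  invisible(x)
}

#' Write a selection trace as a tab-separated log
#' @param selection A `pk_selection`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_selection_trace <- function(selection, path) {
  utils::write.table(selection$trace, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
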