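# Rectangular event dataset (NONMEM-style): one row per dose or observation.
# Mandatory columns: ID, TIME (h), AMT (mg; dose rows), DV (ng/mL;
# observation rows), EVID (1 = dose, 0 = observation), CVRC (ug/mL),
# CREA (umol/L). Extra columns (demographics, genotypes) are carried along.

PK_REQUIRED_COLS <- c("ID", "TIME", "AMT", "DV", "EVID", "CVRC", "CREA")

#' Construct and validate a PK event dataset
#'
#' Validates the event-record invariants: non-negative, within-subject
#' non-decreasing times; EVID in \{0, 1\}; doses carry AMT and no DV;
#' observations carry DV and no AMT; every observation preceded by at least
#' one dose for that subject; at least one observation per subject; covariate
#' columns finite with CVRC >= 0 and CREA > 0.
#'
#' @param df A data.frame with at least the columns
#'   `ID, TIME, AMT, DV, EVID, CVRC, CREA`.
#' @return The validated data.frame with class `pk_dataset`.
#' @export
pk_dataset <- function(df) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(PK_REQUIRED_COLS, names(df))
  if (length(missing_cols) > 0)
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  df <- as.data.frame(df)
  problems <- character(0)
  note <- function(rows, msg) {
    if (length(rows) > 0)
      problems <<- c(problems,
                     sprintf("row %d: %s", utils::head(rows, 5), msg))
  }
  note(which(!df$EVID %in% c(0L, 1L)), "EVID must be 0 (observation) or 1 (dose)")
  note(which(!is.finite(df$TIME) | df$TIME < 0), "TIME must be finite and >= 0")
  note(which(df$EVID == 1 & !is.na(df$DV)), "DV must be missing on a dose (EVID=1) row")
  note(which(df$EVID == 1 & (is.na(df$AMT) | df$AMT < 0)),
       "dose rows need AMT >= 0")
  note(which(df$EVID == 0 & is.na(df$DV)), "observation rows need DV")
  note(which(df$EVID == 0 & !is.na(df$AMT) & df$AMT != 0),
       "observation rows must not carry a dose amount")
  note(which(!is.finite(df$CVRC) | df$CVRC < 0), "CVRC must be >= 0")
  note(which(!is.finite(df$CREA) | df$CREA <= 0), "CREA must be > 0")
  for (id in unique(df$ID)) {
    rows <- which(df$ID == id)
    tt <- df$TIME[rows]
    bad <- which(diff(tt) < 0)
    note(rows[bad + 1], sprintf("TIME decreases within subject %s", id))
    ev <- df$EVID[rows]
    if (!any(ev == 0))
      problems <- c(problems, sprintf("subject %s has no observation", id))
    first_dose <- match(1L, ev)
    early_obs <- if (is.na(first_dose)) which(ev == 0) else
      which(ev == 0 & seq_along(ev) < first_dose)
    note(rows[early_obs], sprintf("observation before first dose of subject %s", id))
  }
  if (length(problems) > 0)
    stop("invalid PK event dataset:\n  ",
         paste(utils::head(problems, 10), collapse = "\n  "))
  class(df) <- c("pk_dataset", "data.frame")
  df
}

#' @export
print.pk_dataset <- function(x, ...) {
  cat(sprintf("PK event dataset: %d subjects, %d observations, %d doses\n",
              length(unique(x$ID)), sum(x$EVID == 0), sum(x$EVID == 1)))
  NextMethod()
}

#' Number of observation records
#' @param data A `pk_dataset`.
#' @return Integer count of EVID = 0 rows.
#' @export
n_observations <- function(data) sum(data$EVID == 0)

#' Read a PK event dataset from CSV
#'
#' Comma-separated, dot decimal, mandatory header; `"."` is accepted as a
#' missing value (NONMEM convention). Validation failures are reported with
#' row numbers (header = line 1, so file line = row + 1).
#'
#' @param path Path to a CSV file.
#' @return A validated `pk_dataset`.
#' @export
read_pk_dataset <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, na.strings = c("NA", "."),
                        stringsAsFactors = FALSE)
  tryCatch(pk_dataset(df), error = function(e) {
    stop("while reading ", path, " (row k = file line k+1): ",
         conditionMessage(e), call. = FALSE)
  })
}

#' Write a PK event dataset to CSV
#'
#' Missing values are written as `"."` so that a write/read round trip is
#' exact.
#'
#' @param data A `pk_dataset` (or data.frame passing validation).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_pk_dataset <- function(data, path) {
  data <- pk_dataset(as.data.frame(data))
  df <- as.data.frame(data)
  utils::write.csv(df, path, row.names = FALSE, na = ".", quote = FALSE)
  invisible(path)
}

#' Read a flat key-value parameter configuration
#'
#' Plain-text `key = value` (or `key: value`) pairs, one per line; `#` starts
#' a comment. Recognized keys: `tvKa, tvV, tvCL, theta_vrc_v, theta_vrc_cl,
#' theta_crea_v, theta_crea_cl, crea_ref, omega2_v, omega2_cl, sigma_add,
#' covariate_form`.
#'
#' @param path Path to the configuration file.
#' @return A list with elements `typical`, `effects`, `ranef` (as in
#'   [final_model_parameters()]).
#' @export
read_pk_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)\\s*[=:]\\s*(.+)$", ln))[[1]]
    if (length(m) != 3) stop("unparseable config line: ", ln)
    kv[[m[2]]] <- trimws(m[3])
  }
  num <- function(key, default) {
    if (is.null(kv[[key]])) return(default)
    v <- suppressWarnings(as.numeric(kv[[key]]))
    if (is.na(v)) stop("non-numeric value for key '", key, "'")
    v
  }
  list(
    typical = structural_params(ka = num("tvKa", 8.39),
                                v_f = num("tvV", 2690),
                                cl_f = num("tvCL", 42.87)),
    effects = covariate_effects(theta_vrc_v = num("theta_vrc_v", 0),
                                theta_vrc_cl = num("theta_vrc_cl", 0),
                                theta_crea_v = num("theta_crea_v", 0),
                                theta_crea_cl = num("theta_crea_cl", 0),
                                crea_ref = num("crea_ref", 237),
                                form = if (is.null(kv$covariate_form))
                                  "exponential" else kv$covariate_form),
    ranef = random_effect_spec(omega2_v = num("omega2_v", 0.02),
                               omega2_cl = num("omega2_cl", 0.16),
                               sigma_add = num("sigma_add", 3.50)))
}

#' Write a flat key-value parameter configuration
#'
#' @param params A list with `typical`, `effects`, `ranef` (as returned by
#'   [final_model_parameters()] or [read_pk_config()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pk_config <- function(params, path) {
  lines <- c(
    sprintf("tvKa = %.10g", params$typical$ka),
    sprintf("tvV = %.10g", params$typical$v_f),
    sprintf("tvCL = %.10g", params$typical$cl_f),
    sprintf("theta_vrc_v = %.10g", params$effects$theta_vrc_v),
    sprintf("theta_vrc_cl = %.10g", params$effects$theta_vrc_cl),
    sprintf("theta_crea_v = %.10g", params$effects$theta_crea_v),
    sprintf("theta_crea_cl = %.10g", params$effects$theta_crea_cl),
    sprintf("crea_ref = %.10g", params$effects$crea_ref),
    sprintf("omega2_v = %.10g", params$ranef$omega2_v),
    sprintf("omega2_cl = %.10g", params$ranef$omega2_cl),
    sprintf("sigma_add = %.10g", params$ranef$sigma_add),
    sprintf("covariate_form = %s", params$effects$form))
  writeLines(lines, path)
  invisible(path)
}
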