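# tacropk

Population pharmacokinetics (PopPK) of tacrolimus in renal-transplant
recipients receiving concomitant voriconazole, with Monte Carlo dose
individualization. The package implements, end to end:

- **Structural model** — one-compartment oral kinetics with first-order
  absorption and elimination in closed form (`pk_concentration()`,
  `steady_state_trough()`), with the absorption rate constant Ka fixable
  (default 8.39 h⁻¹).
- **Covariate model** — voriconazole concentration (C_VRC, μg/mL) and serum
  creatinine (CREA, μmol/L) scale apparent clearance CL/F and volume V/F
  (`apply_covariates()`; exponential, shifted-power and centered-power
  families).
- **Estimation** — nonlinear mixed-effects by the Laplace approximation with
  lognormal inter-individual variability on V/F and CL/F and additive
  residual error (`fit_pk()`, `neg2_marginal_loglik()`), information
  criteria (`aic()`, `bic()`), empirical Bayes estimates, shrinkage and
  conditional weighted residuals (`cwres()`, `gof_tables()`).
- **Covariate selection** — stepwise forward inclusion (ΔOFV > 6.635,
  p < 0.01) and backward elimination (ΔOFV > 10.828, p < 0.001)
  with a full audit trace (`stepwise_select()`).
- **Validation** — nonparametric subject-level bootstrap (`bootstrap_pk()`)
  and (prediction-corrected) visual predictive checks (`vpc_pk()`).
- **Simulation** — Monte Carlo day-3 trough concentrations on dose ×
  covariate grids, probability of target attainment for the 5–10 ng/mL
  window and dose recommendation (`simulate_troughs()`, `pta_table()`,
  `recommend_dose()`, `heatmap_table()`), plus published reference trough
  tables and a covariate-family calibration utility
  (`reference_troughs()`, `calibrate_covariate_family()`,
  `compare_to_reference()`).
- **Synthetic cohorts** — a study-like generator with known ground truth
  (`generate_cohort()`) and a parameter-recovery experiment
  (`recovery_experiment()`).
- **Orchestration** — one-call analysis runs writing self-describing
  artifact directories (`run_config()`, `pk_run()`) and a command-line
  wrapper at `inst/cli/tacropk.R`.

## Quick start

```r
library(tacropk)

## 1. A synthetic 19-subject cohort from the published final-model truth
coh <- generate_cohort(seed = 1)

## 2. Fit the final covariate model
spec <- model_spec(effects = c("vrc_v", "vrc_cl", "crea_v"))
fit  <- fit_pk(spec, coh$data)
fit$estimates          # estimates, SEs, CV%, 95% CIs
fit$ofv; fit$aic; fit$bic

## 3. Stepwise covariate selection from scratch
sel <- stepwise_select(model_spec(),
                       c("vrc_v", "vrc_cl", "crea_v", "crea_cl"),
                       coh$data)
sel$selected; sel$trace

## 4. Validate
boot <- bootstrap_pk(coh$data, spec, n_resamples = 200)
vpc  <- vpc_pk(fit, n_sim = 500)

## 5. Simulate day-3 troughs and recommend a dose
tab <- pta_table(final_model_parameters(), c_vrc = c(0, 1, 3, 5),
                 doses = seq(0.5, 5.5, 0.5))
recommend_dose(tab)
```

Command line:

```sh
Rscript inst/cli/tacropk.R generate --out run1 --seed 1
Rscript inst/cli/tacropk.R fit --out run1-fit --data run1/dataset.csv
Rscript inst/cli/tacropk.R recommend --out run1-rec
```

Every subcommand writes `config.json` and `log.txt` next to its outputs so
a run can be reproduced exactly.

## Data format

Rectangular event records (NONMEM-style CSV): `ID, TIME, AMT, DV, EVID,
CVRC, CREA`, one row per dose (`EVID = 1`) or observation (`EVID = 0`);
`"."` is read as missing; extra columns (e.g. `CYP3A5`, `CYP2C19`) are
carried through. See `read_pk_dataset()` for the validated invariants.

## Known limitations

- The day-3 trough is defined literally (six q12h doses, sampled at 72 h);
  published simulation tables appear closer to steady state, so absolute
  cell means are not reproduced — `compare_to_reference()` and
  `calibrate_covariate_family()` quantify the deviation per covariate
  family instead.
- With trough-dominated sampling under accumulation, covariate effects on
  V/F (and ω²_V) are weakly identified; see the methods vignette for the
  sensitivity analysis.
- One residual-error model at a time (additive by default; proportional
  available), no covariance between the V and CL random effects.

## Learn more

The methods vignette (`vignettes/methods.Rmd`) derives the closed-form
kinetics, the Laplace objective and the simulation machinery, and reports
the identifiability analysis for the volume-side covariate effects.
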