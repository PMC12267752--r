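# ventswitch

Phenotyping the switch from controlled to assisted mechanical ventilation
in granular ICU event logs.

In hypoxemic respiratory failure, the transition from fully controlled
ventilation to assisted (patient-triggered) ventilation is a pivotal,
unstandardized decision: switching too early risks patient self-inflicted
lung injury, switching too late prolongs sedation and ventilation. Studying
this moment retrospectively requires heavy event-log machinery before any
statistics can happen — raw ventilator-mode labels differ per center and
ventilator, assist-control ("combined") modes are ambiguous between
controlled and assisted breathing, and abrupt sub-hour mode changes are
artifacts of procedures rather than genuine switch attempts. `ventswitch`
implements that machinery as a tested, reusable pipeline for
epidemiologists and intensivists working with ICU databases:

* **Mode harmonization** — per-center dialect mapping into
  {CONTROLLED, COMBINED, ASSISTED, CPAP, NONINVASIVE_OR_NONE};
  combined-mode reassignment by the nearest spontaneous respiratory rate
  (assisted iff RR > 10 breaths/min); CPAP reassignment by invasive status;
  a ≥ 1 h persistence filter on transitions.
* **Switch-attempt detection and labeling** — the first
  CONTROLLED→ASSISTED transition per stay; *failure* = return to controlled
  ventilation or death within 72 h, *success* otherwise.
* **Peri-switch features** — derived PaO₂/FiO₂, driving pressure
  ΔP = P_plat − PEEP and compliance C_RS = V_T/ΔP via nearest-prior pairing
  (≤ 1 h); 12 h windowed LOCF before the attempt; Δ_h changes after it.
* **Endpoints** — 28-day mortality, ventilator-free days (VFD-28),
  ventilation duration, ICU length of stay, and the
  fraction-still-assisted follow-up curve.
* **Statistics** — χ²/Fisher and Wilcoxon/t group comparisons;
  PEEP-stratified (≤5, 6–10, >10 cmH₂O) distributions with a mixed-effects
  logistic interaction test (random intercept per center, LRT).
* **Prediction** — L1-penalized logistic models of switch failure
  (pre-switch; pre-switch + Δ_3h) with nested cross-validated AUC and
  variable-group contributions.
* **A synthetic multi-center generator** with known ground truth — three
  mode-label dialects, per-center logging grids, per-variable missingness,
  a latent readiness process, a logistic failure mechanism on true
  pre-switch features (computable Bayes AUC), and a lognormal
  time-to-failure with median 8 h — so the whole pipeline is testable
  without access to restricted ICU databases.

## Worked example

```r
library(ventswitch)

cfg <- cohort_config(n_patients = 400, seed = 5)
res <- run_pipeline(run_config(synthetic = cfg, seed = 5), out_dir = "run1")

as.data.frame(res$flow)[c("n_eligible", "n_attempted", "n_success",
                          "n_failure", "pct_failure")]
#>   n_eligible n_attempted n_success n_failure pct_failure
#> 1        363         340       105       235    69.11765

head(res$before_table[, c("variable", "success", "failure", "p_value")], 4)
#>           variable          success          failure      p_value
#> 1      base_excess    2.9 (1.3-4.4)   0.8 (-0.9-2.9) 6.548854e-10
#> 2              crs 42.2 (37.2-48.4) 37.8 (32.6-43.0) 3.543038e-06
#> 3 driving_pressure  10.5 (8.8-11.9) 11.7 (10.3-13.2) 3.124142e-07
#> 4             fio2 34.9 (30.2-39.5) 38.7 (33.7-43.5) 2.816923e-06

res$model1$auc
#> [1] 0.7346302
```

Of 363 eligible synthetic stays, 340 attempted a switch and 69% of first
attempts failed. Failed attempts show lower base excess and compliance and
higher driving pressure and FiO₂ before the switch — the directions the
generator plants — with medians (IQRs) per outcome group and Wilcoxon p
values. Model 1 discriminates failure from success with a held-out AUC of
0.73 on this synthetic cohort (real cohorts are far harder). `run1/`
additionally contains the baseline and Δ_3h tables, the
fraction-still-assisted curve, PEEP-stratified summaries with interaction
p values, a prediction JSON, and a log of every threshold and seed.

A thin CLI wraps the same functions:

```sh
Rscript inst/scripts/ventswitch.R simulate --n 1000 --seed 1 --out cohort/
Rscript inst/scripts/ventswitch.R run --input cohort/ --out results/
Rscript inst/scripts/ventswitch.R sensitivity --n 500 --out sens/
```

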