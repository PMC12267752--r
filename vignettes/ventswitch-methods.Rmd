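---
title: "Phenotyping the switch from controlled to assisted ventilation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotyping the switch from controlled to assisted ventilation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ventswitch)
```

## The problem

In patients ventilated for hypoxemic respiratory failure, the moment of
switching from controlled ventilation (every breath delivered by the
machine) to assisted ventilation (breaths triggered by the patient) is a
critical and poorly standardized decision. A switch attempted too early can
expose an injured lung to vigorous spontaneous effort (patient self-inflicted
lung injury); a switch delayed too long prolongs sedation, muscle weakness
and ventilation itself. `ventswitch` implements the full observational
machinery needed to study this transition in granular ICU event logs:
harmonizing heterogeneous ventilator-mode labels, detecting switch attempts,
labeling their outcome, extracting peri-switch physiology, computing
endpoints, comparing outcome groups, and fitting failure-prediction models.
Because the source databases of such studies are access-restricted, the
package ships a synthetic multi-center event-log generator with known ground
truth, so that every stage of the pipeline is verifiable end to end.

## Mode harmonization

Raw ventilator-mode labels differ between centers, ventilator parks and
charting systems. Each center supplies a *dialect*: a total map from raw
labels to five functional categories — `CONTROLLED` (no patient-triggered
breaths), `COMBINED` (assist-control: patient-triggered breaths besides
mandatory breaths), `ASSISTED` (only patient-triggered breaths), `CPAP`,
and `NONINVASIVE_OR_NONE`. Three further rules produce an unambiguous
controlled/assisted timeline:

1. **Combined modes** are ambiguous about who is breathing. Each combined
   record is reassigned to `ASSISTED` when the spontaneous respiratory rate
   nearest its start (within ±1 h) is strictly above 10 breaths/min,
   indicating active patient effort, and to `CONTROLLED` otherwise. When no
   spontaneous rate is available within tolerance the record is
   conservatively classified `CONTROLLED`: fabricating a switch attempt is
   the worse error, and the choice is visible in the segment provenance.
   The total (set) respiratory rate is never used as a stand-in. A segment
   is resolved by the measurement nearest its *start*: the reference point
   within the segment is a free choice, and the start is where the
   classification decision matters.
2. **CPAP** delivered through an invasive airway is spontaneous breathing
   and becomes `ASSISTED`; CPAP outside invasive ventilation becomes
   `NONINVASIVE_OR_NONE`. A segment straddling extubation is split at the
   boundary.
3. **Persistence filtering**: a transition counts only if the patient stays
   in the new category for at least 1 h (inclusive — a run of exactly 1.0 h
   survives). Shorter runs, e.g. a brief mode change for a bronchoscopy,
   are merged left-to-right into the surrounding category, re-checking
   durations after each merge; the first run of an invasive interval is the
   starting mode, not a transition, and is kept regardless of duration.
   This rule is deterministic and order-stable, and the test suite checks
   it against an independent brute-force enumeration of the merge rule.

Time is real-valued hours since ICU admission and every interval is
half-open `[start, end)`, so category boundaries are never double-counted.
Timelines are built by carrying each logged category forward to the next
log, extubation, or stay end.

## Attempts, outcomes, endpoints

A *switch attempt* is a `CONTROLLED`→`ASSISTED` boundary on the filtered
timeline within invasive ventilation. The first attempt per stay is labeled:
**failure** if a controlled segment (surviving the persistence filter)
begins within 72 h of the attempt, or the patient dies within 72 h without
an earlier return; **success** otherwise. Events at exactly +72 h count as
inside the window (the boundary convention is configurable; the definition
itself does not pin it down). Liberation from the ventilator and discharge
alive before 72 h of follow-up count as success — the definition is "did
not return to controlled ventilation while alive", and a liberated patient
did not return. Attempts whose assisted side exists only through
combined-mode reassignment are typed `rr_change`; all others `mode_change`.

Cohort eligibility mirrors the study design: at least one PaO~2~/FiO~2~
below 300 mmHg in the first 48 h of intubation, at least 48 h of invasive
ventilation, a controlled first mode, and a first ICU stay.

Endpoints per stay: 28-day mortality (anchored at ICU admission; the anchor
is not stated in the source convention and is config-exposed),
ventilator-free days by day 28 in the standard convention (0 on death
before day 28, otherwise 28 minus invasive days accrued to day 28, floored
at 0), total duration of ventilation, and ICU length of stay.

## Peri-switch features

Derived parameters pair a primary measurement with the *nearest prior*
partner within 1 h (simultaneous timestamps count as prior, matching common
charting): PaO~2~/FiO~2~ = PaO~2~ / (FiO~2~/100); driving pressure
ΔP = P~plat~ − PEEP; compliance C~RS~ = V~T~ / ΔP. No point is emitted
without a partner within tolerance — there is no silent extrapolation.
FiO~2~ values at or below 1.0 are treated as fractions and rescaled to
percent on ingest, with a warning.

Pre-switch features use windowed last-observation-carried-forward: the most
recent value in the closed window `[attempt − 12 h, attempt]` (the anchor
itself is pre-switch). Post-switch changes are
Δ~h~ = (latest value in `(attempt, attempt + h]`) − (LOCF pre value), so a
positive Δ is an increase after the switch; Δ exists only when both sides
do. For the Δ analysis, patients who failed or were liberated within the
horizon are excluded; shrinking horizons can only grow this retained set,
which supports the 1–8 h sensitivity sweep. Before-switch variables are
dropped when missing for at least two-thirds of patients (the source rule's
"missing for two-thirds" is read as an inclusive threshold and is
config-exposed); Δ variables are kept when available for at least one-third
(inclusive). No imputation is performed in the comparisons; per-variable
missingness is reported by outcome group to flag complete-case bias.

## Group comparison and the PEEP interaction

Proportions are compared by χ² (Fisher's exact test when any expected cell
is below 5), continuous variables by Wilcoxon rank-sum (medians and
type-7 interpolated IQRs) or Welch's t (means and SDs) — the Δ tables use
the t test, matching their mean (SD) presentation. P values are two-sided
and not multiplicity-adjusted, matching per-variable reporting practice.

Because PaO~2~/FiO~2~ and C~RS~ depend on the set PEEP, their distributions
are stratified by the PEEP paired to the specific measurement (nearest
prior PEEP, not a daily mean) into ≤5, 6–10 and >10 cmH~2~O. Effect
modification is tested by a mixed-effects logistic regression of switch
success on the standardized variable, the PEEP stratum and their
interaction, with a random intercept per center, using a likelihood-ratio
test of the interaction terms (Laplace approximation; with a single center
the model reduces to plain logistic regression, and the two agree exactly in
that case by construction). Strata containing a single outcome class are
dropped with a warning. The random-intercept-only structure and the LRT are
this package's choice — the exact supplementary specification of the source
model is not public. Calibration is checked by simulation: under a null
with center random effects the test's type-I error at α = 0.05 is measured
over 500 replicates of n = 1500, and its power against an effect present
only in the >10 cmH~2~O stratum over 200 replicates of n = 2000.

## Failure prediction

Two L1-penalized logistic models predict failure of the first attempt:
model 1 from pre-switch features, model 2 additionally from Δ~3h~ features
on the 3 h-survivor subset. Continuous features are median-imputed with
paired missingness-indicator columns (the simplest defensible scheme;
iterative imputation is a known alternative and the imputation is
config-switchable); zero-variance columns are dropped. Performance is the
AUC of *held-out* predictions in a nested cross-validation: 5 outer folds
stratified by outcome, penalty chosen per outer fold by 5-fold inner
cross-validation; standardization is learned inside each training fit.
Variable-group contributions are the AUC drop after removing a group
(gas exchange, ventilatory, inflammatory, other) and refitting with the
same folds. The AUC itself is the Mann–Whitney rank statistic, cross-checked
in the tests against `survival::concordance`.

## The synthetic generator

The generator emulates the *statistical structure* the analyses rely on,
not ICU physiology:

* **Three centers** with distinct mode-label dialects (≥ 10 labels each,
  including combined and CPAP labels so every mapping branch is exercised),
  distinct logging grids (e.g. ventilator parameters every 1–2 h, blood
  gases every 4–6 h, labs daily), and per-variable missingness thinning.
* **A latent severity** per patient that improves over the stay; the switch
  attempt occurs at a lognormal readiness time (median ≈ 1.45 days,
  occasionally premature), so earlier attempts see sicker physiology.
* **A logistic failure mechanism** on the *true* (noise-free) pre-switch
  PaO~2~/FiO~2~, PEEP, base excess, lactate and ΔP, with measurement noise
  added only afterwards. This makes the Bayes-optimal AUC computable — it
  is the AUC of the true failure probability itself — giving prediction an
  exact oracle. The intercept is set so that about two-thirds of first
  attempts fail, the failure rate reported for this transition.
* **Time to failure** lognormal with median 8 h and sdlog 1.15 (chosen to
  reproduce the reported 4–19 h interquartile range), truncated to
  `[1, 72]` h: above 72 h a return is by definition a success, and below
  1 h a return is removed by the persistence rule and is not a genuine
  attempt. Failures return to a controlled mode (or die, for a minority)
  at that delay; failed stays then make a Poisson number of secondary
  attempts.
* **28-day mortality** drawn from a logistic model with a log-odds shift
  for failed attempts (16% vs 27% at the defaults) and a large shift for
  the never-switched group; deaths of successful switches are placed after
  attempt + 72 h so they cannot contradict the label. Because eligibility
  (≥ 48 h of ventilation) preferentially removes early failure-deaths, the
  observed mortality contrast in an eligible cohort sits somewhat below the
  generating 27%.

Mode changes are logged at the moment they occur plus periodic re-logs, so
attempt times are exactly recoverable; what sparse logging degrades is the
combined-mode reassignment and feature availability. What the generator
does *not* emulate: autocorrelated physiologic drift beyond a linear trend,
informative (outcome-dependent) missingness unless configured, clinician
behavior, re-intubation episodes, and inter-variable dynamics beyond the
shared severity — so passing tests demonstrate the pipeline's correctness
under the assumed structure, not clinical validity on real data.

`inject_combined_modes()` overwrites a chosen fraction of mode records with
combined labels and emits spontaneous-RR measurements consistent with the
ground truth, to exercise the reassignment path; at full injection and
dense logging the downstream pipeline recovers the original timeline on
over 99% of segments.

## Numerical choices and degenerate inputs

* Nearest-measurement searches use a ±1 h tolerance everywhere, with exact
  ties resolved to the earlier point; "prior" includes equal timestamps.
* FiO~2~ ≤ 0, negative ΔP, and ΔP = 0 in the compliance derivation are
  skipped with warnings rather than propagated.
* An invasive interval with no mode record raises `vs_missing_mode_data`;
  unknown labels raise `vs_unknown_mode_label` in strict mode and map to
  `NONINVASIVE_OR_NONE` with a warning otherwise.
* Zero patients produce empty tables, not errors; a constant outcome or a
  degenerate design matrix is an error in the prediction stage.
* Quartiles are type-7 (linear interpolation) throughout; the convention is
  stated because sources rarely print theirs.
* All randomness flows from explicit integer seeds; identical configuration
  and seed reproduce every table byte-for-byte.

## Problem sizes in the test suite

The packaged checks run the detector-fidelity comparison on 1000 dense
fully-observed stays, the persistence-filter oracle on 1000 random segment
sequences, prediction calibration on 2000 (null) and 5000 (Bayes recovery)
patients, interaction-test calibration on 500 null and 200 alternative
replicates, and the generator's time-to-failure check on 5000 patients —
sizes at which binomial/sampling error is well inside each check's stated
band.

## Known limitations

Only the first attempt's outcome is labeled (secondary attempts are counted
but not labeled). Eligibility screening, like the underlying definition,
assumes intubation times are trustworthy. The mixed model treats PEEP
strata as categorical and adjusts for nothing else. The generator's
missingness is non-informative by default, which is the favorable case for
complete-case comparisons.
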