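---
title: "Quantifying ART adherence and predicting virological outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ART adherence and predicting virological outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adherekit)
library(dplyr)
```

## The problem

Incomplete adherence to antiretroviral therapy (ART) drives virological
failure and the selection of drug-resistance mutations, yet no single
adherence measure is a gold standard. Treatment programmes — especially in
resource-limited settings — have several imperfect instruments at hand:
what the patient says, what the pharmacy dispensed, what came back in the
pill bottle, what is in the blood, and (where available) what an electronic
pillbox recorded. These instruments disagree systematically: self-report is
optimistic, refill-based measures can exceed 100%, electronic monitors
undercount. `adherekit` implements the six standard estimators on a common
per-protocol evaluation frame, models each measure's association with
landmark virological failure and genotypic resistance, and compares their
predictive performance with ROC/AUC methods. A seeded synthetic cohort
generator with retained ground truth makes every step testable without
access to participant data.

## Evaluation frame: landmarks and per-protocol windows

All analyses are anchored to two landmarks after ART start
(randomisation): **week 16** and **week 48**. A participant contributes to
a landmark only if an HIV-RNA result falls inside that landmark's window —
days 84–140 (weeks 12–20) for week 16, days 224–448 (weeks 32–64) for
week 48. No outcome is imputed for anyone else (per-protocol). When
several results qualify, the one closest to the nominal day (112 or 336)
is used, ties going to the earlier date; the choice is flagged in the
output.

Failure thresholds are landmark-specific: HIV-RNA **>400 copies/ml at
week 16** and **>40 copies/ml at week 48**. Resistance is defined among
genotyped samples (amplification requires >500 copies/ml) as carriage of
at least one major mutation affecting at least one drug in the regimen;
the mutation→drug map is user-supplied configuration
(`resistance_rule()`), with a default covering the common first-line
mutations (K65R→tenofovir, M184V/I→lamivudine/emtricitabine, and the NNRTI
set for efavirenz/nevirapine).

All day arithmetic is half-open `[start, end)`: "days between" two dates is
their integer difference, applied identically everywhere. Cumulative
measures run from randomisation to the landmark viral-load date, truncated
at the end-of-care date if earlier.

## The six estimators

**Self-report (SR).** Percent of the last three days reported dosed
("Did you swallow your pills yesterday / 2 days ago / 3 days ago?"):
values in {0, 33.3, 66.7, 100}. A "yes" day counts as fully dosed even on
twice-daily regimens, because the question is asked per day. Missing any
answer yields an absent estimate, never zero.

**Clinic pill count (CPC).** `(tablets dispensed − tablets returned) /
(days in interval × doses per day)`, over the interval since the most
recent dispensing (about one month before week 16, two before week 48,
following the dispensing schedule rather than a fixed constant). Only the
anchor drug (efavirenz, nevirapine, or lopinavir/r after a switch) is
counted. Values above 100% are possible and kept; more tablets returned
than dispensed implies undisclosed home stock and is flagged.

**Pharmacy refill, average (PR-average).** Days of anchor-drug supply
dispensed in `[randomisation, VL date)` divided by days in care. Early
refills accumulate, so the measure is unbounded above — its excess over
100% is informative about refill behaviour, not an error.

**Pharmacy refill, gaps (PR-gaps).** A daily possession ledger
(`build_stock_ledger()`): each dispensing adds its days of supply to the
stock on hand, each day consumes one day of supply if any is available,
and a day with no possible possession is a *medication-free day*. Surplus
carries forward without cap — possession accumulates, so an early refill
never creates a gap. Adherence is `(period − medication-free days) /
period`, bounded in [0, 100]. This is the only refill measure sensitive to
the *timing* of refills rather than just their total.

**Electronic monitoring (EAMD).** A monitor day runs 06:00→05:59 (a
03:00 opening credits the previous day — late-evening dosing is common).
A day with no heartbeat signal, or whose minimum reported battery voltage
is below the threshold (default 3660 device units), is censored as a
dead-battery day. Otherwise the day is adherent if the box was opened at
least once in its window. Cumulative adherence is adherent days over days
in care **minus censored days**: the device being dead is not evidence of
non-adherence, so censored days leave the denominator. Since this reading
is not the only defensible one, the full-denominator variant is reported
alongside (`value_full_denominator`), along with the censored count and
fraction.

**Therapeutic drug monitoring (TDM).** Mid-dosing-interval efavirenz
concentration in mg/L, flagged against the inclusive therapeutic range
1–4 mg/L. Models use log10 concentration (the raw distribution is heavily
right-skewed); undetectable/zero values are floored at a configurable
0.05 mg/L before the transform, since log10(0) is undefined and the
assay's information below the detection limit is only "low".

Estimates are kept at full precision internally and rounded (1 d.p.) only
for presentation.

## Outcome models

For each measure × landmark × outcome cell, the package fits

* a univariate logistic model of the outcome on the adherence measure in
  **10%-units**, so `exp(β)` reads as the odds ratio per 10% adherence
  increase (TDM enters as log10 concentration: OR per 1-log increase);
* a multivariable model adding the three prespecified baseline covariates:
  age, CD4 count and log10 HIV-RNA.

Estimation is plain maximum likelihood (`stats::glm`) with Wald intervals
and p-values. Complete-case per method: a participant missing one measure
drops out of that measure's models only, so each row has its own n — as
cohort tables conventionally show. Resistance cells can have single-digit
event counts, where (quasi-)complete separation is likely; a detected
separation triggers a Firth-penalized refit (`firth_logistic()`, the
Jeffreys-prior adjusted score iteration with step damping and a
ridge-guarded solve) and the cell is flagged rather than reported with an
infinite OR. Cells with fewer than five events or non-events carry a
small-sample flag. No multiple-testing adjustment is applied across the
24 cells; the table is descriptive, matching how such comparisons are
conventionally presented.

## ROC and AUC comparison

`auc_delong()` computes the AUC as the Mann–Whitney concordance
probability via placement values (ties count ½) and the DeLong variance
`var(V10)/m + var(V01)/n` for a Wald CI truncated to [0, 1]. Univariate
models are scored by their fitted probabilities, which orients "higher
score = higher risk" automatically and leaves the AUC invariant to the
monotone link — asserted against the sign-oriented raw measure in the
test-suite, and against brute-force pairwise concordance on small
instances.

`compare_auc()` performs the paired two-measure comparison on shared
subjects using the paired DeLong covariance; "non-parametric comparison"
is interpreted as paired DeLong, with a seed-fixed stratified bootstrap
(2,000 resamples by default) reported alongside as a sensitivity
analysis. With fewer than two events or two non-events the paired variance
does not exist and the comparison is reported absent rather than invented.
`compare_methods_auc()` assembles the comparison matrix against a
reference method (the electronic monitor by default).

## The synthetic cohort generator

`simulate_cohort()` emulates the *measurement processes*, not merely the
marginal distributions, because the differences between estimators live in
the measurement mechanics:

* **Dosing truth** is a per-participant two-state (dosing/gap) daily Markov
  chain, not i.i.d. Bernoulli — missed days cluster into gaps, which is
  exactly what separates PR-gaps and EAMD from averaged measures. Three
  latent classes (50% high, 30% medium, 20% low) have stationary dosing
  probabilities 0.97/0.83/0.50 and mean gap lengths of about 3/7/14 days
  (`markov_stationary_adherence()` gives the closed form used in the
  tests).
* **Dispensing** follows the standard-of-care schedule (visits at days 0,
  28, 56, 84, then every 56 days; 28-day supply early, 56-day later) with
  ±1.5-day refill jitter and class-dependent missed-visit probabilities
  (3/8/20%) — so refill-based measures correlate with the truth through
  attendance, as they do in clinics. Note that the day-84 dispensing of a
  56-day supply overhangs the week-16 landmark, inflating week-16
  PR-average well above 100%; this is the schedule's structural oversupply
  at that evaluation point, not a bug.
* **EAMD** misses pocket doses (8% of taken doses) and loses whole days to
  dead-battery episodes (start rate 0.0111/day, mean length 10 days,
  giving ≈10% censored days). Event streams carry daily heartbeats with
  battery voltages and evening-skewed opening timestamps, so the
  06:00-boundary classifier is exercised end to end.
* **Self-report** answers "yes" for a missed day with probability 0.85
  (social desirability); **pill counts** are inflated by partial pill
  dumping in a quarter of participants; **efavirenz concentration** is a
  deliberately simple log-linear function of doses in the prior three days
  plus a subject-level random effect, with optional white-coat dosing on
  the visit eve — only the rank information feeding the TDM models
  matters, so no mechanistic PK model is attempted.
* **Outcomes** are drawn from a logistic model on true cumulative
  adherence (OR 0.70 per 10%, intercept set for ≈15% week-48 failure) plus
  centred covariate effects; resistance arises only among amplifiable
  failures, with probability decreasing in adherence, and mutations are
  sampled labels from a fixed list (no sequence simulation).
* **Attrition** assigns care statuses at published cohort proportions with
  uniform end-of-care days.

Ground truth (per-day dosing) is retained (`truth`, `truth_adherence()`),
so oracle tests can compare any estimator to what actually happened — with
measurement noise switched off, EAMD and PR-gaps recover the truth
exactly, and SR is 100 exactly when the last three days were dosed.

What the generator does **not** emulate: informative attrition (dropout is
independent of adherence class), assay noise in HIV-RNA, regimen switches,
within-day dose timing effects on concentrations, and correlation between
the week-16 and week-48 failure draws beyond their shared adherence
process. Passing tests therefore show that the estimators and models
behave correctly under a realistic, known data-generating process — not
that any particular real cohort's numbers will be reproduced. Real-cohort
numbers are reproducible by depositing the participant-level streams in
the documented CSV normal form and running the identical pipeline.

## Numerical and design choices

* Ties among in-window viral loads break to the earlier date; the same
  rule picks visit-based records (self-report, pill count, TDM sample)
  nearest the nominal landmark day.
* The possession ledger is integer arithmetic throughout; its
  medication-free-day count is verified exactly against an independent
  interval-algebra oracle on 1,000 random schedules.
* The EAMD battery threshold (3660) and the 06:00 day anchor are
  configuration, not constants; classification is exact at the one-second
  boundary (05:59:59 vs 06:00:00).
* A day with an opening but no heartbeat is censored, not adherent: the
  heartbeat is the evidence the device was alive, and in practice live
  devices heartbeat daily.
* Undetectable concentrations floor at 0.05 mg/L; negative concentrations
  are a hard error, not a floored value.
* Degenerate model cells (single outcome class, constant predictor) are
  reported absent with a reason; they are never silently dropped or forced.

## Problem sizes used in the simulation studies

The packaged studies use the generator's default conditions (230
participants, 336 follow-up days). Calibration of the logistic model uses
200 replicates of n = 2,000 (bias and coverage of the per-10% OR) and 200
null replicates of n = 500 (test size); the measurement-bias ordering and
the monitor-vs-self-report AUC comparison use 200 default cohorts through
the generator's day-level summary path, which is asserted to agree exactly
with the event-level estimator pipeline.

## Limitations

Resistance cells are intrinsically tiny at these landmarks (≈10 genotyped
participants), so their ORs and AUCs are unstable even with penalized
fits — they are flagged, and should be read as directional. The PR-gaps
possession model assumes dispensed supply is the only possible source of
drug (no sharing or stockpiling before baseline). The EAMD denominator
decision (censored days removed) is one of two defensible readings; both
are computed. The 3-day recall window makes SR nearly informationless by
design — its weakness here reflects the instrument, not an implementation
artefact.
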