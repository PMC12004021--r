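---
title: "Interval-valued chronic liver disease risk from longitudinal health records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interval-valued chronic liver disease risk from longitudinal health records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clivdr)
```

## The problem

The CLivD score predicts an individual's 10-year risk of severe chronic liver
disease from sex, age, current smoking, weekly alcohol servings, waist-hip
ratio (WHR) and diabetes status, with a laboratory variant that additionally
uses gamma-glutamyl transferase (GGT). Applying such a score to routinely
collected electronic health records runs into a structural obstacle: most of
these inputs are rarely recorded in structured form, and absence of a record
is not evidence of absence (an unrecorded smoking status does not mean the
person is a non-smoker).

`clivdr` addresses this by propagating missingness as an *interval*. Every
missing input is substituted twice, once with the value that minimises risk
and once with the value that maximises it:

| input    | minimum | maximum |
|----------|---------|---------|
| WHR      | 0.7     | 1.3     |
| smoking  | false   | true    |
| alcohol (servings/week) | 0 | 49 |
| diabetes | false   | true    |
| GGT      | switch both ends to the non-GGT variant | — |

Scoring both vectors yields a risk interval `(risk_min, risk_max)`. Its width
is the precision of the assessment: fully observed inputs give width zero, an
uninformative record gives a wide interval. Patients are then categorized by
where the interval sits relative to cutoffs at 5% and 10%:

* **high** — minimum risk ≥ 10% (even the optimistic end is high);
* **low** — maximum risk < 5% (even the pessimistic end is low);
* **moderate** — minimum risk > 5% (and, by the order of checks, below 10%);
* **not specified** — the interval spans the cutoffs; no call can be made.

The decision order makes the categorization total and single-valued for every
valid interval, including the gap cases (e.g. minimum below 5% with maximum
between 5% and 10%) that a literal reading of the cutoff table leaves
uncovered; those honestly fall to *not specified*.

## The risk function and the packaged coefficients

The score has the proportional-hazards form

$$\text{risk}_{10} = 1 - S_0^{\exp(\beta^\top x)}$$

with a variant switch: when a valid GGT measurement exists the `lab` variant
(which includes a log-GGT term) is used at both interval ends; otherwise the
`nonlab` variant is used.

Coefficients are loaded from a YAML transcription file, never hard-coded, so
the transcription is auditable and replaceable
(`clivd_coefficients("your_file.yaml")`). **The packaged default,
`clivd_coefficients_synthetic.yaml`, is a synthetic stand-in**: it reproduces
the published model's functional form, input set and coefficient signs, but
its numeric values are package-chosen, calibrated once so that the reference
profile (female, age 55, non-smoker, no alcohol, WHR 1.0, no diabetes) has a
1% ten-year risk — a plausible general-population magnitude. Analyses of the
*relative* behaviour of the pipeline (interval narrowing, category movement,
scenario comparisons) are insensitive to this choice because every term is
monotone with the published sign; absolute risk levels and category counts
are not, and should not be read as clinical estimates. Users with access to
the published coefficients can drop in their own file.

Because all coefficients of interval-bounded inputs are non-negative, scoring
the minimum vector can never exceed scoring the maximum vector;
`risk_interval()` still asserts this at run time to guard against a
non-monotone user transcription.

## Eligibility screening

Risk calculation applies to ages 40-70 inclusive. The published exclusion
box says "above 40 and under 71" while the substitution table bounds age at
40 and 70; we follow the table (the window is configurable). Further
exclusions, all prefix-matched on ICD-10 families: chronic liver disease
(K70-K77, C22.0), chronic viral hepatitis (B18), and
current-abstainer-with-prior-use. The last one is genuinely ambiguous:
F10.2x (alcohol dependence) codes identify abstainers with prior use *and*
are heavy-use evidence for the alcohol approximation. Using them for both
would exclude exactly the patients the approximation helps. Default
(`abstainer_mode = "text_confirmed"`): F10.2x feeds the alcohol floor, and
triggers exclusion only when an abstinence text finding co-occurs;
`"code_only"` and `"off"` are available.

Diabetes has no published code list in this context; the package defaults to
ICD-10 E10-E14 and ICPC-2 T89/T90. A fasting glucose at or above 7 mmol/L is
an alternative diabetes criterion; below 7 rules it out (until the
measurement expires); with no evidence at all, missing is interpreted as "no
diabetes" by default (`diabetes_missing_as_false = TRUE`). Note this makes
the (false, true) diabetes substitution interval unreachable under defaults —
it re-activates when the flag is turned off.

## Parameter lifecycles

Records are dated; a 2014 weight says little about 2021. A
`lifecycle_policy()` defines validity windows: the `one_year` preset makes
measurements valid for 365 days after their date; the `infinite` preset
carries the last observation forward until superseded. Diagnoses accumulate
with infinite validity under both presets. Two interpretation choices worth
stating:

* **Forward-only validity.** A record informs only dates at or after its own
  date (a `lookback` option exists, default 0 days). Backward validity would
  let future measurements inform past risk, which is wrong for retrospective
  series.
* **Infinite means last-observation-carried-forward.** Once observed, a
  parameter never reverts to missing at a later date; the "end of document
  history" is the analysis horizon, not a validity cut-off.

Yearly series are evaluated at December 31 of each grid year (the published
per-year averages state no evaluation date; any fixed date works, and Dec 31
makes "the state of knowledge at the end of year Y" literal). Same-parameter,
same-date ties resolve to the last record in file order — deterministic and
consistent with until-the-next-measurement semantics.

## Enrichment from diagnoses and free text

Missing smoking and alcohol inputs can be bounded from other record content:

* **Diagnosis codes** (`code_mapping()`): tobacco-use codes (ICD-10 Z72.0,
  ICPC-2 P17) set smoking = true — an exact input, since the model ignores
  cigarette counts. Alcohol dependence/abuse codes (F10.x families, P15, P16)
  mark heavy use, flooring weekly servings at the Finnish THL hazardous-use
  limits — 23 for men, 12 for women — while the ceiling stays at the
  49-servings substitution default.
* **Free text** (`extract_text_findings()`): case-insensitive regex keyword
  search over Finnish clinical narrative. The alcohol patterns are the
  canonical stems for this task (negation `ei\s*\w*\s*alkohol` → category
  *none*; `runsa\w*\s*alkohol` and the withdrawal/intoxication alternation
  `vieroitus|vierotus|päihtymys|putki|katkaisu` → *heavy*; a generic use stem
  → *moderate*). The smoking stems and the intermediate alcohol category
  boundaries are package defaults, clearly editable — they are artifact
  choices, not published values. Overlapping matches resolve by priority
  (negations outrank positives), so "ei käytä alkoholia" yields exactly one
  finding.

Alcohol categories convert to serving bounds via `alcohol_categories()`; the
*heavy* category floors at the same THL limits as the diagnosis route, so the
two evidence sources agree by construction.

Merging (`merge_evidence()`) uses precedence **structured > text >
diagnosis**, most recent first within a source. Rationale: structured values
are professionally recorded exact inputs; text findings are dated
observations of a habit; diagnoses are coarse approximations. Text findings
obey the *measurement* lifecycle (habits change; a note from 2015 should
expire under a one-year policy), diagnoses the diagnosis lifecycle. Because
every enrichment bound lies inside the substitution defaults and the score is
monotone, enrichment can only narrow intervals — a property the test suite
checks cohort-wide.

## WHR availability scenarios

WHR is the score's key adiposity input and is absent from structured
registry data, so the package simulates availability counterfactuals
(`whr_scenario()` + `apply_whr_scenario()`):

* `document_coverage`: each distinct patient-event-date independently carries
  a WHR measurement with probability `coverage`. The two reference settings
  are 0.5% (parity with other physiological measurements) and 10% (high
  availability). Coverage is interpreted per event date — the closest
  available reading of "of all documents".
* `self_report_exact` / `self_report_categorical`: one WHR per patient at
  their first age-eligible event date, emulating asking the individual.

Values are drawn from sex-specific normals: male mean 0.96, female mean 0.84,
variance 0.07 — Finnish-population-representative parameters. **The
dispersion is implemented literally as a variance** (SD ≈ 0.26), which is
physiologically wide; this is flagged rather than silently corrected, and
`variance_is_sd = TRUE` reinterprets it. Draws are truncated by rejection to
the physiological range (0.3, 2.0) by default; truncation trims the lower
tail and biases the sample mean upward by about 0.005 (men) / 0.013 (women),
which the tests account for and `truncate = FALSE` removes.

Categorical self-report is modelled by `whr_bin_scheme()`: the three-bin
edges are (0.85, 1.00); the five-bin edges are (0.85, 0.93, 1.00, 1.10).
The five-bin edges deliberately *contain* the three-bin edges so that every
five-bin interval nests inside a three-bin interval, which nests inside the
full (0.7, 1.3) default — guaranteeing that finer schemes never widen any
interval and that the cohort mean risk difference is non-increasing across
{no WHR, 3-bin, 5-bin, exact}. (A non-nested five-bin grid such as
0.80/0.90/1.00/1.10 would break this containment around values like 0.87.)
Outer bins clamp to the substitution defaults; a value outside its bin's
clamped bounds widens the bound just enough to enclose it, keeping the
enclosure invariant unconditional. Exact bin boundaries for a body-type
questionnaire are not published; these edges are package defaults and fully
configurable.

## The synthetic cohort generator

No public data exist for this setting (the emulated repository is a
restricted national registry), so `generate_cohort()` is a first-class,
tested module, not a fixture. It emulates, per patient:

* **Occurrence histograms**: the number of times each structured parameter
  occurs in a patient's history is drawn from the configured class histogram
  (classes 0 / 1 / 2-5 / 6-10 / 11-15 / >15; defaults are the published
  repository proportions, e.g. ~5% of patients have at least one GGT and
  ~13% at least one fasting glucose). Within-class counts are uniform over
  the class range — only class totals are published.
* **Latent truth first**: each patient gets a latent smoker flag (22%),
  drinking category (none 15% / moderate 60% / at-risk 15% / heavy 10%) and
  diabetes flag (8%) — artifact-chosen, plausible Finnish adult rates. The
  latent truth drives both diagnosis and text emission, so end-to-end
  recovery tests are possible.
* **Diagnoses**: the published alcohol/smoking code counts are event counts;
  scaled by the repository size they become expected events per patient,
  emitted as Poisson counts from latent-compatible patients only (heavy
  drinkers, smokers). Small rates of exclusion diagnoses (K70.3, B18.2,
  C22.0) and diabetes codes exercise the screening logic.
* **Texts**: Poisson(3) notes per patient; each note mentions smoking or
  alcohol with probability 0.10 each, phrased to match the latent truth using
  the snippets the keyword table recognises, on top of neutral filler.
* **No structured WHR or weekly-alcohol events** are generated under
  defaults, mirroring their absence from the emulated repository.

Dates are uniform over 2014-01-01 to 2022-06-30; ages at period start are
uniform 18-85, sex balanced. Measurement values (heights, weights, GGT,
glucose) use plausible adult distributions — the published tables give
occurrences, not values, so these are artifact choices; fasting glucose is
drawn higher for latent diabetics so the 7 mmol/L criterion has signal.

What passing tests on this generator do **not** show about real data: real
records have care-episode structure, provider effects, informative
missingness (sicker patients are measured more), and age-dependent
measurement rates (the published histograms pool all ages, and the generator
applies them uniformly). Results here quantify the *mechanics* of interval
narrowing, not population risk distributions.

## The cohort pipeline

`cohort_risk()` composes the stages at every grid date; the evaluation
surfaces mirror the published analysis design:

* `mean_risk_difference_by_year()` — the average interval width over patients
  eligible at each year's evaluation date (a year with no eligible patients
  reports a missing, not zero, mean). Eligibility is evaluated per grid date:
  a patient enters the denominator the year they turn 40 and leaves after 70.
* `best_category_over_history()` — per patient, the grid date with the
  narrowest interval, ties broken by the latest date (the most precise and,
  among equally precise, the most current assessment); used by
  `categorize_cohort()` for per-person category counts, so a person is
  counted once even if eligible in many years.
* The four nested configurations — structured only, +diagnoses, +text,
  +WHR scenario — are monotone by construction: each adds evidence inside the
  previous bounds, so year-wise mean widths are non-increasing along the
  sequence. The test suite asserts this ordering on generated cohorts.

One qualitative reproduction worth stating precisely: with no WHR data the
minimum-risk vector always carries the WHR floor of 0.7, and under the
packaged coefficients no combination of the remaining evidence-bounded
inputs lifts the minimum risk to the 10% cutoff — so **nobody can reach the
high category without WHR information**, while enabling a WHR scenario
immediately produces high-category patients (including, as in any
simulation with an imprecise input, a few placed there by an unrepresentative
simulated value).

## Numerical choices and problem sizes

* Dates are whole calendar days; no intra-day ordering exists.
* Ages are whole years at the query date (age at last birthday).
* Interval-containment assertions use a 1e-12 absolute slack for float noise.
* The interval consistency check (`risk_min <= risk_max`) aborts rather than
  clamps: a violation means a broken coefficient file, not a data problem.
* Event files serialise numbers with 15 significant digits; the generator
  rounds emitted values (4 decimals for simulated WHR) so cohorts round-trip
  byte-exactly.
* Test problem sizes: property tests run on generated cohorts of 150-1,000
  patients over 2-8 grid dates; generator goodness-of-fit uses 5,000
  patients; WHR generator recovery uses 100,000 draws; the coverage-recovery
  check uses a cohort with at least 10,000 distinct event dates. These sizes
  put Monte-Carlo error well below the asserted tolerances (3-4 standard
  errors) while keeping the full suite under a minute.

## Known limitations

* The packaged coefficients are a labelled synthetic stand-in (above);
  absolute risks and category counts are illustrative.
* Text analysis is the configured keyword table only — no negation-scope
  parsing beyond pattern priority, no machine learning; this matches the
  constraint environment the pipeline emulates, and mislabels e.g. "has
  smoked 10 years ago" as current smoking.
* WHR is never predicted from BMI or other anthropometrics (deliberately out
  of scope; the BMI-WHR relationship is disputed as a liver-risk predictor).
* The generator emulates marginal statistics, not joint structure; see above.
* Real registry formats (HL7 CDA R2 XML) are out of scope; the line-delimited
  event format is the package's own interchange format.
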