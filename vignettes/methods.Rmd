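---
title: "Detecting documented cognitive impairments in clinical notes and analyzing their utilization burden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting documented cognitive impairments in clinical notes and analyzing their utilization burden}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cogehr)
```

`cogehr` operationalizes a retrospective cohort analysis of *documented*
cognitive impairments in schizophrenia: a rule-based extractor over
free-text notes, cohort construction over EHR and linked claims records,
and utilization comparisons between patients with and without documentation.
This vignette is the package's account of the method: what each stage
assumes, which knobs matter, what the synthetic-data generator does and does
not emulate, and where the design was genuinely open.

## 1. The extraction model

The unit of inference is the **patient-domain flag**.  A domain flag is set
when at least one sentence, in at least one note, contains a retained match
for a lexicon entry of that domain.  This is deliberately minimal: no
temporal resolution, no severity grading, no coreference across sentences.
The measurement target is therefore *documentation*, not underlying
impairment — a patient whose clinician never wrote the phrase down is
negative by construction.

### Lexicon

The bundled lexicon (`default_lexicon()`) carries 30 phrase categories in
five domains descended from the MCCB cognitive battery.  Two refinements are
baked into the domain set: social cognition is omitted (its terms are rarely
documented in notes) and visual learning is merged into verbal learning and
memory (their key terms overlap too heavily to separate in free text); the
bundled file documents the merge.  Each category label is authored into one
or more *word-level patterns*: single spaces mean "any whitespace"
(`\s+` after compilation), alternations supply simple morphological variants
("difficulty|difficulties"), and every compiled entry is wrapped in word
boundaries, so "attention" never fires inside "inattention".  Matching is
case-insensitive by default.  The file format is flat YAML so users can
extend or replace the inventory without touching code.

One entry gets special treatment.  "Insight and judgment" is a routine
mental-status-exam heading; matching the bare phrase would flag essentially
every documented exam.  By default the entry only counts when the sentence
also carries an impairment qualifier (impaired, poor, limited, fair, ...).
The gate is a toggle on `compile_lexicon()` because the opposite reading —
count the bare heading — is defensible, and corpora differ; users measuring
broad MSE-heading prevalence should disable it and expect much higher
reasoning-domain rates.

### Preprocessing and segmentation

Notes may arrive wrapped in HTML.  `strip_markup()` replaces block-level
tags with newlines *before* parsing, so "`<div>poor</div><div>memory</div>`"
can never fuse into "poormemory", then delegates tag removal and entity
decoding to the lenient libxml2 HTML parser (via xml2); a regex fallback
covers inputs the parser rejects outright.

`segment_sentences()` is a rule scanner: terminal `.`, `!`, `?` followed by
whitespace closes a sentence, newlines always close one (list items), and a
period is ignored after a known abbreviation (Dr., pt., e.g., ...).
Decimals survive for free because their period is not followed by
whitespace.  Offsets are 0-based half-open into the stripped text, and the
spans jointly cover every non-whitespace character — properties the test
suite asserts directly, because downstream audit depends on them.

### Context exclusion

Following the NegEx tradition but at sentence scope: a trigger anywhere in
the sentence excludes *all* of that sentence's mentions.  Four rule classes
apply in fixed precedence — negation, question (sentence-terminal `?`),
goal, family history — so a sentence like "Denies poor memory?" gets a
deterministic audit label (`negation`); precedence only affects the label,
never whether the mention is excluded.  The trigger vocabularies are
explicit, bundled in `exclusion_rules.yaml`, and configurable; they are a
reasonable default, not a validated clinical standard.  Excluded mentions
are kept in the mention log with their status, so every domain flag can be
traced to a retained witness sentence.

## 2. The synthetic generator

No real EHR or claims data ship with (or were used to build) this package.
The generator (`generate_dataset()`) emulates the statistical structure the
analysis assumes, with parameters collected in a YAML config
(`calibrated_config()`; `smoke_config()` is a tiny variant for fast runs).

**Documentation and domains.**  Each patient is documented (gold
`impaired = TRUE`) or not; documented patients receive at least one clean,
affirmative sentence per planted domain.  Domain targets are specified
*conditional on documentation*, because that is the denominator every
report uses.  Independent Bernoulli planting at the raw target rates would
inflate the conditional marginals by 1/P(at least one domain), so the
generator solves for the detection fraction $c$ with
$c = 1 - \prod_d (1 - t_d c)$ and plants domain $d$ with probability
$t_d c$; conditional on at least one domain, the marginal of $d$ is then
exactly $t_d$.  This calibration requires $\sum_d t_d \ge 1$ (a documented
patient has one domain on average at minimum); degenerate configs fall back
to raw planting.

**Note-count coupling.**  In the calibrated config, documentation
probability follows a logistic curve in log note count, anchored so that
patients with very thin charts (~3 notes) document at about 2.5% and very
thick charts (~70 notes) at about 52%.  This reproduces, as a generator
behaviour, the observed association between chart thickness and documented
impairment; it is a modelling choice, not a claim about mechanism.  For
fixed-prevalence experiments the mode switches to `fixed`, optionally with
`exact_counts` for exact stratum sizes (domain sets are then drawn
conditional on being non-empty, preserving the same conditional marginals).

**Decoys.**  Every note, for documented and undocumented patients alike,
may receive decoy sentences: lexicon phrases embedded under a negation,
question, goal, or family-history construction, at configurable per-note
rates (defaults 10%/4%/4%/4%).  With exclusion rules on, decoys must not
produce flags; with rules disabled, they measurably destroy precision —
the test suite checks both, which is what demonstrates the exclusion rules
do real work.

**Cohort structure.**  Eligibility is drawn explicitly per patient
(sufficient encounters, pre-index activity, exclusionary diagnosis,
under-18, continuous enrollment) and then *realized* as consistent records:
schizophrenia encounter dates, an activity-anchor visit 12+ months before
index (or deliberately not), exclusion codes timed to their rule,
occasionally a prior-to-index-type exclusion code dated *after* index (which
must not exclude), and coverage intervals with or without a post-index gap.
The cohort builder is tested for 100% agreement with these draws.

**Utilization.**  Claim counts are negative binomial with the
$(\mu, k)$ parameterization, variance $\mu + \mu^2/k$.  Group means follow
the published cohort summaries (all-cause claims decompose as outpatient +
pharmacy + ER + inpatient: 45.0 + 37.8 + 1.43 + 0.36 ≈ 84.6 in the
documented group, 40.3 + 35.9 + 1.38 + 0.32 ≈ 77.9 in the undocumented);
dispersions are simulation choices (size 4 for high-volume streams, 1 for
admissions/ER, chosen to give realistic overdispersion).  Relapse episodes
are not drawn directly: ER claims carry a psychiatric primary diagnosis at a
group-specific fraction and inpatient claims a primary schizophrenia /
schizoaffective code at 50%, so that the *detector* recovers the target
relapse means (0.43/0.39) from claim content.  Impairment affects claims
only through the group-specific parameters — there is no individual latent
severity, because only group summaries exist to calibrate against.

**What the generator does not emulate.**  Real clinical language (notes are
templated sentences plus neutral fillers); within-patient correlation
across utilization streams (drawn independently given group); misspellings
and OCR noise; coding practice drift over calendar time; record-linkage
error.  Passing tests on this corpus shows the pipeline implements its
rules correctly and recovers known structure — it does not certify
extraction accuracy on real notes.  Two smaller accounting notes:
treatment-pattern indicators are drawn independently per service, so the
derived any-psychosocial / any-psychiatric-pharmacy rates sit slightly
above their calibration sources (which reported the "any" rows directly);
and therapy sessions are realized as labelled outpatient claims, capped by
the patient's outpatient count.

## 3. Cohort construction

Defaults in `cohort_criteria()`: index window 2016-01-01 to 2022-02-28;
index at the first in-window schizophrenia code (prefixes `295`/`F20`,
matched on dot-stripped uppercase codes, both ICD-9 and ICD-10-CM); age
18+ at index (from birth year); at least two outpatient schizophrenia
encounters on distinct service dates on/after the window start; earliest
EHR activity (any diagnosis or note) at least 12 months before index; no
exclusionary diagnosis.  The exclusionary conditions are split by timing —
neurological insults and neurodegenerative disease (stroke, TBI, dementia,
frontotemporal disease, prion disease, MS, Parkinson's) exclude only when
coded *before* index, developmental/chronic conditions (autism, epilepsy,
intellectual disability) at any time — and the map is configurable, since
the alternative reading (everything at any time) is also plausible.

Open choices resolved here: patients with pre-window schizophrenia codes
are indexed at their first *in-window* code (the literal index definition)
rather than excluded as prevalent cases; "EHR activity" means any recorded
event, because nothing narrower is defensible from first principles; the
two qualifying encounters must fall on distinct dates (configurable);
continuous enrollment allows a 0-day gap by default with a configurable
allowance, since many claims studies permit 30-45 day gaps.  All failures
are recorded per patient, not just the first, so attrition tables and
reason audits stay consistent.

Baseline characteristics: comorbidity flags need one qualifying code in the
half-open window `[index − 12 months, index)`; BMI is the observation
closest to index within ±12 months, ties resolved to the pre-index value;
the Charlson score is consumed from the patient record as a covariate (it
is not computed from raw codes — out of scope here).

## 4. Evaluation

Quality control mirrors a manual-review design: draw a seeded simple random
sample of patients (`sample_qc_patients()`, default n = 250), compare
predicted patient-domain flags against labels, and report per-domain
precision, recall and F1 (harmonic mean; an F1 above 0.8 is the
conventional bar for good performance).  The scoring unit is the
patient-domain pair because that is the denominator of every reported
percentage.  Degenerate cells are flagged, never silently imputed: a
domain never predicted has undefined precision (`NA` with
`precision_defined = FALSE`) and F1 pinned to 0.  On synthetic data the
"manual" labels are the generator's planted truth; with confounders off,
scores must be exactly 1, and the suite enforces this.

## 5. Utilization analysis

With a fixed 12-month post-index window, per-patient-per-year rates equal
raw counts, so `pppy_metrics()` counts claims in `[index, index + 12mo)`
per type, sums inpatient days, and defines length of stay per admission
only over admitted patients (the alternative — zero-filling never-admitted
patients — would answer a different question; the choice is documented and
the metric simply excludes `NA`s from its mean).  Claims outside the window
are dropped with an audit count, not an error.

Stratified comparisons use Welch's two-sided t-test for means (robust to
unequal group sizes and variances; the plain "t-test" is underspecified)
and Pearson's chi-square without continuity correction for proportions
(configurable), with *no* multiplicity adjustment — the analysis is
explicitly descriptive, and every p-value is reported as-is.

The adjusted inpatient-admission estimate uses `MASS::glm.nb` (NB2,
log link) with the impairment indicator plus age, gender, race, region,
CCI, anxiety, bipolar disorder, depression, panic disorder, PTSD and
substance use disorder; categorical covariates take their largest level as
reference.  There is no offset because exposure is fixed at 12 months.
The fit fails loudly — non-convergence, all-zero outcomes,
single-level factors, and separation-style coefficient divergence
(|coefficient| > 15 on the log scale) are errors, never silent output.
Adjusted group rates come from marginal standardization over the cohort:
predict each patient twice (indicator forced on, then off) and average.
This estimator is invariant to covariate centering and reduces to the
stratum means when covariates carry no signal; both properties are tested.

## 6. Numerical choices and problem sizes

Seeds enter in exactly one place per run (`generate_dataset(cfg, seed)`,
`sample_qc_patients(..., seed)`); the caller's RNG stream is saved and
restored, and regeneration from a dataset manifest is byte-identical.
Dates are ISO-8601; month arithmetic clamps the day of month (Jan 31 + 1
month = Feb 28/29).  Offsets are 0-based half-open everywhere.  Percentages
are reported to one decimal; zero denominators yield `NA`, never a division.

The recovery experiments run at sizes chosen to make Monte-Carlo error
comfortably smaller than the quantities examined: 2,000 documented patients
for domain-marginal recovery (binomial SE ≈ 1 point), 5,000-patient
cohorts with 2,500 per stratum for the utilization and regression
recoveries (SE ≈ 0.015 on an admissions mean of 0.38, ≈ 0.6 on a claims
mean of 85), and 100 replicates at n = 5,000 for Wald-interval coverage.
Balanced strata are used for the regression recovery because the target is
a pair of group rates; at a realistic 22% documented prevalence the
documented stratum alone would carry irreducible Poisson-scale noise of
about 0.02 on a 0.38 mean.

## 7. Limitations

The extractor is a rule system: its recall is bounded by the lexicon, its
precision by sentence-scope exclusion (a negation anywhere in the sentence
suppresses all mentions, including genuinely affirmed ones).  The bundled
lexicon is built from category labels with light morphological expansion,
not from a corpus-derived term list, and the trigger vocabularies are
defaults rather than validated rule sets.  Synthetic validation certifies
mechanics, not real-world accuracy.  The utilization analysis is
associational; marginal standardization adjusts for measured covariates
only, and documentation itself is more likely in thicker charts, a
selection pressure the generator reproduces but no regression here removes.
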