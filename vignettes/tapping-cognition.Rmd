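---
title: "Keyboard tapping as a motor marker of cognitive performance: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Keyboard tapping as a motor marker of cognitive performance: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tapcog)
```

## The problem

Alzheimer's disease has a presymptomatic window of a decade or more during
which pathology accumulates before memory symptoms appear. Subtle decline in
hand motor control — slower, less rhythmic, less accurate repetitive
movement — is one of the few signals measurable at home with no equipment
beyond a computer keyboard. `tapcog` implements an analysis pipeline for
brief self-administered keyboard tapping tests in older community cohorts:
it extracts motor features from raw key-press logs, applies auditable
eligibility rules, and asks a single statistical question per cognitive
outcome: *do the tapping features improve prediction of the cognitive score
over and above age, sex, education and mood?*

The protocol has two tests. In the **single-key test** the participant taps
the spacebar with the dominant hand as fast as possible for 10 s, four
times. In the **alternate-key test** the participant alternates between the
"S" and ";" keys as fast as possible for 30 s, once per hand. Cognitive
performance is measured by count-valued scores: paired-associates-learning
total errors at the six-pattern stage (`paltea6`, episodic memory), spatial
working memory between-errors (`swmbe6`) and strategy (`swms`).

## Motor features

Four features are computed per block, from the key-down/key-up event times:

- **Frequency**: key presses per second — the count of key-down events
  divided by the block duration.
- **Variability** (rhythm): the sample standard deviation (n − 1
  denominator) of the natural log of inter-press intervals, where an
  interval is the difference between successive *key-down* times. The log
  makes the measure scale-free: rescaling or shifting all timestamps leaves
  it unchanged. The SD convention (sample vs population) and log base are
  not dictated by the measure itself; one documented convention is fixed
  here for reproducibility.
- **Dwell time**: mean duration, in ms, that keys are held down (key-down
  to key-up). This is the only feature that uses key-up times.
- **Accuracy**: each press scores 1 point on the expected key, 2 on a key
  physically adjacent to it, 3 otherwise; the index is the mean over
  presses, so it lies in [1, 3] and equals 1.0 exactly for perfect
  targeting. For the single-key test the expected key is always the
  spacebar. For the alternate-key test the expected sequence alternates
  between "s" and ";" and is *anchored on the first press that hits either
  target key*, advancing on every press whether or not it was correct.
  Anchoring on the participant's own starting key avoids penalizing someone
  who begins on ";" rather than "S"; advancing on every press treats a
  repeated key as one error rather than cascading errors down the block.
  Adjacency is configurable; the shipped default is a QWERTY map (keys
  bordering the spacebar, "s", and ";").

A press with no observed key-up (key still held at the block end) is
truncated to the block end and flagged, not dropped: dropping it would
silently deflate frequency, while truncation keeps dwell time defined.
Overlapping presses (next key down before the previous key up), which can
occur in alternate tapping, are permitted by the data model; all interval
arithmetic uses key-down times only, so overlap affects no feature except
through dwell.

The full feature vector per participant is 24 values: 4 features × 4
single-key blocks and 4 features × 2 alternate-key hands. Blocks are kept
separate — no within-test averaging — so block-specific effects (e.g. a
warm-up trend) remain visible to model selection. Missing blocks yield
missing cells, never zeros.

## Cohort filtering

Participants are excluded if they report cognitive symptoms (noticed
substantial memory change, dementia diagnosis, or memory-impairment
diagnosis), Parkinson's disease, multiple sclerosis, an incomplete tapping
protocol (fewer than 4 single-key blocks or a missing alternate-key hand),
or missing cognitive scores. Each excluded participant receives exactly one
reason code in a fixed priority order (symptoms > PD > MS > incomplete >
missing scores), which makes the exclusion ledger counts mutually exclusive
and reconcilable: included + per-reason counts = total. A missing answer to
any symptom or diagnosis question is a validation error, never imputed as
"no".

## The synthetic cohort generator

No participant-level data are distributed with studies of this kind, so the
package ships a fully seeded generator that emulates the published cohort
structure end to end — raw keystreams included — and is itself a tested,
first-class module.

**Demographics.** Age is truncated normal (target mean 65.8, SD 7.37,
bounds 51–89 years); sex is Bernoulli (73.1% female); education is
categorical over six levels with the published cohort proportions; HADS
anxiety and depression are rounded, floor-0 normals (means 4.28/2.90, SDs
3.55/2.72, caps at the published maxima). Because truncation and clipping
shift a normal's mean, the generator re-solves the parent location
numerically (`uniroot` on the closed-form truncated/clipped mean) so the
*realized* means hit the configured targets.

**Tapping.** Inter-press intervals are lognormal. This makes the
variability feature the literal generator parameter: the SD of log
intervals recovers `sigma_log_interval` in expectation. Participant
heterogeneity enters through lognormal mean-1 multipliers on rate, rhythm
and dwell; the rate multipliers of the different tests share 50% of their
log-variance through a single latent motor-ability factor, so single- and
alternate-key speeds correlate as they do in real cohorts. Block rates
default to the published block means (5.54/5.62/5.70/5.77 presses/s for
single-key blocks 1–4, reproducing the warm-up trend; 2.17 and 2.00/s for
dominant and non-dominant alternate-key). Because a press count over a
fixed window is a renewal process, the expected count is not exactly
`rate × duration` if the mean interval is naively set to `1/rate`; the
generator applies the first-order renewal correction (mean interval
`t/(f·t + 1/2 − cv²/2)`), which brings the realized mean frequency within
Monte-Carlo error of the target. Intervals are rounded to integer
milliseconds *as intervals* (not as cumulative times), so degenerate
configurations with zero log-interval SD produce exactly constant intervals
and exactly zero variability. Dwell times are truncated normals, released
before the next press lands and clamped at the block end (flagged). Wrong
keys are drawn per press with configurable adjacent/other probabilities;
the alternate-key variability/dwell/accuracy parameters have no published
dispersions and their defaults are plausible rather than calibrated.

**Outcomes.** Each cognitive count follows a log-linear model on centred
covariates and centred motor features, with negative-binomial noise for
`paltea6` (θ = 1.0, matching the published mean 4.40 / SD 4.80) and
`swmbe6` (θ = 1.4), and Poisson noise for `swms` — the published strategy
score is *under*-dispersed (SD 2.76 < mean 7.75), which a negative binomial
cannot produce. Counts are capped at the published observed maxima (22, 13,
13) as a convention. The default scenario injects motor effects on episodic
memory only (`sk_freq_b1` −0.20, `ak_freq_dom` −0.30 per press/s — faster
tapping, fewer errors — and `ak_var_nd` +1.50 per log-unit) and none on the
working-memory outcomes, mirroring the qualitative result pattern the
pipeline is designed to detect. The parameter-recovery test scenario lifts
the PAL cap (`cap = Inf`) so the estimator is checked against the injected
coefficients without ceiling attenuation.

**Determinism.** Every participant is drawn from an RNG substream derived
from the seed and the participant index, so a cohort can grow without
perturbing earlier participants, and the same seed reproduces the cohort
exactly. Exclusion flags (74 symptomatic, 3 PD, 8 MS, 105 incomplete by
default, in a cohort of 1359, leaving 1169 analysed) are injected into
fixed index ranges of the exchangeable cohort.

**What the generator does not emulate.** Device and browser latency,
keyboard debouncing, within-block fatigue, learning across blocks,
non-lognormal interval shapes, and any real link between demographics and
motor performance (covariates and features are independent by
construction unless coefficients are injected). Tests passing on synthetic
cohorts therefore validate the pipeline's correctness and calibration, not
the clinical effect sizes.

## Model selection

Because the motor features are transformations of the same keystream they
are strongly dependent, and per-coefficient p-values are a poor basis for
selection. Instead, for each outcome and each candidate feature set, the
engine fits **every additive subset** of the candidates (2^m models, no
interactions), always including the five fixed covariates (age, sex,
education as an unordered six-level factor, HADS depression, HADS anxiety),
and ranks models by AICc:

AIC = −2·logLik + 2k,  AICc = AIC + 2k(k+1)/(n − k − 1),

where k counts every estimated parameter — intercept, slopes, the five
education contrasts, and the negative-binomial dispersion or Gaussian scale
where present (the dispersion *is* estimated, and AICc is sensitive to k at
these n). Models within 2 AICc units of the best model are treated as
statistically equivalent. The hypothesis decision is: motor features
improve prediction of the outcome iff the covariates-only **null model**
falls *outside* the equivalence set (null ΔAICc > 2). Plain AIC is reported
alongside AICc in every table.

**Families.** Outcomes are counts, so Poisson and negative-binomial nulls
are fitted first; the negative binomial is adopted when it beats Poisson by
more than 2 AICc. On equidispersed data the NB dispersion drifts to the
Poisson boundary (θ → ∞, flagged unstable) but its AICc remains the right
comparison and the Poisson is retained. If the NB null cannot be fitted at
all, the engine falls back to a Gaussian (identity link) model and records
the fallback. Within a dredge, non-converged fits stay visible in the
table, ranked last and flagged, but never define the equivalence set —
this prevents silently optimistic decisions.

**Ties and determinism.** AICc ties break by smaller k, then by feature
names, so tables are reproducible byte for byte.

**Effect reporting.** For count families, incident rate ratios
IRR = exp(β) with exponentiated Wald bounds; IRR < 1 means fewer errors per
unit predictor increase. The reported "adjusted pseudo-R²",
1 − (residual deviance / null deviance) × (n − 1)/(n − k), is a package
convention (it reduces to the classical adjusted R² for Gaussian models
against the intercept-only null) — deviance-based R² for GLMs has no single
standard definition, and values are labelled as this convention wherever
printed.

**Enumeration scale.** The full feature sets are 16 single-key, 8
alternate-key and 24 combined candidates; 2^16 and 2^24 negative-binomial
fits are far beyond interactive use (the enumeration is exact, not
heuristic, so cost doubles per feature). `dredge_subsets()` therefore caps
m at 16 by default (raisable explicitly) and warns above 12, and
`default_feature_sets()` provides desk-scale defaults: block-1 and block-4
single-key features (8 — the first and last blocks bracket the warm-up
trend), all 8 alternate-key features, and the alternate-key features plus
block-1 frequency/variability (10) for the combined set.
`default_feature_sets(full = TRUE)` returns the complete sets for users
prepared to wait.

## Numerical and testing choices

- Problem sizes in the test suite are chosen for statistical adequacy at
  desk scale: moment checks use 4,000–10,000 draws (3-SE bands), parameter
  recovery uses n = 2000 (3-SE bounds on injected coefficients),
  null-scenario calibration uses 100 outcome replicates on a fixed n = 1000
  design (the false-positive threshold, ≥ 75% null-retention, was frozen
  from a pilot run before the tests were written), and the qualitative
  pattern check uses five seeded cohorts of n = 800, sized for roughly 90%
  per-cell power.
- The calibration replicates redraw *outcomes* on a fixed feature design:
  calibration conditional on the design matrix is the standard design for
  GLM false-positive checks and avoids regenerating raw keystreams.
- Feature extraction is validated against an independent brute-force
  reimplementation (explicit loops, no shared code) to 1e-12 relative
  tolerance on randomized small blocks, and the enumeration's ranking is
  validated against independent per-subset refits.
- Degenerate inputs: blocks with fewer than two intervals yield a missing
  variability with a warning (never an exception); empty blocks yield
  frequency 0 and missing dwell/accuracy; a zero-variance outcome is the
  documented path to the Gaussian fallback.

## Known limitations

- The adjusted pseudo-R² convention will not numerically match other
  software's GLM "R²" values.
- Negative-binomial deviances across subsets use each subset's own θ
  estimate; AICc comparisons are unaffected, but deviance-based quantities
  mix θ values.
- The exclusion priority order (symptoms > PD > MS > incomplete > missing)
  is a convention; published single-reason tallies imply mutual exclusivity
  but not an order.
- Whether printed "AIC" values in the literature are AIC or AICc is often
  ambiguous; both are reported here.
- The generator's alternate-key rhythm/dwell/accuracy parameters are
  uncalibrated defaults, flagged as such in the configuration.

## A worked run

```{r, eval = FALSE}
cfg <- run_config(sim = sim_config(seed = 42))
report <- run_study(cfg, verbose = TRUE)
report$hypothesis_matrix
write_study_report(report, "study_out")
```

The hypothesis matrix has nine cells (3 outcomes × 3 feature sets), each
with the chosen family, the null model's ΔAICc and the improvement
decision; `study_out/` receives the report, the ranked model tables, the
decision record and the exclusion ledger.
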