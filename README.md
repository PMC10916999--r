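# tapcog

Keyboard-tapping motor features as digital markers of cognitive
performance in older adults.

Subtle decline in hand motor control appears years before the memory
symptoms of Alzheimer's disease, and a computer keyboard is the one motor
sensor almost every household already owns. `tapcog` is an analysis
pipeline for brief self-administered tapping tests — 10 s single-key
(spacebar) blocks and 30 s alternate-key ("S"/";") blocks — taken by
community cohorts at home, alongside count-valued cognitive scores
(paired-associates-learning errors, spatial working memory errors and
strategy). It is aimed at biostatisticians and cognitive-aging researchers
who need the full chain from raw key events to a defensible statistical
decision, plus a seeded synthetic-cohort generator so every stage is
testable without participant data.

## What it computes

From each tapping block's key-down/key-up log, four motor features:

- **frequency** — key presses per second;
- **variability** — sample SD of ln(inter-press interval), a scale-free
  rhythm measure;
- **dwell time** — mean key-held duration (ms);
- **accuracy** — weighted targeting index: 1 point per correct key, 2 per
  adjacent key, 3 otherwise, averaged over presses (1.0 = perfect).

After auditable cohort exclusions (cognitive symptoms, PD, MS, incomplete
protocol, missing scores — one prioritized reason code each), the core
question is answered per outcome by all-subsets model selection: every
additive combination of candidate motor features is fitted as a
negative-binomial (or Poisson/Gaussian) GLM with the covariates age, sex,
education, anxiety and depression fixed in every model; models are ranked
by small-sample-corrected AIC,

    AICc = -2 logLik + 2k + 2k(k+1)/(n-k-1),

and motor features are declared to improve prediction only when the
covariates-only null model falls outside the ΔAICc < 2 equivalence set.
Effects are reported as incident rate ratios (exp(β) with Wald bounds).

## Worked example

```r
library(tapcog)

cfg <- run_config(sim = sim_config(seed = 4, n_participants = 250,
  exclusions = list(n_symptomatic = 5, n_pd = 1, n_ms = 1, n_incomplete = 8)),
  feature_sets = list(single = c("sk_freq_b1", "sk_var_b1"),
                      alternate = c("ak_freq_dom", "ak_var_nd"),
                      combined = c("sk_freq_b1", "ak_freq_dom", "ak_var_nd")))
report <- run_study(cfg)
report
#> <study_report> 235 participants analysed; 9 hypothesis cells
#> # A tibble: 9 × 5
#>   outcome feature_set family            null_delta_aicc improvement
#>   <chr>   <chr>       <chr>                       <dbl> <lgl>
#> 1 paltea6 single      negative_binomial          11.8   TRUE
#> 2 paltea6 alternate   negative_binomial          13.5   TRUE
#> 3 paltea6 combined    negative_binomial          14.6   TRUE
#> 4 swmbe6  single      negative_binomial           0     FALSE
#> 5 swmbe6  alternate   negative_binomial           0     FALSE
#> 6 swmbe6  combined    negative_binomial           0     FALSE
#> 7 swms    single      poisson                     0.541 FALSE
#> 8 swms    alternate   poisson                     0     FALSE
#> 9 swms    combined    poisson                     0.541 FALSE
```

Reading the matrix: the default synthetic scenario injects a motor link
into episodic memory (`paltea6`) only, and the pipeline recovers exactly
that shape — the null model sits more than 2 AICc units behind the best
motor model for every PAL cell (improvement), while for the working-memory
outcomes the null model is itself top-ranked or within 2 units (no
improvement). The family column shows the automatic choice: negative
binomial for the overdispersed error counts, Poisson for the
under-dispersed strategy score.

`write_study_report(report, "study_out")` writes the report, ranked model
tables, decision JSON and the per-participant exclusion ledger. A thin
command-line wrapper is installed as `exec/tapcog`
(`tapcog simulate|validate|extract|filter|analyze|run`).

The methods vignette (`vignettes/tapping-cognition.Rmd`) documents the
feature conventions, the generator's calibration and its limits, and every
numerically consequential design choice.

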