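# pgxburden

Cumulative pharmacogenetic (PGx) burden scoring and statin regimen
outcome analysis for coronary artery disease cohorts.

Statin therapy is frequently modified or abandoned within a year of
initiation, most often because of muscle symptoms. Three
statin-disposition genes carry the best-established pharmacokinetic
risk variants — *SLCO1B1* (OATP1B1 hepatic uptake), *ABCG2* (BCRP
efflux) and *CYP2C9* (metabolism) — but single variants explain little
alone. `pgxburden` implements, end to end, the analysis that asks
whether *cumulative* PGx burden shifts regimen modification,
intolerance, adherence and adverse outcomes in routine care. It is
aimed at pharmacoepidemiologists and PGx methodologists who want each
stage of such an analysis as tested, reusable functions rather than a
one-off script.

## What it computes

**The burden score.** *SLCO1B1* star alleles are defined by two sites
(c.521T>C rs4149056, c.388A>G rs2306283): \*1 = 388A-521T, \*37 =
388G-521T, \*5 = 388A-521C, \*15 = 388G-521C. The diplotype grouping
{\*1/\*1, \*1/\*37, \*37/\*37} → normal, {\*1/\*5, \*1/\*15, \*37/\*5,
\*37/\*15} → decreased, {\*5/\*5, \*5/\*15, \*15/\*15} → poor maps to
phenotype points *P*; *ABCG2* c.421C>A and *CYP2C9* (\*2/\*3, gene
level) contribute dominant carrier codes *A*, *C* ∈ {0, 1}:

    score = P + A + C ∈ [0, 4],   low burden: score ≤ 1, high: score ≥ 2

with two phenotype-point schemes (`table8_weighted`: normal 0,
decreased 2, poor 2 — the default; `text_ordinal`: 0/1/2).

**Regimen courses.** Dispensing records are classified against the
ACC/AHA low/moderate/high intensity dose ranges; the first intensity
transition defines escalation/de-escalation, with time-to-first-change
censored at 365 days; MPR = supplied days / follow-up days, adherence
at MPR ≥ 0.80.

**Outcomes.** Rule-based phenotyping: CK elevation against sex-specific
ULN (120 IU/L women, 180 IU/L men); statin intolerance as
(CK ≥ 3×ULN and (myopathy or de-escalation)) or > 3 statin switches;
composite adverse outcome = myopathy ∨ liver injury ∨ non-adherence.

**Associations.** Contingency and logistic odds ratios, multinomial
relative risk ratios (reference: no change), Cox hazard ratios with
Kaplan–Meier curves and the log-rank test, descriptive group tables —
all with Wald 95% CIs on the log scale.

**Synthetic cohorts.** `simulate_cohort()` generates seeded cohorts
with Hardy–Weinberg genotypes, 30-day dispensing trajectories, and
lognormal lab series, under configurable OR/RRR/HR effect sizes whose
recovery by the association layer is part of the test suite.

## Worked example

```r
library(pgxburden)

# the unphased SLCO1B1 double heterozygote: phase-ambiguous diplotype,
# unambiguous phenotype
call_slco1b1_diplotype(1, 1)
#> <slco_diplotype> *1/*15 | *37/*5 -> decreased

g <- data.frame(subject_id = "P001", rs4149056 = 1, rs2306283 = 1,
                rs2231142 = 1, rs1799853 = 0, rs4986893 = 0)
pgx_profiles(g)[, c("diplotypes", "phenotype", "burden_score",
                    "burden_category")]
#>      diplotypes phenotype burden_score burden_category
#> 1 *1/*15|*37/*5 decreased            3            high

# burden-by-composite contingency analysis on published reference counts
contingency_or(reference_cohort_counts()$burden_composite)
#> OR [burden_high] = 1.075 (95% CI 0.816-1.414), p = 0.6081, n = 912

# an end-to-end synthetic run at the default study conditions
run <- run_pipeline(pipeline_config(simulate =
  sim_config(n_subjects = 911, seed = 1)))
run
#> <pgx_run> 911 subjects; 911 scored; 911 analysis rows
#> OR [burden_high] = 1.052 (95% CI 0.805-1.374), p = 0.7108, n = 911
#> OR [burden_high] = 1.208 (95% CI 0.759-1.923), p = 0.4246, n = 911
#> HR [burden_high] = 1.045 (95% CI 0.790-1.382), p = 0.7565, n = 911
```

The three printed lines of the run are the unadjusted
burden-by-composite OR, the covariate-adjusted intolerance OR, and the
hazard ratio for time to first regimen change — each for high versus
low burden, hovering around the generator's configured effects (1.14
for intolerance, 1.02 for regimen change) as expected at n = 911.
`run$associations` holds the full set, e.g. the de-escalation relative
risk ratio:

```r
run$associations$multinomial[["de_escalation.burden_categoryhigh"]]
#> RRR [burden_categoryhigh] = 1.158 (95% CI 0.769-1.743), p = 0.4826, n = 911
```

A command-line wrapper is installed at
`system.file("cli", "pgxburden-pipeline.R", package = "pgxburden")`:

```sh
Rscript pgxburden-pipeline.R --config cfg.yaml --seed 1 --out outdir/
```

See `vignettes/pgx-burden-methods.Rmd` for the model, its assumptions,
every tunable threshold, and what the synthetic validation does and
does not demonstrate.

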