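---
title: "Methods: cumulative PGx burden and statin regimen outcomes"
author: "pgxburden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cumulative PGx burden and statin regimen outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgxburden)
```

## The scientific problem

Statins are the backbone of lipid-lowering therapy, yet a substantial
fraction of patients modifies or abandons the regimen within a year,
most often because of statin-associated muscle symptoms. Genetic
variation in three statin-disposition genes is the best-established
pharmacokinetic contributor: *SLCO1B1* (hepatic uptake via OATP1B1),
*ABCG2* (BCRP efflux) and *CYP2C9* (metabolic clearance of some
statins). Single variants explain little on their own, which motivates a
*cumulative* pharmacogenetic (PGx) burden score and the question this
package operationalises: does higher cumulative burden shift statin
regimen modification (escalation / de-escalation), intolerance,
adherence and adverse-outcome rates in routine care?

`pgxburden` implements every stage of that analysis as tested, reusable
code, together with a seeded synthetic-cohort generator so the whole
pipeline can be exercised and validated without patient data.

## The burden score

Five variants are used: *SLCO1B1* c.521T>C (rs4149056) and c.388A>G
(rs2306283), which jointly define the star alleles *1 (388A-521T),
*37 (388G-521T), *5 (388A-521C) and *15 (388G-521C); *ABCG2* c.421C>A
(rs2231142); and the *CYP2C9* reduced-function alleles *2 and *3.

*SLCO1B1* contributes through the diplotype-derived transporter
phenotype: normal = {\*1/\*1, \*1/\*37, \*37/\*37}, decreased =
{\*1/\*5, \*1/\*15, \*37/\*5, \*37/\*15}, poor = {\*5/\*5, \*5/\*15,
\*15/\*15}. Because every haplotype carrying 521C is reduced-function,
the phenotype depends only on the 521C dosage; the unphased double
heterozygote (two candidate diplotypes, \*1/\*15 and \*37/\*5) is
decreased-function under both phasings. `call_slco1b1_diplotype()`
therefore reports the full candidate set for transparency but never
needs phase to assign the phenotype — a property the test suite proves
by enumeration of all nine dosage combinations.

Two scoring schemes are implemented, because the score's prose
definition and its defining table genuinely differ:

| phenotype | `text_ordinal` | `table8_weighted` |
|-----------|---------------:|------------------:|
| normal    | 0 | 0 |
| decreased | 1 | 2 |
| poor      | 2 | 2 |

*ABCG2* and *CYP2C9* each contribute a dominant 0/1 carrier code
(CYP2C9 at the gene level: any *2 or *3 allele counts once). The total
score is the sum (0–4), dichotomized as low (0–1) versus high (2–4).
`table8_weighted` is the default because the tabulated definition is
presented as the score's specification; the schemes disagree exactly for
decreased-function subjects, where the single point of difference can
move a subject across the low/high boundary — which is why reports
always carry the scheme label.

Missing genotypes exclude a subject from scored analyses (with an
explicit manifest entry) rather than being imputed; the source analysis
describes no imputation, and silent imputation of a pharmacogene is the
kind of decision a pipeline should surface, not make.

The CYP2C9*3 locus is keyed internally as `CYP2C9_star3` with a
*configurable* rsID (default rs4986893, as printed in the score's
definition) because published identifiers for this allele are
inconsistent; `pgx_panel()` also matches VCF records by
chrom:pos:ref:alt as a fallback.

## Regimen courses, intensity and adherence

Dispensing records are classified against the ACC/AHA intensity
categories (expected LDL-C reduction <30% / 30–49% / ≥50%), treating the
printed dose ranges as closed intervals in mg/day. Doses covered by no
listed range (e.g. atorvastatin 30 mg, which falls between the moderate
10–20 and high 40–80 ranges) are `unclassifiable`: they are skipped for
intensity-transition detection but still count as switches. This is a
stated convention — the source analysis does not say how such doses were
handled — and it is deliberately conservative: an unclassifiable dose can
never manufacture an escalation.

The three-level modification outcome is the class of the **first**
intensity transition within follow-up (escalation if the level rises,
de-escalation if it falls), so that the class and the time-to-event
analyses refer to the same transition. Same-intensity drug or dose
switches map to no-change for the three-level outcome but increment
`switch_count`, which the intolerance rule consumes. Subjects without a
transition are censored at the end of follow-up (365 days by default).

Adherence uses the medication possession ratio: MPR = days of medication
supplied within follow-up / days of follow-up, each fill truncated at
the follow-up end, capped at 1, with adherence defined as MPR ≥ 0.80
(inclusive — 292 supplied days over 365 is exactly 0.8 and adherent).
Overlapping fills are summed without de-duplication, matching the plain
reading of the formula.

## Outcome phenotyping

Creatine kinase uses sex-specific upper limits of normal (ULN): 120 IU/L
for women, 180 IU/L for men. `ck_elevated` (≥1×ULN) is reported
separately from the intolerance criterion (≥3×ULN). The intolerance rule
is grammatically ambiguous in its source, so both readings are
implemented:

* **extended** (default): (max CK ≥ 3×ULN AND (myopathy OR
  de-escalation)) OR more than 3 statin switches — the switch route is a
  behavioural marker needing no CK data;
* **strict**: the 3×ULN elevation is required for all three sub-clauses.

Myopathy and liver injury are consumed as EHR-style diagnosis flags; no
numeric liver-injury threshold is imposed because the source defines
none (ALT/AST are carried for descriptive tables only). The composite
adverse outcome is the OR of myopathy, liver injury and non-adherence.
Missing inputs always degrade the affected clause to FALSE with a
logged note — absence of evidence never asserts an adverse outcome.

## Association layer

All effect estimates are ratios with Wald 95% confidence intervals on
the log scale: contingency and logistic odds ratios (OR), multinomial
relative risk ratios (RRR, reference = no change; `nnet::multinom`),
and Cox hazard ratios (HR, Efron ties; `survival`), with Kaplan–Meier
curves and the log-rank test for persistence. Numerical conventions:

* zero cells in a 2×2 table get the Haldane–Anscombe 0.5 correction,
  flagged, never silent;
* r×c chi-square tests use no continuity correction; Fisher's exact p is
  reported *alongside* whenever an expected cell is below 5 (simulated
  p for tables larger than 2×2);
* collinear covariates are dropped with an explicit flag; separation is
  flagged with infinite CI bounds rather than penalized away
  (a Wald SE above 15 on the log scale is treated as separation —
  ratios beyond e^15 are not distinguishable from divergence at any
  realistic cohort size);
* complete-case analysis per model, with `n_used` carried on every
  result; no multiple-testing adjustment is applied, but the manifest
  reports how many hypothesis tests a run performed;
* multinomial fits use tight convergence tolerances (`reltol` and
  `abstol` 1e-12) so that the degenerate two-class case reproduces the
  binary logistic fit to 1e-6, an identity the tests assert.

## The synthetic cohort generator

`simulate_cohort()` emulates the study conditions of a 12-month
retrospective statin cohort: its defaults are the published cohort's
printed marginals, and everything is configurable through
`sim_config()`.

* **Genotypes**: independent per-locus Hardy–Weinberg draws (the loci
  lie on chromosomes 12, 4 and 10; no LD model, matching the score's
  independence assumption). Default frequencies follow the published
  genotype marginals (521C 0.20, 388G 0.485, 421A 0.062, CYP2C9*2
  0.11, *3 0.045). The two SLCO1B1 sites are generated as phased
  haplotypes internally — so truth diplotypes exist — but emitted
  unphased, exercising the caller's ambiguity handling.
* **Dispensing**: 30-day fills over 365 days; drug mix atorvastatin
  0.614 / rosuvastatin 0.337 / pravastatin 0.024 / simvastatin 0.022 /
  fluvastatin 0.003; baseline intensity mix low 0.016 / moderate 0.446 /
  high 0.538, restricted to the levels the intensity table lists for the
  drawn drug. At a regimen change the running fill is truncated and the
  new regimen starts the same day, switching drug when the target
  intensity is unavailable for the current drug. Non-adherent subjects
  stop refilling at a uniform 30–70% of follow-up, which bounds their
  MPR below 0.8 by construction.
* **Labs and outcomes**: lognormal CK per sex (default medians 120 IU/L
  men, 80 IU/L women, sigma 0.45 — small enough that spontaneous ≥3×ULN
  excursions are rare); subjects latently designated intolerant receive
  a CK peak of 3–9×ULN plus a myopathy flag so the rule-based phenotype
  recovers the designation; lab missingness is applied last.
* **Effects**: one pseudo-random stream per component (genotypes,
  latent assignment, dispensing, labs) is split from the master seed, so
  extending one component never perturbs the others, and identical
  configurations are byte-identical. Baseline rates (escalation 0.1021,
  de-escalation 0.1142, non-adherence 0.295, myopathy 0.145, liver
  injury 0.025, latent intolerance 0.10) describe the low-burden,
  no-myopathy stratum.

The generative model for regimen change combines two scales on purpose:
class probabilities follow a multinomial logit (so configured RRRs are
exactly the parameters a multinomial fit estimates) and the time to
change follows an exponential hazard equal to the multinomial no-change
hazard scaled by `hr^high` (so a configured HR is exactly what a Cox fit
estimates). Each effect is therefore exactly recoverable when the other
effects are at 1 — which is how the parameter-recovery validation runs,
one effect at a time. When several effects are non-null simultaneously
the two scales interact and each fitted marginal estimate sits near,
but not exactly at, its configured value; the truth labels always
record the configured inputs. The latent intolerance rate has no
published value; 0.10 is a field-typical statin-intolerance prevalence,
fixed once.

Covariates (age, sex, LDL, diabetes, interacting-drug flag) are drawn
independently of the latent outcome assignment, and baseline intensity
is drawn conditional on the change class. By Bayes' rule this makes the
adjusted multinomial model (class ~ burden + intensity + ...) correctly
specified with an unchanged burden coefficient, so adjusted and
unadjusted recovery agree — a property the directional-pattern
validation exploits.

What the generator does **not** emulate: LDL trajectories under
treatment, drug–drug interaction pharmacokinetics, correlated
comorbidity structure, informative lab-ordering (in real EHR data CK is
measured *because* of symptoms), more than one regimen change per
subject, or more than three switches. Passing recovery tests therefore
demonstrate that the estimators are consistent for the generative model
the analysis assumes — not that real EHR data meet those assumptions.

## Validation problem sizes

The bundled validation uses fixed seeds throughout: coverage of
configured OR/RRR/HR ∈ {0.5, 1, 2} is checked over 20 replicates of
n = 5000 per configuration (expecting ≥ 90% CI coverage); null
calibration uses 200 replicates of n = 2000 (type-I error ≤ 0.07 at
nominal 0.05, and approximate uniformity of p-values); Hardy–Weinberg
calibration uses 20 seeds of n = 5000 across the five loci. These sizes
give Monte-Carlo error comfortably below the tolerances being asserted
while keeping the full suite fast.

## Known limitations

* The score covers only the four SLCO1B1 haplotypes the published
  diplotype table uses — no general star-allele catalogue, no activity
  scores, no CYP2C19-style extensive metabolizer framework.
* No dose-equivalence conversion across statins beyond the intensity
  categories; high-intensity simvastatin/pravastatin/fluvastatin doses
  do not exist in the table, so escalation from those drugs' top listed
  level requires a drug switch.
* Published cohort-level *adjusted* regression estimates are functions
  of that cohort's covariate structure and cannot be reproduced from
  printed summaries; the package validates direction and calibration
  under configured effects instead, and reproduces exactly the
  quantities that are functions of printed counts.
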