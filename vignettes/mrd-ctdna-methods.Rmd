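---
title: "Methods: ctDNA minimal residual disease analysis with mrdliquid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ctDNA minimal residual disease analysis with mrdliquid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrdliquid)
```

## The problem

After curative-intent resection of colorectal liver metastases, a large
fraction of patients recur, yet there is no routine biomarker that says
*which* patients harbour minimal residual disease (MRD) and should be
treated or watched more intensively. Tumor-informed circulating tumor DNA
(ctDNA) analysis addresses this: one somatic mutation is identified in the
patient's tumor tissue, and a personalized deep-sequencing assay then looks
for that exact mutation in cell-free plasma DNA at defined timepoints —
baseline before any treatment (T0), before neoadjuvant chemotherapy cycles
2–4 (TC2–TC4), 4–10 weeks after surgery (TP), at the end of adjuvant
chemotherapy (TEOT), and in follow-up.

`mrdliquid` implements the complete analysis chain for such a study —
molecular-barcode consensus calling, positivity testing, longitudinal
dynamics, and survival analysis — together with a synthetic cohort
generator so that every stage is testable end-to-end without patient data.

## Supermutant calling and MAF

Plasma sequencing at the interrogated nucleotide is error-corrected with
unique molecular identifiers (UIDs): all reads sharing a barcode descend
from one template molecule. A family is a **supermutant** only when the
mutant base is present in *strictly more than* 90% of its reads
(`call_families()`, `consensus_threshold = 0.9`); a family at exactly 90%
is ambiguous, as is any family with fewer than `min_family_reads = 2`
reads, since a single read carries no consensus information. The paper
family of assays defines the **mutant allele fraction (MAF)** as the ratio
of supermutant families to wild-type UID families (not to all families);
`compute_maf()` implements that definition, with the
mutant/(mutant+wild-type) convention available as an option.

Positivity is decided against a panel of tumor-free controls
(`positivity_test()`). The null distribution is generated by resampling:
each permutation draws a pseudo-sample of the test sample's UID depth from
the pooled control supermutant frequency and computes its MAF; the p-value
is `(1 + #[null MAF >= observed]) / (B + 1)` (add-one correction, so p is
never 0), and a sample is positive when `p < alpha` **and** at least one
supermutant was observed. Because the reference scheme for this test is not
fully specified in the source literature, binomial resampling at matched
depth is this package's concretization; with a clean control panel it
reduces to "any supermutant is significant", and with contaminated controls
it agrees with the closed-form binomial tail (verified in the tests).
`alpha` defaults to 0.01, reflecting the high specificity such assays
claim; both `alpha` and the number of permutations are configurable.

## Longitudinal dynamics

Serial MAFs are analysed on the natural-log scale. Zero MAFs are logged at
a fixed offset of 1e-6 (`log_transform_maf()`); an all-values
`log(maf + offset)` variant is available. The model (`fit_lmm()`) is a
linear mixed model of log-MAF on timepoint (categorical, T0 reference) with
a random intercept per patient, or a random slope on the cycle index, fitted
by maximum likelihood with `lme4`. The random-intercepts and random-slopes
structures are compared by AIC (`select_structure()`), ties going to the
simpler intercepts model.

Fixed-effect inference uses a hand-rolled CR1 cluster-robust sandwich
clustered on patient — the operationalization of
"heteroscedasticity-consistent" standard errors for repeated measures —
because no sandwich-estimator package is assumed. Fold changes between
timepoints (`fold_change()`) are exponentiated contrasts,
`exp(beta_from − beta_to)`, with normal-theory 95% CIs on the log scale;
fold changes compose multiplicatively across timepoints by construction.
The decline in the *detection rate* across cycles is tested with a
Cochran–Armitage trend test (`detection_trend_test()`); the source study
does not name its trend test, and the CA test ignores within-patient
correlation across cycles — a documented simplification.

A practical warning established while validating the package: with finite
UID depth, samples whose true MAF falls below roughly 1/depth are observed
as zeros and enter the model at `log(1e-6)`, which *inflates* fold-change
estimates (we measured 95%-CI coverage of the true fold dropping from
93/100 on true trajectories to 79/100 on called MAFs at depth 50,000 when
the baseline MAF spread is wide). The offset rule is kept because it is the
field's convention, but fold changes over cycles where many samples are
undetectable should be read as upper-bound-flavoured.

## Survival analysis

`build_endpoints()` constructs recurrence-free survival (RFS: recurrence
events; deaths without recurrence censored at death) and overall survival
(OS) in months from surgery (days / 30.4375). `km_estimate()` is the
product-limit estimator with the Greenwood variance of log S,
`V(t) = sum d_i / (n_i (n_i − d_i))`; `km_at()` evaluates the
right-continuous step function, flagging extrapolation beyond the observed
follow-up.

When one group has no events a Cox hazard ratio is infinite, so fixed-time
comparisons use the Klein two-sample test (`klein_fixed_time_test()`):
`Z = (log S_A(t0) − log S_B(t0)) / sqrt(V_A + V_B)` with unpooled Greenwood
variances and a two-sided normal p-value; the log transform is the default
(and only enabled) transform because it is the one named by the study
design this package follows. `rfs_table()` applies the policy: per-group KM
at 60 months, pairwise Klein tests always, Cox HRs only when both groups
have events.

`cox_fit()` maximizes the Cox partial likelihood by damped Newton with
step-halving (max 50 iterations, gradient tolerance 1e-8). Tied event
times use the **exact partial likelihood**: a tie of multiplicity d at one
time contributes `exp(sum eta_D) / e_d({exp(eta_j): j in risk set})`, where
`e_d` is the order-d elementary symmetric polynomial. `e_d` and its first
two derivatives in beta are evaluated by the add-one-member recurrence
(`esp_derivs()`), shifted by max(eta) for overflow safety — never by subset
enumeration, which the tests use as the independent oracle. Monotone
likelihood (separation) is flagged when a coefficient runs beyond |beta| >
15, rather than reporting a spurious finite HR. Breslow tie handling is
available and coincides with exact on tie-free data (tested to 1e-6).

## Cohort statistics

- `two_proportion_test()`: pooled-variance z-test, the classic
  baseline-table comparison.
- `median_test()`: K-sample equality-of-medians; values equal to the grand
  median count as "not above" (one common convention; the choice matters
  only at ties), Yates continuity correction applied for two groups.
- `bonferroni_threshold()`: alpha / comparisons, reported to 2 significant
  figures as such thresholds are quoted in clinical tables.
- `fisher_power()`: Monte-Carlo power of a two-sided Fisher exact test for
  the two-arm MRD design (default: 25 enrolled, 20% dropout → 20
  analyzable, each patient ctDNA-positive with probability 2/3, 2-year
  recurrence-free probabilities 0.20 vs 0.90, alpha 0.05). Binomial
  allocation is the default — each patient is independently positive with
  probability 2/3 — with a fixed-margin option; the design description is
  a ratio, and the binomial reading reflects how an observational cohort
  actually accrues. Identical 2×2 tables are evaluated once and reused,
  which makes 10,000 replicates take well under a second.
- `transitions_table()`: TP→TEOT positivity transitions with recurrence
  tallies (the Sankey-plot numbers); incomplete pairs are excluded with
  logged reasons.
- `maf_quartile_strata()`: baseline-MAF quartile groups with default
  cut-offs Q1 ≤ 0.15 < Q2 ≤ 1.04 < Q3 ≤ 7.2 < Q4 (percent), boundaries to
  the lower stratum.

## The synthetic cohort generator

`simulate_cohort()` generates the world the analysis assumes, not a copy of
any real dataset. Stated targets (the generator's defaults):

| quantity | default | basis |
|---|---|---|
| baseline ctDNA positivity | 0.85 | study-reported 46/54 |
| postop positivity given baseline+ | 0.28 | 12/49 overall ≈ 0.85 × 0.28 |
| baseline MAF | lognormal, median 1.86%, log-SD 2.17 | reported median / IQR 0.44–8.2% |
| per-cycle MAF decay | 0.29 | ≈40-fold over the three T0→TC4 steps |
| RFS hazards (per month) | 0.030 vs 0.005 | HR 6, 5-y RFS ≈ 17% vs 74% |
| UID depth / reads per family / error | 5000 / 15 / 1e-3 | typical barcode-assay scale |

Free parameters the sources do not state, chosen once: within-patient
log-normal noise SD 0.5 per timepoint; postoperative residual MAF lognormal
(median 0.09%, log-SD 1.5) floored at the assay's ~2-molecule scale, so
"MRD-positive" means *detectable* residual disease; adjuvant clearance
probability 0.27 (3 of 11); background (recurrence-free) death hazard
0.001/month; administrative censoring uniform over the 42-month accrual
window ending at 82 months. Neoadjuvant clearance is tied to MRD status:
patients destined to be MRD-negative clear at a cycle drawn uniformly from
{2,3,4}, while MRD-positive patients decay but stay detectable — with ~85%
baseline positivity and 28% persistence this reproduces the qualitative
staircase of detection rates across cycles. One locus per patient is
simulated (the highest-MAF tumor mutation is the assay target), and a
single global seed expands into per-patient substreams, so increasing the
cohort never reshuffles earlier patients.

What the generator does **not** emulate: baseline-negative patients never
become positive later (the rare T0−/TP+ conversion is not modelled);
clinicopathologic covariates are drawn at realistic marginals but without
the correlation structure of a real cohort (only postoperative CEA is
linked to MRD); TEOT status has no effect on the recurrence hazard, which
is keyed to postoperative status alone; and detection-rate declines during
chemotherapy are somewhat shallower than in real cohorts because assay
input depth is held constant. A green recovery test therefore establishes
that the estimators recover the stated parameters under this stated world —
not that the pipeline reproduces any particular study's patient-level
numbers, which are not publicly deposited.

## Numerical choices

- Months = days / 30.4375 throughout.
- Positivity p-values use the add-one correction; Monte-Carlo equivalence
  to the binomial tail is asserted within 3 MC standard deviations.
- Newton iterations: step-halving (max 25 halvings), gradient sup-norm
  tolerance 1e-8, separation bound |beta| > 15.
- AIC comparisons use ML (not REML) fits, as required for fixed-effect
  model comparison; singular random-slopes fits fall back to random
  intercepts with a structured warning.
- All user-facing randomness is seed-controlled, and library code restores
  the caller's RNG state.

## Worked example

```{r example, eval = FALSE}
set.seed(1)
sim <- simulate_cohort(cohort_config(n_patients = 54, seed = 7))
controls <- simulate_control_panel(10, seed = 8)
calls <- call_samples(sim$samples, controls, seed = 9)

# postoperative MRD and recurrence-free survival
ep <- build_endpoints(sim$patients)
rfs <- ep[ep$endpoint == "RFS", ]
tp <- calls[calls$timepoint == "TP", ]
status <- tp$positive[match(rfs$patient_id, tp$patient_id)]
cox_fit(rfs$time, rfs$event,
        matrix(as.numeric(status), ncol = 1,
               dimnames = list(NULL, "tp_positive")))
```

Or run everything at once:

```{r pipeline, eval = FALSE}
res <- run_pipeline(list(simulate = TRUE,
                         cohort = list(n_patients = 54),
                         controls = "simulate",
                         seed = 7, out_dir = "mrd_report"))
```

## Known limitations

- The permutation positivity scheme is a concretization; laboratories with
  a validated per-amplicon control scheme should supply their own controls
  and alpha.
- The Cochran–Armitage trend test treats per-cycle detections as
  independent binomials.
- The exact-ties Cox implementation targets clinical-scale data (risk sets
  of hundreds, tie multiplicities of a handful); it is not optimized for
  heavily grouped data with very large tie sets.
- Fold-change estimates spanning many undetectable samples inherit the
  offset-rule bias discussed above.
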