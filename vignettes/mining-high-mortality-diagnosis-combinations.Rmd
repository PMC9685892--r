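---
title: "Mining high-mortality diagnosis combinations: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining high-mortality diagnosis combinations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ihtrules)
```

## The problem and the method

Interhospital-transfer (IHT) patients — adults moved from a community
hospital to a tertiary receiving hospital for continued care — experience
markedly higher in-hospital mortality than non-transferred admissions, and
the excess is concentrated in subgroups defined by *combinations* of
diagnoses rather than by any single condition. `ihtrules` operationalizes a
rule-based approach to finding those subgroups.

Every coded diagnosis attached to a transfer episode (referring and
receiving encounters, clinical and administrative sources) is mapped to a
concept and assigned one of six subcategories — primary/admitting diagnosis
(`pdx`), problem list (`pl`), general/unassigned diagnosis (`dx`),
comorbidity (`cm`), past history (`hx`), discharge diagnosis (`ddx`) — and
flagged as a present/absent indicator per patient. The subcategory is part
of the item's identity: atrial fibrillation as an acute problem
(`pl_Atrial.Fibrillation`) and as a standing comorbidity
(`cm_Atrial.Fibrillation`) are different items, and the package never
collapses them (a precedence-based single-category mode exists behind a
flag for users whose mapping tables encode one).

Rules have the form X ⇒ death, where the antecedent X is a set of 1–4
items. With N patients, D deaths and n(X) carriers of all items in X:

* coverage(X) = n(X) / N;
* confidence(X) = deaths among carriers / n(X) — the carrier mortality rate;
* outcome lift = confidence / (D/N), the multiplicative excess over the
  cohort baseline (this is the quantity printed as "lift" in published
  rule tables of this kind, and `lift_outcome × (D/N) = confidence` holds
  exactly by construction);
* co-occurrence lift = n(X) / (N ∏ᵢ pᵢ), the textbook definition on the
  antecedent itemset — observed carriers over the count expected if the
  items occurred independently.

Both lifts are reported because the two definitions genuinely differ and
each answers a different question; column names keep them apart.

### Search

`mine_frequent_antecedents()` is a classic Apriori: levelwise candidate
generation by prefix join, pruning any candidate with an infrequent
subset (support is anti-monotone), and carrier counting by intersecting
per-item patient bitsets (packed 64-bit blocks with popcount, in C++).
The support floor is *absolute and outcome-agnostic*: an antecedent
survives if at least `min_antecedent_count` patients carry it, regardless
of how many died — the floor is a stability constraint on the antecedent,
not an effect filter. The default floor of 25 subjects and the maximum
order of 4 are the study constraints the pipeline is designed around.
Deaths among carriers are counted in the same pass, so rule metrics are
exact integer counts with no second scan. `brute_force_mine()` enumerates
every subset of up to 16 items directly and serves as the reference
semantics in the test suite; the two must agree exactly, counts included,
on every random instance.

Output order is deterministic: items are put in lexicographic name order
before mining, and ties anywhere downstream break lexicographically on the
antecedent string.

### Minimum-improvement filtering

A rule is only interesting if its mortality meaningfully exceeds what its
own sub-combinations already achieve. The improvement of X is

> 100 × (confidence(X) − max over comparison set),

where the comparison set contains the confidence of *every* proper
non-empty subset of X that met the support floor, plus the cohort baseline
(so single items are comparable — and filterable — too). The default
threshold retains rules with improvement ≥ 10 *percentage points*.

Three choices here were genuinely open:

* **Absolute vs relative margin.** "10% higher" is read as 10 percentage
  points of mortality. The canonical worked example — a pair at 72.6%
  against singletons at 25.0% and 59.3%, a margin of 13.3 points —
  passes under both readings, but the arithmetic framing ("mortality has
  to be 10% higher than any subcombination") is additive. A relative mode
  (`mode = "relative"`) is provided behind a flag.
* **All subsets vs immediate subsets.** The comparison spans the whole
  proper-subset lattice, the stricter and more literal reading. When
  confidence is monotone along the lattice the two agree; when it is not,
  all-subsets discards more.
* **Subsets below the support floor.** Their confidence is unknown under
  the mining constraints, so they are skipped and tallied
  (`n_subsets_below_floor`), never imputed.

One consequence worth stating: improvement can be negative (a
refinement can be *worse* than its best sub-rule), so a threshold of 0 is
not a no-op — it retains exactly the rules that are no worse than their
best sub-combination. The tests pin this semantics.

### Effect estimation

For each combination, the 2×2 carriage-by-death table gives the unadjusted
odds ratio (a·d)/(b·c) with a Wald 95% interval on the log scale; a table
containing a zero cell receives the Haldane–Anscombe correction (0.5 added
to all four cells) and is flagged rather than silently altered. Two zeros
in one margin leave the odds ratio undefined and raise an error.

The adjusted odds ratio comes from one logistic regression per rule —
`death ~ carrier + age + sex + race`, the combination as the main
independent variable — fitted by the package's own IRLS implementation:
per-observation initialization at (y + 0.5)/2 as in classic binomial
IRLS, weighted least squares via QR of √W·X, step-halving whenever a
Newton step increases the deviance, convergence when the deviance changes
by < 1e-8 (cap 50 iterations), standard errors from the inverse observed
information, and a separation flag when any coefficient exceeds 15 in
absolute value on the logit scale. The step-halving is not decorative: a
plain Newton path can overshoot catastrophically for rare-carrier designs
and then plateau on clamped probabilities. The test suite cross-checks
coefficients and standard errors against `stats::glm` to ~1e-7 and the
single-binary-covariate coefficient against the 2×2 log odds ratio to
1e-6 (a saturated-model identity).

Covariate coding is fixed by convention and recorded in every report: age
in years, entered linearly; sex with male as reference; race with white as
reference (levels black, other). No multiple-testing adjustment is applied
to the rule tables, matching the exploratory framing; a
Benjamini–Hochberg-adjusted p-value column for the carrier coefficient is
emitted alongside, clearly labeled as an extension.

## The synthetic cohort generator

Real transfer-episode EHR data cannot be redistributed, so the package
generates cohorts whose *relevant* structure matches the published summary
tables, with known ground truth planted for recovery tests.

**Demographics.** Age is truncated-normal (mean 63.5, SD 14.3 years) on
[21, 90], integer-rounded and top-coded at 90 — mirroring the
deidentification convention of the reference tables; sex (53.5% male) and
race (73.4% white, 22.2% black, 4.4% other) are drawn from the published
marginals. Survivor discharge dispositions are sampled from the published
proportions renormalized over non-death categories; disposition is
descriptive only.

**Items.** Presence of item *j* in patient *i* is Bernoulli with
log-odds `bⱼ + λⱼ·Zᵢ + αⱼ·(ageᵢ − 63.5)/10`, where `Zᵢ` is a single
standard-normal latent *burden* (acuity) factor. One shared factor is the
simplest mechanism that reproduces the heavy positive co-occurrence of
comorbid conditions without inventing an unreported correlation
structure; the age loadings `αⱼ` let chronic conditions accumulate with
age, which is also what makes the crude odds ratio of an age-correlated
null item exceed its adjusted one (a directional confounding check used in
the tests). `bⱼ` is solved numerically at configuration load so each
item's marginal prevalence matches its target, integrating over the latent
scale (the age contribution enters through a normal approximation of the
truncated age distribution — prevalence targets are approximate by
design).

**Catalog defaults.** The versioned default configuration
(`inst/extdata/default_cohort_config.yaml`) has 70 items spread over the
six subcategories so the per-subcategory mean counts land near the
published ones (pdx ≈ 3, pl ≈ 5, dx ≈ 8, cm ≈ 6, hx ≈ 2, ddx ≈ 1).
Prevalences of named high-risk items follow printed coverages
(cm_Acidosis 12.6%, pdx_Cardiac.Arrest 1.6%, pl_Acute.respiratory.failure
9.6%, ...); all other per-item prevalences are *plausible inventions* —
the published tables do not report them — and are labeled as such in the
configuration file. The two planted-pair items carry large burden
loadings (1.2–1.3) because the printed tables imply their joint coverage
(0.5%) is ~2.4× the independence expectation; outcome effects for the
pair members were set so their singleton carrier mortalities sit near the
printed 25.0% and 59.3%.

**Outcome.** Death is logistic with item main effects, age/sex/race
effects (0.40 per decade; +0.17 for female; race null) and planted
interaction terms γ·1{X ⊆ items}. The intercept is calibrated by
bisection on the generated sample itself so the model-implied mean death
probability equals the 11.7% target exactly; a planted interaction may
specify γ directly or a target carrier mortality, in which case γ is
solved by bisection jointly with the intercept (alternating sweeps — the
fixed point settles quickly because carriers are a small fraction of the
cohort). Bisection was chosen because it is derivative-free,
deterministic, and monotone: 100 halvings of [−30, 30] are exact to
machine precision, and an unreachable target raises a calibration error
naming the achieved rate. The default planted pair —
{cm_Acidosis, pdx_Cardiac.Arrest} at 72.6% carrier mortality — gives the
mine-and-filter pipeline a known needle: at 50,000 patients it must
surface that exact antecedent with confidence within Monte-Carlo noise of
the target and an improvement margin comfortably above 10 points.

**What the generator does not emulate.** Transfer logistics (mode,
timing), lengths of stay, costs, code-level ICD semantics (the shipped
mapping uses synthetic placeholder codes, one per item, and says so),
source/phase information content (assigned deterministically, carrying no
signal), multi-factor comorbidity structure, and any item-item interaction
in the *presence* model beyond the single burden factor. Passing tests
therefore demonstrate that the pipeline recovers structure *of the kind
the generator encodes* at realistic sizes and rates — they cannot certify
behavior on real EHR idiosyncrasies such as coding drift, source
disagreement, or informative missingness.

## Published-table consistency checks

Transcriptions of the published summary tables ship with the package
(`published_tables()`), and three arithmetic identities are checked
against them, entirely independent of simulation:

* **Baseline identity:** 1,041 deaths / 8,893 patients = 11.7% at one
  decimal.
* **Lift identity:** printed lift = printed confidence ÷ (1041/8893) at
  two decimals. Rows where the 1-d.p. printed confidence leaves the second
  lift decimal undetermined are classified `boundary` and excluded from
  strict assertion; two printed rows (lifts 6.19 and 5.80) are inconsistent
  with the identity by more than a rounding boundary and are reported as
  `mismatch` rather than asserted.
* **Odds-ratio reconstruction:** from printed coverage c% and confidence
  f%, the 2×2 cells are rebuilt as n₁ = round(cN/100), a = round(f·n₁/100),
  b = n₁ − a, c = D − a, d = N − n₁ − c, and the cross-product odds ratio
  is compared with the printed one for all rows with coverage ≥ 0.5%
  (below that, printed-percentage rounding dominates the cells).
  Agreement is measured as symmetric relative percent difference,
  200·|computed − printed|/(computed + printed) — the standard symmetric
  agreement measure for ratio-scale quantities — and must stay within 5%.
  Reconstruction from *unrounded* implied cells agrees substantially more
  tightly, which the stage-5 analysis table reports for transparency.

## Problem sizes and runtime choices

The test suite and acceptance script size their simulations as follows:
oracle-equivalence runs use 50 random 200 × 12 matrices (small enough for
exhaustive enumeration, large enough to exercise all four orders);
calibration, co-occurrence and confounding checks use cohorts of
20,000–50,000 patients (binomial noise on a rate at n = 50,000 is ~0.0014,
an order of magnitude below the 0.01 calibration tolerance being
asserted); parameter recovery uses 100 replicates of n = 5,000 with three
parameters; and the planted-recovery check mines the full default catalog
at 50,000 patients, orders 1–4, floor 25 — roughly 600,000 antecedents.
The workflow scripts under `analysis/` run the same pipeline at the study
size of 8,893.

One statistical caveat is inherent to the parameter-recovery check: the
fit's 2-standard-error coverage is nominal (~95.4%; measured 95.3–96.2%
over 1,000 replicates during development), so the minimum coverage count
across three parameters in any single 100-replicate run fluctuates
binomially, and values of 91–96 out of 100 are all compatible with a
correct estimator.

## Known limitations

* The improvement filter needs its sub-rules: antecedents whose subsets
  fell below the support floor are compared against a smaller set, which
  can only make the filter more permissive for those rules; the count of
  skipped subsets is carried on every rule so the effect is auditable.
* One regression per rule means overlapping rules are separate models;
  no joint or hierarchical modeling is attempted, and no causal reading
  is warranted — the adjusted odds ratio conditions on three demographics
  only.
* Wald intervals can be poor for very sparse cells even after the 0.5
  correction; the separation flag marks fits where the MLE is effectively
  unbounded, and flagged estimates should not be quoted.
* The synthetic generator's single latent factor produces exchangeable
  positive co-occurrence; it cannot generate negatively associated items
  or cluster-specific structure.
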