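---
title: "Methods: family-health-history risk assessment in fhhrisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: family-health-history risk assessment in fhhrisk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fhhrisk)
```

# The problem

Systematic risk assessment in primary care asks one question for every
patient: given their personal risk factors and a structured family health
history (FHH), which guideline-based screening or prevention strategies do
they meet criteria for? Answering it requires four pieces of machinery,
which this package provides end to end:

1. **Pedigree capture** — relationship-coded relative records validated
   against a closed vocabulary, scored for quality, and expanded into an
   explicit parent-linked graph;
2. **Risk calculators** — a Mendelian carrier model for the breast/ovarian
   cancer genes plus five absolute-risk equations (Gail, a Tyrer-Cuzick
   simplification, Framingham general CVD, Reynolds, and the pooled cohort
   equations), all under one eligibility and missing-data contract;
3. **A rule engine** — a three-tier guideline catalog (monogenic /
   familial / common chronic disease) evaluated deterministically with
   replayable evidence;
4. **Cohort statistics and simulation** — the familial-clustering measures
   used to describe FHH at population scale, and a seeded generator of
   realistic cohorts so every component is testable without patient data.

# Pedigree model

## Vocabulary and degrees

Relatives are coded with a closed vocabulary (parents, siblings,
half-siblings, children, grandparents, aunts/uncles, nieces/nephews,
grandchildren, cousins, with maternal/paternal sides where the code can
carry one). Degree of relationship is a pure function of the code:
parents, siblings and children are first-degree (FDR); aunts, uncles,
grandparents, nieces, nephews, grandchildren and half-siblings
second-degree (SDR); cousins third-degree (TDR). "Other" relatives are
rejected rather than guessed, because Mendelian expansion needs
unambiguous codes.

## Quality

A high-quality history records five elements: (1) each relative's
relationship and sex, (2) side of family, (3) vital status with ages,
(4) all conditions with an age of onset, and (5) at least three
generations (at a minimum parents and grandparents, which is also the
six-relative entry requirement enforced by `validate_required()`). The
five flags are evaluated independently and are monotone: removing
information can never turn a false element true. Element 4 is false when
no condition is entered at all — otherwise deleting an onset-less
condition entry would "improve" quality.

## Graph expansion

`expand_to_graph()` resolves relation codes into mother/father links,
inserting placeholder connectors where a relationship implies someone who
was never entered. The conventions are deterministic and documented on
the function: parent links always come in couples (so a lone maternal
aunt implies the mother, both maternal grandparents *and* the proband's
other parent); all full siblings share the same parent couple;
half-siblings of a side share one placeholder co-parent; all children of
the proband share one placeholder partner; nieces/nephews attach to the
first entered full sibling (else one placeholder sibling); grandchildren
to the first entered child; cousins always attach through a placeholder
aunt/uncle connector, never to an entered aunt or uncle, because the
relation code does not say whose child they are. Placeholders carry
`history_known = FALSE` and therefore contribute no phenotype information
— only transmission structure.

Consanguinity is stored and surfaced but not modelled: the likelihood
engine rejects marriage loops. Twin status is stored and exported but
identical twins are not collapsed to a single genotype node.

# The Mendelian carrier model

## Likelihood

The gene model declares autosomal-dominant susceptibility genes (default
BRCA1/BRCA2) with Hardy-Weinberg founder priors per ancestry stratum
(general / Ashkenazi) and cumulative penetrance curves per cancer, sex and
carrier class on an annual age grid (20-110), interpolated from anchor
points in YAML. Genotypes are counted in mutant-allele copies per gene;
the joint state space is the product over genes (9 states for two genes).
Carrier classes collapse states for reporting: noncarrier, one class per
gene, and `multiple` (penetrance: pointwise maximum of the carried genes'
curves).

Each individual contributes a phenotype term per modelled cancer:

* affected at onset $a$: the annual increment $F_G(a) - F_G(a-1)$ of the
  cumulative penetrance (the natural density on an annual grid), floored
  at $10^{-300}$ so an onset in a flat region of a curve cannot zero out
  an entire pedigree;
* affected with unknown onset: $F_G(c)$ at the censoring age $c$ — the
  probability of having become affected by then;
* unaffected to censoring age $c$: $1 - F_G(c)$;
* history unknown (or no ages recorded): 1.

The pedigree likelihood is computed exactly by variable elimination over
the genotype factor graph — Elston-Stewart peeling generalised to an
arbitrary loop-free elimination order, with a greedy minimum-width
heuristic. Intermediate factors are rescaled to unit maximum with the log
constant accumulated, so 70-member pedigrees cannot underflow. Families
here are at most ~75 members and loop-free, so exact inference is cheap;
exhaustive enumeration over all genotype assignments is retained as the
independent test oracle and the two agree to $10^{-9}$ on batteries of
random pedigrees.

The carrier posterior is prior x likelihood, normalised; residual
absolute risk is the posterior mixture of conditional cumulative risks
$\sum_G P(G \mid \text{FHH}) \, \frac{F_G(a+h) - F_G(a)}{1 - F_G(a)}$.

## Parameter provenance

Allele frequencies and penetrance anchors are implementer-sourced
approximations from the public carrier-model literature, shipped as
versioned, editable YAML with comments. No claim is made about the exact
penetrance vintage embedded in any particular clinical deployment; the
functional form and the inference machinery are the contract, the
numerals are configuration.

# Risk calculators

All coefficient sets live in per-calculator YAML configs. Every
calculator enforces the same contract: it is either *computed* (a percent
with two decimals, matching the usual display precision), or
*not calculated* with the missing inputs named — never an imputed number.
Missing inputs are reported before eligibility, so deleting any required
input always surfaces that input by name.

**Gail.** The relative risk is a product of published category RRs
(menarche age; biopsies with an age-50 split and an atypical-hyperplasia
multiplier; age at first live birth crossed with the affected-FDR count,
the count being computed from the pedigree). Absolute 5-year risk
composes RR(age) with a baseline composite incidence, the
attributable-risk deflator (split at 50) and competing mortality in an
annual piecewise-exponential projection. The baseline table is a
white-population approximation; other strata map to it with a warning.

**Framingham / Reynolds / PCE.** All three take the proportional-hazards
form $1 - S_0^{\exp(\sum\beta x - \sum\beta x_{\mathrm{ref}})}$,
sex-stratified (race- and sex-stratified with age interactions for the
pooled cohort equations; hsCRP and parental premature MI for Reynolds).
The 2008 *general-CVD* Framingham variant is configured by default — the
variant choice is an assumption, recorded here. One deliberate
calibration choice: each stratum's reference linear predictor is derived
at load time from a stored reference profile (mean continuous inputs,
binary factors off, untreated blood pressure) rather than taken from the
published cohort-mean linear predictor, which folds in smoking and
diabetes prevalence. This makes the exponent-zero identity — risk equals
$1 - S_0$ exactly at the reference inputs — hold by construction and
testable; the cost is that $S_0$ now anchors the non-smoking,
non-diabetic mean-risk-factor individual rather than the cohort average,
a small, documented recalibration.

**Tyrer-Cuzick (single-locus simplification).** Lifetime (to age 85,
configurable) breast-cancer risk combining (a) the Mendelian posterior
over BRCA1/BRCA2 extended with one common, dominant, low-penetrance
hypothetical locus that absorbs residual familial aggregation, and
(b) hormonal/benign-disease relative risks applied proportional-hazards
style ($F \mapsto 1-(1-F)^{RR}$) to the *non-high-risk-gene* classes
(noncarriers and hypothetical-locus carriers); the BRCA classes are
genotype-dominated and left unscaled. This is an explicit approximation
of the commercial IBIS program, not a reimplementation of it.

**Eligibility.** Breast calculators apply to women without prior breast
cancer inside their published age windows (Gail 35-85; Tyrer-Cuzick and
the BRCAPro-style lifetime score 20-85); CVD calculators inside theirs
(Framingham 30-74, Reynolds 45-80, PCE 40-79). Unknown age or sex makes
nothing applicable.

# The rule engine

Rules are declarative YAML: a tier (`monogenic`, `familial`, `common`),
a citation, and a predicate of nested `all:`/`any:` combinators over
comparison leaves. A leaf compares either a declared variable (profile
field, derived BMI, pedigree flag, or a calculator score) or a pedigree
aggregate — the count of affected individuals filtered by condition,
degree, side, sex and onset bounds. There is deliberately no general
scripting: every fired rule stores the (variable, observed, comparator,
threshold) triples that satisfied it, and `replay_evidence()` re-checks
them.

Evaluation is three-valued (Kleene): a leaf on an unknown input is
*unknown*, and a rule that cannot be decided is reported **not
evaluable**, distinct from *not met* — missingness is accounted for,
never silently dropped. Entries whose onset is unrecorded are excluded
from onset-filtered counts.

Two numeric criteria are fixed by widely printed guideline text and kept
with their printed boundary semantics: adjunct breast MRI at lifetime
breast-cancer risk strictly greater than 20%, and ASCVD-linked prevention
at 10-year risk of at least 7.5% (inclusive). Every other predicate is an
editable encoding of its cited guideline family (NCCN-style
hereditary-cancer patterns, USPSTF-style screening criteria); the engine,
not the exact clinical content, is the contract. The genetic-counseling
referral for hereditary cancer is modelled as four sub-rules (HBOC,
Lynch, FAP, PTEN) because those referrals are reported separately in
practice. The default catalog carries 19 rules — 15 line items with the
cancer referral split four ways; the strategy count is documented in the
catalog header rather than resolved, since published enumerations of
"the 18 strategies" are ambiguous.

# Cohort statistics

Two clustering measures describe a condition across a cohort of families:

* **affected families** — the proportion of families (proband included)
  with at least one affected member;
* **within family** — among affected families only, the mean (and SD) of
  each family's affected fraction. The family-size denominator includes
  the proband; that choice is not forced by any definition we know of,
  so it is documented and configurable in spirit (the functions take the
  pedigree as-is). With a single affected family the SD is defined as 0;
  with none, the result is flagged undefined rather than returned as a
  number.

Rare monogenic conditions show within >> affected (few families, strong
clustering inside them); common multifactorial conditions the reverse.
Both regimes are exercised by the simulator and asserted in tests.

Patient Activation Measure raw scores (0-100) map to the 4-level ordinal
scale through configured cut points (47.0, 55.1, 67.0; upper bounds
inclusive), the scheme used for all reported activation results; a
5-level variant sometimes described alongside it is noted as a
discrepancy in the source material and deliberately not implemented.

# The synthetic cohort generator

`simulate_cohort()` emulates the structure of patient-entered FHH data.
Its defaults are the study conditions, fixed once:

* family sizes: 7 required members plus a negative-binomial excess
  (mu 6.7, size 0.85), truncated to the 7-74 support — mean ~13.7,
  SD ~8;
* history known for 95% / 70% / 54% of FDR / SDR / TDR;
* 89.5% of condition entries carry an onset;
* labs: lipids available for ~65% of probands, blood pressure 90%,
  hsCRP 4% (the scarcity that leaves the Reynolds score mostly
  uncomputed), anthropometrics 95%;
* PAM scores Normal(70.8, 13.9) truncated to [0, 100];
* a condition mix spanning common sporadic disease (type 2 diabetes,
  coronary disease), intermediate cancers, one moderately familial
  condition (breast cancer with a 0.3%-frequency susceptibility locus)
  and one rare highly penetrant dominant syndrome, so both clustering
  regimes arise.

Ages are built parent-before-child with generation gaps of at least 15
years; relatives whose attained age exceeds their drawn death age are
recorded as deceased. Disease is modelled with constant annual hazards
from a condition-specific starting age; where a dominant locus is
specified, genotypes are gene-dropped (Hardy-Weinberg founders, Mendelian
transmission) down the expanded graph including placeholders, and
carriers swap to the carrier hazard. A family-level log-normal frailty
multiplies every member's hazard — the simplest mechanism that reproduces
the affected-vs-within-family contrast; that is a modelling choice of
this package, not a claim about any study's data-generating process.
Each family consumes an independent seed substream derived from the
master seed, so per-family output does not depend on cohort size or
generation order. Truth tables (genotypes, frailties) are emitted for
parameter-recovery tests and never read by the assessment pipeline.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: age-specific (non-constant) hazards, secular
trends, reporting error and recall bias in self-reported FHH, shared
households distinct from genetic relatedness, X-linked or recessive
inheritance, and correlated missingness (e.g. labs missing *because* the
patient is healthy).

# Numerical choices

* Penetrance anchors are linearly interpolated to the annual grid and
  forced nondecreasing (`cummax`); curves are validated at load (bounds,
  noncarrier <= carrier).
* Peeling rescales every intermediate factor to unit maximum and
  accumulates the log constant; onset-density terms are floored at
  $10^{-300}$.
* Elimination order: greedy minimum-width; exact for trees, and all
  supported pedigrees are trees after placeholder insertion.
* Risk scores are rounded to two decimals in percent at the reporting
  boundary only; monotonicity assertions therefore use non-strict
  inequalities.
* Problem sizes in the test suite are chosen to keep the default run
  under a minute of compute on one core: 200 random pedigrees of at most
  12 members for the enumeration battery (3-state model; the 9-state
  two-gene model is cross-checked at up to 6 members), a 500-family
  cohort for the rule-engine audit, 40-80 family cohorts for clustering
  and recovery properties.

# Known limitations

* The 27-condition catalog is a configurable stand-in; real intake
  vocabularies are larger and mapped by curation, which is out of scope.
* Consanguinity and identical-twin genotype sharing are stored but not
  modelled.
* Calculator coefficient sets are cited approximations in config; any
  clinical use would require replacing them with a validated, versioned
  coefficient release and local recalibration.
* The Tyrer-Cuzick simplification underestimates the variance captured by
  the full IBIS model (no polygenic tail beyond the single hypothetical
  locus, no mammographic density).
* Rule predicates encode guideline families, not any institution's exact
  clinical content; the catalog is meant to be edited.
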