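---
title: "Methods: triage logic, risk profiles and synthetic pedigrees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: triage logic, risk profiles and synthetic pedigrees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hboctriage)
```

## The screening model

`hboctriage` models the decision machinery of a two-tier (Spoke/Hub)
population screening program for hereditary breast and ovarian cancer.
The flow for one woman is:

1. **Primary questionnaire.** Every diagnosis reported in the family
   contributes 0–2 points depending on the relative's kinship position and
   on the breast-cancer age band; a total of ≥ 2 points triggers an
   invitation to the Spoke tier. Independently, seven *direct criteria*
   (male breast cancer; breast + ovarian cancer in one patient or one
   blood line; breast cancer ≤ 35; bilateral breast cancer ≤ 50;
   non-mucinous non-borderline ovarian cancer; two first-degree relatives
   with breast cancer of which one ≤ 40 or bilateral; triple-negative
   breast cancer ≤ 60) send the family straight to the Hub tier. A woman
   with her own breast cancer at 36–40 is also routed to the Spoke even
   when neither trigger fires.
2. **Spoke risk assessment.** A lifetime-risk model — externally supplied
   numbers, or the package's toy model — yields the ratio *r* of
   individual to general-population lifetime risk. Profile 1 (*r* < 2) is
   returned to population screening, profile 2 (2 ≤ *r* ≤ 3) gets an
   intermediate schedule, profile 3 (*r* > 3) is referred to the Hub.
3. **Hub evaluation.** Families satisfying at least one direct criterion
   are eligible for *BRCA1/2* testing; the most indicative alive affected
   member (index case) is tested first. Class C4/C5 variants are positive:
   carriers enter the intensive surveillance protocol, C1–C3 results fall
   back to the profile schedule.

The package treats each step as a pure function of validated inputs, so
the whole funnel is reproducible and each rule is testable in isolation.

## Kinship and the scoring grid

Relations are inferred from parent links only. The eleven grid labels are
`self`, `mother`, `sister`, `daughter`, `paternal_grandmother`,
`paternal_aunt`, `maternal_grandmother`, `maternal_aunt`,
`paternal_cousin` (daughter of the father's brother), `niece`, and the
catch-all `other`. Conventions the data do not decide for us:

- **Half-siblings count as siblings** (one shared recorded parent), for
  the proband's sisters and for the aunt/uncle steps alike. The
  questionnaire does not distinguish, and requiring both parents would
  silently drop real first-degree-like histories. First-degree *pairs*
  for the two-relatives criterion, by contrast, use the strict
  definition: parent–child, or full siblings.
- **The "niece" row is read as daughters of a sibling of the proband**;
  granddaughters map to `other`. The grid's columns describe female
  breast/ovarian age bands, and a sibling's daughter is the second-degree
  relation a family-history questionnaire ordinarily asks about.
- **Male relatives map to `other`** regardless of path; a male relative's
  breast cancer scores through a dedicated row worth 2 points at any age
  and any kinship position, so no information is lost.

Age bands are `<40` (≤ 39), `40–49` split by laterality, `50–59`, and
`≥ 60`. Three degenerate-input rules are deliberate:

- **Bilateral disease below 40 scores in the `<40` column** — laterality
  splits only the 40–49 band — and bilateral disease at 50+ scores in its
  age column. Bilateral disease is recorded as *one* diagnosis. The
  bilateral-≤ 50 direct criterion is evaluated independently of the grid,
  so the proband's bilateral cancer at, say, 45 both scores 2 points and
  fires the direct criterion; the two mechanisms are separate by design.
- **Unknown laterality in 40–49 scores as monolateral** (the lower cell),
  with a warning. This is conservative for the grid; the direct criteria
  still see the diagnosis.
- **Unknown age at onset contributes 0 points**, with a warning, rather
  than guessing a band; age-thresholded direct criteria are likewise never
  satisfied by unknown ages. Ovarian cancer scores at every age, so an
  unknown ovarian onset still scores.

## Risk profiles

The profile bands live on the *ratio* scale. Verbal band definitions of
the "so-many-times more than the population" kind leave the interval
between 1× and 2× formally unassigned, so the package fixes a documented
convention: profile 1 on `[0, 2)`, profile 2 on `[2, 3]`, profile 3 on
`(3, ∞)`. Both edges of the intermediate band are closed; 2.0 and 3.0 are
both profile 2. Classification is monotone in the ratio by construction.

The toy risk model is a multiplicative relative-risk model: lifetime risk
= baseline (default 0.10) × one factor per affected first- or
second-degree relative (defaults 2.5/1.8 for first-degree breast cancer
before/after 40, 1.5/1.2 second-degree, 2.0/1.3 for ovarian cancer),
capped at 1; unknown onset ages take the later-onset factor. The factors
are conventional familial relative risks of the right order of magnitude.
The model exists so the pipeline can run end to end and so contract
violations (outputs outside `[0, 1]`) are exercised; it is **not** a
validated risk estimator, and external per-record ratios (e.g. from a real
Tyrer-Cuzick implementation) bypass it entirely via `assess(ratio = ...)`
or the `risk_ratio` record field.

## Surveillance schedules

`build_plan()` emits age-windowed items with intervals of 6, 12 or 24
months. Two places the sources of the protocol disagree internally were
resolved as follows:

- **Profile-3 (non-carrier) ultrasound runs 25–60**, following the
  protocol table rather than the narrative "until 49": the table is the
  more specific statement of the schedule.
- **Carrier ultrasound starts at `max(18, age at detection)`** and runs
  to 69, reconciling "from 18" with "from detection".

MRI for profile 2 and non-carrier profile 3 is emitted as the opaque
`MRI_PER_EUSOMA` marker with no invented schedule (its rows carry `NA`
windows and are excluded from appointment counts). The post-mastectomy
modifier reduces breast modalities to six-monthly ultrasound (residual
post-mastectomy risk is a few percent and MRI has no established role
there); the prior-ovarian-cancer modifier replaces transvaginal
ultrasound + Ca.125 with six-monthly Ca.125 alone. The two modifiers
touch disjoint modality groups, so they commute; plans are a function of
the modifier *set*.

## Funnel accounting

Percentages are computed with exact integer arithmetic and **half-up
rounding at one decimal** (`floor((2000n + d) / 2d) / 10`); banker's
rounding was explicitly rejected because it cannot reproduce the
conventions of program reports. A zero denominator is an error, never
`NaN`. Non-attendance at each funnel step (Spoke attendance, assessment
completion, Hub attendance, test acceptance) is modelled as independent
Bernoulli draws with configurable probabilities; with all probabilities
at 1 the pipeline is deterministic, and for any fixed seed it is
reproducible. The main stage path (records → triage-eligible → arrived →
evaluated → Hub-evaluated → test-eligible → tested → carriers) is
monotonically non-increasing, and branch counts reconcile: Spoke
evaluations + refusals = attendances, and the three profiles partition
the evaluations.

The shipped `era_*.csv` tables carry the published 2012–2016 stage counts
of the Emilia-Romagna regional program as plain-text package data. They
are reporting inputs — the test suite recomputes every printed percentage
from them and reconciles the arrival table's totals — not simulation
targets.

## The synthetic population

`generate_population()` builds three-generation families: proband,
parents, four grandparents, and probabilistically present sisters,
daughters, aunts on both sides, paternal cousins (with their married-in
mother as a non-blood link node) and nieces. Founders carry a dominant
risk allele with probability `carrier_freq` (default 0.005) and each
carrier parent transmits it with probability 1/2. Cancer onset is drawn
per decade of age from piecewise-constant hazards, separately by genotype
and site; carrier hazards must dominate non-carrier hazards in every
decade (validated at configuration time). Breast diagnoses are bilateral
with probability 0.08 and triple-negative with probability 0.15; ovarian
diagnoses are mucinous or borderline with probability 0.10 each; male
breast hazards are the female hazards × 0.02.

What the defaults aim for: carrier lifetime risks of roughly 70% (breast)
and 40% (ovary) — the order of magnitude of high-penetrance alleles — and
non-carrier hazards set *below* true population incidence (roughly 6% and
1% by 80) to mimic the sparsity of family histories *as reported* in a
screening interview, so that a few percent of probands cross the grid
threshold, the order of magnitude a population program sees. Referral
sources are age-dependent: women under 45 are outside the mammography
program and can only arrive via GPs or specialists.

What the generator does **not** emulate: real demographic structure
(family sizes, cohort effects, differential mortality by cause),
penetrance curves estimated from data, phenocopies beyond the flat
non-carrier hazards, recall bias in reported ages, de-novo variants, or
any calibration to a specific region. Passing tests therefore demonstrate
the *logic* of the triage engine — scoring, routing, conservation,
Mendelian transmission, carrier enrichment — not epidemiological realism
of the simulated counts.

## Design choices on genuinely open points

- **One criterion set for direct referral and test eligibility.** The
  direct-referral list and the Hub eligibility list differ only in
  wording; both are implemented as one set with the explicit thresholds
  (≤ 35 early onset, ≤ 50 bilateral, ≤ 60 triple-negative), because that
  is the only place the thresholds are stated numerically.
- **Breast + ovary "in the family" requires both sites among blood
  relatives** of the proband; a cancer in a married-in relative never
  combines with the blood line. The proband counts as her own blood
  relative, and as a possible member of the two-first-degree-relatives
  pair.
- **Index-case ranking** beyond "alive and affected" is a documented
  heuristic (both sites in one person; non-mucinous non-borderline
  ovarian cancer; earliest breast onset; bilateral disease; proband
  first; id as a final deterministic tie-break). Programs do this by
  clinical judgement; the heuristic encodes the features that make a
  positive test most informative, and is deliberately replaceable.
- **Age 60 scores in the `≥ 60` column.** Literal band headers of the
  `50–59` / `>60` kind leave exactly age 60 unassigned; the package
  closes the gap on the high side, consistently with the ≤ 60
  triple-negative threshold being evaluated by the criteria rather than
  the grid.
- **CLI as a thin veneer.** The `inst/cli/hboctriage` script only parses
  arguments and calls exported functions, so everything reachable from
  the shell is tested through the package surface.

## Problem sizes and tolerances in the test suite

The suite exercises: grid totals against an independent cell-lookup
oracle on 1 000 randomly constructed families (each built from named
kinship slots, so true relations are known without the package's path
inference); criterion flags against straight-line predicates on the same
families; round-trips of both serialisation formats; funnel conservation
on 2 000 simulated families with partial attendance; Mendelian
transmission on ≈ 2 600 families at `carrier_freq = 0.5`, giving more
than 5 000 informative single-carrier-parent offspring, checked within
four binomial standard errors of 1/2; and carrier enrichment among
test-eligible families under default penetrance. These sizes keep the
whole suite under a couple of minutes on one core while leaving the
stochastic checks comfortably powered.

## Known limitations

- Kinship inference covers the eleven questionnaire labels; more distant
  or compound relations (double cousins, adoptive links) fall into
  `other` and score 0.
- The toy risk model ignores all personal covariates except age and is
  not calibrated; real deployments should inject external risk numbers.
- Surveillance plans are age-windowed templates; calendar scheduling,
  capacity and booking are out of scope, as are risk-reducing surgery
  decisions.
- Variant classes are inputs: no laboratory assay, and no periodic C3
  reclassification service, is modelled.
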