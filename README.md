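# hboctriage

Triage engine for regional hereditary breast and ovarian cancer (HBOC)
screening programs organised on a Spoke/Hub model.

Up to a tenth of breast cancers arise in families with a hereditary
syndrome, most often driven by germline *BRCA1/2* variants. A
population-based program cannot send every woman to genetic counseling, so
it triages: a short family-history questionnaire at the mammography visit,
a risk assessment at a local **Spoke** center for women whose score crosses
a threshold, and genetic counseling and *BRCA1/2* testing at a regional
**Hub** center for women at high risk or with a directly diagnostic family
history. `hboctriage` implements that decision machinery as reusable,
testable code:

- **Family-history data model** — proband-rooted pedigrees with breast and
  ovarian diagnoses (age at onset, laterality, triple-negative flag,
  mucinous/borderline histology), a documented JSON schema (canonical,
  shipped in `inst/extdata/pedigree-schema.json`) and a flat CSV dialect,
  with full structural validation.
- **Questionnaire grid** (`score_diagnosis()`, `total_score()`) — each
  relative's diagnosis contributes 0–2 points by kinship row and age band
  (`<40`, `40–49` split bilateral/monolateral, `50–59`, `≥60`; a single
  column for ovarian cancer at any age; male breast cancer scores 2
  everywhere). A total ≥ 2 triggers the Spoke referral.
- **Direct Hub criteria** (`direct_hub_criteria()`, `route()`) — male
  breast cancer; breast and ovarian cancer in one patient or one blood
  line; breast cancer ≤ 35; bilateral breast cancer ≤ 50; non-mucinous
  non-borderline ovarian cancer; two first-degree relatives with breast
  cancer, one ≤ 40 or bilateral; triple-negative breast cancer ≤ 60. Any
  of these bypasses the Spoke. The same set defines genetic-testing
  eligibility (`hub_test_eligibility()`), and `select_index_case()` picks
  the most indicative alive affected family member for first testing.
- **Risk profiles** (`assess()`, `classify_profile()`) — lifetime-risk
  ratio *r* against the general population: profile 1 (low, *r* < 2),
  profile 2 (intermediate, 2 ≤ *r* ≤ 3), profile 3 (high, *r* > 3,
  Hub-referable). Any model honouring the contract can supply the risks —
  e.g. an external Tyrer-Cuzick run, injected per record — and a documented
  toy multiplicative model ships for exercising the pipeline.
- **Surveillance plans** (`build_plan()`, `appointments_in_window()`) —
  per-profile schedules from population mammography (profile 1) to the
  carrier protocol (six-monthly ultrasound, annual MRI 25–74, annual
  mammography 35–69 and biennial to 74, six-monthly transvaginal
  ultrasound + Ca.125), with post-mastectomy and prior-ovarian-cancer
  modifiers.
- **Funnel accounting** (`run_pipeline()`, `percent()`,
  `tabulate_decisions()`) — stage counts over a population with
  configurable non-attendance at each step, conservation checks, and the
  one-decimal half-up percentages used in program reports.
- **Synthetic populations** (`synth_config()`, `generate_population()`) —
  three-generation pedigrees with autosomal-dominant carrier transmission
  (probability 1/2 per carrier parent) and per-decade, genotype-specific
  cancer hazards, so every pipeline stage is testable without patient
  data.

A thin command-line front end (`inst/cli/hboctriage`) exposes `score`,
`triage`, `plan`, `report` and `simulate` subcommands over the same
functions.

## Worked example

A 47-year-old woman at the mammography visit reports her mother's breast
cancer at 38:

```r
library(hboctriage)

ped <- parse_pedigree(paste(
  "id,proband,sex,age,alive,mother_id,father_id,dx_site,dx_age_at_onset,dx_laterality,dx_triple_negative,dx_mucinous,dx_borderline",
  "anna,yes,female,47,yes,carla,dario,,,,,,",
  "carla,no,female,74,yes,,,breast,38,unilateral,no,,",
  "dario,no,male,76,yes,,,,,,,,",
  sep = "\n"))

(gs <- total_score(ped))
#> <hboc_grid_score> total 2 (Spoke-eligible)
#>  individual_id relation diagnosis_index points
#>          carla   mother               1      2

route(ped, gs)$route
#> [1] "spoke"
```

The mother's early-onset cancer sits in the `<40` column of the mother
row, worth 2 points: the total reaches the ≥ 2 threshold and the woman is
invited to the Spoke (no direct Hub criterion fires — her mother was over
35, unilateral, not triple-negative, and there is no second first-degree
case). At the Spoke, the risk model places her in the intermediate
profile:

```r
(ra <- assess(ped, covariates = list(age = 47)))
#> <hboc_risk> lifetime 0.250 vs population 0.100 (ratio 2.50): profile 2

build_plan(ra$profile, carrier = FALSE, current_age = 47)
#> <hboc_plan> basis profile2, starts at 36 y
#>        modality start_age end_age interval_months                      condition
#>             MMG        40      50              12                           <NA>
#>             MMG        51      74              24           population screening
#>  MRI_PER_EUSOMA        NA      NA              NA according to EUSOMA guidelines
```

A ratio of 2.50 (toy model: one first-degree relative with onset before
40, factor 2.5 over the 0.10 population baseline) means annual mammography
from 40 and biennial from 51, with MRI per EUSOMA guidelines — not a Hub
referral, which would require ratio > 3 or a direct criterion.

Population-scale use goes through the simulator and pipeline:

```r
pop <- generate_population(synth_config(n_probands = 2000, seed = 73))
run_pipeline(pop, funnel_params(p_attend_spoke = 0.4, seed = 11))
```

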