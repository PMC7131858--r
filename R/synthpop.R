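# Synthetic screening populations: three-generation pedigrees with
# Mendelian autosomal-dominant carrier transmission and age-dependent,
# genotype-specific cancer penetrance.
#
# The generator emulates the population a regional screening program
# interviews: female probands (by default aged 45-74, the mammography
# screening window), their parents and grandparents, and probabilistically
# present sisters, daughters, aunts on both sides, paternal cousins and
# nieces. Founders (grandparents and married-in parents of cousins) carry a
# dominant risk allele with configurable frequency; each carrier parent
# transmits it with probability 1/2. Cancer onset is drawn from
# piecewise-constant hazards per decade of age, separately by genotype and
# site; these are order-of-magnitude penetrance curves, not published
# estimates.

#' Default per-decade cancer hazards by genotype and site
#'
#' Annual hazards for the eight decades of age 0-79. Carrier lifetime risks
#' are roughly 70% (breast) and 40% (ovary), the order of magnitude of
#' high-penetrance BRCA-like alleles. Non-carrier hazards (roughly 6% and
#' 1% by age 80) are deliberately set below true population incidence to
#' mimic the sparsity of family histories *as reported* at a screening
#' interview, so that a few percent of probands reach the Spoke-referral
#' grid threshold -- the order of magnitude seen in population screening --
#' without claiming demographic calibration.
#'
#' @return Nested list `penetrance[[genotype]][[site]]`, each a numeric
#'   vector of eight per-year hazards.
#' @export
default_penetrance <- function() {
  list(
    noncarrier = list(
      breast = c(0, 0, 0.0001, 0.00025, 0.0007, 0.0012, 0.0018, 0.0022),
      ovary  = c(0, 0, 0.00002, 0.00005, 0.0001, 0.0002, 0.0003, 0.0004)
    ),
    carrier = list(
      breast = c(0, 0, 0.005, 0.02, 0.03, 0.03, 0.025, 0.02),
      ovary  = c(0, 0, 0.001, 0.004, 0.012, 0.015, 0.012, 0.01)
    )
  )
}

#' Default family template
#'
#' Relative slots beyond the always-present parents and four grandparents:
#' each slot type has a maximum count `n` and an independent presence
#' probability `p` per slot.
#'
#' @return Named list of `list(n, p)` slot definitions for `sisters`,
#'   `daughters`, `aunts` (per side), `cousins` (daughters of a paternal
#'   uncle) and `nieces` (daughters of a sister).
#' @export
default_family_template <- function() {
  list(sisters = list(n = 2L, p = 0.3),
       daughters = list(n = 2L, p = 0.3),
       aunts = list(n = 2L, p = 0.2),
       cousins = list(n = 2L, p = 0.2),
       nieces = list(n = 2L, p = 0.2))
}

#' Configuration for the synthetic population generator
#'
#' @param n_probands Number of families to generate.
#' @param seed Integer seed; generation is fully deterministic given the
#'   configuration.
#' @param carrier_freq Probability that a founder carries the dominant risk
#'   allele.
#' @param penetrance Per-genotype, per-site hazards; see
#'   [default_penetrance()]. Carrier hazards must dominate non-carrier
#'   hazards in every decade.
#' @param bilateral_prob,tnbc_prob Probability that a breast diagnosis is
#'   bilateral / triple-negative.
#' @param mucinous_prob,borderline_prob Probability that an ovarian
#'   diagnosis is mucinous / borderline.
#' @param male_bc_factor Multiplier mapping female breast hazards to male
#'   breast hazards (male breast cancer is rare but diagnostic).
#' @param family_template See [default_family_template()].
#' @param proband_age_range Two integers; probands are drawn uniformly in
#'   this range (default the 45-74 screening window).
#' @return A validated object of class `hboc_synth_config`.
#' @export
synth_config <- function(n_probands = 100L, seed = 1L, carrier_freq = 0.005,
                         penetrance = default_penetrance(),
                         bilateral_prob = 0.08, tnbc_prob = 0.15,
                         mucinous_prob = 0.10, borderline_prob = 0.10,
                         male_bc_factor = 0.02,
                         family_template = default_family_template(),
                         proband_age_range = c(45L, 74L)) {
  cfg <- list(n_probands = as.integer(n_probands), seed = as.integer(seed),
              carrier_freq = carrier_freq, penetrance = penetrance,
              bilateral_prob = bilateral_prob, tnbc_prob = tnbc_prob,
              mucinous_prob = mucinous_prob,
              borderline_prob = borderline_prob,
              male_bc_factor = male_bc_factor,
              family_template = family_template,
              proband_age_range = as.integer(proband_age_range))
  bad <- character(0)
  probs <- c(carrier_freq = carrier_freq, bilateral_prob = bilateral_prob,
             tnbc_prob = tnbc_prob, mucinous_prob = mucinous_prob,
             borderline_prob = borderline_prob)
  bad <- c(bad, names(probs)[probs < 0 | probs > 1])
  if (cfg$n_probands < 0L) bad <- c(bad, "n_probands")
  if (male_bc_factor < 0) bad <- c(bad, "male_bc_factor")
  for (g in c("noncarrier", "carrier")) {
    for (s in c("breast", "ovary")) {
      h <- penetrance[[g]][[s]]
      if (is.null(h) || length(h) != 8L || any(h < 0)) {
        bad <- c(bad, sprintf("penetrance$%s$%s", g, s))
      }
    }
  }
  if (!length(bad)) {
    for (s in c("breast", "ovary")) {
      if (any(penetrance$carrier[[s]] < penetrance$noncarrier[[s]])) {
        bad <- c(bad, sprintf(
          "penetrance$carrier$%s (must dominate noncarrier in every decade)",
          s))
      }
    }
  }
  for (slot in names(family_template)) {
    tpl <- family_template[[slot]]
    if (is.null(tpl$n) || is.null(tpl$p) || tpl$n < 0 || tpl$p < 0 ||
        tpl$p > 1) {
      bad <- c(bad, sprintf("family_template$%s", slot))
    }
  }
  if (length(proband_age_range) != 2L ||
      proband_age_range[1] > proband_age_range[2] ||
      proband_age_range[1] < 18L) {
    bad <- c(bad, "proband_age_range")
  }
  if (length(bad)) {
    stop(sprintf("invalid synthetic-population config: %s",
                 paste(unique(bad), collapse = ", ")), call. = FALSE)
  }
  structure(cfg, class = "hboc_synth_config")
}

# Onset sampling from piecewise-constant per-decade hazards, up to `age`.
# Returns the onset age, or NA if no onset occurred.
sample_onset <- function(hazards, age) {
  if (age <= 0) return(NA_integer_)
  for (dec in seq_len(8L)) {
    lo <- (dec - 1L) * 10L
    if (lo >= age) break
    yrs <- min(age, lo + 10L) - lo
    h <- hazards[[dec]]
    if (h <= 0) next
    if (stats::runif(1) < 1 - exp(-h * yrs)) {
      return(lo + sample.int(yrs, 1L) - 1L)
    }
  }
  NA_integer_
}

# Diagnoses for one individual given sex, genotype and attained age.
sample_diagnoses <- function(cfg, sex, carrier, age) {
  pen <- cfg$penetrance[[if (carrier) "carrier" else "noncarrier"]]
  dxs <- list()
  bh <- pen$breast
  if (sex == "male") bh <- bh * cfg$male_bc_factor
  onset <- sample_onset(bh, age)
  if (!is.na(onset)) {
    dxs[[length(dxs) + 1L]] <- diagnosis(
      "breast", onset,
      laterality = if (stats::runif(1) < cfg$bilateral_prob) "bilateral"
        else "unilateral",
      triple_negative = if (stats::runif(1) < cfg$tnbc_prob) "yes" else "no")
  }
  if (sex == "female") {
    onset <- sample_onset(pen$ovary, age)
    if (!is.na(onset)) {
      dxs[[length(dxs) + 1L]] <- diagnosis(
        "ovary", onset,
        mucinous = if (stats::runif(1) < cfg$mucinous_prob) "yes" else "no",
        borderline = if (stats::runif(1) < cfg$borderline_prob) "yes"
          else "no")
    }
  }
  dxs
}

# Crude age-dependent survival for vital status.
sample_alive <- function(age) {
  p <- if (age < 60) 0.97 else if (age < 75) 0.88 else if (age < 85) 0.65
       else 0.3
  if (stats::runif(1) < p) "yes" else "no"
}

rint <- function(mean, sd, min = 0L) {
  max(min, as.integer(round(stats::rnorm(1, mean, sd))))
}

#' Generate a synthetic screening population
#'
#' Builds `n_probands` families from the template, draws founder genotypes,
#' transmits the allele down the pedigree (probability 1/2 per carrier
#' parent), samples diagnoses from the genotype-specific hazards, and
#' assigns a referral source by age (women under 45 are outside the
#' mammography screening program, so their questionnaires come from GPs or
#' specialists only).
#'
#' @param cfg A validated [synth_config()].
#' @return List of records ready for [run_pipeline()]: each has `pedigree`,
#'   `covariates` (list with `age`), `source`, `true_genotype`
#'   (`"carrier"` if the allele segregates among the proband's blood
#'   relatives, else `"noncarrier"`) and `genotypes` (named logical vector
#'   of individual carrier states, for transmission checks).
#' @export
generate_population <- function(cfg) {
  stopifnot(inherits(cfg, "hboc_synth_config"))
  set.seed(cfg$seed)
  lapply(seq_len(cfg$n_probands), function(i) generate_family(cfg, i))
}

generate_family <- function(cfg, fam_idx) {
  tpl <- cfg$family_template
  pid <- function(tag) sprintf("f%d_%s", fam_idx, tag)
  carrier <- new.env(parent = emptyenv())

  founder <- function() stats::runif(1) < cfg$carrier_freq
  transmit <- function(...) {
    parents <- c(...)
    any(vapply(parents, function(p) {
      isTRUE(carrier[[p]]) && stats::runif(1) < 0.5
    }, logical(1)))
  }

  page <- sample(seq(cfg$proband_age_range[1], cfg$proband_age_range[2]), 1L)
  ages <- list(
    pgf = page + rint(52, 5), pgm = page + rint(51, 5),
    mgf = page + rint(52, 5), mgm = page + rint(51, 5),
    father = page + rint(27, 4), mother = page + rint(26, 4)
  )

  for (f in c("pgf", "pgm", "mgf", "mgm")) carrier[[pid(f)]] <- founder()
  carrier[[pid("father")]] <- transmit(pid("pgf"), pid("pgm"))
  carrier[[pid("mother")]] <- transmit(pid("mgf"), pid("mgm"))
  carrier[[pid("proband")]] <- transmit(pid("father"), pid("mother"))

  inds <- list()
  push <- function(tag, sex, age, mother = NA, father = NA) {
    age <- as.integer(age)
    alive <- sample_alive(age)
    dxs <- sample_diagnoses(cfg, sex, isTRUE(carrier[[pid(tag)]]), age)
    inds[[length(inds) + 1L]] <<- individual(
      pid(tag), sex, age = age, alive = alive,
      mother_id = if (is.na(mother)) NA else pid(mother),
      father_id = if (is.na(father)) NA else pid(father),
      diagnoses = dxs)
  }

  push("pgf", "male", ages$pgf); push("pgm", "female", ages$pgm)
  push("mgf", "male", ages$mgf); push("mgm", "female", ages$mgm)
  push("father", "male", ages$father, "pgm", "pgf")
  push("mother", "female", ages$mother, "mgm", "mgf")
  push("proband", "female", page, "mother", "father")

  n_slot <- function(slot) {
    sum(stats::runif(tpl[[slot]]$n) < tpl[[slot]]$p)
  }

  sisters <- n_slot("sisters")
  for (k in seq_len(sisters)) {
    tag <- sprintf("sister%d", k)
    carrier[[pid(tag)]] <- transmit(pid("father"), pid("mother"))
    push(tag, "female", max(18L, page + rint(0, 5, min = -100L)),
         "mother", "father")
  }
  for (k in seq_len(n_slot("daughters"))) {
    tag <- sprintf("daughter%d", k)
    carrier[[pid(tag)]] <- transmit(pid("proband"))
    push(tag, "female", max(0L, page - rint(26, 4)), "proband")
  }
  for (side in c("p", "m")) {
    gm <- if (side == "p") "pgm" else "mgm"
    gf <- if (side == "p") "pgf" else "mgf"
    parent_age <- if (side == "p") ages$father else ages$mother
    for (k in seq_len(n_slot("aunts"))) {
      tag <- sprintf("%saunt%d", side, k)
      carrier[[pid(tag)]] <- transmit(pid(gf), pid(gm))
      push(tag, "female", max(18L, parent_age + rint(0, 6, min = -100L)),
           gm, gf)
    }
  }
  cousins <- n_slot("cousins")
  if (cousins > 0L) {
    carrier[[pid("puncle")]] <- transmit(pid("pgf"), pid("pgm"))
    carrier[[pid("puncle_wife")]] <- founder()
    push("puncle", "male", max(18L, ages$father + rint(0, 6, min = -100L)),
         "pgm", "pgf")
    push("puncle_wife", "female",
         max(18L, ages$father + rint(0, 6, min = -100L)))
    for (k in seq_len(cousins)) {
      tag <- sprintf("cousin%d", k)
      carrier[[pid(tag)]] <- transmit(pid("puncle"), pid("puncle_wife"))
      push(tag, "female", max(0L, page + rint(0, 8, min = -100L)),
           "puncle_wife", "puncle")
    }
  }
  if (sisters > 0L) {
    for (k in seq_len(n_slot("nieces"))) {
      tag <- sprintf("niece%d", k)
      carrier[[pid(tag)]] <- transmit(pid("sister1"))
      push(tag, "female", max(0L, page - rint(24, 4)), "sister1")
    }
  }

  ped <- pedigree(inds, proband_id = pid("proband"))

  src <- if (page < 45L) {
    if (stats::runif(1) < 0.4) "gp" else "specialist"
  } else {
    u <- stats::runif(1)
    if (u < 0.70) "screening_program" else if (u < 0.82) "gp" else
      "specialist"
  }

  genos <- vapply(names(ped$individuals),
                  function(id) isTRUE(carrier[[id]]), logical(1))
  blood <- blood_relative_ids(ped)
  list(
    pedigree = ped,
    covariates = list(age = page),
    source = src,
    true_genotype = if (any(genos[blood])) "carrier" else "noncarrier",
    genotypes = genos
  )
}

#' Carrier enrichment among test-eligible families
#'
#' Compares the carrier-family fraction among records the pipeline found
#' test-eligible with the carrier-family fraction of the whole population.
#' Under carrier-elevated penetrance the eligible set is enriched for
#' carriers -- the mechanism that makes a multistep family-history funnel
#' yield far more mutation carriers than unselected testing would.
#'
#' @param population Output of [generate_population()].
#' @param decisions Decision frame from [run_pipeline()] on that
#'   population.
#' @return List with `eligible_carrier_fraction`,
#'   `population_carrier_fraction`, `n_eligible`, `n`.
#' @export
enrichment_check <- function(population, decisions) {
  stopifnot(length(population) == nrow(decisions))
  is_carrier <- vapply(population, function(r)
    identical(r$true_genotype, "carrier"), logical(1))
  elig <- decisions$test_eligible
  list(
    eligible_carrier_fraction = if (any(elig)) mean(is_carrier[elig]) else 0,
    population_carrier_fraction = if (length(is_carrier))
      mean(is_carrier) else 0,
    n_eligible = sum(elig),
    n = length(population)
  )
}
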