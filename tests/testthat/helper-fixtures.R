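# Shared fixtures and independent oracles.
#
# The random-pedigree builder constructs families from named kinship slots,
# so every individual's true relation to the proband is known by
# construction -- independently of the package's path-based relation
# inference. The grid oracle re-encodes the questionnaire cells in a
# different representation (a long lookup table instead of row vectors),
# and the criterion oracles are straight-line predicates over the raw
# diagnosis lists.

ped_trio <- function(mother_dx = list()) {
  pedigree(list(
    individual("p", "female", age = 46, alive = "yes",
               mother_id = "m", father_id = "f"),
    individual("m", "female", age = 70, alive = "yes",
               diagnoses = mother_dx),
    individual("f", "male", age = 72, alive = "yes")
  ), proband_id = "p")
}

# Proband + parents + both grandparent couples + paternal aunt + sister:
# 3 generations, 9 individuals.
ped_three_gen <- function() {
  pedigree(list(
    individual("p", "female", age = 50, alive = "yes",
               mother_id = "m", father_id = "f"),
    individual("s", "female", age = 48, alive = "yes",
               mother_id = "m", father_id = "f",
               diagnoses = list(diagnosis("breast", 44,
                                          laterality = "unilateral",
                                          triple_negative = "no"))),
    individual("m", "female", age = 75, alive = "yes",
               mother_id = "mgm", father_id = "mgf"),
    individual("f", "male", age = 78, alive = "no",
               mother_id = "pgm", father_id = "pgf"),
    individual("pa", "female", age = 80, alive = "unknown",
               mother_id = "pgm", father_id = "pgf"),
    individual("pgm", "female", age = 95, alive = "no"),
    individual("pgf", "male", age = 96, alive = "no"),
    individual("mgm", "female", alive = "no",
               diagnoses = list(diagnosis("ovary",
                                          mucinous = "unknown",
                                          borderline = "unknown"))),
    individual("mgf", "male", age = 90, alive = "no")
  ), proband_id = "p")
}

# Random family built from known kinship slots. Returns the pedigree, the
# true relation label of every individual, a blood-relative flag, and the
# slot structure. All ages and flags are known values.
random_family <- function() {
  rdx_breast <- function(max_age) {
    onset <- sample(25:min(80, max_age), 1)
    diagnosis("breast", onset,
              laterality = sample(c("unilateral", "bilateral"), 1,
                                  prob = c(0.85, 0.15)),
              triple_negative = sample(c("yes", "no"), 1,
                                       prob = c(0.2, 0.8)))
  }
  rdx_ovary <- function(max_age) {
    diagnosis("ovary", sample(30:min(80, max_age), 1),
              mucinous = sample(c("yes", "no"), 1, prob = c(0.2, 0.8)),
              borderline = sample(c("yes", "no"), 1, prob = c(0.2, 0.8)))
  }
  rdxs <- function(age, sex) {
    dxs <- list()
    if (sex == "female") {
      if (runif(1) < 0.30) dxs <- c(dxs, list(rdx_breast(age)))
      if (runif(1) < 0.12) dxs <- c(dxs, list(rdx_ovary(age)))
    } else if (runif(1) < 0.06) {
      dxs <- c(dxs, list(rdx_breast(age)))
    }
    dxs
  }

  inds <- list(); rels <- character(0); blood <- logical(0)
  add <- function(id, sex, age, rel, is_blood, mother = NA, father = NA) {
    age <- max(age, 30L)
    inds[[length(inds) + 1L]] <<- individual(
      id, sex, age = as.integer(age),
      alive = sample(c("yes", "no"), 1, prob = c(0.8, 0.2)),
      mother_id = mother, father_id = father, diagnoses = rdxs(age, sex))
    rels[id] <<- rel; blood[id] <<- is_blood
  }

  page <- sample(40:70, 1)
  add("pgm", "female", page + 50, "paternal_grandmother", TRUE)
  add("pgf", "male", page + 52, "other", TRUE)
  add("mgm", "female", page + 50, "maternal_grandmother", TRUE)
  add("mgf", "male", page + 52, "other", TRUE)
  add("f", "male", page + 26, "other", TRUE, "pgm", "pgf")
  add("m", "female", page + 25, "mother", TRUE, "mgm", "mgf")
  add("p", "female", page, "self", TRUE, "m", "f")
  n_sis <- sample(0:2, 1)
  for (k in seq_len(n_sis)) {
    add(paste0("sis", k), "female", page + sample(-5:5, 1), "sister", TRUE,
        "m", "f")
  }
  if (runif(1) < 0.3) add("bro", "male", page + sample(-5:5, 1), "other",
                          TRUE, "m", "f")
  if (runif(1) < 0.5) add("dau", "female", page - 25, "daughter", TRUE, "p")
  if (runif(1) < 0.5) add("pa", "female", page + 27, "paternal_aunt", TRUE,
                          "pgm", "pgf")
  if (runif(1) < 0.5) add("ma", "female", page + 24, "maternal_aunt", TRUE,
                          "mgm", "mgf")
  if (runif(1) < 0.4) {
    add("pu", "male", page + 28, "other", TRUE, "pgm", "pgf")
    add("puw", "female", page + 27, "other", FALSE)      # married in
    add("cz", "female", page + sample(-6:6, 1), "paternal_cousin", TRUE,
        "puw", "pu")
  }
  if (n_sis > 0 && runif(1) < 0.4) {
    add("ni", "female", page - 22, "niece", TRUE, "sis1")
  }
  if (runif(1) < 0.3) {
    # mother's brother's daughter: an unscored kinship pattern
    add("mu", "male", page + 26, "other", TRUE, "mgm", "mgf")
    add("muw", "female", page + 25, "other", FALSE)
    add("mcz", "female", page + sample(-6:6, 1), "other", TRUE, "muw", "mu")
  }
  list(ped = pedigree(inds, proband_id = "p"), relations = rels,
       blood = blood)
}

# Independent grid oracle: long-format cell table, looked up by row label
# and band index. Bands: 1 <40; 2 40-49 bilateral; 3 40-49 monolateral;
# 4 50-59; 5 >=60; 6 ovary.
oracle_grid_cell <- local({
  cells <- expand.grid(rel = c("self", "mother", "sister", "daughter",
                               "paternal_grandmother", "paternal_aunt",
                               "maternal_grandmother", "maternal_aunt",
                               "paternal_cousin", "niece", "other"),
                       band = 1:6, stringsAsFactors = FALSE)
  pts <- function(rel, band) {
    high <- c("self", "mother", "sister", "daughter",
              "paternal_grandmother", "paternal_aunt")
    if (band == 6) {
      return(if (rel == "self") 2 else if (rel == "other") 0 else 1)
    }
    if (rel %in% high) c(2, 2, 1, 1, 0)[band]
    else if (rel %in% c("maternal_grandmother", "maternal_aunt", "niece"))
      c(1, 1, 1, 0, 0)[band]
    else if (rel == "paternal_cousin") c(1, 0, 0, 0, 0)[band]
    else 0
  }
  cells$points <- mapply(pts, cells$rel, cells$band)
  function(rel, band) cells$points[cells$rel == rel & cells$band == band]
})

oracle_band <- function(dx) {
  if (dx$site == "ovary") return(6L)
  a <- dx$age_at_onset
  if (is.na(a)) return(NA_integer_)
  if (a < 40) 1L
  else if (a < 50) (if (identical(dx$laterality, "bilateral")) 2L else 3L)
  else if (a < 60) 4L
  else 5L
}

# Independent total-score oracle using the true relation labels.
oracle_total <- function(ped, relations) {
  tot <- 0
  for (id in names(ped$individuals)) {
    ind <- ped$individuals[[id]]
    for (dx in ind$diagnoses) {
      if (ind$sex == "male") {
        tot <- tot + 2            # male breast cancer row: 2 at any age
      } else {
        band <- oracle_band(dx)
        tot <- tot + if (is.na(band)) 0 else
          oracle_grid_cell(relations[[id]], band)
      }
    }
  }
  tot
}

# Independent first-degree check straight off the parent fields.
oracle_first_degree <- function(ped, a, b) {
  ia <- ped$individuals[[a]]; ib <- ped$individuals[[b]]
  pc <- identical(ia$mother_id, b) || identical(ia$father_id, b) ||
    identical(ib$mother_id, a) || identical(ib$father_id, a)
  sib <- !is.na(ia$mother_id) && !is.na(ia$father_id) &&
    identical(ia$mother_id, ib$mother_id) &&
    identical(ia$father_id, ib$father_id)
  pc || sib
}

# Independent straight-line predicates for the seven direct criteria.
oracle_criteria <- function(ped, blood) {
  flags <- c(MALE_BC = FALSE, BC_AND_OC = FALSE, EARLY_ONSET_BC = FALSE,
             BILATERAL_BC_LE50 = FALSE, NONMUC_NONBORD_OC = FALSE,
             TWO_FDR_BC = FALSE, TNBC_LE60 = FALSE)
  bc_ids <- character(0)
  bc_blood <- FALSE; oc_blood <- FALSE
  for (id in names(ped$individuals)) {
    ind <- ped$individuals[[id]]
    for (dx in ind$diagnoses) {
      if (dx$site == "breast") {
        bc_ids <- unique(c(bc_ids, id))
        if (isTRUE(blood[[id]])) bc_blood <- TRUE
        if (ind$sex == "male") flags["MALE_BC"] <- TRUE
        if (!is.na(dx$age_at_onset) && dx$age_at_onset <= 35) {
          flags["EARLY_ONSET_BC"] <- TRUE
        }
        if (identical(dx$laterality, "bilateral") &&
            !is.na(dx$age_at_onset) && dx$age_at_onset <= 50) {
          flags["BILATERAL_BC_LE50"] <- TRUE
        }
        if (identical(dx$triple_negative, "yes") &&
            !is.na(dx$age_at_onset) && dx$age_at_onset <= 60) {
          flags["TNBC_LE60"] <- TRUE
        }
      } else {
        if (isTRUE(blood[[id]])) oc_blood <- TRUE
        if (identical(dx$mucinous, "no") &&
            identical(dx$borderline, "no")) {
          flags["NONMUC_NONBORD_OC"] <- TRUE
        }
      }
    }
  }
  flags["BC_AND_OC"] <- bc_blood && oc_blood
  young_or_bilat <- function(id) {
    any(vapply(ped$individuals[[id]]$diagnoses, function(dx) {
      dx$site == "breast" &&
        ((!is.na(dx$age_at_onset) && dx$age_at_onset <= 40) ||
           identical(dx$laterality, "bilateral"))
    }, logical(1)))
  }
  if (length(bc_ids) >= 2) {
    for (i in seq_along(bc_ids)) {
      for (j in seq_along(bc_ids)) {
        if (i < j && oracle_first_degree(ped, bc_ids[i], bc_ids[j]) &&
            (young_or_bilat(bc_ids[i]) || young_or_bilat(bc_ids[j]))) {
          flags["TWO_FDR_BC"] <- TRUE
        }
      }
    }
  }
  flags
}

criterion_codes <- function(crits) {
  sort(vapply(crits, function(cr) cr$code, character(1)))
}
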