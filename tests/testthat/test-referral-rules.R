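ped_with <- function(...) {
  # proband + parents + optional extra individuals supplied by the caller
  inds <- list(
    individual("p", "female", age = 48, alive = "yes",
               mother_id = "m", father_id = "f"),
    individual("m", "female", age = 74, alive = "yes"),
    individual("f", "male", age = 76, alive = "yes"))
  pedigree(c(inds, list(...)), proband_id = "p")
}

ped_proband_dx <- function(...) {
  pedigree(list(
    individual("p", "female", age = 66, alive = "yes",
               mother_id = "m", father_id = "f",
               diagnoses = list(...)),
    individual("m", "female", age = 74, alive = "yes"),
    individual("f", "male", age = 76, alive = "yes")
  ), proband_id = "p")
}

test_that("each direct criterion fires on its defining history", {
  # male breast cancer anywhere in the family
  bro <- individual("b", "male", age = 75, alive = "yes",
                    mother_id = "m", father_id = "f",
                    diagnoses = list(diagnosis("breast", 70)))
  crits <- direct_hub_criteria(ped_with(bro))
  expect_identical(criterion_codes(crits), "MALE_BC")
  expect_identical(crits[[1]]$evidence$individual_id, "b")

  expect_length(direct_hub_criteria(ped_with()), 0L)

  # early onset <= 35 is strict: 36 does not fire
  expect_true("EARLY_ONSET_BC" %in% criterion_codes(direct_hub_criteria(
    ped_proband_dx(diagnosis("breast", 35)))))
  expect_false("EARLY_ONSET_BC" %in% criterion_codes(direct_hub_criteria(
    ped_proband_dx(diagnosis("breast", 36)))))

  # bilateral at exactly 50 fires alone; at 51 it does not
  expect_identical(criterion_codes(direct_hub_criteria(ped_proband_dx(
    diagnosis("breast", 50, laterality = "bilateral")))),
    "BILATERAL_BC_LE50")
  expect_length(direct_hub_criteria(ped_proband_dx(
    diagnosis("breast", 51, laterality = "bilateral"))), 0L)
})

test_that("breast+ovary combines only across blood relatives", {
  oc <- diagnosis("ovary", 61, mucinous = "no", borderline = "no")
  # proband's own OC, non-mucinous non-borderline
  crits <- direct_hub_criteria(ped_proband_dx(oc))
  expect_identical(criterion_codes(crits), "NONMUC_NONBORD_OC")
  # adding any blood-relative BC turns on the family BC_AND_OC form
  mother_bc <- individual("m2", "female", age = 80, alive = "no",
                          mother_id = "mgm",
                          diagnoses = list(diagnosis("breast", 58)))
  ped <- pedigree(list(
    individual("p", "female", age = 66, mother_id = "m2",
               diagnoses = list(oc)),
    individual("mgm", "female", age = 99, alive = "no"),
    mother_bc), proband_id = "p")
  expect_true("BC_AND_OC" %in% criterion_codes(direct_hub_criteria(ped)))
  # an ovarian cancer in a married-in relative never combines
  ped2 <- pedigree(list(
    individual("p", "female", age = 48, mother_id = "m", father_id = "f",
               diagnoses = list(diagnosis("breast", 45))),
    individual("m", "female", age = 74),
    individual("f", "male", age = 76, mother_id = "pgm", father_id = "pgf"),
    individual("pgm", "female", age = 97), individual("pgf", "male", age = 98),
    individual("pu", "male", age = 70, mother_id = "pgm", father_id = "pgf"),
    individual("puw", "female", age = 68,
               diagnoses = list(diagnosis("ovary", 60, mucinous = "yes",
                                          borderline = "yes"))),
    individual("cz", "female", age = 45, mother_id = "puw", father_id = "pu")
  ), proband_id = "p")
  expect_false("BC_AND_OC" %in% criterion_codes(direct_hub_criteria(ped2)))
})

test_that("two first-degree BC cases need one young or bilateral member", {
  mk <- function(proband_age_dx, mother_age_dx) {
    pedigree(list(
      individual("p", "female", age = 55, alive = "yes", mother_id = "m",
                 diagnoses = list(diagnosis("breast", proband_age_dx))),
      individual("m", "female", age = 80, alive = "yes",
                 diagnoses = list(diagnosis("breast", mother_age_dx)))
    ), proband_id = "p")
  }
  # mother at 39 <= 40 qualifies the mother-daughter pair; 39 > 35 so no
  # early onset
  crits <- criterion_codes(direct_hub_criteria(mk(48, 39)))
  expect_true("TWO_FDR_BC" %in% crits)
  expect_false("EARLY_ONSET_BC" %in% crits)
  # both members late-onset monolateral: the pair does not qualify
  expect_false("TWO_FDR_BC" %in%
                 criterion_codes(direct_hub_criteria(mk(48, 52))))
  # unrelated (non-first-degree) young pair does not qualify
  aunt <- individual("ma", "female", age = 70, alive = "yes",
                     diagnoses = list(diagnosis("breast", 38)))
  ped <- pedigree(list(
    individual("p", "female", age = 55, mother_id = "m",
               diagnoses = list(diagnosis("breast", 48))),
    individual("m", "female", age = 80, mother_id = "mgm"),
    individual("mgm", "female", age = 99), aunt), proband_id = "p")
  expect_false("TWO_FDR_BC" %in%
                 criterion_codes(direct_hub_criteria(ped)))
})

test_that("triple-negative fires only at <= 60 with a positive flag", {
  tn <- function(age, flag) ped_proband_dx(
    diagnosis("breast", age, laterality = "unilateral",
              triple_negative = flag))
  expect_true("TNBC_LE60" %in%
                criterion_codes(direct_hub_criteria(tn(60, "yes"))))
  expect_false("TNBC_LE60" %in%
                 criterion_codes(direct_hub_criteria(tn(61, "yes"))))
  expect_false("TNBC_LE60" %in%
                 criterion_codes(direct_hub_criteria(tn(55, "unknown"))))
})

test_that("routing prefers direct criteria, then grid or BC at 36-40", {
  # early-onset proband goes straight to the Hub
  ped <- ped_proband_dx(diagnosis("breast", 34))
  rd <- route(ped, total_score(ped))
  expect_identical(rd$route, "hub_direct")
  expect_true("EARLY_ONSET_BC" %in% rd$reasons)

  # BC at 38: no direct criterion, but both Spoke triggers fire
  ped <- ped_proband_dx(diagnosis("breast", 38))
  rd <- route(ped, total_score(ped))
  expect_identical(rd$route, "spoke")
  expect_setequal(rd$reasons, c("GRID_SCORE", "BC_36_40"))

  # BC at 40 monolateral: grid gives only 1 point, the 36-40 window routes
  ped <- ped_proband_dx(diagnosis("breast", 40, laterality = "unilateral"))
  gs <- total_score(ped)
  expect_identical(gs$total, 1L)
  rd <- route(ped, gs)
  expect_identical(rd$route, "spoke")
  expect_identical(rd$reasons, "BC_36_40")

  # healthy proband, maternal grandmother BC at 45 monolateral: 1 point
  ped <- pedigree(list(
    individual("p", "female", age = 50, mother_id = "m"),
    individual("m", "female", age = 75, mother_id = "mgm"),
    individual("mgm", "female", age = 95, alive = "no",
               diagnoses = list(diagnosis("breast", 45,
                                          laterality = "unilateral")))
  ), proband_id = "p")
  rd <- route(ped, total_score(ped))
  expect_identical(rd$route, "none")
  expect_length(rd$reasons, 0L)
})

test_that("criterion flags match independent predicates on random families", {
  set.seed(808)
  for (i in 1:200) {
    fam <- random_family()
    got <- criterion_codes(direct_hub_criteria(fam$ped))
    want <- oracle_criteria(fam$ped, fam$blood)
    expect_identical(got, sort(names(want)[want]),
                     label = sprintf("family %d", i))
    # Hub test eligibility is the same criterion set
    expect_identical(hub_test_eligibility(fam$ped)$eligible,
                     length(got) > 0L)
  }
})

test_that("routing is independent of individual enumeration order", {
  set.seed(31)
  for (i in 1:20) {
    fam <- random_family()
    rd1 <- route(fam$ped, total_score(fam$ped))
    shuffled <- pedigree(unname(
      fam$ped$individuals[sample(names(fam$ped$individuals))]),
      proband_id = "p")
    rd2 <- route(shuffled, total_score(shuffled))
    expect_identical(rd1$route, rd2$route)
    expect_setequal(rd1$reasons, rd2$reasons)
  }
})

test_that("high risk by ratio alone is not test-eligible", {
  ped <- ped_with()   # empty history
  expect_false(hub_test_eligibility(ped)$eligible)
  ra <- assess(ped, ratio = 4.2)
  expect_identical(ra$profile, 3L)
  expect_true(ra$hub_referable)   # followed under profile-3 surveillance
})

test_that("the index case is the most indicative alive affected member", {
  # single alive affected candidate: the proband herself
  ped <- ped_proband_dx(diagnosis("breast", 38))
  expect_identical(select_index_case(ped), "p")

  # earlier onset wins between two alive affected relatives
  ped <- pedigree(list(
    individual("p", "female", age = 50, mother_id = "m"),
    individual("m", "female", age = 78, alive = "yes", mother_id = "mgm",
               diagnoses = list(diagnosis("breast", 38))),
    individual("mgm", "female", age = 99, alive = "no"),
    individual("ma", "female", age = 73, alive = "yes", mother_id = "mgm",
               diagnoses = list(diagnosis("breast", 55)))
  ), proband_id = "p")
  expect_identical(select_index_case(ped), "m")

  # breast + ovary in one person outranks an earlier breast-only case
  ped <- pedigree(list(
    individual("p", "female", age = 50, mother_id = "m"),
    individual("m", "female", age = 78, alive = "yes", mother_id = "mgm",
               diagnoses = list(diagnosis("breast", 38))),
    individual("mgm", "female", age = 99, alive = "no"),
    individual("ma", "female", age = 73, alive = "yes", mother_id = "mgm",
               diagnoses = list(diagnosis("breast", 60),
                                diagnosis("ovary", 65)))
  ), proband_id = "p")
  expect_identical(select_index_case(ped), "ma")

  # all affected deceased: no index case
  ped <- pedigree(list(
    individual("p", "female", age = 50, mother_id = "m"),
    individual("m", "female", age = 78, alive = "no",
               diagnoses = list(diagnosis("breast", 38)))
  ), proband_id = "p")
  expect_identical(select_index_case(ped), NA_character_)
})

test_that("variant classes route carriers and non-carriers", {
  ra <- assess(ped_trio(), ratio = 3.4)
  expect_identical(
    classify_result(genetic_test_result("BRCA1", "C5"), ra),
    "carrier_surveillance")
  expect_identical(
    classify_result(genetic_test_result("BRCA2", "C4"), ra),
    "carrier_surveillance")
  expect_identical(
    classify_result(genetic_test_result("none", "C3"), ra),
    "profile_based")
  expect_identical(
    classify_result(genetic_test_result("none", "C1"), ra),
    "profile_based")
  expect_true(genetic_test_result("BRCA1", "C4")$carrier)
  expect_false(genetic_test_result("none", "C3")$carrier)
  expect_error(
    classify_result(genetic_test_result("none", "not_tested"), ra),
    "contract violation")
})
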