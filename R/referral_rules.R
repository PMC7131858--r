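# Direct Hub criteria, Spoke/Hub routing, genetic-testing eligibility,
# index-case selection, and variant-class result routing.
#
# Seven family-history features send a woman straight to the Hub (genetic
# counseling) tier, bypassing the Spoke risk assessment: male breast cancer;
# breast and ovarian cancer in the same patient or the same family; early
# onset breast cancer (<= 35 years); bilateral breast cancer at <= 50 years;
# non-mucinous non-borderline ovarian cancer; two first-degree relatives
# with breast cancer, one arising at <= 40 years or bilateral; and
# triple-negative breast cancer at <= 60 years. The same feature set defines
# eligibility for BRCA1/2 testing at the Hub.

CRITERION_CODES <- c("MALE_BC", "BC_AND_OC", "EARLY_ONSET_BC",
                     "BILATERAL_BC_LE50", "NONMUC_NONBORD_OC",
                     "TWO_FDR_BC", "TNBC_LE60")

# Flat view of every diagnosis in the pedigree.
diagnosis_table <- function(ped) {
  rows <- list()
  for (id in names(ped$individuals)) {
    ind <- ped$individuals[[id]]
    for (k in seq_along(ind$diagnoses)) {
      d <- ind$diagnoses[[k]]
      rows[[length(rows) + 1L]] <- data.frame(
        individual_id = id, diagnosis_index = k, sex = ind$sex,
        alive = ind$alive, site = d$site, age_at_onset = d$age_at_onset,
        laterality = d$laterality, triple_negative = d$triple_negative,
        mucinous = d$mucinous, borderline = d$borderline,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(individual_id = character(0),
                      diagnosis_index = integer(0), sex = character(0),
                      alive = character(0), site = character(0),
                      age_at_onset = integer(0), laterality = character(0),
                      triple_negative = character(0), mucinous = character(0),
                      borderline = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

new_criterion <- function(code, evidence) {
  stopifnot(code %in% CRITERION_CODES, nrow(evidence) >= 1L)
  structure(list(code = code,
                 evidence = evidence[, c("individual_id", "diagnosis_index")]),
            class = "hboc_criterion")
}

#' Evaluate the direct Hub-referral criteria
#'
#' Checks the seven direct criteria against the proband and every relative.
#' An unknown age at onset never satisfies an age-thresholded criterion.
#' The breast-plus-ovary "family" form counts sites only among blood
#' relatives of the proband (see [blood_relative_ids()]): a cancer in a
#' relative by marriage never combines with one in the blood line. The
#' two-first-degree-relatives criterion counts the proband herself as a
#' possible member of the pair.
#'
#' @param ped A validated [pedigree()].
#' @return A list of `hboc_criterion` objects (possibly empty), each with a
#'   `code` and a non-empty `evidence` data frame of
#'   `(individual_id, diagnosis_index)` pairs.
#' @export
direct_hub_criteria <- function(ped) {
  stopifnot(inherits(ped, "hboc_pedigree"))
  dxs <- diagnosis_table(ped)
  out <- list()
  add <- function(code, ev) {
    if (nrow(ev)) out[[length(out) + 1L]] <<- new_criterion(code, ev)
  }

  bc <- dxs[dxs$site == "breast", , drop = FALSE]
  oc <- dxs[dxs$site == "ovary", , drop = FALSE]

  add("MALE_BC", bc[bc$sex == "male", , drop = FALSE])

  blood <- blood_relative_ids(ped)
  bc_blood <- bc[bc$individual_id %in% blood, , drop = FALSE]
  oc_blood <- oc[oc$individual_id %in% blood, , drop = FALSE]
  if (nrow(bc_blood) && nrow(oc_blood)) {
    add("BC_AND_OC", rbind(bc_blood, oc_blood))
  }

  add("EARLY_ONSET_BC",
      bc[!is.na(bc$age_at_onset) & bc$age_at_onset <= 35L, , drop = FALSE])

  add("BILATERAL_BC_LE50",
      bc[bc$laterality %in% "bilateral" & !is.na(bc$age_at_onset) &
           bc$age_at_onset <= 50L, , drop = FALSE])

  add("NONMUC_NONBORD_OC",
      oc[oc$mucinous %in% "no" & oc$borderline %in% "no", , drop = FALSE])

  # two breast-cancer cases related in the first degree, one <= 40 or
  # bilateral
  affected <- unique(bc$individual_id)
  if (length(affected) >= 2L) {
    pairs <- first_degree_pairs(ped, affected)
    ev_ids <- character(0)
    young_or_bilat <- function(id) {
      b <- bc[bc$individual_id == id, , drop = FALSE]
      any((!is.na(b$age_at_onset) & b$age_at_onset <= 40L) |
            b$laterality %in% "bilateral")
    }
    for (r in seq_len(nrow(pairs))) {
      a <- pairs$id1[[r]]; b <- pairs$id2[[r]]
      if (young_or_bilat(a) || young_or_bilat(b)) ev_ids <- c(ev_ids, a, b)
    }
    add("TWO_FDR_BC",
        bc[bc$individual_id %in% unique(ev_ids), , drop = FALSE])
  }

  add("TNBC_LE60",
      bc[bc$triple_negative %in% "yes" & !is.na(bc$age_at_onset) &
           bc$age_at_onset <= 60L, , drop = FALSE])

  out
}

#' Route a woman through the screening tiers
#'
#' Decides the referral route from the direct criteria and the grid score:
#' `hub_direct` when at least one direct criterion holds; otherwise `spoke`
#' when the grid total is >= 2 or the proband herself had breast cancer
#' diagnosed between 36 and 40 years; otherwise `none`. Reasons list every
#' trigger (criterion codes, `GRID_SCORE`, `BC_36_40`).
#'
#' @param ped A validated [pedigree()].
#' @param gs The [total_score()] of `ped`.
#' @return An object of class `hboc_referral`: list with `route`
#'   (`"none"`, `"spoke"` or `"hub_direct"`), `reasons` (character vector),
#'   and `criteria` (the satisfied criterion objects).
#' @export
route <- function(ped, gs) {
  stopifnot(inherits(ped, "hboc_pedigree"), inherits(gs, "hboc_grid_score"))
  crits <- direct_hub_criteria(ped)
  if (length(crits)) {
    return(structure(list(
      route = "hub_direct",
      reasons = vapply(crits, `[[`, character(1), "code"),
      criteria = crits), class = "hboc_referral"))
  }
  reasons <- character(0)
  if (gs$spoke_eligible) reasons <- c(reasons, "GRID_SCORE")
  if (proband_bc_36_40(ped)) reasons <- c(reasons, "BC_36_40")
  structure(list(
    route = if (length(reasons)) "spoke" else "none",
    reasons = reasons, criteria = list()), class = "hboc_referral")
}

proband_bc_36_40 <- function(ped) {
  pro <- ped$individuals[[ped$proband_id]]
  any(vapply(pro$diagnoses, function(d) {
    d$site == "breast" && !is.na(d$age_at_onset) &&
      d$age_at_onset >= 36L && d$age_at_onset <= 40L
  }, logical(1)))
}

#' Genetic-testing eligibility at the Hub
#'
#' A family is eligible for BRCA1/2 testing when at least one of the direct
#' criteria holds; the Hub eligibility list and the direct-referral list are
#' one criterion set with the thresholds stated on the primary questionnaire
#' (early onset <= 35, bilateral <= 50, triple-negative <= 60). A woman at
#' high risk by lifetime-risk ratio alone, with no family-history criterion,
#' is not test-eligible and is followed under profile-3 surveillance
#' instead.
#'
#' @param ped A validated [pedigree()].
#' @return List with `eligible` (logical) and `criteria` (list of satisfied
#'   criterion objects).
#' @export
hub_test_eligibility <- function(ped) {
  crits <- direct_hub_criteria(ped)
  list(eligible = length(crits) > 0L, criteria = crits)
}

#' Select the index case for first genetic testing
#'
#' Among alive affected family members, returns the most indicative one for
#' BRCA1/2 analysis under a documented heuristic, ranked by: (1) both breast
#' and ovarian cancer in the same person; (2) non-mucinous non-borderline
#' ovarian cancer; (3) earliest breast-cancer onset (unknown ages rank
#' last); (4) bilateral breast cancer; (5) the proband before relatives;
#' remaining ties break by id for determinism.
#'
#' @param ped A validated [pedigree()].
#' @return The selected individual id, or `NA_character_` when no alive
#'   affected individual exists.
#' @export
select_index_case <- function(ped) {
  stopifnot(inherits(ped, "hboc_pedigree"))
  dxs <- diagnosis_table(ped)
  cand <- unique(dxs$individual_id[dxs$alive == "yes"])
  if (!length(cand)) return(NA_character_)
  feats <- lapply(cand, function(id) {
    d <- dxs[dxs$individual_id == id, , drop = FALSE]
    bc_ages <- d$age_at_onset[d$site == "breast"]
    list(
      both = any(d$site == "breast") && any(d$site == "ovary"),
      ocnb = any(d$site == "ovary" & d$mucinous %in% "no" &
                   d$borderline %in% "no"),
      bc_age = if (any(d$site == "breast") && any(!is.na(bc_ages)))
        min(bc_ages, na.rm = TRUE) else Inf,
      bilat = any(d$site == "breast" & d$laterality %in% "bilateral"),
      proband = id == ped$proband_id
    )
  })
  ord <- order(
    -vapply(feats, function(f) as.integer(f$both), 1L),
    -vapply(feats, function(f) as.integer(f$ocnb), 1L),
    vapply(feats, function(f) f$bc_age, 1),
    -vapply(feats, function(f) as.integer(f$bilat), 1L),
    -vapply(feats, function(f) as.integer(f$proband), 1L),
    cand
  )
  cand[[ord[[1L]]]]
}

#' Construct a genetic test result
#'
#' Variant classes follow the five-tier ENIGMA classification; classes C4
#' (likely pathogenic) and C5 (pathogenic) are positive results, so
#' `carrier` is derived, never supplied.
#'
#' @param gene `"BRCA1"`, `"BRCA2"` or `"none"`.
#' @param variant_class One of `"C1"` ... `"C5"` or `"not_tested"`.
#' @return An object of class `hboc_test_result` with derived `carrier`
#'   flag.
#' @export
genetic_test_result <- function(gene = c("none", "BRCA1", "BRCA2"),
                                variant_class = c("not_tested", "C1", "C2",
                                                  "C3", "C4", "C5")) {
  gene <- match.arg(gene)
  variant_class <- match.arg(variant_class)
  structure(list(gene = gene, variant_class = variant_class,
                 carrier = variant_class %in% c("C4", "C5")),
            class = "hboc_test_result")
}

#' Route a woman after her genetic test result
#'
#' Positive results (C4/C5) enter carrier surveillance; C1/C2/C3 results
#' fall back to the surveillance schedule of the woman's risk profile.
#'
#' @param res A [genetic_test_result()]; `not_tested` is a contract
#'   violation.
#' @param ra A risk assessment (see [assess()]) supplying the profile used
#'   on the `profile_based` branch.
#' @return `"carrier_surveillance"` or `"profile_based"`.
#' @export
classify_result <- function(res, ra) {
  stopifnot(inherits(res, "hboc_test_result"))
  if (res$variant_class == "not_tested") {
    stop("contract violation: classify_result requires a tested result",
         call. = FALSE)
  }
  if (res$carrier) "carrier_surveillance" else "profile_based"
}
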