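# Lifetime-risk profile classification behind a pluggable risk-model
# contract.
#
# Any model that maps (pedigree, covariates) to a 10-year and a lifetime
# breast-cancer risk in [0, 1] can drive the classification -- in
# production that is an external Tyrer-Cuzick implementation, whose outputs
# are supplied as numbers. The package ships a deliberately simple
# multiplicative toy model so the full pipeline can be exercised and tested
# without one.
#
# Profiles are defined on the ratio of individual to general-population
# lifetime risk: profile 1 (low) for ratio < 2, profile 2 (intermediate)
# for ratio in [2, 3], profile 3 (high) for ratio > 3. The band edges are a
# documented convention of this package: the program's verbal definitions
# ("at most 1 time more", "between two and three times more") do not pin
# down the (1x, 2x) interval, so the low/intermediate boundary is fixed at
# 2x on the ratio scale and both edges of the intermediate band are closed.

#' Classify a lifetime-risk ratio into a profile
#'
#' @param ratio Nonnegative ratio of individual to general-population
#'   lifetime breast-cancer risk.
#' @return Integer profile: `1L` (low, ratio < 2), `2L` (intermediate,
#'   2 <= ratio <= 3), or `3L` (high, ratio > 3).
#' @examples
#' classify_profile(1.0)  # 1
#' classify_profile(3.0)  # 2 (upper edge of the intermediate band)
#' classify_profile(3.5)  # 3
#' @export
classify_profile <- function(ratio) {
  if (!is.numeric(ratio) || length(ratio) != 1L || is.na(ratio) || ratio < 0) {
    stop("contract violation: ratio must be a single nonnegative number",
         call. = FALSE)
  }
  if (ratio < 2) 1L else if (ratio <= 3) 2L else 3L
}

#' Default relative-risk factors of the toy model
#'
#' Multiplicative factors per affected relative, stratified by kinship
#' degree, cancer site and (for breast) onset before 40. Values are
#' conventional familial relative risks of the right order of magnitude;
#' the model exists to exercise the pipeline, not to estimate risk.
#'
#' @return Named numeric vector of relative-risk factors.
#' @export
toy_rr_factors <- function() {
  c(bc_first_lt40  = 2.5,
    bc_first_ge40  = 1.8,
    bc_second_lt40 = 1.5,
    bc_second_ge40 = 1.2,
    oc_first       = 2.0,
    oc_second      = 1.3)
}

#' Toy multiplicative familial risk model
#'
#' A documented stand-in satisfying the risk-model contract: lifetime risk
#' is the baseline population lifetime risk times a product of relative-risk
#' factors, one per affected first- or second-degree relative of the
#' proband, stratified by site and by breast-cancer onset before age 40
#' (unknown onset ages take the later-onset factor). The result is capped at
#' 1. The 10-year risk is the remaining lifetime risk spread uniformly over
#' the years to age 85. This model is for exercising and testing the
#' pipeline only; it is not a validated risk estimator and is not a
#' substitute interface for any published model beyond sharing the output
#' contract.
#'
#' @param ped A validated [pedigree()].
#' @param covariates List of personal covariates; `age` (years, default 45)
#'   is the only one the toy model uses. The contract admits the fuller set
#'   collected by production models (age at menarche, height, weight,
#'   parity, previous breast lesions, menopausal status).
#' @param baseline Population lifetime breast-cancer risk (default 0.10).
#' @param factors Relative-risk table, defaulting to [toy_rr_factors()].
#' @return List with `ten_year_risk` and `lifetime_risk`, both in `[0, 1]`.
#' @export
toy_risk_model <- function(ped, covariates = list(), baseline = 0.10,
                           factors = toy_rr_factors()) {
  stopifnot(inherits(ped, "hboc_pedigree"))
  age <- covariates$age %||% 45
  rr <- 1
  for (id in setdiff(names(ped$individuals), ped$proband_id)) {
    deg <- kinship_degree(ped, id)
    if (is.na(deg)) next
    for (d in ped$individuals[[id]]$diagnoses) {
      key <- if (d$site == "breast") {
        lt40 <- !is.na(d$age_at_onset) && d$age_at_onset < 40L
        if (deg == 1L) {
          if (lt40) "bc_first_lt40" else "bc_first_ge40"
        } else {
          if (lt40) "bc_second_lt40" else "bc_second_ge40"
        }
      } else {
        if (deg == 1L) "oc_first" else "oc_second"
      }
      rr <- rr * factors[[key]]
    }
  }
  lifetime <- min(1, baseline * rr)
  years_left <- max(1, 85 - age)
  ten_year <- min(1, lifetime * min(10, years_left) / years_left)
  list(ten_year_risk = ten_year, lifetime_risk = lifetime)
}

#' Assess a woman's risk profile
#'
#' Calls a risk model satisfying the contract (or takes an externally
#' computed lifetime-risk ratio, e.g. from a real Tyrer-Cuzick run),
#' computes the ratio to the general-population lifetime risk, and
#' classifies the profile. Profile-3 women are flagged Hub-referable.
#'
#' @param ped A validated [pedigree()].
#' @param covariates List of personal covariates passed to the model.
#' @param model A function `(ped, covariates)` returning a list with
#'   `ten_year_risk` and `lifetime_risk` in `[0, 1]`; default
#'   [toy_risk_model()].
#' @param population_lifetime_risk General-population lifetime risk in
#'   (0, 1], default 0.10.
#' @param ratio Optional externally supplied lifetime-risk ratio; when
#'   given, the model is not called and `lifetime_risk` is reconstructed as
#'   `ratio * population_lifetime_risk`.
#' @return An object of class `hboc_risk`: list with `ten_year_risk`,
#'   `lifetime_risk`, `population_lifetime_risk`, `ratio`, `profile`,
#'   `hub_referable`.
#' @export
assess <- function(ped, covariates = list(), model = toy_risk_model,
                   population_lifetime_risk = 0.10, ratio = NULL) {
  stopifnot(is.numeric(population_lifetime_risk),
            population_lifetime_risk > 0, population_lifetime_risk <= 1)
  if (is.null(ratio)) {
    out <- model(ped, covariates)
    for (fld in c("ten_year_risk", "lifetime_risk")) {
      v <- out[[fld]]
      if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
        stop(sprintf(
          "contract violation: model '%s' returned %s outside [0, 1]",
          deparse(substitute(model)), fld), call. = FALSE)
      }
    }
    lifetime <- out$lifetime_risk
    ten_year <- out$ten_year_risk
    ratio <- lifetime / population_lifetime_risk
  } else {
    stopifnot(is.numeric(ratio), length(ratio) == 1L, ratio >= 0)
    lifetime <- min(1, ratio * population_lifetime_risk)
    ten_year <- NA_real_
  }
  profile <- classify_profile(ratio)
  structure(
    list(ten_year_risk = ten_year, lifetime_risk = lifetime,
         population_lifetime_risk = population_lifetime_risk,
         ratio = ratio, profile = profile, hub_referable = profile == 3L),
    class = "hboc_risk"
  )
}

#' @export
print.hboc_risk <- function(x, ...) {
  cat(sprintf(
    "<hboc_risk> lifetime %.3f vs population %.3f (ratio %.2f): profile %d%s\n",
    x$lifetime_risk, x$population_lifetime_risk, x$ratio, x$profile,
    if (x$hub_referable) " [Hub-referable]" else ""))
  invisible(x)
}
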