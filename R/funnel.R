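# End-to-end triage pipeline over a population of family histories, plus
# the stage-count bookkeeping of the multistep screening funnel.
#
# Stage flow (main path, monotonically non-increasing): records ->
# triage-eligible (grid or direct criteria) -> arrived (attended Spoke, or
# attended Hub directly) -> evaluated -> Hub-evaluated -> test-eligible ->
# tested -> carriers. Non-attendance at each step is modelled as an
# independent Bernoulli draw with configurable probabilities; with all
# probabilities at 1 the funnel is deterministic.

FUNNEL_SOURCES <- c("gp", "specialist", "screening_program")

#' One-decimal percentage with half-up rounding
#'
#' Computes `100 * numerator / denominator` rounded half-up to one decimal
#' using exact integer arithmetic, the convention used in screening-program
#' reports (banker's rounding is deliberately not used).
#'
#' @param numerator,denominator Nonnegative counts; `denominator > 0`
#'   (a zero denominator is an explicit error, never `NaN`). Vectorised.
#' @return Numeric percentage(s) with one decimal of precision.
#' @examples
#' percent(5615, 22289)  # 25.2
#' percent(544, 2342)    # 23.2
#' @export
percent <- function(numerator, denominator) {
  stopifnot(is.numeric(numerator), is.numeric(denominator),
            length(numerator) == length(denominator) ||
              length(denominator) == 1L)
  if (any(denominator <= 0)) {
    stop("undefined percentage: zero or negative denominator", call. = FALSE)
  }
  if (any(numerator < 0)) {
    stop("negative numerator", call. = FALSE)
  }
  # half-up at one decimal: floor((2000 n + d) / (2 d)) / 10, exact for
  # integer counts well beyond screening-program sizes
  floor((2000 * numerator + denominator) / (2 * denominator)) / 10
}

#' Age band label
#'
#' @param age Age in years (vectorised).
#' @param scheme `"spoke"` for the arrival-table bands (`<35`, `35-39`,
#'   `40-44`, ..., `70-74`) or `"fine"` for five-year bands from `<25`.
#' @return Character vector of band labels.
#' @export
age_band <- function(age, scheme = c("spoke", "fine")) {
  scheme <- match.arg(scheme)
  lo <- if (scheme == "spoke") 35L else 25L
  vapply(age, function(a) {
    if (is.na(a)) return(NA_character_)
    if (a < lo) return(paste0("<", lo))
    if (a >= 75L) return(">=75")
    b <- (a %/% 5L) * 5L
    sprintf("%d-%d", b, b + 4L)
  }, character(1))
}

#' Pipeline step-acceptance parameters
#'
#' @param p_attend_spoke Probability an invited woman attends the Spoke.
#' @param p_complete_spoke Probability an attending woman completes the
#'   assessment.
#' @param p_attend_hub Probability a Hub-referred woman attends the Hub.
#' @param p_accept_test Probability an eligible family accepts testing.
#' @param seed Integer seed driving the Bernoulli non-attendance draws.
#' @return A named list of validated parameters.
#' @export
funnel_params <- function(p_attend_spoke = 1, p_complete_spoke = 1,
                          p_attend_hub = 1, p_accept_test = 1, seed = 1L) {
  p <- c(p_attend_spoke, p_complete_spoke, p_attend_hub, p_accept_test)
  stopifnot(all(p >= 0), all(p <= 1), is.numeric(seed))
  list(p_attend_spoke = p_attend_spoke, p_complete_spoke = p_complete_spoke,
       p_attend_hub = p_attend_hub, p_accept_test = p_accept_test,
       seed = as.integer(seed))
}

#' Run the full triage pipeline over a population
#'
#' For each record: grid score, referral route, (if arrived) risk profile,
#' (if high risk or direct criterion) Hub evaluation and test eligibility,
#' carrier routing, and the resulting surveillance basis. Carrier status is
#' taken from a supplied [genetic_test_result()] when present, otherwise
#' from the record's simulated `true_genotype` (a perfectly sensitive assay
#' is assumed), otherwise no variant is identified.
#'
#' @param population List of records; each record is a list with `pedigree`
#'   (required), and optional `covariates` (list), `source` (one of
#'   `"gp"`, `"specialist"`, `"screening_program"`), `risk_ratio`
#'   (externally computed lifetime-risk ratio), `genetic_result`
#'   ([genetic_test_result()]), and `true_genotype` (`"carrier"` or
#'   `"noncarrier"`).
#' @param params [funnel_params()] controlling step acceptance and the
#'   seed.
#' @param model Risk model honouring the contract of [assess()].
#' @param population_lifetime_risk Baseline lifetime risk for the ratio.
#' @return An object of class `hboc_funnel`: list with `decisions` (one
#'   data-frame row per record) and `stats` (see [funnel_stats()]).
#' @export
run_pipeline <- function(population, params = funnel_params(),
                         model = toy_risk_model,
                         population_lifetime_risk = 0.10) {
  stopifnot(is.list(population))
  set.seed(params$seed)
  rows <- vector("list", length(population))
  for (i in seq_along(population)) {
    rec <- population[[i]]
    ped <- rec$pedigree
    stopifnot(inherits(ped, "hboc_pedigree"))
    src <- rec$source %||% NA_character_
    if (!is.na(src) && !src %in% FUNNEL_SOURCES) {
      stop(sprintf("unknown source label '%s' (record %d)", src, i),
           call. = FALSE)
    }
    pro <- ped$individuals[[ped$proband_id]]
    gs <- total_score(ped)
    rd <- route(ped, gs)

    attended_spoke <- FALSE; spoke_evaluated <- FALSE
    hub_attended <- FALSE
    ratio <- NA_real_; profile <- NA_integer_
    test_eligible <- FALSE; index_case <- NA_character_
    tested <- FALSE; carrier <- FALSE

    eval_profile <- function() {
      ra <- assess(ped, covariates = rec$covariates %||% list(),
                   model = model,
                   population_lifetime_risk = population_lifetime_risk,
                   ratio = rec$risk_ratio)
      list(ratio = ra$ratio, profile = ra$profile)
    }

    if (rd$route == "spoke") {
      attended_spoke <- stats::runif(1) < params$p_attend_spoke
      if (attended_spoke) {
        spoke_evaluated <- stats::runif(1) < params$p_complete_spoke
      }
      if (spoke_evaluated) {
        pr <- eval_profile()
        ratio <- pr$ratio; profile <- pr$profile
        if (profile == 3L) {
          hub_attended <- stats::runif(1) < params$p_attend_hub
        }
      }
    } else if (rd$route == "hub_direct") {
      hub_attended <- stats::runif(1) < params$p_attend_hub
      if (hub_attended) {
        pr <- eval_profile()
        ratio <- pr$ratio; profile <- pr$profile
      }
    }

    if (hub_attended) {
      elig <- hub_test_eligibility(ped)
      test_eligible <- elig$eligible
      index_case <- select_index_case(ped)
      if (test_eligible && !is.na(index_case)) {
        tested <- stats::runif(1) < params$p_accept_test
      }
      if (tested) {
        carrier <- if (!is.null(rec$genetic_result)) {
          rec$genetic_result$carrier
        } else if (!is.null(rec$true_genotype)) {
          identical(rec$true_genotype, "carrier")
        } else {
          FALSE
        }
      }
    }

    basis <- if (tested && carrier) {
      "profile3_mutation"
    } else if (!is.na(profile)) {
      c("profile1", "profile2", "profile3_no_mutation")[[profile]]
    } else {
      "none"
    }

    rows[[i]] <- data.frame(
      record = i, proband_id = ped$proband_id, source = src,
      age = pro$age, grid_total = gs$total, route = rd$route,
      reasons = paste(rd$reasons, collapse = "+"),
      attended_spoke = attended_spoke, spoke_evaluated = spoke_evaluated,
      ratio = ratio, profile = profile, hub_attended = hub_attended,
      test_eligible = test_eligible, index_case = index_case,
      tested = tested, carrier = carrier, basis = basis,
      stringsAsFactors = FALSE)
  }
  decisions <- do.call(rbind, rows)
  structure(list(decisions = decisions, stats = funnel_stats(decisions)),
            class = "hboc_funnel")
}

#' Aggregate per-record decisions into funnel stage counts
#'
#' @param decisions The per-record decision frame from [run_pipeline()].
#' @return An object of class `hboc_funnel_stats`: `stages` (ordered
#'   data frame of stage name and count along the monotone main path),
#'   `derived` (one-decimal percentages of each stage over its
#'   predecessor), `branches` (Spoke refusals and the low/intermediate/high
#'   profile split, whose counts must reconcile with the main path), and
#'   `strata` (arrivals cross-tabulated by age band and source).
#' @export
funnel_stats <- function(decisions) {
  d <- decisions
  arrived <- d$attended_spoke | (d$route == "hub_direct" & d$hub_attended)
  evaluated <- d$spoke_evaluated | (d$route == "hub_direct" & d$hub_attended)
  stages <- data.frame(
    stage = c("records", "triage_eligible", "arrived", "evaluated",
              "hub_evaluated", "test_eligible", "tested", "carriers"),
    count = c(nrow(d), sum(d$route != "none"), sum(arrived), sum(evaluated),
              sum(d$hub_attended), sum(d$hub_attended & d$test_eligible),
              sum(d$tested), sum(d$carrier)),
    stringsAsFactors = FALSE)
  derived <- data.frame(
    label = paste0(stages$stage[-1], "_of_", stages$stage[-nrow(stages)]),
    numerator = stages$count[-1],
    denominator = stages$count[-nrow(stages)],
    stringsAsFactors = FALSE)
  derived$percent <- ifelse(derived$denominator > 0,
                            percent(pmax(derived$numerator, 0),
                                    pmax(derived$denominator, 1)),
                            NA_real_)
  derived$percent[derived$denominator == 0] <- NA_real_
  spoke_eval <- sum(d$spoke_evaluated)
  branches <- data.frame(
    label = c("spoke_attended", "spoke_refused", "spoke_evaluated",
              "profile_low", "profile_intermediate", "profile_high",
              "hub_direct_attended"),
    count = c(sum(d$attended_spoke),
              sum(d$attended_spoke) - spoke_eval,
              spoke_eval,
              sum(d$profile %in% 1L & d$spoke_evaluated),
              sum(d$profile %in% 2L & d$spoke_evaluated),
              sum(d$profile %in% 3L & d$spoke_evaluated),
              sum(d$route == "hub_direct" & d$hub_attended)),
    stringsAsFactors = FALSE)
  strata <- if (any(arrived & !is.na(d$source))) {
    tabulate_decisions(d[arrived & !is.na(d$source), , drop = FALSE],
                       by = c("age_band", "source"))
  } else {
    NULL
  }
  structure(list(stages = stages, derived = derived, branches = branches,
                 strata = strata),
            class = "hboc_funnel_stats")
}

#' Cross-tabulate decisions by age band and/or source
#'
#' @param decisions A decision frame (or subset) from [run_pipeline()].
#' @param by Character vector among `"age_band"` and `"source"`.
#' @param scheme Age-band scheme passed to [age_band()].
#' @return A contingency table with row/column totals (margin `"Total"`).
#' @export
tabulate_decisions <- function(decisions, by = c("age_band", "source"),
                               scheme = "spoke") {
  by <- match.arg(by, c("age_band", "source"), several.ok = TRUE)
  cols <- list()
  if ("age_band" %in% by) {
    cols$age_band <- age_band(decisions$age, scheme = scheme)
  }
  if ("source" %in% by) cols$source <- decisions$source
  tab <- table(cols, useNA = "no")
  stats::addmargins(tab, FUN = list(Total = sum), quiet = TRUE)
}

#' @export
print.hboc_funnel_stats <- function(x, ...) {
  cat("<hboc_funnel_stats>\n")
  df <- x$stages
  df$percent_of_previous <- c(NA, x$derived$percent)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
print.hboc_funnel <- function(x, ...) {
  print(x$stats)
  invisible(x)
}

#' Published stage-count tables of the Emilia-Romagna HBOC program
#'
#' The 2012-2016 stage counts reported by the Emilia-Romagna regional
#' hereditary breast/ovarian cancer screening program, keyed in as plain-CSV
#' package data: Spoke referrals from the mammography screening program by
#' age; arrivals at the Spoke centers by age, source and profile outcome;
#' Hub referrals by age group and source; and gene-test outcomes by age.
#' These tables are reporting *inputs* (for funnel percentage reproduction
#' and report formatting); the package never claims to re-simulate them.
#'
#' @return Named list of data frames: `spoke_referrals_by_age`,
#'   `spoke_arrivals`, `hub_referrals`, `gene_tests`, `funnel_stages`.
#' @export
era_program_tables <- function() {
  dir <- system.file("extdata", package = "hboctriage", mustWork = TRUE)
  read1 <- function(f) utils::read.csv(file.path(dir, f),
                                       check.names = FALSE,
                                       stringsAsFactors = FALSE)
  list(
    spoke_referrals_by_age = read1("era_spoke_referrals_by_age.csv"),
    spoke_arrivals = read1("era_spoke_arrivals.csv"),
    hub_referrals = read1("era_hub_referrals.csv"),
    gene_tests = read1("era_gene_tests.csv"),
    funnel_stages = read1("era_funnel_stages.csv")
  )
}
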