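# Surveillance schedule generation per risk profile and mutation status.
#
# Modalities: breast ultrasound (US), mammography (MMG), breast MRI (MRI),
# transvaginal ultrasound plus Ca.125 dosage (TVUS_CA125), Ca.125 dosage
# alone (CA125_ONLY), and the opaque marker MRI_PER_EUSOMA for profiles
# whose MRI indication follows EUSOMA guidelines (no schedule is invented
# for it: the marker rows carry NA start/end/interval).
#
# Schedules by basis:
#   profile 1            annual MMG 45-50, biennial MMG 51-74 (population
#                        screening).
#   profile 2            plan starts at 36 (25 with a relative with early
#                        onset BC); annual MMG 40-50, biennial 51-74;
#                        US after 41 only for high breast density;
#                        MRI per EUSOMA.
#   profile 3, no        six-monthly US 25-60; annual MMG 35-69, biennial
#   mutation             70-74; MRI per EUSOMA.
#   profile 3, mutation  six-monthly US from max(18, detection age) to 69;
#                        annual MRI 25-74; annual MMG 35-69, biennial
#                        70-74; six-monthly TVUS + Ca.125.
# Modifiers: post_mastectomy reduces breast modalities to six-monthly US
# only (the residual risk after bilateral mastectomy does not support MMG
# or MRI); prior_OC replaces TVUS + Ca.125 with six-monthly Ca.125 alone.

SURVEILLANCE_MODALITIES <- c("US", "MMG", "MRI", "TVUS_CA125", "CA125_ONLY",
                             "POPULATION_SCREENING", "MRI_PER_EUSOMA")
PLAN_MODIFIERS <- c("post_mastectomy", "prior_OC", "relative_EOBC",
                    "high_density")

sched_item <- function(modality, start_age = NA, end_age = NA,
                       interval_months = NA, condition = NA_character_) {
  stopifnot(modality %in% SURVEILLANCE_MODALITIES)
  if (!is.na(interval_months)) {
    stopifnot(interval_months %in% c(6L, 12L, 24L))
    stopifnot(!is.na(start_age), !is.na(end_age), start_age <= end_age)
  }
  data.frame(modality = modality, start_age = as.numeric(start_age),
             end_age = as.numeric(end_age),
             interval_months = as.integer(interval_months),
             condition = condition, stringsAsFactors = FALSE)
}

#' Build a surveillance plan
#'
#' @param profile Risk profile `1`, `2` or `3`.
#' @param carrier Is the woman a BRCA1/2 carrier (variant class C4/C5)? A
#'   carrier with a stated profile below 3 is normalised to the carrier
#'   schedule with a warning.
#' @param current_age Age in years at plan generation (mutation detection
#'   age for carriers), in `[18, 74]`.
#' @param modifiers Character subset of
#'   `c("post_mastectomy", "prior_OC", "relative_EOBC", "high_density")`.
#' @return An object of class `hboc_plan`: list with `items` (data frame of
#'   schedule rows), `basis` (`"profile1"`, `"profile2"`,
#'   `"profile3_no_mutation"`, `"profile3_mutation"`), and `modifiers`.
#' @examples
#' build_plan(1, carrier = FALSE, current_age = 46)
#' build_plan(3, carrier = TRUE, current_age = 30)
#' @export
build_plan <- function(profile, carrier = FALSE, current_age,
                       modifiers = character()) {
  stopifnot(profile %in% 1:3, is.logical(carrier), length(carrier) == 1L,
            is.numeric(current_age), length(current_age) == 1L,
            current_age >= 18, current_age <= 74)
  bad <- setdiff(modifiers, PLAN_MODIFIERS)
  if (length(bad)) {
    stop(sprintf("unknown modifier(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  modifiers <- sort(unique(modifiers))
  if (carrier && profile < 3) {
    warning("carrier status implies the profile-3 mutation schedule; ",
            "profile ", profile, " overridden", call. = FALSE)
    profile <- 3L
  }

  popscr <- "population screening"
  eusoma <- "according to EUSOMA guidelines"
  if (carrier) {
    basis <- "profile3_mutation"
    us_start <- max(18, current_age)
    items <- rbind(
      sched_item("US", us_start, 69, 6L),
      sched_item("MRI", 25, 74, 12L),
      sched_item("MMG", 35, 69, 12L),
      sched_item("MMG", 70, 74, 24L),
      sched_item("TVUS_CA125", us_start, 74, 6L)
    )
  } else if (profile == 3L) {
    basis <- "profile3_no_mutation"
    items <- rbind(
      sched_item("US", 25, 60, 6L),
      sched_item("MMG", 35, 69, 12L),
      sched_item("MMG", 70, 74, 24L),
      sched_item("MRI_PER_EUSOMA", condition = eusoma)
    )
  } else if (profile == 2L) {
    basis <- "profile2"
    items <- rbind(
      sched_item("MMG", 40, 50, 12L),
      sched_item("MMG", 51, 74, 24L, condition = popscr),
      sched_item("MRI_PER_EUSOMA", condition = eusoma)
    )
    if ("high_density" %in% modifiers) {
      items <- rbind(items,
                     sched_item("US", 42, 74, 12L,
                                condition = "high breast density"))
    }
  } else {
    basis <- "profile1"
    items <- rbind(
      sched_item("MMG", 45, 50, 12L, condition = popscr),
      sched_item("MMG", 51, 74, 24L, condition = popscr)
    )
  }

  plan_start <- switch(basis,
    profile1 = 45,
    profile2 = if ("relative_EOBC" %in% modifiers) 25 else 36,
    profile3_no_mutation = 25,
    profile3_mutation = max(18, current_age))

  # modifiers are applied in a fixed canonical order; they touch disjoint
  # modality groups, so any order gives the same plan
  if ("post_mastectomy" %in% modifiers) {
    breast <- c("MMG", "MRI", "MRI_PER_EUSOMA")
    items <- items[!items$modality %in% breast, , drop = FALSE]
    if (any(items$modality == "US")) {
      items$interval_months[items$modality == "US"] <- 6L
    } else {
      items <- rbind(items, sched_item("US", max(18, current_age), 69, 6L))
    }
  }
  if ("prior_OC" %in% modifiers) {
    items$modality[items$modality == "TVUS_CA125"] <- "CA125_ONLY"
  }

  rownames(items) <- NULL
  structure(list(items = items, basis = basis, start_age = plan_start,
                 modifiers = modifiers),
            class = "hboc_plan")
}

#' Count scheduled appointments in an age window
#'
#' For every concrete schedule row, events fall at
#' `start_age + k * interval_months / 12` for `k = 0, 1, ...` while within
#' the row's age range; the count per modality is the number of events in
#' the half-open window `[from_age, to_age)`. Marker rows without a
#' schedule (NA interval, e.g. `MRI_PER_EUSOMA`) contribute nothing.
#'
#' @param plan An [build_plan()] result.
#' @param from_age,to_age Window bounds in years, `from_age <= to_age`.
#' @return Named integer vector, one entry per modality present in the
#'   plan.
#' @export
appointments_in_window <- function(plan, from_age, to_age) {
  stopifnot(inherits(plan, "hboc_plan"), from_age <= to_age)
  counts <- stats::setNames(integer(length(unique(plan$items$modality))),
                            unique(plan$items$modality))
  for (r in seq_len(nrow(plan$items))) {
    row <- plan$items[r, ]
    if (is.na(row$interval_months)) next
    step <- row$interval_months / 12
    k <- 0
    repeat {
      ev <- row$start_age + k * step
      if (ev > row$end_age) break
      if (ev >= from_age && ev < to_age) {
        counts[[row$modality]] <- counts[[row$modality]] + 1L
      }
      if (ev >= to_age) break
      k <- k + 1
    }
  }
  counts
}

#' @export
print.hboc_plan <- function(x, ...) {
  cat(sprintf("<hboc_plan> basis %s, starts at %g y%s\n", x$basis,
              x$start_age,
              if (length(x$modifiers))
                paste0(" [", paste(x$modifiers, collapse = ", "), "]")
              else ""))
  print(x$items, row.names = FALSE)
  invisible(x)
}
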