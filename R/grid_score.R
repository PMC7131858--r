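# Family-risk questionnaire grid.
#
# Each diagnosis in the family contributes 0, 1 or 2 points depending on the
# relative's kinship position and, for breast cancer, on an age band crossed
# with laterality in the 40-49 band. A total of >= 2 points makes the woman
# eligible for the Spoke (oncogenetic counseling) referral.
#
# Breast columns: <40 | 40-49 bilateral | 40-49 monolateral | 50-59 | >=60.
# Ovarian cancer has a single column ("every" age).

# Row scores: breast columns in the order above, then the ovary column.
GRID_ROWS <- list(
  self                 = c(2L, 2L, 1L, 1L, 0L, 2L),
  mother               = c(2L, 2L, 1L, 1L, 0L, 1L),
  sister               = c(2L, 2L, 1L, 1L, 0L, 1L),
  daughter             = c(2L, 2L, 1L, 1L, 0L, 1L),
  paternal_grandmother = c(2L, 2L, 1L, 1L, 0L, 1L),
  paternal_aunt        = c(2L, 2L, 1L, 1L, 0L, 1L),
  maternal_grandmother = c(1L, 1L, 1L, 0L, 0L, 1L),
  maternal_aunt        = c(1L, 1L, 1L, 0L, 0L, 1L),
  paternal_cousin      = c(1L, 0L, 0L, 0L, 0L, 1L),
  niece                = c(1L, 1L, 1L, 0L, 0L, 1L),
  other                = c(0L, 0L, 0L, 0L, 0L, 0L)
)

# Male breast cancer scores 2 in every age band regardless of kinship; the
# male row has no ovary column (ovarian disease in males is blocked upstream).
MBC_POINTS <- 2L

#' Grid points for a single diagnosis
#'
#' Looks up the questionnaire-grid cell for one diagnosis given the
#' relative's kinship label. Conventions: bilateral breast cancer under 40
#' scores in the `<40` column (laterality only splits the 40-49 band);
#' unknown laterality in the 40-49 band scores as monolateral -- the lower
#' cell -- with a warning; an unknown age at onset contributes 0 with a
#' warning rather than guessing a band. A male relative's breast cancer
#' scores 2 at any age and any kinship position. An unscored (`other`)
#' female relation contributes 0.
#'
#' @param relation One of the eleven kinship labels
#'   (see [relation_to_proband()]).
#' @param dx A [diagnosis()].
#' @param is_male Is the diagnosed relative male?
#' @return Integer points in `{0, 1, 2}`.
#' @export
score_diagnosis <- function(relation, dx, is_male = FALSE) {
  relation <- match.arg(relation, names(GRID_ROWS))
  stopifnot(inherits(dx, "hboc_diagnosis"))
  if (dx$site == "ovary") {
    if (is_male) {
      stop("contract violation: ovary diagnosis for a male relative",
           call. = FALSE)
    }
    return(GRID_ROWS[[relation]][[6L]])
  }
  if (is_male) return(MBC_POINTS)
  age <- dx$age_at_onset
  if (is.na(age)) {
    warning(sprintf("unknown age at onset (%s, breast): contributes 0 points",
                    relation), call. = FALSE)
    return(0L)
  }
  col <- if (age <= 39L) {
    1L
  } else if (age <= 49L) {
    if (identical(dx$laterality, "bilateral")) {
      2L
    } else {
      if (identical(dx$laterality, "unknown")) {
        warning(sprintf(
          "unknown laterality at age %d (%s): scored as monolateral",
          age, relation), call. = FALSE)
      }
      3L
    }
  } else if (age <= 59L) {
    4L
  } else {
    5L
  }
  GRID_ROWS[[relation]][[col]]
}

#' Total questionnaire score of a pedigree
#'
#' Sums [score_diagnosis()] over every diagnosis of every family member,
#' computing each member's kinship label via [relation_to_proband()].
#' Contributions are listed in a deterministic order: individuals by id,
#' then diagnoses in recorded order.
#'
#' @param ped A validated [pedigree()].
#' @return An object of class `hboc_grid_score`: a list with
#'   `contributions` (data frame: `individual_id`, `relation`,
#'   `diagnosis_index`, `points`), `total`, and `spoke_eligible`
#'   (`total >= 2`).
#' @examples
#' ped <- pedigree(
#'   list(individual("p", "female", age = 46,
#'                   mother_id = "m", father_id = "f"),
#'        individual("m", "female", age = 70,
#'                   diagnoses = list(diagnosis("breast", 38))),
#'        individual("f", "male", age = 72)),
#'   proband_id = "p")
#' total_score(ped)  # mother with BC <40 scores 2: Spoke-eligible
#' @export
total_score <- function(ped) {
  stopifnot(inherits(ped, "hboc_pedigree"))
  ids <- sort(names(ped$individuals))
  rows <- list()
  for (id in ids) {
    ind <- ped$individuals[[id]]
    if (!length(ind$diagnoses)) next
    rel <- relation_to_proband(ped, id)
    for (k in seq_along(ind$diagnoses)) {
      pts <- score_diagnosis(rel, ind$diagnoses[[k]],
                             is_male = ind$sex == "male")
      rows[[length(rows) + 1L]] <- data.frame(
        individual_id = id, relation = rel, diagnosis_index = k,
        points = pts, stringsAsFactors = FALSE)
    }
  }
  contributions <- if (length(rows)) do.call(rbind, rows) else
    data.frame(individual_id = character(0), relation = character(0),
               diagnosis_index = integer(0), points = integer(0),
               stringsAsFactors = FALSE)
  total <- sum(contributions$points)
  structure(
    list(contributions = contributions, total = total,
         spoke_eligible = total >= 2L),
    class = "hboc_grid_score"
  )
}

#' @export
print.hboc_grid_score <- function(x, ...) {
  cat(sprintf("<hboc_grid_score> total %d (%sSpoke-eligible)\n", x$total,
              if (x$spoke_eligible) "" else "not "))
  if (nrow(x$contributions)) print(x$contributions, row.names = FALSE)
  invisible(x)
}
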