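#' Create a cancer diagnosis record
#'
#' One tumour event for one individual. Breast diagnoses carry laterality and
#' a triple-negative flag; ovarian diagnoses carry mucinous and borderline
#' histology flags. Fields that do not apply to the site are stored as `NA`.
#'
#' @param site `"breast"` or `"ovary"`.
#' @param age_at_onset Age in whole years at diagnosis, or `NA` if unknown.
#' @param laterality Breast only: `"unilateral"`, `"bilateral"` or
#'   `"unknown"`. Bilateral disease is recorded as one diagnosis, not two.
#' @param triple_negative Breast only: `"yes"`, `"no"` or `"unknown"`.
#' @param mucinous,borderline Ovary only: `"yes"`, `"no"` or `"unknown"`.
#' @return An object of class `hboc_diagnosis`.
#' @examples
#' diagnosis("breast", 38, laterality = "unilateral")
#' diagnosis("ovary", 61, mucinous = "no", borderline = "no")
#' @export
diagnosis <- function(site,
                      age_at_onset = NA,
                      laterality = "unknown",
                      triple_negative = "unknown",
                      mucinous = "unknown",
                      borderline = "unknown") {
  site <- match.arg(site, c("breast", "ovary"))
  if (!is.na(age_at_onset)) {
    age_at_onset <- as.integer(age_at_onset)
    if (is.na(age_at_onset) || age_at_onset < 0) {
      stop("age_at_onset must be a nonnegative integer or NA", call. = FALSE)
    }
  } else {
    age_at_onset <- NA_integer_
  }
  yn <- c("yes", "no", "unknown")
  if (site == "breast") {
    laterality <- match.arg(laterality, c("unilateral", "bilateral", "unknown"))
    triple_negative <- match.arg(triple_negative, yn)
    mucinous <- NA_character_
    borderline <- NA_character_
  } else {
    laterality <- NA_character_
    triple_negative <- NA_character_
    mucinous <- match.arg(mucinous, yn)
    borderline <- match.arg(borderline, yn)
  }
  structure(
    list(site = site, age_at_onset = age_at_onset, laterality = laterality,
         triple_negative = triple_negative, mucinous = mucinous,
         borderline = borderline),
    class = "hboc_diagnosis"
  )
}

#' Create an individual record
#'
#' @param id Opaque identifier, unique within the pedigree.
#' @param sex `"female"` or `"male"`.
#' @param age Current age (or age at death) in years, or `NA` if unknown.
#' @param alive `"yes"`, `"no"` or `"unknown"`.
#' @param mother_id,father_id Identifiers of the parents, or `NA`.
#' @param diagnoses List of [diagnosis()] objects, possibly empty.
#' @return An object of class `hboc_individual`.
#' @export
individual <- function(id, sex, age = NA, alive = "unknown",
                       mother_id = NA, father_id = NA, diagnoses = list()) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop("id must be a non-empty string", call. = FALSE)
  }
  sex <- match.arg(sex, c("female", "male"))
  alive <- match.arg(alive, c("yes", "no", "unknown"))
  if (!is.na(age)) {
    age <- as.integer(age)
    if (is.na(age) || age < 0) stop("age must be a nonnegative integer or NA",
                                    call. = FALSE)
  } else {
    age <- NA_integer_
  }
  mother_id <- if (is.na(mother_id)) NA_character_ else as.character(mother_id)
  father_id <- if (is.na(father_id)) NA_character_ else as.character(father_id)
  stopifnot(is.list(diagnoses))
  for (dx in diagnoses) {
    if (!inherits(dx, "hboc_diagnosis")) {
      stop("diagnoses must be a list of hboc_diagnosis objects", call. = FALSE)
    }
    if (!is.na(dx$age_at_onset) && !is.na(age) && dx$age_at_onset > age) {
      stop(sprintf("individual '%s': age_at_onset %d exceeds current age %d",
                   id, dx$age_at_onset, age), call. = FALSE)
    }
  }
  structure(
    list(id = id, sex = sex, age = age, alive = alive,
         mother_id = mother_id, father_id = father_id, diagnoses = diagnoses),
    class = "hboc_individual"
  )
}

#' Assemble and validate a pedigree
#'
#' A proband-rooted family graph. Parent links must form a DAG, referenced
#' ids must exist, mothers must be female and fathers male, ovarian diagnoses
#' may occur only in females, and the proband must exist and be female (the
#' screening population is women; male breast cancer in *relatives* is fully
#' supported).
#'
#' @param individuals List of [individual()] objects.
#' @param proband_id Identifier of the proband.
#' @return An object of class `hboc_pedigree` with elements `proband_id` and
#'   `individuals` (a named list keyed by id, in input order).
#' @examples
#' ped <- pedigree(
#'   list(
#'     individual("p", "female", age = 46, alive = "yes",
#'                mother_id = "m", father_id = "f"),
#'     individual("m", "female", age = 70, alive = "yes",
#'                diagnoses = list(diagnosis("breast", 38))),
#'     individual("f", "male", age = 72, alive = "yes")
#'   ),
#'   proband_id = "p"
#' )
#' @export
pedigree <- function(individuals, proband_id) {
  stopifnot(is.list(individuals), length(individuals) >= 1L)
  for (ind in individuals) {
    if (!inherits(ind, "hboc_individual")) {
      stop("individuals must be a list of hboc_individual objects",
           call. = FALSE)
    }
  }
  ids <- vapply(individuals, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate individual id(s): %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  }
  names(individuals) <- ids
  ped <- structure(
    list(proband_id = as.character(proband_id), individuals = individuals),
    class = "hboc_pedigree"
  )
  validate_pedigree(ped)
  ped
}

# Full structural validation; stops with a descriptive message on the first
# violated invariant.
validate_pedigree <- function(ped) {
  inds <- ped$individuals
  ids <- names(inds)

  if (!ped$proband_id %in% ids) {
    stop(sprintf("missing proband: id '%s' not found in pedigree",
                 ped$proband_id), call. = FALSE)
  }
  if (inds[[ped$proband_id]]$sex != "female") {
    stop("proband must be female", call. = FALSE)
  }

  for (ind in inds) {
    for (role in c("mother_id", "father_id")) {
      pid <- ind[[role]]
      if (is.na(pid)) next
      if (!pid %in% ids) {
        stop(sprintf("unknown parent id: individual '%s' references %s '%s'",
                     ind$id, sub("_id$", "", role), pid), call. = FALSE)
      }
      want <- if (role == "mother_id") "female" else "male"
      if (inds[[pid]]$sex != want) {
        stop(sprintf("individual '%s' referenced as %s must be %s",
                     pid, sub("_id$", "", role), want), call. = FALSE)
      }
    }
    if (ind$sex == "male") {
      for (dx in ind$diagnoses) {
        if (dx$site == "ovary") {
          stop(sprintf("ovary diagnosis recorded for male individual '%s'",
                       ind$id), call. = FALSE)
        }
      }
    }
  }

  # cycle detection over parent links (child -> parent edges)
  color <- stats::setNames(rep(0L, length(ids)), ids)  # 0 white 1 grey 2 black
  visit <- function(id, path) {
    color[[id]] <<- 1L
    path <- c(path, id)
    parents <- c(inds[[id]]$mother_id, inds[[id]]$father_id)
    for (p in parents[!is.na(parents)]) {
      if (color[[p]] == 1L) {
        cyc <- c(path[which(path == p)[1]:length(path)], p)
        stop(sprintf("cycle in parent links: %s",
                     paste(cyc, collapse = " -> ")), call. = FALSE)
      }
      if (color[[p]] == 0L) visit(p, path)
    }
    color[[id]] <<- 2L
  }
  for (id in ids) if (color[[id]] == 0L) visit(id, character(0))

  invisible(ped)
}

# Internal accessor with a lookup error for dangling ids.
ped_individual <- function(ped, id) {
  ind <- ped$individuals[[id]]
  if (is.null(ind)) {
    stop(sprintf("lookup error: no individual with id '%s'", id),
         call. = FALSE)
  }
  ind
}

#' @export
print.hboc_pedigree <- function(x, ...) {
  n_dx <- sum(vapply(x$individuals, function(i) length(i$diagnoses), 1L))
  cat(sprintf("<hboc_pedigree> proband '%s': %d individuals, %d diagnoses\n",
              x$proband_id, length(x$individuals), n_dx))
  invisible(x)
}

#' @export
print.hboc_diagnosis <- function(x, ...) {
  extra <- if (x$site == "breast") {
    sprintf("laterality=%s, TN=%s", x$laterality, x$triple_negative)
  } else {
    sprintf("mucinous=%s, borderline=%s", x$mucinous, x$borderline)
  }
  cat(sprintf("<hboc_diagnosis> %s at age %s (%s)\n", x$site,
              ifelse(is.na(x$age_at_onset), "unknown", x$age_at_onset), extra))
  invisible(x)
}
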