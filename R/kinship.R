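# Kinship helpers ------------------------------------------------------------

# Parents of an individual as a character vector (non-NA only).
parent_ids <- function(ped, id) {
  ind <- ped_individual(ped, id)
  p <- c(ind$mother_id, ind$father_id)
  p[!is.na(p)]
}

# TRUE if a and b share at least one recorded parent (half-siblings count).
shares_parent <- function(ped, a, b) {
  if (a == b) return(FALSE)
  length(intersect(parent_ids(ped, a), parent_ids(ped, b))) > 0L
}

# TRUE if a and b are full siblings: both parents recorded and identical.
full_siblings <- function(ped, a, b) {
  if (a == b) return(FALSE)
  ia <- ped_individual(ped, a); ib <- ped_individual(ped, b)
  !is.na(ia$mother_id) && !is.na(ia$father_id) &&
    identical(ia$mother_id, ib$mother_id) &&
    identical(ia$father_id, ib$father_id)
}

# TRUE if `child` lists `parent` among its parents.
is_parent_of <- function(ped, parent, child) {
  parent %in% parent_ids(ped, child)
}

# Ancestor closure of an id, including the id itself.
ancestors_incl_self <- function(ped, id) {
  seen <- character(0)
  queue <- id
  while (length(queue)) {
    cur <- queue[[1]]; queue <- queue[-1]
    if (cur %in% seen) next
    seen <- c(seen, cur)
    queue <- c(queue, parent_ids(ped, cur))
  }
  seen
}

#' Blood relatives of the proband
#'
#' Ids of all individuals who share at least one common ancestor with the
#' proband (each individual counting as their own ancestor, so ancestors and
#' descendants of the proband qualify). Relatives by marriage -- e.g. an
#' aunt's husband present only as a parent link node -- are excluded.
#'
#' @param ped A validated [pedigree()].
#' @return Character vector of ids, including the proband.
#' @export
blood_relative_ids <- function(ped) {
  anc <- lapply(names(ped$individuals), function(id)
    ancestors_incl_self(ped, id))
  names(anc) <- names(ped$individuals)
  pro_anc <- anc[[ped$proband_id]]
  keep <- vapply(anc, function(a) length(intersect(a, pro_anc)) > 0L,
                 logical(1))
  names(ped$individuals)[keep]
}

#' Kinship label of an individual relative to the proband
#'
#' Maps the parent-link path from the proband onto the eleven labels used by
#' the family-risk questionnaire grid: `self`, `mother`, `sister`,
#' `daughter`, `paternal_grandmother`, `paternal_aunt`,
#' `maternal_grandmother`, `maternal_aunt`, `paternal_cousin` (daughter of
#' the father's brother), `niece` (daughter of a sibling of the proband), and
#' the catch-all `other`. "Sister" and the aunt/uncle steps require at least
#' one shared recorded parent (half-siblings count). Labels other than
#' `self`/`other` are female kinship positions; male relatives (including the
#' father) map to `other` -- scoring handles male breast cancer through a
#' dedicated row regardless of this label.
#'
#' @param ped A validated [pedigree()].
#' @param individual_id Id present in `ped` (a dangling id is a lookup
#'   error).
#' @return One of the eleven label strings.
#' @export
relation_to_proband <- function(ped, individual_id) {
  ind <- ped_individual(ped, individual_id)
  pro <- ped_individual(ped, ped$proband_id)
  pid <- ped$proband_id
  id <- individual_id

  if (id == pid) return("self")
  if (!is.na(pro$mother_id) && id == pro$mother_id) return("mother")
  if (ind$sex != "female") return("other")

  if (is_parent_of(ped, pid, id)) return("daughter")
  if (shares_parent(ped, id, pid)) return("sister")

  father <- pro$father_id
  mother <- pro$mother_id
  if (!is.na(father)) {
    f <- ped_individual(ped, father)
    if (!is.na(f$mother_id) && id == f$mother_id) {
      return("paternal_grandmother")
    }
    if (shares_parent(ped, id, father)) return("paternal_aunt")
    # daughter of father's brother
    for (par in parent_ids(ped, id)) {
      p <- ped_individual(ped, par)
      if (p$sex == "male" && shares_parent(ped, par, father)) {
        return("paternal_cousin")
      }
    }
  }
  if (!is.na(mother)) {
    m <- ped_individual(ped, mother)
    if (!is.na(m$mother_id) && id == m$mother_id) {
      return("maternal_grandmother")
    }
    if (shares_parent(ped, id, mother)) return("maternal_aunt")
  }
  # daughter of a sibling of the proband
  for (par in parent_ids(ped, id)) {
    if (shares_parent(ped, par, pid)) return("niece")
  }
  "other"
}

#' First-degree pairs within a set of individuals
#'
#' Every unordered pair within `ids` related as parent-child or as full
#' siblings (both parents recorded and identical).
#'
#' @param ped A validated [pedigree()].
#' @param ids Character vector of ids, all present in `ped`.
#' @return A data frame with columns `id1`, `id2` (lexicographically ordered
#'   within and across rows); zero rows when no pair qualifies.
#' @export
first_degree_pairs <- function(ped, ids) {
  ids <- sort(unique(as.character(ids)))
  for (id in ids) ped_individual(ped, id)  # lookup errors surface here
  out <- list()
  if (length(ids) >= 2L) {
    for (i in seq_len(length(ids) - 1L)) {
      for (j in seq(i + 1L, length(ids))) {
        a <- ids[[i]]; b <- ids[[j]]
        if (is_parent_of(ped, a, b) || is_parent_of(ped, b, a) ||
            full_siblings(ped, a, b)) {
          out[[length(out) + 1L]] <- c(a, b)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(id1 = character(0), id2 = character(0),
                      stringsAsFactors = FALSE))
  }
  m <- do.call(rbind, out)
  data.frame(id1 = m[, 1], id2 = m[, 2], stringsAsFactors = FALSE)
}

# Kinship degree of an individual w.r.t. the proband: 1L for parent, child or
# sibling (>=1 shared parent); 2L for grandparent, grandchild, parent's
# sibling, or sibling's child; NA otherwise. Used by the toy risk model.
kinship_degree <- function(ped, id) {
  pid <- ped$proband_id
  if (id == pid) return(NA_integer_)
  if (is_parent_of(ped, id, pid) || is_parent_of(ped, pid, id) ||
      shares_parent(ped, id, pid)) {
    return(1L)
  }
  for (par in parent_ids(ped, pid)) {        # grandparents, parent's siblings
    if (is_parent_of(ped, id, par) || shares_parent(ped, id, par)) return(2L)
  }
  for (par in parent_ids(ped, id)) {         # sibling's children
    if (shares_parent(ped, par, pid)) return(2L)
  }
  for (kid in names(ped$individuals)) {      # grandchildren
    if (is_parent_of(ped, pid, kid) && is_parent_of(ped, kid, id)) return(2L)
  }
  NA_integer_
}
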