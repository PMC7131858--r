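# Family-history IO: a canonical JSON schema plus a flat CSV dialect.
#
# JSON (canonical, versioned): an object with schema_version, proband_id and
# an `individuals` array; each individual carries id/sex/age/alive/
# mother_id/father_id and a `diagnoses` array. Unknown scalars are omitted.
# A machine-readable copy of the schema ships in
# inst/extdata/pedigree-schema.json.
#
# CSV: one row per individual, UTF-8, comma-separated, header mandatory.
# An individual with several diagnoses repeats its row with the same id
# (individual-level fields are taken from the first occurrence). Empty cells
# mean unknown / absent.

PEDIGREE_SCHEMA_VERSION <- "1.0"

csv_columns <- c("id", "proband", "sex", "age", "alive", "mother_id",
                 "father_id", "dx_site", "dx_age_at_onset", "dx_laterality",
                 "dx_triple_negative", "dx_mucinous", "dx_borderline")

#' Parse a pedigree from JSON or CSV
#'
#' Accepts a file path or literal text in either of the package's two
#' schemas. JSON input is recognised by a leading `{` (or a `.json`
#' extension); anything else is treated as CSV. The parsed pedigree is fully
#' validated: parent-link cycles, dangling parent ids, a missing or male
#' proband, and ovarian diagnoses in males are all validation errors.
#'
#' @param source Path to a file, or a single string of JSON/CSV text.
#' @return A validated [pedigree()].
#' @seealso [write_pedigree()] for the inverse operation.
#' @export
parse_pedigree <- function(source) {
  stopifnot(is.character(source), length(source) == 1L)
  txt <- if (file.exists(source)) {
    paste(readLines(source, warn = FALSE, encoding = "UTF-8"),
          collapse = "\n")
  } else {
    source
  }
  if (grepl("^\\s*\\{", txt)) parse_pedigree_json(txt) else
    parse_pedigree_csv(txt)
}

parse_pedigree_json <- function(txt) {
  obj <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  if (is.null(obj$proband_id)) stop("missing proband: no proband_id field",
                                    call. = FALSE)
  if (!length(obj$individuals)) stop("no individuals in pedigree record",
                                     call. = FALSE)
  inds <- lapply(obj$individuals, function(rec) {
    dxs <- lapply(rec$diagnoses, function(d) {
      diagnosis(
        site = d$site,
        age_at_onset = if (is.null(d$age_at_onset)) NA else d$age_at_onset,
        laterality = d$laterality %||% "unknown",
        triple_negative = d$triple_negative %||% "unknown",
        mucinous = d$mucinous %||% "unknown",
        borderline = d$borderline %||% "unknown"
      )
    })
    individual(
      id = rec$id, sex = rec$sex,
      age = if (is.null(rec$age)) NA else rec$age,
      alive = rec$alive %||% "unknown",
      mother_id = rec$mother_id %||% NA,
      father_id = rec$father_id %||% NA,
      diagnoses = dxs
    )
  })
  pedigree(inds, proband_id = obj$proband_id)
}

parse_pedigree_csv <- function(txt) {
  df <- utils::read.csv(text = txt, colClasses = "character",
                        check.names = FALSE, fileEncoding = "UTF-8")
  missing_cols <- setdiff(csv_columns, names(df))
  if (length(missing_cols)) {
    stop(sprintf("CSV is missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  blank2na <- function(x) ifelse(nzchar(x), x, NA_character_)
  ids <- unique(df$id)
  inds <- lapply(ids, function(id) {
    rows <- df[df$id == id, , drop = FALSE]
    first <- rows[1L, ]
    dxs <- list()
    for (k in seq_len(nrow(rows))) {
      r <- rows[k, ]
      if (!nzchar(r$dx_site)) next
      dxs[[length(dxs) + 1L]] <- diagnosis(
        site = r$dx_site,
        age_at_onset = if (nzchar(r$dx_age_at_onset))
          as.integer(r$dx_age_at_onset) else NA,
        laterality = if (nzchar(r$dx_laterality)) r$dx_laterality else
          "unknown",
        triple_negative = if (nzchar(r$dx_triple_negative))
          r$dx_triple_negative else "unknown",
        mucinous = if (nzchar(r$dx_mucinous)) r$dx_mucinous else "unknown",
        borderline = if (nzchar(r$dx_borderline)) r$dx_borderline else
          "unknown"
      )
    }
    individual(
      id = id, sex = first$sex,
      age = if (nzchar(first$age)) as.integer(first$age) else NA,
      alive = if (nzchar(first$alive)) first$alive else "unknown",
      mother_id = blank2na(first$mother_id),
      father_id = blank2na(first$father_id),
      diagnoses = dxs
    )
  })
  proband <- df$id[df$proband %in% c("yes", "true", "1")]
  if (!length(proband)) {
    stop("missing proband: no row flagged proband=yes", call. = FALSE)
  }
  pedigree(inds, proband_id = unique(proband)[[1]])
}

#' Serialise a pedigree to JSON or CSV
#'
#' `parse_pedigree(write_pedigree(p))` reproduces `p` exactly, including
#' unknown ages and histology flags, in both formats.
#'
#' @param ped A validated [pedigree()].
#' @param path Optional file path; when given, the text is also written
#'   there.
#' @param format `"json"` (canonical) or `"csv"`.
#' @return The serialised text, invisibly when `path` is given.
#' @export
write_pedigree <- function(ped, path = NULL, format = c("json", "csv")) {
  stopifnot(inherits(ped, "hboc_pedigree"))
  format <- match.arg(format)
  txt <- if (format == "json") pedigree_to_json(ped) else pedigree_to_csv(ped)
  if (!is.null(path)) {
    writeLines(txt, path, useBytes = TRUE)
    return(invisible(txt))
  }
  txt
}

pedigree_to_json <- function(ped) {
  strip_na <- function(x) x[!vapply(x, function(v) is.null(v) ||
                                      (length(v) == 1L && is.na(v)),
                                    logical(1))]
  inds <- lapply(unname(ped$individuals), function(ind) {
    dxs <- lapply(ind$diagnoses, function(d) strip_na(unclass(d)))
    rec <- strip_na(list(
      id = ind$id, sex = ind$sex, age = ind$age, alive = ind$alive,
      mother_id = ind$mother_id, father_id = ind$father_id
    ))
    rec$diagnoses <- dxs
    rec
  })
  jsonlite::toJSON(
    list(schema_version = PEDIGREE_SCHEMA_VERSION,
         proband_id = ped$proband_id,
         individuals = inds),
    auto_unbox = TRUE, pretty = TRUE, null = "null"
  )
}

pedigree_to_csv <- function(ped) {
  na2blank <- function(x) ifelse(is.na(x), "", as.character(x))
  rows <- list()
  for (ind in ped$individuals) {
    base <- c(id = ind$id,
              proband = if (ind$id == ped$proband_id) "yes" else "no",
              sex = ind$sex, age = na2blank(ind$age), alive = ind$alive,
              mother_id = na2blank(ind$mother_id),
              father_id = na2blank(ind$father_id))
    dxs <- ind$diagnoses
    if (!length(dxs)) {
      rows[[length(rows) + 1L]] <- c(base, dx_site = "",
                                     dx_age_at_onset = "",
                                     dx_laterality = "",
                                     dx_triple_negative = "",
                                     dx_mucinous = "", dx_borderline = "")
    } else {
      for (d in dxs) {
        rows[[length(rows) + 1L]] <- c(
          base,
          dx_site = d$site,
          dx_age_at_onset = na2blank(d$age_at_onset),
          dx_laterality = na2blank(d$laterality),
          dx_triple_negative = na2blank(d$triple_negative),
          dx_mucinous = na2blank(d$mucinous),
          dx_borderline = na2blank(d$borderline)
        )
      }
    }
  }
  m <- do.call(rbind, rows)
  df <- as.data.frame(m, stringsAsFactors = FALSE)[, csv_columns]
  con <- textConnection("out", "w", local = TRUE)
  utils::write.csv(df, con, row.names = FALSE)
  close(con)
  paste(out, collapse = "\n")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
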