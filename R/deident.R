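#' Personal identifiers of a source record
#'
#' @param name Patient name.
#' @param hospitalization_record_number Hospital record number (non-empty).
#' @param hospital_id Hospital identifier (non-empty).
#' @param national_id Optional government-issued ID; when present it is the
#'   preferred basis for the internal study ID.
#' @param other_identifiers Named character vector of further identifying
#'   strings (address, phone, physician name) that must also be scrubbed
#'   from de-identified payloads.
#' @return An object of class `personal_identifiers`.
#' @export
personal_identifiers <- function(name, hospitalization_record_number,
                                 hospital_id, national_id = NA_character_,
                                 other_identifiers = character()) {
  if (is_missing_value(hospitalization_record_number))
    stop("hospitalization_record_number must be non-empty", call. = FALSE)
  if (is_missing_value(hospital_id))
    stop("hospital_id must be non-empty", call. = FALSE)
  structure(
    list(name = as.character(name),
         national_id = as.character(national_id),
         hospitalization_record_number = as.character(hospitalization_record_number),
         hospital_id = as.character(hospital_id),
         other_identifiers = other_identifiers),
    class = "personal_identifiers"
  )
}

# Normalization of identifier text before hashing: NFC, trim, casefold.
# The source system never specifies this; any fixed choice works as long as
# it is applied consistently on both assignment and relinking.
normalize_identifier <- function(x) {
  tolower(trimws(stringi::stri_trans_nfc(as.character(x))))
}

#' Assign an internal study ID
#'
#' The study ID is a keyed one-way digest (HMAC-SHA256) of the normalized
#' national ID when one is available, otherwise of the normalized composite
#' of patient name, hospitalization record number and hospital ID. The two
#' branches are domain-separated so the same person yields different (but
#' individually stable) IDs depending on which branch applies.
#'
#' @param ids A [personal_identifiers()] object.
#' @param salt Secret key for the digest; must be non-empty. Without the
#'   salt the mapping from identifiers to study IDs cannot be reproduced.
#' @return A 64-character hexadecimal study ID.
#' @export
assign_internal_id <- function(ids, salt) {
  stopifnot(inherits(ids, "personal_identifiers"))
  if (!is.character(salt) || length(salt) != 1L || !nzchar(salt))
    stop("salt must be a non-empty string", call. = FALSE)
  msg <- if (!is_missing_value(ids$national_id)) {
    paste0("nid:", normalize_identifier(ids$national_id))
  } else {
    paste0("composite:",
           paste(normalize_identifier(ids$name),
                 normalize_identifier(ids$hospitalization_record_number),
                 normalize_identifier(ids$hospital_id), sep = "|"))
  }
  as.character(openssl::sha256(msg, key = salt))
}

redaction_token <- "[REDACTED]"

identifier_strings <- function(ids) {
  vals <- c(ids$name, ids$national_id, ids$hospitalization_record_number,
            ids$hospital_id, unlist(ids$other_identifiers, use.names = FALSE))
  vals <- vals[!vapply(vals, is_missing_value, logical(1))]
  unique(trimws(vals))
}

scrub_text <- function(x, identifiers) {
  for (id in identifiers[order(-nchar(identifiers))]) {
    x <- gsub(id, redaction_token, x, fixed = FALSE, ignore.case = TRUE,
              perl = TRUE, useBytes = FALSE)
  }
  x
}

# gsub with fixed = FALSE would treat identifiers as regex; escape them.
regex_escape <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

#' De-identify a raw record
#'
#' Splits a record into de-identified per-module payloads and a separate
#' linkage entry. Every occurrence of any known identifier string is
#' replaced (exact, case-insensitive match) by a fixed redaction token.
#' Free-text identifying content beyond the known identifier fields is not
#' detected.
#'
#' @param record A list with elements `identifiers` (a
#'   [personal_identifiers()]) and `modules` (named list: module name ->
#'   named character vector of variable values).
#' @param schema A [cdm_schema()]; every payload module must exist in it.
#' @param salt Secret key passed to [assign_internal_id()].
#' @return A list with `deid` (class `deidentified_record`: `study_id` and
#'   `module_payloads`) and `linkage` (class `linkage_entry`: `study_id`,
#'   `identifiers`, `created_at`). The linkage entry is never embedded in
#'   the de-identified record.
#' @export
deidentify_record <- function(record, schema, salt) {
  stopifnot(inherits(record$identifiers, "personal_identifiers"))
  mods <- names(record$modules)
  bad <- setdiff(mods, schema$modules)
  if (length(bad))
    stop(sprintf("payload module(s) absent from schema: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  study_id <- assign_internal_id(record$identifiers, salt)
  idents <- regex_escape(identifier_strings(record$identifiers))
  payloads <- lapply(record$modules, function(values) {
    out <- vapply(values, function(v) {
      if (is_missing_value(v)) NA_character_ else scrub_text(as.character(v), idents)
    }, character(1))
    names(out) <- names(values)
    out
  })
  deid <- structure(list(study_id = study_id, module_payloads = payloads),
                    class = "deidentified_record")
  linkage <- structure(list(study_id = study_id,
                            identifiers = record$identifiers,
                            created_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
                       class = "linkage_entry")
  list(deid = deid, linkage = linkage)
}

#' Build a linkage store from linkage entries
#'
#' @param entries List of `linkage_entry` objects.
#' @return A data frame (class `linkage_store`) with one row per study ID.
#' @export
linkage_store <- function(entries) {
  if (length(entries) == 0L) {
    df <- data.frame(study_id = character(), name = character(),
                     national_id = character(),
                     hospitalization_record_number = character(),
                     hospital_id = character(), extra_json = character(),
                     stringsAsFactors = FALSE)
    class(df) <- c("linkage_store", "data.frame")
    return(df)
  }
  ids <- vapply(entries, `[[`, character(1), "study_id")
  if (anyDuplicated(ids)) stop("duplicate study_id in linkage store", call. = FALSE)
  df <- do.call(rbind, lapply(entries, function(e) {
    i <- e$identifiers
    data.frame(study_id = e$study_id, name = i$name,
               national_id = i$national_id,
               hospitalization_record_number = i$hospitalization_record_number,
               hospital_id = i$hospital_id,
               extra_json = as.character(
                 jsonlite::toJSON(as.list(i$other_identifiers), auto_unbox = TRUE)),
               stringsAsFactors = FALSE)
  }))
  class(df) <- c("linkage_store", "data.frame")
  df
}

# Linkage data must live outside the de-identified output tree ("physically
# separated" modeled as a path-disjointness contract).
assert_separated <- function(linkage_dir, deid_dir) {
  norm <- function(p) normalizePath(p, winslash = "/", mustWork = FALSE)
  a <- norm(linkage_dir); b <- norm(deid_dir)
  if (a == b || startsWith(paste0(a, "/"), paste0(b, "/")))
    stop("linkage data must not be stored in (or under) the de-identified output directory",
         call. = FALSE)
  invisible(TRUE)
}

#' Write a linkage store to CSV
#'
#' Refuses to write into (or under) the directory holding de-identified
#' output: the linkage file is the only route from study IDs back to
#' persons and must stay physically separated.
#'
#' @param store A [linkage_store()].
#' @param path Output CSV path.
#' @param deid_dir Directory holding (or designated for) de-identified
#'   output; the writer errors if `path`'s directory equals or is nested in
#'   it.
#' @return `path`, invisibly.
#' @export
write_linkage <- function(store, path, deid_dir) {
  assert_separated(dirname(path), deid_dir)
  utils::write.csv(as.data.frame(store), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a linkage store from CSV
#'
#' @param path CSV path written by [write_linkage()].
#' @return A `linkage_store`.
#' @export
read_linkage <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  df$national_id[!nzchar(df$national_id)] <- NA_character_
  class(df) <- c("linkage_store", "data.frame")
  df
}

#' Recover personal identifiers for a de-identified record
#'
#' @param deid A `deidentified_record` (or a study ID string).
#' @param store A [linkage_store()].
#' @return The [personal_identifiers()] for the record's study ID.
#' @export
relink <- function(deid, store) {
  study_id <- if (inherits(deid, "deidentified_record")) deid$study_id else as.character(deid)
  row <- store[store$study_id == study_id, , drop = FALSE]
  if (nrow(row) == 0L)
    stop(sprintf("study_id '%s' not present in linkage store", study_id), call. = FALSE)
  extra <- unlist(jsonlite::fromJSON(row$extra_json[1]))
  if (is.null(extra)) extra <- character()
  personal_identifiers(
    name = row$name[1],
    hospitalization_record_number = row$hospitalization_record_number[1],
    hospital_id = row$hospital_id[1],
    national_id = row$national_id[1],
    other_identifiers = extra
  )
}

#' Write de-identified records as JSON-lines
#'
#' One record per line: `{"study_id": ..., "modules": {...}}`.
#'
#' @param deids List of `deidentified_record` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_deidentified <- function(deids, path) {
  lines <- vapply(deids, function(d) {
    as.character(jsonlite::toJSON(
      list(study_id = d$study_id,
           modules = lapply(d$module_payloads, as.list)),
      auto_unbox = TRUE, na = "null"))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read de-identified records from JSON-lines
#'
#' @param path Path written by [write_deidentified()].
#' @return List of `deidentified_record` objects.
#' @export
read_deidentified <- function(path) {
  lapply(readLines(path), function(line) {
    x <- jsonlite::fromJSON(line, simplifyVector = FALSE)
    payloads <- lapply(x$modules, function(m) {
      out <- vapply(m, function(v) if (is.null(v)) NA_character_ else as.character(v),
                    character(1))
      names(out) <- names(m)
      out
    })
    structure(list(study_id = x$study_id, module_payloads = payloads),
              class = "deidentified_record")
  })
}
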