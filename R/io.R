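# Tabular I/O. All CSVs are UTF-8, comma-separated, header row mandatory.
# Entry long format: study_id,module,variable,value,reader_id,round
# (missing value = empty field).

entry_header <- c("study_id", "module", "variable", "value", "reader_id", "round")

#' Write entry sets to a long-format CSV
#'
#' @param entries List of [entry_set()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_entries <- function(entries, path) {
  rows <- lapply(entries, function(e) {
    data.frame(study_id = e$study_id, module = e$module,
               variable = names(e$values),
               value = unname(e$values), reader_id = e$reader_id,
               round = e$round, stringsAsFactors = FALSE)
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    as.data.frame(stats::setNames(rep(list(character()), 6), entry_header))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read entry sets from a long-format CSV
#'
#' Values are grouped by (study_id, module, reader_id, round) into
#' [entry_set()]s. Rows naming variables unknown to the schema are
#' collected into an `"unknown_variables"` attribute (a warning is raised),
#' never silently dropped into the entries.
#'
#' @param path Input CSV with header
#'   `study_id,module,variable,value,reader_id,round`.
#' @param schema A [cdm_schema()].
#' @return List of [entry_set()]s with attribute `"unknown_variables"`.
#' @export
read_entries <- function(path, schema) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character")
  if (!identical(names(df), entry_header))
    stop(sprintf("%s: header must be exactly '%s'", path,
                 paste(entry_header, collapse = ",")), call. = FALSE)
  bad <- which(!nzchar(df$study_id) | !nzchar(df$module) | !nzchar(df$variable) |
               is.na(suppressWarnings(as.integer(df$round))))
  if (length(bad))
    stop(sprintf("%s: malformed row at line %d", path, bad[1] + 1L), call. = FALSE)
  unknown <- setdiff(unique(df$variable), names(schema$variables))
  if (length(unknown)) {
    warning(sprintf("unknown variable(s) in %s: %s", path,
                    paste(unknown, collapse = ", ")), call. = FALSE)
    df <- df[df$variable %in% names(schema$variables), , drop = FALSE]
  }
  key <- paste(df$study_id, df$module, df$reader_id, df$round, sep = "\r")
  out <- lapply(split(df, key), function(g) {
    entry_set(g$study_id[1], g$module[1], g$reader_id[1],
              stats::setNames(g$value, g$variable), as.integer(g$round[1]))
  })
  out <- unname(out)
  attr(out, "unknown_variables") <- unknown
  out
}

#' Write committed records as wide CSV plus provenance CSV
#'
#' @param committed List of `committed_record` objects.
#' @param path Output CSV (`study_id` plus one column per variable).
#' @param provenance_path Optional provenance CSV
#'   (`study_id,variable,provenance`).
#' @return `path`, invisibly.
#' @export
write_committed <- function(committed, path, provenance_path = NULL) {
  vars <- unique(unlist(lapply(committed, function(r) names(r$values))))
  df <- do.call(rbind, lapply(committed, function(r) {
    row <- stats::setNames(as.list(rep(NA_character_, length(vars))), vars)
    row[names(r$values)] <- unname(r$values)
    cbind(data.frame(study_id = r$study_id, stringsAsFactors = FALSE),
          as.data.frame(row, stringsAsFactors = FALSE))
  }))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  if (!is.null(provenance_path)) {
    pv <- do.call(rbind, lapply(committed, function(r)
      data.frame(study_id = r$study_id, variable = names(r$provenance),
                 provenance = unname(r$provenance), stringsAsFactors = FALSE)))
    utils::write.csv(pv, provenance_path, row.names = FALSE, na = "")
  }
  invisible(path)
}

#' Write the reproducibility report CSVs
#'
#' @param report A `repro_report`.
#' @param path Per-variable report CSV
#'   (`module,variable,kind,difficulty,n,statistic,estimate,ci_low,ci_high,eligibility`).
#' @param summary_path Optional per-module summary CSV
#'   (`module,count,min,max,median,mean`).
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(report, path, summary_path = NULL) {
  el <- report$eligibility
  res <- report$results
  merged <- merge(el[, c("module", "variable", "kind", "difficulty", "status")],
                  if (is.null(res)) data.frame(variable = character(),
                                               n = integer(), statistic = character(),
                                               estimate = numeric(), ci_low = numeric(),
                                               ci_high = numeric())
                  else res[, c("variable", "n", "statistic", "estimate",
                               "ci_low", "ci_high")],
                  by = "variable", all.x = TRUE)
  names(merged)[names(merged) == "status"] <- "eligibility"
  merged <- merged[, c("module", "variable", "kind", "difficulty", "n",
                       "statistic", "estimate", "ci_low", "ci_high",
                       "eligibility")]
  utils::write.csv(merged, path, row.names = FALSE, na = "")
  if (!is.null(summary_path) && !is.null(report$summaries))
    utils::write.csv(report$summaries, summary_path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write a quality-trend report CSV
#'
#' @param trend A [quality_trend()] result.
#' @param path Output CSV (`period,issues,processed,rate,flag,reason`).
#' @return `path`, invisibly.
#' @export
write_trend_csv <- function(trend, path) {
  utils::write.csv(as.data.frame(trend), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write a long-format dataset CSV
#'
#' @param df Data frame with `study_id`, `module`, `variable`, `value`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a long-format dataset CSV
#'
#' @param path CSV with columns `study_id`, `variable`, `value` (a
#'   `module` column is allowed and preserved).
#' @return Data frame.
#' @export
read_dataset <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("study_id", "variable", "value")
  if (!all(need %in% names(df)))
    stop(sprintf("%s: needs columns %s", path, paste(need, collapse = ", ")),
         call. = FALSE)
  df$value[!nzchar(df$value)] <- NA_character_
  df
}
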