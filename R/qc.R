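#' Weekly QC sample size
#'
#' The sampling re-entry protocol draws one record in each of the first
#' three weeks of a month and, in the fourth week, ceiling(sqrt(n + 1))
#' records where n is the month-to-date count of submitted records. The
#' draw can never exceed the number of submitted records.
#'
#' @param week_index Week of the month, 1-4.
#' @param n_submitted Month-to-date count of submitted records (>= 0).
#' @return Integer sample size.
#' @export
weekly_sample_size <- function(week_index, n_submitted) {
  week_index <- as.integer(week_index)
  n_submitted <- as.integer(n_submitted)
  if (is.na(week_index) || week_index < 1L || week_index > 4L)
    stop("week_index must be between 1 and 4", call. = FALSE)
  if (is.na(n_submitted) || n_submitted < 0L)
    stop("n_submitted must be a non-negative count", call. = FALSE)
  if (week_index <= 3L) return(min(1L, n_submitted))
  min(as.integer(ceiling(sqrt(n_submitted + 1))), n_submitted)
}

#' Draw a QC sample of committed records
#'
#' Simple random sample without replacement, reproducible under `seed`.
#'
#' @param study_ids Character vector of committed record IDs (or a list of
#'   `committed_record` objects).
#' @param k Sample size; must not exceed the population size.
#' @param seed Integer seed.
#' @return Character vector of sampled study IDs.
#' @export
draw_qc_sample <- function(study_ids, k, seed) {
  if (is.list(study_ids))
    study_ids <- vapply(study_ids, `[[`, character(1), "study_id")
  k <- as.integer(k)
  if (k > length(study_ids))
    stop(sprintf("cannot sample %d from a population of %d", k, length(study_ids)),
         call. = FALSE)
  with_seed(seed, sample(study_ids, k, replace = FALSE))
}

qc_issue <- function(study_id, variable, source, detail, timestamp = NULL) {
  data.frame(
    timestamp = if (is.null(timestamp)) format(Sys.time(), "%Y-%m-%dT%H:%M:%S") else timestamp,
    study_id = as.character(study_id), variable = as.character(variable),
    source = source, detail = as.character(detail), stringsAsFactors = FALSE)
}

no_qc_issues <- function() {
  data.frame(timestamp = character(), study_id = character(),
             variable = character(), source = character(),
             detail = character(), stringsAsFactors = FALSE)
}

#' Evaluate a sampling re-entry against a committed record
#'
#' Re-entry covers the error-prone variables only; a mismatch on any other
#' variable is outside the protocol's scope and raises no issue.
#'
#' @param committed A `committed_record`.
#' @param reentry An [entry_set()] holding the re-entered values.
#' @param error_prone_vars Character vector of error-prone variable names
#'   to check; the re-entry must cover all of them.
#' @param schema A [cdm_schema()] (for canonical comparison).
#' @param tau Continuous comparison tolerance.
#' @return Data frame of `sampling_mismatch` QC issues (possibly 0 rows).
#' @export
evaluate_qc_sample <- function(committed, reentry, error_prone_vars, schema,
                               tau = 0) {
  stopifnot(inherits(committed, "committed_record"), inherits(reentry, "entry_set"))
  not_covered <- setdiff(error_prone_vars, names(reentry$values))
  if (length(not_covered))
    stop(sprintf("re-entry does not cover error-prone variable(s): %s",
                 paste(not_covered, collapse = ", ")), call. = FALSE)
  issues <- no_qc_issues()
  for (v in error_prone_vars) {
    kind <- schema_variable(schema, v)$kind
    cv <- if (v %in% names(committed$values)) committed$values[[v]] else NA_character_
    rv <- reentry$values[[v]]
    if (!values_equal(cv, rv, kind, tau)) {
      issues <- rbind(issues, qc_issue(
        committed$study_id, v, "sampling_mismatch",
        sprintf("committed '%s' vs re-entry '%s'", cv, rv)))
    }
  }
  issues
}

#' Temporal quality-trend monitoring
#'
#' Shewhart-style control rules over per-period issue rates: a period is
#' flagged when (a) its rate exceeds the mean + 3 standard deviations of
#' all preceding periods, once at least `min_baseline` prior periods exist,
#' or (b) rates rise strictly over three consecutive periods. Periods with
#' fewer than `min_baseline` predecessors get status
#' `"insufficient baseline"` for rule (a).
#'
#' @param issues Data frame of QC issues with a `period` column (or a
#'   character vector of periods, one element per issue).
#' @param processed_per_period Named integer vector: records processed per
#'   period, in chronological order. A period with issues but zero
#'   processed records is a data error.
#' @param min_baseline Minimum number of prior periods before rule (a)
#'   applies (default 4).
#' @return An object of class `quality_trend`: data frame with `period`,
#'   `issues`, `processed`, `rate`, `flag`, `reason`.
#' @export
quality_trend <- function(issues, processed_per_period, min_baseline = 4L) {
  periods <- names(processed_per_period)
  if (is.null(periods)) stop("processed_per_period must be named by period", call. = FALSE)
  issue_periods <- if (is.data.frame(issues)) issues$period else as.character(issues)
  counts <- table(factor(issue_periods, levels = periods))
  processed <- as.integer(processed_per_period)
  bad <- which(counts > 0 & processed == 0)
  if (length(bad))
    stop(sprintf("period '%s' has issues but zero processed records",
                 periods[bad[1]]), call. = FALSE)
  rate <- ifelse(processed > 0, as.integer(counts) / processed, NA_real_)
  n <- length(periods)
  flag <- logical(n); reason <- character(n)
  for (i in seq_len(n)) {
    if (is.na(rate[i])) { reason[i] <- "no records processed"; next }
    base <- rate[seq_len(i - 1L)]
    base <- base[!is.na(base)]
    if (length(base) < min_baseline) {
      reason[i] <- "insufficient baseline"
    } else {
      thr <- mean(base) + 3 * stats::sd(base)
      if (!is.na(thr) && rate[i] > thr) {
        flag[i] <- TRUE
        reason[i] <- sprintf("rate %.4f exceeds baseline mean+3sd (%.4f)", rate[i], thr)
      }
    }
    if (i >= 3L && !anyNA(rate[(i - 2L):i]) &&
        rate[i - 2L] < rate[i - 1L] && rate[i - 1L] < rate[i]) {
      flag[i] <- TRUE
      reason[i] <- paste(c(if (nzchar(reason[i]) && reason[i] != "insufficient baseline") reason[i],
                           "strict rise over 3 consecutive periods"), collapse = "; ")
    }
  }
  out <- data.frame(period = periods, issues = as.integer(counts),
                    processed = processed, rate = rate, flag = flag,
                    reason = reason, stringsAsFactors = FALSE)
  class(out) <- c("quality_trend", "data.frame")
  out
}

#' Write a QC issue log as JSON-lines
#'
#' @param issues QC issue data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qc_log <- function(issues, path) {
  lines <- vapply(seq_len(nrow(issues)), function(i)
    as.character(jsonlite::toJSON(as.list(issues[i, ]), auto_unbox = TRUE, na = "null")),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a QC issue log from JSON-lines
#'
#' @param path Path written by [write_qc_log()].
#' @return QC issue data frame.
#' @export
read_qc_log <- function(path) {
  rows <- lapply(readLines(path), function(line)
    as.data.frame(jsonlite::fromJSON(line), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
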