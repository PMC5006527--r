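#' One reader's entry for one record-module
#'
#' @param study_id Study ID of the record.
#' @param module Module name.
#' @param reader_id Identifier of the data specialist who entered the data.
#' @param values Named character vector mapping variable names to raw text;
#'   an absent name (or `NA`) means missing.
#' @param round Entry round: 1 for initial entries, >= 2 for re-entries.
#' @return An object of class `entry_set`.
#' @export
entry_set <- function(study_id, module, reader_id, values, round = 1L) {
  round <- as.integer(round)
  if (round < 1L) stop("round must be >= 1", call. = FALSE)
  values <- vapply(as.list(values), function(v)
    if (is_missing_value(v)) NA_character_ else as.character(v), character(1))
  structure(
    list(study_id = as.character(study_id), module = as.character(module),
         reader_id = as.character(reader_id), round = round,
         values = values,
         submitted_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    class = "entry_set"
  )
}

audit_event <- function(actor_id, action, study_id = NA, module = NA,
                        variable = NA, payload = "") {
  list(timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3"),
       actor_id = as.character(actor_id), action = action,
       study_id = as.character(study_id), module = as.character(module),
       variable = as.character(variable), payload = as.character(payload))
}

conflict_key <- function(study_id, module, variable)
  paste(study_id, module, variable, sep = "\r")

#' Create a double-entry workflow
#'
#' The workflow object is a value: every operation takes a workflow and
#' returns the updated workflow. It tracks entry tasks, submitted entries,
#' conflicts with their adjudication state machine, a global append-only
#' audit trail, and committed records.
#'
#' @param schema A [cdm_schema()].
#' @param tau Continuous comparison tolerance passed to [compare_entries()].
#' @param max_rounds Maximum adjudication rounds before a still-disagreeing
#'   conflict is force-escalated (default 2).
#' @return An object of class `dress_workflow`.
#' @export
dress_workflow <- function(schema, tau = 0, max_rounds = 2L) {
  stopifnot(inherits(schema, "cdm_schema"))
  structure(
    list(schema = schema, tau = tau, max_rounds = as.integer(max_rounds),
         tasks = data.frame(task_id = character(), study_id = character(),
                            module = character(), slot = character(),
                            round = integer(), variable = character(),
                            status = character(), reader_id = character(),
                            stringsAsFactors = FALSE),
         entries = list(), conflicts = list(), audit = list(),
         committed = list()),
    class = "dress_workflow"
  )
}

#' @export
print.dress_workflow <- function(x, ...) {
  states <- vapply(x$conflicts, `[[`, character(1), "state")
  cat(sprintf(
    "double-entry workflow: %d tasks (%d open), %d entries, %d conflicts (%d unresolved), %d committed records\n",
    nrow(x$tasks), sum(x$tasks$status == "open"), length(x$entries),
    length(states), sum(!states %in% c("final", "final_escalated")),
    length(x$committed)))
  invisible(x)
}

append_audit <- function(wf, ev) { wf$audit[[length(wf$audit) + 1L]] <- ev; wf }

#' Create entry tasks for a de-identified record
#'
#' Two independent entry tasks (slots A and B) are created for every
#' non-empty module of the record. Reader identities are bound at
#' submission time, where distinctness within a module is enforced.
#'
#' @param wf A [dress_workflow()].
#' @param deid A `deidentified_record`.
#' @return The updated workflow.
#' @export
create_tasks <- function(wf, deid) {
  stopifnot(inherits(wf, "dress_workflow"), inherits(deid, "deidentified_record"))
  mods <- names(deid$module_payloads)
  mods <- mods[vapply(deid$module_payloads, length, integer(1)) > 0L]
  bad <- setdiff(mods, wf$schema$modules)
  if (length(bad))
    stop(sprintf("record modules not in schema: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  for (m in mods) for (slot in c("A", "B")) {
    wf$tasks <- rbind(wf$tasks, data.frame(
      task_id = sprintf("%s/%s/%s/r1", deid$study_id, m, slot),
      study_id = deid$study_id, module = m, slot = slot, round = 1L,
      variable = NA_character_, status = "open", reader_id = NA_character_,
      stringsAsFactors = FALSE))
  }
  append_audit(wf, audit_event("system", "compare", deid$study_id,
                               paste(mods, collapse = ","),
                               payload = sprintf("%d entry tasks created", 2L * length(mods))))
}

entry_key <- function(study_id, module, slot, round)
  paste(study_id, module, slot, round, sep = "\r")

#' Submit one reader's entry
#'
#' Fills an open round-1 task slot. The two tasks of a module must be
#' claimed by distinct readers. Every submission is validated against the
#' schema (range/category/parse checks) and the issues recorded in the
#' audit trail. When the second entry of a module arrives, comparison runs
#' automatically and conflicts are materialized.
#'
#' @param wf A [dress_workflow()].
#' @param entries An [entry_set()] with `round = 1`.
#' @return The updated workflow.
#' @export
submit_entry <- function(wf, entries) {
  stopifnot(inherits(wf, "dress_workflow"), inherits(entries, "entry_set"))
  idx <- which(wf$tasks$study_id == entries$study_id &
               wf$tasks$module == entries$module &
               wf$tasks$round == 1L & is.na(wf$tasks$variable))
  if (length(idx) == 0L)
    stop(sprintf("no entry tasks exist for record %s module %s",
                 entries$study_id, entries$module), call. = FALSE)
  open_idx <- idx[wf$tasks$status[idx] == "open"]
  if (length(open_idx) == 0L)
    stop(sprintf("both entry tasks for record %s module %s are already closed",
                 entries$study_id, entries$module), call. = FALSE)
  other <- setdiff(idx, open_idx)
  if (length(other) && entries$reader_id %in% wf$tasks$reader_id[other])
    stop(sprintf("reader '%s' already entered module %s of this record; the two entries must be independent",
                 entries$reader_id, entries$module), call. = FALSE)
  unknown <- setdiff(names(entries$values),
                     schema_variables(wf$schema, entries$module))
  if (length(unknown))
    stop(sprintf("entry contains variable(s) not in module %s: %s",
                 entries$module, paste(unknown, collapse = ", ")), call. = FALSE)

  take <- open_idx[1]
  wf$tasks$status[take] <- "closed"
  wf$tasks$reader_id[take] <- entries$reader_id
  slot <- wf$tasks$slot[take]
  wf$entries[[entry_key(entries$study_id, entries$module, slot, 1L)]] <- entries

  issues <- do.call(rbind, c(list(no_issues()), lapply(names(entries$values), function(v)
    validate_value(wf$schema, v, entries$values[[v]], entries$study_id))))
  wf <- append_audit(wf, audit_event(
    entries$reader_id, "compare", entries$study_id, entries$module,
    payload = sprintf("entry submitted to slot %s; %d validation issue(s)%s",
                      slot, nrow(issues),
                      if (nrow(issues)) paste0(": ", paste(issues$variable, issues$issue_kind,
                                                           sep = "/", collapse = "; "))
                      else "")))

  if (all(wf$tasks$status[idx] == "closed")) {
    a <- wf$entries[[entry_key(entries$study_id, entries$module, "A", 1L)]]
    b <- wf$entries[[entry_key(entries$study_id, entries$module, "B", 1L)]]
    confs <- compare_entries(a, b, wf$schema, wf$tau)
    for (cf in confs)
      wf$conflicts[[conflict_key(cf$study_id, cf$module, cf$variable)]] <- cf
    wf <- append_audit(wf, audit_event(
      "system", "compare", entries$study_id, entries$module,
      payload = sprintf("second entry received; comparison found %d conflict(s)",
                        length(confs))))
  }
  wf
}

#' Module entry status
#'
#' @param wf A [dress_workflow()].
#' @param study_id,module Record and module.
#' @return `"awaiting first entry"`, `"awaiting second entry"` or
#'   `"compared"`.
#' @export
module_status <- function(wf, study_id, module) {
  idx <- which(wf$tasks$study_id == study_id & wf$tasks$module == module &
               wf$tasks$round == 1L & is.na(wf$tasks$variable))
  if (length(idx) == 0L) stop("no such module tasks", call. = FALSE)
  n <- sum(wf$tasks$status[idx] == "closed")
  c("awaiting first entry", "awaiting second entry", "compared")[n + 1L]
}

#' Detect conflicts between two independent entries
#'
#' One conflict per variable whose canonicalized values differ (see
#' [values_equal()] for the canonical forms). Missing-vs-present is a
#' conflict; missing-vs-missing agrees.
#'
#' @param a,b [entry_set()]s with the same study ID, module and round and
#'   distinct readers.
#' @param schema A [cdm_schema()].
#' @param tau Continuous comparison tolerance (default 0).
#' @return A list of `dress_conflict` objects in state `"open"`.
#' @export
compare_entries <- function(a, b, schema, tau = 0) {
  stopifnot(inherits(a, "entry_set"), inherits(b, "entry_set"))
  if (a$study_id != b$study_id || a$module != b$module || a$round != b$round)
    stop("entry sets must share study_id, module and round", call. = FALSE)
  if (a$reader_id == b$reader_id)
    stop("the two entries must come from distinct readers", call. = FALSE)
  vars <- union(names(a$values), names(b$values))
  conflicts <- list()
  for (v in vars) {
    kind <- schema_variable(schema, v)$kind
    va <- if (v %in% names(a$values)) a$values[[v]] else NA_character_
    vb <- if (v %in% names(b$values)) b$values[[v]] else NA_character_
    if (!values_equal(va, vb, kind, tau)) {
      conflicts[[length(conflicts) + 1L]] <- structure(
        list(study_id = a$study_id, module = a$module, variable = v,
             value_a = va, value_b = vb, state = "open",
             adjudicated_value = NA_character_, final_value = NA_character_,
             readers = c(A = a$reader_id, B = b$reader_id),
             adjudicators = character(), rounds_used = 0L,
             audit = list(audit_event("system", "compare", a$study_id,
                                      a$module, v,
                                      payload = sprintf("'%s' vs '%s'", va, vb)))),
        class = "dress_conflict")
    }
  }
  conflicts
}

get_conflict <- function(wf, study_id, module, variable) {
  cf <- wf$conflicts[[conflict_key(study_id, module, variable)]]
  if (is.null(cf))
    stop(sprintf("no conflict recorded for %s/%s/%s", study_id, module, variable),
         call. = FALSE)
  cf
}

#' List conflicts of a workflow
#'
#' @param wf A [dress_workflow()].
#' @param study_id Optional filter.
#' @return Data frame with one row per conflict.
#' @export
conflicts <- function(wf, study_id = NULL) {
  cfs <- wf$conflicts
  if (!is.null(study_id))
    cfs <- Filter(function(cf) cf$study_id %in% study_id, cfs)
  if (length(cfs) == 0L)
    return(data.frame(study_id = character(), module = character(),
                      variable = character(), value_a = character(),
                      value_b = character(), state = character(),
                      final_value = character(), stringsAsFactors = FALSE))
  do.call(rbind, lapply(unname(cfs), function(cf)
    data.frame(study_id = cf$study_id, module = cf$module,
               variable = cf$variable, value_a = cf$value_a,
               value_b = cf$value_b, state = cf$state,
               final_value = cf$final_value, stringsAsFactors = FALSE)))
}

conflict_actors <- function(cf) unique(c(cf$readers, cf$adjudicators))

#' Adjudicate an open conflict
#'
#' The adjudicator (distinct from both readers) records the post-QC value,
#' which is *not* disclosed to the readers: two blind round-2 re-entry
#' tasks for the conflicted variable are created instead.
#'
#' @param wf A [dress_workflow()].
#' @param study_id,module,variable Conflict coordinates.
#' @param value The adjudicated raw value.
#' @param adjudicator_id Identity of the adjudicating QC specialist.
#' @return The updated workflow.
#' @export
adjudicate <- function(wf, study_id, module, variable, value, adjudicator_id) {
  cf <- get_conflict(wf, study_id, module, variable)
  if (cf$state != "open")
    stop(sprintf("conflict %s/%s is in state '%s'; only open conflicts can be adjudicated",
                 module, variable, cf$state), call. = FALSE)
  if (adjudicator_id %in% conflict_actors(cf))
    stop(sprintf("adjudicator '%s' already acted on this conflict; adjudication must be independent",
                 adjudicator_id), call. = FALSE)
  cf$adjudicated_value <- as.character(value)
  cf$adjudicators <- c(cf$adjudicators, adjudicator_id)
  cf$rounds_used <- cf$rounds_used + 1L
  cf$state <- "reentry_pending"
  cf$audit <- c(cf$audit, list(audit_event(adjudicator_id, "adjudicate",
                                           study_id, module, variable)))
  round <- cf$rounds_used + 1L
  for (slot in c("A", "B")) {
    wf$tasks <- rbind(wf$tasks, data.frame(
      task_id = sprintf("%s/%s/%s/%s/r%d", study_id, module, variable, slot, round),
      study_id = study_id, module = module, slot = slot, round = round,
      variable = variable, status = "open",
      reader_id = unname(cf$readers[slot]), stringsAsFactors = FALSE))
  }
  wf$conflicts[[conflict_key(study_id, module, variable)]] <- cf
  wf <- append_audit(wf, audit_event(adjudicator_id, "adjudicate", study_id,
                                     module, variable,
                                     payload = "post-QC value recorded; blind re-entry tasks issued"))
  append_audit(wf, audit_event("system", "reentry", study_id, module, variable,
                               payload = sprintf("2 blind re-entry tasks (round %d)", round)))
}

#' Blind re-entry tasks of a workflow
#'
#' Re-entry tasks never carry the adjudicated value; this accessor returns
#' exactly what a reader would see.
#'
#' @param wf A [dress_workflow()].
#' @return Data frame of open re-entry tasks (round >= 2).
#' @export
reentry_tasks <- function(wf) {
  wf$tasks[wf$tasks$round >= 2L & wf$tasks$status == "open", , drop = FALSE]
}

#' Process both blind re-entries for a conflict
#'
#' Outcomes: (i) both re-entries canonically equal the adjudicated value:
#' consensus, the conflict is final; (ii) the re-entries agree with each
#' other but not with the adjudicated value: the readers implicitly
#' question the adjudicator and the conflict auto-escalates; (iii) the
#' re-entries disagree: the conflict reopens for another adjudication
#' round, or escalates once `max_rounds` adjudication rounds are exhausted.
#'
#' @param wf A [dress_workflow()].
#' @param study_id,module,variable Conflict coordinates.
#' @param re_a,re_b Raw re-entered values from readers A and B.
#' @return The updated workflow.
#' @export
process_reentries <- function(wf, study_id, module, variable, re_a, re_b) {
  cf <- get_conflict(wf, study_id, module, variable)
  if (cf$state != "reentry_pending")
    stop(sprintf("conflict %s/%s is in state '%s'; expected reentry_pending",
                 module, variable, cf$state), call. = FALSE)
  kind <- schema_variable(wf$schema, variable)$kind
  tau <- wf$tau
  ridx <- which(wf$tasks$study_id == study_id & wf$tasks$module == module &
                !is.na(wf$tasks$variable) & wf$tasks$variable == variable &
                wf$tasks$status == "open")
  wf$tasks$status[ridx] <- "closed"

  a_ok <- values_equal(re_a, cf$adjudicated_value, kind, tau)
  b_ok <- values_equal(re_b, cf$adjudicated_value, kind, tau)
  ab <- values_equal(re_a, re_b, kind, tau)
  cf$audit <- c(cf$audit, list(audit_event(cf$readers[["A"]], "reentry",
                                           study_id, module, variable),
                               audit_event(cf$readers[["B"]], "reentry",
                                           study_id, module, variable)))
  if (a_ok && b_ok) {
    cf$state <- "final"
    cf$final_value <- cf$adjudicated_value
    cf$audit <- c(cf$audit, list(audit_event("system", "consensus", study_id,
                                             module, variable)))
    wf <- append_audit(wf, audit_event("system", "consensus", study_id, module,
                                       variable, payload = "re-entries match adjudicated value"))
  } else if (ab) {
    cf$state <- "escalated_pending"
    cf$audit <- c(cf$audit, list(audit_event("system", "escalate", study_id,
                                             module, variable)))
    wf <- append_audit(wf, audit_event("system", "escalate", study_id, module,
                                       variable,
                                       payload = "readers agree against adjudicated value"))
  } else if (cf$rounds_used >= wf$max_rounds) {
    cf$state <- "escalated_pending"
    cf$audit <- c(cf$audit, list(audit_event("system", "escalate", study_id,
                                             module, variable)))
    wf <- append_audit(wf, audit_event("system", "escalate", study_id, module,
                                       variable,
                                       payload = sprintf("adjudication rounds exhausted (%d)",
                                                         cf$rounds_used)))
  } else {
    cf$state <- "open"
    cf$adjudicated_value <- NA_character_
    wf <- append_audit(wf, audit_event("system", "compare", study_id, module,
                                       variable,
                                       payload = "re-entries disagree; reopened for adjudication"))
  }
  wf$conflicts[[conflict_key(study_id, module, variable)]] <- cf
  wf
}

#' Senior decision on an escalated conflict
#'
#' @param wf A [dress_workflow()].
#' @param study_id,module,variable Conflict coordinates.
#' @param value Final raw value.
#' @param senior_id Senior QC identity; must be distinct from every prior
#'   actor on this conflict.
#' @return The updated workflow.
#' @export
senior_decide <- function(wf, study_id, module, variable, value, senior_id) {
  cf <- get_conflict(wf, study_id, module, variable)
  if (cf$state != "escalated_pending")
    stop(sprintf("conflict %s/%s is in state '%s'; only escalated conflicts take a senior decision",
                 module, variable, cf$state), call. = FALSE)
  if (senior_id %in% conflict_actors(cf))
    stop(sprintf("'%s' already acted on this conflict; the senior decision must be independent",
                 senior_id), call. = FALSE)
  cf$state <- "final_escalated"
  cf$final_value <- as.character(value)
  cf$audit <- c(cf$audit, list(audit_event(senior_id, "senior_decision",
                                           study_id, module, variable)))
  wf$conflicts[[conflict_key(study_id, module, variable)]] <- cf
  append_audit(wf, audit_event(senior_id, "senior_decision", study_id, module,
                               variable, payload = "final decision recorded"))
}

#' Commit a record's resolved values
#'
#' Requires both entries for every requested module and every conflict in a
#' final state. Produces per-variable canonical values with provenance
#' `"agreed"` (no conflict), `"adjudicated"` (consensus after blind
#' re-entry) or `"escalated"` (senior decision).
#'
#' @param wf A [dress_workflow()].
#' @param study_id Record to commit.
#' @param modules Modules to commit; default: all modules with entry tasks
#'   for this record.
#' @return The updated workflow; retrieve the record with
#'   [committed_record()].
#' @export
commit_record <- function(wf, study_id, modules = NULL) {
  if (!is.null(wf$committed[[study_id]]))
    stop(sprintf("record %s is already committed", study_id), call. = FALSE)
  if (is.null(modules)) {
    modules <- unique(wf$tasks$module[wf$tasks$study_id == study_id &
                                      wf$tasks$round == 1L])
  }
  values <- character(); provenance <- character()
  blocking <- character()
  for (m in modules) {
    a <- wf$entries[[entry_key(study_id, m, "A", 1L)]]
    b <- wf$entries[[entry_key(study_id, m, "B", 1L)]]
    if (is.null(a) || is.null(b))
      stop(sprintf("module %s of record %s lacks both entries", m, study_id),
           call. = FALSE)
    for (v in schema_variables(wf$schema, m)) {
      cf <- wf$conflicts[[conflict_key(study_id, m, v)]]
      if (is.null(cf)) {
        raw <- if (v %in% names(a$values)) a$values[[v]] else NA_character_
        values[v] <- raw
        provenance[v] <- "agreed"
      } else if (cf$state == "final") {
        values[v] <- cf$final_value
        provenance[v] <- "adjudicated"
      } else if (cf$state == "final_escalated") {
        values[v] <- cf$final_value
        provenance[v] <- "escalated"
      } else {
        blocking <- c(blocking, sprintf("%s/%s (%s)", m, v, cf$state))
      }
    }
  }
  if (length(blocking))
    stop(sprintf("cannot commit record %s: unresolved conflict(s) on %s",
                 study_id, paste(blocking, collapse = ", ")), call. = FALSE)
  rec <- structure(list(study_id = study_id, modules = modules,
                        values = values, provenance = provenance),
                   class = "committed_record")
  wf$committed[[study_id]] <- rec
  append_audit(wf, audit_event("system", "commit", study_id,
                               paste(modules, collapse = ","),
                               payload = sprintf("%d variables committed", length(values))))
}

#' Retrieve a committed record
#'
#' @param wf A [dress_workflow()].
#' @param study_id Record ID.
#' @return The `committed_record`, or an error if not committed.
#' @export
committed_record <- function(wf, study_id) {
  rec <- wf$committed[[study_id]]
  if (is.null(rec)) stop(sprintf("record %s is not committed", study_id), call. = FALSE)
  rec
}

#' Audit trail of a workflow or conflict
#'
#' @param wf A [dress_workflow()].
#' @param study_id,module,variable Optional filters; with all three set,
#'   the per-conflict trail is returned.
#' @return Data frame of audit events in order.
#' @export
audit_trail <- function(wf, study_id = NULL, module = NULL, variable = NULL) {
  evs <- if (!is.null(study_id) && !is.null(module) && !is.null(variable)) {
    get_conflict(wf, study_id, module, variable)$audit
  } else {
    wf$audit
  }
  if (length(evs) == 0L)
    return(data.frame(timestamp = character(), actor_id = character(),
                      action = character(), study_id = character(),
                      module = character(), variable = character(),
                      payload = character(), stringsAsFactors = FALSE))
  do.call(rbind, lapply(evs, function(e)
    data.frame(e, stringsAsFactors = FALSE)))
}

#' Replay a conflict's audit trail to its implied state
#'
#' Deterministically reconstructs the lifecycle state from the ordered
#' action sequence alone, independent of the stored `state` field; used to
#' verify that the audit trail is a faithful record.
#'
#' @param actions Character vector of audit actions in order.
#' @return The implied state string.
#' @export
replay_conflict_state <- function(actions) {
  state <- NA_character_
  for (act in actions) {
    state <- switch(act,
      compare = if (is.na(state)) "open" else state,
      adjudicate = "reentry_pending",
      reentry = state,
      consensus = "final",
      escalate = "escalated_pending",
      senior_decision = "final_escalated",
      state)
  }
  state
}

#' Write an audit trail as JSON-lines
#'
#' @param wf A [dress_workflow()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_audit_log <- function(wf, path) {
  lines <- vapply(wf$audit, function(e)
    as.character(jsonlite::toJSON(e, auto_unbox = TRUE, na = "null")),
    character(1))
  writeLines(lines, path)
  invisible(path)
}
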