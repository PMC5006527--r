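# End-to-end driver: truth -> de-identification -> two simulated entries ->
# conflict detection -> oracle-driven adjudication, re-entry and escalation
# -> commit. Exercises the whole engine on synthetic records and is the
# backbone of the workflow-safety checks.

simulate_reentry_value <- function(truth_value, vdef, param, model) {
  if (stats::runif(1) < error_rate(model, vdef$difficulty))
    perturb_value(truth_value, vdef, param, model)
  else truth_value
}

#' Run the full double-entry pipeline on simulated records
#'
#' For every record: de-identify, create tasks, submit two independently
#' simulated entries, then resolve every conflict with a truth oracle as
#' adjudicator — the adjudicated value is the true value, blind re-entries
#' are fresh reads under the same error model, disagreeing re-entries
#' trigger another adjudication round, exhausted or contested rounds
#' escalate to a senior decision (also the true value) — and finally
#' commit.
#'
#' @param schema A schema from [simulate_schema()].
#' @param records Records from [simulate_truth()].
#' @param model An [error_model()].
#' @param seed Integer seed driving entries and re-entries.
#' @param salt Salt for study-ID assignment.
#' @param readers Two reader identities.
#' @return A list per record with `study_id`, `committed`
#'   (`committed_record`), `conflicts` (data frame), `entries` (the two
#'   round-1 [entry_set()]s), `truth` (named character vector of true
#'   values) and `audit` (the record's workflow audit trail).
#' @export
run_double_entry <- function(schema, records, model = error_model(),
                             seed = 1L, salt = "sim-salt",
                             readers = c("DS_A", "DS_B")) {
  params <- attr(schema, "sim_params")
  lapply(records, function(record) {
    deid <- deidentify_record(record, schema, salt)$deid
    sid <- deid$study_id
    wf <- dress_workflow(schema)
    wf <- create_tasks(wf, deid)
    ents <- lapply(readers, function(rid) {
      es <- simulate_entries(record, schema, model, rid, seed)
      lapply(es, function(e) { e$study_id <- sid; e })
    })
    for (ri in seq_along(readers))
      for (m in names(ents[[ri]]))
        wf <- submit_entry(wf, ents[[ri]][[m]])

    truth <- unlist(unname(record$modules))
    cfs <- conflicts(wf, sid)
    qc_round <- 0L
    repeat {
      open <- conflicts(wf, sid)
      open <- open[!open$state %in% c("final", "final_escalated"), , drop = FALSE]
      if (nrow(open) == 0L) break
      for (j in seq_len(nrow(open))) {
        m <- open$module[j]; v <- open$variable[j]; st <- open$state[j]
        tv <- truth[[v]]
        if (st == "open") {
          qc_round <- qc_round + 1L
          wf <- adjudicate(wf, sid, m, v, tv, sprintf("QC%d", qc_round))
        } else if (st == "reentry_pending") {
          vdef <- schema_variable(schema, v)
          res <- with_seed(derive_seed(seed, paste(sid, v, qc_round)), {
            list(a = simulate_reentry_value(tv, vdef, params[[v]], model),
                 b = simulate_reentry_value(tv, vdef, params[[v]], model))
          })
          wf <- process_reentries(wf, sid, m, v, res$a, res$b)
        } else if (st == "escalated_pending") {
          wf <- senior_decide(wf, sid, m, v, tv, "QC_SENIOR")
        }
      }
    }
    wf <- commit_record(wf, sid)
    list(study_id = sid, committed = committed_record(wf, sid),
         conflicts = cfs, entries = ents, truth = truth,
         audit = audit_trail(wf))
  })
}
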