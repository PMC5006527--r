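make_deid <- function(schema = tiny_schema(), study_id = "S001") {
  structure(list(
    study_id = study_id,
    module_payloads = list(
      general_patient_information = c(gender = "Male", height = "172.0"),
      surgery = c(op_note = "routine", op_minutes = "120"))),
    class = "deidentified_record")
}

test_that("task creation yields two tasks per non-empty module", {
  schema <- tiny_schema()
  wf <- create_tasks(dress_workflow(schema), make_deid(schema))
  expect_equal(nrow(wf$tasks), 4L)          # 2 modules x 2 slots
  expect_setequal(wf$tasks$slot, c("A", "B"))
  empty <- structure(list(study_id = "S9", module_payloads = list()),
                     class = "deidentified_record")
  wf0 <- create_tasks(dress_workflow(schema), empty)
  expect_equal(nrow(wf0$tasks), 0L)
})

test_that("submission enforces reader independence and task state", {
  schema <- tiny_schema()
  wf <- create_tasks(dress_workflow(schema), make_deid(schema))
  e1 <- entry_set("S001", "general_patient_information", "DS_A",
                  c(gender = "Male", height = "172.0"))
  wf <- submit_entry(wf, e1)
  expect_equal(module_status(wf, "S001", "general_patient_information"),
               "awaiting second entry")
  # same reader cannot take both slots of one module
  e_same <- entry_set("S001", "general_patient_information", "DS_A",
                      c(gender = "Male"))
  expect_error(submit_entry(wf, e_same), "independent")
  e2 <- entry_set("S001", "general_patient_information", "DS_B",
                  c(gender = "Male", height = "172.0"))
  wf <- submit_entry(wf, e2)
  expect_equal(module_status(wf, "S001", "general_patient_information"),
               "compared")
  # third submission to a compared module is refused
  e3 <- entry_set("S001", "general_patient_information", "DS_C",
                  c(gender = "Male"))
  expect_error(submit_entry(wf, e3), "already closed")
})

test_that("validation issues from submissions land in the audit trail", {
  schema <- tiny_schema()
  wf <- create_tasks(dress_workflow(schema), make_deid(schema))
  wf <- submit_entry(wf, entry_set("S001", "general_patient_information", "DS_A",
                                   c(gender = "X", height = "500")))
  trail <- audit_trail(wf)
  expect_true(any(grepl("gender/category", trail$payload) &
                  grepl("height/range", trail$payload)))
})

test_that("conflict detection canonicalizes by kind", {
  schema <- tiny_schema()
  # identical entries: no conflicts
  p <- entry_pair(c(gender = "Male", height = "172.0"),
                  c(gender = "Male", height = "172.0"))
  expect_length(compare_entries(p$a, p$b, schema), 0L)
  # canonical numeric equality: "54" vs "54.0"
  p <- entry_pair(c(height = "54"), c(height = "54.0"))
  expect_length(compare_entries(p$a, p$b, schema), 0L)
  # two genuine disagreements
  p <- entry_pair(c(gender = "Male", height = "165"),
                  c(gender = "Female", height = "164"))
  cfs <- compare_entries(p$a, p$b, schema)
  expect_length(cfs, 2L)
  expect_setequal(vapply(cfs, `[[`, character(1), "variable"),
                  c("gender", "height"))
  # missing-vs-present conflicts; missing-vs-missing agrees
  p <- entry_pair(c(gender = "Male"), c(gender = "Male", height = "170"))
  expect_length(compare_entries(p$a, p$b, schema), 1L)
  p <- entry_pair(c(gender = "Male"), c(gender = "Male"))
  expect_length(compare_entries(p$a, p$b, schema), 0L)
  # whitespace/normalization for text
  p2 <- entry_pair(c(op_note = "left  upper lobe "),
                   c(op_note = "left upper lobe"), module = "surgery")
  expect_length(compare_entries(p2$a, p2$b, schema), 0L)
  # date canonicalization
  p <- entry_pair(c(admission_date = "2015-10-01"),
                  c(admission_date = "2015-10-01"))
  expect_length(compare_entries(p$a, p$b, schema), 0L)
  # usage errors
  expect_error(compare_entries(p$a, entry_set("S002", "general_patient_information",
                                              "DS_B", c(gender = "Male")), schema),
               "share study_id")
  expect_error(compare_entries(p$a, entry_set("S001", "general_patient_information",
                                              "DS_A", c(gender = "Male")), schema),
               "distinct readers")
})

test_that("continuous tolerance tau admits small numeric differences", {
  schema <- tiny_schema()
  p <- entry_pair(c(height = "172.0"), c(height = "172.4"))
  expect_length(compare_entries(p$a, p$b, schema, tau = 0.5), 0L)
  expect_length(compare_entries(p$a, p$b, schema, tau = 0), 1L)
})

test_that("conflict count equals the independent field-comparison oracle", {
  schema <- simulate_schema(vars_per_module = c(pathology = 6L, surgery = 4L),
                            seed = 21)
  records <- simulate_truth(schema, 40, seed = 21)
  model <- error_model(0.1, 0.15, 0.25, missing_prob = 0.08)
  for (i in seq_along(records)) {
    ents <- lapply(c("DS_A", "DS_B"), function(rid)
      simulate_entries(records[[i]], schema, model, rid, seed = 21))
    for (m in names(records[[i]]$modules)) {
      got <- length(compare_entries(ents[[1]][[m]], ents[[2]][[m]], schema))
      want <- brute_force_conflicts(ents[[1]][[m]], ents[[2]][[m]], schema)
      expect_equal(got, want)
    }
  }
})

# Build a workflow with one open gender conflict.
conflicted_wf <- function() {
  schema <- tiny_schema()
  wf <- create_tasks(dress_workflow(schema), make_deid(schema))
  wf <- submit_entry(wf, entry_set("S001", "general_patient_information", "DS_A",
                                   c(gender = "Male", height = "172.0")))
  wf <- submit_entry(wf, entry_set("S001", "general_patient_information", "DS_B",
                                   c(gender = "Female", height = "172.0")))
  wf <- submit_entry(wf, entry_set("S001", "surgery", "DS_A",
                                   c(op_note = "routine", op_minutes = "120")))
  wf <- submit_entry(wf, entry_set("S001", "surgery", "DS_B",
                                   c(op_note = "routine", op_minutes = "120")))
  wf
}

test_that("adjudication spawns blind re-entry tasks", {
  wf <- conflicted_wf()
  expect_equal(conflicts(wf)$state, "open")
  # adjudicator must be independent of both readers
  expect_error(adjudicate(wf, "S001", "general_patient_information", "gender",
                          "Male", "DS_A"), "independent")
  wf <- adjudicate(wf, "S001", "general_patient_information", "gender",
                   "Male", "QC1")
  expect_equal(conflicts(wf)$state[1], "reentry_pending")
  rts <- reentry_tasks(wf)
  expect_equal(nrow(rts), 2L)
  expect_equal(rts$variable, c("gender", "gender"))
  # serialized re-entry tasks never disclose the adjudicated value
  expect_false(any(grepl("Male", unlist(lapply(rts, as.character)))))
  # double adjudication refused
  expect_error(adjudicate(wf, "S001", "general_patient_information", "gender",
                          "Male", "QC2"), "open")
})

test_that("re-entry consensus finalizes at the adjudicated value", {
  wf <- conflicted_wf()
  wf <- adjudicate(wf, "S001", "general_patient_information", "gender",
                   "Male", "QC1")
  wf <- process_reentries(wf, "S001", "general_patient_information", "gender",
                          "Male", "Male")
  cf <- conflicts(wf)[1, ]
  expect_equal(cf$state, "final")
  expect_equal(cf$final_value, "Male")
})

test_that("re-entries agreeing against the adjudicator escalate", {
  wf <- conflicted_wf()
  wf <- adjudicate(wf, "S001", "general_patient_information", "gender",
                   "Male", "QC1")
  wf <- process_reentries(wf, "S001", "general_patient_information", "gender",
                          "Female", "Female")
  expect_equal(conflicts(wf)$state[1], "escalated_pending")
  # senior must be a fresh actor
  expect_error(senior_decide(wf, "S001", "general_patient_information", "gender",
                             "Female", "QC1"), "independent")
  wf <- senior_decide(wf, "S001", "general_patient_information", "gender",
                      "Female", "QC_SR")
  cf <- conflicts(wf)[1, ]
  expect_equal(cf$state, "final_escalated")
  expect_equal(cf$final_value, "Female")
})

test_that("disagreeing re-entries reopen, then escalate at max_rounds", {
  wf <- conflicted_wf()
  wf <- adjudicate(wf, "S001", "general_patient_information", "gender",
                   "Male", "QC1")
  wf <- process_reentries(wf, "S001", "general_patient_information", "gender",
                          "Male", "Female")
  expect_equal(conflicts(wf)$state[1], "open")
  wf <- adjudicate(wf, "S001", "general_patient_information", "gender",
                   "Male", "QC2")
  wf <- process_reentries(wf, "S001", "general_patient_information", "gender",
                          "Male", "Female")
  expect_equal(conflicts(wf)$state[1], "escalated_pending")
})

test_that("senior decision only applies to escalated conflicts", {
  wf <- conflicted_wf()
  expect_error(senior_decide(wf, "S001", "general_patient_information", "gender",
                             "Male", "QC_SR"), "escalated")
})

test_that("commit requires resolution and records provenance", {
  wf <- conflicted_wf()
  # open conflict blocks the commit and is named
  expect_error(commit_record(wf, "S001"), "gender")
  wf <- adjudicate(wf, "S001", "general_patient_information", "gender",
                   "Male", "QC1")
  wf <- process_reentries(wf, "S001", "general_patient_information", "gender",
                          "Male", "Male")
  wf <- commit_record(wf, "S001")
  rec <- committed_record(wf, "S001")
  expect_equal(unname(rec$provenance[["gender"]]), "adjudicated")
  expect_equal(unname(rec$provenance[["height"]]), "agreed")
  expect_equal(unname(rec$values[["gender"]]), "Male")
  # double commit refused
  expect_error(commit_record(wf, "S001"), "already committed")
})

test_that("conflict-free module commits with all-agreed provenance", {
  schema <- tiny_schema()
  wf <- create_tasks(dress_workflow(schema), make_deid(schema))
  vals <- c(gender = "Male", height = "172.0")
  wf <- submit_entry(wf, entry_set("S001", "general_patient_information", "DS_A", vals))
  wf <- submit_entry(wf, entry_set("S001", "general_patient_information", "DS_B", vals))
  wf <- commit_record(wf, "S001", "general_patient_information")
  rec <- committed_record(wf, "S001")
  expect_true(all(rec$provenance == "agreed"))
})

test_that("escalated resolution carries provenance 'escalated'", {
  wf <- conflicted_wf()
  wf <- adjudicate(wf, "S001", "general_patient_information", "gender",
                   "Male", "QC1")
  wf <- process_reentries(wf, "S001", "general_patient_information", "gender",
                          "Female", "Female")
  wf <- senior_decide(wf, "S001", "general_patient_information", "gender",
                      "Female", "QC_SR")
  wf <- commit_record(wf, "S001")
  rec <- committed_record(wf, "S001")
  expect_equal(unname(rec$provenance[["gender"]]), "escalated")
  expect_equal(unname(rec$values[["gender"]]), "Female")
})

test_that("audit trails are append-only and replay to the final state", {
  wf <- conflicted_wf()
  n0 <- nrow(audit_trail(wf))
  wf <- adjudicate(wf, "S001", "general_patient_information", "gender",
                   "Male", "QC1")
  n1 <- nrow(audit_trail(wf))
  expect_gt(n1, n0)
  wf <- process_reentries(wf, "S001", "general_patient_information", "gender",
                          "Female", "Female")
  wf <- senior_decide(wf, "S001", "general_patient_information", "gender",
                      "Female", "QC_SR")
  n2 <- nrow(audit_trail(wf))
  expect_gt(n2, n1)
  # per-conflict replay reconstructs the state machine deterministically
  cf_trail <- audit_trail(wf, "S001", "general_patient_information", "gender")
  expect_equal(replay_conflict_state(cf_trail$action), "final_escalated")
  expect_equal(conflicts(wf)$state[1], "final_escalated")
})

test_that("workflow audit log serializes as JSON-lines", {
  wf <- conflicted_wf()
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_audit_log(wf, path)
  lines <- readLines(path)
  expect_equal(length(lines), length(wf$audit))
  ev <- jsonlite::fromJSON(lines[1])
  expect_true(all(c("timestamp", "actor_id", "action") %in% names(ev)))
})
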