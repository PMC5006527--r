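# Shared in-code fixtures: a small clinical schema and entry builders.

tiny_schema <- function() {
  cdm_schema(
    version_id = "test-cdm-1.0",
    modules = c("general_patient_information", "surgery"),
    variables = list(
      cdm_variable("gender", "general_patient_information", "categorical",
                   categories = c("Male", "Female"), difficulty = "easy",
                   error_prone = TRUE),
      cdm_variable("height", "general_patient_information", "continuous",
                   unit = "cm", range = c(50, 250), difficulty = "easy"),
      cdm_variable("admission_date", "general_patient_information", "date",
                   difficulty = "easy"),
      cdm_variable("discharge_date", "general_patient_information", "date",
                   difficulty = "easy"),
      cdm_variable("op_note", "surgery", "text", difficulty = "difficult"),
      cdm_variable("op_minutes", "surgery", "continuous", unit = "min",
                   range = c(0, 2000), difficulty = "medium",
                   error_prone = TRUE)
    ),
    logic_rules = list(
      logic_rule("discharge_after_admission", "compare",
                 var_a = "discharge_date", op = ">=", var_b = "admission_date",
                 message = "discharge precedes admission")
    )
  )
}

entry_pair <- function(values_a, values_b, module = "general_patient_information",
                       study_id = "S001") {
  list(a = entry_set(study_id, module, "DS_A", values_a),
       b = entry_set(study_id, module, "DS_B", values_b))
}

# Independent field-by-field disagreement oracle used against the engine.
brute_force_conflicts <- function(a, b, schema, tau = 0) {
  vars <- union(names(a$values), names(b$values))
  sum(vapply(vars, function(v) {
    va <- if (v %in% names(a$values)) a$values[[v]] else NA_character_
    vb <- if (v %in% names(b$values)) b$values[[v]] else NA_character_
    kind <- schema$variables[[v]]$kind
    ma <- is.na(va) || !nzchar(trimws(va)); mb <- is.na(vb) || !nzchar(trimws(vb))
    if (ma && mb) return(FALSE)
    if (ma || mb) return(TRUE)
    if (kind == "continuous") {
      na_ <- suppressWarnings(as.numeric(va)); nb_ <- suppressWarnings(as.numeric(vb))
      if (!is.na(na_) && !is.na(nb_)) return(abs(na_ - nb_) > tau)
    }
    trimws(va) != trimws(vb)
  }, logical(1)))
}

# Independent kappa oracle from cell proportions (coded separately from the
# package's batch implementation).
oracle_kappa <- function(tab) {
  n <- sum(tab)
  p <- tab / n
  po <- sum(diag(as.matrix(p)))
  pe <- sum(rowSums(as.matrix(p)) * colSums(as.matrix(p)))
  (po - pe) / (1 - pe)
}

make_series <- function(kind, primary, repeated, categories = NULL,
                        name = "v", module = "general_patient_information") {
  v <- cdm_variable(name, module, kind, categories = categories,
                    unit = if (kind == "continuous") "unit" else NULL)
  paired_series(v, primary, repeated)
}

# Enumerate all k x k contingency tables with total count <= nmax as a
# matrix (one row per table, cells in column-major order).
enumerate_tables <- function(k, nmax) {
  cells <- k * k
  m <- matrix(0:nmax, ncol = 1)
  for (j in 2:cells) {
    rem <- nmax - rowSums(m)
    idx <- rep(seq_len(nrow(m)), rem + 1L)
    newv <- sequence(rem + 1L) - 1L
    m <- cbind(m[idx, , drop = FALSE], newv)
  }
  colnames(m) <- NULL
  m
}
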