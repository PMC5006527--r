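#' Define a CDM variable
#'
#' A variable definition in the common data model (CDM): its module, value
#' kind, allowed categories or numeric range, abstraction difficulty, and
#' whether it is flagged as error-prone (eligible for sampling re-entry QC).
#'
#' @param name Variable identifier, unique within a schema.
#' @param module Name of the module the variable belongs to.
#' @param kind One of `"categorical"`, `"continuous"`, `"text"`, `"date"`.
#' @param categories Character vector of at least two distinct category codes
#'   (categorical variables only).
#' @param unit Free-text measurement unit (continuous variables only).
#' @param range Optional numeric `c(low, high)` with `low < high`
#'   (continuous variables only).
#' @param difficulty Abstraction difficulty: `"easy"`, `"medium"` or
#'   `"difficult"`. Easy values sit at one known position in the record;
#'   medium requires scanning several positions; difficult requires
#'   synthesising several sources.
#' @param error_prone Logical; marks the variable for periodic
#'   sampling-based re-entry QC.
#' @return An object of class `cdm_variable`.
#' @export
cdm_variable <- function(name, module, kind,
                         categories = NULL, unit = NULL, range = NULL,
                         difficulty = "easy", error_prone = FALSE) {
  kind <- match.arg(kind, c("categorical", "continuous", "text", "date"))
  difficulty <- match.arg(difficulty, c("easy", "medium", "difficult"))
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("variable `name` must be a non-empty string", call. = FALSE)
  if (!is.character(module) || length(module) != 1L || !nzchar(module))
    stop("variable `module` must be a non-empty string", call. = FALSE)
  if (kind == "categorical") {
    categories <- as.character(categories)
    if (length(unique(categories)) < 2L)
      stop(sprintf("categorical variable '%s' needs >= 2 distinct categories", name),
           call. = FALSE)
    if (anyDuplicated(categories))
      stop(sprintf("categorical variable '%s' has duplicated categories", name),
           call. = FALSE)
  } else {
    categories <- NULL
  }
  if (kind != "continuous") {
    unit <- NULL
    range <- NULL
  } else if (!is.null(range)) {
    range <- as.numeric(range)
    if (length(range) != 2L || anyNA(range) || range[1] >= range[2])
      stop(sprintf("variable '%s': valid_range must be c(low, high) with low < high", name),
           call. = FALSE)
  }
  structure(
    list(name = name, module = module, kind = kind,
         categories = categories, unit = unit, range = range,
         difficulty = difficulty, error_prone = isTRUE(error_prone)),
    class = "cdm_variable"
  )
}

#' Define a cross-field logic rule
#'
#' Logic rules express either a binary comparison between two variables
#' (`kind = "compare"`, e.g. discharge date on or after admission date) or a
#' single implication (`kind = "implies"`: if variable A holds a given code,
#' variable B must satisfy a comparison against a constant).
#'
#' @param id Rule identifier.
#' @param kind `"compare"` or `"implies"`.
#' @param var_a,op,var_b For `"compare"`: left variable, operator (one of
#'   `<`, `<=`, `==`, `!=`, `>=`, `>`), right variable.
#' @param if_var,if_value,then_var,then_op,then_value For `"implies"`: when
#'   `if_var` equals `if_value`, `then_var` must satisfy
#'   `then_op` against constant `then_value`.
#' @param message Human-readable description used in validation issues.
#' @return An object of class `logic_rule`.
#' @export
logic_rule <- function(id, kind = c("compare", "implies"),
                       var_a = NULL, op = NULL, var_b = NULL,
                       if_var = NULL, if_value = NULL,
                       then_var = NULL, then_op = NULL, then_value = NULL,
                       message = "") {
  kind <- match.arg(kind)
  ops <- c("<", "<=", "==", "!=", ">=", ">")
  if (kind == "compare") {
    if (is.null(var_a) || is.null(op) || is.null(var_b))
      stop("compare rule needs var_a, op, var_b", call. = FALSE)
    if (!op %in% ops) stop(sprintf("unknown operator '%s'", op), call. = FALSE)
  } else {
    if (is.null(if_var) || is.null(if_value) || is.null(then_var) ||
        is.null(then_op) || is.null(then_value))
      stop("implies rule needs if_var, if_value, then_var, then_op, then_value",
           call. = FALSE)
    if (!then_op %in% ops) stop(sprintf("unknown operator '%s'", then_op), call. = FALSE)
  }
  structure(
    list(id = as.character(id), kind = kind,
         var_a = var_a, op = op, var_b = var_b,
         if_var = if_var, if_value = if_value,
         then_var = then_var, then_op = then_op, then_value = then_value,
         message = as.character(message)),
    class = "logic_rule"
  )
}

rule_variables <- function(rule) {
  if (rule$kind == "compare") c(rule$var_a, rule$var_b) else c(rule$if_var, rule$then_var)
}

#' Assemble a CDM schema
#'
#' @param version_id Free-text schema version tag.
#' @param modules Ordered character vector of module names (non-empty).
#' @param variables List of [cdm_variable()] objects; names must be unique
#'   and every variable's module must appear in `modules`.
#' @param logic_rules List of [logic_rule()] objects; every referenced
#'   variable must exist in the schema.
#' @return An object of class `cdm_schema`.
#' @export
cdm_schema <- function(version_id, modules, variables, logic_rules = list()) {
  modules <- as.character(modules)
  if (length(modules) == 0L) stop("module list must be non-empty", call. = FALSE)
  if (anyDuplicated(modules)) stop("duplicated module names", call. = FALSE)
  stopifnot(is.list(variables))
  vnames <- vapply(variables, function(v) v$name, character(1))
  if (anyDuplicated(vnames)) {
    dup <- vnames[duplicated(vnames)][1]
    stop(sprintf("duplicate variable name '%s'", dup), call. = FALSE)
  }
  vmods <- vapply(variables, function(v) v$module, character(1))
  bad <- setdiff(unique(vmods), modules)
  if (length(bad))
    stop(sprintf("variable module(s) not in schema module list: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  names(variables) <- vnames
  for (r in logic_rules) {
    miss <- setdiff(rule_variables(r), vnames)
    if (length(miss))
      stop(sprintf("logic rule '%s' references unknown variable(s): %s",
                   r$id, paste(miss, collapse = ", ")), call. = FALSE)
  }
  structure(
    list(version_id = as.character(version_id), modules = modules,
         variables = variables, logic_rules = logic_rules),
    class = "cdm_schema"
  )
}

#' @export
print.cdm_schema <- function(x, ...) {
  cat(sprintf("CDM schema %s: %d modules, %d variables, %d logic rules\n",
              x$version_id, length(x$modules), length(x$variables),
              length(x$logic_rules)))
  tab <- table(factor(vapply(x$variables, `[[`, character(1), "module"),
                      levels = x$modules))
  for (m in x$modules) cat(sprintf("  %-30s %3d variables\n", m, tab[[m]]))
  invisible(x)
}

#' Look up a variable definition
#'
#' @param schema A [cdm_schema()].
#' @param variable Variable name.
#' @return The `cdm_variable` definition.
#' @export
schema_variable <- function(schema, variable) {
  v <- schema$variables[[variable]]
  if (is.null(v)) stop(sprintf("unknown variable '%s'", variable), call. = FALSE)
  v
}

#' Variable names of a schema
#'
#' @param schema A [cdm_schema()].
#' @param module Optional module name to restrict to.
#' @return Character vector of variable names.
#' @export
schema_variables <- function(schema, module = NULL) {
  v <- names(schema$variables)
  if (!is.null(module)) {
    mods <- vapply(schema$variables, `[[`, character(1), "module")
    v <- v[mods == module]
  }
  v
}

schema_to_list <- function(schema) {
  list(
    version_id = schema$version_id,
    modules = as.list(schema$modules),
    variables = lapply(unname(schema$variables), function(v) {
      out <- list(name = v$name, module = v$module, kind = v$kind)
      if (!is.null(v$categories)) out$categories <- as.list(v$categories)
      if (!is.null(v$unit)) out$unit <- v$unit
      if (!is.null(v$range)) out$range <- as.list(v$range)
      out$difficulty <- v$difficulty
      out$error_prone <- v$error_prone
      out
    }),
    logic_rules = lapply(schema$logic_rules, function(r) {
      out <- list(id = r$id, kind = r$kind)
      if (r$kind == "compare") {
        out$var_a <- r$var_a; out$op <- r$op; out$var_b <- r$var_b
      } else {
        out$if_var <- r$if_var; out$if_value <- r$if_value
        out$then_var <- r$then_var; out$then_op <- r$then_op
        out$then_value <- r$then_value
      }
      out$message <- r$message
      out
    })
  )
}

schema_from_list <- function(x) {
  for (key in c("version_id", "modules", "variables"))
    if (is.null(x[[key]]))
      stop(sprintf("schema config missing key '%s'", key), call. = FALSE)
  vars <- lapply(x$variables, function(v) {
    cdm_variable(
      name = v$name, module = v$module, kind = v$kind,
      categories = if (!is.null(v$categories)) unlist(v$categories),
      unit = v$unit,
      range = if (!is.null(v$range)) unlist(v$range),
      difficulty = if (is.null(v$difficulty)) "easy" else v$difficulty,
      error_prone = isTRUE(v$error_prone)
    )
  })
  rules <- lapply(x$logic_rules, function(r) {
    do.call(logic_rule, r[!vapply(r, is.null, logical(1))])
  })
  cdm_schema(x$version_id, unlist(x$modules), vars, rules)
}

#' Load a CDM schema from a config file
#'
#' The schema format is a single structured document (JSON or YAML) with
#' top-level keys `version_id`, `modules`, `variables` and `logic_rules`.
#' Loading and [write_cdm_schema()] round-trip losslessly.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A [cdm_schema()].
#' @export
load_cdm_schema <- function(path) {
  if (!file.exists(path)) stop(sprintf("schema file not found: %s", path), call. = FALSE)
  x <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  }
  schema_from_list(x)
}

#' Write a CDM schema to a config file
#'
#' @param schema A [cdm_schema()].
#' @param path Output path; format chosen by extension (`.json` default,
#'   `.yaml`/`.yml` for YAML).
#' @return `path`, invisibly.
#' @export
write_cdm_schema <- function(schema, path) {
  x <- schema_to_list(schema)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(path)
}

validation_issue <- function(record_id, variable, issue_kind, detail) {
  data.frame(record_id = as.character(record_id),
             variable = as.character(variable),
             issue_kind = issue_kind, detail = detail,
             stringsAsFactors = FALSE)
}

no_issues <- function() {
  data.frame(record_id = character(), variable = character(),
             issue_kind = character(), detail = character(),
             stringsAsFactors = FALSE)
}

is_missing_value <- function(x) {
  is.null(x) || length(x) == 0L || is.na(x) || !nzchar(trimws(as.character(x)))
}

# Deterministic numeric grammar: optional sign, digits, optional single
# decimal fraction. Comma separators and scientific notation are parse issues.
parse_number <- function(x) {
  x <- trimws(as.character(x))
  if (!grepl("^[+-]?[0-9]+(\\.[0-9]+)?$", x)) return(NA_real_)
  as.numeric(x)
}

# ISO-8601 calendar dates only.
parse_iso_date <- function(x) {
  x <- trimws(as.character(x))
  if (!grepl("^[0-9]{4}-[0-9]{2}-[0-9]{2}$", x)) return(as.Date(NA))
  d <- as.Date(x, format = "%Y-%m-%d")
  if (is.na(d) || format(d, "%Y-%m-%d") != x) return(as.Date(NA))
  d
}

#' Validate a single raw value against the schema
#'
#' Deterministic and total: every raw text yields a defined issue list.
#' A missing value (`NA` or blank) is never an issue at this level.
#'
#' @param schema A [cdm_schema()].
#' @param variable Variable name (must exist in the schema).
#' @param raw Raw entered text.
#' @param record_id Optional record identifier carried into issues.
#' @return A data frame of validation issues (zero rows when valid) with
#'   columns `record_id`, `variable`, `issue_kind` (`"range"`, `"category"`,
#'   `"logic"` or `"parse"`) and `detail`.
#' @export
validate_value <- function(schema, variable, raw, record_id = NA_character_) {
  v <- schema_variable(schema, variable)
  if (is_missing_value(raw)) return(no_issues())
  raw <- trimws(as.character(raw))
  switch(v$kind,
    continuous = {
      num <- parse_number(raw)
      if (is.na(num))
        return(validation_issue(record_id, variable, "parse",
                                sprintf("'%s' is not a plain decimal number", raw)))
      if (!is.null(v$range) && (num < v$range[1] || num > v$range[2]))
        return(validation_issue(record_id, variable, "range",
                                sprintf("%s outside [%s, %s]", raw,
                                        v$range[1], v$range[2])))
      no_issues()
    },
    categorical = {
      if (!raw %in% v$categories)
        return(validation_issue(record_id, variable, "category",
                                sprintf("code '%s' not among {%s}", raw,
                                        paste(v$categories, collapse = ", "))))
      no_issues()
    },
    date = {
      if (is.na(parse_iso_date(raw)))
        return(validation_issue(record_id, variable, "parse",
                                sprintf("'%s' is not an ISO-8601 calendar date", raw)))
      no_issues()
    },
    text = no_issues()
  )
}

# Comparable scalar for logic evaluation: numeric for continuous, Date for
# date variables, trimmed string otherwise. NA when unparseable.
logic_operand <- function(schema, variable, raw) {
  v <- schema_variable(schema, variable)
  raw <- trimws(as.character(raw))
  switch(v$kind,
    continuous = parse_number(raw),
    date = parse_iso_date(raw),
    raw
  )
}

apply_op <- function(a, op, b) {
  switch(op,
    "<"  = a < b, "<=" = a <= b, "==" = a == b,
    "!=" = a != b, ">=" = a >= b, ">"  = a > b)
}

#' Run the schema's logic rules over a value mapping
#'
#' Each rule is evaluated against the supplied values; rules with any
#' missing or unparseable operand are skipped (reported, not violated).
#'
#' @param schema A [cdm_schema()].
#' @param values Named character vector or list mapping variable names to
#'   raw values. Every name must be a schema variable.
#' @param record_id Optional record identifier carried into issues.
#' @return A list with `violations` (validation-issue data frame, one
#'   `logic` row per violated rule, `detail` starting with the rule id) and
#'   `skipped` (character vector of rule ids with missing operands).
#' @export
check_logic <- function(schema, values, record_id = NA_character_) {
  values <- as.list(values)
  unknown <- setdiff(names(values), names(schema$variables))
  if (length(unknown))
    stop(sprintf("values reference unknown variable(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  violations <- no_issues()
  skipped <- character()
  for (rule in schema$logic_rules) {
    need <- rule_variables(rule)
    raws <- values[need]
    if (any(vapply(raws, is_missing_value, logical(1)))) {
      skipped <- c(skipped, rule$id)
      next
    }
    if (rule$kind == "compare") {
      a <- logic_operand(schema, rule$var_a, values[[rule$var_a]])
      b <- logic_operand(schema, rule$var_b, values[[rule$var_b]])
      if (is.na(a) || is.na(b)) { skipped <- c(skipped, rule$id); next }
      ok <- apply_op(a, rule$op, b)
      bad_var <- rule$var_a
    } else {
      cond <- trimws(as.character(values[[rule$if_var]])) == rule$if_value
      if (!cond) { next }
      b <- logic_operand(schema, rule$then_var, values[[rule$then_var]])
      cv <- schema_variable(schema, rule$then_var)
      const <- switch(cv$kind,
                      continuous = as.numeric(rule$then_value),
                      date = parse_iso_date(rule$then_value),
                      as.character(rule$then_value))
      if (is.na(b) || is.na(const)) { skipped <- c(skipped, rule$id); next }
      ok <- apply_op(b, rule$then_op, const)
      bad_var <- rule$then_var
    }
    if (!isTRUE(ok)) {
      msg <- if (nzchar(rule$message)) rule$message else "logic rule violated"
      violations <- rbind(violations,
                          validation_issue(record_id, bad_var, "logic",
                                           sprintf("%s: %s", rule$id, msg)))
    }
  }
  list(violations = violations, skipped = skipped)
}
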