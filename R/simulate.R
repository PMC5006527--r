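# Synthetic-record engine. Defaults describe a desk-scale analogue of a
# six-module lung-cancer abstraction study: 100 records, 217 variables,
# tiered per-entry transcription-error rates by difficulty.

default_modules <- c("pathology", "radio_chemo_therapy", "clinical_examination",
                     "surgery", "medical_image", "general_patient_information")

default_vars_per_module <- c(pathology = 38L, radio_chemo_therapy = 9L,
                             clinical_examination = 51L, surgery = 25L,
                             medical_image = 51L,
                             general_patient_information = 43L)

#' Transcription-error model
#'
#' Per-entry error probabilities tiered by abstraction difficulty, plus a
#' missingness probability and the spread of continuous errors. Readers
#' err independently given the true value; an erring categorical entry is
#' drawn uniformly from the other categories, an erring continuous entry
#' receives additive zero-centred noise rounded to the variable's
#' precision.
#'
#' @param e_easy,e_medium,e_difficult Per-entry error probabilities in
#'   \[0, 1). Defaults (0.01 / 0.03 / 0.08) are calibration defaults
#'   chosen so simulated overall reproducibility lands near the high-0.9
#'   range typical of audited double entry; they are configuration, not
#'   estimates of any real workforce.
#' @param continuous_noise_sd Standard deviation of the additive error for
#'   continuous variables, in units of the variable's own scale spread.
#' @param missing_prob Probability an entered value is omitted.
#' @return An object of class `error_model`.
#' @export
error_model <- function(e_easy = 0.01, e_medium = 0.03, e_difficult = 0.08,
                        continuous_noise_sd = 1, missing_prob = 0.02) {
  e <- c(easy = e_easy, medium = e_medium, difficult = e_difficult)
  if (any(e < 0 | e >= 1)) stop("error probabilities must lie in [0, 1)", call. = FALSE)
  if (missing_prob < 0 || missing_prob >= 1)
    stop("missing_prob must lie in [0, 1)", call. = FALSE)
  structure(list(e = e, continuous_noise_sd = continuous_noise_sd,
                 missing_prob = missing_prob),
            class = "error_model")
}

error_rate <- function(model, difficulty) unname(model$e[[difficulty]])

#' Simulate a CDM schema
#'
#' Generates a schema with the configured modules and per-module variable
#' counts. Variable kinds, category counts and distributions, difficulty
#' levels and error-prone flags are drawn from the configured proportions;
#' per-variable generative parameters (category probabilities, location and
#' scale of continuous variables) are attached as the `"sim_params"`
#' attribute for [simulate_truth()].
#'
#' @param vars_per_module Named integer vector: variables per module; all
#'   counts must be >= 1. Default: six modules totalling 217 variables.
#' @param kind_probs Probabilities of categorical / continuous / text /
#'   date kinds.
#' @param difficulty_probs Probabilities of easy / medium / difficult.
#' @param error_prone_prob Probability a variable is flagged error-prone.
#' @param seed Integer seed; the schema is deterministic under it.
#' @return A [cdm_schema()] with a `"sim_params"` attribute.
#' @export
simulate_schema <- function(vars_per_module = default_vars_per_module,
                            kind_probs = c(categorical = 0.55, continuous = 0.30,
                                           text = 0.10, date = 0.05),
                            difficulty_probs = c(easy = 0.6, medium = 0.3,
                                                 difficult = 0.1),
                            error_prone_prob = 0.2,
                            seed = 1L) {
  if (is.null(names(vars_per_module)))
    stop("vars_per_module must be named by module", call. = FALSE)
  if (any(vars_per_module < 1L))
    stop("every module must have at least one variable", call. = FALSE)
  if (abs(sum(kind_probs) - 1) > 1e-8 || abs(sum(difficulty_probs) - 1) > 1e-8)
    stop("kind and difficulty probabilities must each sum to 1", call. = FALSE)
  with_seed(seed, {
    vars <- list(); params <- list()
    for (m in names(vars_per_module)) {
      for (i in seq_len(vars_per_module[[m]])) {
        vn <- sprintf("%s_v%02d", m, i)
        kind <- sample(names(kind_probs), 1, prob = kind_probs)
        difficulty <- sample(names(difficulty_probs), 1, prob = difficulty_probs)
        ep <- stats::runif(1) < error_prone_prob
        if (kind == "categorical") {
          k <- sample(2:4, 1, prob = c(0.6, 0.25, 0.15))
          cats <- paste0("C", seq_len(k))
          # Dirichlet-ish probabilities kept away from degeneracy
          w <- stats::rgamma(k, shape = 2) + 0.2
          pi <- w / sum(w)
          vars[[vn]] <- cdm_variable(vn, m, "categorical", categories = cats,
                                     difficulty = difficulty, error_prone = ep)
          params[[vn]] <- list(kind = kind, pi = pi, categories = cats)
        } else if (kind == "continuous") {
          mu <- stats::runif(1, 10, 200); sdv <- stats::runif(1, 1, 20)
          vars[[vn]] <- cdm_variable(vn, m, "continuous", unit = "unit",
                                     range = c(mu - 10 * sdv, mu + 10 * sdv),
                                     difficulty = difficulty, error_prone = ep)
          params[[vn]] <- list(kind = kind, mean = mu, sd = sdv, digits = 1L)
        } else if (kind == "date") {
          vars[[vn]] <- cdm_variable(vn, m, "date", difficulty = difficulty,
                                     error_prone = ep)
          params[[vn]] <- list(kind = kind,
                               origin = as.Date("2015-01-01"), span = 330L)
        } else {
          vars[[vn]] <- cdm_variable(vn, m, "text", difficulty = difficulty,
                                     error_prone = ep)
          params[[vn]] <- list(kind = kind)
        }
      }
    }
    schema <- cdm_schema(version_id = "sim-cdm-0.1", modules = names(vars_per_module),
                         variables = vars)
    attr(schema, "sim_params") <- params
    schema
  })
}

random_name <- function(n) {
  syll <- c("an", "bo", "chen", "da", "el", "fa", "gu", "hai", "jin", "ko",
            "li", "mei", "na", "or", "pei", "qi", "ran", "su", "tao", "wei")
  vapply(seq_len(n), function(i) {
    s <- sample(syll, sample(2:3, 1), replace = TRUE)
    paste0(toupper(substring(s[1], 1, 1)), substring(s[1], 2),
           paste(s[-1], collapse = ""))
  }, character(1))
}

#' Simulate true records with synthetic identifiers
#'
#' @param schema A schema from [simulate_schema()] (needs the
#'   `"sim_params"` attribute).
#' @param n Number of records (>= 1).
#' @param seed Integer seed; deterministic under it.
#' @param national_id_prob Probability a record carries a national ID.
#' @return List of `n` raw records, each a list with `identifiers` (a
#'   [personal_identifiers()], unique record numbers) and `modules` (named
#'   list of named character vectors of true values).
#' @export
simulate_truth <- function(schema, n, seed = 1L, national_id_prob = 0.7) {
  params <- attr(schema, "sim_params")
  if (is.null(params)) stop("schema lacks sim_params; use simulate_schema()", call. = FALSE)
  stopifnot(n >= 1)
  with_seed(seed, {
    names_pool <- random_name(n)
    lapply(seq_len(n), function(i) {
      has_nid <- stats::runif(1) < national_id_prob
      ids <- personal_identifiers(
        name = sprintf("%s-%04d", names_pool[i], i),
        hospitalization_record_number = sprintf("HRN%06d", i),
        hospital_id = sprintf("H%02d", sample(1:12, 1)),
        national_id = if (has_nid) sprintf("NID%010d", sample.int(.Machine$integer.max, 1)) else NA_character_,
        other_identifiers = c(physician = sprintf("Dr %s", sample(names_pool, 1)))
      )
      modules <- lapply(schema$modules, function(m) {
        vs <- schema_variables(schema, m)
        vals <- vapply(vs, function(vn) {
          p <- params[[vn]]
          switch(p$kind,
            categorical = sample(p$categories, 1, prob = p$pi),
            continuous = sprintf(paste0("%.", p$digits, "f"),
                                 stats::rnorm(1, p$mean, p$sd)),
            date = format(p$origin + sample.int(p$span, 1), "%Y-%m-%d"),
            text = sprintf("note %d for %s", i, vn))
        }, character(1))
        names(vals) <- vs
        vals
      })
      names(modules) <- schema$modules
      list(identifiers = ids, modules = modules)
    })
  })
}

perturb_value <- function(value, vdef, param, model) {
  switch(vdef$kind,
    categorical = {
      others <- setdiff(vdef$categories, value)
      sample(others, 1)
    },
    continuous = {
      num <- parse_number(value)
      digits <- if (!is.null(param$digits)) param$digits else 1L
      noise <- 0
      while (round(noise, digits) == 0)
        noise <- stats::rnorm(1, 0, model$continuous_noise_sd)
      sprintf(paste0("%.", digits, "f"), num + round(noise, digits))
    },
    date = {
      d <- parse_iso_date(value)
      format(d + sample(c(-3:-1, 1:3), 1), "%Y-%m-%d")
    },
    { # text: drop one character, a digit-level transcription slip
      if (nchar(value) > 1) {
        pos <- sample.int(nchar(value), 1)
        paste0(substr(value, 1, pos - 1), substr(value, pos + 1, nchar(value)))
      } else paste0(value, "?")
    })
}

#' Simulate one reader's transcription of a record
#'
#' Per variable: with the difficulty-tier error probability the value is
#' perturbed (categorical: uniform draw over the other categories;
#' continuous: additive rounded noise; date: day shift; text: character
#' slip); independently, with the missingness probability the value is
#' omitted. Distinct `(seed, reader_id)` pairs give readers that are
#' independent given the truth.
#'
#' @param record A record from [simulate_truth()].
#' @param schema The generating schema.
#' @param model An [error_model()].
#' @param reader_id Reader identity (also seeds the reader's stream).
#' @param seed Base integer seed.
#' @return Named list of [entry_set()]s, one per module.
#' @export
simulate_entries <- function(record, schema, model, reader_id, seed = 1L) {
  params <- attr(schema, "sim_params")
  study_tag <- record$identifiers$hospitalization_record_number
  sub_seed <- derive_seed(seed, paste0(reader_id, "|", study_tag))
  with_seed(sub_seed, {
    out <- lapply(names(record$modules), function(m) {
      truth <- record$modules[[m]]
      vals <- character(0)
      for (vn in names(truth)) {
        vdef <- schema_variable(schema, vn)
        val <- truth[[vn]]
        if (stats::runif(1) < error_rate(model, vdef$difficulty))
          val <- perturb_value(val, vdef, params[[vn]], model)
        if (stats::runif(1) < model$missing_prob) val <- NA_character_
        vals[vn] <- val
      }
      entry_set(study_tag, m, reader_id, vals)
    })
    names(out) <- names(record$modules)
    out
  })
}

#' Analytic expected kappa under symmetric transcription error
#'
#' For a categorical variable with true category distribution `pi` and two
#' independent readers who each record the truth with probability `1 - e`
#' and otherwise a uniform draw over the other `k - 1` categories, the
#' misclassification kernel is q(c|t) = 1 - e if c = t, else e / (k - 1).
#' Observed agreement is p_o = sum_t pi_t sum_c q(c|t)^2, the common
#' marginal is m_c = sum_t pi_t q(c|t), chance agreement p_e = sum_c m_c^2,
#' and the expected kappa is (p_o - p_e) / (1 - p_e).
#'
#' @param pi Category probability vector (sums to 1).
#' @param e Per-entry error probability in \[0, 1).
#' @param k Number of categories (default `length(pi)`).
#' @return The expected kappa.
#' @export
expected_kappa <- function(pi, e, k = length(pi)) {
  stopifnot(length(pi) == k, k >= 2, e >= 0, e < 1)
  if (abs(sum(pi) - 1) > 1e-8) stop("pi must sum to 1", call. = FALSE)
  q <- matrix(e / (k - 1), k, k)
  diag(q) <- 1 - e
  p_o <- sum(pi * rowSums(q^2))          # q[t, c] = q(c|t); rows are truths
  m <- as.vector(pi %*% q)
  p_e <- sum(m^2)
  if (p_e >= 1) stop("degenerate: chance agreement is 1", call. = FALSE)
  (p_o - p_e) / (1 - p_e)
}

#' Analytic two-reader disagreement probability
#'
#' Complement of the expected observed agreement under the same error
#' kernel as [expected_kappa()].
#'
#' @inheritParams expected_kappa
#' @return Probability that two independent readers disagree.
#' @export
expected_disagreement <- function(pi, e, k = length(pi)) {
  q <- matrix(e / (k - 1), k, k)
  diag(q) <- 1 - e
  1 - sum(pi * rowSums(q^2))
}

# --- Table-2-style eligibility fixture ------------------------------------

# Per-module variable accounting engineered into the fixture:
# (selected, text_based, too_few, extreme, other_excluded)
table2_composition <- function() {
  data.frame(
    module = default_modules,
    selected = c(20L, 7L, 42L, 15L, 18L, 25L),
    text_based = c(12L, 1L, 4L, 2L, 14L, 4L),
    too_few = c(0L, 0L, 1L, 0L, 7L, 10L),
    extreme = c(4L, 0L, 3L, 6L, 8L, 2L),
    other = c(2L, 1L, 1L, 2L, 4L, 2L),
    # selected variables that are continuous (remainder categorical)
    sel_continuous = c(4L, 0L, 22L, 7L, 4L, 5L),
    stringsAsFactors = FALSE)
}

balanced_binary <- function(n, cats = c("Yes", "No")) {
  rep(cats, c(ceiling(n / 2), floor(n / 2)))
}

flip_some <- function(x, cats, n_flip) {
  if (n_flip == 0L) return(x)
  idx <- sample(seq_along(x), n_flip)
  x[idx] <- vapply(x[idx], function(v) sample(setdiff(cats, v), 1), character(1))
  x
}

#' Build the six-module eligibility fixture
#'
#' Constructs a 217-variable schema over the six standard modules together
#' with paired primary/repeated entry datasets for 100 records, engineered
#' so that the eligibility filter chain reproduces a fixed per-module
#' accounting: 127 selected variables and, per module, fixed counts of
#' text-based, too-few (< 50 complete pairs), extreme (> 95% single
#' category) and manually flagged exclusions. Counts are deterministic for
#' every seed: the seed only shuffles placements and transcription noise.
#'
#' @param seed Integer seed.
#' @param n Number of records (default 100).
#' @return List with `schema` (a [cdm_schema()]), `primary` and `repeated`
#'   (long data frames: `study_id`, `module`, `variable`, `value`) and
#'   `manual_flags` (character vector for `other_excluded`).
#' @export
build_table2_fixture <- function(seed = 1L, n = 100L) {
  comp <- table2_composition()
  em <- error_model()
  with_seed(seed, {
    vars <- list(); manual_flags <- character()
    prim_rows <- list(); rep_rows <- list()
    ids <- sprintf("S%04d", seq_len(n))
    difficulties <- c("easy", "medium", "difficult")
    add_rows <- function(store, vn, m, values) {
      store[[vn]] <- data.frame(study_id = ids, module = m, variable = vn,
                                value = values, stringsAsFactors = FALSE)
      store
    }
    for (r in seq_len(nrow(comp))) {
      m <- comp$module[r]
      vi <- 0L
      new_name <- function() { vi <<- vi + 1L; sprintf("%s_v%02d", m, vi) }

      n_cat <- comp$selected[r] - comp$sel_continuous[r]
      for (i in seq_len(n_cat)) {
        vn <- new_name()
        k <- if (i %% 3 == 0) 3L else 2L
        cats <- paste0("C", seq_len(k))
        diff <- difficulties[1L + (i %% 3L)]
        vars[[vn]] <- cdm_variable(vn, m, "categorical", categories = cats,
                                   difficulty = diff,
                                   error_prone = i %% 4 == 0)
        base <- sample(rep(cats, length.out = n))   # balanced truth
        prim <- flip_some(base, cats, round(n * error_rate(em, diff)))
        repe <- flip_some(base, cats, round(n * error_rate(em, diff)))
        prim_rows <- add_rows(prim_rows, vn, m, prim)
        rep_rows <- add_rows(rep_rows, vn, m, repe)
      }
      for (i in seq_len(comp$sel_continuous[r])) {
        vn <- new_name()
        diff <- difficulties[1L + (i %% 3L)]
        vars[[vn]] <- cdm_variable(vn, m, "continuous", unit = "unit",
                                   difficulty = diff, error_prone = i %% 4 == 0)
        mu <- stats::runif(1, 20, 180); sdv <- stats::runif(1, 2, 15)
        base <- stats::rnorm(n, mu, sdv)
        err <- function() {
          x <- base
          idx <- sample(n, round(n * error_rate(em, diff)))
          x[idx] <- x[idx] + stats::rnorm(length(idx), 0, sdv)
          sprintf("%.1f", x)
        }
        prim_rows <- add_rows(prim_rows, vn, m, err())
        rep_rows <- add_rows(rep_rows, vn, m, err())
      }
      for (i in seq_len(comp$text_based[r])) {
        vn <- new_name()
        vars[[vn]] <- cdm_variable(vn, m, "text", difficulty = "medium")
        txt <- sprintf("free-text note %s #%d", m, seq_len(n))
        prim_rows <- add_rows(prim_rows, vn, m, txt)
        rep_rows <- add_rows(rep_rows, vn, m, txt)
      }
      for (i in seq_len(comp$too_few[r])) {
        vn <- new_name()
        cats <- c("Yes", "No")
        vars[[vn]] <- cdm_variable(vn, m, "categorical", categories = cats,
                                   difficulty = "easy")
        base <- sample(balanced_binary(n, cats))
        repe <- base
        repe[sample(n, n - 30L)] <- NA_character_   # exactly 30 complete pairs
        prim_rows <- add_rows(prim_rows, vn, m, base)
        rep_rows <- add_rows(rep_rows, vn, m, repe)
      }
      for (i in seq_len(comp$extreme[r])) {
        vn <- new_name()
        cats <- c("Yes", "No")
        vars[[vn]] <- cdm_variable(vn, m, "categorical", categories = cats,
                                   difficulty = "easy")
        base <- sample(rep(cats, c(n - 2L, 2L)))    # pooled 98% one category
        prim_rows <- add_rows(prim_rows, vn, m, base)
        rep_rows <- add_rows(rep_rows, vn, m, base)
      }
      for (i in seq_len(comp$other[r])) {
        vn <- new_name()
        cats <- c("C1", "C2")
        vars[[vn]] <- cdm_variable(vn, m, "categorical", categories = cats,
                                   difficulty = "easy")
        base <- sample(balanced_binary(n, cats))
        prim_rows <- add_rows(prim_rows, vn, m, base)
        rep_rows <- add_rows(rep_rows, vn, m, base)
        manual_flags <- c(manual_flags, vn)
      }
    }
    schema <- cdm_schema("fixture-cdm-2.1", comp$module, vars)
    list(schema = schema,
         primary = do.call(rbind, unname(prim_rows)),
         repeated = do.call(rbind, unname(rep_rows)),
         manual_flags = manual_flags)
  })
}
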