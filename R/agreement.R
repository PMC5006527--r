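#' Paired primary/repeated values for one variable
#'
#' @param variable A [cdm_variable()] definition.
#' @param primary,repeated Character vectors of raw values, aligned by
#'   record; `NA` for missing. A pair is complete when both are present.
#' @return An object of class `paired_series`.
#' @export
paired_series <- function(variable, primary, repeated) {
  stopifnot(inherits(variable, "cdm_variable"))
  if (length(primary) != length(repeated))
    stop("primary and repeated must have equal length", call. = FALSE)
  primary <- as.character(primary); repeated <- as.character(repeated)
  primary[vapply(primary, is_missing_value, logical(1))] <- NA_character_
  repeated[vapply(repeated, is_missing_value, logical(1))] <- NA_character_
  structure(list(variable = variable, primary = primary, repeated = repeated),
            class = "paired_series")
}

complete_pairs <- function(series) {
  ok <- !is.na(series$primary) & !is.na(series$repeated)
  list(primary = series$primary[ok], repeated = series$repeated[ok], n = sum(ok))
}

#' Classify a variable's eligibility for the reproducibility analysis
#'
#' Exclusion rules, in precedence order: a manual flag (`other_excluded`),
#' text variables (`text_based`), categorical variables with fewer than 50
#' complete pairs (`too_few`), and categorical variables where any single
#' category's pooled relative frequency across both entries' non-missing
#' values strictly exceeds 95% (`extreme`). Everything else is `selected`.
#'
#' @param series A [paired_series()].
#' @param manual_flags Character vector of variable names manually excluded.
#' @param min_pairs Minimum complete pairs for categorical variables
#'   (default 50).
#' @param max_freq Pooled single-category frequency above which a
#'   categorical variable is excluded (default 0.95, strict inequality).
#' @return A list with `variable`, `status` and `reason`.
#' @export
classify_eligibility <- function(series, manual_flags = character(),
                                 min_pairs = 50L, max_freq = 0.95) {
  v <- series$variable
  if (v$name %in% manual_flags)
    return(list(variable = v$name, status = "other_excluded",
                reason = "manually flagged for exclusion"))
  if (v$kind == "text")
    return(list(variable = v$name, status = "text_based",
                reason = "text variables are excluded from agreement statistics"))
  cp <- complete_pairs(series)
  if (v$kind == "categorical") {
    if (cp$n < min_pairs)
      return(list(variable = v$name, status = "too_few",
                  reason = sprintf("%d complete pairs < %d", cp$n, min_pairs)))
    pooled <- c(series$primary, series$repeated)
    pooled <- pooled[!is.na(pooled)]
    freq <- max(table(pooled)) / length(pooled)
    if (freq > max_freq)
      return(list(variable = v$name, status = "extreme",
                  reason = sprintf("a category holds %.1f%% of pooled values (> %.0f%%)",
                                   100 * freq, 100 * max_freq)))
  }
  list(variable = v$name, status = "selected", reason = "")
}

#' Batch Cohen's kappa from contingency-table counts
#'
#' Workhorse behind [kappa_from_table()], vectorized over many k-by-k
#' tables at once: each row of `counts` holds one table's cells in
#' column-major order. Returns the observed agreement p_o (diagonal
#' proportion), the chance agreement p_e (sum of products of row and column
#' marginal proportions), the kappa estimate (p_o - p_e)/(1 - p_e) and its
#' large-sample standard error sqrt(p_o (1 - p_o) / (n (1 - p_e)^2)).
#' Degenerate tables (p_e = 1, a single observed category) yield `NA`.
#'
#' @param counts Numeric matrix, one row per table, `k * k` columns
#'   (column-major cell order).
#' @param k Number of categories.
#' @return Data frame with columns `n`, `p_o`, `p_e`, `estimate`, `se`.
#' @export
kappa_batch <- function(counts, k) {
  counts <- matrix(as.numeric(counts), ncol = k * k)
  n <- rowSums(counts)
  diag_idx <- (seq_len(k) - 1L) * k + seq_len(k)
  p_o <- rowSums(counts[, diag_idx, drop = FALSE]) / n
  p_e <- rep(0, nrow(counts))
  for (i in seq_len(k)) {
    row_i <- rowSums(counts[, (seq_len(k) - 1L) * k + i, drop = FALSE]) / n
    col_i <- rowSums(counts[, (i - 1L) * k + seq_len(k), drop = FALSE]) / n
    p_e <- p_e + row_i * col_i
  }
  degen <- n == 0 | p_e >= 1
  estimate <- ifelse(degen, NA_real_, (p_o - p_e) / (1 - p_e))
  se <- ifelse(degen, NA_real_, sqrt(p_o * (1 - p_o) / (n * (1 - p_e)^2)))
  data.frame(n = n, p_o = p_o, p_e = p_e, estimate = estimate, se = se)
}

#' Cohen's kappa with a 95% confidence interval from a contingency table
#'
#' @param tab Square contingency table (matrix) of primary-by-repeated
#'   counts.
#' @param conf_level Confidence level (default 0.95).
#' @return List with `estimate`, `se`, `ci_low`, `ci_high`, `p_o`, `p_e`,
#'   `n`. The interval is clipped to \[-1, 1\].
#' @export
kappa_from_table <- function(tab, conf_level = 0.95) {
  tab <- as.matrix(tab)
  if (nrow(tab) != ncol(tab)) stop("contingency table must be square", call. = FALSE)
  k <- nrow(tab)
  res <- kappa_batch(matrix(as.vector(tab), nrow = 1), k)
  if (res$n == 0) stop("no complete pairs", call. = FALSE)
  if (is.na(res$estimate))
    stop("degenerate table: a single observed category gives undefined agreement",
         call. = FALSE)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(estimate = res$estimate, se = res$se,
       ci_low = max(-1, res$estimate - z * res$se),
       ci_high = min(1, res$estimate + z * res$se),
       p_o = res$p_o, p_e = res$p_e, n = res$n)
}

agreement_result <- function(variable, statistic_kind, estimate, ci_low,
                             ci_high, n, note = "") {
  structure(
    list(variable = variable$name, module = variable$module,
         difficulty = variable$difficulty, statistic_kind = statistic_kind,
         estimate = estimate, ci_low = ci_low, ci_high = ci_high, n = n,
         note = note),
    class = "agreement_result")
}

#' Cohen's kappa for a paired categorical series
#'
#' Unweighted kappa over complete pairs, cross-classifying primary against
#' repeated values on the union of observed categories and the variable's
#' declared category set.
#'
#' @param series A [paired_series()] for a categorical variable.
#' @param conf_level Confidence level (default 0.95).
#' @return An `agreement_result` with `statistic_kind = "kappa"`.
#' @export
cohen_kappa <- function(series, conf_level = 0.95) {
  v <- series$variable
  if (v$kind != "categorical")
    stop("cohen_kappa applies to categorical variables", call. = FALSE)
  cp <- complete_pairs(series)
  if (cp$n == 0L) stop("no complete pairs", call. = FALSE)
  lev <- union(v$categories, union(cp$primary, cp$repeated))
  tab <- table(factor(trimws(cp$primary), levels = lev),
               factor(trimws(cp$repeated), levels = lev))
  observed <- rowSums(tab) + colSums(tab) > 0
  tab <- tab[observed, observed, drop = FALSE]
  res <- kappa_from_table(tab, conf_level)
  agreement_result(v, "kappa", res$estimate, res$ci_low, res$ci_high, res$n)
}

#' Pearson correlation with a Fisher-z confidence interval
#'
#' Correlation between primary and repeated values over complete pairs;
#' the interval is tanh(atanh(r) +/- z / sqrt(n - 3)). At r = +/-1 the
#' interval collapses to the point.
#'
#' @param series A [paired_series()] for a continuous variable.
#' @param conf_level Confidence level (default 0.95).
#' @return An `agreement_result` with `statistic_kind = "pearson_r"`.
#' @export
pearson_ci <- function(series, conf_level = 0.95) {
  v <- series$variable
  if (v$kind != "continuous")
    stop("pearson_ci applies to continuous variables", call. = FALSE)
  cp <- complete_pairs(series)
  x <- vapply(cp$primary, parse_number, numeric(1), USE.NAMES = FALSE)
  y <- vapply(cp$repeated, parse_number, numeric(1), USE.NAMES = FALSE)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("need at least 4 complete numeric pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in one entry: correlation undefined", call. = FALSE)
  r <- stats::cor(x, y)
  if (abs(r) >= 1 - 1e-15) {
    lo <- hi <- r <- sign(r)
  } else {
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    fz <- atanh(r)
    lo <- tanh(fz - z / sqrt(n - 3))
    hi <- tanh(fz + z / sqrt(n - 3))
  }
  agreement_result(v, "pearson_r", r, lo, hi, n)
}

#' Marginal-homogeneity test between the two entries
#'
#' Categorical variables: chi-square test of homogeneity on the 2-sample by
#' k-category marginal count table (categories with zero total dropped; no
#' continuity correction). Continuous variables: paired t-test on complete
#' pairs by default, or a two-sample t-test. An all-zero difference vector
#' gives p = 1 by convention; a constant non-zero difference gives p = 0.
#'
#' @param series A [paired_series()].
#' @param continuous_test `"paired"` (default) or `"two_sample"`.
#' @return List with `statistic`, `p_value`, `method`, `df`.
#' @export
marginal_homogeneity <- function(series, continuous_test = c("paired", "two_sample")) {
  continuous_test <- match.arg(continuous_test)
  v <- series$variable
  if (v$kind == "categorical") {
    p <- series$primary[!is.na(series$primary)]
    r <- series$repeated[!is.na(series$repeated)]
    lev <- union(v$categories, union(p, r))
    m <- rbind(primary = table(factor(p, levels = lev)),
               repeated = table(factor(r, levels = lev)))
    m <- m[, colSums(m) > 0, drop = FALSE]
    if (ncol(m) < 2L)
      stop("fewer than two surviving categories: homogeneity test degenerate",
           call. = FALSE)
    if (identical(unname(m[1, ]), unname(m[2, ]))) {
      # identical marginals: chi-square statistic is exactly zero
      return(list(statistic = 0, p_value = 1, method = "chi-square homogeneity",
                  df = ncol(m) - 1L))
    }
    ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         method = "chi-square homogeneity", df = unname(ht$parameter))
  } else if (v$kind == "continuous") {
    cp <- complete_pairs(series)
    x <- vapply(cp$primary, parse_number, numeric(1), USE.NAMES = FALSE)
    y <- vapply(cp$repeated, parse_number, numeric(1), USE.NAMES = FALSE)
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    if (continuous_test == "paired") {
      d <- x - y
      if (all(d == 0))
        return(list(statistic = 0, p_value = 1, method = "paired t-test",
                    df = length(d) - 1L))
      if (stats::sd(d) == 0)
        return(list(statistic = sign(mean(d)) * Inf, p_value = 0,
                    method = "paired t-test", df = length(d) - 1L))
      ht <- stats::t.test(x, y, paired = TRUE)
    } else {
      if (stats::sd(c(x, y)) == 0)
        return(list(statistic = 0, p_value = 1, method = "two-sample t-test",
                    df = length(x) + length(y) - 2L))
      ht <- stats::t.test(x, y, paired = FALSE)
    }
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         method = paste0(continuous_test, " t-test"), df = unname(ht$parameter))
  } else {
    stop("marginal homogeneity applies to categorical or continuous variables",
         call. = FALSE)
  }
}

#' Summarize agreement estimates within a module
#'
#' @param results List of `agreement_result`s (or a data frame with
#'   `module` and `estimate` columns) from a single module.
#' @return List with `module`, `count`, `min`, `max`, `median`, `mean`.
#' @export
summarize_module <- function(results) {
  if (is.data.frame(results)) {
    est <- results$estimate
    mod <- unique(results$module)
  } else {
    est <- vapply(results, `[[`, numeric(1), "estimate")
    mod <- unique(vapply(results, `[[`, character(1), "module"))
  }
  est <- est[!is.na(est)]
  if (length(est) == 0L) stop("no estimates to summarize", call. = FALSE)
  if (length(mod) > 1L) stop("results span more than one module", call. = FALSE)
  list(module = mod, count = length(est), min = min(est), max = max(est),
       median = stats::median(est), mean = mean(est))
}

build_series_map <- function(primary, repeated, schema) {
  need <- c("study_id", "variable", "value")
  for (df in list(primary, repeated))
    if (!all(need %in% names(df)))
      stop("datasets need columns study_id, variable, value", call. = FALSE)
  ids <- intersect(unique(primary$study_id), unique(repeated$study_id))
  if (length(ids) == 0L)
    stop("primary and repeated datasets share no study_ids", call. = FALSE)
  vars <- names(schema$variables)
  wide <- function(df) {
    m <- matrix(NA_character_, nrow = length(ids), ncol = length(vars),
                dimnames = list(ids, vars))
    df <- df[df$study_id %in% ids & df$variable %in% vars, , drop = FALSE]
    m[cbind(match(df$study_id, ids), match(df$variable, vars))] <-
      as.character(df$value)
    m
  }
  list(ids = ids, primary = wide(primary), repeated = wide(repeated))
}

#' Build the full reproducibility report
#'
#' Pairs the primary and repeated datasets by study ID, classifies every
#' schema variable's eligibility, computes Cohen's kappa (categorical) or
#' the Pearson correlation (continuous) with 95% confidence intervals for
#' each selected variable, summarizes estimates per module, and optionally
#' runs marginal-homogeneity tests on a configured variable subset.
#'
#' @param primary,repeated Long data frames with columns `study_id`,
#'   `variable`, `value` (`NA` or absent row = missing).
#' @param schema A [cdm_schema()].
#' @param manual_flags Character vector of variables manually excluded.
#' @param homogeneity_vars Optional character vector of variables for the
#'   marginal-homogeneity table.
#' @param conf_level Confidence level for intervals (default 0.95).
#' @return An object of class `repro_report` with components `eligibility`,
#'   `results`, `summaries`, `homogeneity` (data frames) and `schema`.
#' @export
repro_report <- function(primary, repeated, schema, manual_flags = character(),
                         homogeneity_vars = NULL, conf_level = 0.95) {
  sm <- build_series_map(primary, repeated, schema)
  elig_rows <- list(); res_rows <- list(); hom_rows <- list()
  for (vn in names(schema$variables)) {
    v <- schema$variables[[vn]]
    series <- paired_series(v, sm$primary[, vn], sm$repeated[, vn])
    el <- classify_eligibility(series, manual_flags)
    elig_rows[[vn]] <- data.frame(
      module = v$module, variable = vn, kind = v$kind,
      difficulty = v$difficulty, n_complete = complete_pairs(series)$n,
      status = el$status, reason = el$reason, stringsAsFactors = FALSE)
    if (el$status == "selected") {
      ar <- tryCatch(
        if (v$kind == "categorical") cohen_kappa(series, conf_level)
        else pearson_ci(series, conf_level),
        error = function(e) agreement_result(v,
          if (v$kind == "categorical") "kappa" else "pearson_r",
          NA_real_, NA_real_, NA_real_, complete_pairs(series)$n,
          note = conditionMessage(e)))
      res_rows[[vn]] <- data.frame(
        module = v$module, variable = vn, kind = v$kind,
        difficulty = v$difficulty, n = ar$n,
        statistic = ar$statistic_kind, estimate = ar$estimate,
        ci_low = ar$ci_low, ci_high = ar$ci_high, note = ar$note,
        stringsAsFactors = FALSE)
    }
    if (!is.null(homogeneity_vars) && vn %in% homogeneity_vars) {
      mh <- tryCatch(marginal_homogeneity(series), error = function(e) NULL)
      if (!is.null(mh))
        hom_rows[[vn]] <- data.frame(
          module = v$module, variable = vn, method = mh$method,
          statistic = mh$statistic, p_value = mh$p_value,
          stringsAsFactors = FALSE)
    }
  }
  eligibility <- do.call(rbind, unname(elig_rows))
  results <- if (length(res_rows)) do.call(rbind, unname(res_rows)) else NULL
  summaries <- NULL
  if (!is.null(results)) {
    by_mod <- split(results, factor(results$module, levels = schema$modules))
    rows <- lapply(by_mod[vapply(by_mod, function(d) any(!is.na(d$estimate)),
                                 logical(1))], function(d) {
      s <- summarize_module(d)
      data.frame(module = s$module, count = s$count, min = s$min, max = s$max,
                 median = s$median, mean = s$mean, stringsAsFactors = FALSE)
    })
    summaries <- do.call(rbind, unname(rows))
  }
  homogeneity <- if (length(hom_rows)) do.call(rbind, unname(hom_rows)) else NULL
  structure(
    list(eligibility = eligibility, results = results, summaries = summaries,
         homogeneity = homogeneity, n_records = length(sm$ids),
         version_id = schema$version_id, modules = schema$modules),
    class = "repro_report")
}

#' @export
print.repro_report <- function(x, ...) {
  cat(sprintf("reproducibility report: %d records, %d variables (%d selected)\n",
              x$n_records, nrow(x$eligibility),
              sum(x$eligibility$status == "selected")))
  tab <- table(x$eligibility$status)
  cat("  eligibility:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  if (!is.null(x$summaries)) {
    cat("  per-module agreement (min / median / mean / max):\n")
    for (i in seq_len(nrow(x$summaries))) {
      s <- x$summaries[i, ]
      cat(sprintf("    %-30s n=%2d  %.3f / %.3f / %.3f / %.3f\n",
                  s$module, s$count, s$min, s$median, s$mean, s$max))
    }
  }
  invisible(x)
}

#' @export
summary.repro_report <- function(object, ...) {
  el <- table(factor(object$eligibility$status,
                     levels = c("selected", "text_based", "too_few",
                                "extreme", "other_excluded")),
              factor(object$eligibility$module, levels = object$modules))
  out <- list(eligibility_by_module = el, summaries = object$summaries,
              overall_mean = if (!is.null(object$results))
                mean(object$results$estimate, na.rm = TRUE) else NA_real_)
  class(out) <- "summary.repro_report"
  out
}

#' @export
print.summary.repro_report <- function(x, ...) {
  cat("eligibility by module:\n")
  print(x$eligibility_by_module)
  if (!is.null(x$summaries)) { cat("\nper-module agreement:\n"); print(x$summaries) }
  cat(sprintf("\noverall mean agreement across selected variables: %.4f\n",
              x$overall_mean))
  invisible(x)
}

#' Dot-and-interval plot of per-variable agreement
#'
#' One panel per module: point estimates with their confidence intervals,
#' colour-coded by abstraction difficulty (easy black, medium green,
#' difficult red).
#'
#' @param x A `repro_report`.
#' @param modules Modules to draw (default: all with results).
#' @param ... Unused.
#' @return `x`, invisibly.
#' @export
plot.repro_report <- function(x, modules = NULL, ...) {
  if (is.null(x$results)) stop("report holds no agreement results", call. = FALSE)
  res <- x$results[!is.na(x$results$estimate), , drop = FALSE]
  if (is.null(modules)) modules <- intersect(x$modules, unique(res$module))
  cols <- c(easy = "black", medium = "forestgreen", difficult = "red")
  old <- graphics::par(mfrow = c(length(modules), 1),
                       mar = c(2.5, 10, 1.5, 1))
  on.exit(graphics::par(old))
  for (m in modules) {
    d <- res[res$module == m, , drop = FALSE]
    d <- d[order(d$estimate), , drop = FALSE]
    y <- seq_len(nrow(d))
    graphics::plot(d$estimate, y, xlim = c(min(0, d$ci_low, na.rm = TRUE), 1),
                   pch = 15, col = "steelblue", yaxt = "n", xlab = "",
                   ylab = "", main = m, cex.main = 0.9)
    graphics::segments(d$ci_low, y, d$ci_high, y, col = "steelblue")
    graphics::axis(2, at = y, labels = d$variable, las = 2, cex.axis = 0.6,
                   col.axis = "black")
    graphics::mtext(d$variable, side = 2, at = y, las = 2, cex = 0.45,
                    col = cols[d$difficulty], line = 0.8)
    s <- summarize_module(d)
    graphics::legend("bottomleft", bty = "n", cex = 0.7,
                     legend = sprintf("range %.2f-%.2f, median %.2f, mean %.2f",
                                      s$min, s$max, s$median, s$mean))
  }
  invisible(x)
}
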