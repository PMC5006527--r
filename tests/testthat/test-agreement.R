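test_that("eligibility classification applies the filter chain with precedence", {
  # text variables are excluded as text_based
  s <- make_series("text", rep("note", 100), rep("note", 100))
  expect_equal(classify_eligibility(s)$status, "text_based")
  # categorical with 49 complete pairs is too_few
  prim <- rep(c("Yes", "No"), length.out = 100)
  repe <- prim; repe[50:100] <- NA
  s <- make_series("categorical", prim, repe, categories = c("Yes", "No"))
  expect_equal(sum(!is.na(prim) & !is.na(repe)), 49L)
  expect_equal(classify_eligibility(s)$status, "too_few")
  # 96% single category over 100 pairs is extreme
  prim <- rep(c("Yes", "No"), c(96, 4)); repe <- prim
  s <- make_series("categorical", prim, repe, categories = c("Yes", "No"))
  expect_equal(classify_eligibility(s)$status, "extreme")
  # exactly 95% is not extreme (strict inequality)
  prim <- rep(c("Yes", "No"), c(95, 5)); repe <- prim
  s <- make_series("categorical", prim, repe, categories = c("Yes", "No"))
  expect_equal(classify_eligibility(s)$status, "selected")
  # manual flag takes precedence over everything
  s <- make_series("text", rep("x", 10), rep("x", 10), name = "flagged")
  expect_equal(classify_eligibility(s, manual_flags = "flagged")$status,
               "other_excluded")
  # balanced categorical with full pairs is selected
  prim <- rep(c("Yes", "No"), 50)
  s <- make_series("categorical", prim, prim, categories = c("Yes", "No"))
  expect_equal(classify_eligibility(s)$status, "selected")
})

test_that("kappa matches hand-computed tables and clips its interval", {
  # perfect agreement: kappa 1, CI collapses at 1
  prim <- rep(c("A", "B"), 50)
  s <- make_series("categorical", prim, prim, categories = c("A", "B"))
  res <- cohen_kappa(s)
  expect_equal(res$estimate, 1)
  expect_equal(res$ci_low, 1)
  expect_equal(res$ci_high, 1)
  # 2x2 table [[45,5],[5,45]]: p_o = .9, p_e = .5, kappa = .8
  tab <- matrix(c(45, 5, 5, 45), 2, 2)
  res <- kappa_from_table(tab)
  expect_equal(res$estimate, 0.8)
  expect_equal(res$p_o, 0.9)
  expect_equal(res$p_e, 0.5)
  expect_equal(res$se, sqrt(0.9 * 0.1 / (100 * 0.25)))
  expect_equal(res$ci_low, 0.8 - qnorm(0.975) * res$se)
  # degenerate single-category table errors
  expect_error(kappa_from_table(matrix(c(10, 0, 0, 0), 2, 2)), "degenerate")
  expect_error(cohen_kappa(make_series("categorical", rep(NA, 5), rep(NA, 5),
                                       categories = c("A", "B"))),
               "no complete pairs")
})

test_that("kappa of independently permuted labels is near zero in expectation", {
  prim <- rep(c("A", "B"), 50)
  est <- vapply(1:500, function(s) {
    set.seed(s)
    repe <- sample(prim)
    k <- tryCatch(
      cohen_kappa(make_series("categorical", prim, repe,
                              categories = c("A", "B")))$estimate,
      error = function(e) NA_real_)
    k
  }, numeric(1))
  expect_lt(abs(mean(est, na.rm = TRUE)), 0.02)
})

test_that("kappa is invariant to simultaneous relabeling of categories", {
  set.seed(7)
  prim <- sample(c("A", "B", "C"), 200, replace = TRUE)
  repe <- ifelse(runif(200) < 0.15,
                 sample(c("A", "B", "C"), 200, replace = TRUE), prim)
  k1 <- cohen_kappa(make_series("categorical", prim, repe,
                                categories = c("A", "B", "C")))$estimate
  relab <- c(A = "Z", B = "Y", C = "X")
  k2 <- cohen_kappa(make_series("categorical", unname(relab[prim]),
                                unname(relab[repe]),
                                categories = c("X", "Y", "Z")))$estimate
  expect_equal(k1, k2)
})

test_that("formula kappa equals the brute-force cell-proportion oracle on small tables", {
  # exhaustive over all 2x2 tables with n <= 12 here; the full n <= 20
  # sweep (incl. 3x3) runs in the acceptance suite
  tabs <- enumerate_tables(2, 12)
  keep <- rowSums(tabs) > 0
  tabs <- tabs[keep, , drop = FALSE]
  got <- kappa_batch(tabs, 2)$estimate
  want <- apply(tabs, 1, function(cells) {
    tab <- matrix(cells, 2, 2)
    if (sum(diag(tab)) == sum(tab) &&
        (all(tab[1, ] + tab[, 1] == 0) || all(tab[2, ] + tab[, 2] == 0)))
      return(NA_real_)  # single observed category
    k <- oracle_kappa(tab)
    if (!is.finite(k)) NA_real_ else k
  })
  expect_equal(got, unname(want), tolerance = 1e-12)
})

test_that("pearson estimates and Fisher-z intervals are exact on closed forms", {
  v <- seq(1, 100)
  # identical entries: r = 1, point interval
  s <- make_series("continuous", as.character(v), as.character(v))
  res <- pearson_ci(s)
  expect_equal(res$estimate, 1)
  expect_equal(res$ci_low, 1)
  # negated entries: r = -1
  s <- make_series("continuous", as.character(v), as.character(rev(v)))
  expect_equal(pearson_ci(s)$estimate, -1)
  # Fisher transform at r = 0.5, n = 100
  set.seed(5)
  x <- rnorm(100)
  y <- 0.5 * scale(x)[, 1] + sqrt(1 - 0.25) * scale(rnorm(100))[, 1]
  s <- make_series("continuous", sprintf("%.6f", x), sprintf("%.6f", y))
  res <- pearson_ci(s)
  r <- res$estimate
  expect_equal(res$ci_low, tanh(atanh(r) - qnorm(0.975) / sqrt(97)), tolerance = 1e-10)
  expect_equal(res$ci_high, tanh(atanh(r) + qnorm(0.975) / sqrt(97)), tolerance = 1e-10)
  # zero variance errors
  expect_error(pearson_ci(make_series("continuous", rep("3.0", 10),
                                      as.character(1:10))), "variance")
  # under 4 pairs errors
  expect_error(pearson_ci(make_series("continuous", c("1", "2", "3"),
                                      c("1", "2", "3"))), "at least 4")
})

test_that("Fisher-z interval is consistent with a bootstrap oracle", {
  set.seed(31)
  n <- 100
  x <- rnorm(n)
  y <- 0.5 * x + rnorm(n, sd = sqrt(0.75))
  s <- make_series("continuous", sprintf("%.6f", x), sprintf("%.6f", y))
  res <- pearson_ci(s)
  boot <- vapply(1:2000, function(i) {
    idx <- sample.int(n, replace = TRUE)
    suppressWarnings(cor(x[idx], y[idx]))
  }, numeric(1))
  bq <- quantile(boot, c(0.025, 0.975), na.rm = TRUE)
  # analytic and bootstrap intervals agree to a few hundredths
  expect_lt(abs(res$ci_low - bq[[1]]), 0.06)
  expect_lt(abs(res$ci_high - bq[[2]]), 0.06)
})

test_that("marginal homogeneity reproduces the printed gender worked example", {
  # marginals (54,46) vs (54,46): chi-square 0, p exactly 1
  prim <- rep(c("Male", "Female"), c(54, 46))
  repe <- rep(c("Male", "Female"), c(54, 46))
  s <- make_series("categorical", prim, repe, categories = c("Male", "Female"))
  res <- marginal_homogeneity(s)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  # maximal heterogeneity drives p toward zero
  s <- make_series("categorical", rep("Male", 100), rep("Female", 100),
                   categories = c("Male", "Female"))
  expect_lt(marginal_homogeneity(s)$p_value, 1e-10)
  # identical continuous vectors: zero-variance convention p = 1
  s <- make_series("continuous", as.character(1:50), as.character(1:50))
  expect_equal(marginal_homogeneity(s)$p_value, 1)
  # single surviving category degenerates
  s <- make_series("categorical", rep("Male", 10), rep("Male", 10),
                   categories = c("Male", "Female"))
  expect_error(marginal_homogeneity(s), "degenerate")
})

test_that("module summaries agree with independent order statistics", {
  mk <- function(est) data.frame(module = "m", estimate = est,
                                 stringsAsFactors = FALSE)
  s <- summarize_module(mk(c(0.9, 0.95, 1.0)))
  expect_equal(s$min, 0.9); expect_equal(s$max, 1.0)
  expect_equal(s$median, 0.95)
  expect_equal(s$mean, mean(c(0.9, 0.95, 1.0)))
  s <- summarize_module(mk(0.85))
  expect_true(all(unlist(s[c("min", "max", "median", "mean")]) == 0.85))
  s <- summarize_module(mk(c(1, 1, 0.8, 0.6)))
  expect_equal(s$median, 0.9)
  expect_equal(s$mean, 0.85)
  # random cross-check against sort/quantile
  set.seed(13)
  for (i in 1:20) {
    est <- runif(sample(2:30, 1))
    s <- summarize_module(mk(est))
    expect_equal(s$min, min(est)); expect_equal(s$max, max(est))
    expect_equal(s$median, median(est)); expect_equal(s$mean, mean(est))
  }
  expect_error(summarize_module(data.frame(module = character(0),
                                           estimate = numeric(0))),
               "no estimates")
  expect_error(summarize_module(data.frame(module = c("a", "b"),
                                           estimate = c(0.5, 0.6))),
               "more than one module")
})

test_that("a report on a perfect duplicate dataset scores 1 everywhere", {
  fx <- build_table2_fixture(seed = 2)
  rep <- repro_report(fx$primary, fx$primary, fx$schema,
                      manual_flags = fx$manual_flags)
  sel <- rep$results[!is.na(rep$results$estimate), ]
  expect_true(all(sel$estimate == 1))
  expect_equal(nrow(rep$results), sum(rep$eligibility$status == "selected"))
})

test_that("the report pairs by study_id and fails on disjoint id sets", {
  fx <- build_table2_fixture(seed = 2)
  other <- fx$repeated
  other$study_id <- paste0("X", other$study_id)
  expect_error(repro_report(fx$primary, other, fx$schema), "share no study_ids")
})

test_that("marginal homogeneity table appears for configured variables", {
  fx <- build_table2_fixture(seed = 2)
  vars <- head(fx$schema$modules, 0)  # none
  rep <- repro_report(fx$primary, fx$repeated, fx$schema,
                      manual_flags = fx$manual_flags,
                      homogeneity_vars = c("pathology_v01", "pathology_v05"))
  expect_equal(sort(rep$homogeneity$variable),
               c("pathology_v01", "pathology_v05"))
  expect_true(all(rep$homogeneity$p_value >= 0 & rep$homogeneity$p_value <= 1))
})

test_that("report CSVs carry the documented columns", {
  fx <- build_table2_fixture(seed = 2)
  rep <- repro_report(fx$primary, fx$repeated, fx$schema,
                      manual_flags = fx$manual_flags)
  path <- withr::local_tempfile(fileext = ".csv")
  spath <- withr::local_tempfile(fileext = ".csv")
  write_report_csv(rep, path, spath)
  out <- read.csv(path)
  expect_equal(names(out), c("module", "variable", "kind", "difficulty", "n",
                             "statistic", "estimate", "ci_low", "ci_high",
                             "eligibility"))
  expect_equal(nrow(out), 217L)
  smry <- read.csv(spath)
  expect_equal(names(smry), c("module", "count", "min", "max", "median", "mean"))
  expect_equal(nrow(smry), 6L)
})
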