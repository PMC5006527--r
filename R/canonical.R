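# Canonical value comparison shared by conflict detection, re-entry
# checking and sampling QC.
#
# Canonical forms by kind:
#   continuous  -> parsed number, compared within tolerance tau (default 0)
#   categorical -> trimmed code, exact match
#   text        -> NFC-normalized, trimmed, internal whitespace collapsed
#   date        -> parsed ISO calendar date
# Unparseable values fall back to trimmed-string comparison.
# Missing-vs-missing agrees; missing-vs-present never does.

canonical_text <- function(x) {
  x <- stringi::stri_trans_nfc(as.character(x))
  x <- trimws(x)
  gsub("[[:space:]]+", " ", x)
}

#' Compare two raw values under a variable's canonical form
#'
#' @param a,b Raw values (character, possibly `NA` for missing).
#' @param kind Value kind: `"categorical"`, `"continuous"`, `"text"` or
#'   `"date"`.
#' @param tau Non-negative tolerance for continuous comparison; the default
#'   0 treats any numeric difference as a disagreement (transcription of the
#'   same printed number should parse identically).
#' @return `TRUE` if the values agree canonically.
#' @export
values_equal <- function(a, b, kind = "text", tau = 0) {
  ma <- is_missing_value(a); mb <- is_missing_value(b)
  if (ma && mb) return(TRUE)
  if (ma || mb) return(FALSE)
  a <- as.character(a); b <- as.character(b)
  switch(kind,
    continuous = {
      na <- parse_number(a); nb <- parse_number(b)
      if (!is.na(na) && !is.na(nb)) abs(na - nb) <= tau
      else trimws(a) == trimws(b)
    },
    categorical = trimws(a) == trimws(b),
    date = {
      da <- parse_iso_date(a); db <- parse_iso_date(b)
      if (!is.na(da) && !is.na(db)) da == db
      else trimws(a) == trimws(b)
    },
    canonical_text(a) == canonical_text(b)
  )
}

# Run a block with a local RNG state derived from `seed`, restoring the
# caller's state afterwards. All package randomness flows through this.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Deterministic integer sub-seed derived from a base seed and a label.
# Polynomial rolling hash plus a multiplicative scramble: labels differing
# in one character (e.g. two reader IDs) land on unrelated seeds, keeping
# the derived RNG streams independent.
derive_seed <- function(seed, label) {
  h <- 0
  for (ch in utf8ToInt(paste0(label, collapse = ""))) {
    h <- (h * 131 + ch) %% 2147483647
  }
  h <- (h + as.numeric(seed) * 1103515245) %% 2147483647
  as.integer((h * 48271) %% 2147483647)
}
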