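---
title: "Double reading/entry, adjudication and reproducibility analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Double reading/entry, adjudication and reproducibility analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dressr)
```

## The problem

Most clinical information sits in unstructured medical records. Turning it
into computable, patient-centred data elements at scale is usually done by
trained staff who read a record and transcribe structured variables into a
database — a process that itself introduces transcription error. The
standard defence is *double data entry*: two readers independently
transcribe the same source, a comparison function detects every field-level
disagreement, and a third party adjudicates. `dressr` implements this whole
pipeline at desk scale: a common data model (CDM) with validation rules,
de-identification with a physically separated linkage file, the two-reader
entry and adjudication engine, sampling-based quality control, and a
reproducibility analyzer quantifying how well two independent passes agree.

Everything is exercisable on synthetic records; no real medical data is
required (or included).

## The common data model

A `cdm_schema()` declares modules (the six defaults mirror how a surgical
oncology record splits: pathology, radio/chemo therapy, clinical
examination, surgery, medical image, general patient information) and typed
variables: `categorical` (a closed code list, at least two codes),
`continuous` (unit, optional `[low, high]` range), `text`, and ISO-8601
`date`. Each variable carries an abstraction *difficulty* (`easy`: the
value sits at one known position in the record; `medium`: several positions
must be scanned; `difficult`: several sources must be synthesised) and an
`error_prone` flag marking it for sampling re-entry QC.

Validation is deliberately strict and deterministic, because canonical
forms feed conflict detection downstream:

* numbers must match `^[+-]?\d+(\.\d+)?$` — comma separators and scientific
  notation are parse issues, so "54" and "54.0" are equal but "5,4" never
  silently becomes anything;
* dates are ISO-8601 calendar dates only;
* logic rules are restricted to binary comparisons between two variables
  and single implications ("if A has code c then B satisfies P"). A rule
  with any missing or unparseable operand is *skipped* and reported as
  skipped, never counted as violated — an absent admission date is a
  missingness problem, not evidence of a date inversion.

## De-identification and the linkage contract

`assign_internal_id()` derives the study ID as a keyed one-way digest
(HMAC-SHA256): of the normalized national ID when one exists, otherwise of
the normalized composite *name | hospitalization record number | hospital
ID*. The two branches are domain-separated, so the same person yields a
different (but individually stable) ID per branch. Normalization is NFC,
trim, casefold — a choice this package makes explicitly, since character
encoding and whitespace handling must be fixed for the digest to be
reproducible. Without the salt, the mapping is not recomputable; with a
different salt, relinking fails closed (the ID is simply absent from the
store).

Scrubbing replaces every occurrence of a *known* identifier string
(case-insensitive) with a fixed redaction token. This is a deliberate
limitation: free-text identifying content beyond the declared identifier
fields is not detected, because general named-entity recognition is out of
scope. "Physical separation" of the linkage file is modelled as a
path-disjointness contract: `write_linkage()` refuses a target inside the
de-identified output tree.

## The entry engine and its state machine

Per record-module, two tasks (slots A and B) are created; readers bind at
submission and must be distinct. When the second entry arrives, comparison
fires automatically. A variable conflicts when its canonicalized values
differ: continuous values compare as parsed numbers within a tolerance
`tau` (default 0 — two transcriptions of the same printed number should
parse identically; the tolerance exists for variables where re-measurement
noise is expected), categorical codes compare trimmed and exact, text
compares NFC-normalized with collapsed whitespace, dates compare as parsed
dates. Missing-vs-present conflicts; missing-vs-missing agrees.

Each conflict walks a fixed lifecycle:

```
open --adjudicate--> reentry_pending --process_reentries--> final
                                     \-> escalated_pending --senior--> final_escalated
                                     \-> open (another adjudication round)
```

The adjudicator — necessarily distinct from both readers — records a
post-QC value that is *not disclosed*: two blind re-entry tasks go back to
the readers. If both re-entries match the adjudicated value, the conflict
finalizes there. If the re-entries agree with *each other* against the
adjudicator, the package auto-escalates: the readers have, in effect,
questioned the adjudicator, and making that transition automatic keeps the
engine deterministic (no modelling of an explicit human escalation action).
If the re-entries disagree, another adjudication round begins, up to
`max_rounds` (default 2 — one re-entry loop and one retry) after which the
conflict force-escalates, guaranteeing termination. A senior decision
(again a fresh actor) is final. Re-entry always occurs after adjudication,
even when the adjudicated value equals one reader's original entry: the
blind re-entry is the check *on the adjudicator*, and skipping it would
remove that check exactly when the adjudicator sided with one reader.

`commit_record()` refuses while any conflict is unresolved, naming the
blocking variables; committed values carry provenance `agreed`,
`adjudicated` or `escalated`, and the audit trail (append-only, replayable
to the final state) records every action.

Text variables participate fully in conflict detection even though the
agreement statistics exclude them: entry QC and reproducibility analysis
have different scopes.

## Sampling QC and trend monitoring

`weekly_sample_size()` implements the acceptance-sampling schedule: one
record in each of the first three weeks of a month, and ceiling(sqrt(n+1))
in the fourth week, with n the month-to-date submitted count. Ceiling is
the conservative rounding (never fewer than the rule's real value); the
draw is additionally capped at n itself, since one cannot sample records
that do not exist — in particular the fourth-week draw from an empty month
is 0, not 1. Re-entry on a sampled record checks *only* the error-prone
variables; a discrepancy elsewhere is outside the protocol's scope by
design (the protocol exists because low-cardinality categorical variables
can be consistently wrong by chance; its cost is bounded by restricting to
flagged variables).

`quality_trend()` concretizes "watch for unexpected temporal trends" as two
standard control-chart rules: flag a period whose issue rate exceeds the
mean + 3 SD of all preceding periods (once at least `min_baseline = 4`
prior periods exist — below that the period is reported as "insufficient
baseline"), and flag any strict rise across three consecutive periods. The
3-sigma Shewhart limit and the run rule are the textbook choices; nothing
in the workflow depends on the specific rules beyond their determinism.

## Agreement statistics

For a categorical variable, `cohen_kappa()` builds the k-by-k
cross-classification over complete pairs and computes unweighted kappa
(p_o − p_e)/(1 − p_e), with p_o the diagonal proportion and p_e the sum of
products of marginal proportions. No ordinal weighting is applied — one
agreement figure per variable, regardless of category count. The standard
error is the classical large-sample form

  SE = sqrt( p_o (1 − p_o) / ( n (1 − p_e)^2 ) ),

and the 95% interval `estimate ± 1.96 SE` is clipped to [−1, 1]. The exact
delta-method variance (Fleiss–Cohen–Everitt) is a documented alternative;
the simple form is closed-form, testable, and its empirical coverage at the
package's own calibration point (binary, balanced, 10% per-entry error,
n = 100) is verified by simulation in the test suite to sit at the nominal
95% within ±2.5 points. A table with a single observed category (p_e = 1)
has undefined agreement and errors rather than returning a value.

For a continuous variable, `pearson_ci()` computes r over complete pairs
with the Fisher-z interval tanh(atanh(r) ± 1.96/sqrt(n−3)), collapsing to a
point at r = ±1; it requires n ≥ 4 and positive variance in both entries.

`marginal_homogeneity()` compares the two entries' *marginal*
distributions: a chi-square test of homogeneity on the 2-by-k marginal
count table for categorical variables (zero-total categories dropped, no
continuity correction — identical marginals give statistic exactly 0 and
p = 1), and a t-test for continuous variables. The default t-test is
paired, because both entries describe the same patients; a two-sample
variant is selectable since published tables do not always make the
pairing recoverable. An all-zero difference vector yields p = 1 by
convention; a constant non-zero difference yields p = 0.

### Eligibility filters

`classify_eligibility()` applies, in precedence order: manual exclusion
flag → text variable → categorical with fewer than 50 complete pairs →
categorical where any single category holds more than 95% (strict) of the
pooled non-missing values from both entries. The 50-pair floor is tied to
kappa's small-sample instability and therefore applies to categorical
variables only; a continuous variable with too few pairs for a Fisher
interval surfaces as an `NA` estimate with an explanatory note instead of a
new exclusion class. Pooling both entries for the frequency rule is the
symmetric reading of "a category's frequency"; computing it on either entry
alone would make eligibility depend on which pass is called primary.

`repro_report()` runs the whole chain over paired long-format datasets and
returns eligibility, per-variable estimates with intervals, per-module
summaries (min/median/mean/max of estimates) and the optional homogeneity
table, with print/summary/plot methods (the plot is the familiar
dot-and-interval panel per module, colour-coded by difficulty).

## The simulator

The synthetic-data engine emulates the study conditions this package is
designed around: 100 records, six modules, 217 variables, per-variable
difficulty tiers, and two readers who err independently given the truth.
Its error model is symmetric-uniform: with the difficulty-tier probability
e, a categorical entry is replaced by a uniform draw over the other k−1
categories; a continuous entry receives additive zero-centred noise rounded
to the variable's precision; independently, with `missing_prob` the value
is omitted. Symmetric misclassification is the simplest model that admits a
closed-form expected kappa, which is exactly why it was chosen:
`expected_kappa()` evaluates p_o = Σ_t π_t Σ_c q(c|t)² and
p_e = Σ_c (Σ_t π_t q(c|t))² under the kernel q(c|t) = 1−e (c = t) or
e/(k−1), giving an analytic oracle for parameter-recovery tests — e.g.
binary, balanced, e = 0.1 gives κ = 0.64 exactly.

Default tier error rates are easy 0.01, medium 0.03, difficult 0.08. These
are calibration defaults placing simulated per-variable agreement in the
high-0.9 range typical of audited double entry; they are configuration, not
estimates of any real workforce, and no test treats them as empirical
claims. Reader streams derive from `(seed, reader, record)` through a
polynomial hash with a multiplicative scramble, so all outputs are
bit-reproducible under a fixed seed while the two readers' streams stay
independent given the truth (naive sub-seed arithmetic demonstrably
correlates the readers' first draws — the package tests the realized
two-reader disagreement against its analytic value 2e(1−e)).

`build_table2_fixture()` engineers a 217-variable, six-module dataset whose
eligibility accounting is *constructed*, not sampled: balanced categorical
variables with exactly 100 complete pairs for the selected set, exactly 30
complete pairs for the too-few set, exactly 98% single-category pooled
frequency for the extreme set, and a manual-flag list for the rest. The
seed shuffles placements and transcription noise but cannot move a variable
across an eligibility boundary, so the accounting (127 selected; per module
20/7/42/15/18/25 across the six modules in schema order) is identical for
every seed.

What the simulator does *not* emulate: real clinical text (its text values
are synthetic notes), OCR or image noise, reader learning and fatigue,
non-uniform confusion structure between specific category pairs, and
informative missingness. Tests passing on simulated data therefore
demonstrate the correctness of the machinery — conflict detection,
state-machine safety, statistical formulas, filter precedence — not the
field performance of any particular abstraction workforce; enterprise-scale
reproducibility levels depend on human readers and source records that a
desk-scale package cannot contain.

## Numerical and design choices

* Continuous conflict tolerance defaults to 0; tolerance is per-comparison
  configurable, not per-schema, so QC re-entry can be stricter than entry
  comparison if desired.
* Kappa tables drop categories unobserved in both margins (they carry no
  information and would not change p_o or p_e).
* Module summary medians use the mean-of-middle-two convention for even
  counts (base R `median`).
* Degenerate inputs error loudly (zero variance, single-category tables,
  empty summaries) rather than returning sentinel estimates; the report
  layer converts these errors to `NA` estimates with notes so one bad
  variable cannot sink a 217-variable report.
* All randomness flows through a seed-restoring wrapper; no function
  disturbs the caller's RNG state.

## Problem sizes used by the test suite

The suite validates the kappa implementation exhaustively against an
independently coded cell-proportion oracle on every 2×2 and 3×3 table with
total count ≤ 20 (about 10 million 3×3 tables, run through the same
vectorized code path the user-facing function wraps), recovers the analytic
κ = 0.64 from 1000 simulated replicates at n = 100, and pushes 1000
simulated records end-to-end through entry, adjudication and commit with a
truth oracle, cross-checking every conflict count against a brute-force
field comparison. These sizes were chosen to make the checks exhaustive or
tightly concentrated while keeping the default suite comfortably fast.

## Limitations

* Scrubbing removes known identifier strings only; free-text PHI beyond the
  declared fields passes through.
* The kappa interval is a large-sample approximation; for very small n or
  extreme marginals, exact or bootstrap intervals would be preferable.
* The CLI is stateless per invocation (entry CSVs in, result CSVs out); a
  persistent multi-user task queue — routing, certification levels,
  priorities — is an enterprise concern outside this package's scope.
* Weighted kappa and intraclass correlation are intentionally absent; the
  reproducibility analysis reports one unweighted statistic per variable.
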