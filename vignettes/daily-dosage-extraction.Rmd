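---
title: "Extracting daily dosage from free-text sigs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting daily dosage from free-text sigs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigdose)
```

## The problem

A prescription signature (sig) is the free-text instruction on a
medication order — "take one tablet twice daily". The clinically
important quantity buried in it is the **daily dosage**: per-administration
dose × administrations per day, possibly a range, possibly changing over
successive **medication periods** as a drug is titrated upward ("1 tablet
daily for 1 week then 2 tablets daily"). Checking whether heart-failure
patients reach guideline-recommended daily doses, for example, requires
this number at scale, and clinicians frequently bypass structured order
entry and type free text.

sigdose implements a deterministic, rule-based extractor for this task,
together with the evaluation framework used to score such extractors and
a synthetic gold-annotated corpus generator, so every part of the system
is testable without clinical data.

A design principle runs through the whole package: **a wrong daily dose is
worse than no daily dose**. A rule-based extractor for clinical use should
maximize positive predictive value — when it asserts a dose, that dose
should be right — and refuse to answer otherwise. Several choices below
(no default frequency, the uncertainty flag, all-or-nothing evaluation)
follow from this.

## The data model

Each sig maps to an ordered list of **period objects** carrying twelve
variables: `optional_period`, `start_condition`, `daily_dose_low/high/units`,
`alt_daily_dose_low/high/units` (the same dosage re-expressed in mass or
volume units when a strength is known), `duration_low/high/units` and
`hold_condition`. Only the daily-dose, alternate-dose and duration
variables participate in evaluation; the condition fields are carried as
raw text, never interpreted. Construction validates `low <= high` on every
pair, joint presence of the alternate-dose triple and day/week/month
duration units; violations are errors, never coerced.

A sig's gold annotation distinguishes three states that must survive
serialization: unannotated (no `gold` key in JSONL), annotated-as-no-dose
(`"gold": []`) and annotated with periods. Corpora kept for evaluation
deliberately include no-dose sigs ("use as directed") so that extractors
are scored on *not* asserting a dose where none exists. Decimals are
serialized as strings with at most three decimal places, which makes
write→read round trips exact and repeated writes byte-identical.

## Normalization

`normalize_sig()` applies, in fixed order: lowercasing; number-word and
fraction conversion (`words_to_numbers()`); synonym canonicalization
(`apply_synonyms()`); irrelevant-text stripping (`strip_irrelevant()`);
whitespace collapse. The order matters: synonym keys are written against
numeric forms ("2 times daily"), so numbers are rewritten first, and
stripping runs last so no stop phrase can swallow a numeral before the
extractor sees it. The composition is idempotent by construction, and the
lexicon constructor rejects tables that would break that (no canonical
form may contain another key as a whole word).

Two details deserve note:

* Fractions: "1/2" becomes 0.5 only when it is not date-like — not part
  of a `dd/dd/dddd` token and with no 4-digit (year) component. Dates must
  survive verbatim because the uncertainty rule later exempts them.
* The shipped synonym and stop-phrase tables
  (`inst/extdata/*.tsv`) are a curated reconstruction of common sig
  vocabulary; they are plain TSV, user-replaceable via `load_lexicon()`,
  and deliberately small. They do no spelling correction and assume
  English sigs.

## Extraction and the dosage arithmetic

The normalized sig is split into period spans on the titration keywords
"then" and "increase to" (`split_periods()`); the object of "increase to"
stays in the following span. Within each span four matchers run:

* **dose** — quantity (or range) plus a dose-form unit: "0.5 tablet",
  "1-2 capsule". A parenthetical strength immediately after the dose
  expression — "(50 mg)" — is captured as the **per-administration
  amount**, not a per-tablet strength. This interpretation is the safer
  reading of an ambiguous convention: under the per-tablet reading,
  "take 1/2 tablet (50 mg) every day" would yield 25 mg/day, half of what
  the prescriber intended by the common convention of annotating the
  amount actually taken. With no form word at all, an inline "50 mg" is
  treated as a dose expressed directly in strength units.
* **frequency** — phrases mapped to administrations/day: "N times daily"
  → N, "every day"/"daily"/"nightly"/"every morning"/"every evening" → 1,
  "every other day" → 0.5, "weekly" → 1/7, ranges "2 to 3 times daily"
  → (2, 3).
* **interval** — q-notation via a single documented pattern
  (`interval_regex`): "q4hr" → every 4 hours, "q2-3hr" → every 2 to 3
  hours; bare "qN" defaults to hours, matching clinical convention for
  q-notation. Administrations/day come from **inversion**: `f_low =
  24/interval_high`, `f_high = 24/interval_low` (the longest gap gives the
  fewest administrations), with day/week/month intervals using 1, 7 and 30
  days. When both a frequency phrase and an interval match, the interval —
  the more specific expression — wins, but both matches count as consumed.
* **duration** — "for N unit", "for N–M unit", "x N unit" with unit in
  day/week/month.

`compute_period()` then computes `daily = dose × f` pairwise (low×low,
high×high; range doses pair with range frequencies low-with-low and
high-with-high), `alt_daily = strength × f` when a strength is present,
and copies durations. PRN ("as needed") dosing zeroes the daily and
alternate lows: the patient may take nothing. Final values are rounded to
3 decimal places — a reporting precision, not a dose grid. Missing dose
*or* missing schedule means **no period**: the package never assumes
once-daily, because a guessed frequency manufactures false positives.

### The uncertainty flag

After extraction the parser re-scans the whole normalized sig for numeric
tokens not covered by any matcher's consumed character ranges. Any such
numeral that is not date-like (dd/dd and dd/dd/dddd tokens, month-name
dates, 4-digit years) flips the result to `uncertain`, the periods are
discarded, and the leftover tokens are reported. A sig like "take 1
tablet daily hold if sbp less than 90" therefore yields no dose rather
than a dose that silently ignores the hold threshold. The year exemption
is restricted to 1900–2099 so that large amounts ("max 2000 mg") are not
mistaken for dates. Downstream, uncertain results count as unparsed.

## Evaluation semantics

Scoring is per sig and all-or-nothing: a daily dosage is correct only if
the period count matches and every evaluated variable of every period
matches gold exactly — numerics after 3-decimal canonicalization (both
sides are produced under the same rounding contract, so comparison is
exact, not tolerance-based), units after canonical-token normalization.
The confusion cells are: extracted and correct (TP), extracted and
incorrect — including when gold says nothing was extractable (FP), not
extracted when nothing was extractable (TN), not extracted when something
was (FN). PPV = TP/(TP+FP), sensitivity = TP/(TP+FN), F1 their harmonic
mean. Zero denominators propagate as *undefined*, never as 0, so small
subgroup tables are not silently distorted. Subgroup tables recompute the
cells within each value of a grouping attribute; sigs missing the
attribute are excluded.

`permutation_test()` compares two parsers scored on the same sigs with a
paired sign-flip design: the statistic is the F1 difference computed from
per-sig cells; each permutation swaps both parsers' cells sig-by-sig with
probability ½; the two-sided p-value uses add-one smoothing,
`(1 + #{|stat*| ≥ |stat|})/(n_perm + 1)`. This is the standard paired
design for classifier comparison; the default is 10,000 permutations and
the seed is mandatory. An undefined F1 arising inside a permutation
contributes 0 to the statistic. The Monte-Carlo p-value is checked in the
test suite against exact enumeration of all 2^n sign patterns at small n.

A related arithmetic point the test suite documents: published benchmark
tables that print PPV, sensitivity and F1 at 2 decimal places are only
self-consistent to within the propagation of that rounding. Recomputing
F1 from 2-dp inputs reproduces the printed value exactly for pairs like
(0.96, 1.00) → 0.98 and (0.99, 0.92) → 0.95, but can land one ulp off for
others (e.g. 2·0.56·0.99/1.55 = 0.7153 prints as 0.72, not 0.71, because
the original F1 was computed from unrounded inputs). The tests assert the
identity exactly where it holds and within ±0.01 — the bound implied by
±0.005 input rounding — elsewhere.

## The synthetic corpus generator

`generate_sigs()` emulates the structure of a titration-heavy
prescription corpus: single-period sigs and multi-period titrations of up
to 5 periods joined by "then"/"increase to" with escalating doses; dose
ranges; q-notation schedules; parenthetical strengths; PRN clauses;
duration clauses on non-final titration periods; no-dose sigs; and
numeral-bearing hold clauses. Defaults (30% titrations, 10% no-dose, 10%
PRN, 25% strengths, 5% hold clauses, noise level 0.5) were chosen once as
a plausible mix for such corpora; the knobs exist because real pattern
distributions are site-specific, not to be tuned against test outcomes.
Group attributes (`drug_class` over the six heart-failure classes, `sex`)
exist to exercise subgroup evaluation, not to model demographics.

Two properties make the generator a test oracle rather than a tautology:

* **Independent gold arithmetic.** The gold annotation is computed from
  the template parameters by a separate implementation of the dosage
  contract (dose × frequency, interval inversion, PRN low = 0, 3-dp
  rounding) that shares no code with `compute_period()`. Agreement
  between parser and gold is therefore a genuine cross-check.
* **Invertible noise.** Each lexical noise operator (number words,
  "tab"/"wk" abbreviations, "bid"/"qday" frequency shorthand, route and
  filler phrases, case) is the inverse image of a normalizer rule, so a
  noisy rendering normalizes back to its canonical form. Hold-clause
  records are the deliberate exception: they are annotated in gold but
  flagged `expect_uncertain`, and the parser is expected to refuse them.

On generated corpora the parser achieves PPV = sensitivity = 1.0 on
non-flagged records and flags 100% of hold-clause records — by
construction, and any miss is a bug. That is what these tests show, and
all they show: the generator covers the grammar the parser implements.
Real sigs contain misspellings, novel abbreviations, non-English text,
weight-based dosing and taper grammars the generator does not emulate, so
closure here says nothing about recall on a real corpus; published
evaluations of comparable rule-based extractors on clinical data report
sensitivity well below 1 for exactly that reason.

## Numerical and degenerate-input choices

* All dose/duration values round to 3 dp at computation; serialization
  uses ≤3-dp decimal strings; evaluation compares after the same
  canonicalization, so no float tolerance is needed anywhere.
* Zero or negative intervals ("q0hr") are clause errors, not zero doses.
* Empty sig text is rejected at the record boundary; whitespace-only text
  cannot enter parsing.
* An uncertain result empties its periods rather than carrying tentative
  ones; whether a production system should retain them for review is a
  policy question left outside the parser.
* The final period of a titration is open-ended: its duration fields stay
  empty rather than being imputed.
* Problem sizes in the shipped tests (corpora of 60–1,000 sigs, 300–4,000
  permutations, exact enumeration at n = 8) keep the full suite under a
  minute while leaving every property with real coverage.

## Known limitations

* The synonym/stop lists are small curated reconstructions; recall on
  real text depends directly on their coverage.
* Strength parentheticals are read as per-administration amounts; sites
  using per-tablet conventions must adapt the dose matcher.
* No weight-based (mg/kg) dosing, no per-day taper decrements beyond the
  period grammar, no start/hold condition semantics.
* The pairing of range doses with range frequencies (low×low, high×high)
  is an assumption; corpora that intend "1–2 tablets, 2–3 times daily" as
  a full cross product would need (low×low, high×high) replaced by
  (min, max) over the cross product — the current choice is the narrower,
  PPV-friendlier reading.
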