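# Sig-level exact-match evaluation: confusion semantics, PPV/sensitivity/
# F1, subgroup tables and the paired permutation test.

num_eq3 <- function(a, b) {
  if (is.na(a) && is.na(b)) return(TRUE)
  if (is.na(a) || is.na(b)) return(FALSE)
  abs(round(a, 3) - round(b, 3)) < 1e-9
}

unit_eq <- function(a, b) {
  ca <- canonical_unit(a)
  cb <- canonical_unit(b)
  (is.na(ca) && is.na(cb)) || (!is.na(ca) && !is.na(cb) && ca == cb)
}

#' Exact match of predicted vs gold period lists
#'
#' A sig's daily dosage counts as correctly extracted only when the period
#' count matches and, position by position, all daily-dosage variables
#' agree: daily dose low/high/units, alternate daily dose low/high/units
#' and duration low/high/units. Numeric fields are compared exactly after
#' 3-decimal canonicalization, unit tokens after [canonical_unit()]
#' normalization. `optional_period`, `start_condition` and
#' `hold_condition` are outside the scope of daily-dosage evaluation and
#' are ignored.
#'
#' @param predicted,gold lists of [period_object()]s
#' @return TRUE iff the two lists match on all evaluated variables
#' @export
match_periods <- function(predicted, gold) {
  stopifnot(is.list(predicted), is.list(gold))
  if (length(predicted) != length(gold)) return(FALSE)
  for (i in seq_along(predicted)) {
    p <- predicted[[i]]; g <- gold[[i]]
    ok <- num_eq3(p$daily_dose_low, g$daily_dose_low) &&
      num_eq3(p$daily_dose_high, g$daily_dose_high) &&
      unit_eq(p$daily_dose_units, g$daily_dose_units) &&
      num_eq3(p$alt_daily_dose_low, g$alt_daily_dose_low) &&
      num_eq3(p$alt_daily_dose_high, g$alt_daily_dose_high) &&
      unit_eq(p$alt_daily_dose_units, g$alt_daily_dose_units) &&
      num_eq3(p$duration_low, g$duration_low) &&
      num_eq3(p$duration_high, g$duration_high) &&
      unit_eq(p$duration_units, g$duration_units)
    if (!ok) return(FALSE)
  }
  TRUE
}

#' Assign one sig to a confusion cell
#'
#' * TP: a daily dose was extracted (status "parsed") and it matches gold;
#' * FP: a daily dose was extracted but is incorrect (including when gold
#'   says none should have been extracted);
#' * TN: no daily dose was extracted ("no_dose" or "uncertain") and gold
#'   says none was extractable (empty gold list);
#' * FN: no daily dose was extracted but one could have been.
#'
#' Uncertain results count as unparsed. Every annotated sig lands in
#' exactly one cell.
#'
#' @param result a [parse_result()]
#' @param gold the sig's gold annotation: a (possibly empty) list of
#'   [period_object()]s. An unannotated sig (`NULL`) is an error — it
#'   cannot be scored.
#' @return one of "TP", "FP", "TN", "FN"
#' @export
classify_sig <- function(result, gold) {
  stopifnot(inherits(result, "parse_result"))
  if (is.null(gold))
    stop("sig ", result$sig_id, " is unannotated and cannot be scored",
         call. = FALSE)
  extracted <- result$status == "parsed"
  if (extracted) {
    if (match_periods(result$periods, gold)) "TP" else "FP"
  } else {
    if (length(gold) == 0) "TN" else "FN"
  }
}

#' Confusion counts from per-sig cells
#' @param cells character vector of "TP"/"FP"/"TN"/"FN"
#' @return named integer vector with tp, fp, tn, fn
#' @export
confusion_counts <- function(cells) {
  stopifnot(all(cells %in% c("TP", "FP", "TN", "FN")))
  c(tp = sum(cells == "TP"), fp = sum(cells == "FP"),
    tn = sum(cells == "TN"), fn = sum(cells == "FN"))
}

#' F1 score from PPV and sensitivity
#'
#' `f1 = 2 * ppv * sensitivity / (ppv + sensitivity)`; undefined (NA) when
#' either input is undefined or both are zero.
#'
#' @param ppv,sensitivity values in \[0, 1\] or NA
#' @return the F1 score, or NA when undefined
#' @export
#' @examples
#' f1_score(0.96, 1.00)  # 0.98 to 2 dp
#' f1_score(0.99, 0.92)  # 0.95 to 2 dp
f1_score <- function(ppv, sensitivity) {
  if (is.na(ppv) || is.na(sensitivity)) return(NA_real_)
  if (ppv + sensitivity == 0) return(NA_real_)
  2 * ppv * sensitivity / (ppv + sensitivity)
}

#' PPV, sensitivity and F1 from confusion counts
#'
#' `ppv = tp/(tp+fp)`, `sensitivity = tp/(tp+fn)`, F1 their harmonic mean.
#' A zero denominator makes the metric undefined (NA) — never silently 0,
#' which would distort small subgroup tables.
#'
#' @param counts named vector/list with tp, fp, tn, fn (as from
#'   [confusion_counts()])
#' @return object of class `sig_metrics`: list with `ppv`, `sensitivity`,
#'   `f1` and the counts
#' @export
compute_metrics <- function(counts) {
  counts <- as.list(counts)
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  stopifnot(!is.null(tp), !is.null(fp), !is.null(tn), !is.null(fn))
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  structure(list(ppv = ppv, sensitivity = sens, f1 = f1_score(ppv, sens),
                 counts = c(tp = tp, fp = fp, tn = tn, fn = fn)),
            class = "sig_metrics")
}

#' @export
print.sig_metrics <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.3f", v)
  cat(sprintf("PPV %s | sensitivity %s | F1 %s  (tp %d fp %d tn %d fn %d)\n",
              fmt(x$ppv), fmt(x$sensitivity), fmt(x$f1),
              x$counts["tp"], x$counts["fp"], x$counts["tn"], x$counts["fn"]))
  invisible(x)
}

# Pair parse results with their annotated records by sig_id.
align_results <- function(results, records) {
  res_ids <- vapply(results, `[[`, "", "sig_id")
  rec_ids <- vapply(records, `[[`, "", "sig_id")
  missing <- setdiff(res_ids, rec_ids)
  if (length(missing) > 0)
    stop("no gold record for sig id(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  recs <- records[match(res_ids, rec_ids)]
  unann <- vapply(recs, function(r) is.null(r$gold), logical(1))
  if (any(unann))
    stop("unannotated sig(s) cannot be scored: ",
         paste(res_ids[unann], collapse = ", "), call. = FALSE)
  recs
}

#' Evaluate parse results against gold annotations
#'
#' Classifies every sig into its confusion cell and computes global
#' PPV/sensitivity/F1, optionally with per-group breakdowns.
#'
#' @param results list of [parse_result()]s
#' @param records list of annotated [sig_record()]s (matched by `sig_id`)
#' @param group_by optional group label name for a subgroup table
#' @return object of class `sig_eval`: list with `cells` (named per-sig
#'   cell vector), `metrics` (global [compute_metrics()] result) and
#'   `groups` (named list of per-group metrics, if requested)
#' @export
evaluate_results <- function(results, records, group_by = NULL) {
  recs <- align_results(results, records)
  cells <- vapply(seq_along(results), function(i)
    classify_sig(results[[i]], recs[[i]]$gold), character(1))
  names(cells) <- vapply(results, `[[`, "", "sig_id")
  out <- list(cells = cells, metrics = compute_metrics(confusion_counts(cells)),
              groups = NULL)
  if (!is.null(group_by))
    out$groups <- subgroup_metrics(results, records, group_by)
  structure(out, class = "sig_eval")
}

#' @export
print.sig_eval <- function(x, ...) {
  cat("Overall: ")
  print(x$metrics)
  for (g in names(x$groups)) {
    cat(sprintf("%-20s ", g))
    print(x$groups[[g]])
  }
  invisible(x)
}

#' Per-group evaluation metrics
#'
#' Splits the evaluated sigs by the value of one group label and computes
#' metrics within each group independently. Sigs that do not carry the
#' label are excluded (mirroring the exclusion of records with missing
#' demographic attributes).
#'
#' @param results list of [parse_result()]s
#' @param records list of annotated [sig_record()]s
#' @param group_label name of the group attribute (e.g. "drug_class")
#' @return named list: group value -> `sig_metrics`
#' @export
subgroup_metrics <- function(results, records, group_label) {
  stopifnot(is.character(group_label), length(group_label) == 1)
  recs <- align_results(results, records)
  vals <- vapply(recs, function(r) {
    v <- r$groups[[group_label]]
    if (is.null(v)) NA_character_ else as.character(v)
  }, character(1))
  if (all(is.na(vals)))
    stop("no sig carries group label '", group_label, "'", call. = FALSE)
  keep <- !is.na(vals)
  cells <- vapply(which(keep), function(i)
    classify_sig(results[[i]], recs[[i]]$gold), character(1))
  split_cells <- split(cells, vals[keep])
  lapply(split_cells, function(cc) compute_metrics(confusion_counts(cc)))
}

f1_from_cells <- function(cells) {
  m <- compute_metrics(confusion_counts(cells))
  if (is.na(m$f1)) 0 else m$f1
}

#' Paired permutation test on per-sig correctness
#'
#' Compares two parsers scored on the same sigs. The statistic is the
#' difference in F1 computed from the per-sig confusion cells; the null
#' distribution is generated by swapping each sig's paired cell assignment
#' between the two parsers with probability 1/2 (a paired sign-flip
#' design). The two-sided p-value uses add-one smoothing:
#' `(1 + #\{|stat*| >= |stat|\}) / (n_perm + 1)`. An undefined F1 inside a
#' permutation contributes 0 to the statistic.
#'
#' @param outcomes_a,outcomes_b character vectors of per-sig cells
#'   ("TP"/"FP"/"TN"/"FN"), paired by position (same sigs, same order)
#' @param n_perm number of permutations (default 10000)
#' @param seed RNG seed (required, for reproducibility)
#' @return object of class `sig_permutation`: list with `statistic`
#'   (observed F1 difference), `p_value`, `n_perm`, `seed`
#' @export
permutation_test <- function(outcomes_a, outcomes_b, n_perm = 10000, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (length(outcomes_a) != length(outcomes_b))
    stop("outcome vectors must have equal length (paired by sig)",
         call. = FALSE)
  stopifnot(all(c(outcomes_a, outcomes_b) %in% c("TP", "FP", "TN", "FN")),
            n_perm >= 1)
  n <- length(outcomes_a)
  obs <- f1_from_cells(outcomes_a) - f1_from_cells(outcomes_b)
  exceed <- with_seed(seed, {
    cnt <- 0L
    for (k in seq_len(n_perm)) {
      swap <- stats::runif(n) < 0.5
      a <- ifelse(swap, outcomes_b, outcomes_a)
      b <- ifelse(swap, outcomes_a, outcomes_b)
      stat <- f1_from_cells(a) - f1_from_cells(b)
      if (abs(stat) >= abs(obs) - 1e-12) cnt <- cnt + 1L
    }
    cnt
  })
  structure(list(statistic = obs, p_value = (1 + exceed) / (n_perm + 1),
                 n_perm = n_perm, seed = seed),
            class = "sig_permutation")
}

#' @export
print.sig_permutation <- function(x, ...) {
  cat(sprintf("Paired permutation test: F1 difference %.4f, p = %.4f (%d permutations, seed %d)\n",
              x$statistic, x$p_value, x$n_perm, x$seed))
  invisible(x)
}
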