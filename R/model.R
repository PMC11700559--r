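#' Construct a medication period object
#'
#' A period object holds the structured daily dosage for one contiguous
#' medication period of a sig. Titration sigs ("1 tablet daily for 1 week
#' then 2 tablets daily") chain several period objects in order. The daily
#' dose is a range (`daily_dose_low`/`daily_dose_high`) in a dose-form unit
#' (tablet, capsule, ...); the alternate daily dose expresses the same
#' period in mass/volume units (mg, mcg, mL) when a strength is known; the
#' duration bounds how long the period lasts, in day/week/month units.
#'
#' Invariants enforced at construction (violations are errors, never
#' silently coerced):
#' * all numeric fields non-negative; `low <= high` for the daily, alternate
#'   and duration pairs;
#' * the three alternate-dose fields are jointly present or jointly empty;
#' * a duration value requires `duration_units`, one of day/week/month.
#'
#' Empty numeric fields are `NA`, empty unit fields are `NA`, and the two
#' free-text condition fields default to `""`.
#'
#' @param daily_dose_low,daily_dose_high lowest/highest daily dose
#' @param daily_dose_units canonical dose-form unit token (e.g. "tablet")
#' @param alt_daily_dose_low,alt_daily_dose_high alternate (mass/volume)
#'   daily dose bounds, or NA
#' @param alt_daily_dose_units alternate unit token (e.g. "mg"), or NA
#' @param duration_low,duration_high duration bounds, or NA
#' @param duration_units "day", "week" or "month", or NA
#' @param optional_period logical; is the period optional for the patient
#' @param start_condition,hold_condition free-text condition clauses ("" if
#'   none); carried verbatim, never interpreted, and excluded from
#'   evaluation
#' @return an object of class `period_object`
#' @export
#' @examples
#' period_object(2, 2, "tablet")
#' period_object(0.5, 0.5, "tablet", 50, 50, "mg")
period_object <- function(daily_dose_low, daily_dose_high, daily_dose_units,
                          alt_daily_dose_low = NA_real_,
                          alt_daily_dose_high = NA_real_,
                          alt_daily_dose_units = NA_character_,
                          duration_low = NA_real_,
                          duration_high = NA_real_,
                          duration_units = NA_character_,
                          optional_period = FALSE,
                          start_condition = "",
                          hold_condition = "") {
  p <- structure(list(
    optional_period = isTRUE(optional_period),
    start_condition = as.character(start_condition %||% ""),
    daily_dose_low = as.numeric(daily_dose_low),
    daily_dose_high = as.numeric(daily_dose_high),
    daily_dose_units = as.character(daily_dose_units),
    alt_daily_dose_low = as.numeric(alt_daily_dose_low),
    alt_daily_dose_high = as.numeric(alt_daily_dose_high),
    alt_daily_dose_units = as.character(alt_daily_dose_units),
    duration_low = as.numeric(duration_low),
    duration_high = as.numeric(duration_high),
    duration_units = as.character(duration_units),
    hold_condition = as.character(hold_condition %||% "")
  ), class = "period_object")
  validate_period(p)
  p
}

#' Validate a period object's invariants
#' @param p a `period_object`
#' @return `p`, invisibly, or an error describing the violated invariant
#' @export
validate_period <- function(p) {
  stopifnot(inherits(p, "period_object"))
  chk_pair <- function(lo, hi, what) {
    if (!is.na(lo) && lo < 0) stop(what, "_low must be non-negative", call. = FALSE)
    if (!is.na(hi) && hi < 0) stop(what, "_high must be non-negative", call. = FALSE)
    if (!is.na(lo) && !is.na(hi) && lo > hi)
      stop(what, "_low must be <= ", what, "_high", call. = FALSE)
  }
  if (is.na(p$daily_dose_low) || is.na(p$daily_dose_high))
    stop("daily_dose_low and daily_dose_high are required", call. = FALSE)
  if (is.na(p$daily_dose_units) || !nzchar(p$daily_dose_units))
    stop("daily_dose_units is required", call. = FALSE)
  chk_pair(p$daily_dose_low, p$daily_dose_high, "daily_dose")
  chk_pair(p$alt_daily_dose_low, p$alt_daily_dose_high, "alt_daily_dose")
  chk_pair(p$duration_low, p$duration_high, "duration")
  alt_present <- c(!is.na(p$alt_daily_dose_low), !is.na(p$alt_daily_dose_high),
                   !is.na(p$alt_daily_dose_units) && nzchar(p$alt_daily_dose_units))
  if (any(alt_present) && !all(alt_present))
    stop("alt_daily_dose fields must be jointly present or jointly empty",
         call. = FALSE)
  if ((!is.na(p$duration_low) || !is.na(p$duration_high))) {
    if (is.na(p$duration_units) || !nzchar(p$duration_units))
      stop("duration values require duration_units", call. = FALSE)
  }
  if (!is.na(p$duration_units) && nzchar(p$duration_units) &&
      !p$duration_units %in% c("day", "week", "month"))
    stop("duration_units must be one of day/week/month", call. = FALSE)
  invisible(p)
}

#' @export
print.period_object <- function(x, ...) {
  rng <- function(lo, hi, un) {
    if (is.na(lo)) return("-")
    v <- if (!is.na(hi) && hi != lo) paste0(fmt_dec(lo), "-", fmt_dec(hi)) else fmt_dec(lo)
    if (!is.na(un) && nzchar(un)) paste(v, un) else v
  }
  cat("<period> daily", rng(x$daily_dose_low, x$daily_dose_high, x$daily_dose_units))
  if (!is.na(x$alt_daily_dose_low))
    cat(" | alt", rng(x$alt_daily_dose_low, x$alt_daily_dose_high, x$alt_daily_dose_units))
  if (!is.na(x$duration_low))
    cat(" | for", rng(x$duration_low, x$duration_high, x$duration_units))
  if (nzchar(x$hold_condition)) cat(" | hold:", x$hold_condition)
  cat("\n")
  invisible(x)
}

#' Construct a sig record
#'
#' One free-text prescription signature, optionally with grouping attributes
#' (used for subgroup evaluation) and a gold annotation. The gold annotation
#' distinguishes three states: `NULL` (unannotated), an empty list
#' (annotated: no daily dose is extractable from this sig) and a non-empty
#' list of [period_object()]s.
#'
#' @param sig_id unique identifier (non-empty string)
#' @param text raw free-text sig; must be non-empty after trimming
#' @param groups optional named list/character of group labels, e.g.
#'   `list(drug_class = "beta blocker", sex = "F")`
#' @param gold optional list of [period_object()]s; `list()` means
#'   annotated-as-no-dose, `NULL` means unannotated
#' @return an object of class `sig_record`
#' @export
sig_record <- function(sig_id, text, groups = NULL, gold = NULL) {
  sig_id <- as.character(sig_id)
  text <- as.character(text)
  if (length(sig_id) != 1 || is.na(sig_id) || !nzchar(sig_id))
    stop("sig_id must be a non-empty string", call. = FALSE)
  if (length(text) != 1 || is.na(text) || !nzchar(trimws(text)))
    stop("text must be non-empty after trimming", call. = FALSE)
  if (!is.null(groups)) {
    groups <- as.list(groups)
    if (is.null(names(groups)) || any(!nzchar(names(groups))))
      stop("groups must be a named list", call. = FALSE)
    groups <- lapply(groups, as.character)
    groups <- groups[order(names(groups))]  # canonical label order
  }
  if (!is.null(gold)) {
    stopifnot(is.list(gold))
    lapply(gold, validate_period)
  }
  structure(list(sig_id = sig_id, text = text, groups = groups, gold = gold),
            class = "sig_record")
}

#' @export
print.sig_record <- function(x, ...) {
  cat("<sig ", x$sig_id, "> ", x$text, "\n", sep = "")
  if (!is.null(x$gold))
    cat("  gold:", if (length(x$gold) == 0) "no daily dose" else
        paste(length(x$gold), "period(s)"), "\n")
  invisible(x)
}

#' Construct a parse result
#'
#' The output of [parse_sig()] for one sig. `status` is one of:
#' * `"parsed"` — at least one period was computed and every numeral in the
#'   sig was accounted for; `periods` is non-empty;
#' * `"no_dose"` — no daily dose could be computed (and no stray numerals
#'   remained);
#' * `"uncertain"` — numerals other than dates remained unconsumed after
#'   extraction; `periods` is emptied and the leftover numeric tokens are
#'   listed in `residual_tokens`. Downstream evaluation treats uncertain
#'   sigs as unparsed.
#'
#' @param sig_id sig identifier
#' @param status "parsed", "no_dose" or "uncertain"
#' @param periods list of [period_object()]s (empty unless parsed)
#' @param residual_tokens character vector of unconsumed numeric tokens
#'   (non-empty iff status is "uncertain")
#' @param normalized_text the sig text after [normalize_sig()]
#' @return an object of class `parse_result`
#' @export
parse_result <- function(sig_id, status, periods = list(),
                         residual_tokens = character(), normalized_text = "") {
  status <- match.arg(status, c("parsed", "no_dose", "uncertain"))
  if (status == "parsed") {
    if (length(periods) == 0)
      stop("status 'parsed' requires at least one period", call. = FALSE)
    lapply(periods, validate_period)
  } else if (length(periods) != 0) {
    stop("periods must be empty unless status is 'parsed'", call. = FALSE)
  }
  if (status == "uncertain" && length(residual_tokens) == 0)
    stop("status 'uncertain' requires residual_tokens", call. = FALSE)
  if (status != "uncertain" && length(residual_tokens) != 0)
    stop("residual_tokens only populate when status is 'uncertain'", call. = FALSE)
  structure(list(sig_id = as.character(sig_id), status = status,
                 periods = periods,
                 residual_tokens = as.character(residual_tokens),
                 normalized_text = as.character(normalized_text)),
            class = "parse_result")
}

#' @export
print.parse_result <- function(x, ...) {
  cat("<parse ", x$sig_id, "> ", x$status, sep = "")
  if (x$status == "uncertain")
    cat(" [", paste(x$residual_tokens, collapse = ", "), "]", sep = "")
  cat("\n")
  for (p in x$periods) print(p)
  invisible(x)
}
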