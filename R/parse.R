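# Per-span clause assembly, daily-dose arithmetic and the full pipeline.

# Gather all clause matches for one period span. When both a frequency
# phrase and an interval match, the interval wins (more specific); both
# matches are still marked consumed.
extract_clauses <- function(span_text) {
  interval <- extract_interval(span_text)
  freq <- extract_frequency(span_text)
  dose <- extract_dose(span_text)
  duration <- extract_duration(span_text)
  prn_m <- first_match("\\bprn\\b", span_text)
  prn <- !is.null(prn_m) || (!is.null(interval) && interval$prn)
  spans <- c(if (!is.null(dose)) dose$spans,
             if (!is.null(interval)) interval$spans,
             if (!is.null(freq)) freq$spans,
             if (!is.null(duration)) duration$spans,
             if (!is.null(prn_m)) list(prn_m$range))
  list(dose = dose, interval = interval, freq = freq, duration = duration,
       prn = prn, spans = spans)
}

#' Compute a period object from extracted clauses
#'
#' Applies the daily-dose arithmetic contract to the clauses extracted from
#' one period span:
#' * frequency comes from the interval when one is present, by inversion:
#'   `f_low = 24/interval_high`, `f_high = 24/interval_low` for hour
#'   intervals; an interval of N days gives `f = 1/N` (weeks and months use
#'   7 and 30 days);
#' * `daily_dose_low = dose_low * f_low`, `daily_dose_high = dose_high *
#'   f_high`; the alternate daily dose is `strength * f` when a strength
#'   was captured;
#' * PRN (as-needed) dosing sets the daily and alternate lows to 0 — the
#'   patient may take nothing;
#' * duration fields are copied through; final values are rounded to 3
#'   decimal places.
#'
#' No dose, or neither a frequency nor an interval, means no daily dose can
#' be computed and `NULL` is returned; there is no implicit once-daily
#' default, since guessing a frequency would manufacture false positives.
#'
#' @param clauses list as produced by the span extractors: elements
#'   `dose`, `interval`, `freq`, `duration` (each `NULL` or the
#'   corresponding extractor's result) and `prn` (logical)
#' @return a [period_object()] or `NULL` when no daily dose is computable
#' @export
compute_period <- function(clauses) {
  dose <- clauses$dose
  if (is.null(dose)) return(NULL)
  f <- NULL
  if (!is.null(clauses$interval)) {
    iv <- clauses$interval
    if (iv$low <= 0 || iv$high <= 0)
      stop("interval bounds must be positive", call. = FALSE)
    per_day <- switch(iv$unit, hours = 24, day = 1, week = 1 / 7,
                      month = 1 / 30)
    # inversion: the longest gap gives the fewest administrations per day
    f <- c(per_day / iv$high, per_day / iv$low)
  } else if (!is.null(clauses$freq)) {
    f <- c(clauses$freq$low, clauses$freq$high)
  }
  if (is.null(f)) return(NULL)
  prn <- isTRUE(clauses$prn)
  daily_low <- round(dose$dose_low * f[1], 3)
  daily_high <- round(dose$dose_high * f[2], 3)
  if (prn) daily_low <- 0
  alt <- list(low = NA_real_, high = NA_real_, unit = NA_character_)
  if (!is.na(dose$strength_low)) {
    alt$low <- round(dose$strength_low * f[1], 3)
    alt$high <- round(dose$strength_high * f[2], 3)
    if (prn) alt$low <- 0
    alt$unit <- dose$strength_unit
  }
  dur <- clauses$duration
  period_object(
    daily_dose_low = daily_low, daily_dose_high = daily_high,
    daily_dose_units = dose$dose_unit,
    alt_daily_dose_low = alt$low, alt_daily_dose_high = alt$high,
    alt_daily_dose_units = alt$unit,
    duration_low = if (is.null(dur)) NA_real_ else dur$low,
    duration_high = if (is.null(dur)) NA_real_ else dur$high,
    duration_units = if (is.null(dur)) NA_character_ else dur$unit,
    optional_period = isTRUE(clauses$prn)
  )
}

month_names <- c("january", "february", "march", "april", "may", "june",
                 "july", "august", "september", "october", "november",
                 "december", "jan", "feb", "mar", "apr", "jun", "jul",
                 "aug", "sep", "sept", "oct", "nov", "dec")

# 0-based half-open ranges of date-like tokens in normalized text:
# dd/dd and dd/dd/dddd, month-name + day, day + month-name, and 4-digit
# years (1900-2099; unrestricted 4-digit exemption would excuse large
# doses such as "max 2000 mg").
date_ranges <- function(text) {
  pats <- c(
    "\\b[0-9]{1,2}/[0-9]{1,2}(?:/[0-9]{2,4})?\\b",
    paste0("\\b(?:", paste(month_names, collapse = "|"),
           ")\\s+[0-9]{1,2}(?:\\s+(?:19|20)[0-9]{2})?\\b"),
    paste0("\\b[0-9]{1,2}\\s+(?:", paste(month_names, collapse = "|"),
           ")\\b"),
    "\\b(?:19|20)[0-9]{2}\\b"
  )
  out <- list()
  for (p in pats) {
    m <- gregexpr(p, text, perl = TRUE)[[1]]
    if (m[1] == -1) next
    for (i in seq_along(m))
      out[[length(out) + 1L]] <- match_range(m[i], attr(m, "match.length")[i])
  }
  out
}

#' Flag unconsumed numerals as uncertainty
#'
#' The parser's safety mechanism: after extraction, any numeral left in the
#' sig that is not part of a date (dd/dd, dd/dd/dddd, month-name dates,
#' 4-digit years) means the sig contains numeric information the extractor
#' did not understand — e.g. a hold threshold ("hold if sbp less than 90")
#' or a cap ("max 90 mg"). Such results are tagged uncertain and treated
#' as unparsed downstream rather than risking a wrong dose.
#'
#' @param normalized_text the full normalized sig
#' @param consumed_spans list of 0-based half-open character ranges
#'   consumed by the extractors (global coordinates)
#' @return list with `uncertain` (logical) and `residual_tokens`
#'   (character vector of leftover numeric tokens)
#' @export
detect_uncertainty <- function(normalized_text, consumed_spans) {
  exempt <- c(consumed_spans, date_ranges(normalized_text))
  m <- gregexpr("[0-9]+(?:\\.[0-9]+)?", normalized_text, perl = TRUE)[[1]]
  residual <- character(0)
  if (m[1] != -1) {
    for (i in seq_along(m)) {
      r <- match_range(m[i], attr(m, "match.length")[i])
      if (!range_covers(exempt, r[1], r[2]))
        residual <- c(residual, substr(normalized_text, m[i],
                                       m[i] + attr(m, "match.length")[i] - 1))
    }
  }
  list(uncertain = length(residual) > 0, residual_tokens = residual)
}

#' Parse one sig into structured daily-dosage periods
#'
#' The full deterministic pipeline: [normalize_sig()], [split_periods()]
#' on "then"/"increase to", per-span clause extraction, [compute_period()]
#' arithmetic, then [detect_uncertainty()] over the whole sig. The result
#' status is `"parsed"` only if at least one period was computed and no
#' stray numeral remained; uncertain results have their periods emptied so
#' downstream evaluation counts them as unparsed.
#'
#' @param record a [sig_record()], or a character sig (an id is invented)
#' @param lexicon a [sig_lexicon()] for normalization
#' @return a [parse_result()]
#' @export
#' @examples
#' parse_sig("take one tablet twice daily")
#' parse_sig("take 1/2 tablet (50 mg) by mouth every day")
parse_sig <- function(record, lexicon = default_lexicon()) {
  if (is.character(record)) record <- sig_record("sig", record)
  stopifnot(inherits(record, "sig_record"))
  if (!nzchar(trimws(record$text)))
    stop("cannot parse an empty sig", call. = FALSE)
  normalized <- normalize_sig(record$text, lexicon)
  spans <- split_periods(normalized)
  periods <- list()
  consumed <- list()
  for (sp in spans) {
    cl <- extract_clauses(sp$text)
    for (r in cl$spans)
      consumed[[length(consumed) + 1L]] <- sp$start + r
    p <- compute_period(cl)
    if (!is.null(p)) periods[[length(periods) + 1L]] <- p
  }
  unc <- detect_uncertainty(normalized, consumed)
  if (unc$uncertain) {
    parse_result(record$sig_id, "uncertain", periods = list(),
                 residual_tokens = unc$residual_tokens,
                 normalized_text = normalized)
  } else if (length(periods) > 0) {
    parse_result(record$sig_id, "parsed", periods = periods,
                 normalized_text = normalized)
  } else {
    parse_result(record$sig_id, "no_dose", normalized_text = normalized)
  }
}

#' Parse a list of sig records
#'
#' @param records list of [sig_record()]s
#' @param lexicon a [sig_lexicon()]
#' @return list of [parse_result()]s, in input order
#' @export
parse_sigs <- function(records, lexicon = default_lexicon()) {
  lapply(records, parse_sig, lexicon = lexicon)
}
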