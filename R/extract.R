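# Regular-expression extraction of structured dosage elements from a
# normalized sig span. Every matcher returns the 0-based half-open
# character ranges it consumed; the uncertainty detector later flags any
# numeral that no matcher accounted for.

#' The q-notation interval pattern
#'
#' Matches interval shorthand such as "q4hr" (every 4 hours) and "q2-3hr"
#' (every 2 to 3 hours), capturing the bound(s) and a unit suffix
#' (hr/h, day, week, month), an empty suffix (bare "qN", read as hours) or
#' a "prn" suffix. The leading alternative requires the `q` to be
#' string-initial or preceded by a space so the pattern never fires inside
#' a word.
#'
#' @format A character scalar (a Perl-compatible regular expression).
#' @export
interval_regex <- "((^q)|( q))([\\s]?)([\\d]+)((-)([\\d]+))?([\\s]?)((hr$)|(h$)|(hr)|(h)|(month)|(week)|(day)|($)|(prn))"

num_rx <- "([0-9]+(?:\\.[0-9]+)?)"
range_rx <- function(n) paste0(n, "(?:\\s*(?:-|\\bto\\b)\\s*", n, ")?")

first_match <- function(pattern, text) {
  m <- regexpr(pattern, text, perl = TRUE)
  if (m[1] == -1) return(NULL)
  st <- attr(m, "capture.start")
  le <- attr(m, "capture.length")
  groups <- character(0)
  if (!is.null(st)) {
    groups <- vapply(seq_along(st), function(i) {
      if (st[i] > 0) substr(text, st[i], st[i] + le[i] - 1) else NA_character_
    }, character(1))
  }
  list(start = m[1], length = attr(m, "match.length"),
       range = match_range(m[1], attr(m, "match.length")),
       text = substr(text, m[1], m[1] + attr(m, "match.length") - 1),
       groups = groups)
}

#' Extract a q-notation interval from a span
#'
#' Applies [interval_regex]. A single captured value gives `low == high`;
#' the unit suffix resolves to hours (hr/h, bare "qN", or "prn" suffix) or
#' to day/week/month literally. The `prn` flag is set when the matched
#' suffix is "prn" or the span contains a standalone "prn" token.
#'
#' @param span_text normalized span text
#' @return `NULL` if no interval, else a list with `low`, `high`, `unit`
#'   ("hours", "day", "week" or "month"), `prn` (logical) and `spans`
#'   (consumed character ranges, 0-based half-open)
#' @export
#' @examples
#' extract_interval("q4hr")
#' extract_interval("q2-3hr")
extract_interval <- function(span_text) {
  m <- first_match(interval_regex, span_text)
  if (is.null(m)) return(NULL)
  g <- m$groups
  low <- as.numeric(g[5])
  high <- if (!is.na(g[8])) as.numeric(g[8]) else low
  raw_unit <- g[10]
  if (is.na(raw_unit)) raw_unit <- ""
  unit <- switch(raw_unit,
                 hr = "hours", h = "hours", prn = "hours",
                 month = "month", week = "week", day = "day",
                 "hours")
  prn <- identical(raw_unit, "prn") ||
    grepl("\\bprn\\b", span_text, perl = TRUE)
  list(low = low, high = high, unit = unit, prn = prn, spans = list(m$range))
}

#' Extract a dosing frequency (administrations per day) from a span
#'
#' Maps frequency phrases in the normalized span onto administrations per
#' day: "N times daily" (and ranges "N to M times daily") to N (M);
#' "every day"/"daily"/"nightly"/"every morning"/"every evening" to 1;
#' "every other day" to 0.5; "weekly" to 1/7.
#'
#' @param span_text normalized span text
#' @return `NULL` if no frequency phrase, else list with `low`, `high`
#'   (administrations/day) and `spans` (consumed ranges)
#' @export
#' @examples
#' extract_frequency("take 1 tablet 2 times daily")
extract_frequency <- function(span_text) {
  daily_tail <- "\\s+times?\\s+(?:daily|a day|per day|each day)\\b"
  pats <- list(
    list(rx = paste0("\\b", num_rx, "\\s*(?:-|\\bto\\b)\\s*", num_rx, daily_tail),
         f = function(g) c(as.numeric(g[1]), as.numeric(g[2]))),
    list(rx = paste0("\\b", num_rx, daily_tail),
         f = function(g) rep(as.numeric(g[1]), 2)),
    list(rx = "\\bevery other day\\b", f = function(g) c(0.5, 0.5)),
    list(rx = "\\b(?:weekly)\\b", f = function(g) c(1 / 7, 1 / 7)),
    list(rx = paste0("\\b(?:every day|daily|nightly|every night|",
                     "every morning|every evening)\\b"),
         f = function(g) c(1, 1))
  )
  for (p in pats) {
    m <- first_match(p$rx, span_text)
    if (!is.null(m)) {
      v <- p$f(m$groups)
      return(list(low = v[1], high = v[2], spans = list(m$range)))
    }
  }
  NULL
}

form_units <- c("tablet", "capsule", "pill", "puff", "drop", "spray",
                "patch", "ml")
strength_units <- c("mg", "mcg", "g", "ml", "unit")

#' Extract the per-administration dose (and optional strength) from a span
#'
#' Matches a quantity (optionally a range) followed by a dose-form unit,
#' e.g. "0.5 tablet" or "1-2 capsule". A parenthetical strength
#' "(X mg|mcg|mL)" immediately after the dose expression is captured as the
#' per-administration strength X — the amount taken at each
#' administration, not a per-unit tablet strength. When no form-unit dose
#' is present, an inline "X mg" is captured as a dose expressed directly in
#' strength units.
#'
#' @param span_text normalized span text
#' @return `NULL` if no dose, else list with `dose_low`, `dose_high`,
#'   `dose_unit`, `strength_low`, `strength_high`, `strength_unit`
#'   (strength fields NA when absent) and `spans` (consumed ranges)
#' @export
#' @examples
#' extract_dose("take 0.5 tablet (50 mg) every day")
extract_dose <- function(span_text) {
  dose_rx <- paste0("\\b", range_rx(num_rx), "\\s*(",
                    paste(form_units, collapse = "|"), ")s?\\b")
  m <- first_match(dose_rx, span_text)
  if (!is.null(m)) {
    g <- m$groups
    out <- list(dose_low = as.numeric(g[1]),
                dose_high = if (!is.na(g[2])) as.numeric(g[2]) else as.numeric(g[1]),
                dose_unit = canonical_unit(g[3]),
                strength_low = NA_real_, strength_high = NA_real_,
                strength_unit = NA_character_,
                spans = list(m$range))
    rest <- substr(span_text, m$start + m$length, nchar(span_text))
    paren_rx <- paste0("^\\s*\\(\\s*", range_rx(num_rx), "\\s*(",
                       paste(strength_units, collapse = "|"), ")s?\\s*\\)")
    pm <- first_match(paren_rx, rest)
    if (!is.null(pm)) {
      pg <- pm$groups
      out$strength_low <- as.numeric(pg[1])
      out$strength_high <- if (!is.na(pg[2])) as.numeric(pg[2]) else as.numeric(pg[1])
      out$strength_unit <- canonical_unit(pg[3])
      off <- m$start + m$length - 1L  # 0-based offset of `rest` in span
      out$spans <- c(out$spans,
                     list(c(off + pm$range[1], off + pm$range[2])))
    }
    return(out)
  }
  # inline strength with no form word: dose in strength units
  inline_rx <- paste0("\\b", range_rx(num_rx), "\\s*(",
                      paste(setdiff(strength_units, "ml"), collapse = "|"),
                      ")s?\\b")
  m <- first_match(inline_rx, span_text)
  if (is.null(m)) return(NULL)
  g <- m$groups
  list(dose_low = as.numeric(g[1]),
       dose_high = if (!is.na(g[2])) as.numeric(g[2]) else as.numeric(g[1]),
       dose_unit = canonical_unit(g[3]),
       strength_low = NA_real_, strength_high = NA_real_,
       strength_unit = NA_character_,
       spans = list(m$range))
}

#' Extract a duration clause from a span
#'
#' Matches "for N unit", "for N-M unit" / "for N to M unit" and "x N unit"
#' with unit one of day/week/month (singular after normalization).
#'
#' @param span_text normalized span text
#' @return `NULL` if no duration, else list with `low`, `high`, `unit` and
#'   `spans` (consumed ranges)
#' @export
#' @examples
#' extract_duration("take 1 tablet daily for 1 week")
extract_duration <- function(span_text) {
  rx <- paste0("\\b(?:for|x)\\s+", range_rx(num_rx),
               "\\s*(day|week|month)s?\\b")
  m <- first_match(rx, span_text)
  if (is.null(m)) return(NULL)
  g <- m$groups
  list(low = as.numeric(g[1]),
       high = if (!is.na(g[2])) as.numeric(g[2]) else as.numeric(g[1]),
       unit = g[3], spans = list(m$range))
}

#' Split a normalized sig into medication-period spans
#'
#' Titration sigs chain periods with the keywords "then" and
#' "increase to"; splitting on them yields one span per period, in textual
#' order. The phrase following "increase to" stays inside the next span.
#'
#' @param normalized_text output of [normalize_sig()]
#' @return list of spans, each a list with `index` (0-based), `text`
#'   (trimmed span text), `start` (0-based offset of the trimmed text in
#'   `normalized_text`) and `joiner` (keyword preceding the span, "" for
#'   the first)
#' @export
#' @examples
#' split_periods("take 1 tablet daily for 1 week then 2 tablet daily")
split_periods <- function(normalized_text) {
  stopifnot(is.character(normalized_text), length(normalized_text) == 1)
  rx <- "\\b(?:then|increase to)\\b"
  m <- gregexpr(rx, normalized_text, perl = TRUE)[[1]]
  cuts <- if (m[1] == -1) integer(0) else as.integer(m)
  lens <- if (m[1] == -1) integer(0) else attr(m, "match.length")
  starts <- c(1L, cuts + lens)
  ends <- c(cuts - 1L, nchar(normalized_text))
  joiners <- c("", if (length(cuts))
    substring(normalized_text, cuts, cuts + lens - 1L))
  spans <- list()
  idx <- 0L
  for (i in seq_along(starts)) {
    raw <- substring(normalized_text, starts[i], ends[i])
    lead <- attr(regexpr("^\\s*", raw), "match.length")
    txt <- squish(raw)
    if (!nzchar(txt)) next
    spans[[length(spans) + 1L]] <- list(
      index = idx, text = txt,
      start = starts[i] - 1L + lead,  # 0-based offset of trimmed text
      joiner = joiners[i])
    idx <- idx + 1L
  }
  spans
}
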