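# Lexical normalization: rewrite a raw sig into the canonical form the
# extractor's patterns are written against. All stages are deterministic,
# locale-independent and never remove or alter a numeral once it exists
# (uncertainty detection counts leftover numerals).

#' Convert spelled-out quantities to decimal numerals
#'
#' Rewrites number words (one..ten), "half"/"one-half", "N and a half" and
#' fraction literals ("1/2") to decimal numerals; everything else passes
#' through unchanged. Fractions are left alone when they look like dates:
#' part of a dd/dd/dddd token, or either side is a 4-digit year.
#'
#' @param text character scalar
#' @return the rewritten string
#' @export
#' @examples
#' words_to_numbers("take one tablet twice daily")
#' words_to_numbers("take 1/2 tablet")
words_to_numbers <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  if (is.na(text) || !nzchar(text)) return(text)
  x <- text
  words <- c(one = 1, two = 2, three = 3, four = 4, five = 5,
             six = 6, seven = 7, eight = 8, nine = 9, ten = 10)
  word_alt <- paste(names(words), collapse = "|")

  # "N and a half" / "word and one half" -> N.5
  rx <- paste0("\\b(", word_alt, "|[0-9]+)\\s+and\\s+(a|one)[\\s-]half\\b")
  m <- gregexpr(rx, x, perl = TRUE, ignore.case = TRUE)[[1]]
  if (m[1] != -1) {
    for (i in rev(seq_along(m))) {
      s <- m[i]; e <- s + attr(m, "match.length")[i] - 1
      tok <- substr(x, s, e)
      base <- tolower(sub("(?i)\\s+and\\s+(a|one)[\\s-]half", "", tok, perl = TRUE))
      n <- if (base %in% names(words)) words[[base]] else as.numeric(base)
      x <- paste0(substr(x, 1, s - 1), fmt_dec(n + 0.5),
                  substr(x, e + 1, nchar(x)))
    }
  }
  # "one-half" / "one half" / bare "half" -> 0.5
  x <- gsub("\\bone[\\s-]half\\b", "0.5", x, perl = TRUE, ignore.case = TRUE)
  x <- gsub("\\b(a\\s+)?half\\b", "0.5", x, perl = TRUE, ignore.case = TRUE)
  # number words -> digits
  for (w in names(words)) {
    x <- gsub(paste0("\\b", w, "\\b"), as.character(words[[w]]), x,
              perl = TRUE, ignore.case = TRUE)
  }
  convert_fractions(x)
}

# "a/b" -> decimal (3 dp) unless date-like: token followed/preceded by
# another "/", or either side is a 4-digit number (year).
convert_fractions <- function(x) {
  m <- gregexpr("[0-9]+/[0-9]+", x, perl = TRUE)[[1]]
  if (m[1] == -1) return(x)
  for (i in rev(seq_along(m))) {
    s <- m[i]; e <- s + attr(m, "match.length")[i] - 1
    before <- if (s > 1) substr(x, s - 1, s - 1) else ""
    after <- if (e < nchar(x)) substr(x, e + 1, e + 1) else ""
    if (before == "/" || after == "/") next
    tok <- substr(x, s, e)
    parts <- strsplit(tok, "/", fixed = TRUE)[[1]]
    if (any(nchar(parts) == 4)) next  # year-like
    den <- as.numeric(parts[2])
    if (den == 0) next
    x <- paste0(substr(x, 1, s - 1), fmt_dec(as.numeric(parts[1]) / den),
                substr(x, e + 1, nchar(x)))
  }
  x
}

#' Apply a synonym table to sig text
#'
#' Replaces every surface key in `table` with its canonical form.
#' Matching is case-insensitive and word-boundary-safe ("weekly" is never
#' rewritten via the key "wk"); longer keys are tried before shorter ones.
#'
#' @param text character scalar (expected already number-normalized)
#' @param table a [sig_lexicon()] (its synonym map is used)
#' @return the rewritten string
#' @export
#' @examples
#' apply_synonyms("for 2 wk")
apply_synonyms <- function(text, table = default_lexicon()) {
  stopifnot(is.character(text), length(text) == 1)
  if (is.na(text) || !nzchar(text)) return(text)
  syn <- table$synonyms
  x <- text
  for (k in names(syn)) {
    x <- gsub(paste0("\\b", escape_rx(k), "\\b"), syn[[k]], x,
              perl = TRUE, ignore.case = TRUE)
  }
  x
}

#' Remove text irrelevant to daily-dose extraction
#'
#' Drops stop phrases (route phrases such as "by mouth", filler such as
#' "please", "with food") and punctuation noise (commas, semicolons,
#' colons, periods that are not decimal points). Numerals are never
#' removed. Whitespace is collapsed.
#'
#' @param text character scalar
#' @param table a [sig_lexicon()] (its stop-phrase list is used)
#' @return the stripped string
#' @export
#' @examples
#' strip_irrelevant("take 1 tablet by mouth every day")
strip_irrelevant <- function(text, table = default_lexicon()) {
  stopifnot(is.character(text), length(text) == 1)
  if (is.na(text) || !nzchar(text)) return(text)
  x <- text
  for (ph in table$stop_phrases) {
    x <- gsub(paste0("\\b", escape_rx(ph), "\\b"), " ", x,
              perl = TRUE, ignore.case = TRUE)
  }
  x <- gsub("[,;:]", " ", x)
  x <- gsub("(?<![0-9])\\.(?![0-9])", " ", x, perl = TRUE)
  squish(x)
}

#' Normalize a sig into canonical lexical form
#'
#' The deterministic rewrite applied before extraction, in fixed order:
#' lowercase, [words_to_numbers()], [apply_synonyms()],
#' [strip_irrelevant()], whitespace collapse. Synonym keys are written
#' against numeric forms ("2 times"), so number conversion runs first, and
#' stripping runs last so no numeral can be eaten before extraction sees
#' it. The composition is idempotent: `normalize_sig(normalize_sig(x))`
#' equals `normalize_sig(x)`.
#'
#' @param text character scalar
#' @param lexicon a [sig_lexicon()]
#' @return the normalized string
#' @export
#' @examples
#' normalize_sig("Take ONE tab PO qday")
normalize_sig <- function(text, lexicon = default_lexicon()) {
  stopifnot(is.character(text), length(text) == 1)
  if (is.na(text)) return(text)
  x <- tolower(text)
  x <- words_to_numbers(x)
  x <- apply_synonyms(x, lexicon)
  x <- strip_irrelevant(x, lexicon)
  squish(x)
}
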