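#' Build a normalization lexicon
#'
#' A lexicon bundles the two editable tables used by [normalize_sig()]:
#' an ordered synonym map (surface token/phrase to canonical form, e.g.
#' "wk" to "week", "bid" to "2 times daily") and a stop-phrase list of text
#' known to be irrelevant to daily-dose extraction (route phrases, filler).
#' Keys are matched case-insensitively on word boundaries, longer keys
#' before shorter ones.
#'
#' The constructor enforces idempotence: no canonical form may itself
#' contain another key as a whole word, so applying the table twice equals
#' applying it once. Stop phrases may not contain numerals (numerals are
#' never removed by normalization; uncertainty detection depends on that).
#'
#' @param synonyms named character vector: `names()` are surface forms,
#'   values are canonical forms
#' @param stop_phrases character vector of phrases to remove
#' @return an object of class `sig_lexicon`
#' @export
sig_lexicon <- function(synonyms, stop_phrases) {
  stopifnot(is.character(synonyms), !is.null(names(synonyms)),
            is.character(stop_phrases))
  synonyms <- synonyms[order(-nchar(names(synonyms)))]
  keys <- tolower(names(synonyms))
  vals <- tolower(unname(synonyms))
  for (v in vals) {
    hit <- vapply(keys, function(k)
      grepl(paste0("\\b", escape_rx(k), "\\b"), v, perl = TRUE), logical(1))
    if (any(hit))
      stop("synonym table not idempotent: canonical form '", v,
           "' contains key '", keys[which(hit)[1]], "'", call. = FALSE)
  }
  if (any(grepl("[0-9]", stop_phrases)))
    stop("stop phrases must not contain numerals", call. = FALSE)
  structure(list(synonyms = stats::setNames(vals, keys),
                 stop_phrases = tolower(stop_phrases)),
            class = "sig_lexicon")
}

escape_rx <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

.lexicon_cache <- new.env(parent = emptyenv())

#' The default normalization lexicon
#'
#' Loads the synonym and stop-phrase tables shipped with the package
#' (`inst/extdata/synonyms.tsv`, `inst/extdata/stop_phrases.tsv`). These
#' tables are a curated reconstruction of typical sig vocabulary (only the
#' "wk" to "week" mapping is anchored in published material); they are plain
#' TSV files and can be replaced wholesale via [load_lexicon()].
#'
#' @return a `sig_lexicon`
#' @export
default_lexicon <- function() {
  if (!is.null(.lexicon_cache$default)) return(.lexicon_cache$default)
  dir <- system.file("extdata", package = "sigdose")
  lex <- load_lexicon(dir)
  .lexicon_cache$default <- lex
  lex
}

#' Load a lexicon from a directory of TSV files
#'
#' Expects `synonyms.tsv` (two tab-separated columns: surface, canonical)
#' and `stop_phrases.tsv` (one phrase per line) in `dir`. Files are UTF-8,
#' no header.
#'
#' @param dir directory containing the two files
#' @return a `sig_lexicon`
#' @export
load_lexicon <- function(dir) {
  syn_path <- file.path(dir, "synonyms.tsv")
  stop_path <- file.path(dir, "stop_phrases.tsv")
  if (!file.exists(syn_path) || !file.exists(stop_path))
    stop("lexicon directory must contain synonyms.tsv and stop_phrases.tsv",
         call. = FALSE)
  syn <- utils::read.delim(syn_path, header = FALSE, sep = "\t",
                           quote = "", comment.char = "",
                           stringsAsFactors = FALSE, encoding = "UTF-8")
  if (ncol(syn) != 2) stop("synonyms.tsv must have exactly 2 columns", call. = FALSE)
  stops <- readLines(stop_path, encoding = "UTF-8", warn = FALSE)
  stops <- stops[nzchar(trimws(stops))]
  sig_lexicon(stats::setNames(syn[[2]], syn[[1]]), stops)
}
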