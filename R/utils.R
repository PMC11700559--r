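# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Collapse runs of whitespace and trim the ends
#' @param x character vector
#' @return character vector
#' @keywords internal
#' @noRd
squish <- function(x) {
  x <- gsub("[[:space:]]+", " ", x)
  sub("^ ", "", sub(" $", "", x))
}

#' Format a decimal with at most 3 decimal places, no trailing zeros
#'
#' Serialization contract for all dose/duration numbers: values are written
#' as plain decimal strings with at most three decimal places so that a
#' write/read round trip is exact.
#' @param x numeric scalar (may be NA)
#' @return character scalar ("" for NA)
#' @keywords internal
#' @noRd
fmt_dec <- function(x) {
  if (length(x) != 1 || is.na(x)) return("")
  s <- formatC(round(as.numeric(x), 3), format = "f", digits = 3)
  s <- sub("0+$", "", s)
  sub("\\.$", "", s)
}

parse_dec <- function(s) {
  if (is.null(s) || length(s) == 0 || is.na(s) || !nzchar(s)) return(NA_real_)
  as.numeric(s)
}

# Run expr with a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(expr)
}

#' Canonicalize a unit token for comparison
#'
#' Maps common surface variants of dose-form and mass/volume units onto one
#' canonical lowercase token so that unit equality in evaluation is not
#' sensitive to pluralization or capitalization ("Tablets" == "tablet",
#' "mL" == "ml").
#'
#' @param u character scalar or NA
#' @return canonical lowercase token, or NA if `u` is NA/empty
#' @export
canonical_unit <- function(u) {
  if (is.null(u) || length(u) == 0 || is.na(u) || !nzchar(u)) return(NA_character_)
  u <- tolower(trimws(u))
  aliases <- c(
    tabs = "tablet", tab = "tablet", tablets = "tablet",
    caps = "capsule", cap = "capsule", capsules = "capsule",
    pills = "pill", puffs = "puff", drops = "drop", sprays = "spray",
    cc = "ml", milliliter = "ml", milliliters = "ml",
    milligram = "mg", milligrams = "mg",
    microgram = "mcg", micrograms = "mcg", ug = "mcg",
    units = "unit", days = "day", weeks = "week", months = "month"
  )
  if (u %in% names(aliases)) unname(aliases[[u]]) else u
}

# 0-based half-open character ranges: list of c(start, end).
range_covers <- function(ranges, start, end) {
  for (r in ranges) {
    if (start >= r[1] && end <= r[2]) return(TRUE)
  }
  FALSE
}

# Convert a regmatches-style match (1-based start + length) to a 0-based
# half-open range.
match_range <- function(start1, len) c(start1 - 1L, start1 - 1L + len)
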