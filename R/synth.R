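# Seeded generator of gold-annotated synthetic sigs. The gold daily-dose
# arithmetic here is a deliberately separate implementation of the same
# contract as compute_period() (dose x frequency, interval inversion, PRN
# low = 0, 3-dp rounding), so that parser-vs-gold comparisons in tests are
# an oracle check rather than a tautology.

hf_drug_classes <- c("ACE inhibitor", "beta blocker", "ARB", "ARNI",
                     "SGLT-2 inhibitor", "MRA")

#' Configuration for the synthetic sig generator
#'
#' Distributional knobs for [generate_sigs()]. Defaults describe a corpus
#' with the structural variety of real titration-heavy heart-failure
#' prescriptions: mostly single-period sigs with a multi-period (titration)
#' minority chaining up to 5 periods, occasional dose ranges, PRN clauses,
#' parenthetical strengths, duration clauses, sigs with no extractable
#' daily dose, and numeral-bearing hold-condition clauses.
#'
#' @param n_sigs number of sigs to generate
#' @param seed integer RNG seed (generation is deterministic given the
#'   seed and config)
#' @param max_periods maximum periods per sig (1..5)
#' @param p_multi_period probability a sig is a multi-period titration
#' @param p_range_dose probability a period's dose is a range ("1-2 tablet")
#' @param p_prn probability a single-period sig is as-needed
#' @param p_strength_paren probability of a parenthetical strength
#' @param p_duration probability a single-period sig carries a duration
#' @param p_no_dose probability the sig has no extractable daily dose
#' @param p_hold_condition probability a numeral-bearing hold clause is
#'   appended (such records are flagged `expect_uncertain`)
#' @param noise_level probability in \[0,1\] that each lexical noise
#'   operator (abbreviations, number words, fillers, case) fires
#' @param drug_classes label set for the drug_class group attribute
#' @return object of class `synth_config`
#' @export
synth_config <- function(n_sigs = 100, seed = 1, max_periods = 5,
                         p_multi_period = 0.3, p_range_dose = 0.15,
                         p_prn = 0.1, p_strength_paren = 0.25,
                         p_duration = 0.2, p_no_dose = 0.1,
                         p_hold_condition = 0.05, noise_level = 0.5,
                         drug_classes = hf_drug_classes) {
  probs <- c(p_multi_period, p_range_dose, p_prn, p_strength_paren,
             p_duration, p_no_dose, p_hold_condition, noise_level)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must be in [0, 1]", call. = FALSE)
  if (max_periods < 1 || max_periods > 5)
    stop("max_periods must be between 1 and 5", call. = FALSE)
  if (n_sigs < 0) stop("n_sigs must be non-negative", call. = FALSE)
  structure(list(n_sigs = as.integer(n_sigs), seed = as.integer(seed),
                 max_periods = as.integer(max_periods),
                 p_multi_period = p_multi_period, p_range_dose = p_range_dose,
                 p_prn = p_prn, p_strength_paren = p_strength_paren,
                 p_duration = p_duration, p_no_dose = p_no_dose,
                 p_hold_condition = p_hold_condition,
                 noise_level = noise_level,
                 drug_classes = as.character(drug_classes)),
            class = "synth_config")
}

# Schedule menu. Frequency entries carry administrations/day directly;
# interval entries carry the q-notation bounds in hours and derive the
# frequency by inversion inside the gold oracle.
freq_menu <- list(
  list(phrase = "every day", f_low = 1, f_high = 1),
  list(phrase = "2 times daily", f_low = 2, f_high = 2),
  list(phrase = "3 times daily", f_low = 3, f_high = 3),
  list(phrase = "2 to 3 times daily", f_low = 2, f_high = 3),
  list(phrase = "every other day", f_low = 0.5, f_high = 0.5),
  list(phrase = "every morning", f_low = 1, f_high = 1),
  list(phrase = "nightly", f_low = 1, f_high = 1),
  list(phrase = "weekly", f_low = 1 / 7, f_high = 1 / 7)
)
interval_menu <- list(
  list(phrase = "q12hr", n_low = 12, n_high = 12),
  list(phrase = "q8hr", n_low = 8, n_high = 8),
  list(phrase = "q6h", n_low = 6, n_high = 6),
  list(phrase = "q4-6hr", n_low = 4, n_high = 6)
)

no_dose_texts <- c("use as directed",
                   "take as directed by prescriber",
                   "apply as directed",
                   "use per written instructions",
                   "take per sliding scale instructions")

hold_clauses <- c("hold if sbp less than 90",
                  "hold if heart rate below 55",
                  "hold if potassium above 5")

# Independent gold arithmetic (the oracle side of the shared contract).
oracle_period <- function(tpl) {
  if (is.null(tpl$interval)) {
    f_low <- tpl$f_low; f_high <- tpl$f_high
  } else {
    f_low <- 24 / tpl$interval$n_high
    f_high <- 24 / tpl$interval$n_low
  }
  d_low <- round(tpl$dose_low * f_low, 3)
  d_high <- round(tpl$dose_high * f_high, 3)
  if (tpl$prn) d_low <- 0
  alt <- list(low = NA_real_, high = NA_real_, unit = NA_character_)
  if (!is.na(tpl$strength)) {
    alt$low <- round(tpl$strength * f_low, 3)
    alt$high <- round(tpl$strength * f_high, 3)
    if (tpl$prn) alt$low <- 0
    alt$unit <- "mg"
  }
  period_object(
    daily_dose_low = d_low, daily_dose_high = d_high,
    daily_dose_units = tpl$unit,
    alt_daily_dose_low = alt$low, alt_daily_dose_high = alt$high,
    alt_daily_dose_units = alt$unit,
    duration_low = if (is.null(tpl$duration)) NA_real_ else tpl$duration$n,
    duration_high = if (is.null(tpl$duration)) NA_real_ else tpl$duration$n,
    duration_units = if (is.null(tpl$duration)) NA_character_ else tpl$duration$unit,
    optional_period = tpl$prn,
    hold_condition = tpl$hold %||% ""
  )
}

period_text <- function(tpl) {
  sched <- if (is.null(tpl$interval)) tpl$phrase else tpl$interval$phrase
  dose_txt <- if (tpl$dose_low == tpl$dose_high) fmt_dec(tpl$dose_low) else
    paste0(fmt_dec(tpl$dose_low), "-", fmt_dec(tpl$dose_high))
  parts <- c(paste(dose_txt, tpl$unit),
             if (!is.na(tpl$strength)) paste0("(", fmt_dec(tpl$strength), " mg)"),
             sched,
             if (tpl$prn) "prn",
             if (!is.null(tpl$duration))
               paste("for", fmt_dec(tpl$duration$n), tpl$duration$unit))
  paste(parts, collapse = " ")
}

sample1 <- function(x) x[[sample.int(length(x), 1)]]

make_period_tpl <- function(cfg, dose_level, allow_prn, need_duration) {
  dose_menu <- c(0.5, 1, 1.5, 2, 3)
  dose_low <- dose_menu[min(dose_level, length(dose_menu))]
  ranged <- stats::runif(1) < cfg$p_range_dose
  dose_high <- if (ranged) dose_low + sample(c(0.5, 1), 1) else dose_low
  unit <- sample(c("tablet", "capsule", "pill"), 1,
                 prob = c(0.7, 0.2, 0.1))
  use_interval <- stats::runif(1) < 0.25
  iv <- NULL; phrase <- NULL; f_low <- NA; f_high <- NA
  if (use_interval) {
    iv <- sample1(interval_menu)
  } else {
    fr <- sample1(freq_menu)
    phrase <- fr$phrase; f_low <- fr$f_low; f_high <- fr$f_high
  }
  strength <- NA_real_
  if (!ranged && unit == "tablet" && stats::runif(1) < cfg$p_strength_paren)
    strength <- sample(c(12.5, 25, 50, 100), 1)
  prn <- allow_prn && stats::runif(1) < cfg$p_prn
  duration <- NULL
  if (need_duration || (allow_prn && stats::runif(1) < cfg$p_duration))
    duration <- list(n = sample(c(1, 2, 4), 1),
                     unit = sample(c("day", "week", "month"), 1,
                                   prob = c(0.3, 0.6, 0.1)))
  list(dose_low = dose_low, dose_high = dose_high, unit = unit,
       interval = iv, phrase = phrase, f_low = f_low, f_high = f_high,
       strength = strength, prn = prn, duration = duration, hold = NULL)
}

# Lexical noise operators. Each is the inverse image of a normalizer rule,
# so normalization maps the noisy text back to the canonical rendering and
# the parser's closure against gold is preserved.
apply_noise <- function(text, level) {
  applied <- character(0)
  fire <- function() stats::runif(1) < level
  x <- text
  if (fire() && grepl("\\b0\\.5\\b", x)) {
    x <- gsub("\\b0\\.5\\b", "1/2", x)
    applied <- c(applied, "half_fraction")
  }
  if (fire()) {
    words <- c("one", "two", "three", "four", "five", "six", "seven",
               "eight", "nine", "ten")
    m <- gregexpr("(?<![0-9./-])\\b([1-9]|10)\\b(?![0-9./-])", x, perl = TRUE)[[1]]
    if (m[1] != -1) {
      for (i in rev(seq_along(m))) {
        s <- m[i]; e <- s + attr(m, "match.length")[i] - 1
        x <- paste0(substr(x, 1, s - 1),
                    words[as.integer(substr(x, s, e))],
                    substr(x, e + 1, nchar(x)))
      }
      applied <- c(applied, "number_words")
    }
  }
  subs <- list(
    c("\\btablet\\b", "tab"), c("\\btablet\\b", "tabs"),
    c("\\bcapsule\\b", "cap"), c("\\bweek\\b", "wk"),
    c("\\b2 times daily\\b", "bid"), c("\\b2 times daily\\b", "twice daily"),
    c("(?<!to )\\b3 times daily\\b", "tid"),
    c("\\bevery day\\b", "daily"), c("\\bevery day\\b", "qday"),
    c("\\bevery day\\b", "once daily"),
    c("\\bnightly\\b", "at bedtime"), c("\\bevery morning\\b", "qam"),
    c("\\bevery other day\\b", "qod"), c("\\bprn\\b", "as needed")
  )
  for (s in subs) {
    if (grepl(s[1], x, perl = TRUE) && fire()) {
      x <- gsub(s[1], s[2], x, perl = TRUE)
      applied <- c(applied, paste0("abbrev:", s[2]))
    }
  }
  if (fire()) {
    x <- sub("^", "please take ", sub("^take ", "", x))
    applied <- c(applied, "filler_please")
  }
  if (fire()) {
    x <- paste(x, sample(c("by mouth", "with food", "po"), 1))
    applied <- c(applied, "filler_tail")
  }
  if (fire()) {
    x <- toupper(x)
    applied <- c(applied, "uppercase")
  }
  list(text = x, applied = applied)
}

#' Generate gold-annotated synthetic sigs
#'
#' Draws `config$n_sigs` sigs: no-dose sigs (gold is the empty list, text
#' contains no numerals), single-period sigs and multi-period titrations
#' joined by "then"/"increase to" with escalating doses, with optional
#' dose ranges, q-notation intervals, parenthetical strengths, PRN and
#' duration clauses. Lexical noise (abbreviations, number words, route and
#' filler phrases, case) is applied at `noise_level`; every noise operator
#' is invertible by the normalizer. Records with an appended
#' numeral-bearing hold clause keep their full gold annotation but are
#' flagged `expect_uncertain = TRUE`: the parser is expected to refuse
#' them rather than guess.
#'
#' Generation is deterministic given `(seed, config)` and does not disturb
#' the caller's RNG state.
#'
#' @param config a [synth_config()]
#' @return list of `synth_record` objects: each has `record` (a
#'   [sig_record()] with gold always present), `template_id`,
#'   `noise_applied` (character vector) and `expect_uncertain` (logical)
#' @export
generate_sigs <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, {
    out <- vector("list", config$n_sigs)
    for (i in seq_len(config$n_sigs)) {
      sig_id <- sprintf("syn%05d", i)
      groups <- list(drug_class = sample(config$drug_classes, 1),
                     sex = sample(c("F", "M"), 1))
      if (stats::runif(1) < config$p_no_dose) {
        txt <- sample(no_dose_texts, 1)
        groups$expect_uncertain <- "no"
        out[[i]] <- structure(list(
          record = sig_record(sig_id, txt, groups = groups, gold = list()),
          template_id = "no_dose", noise_applied = character(0),
          expect_uncertain = FALSE, is_multi = FALSE, has_prn = FALSE,
          is_no_dose = TRUE), class = "synth_record")
        next
      }
      multi <- config$max_periods > 1 &&
        stats::runif(1) < config$p_multi_period
      n_p <- if (multi) sample(2:config$max_periods, 1) else 1L
      base_level <- sample.int(3, 1)
      tpls <- vector("list", n_p)
      for (k in seq_len(n_p)) {
        tpls[[k]] <- make_period_tpl(
          config, dose_level = base_level + (k - 1L),
          allow_prn = n_p == 1L, need_duration = k < n_p)
      }
      # one drug, one form and one schedule style across a titration
      if (n_p > 1) {
        for (k in 2:n_p) {
          tpls[[k]]$unit <- tpls[[1]]$unit
          tpls[[k]]$strength <- NA_real_
        }
        tpls[[1]]$strength <- NA_real_
      }
      hold <- stats::runif(1) < config$p_hold_condition
      if (hold) tpls[[n_p]]$hold <- sample(hold_clauses, 1)
      segs <- vapply(tpls, period_text, character(1))
      joiners <- if (n_p > 1)
        sample(c("then", "increase to"), n_p - 1, replace = TRUE) else character(0)
      txt <- paste0("take ", segs[1])
      if (n_p > 1) {
        for (k in 2:n_p) txt <- paste(txt, joiners[k - 1], segs[k])
      }
      if (hold) txt <- paste(txt, tpls[[n_p]]$hold)
      noise <- apply_noise(txt, config$noise_level)
      gold <- lapply(tpls, oracle_period)
      groups$expect_uncertain <- if (hold) "yes" else "no"
      out[[i]] <- structure(list(
        record = sig_record(sig_id, noise$text, groups = groups, gold = gold),
        template_id = if (n_p > 1) sprintf("titration_%d", n_p) else "single",
        noise_applied = noise$applied,
        expect_uncertain = hold, is_multi = n_p > 1,
        has_prn = any(vapply(tpls, `[[`, logical(1), "prn")),
        is_no_dose = FALSE), class = "synth_record")
    }
    out
  })
}

#' Extract the plain sig records from a synthetic corpus
#' @param srecords list of `synth_record`s from [generate_sigs()]
#' @return list of [sig_record()]s
#' @export
as_sig_records <- function(srecords) lapply(srecords, `[[`, "record")

#' Summary statistics of a synthetic corpus
#'
#' Realized proportions for comparison against the generating config.
#'
#' @param srecords non-empty list of `synth_record`s
#' @return list with `n`, `p_multi_period`, `p_prn`, `p_no_dose`,
#'   `p_expect_uncertain` and `unique_text_ratio`
#' @export
corpus_stats <- function(srecords) {
  if (length(srecords) == 0) stop("empty corpus", call. = FALSE)
  texts <- vapply(srecords, function(s) s$record$text, character(1))
  list(
    n = length(srecords),
    p_multi_period = mean(vapply(srecords, `[[`, logical(1), "is_multi")),
    p_prn = mean(vapply(srecords, `[[`, logical(1), "has_prn")),
    p_no_dose = mean(vapply(srecords, `[[`, logical(1), "is_no_dose")),
    p_expect_uncertain = mean(vapply(srecords, `[[`, logical(1),
                                     "expect_uncertain")),
    unique_text_ratio = length(unique(texts)) / length(texts)
  )
}
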