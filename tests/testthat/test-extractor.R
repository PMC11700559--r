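test_that("interval pattern handles q-notation singles, ranges and suffixes", {
  iv <- extract_interval("q4hr")
  expect_equal(iv[c("low", "high", "unit")],
               list(low = 4, high = 4, unit = "hours"))
  expect_false(iv$prn)
  iv <- extract_interval("q2-3hr")
  expect_equal(iv[c("low", "high", "unit")],
               list(low = 2, high = 3, unit = "hours"))
  iv <- extract_interval("q6h prn")
  expect_equal(iv[c("low", "high", "unit", "prn")],
               list(low = 6, high = 6, unit = "hours", prn = TRUE))
  # bare qN defaults to hours; day/week/month literal
  expect_equal(extract_interval("take 1 tablet q8")[c("low", "unit")],
               list(low = 8, unit = "hours"))
  expect_equal(extract_interval("q1week")$unit, "week")
  # never fires inside a word
  expect_null(extract_interval("liquid 4 ml daily"))
  expect_null(extract_interval("no interval here"))
})

test_that("frequency phrases map to administrations per day", {
  expect_equal(extract_frequency("take 1 tablet 2 times daily")[c("low", "high")],
               list(low = 2, high = 2))
  expect_equal(extract_frequency("1 tablet every other day")[c("low", "high")],
               list(low = 0.5, high = 0.5))
  expect_equal(extract_frequency("2 to 3 times daily")[c("low", "high")],
               list(low = 2, high = 3))
  expect_equal(extract_frequency("1 tablet weekly")$low, 1 / 7)
  expect_equal(extract_frequency("1 tablet nightly")$low, 1)
  expect_null(extract_frequency("no frequency words here"))
})

test_that("dose extraction captures ranges and parenthetical strength", {
  d <- extract_dose("take 0.5 tablet (50 mg) every day")
  expect_equal(d[c("dose_low", "dose_high", "dose_unit")],
               list(dose_low = 0.5, dose_high = 0.5, dose_unit = "tablet"))
  expect_equal(d[c("strength_low", "strength_high", "strength_unit")],
               list(strength_low = 50, strength_high = 50,
                    strength_unit = "mg"))
  d <- extract_dose("take 1-2 tablet")
  expect_equal(d[c("dose_low", "dose_high")], list(dose_low = 1, dose_high = 2))
  expect_true(is.na(d$strength_low))
  expect_null(extract_dose("use as directed"))
  # inline strength with no form word: dose lands in strength units
  d <- extract_dose("take 50 mg every day")
  expect_equal(d[c("dose_low", "dose_unit")], list(dose_low = 50,
                                                   dose_unit = "mg"))
})

test_that("duration clauses parse with day/week/month units", {
  expect_equal(extract_duration("take 1 tablet daily for 1 week")[c("low", "high", "unit")],
               list(low = 1, high = 1, unit = "week"))
  expect_equal(extract_duration("for 7 to 10 day")[c("low", "high", "unit")],
               list(low = 7, high = 10, unit = "day"))
  expect_equal(extract_duration("x 5 day")[c("low", "unit")],
               list(low = 5, unit = "day"))
  expect_null(extract_duration("take 1 tablet daily"))
})

test_that("split_periods cuts on titration keywords", {
  sp <- split_periods("take 1 tablet daily for 1 week then 2 tablet daily")
  expect_length(sp, 2)
  expect_equal(sp[[1]]$text, "take 1 tablet daily for 1 week")
  expect_equal(sp[[2]]$text, "2 tablet daily")
  expect_equal(sp[[2]]$joiner, "then")
  expect_length(split_periods("take 1 tablet daily"), 1)
  sp <- split_periods("1 tablet daily increase to 2 tablet daily after titration")
  expect_length(sp, 2)
  expect_equal(sp[[2]]$text, "2 tablet daily after titration")
  # span offsets index into the normalized string
  txt <- "take 1 tablet daily then 2 tablet daily"
  for (s in split_periods(txt))
    expect_equal(substr(txt, s$start + 1, s$start + nchar(s$text)), s$text)
})

test_that("compute_period applies the daily-dose arithmetic contract", {
  clauses <- function(dose = NULL, freq = NULL, interval = NULL,
                      duration = NULL, prn = FALSE)
    list(dose = dose, freq = freq, interval = interval,
         duration = duration, prn = prn, spans = list())
  dose1 <- list(dose_low = 1, dose_high = 1, dose_unit = "tablet",
                strength_low = NA_real_, strength_high = NA_real_,
                strength_unit = NA_character_)
  # 1 tablet twice daily -> 2 per day
  p <- compute_period(clauses(dose1, freq = list(low = 2, high = 2)))
  expect_equal(c(p$daily_dose_low, p$daily_dose_high), c(2, 2))
  # strength rides the same frequency
  dose_s <- utils::modifyList(dose1, list(dose_low = 0.5, dose_high = 0.5,
                                          strength_low = 50,
                                          strength_high = 50,
                                          strength_unit = "mg"))
  p <- compute_period(clauses(dose_s, freq = list(low = 1, high = 1)))
  expect_equal(c(p$daily_dose_low, p$daily_dose_high), c(0.5, 0.5))
  expect_equal(c(p$alt_daily_dose_low, p$alt_daily_dose_high), c(50, 50))
  # interval inversion: dose 1-2, q2-3hr -> f (8, 12) -> daily 8-24
  dose_r <- utils::modifyList(dose1, list(dose_low = 1, dose_high = 2))
  p <- compute_period(clauses(dose_r,
                              interval = list(low = 2, high = 3,
                                              unit = "hours", prn = FALSE)))
  expect_equal(c(p$daily_dose_low, p$daily_dose_high), c(8, 24))
  # PRN floors the lows at zero
  p <- compute_period(clauses(dose_s, freq = list(low = 1, high = 1),
                              prn = TRUE))
  expect_equal(p$daily_dose_low, 0)
  expect_equal(p$alt_daily_dose_low, 0)
  expect_equal(p$alt_daily_dose_high, 50)
  # no dose, or no schedule, means no period (no once-daily default)
  expect_null(compute_period(clauses(NULL, freq = list(low = 1, high = 1))))
  expect_null(compute_period(clauses(dose1)))
  # degenerate interval is an error
  expect_error(compute_period(clauses(dose1,
    interval = list(low = 0, high = 0, unit = "hours", prn = FALSE))),
    "positive")
})

test_that("interval inversion always keeps f_low <= f_high", {
  set.seed(11)
  for (i in 1:200) {
    a <- sample(1:24, 1)
    b <- a + sample(0:24, 1)
    iv <- extract_interval(sprintf("q%d-%dhr", a, b))
    f_low <- 24 / iv$high
    f_high <- 24 / iv$low
    expect_lte(f_low, f_high)
  }
})

test_that("uncertainty flags leftover non-date numerals", {
  r <- parse_sig("take 1 tablet daily hold if sbp less than 90")
  expect_equal(r$status, "uncertain")
  expect_equal(r$residual_tokens, "90")
  expect_length(r$periods, 0)
  # dates are exempt
  expect_equal(parse_sig("take 1 tablet daily starting 01/02/2024")$status,
               "parsed")
  expect_equal(parse_sig("take 1 tablet daily until january 5")$status,
               "parsed")
  expect_equal(parse_sig("take 1 tablet daily through 2025")$status,
               "parsed")
  # a large leftover amount is not a date
  expect_equal(parse_sig("take 1 tablet daily max 90 mg")$status,
               "uncertain")
})

test_that("parse_sig composes the full pipeline", {
  r <- parse_sig("take one tablet twice daily")
  expect_equal(r$status, "parsed")
  expect_length(r$periods, 1)
  expect_equal(c(r$periods[[1]]$daily_dose_low,
                 r$periods[[1]]$daily_dose_high), c(2, 2))
  expect_equal(r$periods[[1]]$daily_dose_units, "tablet")

  r <- parse_sig("take 1/2 tablet (50 mg) by mouth every day")
  expect_equal(r$status, "parsed")
  expect_equal(r$periods[[1]]$alt_daily_dose_low, 50)
  expect_equal(r$periods[[1]]$alt_daily_dose_high, 50)
  expect_equal(r$periods[[1]]$alt_daily_dose_units, "mg")
  expect_equal(r$periods[[1]]$daily_dose_low, 0.5)

  expect_equal(parse_sig("use as directed")$status, "no_dose")
  expect_error(parse_sig(sig_record("e", "x", gold = NULL) |>
                           (\(r) {r$text <- " "; r})()), "empty")

  # titration keeps period order and per-period durations
  r <- parse_sig("take 1 tablet daily for 1 week then 2 tablets daily")
  expect_equal(length(r$periods), 2)
  expect_equal(r$periods[[1]]$duration_units, "week")
  expect_true(is.na(r$periods[[2]]$duration_low))
})

test_that("appending a numeral-bearing hold clause flips to uncertain", {
  base <- c("take 1 tablet daily",
            "take 2 tablets 2 times daily for 1 week then 3 tablets daily",
            "1 cap q12hr")
  for (tx in base) {
    r0 <- parse_sig(tx)
    expect_equal(r0$status, "parsed", label = tx)
    r1 <- parse_sig(paste(tx, "hold if sbp less than 90"))
    expect_equal(r1$status, "uncertain", label = tx)
    expect_true("90" %in% r1$residual_tokens)
    expect_length(r1$periods, 0)
  }
})

test_that("parsed periods always satisfy low <= high on all pairs", {
  corpus <- generate_sigs(synth_config(n_sigs = 150, seed = 23,
                                       noise_level = 0.8))
  for (res in parse_sigs(as_sig_records(corpus))) {
    for (p in res$periods) {
      expect_lte(p$daily_dose_low, p$daily_dose_high)
      if (!is.na(p$alt_daily_dose_low))
        expect_lte(p$alt_daily_dose_low, p$alt_daily_dose_high)
      if (!is.na(p$duration_low))
        expect_lte(p$duration_low, p$duration_high)
    }
  }
})

test_that("parsing is deterministic", {
  txt <- "take 1-2 tablets (25 mg) q4-6hr prn for 7 to 10 days"
  expect_identical(parse_sig(txt), parse_sig(txt))
})
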