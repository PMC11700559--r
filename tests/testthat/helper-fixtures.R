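# Shared fixture builders and independent oracles.

# Quick period builders
p_daily <- function(low, high = low, units = "tablet", ...) {
  period_object(daily_dose_low = low, daily_dose_high = high,
                daily_dose_units = units, ...)
}

# Independent brute-force metrics from per-sig cells (plain arithmetic,
# no package calls) used to cross-check compute_metrics and the
# permutation statistic.
brute_metrics <- function(cells) {
  tp <- sum(cells == "TP"); fp <- sum(cells == "FP")
  fn <- sum(cells == "FN")
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (is.na(ppv) || is.na(sens) || ppv + sens == 0) NA_real_ else
    2 * ppv * sens / (ppv + sens)
  list(ppv = ppv, sensitivity = sens, f1 = f1)
}

brute_f1_or0 <- function(cells) {
  f <- brute_metrics(cells)$f1
  if (is.na(f)) 0 else f
}

# Exact paired sign-flip distribution: enumerate all 2^n swap masks and
# return the exact two-sided tail probability of |stat*| >= |observed|.
exact_perm_p <- function(cells_a, cells_b) {
  n <- length(cells_a)
  stopifnot(n <= 12)
  obs <- brute_f1_or0(cells_a) - brute_f1_or0(cells_b)
  hits <- 0L
  for (mask in 0:(2^n - 1)) {
    swap <- bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L
    a <- ifelse(swap, cells_b, cells_a)
    b <- ifelse(swap, cells_a, cells_b)
    stat <- brute_f1_or0(a) - brute_f1_or0(b)
    if (abs(stat) >= abs(obs) - 1e-12) hits <- hits + 1L
  }
  hits / 2^n
}

# A small pool of realistic raw sig strings for normalizer properties.
raw_sig_pool <- function() {
  c("Take ONE tab PO qday",
    "take 1/2 tablet (50 mg) by mouth every day",
    "2 tabs bid with food",
    "take one and a half tablets twice daily",
    "1 cap q12hr prn",
    "take 1-2 pills every other day please",
    "use as directed",
    "take 2 tablets daily for 2 wks then 3 tablets daily",
    "half tablet nightly at bedtime",
    "TAKE 1 TABLET EVERY MORNING WITH WATER",
    "1 tablet daily, increase to 2 tablets daily",
    "take 1 tablet daily starting 01/02/2024",
    "take 1 tablet q4-6hr as needed",
    "take 1 tablet daily hold if sbp less than 90")
}
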