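test_that("match_periods compares the daily-dosage variables exactly", {
  a <- list(p_daily(2))
  expect_true(match_periods(a, list(p_daily(2))))
  expect_false(match_periods(a, list(p_daily(2, units = "capsule"))))
  expect_false(match_periods(list(p_daily(2), p_daily(3)), a))
  # unit canonicalization: tab == tablet, mL == ml
  expect_true(match_periods(list(p_daily(2, units = "tab")),
                            list(p_daily(2, units = "tablet"))))
  expect_true(match_periods(list(p_daily(5, units = "mL")),
                            list(p_daily(5, units = "ml"))))
  # conditions and optional flag are ignored
  expect_true(match_periods(
    list(p_daily(2, hold_condition = "hold if sbp < 90",
                 optional_period = TRUE)),
    list(p_daily(2))))
  # alt and duration fields do count
  expect_false(match_periods(list(period_object(2, 2, "tablet", 50, 50, "mg")),
                             list(p_daily(2))))
  expect_false(match_periods(
    list(period_object(2, 2, "tablet", duration_low = 1, duration_high = 1,
                       duration_units = "week")),
    list(period_object(2, 2, "tablet", duration_low = 2, duration_high = 2,
                       duration_units = "week"))))
})

test_that("classify_sig implements the confusion semantics", {
  parsed2 <- parse_result("s", "parsed", periods = list(p_daily(2)))
  nodose <- parse_result("s", "no_dose")
  uncertain <- parse_result("s", "uncertain", residual_tokens = "90")
  expect_equal(classify_sig(parsed2, list(p_daily(2))), "TP")
  expect_equal(classify_sig(parsed2, list(p_daily(3))), "FP")
  expect_equal(classify_sig(parsed2, list()), "FP")
  expect_equal(classify_sig(nodose, list()), "TN")
  expect_equal(classify_sig(nodose, list(p_daily(2))), "FN")
  # uncertain counts as unparsed
  expect_equal(classify_sig(uncertain, list(p_daily(2))), "FN")
  expect_equal(classify_sig(uncertain, list()), "TN")
  expect_error(classify_sig(parsed2, NULL), "unannotated")
})

test_that("compute_metrics matches direct formulas and keeps NA semantics", {
  m <- compute_metrics(c(tp = 2, fp = 1, tn = 0, fn = 1))
  expect_equal(m$ppv, 2 / 3)
  expect_equal(m$sensitivity, 2 / 3)
  expect_equal(m$f1, 2 / 3)
  m <- compute_metrics(c(tp = 0, fp = 0, tn = 5, fn = 2))
  expect_true(is.na(m$ppv))
  expect_equal(m$sensitivity, 0)
  expect_true(is.na(m$f1))
  m <- compute_metrics(c(tp = 0, fp = 0, tn = 5, fn = 0))
  expect_true(is.na(m$ppv) && is.na(m$sensitivity) && is.na(m$f1))
})

test_that("compute_metrics agrees with a brute-force recount", {
  set.seed(99)
  for (i in 1:25) {
    cells <- sample(c("TP", "FP", "TN", "FN"), 40, replace = TRUE)
    m <- compute_metrics(confusion_counts(cells))
    b <- brute_metrics(cells)
    expect_equal(m$ppv, b$ppv)
    expect_equal(m$sensitivity, b$sensitivity)
    expect_equal(m$f1, b$f1)
  }
})

test_that("published benchmark rows are consistent with the F1 formula", {
  # the two strongest parsers reproduce exactly at 2 dp
  expect_equal(round(f1_score(0.96, 1.00), 2), 0.98)
  expect_equal(round(f1_score(0.99, 0.92), 2), 0.95)
  # the remaining rows were published with F1 computed from unrounded
  # inputs; from 2-dp inputs they agree within the +-0.01 propagation
  # bound of +-0.005 input rounding
  rows <- list(c(0.56, 0.99, 0.71),  # BiLSTM
               c(0.84, 0.93, 0.88),  # Parsigs
               c(0.65, 1.00, 0.78))  # Sig2db
  for (r in rows)
    expect_lt(abs(f1_score(r[1], r[2]) - r[3]), 0.011)
})

test_that("subgroup metrics partition the evaluated sigs", {
  # 6-sig fixture split 3/3 with known cells:
  # group x: TP TP FN  -> ppv 1, sens 2/3
  # group y: TP FP TN  -> ppv 1/2, sens 1
  mk <- function(id, status, grp) {
    rec <- sig_record(id, "take 1 tablet daily",
                      groups = list(g = grp),
                      gold = if (status == "TN") list() else list(p_daily(1)))
    res <- switch(status,
      TP = parse_result(id, "parsed", periods = list(p_daily(1))),
      FP = parse_result(id, "parsed", periods = list(p_daily(9))),
      FN = parse_result(id, "no_dose"),
      TN = parse_result(id, "no_dose"))
    list(rec = rec, res = res)
  }
  fix <- list(mk("a", "TP", "x"), mk("b", "TP", "x"), mk("c", "FN", "x"),
              mk("d", "TP", "y"), mk("e", "FP", "y"), mk("f", "TN", "y"))
  results <- lapply(fix, `[[`, "res")
  records <- lapply(fix, `[[`, "rec")
  by_g <- subgroup_metrics(results, records, "g")
  expect_equal(by_g$x$ppv, 1)
  expect_equal(by_g$x$sensitivity, 2 / 3)
  expect_equal(by_g$y$ppv, 1 / 2)
  expect_equal(by_g$y$sensitivity, 1)
  # single group equals the global metrics
  recs1 <- lapply(records, function(r) {
    r$groups$g <- "all"; r
  })
  global <- evaluate_results(results, records)
  one <- subgroup_metrics(results, recs1, "g")$all
  expect_equal(one$ppv, global$metrics$ppv)
  expect_equal(one$f1, global$metrics$f1)
  expect_error(subgroup_metrics(results, records, "nope"), "group label")
  # partition: cells sum to n
  expect_equal(sum(global$metrics$counts), length(results))
})

test_that("evaluation cells partition generated corpora", {
  corpus <- generate_sigs(synth_config(n_sigs = 200, seed = 5,
                                       p_hold_condition = 0.15))
  recs <- as_sig_records(corpus)
  ev <- evaluate_results(parse_sigs(recs), recs)
  expect_equal(sum(ev$metrics$counts), 200)
  expect_true(all(ev$cells %in% c("TP", "FP", "TN", "FN")))
})

test_that("permutation test: ties, symmetry, and a clear separation", {
  a <- rep("TP", 30)
  expect_equal(permutation_test(a, a, n_perm = 500, seed = 1)$p_value, 1.0)
  # relabeling a<->b negates the statistic, p unchanged
  b <- c(rep("TP", 12), rep("FP", 10), rep("FN", 8))
  p_ab <- permutation_test(a, b, n_perm = 2000, seed = 3)
  p_ba <- permutation_test(b, a, n_perm = 2000, seed = 3)
  expect_equal(p_ab$statistic, -p_ba$statistic)
  expect_equal(p_ab$p_value, p_ba$p_value)
  # all-correct vs all-wrong on 50 sigs is decisively significant
  p <- permutation_test(rep("TP", 50), rep("FP", 50),
                        n_perm = 9999, seed = 7)
  expect_lte(p$p_value, 0.001)
  expect_error(permutation_test(a, b[1:5], seed = 1), "equal length")
  expect_error(permutation_test(a, a, n_perm = 10), "seed")
})

test_that("permutation p-values agree with exact enumeration at small n", {
  cases <- list(
    list(a = c("TP", "TP", "FP", "TN", "FN", "TP", "FP", "TP"),
         b = c("FP", "TP", "TP", "TN", "TP", "FN", "FP", "TN")),
    list(a = rep("TP", 8), b = c(rep("TP", 4), rep("FP", 4))),
    list(a = c("TP", "FN", "TP", "FN", "TP", "FN"),
         b = c("FP", "TP", "FP", "TP", "FP", "TP"))
  )
  for (cs in cases) {
    exact <- exact_perm_p(cs$a, cs$b)
    mc <- permutation_test(cs$a, cs$b, n_perm = 4000, seed = 17)$p_value
    expect_lt(abs(mc - exact), 0.04)
    expect_gt(mc, 0)
    expect_lte(mc, 1)
  }
})
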