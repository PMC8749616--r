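test_that("thresholds move against the trend so sensitivity grows with k", {
  expect_equal(unname(compute_thresholds(5, 1, "In")$thresholds), c(5, 4, 3))
  expect_equal(unname(compute_thresholds(5, 1, "De")$thresholds), c(5, 6, 7))
  expect_equal(unname(compute_thresholds(5, 0, "In")$thresholds), c(5, 5, 5))
  expect_error(compute_thresholds(5, -1, "In"), "non-negative")
  # the literal shifted-with-the-trend reading stays available
  expect_equal(unname(compute_thresholds(5, 1, "In", literal = TRUE)$thresholds),
               c(5, 6, 7))
})

test_that("annotation is strict with ties counted as non-pregnant", {
  expect_equal(annotate_pregnancy(4.5, 5, "In"), 0L)
  expect_equal(annotate_pregnancy(4.5, 4, "In"), 1L)
  expect_equal(annotate_pregnancy(5, 5, "In"), 0L)
  expect_equal(annotate_pregnancy(5, 5, "De"), 0L)
  expect_equal(annotate_pregnancy(4.5, 5, "De"), 1L)
  expect_equal(annotate_pregnancy(c(1, 5, 9), 5, "In"), c(0L, 0L, 1L))
  expect_error(annotate_pregnancy(Inf, 5, "In"), "finite")
})

test_that("accuracy metrics reproduce reference confusion tables", {
  m <- accuracy_metrics(tp = 2, fp = 0, tn = 13, fn = 12)
  expect_equal(unname(m), c(0.14, 1.00, 1.00, 0.52))
  # degenerate classifier calling everything positive: 0/0 NPV is 1.00
  m2 <- accuracy_metrics(tp = 14, fp = 13, tn = 0, fn = 0)
  expect_equal(unname(m2), c(1.00, 0.00, 0.52, 1.00))
  m3 <- accuracy_metrics(tp = 9, fp = 0, tn = 9, fn = 0)
  expect_equal(unname(m3), c(1, 1, 1, 1))
  expect_error(accuracy_metrics(0, 1, 1, 0), "positive")
  expect_error(accuracy_metrics(1, 0, 0, 1), "negative")
  expect_error(accuracy_metrics(1.5, 0, 3, 2), "integers")
})

test_that("two-decimal rates invert to unique counts", {
  expect_equal(counts_from_rounded_rates(0.43, 14), 6)
  expect_equal(counts_from_rounded_rates(1.00, 13), 13)
  expect_equal(counts_from_rounded_rates(0.33, 3), 1)
  expect_error(counts_from_rounded_rates(0.92, 14), "no count")
  expect_error(counts_from_rounded_rates(0.5, 1000), "ambiguous")
})

test_that("round trip: metrics of any 14/13 confusion table invert exactly", {
  for (tp in 0:14) {
    for (tn in 0:13) {
      if (tp + (13 - tn) == 0 || tn + (14 - tp) == 0) next
      m <- accuracy_metrics(tp, 13 - tn, tn, 14 - tp)
      expect_equal(counts_from_rounded_rates(m[["Se"]], 14), tp)
      expect_equal(counts_from_rounded_rates(m[["Sp"]], 13), tn)
    }
  }
})

test_that("prevalence-adjusted predictive values obey their algebra", {
  expect_equal(prevalence_adjusted(0.8, 1, 0.3)$PPV, 1)
  adj <- prevalence_adjusted(0.14, 1.00, 14 / 27)
  expect_equal(round_half_away(adj$NPV, 2), 0.52)
  # at p = 1 with perfect sensitivity the NPV is 0/0, defined as 1; with
  # imperfect sensitivity it is a true 0 (all negatives are misses)
  ext <- prevalence_adjusted(1, 0.8, 1)
  expect_equal(ext$NPV, 1)
  expect_equal(ext$PPV, 1)
  expect_equal(prevalence_adjusted(0.9, 0.8, 1)$NPV, 0)

  # consistency with count-based predictive values at the sample prevalence
  withr::with_seed(12, {
    for (i in 1:20) {
      tp <- sample(0:14, 1); tn <- sample(0:13, 1)
      if (tp + 13 - tn == 0 || tn + 14 - tp == 0) next
      m <- accuracy_metrics(tp, 13 - tn, tn, 14 - tp)
      adj <- prevalence_adjusted(tp / 14, tn / 13, 14 / 27)
      expect_equal(round_half_away(adj$PPV, 2), m[["PPV"]])
      expect_equal(round_half_away(adj$NPV, 2), m[["NPV"]])
    }
  })
})

make_feature_table <- function(np_vals, month_vals, comp = "R",
                               appr = "GLCM", feat = "Entropy") {
  rows <- list()
  for (s in 1:4) {
    rows[[s]] <- data.frame(mare_id = sprintf("NP%02d", seq_along(np_vals[[s]])),
                            group = "NP", subgroup = "-", month = NA_integer_,
                            session = s, component = comp, approach = appr,
                            feature = feat, value = np_vals[[s]],
                            stringsAsFactors = FALSE)
  }
  for (m in names(month_vals)) {
    sub <- if (as.integer(m) %% 2 == 0) "A" else "B"
    ses <- match(as.integer(m), if (sub == "A") c(4, 6, 8, 10) else c(5, 7, 9, 11))
    rows[[length(rows) + 1]] <- data.frame(
      mare_id = sprintf("P%s%02d", sub, seq_along(month_vals[[m]])),
      group = "P", subgroup = sub, month = as.integer(m), session = ses,
      component = comp, approach = appr, feature = feat,
      value = month_vals[[m]], stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

test_that("evaluation of a separable feature is perfect at every threshold", {
  # degenerate negatives: every non-pregnant value equals the pooled mean,
  # so the tie rule annotates them all non-pregnant at every threshold
  np <- replicate(4, rep(5, 14), simplify = FALSE)
  months <- withr::with_seed(113, stats::setNames(
    lapply(4:11, function(m) rnorm(13, 50 + m, 0.1)), 4:11))
  ft <- make_feature_table(np, months)
  selection <- data.frame(component = "R", approach = "GLCM",
                          feature = "Entropy", pass_c1 = TRUE,
                          pooled_mean = mean(unlist(np)),
                          pooled_sd = sd(unlist(np)),
                          first_sep_month = 4L, trend = "In", selected = TRUE,
                          stringsAsFactors = FALSE)
  acc <- evaluate_accuracy(ft, selection)
  expect_equal(nrow(acc), 8 * 3)
  expect_true(all(acc$Se == 1))
  expect_true(all(acc$Sp == 1))
  expect_true(all(acc$TP == 13 & acc$TN == 14))
})

test_that("accuracy records cover combination x month x threshold", {
  np <- withr::with_seed(14, replicate(4, rnorm(14), simplify = FALSE))
  months <- withr::with_seed(114, stats::setNames(
    lapply(4:11, function(m) rnorm(13, m / 4)), 4:11))
  combos <- expand.grid(component = c("R", "G", "B", "I", "Q", "S")[1:5],
                        feature = c("Entropy", "Mean", "Perc10")[1:3],
                        stringsAsFactors = FALSE)[1:13, ]
  ft <- do.call(rbind, lapply(seq_len(13), function(i) {
    make_feature_table(np, months, combos$component[i], "GLCM",
                       combos$feature[i])
  }))
  selection <- data.frame(component = combos$component, approach = "GLCM",
                          feature = combos$feature, pass_c1 = TRUE,
                          pooled_mean = 0, pooled_sd = 1,
                          first_sep_month = 4L, trend = "In", selected = TRUE,
                          stringsAsFactors = FALSE)
  acc <- evaluate_accuracy(ft, selection)
  expect_equal(nrow(acc), 13 * 8 * 3)
  # threshold monotonicity: Se never falls, Sp never rises with k
  acc <- acc[order(acc$threshold_k), ]
  key <- interaction(acc$component, acc$feature, acc$month)
  for (grpi in split(acc, key)) {
    expect_true(all(diff(grpi$Se) >= 0))
    expect_true(all(diff(grpi$Sp) <= 0))
  }
})

test_that("prevalence sweep returns the requested grid per record", {
  np <- withr::with_seed(15, replicate(4, rnorm(14), simplify = FALSE))
  months <- withr::with_seed(115, stats::setNames(
    lapply(4:11, function(m) rnorm(13, 5)), 4:11))
  ft <- make_feature_table(np, months)
  selection <- data.frame(component = "R", approach = "GLCM",
                          feature = "Entropy", pass_c1 = TRUE, pooled_mean = 0,
                          pooled_sd = 1, first_sep_month = 4L, trend = "In",
                          selected = TRUE, stringsAsFactors = FALSE)
  acc <- evaluate_accuracy(ft, selection)
  sw <- prevalence_sweep(acc[1:2, ])
  expect_equal(nrow(sw), 20)
  expect_equal(unique(sw$p), seq(0.1, 1, 0.1))
  expect_true(all(sw$PPV >= 0 & sw$PPV <= 1))
})
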