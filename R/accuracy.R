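#' Diagnostic thresholds from the pooled non-pregnant reference
#'
#' Builds the three decision thresholds (indices k = 0, 1, 2) from the
#' pooled non-pregnant mean and SD of a combination. For a feature that
#' increases with pregnancy the thresholds are `mean - k * SD` (a laxer
#' threshold admits more positives, so sensitivity rises and specificity
#' falls with k); for a decreasing feature, `mean + k * SD`. The literal
#' shifted-up reading (`mean + k * SD` for increasing features) is
#' available via `literal = TRUE`.
#'
#' @param pooled_mean,pooled_sd pooled non-pregnant statistics
#'   (criterion 1); `pooled_sd >= 0`.
#' @param direction `"In"` (feature increases with pregnancy) or `"De"`.
#' @param literal use the literal shifted-with-the-trend reading.
#' @return object of class `threshold_set`: list with `thresholds`
#'   (named numeric, k0..k2) and `direction`.
#' @export
#' @examples
#' compute_thresholds(5, 1, "In")$thresholds  # 5 4 3
#' compute_thresholds(5, 1, "De")$thresholds  # 5 6 7
compute_thresholds <- function(pooled_mean, pooled_sd, direction,
                               literal = FALSE) {
  stopifnot_scalar_number(pooled_mean, "pooled_mean")
  stopifnot_scalar_number(pooled_sd, "pooled_sd")
  if (pooled_sd < 0) stop("`pooled_sd` must be non-negative", call. = FALSE)
  direction <- match.arg(direction, c("In", "De"))
  sgn <- if (xor(direction == "In", literal)) -1 else 1
  th <- pooled_mean + sgn * (0:2) * pooled_sd
  structure(list(thresholds = stats::setNames(th, c("k0", "k1", "k2")),
                 direction = direction, pooled_mean = pooled_mean,
                 pooled_sd = pooled_sd),
            class = "threshold_set")
}

#' Annotate a feature value as pregnant (1) or non-pregnant (0)
#'
#' A value strictly beyond the threshold in the trend direction is
#' annotated pregnant: above it for increasing features, below it for
#' decreasing ones. Equality counts as non-pregnant.
#'
#' @param value numeric feature value(s).
#' @param threshold decision threshold.
#' @param direction `"In"` or `"De"`.
#' @return integer vector of 0/1 annotations.
#' @export
annotate_pregnancy <- function(value, threshold, direction) {
  direction <- match.arg(direction, c("In", "De"))
  if (any(!is.finite(value)) || !is.finite(threshold)) {
    stop("values and threshold must be finite", call. = FALSE)
  }
  if (direction == "In") as.integer(value > threshold) else as.integer(value < threshold)
}

ratio01 <- function(num, den) if (den == 0) 1 else num / den

#' Diagnostic accuracy from confusion counts
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, positive
#' predictive value `TP/(TP+FP)`, and negative predictive value
#' `TN/(TN+FN)`, each rounded half away from zero to two decimals. A 0/0
#' ratio is defined as 1.00 (a vacuous predictive value with no
#' classifications of that kind).
#'
#' @param tp,fp,tn,fn non-negative confusion counts; `tp + fn` and
#'   `tn + fp` must each be at least 1.
#' @return named numeric vector `Se`, `Sp`, `PPV`, `NPV`.
#' @export
#' @examples
#' accuracy_metrics(tp = 2, fp = 0, tn = 13, fn = 12)
accuracy_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp, fp, tn, fn)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("confusion counts must be non-negative integers", call. = FALSE)
  }
  if (tp + fn < 1) stop("no positive cases (TP + FN = 0)", call. = FALSE)
  if (tn + fp < 1) stop("no negative cases (TN + FP = 0)", call. = FALSE)
  round_half_away(c(Se = tp / (tp + fn), Sp = tn / (tn + fp),
                    PPV = ratio01(tp, tp + fp), NPV = ratio01(tn, tn + fn)), 2)
}

#' Invert a two-decimal rate to its integer count
#'
#' Finds the unique count `c` in `0..denominator` whose ratio
#' `c/denominator` rounds (half away from zero) to the given two-decimal
#' rate. Used to validate reported accuracy tables: a printed rate that
#' admits no count, or several, is flagged with an error.
#'
#' @param rate two-decimal rate in `[0, 1]`.
#' @param denominator positive integer.
#' @return the unique integer count.
#' @export
#' @examples
#' counts_from_rounded_rates(0.43, 14)  # 6
counts_from_rounded_rates <- function(rate, denominator) {
  stopifnot(rate >= 0, rate <= 1, denominator >= 1)
  cand <- 0:denominator
  hit <- cand[round_half_away(cand / denominator, 2) == round_half_away(rate, 2)]
  if (length(hit) == 0) {
    stop(sprintf("no count over %d rounds to %.2f", denominator, rate), call. = FALSE)
  }
  if (length(hit) > 1) {
    stop(sprintf("rate %.2f over %d is ambiguous (counts %s)", rate,
                 denominator, paste(hit, collapse = ", ")), call. = FALSE)
  }
  hit
}

#' Prevalence-adjusted predictive values
#'
#' PPV and NPV at an assumed pregnancy prevalence `p`, from Bayes'
#' formula: `PPV = Se p / (Se p + (1 - Sp)(1 - p))` and
#' `NPV = Sp (1 - p) / ((1 - Se) p + Sp (1 - p))`; 0/0 is defined as 1.
#'
#' @param se,sp sensitivity and specificity in `[0, 1]`.
#' @param p prevalence in `[0, 1]` (may be a vector).
#' @return data.frame with columns `p`, `PPV`, `NPV`.
#' @export
prevalence_adjusted <- function(se, sp, p) {
  stopifnot(se >= 0, se <= 1, sp >= 0, sp <= 1, all(p >= 0), all(p <= 1))
  ppv <- vapply(p, function(pi) ratio01(se * pi, se * pi + (1 - sp) * (1 - pi)),
                numeric(1))
  npv <- vapply(p, function(pi) ratio01(sp * (1 - pi), (1 - se) * pi + sp * (1 - pi)),
                numeric(1))
  data.frame(p = p, PPV = ppv, NPV = npv)
}

# non-pregnant session index concurrent with a pregnant gestation month:
# subgroup schedules are interleaved, so each month maps to the position
# it holds in its own subgroup's schedule
session_for_month <- function(month, months_a, months_b) {
  s <- match(month, months_a)
  if (is.na(s)) s <- match(month, months_b)
  if (is.na(s)) stop(sprintf("month %d is not on either imaging schedule", month),
                     call. = FALSE)
  s
}

#' Threshold-based diagnostic accuracy of the selected combinations
#'
#' For every finally selected color/feature combination, gestation month,
#' and threshold index k in 0..2: pregnant mares imaged that month are
#' the positives, the non-pregnant mares at the concurrent session are
#' the negatives, each animal is annotated by comparing its feature value
#' to the threshold, and the confusion counts and Se/Sp/PPV/NPV are
#' reported.
#'
#' @param features feature table from [extract_cohort_features()].
#' @param selection a [run_selection()] result (or its `results`
#'   data.frame).
#' @param literal_thresholds passed to [compute_thresholds()].
#' @return data.frame: one row per combination x month x threshold with
#'   columns `component`, `approach`, `feature`, `month`, `threshold_k`,
#'   `threshold`, `TP`, `FP`, `TN`, `FN`, `Se`, `Sp`, `PPV`, `NPV`.
#' @export
evaluate_accuracy <- function(features, selection, literal_thresholds = FALSE) {
  results <- if (inherits(selection, "selection_result")) selection$results else selection
  sel <- results[results$selected, , drop = FALSE]
  if (nrow(sel) == 0) {
    stop("no selected combinations to evaluate", call. = FALSE)
  }
  p_rows <- features[features$group == "P", ]
  months_a <- sort(unique(p_rows$month[p_rows$subgroup == "A"]))
  months_b <- sort(unique(p_rows$month[p_rows$subgroup == "B"]))
  out <- list()
  for (i in seq_len(nrow(sel))) {
    cmb <- sel[i, ]
    ft <- features[features$component == cmb$component &
                     features$approach == cmb$approach &
                     features$feature == cmb$feature, ]
    ths <- compute_thresholds(cmb$pooled_mean, cmb$pooled_sd, cmb$trend,
                              literal = literal_thresholds)
    for (m in sort(unique(ft$month[ft$group == "P"]))) {
      pos <- ft$value[ft$group == "P" & ft$month == m]
      ses <- session_for_month(m, months_a, months_b)
      neg <- ft$value[ft$group == "NP" & ft$session == ses]
      if (length(pos) == 0 || length(neg) == 0) {
        stop(sprintf("month %d has no positive or no negative observations", m),
             call. = FALSE)
      }
      for (k in 0:2) {
        th <- ths$thresholds[[k + 1]]
        tp <- sum(annotate_pregnancy(pos, th, cmb$trend))
        fp <- sum(annotate_pregnancy(neg, th, cmb$trend))
        met <- accuracy_metrics(tp, fp, length(neg) - fp, length(pos) - tp)
        out[[length(out) + 1L]] <- data.frame(
          component = cmb$component, approach = cmb$approach,
          feature = cmb$feature, month = m, threshold_k = k, threshold = th,
          TP = tp, FP = fp, TN = length(neg) - fp, FN = length(pos) - tp,
          Se = met[["Se"]], Sp = met[["Sp"]], PPV = met[["PPV"]],
          NPV = met[["NPV"]], stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Prevalence sweep of predictive values
#'
#' Recomputes PPV/NPV of each accuracy record across a grid of assumed
#' pregnancy prevalences.
#'
#' @param accuracy an [evaluate_accuracy()] result.
#' @param p prevalence grid (default `seq(0.1, 1, by = 0.1)`).
#' @return long data.frame with the record keys plus `p`, `PPV`, `NPV`.
#' @export
prevalence_sweep <- function(accuracy, p = seq(0.1, 1, by = 0.1)) {
  out <- lapply(seq_len(nrow(accuracy)), function(i) {
    rec <- accuracy[i, ]
    adj <- prevalence_adjusted(rec$Se, rec$Sp, p)
    cbind(rec[rep(1L, nrow(adj)),
              c("component", "approach", "feature", "month", "threshold_k")],
          adj, row.names = NULL)
  })
  do.call(rbind, out)
}
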