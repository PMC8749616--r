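#' Selection-cascade configuration
#'
#' @param alpha significance level for the omnibus and post-hoc tests
#'   (default 0.05).
#' @param normality_alpha level for the Shapiro-Wilk gate (default 0.05).
#' @param c2_method criterion-2 comparison structure: `"omnibus"`
#'   (default; one omnibus test over pooled non-pregnant plus all pregnant
#'   months, followed by adjusted non-pregnant-vs-month contrasts) or
#'   `"pairwise"` (per-month two-sample tests, unadjusted).
#' @param drop_glch `"auto"` (drop GLCH after criterion 2 when its
#'   surviving combinations duplicate GLCM's), `"always"`, or `"never"`.
#' @return object of class `selection_config`.
#' @export
selection_config <- function(alpha = 0.05, normality_alpha = 0.05,
                             c2_method = c("omnibus", "pairwise"),
                             drop_glch = c("auto", "always", "never")) {
  stopifnot(alpha > 0, alpha < 1, normality_alpha > 0, normality_alpha < 1)
  structure(list(alpha = alpha, normality_alpha = normality_alpha,
                 c2_method = match.arg(c2_method),
                 drop_glch = match.arg(drop_glch)),
            class = "selection_config")
}

is_constant <- function(x) max(x) - min(x) <= 0

#' Shapiro-Wilk gate for a family of series
#'
#' Decides between the parametric (ANOVA/Tukey) and nonparametric
#' (Kruskal-Wallis/Dunn) test family for one comparison: parametric only
#' when every series in the family passes the Shapiro-Wilk normality test
#' at `normality_alpha`. Degenerate (constant) series count as
#' non-Gaussian.
#'
#' @param series list of numeric vectors, each of length >= 3.
#' @param normality_alpha significance level of the gate.
#' @return `"parametric"` or `"nonparametric"`.
#' @export
normality_gate <- function(series, normality_alpha = 0.05) {
  if (any(vapply(series, length, integer(1)) < 3)) {
    stop("every series needs at least 3 observations for the normality gate",
         call. = FALSE)
  }
  ok <- vapply(series, function(x) {
    if (is_constant(x)) return(FALSE)
    stats::shapiro.test(x)$p.value >= normality_alpha
  }, logical(1))
  if (all(ok)) "parametric" else "nonparametric"
}

omnibus_pvalue <- function(values, groups, family) {
  if (is_constant(values)) return(1)
  groups <- factor(groups)
  if (family == "parametric") {
    fit <- stats::aov(values ~ groups)
    summary(fit)[[1]][["Pr(>F)"]][1]
  } else {
    stats::kruskal.test(values, groups)$p.value
  }
}

# Dunn's rank-based multiple-comparison z tests after Kruskal-Wallis,
# with tie correction; p-values Bonferroni-adjusted over the requested
# contrast family.
dunn_contrasts <- function(values, groups, control, others) {
  groups <- factor(groups)
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  n <- tapply(r, groups, length)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_corr
  m <- length(others)
  p <- vapply(others, function(g) {
    z <- (rbar[[control]] - rbar[[g]]) /
      sqrt(s2 * (1 / n[[control]] + 1 / n[[g]]))
    2 * stats::pnorm(-abs(z))
  }, numeric(1))
  stats::setNames(pmin(1, p * m), others)
}

tukey_contrasts <- function(values, groups, control, others) {
  groups <- factor(groups)
  tk <- stats::TukeyHSD(stats::aov(values ~ groups))$groups
  p <- vapply(others, function(g) {
    key <- paste(sort(c(control, g))[2], sort(c(control, g))[1], sep = "-")
    if (!key %in% rownames(tk)) key <- paste(control, g, sep = "-")
    tk[key, "p adj"]
  }, numeric(1))
  stats::setNames(p, others)
}

#' Criterion 1: homogeneity of the non-pregnant group across sessions
#'
#' Tests whether a combination's non-pregnant series differ between
#' consecutive imaging sessions (omnibus one-way ANOVA for Gaussian data
#' or Kruskal-Wallis otherwise, family chosen by the Shapiro-Wilk gate).
#' The combination passes when the omnibus test is non-significant at
#' `alpha`; on a pass, the pooled mean and SD over all sessions are
#' reported as the non-pregnant reference values.
#'
#' @param sessions list of numeric vectors, one per session, each of
#'   length >= 3.
#' @param cfg a [selection_config()].
#' @return list with `pass`, `p_value`, `family`, `pooled_mean`,
#'   `pooled_sd` (the pooled values are `NA` on a fail), and `degenerate`
#'   (`TRUE` when every value is identical).
#' @export
criterion1_homogeneity <- function(sessions, cfg = selection_config()) {
  if (any(vapply(sessions, length, integer(1)) < 3)) {
    stop("every session series needs at least 3 observations", call. = FALSE)
  }
  values <- unlist(sessions, use.names = FALSE)
  if (is_constant(values)) {
    return(list(pass = TRUE, p_value = 1, family = "degenerate",
                pooled_mean = values[1], pooled_sd = 0, degenerate = TRUE))
  }
  family <- normality_gate(sessions, cfg$normality_alpha)
  groups <- rep(seq_along(sessions), vapply(sessions, length, integer(1)))
  p <- omnibus_pvalue(values, groups, family)
  pass <- p >= cfg$alpha
  list(pass = pass, p_value = p, family = family,
       pooled_mean = if (pass) mean(values) else NA_real_,
       pooled_sd = if (pass) stats::sd(values) else NA_real_,
       degenerate = FALSE)
}

#' Criterion 2: sustained separation of pregnant months from the pooled
#' non-pregnant reference
#'
#' Compares the pooled non-pregnant values against the pregnant series of
#' each scheduled gestation month and returns the earliest month from
#' which the separation is significant through the end of pregnancy
#' (post-hoc-adjusted p < `alpha` for that month and every later one), or
#' `NA` when no such month exists. With the default `"omnibus"` method
#' the contrasts come from Tukey's test after one-way ANOVA (Gaussian
#' family) or Dunn's test after Kruskal-Wallis, over one omnibus model
#' containing the pooled non-pregnant group and all months.
#'
#' @param pooled_np numeric vector: pooled non-pregnant values.
#' @param month_series named list of numeric vectors, one per gestation
#'   month (names are the month numbers), in increasing month order.
#' @param cfg a [selection_config()].
#' @return list with `first_sep_month` (integer or `NA`), `sig_months`
#'   (named logical), `family`, and `p_omnibus` (the omnibus p-value; `NA`
#'   under the pairwise method).
#' @export
criterion2_separation <- function(pooled_np, month_series,
                                  cfg = selection_config()) {
  if (length(month_series) == 0 ||
      any(vapply(month_series, length, integer(1)) == 0)) {
    stop("a scheduled gestation month has no pregnant observations", call. = FALSE)
  }
  months <- as.integer(names(month_series))
  stopifnot(!is.na(months), !is.unsorted(months, strictly = TRUE))
  all_series <- c(list(NP = pooled_np), month_series)
  values <- unlist(all_series, use.names = FALSE)
  labels <- rep(c("NP", names(month_series)),
                vapply(all_series, length, integer(1)))
  if (is_constant(values)) {
    sig <- stats::setNames(rep(FALSE, length(months)), names(month_series))
    return(list(first_sep_month = NA_integer_, sig_months = sig,
                family = "degenerate", p_omnibus = 1))
  }
  family <- normality_gate(all_series, cfg$normality_alpha)
  p_omni <- NA_real_
  if (cfg$c2_method == "omnibus") {
    p_omni <- omnibus_pvalue(values, labels, family)
    if (p_omni >= cfg$alpha) {
      p <- stats::setNames(rep(1, length(months)), names(month_series))
    } else {
      p <- if (family == "parametric") {
        tukey_contrasts(values, labels, "NP", names(month_series))
      } else {
        dunn_contrasts(values, labels, "NP", names(month_series))
      }
    }
  } else {
    p <- vapply(month_series, function(x) {
      if (is_constant(c(pooled_np, x))) return(1)
      if (family == "parametric") {
        stats::t.test(pooled_np, x)$p.value
      } else {
        stats::wilcox.test(pooled_np, x, exact = FALSE)$p.value
      }
    }, numeric(1))
  }
  sig <- p < cfg$alpha
  sustained <- rev(cumprod(rev(sig))) > 0   # TRUE where sig from here to end
  first <- if (any(sustained)) months[which(sustained)[1]] else NA_integer_
  list(first_sep_month = first, sig_months = sig, family = family,
       p_omnibus = p_omni)
}

#' Criterion 3: monotone gestational trend
#'
#' Classifies the per-month pregnant means as gradually increasing
#' (`"In"`), gradually decreasing (`"De"`), or neither (`"none"`).
#' Increasing means non-decreasing month means with strictly positive
#' total change and a Spearman rank correlation of exactly +1 between
#' mean and month (ties therefore disqualify); decreasing is symmetric.
#'
#' @param month_means numeric vector of per-month means, in increasing
#'   month order, length >= 3.
#' @return `"In"`, `"De"`, or `"none"`.
#' @export
criterion3_trend <- function(month_means) {
  if (length(month_means) < 3) stop("need means for at least 3 months", call. = FALSE)
  d <- diff(month_means)
  rho <- suppressWarnings(
    stats::cor(month_means, seq_along(month_means), method = "spearman"))
  if (all(d >= 0) && sum(d) > 0 && isTRUE(all.equal(rho, 1))) return("In")
  if (all(d <= 0) && sum(d) < 0 && isTRUE(all.equal(rho, -1))) return("De")
  "none"
}

split_series <- function(ft) {
  np <- ft[ft$group == "NP", ]
  p <- ft[ft$group == "P", ]
  sessions <- split(np$value, np$session)
  months <- split(p$value, p$month)   # names sorted increasing
  list(sessions = sessions, months = months)
}

#' Run the three-criterion selection cascade
#'
#' Applies, for every color-component/approach/feature combination in the
#' feature table: (1) non-pregnant between-session homogeneity, (2)
#' sustained pregnant/non-pregnant separation, and (3) monotone
#' gestational trend. After criterion 2 the asymmetric co-occurrence
#' (GLCH) combinations are dropped when their surviving set duplicates
#' the symmetric (GLCM) set, since they then carry no additional
#' information.
#'
#' @param features feature table from [extract_cohort_features()] (columns
#'   `mare_id`, `group`, `month`, `session`, `component`, `approach`,
#'   `feature`, `value`).
#' @param cfg a [selection_config()].
#' @return object of class `selection_result`: list with `results`
#'   (data.frame: `component`, `approach`, `feature`, `pass_c1`,
#'   `pooled_mean`, `pooled_sd`, `first_sep_month`, `c2_p_omnibus`,
#'   `trend`, `selected`)
#'   and `stage_counts` (per-approach and total survivors at each stage).
#' @export
run_selection <- function(features, cfg = selection_config()) {
  key <- interaction(features$component, features$approach, features$feature,
                     drop = TRUE)
  combos <- split(features, key)
  res <- lapply(combos, function(ft) {
    s <- split_series(ft)
    c1 <- criterion1_homogeneity(s$sessions, cfg)
    row <- data.frame(component = ft$component[1], approach = ft$approach[1],
                      feature = ft$feature[1], pass_c1 = c1$pass,
                      pooled_mean = c1$pooled_mean, pooled_sd = c1$pooled_sd,
                      first_sep_month = NA_integer_, c2_p_omnibus = NA_real_,
                      trend = NA_character_,
                      stringsAsFactors = FALSE)
    if (!c1$pass) return(row)
    pooled_np <- unlist(s$sessions, use.names = FALSE)
    c2 <- criterion2_separation(pooled_np, s$months, cfg)
    row$first_sep_month <- c2$first_sep_month
    row$c2_p_omnibus <- c2$p_omnibus
    if (is.na(c2$first_sep_month)) return(row)
    means <- vapply(s$months, mean, numeric(1))
    row$trend <- criterion3_trend(means)
    row
  })
  results <- do.call(rbind, c(res, list(make.row.names = FALSE)))

  by_approach <- function(flag) {
    vapply(c("HS", "GLCM", "GLCH"),
           function(a) sum(flag & results$approach == a), numeric(1))
  }
  n_enum <- by_approach(rep(TRUE, nrow(results)))
  n_c1 <- by_approach(results$pass_c1)
  n_c2 <- by_approach(results$pass_c1 & !is.na(results$first_sep_month))

  surv_set <- function(a) {
    r <- results[results$approach == a & results$pass_c1 &
                   !is.na(results$first_sep_month), ]
    sort(paste(r$component, r$feature))
  }
  glch_dropped <- switch(cfg$drop_glch,
    always = TRUE,
    never = FALSE,
    auto = identical(surv_set("GLCM"), surv_set("GLCH")))

  considered <- results$pass_c1 & !is.na(results$first_sep_month)
  if (glch_dropped) considered <- considered & results$approach != "GLCH"
  results$selected <- considered & !is.na(results$trend) &
    results$trend != "none"

  stage_counts <- list(
    enumerated = sum(n_enum), enumerated_by_approach = n_enum,
    after_c1 = sum(n_c1), after_c1_by_approach = n_c1,
    after_c2 = sum(n_c2), after_c2_by_approach = n_c2,
    glch_dropped = glch_dropped,
    after_glch_drop = sum(if (glch_dropped) n_c2[c("HS", "GLCM")] else n_c2),
    final = sum(results$selected),
    final_by_approach = by_approach(results$selected))
  structure(list(results = results, stage_counts = stage_counts,
                 config = cfg),
            class = "selection_result")
}

#' Stage-count bookkeeping for the selection cascade
#'
#' Computes the stage totals of the cascade from per-approach survivor
#' counts: total enumerated combinations, survivors of criteria 1 and 2,
#' the count retained after dropping the duplicated GLCH set, and the
#' final indicator count.
#'
#' @param after_c1,after_c2 named numeric vectors with elements `HS`,
#'   `GLCM`, `GLCH`.
#' @param final named numeric vector of finally selected counts by
#'   approach (GLCH absent after the drop).
#' @param n_components,n_features_hs,n_features_glcm size of the
#'   enumeration grid (defaults 10, 13, 11).
#' @return named list of stage totals.
#' @export
#' @examples
#' selection_stage_summary(
#'   after_c1 = c(HS = 127, GLCM = 110, GLCH = 110),
#'   after_c2 = c(HS = 77, GLCM = 76, GLCH = 76),
#'   final = c(HS = 5, GLCM = 8))
selection_stage_summary <- function(after_c1, after_c2, final,
                                    n_components = 10, n_features_hs = 13,
                                    n_features_glcm = 11) {
  list(enumerated = n_components * (n_features_hs + 2 * n_features_glcm),
       after_c1 = sum(after_c1),
       after_c2 = sum(after_c2),
       after_glch_drop = sum(after_c2[c("HS", "GLCM")]),
       final = sum(final))
}
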