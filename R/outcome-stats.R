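#' Paired t-test with effect size and percent reduction
#'
#' Standard two-sided paired t-test on `pre - post` differences
#' (via [stats::t.test()]), augmented with the paired-design effect size
#' `dz = t / sqrt(n)` and the percent reduction
#' `100 * (mean(pre) - mean(post)) / mean(pre)`.
#'
#' @param pre,post Numeric vectors of equal length `n >= 2`; the
#'   differences must not have zero variance.
#' @return A list of class `"paired_result"`: `t_stat`, `df`, `p_value`,
#'   `cohens_dz`, `pre_mean`, `pre_sd`, `post_mean`, `post_sd`,
#'   `mean_diff`, `pct_reduction`, `n`.
#' @export
paired_t <- function(pre, post) {
  if (length(pre) != length(post)) stop("'pre' and 'post' lengths differ")
  n <- length(pre)
  if (n < 2) stop("need n >= 2 pairs")
  d <- pre - post
  if (stats::sd(d) == 0)
    stop("zero-variance differences: paired t-test undefined")
  tt <- stats::t.test(pre, post, paired = TRUE)
  out <- list(t_stat = unname(tt$statistic), df = unname(tt$parameter),
              p_value = tt$p.value,
              cohens_dz = unname(tt$statistic) / sqrt(n),
              pre_mean = mean(pre), pre_sd = stats::sd(pre),
              post_mean = mean(post), post_sd = stats::sd(post),
              mean_diff = mean(d),
              pct_reduction = percent_reduction(mean(pre), mean(post)),
              n = n)
  class(out) <- "paired_result"
  out
}

#' @export
print.paired_result <- function(x, ...) {
  cat(sprintf("paired t(%d) = %.2f, p = %.3g, dz = %.2f\n",
              x$df, x$t_stat, x$p_value, x$cohens_dz))
  cat(sprintf("pre %.2f (%.2f) -> post %.2f (%.2f): diff %.2f (%.1f%% reduction)\n",
              x$pre_mean, x$pre_sd, x$post_mean, x$post_sd,
              x$mean_diff, x$pct_reduction))
  invisible(x)
}

#' Paired-design Cohen's d from a t statistic
#'
#' The within-pair effect size `dz = t / sqrt(n)` for a paired design with
#' `n` pairs.
#'
#' @param t_stat Paired t statistic.
#' @param n Number of pairs (>= 2).
#' @return Numeric.
#' @export
#' @examples
#' cohens_dz(41.40, 55)  # 5.58
cohens_dz <- function(t_stat, n) {
  if (any(n < 2)) stop("'n' must be >= 2")
  t_stat / sqrt(n)
}

#' Percent reduction between two means
#'
#' `100 * (pre - post) / pre`; scale-invariant in the common factor.
#'
#' @param pre_mean,post_mean Means; `pre_mean` must be non-zero.
#' @return Numeric percentage.
#' @export
percent_reduction <- function(pre_mean, post_mean) {
  if (any(pre_mean == 0)) stop("'pre_mean' must be non-zero")
  100 * (pre_mean - post_mean) / pre_mean
}

#' Classify a fear-questionnaire total score into severity strata
#'
#' Bands: `high` for scores >= 80, `moderate` for 50-79, `low_moderate`
#' for 40-49, `excluded` below the study's operational inclusion threshold
#' of 40. Vectorised; partitions `[0, Inf)` with no gaps or overlaps.
#'
#' @param score Numeric score(s), >= 0.
#' @return Character vector of stratum labels.
#' @export
#' @examples
#' classify_fsq(c(39, 40, 49, 50, 79, 80))
classify_fsq <- function(score) {
  if (any(score < 0)) stop("'score' must be >= 0")
  ifelse(score >= 80, "high",
         ifelse(score >= 50, "moderate",
                ifelse(score >= 40, "low_moderate", "excluded")))
}

#' Score post-session questionnaire responses
#'
#' Computes the domain indices from the 15-item response table: the two
#' state-anxiety items are reported separately on their 0-100 scale (never
#' pooled with Likert items); the avoidance, control and presence indices
#' are item means on 1-7; the tolerability index is `mean(T1, 8 - T2, T3)`
#' (T2, the nausea/dizziness item, is reverse-coded); and the step-up
#' readiness flag is `R1 >= 5` contingent on tolerability `>= 5` and no
#' adverse event.
#'
#' @param responses Data frame with columns `A1, A2, AV1:AV3, C1:C3,
#'   P1:P3, T1:T3, R1` and `AE` (`"yes"`/`"no"` or logical), one row per
#'   respondent. Out-of-range items are rejected by name.
#' @return Data frame of class `"psq_scores"` with one row per respondent:
#'   `anxiety_end`, `anxiety_peak`, `avoidance_index`, `control_index`,
#'   `presence_index`, `tolerability_index`, `readiness`, `adverse_event`,
#'   `step_up_ready`.
#' @export
score_psq <- function(responses) {
  likert_items <- c("AV1", "AV2", "AV3", "C1", "C2", "C3",
                    "P1", "P2", "P3", "T1", "T2", "T3", "R1")
  need <- c("A1", "A2", likert_items, "AE")
  missing_cols <- setdiff(need, names(responses))
  if (length(missing_cols))
    stop("missing items: ", paste(missing_cols, collapse = ", "))
  for (it in c("A1", "A2")) {
    v <- responses[[it]]
    if (any(v < 0 | v > 100)) stop("item ", it, " out of range [0, 100]")
  }
  for (it in likert_items) {
    v <- responses[[it]]
    if (any(v < 1 | v > 7)) stop("item ", it, " out of range [1, 7]")
  }
  ae <- if (is.logical(responses$AE)) responses$AE else
    tolower(as.character(responses$AE)) %in% c("yes", "y", "true", "1")
  rowmean <- function(...) rowMeans(cbind(...))
  tol <- rowmean(responses$T1, 8 - responses$T2, responses$T3)
  out <- data.frame(
    anxiety_end = responses$A1, anxiety_peak = responses$A2,
    avoidance_index = rowmean(responses$AV1, responses$AV2, responses$AV3),
    control_index = rowmean(responses$C1, responses$C2, responses$C3),
    presence_index = rowmean(responses$P1, responses$P2, responses$P3),
    tolerability_index = tol,
    readiness = responses$R1,
    adverse_event = ae,
    step_up_ready = responses$R1 >= 5 & tol >= 5 & !ae)
  class(out) <- c("psq_scores", "data.frame")
  out
}

#' Fear-score change table by baseline severity stratum
#'
#' Per-stratum (and total-sample) summary of pre/post fear-questionnaire
#' scores: n, means and SDs, mean difference, percent reduction, paired t
#' and p.
#'
#' @param participants Data frame with columns `stratum`, `fsq_pre`,
#'   `fsq_post` (the `participants` element of a
#'   [generate_cohort()] result fits directly).
#' @return Data frame, one row per stratum plus `"total"`.
#' @export
fsq_change_table <- function(participants) {
  one <- function(label, pre, post) {
    pt <- paired_t(pre, post)
    data.frame(group = label, n = pt$n,
               pre_mean = pt$pre_mean, pre_sd = pt$pre_sd,
               post_mean = pt$post_mean, post_sd = pt$post_sd,
               mean_diff = -pt$mean_diff,
               pct_reduction = pt$pct_reduction,
               t_value = pt$t_stat, p_value = pt$p_value)
  }
  groups <- unique(participants$stratum)
  rows <- lapply(groups, function(g) {
    sel <- participants$stratum == g
    one(g, participants$fsq_pre[sel], participants$fsq_post[sel])
  })
  rows[[length(rows) + 1L]] <-
    one("total", participants$fsq_pre, participants$fsq_post)
  do.call(rbind, rows)
}

#' Paired pre/post outcome table across key indicators
#'
#' Emulates the cohort-level paired-test summary: fear-questionnaire
#' pre/post plus first-versus-last-session contrasts of heart rate,
#' time-on-task and head movement, each reported with paired t, p and
#' Cohen's dz.
#'
#' @param cohort A `"cohort_dataset"` from [generate_cohort()].
#' @return Data frame, one row per measure.
#' @export
paired_outcomes_table <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  ses <- cohort$sessions
  first <- ses[ses$session == min(ses$session), ]
  last <- ses[ses$session == max(ses$session), ]
  first <- first[order(first$participant), ]
  last <- last[order(last$participant), ]
  row_of <- function(measure, pre, post) {
    pt <- paired_t(pre, post)
    data.frame(measure = measure,
               pre_mean = pt$pre_mean, pre_sd = pt$pre_sd,
               post_mean = pt$post_mean, post_sd = pt$post_sd,
               t_value = pt$t_stat, p_value = pt$p_value,
               cohens_dz = pt$cohens_dz)
  }
  rbind(
    row_of("fsq", cohort$participants$fsq_pre, cohort$participants$fsq_post),
    row_of("heart_rate", first$hr_bpm, last$hr_bpm),
    row_of("time_spent", first$time_s, last$time_s),
    row_of("head_movement", first$head_move, last$head_move))
}
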