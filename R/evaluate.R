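#' Confusion table from scan verdicts
#'
#' Cross-tabulates quantitative scan verdicts against the standard of truth
#' (e.g. the clinical follow-up diagnosis).
#'
#' @param verdicts a list of [classify_scan()] verdicts, or a data.frame
#'   with columns `subject_id` and `scan_abnormal`.
#' @param truth named logical vector: `TRUE` = truly abnormal, names are
#'   subject ids.
#' @return An object of class `confusion_table` with fields `tp`, `fp`,
#'   `tn`, `fn`.
#' @export
confusion <- function(verdicts, truth) {
  if (is.list(verdicts) && !is.data.frame(verdicts) &&
      all(vapply(verdicts, inherits, TRUE, "scan_verdict"))) {
    verdicts <- data.frame(
      subject_id = vapply(verdicts, `[[`, "", "subject_id"),
      scan_abnormal = vapply(verdicts, `[[`, TRUE, "scan_abnormal"),
      stringsAsFactors = FALSE)
  }
  missing <- setdiff(verdicts$subject_id, names(truth))
  if (length(missing))
    stop("no truth label for subject(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  t_abn <- as.logical(truth[verdicts$subject_id])
  v_abn <- as.logical(verdicts$scan_abnormal)
  structure(list(tp = sum(v_abn & t_abn), fp = sum(v_abn & !t_abn),
                 tn = sum(!v_abn & !t_abn), fn = sum(!v_abn & t_abn)),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  cat(sprintf("<confusion_table> TP %d  FP %d  TN %d  FN %d\n",
              x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

# Round half away from zero (the convention of clinical tables), avoiding
# R's round-half-even.
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Sensitivity and specificity (percent, one decimal)
#'
#' `sensitivity = 100 * tp / (tp + fn)`; `specificity = 100 * tn /
#' (tn + fp)`; both rounded half away from zero to one decimal place.
#'
#' @param t a [confusion()] table.
#' @return percentage.
#' @export
sensitivity <- function(t) {
  stopifnot(inherits(t, "confusion_table"))
  if (t$tp + t$fn == 0)
    stop("sensitivity undefined: no truth-abnormal subjects", call. = FALSE)
  round_half_up(100 * t$tp / (t$tp + t$fn), 1)
}

#' @rdname sensitivity
#' @export
specificity <- function(t) {
  stopifnot(inherits(t, "confusion_table"))
  if (t$tn + t$fp == 0)
    stop("specificity undefined: no truth-normal subjects", call. = FALSE)
  round_half_up(100 * t$tn / (t$tn + t$fp), 1)
}

# ---- ROC / DeLong ----------------------------------------------------------

# Mid-rank placement components of the Mann-Whitney AUC (DeLong et al.):
# for positives x and negatives y, V10[i] = mean_j psi(x_i, y_j) and
# V01[j] = mean_i psi(x_i, y_j), psi = 1, 1/2, 0 for >, =, <.
delong_placements <- function(pos, neg) {
  m <- length(pos); n <- length(neg)
  all_r <- rank(c(pos, neg), ties.method = "average")
  r_pos <- rank(pos, ties.method = "average")
  r_neg <- rank(neg, ties.method = "average")
  v10 <- (all_r[seq_len(m)] - r_pos) / n
  v01 <- 1 - (all_r[m + seq_len(n)] - r_neg) / m
  auc <- (sum(all_r[seq_len(m)]) / m - (m + 1) / 2) / n
  list(auc = auc, v10 = v10, v01 = v01, m = m, n = n)
}

split_scores <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length", call. = FALSE)
  if (any(!is.finite(scores))) stop("non-finite scores", call. = FALSE)
  if (!any(labels) || all(labels))
    stop("both classes (abnormal and normal) must be present", call. = FALSE)
  # lower SBR = more abnormal; negate so larger score = positive class
  list(pos = -scores[labels], neg = -scores[!labels])
}

#' ROC AUC with DeLong confidence interval
#'
#' Nonparametric (Mann-Whitney) area under the ROC curve, ties counting
#' one half, for an SBR-like score where *lower* values indicate
#' abnormality (scores are negated internally so that AUC >= 0.5 means
#' discrimination in the expected direction). The confidence interval uses
#' the DeLong variance estimator, truncated to [0, 1].
#'
#' @param scores numeric scores (e.g. scan-level SBR).
#' @param labels logical: `TRUE` = truly abnormal.
#' @param conf_level confidence level for the CI.
#' @return list with `auc`, `se`, `ci` (length 2), `n_abnormal`, `n_normal`.
#' @export
roc_auc <- function(scores, labels, conf_level = 0.95) {
  s <- split_scores(scores, labels)
  pl <- delong_placements(s$pos, s$neg)
  v <- if (pl$m > 1 && pl$n > 1)
    stats::var(pl$v10) / pl$m + stats::var(pl$v01) / pl$n
  else NA_real_
  se <- sqrt(v)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- if (is.finite(se)) pmin(pmax(pl$auc + c(-1, 1) * z * se, 0), 1)
  else c(NA_real_, NA_real_)
  list(auc = pl$auc, se = se, ci = ci, n_abnormal = pl$m, n_normal = pl$n)
}

#' Paired comparison of two correlated AUCs (DeLong test)
#'
#' Tests the AUC difference of two scores measured on the same subjects.
#' The covariance of the two AUCs is estimated from the paired DeLong
#' placement components; `z = (AUC_A - AUC_B) / sqrt(var)` with a two-sided
#' normal p-value. Identical scores give `z = 0`, `p = 1` by convention.
#'
#' @param scores_a,scores_b scores of methods A and B (same subjects, same
#'   order; lower = more abnormal).
#' @param labels logical truth, `TRUE` = abnormal.
#' @return list with `auc_a`, `auc_b`, `diff`, `se`, `z`, `p_value`.
#' @export
compare_auc_paired <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b))
    stop("paired scores must have equal length", call. = FALSE)
  sa <- split_scores(scores_a, labels)
  sb <- split_scores(scores_b, labels)
  pa <- delong_placements(sa$pos, sa$neg)
  pb <- delong_placements(sb$pos, sb$neg)
  d <- pa$auc - pb$auc
  if (pa$m < 2 || pa$n < 2)
    stop("paired AUC variance degenerate: need at least 2 subjects per class",
         call. = FALSE)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / pa$m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / pa$n
  if (v <= 0) {
    if (abs(d) < .Machine$double.eps^0.5)
      return(list(auc_a = pa$auc, auc_b = pb$auc, diff = 0, se = 0,
                  z = 0, p_value = 1))
    stop("degenerate variance in paired AUC comparison", call. = FALSE)
  }
  z <- d / sqrt(v)
  list(auc_a = pa$auc, auc_b = pb$auc, diff = d, se = sqrt(v), z = z,
       p_value = 2 * stats::pnorm(-abs(z)))
}

#' Two-tailed McNemar chi-square test
#'
#' Paired comparison of two classifiers from their discordant counts:
#' `chi2 = (|b - c| - correction)^2 / (b + c)` with 1 degree of freedom,
#' where `b` and `c` are the subjects misjudged by only one of the two
#' methods. Defaults to no continuity correction.
#'
#' @param n_discordant_a_only count where only method A disagrees with truth.
#' @param n_discordant_b_only count where only method B disagrees with truth.
#' @param continuity_correction subtract 1 from `|b - c|` (Yates/Edwards).
#' @return list with `statistic` (chi-square), `p_value`, `b`, `c`.
#' @export
mcnemar_test <- function(n_discordant_a_only, n_discordant_b_only,
                         continuity_correction = FALSE) {
  b <- n_discordant_a_only; c <- n_discordant_b_only
  if (b < 0 || c < 0 || b != round(b) || c != round(c))
    stop("discordant counts must be non-negative integers", call. = FALSE)
  if (b + c == 0)
    stop("McNemar test undefined: no discordant pairs", call. = FALSE)
  corr <- if (continuity_correction) 1 else 0
  stat <- (max(abs(b - c) - corr, 0))^2 / (b + c)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       b = b, c = c)
}

#' Scan-level score for ROC analysis
#'
#' Reduces a subject's per-region SBRs to one scan score: the minimum SBR
#' over the regions the rule inspects (the most affected side drives the
#' diagnosis). Uses calibrated values when present, measured otherwise.
#'
#' @param records SBR records for a single subject.
#' @param rule scan rule id, see [rule_regions()].
#' @param use_calibrated prefer `calibrated_sbr` when available.
#' @return numeric scan score.
#' @export
scan_score <- function(records, rule, use_calibrated = TRUE) {
  need <- rule_regions(rule)
  vals <- numeric(nrow(need))
  for (i in seq_len(nrow(need))) {
    hit <- records$side == need$side[i] &
      records$structure == need$structure[i]
    if (!any(hit))
      stop("rule ", rule, " needs region ", need$side[i], "/",
           need$structure[i], " but it is missing", call. = FALSE)
    v <- if (use_calibrated && any(is.finite(records$calibrated_sbr[hit])))
      records$calibrated_sbr[hit] else records$measured_sbr[hit]
    vals[i] <- min(v[is.finite(v)])
  }
  min(vals)
}
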