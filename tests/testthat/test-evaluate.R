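make_verdicts <- function(truth, wrong_ids = character(0)) {
  data.frame(subject_id = names(truth),
             scan_abnormal = ifelse(names(truth) %in% wrong_ids,
                                    !truth, truth),
             stringsAsFactors = FALSE)
}

test_that("confusion tables cross-tabulate verdicts against truth", {
  truth <- setNames(rep(c(TRUE, FALSE), c(43, 34)), sprintf("S%02d", 1:77))
  all_right <- confusion(make_verdicts(truth), truth)
  expect_equal(c(all_right$fp, all_right$fn), c(0, 0))
  # 4 of 43 abnormal subjects called normal
  ct <- confusion(make_verdicts(truth, wrong_ids = sprintf("S%02d", 1:4)),
                  truth)
  expect_equal(ct$fn, 4)
  expect_equal(ct$tp, 39)
  empty <- confusion(data.frame(subject_id = character(0),
                                scan_abnormal = logical(0)), truth)
  expect_equal(unlist(empty[c("tp", "fp", "tn", "fn")]),
               c(tp = 0, fp = 0, tn = 0, fn = 0))
  expect_error(confusion(data.frame(subject_id = "ghost",
                                    scan_abnormal = TRUE), truth), "ghost")
})

test_that("sensitivity and specificity print to one decimal like the tables", {
  ct <- structure(list(tp = 39, fp = 6, tn = 28, fn = 4),
                  class = "confusion_table")
  expect_equal(sensitivity(ct), 90.7)
  expect_equal(specificity(ct), 82.4)
  perfect <- structure(list(tp = 10, fp = 0, tn = 5, fn = 0),
                       class = "confusion_table")
  expect_equal(sensitivity(perfect), 100.0)
  none <- structure(list(tp = 0, fp = 0, tn = 5, fn = 0),
                    class = "confusion_table")
  expect_error(sensitivity(none), "undefined")
})

test_that("roc_auc equals the exhaustive pair-count oracle", {
  # 6-point toy set with a tie
  scores <- c(1, 2, 2, 3, 4, 5)
  labels <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)
  expect_equal(roc_auc(scores, labels)$auc, brute_force_auc(scores, labels))
  # random instances, including heavy ties
  withr::with_seed(90, {
    for (i in 1:50) {
      n <- sample(5:30, 1)
      labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
      if (all(labels) || !any(labels)) labels[1:2] <- c(TRUE, FALSE)
      scores <- sample(1:8, n, replace = TRUE) + 0.5 * rbinom(n, 1, 0.5)
      expect_equal(roc_auc(scores, labels)$auc,
                   brute_force_auc(scores, labels), tolerance = 1e-12)
    }
  })
})

test_that("roc_auc orientation and edge behaviour", {
  # lower SBR = abnormal: perfectly separated scores give AUC 1
  r <- roc_auc(c(1, 2, 3, 7, 8, 9), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(r$auc, 1)
  expect_true(r$ci[1] <= 1 && r$ci[2] <= 1)
  null <- withr::with_seed(13, roc_auc(rnorm(2000), rep(c(TRUE, FALSE), 1000)))
  expect_equal(null$auc, 0.5, tolerance = 0.05)
  expect_error(roc_auc(1:5, rep(TRUE, 5)), "both classes")
})

test_that("paired AUC comparison behaves like the DeLong test", {
  labels <- rep(c(TRUE, FALSE), each = 100)
  sim <- withr::with_seed(55, {
    good <- ifelse(labels, 0, 3) + rnorm(200)   # lower = abnormal
    noise <- rnorm(200)
    list(good = good, noise = noise)
  })
  same <- compare_auc_paired(sim$good, sim$good, labels)
  expect_equal(same$z, 0)
  expect_equal(same$p_value, 1)
  diff <- compare_auc_paired(sim$good, sim$noise, labels)
  expect_lt(diff$p_value, 0.001)
  swapped <- compare_auc_paired(sim$noise, sim$good, labels)
  expect_equal(swapped$z, -diff$z, tolerance = 1e-12)
  expect_equal(swapped$p_value, diff$p_value, tolerance = 1e-12)
  expect_error(compare_auc_paired(sim$good[1:4], sim$noise, labels),
               "equal length")
  expect_error(compare_auc_paired(c(1, 2), c(2, 1), c(TRUE, FALSE)),
               "at least 2")
})

test_that("McNemar test matches its closed form", {
  sym <- mcnemar_test(5, 5)
  expect_equal(sym$statistic, 0)
  expect_equal(sym$p_value, 1)
  m <- mcnemar_test(10, 2)
  expect_equal(m$statistic, 16 / 3, tolerance = 1e-12)
  expect_equal(m$p_value, 2 * pnorm(-sqrt(16 / 3)), tolerance = 1e-12)
  expect_equal(m$p_value, 0.0209, tolerance = 5e-3)
  expect_error(mcnemar_test(0, 0), "no discordant")
  # depends only on discordant counts by construction; corrected variant
  mc <- mcnemar_test(10, 2, continuity_correction = TRUE)
  expect_equal(mc$statistic, 49 / 12, tolerance = 1e-12)
})

test_that("scan scores take the minimum over the rule's regions", {
  recs <- data.frame(side = c("left", "right", "left", "right"),
                     structure = c("striatum", "striatum",
                                   "putamen", "putamen"),
                     measured_sbr = c(2, 4, 1.5, 3.5),
                     calibrated_sbr = NA_real_)
  expect_equal(scan_score(recs, "striatum_either_side"), 2)
  expect_equal(scan_score(recs, "putamen_either_side"), 1.5)
  sym <- recs; sym$measured_sbr <- c(3, 3, 2, 2)
  expect_equal(scan_score(sym, "striatum_either_side"), 3)
  expect_error(scan_score(recs[1:2, ], "putamen_either_side"), "missing")
  # calibrated values take precedence when present
  recs$calibrated_sbr <- recs$measured_sbr * 2
  expect_equal(scan_score(recs, "striatum_either_side"), 4)
})

test_that("min-score beats mean-score ROC on asymmetric disease", {
  sim <- withr::with_seed(40, {
    n_ab <- 150; n_no <- 150
    # normals: symmetric around 7; abnormal: one side drops hard
    left_no <- rnorm(n_no, 7, 0.8); right_no <- rnorm(n_no, 7, 0.8)
    base <- rnorm(n_ab, 7, 0.8)
    worse <- base * runif(n_ab, 0.3, 0.8)
    better <- base * runif(n_ab, 0.8, 1.0)
    flip <- runif(n_ab) < 0.5
    left_ab <- ifelse(flip, worse, better)
    right_ab <- ifelse(flip, better, worse)
    list(left = c(left_ab, left_no), right = c(right_ab, right_no),
         labels = rep(c(TRUE, FALSE), c(n_ab, n_no)))
  })
  auc_min <- roc_auc(pmin(sim$left, sim$right), sim$labels)$auc
  auc_mean <- roc_auc((sim$left + sim$right) / 2, sim$labels)$auc
  expect_gte(auc_min, auc_mean)
})
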