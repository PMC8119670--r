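test_that("confusion matrix tallies match brute-force counting", {
  perfect <- confusion_matrix(c("live", "dead"), c("live", "dead"))
  expect_identical(perfect["live", "dead"] + perfect["dead", "live"], 0L)
  all_live <- confusion_matrix(rep("live", 4), c("live", "live", "dead", "dead"))
  expect_identical(sum(all_live[, "dead"]), 0L)
  withr::with_seed(40, {
    for (i in 1:20) {
      p <- sample(c("live", "dead"), 30, TRUE)
      t <- sample(c("live", "dead"), 30, TRUE)
      expect_identical(confusion_matrix(p, t), oracle_confusion(p, t))
    }
  })
  expect_error(confusion_matrix("live", c("live", "dead")), "length mismatch")
})

test_that("balanced accuracy is the mean per-class recall", {
  expect_identical(balanced_accuracy(matrix(c(10L, 0L, 0L, 5L), 2, 2)), 1)
  one_sided <- confusion_matrix(rep("live", 10),
                                rep(c("live", "dead"), each = 5))
  expect_identical(balanced_accuracy(one_sided), 0.5)
  m <- matrix(c(90, 30, 10, 70), 2, 2) # rows truth: (90,10) and (30,70)
  expect_equal(balanced_accuracy(m), 0.8, tolerance = 1e-15)
  expect_error(balanced_accuracy(matrix(c(3L, 0L, 1L, 0L), 2, 2)),
               "at least one sample")
  withr::with_seed(41, {
    p <- sample(c("live", "dead"), 200, TRUE)
    t <- sample(c("live", "dead"), 200, TRUE)
    expect_equal(balanced_accuracy(confusion_matrix(p, t)),
                 oracle_balanced_accuracy(p, t), tolerance = 1e-15)
  })
})

test_that("AUC equals all-pairs concordance and is rank-invariant", {
  sep <- roc_auc(c(0.9, 0.8, 0.2, 0.1), c("live", "live", "dead", "dead"))
  expect_identical(sep$auc, 1)
  ties <- roc_auc(rep(0.5, 6), rep(c("live", "dead"), 3))
  expect_identical(ties$auc, 0.5)
  withr::with_seed(42, {
    for (i in 1:5) {
      n <- 200
      truth <- sample(c("live", "dead"), n, TRUE)
      scores <- round(runif(n), 2) # coarse grid forces ties
      got <- roc_auc(scores, truth)$auc
      expect_equal(got, oracle_auc(scores, truth), tolerance = 1e-12)
      # strictly monotone transforms leave the AUC unchanged
      expect_equal(roc_auc(stats::qlogis(scores / 2 + 0.25), truth)$auc, got,
                   tolerance = 1e-12)
    }
  })
  expect_error(roc_auc(runif(5), rep("live", 5)), "both classes")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(43, {
    truth <- sample(c("live", "dead"), 150, TRUE)
    scores <- runif(150) + (truth == "live") * 0.3
  })
  ours <- roc_auc(scores, truth)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(response = truth, predictor = scores,
                                        levels = c("dead", "live"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("ROC curve starts at (0,0), ends at (1,1) and is monotone", {
  withr::with_seed(44, {
    truth <- sample(c("live", "dead"), 60, TRUE)
    scores <- runif(60)
  })
  curve <- roc_auc(scores, truth)$curve
  expect_identical(c(curve$fpr[1], curve$tpr[1]), c(0, 0))
  expect_identical(c(dplyr::last(curve$fpr), dplyr::last(curve$tpr)), c(1, 1))
  expect_true(all(diff(curve$fpr) >= 0))
  expect_true(all(diff(curve$tpr) >= 0))
})

test_that("bootstrap CI collapses for a zero-variance metric and covers truth", {
  ba_metric <- function(p, t) balanced_accuracy(confusion_matrix(p, t))
  truth <- rep(c("live", "dead"), each = 20)
  ci <- bootstrap_ci(ba_metric, truth, truth, n_boot = 100, seed = 1)
  expect_identical(ci, c(1, 1))
  withr::with_seed(45, {
    pred <- ifelse(runif(40) < 0.85, truth, ifelse(truth == "live", "dead", "live"))
  })
  est <- ba_metric(pred, truth)
  ci2 <- bootstrap_ci(ba_metric, pred, truth, n_boot = 300, seed = 2)
  expect_lte(ci2[1], est)
  expect_gte(ci2[2], est)
  expect_error(bootstrap_ci(ba_metric, pred[1:10], truth[1:10]), "n >= 30")
})

test_that("bootstrap CI coverage reaches nominal order on simulated tests", {
  ba_metric <- function(p, t) balanced_accuracy(confusion_matrix(p, t))
  acc <- 0.8
  covered <- withr::with_seed(46, {
    vapply(1:200, function(r) {
      truth <- rep(c("live", "dead"), each = 30)
      flip <- runif(60) > acc
      pred <- ifelse(flip, ifelse(truth == "live", "dead", "live"), truth)
      ci <- bootstrap_ci(ba_metric, pred, truth, n_boot = 200)
      ci[1] <= acc && acc <= ci[2]
    }, logical(1))
  })
  expect_gte(mean(covered), 0.9)
})

test_that("the fluorescence-score correlation matches the direct formula", {
  fl <- seq(100, 700, length.out = 50)
  exact <- fluorescence_score_correlation(fl, -0.001 * fl + 1)
  expect_equal(exact$r, -1, tolerance = 1e-12)
  withr::with_seed(47, {
    a <- rnorm(400); b <- rnorm(400)
  })
  got <- fluorescence_score_correlation(a, b)
  oracle_r <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(got$r, oracle_r, tolerance = 1e-12)
  expect_lt(abs(got$r), 0.15) # independent vectors hover near zero
  expect_error(fluorescence_score_correlation(rep(1, 10), rnorm(10)),
               "zero variance")
  expect_error(fluorescence_score_correlation(1:2, 1:2), "at least 3")
})

test_that("the evaluation report is internally consistent", {
  study <- synthetic_study()
  rep <- study$report
  expect_identical(sum(rep$confusion), rep$n_test)
  expect_equal(rep$balanced_accuracy,
               oracle_balanced_accuracy(rep$predictions$label,
                                        study$test$label),
               tolerance = 1e-12)
  expect_equal(rep$auc, oracle_auc(rep$predictions$p_live, study$test$label),
               tolerance = 1e-12)
})
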