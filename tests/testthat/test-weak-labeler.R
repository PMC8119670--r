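test_that("mean fluorescence is the plain pixel average", {
  expect_identical(mean_fluorescence(matrix(0, 5, 5)), 0)
  expect_identical(mean_fluorescence(matrix(100, 7, 3)), 100)
  x <- withr::with_seed(1, matrix(runif(224 * 224, 0, 65535), 224, 224))
  expect_equal(mean_fluorescence(x), sum(x) / length(x), tolerance = 1e-14)
  expect_error(mean_fluorescence(numeric(0)), "empty")
})

test_that("EM refit recovers the printed component means from simulation", {
  mix <- paper_mixture()
  x <- sample_fluorescence_means(mix, 20000, seed = 301)
  fit <- fit_mixture(x, n_restarts = 10, seed = 301)
  se_live <- mix$sigma_live / sqrt(20000 * 0.5)
  se_dead <- mix$sigma_dead / sqrt(20000 * 0.5)
  expect_lt(abs(fit$mu_live - mix$mu_live), 3 * se_live + 1e-9)
  expect_lt(abs(fit$mu_dead - mix$mu_dead), 3 * se_dead + 1e-9)
  expect_true(fit$mu_live < fit$mu_dead)
  expect_true(fit$converged)
})

test_that("mixture-fit bias stays below 2% across seeds for separated components", {
  mix <- paper_mixture()
  # separation 325.9 exceeds twice the combined sigma (2 * 157.4)
  expect_gt(mix$mu_dead - mix$mu_live,
            2 * sqrt(mix$sigma_live^2 + mix$sigma_dead^2))
  fits <- lapply(1:20, function(s) {
    x <- sample_fluorescence_means(mix, 5000, seed = 400 + s)
    fit_mixture(x, n_restarts = 5, seed = 400 + s)
  })
  bias_live <- mean(vapply(fits, function(f) f$mu_live, numeric(1))) - mix$mu_live
  bias_dead <- mean(vapply(fits, function(f) f$mu_dead, numeric(1))) - mix$mu_dead
  expect_lt(abs(bias_live) / mix$mu_live, 0.02)
  expect_lt(abs(bias_dead) / mix$mu_dead, 0.02)
})

test_that("the returned fit dominates every restart's log-likelihood", {
  x <- sample_fluorescence_means(paper_mixture(), 2000, seed = 17)
  fit <- fit_mixture(x, n_restarts = 8, seed = 17)
  expect_true(all(fit$loglik >= fit$restarts - 1e-6))
})

test_that("two constant clusters collapse to their exact means", {
  x <- c(rep(0, 50), rep(1000, 50))
  fit <- fit_mixture(x, seed = 2)
  expect_equal(fit$mu_live, 0, tolerance = 1e-6)
  expect_equal(fit$mu_dead, 1000, tolerance = 1e-3)
  expect_lt(fit$sigma_live, 1)
  expect_lt(fit$sigma_dead, 1)
})

test_that("the EM fit agrees with an independent mixture implementation", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust") # Mclust resolves helpers only when attached
  x <- sample_fluorescence_means(paper_mixture(), 5000, seed = 99)
  fit <- fit_mixture(x, seed = 99)
  ref <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  ref_mu <- unname(sort(ref$parameters$mean))
  expect_equal(fit$mu_live, ref_mu[1], tolerance = 0.01)
  expect_equal(fit$mu_dead, ref_mu[2], tolerance = 0.01)
})

test_that("fit_mixture enforces its preconditions", {
  expect_error(fit_mixture(c(1, 2, 3)), "at least 10")
  expect_error(fit_mixture(c(rnorm(20), NA)), "finite")
})

test_that("threshold arithmetic is exact and refuses degenerate bands", {
  th <- derive_thresholds(paper_mixture())
  expect_equal(th$live_max, 258.97, tolerance = 1e-12)
  expect_equal(th$dead_min, 396.89, tolerance = 1e-12)
  # zero sigmas: thresholds sit exactly on the component means
  th0 <- derive_thresholds(list(mu_live = 100, sigma_live = 0,
                                mu_dead = 500, sigma_dead = 0))
  expect_identical(c(th0$live_max, th0$dead_min), c(100, 500))
  expect_error(derive_thresholds(list(mu_live = 300, sigma_live = 100,
                                      mu_dead = 420, sigma_dead = 100)),
               "no discard band")
  # random valid models against the direct-arithmetic oracle, exactly
  withr::with_seed(6, {
    for (i in 1:1000) {
      mu1 <- runif(1, 0, 300); s1 <- runif(1, 0, 50)
      mu2 <- mu1 + runif(1, 200, 600); s2 <- runif(1, 0, 80)
      th_i <- derive_thresholds(list(mu_live = mu1, sigma_live = s1,
                                     mu_dead = mu2, sigma_dead = s2))
      expect_identical(th_i$live_max, mu1 + s1)
      expect_identical(th_i$dead_min, mu2 - s2)
    }
  })
})

test_that("labels follow the open discard band with boundaries discarded", {
  th <- derive_thresholds(paper_mixture())
  expect_identical(assign_label(250, th), "live")
  expect_identical(assign_label(300, th), "discarded")
  expect_identical(assign_label(400, th), "dead")
  expect_identical(assign_label(c(th$live_max, th$dead_min), th),
                   c("discarded", "discarded"))
})

test_that("label monotonicity: higher mean never moves toward live", {
  th <- derive_thresholds(paper_mixture())
  m <- sort(withr::with_seed(3, runif(500, 0, 900)))
  rank_of <- c(live = 1, discarded = 2, dead = 3)
  ranks <- rank_of[assign_label(m, th)]
  expect_true(all(diff(ranks) >= 0))
})

test_that("label_dataset partitions every patch and counts by class", {
  th <- derive_thresholds(paper_mixture())
  empty <- label_dataset(tibble::tibble(patch_id = character(),
                                        fluorescence = list()), th)
  expect_identical(nrow(empty), 0L)
  expect_true(all(label_summary(empty)$n == 0))
  means <- withr::with_seed(8, runif(300, 0, 900))
  d <- tibble::tibble(patch_id = sprintf("p%03d", 1:300),
                      mean_fluorescence = means)
  lab <- label_dataset(d, th)
  expect_identical(nrow(lab), 300L)
  expect_identical(sum(label_summary(lab)$n), 300L)
  expect_identical(lab$label, assign_label(means, th))
})

test_that("weak labels agree with ground-truth state outside the discard band", {
  study <- synthetic_study()
  gt <- study$ground_truth
  th <- study$thresholds
  labels <- assign_label(gt$mean_fluorescence, th)
  outside <- labels != "discarded" & !gt$empty
  agree <- labels[outside] == gt$state[outside]
  expect_gte(mean(agree), 0.95)
})

test_that("one set of thresholds labels both conditions without refitting", {
  th <- derive_thresholds(paper_mixture())
  treated <- synthetic_config(n_raw_images = 1, image_width = 448,
                              image_height = 448, condition = "treated",
                              cells_per_image = c(8, 12), rng_seed = 61)
  g <- generate_raw_pair(treated, 1)
  p <- crop_patches(g$pair, stride = 224)
  lab <- label_dataset(p, th)
  expect_identical(nrow(lab), 4L)
  expect_true(all(lab$label %in% c("live", "dead", "discarded")))
  # treated-like data skew heavily dead under the imbalanced default
  expect_gte(sum(lab$label == "dead"), 2L)
})
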