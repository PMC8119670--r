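test_that("config validation rejects unusable settings", {
  expect_error(synthetic_config(image_width = 200, image_height = 448),
               "smaller than one")
  expect_error(synthetic_config(fluor_mixture = list(mu_live = 600)),
               "mu_live < mu_dead")
  expect_error(synthetic_config(fluor_mixture = list(sigma_live = 0)),
               "sigmas")
  expect_error(synthetic_config(frac_empty_regions = 1.2), "\\[0, 1\\]")
  expect_error(synthetic_config(cells_per_image = c(10, 5)), "range")
})

test_that("same (seed, index) gives bit-identical output, other indices differ", {
  cfg <- synthetic_config(n_raw_images = 2, image_width = 224,
                          image_height = 224, cells_per_image = c(4, 8),
                          rng_seed = 9)
  a <- generate_raw_pair(cfg, 1)
  b <- generate_raw_pair(cfg, 1)
  expect_identical(a$pair$bright_field, b$pair$bright_field)
  expect_identical(a$pair$fluorescence, b$pair$fluorescence)
  expect_identical(a$ground_truth$mean_fluorescence,
                   b$ground_truth$mean_fluorescence)
  c2 <- generate_raw_pair(cfg, 2)
  expect_false(identical(a$pair$fluorescence, c2$pair$fluorescence))
})

test_that("no dead cells and no noise leaves fluorescence flat per region", {
  cfg <- synthetic_config(n_raw_images = 1, image_width = 448,
                          image_height = 448, frac_dead_cells = 0,
                          frac_empty_regions = 0.25, noise_sd = 0,
                          cells_per_image = c(4, 8), rng_seed = 21)
  g <- generate_raw_pair(cfg, 1)
  expect_true(all(g$ground_truth$state != "dead"))
  for (i in seq_len(nrow(g$ground_truth))) {
    ys <- g$ground_truth$y_offset[i] + 1:224
    xs <- g$ground_truth$x_offset[i] + 1:224
    reg <- g$pair$fluorescence[ys, xs]
    # no PI signal: the channel is its flat background (one value per region)
    expect_lte(diff(range(reg)), 1L)
  }
})

test_that("with only dead cells every patch mean clears the dead threshold", {
  cfg <- synthetic_config(n_raw_images = 1, image_width = 448,
                          image_height = 672, frac_dead_cells = 1,
                          frac_empty_regions = 0, cells_per_image = c(12, 18),
                          rng_seed = 33)
  g <- generate_raw_pair(cfg, 1)
  dead_min <- cfg$fluor_mixture$mu_dead - cfg$fluor_mixture$sigma_dead
  for (i in seq_len(nrow(g$ground_truth))) {
    ys <- g$ground_truth$y_offset[i] + 1:224
    xs <- g$ground_truth$x_offset[i] + 1:224
    # direct pixel-average oracle, independent of the stored record
    m <- sum(g$pair$fluorescence[ys, xs]) / (224 * 224)
    expect_gt(m, dead_min)
  }
})

test_that("empty-region fraction matches the configured rate within 3 sigma", {
  cfg <- synthetic_config(n_raw_images = 25, image_width = 672,
                          image_height = 448, frac_empty_regions = 0.2,
                          cells_per_image = c(8, 16), rng_seed = 55)
  empty <- unlist(lapply(seq_len(25), function(i) {
    generate_raw_pair(cfg, i)$ground_truth$empty
  }))
  p_hat <- mean(empty)
  se <- sqrt(0.2 * 0.8 / length(empty))
  expect_lt(abs(p_hat - 0.2), 3 * se)
})

test_that("non-empty patch means are bimodal for well-separated components", {
  cfg <- synthetic_config(n_raw_images = 12, image_width = 672,
                          image_height = 448,
                          fluor_mixture = list(sigma_dead = 80),
                          cells_per_image = c(10, 16), rng_seed = 70)
  m <- cfg$fluor_mixture
  expect_gt(m$mu_dead - m$mu_live, 3 * max(m$sigma_live, m$sigma_dead))
  gt <- dplyr::bind_rows(lapply(seq_len(12), function(i) {
    generate_raw_pair(cfg, i)$ground_truth
  }))
  means <- gt$mean_fluorescence[!gt$empty]
  expect_gte(count_modes(means), 2)
})

test_that("mixture sampler honours degenerate and analytic properties", {
  mix <- paper_mixture()
  expect_error(sample_fluorescence_means(mix, 0), "n must be")
  bad <- mix; bad$sigma_live <- -1
  expect_error(sample_fluorescence_means(bad, 10), "sigmas")
  degen <- mix; degen$sigma_live <- 0; degen$sigma_dead <- 0
  draws <- sample_fluorescence_means(degen, 500, seed = 3)
  expect_true(all(draws %in% c(mix$mu_live, mix$mu_dead)))
  # sample mean within 3 standard errors of the closed-form mixture mean
  n <- 10000
  x <- sample_fluorescence_means(mix, n, seed = 8)
  mu <- mix$weight_live * mix$mu_live + (1 - mix$weight_live) * mix$mu_dead
  second <- mix$weight_live * (mix$sigma_live^2 + mix$mu_live^2) +
    (1 - mix$weight_live) * (mix$sigma_dead^2 + mix$mu_dead^2)
  se <- sqrt((second - mu^2) / n)
  expect_lt(abs(mean(x) - mu), 3 * se)
})

test_that("a sampled histogram of the printed mixture is bimodal", {
  x <- sample_fluorescence_means(paper_mixture(), 20000, seed = 101)
  expect_gte(count_modes(x), 2)
})

test_that("generate_dataset writes a loadable, faithful on-disk copy", {
  dir <- withr::local_tempdir()
  cfg <- synthetic_config(n_raw_images = 2, image_width = 224,
                          image_height = 224, cells_per_image = c(3, 6),
                          rng_seed = 12)
  out <- generate_dataset(cfg, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(file.exists(file.path(dir, "config.json")))
  loaded <- load_dataset(file.path(dir, "manifest.csv"))
  expect_length(loaded$pairs, 2)
  expect_identical(nrow(loaded$unpaired), 0L)
  ref <- generate_raw_pair(cfg, 1)$pair
  got <- loaded$pairs[[which(vapply(loaded$pairs, function(p) p$raw_image_id,
                                    character(1)) == ref$raw_image_id)]]
  expect_identical(got$fluorescence, ref$fluorescence)
  expect_identical(got$bright_field, ref$bright_field)
})
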