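# Shared fixtures, built lazily once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

# Render a single 224 x 224 region patch of a given state via the
# generator's region renderer; returns raw 16-bit bf / fl matrices.
make_region_patch <- function(state, seed, n_cells = 4L,
                              cfg = synthetic_config(n_raw_images = 1,
                                                     image_width = 224,
                                                     image_height = 224)) {
  withr::with_seed(seed, {
    stainfree:::render_region(state, if (state == "empty") 0L else n_cells, cfg)
  })
}

# Tibble of rendered patches with 8-bit bright-field, ready for the
# empty-patch filter.
make_patch_set <- function(states, seed0 = 1000L) {
  bf <- vector("list", length(states))
  for (i in seq_along(states)) {
    bf[[i]] <- convert_16bit_to_8bit(make_region_patch(states[i], seed0 + i)$bf)
  }
  tibble::tibble(patch_id = sprintf("p%04d", seq_along(states)),
                 state = states, bright_field = bf)
}

# The standard synthetic study: generate, label with the printed-parameter
# thresholds, split by raw image, train the tiny backbone, evaluate.
synthetic_study <- function() {
  if (!is.null(.fixture_env$study)) return(.fixture_env$study)
  cfg <- synthetic_config(n_raw_images = 20, image_width = 672,
                          image_height = 448, cells_per_image = c(12, 24),
                          frac_dead_cells = 0.5, frac_empty_regions = 0.1,
                          rng_seed = 11)
  gt <- vector("list", cfg$n_raw_images)
  patches <- vector("list", cfg$n_raw_images)
  for (i in seq_len(cfg$n_raw_images)) {
    g <- generate_raw_pair(cfg, i)
    gt[[i]] <- g$ground_truth
    patches[[i]] <- crop_patches(g$pair, stride = 224)
  }
  patches <- dplyr::bind_rows(patches)
  ground_truth <- dplyr::bind_rows(gt)
  thresholds <- derive_thresholds(cfg$fluor_mixture)
  labeled <- label_dataset(patches, thresholds)
  patches <- patches |>
    dplyr::mutate(bright_field = lapply(bright_field, convert_16bit_to_8bit),
                  mean_fluorescence = labeled$mean_fluorescence,
                  label = labeled$label)
  kept <- dplyr::filter(patches, label != "discarded")
  manifest <- grouped_split(kept, seed = 5)
  tr <- dplyr::filter(manifest, partition == "train")
  va <- dplyr::filter(manifest, partition == "valid")
  te <- dplyr::filter(manifest, partition == "test")
  model <- train_classifier(tr, va, class_weights(table(tr$label)),
                            train_config(learning_rate = 1e-3, epochs = 15,
                                         seed = 2))
  report <- evaluate_classifier(model, te, n_boot = 500, seed = 3)
  .fixture_env$study <- list(config = cfg, ground_truth = ground_truth,
                             patches = patches, thresholds = thresholds,
                             manifest = manifest, train = tr, valid = va,
                             test = te, model = model, report = report)
  .fixture_env$study
}

# A small, trivially separable patch set at reduced input size for fast
# trainer checks: live patches are bright with light texture, dead patches
# dark with a blob.
separable_patch_set <- function(n = 200L, size = 32L, seed = 77L) {
  withr::with_seed(seed, {
    labels <- rep(c("live", "dead"), length.out = n)
    imgs <- lapply(labels, function(lb) {
      base <- if (lb == "live") 190 else 60
      m <- matrix(pmin(pmax(round(base + rnorm(size * size, sd = 12)), 0), 255),
                  size, size)
      m
    })
    tibble::tibble(patch_id = sprintf("sep%04d", seq_len(n)),
                   raw_image_id = sprintf("img%02d", rep(seq_len(20), length.out = n)),
                   label = labels, bright_field = imgs)
  })
}

separable_model <- function() {
  if (!is.null(.fixture_env$sep_model)) return(.fixture_env$sep_model)
  d <- separable_patch_set()
  tr <- d[1:140, ]
  va <- d[141:200, ]
  .fixture_env$sep_model <- list(
    model = train_classifier(tr, va, NULL,
                             train_config(learning_rate = 1e-3, epochs = 30,
                                          seed = 4, input_size = 32L)),
    train = tr, valid = va)
  .fixture_env$sep_model
}
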