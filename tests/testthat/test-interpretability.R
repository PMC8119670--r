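test_that("embeddings give one finite row per patch and equal rows for duplicates", {
  fx <- separable_model()
  pats <- fx$valid[1:6, ]
  emb <- embed_features(fx$model, pats)
  expect_identical(nrow(emb), 6L)
  expect_true(all(is.finite(as.matrix(dplyr::select(emb, dplyr::starts_with("e"))))))
  dup <- pats
  dup$bright_field[[2]] <- dup$bright_field[[1]]
  emb2 <- embed_features(fx$model, dup)
  expect_identical(as.numeric(unlist(emb2[1, grep("^e[0-9]+$", names(emb2))])),
                   as.numeric(unlist(emb2[2, grep("^e[0-9]+$", names(emb2))])))
})

test_that("embeddings of a trained model separate the classes linearly", {
  fx <- separable_model()
  emb <- embed_features(fx$model, fx$valid)
  X <- as.matrix(dplyr::select(emb, dplyr::matches("^e[0-9]+$")))
  y <- emb$label
  centroids <- rbind(colMeans(X[y == "live", , drop = FALSE]),
                     colMeans(X[y == "dead", , drop = FALSE]))
  assign_nearest <- apply(X, 1, function(v) {
    c("live", "dead")[which.min(c(sum((v - centroids[1, ])^2),
                                  sum((v - centroids[2, ])^2)))]
  })
  expect_gte(mean(assign_nearest == y), 0.95)
})

test_that("the 2-D projection is seed-deterministic and size-preserving", {
  withr::with_seed(50, {
    X <- rbind(matrix(rnorm(30 * 5), 30, 5),
               matrix(rnorm(30 * 5, mean = 12), 30, 5))
  })
  colnames(X) <- paste0("e", 1:5)
  feats <- tibble::as_tibble(X)
  feats$patch_id <- sprintf("p%02d", 1:60)
  feats$label <- rep(c("live", "dead"), each = 30)
  p1 <- project_2d(feats, perplexity = 8, seed = 4)
  p2 <- project_2d(feats, perplexity = 8, seed = 4)
  expect_identical(p1$dim1, p2$dim1)
  expect_identical(nrow(p1), 60L)
  expect_error(project_2d(feats, perplexity = 30), "too large")
})

test_that("well-separated clusters keep positive silhouette after projection", {
  skip_if_not_installed("cluster")
  withr::with_seed(51, {
    X <- rbind(matrix(rnorm(40 * 8, sd = 0.5), 40, 8),
               matrix(rnorm(40 * 8, mean = 15, sd = 0.5), 40, 8))
  })
  pr <- project_2d(X, perplexity = 10, seed = 6)
  sil <- cluster::silhouette(rep(1:2, each = 40),
                             stats::dist(cbind(pr$dim1, pr$dim2)))
  expect_gt(mean(sil[, "sil_width"]), 0)
})

test_that("Grad-CAM reproduces the closed-form tiny-network computation", {
  withr::with_seed(52, {
    w1 <- matrix(rnorm(9), 3, 3)
    w2 <- matrix(rnorm(9), 3, 3)
    wd <- matrix(rnorm(4), 2, 2)
  })
  net <- nn_network(
    nn_conv(1L, 2L, weights = cbind(as.numeric(w1), as.numeric(w2)),
            bias = c(0.1, -0.2)),
    nn_gap(),
    nn_dense(2L, 2L, weights = wd, bias = c(0, 0)),
    input_size = 4L)
  model <- list(net = net, class_levels = c("live", "dead"))
  patch <- withr::with_seed(53, matrix(sample(0:255, 16, TRUE), 4, 4))
  cam <- grad_cam(model, patch, target_class = "dead", normalize = FALSE)
  # closed form: A_k = conv_k(x), dlogit/dA_k = wd[k, 2] / 16 everywhere,
  # alpha_k = wd[k, 2] / 16, map = ReLU(sum_k alpha_k A_k)
  x <- patch / 255 - 0.5
  A1 <- oracle_conv3x3(x, w1, 0.1)
  A2 <- oracle_conv3x3(x, w2, -0.2)
  manual <- pmax((wd[1, 2] / 16) * A1 + (wd[2, 2] / 16) * A2, 0)
  expect_equal(cam$raw_map, manual, tolerance = 1e-6)
})

test_that("a logit constant in the input yields an identically zero map", {
  net <- nn_network(
    nn_conv(1L, 2L, weights = matrix(rnorm(18), 9, 2), bias = c(0, 0)),
    nn_gap(),
    nn_dense(2L, 2L, weights = matrix(c(1, 1, 0, 0), 2, 2), bias = c(0, 3)),
    input_size = 4L)
  model <- list(net = net, class_levels = c("live", "dead"))
  patch <- matrix(sample(0:255, 16, TRUE), 4, 4)
  cam <- grad_cam(model, patch, target_class = "dead")
  expect_true(all(cam$heatmap == 0))
})

test_that("activation maps respect the [0,1] x input-size contract", {
  study <- synthetic_study()
  patch <- study$test$bright_field[[1]]
  cam <- grad_cam(study$model, patch, "dead")
  expect_identical(dim(cam$heatmap), c(224L, 224L))
  expect_true(all(cam$heatmap >= 0 & cam$heatmap <= 1))
  expect_error(grad_cam(study$model, patch, "nonsense"), "unknown target")
})

test_that("dead-class heat concentrates on the dead cell's footprint", {
  study <- synthetic_study()
  gt <- study$ground_truth
  dead_regions <- dplyr::filter(gt, state == "dead", n_cells >= 1)
  dead_regions <- utils::head(dead_regions, 10)
  hits <- vapply(seq_len(nrow(dead_regions)), function(i) {
    row <- dead_regions[i, ]
    pid <- sprintf("%s_x%04d_y%04d", row$raw_image_id, row$x_offset,
                   row$y_offset)
    patch <- study$patches$bright_field[[match(pid, study$patches$patch_id)]]
    cam <- grad_cam(study$model, patch, "dead")
    peak <- which(cam$heatmap == max(cam$heatmap), arr.ind = TRUE)[1, ]
    cells <- row$cells[[1]]
    any(sqrt((cells$cx - peak["col"])^2 + (cells$cy - peak["row"])^2) <=
          cells$rx + 40)
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
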