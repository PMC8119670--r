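# Model inspection: penultimate-layer embeddings, 2-D t-SNE projections and
# gradient-weighted class activation maps (Grad-CAM).

#' Penultimate-layer embeddings for a set of patches
#'
#' Runs each patch through the classifier and collects the globally pooled
#' activations of the last convolutional stage (the layer feeding the
#' classification head) as the patch's feature signature.
#'
#' @param model A [train_classifier()] result.
#' @param patches Patch tibble (`bright_field` list-column of 8-bit
#'   matrices) or list of matrices.
#' @return A tibble with `patch_id`, embedding columns `e1 ... eC`, the
#'   predicted label and live probability, and `label` (truth) when present
#'   in `patches`.
#' @export
embed_features <- function(model, patches) {
  stopifnot(inherits(model, "trained_classifier"))
  imgs <- patch_list(patches)
  gap_i <- nn_gap_layer(model$net)
  rows <- lapply(imgs, function(p) {
    fwd <- nn_forward(model$net, prep_input(p), keep = TRUE)
    list(emb = as.numeric(fwd$outputs[[gap_i]]),
         prob = nn_softmax(fwd$logits))
  })
  emb <- t(vapply(rows, function(r) r$emb, rows[[1]]$emb))
  colnames(emb) <- paste0("e", seq_len(ncol(emb)))
  probs <- t(vapply(rows, function(r) r$prob, numeric(2)))
  ids <- if (is.data.frame(patches) && "patch_id" %in% names(patches)) {
    patches$patch_id
  } else {
    sprintf("patch%04d", seq_along(imgs))
  }
  out <- dplyr::bind_cols(
    tibble::tibble(patch_id = ids),
    tibble::as_tibble(emb),
    tibble::tibble(p_live = probs[, 1],
                   predicted = model$class_levels[max.col(probs, ties.method = "first")]))
  if (is.data.frame(patches) && "label" %in% names(patches)) {
    out$label <- patches$label
  }
  out
}

#' Project embeddings to two dimensions with t-SNE
#'
#' @param features An [embed_features()] tibble, or any tibble/matrix whose
#'   numeric `e*`/feature columns form the embedding.
#' @param perplexity t-SNE perplexity (default 30); requires
#'   `n > 3 * perplexity`.
#' @param seed Integer seed; the projection is deterministic given the seed.
#' @param ... Passed to [Rtsne::Rtsne()].
#' @return A tibble with `patch_id` (when available), `dim1`, `dim2` and any
#'   `label` / `predicted` columns carried over.
#' @export
project_2d <- function(features, perplexity = 30, seed = 1L, ...) {
  if (is.matrix(features)) {
    x <- features
    meta <- tibble::tibble(.rows = nrow(x))
  } else {
    num <- dplyr::select(features, dplyr::matches("^(e|f)[0-9]+$"))
    x <- as.matrix(num)
    meta <- dplyr::select(features,
                          dplyr::any_of(c("patch_id", "label", "predicted",
                                          "p_live")))
  }
  n <- nrow(x)
  if (n <= 3 * perplexity) {
    stop("perplexity ", perplexity, " too large for n = ", n,
         " (need n > 3 * perplexity)")
  }
  fit <- withr::with_seed(as.integer(seed), {
    Rtsne::Rtsne(x, dims = 2L, perplexity = perplexity, theta = 0.0,
                 check_duplicates = FALSE, pca = FALSE, verbose = FALSE, ...)
  })
  dplyr::bind_cols(meta, tibble::tibble(dim1 = fit$Y[, 1], dim2 = fit$Y[, 2]))
}

# Bilinear upsampling of a small matrix to size out x out.
upsample_bilinear <- function(m, out) {
  r <- EBImage::resize(m, w = out, h = out)
  matrix(as.numeric(r), out, out)
}

#' Gradient-weighted class activation map (Grad-CAM)
#'
#' Computes the gradient of the target-class logit with respect to the last
#' convolutional layer's activations, averages it spatially into channel
#' weights, and forms the rectified weighted sum of those activations. The
#' map is min-max normalised to \[0, 1\] (an identically zero map stays
#' zero) and bilinearly upsampled to the input size.
#'
#' @param model A [train_classifier()] result, or any [nn_network()] wrapped
#'   in a list with fields `net` and `class_levels`.
#' @param patch 8-bit bright-field matrix of the network's input size.
#' @param target_class `"live"`, `"dead"`, or a logit index.
#' @param normalize Min-max normalise the map (default `TRUE`; `FALSE`
#'   returns the raw rectified weighted sum, useful for closed-form
#'   verification).
#' @return An object of class `activation_map`: list with `heatmap` (input
#'   size square matrix in \[0, 1\]), `raw_map` (pre-upsampling grid),
#'   `target_class` and `probability` (softmax probability of the target
#'   class).
#' @export
grad_cam <- function(model, patch, target_class = "dead", normalize = TRUE) {
  net <- if (inherits(model, "nn_network")) model else model$net
  levels <- if (!is.null(model$class_levels)) model$class_levels else NULL
  ti <- if (is.character(target_class)) {
    if (is.null(levels) || !target_class %in% levels) {
      stop("unknown target class: ", target_class)
    }
    match(target_class, levels)
  } else {
    as.integer(target_class)
  }
  x <- prep_input(patch)
  fwd <- nn_forward(net, x, keep = TRUE)
  k <- length(fwd$logits)
  if (ti < 1 || ti > k) stop("target class index out of range")
  conv_i <- nn_last_conv(net)
  dlogits <- numeric(k)
  dlogits[ti] <- 1
  gr <- nn_gradients(net, fwd, dlogits, stop_at = conv_i)
  A <- fwd$outputs[[conv_i]]          # (h*w) x channels activations
  dA <- gr$d_output[[conv_i]]         # same shape gradients
  alpha <- colMeans(dA)               # spatially averaged channel weights
  cam <- pmax(as.numeric(A %*% alpha), 0)
  side <- as.integer(sqrt(length(cam)))
  raw_map <- matrix(cam, side, side)
  heat <- raw_map
  if (normalize) {
    mx <- max(heat); mn <- min(heat)
    if (mx > mn) {
      heat <- (heat - mn) / (mx - mn)
    } else if (mx > 0) {
      heat[] <- 1 # constant non-zero map
    } # identically zero map stays zero
  }
  heat_up <- upsample_bilinear(heat, nrow(patch))
  if (normalize) heat_up <- pmin(pmax(heat_up, 0), 1)
  structure(list(heatmap = heat_up, raw_map = raw_map,
                 target_class = if (!is.null(levels)) levels[ti] else ti,
                 probability = nn_softmax(fwd$logits)[ti]),
            class = "activation_map")
}

#' @export
print.activation_map <- function(x, ...) {
  cat(sprintf("<activation_map> target '%s' (p = %.3f), %dx%d heatmap\n",
              as.character(x$target_class), x$probability,
              nrow(x$heatmap), ncol(x$heatmap)))
  invisible(x)
}
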