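# Minimal convolutional network engine.
#
# Activations are stored as (h*w) x channels matrices in column-major spatial
# order, so every layer reduces to dense linear algebra: 3x3 same-padding
# convolutions go through an im2col index, pooling through rowsum() over a
# precomputed cell index. The full backward pass is implemented because the
# package needs gradients twice over: for Adam fine-tuning of the classifier
# head and for gradient-weighted class activation maps.

nn_im2col_index <- function(h, w) {
  n <- h * w
  sentinel <- n + 1L # points at an appended zero row (padding)
  rows <- rep.int(seq_len(h), w)
  cols <- rep(seq_len(w), each = h)
  idx <- matrix(sentinel, nrow = n, ncol = 9L)
  o <- 0L
  for (dc in -1:1) {
    for (dr in -1:1) {
      o <- o + 1L
      r2 <- rows + dr
      c2 <- cols + dc
      ok <- r2 >= 1L & r2 <= h & c2 >= 1L & c2 <= w
      idx[ok, o] <- r2[ok] + (c2[ok] - 1L) * h
    }
  }
  idx
}

nn_pool_index <- function(h, w, f) {
  stopifnot(h %% f == 0L, w %% f == 0L)
  rows <- rep.int(seq_len(h), w)
  cols <- rep(seq_len(w), each = h)
  ho <- h %/% f
  ((rows - 1L) %/% f + 1L) + (((cols - 1L) %/% f)) * ho
}

nn_he_init <- function(nr, nc, fan_in) {
  matrix(rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
}

#' Layer constructors for the built-in convolutional engine
#'
#' These low-level constructors assemble the small networks used throughout
#' the package: the trainable `tiny_test` classifier, the fixed random-weight
#' feature extractors behind the empty-patch filter, and the hand-built
#' networks used to verify Grad-CAM against closed-form computation. All
#' convolutions are 3x3, stride 1, zero ("same") padding.
#'
#' @param in_channels,out_channels Channel counts for a convolution.
#' @param weights Optional `(9 * in_channels) x out_channels` weight matrix;
#'   rows are ordered kernel-offset-major (the 9 offsets scan the kernel
#'   column by column, i.e. `(dr, dc)` with `dc` outer), channels inner.
#'   When `NULL`, He-normal initialisation is used.
#' @param bias Optional bias vector of length `out_channels` (default zeros).
#' @param f Pooling factor (window and stride) of an average-pooling layer.
#' @param in_features,out_features Dimensions of a dense (fully connected)
#'   layer; `weights` is then `in_features x out_features`.
#' @return A layer object (a list with a `type` field) to be passed to
#'   [nn_network()].
#' @seealso [nn_network()], [nn_forward()]
#' @export
nn_conv <- function(in_channels, out_channels, weights = NULL, bias = NULL) {
  if (is.null(weights)) {
    weights <- nn_he_init(9L * in_channels, out_channels, 9L * in_channels)
  }
  stopifnot(nrow(weights) == 9L * in_channels, ncol(weights) == out_channels)
  if (is.null(bias)) bias <- numeric(out_channels)
  structure(list(type = "conv", cin = in_channels, cout = out_channels,
                 W = weights, b = bias), class = "nn_layer")
}

#' @rdname nn_conv
#' @export
nn_relu <- function() structure(list(type = "relu"), class = "nn_layer")

#' @rdname nn_conv
#' @export
nn_avgpool <- function(f) {
  stopifnot(f >= 1)
  structure(list(type = "avgpool", f = as.integer(f)), class = "nn_layer")
}

#' @rdname nn_conv
#' @export
nn_gap <- function() structure(list(type = "gap"), class = "nn_layer")

#' @rdname nn_conv
#' @export
nn_dense <- function(in_features, out_features, weights = NULL, bias = NULL) {
  if (is.null(weights)) {
    weights <- nn_he_init(in_features, out_features, in_features)
  }
  stopifnot(nrow(weights) == in_features, ncol(weights) == out_features)
  if (is.null(bias)) bias <- numeric(out_features)
  structure(list(type = "dense", W = weights, b = bias), class = "nn_layer")
}

#' Assemble a network from layers
#'
#' @param ... Layers built with [nn_conv()] and friends, applied in order.
#' @param input_size Side length of the (square, single-channel) input image.
#' @return An object of class `nn_network`.
#' @export
nn_network <- function(..., input_size) {
  layers <- list(...)
  stopifnot(length(layers) >= 1, input_size >= 1)
  structure(list(layers = layers, input_size = as.integer(input_size)),
            class = "nn_network")
}

#' @export
print.nn_network <- function(x, ...) {
  cat("<nn_network> input", x$input_size, "x", x$input_size, "\n")
  for (l in x$layers) {
    cat(" -", l$type,
        if (l$type == "conv") paste0(l$cin, "->", l$cout),
        if (l$type == "avgpool") paste0("f=", l$f),
        if (l$type == "dense") paste0(nrow(l$W), "->", ncol(l$W)), "\n")
  }
  invisible(x)
}

nn_n_params <- function(net) {
  sum(vapply(net$layers, function(l) {
    if (l$type %in% c("conv", "dense")) length(l$W) + length(l$b) else 0L
  }, integer(1)))
}

#' Forward pass through a network
#'
#' @param net An [nn_network()].
#' @param x A square numeric matrix (single-channel image) whose side equals
#'   the network's `input_size`. Callers are responsible for intensity
#'   scaling (the classifiers in this package feed 8-bit images divided by
#'   255).
#' @param keep Keep per-layer outputs and backward caches (needed by
#'   [nn_gradients()], Grad-CAM and embedding extraction).
#' @return A list with `logits` (numeric vector) and, when `keep = TRUE`,
#'   `outputs` (per-layer activations as `(h*w) x channels` matrices) and
#'   internal caches.
#' @export
nn_forward <- function(net, x, keep = FALSE) {
  if (!is.matrix(x) || nrow(x) != net$input_size || ncol(x) != net$input_size) {
    stop("input must be a ", net$input_size, "x", net$input_size, " matrix, got ",
         paste(dim(x), collapse = "x"))
  }
  h <- w <- net$input_size
  a <- matrix(as.numeric(x), ncol = 1L)
  caches <- outputs <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    if (l$type == "conv") {
      idx <- nn_im2col_index(h, w)
      C <- ncol(a)
      a_pad <- rbind(a, 0)
      cols <- matrix(0, nrow = h * w, ncol = 9L * C)
      for (o in 1:9) {
        cols[, ((o - 1L) * C + 1L):(o * C)] <- a_pad[idx[, o], , drop = FALSE]
      }
      a <- sweep(cols %*% l$W, 2L, l$b, "+")
      if (keep) caches[[i]] <- list(cols = cols, idx = idx, h = h, w = w, cin = C)
    } else if (l$type == "relu") {
      mask <- a > 0
      a <- a * mask
      if (keep) caches[[i]] <- list(mask = mask)
    } else if (l$type == "avgpool") {
      pidx <- nn_pool_index(h, w, l$f)
      a <- rowsum(a, pidx) / (l$f^2)
      if (keep) caches[[i]] <- list(pidx = pidx)
      h <- h %/% l$f
      w <- w %/% l$f
    } else if (l$type == "gap") {
      if (keep) caches[[i]] <- list(hw = h * w)
      a <- matrix(colMeans(a), nrow = 1L)
      h <- w <- 1L
    } else if (l$type == "dense") {
      if (keep) caches[[i]] <- list(input = a)
      a <- sweep(a %*% l$W, 2L, l$b, "+")
    } else {
      stop("unknown layer type: ", l$type)
    }
    if (keep) outputs[[i]] <- a
  }
  out <- list(logits = as.numeric(a))
  if (keep) {
    out$outputs <- outputs
    out$caches <- caches
  }
  out
}

#' Backward pass: parameter gradients and per-layer output gradients
#'
#' Propagates a gradient with respect to the logits back through the network.
#'
#' @param net An [nn_network()].
#' @param fwd The result of `nn_forward(net, x, keep = TRUE)`.
#' @param dlogits Gradient of the loss (or of a chosen logit) with respect to
#'   the network output, as a numeric vector.
#' @param stop_at Optional layer index: the backward pass stops after
#'   computing the gradient with respect to that layer's *output* (used by
#'   Grad-CAM); parameter gradients above it are still returned.
#' @return A list with `param_grads` (per layer, `NULL` for parameter-free
#'   layers, else `list(W, b)`) and `d_output` (per layer, the gradient with
#'   respect to that layer's output; filled for layers from `stop_at` up).
#' @export
nn_gradients <- function(net, fwd, dlogits, stop_at = 0L) {
  stopifnot(!is.null(fwd$caches))
  nl <- length(net$layers)
  d <- matrix(as.numeric(dlogits), nrow = 1L)
  param_grads <- vector("list", nl)
  d_output <- vector("list", nl)
  for (i in rev(seq_len(nl))) {
    d_output[[i]] <- d
    if (i == stop_at) break
    l <- net$layers[[i]]
    cc <- fwd$caches[[i]]
    if (l$type == "dense") {
      param_grads[[i]] <- list(W = crossprod(cc$input, d), b = as.numeric(d))
      d <- d %*% t(l$W)
    } else if (l$type == "gap") {
      C <- ncol(d)
      d <- matrix(rep(as.numeric(d) / cc$hw, each = cc$hw), nrow = cc$hw, ncol = C)
    } else if (l$type == "avgpool") {
      d <- d[cc$pidx, , drop = FALSE] / (l$f^2)
    } else if (l$type == "relu") {
      d <- d * cc$mask
    } else if (l$type == "conv") {
      param_grads[[i]] <- list(W = crossprod(cc$cols, d), b = colSums(d))
      dcols <- tcrossprod(d, l$W)
      C <- cc$cin
      dx <- matrix(0, nrow = cc$h * cc$w, ncol = C)
      n <- cc$h * cc$w
      for (o in 1:9) {
        tgt <- cc$idx[, o]
        ok <- tgt <= n
        block <- dcols[, ((o - 1L) * C + 1L):(o * C), drop = FALSE]
        dx[tgt[ok], ] <- dx[tgt[ok], , drop = FALSE] + block[ok, , drop = FALSE]
      }
      d <- dx
    }
  }
  list(param_grads = param_grads, d_output = d_output)
}

nn_softmax <- function(logits) {
  z <- logits - max(logits)
  e <- exp(z)
  e / sum(e)
}

# Cross-entropy loss and its gradient wrt logits for one sample.
nn_ce_loss <- function(logits, class_index) {
  p <- nn_softmax(logits)
  dlogits <- p
  dlogits[class_index] <- dlogits[class_index] - 1
  list(loss = -log(max(p[class_index], 1e-12)), dlogits = dlogits, prob = p)
}

# Adam optimiser state and update (L2-style weight decay folded into the
# gradient, matching the convention of the reference deep-learning stack).
nn_adam_init <- function(net) {
  lapply(net$layers, function(l) {
    if (l$type %in% c("conv", "dense")) {
      list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0)
    } else NULL
  })
}

nn_adam_step <- function(net, state, grads, lr, betas, weight_decay, t, eps = 1e-8) {
  b1 <- betas[1]; b2 <- betas[2]
  corr1 <- 1 - b1^t
  corr2 <- 1 - b2^t
  for (i in seq_along(net$layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    l <- net$layers[[i]]
    gW <- g$W + weight_decay * l$W
    gb <- g$b + weight_decay * l$b
    s <- state[[i]]
    s$mW <- b1 * s$mW + (1 - b1) * gW
    s$vW <- b2 * s$vW + (1 - b2) * gW^2
    s$mb <- b1 * s$mb + (1 - b1) * gb
    s$vb <- b2 * s$vb + (1 - b2) * gb^2
    net$layers[[i]]$W <- l$W - lr * (s$mW / corr1) / (sqrt(s$vW / corr2) + eps)
    net$layers[[i]]$b <- l$b - lr * (s$mb / corr1) / (sqrt(s$vb / corr2) + eps)
    state[[i]] <- s
  }
  list(net = net, state = state)
}

# Index of the last convolution layer (the Grad-CAM / feature target).
nn_last_conv <- function(net) {
  idx <- which(vapply(net$layers, function(l) l$type == "conv", logical(1)))
  if (length(idx) == 0) stop("network has no convolutional layer")
  max(idx)
}

# Index of the global-average-pooling layer (penultimate feature vector).
nn_gap_layer <- function(net) {
  idx <- which(vapply(net$layers, function(l) l$type == "gap", logical(1)))
  if (length(idx) == 0) stop("network has no global pooling layer")
  max(idx)
}
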