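# Binary live/dead classifier training: cross-entropy loss, Adam,
# inverse-count weighted sampling with replacement, and dihedral-group data
# augmentation. The desk-scale `tiny_test` backbone (three conv blocks,
# ~6k parameters) trains in minutes on one CPU; the full-size pretrained
# backbones the pipeline targets are consumed as pluggable black boxes and
# are not bundled.

#' Training configuration
#'
#' Defaults follow the reference training recipe: learning rate 1e-5, batch
#' size 4, 30 epochs, Adam with betas (0.5, 0.999) and weight decay 1e-5.
#' The `tiny_test` backbone is trained from scratch, so small desk-scale
#' runs typically raise the learning rate (the examples use 1e-3).
#'
#' @param backbone `"tiny_test"` (built in, trainable) or one of the
#'   full-size backbone names (`"residual18"`, `"squeeze"`,
#'   `"inception_v3"`), which require externally supplied weights.
#' @param learning_rate,batch_size,epochs,adam_betas,weight_decay Optimiser
#'   hyperparameters.
#' @param augmentation Apply a random dihedral transform to each sampled
#'   training patch.
#' @param pretrained Start from pretrained weights (only meaningful for the
#'   full-size backbones; unsupported without supplied weights).
#' @param seed Integer seed controlling initialisation, sampling and
#'   augmentation.
#' @param input_size Patch side length (default 224).
#' @return An object of class `train_config`.
#' @export
train_config <- function(backbone = c("tiny_test", "residual18", "squeeze",
                                      "inception_v3"),
                         learning_rate = 1e-5, batch_size = 4L, epochs = 30L,
                         adam_betas = c(0.5, 0.999), weight_decay = 1e-5,
                         augmentation = TRUE, pretrained = FALSE, seed = 1L,
                         input_size = 224L) {
  backbone <- match.arg(backbone)
  stopifnot(learning_rate > 0, batch_size >= 1, epochs >= 0,
            length(adam_betas) == 2, all(adam_betas > 0), all(adam_betas < 1),
            weight_decay >= 0, input_size >= 8)
  structure(list(backbone = backbone, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), adam_betas = adam_betas,
                 weight_decay = weight_decay,
                 augmentation = isTRUE(augmentation),
                 pretrained = isTRUE(pretrained), seed = as.integer(seed),
                 input_size = as.integer(input_size)),
            class = "train_config")
}

# Dihedral group of the square: k in 0..3 rotations, 4..7 flip then rotate.
rot90cw <- function(m) t(m[nrow(m):1, , drop = FALSE])
flip_h <- function(m) m[, ncol(m):1, drop = FALSE]

#' Random dihedral augmentation of a square patch
#'
#' Applies one of the eight symmetries of the square (four 90-degree
#' rotations, each optionally preceded by a horizontal flip). The pixel
#' multiset, and hence the patch label, is invariant.
#'
#' @param patch Square numeric matrix.
#' @param transform Integer 0-7 selecting the transform; `NULL` (default)
#'   draws one uniformly from the current RNG stream.
#' @return The transformed matrix.
#' @export
augment <- function(patch, transform = NULL) {
  if (!is.matrix(patch) || nrow(patch) != ncol(patch)) {
    stop("augmentation requires a square patch")
  }
  if (is.null(transform)) transform <- sample.int(8L, 1L) - 1L
  stopifnot(transform %in% 0:7)
  m <- patch
  if (transform >= 4L) m <- flip_h(m)
  for (i in seq_len(transform %% 4L)) m <- rot90cw(m)
  m
}

build_classifier_net <- function(config) {
  if (config$backbone != "tiny_test") {
    stop("backbone '", config$backbone, "' requires externally supplied ",
         "(pretrained) weights, which are not bundled; use 'tiny_test' for ",
         "desk-scale runs or wrap your own network")
  }
  s <- config$input_size
  stopifnot(s %% 16L == 0L)
  nn_network(
    nn_avgpool(4L),
    nn_conv(1L, 8L), nn_relu(), nn_avgpool(2L),
    nn_conv(8L, 16L), nn_relu(), nn_avgpool(2L),
    nn_conv(16L, 32L), nn_relu(),
    nn_gap(),
    nn_dense(32L, 2L),
    input_size = s)
}

patch_list <- function(data, column = "bright_field") {
  if (is.data.frame(data)) data[[column]] else data
}

# 8-bit patch -> network input: scale to [0, 1] and centre at zero.
prep_input <- function(patch) patch / 255 - 0.5

#' Train the live/dead classifier
#'
#' Minimises softmax cross-entropy with Adam over batches drawn by a
#' weighted with-replacement sampler (weights from [class_weights()]), with
#' optional dihedral augmentation. After each epoch the balanced accuracy on
#' the (non-augmented) validation set is recorded and the weights with the
#' best validation balanced accuracy are retained.
#'
#' @param train,valid Tibbles with a `bright_field` list-column of 8-bit
#'   `input_size` x `input_size` matrices and a `label` column
#'   (`live` / `dead`). The training set must contain both classes.
#' @param weights A [class_weights()] vector for `live` and `dead`; `NULL`
#'   computes inverse counts from the training labels.
#' @param config A [train_config()].
#' @return An object of class `trained_classifier` with the fitted network,
#'   class order (`live`, `dead`), per-epoch `history` tibble and the
#'   configuration snapshot.
#' @export
train_classifier <- function(train, valid, weights = NULL, config = train_config()) {
  stopifnot(inherits(config, "train_config"))
  if (nrow(train) == 0 || nrow(valid) == 0) stop("train and valid must be non-empty")
  classes <- c("live", "dead")
  y_train <- match(train$label, classes)
  y_valid <- match(valid$label, classes)
  if (any(is.na(y_train)) || any(is.na(y_valid))) {
    stop("labels must be 'live' or 'dead'")
  }
  if (length(unique(y_train)) < 2) {
    stop("training set contains a single class; cannot fit a discriminator")
  }
  if (is.null(weights)) {
    weights <- class_weights(table(train$label))
  }
  imgs_train <- patch_list(train)
  imgs_valid <- patch_list(valid)
  p_draw <- as.numeric(weights[train$label])
  n <- nrow(train)
  steps <- ceiling(n / config$batch_size)
  withr::with_seed(config$seed, {
    net <- build_classifier_net(config)
    best_net <- net
    best_ba <- -Inf
    best_epoch <- 0L
    state <- nn_adam_init(net)
    t_step <- 0L
    history <- vector("list", config$epochs)
    for (epoch in seq_len(config$epochs)) {
      losses <- numeric(steps)
      for (s in seq_len(steps)) {
        idx <- sample.int(n, config$batch_size, replace = TRUE, prob = p_draw)
        grads <- NULL
        loss_acc <- 0
        for (i in idx) {
          x <- prep_input(imgs_train[[i]])
          if (config$augmentation) x <- augment(x)
          fwd <- nn_forward(net, x, keep = TRUE)
          lg <- nn_ce_loss(fwd$logits, y_train[i])
          loss_acc <- loss_acc + lg$loss
          g <- nn_gradients(net, fwd, lg$dlogits)$param_grads
          grads <- if (is.null(grads)) g else add_grads(grads, g)
        }
        grads <- scale_grads(grads, 1 / config$batch_size)
        losses[s] <- loss_acc / config$batch_size
        t_step <- t_step + 1L
        upd <- nn_adam_step(net, state, grads, lr = config$learning_rate,
                            betas = config$adam_betas,
                            weight_decay = config$weight_decay, t = t_step)
        net <- upd$net
        state <- upd$state
      }
      pred_valid <- vapply(imgs_valid, function(p) {
        which.max(nn_forward(net, prep_input(p))$logits)
      }, integer(1))
      ba <- mean(vapply(1:2, function(cl) {
        mean(pred_valid[y_valid == cl] == cl)
      }, numeric(1)), na.rm = TRUE)
      history[[epoch]] <- tibble::tibble(epoch = epoch,
                                         train_loss = mean(losses),
                                         valid_balanced_accuracy = ba)
      if (ba > best_ba) {
        best_ba <- ba
        best_net <- net
        best_epoch <- epoch
      }
    }
    if (config$epochs == 0L) {
      best_net <- net
      best_ba <- NA_real_
    }
    structure(list(net = best_net, final_net = net, class_levels = classes,
                   history = dplyr::bind_rows(history),
                   best_epoch = best_epoch,
                   best_valid_balanced_accuracy = best_ba,
                   config = config),
              class = "trained_classifier")
  })
}

add_grads <- function(a, b) {
  for (i in seq_along(a)) {
    if (!is.null(a[[i]])) {
      a[[i]]$W <- a[[i]]$W + b[[i]]$W
      a[[i]]$b <- a[[i]]$b + b[[i]]$b
    }
  }
  a
}

scale_grads <- function(g, s) {
  for (i in seq_along(g)) {
    if (!is.null(g[[i]])) {
      g[[i]]$W <- g[[i]]$W * s
      g[[i]]$b <- g[[i]]$b * s
    }
  }
  g
}

#' @export
print.trained_classifier <- function(x, ...) {
  cat("<trained_classifier>", x$config$backbone, "-", nn_n_params(x$net),
      "parameters\n")
  if (nrow(x$history) > 0) {
    cat(sprintf("  best validation balanced accuracy %.3f at epoch %d/%d\n",
                x$best_valid_balanced_accuracy, x$best_epoch,
                x$config$epochs))
  }
  invisible(x)
}

#' Predict class probabilities for bright-field patches
#'
#' The classification *score* of a patch is its live-class probability:
#' high scores signal live cells, low scores dead ones.
#'
#' @param object A [train_classifier()] result.
#' @param newdata Patch tibble (with `bright_field` list-column of 8-bit
#'   matrices) or a list of matrices.
#' @param ... Unused.
#' @return A tibble with `patch_id` (when available), `p_live`, `p_dead`
#'   and the hard `label` (argmax).
#' @export
predict.trained_classifier <- function(object, newdata, ...) {
  imgs <- patch_list(newdata)
  probs <- t(vapply(imgs, function(p) {
    nn_softmax(nn_forward(object$net, prep_input(p))$logits)
  }, numeric(2)))
  out <- tibble::tibble(p_live = probs[, 1], p_dead = probs[, 2],
                        label = object$class_levels[max.col(probs, ties.method = "first")])
  if (is.data.frame(newdata) && "patch_id" %in% names(newdata)) {
    out <- dplyr::bind_cols(tibble::tibble(patch_id = newdata$patch_id), out)
  }
  out
}

#' @exportS3Method generics::tidy
tidy.trained_classifier <- function(x, ...) x$history

#' @exportS3Method generics::glance
glance.trained_classifier <- function(x, ...) {
  tibble::tibble(backbone = x$config$backbone, n_params = nn_n_params(x$net),
                 epochs = x$config$epochs, best_epoch = x$best_epoch,
                 best_valid_balanced_accuracy = x$best_valid_balanced_accuracy)
}
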