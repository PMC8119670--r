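# Empty-patch rejection: deep features from a frozen convolutional backbone
# plus a support vector machine trained on a small manually labelled set of
# empty and properly captured patches.

#' A frozen random-weight convolutional feature extractor
#'
#' Builds a fixed-seed, random-weight convolutional backbone with the same
#' contract as a pretrained network used for feature reuse: a 224 x 224
#' 8-bit bright-field patch in, a globally average-pooled feature vector
#' out. Random convolutional features are a standard desk-scale stand-in for
#' pretrained ones in outlier-detection settings; a genuinely pretrained
#' backbone can be plugged in via [custom_backbone()]. The default feature
#' length matches the 512-dimensional output of an 18-layer residual
#' reference backbone.
#'
#' @param feature_length Length of the pooled feature vector (default 512).
#' @param hidden_channels Channels of the intermediate convolution.
#' @param seed Seed fixing the random weights; the extractor is frozen and
#'   deterministic thereafter.
#' @param input_size Expected patch side length (default 224).
#' @return An object of class `sf_backbone`.
#' @export
random_backbone <- function(feature_length = 512L, hidden_channels = 16L,
                            seed = 42L, input_size = 224L) {
  net <- withr::with_seed(as.integer(seed), {
    nn_network(
      nn_avgpool(8L),
      nn_conv(1L, hidden_channels),
      nn_relu(),
      nn_avgpool(2L),
      nn_conv(hidden_channels, as.integer(feature_length)),
      nn_relu(),
      nn_gap(),
      input_size = as.integer(input_size))
  })
  structure(list(net = net, feature_length = as.integer(feature_length),
                 input_size = as.integer(input_size),
                 description = sprintf("random-weight conv extractor (seed %d)", seed)),
            class = "sf_backbone")
}

#' Wrap an arbitrary feature-extraction function as a backbone
#'
#' @param fn Function taking a single `input_size` x `input_size` matrix
#'   (8-bit intensities) and returning a numeric feature vector of length
#'   `feature_length`.
#' @param feature_length Length of the returned vector.
#' @param input_size Expected patch side length.
#' @param description Free-text provenance note.
#' @return An object of class `sf_backbone`.
#' @export
custom_backbone <- function(fn, feature_length, input_size = 224L,
                            description = "user-supplied backbone") {
  stopifnot(is.function(fn))
  structure(list(fn = fn, feature_length = as.integer(feature_length),
                 input_size = as.integer(input_size),
                 description = description),
            class = "sf_backbone")
}

#' @export
print.sf_backbone <- function(x, ...) {
  cat("<sf_backbone>", x$description, "-", x$feature_length, "features from",
      x$input_size, "px patches\n")
  invisible(x)
}

backbone_features_one <- function(backbone, patch) {
  if (!is.matrix(patch) || nrow(patch) != backbone$input_size ||
      ncol(patch) != backbone$input_size) {
    stop("patch must be ", backbone$input_size, "x", backbone$input_size,
         ", got ", paste(dim(patch), collapse = "x"))
  }
  v <- if (!is.null(backbone$fn)) {
    backbone$fn(patch)
  } else {
    nn_forward(backbone$net, patch / 255)$logits
  }
  if (length(v) != backbone$feature_length || any(!is.finite(v))) {
    stop("backbone returned an invalid feature vector")
  }
  as.numeric(v)
}

#' Extract deep features from bright-field patches
#'
#' @param patches Tibble with `patch_id` and a `bright_field` list-column of
#'   8-bit matrices, or a plain list of matrices.
#' @param backbone An `sf_backbone` ([random_backbone()] or
#'   [custom_backbone()]); frozen, so extraction is deterministic.
#' @return A tibble with `patch_id` and feature columns `f1 ... fK`.
#' @export
extract_features <- function(patches, backbone) {
  stopifnot(inherits(backbone, "sf_backbone"))
  if (is.data.frame(patches)) {
    ids <- patches$patch_id
    imgs <- patches$bright_field
  } else {
    imgs <- patches
    ids <- names(imgs) %||% sprintf("patch%04d", seq_along(imgs))
  }
  mat <- t(vapply(imgs, function(p) backbone_features_one(backbone, p),
                  numeric(backbone$feature_length)))
  colnames(mat) <- paste0("f", seq_len(backbone$feature_length))
  dplyr::bind_cols(tibble::tibble(patch_id = ids), tibble::as_tibble(mat))
}

feature_matrix <- function(features) {
  as.matrix(dplyr::select(features, dplyr::starts_with("f") &
                            dplyr::where(is.numeric)))
}

#' Fit the empty-patch detector
#'
#' Trains a support vector machine on deep features of manually labelled
#' empty and non-empty patches. The default is a two-class RBF SVM (both
#' classes are labelled in the curation design); a one-class mode trained on
#' non-empty features only is available for strict outlier detection.
#'
#' @param empty_features,nonempty_features Feature tibbles from
#'   [extract_features()] (or numeric matrices). In one-class mode
#'   `empty_features` may be empty.
#' @param mode `"two_class"` (default) or `"one_class"`.
#' @param kernel,cost,gamma,nu Passed to [e1071::svm()]; `gamma` defaults to
#'   1 / feature length.
#' @return An object of class `empty_detector`.
#' @export
fit_empty_detector <- function(empty_features, nonempty_features,
                               mode = c("two_class", "one_class"),
                               kernel = "radial", cost = 1, gamma = NULL,
                               nu = 0.1) {
  mode <- match.arg(mode)
  xe <- if (is.matrix(empty_features)) empty_features else feature_matrix(empty_features)
  xn <- if (is.matrix(nonempty_features)) nonempty_features else feature_matrix(nonempty_features)
  if (nrow(xn) == 0) stop("nonempty_features must be non-empty")
  if (mode == "two_class" && nrow(xe) == 0) {
    stop("empty_features must be non-empty to fit a two-class discriminator")
  }
  if (nrow(xe) > 0 && ncol(xe) != ncol(xn)) {
    stop("feature length mismatch: ", ncol(xe), " vs ", ncol(xn))
  }
  d <- ncol(xn)
  if (is.null(gamma)) gamma <- 1 / d
  # standardise features once; the scaling is part of the detector
  x_all <- rbind(xe, xn)
  ctr <- colMeans(x_all)
  scl <- pmax(apply(x_all, 2L, stats::sd), 1e-8)
  scale_fn <- function(x) sweep(sweep(x, 2L, ctr), 2L, scl, "/")
  if (mode == "two_class") {
    x <- scale_fn(x_all)
    y <- factor(c(rep("empty", nrow(xe)), rep("cell", nrow(xn))),
                levels = c("empty", "cell"))
    fit <- e1071::svm(x, y, kernel = kernel, cost = cost, gamma = gamma,
                      scale = FALSE)
  } else {
    fit <- e1071::svm(scale_fn(xn), y = NULL, type = "one-classification",
                      kernel = kernel, nu = nu, gamma = gamma, scale = FALSE)
  }
  structure(list(fit = fit, mode = mode, feature_length = d,
                 center = ctr, scale = scl,
                 n_train = c(empty = nrow(xe), nonempty = nrow(xn)),
                 kernel = kernel),
            class = "empty_detector")
}

#' @export
print.empty_detector <- function(x, ...) {
  cat("<empty_detector>", x$mode, x$kernel, "SVM on", x$feature_length,
      "features (", x$n_train["empty"], "empty /", x$n_train["nonempty"],
      "non-empty )\n")
  invisible(x)
}

#' Predict empty/cell for feature vectors
#'
#' @param object An `empty_detector`.
#' @param features Feature tibble or matrix; its feature length must match
#'   the detector's.
#' @param ... Unused.
#' @return Character vector in `{"empty", "cell"}`.
#' @export
predict.empty_detector <- function(object, features, ...) {
  x <- if (is.matrix(features)) features else feature_matrix(features)
  if (ncol(x) != object$feature_length) {
    stop("feature length ", ncol(x), " does not match detector (",
         object$feature_length, ")")
  }
  xs <- sweep(sweep(x, 2L, object$center), 2L, object$scale, "/")
  if (object$mode == "two_class") {
    as.character(predict(object$fit, xs))
  } else {
    ifelse(as.logical(predict(object$fit, xs)), "cell", "empty")
  }
}

#' F1 score for the empty class
#'
#' Harmonic mean of precision and recall for the positive class. When there
#' are neither positive predictions nor positive truths the score is defined
#' as 0 with a warning.
#'
#' @param predicted,truth Vectors of equal length with values in
#'   `{"empty", "cell"}` (or any two levels; `positive` names the one
#'   scored).
#' @param positive The positive class (default `"empty"`).
#' @return A number in \[0, 1\].
#' @export
f1_score <- function(predicted, truth, positive = "empty") {
  if (length(predicted) != length(truth)) stop("length mismatch")
  tp <- sum(predicted == positive & truth == positive)
  fp <- sum(predicted == positive & truth != positive)
  fn <- sum(predicted != positive & truth == positive)
  if (tp + fp + fn == 0) {
    warning("no positive predictions and no positive truths; f1 defined as 0")
    return(0)
  }
  if (tp == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

#' Partition patches into kept and discarded by the empty-patch detector
#'
#' @param patches Patch tibble (with a `bright_field` list-column of 8-bit
#'   matrices).
#' @param detector A fitted [fit_empty_detector()].
#' @param backbone The same backbone used to train the detector.
#' @return A list with `kept` and `discarded` patch tibbles; together they
#'   partition the input in stable order.
#' @export
filter_patches <- function(patches, detector, backbone) {
  stopifnot(inherits(detector, "empty_detector"))
  if (nrow(patches) == 0) {
    return(list(kept = patches, discarded = patches))
  }
  feats <- extract_features(patches, backbone)
  pred <- predict(detector, feats)
  list(kept = patches[pred == "cell", , drop = FALSE],
       discarded = patches[pred == "empty", , drop = FALSE])
}
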