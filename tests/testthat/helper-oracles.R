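# Independent oracles used across test files. These deliberately use naive
# enumeration / direct formulas, not the package's code paths.

# All-pairs concordance AUC: P(score_pos > score_neg), ties count 1/2.
oracle_auc <- function(scores, truth, positive = "live") {
  sp <- scores[truth == positive]
  sn <- scores[truth != positive]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# Counting-based F1 for the positive class.
oracle_f1 <- function(pred, truth, positive = "empty") {
  tp <- 0; fp <- 0; fn <- 0
  for (i in seq_along(pred)) {
    if (pred[i] == positive && truth[i] == positive) tp <- tp + 1
    if (pred[i] == positive && truth[i] != positive) fp <- fp + 1
    if (pred[i] != positive && truth[i] == positive) fn <- fn + 1
  }
  prec <- tp / (tp + fp)
  rec <- tp / (tp + fn)
  if (!is.finite(prec) || !is.finite(rec) || prec + rec == 0) return(0)
  2 * prec * rec / (prec + rec)
}

# Brute-force confusion tally.
oracle_confusion <- function(pred, truth) {
  lv <- c("live", "dead")
  m <- matrix(0L, 2, 2, dimnames = list(truth = lv, pred = lv))
  for (i in seq_along(pred)) {
    m[truth[i], pred[i]] <- m[truth[i], pred[i]] + 1L
  }
  m
}

# Balanced accuracy straight from per-class recall counting.
oracle_balanced_accuracy <- function(pred, truth) {
  classes <- unique(truth)
  mean(vapply(classes, function(cl) {
    mean(pred[truth == cl] == cl)
  }, numeric(1)))
}

# Exhaustive grid-offset enumeration for the cropping contract.
oracle_offsets <- function(extent, patch, stride) {
  offs <- integer(0)
  o <- 0L
  while (o + patch <= extent) {
    offs <- c(offs, o)
    o <- o + stride
  }
  if (offs[length(offs)] + patch < extent) offs <- c(offs, extent - patch)
  offs
}

# Kernel-density mode count (a dip-style bimodality check): number of local
# maxima whose height exceeds `min_frac` of the tallest mode.
count_modes <- function(x, min_frac = 0.05) {
  d <- stats::density(x, n = 512)
  y <- d$y
  peaks <- which(diff(sign(diff(y))) == -2) + 1L
  sum(y[peaks] >= min_frac * max(y))
}

# Direct same-padding 3x3 convolution by quadruple loop (closed-form
# Grad-CAM verification).
oracle_conv3x3 <- function(x, w3, bias) {
  h <- nrow(x); wd <- ncol(x)
  out <- matrix(0, h, wd)
  for (r in seq_len(h)) {
    for (cc in seq_len(wd)) {
      acc <- bias
      for (dr in -1:1) {
        for (dc in -1:1) {
          rr <- r + dr; c2 <- cc + dc
          if (rr >= 1 && rr <= h && c2 >= 1 && c2 <= wd) {
            acc <- acc + x[rr, c2] * w3[dr + 2, dc + 2]
          }
        }
      }
      out[r, cc] <- acc
    }
  }
  out
}

# Printed reference mixture of the untreated condition.
paper_mixture <- function(weight_live = 0.5) {
  list(mu_live = 224.51, sigma_live = 34.46,
       mu_dead = 550.44, sigma_dead = 153.55,
       weight_live = weight_live)
}
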