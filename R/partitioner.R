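# Leakage-free train/validation/test splitting grouped by raw image, the
# dataset-summary bookkeeping, and inverse-count class weights for the
# imbalance-corrected sampler.

#' Grouped train/validation/test split
#'
#' All patches of a raw image travel together: groups (raw images) are
#' shuffled by seed, ordered largest-first, and each is assigned greedily to
#' the partition with the largest remaining patch deficit relative to the
#' target fractions. Discarded-label patches are excluded before splitting.
#'
#' @param labels Tibble with `patch_id`, `raw_image_id` and `label` columns
#'   (e.g. [label_dataset()] output joined with parent ids).
#' @param fractions Numeric length-3 target patch fractions for
#'   train/valid/test; must sum to 1.
#' @param seed Integer seed for the shuffle.
#' @return A `split_manifest`: the labeled tibble with a `partition` column
#'   (`train` / `valid` / `test`), with `fractions` and `seed` attached as
#'   attributes.
#' @export
grouped_split <- function(labels, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  stopifnot(all(c("patch_id", "raw_image_id", "label") %in% names(labels)))
  if (length(fractions) != 3 || abs(sum(fractions) - 1) > 1e-8 ||
      any(fractions <= 0)) {
    stop("fractions must be 3 positive values summing to 1")
  }
  labels <- dplyr::filter(labels, .data$label != "discarded")
  groups <- unique(labels$raw_image_id)
  if (length(groups) < 3) {
    stop("need at least 3 distinct raw_image_ids to form 3 partitions, got ",
         length(groups))
  }
  parts <- c("train", "valid", "test")
  sizes <- labels |>
    dplyr::count(.data$raw_image_id, name = "n_patches")
  assigned <- withr::with_seed(as.integer(seed), {
    shuffled <- sizes[sample.int(nrow(sizes)), , drop = FALSE]
    shuffled <- shuffled[order(-shuffled$n_patches), , drop = FALSE]
    total <- sum(shuffled$n_patches)
    got <- c(train = 0, valid = 0, test = 0)
    part_of <- character(nrow(shuffled))
    for (i in seq_len(nrow(shuffled))) {
      deficit <- fractions * total - got
      j <- which.max(deficit)
      part_of[i] <- parts[j]
      got[j] <- got[j] + shuffled$n_patches[i]
    }
    tibble::tibble(raw_image_id = shuffled$raw_image_id, partition = part_of)
  })
  # guarantee every partition is non-empty (possible with few groups)
  for (p in parts) {
    if (!p %in% assigned$partition) {
      donor <- names(which.max(table(assigned$partition)))
      idx <- utils::tail(which(assigned$partition == donor), 1)
      assigned$partition[idx] <- p
    }
  }
  out <- dplyr::inner_join(labels, assigned, by = "raw_image_id")
  attr(out, "fractions") <- setNames(fractions, parts)
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("split_manifest", class(out))
  out
}

#' Per-partition class counts (dataset-summary bookkeeping)
#'
#' Tabulates live/dead counts and totals per partition (and per condition
#' when a `condition` column is present), with `total = live + dead` on
#' every row.
#'
#' @param manifest A [grouped_split()] manifest, or any tibble with `label`
#'   and `partition` columns. An empty manifest yields an all-zero table.
#' @return A tibble with columns `partition` (train/valid/test/all),
#'   optional `condition`, `live`, `dead`, `total`.
#' @export
manifest_counts <- function(manifest) {
  parts <- c("train", "valid", "test")
  by_cond <- "condition" %in% names(manifest) &&
    any(!is.na(manifest$condition))
  skeleton <- if (by_cond) {
    tidyr::expand_grid(condition = unique(manifest$condition), partition = parts)
  } else {
    tibble::tibble(partition = parts)
  }
  if (nrow(manifest) == 0) {
    return(dplyr::mutate(tibble::tibble(partition = parts),
                         live = 0L, dead = 0L, total = 0L))
  }
  stopifnot(all(c("label", "partition") %in% names(manifest)))
  keys <- if (by_cond) c("condition", "partition") else "partition"
  counts <- tibble::as_tibble(manifest) |>
    dplyr::filter(.data$label %in% c("live", "dead")) |>
    dplyr::count(dplyr::across(dplyr::all_of(c(keys, "label")))) |>
    tidyr::pivot_wider(names_from = "label", values_from = "n",
                       values_fill = 0L)
  for (cl in c("live", "dead")) {
    if (!cl %in% names(counts)) counts[[cl]] <- 0L
  }
  out <- skeleton |>
    dplyr::left_join(counts, by = keys) |>
    dplyr::mutate(live = dplyr::coalesce(.data$live, 0L),
                  dead = dplyr::coalesce(.data$dead, 0L),
                  total = .data$live + .data$dead)
  out
}

#' Inverse-count class weights
#'
#' Sampling weights proportional to the inverse of the per-class sample
#' count, so a weighted with-replacement sampler draws each class equally
#' often in expectation.
#'
#' @param counts Named numeric vector of per-class counts (all > 0), e.g.
#'   `c(live = 4195, dead = 42966)`.
#' @return A named numeric vector of class `class_weights` with
#'   `weight = 1 / count` (unnormalised; the sampler normalises).
#' @export
class_weights <- function(counts) {
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop("counts must be named by class")
  }
  if (any(counts <= 0)) stop("all class counts must be > 0")
  structure(1 / as.numeric(counts), names = names(counts),
            class = "class_weights")
}

#' Weighted with-replacement draws over a labeled set
#'
#' @param labels Character vector of per-item class labels.
#' @param weights A [class_weights()] vector covering every label present.
#' @param n Number of draws.
#' @param seed Optional seed.
#' @return Integer vector of drawn indices into `labels`.
#' @export
weighted_sample <- function(labels, weights, n, seed = NULL) {
  if (!all(unique(labels) %in% names(weights))) {
    stop("weights missing for some labels")
  }
  p <- as.numeric(weights[labels])
  draw <- function() sample.int(length(labels), n, replace = TRUE, prob = p)
  if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
}
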