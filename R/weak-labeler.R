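# Weak labeling from mean fluorescence: a two-component Gaussian mixture is
# fitted to per-patch mean fluorescence of the reference (untreated)
# condition; patches below mu_live + sigma_live are labelled live, above
# mu_dead - sigma_dead dead, and the open band between the two cut-offs is
# discarded. The same thresholds are applied to every condition without
# refitting.

#' Mean fluorescence of a patch
#'
#' Arithmetic mean over all pixels of a raw-intensity fluorescence patch.
#' Labeling operates on raw 16-bit intensities, never on the 8-bit display
#' conversion: the component means the thresholds are built from exceed the
#' 8-bit maximum.
#'
#' @param patch Numeric matrix (raw intensity units).
#' @return A single numeric value.
#' @export
mean_fluorescence <- function(patch) {
  if (length(patch) == 0) stop("patch is empty")
  mean(patch)
}

#' Add a mean-fluorescence column to a patch tibble
#'
#' @param patches Tibble with a `fluorescence` list-column (raw-intensity
#'   matrices), as produced by [crop_patches()].
#' @return The tibble with a `mean_fluorescence` column appended.
#' @export
add_mean_fluorescence <- function(patches) {
  stopifnot("fluorescence" %in% names(patches))
  dplyr::mutate(patches,
                mean_fluorescence = vapply(.data$fluorescence, mean_fluorescence,
                                           numeric(1)))
}

# One EM run from a given initialisation; means/sds/weights of k components.
em_run <- function(x, mu, sigma, w, tol, max_iter) {
  n <- length(x)
  k <- length(mu)
  sigma_floor <- max(stats::sd(x), 1e-8) * 1e-6
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    # E-step in log space
    logd <- vapply(seq_len(k), function(j) {
      dnorm(x, mu[j], max(sigma[j], sigma_floor), log = TRUE) + log(w[j])
    }, numeric(n))
    mx <- apply(logd, 1L, max)
    lse <- mx + log(rowSums(exp(logd - mx)))
    ll <- sum(lse)
    r <- exp(logd - lse)
    # M-step
    nk <- colSums(r)
    if (any(nk < 1e-10)) break # component collapsed; keep previous params
    w <- nk / n
    mu <- colSums(r * x) / nk
    sigma <- sqrt(pmax(colSums(r * (x - rep(mu, each = n))^2) / nk, sigma_floor^2))
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (1 + abs(ll))) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
    if (iter >= max_iter) break
  }
  list(mu = mu, sigma = sigma, w = w, loglik = ll_old, converged = converged,
       iter = iter)
}

#' Fit a two-component Gaussian mixture to per-patch means
#'
#' Expectation-maximisation with k-means initialisation, run `n_restarts`
#' times (the first restart from the plain k-means solution, the others from
#' jittered variants); the fit with the highest log-likelihood is returned.
#' Components are reported sorted by mean, the lower one named *live*.
#'
#' @param means Numeric vector of per-patch mean fluorescence (>= 10 values).
#' @param n_components Number of components; the labeling rule uses 2.
#' @param n_restarts Number of EM restarts (default 10).
#' @param seed Integer seed, recorded in the model.
#' @param tol Relative log-likelihood convergence tolerance (default 1e-6).
#' @param max_iter Maximum EM iterations per restart.
#' @return An object of class `mixture_model` with fields `mu_live`,
#'   `sigma_live`, `mu_dead`, `sigma_dead`, `weight_live` (for 2 components;
#'   generally `mu`, `sigma`, `weight` vectors sorted by mean), `loglik`,
#'   `n`, `seed`, `converged`, and `restarts` (per-restart log-likelihoods).
#' @export
fit_mixture <- function(means, n_components = 2L, n_restarts = 10L, seed = 1L,
                        tol = 1e-6, max_iter = 500L) {
  x <- as.numeric(means)
  if (any(!is.finite(x))) stop("means must be finite")
  if (length(x) < 10) stop("need at least 10 values to fit the mixture")
  k <- as.integer(n_components)
  if (length(x) < k) stop("fewer points than components")
  fits <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(n_restarts), function(r) {
      km <- suppressWarnings(kmeans(x, centers = k, nstart = 1))
      mu <- as.numeric(km$centers)
      sigma <- vapply(seq_len(k), function(j) {
        xs <- x[km$cluster == j]
        max(stats::sd(xs), stats::sd(x) * 1e-3, 1e-8)
      }, numeric(1))
      if (any(!is.finite(sigma))) sigma <- rep(max(stats::sd(x), 1e-8), k)
      w <- pmax(tabulate(km$cluster, k) / length(x), 1e-6)
      w <- w / sum(w)
      if (r > 1) mu <- mu + rnorm(k, sd = stats::sd(x) * 0.1)
      em_run(x, mu, sigma, w, tol = tol, max_iter = max_iter)
    })
  })
  lls <- vapply(fits, function(f) f$loglik, numeric(1))
  if (all(!is.finite(lls))) stop("EM failed to produce a finite likelihood")
  best <- fits[[which.max(lls)]]
  if (!best$converged) {
    stop("EM did not converge in ", max_iter, " iterations ",
         "(best log-likelihood ", format(best$loglik), ")")
  }
  ord <- order(best$mu)
  model <- list(mu = best$mu[ord], sigma = best$sigma[ord],
                weight = best$w[ord], loglik = best$loglik,
                n = length(x), seed = as.integer(seed),
                n_restarts = as.integer(n_restarts),
                converged = best$converged, restarts = lls)
  if (k == 2L) {
    model$mu_live <- model$mu[1]; model$sigma_live <- model$sigma[1]
    model$mu_dead <- model$mu[2]; model$sigma_dead <- model$sigma[2]
    model$weight_live <- model$weight[1]
  }
  structure(model, class = "mixture_model")
}

#' @export
print.mixture_model <- function(x, ...) {
  cat("<mixture_model>", length(x$mu), "components, n =", x$n, "\n")
  for (j in seq_along(x$mu)) {
    cat(sprintf("  comp %d: mu = %.2f, sigma = %.2f, weight = %.3f\n",
                j, x$mu[j], x$sigma[j], x$weight[j]))
  }
  cat("  log-likelihood:", format(x$loglik), "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.mixture_model <- function(x, ...) {
  tibble::tibble(component = if (length(x$mu) == 2) c("live", "dead")
                 else paste0("comp", seq_along(x$mu)),
                 mean = x$mu, sd = x$sigma, weight = x$weight)
}

#' @exportS3Method generics::glance
glance.mixture_model <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, n = x$n, n_components = length(x$mu),
                 converged = x$converged, seed = x$seed)
}

#' Derive live/dead labeling thresholds from a fitted mixture
#'
#' The live cut-off is `mu_live + sigma_live`; the dead cut-off is
#' `mu_dead - sigma_dead`. Pure arithmetic, no tolerance. When the live
#' cut-off is not strictly below the dead cut-off there is no discard band
#' and labeling refuses to proceed.
#'
#' @param model A `mixture_model` (2 components) or a list with `mu_live`,
#'   `sigma_live`, `mu_dead`, `sigma_dead`.
#' @return An object of class `label_thresholds` with `live_max` and
#'   `dead_min`.
#' @export
derive_thresholds <- function(model) {
  need <- c("mu_live", "sigma_live", "mu_dead", "sigma_dead")
  if (!all(need %in% names(model))) {
    stop("model lacks fields: ", paste(setdiff(need, names(model)), collapse = ", "))
  }
  live_max <- model$mu_live + model$sigma_live
  dead_min <- model$mu_dead - model$sigma_dead
  if (live_max >= dead_min) {
    stop("degenerate thresholds: live_max (", format(live_max),
         ") >= dead_min (", format(dead_min), "); no discard band exists")
  }
  structure(list(live_max = live_max, dead_min = dead_min),
            class = "label_thresholds")
}

#' @export
print.label_thresholds <- function(x, ...) {
  cat(sprintf("<label_thresholds> live < %.2f | discard | dead > %.2f\n",
              x$live_max, x$dead_min))
  invisible(x)
}

#' Assign live/dead/discarded labels from mean fluorescence
#'
#' Means strictly below `live_max` are live, strictly above `dead_min` dead;
#' everything in between (including values exactly equal to a cut-off) is
#' discarded.
#'
#' @param mean Numeric vector of mean fluorescence values.
#' @param thresholds A [derive_thresholds()] result.
#' @return Character vector in `{"live", "dead", "discarded"}`.
#' @export
assign_label <- function(mean, thresholds) {
  stopifnot(inherits(thresholds, "label_thresholds"))
  dplyr::case_when(mean < thresholds$live_max ~ "live",
                   mean > thresholds$dead_min ~ "dead",
                   TRUE ~ "discarded")
}

#' Label a patch dataset with fixed thresholds
#'
#' Applies thresholds fitted on the reference condition to any patch set
#' without refitting.
#'
#' @param patches Tibble with `patch_id` and either a `mean_fluorescence`
#'   column or a `fluorescence` list-column (means are then computed).
#' @param thresholds A [derive_thresholds()] result.
#' @return A tibble with `patch_id`, carried-over identifiers
#'   (`raw_image_id`, `condition` when present), `mean_fluorescence` and
#'   `label`; the per-label counts are attached as attribute `"summary"`
#'   (see [label_summary()]).
#' @export
label_dataset <- function(patches, thresholds) {
  stopifnot(inherits(thresholds, "label_thresholds"))
  if (nrow(patches) == 0) {
    out <- tibble::tibble(patch_id = character(),
                          mean_fluorescence = numeric(), label = character())
    attr(out, "summary") <- tibble::tibble(label = c("live", "dead", "discarded"),
                                           n = 0L)
    return(out)
  }
  if (!"mean_fluorescence" %in% names(patches)) {
    patches <- add_mean_fluorescence(patches)
  }
  keep <- intersect(c("patch_id", "raw_image_id", "condition",
                      "mean_fluorescence"), names(patches))
  out <- patches |>
    dplyr::select(dplyr::all_of(keep)) |>
    dplyr::mutate(label = assign_label(.data$mean_fluorescence, thresholds))
  smry <- tibble::tibble(label = c("live", "dead", "discarded")) |>
    dplyr::left_join(dplyr::count(out, .data$label), by = "label") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
  attr(out, "summary") <- smry
  out
}

#' @rdname label_dataset
#' @param labeled The result of [label_dataset()].
#' @export
label_summary <- function(labeled) {
  attr(labeled, "summary")
}
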