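# Synthetic paired bright-field / fluorescence image generator.
#
# The generator lays cells out on a fixed 224-px grid of regions. Each region
# is empty, live or dead; the *patch-mean* fluorescence of a region is drawn
# from the corresponding component of a two-component Gaussian mixture and
# the rendered blob field is mean-centred so the realised mean hits that draw
# (up to pixel noise and 16-bit rounding). Bright-field morphology carries
# the discriminative cues: live cells are crisp, mildly darker ellipses with
# a small dark nucleus; dead cells are soft dark halos.

PATCH_SIZE <- 224L

#' Configuration for the synthetic paired-image generator
#'
#' Defines the study-like conditions under which synthetic data are drawn:
#' image geometry, cell counts, the dead-cell fraction, the empty-region
#' fraction, and the raw-intensity fluorescence mixture whose two components
#' represent mostly-live (low) and mostly-dead (high) patches.
#'
#' @param n_raw_images Number of raw image pairs to generate.
#' @param image_width,image_height Raw image size in pixels. Defaults match
#'   the full-resolution captures the pipeline targets (1344 x 1024); both
#'   must be at least one patch (224 px).
#' @param cells_per_image Integer range (length 2): total cells drawn per
#'   image, distributed over non-empty grid regions.
#' @param frac_dead_cells Probability that a non-empty region holds dead
#'   cells. Neighbouring cells share state, so this is also the expected
#'   dead-patch fraction.
#' @param frac_empty_regions Probability that a grid region holds no cells.
#' @param fluor_mixture List with `mu_live`, `sigma_live`, `mu_dead`,
#'   `sigma_dead`, `weight_live`, in raw (16-bit) intensity units. Defaults
#'   are the component estimates of the untreated reference condition
#'   (224.51 / 34.46 and 550.44 / 153.55) with equal weights.
#' @param noise_sd Per-pixel Gaussian noise on the fluorescence channel, raw
#'   intensity units.
#' @param condition `"no_treatment"` or `"treated"`. Choosing `"treated"`
#'   without explicit `frac_dead_cells` / `weight_live` applies the severely
#'   imbalanced defaults (8% live).
#' @param rng_seed Integer seed; together with the image index it fixes every
#'   generated byte.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_raw_images = 8,
                             image_width = 1344, image_height = 1024,
                             cells_per_image = c(40, 80),
                             frac_dead_cells = NULL,
                             frac_empty_regions = 0.1,
                             fluor_mixture = list(),
                             noise_sd = 8,
                             condition = c("no_treatment", "treated"),
                             rng_seed = 1L) {
  condition <- match.arg(condition)
  mix_default <- list(mu_live = 224.51, sigma_live = 34.46,
                      mu_dead = 550.44, sigma_dead = 153.55,
                      weight_live = if (condition == "treated") 0.08 else 0.5)
  mix <- utils::modifyList(mix_default, fluor_mixture)
  if (is.null(frac_dead_cells)) {
    frac_dead_cells <- 1 - mix$weight_live
  }
  cfg <- list(n_raw_images = as.integer(n_raw_images),
              image_width = as.integer(image_width),
              image_height = as.integer(image_height),
              cells_per_image = as.integer(cells_per_image),
              frac_dead_cells = frac_dead_cells,
              frac_empty_regions = frac_empty_regions,
              fluor_mixture = mix,
              noise_sd = noise_sd,
              condition = condition,
              rng_seed = as.integer(rng_seed))
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  m <- cfg$fluor_mixture
  if (cfg$n_raw_images < 1) stop("n_raw_images must be >= 1")
  if (cfg$image_width < PATCH_SIZE || cfg$image_height < PATCH_SIZE) {
    stop("image dimensions (", cfg$image_width, "x", cfg$image_height,
         ") are smaller than one ", PATCH_SIZE, "-px patch: unusable geometry")
  }
  if (length(cfg$cells_per_image) != 2 || any(cfg$cells_per_image < 0) ||
      cfg$cells_per_image[1] > cfg$cells_per_image[2]) {
    stop("cells_per_image must be a non-decreasing range of length 2")
  }
  for (p in c("frac_dead_cells", "frac_empty_regions")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must lie in [0, 1]")
  }
  if (!(m$mu_live < m$mu_dead)) stop("fluor_mixture requires mu_live < mu_dead")
  if (m$sigma_live <= 0 || m$sigma_dead <= 0) stop("mixture sigmas must be > 0")
  if (m$weight_live <= 0 || m$weight_live >= 1) stop("weight_live must be in (0, 1)")
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0")
  invisible(cfg)
}

#' @export
print.synthetic_config <- function(x, ...) {
  m <- x$fluor_mixture
  cat("<synthetic_config>", x$n_raw_images, "images",
      paste0(x$image_width, "x", x$image_height), "-", x$condition, "\n")
  cat(sprintf("  mixture: live N(%.2f, %.2f) / dead N(%.2f, %.2f), weight_live %.2f\n",
              m$mu_live, m$sigma_live, m$mu_dead, m$sigma_dead, m$weight_live))
  cat(sprintf("  frac_dead %.2f, frac_empty %.2f, noise_sd %.1f, seed %d\n",
              x$frac_dead_cells, x$frac_empty_regions, x$noise_sd, x$rng_seed))
  invisible(x)
}

# Per-image seed derived from the config seed; kept inside 32-bit range.
image_seed <- function(rng_seed, image_index) {
  as.integer((as.numeric(rng_seed) * 10007 + image_index) %% 2147483647)
}

# Draw from one Gaussian component truncated to its side of the discard band
# (dead >= mu_dead - sigma_dead + margin, live <= mu_live + sigma_live -
# margin), so ground-truth state and the threshold rule agree by design.
draw_region_target <- function(state, m, margin = 1) {
  if (state == "dead") {
    lo <- m$mu_dead - m$sigma_dead + margin
    repeat {
      v <- rnorm(1, m$mu_dead, m$sigma_dead)
      if (v >= lo) return(v)
    }
  } else {
    hi <- m$mu_live + m$sigma_live - margin
    repeat {
      v <- rnorm(1, m$mu_live, m$sigma_live)
      if (v <= hi && v >= 0) return(v)
    }
  }
}

# Add a radially symmetric bump (value * exp(-d^2 / (2 sigma^2))) to `img`
# inside a local window around (cx, cy). Returns the modified matrix.
add_radial_bump <- function(img, cx, cy, sigma, value) {
  h <- nrow(img); w <- ncol(img)
  r <- ceiling(3 * sigma)
  ys <- max(1, round(cy) - r):min(h, round(cy) + r)
  xs <- max(1, round(cx) - r):min(w, round(cx) + r)
  d2 <- outer((ys - cy)^2, (xs - cx)^2, "+")
  img[ys, xs] <- img[ys, xs] + value * exp(-d2 / (2 * sigma^2))
  img
}

# Render one live cell: crisp darker ellipse plus a small dark nucleus.
render_live_cell <- function(bf, cx, cy, rx, ry, body_drop, nucleus_drop) {
  h <- nrow(bf); w <- ncol(bf)
  ys <- max(1, round(cy - ry)):min(h, round(cy + ry))
  xs <- max(1, round(cx - rx)):min(w, round(cx + rx))
  inside <- outer(((ys - cy) / ry)^2, ((xs - cx) / rx)^2, "+") <= 1
  bf[ys, xs][inside] <- bf[ys, xs][inside] - body_drop
  add_radial_bump(bf, cx, cy, sigma = 2.5, value = -nucleus_drop)
}

# Render one region (224 x 224) of both channels plus its ground truth.
render_region <- function(state, n_cells, cfg) {
  ps <- PATCH_SIZE
  m <- cfg$fluor_mixture
  bf_bg <- 36000
  bf <- matrix(bf_bg + rnorm(ps * ps, sd = 500), ps, ps)
  blob <- matrix(0, ps, ps)
  cells <- NULL
  if (state != "empty" && n_cells > 0) {
    cx <- runif(n_cells, 20, ps - 20)
    cy <- runif(n_cells, 20, ps - 20)
    if (state == "live") {
      rx <- runif(n_cells, 10, 18)
      ry <- runif(n_cells, 10, 18)
      for (k in seq_len(n_cells)) {
        bf <- render_live_cell(bf, cx[k], cy[k], rx[k], ry[k],
                               body_drop = runif(1, 3000, 5000),
                               nucleus_drop = runif(1, 12000, 16000))
      }
    } else {
      rx <- ry <- runif(n_cells, 14, 24)
      for (k in seq_len(n_cells)) {
        # blurred dark halo in bright-field, bright blob in fluorescence
        bf <- add_radial_bump(bf, cx[k], cy[k], sigma = rx[k],
                              value = -runif(1, 12000, 18000))
        blob <- add_radial_bump(blob, cx[k], cy[k], sigma = 0.9 * rx[k],
                                value = runif(1, 1500, 2500))
      }
    }
    cells <- tibble::tibble(cx = cx, cy = cy, rx = rx, ry = ry)
  }
  target <- draw_region_target(if (state == "dead") "dead" else "live", m)
  mb <- mean(blob)
  base <- target - mb
  if (mb > 0 && base < 3 * cfg$noise_sd) {
    # blobs too bright for the drawn mean: rescale so the flat base stays
    # comfortably positive while the patch mean still equals the target
    blob <- blob * (target / 2) / mb
    base <- target / 2
  }
  fl <- base + blob
  if (cfg$noise_sd > 0) fl <- fl + rnorm(ps * ps, sd = cfg$noise_sd)
  list(bf = bf, fl = fl, target = target, cells = cells)
}

#' Generate one synthetic raw image pair with ground truth
#'
#' Deterministic in `(config$rng_seed, image_index)`: the same pair of values
#' always produces bit-identical images.
#'
#' @param config A [synthetic_config()].
#' @param image_index Positive integer index of the image within the dataset.
#' @return A list with `pair` (class `raw_image_pair`: `raw_image_id`,
#'   integer `bright_field` and `fluorescence` matrices in \[0, 65535\], and
#'   `condition`) and `ground_truth`, a tibble with one row per 224-px grid
#'   region: offsets, `state` (live/dead/empty), `empty` flag, cell count and
#'   footprints, and the realised `mean_fluorescence` of the region.
#' @export
generate_raw_pair <- function(config, image_index) {
  stopifnot(inherits(config, "synthetic_config"))
  validate_synthetic_config(config)
  ps <- PATCH_SIZE
  w <- config$image_width; h <- config$image_height
  nx <- w %/% ps; ny <- h %/% ps
  id <- sprintf("%s_img%04d", config$condition, as.integer(image_index))
  withr::with_seed(image_seed(config$rng_seed, image_index), {
    states <- matrix("live", ny, nx)
    states[matrix(runif(ny * nx) < config$frac_empty_regions, ny, nx)] <- "empty"
    nonempty <- states != "empty"
    states[nonempty & matrix(runif(ny * nx), ny, nx) < config$frac_dead_cells] <- "dead"
    states[nonempty & states == "live"] <- "live"
    n_total_cells <- if (config$cells_per_image[1] == config$cells_per_image[2]) {
      config$cells_per_image[1]
    } else {
      sample(config$cells_per_image[1]:config$cells_per_image[2], 1)
    }
    n_nonempty <- sum(states != "empty")
    counts <- matrix(0L, ny, nx)
    if (n_nonempty > 0) {
      per <- rep(1L, n_nonempty)
      extra <- max(0L, n_total_cells - n_nonempty)
      if (extra > 0) {
        add <- tabulate(sample.int(n_nonempty, extra, replace = TRUE), n_nonempty)
        per <- per + add
      }
      counts[states != "empty"] <- per
    }
    bf <- matrix(36000 + rnorm(h * w, sd = 500), h, w)
    fl_base <- draw_region_target("live", config$fluor_mixture)
    fl <- matrix(fl_base, h, w)
    if (config$noise_sd > 0) fl <- fl + rnorm(h * w, sd = config$noise_sd)
    gt <- vector("list", ny * nx)
    k <- 0L
    for (ry in seq_len(ny)) {
      for (rx in seq_len(nx)) {
        k <- k + 1L
        reg <- render_region(states[ry, rx], counts[ry, rx], config)
        ys <- ((ry - 1L) * ps + 1L):(ry * ps)
        xs <- ((rx - 1L) * ps + 1L):(rx * ps)
        bf[ys, xs] <- reg$bf
        fl[ys, xs] <- reg$fl
        gt[[k]] <- tibble::tibble(
          raw_image_id = id,
          region_row = ry, region_col = rx,
          x_offset = (rx - 1L) * ps, y_offset = (ry - 1L) * ps,
          state = states[ry, rx],
          empty = states[ry, rx] == "empty",
          n_cells = counts[ry, rx],
          cells = list(reg$cells),
          target_mean = reg$target
        )
      }
    }
    bf <- matrix(as.integer(pmin(pmax(round(bf), 0), 65535)), h, w)
    fl <- matrix(as.integer(pmin(pmax(round(fl), 0), 65535)), h, w)
    gt <- dplyr::bind_rows(gt)
    gt$mean_fluorescence <- vapply(seq_len(nrow(gt)), function(i) {
      ys <- gt$y_offset[i] + seq_len(ps)
      xs <- gt$x_offset[i] + seq_len(ps)
      mean(fl[ys, xs])
    }, numeric(1))
    pair <- structure(list(raw_image_id = id, bright_field = bf,
                           fluorescence = fl, condition = config$condition),
                      class = "raw_image_pair")
    list(pair = pair, ground_truth = gt)
  })
}

#' @export
print.raw_image_pair <- function(x, ...) {
  cat("<raw_image_pair>", x$raw_image_id, "-", x$condition, "-",
      nrow(x$bright_field), "x", ncol(x$bright_field), "px\n")
  invisible(x)
}

#' Generate a synthetic dataset on disk
#'
#' Writes 16-bit TIFF pairs, a manifest CSV (`raw_image_id`, `channel`,
#' `path`, `condition`), a ground-truth CSV and a JSON copy of the
#' configuration, mirroring the on-disk layout the loading functions expect.
#'
#' @param config A [synthetic_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with `manifest` and `ground_truth` tibbles and
#'   the `config`.
#' @export
generate_dataset <- function(config, out_dir) {
  stopifnot(inherits(config, "synthetic_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", config$n_raw_images)
  gts <- vector("list", config$n_raw_images)
  for (i in seq_len(config$n_raw_images)) {
    g <- generate_raw_pair(config, i)
    bf_path <- file.path(out_dir, paste0(g$pair$raw_image_id, "_bf.tif"))
    fl_path <- file.path(out_dir, paste0(g$pair$raw_image_id, "_fl.tif"))
    write_image_16bit(g$pair$bright_field, bf_path)
    write_image_16bit(g$pair$fluorescence, fl_path)
    rows[[i]] <- tibble::tibble(
      raw_image_id = g$pair$raw_image_id,
      channel = c("bright_field", "fluorescence"),
      path = c(bf_path, fl_path),
      condition = config$condition)
    gts[[i]] <- g$ground_truth
  }
  manifest <- dplyr::bind_rows(rows)
  ground_truth <- dplyr::bind_rows(gts)
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
  readr::write_csv(dplyr::select(ground_truth, -"cells"),
                   file.path(out_dir, "ground_truth.csv"))
  cfg <- unclass(config)
  jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(manifest = manifest, ground_truth = ground_truth,
                 config = config))
}

#' Draw per-patch mean fluorescence values from a two-component mixture
#'
#' Independent draws from the Gaussian mixture that models per-patch mean
#' fluorescence: a low (mostly live) and a high (mostly dead) component.
#'
#' @param mixture A list or fitted mixture with fields `mu_live`,
#'   `sigma_live`, `mu_dead`, `sigma_dead`, `weight_live`.
#' @param n Number of draws (>= 1).
#' @param seed Optional integer seed for reproducible draws.
#' @return Numeric vector of length `n`, raw intensity units.
#' @export
sample_fluorescence_means <- function(mixture, n, seed = NULL) {
  m <- mixture_params(mixture)
  if (n < 1) stop("n must be >= 1")
  if (m$sigma_live < 0 || m$sigma_dead < 0) stop("mixture sigmas must be >= 0")
  if (m$weight_live < 0 || m$weight_live > 1) stop("weight_live must be in [0, 1]")
  draw <- function() {
    live <- runif(n) < m$weight_live
    ifelse(live, rnorm(n, m$mu_live, m$sigma_live),
           rnorm(n, m$mu_dead, m$sigma_dead))
  }
  if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
}

# Accepts a plain list, a synthetic_config or a fitted mixture_model and
# returns the five mixture parameters.
mixture_params <- function(mixture) {
  if (inherits(mixture, "synthetic_config")) mixture <- mixture$fluor_mixture
  if (inherits(mixture, "mixture_model")) {
    mixture <- list(mu_live = mixture$mu_live, sigma_live = mixture$sigma_live,
                    mu_dead = mixture$mu_dead, sigma_dead = mixture$sigma_dead,
                    weight_live = mixture$weight_live)
  }
  need <- c("mu_live", "sigma_live", "mu_dead", "sigma_dead", "weight_live")
  missing <- setdiff(need, names(mixture))
  if (length(missing)) stop("mixture lacks fields: ", paste(missing, collapse = ", "))
  mixture[need]
}
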