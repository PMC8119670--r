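# Reading raw image pairs, bit-depth conversion and patch cropping.

#' Write / read a 16-bit grayscale TIFF
#'
#' Thin wrappers around the tiff package storing raw integer intensities in
#' \[0, 65535\].
#'
#' @param image Integer or numeric matrix with values in \[0, 65535\].
#' @param path File path.
#' @return `read_image_16bit` returns an integer matrix; `write_image_16bit`
#'   returns `path` invisibly.
#' @export
write_image_16bit <- function(image, path) {
  stopifnot(is.matrix(image))
  tiff::writeTIFF(image / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' @rdname write_image_16bit
#' @export
read_image_16bit <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}

#' Convert a 16-bit image to 8-bit
#'
#' Linear full-range rescale by 1/257 (65535 maps to 255), rounding half away
#' from zero. Out-of-range inputs are clamped with a warning.
#'
#' @param image Numeric matrix (or array) with values expected in
#'   \[0, 65535\].
#' @return The same shape with integer values in \[0, 255\].
#' @export
convert_16bit_to_8bit <- function(image) {
  v <- as.numeric(image)
  n_out <- sum(v < 0 | v > 65535)
  if (n_out > 0) {
    warning(n_out, " value(s) outside [0, 65535] were clamped")
    v <- pmin(pmax(v, 0), 65535)
  }
  out <- floor(v / 257 + 0.5) # round half away from zero (inputs are >= 0)
  out <- as.integer(out)
  if (is.matrix(image)) out <- matrix(out, nrow(image), ncol(image))
  out
}

# Offsets {0, stride, 2 stride, ...} plus one trailing offset flush with the
# far edge when the grid does not land exactly on it.
grid_offsets <- function(extent, patch_size, stride) {
  last <- extent - patch_size
  offs <- seq.int(0L, last, by = stride)
  if (offs[length(offs)] != last) offs <- c(offs, last)
  as.integer(offs)
}

#' Crop a raw image pair into registered 224 x 224 patch pairs
#'
#' Both channels are cropped at identical offsets on a regular grid with the
#' given stride, plus one trailing patch flush with each far edge so no pixel
#' is lost. Coordinates are 0-based with a top-left origin; a patch occupies
#' the half-open window `[offset, offset + patch_size)`.
#'
#' @param pair A `raw_image_pair` (see [generate_raw_pair()] or
#'   [load_dataset()]).
#' @param patch_size Patch side length in px (default 224).
#' @param stride Grid step in px (default 112, i.e. 50% overlap).
#' @return A tibble with one row per patch: `patch_id`, `raw_image_id`,
#'   `condition`, `x_offset`, `y_offset`, and list-columns `bright_field`
#'   and `fluorescence` holding the raw-intensity crops.
#' @export
crop_patches <- function(pair, patch_size = 224L, stride = 112L) {
  stopifnot(inherits(pair, "raw_image_pair"))
  patch_size <- as.integer(patch_size)
  stride <- as.integer(stride)
  if (stride < 1) stop("stride must be >= 1")
  h <- nrow(pair$bright_field); w <- ncol(pair$bright_field)
  if (!identical(dim(pair$bright_field), dim(pair$fluorescence))) {
    stop("channel dimensions differ for ", pair$raw_image_id)
  }
  if (patch_size > h || patch_size > w) {
    stop("patch size ", patch_size, " exceeds image dimensions ", w, "x", h)
  }
  xs <- grid_offsets(w, patch_size, stride)
  ys <- grid_offsets(h, patch_size, stride)
  grid <- expand.grid(y_offset = ys, x_offset = xs, KEEP.OUT.ATTRS = FALSE)
  crops_bf <- vector("list", nrow(grid))
  crops_fl <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    yr <- grid$y_offset[i] + seq_len(patch_size)
    xr <- grid$x_offset[i] + seq_len(patch_size)
    crops_bf[[i]] <- pair$bright_field[yr, xr]
    crops_fl[[i]] <- pair$fluorescence[yr, xr]
  }
  tibble::tibble(
    patch_id = sprintf("%s_x%04d_y%04d", pair$raw_image_id,
                       grid$x_offset, grid$y_offset),
    raw_image_id = pair$raw_image_id,
    condition = pair$condition %||% NA_character_,
    x_offset = as.integer(grid$x_offset),
    y_offset = as.integer(grid$y_offset),
    bright_field = crops_bf,
    fluorescence = crops_fl)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load raw image pairs from a manifest
#'
#' Reads a manifest CSV with columns `raw_image_id`, `channel`
#' (`bright_field` / `fluorescence`), `path` and optionally `condition`, and
#' pairs the two channels by `raw_image_id`. Unmatched rows are reported in
#' the `unpaired` tibble, never silently dropped.
#'
#' @param manifest Path to the manifest CSV, or an equivalent data frame.
#' @return A list with `pairs` (list of `raw_image_pair`) and `unpaired`
#'   (tibble of ids lacking one channel, with the missing channel named).
#' @export
load_dataset <- function(manifest) {
  man <- if (is.character(manifest)) {
    readr::read_csv(manifest, show_col_types = FALSE)
  } else {
    tibble::as_tibble(manifest)
  }
  need <- c("raw_image_id", "channel", "path")
  if (!all(need %in% names(man))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  }
  missing_files <- man$path[!file.exists(man$path)]
  if (length(missing_files)) {
    stop("manifest references missing file(s): ",
         paste(utils::head(missing_files, 3), collapse = ", "))
  }
  wide <- tidyr::pivot_wider(man, id_cols = dplyr::any_of(c("raw_image_id", "condition")),
                             names_from = "channel", values_from = "path")
  for (ch in c("bright_field", "fluorescence")) {
    if (!ch %in% names(wide)) wide[[ch]] <- NA_character_
  }
  unpaired <- wide |>
    dplyr::filter(is.na(.data$bright_field) | is.na(.data$fluorescence)) |>
    dplyr::mutate(missing_channel = ifelse(is.na(.data$bright_field),
                                           "bright_field", "fluorescence")) |>
    dplyr::select("raw_image_id", "missing_channel")
  complete <- dplyr::filter(wide, !is.na(.data$bright_field) &
                              !is.na(.data$fluorescence))
  pairs <- lapply(seq_len(nrow(complete)), function(i) {
    bf <- read_image_16bit(complete$bright_field[i])
    fl <- read_image_16bit(complete$fluorescence[i])
    if (!identical(dim(bf), dim(fl))) {
      stop("channel dimension mismatch for ", complete$raw_image_id[i], ": ",
           paste(dim(bf), collapse = "x"), " vs ", paste(dim(fl), collapse = "x"))
    }
    cond <- if ("condition" %in% names(complete)) complete$condition[i] else NA_character_
    structure(list(raw_image_id = complete$raw_image_id[i],
                   bright_field = bf, fluorescence = fl, condition = cond),
              class = "raw_image_pair")
  })
  if (nrow(unpaired) > 0) {
    warning(nrow(unpaired), " raw image id(s) lack a channel partner; ",
            "see the 'unpaired' element")
  }
  list(pairs = pairs, unpaired = unpaired)
}
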