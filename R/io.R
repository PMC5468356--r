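# Image, seed-table and configuration I/O. Internal pixel convention is
# always an H x W x 3 array in RGB channel order with values 0-255;
# coordinates are 1-based (row, col) with row increasing downward.

#' Read an RGB image from PNG or TIFF
#'
#' Grayscale input is promoted by channel replication and an alpha channel
#' is dropped, each with a warning. Values are returned on the 0--255
#' scale.
#'
#' @param path File path (`.png`, `.tif`/`.tiff`).
#' @return H x W x 3 integer array.
#' @export
read_image <- function(path) {
  if (!file.exists(path))
    stop(sprintf("image file not found: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                stop(sprintf("unsupported image format '%s' for %s", ext, path),
                     call. = FALSE))
  if (is.matrix(img)) {
    warning(sprintf("%s is grayscale; replicating channels", basename(path)))
    img <- array(rep(img, 3), c(dim(img), 3))
  }
  if (dim(img)[3] == 4L) {
    warning(sprintf("%s has an alpha channel; dropping it", basename(path)))
    img <- img[, , 1:3, drop = FALSE]
  }
  if (dim(img)[3] == 2L) {   # gray + alpha
    warning(sprintf("%s is grayscale with alpha; replicating channels", basename(path)))
    img <- array(rep(img[, , 1], 3), c(dim(img)[1:2], 3))
  }
  out <- round(img * 255)
  storage.mode(out) <- "integer"
  out
}

#' @rdname read_image
#' @param image H x W x 3 array (0--255).
#' @export
write_image <- function(image, path) {
  ext <- tolower(tools::file_ext(path))
  arr <- clip01(image / 255)
  switch(ext,
         png = png::writePNG(arr, path),
         tif = ,
         tiff = tiff::writeTIFF(arr, path, bits.per.sample = 8L),
         stop(sprintf("unsupported image format '%s'", ext), call. = FALSE))
  invisible(path)
}

#' Read and write seed-point tables
#'
#' CSV with header `image_id,row,col,class[,area]`; coordinates 1-based.
#' The class vocabulary is validated against [nucleus_classes()] and a
#' parse error names the offending line.
#'
#' @param path CSV path.
#' @return data.frame with columns `image_id`, `row`, `col`, `class` and,
#'   if present, `area`.
#' @export
read_seeds <- function(path) {
  if (!file.exists(path))
    stop(sprintf("seeds file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", "row", "col", "class")
  if (!all(need %in% names(df)))
    stop(sprintf("seeds CSV must have columns %s", paste(need, collapse = ",")),
         call. = FALSE)
  bad <- which(!df$class %in% nucleus_classes())
  if (length(bad))
    stop(sprintf("unknown class '%s' at line %d of %s",
                 df$class[bad[1]], bad[1] + 1L, path), call. = FALSE)
  df
}

#' @rdname read_seeds
#' @param seeds data.frame with `row`, `col`, `class` (and optionally
#'   `image_id`, `area`).
#' @param image_id Identifier used when `seeds` lacks one.
#' @export
write_seeds <- function(seeds, path, image_id = "image") {
  if (!"image_id" %in% names(seeds) && nrow(seeds) >= 0)
    seeds <- cbind(image_id = rep(image_id, nrow(seeds)), seeds)
  keep <- intersect(c("image_id", "row", "col", "class", "area"), names(seeds))
  utils::write.csv(seeds[, keep, drop = FALSE], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

config_defaults <- function() list(
  scene = list(image_height = 256L, image_width = 256L,
               n_immunopositive = 10L, n_immunonegative = 30L,
               nucleus_radius_min = 8, nucleus_radius_max = 14,
               overlap_fraction = 0, color_jitter_sd = 8, noise_sd = 5),
  detection = list(components_per_class = 1L, em_tol = 1e-5,
                   em_max_iter = 200L, covariance_floor = 1.0, beta = 0,
                   min_component_area = 30L),
  split = list(train_fraction = 0.7, val_fraction = 0.3, k_folds = 5L),
  network = list(profile = "desk", dropout_ratio = 0.5),
  train = list(learning_rate = 0.01, momentum = 0.85, weight_decay = 0.005,
               batch_size = 128L, max_iter = 450000L, test_interval = 5000L),
  rng_seed = 1L)

merge_config <- function(defaults, override, path = character()) {
  extra <- setdiff(names(override), names(defaults))
  if (length(extra))
    stop(sprintf("unknown config key(s): %s",
                 paste(c(paste(path, collapse = "."), extra), collapse = ".")),
         call. = FALSE)
  for (nm in names(override)) {
    if (is.list(defaults[[nm]]) && is.list(override[[nm]]))
      defaults[[nm]] <- merge_config(defaults[[nm]], override[[nm]],
                                     c(path, nm))
    else defaults[[nm]] <- override[[nm]]
  }
  defaults
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file, merges it over the built-in defaults (the reference
#' optimizer settings: learning rate 0.01, momentum 0.85, weight decay
#' 0.005, batch 128, dropout 0.5, test interval 5000, 450,000 iterations)
#' and validates every section; unknown keys are rejected.
#'
#' @param path YAML path, or `NULL` for pure defaults.
#' @return Nested list of class `run_config` (sections `scene`,
#'   `detection`, `split`, `network`, `train`, plus `rng_seed`).
#' @export
load_config <- function(path = NULL) {
  cfg <- config_defaults()
  if (!is.null(path)) {
    if (!file.exists(path))
      stop(sprintf("config file not found: %s", path), call. = FALSE)
    override <- yaml::read_yaml(path)
    if (!is.null(override)) cfg <- merge_config(cfg, override)
  }
  problems <- character(0)
  if (cfg$train$learning_rate < 0)
    problems <- c(problems, "train.learning_rate must be >= 0")
  if (cfg$train$momentum < 0 || cfg$train$momentum >= 1)
    problems <- c(problems, "train.momentum must be in [0, 1)")
  if (cfg$network$dropout_ratio < 0 || cfg$network$dropout_ratio >= 1)
    problems <- c(problems, "network.dropout_ratio must be in [0, 1)")
  if (cfg$detection$beta < 0)
    problems <- c(problems, "detection.beta must be >= 0")
  if (cfg$split$train_fraction + cfg$split$val_fraction > 1 + 1e-9)
    problems <- c(problems, "split fractions must sum to at most 1")
  if (length(problems))
    stop(paste(c("invalid configuration:", problems), collapse = "\n  "),
         call. = FALSE)
  structure(cfg, class = "run_config")
}

#' Write a reproducibility manifest
#'
#' Records the resolved configuration, the seeds used and the MD5
#' checksum of each artifact, sufficient to reproduce a run bit-for-bit.
#'
#' @param path Output JSON path.
#' @param config The resolved configuration (any list).
#' @param seed Master seed of the run.
#' @param artifacts Character vector of file paths to checksum.
#' @export
write_manifest <- function(path, config, seed, artifacts = character()) {
  sums <- if (length(artifacts))
    as.list(tools::md5sum(artifacts)) else list()
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  config <- strip(config)
  jsonlite::write_json(list(config = config, rng_seed = seed,
                            artifacts = sums),
                       path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
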