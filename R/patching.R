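# Patch extraction around seed points and dataset splitting. The
# classifier's input unit is a fixed 71 x 71 RGB crop centered on a seed
# centroid; 71 is odd so the centroid sits on an exact center pixel.

#' Crop a fixed-size patch centered on a seed point
#'
#' The seed maps to patch index `(floor(size/2) + 1, floor(size/2) + 1)`
#' (1-based). Regions falling outside the image are handled by the
#' `boundary` policy: `"reflect"` mirrors the image content (default, keeps
#' every seed usable near borders without constant-color artifacts),
#' `"constant"` pads with `fill`, `"skip"` returns `NULL` so the caller can
#' omit the patch.
#'
#' @param image H x W x 3 numeric array.
#' @param seed List or one-row data.frame with `row`, `col` (1-based).
#' @param size Patch side in pixels (default 71).
#' @param boundary One of `"reflect"`, `"constant"`, `"skip"`.
#' @param fill Fill value for `boundary = "constant"`.
#' @return `size` x `size` x 3 array, or `NULL` when `boundary = "skip"`
#'   and the patch exceeds the image.
#' @export
crop_patch <- function(image, seed, size = 71L,
                       boundary = c("reflect", "constant", "skip"),
                       fill = 0) {
  boundary <- match.arg(boundary)
  d <- dim(image)
  H <- d[1]; W <- d[2]
  r0 <- as.integer(seed$row); c0 <- as.integer(seed$col)
  if (r0 < 1 || r0 > H || c0 < 1 || c0 > W)
    stop("seed lies outside the image", call. = FALSE)
  half <- size %/% 2L
  rows <- (r0 - half):(r0 - half + size - 1L)
  cols <- (c0 - half):(c0 - half + size - 1L)
  oob <- any(rows < 1L) || any(rows > H) || any(cols < 1L) || any(cols > W)
  if (!oob) return(image[rows, cols, , drop = FALSE])
  switch(boundary,
    skip = NULL,
    constant = {
      out <- array(fill, c(size, size, d[3]))
      rin <- rows >= 1L & rows <= H
      cin <- cols >= 1L & cols <= W
      out[rin, cin, ] <- image[rows[rin], cols[cin], , drop = FALSE]
      out
    },
    reflect = {
      if (size > 2L * min(H, W))
        warning("patch larger than image extent; reflection tiling applied")
      image[reflect_index(rows, H), reflect_index(cols, W), , drop = FALSE]
    })
}

# Mirror out-of-range indices into [1, n] (reflection without edge repeat,
# tiling for arbitrarily far indices).
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  period <- 2L * (n - 1L)
  j <- (i - 1L) %% period
  j <- ifelse(j >= n, period - j, j)
  as.integer(j + 1L)
}

#' Crop patches for a table of seeds
#'
#' Vectorized convenience over [crop_patch()]; skipped patches (under
#' `boundary = "skip"`) are dropped from the output with a message.
#'
#' @inheritParams crop_patch
#' @param seeds data.frame with columns `row`, `col` and optionally
#'   `class`.
#' @return List: `patches` (size x size x 3 x n array, values rescaled to
#'   `[0, 1]`), `labels` (factor of classes or `NULL`), `kept` (indices of
#'   seeds retained).
#' @export
crop_patches <- function(image, seeds, size = 71L, boundary = "reflect") {
  n <- nrow(seeds)
  keep <- logical(n)
  arrs <- vector("list", n)
  for (i in seq_len(n)) {
    p <- crop_patch(image, seeds[i, ], size = size, boundary = boundary)
    if (!is.null(p)) { arrs[[i]] <- p; keep[i] <- TRUE }
  }
  if (sum(!keep))
    message(sprintf("%d seed(s) omitted: patch exceeds image bounds under boundary='skip'",
                    sum(!keep)))
  kept <- which(keep)
  out <- array(0, c(size, size, 3, length(kept)))
  for (j in seq_along(kept)) out[, , , j] <- arrs[[kept[j]]] / 255
  labels <- if ("class" %in% names(seeds))
    factor(seeds$class[kept], levels = nucleus_classes()) else NULL
  list(patches = out, labels = labels, kept = kept)
}

#' Split patches into stratified train/validation sets or k folds
#'
#' Class-stratified partitioning, reproducible from `rng_seed`. With
#' `k_folds >= 2`, returns disjoint exhaustive folds each holding
#' `1/k` of every class (within one patch). Otherwise returns a
#' train/validation split at the given fractions. `group_by_image = TRUE`
#' keeps all patches of one source image in the same fold (leakage
#' control) at the cost of exact stratification.
#'
#' @param labels Factor/character vector of patch classes.
#' @param k_folds `NULL` (train/val mode) or integer >= 2.
#' @param train_fraction,val_fraction Fractions for train/val mode
#'   (defaults 0.7 / 0.3).
#' @param image_id Optional vector of source-image ids (for grouping).
#' @param group_by_image Keep each image's patches in one fold.
#' @param rng_seed Integer seed.
#' @return In fold mode, an integer vector of fold ids (1..k). In
#'   train/val mode, a character vector of `"train"` / `"val"`.
#' @export
build_splits <- function(labels, k_folds = NULL,
                         train_fraction = 0.7, val_fraction = 0.3,
                         image_id = NULL, group_by_image = FALSE,
                         rng_seed = 1L) {
  labels <- as.character(labels)
  n <- length(labels)
  if (length(unique(labels)) < 2L)
    stop("stratification requires both nucleus classes to be present",
         call. = FALSE)
  if (!is.null(k_folds)) {
    k <- as.integer(k_folds)
    if (k < 2L) stop("k_folds must be >= 2", call. = FALSE)
    if (n < k) stop("fewer patches than folds", call. = FALSE)
    fold <- with_seed(rng_seed, {
      if (group_by_image && !is.null(image_id)) {
        ids <- sample(unique(image_id))
        gf <- rep_len(seq_len(k), length(ids))
        gf[match(image_id, ids)]
      } else {
        f <- integer(n)
        cnt <- 0L   # continue the fold cycle across classes to balance totals
        for (cl in unique(labels)) {
          idx <- sample(which(labels == cl))
          f[idx] <- ((cnt + seq_along(idx) - 1L) %% k) + 1L
          cnt <- cnt + length(idx)
        }
        f
      }
    })
    return(fold)
  }
  if (train_fraction <= 0 || val_fraction <= 0 ||
      train_fraction + val_fraction > 1 + 1e-9)
    stop("fractions must be positive and sum to at most 1", call. = FALSE)
  with_seed(rng_seed, {
    split <- character(n)
    # largest-remainder allocation so the global train count is exactly
    # round(n * train_fraction) while staying stratified
    cls <- unique(labels)
    sizes <- vapply(cls, function(cl) sum(labels == cl), integer(1))
    quota <- sizes * train_fraction
    n_tr <- pmin(floor(quota), sizes)
    rem <- round(n * train_fraction) - sum(n_tr)
    if (rem > 0) {
      ord <- order(quota - floor(quota), decreasing = TRUE)
      for (j in ord) {
        if (rem == 0) break
        if (n_tr[j] < sizes[j]) { n_tr[j] <- n_tr[j] + 1L; rem <- rem - 1L }
      }
    }
    for (j in seq_along(cls)) {
      idx <- sample(which(labels == cls[j]))
      tr <- idx[seq_len(n_tr[j])]
      split[tr] <- "train"
      split[setdiff(idx, tr)] <- "val"
    }
    split
  })
}
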