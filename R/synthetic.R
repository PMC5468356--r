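# Synthetic immunohistochemistry-like scene generator.
#
# Emulates brightfield Ki-67 fields: brown (immunopositive) and blue
# (immunonegative) elliptical nuclei on a pale background, with per-image
# ground-truth seed coordinates, class labels and the true proliferation
# ratio, so every downstream stage is testable without clinical data.

#' Specify a synthetic IHC scene
#'
#' Describes one synthetic field: canvas size, nucleus counts per class,
#' nucleus geometry, class colors and noise. Identical `(spec, rng_seed)`
#' pairs reproduce an identical image bit-for-bit.
#'
#' @param image_height,image_width Canvas size in pixels.
#' @param n_immunopositive,n_immunonegative Nucleus counts per class.
#' @param nucleus_radius_range Length-2 vector, min/max semi-axis in pixels.
#' @param overlap_fraction Maximum allowed pairwise overlap, in `[0, 1]`.
#'   `0` forces pairwise-disjoint nucleus masks.
#' @param color_means List with RGB triplets (0--255) `immunopositive`
#'   (DAB brown), `immunonegative` (hematoxylin blue) and `background`.
#' @param color_jitter_sd Per-nucleus, per-channel SD of the color jitter.
#' @param noise_sd Additive per-pixel Gaussian noise SD (clipped to 8-bit).
#' @param rng_seed Integer seed driving all randomness of the scene.
#' @return An object of class `scene_spec`.
#' @examples
#' sp <- scene_spec(n_immunopositive = 13, n_immunonegative = 87)
#' @export
scene_spec <- function(image_height = 256L, image_width = 256L,
                       n_immunopositive = 10L, n_immunonegative = 30L,
                       nucleus_radius_range = c(8, 14),
                       overlap_fraction = 0,
                       color_means = list(
                         immunopositive = c(150, 100, 60),
                         immunonegative = c(70, 80, 150),
                         background     = c(235, 230, 240)),
                       color_jitter_sd = 8,
                       noise_sd = 5,
                       rng_seed = 1L) {
  stopifnot_scalar(image_height, "image_height", 1)
  stopifnot_scalar(image_width, "image_width", 1)
  stopifnot_scalar(n_immunopositive, "n_immunopositive", 0)
  stopifnot_scalar(n_immunonegative, "n_immunonegative", 0)
  if (length(nucleus_radius_range) != 2L ||
      nucleus_radius_range[1] > nucleus_radius_range[2] ||
      nucleus_radius_range[1] <= 0)
    stop("`nucleus_radius_range` must be positive (min, max) with min <= max",
         call. = FALSE)
  stopifnot_scalar(overlap_fraction, "overlap_fraction", 0, 1)
  need <- c("immunopositive", "immunonegative", "background")
  if (!all(need %in% names(color_means)))
    stop("`color_means` must name immunopositive, immunonegative, background",
         call. = FALSE)
  for (nm in need)
    if (any(color_means[[nm]] < 0) || any(color_means[[nm]] > 255))
      stop("color means must lie in [0, 255]", call. = FALSE)
  structure(list(
    image_height = as.integer(image_height),
    image_width = as.integer(image_width),
    n_immunopositive = as.integer(n_immunopositive),
    n_immunonegative = as.integer(n_immunonegative),
    nucleus_radius_range = as.numeric(nucleus_radius_range),
    overlap_fraction = overlap_fraction,
    color_means = lapply(color_means[need], as.numeric),
    color_jitter_sd = color_jitter_sd,
    noise_sd = noise_sd,
    rng_seed = as.integer(rng_seed)
  ), class = "scene_spec")
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf("Synthetic IHC scene: %d x %d px, %d immunopositive + %d immunonegative nuclei\n",
              x$image_height, x$image_width,
              x$n_immunopositive, x$n_immunonegative))
  cat(sprintf("  radii %.1f-%.1f px, overlap <= %.2f, jitter sd %.1f, noise sd %.1f, seed %d\n",
              x$nucleus_radius_range[1], x$nucleus_radius_range[2],
              x$overlap_fraction, x$color_jitter_sd, x$noise_sd, x$rng_seed))
  invisible(x)
}

# Rasterize one rotated ellipse; returns integer matrix indices (row, col).
ellipse_pixels <- function(cy, cx, a, b, theta, H, W) {
  r <- ceiling(max(a, b))
  rows <- max(1L, floor(cy - r)):min(H, ceiling(cy + r))
  cols <- max(1L, floor(cx - r)):min(W, ceiling(cx + r))
  if (!length(rows) || !length(cols)) return(cbind(row = integer(), col = integer()))
  g <- expand.grid(row = rows, col = cols)
  dy <- g$row - cy; dx <- g$col - cx
  u <-  dy * cos(theta) + dx * sin(theta)
  v <- -dy * sin(theta) + dx * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  cbind(row = g$row[inside], col = g$col[inside])
}

#' Generate one synthetic IHC image with ground truth
#'
#' Renders the scene described by a [scene_spec()]: rotated elliptical
#' nuclei with per-nucleus color jitter over a pale background, plus
#' additive Gaussian pixel noise, quantized to 8 bits. Ground truth records
#' every nucleus centroid, its class, a per-nucleus label image and the true
#' proliferation percentage.
#'
#' @param spec A [scene_spec()].
#' @return A list with elements `image` (H x W x 3 array, integer values
#'   0--255) and `truth` (list: `seeds` data.frame with columns
#'   `row`, `col`, `class`; `true_aps` percentage or `NA` for an empty
#'   scene; `nucleus_labels` integer H x W matrix, 0 = background).
#' @examples
#' out <- generate_image(scene_spec(n_immunopositive = 2, n_immunonegative = 3,
#'                                  image_height = 96, image_width = 96))
#' out$truth$true_aps  # 40
#' @export
generate_image <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  H <- spec$image_height; W <- spec$image_width
  n_pos <- spec$n_immunopositive; n_neg <- spec$n_immunonegative
  n_tot <- n_pos + n_neg
  rmax <- spec$nucleus_radius_range[2]
  # conservative capacity check: bounding circles packed at (2 rmax)^2 cells
  capacity <- floor(H / (2 * rmax)) * floor(W / (2 * rmax))
  if (spec$overlap_fraction == 0 && n_tot > capacity)
    stop(sprintf(paste0("canvas %dx%d cannot hold %d disjoint nuclei of max ",
                        "radius %.1f (capacity ~%d); reduce counts or ",
                        "nucleus_radius_range"),
                 H, W, n_tot, rmax, capacity), call. = FALSE)

  with_seed(spec$rng_seed, {
    img <- array(rep(spec$color_means$background, each = H * W), c(H, W, 3))
    labels <- matrix(0L, H, W)
    classes <- rep(nucleus_classes(), c(n_pos, n_neg))
    if (n_tot > 0) classes <- sample(classes)  # interleave placement order
    seeds <- data.frame(row = integer(0), col = integer(0),
                        class = character(0), stringsAsFactors = FALSE)
    placed <- data.frame(cy = numeric(0), cx = numeric(0), r = numeric(0))
    for (i in seq_len(n_tot)) {
      ok <- FALSE
      for (try in seq_len(400L)) {
        a <- runif(1, spec$nucleus_radius_range[1], spec$nucleus_radius_range[2])
        b <- runif(1, spec$nucleus_radius_range[1], spec$nucleus_radius_range[2])
        theta <- runif(1, 0, pi)
        rr <- max(a, b)
        cy <- runif(1, 1 + rr, H - rr)
        cx <- runif(1, 1 + rr, W - rr)
        if (nrow(placed)) {
          d <- sqrt((placed$cy - cy)^2 + (placed$cx - cx)^2)
          sep <- placed$r + rr
          # overlap_fraction scales how deeply bounding circles may
          # interpenetrate; at 0, a 2 px margin keeps rasterized masks from
          # even touching diagonally
          margin <- if (spec$overlap_fraction == 0) 2 else 0
          if (any(d < sep * (1 - spec$overlap_fraction) + margin)) next
        }
        ok <- TRUE
        break
      }
      if (!ok)
        stop(sprintf(paste0("could not place nucleus %d of %d after 400 tries; ",
                            "limiting parameters: n_immunopositive + ",
                            "n_immunonegative vs canvas size and ",
                            "nucleus_radius_range"), i, n_tot), call. = FALSE)
      px <- ellipse_pixels(cy, cx, a, b, theta, H, W)
      col_mean <- spec$color_means[[classes[i]]] +
        rnorm(3, 0, spec$color_jitter_sd)
      for (ch in 1:3)
        img[cbind(px, ch)] <- col_mean[ch]
      labels[px] <- i
      placed <- rbind(placed, data.frame(cy = cy, cx = cx, r = rr))
      seeds <- rbind(seeds, data.frame(
        row = as.integer(round(mean(px[, "row"]))),
        col = as.integer(round(mean(px[, "col"]))),
        class = classes[i], stringsAsFactors = FALSE))
    }
    if (spec$noise_sd > 0)
      img <- img + array(rnorm(length(img), 0, spec$noise_sd), dim(img))
    img <- round(pmin(pmax(img, 0), 255))
    storage.mode(img) <- "integer"
    true_aps <- if (n_tot > 0) 100 * n_pos / n_tot else NA_real_
    list(image = img,
         truth = list(seeds = seeds, true_aps = true_aps,
                      nucleus_labels = labels))
  })
}

#' Generate a dataset of synthetic IHC images
#'
#' Produces `n_images` scenes from one master seed. Per-image nucleus
#' counts are chosen so that ground-truth proliferation percentages cycle
#' through the three clinical reference categories (low < 15, average
#' 16--30, high > 31) unless `aps_targets` overrides them.
#'
#' @param n_images Number of images (>= 1).
#' @param spec_template A [scene_spec()]; per-image specs inherit everything
#'   but counts and seed from it.
#' @param rng_seed Master seed; per-image seeds are derived from it.
#' @param aps_targets Optional vector of target APS percentages recycled
#'   over images; the default `c(10, 25, 60)` spans the three categories.
#' @return List of `n_images` elements, each as returned by
#'   [generate_image()], with an `aps_target` attribute per element.
#' @export
generate_dataset <- function(n_images, spec_template = scene_spec(),
                             rng_seed = 1L, aps_targets = c(10, 25, 60)) {
  stopifnot_scalar(n_images, "n_images", 1)
  if (spec_template$image_height * spec_template$image_width >= 2048 * 1536)
    message("note: generating full-acquisition-scale images (>= 2048x1536)")
  n_tot <- spec_template$n_immunopositive + spec_template$n_immunonegative
  seeds <- derive_seeds(rng_seed, n_images)
  lapply(seq_len(n_images), function(i) {
    target <- aps_targets[((i - 1L) %% length(aps_targets)) + 1L]
    n_pos <- as.integer(round(n_tot * target / 100))
    sp <- spec_template
    sp$n_immunopositive <- n_pos
    sp$n_immunonegative <- n_tot - n_pos
    sp$rng_seed <- seeds[i]
    out <- generate_image(sp)
    attr(out, "aps_target") <- target
    out
  })
}
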