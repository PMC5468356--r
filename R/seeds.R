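# Seed-point extraction: 8-connected components of the nucleus-labeled
# pixel map, small-component rejection, and centroid computation. The
# centroid of each surviving component is the seed point that drives patch
# cropping.

# 8-connected labeling of a logical mask by iterative minimum-label
# propagation (vectorized over the whole image; converges in at most the
# longest geodesic diameter of a component, small for blob-like nuclei).
label_components <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  lab[mask] <- which(mask)   # linear-index provisional labels
  big <- .Machine$integer.max
  repeat {
    m <- lab; m[!mask] <- big
    shift_min <- function(acc, dr, dc) {
      src_r <- seq_len(H) + dr; src_c <- seq_len(W) + dc
      ok_r <- src_r >= 1 & src_r <= H; ok_c <- src_c >= 1 & src_c <= W
      sh <- matrix(big, H, W)
      sh[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
      pmin(acc, sh)
    }
    acc <- m
    for (dr in -1:1) for (dc in -1:1)
      if (dr != 0 || dc != 0) acc <- shift_min(acc, dr, dc)
    new <- lab
    new[mask] <- acc[mask]
    if (identical(new, lab)) break
    lab <- new
  }
  # compact labels to 1..K
  ids <- sort(unique(lab[lab > 0L]))
  lab[lab > 0L] <- match(lab[lab > 0L], ids)
  lab
}

#' Extract nucleus seed points from a pixel label map
#'
#' Finds 8-connected components of each nucleus class in a MAP label map,
#' discards components smaller than `min_component_area`, and returns the
#' rounded centroid of each survivor. Background pixels are ignored.
#' Output ordering is deterministic: by class
#' (immunopositive first), then row, then column.
#'
#' @param labels H x W character matrix of class labels (as produced by
#'   [map_label()]).
#' @param config A [seed_detection_config()] supplying
#'   `min_component_area`.
#' @return data.frame with columns `row`, `col` (1-based pixel
#'   coordinates), `class`, `area` (component pixel count). Zero rows if
#'   nothing survives.
#' @export
extract_seed_points <- function(labels, config = seed_detection_config()) {
  out <- list()
  for (cl in nucleus_classes()) {
    mask <- labels == cl
    if (!any(mask)) next
    comp <- label_components(mask)
    K <- max(comp)
    if (K == 0L) next
    idx <- which(comp > 0L)
    rows <- ((idx - 1L) %% nrow(comp)) + 1L
    cols <- ((idx - 1L) %/% nrow(comp)) + 1L
    id <- comp[idx]
    area <- tabulate(id, K)
    cy <- tapply(rows, id, mean)
    cx <- tapply(cols, id, mean)
    keep <- area >= config$min_component_area
    if (!any(keep)) next
    out[[cl]] <- data.frame(row = as.integer(round(cy[keep])),
                            col = as.integer(round(cx[keep])),
                            class = cl, area = area[keep],
                            stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(row = integer(0), col = integer(0),
                      class = character(0), area = integer(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out[intersect(nucleus_classes(), names(out))])
  res <- res[order(match(res$class, nucleus_classes()), res$row, res$col), ]
  rownames(res) <- NULL
  res
}

# Assign fitted mixture components to semantic classes by stain color:
# background is the palest component (highest mean luminance); of the rest,
# DAB brown has R - B largest, hematoxylin blue smallest.
assign_components <- function(fit) {
  k <- length(fit$weights)
  if (k < 3L) stop("need at least 3 components for the 3-way labeling",
                   call. = FALSE)
  mu <- do.call(rbind, fit$means)
  lum <- mu %*% c(0.299, 0.587, 0.114)
  ord_bg <- order(lum, decreasing = TRUE)
  n_bg <- k - 2L * (k %/% 3L)           # split components ~evenly, extra to bg
  n_each <- k %/% 3L
  bg <- ord_bg[seq_len(n_bg)]
  rest <- setdiff(seq_len(k), bg)
  rb <- mu[rest, 1] - mu[rest, 3]
  ord_rb <- rest[order(rb, decreasing = TRUE)]
  pos <- ord_rb[seq_len(n_each)]
  neg <- setdiff(rest, pos)
  sub_fit <- function(sel) {
    structure(list(means = fit$means[sel], covs = fit$covs[sel],
                   weights = fit$weights[sel] / sum(fit$weights[sel]),
                   loglik_trace = fit$loglik_trace, n_iter = fit$n_iter,
                   converged = fit$converged, n_fit_pixels = fit$n_fit_pixels),
              class = "ki67_gmm")
  }
  priors <- c(sum(fit$weights[pos]), sum(fit$weights[neg]), sum(fit$weights[bg]))
  gmm_params(list(immunopositive = sub_fit(pos),
                  immunonegative = sub_fit(neg),
                  background = sub_fit(bg)),
             class_priors = priors)
}

#' Detect nucleus seed points in an IHC image
#'
#' The full seed-detection stage: fit a Gaussian mixture with
#' `3 * components_per_class` components to a pixel subsample by EM, assign
#' components to the immunopositive / immunonegative / background classes
#' by stain color (background = palest, brown = largest red-minus-blue),
#' MAP-label every pixel (optionally smoothed by the Potts prior), and
#' extract per-component centroids.
#'
#' @param image H x W x 3 array (0--255).
#' @param config A [seed_detection_config()].
#' @param stain_references List of three RGB triplets
#'   (`immunopositive`, `immunonegative`, `background`) used to initialize
#'   the EM component assignment; defaults to canonical DAB brown,
#'   hematoxylin blue and pale background. Initializing at the stain
#'   colors keeps a scarce class (e.g. few immunopositive nuclei in a
#'   low-proliferation field) from being absorbed into the background
#'   during fitting; EM still adapts all parameters to the image.
#' @return List: `seeds` (data.frame as [extract_seed_points()]), `labels`
#'   (character label map), `params` ([gmm_params()]), `fit` (the raw
#'   `ki67_gmm`).
#' @examples
#' sc <- generate_image(scene_spec(n_immunopositive = 3, n_immunonegative = 5,
#'                                 image_height = 128, image_width = 128))
#' det <- detect_seeds(sc$image, seed_detection_config())
#' nrow(det$seeds)
#' @export
detect_seeds <- function(image, config = seed_detection_config(),
                         stain_references = list(
                           immunopositive = c(150, 100, 60),
                           immunonegative = c(70, 80, 150),
                           background     = c(235, 230, 240))) {
  px <- matrix(as.numeric(image), ncol = 3)
  c_per <- config$components_per_class
  # one init mean per component: jitter duplicates slightly so nearest-mean
  # partitions differ when c_per > 1
  init_means <- list()
  for (ref in stain_references)
    for (j in seq_len(c_per))
      init_means[[length(init_means) + 1L]] <- ref + (j - 1) * 5
  fit <- fit_gmm_em(px, 3L * c_per, config, init_means = init_means)
  params <- assign_components(fit)
  # a nucleus class whose color collapsed onto the background is absent
  mom <- lapply(params$fits, collapse_gaussian)
  bg_mu <- mom$background$mu
  present <- vapply(nucleus_classes(), function(cl)
    sqrt(sum((mom[[cl]]$mu - bg_mu)^2)) >= config$min_stain_separation,
    logical(1))
  if (!all(present)) {
    keep <- c(nucleus_classes()[present], "background")
    sel <- match(keep, params$classes)
    params <- gmm_params(params$fits[sel],
                         class_priors = params$class_priors[sel])
  }
  labels <- map_label(image, params, config)
  seeds <- extract_seed_points(labels, config)
  list(seeds = seeds, labels = labels, params = params, fit = fit)
}
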