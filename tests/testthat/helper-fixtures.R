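# Fixture builders shared across test files. Everything is generated in
# code from fixed seeds; nothing is read from disk.

# A small batch of labeled synthetic patches (size x size x 3 x n, [0,1]).
make_patch_set <- function(n_images = 4, n_pos = 15, n_neg = 25,
                           size = 71L, canvas = 300L, seed = 11L) {
  ds <- generate_dataset(n_images,
                         scene_spec(image_height = canvas,
                                    image_width = canvas,
                                    n_immunopositive = n_pos,
                                    n_immunonegative = n_neg),
                         rng_seed = seed,
                         aps_targets = 100 * n_pos / (n_pos + n_neg))
  pl <- list(); lb <- character(0)
  for (d in ds) {
    cp <- crop_patches(d$image, d$truth$seeds, size = size)
    pl[[length(pl) + 1]] <- cp$patches
    lb <- c(lb, as.character(cp$labels))
  }
  patches <- array(0, c(size, size, 3, length(lb)))
  i <- 1
  for (p in pl) {
    k <- dim(p)[4]
    patches[, , , i:(i + k - 1)] <- p
    i <- i + k
  }
  list(patches = patches, labels = lb)
}

# Two well-separated Gaussian pixel clusters with known parameters.
make_two_cluster_pixels <- function(n_each = 5000, sd = 8, seed = 42) {
  set.seed(seed)
  rbind(matrix(rnorm(n_each * 3, mean = rep(c(150, 100, 60), each = n_each),
                     sd = sd), n_each, 3),
        matrix(rnorm(n_each * 3, mean = rep(c(70, 80, 150), each = n_each),
                     sd = sd), n_each, 3))
}

# gmm_params with two unit-ish Gaussian classes at given means.
make_simple_params <- function(mu_pos = c(150, 100, 60),
                               mu_neg = c(70, 80, 150),
                               sigma = diag(3) * 25) {
  gauss <- function(mu) structure(
    list(means = list(mu), covs = list(sigma), weights = 1,
         loglik_trace = 0, n_iter = 1L, converged = TRUE, n_fit_pixels = 1L),
    class = "ki67_gmm")
  gmm_params(list(immunopositive = gauss(mu_pos),
                  immunonegative = gauss(mu_neg)))
}

# Tiny 2x3 two-class test image: pixels near the two class means with a
# couple of ambiguous ones, for exhaustive MAP enumeration.
make_toy_image <- function() {
  mu_pos <- c(150, 100, 60); mu_neg <- c(70, 80, 150)
  mid <- (mu_pos + mu_neg) / 2
  px <- rbind(mu_pos + 5, mu_neg - 5, mid + c(4, 0, -4),
              mid - c(4, 0, -4), mu_pos - 8, mu_neg + 8)
  img <- array(0, c(2, 3, 3))
  for (ch in 1:3) img[, , ch] <- matrix(px[, ch], 2, 3)
  img
}

# Greedy nearest matching of detected seeds to ground truth; returns
# recall and class purity at the given distance tolerance.
match_seeds <- function(detected, truth, tol = 5) {
  if (!nrow(detected)) return(list(recall = 0, purity = NA_real_))
  d <- outer(detected$row, truth$row, `-`)^2 +
    outer(detected$col, truth$col, `-`)^2
  d <- sqrt(d)
  matched <- 0L; correct <- 0L
  used <- rep(FALSE, nrow(truth))
  for (i in order(apply(d, 1, min))) {
    j <- which.min(ifelse(used, Inf, d[i, ]))
    if (is.finite(d[i, j]) && d[i, j] <= tol && !used[j]) {
      used[j] <- TRUE; matched <- matched + 1L
      if (detected$class[i] == truth$class[j]) correct <- correct + 1L
    }
  }
  list(recall = matched / nrow(truth),
       purity = if (matched) correct / matched else NA_real_)
}
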