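# Gaussian mixture modeling of RGB pixel intensities, fitted by
# expectation-maximization. Pixels are 3-vectors; each class (nucleus brown,
# nucleus blue, background) is modeled by a weighted mixture of full-
# covariance Gaussians. The abstract description of the source method calls
# this family a "Gamma mixture", but every density it writes down is
# Gaussian; the Gaussian form is what is implemented here, behind a density
# interface so another per-channel family could be slotted in.

#' Seed-detection configuration
#'
#' Tuning parameters for mixture fitting, MAP pixel labeling and seed
#' extraction.
#'
#' @param components_per_class Gaussian components per class (default 1).
#' @param em_tol Relative log-likelihood change for EM convergence.
#' @param em_max_iter Maximum EM iterations.
#' @param covariance_floor Value added to covariance diagonals each M-step
#'   (intensity^2 units); keeps covariances positive-definite.
#' @param beta Potts coupling (>= 0) of the Gibbs smoothness prior used by
#'   MAP labeling; `0` gives pure per-pixel maximum-likelihood labeling.
#' @param min_component_area Connected components smaller than this many
#'   pixels are discarded during seed extraction.
#' @param min_stain_separation A nucleus class whose fitted mean color
#'   lies within this Euclidean RGB distance of the background mean is
#'   treated as absent from the image (its EM components have collapsed
#'   onto the background, as happens on fields with no nuclei of that
#'   class).
#' @param max_fit_pixels EM fits on at most this many pixels (subsampled);
#'   labeling always uses every pixel.
#' @param rng_seed Seed for subsampling and k-means initialization.
#' @return An object of class `seed_detection_config`.
#' @export
seed_detection_config <- function(components_per_class = 1L,
                                  em_tol = 1e-5, em_max_iter = 200L,
                                  covariance_floor = 1.0, beta = 0,
                                  min_component_area = 30L,
                                  min_stain_separation = 30,
                                  max_fit_pixels = 100000L,
                                  rng_seed = 1L) {
  stopifnot_scalar(em_tol, "em_tol", .Machine$double.xmin)
  stopifnot_scalar(beta, "beta", 0)
  stopifnot_scalar(min_component_area, "min_component_area", 1)
  stopifnot_scalar(min_stain_separation, "min_stain_separation", 0)
  structure(list(components_per_class = as.integer(components_per_class),
                 em_tol = em_tol, em_max_iter = as.integer(em_max_iter),
                 covariance_floor = covariance_floor, beta = beta,
                 min_component_area = as.integer(min_component_area),
                 min_stain_separation = min_stain_separation,
                 max_fit_pixels = as.integer(max_fit_pixels),
                 rng_seed = as.integer(rng_seed)),
            class = "seed_detection_config")
}

# log N(x; mu, Sigma) for rows of x (n x d), via Cholesky
mvn_logdensity <- function(x, mu, sigma) {
  ch <- chol(sigma)
  d <- ncol(x)
  z <- forwardsolve(t(ch), t(x) - mu)
  -0.5 * colSums(z^2) - sum(log(diag(ch))) - 0.5 * d * log(2 * pi)
}

# n x k matrix of log(w_k * N(x; mu_k, Sigma_k))
gmm_log_components <- function(x, means, covs, weights) {
  k <- length(weights)
  out <- matrix(0, nrow(x), k)
  for (j in seq_len(k))
    out[, j] <- log(weights[j]) + mvn_logdensity(x, means[[j]], covs[[j]])
  out
}

logsumexp_rows <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

#' Fit a Gaussian mixture to RGB pixels by expectation-maximization
#'
#' Full-covariance EM with k-means initialization on a fixed-seed
#' subsample. Covariance diagonals are floored each M-step
#' (`covariance_floor`), which keeps degenerate inputs (e.g. all pixels
#' identical) well-defined; the log-likelihood trace is non-decreasing up
#' to that regularization.
#'
#' @param pixels Numeric matrix, one pixel per row, 3 columns (RGB, 0--255).
#' @param n_components Number of Gaussian components (>= 1).
#' @param config A [seed_detection_config()].
#' @param init_means Optional list of `n_components` mean vectors used to
#'   seed the component assignment (nearest-mean partition) instead of
#'   k-means; [detect_seeds()] passes reference stain colors here so that
#'   a scarce nucleus class is never lost to a k-means local optimum.
#' @return An object of class `ki67_gmm`: list with `means` (list of
#'   3-vectors), `covs` (list of 3x3 matrices), `weights`, `loglik_trace`
#'   (mean log-likelihood per iteration), `n_iter`, `converged`.
#' @examples
#' px <- rbind(matrix(rnorm(300, 150, 5), ncol = 3),
#'             matrix(rnorm(300, 70, 5), ncol = 3))
#' fit <- fit_gmm_em(px, 2, seed_detection_config())
#' @export
fit_gmm_em <- function(pixels, n_components,
                       config = seed_detection_config(),
                       init_means = NULL) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (nrow(pixels) == 0L) stop("empty pixel set", call. = FALSE)
  k <- as.integer(n_components)
  if (k < 1L) stop("n_components must be >= 1", call. = FALSE)
  n_distinct <- nrow(unique(pixels))
  if (n_distinct < k)
    warning(sprintf("only %d distinct pixels for %d components; expect collapsed components held apart by covariance_floor",
                    n_distinct, k))
  d <- ncol(pixels)
  floor_mat <- diag(config$covariance_floor, d)

  init <- with_seed(config$rng_seed, {
    if (nrow(pixels) > config$max_fit_pixels)
      pixels <- pixels[sample.int(nrow(pixels), config$max_fit_pixels), , drop = FALSE]
    if (!is.null(init_means)) {
      if (length(init_means) != k)
        stop("init_means must supply one mean per component", call. = FALSE)
      ctr <- do.call(rbind, init_means)
      d2 <- outer(rowSums(pixels^2), rowSums(ctr^2), `+`) -
        2 * pixels %*% t(ctr)
      list(cluster = max.col(-d2, ties.method = "first"), pixels = pixels)
    } else if (k == 1L || n_distinct < k) {
      list(cluster = rep_len(seq_len(k), nrow(pixels)), pixels = pixels)
    } else {
      km <- suppressWarnings(stats::kmeans(pixels, centers = k, nstart = 3,
                                           iter.max = 50))
      list(cluster = km$cluster, pixels = pixels)
    }
  })
  pixels <- init$pixels
  n <- nrow(pixels)

  means <- covs <- vector("list", k)
  weights <- numeric(k)
  for (j in seq_len(k)) {
    sel <- pixels[init$cluster == j, , drop = FALSE]
    if (nrow(sel) == 0L) sel <- pixels
    means[[j]] <- colMeans(sel)
    covs[[j]] <- stats::cov(sel) * (max(nrow(sel) - 1, 1) / max(nrow(sel), 1)) + floor_mat
    if (anyNA(covs[[j]])) covs[[j]] <- floor_mat
    weights[j] <- max(nrow(sel), 1) / n
  }
  weights <- weights / sum(weights)

  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    lc <- gmm_log_components(pixels, means, covs, weights)
    lse <- logsumexp_rows(lc)
    ll <- mean(lse)
    trace <- c(trace, ll)
    resp <- exp(lc - lse)                     # E-step responsibilities
    nk <- colSums(resp)
    nk <- pmax(nk, 1e-12)
    weights <- nk / n
    for (j in seq_len(k)) {
      mu <- colSums(resp[, j] * pixels) / nk[j]
      xc <- sweep(pixels, 2, mu)
      sg <- crossprod(xc * sqrt(resp[, j])) / nk[j] + floor_mat
      means[[j]] <- mu
      covs[[j]] <- (sg + t(sg)) / 2
    }
    if (iter > 1L) {
      rel <- abs(trace[iter] - trace[iter - 1L]) /
        max(abs(trace[iter - 1L]), .Machine$double.eps)
      if (rel < config$em_tol) { converged <- TRUE; break }
    }
    if (iter >= config$em_max_iter) break
  }
  structure(list(means = means, covs = covs, weights = weights,
                 loglik_trace = trace, n_iter = iter, converged = converged,
                 n_fit_pixels = n),
            class = "ki67_gmm")
}

#' @export
print.ki67_gmm <- function(x, ...) {
  cat(sprintf("Gaussian mixture (%d components) fit by EM on %d pixels\n",
              length(x$weights), x$n_fit_pixels))
  cat(sprintf("  %d iterations, %sconverged; mean log-likelihood %.4f\n",
              x$n_iter, if (x$converged) "" else "NOT ", utils::tail(x$loglik_trace, 1)))
  for (j in seq_along(x$weights))
    cat(sprintf("  comp %d: w = %.3f, mean = (%s)\n", j, x$weights[j],
                paste(sprintf("%.1f", x$means[[j]]), collapse = ", ")))
  invisible(x)
}

#' Per-class mixture parameters for pixel labeling
#'
#' Bundles one fitted mixture per label class into the parameter object the
#' MAP labeler consumes. Per-class component weights are renormalized to
#' sum to 1; `class_priors` carries the relative class frequencies.
#'
#' @param fits Named list of `ki67_gmm` objects, names from
#'   `c(nucleus_classes(), "background")` (background optional).
#' @param class_priors Optional prior class probabilities (recycled uniform).
#' @return An object of class `gmm_params`.
#' @export
gmm_params <- function(fits, class_priors = NULL) {
  if (is.null(names(fits)) || !all(names(fits) %in% label_classes()))
    stop("`fits` must be named with classes from label_classes()", call. = FALSE)
  if (is.null(class_priors)) class_priors <- rep(1 / length(fits), length(fits))
  class_priors <- class_priors / sum(class_priors)
  for (f in fits) stopifnot(inherits(f, "ki67_gmm"))
  structure(list(classes = names(fits), fits = fits,
                 class_priors = class_priors),
            class = "gmm_params")
}

#' Likelihood energy of a pixel labeling
#'
#' The Gaussian data term of the MAP labeling objective: for each pixel
#' `q` with label `K_q`,
#' \deqn{U = \sum_q \tfrac12 (I_q-\mu_{K_q})^\top \Sigma_{K_q}^{-1}(I_q-\mu_{K_q}) + \tfrac12 \ln|\Sigma_{K_q}|}
#' Classes with more than one mixture component are collapsed to their
#' moment-matched single Gaussian for this energy.
#'
#' @param image H x W x 3 numeric array.
#' @param labels H x W matrix of labels (values in `params$classes`).
#' @param params A [gmm_params()].
#' @return Scalar energy.
#' @export
likelihood_energy <- function(image, labels, params) {
  stopifnot(inherits(params, "gmm_params"))
  d <- dim(image)
  if (!identical(dim(labels), d[1:2]))
    stop("labels and image dimensions disagree", call. = FALSE)
  used <- unique(as.vector(labels))
  missing <- setdiff(used, params$classes)
  if (length(missing))
    stop(sprintf("no mixture parameters for label(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  px <- matrix(image, ncol = 3)
  lab <- as.vector(labels)
  total <- 0
  for (cl in used) {
    mom <- collapse_gaussian(params$fits[[cl]])
    sel <- lab == cl
    x <- px[sel, , drop = FALSE]
    ch <- chol(mom$sigma)
    z <- forwardsolve(t(ch), t(x) - mom$mu)
    total <- total + 0.5 * sum(z^2) + sum(sel) * sum(log(diag(ch)))
  }
  total
}

# Moment-match a mixture to one Gaussian.
collapse_gaussian <- function(fit) {
  w <- fit$weights / sum(fit$weights)
  mu <- Reduce(`+`, Map(`*`, fit$means, w))
  sigma <- Reduce(`+`, Map(function(m, s, wj) wj * (s + tcrossprod(m - mu)),
                           fit$means, fit$covs, as.list(w)))
  list(mu = mu, sigma = (sigma + t(sigma)) / 2)
}

# n x C matrix of per-class log weighted-mixture density + log class prior.
class_log_posteriors <- function(px, params) {
  C <- length(params$classes)
  out <- matrix(0, nrow(px), C)
  for (ci in seq_len(C)) {
    f <- params$fits[[ci]]
    lc <- gmm_log_components(px, f$means, f$covs, f$weights / sum(f$weights))
    out[, ci] <- logsumexp_rows(lc) + log(params$class_priors[ci])
  }
  colnames(out) <- params$classes
  out
}

#' MAP pixel labeling with an optional Potts smoothness prior
#'
#' With `beta = 0` every pixel independently receives the label maximizing
#' its weighted class-conditional density (equivalently, minimizing its
#' unary energy). With `beta > 0` the Gibbs prior couples 4-neighbor
#' pixels through a Potts penalty `beta * [labels differ]` and the combined
#' energy is minimized by iterated conditional modes (ICM) from the unary
#' initialization until no pixel changes or `max_icm_iter` sweeps.
#' Ties break toward the lowest class index.
#'
#' @param image H x W x 3 numeric array (0--255).
#' @param params A [gmm_params()].
#' @param config A [seed_detection_config()]; `config$beta` selects the
#'   prior strength.
#' @param max_icm_iter ICM sweep cap.
#' @return H x W character matrix of class labels, with attribute
#'   `"icm_iters"` when `beta > 0`.
#' @export
map_label <- function(image, params, config = seed_detection_config(),
                      max_icm_iter = 20L) {
  stopifnot(inherits(params, "gmm_params"))
  d <- dim(image)
  H <- d[1]; W <- d[2]
  px <- matrix(as.numeric(image), ncol = 3)
  lp <- class_log_posteriors(px, params)
  # ties to lowest class index: strict improvement required to switch
  lab <- max.col(lp, ties.method = "first")
  if (config$beta > 0) {
    C <- ncol(lp)
    parity <- (outer(seq_len(H), seq_len(W), `+`) %% 2L) == 0L
    it <- 0L
    repeat {
      it <- it + 1L
      changed <- FALSE
      # red-black sweeps: pixels of one parity are mutually non-adjacent,
      # so updating them jointly is exact coordinate descent on the energy
      for (par in c(TRUE, FALSE)) {
        labm <- matrix(lab, H, W)
        nbrs <- matrix(0, H * W, C)
        for (ci in seq_len(C)) {
          m <- (labm == ci) * 1
          s <- matrix(0, H, W)
          if (H > 1) { s[-1, ] <- s[-1, ] + m[-H, ]; s[-H, ] <- s[-H, ] + m[-1, ] }
          if (W > 1) { s[, -1] <- s[, -1] + m[, -W]; s[, -W] <- s[, -W] + m[, -1] }
          nbrs[, ci] <- as.vector(s)
        }
        # candidate score: log posterior - beta * (#neighbors disagreeing)
        score <- lp + config$beta * nbrs
        new_lab <- max.col(score, ties.method = "first")
        sel <- as.vector(parity == par)
        if (any(new_lab[sel] != lab[sel])) changed <- TRUE
        lab[sel] <- new_lab[sel]
      }
      if (!changed || it >= max_icm_iter) break
    }
    out <- matrix(params$classes[lab], H, W)
    attr(out, "icm_iters") <- it
    return(out)
  }
  matrix(params$classes[lab], H, W)
}

# Total MAP energy (unary + Potts) of a labeling; used by tests and ICM
# verification. Unary is -log posterior (mixture form), pairwise counts
# each 4-neighbor pair with differing labels once.
labeling_energy <- function(image, labels, params, beta) {
  px <- matrix(as.numeric(image), ncol = 3)
  lp <- class_log_posteriors(px, params)
  idx <- match(as.vector(labels), params$classes)
  un <- -sum(lp[cbind(seq_along(idx), idx)])
  H <- dim(labels)[1]; W <- dim(labels)[2]
  pw <- 0
  if (H > 1) pw <- pw + sum(labels[-H, ] != labels[-1, ])
  if (W > 1) pw <- pw + sum(labels[, -W] != labels[, -1])
  un + beta * pw
}
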