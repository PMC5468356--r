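# EM fitting, likelihood energy, MAP labeling and seed extraction.

test_that("EM on a point mass returns the mean with floored covariance", {
  px <- matrix(100, 200, 3)
  expect_warning(fit <- fit_gmm_em(px, 1, seed_detection_config()), NA)
  expect_equal(fit$means[[1]], c(100, 100, 100), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(fit$covs[[1]], diag(3) * 1.0, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(fit$weights, 1)
})

test_that("EM recovers two well-separated clusters near the generating values", {
  px <- make_two_cluster_pixels(n_each = 5000, sd = 8, seed = 42)
  fit <- fit_gmm_em(px, 2, seed_detection_config(rng_seed = 1))
  # order components by red channel
  ord <- order(vapply(fit$means, `[`, numeric(1), 1), decreasing = TRUE)
  expect_equal(fit$means[[ord[1]]], c(150, 100, 60), tolerance = 3 / 60,
               ignore_attr = TRUE)
  expect_true(max(abs(fit$means[[ord[1]]] - c(150, 100, 60))) < 3)
  expect_true(max(abs(fit$means[[ord[2]]] - c(70, 80, 150))) < 3)
  expect_true(all(abs(fit$weights - 0.5) < 0.02))
})

test_that("EM agrees with an independent mixture fitter on the same data", {
  suppressMessages(library(mclust))
  px <- make_two_cluster_pixels(n_each = 1500, sd = 8, seed = 17)
  fit <- fit_gmm_em(px, 2, seed_detection_config(rng_seed = 1,
                                                 covariance_floor = 0.01))
  mc <- mclust::Mclust(px, G = 2, modelNames = "VVV", verbose = FALSE)
  ours <- do.call(rbind, fit$means)
  ours <- ours[order(ours[, 1]), ]
  theirs <- t(mc$parameters$mean)
  theirs <- theirs[order(theirs[, 1]), ]
  expect_true(max(abs(ours - theirs)) < 1)
})

test_that("EM log-likelihood trace is monotone non-decreasing", {
  for (seed in c(2, 23, 101)) {
    set.seed(seed)
    px <- matrix(runif(900, 0, 255), ncol = 3)
    fit <- fit_gmm_em(px, 3, seed_detection_config(rng_seed = seed))
    d <- diff(fit$loglik_trace)
    expect_true(all(d >= -1e-6 * abs(fit$loglik_trace[-length(fit$loglik_trace)])),
                label = sprintf("monotone trace (seed %d)", seed))
  }
})

test_that("likelihood energy matches closed forms and a brute-force oracle", {
  params <- make_simple_params(sigma = diag(3))
  # single pixel at its class mean, identity covariance -> energy 0
  img <- array(c(150, 100, 60), c(1, 1, 3))
  lab <- matrix("immunopositive", 1, 1)
  expect_equal(likelihood_energy(img, lab, params), 0)
  # one SD along an eigenvector -> 1/2
  img2 <- array(c(151, 100, 60), c(1, 1, 3))
  expect_equal(likelihood_energy(img2, lab, params), 0.5)
  # random 4x4 image vs term-by-term summation
  set.seed(8)
  img3 <- array(runif(4 * 4 * 3, 0, 255), c(4, 4, 3))
  lab3 <- matrix(sample(nucleus_classes(), 16, TRUE), 4, 4)
  params2 <- make_simple_params(sigma = diag(3) * 25 + 5)
  oracle <- 0
  for (r in 1:4) for (cc in 1:4) {
    cl <- lab3[r, cc]
    mu <- params2$fits[[cl]]$means[[1]]
    sg <- params2$fits[[cl]]$covs[[1]]
    v <- img3[r, cc, ] - mu
    oracle <- oracle + 0.5 * t(v) %*% solve(sg) %*% v +
      0.5 * log(det(sg))
  }
  expect_equal(likelihood_energy(img3, lab3, params2), as.numeric(oracle),
               tolerance = 1e-9)
  # label without parameters -> configuration error
  lab_bad <- matrix("background", 1, 1)
  expect_error(likelihood_energy(img, lab_bad, params), "background")
})

test_that("MAP labeling at beta = 0 is the per-pixel weighted-density argmax", {
  params <- make_simple_params()
  # pixel at a class mean gets that class
  img <- array(c(150, 100, 60), c(1, 1, 3))
  expect_equal(as.vector(map_label(img, params)), "immunopositive")
  # random image: equals independent per-pixel argmax
  set.seed(31)
  img2 <- array(runif(6 * 5 * 3, 0, 255), c(6, 5, 3))
  got <- map_label(img2, params)
  px <- matrix(img2, ncol = 3)
  lp <- ki67score:::class_log_posteriors(px, params)
  expect_equal(as.vector(got), params$classes[max.col(lp, "first")])
})

test_that("MAP labeling at beta = 0 commutes with joint channel permutation", {
  params <- make_simple_params(sigma = diag(c(20, 30, 40)) + 4)
  set.seed(12)
  img <- array(runif(8 * 8 * 3, 0, 255), c(8, 8, 3))
  perm <- c(3, 1, 2)
  img_p <- img[, , perm, drop = FALSE]
  params_p <- params
  for (cl in params$classes) {
    params_p$fits[[cl]]$means[[1]] <- params$fits[[cl]]$means[[1]][perm]
    params_p$fits[[cl]]$covs[[1]] <- params$fits[[cl]]$covs[[1]][perm, perm]
  }
  expect_identical(map_label(img, params), map_label(img_p, params_p))
})

test_that("ICM at beta > 0 reaches an energy no worse than its unary start, verified exhaustively", {
  params <- make_simple_params()
  img <- make_toy_image()
  cfg <- seed_detection_config(beta = 0.5)
  got <- map_label(img, params, cfg)
  beta <- 0.5
  e_got <- ki67score:::labeling_energy(img, got, params, beta)
  # exhaustive enumeration of all 2^6 labelings
  combos <- expand.grid(rep(list(nucleus_classes()), 6),
                        stringsAsFactors = FALSE)
  energies <- apply(combos, 1, function(v)
    ki67score:::labeling_energy(img, matrix(v, 2, 3), params, beta))
  e_min <- min(energies)
  unary <- map_label(img, params, seed_detection_config(beta = 0))
  e_unary <- ki67score:::labeling_energy(img, unary, params, beta)
  # returned labeling is at least as good as the unary initialization ...
  expect_lte(e_got, e_unary + 1e-9)
  # ... and is either the exhaustive optimum or a single-flip local minimum
  is_local_min <- TRUE
  for (i in 1:6) {
    flip <- got
    flip[i] <- setdiff(nucleus_classes(), got[i])
    if (ki67score:::labeling_energy(img, flip, params, beta) < e_got - 1e-9)
      is_local_min <- FALSE
  }
  expect_true(abs(e_got - e_min) < 1e-9 || is_local_min)
})

test_that("seed extraction handles empty maps and symmetric components", {
  cfg <- seed_detection_config(min_component_area = 1)
  empty <- matrix("background", 10, 10)
  expect_equal(nrow(extract_seed_points(empty, cfg)), 0)
  one <- matrix("background", 10, 10)
  one[4:6, 4:6] <- "immunopositive"
  got <- extract_seed_points(one, cfg)
  expect_equal(got$row, 5L)
  expect_equal(got$col, 5L)
  expect_equal(got$area, 9L)
  expect_equal(got$class, "immunopositive")
  # area filter discards it
  expect_equal(nrow(extract_seed_points(one,
                                        seed_detection_config(min_component_area = 10))), 0)
})

test_that("8-connectivity merges diagonally touching components", {
  m <- matrix("background", 6, 6)
  m[cbind(c(1, 2, 3), c(1, 2, 3))] <- "immunonegative"
  got <- extract_seed_points(m, seed_detection_config(min_component_area = 1))
  expect_equal(nrow(got), 1)
  expect_equal(got$area, 3L)
})

test_that("detection recovers disjoint synthetic nuclei with matched centroids", {
  sc <- generate_image(scene_spec(n_immunopositive = 5, n_immunonegative = 5,
                                  image_height = 224, image_width = 224,
                                  rng_seed = 77))
  det <- detect_seeds(sc$image, seed_detection_config())
  expect_equal(nrow(det$seeds), 10)
  m <- match_seeds(det$seeds, sc$truth$seeds, tol = 2)
  expect_equal(m$recall, 1)
  expect_equal(m$purity, 1)
  # deterministic ordering: class then row then col
  expect_false(is.unsorted(match(det$seeds$class, nucleus_classes())))
})

test_that("seed recall and class purity exceed 0.9 on default scenes", {
  for (seed in 1:5) {
    sc <- generate_image(scene_spec(n_immunopositive = 8,
                                    n_immunonegative = 16,
                                    image_height = 224, image_width = 224,
                                    noise_sd = 10, rng_seed = seed * 13))
    det <- detect_seeds(sc$image, seed_detection_config())
    m <- match_seeds(det$seeds, sc$truth$seeds, tol = 5)
    expect_gte(m$recall, 0.9)
    expect_gte(m$purity, 0.9)
    # never more seeds than ground-truth components on disjoint scenes
    expect_lte(nrow(det$seeds), nrow(sc$truth$seeds))
  }
})

test_that("empty pixel set and degenerate inputs error or warn as contracted", {
  expect_error(fit_gmm_em(matrix(numeric(0), 0, 3), 1), "empty")
  expect_warning(fit_gmm_em(matrix(5, 50, 3), 2), "distinct")
})
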