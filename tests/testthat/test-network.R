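# Layer primitives, the decision-forest layer and network training.

test_that("convolution reproduces the printed layer arithmetic", {
  # 71x71x3 through conv-1 (90 maps, 2x2) -> 70x70x90
  set.seed(1)
  x <- array(runif(71 * 71 * 3), c(71, 71, 3, 1))
  W <- matrix(rnorm(2 * 2 * 3 * 90, 0, 0.1), 12, 90)
  out <- conv_forward(x, W, numeric(90), c(2, 2))$out
  expect_equal(dim(out), c(70, 70, 90, 1))
  # 35x35 input with a 4x4 filter -> 32x32
  x2 <- array(runif(35 * 35 * 2), c(35, 35, 2, 1))
  W2 <- matrix(rnorm(4 * 4 * 2 * 5, 0, 0.1), 32, 5)
  expect_equal(dim(conv_forward(x2, W2, numeric(5), c(4, 4))$out)[1:2],
               c(32, 32))
})

test_that("identity kernel with zero bias is the identity map", {
  x <- array(matrix(1:9, 3), c(3, 3, 1, 1))
  out <- conv_forward(x, matrix(1, 1, 1), 0, c(1, 1))$out
  expect_equal(out[, , 1, 1], matrix(1:9, 3))
})

test_that("convolution rejects a filter larger than its input", {
  x <- array(0, c(3, 3, 1, 1))
  expect_error(conv_forward(x, matrix(0, 16, 1), 0, c(4, 4)), "larger")
})

test_that("max pooling matches the exhaustive block maximum", {
  x <- array(matrix(1:16, 4, byrow = TRUE), c(4, 4, 1, 1))
  out <- maxpool_forward(x, c(2, 2))$out
  expect_equal(out[, , 1, 1], matrix(c(6, 14, 8, 16), 2))
  # constant input -> constant output
  xc <- array(3.5, c(6, 6, 2, 1))
  expect_true(all(maxpool_forward(xc)$out == 3.5))
  # 70x70 -> 35x35, and floor division 7 -> 3
  expect_equal(dim(maxpool_forward(array(0, c(70, 70, 1, 1)))$out)[1:2],
               c(35, 35))
  expect_equal(dim(maxpool_forward(array(0, c(7, 7, 1, 1)))$out)[1:2],
               c(3, 3))
})

test_that("relu clamps negatives and preserves shape", {
  expect_equal(relu(c(-3, 0, 5)), c(0, 0, 5))
  x <- array(c(-1, 2), c(2, 1, 1, 1))
  expect_equal(dim(relu(x)), dim(x))
})

test_that("routing probabilities sum to 1 and saturate as contracted", {
  # zero functionals, depth 2 -> every leaf 1/4
  fs <- forest_state(5, n_trees = 2, depth = 2, rng_seed = 1)
  fs$weights[] <- 0; fs$bias[] <- 0
  mu <- decision_routing(rnorm(5), fs, 1)
  expect_equal(mu, rep(0.25, 4))
  # saturated routing: huge positive functional at every node -> one leaf
  fs$bias[] <- 50
  mu2 <- decision_routing(rnorm(5), fs, 1)
  expect_equal(mu2[1], 1, tolerance = 1e-9)
  expect_equal(sum(mu2), 1, tolerance = 1e-12)
})

test_that("routing equals a brute-force path-product enumeration at depth 3", {
  fs <- forest_state(6, n_trees = 2, depth = 3, rng_seed = 7)
  set.seed(8)
  x <- rnorm(6)
  for (t in 1:2) {
    cols <- ((t - 1) * 7 + 1):(t * 7)
    d <- stats::plogis(as.vector(x %*% fs$weights[, cols]) + fs$bias[cols])
    # heap order: node k has children 2k (left, prob d) and 2k+1 (right)
    mu_oracle <- numeric(8)
    for (leaf in 0:7) {
      bits <- as.integer(intToBits(leaf))[3:1]   # path choices, root first
      node <- 1; p <- 1
      for (b in bits) {
        p <- p * if (b == 0) d[node] else 1 - d[node]
        node <- 2 * node + b
      }
      mu_oracle[leaf + 1] <- p
    }
    expect_equal(decision_routing(x, fs, t), mu_oracle, tolerance = 1e-12)
  }
})

test_that("routing normalization holds for random parameter draws", {
  fs <- forest_state(4, n_trees = 5, depth = 3, rng_seed = 3)
  set.seed(4)
  X <- matrix(rnorm(2000 * 4, 0, 3), 2000, 4)
  for (t in 1:5) {
    mu <- decision_routing(X, fs, t)
    expect_true(max(abs(rowSums(mu) - 1)) < 1e-9)
  }
})

test_that("forest prediction is a valid distribution and honors degenerate trees", {
  # uniform leaf distributions -> uniform output regardless of routing
  fs <- forest_state(5, n_trees = 3, depth = 2, rng_seed = 5)
  out <- forest_predict(rnorm(5), fs)
  expect_equal(unname(out), c(0.5, 0.5), tolerance = 1e-12)
  # single depth-0 tree -> output is that leaf's distribution
  fs0 <- forest_state(5, n_trees = 1, depth = 0, rng_seed = 5)
  fs0$pi_logits[1, , 1] <- c(log(0.9), log(0.1))
  expect_equal(unname(forest_predict(rnorm(5), fs0)), c(0.9, 0.1),
               tolerance = 1e-12)
})

test_that("two-tree depth-1 forest matches hand-computed arithmetic", {
  fs <- forest_state(2, n_trees = 2, depth = 1, rng_seed = 1)
  fs$weights[] <- 0
  fs$bias <- c(0.3, -0.2)            # one decision node per tree
  fs$pi_logits[, , 1] <- log(rbind(c(0.8, 0.2), c(0.3, 0.7)))
  fs$pi_logits[, , 2] <- log(rbind(c(0.6, 0.4), c(0.1, 0.9)))
  x <- c(1, -1)
  d1 <- 1 / (1 + exp(-0.3)); d2 <- 1 / (1 + exp(0.2))
  t1 <- d1 * c(0.8, 0.2) + (1 - d1) * c(0.3, 0.7)
  t2 <- d2 * c(0.6, 0.4) + (1 - d2) * c(0.1, 0.9)
  expect_equal(unname(forest_predict(x, fs)), (t1 + t2) / 2,
               tolerance = 1e-12)
})

test_that("decision layer defaults give width 720 with unit tree slices", {
  fs <- forest_state(5760, n_trees = 45, depth = 4, rng_seed = 2)
  x <- matrix(rnorm(5760), 1)
  out <- decision_layer_forward(x, fs)$out
  expect_equal(ncol(out), 720)
  for (t in 1:45)
    expect_equal(sum(out[1, ((t - 1) * 16 + 1):(t * 16)]), 1,
                 tolerance = 1e-9)
  # all-zero functionals -> embedding uniform at 1/16
  fs$weights[] <- 0; fs$bias[] <- 0
  out0 <- decision_layer_forward(x, fs)$out
  expect_equal(unname(out0[1, ]), rep(1 / 16, 720), tolerance = 1e-12)
  expect_error(decision_layer_forward(matrix(rnorm(100), 1), fs), "width")
})

test_that("decision-layer backpropagation matches finite differences", {
  fs <- forest_state(7, n_trees = 2, depth = 2, rng_seed = 4)
  set.seed(5)
  X <- matrix(rnorm(3 * 7), 3, 7)
  G <- matrix(rnorm(3 * 8), 3, 8)
  fw <- decision_layer_forward(X, fs)
  bw <- ki67score:::decision_layer_backward(G, fw$cache)
  eps <- 1e-6
  f <- function(W, b, x) {
    fs2 <- fs; fs2$weights <- W; fs2$bias <- b
    sum(decision_layer_forward(x, fs2)$out * G)
  }
  rel_err <- function(num, ana) max(abs(num - ana)) / max(abs(num), 1e-10)
  num <- fs$weights
  for (i in seq_along(num)) {
    Wp <- fs$weights; Wp[i] <- Wp[i] + eps
    Wm <- fs$weights; Wm[i] <- Wm[i] - eps
    num[i] <- (f(Wp, fs$bias, X) - f(Wm, fs$bias, X)) / (2 * eps)
  }
  expect_lt(rel_err(num, bw$dW), 1e-4)
  numb <- fs$bias
  for (i in seq_along(numb)) {
    bp <- fs$bias; bp[i] <- bp[i] + eps
    bm <- fs$bias; bm[i] <- bm[i] - eps
    numb[i] <- (f(fs$weights, bp, X) - f(fs$weights, bm, X)) / (2 * eps)
  }
  expect_lt(rel_err(numb, bw$db), 1e-4)
  numx <- X
  for (i in seq_along(numx)) {
    Xp <- X; Xp[i] <- Xp[i] + eps
    Xm <- X; Xm[i] <- Xm[i] - eps
    numx[i] <- (f(fs$weights, fs$bias, Xp) - f(fs$weights, fs$bias, Xm)) / (2 * eps)
  }
  expect_lt(rel_err(numx, bw$dx), 1e-4)
})

test_that("full-stack gradients agree with finite differences on a tiny network", {
  cfg <- network_config(layers = list(
    layer_conv(3, 2), layer_pool(2), layer_conv(4, 2),
    layer_decision(2, 2), layer_fc(5), layer_fc(2)),
    dropout_ratio = 0, input_shape = c(9, 9, 2))
  params <- ki67score:::network_init(cfg, 5)
  set.seed(6)
  x <- array(rnorm(9 * 9 * 2 * 2), c(9, 9, 2, 2))
  y <- c(1L, 2L)
  lossf <- function(p)
    ki67score:::softmax_xent(
      ki67score:::network_forward(x, cfg, p)$scores, y)$loss
  fw <- ki67score:::network_forward(x, cfg, params)
  ls <- ki67score:::softmax_xent(fw$scores, y)
  gr <- ki67score:::network_backward(ls$dscores, cfg, params, fw$caches)
  eps <- 1e-6
  gf <- c(W = "W", b = "b", weights = "W", bias = "b")
  set.seed(7)
  for (li in seq_along(params)) {
    if (is.null(params[[li]])) next
    fields <- if (inherits(params[[li]], "forest_state"))
      c("weights", "bias") else c("W", "b")
    for (f in fields) {
      v <- params[[li]][[f]]
      for (i in sample(length(v), min(6, length(v)))) {
        pp <- params; pp[[li]][[f]][i] <- v[i] + eps
        pm <- params; pm[[li]][[f]][i] <- v[i] - eps
        numg <- (lossf(pp) - lossf(pm)) / (2 * eps)
        anag <- gr[[li]][[gf[f]]][i]
        expect_lt(abs(numg - anag) / max(abs(numg), abs(anag), 1e-6), 1e-4)
      }
    }
  }
})

test_that("the default architecture reproduces every printed shape", {
  sh <- network_shapes(network_config())
  expect_equal(sh$height[sh$kind %in% c("conv", "maxpool")],
               c(70, 35, 32, 16, 14, 7, 6, 3, 2))
  expect_equal(sh$maps[sh$kind == "conv"], c(90, 180, 360, 720, 1440))
  expect_equal(sh$maps[sh$kind == "decision"], 720)
  expect_equal(sh$maps[sh$kind == "fc"], c(100, 2))
})

test_that("inference is deterministic with dropout disabled and scores have width 2", {
  cfg <- desk_network_config()
  params <- ki67score:::network_init(cfg, 9)
  set.seed(10)
  x <- array(runif(71 * 71 * 3 * 2), c(71, 71, 3, 2))
  s1 <- ki67score:::network_forward(x, cfg, params)$scores
  s2 <- ki67score:::network_forward(x, cfg, params)$scores
  expect_identical(s1, s2)
  expect_equal(dim(s1), c(2, 2))
})

test_that("zero learning rate leaves parameters untouched and training is reproducible", {
  ps <- make_patch_set(n_images = 1, n_pos = 4, n_neg = 4, canvas = 200,
                       seed = 19)
  cfg <- network_config(layers = list(
    layer_conv(2, 2), layer_pool(2), layer_conv(3, 2),
    layer_decision(2, 2), layer_fc(4), layer_fc(2)),
    dropout_ratio = 0.5, input_shape = c(71, 71, 3))
  tc0 <- train_config(learning_rate = 0, batch_size = 4, max_iter = 5,
                      test_interval = 10, rng_seed = 3)
  net0 <- ndf_train(ps$patches, ps$labels, cfg, tc0)
  init <- ki67score:::network_init(cfg, with_seed(3L, {
    sample.int(.Machine$integer.max - 1, 1)
  }))
  expect_equal(net0$params[[1]]$W, init[[1]]$W)
  expect_equal(net0$params[[6]]$W, init[[6]]$W)
  # same seed twice -> identical loss trajectory
  tc <- train_config(batch_size = 4, max_iter = 8, test_interval = 10,
                     rng_seed = 4)
  n1 <- ndf_train(ps$patches, ps$labels, cfg, tc)
  n2 <- ndf_train(ps$patches, ps$labels, cfg, tc)
  expect_identical(n1$history, n2$history)
  expect_identical(n1$params, n2$params)
})

test_that("classifier posteriors sum to 1 and empty input yields empty output", {
  ps <- make_patch_set(n_images = 1, n_pos = 4, n_neg = 4, canvas = 200,
                       seed = 23)
  cfg <- network_config(layers = list(
    layer_conv(2, 2), layer_pool(2), layer_conv(3, 2),
    layer_decision(2, 2), layer_fc(4), layer_fc(2)),
    dropout_ratio = 0, input_shape = c(71, 71, 3))
  net <- ndf_train(ps$patches, ps$labels, cfg,
                   train_config(batch_size = 4, max_iter = 10,
                                test_interval = 20, rng_seed = 5))
  pred <- predict(net, ps$patches)
  expect_equal(pred$p_immunopositive + pred$p_immunonegative,
               rep(1, nrow(pred)), tolerance = 1e-9)
  empty <- predict(net, array(0, c(71, 71, 3, 0)))
  expect_equal(nrow(empty), 0)
})
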