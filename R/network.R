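# Network assembly: the convolutional stack with ReLU after every
# convolution, non-overlapping max-pooling, the decision-forest layer
# between the last convolution and the fully connected head, dropout after
# FC-1, and a 2-way FC output. Trained by mini-batch SGD with momentum and
# weight decay on a softmax cross-entropy loss.

layer_conv <- function(maps, filter)
  list(kind = "conv", maps = as.integer(maps),
       filter = as.integer(rep(filter, length.out = 2)))
layer_pool <- function(window = 2L)
  list(kind = "maxpool", window = as.integer(rep(window, length.out = 2)))
layer_decision <- function(n_trees = 45L, depth = 4L)
  list(kind = "decision", n_trees = as.integer(n_trees),
       depth = as.integer(depth))
layer_fc <- function(units) list(kind = "fc", units = as.integer(units))

# The reference architecture: 71x71x3 input ->
#   conv 90@2x2, pool, conv 180@4x4, pool, conv 360@3x3, pool,
#   conv 720@2x2, pool, conv 1440@2x2, decision (45 trees x depth 4 = 720),
#   FC-1 100, FC-2 2.
reference_layers <- function() list(
  layer_conv(90, 2), layer_pool(2),
  layer_conv(180, 4), layer_pool(2),
  layer_conv(360, 3), layer_pool(2),
  layer_conv(720, 2), layer_pool(2),
  layer_conv(1440, 2),
  layer_decision(45, 4),
  layer_fc(100), layer_fc(2))

#' Network configuration
#'
#' Layer stack, dropout ratio and class count for the patch classifier.
#' The default stack is the full reference architecture (five
#' convolutions of 90/180/360/720/1440 maps, four 2x2 max-poolings, a
#' 45-tree depth-4 decision layer of width 720, and FC layers of 100 and 2
#' units); [desk_network_config()] is a reduced-width profile with the
#' same topology for CPU-scale experiments.
#'
#' @param layers List of layer specs (`layer_conv`, `layer_pool`,
#'   `layer_decision`, `layer_fc`).
#' @param dropout_ratio Dropout probability after FC-1 (default 0.5).
#' @param n_classes Output classes (must equal the final FC width).
#' @param input_shape `c(H, W, C)` of the input patch.
#' @return Object of class `network_config`.
#' @export
network_config <- function(layers = reference_layers(), dropout_ratio = 0.5,
                           n_classes = 2L, input_shape = c(71L, 71L, 3L)) {
  stopifnot_scalar(dropout_ratio, "dropout_ratio", 0, 1 - 1e-9)
  last <- layers[[length(layers)]]
  if (last$kind != "fc" || last$units != n_classes)
    stop("final layer must be an fc layer of width n_classes", call. = FALSE)
  cfg <- structure(list(layers = layers, dropout_ratio = dropout_ratio,
                        n_classes = as.integer(n_classes),
                        input_shape = as.integer(input_shape)),
                   class = "network_config")
  network_shapes(cfg)  # validates the chain
  cfg
}

#' Reduced-width network profile for CPU-scale runs
#'
#' Same topology and spatial chain as the reference architecture (so every
#' spatial size is preserved) with narrower maps, a smaller forest and a
#' smaller FC-1; suitable for training on a desktop CPU in minutes.
#'
#' @inheritParams network_config
#' @export
desk_network_config <- function(dropout_ratio = 0.5) {
  network_config(layers = list(
    layer_conv(6, 2), layer_pool(2),
    layer_conv(12, 4), layer_pool(2),
    layer_conv(24, 3), layer_pool(2),
    layer_conv(24, 2), layer_pool(2),
    layer_conv(48, 2),
    layer_decision(8, 3),
    layer_fc(32), layer_fc(2)),
    dropout_ratio = dropout_ratio)
}

#' Layer-by-layer output shapes of a network configuration
#'
#' Chains the shape arithmetic from the input patch: valid stride-1
#' convolution (side - filter + 1), floor-divided non-overlapping pooling,
#' decision-layer width `n_trees * 2^depth`, FC widths.
#'
#' @param config A [network_config()].
#' @return data.frame with columns `layer`, `kind`, `maps`, `height`,
#'   `width` (spatial sides; 1 for vector layers).
#' @export
network_shapes <- function(config) {
  s <- config$input_shape
  h <- s[1]; w <- s[2]; c <- s[3]
  rows <- list(data.frame(layer = "input", kind = "input", maps = c,
                          height = h, width = w))
  vec_width <- NA_integer_
  for (i in seq_along(config$layers)) {
    ly <- config$layers[[i]]
    nm <- sprintf("%s-%d", ly$kind, i)
    if (ly$kind == "conv") {
      h2 <- h - ly$filter[1] + 1L; w2 <- w - ly$filter[2] + 1L
      if (h2 < 1L || w2 < 1L)
        stop(sprintf("layer %s: filter exceeds input %dx%d", nm, h, w),
             call. = FALSE)
      h <- h2; w <- w2; c <- ly$maps
      rows[[length(rows) + 1L]] <- data.frame(layer = nm, kind = "conv",
                                              maps = c, height = h, width = w)
    } else if (ly$kind == "maxpool") {
      h <- h %/% ly$window[1]; w <- w %/% ly$window[2]
      if (h < 1L || w < 1L)
        stop(sprintf("layer %s: pooling window exceeds input", nm),
             call. = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(layer = nm, kind = "maxpool",
                                              maps = c, height = h, width = w)
    } else if (ly$kind == "decision") {
      vec_width <- ly$n_trees * 2L^ly$depth
      rows[[length(rows) + 1L]] <- data.frame(layer = nm, kind = "decision",
                                              maps = vec_width, height = 1L,
                                              width = 1L)
      h <- w <- 1L; c <- vec_width
    } else if (ly$kind == "fc") {
      c <- ly$units
      rows[[length(rows) + 1L]] <- data.frame(layer = nm, kind = "fc",
                                              maps = c, height = 1L,
                                              width = 1L)
      h <- w <- 1L
    }
  }
  do.call(rbind, rows)
}

# Initialize all learnable parameters; scaled-uniform fan-in for conv/fc,
# normal for the forest functionals.
network_init <- function(config, rng_seed = 1L) {
  s <- config$input_shape
  h <- s[1]; w <- s[2]; cin <- s[3]
  seeds <- derive_seeds(rng_seed, length(config$layers))
  params <- vector("list", length(config$layers))
  for (i in seq_along(config$layers)) {
    ly <- config$layers[[i]]
    if (ly$kind == "conv") {
      fan_in <- ly$filter[1] * ly$filter[2] * cin
      a <- sqrt(6 / fan_in)
      params[[i]] <- with_seed(seeds[i], list(
        W = matrix(stats::runif(fan_in * ly$maps, -a, a), fan_in, ly$maps),
        b = numeric(ly$maps)))
      h <- h - ly$filter[1] + 1L; w <- w - ly$filter[2] + 1L; cin <- ly$maps
    } else if (ly$kind == "maxpool") {
      h <- h %/% ly$window[1]; w <- w %/% ly$window[2]
    } else if (ly$kind == "decision") {
      dn <- h * w * cin
      params[[i]] <- forest_state(dn, ly$n_trees, ly$depth,
                                  config$n_classes, rng_seed = seeds[i])
      cin <- ly$n_trees * 2L^ly$depth; h <- w <- 1L
    } else if (ly$kind == "fc") {
      fan_in <- h * w * cin
      a <- sqrt(6 / fan_in)
      params[[i]] <- with_seed(seeds[i], list(
        W = matrix(stats::runif(fan_in * ly$units, -a, a), fan_in, ly$units),
        b = numeric(ly$units)))
      cin <- ly$units; h <- w <- 1L
    }
  }
  params
}

# Forward pass over the full stack. x: [H,W,C,N] in [0,1].
# ReLU follows every conv and FC-1; dropout follows FC-1 (train only).
network_forward <- function(x, config, params, train_mode = FALSE) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  caches <- vector("list", length(config$layers))
  n_fc_seen <- 0L
  n_fc_total <- sum(vapply(config$layers, function(l) l$kind == "fc", TRUE))
  cur <- x
  for (i in seq_along(config$layers)) {
    ly <- config$layers[[i]]
    if (ly$kind == "conv") {
      fw <- conv_forward(cur, params[[i]]$W, params[[i]]$b, ly$filter)
      mask <- fw$out > 0
      cur <- fw$out * mask
      caches[[i]] <- list(kind = "conv", conv = fw$cache, relu_mask = mask)
    } else if (ly$kind == "maxpool") {
      fw <- maxpool_forward(cur, ly$window)
      cur <- fw$out
      caches[[i]] <- list(kind = "maxpool", pool = fw$cache)
    } else if (ly$kind == "decision") {
      fw <- decision_layer_forward(cur, params[[i]], mode = "embedding")
      cur <- fw$out
      caches[[i]] <- list(kind = "decision", dec = fw$cache)
    } else if (ly$kind == "fc") {
      n_fc_seen <- n_fc_seen + 1L
      if (!is.matrix(cur)) {                  # flatten a feature stack
        d <- dim(cur)
        cur <- t(matrix(cur, prod(d[1:3]), d[4]))
      }
      fw <- fc_forward(cur, params[[i]]$W, params[[i]]$b)
      if (n_fc_seen < n_fc_total) {           # hidden FC: ReLU + dropout
        mask <- fw$out > 0
        act <- fw$out * mask
        dp <- dropout_forward(act, config$dropout_ratio, train_mode)
        cur <- dp$out
        caches[[i]] <- list(kind = "fc", fc = fw$cache, relu_mask = mask,
                            drop_mask = dp$cache)
      } else {
        cur <- fw$out
        caches[[i]] <- list(kind = "fc", fc = fw$cache)
      }
    }
  }
  list(scores = cur, caches = caches)
}

network_backward <- function(dscores, config, params, caches) {
  grads <- vector("list", length(config$layers))
  cur <- dscores
  for (i in rev(seq_along(config$layers))) {
    ca <- caches[[i]]
    if (ca$kind == "fc") {
      if (!is.null(ca$relu_mask)) {
        if (!is.null(ca$drop_mask)) cur <- cur * ca$drop_mask
        cur <- cur * ca$relu_mask
      }
      bw <- fc_backward(cur, ca$fc)
      grads[[i]] <- list(W = bw$dW, b = bw$db)
      cur <- bw$dx
    } else if (ca$kind == "decision") {
      bw <- decision_layer_backward(cur, ca$dec)
      grads[[i]] <- list(W = bw$dW, b = bw$db)
      cur <- bw$dx
      # reshape back to the conv stack shape for the layer below
      below <- caches[[i - 1L]]
      d_below <- dim(below$relu_mask)
      cur <- array(t(cur), d_below)
    } else if (ca$kind == "maxpool") {
      if (is.matrix(cur)) {  # came from a flattening fc layer
        d <- ca$pool
        cur <- array(t(cur), c(d$oh, d$ow, d$in_dim[3], d$in_dim[4]))
      }
      cur <- maxpool_backward(cur, ca$pool)
    } else if (ca$kind == "conv") {
      if (is.matrix(cur)) {
        md <- dim(ca$relu_mask)
        cur <- array(t(cur), md)
      }
      cur <- cur * ca$relu_mask
      bw <- conv_backward(cur, ca$conv)
      grads[[i]] <- list(W = bw$dW, b = bw$db)
      cur <- bw$dx
    }
  }
  grads
}

#' Training configuration
#'
#' Optimizer settings for [ndf_train()]. Defaults follow the reference
#' schedule (learning rate 0.01, momentum 0.85, weight decay 0.005, batch
#' 128, 450,000 iterations, evaluation every 5,000); use
#' [desk_train_config()] for a CPU-scale run.
#'
#' @param learning_rate SGD step size (> 0; 0 allowed and leaves
#'   parameters untouched, useful for dry runs).
#' @param momentum Momentum coefficient in `[0, 1)`.
#' @param weight_decay L2 penalty coefficient.
#' @param batch_size Mini-batch size.
#' @param max_iter Number of SGD iterations.
#' @param test_interval Validation-accuracy evaluation period.
#' @param rng_seed Seed for initialization, batch sampling and dropout.
#' @return Object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.01, momentum = 0.85,
                         weight_decay = 0.005, batch_size = 128L,
                         max_iter = 450000L, test_interval = 5000L,
                         rng_seed = 1L) {
  stopifnot_scalar(learning_rate, "learning_rate", 0)
  stopifnot_scalar(momentum, "momentum", 0, 1 - 1e-12)
  stopifnot_scalar(batch_size, "batch_size", 1)
  structure(list(learning_rate = learning_rate, momentum = momentum,
                 weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 max_iter = as.integer(max_iter),
                 test_interval = as.integer(test_interval),
                 rng_seed = as.integer(rng_seed)),
            class = "train_config")
}

#' @rdname train_config
#' @param max_iter,batch_size,test_interval Scaled-down defaults.
#' @export
desk_train_config <- function(max_iter = 300L, batch_size = 32L,
                              test_interval = 50L, rng_seed = 1L)
  train_config(batch_size = batch_size, max_iter = max_iter,
               test_interval = test_interval, rng_seed = rng_seed)

# apply one SGD-with-momentum step to a params/velocity pair
sgd_step <- function(params, grads, vel, tc) {
  for (i in seq_along(params)) {
    if (is.null(grads[[i]])) next
    if (inherits(params[[i]], "forest_state")) {
      for (f in c("weights", "bias")) {
        g <- if (f == "weights") grads[[i]]$W else grads[[i]]$b
        vel[[i]][[f]] <- tc$momentum * vel[[i]][[f]] -
          tc$learning_rate * (g + tc$weight_decay * params[[i]][[f]])
        params[[i]][[f]] <- params[[i]][[f]] + vel[[i]][[f]]
      }
    } else {
      for (f in c("W", "b")) {
        vel[[i]][[f]] <- tc$momentum * vel[[i]][[f]] -
          tc$learning_rate * (grads[[i]][[f]] + tc$weight_decay * params[[i]][[f]])
        params[[i]][[f]] <- params[[i]][[f]] + vel[[i]][[f]]
      }
    }
  }
  list(params = params, vel = vel)
}

#' Train the patch classifier
#'
#' Mini-batch stochastic gradient descent with momentum and weight decay
#' on softmax cross-entropy. Fully reproducible from
#' `train_config$rng_seed`, which drives initialization, batch sampling
#' and dropout. Training aborts with an error if the loss becomes
#' non-finite.
#'
#' @param patches `size x size x 3 x N` array of training patches, values
#'   in `[0, 1]` (as produced by [crop_patches()]).
#' @param labels Factor/character vector of patch classes
#'   (`nucleus_classes()`).
#' @param net_config A [network_config()].
#' @param tc A [train_config()].
#' @param val_patches,val_labels Optional held-out set evaluated every
#'   `test_interval` iterations.
#' @param verbose Print progress every `test_interval` iterations.
#' @return Object of class `ki67_net`: `params`, `config`, `classes`,
#'   `history` (data.frame iter/loss), `val_history` (iter/accuracy).
#' @export
ndf_train <- function(patches, labels, net_config = desk_network_config(),
                      tc = desk_train_config(),
                      val_patches = NULL, val_labels = NULL,
                      verbose = FALSE) {
  labels <- factor(as.character(labels), levels = nucleus_classes())
  if (any(is.na(labels))) stop("labels must be nucleus classes", call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("training requires both classes present", call. = FALSE)
  n <- dim(patches)[4]
  stopifnot(n == length(labels))
  y <- as.integer(labels)

  with_seed(tc$rng_seed, {
    params <- network_init(net_config,
                           rng_seed = sample.int(.Machine$integer.max - 1, 1))
    vel <- lapply(params, function(p) {
      if (is.null(p)) return(NULL)
      if (inherits(p, "forest_state"))
        list(weights = p$weights * 0, bias = p$bias * 0)
      else list(W = p$W * 0, b = p$b * 0)
    })
    history <- data.frame(iter = integer(0), loss = numeric(0))
    val_history <- data.frame(iter = integer(0), accuracy = numeric(0))
    for (it in seq_len(tc$max_iter)) {
      bi <- sample.int(n, min(tc$batch_size, n),
                       replace = tc$batch_size > n)
      fw <- network_forward(patches[, , , bi, drop = FALSE], net_config,
                            params, train_mode = TRUE)
      ls <- softmax_xent(fw$scores, y[bi])
      if (!is.finite(ls$loss))
        stop(sprintf("training diverged (non-finite loss) at iteration %d", it),
             call. = FALSE)
      grads <- network_backward(ls$dscores, net_config, params, fw$caches)
      st <- sgd_step(params, grads, vel, tc)
      params <- st$params; vel <- st$vel
      history <- rbind(history, data.frame(iter = it, loss = ls$loss))
      if (it %% tc$test_interval == 0L || it == tc$max_iter) {
        acc <- NA_real_
        if (!is.null(val_patches)) {
          pred <- network_predict(val_patches, net_config, params)
          acc <- mean(pred$label == as.character(val_labels))
          val_history <- rbind(val_history,
                               data.frame(iter = it, accuracy = acc))
        }
        if (verbose)
          message(sprintf("iter %d: loss %.4f%s", it, ls$loss,
                          if (is.na(acc)) "" else sprintf(", val acc %.3f", acc)))
      }
    }
    structure(list(params = params, config = net_config,
                   classes = nucleus_classes(), history = history,
                   val_history = val_history, train_config = tc),
              class = "ki67_net")
  })
}

# batched inference (keeps memory bounded)
network_predict <- function(patches, config, params, batch = 128L) {
  if (length(dim(patches)) == 3L) dim(patches) <- c(dim(patches), 1L)
  n <- dim(patches)[4]
  post <- matrix(0, n, config$n_classes)
  i <- 1L
  while (i <= n) {
    j <- min(i + batch - 1L, n)
    fw <- network_forward(patches[, , , i:j, drop = FALSE], config, params,
                          train_mode = FALSE)
    post[i:j, ] <- softmax_rows(fw$scores)
    i <- j + 1L
  }
  colnames(post) <- nucleus_classes()[seq_len(config$n_classes)]
  label <- nucleus_classes()[max.col(post, ties.method = "first")]
  list(label = label, posterior = post)
}

#' @export
print.ki67_net <- function(x, ...) {
  sh <- network_shapes(x$config)
  cat(sprintf("Ki-67 patch classifier: %d layers, trained %d iterations\n",
              nrow(sh) - 1L, max(x$history$iter, 0)))
  cat(sprintf("  final training loss %.4f", utils::tail(x$history$loss, 1)))
  if (nrow(x$val_history))
    cat(sprintf(", last validation accuracy %.3f",
                utils::tail(x$val_history$accuracy, 1)))
  cat("\n")
  invisible(x)
}

#' Classify patches with a trained network
#'
#' @param object A `ki67_net` from [ndf_train()].
#' @param patches `size x size x 3 x N` array in `[0, 1]`.
#' @param ... Unused.
#' @return data.frame with `label`, `p_immunopositive`,
#'   `p_immunonegative`; zero rows for an empty patch array.
#' @export
predict.ki67_net <- function(object, patches, ...) {
  if (length(dim(patches)) == 3L) dim(patches) <- c(dim(patches), 1L)
  if (dim(patches)[4] == 0L)
    return(data.frame(label = character(0), p_immunopositive = numeric(0),
                      p_immunonegative = numeric(0)))
  pr <- network_predict(patches, object$config, object$params)
  data.frame(label = pr$label,
             p_immunopositive = pr$posterior[, "immunopositive"],
             p_immunonegative = pr$posterior[, "immunonegative"],
             stringsAsFactors = FALSE)
}

#' @rdname predict.ki67_net
#' @param net A `ki67_net`.
#' @export
classify_patches <- function(patches, net) predict(net, patches)
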