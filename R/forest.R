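# Differentiable decision forest ("decision layer"). Each tree is a full
# binary tree of the stated depth. Every decision node d carries an affine
# functional f_r of the input features; its routing decision is the
# sigmoid f_d(x) = sigma(f_r(x)), sending mass f_d to the left subtree and
# 1 - f_d to the right. The probability mu_p that a sample reaches leaf p
# is the product of these node decisions along the root-to-leaf path, so
# sum_p mu_p = 1 per tree. Each leaf p carries a class distribution pi_p;
# a tree's prediction is sum_p pi_p * mu_p and the forest averages its
# trees. In the full network the layer is used in "embedding" mode: the
# concatenated leaf-reach probabilities of all trees (width
# n_trees * 2^depth) feed the fully connected head.
#
# Nodes use 1-based heap indexing: node 1 is the root, node k has children
# 2k (left) and 2k + 1 (right); level l holds nodes 2^l .. 2^(l+1) - 1.

#' Initialize a decision-forest state
#'
#' @param input_dim Dimension of the (flattened) feature vector each
#'   decision functional reads.
#' @param n_trees Number of trees `z` (default 45).
#' @param depth Tree depth (levels of decision nodes; `2^depth` leaves per
#'   tree, default 4, so the default embedding width is 45 * 16 = 720).
#' @param n_classes Classes for the leaf distributions (default 2).
#' @param rng_seed Seed for the decision-functional weights.
#' @param init_sd SD of the normal weight initialization, default
#'   `1/sqrt(input_dim)`.
#' @return Object of class `forest_state`: `weights`
#'   (`input_dim x (n_trees*n_nodes)`), `bias`, `pi_logits`
#'   (`n_leaves x n_classes x n_trees`), plus the shape fields.
#' @export
forest_state <- function(input_dim, n_trees = 45L, depth = 4L,
                         n_classes = 2L, rng_seed = 1L, init_sd = NULL) {
  stopifnot(depth >= 0, n_trees >= 1)
  n_nodes <- 2L^depth - 1L
  n_leaves <- 2L^depth
  if (is.null(init_sd)) init_sd <- 1 / sqrt(max(input_dim, 1))
  with_seed(rng_seed, {
    W <- matrix(stats::rnorm(input_dim * n_trees * n_nodes, 0, init_sd),
                input_dim, n_trees * n_nodes)
    structure(list(weights = W, bias = numeric(n_trees * n_nodes),
                   pi_logits = array(0, c(n_leaves, n_classes, n_trees)),
                   input_dim = as.integer(input_dim),
                   n_trees = as.integer(n_trees), depth = as.integer(depth),
                   n_nodes = n_nodes, n_leaves = n_leaves,
                   n_classes = as.integer(n_classes)),
              class = "forest_state")
  })
}

# Leaf-reach probabilities from node decisions.
# D: N x n_nodes sigmoid outputs (heap order). Returns list of per-level
# reach matrices; the last is mu (N x n_leaves).
routing_from_decisions <- function(D, depth) {
  P <- list(matrix(1, nrow(D), 1))
  if (depth == 0L) return(P)
  for (l in 0:(depth - 1L)) {
    nodes <- (2L^l):(2L^(l + 1L) - 1L)
    d <- D[, nodes, drop = FALSE]
    prev <- P[[l + 1L]]
    nxt <- matrix(0, nrow(D), 2L^(l + 1L))
    nxt[, 2L * seq_along(nodes) - 1L] <- prev * d
    nxt[, 2L * seq_along(nodes)] <- prev * (1 - d)
    P[[l + 2L]] <- nxt
  }
  P
}

#' Leaf-reach probabilities of one decision tree
#'
#' Routes a feature vector through one tree: at each decision node the
#' sigmoid of the node's affine functional sends probability mass left
#' (`f_d`) and right (`1 - f_d`); a leaf's reach probability is the
#' product along its path, and the probabilities sum to 1.
#'
#' @param features Numeric vector (length `forest$input_dim`) or
#'   `N x input_dim` matrix.
#' @param forest A [forest_state()].
#' @param tree Tree index.
#' @return Vector (or `N x n_leaves` matrix) of leaf-reach probabilities
#'   `mu`.
#' @export
decision_routing <- function(features, forest, tree = 1L) {
  stopifnot(inherits(forest, "forest_state"))
  x <- if (is.matrix(features)) features else matrix(features, nrow = 1)
  if (forest$depth == 0L) {
    mu <- matrix(1, nrow(x), 1)
  } else {
    cols <- ((tree - 1L) * forest$n_nodes + 1L):(tree * forest$n_nodes)
    S <- sweep(x %*% forest$weights[, cols, drop = FALSE], 2L,
               forest$bias[cols], `+`)
    mu <- routing_from_decisions(stats::plogis(S), forest$depth)[[forest$depth + 1L]]
  }
  if (is.matrix(features)) mu else drop(mu)
}

forest_leaf_distributions <- function(forest) {
  # softmax over classes per leaf
  apply(forest$pi_logits, c(1, 3), function(v) {
    e <- exp(v - max(v)); e / sum(e)
  })  # n_classes x n_leaves x n_trees
}

#' Forest class prediction
#'
#' Per tree, the class distribution is `sum_p pi_p * mu_p`; the forest
#' output is the uniform average over its trees and sums to 1.
#'
#' @inheritParams decision_routing
#' @return Named class-probability vector (or `N x n_classes` matrix).
#' @export
forest_predict <- function(features, forest) {
  stopifnot(inherits(forest, "forest_state"))
  x <- if (is.matrix(features)) features else matrix(features, nrow = 1)
  pis <- forest_leaf_distributions(forest)   # n_classes x n_leaves x n_trees
  out <- matrix(0, nrow(x), forest$n_classes)
  for (t in seq_len(forest$n_trees)) {
    mu <- decision_routing(x, forest, t)
    if (!is.matrix(mu)) mu <- matrix(mu, nrow = 1)
    out <- out + mu %*% t(pis[, , t, drop = TRUE])
  }
  out <- out / forest$n_trees
  colnames(out) <- nucleus_classes()[seq_len(forest$n_classes)]
  if (is.matrix(features)) out else drop(out)
}

#' Decision-layer forward pass
#'
#' Flattens the final convolutional feature stack and routes it through
#' every tree. In `"embedding"` mode (the default, matching the printed
#' architecture where the layer's 720 outputs feed FC-1) the output is the
#' concatenation of all trees' leaf-reach probabilities, width
#' `n_trees * 2^depth`. In `"probability"` mode the per-tree class
#' posteriors are concatenated instead (standalone forest use).
#'
#' @param x Feature stack `[h, w, c, N]` or feature matrix `N x input_dim`.
#' @param forest A [forest_state()].
#' @param mode `"embedding"` or `"probability"`.
#' @return List: `out` (N x width matrix), `cache`.
#' @export
decision_layer_forward <- function(x, forest,
                                   mode = c("embedding", "probability")) {
  mode <- match.arg(mode)
  if (!is.matrix(x)) {
    d <- dim(x)
    if (length(d) == 3L) dim(x) <- c(d, 1L)
    d <- dim(x)
    x <- t(matrix(x, prod(d[1:3]), d[4]))
  }
  if (ncol(x) != forest$input_dim)
    stop(sprintf("decision layer: flattened input width %d != expected %d",
                 ncol(x), forest$input_dim), call. = FALSE)
  S <- sweep(x %*% forest$weights, 2L, forest$bias, `+`)
  D <- stats::plogis(S)
  N <- nrow(x)
  levels <- vector("list", forest$n_trees)
  emb <- matrix(0, N, forest$n_trees * forest$n_leaves)
  for (t in seq_len(forest$n_trees)) {
    if (forest$depth == 0L) {
      P <- list(matrix(1, N, 1))
    } else {
      cols <- ((t - 1L) * forest$n_nodes + 1L):(t * forest$n_nodes)
      P <- routing_from_decisions(D[, cols, drop = FALSE], forest$depth)
    }
    levels[[t]] <- P
    emb[, ((t - 1L) * forest$n_leaves + 1L):(t * forest$n_leaves)] <-
      P[[forest$depth + 1L]]
  }
  out <- if (mode == "embedding") emb else {
    pis <- forest_leaf_distributions(forest)
    pr <- matrix(0, N, forest$n_trees * forest$n_classes)
    for (t in seq_len(forest$n_trees)) {
      mu <- emb[, ((t - 1L) * forest$n_leaves + 1L):(t * forest$n_leaves),
                drop = FALSE]
      pr[, ((t - 1L) * forest$n_classes + 1L):(t * forest$n_classes)] <-
        mu %*% t(pis[, , t, drop = TRUE])
    }
    pr
  }
  list(out = out,
       cache = list(x = x, D = D, levels = levels, forest = forest,
                    mode = mode))
}

# Backward through the embedding-mode decision layer.
# dout: N x (n_trees * n_leaves) gradient wrt the embedding.
decision_layer_backward <- function(dout, cache) {
  forest <- cache$forest
  if (cache$mode != "embedding")
    stop("backward implemented for embedding mode", call. = FALSE)
  N <- nrow(dout)
  dD <- matrix(0, N, forest$n_trees * forest$n_nodes)
  for (t in seq_len(forest$n_trees)) {
    P <- cache$levels[[t]]
    cols <- ((t - 1L) * forest$n_nodes + 1L):(t * forest$n_nodes)
    Dt <- cache$D[, cols, drop = FALSE]
    G <- dout[, ((t - 1L) * forest$n_leaves + 1L):(t * forest$n_leaves),
              drop = FALSE]
    if (forest$depth > 0L)
      for (l in (forest$depth - 1L):0L) {
        nodes <- (2L^l):(2L^(l + 1L) - 1L)
        d <- Dt[, nodes, drop = FALSE]
        prev <- P[[l + 1L]]
        gl <- G[, 2L * seq_along(nodes) - 1L, drop = FALSE]
        gr <- G[, 2L * seq_along(nodes), drop = FALSE]
        dD[, cols[nodes]] <- gl * prev - gr * prev
        G <- gl * d + gr * (1 - d)
      }
  }
  dS <- dD * cache$D * (1 - cache$D)
  list(dx = dS %*% t(forest$weights),
       dW = crossprod(cache$x, dS),
       db = colSums(dS))
}
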