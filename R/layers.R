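# Network building blocks. Feature stacks are 4-d arrays [H, W, C, N]
# (rows, cols, channels/maps, batch). Convolutions are valid (no padding),
# stride 1, implemented as im2col + one BLAS matrix product; that
# arithmetic (71 -> 70 with a 2x2 filter, 35 -> 32 with 4x4) is what the
# reference architecture's layer sizes imply. Max-pooling is
# non-overlapping with stride = window and floor division on odd sides
# (7 -> 3 with a 2x2 window).

# Patch-extraction index matrix for one sample: (oh*ow) x (kh*kw*C),
# entries are linear indices into an [H, W, C] array.
im2col_index <- function(H, W, C, kh, kw) {
  oh <- H - kh + 1L; ow <- W - kw + 1L
  if (oh < 1L || ow < 1L)
    stop(sprintf("filter %dx%d larger than input %dx%d", kh, kw, H, W),
         call. = FALSE)
  off <- as.vector(outer(0:(kh - 1L), H * (0:(kw - 1L)), `+`))
  off <- as.vector(outer(off, H * W * (0:(C - 1L)), `+`))
  st <- as.vector(outer(seq_len(oh), H * (seq_len(ow) - 1L), `+`))
  list(idx = outer(st, off, `+`), oh = oh, ow = ow)
}

# x: [H,W,C,N] -> col matrix (oh*ow*N) x (kh*kw*C), rows ordered position-
# within-sample fastest, then sample.
im2col <- function(x, kh, kw) {
  d <- dim(x)
  ii <- im2col_index(d[1], d[2], d[3], kh, kw)
  npos <- ii$oh * ii$ow
  K <- ncol(ii$idx)
  N <- d[4]
  idxN <- ii$idx[rep(seq_len(npos), N), , drop = FALSE] +
    rep((0:(N - 1)) * prod(d[1:3]), each = npos)
  col <- x[idxN]
  dim(col) <- c(npos * N, K)
  list(col = col, idxN = idxN, oh = ii$oh, ow = ii$ow, in_dim = d)
}

#' Convolution layer forward pass
#'
#' Valid (no padding), stride-1 cross-correlation with per-map bias:
#' output spatial side = input side - filter side + 1.
#'
#' @param x Feature stack `[H, W, C, N]` (a 3-d `[H, W, C]` array is
#'   treated as a batch of one).
#' @param weights Kernel matrix `(kh*kw*C) x M` (column-major `[kh, kw, C]`
#'   flattening per column).
#' @param bias Length-`M` vector.
#' @param filter `c(kh, kw)`.
#' @return List: `out` (`[oh, ow, M, N]`), `cache` for the backward pass.
#' @export
conv_forward <- function(x, weights, bias, filter) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  d <- dim(x)
  if (nrow(weights) != filter[1] * filter[2] * d[3])
    stop(sprintf("conv layer: kernel depth %d does not match input channels %d",
                 nrow(weights) / (filter[1] * filter[2]), d[3]), call. = FALSE)
  ic <- im2col(x, filter[1], filter[2])
  M <- ncol(weights)
  out <- ic$col %*% weights
  out <- sweep(out, 2L, bias, `+`)
  dim(out) <- c(ic$oh, ic$ow, d[4], M)
  out <- aperm(out, c(1, 2, 4, 3))
  list(out = out, cache = list(col = ic$col, idxN = ic$idxN,
                               in_dim = d, weights = weights))
}

conv_backward <- function(dout, cache) {
  d <- dim(dout)                       # oh ow M N
  dmat <- aperm(dout, c(1, 2, 4, 3))
  dim(dmat) <- c(d[1] * d[2] * d[4], d[3])
  dW <- crossprod(cache$col, dmat)
  db <- colSums(dmat)
  dcol <- dmat %*% t(cache$weights)
  dx <- numeric(prod(cache$in_dim))
  for (j in seq_len(ncol(dcol))) {
    ij <- cache$idxN[, j]
    dx[ij] <- dx[ij] + dcol[, j]
  }
  dim(dx) <- cache$in_dim
  list(dx = dx, dW = dW, db = db)
}

#' Max-pooling layer forward pass
#'
#' Per-channel block maximum over non-overlapping windows (stride =
#' window). Odd trailing rows/columns are dropped (floor division), which
#' is what takes a 7x7 map to 3x3 under a 2x2 window.
#'
#' @param x Feature stack `[H, W, C, N]`.
#' @param window `c(ph, pw)` pooling window.
#' @return List: `out` (`[floor(H/ph), floor(W/pw), C, N]`), `cache`.
#' @export
maxpool_forward <- function(x, window = c(2L, 2L)) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  d <- dim(x)
  ph <- window[1]; pw <- window[2]
  oh <- d[1] %/% ph; ow <- d[2] %/% pw
  if (oh < 1L || ow < 1L)
    stop("pooling window larger than input", call. = FALSE)
  xt <- x[seq_len(oh * ph), seq_len(ow * pw), , , drop = FALSE]
  dim(xt) <- c(ph, oh, pw, ow, d[3], d[4])
  xt <- aperm(xt, c(1, 3, 2, 4, 5, 6))
  m <- matrix(xt, nrow = ph * pw)
  mx <- m[1, ]
  am <- rep(1L, ncol(m))
  for (r in seq_len(ph * pw)[-1]) {
    upd <- m[r, ] > mx
    mx[upd] <- m[r, upd]
    am[upd] <- r
  }
  dim(mx) <- c(oh, ow, d[3], d[4])
  list(out = mx, cache = list(am = am, in_dim = d, window = window,
                              oh = oh, ow = ow))
}

maxpool_backward <- function(dout, cache) {
  d <- cache$in_dim
  ph <- cache$window[1]; pw <- cache$window[2]
  oh <- cache$oh; ow <- cache$ow
  dm <- matrix(0, ph * pw, oh * ow * d[3] * d[4])
  dm[cbind(cache$am, seq_len(ncol(dm)))] <- as.vector(dout)
  dim(dm) <- c(ph, pw, oh, ow, d[3], d[4])
  dm <- aperm(dm, c(1, 3, 2, 4, 5, 6))
  dim(dm) <- c(ph * oh, pw * ow, d[3], d[4])
  dx <- array(0, d)
  dx[seq_len(oh * ph), seq_len(ow * pw), , ] <- dm
  dx
}

#' Rectified linear unit
#'
#' Elementwise `max(0, x)`; the shape of the input is preserved.
#'
#' @param x Numeric array or vector.
#' @return Same shape as `x`.
#' @examples relu(c(-3, 0, 5))  # 0 0 5
#' @export
relu <- function(x) {
  out <- pmax(x, 0)
  if (!is.null(dim(x))) dim(out) <- dim(x)
  out
}

fc_forward <- function(x, weights, bias) {
  out <- x %*% weights
  out <- sweep(out, 2L, bias, `+`)
  list(out = out, cache = list(x = x, weights = weights))
}

fc_backward <- function(dout, cache) {
  list(dx = dout %*% t(cache$weights),
       dW = crossprod(cache$x, dout),
       db = colSums(dout))
}

# Inverted dropout: active only in training; expectation-preserving.
dropout_forward <- function(x, ratio, train_mode) {
  if (!train_mode || ratio <= 0)
    return(list(out = x, cache = NULL))
  keep <- 1 - ratio
  mask <- (stats::runif(length(x)) < keep) / keep
  dim(mask) <- dim(x)
  list(out = x * mask, cache = mask)
}

softmax_rows <- function(scores) {
  e <- exp(scores - apply(scores, 1, max))
  e / rowSums(e)
}

# Cross-entropy on softmax outputs; y: integer class index per row.
softmax_xent <- function(scores, y) {
  p <- softmax_rows(scores)
  n <- nrow(scores)
  loss <- -mean(log(pmax(p[cbind(seq_len(n), y)], 1e-12)))
  dscores <- p
  dscores[cbind(seq_len(n), y)] <- dscores[cbind(seq_len(n), y)] - 1
  list(loss = loss, dscores = dscores / n)
}
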