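# Minimal neural-network primitives: parameter containers as nested named
# lists of numeric arrays, explicit forward/backward passes, and Adam.
# Everything is batch-vectorized; recurrent loops run over time only.
# Gradients are verified against finite differences in the test suite.

sigmoid <- function(x) 1 / (1 + exp(-x))

# Row-wise softmax with max-shift for stability.
row_softmax <- function(x) {
  e <- exp(x - apply(x, 1L, max))
  e / rowSums(e)
}

# Glorot-uniform initialization.
init_mat <- function(nin, nout) {
  a <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -a, a), nin, nout)
}

init_linear <- function(nin, nout)
  list(W = init_mat(nin, nout), b = numeric(nout))

linear_forward <- function(X, p) X %*% p$W + rep(p$b, each = nrow(X))

linear_backward <- function(dY, X, p)
  list(grads = list(W = crossprod(X, dY), b = colSums(dY)),
       dX = tcrossprod(dY, p$W))

# --------------------------------------------------------------------------
# Parameter-tree utilities (nested named lists with numeric leaves)

nn_map <- function(f, p) {
  if (is.list(p)) lapply(p, function(q) nn_map(f, q)) else f(p)
}

nn_map2 <- function(f, p, q) {
  if (is.list(p)) {
    out <- vector("list", length(p))
    names(out) <- names(p)
    for (i in seq_along(p)) out[[i]] <- nn_map2(f, p[[i]], q[[i]])
    out
  } else f(p, q)
}

nn_zeros_like <- function(p) nn_map(function(x) x * 0, p)

nn_add <- function(p, q) nn_map2(`+`, p, q)

# Adam optimizer over a parameter tree.
adam_init <- function(params)
  list(m = nn_zeros_like(params), v = nn_zeros_like(params), t = 0L)

# lr_mult: optional named list of per-top-level-subtree learning-rate
# multipliers (e.g., to let a low-gradient head train faster).
adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, lr_mult = NULL) {
  state$t <- state$t + 1L
  state$m <- nn_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                     state$m, grads)
  state$v <- nn_map2(function(v, g) beta2 * v + (1 - beta2) * g^2,
                     state$v, grads)
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  upd <- nn_map2(function(m, v) lr * (m / corr1) / (sqrt(v / corr2) + eps),
                 state$m, state$v)
  if (!is.null(lr_mult))
    for (nm in names(lr_mult))
      upd[[nm]] <- nn_map(function(x) x * lr_mult[[nm]], upd[[nm]])
  list(params = nn_map2(`-`, params, upd), state = state)
}

# --------------------------------------------------------------------------
# GRU layer (batched; gates ordered r, z, n).
#
# Time-major stacked representation: a length-T sequence of (B x nin)
# inputs is one (T*B x nin) matrix whose t-th row block is the batch at
# step t. Input projections for all steps run as a single GEMM; only the
# hidden-to-hidden product stays inside the time loop.

gru_init <- function(nin, H)
  list(Wx = init_mat(nin, 3L * H), Wh = init_mat(H, 3L * H),
       bx = numeric(3L * H), bh = numeric(3L * H))

time_blocks <- function(Tn, B)
  lapply(seq_len(Tn), function(t) ((t - 1L) * B + 1L):(t * B))

# Reverse the time order of the row blocks.
reverse_time <- function(Xbig, B) {
  Tn <- nrow(Xbig) %/% B
  idx <- unlist(lapply(rev(seq_len(Tn)), function(t)
    ((t - 1L) * B + 1L):(t * B)))
  Xbig[idx, , drop = FALSE]
}

gru_forward <- function(Xbig, B, p, h0 = NULL) {
  if (is.null(h0)) h0 <- matrix(0, B, nrow(p$Wh))
  out <- gru_core_forward(Xbig, B, p$Wx, p$Wh, p$bx, p$bh, h0)
  out$B <- B
  out$Tn <- nrow(Xbig) %/% B
  out$Xbig <- Xbig
  out$p <- p
  out
}

# dHbig: upstream gradient on the full hidden sequence (or NULL);
# dh_last: gradient on the final hidden state (or NULL).
gru_backward <- function(fw, dHbig = NULL, dh_last = NULL) {
  H <- nrow(fw$p$Wh)
  if (is.null(dHbig)) dHbig <- matrix(0, nrow(fw$Xbig), H)
  if (is.null(dh_last)) dh_last <- matrix(0, fw$B, H)
  out <- gru_core_backward(fw$Xbig, fw$B, fw$p$Wx, fw$p$Wh, fw$Hprev,
                           fw$r, fw$z, fw$n, fw$ghn, dHbig, dh_last)
  list(grads = list(Wx = out$dWx, Wh = out$dWh, bx = as.numeric(out$dbx),
                    bh = as.numeric(out$dbh)),
       dX = out$dX, dh0 = out$dh0)
}

# Bidirectional GRU: forward and time-reversed streams, per-step outputs
# concatenated as [forward_t, backward_t].
bigru_forward <- function(Xbig, B, pf, pb) {
  fwd <- gru_forward(Xbig, B, pf)
  bwd <- gru_forward(reverse_time(Xbig, B), B, pb)
  list(Hbig = cbind(fwd$Hbig, reverse_time(bwd$Hbig, B)),
       h_last_f = fwd$h_last, h_last_b = bwd$h_last, fwd = fwd, bwd = bwd,
       B = B)
}

bigru_backward <- function(fw, dHbig = NULL, dh_last_f = NULL,
                           dh_last_b = NULL) {
  B <- fw$B
  H <- ncol(fw$fwd$h_last)
  df <- NULL; db <- NULL
  if (!is.null(dHbig)) {
    df <- dHbig[, seq_len(H), drop = FALSE]
    db <- reverse_time(dHbig[, H + seq_len(H), drop = FALSE], B)
  }
  bf <- gru_backward(fw$fwd, df, dh_last_f)
  bb <- gru_backward(fw$bwd, db, dh_last_b)
  list(grads_f = bf$grads, grads_b = bb$grads,
       dX = bf$dX + reverse_time(bb$dX, B))
}

# --------------------------------------------------------------------------
# Layer normalization (per row)

layernorm_init <- function(D) list(g = rep(1, D), b = numeric(D))

layernorm_forward <- function(X, p, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  list(Y = sweep(xhat, 2L, p$g, `*`) + rep(p$b, each = nrow(X)),
       xhat = xhat, inv = inv, p = p)
}

layernorm_backward <- function(fw, dY) {
  D <- ncol(fw$xhat)
  dxhat <- sweep(dY, 2L, fw$p$g, `*`)
  dX <- (dxhat - rowMeans(dxhat) -
           fw$xhat * rowMeans(dxhat * fw$xhat)) * fw$inv
  list(grads = list(g = colSums(dY * fw$xhat), b = colSums(dY)), dX = dX)
}

# --------------------------------------------------------------------------
# Weighted softmax cross-entropy. logits: B x C; target: integer class
# index; w: per-class weights (default 1). Loss is the weighted mean.
softmax_ce_forward <- function(logits, target, w = NULL) {
  B <- nrow(logits)
  P <- row_softmax(logits)
  if (is.null(w)) w <- rep(1, ncol(logits))
  wt <- w[target]
  eps <- 1e-12
  loss <- -sum(wt * log(P[cbind(seq_len(B), target)] + eps)) / sum(wt)
  list(loss = loss, P = P, target = target, wt = wt)
}

softmax_ce_backward <- function(fw) {
  B <- nrow(fw$P)
  dlogits <- fw$P
  dlogits[cbind(seq_len(B), fw$target)] <-
    dlogits[cbind(seq_len(B), fw$target)] - 1
  dlogits * (fw$wt / sum(fw$wt))
}

# Class-balanced window sampling: the probability of drawing a training
# window is proportional to 1/sqrt(count) of its center label. Combined
# with the matching cross-entropy class weights below, the effective
# per-class emphasis is inverse-count, split into sampling x weighting so
# per-batch gradients stay low-variance.
window_sampling_weights <- function(target_all, c_off, max_start) {
  centers <- target_all[seq_len(max_start) + c_off]
  cnt <- table(centers)
  w <- stats::setNames(1 / sqrt(as.numeric(cnt)), names(cnt))
  as.numeric(w[as.character(centers)])
}

# Inverse square-root frequency class weights, normalized to mean 1.
# Available for custom training schemes; the fitted models use balanced
# window sampling with uniform loss weights instead.
class_weights <- function(target_idx, n_classes) {
  cnt <- tabulate(target_idx, nbins = n_classes)
  w <- ifelse(cnt > 0, 1 / sqrt(cnt), 0)
  w / mean(w[cnt > 0])
}

# --------------------------------------------------------------------------
# Multi-head self-attention parameters; the fused encoder-layer kernels in
# src/transformer_layer.cpp consume them directly.

attn_init <- function(D)
  list(Wq = init_mat(D, D), Wk = init_mat(D, D), Wv = init_mat(D, D),
       Wo = init_mat(D, D), bo = numeric(D))
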