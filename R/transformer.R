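# Masked-span Transformer for behavioral time-series: a small attention
# encoder pre-trained by reconstructing one contiguous masked span per
# sequence, trained jointly with a bidirectional-GRU classification head
# over a short central slice of the encoded sequence.
#
# Flat layout convention: a batch of B sequences of length S is a
# (S*B x D) matrix with row (b-1)*S + s = position s of sample b.

#' Configuration for the masked-span Transformer
#'
#' @param n_layers Encoder layers.
#' @param n_heads Attention heads per layer.
#' @param d_model Token embedding width (must be divisible by `n_heads`).
#' @param ff_hidden Feed-forward hidden size.
#' @param seq_len Input sequence length in samples.
#' @param mask_ratio Fraction of the sequence masked as one contiguous
#'   span; the span length is `round(mask_ratio * seq_len)`.
#' @param slice_len Length of the central encoded slice sent to the
#'   classification head.
#' @param cls_hidden Hidden size of the bidirectional GRU head (per
#'   direction).
#' @param w_cls Weight of the classification loss added to the masked
#'   reconstruction loss.
#' @param lr Adam learning rate.
#' @param epochs,batch_size,windows_per_epoch Training budget.
#' @param use_positional Inject positional information? Fixed sinusoidal
#'   position encodings are added to the input embeddings; switching them
#'   off (ablation) leaves the encoder order-blind, which destroys masked
#'   reconstruction of periodic classes.
#' @param two_phase If `TRUE`, the first half of training runs pure masked
#'   reconstruction and classification joins afterwards; default trains
#'   both simultaneously.
#' @param seed RNG seed.
#' @return A list of class `transformer_config`.
#' @export
transformer_config <- function(n_layers = 4L, n_heads = 4L, d_model = 32L,
                               ff_hidden = 80L, seq_len = 20L,
                               mask_ratio = 0.45, slice_len = 5L,
                               cls_hidden = 30L, w_cls = 2, lr = 3e-3,
                               epochs = 30L, batch_size = 60L,
                               windows_per_epoch = 900L,
                               use_positional = TRUE, two_phase = FALSE,
                               seed = 1L) {
  stopifnot(mask_ratio > 0, mask_ratio < 1, slice_len <= seq_len,
            d_model %% n_heads == 0L,
            round(mask_ratio * seq_len) >= 1)
  structure(list(n_layers = as.integer(n_layers),
                 n_heads = as.integer(n_heads),
                 d_model = as.integer(d_model),
                 ff_hidden = as.integer(ff_hidden),
                 seq_len = as.integer(seq_len), mask_ratio = mask_ratio,
                 slice_len = as.integer(slice_len),
                 cls_hidden = as.integer(cls_hidden), w_cls = w_cls,
                 lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 windows_per_epoch = as.integer(windows_per_epoch),
                 use_positional = use_positional, two_phase = two_phase,
                 seed = as.integer(seed)),
            class = "transformer_config")
}

transformer_init_params <- function(cfg, n_features, n_classes) {
  dm <- cfg$d_model
  layers <- lapply(seq_len(cfg$n_layers), function(i)
    list(attn = attn_init(dm), ln1 = layernorm_init(dm),
         ff1 = init_linear(dm, cfg$ff_hidden),
         ff2 = init_linear(cfg$ff_hidden, dm), ln2 = layernorm_init(dm)))
  names(layers) <- paste0("layer", seq_len(cfg$n_layers))
  c(list(emb = init_linear(n_features, dm),
         mask_tok = list(m = 0.02 * stats::rnorm(dm)),
         dec = init_linear(dm, n_features),
         clsf = gru_init(dm, cfg$cls_hidden),
         clsb = gru_init(dm, cfg$cls_hidden),
         cls_out = init_linear(2L * cfg$cls_hidden, n_classes)),
    layers)
}

# Standard fixed sinusoidal position encodings (pairs of sin/cos at
# geometrically spaced wavelengths).
sinusoidal_pe <- function(S, D) {
  pos <- seq_len(S) - 1L
  i <- seq_len(D %/% 2L) - 1L
  ang <- outer(pos, 1 / 10000^(2 * i / D))
  P <- matrix(0, S, D)
  P[, 2L * i + 1L] <- sin(ang)
  P[, 2L * i + 2L] <- cos(ang)
  P
}

#' Mask a contiguous span of a sequence
#'
#' Replaces one contiguous span of length `round(ratio * seq_len)` at a
#' uniformly random feasible start with `mask_value`. Span masking (rather
#' than masking isolated samples) prevents the trivial solution of
#' interpolating a sample from its immediate neighbors.
#'
#' @param x A `seq_len x F` matrix.
#' @param ratio Mask ratio in (0, 1).
#' @param mask_value Value written into the masked positions; the trained
#'   model uses a learned mask token in embedding space instead.
#' @return A list with `masked` (the matrix with the span overwritten),
#'   `start` (0-based span start) and `length`.
#' @export
mask_span <- function(x, ratio, mask_value = NA_real_) {
  if (ratio <= 0 || ratio >= 1) stop("mask ratio must be in (0, 1)")
  S <- nrow(x)
  L <- as.integer(round(ratio * S))
  if (L < 1L) stop("mask span would be empty")
  start <- sample.int(S - L + 1L, 1L) - 1L
  x[start + seq_len(L), ] <- mask_value
  list(masked = x, start = start, length = L)
}

# Encoder forward over a flat (S*B x F) batch. mask: NULL, or a list with
# per-sample 1-based span starts (vector `start`, scalar `len`); masked
# positions are replaced by the learned mask token after input embedding.
transformer_encode_forward <- function(p, Xflat, S, B, cfg, mask = NULL) {
  E <- linear_forward(Xflat, p$emb)
  mask_rows <- NULL
  if (!is.null(mask)) {
    mask_rows <- as.vector(vapply(seq_len(B), function(b)
      (b - 1L) * S + mask$start[b] + seq_len(mask$len) - 1L,
      integer(mask$len)))
    E[mask_rows, ] <- matrix(p$mask_tok$m, length(mask_rows),
                             cfg$d_model, byrow = TRUE)
  }
  if (cfg$use_positional)
    E <- E + sinusoidal_pe(S, cfg$d_model)[rep(seq_len(S), B), ,
                                           drop = FALSE]
  x <- E
  caches <- vector("list", cfg$n_layers)
  for (li in seq_len(cfg$n_layers)) {
    lp <- p[[paste0("layer", li)]]
    fw <- tf_layer_forward(x, B, cfg$n_heads, lp$attn$Wq, lp$attn$Wk,
                           lp$attn$Wv, lp$attn$Wo, lp$attn$bo, lp$ln1$g,
                           lp$ln1$b, lp$ff1$W, lp$ff1$b, lp$ff2$W,
                           lp$ff2$b, lp$ln2$g, lp$ln2$b)
    fw$x <- x
    caches[[li]] <- fw
    x <- fw$Y
  }
  list(H = x, caches = caches, Xflat = Xflat, mask_rows = mask_rows)
}

transformer_encode_backward <- function(p, enc, dH, S, B, cfg, grads) {
  dx <- dH
  for (li in rev(seq_len(cfg$n_layers))) {
    lp <- p[[paste0("layer", li)]]
    cc <- enc$caches[[li]]
    lname <- paste0("layer", li)
    bw <- tf_layer_backward(cc$x, B, cfg$n_heads, dx, lp$attn$Wq,
                            lp$attn$Wk, lp$attn$Wv, lp$attn$Wo, lp$ln1$g,
                            lp$ln2$g, lp$ff1$W, lp$ff2$W, cc$Q, cc$K,
                            cc$V, cc$P, cc$O, cc$xhat1, cc$inv1, cc$Y1,
                            cc$H1, cc$HR, cc$xhat2, cc$inv2)
    g <- grads[[lname]]
    g$attn$Wq <- g$attn$Wq + bw$dWq; g$attn$Wk <- g$attn$Wk + bw$dWk
    g$attn$Wv <- g$attn$Wv + bw$dWv; g$attn$Wo <- g$attn$Wo + bw$dWo
    g$attn$bo <- g$attn$bo + as.numeric(bw$dbo)
    g$ln1$g <- g$ln1$g + as.numeric(bw$dg1)
    g$ln1$b <- g$ln1$b + as.numeric(bw$dc1)
    g$ff1$W <- g$ff1$W + bw$dW1; g$ff1$b <- g$ff1$b + as.numeric(bw$db1)
    g$ff2$W <- g$ff2$W + bw$dW2; g$ff2$b <- g$ff2$b + as.numeric(bw$db2)
    g$ln2$g <- g$ln2$g + as.numeric(bw$dg2)
    g$ln2$b <- g$ln2$b + as.numeric(bw$dc2)
    grads[[lname]] <- g
    dx <- bw$dX
  }
  # dx is now the gradient on the embedded input E (the fixed sinusoidal
  # position encodings carry no parameters)
  if (!is.null(enc$mask_rows)) {
    grads$mask_tok$m <- grads$mask_tok$m +
      colSums(dx[enc$mask_rows, , drop = FALSE])
    dx[enc$mask_rows, ] <- 0
  }
  be <- linear_backward(dx, enc$Xflat, p$emb)
  grads$emb <- nn_add(grads$emb, be$grads)
  grads
}

slice_rows <- function(S, B, slice_start, slice_len) {
  # time-major stacked rows for the GRU: step t = slice position t, all b
  as.vector(vapply(seq_len(slice_len), function(t)
    (seq_len(B) - 1L) * S + slice_start + t - 1L, integer(B)))
}

# Classification head forward: central slice -> biGRU -> linear.
transformer_cls_forward <- function(p, H, S, B, cfg) {
  slice_start <- (cfg$seq_len - cfg$slice_len) %/% 2L + 1L
  rows <- slice_rows(S, B, slice_start, cfg$slice_len)
  Hs <- H[rows, , drop = FALSE]
  gr <- bigru_forward(Hs, B, p$clsf, p$clsb)
  feat <- cbind(gr$h_last_f, gr$h_last_b)
  logits <- linear_forward(feat, p$cls_out)
  list(logits = logits, gr = gr, feat = feat, rows = rows)
}

transformer_cls_backward <- function(p, cls, dlogits, H, S, B, grads) {
  bo <- linear_backward(dlogits, cls$feat, p$cls_out)
  grads$cls_out <- nn_add(grads$cls_out, bo$grads)
  Hc <- ncol(cls$gr$h_last_f)
  bg <- bigru_backward(cls$gr, NULL,
                       dh_last_f = bo$dX[, seq_len(Hc), drop = FALSE],
                       dh_last_b = bo$dX[, Hc + seq_len(Hc), drop = FALSE])
  grads$clsf <- nn_add(grads$clsf, bg$grads_f)
  grads$clsb <- nn_add(grads$clsb, bg$grads_b)
  dH <- matrix(0, nrow(H), ncol(H))
  dH[cls$rows, ] <- dH[cls$rows, ] + bg$dX
  list(grads = grads, dH = dH)
}

# One co-training batch: masked-span reconstruction pass + unmasked
# classification pass; gradients from both passes accumulate.
transformer_batch <- function(p, Xflat, B, target, cw, cfg, wts) {
  S <- cfg$seq_len
  nf <- ncol(Xflat)
  grads <- nn_zeros_like(p)
  L <- as.integer(round(cfg$mask_ratio * S))
  out <- list()

  if (wts$recon > 0) {
    starts <- sample.int(S - L + 1L, B, replace = TRUE)
    enc_m <- transformer_encode_forward(p, Xflat, S, B, cfg,
                                        mask = list(start = starts, len = L))
    pred <- linear_forward(enc_m$H[enc_m$mask_rows, , drop = FALSE], p$dec)
    truth <- Xflat[enc_m$mask_rows, , drop = FALSE]
    res <- pred - truth
    recon <- sum(res^2) / length(res)
    dpred <- wts$recon * 2 * res / length(res)
    bd <- linear_backward(dpred, enc_m$H[enc_m$mask_rows, , drop = FALSE],
                          p$dec)
    grads$dec <- nn_add(grads$dec, bd$grads)
    dH <- matrix(0, S * B, cfg$d_model)
    dH[enc_m$mask_rows, ] <- bd$dX
    grads <- transformer_encode_backward(p, enc_m, dH, S, B, cfg, grads)
    out$recon <- recon
  } else out$recon <- NA_real_

  if (wts$cls > 0) {
    enc <- transformer_encode_forward(p, Xflat, S, B, cfg, mask = NULL)
    cls <- transformer_cls_forward(p, enc$H, S, B, cfg)
    ce <- softmax_ce_forward(cls$logits, target, cw)
    dlogits <- wts$cls * softmax_ce_backward(ce)
    cb <- transformer_cls_backward(p, cls, dlogits, enc$H, S, B, grads)
    grads <- transformer_encode_backward(p, enc, cb$dH, S, B, cfg, cb$grads)
    out$cls <- ce$loss
  } else out$cls <- NA_real_

  out$grads <- grads
  out$loss <- sum(c(wts$recon * out$recon, wts$cls * out$cls), na.rm = TRUE)
  out
}

#' Fit the masked-span Transformer
#'
#' Each gradient step runs two passes over the batch: a self-supervised
#' pass in which one contiguous span per sequence is replaced by the
#' learned mask token and reconstructed (mean-squared error on the span
#' only), and a supervised pass in which the unmasked sequence is encoded
#' and the central `slice_len` encoded vectors are classified by a
#' bidirectional GRU head against the label of the slice's central sample.
#' Both losses are optimized simultaneously; `two_phase = TRUE` defers
#' classification to the second half of training instead. Training windows
#' are sampled class-balanced exactly as in [fit_rnn_vae()].
#'
#' @param series An `ethogram_series`.
#' @param config A [transformer_config()].
#' @return An object of class `span_transformer` with trained parameters,
#'   label set, per-epoch loss curves and the config.
#' @export
fit_transformer <- function(series, config = transformer_config()) {
  stopifnot(inherits(series, "ethogram_series"))
  n <- nrow(series$features)
  if (n < config$seq_len) stop("series shorter than the sequence length")
  labels <- spec_labels(series$spec)
  target_all <- series_targets(series, labels)
  nf <- ncol(series$features)
  set.seed(config$seed)
  p <- transformer_init_params(config, nf, length(labels))
  cw <- rep(1, length(labels))
  opt <- adam_init(p)
  S <- config$seq_len
  c_off <- (S - config$slice_len) %/% 2L + (config$slice_len - 1L) %/% 2L
  max_start <- n - S + 1L
  samp_w <- window_sampling_weights(target_all, c_off, max_start)
  n_batches <- max(1L, config$windows_per_epoch %/% config$batch_size)
  losses <- matrix(NA_real_, config$epochs, 3L,
                   dimnames = list(NULL, c("total", "recon", "cls")))
  for (epoch in seq_len(config$epochs)) {
    w_cls_e <- if (config$two_phase && epoch <= config$epochs %/% 2L) 0
               else config$w_cls
    wts <- list(recon = 1, cls = w_cls_e)
    acc <- numeric(3L)
    for (bi in seq_len(n_batches)) {
      starts <- sample.int(max_start, config$batch_size, replace = TRUE,
                           prob = samp_w)
      idx <- as.vector(vapply(starts, function(st) st + seq_len(S) - 1L,
                              integer(S)))
      Xflat <- series$features[idx, , drop = FALSE]
      target <- target_all[starts + c_off]
      out <- transformer_batch(p, Xflat, config$batch_size, target, cw,
                               config, wts)
      st <- adam_step(p, out$grads, opt, lr = config$lr)
      p <- st$params; opt <- st$state
      acc <- acc + c(out$loss, out$recon,
                     if (is.na(out$cls)) 0 else out$cls)
    }
    losses[epoch, ] <- acc / n_batches
  }
  structure(list(params = p, config = config, labels = labels,
                 losses = as.data.frame(cbind(epoch = seq_len(config$epochs),
                                              losses)),
                 spec_name = series$spec_name, n_features = nf),
            class = c("span_transformer", "etho_model"))
}

#' Reconstruct a masked span
#'
#' Masks one contiguous span of the input sequence (at the given or a
#' random start), encodes, and predicts the span values only.
#'
#' @param object A fitted `span_transformer`.
#' @param x A `seq_len x F` matrix.
#' @param start Optional 0-based span start; random if `NULL`.
#' @param ... Unused.
#' @return A list with `pred` (`span_len x F`), `truth`, `start` and the
#'   span mean-squared error `mse`.
#' @export
reconstruct <- function(object, ...) UseMethod("reconstruct")

#' @rdname reconstruct
#' @export
reconstruct.span_transformer <- function(object, x, start = NULL, ...) {
  cfg <- object$config
  S <- cfg$seq_len
  stopifnot(nrow(x) == S)
  L <- as.integer(round(cfg$mask_ratio * S))
  if (is.null(start)) start <- sample.int(S - L + 1L, 1L) - 1L
  enc <- transformer_encode_forward(object$params, x, S, 1L, cfg,
                                    mask = list(start = start + 1L, len = L))
  pred <- linear_forward(enc$H[enc$mask_rows, , drop = FALSE],
                         object$params$dec)
  truth <- x[start + seq_len(L), , drop = FALSE]
  list(pred = pred, truth = truth, start = start,
       mse = mean((pred - truth)^2))
}

#' Classify the central slice of a sequence
#'
#' Encodes the full unmasked sequence and classifies the central
#' `slice_len` encoded vectors with the recurrent head.
#'
#' @param object A fitted `span_transformer`.
#' @param x A `seq_len x F` matrix (or flat batch with `B` sequences).
#' @param B Batch size when `x` is a stacked batch.
#' @param ... Unused.
#' @return Row-normalized class probability matrix.
#' @export
classify_slice <- function(object, x, B = 1L, ...) {
  cfg <- object$config
  enc <- transformer_encode_forward(object$params, x, cfg$seq_len, B, cfg)
  cls <- transformer_cls_forward(object$params, enc$H, cfg$seq_len, B, cfg)
  P <- row_softmax(cls$logits)
  colnames(P) <- object$labels
  P
}

#' Per-sample label prediction for a fitted Transformer
#'
#' Slides the sequence at stride 1 so that each sample is the central
#' sample of the classified slice of its sequence; boundary samples use
#' the first/last valid sequence. Deterministic in evaluation.
#'
#' @param object A fitted `span_transformer`.
#' @param newdata An `ethogram_series` or feature matrix.
#' @param type `"class"` or `"prob"`.
#' @param batch Sequences per forward batch.
#' @param ... Unused.
#' @return Character labels (length = series length) or probability matrix.
#' @export
predict.span_transformer <- function(object, newdata,
                                     type = c("class", "prob"),
                                     batch = 512L, ...) {
  type <- match.arg(type)
  features <- if (inherits(newdata, "ethogram_series")) newdata$features
              else as.matrix(newdata)
  n <- nrow(features)
  cfg <- object$config
  S <- cfg$seq_len
  if (n < S) stop("series shorter than the sequence length")
  c_off <- (S - cfg$slice_len) %/% 2L + (cfg$slice_len - 1L) %/% 2L
  p <- object$params
  predict_fn <- function(starts) {
    B <- length(starts)
    idx <- as.vector(vapply(starts, function(st) st + seq_len(S) - 1L,
                            integer(S)))
    Xflat <- features[idx, , drop = FALSE]
    enc <- transformer_encode_forward(p, Xflat, S, B, cfg)
    cls <- transformer_cls_forward(p, enc$H, S, B, cfg)
    row_softmax(cls$logits)
  }
  c_off_pred <- c_off
  starts <- pmin(pmax(seq_len(n) - c_off_pred, 1L), n - S + 1L)
  probs <- matrix(NA_real_, n, length(object$labels))
  for (i0 in seq(1L, n, by = batch)) {
    ii <- i0:min(n, i0 + batch - 1L)
    probs[ii, ] <- predict_fn(starts[ii])
  }
  colnames(probs) <- object$labels
  if (type == "prob") probs
  else object$labels[max.col(probs, ties.method = "first")]
}

#' @export
print.span_transformer <- function(x, ...) {
  cfg <- x$config
  cat("Masked-span Transformer:", cfg$n_layers, "layers x", cfg$n_heads,
      "heads, d_model", cfg$d_model, ", seq", cfg$seq_len, ", mask ratio",
      cfg$mask_ratio, "\n")
  cat("  trained", cfg$epochs, "epochs on '", x$spec_name,
      "'; final losses:\n", sep = "")
  print(round(x$losses[nrow(x$losses), -1L], 4))
  invisible(x)
}

#' @export
summary.span_transformer <- function(object, ...) {
  cat("Classes:", paste(object$labels, collapse = ", "), "\n")
  print(round(object$losses[unique(c(1L, nrow(object$losses) %/% 2L,
                                     nrow(object$losses))), ], 4))
  invisible(object)
}

#' @export
coef.span_transformer <- function(object, ...) object$params

#' @export
plot.span_transformer <- function(x, ...) {
  l <- x$losses
  graphics::matplot(l$epoch, l[, c("total", "recon", "cls")], type = "l",
                    lty = 1, lwd = 2, xlab = "epoch", ylab = "loss", ...)
  graphics::legend("topright", c("total", "recon", "cls"), col = 1:3,
                   lty = 1, lwd = 2)
  invisible(x)
}
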