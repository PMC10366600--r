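# Supervised recurrent variational auto-encoder: a two-layer bidirectional
# GRU encoder over short windows, a diagonal-Gaussian variational
# bottleneck, a one-layer GRU decoder, a spectral motif-clustering
# regularizer and a linear motif -> class head whose cross-entropy weight is
# ramped up during training.

#' Configuration for the recurrent VAE
#'
#' @param T Window length in samples. The default of 12 corresponds to a
#'   0.5 s window at 25 frames per second, the native resolution the window
#'   length was designed for; artificial series carry no frame rate, so the
#'   sample count is what is held fixed.
#' @param d Embedding size (6 for one-feature data; 30 is the keypoint
#'   configuration for 14 features).
#' @param h_enc Encoder GRU hidden size per direction (two bidirectional
#'   layers).
#' @param h_dec Decoder GRU hidden size.
#' @param n_motifs Width of the motif soft-assignment layer.
#' @param w_recon,w_kl,w_cluster,w_cls Loss weights for reconstruction, KL,
#'   motif-clustering and classification terms.
#' @param kl_warmup Fraction of epochs over which the KL weight ramps
#'   linearly from 0 to `w_kl`.
#' @param ramp_frac Fraction of epochs over which the classification weight
#'   ramps linearly from 0 to `w_cls`; it stays at `w_cls` afterwards.
#' @param lr Adam learning rate. After two thirds of the epochs the rate
#'   drops to `lr_decay * lr`, a plain step schedule that settles the
#'   embedding before the classification ramp finishes.
#' @param lr_decay Late-training learning-rate factor.
#' @param head_lr_mult Learning-rate multiplier for the motif/class head
#'   (`cls1`, `cls2`). The double-softmax head passes gradients attenuated
#'   by roughly the motif count at initialization; a faster head keeps
#'   every class routed to its own motif region at short training budgets.
#' @param epochs Training epochs.
#' @param batch_size Windows per gradient step.
#' @param windows_per_epoch Training windows sampled per epoch.
#' @param seed Seed for initialization, window sampling and reparameterized
#'   draws.
#' @return A list of class `vae_config`.
#' @export
vae_config <- function(T = 12L, d = 6L, h_enc = 64L, h_dec = 32L,
                       n_motifs = 30L, w_recon = 1, w_kl = 0.02,
                       w_cluster = 0.01, w_cls = 1, kl_warmup = 0.25,
                       ramp_frac = 0.5, lr = 3e-3, lr_decay = 1,
                       epochs = 30L, batch_size = 60L,
                       windows_per_epoch = 2220L, head_lr_mult = 15,
                       seed = 1L) {
  stopifnot(T >= 2L, d >= 1L, n_motifs >= 2L)
  structure(list(T = as.integer(T), d = as.integer(d),
                 h_enc = as.integer(h_enc), h_dec = as.integer(h_dec),
                 n_motifs = as.integer(n_motifs), w_recon = w_recon,
                 w_kl = w_kl, w_cluster = w_cluster, w_cls = w_cls,
                 kl_warmup = kl_warmup, ramp_frac = ramp_frac, lr = lr,
                 lr_decay = lr_decay, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 windows_per_epoch = as.integer(windows_per_epoch),
                 head_lr_mult = head_lr_mult, seed = as.integer(seed)),
            class = "vae_config")
}

vae_init_params <- function(cfg, n_features, n_classes) {
  H <- cfg$h_enc
  list(enc1f = gru_init(n_features, H), enc1b = gru_init(n_features, H),
       enc2f = gru_init(2L * H, H), enc2b = gru_init(2L * H, H),
       mu = init_linear(4L * H, cfg$d), lv = init_linear(4L * H, cfg$d),
       dec = gru_init(cfg$d, cfg$h_dec),
       dec_out = init_linear(cfg$h_dec, n_features),
       cls1 = init_linear(cfg$d, cfg$n_motifs),
       cls2 = init_linear(cfg$n_motifs, n_classes))
}

# Extract windows starting at `starts` (1-based) as one time-major stacked
# (T*B x F) matrix (row block t = the batch at step t).
window_big <- function(features, starts, T) {
  idx <- as.vector(outer(starts, seq_len(T) - 1L, `+`))
  features[idx, , drop = FALSE]
}

# Encoder forward: windows -> concatenated final hidden states of both
# layers and directions (4 * h_enc) -> (mu, log-variance).
vae_encode_forward <- function(p, Xbig, B) {
  l1 <- bigru_forward(Xbig, B, p$enc1f, p$enc1b)
  l2 <- bigru_forward(l1$Hbig, B, p$enc2f, p$enc2b)
  Hcat <- cbind(l1$h_last_f, l1$h_last_b, l2$h_last_f, l2$h_last_b)
  mu <- linear_forward(Hcat, p$mu)
  lv <- pmin(pmax(linear_forward(Hcat, p$lv), -8), 8)
  list(l1 = l1, l2 = l2, Hcat = Hcat, mu = mu, lv = lv)
}

# Backward through the encoder given gradients on mu and lv.
vae_encode_backward <- function(p, enc, dmu, dlv, grads) {
  bmu <- linear_backward(dmu, enc$Hcat, p$mu)
  blv <- linear_backward(dlv, enc$Hcat, p$lv)
  grads$mu <- nn_add(grads$mu, bmu$grads)
  grads$lv <- nn_add(grads$lv, blv$grads)
  dH <- bmu$dX + blv$dX
  H <- ncol(enc$l1$h_last_f)
  i1 <- seq_len(H)
  b2 <- bigru_backward(enc$l2, dHbig = NULL,
                       dh_last_f = dH[, 2L * H + i1, drop = FALSE],
                       dh_last_b = dH[, 3L * H + i1, drop = FALSE])
  grads$enc2f <- nn_add(grads$enc2f, b2$grads_f)
  grads$enc2b <- nn_add(grads$enc2b, b2$grads_b)
  b1 <- bigru_backward(enc$l1, dHbig = b2$dX,
                       dh_last_f = dH[, i1, drop = FALSE],
                       dh_last_b = dH[, H + i1, drop = FALSE])
  grads$enc1f <- nn_add(grads$enc1f, b1$grads_f)
  grads$enc1b <- nn_add(grads$enc1b, b1$grads_b)
  grads
}

#' Motif-clustering regularizer
#'
#' The spectral term that encourages the batch embedding matrix to be
#' cluster-friendly: the sum of the smallest `min(batch, d) - k_eff`
#' singular values of the centered batch embedding matrix, with
#' `k_eff = min(n_motifs, d)`. It is non-negative and exactly zero when the
#' embedding rank is at most `k_eff`; when the embedding dimension does not
#' exceed the motif count (as in the one-feature configuration, d = 6 vs
#' 30 motifs) the rank target is vacuous and the term vanishes identically.
#'
#' @param E Batch embedding matrix (batch by d).
#' @param n_motifs Motif count.
#' @return Scalar loss. With a batch smaller than `n_motifs` the term is
#'   skipped (returns 0 with a warning), matching training behavior.
#' @export
cluster_loss <- function(E, n_motifs) {
  if (nrow(E) < n_motifs) {
    warning("batch smaller than n_motifs; cluster loss skipped")
    return(0)
  }
  cl <- cluster_loss_grad(E, n_motifs)
  cl$loss
}

cluster_loss_grad <- function(E, n_motifs) {
  B <- nrow(E); d <- ncol(E)
  k_eff <- min(n_motifs, d)
  r <- min(B, d)
  if (r - k_eff <= 0L || B < n_motifs)
    return(list(loss = 0, dE = matrix(0, B, d)))
  Ec <- sweep(E, 2L, colMeans(E))
  sv <- svd(Ec)
  idx <- (k_eff + 1L):r
  dEc <- sv$u[, idx, drop = FALSE] %*% t(sv$v[, idx, drop = FALSE])
  dE <- sweep(dEc, 2L, colMeans(dEc))
  list(loss = sum(sv$d[idx]), dE = dE)
}

# One training batch: forward all heads, combine weighted losses, backprop.
vae_batch <- function(p, Xbig, B, target, cw, cfg, wts, n_classes,
                      train = TRUE) {
  Tn <- nrow(Xbig) %/% B
  nf <- ncol(Xbig)
  grads <- nn_zeros_like(p)

  enc <- vae_encode_forward(p, Xbig, B)
  if (train) {
    eps <- matrix(stats::rnorm(B * cfg$d), B, cfg$d)
    z <- enc$mu + exp(0.5 * enc$lv) * eps
  } else {
    eps <- NULL
    z <- enc$mu
  }

  # decoder: z fed as input at every step
  Zbig <- z[rep(seq_len(B), Tn), , drop = FALSE]
  dec <- gru_forward(Zbig, B, p$dec)
  Yhat <- linear_forward(dec$Hbig, p$dec_out)
  res <- Yhat - Xbig
  recon <- sum(res^2) / (B * Tn * nf)

  kl <- sum(0.5 * (enc$mu^2 + exp(enc$lv) - enc$lv - 1)) / B

  clu <- cluster_loss_grad(z, cfg$n_motifs)

  A1 <- linear_forward(z, p$cls1)
  M <- row_softmax(A1)
  logits <- linear_forward(M, p$cls2)
  ce <- softmax_ce_forward(logits, target, cw)

  total <- wts$recon * recon + wts$kl * kl + wts$cluster * clu$loss +
    wts$cls * ce$loss

  # ---- backward ----
  dz <- matrix(0, B, cfg$d)
  # reconstruction
  dY <- wts$recon * 2 * res / (B * Tn * nf)
  bo <- linear_backward(dY, dec$Hbig, p$dec_out)
  grads$dec_out <- nn_add(grads$dec_out, bo$grads)
  bdec <- gru_backward(dec, bo$dX, NULL)
  grads$dec <- nn_add(grads$dec, bdec$grads)
  dz <- dz + rowsum(bdec$dX, rep(seq_len(B), Tn))
  # classification
  dlogits <- wts$cls * softmax_ce_backward(ce)
  b2 <- linear_backward(dlogits, M, p$cls2)
  grads$cls2 <- nn_add(grads$cls2, b2$grads)
  dA1 <- M * (b2$dX - rowSums(b2$dX * M))
  b1 <- linear_backward(dA1, z, p$cls1)
  grads$cls1 <- nn_add(grads$cls1, b1$grads)
  dz <- dz + b1$dX
  # cluster
  dz <- dz + wts$cluster * clu$dE
  # KL on mu, lv directly
  dmu <- wts$kl * enc$mu / B
  dlv <- wts$kl * 0.5 * (exp(enc$lv) - 1) / B
  # reparameterization
  if (train) {
    dmu <- dmu + dz
    dlv <- dlv + dz * eps * 0.5 * exp(0.5 * enc$lv)
  } else {
    dmu <- dmu + dz
  }
  dlv[enc$lv <= -8 | enc$lv >= 8] <- 0
  grads <- vae_encode_backward(p, enc, dmu, dlv, grads)

  list(loss = total, recon = recon, kl = kl, cluster = clu$loss,
       cls = ce$loss, grads = grads, P = ce$P)
}

series_targets <- function(series, labels) {
  idx <- match(series$behavior, labels)
  if (anyNA(idx)) stop("series contains labels outside the model's label set")
  idx
}

#' Fit the supervised recurrent VAE
#'
#' Trains on randomly positioned windows of length `config$T`; each
#' window's supervision target is the behavior label of its center sample
#' (the transition label is a class like any other). The total loss is
#' `w_recon * MSE + w_kl(epoch) * KL + w_cluster * cluster +
#' ramp(epoch) * w_cls * weighted cross-entropy`, with the classification
#' ramp rising linearly from 0 to 1 over the first `ramp_frac` of epochs.
#' Class weights are inverse square-root frequency so one-sample point
#' events stay visible. Training is deterministic given `config$seed`.
#'
#' @param series An `ethogram_series` with behavior labels.
#' @param config A [vae_config()].
#' @return An object of class `rnn_vae` with the trained parameters, the
#'   label set, per-epoch loss curves (`$losses`) and the config.
#' @seealso [predict.rnn_vae()], [encode()], [decode()], [cluster_loss()]
#' @export
fit_rnn_vae <- function(series, config = vae_config()) {
  stopifnot(inherits(series, "ethogram_series"))
  if (is.null(series$behavior)) stop("series carries no behavior labels")
  n <- nrow(series$features)
  if (n < config$T) stop("series shorter than the window length")
  labels <- spec_labels(series$spec)
  target_all <- series_targets(series, labels)
  nf <- ncol(series$features)
  set.seed(config$seed)
  p <- vae_init_params(config, nf, length(labels))
  cw <- rep(1, length(labels))
  opt <- adam_init(p)
  c_off <- config$T %/% 2L
  max_start <- n - config$T + 1L
  samp_w <- window_sampling_weights(target_all, c_off, max_start)
  n_batches <- max(1L, config$windows_per_epoch %/% config$batch_size)
  ramp_end <- max(1L, ceiling(config$epochs * config$ramp_frac))
  warm_end <- max(1L, ceiling(config$epochs * config$kl_warmup))
  losses <- matrix(NA_real_, config$epochs, 5L,
                   dimnames = list(NULL, c("total", "recon", "kl",
                                           "cluster", "cls")))
  for (epoch in seq_len(config$epochs)) {
    lr_e <- config$lr *
      if (epoch > ceiling(2 * config$epochs / 3)) config$lr_decay else 1
    ramp <- if (ramp_end == 1L) 1 else min(1, (epoch - 1) / (ramp_end - 1))
    warm <- min(1, epoch / warm_end)
    wts <- list(recon = config$w_recon, kl = config$w_kl * warm,
                cluster = config$w_cluster, cls = config$w_cls * ramp)
    acc <- numeric(5L)
    for (bi in seq_len(n_batches)) {
      starts <- sample.int(max_start, config$batch_size, replace = TRUE,
                           prob = samp_w)
      X <- window_big(series$features, starts, config$T)
      target <- target_all[starts + c_off]
      out <- vae_batch(p, X, config$batch_size, target, cw, config, wts,
                       length(labels))
      st <- adam_step(p, out$grads, opt, lr = lr_e,
                      lr_mult = list(cls1 = config$head_lr_mult,
                                     cls2 = config$head_lr_mult))
      p <- st$params; opt <- st$state
      acc <- acc + c(out$loss, out$recon, out$kl, out$cluster, out$cls)
    }
    losses[epoch, ] <- acc / n_batches
  }
  structure(list(params = p, config = config, labels = labels,
                 class_weights = cw,
                 losses = as.data.frame(cbind(epoch = seq_len(config$epochs),
                                              losses)),
                 spec_name = series$spec_name, n_features = nf),
            class = c("rnn_vae", "etho_model"))
}

#' Encode windows into the variational embedding
#'
#' @param object A fitted `rnn_vae`.
#' @param windows A `T x F` matrix or a list of windows.
#' @param sample Draw `z` by reparameterization (training behavior)? At
#'   evaluation the embedding is deterministic, `z = mu`.
#' @param ... Unused.
#' @return A list with matrices `mu`, `sigma` and `z` (one row per window).
#' @export
encode <- function(object, ...) UseMethod("encode")

#' @rdname encode
#' @export
encode.rnn_vae <- function(object, windows, sample = FALSE, ...) {
  if (is.matrix(windows)) windows <- list(windows)
  Tn <- object$config$T
  stopifnot(all(vapply(windows, nrow, integer(1)) == Tn))
  B <- length(windows)
  Xbig <- do.call(rbind, lapply(seq_len(Tn), function(t)
    do.call(rbind, lapply(windows, function(w) w[t, , drop = FALSE]))))
  enc <- vae_encode_forward(object$params, Xbig, B)
  sigma <- exp(0.5 * enc$lv)
  z <- if (sample) enc$mu + sigma * matrix(stats::rnorm(B * ncol(sigma)),
                                           B) else enc$mu
  list(mu = enc$mu, sigma = sigma, z = z)
}

#' Decode embeddings back to windows
#'
#' @param object A fitted `rnn_vae`.
#' @param z Embedding vector of length `d` or a matrix (rows = embeddings).
#' @param ... Unused.
#' @return A `T x F` matrix for a single embedding, else a list of them.
#' @export
decode <- function(object, ...) UseMethod("decode")

#' @rdname decode
#' @export
decode.rnn_vae <- function(object, z, ...) {
  single <- is.null(dim(z))
  if (single) z <- matrix(z, 1L)
  stopifnot(ncol(z) == object$config$d)
  Tn <- object$config$T
  B <- nrow(z)
  dec <- gru_forward(z[rep(seq_len(B), Tn), , drop = FALSE], B,
                     object$params$dec)
  Y <- linear_forward(dec$Hbig, object$params$dec_out)
  out <- lapply(seq_len(B), function(b)
    Y[b + (seq_len(Tn) - 1L) * B, , drop = FALSE])
  if (single) out[[1L]] else out
}

#' Classify embeddings through the motif layer
#'
#' Soft motif assignment followed by a linear class map; both are part of
#' the jointly trained model.
#'
#' @param object A fitted `rnn_vae`.
#' @param z Embedding matrix (rows = embeddings).
#' @param motifs Also return the motif soft assignment?
#' @return Row-normalized class probability matrix, or a list with `probs`
#'   and `motifs`.
#' @export
classify <- function(object, ...) UseMethod("classify")

#' @rdname classify
#' @export
classify.rnn_vae <- function(object, z, motifs = FALSE, ...) {
  if (is.null(dim(z))) z <- matrix(z, 1L)
  M <- row_softmax(linear_forward(z, object$params$cls1))
  P <- row_softmax(linear_forward(M, object$params$cls2))
  colnames(P) <- object$labels
  if (motifs) list(probs = P, motifs = M) else P
}

# Shared per-sample sliding-window prediction: sample i is predicted from
# the window whose center is i; boundary samples use the first/last valid
# window. predict_fn(starts) must return a B x C probability matrix.
predict_sliding <- function(n, T, labels, predict_fn, batch = 512L,
                            type = "class") {
  c_off <- T %/% 2L
  starts <- pmin(pmax(seq_len(n) - c_off, 1L), n - T + 1L)
  probs <- matrix(NA_real_, n, length(labels))
  for (i0 in seq(1L, n, by = batch)) {
    idx <- i0:min(n, i0 + batch - 1L)
    probs[idx, ] <- predict_fn(starts[idx])
  }
  colnames(probs) <- labels
  if (type == "prob") probs else labels[max.col(probs, ties.method = "first")]
}

#' Per-sample label prediction for a fitted VAE
#'
#' Slides the window at stride 1; each sample is predicted from the window
#' centered on it, with clamped windows at the series boundaries, so the
#' output has exactly one label per sample. Evaluation is deterministic
#' (`z = mu`).
#'
#' @param object A fitted `rnn_vae`.
#' @param newdata An `ethogram_series` (or feature matrix).
#' @param type `"class"` for labels, `"prob"` for the probability matrix.
#' @param batch Windows per forward batch.
#' @param ... Unused.
#' @return Character vector of length `nrow(features)`, or a probability
#'   matrix.
#' @export
predict.rnn_vae <- function(object, newdata, type = c("class", "prob"),
                            batch = 512L, ...) {
  type <- match.arg(type)
  features <- if (inherits(newdata, "ethogram_series")) newdata$features
              else as.matrix(newdata)
  n <- nrow(features)
  Tn <- object$config$T
  if (n < Tn) stop("series shorter than the window length")
  p <- object$params
  predict_fn <- function(starts) {
    X <- window_big(features, starts, Tn)
    enc <- vae_encode_forward(p, X, length(starts))
    M <- row_softmax(linear_forward(enc$mu, p$cls1))
    row_softmax(linear_forward(M, p$cls2))
  }
  predict_sliding(n, Tn, object$labels, predict_fn, batch, type)
}

#' @export
print.rnn_vae <- function(x, ...) {
  cat("Recurrent VAE (supervised): T =", x$config$T, ", d =", x$config$d,
      ", motifs =", x$config$n_motifs, "\n")
  cat("  trained", x$config$epochs, "epochs on '", x$spec_name,
      "'; final losses:\n", sep = "")
  print(round(x$losses[nrow(x$losses), -1L], 4))
  invisible(x)
}

#' @export
summary.rnn_vae <- function(object, ...) {
  cat("Classes:", paste(object$labels, collapse = ", "), "\n")
  cat("Loss curves over", nrow(object$losses), "epochs:\n")
  print(round(object$losses[unique(c(1L, nrow(object$losses) %/% 2L,
                                     nrow(object$losses))), ], 4))
  invisible(object)
}

#' @export
coef.rnn_vae <- function(object, ...) object$params

#' @export
plot.rnn_vae <- function(x, ...) {
  l <- x$losses
  graphics::matplot(l$epoch, l[, c("total", "recon", "kl", "cls")],
                    type = "l", lty = 1, lwd = 2, xlab = "epoch",
                    ylab = "loss", ...)
  graphics::legend("topright", c("total", "recon", "kl", "cls"),
                   col = 1:4, lty = 1, lwd = 2)
  invisible(x)
}
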