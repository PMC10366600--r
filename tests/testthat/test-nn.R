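# Finite-difference verification of every hand-written backward pass.
# The checks use tiny shapes; agreement to ~1e-6 over random coordinates
# certifies the analytic gradients used everywhere else.

numgrad_max_err <- function(lossf, params, grads, paths, k = 8L,
                            eps = 1e-6) {
  maxerr <- 0
  for (pt in paths) {
    getp <- function(p) Reduce(`[[`, pt, p)
    g <- getp(params)
    ga <- getp(grads)
    for (i in sample(seq_along(g), min(k, length(g)))) {
      p1 <- params; p2 <- params
      expr <- paste0("p", paste0("[['", pt, "']]", collapse = ""))
      v1 <- g; v1[i] <- g[i] + eps
      v2 <- g; v2[i] <- g[i] - eps
      p1 <- assign_path(p1, pt, v1)
      p2 <- assign_path(p2, pt, v2)
      num <- (lossf(p1) - lossf(p2)) / (2 * eps)
      maxerr <- max(maxerr, abs(num - ga[i]))
    }
  }
  maxerr
}

assign_path <- function(p, pt, value) {
  if (length(pt) == 1L) { p[[pt]] <- value; return(p) }
  p[[pt[1L]]] <- assign_path(p[[pt[1L]]], pt[-1L], value)
  p
}

test_that("GRU backward matches finite differences", {
  set.seed(1)
  B <- 3L; Tn <- 5L; nin <- 2L; H <- 4L
  X <- matrix(rnorm(Tn * B * nin), Tn * B, nin)
  p <- ethosim:::gru_init(nin, H)
  lossf <- function(p) {
    fw <- ethosim:::gru_forward(X, B, p)
    sum(fw$h_last^2) / 2 + 0.1 * sum(fw$Hbig)
  }
  fw <- ethosim:::gru_forward(X, B, p)
  bw <- ethosim:::gru_backward(fw, matrix(0.1, Tn * B, H), fw$h_last)
  err <- numgrad_max_err(lossf, p, bw$grads,
                         list("Wx", "Wh", "bx", "bh"))
  expect_lt(err, 1e-6)
})

test_that("bidirectional GRU concatenates forward and reversed streams", {
  set.seed(2)
  B <- 2L; Tn <- 4L; H <- 3L
  X <- matrix(rnorm(Tn * B), Tn * B, 1L)
  pf <- ethosim:::gru_init(1L, H); pb <- ethosim:::gru_init(1L, H)
  bi <- ethosim:::bigru_forward(X, B, pf, pb)
  fwd <- ethosim:::gru_forward(X, B, pf)
  bwd <- ethosim:::gru_forward(ethosim:::reverse_time(X, B), B, pb)
  expect_equal(bi$Hbig[, 1:H], fwd$Hbig)
  expect_equal(bi$Hbig[1:B, H + 1:H],
               bwd$Hbig[(Tn - 1L) * B + 1:B, ])
  expect_equal(bi$h_last_f, fwd$h_last)
})

test_that("full VAE batch loss gradients match finite differences", {
  set.seed(3)
  cfg <- vae_config(T = 5L, d = 3L, h_enc = 4L, h_dec = 3L, n_motifs = 2L,
                    batch_size = 6L, seed = 1L)
  B <- 6L
  p <- ethosim:::vae_init_params(cfg, 1L, 4L)
  X <- matrix(rnorm(cfg$T * B), cfg$T * B, 1L)
  target <- sample.int(4L, B, replace = TRUE)
  wts <- list(recon = 1, kl = 0.1, cluster = 0.05, cls = 0.7)
  lossf <- function(p) {
    set.seed(99)
    ethosim:::vae_batch(p, X, B, target, rep(1, 4), cfg, wts, 4L)$loss
  }
  set.seed(99)
  out <- ethosim:::vae_batch(p, X, B, target, rep(1, 4), cfg, wts, 4L)
  err <- numgrad_max_err(lossf, p, out$grads,
                         list(c("enc1f", "Wx"), c("enc1b", "Wh"),
                              c("enc2f", "Wx"), c("enc2b", "bh"),
                              c("mu", "W"), c("lv", "W"), c("dec", "Wh"),
                              c("dec_out", "W"), c("cls1", "W"),
                              c("cls2", "b")))
  expect_lt(err, 1e-6)
})

test_that("full Transformer batch loss gradients match finite differences", {
  set.seed(4)
  cfg <- transformer_config(n_layers = 2L, n_heads = 2L, d_model = 8L,
                            ff_hidden = 10L, seq_len = 7L,
                            mask_ratio = 0.45, slice_len = 3L,
                            cls_hidden = 4L, batch_size = 4L, seed = 1L)
  B <- 4L
  p <- ethosim:::transformer_init_params(cfg, 1L, 3L)
  X <- matrix(rnorm(cfg$seq_len * B), cfg$seq_len * B, 1L)
  target <- sample.int(3L, B, replace = TRUE)
  wts <- list(recon = 1, cls = 0.8)
  lossf <- function(p) {
    set.seed(42)
    ethosim:::transformer_batch(p, X, B, target, rep(1, 3), cfg, wts)$loss
  }
  set.seed(42)
  out <- ethosim:::transformer_batch(p, X, B, target, rep(1, 3), cfg, wts)
  err <- numgrad_max_err(lossf, p, out$grads,
                         list(c("emb", "W"), c("mask_tok", "m"),
                              c("dec", "W"), c("clsf", "Wx"),
                              c("clsb", "Wh"), c("cls_out", "W"),
                              c("layer1", "attn", "Wq"),
                              c("layer1", "attn", "Wo"),
                              c("layer1", "ln1", "g"),
                              c("layer2", "ff1", "W"),
                              c("layer2", "ff2", "b"),
                              c("layer2", "ln2", "b")))
  expect_lt(err, 1e-6)
})

test_that("Adam minimizes a quadratic and respects per-subtree multipliers", {
  p <- list(a = c(2, -3), head = list(W = matrix(2, 1, 1)))
  st <- ethosim:::adam_init(p)
  for (i in 1:400) {
    g <- list(a = p$a, head = list(W = p$head$W))
    up <- ethosim:::adam_step(p, g, st, lr = 0.05,
                              lr_mult = list(head = 2))
    p <- up$params; st <- up$state
  }
  expect_lt(max(abs(p$a)), 1e-2)
  expect_lt(abs(p$head$W), 1e-2)
})
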