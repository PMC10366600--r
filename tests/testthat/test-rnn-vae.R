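test_that("encoder produces d-dimensional embeddings from concatenated hidden states", {
  s <- generate_dataset(flat_spec(noise = 0.05, spread = 0.1), 60L, seed = 1)
  m <- fit_rnn_vae(s, tiny_vae_cfg(epochs = 1L))
  # projection input is 2 layers x 2 directions x h_enc
  expect_identical(nrow(m$params$mu$W), 4L * m$config$h_enc)
  w <- s$features[1:8, , drop = FALSE]
  e <- encode(m, w)
  expect_identical(dim(e$mu), c(1L, m$config$d))
  expect_true(all(e$sigma > 0))
  # evaluation embedding is deterministic: z = mu
  e2 <- encode(m, w)
  expect_identical(e$z, e2$z)
  expect_identical(e$z, e$mu)
  # default configuration carries the published sizes
  dflt <- vae_config()
  expect_identical(c(dflt$h_enc, dflt$h_dec, dflt$d, dflt$n_motifs),
                   c(64L, 32L, 6L, 30L))
})

test_that("decoder maps embeddings to full windows and stays finite untrained", {
  s <- generate_dataset(flat_spec(noise = 0.05, spread = 0.1), 60L, seed = 1)
  m <- fit_rnn_vae(s, tiny_vae_cfg(epochs = 1L))
  y <- decode(m, numeric(m$config$d))
  expect_identical(dim(y), c(m$config$T, 1L))
  expect_true(all(is.finite(y)))
})

test_that("cluster regularizer is zero at low rank and equals the SVD tail sum", {
  set.seed(10)
  # embeddings on exactly 4 distinct points: rank <= 4 = n_motifs -> 0
  pts <- matrix(rnorm(4 * 6), 4, 6)
  E <- pts[sample.int(4L, 64L, replace = TRUE), ]
  expect_equal(cluster_loss(E, 4L), 0)
  # full-rank random embeddings: positive, equal to the brute-force tail
  E2 <- matrix(rnorm(64 * 6), 64, 6)
  cl <- cluster_loss(E2, 4L)
  expect_gt(cl, 0)
  sv <- svd(scale(E2, scale = FALSE))$d
  expect_equal(cl, sum(sv[5:6]))
  # batches smaller than the motif count are skipped with a warning
  expect_warning(z <- cluster_loss(E2[1:3, ], 4L), "skipped")
  expect_equal(z, 0)
})

test_that("KL term is the closed-form diagonal-Gaussian divergence and non-negative", {
  set.seed(11)
  cfg <- tiny_vae_cfg()
  p <- ethosim:::vae_init_params(cfg, 1L, 3L)
  B <- 24L
  X <- matrix(rnorm(cfg$T * B), cfg$T * B, 1L)
  out <- ethosim:::vae_batch(p, X, B, sample.int(3L, B, replace = TRUE),
                             rep(1, 3), cfg,
                             list(recon = 1, kl = 1, cluster = 0, cls = 0),
                             3L)
  expect_gte(out$kl, 0)
  enc <- ethosim:::vae_encode_forward(p, X, B)
  kl_direct <- sum(0.5 * (enc$mu^2 + exp(enc$lv) - enc$lv - 1)) / B
  expect_equal(out$kl, kl_direct)
})

test_that("classifier outputs a normalized distribution through the motif layer", {
  s <- generate_dataset(flat_spec(noise = 0.05, spread = 0.1), 60L, seed = 1)
  m <- fit_rnn_vae(s, tiny_vae_cfg(epochs = 1L))
  z <- matrix(rnorm(5 * m$config$d), 5)
  out <- classify(m, z, motifs = TRUE)
  expect_equal(rowSums(out$probs), rep(1, 5))
  expect_identical(ncol(out$motifs), m$config$n_motifs)
  expect_equal(rowSums(out$motifs), rep(1, 5))
})

test_that("training ramps classification in, reduces the loss, and is reproducible", {
  s <- generate_dataset(flat_spec(noise = 0.05, spread = 0.1), 100L,
                        seed = 3)
  cfg <- tiny_vae_cfg(epochs = 6L)
  m <- fit_rnn_vae(s, cfg)
  expect_lt(m$losses$total[6L], m$losses$total[1L])
  m2 <- fit_rnn_vae(s, cfg)
  expect_identical(m$params, m2$params)
  # w_cls = 0: the classification head receives no gradient at all
  cfg0 <- tiny_vae_cfg(epochs = 2L, w_cls = 0)
  m0 <- fit_rnn_vae(s, cfg0)
  set.seed(cfg0$seed)
  p_init <- ethosim:::vae_init_params(cfg0, 1L,
                                      length(spec_labels(s$spec)))
  expect_identical(m0$params$cls1, p_init$cls1)
  expect_identical(m0$params$cls2, p_init$cls2)
  expect_false(identical(m0$params$enc1f, p_init$enc1f))
})

test_that("a constant series is reconstructed to the noise floor", {
  # both behaviors share one near-degenerate pose: the series is constant
  # up to ~1e-2 noise, so reconstruction error must approach zero
  sp <- ethogram_spec(list(
    behavior_atomic("bA", state_constituent(key_pose("pA", 0.5, 1e-4),
                                            dur_gamma(15))),
    behavior_atomic("bB", state_constituent(key_pose("pB", 0.5, 1e-4),
                                            dur_gamma(15)))),
    noise_sigma = 0.01, name = "const")
  s <- generate_dataset(sp, 100L, seed = 4)
  m <- fit_rnn_vae(s, tiny_vae_cfg(epochs = 15L,
                                   windows_per_epoch = 480L))
  expect_lt(tail(m$losses$recon, 1L), 1e-2)
})

test_that("a near-noiseless two-pose series is learned to high accuracy", {
  s <- generate_dataset(flat_spec(noise = 0.01, spread = 0.01), 150L,
                        seed = 4)
  m <- fit_rnn_vae(s, tiny_vae_cfg(epochs = 25L,
                                   windows_per_epoch = 480L))
  pr <- predict(m, s)
  expect_length(pr, nrow(s$features))
  core <- s$behavior %in% c("bA", "bB")
  expect_gt(mean(pr[core] == s$behavior[core]), 0.9)
  pr2 <- predict(m, s)
  expect_identical(pr, pr2)
  probs <- predict(m, s, type = "prob")
  expect_equal(rowSums(probs), rep(1, nrow(s$features)))
  expect_error(predict(m, s$features[1:3, , drop = FALSE]), "shorter")
})
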