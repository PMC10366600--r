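test_that("mask spans have the exact length, contiguity and uniform placement", {
  set.seed(1)
  x <- matrix(rnorm(20), 20, 1)
  out <- mask_span(x, 0.45)
  expect_identical(out$length, 9L)
  masked <- which(is.na(out$masked[, 1L]))
  expect_identical(masked, out$start + 1:9)
  expect_error(mask_span(x, 1.2), "ratio")
  expect_error(mask_span(x, 0), "ratio")
  # start uniform over the 12 feasible offsets {0..11}
  starts <- vapply(1:10000, function(i) mask_span(x, 0.45)$start,
                   integer(1))
  expect_identical(sort(unique(starts)), 0:11)
  chi <- stats::chisq.test(table(factor(starts, levels = 0:11)))
  expect_gt(chi$p.value, 1e-4)
})

test_that("the classified slice is the central five encoded positions", {
  cfg <- transformer_config()
  slice_start <- (cfg$seq_len - cfg$slice_len) %/% 2L + 1L
  rows <- ethosim:::slice_rows(cfg$seq_len, 1L, slice_start, cfg$slice_len)
  expect_identical(rows, 8:12)  # 0-based positions 7..11
  # published defaults
  expect_identical(c(cfg$n_layers, cfg$n_heads, cfg$ff_hidden,
                     cfg$seq_len, cfg$slice_len, cfg$cls_hidden),
                   c(4L, 4L, 80L, 20L, 5L, 30L))
  expect_equal(cfg$mask_ratio, 0.45)
})

test_that("masked reconstruction scores the span and only the span", {
  s <- generate_dataset(flat_spec(noise = 0.05, spread = 0.1), 80L, seed = 2)
  cfg <- tiny_tf_cfg(epochs = 1L)
  m <- fit_transformer(s, cfg)
  x <- s$features[1:cfg$seq_len, , drop = FALSE]
  set.seed(9)
  rec <- reconstruct(m, x, start = 3L)
  L <- as.integer(round(cfg$mask_ratio * cfg$seq_len))
  expect_identical(dim(rec$pred), c(L, 1L))
  expect_equal(rec$mse, mean((rec$pred - x[3L + 1:L, ])^2))
  # loss targets are local to the span: values outside the span do not
  # enter the scored truth
  x2 <- x
  x2[-(3L + 1:L), ] <- 999
  rec2 <- reconstruct(m, x2, start = 3L)
  expect_identical(rec2$truth, rec$truth)
})

test_that("slice classification yields normalized distributions consistent with predict", {
  s <- generate_dataset(flat_spec(noise = 0.05, spread = 0.1), 80L, seed = 2)
  cfg <- tiny_tf_cfg(epochs = 2L)
  m <- fit_transformer(s, cfg)
  S <- cfg$seq_len
  x <- s$features[1:S, , drop = FALSE]
  P <- classify_slice(m, x)
  expect_equal(sum(P), 1)
  expect_identical(colnames(P), m$labels)
  # the sample at the slice center of the first window gets that window's
  # prediction under predict()
  pr <- predict(m, s)
  c_off <- (S - cfg$slice_len) %/% 2L + (cfg$slice_len - 1L) %/% 2L
  expect_identical(pr[1L + c_off], m$labels[which.max(P)])
  expect_length(pr, nrow(s$features))
  expect_identical(pr, predict(m, s))
})

test_that("co-training reduces the loss and is reproducible; w_cls = 0 is pure pre-training", {
  s <- generate_dataset(flat_spec(noise = 0.05, spread = 0.1), 100L,
                        seed = 3)
  cfg <- tiny_tf_cfg(epochs = 5L)
  m <- fit_transformer(s, cfg)
  expect_lt(m$losses$total[5L], m$losses$total[1L])
  m2 <- fit_transformer(s, cfg)
  expect_identical(m$params, m2$params)
  cfg0 <- tiny_tf_cfg(epochs = 2L, w_cls = 0)
  m0 <- fit_transformer(s, cfg0)
  set.seed(cfg0$seed)
  p_init <- ethosim:::transformer_init_params(cfg0, 1L,
                                              length(m0$labels))
  expect_identical(m0$params$cls_out, p_init$cls_out)
  expect_false(identical(m0$params$layer1, p_init$layer1))
  expect_error(fit_transformer(
    generate_dataset(flat_spec(), 1L, seed = 1) |>
      (\(x) { x$features <- x$features[1:5, , drop = FALSE]
              x$behavior <- x$behavior[1:5]; x })(),
    cfg), "shorter")
})

test_that("masked reconstruction of a periodic signal needs positional information", {
  # pure sinusoid; an order-blind encoder cannot know which phase the
  # masked span covers, so span reconstruction must degrade without
  # positional encodings
  sp <- ethogram_spec(list(
    behavior_atomic("bP", state_constituent(
      key_pose("pP", 0, 1e-6), dur_gamma(60, minimum = 30),
      fluctuation(period = 6, period_amplitude = 1))),
    behavior_atomic("bQ", state_constituent(
      key_pose("pQ", 0, 1e-6), dur_gamma(60, minimum = 30),
      fluctuation(period = 6, period_amplitude = 1)))),
    noise_sigma = 0, name = "periodic")
  s <- generate_dataset(sp, 60L, seed = 6)
  cfg_pos <- tiny_tf_cfg(epochs = 8L, w_cls = 0, lr = 3e-3)
  cfg_nopos <- tiny_tf_cfg(epochs = 8L, w_cls = 0, lr = 3e-3,
                           use_positional = FALSE)
  m_pos <- fit_transformer(s, cfg_pos)
  m_nopos <- fit_transformer(s, cfg_nopos)
  expect_lt(tail(m_pos$losses$recon, 1L),
            0.7 * tail(m_nopos$losses$recon, 1L))
})
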