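# Shared fixtures: tiny configs keep model tests fast; a two-behavior
# constant-pose spec gives a near-deterministic signal for sanity fits.

tiny_vae_cfg <- function(...) {
  args <- list(T = 8L, d = 4L, h_enc = 12L, h_dec = 8L, n_motifs = 6L,
               epochs = 3L, batch_size = 24L, windows_per_epoch = 240L,
               seed = 1L)
  over <- list(...)
  args[names(over)] <- over
  do.call(vae_config, args)
}

tiny_tf_cfg <- function(...) {
  args <- list(n_layers = 2L, n_heads = 2L, d_model = 12L,
               ff_hidden = 16L, seq_len = 12L, slice_len = 3L,
               cls_hidden = 8L, epochs = 3L, batch_size = 24L,
               windows_per_epoch = 240L, seed = 1L)
  over <- list(...)
  args[names(over)] <- over
  do.call(transformer_config, args)
}

# Two well-separated constant-ish behaviors; near-zero scatter and noise.
flat_spec <- function(noise = 0, spread = 1e-6) {
  ethogram_spec(list(
    behavior_atomic("bA", state_constituent(
      key_pose("pA", -1, spread), dur_gamma(15))),
    behavior_atomic("bB", state_constituent(
      key_pose("pB", 1, spread), dur_gamma(15)))),
    noise_sigma = noise, name = "flat")
}

pass_2_of_3 <- function(values, check) sum(vapply(values, check, logical(1))) >= 2L
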