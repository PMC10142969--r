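# Shared miniature fixtures, built in code at test time. Phantom volumes for
# model tests use small scans so the convolutional nets stay desk-scale.

tiny_phantoms <- function(labels, seed_base, n_scans = 6L, height = 24L,
                          width = 32L) {
  lapply(seq_along(labels), function(i)
    generate_oct_volume(
      volume_config(n_scans = n_scans, height = height, width = width,
                    noise_sd = 0.03, fluid_contrast = 0.6,
                    n_fluid_pockets = 4L, seed = seed_base + i),
      has_fluid = labels[i] == 1)$data)
}

tiny_cnn_config <- function(max_epochs, seed, learning_rate = 1e-2, ...) {
  training_config(cnn_type = "resnet2p5d", channels = 4L, n_blocks = 1L,
                  batch_size = 8L, learning_rate = learning_rate,
                  weight_decay = 1e-4, dropout = 0, use_wavelet_input = FALSE,
                  augment = FALSE, max_epochs = max_epochs, seed = seed, ...)
}

# standard-protocol-only cohort with planted covariate effects
planted_cohort <- function(n, seed, effect_age = -0.8,
                           effect_sex_female = -0.4, effect_logcst = 0.8) {
  cfg <- cohort_config(n, short_protocol_prob = 0, second_eye_prob = 0,
                       effect_age = effect_age,
                       effect_sex_female = effect_sex_female,
                       effect_logcst = effect_logcst, seed = seed)
  ch <- generate_synthetic_cohort(cfg)
  ch$protocol <- classify_protocol(ch)
  ch
}

# synthetic per-model score panels with a known quality ordering
score_panel <- function(n, seed, strengths = c(cnn = 2, clinical = 1.2,
                                               fft_lasso = 0)) {
  set.seed(seed)
  y <- rbinom(n, 1, 0.5)
  s <- sapply(strengths, function(b)
    plogis(b * (2 * y - 1) / 2 + rnorm(n)))
  list(scores = as.data.frame(s), labels = y)
}
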