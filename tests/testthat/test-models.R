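test_that("training configuration validates its fields", {
  expect_error(training_config(learning_rate = 0), "learning_rate")
  expect_error(training_config(dropout = 1), "dropout")
  expect_error(training_config(batch_size = 0), "batch_size")
  cfg <- training_config()
  expect_identical(cfg$cnn_type, "resnet2p5d")
  expect_true(cfg$use_wavelet_input)
})

test_that("the 3D network has six convolutional layers and valid scores", {
  cfg <- training_config(cnn_type = "cam3d", width = 2L, dropout = 0,
                         use_wavelet_input = FALSE, augment = FALSE, seed = 4)
  m <- build_cnn(cfg)
  expect_equal(sum(grepl("^conv[0-9]+\\.W$", names(m$params))), 6L)
  vols <- tiny_phantoms(c(0, 1), 700, n_scans = 6)
  sc <- predict(m, vols, transform = FALSE)
  expect_true(all(sc >= 0 & sc <= 1))
})

test_that("2.5D scores are invariant to scan permutation and repeatable", {
  cfg <- tiny_cnn_config(1, seed = 5)
  m <- build_cnn(cfg)
  set.seed(31)
  arr <- array(rnorm(20 * 24 * 32), c(20, 24, 32))
  s1 <- predict(m, list(arr), transform = FALSE)
  s2 <- predict(m, list(arr[sample(20), , ]), transform = FALSE)
  expect_lt(abs(s1 - s2), 1e-5)
  expect_identical(s1, predict(m, list(arr), transform = FALSE))
})

test_that("training learns separable phantoms with best-epoch selection", {
  labs <- rep(c(0, 1), 10)
  vols <- tiny_phantoms(labs, 1000)
  cfg <- tiny_cnn_config(16, seed = 7)
  fit <- train_image_model(build_cnn(cfg), vols, labs)
  expect_gt(auroc(predict(fit, vols), labs), 0.9)
  expect_true(fit$best_epoch >= 1 && fit$best_epoch <= 16)
  expect_equal(nrow(fit$history), 16)
  # sanity oracle: the task is separable for a logistic fit on mean
  # in-band intensity, so a CNN reaching AUROC > 0.9 is plausible, not magic
  mi <- vapply(vols, mean, numeric(1))
  or_fit <- glm(labs ~ mi, family = binomial())
  expect_true(is.finite(coef(or_fit)[2]))

  # seeded determinism of the whole training path
  fit2 <- train_image_model(build_cnn(cfg), vols, labs)
  expect_identical(fit$best_epoch, fit2$best_epoch)
  expect_equal(fit$history, fit2$history)
  expect_equal(predict(fit, vols), predict(fit2, vols))
})

test_that("single-class training sets are rejected", {
  vols <- tiny_phantoms(c(1, 1, 1, 1), 1100)
  cfg <- tiny_cnn_config(2, seed = 8)
  expect_error(train_image_model(build_cnn(cfg), vols, c(1, 1, 1, 1)),
               "class")
})

test_that("transfer retraining reuses weights and helps on a related task", {
  src_labs <- rep(c(0, 1), 8)
  src <- tiny_phantoms(src_labs, 1200)
  srcm <- train_image_model(build_cnn(tiny_cnn_config(10, seed = 7)),
                            src, src_labs)

  # zero retraining epochs: identical scores to the source model
  frozen <- transfer_retrain(srcm, src, src_labs,
                             tiny_cnn_config(0, seed = 9))
  expect_identical(predict(frozen, src), predict(srcm, src))

  # architecture mismatch is rejected
  expect_error(transfer_retrain(srcm, src, src_labs,
                                training_config(channels = 8L, n_blocks = 1L,
                                                max_epochs = 1L)),
               "architecture")

  # retraining on flipped labels inverts the score ordering
  flip <- transfer_retrain(srcm, src, 1 - src_labs,
                           tiny_cnn_config(6, seed = 10))
  expect_lt(auroc(predict(flip, src), src_labs), 0.5)

  # transfer beats an equal-budget from-scratch model in most repeats
  tst_labs <- rep(c(0, 1), 8)
  tst <- tiny_phantoms(tst_labs, 3000)
  wins <- 0
  for (r in 1:10) {
    tg_labs <- rep(c(0, 1), 5)
    tg <- tiny_phantoms(tg_labs, 2000 + 20 * r)
    cfg_r <- tiny_cnn_config(2, seed = 50 + r)
    a_tr <- auroc(predict(transfer_retrain(srcm, tg, tg_labs, cfg_r), tst),
                  tst_labs)
    a_sc <- auroc(predict(train_image_model(build_cnn(cfg_r), tg, tg_labs,
                                            cfg_r), tst), tst_labs)
    wins <- wins + (a_tr > a_sc)
  }
  expect_gte(wins, 6)
})

test_that("FFT mask keeps 15% of coefficients, led by dominant frequencies", {
  scans <- list(matrix(runif(40 * 60), 40, 60), matrix(runif(40 * 60), 40, 60))
  mask <- fit_fft_mask(scans)
  expect_equal(length(mask$idx), round(0.15 * 40 * 60))
  # constant image: all energy at the zero frequency
  maskc <- fit_fft_mask(list(matrix(1, 20, 20)))
  expect_true(1L %in% maskc$idx)
  feats <- extract_fft_features(scans[[1]], mask)
  expect_length(feats, length(mask$idx))
  expect_error(extract_fft_features(matrix(0, 10, 10), mask), "size")
})

test_that("FFT mask is defined by training scans only", {
  labs <- rep(c(0, 1), 4)
  train <- tiny_phantoms(labs, 1300)
  mask1 <- fit_fft_mask(train)
  test_vol <- tiny_phantoms(1, 1400)[[1]]
  test_vol[1, , ] <- test_vol[1, , ] + 0.5   # perturb a test volume
  mask2 <- fit_fft_mask(train)                # recompute: unchanged
  expect_identical(mask1$idx, mask2$idx)
})

test_that("FFT-lasso inherits volume labels and averages scan scores", {
  labs <- rep(c(0, 1), 8)
  vols <- tiny_phantoms(labs, 1500)
  fit <- fit_fft_lasso(vols, labs, seed = 2)
  sc <- predict(fit, vols)
  expect_true(all(sc >= 0 & sc <= 1))
  expect_gt(auroc(sc, labs), 0.9)
  # volume score equals the arithmetic mean of its scan scores
  a <- vols[[1]]
  X <- t(vapply(seq_len(dim(a)[1]),
                function(s) extract_fft_features(a[s, , ], fit$mask),
                numeric(length(fit$mask$idx))))
  scan_probs <- as.numeric(predict(fit$cv, newx = X, s = "lambda.min",
                                   type = "response"))
  expect_equal(sc[1], mean(scan_probs), tolerance = 1e-12)
  expect_error(fit_fft_lasso(vols, rep(1, 16)), "class")
})

test_that("lasso sparsity weakly decreases with regularisation strength", {
  set.seed(44)
  X <- matrix(rnorm(200 * 30), 200, 30)
  y <- rbinom(200, 1, plogis(X[, 1] - X[, 2]))
  fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 1,
                        lambda = c(0.5, 0.1, 0.02, 0.004))
  nz <- colSums(as.matrix(fit$beta) != 0)
  expect_true(all(diff(nz) >= 0))   # lambda decreasing -> nonzeros grow
})

test_that("clinical model recovers planted effects and ranks them", {
  ch <- planted_cohort(2000, seed = 40, effect_age = -0.9,
                       effect_sex_female = -0.2, effect_logcst = 0.3)
  f <- normalize_clinical(ch, ch$eye_id)
  fit <- fit_clinical_logreg(f, ch$outcome, seed = 3)
  cf <- coef(fit)
  expect_lt(cf["age"], 0)
  expect_gt(cf["log_cst"], 0)
  expect_lt(cf["sex_female"], 0)
  expect_equal(names(coef_ranking(fit))[1], "age")
  # univariate oracle agrees on the dominant feature
  uni <- abs(vapply(c("age", "log_cst", "trv"), function(col)
    coef(glm(ch$outcome ~ f$x[, col], family = binomial()))[2], numeric(1)))
  expect_equal(names(which.max(uni)), "age")
  expect_error(fit_clinical_logreg(f, rep(1, nrow(ch))), "class")
})

test_that("hyperparameter search is seeded and finds helpful settings", {
  space <- list(use_wavelet = c(TRUE, FALSE),
                lr = list(min = 1e-4, max = 1e-1, log = TRUE))
  # budget 1 returns the single sampled configuration
  one <- random_hyperparameter_search(space, 1, seed = 5,
                                      eval_fn = function(cfg) 0.5)
  expect_named(one$best_config, c("use_wavelet", "lr"))
  expect_equal(nrow(one$trials), 1)

  # identical trial sequence under one seed
  r1 <- random_hyperparameter_search(space, 8, seed = 6,
                                     eval_fn = function(cfg) cfg$lr)
  r2 <- random_hyperparameter_search(space, 8, seed = 6,
                                     eval_fn = function(cfg) cfg$lr)
  expect_identical(r1$trials, r2$trials)
  expect_true(r1$best_score >= max(r1$trials$score) - 1e-12)

  # a task where edge input is constructed to help: two textures with equal
  # means, separable only through wavelet detail energy
  make_scan <- function(freqy, seed) {
    set.seed(seed)
    base <- outer(1:16, 1:16, function(i, j) 0.5 + 0.3 * sin(freqy * i))
    base + matrix(rnorm(256, 0, 0.05), 16, 16)
  }
  eval_fn <- function(cfg) {
    tr_lab <- rep(c(0, 1), 10); va_lab <- rep(c(0, 1), 10)
    feat <- function(lab, off) vapply(seq_along(lab), function(i) {
      s <- make_scan(if (lab[i] == 1) 2.8 else 0.4, off + i)
      if (isTRUE(cfg$use_wavelet)) mean(abs(wavelet_edge_map(s, FALSE)))
      else mean(s)
    }, numeric(1))
    xt <- feat(tr_lab, 900); xv <- feat(va_lab, 950)
    fit <- glm(tr_lab ~ xt, family = binomial())
    auroc(cbind(1, xv) %*% coef(fit), va_lab)
  }
  picks <- vapply(1:6, function(s)
    random_hyperparameter_search(space, 6, seed = s, eval_fn)$best_config$use_wavelet,
    logical(1))
  expect_gt(mean(picks), 0.5)
  expect_error(random_hyperparameter_search(list(), 3, 1, eval_fn), "empty")
})
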