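test_that("Haar decomposition is orthonormal and kills constants", {
  set.seed(1)
  img <- matrix(rnorm(40 * 60), 40, 60)
  sub <- haar_decompose(img)
  # Parseval on the orthonormal basis
  expect_equal(sum(img^2),
               sum(sub$LL^2 + sub$LH^2 + sub$HL^2 + sub$HH^2),
               tolerance = 1e-10)
  const <- matrix(3.7, 16, 16)
  subc <- haar_decompose(const)
  expect_true(all(subc$LH == 0) && all(subc$HL == 0) && all(subc$HH == 0))
})

test_that("edge map matches direct Haar filtering and standardises exactly", {
  # horizontal step edge falling inside a row pair
  img <- matrix(0, 12, 16)
  img[6:12, ] <- 1                      # step between rows 5 and 6 (pair 3)
  e <- wavelet_edge_map(img, standardize = FALSE)
  # direct 2x2 filter oracle: the step pair is rows (5,6); the row filter
  # gives d = -1/sqrt(2) there, column smoothing doubles it to |HL| = 1
  expect_true(all(e[5:6, ] > 0))
  expect_true(all(e[setdiff(1:12, 5:6), ] == 0))
  # oracle value: row filter gives d = (0 - 1)/sqrt(2); column smoothing
  # gives HL = d * 2 / sqrt(2) = -1, so |HL| contribution is 1
  expect_equal(unname(e[5, 1]), 1)

  set.seed(2)
  img2 <- matrix(rnorm(30 * 40), 30, 40)
  e2 <- wavelet_edge_map(img2)
  expect_equal(mean(e2), 0, tolerance = 1e-6)
  expect_equal(sd(e2), 1, tolerance = 1e-6)
  expect_equal(dim(e2), dim(img2))

  ec <- wavelet_edge_map(matrix(5, 10, 10))
  expect_true(attr(ec, "constant"))
  expect_true(all(ec == 0))
})

test_that("foreground detection: degenerate scans, threshold arithmetic, monotonicity", {
  z <- matrix(0, 20, 30)
  b <- detect_foreground(z)
  expect_true(all(is.na(b$top)) && all(is.na(b$bottom)))

  # blend 0.5, column mean 0.2, image mean 0.4, multiplier 1 -> threshold 0.3
  scan <- cbind(matrix(0.2, 10, 1), matrix(0.6, 10, 1))
  # column 1 mean 0.2; image mean 0.4; threshold col1 = 0.5*0.2 + 0.5*0.4 = 0.3
  cfg <- foreground_config(upper_luminosity_multiplier = 1,
                           lower_luminosity_multiplier = 1,
                           edge_sd_multiplier = 100)   # edges out of the way
  bb <- detect_foreground(scan, config = cfg)
  expect_true(is.na(bb$top[1]))        # 0.2 does not surpass 0.3
  expect_equal(bb$top[2], 1L)          # 0.6 surpasses its threshold
  expect_equal(bb$bottom[2], 10L)

  # raising the upper multiplier never moves the top boundary upward
  v <- generate_oct_volume(volume_config(n_scans = 1, height = 80,
                                         width = 100, seed = 9),
                           has_fluid = FALSE)
  s1 <- v$data[1, , ]
  lo <- detect_foreground(s1, config = foreground_config(
    upper_luminosity_multiplier = 1.2))
  hi <- detect_foreground(s1, config = foreground_config(
    upper_luminosity_multiplier = 2.5))
  ok <- !is.na(lo$top) & !is.na(hi$top)
  expect_true(all(hi$top[ok] >= lo$top[ok]))

  expect_error(detect_foreground(z, edge_map = matrix(0, 5, 5)), "shape")
})

test_that("background zeroing conserves foreground and clears background", {
  v <- generate_oct_volume(volume_config(n_scans = 2, height = 60, width = 80,
                                         noise_sd = 0, seed = 13),
                           has_fluid = FALSE)
  s <- v$data[1, , ]
  truth <- list(top = v$truth$top[1, ], bottom = v$truth$bottom[1, ])
  z <- zero_background(s, truth)
  R <- row(s)
  TOP <- matrix(truth$top, 60, 80, byrow = TRUE)
  BOT <- matrix(truth$bottom, 60, 80, byrow = TRUE)
  fg <- R >= TOP & R <= BOT
  expect_identical(z[fg], s[fg])
  expect_true(all(z[!fg] == 0))
  expect_equal(sum(z[fg]), sum(s[fg]))

  # fully-background column
  tr2 <- truth; tr2$top[3] <- NA; tr2$bottom[3] <- NA
  z2 <- zero_background(s, tr2)
  expect_true(all(z2[, 3] == 0))

  # phantom: residual background energy after detector-based zeroing < 1%
  vn <- generate_oct_volume(volume_config(n_scans = 1, height = 120,
                                          width = 150, seed = 14),
                            has_fluid = FALSE)
  sn <- vn$data[1, , ]
  det <- detect_foreground(sn)
  zn <- zero_background(sn, det)
  Rn <- row(sn)
  TOPn <- matrix(vn$truth$top[1, ], 120, 150, byrow = TRUE)
  BOTn <- matrix(vn$truth$bottom[1, ], 120, 150, byrow = TRUE)
  bg <- Rn < TOPn | Rn > BOTn
  expect_lt(sum(zn[bg]^2), 0.01 * sum(sn[bg]^2))
})

test_that("augmentation validates ranges and behaves geometrically", {
  expect_error(augmentation_params(rotation = 30), "rotation")
  expect_error(augmentation_params(translation = c(0, 15)), "translation")
  expect_error(augmentation_params(scale = 0.5), "scale")
  expect_error(augmentation_params(scale = 1.6), "scale")

  v <- generate_oct_volume(volume_config(n_scans = 3, height = 40, width = 50,
                                         seed = 17), has_fluid = TRUE)$data
  expect_identical(augment_volume(v, augmentation_params()), v)
  flipped2 <- augment_volume(augment_volume(v, augmentation_params(hflip = TRUE)),
                             augmentation_params(hflip = TRUE))
  expect_equal(flipped2, v, tolerance = 1e-12)
})

test_that("augmentation matches an independent affine resampling oracle", {
  v <- generate_oct_volume(volume_config(n_scans = 2, height = 36, width = 44,
                                         noise_sd = 0, seed = 18),
                           has_fluid = FALSE)$data
  params <- augmentation_params(rotation = 10, translation = c(3, -4),
                                hflip = TRUE, scale = 1.2)
  got <- augment_volume(v, params)
  for (s in 1:2) {
    want <- affine_oracle(v[s, , ], rotation = 10, translation = c(3, -4),
                          hflip = TRUE, scale = 1.2)
    # interior only: boundary pixels differ by fill handling of partial taps
    expect_lt(max(abs(got[s, 3:34, 3:42] - want[3:34, 3:42])), 1e-6)
  }

  # rotation +10 then -10 recovers the interior up to interpolation blur
  r1 <- augment_volume(v, augmentation_params(rotation = 10))
  r2 <- augment_volume(r1, augmentation_params(rotation = -10))
  interior <- abs(r2[1, 6:31, 6:39] - v[1, 6:31, 6:39])
  expect_lt(mean(interior), 0.05)

  # same parameters move scan k and scan j identically: transform a
  # coordinate-grid volume and compare the two scans
  grid <- array(0, c(2, 36, 44))
  grid[1, , ] <- outer(1:36, 1:44, function(i, j) i + j / 100)
  grid[2, , ] <- grid[1, , ]
  tg <- augment_volume(grid, params)
  expect_identical(tg[1, , ], tg[2, , ])
})
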