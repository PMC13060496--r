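test_that("affine sampling respects degenerate and fixed ranges", {
  expect_equal(sample_affine(identity_synth_config()), diag(4))
  cfg2 <- identity_synth_config(scale_range = c(2, 2))
  expect_equal(sample_affine(cfg2), diag(c(2, 2, 2, 1)))
  cfg <- synth_config()
  set.seed(11); A1 <- sample_affine(cfg)
  set.seed(11); A2 <- sample_affine(cfg)
  expect_identical(A1, A2)
  expect_gt(abs(det(A1)), 0)
})

test_that("nonlinear fields are bounded, seeded, and faster along AP", {
  cfg <- synth_config()
  f0 <- sample_nonlinear_field(c(20, 20, 20), cfg, amplitude = 0)
  expect_true(all(f0$disp == 0))
  expect_error(sample_nonlinear_field(c(20, 20, 20), cfg, amplitude = -1),
               "nonnegative")

  set.seed(5); f1 <- sample_nonlinear_field(c(24, 24, 24), cfg, amplitude = 3)
  set.seed(5); f2 <- sample_nonlinear_field(c(24, 24, 24), cfg, amplitude = 3)
  expect_identical(f1$disp, f2$disp)
  mag <- sqrt(f1$disp[, , , 1]^2 + f1$disp[, , , 2]^2 + f1$disp[, , , 3]^2)
  expect_lte(max(mag), 3 + 1e-12)

  cfgf <- synth_config(nonlin_corr_ap = 4, nonlin_corr_inplane = 16)
  for (s in 1:3) {
    set.seed(s)
    f <- sample_nonlinear_field(c(48, 48, 48), cfgf, amplitude = 3)
    comp <- f$disp[, , , 1]
    expect_lt(field_autocorr_halfwidth(comp, 3),
              min(field_autocorr_halfwidth(comp, 1),
                  field_autocorr_halfwidth(comp, 2)))
  }
})

test_that("label deformation is categorical and matches the shift oracle", {
  set.seed(2)
  lv <- label_volume(array(sample(0:3, 18^3, TRUE), c(18, 18, 18)))
  expect_identical(deform_labels(lv)$labels, lv$labels)

  A <- diag(4); A[1, 4] <- 1  # one-voxel translation along axis 1
  out <- deform_labels(lv, A)
  ref <- array(0L, dim(lv$labels))
  ref[1:17, , ] <- lv$labels[2:18, , ]
  expect_identical(out$labels, ref)

  cfg <- synth_config()
  set.seed(3)
  Arand <- sample_affine(cfg)
  fld <- sample_nonlinear_field(dim(lv$labels), cfg)
  warped <- deform_labels(lv, Arand, fld)
  expect_true(all(unique(as.vector(warped$labels)) %in%
                    c(0L, unique(as.vector(lv$labels)))))
})

test_that("GMM synthesis draws label-conditioned Gaussians", {
  lab1 <- label_volume(array(1L, c(10, 10, 10)))
  g <- data.frame(label = 1, mean = 5, sd = 0)
  expect_true(all(synthesize_intensity(lab1, g) == 5))

  mask <- array(0L, c(12, 12, 12)); mask[1:6, , ] <- 1L; mask[7:12, , ] <- 2L
  lab2 <- label_volume(mask)
  g2 <- data.frame(label = c(1, 2), mean = c(1, 9), sd = c(0, 0))
  img <- synthesize_intensity(lab2, g2)
  expect_true(all(img[mask == 1] == 1) && all(img[mask == 2] == 9))

  set.seed(4)
  lab3 <- label_volume(array(7L, c(25, 25, 25)))  # 15625 voxels
  img3 <- synthesize_intensity(lab3, data.frame(label = 7, mean = 10, sd = 2))
  expect_lt(abs(mean(img3) - 10), 0.1)
  expect_lt(abs(sd(img3) - 2), 0.1)

  expect_error(synthesize_intensity(lab2, g), "without GMM")
})

test_that("gamma augmentation is a monotone power on normalized intensities", {
  cfg <- synth_config()
  v <- array(runif(4^3), c(4, 4, 4))
  expect_equal(as.vector(gamma_augment(v, cfg, gamma = 1)),
               as.vector((v - min(v)) / (max(v) - min(v))))

  v2 <- array(c(0, 0.25, 1, 0.5), c(2, 2, 1))
  g2 <- gamma_augment(v2, cfg, gamma = 2)
  expect_equal(as.vector(g2)[1:3], c(0, 0.0625, 1))

  set.seed(6)
  v3 <- array(rnorm(200), c(10, 10, 2))
  g3 <- gamma_augment(v3, cfg, gamma = exp(0.29))
  expect_identical(rank(as.vector(g3)), rank(as.vector(v3)))

  expect_message(gc0 <- gamma_augment(array(3, c(3, 3, 3)), cfg, gamma = 2),
                 "constant")
  expect_true(all(gc0 == 0))
})

test_that("illumination is a strictly positive multiplicative gain", {
  v <- array(3, c(5, 5, 5))
  f1 <- structure(list(gain = array(1, c(5, 5, 5)), corr = c(1, 1, 1)),
                  class = "illumination_field")
  expect_equal(apply_illumination(v, f1), v)
  f2 <- structure(list(gain = array(2, c(5, 5, 5)), corr = c(1, 1, 1)),
                  class = "illumination_field")
  expect_true(all(apply_illumination(v, f2) == 6))
  v0 <- v; v0[1] <- 0
  expect_equal(apply_illumination(v0, f2)[1], 0)
  fbad <- f2; fbad$gain[2] <- 0
  expect_error(apply_illumination(v, fbad), "positive")

  set.seed(8)
  fs <- sample_illumination_field(c(40, 40, 40), synth_config())
  expect_true(all(fs$gain > 0))
  expect_lt(field_autocorr_halfwidth(log(fs$gain), 3),
            field_autocorr_halfwidth(log(fs$gain), 1))
})

test_that("digital slabbing samples consistent triplets", {
  cfg <- synth_config()
  const_ap <- array(rep(matrix(runif(64), 8, 8), 20), c(8, 8, 20))
  set.seed(9)
  tr <- digital_slab_sample(const_ap, cfg)
  expect_equal(tr$x1, tr$x2)
  expect_equal(tr$x1, tr$y)

  set.seed(10)
  vol <- array(runif(8 * 8 * 20), c(8, 8, 20))
  for (i in 1:200) {
    tr <- digital_slab_sample(vol, cfg)
    d <- tr$d1 + tr$d2
    expect_true(d >= 2 && d <= 12)
    expect_true(tr$d1 >= 0 && tr$d2 >= 0)
  }

  ramp <- ramp_volume(8, 8, 20, slope = 1.5)
  set.seed(12)
  for (i in 1:20) {
    tr <- digital_slab_sample(ramp, cfg)
    ylin <- linear_interpolate(impute_query(tr$x1, tr$x2, tr$d1, tr$d2))
    expect_equal(tr$y, ylin, tolerance = 1e-12)
  }

  tiny <- array(0, c(4, 4, 10))  # AP extent 9 < max thickness 12
  expect_error(digital_slab_sample(tiny, cfg), "extent")
})

test_that("minibatches have the configured size and replay exactly", {
  cfg <- synth_config()
  vol <- array(runif(8 * 8 * 20), c(8, 8, 20))
  set.seed(13)
  mb <- make_minibatch(vol, cfg)
  expect_length(mb, 32)
  expect_length(make_minibatch(vol, cfg, n = 1), 1)
  set.seed(14); a <- make_minibatch(vol, cfg)
  set.seed(14); b <- make_minibatch(vol, cfg)
  expect_identical(a, b)
})

test_that("the full synthesis pipeline composes and is deterministic", {
  lv1 <- label_volume(array(1L, c(16, 16, 16)))
  cfg0 <- identity_synth_config(gmm_mean_range = c(5, 5), gmm_sd_range = c(0, 0))
  suppressMessages(sv0 <- generate_synthetic_volume(lv1, cfg0))
  expect_true(all(sv0$image == sv0$image[1]))  # constant volume

  pv <- generate_phantom(phantom_spec(shape = c(24, 24, 20)))
  cfg <- synth_config()
  set.seed(15); a <- generate_synthetic_volume(pv, cfg)
  set.seed(15); b <- generate_synthetic_volume(pv, cfg)
  expect_identical(a$image, b$image)
  expect_identical(a$labels$labels, b$labels$labels)
  expect_true(all(is.finite(a$image)))
  expect_true(min(a$image) >= 0)
  # pre-illumination intensities lie in [0, 1], so the gain bounds the image
  expect_lte(max(a$image), a$params$illum_range[2] + 1e-12)
})
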