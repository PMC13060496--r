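test_that("imputation plans enumerate the 1 mm grid with bounding slabs", {
  h <- matrix(0, 4, 4)
  rec <- reconstruction_volume(list(h, h + 1, h + 2), c(0, 4, 8))
  plan <- plan_imputation_grid(rec, 1)
  expect_equal(plan$target_mm, 0:8)
  expect_equal(which(plan$passthrough), c(1, 5, 9))
  expect_equal(plan$d1 + plan$d2, rep(4, 9))

  rec2 <- reconstruction_volume(list(h, h, h), c(0, 3, 11))
  plan2 <- plan_imputation_grid(rec2, 1)
  row7 <- plan2[plan2$target_mm == 7, ]
  expect_equal(row7$i_anterior, 2)
  expect_equal(row7$i_posterior, 3)
  expect_equal(row7$d1, 4)
  expect_equal(row7$d2, 4)
  expect_equal(sum(plan2$passthrough), 3)

  rec3 <- reconstruction_volume(list(h, h), c(0, 5))
  plan3 <- plan_imputation_grid(rec3, 1)
  expect_equal(nrow(plan3), 6)
  expect_true(all(plan3$i_anterior == 1 & plan3$i_posterior == 2))
  expect_error(plan_imputation_grid(rec, 0), "positive")
})

test_that("imputed volumes pass observed slices through bit-exactly", {
  set.seed(51)
  slices <- lapply(1:4, function(i) matrix(runif(32 * 32), 32))
  rec <- reconstruction_volume(slices, c(0, 4, 9, 15))
  net <- unet_init(base_width = 8, zero_head = FALSE)
  iso <- suppressWarnings(impute_volume(rec, net))
  for (i in seq_along(slices)) {
    t <- which(iso$ap_coords == rec$ap_coords[i])
    expect_identical(iso$slices[, , 1, t], slices[[i]])
  }
  expect_equal(iso$ap_coords, 0:15)
  expect_equal(iso$affine[3, 3], 1)
})

test_that("constant stacks and linear ramps are reproduced by the baseline", {
  const <- matrix(runif(32 * 32), 32)
  rec <- reconstruction_volume(list(const, const, const), c(0, 5, 10))
  net0 <- unet_init(base_width = 8)  # zero head
  iso <- impute_volume(rec, net0)
  for (t in seq_len(dim(iso$slices)[4]))
    expect_equal(iso$slices[, , 1, t], const, tolerance = 1e-12)

  ramp <- ramp_volume(32, 32, 25, slope = 1.3)
  iso_in <- as_reconstruction_volume(ramp)
  dec <- decimate_volume(iso_in, 4)
  back <- impute_volume(dec, net0)
  expect_equal(back$slices[, , 1, ], ramp, tolerance = 1e-12)
})

test_that("RGB channels are processed independently and equivariantly", {
  set.seed(52)
  arr <- array(runif(32 * 32 * 3 * 3), c(32, 32, 3, 3))
  rec <- reconstruction_volume(arr, c(0, 3, 7))
  net <- unet_init(base_width = 8, zero_head = FALSE)
  iso <- impute_volume(rec, net)
  perm <- c(2, 3, 1)
  rec_p <- reconstruction_volume(arr[, , perm, ], c(0, 3, 7))
  iso_p <- impute_volume(rec_p, net)
  expect_identical(iso_p$slices, iso$slices[, , perm, ])
})

test_that("decimation keeps every k-th slice with its coordinates", {
  vol <- array(runif(8 * 8 * 25), c(8, 8, 25))
  iso <- as_reconstruction_volume(vol)
  dec <- decimate_volume(iso, 4)
  expect_equal(dec$ap_coords, seq(0, 24, by = 4))
  expect_equal(dim(dec$slices)[4], 7)
  expect_identical(dec$slices[, , 1, 2], vol[, , 5])
  expect_identical(decimate_volume(iso, 1)$slices, iso$slices)
  expect_error(decimate_volume(iso, 2.5), "multiple")
  nonuni <- reconstruction_volume(list(vol[, , 1], vol[, , 2], vol[, , 4]),
                                  c(0, 1, 3))
  expect_error(decimate_volume(nonuni, 2), "uniform")
})

test_that("slabs outside the trained thickness range warn but proceed", {
  h <- matrix(runif(32 * 32), 32)
  rec <- reconstruction_volume(list(h, h + 1), c(0, 20))
  net0 <- unet_init(base_width = 8)
  expect_warning(iso <- impute_volume(rec, net0), "outside the trained")
  expect_equal(dim(iso$slices)[4], 21)
})
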