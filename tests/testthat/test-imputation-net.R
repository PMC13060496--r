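test_that("linear interpolation is the exact distance-weighted baseline", {
  q <- impute_query(matrix(c(0, 2), 1), matrix(c(4, 6), 1), 1, 3)
  expect_equal(linear_interpolate(q), matrix(c(1, 3), 1))

  x1 <- matrix(runif(36), 6); x2 <- matrix(runif(36), 6)
  expect_identical(linear_interpolate(impute_query(x1, x2, 0, 5)), x1)
  expect_identical(linear_interpolate(impute_query(x1, x2, 5, 0)), x2)
  expect_equal(linear_interpolate(impute_query(x1, x2, 2, 2)), (x1 + x2) / 2)
  expect_error(impute_query(x1, x2, 0, 0))
})

test_that("input assembly stacks slices and replicated distance planes", {
  q <- impute_query(matrix(runif(64 * 64), 64), matrix(runif(64 * 64), 64), 3, 1.5)
  a <- assemble_input(q)
  expect_equal(dim(a), c(64, 64, 4))
  expect_equal(a[, , 1], q$x1)
  expect_equal(a[, , 2], q$x2)
  expect_true(all(a[, , 3] == 3))
  expect_true(all(a[, , 4] == 1.5))
  swapped <- assemble_input(impute_query(q$x2, q$x1, q$d2, q$d1))
  expect_identical(swapped[, , c(2, 1, 4, 3)], a)
})

test_that("scaled-down network keeps the doubling channel schedule and shape", {
  set.seed(21)
  net <- unet_init(base_width = 8)
  m <- unet_meta(net)
  expect_equal(m$encoder_widths, c(8L, 16L, 32L, 64L))
  expect_equal(m$bottleneck_channels, 128L)
  x <- array(rnorm(64 * 64 * 4), c(64, 64, 4))
  expect_equal(dim(unet_forward(net, x)), c(64, 64))
})

test_that("the network is nonlinear and pads non-divisible inputs", {
  set.seed(22)
  net <- unet_init(base_width = 8, zero_head = FALSE)
  x <- array(rnorm(64 * 64 * 4), c(64, 64, 4))
  y1 <- unet_forward(net, x)
  y2 <- unet_forward(net, 2 * x)
  expect_gt(max(abs(y2 - 2 * y1)), 1e-4)  # no proportional response

  xo <- array(rnorm(50 * 70 * 4), c(50, 70, 4))
  expect_equal(dim(unet_forward(net, xo)), c(50, 70))
})

test_that("residual decomposition is exact with a zeroed head", {
  set.seed(23)
  net <- unet_init(base_width = 8)  # zero head by default
  for (i in 1:5) {
    q <- random_query(32, 48)
    expect_identical(impute_slice(q, net), linear_interpolate(q))
  }
  # boundary composition: d1 = 0 with zero head returns x1 itself
  q0 <- random_query(32, 32); q0$d1 <- 0
  expect_identical(impute_slice(q0, net), q0$x1)
})

test_that("forward passes are deterministic and survive checkpoint round trips", {
  set.seed(24)
  net <- unet_init(base_width = 8, zero_head = FALSE)
  q <- random_query(32, 32)
  y1 <- impute_slice(q, net)
  expect_identical(impute_slice(q, net), y1)

  ck <- tempfile(fileext = ".rds")
  save_checkpoint(net, ck, config_hash = "abc")
  net2 <- load_checkpoint(ck)
  expect_identical(attr(net2, "config_hash"), "abc")
  expect_identical(impute_slice(q, net2), y1)

  clone <- unet_clone(net, zero_head = TRUE)
  expect_identical(impute_slice(q, clone), linear_interpolate(q))
  # original head untouched by the clone
  expect_identical(impute_slice(q, net), y1)
  expect_error(load_checkpoint(tempfile()), class = "slabimpute_format_error")
  unlink(ck)
})
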