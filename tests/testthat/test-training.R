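test_that("min-max normalization follows the documented degenerate rule", {
  expect_equal(minmax_normalize(matrix(c(2, 4, 6), 1)), matrix(c(0, 0.5, 1), 1))
  u <- matrix(c(0, 0.3, 1, 0.7), 2)
  expect_equal(minmax_normalize(u), u)
  expect_true(all(minmax_normalize(matrix(5, 3, 3)) == 0))
})

test_that("Sobel magnitude matches a literal 3x3 correlation", {
  expect_true(all(sobel_gradient_magnitude(matrix(7, 6, 6)) == 0))

  # vertical step edge of height h: interior magnitude 4h at the edge columns
  h <- 2.5
  step <- matrix(rep(c(0, 0, h, h, h), each = 5), 5, 5)
  mag <- sobel_gradient_magnitude(step)
  expect_equal(mag[3, 2], 4 * h)
  expect_equal(mag[3, 3], 4 * h)
  expect_equal(mag[3, 5], 0)

  set.seed(31)
  for (i in 1:5) {
    x <- matrix(rnorm(64), 8, 8)
    expect_equal(sobel_gradient_magnitude(x), brute_force_sobel(x),
                 tolerance = 1e-10)
    # 90-degree rotation commutes with the magnitude
    rot <- t(x)[, rev(seq_len(8))]
    rotmag <- t(sobel_gradient_magnitude(x))[, rev(seq_len(8))]
    expect_equal(sobel_gradient_magnitude(rot), rotmag, tolerance = 1e-10)
  }
  expect_error(sobel_gradient_magnitude(matrix(1, 2, 5)))
})

test_that("imputation loss is zero iff normalized slices agree", {
  set.seed(32)
  y <- matrix(runif(100), 10)
  expect_equal(imputation_loss(y, y), 0)
  expect_gt(imputation_loss(y + matrix(rnorm(100, sd = .1), 10), y), 0)
  # normalization removes affine maps of the intensities
  expect_equal(imputation_loss(2 * y + 7, y), 0)
  # constant offset in unnormalized mode: pure MAE term
  expect_equal(imputation_loss(y + 0.1, y, lambda = 0, normalize = FALSE), 0.1)

  yhat <- matrix(runif(100), 10)
  ref <- mean(abs(minmax_normalize(yhat) - minmax_normalize(y))) +
    0.7 * mean(abs(brute_force_sobel(minmax_normalize(yhat)) -
                     brute_force_sobel(minmax_normalize(y))))
  expect_equal(imputation_loss(yhat, y, lambda = 0.7), ref, tolerance = 1e-6)
})

test_that("validation MAE is zero where the linear baseline is exact", {
  ramp <- ramp_volume(16, 16, 20)
  cfg <- synth_config()
  set.seed(33)
  triplets <- make_minibatch(ramp, cfg, n = 8)
  net <- unet_init(base_width = 4, zero_head = TRUE)
  expect_lt(validate(net, triplets), 1e-6)
  expect_gte(validate(NULL, triplets), 0)
  expect_error(validate(NULL, list()), "empty")

  one <- triplets[1]
  expect_equal(validate(NULL, one),
               mean(abs(minmax_normalize(linear_interpolate(
                 impute_query(one[[1]]$x1, one[[1]]$x2, one[[1]]$d1, one[[1]]$d2))) -
                   minmax_normalize(one[[1]]$y))),
               tolerance = 1e-6)
})

test_that("training is a no-op at zero iterations and replays bit-exactly", {
  pv <- generate_phantom(phantom_spec(shape = c(32, 32, 20)))
  cfg <- synth_config()
  gen <- training_generator(list(pv), cfg)
  tc0 <- train_config(profile = "desk", max_iter = 0)
  set.seed(41)
  net <- unet_init(base_width = 4)
  fit0 <- train(gen, net, tc0)
  expect_equal(nrow(fit0$history), 0)
  expect_identical(fit0$net, net)

  run <- function() {
    set.seed(42)
    n <- unet_init(base_width = 4)
    train(gen, n, train_config(profile = "desk", seed = 7, max_iter = 5,
                               val_size = 4, val_interval = 5, batch = 4))
  }
  a <- run(); b <- run()
  expect_identical(a$history, b$history)
  expect_identical(a$validation, b$validation)
  expect_identical(unet_forward(a$net, array(1, c(32, 32, 4))),
                   unet_forward(b$net, array(1, c(32, 32, 4))))
})

test_that("the checkpoint with the best validation MAE is returned", {
  pv <- generate_phantom(phantom_spec(shape = c(32, 32, 20)))
  gen <- training_generator(list(pv), synth_config())
  tc <- train_config(profile = "desk", seed = 8, max_iter = 30, val_size = 6,
                     val_interval = 10, batch = 4)
  set.seed(43)
  net <- unet_init(base_width = 4)
  fit <- train(gen, net, tc)
  expect_equal(fit$best_val, min(fit$validation$val_mae))
  # re-freeze the same validation set and confirm the returned parameters
  set.seed(tc$seed)
  val <- list()
  while (length(val) < tc$val_size) val <- c(val, gen())
  val <- val[seq_len(tc$val_size)]
  expect_equal(validate(fit$net, val), fit$best_val, tolerance = 1e-7)
})
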