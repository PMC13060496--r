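test_that("Dice follows the overlap formula and its conventions", {
  a <- array(0L, c(6, 6, 6)); b <- array(0L, c(6, 6, 6))
  a[1:10] <- 1L; b[5:14] <- 1L  # |A| = |B| = 10, overlap 6
  expect_equal(dice_score(a, b, 1), 0.6)
  expect_equal(dice_score(a, a, 1), 1)
  b2 <- array(0L, c(6, 6, 6)); b2[100:109] <- 1L
  expect_equal(dice_score(a, b2, 1), 0)
  expect_equal(dice_score(a, b, 99), 1)   # absent from both
  expect_equal(dice_score(a, b2, 1), dice_score(b2, a, 1))  # symmetry
  set.seed(61)
  p <- sample(216)
  expect_equal(dice_score(array(a[p], dim(a)), array(b[p], dim(b)), 1),
               dice_score(a, b, 1))
  expect_error(dice_score(a, array(0L, c(5, 5, 5)), 1), "grid")
})

test_that("region Dice tables keep deterministic order and flag conventions", {
  set.seed(62)
  a <- array(sample(0:3, 1000, TRUE), c(10, 10, 10))
  tab <- region_dice_table(a, a)
  expect_equal(tab$dice, rep(1, 3))
  expect_equal(tab$label, 1:3)

  b <- a; b[b == 3L] <- 0L
  tab2 <- region_dice_table(a, b, labels = c(1, 3, 9))
  expect_equal(tab2$label, c(1, 3, 9))
  expect_equal(tab2$dice[tab2$label == 1], 1)
  expect_equal(tab2$dice[tab2$label == 3], 0)   # present in exactly one
  expect_equal(tab2$dice[tab2$label == 9], 1)   # empty-empty convention
  expect_true(tab2$empty_empty[tab2$label == 9])

  one <- region_dice_table(a, b, labels = 2)
  expect_equal(nrow(one), 1)
  expect_equal(one$dice, dice_score(a, b, 2))
})

test_that("closest-point distances agree with analytic spheres and brute force", {
  s10 <- make_sphere_mesh(10, 3)
  expect_true(all(abs(sqrt(rowSums(s10$vertices^2)) - 10) < 1e-6))
  expect_equal(max(closest_point_distances(s10, s10)), 0, tolerance = 1e-9)

  s12 <- make_sphere_mesh(12, 3)
  d <- closest_point_distances(s10, s12)
  expect_true(all(abs(d - 2) < 0.05))

  # translation adds at most |t| to every distance (triangle inequality)
  t3 <- c(0.4, -0.2, 0.3)
  moved <- surface_mesh(sweep(s10$vertices, 2, t3, "+"), s10$faces)
  dm <- closest_point_distances(moved, s12)
  expect_true(all(abs(dm - d) <= sqrt(sum(t3^2)) + 1e-9))

  set.seed(63)
  ref <- surface_mesh(matrix(rnorm(18, sd = 3), 6, 3),
                      rbind(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5), c(4, 5, 6)))
  pts <- matrix(rnorm(15, sd = 4), 5, 3)
  src <- surface_mesh(rbind(pts, pts[1, , drop = FALSE] * 0 + 9),
                      matrix(c(1, 2, 3), 1))
  got <- closest_point_distances(src, ref)
  want <- brute_force_surface_distance(src$vertices, ref, grid = 120)
  expect_equal(got, want, tolerance = 5e-3)
})

test_that("parcel means average unweighted and their grand mean ignores size", {
  d <- c(rep(1, 10), rep(3, 2))
  lab <- c(rep("a", 10), rep("b", 2))
  mp <- mean_parcel_distance(d, lab)
  expect_equal(mp$parcel$mean, c(1, 3))
  expect_equal(mp$grand_mean, 2)  # mean of means, not vertex-weighted
  expect_equal(mean_parcel_distance(rep(0, 7), rep(1:7))$grand_mean, 0)

  set.seed(64)
  dist <- runif(300)
  labs <- sample(letters[1:6], 300, TRUE)
  mp2 <- mean_parcel_distance(dist, labs)
  ref <- tapply(dist, labs, mean)
  expect_equal(mp2$parcel$mean, as.numeric(ref[mp2$parcel$parcel]))
  expect_equal(mp2$grand_mean, mean(ref))
  expect_message(mean_parcel_distance(dist, labs, parcels = c(letters[1:6], "z")),
                 "empty")
})

test_that("cortical thickness and its parcel errors behave analytically", {
  w <- make_sphere_mesh(10, 2)
  expect_equal(max(cortical_thickness(w, w)), 0, tolerance = 1e-9)
  p <- make_sphere_mesh(12.5, 3)
  th <- cortical_thickness(w, p)
  expect_true(all(th >= 0))
  expect_true(all(abs(th - 2.5) < 0.06))

  set.seed(65)
  ta <- runif(200, 1, 4)
  labs <- sample(1:5, 200, TRUE)
  te <- thickness_error(ta, ta + 0.4, labs)
  expect_equal(te$parcel$abs_error, rep(0.4, 5))
  expect_equal(te$grand_mean, 0.4)
  expect_equal(thickness_error(ta, ta, labs)$grand_mean, 0)

  tb <- runif(200, 1, 4)
  te2 <- thickness_error(ta, tb, labs)
  ref <- abs(tapply(ta, labs, mean) - tapply(tb, labs, mean))
  expect_equal(te2$parcel$abs_error, as.numeric(ref))
  expect_error(thickness_error(ta, tb[labs != 5], labs, labs[labs != 5]),
               "disagree")
})

test_that("nearest-neighbor resampling maps labels through both affines", {
  set.seed(66)
  lab <- array(sample(0:2, 8^3, TRUE), c(8, 8, 8))
  seg <- segmentation_volume(lab)
  same <- resample_labels_nn(seg, c(8, 8, 8), diag(4))
  expect_identical(same$labels, lab)
  # doubling the target voxel size keeps every second label
  aff2 <- diag(c(2, 2, 2, 1)); aff2[4, 4] <- 1
  half <- resample_labels_nn(seg, c(4, 4, 4), aff2)
  expect_identical(half$labels[2, 3, 1], lab[4, 6, 2])
})
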