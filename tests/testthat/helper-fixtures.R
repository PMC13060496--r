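# shared fixtures: everything is generated in code at test time

options(slabimpute.verbose = "warn")

# volume affine in the AP coordinate with a fixed in-plane pattern:
# v(x, y, z) = P(x, y) + slope * z  (z in mm, 0-based slice index)
ramp_volume <- function(h = 16, w = 16, nz = 30, slope = 2, offset = 5) {
  P <- outer(seq_len(h), seq_len(w), function(i, j) sin(i / 3) + cos(j / 5))
  arr <- array(0, dim = c(h, w, nz))
  for (z in seq_len(nz)) arr[, , z] <- P + offset + slope * (z - 1)
  arr
}

# synthesis config with every randomization collapsed to a constant
identity_synth_config <- function(...) {
  args <- utils::modifyList(
    list(rotation_deg = 0, scale_range = c(1, 1), shear_range = c(0, 0),
         translation_mm = 0, nonlin_amp_range = c(0, 0),
         gamma_log_range = c(0, 0), illum_sd = 0),
    list(...))
  do.call(synth_config, args)
}

random_query <- function(h = 8, w = 8) {
  d1 <- runif(1, 0.1, 6)
  d2 <- runif(1, 0.1, 6)
  impute_query(matrix(runif(h * w), h), matrix(runif(h * w), h), d1, d2)
}

# training runs are expensive; criterion-style tests share them via a cache
.fit_cache <- new.env(parent = emptyenv())

# the desk-scale study conditions: three procedural phantoms, default
# domain-randomization, base-width-8 network, 200 Adam iterations at the
# desk learning rate, frozen 100-slice validation set
desk_phantoms <- function() {
  if (is.null(.fit_cache$phantoms))
    .fit_cache$phantoms <- lapply(1:3, function(s)
      generate_phantom(phantom_spec(seed = s)))
  .fit_cache$phantoms
}

desk_training_run <- function(seed, max_iter = 200) {
  key <- sprintf("fit_%d_%d", seed, max_iter)
  if (!is.null(.fit_cache[[key]])) return(.fit_cache[[key]])
  cfg <- synth_config()
  gen <- training_generator(desk_phantoms(), cfg)
  tc <- train_config(profile = "desk", seed = seed, max_iter = max_iter,
                     val_interval = 50)
  set.seed(seed)
  net <- unet_init(base_width = 8)
  fit <- train(gen, net, tc)
  # regenerate the identical frozen validation set for baseline comparison
  set.seed(tc$seed)
  val <- list()
  while (length(val) < tc$val_size) val <- c(val, gen())
  val <- val[seq_len(tc$val_size)]
  out <- list(net = fit$net, fit = fit, val = val,
              baseline_mae = validate(NULL, val),
              trained_mae = validate(fit$net, val))
  .fit_cache[[key]] <- out
  out
}

# straightforward quadratic-time closest-point reference: densely sample
# every triangle with a barycentric grid and take the minimum distance
brute_force_surface_distance <- function(points, mesh, grid = 40) {
  bc <- expand.grid(a = seq(0, 1, length.out = grid),
                    b = seq(0, 1, length.out = grid))
  bc <- bc[bc$a + bc$b <= 1, ]
  samples <- do.call(rbind, lapply(seq_len(nrow(mesh$faces)), function(t) {
    A <- mesh$vertices[mesh$faces[t, 1], ]
    B <- mesh$vertices[mesh$faces[t, 2], ]
    C <- mesh$vertices[mesh$faces[t, 3], ]
    cbind(A[1] + bc$a * (B[1] - A[1]) + bc$b * (C[1] - A[1]),
          A[2] + bc$a * (B[2] - A[2]) + bc$b * (C[2] - A[2]),
          A[3] + bc$a * (B[3] - A[3]) + bc$b * (C[3] - A[3]))
  }))
  apply(points, 1, function(p)
    sqrt(min((samples[, 1] - p[1])^2 + (samples[, 2] - p[2])^2 +
               (samples[, 3] - p[3])^2)))
}

# reference Sobel magnitude: literal 3x3 correlation on an edge-padded image
brute_force_sobel <- function(x) {
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
  ky <- t(kx)
  h <- nrow(x); w <- ncol(x)
  p <- x[c(1, seq_len(h), h), c(1, seq_len(w), w)]
  gx <- matrix(0, h, w); gy <- matrix(0, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      blk <- p[i:(i + 2), j:(j + 2)]
      gx[i, j] <- sum(kx * blk)
      gy[i, j] <- sum(ky * blk)
    }
  }
  sqrt(gx^2 + gy^2)
}
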