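#' Smooth random scalar field
#'
#' Samples white Gaussian noise on a coarse node grid whose per-axis spacing
#' equals the requested correlation length, then linearly upsamples to the
#' full grid. The per-axis node spacing therefore controls how fast the
#' field varies along that axis: a shorter correlation length yields faster
#' variation. The returned field has approximately unit standard deviation.
#'
#' @param shape integer vector of 3 grid dimensions (voxels, 1 mm spacing).
#' @param corr per-axis correlation lengths in mm (length 3).
#' @return a 3D array of dimension `shape`.
#' @export
smooth_random_field <- function(shape, corr) {
  stopifnot(length(shape) == 3, length(corr) == 3, all(corr > 0))
  nodes <- pmax(2L, as.integer(ceiling(shape / corr)) + 1L)
  noise <- array(rnorm(prod(nodes)), dim = nodes)
  f <- noise
  for (ax in 1:3)
    f <- apply_axis_matrix(f, interp_matrix(shape[ax], dim(f)[ax]), ax)
  s <- stats::sd(as.vector(f))
  if (s > 0) f <- f / s
  f
}

# linear interpolation matrix mapping n_nodes values to n_out positions,
# nodes placed at seq(1, n_out, length.out = n_nodes)
interp_matrix <- function(n_out, n_nodes) {
  pos <- seq(1, n_out, length.out = n_nodes)
  M <- matrix(0, n_out, n_nodes)
  for (i in seq_len(n_out)) {
    j <- findInterval(i, pos, rightmost.closed = TRUE)
    j <- min(max(j, 1L), n_nodes - 1L)
    f <- (i - pos[j]) / (pos[j + 1] - pos[j])
    M[i, j] <- 1 - f
    M[i, j + 1] <- f
  }
  M
}

# multiply a matrix along one axis of a 3D array
apply_axis_matrix <- function(arr, M, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  out <- M %*% matrix(a, nrow = d[axis])
  out <- array(out, dim = c(nrow(M), d[perm[2]], d[perm[3]]))
  aperm(out, order(perm))
}

#' Empirical autocorrelation half-width of a field along one axis
#'
#' Computes the normalized autocorrelation of the (mean-centered) field as a
#' function of lag along `axis`, averaged over all parallel lines, and
#' returns the lag (in voxels, linearly interpolated) at which it first
#' drops below 0.5. Used to verify that deformation and illumination fields
#' vary faster along the AP axis than in-plane.
#'
#' @param field a 3D array.
#' @param axis axis index (1-3).
#' @param max_lag largest lag examined.
#' @return half-width in voxels (`max_lag` if the autocorrelation never
#'   drops below 0.5).
#' @export
field_autocorr_halfwidth <- function(field, axis, max_lag = NULL) {
  d <- dim(field)
  stopifnot(length(d) == 3, axis %in% 1:3)
  if (is.null(max_lag)) max_lag <- d[axis] - 1L
  f <- field - mean(field)
  denom <- sum(f * f)
  if (denom == 0) return(as.numeric(max_lag))
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(f, perm)
  n <- dim(a)[1]
  ac <- numeric(max_lag)
  prev <- 1
  for (lag in seq_len(max_lag)) {
    num <- sum(a[seq_len(n - lag), , , drop = FALSE] *
                 a[(lag + 1):n, , , drop = FALSE])
    ac[lag] <- num / denom * n / (n - lag)
    if (ac[lag] < 0.5) {
      # linear interpolation between the bracketing lags
      return((lag - 1) + (prev - 0.5) / (prev - ac[lag]))
    }
    prev <- ac[lag]
  }
  as.numeric(max_lag)
}

#' Sample a nonlinear deformation field
#'
#' Draws a zero-mean smooth random 3D displacement field whose maximum
#' displacement magnitude equals `amplitude` (drawn uniformly from
#' `config$nonlin_amp_range` when not supplied). The field's correlation
#' length along the AP axis (`config$nonlin_corr_ap`) is strictly smaller
#' than in-plane, so it varies fastest front-to-back.
#'
#' @param grid_shape 3D grid dimensions.
#' @param config a [synth_config()].
#' @param amplitude optional fixed maximum displacement (mm); must be >= 0.
#' @return list of class `deformation_field` with elements `disp` (4D array,
#'   last dimension the 3 displacement components, mm) and `corr`.
#' @export
sample_nonlinear_field <- function(grid_shape, config, amplitude = NULL) {
  stopifnot(inherits(config, "synth_config"), length(grid_shape) == 3)
  if (is.null(amplitude))
    amplitude <- runif(1, config$nonlin_amp_range[1], config$nonlin_amp_range[2])
  if (amplitude < 0) stop("deformation amplitude must be nonnegative")
  corr <- c(config$nonlin_corr_inplane, config$nonlin_corr_inplane,
            config$nonlin_corr_ap)
  disp <- array(0, dim = c(grid_shape, 3))
  if (amplitude > 0) {
    for (k in 1:3) disp[, , , k] <- smooth_random_field(grid_shape, corr)
    mag <- sqrt(disp[, , , 1]^2 + disp[, , , 2]^2 + disp[, , , 3]^2)
    peak <- max(mag)
    if (peak > 0) disp <- disp * (amplitude / peak)
  }
  structure(list(disp = disp, corr = corr, amplitude = amplitude),
            class = "deformation_field")
}

#' Sample a multiplicative illumination field
#'
#' The gain is `exp(g)` where `g` is a smooth random field scaled to
#' standard deviation `config$illum_sd`; it is strictly positive and varies
#' faster along the AP axis, emulating slab-to-slab lighting differences.
#'
#' @inheritParams sample_nonlinear_field
#' @return list of class `illumination_field` with elements `gain` and `corr`.
#' @export
sample_illumination_field <- function(grid_shape, config) {
  stopifnot(inherits(config, "synth_config"), length(grid_shape) == 3)
  corr <- c(config$illum_corr_inplane, config$illum_corr_inplane,
            config$illum_corr_ap)
  g <- if (config$illum_sd > 0) {
    smooth_random_field(grid_shape, corr) * config$illum_sd
  } else {
    array(0, dim = grid_shape)
  }
  structure(list(gain = exp(g), corr = corr), class = "illumination_field")
}
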