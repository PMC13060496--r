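#' Reconstruction volume: an ordered stack of observed coronal slices
#'
#' @param slices either a list of 2D matrices (1 channel) / `c(H, W, 3)`
#'   arrays (RGB), or an array of dimension `c(H, W, C, n)`.
#' @param ap_coords strictly increasing per-slice anterior-posterior world
#'   coordinates in mm.
#' @param affine in-plane voxel-to-world map (4x4); the AP row is rewritten
#'   on output from the slice coordinates.
#' @export
reconstruction_volume <- function(slices, ap_coords, affine = diag(4)) {
  if (is.list(slices)) {
    first <- slices[[1]]
    ch <- if (length(dim(first)) == 3) dim(first)[3] else 1L
    h <- nrow(first); w <- ncol(first)
    arr <- array(0, dim = c(h, w, ch, length(slices)))
    for (i in seq_along(slices)) {
      s <- slices[[i]]
      if (ch == 1) {
        stopifnot(is.matrix(s), all(dim(s) == c(h, w)))
        arr[, , 1, i] <- s
      } else {
        stopifnot(all(dim(s) == c(h, w, ch)))
        arr[, , , i] <- s
      }
    }
    slices <- arr
  }
  d <- dim(slices)
  stopifnot(length(d) == 4, d[3] %in% c(1L, 3L),
            length(ap_coords) == d[4], d[4] >= 2,
            all(diff(ap_coords) > 0))
  structure(list(slices = slices, ap_coords = as.numeric(ap_coords),
                 affine = affine, channels = d[3]),
            class = "reconstruction_volume")
}

#' @export
print.reconstruction_volume <- function(x, ...) {
  sp <- diff(x$ap_coords)
  cat(sprintf(
    "<reconstruction_volume> %d slices (%dx%d, %d channel%s), AP %g..%g mm (spacing %s)\n",
    dim(x$slices)[4], dim(x$slices)[1], dim(x$slices)[2], x$channels,
    if (x$channels > 1) "s" else "", min(x$ap_coords), max(x$ap_coords),
    if (max(sp) - min(sp) < 1e-9) sprintf("%g mm", sp[1]) else "non-uniform"))
  invisible(x)
}

#' Plan the imputation grid
#'
#' Enumerates the arithmetic target grid at `spacing_mm` spanning the
#' observed AP range (inclusive), maps each target to its two nearest
#' bounding observed slices, and flags targets that coincide (within `tol`
#' mm) with an observed slice as passthrough. Variable inter-slice spacing
#' is handled naturally: each target simply records its own `d1`, `d2`.
#'
#' @param recon a [reconstruction_volume()].
#' @param spacing_mm output slice spacing (default 1 mm).
#' @param tol passthrough coordinate tolerance in mm.
#' @return data.frame of class `imputation_plan` with columns `target_mm`,
#'   `i_anterior`, `i_posterior`, `d1`, `d2`, `passthrough`, `pass_index`.
#' @export
plan_imputation_grid <- function(recon, spacing_mm = 1, tol = 1e-6) {
  stopifnot(inherits(recon, "reconstruction_volume"))
  if (spacing_mm <= 0) stop("spacing must be positive")
  coords <- recon$ap_coords
  lo <- coords[1]; hi <- coords[length(coords)]
  n_targets <- floor((hi - lo) / spacing_mm + tol) + 1
  targets <- lo + (seq_len(n_targets) - 1) * spacing_mm
  i1 <- findInterval(targets, coords)
  i1 <- pmin(pmax(i1, 1L), length(coords) - 1L)
  d1 <- targets - coords[i1]
  d2 <- coords[i1 + 1L] - targets
  nearest <- vapply(targets, function(t) which.min(abs(coords - t)), integer(1))
  pass <- abs(coords[nearest] - targets) <= tol
  plan <- data.frame(target_mm = targets, i_anterior = i1,
                     i_posterior = i1 + 1L, d1 = d1, d2 = d2,
                     passthrough = pass,
                     pass_index = ifelse(pass, nearest, NA_integer_))
  class(plan) <- c("imputation_plan", "data.frame")
  plan
}

#' Impute an isotropic volume from an anisotropic slice stack
#'
#' Runs the trained residual network at every target of the imputation plan.
#' Targets coinciding with observed slices copy the observed image verbatim
#' (passthrough); all others are [impute_slice()] outputs. Multi-channel
#' (RGB) stacks are processed channel by channel with identical distance
#' queries, so channel permutation commutes with imputation. Slabs thicker
#' than the trained 2-12 mm range trigger a warning but are imputed (the
#' network is conditioned on the distances and may extrapolate).
#'
#' @param recon a [reconstruction_volume()].
#' @param net a trained `slab_unet`.
#' @param spacing_mm output AP spacing (default 1 mm).
#' @param clip clip predictions to the observed intensity range of the
#'   bounding slices.
#' @param trained_range slab thickness range the network was trained on.
#' @return a [reconstruction_volume()] on the uniform output grid; its
#'   `affine` has the AP voxel size set to `spacing_mm`.
#' @export
impute_volume <- function(recon, net, spacing_mm = 1, clip = TRUE,
                          trained_range = c(2, 12)) {
  stopifnot(inherits(recon, "reconstruction_volume"), inherits(net, "slab_unet"))
  plan <- plan_imputation_grid(recon, spacing_mm)
  thick <- plan$d1 + plan$d2
  outside <- !plan$passthrough &
    (thick < trained_range[1] - 1e-9 | thick > trained_range[2] + 1e-9)
  if (any(outside))
    warning(sprintf(
      "%d target(s) lie in slabs outside the trained thickness range [%g, %g] mm",
      sum(outside), trained_range[1], trained_range[2]))
  d <- dim(recon$slices)
  h <- d[1]; w <- d[2]; ch <- d[3]
  out <- array(0, dim = c(h, w, ch, nrow(plan)))
  for (t in seq_len(nrow(plan))) {
    if (plan$passthrough[t]) {
      out[, , , t] <- recon$slices[, , , plan$pass_index[t], drop = FALSE]
      next
    }
    for (c in seq_len(ch)) {
      q <- impute_query(recon$slices[, , c, plan$i_anterior[t]],
                        recon$slices[, , c, plan$i_posterior[t]],
                        plan$d1[t], plan$d2[t])
      out[, , c, t] <- impute_slice(q, net, clip = clip)
    }
  }
  aff <- recon$affine
  aff[3, 3] <- spacing_mm
  reconstruction_volume(out, plan$target_mm, aff)
}

#' Decimate an isotropic volume into a thick-slab stack
#'
#' Keeps every k-th slice (`k = thickness_mm / spacing`), recording the
#' retained AP coordinates; used to build matched anisotropic/isotropic
#' evaluation pairs from synthetic volumes.
#'
#' @param iso a [reconstruction_volume()] with uniform AP spacing.
#' @param thickness_mm desired slab thickness; must be a positive multiple
#'   of the input spacing.
#' @export
decimate_volume <- function(iso, thickness_mm) {
  stopifnot(inherits(iso, "reconstruction_volume"))
  sp <- diff(iso$ap_coords)
  if (max(sp) - min(sp) > 1e-9) stop("input volume must be uniformly spaced")
  sp <- sp[1]
  k <- thickness_mm / sp
  if (abs(k - round(k)) > 1e-9 || k < 1)
    stop("thickness must be a positive multiple of the input spacing")
  k <- as.integer(round(k))
  idx <- seq(1L, dim(iso$slices)[4], by = k)
  if (length(idx) < 2) stop("decimation leaves fewer than 2 slices")
  reconstruction_volume(iso$slices[, , , idx, drop = FALSE],
                        iso$ap_coords[idx], iso$affine)
}

#' Wrap a 3D (or 4D channel) array as a reconstruction volume
#'
#' Convenience for synthetic volumes on the 1 mm grid: slice `i` receives
#' AP coordinate `i - 1` mm.
#'
#' @param vol array `c(H, W, nAP)` or `c(H, W, C, nAP)`.
#' @param spacing_mm AP spacing of the input grid.
#' @export
as_reconstruction_volume <- function(vol, spacing_mm = 1) {
  d <- dim(vol)
  if (length(d) == 3) dim(vol) <- c(d[1], d[2], 1L, d[3])
  n <- dim(vol)[4]
  reconstruction_volume(vol, (seq_len(n) - 1) * spacing_mm)
}
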