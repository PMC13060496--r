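#' Label volume
#'
#' A 3D integer segmentation plus its voxel-to-world affine. Label 0 is
#' background. By package convention the anterior-posterior axis is the
#' third voxel axis (the axis along which slabs are cut); [read_volume()]
#' and the command line expose a remapping flag for other layouts.
#'
#' @param labels 3D array of nonnegative integer label IDs.
#' @param affine 4x4 voxel-to-world map (mm); must be finite and invertible.
#' @param require_labels minimum number of distinct non-background labels
#'   (synthesis needs at least 2).
#' @export
label_volume <- function(labels, affine = diag(4), require_labels = 0L) {
  labels <- as.array(labels)
  stopifnot(length(dim(labels)) == 3, all(labels >= 0),
            all(labels == round(labels)),
            all(dim(affine) == c(4, 4)), all(is.finite(affine)))
  if (abs(det(affine)) < .Machine$double.eps)
    stop("affine is singular")
  if (require_labels > 0) {
    nl <- length(setdiff(unique(as.vector(labels)), 0))
    if (nl < require_labels)
      stop(sprintf("need at least %d non-background labels, found %d",
                   require_labels, nl))
  }
  structure(list(labels = labels, affine = affine, ap_axis = 3L),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("<label_volume> %s voxels, %d labels (incl. background)\n",
              paste(dim(x$labels), collapse = "x"),
              length(unique(as.vector(x$labels)))))
  invisible(x)
}

#' Sample a random affine augmentation
#'
#' Composes translation, rotation (about the three axes), shear and
#' anisotropic scaling, each drawn uniformly from the ranges in `config`.
#' Zero-width ranges collapse to the deterministic transform. The matrix is
#' applied about the volume center by [deform_labels()].
#'
#' @param config a [synth_config()].
#' @return invertible 4x4 matrix.
#' @export
sample_affine <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  ang <- runif(3, -config$rotation_deg, config$rotation_deg) * pi / 180
  sc <- runif(3, config$scale_range[1], config$scale_range[2])
  sh <- runif(3, config$shear_range[1], config$shear_range[2])
  tr <- runif(3, -config$translation_mm, config$translation_mm)
  cx <- cos(ang[1]); sx <- sin(ang[1])
  cy <- cos(ang[2]); sy <- sin(ang[2])
  cz <- cos(ang[3]); sz <- sin(ang[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Sh <- rbind(c(1, sh[1], sh[2]), c(0, 1, sh[3]), c(0, 0, 1))
  A3 <- Rz %*% Ry %*% Rx %*% Sh %*% diag(sc)
  A <- diag(4)
  A[1:3, 1:3] <- A3
  A[1:3, 4] <- tr
  A
}

#' Geometrically augment a label volume
#'
#' Resamples the labels through the composed affine and nonlinear warp with
#' nearest-neighbor interpolation (labels are categorical). For each output
#' voxel `x` (in voxel units, 1 mm grid), the source location is
#' `A (x - c) + c + u(x)` where `c` is the volume center and `u` the
#' displacement field evaluated at `x`; out-of-volume sources become
#' background. The output grid equals the input grid and the output label
#' set is a subset of the input's plus background.
#'
#' @param vol a [label_volume()].
#' @param affine 4x4 transform from [sample_affine()] (identity by default).
#' @param field optional [sample_nonlinear_field()] result on the same grid.
#' @export
deform_labels <- function(vol, affine = diag(4), field = NULL) {
  stopifnot(inherits(vol, "label_volume"))
  d <- dim(vol$labels)
  if (!is.null(field) && !all(dim(field$disp)[1:3] == d))
    stop("deformation field grid does not match the volume")
  identity_affine <- isTRUE(all.equal(affine, diag(4), tolerance = 0))
  zero_field <- is.null(field) || all(field$disp == 0)
  if (identity_affine && zero_field) return(vol)

  lab <- vol$labels
  storage.mode(lab) <- "integer"
  out <- nn_warp_cpp(lab, dim(lab), affine,
                     if (zero_field) numeric(0) else field$disp, !zero_field)
  label_volume(out, vol$affine)
}

#' Sample per-label Gaussian intensity parameters
#'
#' One (mean, sd) pair per label present in the volume, drawn uniformly from
#' the configured ranges. Randomizing these makes the downstream network
#' agnostic to tissue appearance.
#'
#' @param vol a [label_volume()] (or integer array).
#' @param config a [synth_config()].
#' @return data.frame of class `gmm_params` with columns label, mean, sd.
#' @export
sample_gmm_params <- function(vol, config) {
  labels <- if (inherits(vol, "label_volume")) vol$labels else vol
  present <- sort(unique(as.vector(labels)))
  out <- data.frame(
    label = present,
    mean = runif(length(present), config$gmm_mean_range[1], config$gmm_mean_range[2]),
    sd = runif(length(present), config$gmm_sd_range[1], config$gmm_sd_range[2]))
  class(out) <- c("gmm_params", "data.frame")
  out
}

#' Synthesize an intensity volume from labels
#'
#' Every voxel's intensity is drawn independently from the Gaussian of its
#' label: a label-conditioned mixture in which the segmentation decides the
#' component. Errors if a label present in the volume has no entry.
#'
#' @param vol a [label_volume()].
#' @param gmm a [sample_gmm_params()] table (columns label, mean, sd).
#' @return 3D numeric array.
#' @export
synthesize_intensity <- function(vol, gmm) {
  stopifnot(inherits(vol, "label_volume"), all(gmm$sd >= 0))
  lab <- as.vector(vol$labels)
  idx <- match(lab, gmm$label)
  if (anyNA(idx)) {
    missing <- unique(lab[is.na(idx)])
    stop(sprintf("labels without GMM parameters: %s",
                 paste(missing, collapse = ", ")))
  }
  array(rnorm(length(lab), mean = gmm$mean[idx], sd = gmm$sd[idx]),
        dim = dim(vol$labels))
}

#' Gamma intensity augmentation
#'
#' Min-max rescales the volume to [0, 1] and raises it elementwise to a
#' random exponent `exp(u)`, `u ~ U(config$gamma_log_range)`, skewing the
#' intensity distribution while preserving voxel ordering. A constant input
#' (degenerate min-max) returns the zero volume and logs a warning.
#'
#' @param vol 3D numeric array with finite values.
#' @param config a [synth_config()].
#' @param gamma optional fixed exponent (> 0) overriding the random draw.
#' @return 3D array in [0, 1]; the exponent used is attached as
#'   `attr(, "gamma")`.
#' @export
gamma_augment <- function(vol, config, gamma = NULL) {
  stopifnot(all(is.finite(vol)))
  if (is.null(gamma))
    gamma <- exp(runif(1, config$gamma_log_range[1], config$gamma_log_range[2]))
  stopifnot(gamma > 0)
  lo <- min(vol); hi <- max(vol)
  if (hi <= lo) {
    slab_log("warn", "gamma_augment: constant input volume, returning zeros")
    out <- array(0, dim = dim(vol))
  } else {
    out <- ((vol - lo) / (hi - lo))^gamma
  }
  attr(out, "gamma") <- gamma
  out
}

#' Apply a multiplicative illumination field
#'
#' @param vol 3D numeric array.
#' @param field an [sample_illumination_field()] result on the same grid.
#' @return elementwise product `vol * field$gain`.
#' @export
apply_illumination <- function(vol, field) {
  stopifnot(inherits(field, "illumination_field"),
            all(dim(field$gain) == dim(vol)))
  if (any(field$gain <= 0)) stop("illumination gain must be strictly positive")
  out <- vol * field$gain
  attributes(out) <- attributes(vol)[c("dim")]
  out
}

# extract the coronal slice at continuous AP coordinate z (mm, 0-based) by
# linear interpolation between the two neighboring 1 mm grid slices
extract_ap_slice <- function(vol, z) {
  d <- dim(vol)
  if (z < 0 || z > d[3] - 1) stop("AP coordinate outside the volume")
  i0 <- floor(z)
  f <- z - i0
  if (f == 0) return(vol[, , i0 + 1])
  (1 - f) * vol[, , i0 + 1] + f * vol[, , i0 + 2]
}

#' Digitally slab a synthetic volume into a training triplet
#'
#' Draws a random slab thickness `d` from `config$slab_range` (2-12 mm by
#' default), a random AP coordinate `a` such that the slab fits in the
#' volume, and a random target offset `d1 ~ U(0, d)`. The two slab faces
#' `x1` (anterior) and `x2` (posterior) are the coronal slices at `a` and
#' `a + d`; the target `y` sits at `a + d1`, so `d2 = d - d1`. Slices at
#' continuous coordinates are linearly interpolated from the 1 mm grid.
#'
#' @param vol 3D synthetic intensity array (isotropic 1 mm).
#' @param config a [synth_config()].
#' @return list of class `slab_triplet` with `x1`, `x2`, `y`, `d1`, `d2`.
#' @export
digital_slab_sample <- function(vol, config) {
  d3 <- dim(vol)[3]
  extent <- d3 - 1
  if (extent <= config$slab_range[2])
    stop("volume AP extent must exceed the maximum slab thickness")
  d <- runif(1, config$slab_range[1], config$slab_range[2])
  a <- runif(1, 0, extent - d)
  d1 <- runif(1, 0, d)
  structure(list(x1 = extract_ap_slice(vol, a),
                 x2 = extract_ap_slice(vol, a + d),
                 y = extract_ap_slice(vol, a + d1),
                 d1 = d1, d2 = d - d1),
            class = "slab_triplet")
}

#' Sample a minibatch of training triplets from one synthetic volume
#'
#' @inheritParams digital_slab_sample
#' @param n number of triplets (defaults to `config$minibatch`, 32).
#' @return list of `slab_triplet`s.
#' @export
make_minibatch <- function(vol, config, n = config$minibatch) {
  stopifnot(n >= 1)
  lapply(seq_len(n), function(i) digital_slab_sample(vol, config))
}

#' Generate one domain-randomized synthetic volume
#'
#' Full synthesis pipeline: random affine + nonlinear deformation of the
#' label map, label-conditioned Gaussian intensity synthesis, gamma
#' augmentation and multiplicative illumination. Returns both the image and
#' the deformed labels (the latter serve as evaluation fixtures downstream).
#' Every sampled hyperparameter is logged at debug level and returned.
#'
#' @param labelvol a [label_volume()].
#' @param config a [synth_config()].
#' @return list with `image` (3D array), `labels` (deformed
#'   [label_volume()]), and `params` (the sampled randomization parameters).
#' @export
generate_synthetic_volume <- function(labelvol, config) {
  stopifnot(inherits(labelvol, "label_volume"), inherits(config, "synth_config"))
  d <- dim(labelvol$labels)
  A <- sample_affine(config)
  fld <- sample_nonlinear_field(d, config)
  def <- deform_labels(labelvol, A, fld)
  gmm <- sample_gmm_params(def, config)
  img <- synthesize_intensity(def, gmm)
  img <- gamma_augment(img, config)
  gam <- attr(img, "gamma")
  illum <- sample_illumination_field(d, config)
  img <- apply_illumination(img, illum)
  slab_log("debug", sprintf(
    "synthetic volume: nonlin amplitude %.3f mm, gamma %.3f, %d labels",
    fld$amplitude, gam, nrow(gmm)))
  list(image = img, labels = def,
       params = list(affine = A, nonlin_amplitude = fld$amplitude,
                     gmm = gmm, gamma = gam,
                     illum_range = range(illum$gain)))
}
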