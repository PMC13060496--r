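#' Configuration of the domain-randomized synthetic generator
#'
#' Houses every randomization range used by [generate_synthetic_volume()] and
#' the digital slabbing in [digital_slab_sample()]. Geometry is augmented with
#' a random affine (rotation, anisotropic scaling, shear, translation) and a
#' smooth nonlinear displacement field that varies faster along the AP axis
#' than in-plane, emulating the imperfect stacking of photographed slabs.
#' Appearance is randomized with a label-conditioned Gaussian model, gamma
#' augmentation, and a smooth multiplicative illumination field (again with
#' faster AP variation, emulating slab-to-slab lighting changes).
#'
#' @param rotation_deg max absolute rotation per axis, degrees.
#' @param scale_range multiplicative scaling range (per axis, anisotropic).
#' @param shear_range shear coefficient range.
#' @param translation_mm max absolute translation per axis, mm.
#' @param nonlin_amp_range range (mm) from which the maximum displacement
#'   magnitude of the nonlinear field is drawn per volume.
#' @param nonlin_corr_ap,nonlin_corr_inplane correlation lengths (mm) of the
#'   displacement field; the AP value must be strictly smaller.
#' @param gmm_mean_range,gmm_sd_range per-label Gaussian intensity
#'   mean / standard-deviation sampling ranges (arbitrary units).
#' @param gamma_log_range the gamma exponent is `exp(u)` with `u` uniform in
#'   this range; applied on min-max normalized intensities.
#' @param illum_sd standard deviation of the log illumination gain field.
#' @param illum_corr_ap,illum_corr_inplane correlation lengths (mm) of the
#'   illumination field; AP strictly smaller.
#' @param slab_range range (mm) of the digital slab thickness `d`.
#' @param minibatch triplets sampled per synthetic volume per iteration.
#' @return a list of class `synth_config`.
#' @export
synth_config <- function(rotation_deg = 15,
                         scale_range = c(0.85, 1.15),
                         shear_range = c(-0.1, 0.1),
                         translation_mm = 10,
                         nonlin_amp_range = c(0, 4),
                         nonlin_corr_ap = 5,
                         nonlin_corr_inplane = 20,
                         gmm_mean_range = c(0, 255),
                         gmm_sd_range = c(0, 25),
                         gamma_log_range = c(-0.3, 0.3),
                         illum_sd = 0.2,
                         illum_corr_ap = 8,
                         illum_corr_inplane = 32,
                         slab_range = c(2, 12),
                         minibatch = 32) {
  cfg <- list(rotation_deg = rotation_deg, scale_range = scale_range,
              shear_range = shear_range, translation_mm = translation_mm,
              nonlin_amp_range = nonlin_amp_range,
              nonlin_corr_ap = nonlin_corr_ap,
              nonlin_corr_inplane = nonlin_corr_inplane,
              gmm_mean_range = gmm_mean_range, gmm_sd_range = gmm_sd_range,
              gamma_log_range = gamma_log_range, illum_sd = illum_sd,
              illum_corr_ap = illum_corr_ap,
              illum_corr_inplane = illum_corr_inplane,
              slab_range = slab_range, minibatch = as.integer(minibatch))
  stopifnot(rotation_deg >= 0, translation_mm >= 0,
            length(scale_range) == 2, diff(scale_range) >= 0,
            all(scale_range > 0),
            length(shear_range) == 2, diff(shear_range) >= 0,
            length(nonlin_amp_range) == 2, all(nonlin_amp_range >= 0),
            nonlin_corr_ap < nonlin_corr_inplane,
            illum_corr_ap < illum_corr_inplane, illum_sd >= 0,
            length(slab_range) == 2, slab_range[1] > 0,
            diff(slab_range) >= 0, cfg$minibatch >= 1)
  class(cfg) <- "synth_config"
  cfg
}

#' Training configuration
#'
#' Two named profiles are shipped: `"full"` (Adam learning rate 1e-6,
#' 1,000-slice validation set, open-ended iteration budget) reflects the
#' full-scale training schedule, and `"desk"` (learning rate 1e-4, 100-slice
#' validation set, 500 iterations) converges on a single CPU in minutes and
#' is used throughout the test suite.
#'
#' @param profile `"full"` or `"desk"`; sets defaults that any explicit
#'   argument overrides.
#' @param lr Adam learning rate.
#' @param batch triplets per optimization step.
#' @param max_iter iteration budget.
#' @param val_size number of frozen synthetic validation slices.
#' @param val_interval iterations between validation checks.
#' @param patience consecutive validation checks without an improvement
#'   greater than `min_delta` before stopping.
#' @param min_delta minimal validation improvement counted as progress.
#' @param lambda weight of the Sobel gradient-magnitude term in the loss.
#' @param seed RNG seed controlling data generation and weight init.
#' @return a list of class `train_config`.
#' @export
train_config <- function(profile = c("full", "desk"),
                         lr = NULL, batch = 32L, max_iter = NULL,
                         val_size = NULL, val_interval = NULL,
                         patience = 10L, min_delta = 1e-5,
                         lambda = 1, seed = 1L) {
  profile <- match.arg(profile)
  defaults <- if (profile == "full") {
    list(lr = 1e-6, max_iter = 100000L, val_size = 1000L, val_interval = 250L)
  } else {
    list(lr = 1e-4, max_iter = 500L, val_size = 100L, val_interval = 50L)
  }
  cfg <- list(profile = profile,
              lr = if (is.null(lr)) defaults$lr else lr,
              batch = as.integer(batch),
              max_iter = if (is.null(max_iter)) defaults$max_iter else as.integer(max_iter),
              val_size = if (is.null(val_size)) defaults$val_size else as.integer(val_size),
              val_interval = if (is.null(val_interval)) defaults$val_interval else as.integer(val_interval),
              patience = as.integer(patience), min_delta = min_delta,
              lambda = lambda, seed = as.integer(seed))
  stopifnot(cfg$lr > 0, cfg$batch >= 1, cfg$max_iter >= 0, cfg$val_size >= 1,
            cfg$val_interval >= 1, cfg$patience >= 1, cfg$lambda >= 0)
  class(cfg) <- "train_config"
  cfg
}

#' Read / write a run configuration as YAML
#'
#' A run configuration is any plain list (for instance the combination of a
#' [synth_config()] and a [train_config()]); it round-trips losslessly.
#'
#' @param config a list.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass_rec(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}

unclass_rec <- function(x) {
  if (is.list(x)) return(lapply(unclass(x), unclass_rec))
  x
}
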