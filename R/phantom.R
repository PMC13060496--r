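#' Procedural brain phantom specification
#'
#' Defines a nested-shell label geometry: a folded "cortex" ribbon wrapping
#' a "white matter" core, optionally containing a "ventricle". The outer
#' boundary is an ellipsoid whose radius is modulated by sinusoidal
#' perturbations in the two angular coordinates, giving gyrus/sulcus-like
#' folding whose detail is visibly destroyed by slab decimation — the
#' failure mode slice imputation is meant to repair. Labels are contiguous
#' integers from 0 (background).
#'
#' @param shape grid dimensions (voxels; 1 mm isotropic). The AP extent
#'   (axis 3) must exceed 12 mm plus the structure margin.
#' @param n_labels 3 (background/core/shell) or 4 (adds a ventricle).
#' @param seed seed fixing the random fold phases; the phantom is a pure
#'   function of its spec.
#' @param fold_amp relative amplitude of the folding perturbation.
#' @param fold_freq angular frequencies (length 2) of the folding.
#' @param shell relative thickness of the cortex shell.
#' @param ventricle relative radius of the ventricle (used when
#'   `n_labels >= 4`).
#' @export
phantom_spec <- function(shape = c(64, 64, 48), n_labels = 4L, seed = 1L,
                         fold_amp = 0.09, fold_freq = c(6, 5),
                         shell = 0.16, ventricle = 0.3) {
  stopifnot(length(shape) == 3, all(shape >= 16), shape[3] > 14,
            n_labels %in% c(3L, 4L), fold_amp >= 0, shell > 0,
            shell < 0.5, ventricle > 0, ventricle < 1 - 2 * shell)
  structure(list(shape = as.integer(shape), n_labels = as.integer(n_labels),
                 seed = as.integer(seed), fold_amp = fold_amp,
                 fold_freq = fold_freq, shell = shell, ventricle = ventricle),
            class = "phantom_spec")
}

#' Generate a procedural label phantom
#'
#' Deterministic given the spec (the spec seed scopes its own RNG draws and
#' the caller's RNG state is restored). Voxels are classified by their
#' normalized ellipsoidal radius against the folded outer boundary: outside
#' it background (0), inside it core/"white matter" (1) wrapped by the
#' folded "cortex" shell (2), with an optional central "ventricle" (3).
#'
#' @param spec a [phantom_spec()].
#' @return a [label_volume()].
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)
  d <- spec$shape
  ph <- runif(4, 0, 2 * pi)
  ctr <- (d + 1) / 2
  semi <- 0.42 * d
  n <- prod(d)
  i <- rep_len(seq_len(d[1]), n)
  j <- rep(rep(seq_len(d[2]), each = d[1]), times = d[3])
  k <- rep(seq_len(d[3]), each = d[1] * d[2])
  x <- (i - ctr[1]) / semi[1]
  y <- (j - ctr[2]) / semi[2]
  z <- (k - ctr[3]) / semi[3]
  rho <- sqrt(x^2 + y^2 + z^2)
  theta <- atan2(y, x)
  phi <- acos(ifelse(rho > 0, pmin(pmax(z / pmax(rho, 1e-12), -1), 1), 1))
  fold <- 1 + spec$fold_amp *
    sin(spec$fold_freq[1] * theta + ph[1]) *
    sin(spec$fold_freq[2] * 2 * phi + ph[2]) +
    0.5 * spec$fold_amp * sin((spec$fold_freq[1] - 2) * theta + ph[3]) *
    cos((spec$fold_freq[2] + 2) * phi + ph[4])
  outer_b <- (1 - spec$fold_amp * 1.5) * fold
  inner_b <- outer_b - spec$shell
  lab <- integer(n)
  lab[rho <= outer_b] <- 2L            # cortex shell
  lab[rho <= inner_b] <- 1L            # white matter core
  if (spec$n_labels >= 4L)
    lab[rho <= spec$ventricle * min(inner_b)] <- 3L
  label_volume(array(lab, dim = d))
}
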