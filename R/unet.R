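#' Imputation query
#'
#' One output coordinate mapped to its two bounding observed slices: the
#' anterior slice `x1` at distance `d1` from the target and the posterior
#' slice `x2` at distance `d2` (mm). `d = d1 + d2` is the slab thickness.
#'
#' @param x1,x2 2D numeric matrices of identical shape.
#' @param d1,d2 nonnegative distances (mm) with `d1 + d2 > 0`.
#' @export
impute_query <- function(x1, x2, d1, d2) {
  stopifnot(is.matrix(x1), is.matrix(x2), all(dim(x1) == dim(x2)),
            d1 >= 0, d2 >= 0, d1 + d2 > 0)
  structure(list(x1 = x1, x2 = x2, d1 = d1, d2 = d2), class = "impute_query")
}

#' Linear slice interpolation
#'
#' The analytic baseline `y_lin = (d2/d) x1 + (d1/d) x2` with `d = d1 + d2`:
#' an exact convex combination of the two bounding slices, weighted by the
#' distance to the *other* slice so that `d1 = 0` returns `x1` exactly.
#'
#' @param q an [impute_query()].
#' @return 2D matrix of the same shape as the inputs.
#' @export
linear_interpolate <- function(q) {
  stopifnot(inherits(q, "impute_query"))
  d <- q$d1 + q$d2
  if (d == 0) stop("d1 + d2 must be positive")
  if (q$d1 == 0) return(q$x1)
  if (q$d2 == 0) return(q$x2)
  (q$d2 / d) * q$x1 + (q$d1 / d) * q$x2
}

#' Assemble the 4-channel network input
#'
#' Channel order (fixed): `x1`, `x2`, then the distances `d1` and `d2`
#' replicated into constant 2D planes of the same size.
#'
#' @param q an [impute_query()].
#' @return array of dimension `c(nrow, ncol, 4)`.
#' @export
assemble_input <- function(q) {
  stopifnot(inherits(q, "impute_query"))
  h <- nrow(q$x1); w <- ncol(q$x1)
  out <- array(0, dim = c(h, w, 4))
  out[, , 1] <- q$x1
  out[, , 2] <- q$x2
  out[, , 3] <- q$d1
  out[, , 4] <- q$d2
  out
}

#' Initialize the residual U-Net
#'
#' Four encoder and four decoder stages of two units each (Group
#' Normalization, 3x3 convolution, Leaky ReLU), 2x2 max pooling between
#' encoder stages, bilinear upsampling plus concatenated skip connections in
#' the decoder, and a 1x1 output head. Each encoder stage halves resolution
#' and doubles channels; with the default base width 64 the stage widths are
#' 64/128/256/512 and the bottleneck has 1024 channels. The raw 4-channel
#' input is not normalized (per-channel normalization would erase the
#' constant distance planes), so the very first unit has no normalization
#' layer. The output head is zero-initialized by default: an untrained
#' network then predicts a zero residual, i.e. starts exactly at the linear
#' baseline.
#'
#' @param in_channels input channels (4: two slices + two distance planes).
#' @param base_width channels of the first stage; 64 reproduces the paper's
#'   scale, 8 gives a desk-scale network (bottleneck 128) for CPU tests.
#' @param depth number of 2x downsamplings (4).
#' @param groups preferred Group Normalization group count (capped at, and
#'   adjusted to divide, the channel count).
#' @param leaky_slope negative slope of the Leaky ReLU.
#' @param zero_head zero-initialize the 1x1 output projection.
#' @return object of class `slab_unet`.
#' @export
unet_init <- function(in_channels = 4L, base_width = 64L, depth = 4L,
                      groups = 8L, leaky_slope = 0.01, zero_head = TRUE) {
  ptr <- unet_create_cpp(as.integer(in_channels), as.integer(base_width),
                         as.integer(depth), as.integer(groups),
                         leaky_slope, zero_head)
  structure(list(ptr = ptr), class = "slab_unet")
}

#' Architecture metadata of a network
#'
#' @param net a `slab_unet`.
#' @return list with channel widths, depth, normalization settings.
#' @export
unet_meta <- function(net) {
  stopifnot(inherits(net, "slab_unet"))
  unet_meta_cpp(net$ptr)
}

#' @export
print.slab_unet <- function(x, ...) {
  m <- unet_meta(x)
  cat(sprintf(
    "<slab_unet> depth %d, widths %s, bottleneck %d channels\n",
    m$depth, paste(m$encoder_widths, collapse = "/"), m$bottleneck_channels))
  invisible(x)
}

#' Zero / randomize the output head
#'
#' With a zeroed head the predicted residual is identically zero and
#' [impute_slice()] reduces exactly to [linear_interpolate()].
#'
#' @param net a `slab_unet` (modified in place).
#' @export
unet_zero_head <- function(net) {
  stopifnot(inherits(net, "slab_unet"))
  unet_zero_head_cpp(net$ptr)
  invisible(net)
}

#' @rdname unet_zero_head
#' @param sd standard deviation of the random head weights.
#' @export
unet_randomize_head <- function(net, sd = 0.05) {
  stopifnot(inherits(net, "slab_unet"))
  unet_randomize_head_cpp(net$ptr, sd)
  invisible(net)
}

# mirror (edge-inclusive) padding of a (H, W, C[, N]) array to target H/W
pad_reflect_hw <- function(x, target_h, target_w) {
  d <- dim(x)
  mirror_idx <- function(n, m) {
    extra <- m - n
    lo <- extra %/% 2
    idx <- c(rev(seq_len(lo)), seq_len(n), n + 1 - seq_len(extra - lo))
    pmin(pmax(idx, 1L), n)
  }
  ri <- mirror_idx(d[1], target_h)
  ci <- mirror_idx(d[2], target_w)
  if (length(d) == 2) return(x[ri, ci, drop = FALSE])
  if (length(d) == 3) return(x[ri, ci, , drop = FALSE])
  x[ri, ci, , , drop = FALSE]
}

#' Forward pass of the residual network
#'
#' Accepts a single 4-channel input (`c(H, W, 4)`) or a batch
#' (`c(H, W, 4, N)`). In-plane dimensions must be divisible by
#' `2^depth` (16 by default); otherwise the input is mirror-padded to the
#' next multiple and the output cropped back (logged at debug level).
#'
#' @param net a `slab_unet`.
#' @param input the assembled input array (see [assemble_input()]).
#' @return the predicted residual: `c(H, W)` matrix or `c(H, W, N)` array.
#' @export
unet_forward <- function(net, input) {
  stopifnot(inherits(net, "slab_unet"))
  d <- dim(input)
  single <- length(d) == 3
  if (single) dim(input) <- c(d, 1L)
  d <- dim(input)
  m <- unet_meta(net)
  if (d[3] != m$in_channels)
    stop(sprintf("expected %d input channels, got %d", m$in_channels, d[3]))
  div <- 2L^m$depth
  h2 <- as.integer(ceiling(d[1] / div) * div)
  w2 <- as.integer(ceiling(d[2] / div) * div)
  padded <- h2 != d[1] || w2 != d[2]
  x <- input
  if (padded) {
    slab_log("debug", sprintf("padding %dx%d input to %dx%d", d[1], d[2], h2, w2))
    x <- pad_reflect_hw(input, h2, w2)
  }
  # C++ expects slices ordered channel-fastest: (H, W, C*N)
  dim(x) <- c(h2, w2, d[3] * d[4])
  out <- unet_forward_cpp(net$ptr, x, h2, w2, d[4])
  if (padded) {
    off_h <- (h2 - d[1]) %/% 2
    off_w <- (w2 - d[2]) %/% 2
    out <- out[off_h + seq_len(d[1]), off_w + seq_len(d[2]), , drop = FALSE]
  }
  if (single) out[, , 1] else out
}

# joint min-max of the two observed slices; the same affine map is applied
# to x1, x2 and (implicitly) y_lin, and inverted on the prediction
query_norm_range <- function(q) {
  lo <- min(q$x1, q$x2)
  hi <- max(q$x1, q$x2)
  c(lo, hi)
}

#' Impute one slice
#'
#' Implements the residual decomposition: the imputed slice is the linear
#' interpolation of the two observed slices plus the network residual,
#' `yhat = y_lin + S(x1, x2, d1, d2)`. The network operates on the two
#' slices jointly min-max normalized (distances are fed in mm,
#' unnormalized); the residual is mapped back to the input intensity range,
#' so a zeroed head reproduces `y_lin` bit for bit. When `clip = TRUE`
#' (default) the result is clipped to the observed intensity range of
#' `x1`/`x2` (a no-op for the pure linear baseline).
#'
#' @param q an [impute_query()].
#' @param net a trained `slab_unet`.
#' @param clip clip the prediction to the observed intensity range.
#' @return 2D matrix (same shape as the inputs).
#' @export
impute_slice <- function(q, net, clip = TRUE) {
  stopifnot(inherits(q, "impute_query"), inherits(net, "slab_unet"))
  ylin <- linear_interpolate(q)
  rng <- query_norm_range(q)
  den <- rng[2] - rng[1]
  if (den <= 0) return(ylin)  # constant inputs: baseline is exact
  qn <- impute_query((q$x1 - rng[1]) / den, (q$x2 - rng[1]) / den, q$d1, q$d2)
  S <- unet_forward(net, assemble_input(qn))
  yhat <- ylin + den * S
  if (clip) yhat <- pmin(pmax(yhat, rng[1]), rng[2])
  yhat
}

#' Save / load a network checkpoint
#'
#' The checkpoint is a single-file archive holding the full parameter set
#' together with the architecture metadata, a format version field, and an
#' optional training-configuration hash; save/load round trips reproduce
#' forward outputs bit-exactly.
#'
#' @param net a `slab_unet`.
#' @param path destination file.
#' @param config_hash optional hash (or any identifier) of the training
#'   configuration stored alongside the weights.
#' @export
save_checkpoint <- function(net, path, config_hash = NULL) {
  stopifnot(inherits(net, "slab_unet"))
  obj <- list(format = "slabimpute-checkpoint", version = 1L,
              params = unet_export_cpp(net$ptr),
              config_hash = config_hash,
              created = format(Sys.time(), tz = "UTC"))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- tryCatch(suppressWarnings(readRDS(path)), error = function(e)
    format_error(sprintf("cannot read checkpoint %s: %s", path,
                         conditionMessage(e))))
  if (!identical(obj$format, "slabimpute-checkpoint") || is.null(obj$version))
    format_error("not a slabimpute checkpoint file")
  net <- structure(list(ptr = unet_import_cpp(obj$params)), class = "slab_unet")
  attr(net, "config_hash") <- obj$config_hash
  net
}

#' Deep-copy a network, optionally zeroing the output head
#'
#' A zero-head clone predicts the pure linear baseline and is the frozen
#' reference against which trained networks are compared.
#'
#' @param net a `slab_unet`.
#' @param zero_head zero the head of the copy.
#' @export
unet_clone <- function(net, zero_head = FALSE) {
  stopifnot(inherits(net, "slab_unet"))
  out <- structure(list(ptr = unet_import_cpp(unet_export_cpp(net$ptr))),
                   class = "slab_unet")
  if (zero_head) unet_zero_head(out)
  out
}
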