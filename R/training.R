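#' Min-max normalization of a slice
#'
#' `(v - min) / (max - min)`; a constant slice maps to all zeros (documented
#' degenerate rule, shared by every normalization step in the package).
#'
#' @param x numeric matrix or array.
#' @export
minmax_normalize <- function(x) {
  lo <- min(x); hi <- max(x)
  if (hi <= lo) return(array(0, dim = dim(x)))
  (x - lo) / (hi - lo)
}

sobel_kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)  # d/dcolumn
sobel_ky <- t(sobel_kx)                                    # d/drow

# edge-replicating 1-pixel pad
pad_edge_r <- function(x) {
  h <- nrow(x); w <- ncol(x)
  x[c(1, seq_len(h), h), c(1, seq_len(w), w)]
}

#' Sobel gradient magnitude
#'
#' `sqrt(Gx^2 + Gy^2)` with the standard 3x3 Sobel kernels (applied as
#' correlation masks), boundaries handled by edge reflection.
#'
#' @param x 2D numeric matrix with both dimensions >= 3.
#' @return nonnegative matrix of the same shape.
#' @export
sobel_gradient_magnitude <- function(x) {
  stopifnot(is.matrix(x), nrow(x) >= 3, ncol(x) >= 3)
  p <- pad_edge_r(x)
  h <- nrow(x); w <- ncol(x)
  gx <- matrix(0, h, w); gy <- matrix(0, h, w)
  for (dj in 0:2) {
    for (di in 0:2) {
      blk <- p[di + seq_len(h), dj + seq_len(w)]
      gx <- gx + sobel_kx[di + 1, dj + 1] * blk
      gy <- gy + sobel_ky[di + 1, dj + 1] * blk
    }
  }
  sqrt(gx^2 + gy^2)
}

#' Imputation training loss
#'
#' `MAE(norm(yhat), norm(y)) + lambda * MAE(sobel(norm(yhat)), sobel(norm(y)))`
#' where `norm` is per-slice min-max normalization ([minmax_normalize()]).
#' Zero if and only if the normalized slices are identical. Setting
#' `normalize = FALSE` skips the normalization (useful for testing the raw
#' MAE behaviour, e.g. under constant offsets that normalization removes).
#'
#' @param yhat,y numeric matrices of identical shape.
#' @param lambda weight of the gradient-magnitude term.
#' @param normalize apply per-slice min-max normalization first.
#' @return scalar loss.
#' @export
imputation_loss <- function(yhat, y, lambda = 1, normalize = TRUE) {
  stopifnot(all(dim(yhat) == dim(y)), lambda >= 0)
  if (normalize) {
    yhat <- minmax_normalize(yhat)
    y <- minmax_normalize(y)
  }
  loss <- mean(abs(yhat - y))
  if (lambda > 0)
    loss <- loss + lambda * mean(abs(sobel_gradient_magnitude(yhat) -
                                       sobel_gradient_magnitude(y)))
  loss
}

# pack a list of slab_triplets into the arrays the C++ engine consumes:
# the whole triplet is normalized into the joint x1/x2 min-max frame (the
# same affine map a query sees at inference), y_lin is computed there, and
# the training loss compares prediction and target in that shared frame.
prep_triplet_batch <- function(triplets) {
  n <- length(triplets)
  h <- nrow(triplets[[1]]$x1); w <- ncol(triplets[[1]]$x1)
  x <- array(0, dim = c(h, w, 4L * n))
  ylin <- array(0, dim = c(h, w, n))
  y <- array(0, dim = c(h, w, n))
  for (i in seq_len(n)) {
    tr <- triplets[[i]]
    lo <- min(tr$x1, tr$x2); hi <- max(tr$x1, tr$x2)
    den <- hi - lo
    if (den > 0) {
      x1 <- (tr$x1 - lo) / den
      x2 <- (tr$x2 - lo) / den
      yt <- (tr$y - lo) / den
    } else {
      x1 <- matrix(0, h, w); x2 <- matrix(0, h, w)
      yt <- matrix(0, h, w)
    }
    k <- 4L * (i - 1L)
    x[, , k + 1] <- x1
    x[, , k + 2] <- x2
    x[, , k + 3] <- tr$d1
    x[, , k + 4] <- tr$d2
    d <- tr$d1 + tr$d2
    ylin[, , i] <- (tr$d2 / d) * x1 + (tr$d1 / d) * x2
    y[, , i] <- yt
  }
  list(x = x, ylin = ylin, y = y, h = h, w = w, n = n)
}

#' Validation MAE
#'
#' Mean, over a frozen set of synthetic triplets, of the mean absolute error
#' between the min-max normalized imputed slice and the min-max normalized
#' target. `net = NULL` evaluates the frozen linear baseline (zero
#' residual), the reference a trained network must undercut.
#'
#' @param net a `slab_unet` or `NULL` for the linear baseline.
#' @param triplets list of `slab_triplet`s (see [make_minibatch()]).
#' @return scalar mean MAE.
#' @export
validate <- function(net, triplets) {
  if (length(triplets) == 0) stop("empty validation set")
  b <- prep_triplet_batch(triplets)
  if (is.null(net)) {
    maes <- vapply(seq_len(b$n), function(i) {
      mean(abs(minmax_normalize(b$ylin[, , i]) - minmax_normalize(b$y[, , i])))
    }, numeric(1))
    return(mean(maes))
  }
  stopifnot(inherits(net, "slab_unet"))
  res <- unet_eval_loss_cpp(net$ptr, b$x, b$ylin, b$y, b$h, b$w, b$n, 0)
  mean(res$mae)
}

#' Build a training generator from label volumes
#'
#' Returns a closure producing one minibatch per call: it picks a label
#' volume at random, synthesizes a fresh domain-randomized volume
#' ([generate_synthetic_volume()]) and digitally slabs it into
#' `config$minibatch` triplets — i.e. one new synthetic volume per training
#' iteration.
#'
#' @param label_volumes list of [label_volume()]s.
#' @param config a [synth_config()].
#' @export
training_generator <- function(label_volumes, config) {
  stopifnot(length(label_volumes) >= 1,
            all(vapply(label_volumes, inherits, logical(1), "label_volume")))
  force(config)
  function() {
    lv <- label_volumes[[sample.int(length(label_volumes), 1)]]
    sv <- generate_synthetic_volume(lv, config)
    make_minibatch(sv$image, config)
  }
}

#' Train the residual network
#'
#' Adam optimization of the combined MAE + Sobel-gradient MAE loss on
#' minibatches drawn from `generator`. A frozen validation set of
#' `config$val_size` synthetic slices is generated up front (from the same
#' generator, under the run seed); the parameters achieving the best
#' validation MAE are checkpointed and returned. The initial parameters are
#' validated as checkpoint 0, so the result is never worse than the
#' starting point (for the default zero-head init: the linear baseline) on
#' the validation set. Training stops at
#' `config$max_iter` or when no validation improvement larger than
#' `config$min_delta` has been seen for `config$patience` consecutive
#' checks. A non-finite loss aborts with a diagnostic dump of the iteration
#' state. With fixed seeds the run is bit-reproducible on the same
#' hardware and thread settings.
#'
#' @param generator a function returning a list of `slab_triplet`s per call
#'   (see [training_generator()]).
#' @param net an initialized `slab_unet`; modified in place, and the best
#'   checkpoint is additionally returned as a fresh network.
#' @param config a [train_config()].
#' @return list with `net` (best-validation parameters), `history`
#'   (data.frame of per-iteration losses), `validation` (data.frame of
#'   per-check validation MAE) and `best_val`.
#' @export
train <- function(generator, net, config) {
  stopifnot(is.function(generator), inherits(net, "slab_unet"),
            inherits(config, "train_config"))
  set.seed(config$seed)
  history <- data.frame(iter = integer(), loss = numeric(),
                        mae = numeric(), grad_mae = numeric())
  if (config$max_iter == 0)
    return(list(net = net, history = history,
                validation = data.frame(iter = integer(), val_mae = numeric()),
                best_val = NA_real_))

  # frozen validation set
  val <- list()
  while (length(val) < config$val_size)
    val <- c(val, generator())
  val <- val[seq_len(config$val_size)]

  # validate the initial parameters as checkpoint 0: with the zero-head
  # init this is exactly the linear baseline, so training can only return
  # parameters at least as good as the starting point on the validation set
  best_val <- validate(net, val)
  best_params <- unet_export_cpp(net$ptr)
  last_progress_val <- best_val
  stale <- 0L
  vlog <- data.frame(iter = 0L, val_mae = best_val)

  for (it in seq_len(config$max_iter)) {
    batch <- generator()
    if (length(batch) != config$batch)
      batch <- batch[seq_len(min(length(batch), config$batch))]
    b <- prep_triplet_batch(batch)
    st <- unet_train_step_cpp(net$ptr, b$x, b$ylin, b$y, b$h, b$w, b$n,
                              config$lr, config$lambda, 0.9, 0.999, 1e-8)
    if (!is.finite(st$loss)) {
      stop(sprintf(paste0(
        "non-finite loss at iteration %d (mae=%g, grad_mae=%g); ",
        "last validation MAE %g"), it, st$mae, st$grad_mae,
        if (nrow(vlog)) vlog$val_mae[nrow(vlog)] else NA))
    }
    history[nrow(history) + 1L, ] <- list(it, st$loss, st$mae, st$grad_mae)
    if (it %% config$val_interval == 0 || it == config$max_iter) {
      v <- validate(net, val)
      vlog[nrow(vlog) + 1L, ] <- list(it, v)
      if (v < best_val) {
        best_val <- v
        best_params <- unet_export_cpp(net$ptr)
      }
      if (v < last_progress_val - config$min_delta) {
        last_progress_val <- v
        stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= config$patience) {
          slab_log("info", sprintf("stopping at iteration %d (patience)", it))
          break
        }
      }
    }
  }
  best_net <- if (is.null(best_params)) unet_clone(net) else
    structure(list(ptr = unet_import_cpp(best_params)), class = "slab_unet")
  list(net = best_net, history = history, validation = vlog,
       best_val = best_val)
}
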