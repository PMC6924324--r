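# The fully convolutional tissue classifier.
#
# Architecture (fixed): seven convolutions with ReLU activations except for a
# final two-channel softmax, with 2x2/2 max pooling after each of the first
# three convolutions, for a total downsampling factor of 8:
#
#   layer  type  kernel  stride  filters
#   0      conv  5x5     1       16
#   1      pool  2x2     2
#   2      conv  5x5     1       32
#   3      pool  2x2     2
#   4      conv  3x3     1       64
#   5      pool  2x2     2
#   6      conv  3x3     1       64
#   7      conv  3x3     1       1024
#   8      conv  1x1     1       512
#   9      conv  1x1     1       2 (softmax)
#
# Convolutions are zero-padded ("same"), so a 128 x 128 patch yields a
# 16 x 16 two-channel probability map. Weight matrices are stored as
# (filters) x (in_channels * k * k) with column index c + C*(ky + k*kx).

FCNN_KS <- c(5L, 5L, 3L, 3L, 3L, 1L, 1L)
FCNN_CIN <- c(3L, 16L, 32L, 64L, 64L, 1024L, 512L)
FCNN_COUT <- c(16L, 32L, 64L, 64L, 1024L, 512L, 2L)
FCNN_DOWNSAMPLE <- 8L
FCNN_RECEPTIVE_FIELD <- 60L

#' Network layer specification
#'
#' @return Data frame describing the fixed architecture, one row per
#'   convolution, with kernel size, input and output channels.
#' @export
network_spec <- function() {
  data.frame(layer = seq_along(FCNN_KS) - 1L, kernel = FCNN_KS,
             channels_in = FCNN_CIN, channels_out = FCNN_COUT,
             pool_after = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
}

#' Build a randomly initialised network
#'
#' Weights follow the He initialisation: zero-mean Gaussian with standard
#' deviation `sqrt(2 / fan_in)`; biases start at zero. Two builds with the
#' same seed produce identical weights.
#'
#' @param seed Integer seed for the weight initialisation.
#' @return An `fcnn_model` with elements `W` (list of 7 weight matrices),
#'   `b` (list of 7 bias vectors) and `spec`.
#' @export
build_network <- function(seed = 1L) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  W <- vector("list", 7L)
  b <- vector("list", 7L)
  for (l in 1:7) {
    fan_in <- FCNN_CIN[l] * FCNN_KS[l]^2
    W[[l]] <- matrix(rnorm(FCNN_COUT[l] * fan_in, sd = sqrt(2 / fan_in)),
                     FCNN_COUT[l], fan_in)
    b[[l]] <- numeric(FCNN_COUT[l])
  }
  structure(list(W = W, b = b, spec = network_spec(), seed = as.integer(seed)),
            class = "fcnn_model")
}

#' @export
print.fcnn_model <- function(x, ...) {
  np <- sum(vapply(x$W, length, numeric(1))) + sum(vapply(x$b, length, numeric(1)))
  cat(sprintf("fcnn_model: 7 conv layers, %s parameters\n",
              format(np, big.mark = ",")))
  invisible(x)
}

#' Forward pass of the network
#'
#' @param model An `fcnn_model`.
#' @param x `(H, W, 3, N)` array (sides multiples of 8) or a single
#'   `(H, W, 3)` patch.
#' @return `(H/8, W/8, 2, N)` array of softmax probabilities; channel 2 is
#'   the tissue probability.
#' @export
fcnn_forward <- function(model, x) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  .cpp_fcnn_forward(x, model$W, model$b)
}

#' Training configuration
#'
#' Defaults reproduce the full training protocol; the iteration counts are
#' scalable down for desk-scale runs. The class sampling weights follow the
#' (edge, artifacts, background, external margin, internal margin, tissue) =
#' (1, 1, 1, 1, 5, 1) distribution that oversamples the ambiguous inner
#' border band.
#'
#' @param patch_size Patch side in pixels.
#' @param batch_size Patches per iteration.
#' @param train_iterations,val_iterations Iterations per epoch.
#' @param max_epochs Upper bound on epochs (full protocol runs until early
#'   stopping).
#' @param initial_lr Initial Adam learning rate.
#' @param lr_halving_patience Epochs without improvement before the learning
#'   rate is halved.
#' @param stop_patience Epochs without improvement before training stops.
#' @param l2_lambda L2 regularisation weight.
#' @param class_weights Sampling weights for the six mask labels.
#' @param spacings Source pixel spacings (um); a single value trains a
#'   single-level network, several values a multi-level one (the source
#'   level is drawn uniformly per patch).
#' @param improvement_tol Minimal increase in mean validation accuracy that
#'   counts as improvement.
#' @param augment Apply the augmentation pipeline during training.
#' @param seed Seed for sampling, augmentation and initialisation.
#' @return A `train_config` object.
#' @export
train_config <- function(patch_size = 128L, batch_size = 32L,
                         train_iterations = 25600L, val_iterations = 6400L,
                         max_epochs = 1000L, initial_lr = 1e-4,
                         lr_halving_patience = 4L, stop_patience = 16L,
                         l2_lambda = 1e-5,
                         class_weights = c(edge = 1, artifacts = 1,
                                           background = 1, external_margin = 1,
                                           internal_margin = 5, tissue = 1),
                         spacings = c(0.5, 1, 2, 4, 8),
                         improvement_tol = 1e-4, augment = TRUE, seed = 1L) {
  stopifnot(patch_size %% 8L == 0L, all(class_weights > 0),
            all(spacings > 0))
  structure(list(patch_size = as.integer(patch_size),
                 batch_size = as.integer(batch_size),
                 train_iterations = as.integer(train_iterations),
                 val_iterations = as.integer(val_iterations),
                 max_epochs = as.integer(max_epochs),
                 initial_lr = initial_lr,
                 lr_halving_patience = as.integer(lr_halving_patience),
                 stop_patience = as.integer(stop_patience),
                 l2_lambda = l2_lambda,
                 class_weights = class_weights,
                 spacings = spacings,
                 improvement_tol = improvement_tol,
                 augment = isTRUE(augment),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Prepare a patch sampler for one slide
#'
#' Precomputes the pixel index lists of every mask label at every requested
#' spacing so patches can be drawn in O(1).
#'
#' @param pyramid The slide's `image_pyramid`.
#' @param annotations Cleaned `annotation_set`, or a precomputed list of
#'   `sampling_mask` objects (one per spacing).
#' @param spacings Pixel spacings (um) patches may be drawn from.
#' @return A `patch_sampler` object.
#' @export
patch_sampler <- function(pyramid, annotations, spacings = c(0.5, 1, 2, 4, 8)) {
  masks <- if (is_annotation_set(annotations)) {
    lapply(spacings, function(s) make_sampling_mask(annotations, pyramid, s))
  } else {
    annotations
  }
  idx <- lapply(masks, function(m) {
    lapply(seq_along(MASK_LABELS), function(l) which(m$data == l))
  })
  structure(list(pyramid = pyramid, masks = masks, index = idx,
                 spacings = spacings),
            class = "patch_sampler")
}

# Remembers which absent-class warnings were already emitted this session.
.sampling_notes <- new.env(parent = emptyenv())

# Draw n class labels according to the weight distribution restricted to the
# classes present in mask `mi` of the sampler.
draw_classes <- function(sampler, mi, weights, n) {
  present <- which(vapply(sampler$index[[mi]], length, integer(1)) > 0L)
  if (!length(present)) stop("sampling mask has no labelled pixels")
  w <- weights[present]
  missing <- setdiff(seq_along(MASK_LABELS), present)
  if (length(missing) && n > 0L) {
    # absent classes are excluded and the remaining weights renormalised;
    # log once per combination to keep training output readable
    key <- paste(missing, collapse = ",")
    if (is.null(.sampling_notes[[key]])) {
      .sampling_notes[[key]] <- TRUE
      message("classes absent from mask, renormalising weights: ",
              paste(names(MASK_LABELS)[missing], collapse = ", "))
    }
  }
  if (length(present) == 1L) rep(present, n)
  else sample(present, n, replace = TRUE, prob = w / sum(w))
}

#' Sample one training patch
#'
#' A mask label is drawn with probability proportional to its weight among
#' the labels present, a pixel of that label is drawn uniformly, and the RGB
#' window centred on it is extracted together with the binary (tissue /
#' non-tissue) label window. Windows reaching past the slide extent are
#' padded with white pixels and background labels.
#'
#' @param sampler A `patch_sampler`.
#' @param weights Sampling weights for the six labels.
#' @param patch_size Window side in pixels.
#' @param spacing_index Index into the sampler's spacings (drawn uniformly
#'   when `NULL` and several spacings are configured).
#' @param class_label Fix the drawn label (internal use).
#' @return List with `patch` (`(s, s, 3)` array), `labels` (binary `s x s`
#'   matrix), `class` (drawn label code), `spacing`, `center` (`(x, y)`).
#' @export
sample_patch <- function(sampler, weights = c(1, 1, 1, 1, 5, 1),
                         patch_size = 128L, spacing_index = NULL,
                         class_label = NULL) {
  stopifnot(inherits(sampler, "patch_sampler"))
  mi <- spacing_index %||% if (length(sampler$spacings) > 1L) {
    sample.int(length(sampler$spacings), 1L)
  } else 1L
  cl <- class_label %||% draw_classes(sampler, mi, weights, 1L)
  pool <- sampler$index[[mi]][[cl]]
  p <- pool[sample.int(length(pool), 1L)]
  msk <- sampler$masks[[mi]]
  H <- nrow(msk$data)
  cy <- (p - 1L) %% H
  cx <- (p - 1L) %/% H
  half <- patch_size %/% 2L
  lv <- level_ref(msk$level_index, msk$spacing)
  patch <- read_region(sampler$pyramid, lv,
                       origin = c(cx - half, cy - half),
                       size = c(patch_size, patch_size))
  lab <- matrix(MASK_LABELS[["background"]], patch_size, patch_size)
  rr <- intersect(seq.int(cy - half, cy + half - 1L), 0:(H - 1L))
  cc <- intersect(seq.int(cx - half, cx + half - 1L),
                  0:(ncol(msk$data) - 1L))
  lab[rr - (cy - half) + 1L, cc - (cx - half) + 1L] <-
    msk$data[rr + 1L, cc + 1L]
  bin <- to_binary(lab, spacing = msk$spacing)$data
  list(patch = patch, labels = bin, class = cl, spacing = msk$spacing,
       center = c(cx, cy))
}

# Dense training target: the binary label patch pooled 8x with a majority
# rule (a cell is tissue when at least half of its 8x8 pixels are tissue),
# which keeps the decision boundary centred on the annotated border.
pool_labels <- function(labels, factor = FCNN_DOWNSAMPLE) {
  H <- nrow(labels) %/% factor
  W <- ncol(labels) %/% factor
  s <- matrix(0, H, W)
  for (dy in seq_len(factor)) {
    for (dx in seq_len(factor)) {
      s <- s + labels[seq(dy, by = factor, length.out = H),
                      seq(dx, by = factor, length.out = W)]
    }
  }
  (s >= factor^2 / 2) + 0L
}

# Assemble one mini-batch from a list of samplers.
make_batch <- function(samplers, config, rng_augment = config$augment) {
  ps <- config$patch_size
  x <- array(0, dim = c(ps, ps, 3L, config$batch_size))
  y <- array(0L, dim = c(ps %/% 8L, ps %/% 8L, config$batch_size))
  multi <- length(config$spacings) > 1L
  for (i in seq_len(config$batch_size)) {
    s <- samplers[[sample.int(length(samplers), 1L)]]
    si <- if (multi) sample.int(length(s$spacings), 1L) else 1L
    if (rng_augment) {
      prm <- random_augmentation_params()
      src <- round(ps * prm$z / 2) * 2L # even source window
      smp <- sample_patch(s, config$class_weights, patch_size = src,
                          spacing_index = si)
      aug <- augment_patch(smp$patch, smp$labels, prm, out_size = ps)
      x[, , , i] <- aug$patch
      y[, , i] <- pool_labels(aug$labels)
    } else {
      smp <- sample_patch(s, config$class_weights, patch_size = ps,
                          spacing_index = si)
      x[, , , i] <- smp$patch
      y[, , i] <- pool_labels(smp$labels)
    }
  }
  list(x = x, y = y)
}

adam_init <- function(model) {
  list(mW = lapply(model$W, function(w) w * 0),
       vW = lapply(model$W, function(w) w * 0),
       mb = lapply(model$b, function(v) v * 0),
       vb = lapply(model$b, function(v) v * 0),
       t = 0L)
}

adam_update <- function(model, grads, state, lr, l2_lambda,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (l in 1:7) {
    gw <- grads$grad_w[[l]] + l2_lambda * model$W[[l]]
    state$mW[[l]] <- beta1 * state$mW[[l]] + (1 - beta1) * gw
    state$vW[[l]] <- beta2 * state$vW[[l]] + (1 - beta2) * gw^2
    model$W[[l]] <- model$W[[l]] -
      lr * (state$mW[[l]] / bc1) / (sqrt(state$vW[[l]] / bc2) + eps)
    gb <- grads$grad_b[[l]]
    state$mb[[l]] <- beta1 * state$mb[[l]] + (1 - beta1) * gb
    state$vb[[l]] <- beta2 * state$vb[[l]] + (1 - beta2) * gb^2
    model$b[[l]] <- model$b[[l]] -
      lr * (state$mb[[l]] / bc1) / (sqrt(state$vb[[l]] / bc2) + eps)
  }
  list(model = model, state = state)
}

#' Train the fully convolutional network
#'
#' Adam optimisation of the categorical cross entropy with L2 regularisation.
#' The mean validation accuracy is monitored per epoch: after
#' `lr_halving_patience` consecutive epochs without improvement the learning
#' rate is halved, and after `stop_patience` such epochs training stops; the
#' weights of the best validation epoch are returned. For multi-level
#' configurations the source level of every patch is drawn uniformly from
#' the configured spacings.
#'
#' @param config A `train_config`.
#' @param train_samplers,val_samplers Lists of `patch_sampler` objects for
#'   the training and validation slides.
#' @param verbose Print one line per epoch.
#' @return List with `model` (best-validation `fcnn_model`) and `history`
#'   (data frame: epoch, loss, validation accuracy, learning rate).
#' @export
train_fcnn <- function(config, train_samplers, val_samplers, verbose = FALSE) {
  stopifnot(inherits(config, "train_config"))
  if (!length(train_samplers) || !length(val_samplers)) {
    stop("training and validation sets must be non-empty")
  }
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)
  model <- build_network(seed = sample.int(.Machine$integer.max, 1L))
  state <- adam_init(model)
  lr <- config$initial_lr
  best_acc <- -Inf
  best_model <- model
  stagnant <- 0L
  history <- list()
  for (epoch in seq_len(config$max_epochs)) {
    tr_loss <- 0
    for (it in seq_len(config$train_iterations)) {
      batch <- make_batch(train_samplers, config)
      step <- .cpp_fcnn_train_step(batch$x, batch$y, model$W, model$b)
      upd <- adam_update(model, step, state, lr, config$l2_lambda)
      model <- upd$model
      state <- upd$state
      tr_loss <- tr_loss + step$loss
    }
    val_acc <- 0
    for (it in seq_len(config$val_iterations)) {
      batch <- make_batch(val_samplers, config, rng_augment = FALSE)
      p <- .cpp_fcnn_forward(batch$x, model$W, model$b)
      pred <- (p[, , 2, ] > p[, , 1, ]) + 0L
      val_acc <- val_acc + mean(pred == as.vector(batch$y))
    }
    val_acc <- val_acc / config$val_iterations
    history[[epoch]] <- data.frame(
      epoch = epoch, train_loss = tr_loss / config$train_iterations,
      val_accuracy = val_acc, lr = lr)
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  val acc %.4f  lr %.2e",
                      epoch, tr_loss / config$train_iterations, val_acc, lr))
    }
    if (val_acc > best_acc + config$improvement_tol) {
      best_acc <- val_acc
      best_model <- model
      stagnant <- 0L
    } else {
      stagnant <- stagnant + 1L
      if (stagnant %% config$lr_halving_patience == 0L) lr <- lr / 2
      if (stagnant >= config$stop_patience) break
    }
  }
  list(model = best_model, history = do.call(rbind, history))
}

#' Save / load a model checkpoint
#'
#' @param model An `fcnn_model`.
#' @param path Checkpoint file path.
#' @return `path` invisibly; `load_checkpoint` returns the model.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "fcnn_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "fcnn_model")) stop("not an fcnn_model checkpoint")
  m
}
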