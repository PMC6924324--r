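# Patch augmentation pipeline.
#
# Steps, applied in this order with per-patch parameters drawn uniformly
# from the stated ranges: horizontal mirroring; 90-degree rotations; scaling
# z in (0.75, 1.25); hue shift h in (-1, 1) mapped to h * 180 degrees on the
# hue circle (so the full circle is reachable); saturation offset s in
# (-0.25, 0.25); brightness offset b in (-0.25, 0.25); contrast c in
# (-0.25, 0.25); additive Gaussian noise sigma_a in (0, 0.05); Gaussian
# blur sigma_b in (0, 1). Geometric steps transform the patch and its label
# window identically; photometric steps touch the patch only. Hue shifting
# rotates every color by the same angle, leaving pairwise hue distances
# unchanged, which forces the trained network to ignore the absolute stain
# color.

#' Augmentation parameters
#'
#' @param mirror Mirror horizontally (logical).
#' @param rotation One of 0, 90, 180, 270 (degrees).
#' @param z Scale factor in `(0.75, 1.25)`.
#' @param h Hue shift in `(-1, 1)` (fraction of a half-turn).
#' @param s Saturation offset in `(-0.25, 0.25)`.
#' @param b Brightness offset in `(-0.25, 0.25)`.
#' @param c Contrast adjustment in `(-0.25, 0.25)`.
#' @param noise_sd Additive Gaussian noise sigma in `(0, 0.05)`.
#' @param blur_sd Gaussian blur sigma in `(0, 1)` pixels.
#' @return An `augmentation_params` object.
#' @export
augmentation_params <- function(mirror = FALSE, rotation = 0, z = 1,
                                h = 0, s = 0, b = 0, c = 0,
                                noise_sd = 0, blur_sd = 0) {
  if (!rotation %in% c(0, 90, 180, 270)) stop("rotation must be a multiple of 90")
  if (z < 0.75 || z > 1.25) stop("scale z out of range (0.75, 1.25)")
  if (abs(h) > 1) stop("hue shift out of range (-1, 1)")
  if (abs(s) > 0.25) stop("saturation offset out of range (-0.25, 0.25)")
  if (abs(b) > 0.25) stop("brightness offset out of range (-0.25, 0.25)")
  if (abs(c) > 0.25) stop("contrast adjustment out of range (-0.25, 0.25)")
  if (noise_sd < 0 || noise_sd > 0.05) stop("noise sigma out of range (0, 0.05)")
  if (blur_sd < 0 || blur_sd > 1) stop("blur sigma out of range (0, 1)")
  structure(list(mirror = isTRUE(mirror), rotation = rotation, z = z,
                 h = h, s = s, b = b, c = c, noise_sd = noise_sd,
                 blur_sd = blur_sd),
            class = "augmentation_params")
}

#' Draw random augmentation parameters
#'
#' Uniform draws from the configured ranges.
#' @return An `augmentation_params` object.
#' @export
random_augmentation_params <- function() {
  augmentation_params(
    mirror = runif(1) < 0.5,
    rotation = sample(c(0, 90, 180, 270), 1L),
    z = runif(1, 0.75, 1.25),
    h = runif(1, -1, 1),
    s = runif(1, -0.25, 0.25),
    b = runif(1, -0.25, 0.25),
    c = runif(1, -0.25, 0.25),
    noise_sd = runif(1, 0, 0.05),
    blur_sd = runif(1, 0, 1))
}

rot90_mat <- function(m) t(m)[, nrow(m):1, drop = FALSE]

rot90_arr <- function(a, times) {
  times <- times %% 4L
  for (k in seq_len(times)) {
    a <- if (length(dim(a)) == 3L) {
      aperm(a, c(2, 1, 3))[, dim(a)[1]:1, , drop = FALSE]
    } else {
      rot90_mat(a)
    }
  }
  a
}

# Vectorised HSV -> RGB (h, s, v in [0, 1]).
hsv_to_rgb <- function(h, s, v) {
  n <- max(length(h), length(s), length(v))
  h <- rep_len(h, n); s <- rep_len(s, n); v <- rep_len(v, n)
  h6 <- (h %% 1) * 6
  i <- as.integer(h6) %% 6L
  f <- h6 - as.integer(h6)
  p <- v * (1 - s)
  q <- v * (1 - f * s)
  t <- v * (1 - (1 - f) * s)
  r <- v; g <- v; b <- v
  m <- i == 0L; g[m] <- t[m]; b[m] <- p[m]
  m <- i == 1L; r[m] <- q[m]; b[m] <- p[m]
  m <- i == 2L; r[m] <- p[m]; b[m] <- t[m]
  m <- i == 3L; r[m] <- p[m]; g[m] <- q[m]
  m <- i == 4L; r[m] <- t[m]; g[m] <- p[m]
  m <- i == 5L; g[m] <- p[m]; b[m] <- q[m]
  cbind(r, g, b)
}

# Hue / saturation / brightness adjustment of an (H, W, 3) patch in [0, 1].
adjust_hsb <- function(patch, h_shift, s_off, b_off) {
  d <- dim(patch)
  m <- matrix(patch, ncol = 3L)
  hsv <- rgb2hsv(t(m), maxColorValue = 1)
  hh <- (hsv[1, ] + h_shift * 0.5) %% 1
  ss <- pmin(pmax(hsv[2, ] + s_off, 0), 1)
  vv <- pmin(pmax(hsv[3, ] + b_off, 0), 1)
  array(hsv_to_rgb(hh, ss, vv), dim = d)
}

#' Apply an augmentation to a patch and its label window
#'
#' Geometric steps (mirror, rotation, scaling) transform patch and labels
#' identically (labels with nearest-neighbour resampling); photometric steps
#' apply to the patch only. Scaling is realised by resampling the source
#' window (of side `round(out_size * z)`) to `out_size` pixels, so the output
#' patch always measures `out_size`.
#'
#' @param patch `(n, n, 3)` RGB array in `[0, 1]`.
#' @param labels `n x n` binary label matrix.
#' @param params An `augmentation_params` object.
#' @param out_size Output side length; by default the input side divided by
#'   the scale factor `z` (so the training loop samples a `round(128 z)`
#'   window and receives a 128-pixel patch back).
#' @return List with the augmented `patch` and `labels`.
#' @export
augment_patch <- function(patch, labels, params, out_size = NULL) {
  stopifnot(inherits(params, "augmentation_params"))
  out_size <- as.integer(out_size %||% round(dim(patch)[1] / params$z))
  if (params$mirror) {
    patch <- patch[, dim(patch)[2]:1, , drop = FALSE]
    labels <- labels[, ncol(labels):1, drop = FALSE]
  }
  k <- params$rotation / 90
  patch <- rot90_arr(patch, k)
  labels <- rot90_arr(labels, k)
  if (dim(patch)[1] != out_size) {
    patch <- EBImage::resize(patch, w = out_size, h = out_size,
                             filter = "bilinear")
    labels <- EBImage::resize(labels, w = out_size, h = out_size,
                              filter = "none")
    labels <- (labels > 0.5) + 0L
  }
  if (params$h != 0 || params$s != 0 || params$b != 0) {
    patch <- adjust_hsb(patch, params$h, params$s, params$b)
  }
  if (params$c != 0) {
    patch <- pmin(pmax((patch - 0.5) * (1 + params$c) + 0.5, 0), 1)
  }
  if (params$noise_sd > 0) {
    patch <- patch + rnorm(length(patch), 0, params$noise_sd)
    patch <- pmin(pmax(patch, 0), 1)
  }
  if (params$blur_sd > 0) {
    patch <- EBImage::gblur(patch, sigma = params$blur_sd)
    patch <- pmin(pmax(patch, 0), 1)
  }
  dim(patch) <- c(out_size, out_size, 3L)
  list(patch = patch, labels = matrix(as.integer(labels), out_size, out_size))
}
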