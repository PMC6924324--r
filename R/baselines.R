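# Classical tissue segmenters used as references for the neural network:
# thresholding at a predefined grayscale value, Otsu's adaptive threshold,
# and foreground extraction from structure information (FESI).
#
# For both thresholding methods the tissue is the *dark* class (gray strictly
# below the threshold); the near-white slide background lies above it.
# Pixels exactly at the threshold count as background.

#' Convert an RGB raster to grayscale
#'
#' Unweighted mean of the red, green and blue channels.
#'
#' @param rgb `(H, W, 3)` array, doubles in `[0, 1]` or bytes `0..255`.
#' @return Matrix on the same intensity scale as the input.
#' @export
grayscale <- function(rgb) {
  d <- dim(rgb)
  if (length(d) != 3L || d[3] != 3L) stop("input must have exactly 3 channels")
  (rgb[, , 1] + rgb[, , 2] + rgb[, , 3]) / 3
}

#' Segment tissue by thresholding at a predefined grayscale value
#'
#' Grayscale (channel mean) pixels strictly below `threshold` become tissue;
#' the mask is then refined by filling all enclosed holes and a morphological
#' closing. The default threshold of 217 (8-bit scale) was tuned for maximum
#' Dice on validation slides; background white lies well above it. Apply
#' [postprocess()] to the result before evaluating, as for every method.
#'
#' @param image `(H, W, 3)` RGB array in `[0, 1]`.
#' @param spacing Pixel spacing in micrometres.
#' @param threshold Gray threshold on the 0-255 scale (default 217).
#' @param level_index 0-based level index, recorded in the mask.
#' @param refine Apply hole filling and closing (default TRUE); disable to
#'   obtain the raw threshold response.
#' @param closing_px Diameter of the closing disc in pixels.
#' @return A `binary_mask`.
#' @export
fixed_threshold_segment <- function(image, spacing, threshold = 217,
                                    level_index = NA_integer_, refine = TRUE,
                                    closing_px = 5L) {
  g <- grayscale(image) * 255
  m <- (g < threshold) + 0L
  if (refine && any(m == 1L) && any(m == 0L)) {
    m <- EBImage::fillHull(m)
    m <- EBImage::closing(m, EBImage::makeBrush(closing_px, shape = "disc"))
    m <- matrix(as.integer(m > 0), nrow(g), ncol(g))
  }
  binary_mask(m, spacing = spacing, level_index = level_index)
}

#' Otsu's threshold from a 256-bin grayscale histogram
#'
#' Returns the threshold level `t` that minimises the combined within-class
#' variance (equivalently maximises the between-class variance) of the split
#' gray < t versus gray >= t, scanning all 256 candidate levels. Ties are
#' broken toward the lowest level. A histogram with fewer than two non-empty
#' bins has no two classes to separate and raises an error.
#'
#' @param counts Integer vector of length 256: counts of gray levels 0..255.
#' @return The threshold as a gray level in `1..255`.
#' @export
otsu_threshold <- function(counts) {
  if (length(counts) != 256L) stop("histogram must have 256 bins")
  if (sum(counts > 0) < 2L) stop("degenerate histogram: fewer than 2 non-empty bins")
  counts <- as.numeric(counts)
  n <- sum(counts)
  lev <- 0:255
  csum <- cumsum(counts)            # pixels with gray < t for t = level + 1
  cmu <- cumsum(counts * lev)
  w0 <- csum / n
  mu0 <- ifelse(csum > 0, cmu / csum, 0)
  mu1 <- ifelse(n - csum > 0, (cmu[256] - cmu) / (n - csum), 0)
  between <- w0 * (1 - w0) * (mu0 - mu1)^2
  # candidate thresholds t = 1..255 split at index t (gray < t vs >= t)
  bc <- between[1:255]
  valid <- csum[1:255] > 0 & csum[1:255] < n
  bc[!valid] <- -Inf
  which.max(bc)                      # first (lowest) maximiser
}

#' Segment tissue with Otsu's adaptive threshold
#'
#' The image is converted to grayscale by channel averaging, the threshold is
#' estimated from its 256-bin histogram with [otsu_threshold()], and pixels
#' strictly below the threshold become tissue.
#'
#' @param image `(H, W, 3)` RGB array in `[0, 1]`.
#' @param spacing Pixel spacing in micrometres.
#' @param level_index 0-based level index.
#' @return A `binary_mask`.
#' @export
otsu_segment <- function(image, spacing, level_index = NA_integer_) {
  g <- pmin(pmax(round(grayscale(image) * 255), 0), 255)
  counts <- tabulate(as.vector(g) + 1L, nbins = 256L)
  t <- otsu_threshold(counts)
  binary_mask((g < t) + 0L, spacing = spacing, level_index = level_index)
}

#' FESI parameters
#'
#' Kernel sizes and the two seed-selection constants of the foreground
#' extraction from structure information algorithm. The 100/100 seed rule is
#' fixed by the method's definition; the kernels are implementation choices
#' exposed for tuning.
#'
#' @param seed_accept_distance Distance-transform value (pixels) above which
#'   a seed is accepted outright (default 100).
#' @param seed_proximity Distance (pixels) to a previously accepted seed
#'   within which a seed is also accepted (default 100).
#' @param gaussian_sigma Sigma of the Gaussian blur of the Laplacian image.
#' @param median_size Half-width of the median filter window.
#' @param opening_px Diameter of the opening disc in pixels.
#' @return A `fesi_params` object.
#' @export
fesi_params <- function(seed_accept_distance = 100, seed_proximity = 100,
                        gaussian_sigma = 2, median_size = 2L,
                        opening_px = 5L) {
  stopifnot(seed_accept_distance > 0, seed_proximity > 0,
            gaussian_sigma > 0, median_size > 0, opening_px > 0)
  structure(list(seed_accept_distance = seed_accept_distance,
                 seed_proximity = seed_proximity,
                 gaussian_sigma = gaussian_sigma,
                 median_size = as.integer(median_size),
                 opening_px = as.integer(opening_px)),
            class = "fesi_params")
}

#' Segment tissue by foreground extraction from structure information
#'
#' Edge-based detector: the absolute Laplacian of the grayscale image is
#' Gaussian-blurred and thresholded at its global mean, refined by median
#' blurring and morphological opening, and the background is selected by
#' flood filling from the point farthest from any foreground structure
#' (which also fills holes in the tissue). Finally small regions are pruned
#' by iterating over the maxima of the distance transform: the point with
#' the maximal distance value is taken as a seed and accepted if its value
#' exceeds `seed_accept_distance` or lies within `seed_proximity` pixels of
#' a previously accepted seed; the regions of rejected seeds are removed.
#'
#' @param image `(H, W, 3)` RGB array in `[0, 1]`.
#' @param spacing Pixel spacing in micrometres.
#' @param params A `fesi_params` object.
#' @param level_index 0-based level index.
#' @return A `binary_mask`.
#' @export
fesi_segment <- function(image, spacing, params = fesi_params(),
                         level_index = NA_integer_) {
  stopifnot(inherits(params, "fesi_params"))
  g <- grayscale(image)
  lap_k <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  lap <- abs(EBImage::filter2(g, lap_k, boundary = "replicate"))
  sm <- EBImage::gblur(lap, sigma = params$gaussian_sigma)
  fg <- sm > mean(sm)
  if (!any(fg)) {
    return(binary_mask(matrix(0L, nrow(g), ncol(g)), spacing = spacing,
                       level_index = level_index))
  }
  fg <- EBImage::medianFilter(matrix(as.numeric(fg), nrow(g)),
                              size = params$median_size) > 0.5
  fg <- EBImage::opening(matrix(as.numeric(fg), nrow(g)),
                         EBImage::makeBrush(params$opening_px, shape = "disc")) > 0
  if (!any(fg)) {
    return(binary_mask(matrix(0L, nrow(g), ncol(g)), spacing = spacing,
                       level_index = level_index))
  }
  # flood the background from the point farthest away from any foreground;
  # holes enclosed by tissue are not reached and therefore become tissue
  dist_to_fg <- EBImage::distmap(matrix(as.numeric(!fg), nrow(g)))
  seed <- which.max(dist_to_fg)
  bg_lab <- .cpp_label_components(matrix(as.integer(!fg), nrow(g)), 4L)
  tissue <- matrix(as.integer(bg_lab != bg_lab[seed]), nrow(g))
  # prune small regions via distance-transform maxima and the seed rule
  dt <- EBImage::distmap(matrix(as.numeric(tissue), nrow(g)))
  lab <- .cpp_label_components(tissue, 8L)
  ncomp <- max(lab)
  if (ncomp > 0L) {
    peak_val <- numeric(ncomp)
    peak_pos <- integer(ncomp)
    ord <- order(dt, decreasing = TRUE)
    seen <- logical(ncomp)
    for (p in ord) {
      l <- lab[p]
      if (l == 0L) next
      if (!seen[l]) {
        seen[l] <- TRUE
        peak_val[l] <- dt[p]
        peak_pos[l] <- p
        if (all(seen)) break
      }
    }
    H <- nrow(g)
    py <- (peak_pos - 1L) %% H
    px <- (peak_pos - 1L) %/% H
    accepted <- logical(ncomp)
    acc_x <- numeric(0)
    acc_y <- numeric(0)
    for (l in order(peak_val, decreasing = TRUE)) {
      ok <- peak_val[l] > params$seed_accept_distance
      if (!ok && length(acc_x)) {
        ok <- min(sqrt((acc_x - px[l])^2 + (acc_y - py[l])^2)) <=
          params$seed_proximity
      }
      if (ok) {
        accepted[l] <- TRUE
        acc_x <- c(acc_x, px[l])
        acc_y <- c(acc_y, py[l])
      }
    }
    tissue[!matrix(accepted[pmax(lab, 1L)] & lab > 0L, nrow(g))] <- 0L
  }
  binary_mask(tissue, spacing = spacing, level_index = level_index)
}
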