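# Multiresolution (pyramidal) image handling.
#
# A whole-slide image is stored as an ordered list of RGB rasters whose pixel
# spacing doubles (and pixel count halves) from one level to the next. Level
# arrays are (H, W, 3) in [0, 1] doubles, or raw bytes 0..255 for large
# pyramids; `read_region()` always returns doubles. Coordinates are 0-based
# (x, y) = (column, row) with the origin at the top-left corner; regions are
# half-open.

#' Construct an image pyramid
#'
#' @param levels List of RGB rasters, finest first. Each element is an
#'   `(H, W, 3)` array, either doubles in `[0, 1]` or raw bytes.
#' @param spacings Numeric vector of per-level pixel sizes in micrometres,
#'   one per level, strictly increasing and doubling within tolerance.
#' @param validate Check the pyramid invariants (spacing ratio in
#'   `[1.9, 2.1]`, dimension halving within one pixel, 3 channels).
#' @return An `image_pyramid` object.
#' @export
image_pyramid <- function(levels, spacings, validate = TRUE) {
  if (length(levels) == 0L) stop("a pyramid needs at least one level")
  if (length(levels) != length(spacings)) {
    stop("'levels' and 'spacings' must have the same length")
  }
  obj <- structure(list(levels = levels, spacings = as.numeric(spacings)),
                   class = "image_pyramid")
  if (validate) validate_pyramid(obj)
  obj
}

#' @export
print.image_pyramid <- function(x, ...) {
  d <- pyramid_dimensions(x)
  cat(sprintf("image_pyramid: %d level(s)\n", length(x$levels)))
  for (k in seq_along(x$levels)) {
    cat(sprintf("  level %d: %d x %d px, %.4f um/px\n",
                k - 1L, d[k, 1], d[k, 2], x$spacings[k]))
  }
  invisible(x)
}

#' Per-level dimensions of a pyramid
#'
#' @param pyramid An `image_pyramid`.
#' @return Integer matrix with one row per level and columns `width`, `height`
#'   (pixels).
#' @export
pyramid_dimensions <- function(pyramid) {
  d <- t(vapply(pyramid$levels,
                function(l) c(dim(l)[2], dim(l)[1]), integer(2)))
  colnames(d) <- c("width", "height")
  d
}

validate_pyramid <- function(p) {
  d <- pyramid_dimensions(p)
  for (k in seq_along(p$levels)) {
    dk <- dim(p$levels[[k]])
    if (length(dk) != 3L || dk[3] != 3L) {
      stop(sprintf("level %d is not an (H, W, 3) RGB raster", k - 1L))
    }
  }
  if (length(p$levels) > 1L) {
    r <- p$spacings[-1] / p$spacings[-length(p$spacings)]
    if (any(r < 1.9 | r > 2.1)) {
      stop("consecutive level spacings must double (ratio in [1.9, 2.1])")
    }
    for (k in seq_len(length(p$levels) - 1L)) {
      expected <- ceiling(d[k, ] / 2)
      if (any(abs(d[k + 1L, ] - expected) > 1L)) {
        stop(sprintf("level %d dimensions are not half of level %d",
                     k, k - 1L))
      }
    }
  }
  invisible(p)
}

#' Reference to one pyramid level
#'
#' @param level_index 0-based level index.
#' @param spacing Pixel spacing of that level in micrometres.
#' @return A `level_ref` object.
#' @export
level_ref <- function(level_index, spacing) {
  structure(list(level_index = as.integer(level_index),
                 spacing = as.numeric(spacing)),
            class = "level_ref")
}

#' Select the pyramid level closest to a target pixel spacing
#'
#' Picks the level whose spacing minimises the absolute difference to
#' `target_spacing`. Exact ties are broken toward the lower (finer) level
#' index, which favors sensitivity.
#'
#' @param pyramid An `image_pyramid`.
#' @param target_spacing Target pixel spacing in micrometres (> 0).
#' @return A `level_ref`.
#' @export
closest_level <- function(pyramid, target_spacing) {
  if (!inherits(pyramid, "image_pyramid") || length(pyramid$levels) == 0L) {
    stop("unusable input: pyramid has no levels")
  }
  if (!is.numeric(target_spacing) || target_spacing <= 0) {
    stop("'target_spacing' must be a positive number")
  }
  idx <- which.min(abs(pyramid$spacings - target_spacing))
  level_ref(idx - 1L, pyramid$spacings[idx])
}

# Convert a (possibly raw) level window to doubles in [0, 1].
level_pixels <- function(level, rows, cols) {
  w <- level[rows, cols, , drop = FALSE]
  if (is.raw(w)) {
    w <- array(as.integer(w) / 255, dim = dim(w))
  }
  w
}

#' Read a rectangular region from a pyramid level
#'
#' Out-of-extent pixels are filled with white `(1, 1, 1)`, matching the
#' appearance of empty slide background. A region that lies fully outside the
#' level extent is an error.
#'
#' @param pyramid An `image_pyramid`.
#' @param level A `level_ref` or 0-based level index.
#' @param origin Length-2 vector `(x, y)`, 0-based top-left corner.
#' @param size Length-2 vector `(width, height)` in pixels.
#' @return `(height, width, 3)` double array in `[0, 1]`.
#' @export
read_region <- function(pyramid, level, origin, size) {
  k <- if (inherits(level, "level_ref")) level$level_index else as.integer(level)
  if (k < 0L || k >= length(pyramid$levels)) stop("level index out of range")
  lv <- pyramid$levels[[k + 1L]]
  H <- dim(lv)[1]; W <- dim(lv)[2]
  x0 <- as.integer(origin[1]); y0 <- as.integer(origin[2])
  w <- as.integer(size[1]); h <- as.integer(size[2])
  if (w <= 0L || h <= 0L) stop("region size must be positive")
  if (x0 >= W || y0 >= H || x0 + w <= 0L || y0 + h <= 0L) {
    stop("region lies fully outside the level extent")
  }
  out <- array(1, dim = c(h, w, 3))
  rr <- intersect(seq.int(y0, y0 + h - 1L), 0:(H - 1L))
  cc <- intersect(seq.int(x0, x0 + w - 1L), 0:(W - 1L))
  out[rr - y0 + 1L, cc - x0 + 1L, ] <- level_pixels(lv, rr + 1L, cc + 1L)
  out
}

# 2x2 mean downsampling; odd dimensions are padded by edge replication so the
# output has ceiling(n / 2) pixels per axis.
downsample2_mean <- function(arr) {
  H <- dim(arr)[1]; W <- dim(arr)[2]; C <- dim(arr)[3]
  if (H %% 2L == 1L) arr <- arr[c(seq_len(H), H), , , drop = FALSE]
  if (W %% 2L == 1L) arr <- arr[, c(seq_len(W), W), , drop = FALSE]
  H2 <- dim(arr)[1] %/% 2L; W2 <- dim(arr)[2] %/% 2L
  out <- array(0, dim = c(H2, W2, C))
  for (ch in seq_len(C)) {
    m <- arr[, , ch]
    out[, , ch] <- (m[seq(1, 2 * H2, 2), seq(1, 2 * W2, 2)] +
                    m[seq(2, 2 * H2, 2), seq(1, 2 * W2, 2)] +
                    m[seq(1, 2 * H2, 2), seq(2, 2 * W2, 2)] +
                    m[seq(2, 2 * H2, 2), seq(2, 2 * W2, 2)]) / 4
  }
  out
}

# 2x2 majority downsampling for binary masks; a 2-2 tie counts as foreground
# so thin tissue strands survive coarsening.
downsample2_majority <- function(m) {
  H <- nrow(m); W <- ncol(m)
  if (H %% 2L == 1L) m <- m[c(seq_len(H), H), , drop = FALSE]
  if (W %% 2L == 1L) m <- m[, c(seq_len(W), W), drop = FALSE]
  H2 <- nrow(m) %/% 2L; W2 <- ncol(m) %/% 2L
  s <- m[seq(1, 2 * H2, 2), seq(1, 2 * W2, 2)] +
       m[seq(2, 2 * H2, 2), seq(1, 2 * W2, 2)] +
       m[seq(1, 2 * H2, 2), seq(2, 2 * W2, 2)] +
       m[seq(2, 2 * H2, 2), seq(2, 2 * W2, 2)]
  (s >= 2) + 0L
}

#' Build a pyramid from a level-0 raster
#'
#' Coarser levels are produced by 2x2 mean downsampling, mirroring how
#' scanners derive their resolution pyramid.
#'
#' @param level0 `(H, W, 3)` double array in `[0, 1]`.
#' @param spacing0 Level-0 pixel spacing in micrometres.
#' @param n_levels Number of levels to build.
#' @param storage `"double"` or `"raw"` (one byte per channel, saves memory).
#' @return An `image_pyramid`.
#' @export
build_pyramid <- function(level0, spacing0, n_levels, storage = c("double", "raw")) {
  storage <- match.arg(storage)
  levels <- vector("list", n_levels)
  cur <- level0
  for (k in seq_len(n_levels)) {
    levels[[k]] <- if (storage == "raw") {
      q <- as.integer(round(cur * 255))
      q[q > 255L] <- 255L
      q[q < 0L] <- 0L
      array(as.raw(q), dim = dim(cur))
    } else cur
    if (k < n_levels) cur <- downsample2_mean(cur)
  }
  image_pyramid(levels, spacing0 * 2^(seq_len(n_levels) - 1L))
}

spacing_sidecar <- function(path) paste0(path, ".spacing.json")

#' Write an image pyramid as a multi-page TIFF
#'
#' Levels are written as LZW-compressed 8-bit RGB pages, finest first. The
#' baseline TIFF tags carry no micrometre pixel size, so spacings are stored
#' in a JSON sidecar (`<path>.spacing.json`) which the reader picks up again;
#' a `pixel_spacing_um` argument on the reader overrides or replaces it.
#'
#' @param pyramid An `image_pyramid`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pyramid_tiff <- function(pyramid, path) {
  pages <- lapply(seq_along(pyramid$levels), function(k) {
    lv <- pyramid$levels[[k]]
    if (is.raw(lv)) array(as.integer(lv) / 255, dim = dim(lv)) else lv
  })
  ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = 8L,
                            compression = "LZW", reduce = FALSE),
            silent = TRUE)
  if (inherits(ok, "try-error")) stop("cannot write TIFF at '", path, "'")
  jsonlite::write_json(list(pixel_spacing_um = pyramid$spacings),
                       spacing_sidecar(path), auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read a multi-page pyramidal TIFF
#'
#' Pages are ordered by decreasing pixel count. Pixel spacing is taken from
#' the JSON sidecar written by [write_pyramid_tiff()] when present, then from
#' TIFF resolution tags when they encode a physical size, and finally from
#' `pixel_spacing_um`; without any of these the file cannot be interpreted
#' physically and an error is raised.
#'
#' @param path TIFF file path.
#' @param pixel_spacing_um Optional level-0 pixel spacing in micrometres used
#'   when the file carries no spacing metadata.
#' @return An `image_pyramid`.
#' @export
read_pyramid_tiff <- function(path, pixel_spacing_um = NULL) {
  if (!file.exists(path)) stop("no such file: '", path, "'")
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  sizes <- vapply(pages, function(p) prod(dim(p)[1:2]), numeric(1))
  pages <- pages[order(sizes, decreasing = TRUE)]
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 2L) p <- array(rep(p, 3L), dim = c(dim(p), 3L))
    if (dim(p)[3] > 3L) p <- p[, , 1:3, drop = FALSE]
    p
  })
  spacings <- NULL
  sc <- spacing_sidecar(path)
  if (file.exists(sc)) {
    spacings <- as.numeric(jsonlite::read_json(sc,
                                               simplifyVector = TRUE)$pixel_spacing_um)
  }
  if (is.null(spacings)) {
    xres <- attr(pages[[1]], "x.resolution")
    unit <- attr(pages[[1]], "resolution.unit")
    if (!is.null(xres) && !is.null(unit) && xres > 0 &&
        unit %in% c("cm", "centimeter", "inch")) {
      um_per_px <- if (unit == "inch") 25400 / xres else 10000 / xres
      spacings <- um_per_px * 2^(seq_along(pages) - 1L)
    }
  }
  if (is.null(spacings) && !is.null(pixel_spacing_um)) {
    spacings <- pixel_spacing_um * 2^(seq_along(pages) - 1L)
  }
  if (is.null(spacings)) {
    stop("no pixel spacing metadata; supply 'pixel_spacing_um'")
  }
  image_pyramid(pages, spacings)
}

#' Write a binary mask as a pyramidal TIFF
#'
#' Level 0 equals the mask; coarser levels are derived by 2x2 majority vote,
#' which preserves thin tissue strands better than plain subsampling. The
#' round trip through [read_mask_pyramid()] reproduces level 0 bit-exactly.
#'
#' @param mask A `binary_mask`.
#' @param path Output file path.
#' @param n_levels Number of pyramid levels to write.
#' @return `path`, invisibly.
#' @export
write_mask_pyramid <- function(mask, path, n_levels = 4L) {
  stopifnot(inherits(mask, "binary_mask"))
  if (is.null(mask$spacing) || !is.finite(mask$spacing)) {
    stop("mask must state its pixel spacing")
  }
  pages <- vector("list", n_levels)
  cur <- mask$data
  for (k in seq_len(n_levels)) {
    pages[[k]] <- matrix(as.numeric(cur), nrow(cur), ncol(cur))
    if (k < n_levels) cur <- downsample2_majority(cur)
  }
  ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = 8L,
                            compression = "LZW", reduce = FALSE), silent = TRUE)
  if (inherits(ok, "try-error")) stop("cannot write TIFF at '", path, "'")
  jsonlite::write_json(
    list(pixel_spacing_um = mask$spacing * 2^(seq_len(n_levels) - 1L)),
    spacing_sidecar(path), auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read a mask pyramid written by [write_mask_pyramid()]
#'
#' @param path TIFF file path.
#' @param pixel_spacing_um Optional level-0 spacing when no sidecar exists.
#' @return List of `binary_mask` objects, finest first.
#' @export
read_mask_pyramid <- function(path, pixel_spacing_um = NULL) {
  if (!file.exists(path)) stop("no such file: '", path, "'")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  sizes <- vapply(pages, function(p) prod(dim(p)[1:2]), numeric(1))
  pages <- pages[order(sizes, decreasing = TRUE)]
  spacings <- NULL
  sc <- spacing_sidecar(path)
  if (file.exists(sc)) {
    spacings <- as.numeric(jsonlite::read_json(sc,
                                               simplifyVector = TRUE)$pixel_spacing_um)
  } else if (!is.null(pixel_spacing_um)) {
    spacings <- pixel_spacing_um * 2^(seq_along(pages) - 1L)
  } else {
    stop("no pixel spacing metadata; supply 'pixel_spacing_um'")
  }
  lapply(seq_along(pages), function(k) {
    m <- pages[[k]]
    if (length(dim(m)) == 3L) m <- m[, , 1]
    binary_mask((round(m * 255) > 0) + 0L, spacing = spacings[k],
                level_index = k - 1L)
  })
}
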