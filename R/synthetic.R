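# Synthetic pyramidal slides with ground-truth annotations.
#
# The generator emulates the difficulty axes of scanned slides: near-white
# background with sensor noise, stained tissue blobs with nucleus-like
# texture, sparse "fatty" tissue rendered as thin stained membranes around
# near-white lobules, out-of-focus patches, and the common non-tissue
# artifacts (air bubbles, cover-slip edge, pen markings, stain residue).
# It does not attempt photorealism: textures are band-limited noise and
# membranes are Voronoi edges, which is enough to make color thresholding
# succeed or fail for the same reasons it does on real slides.

#' Synthetic slide specification
#'
#' Defaults describe a desk-scale stand-in for a scanned slide: a 3072 px
#' square canvas at 0.5 um spacing with five pyramid levels (0.5 to 8 um),
#' one or two stained tissue sections of 250-400 um equivalent radius, and
#' all common artifact types enabled. Section radii are chosen large enough
#' that the coarsest level still resolves them across several network output
#' cells, as real centimetre-scale sections are.
#'
#' @param canvas_px Level-0 canvas side in pixels.
#' @param spacing0 Level-0 pixel spacing in micrometres.
#' @param n_levels Number of pyramid levels.
#' @param n_blobs Number of tissue blobs (single value or range).
#' @param blob_radius_um Range of blob radii in micrometres.
#' @param fatty_fraction Fraction of blobs rendered as fatty tissue.
#' @param stain_hue Stain hue in degrees (0-360); 300 approximates an
#'   eosin-dominated pink-purple.
#' @param stain_saturation Stain saturation in `[0, 1]`.
#' @param artifacts Named logical vector toggling `air_bubble`,
#'   `coverslip_edge`, `pen_mark`, `stain_residue`.
#' @param blur_fraction Fraction of the canvas affected by an out-of-focus
#'   patch (0 disables).
#' @param background_gray,background_sd Mean and standard deviation of the
#'   near-white background intensity in `[0, 1]`.
#' @param texture Render nucleus-like texture inside tissue; `FALSE` gives
#'   flat mid-gray blobs (useful for analytically solvable fixtures).
#' @param min_gap_um Minimal gap between blob boundaries.
#' @param seed Seed making the slide reproducible.
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(canvas_px = 3072L, spacing0 = 0.5, n_levels = 5L,
                           n_blobs = c(1L, 2L), blob_radius_um = c(250, 400),
                           fatty_fraction = 0, stain_hue = 300,
                           stain_saturation = 0.45,
                           artifacts = c(air_bubble = TRUE,
                                         coverslip_edge = TRUE,
                                         pen_mark = FALSE,
                                         stain_residue = TRUE),
                           blur_fraction = 0.05,
                           background_gray = 0.96, background_sd = 0.01,
                           texture = TRUE, min_gap_um = 100, seed = 1L) {
  stopifnot(n_levels >= 1L, fatty_fraction >= 0, fatty_fraction <= 1,
            blur_fraction >= 0, blur_fraction <= 1, canvas_px >= 64L)
  art <- c(air_bubble = FALSE, coverslip_edge = FALSE, pen_mark = FALSE,
           stain_residue = FALSE)
  artifacts <- unlist(artifacts) # accept YAML-style named lists
  art[names(artifacts)] <- as.logical(artifacts)
  structure(list(canvas_px = as.integer(canvas_px), spacing0 = spacing0,
                 n_levels = as.integer(n_levels), n_blobs = n_blobs,
                 blob_radius_um = blob_radius_um,
                 fatty_fraction = fatty_fraction, stain_hue = stain_hue,
                 stain_saturation = stain_saturation, artifacts = art,
                 blur_fraction = blur_fraction,
                 background_gray = background_gray,
                 background_sd = background_sd, texture = isTRUE(texture),
                 min_gap_um = min_gap_um, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Smooth random radial blob polygon around (cx, cy), radius r (all px).
blob_polygon <- function(cx, cy, r, n_vertices = 40L, roughness = 0.14) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  w <- rnorm(n_vertices)
  # circular moving average for a smooth perturbation
  k <- 7L
  wpad <- c(tail(w, k), w, head(w, k))
  sm <- stats::filter(wpad, rep(1 / (2 * k + 1), 2 * k + 1), circular = FALSE)
  sm <- as.numeric(sm)[k + seq_len(n_vertices)]
  sm <- sm / max(abs(sm), 1e-9)
  rr <- r * (1 + roughness * sm)
  cbind(cx + rr * cos(th), cy + rr * sin(th))
}

# Band-limited noise field in [-1, 1].
noise_field <- function(H, W, sigma) {
  n <- EBImage::gblur(matrix(rnorm(H * W), H, W), sigma = sigma)
  n / max(abs(n), 1e-9)
}

# Paint stained tissue texture into `img` at the pixels of `sel` (logical
# matrix over the bbox rows `rr`, cols `cc`).
paint_tissue <- function(img, rr, cc, sel, hue, sat, textured) {
  h <- hue / 360
  if (!textured) {
    base <- hsv_to_rgb(h, sat, 1)
    v <- (150 / 255) / mean(base)
    col <- hsv_to_rgb(h, sat, min(v, 1))
    for (ch in 1:3) {
      plane <- img[rr, cc, ch]
      plane[sel] <- col[ch]
      img[rr, cc, ch] <- plane
    }
    return(img)
  }
  Hb <- length(rr); Wb <- length(cc)
  tex <- noise_field(Hb, Wb, sigma = 4)
  nuc <- noise_field(Hb, Wb, sigma = 1.5)
  nucleus <- nuc < stats::quantile(nuc[sel], 0.18)
  V <- pmin(pmax(0.62 + 0.16 * tex, 0), 1)
  S <- pmin(pmax(sat * (1 + 0.35 * tex), 0), 1)
  V[nucleus] <- pmax(V[nucleus] - 0.28, 0.05)
  S[nucleus] <- pmin(S[nucleus] + 0.2, 1)
  rgbm <- hsv_to_rgb(h, as.vector(S[sel]), as.vector(V[sel]))
  for (ch in 1:3) {
    plane <- img[rr, cc, ch]
    plane[sel] <- rgbm[, ch]
    img[rr, cc, ch] <- plane
  }
  img
}

# Fatty tissue: near-white lobules bounded by thin stained membranes
# (Voronoi edges of random seeds), computed on a 4x coarse grid.
paint_fatty <- function(img, rr, cc, sel, hue, sat, spacing0) {
  Hb <- length(rr); Wb <- length(cc)
  lobule_px <- 55 / spacing0        # ~55 um lobules
  membrane_px <- 7 / spacing0       # ~7 um membranes
  n_seeds <- max(4L, round(Hb * Wb / lobule_px^2))
  sx <- runif(n_seeds, 1, Wb)
  sy <- runif(n_seeds, 1, Hb)
  f <- 4L
  Hc <- ceiling(Hb / f); Wc <- ceiling(Wb / f)
  gx <- (rep(seq_len(Wc), each = Hc) - 0.5) * f
  gy <- (rep(seq_len(Hc), times = Wc) - 0.5) * f
  d1 <- rep(Inf, Hc * Wc)
  d2 <- rep(Inf, Hc * Wc)
  for (s in seq_len(n_seeds)) {
    d <- sqrt((gx - sx[s])^2 + (gy - sy[s])^2)
    closer <- d < d1
    d2 <- ifelse(closer, d1, pmin(d2, d))
    d1 <- pmin(d1, d)
  }
  memb_c <- matrix((d2 - d1) < membrane_px, Hc, Wc)
  memb <- memb_c[rep(seq_len(Hc), each = f)[seq_len(Hb)],
                 rep(seq_len(Wc), each = f)[seq_len(Wb)]]
  h <- hue / 360
  mcol <- hsv_to_rgb(h, min(1, sat + 0.15), 0.52)
  fat <- 0.955
  for (ch in 1:3) {
    plane <- img[rr, cc, ch]
    plane[sel & memb] <- mcol[ch]
    plane[sel & !memb] <- fat
    img[rr, cc, ch] <- plane
  }
  img
}

fill_in_canvas <- function(coords, H, W) {
  f <- .cpp_fill_polygon(coords[, 1], coords[, 2], H, W)
  sel <- matrix(FALSE, H, W)
  if (nrow(f$mask)) {
    sel[f$row0 + seq_len(nrow(f$mask)), f$col0 + seq_len(ncol(f$mask))] <-
      f$mask
  }
  sel
}

disc_polygon <- function(cx, cy, r, n = 32L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(cx + r * cos(th), cy + r * sin(th))
}

#' Generate a synthetic slide
#'
#' Renders the level-0 canvas, derives the coarser levels by 2x2 mean
#' downsampling, and returns the pyramid together with its ground-truth
#' polygon annotations (tissue blobs plus any rendered artifacts in their
#' annotation classes). Identical seeds give bit-identical output.
#'
#' @param spec A `synthetic_spec`.
#' @param storage Pyramid storage mode (`"raw"` halves memory; default).
#' @return List with `pyramid` (an `image_pyramid`) and `annotations`
#'   (an `annotation_set`).
#' @export
synth_generate <- function(spec, storage = c("raw", "double")) {
  stopifnot(inherits(spec, "synthetic_spec"))
  storage <- match.arg(storage)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed)
  H <- spec$canvas_px; W <- spec$canvas_px
  sp <- spec$spacing0
  img <- array(pmin(pmax(rnorm(H * W, spec$background_gray,
                               spec$background_sd), 0), 1), dim = c(H, W, 1))
  img <- array(rep(img, 3L), dim = c(H, W, 3L))

  nb <- if (length(spec$n_blobs) > 1L) {
    sample(seq.int(spec$n_blobs[1], spec$n_blobs[2]), 1L)
  } else spec$n_blobs
  gap_px <- spec$min_gap_um / sp
  rad_px <- NULL
  centers <- NULL
  # rejection-sample the whole configuration; an early blob can otherwise
  # block all later ones on a crowded canvas
  for (restart in seq_len(60L)) {
    rad_try <- numeric(nb)
    cen_try <- matrix(NA_real_, 0, 2)
    failed <- FALSE
    for (i in seq_len(nb)) {
      placed <- FALSE
      for (try in seq_len(200L)) {
        r_i <- runif(1, spec$blob_radius_um[1], spec$blob_radius_um[2]) / sp
        margin <- r_i * 1.15 + 8
        if (margin * 2 >= min(H, W)) next
        cx <- runif(1, margin, W - margin)
        cy <- runif(1, margin, H - margin)
        ok <- !nrow(cen_try) || all(sqrt((cen_try[, 1] - cx)^2 +
                                         (cen_try[, 2] - cy)^2) >
                                    rad_try[seq_len(nrow(cen_try))] * 1.15 +
                                    r_i * 1.15 + gap_px)
        if (ok) {
          rad_try[i] <- r_i
          cen_try <- rbind(cen_try, c(cx, cy))
          placed <- TRUE
          break
        }
      }
      if (!placed) { failed <- TRUE; break }
    }
    if (!failed) { rad_px <- rad_try; centers <- cen_try; break }
  }
  if (is.null(centers)) stop("canvas too small for the requested blobs")

  fatty <- runif(nb) < spec$fatty_fraction
  polys <- list()
  for (i in seq_len(nb)) {
    coords <- blob_polygon(centers[i, 1], centers[i, 2], rad_px[i])
    sel_full <- fill_in_canvas(coords, H, W)
    rows <- which(rowSums(sel_full) > 0)
    cols <- which(colSums(sel_full) > 0)
    rr <- seq.int(min(rows), max(rows))
    cc <- seq.int(min(cols), max(cols))
    sel <- sel_full[rr, cc]
    img <- if (fatty[i]) {
      paint_fatty(img, rr, cc, sel, spec$stain_hue, spec$stain_saturation, sp)
    } else {
      paint_tissue(img, rr, cc, sel, spec$stain_hue, spec$stain_saturation,
                   spec$texture)
    }
    polys[[length(polys) + 1L]] <- list(coords = coords, class = "tissue")
  }

  blob_clearance <- function(cx, cy, need) {
    !nrow(centers) || all(sqrt((centers[, 1] - cx)^2 +
                               (centers[, 2] - cy)^2) >
                          rad_px * 1.25 + need)
  }

  if (spec$artifacts[["coverslip_edge"]]) {
    wpx <- max(2, round(5 / sp))
    x0 <- W - round(40 / sp)
    rect <- cbind(c(x0, x0 + wpx, x0 + wpx, x0), c(0, 0, H, H))
    sel <- fill_in_canvas(rect, H, W)
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[sel] <- 0.45
      img[, , ch] <- plane
    }
    polys[[length(polys) + 1L]] <- list(coords = rect, class = "edge")
  }

  if (spec$artifacts[["air_bubble"]]) {
    r <- round(110 / sp)
    for (try in seq_len(200L)) {
      cx <- runif(1, r + 5, W - r - 5)
      cy <- runif(1, r + 5, H - r - 5)
      if (blob_clearance(cx, cy, r + 20 / sp)) break
    }
    ring <- max(2, round(8 / sp))
    bx <- seq.int(max(1, floor(cx - r - 2)), min(W, ceiling(cx + r + 2)))
    by <- seq.int(max(1, floor(cy - r - 2)), min(H, ceiling(cy + r + 2)))
    dx <- matrix(rep(bx, each = length(by)), length(by)) - cx
    dy <- matrix(rep(by, length(bx)), length(by)) - cy
    d <- sqrt(dx^2 + dy^2)
    band <- d <= r & d >= r - ring
    inner <- d < r - ring
    for (ch in 1:3) {
      plane <- img[by, bx, ch]
      plane[band] <- 0.72
      plane[inner] <- pmin(plane[inner] + 0.015, 1) * 0.97
      img[by, bx, ch] <- plane
    }
    polys[[length(polys) + 1L]] <- list(coords = disc_polygon(cx, cy, r),
                                        class = "inner_artifact")
  }

  if (spec$artifacts[["pen_mark"]]) {
    wpx <- round(25 / sp)
    y0 <- round(H * 0.08)
    rect <- cbind(c(W * 0.1, W * 0.55, W * 0.55, W * 0.1),
                  c(y0, y0, y0 + wpx, y0 + wpx))
    sel <- fill_in_canvas(rect, H, W)
    col <- hsv_to_rgb(120 / 360, 0.8, 0.45)
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[sel] <- col[ch]
      img[, , ch] <- plane
    }
    polys[[length(polys) + 1L]] <- list(coords = rect, class = "edge")
  }

  if (spec$artifacts[["stain_residue"]]) {
    r <- round(70 / sp)
    rmax <- r * 1.35 # roughness head-room so the polygon stays in extent
    for (try in seq_len(200L)) {
      cx <- runif(1, rmax + 5, W - rmax - 5)
      cy <- runif(1, rmax + 5, H - rmax - 5)
      if (blob_clearance(cx, cy, rmax + 20 / sp)) break
    }
    coords <- blob_polygon(cx, cy, r, roughness = 0.3)
    sel <- fill_in_canvas(coords, H, W)
    col <- hsv_to_rgb(spec$stain_hue / 360, 0.18, 0.9)
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[sel] <- 0.5 * plane[sel] + 0.5 * col[ch]
      img[, , ch] <- plane
    }
    polys[[length(polys) + 1L]] <- list(coords = coords,
                                        class = "inner_artifact")
  }

  if (spec$blur_fraction > 0) {
    r <- round(sqrt(spec$blur_fraction * H * W / pi))
    cx <- runif(1, r, W - r)
    cy <- runif(1, r, H - r)
    x0 <- max(1, round(cx - r)); x1 <- min(W, round(cx + r))
    y0 <- max(1, round(cy - r)); y1 <- min(H, round(cy + r))
    sub <- img[y0:y1, x0:x1, , drop = FALSE]
    blurred <- EBImage::gblur(sub, sigma = 4)
    dx <- matrix(rep(x0:x1, each = y1 - y0 + 1L), y1 - y0 + 1L) - cx
    dy <- matrix(rep(y0:y1, x1 - x0 + 1L), y1 - y0 + 1L) - cy
    w <- pmin(pmax(1 - (sqrt(dx^2 + dy^2) / r), 0), 1)
    for (ch in 1:3) {
      img[y0:y1, x0:x1, ch] <- w * blurred[, , ch] +
        (1 - w) * sub[, , ch]
    }
  }

  pyramid <- build_pyramid(img, spacing0 = sp, n_levels = spec$n_levels,
                           storage = storage)
  list(pyramid = pyramid, annotations = annotation_set(polys))
}
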