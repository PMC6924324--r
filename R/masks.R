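# Mask containers and the six-label sampling-mask machinery.
#
# Sampling-mask labels (integer codes used throughout):
#   1 edge            non-tissue  artifacts on the edge of the glass slide
#   2 artifacts       non-tissue  artifacts inside the glass slide
#   3 background      non-tissue  background free of artifacts
#   4 external_margin non-tissue  background within 125 px of tissue
#   5 internal_margin tissue      tissue within 125 px of background
#   6 tissue          tissue      tissue interior
# The binary mapping keeps {5, 6} as tissue and everything else as
# non-tissue, so converting a sampling mask to binary loses no tissue pixel.

#' Sampling-mask label codes
#'
#' Named integer vector mapping label names to the codes stored in a
#' `sampling_mask` raster.
#' @export
MASK_LABELS <- c(edge = 1L, artifacts = 2L, background = 3L,
                 external_margin = 4L, internal_margin = 5L, tissue = 6L)

# Annotation classes and their rasterized base labels.
ANNOTATION_CLASSES <- c("tissue", "background", "edge", "inner_artifact")
CLASS_TO_LABEL <- c(tissue = 6L, background = 3L, edge = 1L,
                    inner_artifact = 2L)

#' Construct a binary tissue mask
#'
#' @param data Integer or logical matrix; non-zero is tissue.
#' @param spacing Pixel spacing in micrometres.
#' @param level_index 0-based pyramid level the mask refers to.
#' @return A `binary_mask` object.
#' @export
binary_mask <- function(data, spacing, level_index = NA_integer_) {
  m <- (as.matrix(data) != 0) + 0L
  structure(list(data = m, spacing = as.numeric(spacing),
                 level_index = as.integer(level_index)),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("binary_mask: %d x %d px, %.4f um/px, %.1f%% tissue\n",
              ncol(x$data), nrow(x$data), x$spacing,
              100 * mean(x$data)))
  invisible(x)
}

#' Construct a six-label sampling mask
#'
#' @param data Integer matrix of labels in `1:6` (see [MASK_LABELS]).
#' @param spacing Pixel spacing in micrometres.
#' @param level_index 0-based pyramid level the mask refers to.
#' @return A `sampling_mask` object.
#' @export
sampling_mask <- function(data, spacing, level_index = NA_integer_) {
  m <- as.matrix(data)
  storage.mode(m) <- "integer"
  if (any(!(m %in% MASK_LABELS))) stop("sampling mask labels must be in 1:6")
  structure(list(data = m, spacing = as.numeric(spacing),
                 level_index = as.integer(level_index)),
            class = "sampling_mask")
}

#' Add margin labels around the tissue boundary
#'
#' Background pixels within 125 pixels (Euclidean, inclusive) of any tissue
#' pixel become *external margin*; tissue pixels within 125 pixels of any
#' background pixel become *internal margin*. Distances are measured at the
#' raster's own level, so the physical margin width is `125 * spacing`
#' micrometres (62.5, 250 and 1000 um at 0.5, 2 and 8 um spacing). Edge and
#' artifact pixels take no part in the margins.
#'
#' @param raster Integer matrix with the four base labels
#'   (tissue 6, background 3, edge 1, inner artifacts 2), e.g. from
#'   [rasterize_annotations()].
#' @param spacing Pixel spacing in micrometres.
#' @param level_index 0-based level index.
#' @param margin_px Margin width in pixels (default 125).
#' @return A `sampling_mask`.
#' @export
add_margins <- function(raster, spacing, level_index = NA_integer_,
                        margin_px = 125) {
  m <- as.matrix(raster)
  storage.mode(m) <- "integer"
  tissue <- m == MASK_LABELS[["tissue"]]
  backgr <- m == MASK_LABELS[["background"]]
  out <- m
  if (any(tissue) && any(backgr)) {
    # distance from every pixel to the nearest tissue / background pixel
    d_tissue <- EBImage::distmap(matrix(as.numeric(!tissue), nrow(m)))
    d_backgr <- EBImage::distmap(matrix(as.numeric(!backgr), nrow(m)))
    out[backgr & d_tissue <= margin_px] <- MASK_LABELS[["external_margin"]]
    out[tissue & d_backgr <= margin_px] <- MASK_LABELS[["internal_margin"]]
  }
  sampling_mask(out, spacing = spacing, level_index = level_index)
}

#' Collapse a sampling mask to a binary tissue mask
#'
#' Tissue and internal-margin labels map to tissue; edge, artifacts,
#' background and external-margin labels map to non-tissue.
#'
#' @param mask A `sampling_mask` (or a bare label matrix).
#' @param spacing,level_index Used only when `mask` is a bare matrix.
#' @return A `binary_mask`.
#' @export
to_binary <- function(mask, spacing = NULL, level_index = NA_integer_) {
  if (inherits(mask, "sampling_mask")) {
    m <- mask$data
    spacing <- mask$spacing
    level_index <- mask$level_index
  } else {
    m <- as.matrix(mask)
    if (is.null(spacing)) stop("'spacing' required for a bare label matrix")
  }
  if (any(!(m %in% MASK_LABELS))) stop("unknown label value in mask")
  tissue <- m == MASK_LABELS[["tissue"]] | m == MASK_LABELS[["internal_margin"]]
  binary_mask(tissue + 0L, spacing = spacing, level_index = level_index)
}

# Strict sub-threshold test for the equivalent-area diameter rule:
# a region is "smaller than `diameter_um`" when 2 * sqrt(area / pi) <
# diameter_um, i.e. area_px < pi * (diameter_um / 2 / spacing)^2.
small_region_area_px <- function(diameter_um, spacing) {
  pi * (diameter_um / 2 / spacing)^2
}

#' Shared morphological post-processing
#'
#' Applied identically to the output of every segmentation method: removes
#' every disjoint foreground region whose equivalent-area diameter is below
#' `min_diameter_um`, then fills every enclosed hole below the same
#' threshold. "Diameter" is the equivalent-area diameter `2 * sqrt(A / pi)`
#' and "smaller than" is strict, so a region of exactly the threshold
#' diameter is retained. Foreground components use 8-connectivity and holes
#' 4-connectivity. The operation is idempotent.
#'
#' @param mask A `binary_mask` with known spacing.
#' @param min_diameter_um Diameter threshold in micrometres (default 250).
#' @return The post-processed `binary_mask`.
#' @export
postprocess <- function(mask, min_diameter_um = 250) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!is.finite(mask$spacing)) stop("mask spacing must be known")
  min_area <- small_region_area_px(min_diameter_um, mask$spacing)
  m <- mask$data
  # remove small foreground components
  lab <- .cpp_label_components(m, 8L)
  if (max(lab) > 0L) {
    areas <- tabulate(lab, nbins = max(lab))
    drop <- which(areas < min_area)
    if (length(drop)) m[lab %in% drop] <- 0L
  }
  # fill small enclosed holes: background components (4-connectivity) that do
  # not touch the raster border
  bg <- 1L - m
  lab <- .cpp_label_components(bg, 4L)
  if (max(lab) > 0L) {
    border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    areas <- tabulate(lab, nbins = max(lab))
    fill <- setdiff(which(areas < min_area), border)
    if (length(fill)) m[lab %in% fill] <- 1L
  }
  binary_mask(m, spacing = mask$spacing, level_index = mask$level_index)
}
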