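# Polygon annotations in level-0 pixel coordinates.
#
# Four annotation classes are used: tissue, background (holes in the tissue
# and anatomical structures), edge (cover-slip edge, bubbles and markings at
# the slide edge) and inner_artifact (stain residue, debris, inner bubbles).

#' Construct an annotation set
#'
#' @param polygons List of polygons; each polygon is a list with `coords`
#'   (n x 2 matrix of `(x, y)` level-0 pixel coordinates, n >= 3) and
#'   `class` (one of `"tissue"`, `"background"`, `"edge"`,
#'   `"inner_artifact"`).
#' @return An `annotation_set` object.
#' @export
annotation_set <- function(polygons = list()) {
  for (p in polygons) {
    if (!is.matrix(p$coords) || ncol(p$coords) != 2L || nrow(p$coords) < 3L) {
      stop("each polygon needs an (n x 2) coordinate matrix with n >= 3")
    }
    if (!p$class %in% ANNOTATION_CLASSES) {
      stop("unknown annotation class '", p$class, "'")
    }
  }
  structure(list(polygons = polygons), class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cls <- vapply(x$polygons, `[[`, character(1), "class")
  cat(sprintf("annotation_set: %d polygon(s)\n", length(x$polygons)))
  if (length(cls)) print(table(cls))
  invisible(x)
}

#' @rdname annotation_set
#' @param x Object to test.
#' @export
is_annotation_set <- function(x) inherits(x, "annotation_set")

# Shoelace area of a polygon (level-0 square pixels).
polygon_area <- function(coords) {
  x <- coords[, 1]; y <- coords[, 2]
  n <- nrow(coords)
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# Minimum Euclidean distance between two polygon boundaries (vertex-to-edge,
# both directions). Adequate for the cleanup gap test on annotation-scale
# polygons.
polygon_min_distance <- function(a, b) {
  pt_seg <- function(px, py, x1, y1, x2, y2) {
    dx <- x2 - x1; dy <- y2 - y1
    L2 <- dx * dx + dy * dy
    t <- ifelse(L2 == 0, 0, pmin(pmax(((px - x1) * dx + (py - y1) * dy) / L2, 0), 1))
    sqrt((x1 + t * dx - px)^2 + (y1 + t * dy - py)^2)
  }
  min_dir <- function(p, q) {
    n <- nrow(q)
    j <- c(2:n, 1)
    best <- Inf
    for (i in seq_len(nrow(p))) {
      best <- min(best, pt_seg(p[i, 1], p[i, 2], q[, 1], q[, 2],
                               q[j, 1], q[j, 2]))
    }
    best
  }
  min(min_dir(a, b), min_dir(b, a))
}

#' Clean tissue annotations
#'
#' Reproduces the annotation normalisation applied before mask generation:
#' every tissue region with equivalent-area diameter below 250 um is
#' removed, every annotated hole (background polygon) below 250 um diameter
#' is removed, and tissue regions closer than 50 um are merged into a single
#' enclosing region. Removal precedes merging. Merging is realised as
#' morphological closing with a 25 um-radius disc on a raster of the
#' affected polygons, followed by hole filling of the merged cluster and
#' boundary tracing back to polygons; untouched polygons pass through
#' unchanged. The operation is idempotent.
#'
#' @param annotations An `annotation_set` in level-0 pixel coordinates.
#' @param spacing Level-0 pixel spacing in micrometres (> 0).
#' @param min_diameter_um Small-region/hole threshold (default 250; strict).
#' @param merge_distance_um Merge distance (default 50).
#' @param work_spacing_um Raster resolution used for the merge geometry.
#' @return The cleaned `annotation_set`.
#' @export
clean_annotations <- function(annotations, spacing, min_diameter_um = 250,
                              merge_distance_um = 50,
                              work_spacing_um = merge_distance_um / 20) {
  stopifnot(is_annotation_set(annotations), spacing > 0)
  polys <- annotations$polygons
  if (!length(polys)) return(annotations)
  cls <- vapply(polys, `[[`, character(1), "class")
  areas_um2 <- vapply(polys, function(p) polygon_area(p$coords),
                      numeric(1)) * spacing^2
  diam_um <- 2 * sqrt(areas_um2 / pi)
  keep <- !(cls %in% c("tissue", "background") & diam_um < min_diameter_um)
  polys <- polys[keep]
  cls <- cls[keep]
  ti <- which(cls == "tissue")
  if (length(ti) >= 2L) {
    gap_px <- merge_distance_um / spacing
    adj <- matrix(FALSE, length(ti), length(ti))
    for (a in seq_along(ti)) {
      for (b in seq_along(ti)) {
        if (b <= a) next
        d <- polygon_min_distance(polys[[ti[a]]]$coords,
                                  polys[[ti[b]]]$coords)
        adj[a, b] <- adj[b, a] <- d < gap_px
      }
    }
    comp <- components_from_adjacency(adj)
    merged <- list()
    drop <- integer(0)
    for (g in unique(comp)) {
      members <- ti[comp == g]
      if (length(members) < 2L) next
      merged[[length(merged) + 1L]] <-
        merge_tissue_polygons(polys[members], spacing,
                              merge_distance_um / 2, work_spacing_um)
      drop <- c(drop, members)
    }
    if (length(drop)) {
      polys <- polys[-drop]
      polys <- c(polys, do.call(c, merged))
    }
  }
  annotation_set(polys)
}

# Union-find-free connected components of a small adjacency matrix.
components_from_adjacency <- function(adj) {
  n <- nrow(adj)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      nb <- which(adj[i, ])
      if (length(nb) && any(comp[nb] < comp[i])) {
        comp[i] <- min(comp[nb], comp[i])
        changed <- TRUE
      } else if (length(nb)) {
        newc <- min(comp[i], comp[nb])
        if (any(comp[nb] != newc)) {
          comp[nb] <- newc
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  comp
}

# Merge a cluster of tissue polygons: rasterize at work_spacing, close with a
# disc of close_radius_um, fill enclosed holes (merged annotations are single
# enclosing polygons), trace boundaries, and return polygons in level-0
# pixel coordinates.
merge_tissue_polygons <- function(polys, spacing, close_radius_um,
                                  work_spacing_um) {
  scale <- spacing / work_spacing_um # level-0 px -> work px
  all_xy <- do.call(rbind, lapply(polys, `[[`, "coords")) * scale
  r_px <- max(1, round(close_radius_um / work_spacing_um))
  pad <- r_px + 2L
  x0 <- floor(min(all_xy[, 1])) - pad
  y0 <- floor(min(all_xy[, 2])) - pad
  W <- ceiling(max(all_xy[, 1])) - x0 + pad + 1L
  H <- ceiling(max(all_xy[, 2])) - y0 + pad + 1L
  m <- matrix(0L, H, W)
  for (p in polys) {
    xy <- p$coords * scale
    f <- .cpp_fill_polygon(xy[, 1] - x0, xy[, 2] - y0, H, W)
    if (nrow(f$mask)) {
      rr <- f$row0 + seq_len(nrow(f$mask))
      cc <- f$col0 + seq_len(ncol(f$mask))
      m[rr, cc] <- m[rr, cc] | f$mask
    }
  }
  k <- EBImage::makeBrush(2L * r_px + 1L, shape = "disc")
  m <- EBImage::closing(m, k)
  m <- EBImage::fillHull(m)
  polysw <- .cpp_trace_boundaries(matrix(as.integer(m > 0), H, W))
  lapply(polysw, function(v) {
    coords <- cbind((v[, 1] + x0) / scale, (v[, 2] + y0) / scale)
    list(coords = coords, class = "tissue")
  })
}

#' Rasterize annotations into a four-label raster
#'
#' Produces one label per pixel at the requested level: non-annotated pixels
#' are background; annotated pixels take their class label. A pixel belongs
#' to a polygon when its center lies inside it (even-odd rule). Partially
#' overlapping polygons are resolved with priority tissue > inner_artifact >
#' edge > background, except that an explicitly annotated background polygon
#' nested inside a tissue polygon punches a hole (holes in the tissue are
#' annotated as background). Polygons reaching outside the extent are
#' clipped with a warning.
#'
#' @param annotations A cleaned `annotation_set` (level-0 pixel coordinates).
#' @param width,height Raster size in pixels at the target level.
#' @param level A `level_ref` for the target level.
#' @param spacing0 Level-0 pixel spacing in micrometres, used to scale the
#'   coordinates to the target level (`scale = spacing0 / level$spacing`).
#' @return Integer matrix of base labels (see [MASK_LABELS]).
#' @export
rasterize_annotations <- function(annotations, width, height, level,
                                  spacing0 = level$spacing) {
  stopifnot(is_annotation_set(annotations))
  scale <- spacing0 / level$spacing
  m <- matrix(MASK_LABELS[["background"]], height, width)
  cls <- vapply(annotations$polygons, `[[`, character(1), "class")
  clipped <- FALSE
  paint <- function(m, idx, label) {
    for (i in idx) {
      xy <- annotations$polygons[[i]]$coords * scale
      f <- .cpp_fill_polygon(xy[, 1], xy[, 2], height, width)
      if (isTRUE(f$clipped)) clipped <<- TRUE
      if (nrow(f$mask)) {
        rr <- f$row0 + seq_len(nrow(f$mask))
        cc <- f$col0 + seq_len(ncol(f$mask))
        sub <- m[rr, cc]
        sub[f$mask] <- label
        m[rr, cc] <- sub
      }
    }
    m
  }
  # ascending priority: edge < inner_artifact < tissue
  m <- paint(m, which(cls == "edge"), CLASS_TO_LABEL[["edge"]])
  m <- paint(m, which(cls == "inner_artifact"), CLASS_TO_LABEL[["inner_artifact"]])
  m <- paint(m, which(cls == "tissue"), CLASS_TO_LABEL[["tissue"]])
  # explicit background polygons nested inside tissue punch holes
  bg <- which(cls == "background")
  if (length(bg)) {
    tis <- which(cls == "tissue")
    nested <- vapply(bg, function(i) {
      v <- annotations$polygons[[i]]$coords[1, ]
      any(vapply(tis, function(j) {
        point_in_polygon(v[1], v[2], annotations$polygons[[j]]$coords)
      }, logical(1)))
    }, logical(1))
    m <- paint(m, bg[nested], CLASS_TO_LABEL[["background"]])
  }
  if (clipped) warning("polygon outside raster extent was clipped")
  storage.mode(m) <- "integer"
  m
}

# Even-odd point-in-polygon test.
point_in_polygon <- function(px, py, coords) {
  x <- coords[, 1]; y <- coords[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  cross <- ((y > py) != (y[j] > py)) &
    (px < x + (py - y) * (x[j] - x) / (y[j] - y))
  sum(cross, na.rm = TRUE) %% 2 == 1
}

#' Build a six-label sampling mask for one pyramid level
#'
#' Convenience wrapper: rasterizes cleaned annotations at the level matching
#' `target_spacing` and adds the 125-pixel margin bands.
#'
#' @param annotations A cleaned `annotation_set`.
#' @param pyramid The `image_pyramid` the annotations belong to.
#' @param target_spacing Pixel spacing (um) selecting the level.
#' @param margin_px Margin band width in pixels.
#' @return A `sampling_mask`.
#' @export
make_sampling_mask <- function(annotations, pyramid, target_spacing,
                               margin_px = 125) {
  lv <- closest_level(pyramid, target_spacing)
  d <- pyramid_dimensions(pyramid)[lv$level_index + 1L, ]
  r <- rasterize_annotations(annotations, width = d[["width"]],
                             height = d[["height"]], level = lv,
                             spacing0 = pyramid$spacings[1])
  add_margins(r, spacing = lv$spacing, level_index = lv$level_index,
              margin_px = margin_px)
}

#' Reference binary mask from annotations
#'
#' @inheritParams make_sampling_mask
#' @return A `binary_mask` at the selected level.
#' @export
reference_mask <- function(annotations, pyramid, target_spacing) {
  lv <- closest_level(pyramid, target_spacing)
  d <- pyramid_dimensions(pyramid)[lv$level_index + 1L, ]
  r <- rasterize_annotations(annotations, width = d[["width"]],
                             height = d[["height"]], level = lv,
                             spacing0 = pyramid$spacings[1])
  to_binary(r, spacing = lv$spacing, level_index = lv$level_index)
}

#' Read polygon annotations from an ASAP XML file
#'
#' Reads the polygon annotation dialect used by the ASAP viewer: Annotation
#' elements with Coordinate children (X/Y attributes in level-0 pixels) and
#' a PartOfGroup/group attribute carrying the class. Group names are matched
#' case-insensitively to tissue / background / edge / inner_artifact (with
#' "edge artifacts" and "inner artifacts" accepted as synonyms).
#'
#' @param path XML file path.
#' @return An `annotation_set`.
#' @export
read_asap_xml <- function(path) {
  if (!file.exists(path)) stop("no such file: '", path, "'")
  doc <- xml2::read_xml(path)
  anns <- xml2::xml_find_all(doc, ".//Annotation")
  polys <- lapply(anns, function(a) {
    grp <- xml2::xml_attr(a, "PartOfGroup")
    if (is.na(grp)) grp <- xml2::xml_attr(a, "Group")
    cls <- normalize_group(grp)
    co <- xml2::xml_find_all(a, ".//Coordinate")
    xy <- cbind(as.numeric(xml2::xml_attr(co, "X")),
                as.numeric(xml2::xml_attr(co, "Y")))
    ord <- as.numeric(xml2::xml_attr(co, "Order"))
    if (!any(is.na(ord))) xy <- xy[order(ord), , drop = FALSE]
    list(coords = xy, class = cls)
  })
  annotation_set(polys)
}

normalize_group <- function(grp) {
  g <- gsub("[ _-]+", "_", tolower(trimws(grp %||% "")))
  map <- c(tissue = "tissue", background = "background",
           edge = "edge", edge_artifacts = "edge", edge_artifact = "edge",
           inner_artifact = "inner_artifact",
           inner_artifacts = "inner_artifact", artifacts = "inner_artifact")
  if (!g %in% names(map)) stop("unknown annotation group '", grp, "'")
  unname(map[g])
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || is.na(a)) b else a

#' Write annotations to an ASAP XML file
#'
#' @param annotations An `annotation_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_asap_xml <- function(annotations, path) {
  stopifnot(is_annotation_set(annotations))
  grp_name <- c(tissue = "tissue", background = "background",
                edge = "edge artifacts", inner_artifact = "inner artifacts")
  doc <- xml2::xml_new_root("ASAP_Annotations")
  anns <- xml2::xml_add_child(doc, "Annotations")
  for (i in seq_along(annotations$polygons)) {
    p <- annotations$polygons[[i]]
    a <- xml2::xml_add_child(anns, "Annotation",
                             Name = sprintf("Annotation %d", i - 1L),
                             Type = "Polygon",
                             PartOfGroup = grp_name[[p$class]])
    cs <- xml2::xml_add_child(a, "Coordinates")
    for (k in seq_len(nrow(p$coords))) {
      xml2::xml_add_child(cs, "Coordinate", Order = as.character(k - 1L),
                          X = format(p$coords[k, 1], digits = 10),
                          Y = format(p$coords[k, 2], digits = 10))
    }
  }
  grps <- xml2::xml_add_child(doc, "AnnotationGroups")
  for (g in unique(grp_name)) {
    xml2::xml_add_child(grps, "Group", Name = g, PartOfGroup = "None")
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read polygon annotations from GeoJSON
#'
#' Accepts a FeatureCollection of Polygon features whose properties carry the
#' class under `classification`, `class` or `group`. Only outer rings are
#' used; holes should be separate background features.
#'
#' @param path GeoJSON file path.
#' @return An `annotation_set`.
#' @export
read_annotation_geojson <- function(path) {
  if (!file.exists(path)) stop("no such file: '", path, "'")
  js <- jsonlite::read_json(path)
  feats <- if (!is.null(js$features)) js$features else list(js)
  polys <- lapply(feats, function(f) {
    if (!identical(f$geometry$type, "Polygon")) {
      stop("only Polygon geometries are supported")
    }
    ring <- f$geometry$coordinates[[1]]
    xy <- do.call(rbind, lapply(ring, function(pt) {
      c(as.numeric(pt[[1]]), as.numeric(pt[[2]]))
    }))
    # drop a closing vertex that repeats the first
    if (nrow(xy) > 1L && all(xy[1, ] == xy[nrow(xy), ])) {
      xy <- xy[-nrow(xy), , drop = FALSE]
    }
    cls <- f$properties$classification %||% f$properties$class %||%
      f$properties$group
    if (is.list(cls)) cls <- cls$name
    list(coords = xy, class = normalize_group(as.character(cls)))
  })
  annotation_set(polys)
}
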