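disc_poly <- function(cx, cy, r, n = 64L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  list(coords = cbind(cx + r * cos(th), cy + r * sin(th)), class = "tissue")
}

square_poly <- function(x0, y0, side, class = "tissue") {
  list(coords = cbind(c(x0, x0 + side, x0 + side, x0),
                      c(y0, y0, y0 + side, y0 + side)), class = class)
}

test_that("small tissue regions are removed at the 250 um diameter rule", {
  sp <- 0.5 # um / px
  small <- annotation_set(list(disc_poly(500, 500, 120 / sp))) # 240 um disc
  out <- clean_annotations(small, spacing = sp)
  expect_length(out$polygons, 0L)
  big <- annotation_set(list(disc_poly(500, 500, 130 / sp)))   # 260 um disc
  out2 <- clean_annotations(big, spacing = sp)
  expect_identical(out2$polygons, big$polygons) # retained unchanged
})

test_that("small annotated holes are removed too", {
  sp <- 0.5
  anns <- annotation_set(list(
    disc_poly(500, 500, 400 / sp),
    modifyList(disc_poly(500, 500, 100 / sp), list(class = "background"))))
  out <- clean_annotations(anns, spacing = sp)
  cls <- vapply(out$polygons, `[[`, character(1), "class")
  expect_false("background" %in% cls) # 200 um hole removed
  expect_equal(sum(cls == "tissue"), 1L)
})

test_that("tissue regions within 50 um merge; farther ones do not", {
  sp <- 0.5
  side <- 300 / sp
  # two 300 um squares separated by a 40 um gap
  near <- annotation_set(list(square_poly(100, 100, side),
                              square_poly(100 + side + 40 / sp, 100, side)))
  merged <- clean_annotations(near, spacing = sp)
  expect_length(merged$polygons, 1L)
  a_merged <- tissueseg:::polygon_area(merged$polygons[[1]]$coords)
  expect_gte(a_merged, 2 * side^2)
  # a 60 um gap stays two (unchanged) regions
  far <- annotation_set(list(square_poly(100, 100, side),
                             square_poly(100 + side + 60 / sp, 100, side)))
  expect_identical(clean_annotations(far, spacing = sp)$polygons,
                   far$polygons)
})

test_that("clean_annotations is idempotent", {
  sp <- 0.5
  side <- 300 / sp
  anns <- annotation_set(list(
    square_poly(100, 100, side),
    square_poly(100 + side + 40 / sp, 100, side),
    disc_poly(2000, 2000, 200 / sp),
    disc_poly(3000, 500, 100 / sp)))
  once <- clean_annotations(anns, spacing = sp)
  twice <- clean_annotations(once, spacing = sp)
  expect_length(once$polygons, 2L)
  expect_identical(lapply(twice$polygons, `[[`, "coords"),
                   lapply(once$polygons, `[[`, "coords"))
  expect_identical(clean_annotations(annotation_set(), spacing = sp)$polygons,
                   list())
})

test_that("merge matches brute-force closing semantics on pixel rasters", {
  # dilation/erosion by the 25 um disc bridges the 40 um gap but not 60 um
  sp <- 1
  side <- 300
  for (gap in c(40, 60)) {
    anns <- annotation_set(list(square_poly(50, 50, side),
                                square_poly(50 + side + gap, 50, side)))
    out <- clean_annotations(anns, spacing = sp)
    r <- 25
    k <- EBImage::makeBrush(2 * r + 1, "disc")
    m <- matrix(0L, 420, 800)
    for (p in anns$polygons) {
      f <- tissueseg:::.cpp_fill_polygon(p$coords[, 1], p$coords[, 2],
                                         420L, 800L)
      m[f$row0 + seq_len(nrow(f$mask)), f$col0 + seq_len(ncol(f$mask))] <-
        m[f$row0 + seq_len(nrow(f$mask)), f$col0 + seq_len(ncol(f$mask))] |
        f$mask
    }
    closed <- EBImage::closing(m, k)
    expect_equal(length(out$polygons),
                 max(tissueseg:::.cpp_label_components(
                   matrix(as.integer(closed > 0), nrow(m)), 8L)))
  }
})

test_that("rasterization fills by pixel center with even-odd rule", {
  lv <- level_ref(0L, 1)
  # empty set: all background
  r0 <- rasterize_annotations(annotation_set(), 32, 32, lv)
  expect_true(all(r0 == MASK_LABELS[["background"]]))
  # axis-aligned 10x10 square covers exactly 100 pixel centers
  sq <- annotation_set(list(square_poly(5, 5, 10)))
  r1 <- rasterize_annotations(sq, 32, 32, lv)
  expect_equal(sum(r1 == MASK_LABELS[["tissue"]]), 100L)
  # brute-force point-in-polygon over every pixel center agrees
  inside <- matrix(FALSE, 32, 32)
  for (i in 1:32) for (j in 1:32) {
    inside[i, j] <- tissueseg:::point_in_polygon(j - 0.5, i - 0.5,
                                                 sq$polygons[[1]]$coords)
  }
  expect_identical(unname(r1 == MASK_LABELS[["tissue"]]), inside)
})

test_that("background holes inside tissue are punched through", {
  lv <- level_ref(0L, 1)
  anns <- annotation_set(list(
    square_poly(2, 2, 28),
    square_poly(10, 10, 8, class = "background")))
  r <- rasterize_annotations(anns, 32, 32, lv)
  expect_equal(sum(r == MASK_LABELS[["background"]]),
               sum(r0_bg <- 32 * 32 - 28 * 28) + 64L)
  expect_equal(unname(r[15, 15]), unname(MASK_LABELS[["background"]]))
  expect_equal(unname(r[5, 5]), unname(MASK_LABELS[["tissue"]]))
})

test_that("polygons outside the extent are clipped with a warning", {
  lv <- level_ref(0L, 1)
  anns <- annotation_set(list(square_poly(-20, 10, 40)))
  expect_warning(r <- rasterize_annotations(anns, 32, 32, lv), "clipped")
  expect_gt(sum(r == MASK_LABELS[["tissue"]]), 0L)
})

test_that("ASAP XML annotations round trip", {
  anns <- annotation_set(list(
    square_poly(10.5, 20.25, 100),
    modifyList(square_poly(300, 300, 50), list(class = "background")),
    modifyList(square_poly(500, 100, 40), list(class = "edge")),
    modifyList(square_poly(700, 100, 40), list(class = "inner_artifact"))))
  path <- tempfile(fileext = ".xml")
  write_asap_xml(anns, path)
  r <- read_asap_xml(path)
  expect_length(r$polygons, 4L)
  expect_equal(vapply(r$polygons, `[[`, character(1), "class"),
               vapply(anns$polygons, `[[`, character(1), "class"))
  for (i in 1:4) {
    expect_equal(unname(r$polygons[[i]]$coords),
                 unname(anns$polygons[[i]]$coords), tolerance = 1e-8)
  }
  unlink(path)
})

test_that("GeoJSON annotations are read", {
  js <- list(type = "FeatureCollection", features = list(
    list(type = "Feature",
         properties = list(classification = list(name = "tissue")),
         geometry = list(type = "Polygon",
                         coordinates = list(list(list(0, 0), list(10, 0),
                                                 list(10, 10), list(0, 10),
                                                 list(0, 0)))))))
  path <- tempfile(fileext = ".geojson")
  jsonlite::write_json(js, path, auto_unbox = TRUE)
  r <- read_annotation_geojson(path)
  expect_length(r$polygons, 1L)
  expect_equal(r$polygons[[1]]$class, "tissue")
  expect_equal(nrow(r$polygons[[1]]$coords), 4L) # closing vertex dropped
  unlink(path)
})
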