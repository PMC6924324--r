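bm <- function(m, sp = 1) binary_mask(m, spacing = sp)

test_that("dice follows its definition and conventions", {
  a <- matrix(0L, 10, 10); a[1:8, 1:10] <- 1L # 80 px
  b <- matrix(0L, 10, 10); b[1:10, 1:10] <- 1L # 100 px, contains a
  expect_equal(dice(bm(a), bm(b)), 160 / 180)
  expect_equal(dice(bm(a), bm(a)), 1)
  d <- matrix(0L, 10, 10); d[9:10, ] <- 1L
  expect_equal(dice(bm(a), bm(d)), 0)
  # conventions for empty masks
  e <- matrix(0L, 5, 5)
  expect_equal(dice(bm(e), bm(e)), 1)
  expect_equal(dice(bm(e), bm(a[1:5, 1:5])), 0)
  expect_error(dice(bm(a), bm(e)), "shape")
})

test_that("dice is symmetric and bounded on random masks", {
  set.seed(19)
  for (k in 1:20) {
    a <- random_mask(40, 40, 2)
    b <- random_mask(40, 40, 2)
    d1 <- dice(bm(a), bm(b))
    expect_identical(d1, dice(bm(b), bm(a)))
    expect_gte(d1, 0)
    expect_lte(d1, 1)
  }
})

test_that("region metrics implement the 80 percent rule at its boundary", {
  ref <- matrix(0L, 20, 20)
  ref[1:10, 1:10] <- 1L # one region of 100 px
  pred80 <- matrix(0L, 20, 20); pred80[1:8, 1:10] <- 1L # 80 px detected
  r <- region_metrics(bm(pred80), bm(ref))
  expect_equal(r$tp, 1L)
  expect_equal(r$sensitivity, 1)
  pred79 <- pred80; pred79[8, 10] <- 0L # 79 px
  r2 <- region_metrics(bm(pred79), bm(ref))
  expect_equal(r2$tp, 0L)
  expect_equal(r2$fn, 1L)
  expect_equal(r2$sensitivity, 0)
})

test_that("false positives are disjoint predicted regions", {
  ref <- matrix(0L, 30, 30); ref[1:10, 1:10] <- 1L
  pred <- matrix(0L, 30, 30)
  pred[1:10, 1:10] <- 1L      # overlaps reference
  pred[20:25, 20:25] <- 1L    # disjoint blob: 1 FP
  r <- region_metrics(bm(pred), bm(ref))
  expect_equal(r$fp, 1L)
  expect_equal(r$fp_area_fraction, 36 / 900)
  # a single shared pixel suffices to escape the FP count
  pred2 <- matrix(0L, 30, 30); pred2[10:15, 10:15] <- 1L
  expect_equal(region_metrics(bm(pred2), bm(ref))$fp, 0L)
  # no reference regions: sensitivity undefined
  r3 <- region_metrics(bm(pred), bm(matrix(0L, 30, 30)))
  expect_true(is.nan(r3$sensitivity))
})

test_that("dice and region metrics match brute-force counting", {
  set.seed(23)
  for (k in 1:25) {
    H <- sample(40:96, 1); W <- sample(40:96, 1)
    p <- random_mask(H, W, sample(1:4, 1))
    r <- random_mask(H, W, sample(1:4, 1))
    expect_equal(dice(bm(p), bm(r)),
                 { i <- sum(p & r); s <- sum(p) + sum(r)
                   if (s == 0) 1 else 2 * i / s })
    got <- region_metrics(bm(p), bm(r))
    want <- oracle_region_metrics(p, r)
    expect_equal(got[c("tp", "fn", "fp")], want[c("tp", "fn", "fp")])
    expect_equal(got$fp_area_fraction, want$fp_area_fraction)
  }
})

test_that("region metrics are invariant to joint translation", {
  set.seed(29)
  p <- matrix(0L, 60, 60); p[10:20, 10:25] <- 1L; p[40:45, 40:45] <- 1L
  r <- matrix(0L, 60, 60); r[10:20, 10:24] <- 1L
  shift <- function(m, dy, dx) {
    out <- matrix(0L, nrow(m), ncol(m))
    out[(1 + dy):nrow(m), (1 + dx):ncol(m)] <-
      m[1:(nrow(m) - dy), 1:(ncol(m) - dx)]
    out
  }
  a <- region_metrics(bm(p), bm(r))
  b <- region_metrics(bm(shift(p, 7, 3)), bm(shift(r, 7, 3)))
  expect_equal(a[c("tp", "fn", "fp", "sensitivity")],
               b[c("tp", "fn", "fp", "sensitivity")])
})

test_that("compare_methods matches the reference t-test implementation", {
  set.seed(37)
  for (k in 1:100) {
    n <- sample(4:12, 1)
    a <- runif(n, 0.5, 1)
    b <- pmin(a + rnorm(n, 0, 0.05), 1)
    res <- compare_methods(data.frame(a = a, b = b))
    ref <- t.test(a, b, paired = TRUE)
    expect_equal(res$p_raw, ref$p.value, tolerance = 1e-10)
    expect_equal(res$t, unname(ref$statistic), tolerance = 1e-10)
  }
})

test_that("compare_methods applies the Bonferroni factor and handles ties", {
  set.seed(41)
  x <- runif(6)
  sc <- data.frame(a = x, b = x + rnorm(6, 0, 0.02), c = x + rnorm(6, 0, 0.02))
  res <- compare_methods(sc)
  expect_equal(nrow(res), 3L)
  expect_equal(res$p_corrected, pmin(1, res$p_raw * 3))
  # identical scores: t = 0, p = 1, not significant
  same <- compare_methods(data.frame(a = x, b = x))
  expect_equal(same$t, 0)
  expect_equal(same$p_corrected, 1)
  expect_false(same$significant)
  expect_true(same$degenerate)
  # constant non-zero difference: degenerate, reported below machine epsilon
  const <- compare_methods(data.frame(a = c(0.9, 0.92, 0.95, 0.97),
                                      b = c(0.7, 0.72, 0.75, 0.77)))
  expect_true(const$degenerate)
  expect_lte(const$p_raw, .Machine$double.eps)
  expect_true(const$significant)
  expect_equal(const$mean_diff, 0.2)
  expect_error(compare_methods(data.frame(a = 1:3)), "two methods")
  expect_error(compare_methods(data.frame(a = 1, b = 2)), "observations")
})

test_that("eval_report aggregates are recomputable from the rows", {
  rows <- data.frame(image = rep(c("i1", "i2", "i3"), 2),
                     method = rep(c("m1", "m2"), each = 3),
                     dice = c(0.9, 0.8, 0.7, 0.95, 0.85, 0.75),
                     sensitivity = c(1, 1, 0.5, 1, 1, 1),
                     fp = c(0L, 2L, 1L, 0L, 0L, 1L),
                     fp_area_fraction = rep(0.01, 6))
  rep_ <- eval_report(rows)
  m1 <- rep_$aggregates[rep_$aggregates$method == "m1", ]
  expect_equal(m1$dice_mean, mean(c(0.9, 0.8, 0.7)))
  expect_equal(m1$dice_sd, sd(c(0.9, 0.8, 0.7)))
  expect_equal(m1$dice_min, 0.7)
  expect_equal(m1$fp_max, 2)
})
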