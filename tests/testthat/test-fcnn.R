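test_that("the network has the declared architecture and parameter count", {
  spec <- network_spec()
  expect_equal(nrow(spec), 7L)
  expect_equal(spec$kernel, c(5, 5, 3, 3, 3, 1, 1))
  expect_equal(spec$channels_out, c(16, 32, 64, 64, 1024, 512, 2))
  expect_equal(sum(spec$pool_after), 3L)
  m <- build_network(seed = 1)
  n_params <- sum(vapply(m$W, length, numeric(1))) +
    sum(vapply(m$b, length, numeric(1)))
  # direct computation from the layer table
  want <- sum(spec$kernel^2 * spec$channels_in * spec$channels_out +
                spec$channels_out)
  expect_equal(n_params, want)
})

test_that("a 128x128 patch yields a 16x16 softmax map", {
  m <- build_network(seed = 2)
  x <- array(runif(128 * 128 * 3), c(128, 128, 3))
  p <- fcnn_forward(m, x)
  expect_equal(dim(p), c(16L, 16L, 2L, 1L))
  expect_lt(max(abs(p[, , 1, 1] + p[, , 2, 1] - 1)), 1e-5)
  expect_true(all(p >= 0 & p <= 1))
})

test_that("initialisation is seeded and deterministic", {
  m1 <- build_network(seed = 42)
  m2 <- build_network(seed = 42)
  m3 <- build_network(seed = 43)
  expect_identical(m1$W, m2$W)
  expect_false(identical(m1$W[[1]], m3$W[[1]]))
  # He scaling: sd ~ sqrt(2 / fan_in)
  expect_equal(sd(m1$W[[5]]), sqrt(2 / (64 * 9)), tolerance = 0.05)
})

test_that("the compiled forward pass matches a direct R computation", {
  m <- build_network(seed = 3)
  # thin the big layers so the naive oracle stays fast: zero most weights
  set.seed(4)
  for (l in 5:6) {
    keep <- sample(length(m$W[[l]]), 3000)
    w <- numeric(length(m$W[[l]]))
    w[keep] <- m$W[[l]][keep]
    m$W[[l]] <- matrix(w, nrow(m$W[[l]]), ncol(m$W[[l]]))
  }
  x <- array(runif(16 * 16 * 3), c(16, 16, 3))
  got <- fcnn_forward(m, x)[, , , 1]
  want <- oracle_fcnn_forward(m, x)
  expect_equal(got, want, tolerance = 1e-4)
})

test_that("analytic gradients match finite differences", {
  m <- build_network(seed = 5)
  set.seed(6)
  x <- array(runif(16 * 16 * 3), c(16, 16, 3, 1))
  y <- array(sample(0:1, 4, TRUE), c(2, 2, 1))
  st <- tissueseg:::.cpp_fcnn_train_step(x, y, m$W, m$b)
  loss_at <- function(W) tissueseg:::.cpp_fcnn_train_step(x, y, W, m$b)$loss
  h <- 1e-3
  worst <- 0
  for (l in c(1, 3, 5, 7)) {
    for (k in 1:3) {
      i <- sample(length(m$W[[l]]), 1)
      Wp <- m$W; Wp[[l]][i] <- Wp[[l]][i] + h
      Wm <- m$W; Wm[[l]][i] <- Wm[[l]][i] - h
      num <- (loss_at(Wp) - loss_at(Wm)) / (2 * h)
      ana <- st$grad_w[[l]][i]
      worst <- max(worst, abs(num - ana) / max(abs(num), abs(ana), 1e-3))
    }
  }
  expect_lt(worst, 0.05)
})

test_that("patch sampling follows the weighted class law", {
  # six-label mask with all classes present
  set.seed(8)
  mlab <- matrix(sample(1:6, 64 * 64, TRUE), 64, 64)
  sm <- sampling_mask(mlab, spacing = 1, level_index = 0L)
  pyr <- build_pyramid(array(runif(64 * 64 * 3), c(64, 64, 3)), 1, 1)
  smp <- patch_sampler(pyr, list(sm), spacings = 1)
  w <- c(1, 1, 1, 1, 5, 1)
  n <- 60000L
  cls <- tissueseg:::draw_classes(smp, 1L, w, n)
  freq <- tabulate(cls, 6L) / n
  expect_lt(abs(freq[5] - 0.5), 0.01)
  # chi-squared goodness of fit against the weight law
  expect_gt(chisq.test(tabulate(cls, 6L), p = w / sum(w))$p.value, 0.01)
})

test_that("sample_patch centers patches on the drawn class", {
  set.seed(9)
  mlab <- matrix(MASK_LABELS[["tissue"]], 64, 64)
  sm <- sampling_mask(mlab, spacing = 1, level_index = 0L)
  pyr <- build_pyramid(array(runif(64 * 64 * 3), c(64, 64, 3)), 1, 1)
  smp <- patch_sampler(pyr, list(sm), spacings = 1)
  for (k in 1:10) {
    s <- sample_patch(smp, patch_size = 16L)
    expect_equal(s$class, unname(MASK_LABELS[["tissue"]]))
    expect_equal(unname(mlab[s$center[2] + 1L, s$center[1] + 1L]),
                 unname(MASK_LABELS[["tissue"]]))
    expect_equal(dim(s$patch), c(16, 16, 3))
    expect_equal(dim(s$labels), c(16L, 16L))
  }
  # seeded determinism of the patch sequence
  set.seed(123)
  s1 <- lapply(1:5, function(i) sample_patch(smp, patch_size = 16L))
  set.seed(123)
  s2 <- lapply(1:5, function(i) sample_patch(smp, patch_size = 16L))
  expect_identical(s1, s2)
})

test_that("windows past the slide edge are padded white with background labels", {
  mlab <- matrix(MASK_LABELS[["tissue"]], 16, 16)
  sm <- sampling_mask(mlab, spacing = 1, level_index = 0L)
  pyr <- build_pyramid(array(0.2, c(16, 16, 3)), 1, 1)
  smp <- patch_sampler(pyr, list(sm), spacings = 1)
  set.seed(10)
  s <- sample_patch(smp, patch_size = 32L)
  expect_equal(dim(s$patch), c(32, 32, 3))
  expect_true(any(s$patch == 1)) # white padding present
  expect_true(any(s$labels == 0L)) # padded labels are non-tissue
})

test_that("dense targets pool the label window with the majority rule", {
  lab <- matrix(0L, 16, 16)
  lab[1:8, 1:8] <- 1L            # cell (1,1): all tissue
  lab[1:4, 9:16] <- 1L           # cell (1,2): exactly half -> tissue
  lab[9:11, 1:8] <- 1L           # cell (2,1): 3/8 -> non-tissue
  y <- tissueseg:::pool_labels(lab, 8L)
  expect_identical(y, matrix(c(1L, 0L, 1L, 0L), 2, 2))
})

test_that("the learning-rate schedule halves on stagnation and stops at 16", {
  # flat-accuracy training: tiny patches, zero learning progress expected
  mlab <- matrix(MASK_LABELS[["tissue"]], 32, 32)
  sm <- sampling_mask(mlab, spacing = 1, level_index = 0L)
  pyr <- build_pyramid(array(0.5, c(32, 32, 3)), 1, 1)
  smp <- list(patch_sampler(pyr, list(sm), spacings = 1))
  cfg <- train_config(patch_size = 16L, batch_size = 1L,
                      train_iterations = 1L, val_iterations = 1L,
                      max_epochs = 100L, spacings = 1,
                      improvement_tol = 2, # unattainable: accuracy <= 1
                      augment = FALSE, seed = 7L)
  fit <- train_fcnn(cfg, smp, smp)
  h <- fit$history
  # epoch 1 sets the best; 16 stagnant epochs follow
  expect_equal(nrow(h), 17L)
  expect_equal(h$lr[2], 1e-4)
  # lr used after one and two 4-epoch stagnations
  expect_equal(h$lr[6], 5e-5)
  expect_equal(h$lr[10], 2.5e-5)
  expect_equal(h$lr[14], 1.25e-5)
})

test_that("training is reproducible given the seed", {
  set.seed(77)
  mlab <- matrix(sample(c(3L, 6L), 32 * 32, TRUE), 32, 32)
  sm <- sampling_mask(mlab, spacing = 1, level_index = 0L)
  pyr <- build_pyramid(array(runif(32 * 32 * 3), c(32, 32, 3)), 1, 1)
  smp <- list(patch_sampler(pyr, list(sm), spacings = 1))
  cfg <- train_config(patch_size = 16L, batch_size = 2L,
                      train_iterations = 3L, val_iterations = 2L,
                      max_epochs = 2L, spacings = 1, augment = TRUE,
                      seed = 99L)
  f1 <- train_fcnn(cfg, smp, smp)
  f2 <- train_fcnn(cfg, smp, smp)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$W, f2$model$W)
  expect_error(train_fcnn(cfg, list(), smp), "non-empty")
})

test_that("checkpoints round trip", {
  m <- build_network(seed = 12)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  r <- load_checkpoint(path)
  expect_identical(r$W, m$W)
  unlink(path)
  saveRDS(list(1), path)
  expect_error(load_checkpoint(path), "checkpoint")
  unlink(path)
})
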