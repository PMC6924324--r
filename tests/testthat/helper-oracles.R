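# Independent oracles used across the suite. These deliberately use naive
# formulations (exhaustive scans, per-pixel loops, direct convolution) so
# they share no code path with the implementation they check.

# Exhaustive Otsu: scan all 256 candidate thresholds, computing the combined
# within-class variance directly from its definition.
oracle_otsu <- function(counts) {
  n <- sum(counts)
  lev <- 0:255
  best_t <- NA_integer_
  best_wcv <- Inf
  for (t in 1:255) {
    c0 <- counts[lev < t]
    c1 <- counts[lev >= t]
    n0 <- sum(c0)
    n1 <- sum(c1)
    if (n0 == 0 || n1 == 0) next
    l0 <- lev[lev < t]
    l1 <- lev[lev >= t]
    m0 <- sum(l0 * c0) / n0
    m1 <- sum(l1 * c1) / n1
    v0 <- sum(c0 * (l0 - m0)^2) / n0
    v1 <- sum(c1 * (l1 - m1)^2) / n1
    wcv <- (n0 * v0 + n1 * v1) / n
    if (wcv < best_wcv - 1e-9) {
      best_wcv <- wcv
      best_t <- t
    }
  }
  best_t
}

# Per-pixel Euclidean distance to the nearest TRUE pixel of `target`.
oracle_distance_to <- function(target) {
  H <- nrow(target); W <- ncol(target)
  idx <- which(target, arr.ind = TRUE)
  out <- matrix(Inf, H, W)
  if (!nrow(idx)) return(out)
  for (r in seq_len(H)) {
    for (c in seq_len(W)) {
      out[r, c] <- sqrt(min((idx[, 1] - r)^2 + (idx[, 2] - c)^2))
    }
  }
  out
}

# Connected components by repeated flood fill over an explicit neighbour
# list (no shared code with the C++ labelling).
oracle_label <- function(mask, connectivity = 8) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nb <- if (connectivity == 8) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  cur <- 0L
  for (j in seq_len(W)) for (i in seq_len(H)) {
    if (mask[i, j] == 0 || lab[i, j] != 0L) next
    cur <- cur + 1L
    queue <- list(c(i, j))
    lab[i, j] <- cur
    while (length(queue)) {
      p <- queue[[1]]
      queue <- queue[-1]
      for (k in seq_len(nrow(nb))) {
        ni <- p[1] + nb[k, 1]; nj <- p[2] + nb[k, 2]
        if (ni >= 1 && ni <= H && nj >= 1 && nj <= W &&
            mask[ni, nj] != 0 && lab[ni, nj] == 0L) {
          lab[ni, nj] <- cur
          queue[[length(queue) + 1L]] <- c(ni, nj)
        }
      }
    }
  }
  lab
}

# Region metrics by explicit per-component loops over oracle labels.
oracle_region_metrics <- function(pred, ref, tp_fraction = 0.8) {
  rl <- oracle_label(ref, 8)
  tp <- 0L; fn <- 0L
  if (max(rl) > 0) {
    for (l in seq_len(max(rl))) {
      a <- sum(rl == l)
      d <- sum(rl == l & pred != 0)
      if (d / a >= tp_fraction) tp <- tp + 1L else fn <- fn + 1L
    }
  }
  pl <- oracle_label(pred, 8)
  fp <- 0L; fp_area <- 0
  if (max(pl) > 0) {
    for (l in seq_len(max(pl))) {
      if (sum(pl == l & ref != 0) == 0) {
        fp <- fp + 1L
        fp_area <- fp_area + sum(pl == l)
      }
    }
  }
  list(tp = tp, fn = fn, fp = fp,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NaN,
       fp_area_fraction = fp_area / length(pred))
}

# Direct (quadruple-loop) forward pass of the network in double precision:
# same architecture, naive computation.
oracle_fcnn_forward <- function(model, x) {
  ks <- c(5, 5, 3, 3, 3, 1, 1)
  cin <- c(3, 16, 32, 64, 64, 1024, 512)
  cout <- c(16, 32, 64, 64, 1024, 512, 2)
  pool <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  a <- x # (H, W, C)
  for (l in 1:7) {
    k <- ks[l]; p <- k %/% 2
    H <- dim(a)[1]; W <- dim(a)[2]
    z <- array(0, c(H, W, cout[l]))
    for (co in seq_len(cout[l])) {
      acc <- matrix(model$b[[l]][co], H, W)
      for (ci in seq_len(cin[l])) {
        for (ky in seq_len(k)) for (kx in seq_len(k)) {
          wcol <- ci + cin[l] * ((ky - 1) + k * (kx - 1))
          w <- model$W[[l]][co, wcol]
          if (w == 0) next
          dy <- ky - 1 - p; dx <- kx - 1 - p
          src <- matrix(0, H, W)
          rs <- max(1, 1 + dy):min(H, H + dy)
          cs <- max(1, 1 + dx):min(W, W + dx)
          src[rs - dy, cs - dx] <- a[rs, cs, ci]
          acc <- acc + w * src
        }
      }
      z[, , co] <- acc
    }
    if (l < 7) z[z < 0] <- 0
    if (pool[l]) {
      H2 <- H %/% 2; W2 <- W %/% 2
      zp <- array(0, c(H2, W2, cout[l]))
      for (co in seq_len(cout[l])) {
        m <- z[, , co]
        zp[, , co] <- pmax(pmax(m[seq(1, 2 * H2, 2), seq(1, 2 * W2, 2)],
                                m[seq(2, 2 * H2, 2), seq(1, 2 * W2, 2)]),
                           pmax(m[seq(1, 2 * H2, 2), seq(2, 2 * W2, 2)],
                                m[seq(2, 2 * H2, 2), seq(2, 2 * W2, 2)]))
      }
      z <- zp
    }
    a <- z
  }
  e0 <- exp(a[, , 1] - pmax(a[, , 1], a[, , 2]))
  e1 <- exp(a[, , 2] - pmax(a[, , 1], a[, , 2]))
  array(c(e0 / (e0 + e1), e1 / (e0 + e1)), c(dim(a)[1], dim(a)[2], 2))
}

# A model whose output probability is a constant, independent of the input:
# all weights zero, final biases chosen for the requested tissue odds.
constant_prob_model <- function(p_tissue) {
  m <- build_network(seed = 1)
  for (l in 1:7) {
    m$W[[l]][] <- 0
    m$b[[l]][] <- 1 # keep ReLU channels alive
  }
  m$b[[7]] <- c(0, log(p_tissue / (1 - p_tissue)))
  m
}

# Random blobby binary mask for metric fixtures.
random_mask <- function(H, W, n_blobs = 3, rmax = NULL) {
  m <- matrix(0L, H, W)
  rmax <- rmax %||% (min(H, W) / 4)
  for (b in seq_len(n_blobs)) {
    r <- runif(1, 3, rmax)
    cy <- runif(1, 1, H)
    cx <- runif(1, 1, W)
    yy <- matrix(rep(seq_len(H), W), H)
    xx <- matrix(rep(seq_len(W), each = H), H)
    m[(yy - cy)^2 + (xx - cx)^2 <= r^2] <- 1L
  }
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Tiny flat-colour slide spec for fast pipeline tests. Small canvases get
# sub-cleanup-threshold blobs and are only suitable for tests that skip
# clean_annotations (e.g. tile-seam checks).
tiny_flat_spec <- function(seed, canvas = 768L, ...) {
  radius <- if (canvas < 700L) c(80, 105) else c(130, 180)
  synthetic_spec(canvas_px = canvas, spacing0 = 0.5, n_levels = 3L,
                 n_blobs = 1L, blob_radius_um = radius,
                 fatty_fraction = 0, texture = FALSE, blur_fraction = 0,
                 artifacts = c(air_bubble = FALSE, coverslip_edge = FALSE,
                               pen_mark = FALSE, stain_residue = FALSE),
                 background_sd = 0.003, seed = seed, ...)
}
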