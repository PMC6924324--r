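# Quantitative comparison of segmenters against reference masks.

#' Dice score between two binary masks
#'
#' `2 |P ∩ R| / (|P| + |R|)`. Two empty masks score 1.0 (nothing to find,
#' nothing found); one empty mask against a non-empty one scores 0.0.
#'
#' @param pred,ref `binary_mask` objects (or bare 0/1 matrices) of identical
#'   shape.
#' @return Dice score in `[0, 1]`.
#' @export
dice <- function(pred, ref) {
  p <- if (inherits(pred, "binary_mask")) pred$data else as.matrix(pred)
  r <- if (inherits(ref, "binary_mask")) ref$data else as.matrix(ref)
  if (!all(dim(p) == dim(r))) stop("mask shapes differ")
  np <- sum(p != 0)
  nr <- sum(r != 0)
  if (np + nr == 0L) return(1)
  2 * sum(p != 0 & r != 0) / (np + nr)
}

#' Region-level detection metrics
#'
#' Each 8-connected reference tissue region counts as a true positive when
#' at least 80 percent of its area is detected, otherwise as a false
#' negative. Each predicted region with no overlap at all with the reference
#' tissue counts as a false positive. Sensitivity is `TP / (TP + FN)`
#' (`NaN` when the reference has no regions); `fp_area_fraction` is the
#' summed false-positive area divided by the full level area.
#'
#' @param pred,ref `binary_mask` objects of identical shape.
#' @param tp_fraction Detection fraction making a reference region a true
#'   positive (default 0.8, inclusive).
#' @return List with `tp`, `fn`, `fp`, `sensitivity`, `fp_area_fraction`.
#' @export
region_metrics <- function(pred, ref, tp_fraction = 0.8) {
  p <- if (inherits(pred, "binary_mask")) pred$data else as.matrix(pred)
  r <- if (inherits(ref, "binary_mask")) ref$data else as.matrix(ref)
  if (!all(dim(p) == dim(r))) stop("mask shapes differ")
  rl <- .cpp_label_components(r, 8L)
  tp <- 0L; fn <- 0L
  if (max(rl) > 0L) {
    areas <- tabulate(rl, nbins = max(rl))
    hit <- tabulate(rl[p != 0], nbins = max(rl))
    tp <- sum(hit / areas >= tp_fraction)
    fn <- max(rl) - tp
  }
  pl <- .cpp_label_components(p, 8L)
  fp <- 0L; fp_area <- 0
  if (max(pl) > 0L) {
    overlap <- tabulate(pl[r != 0], nbins = max(pl))
    areas_p <- tabulate(pl, nbins = max(pl))
    fp_ids <- which(overlap == 0L)
    fp <- length(fp_ids)
    fp_area <- sum(areas_p[fp_ids])
  }
  list(tp = as.integer(tp), fn = as.integer(fn), fp = as.integer(fp),
       sensitivity = if (tp + fn > 0L) tp / (tp + fn) else NaN,
       fp_area_fraction = fp_area / length(p))
}

#' Evaluate one predicted mask against its reference
#'
#' @param pred,ref `binary_mask` objects of identical shape.
#' @return One-row data frame: dice, sensitivity, tp, fn, fp,
#'   fp_area_fraction.
#' @export
evaluate_mask <- function(pred, ref) {
  rm <- region_metrics(pred, ref)
  data.frame(dice = dice(pred, ref), sensitivity = rm$sensitivity,
             tp = rm$tp, fn = rm$fn, fp = rm$fp,
             fp_area_fraction = rm$fp_area_fraction)
}

#' Per-method evaluation report
#'
#' @param results Data frame with one row per image and method (columns
#'   `image`, `method`, plus the [evaluate_mask()] metrics).
#' @return An `eval_report`: the per-image rows plus per-method aggregates
#'   (mean, standard deviation, min, max of each metric).
#' @export
eval_report <- function(results) {
  stopifnot(all(c("image", "method", "dice") %in% names(results)))
  metrics <- intersect(c("dice", "sensitivity", "fp", "fp_area_fraction"),
                       names(results))
  agg <- do.call(rbind, lapply(split(results, results$method), function(g) {
    row <- data.frame(method = g$method[1])
    for (m in metrics) {
      v <- g[[m]][is.finite(g[[m]])]
      row[[paste0(m, "_mean")]] <- mean(v)
      row[[paste0(m, "_sd")]] <- if (length(v) > 1L) sd(v) else NA_real_
      row[[paste0(m, "_min")]] <- if (length(v)) min(v) else NA_real_
      row[[paste0(m, "_max")]] <- if (length(v)) max(v) else NA_real_
    }
    row
  }))
  rownames(agg) <- NULL
  structure(list(per_image = results, aggregates = agg),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("eval_report:", nrow(x$per_image), "image-method rows\n")
  print(x$aggregates, digits = 4)
  invisible(x)
}

#' Pairwise paired t-tests between methods
#'
#' Paired two-sided t-tests on per-image Dice scores for every method pair,
#' with Bonferroni correction (raw p multiplied by the number of pairs,
#' capped at 1). When the paired differences have zero variance the t
#' statistic is degenerate: the p-value is reported as 1 for identical
#' scores and as the machine-epsilon bound otherwise, with a `degenerate`
#' flag.
#'
#' @param scores Data frame or matrix with one column per method and one row
#'   per image (paired observations).
#' @param alpha Significance level applied to the corrected p (default 0.05).
#' @return Data frame with one row per method pair: mean difference, t
#'   statistic, raw and corrected p, significance flag, degeneracy flag.
#' @export
compare_methods <- function(scores, alpha = 0.05) {
  scores <- as.data.frame(scores)
  if (ncol(scores) < 2L) stop("need at least two methods")
  if (nrow(scores) < 2L) stop("need at least two paired observations")
  pairs <- utils::combn(names(scores), 2L)
  n_pairs <- ncol(pairs)
  rows <- lapply(seq_len(n_pairs), function(k) {
    a <- scores[[pairs[1, k]]]
    b <- scores[[pairs[2, k]]]
    d <- a - b
    n <- length(d)
    md <- mean(d)
    sdd <- sd(d)
    # zero-variance detection up to float rounding of the differences
    degen <- sdd == 0 || (abs(md) > 0 && sdd / abs(md) < 1e-12)
    if (degen) {
      tstat <- if (md == 0) 0 else sign(md) * Inf
      p <- if (md == 0) 1 else .Machine$double.eps
    } else {
      tstat <- md / (sdd / sqrt(n))
      p <- 2 * pt(-abs(tstat), df = n - 1L)
    }
    data.frame(method_a = pairs[1, k], method_b = pairs[2, k],
               mean_diff = md, t = tstat, p_raw = p,
               p_corrected = min(1, p * n_pairs),
               significant = min(1, p * n_pairs) < alpha,
               degenerate = degen)
  })
  do.call(rbind, rows)
}
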