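# Per-image, per-region segmentation metrics and their test-set summaries.
#
# Six metrics are computed per region of each image: four overlap metrics
# (IoU, Dice, precision, recall) from the pixel confusion counts, and two
# surface-distance metrics (HD95, ASSD) from the boundary pixels under the
# Euclidean metric. Two composite metrics then condense the six means:
# the average of the four overlap means, and the average of the two
# distance means.

#' Overlap metrics for one region of one image
#'
#' Computes the confusion counts and the four overlap metrics between a
#' predicted and a ground-truth binary mask. Conventions for degenerate
#' masks: if both masks are empty all four metrics are 1 (a correctly
#' predicted absent region); if exactly one is empty all four are 0.
#'
#' @param pred_mask,gt_mask binary matrices of identical shape.
#' @return list with `confusion` (tp, fp, fn) and `iou`, `dice`,
#'   `precision`, `recall`.
#' @examples
#' a <- matrix(0, 4, 4); a[2:3, 2:3] <- 1
#' overlap_metrics(a, a)$iou
#' @export
overlap_metrics <- function(pred_mask, gt_mask) {
  p <- check_mask(pred_mask, "pred_mask")
  g <- check_mask(gt_mask, "gt_mask")
  if (!all(dim(p) == dim(g))) stopf("pred_mask and gt_mask must share shape")
  tp <- sum(p == 1L & g == 1L)
  fp <- sum(p == 1L & g == 0L)
  fn <- sum(p == 0L & g == 1L)
  if (tp + fp + fn == 0L) {          # both empty: perfect absence
    m <- c(iou = 1, dice = 1, precision = 1, recall = 1)
  } else {
    m <- c(iou = tp / (tp + fp + fn),
           dice = 2 * tp / (2 * tp + fp + fn),
           precision = if (tp + fp > 0L) tp / (tp + fp) else 0,
           recall = if (tp + fn > 0L) tp / (tp + fn) else 0)
  }
  c(list(confusion = c(tp = tp, fp = fp, fn = fn)), as.list(m))
}

# Boundary pixels: foreground pixels with at least one background 4-neighbour;
# pixels on the frame edge count the outside as background.
boundary_mask <- function(mask) {
  m <- check_mask(mask)
  n <- nrow(m); k <- ncol(m)
  up <- rbind(matrix(0L, 1, k), m[-n, , drop = FALSE])
  dn <- rbind(m[-1, , drop = FALSE], matrix(0L, 1, k))
  lf <- cbind(matrix(0L, n, 1), m[, -k, drop = FALSE])
  rt <- cbind(m[, -1, drop = FALSE], matrix(0L, n, 1))
  m == 1L & (up == 0L | dn == 0L | lf == 0L | rt == 0L)
}

# Distance from every pixel to the nearest TRUE pixel of `target` (exact
# Euclidean distance transform).
dist_to_set <- function(target) {
  if (!any(target)) stopf("dist_to_set: empty target set")
  # distmap(x): distance of non-zero pixels to the nearest zero pixel.
  d <- EBImage::distmap(matrix(as.numeric(!target), nrow(target)), metric = "euclidean")
  matrix(EBImage::imageData(d), nrow(target))
}

#' Symmetric surface-distance metrics (HD95 and ASSD)
#'
#' Extracts the boundary pixels of both masks, computes the directed
#' Euclidean distances from each boundary pixel of one mask to the nearest
#' boundary pixel of the other, pools both directions, and reports the 95th
#' percentile (HD95, linear interpolation between order statistics) and the
#' mean (ASSD) of the pooled distances, in pixels.
#'
#' If either mask is empty the distances are undefined: the metrics are
#' returned as `NA` with `valid = FALSE`, never fabricated.
#'
#' @param pred_mask,gt_mask binary matrices of identical shape.
#' @param hd_floor optional lower floor applied to HD95 for compatibility
#'   with pipelines that clamp it (e.g. `hd_floor = 1`); default none.
#' @return list with `hd95`, `assd` and `valid`.
#' @export
surface_distance_metrics <- function(pred_mask, gt_mask, hd_floor = NULL) {
  p <- check_mask(pred_mask, "pred_mask")
  g <- check_mask(gt_mask, "gt_mask")
  if (!all(dim(p) == dim(g))) stopf("pred_mask and gt_mask must share shape")
  if (!any(p == 1L) || !any(g == 1L))
    return(list(hd95 = NA_real_, assd = NA_real_, valid = FALSE))
  bp <- boundary_mask(p)
  bg <- boundary_mask(g)
  d_to_g <- dist_to_set(bg)
  d_to_p <- dist_to_set(bp)
  pooled <- c(d_to_g[bp], d_to_p[bg])
  hd95 <- unname(stats::quantile(pooled, 0.95, type = 7))
  if (!is.null(hd_floor)) hd95 <- max(hd95, hd_floor)
  list(hd95 = hd95, assd = mean(pooled), valid = TRUE)
}

#' All six metrics for every region of one image pair
#'
#' @param pred_map,gt_map label maps (values 0..4) of identical shape.
#' @param image id recorded in the output rows.
#' @param hd_floor see [surface_distance_metrics()].
#' @return data frame with one row per region and columns
#'   `image, region, iou, dice, precision, recall, hd95, assd, valid`.
#' @export
evaluate_image <- function(pred_map, gt_map, image = NA_character_, hd_floor = NULL) {
  pm <- check_label_map(pred_map, "pred_map")
  gm <- check_label_map(gt_map, "gt_map")
  if (!all(dim(pm) == dim(gm))) stopf("pred_map and gt_map must share shape")
  rows <- lapply(1:4, function(k) {
    p <- matrix(as.integer(pm == k), nrow(pm))
    g <- matrix(as.integer(gm == k), nrow(gm))
    ov <- overlap_metrics(p, g)
    sd <- surface_distance_metrics(p, g, hd_floor = hd_floor)
    data.frame(image = image, region = REGIONS[k],
               iou = ov$iou, dice = ov$dice, precision = ov$precision,
               recall = ov$recall, hd95 = sd$hd95, assd = sd$assd,
               valid = sd$valid, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Test-set summary of per-image metrics for one region
#'
#' Mean, sample standard deviation (N-1), maximum and minimum per metric.
#' Images whose distance metrics are invalid (empty prediction or ground
#' truth) are excluded from the HD95/ASSD summaries, with the excluded
#' count reported.
#'
#' @param records data frame of per-image metrics for one region, as
#'   produced by [evaluate_image()] (columns iou, dice, precision, recall,
#'   hd95, assd, valid).
#' @return an object of class `region_summary`: per-metric rows of
#'   mean/sd/max/min, `n` images, `n_invalid_distance`.
#' @export
summarize_region <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) >= 1L)
  overlap_cols <- c("iou", "dice", "precision", "recall")
  dist_cols <- c("hd95", "assd")
  valid <- if ("valid" %in% names(records)) records$valid else !is.na(records$hd95)
  summ <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0L) return(c(mean = NA, sd = NA, max = NA, min = NA))
    c(mean = mean(x), sd = if (length(x) > 1L) stats::sd(x) else 0,
      max = max(x), min = min(x))
  }
  tab <- rbind(
    t(vapply(records[overlap_cols], summ, numeric(4))),
    t(vapply(lapply(records[dist_cols], function(x) x[valid]), summ, numeric(4)))
  )
  rownames(tab) <- c(overlap_cols, dist_cols)
  structure(list(table = tab, n = nrow(records),
                 n_invalid_distance = sum(!valid)),
            class = "region_summary")
}

#' @export
print.region_summary <- function(x, ...) {
  cat(sprintf("Region summary over %d images (%d excluded from distance metrics)\n",
              x$n, x$n_invalid_distance))
  tab <- x$table
  for (m in rownames(tab))
    cat(sprintf("  %-9s %.4f ± %.4f (%.4f–%.4f)\n",
                m, tab[m, "mean"], tab[m, "sd"], tab[m, "max"], tab[m, "min"]))
  invisible(x)
}

#' Composite metrics from the six per-region means
#'
#' The first composite is the average of the four overlap means
#' (`(mIoU + mDice + mPrecision + mRecall) / 4`, unitless, higher better);
#' the second is the average of the two distance means
#' (`(mHD95 + mASSD) / 2`, pixels, lower better).
#'
#' @param means a `region_summary` object, or a named numeric vector with
#'   entries `iou, dice, precision, recall, hd95, assd` holding the means.
#' @return named numeric vector `c(mean_metric_1, mean_metric_2)`.
#' @examples
#' comprehensive(c(iou = 0.9320, dice = 0.9644, precision = 0.9733,
#'                 recall = 0.9566, hd95 = 2.4335, assd = 0.8414))
#' @export
comprehensive <- function(means) {
  if (inherits(means, "region_summary")) means <- means$table[, "mean"]
  need <- c("iou", "dice", "precision", "recall", "hd95", "assd")
  if (!all(need %in% names(means)) || anyNA(means[need]))
    stopf("all six metric means must be present and non-missing")
  m <- as.numeric(means[need])
  c(mean_metric_1 = sum(m[1:4]) / 4, mean_metric_2 = sum(m[5:6]) / 2)
}

#' Cross-region overall means
#'
#' Unweighted average, per metric, of the four per-region means.
#'
#' @param region_means data frame with one row per region and columns
#'   `mean_iou, mean_dice, mean_precision, mean_recall, mean_hd95,
#'   mean_assd` (or a list of four `region_summary` objects).
#' @return named numeric vector of the six overall means.
#' @export
overall_means <- function(region_means) {
  if (is.list(region_means) && !is.data.frame(region_means)) {
    stopifnot(length(region_means) == 4L)
    region_means <- do.call(rbind, lapply(region_means, function(s) {
      stopifnot(inherits(s, "region_summary"))
      as.data.frame(as.list(stats::setNames(s$table[, "mean"],
        paste0("mean_", rownames(s$table)))))
    }))
  }
  need <- paste0("mean_", c("iou", "dice", "precision", "recall", "hd95", "assd"))
  if (!all(need %in% names(region_means))) stopf("missing mean columns")
  if (nrow(region_means) != 4L) stopf("all four regions must be present")
  stats::setNames(colMeans(region_means[need]), need)
}

#' Improvement in percentage points between two means
#'
#' For ascending metrics (overlap: higher is better) the improvement is
#' `(new - baseline) * 100`; for descending metrics (HD95/ASSD: lower is
#' better) it is `(baseline - new) * 100`, so positive always means the new
#' model improved.
#'
#' @param baseline_mean,new_mean the two means.
#' @param direction `"ascending"` or `"descending"`.
#' @return improvement in percentage points, rounded to 2 decimals.
#' @export
improvement_pp <- function(baseline_mean, new_mean,
                           direction = c("ascending", "descending")) {
  direction <- match.arg(direction)
  stopifnot(is.finite(baseline_mean), is.finite(new_mean))
  d <- if (direction == "ascending") new_mean - baseline_mean else baseline_mean - new_mean
  round(d * 100, 2)
}

#' Write per-image metric records as CSV
#' @param records data frame from [evaluate_image()] (possibly rbind-ed).
#' @param path output path.
#' @export
write_metrics_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}
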