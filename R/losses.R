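# Loss components for multi-object region segmentation.
#
# Each of the four foreground regions is treated as an independent binary
# problem (one-vs-rest): the network predicts a foreground probability map
# per region, and the per-region binary cross-entropy losses are combined
# with external weights (alpha, beta, gamma, eta). Soft Dice and boundary
# terms can be mixed in with coefficients tau1 (CE), tau2 (Dice), tau3
# (boundary).

PROB_FLOOR <- 1e-7  # probabilities are clamped away from 0/1 before log

#' Prediction batch container
#'
#' Validates and bundles per-region foreground probabilities with their
#' binary targets. Both are arrays whose last dimension indexes the four
#' regions; all leading dimensions (pixels, images) are treated alike.
#'
#' @param probs numeric array in `[0, 1]`, last dimension of extent 4.
#' @param targets binary array of the same shape.
#' @return object of class `prediction_batch`.
#' @export
prediction_batch <- function(probs, targets) {
  probs <- as.array(probs); targets <- as.array(targets)
  if (!identical(dim(probs), dim(targets))) stopf("probs and targets must share shape")
  nd <- length(dim(probs))
  if (dim(probs)[nd] != 4L) stopf("last dimension must index the 4 regions")
  if (any(probs < 0 | probs > 1)) stopf("probs must lie in [0, 1]")
  if (!all(targets %in% c(0, 1))) stopf("targets must be binary")
  structure(list(probs = probs, targets = targets,
                 n_pixels = prod(dim(probs)[-nd])),
            class = "prediction_batch")
}

region_slice <- function(a, k) {
  nd <- length(dim(a))
  idx <- rep(list(quote(expr = )), nd)
  idx[[nd]] <- k
  as.numeric(do.call(`[`, c(list(a), idx)))
}

#' Weighted binary cross-entropy for one region
#'
#' The negative mean over pixels of the internally weighted log-likelihood
#' of the region's binary problem: foreground pixels contribute
#' `w_fg * log(p)` and background pixels `w_bg * log(1 - p)`. Probabilities
#' are clamped to `[1e-7, 1 - 1e-7]` before the log.
#'
#' @param probs,targets numeric vectors/arrays of equal length (one region).
#' @param internal length-2 positive vector `c(w_bg, w_fg)` of internal
#'   class weights; default `c(1, 1)` (the plain binary CE).
#' @return scalar loss.
#' @examples
#' region_binary_ce(c(0.8, 0.4), c(1, 0))  # -(log .8 + log .6)/2
#' @export
region_binary_ce <- function(probs, targets, internal = c(1, 1)) {
  p <- as.numeric(probs); y <- as.numeric(targets)
  if (length(p) != length(y)) stopf("probs and targets must share shape")
  if (length(internal) != 2L || any(internal <= 0)) stopf("internal weights must be 2 positive numbers")
  p <- clamp(p, PROB_FLOOR, 1 - PROB_FLOOR)
  -mean(internal[2] * y * log(p) + internal[1] * (1 - y) * log(1 - p))
}

#' External weighting of the four per-region CE losses
#'
#' @param per_region_losses numeric vector of four finite per-region losses.
#' @param weights an [external_weights()] object (scheme CE1 or CE2).
#' @return scalar weighted sum.
#' @export
weighted_ce <- function(per_region_losses, weights) {
  stopifnot(inherits(weights, "external_weights"))
  l <- as_region_vector(per_region_losses, "per-region losses")
  if (any(!is.finite(l))) stopf("per-region losses must be finite")
  sum(weights$weights * l)
}

#' Soft Dice loss over the four regions
#'
#' One minus the mean over regions of the smoothed Dice coefficient
#' `(2 * sum(p*y) + s) / (sum(p) + sum(y) + s)`. With the default smoothing
#' `s = 1` an empty target with an empty prediction scores a perfect 1
#' (zero loss contribution).
#'
#' @param batch a [prediction_batch()].
#' @param smooth smoothing constant `s`.
#' @return scalar loss in `[0, 1]`.
#' @export
soft_dice_loss <- function(batch, smooth = 1) {
  stopifnot(inherits(batch, "prediction_batch"))
  terms <- vapply(1:4, function(k) {
    p <- region_slice(batch$probs, k); y <- region_slice(batch$targets, k)
    (2 * sum(p * y) + smooth) / (sum(p) + sum(y) + smooth)
  }, numeric(1))
  1 - mean(terms)
}

#' Signed Euclidean distance map of a binary mask
#'
#' Positive outside the region (distance to the nearest foreground pixel),
#' negative inside, with the region's boundary pixels (foreground pixels
#' having a background 4-neighbour) at exactly zero: interior values are
#' `-(d_bg - 1)` where `d_bg` is the distance to the nearest background
#' pixel. The frame is treated as surrounded by background, so a region
#' touching the frame edge has zero there.
#'
#' An all-background mask has no meaningful interior; it is returned as all
#' `NA` with attribute `degenerate = TRUE` and a warning.
#'
#' @param binary_mask binary matrix.
#' @return numeric matrix of signed distances (pixels).
#' @export
signed_distance_map <- function(binary_mask) {
  m <- check_mask(binary_mask, "binary_mask")
  if (!any(m == 1L)) {
    warning("signed_distance_map: all-background mask is degenerate")
    out <- matrix(NA_real_, nrow(m), ncol(m))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- matrix(0, nrow(m), ncol(m))
  if (any(m == 0L)) {
    d_out <- dist_to_set(m == 1L)          # bg pixels: distance to region
    out[m == 0L] <- d_out[m == 0L]
  }
  # interior: pad with a background ring so edge-touching regions behave
  pad <- matrix(0L, nrow(m) + 2L, ncol(m) + 2L)
  pad[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] <- m
  d_in <- dist_to_set(pad == 0L)[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)]
  out[m == 1L] <- -(d_in[m == 1L] - 1)
  attr(out, "degenerate") <- FALSE
  out
}

#' Boundary loss over the four regions
#'
#' The mean over regions of the pixel-mean of `p * phi`, where `phi` is the
#' ground-truth signed distance map of the region. Probability mass inside
#' the target (negative `phi`) decreases the loss; mass far outside
#' increases it. Regions whose ground truth is empty have a degenerate
#' distance map and are excluded from the mean.
#'
#' @param batch a [prediction_batch()].
#' @param gt_sdm optional list of four signed distance maps matching the
#'   targets; computed from the targets when omitted (requires the batch to
#'   hold whole images, i.e. matrix-shaped region slices).
#' @return scalar loss (can be negative).
#' @export
boundary_loss <- function(batch, gt_sdm = NULL) {
  stopifnot(inherits(batch, "prediction_batch"))
  dims <- dim(batch$probs)
  if (is.null(gt_sdm)) {
    if (length(dims) != 3L) stopf("gt_sdm must be supplied unless the batch is a single [H, W, 4] image")
    gt_sdm <- lapply(1:4, function(k)
      suppressWarnings(signed_distance_map(matrix(region_slice(batch$targets, k), dims[1]))))
  }
  stopifnot(length(gt_sdm) == 4L)
  terms <- vapply(1:4, function(k) {
    phi <- as.numeric(gt_sdm[[k]])
    if (isTRUE(attr(gt_sdm[[k]], "degenerate")) || anyNA(phi)) return(NA_real_)
    p <- region_slice(batch$probs, k)
    if (length(p) != length(phi)) stopf("signed distance map %d does not match batch shape", k)
    mean(p * phi)
  }, numeric(1))
  if (all(is.na(terms))) stopf("all regions degenerate in boundary loss")
  mean(terms, na.rm = TRUE)
}

#' Mix configuration for the combined loss
#'
#' @param tau1,tau2,tau3 nonnegative coefficients for the weighted CE, soft
#'   Dice and boundary components; at least one must be positive.
#' @return object of class `loss_mix`.
#' @export
loss_mix <- function(tau1 = 1, tau2 = 0, tau3 = 0) {
  tau <- c(tau1 = tau1, tau2 = tau2, tau3 = tau3)
  if (any(tau < 0) || all(tau == 0)) stopf("mix coefficients must be nonnegative with at least one positive")
  structure(as.list(tau), class = "loss_mix")
}

#' Mixed segmentation loss with full breakdown
#'
#' Computes the per-region CE losses, their externally weighted sum, the
#' soft Dice and boundary components, and the mixed total
#' `tau1 * L_CE + tau2 * L_Dice + tau3 * L_BD`.
#'
#' @param batch a [prediction_batch()].
#' @param weights an [external_weights()] object.
#' @param internal internal class weights `c(w_bg, w_fg)` for the CE terms.
#' @param mix a [loss_mix()].
#' @param smooth Dice smoothing constant.
#' @param gt_sdm optional precomputed signed distance maps (see
#'   [boundary_loss()]); only needed when `tau3 > 0`.
#' @return object of class `loss_breakdown` with fields `per_region_ce`,
#'   `ce_total`, `dice_total`, `bd_total`, `mixed_total`, `weights`, `mix`.
#' @export
mixed_loss <- function(batch, weights, internal = c(1, 1),
                       mix = loss_mix(1, 0, 0), smooth = 1, gt_sdm = NULL) {
  stopifnot(inherits(batch, "prediction_batch"), inherits(mix, "loss_mix"))
  per_region <- vapply(1:4, function(k)
    region_binary_ce(region_slice(batch$probs, k),
                     region_slice(batch$targets, k), internal),
    numeric(1))
  names(per_region) <- REGIONS
  ce <- weighted_ce(per_region, weights)
  dice <- soft_dice_loss(batch, smooth)
  bd <- if (mix$tau3 > 0) boundary_loss(batch, gt_sdm) else 0
  structure(list(per_region_ce = per_region, ce_total = ce,
                 dice_total = dice, bd_total = bd,
                 mixed_total = mix$tau1 * ce + mix$tau2 * dice + mix$tau3 * bd,
                 weights = weights, mix = mix),
            class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf("Mixed loss: %.6f  (tau = %.2f/%.2f/%.2f, scheme %s)\n",
              x$mixed_total, x$mix$tau1, x$mix$tau2, x$mix$tau3, x$weights$scheme))
  cat(sprintf("  CE total %.6f | Dice %.6f | Boundary %.6f\n",
              x$ce_total, x$dice_total, x$bd_total))
  cat("  per-region CE:", paste(sprintf("%s=%.4f", names(x$per_region_ce),
                                        x$per_region_ce), collapse = ", "), "\n")
  invisible(x)
}

#' Read a loss configuration from YAML
#'
#' Expected fields: `scheme` (`CE1`/`CE2`), `tau` (three mix
#' coefficients), `internal_weights` (`auto` or two numbers), `smoothing`.
#' Missing fields take the package defaults.
#'
#' @param path YAML file path.
#' @return list with `scheme`, `mix` (a [loss_mix()]), `internal`,
#'   `smooth`.
#' @export
read_loss_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  tau <- cfg$tau %||% c(1, 0, 0)
  if (length(tau) != 3) stopf("tau must have three entries")
  list(scheme = match.arg(cfg$scheme %||% "CE2", c("CE2", "CE1")),
       mix = loss_mix(tau[1], tau[2], tau[3]),
       internal = cfg$internal_weights %||% c(1, 1),
       smooth = cfg$smoothing %||% 1)
}

# ---- gradients w.r.t. the foreground probabilities --------------------------
# Used by the training harness, whose model backward maps d(loss)/d(probs)
# through its own output nonlinearity (softmax for the reference model).

grad_ce_probs <- function(p, y, internal = c(1, 1)) {
  pc <- clamp(p, PROB_FLOOR, 1 - PROB_FLOOR)
  # d/dp of -mean(w1 y log p + w0 (1-y) log(1-p))
  (internal[1] * (1 - y) / (1 - pc) - internal[2] * y / pc) / length(p)
}

grad_dice_probs <- function(p, y, smooth = 1) {
  num <- 2 * sum(p * y) + smooth
  den <- sum(p) + sum(y) + smooth
  dT_dp <- (2 * y * den - num) / den^2
  # loss term for one region is -T/4 (mean over 4 regions)
  -dT_dp / 4
}

grad_bd_probs <- function(p, phi, n_active = 4) {
  phi / (n_active * length(p))
}
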