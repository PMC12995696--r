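# Desk-scale training harness.
#
# The harness trains any model satisfying a small contract — a factory
# returning init/forward/backward closures mapping an image to four
# per-region foreground probability maps — under the three-phase learning
# rate schedule, an AdamW-style optimizer and the serial stopping criteria,
# then evaluates the best-on-validation parameters on the test split.
#
# The built-in reference model is deliberately small: a pixelwise
# multilayer perceptron (one shared tanh hidden layer, a 5-class softmax
# head over background + the four regions) over handcrafted per-pixel
# features. The softmax coupling is what makes the external region
# weighting matter, exactly as in full segmentation networks: the regions
# compete for probability mass on every pixel, so up-weighting the tendon's
# loss moves ambiguous pixels toward the tendon instead of merely rescaling
# an independent head. It is a test vehicle for the loss/metric stack, not
# a segmentation network of record.

# Per-pixel feature matrix for one image: intensity at several blur scales,
# a difference-of-Gaussians band-pass (thin bright structures such as the
# tendon respond strongly at their own scale), gradient magnitude (high on
# bone edges, moderate inside thin bands) and normalized coordinates.
pixel_features <- function(image) {
  n <- nrow(image)
  blur_m <- function(s) matrix(EBImage::imageData(EBImage::gblur(image, sigma = s)), n)
  b1 <- blur_m(1); b2 <- blur_m(2); b4 <- blur_m(4)
  gx <- cbind(b1[, -1] - b1[, -n], 0)
  gy <- rbind(b1[-1, ] - b1[-n, ], 0)
  grad <- sqrt(gx^2 + gy^2)
  i1 <- as.numeric(image)
  g <- coord_grids(n)
  cbind(intensity = i1, blur2 = as.numeric(b2), blur4 = as.numeric(b4),
        dog = as.numeric(b1 - b4), grad = as.numeric(grad),
        x = (as.numeric(g$x) - 0.5) / n, y = (as.numeric(g$y) - 0.5) / n,
        int2 = i1^2)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Factory for the built-in small reference segmentation model
#'
#' A pixelwise MLP with one shared tanh hidden layer and a 5-class softmax
#' output (background plus the four regions). The model exposes the four
#' foreground probability maps; gradients are taken with respect to the
#' five softmax logits, so the regions genuinely compete for probability
#' mass on each pixel.
#'
#' @param hidden number of hidden units in the shared layer.
#' @return a model factory (function of a seed) satisfying the harness
#'   contract: the factory returns a list with `init(d)`, `forward(X,
#'   params)` giving an N x 4 foreground-probability matrix, and
#'   `backward(X, params, cache, dP)` giving parameter gradients from the
#'   loss gradient with respect to the four foreground probabilities.
#' @export
reference_small <- function(hidden = 24) {
  function(seed) {
    list(
      init = function(d) {
        withr::with_seed(seed, list(
          W1 = matrix(stats::rnorm(d * hidden, 0, sqrt(1 / d)), d, hidden),
          b1 = numeric(hidden),
          W2 = matrix(stats::rnorm(hidden * 5, 0, sqrt(1 / hidden)), hidden, 5),
          b2 = numeric(5)))
      },
      forward = function(X, params) {
        H <- tanh(sweep(X %*% params$W1, 2, params$b1, `+`))
        Z <- sweep(H %*% params$W2, 2, params$b2, `+`)
        E <- exp(Z - apply(Z, 1, max))
        P5 <- E / rowSums(E)
        list(probs = P5[, 1:4, drop = FALSE], cache = list(H = H, P5 = P5))
      },
      backward = function(X, params, cache, dP) {
        # dP: d(loss)/d(foreground probs), N x 4; softmax Jacobian gives
        # dZ_j = sum_k dP_k * P_k * (1[k == j] - P_j) over the 5 logits
        H <- cache$H; P5 <- cache$P5
        gP <- P5[, 1:4, drop = FALSE] * dP
        s <- rowSums(gP)
        dZ <- cbind(gP, 0) - P5 * s
        dW2 <- crossprod(H, dZ)
        db2 <- colSums(dZ)
        dH <- dZ %*% t(params$W2) * (1 - H^2)
        list(W1 = crossprod(X, dH), b1 = colSums(dH), W2 = dW2, b2 = db2)
      })
  }
}

adamw_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, weight_decay = 0.01) {
  state$t <- state$t + 1
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * (mhat / (sqrt(vhat) + eps) +
                                         weight_decay * params[[nm]])
  }
  list(params = params, state = state)
}

targets_from_label_map <- function(lm) {
  vapply(1:4, function(k) as.numeric(lm == k), numeric(length(lm)))
}

# Label map by arg-max over background and the four regions; the background
# score is the probability mass not claimed by any region.
probs_to_label_map <- function(P, n) {
  pbg <- pmax(0, 1 - rowSums(P))
  lab <- max.col(cbind(pbg, P), ties.method = "first") - 1L
  matrix(as.integer(lab), n)
}

miou_on_set <- function(model, params, feats, labs, n) {
  ious <- vapply(seq_along(feats), function(i) {
    P <- model$forward(feats[[i]], params)$probs
    lab <- probs_to_label_map(P, n)
    vapply(1:4, function(k) {
      p <- as.integer(lab) == k
      g <- labs[[i]] == k
      u <- sum(p | g)
      if (u == 0) 1 else sum(p & g) / u
    }, numeric(1))
  }, numeric(4))
  list(total = mean(ious), per_region = rowMeans(ious))
}

#' Experiment specification for the harness
#'
#' @param network model name; `"reference_small"` selects the built-in
#'   model, any other name requires an explicit `model_factory` in
#'   [run_experiment()].
#' @param scheme `"CE1"` or `"CE2"` external weighting.
#' @param mix a [loss_mix()] giving the CE/Dice/boundary coefficients.
#' @return object of class `experiment_spec`.
#' @export
experiment_spec <- function(network = "reference_small",
                            scheme = c("CE2", "CE1"), mix = loss_mix(1, 0, 0)) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(mix, "loss_mix"))
  structure(list(network = network, scheme = scheme, mix = mix),
            class = "experiment_spec")
}

#' Train a model on phantom data and evaluate it on the test split
#'
#' Trains with an AdamW-style optimizer under the three-phase learning-rate
#' schedule; validates every 50 iterations (total and tendon mean IoU),
#' applies the serial stopping criteria, keeps the parameters that perform
#' best on the validation set (largest total mean IoU), and finally
#' evaluates those parameters on the test split with the full six-metric
#' suite. External CE2 weights are computed from the training-split label
#' maps only.
#'
#' @param spec an [experiment_spec()].
#' @param data list with `train`, `val`, `test`: each a list of
#'   `knee_phantom` objects (or lists with `image` and `label_map`).
#' @param seed integer seed controlling initialization and batch sampling.
#' @param model_factory optional factory overriding the built-in
#'   [reference_small()] contract.
#' @param control list: `max_iters` (2000), `batch` (1024 pixels),
#'   `eval_every` (50), `lr` (an [lr_schedule_config()]), `thresholds`
#'   (see [stopping_decision()]), `internal` CE class weights — a fixed
#'   length-2 vector `c(w_bg, w_fg)` applied to every region (default
#'   `c(1, 1)`), or `"auto"` to derive inverse-frequency weights per region
#'   from the training split.
#' @return object of class `knee_experiment`: `params` (best-on-validation),
#'   `metrics` (per-image, per-region test records), `history` (data frame
#'   of iteration, lr, loss, validation mIoUs), `stop_reason`, `weights`.
#' @export
run_experiment <- function(spec, data, seed = 1, model_factory = NULL,
                           control = list()) {
  stopifnot(inherits(spec, "experiment_spec"))
  stopifnot(all(c("train", "val", "test") %in% names(data)))
  ctrl <- utils::modifyList(list(
    max_iters = 2000, batch = 1024, eval_every = 50, lr = NULL,
    thresholds = list(loss = 0.2, total_miou = 0.8, tendon_miou = 0.85,
                      fluctuation = 0.001, max_iters = 2000),
    internal = c(1, 1)), control)
  ctrl$lr <- ctrl$lr %||%
    lr_schedule_config(base_lr = 0.02, warmup_steps = 50,
                       poly_end_step = round(0.8 * ctrl$max_iters),
                       max_iters = ctrl$max_iters)
  ctrl$thresholds$max_iters <- ctrl$max_iters

  factory <- model_factory %||%
    (if (spec$network == "reference_small") reference_small()
     else stopf("no model factory supplied for network '%s'", spec$network))
  model <- factory(seed)
  if (!all(c("init", "forward", "backward") %in% names(model)))
    stopf("model factory violates the contract: needs init/forward/backward")

  # external weights from the training split only
  train_maps <- lapply(data$train, `[[`, "label_map")
  w <- if (spec$scheme == "CE2") dual_level_weights(area_stats(train_maps))$weights
       else uniform_weights()
  ww <- w$weights

  n <- nrow(data$train[[1]]$image)
  feats_tr <- lapply(data$train, function(f) pixel_features(f$image))
  labs_tr <- lapply(data$train, function(f) as.integer(f$label_map))
  X_all <- do.call(rbind, feats_tr)
  Y_all <- targets_from_label_map(unlist(labs_tr))
  sdm_all <- if (spec$mix$tau3 > 0) {
    do.call(rbind, lapply(data$train, function(f)
      vapply(1:4, function(k)
        as.numeric(suppressWarnings(signed_distance_map(
          matrix(as.integer(f$label_map == k), n)))), numeric(n * n))))
  } else NULL

  feats_val <- lapply(data$val, function(f) pixel_features(f$image))
  labs_val <- lapply(data$val, function(f) f$label_map)

  # internal class weights per region: inverse frequency over the training
  # pixels (mean weight 1 within each region's binary problem)
  internal_k <- if (identical(ctrl$internal, "auto")) {
    lapply(1:4, function(k) {
      q <- clamp(mean(Y_all[, k]), 1e-4, 1 - 1e-4)
      c(1 / (2 * (1 - q)), 1 / (2 * q))
    })
  } else {
    stopifnot(length(ctrl$internal) == 2L)
    rep(list(ctrl$internal), 4)
  }

  params <- model$init(ncol(X_all))
  opt <- list(t = 0,
              m = lapply(params, function(p) p * 0),
              v = lapply(params, function(p) p * 0))
  smooth <- 1
  contract_checked <- FALSE
  best <- list(miou = -Inf, params = params)
  window <- numeric(0)
  history <- list()
  stop_reason <- "stop_max_iters"

  withr::with_seed(seed + 7919L, {
    for (it in seq_len(ctrl$max_iters)) {
      idx <- sample.int(nrow(X_all), ctrl$batch)
      X <- X_all[idx, , drop = FALSE]
      Y <- Y_all[idx, , drop = FALSE]
      fw <- model$forward(X, params)
      P <- fw$probs
      if (!contract_checked) {
        if (!is.matrix(P) || ncol(P) != 4L || any(P < 0 | P > 1))
          stopf("model factory violates the prediction contract (N x 4 probabilities)")
        contract_checked <- TRUE
      }
      dP <- matrix(0, nrow(P), 4)
      loss_ce <- 0
      for (k in 1:4) {
        lk <- region_binary_ce(P[, k], Y[, k], internal_k[[k]])
        loss_ce <- loss_ce + ww[k] * lk
        dP[, k] <- dP[, k] + spec$mix$tau1 * ww[k] *
          grad_ce_probs(P[, k], Y[, k], internal_k[[k]])
      }
      loss_dice <- 0
      if (spec$mix$tau2 > 0) {
        for (k in 1:4) {
          num <- 2 * sum(P[, k] * Y[, k]) + smooth
          den <- sum(P[, k]) + sum(Y[, k]) + smooth
          loss_dice <- loss_dice + (1 - num / den) / 4
          dP[, k] <- dP[, k] + spec$mix$tau2 * grad_dice_probs(P[, k], Y[, k], smooth)
        }
      }
      loss_bd <- 0
      if (spec$mix$tau3 > 0) {
        phi <- sdm_all[idx, , drop = FALSE]
        for (k in 1:4) {
          loss_bd <- loss_bd + mean(P[, k] * phi[, k]) / 4
          dP[, k] <- dP[, k] + spec$mix$tau3 * grad_bd_probs(P[, k], phi[, k])
        }
      }
      loss <- spec$mix$tau1 * loss_ce + spec$mix$tau2 * loss_dice +
              spec$mix$tau3 * loss_bd
      grads <- model$backward(X, params, fw$cache, dP)
      stepped <- adamw_step(params, grads, opt, lr_at(it, ctrl$lr))
      params <- stepped$params; opt <- stepped$state

      if (it %% ctrl$eval_every == 0) {
        vm <- miou_on_set(model, params, feats_val, labs_val, n)
        window <- c(window, vm$total)
        history[[length(history) + 1]] <- data.frame(
          iteration = it, lr = lr_at(it, ctrl$lr), loss = loss,
          val_total_miou = vm$total, val_tendon_miou = vm$per_region[4])
        if (vm$total > best$miou) best <- list(miou = vm$total, params = params)
        dec <- stopping_decision(
          list(iteration = it, train_loss = loss, val_total_miou = vm$total,
               val_tendon_miou = vm$per_region[4], miou_window = window),
          ctrl$thresholds)
        if (dec != "continue") { stop_reason <- dec; break }
      }
    }
  })
  if (best$miou == -Inf) best$params <- params

  metrics <- do.call(rbind, lapply(seq_along(data$test), function(i) {
    f <- data$test[[i]]
    P <- model$forward(pixel_features(f$image), best$params)$probs
    evaluate_image(probs_to_label_map(P, n), f$label_map,
                   image = sprintf("test_%02d", i))
  }))
  structure(list(spec = spec, params = best$params, weights = w,
                 metrics = metrics,
                 history = do.call(rbind, history),
                 stop_reason = stop_reason, seed = seed,
                 val_miou = best$miou, model = model, image_side = n),
            class = "knee_experiment")
}

#' @export
print.knee_experiment <- function(x, ...) {
  cat(sprintf("Trained %s [%s, tau %.2f/%.2f/%.2f], seed %d\n",
              x$spec$network, x$spec$scheme, x$spec$mix$tau1, x$spec$mix$tau2,
              x$spec$mix$tau3, x$seed))
  cat(sprintf("  stop: %s after %d iterations; best val total mIoU %.4f\n",
              x$stop_reason, max(x$history$iteration), x$val_miou))
  agg <- stats::aggregate(iou ~ region, x$metrics, mean)
  cat("  test mean IoU:", paste(sprintf("%s=%.3f", agg$region, agg$iou),
                                collapse = ", "), "\n")
  invisible(x)
}

#' Predict a label map for a new image with a trained experiment
#' @param object a `knee_experiment`.
#' @param image square intensity matrix matching the training resolution.
#' @param ... unused.
#' @return integer label map.
#' @export
predict.knee_experiment <- function(object, image, ...) {
  stopifnot(nrow(image) == object$image_side)
  P <- object$model$forward(pixel_features(image), object$params)$probs
  probs_to_label_map(P, nrow(image))
}
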