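# Learning-rate schedule, serial stopping criteria, and the experiment grid.

#' Three-phase learning-rate schedule configuration
#'
#' The schedule has a linear warmup to the base rate, a polynomial decay
#' phase down to `poly_end_factor * base_lr`, and a cosine tail to zero.
#' The phases are continuous at both boundaries.
#'
#' @param base_lr peak learning rate reached at the end of warmup.
#' @param warmup_steps length of the linear warmup.
#' @param warmup_start_factor fraction of `base_lr` at step 0.
#' @param poly_end_step last step of the polynomial phase (default 80% of
#'   `max_iters`).
#' @param poly_power polynomial decay exponent.
#' @param poly_end_factor fraction of `base_lr` at the end of the
#'   polynomial phase (where the cosine tail takes over).
#' @param cosine_end_step step at which the cosine tail reaches zero.
#' @param max_iters hard iteration cap.
#' @return object of class `lr_schedule_config`.
#' @export
lr_schedule_config <- function(base_lr = 1e-4, warmup_steps = 500,
                               warmup_start_factor = 0.01,
                               poly_end_step = NULL, poly_power = 0.9,
                               poly_end_factor = 0.1,
                               cosine_end_step = NULL, max_iters = 50000) {
  poly_end_step <- poly_end_step %||% round(0.8 * max_iters)
  cosine_end_step <- cosine_end_step %||% max_iters
  stopifnot(base_lr > 0, warmup_start_factor > 0, warmup_start_factor <= 1,
            poly_power > 0, poly_end_factor > 0, poly_end_factor < 1)
  if (!(warmup_steps > 0 && warmup_steps <= poly_end_step &&
        poly_end_step <= cosine_end_step && cosine_end_step <= max_iters))
    stopf("need 0 < warmup_steps <= poly_end_step <= cosine_end_step <= max_iters")
  structure(list(base_lr = base_lr, warmup_steps = warmup_steps,
                 warmup_start_factor = warmup_start_factor,
                 poly_end_step = poly_end_step, poly_power = poly_power,
                 poly_end_factor = poly_end_factor,
                 cosine_end_step = cosine_end_step, max_iters = max_iters),
            class = "lr_schedule_config")
}

#' Learning rate at a training step
#'
#' @param step integer step (vectorized), `0 <= step <= max_iters`.
#' @param config an [lr_schedule_config()].
#' @return learning rate(s).
#' @export
lr_at <- function(step, config = lr_schedule_config()) {
  stopifnot(inherits(config, "lr_schedule_config"))
  if (any(step < 0 | step > config$max_iters)) stopf("step out of [0, max_iters]")
  b <- config$base_lr
  lr_end <- config$poly_end_factor * b
  warm <- b * (config$warmup_start_factor +
               (1 - config$warmup_start_factor) * step / config$warmup_steps)
  tpoly <- clamp((step - config$warmup_steps) /
                 (config$poly_end_step - config$warmup_steps), 0, 1)
  poly <- lr_end + (b - lr_end) * (1 - tpoly)^config$poly_power
  tcos <- clamp((step - config$poly_end_step) /
                (config$cosine_end_step - config$poly_end_step), 0, 1)
  cosine <- lr_end * 0.5 * (1 + cos(pi * tcos))
  out <- ifelse(step <= config$warmup_steps, warm,
         ifelse(step <= config$poly_end_step, poly, cosine))
  ifelse(step > config$cosine_end_step, 0, out)
}

#' Serial stopping decision
#'
#' Four criteria in series, all of which must hold to stop before the
#' iteration cap: training loss below the loss threshold, validation total
#' mean IoU above its threshold, validation patellar-tendon mean IoU above
#' its (stricter) threshold, and a stable plateau — the relative
#' fluctuation `(max - min) / mean` of the total mean IoU over the last 10
#' validation evaluations below the fluctuation threshold. The cap stops
#' training regardless.
#'
#' @param state list with `iteration`, `train_loss`, `val_total_miou`,
#'   `val_tendon_miou` and `miou_window` (up to the last 10 total-mIoU
#'   evaluations, most recent last).
#' @param thresholds list with `loss` (0.2), `total_miou` (0.8),
#'   `tendon_miou` (0.85), `fluctuation` (0.001), `max_iters` (50000).
#' @return `"continue"`, `"stop_converged"` or `"stop_max_iters"`.
#' @export
stopping_decision <- function(state,
                              thresholds = list(loss = 0.2, total_miou = 0.8,
                                                tendon_miou = 0.85,
                                                fluctuation = 0.001,
                                                max_iters = 50000)) {
  stopifnot(is.list(state), !is.null(state$iteration))
  if (state$iteration >= thresholds$max_iters) return("stop_max_iters")
  w <- state$miou_window
  ok <- isTRUE(state$train_loss < thresholds$loss) &&
        isTRUE(state$val_total_miou > thresholds$total_miou) &&
        isTRUE(state$val_tendon_miou > thresholds$tendon_miou) &&
        length(w) >= 10 &&
        {
          w10 <- utils::tail(w, 10)
          (max(w10) - min(w10)) / mean(w10) < thresholds$fluctuation
        }
  if (ok) "stop_converged" else "continue"
}

#' Enumerate the loss-function experiment grid
#'
#' For each network: the plain dual-level CE model, optionally the
#' equal-weight CE baseline, three CE+Dice mixes, three CE+boundary mixes
#' (ratios 0.90:0.10, 0.50:0.50, 0.10:0.90 each), and three triple mixes
#' (0.80:0.10:0.10, 0.34:0.33:0.33, 0.50:0.25:0.25) — eleven (or ten)
#' models per network.
#'
#' @param networks character vector of network names.
#' @param include_ce1 include the equal-weight CE baseline per network.
#' @return data frame of experiment specs: `network`, `scheme`, `tau1`,
#'   `tau2`, `tau3`, `model_id`.
#' @export
enumerate_experiments <- function(networks = c("FCN_UNet", "PSPNet_R50c",
                                               "DeepLabV3+_R50c", "UPerNet_R50c",
                                               "SegFormer_B2"),
                                  include_ce1 = TRUE) {
  pair <- rbind(c(0.90, 0.10), c(0.50, 0.50), c(0.10, 0.90))
  triple <- rbind(c(0.80, 0.10, 0.10), c(0.34, 0.33, 0.33), c(0.50, 0.25, 0.25))
  one_net <- function(net) {
    rows <- list()
    if (include_ce1)
      rows[[length(rows) + 1]] <- data.frame(network = net, scheme = "CE1",
                                             tau1 = NA_real_, tau2 = NA_real_, tau3 = NA_real_)
    rows[[length(rows) + 1]] <- data.frame(network = net, scheme = "CE2",
                                           tau1 = NA_real_, tau2 = NA_real_, tau3 = NA_real_)
    for (i in 1:3)
      rows[[length(rows) + 1]] <- data.frame(network = net, scheme = "CE2+DICE",
                                             tau1 = pair[i, 1], tau2 = pair[i, 2], tau3 = NA_real_)
    for (i in 1:3)
      rows[[length(rows) + 1]] <- data.frame(network = net, scheme = "CE2+BD",
                                             tau1 = pair[i, 1], tau2 = NA_real_, tau3 = pair[i, 2])
    for (i in 1:3)
      rows[[length(rows) + 1]] <- data.frame(network = net, scheme = "CE2+DICE+BD",
                                             tau1 = triple[i, 1], tau2 = triple[i, 2], tau3 = triple[i, 3])
    do.call(rbind, rows)
  }
  out <- do.call(rbind, lapply(networks, one_net))
  ratio_str <- ifelse(is.na(out$tau1), "",
                      paste0(" ", sprintf("%.2f", out$tau1),
                             ifelse(is.na(out$tau2), "", paste0(":", sprintf("%.2f", out$tau2))),
                             ifelse(is.na(out$tau3), "", paste0(":", sprintf("%.2f", out$tau3)))))
  out$model_id <- paste0(out$network, " | ", out$scheme, ratio_str)
  rownames(out) <- NULL
  out
}
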