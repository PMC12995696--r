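# Synthetic knee phantom generator.
#
# The phantom is not an anatomical model: it reproduces the one property
# that drives the loss-weighting machinery — a severely imbalanced division
# of the labeled area among four simply connected structures, with a thin
# tendon band — in a lateral-view-like layout. Femur and tibia are elongated
# capsule-ended shafts meeting at a joint gap, the patella is an ellipse
# anterior to the femur, and the patellar tendon is a thin band from the
# patella to the tibial tuberosity. The tibial shaft swings with the flexion
# angle.

#' Phantom configuration
#'
#' @param image_size pixels per side (square frame), at least 64.
#' @param target_ratios four positive fractions of the *labeled* area
#'   (patella, femur, tibia, patellar tendon) summing to 1. The default is
#'   the knee-like imbalance implied by the area-balanced CE2 weights:
#'   normalizing the reciprocals of (0.2704, 0.0324, 0.0360, 0.6612).
#' @param flexion_angle knee flexion in degrees, in `[0, 120]`.
#' @param noise_sd additive Gaussian intensity noise (intensity units,
#'   image range is `[0, 1]`).
#' @param blur_sigma Gaussian blur applied to the rendered intensities
#'   (pixels), emulating focal blur and soft-tissue scatter.
#' @param labeled_fraction fraction of the frame covered by the four
#'   labeled structures together.
#' @param seed integer seed; the generator is a pure function of the
#'   configuration including the seed.
#' @return object of class `phantom_config`.
#' @export
phantom_config <- function(image_size = 512,
                           target_ratios = c(patella = 0.058, femur = 0.483,
                                             tibia = 0.435, patellar_tendon = 0.024),
                           flexion_angle = 0, noise_sd = 0.03, blur_sigma = 1.5,
                           labeled_fraction = 0.35, seed = 1) {
  target_ratios <- as_region_vector(target_ratios, "target_ratios")
  if (any(target_ratios <= 0)) stopf("target_ratios must be strictly positive")
  if (abs(sum(target_ratios) - 1) > 1e-9) stopf("target_ratios must sum to 1")
  if (!is_count(image_size) || image_size < 64) stopf("image_size must be an integer >= 64")
  if (flexion_angle < 0 || flexion_angle > 120) stopf("flexion_angle must be in [0, 120]")
  stopifnot(noise_sd >= 0, blur_sigma >= 0,
            labeled_fraction > 0, labeled_fraction < 0.8)
  structure(list(image_size = as.integer(image_size), target_ratios = target_ratios,
                 flexion_angle = flexion_angle, noise_sd = noise_sd,
                 blur_sigma = blur_sigma, labeled_fraction = labeled_fraction,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# Pixel-center coordinate grids (x = column, y = row).
coord_grids <- function(n) {
  list(x = matrix(rep(seq_len(n), each = n), n),
       y = matrix(rep(seq_len(n), times = n), n))
}

# Membership of a capsule: rectangle of half-width w2 along direction
# (ux, uy) from v in [v0, v1], plus a semicircular cap at the v1 end.
capsule_mask <- function(g, cx, cy, ux, uy, w2, v0, v1, cap = c("none", "start", "end")) {
  cap <- match.arg(cap)
  dx <- g$x - cx; dy <- g$y - cy
  v <- dx * ux + dy * uy          # along axis
  u <- -dx * uy + dy * ux         # across axis
  m <- abs(u) <= w2 & v >= v0 & v <= v1
  if (cap == "end")   m <- m | ((v - v1)^2 + u^2 <= w2^2 & v > v1)
  if (cap == "start") m <- m | ((v - v0)^2 + u^2 <= w2^2 & v < v0)
  m
}

# Distance from points to the segment p1-p2 (vectorized over matrices).
seg_dist <- function(gx, gy, x1, y1, x2, y2) {
  vx <- x2 - x1; vy <- y2 - y1
  L2 <- vx^2 + vy^2
  t <- clamp(((gx - x1) * vx + (gy - y1) * vy) / L2, 0, 1)
  sqrt((gx - (x1 + t * vx))^2 + (gy - (y1 + t * vy))^2)
}

#' Generate one knee phantom frame
#'
#' Deterministic given the configuration (including its seed). The realized
#' labeled-area fraction of every region is guaranteed within ±20% relative
#' of its target ratio; geometry that cannot satisfy the targets at the
#' requested image size (for example a tendon band thinner than one pixel)
#' raises an error.
#'
#' @param config a [phantom_config()].
#' @return object of class `knee_phantom`: `image` (matrix in `[0, 1]`),
#'   `label_map` (integer matrix, 0 = background, 1 = patella, 2 = femur,
#'   3 = tibia, 4 = patellar tendon), `true_areas` (pixel counts including
#'   background), `frame_index`, `flexion_angle`.
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  withr::with_seed(config$seed, generate_phantom_impl(config))
}

generate_phantom_impl <- function(config) {
  n <- config$image_size
  A_lab <- config$labeled_fraction * n^2
  A <- config$target_ratios * A_lab   # target pixel areas per region
  g <- coord_grids(n)

  # Seeded geometric jitter keeps frames from being identical across seeds.
  jit <- function(s) stats::runif(1, -s, s)
  cx <- (0.52 + jit(0.015)) * n       # joint center
  cy <- (0.48 + jit(0.015)) * n
  gap <- max(2, 0.015 * n)            # joint space between femur and tibia

  # Capsule area = (l - w/2) * w + pi * w^2 / 8; solve for w by fixed point.
  capsule_width <- function(A, l) {
    w <- A / l
    for (i in 1:6) w <- A / (l - (0.5 - pi / 8) * w)
    w
  }

  # Femur: near-vertical shaft above the joint; the rounded distal cap
  # reaches the joint line.
  th_f <- (jit(2) * pi / 180)         # small axis jitter
  uf <- c(sin(th_f), -cos(th_f))      # pointing up
  l_f <- min((0.44 + jit(0.01)) * n, cy - gap / 2 - 2)
  w_f <- capsule_width(A[["femur"]], l_f)
  if (w_f < 2 || w_f > 0.55 * n) stopf("phantom geometry unsatisfiable: femur width %.1f px", w_f)
  femur <- capsule_mask(g, cx, cy - gap / 2, uf[1], uf[2], w_f / 2, w_f / 2, l_f,
                        cap = "start")

  # Tibia: shaft below the joint, swung anteriorly with flexion.
  swing <- config$flexion_angle * 0.4 * pi / 180  # screen-space swing
  ut <- c(-sin(swing + th_f), cos(swing + th_f))  # pointing down, rotated
  l_t <- (0.42 + jit(0.01)) * n
  w_t <- capsule_width(A[["tibia"]], l_t)
  if (w_t < 2 || w_t > 0.55 * n) stopf("phantom geometry unsatisfiable: tibia width %.1f px", w_t)
  tibia <- capsule_mask(g, cx, cy + gap / 2, ut[1], ut[2], w_t / 2, w_t / 2, l_t,
                        cap = "start")

  # Patella: ellipse anterior (to the left) of the femoral shaft.
  b_p <- sqrt(A[["patella"]] * 1.8 / pi)   # vertical semi-axis, aspect 1.8
  a_p <- b_p / 1.8
  px <- cx - w_f / 2 - 0.025 * n - a_p
  py <- cy - (0.10 + jit(0.01)) * n
  if (px - a_p < 1) stopf("phantom geometry unsatisfiable: patella outside frame")
  patella <- ((g$x - px) / a_p)^2 + ((g$y - py) / b_p)^2 <= 1

  # Patellar tendon: thin band from the patellar apex to the tibial
  # tuberosity. The band is a stadium around the segment p1-tub; its width
  # is the order statistic of the segment distances over unoccupied pixels
  # that realizes the target pixel count exactly, so overlap with the
  # patella/tibia cannot bias the tendon's area share.
  p1 <- c(px + 0.2 * a_p, py + b_p + 1)
  tub <- c(cx, cy + gap / 2) + 0.25 * n * ut + c(-1, 0) * (w_t / 2)
  band_d <- seg_dist(g$x, g$y, p1[1], p1[2], tub[1], tub[2])
  occupied <- femur | tibia | patella
  free_d <- sort(band_d[!occupied])
  target_px <- round(A[["patellar_tendon"]])
  if (target_px < 1 || target_px > length(free_d))
    stopf("phantom geometry unsatisfiable: tendon target of %d px", target_px)
  th_w <- 2 * free_d[target_px]
  if (th_w < 1) stopf("phantom geometry unsatisfiable: tendon thinner than 1 px at image_size %d", n)
  tendon <- band_d <= th_w / 2

  lm <- matrix(0L, n, n)
  lm[femur] <- 2L
  lm[tibia & lm == 0L] <- 3L
  lm[patella & lm == 0L] <- 1L
  lm[tendon & lm == 0L] <- 4L

  counts <- tabulate(lm[lm > 0L], nbins = 4L)
  realized <- counts / sum(counts)
  rel_err <- abs(realized - config$target_ratios) / config$target_ratios
  if (any(rel_err > 0.20))
    stopf("phantom geometry unsatisfiable: realized ratios (%s) deviate > 20%% from targets",
          paste(sprintf("%.4f", realized), collapse = ", "))

  img <- matrix(0.12, n, n)
  img[lm == 2L | lm == 3L] <- 0.85
  img[lm == 1L] <- 0.80
  img[lm == 4L] <- 0.45
  if (config$blur_sigma > 0)
    img <- matrix(EBImage::imageData(EBImage::gblur(img, sigma = config$blur_sigma)), n)
  if (config$noise_sd > 0)
    img <- img + matrix(stats::rnorm(n * n, 0, config$noise_sd), n)
  img <- clamp(img, 0, 1)

  structure(list(image = img, label_map = lm,
                 true_areas = stats::setNames(c(sum(lm == 0L), counts),
                                              c("background", REGIONS)),
                 frame_index = 0L, flexion_angle = config$flexion_angle),
            class = "knee_phantom")
}

#' @export
print.knee_phantom <- function(x, ...) {
  n <- nrow(x$image)
  cat(sprintf("Knee phantom %dx%d, frame %d, flexion %.1f deg\n",
              n, n, x$frame_index, x$flexion_angle))
  fg <- x$true_areas[-1]
  cat("  labeled-area fractions:",
      paste(sprintf("%s=%.3f", names(fg), fg / sum(fg)), collapse = ", "), "\n")
  invisible(x)
}

#' Generate a dynamic sequence of phantom frames
#'
#' Frames emulate a dynamic acquisition: the flexion angle varies
#' monotonically over `angle_range` across `n_frames` frames (the frame
#' rate itself is metadata, not geometry).
#'
#' @param config a [phantom_config()]; its `flexion_angle` is overridden
#'   per frame.
#' @param n_frames number of frames (>= 1).
#' @param angle_range length-2 increasing vector of flexion angles spanned.
#' @return list of `knee_phantom` objects with increasing `frame_index`.
#' @export
generate_sequence <- function(config, n_frames, angle_range = c(0, 50)) {
  stopifnot(inherits(config, "phantom_config"), is_count(n_frames), n_frames >= 1)
  if (n_frames > 1 && angle_range[2] <= angle_range[1])
    stopf("angle_range must be increasing when n_frames > 1")
  angles <- seq(angle_range[1], angle_range[2], length.out = n_frames)
  lapply(seq_len(n_frames), function(i) {
    cf <- config
    cf$flexion_angle <- angles[i]
    cf$seed <- config$seed + (i - 1L) * 1000L
    ph <- generate_phantom(cf)
    ph$frame_index <- i - 1L
    ph
  })
}

#' Perturb a label map into a synthetic "prediction"
#'
#' Produces prediction masks with analytically known metric values:
#' translation by integer pixels (one region or all), morphological
#' dilation/erosion with a square structuring element of radius `r`, or
#' dropping a region to background. Dilation claims background pixels only
#' (other regions are never overwritten); a translated single region
#' overwrites what it lands on.
#'
#' @param label_map integer label map (0..4).
#' @param type one of `"shift"`, `"dilate"`, `"erode"`, `"drop_region"`.
#' @param dx,dy integer shift in columns/rows (shift only).
#' @param r structuring-element radius in pixels (dilate/erode).
#' @param region region label 1..4 to perturb; `NULL` means all regions
#'   (shift only).
#' @return perturbed label map.
#' @export
perturb_mask <- function(label_map, type = c("shift", "dilate", "erode", "drop_region"),
                         dx = 0, dy = 0, r = 1, region = NULL) {
  lm <- check_label_map(label_map)
  type <- match.arg(type)
  n <- nrow(lm); k <- ncol(lm)
  shift_one <- function(mask, dx, dy) {
    out <- matrix(FALSE, n, k)
    idx <- which(mask, arr.ind = TRUE)
    nr <- idx[, 1] + dy; nc <- idx[, 2] + dx
    keep <- nr >= 1 & nr <= n & nc >= 1 & nc <= k
    if (!any(keep)) stopf("shift moves the region fully outside the frame")
    out[cbind(nr[keep], nc[keep])] <- TRUE
    out
  }
  switch(type,
    shift = {
      stopifnot(is_count(dx), is_count(dy))
      if (is.null(region)) {
        out <- matrix(0L, n, k)
        for (lab in 1:4) {
          m <- lm == lab
          if (!any(m)) next
          out[shift_one(m, dx, dy)] <- lab
        }
        out
      } else {
        stopifnot(region %in% 1:4)
        m <- lm == region
        if (!any(m)) stopf("region %d absent", region)
        out <- lm
        out[m] <- 0L
        out[shift_one(m, dx, dy)] <- as.integer(region)
        out
      }
    },
    dilate = {
      stopifnot(!is.null(region), region %in% 1:4, is_count(r), r >= 1)
      m <- lm == region
      grown <- m
      for (dy2 in -r:r) for (dx2 in -r:r) {
        if (dx2 == 0 && dy2 == 0) next
        idx <- which(m, arr.ind = TRUE)
        nr <- clamp(idx[, 1] + dy2, 1, n); nc <- clamp(idx[, 2] + dx2, 1, k)
        sh <- matrix(FALSE, n, k); sh[cbind(nr, nc)] <- TRUE
        grown <- grown | sh
      }
      out <- lm
      out[grown & lm == 0L] <- as.integer(region)
      out
    },
    erode = {
      stopifnot(!is.null(region), region %in% 1:4, is_count(r), r >= 1)
      m <- lm == region
      keep <- m
      pad <- matrix(FALSE, n + 2L * r, k + 2L * r)
      pad[(r + 1):(r + n), (r + 1):(r + k)] <- m
      for (dy2 in -r:r) for (dx2 in -r:r) {
        keep <- keep & pad[(r + 1 + dy2):(r + n + dy2), (r + 1 + dx2):(r + k + dx2)]
      }
      out <- lm
      out[m & !keep] <- 0L
      out
    },
    drop_region = {
      stopifnot(!is.null(region), region %in% 1:4)
      out <- lm
      out[lm == region] <- 0L
      out
    })
}

#' Augmentation specification
#'
#' @param ops character subset of
#'   `c("noise", "filter", "scale", "crop", "flip", "rotate", "gamma")`,
#'   applied in that canonical order.
#' @param params named list overriding the default parameter ranges:
#'   `noise_sd_max` (0.05), `filter_sigma` (range, c(0.5, 1.5)),
#'   `scale` (c(0.9, 1.1)), `crop_fraction` (c(0.8, 1)),
#'   `rotate` (degrees, c(-15, 15)), `gamma` (c(0.7, 1.4)).
#' @param seed integer seed making the random draws reproducible.
#' @return object of class `augmentation_spec`.
#' @export
augmentation_spec <- function(ops = character(), params = list(), seed = 1) {
  all_ops <- c("noise", "filter", "scale", "crop", "flip", "rotate", "gamma")
  if (!all(ops %in% all_ops)) stopf("unknown ops: %s", paste(setdiff(ops, all_ops), collapse = ", "))
  defaults <- list(noise_sd_max = 0.05, filter_sigma = c(0.5, 1.5),
                   scale = c(0.9, 1.1), crop_fraction = c(0.8, 1),
                   rotate = c(-15, 15), gamma = c(0.7, 1.4))
  bad <- setdiff(names(params), names(defaults))
  if (length(bad)) stopf("unknown augmentation params: %s", paste(bad, collapse = ", "))
  defaults[names(params)] <- params
  structure(list(ops = ops[order(match(ops, all_ops))], params = defaults,
                 seed = as.integer(seed)),
            class = "augmentation_spec")
}

# Joint geometric resampling: output pixel (r, c) takes its value from input
# coordinates given by map_fun; bilinear for intensity, nearest-neighbour for
# labels (labels are categorical). Out-of-frame samples: intensity 0, label 0.
warp_pair <- function(image, label_map, map_fun) {
  n <- nrow(image); k <- ncol(image)
  g <- coord_grids(n)          # square frames only (512x512 pipeline)
  src <- map_fun(g$x, g$y)
  sx <- src$x; sy <- src$y
  # nearest neighbour for labels
  ri <- round(sy); ci <- round(sx)
  ok <- ri >= 1 & ri <= n & ci >= 1 & ci <= k
  new_lm <- matrix(0L, n, k)
  new_lm[ok] <- label_map[cbind(ri[ok], ci[ok])]
  # bilinear for intensity
  x0 <- floor(sx); y0 <- floor(sy)
  wx <- sx - x0; wy <- sy - y0
  val <- function(r, c) {
    inb <- r >= 1 & r <= n & c >= 1 & c <= k
    v <- matrix(0, n, k)
    v[inb] <- image[cbind(r[inb], c[inb])]
    v
  }
  new_img <- val(y0, x0) * (1 - wx) * (1 - wy) + val(y0, x0 + 1) * wx * (1 - wy) +
             val(y0 + 1, x0) * (1 - wx) * wy + val(y0 + 1, x0 + 1) * wx * wy
  inb_any <- sx >= 1 & sx <= k & sy >= 1 & sy <= n
  new_img[!inb_any] <- 0
  list(image = new_img, label_map = new_lm)
}

#' Apply augmentation jointly to an image and its label map
#'
#' Geometric operations (scale, crop, flip, rotate) are applied identically
#' to the image and the label map, with nearest-neighbour interpolation for
#' the categorical labels; photometric operations (noise, filter, gamma)
#' touch the image only. Deterministic given `spec$seed`.
#'
#' @param image square intensity matrix in `[0, 1]`.
#' @param label_map integer label map of the same shape.
#' @param spec an [augmentation_spec()].
#' @return list with the augmented `image` and `label_map`.
#' @export
augment <- function(image, label_map, spec) {
  stopifnot(inherits(spec, "augmentation_spec"))
  lm <- check_label_map(label_map)
  stopifnot(is.matrix(image), all(dim(image) == dim(lm)), nrow(image) == ncol(image))
  withr::with_seed(spec$seed, {
    img <- image
    n <- nrow(img)
    ctr <- (n + 1) / 2
    p <- spec$params
    for (op in spec$ops) {
      if (op == "noise") {
        img <- clamp(img + matrix(stats::rnorm(n * n, 0, stats::runif(1, 0, p$noise_sd_max)), n), 0, 1)
      } else if (op == "filter") {
        sg <- stats::runif(1, p$filter_sigma[1], p$filter_sigma[2])
        img <- matrix(EBImage::imageData(EBImage::gblur(img, sigma = sg)), n)
      } else if (op == "scale") {
        s <- stats::runif(1, p$scale[1], p$scale[2])
        w <- warp_pair(img, lm, function(x, y)
          list(x = (x - ctr) / s + ctr, y = (y - ctr) / s + ctr))
        img <- w$image; lm <- w$label_map
      } else if (op == "crop") {
        f <- stats::runif(1, p$crop_fraction[1], p$crop_fraction[2])
        side <- max(2, round(f * n))
        off_r <- sample.int(n - side + 1L, 1L) - 1L
        off_c <- sample.int(n - side + 1L, 1L) - 1L
        sc <- side / n
        w <- warp_pair(img, lm, function(x, y)
          list(x = (x - 0.5) * sc + 0.5 + off_c, y = (y - 0.5) * sc + 0.5 + off_r))
        img <- w$image; lm <- w$label_map
      } else if (op == "flip") {
        img <- img[, n:1]
        lm <- lm[, n:1]
      } else if (op == "rotate") {
        th <- stats::runif(1, p$rotate[1], p$rotate[2]) * pi / 180
        w <- warp_pair(img, lm, function(x, y) {
          dx <- x - ctr; dy <- y - ctr
          list(x = cos(th) * dx + sin(th) * dy + ctr,
               y = -sin(th) * dx + cos(th) * dy + ctr)
        })
        img <- w$image; lm <- w$label_map
      } else if (op == "gamma") {
        gm <- stats::runif(1, p$gamma[1], p$gamma[2])
        img <- clamp(img, 0, 1)^gm
      }
    }
    list(image = img, label_map = lm)
  })
}
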