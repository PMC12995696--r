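toy_batch <- function(n = 8, seed = 1) {
  withr::with_seed(seed, {
    targets <- array(rbinom(n * n * 4, 1, 0.3), dim = c(n, n, 4))
    probs <- array(runif(n * n * 4), dim = c(n, n, 4))
    prediction_batch(probs, targets)
  })
}

test_that("region binary CE matches its closed forms", {
  # perfect prediction after clamping
  y <- c(1, 0, 1, 1, 0)
  expect_lt(region_binary_ce(y, y), 1e-6)
  # uniform 0.5 prediction: loss = ln 2
  expect_equal(region_binary_ce(rep(0.5, 10), rbinom(10, 1, 0.5)), log(2))
  # two-pixel hand evaluation
  expect_equal(region_binary_ce(c(0.8, 0.4), c(1, 0)), -(log(0.8) + log(0.6)) / 2)
  # internal weights scale the class terms
  expect_equal(region_binary_ce(c(0.5, 0.5), c(1, 0), internal = c(2, 4)),
               -(4 * log(0.5) + 2 * log(0.5)) / 2)
  expect_error(region_binary_ce(c(0.5), c(1, 0)), "share shape")
})

test_that("external weighting reduces correctly on hand-picked loss vectors", {
  expect_equal(weighted_ce(c(1, 1, 1, 1), uniform_weights()), 1)
  expect_equal(weighted_ce(c(4, 0, 0, 0), uniform_weights()), 1)
  ce2 <- external_weights(c(0.2704, 0.0324, 0.0360, 0.6612))
  expect_equal(weighted_ce(c(1, 0, 0, 1), ce2), 0.9316)
})

test_that("CE1 weighting equals the plain average of the per-region losses", {
  b <- toy_batch()
  per <- vapply(1:4, function(k)
    region_binary_ce(b$probs[, , k], b$targets[, , k]), numeric(1))
  expect_equal(weighted_ce(per, uniform_weights()), mean(per) * 4 * 0.25)
})

test_that("soft Dice loss follows the smoothed formula and conventions", {
  n <- 6
  tg <- array(0, dim = c(n, n, 4)); pr <- array(0, dim = c(n, n, 4))
  # region 1: disjoint hard masks with |P| = |G| = 8
  tg[1:2, 1:4, 1] <- 1; pr[5:6, 1:4, 1] <- 1
  b <- prediction_batch(pr, tg)
  terms <- c(1 / 17, 1, 1, 1)  # empty-empty regions are perfect
  expect_equal(soft_dice_loss(b, smooth = 1), 1 - mean(terms))
  # perfect hard prediction: near-zero loss
  expect_lt(soft_dice_loss(prediction_batch(tg, tg)), 0.01)
})

test_that("signed distance map matches the all-pairs oracle and its conventions", {
  # single interior pixel: 4-neighbours at distance 1
  m <- matrix(0L, 7, 7); m[4, 4] <- 1L
  sdm <- signed_distance_map(m)
  expect_equal(sdm[4, 4], 0)
  expect_equal(c(sdm[3, 4], sdm[5, 4], sdm[4, 3], sdm[4, 5]), rep(1, 4))
  # full-frame region: all values <= 0
  expect_true(all(signed_distance_map(matrix(1L, 5, 5)) <= 0))
  # all-background mask is degenerate
  expect_warning(d <- signed_distance_map(matrix(0L, 4, 4)), "degenerate")
  expect_true(attr(d, "degenerate"))
  # oracle agreement on random masks, and near-negation of the complement
  for (s in 1:25) {
    n <- 6 + (s %% 10)
    m <- random_mask(n, 5000 + s)
    if (!any(m == 1) || !any(m == 0)) next
    expect_equal(signed_distance_map(m), oracle_signed_distance(m),
                 ignore_attr = TRUE, tolerance = 1e-9)
  }
})

test_that("boundary loss is zero for null predictions and negative on the target", {
  n <- 8
  tg <- array(0, dim = c(n, n, 4))
  tg[3:6, 3:6, 1] <- 1; tg[1:2, 1:2, 2] <- 1; tg[7:8, 7:8, 3] <- 1; tg[5, 1, 4] <- 1
  zero <- prediction_batch(array(0, dim = dim(tg)), tg)
  expect_equal(suppressWarnings(boundary_loss(zero)), 0)
  ind <- prediction_batch(tg, tg)
  bl <- suppressWarnings(boundary_loss(ind))
  expect_lt(bl, 0)
  # hand evaluation on a 4x4 square region: mean of p * phi over pixels
  phi <- signed_distance_map(matrix(as.integer(tg[, , 1]), n))
  hand <- mean(tg[, , 1] * phi) / 4 +
    sum(vapply(2:4, function(k) {
      pk <- signed_distance_map(matrix(as.integer(tg[, , k]), n))
      mean(tg[, , k] * pk) / 4
    }, numeric(1)))
  expect_equal(bl, hand)
  # moving a fixed-mass blob away from the target increases the loss
  near <- array(0, dim = dim(tg)); near[3:6, 3:6, 1] <- 1
  far <- array(0, dim = dim(tg)); far[1:4, 5:8, 1] <- 1
  expect_lt(suppressWarnings(boundary_loss(prediction_batch(near, tg))),
            suppressWarnings(boundary_loss(prediction_batch(far, tg))))
})

test_that("mixed loss composes its components linearly in the mix weights", {
  b <- toy_batch(n = 6, seed = 3)
  w <- dual_level_weights(c(0.058, 0.483, 0.435, 0.024))$weights
  only_ce <- mixed_loss(b, w, mix = loss_mix(1, 0, 0))
  expect_equal(only_ce$mixed_total, only_ce$ce_total)
  mx <- mixed_loss(b, w, mix = loss_mix(0.5, 0.25, 0.25))
  expect_equal(mx$mixed_total,
               0.5 * mx$ce_total + 0.25 * mx$dice_total + 0.25 * mx$bd_total,
               tolerance = 1e-9)
  # component arithmetic: (2, 4, -1) at mix (0.5, 0.25, 0.25) -> 1.75
  expect_equal(0.5 * 2 + 0.25 * 4 + 0.25 * (-1), 1.75)
  # linearity in tau1 with fixed components
  mx2 <- mixed_loss(b, w, mix = loss_mix(1.0, 0.25, 0.25))
  expect_equal(mx2$mixed_total - mx$mixed_total, 0.5 * mx$ce_total, tolerance = 1e-9)
  expect_error(loss_mix(0, 0, 0), "at least one positive")
})

test_that("tendon-only errors are amplified by the dual-level weights", {
  n <- 10
  tg <- array(0, dim = c(n, n, 4))
  tg[1:3, 1:8, 2] <- 1; tg[6:9, 1:8, 3] <- 1; tg[4, 1:2, 1] <- 1; tg[5, 4:5, 4] <- 1
  pr <- tg
  pr[, , 4] <- pmin(1, pmax(0, tg[, , 4] * 0.2))  # err only on the tendon
  b <- prediction_batch(pr, tg)
  ce2 <- dual_level_weights(c(0.058, 0.483, 0.435, 0.024))$weights
  l1 <- mixed_loss(b, uniform_weights())$ce_total
  l2 <- mixed_loss(b, ce2)$ce_total
  expect_equal(l2 / l1, unname(ce2$weights[4]) / 0.25, tolerance = 1e-4)
})

test_that("one gradient step in probability space decreases each loss component", {
  withr::with_seed(11, {
    y <- rbinom(30, 1, 0.4)
    p <- runif(30, 0.2, 0.8)
    step <- function(p, g, lr = 0.05) pmin(1 - 1e-7, pmax(1e-7, p - lr * g))
    # CE
    g <- kneeseg:::grad_ce_probs(p, y)
    expect_lt(region_binary_ce(step(p, g), y), region_binary_ce(p, y))
    # finite-difference agreement for the CE gradient
    eps <- 1e-6
    i <- 7
    fd <- (region_binary_ce(replace(p, i, p[i] + eps), y) -
           region_binary_ce(replace(p, i, p[i] - eps), y)) / (2 * eps)
    expect_equal(g[i], fd, tolerance = 1e-5)
    # Dice (single-region view: term enters the 4-region mean)
    dice_term <- function(p) 1 - ((2 * sum(p * y) + 1) / (sum(p) + sum(y) + 1) + 3) / 4
    gd <- kneeseg:::grad_dice_probs(p, y)
    expect_lt(dice_term(step(p, gd, lr = 1)), dice_term(p))
    # Boundary
    phi <- runif(30, -2, 2)
    bd_term <- function(p) mean(p * phi) / 4
    gb <- kneeseg:::grad_bd_probs(p, phi)
    expect_lt(bd_term(step(p, gb, lr = 1)), bd_term(p))
  })
})
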