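square_mask <- function(n, r0, r1, c0, c1) {
  m <- matrix(0L, n, n); m[r0:r1, c0:c1] <- 1L; m
}

test_that("overlap metrics match hand-computed confusion arithmetic", {
  a <- square_mask(8, 2, 4, 2, 4)
  id <- overlap_metrics(a, a)
  expect_equal(unlist(id[c("iou", "dice", "precision", "recall")]),
               c(iou = 1, dice = 1, precision = 1, recall = 1))

  # tp=2, fp=1, fn=1
  p <- matrix(0L, 2, 3); p[1, 1:3] <- 1L
  g <- matrix(0L, 2, 3); g[1, 1:2] <- 1L; g[2, 1] <- 1L
  m <- overlap_metrics(p, g)
  expect_equal(m$confusion, c(tp = 2, fp = 1, fn = 1))
  expect_equal(m$iou, 0.5)
  expect_equal(m$dice, 2 / 3)
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$recall, 2 / 3)

  disj <- overlap_metrics(square_mask(8, 1, 2, 1, 2), square_mask(8, 5, 6, 5, 6))
  expect_equal(unlist(disj[c("iou", "dice", "precision", "recall")]),
               c(iou = 0, dice = 0, precision = 0, recall = 0))

  empty <- matrix(0L, 4, 4)
  expect_equal(overlap_metrics(empty, empty)$iou, 1)     # correctly absent
  expect_equal(overlap_metrics(empty, square_mask(4, 1, 1, 1, 1))$iou, 0)
})

test_that("a 3-pixel horizontal shift of a solid square yields HD95 = 3", {
  a <- square_mask(20, 5, 14, 3, 12)
  b <- square_mask(20, 5, 14, 6, 15)
  sd <- surface_distance_metrics(a, b)
  expect_equal(sd$hd95, 3)
  orc <- oracle_hd95_assd(a, b)
  expect_equal(sd$assd, unname(orc["assd"]), tolerance = 1e-9)
  # symmetric pooling
  sd2 <- surface_distance_metrics(b, a)
  expect_equal(sd$hd95, sd2$hd95)
  expect_equal(sd$assd, sd2$assd)
  # shift distances d in {1, 2, 3, 5} give hd95 = d exactly
  for (d in c(1, 2, 3, 5)) {
    shifted <- perturb_mask(square_mask(24, 6, 17, 4, 15) * 2L, "shift", dx = d)
    sdd <- surface_distance_metrics(shifted == 2L, square_mask(24, 6, 17, 4, 15))
    expect_equal(sdd$hd95, d)
  }
})

test_that("surface distances equal the exhaustive all-pairs oracle on random masks", {
  checked <- 0
  for (s in 1:200) {
    n <- 8 + (s %% 25)
    pred <- random_mask(n, 1000 + s)
    gt <- random_mask(n, 2000 + s)
    if (!any(pred == 1) || !any(gt == 1)) {
      expect_false(surface_distance_metrics(pred, gt)$valid)
      next
    }
    got <- surface_distance_metrics(pred, gt)
    orc <- oracle_hd95_assd(pred, gt)
    expect_equal(got$hd95, unname(orc["hd95"]), tolerance = 1e-9)
    expect_equal(got$assd, unname(orc["assd"]), tolerance = 1e-9)
    checked <- checked + 1
  }
  expect_gt(checked, 150)
})

test_that("empty masks invalidate distance metrics instead of fabricating them", {
  a <- square_mask(6, 2, 3, 2, 3)
  out <- surface_distance_metrics(matrix(0L, 6, 6), a)
  expect_false(out$valid)
  expect_true(is.na(out$hd95) && is.na(out$assd))
  # hd floor compatibility flag
  near <- surface_distance_metrics(a, a, hd_floor = 1)
  expect_equal(near$hd95, 1)
})

test_that("Dice identities hold on random hard mask pairs", {
  for (s in 1:100) {
    n <- 6 + (s %% 20)
    p <- random_mask(n, 3000 + s)
    g <- random_mask(n, 4000 + s)
    m <- overlap_metrics(p, g)
    expect_equal(m$dice, 2 * m$iou / (1 + m$iou), tolerance = 1e-9)
    if (m$precision + m$recall > 0)
      expect_equal(m$dice, 2 * m$precision * m$recall / (m$precision + m$recall),
                   tolerance = 1e-9)
  }
})

test_that("all six metrics are translation invariant", {
  p <- random_mask(18, 11); g <- random_mask(18, 12)
  pad <- function(m, dr, dc) {
    out <- matrix(0L, 26, 26)
    out[dr + seq_len(nrow(m)), dc + seq_len(ncol(m))] <- m
    out
  }
  base_ov <- overlap_metrics(pad(p, 1, 1), pad(g, 1, 1))
  base_sd <- surface_distance_metrics(pad(p, 1, 1), pad(g, 1, 1))
  mv_ov <- overlap_metrics(pad(p, 6, 4), pad(g, 6, 4))
  mv_sd <- surface_distance_metrics(pad(p, 6, 4), pad(g, 6, 4))
  expect_equal(base_ov$iou, mv_ov$iou)
  expect_equal(base_sd$hd95, mv_sd$hd95)
  expect_equal(base_sd$assd, mv_sd$assd)
})

test_that("region summaries report mean/sd/extrema and exclude invalid distances", {
  rec <- data.frame(iou = c(1, 2, 3), dice = c(1, 2, 3), precision = c(1, 2, 3),
                    recall = c(1, 2, 3), hd95 = c(5, NA, 7), assd = c(1, NA, 3),
                    valid = c(TRUE, FALSE, TRUE))
  s <- summarize_region(rec)
  expect_equal(unname(s$table["iou", ]), c(2, 1, 3, 1))
  expect_equal(unname(s$table["hd95", "mean"]), 6)
  expect_equal(s$n_invalid_distance, 1)
  one <- summarize_region(rec[1, ])
  expect_equal(unname(one$table["iou", c("mean", "sd")]), c(1, 0))
})

test_that("sampled IoU summaries recover the generator mean", {
  withr::with_seed(42, {
    x <- rbeta(1000, 8, 2)   # mean 0.8
    rec <- data.frame(iou = x, dice = x, precision = x, recall = x,
                      hd95 = 1, assd = 1, valid = TRUE)
    s <- summarize_region(rec)
    se <- sqrt(8 * 2 / ((8 + 2)^2 * 11)) / sqrt(1000)
    expect_lt(abs(s$table["iou", "mean"] - 0.8), 3 * se)
  })
})

test_that("composite metrics average the overlap and distance means", {
  cm <- comprehensive(c(iou = 0.9320, dice = 0.9644, precision = 0.9733,
                        recall = 0.9566, hd95 = 2.4335, assd = 0.8414))
  expect_equal(round(unname(cm["mean_metric_1"]), 4), 0.9566)
  expect_equal(round(unname(cm["mean_metric_2"]), 4), 1.6375)
  flat <- comprehensive(c(iou = 0.7, dice = 0.7, precision = 0.7, recall = 0.7,
                          hd95 = 0.7, assd = 0.7))
  expect_equal(unname(flat), c(0.7, 0.7))
  expect_error(comprehensive(c(iou = 1, dice = 1)), "six metric means")
})

test_that("overall means average the four regions unweighted", {
  df <- data.frame(mean_iou = c(0.9320, 0.9706, 0.9703, 0.6953),
                   mean_dice = 1, mean_precision = 1, mean_recall = 1,
                   mean_hd95 = c(2.4335, 2.2607, 2.3310, 4.6326), mean_assd = 1)
  om <- overall_means(df)
  expect_lt(abs(om[["mean_iou"]] - 0.8921), 5e-5)
  expect_lt(abs(om[["mean_hd95"]] - 2.9145), 5e-5)
  same <- df[c(1, 1, 1, 1), ]
  expect_equal(unname(overall_means(same)["mean_iou"]), 0.9320)
  expect_error(overall_means(df[1:3, ]), "four regions")
})

test_that("improvements are mean differences in percentage points with direction", {
  expect_equal(improvement_pp(0.6650, 0.7214, "ascending"), 5.64)
  expect_equal(improvement_pp(27.8598, 5.7483, "descending"), 2211.15)
  expect_equal(improvement_pp(0.5, 0.5), 0)
})

test_that("evaluate_image produces one consistent row per region", {
  ph <- generate_phantom(phantom_config(image_size = 64, seed = 5))
  rec <- evaluate_image(ph$label_map, ph$label_map, image = "self")
  expect_equal(nrow(rec), 4)
  expect_true(all(rec$iou == 1 & rec$dice == 1))
  expect_true(all(rec$hd95 == 0 & rec$assd == 0))
  shifted <- perturb_mask(ph$label_map, "shift", dx = 2)
  rec2 <- evaluate_image(shifted, ph$label_map)
  expect_true(all(rec2$iou < 1))
  expect_true(all(rec2$valid))
})
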