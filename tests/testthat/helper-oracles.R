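# Independent brute-force oracles used to validate the fast implementations.

# Boundary definition shared with the package contract: foreground pixel
# with at least one background 4-neighbour (outside the frame counts as
# background).
oracle_boundary <- function(m) {
  n <- nrow(m); k <- ncol(m)
  out <- matrix(FALSE, n, k)
  for (r in seq_len(n)) for (c in seq_len(k)) {
    if (m[r, c] != 1) next
    nb <- c(if (r > 1) m[r - 1, c] else 0, if (r < n) m[r + 1, c] else 0,
            if (c > 1) m[r, c - 1] else 0, if (c < k) m[r, c + 1] else 0)
    out[r, c] <- any(nb == 0)
  }
  out
}

# Exhaustive all-pairs symmetric surface distances: for each boundary pixel
# of one mask, the minimum Euclidean distance to the other mask's boundary,
# pooled over both directions.
oracle_surface_distances <- function(pred, gt) {
  bp <- which(oracle_boundary(pred), arr.ind = TRUE)
  bg <- which(oracle_boundary(gt), arr.ind = TRUE)
  d <- function(a, b) apply(a, 1, function(p)
    sqrt(min((p[1] - b[, 1])^2 + (p[2] - b[, 2])^2)))
  c(d(bp, bg), d(bg, bp))
}

oracle_hd95_assd <- function(pred, gt) {
  pooled <- oracle_surface_distances(pred, gt)
  c(hd95 = unname(quantile(pooled, 0.95, type = 7)), assd = mean(pooled))
}

# All-pairs signed distance oracle matching the package convention:
# outside pixels: distance to the nearest foreground pixel; inside pixels:
# -(distance to nearest background pixel - 1), the frame padded with
# background.
oracle_signed_distance <- function(m) {
  n <- nrow(m); k <- ncol(m)
  fg <- which(m == 1, arr.ind = TRUE)
  padbg <- rbind(which(m == 0, arr.ind = TRUE),
                 cbind(rep(0, k + 2), 0:(k + 1)), cbind(rep(n + 1, k + 2), 0:(k + 1)),
                 cbind(1:n, rep(0, n)), cbind(1:n, rep(k + 1, n)))
  out <- matrix(NA_real_, n, k)
  for (r in seq_len(n)) for (c in seq_len(k)) {
    if (m[r, c] == 1) {
      out[r, c] <- -(sqrt(min((r - padbg[, 1])^2 + (c - padbg[, 2])^2)) - 1)
    } else {
      out[r, c] <- sqrt(min((r - fg[, 1])^2 + (c - fg[, 2])^2))
    }
  }
  out
}

# Brute-force morphological dilation of one label with a (2r+1)^2 square
# structuring element, claiming background pixels only.
oracle_dilate <- function(lm, region, r) {
  n <- nrow(lm); k <- ncol(lm)
  out <- lm
  for (rr in seq_len(n)) for (cc in seq_len(k)) {
    if (lm[rr, cc] != 0) next
    win <- lm[max(1, rr - r):min(n, rr + r), max(1, cc - r):min(k, cc + r)]
    if (any(win == region)) out[rr, cc] <- region
  }
  out
}

# Random blob mask: a few overlapping discs, possibly empty.
random_mask <- function(n, seed, p_empty = 0) {
  withr::with_seed(seed, {
    if (runif(1) < p_empty) return(matrix(0L, n, n))
    m <- matrix(0L, n, n)
    for (i in seq_len(sample(1:3, 1))) {
      cx <- runif(1, 2, n - 1); cy <- runif(1, 2, n - 1); rad <- runif(1, 1.5, n / 3)
      g <- expand.grid(r = 1:n, c = 1:n)
      m[as.matrix(g[(g$r - cy)^2 + (g$c - cx)^2 <= rad^2, ])] <- 1L
    }
    m
  })
}

# Tiny phantom dataset shared by harness tests.
make_phantom_split <- function(seed, n = 64, n_tr = 60, n_val = 10, n_te = 10) {
  gen <- function(i) generate_phantom(phantom_config(
    image_size = n, flexion_angle = (i %% 6) * 8, seed = seed * 100000L + i))
  list(train = lapply(seq_len(n_tr), gen),
       val = lapply(n_tr + seq_len(n_val), gen),
       test = lapply(n_tr + n_val + seq_len(n_te), gen))
}
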