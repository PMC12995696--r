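# Preprocessing, dataset splitting, and readers/writers.
#
# Preprocessing follows the standard dynamic-radiograph pipeline: a center
# square crop to the shorter side, then a resize to a uniform 512x512
# (bilinear for intensities, nearest-neighbour for categorical labels).

#' Center square crop
#'
#' Crops the centered square of side `min(H, W)`. Even margins are split
#' equally; when a margin is odd the extra pixel is removed from the
#' bottom/right, a fixed convention for bit-reproducibility.
#'
#' @param image matrix.
#' @param label_map optional matrix of the same shape, cropped identically.
#' @return list with `image` (and `label_map` if given).
#' @export
center_square_crop <- function(image, label_map = NULL) {
  stopifnot(is.matrix(image), nrow(image) >= 1, ncol(image) >= 1)
  side <- min(dim(image))
  r0 <- floor((nrow(image) - side) / 2) + 1L
  c0 <- floor((ncol(image) - side) / 2) + 1L
  rows <- r0:(r0 + side - 1L); cols <- c0:(c0 + side - 1L)
  out <- list(image = image[rows, cols, drop = FALSE])
  if (!is.null(label_map)) {
    stopifnot(all(dim(label_map) == dim(image)))
    out$label_map <- label_map[rows, cols, drop = FALSE]
  }
  out
}

resize_bilinear <- function(m, side) {
  n <- nrow(m)
  if (n == side) return(m)
  sc <- n / side
  ctr <- (seq_len(side) - 0.5) * sc + 0.5   # pixel-center mapping
  i0 <- clamp(floor(ctr), 1, n); i1 <- pmin(i0 + 1, n)
  w <- clamp(ctr - i0, 0, 1)
  rows <- m[i0, , drop = FALSE] * (1 - w) + m[i1, , drop = FALSE] * w
  t(t(rows[, i0, drop = FALSE]) * (1 - w) + t(rows[, i1, drop = FALSE]) * w)
}

resize_nearest <- function(m, side) {
  n <- nrow(m)
  if (n == side) return(m)
  idx <- clamp(round((seq_len(side) - 0.5) * n / side + 0.5), 1, n)
  m[idx, idx, drop = FALSE]
}

#' Resize a square image (and label map) to side x side
#'
#' Bilinear interpolation for intensities, nearest-neighbour for labels.
#' Non-square input is an error: crop first with [center_square_crop()].
#'
#' @param image square matrix.
#' @param label_map optional square matrix resized with nearest-neighbour.
#' @param side target side in pixels (default 512).
#' @return list with `image` (and `label_map` if given).
#' @export
resize_to <- function(image, label_map = NULL, side = 512) {
  stopifnot(is.matrix(image))
  if (nrow(image) != ncol(image)) stopf("resize_to requires square input; crop first")
  stopifnot(is_count(side), side >= 1)
  out <- list(image = resize_bilinear(image, side))
  if (!is.null(label_map)) {
    stopifnot(all(dim(label_map) == dim(image)))
    out$label_map <- resize_nearest(label_map, side)
  }
  out
}

#' Case-level dataset split
#'
#' Splits *cases* (not frames) into train/validation/test so that every
#' frame of a case lands in exactly one split — the grouping that prevents
#' leakage between splits in dynamic sequences. Split sizes are apportioned
#' by largest remainder so they always sum to the number of cases.
#'
#' @param case_ids character or integer vector of unique case identifiers.
#' @param frame_counts optional vector (same length) of frames per case;
#'   when given, a per-sample assignment table is included.
#' @param fractions length-3 nonnegative vector `(train, val, test)`
#'   summing to 1.
#' @param seed integer seed for the case shuffle.
#' @return object of class `dataset_split`: `$train`, `$val`, `$test`
#'   (case ids), `$cases` (data frame case/split) and optionally
#'   `$samples` (data frame sample_id/case/split).
#' @export
split_cases <- function(case_ids, frame_counts = NULL,
                        fractions = c(train = 0.67, val = 0.11, test = 0.22),
                        seed = 1) {
  stopifnot(!anyDuplicated(case_ids), length(fractions) == 3L)
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-9)
    stopf("fractions must be nonnegative and sum to 1")
  n <- length(case_ids)
  if (n < sum(fractions > 0)) stopf("fewer cases than nonzero splits")
  raw <- fractions * n
  k <- floor(raw)
  rem <- n - sum(k)
  if (rem > 0) {
    extra <- order(raw - k, seq_along(k), decreasing = TRUE)[seq_len(rem)]
    k[extra] <- k[extra] + 1
  }
  shuffled <- withr::with_seed(seed, sample(case_ids))
  split_of <- rep(c("train", "val", "test"), times = k)
  cases <- data.frame(case = shuffled, split = split_of, stringsAsFactors = FALSE)
  out <- list(train = shuffled[split_of == "train"],
              val = shuffled[split_of == "val"],
              test = shuffled[split_of == "test"],
              cases = cases)
  if (!is.null(frame_counts)) {
    stopifnot(length(frame_counts) == n)
    fc <- frame_counts[match(cases$case, case_ids)]
    out$samples <- data.frame(
      sample_id = unlist(mapply(function(cs, m) paste0(cs, "_f", seq_len(m) - 1L),
                                cases$case, fc, SIMPLIFY = FALSE), use.names = FALSE),
      case = rep(cases$case, fc),
      split = rep(cases$split, fc),
      stringsAsFactors = FALSE)
  }
  structure(out, class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("Case-level split: %d train / %d val / %d test cases\n",
              length(x$train), length(x$val), length(x$test)))
  if (!is.null(x$samples))
    print(table(x$samples$split))
  invisible(x)
}

# ---- metric tables ----------------------------------------------------------

METRIC_TABLE_COLS <- c("experiment", "network", "tau1", "tau2", "tau3",
                       "region", "mean_metric_1", "mean_metric_2", "printed_score")

model_id_from_row <- function(network, tau1, tau2, tau3) {
  scheme <- ifelse(is.na(tau1), "CE2",
            ifelse(!is.na(tau2) & !is.na(tau3),
                   sprintf("CE2+DICE+BD %.2f:%.2f:%.2f", tau1, tau2, tau3),
            ifelse(!is.na(tau2), sprintf("CE2+DICE %.2f:%.2f", tau1, tau2),
                   sprintf("CE2+BD %.2f:%.2f", tau1, tau3))))
  paste(network, scheme, sep = " | ")
}

#' Read a per-region model metric table
#'
#' Reads a CSV with header
#' `experiment,network,tau1,tau2,tau3,region,mean_metric_1,mean_metric_2,printed_score`.
#' Empty cells, `-`, `–` and `NA` are parsed as missing (a model that
#' failed to produce the region). A `model_id` column combining the network
#' and the loss-mix ratios is added.
#'
#' @param path CSV file path.
#' @return data frame (possibly empty) with typed columns and `model_id`.
#' @export
read_metric_table <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (nrow(raw) == 0L)
    return(cbind(stats::setNames(as.data.frame(lapply(METRIC_TABLE_COLS, function(x) character(0))),
                                 METRIC_TABLE_COLS), model_id = character(0))[FALSE, ])
  missing_cols <- setdiff(METRIC_TABLE_COLS, names(raw))
  if (length(missing_cols)) stopf("metric table missing columns: %s", paste(missing_cols, collapse = ", "))
  num <- function(col) {
    x <- trimws(raw[[col]])
    x[x %in% c("", "-", "–", "NA")] <- NA
    bad <- !is.na(x) & is.na(suppressWarnings(as.numeric(x)))
    if (any(bad)) stopf("malformed numeric cell in column '%s', row %d of %s",
                        col, which(bad)[1], basename(path))
    as.numeric(x)
  }
  out <- data.frame(experiment = num("experiment"), network = raw$network,
                    tau1 = num("tau1"), tau2 = num("tau2"), tau3 = num("tau3"),
                    region = raw$region,
                    mean_metric_1 = num("mean_metric_1"),
                    mean_metric_2 = num("mean_metric_2"),
                    printed_score = num("printed_score"),
                    stringsAsFactors = FALSE)
  bad1 <- !is.na(out$mean_metric_1) & (out$mean_metric_1 < 0 | out$mean_metric_1 > 1)
  if (any(bad1)) stopf("mean_metric_1 outside [0, 1] in row %d of %s", which(bad1)[1], basename(path))
  bad2 <- !is.na(out$mean_metric_2) & out$mean_metric_2 < 0
  if (any(bad2)) stopf("negative mean_metric_2 in row %d of %s", which(bad2)[1], basename(path))
  out$model_id <- model_id_from_row(out$network, out$tau1, out$tau2, out$tau3)
  out
}

#' Write a metric table (inverse of [read_metric_table()])
#' @param df data frame with the metric-table columns.
#' @param path output CSV path.
#' @export
write_metric_table <- function(df, path) {
  utils::write.csv(df[intersect(METRIC_TABLE_COLS, names(df))], path,
                   row.names = FALSE, na = "")
  invisible(path)
}

#' Path to a bundled per-region metric-table fixture
#' @param region one of `"patella"`, `"femur"`, `"tibia"`,
#'   `"patellar_tendon"`.
#' @return file path inside the installed package.
#' @export
bundled_metric_table <- function(region = REGIONS) {
  region <- match.arg(region)
  fname <- switch(region,
                  patella = "table5_patella.csv",
                  femur = "table6_femur.csv",
                  tibia = "table7_tibia.csv",
                  patellar_tendon = "table8_patellar_tendon.csv")
  system.file("extdata", fname, package = "kneeseg", mustWork = TRUE)
}

# ---- PNG image IO -----------------------------------------------------------

#' Write/read intensity frames and label maps as PNG
#'
#' Intensity frames are written as 16-bit grayscale PNG; label maps as
#' 8-bit grayscale PNG holding the raw label values (0..4).
#'
#' @param image matrix in `[0, 1]`.
#' @param label_map integer label map.
#' @param path file path.
#' @name phantom_png_io
NULL

# CRC-32 (PNG chunk checksums); table-driven, logical right shifts.
png_crc_table <- local({
  tab <- integer(256)
  poly <- -306674912L  # 0xEDB88320
  for (i in 0:255) {
    c <- i
    for (j in 1:8)
      c <- if (bitwAnd(c, 1L) != 0L) bitwXor(bitwShiftR(c, 1L), poly)
           else bitwShiftR(c, 1L)
    tab[i + 1] <- c
  }
  tab
})

png_crc32 <- function(bytes) {
  crc <- -1L
  b <- as.integer(bytes)
  for (i in seq_along(b))
    crc <- bitwXor(bitwShiftR(crc, 8L),
                   png_crc_table[bitwAnd(bitwXor(crc, b[i]), 255L) + 1L])
  bitwXor(crc, -1L)
}

png_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "big")

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(png_u32(length(data)), body, png_u32(png_crc32(body)))
}

#' @rdname phantom_png_io
#' @export
write_image_png <- function(image, path) {
  stopifnot(is.matrix(image))
  n <- nrow(image); k <- ncol(image)
  v <- matrix(as.integer(round(clamp(image, 0, 1) * 65535)), n, k)
  # scanlines top-to-bottom: filter byte 0, then 16-bit big-endian samples
  inter <- array(0L, c(2L, k, n))
  inter[1, , ] <- t(v %/% 256L)
  inter[2, , ] <- t(v %% 256L)
  scan <- rbind(0L, matrix(inter, 2L * k, n))
  ihdr <- c(png_u32(k), png_u32(n),
            as.raw(c(16L, 0L, 0L, 0L, 0L)))  # 16-bit grayscale
  out <- c(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)),
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", memCompress(as.raw(as.vector(scan)), "gzip")),
           png_chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}

#' @rdname phantom_png_io
#' @export
read_image_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  m
}

#' @rdname phantom_png_io
#' @export
write_label_png <- function(label_map, path) {
  lm <- check_label_map(label_map)
  png::writePNG(lm / 255, path)
  invisible(path)
}

#' @rdname phantom_png_io
#' @export
read_label_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  matrix(as.integer(round(m * 255)), nrow(m))
}

#' Write a phantom sequence to disk with a JSON manifest
#'
#' @param frames list of `knee_phantom` objects from [generate_sequence()].
#' @param dir output directory (created if needed).
#' @param prefix filename prefix.
#' @param seed seed recorded in the manifest.
#' @return manifest path, invisibly.
#' @export
write_sequence <- function(frames, dir, prefix = "frame", seed = NA) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- lapply(frames, function(f) {
    img <- file.path(dir, sprintf("%s_%03d.png", prefix, f$frame_index))
    lab <- file.path(dir, sprintf("%s_%03d_labels.png", prefix, f$frame_index))
    write_image_png(f$image, img)
    write_label_png(f$label_map, lab)
    list(frame_index = f$frame_index, flexion_angle = f$flexion_angle,
         image = basename(img), labels = basename(lab))
  })
  manifest <- file.path(dir, paste0(prefix, "_manifest.json"))
  jsonlite::write_json(list(seed = seed, n_frames = length(frames), frames = entries),
                       manifest, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
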