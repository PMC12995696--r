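#' Per-region area statistics from training label maps
#'
#' Counts the labeled pixels of each foreground region (patella, femur, tibia,
#' patellar tendon) across a collection of label maps and derives each
#' region's share of the total labeled area. Background (label 0) is excluded
#' from the total: the ratios describe how the *labeled* area is divided
#' among the four structures, which is what drives the dual-level loss
#' weighting.
#'
#' @param label_maps a single label map (integer matrix with values 0..4) or
#'   a list of them, typically the training-split ground truth.
#' @param pixel_area physical area of one pixel. It cancels in the ratios and
#'   defaults to 1; it is kept as a field for unit transparency.
#' @return an object of class `region_area_stats` with fields `areas` (named
#'   per-region area), `pixel_area`, `total` and `ratios` (summing to 1).
#' @seealso [dual_level_weights()]
#' @examples
#' lm <- matrix(0L, 4, 4)
#' lm[1:2, 1:2] <- 1L; lm[1:2, 3:4] <- 2L; lm[3:4, 1:2] <- 3L; lm[3:4, 3:4] <- 4L
#' area_stats(lm)$ratios
#' @export
area_stats <- function(label_maps, pixel_area = 1) {
  if (is.matrix(label_maps)) label_maps <- list(label_maps)
  if (!is.list(label_maps) || length(label_maps) == 0L)
    stopf("label_maps must be a non-empty label map or list of label maps")
  stopifnot(pixel_area > 0)
  counts <- stats::setNames(numeric(4), REGIONS)
  for (lm in label_maps) {
    lm <- check_label_map(lm)
    tab <- tabulate(lm[lm > 0L], nbins = 4L)
    counts <- counts + tab
  }
  areas <- counts * pixel_area
  total <- sum(areas)
  if (total <= 0) stopf("no labeled pixels in any map")
  structure(
    list(areas = areas, pixel_area = pixel_area, total = total,
         ratios = areas / total),
    class = "region_area_stats"
  )
}

#' @export
print.region_area_stats <- function(x, ...) {
  cat("Region area statistics (pixel_area =", x$pixel_area, ")\n")
  print(round(rbind(area = x$areas, ratio = x$ratios), 4))
  invisible(x)
}

#' External per-region weights for the weighted cross-entropy loss
#'
#' Constructs and validates a set of external weights (alpha, beta, gamma,
#' eta) multiplying the per-region cross-entropy losses. Scheme `"CE1"` is
#' the traditional equal weighting (0.25 each); scheme `"CE2"` carries the
#' dual-level area-derived weights.
#'
#' @param weights numeric vector of four weights summing to 1, in region
#'   order (patella, femur, tibia, patellar tendon).
#' @param scheme `"CE1"` or `"CE2"`.
#' @return an object of class `external_weights`.
#' @export
external_weights <- function(weights, scheme = c("CE2", "CE1")) {
  scheme <- match.arg(scheme)
  w <- as_region_vector(weights, "weights")
  if (any(w <= 0)) stopf("external weights must be strictly positive")
  if (abs(sum(w) - 1) > 1e-9) stopf("external weights must sum to 1 (got %.12f)", sum(w))
  if (scheme == "CE1" && any(abs(w - 0.25) > 1e-9))
    stopf("CE1 scheme requires all weights equal to 0.25")
  structure(list(scheme = scheme, weights = w), class = "external_weights")
}

#' @export
print.external_weights <- function(x, ...) {
  cat(sprintf("External CE weights [%s]: %s\n", x$scheme,
              paste(sprintf("%s=%.4f", names(x$weights), x$weights), collapse = ", ")))
  invisible(x)
}

#' Dual-level (area-balanced) external cross-entropy weights
#'
#' Derives the external region weights from labeled-area ratios: each raw
#' weight is inversely proportional to its region's area share
#' (`omega_i = epsilon / ratio_i`, so that `omega_i * ratio_i` is constant),
#' and the raw weights are then normalized to sum to 1. The result is
#' independent of `epsilon`. Small structures such as the patellar tendon
#' thus receive the largest weight, counteracting the severe area imbalance
#' between the bones and the tendon.
#'
#' @param stats a `region_area_stats` object from [area_stats()], or a
#'   numeric vector of four positive area ratios summing to 1.
#' @param epsilon arbitrary positive balancing constant; the normalized
#'   weights do not depend on it.
#' @return a list with `derivation` (epsilon, raw weights, normalized
#'   weights) and `weights`, an [external_weights()] object with scheme
#'   `"CE2"`.
#' @examples
#' dual_level_weights(c(0.1, 0.2, 0.3, 0.4))$weights
#' @export
dual_level_weights <- function(stats, epsilon = 1) {
  if (inherits(stats, "region_area_stats")) ratios <- stats$ratios
  else ratios <- as_region_vector(stats, "ratios")
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0)
    stopf("epsilon must be a single positive number")
  if (any(ratios <= 0))
    stopf("all region area ratios must be strictly positive; zero-area region(s): %s",
          paste(names(ratios)[ratios <= 0], collapse = ", "))
  if (abs(sum(ratios) - 1) > 1e-6)
    stopf("ratios must sum to 1 (got %.9f)", sum(ratios))
  raw <- epsilon / ratios
  normalized <- raw / sum(raw)
  list(
    derivation = list(epsilon = epsilon, raw_weights = raw, normalized = normalized),
    weights = external_weights(normalized, scheme = "CE2")
  )
}

#' Uniform external weights (traditional weighted cross-entropy)
#'
#' @return an [external_weights()] object with scheme `"CE1"` and all four
#'   weights equal to 0.25.
#' @export
uniform_weights <- function() {
  external_weights(rep(0.25, 4), scheme = "CE1")
}

#' Write external weights (with their source ratios) to JSON
#'
#' @param w an [external_weights()] object.
#' @param path output file path.
#' @param ratios optional area ratios used to derive the weights.
#' @export
write_weights_json <- function(w, path, ratios = NULL) {
  stopifnot(inherits(w, "external_weights"))
  obj <- list(scheme = w$scheme,
              alpha = unname(w$weights[1]), beta = unname(w$weights[2]),
              gamma = unname(w$weights[3]), eta = unname(w$weights[4]))
  if (!is.null(ratios)) obj$ratios <- as.list(as_region_vector(ratios, "ratios"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
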