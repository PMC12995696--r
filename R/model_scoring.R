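# Rank-sum scoring of candidate segmentation models.
#
# Each model is scored per region by its rank on the two composite metrics:
# the best value receives a score equal to the number of models N, the worst
# receives 1. Composite 1 (overlap average) is better when larger; composite
# 2 (distance average) is better when smaller. The two scores are summed per
# region, region scores are summed across the four regions, and the model
# with the largest grand total wins.

#' Integer rank scores for one metric column
#'
#' The best value receives score `N` (the number of models), the worst 1.
#' Missing values receive the minimum score 1 (a model that failed to
#' produce the region at all cannot outrank one that did). Ties are broken
#' ordinally by input-row order: tied values receive distinct consecutive
#' scores, with the later row scoring higher — the convention that best
#' reconciles published score tables we validate against; tied inputs are
#' flagged via the `"ties"` attribute.
#'
#' @param values numeric vector, possibly with `NA`.
#' @param direction `"higher_better"` (rank descending) or `"lower_better"`
#'   (rank ascending).
#' @return integer vector of scores in `[1, N]` with attribute `ties`.
#' @examples
#' rank_scores(c(0.3, 0.9, 0.6), "higher_better")  # 1 3 2
#' @export
rank_scores <- function(values, direction = c("higher_better", "lower_better")) {
  direction <- match.arg(direction)
  n <- length(values)
  if (n < 1L) stopf("need at least one value")
  if (all(is.na(values))) stopf("all values missing")
  key <- ifelse(is.na(values), -Inf,
                if (direction == "higher_better") values else -values)
  ord <- order(key, seq_len(n), decreasing = TRUE)  # best first; ties: later row higher
  sc <- integer(n)
  sc[ord] <- n:1
  sc[is.na(values)] <- 1L
  dup <- !is.na(values) & (duplicated(values) | duplicated(values, fromLast = TRUE))
  attr(sc, "ties") <- which(dup)
  sc
}

#' Per-region score table
#'
#' Applies [rank_scores()] to the two composite-metric columns of one
#' region's model table and sums them into the region score.
#'
#' @param entries data frame with columns `model_id`, `mean_metric_1`,
#'   `mean_metric_2` (additional columns are carried through). `model_id`
#'   must be unique.
#' @return the input data frame with added integer columns
#'   `score_metric_1`, `score_metric_2`, `region_score`, of class
#'   `score_table`; rows with tied metric values are listed in the
#'   `"tied_rows"` attribute.
#' @export
region_scores <- function(entries) {
  stopifnot(is.data.frame(entries))
  need <- c("model_id", "mean_metric_1", "mean_metric_2")
  if (!all(need %in% names(entries))) stopf("entries must have columns %s", paste(need, collapse = ", "))
  if (anyDuplicated(entries$model_id)) stopf("duplicate model ids")
  s1 <- rank_scores(entries$mean_metric_1, "higher_better")
  s2 <- rank_scores(entries$mean_metric_2, "lower_better")
  out <- entries
  out$score_metric_1 <- as.integer(s1)
  out$score_metric_2 <- as.integer(s2)
  out$region_score <- out$score_metric_1 + out$score_metric_2
  attr(out, "tied_rows") <- sort(union(attr(s1, "ties"), attr(s2, "ties")))
  class(out) <- c("score_table", class(out))
  out
}

#' Cross-region leaderboard and optimal-model selection
#'
#' Sums each model's four region scores into a grand total and sorts the
#' models from high to low. Ties on the total share consecutive positions in
#' input order of the first table (a stated deterministic key).
#'
#' @param tables named or ordered list of four `score_table` objects
#'   (patella, femur, tibia, patellar tendon). All must contain the same
#'   model set.
#' @return an object of class `leaderboard`: a data frame with the four
#'   region scores, `total_score` and `rank`, sorted descending, plus the
#'   `optimal_model` attribute.
#' @export
leaderboard <- function(tables) {
  stopifnot(is.list(tables), length(tables) == 4L)
  ids <- tables[[1]]$model_id
  for (t in tables) {
    stopifnot(inherits(t, "score_table"))
    if (!setequal(t$model_id, ids) || length(t$model_id) != length(ids))
      stopf("all four region tables must contain the same model set")
  }
  region_names <- names(tables) %||% REGIONS
  scores <- matrix(vapply(tables, function(t) t$region_score[match(ids, t$model_id)],
                          numeric(length(ids))),
                   nrow = length(ids), dimnames = list(NULL, region_names))
  total <- rowSums(scores)
  ord <- order(total, -seq_along(ids), decreasing = TRUE)
  out <- data.frame(model_id = ids, scores, total_score = total,
                    check.names = FALSE, stringsAsFactors = FALSE)[ord, ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "optimal_model") <- out$model_id[1]
  class(out) <- c("leaderboard", class(out))
  out
}

#' @export
print.leaderboard <- function(x, n = 10, ...) {
  cat("Model leaderboard (rank-sum criterion); optimal model:\n  ",
      attr(x, "optimal_model"), "\n", sep = "")
  print.data.frame(utils::head(x, n))
  if (nrow(x) > n) cat("  ...", nrow(x) - n, "more models\n")
  invisible(x)
}

#' Write a leaderboard as CSV plus a JSON report of the optimal model
#' @param lb a `leaderboard` object.
#' @param csv_path,json_path output paths (either may be `NULL` to skip).
#' @export
write_leaderboard <- function(lb, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(lb, "leaderboard"))
  if (!is.null(csv_path)) utils::write.csv(lb, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(optimal_model = attr(lb, "optimal_model"),
                              top_total = lb$total_score[1],
                              n_models = nrow(lb)),
                         json_path, auto_unbox = TRUE, digits = NA)
  invisible(lb)
}
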