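#' Top-50% vote for one screening criterion
#'
#' Awards 1 point to every candidate ranking in the top half of the
#' field for a criterion and 0 to the rest. With N candidates the
#' threshold is the k-th best score where `k = ceiling(N / 2)`;
#' candidates tying the threshold score are all promoted, so boundary
#' ties can push the number of voted candidates above k.
#'
#' @param scores Numeric vector (no missing values).
#' @param higher_is_better If `FALSE`, lower scores rank higher (e.g.
#'   binding energies).
#' @return Integer 0/1 vector aligned with `scores`.
#' @examples
#' vote_points(c(3, 1, 2, 2))  # threshold is the 2nd best (2): ties promoted
#' @export
vote_points <- function(scores, higher_is_better = TRUE) {
  if (length(scores) < 1L) stop("empty score vector", call. = FALSE)
  if (any(is.na(scores))) stop("missing score", call. = FALSE)
  s <- if (higher_is_better) scores else -scores
  k <- ceiling(length(s) / 2)
  threshold <- sort(s, decreasing = TRUE)[k]
  as.integer(s >= threshold)
}

#' Build a consensus vote table
#'
#' Applies [vote_points()] to each criterion column of a screening
#' table and appends the multi-target bonus flag and the total score
#' (row sum of points plus the flag).
#'
#' @param scores Data frame with an `id` column, one numeric column per
#'   criterion, and optionally a 0/1 `multi_target` column.
#' @param multi_target Optional 0/1 vector overriding/replacing the
#'   `multi_target` column (default all 0).
#' @param higher_is_better Logical scalar or named vector per
#'   criterion.
#' @return A `vote_table` tibble: `id`, one 0/1 points column per
#'   criterion, `multi_target` and `total`.
#' @export
vote_table <- function(scores, multi_target = NULL, higher_is_better = TRUE) {
  stopifnot("id" %in% names(scores))
  crit <- setdiff(names(scores), c("id", "multi_target"))
  stopifnot(length(crit) >= 1L)
  n <- nrow(scores)
  flags <- multi_target %||% scores[["multi_target"]] %||% rep(0L, n)
  if (length(flags) != n) stop("multi_target length mismatch", call. = FALSE)
  hib <- if (length(higher_is_better) == 1L)
    stats::setNames(rep(higher_is_better, length(crit)), crit)
  else higher_is_better[crit]
  pts <- lapply(crit, function(cn) {
    col <- scores[[cn]]
    if (length(col) != n) stop("criterion length mismatch", call. = FALSE)
    vote_points(col, hib[[cn]])
  })
  names(pts) <- crit
  out <- tibble::tibble(id = scores$id, !!!pts,
                        multi_target = as.integer(flags))
  out$total <- rowSums(out[crit]) + out$multi_target
  structure(out, criteria = crit,
            class = c("vote_table", class(tibble::tibble())))
}

#' Rank candidates by total vote score
#'
#' @param table A `vote_table` (or the raw scores data frame, which is
#'   passed through [vote_table()] first).
#' @param ... Passed to [vote_table()] when `table` is a raw scores
#'   frame.
#' @return The vote table sorted by decreasing total score, stable in
#'   the input order for ties, with a `rank` column (ties share the
#'   minimum rank).
#' @export
total_votes <- function(table, ...) {
  if (!inherits(table, "vote_table")) table <- vote_table(table, ...)
  ord <- order(-table$total)  # order() is stable
  out <- table[ord, , drop = FALSE]
  out$rank <- as.integer(rank(-out$total, ties.method = "min"))
  out
}

#' Screening scores of the top 10 ZINC candidates
#'
#' The bundled virtual-screening table used in examples and the
#' acceptance checks: ten ZINC compounds with a docking score, the
#' pIC50 predicted by each of the five models (GIAN, GIAT, SGCA, RF,
#' SVR), and the multi-target flag marking candidates that also docked
#' well against the second pathway enzyme.
#'
#' @return A tibble with columns `id`, `docking_score`, `GIAN`, `GIAT`,
#'   `SGCA`, `RF`, `SVR`, `multi_target`.
#' @export
zinc_top10_scores <- function() {
  path <- system.file("extdata", "zinc_top10_scores.csv",
                      package = "multignn", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
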