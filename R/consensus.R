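# Consensus mathematics used during elicitation: panelists score candidate
# relationships 0-3; inclusion requires a high median and a low
# interpercentile range (IPR) across panelists.

#' Median and interpercentile range of panel ratings
#'
#' Percentiles use the Weibull plotting position (`quantile` type 6, linear
#' interpolation at `(n + 1) p`), the convention usual for appropriateness
#' panels; the default range is the 30th-70th.
#'
#' @param scores integer ratings on the 0-3 scale (missing values dropped).
#' @param low_pct,high_pct percentile bounds in percent.
#' @return named numeric vector `c(median =, ipr =)`.
#' @export
rating_consensus <- function(scores, low_pct = 30, high_pct = 70) {
  scores <- scores[!is.na(scores)]
  if (!length(scores))
    stop("rating_consensus: no scores supplied", call. = FALSE)
  if (any(scores < 0 | scores > 3 | scores != round(scores)))
    stop("rating_consensus: scores must be integers in 0..3", call. = FALSE)
  if (low_pct > high_pct)
    stop("rating_consensus: low_pct must not exceed high_pct", call. = FALSE)
  qs <- stats::quantile(scores, probs = c(low_pct, high_pct) / 100,
                        type = 6, names = FALSE)
  c(median = stats::median(scores), ipr = qs[2] - qs[1])
}

#' Edge inclusion decision from panel ratings
#'
#' A relationship is included when the panel's median rating is at least
#' `median_min` and the interpercentile range is at most `ipr_max`
#' (high median, low dispersion).
#'
#' @inheritParams rating_consensus
#' @param median_min minimum median for inclusion (default 2 on the 0-3
#'   scale).
#' @param ipr_max maximum interpercentile range for inclusion (default 1).
#' @return a list of class `ssp_consensus`: `median`, `ipr`, `decision`
#'   (`"include"`/`"exclude"`) and the thresholds used.
#' @export
edge_decision <- function(scores, median_min = 2, ipr_max = 1,
                          low_pct = 30, high_pct = 70) {
  cs <- rating_consensus(scores, low_pct, high_pct)
  structure(list(
    median = unname(cs[["median"]]), ipr = unname(cs[["ipr"]]),
    decision = if (cs[["median"]] >= median_min && cs[["ipr"]] <= ipr_max)
      "include" else "exclude",
    thresholds = c(median_min = median_min, ipr_max = ipr_max,
                   low_pct = low_pct, high_pct = high_pct)),
    class = "ssp_consensus")
}

#' @export
print.ssp_consensus <- function(x, ...) {
  cat(sprintf("<consensus> median %.2f, IPR %.2f -> %s\n",
              x$median, x$ipr, x$decision))
  invisible(x)
}

#' Cell-wise consensus over a relationship grid
#'
#' Applies [edge_decision()] to every cell of a structure-elicitation grid
#' (rows and columns are variables; each cell holds all panelists' 0-3
#' scores for that candidate relationship).
#'
#' @param grid data.frame in long form with columns `row_item`, `col_item`,
#'   `score` (one row per panelist rating).
#' @inheritParams edge_decision
#' @return data.frame with one row per (row_item, col_item) cell: `median`,
#'   `ipr`, `decision`, `included` (logical).
#' @export
grid_consensus <- function(grid, median_min = 2, ipr_max = 1,
                           low_pct = 30, high_pct = 70) {
  stopifnot(all(c("row_item", "col_item", "score") %in% names(grid)))
  cells <- unique(grid[c("row_item", "col_item")])
  out <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- grid$row_item == cells$row_item[i] &
      grid$col_item == cells$col_item[i]
    sc <- grid$score[sel]
    sc <- sc[!is.na(sc)]
    if (!length(sc))
      stop("grid_consensus: empty cell (", cells$row_item[i], ", ",
           cells$col_item[i], ")", call. = FALSE)
    d <- edge_decision(sc, median_min, ipr_max, low_pct, high_pct)
    data.frame(row_item = cells$row_item[i], col_item = cells$col_item[i],
               median = d$median, ipr = d$ipr, decision = d$decision,
               included = d$decision == "include",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Aggregate panelists' importance rankings
#'
#' Items are ordered by ascending median rank across panelists; ties are
#' broken lexicographically by item name.
#'
#' @param rankings list of character vectors, each a permutation of the same
#'   item set (most important first).
#' @return data.frame `item`, `median_rank`, ordered by consensus; the
#'   consensus ordering is also returned as attribute `ordering`.
#' @export
aggregate_rankings <- function(rankings) {
  if (!length(rankings))
    stop("aggregate_rankings: no rankings supplied", call. = FALSE)
  items <- sort(rankings[[1]])
  for (r in rankings) {
    if (!identical(sort(r), items) || anyDuplicated(r))
      stop("aggregate_rankings: all rankings must permute the same item set",
           call. = FALSE)
  }
  med <- vapply(items, function(it)
    stats::median(vapply(rankings, function(r) match(it, r), numeric(1))),
    numeric(1))
  ord <- order(med, items)
  out <- data.frame(item = items[ord], median_rank = unname(med[ord]),
                    stringsAsFactors = FALSE)
  attr(out, "ordering") <- out$item
  out
}
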