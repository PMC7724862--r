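#' Rank basins by a baseline selection strategy
#'
#' The four ranking baselines ML-Select is compared against:
#' \describe{
#'   \item{S}{descending basin size;}
#'   \item{S+E}{ascending sum of a size rank (descending size) and an energy
#'     rank (ascending focal energy), both mid-rank;}
#'   \item{PR}{ascending Pareto rank;}
#'   \item{PR+PC}{ascending Pareto rank, ties broken by descending Pareto
#'     count.}
#' }
#' All residual ties break by ascending `basin_id`, so the ordering is
#' deterministic and invariant to the input row order.
#'
#' @param strategy One of `"S"`, `"S+E"`, `"PR"`, `"PR+PC"`.
#' @param rows Basin feature rows from [featurize_basins()].
#' @return Object of class `ranked_selection`: `strategy`,
#'   `ordered_basins` (basin ids, best first) and `scores` (the ordering
#'   scalar, aligned with `ordered_basins`).
#' @export
rank_basins <- function(strategy, rows) {
  if (nrow(rows) == 0) stop("no basins to rank")
  ord_score <- switch(strategy,
    "S" = list(o = order(-rows$size, rows$basin_id), s = rows$size),
    "S+E" = {
      sr <- rank(-rows$size, ties.method = "average")
      er <- rank(rows$focal_energy, ties.method = "average")
      list(o = order(sr + er, rows$basin_id), s = sr + er)
    },
    "PR" = list(o = order(rows$PR, rows$basin_id), s = rows$PR),
    "PR+PC" = list(o = order(rows$PR, -rows$PC, rows$basin_id), s = rows$PR),
    stop("unknown strategy: ", strategy))
  structure(list(strategy = strategy,
                 ordered_basins = rows$basin_id[ord_score$o],
                 scores = ord_score$s[ord_score$o]),
            class = "ranked_selection")
}

#' Merged top-x decoy groups of a basin ranking
#'
#' Builds the cumulative groups `B_1`, `B_1-2`, ..., `B_1-x_max`: the union
#' of the member sets of the top x basins in ranked order.
#'
#' @param ordered_basins Basin ids, best first (e.g. from [rank_basins()]).
#' @param decomp The `basin_decomposition` the ids refer to.
#' @param x_max Number of cumulative groups (default 3).
#' @param members Optional named list mapping basin id to a member index
#'   vector; overrides `decomp` members (used for purified basins).
#' @return List of `min(x_max, length(ordered_basins))` integer vectors of
#'   decoy indices, each a superset of the previous one.
#' @export
select_groups <- function(ordered_basins, decomp, x_max = 3, members = NULL) {
  top <- head(ordered_basins, x_max)
  sets <- lapply(top, function(b) {
    if (!is.null(members)) members[[as.character(b)]]
    else decomp$basins[[b]]$members
  })
  out <- vector("list", length(sets))
  acc <- integer(0)
  for (i in seq_along(sets)) {
    acc <- sort(union(acc, sets[[i]]))
    out[[i]] <- acc
  }
  out
}
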