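#' Pareto rank and count of basins
#'
#' Basins compete on two objectives: maximize size and minimize focal
#' energy. Basin A dominates basin B iff `size_A >= size_B` and
#' `energy_A <= energy_B` with at least one inequality strict. The Pareto
#' rank PR(A) is the number of basins dominating A; the Pareto count PC(A)
#' is the number of basins A dominates.
#'
#' @param basins List of basins (as in a `basin_decomposition`), or a data
#'   frame/list with `size` and `focal_energy`.
#' @return List with integer vectors `PR` and `PC`.
#' @export
pareto_rank_count <- function(basins) {
  if (is.data.frame(basins)) {
    s <- basins$size; e <- basins$focal_energy
  } else {
    s <- vapply(basins, `[[`, numeric(1), "size")
    e <- vapply(basins, `[[`, numeric(1), "focal_energy")
  }
  m <- length(s)
  # dom[a, b]: a dominates b
  ge_s <- outer(s, s, ">=")
  le_e <- outer(e, e, "<=")
  strict <- outer(s, s, ">") | outer(e, e, "<")
  dom <- ge_s & le_e & strict
  list(PR = as.integer(colSums(dom)), PC = as.integer(rowSums(dom)))
}

#' Within-basin graph: mean pairwise distance and component count
#'
#' A basin is a bag of decoys; to recover its spatial organization, its
#' members are embedded in their own nearest-neighbor graph with cutoff
#' `pdist + 1` (distance units), where `pdist` is the mean pairwise member
#' distance. The number of connected components of that graph is the
#' basin's graph feature. Singletons have `pdist = 0` and one component.
#'
#' @param ensemble A [decoy_ensemble()].
#' @param basin A basin (list with `members`).
#' @param dist_matrix Optional precomputed full distance matrix (avoids
#'   recomputation when featurizing many basins).
#' @return List with `pdist` and `n_components`.
#' @export
basin_component_count <- function(ensemble, basin, dist_matrix = NULL) {
  idx <- basin$members
  k <- length(idx)
  if (k == 0) stop("basin has no members")
  if (k == 1) return(list(pdist = 0, n_components = 1L))
  D <- if (is.null(dist_matrix)) ensemble_dist_matrix(ensemble)[idx, idx]
       else dist_matrix[idx, idx]
  pd <- mean(D[upper.tri(D)])
  A <- D <= pd + 1.0
  diag(A) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  list(pdist = pd, n_components = igraph::components(g)$no)
}

#' Per-basin feature rows for phase-1 learning
#'
#' One row per basin with size, focal energy, Pareto rank/count, the two
#' ranks derived from them (mid-rank tie averaging; `pr_rank` ascends in PR,
#' `pc_rank` descends in PC so rank 1 is best for both), the within-basin
#' graph feature, and — when near-native labels are supplied — the basin's
#' true purity (near-native member fraction) as the training label.
#'
#' @param decomp A `basin_decomposition` from [assign_basins()].
#' @param ensemble The matching [decoy_ensemble()].
#' @param labels Optional logical vector (one flag per decoy): is the decoy
#'   a true near-native?
#' @param dist_matrix Optional precomputed full distance matrix.
#' @return Data frame of class `basin_feature_rows` with columns
#'   `basin_id`, `size`, `focal_energy`, `PR`, `PC`, `pr_rank`, `pc_rank`,
#'   `pdist`, `n_components` and (if labelled) `purity_label`.
#' @export
featurize_basins <- function(decomp, ensemble, labels = NULL,
                             dist_matrix = NULL) {
  basins <- decomp$basins
  m <- length(basins)
  pp <- pareto_rank_count(basins)
  comp <- lapply(basins, basin_component_count, ensemble = ensemble,
                 dist_matrix = dist_matrix)
  rows <- data.frame(
    basin_id = vapply(basins, `[[`, integer(1), "basin_id"),
    size = vapply(basins, `[[`, integer(1), "size"),
    focal_energy = vapply(basins, `[[`, numeric(1), "focal_energy"),
    PR = pp$PR,
    PC = pp$PC,
    pr_rank = rank(pp$PR, ties.method = "average"),
    pc_rank = rank(-pp$PC, ties.method = "average"),
    pdist = vapply(comp, `[[`, numeric(1), "pdist"),
    n_components = vapply(comp, function(x) as.integer(x$n_components),
                          integer(1)))
  if (!is.null(labels)) {
    if (length(labels) != ensemble$size)
      stop("labels length (", length(labels), ") != ensemble size (",
           ensemble$size, ")")
    rows$purity_label <- vapply(basins, function(b)
      mean(labels[b$members]), numeric(1))
  }
  class(rows) <- c("basin_feature_rows", class(rows))
  rows
}
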