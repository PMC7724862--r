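#' Pairwise distance between two decoys
#'
#' Distance semantics follow the ensemble's `distance_spec`:
#' \describe{
#'   \item{euclidean-on-coords}{Per-atom RMS of the flat coordinate
#'     difference, i.e. Euclidean distance divided by sqrt(n_atoms).}
#'   \item{common-frame-rmsd}{Every decoy is first rigidly superposed
#'     (Kabsch) onto the reference decoy (index 1); distances are then plain
#'     coordinate RMSDs between the posed copies.}
#'   \item{precomputed-matrix}{Lookup in the attached matrix.}
#' }
#'
#' @param ensemble A [decoy_ensemble()].
#' @param u,v Decoy indices.
#' @return Non-negative scalar; `d(u, u) = 0`; symmetric.
#' @export
pairwise_distance <- function(ensemble, u, v) {
  if (u == v) return(0)
  switch(ensemble$distance_spec,
    "precomputed-matrix" = ensemble$dist_matrix[u, v],
    "euclidean-on-coords" = {
      co <- need_coords(ensemble)
      sqrt(sum((co[u, ] - co[v, ])^2) / (ncol(co) / 3))
    },
    "common-frame-rmsd" = {
      co <- common_frame_coords(ensemble)
      sqrt(sum((co[u, ] - co[v, ])^2) / (ncol(co) / 3))
    })
}

need_coords <- function(ensemble) {
  if (is.null(ensemble$coords))
    stop("distance_spec '", ensemble$distance_spec,
         "' needs coordinates but none are attached")
  ensemble$coords
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Rotates and translates point set `P` onto `Q`, minimizing the RMSD.
#' Both are given as n_atoms x 3 matrices.
#'
#' @param P,Q Numeric matrices, n_atoms x 3.
#' @return List with `coords` (P posed onto Q), `rmsd`, rotation `R` and
#'   translation so that `coords = (P - cP) %*% R + cQ`.
#' @export
kabsch_superpose <- function(P, Q) {
  stopifnot(nrow(P) == nrow(Q), ncol(P) == 3, ncol(Q) == 3)
  cP <- colMeans(P); cQ <- colMeans(Q)
  P0 <- sweep(P, 2, cP); Q0 <- sweep(Q, 2, cQ)
  s <- svd(crossprod(P0, Q0))
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  posed <- sweep(P0 %*% R, 2, cQ, "+")
  list(coords = posed, rmsd = sqrt(mean(rowSums((posed - Q)^2))),
       R = R, center_P = cP, center_Q = cQ)
}

# Superpose every decoy onto decoy 1, once, returning flat coordinates.
common_frame_coords <- function(ensemble) {
  co <- need_coords(ensemble)
  ref <- matrix(co[1, ], ncol = 3, byrow = TRUE)
  t(apply(co, 1, function(v) {
    as.numeric(t(kabsch_superpose(matrix(v, ncol = 3, byrow = TRUE),
                                  ref)$coords))
  }))
}

#' Full pairwise distance matrix of an ensemble
#'
#' @param ensemble A [decoy_ensemble()].
#' @return Dense symmetric matrix of pairwise distances under the
#'   ensemble's `distance_spec`.
#' @export
ensemble_dist_matrix <- function(ensemble) {
  D <- switch(ensemble$distance_spec,
    "precomputed-matrix" = ensemble$dist_matrix,
    "euclidean-on-coords" = {
      co <- need_coords(ensemble)
      as.matrix(dist(co)) / sqrt(ncol(co) / 3)
    },
    "common-frame-rmsd" = {
      co <- common_frame_coords(ensemble)
      as.matrix(dist(co)) / sqrt(ncol(co) / 3)
    })
  if (any(!is.finite(D))) stop("non-finite pairwise distance")
  unname(D)
}

# Bottleneck (max) edge weight of the minimum spanning tree via Prim.
# The epsilon-graph is connected iff epsilon >= this value.
mst_bottleneck <- function(D) {
  n <- nrow(D)
  intree <- logical(n)
  mind <- D[1, ]
  intree[1] <- TRUE
  bottleneck <- 0
  for (i in seq_len(n - 1)) {
    cand <- which(!intree)
    j <- cand[which.min(mind[cand])]
    bottleneck <- max(bottleneck, mind[j])
    intree[j] <- TRUE
    mind <- pmin(mind, D[j, ])
  }
  bottleneck
}

# Connectivity of a logical adjacency matrix by BFS from vertex 1.
adj_connected <- function(A) {
  n <- nrow(A)
  seen <- logical(n)
  seen[1] <- TRUE
  frontier <- 1L
  while (length(frontier)) {
    nxt <- which(colSums(A[frontier, , drop = FALSE]) > 0 & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

#' Build the nearest-neighbor graph over a decoy ensemble
#'
#' Vertices are decoys; `(u, v)` is an edge iff `d(u, v) <= epsilon`. The
#' cutoff starts at `epsilon0` and is escalated along the ladder
#' `epsilon0, epsilon0 + step, ...` until the graph is connected (the
#' smallest such ladder value is used). With `k_cap`, each vertex keeps only
#' its `k_cap` nearest neighbors (an edge survives if either endpoint keeps
#' it) and the ladder continues until the capped graph is connected.
#'
#' @param x A [decoy_ensemble()] or a precomputed symmetric distance matrix.
#' @param epsilon0 Starting cutoff in distance units (default 1.0).
#' @param step Ladder increment (default 0.5).
#' @param k_cap Optional per-vertex neighbor cap; `NULL` (default) disables
#'   density control.
#' @return Object of class `nn_graph`: `n_vertices`, `epsilon`, the distance
#'   matrix `dist`, and logical adjacency `adj`.
#' @export
build_nn_graph <- function(x, epsilon0 = 1.0, step = 0.5, k_cap = NULL) {
  stopifnot(epsilon0 > 0, step > 0)
  D <- if (inherits(x, "decoy_ensemble")) ensemble_dist_matrix(x) else {
    x <- as.matrix(x)
    stopifnot(nrow(x) == ncol(x))
    x
  }
  n <- nrow(D)
  if (n < 2) stop("need at least 2 decoys")
  if (any(!is.finite(D))) stop("non-finite pairwise distance")
  bottleneck <- mst_bottleneck(D)
  eps <- if (bottleneck <= epsilon0) epsilon0 else
    epsilon0 + step * ceiling((bottleneck - epsilon0) / step)
  make_adj <- function(eps) {
    A <- D <= eps
    diag(A) <- FALSE
    if (!is.null(k_cap)) {
      keep <- matrix(FALSE, n, n)
      for (u in seq_len(n)) {
        nb <- which(A[u, ])
        if (length(nb) > k_cap)
          nb <- nb[order(D[u, nb])][seq_len(k_cap)]
        keep[u, nb] <- TRUE
      }
      A <- keep | t(keep)   # edge kept if either endpoint selects it
    }
    A
  }
  A <- make_adj(eps)
  if (!is.null(k_cap)) {
    dmax <- max(D)
    while (!adj_connected(A)) {
      if (eps > dmax + step) stop("capped graph cannot be connected")
      eps <- eps + step
      A <- make_adj(eps)
    }
  }
  structure(list(n_vertices = n, epsilon = eps, dist = D, adj = A,
                 k_cap = k_cap),
            class = "nn_graph")
}

#' @export
print.nn_graph <- function(x, ...) {
  cat("<nn_graph> ", x$n_vertices, " vertices, epsilon = ", x$epsilon,
      ", ", sum(x$adj) / 2, " edges\n", sep = "")
  invisible(x)
}

#' Local minima of an energy over a nearest-neighbor graph
#'
#' A vertex `u` is a local minimum iff `f(u) <= f(v)` for every neighbor
#' `v`; ties are admitted, so flat plateaus can hold several minima.
#'
#' @param graph An [build_nn_graph()] result.
#' @param energies Numeric vector, one fitness value per vertex.
#' @return Sorted integer vector of local-minimum vertex indices.
#' @export
find_local_minima <- function(graph, energies) {
  n <- graph$n_vertices
  stopifnot(length(energies) == n)
  FU <- outer(energies, energies, "-")  # f(u) - f(v), u in rows
  FU[!graph$adj] <- -Inf
  mc <- max.col(FU, ties.method = "first")
  which(FU[cbind(seq_len(n), mc)] <= 0)
}

#' Decompose a landscape into basins of attraction
#'
#' Every non-minimum vertex `u` steps to the neighbor `v` maximizing the
#' descent ratio `(f(u) - f(v)) / d(u, v)` (ties: smallest vertex index;
#' zero-distance neighbors count as ratio `+Inf` when strictly downhill and
#' are skipped otherwise) and the path is followed to a local minimum; the
#' vertices reaching the same minimum form its basin. Since a non-minimum
#' always has a strictly downhill neighbor, energies strictly decrease along
#' each path and the descent terminates.
#'
#' @param graph An [build_nn_graph()] result.
#' @param energies Numeric vector, one fitness value per vertex.
#' @return Object of class `basin_decomposition`: `basins` (list of basins,
#'   each with `basin_id`, `focal_minimum`, `members`, `size`,
#'   `focal_energy`) and `assignment` (vertex -> basin_id). Basins are
#'   numbered in order of their focal-minimum vertex index.
#' @export
assign_basins <- function(graph, energies) {
  n <- graph$n_vertices
  stopifnot(length(energies) == n)
  FU <- outer(energies, energies, "-")
  R <- FU / graph$dist
  zero <- graph$dist == 0
  R[zero & FU > 0] <- Inf
  R[zero & FU <= 0] <- -Inf
  R[!graph$adj] <- -Inf
  succ <- max.col(R, ties.method = "first")
  best <- R[cbind(seq_len(n), succ)]
  minima <- best <= 0            # no strictly-downhill neighbor
  idx <- which(minima)
  succ[idx] <- idx               # minima are fixed points of the descent
  # pointer jumping: paths strictly decrease f, so this converges
  guard <- 0
  while (any(succ[succ] != succ)) {
    succ <- succ[succ]
    guard <- guard + 1
    if (guard > ceiling(log2(n)) + 2)
      stop("internal error: basin descent did not terminate")
  }
  focal <- sort(unique(succ))
  assignment <- match(succ, focal)
  basins <- lapply(seq_along(focal), function(b) {
    members <- which(assignment == b)
    list(basin_id = b, focal_minimum = focal[b], members = members,
         size = length(members), focal_energy = energies[focal[b]])
  })
  structure(list(basins = basins, assignment = assignment),
            class = "basin_decomposition")
}

#' @export
print.basin_decomposition <- function(x, ...) {
  sizes <- vapply(x$basins, `[[`, integer(1), "size")
  cat("<basin_decomposition> ", length(x$basins), " basins over ",
      sum(sizes), " decoys (largest = ", max(sizes), ")\n", sep = "")
  invisible(x)
}
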