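# Independent reference implementations ("oracles") used to validate the
# package's algorithms. These are deliberately written with different
# techniques than the package code (scalar loops, recursion, quaternions,
# ladder scans) so that agreement is informative.

# ---- landscape oracles -----------------------------------------------------

# Neighbor-scan local minima: u is a minimum iff f(u) <= f(v) for all
# neighbors v.
oracle_local_minima <- function(adj, f) {
  n <- length(f)
  which(vapply(seq_len(n), function(u) {
    nb <- which(adj[u, ])
    length(nb) == 0 || all(f[u] <= f[nb])
  }, logical(1)))
}

# Brute-force per-vertex descent under the maximal-ratio rule:
# step from u to the neighbor v maximizing (f(u) - f(v)) / d(u, v)
# (zero-distance neighbors: ratio +Inf when strictly downhill, skipped
# otherwise), ties broken by smallest vertex index, until no strictly
# downhill neighbor remains. Returns the focal-minimum vertex per vertex.
oracle_descend <- function(adj, D, f) {
  n <- length(f)
  vapply(seq_len(n), function(u) {
    steps <- 0
    repeat {
      nb <- which(adj[u, ])
      if (!length(nb)) return(u)
      d <- D[u, nb]
      r <- (f[u] - f[nb]) / d
      r[d == 0 & f[u] > f[nb]] <- Inf
      r[d == 0 & f[u] <= f[nb]] <- -Inf
      best <- max(r)
      if (best <= 0) return(u)
      u <- min(nb[r == best])
      steps <- steps + 1
      if (steps > n) stop("oracle descent did not terminate")
    }
  }, integer(1))
}

# Full oracle partition in the package's basin numbering (basins ordered by
# focal vertex index).
oracle_assignment <- function(adj, D, f) {
  focal_of <- oracle_descend(adj, D, f)
  match(focal_of, sort(unique(focal_of)))
}

# Ladder-scan oracle for the connectivity cutoff: the smallest value of
# epsilon0, epsilon0 + step, ... whose epsilon-graph is connected (BFS).
oracle_connect_eps <- function(D, epsilon0 = 1, step = 0.5) {
  eps <- epsilon0
  repeat {
    A <- D <= eps
    diag(A) <- FALSE
    if (oracle_connected(A)) return(eps)
    eps <- eps + step
  }
}

oracle_connected <- function(A) {
  n <- nrow(A)
  seen <- logical(n)
  queue <- 1L
  seen[1] <- TRUE
  while (length(queue)) {
    u <- queue[1]
    queue <- queue[-1]
    nb <- which(A[u, ] & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

# Random landscape fixture: n points in 3-D, energies loosely coupled to a
# random center, returning the package graph plus the raw pieces.
random_landscape <- function(n, seed) {
  withr::with_seed(seed, {
    pts <- matrix(rnorm(n * 3, sd = 3), n, 3)
    D <- as.matrix(dist(pts))
    f <- sqrt(rowSums(pts^2)) + rnorm(n, sd = 1.5)
  })
  graph <- build_nn_graph(D, epsilon0 = 1, step = 0.5)
  list(graph = graph, D = D, f = f)
}

# ---- superposition oracle --------------------------------------------------

# Horn's quaternion method for optimal rigid superposition RMSD -- an
# algebraically different route than the SVD-based Kabsch in the package.
oracle_superpose_rmsd <- function(P, Q) {
  n <- nrow(P)
  P0 <- sweep(P, 2, colMeans(P))
  Q0 <- sweep(Q, 2, colMeans(Q))
  M <- crossprod(P0, Q0)
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  lambda <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(P0^2) + sum(Q0^2) - 2 * lambda) / n
  sqrt(max(msd, 0))
}

# ---- Pareto oracle ---------------------------------------------------------

# O(m^2) double-loop dominance counting on (maximize size, minimize energy).
oracle_pareto <- function(size, energy) {
  m <- length(size)
  PR <- integer(m)
  PC <- integer(m)
  for (a in seq_len(m)) for (b in seq_len(m)) {
    if (a == b) next
    dominates <- size[a] >= size[b] && energy[a] <= energy[b] &&
      (size[a] > size[b] || energy[a] < energy[b])
    if (dominates) {
      PC[a] <- PC[a] + 1L
      PR[b] <- PR[b] + 1L
    }
  }
  list(PR = PR, PC = PC)
}

# ---- Friedman permutation oracle -------------------------------------------

oracle_friedman_chi2 <- function(P) {
  N <- nrow(P); k <- ncol(P)
  ranks <- t(apply(P, 1, function(r) rank(-r, ties.method = "average")))
  rbar <- colMeans(ranks)
  12 * N / (k * (k + 1)) * sum((rbar - (k + 1) / 2)^2)
}

# Monte-Carlo permutation null: methods are shuffled independently within
# every dataset row; returns the tail probability of the observed statistic.
oracle_friedman_perm_p <- function(P, shuffles = 10000, seed = 1) {
  N <- nrow(P); k <- ncol(P)
  ranks <- t(apply(P, 1, function(r) rank(-r, ties.method = "average")))
  obs <- oracle_friedman_chi2(P)
  withr::with_seed(seed, {
    tot <- matrix(0, shuffles, k)
    for (i in seq_len(N)) {
      idx <- t(replicate(shuffles, sample.int(k)))
      tot <- tot + matrix(ranks[i, ][idx], shuffles, k)
    }
  })
  rbar <- tot / N
  stat <- 12 * N / (k * (k + 1)) * rowSums((rbar - (k + 1) / 2)^2)
  mean(stat >= obs - 1e-12)
}

# ---- small-ensemble fixtures -----------------------------------------------

# Minimal ensemble with explicit coordinates/energies and schema features
# filled with an affine map of an index (content irrelevant to most tests).
toy_ensemble <- function(coords, energies, rmsd = NULL,
                         target_id = "toy", seed = 1) {
  n <- nrow(coords)
  sch <- feature_schema()
  withr::with_seed(seed, {
    feats <- matrix(rnorm(n * sch$total), n, sch$total)
  })
  colnames(feats) <- sch$names
  df <- data.frame(decoy_id = sprintf("d%03d", seq_len(n)),
                   energy = energies, stringsAsFactors = FALSE)
  if (!is.null(rmsd)) df$rmsd_native <- rmsd
  df <- cbind(df, as.data.frame(feats))
  decoy_ensemble(target_id, df, coords = coords,
                 distance_spec = "euclidean-on-coords")
}

# A fabricated prepared-target stand-in for training-set assembly tests.
fake_target <- function(target_id, n_basins, seed = 1) {
  withr::with_seed(seed, {
    rows <- data.frame(
      basin_id = seq_len(n_basins),
      size = sample(1:50, n_basins, replace = TRUE),
      focal_energy = rnorm(n_basins),
      PR = sample(0:(n_basins - 1), n_basins, replace = TRUE),
      PC = sample(0:(n_basins - 1), n_basins, replace = TRUE),
      pr_rank = as.numeric(sample(n_basins)),
      pc_rank = as.numeric(sample(n_basins)),
      pdist = runif(n_basins, 0, 5),
      n_components = sample(1:4, n_basins, replace = TRUE),
      purity_label = runif(n_basins))
  })
  list(rows = rows, ensemble = list(target_id = target_id))
}

# Small labelled synthetic target, prepared end to end.
small_prepared_target <- function(id, difficulty, seed, size = 300,
                                  near_native_frac = 0.06, rho = 0.9) {
  spec <- synthetic_spec(id, difficulty = difficulty, size = size,
                         near_native_frac = near_native_frac, rho = rho,
                         seed = seed)
  ens <- generate_ensemble(spec)
  meta <- classify_target(min(ens$decoys$rmsd_native),
                          rmsds = ens$decoys$rmsd_native, target_id = id)
  prepare_target(ens, meta)
}
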