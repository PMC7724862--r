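test_that("pairwise distances honor the three distance specs", {
  coords <- rbind(c(0, 0, 0), c(3, 4, 0))
  df <- data.frame(decoy_id = c("a", "b"), energy = c(0, 1),
                   stringsAsFactors = FALSE)
  ens <- decoy_ensemble("tri", df, coords = coords,
                        distance_spec = "euclidean-on-coords")
  expect_equal(pairwise_distance(ens, 1, 1), 0)
  expect_equal(pairwise_distance(ens, 1, 2), 5)   # 3-4-5 triangle, 1 atom
  D <- matrix(c(0, 2.5, 2.5, 0), 2, 2)
  ensm <- decoy_ensemble("m", df, distance_spec = "precomputed-matrix",
                         dist_matrix = D)
  expect_equal(pairwise_distance(ensm, 2, 1), 2.5)
  expect_equal(ensemble_dist_matrix(ensm), D)
})

test_that("Kabsch superposition recovers rigid transforms exactly", {
  withr::with_seed(21, {
    P <- matrix(rnorm(30), 10, 3)
    theta <- runif(1, 0, pi)
    R <- rbind(c(cos(theta), -sin(theta), 0),
               c(sin(theta), cos(theta), 0),
               c(0, 0, 1))
    Q <- P %*% R + matrix(rnorm(3), 10, 3, byrow = TRUE)
  })
  fit <- kabsch_superpose(P, Q)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(det(fit$R), 1, tolerance = 1e-10)   # proper rotation
})

test_that("common-frame distances match an independent quaternion oracle", {
  # every decoy is posed onto decoy 1; the distance of any decoy to the
  # reference itself is exactly the optimal superposition RMSD, which the
  # quaternion route recomputes independently
  withr::with_seed(31, coords <- matrix(rnorm(6 * 30, sd = 4), 6, 30))
  df <- data.frame(decoy_id = sprintf("d%d", 1:6), energy = rnorm(6),
                   stringsAsFactors = FALSE)
  ens <- decoy_ensemble("cf", df, coords = coords,
                        distance_spec = "common-frame-rmsd")
  for (v in 2:6) {
    P <- matrix(coords[v, ], ncol = 3, byrow = TRUE)
    Q <- matrix(coords[1, ], ncol = 3, byrow = TRUE)
    expect_equal(pairwise_distance(ens, 1, v), oracle_superpose_rmsd(P, Q),
                 tolerance = 1e-6)
  }
})

test_that("the neighbor graph uses the smallest connecting ladder cutoff", {
  D <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  g <- build_nn_graph(D, epsilon0 = 1)
  expect_equal(g$epsilon, 1)
  expect_equal(sum(g$adj) / 2, 1)   # one edge

  pts <- c(0, 1, 2, 10)
  D4 <- abs(outer(pts, pts, "-"))
  g4 <- build_nn_graph(D4, epsilon0 = 1, step = 0.5)
  expect_equal(g4$epsilon, 8)
  expect_true(adj_connected(g4$adj))
  expect_equal(g4$epsilon, oracle_connect_eps(D4, 1, 0.5))
})

test_that("the MST-bottleneck cutoff equals the ladder-scan oracle", {
  for (seed in 1:25) {
    withr::with_seed(seed, {
      n <- sample(5:40, 1)
      pts <- matrix(rnorm(n * 2, sd = sample(1:6, 1)), n, 2)
    })
    D <- as.matrix(dist(pts))
    g <- build_nn_graph(D, epsilon0 = 1, step = 0.5)
    expect_equal(g$epsilon, oracle_connect_eps(D, 1, 0.5))
    expect_true(adj_connected(g$adj))
    # the epsilon-graph one rung below must be disconnected (or the ladder
    # started there)
    if (g$epsilon > 1) {
      A <- D <= g$epsilon - 0.5
      diag(A) <- FALSE
      expect_false(oracle_connected(A))
    }
  }
})

test_that("neighbor capping keeps mutual selections and reconnects", {
  withr::with_seed(7, pts <- matrix(rnorm(60), 30, 2))
  D <- as.matrix(dist(pts))
  g <- build_nn_graph(D, epsilon0 = 1, step = 0.5, k_cap = 3)
  expect_true(adj_connected(g$adj))
  expect_true(isSymmetric(g$adj))
  # an edge survives iff at least one endpoint ranks the other in its top k
  for (u in 1:30) {
    nb_all <- setdiff(which(D[u, ] <= g$epsilon), u)
    top_u <- nb_all[order(D[u, nb_all])][seq_len(min(3, length(nb_all)))]
    for (v in which(g$adj[u, ])) {
      nb_v <- setdiff(which(D[v, ] <= g$epsilon), v)
      top_v <- nb_v[order(D[v, nb_v])][seq_len(min(3, length(nb_v)))]
      expect_true(v %in% top_u || u %in% top_v)
    }
  }
})

test_that("local minima admit ties and match the neighbor-scan oracle", {
  # path a-b-c with energies (3, 1, 2) -> only b
  D <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3)
  g <- build_nn_graph(D, epsilon0 = 1)
  expect_equal(find_local_minima(g, c(3, 1, 2)), 2L)
  # an edge with equal energies: both vertices are minima
  D2 <- matrix(c(0, 1, 1, 0), 2, 2)
  g2 <- build_nn_graph(D2, epsilon0 = 1)
  expect_equal(find_local_minima(g2, c(2, 2)), c(1L, 2L))
  for (seed in 1:20) {
    lands <- random_landscape(80, seed = 100 + seed)
    expect_equal(find_local_minima(lands$graph, lands$f),
                 oracle_local_minima(lands$graph$adj, lands$f))
  }
})

test_that("the maximal-ratio descent picks the steepest neighbor", {
  # u (f=3) with neighbors v1 (f=1, d=2, ratio 1.0) and v2 (f=2, d=0.5,
  # ratio 2.0): u must join v2's basin
  D <- matrix(c(0, 2.0, 0.5,
                2.0, 0, 2.5,
                0.5, 2.5, 0), 3, 3)
  f <- c(3, 1, 2)
  g <- build_nn_graph(D, epsilon0 = 2.0)   # escalates until connected
  expect_true(g$adj[1, 2] && g$adj[1, 3])
  decomp <- assign_basins(g, f)
  expect_equal(decomp$assignment[1], decomp$assignment[3])
  expect_false(decomp$assignment[1] == decomp$assignment[2])
})

test_that("a monotone chain collapses into a single basin", {
  D <- abs(outer(1:4, 1:4, "-")) * 1.0
  g <- build_nn_graph(D, epsilon0 = 1)
  decomp <- assign_basins(g, c(4, 3, 2, 1))
  expect_length(decomp$basins, 1)
  expect_equal(decomp$basins[[1]]$focal_minimum, 4L)
  expect_equal(decomp$basins[[1]]$focal_energy, 1)
})

test_that("zero-distance duplicates descend or tie per the stated rule", {
  # duplicate points, strictly downhill: the higher vertex joins the lower
  D <- matrix(c(0, 0, 5, 0, 0, 5, 5, 5, 0), 3, 3)
  g <- build_nn_graph(D, epsilon0 = 1, step = 0.5)
  decomp <- assign_basins(g, c(2, 1, 0.5))
  expect_equal(decomp$assignment[1], decomp$assignment[2])
  # duplicate points with equal energy: neither descends into the other
  # (plateau), so both are local minima; the third vertex ties on ratio
  # and joins the smaller index
  decomp2 <- assign_basins(g, c(1, 1, 2))
  expect_length(decomp2$basins, 2)
  expect_equal(decomp2$assignment, c(1L, 2L, 1L))
})

test_that("basin decomposition matches the brute-force descent oracle", {
  for (seed in 1:15) {
    lands <- random_landscape(120, seed = 200 + seed)
    decomp <- assign_basins(lands$graph, lands$f)
    expect_equal(decomp$assignment,
                 oracle_assignment(lands$graph$adj, lands$graph$dist,
                                   lands$f))
    # partition totals and minima correspondence
    sizes <- vapply(decomp$basins, `[[`, integer(1), "size")
    expect_equal(sum(sizes), 120L)
    focal <- vapply(decomp$basins, `[[`, integer(1), "focal_minimum")
    minima <- find_local_minima(lands$graph, lands$f)
    expect_true(all(focal %in% minima))
    expect_equal(sort(unique(decomp$assignment)),
                 seq_along(decomp$basins))
  }
})
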