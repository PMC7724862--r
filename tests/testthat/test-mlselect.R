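test_that("configuration validates its parameter ranges", {
  cfg <- mlselect_config()
  expect_equal(cfg$n_phase1, 10)
  expect_equal(cfg$k_out, 3)
  expect_equal(cfg$q, 10)
  expect_equal(cfg$boosting_rounds, 15)
  expect_equal(cfg$runs, 50)
  expect_error(mlselect_config(tau = 0.3))       # |tau| <= 0.25
  expect_error(mlselect_config(n_phase1 = 2, k_out = 3))
})

test_that("sub-seed derivation is deterministic and in 31-bit range", {
  s <- derive_seed(123456789, 42)
  expect_identical(s, derive_seed(123456789, 42))
  expect_true(s >= 0 && s < 2^31)
  expect_false(derive_seed(1, 1) == derive_seed(1, 2))
  expect_false(derive_seed(1, 1) == derive_seed(2, 1))
  # large seeds must not overflow to NA
  expect_false(is.na(derive_seed(2147483646, 7919)))
})

test_that("the regressor fits constants, planted maps, and is deterministic", {
  withr::with_seed(1, {
    X <- matrix(rnorm(200 * 3), 200, 3)
    colnames(X) <- c("pr_rank", "pc_rank", "n_components")
  })
  # constant labels: regression to the mean
  m0 <- train_gb_regressor(X, rep(0.7, 200))
  expect_equal(unname(predict(m0, X)), rep(0.7, 200), tolerance = 0.05)
  # noiseless planted linear map: holdout R^2 >= 0.99
  for (p in c(3, 20)) {
    withr::with_seed(p, {
      Xtr <- matrix(rnorm(400 * p), 400, p)
      beta <- runif(p, -2, 2)
      Xte <- matrix(rnorm(200 * p), 200, p)
    })
    ytr <- drop(Xtr %*% beta) + 1
    yte <- drop(Xte %*% beta) + 1
    m <- train_gb_regressor(Xtr, ytr)
    pred <- predict(m, Xte)
    r2 <- 1 - sum((pred - yte)^2) / sum((yte - mean(yte))^2)
    expect_gte(r2, 0.99)
  }
  # identical rows and seed give identical predictions
  m1 <- train_gb_regressor(X, X[, 1] + 0.1 * X[, 2], seed = 9)
  m2 <- train_gb_regressor(X, X[, 1] + 0.1 * X[, 2], seed = 9)
  expect_identical(predict(m1, X), predict(m2, X))
  # all-constant features degenerate to the label mean
  mc <- train_gb_regressor(matrix(1, 50, 2), seq_len(50))
  expect_equal(unname(predict(mc, matrix(1, 3, 2))), rep(25.5, 3))
})

test_that("phase-1 sampling takes top q plus q random negatives per target", {
  targets <- lapply(1:6, function(i) fake_target(paste0("t", i), 30,
                                                 seed = i))
  rows <- make_phase1_training_set(targets, q = 10, seed = 4)
  expect_equal(nrow(rows), 120)   # 2q per target
  expect_equal(unname(table(rows$target_id)), rep(10L * 2L, 6),
               ignore_attr = TRUE)
  # per target the top-q purity basins are always included
  for (i in 1:6) {
    tg <- targets[[i]]
    picked <- rows$basin_id[rows$target_id == paste0("t", i)]
    top <- tg$rows$basin_id[order(-tg$rows$purity_label,
                                  -tg$rows$size, tg$rows$basin_id)][1:10]
    expect_true(all(top %in% picked))
  }
  # degenerate rule: <= 2q basins contribute everything
  small <- list(fake_target("small", 5, seed = 99))
  expect_equal(nrow(make_phase1_training_set(small, q = 10)), 5)
  # seeded determinism of the negative resample
  expect_equal(make_phase1_training_set(targets, q = 10, seed = 4), rows)
  expect_false(identical(make_phase1_training_set(targets, q = 10, seed = 5),
                         rows))
})

test_that("phase-1 selection orders by predicted purity with id tie-break", {
  rows <- fake_target("x", 12, seed = 3)$rows
  rows$purity_label <- rows$pr_rank * 0.05   # exactly learnable signal
  cfg <- mlselect_config()
  m <- train_phase1(rows, cfg)
  sel <- phase1_select(m, rows, n_phase1 = 12)
  expect_s3_class(sel, "ranked_selection")
  # predictions increase in pr_rank, so the top basin has maximal pr_rank
  expect_equal(sel$ordered_basins[1], rows$basin_id[which.max(rows$pr_rank)])
  expect_equal(sel$ordered_basins,
               rows$basin_id[order(-sel$scores[match(rows$basin_id,
                                                     sel$ordered_basins)],
                                   rows$basin_id)])
  # n_phase1 truncates
  expect_length(phase1_select(m, rows, n_phase1 = 4)$ordered_basins, 4)
  # a constant model predicts ties everywhere: ascending basin_id
  mconst <- structure(
    list(constant = 0.5, booster = NULL,
         feature_names = cfg$phase1_features,
         center = rep(0, 3), scale = rep(1, 3), keep = rep(TRUE, 3)),
    class = "basin_regressor")
  expect_equal(phase1_select(mconst, rows, 12)$ordered_basins, rows$basin_id)
})

test_that("the phase-2 pool stacks every training decoy in schema order", {
  t1 <- small_prepared_target("p2a", "easy", seed = 1, size = 60)
  t2 <- small_prepared_target("p2b", "easy", seed = 2, size = 40)
  ph2 <- make_phase2_training_set(list(t1, t2))
  expect_equal(nrow(ph2$X), 100)
  expect_equal(ncol(ph2$X), 20)
  expect_equal(colnames(ph2$X), feature_schema()$names)
  expect_equal(ph2$y, c(t1$ensemble$decoys$rmsd_native,
                        t2$ensemble$decoys$rmsd_native))
  unl <- t1
  unl$ensemble$decoys$rmsd_native <- NULL
  unl$ensemble$native_known <- FALSE
  expect_error(make_phase2_training_set(list(unl)), "rmsd_native")
})

test_that("purification removes decoys predicted beyond the shifted cutoff", {
  coords <- cbind(c(0.5, 1.0, 2.5, 3.0, 8), 0, 0)
  ens <- toy_ensemble(coords, energies = 1:5, rmsd = c(0.5, 1, 2.5, 3, 8))
  basins <- list(list(basin_id = 1L, members = 1:4),
                 list(basin_id = 2L, members = 5L))
  # oracle predictions, tau = 0: keep rmsd <= 2
  pur <- purify_basins(oracle_regressor(), ens, basins, dist_thresh = 2)
  expect_equal(pur$cutoff, 2)
  expect_equal(pur$basins[[1]]$retained_members, 1:2)
  expect_equal(pur$basins[[1]]$retained_fraction, 0.5)
  # tau shifts the cutoff multiplicatively: 2 * 1.2 = 2.4
  pur2 <- purify_basins(oracle_regressor(), ens, basins, dist_thresh = 2,
                        tau = 0.2)
  expect_equal(pur2$cutoff, 2.4)
  expect_equal(pur2$basins[[1]]$retained_members, 1:2)
  # all predictions below cutoff: basin unchanged
  pur3 <- purify_basins(oracle_regressor(), ens, basins, dist_thresh = 10)
  expect_equal(pur3$basins[[1]]$retained_fraction, 1)
  expect_equal(pur3$basins[[1]]$retained_members, 1:4)
  # anti-oracle: constant prediction above every cutoff empties everything
  pur4 <- purify_basins(constant_regressor(99), ens, basins, dist_thresh = 2)
  expect_length(pur4$basins, 0)
})

test_that("purified basins rank by retained fraction with stated ties", {
  ens <- toy_ensemble(cbind(seq(0.5, 4, length.out = 8), 0, 0),
                      energies = 1:8,
                      rmsd = seq(0.5, 4, length.out = 8))
  basins <- list(list(basin_id = 1L, members = 1:4),   # 3/4 kept
                 list(basin_id = 2L, members = 5:6),   # 0/2 kept
                 list(basin_id = 3L, members = 7:8))   # 0/2 kept
  pur <- purify_basins(oracle_regressor(), ens, basins, dist_thresh = 2.1)
  expect_equal(vapply(pur$basins, `[[`, integer(1), "basin_id"), 1L)
  expect_equal(pur$ranked_ids, 1L)   # emptied basins never appear
})

test_that("the two-phase run is seeded, disjoint and subset-consistent", {
  train <- lapply(1:6, function(i)
    small_prepared_target(paste0("tr", i), "easy", seed = 10 + i,
                          size = 250))
  test <- small_prepared_target("te", "easy", seed = 99, size = 250)
  cfg <- mlselect_config(runs = 1, seed = 7, n_phase1 = 5, k_out = 3)
  sel <- run_mlselect(train, test, cfg)
  expect_s3_class(sel, "selection_result")
  expect_equal(sel$strategy, "ML")
  # purified members are a subset of their basin's phase-1 members
  for (b in sel$purified$basins) {
    expect_true(all(b$retained_members %in% b$original_members))
    orig <- test$decomp$basins[[b$basin_id]]$members
    expect_equal(b$original_members, orig)
  }
  # groups are cumulative
  sizes <- lengths(sel$groups)
  expect_true(all(diff(sizes) >= 0))
  # byte-identical reruns under the same seed
  sel2 <- run_mlselect(train, test, cfg)
  expect_identical(sel$groups, sel2$groups)
  expect_identical(sel$purified$basins, sel2$purified$basins)
  # train/test overlap is rejected
  expect_error(run_mlselect(c(train[1:5], list(test)), test, cfg),
               "overlaps the training pool")
  # k_out = 1 emits a single group
  cfg1 <- mlselect_config(runs = 1, seed = 7, n_phase1 = 5, k_out = 1)
  expect_length(run_mlselect(train, test, cfg1)$groups, 1)
  # phase-1-only control skips purification
  ctrl <- run_mlselect(train, test, cfg, purify = FALSE)
  expect_equal(ctrl$strategy, "ML-phase1")
  expect_null(ctrl$purified)
})
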