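#' ML-Select configuration
#'
#' Collects the tunable parameters of the two-phase procedure.
#'
#' @param n_phase1 Basins passed from phase 1 to phase 2 (default 10).
#' @param k_out Purified basins returned (default 3).
#' @param q Per-target count of top pure basins (and of randomly drawn
#'   negatives) in the phase-1 training sample — 2q basins per target
#'   (default 10).
#' @param boosting_rounds Boosting rounds for both regressors (default 15).
#' @param booster `"linear"` (gradient-boosted linear base learners, the
#'   default) or `"tree"`.
#' @param tau Signed fractional shift of the purification cutoff:
#'   `cutoff = dist_thresh * (1 + tau)`; magnitude at most 0.25.
#' @param runs Repeated trainings whose metrics are averaged (default 50).
#' @param seed Base random seed.
#' @param phase1_features Feature columns used by the phase-1 regressor.
#' @param per_basin_refit Refit the phase-2 regressor once per selected
#'   basin instead of once per target (the fits differ only by booster
#'   seed; default `FALSE`).
#' @param eta,lambda,alpha Booster learning rate and L2/L1 penalties.
#' @return Object of class `mlselect_config`.
#' @export
mlselect_config <- function(n_phase1 = 10, k_out = 3, q = 10,
                            boosting_rounds = 15,
                            booster = c("linear", "tree"), tau = 0,
                            runs = 50, seed = 1,
                            phase1_features = c("pr_rank", "pc_rank",
                                                "n_components"),
                            per_basin_refit = FALSE,
                            eta = 0.5, lambda = 1e-4, alpha = 0) {
  booster <- match.arg(booster)
  stopifnot(n_phase1 >= k_out, k_out >= 1, q >= 1, runs >= 1,
            abs(tau) <= 0.25, boosting_rounds >= 1)
  structure(list(n_phase1 = n_phase1, k_out = k_out, q = q,
                 boosting_rounds = boosting_rounds, booster = booster,
                 tau = tau, runs = runs, seed = as.integer(seed),
                 phase1_features = phase1_features,
                 per_basin_refit = per_basin_refit,
                 eta = eta, lambda = lambda, alpha = alpha),
            class = "mlselect_config")
}

# Deterministic 31-bit sub-seed derivation, so that every randomized stage
# draws from its own stream.
derive_seed <- function(seed, salt) {
  x <- (as.numeric(seed) %% 2147483647) * 48271 + as.numeric(salt)
  as.integer(x %% 2147483647)
}

#' Fit a gradient-boosted regressor on standardized features
#'
#' Shared trainer for both phases: features are z-scored with training
#' mean/sd (zero-variance features are dropped), then a squared-error
#' gradient-boosted model with linear (default) or tree base learners is
#' fitted for `boosting_rounds` rounds with a fixed seed, single-threaded,
#' so identical inputs give identical predictions.
#'
#' @param X Numeric feature matrix (rows = cases).
#' @param y Numeric response.
#' @param config An [mlselect_config()].
#' @param seed Booster seed (defaults to `config$seed`).
#' @return Object of class `basin_regressor`.
#' @export
train_gb_regressor <- function(X, y, config = mlselect_config(),
                               seed = config$seed) {
  X <- as.matrix(X)
  if (nrow(X) == 0) stop("empty training set")
  stopifnot(nrow(X) == length(y))
  center <- colMeans(X)
  scale <- apply(X, 2, sd)
  keep <- is.finite(scale) & scale > 1e-12
  if (!any(keep)) {
    # all features constant: model degenerates to the label mean
    return(structure(list(constant = mean(y), feature_names = colnames(X),
                          center = center, scale = scale, keep = keep),
                     class = "basin_regressor"))
  }
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2, center[keep]), 2,
              scale[keep], "/")
  params <- if (config$booster == "linear") {
    # greedy coordinate descent: the cyclic selector converges poorly in
    # 15 rounds when features are strongly collinear (as score-function
    # features are); greedy reaches the least-squares optimum there while
    # still recovering uncorrelated planted maps, and is deterministic
    list(booster = "gblinear", objective = "reg:squarederror",
         nthread = 1, eta = config$eta, lambda = config$lambda,
         alpha = config$alpha, updater = "coord_descent",
         feature_selector = "greedy", seed = seed)
  } else {
    list(booster = "gbtree", objective = "reg:squarederror",
         nthread = 1, eta = config$eta, max_depth = 4,
         lambda = config$lambda, alpha = config$alpha, seed = seed)
  }
  booster <- xgboost::xgb.train(
    params = params,
    data = xgboost::xgb.DMatrix(Xs, label = y, nthread = 1),
    nrounds = config$boosting_rounds, verbose = 0)
  structure(list(booster = booster, feature_names = colnames(X),
                 center = center, scale = scale, keep = keep),
            class = "basin_regressor")
}

#' @export
predict.basin_regressor <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (!is.null(object$feature_names) && !is.null(colnames(X))) {
    if (!all(object$feature_names %in% colnames(X)))
      stop("feature mismatch: model expects ",
           paste(object$feature_names, collapse = ", "))
    X <- X[, object$feature_names, drop = FALSE]
  }
  if (ncol(X) != length(object$center))
    stop("feature mismatch: model expects ", length(object$center),
         " features, got ", ncol(X))
  if (is.null(object$booster)) return(rep(object$constant, nrow(X)))
  Xs <- sweep(sweep(X[, object$keep, drop = FALSE], 2,
                    object$center[object$keep]), 2,
              object$scale[object$keep], "/")
  predict(object$booster, xgboost::xgb.DMatrix(Xs, nthread = 1))
}

#' Oracle and constant quality predictors
#'
#' `oracle_regressor()` predicts each decoy's true `rmsd_native` — the
#' idealized phase-2 limit used to validate the purification logic.
#' `constant_regressor(value)` predicts a fixed value for every decoy.
#'
#' @param value Constant prediction.
#' @return A quality-model object usable wherever a phase-2 regressor is.
#' @export
oracle_regressor <- function() {
  structure(list(), class = c("oracle_regressor", "quality_model"))
}

#' @rdname oracle_regressor
#' @export
constant_regressor <- function(value) {
  structure(list(value = value),
            class = c("constant_regressor", "quality_model"))
}

# Predicted decoy quality (rmsd to native) for member indices of an
# ensemble, dispatching on the model type.
predict_quality <- function(model, ensemble, idx) {
  if (inherits(model, "oracle_regressor")) {
    if (!ensemble$native_known) stop("oracle predictor needs rmsd_native")
    return(ensemble$decoys$rmsd_native[idx])
  }
  if (inherits(model, "constant_regressor"))
    return(rep(model$value, length(idx)))
  predict(model, ensemble_features(ensemble)[idx, , drop = FALSE])
}

#' Assemble the phase-1 training sample
#'
#' For every labelled training target, basins are sorted by true purity
#' (descending; ties by larger size, then basin id) and the top `q` are
#' taken as positives; `q` more basins are drawn uniformly without
#' replacement from the remainder with the seeded generator. Targets with
#' at most `2q` basins contribute all their basins.
#'
#' @param targets List of prepared targets (see [prepare_target()]) or of
#'   lists with elements `ensemble`, `decomposition` and `labels`.
#' @param q Positives per target (default 10).
#' @param seed Sampling seed.
#' @return A labelled [featurize_basins()] row set pooled over targets,
#'   with a `target_id` column.
#' @export
make_phase1_training_set <- function(targets, q = 10, seed = 1) {
  rows_list <- withr::with_seed(derive_seed(seed, 101), {
    lapply(targets, function(tg) {
      rows <- target_rows(tg)
      if (is.null(rows$purity_label))
        stop("unlabeled target: phase-1 training needs purity labels")
      ord <- order(-rows$purity_label, -rows$size, rows$basin_id)
      m <- nrow(rows)
      pick <- if (m <= 2 * q) ord else {
        top <- ord[seq_len(q)]
        rest <- ord[-seq_len(q)]
        c(top, sort(sample(rest, q)))
      }
      out <- rows[pick, , drop = FALSE]
      out$target_id <- target_id_of(tg)
      out
    })
  })
  out <- do.call(rbind, rows_list)
  rownames(out) <- NULL
  out
}

target_rows <- function(tg) {
  if (!is.null(tg$rows)) return(tg$rows)
  featurize_basins(tg$decomposition %||% tg$decomp, tg$ensemble, tg$labels)
}

target_id_of <- function(tg) tg$ensemble$target_id

#' Train the phase-1 basin-purity regressor
#'
#' @param rows Labelled basin feature rows (see
#'   [make_phase1_training_set()]).
#' @param config An [mlselect_config()]; `config$phase1_features` selects
#'   the feature columns.
#' @param seed Booster seed (defaults to `config$seed`).
#' @return A `basin_regressor` predicting basin purity.
#' @export
train_phase1 <- function(rows, config = mlselect_config(),
                         seed = config$seed) {
  if (is.null(rows$purity_label)) stop("rows carry no purity_label")
  X <- as.matrix(rows[, config$phase1_features, drop = FALSE])
  train_gb_regressor(X, rows$purity_label, config,
                     seed = derive_seed(seed, 1))
}

#' Phase-1 selection: top n basins by predicted purity
#'
#' @param model The phase-1 `basin_regressor`.
#' @param rows Basin feature rows of the test target (labels, if present,
#'   are ignored).
#' @param n_phase1 Basins to pass on (default 10).
#' @return A `ranked_selection` (strategy `"ML-phase1"`) of the top
#'   `min(n_phase1, m)` basins, ordered by predicted purity descending,
#'   ties by ascending basin id.
#' @export
phase1_select <- function(model, rows, n_phase1 = 10) {
  preds <- predict(model,
                   as.matrix(rows[, model$feature_names, drop = FALSE]))
  ord <- order(-preds, rows$basin_id)
  keep <- head(ord, n_phase1)
  structure(list(strategy = "ML-phase1",
                 ordered_basins = rows$basin_id[keep],
                 scores = preds[keep]),
            class = "ranked_selection")
}

#' Assemble the phase-2 training sample
#'
#' Pools every decoy of every training target: the 20 schema features as
#' predictors, true `rmsd_native` as response.
#'
#' @param targets List of prepared targets (or of lists with `ensemble`).
#' @return List with matrix `X` (decoys x 20, schema column order), vector
#'   `y` and `feature_names`.
#' @export
make_phase2_training_set <- function(targets) {
  Xs <- lapply(targets, function(tg) {
    ens <- tg$ensemble
    if (!ens$native_known || anyNA(ens$decoys$rmsd_native))
      stop("phase-2 training needs rmsd_native for every decoy (target ",
           ens$target_id, ")")
    ensemble_features(ens)
  })
  ys <- lapply(targets, function(tg) tg$ensemble$decoys$rmsd_native)
  X <- do.call(rbind, Xs)
  list(X = X, y = unlist(ys), feature_names = colnames(X))
}

#' Train the phase-2 per-decoy rmsd regressor
#'
#' @param rows A [make_phase2_training_set()] result.
#' @param config An [mlselect_config()].
#' @param seed Booster seed (defaults to `config$seed`).
#' @return A `basin_regressor` predicting rmsd to the native.
#' @export
train_phase2 <- function(rows, config = mlselect_config(),
                         seed = config$seed) {
  train_gb_regressor(rows$X, rows$y, config, seed = derive_seed(seed, 2))
}

#' Purify selected basins with a per-decoy rmsd predictor
#'
#' Each member of each selected basin gets a predicted rmsd to the native;
#' members whose prediction exceeds `dist_thresh * (1 + tau)` are removed.
#' Basins are then re-ranked by retained fraction (descending; ties by
#' larger retained set, then ascending basin id); emptied basins rank last
#' and are dropped from the output.
#'
#' @param model A phase-2 `basin_regressor` (or [oracle_regressor()] /
#'   [constant_regressor()]).
#' @param ensemble The test [decoy_ensemble()].
#' @param selected List of basins (with `basin_id` and `members`), e.g. the
#'   top-n basins of a `basin_decomposition`.
#' @param dist_thresh Near-native distance threshold of the target (> 0).
#' @param tau Signed fractional shift of the cutoff (default 0).
#' @param k_out Purified basins to return (default 3).
#' @return List (class `purified_selection`) with `basins` — up to `k_out`
#'   purified basins, each carrying `basin_id`, `original_members`,
#'   `retained_members`, `predicted_rmsd`, `retained_fraction` — plus the
#'   `cutoff` used and the ranking over all non-empty inputs.
#' @export
purify_basins <- function(model, ensemble, selected, dist_thresh, tau = 0,
                          k_out = 3) {
  if (!length(selected)) stop("no basins selected")
  stopifnot(dist_thresh > 0)
  cutoff <- dist_thresh * (1 + tau)
  purified <- lapply(selected, function(b) {
    pred <- predict_quality(model, ensemble, b$members)
    keep <- pred <= cutoff
    list(basin_id = b$basin_id,
         original_members = b$members,
         retained_members = b$members[keep],
         predicted_rmsd = pred,
         retained_fraction = mean(keep))
  })
  frac <- vapply(purified, `[[`, numeric(1), "retained_fraction")
  nret <- vapply(purified, function(p) length(p$retained_members),
                 integer(1))
  ids <- vapply(purified, `[[`, integer(1), "basin_id")
  ord <- order(-frac, -nret, ids)
  ord <- ord[nret[ord] > 0]           # emptied basins are dropped
  structure(list(basins = purified[head(ord, k_out)],
                 cutoff = cutoff,
                 ranked_ids = ids[ord]),
            class = "purified_selection")
}

#' Run the full two-phase ML-Select procedure on one test target
#'
#' Phase 1: train the purity regressor on the six labelled training
#' targets, rank the test target's basins by predicted purity, keep the top
#' `n_phase1`. Phase 2: train the per-decoy rmsd regressor on the pooled
#' training decoys, purify the kept basins at the test target's
#' near-native threshold, and return the top `k_out` purified basins with
#' the merged groups B_1, B_1-2, B_1-3.
#'
#' @param train_targets List of 6 labelled prepared targets (2 per
#'   difficulty; see [prepare_target()]), disjoint from the test target.
#' @param test_target A prepared target.
#' @param config An [mlselect_config()].
#' @param dist_thresh Near-native threshold for purification; defaults to
#'   the test target's `meta$dist_thresh`.
#' @param phase2_data Optional precomputed [make_phase2_training_set()]
#'   result (caching across repeated runs).
#' @param purify If `FALSE`, stop after phase 1 and return the unpurified
#'   top `k_out` basins (the phase-1-only control).
#' @return Object of class `selection_result`: strategy, target id, the
#'   phase-1 ranking, the purified basins, and `groups` — a list of decoy
#'   index vectors for the merged top 1..k_out basins (with matching
#'   `group_ids` of decoy ids).
#' @export
run_mlselect <- function(train_targets, test_target,
                         config = mlselect_config(), dist_thresh = NULL,
                         phase2_data = NULL, purify = TRUE) {
  train_ids <- vapply(train_targets, target_id_of, character(1))
  test_id <- target_id_of(test_target)
  if (test_id %in% train_ids)
    stop("test target '", test_id, "' overlaps the training pool")
  dist_thresh <- dist_thresh %||% test_target$meta$dist_thresh
  if (is.null(dist_thresh)) stop("no dist_thresh available for test target")

  rows1 <- make_phase1_training_set(train_targets, q = config$q,
                                    seed = config$seed)
  m1 <- train_phase1(rows1, config)
  sel1 <- phase1_select(m1, test_target$rows, config$n_phase1)
  decomp <- test_target$decomposition %||% test_target$decomp

  if (!purify) {
    groups <- select_groups(sel1$ordered_basins, decomp, config$k_out)
    return(selection_result("ML-phase1", test_id, sel1, NULL, groups,
                            test_target$ensemble, config))
  }

  ph2 <- phase2_data %||% make_phase2_training_set(train_targets)
  m2 <- train_phase2(ph2, config)
  selected <- decomp$basins[sel1$ordered_basins]
  pur <- if (config$per_basin_refit) {
    # literal per-basin reading: one refit per basin, seeds offset
    refits <- lapply(seq_along(selected), function(i) {
      mi <- train_phase2(ph2, config, seed = derive_seed(config$seed, 10 + i))
      purify_basins(mi, test_target$ensemble, selected[i], dist_thresh,
                    config$tau, k_out = 1)$basins
    })
    all_b <- unlist(refits, recursive = FALSE)
    rerank_purified(all_b, config$k_out)
  } else {
    purify_basins(m2, test_target$ensemble, selected, dist_thresh,
                  config$tau, config$k_out)
  }
  members <- setNames(lapply(pur$basins, `[[`, "retained_members"),
                      vapply(pur$basins, function(b)
                        as.character(b$basin_id), character(1)))
  groups <- if (length(pur$basins))
    select_groups(vapply(pur$basins, `[[`, integer(1), "basin_id"),
                  decomp, config$k_out, members = members)
  else list()
  selection_result("ML", test_id, sel1, pur, groups,
                   test_target$ensemble, config)
}

rerank_purified <- function(basins, k_out) {
  frac <- vapply(basins, `[[`, numeric(1), "retained_fraction")
  nret <- vapply(basins, function(p) length(p$retained_members), integer(1))
  ids <- vapply(basins, `[[`, integer(1), "basin_id")
  ord <- order(-frac, -nret, ids)
  ord <- ord[nret[ord] > 0]
  structure(list(basins = basins[head(ord, k_out)], cutoff = NA,
                 ranked_ids = ids[ord]),
            class = "purified_selection")
}

selection_result <- function(strategy, target_id, phase1, purified, groups,
                             ensemble, config = NULL) {
  structure(list(strategy = strategy,
                 target_id = target_id,
                 phase1 = phase1,
                 purified = purified,
                 groups = groups,
                 group_ids = lapply(groups, function(g)
                   ensemble$decoys$decoy_id[g]),
                 config = config),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  sizes <- vapply(x$groups, length, integer(1))
  cat("<selection_result> ", x$strategy, " on ", x$target_id, ": ",
      length(x$groups), " groups",
      if (length(sizes)) paste0(" (sizes ", paste(sizes, collapse = ", "),
                                ")"), "\n", sep = "")
  invisible(x)
}
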