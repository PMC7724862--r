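#' Prepare a target for selection: decompose, label, featurize
#'
#' Runs the landscape stage once for a target — distance matrix,
#' nearest-neighbor graph with escalated cutoff, basin decomposition — and,
#' when the true rmsd column is present, derives the target's metadata
#' ([classify_target()]), near-native labels at the label threshold, and
#' labelled basin feature rows.
#'
#' @param ensemble A [decoy_ensemble()].
#' @param meta Optional precomputed `target_meta`.
#' @param epsilon0,step,k_cap Passed to [build_nn_graph()].
#' @return Object of class `prepared_target`: `ensemble`, `decomp`,
#'   `rows`, `labels`, `meta`, `epsilon`, `n_basins`. The distance matrix
#'   and graph are not retained.
#' @export
prepare_target <- function(ensemble, meta = NULL, epsilon0 = 1.0,
                           step = 0.5, k_cap = NULL) {
  D <- ensemble_dist_matrix(ensemble)
  graph <- build_nn_graph(D, epsilon0 = epsilon0, step = step,
                          k_cap = k_cap)
  decomp <- assign_basins(graph, ensemble$decoys$energy)
  labels <- NULL
  if (ensemble$native_known) {
    rmsd <- ensemble$decoys$rmsd_native
    if (is.null(meta))
      meta <- classify_target(min_dist = min(rmsd), rmsds = rmsd,
                              target_id = ensemble$target_id)
    labels <- rmsd <= meta$dist_thresh
  }
  rows <- featurize_basins(decomp, ensemble, labels, dist_matrix = D)
  structure(list(ensemble = ensemble, decomp = decomp, rows = rows,
                 labels = labels, meta = meta, epsilon = graph$epsilon,
                 n_basins = length(decomp$basins)),
            class = "prepared_target")
}

#' @export
print.prepared_target <- function(x, ...) {
  cat("<prepared_target> ", x$ensemble$target_id, ": ", x$n_basins,
      " basins (epsilon = ", x$epsilon, ")",
      if (!is.null(x$meta)) paste0(", ", x$meta$difficulty,
                                   ", dist_thresh = ", x$meta$dist_thresh),
      "\n", sep = "")
  invisible(x)
}

#' Leave-one-out substitution of the training pool
#'
#' The designated pool holds 2 targets per difficulty. When the test
#' target is itself a pool member, the first same-difficulty non-pool
#' target (by id order) takes its place, so training never overlaps the
#' test target.
#'
#' @param test_target Target id (or a prepared target).
#' @param pool Character vector of 6 pool target ids (2 per difficulty).
#' @param benchmark Data frame with columns `target_id`, `difficulty`, or
#'   a list of targets carrying `meta`.
#' @return Character vector of 6 training target ids excluding the test
#'   target.
#' @export
leave_one_out_pool <- function(test_target, pool, benchmark) {
  test_id <- if (is.character(test_target)) test_target else
    target_id_of(test_target)
  df <- if (is.data.frame(benchmark)) benchmark else
    data.frame(
      target_id = vapply(benchmark, function(t)
        t$meta$target_id %||% target_id_of(t), character(1)),
      difficulty = vapply(benchmark, function(t) t$meta$difficulty,
                          character(1)),
      stringsAsFactors = FALSE)
  stopifnot(length(pool) == 6, all(pool %in% df$target_id))
  pd <- df$difficulty[match(pool, df$target_id)]
  if (!all(table(factor(pd, c("easy", "medium", "hard"))) == 2))
    stop("training pool must hold 2 targets per difficulty")
  if (!test_id %in% pool) return(pool)
  diff <- pd[match(test_id, pool)]
  candidates <- setdiff(
    sort(df$target_id[df$difficulty == diff]), pool)
  if (!length(candidates))
    stop("no same-difficulty substitute available for ", test_id)
  pool[pool == test_id] <- candidates[1]
  pool
}

#' Repeat a seeded run and average its metrics
#'
#' Executes `run_fn(seed)` for seeds `base_seed + 0 ... base_seed +
#' runs - 1`; each call must return a data frame of per-group metrics with
#' columns including `x`, `n`, `p`, `s`. Per-group arithmetic means and
#' the raw per-run values are returned.
#'
#' @param run_fn Function of one argument (the run seed).
#' @param runs Number of repetitions (default 50).
#' @param base_seed First seed.
#' @return List with `mean` (data frame by `x`) and `runs` (list of raw
#'   per-run data frames).
#' @export
repeat_and_average <- function(run_fn, runs = 50, base_seed = 1) {
  stopifnot(runs >= 1)
  raw <- vector("list", runs)
  for (i in seq_len(runs)) {
    res <- tryCatch(run_fn(base_seed + i - 1),
                    error = function(e)
                      stop("run ", i, " failed: ", conditionMessage(e)))
    raw[[i]] <- res
  }
  xs <- sort(unique(unlist(lapply(raw, `[[`, "x"))))
  mean_df <- do.call(rbind, lapply(xs, function(x) {
    rows <- do.call(rbind, lapply(raw, function(df) df[df$x == x, ]))
    data.frame(x = x, n = mean(rows$n), p = mean(rows$p), s = mean(rows$s))
  }))
  list(mean = mean_df, runs = raw)
}

metrics_df <- function(selection, labels, ensemble, x_max = 3) {
  do.call(rbind, lapply(seq_len(x_max), function(x) {
    m <- group_metrics(selection, labels, ensemble, x)
    data.frame(x = x, n = m$n, p = m$p, s = m$s, tp = m$tp,
               group_size = m$group_size)
  }))
}

#' Run the full benchmark protocol over a set of targets
#'
#' For every target: basin decomposition and features, the four baseline
#' rankings, and ML-Select trained on a leave-one-out substituted pool and
#' repeated `config$runs` times with averaged metrics. Hard targets get
#' their evaluation threshold escalated until some strategy captures a
#' near-native. Per-x purity matrices over targets and strategies feed the
#' Friedman/post-hoc comparison.
#'
#' @param targets List of targets: either `(ensemble, meta)` pairs (as
#'   from [generate_benchmark()]) or prepared targets.
#' @param strategies Subset of `c("ML", "S", "S+E", "PR", "PR+PC")`.
#' @param config An [mlselect_config()]; `config$seed` seeds everything.
#' @param pool Training-pool ids; default: the first 2 targets of each
#'   difficulty in id order.
#' @param x_max Largest merged group (default 3).
#' @return Object of class `benchmark_report`: `config`, `targets`
#'   (per-target metadata), `results` (per target x strategy mean metrics
#'   plus per-run ML raws), `purity` (per-x purity matrices) and `stats`
#'   (per-x `stats_result`, when at least 2 strategies and 2 targets).
#' @export
run_benchmark <- function(targets,
                          strategies = c("ML", "S", "S+E", "PR", "PR+PC"),
                          config = mlselect_config(), pool = NULL,
                          x_max = 3) {
  stopifnot(length(strategies) >= 1)
  prep <- lapply(targets, function(t) {
    if (inherits(t, "prepared_target")) t else
      prepare_target(t$ensemble, meta = t$meta)
  })
  ids <- vapply(prep, target_id_of, character(1))
  names(prep) <- ids
  meta_df <- data.frame(
    target_id = ids,
    difficulty = vapply(prep, function(t) t$meta$difficulty, character(1)),
    min_dist = vapply(prep, function(t) t$meta$min_dist, numeric(1)),
    dist_thresh = vapply(prep, function(t) t$meta$dist_thresh, numeric(1)),
    n_basins = vapply(prep, function(t) t$n_basins, integer(1)),
    epsilon = vapply(prep, function(t) t$epsilon, numeric(1)),
    stringsAsFactors = FALSE)
  rownames(meta_df) <- NULL
  if (is.null(pool) && "ML" %in% strategies) {
    pool <- unlist(lapply(c("easy", "medium", "hard"), function(d)
      head(meta_df$target_id[meta_df$difficulty == d], 2)))
    if (length(pool) != 6)
      stop("cannot build a 2+2+2 training pool from these targets")
  }
  baselines <- intersect(strategies, c("S", "S+E", "PR", "PR+PC"))
  phase2_cache <- new.env(parent = emptyenv())

  results <- vector("list", length(prep))
  names(results) <- ids
  for (ti in seq_along(prep)) {
    tg <- prep[[ti]]
    ens <- tg$ensemble
    base_sel <- lapply(baselines, function(st) {
      rk <- rank_basins(st, tg$rows)
      groups <- select_groups(rk$ordered_basins, tg$decomp, x_max)
      selection_result(st, ids[ti], rk, NULL, groups, ens)
    })
    names(base_sel) <- baselines

    ml <- NULL
    if ("ML" %in% strategies) {
      pool_i <- leave_one_out_pool(ids[ti], pool, meta_df)
      train <- prep[pool_i]
      key <- paste(sort(pool_i), collapse = "|")
      if (is.null(phase2_cache[[key]]))
        phase2_cache[[key]] <- make_phase2_training_set(train)
      ph2 <- phase2_cache[[key]]
      run_one <- function(seed) {
        cfg <- config
        cfg$seed <- as.integer(seed %% 2147483647)
        run_mlselect(train, tg, cfg, phase2_data = ph2)
      }
      ml_first <- run_one(config$seed)
      ml <- list(pool = pool_i, first = ml_first)
    }

    # evaluation threshold: hard targets escalate until some strategy's
    # merged groups capture a near-native
    t_eval <- tg$meta$dist_thresh
    if (tg$meta$difficulty == "hard") {
      sels <- lapply(base_sel, function(s) s$groups)
      if (!is.null(ml)) sels <- c(sels, list(ml$first$groups))
      t_eval <- escalate_threshold(ens, sels, start = tg$meta$hard_start)
    }
    labels_eval <- ens$decoys$rmsd_native <= t_eval

    res_t <- list(dist_thresh = t_eval)
    for (st in baselines)
      res_t[[st]] <- list(
        mean = metrics_df(base_sel[[st]], labels_eval, ens, x_max))
    if (!is.null(ml)) {
      # baselines are deterministic; only the ML strategy is repeated
      avg <- repeat_and_average(function(seed) {
        cfg <- config
        cfg$seed <- as.integer(seed %% 2147483647)
        sel <- run_mlselect(train, tg, cfg, phase2_data = ph2)
        metrics_df(sel, labels_eval, ens, x_max)
      }, runs = config$runs, base_seed = config$seed)
      res_t[["ML"]] <- c(avg, list(pool = pool_i))
    }
    results[[ti]] <- res_t
  }

  purity <- lapply(seq_len(x_max), function(x) {
    P <- sapply(strategies, function(st) vapply(results, function(r)
      r[[st]]$mean$p[r[[st]]$mean$x == x], numeric(1)))
    P <- matrix(P, nrow = length(results),
                dimnames = list(ids, strategies))
    P
  })
  names(purity) <- paste0("B1_", seq_len(x_max))

  stats <- NULL
  if (length(strategies) >= 2 && length(prep) >= 2) {
    stats <- lapply(purity, friedman_hommel)
  } else if (length(strategies) < 2) {
    warning("fewer than 2 strategies: statistical comparison skipped")
  }

  structure(list(config = unclass(config),
                 pool = pool,
                 targets = meta_df,
                 results = results,
                 purity = lapply(purity, function(P)
                   as.data.frame(P, stringsAsFactors = FALSE)),
                 stats = stats),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("<benchmark_report> ", nrow(x$targets), " targets, strategies: ",
      paste(colnames(x$purity[[1]]), collapse = ", "), "\n", sep = "")
  cat("mean B1 purity per strategy:\n")
  print(round(colMeans(as.matrix(x$purity[[1]])), 3))
  if (!is.null(x$stats)) {
    cat("B1 average ranks:\n")
    print(round(x$stats[[1]]$average_rank, 3))
  }
  invisible(x)
}
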