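#' Classify a target's difficulty and near-native threshold
#'
#' Difficulty follows the minimum decoy-to-native distance: easy if
#' `min_dist < 1` (threshold 2 Å), medium if `1 <= min_dist < 2`
#' (threshold 3 Å by default, 2.5 Å by override), hard otherwise (the
#' threshold starts at `hard_start` and is escalated per-method by
#' [escalate_threshold()]). A target with fewer than `scarcity_min`
#' near-natives at its category threshold is demoted one difficulty level
#' and re-thresholded.
#'
#' @param min_dist Minimum rmsd-to-native over the ensemble (>= 0).
#' @param n_near_native Near-native count at the initial category
#'   threshold; ignored when `rmsds` is given.
#' @param scarcity_min Demotion cutoff (default 10).
#' @param rmsds Optional vector of all per-decoy rmsd values; enables
#'   recounting after demotion.
#' @param medium_thresh Medium-category threshold, 2.5 or 3 (default 3).
#' @param hard_start Starting threshold for hard targets (default 3).
#' @param target_id Optional id recorded on the result.
#' @return Object of class `target_meta` with `target_id`, `min_dist`,
#'   `difficulty`, `dist_thresh`, `n_near_native` and `hard_start`.
#' @export
classify_target <- function(min_dist, n_near_native = NULL,
                            scarcity_min = 10, rmsds = NULL,
                            medium_thresh = 3.0, hard_start = 3.0,
                            target_id = NULL) {
  if (min_dist < 0) stop("min_dist must be >= 0")
  if (!is.null(rmsds)) min_dist <- min(rmsds)
  category <- if (min_dist < 1) "easy" else if (min_dist < 2) "medium" else
    "hard"
  thresh_of <- function(cat) switch(cat, easy = 2.0, medium = medium_thresh,
                                    hard = hard_label_threshold(min_dist,
                                                                hard_start))
  thresh <- thresh_of(category)
  count <- if (!is.null(rmsds)) sum(rmsds <= thresh) else n_near_native
  while (category != "hard" && !is.null(count) && count < scarcity_min) {
    category <- if (category == "easy") "medium" else "hard"
    thresh <- thresh_of(category)
    count <- if (!is.null(rmsds)) sum(rmsds <= thresh) else NULL
  }
  structure(list(target_id = target_id, min_dist = min_dist,
                 difficulty = category, dist_thresh = thresh,
                 n_near_native = count, hard_start = hard_start),
            class = "target_meta")
}

# Smallest ladder value start, start+step, ... that admits at least one
# near-native (i.e. >= min_dist), capped at min_dist + 2.
hard_label_threshold <- function(min_dist, start = 3.0, step = 0.5) {
  t <- if (min_dist <= start) start else
    start + step * ceiling((min_dist - start) / step)
  min(t, min_dist + 2.0)
}

#' Escalate a hard target's threshold until some method captures a hit
#'
#' Walks the ladder `start, start + step, ...` and returns the smallest
#' threshold at which at least one strategy's selected groups contain a
#' decoy at or below it; capped at `min_dist + 2` (the cap is returned if
#' no selection ever captures a near-native).
#'
#' @param ensemble The [decoy_ensemble()] (needs `rmsd_native`).
#' @param selections List with one element per strategy: either an integer
#'   vector of selected decoy indices or a list of such group vectors.
#' @param start Ladder start (the hard-category base threshold).
#' @param step Ladder increment (default 0.5).
#' @return The escalated `dist_thresh`.
#' @export
escalate_threshold <- function(ensemble, selections, start, step = 0.5) {
  if (!ensemble$native_known) stop("escalation needs rmsd_native")
  rmsd <- ensemble$decoys$rmsd_native
  cap <- min(rmsd) + 2.0
  best <- suppressWarnings(min(vapply(selections, function(s) {
    idx <- unique(unlist(s))
    if (!length(idx)) Inf else min(rmsd[idx])
  }, numeric(1))))
  if (best <= start) return(min(start, cap))
  t <- start + step * ceiling((best - start) / step)
  if (t > cap) cap else t
}

#' Evaluation metrics of a merged top-x group
#'
#' For the merged group of the top `x` selected basins: `n` — captured
#' fraction of all true near-natives (recall-like), `p` — purity, the
#' near-native fraction of the group (precision-like), `s` — group size
#' relative to the ensemble, and the true-positive count `tp`.
#'
#' @param selection A `selection_result` (or any list with a `groups`
#'   element of cumulative decoy index vectors).
#' @param labels Logical near-native flags, one per decoy.
#' @param ensemble The [decoy_ensemble()].
#' @param x Group index, 1..3.
#' @return List with `x`, `n`, `p`, `s`, `tp`, `group_size`, `truncated`.
#' @export
group_metrics <- function(selection, labels, ensemble, x) {
  stopifnot(x >= 1, length(labels) == ensemble$size)
  groups <- selection$groups
  truncated <- x > length(groups)
  group <- if (length(groups) == 0) integer(0) else
    groups[[min(x, length(groups))]]
  tp <- sum(labels[group])
  total <- sum(labels)
  list(x = x,
       n = if (total > 0) tp / total else NA_real_,
       p = if (length(group)) tp / length(group) else 0,
       s = length(group) / ensemble$size,
       tp = tp,
       group_size = length(group),
       truncated = truncated)
}

#' Friedman rank test with a step-down post-hoc ladder
#'
#' Ranks the methods within every dataset (rank 1 = highest purity,
#' mid-ranks on ties), computes the Friedman chi-square statistic
#' `12N/(k(k+1)) * sum_j (Rbar_j - (k+1)/2)^2` with `k - 1` degrees of
#' freedom (the Iman–Davenport F transform is reported alongside), and
#' compares every method against the best-ranked control:
#' `z = (Rbar_i - Rbar_control) / sqrt(k(k+1)/(6N))` with two-sided normal
#' p-values, judged against the step-down critical ladder
#' `alpha/m, alpha/(m-1), ..., alpha` over the `m = k - 1` comparisons
#' ordered by significance. `posthoc = "hommel"` additionally applies the
#' full Hommel step-up adjustment via [stats::p.adjust()].
#'
#' @param purity_matrix Numeric matrix, datasets x methods (column names =
#'   method names).
#' @param alpha Significance level (default 0.05).
#' @param posthoc `"ladder"` (default) or `"hommel"`.
#' @return Object of class `stats_result`: `average_rank`,
#'   `friedman_statistic`, `friedman_p`, `iman_davenport_F`,
#'   `iman_davenport_p`, `control`, `comparisons` (data frame with method,
#'   z, p, critical level, significance, ordered by p), `alpha`, `N`, `k`.
#' @export
friedman_hommel <- function(purity_matrix, alpha = 0.05,
                            posthoc = c("ladder", "hommel")) {
  posthoc <- match.arg(posthoc)
  P <- as.matrix(purity_matrix)
  if (anyNA(P)) stop("purity matrix has missing cells")
  N <- nrow(P); k <- ncol(P)
  if (N < 2 || k < 2) stop("need at least 2 datasets and 2 methods")
  methods <- colnames(P) %||% paste0("method", seq_len(k))
  ranks <- t(apply(P, 1, function(r) rank(-r, ties.method = "average")))
  rbar <- colMeans(ranks)
  names(rbar) <- methods
  chi2 <- 12 * N / (k * (k + 1)) * sum((rbar - (k + 1) / 2)^2)
  p_chi <- pchisq(chi2, df = k - 1, lower.tail = FALSE)
  denom <- N * (k - 1) - chi2
  ff <- if (denom <= 0) Inf else (N - 1) * chi2 / denom
  p_ff <- if (is.infinite(ff)) 0 else
    pf(ff, k - 1, (N - 1) * (k - 1), lower.tail = FALSE)
  ctrl <- which.min(rbar)
  se <- sqrt(k * (k + 1) / (6 * N))
  others <- setdiff(seq_len(k), ctrl)
  z <- (rbar[others] - rbar[ctrl]) / se
  p_un <- 2 * pnorm(-abs(z))
  ord <- order(p_un, methods[others])
  m <- length(others)
  comparisons <- data.frame(
    method = methods[others][ord],
    z = unname(z[ord]),
    p = unname(p_un[ord]),
    critical = alpha / (m - seq_len(m) + 1),
    stringsAsFactors = FALSE)
  if (posthoc == "hommel") {
    adj <- stats::p.adjust(p_un, method = "hommel")
    comparisons$p_hommel <- unname(adj[ord])
    comparisons$significant <- comparisons$p_hommel < alpha
  } else {
    comparisons$significant <- comparisons$p < comparisons$critical
  }
  structure(list(average_rank = rbar,
                 friedman_statistic = chi2,
                 friedman_p = p_chi,
                 iman_davenport_F = ff,
                 iman_davenport_p = p_ff,
                 control = methods[ctrl],
                 comparisons = comparisons,
                 alpha = alpha, N = N, k = k),
            class = "stats_result")
}

#' @export
print.stats_result <- function(x, ...) {
  cat("<stats_result> Friedman chi-square = ",
      format(x$friedman_statistic, digits = 4), " (df = ", x$k - 1,
      "), p = ", format(x$friedman_p, digits = 4), "\n", sep = "")
  cat("average ranks (1 = best):\n")
  print(round(x$average_rank, 3))
  cat("control:", x$control, "\n")
  print(x$comparisons, digits = 4)
  invisible(x)
}
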