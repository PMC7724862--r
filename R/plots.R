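#' Funnel scatter plot of an ensemble and its selected groups
#'
#' Plots decoys by rmsd to the native (x) and energy (y), coloring the
#' members of up to three selected basin groups — the standard visual
#' check of what a selection strategy captured.
#'
#' @param ensemble A [decoy_ensemble()] with `rmsd_native`.
#' @param selection Optional `selection_result`; its cumulative groups are
#'   decomposed into disjoint top-1/2/3 layers for coloring.
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_decoy_selection <- function(ensemble, selection = NULL, title = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_decoy_selection requires ggplot2")
  if (!ensemble$native_known) stop("plot needs rmsd_native")
  df <- data.frame(rmsd = ensemble$decoys$rmsd_native,
                   energy = ensemble$decoys$energy,
                   group = "unselected", stringsAsFactors = FALSE)
  if (!is.null(selection) && length(selection$groups)) {
    prev <- integer(0)
    for (i in seq_along(selection$groups)) {
      layer <- setdiff(selection$groups[[i]], prev)
      df$group[layer] <- paste0("basin ", i)
      prev <- selection$groups[[i]]
    }
  }
  df$group <- factor(df$group,
                     c("unselected", paste0("basin ",
                                            seq_along(selection$groups))))
  ggplot2::ggplot(df, ggplot2::aes(x = rmsd, y = energy, color = group)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::scale_color_manual(
      values = c("grey70", "#8B1A1A", "#DAA520", "#000080")[
        seq_len(nlevels(df$group))]) +
    ggplot2::labs(x = "lRMSD to native (Å)", y = "energy",
                  title = title %||% ensemble$target_id) +
    ggplot2::theme_minimal()
}
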