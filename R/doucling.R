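#' Doublet Cluster Labeling (DouCLing)
#'
#' Flags subclusters that look like doublet artefacts between two parental
#' large clusters. For each subcluster:
#' \enumerate{
#'   \item relative marker genes are computed against its sibling
#'     subclusters within the same parental cluster ([rank_markers()] with
#'     scope restricted to the siblings);
#'   \item every cell in the atlas is scored with that marker signature
#'     ([score_gene_set()], or a plain mean of the marker genes when
#'     `score_method = "plain_mean"`);
#'   \item the top set is every atlas cell whose score is strictly above the
#'     mean score of the focal subcluster's own cells;
#'   \item the top set's composition by parental cluster is computed (the
#'     focal subcluster's own cells stay in the denominator);
#'   \item the subcluster is flagged as doublet-like when the largest
#'     fraction attributed to a parental cluster other than the focal parent
#'     strictly exceeds `flag_fraction` (default 0.60). With
#'     `union_other = TRUE` the combined fraction of all other parents is
#'     used instead (a stricter sensitivity-analysis variant).
#' }
#' A pure subcluster's markers pull its own parent's cells to the top, so
#' another parent never dominates; a doublet subcluster's relative markers
#' are the partner parent's program, whose cells then dominate the top set.
#'
#' Subclusters whose parent has no siblings, or whose relative marker set is
#' empty, are reported as unevaluable and never flagged. Flagged subclusters
#' are reported, not removed; see [apply_doublet_report()].
#'
#' @param x An [atlas()] with `norm` set.
#' @param parent Per-cell parental large-cluster labels (default
#'   `x$cells$parent_cluster`).
#' @param sub Per-cell subcluster labels (default `x$cells$subcluster`).
#' @param flag_fraction Strict flagging threshold on the other-parent
#'   fraction (default 0.60).
#' @param min_subcluster_size Subclusters below this size are not evaluated
#'   (default 10).
#' @param union_other Use the union of all other parents instead of the
#'   single largest (default FALSE).
#' @param score_method `"control_bin"` (default) or `"plain_mean"`.
#' @param n_bins,ctrl_size,seed Passed to [score_gene_set()].
#' @param ... Passed to [rank_markers()] (marker filters, `top_n`, ...).
#' @return data.frame (`doublet_report`), one row per subcluster: parent,
#'   subcluster, evaluation status, number of marker genes, mean score of
#'   the focal subcluster, top-set size, dominant other parent and its
#'   fraction, and the flag. The per-subcluster top-set composition is in
#'   `attr(, "composition")`.
#' @export
doucling_flag <- function(x, parent = x$cells$parent_cluster,
                          sub = x$cells$subcluster,
                          flag_fraction = 0.60, min_subcluster_size = 10,
                          union_other = FALSE,
                          score_method = c("control_bin", "plain_mean"),
                          n_bins = 25, ctrl_size = 50, seed = 0L, ...) {
  norm <- get_layer(x, "norm")
  score_method <- match.arg(score_method)
  if (is.null(parent) || is.null(sub))
    config_error("two-level labels (parent, sub) are required")
  if (flag_fraction <= 0 || flag_fraction >= 1)
    config_error("'flag_fraction' must be in (0, 1)")
  parent <- as.character(parent); sub <- as.character(sub)

  rows <- list(); comps <- list()
  for (p in unique(parent)) {
    subs <- unique(sub[parent == p])
    single <- length(subs) < 2L
    mk <- if (!single)
      rank_markers(x, labels = sub, scope = subs, ...)
    else NULL
    for (s in subs) {
      cells_s <- which(sub == s)
      row <- data.frame(parent_cluster = p, subcluster = s,
                        n_cells = length(cells_s), status = "evaluated",
                        n_markers = 0L, mean_score_subcluster = NA_real_,
                        top_set_size = NA_integer_,
                        dominant_other = NA_character_,
                        dominant_other_fraction = NA_real_, flagged = FALSE,
                        stringsAsFactors = FALSE)
      if (single) {
        row$status <- "unevaluable_single_subcluster"
      } else if (length(cells_s) < min_subcluster_size) {
        row$status <- "skipped_too_small"
      } else {
        genes <- mk$gene[mk$cluster == s]
        row$n_markers <- length(genes)
        if (!length(genes)) {
          row$status <- "unevaluable_no_markers"
        } else {
          scores <- if (score_method == "control_bin")
            score_gene_set(x, genes, n_bins = n_bins, ctrl_size = ctrl_size,
                           seed = seed)$scores
          else {
            v <- Matrix::rowSums(norm[, genes, drop = FALSE]) / length(genes)
            setNames(as.numeric(v), rownames(norm))
          }
          thr <- mean(scores[cells_s])
          top <- scores > thr
          row$mean_score_subcluster <- thr
          row$top_set_size <- sum(top)
          comp <- if (any(top))
            table(parent[top]) / sum(top)
          else table(character(0))
          comps[[s]] <- as.list(as.numeric(comp)) |> setNames(names(comp))
          other <- comp[names(comp) != p]
          if (length(other)) {
            if (union_other) {
              row$dominant_other <- paste(names(other), collapse = "+")
              row$dominant_other_fraction <- sum(other)
            } else {
              k <- which.max(other)
              row$dominant_other <- names(other)[k]
              row$dominant_other_fraction <- as.numeric(other[k])
            }
            row$flagged <- row$dominant_other_fraction > flag_fraction
          } else {
            row$dominant_other_fraction <- 0
          }
        }
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  attr(res, "composition") <- comps
  attr(res, "params") <- list(flag_fraction = flag_fraction,
                              min_subcluster_size = min_subcluster_size,
                              union_other = union_other,
                              score_method = score_method, seed = seed)
  class(res) <- c("doublet_report", "data.frame")
  res
}

#' Remove cells of flagged doublet subclusters
#'
#' Companion to [doucling_flag()]: dropping flagged subclusters is a
#' deliberate separate step (curation happens between flagging and removal).
#'
#' @param x An [atlas()].
#' @param report A `doublet_report`.
#' @param sub Per-cell subcluster labels (default `x$cells$subcluster`).
#' @return The atlas without cells belonging to flagged subclusters.
#' @export
apply_doublet_report <- function(x, report, sub = x$cells$subcluster) {
  bad <- report$subcluster[report$flagged]
  x[!(as.character(sub) %in% bad), ]
}

#' Write a doublet report as TSV
#' @param report A `doublet_report`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_doublet_report <- function(report, path) {
  write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
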