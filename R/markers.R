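#' Benjamini-Hochberg adjustment
#'
#' Thin validated wrapper over the standard step-up procedure: adjusted
#' values are monotone, capped at 1, and returned in input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
    stop("bh_adjust: p-values must be in [0, 1]", call. = FALSE)
  p.adjust(p, method = "BH")
}

# rank-sum z statistics for every scoped cluster at once: ranks over the
# scoped cells are shared across one-vs-rest comparisons, so compute them
# (and the tie-correction term) once per gene
ranksum_stats <- function(Y) {
  N <- nrow(Y)
  ranks <- matrix(0, N, ncol(Y), dimnames = dimnames(Y))
  ties <- numeric(ncol(Y))
  for (g in seq_len(ncol(Y))) {
    ranks[, g] <- rank(Y[, g])
    t <- tabulate(match(Y[, g], unique(Y[, g])))
    ties[g] <- sum(t^3 - t)
  }
  list(ranks = ranks, ties = ties, N = N)
}

#' One-vs-rest marker ranking with out-group and fold-change filters
#'
#' For each cluster in `scope`, every gene is tested with a two-sided
#' Wilcoxon rank-sum test (normal approximation with tie correction) of
#' log-normalized expression between the cluster's cells and the remaining
#' scoped cells. The fold change is computed on the de-logged CP10K scale,
#' `(mean(expm1(Y_in)) + eps) / (mean(expm1(Y_out)) + eps)`, and reported as
#' log2; the out-group fraction is the share of out-group cells with a
#' nonzero raw count. P-values are BH-adjusted per cluster across all genes,
#' then genes failing either filter (out-group fraction above
#' `max_out_group_fraction`, fold change below `min_fold_change`) are
#' removed, and survivors are ranked by the test statistic, keeping `top_n`.
#'
#' Setting `scope` to the subclusters of one parental cluster yields
#' "relative" markers against siblings only, the mode used by the
#' doublet-cluster detector; the default scope is all clusters (atlas-wide
#' markers).
#'
#' @param x An [atlas()] with `norm` set.
#' @param labels Per-cell cluster labels (character vector, one per cell).
#' @param scope Optional subset of cluster labels defining both the clusters
#'   tested and the background universe (default: all clusters).
#' @param max_out_group_fraction Keep genes expressed in at most this
#'   fraction of out-group cells (default 0.25).
#' @param min_fold_change Keep genes with at least this fold change on the
#'   CP10K scale (default 2).
#' @param top_n Markers kept per cluster after filtering (default 50).
#' @param fc_epsilon Pseudocount on the de-logged means (default 1e-9).
#' @param min_cluster_size Clusters below this size are skipped with a
#'   warning (default 3).
#' @return data.frame (`marker_table`) with columns `cluster`, `gene`,
#'   `statistic` (z), `log2_fold_change`, `out_group_fraction`, `p_raw`,
#'   `p_adj`, `rank`.
#' @export
rank_markers <- function(x, labels, scope = NULL,
                         max_out_group_fraction = 0.25, min_fold_change = 2,
                         top_n = 50, fc_epsilon = 1e-9, min_cluster_size = 3) {
  norm <- get_layer(x, "norm")
  if (length(labels) != nrow(norm))
    config_error("'labels' must have one entry per cell")
  labels <- as.character(labels)
  if (is.null(scope)) scope <- sort(unique(labels))
  scope <- unique(scope)
  if (length(scope) < 2L)
    stop("rank_markers: scope must contain at least two clusters", call. = FALSE)
  in_scope <- labels %in% scope
  lab <- labels[in_scope]
  Y <- as.matrix(norm[in_scope, , drop = FALSE])
  raw <- x$counts[in_scope, , drop = FALSE]

  rs <- ranksum_stats(Y)
  N <- rs$N
  # de-logged CP10K values for fold changes
  E <- expm1(Y)

  out <- list()
  for (cl in scope) {
    idx <- lab == cl
    n1 <- sum(idx); n2 <- N - n1
    if (n1 < min_cluster_size) {
      warning(sprintf("cluster '%s' has %d cells (< %d); skipped", cl, n1,
                      min_cluster_size))
      next
    }
    R1 <- colSums(rs$ranks[idx, , drop = FALSE])
    sig2 <- (n1 * n2 / 12) * ((N + 1) - rs$ties / (N * (N - 1)))
    z <- ifelse(sig2 > 0, (R1 - n1 * (N + 1) / 2) / sqrt(sig2), 0)
    p_raw <- 2 * pnorm(-abs(z))
    p_adj <- bh_adjust(p_raw)
    mean_in <- colSums(E[idx, , drop = FALSE]) / n1
    mean_out <- colSums(E[!idx, , drop = FALSE]) / n2
    fc <- (mean_in + fc_epsilon) / (mean_out + fc_epsilon)
    out_frac <- Matrix::colSums(raw[!idx, , drop = FALSE] > 0) / n2
    keep <- which(out_frac <= max_out_group_fraction & fc >= min_fold_change)
    keep <- keep[order(-z[keep], keep)]
    keep <- head(keep, top_n)
    if (!length(keep)) next
    out[[cl]] <- data.frame(
      cluster = cl, gene = colnames(Y)[keep], statistic = z[keep],
      log2_fold_change = log2(fc[keep]), out_group_fraction = out_frac[keep],
      p_raw = p_raw[keep], p_adj = p_adj[keep], rank = seq_along(keep),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(cluster = character(0), gene = character(0),
               statistic = numeric(0), log2_fold_change = numeric(0),
               out_group_fraction = numeric(0), p_raw = numeric(0),
               p_adj = numeric(0), rank = integer(0))
  rownames(res) <- NULL
  attr(res, "test") <- "wilcoxon-ranksum-normal-approx"
  class(res) <- c("marker_table", "data.frame")
  res
}

#' Write a marker table as TSV
#'
#' @param markers A `marker_table` from [rank_markers()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_markers <- function(markers, path) {
  write.table(markers, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
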