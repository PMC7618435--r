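#' Quality-control filtering with boundary-exact thresholds
#'
#' Applies three filters in a fixed, documented order:
#' \enumerate{
#'   \item genes detected in no more than `min_cells_per_gene` cells removed;
#'   \item cells expressing no more than `min_genes_per_cell` of the
#'     remaining genes removed;
#'   \item cells with a mitochondrial read fraction strictly above
#'     `max_mito_fraction` removed (mitochondrial genes identified by symbol
#'     prefix, computed on the remaining genes).
#' }
#' All thresholds are exclusive: a cell detecting exactly
#' `min_genes_per_cell` genes is removed, one detecting one more is kept; a
#' cell at exactly `max_mito_fraction` is kept. The pass is applied once, not
#' iterated to a fixpoint.
#'
#' @param x An [atlas()] with raw counts.
#' @param min_genes_per_cell Cells must detect strictly more genes (default 200).
#' @param min_cells_per_gene Genes must be detected in strictly more cells
#'   (default 5).
#' @param max_mito_fraction Maximum tolerated mitochondrial fraction,
#'   exclusive (default 0.20).
#' @param mito_prefix Gene-symbol prefix marking mitochondrial genes
#'   (default `"MT-"`).
#' @return list with `atlas` (filtered) and `report` (counts removed per rule
#'   and in/out dimensions).
#' @export
qc_filter <- function(x, min_genes_per_cell = 200, min_cells_per_gene = 5,
                      max_mito_fraction = 0.20, mito_prefix = "MT-") {
  stopifnot_scalar_number(min_genes_per_cell, "min_genes_per_cell", min = 0)
  stopifnot_scalar_number(min_cells_per_gene, "min_cells_per_gene", min = 0)
  stopifnot_scalar_number(max_mito_fraction, "max_mito_fraction", min = 0)
  if (max_mito_fraction > 1) config_error("'max_mito_fraction' must be in [0, 1]")
  m <- x$counts
  n_in <- dim(m)

  cells_per_gene <- Matrix::colSums(m > 0)
  keep_genes <- cells_per_gene > min_cells_per_gene
  x <- x[, keep_genes]

  genes_per_cell <- Matrix::rowSums(x$counts > 0)
  keep_cells <- genes_per_cell > min_genes_per_cell
  n_low_genes <- sum(!keep_cells)
  x <- x[keep_cells, ]

  mito <- startsWith(colnames(x$counts), mito_prefix)
  totals <- Matrix::rowSums(x$counts)
  mito_frac <- if (any(mito))
    Matrix::rowSums(x$counts[, mito, drop = FALSE]) / pmax(totals, 1)
  else rep(0, nrow(x$counts))
  keep_mito <- mito_frac <= max_mito_fraction
  n_mito <- sum(!keep_mito)
  x <- x[keep_mito, ]

  if (nrow(x$counts) == 0L)
    stop("qc_filter: all cells removed", call. = FALSE)
  report <- list(
    genes_in = n_in[2], genes_removed = sum(!keep_genes),
    cells_in = n_in[1], cells_removed_low_genes = n_low_genes,
    cells_removed_mito = n_mito,
    cells_out = nrow(x$counts), genes_out = ncol(x$counts))
  list(atlas = x, report = report)
}

#' Log CP10K normalization
#'
#' Sets the `norm` layer to `Y_ij = ln(x_ij * 10000 / sum_i x_ij + 1)`:
#' each cell's counts are divided by its total, multiplied by 10,000
#' (counts per ten thousand) and log1p-transformed. The raw layer is left
#' untouched; re-running overwrites the layer with identical values. A
#' consequence of the formula is that `sum_i (exp(Y_ij) - 1) = 10000` exactly
#' for every cell.
#'
#' @param x An [atlas()] with raw counts and no all-zero cells.
#' @param scale_factor Post-normalization multiplier (default 10000).
#' @return The atlas with the `norm` layer set (sparse; zeros stay zeros).
#' @export
normalize_cp10k <- function(x, scale_factor = 1e4) {
  m <- get_layer(x, "counts")
  totals <- Matrix::rowSums(m)
  if (any(totals == 0))
    stop(sprintf("normalize_cp10k: all-zero cell(s): %s",
                 paste(head(rownames(m)[totals == 0], 5), collapse = ", ")),
         call. = FALSE)
  norm <- m
  norm@x <- log1p(m@x * scale_factor / totals[m@i + 1L])
  x$norm <- norm
  x
}

# per-gene mean and (n-1) variance of a sparse cells x genes block
sparse_col_stats <- function(m) {
  n <- nrow(m)
  mu <- Matrix::colSums(m) / n
  ssq <- Matrix::colSums(m^2)
  v <- if (n > 1) (ssq - n * mu^2) / (n - 1) else rep(0, ncol(m))
  list(mean = mu, var = pmax(v, 0))
}

#' Per-sample highly variable genes by dispersion
#'
#' For each sample, genes are ranked by the dispersion of their
#' log-normalized expression — sample variance (n - 1 denominator) divided
#' by mean — over that sample's cells; genes with zero mean are excluded and
#' the `top_n` highest-dispersion genes are returned. Ties are broken by
#' gene order in the matrix. Samples with fewer than three cells are skipped
#' with a warning.
#'
#' @param x An [atlas()] with the `norm` layer set.
#' @param samples Per-cell sample labels (defaults to `x$cells$sample`).
#' @param top_n Number of genes per sample (default 2000).
#' @return Named list mapping sample to a character vector of gene names.
#' @export
select_hvgs_per_sample <- function(x, samples = x$cells$sample, top_n = 2000) {
  norm <- get_layer(x, "norm")
  if (is.null(samples)) config_error("per-cell sample labels are required")
  out <- list()
  for (smp in unique(samples)) {
    idx <- which(samples == smp)
    if (length(idx) < 3L) {
      warning(sprintf("sample '%s' has %d cells (< 3); skipped", smp, length(idx)))
      next
    }
    st <- sparse_col_stats(norm[idx, , drop = FALSE])
    disp <- ifelse(st$mean > 0, st$var / st$mean, -Inf)
    ok <- which(is.finite(disp))
    ord <- ok[order(-disp[ok], ok)]
    out[[smp]] <- colnames(norm)[head(ord, top_n)]
  }
  out
}

#' Correlated-gene filter within each sample
#'
#' Keeps, per sample, the highly variable genes whose expression is
#' substantially correlated with at least one other highly variable gene of
#' the same sample (maximum absolute Pearson correlation above `threshold`).
#' This retains genes that participate in co-expression structure —
#' candidate programs — and drops isolated noisy genes.
#'
#' @param x An [atlas()] with the `norm` layer.
#' @param hvgs Named list of per-sample gene vectors, as from
#'   [select_hvgs_per_sample()].
#' @param samples Per-cell sample labels (defaults to `x$cells$sample`).
#' @param threshold Absolute-correlation cutoff, strict (default 0.2).
#' @return Named list mapping sample to the retained gene vector.
#' @export
select_correlated_genes <- function(x, hvgs, samples = x$cells$sample,
                                    threshold = 0.2) {
  norm <- get_layer(x, "norm")
  out <- list()
  for (smp in names(hvgs)) {
    genes <- hvgs[[smp]]
    if (length(genes) < 2L) { out[[smp]] <- character(0); next }
    Y <- as.matrix(norm[samples == smp, genes, drop = FALSE])
    cc <- suppressWarnings(stats::cor(Y))
    diag(cc) <- 0
    cc[is.na(cc)] <- 0
    out[[smp]] <- genes[apply(abs(cc), 1, max) > threshold]
  }
  out
}

#' Merge per-sample gene sets into the final feature list
#'
#' Genes extracted in at least `min_samples` samples form the final feature
#' list, ordered by `gene_order` when supplied (otherwise by first
#' appearance).
#'
#' @param per_sample_sets Named list of gene vectors.
#' @param min_samples Minimum number of samples a gene must appear in
#'   (default 2).
#' @param gene_order Optional full gene ordering used to sort the result.
#' @return Character vector of feature genes.
#' @export
union_features <- function(per_sample_sets, min_samples = 2, gene_order = NULL) {
  if (!length(per_sample_sets)) config_error("at least one sample set required")
  tab <- table(unlist(lapply(per_sample_sets, unique)))
  feats <- names(tab)[tab >= min_samples]
  if (!is.null(gene_order)) feats <- gene_order[gene_order %in% feats]
  feats
}

#' Three-step feature selection across samples
#'
#' (1) per-sample highly variable genes by dispersion; (2) per-sample
#' correlated-gene filter; (3) union of genes retained in at least
#' `min_samples` samples.
#'
#' @inheritParams select_hvgs_per_sample
#' @inheritParams select_correlated_genes
#' @inheritParams union_features
#' @return list with `per_sample_hvgs`, `correlated_genes`, `final_features`
#'   and `min_samples`.
#' @export
select_features <- function(x, samples = x$cells$sample, top_n = 2000,
                            threshold = 0.2, min_samples = 2) {
  hvgs <- select_hvgs_per_sample(x, samples = samples, top_n = top_n)
  corr <- select_correlated_genes(x, hvgs, samples = samples, threshold = threshold)
  feats <- union_features(corr, min_samples = min_samples,
                          gene_order = colnames(x$counts))
  list(per_sample_hvgs = hvgs, correlated_genes = corr,
       final_features = feats, min_samples = min_samples)
}

#' Control-bin gene-signature scoring
#'
#' Scores every cell for a gene set against expression-matched controls:
#' genes are binned into `n_bins` equal-count bins by their average
#' log-normalized expression over all cells; for each set gene, `ctrl_size`
#' control genes are sampled (without replacement, seeded) from its bin,
#' excluding set genes; the per-cell score is the mean expression of the set
#' minus the mean expression of the pooled (unique) control genes. Bit-for-bit
#' reproducible for a fixed seed; the caller's RNG state is untouched.
#'
#' @param x An [atlas()] with the `norm` layer.
#' @param gene_set Character vector of gene symbols (intersected with the
#'   matrix; empty intersection is an error).
#' @param n_bins Number of expression bins (default 25).
#' @param ctrl_size Controls sampled per set gene (default 50).
#' @param seed RNG seed for control sampling (default 0).
#' @return list with `scores` (named numeric, one per cell), `gene_set` (the
#'   genes used), `control_genes`, and the binning parameters.
#' @export
score_gene_set <- function(x, gene_set, n_bins = 25, ctrl_size = 50, seed = 0L) {
  norm <- get_layer(x, "norm")
  gene_set <- intersect(gene_set, colnames(norm))
  if (!length(gene_set))
    stop("score_gene_set: gene set has no genes in the matrix", call. = FALSE)
  avg <- Matrix::colSums(norm) / nrow(norm)
  G <- length(avg)
  n_items <- ceiling(G / n_bins)
  bin <- (rank(avg, ties.method = "min") - 1) %/% n_items
  names(bin) <- colnames(norm)
  ctrl <- with_seed(seed, {
    picked <- character(0)
    for (g in gene_set) {
      pool <- setdiff(names(bin)[bin == bin[[g]]], gene_set)
      if (!length(pool)) next
      picked <- c(picked, pool[sample.int(length(pool),
                                          min(ctrl_size, length(pool)))])
    }
    unique(picked)
  })
  mean_set <- Matrix::rowSums(norm[, gene_set, drop = FALSE]) / length(gene_set)
  mean_ctrl <- if (length(ctrl))
    Matrix::rowSums(norm[, ctrl, drop = FALSE]) / length(ctrl)
  else rep(0, nrow(norm))
  scores <- as.numeric(mean_set - mean_ctrl)
  names(scores) <- rownames(norm)
  list(scores = scores, gene_set = gene_set, control_genes = ctrl,
       n_bins = n_bins, ctrl_size = ctrl_size, seed = seed)
}

#' Regress out covariates and z-scale
#'
#' Per gene, fits ordinary least squares of log-normalized expression on an
#' intercept plus the supplied covariates (typically S and G2M cell-cycle
#' scores), takes residuals, z-scales them per gene (n - 1 standard
#' deviation) and clips at `±clip`. Genes with zero residual variance map to
#' all-zero. The result is stored as the dense `scaled` layer, restricted to
#' `genes` when given (typically the selected features).
#'
#' @param x An [atlas()] with the `norm` layer.
#' @param covariates Numeric matrix or data.frame, one row per cell; may be
#'   NULL for plain scaling.
#' @param clip Clip value for the scaled layer (default 10).
#' @param genes Optional gene subset for the scaled layer.
#' @return The atlas with `scaled` set.
#' @export
regress_out_and_scale <- function(x, covariates = NULL, clip = 10, genes = NULL) {
  norm <- get_layer(x, "norm")
  if (!is.null(genes)) norm <- norm[, genes, drop = FALSE]
  Y <- as.matrix(norm)
  n <- nrow(Y)
  X <- cbind(`(Intercept)` = rep(1, n),
             if (!is.null(covariates)) as.matrix(covariates))
  if (!all(is.finite(X))) config_error("covariates must be finite")
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stop("regress_out_and_scale: covariates are collinear", call. = FALSE)
  resid <- qr.resid(qx, Y)
  sds <- apply(resid, 2, sd)
  # residuals of an exact fit carry O(1e-16) rounding noise; treat residual
  # variance negligible relative to the gene's scale as zero
  zero <- sds <= 1e-10 * pmax(1, apply(abs(Y), 2, max))
  z <- sweep(resid, 2, ifelse(zero, Inf, sds), "/")
  z[z > clip] <- clip
  z[z < -clip] <- -clip
  dimnames(z) <- dimnames(Y)
  x$scaled <- z
  x
}
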