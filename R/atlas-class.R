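#' Construct an `atlas` object
#'
#' The central container of the package: a sparse raw count matrix oriented
#' cells x genes, optional derived layers, and aligned per-cell metadata.
#' Layers:
#' \describe{
#'   \item{counts}{raw UMI counts, non-negative integers (dgCMatrix).}
#'   \item{norm}{log CP10K, `Y = ln(x * 1e4 / colsum + 1)` (dgCMatrix),
#'     set by [normalize_cp10k()].}
#'   \item{scaled}{regressed + z-scaled dense layer on a feature subset,
#'     set by [regress_out_and_scale()].}
#' }
#'
#' @param counts Matrix-like, cells x genes, non-negative integer entries.
#'   Row names are cell barcodes, column names gene symbols (made unique).
#' @param cells Optional data.frame of per-cell metadata, one row per cell in
#'   matrix order (columns such as `sample`, `donor`, `stage_pcw`, `region`,
#'   `parent_cluster`, `subcluster`).
#' @param genes Optional data.frame of per-gene annotation (e.g. `accession`).
#' @return An object of class `atlas`.
#' @examples
#' m <- Matrix::rsparsematrix(20, 30, 0.3, rand.x = function(n) rpois(n, 2) + 1)
#' rownames(m) <- paste0("cell", 1:20); colnames(m) <- paste0("g", 1:30)
#' atlas(m)
#' @export
atlas <- function(counts, cells = NULL, genes = NULL) {
  counts <- as(as(counts, "CsparseMatrix"), "generalMatrix")
  if (length(counts@x) && any(counts@x < 0))
    config_error("raw counts must be non-negative")
  if (length(counts@x) && any(counts@x != round(counts@x)))
    config_error("raw counts must be integers")
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("cell-", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("gene-", seq_len(ncol(counts)))
  colnames(counts) <- make.unique(colnames(counts))
  if (is.null(cells)) cells <- data.frame(row.names = rownames(counts))
  if (nrow(cells) != nrow(counts))
    config_error("cells metadata has %d rows but matrix has %d cells",
                 nrow(cells), nrow(counts))
  rownames(cells) <- rownames(counts)
  if (is.null(genes)) genes <- data.frame(row.names = colnames(counts))
  if (nrow(genes) != ncol(counts))
    config_error("genes table has %d rows but matrix has %d genes",
                 nrow(genes), ncol(counts))
  rownames(genes) <- colnames(counts)
  structure(list(counts = counts, norm = NULL, scaled = NULL,
                 cells = cells, genes = genes),
            class = "atlas")
}

#' @export
dim.atlas <- function(x) dim(x$counts)

#' @export
dimnames.atlas <- function(x) dimnames(x$counts)

#' Number of cells / genes in an atlas
#' @param x An `atlas`.
#' @return Integer count.
#' @export
n_cells <- function(x) nrow(x$counts)

#' @rdname n_cells
#' @export
n_genes <- function(x) ncol(x$counts)

#' @export
print.atlas <- function(x, ...) {
  cat(sprintf("atlas: %d cells x %d genes\n", nrow(x$counts), ncol(x$counts)))
  layers <- c("counts", if (!is.null(x$norm)) "norm", if (!is.null(x$scaled)) "scaled")
  cat("  layers:", paste(layers, collapse = ", "), "\n")
  if (ncol(x$cells))
    cat("  cell metadata:", paste(colnames(x$cells), collapse = ", "), "\n")
  invisible(x)
}

#' Subset an atlas by cells and/or genes
#'
#' All layers and metadata are subset consistently. The scaled layer is kept
#' only for genes still present.
#'
#' @param x An `atlas`.
#' @param i Cell index (logical, integer, or barcode character vector).
#' @param j Gene index.
#' @param ... Ignored.
#' @param drop Ignored; dimensions are always kept.
#' @export
`[.atlas` <- function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  out <- x
  out$counts <- x$counts[i, j, drop = FALSE]
  if (!is.null(x$norm)) out$norm <- x$norm[i, j, drop = FALSE]
  if (!is.null(x$scaled)) {
    keep <- intersect(colnames(x$scaled), colnames(out$counts))
    out$scaled <- x$scaled[i, keep, drop = FALSE]
  }
  out$cells <- x$cells[i, , drop = FALSE]
  out$genes <- x$genes[j, , drop = FALSE]
  out
}

# internal: fetch a layer, failing with a clear message when absent
get_layer <- function(x, layer = c("norm", "counts", "scaled")) {
  layer <- match.arg(layer)
  out <- x[[if (layer == "counts") "counts" else layer]]
  if (is.null(out))
    stop(sprintf("atlas has no '%s' layer; run %s first", layer,
                 if (layer == "norm") "normalize_cp10k()" else "regress_out_and_scale()"),
         call. = FALSE)
  out
}
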