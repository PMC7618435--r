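#' Read a 10x-style MatrixMarket triplet directory
#'
#' Expects `matrix.mtx[.gz]`, `barcodes.tsv[.gz]` and `features.tsv[.gz]`
#' under `dir`. The on-disk convention is genes x cells with 1-based
#' coordinate indices; orientation is auto-detected by matching the header
#' dimensions against the barcode and feature file lengths, and the returned
#' matrix is always cells x genes. Duplicate gene symbols are made unique by
#' suffixing.
#'
#' @param dir Directory containing the triplet files.
#' @return An [atlas()] with the raw counts layer set; per-gene accessions,
#'   when present in `features.tsv`, are kept in the gene table.
#' @export
read_10x <- function(dir) {
  find1 <- function(base) {
    for (p in file.path(dir, c(base, paste0(base, ".gz"))))
      if (file.exists(p)) return(p)
    stop(sprintf("read_10x: '%s[.gz]' not found in %s", base, dir), call. = FALSE)
  }
  open_maybe_gz <- function(p) if (grepl("\\.gz$", p)) gzfile(p, "r") else file(p, "r")

  mtx_path <- find1("matrix.mtx")
  con <- open_maybe_gz(mtx_path)
  m <- Matrix::readMM(con)
  close(con)
  barcodes <- readLines(con2 <- open_maybe_gz(find1("barcodes.tsv"))); close(con2)
  feat_raw <- readLines(con3 <- open_maybe_gz(find1("features.tsv"))); close(con3)
  feats <- do.call(rbind, strsplit(feat_raw, "\t", fixed = TRUE))

  nf <- nrow(feats); nb <- length(barcodes)
  if (nrow(m) == nf && ncol(m) == nb) {
    m <- Matrix::t(m)                      # genes x cells on disk -> cells x genes
  } else if (nrow(m) == nb && ncol(m) == nf) {
    # already cells x genes
  } else {
    stop(sprintf(paste0("read_10x: matrix is %d x %d but there are %d features ",
                        "and %d barcodes"), nrow(m), ncol(m), nf, nb), call. = FALSE)
  }
  symbols <- if (ncol(feats) >= 2) feats[, 2] else feats[, 1]
  genes <- if (ncol(feats) >= 2)
    data.frame(accession = feats[, 1], stringsAsFactors = FALSE) else NULL
  m <- as(as(m, "CsparseMatrix"), "generalMatrix")
  rownames(m) <- barcodes
  colnames(m) <- make.unique(symbols)
  atlas(m, genes = genes)
}

#' Write an atlas as a 10x-style triplet directory
#'
#' Writes `matrix.mtx`, `barcodes.tsv`, `features.tsv` (optionally gzipped)
#' in the 10x
#' orientation (genes x cells, 1-based MatrixMarket coordinates).
#'
#' @param x An [atlas()].
#' @param dir Output directory (created if needed).
#' @param gzip Compress outputs (default TRUE).
#' @return Invisibly, `dir`.
#' @export
write_10x <- function(x, dir, gzip = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gz <- function(path) {
    if (!gzip) return(path)
    con <- gzfile(paste0(path, ".gz"), "wb")
    writeLines(readLines(path), con)
    close(con)
    unlink(path)
    paste0(path, ".gz")
  }
  mtx <- file.path(dir, "matrix.mtx")
  Matrix::writeMM(Matrix::t(x$counts), mtx)
  gz(mtx)
  bc <- file.path(dir, "barcodes.tsv")
  writeLines(rownames(x$counts), bc); gz(bc)
  ft <- file.path(dir, "features.tsv")
  acc <- if ("accession" %in% colnames(x$genes)) x$genes$accession else colnames(x$counts)
  writeLines(paste(acc, colnames(x$counts), "Gene Expression", sep = "\t"), ft)
  gz(ft)
  invisible(dir)
}

#' Read and validate a per-cell metadata TSV
#'
#' Requires columns `barcode`, `sample`, `stage_pcw`, `region`; optional
#' columns (`donor`, `phase`, `parent_cluster`, `subcluster`, ...) are
#' preserved. Region values are case-folded and must be one of `proximal`,
#' `distal`, `whole`; stages must be numeric. When `barcodes` is supplied the
#' join is strict: metadata must cover exactly those barcodes unless
#' `allow_subset = TRUE`, in which case extra metadata rows are dropped.
#'
#' @param path Path to the TSV.
#' @param barcodes Optional character vector of matrix barcodes to join on.
#' @param allow_subset Permit metadata rows absent from `barcodes`.
#' @return data.frame keyed by barcode (row names), in `barcodes` order when
#'   given.
#' @export
read_metadata <- function(path, barcodes = NULL, allow_subset = FALSE) {
  md <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   check.names = FALSE)
  required <- c("barcode", "sample", "stage_pcw", "region")
  missing_cols <- setdiff(required, colnames(md))
  if (length(missing_cols))
    stop(sprintf("metadata is missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  md$region <- tolower(md$region)
  bad_region <- unique(md$region[!md$region %in% c("proximal", "distal", "whole")])
  if (length(bad_region))
    stop(sprintf("unknown region value(s): %s", paste(bad_region, collapse = ", ")),
         call. = FALSE)
  stage <- suppressWarnings(as.numeric(md$stage_pcw))
  if (anyNA(stage))
    stop(sprintf("non-numeric stage_pcw for barcode(s): %s",
                 paste(head(md$barcode[is.na(stage)], 5), collapse = ", ")),
         call. = FALSE)
  md$stage_pcw <- stage
  if (anyDuplicated(md$barcode))
    stop("duplicated barcodes in metadata", call. = FALSE)
  if (!is.null(barcodes)) {
    absent <- setdiff(barcodes, md$barcode)
    if (length(absent))
      stop(sprintf("matrix barcode(s) absent from metadata: %s",
                   paste(head(absent, 5), collapse = ", ")), call. = FALSE)
    extra <- setdiff(md$barcode, barcodes)
    if (length(extra) && !allow_subset)
      stop(sprintf(paste0("metadata has %d barcode(s) not in the matrix ",
                          "(e.g. %s); pass allow_subset = TRUE to drop them"),
                   length(extra), paste(head(extra, 3), collapse = ", ")),
           call. = FALSE)
    md <- md[match(barcodes, md$barcode), , drop = FALSE]
  }
  rownames(md) <- md$barcode
  md
}

#' Write per-cell metadata as TSV
#'
#' @param cells data.frame of per-cell metadata; row names are used as the
#'   `barcode` column when none exists.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_metadata <- function(cells, path) {
  out <- cells
  if (!"barcode" %in% colnames(out))
    out <- cbind(barcode = rownames(cells), out)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
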