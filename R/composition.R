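#' Tabulate cell-type composition by stage and region
#'
#' Builds the count structures the composition-bias statistics operate on:
#' a cell type x stage matrix `C[t, s]`, and per-type proximal/distal counts
#' with their totals. Cells from `"whole"` (undissected) samples contribute
#' to the stage counts but are excluded from the region counts.
#'
#' @param cells Per-cell metadata data.frame with columns `stage_pcw` and
#'   `region`.
#' @param types Per-cell cell-type labels (default `cells$parent_cluster`).
#' @param exclude_types Types to drop entirely, e.g. rare early-stage
#'   clusters excluded before computing the bias coordinates (default none).
#' @return A `composition_table` list: `C` (types x stages), `C_prox`,
#'   `C_dist` (named per-type counts), `total_prox`, `total_dist`, and
#'   `stages` (numeric stage values, column order of `C`).
#' @export
build_composition <- function(cells, types = cells$parent_cluster,
                              exclude_types = character(0)) {
  if (is.null(types)) config_error("cell-type labels are required")
  types <- as.character(types)
  miss <- which(is.na(types) | is.na(cells$stage_pcw) | is.na(cells$region))
  if (length(miss))
    stop(sprintf("missing type/stage/region labels for cell(s): %s",
                 paste(head(rownames(cells)[miss], 5), collapse = ", ")),
         call. = FALSE)
  keep <- !(types %in% exclude_types)
  types <- types[keep]
  stage <- cells$stage_pcw[keep]
  region <- as.character(cells$region[keep])
  type_lv <- sort(unique(types))
  stage_lv <- sort(unique(stage))
  C <- table(factor(types, type_lv), factor(stage, stage_lv))
  C <- matrix(as.numeric(C), nrow(C), ncol(C), dimnames = dimnames(C))
  prox <- region == "proximal"; dist <- region == "distal"
  Cp <- as.numeric(table(factor(types[prox], type_lv)))
  Cd <- as.numeric(table(factor(types[dist], type_lv)))
  names(Cp) <- names(Cd) <- type_lv
  structure(list(C = C, C_prox = Cp, C_dist = Cd,
                 total_prox = sum(Cp), total_dist = sum(Cd),
                 stages = stage_lv),
            class = "composition_table")
}

#' Chi-squared test of independence
#'
#' Pearson chi-squared statistic `sum((O - E)^2 / E)` without continuity
#' correction, with `df = (rows - 1)(cols - 1)`. Empty rows and columns are
#' dropped first (reported in the result).
#'
#' @param tab Count matrix (at least 2 x 2 after dropping empty margins).
#' @return list with `statistic`, `df`, `p`, `table_shape`, and
#'   `dropped` (names of removed empty rows/columns).
#' @export
chi2_independence <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) config_error("counts must be non-negative")
  dropped <- c(rownames(tab)[rowSums(tab) == 0], colnames(tab)[colSums(tab) == 0])
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop("chi2_independence: need at least a 2 x 2 table with positive margins",
         call. = FALSE)
  res <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value, table_shape = dim(tab), dropped = dropped)
}

#' Per-type Fisher exact tests of regional enrichment
#'
#' For every cell type, a two-sided Fisher exact test (conventional
#' definition: sum of hypergeometric table probabilities not exceeding the
#' observed table's) on the 2 x 2 table
#' `[[C_t_prox, C_prox - C_t_prox], [C_t_dist, C_dist - C_t_dist]]`,
#' followed by Benjamini-Hochberg correction across types.
#'
#' @param ct A [build_composition()] result with positive region totals.
#' @return data.frame with one row per type: `type`, `prox`, `dist`,
#'   `odds_ratio` (conditional MLE), `p_raw`, `p_adj`, and `direction`
#'   (`"proximal"`/`"distal"`/`"none"` by the normalized frequency ratio).
#' @export
fisher_per_type <- function(ct) {
  if (ct$total_prox <= 0 || ct$total_dist <= 0)
    stop("fisher_per_type: both region totals must be positive", call. = FALSE)
  types <- names(ct$C_prox)
  p <- or <- numeric(length(types))
  for (k in seq_along(types)) {
    t2 <- matrix(c(ct$C_prox[k], ct$total_prox - ct$C_prox[k],
                   ct$C_dist[k], ct$total_dist - ct$C_dist[k]),
                 nrow = 2, byrow = TRUE)
    ft <- fisher.test(t2)
    # fisher.test can return 1 + eps from summing table probabilities
    p[k] <- min(1, ft$p.value)
    or[k] <- unname(ft$estimate)
  }
  fp <- ct$C_prox / ct$total_prox
  fd <- ct$C_dist / ct$total_dist
  direction <- ifelse(fp > fd, "proximal", ifelse(fd > fp, "distal", "none"))
  data.frame(type = types, prox = unname(ct$C_prox), dist = unname(ct$C_dist),
             odds_ratio = or, p_raw = p, p_adj = bh_adjust(p),
             direction = unname(direction), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Weighted stage and proximal-representation coordinates
#'
#' Computes, per cell type t, the composition-bias coordinates:
#' \deqn{p_{s|t} = \frac{C_{t,s}/\sum_t C_{t,s}}{\sum_s (C_{t,s}/\sum_t C_{t,s})},
#'  \quad x_t = \sum_s s \, p_{s|t}}
#' \deqn{y_t = \frac{C_{t,prox}/C_{prox}}{C_{t,prox}/C_{prox} + C_{t,dist}/C_{dist}}}
#' Counts are first normalized per stage (so unevenly sized stages do not
#' dominate), then each type's stage profile is renormalized to a
#' distribution and its mean stage `x_t` taken. `y_t` compares the type's
#' frequency among proximal cells with its frequency among distal cells,
#' whole-lung samples ignored; it is 0.5 when the type is equally
#' represented, and undefined (NA, with a reason) when the type is absent
#' from both dissected regions.
#'
#' @param ct A [build_composition()] result.
#' @return data.frame with columns `type`, `x`, `y`, `y_missing_reason`, and
#'   the per-type stage distribution `p_s_t` as a matrix attribute.
#' @export
bias_coordinates <- function(ct) {
  stage_vals <- as.numeric(ct$stages)
  xy <- xy_from_counts(ct$C, ct$C_prox, ct$C_dist, stage_vals)
  # expose the stage distribution itself for inspection / plotting
  stage_tot <- colSums(ct$C)
  frac <- sweep(ct$C, 2, ifelse(stage_tot > 0, stage_tot, 1), "/")
  frac[, stage_tot == 0] <- 0
  p_s_t <- frac / ifelse(rowSums(frac) > 0, rowSums(frac), NA_real_)
  res <- data.frame(type = rownames(ct$C), x = xy$x, y = xy$y,
                    y_missing_reason = ifelse(is.na(xy$y),
                                              "absent from both dissected regions", ""),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "p_s_t") <- p_s_t
  res
}
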