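#' Specify a simulated cell type
#'
#' A cell type is a gene-expression program plus a composition profile. The
#' expression mean vector is flat across genes except for `program_genes`,
#' which are multiplied by `program_fold` before renormalizing to sum one, so
#' the fold applies on the relative-expression scale. `abundance_by_stage`
#' drives how abundant the type is across developmental stages (post-conception
#' weeks, pcw); `proximal_bias` is the probability that a cell of this type in
#' a dissected (proximal/distal) sample comes from the proximal piece.
#'
#' @param name Cell type identifier.
#' @param program_genes Integer vector of gene indices forming the type's
#'   expression program.
#' @param program_fold Expression multiplier (> 1) on program genes.
#' @param abundance_by_stage Named numeric vector mapping stage (pcw, as the
#'   name) to a non-negative abundance weight. Stages absent from the map get
#'   weight zero.
#' @param proximal_bias Probability in \[0, 1\]; 0.5 means no regional bias.
#' @return A `cell_type_spec` list.
#' @export
cell_type_spec <- function(name, program_genes, program_fold = 5,
                           abundance_by_stage = c("15" = 1),
                           proximal_bias = 0.5) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    config_error("cell_type_spec: 'name' must be a non-empty string")
  program_genes <- as.integer(program_genes)
  if (anyNA(program_genes) || any(program_genes < 1L))
    config_error("cell_type_spec '%s': 'program_genes' must be positive indices", name)
  stopifnot_scalar_number(program_fold, "program_fold", min = 1, strict_min = TRUE)
  if (is.null(names(abundance_by_stage)) || anyNA(as.numeric(names(abundance_by_stage))))
    config_error("cell_type_spec '%s': 'abundance_by_stage' must be named by stage (pcw)", name)
  if (any(abundance_by_stage < 0) || sum(abundance_by_stage) <= 0)
    config_error("cell_type_spec '%s': abundance weights must be >= 0 with positive sum", name)
  stopifnot_scalar_number(proximal_bias, "proximal_bias", min = 0)
  if (proximal_bias > 1)
    config_error("cell_type_spec '%s': 'proximal_bias' must be in [0, 1]", name)
  structure(list(name = name, program_genes = program_genes,
                 program_fold = program_fold,
                 abundance_by_stage = abundance_by_stage,
                 proximal_bias = proximal_bias),
            class = "cell_type_spec")
}

#' Specify a simulated sample
#'
#' @param name Sample identifier.
#' @param donor Donor identifier.
#' @param stage Developmental stage in pcw (integer in \[5, 22\]).
#' @param region One of `"proximal"`, `"distal"`, `"whole"`.
#' @param n_cells Number of cells to draw for this sample.
#' @return A `sample_spec` list.
#' @export
sample_spec <- function(name, donor, stage, region, n_cells) {
  stopifnot_scalar_number(stage, "stage", min = 5)
  if (stage > 22) config_error("sample_spec '%s': stage must be in [5, 22]", name)
  region <- match.arg(region, c("proximal", "distal", "whole"))
  stopifnot_scalar_number(n_cells, "n_cells", min = 1)
  structure(list(name = name, donor = donor, stage = as.integer(stage),
                 region = region, n_cells = as.integer(n_cells)),
            class = "sample_spec")
}

#' Specify a planted doublet cluster
#'
#' Doublet cells mix two parent programs: their relative expression vector is
#' the average of the two parent mean vectors (renormalized to sum one) and
#' their library size is multiplied by `library_inflation`, mimicking the
#' elevated RNA content of two-cell droplets. In the emitted cluster labels
#' the doublet cells form a subcluster nested under `host_parent`'s parental
#' cluster, which is the configuration the cluster-level doublet detector is
#' designed to catch.
#'
#' @param parent_a,parent_b Names of the two (distinct) parent cell types.
#' @param host_parent Parental cluster the doublet subcluster is nested under
#'   (default `parent_a`).
#' @param n_cells Number of doublet cells.
#' @param library_inflation Library-size multiplier (default 1.5).
#' @param mix_b Mixing weight of `parent_b`'s program in \[0, 1\]: the
#'   doublet mean vector is `(1 - mix_b) * mu_a + mix_b * mu_b`,
#'   renormalized. 0.5 (default) is an even two-cell droplet; other values
#'   model unequal RNA contributions and drive contamination sweeps.
#' @return A `doublet_spec` list.
#' @export
doublet_spec <- function(parent_a, parent_b, host_parent = parent_a,
                         n_cells = 50, library_inflation = 1.5, mix_b = 0.5) {
  if (identical(parent_a, parent_b))
    config_error("doublet_spec: 'parent_a' and 'parent_b' must differ")
  stopifnot_scalar_number(n_cells, "n_cells", min = 1)
  stopifnot_scalar_number(library_inflation, "library_inflation", min = 0, strict_min = TRUE)
  stopifnot_scalar_number(mix_b, "mix_b", min = 0)
  if (mix_b > 1) config_error("doublet_spec: 'mix_b' must be in [0, 1]")
  structure(list(parent_a = parent_a, parent_b = parent_b,
                 host_parent = host_parent, n_cells = as.integer(n_cells),
                 library_inflation = library_inflation, mix_b = mix_b),
            class = "doublet_spec")
}

#' Assemble and validate a simulation configuration
#'
#' @param n_genes Number of genes (>= 10).
#' @param cell_types List of [cell_type_spec()] objects.
#' @param samples List of [sample_spec()] objects.
#' @param doublet_clusters List of [doublet_spec()] objects (may be empty).
#' @param library_size_mean Mean total UMI per cell (gamma-distributed).
#' @param library_size_shape Gamma shape of the library-size distribution.
#' @param nb_dispersion Global negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param seed Integer seed; the same seed reproduces the atlas exactly.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_genes, cell_types, samples, doublet_clusters = list(),
                       library_size_mean = 2000, library_size_shape = 2,
                       nb_dispersion = 0.5, seed = 1L) {
  stopifnot_scalar_number(n_genes, "n_genes", min = 10)
  if (!length(cell_types)) config_error("'cell_types' must be non-empty")
  if (!length(samples)) config_error("'samples' must be non-empty")
  for (ct in cell_types) {
    if (!inherits(ct, "cell_type_spec")) config_error("'cell_types' entries must be cell_type_spec")
    if (any(ct$program_genes > n_genes))
      config_error("cell type '%s': program gene index exceeds n_genes", ct$name)
  }
  type_names <- vapply(cell_types, `[[`, "", "name")
  if (anyDuplicated(type_names)) config_error("cell type names must be unique")
  for (s in samples)
    if (!inherits(s, "sample_spec")) config_error("'samples' entries must be sample_spec")
  if (anyDuplicated(vapply(samples, `[[`, "", "name")))
    config_error("sample names must be unique")
  for (d in doublet_clusters) {
    if (!inherits(d, "doublet_spec")) config_error("'doublet_clusters' entries must be doublet_spec")
    for (fld in c("parent_a", "parent_b", "host_parent"))
      if (!d[[fld]] %in% type_names)
        config_error("doublet_spec: '%s' (%s) is not a configured cell type", d[[fld]], fld)
  }
  stopifnot_scalar_number(library_size_mean, "library_size_mean", min = 0, strict_min = TRUE)
  stopifnot_scalar_number(library_size_shape, "library_size_shape", min = 0, strict_min = TRUE)
  stopifnot_scalar_number(nb_dispersion, "nb_dispersion", min = 0, strict_min = TRUE)
  structure(list(n_genes = as.integer(n_genes), cell_types = cell_types,
                 samples = samples, doublet_clusters = doublet_clusters,
                 library_size_mean = library_size_mean,
                 library_size_shape = library_size_shape,
                 nb_dispersion = nb_dispersion, seed = as.integer(seed)),
            class = "sim_config")
}

# relative expression vector of one type: flat baseline, program genes
# multiplied by program_fold, renormalized to sum 1
type_mean_vector <- function(ct, n_genes) {
  mu <- rep(1, n_genes)
  mu[ct$program_genes] <- ct$program_fold
  mu / sum(mu)
}

# per-sample composition weights over singlet types; region modulates the
# abundance-by-stage weight through proximal_bias
sample_type_weights <- function(config, smp) {
  vapply(config$cell_types, function(ct) {
    w <- ct$abundance_by_stage[as.character(smp$stage)]
    w <- if (is.na(w)) 0 else unname(w)
    w * switch(smp$region,
               proximal = ct$proximal_bias,
               distal   = 1 - ct$proximal_bias,
               whole    = 1)
  }, numeric(1))
}

#' Simulate a multi-sample single-cell atlas
#'
#' Draws, per sample, a multinomial cell-type composition from the configured
#' abundance-by-stage weights (modulated by each type's proximal bias for
#' dissected samples), then per cell a gamma library size and
#' negative-binomial counts with mean `libsize * mu_type`. Planted doublet
#' cells use the averaged, renormalized parent mean vector and an inflated
#' library size, and are spread across samples in proportion to sample size.
#' Cluster labels are emitted at two levels: each singlet type is a parental
#' cluster with one pure subcluster (`<type>.1`); each planted doublet
#' cluster is an extra subcluster under its host parent.
#'
#' @param config A [sim_config()].
#' @return A list with components `atlas` (an [atlas()] whose cell metadata
#'   carries `sample`, `donor`, `stage_pcw`, `region`, `parent_cluster`,
#'   `subcluster`) and `truth` (list: `cells` data.frame with `true_type` and
#'   `is_doublet`; `subclusters` data.frame with `is_doublet_cluster`).
#' @examples
#' cfg <- sim_config(
#'   n_genes = 50,
#'   cell_types = list(
#'     cell_type_spec("A", 1:5, abundance_by_stage = c("15" = 1)),
#'     cell_type_spec("B", 6:10, abundance_by_stage = c("15" = 1))),
#'   samples = list(sample_spec("s1", "d1", 15, "whole", 200)),
#'   seed = 7)
#' sim <- generate_atlas(cfg)
#' table(sim$atlas$cells$parent_cluster)
#' @export
generate_atlas <- function(config) {
  if (!inherits(config, "sim_config")) config_error("'config' must be a sim_config")
  G <- config$n_genes
  mus <- lapply(config$cell_types, type_mean_vector, n_genes = G)
  names(mus) <- vapply(config$cell_types, `[[`, "", "name")
  size <- 1 / config$nb_dispersion
  rate <- config$library_size_shape / config$library_size_mean

  with_seed(config$seed, {
    blocks <- list(); meta <- list()
    for (smp in config$samples) {
      w <- sample_type_weights(config, smp)
      if (sum(w) <= 0)
        config_error("sample '%s': no cell type has positive weight at stage %d in region %s",
                     smp$name, smp$stage, smp$region)
      n_per_type <- as.integer(rmultinom(1, smp$n_cells, w))
      for (k in seq_along(config$cell_types)) {
        n <- n_per_type[k]
        if (n == 0L) next
        ct <- config$cell_types[[k]]
        lib <- rgamma(n, shape = config$library_size_shape, rate = rate)
        mu <- outer(lib, mus[[ct$name]])
        cnt <- matrix(rnbinom(n * G, mu = mu, size = size), nrow = n)
        blocks[[length(blocks) + 1L]] <- cnt
        meta[[length(meta) + 1L]] <- data.frame(
          sample = rep(smp$name, n), donor = smp$donor, stage_pcw = smp$stage,
          region = smp$region, true_type = ct$name, is_doublet = FALSE,
          parent_cluster = ct$name, subcluster = paste0(ct$name, ".1"),
          stringsAsFactors = FALSE)
      }
    }
    # planted doublet clusters, spread over samples by sample size
    smp_sizes <- vapply(config$samples, `[[`, integer(1), "n_cells")
    for (k in seq_along(config$doublet_clusters)) {
      d <- config$doublet_clusters[[k]]
      mu_d <- (1 - d$mix_b) * mus[[d$parent_a]] + d$mix_b * mus[[d$parent_b]]
      mu_d <- mu_d / sum(mu_d)
      alloc <- as.integer(rmultinom(1, d$n_cells, smp_sizes))
      for (si in seq_along(config$samples)) {
        n <- alloc[si]
        if (n == 0L) next
        smp <- config$samples[[si]]
        lib <- d$library_inflation *
          rgamma(n, shape = config$library_size_shape, rate = rate)
        mu <- outer(lib, mu_d)
        cnt <- matrix(rnbinom(n * G, mu = mu, size = size), nrow = n)
        blocks[[length(blocks) + 1L]] <- cnt
        meta[[length(meta) + 1L]] <- data.frame(
          sample = rep(smp$name, n), donor = smp$donor, stage_pcw = smp$stage,
          region = smp$region,
          true_type = paste0(d$parent_a, "+", d$parent_b), is_doublet = TRUE,
          parent_cluster = d$host_parent,
          subcluster = paste0(d$host_parent, ".dbl", k),
          stringsAsFactors = FALSE)
      }
    }
    counts <- do.call(rbind, blocks)
    meta <- do.call(rbind, meta)
    barcodes <- paste0(meta$sample, "-", ave(seq_len(nrow(meta)), meta$sample,
                                             FUN = seq_along))
    rownames(counts) <- barcodes
    colnames(counts) <- sprintf("G%04d", seq_len(G))
    rownames(meta) <- barcodes

    sub_tab <- unique(meta[, c("parent_cluster", "subcluster", "is_doublet")])
    sub_tab <- sub_tab[order(sub_tab$subcluster), ]
    names(sub_tab)[3] <- "is_doublet_cluster"
    rownames(sub_tab) <- NULL

    at <- atlas(Matrix::Matrix(counts, sparse = TRUE),
                cells = meta[, c("sample", "donor", "stage_pcw", "region",
                                 "parent_cluster", "subcluster")])
    list(atlas = at,
         truth = list(cells = data.frame(barcode = barcodes,
                                         true_type = meta$true_type,
                                         is_doublet = meta$is_doublet,
                                         stringsAsFactors = FALSE),
                      subclusters = sub_tab))
  })
}

#' Analytically expected composition-bias coordinates of a simulation
#'
#' Evaluates, in closed form, the weighted mean developmental stage `x_t` and
#' the normalized proximal-representation probability `y_t` implied by a
#' configuration's abundance-by-stage weights and proximal biases, using
#' expected (not sampled) per-sample compositions. Doublet cells are not part
#' of any singlet type and are excluded. Samples with region `"whole"`
#' contribute to the stage axis but never to the region axis.
#'
#' @param config A [sim_config()].
#' @return data.frame with columns `type`, `x` (expected `x_t`, pcw) and `y`
#'   (expected `y_t`; `NA` for types absent from both dissected regions).
#' @export
composition_gradient_truth <- function(config) {
  if (!inherits(config, "sim_config")) config_error("'config' must be a sim_config")
  types <- vapply(config$cell_types, `[[`, "", "name")
  stages <- sort(unique(vapply(config$samples, `[[`, integer(1), "stage")))
  C <- matrix(0, length(types), length(stages), dimnames = list(types, stages))
  Cp <- setNames(numeric(length(types)), types)
  Cd <- setNames(numeric(length(types)), types)
  for (smp in config$samples) {
    w <- sample_type_weights(config, smp)
    if (sum(w) <= 0) next
    exp_n <- smp$n_cells * w / sum(w)
    C[, as.character(smp$stage)] <- C[, as.character(smp$stage)] + exp_n
    if (smp$region == "proximal") Cp <- Cp + exp_n
    if (smp$region == "distal") Cd <- Cd + exp_n
  }
  xy <- xy_from_counts(C, Cp, Cd, as.numeric(stages))
  data.frame(type = types, x = xy$x, y = xy$y, row.names = NULL,
             stringsAsFactors = FALSE)
}

# shared evaluator of the x_t / y_t equations from a type x stage count
# matrix and per-type regional counts; used by both the simulator truth and
# the empirical composition statistics
xy_from_counts <- function(C, Cp, Cd, stage_values) {
  stage_tot <- colSums(C)
  frac <- sweep(C, 2, ifelse(stage_tot > 0, stage_tot, 1), "/")
  frac[, stage_tot == 0] <- 0
  denom <- rowSums(frac)
  x <- as.numeric(frac %*% stage_values) / ifelse(denom > 0, denom, NA_real_)
  tot_p <- sum(Cp); tot_d <- sum(Cd)
  fp <- if (tot_p > 0) Cp / tot_p else rep(0, length(Cp))
  fd <- if (tot_d > 0) Cd / tot_d else rep(0, length(Cd))
  y <- ifelse(fp + fd > 0, fp / (fp + fd), NA_real_)
  list(x = unname(x), y = unname(y))
}

#' Write a simulated atlas to disk
#'
#' Emits one 10x-style triplet directory per sample
#' (`matrix.mtx.gz`, `barcodes.tsv.gz`, `features.tsv.gz`), a combined
#' per-cell metadata TSV and a ground-truth JSON.
#'
#' @param sim The list returned by [generate_atlas()].
#' @param dir Output directory (created if missing).
#' @param gzip Compress the per-sample triplet files (default TRUE).
#' @return Invisibly, the paths written.
#' @export
export_sim <- function(sim, dir, gzip = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (smp in unique(sim$atlas$cells$sample)) {
    sub <- sim$atlas[sim$atlas$cells$sample == smp, ]
    sd <- file.path(dir, smp)
    write_10x(sub, sd, gzip = gzip)
    paths <- c(paths, sd)
  }
  meta_path <- file.path(dir, "metadata.tsv")
  write_metadata(sim$atlas$cells, meta_path)
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(sim$truth, truth_path, dataframe = "columns",
                       auto_unbox = TRUE, digits = NA)
  invisible(c(paths, meta_path, truth_path))
}
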