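#' Assemble and validate a pipeline configuration
#'
#' Collects the per-stage parameters of [run_pipeline()] and validates them
#' up front, so a bad value fails before any stage runs. Clustering itself
#' (PCA / neighbor graph / community detection) is delegated to upstream
#' tools; the cluster labels arrive with the metadata, and the
#' `clustering_provenance` string records how they were made (e.g. number
#' of PCs, neighbors, resolution) without being interpreted here.
#'
#' @param qc Named list of [qc_filter()] arguments.
#' @param features Named list of [select_features()] arguments
#'   (`top_n`, `threshold`, `min_samples`).
#' @param markers Named list of [rank_markers()] filter arguments.
#' @param doucling Named list of [doucling_flag()] arguments
#'   (`flag_fraction`, `min_subcluster_size`, ...).
#' @param exclude_types Types excluded from the composition statistics.
#' @param clustering_provenance Free-text provenance of the cluster labels.
#' @param seed Integer seed used by all seeded stages.
#' @return A validated `pipeline_config` list that round-trips losslessly
#'   through JSON.
#' @export
pipeline_config <- function(qc = list(), features = list(), markers = list(),
                            doucling = list(), exclude_types = character(0),
                            clustering_provenance = "", seed = 0L) {
  if (!is.null(doucling$flag_fraction) &&
      (doucling$flag_fraction <= 0 || doucling$flag_fraction >= 1))
    config_error("doucling$flag_fraction must be in (0, 1)")
  if (!is.null(qc$max_mito_fraction) &&
      (qc$max_mito_fraction < 0 || qc$max_mito_fraction > 1))
    config_error("qc$max_mito_fraction must be in [0, 1]")
  if (!is.null(markers$max_out_group_fraction) &&
      (markers$max_out_group_fraction < 0 || markers$max_out_group_fraction > 1))
    config_error("markers$max_out_group_fraction must be in [0, 1]")
  if (!is.null(markers$min_fold_change) && markers$min_fold_change <= 0)
    config_error("markers$min_fold_change must be > 0")
  structure(list(qc = qc, features = features, markers = markers,
                 doucling = doucling, exclude_types = exclude_types,
                 clustering_provenance = clustering_provenance,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the atlas pipeline end to end
#'
#' Executes the stages in the atlas-building order — QC filtering, log-CP10K
#' normalization, three-step feature selection, doublet-cluster flagging,
#' composition statistics — writing every artifact under `out_dir` and
#' appending a stage record to the run log for each stage that touches the
#' data. The written outputs are a pure function of the input and
#' configuration (all randomness is seeded through `config$seed`;
#' wall-clock timestamps are kept in the returned log only, not in the
#' files), so the same config and seed reproduce byte-identical outputs.
#'
#' Marker ranking and doublet flagging need cluster labels
#' (`parent_cluster`, `subcluster` metadata columns); stages whose inputs
#' are absent are skipped with a log record. A failure mid-run leaves the
#' artifacts of completed stages and a partial log on disk.
#'
#' @param input Either an [atlas()] (with `cells` metadata populated), a
#'   [sim_config()] to simulate from, or a directory containing a 10x
#'   triplet plus `metadata.tsv`.
#' @param out_dir Output directory.
#' @param config A [pipeline_config()].
#' @return Invisibly, the run log (list of stage records, with timestamps).
#' @export
run_pipeline <- function(input, out_dir, config = pipeline_config()) {
  if (!inherits(config, "pipeline_config"))
    config_error("'config' must be a pipeline_config")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- list()
  note <- function(stage, params, dims_in, dims_out) {
    rec <- list(stage = stage, params = params,
                cells_in = dims_in[1], genes_in = dims_in[2],
                cells_out = dims_out[1], genes_out = dims_out[2])
    log[[length(log) + 1L]] <<- c(rec, time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
    # the on-disk log omits the timestamp so reruns are byte-identical
    writable <- lapply(log, function(r) r[names(r) != "time"])
    jsonlite::write_json(writable, file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
  }

  at <- run_stage("input", {
    if (inherits(input, "sim_config")) {
      sim <- generate_atlas(input)
      sim$atlas
    } else if (inherits(input, "atlas")) {
      input
    } else if (is.character(input) && dir.exists(input)) {
      a <- read_10x(input)
      a$cells <- read_metadata(file.path(input, "metadata.tsv"),
                               barcodes = rownames(a$counts))
      a
    } else config_error("'input' must be an atlas, sim_config or directory")
  })
  d0 <- dim(at)
  note("input", list(class = class(input)[1]), d0, d0)

  qcres <- run_stage("qc_filter", do.call(qc_filter, c(list(at), config$qc)))
  at <- qcres$atlas
  jsonlite::write_json(qcres$report, file.path(out_dir, "qc_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  note("qc_filter", config$qc, d0, dim(at))

  at <- run_stage("normalize", normalize_cp10k(at))
  note("normalize", list(scale_factor = 1e4), dim(at), dim(at))

  feats <- run_stage("select_features",
                     do.call(select_features, c(list(at), config$features)))
  jsonlite::write_json(feats[c("per_sample_hvgs", "correlated_genes",
                               "final_features", "min_samples")],
                       file.path(out_dir, "features.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  note("select_features", config$features, dim(at), dim(at))

  write_10x(at, file.path(out_dir, "filtered"))
  write_metadata(at$cells, file.path(out_dir, "metadata.tsv"))

  has_labels <- all(c("parent_cluster", "subcluster") %in% colnames(at$cells))
  if (has_labels && length(unique(at$cells$parent_cluster)) >= 2) {
    mk <- run_stage("markers",
                    do.call(rank_markers,
                            c(list(at, labels = at$cells$parent_cluster),
                              config$markers)))
    write_markers(mk, file.path(out_dir, "markers.tsv"))
    note("markers", config$markers, dim(at), c(nrow(mk), ncol(mk)))

    rep <- run_stage("doucling",
                     do.call(doucling_flag,
                             c(list(at), config$doucling,
                               list(seed = config$seed), config$markers)))
    write_doublet_report(rep, file.path(out_dir, "doublet_report.tsv"))
    note("doucling", c(config$doucling, seed = config$seed), dim(at),
         c(nrow(rep), ncol(rep)))
  } else {
    note("markers", list(skipped = "no two-level cluster labels"), dim(at), dim(at))
  }

  if (has_labels && all(c("stage_pcw", "region") %in% colnames(at$cells))) {
    ct <- run_stage("composition", build_composition(
      at$cells, exclude_types = config$exclude_types))
    coords <- bias_coordinates(ct)
    write.table(coords, file.path(out_dir, "coordinates.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    stats <- list(
      chi2_stage = tryCatch(chi2_independence(ct$C), error = function(e) NULL),
      chi2_region = tryCatch(
        chi2_independence(cbind(prox = ct$C_prox, dist = ct$C_dist)),
        error = function(e) NULL),
      fisher = tryCatch(fisher_per_type(ct), error = function(e) NULL))
    jsonlite::write_json(stats, file.path(out_dir, "composition_stats.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "columns")
    note("composition", list(exclude_types = config$exclude_types),
         dim(at), c(nrow(ct$C), ncol(ct$C)))
  }
  invisible(log)
}
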