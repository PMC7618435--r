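# 12-cell toy matrix exercising every QC boundary exactly:
#  - c01 detects exactly 200 genes (removed), c02 detects 201 (kept)
#  - gene R5 detected in exactly 5 cells (removed), R6 in 6 (kept)
#  - c03 has mito fraction exactly 0.20 (kept), c04 slightly above (removed)
test_that("qc_filter realizes the exact boundary behavior of its thresholds", {
  res <- qc_filter(qc_toy_atlas())
  kept_cells <- rownames(res$atlas$counts)
  kept_genes <- colnames(res$atlas$counts)
  expect_false("c01" %in% kept_cells)   # exactly 200 genes -> removed
  expect_true("c02" %in% kept_cells)    # 201 genes -> kept
  expect_false("R5" %in% kept_genes)    # detected in exactly 5 cells -> removed
  expect_true("R6" %in% kept_genes)     # 6 cells -> kept
  expect_true("c03" %in% kept_cells)    # mito fraction exactly 0.20 -> kept
  expect_false("c04" %in% kept_cells)   # above 0.20 -> removed
  expect_equal(res$report$genes_removed, 1)
  expect_equal(res$report$cells_removed_low_genes, 1)
  expect_equal(res$report$cells_removed_mito, 1)
})

test_that("qc_filter errors when every cell is removed", {
  m <- matrix(1L, 8, 10, dimnames = list(paste0("c", 1:8), paste0("g", 1:10)))
  expect_error(qc_filter(dense_atlas(m)), "all cells removed")
})

test_that("qc_filter is stable under re-application on simulated data", {
  sim <- generate_atlas(two_parent_cfg(5, n_per_sample = 150))
  once <- qc_filter(sim$atlas, min_genes_per_cell = 50)$atlas
  twice <- qc_filter(once, min_genes_per_cell = 50)$atlas
  expect_identical(as.matrix(once$counts), as.matrix(twice$counts))
})

test_that("normalization reproduces the log-CP10K formula entrywise", {
  m <- rbind(c(1, 3, 0),
             c(2, 2, 6),
             c(10000, 0, 0))
  dimnames(m) <- list(paste0("c", 1:3), paste0("g", 1:3))
  at <- normalize_cp10k(dense_atlas(m))
  Y <- as.matrix(at$norm)
  expect_equal(Y["c1", ], c(g1 = log(2501), g2 = log(7501), g3 = 0),
               tolerance = 1e-12)
  expect_equal(Y["c1", "g1"], 7.82445, tolerance = 1e-5)
  expect_equal(Y["c1", "g2"], 8.92280, tolerance = 1e-5)
  # a cell whose total is exactly 10000: the scale factor cancels
  expect_equal(Y["c3", "g1"], log(10000 + 1))
  # raw layer untouched, re-running is idempotent
  expect_identical(as.matrix(at$counts), m)
  expect_identical(as.matrix(normalize_cp10k(at)$norm), Y)
})

test_that("per-cell de-logged normalized values always sum to 10000", {
  sim <- generate_atlas(two_parent_cfg(6, n_per_sample = 50, n_genes = 120))
  at <- normalize_cp10k(sim$atlas)
  sums <- Matrix::rowSums(expm1(as.matrix(at$norm)))
  expect_true(all(abs(sums - 1e4) / 1e4 < 1e-6))
})

test_that("an all-zero gene normalizes to an all-zero column", {
  m <- cbind(a = c(1, 2), b = c(0, 0), c = c(3, 4))
  rownames(m) <- c("c1", "c2")
  at <- normalize_cp10k(dense_atlas(m))
  expect_equal(as.numeric(at$norm[, "b"]), c(0, 0))
})

test_that("all-zero cells are rejected by name", {
  m <- rbind(c1 = c(1, 2), deadcell = c(0, 0))
  colnames(m) <- c("g1", "g2")
  expect_error(normalize_cp10k(dense_atlas(m)), "deadcell")
})

test_that("dispersion is sample variance over mean of log counts", {
  m <- matrix(1L, 4, 3, dimnames = list(paste0("c", 1:4),
                                        c("flat", "var", "low")))
  at <- dense_atlas(m)
  # inject a known normalized layer directly
  at$norm <- Matrix::Matrix(cbind(flat = c(2, 2, 2, 2),
                                  var = c(0, 2, 0, 2),
                                  low = c(0, 0.1, 0, 0)), sparse = TRUE)
  dimnames(at$norm) <- dimnames(m)
  at$cells$sample <- "s1"
  hv <- select_hvgs_per_sample(at, top_n = 2)
  # var gene: variance (n-1) = 4/3, mean 1 -> dispersion 1.3333; flat gene: 0
  disp_var <- var(c(0, 2, 0, 2)) / 1
  expect_equal(disp_var, 4 / 3)
  expect_equal(hv$s1, c("var", "low"))   # constant gene never beats variable ones
})

test_that("samples with disjoint variable genes give disjoint HVG sets", {
  set.seed(10)
  n <- 40
  m <- matrix(rpois(2 * n * 20, 1), 2 * n, 20,
              dimnames = list(paste0("c", 1:(2 * n)), paste0("g", 1:20)))
  # sample 1 varies on genes 1:5 only, sample 2 on genes 6:10 only
  m[1:n, 1:5] <- rpois(n * 5, 8) * rbinom(n * 5, 1, 0.5)
  m[1:n, 6:20] <- 1
  m[(n + 1):(2 * n), 6:10] <- rpois(n * 5, 8) * rbinom(n * 5, 1, 0.5)
  m[(n + 1):(2 * n), c(1:5, 11:20)] <- 1
  at <- normalize_cp10k(dense_atlas(m))
  at$cells$sample <- rep(c("sa", "sb"), each = n)
  hv <- select_hvgs_per_sample(at, top_n = 5)
  expect_setequal(hv$sa, paste0("g", 1:5))
  expect_setequal(hv$sb, paste0("g", 6:10))
  expect_length(intersect(hv$sa, hv$sb), 0)
})

test_that("undersized samples are skipped with a warning", {
  sim <- generate_atlas(two_parent_cfg(8, n_per_sample = 30, n_genes = 60))
  at <- normalize_cp10k(sim$atlas)
  at$cells$sample[1:2] <- "tiny"
  expect_warning(hv <- select_hvgs_per_sample(at, top_n = 10), "tiny")
  expect_false("tiny" %in% names(hv))
})

test_that("union_features keeps genes present in enough samples, in gene order", {
  sets <- list(A = c("g1", "g2", "g3"), B = c("g2", "g3", "g4"), C = "g5")
  expect_equal(union_features(sets, 2, gene_order = paste0("g", 1:9)),
               c("g2", "g3"))
  expect_equal(union_features(list(A = c("g1", "g2")), 2), character(0))
  expect_setequal(union_features(sets, 1), c("g1", "g2", "g3", "g4", "g5"))
})

test_that("per-sample HVGs match a brute-force dispersion ranking", {
  sim <- generate_atlas(two_parent_cfg(12, n_per_sample = 80, n_genes = 300))
  at <- normalize_cp10k(sim$atlas)
  hv <- select_hvgs_per_sample(at, top_n = 40)
  for (smp in names(hv)) {
    Y <- as.matrix(at$norm[at$cells$sample == smp, ])
    mu <- colMeans(Y)
    disp <- ifelse(mu > 0, apply(Y, 2, var) / mu, -Inf)
    ord <- order(-disp, seq_along(disp))
    expect_identical(hv[[smp]], colnames(Y)[ord[1:40]])
  }
})

test_that("three-step feature selection nests its stages consistently", {
  sim <- generate_atlas(two_parent_cfg(12, n_per_sample = 80, n_genes = 300))
  at <- normalize_cp10k(sim$atlas)
  fs <- select_features(at, top_n = 60, min_samples = 2)
  expect_true(all(fs$final_features %in% unique(unlist(fs$correlated_genes))))
  for (s in names(fs$correlated_genes))
    expect_true(all(fs$correlated_genes[[s]] %in% fs$per_sample_hvgs[[s]]))
  # every final feature was extracted in at least two samples
  occ <- table(unlist(lapply(fs$correlated_genes, unique)))
  expect_true(all(occ[fs$final_features] >= 2))
  # feature order follows matrix gene order
  expect_identical(fs$final_features,
                   colnames(at$counts)[colnames(at$counts) %in% fs$final_features])
})

# naive dense reimplementation of control-bin scoring, drawing the same
# seeded control samples
score_oracle <- function(at, gene_set, n_bins, ctrl_size, seed) {
  Y <- as.matrix(at$norm)
  avg <- colMeans(Y)
  n_items <- ceiling(length(avg) / n_bins)
  bin <- (rank(avg, ties.method = "min") - 1) %/% n_items
  set.seed(seed)
  ctrl <- character(0)
  for (g in gene_set) {
    pool <- setdiff(colnames(Y)[bin == bin[[which(colnames(Y) == g)]]], gene_set)
    if (!length(pool)) next
    ctrl <- c(ctrl, pool[sample.int(length(pool), min(ctrl_size, length(pool)))])
  }
  ctrl <- unique(ctrl)
  rowMeans(Y[, gene_set, drop = FALSE]) -
    (if (length(ctrl)) rowMeans(Y[, ctrl, drop = FALSE]) else 0)
}

test_that("control-bin scores separate program cells and match a brute-force oracle", {
  sim <- generate_atlas(two_parent_cfg(13, n_per_sample = 100))
  at <- normalize_cp10k(sim$atlas)
  progA <- sprintf("G%04d", 1:20)
  sc <- score_gene_set(at, progA, seed = 21)
  is_A <- at$cells$parent_cluster == "A" & !sim$truth$cells$is_doublet
  is_B <- at$cells$parent_cluster == "B" & !sim$truth$cells$is_doublet
  expect_gt(mean(sc$scores[is_A]), mean(sc$scores[is_B]))
  oracle <- score_oracle(at, sc$gene_set, 25, 50, seed = 21)
  expect_equal(unname(sc$scores), unname(oracle), tolerance = 1e-12)
})

test_that("scoring is seed-reproducible and leaves the global RNG alone", {
  sim <- generate_atlas(two_parent_cfg(14, n_per_sample = 40, n_genes = 200))
  at <- normalize_cp10k(sim$atlas)
  set.seed(1); before <- runif(1)
  set.seed(1)
  s1 <- score_gene_set(at, sprintf("G%04d", 1:10), seed = 5)
  after <- runif(1)
  s2 <- score_gene_set(at, sprintf("G%04d", 1:10), seed = 5)
  expect_identical(s1$scores, s2$scores)
  expect_identical(before, after)
})

test_that("uniform expression yields a zero score for every cell", {
  m <- matrix(5L, 10, 40, dimnames = list(paste0("c", 1:10),
                                          paste0("g", 1:40)))
  at <- normalize_cp10k(dense_atlas(m))
  sc <- score_gene_set(at, paste0("g", 1:5), n_bins = 2, seed = 3)
  expect_equal(unname(sc$scores), rep(0, 10), tolerance = 1e-12)
})

test_that("scoring an absent gene set is an error", {
  sim <- generate_atlas(two_parent_cfg(15, n_per_sample = 20, n_genes = 50))
  at <- normalize_cp10k(sim$atlas)
  expect_error(score_gene_set(at, c("NOPE1", "NOPE2")), "no genes")
})

test_that("regression + scaling matches a per-gene OLS oracle", {
  set.seed(77)
  n <- 20; G <- 5
  m <- matrix(rpois(n * G, 5) + 1L, n, G,
              dimnames = list(paste0("c", 1:n), paste0("g", 1:G)))
  at <- normalize_cp10k(dense_atlas(m))
  cov <- cbind(s = rnorm(n), g2m = rnorm(n))
  at <- regress_out_and_scale(at, cov, clip = 10)
  Y <- as.matrix(at$norm)
  oracle <- sapply(seq_len(G), function(j) {
    r <- residuals(lm(Y[, j] ~ cov))
    z <- r / sd(r)
    pmin(pmax(z, -10), 10)
  })
  expect_equal(unname(at$scaled), unname(oracle), tolerance = 1e-8)
})

test_that("regression handles orthogonal, degenerate and collinear covariates", {
  n <- 12
  cov <- matrix(rep(c(-1, 1), each = n / 2), ncol = 1)
  Y <- cbind(lin = 3 + 2 * cov[, 1],         # exactly linear in the covariate
             indep = rep(c(1, 2), n / 2))    # orthogonal to it
  m <- matrix(1L, n, 2, dimnames = list(paste0("c", 1:n), colnames(Y)))
  at <- dense_atlas(m)
  at$norm <- Matrix::Matrix(Y, sparse = TRUE)
  dimnames(at$norm) <- dimnames(m)
  at <- regress_out_and_scale(at, cov)
  # gene exactly linear in the covariate: residuals and scaled values all 0
  expect_equal(unname(at$scaled[, "lin"]), rep(0, n))
  # orthogonal gene: scaled values are the z-scored centered expression
  centered <- Y[, "indep"] - mean(Y[, "indep"])
  expect_equal(unname(at$scaled[, "indep"]), unname(centered / sd(centered)),
               tolerance = 1e-10)
  expect_error(regress_out_and_scale(at, cbind(1:n, 2 * (1:n))), "collinear")
})

test_that("scaled values are clipped at the configured bound", {
  set.seed(3)
  n <- 100
  m <- matrix(rpois(n * 3, 3) + 1L, n, 3,
              dimnames = list(paste0("c", 1:n), paste0("g", 1:3)))
  m[1, 1] <- 5000L   # extreme outlier
  at <- regress_out_and_scale(normalize_cp10k(dense_atlas(m)), NULL, clip = 2)
  expect_lte(max(at$scaled), 2)
  expect_gte(min(at$scaled), -2)
})
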