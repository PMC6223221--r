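small_cfg <- function(seed = 101L, ...) {
  simulation_config(n_genes = 4L, genes_per_chrom = 2L, seed = seed,
                    replicates_per_stage = 2L,
                    stages = c("ICM", "post"), stage_means = c(0.3, 0.75),
                    ...)
}

test_that("the generator is deterministic under a fixed seed", {
  s1 <- simulate_methylome(small_cfg())
  s2 <- simulate_methylome(small_cfg())
  expect_identical(as.character(s1$genome), as.character(s2$genome))
  expect_identical(s1$calls, s2$calls)
  expect_identical(s1$expression, s2$expression)
  # written artifacts are byte-identical too
  d1 <- file.path(tempdir(), "sim1"); d2 <- file.path(tempdir(), "sim2")
  simulate_methylome(small_cfg(), outdir = d1)
  simulate_methylome(small_cfg(), outdir = d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_true(length(f1) > 5)
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
  }
  # a different seed changes the draws
  s3 <- simulate_methylome(small_cfg(seed = 102L))
  expect_false(identical(s1$calls, s3$calls))
})

test_that("an empty simulation still produces valid structures", {
  sim <- simulate_methylome(simulation_config(n_genes = 0L))
  expect_equal(nrow(sim$genes), 0L)
  expect_equal(nrow(sim$expression), 0L)
  expect_true(all(vapply(sim$calls, nrow, 0L) == 0L))
  expect_equal(length(sim$truth$transition_genes), 0L)
  d <- file.path(tempdir(), "sim0")
  out <- simulate_methylome(simulation_config(n_genes = 0L), outdir = d)
  expect_true(file.exists(out$paths$manifest))
})

test_that("every CpG in the synthetic genome is a designed call site", {
  sim <- simulate_methylome(small_cfg())
  for (ch in names(sim$chrom_lengths)) {
    scanned <- cpg_positions(sim$genome, ch)
    designed <- sort(unique(sim$calls[[1]]$pos[sim$calls[[1]]$chrom == ch]))
    expect_identical(scanned, as.integer(designed))
  }
  # call tables parse back through the reader
  d <- file.path(tempdir(), "simio")
  out <- simulate_methylome(small_cfg(), outdir = d)
  mf <- read_manifest(out$paths$manifest, stages = c("ICM", "post"))
  calls <- read_cpg_calls(mf$path[1], coverage_min = 5)
  expect_gt(nrow(calls), 100)
  expect_true(all(calls$coverage >= 5))
  genes <- read_gene_models(out$paths$genes)
  expect_equal(genes$gene_id, sim$genes$gene_id)
  expect_equal(genes$exon_starts, sim$genes$exon_starts)
})

test_that("designed promoter CpG-density profile peaks at bin 1", {
  sim <- simulate_methylome(simulation_config(n_genes = 10L, seed = 5L,
                                              stages = c("ICM", "post"),
                                              stage_means = c(0.3, 0.75),
                                              replicates_per_stage = 1L))
  bins <- make_bins(sim$genes, chrom_lengths = sim$chrom_lengths)
  counts <- count_bin_cpgs(bins, cpg_sites(sim$genome))
  per_bin <- tapply(counts$cpg_count, counts$bin, mean)
  expect_equal(as.integer(names(which.max(per_bin))), 1L)
  # designed density classes: outermost upstream bins LCG, TSS block HCG
  cls <- classify_density(per_bin)
  expect_equal(as.character(cls[c("-10", "-9")]), c("LCG", "LCG"))
  expect_true(all(cls[c("-2", "-1", "1", "2", "3", "4")] == "HCG"))
})

test_that("noise-free methylation equals the designed level exactly", {
  sim <- simulate_methylome(small_cfg(noise_sd = 0, meth_gene_sd = 0,
                                      n_transition = 2L))
  # transition genes carry the designed constant across all their CpGs
  tg <- sim$truth$transition_genes[1]
  g <- sim$genes[sim$genes$gene_id == tg, ]
  icm <- sim$calls[["ICM_r1"]]
  on_gene <- icm$chrom == g$chrom & icm$pos >= g$tx_start - 20000 &
    icm$pos < g$tx_end + 20000
  expect_true(all(icm$meth_level[on_gene] == 0.05))
  post <- sim$calls[["post_r1"]]
  expect_true(all(post$meth_level[on_gene] == 0.95))
})

test_that("region-level fast rendering mirrors the design", {
  cfg <- simulation_config(n_genes = 300L, seed = 31L)
  fast1 <- simulate_region_levels(cfg)
  fast2 <- simulate_region_levels(cfg)
  expect_identical(fast1$regions$meth, fast2$regions$meth)
  expect_equal(dim(fast1$regions$meth), c(300L, 12L, 21L))
  expect_equal(dim(fast1$bins$meth), c(300L, 20L, 21L))
  expect_true(all(fast1$regions$meth >= 0 & fast1$regions$meth <= 1))
  # designed correlation signs are recovered on one rendering
  ss <- stage_average(fast1$regions, fast1$manifest)
  cr <- stage_correlation(ss, fast1$expr_mat)
  mean_r <- tapply(cr$r, cr$label, mean)
  strong <- names(which(abs(cfg$designed_r) >= 0.3))
  expect_true(all(sign(mean_r[strong]) ==
                    sign(cfg$designed_r[strong])))
})
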