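simple_annotation <- function() {
  data.frame(gene_id = "G1",
             region = factor(c("up2", "exon"), levels = region_labels()),
             chrom = "chr1", start = c(0L, 1000L), end = c(1000L, 2000L),
             strand = "+")
}

test_that("region methylation is the unweighted mean of in-region CpGs", {
  ann <- simple_annotation()
  calls <- calls_fixture(c(10L, 20L, 30L), c(0.2, 0.4, 0.6))
  rm <- region_methylation(calls, ann)
  up2 <- rm[rm$label == "up2", ]
  expect_equal(up2$meth, 0.4)
  expect_equal(up2$n_cpg, 3L)
  # a region with no covered CpG is missing, not zero
  exon <- rm[rm$label == "exon", ]
  expect_true(is.na(exon$meth))
  expect_equal(exon$n_cpg, 0L)
  # every label of the vocabulary appears even when empty
  expect_setequal(rm$label, region_labels())
})

test_that("interval membership is half-open at both region boundaries", {
  ann <- simple_annotation()
  calls <- calls_fixture(c(0L, 999L, 1000L), c(1, 1, 0))
  rm <- region_methylation(calls, ann)
  # 0 and 999 inside up2 = [0, 1000); 1000 excluded from up2, starts exon
  expect_equal(rm[rm$label == "up2", "n_cpg"], 2L)
  expect_equal(rm[rm$label == "exon", "n_cpg"], 1L)
})

test_that("aggregation matches a brute-force interval-scan oracle", {
  set.seed(23)
  genes <- do.call(rbind, lapply(1:30, function(i)
    random_gene_fixture(paste0("G", i))))
  ann <- partition_regions(genes)
  bins <- make_bins(genes)
  calls <- calls_fixture(sort(sample(seq(0L, 250000L, 2L), 4000)),
                         runif(4000))
  for (a in list(ann, bins)) {
    got <- region_methylation(calls, a)
    want <- oracle_region_means(calls, a)
    key <- paste(got$gene_id, got$label)
    wkey <- paste(want$gene_id, want$label)
    ord <- match(key, wkey)
    # labels with no genomic extent for a gene are absent from the oracle's
    # annotation scan and must be empty cells here
    expect_true(all(is.na(got$meth[is.na(ord)])))
    expect_true(all(got$n_cpg[is.na(ord)] == 0L))
    has <- !is.na(ord)
    expect_equal(got$meth[has], want$meth[ord[has]], tolerance = 1e-12)
    expect_equal(got$n_cpg[has], want$n_cpg[ord[has]])
  }
})

test_that("aggregation is invariant to CpG and sample order", {
  set.seed(31)
  genes <- random_gene_fixture("G1")
  ann <- partition_regions(genes)
  calls <- calls_fixture(sort(sample(seq(0L, 250000L, 2L), 500)),
                         runif(500))
  shuffled <- calls[sample(nrow(calls)), ]
  a <- region_methylation(calls, ann)
  b <- region_methylation(shuffled, ann)
  expect_equal(a, b)
  m1 <- methylation_matrix(list(s1 = calls, s2 = shuffled), ann)
  expect_equal(m1$meth[, , "s1"], m1$meth[, , "s2"])
  # values bounded by the contributing call levels
  ok <- !is.na(a$meth)
  expect_true(all(a$meth[ok] >= min(calls$meth_level) - 1e-12))
  expect_true(all(a$meth[ok] <= max(calls$meth_level) + 1e-12))
})

two_stage_matrix <- function(values) {
  # values: list sample_id -> named gene vector for one label
  genes <- names(values[[1]])
  meth <- array(unlist(values), dim = c(length(genes), 1, length(values)),
                dimnames = list(genes, "gene", names(values)))
  n <- array(ifelse(is.na(meth), 0L, 5L), dim = dim(meth),
             dimnames = dimnames(meth))
  structure(list(meth = meth, n_cpg = n, genes = genes, labels = "gene",
                 samples = names(values)), class = "meth_matrix")
}

test_that("stage averaging uses present replicates and unweighted genes", {
  m <- two_stage_matrix(list(
    a1 = c(g1 = 0.2, g2 = 0.2, g3 = 0.1),
    a2 = c(g1 = 0.4, g2 = NA, g3 = 0.3),
    b1 = c(g1 = 0.1, g2 = 0.2, g3 = 0.6)
  ))
  mf <- data.frame(sample_id = c("a1", "a2", "b1"),
                   stage = factor(c("A", "A", "B"), levels = c("A", "B")),
                   replicate = c(1L, 2L, 1L), path = NA)
  ss <- stage_average(m, mf)
  # replicates [0.2, 0.4] -> 0.3; [0.2, NA] -> 0.2
  expect_equal(ss$meth["g1", "gene", "A"], 0.3)
  expect_equal(ss$meth["g2", "gene", "A"], 0.2)
  expect_equal(ss$n_rep["g2", "gene", "A"], 1L)
  # genome level = mean over genes of per-gene stage values
  expect_equal(ss$global$mean[ss$global$stage == "B"], mean(c(0.1, 0.2, 0.6)))
  # a stage without samples errors
  mf2 <- mf
  levels(mf2$stage) <- c("A", "B", "C")
  expect_error(stage_average(m, mf2), "stage has no samples: C")
  # unknown samples error
  expect_error(stage_average(m, mf[1:2, ]), "not in manifest")
})

test_that("per-chromosome summaries follow the same averaging", {
  m <- two_stage_matrix(list(a1 = c(g1 = 0.2, g2 = 0.4, g3 = 0.9)))
  mf <- data.frame(sample_id = "a1", stage = factor("A"), replicate = 1L,
                   path = NA)
  ss <- stage_average(m, mf, gene_chrom = c(g1 = "chr1", g2 = "chr1",
                                            g3 = "chr2"))
  pc <- ss$per_chrom
  expect_equal(pc$mean[pc$chrom == "chr1"], 0.3)
  expect_equal(pc$mean[pc$chrom == "chr2"], 0.9)
})

test_that("methylated-bin counting needs a covered CpG with level > eps", {
  genes <- c("g1", "g2", "g3")
  meth <- array(c(0, 0.5, NA), dim = c(3, 1, 1),
                dimnames = list(genes, "1", "s1"))
  n <- array(c(3L, 2L, 0L), dim = c(3, 1, 1),
             dimnames = dimnames(meth))
  m <- structure(list(meth = meth, n_cpg = n, genes = genes, labels = "1",
                      samples = "s1"), class = "meth_matrix")
  mb <- methylated_bin_counts(m)
  expect_equal(mb$n_methylated, 1L)
  expect_equal(mb$mean_meth, 0.5)
  # all missing -> zero; all fully methylated -> every gene, mean 1
  m$meth[] <- NA; m$n_cpg[] <- 0L
  expect_equal(methylated_bin_counts(m)$n_methylated, 0L)
  m$meth[] <- 1; m$n_cpg[] <- 4L
  full <- methylated_bin_counts(m)
  expect_equal(full$n_methylated, 3L)
  expect_equal(full$mean_meth, 1)
})
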