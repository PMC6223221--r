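test_that("transcript selection keeps one mature mRNA per gene and TSS", {
  tab <- rbind(
    gene_fixture("geneA", "NM_002", tx_start = 100L, tx_end = 1000L),
    gene_fixture("geneA", "NM_001", tx_start = 100L, tx_end = 1200L),
    gene_fixture("geneB", "NR_100", tx_start = 50L, tx_end = 900L),
    gene_fixture("geneC", "NM_7", tx_start = 10L, tx_end = 800L),
    gene_fixture("geneD", "NM_8", tx_start = 10L, tx_end = 700L)
  )
  sel <- select_transcripts(tab)
  # same gene, same TSS: lexicographically smallest accession wins
  expect_equal(sel$transcript_id[sel$gene_id == "geneA"], "NM_001")
  # non-NM accessions are excluded outright
  expect_false("geneB" %in% sel$gene_id)
  # distinct genes sharing a TSS are never merged
  expect_setequal(sel$gene_id, c("geneA", "geneC", "geneD"))
  # a gene with two distinct TSSs keeps both models
  two_tss <- rbind(
    gene_fixture("geneE", "NM_10", tx_start = 100L, tx_end = 1000L),
    gene_fixture("geneE", "NM_11", tx_start = 400L, tx_end = 1000L)
  )
  expect_equal(nrow(select_transcripts(two_tss)), 2L)
  # TSS of a minus-strand transcript is tx_end, not tx_start
  minus <- rbind(
    gene_fixture("geneF", "NM_20", strand = "-", tx_start = 100L,
                 tx_end = 1000L),
    gene_fixture("geneF", "NM_21", strand = "-", tx_start = 300L,
                 tx_end = 1000L)
  )
  expect_equal(nrow(select_transcripts(minus)), 1L)
  expect_warning(select_transcripts(tab[0, ]), "no gene models")
})

test_that("alternate mature-mRNA prefixes are configurable", {
  tab <- gene_fixture("g", "XM_5", tx_start = 0L, tx_end = 100L)
  expect_equal(nrow(select_transcripts(tab)), 0L)
  expect_equal(nrow(select_transcripts(tab, mrna_prefix = "XM_")), 1L)
})

region_iv <- function(reg, label) {
  r <- reg[reg$region == label, c("start", "end"), drop = FALSE]
  r[order(r$start), , drop = FALSE]
}

test_that("flank regions follow the strand-aware coordinate convention", {
  plus <- gene_fixture(tx_start = 100000L, tx_end = 106000L)
  reg <- partition_regions(plus)
  expect_equal(unlist(region_iv(reg, "up2"), use.names = FALSE),
               c(98000L, 100000L))
  expect_equal(unlist(region_iv(reg, "up5"), use.names = FALSE),
               c(95000L, 98000L))
  expect_equal(unlist(region_iv(reg, "up10"), use.names = FALSE),
               c(90000L, 95000L))
  expect_equal(unlist(region_iv(reg, "up20"), use.names = FALSE),
               c(80000L, 90000L))
  expect_equal(unlist(region_iv(reg, "down2"), use.names = FALSE),
               c(106000L, 108000L))
  expect_equal(unlist(region_iv(reg, "down20"), use.names = FALSE),
               c(116000L, 126000L))
  # minus strand: TSS = tx_end = 100000, upstream means larger coordinates
  minus <- gene_fixture(strand = "-", tx_start = 94000L, tx_end = 100000L)
  regm <- partition_regions(minus)
  expect_equal(unlist(region_iv(regm, "up2"), use.names = FALSE),
               c(100000L, 102000L))
  expect_equal(unlist(region_iv(regm, "down2"), use.names = FALSE),
               c(92000L, 94000L))
  expect_equal(levels(reg$region), region_labels())
})

test_that("gene body splits into UTRs, CDS exon and intron by definition", {
  g <- gene_fixture(tx_start = 0L, tx_end = 1000L, cds_start = 200L,
                    cds_end = 800L, exon_starts = list(0L),
                    exon_ends = list(1000L))
  reg <- partition_regions(g)
  expect_equal(unlist(region_iv(reg, "5UTR"), use.names = FALSE),
               c(0L, 200L))
  expect_equal(unlist(region_iv(reg, "exon"), use.names = FALSE),
               c(200L, 800L))
  expect_equal(unlist(region_iv(reg, "3UTR"), use.names = FALSE),
               c(800L, 1000L))
  expect_equal(nrow(region_iv(reg, "intron")), 0L)
  # non-coding model: CDS-derived regions empty, introns = intra-gene gaps
  nc <- gene_fixture(tx_start = 0L, tx_end = 1000L, cds_start = 500L,
                     cds_end = 500L,
                     exon_starts = list(c(0L, 600L)),
                     exon_ends = list(c(400L, 1000L)))
  expect_message(regn <- partition_regions(nc), "non-coding")
  expect_equal(nrow(region_iv(regn, "5UTR")), 0L)
  expect_equal(nrow(region_iv(regn, "exon")), 0L)
  expect_equal(unlist(region_iv(regn, "intron"), use.names = FALSE),
               c(400L, 600L))
})

test_that("the four gene-body regions partition [tx_start, tx_end)", {
  set.seed(42)
  for (i in 1:20) {
    g <- random_gene_fixture(paste0("G", i))
    reg <- partition_regions(g)
    body <- reg[reg$region %in% c("5UTR", "exon", "intron", "3UTR"), ]
    body <- body[order(body$start), ]
    expect_equal(body$start[1], g$tx_start)
    expect_equal(body$end[nrow(body)], g$tx_end)
    # contiguous and non-overlapping
    expect_true(all(body$start[-1] == body$end[-nrow(body)]))
    expect_equal(sum(body$end - body$start), g$tx_end - g$tx_start)
  }
})

test_that("promoter bins tile TSS +/- 2 kb with bin 1 abutting the TSS", {
  g <- gene_fixture(tx_start = 10000L, tx_end = 16000L)
  b <- make_bins(g)
  expect_equal(nrow(b), 20L)
  expect_setequal(b$bin, bin_indices())
  b1 <- b[b$bin == 1L, ]
  expect_equal(c(b1$start, b1$end), c(10000L, 10200L))
  expect_equal(b[b$bin == -1L, ]$end, 10000L)
  # the -4..6 block spans 800 bp upstream to 1200 bp downstream of the TSS
  expect_equal(b[b$bin == -4L, ]$start, 9200L)
  expect_equal(b[b$bin == 6L, ]$end, 11200L)
  # jointly cover [TSS - 2000, TSS + 2000), pairwise disjoint
  bo <- b[order(b$start), ]
  expect_equal(bo$start[1], 8000L)
  expect_equal(bo$end[20], 12000L)
  expect_true(all(bo$start[-1] == bo$end[-20]))
  # minus strand mirror: bin 1 immediately upstream in genome coordinates
  gm <- gene_fixture(strand = "-", tx_start = 4000L, tx_end = 10000L)
  bm <- make_bins(gm)
  bm1 <- bm[bm$bin == 1L, ]
  expect_equal(c(bm1$start, bm1$end), c(9800L, 10000L))
})

test_that("strand reversal reflects every bin about the TSS", {
  set.seed(7)
  for (i in 1:10) {
    t <- sample(50000:80000, 1)
    plus <- gene_fixture("p", tx_start = t, tx_end = t + 5000L)
    minus <- gene_fixture("m", strand = "-", tx_start = t - 5000L,
                          tx_end = t)
    bp <- make_bins(plus)
    bm <- make_bins(minus)
    for (k in bin_indices()) {
      ip <- bp[bp$bin == k, ]
      im <- bm[bm$bin == k, ]
      expect_equal(im$start, 2L * t - ip$end)
      expect_equal(im$end, 2L * t - ip$start)
    }
  }
})

test_that("bins near a chromosome edge are clipped and flagged partial", {
  g <- gene_fixture(tx_start = 900L, tx_end = 5900L)
  expect_message(b <- make_bins(g, chrom_lengths = c(chr1 = 100000L)),
                 "clipped")
  expect_true(all(b$start >= 0L))
  expect_lt(nrow(b), 20L)              # fully out-of-range bins dropped
  expect_true(any(b$partial))
  expect_equal(min(b[b$partial, "start"]), 0L)
})

test_that("gene tables round-trip through the refFlat reader", {
  set.seed(11)
  genes <- do.call(rbind, lapply(1:5, function(i)
    random_gene_fixture(paste0("G", i))))
  path <- tempfile(fileext = ".tsv")
  rows <- vapply(seq_len(nrow(genes)), function(i) {
    paste(genes$gene_id[i], genes$transcript_id[i], genes$chrom[i],
          genes$strand[i], genes$tx_start[i], genes$tx_end[i],
          genes$cds_start[i], genes$cds_end[i],
          length(genes$exon_starts[[i]]),
          paste0(paste(genes$exon_starts[[i]], collapse = ","), ","),
          paste0(paste(genes$exon_ends[[i]], collapse = ","), ","),
          sep = "\t")
  }, "")
  writeLines(rows, path)
  back <- read_gene_models(path)
  expect_equal(back$gene_id, genes$gene_id)
  expect_equal(back$tx_start, genes$tx_start)
  expect_equal(back$exon_starts, genes$exon_starts)
  # malformed row (non-numeric coordinates) is skipped with a message
  bad <- paste("gX", "NM_X", "chr1", "+", "notanumber", "200", "0", "0",
               "1", "0,", "200,", sep = "\t")
  writeLines(c(rows, bad), path)
  expect_message(back2 <- read_gene_models(path), "malformed")
  expect_equal(nrow(back2), 5L)
})
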