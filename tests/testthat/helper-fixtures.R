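# in-code fixture builders shared across test files

# one-row gene-model data frame with exon list columns
gene_fixture <- function(gene_id = "G1", transcript_id = "NM_1",
                         chrom = "chr1", strand = "+",
                         tx_start = 100000L, tx_end = 106000L,
                         cds_start = tx_start + 500L,
                         cds_end = tx_end - 500L,
                         exon_starts = list(tx_start),
                         exon_ends = list(tx_end)) {
  g <- data.frame(gene_id = gene_id, transcript_id = transcript_id,
                  chrom = chrom, strand = strand,
                  tx_start = tx_start, tx_end = tx_end,
                  cds_start = cds_start, cds_end = cds_end)
  g$exon_starts <- exon_starts
  g$exon_ends <- exon_ends
  g
}

# random multi-exon coding gene on a given strand
random_gene_fixture <- function(gene_id, chrom = "chr1",
                                strand = sample(c("+", "-"), 1)) {
  tx_start <- sample(30000:200000, 1)
  n_exon <- sample(1:4, 1)
  # exon lengths and intron gaps
  ex_len <- sample(200:1500, n_exon, replace = TRUE)
  gaps <- if (n_exon > 1) sample(100:2000, n_exon - 1, replace = TRUE)
          else integer(0)
  starts <- tx_start + cumsum(c(0L, head(ex_len, -1) + gaps))
  ends <- starts + ex_len
  tx_end <- ends[n_exon]
  cds_start <- starts[1] + min(100L, ex_len[1] - 1L)
  cds_end <- ends[n_exon] - min(100L, ex_len[n_exon] - 1L)
  gene_fixture(gene_id = gene_id, transcript_id = paste0("NM_", gene_id),
               chrom = chrom, strand = strand,
               tx_start = tx_start, tx_end = tx_end,
               cds_start = cds_start, cds_end = cds_end,
               exon_starts = list(as.integer(starts)),
               exon_ends = list(as.integer(ends)))
}

# calls data frame in the shape read_cpg_calls() returns
calls_fixture <- function(pos, meth_level, chrom = "chr1", coverage = 10L) {
  data.frame(chrom = chrom, pos = as.integer(pos), strand = "+",
             meth_level = meth_level,
             coverage = rep_len(coverage, length(pos)))
}

# write a call table to a temp file and return the path
write_calls_file <- function(rows) {
  path <- tempfile(fileext = ".tsv")
  write.table(rows, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  path
}

# brute-force oracle: mean methylation per (gene, label) by direct scan
oracle_region_means <- function(calls, annotation) {
  lab_col <- if ("region" %in% names(annotation)) "region" else "bin"
  keys <- unique(annotation[, c("gene_id", lab_col)])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    iv <- annotation[annotation$gene_id == keys$gene_id[i] &
                       annotation[[lab_col]] == keys[[lab_col]][i], ,
                     drop = FALSE]
    hit <- rep(FALSE, nrow(calls))
    for (j in seq_len(nrow(iv))) {
      hit <- hit | (calls$chrom == iv$chrom[j] &
                      calls$pos >= iv$start[j] & calls$pos < iv$end[j])
    }
    data.frame(gene_id = keys$gene_id[i],
               label = as.character(keys[[lab_col]][i]),
               meth = if (any(hit)) mean(calls$meth_level[hit]) else NA_real_,
               n_cpg = sum(hit))
  })
  do.call(rbind, out)
}
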