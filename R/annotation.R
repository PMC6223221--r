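#' Read gene models from a refFlat or BED12 table
#'
#' Parses a transcript table into the gene-model data frame used throughout
#' the package: one row per transcript with 0-based half-open coordinates and
#' exon structure held in list columns. Malformed rows (non-numeric
#' coordinates, `tx_start >= tx_end`, exon count mismatch) are skipped with a
#' message.
#'
#' @param path path to a tab-delimited refFlat file
#'   (geneName, name, chrom, strand, txStart, txEnd, cdsStart, cdsEnd,
#'   exonCount, exonStarts, exonEnds) or a BED12 file.
#' @param format `"refFlat"` (default) or `"bed12"`.
#' @return A `data.frame` with columns `gene_id`, `transcript_id`, `chrom`,
#'   `strand`, `tx_start`, `tx_end`, `cds_start`, `cds_end` and list columns
#'   `exon_starts`, `exon_ends`.
#' @export
read_gene_models <- function(path, format = c("refFlat", "bed12")) {
  format <- match.arg(format)
  dt <- fread(path, header = FALSE, sep = "\t", colClasses = "character")
  if (nrow(dt) == 0L) {
    warning("empty gene table: ", path)
    return(.empty_gene_models())
  }
  if (format == "refFlat") {
    g <- data.table(
      gene_id = dt[[1L]], transcript_id = dt[[2L]], chrom = dt[[3L]],
      strand = dt[[4L]],
      tx_start = suppressWarnings(as.integer(dt[[5L]])),
      tx_end = suppressWarnings(as.integer(dt[[6L]])),
      cds_start = suppressWarnings(as.integer(dt[[7L]])),
      cds_end = suppressWarnings(as.integer(dt[[8L]])),
      n_exon = suppressWarnings(as.integer(dt[[9L]]))
    )
    g$exon_starts <- lapply(strsplit(dt[[10L]], ",", fixed = TRUE),
                            function(x) as.integer(x))
    g$exon_ends <- lapply(strsplit(dt[[11L]], ",", fixed = TRUE),
                          function(x) as.integer(x))
  } else {
    # BED12: chrom start end name score strand thickStart thickEnd rgb
    #        blockCount blockSizes blockStarts; name = gene|transcript or
    #        transcript alone
    nm <- strsplit(dt[[4L]], "|", fixed = TRUE)
    start <- suppressWarnings(as.integer(dt[[2L]]))
    sizes <- lapply(strsplit(dt[[11L]], ",", fixed = TRUE), as.integer)
    offs <- lapply(strsplit(dt[[12L]], ",", fixed = TRUE), as.integer)
    g <- data.table(
      gene_id = vapply(nm, `[`, "", 1L),
      transcript_id = vapply(nm, function(x) x[min(2L, length(x))], ""),
      chrom = dt[[1L]], strand = dt[[6L]],
      tx_start = start,
      tx_end = suppressWarnings(as.integer(dt[[3L]])),
      cds_start = suppressWarnings(as.integer(dt[[7L]])),
      cds_end = suppressWarnings(as.integer(dt[[8L]])),
      n_exon = suppressWarnings(as.integer(dt[[10L]]))
    )
    g$exon_starts <- Map(function(s, o) s + o, start, offs)
    g$exon_ends <- Map(`+`, g$exon_starts, sizes)
  }
  ok <- !is.na(g$tx_start) & !is.na(g$tx_end) & g$tx_start < g$tx_end &
    g$strand %in% c("+", "-") &
    vapply(g$exon_starts, length, 0L) == g$n_exon &
    vapply(g$exon_ends, length, 0L) == g$n_exon
  ok[is.na(ok)] <- FALSE
  if (any(!ok)) {
    message(sum(!ok), " malformed gene-model row(s) skipped")
  }
  g <- g[ok]
  g$n_exon <- NULL
  as.data.frame(g)
}

.empty_gene_models <- function() {
  data.frame(
    gene_id = character(0), transcript_id = character(0),
    chrom = character(0), strand = character(0),
    tx_start = integer(0), tx_end = integer(0),
    cds_start = integer(0), cds_end = integer(0)
  ) -> d
  d$exon_starts <- list()
  d$exon_ends <- list()
  d
}

.tss <- function(genes) {
  ifelse(genes$strand == "+", genes$tx_start, genes$tx_end)
}

.tes <- function(genes) {
  ifelse(genes$strand == "+", genes$tx_end, genes$tx_start)
}

#' Select one representative transcript per gene and TSS
#'
#' Keeps only transcripts whose accession carries the mature-mRNA prefix
#' (RefSeq `"NM_"` by default) and collapses alternative transcripts that
#' share a gene and a transcription start site down to one, choosing the
#' lexicographically smallest transcript accession. Distinct TSSs of the same
#' gene are kept as separate models.
#'
#' @param genes gene-model data frame from [read_gene_models()].
#' @param mrna_prefix accession prefix identifying mature mRNA transcripts.
#' @return Gene-model data frame, one row per `(gene_id, TSS)`.
#' @export
select_transcripts <- function(genes, mrna_prefix = "NM_") {
  if (nrow(genes) == 0L) {
    warning("no gene models supplied")
    return(genes)
  }
  keep <- startsWith(genes$transcript_id, mrna_prefix)
  genes <- genes[keep, , drop = FALSE]
  if (nrow(genes) == 0L) return(genes)
  tss <- .tss(genes)
  key <- paste(genes$gene_id, genes$chrom, tss, sep = "\r")
  ord <- order(key, genes$transcript_id)
  genes <- genes[ord, , drop = FALSE]
  first <- !duplicated(key[ord])
  out <- genes[first, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# plain-vector set ops on half-open [start, end) interval lists; the lists
# here are tiny (per-gene exon structures), so this beats S4 dispatch
.interval_merge <- function(a) {
  a <- a[a$end > a$start, , drop = FALSE]
  if (nrow(a) <= 1L) return(a)
  o <- order(a$start, a$end)
  s <- a$start[o]; e <- a$end[o]
  keep_s <- s[1]; keep_e <- e[1]
  for (i in seq_along(s)[-1]) {
    if (s[i] <= keep_e[length(keep_e)]) {
      keep_e[length(keep_e)] <- max(keep_e[length(keep_e)], e[i])
    } else {
      keep_s <- c(keep_s, s[i]); keep_e <- c(keep_e, e[i])
    }
  }
  data.frame(start = keep_s, end = keep_e)
}

.interval_intersect <- function(a, b) {
  a <- a[a$end > a$start, , drop = FALSE]
  b <- .interval_merge(as.data.frame(b))
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  ss <- ee <- vector("list", nrow(a))
  for (i in seq_len(nrow(a))) {
    s <- pmax(a$start[i], b$start); e <- pmin(a$end[i], b$end)
    k <- e > s
    ss[[i]] <- s[k]; ee[[i]] <- e[k]
  }
  out <- data.frame(start = unlist(ss), end = unlist(ee))
  out[order(out$start), , drop = FALSE]
}

.interval_setdiff <- function(a, b) {
  a <- .interval_merge(as.data.frame(a))
  b <- .interval_merge(as.data.frame(b))
  if (nrow(a) == 0L) return(a)
  if (nrow(b) == 0L) return(a)
  ss <- ee <- vector("list", nrow(a))
  for (i in seq_len(nrow(a))) {
    cur_s <- a$start[i]
    seg_s <- integer(0); seg_e <- integer(0)
    for (j in seq_len(nrow(b))) {
      if (b$end[j] <= cur_s || b$start[j] >= a$end[i]) next
      if (b$start[j] > cur_s) {
        seg_s <- c(seg_s, cur_s); seg_e <- c(seg_e, b$start[j])
      }
      cur_s <- max(cur_s, b$end[j])
    }
    if (cur_s < a$end[i]) {
      seg_s <- c(seg_s, cur_s); seg_e <- c(seg_e, a$end[i])
    }
    ss[[i]] <- seg_s; ee[[i]] <- seg_e
  }
  data.frame(start = unlist(ss), end = unlist(ee))
}

.clip_intervals <- function(iv, chrom_len) {
  iv$start <- pmax(iv$start, 0L)
  if (!is.null(chrom_len) && !is.na(chrom_len)) {
    iv$end <- pmin(iv$end, as.integer(chrom_len))
  }
  iv[iv$end > iv$start, , drop = FALSE]
}

.partition_one <- function(g, flank_bp, chrom_len) {
  plus <- g$strand == "+"
  tss <- if (plus) g$tx_start else g$tx_end
  tes <- if (plus) g$tx_end else g$tx_start
  bounds <- c(0L, flank_bp)              # e.g. 0, 2000, 5000, 10000, 20000
  up_labels <- paste0("up", flank_bp / 1000L)
  down_labels <- paste0("down", flank_bp / 1000L)
  iv <- list()
  for (i in seq_along(flank_bp)) {
    if (plus) {
      iv[[up_labels[i]]] <- data.table(start = tss - bounds[i + 1L],
                                       end = tss - bounds[i])
      iv[[down_labels[i]]] <- data.table(start = tes + bounds[i],
                                         end = tes + bounds[i + 1L])
    } else {
      iv[[up_labels[i]]] <- data.table(start = tss + bounds[i],
                                       end = tss + bounds[i + 1L])
      iv[[down_labels[i]]] <- data.table(start = tes - bounds[i + 1L],
                                         end = tes - bounds[i])
    }
  }
  body <- data.table(start = g$tx_start, end = g$tx_end)
  exonic <- data.table(start = unlist(g$exon_starts),
                       end = unlist(g$exon_ends))
  coding <- !is.na(g$cds_start) && !is.na(g$cds_end) && g$cds_start < g$cds_end
  if (coding) {
    cds <- data.table(start = g$cds_start, end = g$cds_end)
    before <- data.table(start = g$tx_start, end = g$cds_start)
    after <- data.table(start = g$cds_end, end = g$tx_end)
    iv[["5UTR"]] <- .interval_intersect(exonic, if (plus) before else after)
    iv[["3UTR"]] <- .interval_intersect(exonic, if (plus) after else before)
    iv[["exon"]] <- .interval_intersect(exonic, cds)
  } else {
    empty <- data.table(start = integer(0), end = integer(0))
    iv[["5UTR"]] <- empty
    iv[["3UTR"]] <- empty
    iv[["exon"]] <- empty
  }
  iv[["intron"]] <- .interval_setdiff(body, exonic)
  out <- rbindlist(lapply(region_labels(), function(lb) {
    x <- .clip_intervals(as.data.frame(iv[[lb]]), chrom_len)
    if (nrow(x) == 0L) return(NULL)
    data.table(gene_id = g$gene_id, region = lb, chrom = g$chrom,
               start = as.integer(x$start), end = as.integer(x$end),
               strand = g$strand)
  }))
  out
}

#' Partition a gene's +/- 20 kb neighbourhood into the twelve regions
#'
#' For each gene model the upstream flank is cut into up2, up5, up10 and up20
#' segments measured from the TSS against the direction of transcription; the
#' downstream flank into down2..down20 from the TES; and the gene body into
#' 5'UTR (exonic bases between the TSS and the CDS start, in transcript
#' order), exon (exonic bases overlapping the CDS), 3'UTR (exonic bases
#' between the CDS end and the TES) and intron (non-exonic gene-body bases).
#' For non-coding models the three CDS-derived regions are empty and the gene
#' body contributes only introns. All coordinates are 0-based half-open;
#' intervals are clipped to `[0, chrom_length)`.
#'
#' The twelve labels form a fixed vocabulary (the `region` column is a factor
#' over [region_labels()]); a region with no genomic extent simply has no
#' rows for that gene.
#'
#' @param genes gene-model data frame.
#' @param flank_kb increasing flank segment bounds in kb (default 2, 5, 10,
#'   20, giving segments 0-2, 2-5, 5-10 and 10-20 kb from the TSS/TES).
#' @param chrom_lengths optional named integer vector of chromosome lengths
#'   used for clipping.
#' @return `data.frame` with columns `gene_id`, `region` (factor),
#'   `chrom`, `start`, `end`, `strand`.
#' @export
partition_regions <- function(genes, flank_kb = c(2, 5, 10, 20),
                              chrom_lengths = NULL) {
  stopifnot(all(diff(flank_kb) > 0), flank_kb[1] > 0)
  flank_bp <- as.integer(flank_kb * 1000)
  noncoding <- !is.na(genes$cds_start) & !is.na(genes$cds_end) &
    genes$cds_start >= genes$cds_end
  if (any(noncoding)) {
    message(sum(noncoding), " non-coding model(s): 5UTR/exon/3UTR left empty")
  }
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, , drop = FALSE]
    g$exon_starts <- genes$exon_starts[i]
    g$exon_ends <- genes$exon_ends[i]
    cl <- if (is.null(chrom_lengths)) NA else unname(chrom_lengths[g$chrom])
    .partition_one(as.list(g), flank_bp, cl)
  })
  out <- rbindlist(rows)
  if (nrow(out) == 0L) {
    out <- data.table(gene_id = character(0), region = character(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0))
  }
  labs <- c(paste0("up", rev(flank_bp) / 1000L), "5UTR", "exon", "intron",
            "3UTR", paste0("down", flank_bp / 1000L))
  out$region <- factor(out$region, levels = if (identical(flank_bp,
    c(2000L, 5000L, 10000L, 20000L))) region_labels() else labs)
  as.data.frame(out)
}

#' Tile the promoter (TSS +/- 2 kb) into twenty 200 bp bins
#'
#' Bin `k` (k >= 1) covers `[TSS + (k-1)*bin_size, TSS + k*bin_size)` in the
#' direction of transcription; bin `-k` mirrors it upstream. Bin 1 therefore
#' abuts the TSS on the transcribed side and bin -1 immediately upstream;
#' there is no bin 0. On the minus strand all intervals are reflected about
#' the TSS. Bins truncated by a chromosome edge are clipped and flagged
#' `partial`.
#'
#' @param genes gene-model data frame.
#' @param half_width promoter half-width in bp (default 2000).
#' @param bin_size bin width in bp (default 200); must divide `half_width`.
#' @param chrom_lengths optional named chromosome lengths for clipping.
#' @return `data.frame` with columns `gene_id`, `bin` (integer index),
#'   `chrom`, `start`, `end`, `strand`, `partial`.
#' @export
make_bins <- function(genes, half_width = 2000L, bin_size = 200L,
                      chrom_lengths = NULL) {
  stopifnot(half_width %% bin_size == 0L)
  n_side <- as.integer(half_width / bin_size)
  ks <- bin_indices(n_side, n_side)
  if (nrow(genes) == 0L) {
    return(data.frame(gene_id = character(0), bin = integer(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      partial = logical(0)))
  }
  tss <- .tss(genes)
  plus <- genes$strand == "+"
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    k <- ks
    off_lo <- ifelse(k > 0L, (k - 1L) * bin_size, k * bin_size)
    off_hi <- off_lo + bin_size
    if (plus[i]) {
      s <- tss[i] + off_lo
      e <- tss[i] + off_hi
    } else {
      s <- tss[i] - off_hi
      e <- tss[i] - off_lo
    }
    data.table(gene_id = genes$gene_id[i], bin = k, chrom = genes$chrom[i],
               start = as.integer(s), end = as.integer(e),
               strand = genes$strand[i])
  })
  out <- rbindlist(rows)
  cl <- chrom_lengths[out$chrom]
  cs <- pmax(out$start, 0L)
  ce <- if (is.null(chrom_lengths)) out$end else {
    pmin(out$end, ifelse(is.na(cl), out$end, as.integer(cl)))
  }
  out$partial <- cs != out$start | ce != out$end
  out$start <- cs
  out$end <- ce
  out <- out[out$end > out$start, ]
  if (any(out$partial)) {
    message(sum(out$partial), " promoter bin(s) clipped at a chromosome edge")
  }
  as.data.frame(out)
}

#' Collapse an annotation to one merged interval set per gene
#'
#' Merges all intervals of all regions (or bins) of each gene into a single
#' labelled interval set, e.g. to compute whole-neighbourhood or whole-gene
#' methylation with [region_methylation()].
#'
#' @param annotation data frame from [partition_regions()] or [make_bins()].
#' @param label label to assign to the merged set (default `"gene"`).
#' @return Annotation data frame with a single label per gene.
#' @export
collapse_annotation <- function(annotation, label = "gene") {
  dt <- as.data.table(annotation)
  out <- dt[, {
    ir <- IRanges::reduce(.to_iranges(start, end))
    iv <- .from_iranges(ir)
    list(label = label, chrom = chrom[1L], start = iv$start, end = iv$end,
         strand = strand[1L])
  }, by = gene_id]
  setnames(out, "label", "region")
  as.data.frame(out)
}
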