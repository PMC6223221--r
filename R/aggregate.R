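.annotation_labels <- function(annotation) {
  if ("region" %in% names(annotation)) {
    lv <- levels(annotation$region)
    if (is.null(lv)) lv <- unique(as.character(annotation$region))
    lv
  } else if ("bin" %in% names(annotation)) {
    as.character(sort(unique(annotation$bin)))
  } else {
    stop("annotation must have a 'region' or 'bin' column")
  }
}

.annotation_label_col <- function(annotation) {
  as.character(if ("region" %in% names(annotation)) annotation$region
               else annotation$bin)
}

#' Methylation level of every annotated region for one sample
#'
#' Averages per-CpG methylation levels over the CpGs that fall inside each
#' (gene, region) or (gene, bin) interval set. Intervals are 0-based
#' half-open, so a CpG whose C sits exactly at an interval end is excluded
#' while one at the start is included. Cells with no covered CpG are missing
#' (`NA`) with `n_cpg = 0`; the mean is unweighted across CpGs, as coverage
#' already gated which calls exist.
#'
#' @param calls coverage-filtered call data frame from [read_cpg_calls()].
#' @param annotation data frame from [partition_regions()], [make_bins()] or
#'   [collapse_annotation()].
#' @return `data.frame` with one row per (gene, label): `gene_id`, `label`,
#'   `meth`, `n_cpg`.
#' @export
region_methylation <- function(calls, annotation) {
  ann <- as.data.table(annotation)
  ann$label <- .annotation_label_col(ann)
  labels <- .annotation_labels(annotation)
  genes <- unique(ann$gene_id)
  grid <- data.table(gene_id = rep(genes, each = length(labels)),
                     label = rep(labels, length(genes)))
  if (nrow(ann) == 0L || nrow(calls) == 0L) {
    grid$meth <- NA_real_
    grid$n_cpg <- 0L
    return(as.data.frame(grid))
  }
  ann_gr <- GenomicRanges::GRanges(
    seqnames = ann$chrom,
    ranges = IRanges::IRanges(start = ann$start + 1L, end = ann$end)
  )
  call_gr <- GenomicRanges::GRanges(
    seqnames = calls$chrom,
    ranges = IRanges::IRanges(start = calls$pos + 1L, width = 1L)
  )
  hits <- GenomicRanges::findOverlaps(call_gr, ann_gr)
  ov <- data.table(
    gene_id = ann$gene_id[S4Vectors::subjectHits(hits)],
    label = ann$label[S4Vectors::subjectHits(hits)],
    meth_level = calls$meth_level[S4Vectors::queryHits(hits)]
  )
  agg <- ov[, list(meth = mean(meth_level), n_cpg = .N),
            by = list(gene_id, label)]
  out <- merge(grid, agg, by = c("gene_id", "label"), all.x = TRUE,
               sort = FALSE)
  out[is.na(n_cpg), n_cpg := 0L]
  as.data.frame(out)
}

#' Gene x label x sample methylation array
#'
#' Runs [region_methylation()] for every sample and assembles the results
#' into a `meth_matrix`: a pair of 3-d arrays (`meth`, `n_cpg`) over genes,
#' region/bin labels and samples, the container all downstream summaries
#' consume.
#'
#' @param call_sets named list of call data frames, one per sample.
#' @param annotation region or bin annotation data frame.
#' @return An object of class `meth_matrix`: list with `meth` and `n_cpg`
#'   arrays and the axis labels `genes`, `labels`, `samples`.
#' @export
methylation_matrix <- function(call_sets, annotation) {
  stopifnot(length(call_sets) > 0, !is.null(names(call_sets)))
  labels <- .annotation_labels(annotation)
  genes <- unique(annotation$gene_id)
  meth <- array(NA_real_,
                dim = c(length(genes), length(labels), length(call_sets)),
                dimnames = list(genes, labels, names(call_sets)))
  ncpg <- array(0L, dim = dim(meth), dimnames = dimnames(meth))
  # assign the union of CpG positions to (gene, label) cells once, then
  # join each sample's (coverage-filtered) calls against the assignment
  univ <- unique(rbindlist(lapply(call_sets, function(x) {
    as.data.table(x)[, list(chrom, pos)]
  })))
  ann <- as.data.table(annotation)
  ann$label <- .annotation_label_col(ann)
  ann_gr <- GenomicRanges::GRanges(
    seqnames = ann$chrom,
    ranges = IRanges::IRanges(start = ann$start + 1L, end = ann$end))
  pos_gr <- GenomicRanges::GRanges(
    seqnames = univ$chrom,
    ranges = IRanges::IRanges(start = univ$pos + 1L, width = 1L))
  hits <- GenomicRanges::findOverlaps(pos_gr, ann_gr)
  assign <- data.table(
    chrom = univ$chrom[S4Vectors::queryHits(hits)],
    pos = univ$pos[S4Vectors::queryHits(hits)],
    gene_id = ann$gene_id[S4Vectors::subjectHits(hits)],
    label = ann$label[S4Vectors::subjectHits(hits)])
  gi <- match(assign$gene_id, genes)
  li <- match(assign$label, labels)
  for (k in seq_along(call_sets)) {
    calls <- as.data.table(call_sets[[k]])
    lev <- calls[assign, on = c("chrom", "pos")]$meth_level
    ok <- !is.na(lev)
    cell <- gi[ok] + (li[ok] - 1L) * length(genes)
    sums <- rowsum(lev[ok], cell)
    cnts <- rowsum(rep(1L, sum(ok)), cell)
    idx <- as.integer(rownames(sums))
    page <- (k - 1L) * length(genes) * length(labels)
    ncpg[idx + page] <- as.integer(cnts)
    meth[idx + page] <- sums / cnts
  }
  structure(list(meth = meth, n_cpg = ncpg, genes = genes, labels = labels,
                 samples = names(call_sets)),
            class = "meth_matrix")
}

#' @export
print.meth_matrix <- function(x, ...) {
  cat("meth_matrix:", length(x$genes), "genes x", length(x$labels),
      "labels x", length(x$samples), "samples;",
      sprintf("%.1f%% cells missing\n", 100 * mean(is.na(x$meth))))
  invisible(x)
}

#' Replicate- and stage-level methylation summaries
#'
#' Averages a `meth_matrix` over the biological replicates of each
#' developmental stage (mean of the non-missing replicate values per gene and
#' label), and computes the genome-level summary per stage: the unweighted
#' arithmetic mean over genes of the per-gene values, per label. If
#' `gene_chrom` is supplied, per-chromosome means are computed the same way.
#'
#' @param m a `meth_matrix` from [methylation_matrix()].
#' @param manifest manifest data frame mapping `sample_id` to `stage`
#'   ([read_manifest()]); every sample of `m` must be mapped and every stage
#'   must have at least one sample.
#' @param gene_chrom optional named character vector gene_id -> chromosome.
#' @return An object of class `stage_summary`: list with `meth` (genes x
#'   labels x stages array), `n_rep` (replicates contributing), `global`
#'   (data frame stage/label/mean/n_genes) and optionally `per_chrom`.
#' @export
stage_average <- function(m, manifest, gene_chrom = NULL) {
  stopifnot(inherits(m, "meth_matrix"))
  stages <- levels(manifest$stage) %||% unique(as.character(manifest$stage))
  missing_samples <- setdiff(m$samples, manifest$sample_id)
  if (length(missing_samples) > 0) {
    stop("samples not in manifest: ", paste(missing_samples, collapse = ", "))
  }
  meth <- array(NA_real_,
                dim = c(length(m$genes), length(m$labels), length(stages)),
                dimnames = list(m$genes, m$labels, stages))
  nrep <- array(0L, dim = dim(meth), dimnames = dimnames(meth))
  for (st in stages) {
    ids <- manifest$sample_id[manifest$stage == st]
    ids <- intersect(ids, m$samples)
    if (length(ids) == 0L) stop("stage has no samples: ", st)
    slab <- m$meth[, , ids, drop = FALSE]
    present <- !is.na(slab)
    nr <- apply(present, c(1, 2), sum)
    sm <- apply(slab, c(1, 2), function(v) sum(v, na.rm = TRUE))
    meth[, , st] <- ifelse(nr > 0, sm / nr, NA_real_)
    nrep[, , st] <- nr
  }
  global <- rbindlist(lapply(stages, function(st) {
    v <- meth[, , st, drop = FALSE]
    data.table(stage = st, label = m$labels,
               mean = apply(v, 2, function(x) mean(x, na.rm = TRUE)),
               n_genes = apply(v, 2, function(x) sum(!is.na(x))))
  }))
  global$mean[global$n_genes == 0L] <- NA_real_
  per_chrom <- NULL
  if (!is.null(gene_chrom)) {
    ch <- gene_chrom[m$genes]
    per_chrom <- rbindlist(lapply(stages, function(st) {
      rbindlist(lapply(unique(ch), function(cc) {
        v <- meth[which(ch == cc), , st, drop = FALSE]
        data.table(stage = st, chrom = cc, label = m$labels,
                   mean = apply(v, 2, function(x) mean(x, na.rm = TRUE)),
                   n_genes = apply(v, 2, function(x) sum(!is.na(x))))
      }))
    }))
    per_chrom <- as.data.frame(per_chrom)
  }
  structure(list(meth = meth, n_rep = nrep, genes = m$genes,
                 labels = m$labels, stages = stages,
                 global = as.data.frame(global), per_chrom = per_chrom),
            class = "stage_summary")
}

#' @export
print.stage_summary <- function(x, ...) {
  cat("stage_summary:", length(x$genes), "genes x", length(x$labels),
      "labels x", length(x$stages), "stages\n")
  invisible(x)
}

#' Count methylated promoter bins across genes
#'
#' For each bin index and sample, counts the genes whose bin contains at
#' least one covered CpG with a methylation level above `eps` ("had
#' methylated CpGs" with `eps = 0`), and reports the mean methylation level
#' over those methylated bins.
#'
#' @param m a `meth_matrix` over promoter bins.
#' @param eps methylation level a bin must exceed to count as methylated
#'   (default 0).
#' @return `data.frame` with columns `sample_id`, `bin`, `n_methylated`,
#'   `mean_meth` (`NA` when no bin is methylated).
#' @export
methylated_bin_counts <- function(m, eps = 0) {
  stopifnot(inherits(m, "meth_matrix"))
  rbindlist(lapply(m$samples, function(s) {
    v <- m$meth[, , s, drop = FALSE]
    n <- m$n_cpg[, , s, drop = FALSE]
    is_meth <- !is.na(v) & n >= 1L & v > eps
    cnt <- apply(is_meth, 2, sum)
    mm <- vapply(seq_along(m$labels), function(j) {
      sel <- is_meth[, j, 1]
      if (!any(sel)) NA_real_ else mean(v[sel, j, 1])
    }, numeric(1))
    data.table(sample_id = s, bin = as.integer(m$labels),
               n_methylated = as.integer(cnt), mean_meth = mm)
  })) |> as.data.frame()
}
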