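#' Count reference CpGs in each promoter bin
#'
#' Counts the CpG dyads whose + strand C position falls inside each bin
#' interval (0-based half-open, so a C at position `end - 1` counts even when
#' the G of the dyad lies just outside the bin).
#'
#' @param bins bin annotation from [make_bins()].
#' @param sites reference CpG positions: a data frame with columns `chrom`,
#'   `pos` (from [cpg_sites()]), or a sorted integer vector when all bins are
#'   on one chromosome.
#' @return The bin data frame with an added `cpg_count` column.
#' @export
count_bin_cpgs <- function(bins, sites) {
  if (is.numeric(sites)) {
    stopifnot(length(unique(bins$chrom)) <= 1L)
    ch <- if (nrow(bins)) bins$chrom[1] else NA_character_
    sites <- data.frame(chrom = rep(ch, length(sites)),
                        pos = as.integer(sites))
  }
  out <- as.data.table(bins)
  if (nrow(out) == 0L) {
    out$cpg_count <- integer(0)
    return(as.data.frame(out))
  }
  st <- as.data.table(sites)
  counts <- integer(nrow(out))
  for (cc in unique(out$chrom)) {
    idx <- which(out$chrom == cc)
    p <- sort(st[chrom == cc, pos])
    # CpGs with pos in [start, end): count via binary search on sorted pos
    counts[idx] <- findInterval(out$end[idx] - 1L, p) -
      findInterval(out$start[idx] - 1L, p)
  }
  out$cpg_count <- counts
  as.data.frame(out)
}

#' Classify a 200 bp window by CpG density
#'
#' High-CpG (HCG) windows hold more than 8 CpGs, low-CpG (LCG) windows fewer
#' than 4, and intermediate (ICG) windows 4 to 8 inclusive. The
#' classification is a total, monotone step function of the count.
#'
#' @param cpg_count integer vector of CpG counts (>= 0).
#' @param lcg_below counts strictly below this are LCG (default 4).
#' @param hcg_above counts strictly above this are HCG (default 8).
#' @return Factor over `LCG < ICG < HCG`.
#' @export
classify_density <- function(cpg_count, lcg_below = 4L, hcg_above = 8L) {
  if (any(cpg_count < 0, na.rm = TRUE)) stop("CpG counts must be >= 0")
  stopifnot(lcg_below <= hcg_above)
  cls <- ifelse(cpg_count > hcg_above, "HCG",
                ifelse(cpg_count < lcg_below, "LCG", "ICG"))
  factor(cls, levels = c("LCG", "ICG", "HCG"))
}

#' Promoter-level CpG-density class per gene
#'
#' Rolls the per-bin counts of a gene up to one promoter-level class. The
#' default takes the densest bin within TSS +/- 2 kb (`method = "max"`), so a
#' promoter counts as HCG when any of its 200 bp windows does;
#' `method = "mean"` classifies the mean per-bin count instead.
#'
#' @param bin_counts output of [count_bin_cpgs()].
#' @param method `"max"` (default) or `"mean"` roll-up of the per-bin counts.
#' @param ... thresholds passed on to [classify_density()].
#' @return `data.frame` with columns `gene_id`, `cpg_count`, `density_class`.
#' @export
promoter_density <- function(bin_counts, method = c("max", "mean"), ...) {
  method <- match.arg(method)
  dt <- as.data.table(bin_counts)
  agg <- dt[, list(cpg_count = if (method == "max") max(cpg_count)
                   else mean(cpg_count)), by = gene_id]
  agg$density_class <- classify_density(agg$cpg_count, ...)
  as.data.frame(agg)
}
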