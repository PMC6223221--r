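#' @importFrom data.table data.table as.data.table rbindlist setnames setorder fwrite fread :=
#' @importFrom stats rnorm rbeta rnbinom cor prcomp t.test weighted.mean setNames
#' @importFrom utils head tail
NULL

# quiet R CMD check notes for data.table NSE columns
utils::globalVariables(c(
  ".", ".N", ".SD", "chrom", "pos", "strand", "meth_level", "coverage",
  "gene_id", "label", "meth", "n_cpg", "sample_id", "stage", "replicate",
  "rpkm", "log2_expr", "cpg_count", "bin", "w"
))

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The twelve gene-neighbourhood region labels
#'
#' Fixed label set for the partition of a gene's +/- 20 kb neighbourhood:
#' four upstream flank segments, the gene body split into 5'UTR, exon,
#' intron and 3'UTR, and four downstream flank segments, ordered in the
#' direction of transcription.
#'
#' @return Character vector of length 12.
#' @export
region_labels <- function() {
  c("up20", "up10", "up5", "up2",
    "5UTR", "exon", "intron", "3UTR",
    "down2", "down5", "down10", "down20")
}

#' The twenty promoter bin indices
#'
#' Bin indices tiling TSS +/- 2 kb: -10..-1 upstream of the TSS, 1..10
#' downstream (in the direction of transcription); there is no bin 0.
#'
#' @param n_up,n_down number of bins on each side of the TSS
#' @return Integer vector, upstream-to-downstream order.
#' @export
bin_indices <- function(n_up = 10L, n_down = 10L) {
  c(seq.int(-n_up, -1L), seq.int(1L, n_down))
}

# half-open [start, end) integer intervals <-> IRanges (1-based closed)
.to_iranges <- function(start, end) {
  keep <- end > start
  IRanges::IRanges(start = start[keep] + 1L, end = end[keep])
}

.from_iranges <- function(ir) {
  if (length(ir) == 0L) {
    return(data.table(start = integer(0), end = integer(0)))
  }
  data.table(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}
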