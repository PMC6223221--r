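#' Read a reference genome FASTA
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] that trims FASTA
#' descriptions to the first word so sequence names match chromosome names
#' used in annotation tables.
#'
#' @param path path to a (possibly multi-record) FASTA file.
#' @return A [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Positions of CpG dinucleotides on a chromosome
#'
#' Scans the reference sequence for `CG` dinucleotides (case-insensitive) and
#' returns the 0-based position of the C of each dyad on the + strand. CpG
#' cannot overlap CpG, so positions are at least 2 bp apart.
#'
#' @param fasta a [Biostrings::DNAStringSet], or a FASTA file path.
#' @param chrom chromosome name to scan.
#' @return Sorted integer vector of 0-based C positions.
#' @export
cpg_positions <- function(fasta, chrom) {
  if (is.character(fasta)) fasta <- read_fasta(fasta)
  if (!chrom %in% names(fasta)) {
    stop("chromosome not found in FASTA: ", chrom)
  }
  m <- Biostrings::matchPattern("CG", fasta[[chrom]])
  as.integer(IRanges::start(m)) - 1L
}

#' CpG positions for every chromosome
#'
#' @param fasta a [Biostrings::DNAStringSet] or FASTA path.
#' @return `data.frame` with columns `chrom`, `pos` (0-based C position).
#' @export
cpg_sites <- function(fasta) {
  if (is.character(fasta)) fasta <- read_fasta(fasta)
  rbindlist(lapply(names(fasta), function(ch) {
    data.table(chrom = ch, pos = cpg_positions(fasta, ch))
  })) |> as.data.frame()
}

#' Read per-sample CpG methylation calls
#'
#' Reads a tab-delimited methylation-call table (chrom, position, strand,
#' methylation level in \[0,1\], read coverage), applies the read-coverage
#' filter, and optionally collapses the two strands of each CpG dyad onto the
#' + strand C position by a coverage-weighted mean. Rows with a methylation
#' level outside \[0,1\], an unknown strand, or (when a reference is given) a
#' position that is not a CpG in the reference are rejected and counted in
#' the `rejected` attribute of the result.
#'
#' The coverage filter is applied per input row, before dyad collapsing, so a
#' strand read fewer than `coverage_min` times never contributes.
#'
#' @param path path to the call table (no header by default).
#' @param coverage_min minimum read coverage to retain a call (default 5,
#'   i.e. at least fivefold coverage).
#' @param collapse_strands collapse - strand calls onto the + strand C of the
#'   dyad (position - 1) by coverage-weighted mean (default `TRUE`).
#' @param columns named integer vector mapping the fields `chrom`, `pos`,
#'   `strand`, `meth`, `coverage` to column indices, so Bismark-coverage-like
#'   dialects can be read by remapping.
#' @param fasta optional reference ([Biostrings::DNAStringSet] or path) used
#'   to verify that each retained call sits on a reference CpG; calls on
#'   chromosomes absent from the reference are rejected.
#' @param chroms optional character vector restricting calls to these
#'   chromosomes.
#' @return `data.frame` with columns `chrom`, `pos`, `strand`, `meth_level`,
#'   `coverage`, sorted by chromosome and position, with attribute
#'   `rejected` (named counts of rejected rows).
#' @export
read_cpg_calls <- function(path, coverage_min = 5L, collapse_strands = TRUE,
                           columns = c(chrom = 1L, pos = 2L, strand = 3L,
                                       meth = 4L, coverage = 5L),
                           fasta = NULL, chroms = NULL) {
  raw <- if (file.size(path) == 0) data.table() else
    fread(path, header = FALSE, sep = "\t")
  if (nrow(raw) == 0L) {
    warning("no methylation calls in ", path)
    out <- data.frame(chrom = character(0), pos = integer(0),
                      strand = character(0), meth_level = numeric(0),
                      coverage = integer(0))
    attr(out, "rejected") <- c(bad_level = 0L, bad_strand = 0L,
                               unknown_chrom = 0L, not_cpg = 0L)
    return(out)
  }
  dt <- data.table(
    chrom = as.character(raw[[columns[["chrom"]]]]),
    pos = as.integer(raw[[columns[["pos"]]]]),
    strand = as.character(raw[[columns[["strand"]]]]),
    meth_level = as.numeric(raw[[columns[["meth"]]]]),
    coverage = as.integer(raw[[columns[["coverage"]]]])
  )
  rejected <- c(bad_level = 0L, bad_strand = 0L, unknown_chrom = 0L,
                not_cpg = 0L)
  ok <- !is.na(dt$meth_level) & dt$meth_level >= 0 & dt$meth_level <= 1
  rejected["bad_level"] <- sum(!ok)
  dt <- dt[ok]
  ok <- dt$strand %in% c("+", "-")
  rejected["bad_strand"] <- sum(!ok)
  dt <- dt[ok]
  if (!is.null(chroms)) dt <- dt[chrom %in% chroms]
  if (is.character(fasta)) fasta <- read_fasta(fasta)
  if (!is.null(fasta)) {
    ok <- dt$chrom %in% names(fasta)
    rejected["unknown_chrom"] <- sum(!ok)
    dt <- dt[ok]
  }
  dt <- dt[coverage >= coverage_min]
  if (collapse_strands && nrow(dt) > 0L) {
    dt[strand == "-", pos := pos - 1L]
    dt <- dt[, list(
      strand = "+",
      meth_level = weighted.mean(meth_level, coverage),
      coverage = sum(coverage)
    ), by = list(chrom, pos)]
  }
  if (!is.null(fasta) && nrow(dt) > 0L) {
    ok <- vapply(seq_len(nrow(dt)), function(i) {
      s <- fasta[[dt$chrom[i]]]
      p <- dt$pos[i]
      if (dt$strand[i] == "+") {
        p + 2L <= length(s) &&
          as.character(Biostrings::subseq(s, p + 1L, p + 2L)) == "CG"
      } else {
        p >= 1L &&
          as.character(Biostrings::subseq(s, p, p + 1L)) == "CG"
      }
    }, logical(1))
    rejected["not_cpg"] <- sum(!ok)
    dt <- dt[ok]
  }
  setorder(dt, chrom, pos)
  out <- as.data.frame(dt[, list(chrom, pos, strand, meth_level, coverage)])
  attr(out, "rejected") <- rejected
  out
}

#' Write CpG methylation calls
#'
#' Writes calls in the same five-column tab-delimited layout that
#' [read_cpg_calls()] reads, so filtered calls round-trip byte-stably.
#'
#' @param calls call data frame (`chrom`, `pos`, `strand`, `meth_level`,
#'   `coverage`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cpg_calls <- function(calls, path) {
  fwrite(as.data.table(calls)[, list(chrom, pos, strand, meth_level,
                                     coverage)],
         path, sep = "\t", col.names = FALSE, eol = "\n")
  invisible(path)
}

#' Read a sample manifest
#'
#' A manifest maps each methylation-call file to a biological sample: columns
#' `sample_id`, `stage`, `replicate`, `path` (tab-delimited, with header).
#' Stage order follows first appearance unless `stages` is given.
#'
#' @param path manifest path.
#' @param stages optional character vector fixing the stage order.
#' @return `data.frame` with `stage` as an ordered-level factor.
#' @export
read_manifest <- function(path, stages = NULL) {
  m <- as.data.frame(fread(path, header = TRUE, sep = "\t",
                           colClasses = list(character = "sample_id")))
  req <- c("sample_id", "stage", "replicate", "path")
  if (!all(req %in% names(m))) {
    stop("manifest must have columns: ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(m[, c("stage", "replicate")])) {
    stop("manifest (stage, replicate) pairs must be unique")
  }
  # relative call paths are resolved against the manifest's own directory
  rel <- !is.na(m$path) & !grepl("^(/|[A-Za-z]:)", m$path)
  m$path[rel] <- file.path(dirname(path), m$path[rel])
  m$stage <- factor(m$stage, levels = stages %||% unique(m$stage))
  if (anyNA(m$stage)) stop("manifest contains stages not in 'stages'")
  m
}
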