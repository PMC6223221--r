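#' Pipeline configuration
#'
#' Collects input paths and every analysis parameter into one validated
#' object. `pipeline_config()` builds it from arguments;
#' [read_pipeline_config()] loads the same structure from a YAML file.
#'
#' @param fasta,genes,manifest,expression input paths: reference FASTA,
#'   refFlat/BED12 gene table, sample manifest, RPKM expression table.
#' @param outdir output directory (created if absent at run time).
#' @param gene_format `"refFlat"` or `"bed12"`.
#' @param mrna_prefix transcript accession prefix kept by
#'   [select_transcripts()].
#' @param coverage_min minimum CpG read coverage.
#' @param collapse_strands collapse CpG dyads onto the + strand C.
#' @param flank_kb flank segment bounds in kb.
#' @param half_width,bin_size promoter geometry in bp.
#' @param stages optional stage order for the manifest.
#' @param hypo_max,hyper_min methylation-state thresholds.
#' @param methylated_eps level above which a bin counts as methylated.
#' @param zero_reset `"sample"` or `"global"` RPKM zero-reset scope.
#' @param diff_stage_a,diff_stage_b stages compared by the differential
#'   filters (defaults: second-to-last and last manifest stage).
#' @param diff_cfg a [diff_filter_config()].
#' @param seed seed recorded in the run metadata (the analysis itself is
#'   deterministic).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(fasta, genes, manifest, expression, outdir,
                            gene_format = "refFlat", mrna_prefix = "NM_",
                            coverage_min = 5L, collapse_strands = TRUE,
                            flank_kb = c(2, 5, 10, 20),
                            half_width = 2000L, bin_size = 200L,
                            stages = NULL,
                            hypo_max = 0.3, hyper_min = 0.7,
                            methylated_eps = 0,
                            zero_reset = "sample",
                            diff_stage_a = NULL, diff_stage_b = NULL,
                            diff_cfg = diff_filter_config(),
                            seed = 1L) {
  structure(list(
    fasta = fasta, genes = genes, manifest = manifest,
    expression = expression, outdir = outdir,
    gene_format = gene_format, mrna_prefix = mrna_prefix,
    coverage_min = as.integer(coverage_min),
    collapse_strands = isTRUE(collapse_strands),
    flank_kb = flank_kb, half_width = as.integer(half_width),
    bin_size = as.integer(bin_size), stages = stages,
    hypo_max = hypo_max, hyper_min = hyper_min,
    methylated_eps = methylated_eps, zero_reset = zero_reset,
    diff_stage_a = diff_stage_a, diff_stage_b = diff_stage_b,
    diff_cfg = diff_cfg, seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; the
#' `diff_cfg` key holds the arguments of [diff_filter_config()].
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  for (p in c("fasta", "genes", "manifest", "expression")) {
    if (is.null(y[[p]])) stop("config is missing required path: ", p)
  }
  dc <- do.call(diff_filter_config, y$diff_cfg %||% list())
  y$diff_cfg <- NULL
  args <- y[intersect(names(y), names(formals(pipeline_config)))]
  do.call(pipeline_config, c(args, list(diff_cfg = dc)))
}

.write_bed <- function(annotation, label_col, path) {
  dt <- as.data.table(annotation)
  bed <- data.table(dt$chrom, dt$start, dt$end,
                    paste0(dt$gene_id, "|", dt[[label_col]]),
                    0L, dt$strand)
  fwrite(bed, path, sep = "\t", col.names = FALSE, eol = "\n")
  invisible(path)
}

.long_meth <- function(m) {
  rbindlist(lapply(seq_along(m$samples), function(k) {
    data.table(sample_id = m$samples[k],
               gene_id = rep(m$genes, length(m$labels)),
               label = rep(m$labels, each = length(m$genes)),
               meth = as.vector(m$meth[, , k]),
               n_cpg = as.vector(m$n_cpg[, , k]))
  }))
}

.fmt_tsv <- function(dt, path, params = NULL) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (!is.null(params)) {
    writeLines(paste0("# ", names(params), " = ",
                      vapply(params, function(x)
                        paste(format(x), collapse = ","), "")),
               con, sep = "\n")
  }
  writeLines(paste(names(dt), collapse = "\t"), con, sep = "\n")
  body <- do.call(paste, c(lapply(dt, function(col) {
    if (is.double(col)) {
      ifelse(is.na(col), "NA", formatC(col, digits = 10, format = "g"))
    } else as.character(col)
  }), sep = "\t"))
  if (length(body)) writeLines(body, con, sep = "\n")
  invisible(path)
}

#' Run the full methylation sub-pattern pipeline
#'
#' Orchestrates every analysis step from raw inputs to tables: transcript
#' selection, region and bin annotation, per-sample CpG aggregation, stage
#' averaging, genome-level summaries, state classification and transition
#' counts (consecutive stage pairs plus every stage against the final one),
#' promoter CpG-density classes, methylation-expression correlation per
#' region and bin, PCA over bin correlation profiles, and the bin-1
#' differential-methylation filters. All tabular outputs are plain TSV with
#' a parameter header; annotations are written as BED; the differential gene
#' list as one identifier per line; run metadata (parameters, row counts at
#' each filter) as JSON. Outputs are deterministic for a fixed config.
#'
#' @param config a [pipeline_config()] or path to a YAML config.
#' @return Invisibly, a list with the in-memory results and output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  for (p in c("fasta", "genes", "manifest", "expression")) {
    if (!file.exists(config[[p]])) {
      stop("input file not found (", p, "): ", config[[p]])
    }
  }
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  log <- list()

  genome <- read_fasta(config$fasta)
  chrom_lengths <- setNames(Biostrings::width(genome), names(genome))
  gene_table <- read_gene_models(config$genes, format = config$gene_format)
  log$gene_models_read <- nrow(gene_table)
  models <- select_transcripts(gene_table, mrna_prefix = config$mrna_prefix)
  log$gene_models_selected <- nrow(models)
  regions <- partition_regions(models, flank_kb = config$flank_kb,
                               chrom_lengths = chrom_lengths)
  bins <- make_bins(models, half_width = config$half_width,
                    bin_size = config$bin_size,
                    chrom_lengths = chrom_lengths)
  whole <- collapse_annotation(regions)

  manifest <- read_manifest(config$manifest, stages = config$stages)
  calls <- lapply(seq_len(nrow(manifest)), function(i) {
    read_cpg_calls(manifest$path[i], coverage_min = config$coverage_min,
                   collapse_strands = config$collapse_strands)
  })
  names(calls) <- manifest$sample_id
  log$calls_retained <- setNames(vapply(calls, nrow, 0L), names(calls))

  m_regions <- methylation_matrix(calls, regions)
  m_bins <- methylation_matrix(calls, bins)
  m_whole <- methylation_matrix(calls, whole)
  gene_chrom <- setNames(models$chrom, models$gene_id)
  ss_regions <- stage_average(m_regions, manifest)
  ss_bins <- stage_average(m_bins, manifest)
  ss_whole <- stage_average(m_whole, manifest, gene_chrom = gene_chrom)

  thr <- state_thresholds(config$hypo_max, config$hyper_min)
  stages <- ss_whole$stages
  states <- lapply(stages, function(st) {
    classify_states(setNames(ss_whole$meth[, "gene", st], ss_whole$genes),
                    thr)
  })
  names(states) <- stages
  pairs <- cbind(head(stages, -1L), tail(stages, -1L))
  final <- stages[length(stages)]
  pair_tab <- unique(rbind(pairs, cbind(head(stages, -1L), final)))
  if (nrow(pair_tab) == 0L) {
    pair_tab <- matrix(character(0), ncol = 2)
  }
  trans <- rbindlist(c(list(data.table(
    stage_from = character(0), stage_to = character(0),
    from = character(0), to = character(0), count = integer(0),
    excluded = integer(0))),
    lapply(seq_len(nrow(pair_tab)), function(i) {
    tr <- transitions(states[[pair_tab[i, 1]]], states[[pair_tab[i, 2]]])
    data.table(stage_from = pair_tab[i, 1], stage_to = pair_tab[i, 2],
               from = rep(state_levels(), 3),
               to = rep(state_levels(), each = 3),
               count = as.vector(tr$counts),
               excluded = tr$excluded)
  })))

  sites <- cpg_sites(genome)
  bin_counts <- count_bin_cpgs(bins, sites)
  bin_counts$density_class <- classify_density(bin_counts$cpg_count)
  prom_density <- promoter_density(bin_counts)

  expr <- log_expression(
    as.data.frame(fread(config$expression, header = TRUE)),
    zero_reset = config$zero_reset)
  expr_mat <- expression_matrix(expr)
  corr_regions <- stage_correlation(ss_regions, expr_mat)
  corr_bins <- stage_correlation(ss_bins, expr_mat)
  r_mat <- matrix(corr_bins$r, nrow = length(ss_bins$labels),
                  dimnames = list(ss_bins$labels, stages))
  pca <- if (anyNA(r_mat)) NULL else bin_pca(r_mat)

  stage_a <- config$diff_stage_a %||% stages[max(1L, length(stages) - 1L)]
  stage_b <- config$diff_stage_b %||% stages[length(stages)]
  rep_a <- manifest$sample_id[manifest$stage == stage_a]
  rep_b <- manifest$sample_id[manifest$stage == stage_b]
  bin1_a <- matrix(m_bins$meth[, "1", rep_a], nrow = length(m_bins$genes),
                   dimnames = list(m_bins$genes, rep_a))
  bin1_b <- matrix(m_bins$meth[, "1", rep_b], nrow = length(m_bins$genes),
                   dimnames = list(m_bins$genes, rep_b))
  diff <- select_diff_genes(
    bin1_a, bin1_b,
    expr_mat[, stage_a], expr_mat[, stage_b],
    cfg = config$diff_cfg)
  log$diff_genes_pass <- sum(diff$pass)

  params <- list(
    coverage_min = config$coverage_min,
    collapse_strands = config$collapse_strands,
    flank_kb = config$flank_kb, half_width = config$half_width,
    bin_size = config$bin_size, hypo_max = config$hypo_max,
    hyper_min = config$hyper_min, methylated_eps = config$methylated_eps,
    zero_reset = config$zero_reset,
    fold_change_min = config$diff_cfg$fold_change_min,
    p_max = config$diff_cfg$p_max, direction = config$diff_cfg$direction,
    diff_stage_a = stage_a, diff_stage_b = stage_b, seed = config$seed)

  od <- config$outdir
  paths <- list(
    regions_bed = file.path(od, "regions.bed"),
    bins_bed = file.path(od, "bins.bed"),
    region_methylation = file.path(od, "region_methylation.tsv"),
    bin_methylation = file.path(od, "bin_methylation.tsv"),
    stage_region_methylation = file.path(od, "stage_region_methylation.tsv"),
    global_methylation = file.path(od, "global_methylation.tsv"),
    chrom_methylation = file.path(od, "chrom_methylation.tsv"),
    state_transitions = file.path(od, "state_transitions.tsv"),
    bin_density = file.path(od, "bin_density.tsv"),
    promoter_density = file.path(od, "promoter_density.tsv"),
    methylated_bins = file.path(od, "methylated_bin_counts.tsv"),
    correlations = file.path(od, "correlations.tsv"),
    bin_pca = file.path(od, "bin_pca.tsv"),
    diffmeth = file.path(od, "diffmeth_genes.tsv"),
    gene_list = file.path(od, "diff_gene_list.txt"),
    metadata = file.path(od, "run_metadata.json"))

  .write_bed(regions, "region", paths$regions_bed)
  .write_bed(bins, "bin", paths$bins_bed)
  .fmt_tsv(.long_meth(m_regions), paths$region_methylation, params)
  .fmt_tsv(.long_meth(m_bins), paths$bin_methylation, params)
  stage_long <- rbindlist(lapply(stages, function(st) {
    data.table(stage = st,
               gene_id = rep(ss_regions$genes, length(ss_regions$labels)),
               label = rep(ss_regions$labels, each = length(ss_regions$genes)),
               meth = as.vector(ss_regions$meth[, , st]))
  }))
  .fmt_tsv(stage_long, paths$stage_region_methylation, params)
  glob <- as.data.table(ss_whole$global)
  glob_regions <- as.data.table(ss_regions$global)
  .fmt_tsv(rbind(glob, glob_regions), paths$global_methylation, params)
  if (!is.null(ss_whole$per_chrom)) {
    .fmt_tsv(as.data.table(ss_whole$per_chrom), paths$chrom_methylation,
             params)
  }
  .fmt_tsv(trans, paths$state_transitions, params)
  .fmt_tsv(as.data.table(bin_counts)[, list(gene_id, bin, chrom, start, end,
                                            cpg_count, density_class)],
           paths$bin_density, params)
  .fmt_tsv(as.data.table(prom_density), paths$promoter_density, params)
  .fmt_tsv(as.data.table(methylated_bin_counts(m_bins,
                                               eps = config$methylated_eps)),
           paths$methylated_bins, params)
  .fmt_tsv(rbind(data.table(kind = "region", as.data.table(corr_regions)),
                 data.table(kind = "bin", as.data.table(corr_bins))),
           paths$correlations, params)
  if (!is.null(pca)) {
    .fmt_tsv(data.table(bin = rownames(pca$scores),
                        PC1 = pca$scores[, 1],
                        PC2 = if (ncol(pca$scores) > 1) pca$scores[, 2]
                              else NA_real_),
             paths$bin_pca, params)
  }
  .fmt_tsv(as.data.table(diff), paths$diffmeth, params)
  write_gene_list(diff$gene_id[diff$pass], paths$gene_list)
  jsonlite::write_json(list(parameters = params, log = log),
                       paths$metadata, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  invisible(list(
    models = models, regions = regions, bins = bins,
    m_regions = m_regions, m_bins = m_bins, m_whole = m_whole,
    stage_regions = ss_regions, stage_bins = ss_bins,
    stage_whole = ss_whole, states = states, transitions = trans,
    bin_counts = bin_counts, promoter_density = prom_density,
    correlations = list(regions = corr_regions, bins = corr_bins),
    pca = pca, diff = diff, paths = paths, log = log))
}
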