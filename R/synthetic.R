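#' Configuration of the synthetic methylome generator
#'
#' Bundles every knob of [simulate_methylome()] with defaults that emulate
#' the study conditions the pipeline targets: seven developmental stages
#' whose global methylation dips after the zygote, stays low through the
#' blastocyst and rises sharply post-implantation; a hypo-methylated
#' TSS-proximal promoter core; a hyper-methylated 3'UTR; a unimodal promoter
#' CpG-density profile peaking in the first bin downstream of the TSS; and
#' expression coupled to methylation with designed per-region correlation
#' signs (negative at up2/5'UTR and the promoter core, positive at the 3'UTR
#' and distal flanks).
#'
#' Background (distal flank) methylation is calibrated analytically per gene
#' and stage so that the CpG-weighted neighbourhood mean equals the stage's
#' target global level, making `stage_means` directly recoverable by the
#' pipeline.
#'
#' @param n_genes number of genes to simulate.
#' @param genes_per_chrom genes placed per chromosome (bodies >= 40 kb
#'   apart, so neighbourhoods at most touch).
#' @param seed integer seed fixing every random draw.
#' @param stages stage names, pre-implantation first, post-implantation last.
#' @param stage_means per-stage target global methylation fractions.
#' @param replicates_per_stage biological replicates per stage.
#' @param body_length gene-body length in bp (two exons with a CDS spanning
#'   500 bp inside each UTR end).
#' @param promoter_hypo_level methylation of the promoter core bins
#'   (`core_bins`), constant across stages.
#' @param utr3_boost added to the stage mean for the 3'UTR level.
#' @param core_bins bin indices forming the hypo-methylated promoter core.
#' @param cpg_profile named integer vector of CpGs per bin (names = bin
#'   indices -10..10); the default is unimodal with its peak at bin 1 and
#'   yields LCG outermost upstream bins and an HCG block around the TSS.
#' @param utr3_cpg CpGs placed in the 3'UTR.
#' @param bg_cpg_spacing background spacing (bp per CpG) in the gene body
#'   and flanks.
#' @param noise_sd per-CpG per-sample beta noise standard deviation (0 for
#'   noise-free methylation).
#' @param meth_gene_sd standard deviation of the persistent per-gene,
#'   per-zone methylation offset that carries the expression coupling.
#' @param designed_r named vector over [region_labels()] of designed
#'   methylation-expression correlations (sign and magnitude of the gene
#'   offset coupling).
#' @param designed_r_bins named vector over the 20 bin indices; defaults to
#'   -0.3 in `core_bins` and -0.2 elsewhere.
#' @param expr_mu,expr_gene_sd,expr_noise_sd log2 RPKM model: mean, sd of
#'   the gene latent that couples to methylation, and residual stage noise.
#' @param coverage_mean,coverage_size negative-binomial read coverage per
#'   CpG per sample (mean and dispersion size), so the fivefold coverage
#'   filter is exercised.
#' @param n_transition genes designed to switch from hypo-methylated at all
#'   pre-implantation stages to hyper-methylated post-implantation.
#' @param transition_low,transition_high methylation levels of those genes
#'   before/after the switch.
#' @param n_diff genes designed to pass the bin-1 differential filters from
#'   the second-to-last to the last stage.
#' @param diff_a_level,diff_b_level,diff_expr_boost bin-1 methylation at the
#'   two stages and the log2 expression increment for designed diff genes.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(
    n_genes = 100L, genes_per_chrom = 10L, seed = 1L,
    stages = c("zygote", "2cell", "4cell", "8cell", "morula", "ICM", "post"),
    stage_means = c(0.50, 0.35, 0.33, 0.32, 0.30, 0.30, 0.75),
    replicates_per_stage = 3L,
    body_length = 6000L,
    promoter_hypo_level = 0.10, utr3_boost = 0.25,
    core_bins = c(-4L:-1L, 1L:6L),
    cpg_profile = NULL,
    utr3_cpg = 10L, bg_cpg_spacing = 100L,
    noise_sd = 0.05, meth_gene_sd = 0.08,
    designed_r = NULL, designed_r_bins = NULL,
    expr_mu = 3, expr_gene_sd = 2, expr_noise_sd = 0.3,
    coverage_mean = 30, coverage_size = 5,
    n_transition = 0L, transition_low = 0.05, transition_high = 0.95,
    n_diff = 0L, diff_a_level = 0.60, diff_b_level = 0.15,
    diff_expr_boost = 2) {
  stopifnot(length(stage_means) == length(stages),
            all(stage_means >= 0 & stage_means <= 1),
            n_genes >= 0, replicates_per_stage >= 1)
  ks <- bin_indices()
  if (is.null(cpg_profile)) {
    cpg_profile <- setNames(
      c(3L, 3L, 4L, 5L, 5L, 6L, 7L, 8L, 9L, 10L,     # bins -10..-1
        12L, 10L, 9L, 9L, 8L, 7L, 6L, 5L, 4L, 4L),   # bins 1..10
      as.character(ks))
  }
  stopifnot(identical(sort(as.integer(names(cpg_profile))), sort(ks)))
  if (is.null(designed_r)) {
    designed_r <- setNames(
      c(0.3, 0.3, 0.3, -0.3, -0.3, -0.1, -0.1, 0.3, 0.3, 0.3, 0.3, 0.3),
      region_labels())
  }
  if (is.null(designed_r_bins)) {
    designed_r_bins <- setNames(ifelse(ks %in% core_bins, -0.3, -0.2),
                                as.character(ks))
  }
  structure(list(
    n_genes = as.integer(n_genes), genes_per_chrom = as.integer(genes_per_chrom),
    seed = as.integer(seed), stages = stages, stage_means = stage_means,
    replicates_per_stage = as.integer(replicates_per_stage),
    body_length = as.integer(body_length),
    promoter_hypo_level = promoter_hypo_level, utr3_boost = utr3_boost,
    core_bins = as.integer(core_bins), cpg_profile = cpg_profile,
    utr3_cpg = as.integer(utr3_cpg),
    bg_cpg_spacing = as.integer(bg_cpg_spacing),
    noise_sd = noise_sd, meth_gene_sd = meth_gene_sd,
    designed_r = designed_r, designed_r_bins = designed_r_bins,
    expr_mu = expr_mu, expr_gene_sd = expr_gene_sd,
    expr_noise_sd = expr_noise_sd,
    coverage_mean = coverage_mean, coverage_size = coverage_size,
    n_transition = as.integer(n_transition),
    transition_low = transition_low, transition_high = transition_high,
    n_diff = as.integer(n_diff), diff_a_level = diff_a_level,
    diff_b_level = diff_b_level, diff_expr_boost = diff_expr_boost
  ), class = "simulation_config")
}

# beta draw parameterised by mean and sd; sd = 0 returns the mean exactly
.rbeta_meansd <- function(mu, sd) {
  if (sd <= 0) return(mu)
  v <- pmin(sd^2, 0.95 * mu * (1 - mu))
  k <- mu * (1 - mu) / v - 1
  rbeta(length(mu), mu * k, (1 - mu) * k)
}

# gene-model table for simulated genes: two exons, CDS 500 bp inside each end
.sim_gene_models <- function(cfg) {
  n <- cfg$n_genes
  if (n == 0L) {
    g <- .empty_gene_models()
    return(g)
  }
  stride <- cfg$body_length + 42000L
  i <- seq_len(n)
  chrom_i <- (i - 1L) %/% cfg$genes_per_chrom + 1L
  within <- (i - 1L) %% cfg$genes_per_chrom
  B <- 21000L + within * stride
  strand <- ifelse(i %% 2L == 1L, "+", "-")
  L <- cfg$body_length
  q <- as.integer(round(L / 12) * 5)          # exon1 length 2500 at L = 6000
  e2 <- as.integer(L - round(L / 4))          # exon2 start 4500 at L = 6000
  g <- data.frame(
    gene_id = sprintf("G%04d", i),
    transcript_id = sprintf("NM_%06d", i),
    chrom = sprintf("chrS%02d", chrom_i),
    strand = strand,
    tx_start = B, tx_end = B + L,
    cds_start = B + 500L, cds_end = B + L - 500L
  )
  g$exon_starts <- lapply(seq_len(n), function(j) {
    if (strand[j] == "+") B[j] + c(0L, e2) else B[j] + c(0L, L - q)
  })
  g$exon_ends <- lapply(seq_len(n), function(j) {
    if (strand[j] == "+") B[j] + c(q, L) else B[j] + c(L - e2, L)
  })
  g
}

.sim_chrom_lengths <- function(cfg) {
  if (cfg$n_genes == 0L) return(setNames(integer(0), character(0)))
  stride <- cfg$body_length + 42000L
  n_chrom <- ceiling(cfg$n_genes / cfg$genes_per_chrom)
  len <- 21000L + cfg$genes_per_chrom * stride
  setNames(rep(len, n_chrom), sprintf("chrS%02d", seq_len(n_chrom)))
}

# zone table: one row per designed CpG, with gene, zone id, designed rho
# and a base-level function index. zones: bin_<k>, utr3, body, flank
.sim_zones <- function(cfg, genes, regions, bins) {
  pick <- function(start, end, n) {
    grid <- seq.int(start, end - 2L, by = 2L)
    if (n >= length(grid)) return(grid)
    sort(sample(grid, n))
  }
  rows <- list()
  bdt <- as.data.table(bins)
  for (j in seq_len(nrow(bdt))) {
    k <- bdt$bin[j]
    n <- cfg$cpg_profile[[as.character(k)]]
    if (n > 0L) {
      rows[[length(rows) + 1L]] <- data.table(
        gene_id = bdt$gene_id[j], chrom = bdt$chrom[j],
        pos = pick(bdt$start[j], bdt$end[j], n),
        zone = paste0("bin_", k))
    }
  }
  rdt <- as.data.table(regions)
  for (j in which(rdt$region == "3UTR")) {
    rows[[length(rows) + 1L]] <- data.table(
      gene_id = rdt$gene_id[j], chrom = rdt$chrom[j],
      pos = pick(rdt$start[j], rdt$end[j], cfg$utr3_cpg),
      zone = "utr3")
  }
  # body background: gene body minus promoter minus 3'UTR
  gdt <- as.data.table(genes[, c("gene_id", "chrom", "strand",
                                 "tx_start", "tx_end")])
  tss <- .tss(genes)
  names(tss) <- genes$gene_id
  for (j in seq_len(nrow(gdt))) {
    gid <- gdt$gene_id[j]
    body <- data.frame(start = gdt$tx_start[j], end = gdt$tx_end[j])
    prom <- data.frame(start = tss[gid] - 2000L, end = tss[gid] + 2000L)
    utr3 <- rdt[gene_id == gid & region == "3UTR",
                list(start, end)]
    rest <- .interval_setdiff(body, rbind(prom, as.data.frame(utr3)))
    for (r in seq_len(nrow(rest))) {
      w <- rest$end[r] - rest$start[r]
      n <- as.integer(round(w / cfg$bg_cpg_spacing))
      if (n > 0L) {
        rows[[length(rows) + 1L]] <- data.table(
          gene_id = gid, chrom = gdt$chrom[j],
          pos = pick(rest$start[r], rest$end[r], n), zone = "body")
      }
    }
    # distal flanks: 2-20 kb upstream of the TSS and 0-20 kb past the TES
    fl <- rdt[gene_id == gid &
                region %in% c("up5", "up10", "up20",
                              "down2", "down5", "down10", "down20"),
              list(start, end)]
    for (r in seq_len(nrow(fl))) {
      w <- fl$end[r] - fl$start[r]
      n <- as.integer(round(w / cfg$bg_cpg_spacing))
      if (n > 0L) {
        rows[[length(rows) + 1L]] <- data.table(
          gene_id = gid, chrom = gdt$chrom[j],
          pos = pick(fl$start[r], fl$end[r], n), zone = "flank")
      }
    }
  }
  out <- rbindlist(rows)
  setorder(out, chrom, pos)
  out
}

# designed base methylation of a zone at one stage (before gene offsets)
.zone_base <- function(cfg, zone, stage_idx) {
  s <- cfg$stage_means[stage_idx]
  if (startsWith(zone, "bin_")) {
    k <- as.integer(sub("bin_", "", zone))
    if (k %in% cfg$core_bins) cfg$promoter_hypo_level
    else clamp(s, 0.05, 0.90)
  } else if (zone == "utr3") {
    clamp(s + cfg$utr3_boost, 0.05, 0.95)
  } else if (zone == "body") {
    s
  } else {
    NA_real_  # flank: calibrated per gene in .sim_design
  }
}

.zone_rho <- function(cfg, zone) {
  if (startsWith(zone, "bin_")) {
    cfg$designed_r_bins[[sub("bin_", "", zone)]]
  } else if (zone == "utr3") {
    cfg$designed_r[["3UTR"]]
  } else if (zone == "body") {
    mean(cfg$designed_r[c("exon", "intron")])
  } else {
    cfg$designed_r[["up20"]]
  }
}

#' Generate a synthetic genome, methylomes and expression with ground truth
#'
#' Builds everything the pipeline reads: a multi-chromosome genome FASTA in
#' which every CpG dinucleotide was placed by design, a refFlat-style gene
#' table, per-sample CpG call tables for every stage and replicate, a sample
#' manifest, a per-stage RPKM expression table, and a ground-truth record
#' (designed stage means, correlation signs, transition and differential
#' gene sets). With `outdir = NULL` everything stays in memory; otherwise
#' files are written (byte-identically for a fixed config, since the seed
#' fixes every draw).
#'
#' @param cfg a [simulation_config()].
#' @param outdir optional output directory.
#' @return List with elements `genome` (DNAStringSet), `genes`, `calls`
#'   (named list of call data frames), `manifest`, `expression` (long RPKM
#'   table), `truth`, `chrom_lengths`, and `paths` when files were written.
#' @export
simulate_methylome <- function(cfg = simulation_config(), outdir = NULL) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  genes <- .sim_gene_models(cfg)
  chrom_lengths <- .sim_chrom_lengths(cfg)
  n_stage <- length(cfg$stages)
  stage_a <- cfg$stages[max(1L, n_stage - 1L)]
  stage_b <- cfg$stages[n_stage]
  manifest <- data.frame(
    sample_id = as.vector(t(outer(cfg$stages,
                                  seq_len(cfg$replicates_per_stage),
                                  function(s, r) paste0(s, "_r", r)))),
    stage = factor(rep(cfg$stages, each = cfg$replicates_per_stage),
                   levels = cfg$stages),
    replicate = rep(seq_len(cfg$replicates_per_stage), n_stage),
    path = NA_character_
  )
  truth <- list(
    stages = cfg$stages, stage_means = cfg$stage_means,
    designed_r = as.list(cfg$designed_r),
    designed_r_bins = as.list(cfg$designed_r_bins),
    peak_bin = as.integer(names(cfg$cpg_profile))[
      which.max(cfg$cpg_profile)],
    transition_genes = character(0), diff_genes = character(0),
    diff_stage_a = stage_a, diff_stage_b = stage_b
  )
  if (cfg$n_genes == 0L) {
    out <- list(genome = Biostrings::DNAStringSet(), genes = genes,
                calls = setNames(
                  rep(list(data.frame(chrom = character(0), pos = integer(0),
                                      strand = character(0),
                                      meth_level = numeric(0),
                                      coverage = integer(0))),
                      nrow(manifest)), manifest$sample_id),
                manifest = manifest,
                expression = data.frame(gene_id = character(0),
                                        sample_id = character(0),
                                        rpkm = numeric(0)),
                truth = truth, chrom_lengths = chrom_lengths)
    if (!is.null(outdir)) out$paths <- .sim_write(out, outdir)
    return(out)
  }
  regions <- partition_regions(genes, chrom_lengths = chrom_lengths)
  bins <- make_bins(genes, chrom_lengths = chrom_lengths)
  zones <- .sim_zones(cfg, genes, regions, bins)

  # genome: filler drawn from {A, C, T} (no G, hence no stray CG), then the
  # designed CpG dyads written in; every CG in the FASTA is by design
  genome <- Biostrings::DNAStringSet(vapply(names(chrom_lengths),
    function(ch) {
      L <- chrom_lengths[[ch]]
      x <- sample(c("A", "C", "T"), L, replace = TRUE)
      p <- zones[chrom == ch, pos]
      x[p + 1L] <- "C"
      x[p + 2L] <- "G"
      paste(x, collapse = "")
    }, character(1)))

  gene_ids <- genes$gene_id
  transition_genes <- head(gene_ids, cfg$n_transition)
  diff_genes <- head(setdiff(gene_ids, transition_genes), cfg$n_diff)
  truth$transition_genes <- transition_genes
  truth$diff_genes <- diff_genes

  # per-gene latent driving the expression coupling; per-(gene, zone) offset
  u <- setNames(rnorm(cfg$n_genes), gene_ids)
  zone_key <- unique(zones[, list(gene_id, zone)])
  zone_key$v <- rnorm(nrow(zone_key))
  zone_key$rho <- vapply(zone_key$zone, function(z) .zone_rho(cfg, z),
                         numeric(1))
  zone_key$offset <- cfg$meth_gene_sd *
    (zone_key$rho * u[zone_key$gene_id] +
       sqrt(1 - zone_key$rho^2) * zone_key$v)

  # designed mean per (gene, zone, stage), flanks calibrated so that the
  # CpG-weighted neighbourhood mean hits the stage target exactly
  zone_n <- zones[, list(n = .N), by = list(gene_id, zone)]
  mu_tab <- rbindlist(lapply(seq_len(n_stage), function(si) {
    zk <- data.table::copy(zone_key)
    zk$base <- vapply(zk$zone, function(z) .zone_base(cfg, z, si),
                      numeric(1))
    zk <- merge(zk, zone_n, by = c("gene_id", "zone"), sort = FALSE)
    s_target <- cfg$stage_means[si]
    agg <- zk[, list(
      n_tot = sum(n),
      fixed = sum(base[zone != "flank"] * n[zone != "flank"]),
      n_flank = sum(n[zone == "flank"])), by = gene_id]
    agg$flank_base <- clamp((s_target * agg$n_tot - agg$fixed) /
                              pmax(agg$n_flank, 1L), 0.02, 0.98)
    fl <- zk$zone == "flank"
    zk$base[fl] <- agg$flank_base[match(zk$gene_id[fl], agg$gene_id)]
    zk$mu <- clamp(zk$base + zk$offset, 0.02, 0.98)
    if (length(transition_genes)) {
      tl <- if (si == n_stage) cfg$transition_high else cfg$transition_low
      zk$mu[zk$gene_id %in% transition_genes] <- tl
    }
    if (length(diff_genes)) {
      if (cfg$stages[si] == stage_a) {
        zk$mu[zk$gene_id %in% diff_genes & zk$zone == "bin_1"] <-
          cfg$diff_a_level
      } else if (cfg$stages[si] == stage_b) {
        zk$mu[zk$gene_id %in% diff_genes & zk$zone == "bin_1"] <-
          cfg$diff_b_level
      }
    }
    data.table(stage_idx = si, gene_id = zk$gene_id, zone = zk$zone,
               mu = zk$mu)
  }))

  # render per-CpG, per-sample calls
  calls <- vector("list", nrow(manifest))
  names(calls) <- manifest$sample_id
  for (i in seq_len(nrow(manifest))) {
    si <- match(manifest$stage[i], cfg$stages)
    mu <- mu_tab[stage_idx == si][zones, on = c("gene_id", "zone")]$mu
    lev <- .rbeta_meansd(mu, cfg$noise_sd)
    cov <- rnbinom(nrow(zones), mu = cfg$coverage_mean,
                   size = cfg$coverage_size)
    dt <- data.table(chrom = zones$chrom, pos = zones$pos, strand = "+",
                     meth_level = lev, coverage = cov)
    setorder(dt, chrom, pos)
    calls[[i]] <- as.data.frame(dt)
  }

  # expression: one RPKM column per stage, coupled to methylation through u
  log2e <- outer(u, rep(1, n_stage)) * cfg$expr_gene_sd + cfg$expr_mu +
    matrix(rnorm(cfg$n_genes * n_stage, sd = cfg$expr_noise_sd),
           ncol = n_stage)
  colnames(log2e) <- cfg$stages
  if (length(diff_genes)) {
    log2e[diff_genes, stage_b] <- log2e[diff_genes, stage_b] +
      cfg$diff_expr_boost
  }
  expression <- data.frame(
    gene_id = rep(gene_ids, n_stage),
    sample_id = rep(cfg$stages, each = cfg$n_genes),
    rpkm = as.vector(2^log2e)
  )

  out <- list(genome = genome, genes = genes, calls = calls,
              manifest = manifest, expression = expression, truth = truth,
              chrom_lengths = chrom_lengths)
  if (!is.null(outdir)) out$paths <- .sim_write(out, outdir)
  out
}

.sim_write <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outdir, "calls"), showWarnings = FALSE)
  paths <- list(
    fasta = file.path(outdir, "genome.fa"),
    genes = file.path(outdir, "genes.refflat.tsv"),
    manifest = file.path(outdir, "manifest.tsv"),
    expression = file.path(outdir, "expression.tsv"),
    truth = file.path(outdir, "truth.json")
  )
  Biostrings::writeXStringSet(sim$genome, paths$fasta)
  g <- sim$genes
  refflat <- data.table(
    g$gene_id, g$transcript_id, g$chrom, g$strand, g$tx_start, g$tx_end,
    g$cds_start, g$cds_end, vapply(g$exon_starts, length, 0L),
    vapply(g$exon_starts, function(x) paste0(paste(x, collapse = ","), ","),
           ""),
    vapply(g$exon_ends, function(x) paste0(paste(x, collapse = ","), ","),
           "")
  )
  fwrite(refflat, paths$genes, sep = "\t", col.names = FALSE, eol = "\n")
  manifest <- sim$manifest
  for (i in seq_len(nrow(manifest))) {
    rel <- file.path("calls", paste0(manifest$sample_id[i], ".tsv"))
    write_cpg_calls(sim$calls[[manifest$sample_id[i]]],
                    file.path(outdir, rel))
    # paths are stored relative to the manifest so runs relocate cleanly
    manifest$path[i] <- rel
  }
  fwrite(as.data.table(manifest), paths$manifest, sep = "\t", eol = "\n")
  fwrite(as.data.table(sim$expression), paths$expression, sep = "\t",
         eol = "\n")
  jsonlite::write_json(sim$truth, paths$truth, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths$calls <- file.path(outdir, "calls")
  paths
}

#' Fast region-level rendering of the synthetic design
#'
#' Draws methylation directly at region and bin granularity (one beta draw
#' per gene, label and sample around the designed level) instead of placing
#' and averaging individual CpGs. This is the same stage/region/coupling
#' design as [simulate_methylome()] at a coarser fidelity, cheap enough to
#' repeat hundreds of times in simulation studies of estimator properties
#' such as correlation-sign recovery.
#'
#' @param cfg a [simulation_config()].
#' @param region_noise_sd beta noise sd of a region-level value (default
#'   0.02, roughly a CpG-level sd of 0.05 averaged over a few dozen CpGs).
#' @return List with `regions` and `bins` (`meth_matrix` objects),
#'   `manifest`, `expr_mat` (genes x stages log2 matrix), `truth`.
#' @export
simulate_region_levels <- function(cfg = simulation_config(),
                                   region_noise_sd = 0.02) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  n <- cfg$n_genes
  gene_ids <- sprintf("G%04d", seq_len(n))
  n_stage <- length(cfg$stages)
  ks <- as.integer(names(cfg$cpg_profile))
  u <- setNames(rnorm(n), gene_ids)
  manifest <- data.frame(
    sample_id = as.vector(t(outer(cfg$stages,
                                  seq_len(cfg$replicates_per_stage),
                                  function(s, r) paste0(s, "_r", r)))),
    stage = factor(rep(cfg$stages, each = cfg$replicates_per_stage),
                   levels = cfg$stages),
    replicate = rep(seq_len(cfg$replicates_per_stage), n_stage),
    path = NA_character_
  )
  # designed base level of each label at each stage
  bin_base <- function(k, si) {
    if (k %in% cfg$core_bins) cfg$promoter_hypo_level
    else clamp(cfg$stage_means[si], 0.05, 0.90)
  }
  wb <- cfg$cpg_profile / sum(cfg$cpg_profile)
  label_base <- function(lb, si) {
    s <- cfg$stage_means[si]
    switch(lb,
      "up2" = {
        up <- ks[ks < 0]
        sum(vapply(up, bin_base, 0, si = si) * cfg$cpg_profile[as.character(up)]) /
          sum(cfg$cpg_profile[as.character(up)])
      },
      "5UTR" = {
        dn <- ks[ks >= 1 & ks <= 3]
        mean(vapply(dn, bin_base, 0, si = si))
      },
      "3UTR" = clamp(s + cfg$utr3_boost, 0.05, 0.95),
      "exon" = s, "intron" = s,
      s)  # distal flanks follow the stage mean
  }
  build <- function(labels, base_fun, rho_vec) {
    v <- matrix(rnorm(n * length(labels)), n, length(labels),
                dimnames = list(gene_ids, labels))
    meth <- array(NA_real_, dim = c(n, length(labels), nrow(manifest)),
                  dimnames = list(gene_ids, labels, manifest$sample_id))
    for (i in seq_len(nrow(manifest))) {
      si <- match(manifest$stage[i], cfg$stages)
      for (j in seq_along(labels)) {
        rho <- rho_vec[j]
        mu <- clamp(base_fun(labels[j], si) + cfg$meth_gene_sd *
                      (rho * u + sqrt(1 - rho^2) * v[, j]), 0.02, 0.98)
        meth[, j, i] <- .rbeta_meansd(mu, region_noise_sd)
      }
    }
    structure(list(meth = meth,
                   n_cpg = array(1L, dim = dim(meth),
                                 dimnames = dimnames(meth)),
                   genes = gene_ids, labels = labels,
                   samples = manifest$sample_id),
              class = "meth_matrix")
  }
  regions <- build(region_labels(), label_base,
                   cfg$designed_r[region_labels()])
  bins <- build(as.character(ks),
                function(lb, si) bin_base(as.integer(lb), si),
                cfg$designed_r_bins[as.character(ks)])
  log2e <- outer(u, rep(1, n_stage)) * cfg$expr_gene_sd + cfg$expr_mu +
    matrix(rnorm(n * n_stage, sd = cfg$expr_noise_sd), ncol = n_stage)
  colnames(log2e) <- cfg$stages
  rownames(log2e) <- gene_ids
  list(regions = regions, bins = bins, manifest = manifest,
       expr_mat = log2e,
       truth = list(designed_r = cfg$designed_r,
                    designed_r_bins = cfg$designed_r_bins,
                    stage_means = cfg$stage_means))
}
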