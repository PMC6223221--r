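# methbins

Analysis of DNA methylation sub-patterns across gene-neighbourhood regions
and promoter bins from whole-genome bisulfite sequencing (WGBS) CpG calls,
aimed at stage-structured methylomes such as early embryonic development
series, where global methylation collapses after fertilisation and is
re-established after implantation.

## What it computes

For each annotated gene (one representative mature-mRNA transcript per gene
and transcription start site), the ±20 kb neighbourhood is partitioned into
**12 strand-aware regions**

```
up20 | up10 | up5 | up2 | 5'UTR | exon | intron | 3'UTR | down2 | down5 | down10 | down20
```

measured from the TSS/TES in the direction of transcription, and the
candidate promoter (TSS ± 2 kb) is tiled into **20 consecutive 200 bp bins**
indexed −10…−1 upstream and 1…10 downstream of the TSS (no bin 0; bin 1 is
the first 200 bp of the transcript).

On top of that geometry the package provides:

- **Aggregation** — the methylation level of a region in a sample is the
  unweighted mean of its covered CpG levels (coverage ≥ 5 by default,
  opposite-strand dyad calls collapsed by coverage-weighted mean); stage
  levels are arithmetic means over biological replicates, and the
  genome-level value is the unweighted mean over genes.
- **CpG-density classes** — each 200 bp window is HCG (> 8 CpGs),
  ICG (4–8) or LCG (< 4) from the reference sequence.
- **Methylation states** — genes (or any single region/bin) are
  discretised into hypo (≤ 0.3), moderate, hyper (≥ 0.7) states, and
  3 × 3 transition matrices are counted between stage pairs.
- **Expression integration** — Pearson correlation *r* across genes
  between region/bin methylation and log2 RPKM (zeros reset to the
  per-sample minimum non-zero value), per stage; PCA over the bins'
  correlation profiles locates the TSS-proximal block that behaves as the
  functional promoter.
- **Differential genes at bin 1** — four filters between two stages A and
  B: fold change > 2 (decrease A→B), Welch t-test on replicates, bin-1
  level above the cohort mean at A, expression increase A→B; the passing
  list is written one ID per line.
- **A seeded synthetic-data generator** — genome FASTA, gene models, CpG
  call files, manifest and matched expression with known ground truth
  (designed stage means, correlation signs, transition and differential
  gene sets), so the whole pipeline is testable without any download.

## Worked example

Simulate a 60-gene, 7-stage methylome and recover its designed global
trajectory and per-region correlation signs:

```r
library(methbins)

cfg  <- simulation_config(n_genes = 60, seed = 7)
sim  <- simulate_methylome(cfg)

regions <- partition_regions(sim$genes, chrom_lengths = sim$chrom_lengths)
whole   <- collapse_annotation(regions)
calls   <- lapply(sim$calls, function(x) x[x$coverage >= 5, ])

ss <- stage_average(methylation_matrix(calls, whole), sim$manifest)
data.frame(stage = ss$global$stage,
           estimated = round(ss$global$mean, 3),
           designed = cfg$stage_means)
#>   stage estimated designed
#>  zygote     0.496     0.50
#>   2cell     0.346     0.35
#>   4cell     0.326     0.33
#>   8cell     0.316     0.32
#>  morula     0.296     0.30
#>     ICM     0.296     0.30
#>    post     0.741     0.75
```

The estimated genome-level methylation tracks the designed dip-then-rise
trajectory to within a few thousandths. Correlating region methylation with
expression recovers the designed signs — negative at the hypo-methylated
up2/5'UTR promoter flank, positive at the hyper-methylated 3'UTR and the
distal flanks:

```r
ssr <- stage_average(methylation_matrix(calls, regions), sim$manifest)
em  <- expression_matrix(log_expression(sim$expression))
cr  <- stage_correlation(ssr, em)
round(tapply(cr$r, cr$label, mean)[region_labels()], 2)
#>  up20   up10    up5    up2   5UTR   exon intron   3UTR  down2  down5 down10 down20
#>  0.46   0.46   0.46  -0.55  -0.26  -0.48  -0.01   0.27   0.46   0.46   0.45   0.46
```

`run_pipeline(pipeline_config(...))` (or a YAML config, or the wrapper in
`inst/scripts/methbins.R`) runs every step end to end and writes BED
annotations, TSV tables with parameter headers, the differential gene list
and JSON run metadata, byte-identically for a fixed config.

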