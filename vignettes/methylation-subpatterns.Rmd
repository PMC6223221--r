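---
title: "Methylation sub-patterns across gene regions and promoter bins: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation sub-patterns across gene regions and promoter bins: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methbins)
```

## The analysis model

methbins quantifies how DNA methylation is distributed across the
regulatory neighbourhood of genes, and how that distribution relates to
transcription, in datasets with a stage structure (developmental series,
tissue panels). The unit of analysis is never the single CpG but a *named
sub-region of a gene's neighbourhood*, which makes methylation levels
comparable across genes, stages and datasets.

### Coordinate conventions

All genomic intervals are 0-based, half-open `[start, end)`, matching BED
and refFlat inputs. The TSS of a plus-strand model is `tx_start`; on the
minus strand it is `tx_end`, i.e. always the boundary from which
transcription proceeds. A CpG dyad is identified by the position of its
plus-strand C; a call reported on the minus strand refers to position
`pos − 1` of the same dyad.

### The twelve regions

The flanks are fixed-width segments measured from the TSS (upstream) and
TES (downstream) *in the direction of transcription*: up2 = 0–2 kb, up5 =
2–5 kb, up10 = 5–10 kb, up20 = 10–20 kb before the TSS, and down2…down20
symmetrically after the TES. The gene body is split by transcript
structure: 5'UTR (exonic bases between TSS and CDS start, in transcript
order), exon (exonic bases overlapping the CDS), 3'UTR (exonic bases
between CDS end and TES) and intron (all non-exonic gene-body bases).
Defining "exon" as the CDS-overlapping exonic bases keeps the four body
regions a partition of `[tx_start, tx_end)` — the UTRs are drawn as
disjoint from the exon region, so every body base has exactly one label.
For non-coding models the three CDS-derived regions are empty and the body
contributes only introns; all twelve labels remain in the vocabulary (a
factor) even when a gene has no bases under some of them.

Flank regions of neighbouring genes are deliberately **not** trimmed
against each other: a CpG that falls in two genes' neighbourhoods counts
in both. Overlap handling rules differ between published pipelines and any
choice is defensible; not trimming is the simplest reproducible one, and
the synthetic generator places genes far enough apart that it never
matters there.

### The twenty promoter bins

The candidate promoter TSS ± 2 kb is tiled by twenty 200 bp bins indexed
−10…−1 (upstream) and 1…10 (downstream); there is no bin 0. Bin *k* ≥ 1
covers `[TSS + (k−1)·200, TSS + k·200)` in transcription direction, so bin
1 is the first 200 bp of the transcript and bin −4 to bin 6 together span
800 bp upstream to 1200 bp downstream of the TSS. On the minus strand
every bin interval is the reflection of its plus-strand counterpart about
the TSS. Bins clipped by a chromosome end are flagged `partial`.

### Transcript selection

Only transcripts whose accession carries the mature-mRNA prefix (`NM_` by
default, configurable) enter the analysis; alternative transcripts that
share a gene and a TSS are collapsed to one, keeping the lexicographically
smallest accession so the choice is deterministic. Distinct TSSs of one
gene are kept as distinct models, since every bin and flank coordinate is
anchored at the TSS.

### Aggregation

The methylation level of a region in a sample is the **unweighted
arithmetic mean** of the levels of the CpGs inside it — coverage gates
which calls exist (≥ 5 reads by default) but does not weight the mean.
Cells with no covered CpG are missing, never zero, and each cell records
its contributing CpG count. Stage values are means over the biological
replicates present; the genome-level value of a stage is the unweighted
mean over genes (not CpG-weighted), so large genes do not dominate.

The read-coverage threshold default is ≥ 5. The protocol this follows
states the rule both as "greater than five" and "at least fivefold"; the
inclusive reading retains more sites and is the default, with
`coverage_min` exposed everywhere. The coverage filter is applied to each
input row before dyad collapsing, so a strand observed fewer than
`coverage_min` times never contributes to a collapsed call.

### States and transitions

A methylation fraction is discretised as hypo (≤ `hypo_max`), hyper
(≥ `hyper_min`) or moderate. The cut-offs are not canonical in the
literature for this analysis; the defaults 0.3/0.7 are conventional WGBS
values, both bounds are inclusive, configurable, and echoed into every
output header because transition counts depend on them directly.
Transitions between two stages are counted over the genes classified in
both; genes missing in either stage are excluded and reported, which keeps
the matrix total interpretable.

### Expression integration

RPKM values are log2-transformed after resetting zeros to the minimum
non-zero RPKM. The reset scope is per sample by default (each sample has
its own detection floor); a global scope is available. For every stage and
region/bin label, Pearson *r* is computed across genes over
pairwise-complete values; an estimate from fewer than three genes or from
a constant vector is reported missing/unreliable rather than silently
returned. The bin-level correlation profiles (20 bins × stages) are
summarised by PCA with the bins as observations and the stages as
features, centred but not scaled (all entries are already correlation
coefficients on one scale); each component's sign is fixed by making its
largest-magnitude loading positive, so scores are reproducible across
platforms.

### Differential genes at bin 1

Bin 1 — the first 200 bp of the transcript, the CpG-densest and most
consistently hypo-methylated window — is screened between two stages A and
B with four filters: (i) mean methylation fold change above
`fold_change_min` (default 2) in the configured direction (default:
decrease from A to B); (ii) Welch two-sample t-test on the replicate
values with `p < p_max`; (iii) the gene's bin-1 level at stage A above the
cohort mean at A; (iv) expression increase from A to B. Welch's unequal
variance form is used because 1–3 replicates per stage give no basis for a
pooled-variance assumption. The printed protocol gives `p < 0.5`, which is
kept as the default for fidelity even though it is a weak filter and very
likely a typo for 0.05; setting `p_max = 0.05` is a one-argument change.
Genes with fewer than two replicates in either stage cannot be tested and
fail the t-test filter by default (`untestable = "pass"` inverts this).
The filter direction is also configurable because "differential" series
can run either way.

## The synthetic-data generator

`simulate_methylome()` renders a complete, self-consistent dataset from a
designed truth, so every pipeline stage can be validated end to end with
no external data.

**What it emulates.** Seven developmental stages whose genome-level
methylation dips after the zygote (0.50 → 0.35), plateaus around 0.30
through the blastocyst and rises to 0.75 post-implantation; a promoter
core (bins −4…6) pinned hypo-methylated at 0.10 across all stages while
the outer bins follow the global trajectory; a 3'UTR elevated 0.25 above
the stage mean; a unimodal promoter CpG-density profile peaking at 12
CpGs/200 bp in bin 1, yielding LCG outermost upstream bins and an HCG
block around the TSS; expression coupled to methylation with designed
per-region correlations (−0.3 at up2/5'UTR and the promoter core, +0.3 at
the 3'UTR and distal flanks, −0.1 in the gene body, −0.2 in outer bins).
Per-CpG noise is beta-distributed (mean = designed level, sd 0.05 by
default) so values stay in [0, 1]; read coverage is negative-binomial
(mean 30, size 5) so the fivefold filter removes a realistic few percent
of calls. The numbers above are generator parameters chosen to reproduce
the qualitative structure of published early-embryo methylomes, not
measured values.

**Calibration.** Region-specific levels would normally make the realized
genome-level mean drift from the per-stage target. The generator therefore
solves the distal-flank base level analytically per gene and stage so that
the CpG-count-weighted mean over the whole ±20 kb neighbourhood equals the
stage target exactly in expectation. This is what makes
"pipeline-estimated stage means match `stage_means`" a meaningful
recovery check rather than a coincidence.

**Coupling.** Each gene carries a latent `u ~ N(0,1)`. A zone's designed
level is shifted by `meth_gene_sd · (ρ·u + √(1−ρ²)·v)` with an independent
per-zone `v`, and log2 expression is `expr_mu + expr_gene_sd·u` plus small
stage noise — so the methylation–expression correlation at a zone is ρ by
construction, with mild attenuation from clamping to [0.02, 0.98] and from
aggregation noise.

**Two fidelity levels.** The full renderer places every CpG in a genome
FASTA (filler drawn from {A, C, T} so the only CG dinucleotides are the
designed dyads) and draws per-CpG, per-sample levels. For estimator
property studies that need hundreds of repetitions,
`simulate_region_levels()` renders the same design directly at
region/bin granularity — one beta draw per gene, label and sample — which
is two orders of magnitude cheaper and exercises the estimators
identically downstream of aggregation.

**What it does not emulate.** CpG islands/shores as sequence entities,
copy-number or mappability artefacts, bisulfite non-conversion,
cell-to-cell heterogeneity within a sample, distance-decay correlation
between neighbouring CpGs, or overlapping gene models. Passing recovery
tests on this generator therefore demonstrates the correctness of the
bookkeeping and the estimators under the designed signal structure, not
robustness to every artefact of real WGBS data.

## Numerical and design choices

- **Half-open boundaries everywhere**: a CpG whose C sits exactly at a
  region's end coordinate belongs to the next region; a C at position
  `end − 1` belongs to the region even though the dyad's G falls outside.
- **down2 starts at the TES** (`[TES, TES + 2 kb)` in transcription
  direction), interpreting the flank grid symmetrically with up2.
- **Promoter-level density class** is the class of the densest 200 bp bin
  within TSS ± 2 kb (`method = "max"`); a mean-count roll-up is available.
  The per-window class definition is fixed; the roll-up is a choice and is
  therefore exposed.
- **Ties and determinism**: transcript tie-breaks are lexicographic; PCA
  signs follow the dominant-loading convention; pipeline outputs are
  written with fixed number formatting (15 significant digits via C
  locale) so identical config + seed gives byte-identical files, which the
  test suite verifies by checksum.
- **Degenerate inputs**: empty call files, all-zero expression samples,
  constant correlation vectors, genes without CDS, single-replicate
  t-tests and chromosome-edge promoters all have defined, tested
  behaviour (warning, error naming the culprit, missing value, or flag —
  never a silent wrong number).

## Problem sizes used by the test suite

Structural checks run on single hand-built genes. Oracle-equivalence
compares against a brute-force interval scan on 50 random genes × 5000
CpGs at 1e-12. Parameter recovery uses the full renderer at 500 genes ×
7 stages × 3 replicates (estimated stage means within ±0.02 of truth) and
100 fast renderings at 500 genes for correlation-sign recovery (every
region with |designed r| = 0.3 must recover its sign in ≥ 95% of
replicates). Transition recovery uses 60 genes of which 50 are designed
hypo→hyper (all 50 recovered noise-free, ≥ 45 required at CpG noise
sd 0.05). These sizes were chosen so the whole suite completes in a couple
of minutes while leaving the statistical margins wide.

## Known limitations

- Gene-neighbourhood overlap is not resolved; in gene-dense genomes a CpG
  can be counted in several genes' flanks.
- The correlation analysis is cross-sectional per stage; it does not model
  within-gene longitudinal structure across stages.
- The hypo/hyper cut-offs and the promoter density roll-up are
  conventions, not estimated quantities; conclusions that depend on them
  should be checked across a range of settings (they are all single
  arguments).
- GO enrichment of the differential gene list is out of scope; the list
  is written in a form ready for external enrichment tools.
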