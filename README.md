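# exchseq

Quantitative analysis of dual-tag histone-exchange sensor ChIP-seq.

## The problem

Histone turnover — the replacement of a DNA-bound histone by a newly
synthesized or variant copy — shapes chromatin memory, but bulk ChIP-seq only
reports occupancy. A dual-tag cleavage sensor makes turnover measurable: a
histone is fused to **myc–TEV site–HA**, and a TEV protease carried on a
partner histone clips off the myc tag while the sensor resides on chromatin.
Long co-residence therefore destroys myc; recently exchanged (short-residence)
histones keep it. Sequencing the myc and HA immunoprecipitations side by side
gives, per locus,

- **occupancy** — the HA channel, and
- **exchange** — the log-ratio
  `E = log2(myc + 0.05) − log2(HA + 0.05)`,

with a non-cleavable (NC) sensor variant as the antibody-bias control
(myc ≡ HA in expectation, so E centers at 0). `exchseq` is for epigenomics
groups running such sensors (or reanalyzing them): it takes aligned
paired-end fragments plus standard region annotations and produces exchange
tracks, region analytics and replicate-level statistics.

## What the package does

- **Import & preprocessing** — BAM/SAM or fragment-BED import with a
  mapping-quality filter (MQ ≥ 10), fragment-length filter (> 300 bp
  removed), strand-aware 5′-end shift (80 bp ≈ half the mean fragment
  length), per-region mean coverage, depth normalization to a genome-wide
  5 kb-tiling mean of 0.4, and seeded depth-matched replicate pooling.
- **Exchange statistics** — per-region exchange score, pooled
  mean-then-log-ratio bin exchange, histone-mark enrichment
  `log2(mark+1) − log2(input+1)`, control-region normalization (mean E of
  20 kb-shifted regions subtracted), high/low turnover stratification
  (occupancy > 1; E > 1.55 / E < −0.45 log2 units), PRC2 score, and
  dynamics-mode calls (incorporation / eviction / exchange shift / stable).
- **Region analytics** — genome tiling, anchored metaprofile matrices,
  scaled-gene matrices (10 × 500 bp flank bins + 100 body bins = 120
  columns), equal-count covariate binning with coverage filtering, LOESS
  trendlines, top-fraction selection, heterochromatin peak selection.
- **CTCF asymmetry** — strand-aware exchange over the four nucleosomes
  around motif centers (31 bins), per-motif asymmetry
  `A = mean E(+1,+2) − mean E(−1,−2)`, top-vs-bottom-decile contrasts, and
  occupied/unoccupied motif partitions.
- **Repeat quantification** — best-match multimapper assignment (seeded
  ties), total-aligned-read normalization, < 100-read and rRNA filters,
  pairwise log2 enrichment, 250-window element profiles.
- **Differential contrasts** — per-replicate target-minus-reference deltas
  and two-sided t-tests between conditions (pooled Student by default,
  Welch optional), as used for chaperone-knockout comparisons.
- **Simulator** — a seeded kinetic simulator: exponential residence (rate
  λ) races first-order TEV cleavage (rate κ), so the steady-state
  myc-retaining fraction is `f = λ/(λ+κ)`; labeled synthetic genomes with
  genes, enhancers, CTCF motifs, repeats and heterochromatin emit Poisson
  myc/HA fragment channels from ground-truth rates.

## Worked example

Simulate a small labeled genome, sequence its sensor channels, and score
5 kb tiles:

```r
library(exchseq)

fix <- build_genome_fixture(n_genes = 60, n_ctcf = 40, n_repeats = 20,
                            n_enhancers = 30, n_hetero = 4,
                            chrom_lengths = c(chr1 = 1e6, chr2 = 1e6),
                            seed = 7)
ch    <- simulate_channels(fix, depth = 2e5, kappa = 1, seed = 8)
tiles <- tile_genome(fix$genome, 5000)
tr    <- exchange_track(filter_fragments(ch$myc), filter_fragments(ch$HA),
                        tiles, fix$genome)
head(round(tr, 3))
#>     myc    ha exchange
#> 1 0.393 0.522   -0.369
#> 2 0.224 0.373   -0.628
#> 3 0.220 0.280   -0.289
#> 4 0.326 0.229    0.429
#> 5 0.461 0.516   -0.148
#> 6 0.389 0.362    0.095
```

`myc` and `ha` are depth-normalized mean coverages per kb; `exchange` is
their pseudocounted log2 ratio. Open chromatin turns over fast, silent
chromatin slowly:

```r
open <- overlap_flags(tiles, c(granges(fix$enhancers),
                               gene_promoters(fix$genes)))
het  <- overlap_flags(tiles, fix$heterochromatin)
mean(tr$exchange[open])   #>  0.275
mean(tr$exchange[het])    #> -0.754
```

which mirrors the ground truth: the uncleaved fraction for
heterochromatin-like (λ = 0.3), average (λ = 1) and promoter-like (λ = 6)
rates at κ = 1 is

```r
steady_state_uncleaved(c(0.3, 1, 6), 1)
#> 0.231 0.500 0.857
```

The full pipeline (simulate → filter → shift → count → normalize →
exchange → TSS/CTCF analytics, all TSV outputs plus a run manifest) runs
from a YAML config:

```r
run_pipeline(system.file("extdata", "demo-config.yaml", package = "exchseq"),
             out_dir = "demo-out")
```

A thin CLI with `run`, `validate` and `simulate` subcommands is in
`inst/scripts/exchseq.R`.

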