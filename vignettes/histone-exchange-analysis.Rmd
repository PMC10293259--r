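---
title: "Quantifying histone exchange from dual-tag sensor ChIP-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying histone exchange from dual-tag sensor ChIP-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exchseq)
```

## The measurement and its model

A dual-tag exchange sensor is a histone fused to myc–TEV-site–HA, expressed
alongside a TEV protease fused to a partner histone. While the sensor resides
on chromatin next to the protease, its myc tag is progressively cleaved off;
the HA tag is never touched. An anti-HA immunoprecipitation therefore reports
where the sensor sits (occupancy), while anti-myc reports where it arrived
*recently* — the longer a nucleosome stays put, the more completely it loses
myc. The per-locus statistic of interest is the exchange score

$$E = \log_2(\mathrm{myc} + \varepsilon) - \log_2(\mathrm{HA} + \varepsilon),
\qquad \varepsilon = 0.05,$$

computed on depth-normalized mean coverages. The pseudocount damps the noise
of sparsely covered regions; because immunoprecipitation depths are
arbitrary, only *relative* exchange is meaningful, and every downstream
statistic in the package is a ratio, a log-difference, or a contrast against
a control region set.

The simulator formalizes the sensor with the simplest kinetic race that
reproduces its logic: a chromatin-bound sensor leaves its locus after an
exponential residence time with eviction rate $\lambda$ (exchanges per unit
time), while cleavage removes its myc tag at first-order rate $\kappa$. The
probability that eviction wins — the steady-state myc-retaining fraction —
is

$$f(\lambda, \kappa) = \frac{\lambda}{\lambda + \kappa}.$$

This closed form is a modeling choice of this package, not a claim about the
biology: the experimental system only states the qualitative logic (long
co-residence ⇒ productive cleavage ⇒ low myc). $f$ is strictly increasing in
$\lambda$, decreasing in $\kappa$, and equals 1 at $\kappa = 0$ — the
non-cleavable control, for which myc and HA coincide in expectation and $E$
centers at 0. A unit test cross-checks $f$ against a direct simulation of
10^5 exponential races.

Two estimators of binned exchange coexist because both are standard:

- the **per-region score** (`exchange_score`), used for tracks, turnover
  classification and region contrasts;
- the **pooled mean-then-log score** (`pooled_bin_exchange`),
  $\log_2(\overline{\mathrm{myc}} + \varepsilon) -
   \log_2(\overline{\mathrm{HA}} + \varepsilon)$ over a bin of regions,
  used for the CTCF nucleosome bins. The two differ on heterogeneous bins
  (Jensen's inequality), so each call site is bound to one explicitly.

## Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| `min_mapq` | 10 | — | drop ambiguous alignments on import |
| `max_fragment_bp` | 300 | bp | remove over-long templates (> 300 excluded; 300 kept) |
| `shift_bp` | 80 | bp | move 5′ ends to ~fragment midpoints (half of the ~160 bp mean fragment length), strand-aware |
| `depth_target` | 0.4 | mean coverage/kb | common scale: every sample's genome-wide 5 kb-tiling mean is set to 0.4 |
| `pseudocount` | 0.05 | coverage/kb | noise floor of the exchange log-ratio |
| enrichment pseudocount | 1 | count | keeps mark enrichment finite at zero coverage |
| `atac_min_bp` | 120 | bp | ATAC channel keeps ≥ 120 bp (nucleosomal) fragments |
| turnover thresholds | 1 / 1.55 / −0.45 | log2 | occupancy floor, high-, low-exchange cutoffs |
| CTCF layout | 180 bp × 4, 31 bins | bp | two nucleosomes on each side of the motif center |
| control shift | 20 000 | bp | shifted-copy control region sets |
| repeat filters | 100 reads; rRNA | — | minimum evidence per family; class drop |

Processing order matters for two of these: depth normalization is applied
*before* the pseudocount, so a global rescaling of all channels cancels
exactly (asserted by a test that duplicates every fragment and requires
identical exchange scores); and boundary conventions follow the printed
inequalities literally — 300 bp fragments survive the `> 300` filter, 120 bp
fragments survive the `< 120` filter, MQ 10 survives `MQ ≥ 10`.

## Geometry and numerical choices

**Coordinates.** Internally everything is a `GRanges` (1-based, closed —
the Bioconductor convention); BED I/O converts at the boundary. Half-open
BED semantics are preserved: adjacent BED intervals `[a,b)`, `[b,c)` never
overlap after import, and all printed window widths are honored as lengths.

**CTCF bin layout.** The analyzed window is the motif center ± 360 bp (four
180 bp nucleosomes) in 31 bins. 720/31 leaves a 7 bp remainder, which is
absorbed by the *central* bin: that keeps the bin edges mirror-symmetric, so
flipping every motif strand permutes bins exactly and negates every
asymmetry score bit-for-bit (a property the tests assert with
`expect_identical`). Layouts are configurable; an even bin count is only
accepted when the window divides evenly.

**Scaled matrices.** Gene matrices use 10 fixed 500 bp bins per 5 kb flank
and 100 length-scaled body bins (repeat elements: 250 body windows).
Minus-strand bodies are binned by distance from their own 5′ end rather than
by reversing plus-strand bins — the two differ when the length is not a
multiple of the bin count, and only the former makes minus-strand matrices
the exact mirror image of the plus-strand computation.

**Quantile binning.** Covariate bins are equal-count; when `n` does not
divide evenly the remainder is spread one-per-bin over the *leading* bins
(10 regions in 3 bins → 4, 3, 3). Ties keep their original order (stable
radix sort). The same engine serves expression bins, PRC2-score bins and
repeat rankings.

**Shifted controls.** Control regions are literal 20 kb translations
(strand-ignorant by default; a strand-aware mode exists). Shifted intervals
that leave the chromosome are dropped, not clipped — target and control sets
may then differ in size, which is harmless because only control *means* are
ever subtracted. Whether to clip, drop or wrap is genuinely open; dropping
is the conservative choice and the drop count is always reported.

**Trend smoothing.** Display trendlines use LOESS (span 0.5, degree 2,
direct surface) rather than Friedman's supersmoother: trendlines are
cosmetic here — every quantitative statistic is an exact binned mean — and
LOESS reproduces noiseless linear input to machine precision, which makes
the substitution testable.

**Degenerate inputs.** Zero-coverage regions score 0 (pseudocount floor);
empty control sets, non-disjoint contrast sets, single-replicate t-tests and
malformed BED lines (reported with their line number) are all refused with
explicit errors rather than propagating NaN.

## The t-test default

Condition contrasts use the two-sided *pooled-variance Student* t-test by
default, with Welch available via `var_equal = FALSE`. At the replicate
counts these experiments actually have (2 vs 2), the Welch approximation is
badly conservative — a 20,000-run null simulation during development showed
an empirical level of 0.022 at nominal 0.05, versus 0.048 for the pooled
test — and the pooled test also matches the reported methodology of the
experiments this package emulates. The acceptance suite re-checks
calibration (200 null knockout runs) on every run.

## What the simulator does and does not emulate

`build_genome_fixture` lays out non-overlapping genes (log-normal lengths
and expression), stranded CTCF motifs, repeat insertions, three enhancer
classes and heterochromatin blocks on a small genome (default two 5 Mb
chromosomes), then covers every base with exactly one locus (annotation loci
plus 5 kb background tiles — partitioned with exact integer arithmetic, as a
test asserts). Each class gets typical occupancy and exchange-rate values
with log-normal within-class spread (sdlog 0.4): promoters and active
enhancers fast (λ ≈ 6 and 5 on the κ = 1 scale), primed/poised enhancers
intermediate, heterochromatin occupied but slow (O ≈ 0.9, λ ≈ 0.3),
background sparse. Gene-body rates scale with expression so expressed genes
turn over faster. These values are the package's own calibration of
"realistic": severalfold coverage variation across the genome and an order
of magnitude of rate variation between fast and slow chromatin.

`simulate_channels` draws Poisson fragment counts per locus (HA ∝ occupancy,
myc additionally damped by $f$), uniform midpoints, truncated-normal lengths
(160 ± 40 bp), Bernoulli strands; optional input, mark and ATAC channels
(the last with a sub-120 bp nucleosome-free component at open loci).
`simulate_region_counts` is the count-level fast path for repeated
power/calibration studies.

Deliberately **not** modeled: histone recycling and the untagged histone
pool (invisible to the sensor), locus-specific protease availability (only
an optional orientation asymmetry knob at CTCF flanks), PCR duplicates,
GC/mappability bias, replication-coupled dilution, and base-level sequence.
Passing tests therefore show that the *estimators* recover known kinetics
from idealized sequencing noise — not that real libraries are free of the
biases above.

## Problem sizes used by the test and acceptance suites

Rank recovery uses 2,000 loci of 1 kb at ~50 HA fragments each; the
non-cleavable control uses the default 10 Mb fixture at 10^6 fragments per
channel; knockout power and calibration use 2 WT vs 2 KO replicates over
100-region sets at ~200 fragments per region (a size at which a halved
exchange rate gives a design power near 1 for the pooled t-test); the demo
pipeline runs two 1 Mb chromosomes at 2 × 10^5 fragments. These sizes keep
the full suite under a minute while leaving every statistic comfortably
inside its asymptotic regime.

## Known limitations

- Exchange is relative: no calibration to absolute turnover rates in time
  units is attempted (the sensor itself cannot distinguish a global myc
  scale from normalization).
- The kinetic race is memoryless on both sides; cooperative eviction or
  cleavage saturation would bend $f$ away from $\lambda/(\lambda+\kappa)$.
- With 2 + 2 replicates the t-tests have 2 degrees of freedom; they are
  calibrated but weak, and the per-motif asymmetry t-test treats motifs as
  the replication unit.
- The multimapper assignment averages tied best hits uniformly; a true
  EM re-estimation of repeat abundances is out of scope.
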