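---
title: "Two-cultivar WGBS methylome analysis with epimung"
author: "epimung maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-cultivar WGBS methylome analysis with epimung}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epimung)
```

# The problem

Whole-genome bisulfite sequencing (WGBS) reads out DNA methylation at
single-base resolution: unmethylated cytosines are converted to uracil
(read as T), methylated cytosines are protected. After alignment, each
cytosine carries a pair of counts — reads supporting methylation and
reads supporting non-methylation. In plants, methylation occurs in three
sequence contexts, CG, CHG and CHH (H ∈ {A, T, C}), each maintained by a
different enzymatic pathway, so every analysis is stratified by context.

`epimung` implements a complete desk-scale pipeline for comparing the
leaf methylomes of two mungbean (*Vigna radiata*) cultivars: methylation
calling calibrated against an unmethylated chloroplast control, weighted
methylation levels and profiles, differentially methylated sites,
windows (DMRs) and genes, SNP-induced cytosine-context transitions
("obligate epialleles"), and the negative coupling between gene-body
methylation and expression. A seeded synthetic-data generator provides
two-cultivar datasets with complete ground truth, so every stage of the
pipeline is validated by parameter recovery rather than by fiat.

# The calling model

## Non-conversion calibration

Bisulfite conversion is imperfect: a small fraction `p_err` of truly
unmethylated cytosines fails to convert and reads as methylated. The
chloroplast genome is essentially unmethylated in plants, so reads
aligned to it estimate this rate directly:

\[
\hat p_{err} = \frac{\sum_i m_i}{\sum_i (m_i + u_i)}
\]

pooled over all chloroplast cytosines and all contexts
(`estimateNonConversion()`). At the defaults the synthetic control pools
about 10^6 reads, so the estimate lands within a few parts in 10^5 of
the planted rate 0.001114.

## Binomial calling and count correction

For a site with `m` methylated reads out of `n`, the evidence for
methylation is the one-sided upper-tail binomial probability
\(P(X \ge m)\), \(X \sim \mathrm{Binom}(n, p_{err})\) — only an excess
of methylated reads over the conversion-failure floor counts as
evidence, hence one-sided (`binomialP()`, exact, no normal
approximation). P-values are converted to q-values across all covered
sites of a sample, all contexts jointly; Benjamini–Hochberg is the
default (parameter-free and conservative) with a Storey-type estimate
(`fdr = "storey"`, fixed λ = 0.5) as an option. A site is called
methylated iff `q < 0.01`; the threshold is exposed because the
literature this pipeline follows does not fix one.

Counts are then corrected: significant sites keep their raw counts,
while at non-significant sites *all* reads are regarded as unmethylated.
Total reads are conserved (an invariant the test suite asserts), and the
corrected counts feed every downstream level and test. A raw-count mode
is retained behind `counts = "raw"` for diagnostics.

Zero-coverage sites are passed through untested (`p = q = 1`,
unmethylated, corrected counts (0, 0)): no data, no call. A separate
reliability filter (`filterSites()`, strict `depth > 10` and
`level > 0.9`) reproduces the site-selection rule used for the paralog
analysis.

# Context arithmetic

A cytosine's context is decided from the two bases 3' of it *on its own
strand*; minus-strand cytosines (a G on the plus strand) are reported at
the plus-strand coordinate of that G — the Bismark convention, kept at
every interface so coordinates are shared with the reference genome.
Decidability at sequence ends is handled by rule, not imputation: a
terminal "CG" is CG (the third base cannot change it), a terminal "C" or
"CH" is undecidable and excluded, and any N at a decisive position
excludes the site. `enumerateCytosines()` is checked against a
per-position brute-force scan on random sequences, including an
exhaustive strand-symmetry oracle (re-scanning the reverse complement).

# Weighted levels, profiles and categories

The weighted methylation level of a region is
\(\sum m / \sum (m + u)\) over the region's sites of one context — a
depth-weighted mean, equal to the plain mean of site levels only at
uniform depth (an identity the tests exercise). A region with no covered
sites has an *undefined* level, never 0: absence of data is not
hypomethylation. The same convention excludes empty feature-bins from
metagene averages.

`metageneProfile()` length-normalises feature bodies into 20 bins plus
2 kb flanks in 20 bins by default (common metaplot practice; the bin
layout puts remainder bases in the final, most 3' bin, and minus-strand
features are reversed so bins always run 5'→3'). Per-feature bin levels
are averaged across features by default; `aggregate = "pooled"` pools
counts instead — both are offered because either convention appears in
published metaplots. `windowCounts()` tiles chromosomes into 50 kb
windows (truncating the last), and `categorizeSites()` assigns each
methylated site to exactly one genomic category with precedence
UTR > CDS > intron > 1 kb-upstream > intergenic, a partition the tests
check sums exactly.

# Differential methylation

Two-sample comparisons use Fisher's exact test on 2×2 count tables,
implemented in `fisherTwoSided()` by summing hypergeometric outcome
probabilities not exceeding the observed table's probability (the
conventional two-sided rule, with the usual 1 + 1e-7 tie band; validated
exhaustively against an independent enumeration for all tables with row
margins ≤ 30, and against `stats::fisher.test`). Degenerate tables with
a zero margin admit a single outcome and return p = 1.

* **Per-site** (`perSiteTests()`): sites covered in *both* samples
  ("commonly called") are tested on corrected counts and flagged at raw
  `p < 0.01` — raw because the survey statistic this reproduces is
  reported unadjusted.
* **DMRs** (`dmrScan()`): 200 bp windows stepping 50 bp (150 bp
  overlap), fully contained windows only so the candidate threshold is
  comparable across windows. A window is a candidate iff its pooled
  corrected methylated reads strictly exceed 5 in at least one sample;
  candidates are significant at Fisher `p < 0.01`. Windows pool all
  three contexts by default (`context =` restricts). Direction compares
  the window weighted levels.
* **Genes** (`geneDifferential()`): per context, counts pooled over the
  gene body; genes with zero pooled depth in either sample are excluded
  and counted.

# SNP-induced context transitions

A SNP within two bases of a cytosine can move it between CG, CHG and
CHH, or create/destroy a context-decidable cytosine site altogether —
methylation differences at such sites are *obligate epialleles*, fully
explained by the underlying genetic variant. `applySNPs()` builds the
substituted genome (contexts are evaluated on the fully substituted
sequence, so clustered SNPs compose correctly), and
`classifyTransitions()` scans the ±2 bp neighbourhood of every SNP on
both strands. Gain/loss is defined as "a context-decidable site present
in exactly one genome", which makes the local scan *exactly* equal to a
whole-genome re-enumeration diff — the oracle the acceptance suite runs
on 100 random genomes. Both per-cytosine and per-SNP tallies are
emitted, and directed classes can be rolled up to undirected pairs.
`crosstabTransitions()` then tabulates transition classes against the
called state changes (M→M, M→U, U→M, U→U), tallying sites uncovered in
either sample separately.

# Methylation–expression integration

All associations are Spearman rank correlations: expression scales are
heavy-tailed and the planted relationships are monotone, so rank
statistics are both robust and invariant under monotone transforms (a
property the tests assert). Expression per gene is the mean over
replicates. Paralog fold changes are pseudocount-stabilised,
\(\log_2((x_a + 0.01)/(x_b + 0.01))\), keeping log-ratios finite at zero
levels; the antisymmetry under pair swap is exact. The compartment
analysis contrasts genes methylated only in exons (set E) against genes
methylated only in introns (set I), correlating each set's compartment
level with expression; sets below 10 usable genes are reported
not-evaluable rather than erroring. `flagSilencingCases()` reports, for
an externally supplied DEG list, exon levels in both samples and
overlap of the gene's downstream 2 kb window with significant DMRs,
flagging genes whose lower-expressed sample carries the higher exon or
downstream methylation.

# The synthetic-data generator

`simulateDataset()` emulates the *measured structure* of a two-cultivar
plant methylome, not its mechanism. Defaults are the study conditions
used throughout the tests and the acceptance script:

| parameter | default | meaning |
|---|---|---|
| `nChroms` × `chromLength` | 2 × 500 kb | nuclear genome |
| `chloroplastLength` | 100 kb | unmethylated control (~10^6 reads at depth 30) |
| `gcFraction` | 0.35 | i.i.d. base composition (plant-like) |
| `piCG, piCHG, piCHH` | 0.589, 0.515, 0.179 | genome-wide methylated-site probabilities per context |
| `betaShape1, betaShape2` | 8, 2 | true level at methylated sites ~ Beta(8, 2) |
| `pErr` | 0.001114 | non-conversion rate (level at unmethylated sites) |
| `meanDepth` | 30 | site-independent Poisson depth |
| `nGenes`, length range | 250, 1–3 kb | non-overlapping genes, 1–3 exons, terminal 100 bp UTRs |
| `nTEs` | 40 | transposable elements, hypermethylated in all contexts |
| `nPlantedDMRs`, `dmrWidth`, `dmrDelta` | 50, 200 bp, 0.8 | planted inter-cultivar level shifts (random sign, clamped to [0, 1]) |
| `nSNPs` | 2000 | uniform positions (2 bp clear of chromosome ends), alt uniform over the other three bases |
| `exprBeta`, `exprSigma`, `exprIntercept` | 3, 0.5, 5 | log-scale expression coupling to the true exon CG level |
| `fracExonOnly`, `fracIntronOnly` | 0.12, 0.12 | compartment-restricted methylation patterns (multi-exon genes only) |
| `nSilenced` | 4 | genes exon-hypermethylated and silenced in sample B |

Design choices that deserve justification:

* **Per-gene methylation classes.** Independent per-site Bernoulli
  states cannot produce the bimodal gene-body weighted-level landscape
  seen in real plant methylomes — averaging over hundreds of sites
  concentrates every gene near the genome-wide mean. Genes are therefore
  assigned high/low classes for CG and CHG (site rates 0.95 and 0.15,
  giving gene-body levels near 0.76 and 0.12, i.e. the familiar ~80%
  and ~10% peaks). Class counts are fixed exactly at the proportion that
  preserves the genome-wide π, removing class-count sampling noise from
  the recovery checks. CHH stays i.i.d. — its observed gene-level
  spectrum is narrow.
* **Exact rate calibration.** Gene classes, compartment-restricted
  genes and hypermethylated TEs all perturb the genome-wide methylated
  fraction, so after all per-site rates are assigned the background
  (non-gene, non-TE) rate of each context is shifted so the *expected*
  genome-wide fraction equals π exactly. Recovery of π to ±0.02 then
  tests the calling machinery, not the generator's bookkeeping.
* **Sample B is sample A's truth plus planted differences.** Outside
  planted DMRs, SNP-changed contexts and silenced-gene exons, the two
  samples share identical true levels (counts are drawn independently),
  so windows away from planted effects form a genuine null for the DMR
  false-positive check. Sample B's site set is enumerated from the
  SNP-substituted genome — the coordinate system is shared, lost sites
  simply vanish from its report (and are tallied "uncovered"
  downstream), and context-changed sites get fresh states from the new
  context's π.
* **Counts, not reads.** Depth is site-independent Poisson; no
  read-level simulation, no fragment or mapping model. The pipeline
  consumes per-site counts, and read alignment is outside its scope.
* **One RNG stream.** `simulateDataset()` seeds once from
  `params@seed`; identical parameters give byte-identical files
  (hash-checked in the tests).

What the generator does *not* emulate — and hence what passing tests do
not show about real data: linkage of methylation states along the
genome beyond gene-scale classes (no heterochromatin blocks, no
pericentromeric gradient), depth heterogeneity and mapping bias,
beta-binomial overdispersion of counts, strand-asymmetric CG
methylation, TE sequence structure, or any mechanistic pathway model.
Recovery results certify the estimators under the stated generative
model only.

# Numerical choices and degenerate inputs

* `binomialP()` is exact via the binomial CDF; the suite verifies it
  against brute-force mass summation to 1e-12 relative tolerance for
  all `n ≤ 50`.
* `fisherTwoSided()` sums hypergeometric probabilities `≤ p_obs` with
  the conventional `1 + 1e-7` relative tie band (two float routes to a
  genuinely tied probability can differ at 1e-15; a tighter band would
  make tie membership depend on rounding). Zero-margin tables return 1;
  the all-zero table is an error.
* Weighted levels with zero denominators are `NA`, excluded from means,
  never coerced to 0.
* Chromosomes shorter than the DMR window yield zero windows, with a
  message.
* The metagene bin layout uses integer bin widths with the remainder in
  the final bin of each zone, so bins never overlap and always tile the
  feature exactly.
* Q-values are monotone non-decreasing in p (BH property, asserted);
  the Storey variant scales BH by the π₀ estimate and is never larger.

# Problem sizes

The test suite and the acceptance script run the full pipeline on the
default 2 × 500 kb dataset (~350,000 cytosine sites per sample,
~20,000 DMR windows), plus a 100 kb fully unmethylated genome for the
FDR null, ~100 small random genomes for the context oracles, and the
exhaustive Fisher grid at margins ≤ 30. These sizes were chosen so the
statistical checks (3 SE bands, ±0.02 recovery, ≥ 10^4 null windows)
have the power their tolerances assume while the whole suite stays
comfortably fast on one CPU.

# Known limitations

* The per-site survey uses raw p-values at 0.01 by design fidelity;
  an FDR-adjusted mode is a one-line change but is off by default.
* Adjacent significant windows are not merged into maximal DMR
  intervals; the window is the reporting unit.
* Symmetric CG pairs are kept as separate strand-wise sites throughout,
  matching the CX-report grain, and are never merged.
* DEG calling, read alignment, paralog identification and miRNA/hairpin
  analyses are out of scope; their outputs are inputs here.
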