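---
title: "seqscout: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{seqscout: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

seqscout is a headless compute layer for exploratory bulk RNA-Seq work: it
takes a manifest of BAM/BigWig-backed samples grouped by biological
condition and provides condition-averaged coverage profiles, on-the-fly
abundance estimation over annotated genes and arbitrary (possibly
non-annotated) regions such as novel lincRNAs, a lightweight two-test
differential expression pipeline with p-value combination, and the usual
expression analytics (correlation, clustering, PCA, MDS). This vignette
records the statistical models, the numerical conventions, and the design
decisions that were genuinely open, so that users know exactly what the
numbers mean — and what passing the package's own tests does and does not
demonstrate about real data.

## Coordinates and regions

Internally every region is a `GRanges`: 1-based, closed intervals, the
convention shared by the whole Bioconductor interval stack and by GTF and
browser-style query strings (`"chr1:100-200"` spans 101 bases). BED input
(0-based, half-open) is converted at the parsing boundary by the standard
importer. We deliberately did not introduce a second internal convention:
every interval operation (union, overlap, flank, clamp) is delegated to
`GenomicRanges`, and a single convention end to end removes the most common
class of off-by-one errors. Exported bedGraph is 0-based half-open again, as
that format requires.

A gene model is the pool of all its transcripts' exons; gene-level
quantification uses the *exon union* (merged, disjoint exonic intervals),
whose total width is the gene length used by RPKM. Transcript-isoform
quantification is out of scope.

Strand-aware arithmetic: with `anchor = "body"`, `flank_region()` extends a
region `upstream` bp past its 5' end and `downstream` bp past its 3' end
(mirrored on the minus strand); with `anchor = "tss"` it builds a window of
length `upstream + downstream` around the strand-aware transcription start.
Windows are clamped at contig edges with a warning. A property test checks
that flanking commutes with reflecting the genome, so plus- and
minus-strand genes are treated exactly symmetrically.

## Coverage and condition profiles

Coverage from BAM is the per-base depth of primary, QC-pass, non-duplicate
alignments. Depth placement is CIGAR-aware: aligned (`M/=/X`) and deleted
(`D`) reference bases count as covered; skipped introns (`N`), insertions
and clips do not. This is the correct treatment for spliced RNA-Seq
alignments — a read spanning an intron illuminates its two exonic chunks,
not the intron.

Coverage from BigWig is read as stored. The package treats tracks as
already depth-normalized to a per-million scale, which is how the bundled
generator writes them; BAM-derived profiles are scaled to per-million using
the sample's library size (primary, mapped, QC-pass, non-duplicate records,
computed once and cached in the validation report) *before* cross-sample
averaging, so conditions sequenced at different depths are comparable.

Profiles are binned into `n_bins` contiguous near-equal spans (division
remainder widening the leftmost bins by one base), each bin taking the mean
of its member bases; this conserves the region mean exactly whenever
`n_bins` divides the width. Minus-strand profiles are reversed so bin 1 is
always the 5' end. The default of 200 bins is a plotting resolution, not a
statistical choice, and no smoothing is ever applied. The condition band is
the per-bin across-sample SD by default (SE optional); it is a descriptive
dispersion band, not a confidence interval, and is all-zero for
single-sample conditions.

## Counting and abundance scales

A read counts for a feature iff its aligned bases overlap the feature's
intervals by at least `min_overlap_bp` (default 1) in total, after MAPQ
(default ≥ 10), duplicate (excluded by default) and strand (unstranded by
default) filters. A read is counted at most once per feature regardless of
how many of the feature's intervals it touches, and a read overlapping
several genes counts for each — no "ambiguous" discard and no fractional
assignment. These defaults are the simplest defensible contract; all are
explicit `counting_params()` fields.

Size factors are classical median-of-ratios: per sample, the median over
features of the ratio of that sample's count to the feature's geometric
mean across samples, with zero-geometric-mean features excluded. When
custom regions are quantified alongside the annotation, the factors are
computed from the gene-level matrix only: a handful of user regions cannot
support a median-of-ratios estimate, so they are normalized with the
gene-derived factors without influencing them.

Supported scales are `raw`, `normalized` (count / size factor), `rpkm`
(count / (kb of feature × millions of library reads)) and `log2` versions
of each with pseudocount 1. QC flags (`LOW_COUNT` if the max count across
samples is below 10, `SHORT` below 200 bp, `ZERO_IN_ALL`) mark features but
never remove them — filtering is downstream and user-driven.

## Differential expression

The pipeline is intentionally lite and self-contained: raw gene counts →
median-of-ratios normalization → two per-gene tests → p-value combination
→ Benjamini–Hochberg. It is meant for interactive-scale exploration with
replicated designs, not as a replacement for shrinkage-based packages.

**NB Wald test.** Under a negative-binomial model with common dispersion
$\phi$ (variance $\mu + \phi\mu^2$; $\phi = 0$ recovers Poisson), the test
statistic is the log ratio of group means over its delta-method standard
error,

$$z = \frac{\log \bar b - \log \bar a}
  {\sqrt{\frac{\bar a + \phi \bar a^2}{n_a \bar a^2} +
         \frac{\bar b + \phi \bar b^2}{n_b \bar b^2}}},$$

referred to a standard normal, two-sided. Genes with zero counts in both
groups get $p = 1$; a zero mean on one side is continuity-corrected to half
a count. A parametric-bootstrap oracle (100 000 NB redraws under the fitted
null) agrees with the analytic p-values to within a few Monte-Carlo
standard errors at the package's default study size. A $t$ reference with
$n_a + n_b - 2$ degrees of freedom was evaluated and rejected: it is far
too conservative for this statistic (empirical null rejection at the 5%
level collapses to about 1%), because the Wald standard error comes from
the mean–variance model rather than a per-gene sample variance.

**Common dispersion.** Per gene, condition means and variances are pooled
(variances by their degrees of freedom) and $\phi_g = \max(0,
(\hat\sigma^2 - \hat\mu)/\hat\mu^2)$. The common $\phi$ is the **mean** of
the per-gene estimates over expressed genes. The more obvious median was
evaluated and rejected: per-gene moment estimates at 2–3 replicates are
noisy, floored at zero and right-skewed, so their median sits well below
the true common dispersion (about 0.08 for a true 0.1 in the package's
reference simulation), and an under-estimated dispersion makes every
downstream Wald test anti-conservative. The mean is close to unbiased
there (about 0.099) and brings the test's null rejection rate near its
nominal level.

**Welch test.** A two-sided unequal-variance $t$ test on
$\log_2(\text{normalized count} + 1)$, with Welch–Satterthwaite degrees of
freedom. At 3 replicates per group it is mildly conservative (null 5%
rejection around 3–4%), which is the familiar price of a per-gene sample
variance with 2 degrees of freedom.

**Combination.** Per gene, the per-test p-values are joined by one of:
Fisher ($-2\sum\log p_i$ against $\chi^2_{2k}$), Simes
($\min_i k\,p_{(i)}/i$), min, max, or a user-weighted convex combination
$\sum w_i p_i$ (weights are user-supplied; no simulation-trained weighting
scheme ships with the package). **The default is Simes**, and the reason
is worth stating: the two built-in tests are computed on the *same* counts
and are strongly positively dependent, and Fisher's chi-square reference
assumes independence, so Fisher is anti-conservative here — in the
package's reference recovery simulation it inflates the realized false
discovery proportion at BH $q \le 0.05$ to 0.13–0.20, while Simes (a valid
p-value under positive dependence) keeps it below 0.10 with essentially
the same sensitivity. Fisher remains available and appropriate when the
combined p-values come from independent analyses. Selecting a single test
bypasses combination entirely.

Fold changes are $\log_2((\bar b + 1)/(\bar a + 1))$ on normalized counts
(pseudocount 1 throughout), and the MA-plot A coordinate is the log2 grand
mean. BH is used for FDR; `filter_results()` marks rows against q-value,
fold-change, expression and flag criteria without deleting them.
Multi-condition designs are handled as explicit pairwise contrasts.

## Analytics

Correlation (`pearson`, `spearman`, `kendall` tau-b) can be gene-wise
(across samples) or sample-wise (across genes); constant vectors have no
defined correlation and are reported as `NA` with a warning rather than
silently dropped. Hierarchical clustering exposes euclidean, Manhattan and
1 − Pearson distances with single/complete/average/Ward linkage; Ward uses
the squared-increment (ward.D2) criterion and is rejected on non-euclidean
distances, where it has no interpretation. Dendrograms export as Newick.

PCA treats samples as observations (the sample-QC orientation; transpose
the matrix for a gene-axis view), centering by default and dropping
zero-variance features only when unit scaling is requested. Explained
fractions cover all components and sum to one. Classical MDS is
double-centering plus eigendecomposition; on euclidean distances of
centered data it reproduces PCA scores up to sign, which the test suite
verifies via a Procrustes residual below 1e-6. The default expression
scale fed into analytics is log2 normalized counts with pseudocount 1.

## The synthetic-data generator

`make_toy_dataset()` writes a complete miniature dataset — contig sizes, a
GTF of non-overlapping multi-exon gene models on both strands of two 100 kb
contigs, one coordinate-sorted indexed BAM and one per-million-scaled
BigWig per sample, a YAML manifest and truth tables — as a pure function of
a seeded `sim_config()`. Defaults describe the package's reference study:
two conditions × three replicates, 40 genes for the on-disk dataset (2000
genes for the count-only simulations, where no files are needed), NB
baseline mean 100 with dispersion 0.1, 10% of genes differentially
expressed at |log2FC| = 2 with random sign, 50 bp reads, and 60 intronic /
intergenic noise reads per sample so that exon-union counting is genuinely
exercised.

Reads are single-end, fully exonic and unspliced, placed uniformly over
each gene's exons (exon chosen proportionally to its number of valid start
positions). Genes never overlap, so the per-gene truth counts are exact by
construction, and the package's master integration test — counting the
emitted BAMs recovers the simulated count matrix identically — closes the
loop from simulation through SAM/BAM round-trip to the counting code.
CIGAR-aware depth (`N`, `D`, `I`, `S` operations) is exercised separately
by a hand-built spliced fixture, and paired-end fragment counting by the
counting contract's unit tests.

What the generator does *not* emulate — and hence what green tests do not
demonstrate about real data: sequence content and base qualities
(placeholder bases), alignment ambiguity and multi-mapping, positional and
GC bias, fragment-length distributions, overlapping or nested gene models,
isoform structure, and between-gene dispersion variation (a single common
$\phi$). Calibration results on the generator transfer to real data only to
the extent that the NB-with-common-dispersion model does.

BigWig stores values as 32-bit floats, so per-million tracks agree with
independently computed scaled BAM depth to float32 *relative* precision
(about 6e-8), not to any fixed absolute tolerance; the consistency checks
compare relatively for that reason.

## Problem sizes used by the test suite

The bundled checks run the on-disk pipeline on the 40-gene / 6-sample toy
dataset, the counting oracle on 100 random regions against a naive overlap
scan of the generator's read table, and the calibration, recovery and
dispersion simulations on 2000-gene, 3-vs-3 count matrices — sizes chosen
so the whole suite exercises every path in a couple of minutes while
keeping Monte-Carlo noise on empirical rates near ±0.005.

## Known limitations

* Whole-BAM scans are used for counting; for the intended interactive and
  toy scales this is simple and exact, but a production service over very
  large BAMs would want windowed iteration with read deduplication.
* One annotation store per dataset; no multi-source (Ensembl + RefSeq +
  UCSC) reconciliation and no liftover.
* The NB test's common dispersion ignores mean–dispersion trends; strongly
  heteroskedastic datasets are better served by shrinkage-based tools.
* `weighted` combination is a plain convex combination of p-values — a
  documented stand-in for trained weighting schemes, not an emulation of
  one.
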