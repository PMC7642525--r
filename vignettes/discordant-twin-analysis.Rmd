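---
title: "Post-twinning de novo variant analysis in discordant monozygotic quartets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Post-twinning de novo variant analysis in discordant monozygotic quartets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinseg)
```

## The study design

Monozygotic (MZ) twins discordant for a congenital phenotype are close to a
perfect natural experiment. The twins share their germline and most of their
environment, so a genotype present in the affected twin but absent from the
unaffected co-twin must have arisen *after* the twinning split — a
post-zygotic (post-twinning) mutation — and is a direct candidate for the
discordance. The analysis unit is therefore the **quartet**: affected twin
(proband), co-twin, and both parents. Parents serve two purposes: they
distinguish inherited variants from de novo ones, and their sequencing data
(together with the co-twin's) provides a within-family normal reference for
copy-number inference.

twinseg implements this design end to end:

1. **Monozygosity QC** (`twin_concordance()`): genotype-category concordance
   between the twins. MZ co-twins are expected to agree at roughly 99.9% of
   SNV sites; lower values indicate dizygosity or sample problems.
2. **Segregation screen** (`segregate_de_novo()`): sites where the proband
   carries the alternate allele with adequate read support while co-twin and
   both parents are confidently homozygous reference.
3. **Annotation filters** (`apply_annotation_filters()`): the three
   criteria — protein-altering classes only; exclusion of variants common
   (>10%) in any of five population frequency databases (1000 Genomes,
   HapMap CHB, ESP, dbSNP, ExAC); exclusion of synonymous and intronic
   classes.
4. **Cross-family recurrence** (`recurrent_variants()`,
   `recurrent_genes()`, `recurrent_cnv_genes()`): events shared by at least
   two unrelated families are the ones most likely to be causal rather than
   private noise.
5. **CNV calling** (`build_family_reference()`, `log2_ratios()`,
   `segment_and_call()`): read-depth log2 copy ratios of the proband against
   the within-family reference, segmented by thresholding.
6. **Pathway enrichment** (`hypergeom_tail()`, `enrich_families()`): the
   upper-tail hypergeometric probability of seeing the observed number of
   candidate genes in a pathway, with Benjamini–Hochberg q-values.

## Post-twinning versus pre-twinning de novo events

A variant can be "de novo" in two distinct ways in this design. A variant in
**both** twins but neither parent arose before the twinning split; it is a
genuine germline de novo mutation but *cannot* explain the discordance,
since both twins carry it. Only variants in the proband alone are
post-twinning candidates. `segregate_de_novo()` therefore returns the two
sets separately (`$post_twinning`, `$pre_twinning`) and the pipeline carries
only the former forward. This is the only reading consistent with the
discordant-twin logic.

Sites where the co-twin or a parent has a *missing* genotype are excluded
conservatively: absence of evidence of the reference genotype is not
evidence of absence of the allele.

## Filter semantics and defaults

* `maf_threshold = 0.10`: a variant is excluded when **any present**
  database frequency is **strictly greater** than the threshold. A missing
  frequency means the database never observed the variant and never
  triggers exclusion — treating missing as zero would be wrong in the other
  direction, silently passing variants through databases that do not cover
  their region is the accepted cost.
* `protein_altering_classes = {frameshift, nonframeshift-indel, missense,
  stopgain, splice-boundary}`. "Indels" are read as both frameshift and
  in-frame coding indels; intron–exon boundary (splice) variants are their
  own class. `excluded_classes = {synonymous, intronic}`.
* `min_proband_alt_depth = 4`, `min_proband_depth = 8`,
  `max_carrier_alt_fraction = 0.05`: read-evidence guards. The carrier
  fraction rule rejects a candidate when a supposedly homozygous-reference
  family member shows more than 5% alt reads — the typical signature of an
  undercalled allele rather than a true de novo event. These three are
  analysis conventions (no published consensus values exist), and all are
  exposed in `filter_config()`.

Variant identity everywhere is the normalized key `(chrom, pos, ref, alt)`:
chromosome names lose their `chr` prefix, multi-allelic records are split,
and indel alleles are shifted left while their leading bases agree (then
redundant shared suffixes are trimmed). Recurrence matching across families
must not be defeated by representation differences; HGVS strings are kept
for reporting only.

## CNV calling

The caller deliberately implements a transparent, testable core of the
family-reference idea rather than a full production CNV pipeline: each
subject's per-target depth vector is rescaled so its median target depth is
100 (making ratios invariant to total sequencing yield), the per-target
median across the healthy members forms the reference, and the proband
track is `log2((test + c) / (ref + c))` with pseudocount `c = 1`.
Segmentation is threshold-plus-merge: runs of consecutive targets above
`+0.3` (gain) or below `-0.3` (loss) spanning at least `min_targets = 3`
targets are reported. A heterozygous loss sits near `-1`, a single-copy
gain near `log2(1.5) = 0.585` (the pseudocount pulls both slightly toward
0). Circular binary segmentation, GC/mappability correction and
confidence-interval filtering are out of scope; sex chromosomes are
processed but flagged, since no ploidy correction is applied.

## The enrichment statistic

For a pathway holding $M$ of the $N$ universe genes, with $m$ of the $n$
candidate genes inside it,

$$P \;=\; 1 - \sum_{i=0}^{m-1}
  \frac{\binom{M}{i}\binom{N-M}{n-i}}{\binom{N}{n}},$$

the probability of at least $m$ hits under uniform drawing. Numerically the
complement form is a trap: when $P \approx 10^{-12}$, `1 - sum` destroys
every significant digit. `hypergeom_tail()` therefore sums the upper tail
directly in log-space (`exp(lchoose(...) + lchoose(...) - lchoose(...))`),
which the test suite verifies against brute-force summation and frozen
exact-rational references across the full grid $M \le N \le 60$ at
relative error below $10^{-12}$.

Decisions where the procedure was genuinely open:

* $N$ is the union of all pathway genes; candidate genes outside every
  pathway are excluded from $n$ (and counted). Including them would dilute
  $n$ with genes that can never contribute to $m$.
* The recurrence criterion is applied **first** (a pathway must contain at
  least one candidate in each of $\ge 2$ families), and BH correction runs
  over the tested pathways only, matching the two-step order of the
  procedure as described. Testing is done on the pooled (union) candidate
  set; per-family $P$ values are attached as an attribute for transparency.
* The q-value estimator is Benjamini–Hochberg (`p.adjust(..., "BH")`) and
  is labelled as such; significance requires both $P < 0.05$ and $q < 0.2$.

## The synthetic cohort generator

Real discordant-twin sequencing data is protected, so `generate_cohort()`
produces cohorts with planted ground truth. Its defaults *are* the study
conditions the package addresses: **6 quartet families**, co-twin
concordance 99.9% (`twin_discordance_rate = 0.001`), mean target depth
**387.6×** with negative-binomial dispersion 0.1 (variance
$\mu + 0.1\mu^2$; the study reports only a mean, 0.1 is a typical
exome-capture overdispersion). The number of planted post-twinning events
per proband is a free parameter (default 3: one rare missense, one unseen
stopgain, one unseen frameshift) — the true pre-filter count per twin pair
is not established; post-zygotic rates of order $10^{-7}$ per base pair
imply only a handful of coding events.

The germline model is deliberately simple: each parent is independently
heterozygous at a background site with probability `germline_het_rate`
(default 0.3, the scale of heterozygous fractions among a subject's exome
variant sites), hom-alt at a quarter of that, and twins share one Mendelian
draw. Discordance noise perturbs one twin's genotype category at random —
this is somatic mosaicism, so such sites legitimately violate Mendelian
consistency; the Mendelian property is asserted in noise-free mode. With
`depth_dispersion = 0` the generator is fully noise-free (deterministic
depths, exact half-allele fractions), which is what makes
precision = recall = 1 a meaningful expectation for the planted events.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: linkage disequilibrium and population structure,
alignment and calling artifacts (the genotypes are written, not called),
allele dropout, GC-dependent depth bias, multi-allelic sites (downstream
code still parses them by splitting), and realistic gene lengths. The
generator validates performance of the *logic*, not robustness to a real
caller's error modes.

## Problem sizes and numerical conventions

The test suite and acceptance script run, by choice, at desk scale: cohorts
of 600–1,500 background sites for pipeline recovery, 100,000 sites for the
concordance calibration (binomial 99% interval around 0.999), 200 capture
targets with 8-target CNVs, and the exhaustive $M \le N \le 60$
hypergeometric grid (~1.15 million tail values). Published six-family
recurrence tables are bundled as fixtures with synthetic coordinates
(`inst/extdata/*_synthetic_coords.tsv`) because the source prints HGVS
labels, not genomic positions.

Ties and degenerate inputs: zero comparable twin sites yield an undefined
(`NA`) concordance rather than an error; zero-median reference targets are
masked before ratio computation; an empty VCF produces empty tables, not a
failure; `hypergeom_tail(m = 0)` is exactly 1 by the empty-sum convention.
Every random step in the generator is governed by a single scenario seed,
and generation restores the caller's RNG state.

## Known limitations

* The segregation screen treats genotypes as given; it cannot rescue a
  proband variant the upstream caller missed, and read-level re-checking
  of the co-twin (beyond the alt-fraction rule) is not implemented.
* No mosaic-fraction modeling: a post-twinning variant present in only a
  fraction of the proband's cells shows a depressed allele fraction that
  the fixed evidence thresholds may reject.
* Recurrence carries no population background model; with many families
  and a large gene, recurrence by chance is not assessed statistically.
* The CNV caller's threshold segmentation has no smoothing step, so it
  fragments noisy ratio tracks: with the generator's default per-target
  negative-binomial dispersion of 0.1, per-target ratio noise regularly
  crosses the ±0.3 thresholds and produces spurious short segments. The
  exact-recovery guarantees are for the noise-free mode
  (`depth_dispersion = 0`); on noisy data the caller should be read as a
  transparent reference implementation of the family-reference log2-ratio
  idea, not a production segmenter.
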