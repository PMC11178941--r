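---
title: "Methods: linking H3K27ac atlases to variants and GWAS loci"
author: "epivar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking H3K27ac atlases to variants and GWAS loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epivar)
```

## The analysis in one paragraph

Histone H3 lysine-27 acetylation (H3K27ac) marks active enhancers and
promoters. When the same tissue is profiled in two conditions (e.g.,
group- versus single-housed animals) and in two inbred strains, each
merged H3K27ac interval can be classified along two axes: its response
to the environment (increased / decreased / unchanged) and its
strain-selectivity (shared / present only in strain A / only in
strain B). Because inbred strains are homozygous, strain-selective
presence or absence of the mark is a candidate readout of local
regulatory sequence variants, while environment-induced changes should
be largely sequence-independent. `epivar` quantifies both axes against
a variant set: per-kilobase SNV/indel densities inside regions, inside
per-gene regulatory domains, and inside chromatin-state segments;
motif-level scoring of variants that could disrupt transcription-factor
binding; linkage of region classes to expression fold changes; and a
binomial test of whether region midpoints concentrate in the regulatory
territory of human GWAS disease genes mapped through one-to-one
orthologs.

## Coordinate conventions

All intervals inside the package are 0-based, half-open `[start, end)`
on named chromosomes, i.e., BED arithmetic. VCF `POS` (1-based, first
REF base) and GTF (1-based, end-inclusive) are converted at the I/O
boundary and nowhere else. The midpoint of `[start, end)` is
`floor((start + end) / 2)`; even-length intervals therefore take the
lower-middle base, which keeps every midpoint an integer and makes
assignment deterministic.

## Consensus genome and coordinate lifting

`build_consensus()` applies a validated, coordinate-sorted,
non-overlapping variant set to the reference with
`Biostrings::replaceAt`. Substitutions (len(REF) = len(ALT)) never
shift coordinates; each indel ends an aligned block after the
anchor-shared prefix of min(len(REF), len(ALT)) bases. The length
identity `len(consensus) = len(reference) + sum(len(ALT) - len(REF))`
holds exactly and is asserted property-style in the tests. The block
list is an offset map that serializes to a UCSC chain file
(`write_chain()` / `read_chain()` round-trip exactly; the written
chains also drive `rtracklayer::liftOver` to the same coordinates in a
cross-check test).

Lifting an interval projects each endpoint through the blocks. An
endpoint that falls in a deleted segment *snaps inward* to the nearest
projectable base and the result is flagged `partial`; intervals with no
projectable base are `unmapped`. Published pipelines that use default
liftOver drop such regions (their region counts shrink slightly after
conversion), so `strict = TRUE` reproduces that behaviour by turning
partial lifts into unmapped ones. We keep snapping as the default
because it preserves the region inventory and makes losses explicit —
both policies are available since the reference analysis does not state
how edge-overlapping regions were handled. Multi-allelic VCF rows are
split on ingest; overlapping variants are rejected rather than phased.

## LCREDs: single-nearest-gene regulatory domains

Each gene gets one long-range cis-regulatory element domain (LCRED)
anchored at its TSS. Between adjacent TSSs *a* and *b* the boundary is
`floor((a + b) / 2)`; each side extends at most `cap_bp` (default
1,000,000 bp, the GREAT convention) from its TSS, and chromosome ends
clip the terminal domains. Domains are pairwise disjoint by
construction; when two genes share an identical TSS position the
lexicographically smallest `gene_id` is kept and the drop reported,
since the "non-redundant gene" filter of the reference analysis is not
fully specified. Strand never affects geometry — the rule is symmetric.
A midpoint landing exactly on a shared boundary belongs to the
downstream (higher-coordinate) domain, a direct consequence of
half-open intervals. Assignment uses the region midpoint (not
whole-interval containment), matching the convention stated for the
GWAS analysis; on the full-scale annotation of the original study this
rule leaves a small number of regions unassigned, which the package
reports rather than hides.

## Region atlas

`merge_region_sets()` reduces the union of all input sets, merging
book-ended intervals (`min_gap = 0`; the peak caller's own gap policy
is upstream and out of scope). Presence of a merged interval in an
input set is at least `min_overlap = 1` bp of overlap — the reference
analysis states no threshold, so this is an explicit knob. A strain is
"present" when any of its source sets overlaps the interval; presence
in exactly one strain yields a selective label, and
`shared + A_only + B_only = total` is asserted on every simulated
atlas. The published per-strain and union totals satisfy the same
identity by inclusion-exclusion, which the acceptance checks verify as
an arithmetic consistency statement about the counting convention.
Differential labels transfer from labeled regions to the merged
interval containing them; an interval receiving more than one class is
flagged `mixed` and excluded from exclusive-class analyses (rather than
resolved by majority), mirroring the exclusion logic of the reference
study's gene-level comparisons.

## Variant densities

A variant counts toward an interval iff the 0-based position of its
first REF base lies in `[start, end)`; an indel straddling the edge
counts only where its anchor base lies. This matches a standard
BED-intersection of VCF positions. Densities are `count / length *
1000` exactly, with no length adjustment. Multi-allelic records, after
splitting, contribute one count per row. LCRED-level contrasts
("domains containing at least one region of class X versus others")
define "others" as the complement within the full LCRED set, not within
assigned-only genes.

## Binomial GWAS enrichment

Disease gene sets are parsed from an association catalog
(`MAPPED_GENE`-style cells split on commas and `" - "` spans, keeping
both flanking genes), mapped through a one-to-one ortholog table, and
intersected with the LCRED genes; diseases with fewer than `min_genes`
(default 5) surviving genes are dropped. The universe is *all*
ortholog-mapped genes with an LCRED, and its summed domain length plays
the role of the genome size. With `n` region midpoints inside the
universe — midpoints outside any eligible domain are discarded before
`n` is counted, the reading most consistent with letting the eligible
domains be the genome — and a disease territory covering fraction `p`
of the universe, the p-value is the exact upper tail
`P(X >= k), X ~ Binomial(n, p)` via `stats::pbinom`. The test is
one-sided (enrichment only); overlapping disease territories are
allowed and tested marginally; BH correction runs across exactly the
tested disease list. No hypergeometric gene-based filter is applied —
both term-driven and gene-specific enrichment are of interest — but a
per-disease count of distinct contributing genes is emitted so users
can flag single-gene-driven hits. `profile_correlation()` compares two
enrichment profiles by Spearman correlation of `-log10 p` over shared
diseases.

## Motif scanning and allelic affinity

PWMs are position probability matrices (rows sum to 1); a pseudocount
(default 1e-3) is added before renormalising and taking log2 odds
against a uniform background. Both strands are scanned and a window is
a hit when its score reaches `threshold` (default 0.8) of the maximum
achievable score. The published analysis used per-motif log-odds
cutoffs that are not printed, so this fraction-of-maximum default is a
stand-in and its absolute hit counts are not comparable to the
published tables; the overlap workflow and its nested denominators
(variant-overlap fractions are computed over motif-containing regions
only) are what the package reproduces. For an SNV inside a hit,
`delta_affinity()` reports the log-odds difference ALT minus REF at the
variant's offset, complementing alleles and mirroring the offset for
reverse-strand hits; negative delta classifies the substitution as
disruptive. This delta-log-odds score deliberately replaces
biophysical free-energy model scoring, whose model fitting from
HT-SELEX data is outside this package's scope; the published
">75% disruptive" figures are therefore not targets. Overlapping hits
of the same PWM are all kept.

## Expression linkage

Size factors are median-of-ratios: the reference is the per-gene
geometric mean over samples (genes positive in all samples), and each
sample's factor is the median ratio to that reference; the
implementation agrees with `DESeq2::estimateSizeFactorsForMatrix` to
near machine precision in a cross-check test. Note the resulting
factors are invariant to scaling *all* counts by a constant — the
ratios cancel — so the meaningful invariance, asserted in tests, is
that per-gene log2 fold changes are unchanged when one sample is
rescaled. Genes with zero normalized control counts are flagged
incalculable and excluded from fold-change analyses, exactly as genes
without control reads were excluded in the reference analysis.
`class_expression_test()` runs a Kruskal-Wallis omnibus followed by
Dunn's pairwise comparisons over the exclusive-class gene groups.

## Statistical conventions

* Welch t from summaries: used to recompute printed mean +/- SD bounds;
  it is a conservative surrogate for the original two-way ANOVA
  contrasts and documented as such. Both SDs zero with equal means
  gives p = 1 by convention.
* Mann-Whitney: midranks; exact enumeration when min(n) <= 8 and the
  enumeration is feasible, otherwise a tie-corrected normal
  approximation without continuity correction.
* Kruskal-Wallis: `stats::kruskal.test` (tie-corrected H, chi-square
  reference). Dunn z uses pooled midranks with the standard tie
  correction; pairwise p-values are unadjusted by default because the
  reference analysis does not state its adjustment — a `p_adjust =
  "BH"` flag is provided. Fully tied data yield H = 0, p = 1.
* Spearman: Pearson on midranks, t approximation with n - 2 df;
  constant input is an error.
* Linear trend: OLS on the level index with a two-sided slope t-test.
* BH FDR: `stats::p.adjust`. The two-stage step-up procedure used for
  one published figure is out of scope; plain BH only.

## The synthetic-data generator

The generator defines the study conditions the tests exercise. Defaults:
two 2-Mb chromosomes, 200 genes, six region classes (60/60/60 regions
for increased/decreased/unchanged, 40/40/60 for A-only/B-only/shared)
of 500-2,000 bp, and class-conditional SNV densities anchored at the
two published values — 0.14 SNV/kb for environment-induced decreases
and 0.28 SNV/kb for regions selectively absent in the variant-carrying
strain — with the remaining rates chosen once to reproduce the
published qualitative ordering (selective > shared, decreased >
increased); indel rates are 0.3x the SNV rates, a typical indel:SNV
proportion for inbred strain comparisons. Regions are placed mutually
disjoint, and variants are placed only after regions, so
class-conditional densities are exact by construction — the reference
analysis measures densities, it does not generate them. With
`tss_bias = TRUE`, increased regions are drawn near TSSs (exponential
anchor distance, mean 3 kb) and decreased regions distal (mean 200 kb),
mirroring the observed genomic distributions; these bias parameters are
free knobs, since the empirical distance distributions are published
only as binned bar charts. One TSS per gene; indels do not cross region
boundaries unless a stress-test flag is set; a single global seed
drives per-generator substreams, so any generator called twice with the
same config is byte-identical regardless of call order.

Counts are negative-binomial (dispersion 0.05, baseline mean 500) with
condition-2 means scaled by `2^fc` per class (defaults -1 / 0 / +0.5
for decreased / unchanged / increased). The mock GWAS catalog plants
`planted_enriched_diseases` diseases whose genes come preferentially
from a "hot" gene subset; for power checks, `sim_midpoints()` enriches
midpoint density inside a planted disease's territory by
`enrichment_multiplier` (default 3, at which the analytic binomial
power at n = 2,000 midpoints and the simulated territory sizes exceeds
99%).

What the generator does **not** emulate — realistic nucleotide
composition, repeat elements, linkage between variants, multi-sample
genotypes, peak-calling noise, and read-level effects — bounds what
passing tests show: they validate the analytical machinery and its
statistical calibration, not robustness to upstream artifacts in real
data.

## Problem sizes and runtime choices

The test suite and the acceptance script use: density recovery over
~10.2 Mb of territory per class (1,700 regions of 5-7 kb on a 48-Mb
genome), chosen as the smallest scale at which a 3-Poisson-SE band
around 0.14 and 0.28 SNV/kb is meaningfully tight; 200 null catalogs
plus 100 planted-disease runs at n = 2,000 midpoints over a 400-gene
universe for FDR and power; 100 count simulations at 200 genes per
class for expression-ordering recovery; and >= 1,000 randomized
instances on <= 10-kb toy chromosomes for the exact-oracle equivalences
(per-base projection arrays, all-window PWM enumeration, brute-force
assignment and counting). These sizes are the package's own choice of a
desk-scale study; the published dataset-scale numbers (tens of
thousands of regions against the full mouse genome and GWAS catalog)
require the original accessions and are documented, not recomputed.

## Known limitations

* Chain construction is purely indel-derived; alignment-based chains
  between independently assembled genomes, structural variants, and
  phasing are out of scope.
* The motif threshold is a fraction-of-maximum stand-in, so absolute
  motif counts are not comparable to analyses using per-motif
  calibrated cutoffs.
* Enrichment uses marginal binomial tests per disease; correlated
  territories (shared genes) are not modelled jointly, exactly as in
  the GREAT-style original.
* Expression linkage normalizes with median-of-ratios only; the
  probability-based differential-expression caller used upstream in the
  original study is not reimplemented, and class membership in tests
  comes from the H3K27ac labels, not from expression calls.
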