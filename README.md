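# epivar

`epivar` links changes in an H3K27ac region atlas — both
environment-induced (e.g., single-housing of a diabetes-prone inbred
mouse strain) and strain-selective (present in one strain, absent in the
other) — to genome sequence variants, gene expression, and human GWAS
disease/trait associations. It is aimed at regulatory-genomics analysts
who have differential H3K27ac region calls, a variant set (VCF), a gene
annotation, and a GWAS association table, and who want a tested,
reproducible implementation of the downstream comparative analysis.

## What it computes

* **Variant-aware genome projection.** A consensus genome is built by
  integrating SNVs and indels into the reference
  (`build_consensus()`); only indels shift coordinates, and the
  resulting aligned blocks are written as a UCSC chain file
  (`write_chain()`) so intervals can be lifted between the two
  coordinate systems (`lift_intervals()`), with partial lifts flagged
  rather than silently dropped.
* **Regulatory domains (LCREDs).** One non-overlapping long-range
  cis-regulatory element domain per gene, by the GREAT "single nearest
  gene" rule: the boundary between adjacent TSSs *a* and *b* is
  `floor((a + b) / 2)`, with at most 1 Mb of extension on each side
  (`build_lcreds()`). Regions are assigned to genes by their interval
  midpoint (`assign_regions()`).
* **Region atlas.** Region sets from multiple conditions and strains
  are merged into disjoint intervals with a membership matrix
  (`merge_region_sets()`); intervals overlapped by only one strain's
  sets are called strain-selective (`classify_strain_selective()`), and
  differential labels (increased / decreased / unchanged) are
  transferred with conflicts flagged `mixed`
  (`attach_differential_labels()`).
* **Variant densities.** SNVs and indels per kilobase for any interval
  set — regions, LCREDs, or chromatin-state segments — counting a
  variant where its first REF base lies (`variant_density()`,
  `density_by_state()`, `annotation_coverage()`).
* **GWAS enrichment.** A GREAT-style binomial test: disease gene sets
  from an association catalog are mapped through one-to-one orthologs
  onto LCREDs; with `n` region midpoints inside the LCRED universe and
  a disease territory covering fraction `p` of its base pairs, the
  enrichment p-value is the exact tail `P(X >= k)` for
  `X ~ Binomial(n, p)`, followed by Benjamini-Hochberg FDR
  (`build_locus_universe()`, `binomial_enrichment()`).
* **Motifs and variants.** PWM scanning on both strands at a
  fraction-of-maximum log-odds threshold (`scan_pwm()`), motif-variant
  overlap bookkeeping with the nested denominators used for published
  fractions (`motif_variant_overlap()`), and a strand-aware delta
  log-odds score for SNVs inside motif hits (`delta_affinity()`).
* **Expression linkage.** Median-of-ratios size factors, per-gene log2
  fold changes, and a Kruskal-Wallis + Dunn test of whether genes whose
  domains contain exclusively decreased / unchanged / increased regions
  differ in expression change (`size_factors()`, `fold_changes()`,
  `class_expression_test()`).
* **Synthetic data.** Every input above can be simulated with the
  statistical structure the analysis assumes (`sim_config()`,
  `sim_genome()`, `sim_region_sets()`, `sim_variants()`,
  `sim_gwas_catalog()`, `sim_counts()`), so the full pipeline is
  testable without downloads; `run_pipeline()` drives all stages end to
  end.

## Worked example

```r
library(epivar)

cfg <- sim_config(seed = 7)
res <- run_pipeline(cfg, out_dir = "epivar_demo")
#> simulated 320 regions, 74 variants, 610 catalog rows
#> consensus length delta 32 bp over 22 aligned blocks
#> assigned 320/320 regions to 158 genes
#> atlas: 140 merged intervals (60 shared, 40 A-only, 40 B-only)
#> enrichment: 0 disease(s) at q < 0.01 over 49 tested
#> expression omnibus p = 6.64e-08
```

The log lines mirror the bookkeeping a real run reports: the consensus
genome grew by the net indel length over 22 aligned blocks; all 320
simulated H3K27ac regions were assigned to a gene domain by midpoint;
the strain atlas partitions exactly (60 + 40 + 40 = 140); no GWAS
disease is called at q < 0.01 because this tiny default simulation
plants no midpoint enrichment; and the planted expression shift of the
decreased class is detected (omnibus p ~ 1e-7). Stage tables (region
densities, enrichment results, fold changes, chain file, VCF) are
written under `epivar_demo/`, stamped with the config hash in
`summary.json`.

As a statistics-only example, the printed 11-week body-weight summaries
of the two housing groups (32.4 +/- 1.3 g, n = 11, vs 35.8 +/- 2.6 g,
n = 11) give

```r
welch_from_summary(32.4, 1.3, 11, 35.8, 2.6, 11)$pvalue
#> [1] 0.00153344
```

comfortably below the published p < 0.005 bound.

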