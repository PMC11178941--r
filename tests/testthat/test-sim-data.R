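# Synthetic-data generators: determinism, statistical structure, and
# internal consistency of the simulated study.

test_that("generators are deterministic under a fixed config", {
  cfg <- small_config(seed = 42L)
  g1 <- sim_genome(cfg)
  g2 <- sim_genome(cfg)
  expect_identical(as.character(g1), as.character(g2))
  expect_identical(sim_annotation(cfg), sim_annotation(cfg))
  tss <- sim_annotation(cfg)
  r1 <- sim_region_sets(cfg, tss)
  expect_identical(r1, sim_region_sets(cfg, tss))
  v1 <- sim_variants(cfg, g1, r1)
  expect_identical(v1, sim_variants(cfg, g1, r1))
  gc1 <- sim_gwas_catalog(cfg, tss)
  expect_identical(gc1, sim_gwas_catalog(cfg, tss))
  classes <- data.frame(gene_id = tss$gene_id,
                        class = sample(c("increased", "decreased",
                                         "unchanged"), nrow(tss), TRUE))
  expect_identical(sim_counts(cfg, classes), sim_counts(cfg, classes))
  # file-level determinism
  f1 <- tempfile(); f2 <- tempfile()
  write_fasta(g1, f1); write_fasta(g2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("genome has forced lengths and near-uniform base composition", {
  cfg <- sim_config(seed = 1L, n_chroms = 1L, chrom_length = 1000L,
                    n_genes = 3L, region_length = c(50L, 100L))
  g <- sim_genome(cfg)
  expect_equal(length(g), 1L)
  expect_equal(Biostrings::width(g), 1000L)
  # 1 Mb chromosome: each base frequency within 3 binomial SE of 0.25
  big <- sim_config(seed = 2L, n_chroms = 1L, chrom_length = 1000000L,
                    n_genes = 10L)
  freq <- Biostrings::alphabetFrequency(sim_genome(big)[[1]])[c("A", "C",
                                                                "G", "T")]
  se <- sqrt(0.25 * 0.75 / 1e6)
  expect_true(all(abs(freq / 1e6 - 0.25) < 3 * se))
})

test_that("annotation gives distinct TSSs and survives a GTF round trip", {
  cfg <- small_config(seed = 3L)
  tss <- sim_annotation(cfg)
  expect_equal(nrow(tss), cfg$n_genes)
  expect_false(any(duplicated(tss[, c("chrom", "tss")])))
  expect_true(all(tss$tss >= 0 & tss$tss < cfg$chrom_length))
  gtf <- tempfile(fileext = ".gtf")
  write_gtf(tss, gtf, data.frame(chrom = paste0("chr", 1:2),
                                 length = cfg$chrom_length))
  back <- read_gtf_tss(gtf)
  back <- back[match(tss$gene_id, back$gene_id), ]
  expect_equal(back$tss, tss$tss)
  expect_equal(back$strand, tss$strand)
  expect_error(sim_annotation(sim_config(n_chroms = 1L, chrom_length = 10L,
                                         n_genes = 20L,
                                         region_length = c(2L, 5L))),
               "more genes")
})

test_that("TSS spacing matches the uniform order-statistics oracle", {
  cfg <- sim_config(seed = 11L, n_chroms = 1L, chrom_length = 10000000L,
                    n_genes = 1000L)
  tss <- sim_annotation(cfg)
  gaps <- diff(sort(tss$tss))
  # oracle: spacings of n uniform points are approximately Exp(n/L);
  # compare the empirical median to the median of a direct simulation
  sims <- replicate(200, {
    median(diff(sort(stats::runif(1000, 0, 1e7))))
  })
  expect_gt(median(gaps), quantile(sims, 0.001))
  expect_lt(median(gaps), quantile(sims, 0.999))
})

test_that("region sets are disjoint, in bounds, and TSS-biased by class", {
  cfg <- small_config(seed = 5L)
  tss <- sim_annotation(cfg)
  regions <- sim_region_sets(cfg, tss)
  expect_equal(as.integer(table(regions$class)[names(cfg$n_regions_per_class)]),
               unname(cfg$n_regions_per_class))
  expect_true(all(regions$start >= 0 & regions$end <= cfg$chrom_length))
  # disjoint within (and here, across) classes
  gr <- GenomicRanges::GRanges(regions$chrom,
                               IRanges::IRanges(regions$start + 1L,
                                                regions$end))
  expect_equal(sum(IRanges::width(GenomicRanges::reduce(gr))),
               sum(regions$end - regions$start))
  # near-TSS bias: recompute nearest-TSS distances from the output
  nearest <- function(cls) {
    r <- regions[regions$class == cls, ]
    mids <- interval_midpoint(r$start, r$end)
    vapply(seq_len(nrow(r)), function(i) {
      min(abs(mids[i] - tss$tss[tss$chrom == r$chrom[i]]))
    }, numeric(1))
  }
  expect_lt(median(nearest("increased")), median(nearest("decreased")))
})

test_that("single-region classes give six disjoint labeled intervals", {
  cfg <- sim_config(seed = 9L, n_chroms = 1L, chrom_length = 100000L,
                    n_genes = 10L,
                    n_regions_per_class = c(increased = 1L, decreased = 1L,
                                            unchanged = 1L,
                                            strainA_only = 1L,
                                            strainB_only = 1L, shared = 1L),
                    region_length = c(100L, 200L))
  r <- sim_region_sets(cfg, sim_annotation(cfg))
  expect_equal(nrow(r), 6L)
  expect_setequal(r$class, c("increased", "decreased", "unchanged",
                             "strainA_only", "strainB_only", "shared"))
})

test_that("variants match the genome, respect rates, and honor zero rates", {
  cfg <- small_config(seed = 6L)
  g <- sim_genome(cfg)
  tss <- sim_annotation(cfg)
  regions <- sim_region_sets(cfg, tss)
  v <- sim_variants(cfg, g, regions)
  # every REF allele matches the genome at POS
  for (i in seq_len(nrow(v))) {
    expect_identical(
      as.character(Biostrings::extractAt(
        g[[v$chrom[i]]],
        IRanges::IRanges(v$pos[i], v$pos[i] + nchar(v$ref[i]) - 1L))),
      v$ref[i])
  }
  # SNV footprints never overlap (needed downstream for consensus)
  expect_silent(validate_variants(v, g))
  # zero rates: empty variant table
  z <- small_config(seed = 6L,
                    snv_rate_by_class = c(increased = 0, decreased = 0,
                                          unchanged = 0, strainA_only = 0,
                                          strainB_only = 0, shared = 0),
                    indel_rate_by_class = c(increased = 0, decreased = 0,
                                            unchanged = 0, strainA_only = 0,
                                            strainB_only = 0, shared = 0))
  expect_equal(nrow(sim_variants(z, g, regions)), 0L)
  # missing class in the rate map is an error
  bad <- cfg
  bad$snv_rate_by_class <- bad$snv_rate_by_class[-1]
  expect_error(sim_variants(bad, g, regions), "lacks class")
})

test_that("planted diseases overlap the hot gene set; orthologs count out", {
  cfg <- small_config(seed = 8L, n_diseases = 30L,
                      planted_enriched_diseases = 3L)
  tss <- sim_annotation(cfg)
  gc <- sim_gwas_catalog(cfg, tss)
  pairs <- parse_gwas_catalog(gc$catalog)
  hot_h <- toupper(gc$hot_genes)
  jacc <- vapply(split(pairs$gene, pairs$disease), function(g) {
    length(intersect(g, hot_h)) / length(union(g, hot_h))
  }, numeric(1))
  planted <- names(jacc) %in% gc$planted_diseases
  expect_gt(min(jacc[planted]), mean(jacc[!planted]))
  expect_equal(nrow(gc$orthologs),
               round(cfg$ortholog_fraction * cfg$n_genes))
  expect_false(any(duplicated(gc$orthologs$mouse_gene)))
  expect_error(sim_gwas_catalog(small_config(genes_per_disease = c(60L, 60L)),
                                tss),
               "exceeds gene count")
})

test_that("counts track planted fold changes", {
  cfg <- sim_config(seed = 13L, n_genes = 6000L, nb_mean = 500,
                    nb_dispersion = 0.05,
                    fc_by_class = c(increased = 0.5, decreased = -1,
                                    unchanged = 0))
  classes <- data.frame(
    gene_id = sprintf("gene%05d", 1:6000),
    class = rep(c("decreased", "unchanged", "increased"), each = 2000))
  counts <- sim_counts(cfg, classes)
  # generator property: raw ratios at known unit factors (normalization
  # of an asymmetric planted design is exercised separately)
  fc <- fold_changes(counts, factors = c(1, 1))
  med <- tapply(fc$log2_fc, classes$class, median, na.rm = TRUE)
  # decreased genes planted at log2 FC -1: median recovered within 0.1
  expect_lt(abs(med[["decreased"]] - (-1)), 0.1)
  expect_lt(med[["decreased"]], med[["unchanged"]])
  expect_lt(med[["unchanged"]], med[["increased"]])
  # zero fold change everywhere centers log2 FC at 0
  flat <- sim_config(seed = 14L, n_genes = 2000L,
                     fc_by_class = c(increased = 0, decreased = 0,
                                     unchanged = 0))
  fc0 <- fold_changes(sim_counts(flat, classes[1:2000, ]))
  expect_lt(abs(median(fc0$log2_fc, na.rm = TRUE)), 0.05)
})
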