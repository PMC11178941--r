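## Simulation configuration for the synthetic-data module.

#' Region class vocabularies
#'
#' Differential classes describe the response of an H3K27ac region to the
#' environmental manipulation (single housing); strain classes describe
#' presence/absence between the two inbred strains (A plays the reference
#' strain whose regions are selectively absent in B, and vice versa).
#'
#' @name region_classes
#' @keywords internal
NULL

diff_classes <- c("increased", "decreased", "unchanged")
strain_classes <- c("strainA_only", "strainB_only", "shared")
all_region_classes <- c(diff_classes, strain_classes)

#' Build a simulation configuration
#'
#' Defines the study conditions that every generator emulates. The
#' class-conditional SNV densities default to the published islet values:
#' 0.14 SNV/kb in regions whose acetylation decreases after single housing
#' and 0.28 SNV/kb in regions selectively absent in the variant-carrying
#' strain (here `strainA_only`: present only in the reference strain).
#' Remaining rates are free knobs chosen to reproduce the published
#' qualitative ordering (selective > shared; decreased > increased).
#'
#' @param seed global integer seed; per-generator substreams are derived
#'   from it deterministically, so the same config yields byte-identical
#'   outputs whatever the call order.
#' @param n_chroms number of chromosomes.
#' @param chrom_length chromosome length in bp (same for all chromosomes).
#' @param n_genes number of genes (one TSS each).
#' @param n_regions_per_class named integer vector over the six region
#'   classes.
#' @param region_length length-2 integer range (bp) for region widths.
#' @param snv_rate_by_class named numeric vector, SNVs per kb per class.
#' @param indel_rate_by_class named numeric vector, indels per kb per class.
#' @param n_diseases number of diseases/traits in the mock GWAS catalog.
#' @param genes_per_disease length-2 integer range of genes per disease.
#' @param planted_enriched_diseases number of diseases planted to draw
#'   genes from the designated "hot" gene subset.
#' @param enrichment_multiplier multiplier (> 1) applied to midpoint
#'   placement density inside a planted disease's territory.
#' @param nb_mean negative-binomial mean for baseline counts.
#' @param nb_dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param fc_by_class named numeric vector of log2 fold changes by
#'   differential class (condition 2 relative to condition 1).
#' @param tss_bias logical: place `increased` regions near TSSs and
#'   `decreased` regions distal, mirroring the observed genomic
#'   distributions.
#' @param ortholog_fraction fraction of genes given a one-to-one human
#'   ortholog.
#' @param hot_gene_fraction fraction of genes forming the "hot" subset
#'   favoured by planted diseases.
#' @param indels_cross_boundaries logical stress-test flag: allow indels to
#'   cross region boundaries (default FALSE keeps liftover bookkeeping
#'   simple).
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 2L,
                       chrom_length = 2e6,
                       n_genes = 200L,
                       n_regions_per_class = c(increased = 60L, decreased = 60L,
                                               unchanged = 60L,
                                               strainA_only = 40L,
                                               strainB_only = 40L,
                                               shared = 60L),
                       region_length = c(500L, 2000L),
                       snv_rate_by_class = c(increased = 0.07, decreased = 0.14,
                                             unchanged = 0.10,
                                             strainA_only = 0.28,
                                             strainB_only = 0.22,
                                             shared = 0.10),
                       indel_rate_by_class = 0.3 * snv_rate_by_class,
                       n_diseases = 50L,
                       genes_per_disease = c(5L, 20L),
                       planted_enriched_diseases = 1L,
                       enrichment_multiplier = 3,
                       nb_mean = 500,
                       nb_dispersion = 0.05,
                       fc_by_class = c(increased = 0.5, decreased = -1,
                                       unchanged = 0),
                       tss_bias = TRUE,
                       ortholog_fraction = 0.9,
                       hot_gene_fraction = 0.1,
                       indels_cross_boundaries = FALSE) {
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              chrom_length = as.integer(chrom_length),
              n_genes = as.integer(n_genes),
              n_regions_per_class = n_regions_per_class,
              region_length = as.integer(region_length),
              snv_rate_by_class = snv_rate_by_class,
              indel_rate_by_class = indel_rate_by_class,
              n_diseases = as.integer(n_diseases),
              genes_per_disease = as.integer(genes_per_disease),
              planted_enriched_diseases = as.integer(planted_enriched_diseases),
              enrichment_multiplier = enrichment_multiplier,
              nb_mean = nb_mean, nb_dispersion = nb_dispersion,
              fc_by_class = fc_by_class, tss_bias = isTRUE(tss_bias),
              ortholog_fraction = ortholog_fraction,
              hot_gene_fraction = hot_gene_fraction,
              indels_cross_boundaries = isTRUE(indels_cross_boundaries))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' @keywords internal
#' @noRd
validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_chroms < 1L || cfg$chrom_length < 1L) {
    stop("n_chroms and chrom_length must be positive")
  }
  for (nm in c("snv_rate_by_class", "indel_rate_by_class")) {
    if (any(cfg[[nm]] < 0)) stop(nm, ": rates must be >= 0")
  }
  if (length(cfg$region_length) != 2L || any(cfg$region_length < 1L) ||
      cfg$region_length[1] > cfg$region_length[2]) {
    stop("region_length must be an increasing positive range")
  }
  if (cfg$region_length[2] >= cfg$chrom_length) {
    stop("region lengths must be smaller than chrom_length")
  }
  if (cfg$planted_enriched_diseases > cfg$n_diseases) {
    stop("planted_enriched_diseases must not exceed n_diseases")
  }
  if (cfg$enrichment_multiplier <= 1) {
    stop("enrichment_multiplier must be > 1")
  }
  if (cfg$nb_dispersion < 0) stop("nb_dispersion must be >= 0")
  bad <- setdiff(names(cfg$n_regions_per_class), all_region_classes)
  if (length(bad) > 0L) stop("unknown region class(es): ",
                             paste(bad, collapse = ", "))
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> seed", x$seed, "|", x$n_chroms, "chrom x",
      x$chrom_length, "bp |", x$n_genes, "genes |",
      sum(x$n_regions_per_class), "regions |", x$n_diseases, "diseases\n")
  invisible(x)
}
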