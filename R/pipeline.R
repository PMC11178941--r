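## End-to-end driver over synthetic (or user-supplied) inputs:
## simulate -> consensus/chain -> LCREDs -> atlas -> densities ->
## enrichment -> motifs -> expression, writing TSV outputs, a run log and
## a machine-readable summary. Outputs are stamped with a config hash and
## the seed so reruns are auditable.

#' Run the full analysis pipeline on synthetic data
#'
#' @param config [sim_config()] describing the simulated study.
#' @param out_dir output directory (created if needed).
#' @param cap_bp LCRED extension cap (bp).
#' @param min_genes minimum genes per tested disease.
#' @param q_threshold significance threshold on BH q-values.
#' @param pwm_threshold motif-scan fraction-of-max cutoff.
#' @param strict_lift discard partial lifts (default keeps them flagged).
#' @param motifs named list of [pwm()] objects; default loads the bundled
#'   synthetic motifs.
#' @param write_files write TSV/BED/VCF/FASTA artifacts under `out_dir`
#'   (set `FALSE` to only return the in-memory bundle).
#' @return invisible list with every stage's tables plus `summary` (also
#'   written as `summary.json`) and `log` (stage-level counts).
#' @export
run_pipeline <- function(config = sim_config(),
                         out_dir = tempfile("epivar_run_"),
                         cap_bp = 1000000L, min_genes = 5L,
                         q_threshold = 0.01, pwm_threshold = 0.8,
                         strict_lift = FALSE,
                         motifs = NULL,
                         write_files = TRUE) {
  validate_sim_config(config)
  if (write_files) dir.create(out_dir, showWarnings = FALSE,
                              recursive = TRUE)
  log <- character(0)
  note <- function(...) {
    msg <- paste0(...)
    log <<- c(log, msg)
    message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  ## --- simulate -------------------------------------------------------
  genome <- stage("genome", sim_genome(config))
  sizes <- chrom_sizes(genome)
  tss <- stage("annotation", sim_annotation(config))
  regions <- stage("regions", sim_region_sets(config, tss))
  variants <- stage("variants", sim_variants(config, genome, regions))
  gwas <- stage("gwas", sim_gwas_catalog(config, tss))
  note("simulated ", nrow(regions), " regions, ", nrow(variants),
       " variants, ", nrow(gwas$catalog), " catalog rows")

  ## --- consensus + chain ---------------------------------------------
  cons <- stage("consensus", build_consensus(genome, variants))
  note("consensus length delta ",
       sum(Biostrings::width(cons$consensus)) -
         sum(Biostrings::width(genome)), " bp over ",
       nrow(cons$map$blocks), " aligned blocks")

  ## --- LCREDs ---------------------------------------------------------
  lcreds <- stage("lcred", build_lcreds(tss, sizes, cap_bp = cap_bp))
  assignments <- stage("assign", assign_regions(regions, lcreds))
  note("assigned ", sum(!is.na(assignments$gene_id)), "/",
       nrow(assignments), " regions to ",
       length(unique(stats::na.omit(assignments$gene_id))), " genes")

  ## --- atlas ----------------------------------------------------------
  diff_regions <- regions[regions$class %in% diff_classes, , drop = FALSE]
  strain_sets <- list(
    strainA = regions[regions$class %in% c("strainA_only", "shared"), ],
    strainB = regions[regions$class %in% c("strainB_only", "shared"), ])
  atlas <- stage("atlas", merge_region_sets(strain_sets))
  strain_call <- stage("strains", classify_strain_selective(
    atlas, "strainA", "strainB"))
  note("atlas: ", strain_call$counts[["total"]], " merged intervals (",
       strain_call$counts[["shared"]], " shared, ",
       strain_call$counts[["strainA_only"]], " A-only, ",
       strain_call$counts[["strainB_only"]], " B-only)")

  ## --- densities ------------------------------------------------------
  dens <- stage("density", variant_density(regions, variants))
  dens$class <- regions$class
  content <- stage("lcred_content", label_lcred_content(
    assignments, regions[, c("region_id", "class")]))
  lcred_dens <- stage("lcred_density", variant_density(lcreds, variants))
  by_class <- vapply(split(dens$snv_per_kb, dens$class), stats::median,
                     numeric(1))
  note("median SNV/kb by class: ",
       paste(names(by_class), round(by_class, 3), sep = "=",
             collapse = ", "))

  ## --- enrichment -----------------------------------------------------
  pairs <- stage("catalog", parse_gwas_catalog(gwas$catalog))
  universe <- stage("universe", build_locus_universe(
    pairs, gwas$orthologs, lcreds, min_genes = min_genes))
  dec <- regions[regions$class == "decreased", , drop = FALSE]
  midpoints <- data.frame(chrom = dec$chrom,
                          pos = interval_midpoint(dec$start, dec$end))
  enrich <- stage("enrich", binomial_enrichment(midpoints, universe))
  note("enrichment: ", sum(enrich$qvalue < q_threshold), " disease(s) at q < ",
       q_threshold, " over ", nrow(enrich), " tested")

  ## --- motifs ---------------------------------------------------------
  if (is.null(motifs)) {
    motifs <- read_homer_motifs(system.file("extdata", "motifs",
                                            "synthetic_tf.motif",
                                            package = "epivar"))
  }
  hits <- stage("motif", do.call(rbind, lapply(motifs, function(p)
    scan_pwm(genome, dec, p, threshold = pwm_threshold))))
  overlap <- stage("motif_overlap", motif_variant_overlap(
    hits, variants, dec))
  note("motifs: ", overlap$summary$n_with_motif, "/",
       overlap$summary$n_regions, " decreased regions with a hit; ",
       overlap$summary$n_with_overlap, " with a variant inside a hit")

  ## --- expression -----------------------------------------------------
  excl <- content[!is.na(content$exclusive_class) &
                    content$exclusive_class %in% diff_classes,
                  c("gene_id", "exclusive_class")]
  gene_classes <- data.frame(gene_id = tss$gene_id,
                             class = excl$exclusive_class[
                               match(tss$gene_id, excl$gene_id)],
                             stringsAsFactors = FALSE)
  counts <- stage("counts", sim_counts(config, gene_classes))
  fc <- stage("fold_changes", fold_changes(counts))
  expr_test <- if (sum(!is.na(excl$exclusive_class)) > 0 &&
                   length(unique(excl$exclusive_class)) >= 2) {
    names(excl)[2] <- "exclusive_class"
    stage("class_test", class_expression_test(fc, excl))
  } else NULL
  if (!is.null(expr_test)) {
    note("expression omnibus p = ",
         format(expr_test$omnibus$pvalue, digits = 3))
  }

  ## --- summary + outputs ---------------------------------------------
  summary <- list(
    seed = config$seed,
    n_merged_intervals = unname(strain_call$counts[["total"]]),
    strain_counts = as.list(strain_call$counts),
    median_snv_per_kb_by_class = as.list(round(by_class, 6)),
    n_regions_assigned = sum(!is.na(assignments$gene_id)),
    n_diseases_tested = nrow(enrich),
    n_diseases_significant = sum(enrich$qvalue < q_threshold),
    top_disease = enrich$disease[1],
    frac_regions_with_motif = overlap$summary$frac_with_motif,
    expression_omnibus_p = if (is.null(expr_test)) NA else
      expr_test$omnibus$pvalue)

  if (write_files) {
    cfg_path <- file.path(out_dir, "config.txt")
    dput(unclass(config), file = cfg_path)
    summary$config_hash <- unname(tools::md5sum(cfg_path))
    write_fasta(genome, file.path(out_dir, "genome.fa"))
    write_fasta(cons$consensus, file.path(out_dir, "consensus.fa"))
    write_chain(cons$map, file.path(out_dir, "liftover.chain"))
    write_gtf(tss, file.path(out_dir, "annotation.gtf"), sizes)
    write_bed(data.frame(chrom = tss$chrom, start = tss$tss,
                         end = tss$tss + 1L, name = tss$gene_id,
                         score = 0L, strand = tss$strand),
              file.path(out_dir, "tss.bed"))
    write_bed(stats::setNames(
      regions[, c("chrom", "start", "end", "region_id", "class")],
      c("chrom", "start", "end", "name", "score")),
      file.path(out_dir, "regions.bed"))
    write_vcf(variants, file.path(out_dir, "variants.vcf"),
              contigs = sizes)
    write_bed(stats::setNames(lcreds[, c("chrom", "start", "end", "gene_id")],
                              c("chrom", "start", "end", "name")),
              file.path(out_dir, "lcreds.bed"))
    write_tsv(assignments, file.path(out_dir, "assignments.tsv"))
    write_tsv(dens, file.path(out_dir, "region_density.tsv"))
    write_tsv(lcred_dens, file.path(out_dir, "lcred_density.tsv"))
    write_tsv(content, file.path(out_dir, "lcred_content.tsv"))
    write_tsv(enrich, file.path(out_dir, "enrichment.tsv"))
    write_tsv(gwas$catalog, file.path(out_dir, "gwas_catalog.tsv"))
    write_tsv(gwas$orthologs, file.path(out_dir, "orthologs.tsv"))
    write_tsv(counts, file.path(out_dir, "counts.tsv"))
    write_tsv(fc, file.path(out_dir, "fold_changes.tsv"))
    if (nrow(hits) > 0L) write_tsv(hits, file.path(out_dir, "motif_hits.tsv"))
    writeLines(log, file.path(out_dir, "run.log"))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  invisible(list(genome = genome, tss = tss, regions = regions,
                 variants = variants, consensus = cons, lcreds = lcreds,
                 assignments = assignments, atlas = atlas,
                 strain_call = strain_call, density = dens,
                 lcred_density = lcred_dens, content = content,
                 universe = universe, enrichment = enrich,
                 motif_hits = hits, motif_overlap = overlap,
                 counts = counts, fold_changes = fc,
                 expression_test = expr_test,
                 summary = summary, log = log))
}
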