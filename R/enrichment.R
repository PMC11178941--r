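## GREAT-style binomial enrichment of GWAS diseases/traits in a set of
## H3K27ac region midpoints over an LCRED universe. One-sided upper tail
## (enrichment only); the total base pairs of eligible LCREDs play the
## role of the genome size, and midpoints falling outside the universe are
## discarded before n is counted.

#' Parse a GWAS association catalog into disease-gene pairs
#'
#' Multi-gene cells are split on commas and on " - " spans (both genes of
#' a span are kept); duplicate disease-gene pairs are dropped.
#'
#' @param catalog data.frame (or TSV path) with a disease/trait column and
#'   a mapped-gene column.
#' @param disease_col,gene_col column names (GWAS-catalog dialect defaults).
#' @return data.frame with `disease`, `gene` (deduplicated).
#' @export
parse_gwas_catalog <- function(catalog, disease_col = "DISEASE/TRAIT",
                               gene_col = "MAPPED_GENE") {
  if (is.character(catalog) && length(catalog) == 1L) {
    catalog <- read_tsv(catalog)
  }
  if (!all(c(disease_col, gene_col) %in% names(catalog))) {
    stop("catalog lacks column '", disease_col, "' or '", gene_col, "'")
  }
  disease <- catalog[[disease_col]]
  genes <- strsplit(catalog[[gene_col]], ",| - ")
  out <- data.frame(disease = rep(disease, lengths(genes)),
                    gene = trimws(unlist(genes)), stringsAsFactors = FALSE)
  out <- out[out$gene != "", , drop = FALSE]
  out <- unique(out)
  rownames(out) <- NULL
  out
}

#' Build the locus universe for binomial enrichment
#'
#' Human catalog genes are mapped through a one-to-one ortholog table;
#' genes lacking an ortholog or an LCRED are dropped, diseases are
#' filtered to `min_genes` surviving genes, and the universe is the set of
#' all ortholog-mapped genes that have an LCRED (not only disease genes),
#' with `total_bp` the summed length of their (disjoint) domains.
#'
#' @param catalog_pairs output of [parse_gwas_catalog()].
#' @param orthologs data.frame with `human_gene`, `mouse_gene`; duplicated
#'   entries on either side are removed to enforce one-to-one mapping.
#' @param lcreds table from [build_lcreds()].
#' @param min_genes minimum surviving genes per disease (default 5).
#' @return list of class `locus_universe`: `lcreds` (eligible domains),
#'   `total_bp`, `diseases` (data.frame `disease`, `n_genes`,
#'   `territory_bp`), `disease_genes` (named list of mouse gene ids).
#' @export
build_locus_universe <- function(catalog_pairs, orthologs, lcreds,
                                 min_genes = 5L) {
  orth <- orthologs[!duplicated(orthologs$human_gene) &
                      !duplicated(orthologs$mouse_gene), , drop = FALSE]
  eligible <- lcreds[lcreds$gene_id %in% orth$mouse_gene, , drop = FALSE]
  if (nrow(eligible) == 0L) stop("empty locus universe")
  pairs <- catalog_pairs
  pairs$mouse_gene <- orth$mouse_gene[match(pairs$gene, orth$human_gene)]
  pairs <- pairs[!is.na(pairs$mouse_gene) &
                   pairs$mouse_gene %in% eligible$gene_id, , drop = FALSE]
  pairs <- unique(pairs[, c("disease", "mouse_gene")])
  genes_by_disease <- split(pairs$mouse_gene, pairs$disease)
  genes_by_disease <- genes_by_disease[lengths(genes_by_disease) >= min_genes]
  width_by_gene <- stats::setNames(eligible$end - eligible$start,
                                   eligible$gene_id)
  territory <- vapply(genes_by_disease, function(g) sum(width_by_gene[g]),
                      numeric(1))
  structure(list(
    lcreds = eligible,
    total_bp = sum(width_by_gene),
    diseases = data.frame(disease = names(genes_by_disease),
                          n_genes = lengths(genes_by_disease),
                          territory_bp = as.numeric(territory),
                          stringsAsFactors = FALSE, row.names = NULL),
    disease_genes = genes_by_disease), class = "locus_universe")
}

#' @export
print.locus_universe <- function(x, ...) {
  cat("<locus_universe>", nrow(x$lcreds), "gene domains,",
      format(x$total_bp, big.mark = ","), "bp,",
      nrow(x$diseases), "diseases\n")
  invisible(x)
}

#' Binomial disease/trait enrichment over an LCRED universe
#'
#' `n` is the number of midpoints inside any eligible domain (out-of-
#' universe midpoints are discarded first); per disease, `k` counts
#' midpoints inside its territory; `p_frac` is the territory's base-pair
#' fraction; the p-value is the exact upper binomial tail P(X >= k).
#' Benjamini-Hochberg q-values are computed across exactly the tested
#' disease list.
#'
#' @param midpoints data.frame with `chrom`, `pos` (0-based positions).
#' @param universe `locus_universe` from [build_locus_universe()].
#' @return data.frame with `disease`, `k`, `n`, `p_frac`, `pvalue`,
#'   `qvalue`, `n_contributing_genes`, sorted by p-value; attribute
#'   `n_in_universe` records n.
#' @export
binomial_enrichment <- function(midpoints, universe) {
  stopifnot(inherits(universe, "locus_universe"))
  l <- universe$lcreds
  gene <- rep(NA_character_, nrow(midpoints))
  for (cn in unique(midpoints$chrom)) {
    d <- l[l$chrom == cn, , drop = FALSE]
    idx <- which(midpoints$chrom == cn)
    if (nrow(d) == 0L) next
    d <- d[order(d$start), , drop = FALSE]
    i <- findInterval(midpoints$pos[idx], d$start)
    hit <- i > 0L & midpoints$pos[idx] < d$end[pmax(i, 1L)]
    gene[idx[hit]] <- d$gene_id[i[hit]]
  }
  gene <- gene[!is.na(gene)]
  n <- length(gene)
  if (n == 0L) stop("no midpoints fall inside the locus universe")
  counts_by_gene <- table(gene)
  k <- vapply(universe$disease_genes, function(g) {
    sum(counts_by_gene[intersect(g, names(counts_by_gene))])
  }, numeric(1))
  contrib <- vapply(universe$disease_genes, function(g) {
    sum(g %in% names(counts_by_gene))
  }, integer(1))
  p_frac <- universe$diseases$territory_bp / universe$total_bp
  pvalue <- stats::pbinom(k - 1, size = n, prob = p_frac,
                          lower.tail = FALSE)
  res <- data.frame(disease = universe$diseases$disease,
                    k = as.integer(k), n = n, p_frac = p_frac,
                    pvalue = pvalue,
                    qvalue = bh_fdr(pvalue),
                    n_contributing_genes = contrib,
                    stringsAsFactors = FALSE, row.names = NULL)
  res <- res[order(res$pvalue), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_in_universe") <- n
  res
}

#' Benjamini-Hochberg step-up q-values
#'
#' Thin, validating wrapper over `stats::p.adjust(method = "BH")`.
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @return q-values, same order as input.
#' @export
bh_fdr <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Rank correlation between two enrichment profiles
#'
#' Spearman correlation over -log10 p-values of the diseases shared by
#' both result tables.
#'
#' @param resultsA,resultsB outputs of [binomial_enrichment()].
#' @return list with `rho`, `pvalue`, `n_shared`.
#' @export
profile_correlation <- function(resultsA, resultsB) {
  shared <- intersect(resultsA$disease, resultsB$disease)
  if (length(shared) < 3L) stop("need at least 3 shared diseases")
  a <- -log10(resultsA$pvalue[match(shared, resultsA$disease)])
  b <- -log10(resultsB$pvalue[match(shared, resultsB$disease)])
  s <- spearman_cor(a, b)
  list(rho = s$rho, pvalue = s$pvalue, n_shared = length(shared))
}
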