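## Synthetic-data generators. Each generator derives its own RNG substream
## from the config seed, so any generator called twice with the same config
## produces identical output regardless of call order.

#' Generate a random genome
#'
#' Uniform-random A/C/G/T sequence per chromosome (`chr1` ... `chrN`).
#'
#' @param config [sim_config()].
#' @return named [Biostrings::DNAStringSet].
#' @export
sim_genome <- function(config) {
  validate_sim_config(config)
  set.seed(substream_seed(config$seed, "genome"))
  bases <- c("A", "C", "G", "T")
  seqs <- vapply(seq_len(config$n_chroms), function(i) {
    paste(bases[sample.int(4L, config$chrom_length, replace = TRUE)],
          collapse = "")
  }, character(1))
  names(seqs) <- paste0("chr", seq_len(config$n_chroms))
  Biostrings::DNAStringSet(seqs)
}

#' Generate a gene annotation (one TSS per gene)
#'
#' TSS positions are sampled without collision; strands uniform.
#'
#' @param config [sim_config()].
#' @return data.frame with `gene_id`, `gene_name`, `chrom`, `tss` (0-based),
#'   `strand`, sorted by chromosome and position.
#' @export
sim_annotation <- function(config) {
  validate_sim_config(config)
  if (config$n_genes > config$n_chroms * config$chrom_length) {
    stop("more genes than available positions")
  }
  set.seed(substream_seed(config$seed, "annotation"))
  chrom <- sample(paste0("chr", seq_len(config$n_chroms)),
                  config$n_genes, replace = TRUE)
  tss <- integer(config$n_genes)
  for (cn in unique(chrom)) {
    idx <- which(chrom == cn)
    tss[idx] <- sample.int(config$chrom_length, length(idx)) - 1L
  }
  strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)
  o <- order(chrom, tss)
  out <- data.frame(
    gene_id = sprintf("gene%05d", seq_len(config$n_genes)),
    gene_name = sprintf("Gm%05d", seq_len(config$n_genes)),
    chrom = chrom[o], tss = tss[o], strand = strand[o],
    stringsAsFactors = FALSE)
  out
}

# exponential mean distance (bp) from a region midpoint to its anchoring
# TSS; NA places the class uniformly. Mirrors the observed distributions:
# induced regions accumulate near TSSs, decreased regions lie distal.
.bias_mean <- c(increased = 3e3, decreased = 2e5, unchanged = NA,
                strainA_only = NA, strainB_only = NA, shared = NA)

#' Generate labeled, non-overlapping region sets
#'
#' Regions from all classes are placed mutually disjoint (so class
#' territories never share bases and class-conditional variant densities
#' are exact by construction). With `tss_bias = TRUE`, `increased` regions
#' are drawn near TSSs and `decreased` regions distal.
#'
#' @param config [sim_config()].
#' @param tss annotation from [sim_annotation()].
#' @param max_rounds bounded number of rejection-sampling rounds per class.
#' @return data.frame with `chrom`, `start`, `end`, `region_id`, `class`.
#' @export
sim_region_sets <- function(config, tss, max_rounds = 200L) {
  validate_sim_config(config)
  set.seed(substream_seed(config$seed, "regions"))
  chroms <- paste0("chr", seq_len(config$n_chroms))
  L <- config$chrom_length
  occupied <- stats::setNames(
    lapply(chroms, function(x) IRanges::IRanges()), chroms)
  out <- list()
  for (cls in names(config$n_regions_per_class)) {
    n_want <- config$n_regions_per_class[[cls]]
    if (n_want == 0L) next
    got <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0))
    rounds <- 0L
    while (nrow(got) < n_want) {
      rounds <- rounds + 1L
      if (rounds > max_rounds) {
        stop("could not place ", n_want, " non-overlapping '", cls,
             "' regions after ", max_rounds, " rounds")
      }
      k <- n_want - nrow(got)
      len <- sample(seq(config$region_length[1], config$region_length[2]),
                    k, replace = TRUE)
      bm <- .bias_mean[[cls]]
      if (config$tss_bias && !is.na(bm) && nrow(tss) > 0L) {
        anchor <- tss[sample.int(nrow(tss), k, replace = TRUE), ]
        dist <- stats::rexp(k, rate = 1 / bm)
        sgn <- sample(c(-1, 1), k, replace = TRUE)
        mid <- round(anchor$tss + sgn * dist)
        chrom <- anchor$chrom
      } else {
        chrom <- sample(chroms, k, replace = TRUE)
        mid <- floor(stats::runif(k, 0, L))
      }
      start <- pmin(pmax(mid - len %/% 2, 0), L - len)
      cand <- data.frame(chrom = chrom, start = as.integer(start),
                         end = as.integer(start + len))
      # reject candidates clashing with occupied territory or each other
      for (cn in unique(cand$chrom)) {
        idx <- which(cand$chrom == cn)
        ir <- IRanges::IRanges(cand$start[idx] + 1L, cand$end[idx])
        keep <- IRanges::countOverlaps(ir, occupied[[cn]]) == 0L
        # drop within-batch overlaps greedily
        self <- IRanges::findOverlaps(ir, ir)
        dup <- S4Vectors::queryHits(self) > S4Vectors::subjectHits(self)
        keep[unique(S4Vectors::queryHits(self)[dup])] <- FALSE
        acc <- idx[keep]
        if (length(acc) > 0L) {
          occupied[[cn]] <- c(occupied[[cn]],
                              IRanges::IRanges(cand$start[acc] + 1L,
                                               cand$end[acc]))
          got <- rbind(got, cand[acc, , drop = FALSE])
        }
      }
    }
    got <- got[seq_len(n_want), , drop = FALSE]
    got$class <- cls
    out[[cls]] <- got
  }
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out$region_id <- sprintf("region%06d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("chrom", "start", "end", "region_id", "class")]
}

#' Generate variants inside labeled regions
#'
#' SNV and indel counts per region are Poisson at that region class's
#' per-kb rate; REF alleles are read from the genome; ALT is a random
#' differing base (SNV) or a 1-10 bp insertion/deletion. Variant footprints
#' never overlap (required for consensus construction) and, unless
#' `config$indels_cross_boundaries` is set, indels stay inside their
#' region.
#'
#' @param config [sim_config()].
#' @param genome [Biostrings::DNAStringSet] from [sim_genome()].
#' @param regions labeled regions from [sim_region_sets()].
#' @return data.frame with `chrom`, `pos` (1-based first REF base), `id`,
#'   `ref`, `alt`, `type`, `region_id`, `class`, coordinate-sorted.
#' @export
sim_variants <- function(config, genome, regions) {
  validate_sim_config(config)
  missing_cls <- setdiff(unique(regions$class),
                         names(config$snv_rate_by_class))
  if (length(missing_cls) > 0L) {
    stop("snv_rate_by_class lacks class(es): ",
         paste(missing_cls, collapse = ", "))
  }
  set.seed(substream_seed(config$seed, "variants"))
  sizes <- chrom_sizes(genome)
  recs <- vector("list", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    reg <- regions[i, ]
    len <- reg$end - reg$start
    n_snv <- stats::rpois(1L, config$snv_rate_by_class[[reg$class]] *
                            len / 1000)
    n_ind <- stats::rpois(1L, config$indel_rate_by_class[[reg$class]] *
                            len / 1000)
    if (n_snv + n_ind == 0L) next
    n_snv <- min(n_snv, len)
    pos0 <- reg$start + sample.int(len, min(len, n_snv + n_ind)) - 1L
    snv_pos <- pos0[seq_len(min(n_snv, length(pos0)))]
    ind_pos <- pos0[setdiff(seq_along(pos0), seq_len(length(snv_pos)))]
    df <- NULL
    if (length(snv_pos) > 0L) {
      df <- data.frame(chrom = reg$chrom, pos0 = snv_pos, reflen = 1L,
                       kind = "snv", indel_size = 0L, ins = FALSE)
    }
    if (length(ind_pos) > 0L) {
      sz <- sample.int(10L, length(ind_pos), replace = TRUE)
      ins <- sample(c(TRUE, FALSE), length(ind_pos), replace = TRUE)
      reflen <- ifelse(ins, 1L, sz + 1L)
      limit <- if (config$indels_cross_boundaries) {
        sizes$length[match(reg$chrom, sizes$chrom)]
      } else reg$end
      ok <- ind_pos + reflen <= limit
      if (any(ok)) {
        df <- rbind(df, data.frame(chrom = reg$chrom, pos0 = ind_pos[ok],
                                   reflen = reflen[ok], kind = "indel",
                                   indel_size = sz[ok], ins = ins[ok]))
      }
    }
    if (!is.null(df)) {
      df$region_id <- reg$region_id
      df$class <- reg$class
      recs[[i]] <- df
    }
  }
  cand <- do.call(rbind, recs)
  if (is.null(cand) || nrow(cand) == 0L) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      id = character(0), ref = character(0),
                      alt = character(0), type = character(0),
                      region_id = character(0), class = character(0),
                      stringsAsFactors = FALSE))
  }
  cand <- cand[order(cand$chrom, cand$pos0), , drop = FALSE]
  # greedy: drop any candidate whose REF footprint touches the previous one
  keep <- logical(nrow(cand))
  last_chrom <- ""
  last_end <- -1L
  for (i in seq_len(nrow(cand))) {
    if (cand$chrom[i] != last_chrom || cand$pos0[i] > last_end) {
      keep[i] <- TRUE
      last_chrom <- cand$chrom[i]
      last_end <- cand$pos0[i] + cand$reflen[i] - 1L
    }
  }
  cand <- cand[keep, , drop = FALSE]
  # fetch REF alleles from the genome
  ref <- character(nrow(cand))
  for (cn in unique(cand$chrom)) {
    idx <- which(cand$chrom == cn)
    at <- IRanges::IRanges(cand$pos0[idx] + 1L,
                           cand$pos0[idx] + cand$reflen[idx])
    ref[idx] <- as.character(Biostrings::extractAt(genome[[cn]], at))
  }
  bases <- c("A", "C", "G", "T")
  alt <- character(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (cand$kind[i] == "snv") {
      alt[i] <- sample(setdiff(bases, ref[i]), 1L)
    } else if (cand$ins[i]) {
      alt[i] <- paste0(ref[i], paste(sample(bases, cand$indel_size[i],
                                            replace = TRUE), collapse = ""))
    } else {
      alt[i] <- substr(ref[i], 1L, 1L)
    }
  }
  out <- data.frame(chrom = cand$chrom, pos = cand$pos0 + 1L,
                    id = sprintf("var%06d", seq_len(nrow(cand))),
                    ref = ref, alt = alt, type = cand$kind,
                    region_id = cand$region_id, class = cand$class,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Generate a mock GWAS association catalog and an ortholog map
#'
#' Planted diseases draw most of their genes from a designated "hot"
#' subset; the rest sample genes uniformly. Human symbols are upper-cased
#' mouse gene ids; the ortholog map covers `config$ortholog_fraction` of
#' genes one-to-one.
#'
#' @param config [sim_config()].
#' @param genes annotation from [sim_annotation()].
#' @return list with `catalog` (columns `DISEASE/TRAIT`, `MAPPED_GENE`),
#'   `orthologs` (`human_gene`, `mouse_gene`), `hot_genes`,
#'   `planted_diseases`.
#' @export
sim_gwas_catalog <- function(config, genes) {
  validate_sim_config(config)
  rng <- config$genes_per_disease
  if (rng[2] > config$n_genes) stop("genes_per_disease exceeds gene count")
  set.seed(substream_seed(config$seed, "gwas"))
  gid <- genes$gene_id
  n_hot <- max(1L, ceiling(config$hot_gene_fraction * length(gid)))
  hot <- sort(sample(gid, n_hot))
  disease <- sprintf("disease%03d", seq_len(config$n_diseases))
  planted <- disease[seq_len(config$planted_enriched_diseases)]
  rows <- lapply(seq_len(config$n_diseases), function(i) {
    k <- if (rng[1] == rng[2]) rng[1] else sample(seq(rng[1], rng[2]), 1L)
    if (disease[i] %in% planted) {
      k_hot <- min(length(hot), ceiling(0.8 * k))
      g <- c(sample(hot, k_hot),
             sample(setdiff(gid, hot), k - k_hot))
    } else {
      g <- sample(gid, k)
    }
    data.frame(disease = disease[i], gene = toupper(g),
               stringsAsFactors = FALSE)
  })
  catalog <- do.call(rbind, rows)
  names(catalog) <- c("DISEASE/TRAIT", "MAPPED_GENE")
  n_map <- round(config$ortholog_fraction * length(gid))
  mapped <- sort(sample(gid, n_map))
  orthologs <- data.frame(human_gene = toupper(mapped), mouse_gene = mapped,
                          stringsAsFactors = FALSE)
  list(catalog = catalog, orthologs = orthologs, hot_genes = hot,
       planted_diseases = planted)
}

#' Generate a two-condition negative-binomial count matrix
#'
#' Condition-2 means are scaled by `2^fc` of each gene's differential
#' class; genes without a class use fold change 0.
#'
#' @param config [sim_config()].
#' @param gene_class_map data.frame with `gene_id` and `class`.
#' @return data.frame with `gene_id`, `cond1`, `cond2` integer counts.
#' @export
sim_counts <- function(config, gene_class_map) {
  validate_sim_config(config)
  set.seed(substream_seed(config$seed, "counts"))
  fc <- config$fc_by_class[gene_class_map$class]
  fc[is.na(fc)] <- 0
  n <- nrow(gene_class_map)
  mu1 <- rep(config$nb_mean, n)
  mu2 <- config$nb_mean * 2^fc
  draw <- function(mu) {
    if (config$nb_dispersion == 0) stats::rpois(n, mu)
    else stats::rnbinom(n, mu = mu, size = 1 / config$nb_dispersion)
  }
  data.frame(gene_id = gene_class_map$gene_id,
             cond1 = draw(mu1), cond2 = draw(mu2),
             stringsAsFactors = FALSE)
}

#' Sample region midpoints over an LCRED universe
#'
#' Midpoints are placed uniformly per base over the supplied domains,
#' optionally enriching the territory of `hot_genes` by `multiplier`
#' (the planted-disease mechanism used for power checks).
#'
#' @param lcreds LCRED table from [build_lcreds()] (columns `gene_id`,
#'   `chrom`, `start`, `end`).
#' @param n number of midpoints.
#' @param hot_genes genes whose territory is enriched.
#' @param multiplier density multiplier for hot territory (>= 1).
#' @param seed optional seed; when `NULL` the current RNG state is used so
#'   repeated calls vary.
#' @return data.frame with `chrom`, `pos` (0-based) and `gene_id` of the
#'   domain each midpoint fell in.
#' @export
sim_midpoints <- function(lcreds, n, hot_genes = character(0),
                          multiplier = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  w <- (lcreds$end - lcreds$start) *
    ifelse(lcreds$gene_id %in% hot_genes, multiplier, 1)
  pick <- sample.int(nrow(lcreds), n, replace = TRUE, prob = w)
  pos <- lcreds$start[pick] +
    floor(stats::runif(n) * (lcreds$end[pick] - lcreds$start[pick]))
  data.frame(chrom = lcreds$chrom[pick], pos = as.integer(pos),
             gene_id = lcreds$gene_id[pick], stringsAsFactors = FALSE)
}
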