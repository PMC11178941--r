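# Shared fixtures and independent oracles used across test files.

toy_genome <- function(seqs) {
  Biostrings::DNAStringSet(seqs)
}

small_config <- function(seed = 1L, ...) {
  sim_config(seed = seed, n_chroms = 2L, chrom_length = 500000L,
             n_genes = 50L,
             n_regions_per_class = c(increased = 15L, decreased = 15L,
                                     unchanged = 15L, strainA_only = 10L,
                                     strainB_only = 10L, shared = 15L),
             region_length = c(300L, 1500L), ...)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Independent per-base projection oracle: walks the variant list and
# assigns, for every 0-based source base, its 0-based destination index
# (NA for deleted bases). Built directly from the variants, independent of
# the offset-map code path.
perbase_projection <- function(src_len, variants) {
  dst <- integer(0)
  proj <- rep(NA_integer_, src_len)
  cursor <- 0L  # next src base to emit
  out_pos <- 0L # next dst index
  v <- variants[order(variants$pos), , drop = FALSE]
  for (i in seq_len(nrow(v))) {
    p0 <- v$pos[i] - 1L
    r <- nchar(v$ref[i])
    a <- nchar(v$alt[i])
    # identical-coordinate run before the variant
    while (cursor < p0) {
      proj[cursor + 1L] <- out_pos
      cursor <- cursor + 1L
      out_pos <- out_pos + 1L
    }
    if (r == a) {
      # substitution: every base keeps an aligned partner
      for (k in seq_len(r)) {
        proj[cursor + 1L] <- out_pos
        cursor <- cursor + 1L
        out_pos <- out_pos + 1L
      }
    } else if (r > a) {
      # deletion: first a bases aligned, remaining r - a deleted
      for (k in seq_len(a)) {
        proj[cursor + 1L] <- out_pos
        cursor <- cursor + 1L
        out_pos <- out_pos + 1L
      }
      cursor <- cursor + (r - a)
    } else {
      # insertion: r aligned bases, then a - r inserted dst bases
      for (k in seq_len(r)) {
        proj[cursor + 1L] <- out_pos
        cursor <- cursor + 1L
        out_pos <- out_pos + 1L
      }
      out_pos <- out_pos + (a - r)
    }
  }
  while (cursor < src_len) {
    proj[cursor + 1L] <- out_pos
    cursor <- cursor + 1L
    out_pos <- out_pos + 1L
  }
  proj
}

# lift one interval through the per-base oracle with inward snapping
oracle_lift <- function(proj, start, end) {
  s_candidates <- which(!is.na(proj[(start + 1L):length(proj)]))
  e_candidates <- which(!is.na(proj[seq_len(end)]))
  if (length(s_candidates) == 0L || length(e_candidates) == 0L) {
    return(list(status = "unmapped"))
  }
  s_src <- start + s_candidates[1] - 1L
  e_src <- e_candidates[length(e_candidates)] - 1L
  if (e_src < s_src) return(list(status = "unmapped"))
  snapped <- is.na(proj[start + 1L]) || is.na(proj[end])
  list(start = proj[s_src + 1L], end = proj[e_src + 1L] + 1L,
       status = if (snapped) "partial" else "exact")
}

# random non-overlapping variant set on a toy chromosome, VCF-style
# (indels share an anchor base)
random_variants <- function(seq, n = 10L) {
  L <- nchar(seq)
  pos_pool <- sample.int(L - 12L, n)
  pos_pool <- sort(pos_pool)
  keep <- c(TRUE, diff(pos_pool) > 12L)
  pos <- pos_pool[keep]
  bases <- c("A", "C", "G", "T")
  recs <- lapply(pos, function(p) {
    kind <- sample(c("snv", "del", "ins"), 1L)
    refbase <- substr(seq, p, p)
    if (kind == "snv") {
      data.frame(chrom = "chr1", pos = p, ref = refbase,
                 alt = sample(setdiff(bases, refbase), 1L))
    } else if (kind == "del") {
      sz <- sample.int(5L, 1L)
      data.frame(chrom = "chr1", pos = p, ref = substr(seq, p, p + sz),
                 alt = refbase)
    } else {
      sz <- sample.int(5L, 1L)
      data.frame(chrom = "chr1", pos = p, ref = refbase,
                 alt = paste0(refbase, paste(sample(bases, sz, TRUE),
                                             collapse = "")))
    }
  })
  do.call(rbind, recs)
}
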