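## Region atlas: merge H3K27ac region sets across conditions/strains and
## classify merged intervals as differential or strain-selective.

#' Merge region sets into an atlas
#'
#' Computes the union of all input intervals, merging any pair that
#' overlaps or lies within `min_gap` bp (default 0: book-ended intervals
#' merge), and records which input sets overlap each merged interval by at
#' least `min_overlap` bp.
#'
#' @param sets named list of data.frames (`chrom`, `start`, `end`).
#' @param min_gap merge intervals separated by at most this many bases.
#' @param min_overlap minimum overlap (bp) for set membership.
#' @return list with `intervals` (data.frame `chrom`, `start`, `end`,
#'   `interval_id`) and `membership` (logical matrix, one column per input
#'   set).
#' @export
merge_region_sets <- function(sets, min_gap = 0L, min_overlap = 1L) {
  stopifnot(is.list(sets), length(sets) > 0L)
  if (is.null(names(sets)) || any(names(sets) == "")) {
    names(sets) <- paste0("set", seq_along(sets))
  }
  for (nm in names(sets)) validate_intervals(sets[[nm]], what = nm)
  grl <- lapply(sets, as_granges0)
  all_gr <- do.call(c, unname(grl))
  merged <- GenomicRanges::reduce(all_gr, min.gapwidth = min_gap + 1L)
  merged <- GenomicRanges::sort(merged)
  membership <- vapply(grl, function(g) {
    GenomicRanges::countOverlaps(merged, g, minoverlap = min_overlap) > 0L
  }, logical(length(merged)))
  if (length(merged) == 1L) {
    membership <- matrix(membership, nrow = 1L,
                         dimnames = list(NULL, names(sets)))
  }
  iv <- granges_to_df(merged)
  iv$interval_id <- sprintf("merged%06d", seq_len(nrow(iv)))
  list(intervals = iv, membership = membership)
}

#' Classify merged intervals as strain-selective or shared
#'
#' A merged interval is "present" in a strain if it overlaps any of that
#' strain's source sets (per the atlas membership matrix). Present in
#' exactly one strain gives a selective label; present in both, `shared`.
#'
#' @param atlas result of [merge_region_sets()].
#' @param strainA_sets,strainB_sets names (or indices) of the membership
#'   columns belonging to each strain.
#' @return list with `labels` (character vector `strainA_only`,
#'   `strainB_only`, `shared` per merged interval) and `counts` (named
#'   totals, including `total`).
#' @export
classify_strain_selective <- function(atlas, strainA_sets, strainB_sets) {
  mem <- atlas$membership
  if (length(strainA_sets) == 0L || length(strainB_sets) == 0L) {
    stop("both strains need at least one source set")
  }
  inA <- rowSums(mem[, strainA_sets, drop = FALSE]) > 0L
  inB <- rowSums(mem[, strainB_sets, drop = FALSE]) > 0L
  labels <- rep(NA_character_, nrow(mem))
  labels[inA & inB] <- "shared"
  labels[inA & !inB] <- "strainA_only"
  labels[!inA & inB] <- "strainB_only"
  counts <- c(shared = sum(labels == "shared", na.rm = TRUE),
              strainA_only = sum(labels == "strainA_only", na.rm = TRUE),
              strainB_only = sum(labels == "strainB_only", na.rm = TRUE),
              total = length(labels))
  list(labels = labels, counts = counts)
}

#' Transfer differential labels onto merged intervals
#'
#' Each labeled region passes its class (`increased`, `decreased`,
#' `unchanged`) to the merged interval that contains it. Merged intervals
#' receiving more than one class are flagged `"mixed"` (and are excluded
#' from exclusive-class analyses downstream); intervals receiving none are
#' `NA`.
#'
#' @param atlas result of [merge_region_sets()].
#' @param labeled data.frame with `chrom`, `start`, `end`, `class`.
#' @return character vector of labels, one per merged interval.
#' @export
attach_differential_labels <- function(atlas, labeled) {
  validate_intervals(labeled, what = "labeled regions")
  iv <- atlas$intervals
  hits <- GenomicRanges::findOverlaps(as_granges0(labeled), as_granges0(iv),
                                      type = "within")
  if (length(unique(S4Vectors::queryHits(hits))) < nrow(labeled)) {
    miss <- setdiff(seq_len(nrow(labeled)), S4Vectors::queryHits(hits))
    stop(length(miss), " labeled region(s) not contained in any merged ",
         "interval (first: ", labeled$chrom[miss[1]], ":",
         labeled$start[miss[1]], ")")
  }
  lab <- rep(NA_character_, nrow(iv))
  cls_by_iv <- split(labeled$class[S4Vectors::queryHits(hits)],
                     S4Vectors::subjectHits(hits))
  for (k in names(cls_by_iv)) {
    u <- unique(cls_by_iv[[k]])
    lab[as.integer(k)] <- if (length(u) == 1L) u else "mixed"
  }
  lab
}
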