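## Variant densities per interval, per LCRED, and per chromatin-state
## segment. A variant counts toward an interval iff the 0-based position of
## its first REF base lies in [start, end); per-kb densities use 1,000
## exactly.

#' Count variants per interval and compute per-kb densities
#'
#' @param intervals data.frame with `chrom`, `start`, `end` and optionally
#'   an id column (`interval_id`, `region_id` or `gene_id`).
#' @param variants data.frame with `chrom`, `pos` (1-based), `type`
#'   (`"snv"`/`"indel"`; inferred from `ref`/`alt` when absent).
#' @return data.frame with `interval_id`, `chrom`, `start`, `end`,
#'   `length`, `n_snv`, `n_indel`, `snv_per_kb`, `indel_per_kb`.
#' @export
variant_density <- function(intervals, variants) {
  validate_intervals(intervals, what = "density intervals")
  if (any(intervals$end - intervals$start <= 0L)) {
    stop("zero-length interval")
  }
  idcol <- intersect(c("interval_id", "region_id", "gene_id"),
                     names(intervals))
  iid <- if (length(idcol) > 0L) intervals[[idcol[1]]] else
    sprintf("iv%06d", seq_len(nrow(intervals)))
  if (!"type" %in% names(variants)) {
    variants$type <- ifelse(nchar(variants$ref) == 1L &
                              nchar(variants$alt) == 1L, "snv", "indel")
  }
  n_snv <- count_points(intervals, variants[variants$type == "snv", ])
  n_indel <- count_points(intervals, variants[variants$type == "indel", ])
  len <- intervals$end - intervals$start
  data.frame(interval_id = iid, chrom = intervals$chrom,
             start = intervals$start, end = intervals$end, length = len,
             n_snv = n_snv, n_indel = n_indel,
             snv_per_kb = n_snv / len * 1000,
             indel_per_kb = n_indel / len * 1000,
             stringsAsFactors = FALSE)
}

#' @keywords internal
#' @noRd
count_points <- function(intervals, variants) {
  n <- integer(nrow(intervals))
  if (nrow(variants) == 0L) return(n)
  pos0 <- variants$pos - 1L
  for (cn in unique(intervals$chrom)) {
    idx <- which(intervals$chrom == cn)
    p <- sort(pos0[variants$chrom == cn])
    if (length(p) == 0L) next
    # count p in [start, end) via two sorted searches
    n[idx] <- findInterval(intervals$end[idx] - 1L, p) -
      findInterval(intervals$start[idx] - 1L, p)
  }
  n
}

#' Label LCRED content by the classes of assigned regions
#'
#' Per gene, collects the set of classes among the regions assigned to its
#' domain. The label is exclusive when the set is a singleton; per-class
#' `contains_<class>` indicators support the "at least one region of class
#' X" contrasts.
#'
#' @param assignments output of [assign_regions()] (only assigned rows are
#'   used).
#' @param region_classes data.frame with `region_id`, `class`.
#' @return data.frame with `gene_id`, `n_regions`, `classes`
#'   (comma-collapsed), `exclusive_class` (NA unless a singleton), and one
#'   logical `contains_<class>` column per observed class.
#' @export
label_lcred_content <- function(assignments, region_classes) {
  a <- assignments[!is.na(assignments$gene_id), , drop = FALSE]
  cls <- region_classes$class[match(a$region_id, region_classes$region_id)]
  if (anyNA(cls)) stop("region(s) without a class: ",
                       paste(utils::head(a$region_id[is.na(cls)], 3L),
                             collapse = ", "))
  sp <- split(cls, a$gene_id)
  genes <- names(sp)
  uniq <- lapply(sp, unique)
  out <- data.frame(
    gene_id = genes,
    n_regions = lengths(sp),
    classes = vapply(uniq, function(u) paste(sort(u), collapse = ","),
                     character(1)),
    exclusive_class = vapply(uniq, function(u)
      if (length(u) == 1L) u else NA_character_, character(1)),
    stringsAsFactors = FALSE)
  for (cl in sort(unique(cls))) {
    out[[paste0("contains_", cl)]] <- vapply(uniq, function(u) cl %in% u,
                                             logical(1))
  }
  rownames(out) <- NULL
  out
}

#' Variant density by chromatin-state segment
#'
#' @param segments data.frame with `chrom`, `start`, `end`, `state`;
#'   segments must not overlap.
#' @param variants variant table (see [variant_density()]).
#' @return list with `segments` (per-segment [variant_density()] output
#'   plus `state`) and `by_state` (per-state median densities and totals).
#' @export
density_by_state <- function(segments, variants) {
  validate_intervals(segments, what = "state segments")
  gr <- as_granges0(segments)
  if (sum(IRanges::width(GenomicRanges::reduce(gr))) <
      sum(IRanges::width(gr))) {
    stop("overlapping segments")
  }
  d <- variant_density(segments, variants)
  d$state <- segments$state
  agg <- do.call(rbind, lapply(split(d, d$state), function(g) {
    data.frame(state = g$state[1],
               n_segments = nrow(g),
               n_snv = sum(g$n_snv), n_indel = sum(g$n_indel),
               median_snv_per_kb = stats::median(g$snv_per_kb),
               median_indel_per_kb = stats::median(g$indel_per_kb),
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  list(segments = d, by_state = agg)
}

#' Fraction of each segment covered by an annotation
#'
#' Overlapping annotation intervals are collapsed before computing covered
#' bases, so fractions lie in \[0, 1\].
#'
#' @param segments data.frame with `chrom`, `start`, `end`.
#' @param annotation data.frame with `chrom`, `start`, `end`.
#' @return numeric vector of covered fractions, one per segment.
#' @export
annotation_coverage <- function(segments, annotation) {
  validate_intervals(segments, what = "segments")
  seg <- as_granges0(segments)
  if (nrow(annotation) == 0L) return(rep(0, nrow(segments)))
  ann <- GenomicRanges::reduce(as_granges0(annotation))
  hits <- GenomicRanges::findOverlaps(seg, ann)
  cov <- numeric(length(seg))
  if (length(hits) > 0L) {
    ov <- IRanges::width(IRanges::pintersect(
      seg[S4Vectors::queryHits(hits)], ann[S4Vectors::subjectHits(hits)]))
    agg <- tapply(ov, S4Vectors::queryHits(hits), sum)
    cov[as.integer(names(agg))] <- agg
  }
  cov / (segments$end - segments$start)
}
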