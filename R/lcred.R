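## Long-range cis-regulatory element domains (LCREDs): one non-overlapping
## regulatory territory per gene, built by the GREAT "single nearest gene"
## rule. Between adjacent TSSs the boundary is the floor midpoint; each
## side extends at most `cap_bp` from its TSS and chromosome ends clip the
## terminal domains. Strand never affects domain geometry (the rule is
## symmetric).

#' Build LCREDs from a TSS table
#'
#' Two genes with an identical TSS position collapse to the
#' lexicographically smallest `gene_id`; dropped genes are reported in the
#' `"dropped"` attribute.
#'
#' @param tss data.frame with `gene_id`, `chrom`, `tss` (0-based), and
#'   optionally `gene_name`, `strand`.
#' @param sizes data.frame (`chrom`, `length`).
#' @param cap_bp maximum extension on each side of the TSS (default 1 Mb).
#' @return data.frame with `gene_id`, `chrom`, `start`, `end`, `tss`,
#'   sorted by chromosome and position; attribute `dropped` lists genes
#'   removed by the duplicate-TSS rule.
#' @export
build_lcreds <- function(tss, sizes, cap_bp = 1000000L) {
  stopifnot(all(c("gene_id", "chrom", "tss") %in% names(tss)))
  if (anyDuplicated(tss$gene_id)) stop("TSS records must be unique per gene")
  len <- sizes$length[match(tss$chrom, sizes$chrom)]
  if (anyNA(len)) stop("unknown chromosome in TSS table")
  if (any(tss$tss < 0L | tss$tss >= len)) stop("TSS outside chromosome")
  # duplicate-TSS rule: keep lexicographically smallest gene_id
  o <- order(tss$chrom, tss$tss, tss$gene_id)
  t2 <- tss[o, , drop = FALSE]
  dup <- duplicated(t2[, c("chrom", "tss")])
  dropped <- t2$gene_id[dup]
  t2 <- t2[!dup, , drop = FALSE]
  out <- list()
  for (cn in unique(t2$chrom)) {
    g <- t2[t2$chrom == cn, , drop = FALSE]
    L <- sizes$length[sizes$chrom == cn]
    n <- nrow(g)
    p <- g$tss
    left_bound <- c(0L, as.integer((p[-n] + p[-1]) %/% 2))
    right_bound <- c(as.integer((p[-n] + p[-1]) %/% 2), L)
    start <- pmax(left_bound, p - cap_bp)
    end <- pmin(right_bound, p + cap_bp)
    out[[cn]] <- data.frame(gene_id = g$gene_id, chrom = cn,
                            start = as.integer(start), end = as.integer(end),
                            tss = p, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "dropped") <- dropped
  res
}

#' Assign regions to genes by interval midpoint
#'
#' A region belongs to the gene whose LCRED contains the region's floor
#' midpoint; midpoints outside all domains are reported unassigned. Since
#' LCREDs are half-open and disjoint, a midpoint on a shared boundary
#' belongs to the downstream domain.
#'
#' @param regions data.frame with `chrom`, `start`, `end` and optionally
#'   `region_id`.
#' @param lcreds table from [build_lcreds()].
#' @return data.frame with `region_id`, `chrom`, `midpoint`, `gene_id`
#'   (NA when unassigned).
#' @export
assign_regions <- function(regions, lcreds) {
  validate_intervals(regions, what = "regions")
  rid <- if ("region_id" %in% names(regions)) regions$region_id else
    sprintf("region%06d", seq_len(nrow(regions)))
  mid <- interval_midpoint(regions$start, regions$end)
  gene <- rep(NA_character_, nrow(regions))
  for (cn in unique(regions$chrom)) {
    l <- lcreds[lcreds$chrom == cn, , drop = FALSE]
    idx <- which(regions$chrom == cn)
    if (nrow(l) == 0L) next
    l <- l[order(l$start), , drop = FALSE]
    i <- findInterval(mid[idx], l$start)
    hit <- i > 0L & mid[idx] < l$end[pmax(i, 1L)]
    gene[idx[hit]] <- l$gene_id[i[hit]]
  }
  data.frame(region_id = rid, chrom = regions$chrom, midpoint = mid,
             gene_id = gene, stringsAsFactors = FALSE)
}

#' Bin regions by distance from the nearest TSS
#'
#' Distance is `min over TSSs of |midpoint - tss|`; bins are closed on the
#' stated upper boundaries (<= 5 kb; 5-50 kb; 50-500 kb; > 500 kb).
#'
#' @param regions data.frame with `chrom`, `start`, `end`.
#' @param tss data.frame with `chrom`, `tss`.
#' @return named integer vector of counts over the four bins.
#' @export
tss_distance_bins <- function(regions, tss) {
  if (nrow(tss) == 0L) stop("empty TSS set")
  mid <- interval_midpoint(regions$start, regions$end)
  dist <- rep(NA_real_, nrow(regions))
  for (cn in unique(regions$chrom)) {
    p <- sort(tss$tss[tss$chrom == cn])
    idx <- which(regions$chrom == cn)
    if (length(p) == 0L) next
    i <- findInterval(mid[idx], p)
    lo <- ifelse(i >= 1L, abs(mid[idx] - p[pmax(i, 1L)]), Inf)
    hi <- ifelse(i < length(p), abs(p[pmin(i + 1L, length(p))] - mid[idx]),
                 Inf)
    dist[idx] <- pmin(lo, hi)
  }
  if (anyNA(dist)) stop("no TSS on chromosome(s): ",
                        paste(unique(regions$chrom[is.na(dist)]),
                              collapse = ", "))
  bins <- cut(dist, breaks = c(-1, 5000, 50000, 500000, Inf),
              labels = c("<=5kb", "5-50kb", "50-500kb", ">500kb"))
  table(bins) |> as.integer() |>
    stats::setNames(c("<=5kb", "5-50kb", "50-500kb", ">500kb"))
}
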