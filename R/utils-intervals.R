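## Shared interval helpers. All coordinates inside the package are 0-based
## half-open [start, end) on named chromosomes (BED convention); 1-based
## formats (VCF POS, GTF) are converted at I/O boundaries only.

#' Validate a BED-like interval data frame
#'
#' Checks that `x` has `chrom`, `start`, `end` columns with
#' `0 <= start < end`, and (optionally) that intervals stay inside known
#' chromosome bounds.
#'
#' @param x data.frame with columns `chrom`, `start`, `end`.
#' @param chrom_sizes optional data.frame with columns `chrom`, `length`.
#' @param what label used in error messages.
#' @return `x`, invisibly.
#' @keywords internal
validate_intervals <- function(x, chrom_sizes = NULL, what = "intervals") {
  stopifnot(is.data.frame(x))
  miss <- setdiff(c("chrom", "start", "end"), names(x))
  if (length(miss) > 0L) {
    stop(what, " lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(x) == 0L) return(invisible(x))
  if (any(x$start < 0L)) stop(what, ": negative start coordinate")
  if (any(x$end <= x$start)) stop(what, ": end <= start (must be half-open, end > start)")
  if (!is.null(chrom_sizes)) {
    len <- chrom_sizes$length[match(x$chrom, chrom_sizes$chrom)]
    if (anyNA(len)) {
      bad <- unique(x$chrom[is.na(len)])
      stop(what, ": unknown chromosome(s): ", paste(bad, collapse = ", "))
    }
    if (any(x$end > len)) stop(what, ": interval beyond chromosome end")
  }
  invisible(x)
}

#' Convert a BED-like data frame to GRanges
#' @keywords internal
#' @noRd
as_granges0 <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

#' Convert GRanges back to a 0-based data frame
#' @keywords internal
#' @noRd
granges_to_df <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

#' Interval midpoint under half-open arithmetic
#'
#' Floor division: even-length intervals take the lower-middle base.
#'
#' @param start,end 0-based half-open bounds.
#' @return integer midpoint position (0-based).
#' @examples
#' interval_midpoint(10, 20) # 15
#' @export
interval_midpoint <- function(start, end) {
  as.integer((as.numeric(start) + as.numeric(end)) %/% 2)
}

#' Deterministic substream seed derived from a global seed
#'
#' Each generator draws from its own substream so generators can be called
#' in any order (or independently) and still be reproducible from one seed.
#'
#' @keywords internal
#' @noRd
substream_seed <- function(seed, stream) {
  streams <- c(genome = 1L, annotation = 2L, regions = 3L, variants = 4L,
               gwas = 5L, counts = 6L, midpoints = 7L)
  idx <- streams[[stream]]
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, 10L)[idx]
}
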