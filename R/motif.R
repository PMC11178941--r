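## PWM scanning within regions and variant-overlap / allelic affinity
## scoring. Scores are log2 odds sums, sum over positions of
## log2(p_base / background); a window is a hit when its score reaches
## `threshold` times the maximum achievable score. Both strands are
## scanned; a delta log-odds replaces biophysical free-energy scoring for
## substitution effects.

.base_order <- c("A", "C", "G", "T")

#' Construct a position weight matrix object
#'
#' @param matrix numeric matrix, positions x 4 (columns A, C, G, T),
#'   each row a probability distribution (sum 1 within 1e-9).
#' @param name motif name.
#' @param background length-4 background distribution (default uniform).
#' @param pseudocount added to probabilities before renormalising and
#'   taking logs (default 1e-3).
#' @return object of class `pwm` with elements `prob`, `log_odds` (log2),
#'   `max_score`, `min_score`, `width`, `consensus`.
#' @export
pwm <- function(matrix, name = "motif", background = rep(0.25, 4),
                pseudocount = 1e-3) {
  m <- as.matrix(matrix)
  if (ncol(m) != 4L) stop("PWM must have 4 columns (A, C, G, T)")
  if (any(abs(rowSums(m) - 1) > 1e-9)) {
    stop("PWM rows must sum to 1 (within 1e-9)")
  }
  if (abs(sum(background) - 1) > 1e-9) stop("background must sum to 1")
  colnames(m) <- .base_order
  p <- (m + pseudocount) / (1 + 4 * pseudocount)
  lo <- log2(sweep(p, 2L, background, "/"))
  structure(list(prob = m, log_odds = lo,
                 max_score = sum(apply(lo, 1L, max)),
                 min_score = sum(apply(lo, 1L, min)),
                 width = nrow(m),
                 consensus = paste(.base_order[apply(m, 1L, which.max)],
                                   collapse = ""),
                 background = background, name = name,
                 pseudocount = pseudocount), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("<pwm>", x$name, "width", x$width, "consensus", x$consensus,
      sprintf("max log2-odds %.2f\n", x$max_score))
  invisible(x)
}

#' Read HOMER-style motif files
#'
#' Accepts the `.motif` layout: a header line `> consensus name
#' log-odds-threshold`, followed by one row of four probabilities (A C G
#' T) per motif position.
#'
#' @param path motif file (may contain several motifs).
#' @param ... passed to [pwm()] (`background`, `pseudocount`).
#' @return named list of `pwm` objects.
#' @export
read_homer_motifs <- function(path, ...) {
  lines <- trimws(readLines(path))
  lines <- lines[lines != ""]
  starts <- which(startsWith(lines, ">"))
  if (length(starts) == 0L) stop("no motif headers ('>') in ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  out <- list()
  for (i in seq_along(starts)) {
    hdr <- strsplit(sub("^>\\s*", "", lines[starts[i]]), "\\s+")[[1]]
    name <- if (length(hdr) >= 2L) hdr[2] else hdr[1]
    rows <- lines[(starts[i] + 1L):ends[i]]
    m <- do.call(rbind, lapply(strsplit(rows, "\\s+"), as.numeric))
    out[[name]] <- pwm(m, name = name, ...)
  }
  out
}

# encode a DNA string as integers 1..4 (A C G T), NA otherwise
#' @noRd
encode_dna <- function(s) {
  match(strsplit(toupper(s), "")[[1]], .base_order)
}

#' @noRd
revcomp_str <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# score every window of an encoded sequence against a log-odds matrix;
# windows containing non-ACGT bases score -Inf
#' @noRd
score_windows <- function(code, lo) {
  W <- nrow(lo)
  n <- length(code) - W + 1L
  if (n < 1L) return(numeric(0))
  vapply(seq_len(n), function(off) {
    idx <- code[off:(off + W - 1L)]
    if (anyNA(idx)) return(-Inf)
    sum(lo[cbind(seq_len(W), idx)])
  }, numeric(1))
}

#' Scan a PWM over regions of a genome
#'
#' Both strands are scanned; a window is reported when its log2-odds score
#' is at least `threshold * max_score`. Coordinates are genomic, 0-based
#' half-open; reverse-strand hits are reported on the forward coordinate
#' system. Regions shorter than the PWM width are skipped with a warning.
#'
#' @param genome named [Biostrings::DNAStringSet].
#' @param regions data.frame with `chrom`, `start`, `end` and optionally
#'   `region_id`.
#' @param pwm a [pwm()] object.
#' @param threshold fraction of the maximum achievable score in (0, 1\].
#' @return data.frame with `region_id`, `pwm`, `chrom`, `start`, `end`,
#'   `strand`, `score`.
#' @export
scan_pwm <- function(genome, regions, pwm, threshold = 0.8) {
  stopifnot(inherits(pwm, "pwm"))
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  validate_intervals(regions, chrom_sizes = chrom_sizes(genome),
                     what = "scan regions")
  rid <- if ("region_id" %in% names(regions)) regions$region_id else
    sprintf("region%06d", seq_len(nrow(regions)))
  W <- pwm$width
  cutoff <- threshold * pwm$max_score
  short <- which(regions$end - regions$start < W)
  if (length(short) > 0L) {
    warning(length(short), " region(s) shorter than PWM width skipped")
  }
  hits <- list()
  for (i in setdiff(seq_len(nrow(regions)), short)) {
    s <- as.character(Biostrings::extractAt(
      genome[[regions$chrom[i]]],
      IRanges::IRanges(regions$start[i] + 1L, regions$end[i])))
    L <- nchar(s)
    fwd <- score_windows(encode_dna(s), pwm$log_odds)
    rev <- score_windows(encode_dna(revcomp_str(s)), pwm$log_odds)
    f_at <- which(fwd >= cutoff)
    r_at <- which(rev >= cutoff)
    if (length(f_at) > 0L) {
      hits[[length(hits) + 1L]] <- data.frame(
        region_id = rid[i], pwm = pwm$name, chrom = regions$chrom[i],
        start = regions$start[i] + f_at - 1L,
        end = regions$start[i] + f_at - 1L + W,
        strand = "+", score = fwd[f_at], stringsAsFactors = FALSE)
    }
    if (length(r_at) > 0L) {
      # offset j on the reverse complement corresponds to forward
      # coordinates [L - j - W + 1, L - j + 1) within the region
      hits[[length(hits) + 1L]] <- data.frame(
        region_id = rid[i], pwm = pwm$name, chrom = regions$chrom[i],
        start = regions$start[i] + L - r_at - W + 1L,
        end = regions$start[i] + L - r_at + 1L,
        strand = "-", score = rev[r_at], stringsAsFactors = FALSE)
    }
  }
  out <- if (length(hits) > 0L) do.call(rbind, hits) else
    data.frame(region_id = character(0), pwm = character(0),
               chrom = character(0), start = integer(0), end = integer(0),
               strand = character(0), score = numeric(0),
               stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-region motif and motif-variant overlap flags
#'
#' A region `has_motif` when it contains at least one hit; among
#' motif-containing regions, `has_overlap` when at least one variant
#' position falls inside at least one hit (half-open intersection). The
#' overlap fraction follows the published nesting: it is computed over
#' motif-containing regions only.
#'
#' @param hits output of [scan_pwm()] (possibly concatenated over PWMs).
#' @param variants variant table (`chrom`, `pos` 1-based).
#' @param regions data.frame with `chrom`, `start`, `end`, `region_id`.
#' @return list with `regions` (per-region flags) and `summary`
#'   (`n_regions`, `n_with_motif`, `frac_with_motif`, `n_with_overlap`,
#'   `frac_overlap_of_motif`).
#' @export
motif_variant_overlap <- function(hits, variants, regions) {
  rid <- if ("region_id" %in% names(regions)) regions$region_id else
    sprintf("region%06d", seq_len(nrow(regions)))
  has_motif <- rid %in% hits$region_id
  overlap_hit <- if (nrow(hits) > 0L && nrow(variants) > 0L) {
    counts <- count_points(hits, variants)
    unique(hits$region_id[counts > 0L])
  } else character(0)
  has_overlap <- has_motif & (rid %in% overlap_hit)
  n_motif <- sum(has_motif)
  n_overlap <- sum(has_overlap)
  list(regions = data.frame(region_id = rid, has_motif = has_motif,
                            has_overlap = has_overlap,
                            stringsAsFactors = FALSE),
       summary = list(n_regions = length(rid), n_with_motif = n_motif,
                      frac_with_motif = n_motif / length(rid),
                      n_with_overlap = n_overlap,
                      frac_overlap_of_motif =
                        if (n_motif > 0L) n_overlap / n_motif else NA_real_))
}

#' Allelic affinity change of an SNV inside a motif hit
#'
#' Delta is the hit's log2-odds with the ALT base minus with the REF base
#' at the variant's offset; reverse-strand hits complement the alleles and
#' mirror the offset. Negative delta classifies the substitution as
#' disruptive. Indels are rejected (they are reported overlap-only).
#'
#' @param pwm the [pwm()] object that produced the hit.
#' @param hit one row of [scan_pwm()] output.
#' @param variant one variant row (`chrom`, `pos` 1-based, `ref`, `alt`).
#' @return list with `delta`, `disrupted`, `offset` (0-based within the
#'   motif), `ref`, `alt`.
#' @export
delta_affinity <- function(pwm, hit, variant) {
  stopifnot(inherits(pwm, "pwm"))
  if (nchar(variant$ref) != 1L || nchar(variant$alt) != 1L) {
    stop("delta_affinity requires an SNV (indels are overlap-only)")
  }
  pos0 <- variant$pos - 1L
  if (variant$chrom != hit$chrom || pos0 < hit$start || pos0 >= hit$end) {
    stop("variant position lies outside the motif hit")
  }
  if (hit$strand == "-") {
    offset <- hit$end - 1L - pos0
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    ref <- comp[[variant$ref]]
    alt <- comp[[variant$alt]]
  } else {
    offset <- pos0 - hit$start
    ref <- variant$ref
    alt <- variant$alt
  }
  lo <- pwm$log_odds
  delta <- lo[offset + 1L, alt] - lo[offset + 1L, ref]
  list(delta = unname(delta), disrupted = unname(delta < 0),
       offset = offset, ref = ref, alt = alt)
}
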