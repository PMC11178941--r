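## File-format readers and writers. FASTA goes through Biostrings; BED, VCF
## and GTF are plain text written/read here with explicit coordinate
## conversions (BED 0-based half-open; VCF and GTF 1-based).

#' Read a FASTA genome
#'
#' @param path FASTA file.
#' @return named [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  # keep only the first whitespace-delimited token of each header
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' Write a FASTA genome
#'
#' @param seqs named [Biostrings::DNAStringSet] (or named character vector).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, filepath = path, width = 70L)
  invisible(path)
}

#' Chromosome sizes of a genome
#'
#' @param seqs named [Biostrings::DNAStringSet].
#' @return data.frame with columns `chrom`, `length`.
#' @export
chrom_sizes <- function(seqs) {
  data.frame(chrom = names(seqs), length = Biostrings::width(seqs),
             stringsAsFactors = FALSE)
}

#' Read a BED file (BED3/BED4/BED6)
#'
#' Coordinates are kept 0-based half-open. Column 4 becomes `name`,
#' column 5 `score`, column 6 `strand` when present.
#'
#' @param path BED file (no header).
#' @return data.frame with columns `chrom`, `start`, `end` (+ optional).
#' @export
read_bed <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE, comment.char = "#",
                         quote = "")
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  names(x) <- cols[seq_len(min(ncol(x), 6L))]
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  validate_intervals(x, what = basename(path))
  x
}

#' Write a BED file
#'
#' @param x data.frame with `chrom`, `start`, `end` and optionally `name`,
#'   `score`, `strand`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x, what = "BED output")
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(x))
  # BED columns are positional: stop at the first absent one
  keep <- character(0)
  for (cn in c("chrom", "start", "end", "name", "score", "strand")) {
    if (cn %in% cols) keep <- c(keep, cn) else break
  }
  utils::write.table(x[, keep, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write variants as VCF 4.2
#'
#' @param variants data.frame with columns `chrom`, `pos` (1-based position
#'   of the first REF base), `ref`, `alt`, and optionally `id`.
#' @param path output file.
#' @param contigs optional data.frame (`chrom`, `length`) for contig headers.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path, contigs = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  writeLines("##source=epivar", con)
  if (!is.null(contigs)) {
    writeLines(sprintf("##contig=<ID=%s,length=%d>",
                       contigs$chrom, contigs$length), con)
  }
  writeLines("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO", con)
  if (nrow(variants) > 0L) {
    o <- order(variants$chrom, variants$pos)
    v <- variants[o, , drop = FALSE]
    id <- if ("id" %in% names(v)) v$id else rep(".", nrow(v))
    writeLines(sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.",
                       v$chrom, as.integer(v$pos), id, v$ref, v$alt), con)
  }
  invisible(path)
}

#' Read a VCF file into a variant table
#'
#' Multi-allelic rows are split into one record per ALT allele. Unsorted
#' input is sorted on ingest with a warning.
#'
#' @param path VCF 4.x file (uncompressed).
#' @return data.frame with columns `chrom`, `pos` (1-based), `id`, `ref`,
#'   `alt`, `type` (`"snv"` or `"indel"`).
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0L) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      id = character(0), ref = character(0),
                      alt = character(0), type = character(0),
                      stringsAsFactors = FALSE))
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 8L)) {
    stop("malformed VCF line(s): ",
         paste(which(nf < 8L)[seq_len(min(5L, sum(nf < 8L)))], collapse = ", "))
  }
  m <- matrix(unlist(lapply(f, `[`, 1:8)), ncol = 8L, byrow = TRUE)
  v <- data.frame(chrom = m[, 1L], pos = as.integer(m[, 2L]), id = m[, 3L],
                  ref = m[, 4L], alt = m[, 5L], stringsAsFactors = FALSE)
  # split multi-allelic ALT cells
  alts <- strsplit(v$alt, ",", fixed = TRUE)
  v <- v[rep(seq_len(nrow(v)), lengths(alts)), , drop = FALSE]
  v$alt <- unlist(alts)
  o <- order(v$chrom, v$pos)
  if (!identical(o, seq_len(nrow(v)))) {
    warning("VCF rows were not coordinate-sorted; sorted on ingest")
    v <- v[o, , drop = FALSE]
  }
  v$type <- ifelse(nchar(v$ref) == 1L & nchar(v$alt) == 1L, "snv", "indel")
  rownames(v) <- NULL
  v
}

#' Write a minimal gene GTF
#'
#' One `gene` feature per gene. GTF is 1-based, end-inclusive; the stored
#' interval spans `gene_len` bases downstream of the TSS (strand-aware) so
#' that the TSS is recoverable as `start` (+ strand) or `end` (- strand).
#'
#' @param tss data.frame with `gene_id`, `gene_name`, `chrom`, `tss`
#'   (0-based), `strand`.
#' @param path output file.
#' @param sizes data.frame (`chrom`, `length`) used to clip gene bodies.
#' @param gene_len nominal gene-body length in bp.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(tss, path, sizes, gene_len = 1000L) {
  len <- sizes$length[match(tss$chrom, sizes$chrom)]
  fwd <- tss$strand == "+"
  start1 <- ifelse(fwd, tss$tss + 1L, pmax(1L, tss$tss + 2L - gene_len))
  end1 <- ifelse(fwd, pmin(len, tss$tss + gene_len), tss$tss + 1L)
  attrs <- sprintf('gene_id "%s"; gene_name "%s";', tss$gene_id, tss$gene_name)
  lines <- sprintf("%s\tepivar\tgene\t%d\t%d\t.\t%s\t.\t%s",
                   tss$chrom, as.integer(start1), as.integer(end1),
                   tss$strand, attrs)
  writeLines(lines, path)
  invisible(path)
}

#' Read gene records from a GTF file
#'
#' Uses `rtracklayer` when available (the canonical GFF/GTF parser),
#' falling back to a strict 9-column reader for the `gene` features this
#' package writes. Returns 0-based TSS positions.
#'
#' @param path GTF file.
#' @return data.frame with `gene_id`, `gene_name`, `chrom`, `tss` (0-based),
#'   `strand`.
#' @export
read_gtf_tss <- function(path) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    g <- rtracklayer::import(path, format = "gtf")
    g <- g[g$type == "gene"]
    chrom <- as.character(GenomicRanges::seqnames(g))
    strand <- as.character(GenomicRanges::strand(g))
    tss0 <- ifelse(strand == "-", GenomicRanges::end(g) - 1L,
                   GenomicRanges::start(g) - 1L)
    gene_name <- if (!is.null(g$gene_name)) g$gene_name else g$gene_id
    out <- data.frame(gene_id = g$gene_id, gene_name = gene_name,
                      chrom = chrom, tss = as.integer(tss0), strand = strand,
                      stringsAsFactors = FALSE)
    return(out)
  }
  x <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                         stringsAsFactors = FALSE, comment.char = "#")
  x <- x[x[[3]] == "gene", , drop = FALSE]
  gid <- sub('.*gene_id "([^"]+)".*', "\\1", x[[9]])
  gname <- ifelse(grepl('gene_name "', x[[9]]),
                  sub('.*gene_name "([^"]+)".*', "\\1", x[[9]]), gid)
  tss0 <- ifelse(x[[7]] == "-", as.integer(x[[5]]) - 1L,
                 as.integer(x[[4]]) - 1L)
  data.frame(gene_id = gid, gene_name = gname, chrom = x[[1]],
             tss = as.integer(tss0), strand = x[[7]],
             stringsAsFactors = FALSE)
}

#' Write a TSV with a header row
#' @param x data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a TSV with a header row
#' @param path input file.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "")
}
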