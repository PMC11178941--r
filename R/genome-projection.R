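## Variant-incorporated consensus genome, offset map between the two
## coordinate systems, interval lifting, and UCSC chain file I/O.
## SNVs substitute in place and never shift coordinates; only indels
## create new aligned blocks. VCF-style indels share their first (anchor)
## base between REF and ALT; the aligned prefix of each variant is
## min(len(ref), len(alt)) bases.

#' Validate a variant table against a reference genome
#'
#' Checks REF alleles against the genome and rejects overlapping REF
#' footprints.
#'
#' @param variants data.frame with `chrom`, `pos` (1-based), `ref`, `alt`.
#' @param genome named [Biostrings::DNAStringSet].
#' @return the variants, coordinate-sorted, invisibly.
#' @export
validate_variants <- function(variants, genome) {
  v <- variants[order(variants$chrom, variants$pos), , drop = FALSE]
  for (cn in unique(v$chrom)) {
    if (!cn %in% names(genome)) stop("unknown chromosome: ", cn)
    idx <- which(v$chrom == cn)
    ends <- v$pos[idx] + nchar(v$ref[idx]) - 1L
    if (any(ends > length(genome[[cn]]))) {
      bad <- idx[which(ends > length(genome[[cn]]))[1]]
      stop("variant beyond chromosome end at ", cn, ":", v$pos[bad])
    }
    obs <- as.character(Biostrings::extractAt(
      genome[[cn]], IRanges::IRanges(v$pos[idx], ends)))
    mism <- which(obs != v$ref[idx])
    if (length(mism) > 0L) {
      bad <- idx[mism[1]]
      stop("REF mismatch at ", cn, ":", v$pos[bad], " (expected ",
           v$ref[bad], ", genome has ", obs[mism[1]], ")")
    }
    if (length(idx) > 1L) {
      if (any(v$pos[idx][-1] <= ends[-length(ends)])) {
        bad <- idx[which(v$pos[idx][-1] <= ends[-length(ends)])[1] + 1L]
        stop("overlapping variants rejected at ", cn, ":", v$pos[bad])
      }
    }
  }
  invisible(v)
}

#' Build a consensus genome and its offset map
#'
#' Applies every variant exactly once via [Biostrings::replaceAt] and
#' records the aligned blocks relating reference (src) and consensus (dst)
#' coordinates. The length identity
#' `length(consensus) = length(ref) + sum(len(alt) - len(ref))` holds
#' exactly.
#'
#' @param genome named [Biostrings::DNAStringSet] reference.
#' @param variants data.frame with `chrom`, `pos` (1-based), `ref`, `alt`;
#'   REF-validated, sorted, non-overlapping (checked here).
#' @return list with `consensus` ([Biostrings::DNAStringSet]) and `map`
#'   (an `offset_map`).
#' @export
build_consensus <- function(genome, variants) {
  v <- validate_variants(variants, genome)
  cons <- genome
  blocks <- list()
  for (cn in names(genome)) {
    idx <- which(v$chrom == cn)
    src_len <- length(genome[[cn]])
    if (length(idx) > 0L) {
      at <- IRanges::IRanges(v$pos[idx], v$pos[idx] + nchar(v$ref[idx]) - 1L)
      cons[[cn]] <- Biostrings::replaceAt(genome[[cn]], at = at,
                                          value = v$alt[idx])
    }
    # aligned blocks: break only at indels
    ind <- idx[nchar(v$ref[idx]) != nchar(v$alt[idx])]
    src_cursor <- 0L
    d <- 0L  # dst - src offset at the current cursor
    b <- list()
    for (j in ind) {
      p <- v$pos[j] - 1L          # 0-based first REF base
      r <- nchar(v$ref[j])
      a <- nchar(v$alt[j])
      m <- min(r, a)              # aligned (anchor-shared) prefix
      blk_len <- p + m - src_cursor
      if (blk_len > 0L) {
        b[[length(b) + 1L]] <- c(src_cursor, src_cursor + d, blk_len)
      }
      src_cursor <- p + r
      d <- d + a - r
    }
    if (src_len - src_cursor > 0L) {
      b[[length(b) + 1L]] <- c(src_cursor, src_cursor + d, src_len - src_cursor)
    }
    if (length(b) > 0L) {
      m <- do.call(rbind, b)
      blocks[[cn]] <- data.frame(chrom = cn, src_start = m[, 1],
                                 dst_start = m[, 2], length = m[, 3])
    }
  }
  blocks <- if (length(blocks) > 0L) do.call(rbind, blocks) else
    data.frame(chrom = character(0), src_start = integer(0),
               dst_start = integer(0), length = integer(0))
  rownames(blocks) <- NULL
  map <- offset_map(blocks,
                    src_sizes = chrom_sizes(genome),
                    dst_sizes = chrom_sizes(cons))
  list(consensus = cons, map = map)
}

#' Construct an offset map
#'
#' @param blocks data.frame with `chrom`, `src_start`, `dst_start`,
#'   `length` (all 0-based).
#' @param src_sizes,dst_sizes data.frames (`chrom`, `length`) for the two
#'   coordinate systems.
#' @return object of class `offset_map`.
#' @export
offset_map <- function(blocks, src_sizes, dst_sizes) {
  stopifnot(all(c("chrom", "src_start", "dst_start", "length") %in%
                  names(blocks)))
  if (nrow(blocks) > 0L) {
    if (any(blocks$length <= 0)) stop("offset map blocks must have length > 0")
    o <- order(blocks$chrom, blocks$src_start)
    blocks <- blocks[o, , drop = FALSE]
    for (cn in unique(blocks$chrom)) {
      idx <- which(blocks$chrom == cn)
      if (length(idx) > 1L) {
        se <- blocks$src_start[idx] + blocks$length[idx]
        de <- blocks$dst_start[idx] + blocks$length[idx]
        if (any(blocks$src_start[idx][-1] < se[-length(se)]) ||
            any(blocks$dst_start[idx][-1] < de[-length(de)])) {
          stop("offset map blocks overlap on ", cn)
        }
      }
    }
  }
  rownames(blocks) <- NULL
  structure(list(blocks = blocks, src_sizes = src_sizes,
                 dst_sizes = dst_sizes),
            class = "offset_map")
}

#' Identity offset map (no variants)
#'
#' @param sizes data.frame (`chrom`, `length`).
#' @return `offset_map` with one identity block per chromosome.
#' @export
identity_offset_map <- function(sizes) {
  offset_map(data.frame(chrom = sizes$chrom, src_start = 0L, dst_start = 0L,
                        length = sizes$length),
             src_sizes = sizes, dst_sizes = sizes)
}

#' @export
print.offset_map <- function(x, ...) {
  cat("<offset_map>", nrow(x$blocks), "blocks on",
      length(unique(x$blocks$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' Lift intervals through an offset map
#'
#' Endpoints are projected through the aligned blocks. An endpoint falling
#' in a deleted (unaligned) segment snaps inward to the nearest projectable
#' base and the lift is flagged `"partial"`; intervals with no projectable
#' base are `"unmapped"`. With `strict = TRUE`, partial lifts are reported
#' as unmapped (mimicking default liftOver, which discards them).
#'
#' @param map `offset_map`.
#' @param intervals data.frame with `chrom`, `start`, `end` (0-based
#'   half-open) plus any extra columns, carried through.
#' @param direction `"src2dst"` or `"dst2src"`.
#' @param strict drop partial lifts.
#' @return the input data.frame with `start`, `end` replaced by lifted
#'   coordinates and a `lift_status` column (`"exact"`, `"partial"`,
#'   `"unmapped"`); unmapped rows keep NA coordinates.
#' @export
lift_intervals <- function(map, intervals, direction = c("src2dst", "dst2src"),
                           strict = FALSE) {
  direction <- match.arg(direction)
  stopifnot(inherits(map, "offset_map"))
  blocks <- map$blocks
  if (direction == "dst2src") {
    blocks <- data.frame(chrom = blocks$chrom, src_start = blocks$dst_start,
                         dst_start = blocks$src_start, length = blocks$length)
    sizes <- map$dst_sizes
  } else {
    sizes <- map$src_sizes
  }
  validate_intervals(intervals, chrom_sizes = sizes, what = "lift input")
  n <- nrow(intervals)
  out_start <- rep(NA_integer_, n)
  out_end <- rep(NA_integer_, n)
  status <- rep("unmapped", n)
  for (cn in unique(intervals$chrom)) {
    if (!cn %in% sizes$chrom) stop("unknown chromosome: ", cn)
    b <- blocks[blocks$chrom == cn, , drop = FALSE]
    b <- b[order(b$src_start), , drop = FALSE]
    idx <- which(intervals$chrom == cn)
    if (nrow(b) == 0L) next
    bs <- b$src_start
    be <- b$src_start + b$length
    # project a 0-based position; snap = +1 (snap forward) or -1 (backward)
    project <- function(x, snap) {
      i <- findInterval(x, bs)
      snapped <- FALSE
      if (i == 0L || x >= be[i]) {
        snapped <- TRUE
        if (snap > 0) {
          i <- i + 1L
          if (i > nrow(b)) return(NULL)
          x <- bs[i]
        } else {
          if (i == 0L) return(NULL)
          x <- be[i] - 1L
        }
      }
      list(pos = b$dst_start[i] + (x - bs[i]), snapped = snapped)
    }
    for (k in idx) {
      s <- project(intervals$start[k], +1)
      e <- project(intervals$end[k] - 1L, -1)
      if (is.null(s) || is.null(e) || e$pos < s$pos) next
      out_start[k] <- s$pos
      out_end[k] <- e$pos + 1L
      status[k] <- if (s$snapped || e$snapped) "partial" else "exact"
    }
  }
  if (strict) {
    drop <- status == "partial"
    out_start[drop] <- NA_integer_
    out_end[drop] <- NA_integer_
    status[drop] <- "unmapped"
  }
  out <- intervals
  out$start <- out_start
  out$end <- out_end
  out$lift_status <- status
  out
}

#' Write an offset map as a UCSC chain file
#'
#' One chain per chromosome; block lines carry `size dt dq` with a final
#' size-only line, following the UCSC chain spec. `parse(write(map))`
#' recovers the map exactly (see [read_chain()]).
#'
#' @param map `offset_map`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_chain <- function(map, path) {
  stopifnot(inherits(map, "offset_map"))
  con <- file(path, "w")
  on.exit(close(con))
  id <- 0L
  for (cn in map$src_sizes$chrom) {
    b <- map$blocks[map$blocks$chrom == cn, , drop = FALSE]
    if (nrow(b) == 0L) next
    b <- b[order(b$src_start), , drop = FALSE]
    id <- id + 1L
    t_size <- map$src_sizes$length[map$src_sizes$chrom == cn]
    q_size <- map$dst_sizes$length[map$dst_sizes$chrom == cn]
    t_start <- b$src_start[1]
    t_end <- b$src_start[nrow(b)] + b$length[nrow(b)]
    q_start <- b$dst_start[1]
    q_end <- b$dst_start[nrow(b)] + b$length[nrow(b)]
    writeLines(sprintf("chain 1000 %s %d + %d %d %s %d + %d %d %d",
                       cn, t_size, t_start, t_end, cn, q_size,
                       q_start, q_end, id), con)
    if (nrow(b) > 1L) {
      dt <- b$src_start[-1] - (b$src_start[-nrow(b)] + b$length[-nrow(b)])
      dq <- b$dst_start[-1] - (b$dst_start[-nrow(b)] + b$length[-nrow(b)])
      writeLines(sprintf("%d\t%d\t%d", b$length[-nrow(b)], dt, dq), con)
    }
    writeLines(sprintf("%d", b$length[nrow(b)]), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Parse a UCSC chain file into an offset map
#'
#' Supports the plus-strand, same-name chains written by [write_chain()].
#'
#' @param path chain file.
#' @return `offset_map`.
#' @export
read_chain <- function(path) {
  lines <- readLines(path)
  blocks <- list()
  src_sizes <- list()
  dst_sizes <- list()
  i <- 1L
  while (i <= length(lines)) {
    ln <- lines[i]
    if (!startsWith(ln, "chain")) { i <- i + 1L; next }
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    chrom <- f[3]
    src_sizes[[chrom]] <- as.integer(f[4])
    dst_sizes[[f[8]]] <- as.integer(f[9])
    src_cur <- as.integer(f[6])
    dst_cur <- as.integer(f[11])
    i <- i + 1L
    repeat {
      bf <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      if (length(bf) == 0L || bf[1] == "") break
      size <- as.integer(bf[1])
      blocks[[length(blocks) + 1L]] <-
        data.frame(chrom = chrom, src_start = src_cur, dst_start = dst_cur,
                   length = size)
      if (length(bf) == 3L) {
        src_cur <- src_cur + size + as.integer(bf[2])
        dst_cur <- dst_cur + size + as.integer(bf[3])
        i <- i + 1L
      } else {
        i <- i + 1L
        break
      }
    }
  }
  sz <- function(lst) data.frame(chrom = names(lst),
                                 length = unlist(lst, use.names = FALSE),
                                 stringsAsFactors = FALSE)
  offset_map(do.call(rbind, blocks), src_sizes = sz(src_sizes),
             dst_sizes = sz(dst_sizes))
}
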