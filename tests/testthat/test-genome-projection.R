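# Consensus construction, offset maps, interval lifting, and chain I/O.

test_that("empty variant set returns the reference and an identity map", {
  g <- toy_genome(c(chr1 = "ACGTACGTAC", chr2 = "GGGGCCCC"))
  res <- build_consensus(g, data.frame(chrom = character(0),
                                       pos = integer(0), ref = character(0),
                                       alt = character(0)))
  expect_identical(as.character(res$consensus), as.character(g))
  expect_equal(nrow(res$map$blocks), 2L)
  expect_equal(res$map$blocks$length, c(10L, 8L))
  expect_equal(res$map$blocks$src_start, res$map$blocks$dst_start)
})

test_that("worked substitution + deletion example edits the string", {
  # ACGTACGT with C>T at position 2 and TA>T at position 4:
  # manual string edit gives ATGTCGT (length 7)
  g <- toy_genome(c(chr1 = "ACGTACGT"))
  v <- data.frame(chrom = "chr1", pos = c(2L, 4L), ref = c("C", "TA"),
                  alt = c("T", "T"))
  res <- build_consensus(g, v)
  expect_identical(as.character(res$consensus[["chr1"]]), "ATGTCGT")
  expect_equal(length(res$consensus[["chr1"]]), 7L)
  # blocks: [0,4) identity, then [5,8) shifted by -1
  expect_equal(res$map$blocks$src_start, c(0L, 5L))
  expect_equal(res$map$blocks$dst_start, c(0L, 4L))
  expect_equal(res$map$blocks$length, c(4L, 3L))
})

test_that("REF mismatches and overlapping variants are rejected by name", {
  g <- toy_genome(c(chr1 = "ACGTACGT"))
  expect_error(build_consensus(g, data.frame(chrom = "chr1", pos = 2L,
                                             ref = "G", alt = "T")),
               "REF mismatch at chr1:2")
  ov <- data.frame(chrom = "chr1", pos = c(2L, 3L), ref = c("CG", "G"),
                   alt = c("C", "A"))
  expect_error(build_consensus(g, ov), "overlapping")
})

test_that("consensus length identity holds for random variant sets", {
  set.seed(101)
  for (rep in 1:10) {
    seq <- random_dna(2000L)
    g <- toy_genome(c(chr1 = seq))
    v <- random_variants(seq, n = 15L)
    res <- build_consensus(g, v)
    expect_equal(length(res$consensus[["chr1"]]),
                 2000L + sum(nchar(v$alt) - nchar(v$ref)))
  }
})

test_that("lifting matches a per-base projection oracle on toy genomes", {
  set.seed(202)
  n_checked <- 0L
  for (rep in 1:10) {
    L <- sample(2000:10000, 1L)
    seq <- random_dna(L)
    g <- toy_genome(c(chr1 = seq))
    v <- random_variants(seq, n = 25L)
    res <- build_consensus(g, v)
    proj <- perbase_projection(L, v)
    starts <- sample.int(L - 50L, 60L)
    ivs <- data.frame(chrom = "chr1", start = starts - 1L,
                      end = starts - 1L + sample(1:50, 60L, TRUE))
    lifted <- lift_intervals(res$map, ivs)
    for (i in seq_len(nrow(ivs))) {
      oracle <- oracle_lift(proj, ivs$start[i], ivs$end[i])
      expect_identical(lifted$lift_status[i], oracle$status)
      if (oracle$status != "unmapped") {
        expect_equal(lifted$start[i], oracle$start)
        expect_equal(lifted$end[i], oracle$end)
      }
      n_checked <- n_checked + 1L
    }
  }
  expect_gte(n_checked, 500L)
})

test_that("intervals upstream of indels lift unchanged; downstream shift", {
  g <- toy_genome(c(chr1 = "ACGTACGTACGTACGTACGT"))
  # single 1 bp deletion at pos 10 (ref "CG" -> "C")
  v <- data.frame(chrom = "chr1", pos = 10L, ref = "CG", alt = "C")
  res <- build_consensus(g, v)
  up <- lift_intervals(res$map, data.frame(chrom = "chr1", start = 0L,
                                           end = 8L))
  expect_equal(up$start, 0L)
  expect_equal(up$end, 8L)
  expect_equal(up$lift_status, "exact")
  down <- lift_intervals(res$map, data.frame(chrom = "chr1", start = 12L,
                                             end = 18L))
  expect_equal(down$start, 11L)
  expect_equal(down$end, 17L)
  expect_equal(down$lift_status, "exact")
})

test_that("round-trip lifting of indel-free intervals is the identity", {
  set.seed(303)
  seq <- random_dna(5000L)
  g <- toy_genome(c(chr1 = seq))
  v <- random_variants(seq, n = 20L)
  res <- build_consensus(g, v)
  starts <- sample.int(4950L, 1000L, replace = TRUE)
  ivs <- data.frame(chrom = "chr1", start = starts - 1L,
                    end = starts - 1L + sample(1:40, 1000L, TRUE))
  there <- lift_intervals(res$map, ivs)
  exact <- which(there$lift_status == "exact")
  expect_gt(length(exact), 0L)
  back <- lift_intervals(res$map, there[exact, c("chrom", "start", "end")],
                         direction = "dst2src")
  expect_equal(back$start, ivs$start[exact])
  expect_equal(back$end, ivs$end[exact])
  expect_true(all(back$lift_status == "exact"))
})

test_that("strict mode discards partial lifts", {
  g <- toy_genome(c(chr1 = "ACGTACGTACGTACGTACGT"))
  v <- data.frame(chrom = "chr1", pos = 5L, ref = "ACGTA", alt = "A")
  res <- build_consensus(g, v)
  iv <- data.frame(chrom = "chr1", start = 6L, end = 12L)  # starts in gap
  loose <- lift_intervals(res$map, iv)
  expect_equal(loose$lift_status, "partial")
  strict <- lift_intervals(res$map, iv, strict = TRUE)
  expect_equal(strict$lift_status, "unmapped")
  expect_true(is.na(strict$start))
})

test_that("chain files round-trip through write and parse", {
  # identity map: single block of the chromosome length
  sizes <- data.frame(chrom = "chr1", length = 1000L)
  idm <- identity_offset_map(sizes)
  f <- tempfile(fileext = ".chain")
  write_chain(idm, f)
  first <- readLines(f)[1]
  expect_match(first, "^chain 1000 chr1 1000 \\+ 0 1000 chr1 1000 \\+ 0 1000 1$")
  back <- read_chain(f)
  expect_equal(back$blocks, idm$blocks)
  # worked deletion example round-trips with the expected block structure
  g <- toy_genome(c(chr1 = "ACGTACGT"))
  v <- data.frame(chrom = "chr1", pos = c(2L, 4L), ref = c("C", "TA"),
                  alt = c("T", "T"))
  map <- build_consensus(g, v)$map
  write_chain(map, f)
  lines <- readLines(f)
  expect_equal(lines[2], "4\t1\t0")
  expect_equal(read_chain(f)$blocks, map$blocks)
  # property: write-parse identity over random indel maps
  set.seed(404)
  for (rep in 1:20) {
    seq <- random_dna(3000L)
    gg <- toy_genome(c(chr1 = seq))
    vv <- random_variants(seq, n = 12L)
    m <- build_consensus(gg, vv)$map
    write_chain(m, f)
    b <- read_chain(f)
    expect_equal(b$blocks, m$blocks)
    expect_equal(b$src_sizes, m$src_sizes)
    expect_equal(b$dst_sizes, m$dst_sizes)
  }
})

test_that("written chains drive rtracklayer liftOver to the same result", {
  set.seed(505)
  seq <- random_dna(4000L)
  g <- toy_genome(c(chr1 = seq))
  v <- random_variants(seq, n = 15L)
  res <- build_consensus(g, v)
  f <- tempfile(fileext = ".chain")
  write_chain(res$map, f)
  ch <- rtracklayer::import.chain(f)
  starts <- sample.int(3950L, 200L, replace = TRUE)
  ivs <- data.frame(chrom = "chr1", start = starts - 1L,
                    end = starts - 1L + sample(5:30, 200L, TRUE))
  ours <- lift_intervals(res$map, ivs)
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(ivs$start + 1L,
                                                        ivs$end))
  lifted <- rtracklayer::liftOver(gr, ch)
  # rtracklayer splits across gaps; compare on our exact lifts, where the
  # result must be one contiguous range with identical coordinates
  for (i in which(ours$lift_status == "exact")) {
    li <- GenomicRanges::reduce(lifted[[i]], min.gapwidth = 1e9)
    expect_equal(GenomicRanges::start(li) - 1L, ours$start[i])
  }
})
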