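# PWM construction, scanning, motif-variant overlap, and allelic affinity
# change.

toy_pwm <- function() {
  # 3-position toy motif with consensus ACG
  m <- rbind(c(0.7, 0.1, 0.1, 0.1),
             c(0.1, 0.7, 0.1, 0.1),
             c(0.1, 0.1, 0.7, 0.1))
  pwm(m, name = "toy")
}

test_that("pwm validates rows and derives log odds and consensus", {
  p <- toy_pwm()
  expect_equal(p$consensus, "ACG")
  expect_equal(p$width, 3L)
  pc <- p$pseudocount
  expect_equal(p$max_score,
               3 * log2(((0.7 + pc) / (1 + 4 * pc)) / 0.25))
  expect_error(pwm(rbind(c(0.5, 0.5, 0.1, 0.1))), "sum to 1")
})

test_that("an embedded consensus yields exactly one forward hit at 1.0", {
  g <- toy_genome(c(chr1 = "TTTTTTACGTTTTTTTTTTT"))
  region <- data.frame(chrom = "chr1", start = 0L, end = 20L,
                       region_id = "r1")
  hits <- scan_pwm(g, region, toy_pwm(), threshold = 1.0)
  fwd <- hits[hits$strand == "+", ]
  expect_equal(nrow(fwd), 1L)
  expect_equal(fwd$start, 6L)
  expect_equal(fwd$end, 9L)
  expect_equal(fwd$score, toy_pwm()$max_score)
})

test_that("reverse-complemented sequence mirrors hits and flips strands", {
  set.seed(61)
  s <- random_dna(200L)
  g1 <- toy_genome(c(chr1 = s))
  g2 <- toy_genome(c(chr1 = as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))))
  region <- data.frame(chrom = "chr1", start = 0L, end = 200L)
  h1 <- scan_pwm(g1, region, toy_pwm(), threshold = 0.7)
  h2 <- scan_pwm(g2, region, toy_pwm(), threshold = 0.7)
  expect_equal(nrow(h1), nrow(h2))
  # a forward hit at [s, e) maps to a reverse hit at [200 - e, 200 - s)
  mirrored <- data.frame(start = 200L - h1$end, end = 200L - h1$start,
                         strand = ifelse(h1$strand == "+", "-", "+"),
                         score = h1$score)
  o1 <- order(mirrored$start, mirrored$strand)
  o2 <- order(h2$start, h2$strand)
  expect_equal(mirrored$start[o1], h2$start[o2])
  expect_equal(mirrored$strand[o1], h2$strand[o2])
  expect_equal(mirrored$score[o1], h2$score[o2])
})

test_that("scanning equals exhaustive window enumeration", {
  set.seed(62)
  p <- toy_pwm()
  lo <- p$log_odds
  n_instances <- 0L
  for (rep in 1:25) {
    s <- random_dna(200L)
    g <- toy_genome(c(chr1 = s))
    hits <- scan_pwm(g, data.frame(chrom = "chr1", start = 0L, end = 200L),
                     p, threshold = 0.8)
    # oracle: enumerate every window on both strands independently
    score_str <- function(str) {
      codes <- match(strsplit(str, "")[[1]], c("A", "C", "G", "T"))
      vapply(seq_len(nchar(str) - 2L), function(i) {
        sum(lo[cbind(1:3, codes[i:(i + 2L)])])
      }, numeric(1))
    }
    fwd <- score_str(s)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    rev <- score_str(rc)
    cutoff <- 0.8 * p$max_score
    exp_fwd <- which(fwd >= cutoff) - 1L
    exp_rev <- sort(200L - (which(rev >= cutoff) - 1L) - 3L)
    expect_equal(sort(hits$start[hits$strand == "+"]), sort(exp_fwd))
    expect_equal(sort(hits$start[hits$strand == "-"]), exp_rev)
    n_instances <- n_instances + length(fwd) + length(rev)
  }
  expect_gt(n_instances, 1000L)
})

test_that("short regions are skipped with a warning", {
  g <- toy_genome(c(chr1 = "ACGTACGTAC"))
  regions <- data.frame(chrom = "chr1", start = c(0L, 4L), end = c(2L, 10L))
  expect_warning(h <- scan_pwm(g, regions, toy_pwm(), threshold = 0.5),
                 "shorter than PWM")
  expect_true(all(h$start >= 4L))
})

test_that("motif-variant overlap uses half-open bounds and nested fractions", {
  hits <- data.frame(region_id = "r1", pwm = "toy", chrom = "chr1",
                     start = 10L, end = 13L, strand = "+", score = 1)
  regions <- data.frame(chrom = "chr1", start = c(0L, 50L),
                        end = c(30L, 80L), region_id = c("r1", "r2"))
  # variant one base left of the hit start: no overlap
  v_left <- data.frame(chrom = "chr1", pos = 10L, ref = "A", alt = "C")
  ov <- motif_variant_overlap(hits, v_left, regions)
  expect_false(any(ov$regions$has_overlap))
  # variant at the first hit base: overlap
  v_in <- data.frame(chrom = "chr1", pos = 11L, ref = "A", alt = "C")
  ov2 <- motif_variant_overlap(hits, v_in, regions)
  expect_true(ov2$regions$has_overlap[ov2$regions$region_id == "r1"])
  # r2 has no motif: excluded from the overlap denominator
  expect_equal(ov2$summary$n_with_motif, 1L)
  expect_equal(ov2$summary$frac_with_motif, 0.5)
  expect_equal(ov2$summary$frac_overlap_of_motif, 1)
})

test_that("overlap fractions match brute-force recount on synthetic data", {
  set.seed(63)
  cfg <- small_config(seed = 63L)
  g <- sim_genome(cfg)
  tss <- sim_annotation(cfg)
  regions <- sim_region_sets(cfg, tss)
  variants <- sim_variants(cfg, g, regions)
  p <- toy_pwm()
  hits <- scan_pwm(g, regions, p, threshold = 0.9)
  ov <- motif_variant_overlap(hits, variants, regions)
  has_motif <- regions$region_id %in% hits$region_id
  has_ol <- vapply(seq_len(nrow(regions)), function(i) {
    h <- hits[hits$region_id == regions$region_id[i], ]
    if (nrow(h) == 0L) return(FALSE)
    any(vapply(seq_len(nrow(h)), function(j) {
      any(variants$chrom == h$chrom[j] & variants$pos - 1L >= h$start[j] &
            variants$pos - 1L < h$end[j])
    }, logical(1)))
  }, logical(1))
  expect_equal(ov$summary$frac_with_motif, mean(has_motif))
  expect_equal(ov$summary$frac_overlap_of_motif,
               sum(has_ol) / sum(has_motif))
})

test_that("delta affinity is strand-aware and classifies disruption", {
  p <- toy_pwm()
  hit <- data.frame(region_id = "r1", pwm = "toy", chrom = "chr1",
                    start = 100L, end = 103L, strand = "+", score = 1)
  # consensus base -> minimum-probability base at that offset: the hand
  # oracle is log2(p_min / p_cons) after pseudo-count normalization
  v <- data.frame(chrom = "chr1", pos = 101L, ref = "A", alt = "T")
  d <- delta_affinity(p, hit, v)
  pc <- p$pseudocount
  expect_equal(d$delta, log2((0.1 + pc) / (0.7 + pc)))
  expect_true(d$disrupted)
  # no-op substitution: delta 0, not disrupted
  v0 <- data.frame(chrom = "chr1", pos = 101L, ref = "A", alt = "A")
  expect_equal(delta_affinity(p, hit, v0)$delta, 0)
  expect_false(delta_affinity(p, hit, v0)$disrupted)
  # reverse-strand hit on the same site: equal magnitude
  hit_rev <- hit
  hit_rev$strand <- "-"
  # forward offset 0 base A corresponds to reverse motif position 3 base T
  v_rev <- data.frame(chrom = "chr1", pos = 103L, ref = "T", alt = "A")
  d_rev <- delta_affinity(p, hit_rev, v_rev)
  expect_equal(abs(d_rev$delta), abs(d$delta))
  # indels are rejected
  v_ind <- data.frame(chrom = "chr1", pos = 101L, ref = "AC", alt = "A")
  expect_error(delta_affinity(p, hit, v_ind), "SNV")
  # variant outside the hit is rejected
  v_out <- data.frame(chrom = "chr1", pos = 200L, ref = "A", alt = "C")
  expect_error(delta_affinity(p, hit, v_out), "outside")
})

test_that("random substitutions at consensus positions are mostly disruptive", {
  set.seed(64)
  p <- toy_pwm()
  hit <- data.frame(region_id = "r1", pwm = "toy", chrom = "chr1",
                    start = 0L, end = 3L, strand = "+", score = 1)
  cons <- c("A", "C", "G")
  deltas <- replicate(10000, {
    off <- sample.int(3L, 1L)
    ref <- cons[off]
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
    delta_affinity(p, hit, data.frame(chrom = "chr1", pos = off,
                                      ref = ref, alt = alt))$delta
  })
  expect_gt(mean(deltas < 0), 0.5)
})

test_that("HOMER-style motif files round-trip into pwm objects", {
  path <- system.file("extdata", "motifs", "synthetic_tf.motif",
                      package = "epivar")
  motifs <- read_homer_motifs(path)
  expect_named(motifs, c("synTF1", "synTF2"))
  expect_equal(motifs$synTF1$width, 12L)
  expect_equal(motifs$synTF2$consensus, "TGTTTAC")
  expect_s3_class(motifs$synTF1, "pwm")
})
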