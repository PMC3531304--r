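# Discovery filters, partner pairing under the junction gap rule, and fusion
# geometry classification.

test_that("identity/length filter respects the inclusive thresholds", {
  aln <- rbind(
    psl_row("a", 500L, 0L, 150L, matches = 144L, misMatches = 6L),   # id 0.96
    psl_row("b", 500L, 0L, 150L, matches = 143L, misMatches = 7L),   # id .9533
    psl_row("c", 500L, 0L, 100L),                                    # len 100
    psl_row("d", 500L, 0L, 99L, blockSizes = "99,"))                 # len 99
  kept <- filter_alignments(aln, discovery_params())
  expect_equal(kept$qName, c("a", "c"))
  det <- filter_alignments(aln, discovery_params(), detail = TRUE)
  expect_equal(det$dropped$reason, c("identity", "length"))

  # identity just below 96% with ample length is rejected
  one <- psl_row("e", 500L, 0L, 150L, matches = 0L, misMatches = 0L)
  one$matches <- 1438L; one$misMatches <- 62L  # 0.9587
  one$blockSizes <- "1500,"; one$qEnd <- 1500L; one$qSize <- 1500L
  one$tEnd <- one$tStart + 1500L
  expect_equal(nrow(filter_alignments(one, discovery_params())), 0L)
})

test_that("partner pairing applies the 10 nt junction gap/overlap rule", {
  p <- discovery_params()
  mk <- function(qs3, qe5 = 403L) rbind(
    psl_row("q", 900L, 0L, qe5, "chr1", 10000L, 1000L, 1000L + qe5),
    psl_row("q", 900L, qs3, 900L, "chr2", 10000L, 3000L, 3000L + 900L - qs3))
  # perfect junction
  r <- pair_partners(mk(403L), p)
  expect_equal(r$candidate$g, 0L)
  expect_equal(r$candidate$junction_q, 403L)
  # gap of 11 nt is suppressed, overlap of exactly 10 nt kept
  expect_equal(pair_partners(mk(414L, 403L), p)$reason, "gap")
  expect_equal(pair_partners(mk(393L, 403L), p)$candidate$g, -10L)
  expect_equal(pair_partners(mk(413L, 403L), p)$candidate$g, 10L)
  # input order must not matter
  two <- mk(403L)
  expect_equal(pair_partners(two[2:1, ], p)$candidate$p5$tName, "chr1")
  # three loci are ambiguous
  three <- rbind(mk(403L), psl_row("q", 900L, 100L, 300L, "chr3"))
  expect_equal(pair_partners(three, p)$reason, "ambiguous multi-locus")
  # equal qStart cannot assign 5'/3'
  tie <- rbind(psl_row("q", 900L, 0L, 400L, "chr1"),
               psl_row("q", 900L, 0L, 400L, "chr2", tStart = 5000L,
                       tEnd = 5400L))
  expect_match(pair_partners(tie, p)$reason, "ambiguous 5'/3'")
})

test_that("same-strand colinear loci are contiguous unless too far apart", {
  p <- discovery_params(max_intron = 1000000L)
  mk <- function(t3start, tsize = 99000000L) rbind(
    psl_row("q", 900L, 0L, 400L, "chr1", tsize, 1000L, 1400L),
    psl_row("q", 900L, 400L, 900L, "chr1", tsize, t3start, t3start + 500L))
  # a plausible intron separation: one cis transcript, not a chimera
  expect_equal(pair_partners(mk(50000L), p)$reason, "contiguous_loci")
  # separation far beyond any intron: readthrough-style chimera
  far <- pair_partners(mk(58000000L), p)
  expect_equal(far$candidate$order_type, "colinear_readthrough")
  # out-of-order loci are always non-contiguous
  out <- pair_partners(rbind(
    psl_row("q", 900L, 0L, 400L, "chr1", 10000000L, 500000L, 500400L),
    psl_row("q", 900L, 400L, 900L, "chr1", 10000000L, 1000L, 1500L)), p)
  expect_equal(out$candidate$order_type, "partner5_downstream")
})

test_that("fusion classes follow chromosome and strand comparison", {
  mk <- function(c5, s5, c3, s3, t5 = 1000L, t3 = 5000L) {
    pair_partners(rbind(
      psl_row("q", 900L, 0L, 400L, c5, 10000L, t5, t5 + 400L, strand = s5,
              tStarts = paste0(t5, ",")),
      psl_row("q", 900L, 400L, 900L, c3, 10000L, t3, t3 + 500L,
              strand = s3, qStarts = "400,",
              tStarts = paste0(t3, ","))), discovery_params())$candidate
  }
  expect_equal(classify_fusion(mk("chr1", "+", "chr2", "+")),
               "inter_chromosomal")
  expect_equal(classify_fusion(mk("chr3", "+", "chr3", "-")),
               "intra_inter_strand")
  # same chromosome and strand, 5' partner downstream of the 3' partner
  expect_equal(mk("chr16", "+", "chr16", "+", t5 = 5000L, t3 = 1000L)$fusion_class,
               "intra_intra_strand")
})

test_that("ordering types are assigned in transcription direction", {
  mk_cand <- function(strand, s5, e5, s3, e3) {
    list(mrna_id = "q",
         p5 = psl_row("q", 900L, 0L, 400L, "chr1", 10000L, s5, e5,
                      strand = strand,
                      blockSizes = paste0(e5 - s5, ","),
                      tStarts = paste0(s5, ",")),
         p3 = psl_row("q", 900L, 400L, 900L, "chr1", 10000L, s3, e3,
                      strand = strand,
                      blockSizes = paste0(e3 - s3, ","),
                      qStarts = "400,", tStarts = paste0(s3, ",")))
  }
  expect_equal(classify_order(mk_cand("+", 200L, 300L, 50L, 150L))$order_type,
               "partner5_downstream")
  expect_equal(classify_order(mk_cand("+", 0L, 500L, 100L, 200L))$order_type,
               "nested_3p_in_5p")
  expect_equal(classify_order(mk_cand("+", 100L, 200L, 0L, 500L))$order_type,
               "nested_5p_in_3p")
  expect_equal(classify_order(mk_cand("+", 50L, 150L, 200L, 300L))$order_type,
               "colinear_readthrough")
  # minus strand: 5' partner at lower coordinates is downstream in
  # transcription direction
  expect_equal(classify_order(mk_cand("-", 50L, 150L, 200L, 300L))$order_type,
               "partner5_downstream")
  # partial overlap is ambiguous and excluded from tabulation
  expect_equal(classify_order(mk_cand("+", 0L, 300L, 200L, 500L))$order_type,
               "ambiguous")
})

test_that("order classification is invariant under strand mirroring", {
  set.seed(7)
  mirror <- function(cand, size = 10000L) {
    flip <- function(p) {
      bs <- as.integer(strsplit(sub(",$", "", p$blockSizes), ",")[[1]])
      ts <- as.integer(strsplit(sub(",$", "", p$tStarts), ",")[[1]])
      nts <- size - (ts + bs)
      p$tStarts <- paste0(paste(nts, collapse = ","), ",")
      new_start <- size - p$tEnd
      p$tEnd <- size - p$tStart
      p$tStart <- new_start
      p$strand <- if (p$strand == "+") "-" else "+"
      p
    }
    cand$p5 <- flip(cand$p5); cand$p3 <- flip(cand$p3)
    cand
  }
  for (i in 1:25) {
    s5 <- sort(sample(0:9000, 2)); s3 <- sort(sample(0:9000, 2))
    if (s5[1] == s5[2] || s3[1] == s3[2]) next
    st <- sample(c("+", "-"), 1)
    cand <- list(
      mrna_id = "q",
      p5 = psl_row("q", 900L, 0L, 400L, "chr1", 10000L, s5[1], s5[2],
                   strand = st, blockSizes = paste0(s5[2] - s5[1], ","),
                   tStarts = paste0(s5[1], ",")),
      p3 = psl_row("q", 900L, 400L, 900L, "chr1", 10000L, s3[1], s3[2],
                   strand = st, blockSizes = paste0(s3[2] - s3[1], ","),
                   qStarts = "400,", tStarts = paste0(s3[1], ",")))
    expect_equal(classify_order(mirror(cand))$order_type,
                 classify_order(cand)$order_type)
  }
})

test_that("discovery log names the filter that removed a partner", {
  aln <- rbind(
    psl_row("lowid", 900L, 0L, 400L, "chr1", 10000L, 1000L, 1400L,
            matches = 360L, misMatches = 40L),
    psl_row("lowid", 900L, 400L, 900L, "chr2", 10000L, 3000L, 3500L),
    psl_row("short", 900L, 0L, 99L, "chr1", 10000L, 6000L, 6099L,
            blockSizes = "99,"),
    psl_row("short", 900L, 99L, 900L, "chr2", 10000L, 7000L, 7801L))
  d <- discover_chimeras(aln, discovery_params())
  expect_length(d$candidates, 0L)
  expect_equal(d$log$reason[d$log$mrna_id == "lowid"], "identity")
  expect_equal(d$log$reason[d$log$mrna_id == "short"], "length")
})
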