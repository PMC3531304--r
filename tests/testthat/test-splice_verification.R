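# Fused-reference construction, the simplified spliced aligner, junction
# precision, splice signals and reading-frame integrity.

mk_cand <- function(genome, c5, s5, e5, st5, c3, s3, e3, st3,
                    junction_q = e5 - s5) {
  list(mrna_id = "q", junction_q = junction_q, g = 0L,
       p5 = psl_row("q", 900L, 0L, e5 - s5, c5, nchar(genome[[c5]]), s5, e5,
                    strand = st5, blockSizes = paste0(e5 - s5, ","),
                    tStarts = paste0(s5, ",")),
       p3 = psl_row("q", 900L, e5 - s5, (e5 - s5) + (e3 - s3), c3,
                    nchar(genome[[c3]]), s3, e3, strand = st3,
                    blockSizes = paste0(e3 - s3, ","),
                    qStarts = paste0(e5 - s5, ","),
                    tStarts = paste0(s3, ",")))
}

test_that("fused reference joins partner regions in transcript orientation", {
  genome <- c(c1 = "AAAACCCCGGGGTTTT", c2 = "ACGTACGTAACGTTTT")
  cand <- mk_cand(genome, "c1", 0L, 8L, "+", "c2", 8L, 16L, "+")
  fr <- build_fused_reference(genome, cand, flank = 0L)
  expect_equal(fr$seq, paste0("AAAACCCC", "AACGTTTT"))
  expect_equal(fr$boundary, 8L)

  # minus-strand partner is reverse-complemented: "AACG" -> "CGTT"
  genome2 <- c(c1 = "AACGAACGAACGAACG", c2 = "ACGTACGTACGTACGT")
  cand2 <- mk_cand(genome2, "c1", 0L, 4L, "-", "c2", 0L, 4L, "+")
  fr2 <- build_fused_reference(genome2, cand2, flank = 0L)
  expect_equal(substr(fr2$seq, 1, 4), rc_oracle("AACG"))
  expect_equal(substr(fr2$seq, 1, 4), "CGTT")

  expect_error(build_fused_reference(genome, mk_cand(genome, "c1", 0L, 40L,
                                                     "+", "c2", 0L, 4L, "+")),
               "bounds")
})

test_that("fused/genomic coordinate maps invert each other", {
  set.seed(11)
  genome <- c(c1 = random_dna_oracle(4000), c2 = random_dna_oracle(3000))
  cand <- mk_cand(genome, "c1", 1000L, 1500L, "-", "c2", 500L, 1200L, "+")
  fr <- build_fused_reference(genome, cand, flank = 100L)
  pos <- sample(0:(nchar(fr$seq) - 1L), 100L)
  gg <- fused_to_genomic(fr, pos)
  back <- vapply(seq_along(pos), function(i)
    genomic_to_fused(fr, gg$chrom[i], gg$pos[i], gg$segment[i]), 0L)
  expect_equal(back, pos)
})

test_that("spliced alignment recovers planted exon/intron structures", {
  set.seed(21)
  exonA <- random_dna_oracle(120)
  exonB <- random_dna_oracle(150)
  intron <- paste0("GT", random_dna_oracle(76), "AG")
  target <- paste0(exonA, intron, exonB)
  query <- paste0(exonA, exonB)
  al <- spliced_align(query, target, min_intron = 30L)
  expect_equal(al$status, "ok")
  expect_equal(al$blocks$q_end, c(120L, 270L))
  expect_equal(al$blocks$t_start, c(0L, 200L))

  # identity case: one block covering everything
  al2 <- spliced_align(target, target)
  expect_equal(nrow(al2$blocks), 1L)
  expect_equal(al2$blocks$q_end, nchar(target))

  # unalignable query fails rather than erroring
  al3 <- spliced_align(strrep("ACGT", 30), strrep("TGCA", 100))
  expect_equal(al3$status, "failed")
})

test_that("spliced alignment agrees with the brute-force DP oracle", {
  set.seed(31)
  for (rep in 1:4) {
    e1 <- random_dna_oracle(sample(80:140, 1))
    e2 <- random_dna_oracle(sample(80:140, 1))
    i1 <- paste0("GT", random_dna_oracle(sample(40:90, 1)), "AG")
    target <- paste0(random_dna_oracle(50), e1, i1, e2, random_dna_oracle(50))
    query <- paste0(e1, e2)
    if (rep >= 3) {  # plant one internal mismatch
      at <- 40L
      b <- substr(query, at, at)
      substr(query, at, at) <- setdiff(c("A", "C", "G", "T"), b)[1]
    }
    got <- spliced_align(query, target, min_intron = 30L)
    exp <- spliced_oracle(query, target, min_intron = 30L)
    expect_equal(got$status, "ok")
    # optimal splits can slide at matching boundary bases; compare the
    # canonical (maximally left-slid) representative of each alignment
    expect_equal(normalize_blocks(query, target,
                                  got$blocks[, c("q_start", "q_end",
                                                 "t_start", "t_end")]),
                 normalize_blocks(query, target, exp), ignore_attr = TRUE)
  }
})

test_that("junction precision requires an exact query split at the boundary", {
  bl <- function(qe1, qs2) data.frame(q_start = c(0L, qs2),
                                      q_end = c(qe1, 800L),
                                      t_start = c(0L, 1600L),
                                      t_end = c(qe1, 2000L),
                                      mismatches = 0L)
  expect_true(check_junction(bl(403L, 403L), 403L, 1000L))
  expect_false(check_junction(bl(400L, 405L), 403L, 1000L))  # query gap
  expect_false(check_junction(bl(406L, 403L), 403L, 1000L))  # query overlap
  # blocks must straddle the artificial boundary
  same_side <- data.frame(q_start = c(0L, 403L), q_end = c(403L, 800L),
                          t_start = c(0L, 500L), t_end = c(403L, 897L),
                          mismatches = 0L)
  expect_false(check_junction(same_side, 403L, 1000L))
})

test_that("splice signals read GT..AG on the transcribed strand", {
  set.seed(41)
  ex5 <- random_dna_oracle(150); ex3 <- random_dna_oracle(150)
  mk_genome <- function(donor) c(
    c1 = paste0(random_dna_oracle(60), ex5, donor, random_dna_oracle(80)),
    c2 = paste0(random_dna_oracle(80), "AG", ex3, random_dna_oracle(60)))
  run <- function(genome) {
    cand <- mk_cand(genome, "c1", 60L, 210L, "+", "c2", 82L, 232L, "+")
    fr <- build_fused_reference(genome, cand, flank = 50L)
    al <- spliced_align(paste0(ex5, ex3), fr, min_intron = 30L)
    c(splice_signals(fr, al$blocks), precise = check_junction(al$blocks, 150L, fr))
  }
  sig <- run(mk_genome("GT"))
  expect_true(sig$canonical)
  expect_true(sig$precise)
  expect_equal(c(sig$donor, sig$acceptor), c("GT", "AG"))

  sig2 <- run(mk_genome("GC"))
  expect_false(sig2$canonical)
  expect_equal(sig2$donor, "GC")

  # a minus-strand 5' partner whose plus-strand genome shows the reverse
  # complement still reads GT..AG after orientation
  gplus <- mk_genome("GT")
  gneg <- c(c1 = rc_oracle(gplus[["c1"]]), c2 = gplus[["c2"]])
  n <- nchar(gplus[["c1"]])
  cand <- mk_cand(gneg, "c1", n - 210L, n - 60L, "-", "c2", 82L, 232L, "+")
  fr <- build_fused_reference(gneg, cand, flank = 50L)
  al <- spliced_align(paste0(ex5, ex3), fr, min_intron = 30L)
  sig3 <- splice_signals(fr, al$blocks)
  expect_true(sig3$canonical)
})

test_that("reading-frame rule follows the longest sense-strand ORF", {
  # ORF covering the whole toy transcript spans any junction
  orf <- paste0("ATG", strrep("GCT", 60), "TAA")
  expect_true(check_reading_frame(orf, 90L))
  # stop immediately in every frame before the junction
  blocked <- paste0(strrep("TAAGTAAGTAA", 20), strrep("C", 100))
  expect_false(check_reading_frame(blocked, 150L))
  # two ORFs: the longer one decides, matching the exhaustive oracle
  set.seed(51)
  for (i in 1:20) {
    s <- random_dna_oracle(400)
    o1 <- longest_orf(s); o2 <- orf_oracle(s)
    if (is.null(o1)) {
      expect_null(o2)
    } else {
      expect_equal(o1$start, o2$start)
      expect_equal(o1$end, o2$end)
      expect_equal(check_reading_frame(s, 200L),
                   o2$start < 200 && 200 < o2$end)
    }
  }
})
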