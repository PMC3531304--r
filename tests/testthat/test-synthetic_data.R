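# The seeded generator: determinism, GT..AG introns, transcript/genome
# consistency, single-violation decoys, reads and ESTs with truth.

test_that("genome generation is deterministic and honours GC/lengths", {
  g1 <- make_genome(2, c(10000L, 12000L), gc = 0.42, seed = 99L)
  g2 <- make_genome(2, c(10000L, 12000L), gc = 0.42, seed = 99L)
  expect_identical(g1, g2)
  expect_equal(nchar(g1), c(chr1 = 10000L, chr2 = 12000L))
  at <- make_genome(1, 10000L, gc = 0, seed = 1L)
  expect_false(grepl("[GC]", at[[1]]))
})

test_that("planted genes splice back to their transcripts", {
  g <- make_genome(2, c(20000L, 20000L), seed = 3L)
  pg <- plant_genes(g, 5, seed = 4L)
  for (gn in pg$genes) {
    # re-derive the transcript from genome + exon coordinates
    chrom <- pg$genome[[gn$chrom]]
    ord <- order(gn$g_ex_start)
    pieces <- substring(chrom, gn$g_ex_start[ord] + 1L,
                        gn$g_ex_start[ord] + gn$ex_len[ord])
    tx <- paste(pieces, collapse = "")
    if (gn$strand == "-") tx <- rc_oracle(tx)
    expect_equal(tx, gn$transcript)
    # every intron starts GT and ends AG on the transcribed strand
    types <- vapply(gn$segs, `[[`, "", "type")
    for (sg in gn$segs[types == "intron"]) {
      expect_equal(substr(sg$seq, 1, 2), "GT")
      expect_equal(substr(sg$seq, sg$len - 1, sg$len), "AG")
    }
  }
  # BED12 blocks describe the same exons
  expect_equal(nrow(pg$bed), 5L)
  expect_identical(plant_genes(g, 5, seed = 4L)$genome, pg$genome)
})

test_that("planted chimeras pass discovery; decoys fail their own filter", {
  g <- make_genome(2, c(60000L, 40000L), seed = 5L)
  spec <- default_classes_spec()
  spec <- spec[spec$id %in% c("CHIM001", "DECOY_gap", "DECOY_identity",
                              "DECOY_splice"), ]
  ch <- plant_chimeras(g, spec, seed = 6L)
  d <- discover_chimeras(ch$psl, discovery_params(max_intron = 50000L))
  expect_setequal(names(d$candidates), c("CHIM001", "DECOY_splice"))
  expect_equal(d$log$reason[d$log$mrna_id == "DECOY_gap"], "gap")
  expect_equal(d$log$reason[d$log$mrna_id == "DECOY_identity"], "identity")
  expect_equal(d$candidates$CHIM001$g, 0L)
  expect_equal(d$candidates$CHIM001$junction_q,
               ch$chimeras$junction_q[ch$chimeras$id == "CHIM001"])
  # the GC-AG decoy is discovered but fails only the canonical check
  v <- verify_candidates(d$candidates, ch$genome, ch$transcripts)
  expect_true(v$canonical[v$mrna_id == "CHIM001"])
  expect_true(v$frame_ok[v$mrna_id == "CHIM001"])
  expect_false(v$canonical[v$mrna_id == "DECOY_splice"])
  expect_true(v$aligned_precisely[v$mrna_id == "DECOY_splice"])
  expect_true(v$frame_ok[v$mrna_id == "DECOY_splice"])
})

test_that("simulated reads honour depth, recall and junction truth counts", {
  set.seed(7)
  tx <- c(CH = paste(random_dna_oracle(800), collapse = ""))
  ab <- matrix(120L, 1, 2, dimnames = list("CH", c("s1", "s2")))
  sr <- simulate_reads(tx, ab, read_len = 76L, error_rate = 0, seed = 8L,
                       junctions = c(CH = 400L), k = 5L)
  expect_equal(as.vector(table(sr$reads$sample_id)), c(120L, 120L))
  # error-free: every truth junction read is recovered by junction calling
  refs <- build_junction_refs(tx, c(CH = 400L), junction_params(76L, 5L))
  hits <- call_junction_reads(sr$reads, refs, junction_params(76L, 5L))
  expect_true(all(sr$truth$read_id %in% hits$read_id))
  expect_true(all(hits$read_id %in% sr$truth$read_id))
  expect_equal(sort(hits$start_1based),
               sort(sr$truth$ref_start_1based))
  # truth count close to its binomial expectation
  p_span <- (76 - 2 * 5 + 1) / (800 - 76 + 1)
  n <- 240
  expect_lt(abs(nrow(sr$truth) - n * p_span),
            3 * sqrt(n * p_span * (1 - p_span)) + 1)
  # determinism
  sr2 <- simulate_reads(tx, ab, read_len = 76L, error_rate = 0, seed = 8L,
                        junctions = c(CH = 400L), k = 5L)
  expect_identical(sr$reads, sr2$reads)
})

test_that("101 nt reads trim to 76 and keep correct junction truth", {
  set.seed(9)
  tx <- c(CH = random_dna_oracle(900))
  ab <- matrix(200L, 1, 1, dimnames = list("CH", "s1"))
  sr <- simulate_reads(tx, ab, read_len = 101L, target_len = 76L,
                       error_rate = 0, seed = 10L, junctions = c(CH = 450L))
  rd <- qc_trim(sr$reads, target_len = 76L)
  refs <- build_junction_refs(tx, c(CH = 450L), junction_params(76L, 5L))
  hits <- call_junction_reads(rd, refs, junction_params(76L, 5L))
  expect_setequal(hits$read_id, sr$truth$read_id)
})

test_that("EST simulation respects the spanning rules end to end", {
  set.seed(11)
  chim <- c(A = random_dna_oracle(700), B = random_dna_oracle(700))
  jq <- c(A = 350L, B = 320L)
  es <- simulate_ests(chim, jq, n_spanning = c(A = 3L, B = 2L),
                      n_non_spanning = 2L, seed = 12L)
  sup <- compute_est_support(chim, jq, es$ests)
  expect_true(sup$support$supported[sup$support$chimera_id == "A"])
  expect_false(sup$support$supported[sup$support$chimera_id == "B"])
  expect_equal(sup$support$n_spanning[sup$support$chimera_id == "A"], 3L)
  # non-spanning ESTs are never counted as spanning
  expect_equal(sup$support$n_spanning[sup$support$chimera_id == "B"], 2L)
})

test_that("motif planting records offsets that discovery recovers", {
  pairs <- make_region_pairs(6, len = 600L, seed = 13L)
  cons <- "TGGCCACCAGGGGGCGCTA"
  pm <- plant_region_motifs(pairs, cons, fraction = 0.5, seed = 14L,
                            max_mismatches = 0L)
  expect_equal(sum(pm$truth$planted), 3L)
  for (i in which(pm$truth$planted)) {
    sm <- find_shared_motif(pm$pairs$seq5[i], pm$pairs$seq3[i],
                            n_shuffles = 60L, seed = 15L)
    expect_lte(sm$site5, pm$truth$off5[i])
    expect_gte(sm$site5 + sm$width, pm$truth$off5[i] + nchar(cons))
  }
  none <- plant_region_motifs(pairs, cons, fraction = 0, seed = 14L)
  expect_identical(none$pairs, pairs)
})
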