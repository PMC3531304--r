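# Read QC, the pigeonhole genome mapper, junction references, junction-read
# calling by the start-position window, validation and coverage.

mk_reads <- function(seqs, sample_id = "s1", q = 35L) {
  data.frame(read_id = sprintf("r%03d", seq_along(seqs)),
             sample_id = sample_id, seq = seqs,
             qual = vapply(nchar(seqs), function(n)
               paste(rep(intToUtf8(q + 33L), n), collapse = ""), ""),
             stringsAsFactors = FALSE)
}

test_that("junction reference geometry follows 2(L-k) for all L, k", {
  jp <- junction_params(L = 76L, k = 5L)
  expect_equal(jp$ref_len, 142L)
  expect_equal(jp$fusion_offset, 71L)
  expect_equal(jp$last_start, 67L)
  jp49 <- junction_params(L = 49L, k = 5L)
  expect_equal(jp49$ref_len, 88L)
  expect_equal(jp49$fusion_offset, 44L)
  set.seed(101)
  for (i in 1:40) {
    L <- sample(20:150, 1); k <- sample(1:10, 1)
    if (L <= 2 * k) next
    jp <- junction_params(L, k)
    expect_equal(jp$ref_len, 2L * (L - k))
    expect_equal(jp$last_start, L - 2L * k + 1L)
    expect_equal(jp$last_start + (L - 1L), jp$ref_len)  # last read fits
  }
  expect_error(junction_params(L = 10L, k = 5L))
})

test_that("quality trimming truncates from the right and drops poor reads", {
  rd <- rbind(mk_reads(strrep("A", 101)),               # long, high quality
              mk_reads(strrep("C", 76), q = 19L),       # mean Phred 19
              mk_reads(strrep("G", 76), q = 30L),       # fine
              mk_reads(strrep("T", 50)))                # too short
  out <- qc_trim(rd, target_len = 76L, min_q = 20)
  expect_equal(nchar(out$seq), c(76L, 76L))
  expect_equal(substr(out$seq, 1, 1), c("A", "G"))
  # min mode is stricter
  mixed <- mk_reads(strrep("A", 76), q = 35L)
  mixed$qual <- paste0(strrep("D", 10), substr(mixed$qual, 11, 76))  # Phred 35
  mixed$qual <- paste0("!", substr(mixed$qual, 2, 76))               # one 0
  expect_equal(nrow(qc_trim(mixed, 76L, 20, mode = "mean")), 1L)
  expect_equal(nrow(qc_trim(mixed, 76L, 20, mode = "min")), 0L)
})

test_that("genome mapping classifies unique/multi/unmapped exactly", {
  set.seed(111)
  u1 <- random_dna_oracle(300)
  rep2 <- random_dna_oracle(200)
  genome <- c(chrA = paste0(random_dna_oracle(500), u1, rep2,
                            random_dna_oracle(300)),
              chrB = paste0(random_dna_oracle(400), rep2,
                            random_dna_oracle(200)))
  reads <- mk_reads(c(substr(u1, 50, 125),              # unique
                      substr(rep2, 10, 85),             # two copies
                      rc_oracle(substr(u1, 100, 175)),  # unique, minus
                      random_dna_oracle(76)))           # unmapped
  mg <- map_genome(reads, genome, max_mismatches = 2L)
  expect_equal(mg$assignments$status,
               c("unique", "multi", "unique", "unmapped"))
  expect_equal(mg$assignments$strand[c(1, 3)], c("+", "-"))
})

test_that("genome mapping equals the brute-force Hamming scan", {
  set.seed(121)
  genome <- c(c1 = random_dna_oracle(6000), c2 = random_dna_oracle(4000))
  mut <- function(s, nmm) {
    for (at in sample(nchar(s), nmm)) {
      b <- substr(s, at, at)
      substr(s, at, at) <- setdiff(c("A", "C", "G", "T"), b)[1]
    }
    s
  }
  seqs <- character(0)
  for (i in 1:15) {
    p <- sample(1:(6000 - 76), 1)
    s <- mut(substr(genome[["c1"]], p, p + 75), sample(0:3, 1))
    if (i %% 3 == 0) s <- rc_oracle(s)
    seqs <- c(seqs, s)
  }
  seqs <- c(seqs, replicate(5, random_dna_oracle(76)))
  reads <- mk_reads(seqs)
  mg <- map_genome(reads, genome, max_mismatches = 2L)
  for (i in seq_len(nrow(reads))) {
    br <- hamming_scan_oracle(reads$seq[i], genome, 2L)
    status <- if (nrow(br) == 0) "unmapped" else if (nrow(br) == 1) "unique"
              else "multi"
    expect_equal(mg$assignments$status[i], status)
    if (status == "unique") {
      expect_equal(mg$assignments$pos0[i], br$pos0)
      expect_equal(mg$assignments$strand[i], br$strand)
      expect_equal(mg$assignments$mm[i], br$mm)
    }
  }
})

test_that("a read spanning a planted trans-junction is genome-unmapped", {
  set.seed(131)
  locus5 <- random_dna_oracle(400)
  locus3 <- random_dna_oracle(400)
  genome <- c(c1 = paste0(random_dna_oracle(200), locus5,
                          random_dna_oracle(200)),
              c2 = paste0(random_dna_oracle(150), locus3,
                          random_dna_oracle(250)))
  chimera <- paste0(locus5, locus3)
  jread <- substr(chimera, 400 - 37, 400 - 37 + 75)  # 38|38 around junction
  mg <- map_genome(mk_reads(jread), genome, 2L)
  expect_equal(mg$assignments$status, "unmapped")
  expect_equal(nrow(hamming_scan_oracle(jread, genome, 2L)), 0L)
})

test_that("junction references take L-k nt from each side", {
  seqs <- c(ev1 = paste0(strrep("A", 200), strrep("C", 200)))
  refs <- build_junction_refs(seqs, c(ev1 = 200L), junction_params(76L, 5L))
  expect_equal(nchar(refs$seq), 142L)
  expect_equal(refs$fusion_offset, 71L)
  expect_equal(refs$seq, paste0(strrep("A", 71), strrep("C", 71)))
  expect_false(refs$clipped)
  # toy: L=4, k=1 gives "AAA"+"CCC"
  toy <- build_junction_refs(c(t1 = "AAAACCCC"), c(t1 = 4L),
                             junction_params(4L, 1L))
  expect_equal(toy$seq, "AAACCC")
  # a short 5' side is clipped and flagged
  short <- build_junction_refs(c(s1 = paste0(strrep("G", 30),
                                             strrep("T", 200))),
                               c(s1 = 30L), junction_params(76L, 5L))
  expect_true(short$clipped)
  expect_equal(short$fusion_offset, 30L)
})

test_that("junction-read calling honours the start-position window", {
  set.seed(141)
  chim <- c(ev1 = paste0(random_dna_oracle(300), random_dna_oracle(300)))
  jp <- junction_params(76L, 5L)
  refs <- build_junction_refs(chim, c(ev1 = 300L), jp)
  read_at <- function(start1) substr(refs$seq, start1, start1 + 75L)
  rd <- mk_reads(c(read_at(67L), read_at(1L), read_at(34L)))
  hits <- call_junction_reads(rd, refs, jp)
  expect_equal(sort(hits$start_1based), c(1L, 34L, 67L))
  # start 68 violates the 5 nt overhang on the left side of the 3' part:
  # the read no longer fits the reference, so it cannot be called
  rd68 <- mk_reads(paste0(substr(refs$seq, 68L, 142L), "A"))
  expect_equal(nrow(call_junction_reads(rd68, refs, jp)), 0L)
  # two mismatches tolerated, three rejected
  r <- read_at(30L)
  substr(r, 10, 10) <- "N"; substr(r, 20, 20) <- "N"
  expect_equal(call_junction_reads(mk_reads(r), refs, jp)$mismatches, 2L)
  substr(r, 30, 30) <- "N"
  expect_equal(nrow(call_junction_reads(mk_reads(r), refs, jp)), 0L)
})

test_that("event validation needs 3 start positions or 3 samples", {
  jp <- junction_params()
  mk_hits <- function(starts, samples) {
    data.frame(read_id = sprintf("r%d", seq_along(starts)),
               sample_id = samples, event_id = "ev", start_1based = starts,
               mismatches = 0L, shared = FALSE)
  }
  expect_false(validate_events(mk_hits(c(10L, 10L, 10L),
                                       rep("s1", 3)), jp)$validated)
  expect_true(validate_events(mk_hits(c(10L, 11L, 12L),
                                      rep("s1", 3)), jp)$validated)
  expect_true(validate_events(mk_hits(c(10L, 10L, 10L),
                                      c("s1", "s2", "s3")), jp)$validated)
  # shared hits never contribute
  sh <- mk_hits(c(10L, 11L, 12L), rep("s1", 3)); sh$shared <- TRUE
  expect_false(validate_events(sh, jp, all_events = "ev")$validated)
  # monotone under added hits
  set.seed(151)
  h <- mk_hits(10L, "s1")
  prev <- FALSE
  for (i in 1:8) {
    h <- rbind(h, mk_hits(sample(1:67, 1), sample(paste0("s", 1:4), 1)))
    v <- validate_events(h, jp)$validated
    expect_true(v >= prev)
    prev <- v
  }
})

test_that("coverage pooling shows a trough at a lowly-expressed junction", {
  cov <- coverage_profile(data.frame(start0 = 0L, end0 = 76L), 200L)
  expect_equal(cov, c(rep(1L, 76), rep(0L, 124)))
  expect_equal(coverage_profile(NULL, 50L), rep(0L, 50))
  set.seed(161)
  # chimera at 1/5 the abundance of its parents: reads near the junction can
  # come only from the chimera, elsewhere parents contribute too
  tx_len <- 800L; jq <- 400L; L <- 76L
  place <- function(n, lo, hi) {
    s <- sample(lo:hi, n, replace = TRUE)
    data.frame(start0 = s, end0 = s + L)
  }
  n_ch <- 120L; n_par <- 600L
  iv <- rbind(place(n_ch, 0L, tx_len - L),                 # chimera reads
              place(n_par / 2, 0L, jq - L),                # 5' parent
              place(n_par / 2, jq, tx_len - L))            # 3' parent
  cov <- coverage_profile(iv, tx_len)
  expect_equal(sum(cov), 76L * nrow(iv))
  # expected junction coverage: chimera reads only, Binomial(n_ch, L/(T-L+1))
  p_cov <- L / (tx_len - L + 1L)
  expected <- n_ch * p_cov
  sd3 <- 3 * sqrt(n_ch * p_cov * (1 - p_cov))
  expect_lt(abs(cov[jq] - expected), sd3)
  expect_gt(mean(cov[c(150:250, 550:650)]), cov[jq])  # visible trough
})
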