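# Independent oracles used to check the package implementations. Each is a
# deliberately naive, brute-force route kept separate from the package code.

# reverse complement via chartr (independent of Biostrings)
rc_oracle <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, "", USE.NAMES = FALSE)
}

# full Smith-Waterman local alignment via Biostrings (match +1 / mismatch -1,
# effectively ungapped through prohibitive gap costs, matching the seeded
# aligner's scoring on substitution-only data)
sw_oracle <- function(query, target) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  al <- Biostrings::pairwiseAlignment(query, target, type = "local",
                                      substitutionMatrix = mat,
                                      gapOpening = 100, gapExtension = 100)
  p <- Biostrings::pattern(al); s <- Biostrings::subject(al)
  list(q_start = BiocGenerics::start(p) - 1L,
       q_end = BiocGenerics::end(p),
       t_start = BiocGenerics::start(s) - 1L,
       t_end = BiocGenerics::end(s),
       score = Biostrings::score(al),
       identity = Biostrings::pid(al) / 100)
}

# brute-force Hamming scan of a read over every genome position and strand
hamming_scan_oracle <- function(read, genome, max_mm) {
  L <- nchar(read)
  out <- list()
  for (strand in c("+", "-")) {
    r <- if (strand == "+") read else rc_oracle(read)
    ri <- utf8ToInt(r)
    for (chrom in names(genome)) {
      gi <- utf8ToInt(genome[[chrom]])
      npos <- length(gi) - L + 1L
      if (npos < 1L) next
      mm <- integer(npos)
      for (o in seq_len(L)) mm <- mm + (gi[o:(o + npos - 1L)] != ri[o])
      hit <- which(mm <= max_mm)
      if (length(hit))
        out[[length(out) + 1L]] <- data.frame(chrom = chrom, pos0 = hit - 1L,
                                              strand = strand,
                                              mm = mm[hit])
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(0), pos0 = integer(0),
                      strand = character(0), mm = integer(0)))
  do.call(rbind, out)
}

# brute-force spliced alignment by dynamic programming: every query base is
# aligned (semi-global in the query), match +1 / mismatch -1, target jumps of
# at least min_intron between consecutive query bases cost 0.01. Returns the
# block table of the optimal alignment.
spliced_oracle <- function(query, target, min_intron = 30L) {
  qi <- utf8ToInt(query); ti <- utf8ToInt(target)
  n <- length(qi); m <- length(ti)
  NEG <- -1e9
  S <- matrix(NEG, n, m)
  from <- matrix(0L, n, m)  # 0 = start/diag, j' > 0 = intron jump source
  S[1, ] <- ifelse(qi[1] == ti, 1, -1)
  for (i in 2:n) {
    sc <- ifelse(qi[i] == ti, 1, -1)
    prevrow <- S[i - 1, ]
    diag <- c(NEG, prevrow[-m])
    # running max of prevrow up to j - min_intron - 1, with argmax
    best_j <- integer(m); best_v <- rep(NEG, m)
    runmax <- NEG; runarg <- 0L
    for (j in seq_len(m)) {
      jp <- j - min_intron - 1L
      if (jp >= 1L && prevrow[jp] > runmax) { runmax <- prevrow[jp]; runarg <- jp }
      best_v[j] <- runmax; best_j[j] <- runarg
    }
    intron <- best_v - 0.01
    take_intron <- intron > diag
    S[i, ] <- pmax(diag, intron) + sc
    from[i, ] <- ifelse(take_intron, best_j, 0L)
  }
  j <- which.max(S[n, ])
  blocks <- list()
  cur_qe <- n; cur_te <- j
  i <- n
  while (i >= 1L) {
    if (i == 1L) {
      blocks[[length(blocks) + 1L]] <-
        data.frame(q_start = i - 1L, q_end = cur_qe,
                   t_start = j - 1L, t_end = cur_te)
      break
    }
    if (from[i, j] > 0L) {
      blocks[[length(blocks) + 1L]] <-
        data.frame(q_start = i - 1L, q_end = cur_qe,
                   t_start = j - 1L, t_end = cur_te)
      j <- from[i, j]
      cur_qe <- i - 1L; cur_te <- j
      i <- i - 1L
    } else {
      i <- i - 1L; j <- j - 1L
    }
  }
  do.call(rbind, rev(blocks))
}

# slide every query-contiguous block boundary maximally left while the match
# count is preserved: a canonical representative of the slide-equivalence
# class of a spliced alignment, so two optimal alignments can be compared
normalize_blocks <- function(query, target, blocks) {
  if (nrow(blocks) < 2L) return(blocks)
  qi <- utf8ToInt(query); ti <- utf8ToInt(target)
  for (i in seq_len(nrow(blocks) - 1L)) {
    if (blocks$q_start[i + 1L] != blocks$q_end[i]) next
    x0 <- blocks$q_end[i]
    l <- 0L
    while (x0 - l - 1L > blocks$q_start[i] &&
           blocks$t_start[i + 1L] - l - 1L >= 1L &&
           qi[x0 - l] == ti[blocks$t_start[i + 1L] - l] &&
           qi[x0 - l] == ti[blocks$t_end[i] - l])
      l <- l + 1L
    if (l > 0L) {
      blocks$q_end[i] <- x0 - l
      blocks$t_end[i] <- blocks$t_end[i] - l
      blocks$q_start[i + 1L] <- x0 - l
      blocks$t_start[i + 1L] <- blocks$t_start[i + 1L] - l
    }
  }
  blocks
}

# exact rank-sum tail probabilities by enumerating group-B index subsets
# (independent route: enumerates the complement and derives W_A)
ranksum_oracle <- function(a, b) {
  n <- length(a) + length(b)
  r <- rank(c(a, b))
  W <- sum(r[seq_along(a)])
  tot <- sum(r)
  cmb <- combn(n, length(b))
  WB <- colSums(matrix(r[cmb], nrow = length(b)))
  WA <- tot - WB
  eps <- 1e-8
  min(1, 2 * min(mean(WA <= W + eps), mean(WA >= W - eps)))
}

# exhaustive ATG..stop enumeration on the sense strand
orf_oracle <- function(seq) {
  n <- nchar(seq)
  best <- NULL
  for (p in seq_len(max(0, n - 2L))) {
    if (substr(seq, p, p + 2L) != "ATG") next
    e <- n
    q <- p
    while (q + 2L <= n) {
      cod <- substr(seq, q, q + 2L)
      if (q > p && cod %in% c("TAA", "TAG", "TGA")) { e <- q + 2L; break }
      q <- q + 3L
    }
    len <- e - p + 1L
    if (is.null(best) || len > best$len) best <- list(start = p - 1L,
                                                      end = e, len = len)
  }
  best
}

# direct sup-difference KS statistic against Normal(mu, sd)
ks_D_oracle <- function(x, mu, s) {
  x <- sort(x)
  n <- length(x)
  Fx <- pnorm(x, mu, s)
  max(pmax(abs(seq_len(n) / n - Fx), abs((seq_len(n) - 1L) / n - Fx)))
}

# a tiny deterministic PSL row builder for unit tests
psl_row <- function(qName = "q1", qSize = 500L, qStart = 0L, qEnd = 200L,
                    tName = "chr1", tSize = 10000L, tStart = 1000L,
                    tEnd = 1200L, strand = "+", matches = NULL,
                    misMatches = 0L, blockSizes = NULL, qStarts = NULL,
                    tStarts = NULL) {
  if (is.null(blockSizes)) blockSizes <- paste0(qEnd - qStart, ",")
  if (is.null(qStarts)) qStarts <- paste0(qStart, ",")
  if (is.null(tStarts)) tStarts <- paste0(tStart, ",")
  bs <- as.integer(strsplit(sub(",$", "", blockSizes), ",")[[1]])
  if (is.null(matches)) matches <- sum(bs) - misMatches
  data.frame(matches = matches, misMatches = misMatches, repMatches = 0L,
             nCount = 0L, qNumInsert = 0L, qBaseInsert = 0L, tNumInsert = 0L,
             tBaseInsert = 0L, strand = strand, qName = qName, qSize = qSize,
             qStart = qStart, qEnd = qEnd, tName = tName, tSize = tSize,
             tStart = tStart, tEnd = tEnd, blockCount = length(bs),
             blockSizes = blockSizes, qStarts = qStarts, tStarts = tStarts,
             stringsAsFactors = FALSE)
}

random_dna_oracle <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
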