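# Trans-splice verification: build an artificially fused genomic reference
# for a candidate, spliced-align the transcript to it, and inspect the fusion
# point for junction precision, GT-AG splice signals and reading-frame
# integrity.

#' Build an artificially fused genomic reference for a candidate
#'
#' Joins the genomic region of the 5' partner (plus `flank` nt of context on
#' both sides, clipped at chromosome edges) to that of the 3' partner, each
#' segment oriented so the fused sequence reads 5'->3' in transcript
#' orientation (minus-strand segments are reverse-complemented).
#'
#' @param genome Named character vector of chromosome sequences.
#' @param candidate A chimera candidate ([pair_partners()]).
#' @param flank Flank length in nt (default 500).
#' @return List of class `fused_reference`: `seq`, `boundary` (offset of the
#'   artificial join, = length of the 5' segment), and `maps` (two coordinate
#'   maps fused -> genomic).
#' @export
build_fused_reference <- function(genome, candidate, flank = 500L) {
  seg <- function(p) {
    chrom <- p$tName
    if (!chrom %in% names(genome)) stop("locus on unknown chromosome: ", chrom)
    clen <- nchar(genome[[chrom]])
    if (p$tStart < 0 || p$tEnd > clen) stop("locus outside chromosome bounds")
    gs <- max(0L, p$tStart - flank)
    ge <- min(clen, p$tEnd + flank)
    s <- subseq0(genome[[chrom]], gs, ge)
    if (p$strand == "-") s <- revcomp(s)
    list(seq = s, chrom = chrom, g_start = gs, g_end = ge, strand = p$strand)
  }
  s5 <- seg(candidate$p5)
  s3 <- seg(candidate$p3)
  structure(list(seq = paste0(s5$seq, s3$seq), boundary = nchar(s5$seq),
                 maps = list(s5[-1], s3[-1])),
            class = "fused_reference")
}

#' Map a fused-reference position to genomic coordinates
#' @param fref A [build_fused_reference()] object.
#' @param pos 0-based position(s) on the fused sequence.
#' @return data.frame with chrom, pos (0-based genomic), strand, segment.
#' @export
fused_to_genomic <- function(fref, pos) {
  segi <- ifelse(pos < fref$boundary, 1L, 2L)
  out <- lapply(seq_along(pos), function(i) {
    m <- fref$maps[[segi[i]]]
    off <- if (segi[i] == 1L) pos[i] else pos[i] - fref$boundary
    g <- if (m$strand == "+") m$g_start + off else m$g_end - 1L - off
    data.frame(chrom = m$chrom, pos = g, strand = m$strand, segment = segi[i],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Map genomic coordinates back to the fused reference
#' @param fref A [build_fused_reference()] object.
#' @param chrom,pos,segment Genomic chromosome/0-based position and segment
#'   index (1 = 5' partner, 2 = 3' partner).
#' @export
genomic_to_fused <- function(fref, chrom, pos, segment) {
  m <- fref$maps[[segment]]
  stopifnot(chrom == m$chrom, pos >= m$g_start, pos < m$g_end)
  off <- if (m$strand == "+") pos - m$g_start else m$g_end - 1L - pos
  if (segment == 2L) off + fref$boundary else off
}

# collapse exact seed hits on one diagonal into maximal segments, then merge
# same-diagonal segments across mismatch runs while the block mismatch rate
# stays within `max_mm_rate`
.collapse_seeds <- function(hits, query, target, seed_len, max_mm_rate) {
  setorder(hits, diag, q)
  newrun <- c(TRUE, diff(hits$q) != 1L | diff(hits$diag) != 0L)
  hits[, run := cumsum(newrun)]
  segs <- hits[, list(diag = diag[1], qs = q[1], qe = q[.N] + seed_len - 1L),
               by = "run"]
  segs[, `:=`(ts = qs + diag, te = qe + diag, mm = 0L)]
  out <- list()
  for (d in unique(segs$diag)) {
    ss <- segs[segs$diag == d][order(qs)]
    cur <- as.list(ss[1])
    if (nrow(ss) > 1) for (i in 2:nrow(ss)) {
      gap_q <- ss$qs[i] - cur$qe - 1L
      if (gap_q > 0) {
        a <- subseq0(query, cur$qe, cur$qe + gap_q)
        b <- subseq0(target, cur$te, cur$te + gap_q)
        gap_mm <- sum(utf8ToInt(a) != utf8ToInt(b))
      } else gap_mm <- 0L
      merged_len <- ss$qe[i] - cur$qs + 1L
      if (gap_q >= 0 && (cur$mm + gap_mm) / merged_len <= max_mm_rate) {
        cur$qe <- ss$qe[i]; cur$te <- ss$te[i]; cur$mm <- cur$mm + gap_mm
      } else {
        out[[length(out) + 1L]] <- cur
        cur <- as.list(ss[i])
      }
    }
    out[[length(out) + 1L]] <- cur
  }
  rbindlist(lapply(out, function(x) x[c("qs", "qe", "ts", "te", "mm")]))
}

#' Spliced alignment of a transcript to a (fused) genomic sequence
#'
#' A simplified spliced aligner: exact seed matches of length `seed_len` are
#' collapsed along diagonals into ungapped blocks (tolerating mismatches up to
#' a 4% per-block rate), then chained colinearly in query and target; target
#' gaps of at least `min_intron` nt between chained blocks are introns.
#'
#' @param mrna_seq Transcript sequence (character scalar).
#' @param fused_ref A [build_fused_reference()] object, or a plain character
#'   target sequence.
#' @param min_intron Minimum intron length in nt.
#' @param seed_len Exact seed length in nt.
#' @param max_mm_rate Maximum per-block mismatch rate.
#' @return List with `status` ("ok" or "failed"), `blocks` (data.frame with
#'   0-based half-open q_start/q_end/t_start/t_end and mismatches) and
#'   `q_aligned` (fraction of the query covered). Status is "failed" when
#'   less than half of the query aligns.
#' @export
spliced_align <- function(mrna_seq, fused_ref, min_intron = 30L,
                          seed_len = 12L, max_mm_rate = 0.04) {
  target <- if (inherits(fused_ref, "fused_reference")) fused_ref$seq else fused_ref
  nq <- nchar(mrna_seq); nt <- nchar(target)
  stopifnot(nq >= 2L * seed_len)
  qk <- substring(mrna_seq, 1:(nq - seed_len + 1L), seed_len:nq)
  tk <- substring(target, 1:(nt - seed_len + 1L), seed_len:nt)
  idx <- data.table(kmer = tk, t = seq_along(tk))
  qdt <- data.table(kmer = qk, q = seq_along(qk))
  hits <- idx[qdt, on = "kmer", allow.cartesian = TRUE, nomatch = NULL]
  failed <- list(status = "failed", blocks = NULL, q_aligned = 0)
  if (!nrow(hits)) return(failed)
  hits[, diag := t - q]
  segs <- .collapse_seeds(hits, mrna_seq, target, seed_len, max_mm_rate)
  # chain: colinear in q and t, maximise matched bases, small penalty per
  # gap; segments may overlap by a few bases in the query (exon-boundary
  # ambiguity) and the later segment is trimmed at chain reconstruction
  segs <- segs[order(qs, ts)]
  n <- nrow(segs)
  max_ovl <- 2L * seed_len
  score <- segs$qe - segs$qs + 1L - 2L * segs$mm
  best <- as.numeric(score)
  prev <- rep(NA_integer_, n)
  trim <- rep(0L, n)
  if (n > 1) for (i in 2:n) {
    for (j in 1:(i - 1)) {
      o <- max(0L, segs$qe[j] - segs$qs[i] + 1L)
      if (o > max_ovl || segs$qs[i] + o > segs$qe[i]) next
      if (segs$te[j] >= segs$ts[i] + o) next
      cand <- best[j] + score[i] - o - 0.5
      if (cand > best[i]) { best[i] <- cand; prev[i] <- j; trim[i] <- o }
    }
  }
  end <- which.max(best)
  chain <- end
  while (!is.na(prev[chain[1]])) chain <- c(prev[chain[1]], chain)
  bl <- segs[chain]
  tr <- trim[chain]
  tr[1] <- 0L
  blocks <- data.frame(q_start = bl$qs - 1L + tr, q_end = bl$qe,
                       t_start = bl$ts - 1L + tr, t_end = bl$te,
                       mismatches = bl$mm)
  blocks <- .slide_introns(mrna_seq, target, blocks)
  q_aligned <- sum(blocks$q_end - blocks$q_start) / nq
  if (q_aligned < 0.5) return(failed)
  list(status = "ok", blocks = blocks, q_aligned = q_aligned)
}

# Resolve intron-boundary ambiguity the way splice-aware aligners do: when
# the split between two query-contiguous blocks can slide without changing
# the match count (transcript bases equal on both target sides), prefer the
# split whose intron boundaries read GT..AG.
.slide_introns <- function(query, target, blocks) {
  if (nrow(blocks) < 2L) return(blocks)
  qi <- utf8ToInt(query); ti <- utf8ToInt(target)
  din <- function(at) intToUtf8(ti[(at + 1L):(at + 2L)])
  for (i in seq_len(nrow(blocks) - 1L)) {
    if (blocks$q_start[i + 1L] != blocks$q_end[i]) next  # query gap: keep
    x0 <- blocks$q_end[i]
    lmax <- 0L
    while (x0 - lmax - 1L > blocks$q_start[i] &&
           blocks$t_start[i + 1L] - lmax - 1L >= 1L &&
           qi[x0 - lmax] == ti[blocks$t_start[i + 1L] - lmax])
      lmax <- lmax + 1L
    rmax <- 0L
    while (x0 + rmax + 1L < blocks$q_end[i + 1L] &&
           blocks$t_end[i] + rmax + 1L <= length(ti) &&
           qi[x0 + rmax + 1L] == ti[blocks$t_end[i] + rmax + 1L])
      rmax <- rmax + 1L
    if (lmax == 0L && rmax == 0L) next
    shifts <- order(abs(seq(-lmax, rmax)))  # prefer the smallest |shift|
    for (s in seq(-lmax, rmax)[shifts]) {
      d_at <- blocks$t_end[i] + s
      a_at <- blocks$t_start[i + 1L] + s - 2L
      if (d_at + 2L > length(ti) || a_at < 1L) next
      if (din(d_at) == "GT" && din(a_at - 0L) == "AG") {
        blocks$q_end[i] <- x0 + s
        blocks$t_end[i] <- blocks$t_end[i] + s
        blocks$q_start[i + 1L] <- x0 + s
        blocks$t_start[i + 1L] <- blocks$t_start[i + 1L] + s
        break
      }
    }
  }
  blocks
}

#' Is the fusion point aligned precisely, without gap or overlap?
#'
#' TRUE iff some block ends exactly at query position `junction_q`, the next
#' block begins exactly there, and the two blocks lie on opposite sides of the
#' fused reference's boundary.
#'
#' @param blocks Block table from [spliced_align()].
#' @param junction_q 0-based transcript coordinate of the fusion point.
#' @param fused_ref The [build_fused_reference()] object (or its boundary).
#' @export
check_junction <- function(blocks, junction_q, fused_ref) {
  boundary <- if (inherits(fused_ref, "fused_reference")) fused_ref$boundary
              else fused_ref
  if (is.null(blocks) || nrow(blocks) < 2L) return(FALSE)
  for (i in seq_len(nrow(blocks) - 1L)) {
    if (blocks$q_end[i] == junction_q && blocks$q_start[i + 1L] == junction_q &&
        blocks$t_end[i] <= boundary && blocks$t_start[i + 1L] >= boundary)
      return(TRUE)
  }
  FALSE
}

#' Donor/acceptor dinucleotides at the trans-junction
#'
#' The donor is the 2-mer immediately 3' of the last 5'-side block on the
#' fused reference, the acceptor the 2-mer immediately 5' of the first 3'-side
#' block; canonical means donor "GT" and acceptor "AG" on the transcribed
#' strand (minus-strand partners are already oriented by
#' [build_fused_reference()]).
#'
#' @param fused_ref A [build_fused_reference()] object.
#' @param blocks Block table from [spliced_align()].
#' @return List with `donor`, `acceptor`, `canonical`, and `note` ("no-context"
#'   when the junction sits at a segment edge without flank).
#' @export
splice_signals <- function(fused_ref, blocks) {
  none <- list(donor = "NN", acceptor = "NN", canonical = FALSE,
               note = "no-context")
  if (is.null(blocks) || nrow(blocks) < 2L) return(none)
  i5 <- which(blocks$t_end <= fused_ref$boundary)
  if (!length(i5)) return(none)
  i <- max(i5)
  if (i >= nrow(blocks) || blocks$t_start[i + 1L] < fused_ref$boundary)
    return(none)
  n <- nchar(fused_ref$seq)
  d_at <- blocks$t_end[i]
  a_at <- blocks$t_start[i + 1L] - 2L
  if (d_at + 2L > fused_ref$boundary || a_at < fused_ref$boundary) return(none)
  donor <- subseq0(fused_ref$seq, d_at, d_at + 2L)
  acceptor <- subseq0(fused_ref$seq, a_at, a_at + 2L)
  list(donor = donor, acceptor = acceptor,
       canonical = donor == "GT" && acceptor == "AG", note = NULL)
}

#' Longest open reading frame of a transcript (sense strand)
#'
#' Scans the three forward frames for ATG..stop runs (standard genetic code);
#' an ORF reaching the transcript end without a stop is allowed. Ties go to
#' the leftmost ORF.
#'
#' @param seq Transcript sequence.
#' @return List with `start`, `end` (0-based half-open, stop codon included)
#'   or NULL when no ATG exists.
#' @export
longest_orf <- function(seq) {
  n <- nchar(seq)
  stops <- c("TAA", "TAG", "TGA")
  best <- NULL
  codons_at <- function(f) {
    starts <- seq(f + 1L, n - 2L, by = 3L)
    substring(seq, starts, starts + 2L)
  }
  for (f in 0:2) {
    if (n - f < 3L) next
    cod <- codons_at(f)
    atg <- which(cod == "ATG")
    if (!length(atg)) next
    stp <- which(cod %in% stops)
    for (a in atg) {
      s_after <- stp[stp >= a]
      e <- if (length(s_after)) f + 3L * s_after[1] else n
      s <- f + 3L * (a - 1L)
      if (is.null(best) || (e - s) > (best$end - best$start) ||
          ((e - s) == (best$end - best$start) && s < best$start))
        best <- list(start = s, end = as.integer(e))
    }
  }
  best
}

#' Does the longest ORF of the chimera span the fusion point?
#'
#' @param mrna_seq Transcript sequence.
#' @param junction_q 0-based fusion-point coordinate.
#' @return TRUE iff the longest open reading frame strictly spans
#'   `junction_q`.
#' @export
check_reading_frame <- function(mrna_seq, junction_q) {
  orf <- longest_orf(mrna_seq)
  if (is.null(orf)) return(FALSE)
  orf$start < junction_q && junction_q < orf$end
}

#' Verify chimera candidates at the fusion point
#'
#' Runs the full verification for each candidate: fused-reference
#' construction, spliced alignment, junction precision, splice signals and
#' reading-frame integrity.
#'
#' @param candidates List of chimera candidates.
#' @param genome Named character vector of chromosomes.
#' @param mrna_seqs Named character vector of transcript sequences.
#' @param flank,min_intron,seed_len See [build_fused_reference()] and
#'   [spliced_align()].
#' @return data.frame in the `verified` report schema (status "ok" or
#'   "unverifiable").
#' @export
verify_candidates <- function(candidates, genome, mrna_seqs, flank = 500L,
                              min_intron = 30L, seed_len = 12L) {
  rows <- lapply(candidates, function(cd) {
    seq <- mrna_seqs[[cd$mrna_id]]
    if (is.null(seq)) stop("no transcript sequence for ", cd$mrna_id)
    fref <- build_fused_reference(genome, cd, flank)
    al <- spliced_align(seq, fref, min_intron, seed_len)
    if (al$status != "ok")
      return(data.frame(mrna_id = cd$mrna_id, status = "unverifiable",
                        aligned_precisely = FALSE, donor = "NN",
                        acceptor = "NN", canonical = FALSE, frame_ok = FALSE,
                        stringsAsFactors = FALSE))
    precise <- check_junction(al$blocks, cd$junction_q, fref)
    sig <- splice_signals(fref, al$blocks)
    data.frame(mrna_id = cd$mrna_id, status = "ok",
               aligned_precisely = precise, donor = sig$donor,
               acceptor = sig$acceptor, canonical = sig$canonical,
               frame_ok = check_reading_frame(seq, cd$junction_q),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
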