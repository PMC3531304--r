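# Junction-read quantification from single-end RNA-seq: read QC/trimming, an
# exact k-mer pigeonhole mapper (ungapped, <=N mismatches), junction-reference
# construction with overhang windows, junction-read calling, event validation
# and per-base coverage.

#' Junction quantification parameters
#'
#' With read length L and minimum overhang k, the junction reference is
#' 2*(L-k) nt long (L-k on either side of the fusion point) and a junction
#' read must start within positions 1 .. L-2k+1 (1-based) of the reference.
#' Defaults: L = 76, k = 5, at most 2 mismatches, and an event is validated
#' by junction reads from >= 3 distinct start positions or >= 3 samples.
#'
#' @param L Read length in nt.
#' @param k Minimum overhang on either side of the fusion point.
#' @param max_mismatches Mismatch cap for ungapped alignment.
#' @param min_starts,min_samples Validation thresholds.
#' @return List of class `junction_params` with derived fields `ref_len`,
#'   `fusion_offset` and `last_start`.
#' @export
junction_params <- function(L = 76L, k = 5L, max_mismatches = 2L,
                            min_starts = 3L, min_samples = 3L) {
  L <- as.integer(L); k <- as.integer(k)
  stopifnot(L > 2L * k, k >= 1L, max_mismatches >= 0L)
  structure(list(L = L, k = k, max_mismatches = as.integer(max_mismatches),
                 min_starts = as.integer(min_starts),
                 min_samples = as.integer(min_samples),
                 ref_len = 2L * (L - k), fusion_offset = L - k,
                 last_start = L - 2L * k + 1L),
            class = "junction_params")
}

#' Quality-trim single-end reads
#'
#' Reads longer than `target_len` are truncated from the (low-quality) right
#' end; reads shorter than `target_len` are removed; reads whose Phred
#' quality fails the rule (`mode = "mean"`: mean Phred < `min_q`; `"min"`:
#' any base < `min_q`) are removed.
#'
#' @param reads data.frame of reads ([read_fastq()]).
#' @param target_len Uniform read length after trimming.
#' @param min_q Phred threshold.
#' @param mode "mean" (default) or "min".
#' @return The cleaned reads data.frame.
#' @export
qc_trim <- function(reads, target_len = 76L, min_q = 20, mode = c("mean", "min")) {
  mode <- match.arg(mode)
  reads <- reads[nchar(reads$seq) >= target_len, , drop = FALSE]
  if (!nrow(reads)) return(reads)
  reads$seq <- substr(reads$seq, 1L, target_len)
  reads$qual <- substr(reads$qual, 1L, target_len)
  ph <- decode_phred(reads$qual)
  stat <- vapply(ph, if (mode == "mean") mean else min, 0)
  reads[stat >= min_q, , drop = FALSE]
}

# k-mer index of reference sequences: data.table (kmer, ref, pos0) keyed on kmer
.kmer_index <- function(refs, k) {
  rbindlist(lapply(names(refs), function(nm) {
    n <- nchar(refs[[nm]])
    if (n < k) return(NULL)
    data.table(kmer = substring(refs[[nm]], 1:(n - k + 1L), k:n),
               ref = nm, pos0 = 0:(n - k))
  }))
}

# exact all-hits ungapped mapper: pigeonhole seeding with max_mm+1 disjoint
# segments guarantees every alignment with <= max_mm mismatches is found.
# reads: data.frame with seq (all the same length); refs: named character.
# returns data.table (read_idx, ref, pos0, strand, mm) with mm <= max_mm.
.hamming_map <- function(reads, refs, max_mm) {
  L <- unique(nchar(reads$seq))
  stopifnot(length(L) == 1L)
  a <- L %/% (max_mm + 1L)
  stopifnot(a >= 8L)
  idx <- .kmer_index(refs, a)
  setkey(idx, kmer)
  offs <- (0:max_mm) * a
  seqs <- list(`+` = reads$seq, `-` = revcomp(reads$seq))
  cand <- list()
  for (strand in c("+", "-")) {
    s <- seqs[[strand]]
    for (off in offs) {
      q <- data.table(kmer = substr(s, off + 1L, off + a),
                      read_idx = seq_along(s))
      h <- idx[q, on = "kmer", allow.cartesian = TRUE, nomatch = NULL]
      if (nrow(h)) {
        h[, `:=`(pos0 = pos0 - off, strand = strand)]
        cand[[length(cand) + 1L]] <- h[, list(read_idx, ref, pos0, strand)]
      }
    }
  }
  if (!length(cand))
    return(data.table(read_idx = integer(0), ref = character(0),
                      pos0 = integer(0), strand = character(0), mm = integer(0)))
  cand <- unique(rbindlist(cand))
  cand <- cand[pos0 >= 0L]
  cand[, ref_len := nchar(refs)[ref]]
  cand <- cand[pos0 + L <= ref_len]
  if (!nrow(cand))
    return(data.table(read_idx = integer(0), ref = character(0),
                      pos0 = integer(0), strand = character(0), mm = integer(0)))
  tgt <- substring(refs[cand$ref], cand$pos0 + 1L, cand$pos0 + L)
  rd <- ifelse(cand$strand == "+", reads$seq[cand$read_idx],
               seqs[["-"]][cand$read_idx])
  cand[, mm := hamming_vec(rd, tgt)]
  cand[mm <= max_mm, list(read_idx, ref, pos0, strand, mm)]
}

#' Map reads to a genome, classifying unique / multi / unmapped
#'
#' Ungapped (Hamming) mapping with at most `max_mismatches` mismatches on
#' either strand, via exact pigeonhole k-mer seeding: a read is `unique` iff
#' exactly one genomic position aligns, `multi` if more than one, `unmapped`
#' if none. The classification equals a brute-force scan of all positions.
#'
#' @param reads data.frame of reads (uniform length; see [qc_trim()]).
#' @param genome Named character vector of chromosomes.
#' @param max_mismatches Mismatch cap.
#' @return List with `assignments` (reads plus status/chrom/pos0/strand/mm
#'   columns) and `hits` (all hits, for multi-mapped inspection).
#' @export
map_genome <- function(reads, genome, max_mismatches = 2L) {
  check_genome(genome)
  out <- reads
  out$status <- "unmapped"
  out$chrom <- NA_character_; out$pos0 <- NA_integer_
  out$strand <- NA_character_; out$mm <- NA_integer_
  if (!nrow(reads)) return(list(assignments = out, hits = NULL))
  hits <- .hamming_map(reads, genome, max_mismatches)
  if (nrow(hits)) {
    nh <- hits[, .N, by = "read_idx"]
    uni <- nh$read_idx[nh$N == 1L]
    mul <- nh$read_idx[nh$N > 1L]
    out$status[mul] <- "multi"
    out$status[uni] <- "unique"
    hu <- hits[hits$read_idx %in% uni]
    out$chrom[hu$read_idx] <- hu$ref
    out$pos0[hu$read_idx] <- hu$pos0
    out$strand[hu$read_idx] <- hu$strand
    out$mm[hu$read_idx] <- hu$mm
  }
  list(assignments = out, hits = hits)
}

#' Build junction references for chimeric events
#'
#' The reference of an event is the last L-k nt of the 5' part joined to the
#' first L-k nt of the 3' part (with L and k from `params`). Events with a
#' side shorter than L-k are built clipped and flagged; clipped references
#' are excluded from the start-window arithmetic downstream.
#'
#' @param chimera_seqs Named character vector of chimera sequences.
#' @param junctions Named integer vector of 0-based fusion points.
#' @param params [junction_params()].
#' @return data.frame with event_id, seq, fusion_offset, clipped.
#' @export
build_junction_refs <- function(chimera_seqs, junctions, params = junction_params()) {
  side <- params$fusion_offset
  rows <- lapply(names(chimera_seqs), function(id) {
    s <- chimera_seqs[[id]]
    jq <- junctions[[id]]
    n <- nchar(s)
    left <- min(side, jq)
    right <- min(side, n - jq)
    data.frame(event_id = id,
               seq = subseq0(s, jq - left, jq + right),
               fusion_offset = left,
               clipped = left < side || right < side,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Call junction reads against junction references
#'
#' A hit requires an ungapped alignment (either orientation) to a junction
#' reference with at most `max_mismatches` mismatches and a start position
#' within 1 .. L-2k+1 (1-based), which enforces the k-nt overhang on both
#' sides of the fusion point. A read matching several references is assigned
#' to the one with the fewest mismatches; ties are flagged `shared` and
#' excluded from unique-event analysis.
#'
#' @param unmapped_reads data.frame of genome-unmapped reads.
#' @param junction_refs data.frame from [build_junction_refs()].
#' @param params [junction_params()].
#' @return data.frame of hits: read_id, sample_id, event_id, start_1based,
#'   mismatches, shared.
#' @export
call_junction_reads <- function(unmapped_reads, junction_refs,
                                params = junction_params()) {
  empty <- data.frame(read_id = character(0), sample_id = character(0),
                      event_id = character(0), start_1based = integer(0),
                      mismatches = integer(0), shared = logical(0))
  refs_use <- junction_refs[!junction_refs$clipped, , drop = FALSE]
  if (!nrow(unmapped_reads) || !nrow(refs_use)) return(empty)
  refs <- setNames(refs_use$seq, refs_use$event_id)
  hits <- .hamming_map(unmapped_reads, refs, params$max_mismatches)
  if (!nrow(hits)) return(empty)
  hits <- hits[pos0 + 1L >= 1L & pos0 + 1L <= params$last_start]
  if (!nrow(hits)) return(empty)
  # best (fewest-mismatch) assignment per read; ties across events -> shared
  hits[, best := min(mm), by = "read_idx"]
  hits <- hits[mm == best]
  hits[, n_events := length(unique(ref)), by = "read_idx"]
  hits[, shared := n_events > 1L]
  # one row per read x event (lowest start wins if a read matches twice)
  setorder(hits, read_idx, ref, pos0)
  hits <- hits[, head(.SD, 1L), by = c("read_idx", "ref")]
  data.frame(read_id = unmapped_reads$read_id[hits$read_idx],
             sample_id = unmapped_reads$sample_id[hits$read_idx],
             event_id = hits$ref, start_1based = hits$pos0 + 1L,
             mismatches = hits$mm, shared = hits$shared,
             stringsAsFactors = FALSE)
}

#' Validate chimeric events from junction-read evidence
#'
#' An event is validated iff its (non-shared) junction reads come from at
#' least `min_starts` distinct start positions or at least `min_samples`
#' distinct samples.
#'
#' @param hits data.frame from [call_junction_reads()].
#' @param params [junction_params()].
#' @param all_events Optional character vector of event ids to report even
#'   with zero reads.
#' @return data.frame in the `validation` report schema.
#' @export
validate_events <- function(hits, params = junction_params(), all_events = NULL) {
  hits <- hits[!hits$shared, , drop = FALSE]
  ids <- union(all_events %||% character(0), unique(hits$event_id))
  rows <- lapply(ids, function(ev) {
    h <- hits[hits$event_id == ev, , drop = FALSE]
    ns <- length(unique(h$start_1based))
    np <- length(unique(h$sample_id))
    data.frame(event_id = ev, n_reads = nrow(h), n_start_positions = ns,
               n_samples = np,
               validated = ns >= params$min_starts || np >= params$min_samples,
               stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(event_id = character(0), n_reads = integer(0),
                      n_start_positions = integer(0), n_samples = integer(0),
                      validated = logical(0)))
  do.call(rbind, rows)
}

#' Junction-read count matrix (events x samples)
#' @param hits data.frame from [call_junction_reads()] (shared hits dropped).
#' @param samples Optional character vector fixing the sample columns.
#' @return Integer matrix, events in rows, samples in columns.
#' @export
junction_count_matrix <- function(hits, samples = NULL) {
  hits <- hits[!hits$shared, , drop = FALSE]
  samples <- samples %||% sort(unique(hits$sample_id))
  events <- sort(unique(hits$event_id))
  m <- matrix(0L, length(events), length(samples),
              dimnames = list(events, samples))
  if (nrow(hits)) {
    tb <- table(hits$event_id, hits$sample_id)
    m[rownames(tb), colnames(tb)] <- tb
  }
  m
}

#' Per-base read coverage along a transcript
#'
#' @param intervals data.frame with 0-based half-open columns start0, end0
#'   (read placements on the transcript; pool genome-unique hits mapped back
#'   to transcript coordinates with junction-read placements).
#' @param transcript_len Transcript length.
#' @return Integer vector of length `transcript_len`; element i is the number
#'   of reads covering position i-1.
#' @export
coverage_profile <- function(intervals, transcript_len) {
  d <- integer(transcript_len + 1L)
  if (!is.null(intervals) && nrow(intervals)) {
    s <- pmax(intervals$start0, 0L)
    e <- pmin(intervals$end0, transcript_len)
    for (i in seq_along(s)) {
      if (s[i] < e[i]) {
        d[s[i] + 1L] <- d[s[i] + 1L] + 1L
        d[e[i] + 1L] <- d[e[i] + 1L] - 1L
      }
    }
  }
  cumsum(d[seq_len(transcript_len)])
}

#' Map genome-unique read hits into transcript coordinates
#'
#' A genome-mapped read contributes to a chimera's coverage when its genomic
#' interval lies entirely within one aligned block of either partner; the
#' block's coordinate map then places it on the transcript.
#'
#' @param assignments data.frame from [map_genome()] (`status == "unique"`).
#' @param candidate A chimera candidate.
#' @return data.frame with start0/end0 transcript intervals.
#' @export
genome_hits_on_transcript <- function(assignments, candidate) {
  u <- assignments[assignments$status == "unique", , drop = FALSE]
  out <- list()
  for (part in c("p5", "p3")) {
    p <- candidate[[part]]
    bl <- psl_blocks(p)
    L <- nchar(u$seq)
    for (b in seq_len(nrow(bl))) {
      t0 <- bl$tStart[b]; t1 <- t0 + bl$size[b]
      sel <- which(u$chrom == p$tName & u$pos0 >= t0 & (u$pos0 + L) <= t1)
      if (!length(sel)) next
      off <- u$pos0[sel] - t0
      q0 <- if (p$strand == "+") bl$qStart[b] + off
            else bl$qStart[b] + (t1 - (u$pos0[sel] + L[sel]))
      out[[length(out) + 1L]] <- data.frame(start0 = q0, end0 = q0 + L[sel])
    }
  }
  if (!length(out)) return(data.frame(start0 = integer(0), end0 = integer(0)))
  do.call(rbind, out)
}
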