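# Chimera discovery from per-transcript split alignments: identity/length
# filtering, partner pairing under the junction gap/overlap rule, and fusion
# geometry classification.

#' Discovery parameters
#'
#' Defaults follow the original screen: alignments need at least 96% identity
#' and 100 aligned nt, and the two partner alignments may leave a gap or
#' overlap of at most 10 nt at the fusion junction on the transcript. Two
#' same-strand loci in colinear (cis-consistent) order only count as
#' non-contiguous when separated by more than `max_intron`.
#'
#' @param min_identity Minimum alignment identity (fraction).
#' @param min_align_len Minimum aligned query length in nt.
#' @param max_junction_gap Maximum absolute gap/overlap at the junction in nt.
#' @param max_intron Maximum separation (nt) for which a colinear same-strand
#'   pair is still considered one cis transcript.
#' @return List of class `discovery_params`.
#' @export
discovery_params <- function(min_identity = 0.96, min_align_len = 100L,
                             max_junction_gap = 10L, max_intron = 1000000L) {
  stopifnot(min_identity > 0, min_identity <= 1, min_align_len >= 1,
            max_junction_gap >= 0, max_intron >= 0)
  structure(list(min_identity = min_identity,
                 min_align_len = as.integer(min_align_len),
                 max_junction_gap = as.integer(max_junction_gap),
                 max_intron = as.integer(max_intron)),
            class = "discovery_params")
}

#' Filter alignment records on identity and aligned length
#'
#' A record is kept iff identity >= `min_identity` and its aligned query
#' length (qEnd - qStart) >= `min_align_len`; both boundaries inclusive.
#'
#' @param aln data.frame of alignment records ([read_psl()]).
#' @param params [discovery_params()].
#' @param detail If TRUE, also return the dropped records with the name of the
#'   violated filter.
#' @return The kept records, or (with `detail = TRUE`) a list with elements
#'   `kept` and `dropped` (the latter with a `reason` column).
#' @export
filter_alignments <- function(aln, params = discovery_params(), detail = FALSE) {
  id_ok <- alignment_identity(aln) >= params$min_identity
  len_ok <- (aln$qEnd - aln$qStart) >= params$min_align_len
  keep <- id_ok & len_ok
  if (!detail) return(aln[keep, , drop = FALSE])
  reason <- character(nrow(aln))
  reason[!id_ok] <- "identity"
  reason[!len_ok] <- ifelse(nzchar(reason[!len_ok]), "identity;length", "length")
  dropped <- aln[!keep, , drop = FALSE]
  dropped$reason <- reason[!keep]
  list(kept = aln[keep, , drop = FALSE], dropped = dropped)
}

# are two kept records for one query non-contiguous loci?
# returns TRUE/FALSE; r5 is the record with the smaller qStart
.non_contiguous <- function(r5, r3, params) {
  if (r5$tName != r3$tName) return(TRUE)
  if (r5$strand != r3$strand) return(TRUE)
  # transcription-direction coordinates: '+' as-is, '-' mirrored
  if (r5$strand == "+") {
    f <- c(r5$tStart, r5$tEnd); t3 <- c(r3$tStart, r3$tEnd)
  } else {
    f <- c(-r5$tEnd, -r5$tStart); t3 <- c(-r3$tEnd, -r3$tStart)
  }
  colinear <- t3[1] >= f[2]  # 3' part begins at/after 5' part end, cis order
  if (colinear) {
    gap <- t3[1] - f[2]
    return(gap > params$max_intron)
  }
  TRUE  # out of order or nested: inconsistent with a single cis transcript
}

#' Pair the two partner alignments of one transcript into a chimera candidate
#'
#' Requires exactly two kept records sharing a query name whose loci are
#' non-contiguous. The 5' partner is the record with the smaller qStart; the
#' signed junction gap is g = qStart(3') - qEnd(5') (positive = gap, negative
#' = overlap) and must satisfy |g| <= `max_junction_gap`.
#'
#' @param records data.frame of kept alignment records for one query.
#' @param params [discovery_params()].
#' @return List with `candidate` (or NULL) and `reason` (NULL or a string
#'   naming why no candidate was emitted).
#' @export
pair_partners <- function(records, params = discovery_params()) {
  if (length(unique(records$qName)) > 1L)
    stop("pair_partners expects records of a single query")
  n <- nrow(records)
  if (n < 2L) return(list(candidate = NULL, reason = "single_locus"))
  if (n > 2L) return(list(candidate = NULL, reason = "ambiguous multi-locus"))
  records <- records[order(records$qStart), , drop = FALSE]
  if (records$qStart[1] == records$qStart[2])
    return(list(candidate = NULL, reason = "ambiguous 5'/3' assignment"))
  r5 <- records[1, , drop = FALSE]
  r3 <- records[2, , drop = FALSE]
  if (!.non_contiguous(r5, r3, params))
    return(list(candidate = NULL, reason = "contiguous_loci"))
  g <- r3$qStart - r5$qEnd
  if (abs(g) > params$max_junction_gap)
    return(list(candidate = NULL, reason = "gap"))
  cand <- list(mrna_id = r5$qName, p5 = r5, p3 = r3,
               junction_q = r5$qEnd, g = as.integer(g))
  cand$fusion_class <- classify_fusion(cand)
  oc <- classify_order(cand)
  cand$order_type <- oc$order_type
  cand$order_note <- oc$note
  class(cand) <- "chimera_candidate"
  list(candidate = cand, reason = NULL)
}

#' Classify the fusion geometry of a candidate
#'
#' @param candidate A chimera candidate from [pair_partners()].
#' @return One of `inter_chromosomal`, `intra_inter_strand`,
#'   `intra_intra_strand`.
#' @export
classify_fusion <- function(candidate) {
  if (candidate$p5$tName != candidate$p3$tName) return("inter_chromosomal")
  if (candidate$p5$strand != candidate$p3$strand) return("intra_inter_strand")
  "intra_intra_strand"
}

#' Classify the genomic ordering of a same-strand intra-chromosomal candidate
#'
#' Coordinates are taken in the transcription direction of the shared strand:
#' `partner5_downstream` when the 5' partner begins after the 3' partner ends
#' (the dominant configuration), `nested_3p_in_5p` / `nested_5p_in_3p` for
#' nesting, and `colinear_readthrough` when the 5' partner ends before the 3'
#' partner begins. Other (partially overlapping) arrangements are ambiguous
#' and excluded from order tabulation.
#'
#' @param candidate A chimera candidate.
#' @return List with `order_type` and `note` (NULL or "ambiguous").
#' @export
classify_order <- function(candidate) {
  if (classify_fusion(candidate) != "intra_intra_strand")
    return(list(order_type = "not_applicable", note = NULL))
  p5 <- candidate$p5; p3 <- candidate$p3
  if (p5$strand == "+") {
    f <- c(p5$tStart, p5$tEnd); t3 <- c(p3$tStart, p3$tEnd)
  } else {
    f <- c(-p5$tEnd, -p5$tStart); t3 <- c(-p3$tEnd, -p3$tStart)
  }
  if (f[1] >= t3[2]) return(list(order_type = "partner5_downstream", note = NULL))
  if (f[2] <= t3[1]) return(list(order_type = "colinear_readthrough", note = NULL))
  if (t3[1] >= f[1] && t3[2] <= f[2])
    return(list(order_type = "nested_3p_in_5p", note = NULL))
  if (f[1] >= t3[1] && f[2] <= t3[2])
    return(list(order_type = "nested_5p_in_3p", note = NULL))
  list(order_type = "ambiguous", note = "ambiguous")
}

#' Discover chimera candidates from alignment records
#'
#' Applies [filter_alignments()], groups records by query and runs
#' [pair_partners()] on every query. Queries that yield no candidate are
#' logged with the reason; when the identity/length filter removed records of
#' a query that then has fewer than two loci, the log names that filter.
#'
#' @param aln data.frame of alignment records ([read_psl()]).
#' @param params [discovery_params()].
#' @return List with `candidates` (list of chimera candidates) and `log`
#'   (data.frame mrna_id / reason for every query without a candidate).
#' @export
discover_chimeras <- function(aln, params = discovery_params()) {
  fl <- filter_alignments(aln, params, detail = TRUE)
  kept_by_q <- split(seq_len(nrow(fl$kept)), fl$kept$qName)
  drop_by_q <- split(fl$dropped$reason, fl$dropped$qName)
  qnames <- unique(aln$qName)
  candidates <- list()
  log <- list()
  for (q in qnames) {
    rows <- fl$kept[kept_by_q[[q]] %||% integer(0), , drop = FALSE]
    if (nrow(rows) < 2L && !is.null(drop_by_q[[q]])) {
      reason <- paste(sort(unique(unlist(strsplit(drop_by_q[[q]], ";")))),
                      collapse = ";")
      log[[q]] <- data.frame(mrna_id = q, reason = reason)
      next
    }
    pr <- pair_partners(rows, params)
    if (is.null(pr$candidate)) {
      log[[q]] <- data.frame(mrna_id = q, reason = pr$reason)
    } else {
      candidates[[q]] <- pr$candidate
    }
  }
  list(candidates = candidates,
       log = if (length(log)) do.call(rbind, unname(log))
             else data.frame(mrna_id = character(0), reason = character(0)))
}

#' Tabulate chimera candidates as a report data.frame
#' @param candidates List of candidates from [discover_chimeras()].
#' @return data.frame in the `candidates` report schema.
#' @export
candidates_table <- function(candidates) {
  if (!length(candidates))
    return(data.frame(mrna_id = character(0), fusion_class = character(0),
                      order_type = character(0), gap_overlap = integer(0),
                      junction_q = integer(0), chrom5 = character(0),
                      strand5 = character(0), start5 = integer(0),
                      end5 = integer(0), chrom3 = character(0),
                      strand3 = character(0), start3 = integer(0),
                      end3 = integer(0)))
  do.call(rbind, lapply(candidates, function(cd) {
    data.frame(mrna_id = cd$mrna_id, fusion_class = cd$fusion_class,
               order_type = cd$order_type, gap_overlap = cd$g,
               junction_q = cd$junction_q,
               chrom5 = cd$p5$tName, strand5 = cd$p5$strand,
               start5 = cd$p5$tStart, end5 = cd$p5$tEnd,
               chrom3 = cd$p3$tName, strand3 = cd$p3$strand,
               start3 = cd$p3$tStart, end3 = cd$p3$tEnd,
               stringsAsFactors = FALSE)
  }))
}
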