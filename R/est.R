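# EST evidence for fusion junctions: a seeded local aligner (k-mer seeds on
# shared diagonals with exact best ungapped extension) and the spanning-EST
# support rule.

#' Seeded local alignment of two sequences
#'
#' Finds shared k-mers, and for every seed diagonal computes the
#' maximal-scoring ungapped segment containing the seed (match +1, mismatch
#' -1). The best segment across diagonals is returned. Designed for
#' high-identity, substitution-only comparisons.
#'
#' @param query,target Nucleotide sequences (character scalars).
#' @param min_identity Minimum identity of the reported alignment.
#' @param k Seed length.
#' @return NULL if no alignment with identity >= `min_identity` and length >=
#'   2k exists; otherwise a list with 0-based half-open `q_start`, `q_end`,
#'   `t_start`, `t_end`, `identity` and `score`.
#' @export
local_align <- function(query, target, min_identity = 0.96, k = 11L) {
  nq <- nchar(query); nt <- nchar(target)
  if (nq < k || nt < k) return(NULL)
  qk <- substring(query, 1:(nq - k + 1L), k:nq)
  tk <- substring(target, 1:(nt - k + 1L), k:nt)
  idx <- data.table(kmer = tk, t = seq_along(tk))
  qdt <- data.table(kmer = qk, q = seq_along(qk))
  hits <- idx[qdt, on = "kmer", allow.cartesian = TRUE, nomatch = NULL]
  if (!nrow(hits)) return(NULL)
  qi <- utf8ToInt(query); ti <- utf8ToInt(target)
  best <- NULL
  for (d in unique(hits$t - hits$q)) {
    # overlap of the two sequences on diagonal d (1-based query positions)
    q_lo <- max(1L, 1L - d); q_hi <- min(nq, nt - d)
    sc <- ifelse(qi[q_lo:q_hi] == ti[(q_lo:q_hi) + d], 1L, -1L)
    # maximal-scoring contiguous segment (Kadane with position recovery)
    cum <- cumsum(sc)
    run_min <- cummin(c(0L, cum[-length(cum)]))
    gains <- cum - run_min
    e <- which.max(gains)
    s <- which(c(0L, cum)[1:e] == run_min[e])[1]  # prefix index before start
    score <- gains[e]
    len <- e - s + 1L
    matches <- (score + len) / 2L
    cand <- list(q_start = q_lo + s - 2L, q_end = q_lo + e - 1L,
                 t_start = q_lo + s - 2L + d, t_end = q_lo + e - 1L + d,
                 identity = matches / len, score = score)
    if (is.null(best) || cand$score > best$score) best <- cand
  }
  if (is.null(best)) return(NULL)
  if (best$identity < min_identity ||
      (best$q_end - best$q_start) < 2L * k) return(NULL)
  best
}

#' EST spanning support for one chimera
#'
#' An EST hit is spanning iff its span on the chimera covers at least
#' `min_flank` nt on both sides of the fusion point, i.e. covers
#' `[fusion_point - min_flank, fusion_point + min_flank)`. Distinct EST ids
#' are counted once; the chimera is supported when at least `min_ests`
#' distinct ESTs span.
#'
#' @param hits data.frame with columns est_id, t_start, t_end (0-based
#'   half-open spans on the chimera).
#' @param fusion_point 0-based fusion-point coordinate.
#' @param min_flank Minimum covered nt on either side.
#' @param min_ests Minimum number of distinct spanning ESTs.
#' @return List with `n_spanning` and `supported`.
#' @export
spanning_support <- function(hits, fusion_point, min_flank = 20L,
                             min_ests = 3L) {
  if (is.null(hits) || !nrow(hits)) {
    return(list(n_spanning = 0L, supported = FALSE))
  }
  span <- hits$t_start <= fusion_point - min_flank &
    hits$t_end >= fusion_point + min_flank
  n <- length(unique(hits$est_id[span]))
  list(n_spanning = n, supported = n >= min_ests)
}

#' Score all chimeras by EST evidence
#'
#' Aligns every EST against every chimera in both orientations (ESTs are
#' unstranded) with [local_align()] and applies [spanning_support()].
#'
#' @param chimera_seqs Named character vector of chimera sequences.
#' @param junctions Named integer vector: fusion point per chimera id.
#' @param ests Named character vector of EST sequences.
#' @param min_identity,min_flank,min_ests Thresholds.
#' @return List with `support` (data.frame in the `est_support` schema) and
#'   `hits` (per-EST alignment spans).
#' @export
compute_est_support <- function(chimera_seqs, junctions, ests,
                                min_identity = 0.96, min_flank = 20L,
                                min_ests = 3L) {
  hit_rows <- list()
  for (cid in names(chimera_seqs)) {
    cs <- chimera_seqs[[cid]]
    for (eid in names(ests)) {
      fw <- local_align(ests[[eid]], cs, min_identity)
      rv <- local_align(revcomp(ests[[eid]]), cs, min_identity)
      al <- if (is.null(fw)) rv else if (is.null(rv)) fw
            else if (rv$score > fw$score) rv else fw
      if (!is.null(al))
        hit_rows[[length(hit_rows) + 1L]] <-
          data.frame(est_id = eid, chimera_id = cid, t_start = al$t_start,
                     t_end = al$t_end, identity = al$identity,
                     stringsAsFactors = FALSE)
    }
  }
  hits <- if (length(hit_rows)) do.call(rbind, hit_rows)
          else data.frame(est_id = character(0), chimera_id = character(0),
                          t_start = integer(0), t_end = integer(0),
                          identity = numeric(0))
  support <- do.call(rbind, lapply(names(chimera_seqs), function(cid) {
    sp <- spanning_support(hits[hits$chimera_id == cid, , drop = FALSE],
                           junctions[[cid]], min_flank, min_ests)
    data.frame(chimera_id = cid, n_spanning = sp$n_spanning,
               supported = sp$supported, stringsAsFactors = FALSE)
  }))
  list(support = support, hits = hits)
}
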