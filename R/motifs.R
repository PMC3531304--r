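# Shared-motif analysis of parental genomic regions: region extraction by
# annotation category, seeded shared-motif discovery with a dinucleotide-
# shuffle null, category tabulation, and PFM-library comparison.

#' Extract parental region pairs for a chimera candidate
#'
#' For each partner locus the four region categories are taken in
#' transcription direction: `upstream` (up_window nt 5' of the locus),
#' `downstream` (down_window nt 3'), `exon` (concatenated aligned blocks) and
#' `intron` (concatenated inter-block gaps). All category pairings with two
#' nonempty sequences are emitted; windows clipped at a chromosome edge are
#' flagged.
#'
#' @param candidate A chimera candidate.
#' @param genome Named character vector of chromosomes.
#' @param up_window,down_window Window sizes in nt.
#' @return data.frame with chimera_id, category5, category3, seq5, seq3,
#'   clipped5, clipped3.
#' @export
extract_region_pairs <- function(candidate, genome, up_window = 2000L,
                                 down_window = 2000L) {
  regions <- function(p) {
    chrom_seq <- genome[[p$tName]]
    clen <- nchar(chrom_seq)
    bl <- psl_blocks(p)
    bl <- bl[order(bl$tStart), , drop = FALSE]
    exon <- paste(subseq0(chrom_seq, bl$tStart, bl$tStart + bl$size),
                  collapse = "")
    gaps_s <- head(bl$tStart + bl$size, -1L)
    gaps_e <- bl$tStart[-1L]
    keep <- gaps_e > gaps_s
    intron <- if (any(keep))
      paste(subseq0(chrom_seq, gaps_s[keep], gaps_e[keep]), collapse = "")
      else ""
    if (p$strand == "+") {
      u_s <- max(0L, p$tStart - up_window); u_e <- p$tStart
      d_s <- p$tEnd; d_e <- min(clen, p$tEnd + down_window)
      up <- subseq0(chrom_seq, u_s, u_e)
      down <- subseq0(chrom_seq, d_s, d_e)
      up_clip <- (p$tStart - u_s) < up_window
      down_clip <- (d_e - p$tEnd) < down_window
    } else {
      u_s <- p$tEnd; u_e <- min(clen, p$tEnd + up_window)
      d_s <- max(0L, p$tStart - down_window); d_e <- p$tStart
      up <- revcomp(subseq0(chrom_seq, u_s, u_e))
      down <- revcomp(subseq0(chrom_seq, d_s, d_e))
      exon <- revcomp(exon)
      intron <- if (nzchar(intron)) revcomp(intron) else intron
      up_clip <- (u_e - p$tEnd) < up_window
      down_clip <- (p$tStart - d_s) < down_window
    }
    list(seqs = c(upstream = up, exon = exon, intron = intron,
                  downstream = down),
         clipped = c(upstream = up_clip, exon = FALSE, intron = FALSE,
                     downstream = down_clip))
  }
  r5 <- regions(candidate$p5)
  r3 <- regions(candidate$p3)
  rows <- list()
  for (c5 in names(r5$seqs)) for (c3 in names(r3$seqs)) {
    if (nzchar(r5$seqs[[c5]]) && nzchar(r3$seqs[[c3]]))
      rows[[length(rows) + 1L]] <-
        data.frame(chimera_id = candidate$mrna_id, category5 = c5,
                   category3 = c3, seq5 = r5$seqs[[c5]], seq3 = r3$seqs[[c3]],
                   clipped5 = r5$clipped[[c5]], clipped3 = r3$clipped[[c3]],
                   stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Dinucleotide shuffle of a sequence
#'
#' Altschul-Erickson Eulerian-path shuffle: the shuffled sequence preserves
#' the exact dinucleotide counts of the input. Uses the current RNG state.
#'
#' @param seq Nucleotide sequence.
#' @return A shuffled sequence of the same length.
#' @export
dinuc_shuffle <- function(seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  if (n < 3L) return(seq)
  from <- ch[-n]; to <- ch[-1L]
  verts <- unique(ch)
  succ <- split(to, factor(from, levels = verts))
  last <- ch[n]
  nonlast <- setdiff(verts[lengths(succ) > 0L], last)
  # choose a random final edge per non-terminal vertex until they form a tree
  # rooted at the terminal vertex (Altschul-Erickson condition)
  repeat {
    fin <- vapply(nonlast, function(v) {
      s <- succ[[v]]; s[sample.int(length(s), 1L)]
    }, "")
    ok <- TRUE
    for (v in nonlast) {
      cur <- v; seen <- character(0)
      while (cur != last) {
        if (cur %in% seen || !(cur %in% nonlast)) { ok <- FALSE; break }
        seen <- c(seen, cur)
        cur <- fin[[cur]]
      }
      if (!ok) break
    }
    if (ok) break
  }
  # permute remaining edges, append the final edge for each non-terminal vertex
  lists <- lapply(verts, function(v) {
    s <- succ[[v]]
    if (v %in% nonlast) {
      drop1 <- match(fin[[v]], s)
      rest <- s[-drop1]
      c(rest[sample.int(length(rest))], fin[[v]])
    } else {
      s[sample.int(length(s))]
    }
  })
  names(lists) <- verts
  ptr <- setNames(rep(1L, length(verts)), verts)
  out <- character(n)
  out[1] <- ch[1]
  cur <- ch[1]
  for (i in 2:n) {
    nxt <- lists[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    out[i] <- nxt
    cur <- nxt
  }
  paste(out, collapse = "")
}

# best shared-seed extension score between two sequences; seeds are shared
# exact `seed_w`-mers, extended both directions at +1 match / -1 mismatch
# with total width clamped to w_max. Returns NULL if no shared seed.
.best_shared_site <- function(seq5, seq3, seed_w = 10L, w_max = 30L,
                              max_pairs = 2000L) {
  n5 <- nchar(seq5); n3 <- nchar(seq3)
  if (n5 < seed_w || n3 < seed_w) return(NULL)
  k5 <- substring(seq5, 1:(n5 - seed_w + 1L), seed_w:n5)
  k3 <- substring(seq3, 1:(n3 - seed_w + 1L), seed_w:n3)
  shared <- intersect(k5, k3)
  shared <- shared[!grepl("N", shared, fixed = TRUE)]
  if (!length(shared)) return(NULL)
  i5 <- utf8ToInt(seq5); i3 <- utf8ToInt(seq3)
  budget <- w_max - seed_w
  best <- NULL
  pairs_seen <- 0L
  for (km in shared) {
    p5s <- which(k5 == km); p3s <- which(k3 == km)
    for (p5 in p5s) for (p3 in p3s) {
      pairs_seen <- pairs_seen + 1L
      if (pairs_seen > max_pairs) break
      # left extension scores: cumulative +1/-1 going outward
      lmax <- min(p5 - 1L, p3 - 1L, budget)
      lsc <- if (lmax > 0)
        cumsum(ifelse(i5[p5 - seq_len(lmax)] == i3[p3 - seq_len(lmax)], 1L, -1L))
        else integer(0)
      rmax <- min(n5 - (p5 + seed_w - 1L), n3 - (p3 + seed_w - 1L), budget)
      rsc <- if (rmax > 0)
        cumsum(ifelse(i5[p5 + seed_w - 1L + seq_len(rmax)] ==
                        i3[p3 + seed_w - 1L + seq_len(rmax)], 1L, -1L))
        else integer(0)
      lv <- c(0L, lsc)  # score of extending l bases left (l = 0..lmax)
      rv <- c(0L, rsc)
      # best r for each remaining budget: prefix running max of rv
      rbest <- cummax(rv)
      sc_best <- -Inf; l_best <- 0L; r_best <- 0L
      for (l in 0:lmax) {
        rcap <- min(rmax, budget - l)
        val <- lv[l + 1L] + rbest[rcap + 1L]
        if (val > sc_best) {
          sc_best <- val; l_best <- l
          r_best <- which.max(rv[seq_len(rcap + 1L)]) - 1L
        }
      }
      score <- seed_w + sc_best
      if (is.null(best) || score > best$score) {
        best <- list(score = score, site5 = p5 - 1L - l_best,
                     site3 = p3 - 1L - l_best,
                     width = seed_w + l_best + r_best)
      }
    }
  }
  best
}

#' Find a DNA motif shared between two parental genomic sequences
#'
#' Enumerates shared exact 10-mers, extends each seed pair in both directions
#' (match +1 / mismatch -1) with the motif width clamped to
#' `[w_min, w_max]`, and keeps the single best-scoring pair of sites (zero or
#' one site per sequence, at most one motif per pair). Significance is
#' empirical: the fraction of `n_shuffles` dinucleotide-shuffled replicates
#' of `seq3` whose best score reaches the observed one.
#'
#' @param seq5,seq3 Parental region sequences.
#' @param w_min,w_max Motif width bounds (nt).
#' @param n_shuffles Number of shuffle replicates.
#' @param seed RNG seed (required for a reproducible null).
#' @return NULL when no shared seed exists or empirical p > 0.05; otherwise a
#'   list with `width`, `site5`, `site3` (0-based offsets), `matrix` (4 x W
#'   counts over the two sites), `score` and `empirical_p`.
#' @export
find_shared_motif <- function(seq5, seq3, w_min = 10L, w_max = 30L,
                              n_shuffles = 200L, seed = 1L) {
  stopifnot(nchar(seq5) >= w_min, nchar(seq3) >= w_min, w_min >= 10L)
  obs <- .best_shared_site(seq5, seq3, seed_w = 10L, w_max = w_max)
  if (is.null(obs)) return(NULL)
  set.seed(seed)
  null_sc <- vapply(seq_len(n_shuffles), function(i) {
    b <- .best_shared_site(seq5, dinuc_shuffle(seq3), seed_w = 10L,
                           w_max = w_max)
    if (is.null(b)) -Inf else b$score
  }, 0)
  p <- mean(null_sc >= obs$score)
  if (p > 0.05) return(NULL)
  s5 <- subseq0(seq5, obs$site5, obs$site5 + obs$width)
  s3 <- subseq0(seq3, obs$site3, obs$site3 + obs$width)
  counts <- vapply(seq_len(obs$width), function(j) {
    b <- c(substr(s5, j, j), substr(s3, j, j))
    c(A = sum(b == "A"), C = sum(b == "C"), G = sum(b == "G"),
      T = sum(b == "T"))
  }, numeric(4))
  list(width = obs$width, site5 = obs$site5, site3 = obs$site3,
       matrix = counts, score = obs$score, empirical_p = p)
}

#' Tabulate shared motifs by region-category pair
#'
#' Each chimera contributes its single best-scoring category pair. Cells of
#' the 4x4 matrix (5' category x 3' category) count chimeras with a shared
#' motif; the `matched` matrix counts the subset whose shared motif
#' significantly matched a library PFM.
#'
#' @param shared data.frame with chimera_id, category5, category3, score.
#' @param matched_ids Character vector of chimera ids with a significant PFM
#'   match.
#' @return List with `total` and `matched` (4x4 integer matrices) whose
#'   marginals conserve the grand totals.
#' @export
tabulate_categories <- function(shared, matched_ids = character(0)) {
  cats <- c("upstream", "exon", "intron", "downstream")
  tot <- matrix(0L, 4, 4, dimnames = list(cats, cats))
  mat <- tot
  if (!is.null(shared) && nrow(shared)) {
    best <- do.call(rbind, lapply(split(shared, shared$chimera_id),
                                  function(s) s[which.max(s$score), ]))
    for (i in seq_len(nrow(best))) {
      tot[best$category5[i], best$category3[i]] <-
        tot[best$category5[i], best$category3[i]] + 1L
      if (best$chimera_id[i] %in% matched_ids)
        mat[best$category5[i], best$category3[i]] <-
          mat[best$category5[i], best$category3[i]] + 1L
    }
  }
  list(total = tot, matched = mat)
}

# counts -> column frequencies
.pfm_freq <- function(counts) {
  sweep(counts, 2, colSums(counts), "/")
}

# reverse complement of a PFM (reverse columns, swap A<->T, C<->G)
.pfm_rc <- function(counts) {
  out <- counts[c("T", "G", "C", "A"), rev(seq_len(ncol(counts))), drop = FALSE]
  rownames(out) <- c("A", "C", "G", "T")
  out
}

# mean per-column Pearson correlation at the best offset of m (4xWm) vs p
# (4xWp); overlap >= min_overlap columns; zero-variance columns score 0.
.pfm_similarity <- function(fm, fp, min_overlap = 4L) {
  wm <- ncol(fm); wp <- ncol(fp)
  best <- list(similarity = -Inf, offset = NA_integer_)
  for (o in (-(wm - min_overlap)):(wp - min_overlap)) {
    js <- max(1L, 1L - o):min(wm, wp - o)
    if (length(js) < min_overlap) next
    a <- fm[, js, drop = FALSE]; b <- fp[, js + o, drop = FALSE]
    ma <- colMeans(a); mb <- colMeans(b)
    num <- colSums(a * b) - 4 * ma * mb
    den2 <- (colSums(a * a) - 4 * ma^2) * (colSums(b * b) - 4 * mb^2)
    r <- ifelse(den2 > 0, num / sqrt(pmax(den2, 0)), 0)
    s <- mean(r)
    if (s > best$similarity) best <- list(similarity = s, offset = o)
  }
  best
}

#' Compare a shared motif against a PFM library
#'
#' For every library PFM, both orientations and every offset with at least 4
#' overlapping columns are scored by the mean per-column Pearson correlation
#' of frequency columns. Significance is empirical over `n_shuffles`
#' column-shuffled versions of each library motif ((1+k)/(1+n) convention),
#' with Benjamini-Hochberg FDR across the library.
#'
#' @param shared_motif A [find_shared_motif()] result (or any list with a
#'   4 x W `matrix` of counts).
#' @param pfm_library List of PFMs ([read_jaspar()]).
#' @param n_shuffles Shuffle replicates per library motif.
#' @param seed RNG seed.
#' @param p_threshold Report matches with p below this value.
#' @return data.frame sorted by p: pfm_id, offset, orientation, similarity,
#'   p, q.
#' @export
match_pfm <- function(shared_motif, pfm_library, n_shuffles = 400L, seed = 1L,
                      p_threshold = 0.05) {
  stopifnot(length(pfm_library) >= 1L)
  m <- shared_motif$matrix
  if (ncol(m) < 4L) stop("motif width < 4")
  fm <- .pfm_freq(m)
  set.seed(seed)
  rows <- lapply(pfm_library, function(pf) {
    ffw <- .pfm_freq(pf$counts)
    frc <- .pfm_freq(.pfm_rc(pf$counts))
    b_f <- .pfm_similarity(fm, ffw)
    b_r <- .pfm_similarity(fm, frc)
    if (b_f$similarity >= b_r$similarity) {
      obs <- b_f; orient <- "forward"
    } else {
      obs <- b_r; orient <- "reverse-complement"
    }
    null <- vapply(seq_len(n_shuffles), function(i) {
      sh <- pf$counts[, sample.int(ncol(pf$counts)), drop = FALSE]
      max(.pfm_similarity(fm, .pfm_freq(sh))$similarity,
          .pfm_similarity(fm, .pfm_freq(.pfm_rc(sh)))$similarity)
    }, 0)
    p <- (1 + sum(null >= obs$similarity)) / (1 + n_shuffles)
    data.frame(pfm_id = pf$motif_id, offset = obs$offset,
               orientation = orient, similarity = obs$similarity, p = p,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df$q <- p.adjust(df$p, method = "BH")
  df <- df[order(df$p, -df$similarity), , drop = FALSE]
  rownames(df) <- NULL
  df[df$p < p_threshold, , drop = FALSE]
}
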