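# Seeded synthetic-data generator with a known truth table: genome, genes
# with GT..AG introns, planted chimeras of every fusion class and ordering
# type, single-violation decoys, alignments, ESTs, single-end reads with
# Phred qualities, and motif-planted region pairs.

#' Generate a random genome
#'
#' @param n_chrom Number of chromosomes.
#' @param lengths Integer vector of chromosome lengths (each >= 10 kb).
#' @param gc GC content.
#' @param seed RNG seed (the generator is fully deterministic per seed).
#' @return Named character vector of chromosome sequences.
#' @export
make_genome <- function(n_chrom = 4L, lengths = rep(100000L, n_chrom),
                        gc = 0.42, seed = 1L) {
  stopifnot(length(lengths) == n_chrom, all(lengths >= 10000L))
  set.seed(seed)
  g <- vapply(seq_len(n_chrom), function(i) random_dna(lengths[i], gc), "")
  names(g) <- names(lengths) %||% paste0("chr", seq_len(n_chrom))
  g
}

# exon/intron segment list in transcription order; introns begin GT, end AG
# (donor can be overridden to plant non-canonical decoys)
.make_segments <- function(exon_lens, intron_lens, gc = 0.42,
                           donor_override = NULL) {
  stopifnot(length(intron_lens) == length(exon_lens) - 1L, all(intron_lens >= 8L))
  segs <- list()
  for (i in seq_along(exon_lens)) {
    segs[[length(segs) + 1L]] <- list(type = "exon", len = exon_lens[i],
                                      seq = random_dna(exon_lens[i], gc))
    if (i < length(exon_lens)) {
      don <- if (!is.null(donor_override) && !is.na(donor_override[i]))
        donor_override[i] else "GT"
      segs[[length(segs) + 1L]] <-
        list(type = "intron", len = intron_lens[i],
             seq = paste0(don, random_dna(intron_lens[i] - 4L, gc), "AG"))
    }
  }
  segs
}

# assemble a gene record; `start` is the 0-based plus-strand genomic start
.build_gene <- function(id, chrom, strand, start, segs) {
  lens <- vapply(segs, `[[`, 0L, "len")
  types <- vapply(segs, `[[`, "", "type")
  off <- cumsum(c(0L, head(lens, -1L)))  # transcription-space offsets
  glen <- sum(lens)
  is_ex <- types == "exon"
  ex_off <- off[is_ex]; ex_len <- lens[is_ex]
  g_ex_start <- if (strand == "+") start + ex_off
                else start + glen - ex_off - ex_len
  ex_seq <- vapply(segs[is_ex], `[[`, "", "seq")
  q_off <- cumsum(c(0L, head(ex_len, -1L)))
  list(id = id, chrom = chrom, strand = strand, start = start,
       end = start + glen, glen = glen, segs = segs,
       ex_len = ex_len, g_ex_start = g_ex_start, q_off = q_off,
       transcript = paste(ex_seq, collapse = ""))
}

.write_gene_to_genome <- function(genome, gene) {
  s <- paste(vapply(gene$segs, `[[`, "", "seq"), collapse = "")
  if (gene$strand == "-") s <- revcomp(s)
  genome[gene$chrom] <- overwrite_seq(genome[[gene$chrom]], gene$start, s)
  genome
}

# one PSL row for a contiguous run of a gene's exons (transcription order)
.gene_psl_row <- function(gene, exon_idx, q_offset, qname, qsize, chrom_lens,
                          mismatches = 0L) {
  sizes <- gene$ex_len[exon_idx]
  qs <- q_offset + cumsum(c(0L, head(sizes, -1L)))
  ts <- gene$g_ex_start[exon_idx]
  tot <- sum(sizes)
  data.frame(matches = tot - mismatches, misMatches = mismatches,
             repMatches = 0L, nCount = 0L, qNumInsert = 0L, qBaseInsert = 0L,
             tNumInsert = 0L, tBaseInsert = 0L, strand = gene$strand,
             qName = qname, qSize = qsize, qStart = qs[1],
             qEnd = qs[length(qs)] + sizes[length(sizes)],
             tName = gene$chrom, tSize = chrom_lens[[gene$chrom]],
             tStart = min(ts), tEnd = max(ts + sizes),
             blockCount = length(sizes), blockSizes = fmt_commas(sizes),
             qStarts = fmt_commas(qs), tStarts = fmt_commas(ts),
             stringsAsFactors = FALSE)
}

# interval allocator over an occupancy list (per-chromosome data.frame)
.alloc <- function(occ, chrom, len, lo, hi, margin = 150L, tries = 500L) {
  taken <- occ[[chrom]]
  if (hi - len - lo + 1L >= 1L) {
    for (i in seq_len(tries)) {
      s <- lo + sample.int(hi - len - lo + 1L, 1L) - 1L
      if (is.null(taken) || !any(ivl_overlap(taken$start - margin,
                                             taken$end + margin, s, s + len)))
        return(s)
    }
  }
  stop("could not place a feature of length ", len, " on ", chrom)
}

# allocate on any chromosome that can take the feature (random order)
.alloc_any <- function(occ, genome, len, exclude = character(0)) {
  chrom_lens <- nchar(genome)
  cands <- setdiff(names(genome)[chrom_lens >= len + 2000L], exclude)
  for (cc in sample(cands)) {
    s <- tryCatch(.alloc(occ, cc, len, 200L, chrom_lens[[cc]] - 200L,
                         tries = 200L),
                  error = function(e) NULL)
    if (!is.null(s)) return(list(chrom = cc, start = s))
  }
  stop("could not place a feature of length ", len, " on any chromosome")
}

.occ_add <- function(occ, chrom, start, end) {
  occ[[chrom]] <- rbind(occ[[chrom]], data.frame(start = start, end = end))
  occ
}

#' Plant multi-exon genes in a genome
#'
#' Writes non-overlapping genes (random placement, bounded retries) whose
#' introns begin GT and end AG on the transcribed strand; emits a BED12
#' annotation and the spliced transcripts.
#'
#' @param genome Named character vector of chromosomes.
#' @param n_genes Number of genes.
#' @param exons_per_gene Exons per gene.
#' @param seed RNG seed.
#' @param gc GC content of generated sequence.
#' @param occupied Optional occupancy list to respect/extend.
#' @return List with updated `genome`, `genes` (records), `bed` (BED12
#'   data.frame), `transcripts` and `occupied`.
#' @export
plant_genes <- function(genome, n_genes, exons_per_gene = 3L, seed = 1L,
                        gc = 0.42, occupied = NULL) {
  set.seed(seed)
  occ <- occupied %||% setNames(vector("list", length(genome)), names(genome))
  genes <- list()
  for (i in seq_len(n_genes)) {
    exl <- sample(150:280, exons_per_gene, replace = TRUE)
    inl <- sample(80:180, exons_per_gene - 1L, replace = TRUE)
    segs <- .make_segments(exl, inl, gc)
    glen <- sum(vapply(segs, `[[`, 0L, "len"))
    chrom <- sample(names(genome), 1L)
    start <- .alloc(occ, chrom, glen, 200L, nchar(genome[[chrom]]) - 200L)
    strand <- sample(c("+", "-"), 1L)
    g <- .build_gene(sprintf("GENE%03d", i), chrom, strand, start, segs)
    genome <- .write_gene_to_genome(genome, g)
    occ <- .occ_add(occ, chrom, g$start, g$end)
    genes[[g$id]] <- g
  }
  bed <- do.call(rbind, lapply(genes, function(g) {
    ord <- order(g$g_ex_start)
    data.frame(chrom = g$chrom, start = g$start, end = g$end, name = g$id,
               score = 0L, strand = g$strand,
               blockSizes = fmt_commas(g$ex_len[ord]),
               blockStarts = fmt_commas(g$g_ex_start[ord] - g$start),
               stringsAsFactors = FALSE)
  }))
  transcripts <- vapply(genes, `[[`, "", "transcript")
  list(genome = genome, genes = genes, bed = bed,
       transcripts = transcripts, occupied = occ)
}

#' Default planted chimera specification
#'
#' Twenty clean chimeras covering every fusion class and intra-strand
#' ordering type, plus seven decoys each violating exactly one filter.
#'
#' @return data.frame with columns id, class, order, violation.
#' @export
default_classes_spec <- function() {
  clean <- rbind(
    data.frame(class = "inter_chromosomal", order = "not_applicable", n = 5),
    data.frame(class = "intra_inter_strand", order = "not_applicable", n = 5),
    data.frame(class = "intra_intra_strand", order = "partner5_downstream", n = 4),
    data.frame(class = "intra_intra_strand", order = "nested_3p_in_5p", n = 3),
    data.frame(class = "intra_intra_strand", order = "nested_5p_in_3p", n = 2),
    data.frame(class = "intra_intra_strand", order = "colinear_readthrough", n = 1))
  clean <- clean[rep(seq_len(nrow(clean)), clean$n), c("class", "order")]
  clean$violation <- "none"
  clean$id <- sprintf("CHIM%03d", seq_len(nrow(clean)))
  dec <- data.frame(class = "inter_chromosomal", order = "not_applicable",
                    violation = c("identity", "length", "gap", "splice",
                                  "frame", "est", "starts"))
  dec$id <- paste0("DECOY_", dec$violation)
  rbind(clean, dec)[, c("id", "class", "order", "violation")]
}

# break long open reading runs: in every frame, any stop-free run longer than
# max_run codons gets a TAA written over its current codon
.cap_orf_runs <- function(seq, max_run = 40L) {
  stops <- c("TAA", "TAG", "TGA")
  for (pass in 1:10) {
    changed <- FALSE
    for (f in 0:2) {
      n <- nchar(seq)
      if (n - f < 3L) next
      st <- seq(f + 1L, n - 2L, by = 3L)
      cod <- substring(seq, st, st + 2L)
      run <- 0L
      for (i in seq_along(cod)) {
        run <- if (cod[i] %in% stops) 0L else run + 1L
        if (run > max_run) {
          seq <- overwrite_seq(seq, st[i] - 1L, "TAA")
          changed <- TRUE
          run <- 0L
        }
      }
    }
    if (!changed) break
  }
  seq
}

# random stop-free coding stretch: ATG + codons from a stop-free set + TAA
.orf_sequence <- function(len) {
  stopifnot(len %% 3L == 0L, len >= 9L)
  safe <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                            c("A", "C", "G", "T")), 1, paste, collapse = "")
  safe <- setdiff(safe, c("TAA", "TAG", "TGA"))
  mid <- paste(sample(safe, len / 3L - 2L, replace = TRUE), collapse = "")
  paste0("ATG", mid, "TAA")
}

# place the two partner genes of one chimera according to class/order
.place_partners <- function(occ, genome, class, order, lenA, lenB,
                            readthrough_gap) {
  if (class == "inter_chromosomal") {
    a <- .alloc_any(occ, genome, lenA)
    occ <- .occ_add(occ, a$chrom, a$start, a$start + lenA)
    b <- .alloc_any(occ, genome, lenB, exclude = a$chrom)
    occ <- .occ_add(occ, b$chrom, b$start, b$start + lenB)
    return(list(occ = occ, chromA = a$chrom, chromB = b$chrom,
                startA = a$start, startB = b$start,
                strandA = sample(c("+", "-"), 1L),
                strandB = sample(c("+", "-"), 1L)))
  }
  if (class == "intra_inter_strand") {
    a <- .alloc_any(occ, genome, lenA + lenB + 1000L)
    # carve the two genes out of one allocated window
    sA <- a$start
    sB <- a$start + lenA + 500L
    occ <- .occ_add(occ, a$chrom, a$start, a$start + lenA + lenB + 1000L)
    st <- sample(c("+", "-"), 1L)
    return(list(occ = occ, chromA = a$chrom, chromB = a$chrom,
                startA = sA, startB = sB,
                strandA = st, strandB = if (st == "+") "-" else "+"))
  }
  # intra_intra_strand with an ordering type; nested cases are handled by the
  # caller (partner written inside the other's intron), here we place the
  # side-by-side configurations
  st <- sample(c("+", "-"), 1L)
  gap <- if (order == "colinear_readthrough") readthrough_gap
         else sample(2000:5000, 1L)
  total <- lenA + lenB + gap
  a <- .alloc_any(occ, genome, total)
  cc <- a$chrom; lo <- a$start
  occ <- .occ_add(occ, cc, lo, lo + total)
  # first gene in transcription direction sits at low coords on '+', high on '-'
  first_A <- order == "colinear_readthrough"  # A precedes B in tx direction
  if ((st == "+") == first_A) {
    sA <- lo; sB <- lo + lenA + gap
  } else {
    sB <- lo; sA <- lo + lenB + gap
  }
  list(occ = occ, chromA = cc, chromB = cc, startA = sA, startB = sB,
       strandA = st, strandB = st)
}

#' Plant chimeric transcripts, alignments and decoys
#'
#' For each requested (class, order, violation) tuple builds two partner
#' genes, a chimeric transcript whose 5' part is a prefix of gene A's
#' transcript and 3' part a suffix of gene B's (junction at an exon
#' boundary, so the trans-junction inherits a GT donor from A's following
#' intron and an AG acceptor from B's preceding intron), writes the genes
#' into the genome and emits exact PSL records plus a truth table. A long
#' open reading frame is planted across the junction (elsewhere ORF runs are
#' capped) so clean chimeras pass the reading-frame rule; decoys violate
#' exactly the labelled filter (identity 0.95, part length 99 nt, junction
#' gap 11 nt, GC donor, longest ORF confined to the 3' part, EST/read
#' support starved downstream).
#'
#' @param genome Named character vector of chromosomes.
#' @param classes_spec data.frame (id, class, order, violation); see
#'   [default_classes_spec()].
#' @param seed RNG seed.
#' @param occupied Optional occupancy list (from [plant_genes()]).
#' @param gc GC content.
#' @param readthrough_gap Genomic separation of the colinear readthrough
#'   pair (must exceed the discovery `max_intron` to be non-contiguous).
#' @return List with updated `genome`, `chimeras` (truth data.frame),
#'   `transcripts`, `psl`, `records` (per-chimera gene structures and
#'   junction genomic context) and `occupied`.
#' @export
plant_chimeras <- function(genome, classes_spec = default_classes_spec(),
                           seed = 1L, occupied = NULL, gc = 0.42,
                           readthrough_gap = 60000L) {
  set.seed(seed)
  occ <- occupied %||% setNames(vector("list", length(genome)), names(genome))
  chrom_lens <- nchar(genome)
  psl <- list(); truth <- list(); records <- list(); transcripts <- character(0)
  # place the largest-footprint configurations first so the readthrough
  # window (and the nested outer genes) find contiguous space
  ord <- order(classes_spec$order != "colinear_readthrough",
               !(classes_spec$order %in% c("nested_3p_in_5p",
                                           "nested_5p_in_3p")))
  for (i in ord) {
    row <- classes_spec[i, ]
    viol <- row$violation
    # exon/intron geometry (transcription order); junction after A exon 2
    eA <- c(sample(150:220, 1L), sample(160:240, 1L), sample(150:220, 1L))
    iA <- sample(90:160, 2L)
    eB <- c(sample(150:220, 1L), sample(215:260, 1L), sample(150:220, 1L))
    iB <- sample(90:160, 2L)
    jA <- 2L  # junction after A exon jA
    if (viol == "length") { eA[1] <- 99L; jA <- 1L }
    len5 <- sum(eA[seq_len(jA)])
    len3 <- sum(eB[2:3])
    ins <- if (viol == "gap") random_dna(11L, gc) else ""
    q3_off <- len5 + nchar(ins)
    tx_len <- q3_off + len3
    # chimeric transcript: capped ORF background + planted reading frame
    core <- .cap_orf_runs(random_dna(tx_len, gc))
    if (viol == "frame") {
      # stop wall in all three frames just before a long ORF confined to the
      # 3' part: no reading frame can span the junction
      wall <- "TAAGTAAGTAA"
      core <- overwrite_seq(core, q3_off + 30L - nchar(wall), wall)
      core <- overwrite_seq(core, q3_off + 30L, .orf_sequence(297L))
    } else {
      l <- min(120L, len5 - 3L)
      r <- min(201L, len3 - 3L)
      w <- l + r; w <- w - (w %% 3L)
      core <- overwrite_seq(core, q3_off - l, .orf_sequence(w))
    }
    # nested orders: one partner gene is written inside the other's intron
    nested <- row$order %in% c("nested_3p_in_5p", "nested_5p_in_3p")
    lenB_g <- sum(eB) + sum(iB)
    if (row$order == "nested_3p_in_5p") iA[1] <- lenB_g + 60L
    lenA_g <- sum(eA) + sum(iA)
    if (row$order == "nested_5p_in_3p") {
      iB[2] <- lenA_g + 60L
      lenB_g <- sum(eB) + sum(iB)
    }
    if (nested) {
      st <- sample(c("+", "-"), 1L)
      outer_len <- max(lenA_g, lenB_g)
      al <- .alloc_any(occ, genome, outer_len)
      cc <- al$chrom; s_out <- al$start
      occ <- .occ_add(occ, cc, s_out, s_out + outer_len)
      if (row$order == "nested_3p_in_5p") {
        sA <- s_out
        # B inside A's first intron (between the used exons)
        sB <- if (st == "+") sA + eA[1] + 28L
              else sA + lenA_g - eA[1] - 28L - lenB_g
        pl <- list(occ = occ, chromA = cc, chromB = cc, startA = sA,
                   startB = sB, strandA = st, strandB = st)
      } else {
        sB <- s_out
        sA <- if (st == "+") sB + eB[1] + iB[1] + eB[2] + 28L
              else sB + lenB_g - (eB[1] + iB[1] + eB[2] + 28L) - lenA_g
        pl <- list(occ = occ, chromA = cc, chromB = cc, startA = sA,
                   startB = sB, strandA = st, strandB = st)
      }
    } else {
      pl <- .place_partners(occ, genome, row$class, row$order, lenA_g, lenB_g,
                            readthrough_gap)
    }
    occ <- pl$occ
    # build partner genes, exon content taken from the planted transcript
    segsA <- .make_segments(eA, iA, gc,
                            donor_override = if (viol == "splice") {
                              d <- rep(NA_character_, length(eA) - 1L)
                              d[jA] <- "GC"
                              d
                            } else NULL)
    segsB <- .make_segments(eB, iB, gc)
    # overwrite used exon sequences with the chimeric transcript content
    off5 <- 0L
    ex_i <- which(vapply(segsA, `[[`, "", "type") == "exon")
    for (e in seq_len(jA)) {
      segsA[[ex_i[e]]]$seq <- subseq0(core, off5, off5 + eA[e])
      off5 <- off5 + eA[e]
    }
    ex_iB <- which(vapply(segsB, `[[`, "", "type") == "exon")
    off3 <- q3_off
    for (e in 2:3) {
      segsB[[ex_iB[e]]]$seq <- subseq0(core, off3, off3 + eB[e])
      off3 <- off3 + eB[e]
    }
    gA <- .build_gene(paste0(row$id, "_A"), pl$chromA, pl$strandA, pl$startA, segsA)
    gB <- .build_gene(paste0(row$id, "_B"), pl$chromB, pl$strandB, pl$startB, segsB)
    # write outer gene first so the nested partner overwrites intron interior
    if (row$order == "nested_5p_in_3p") {
      genome <- .write_gene_to_genome(genome, gB)
      genome <- .write_gene_to_genome(genome, gA)
    } else {
      genome <- .write_gene_to_genome(genome, gA)
      genome <- .write_gene_to_genome(genome, gB)
    }
    if (!nested) {
      occ <- .occ_add(occ, gA$chrom, gA$start, gA$end)
      occ <- .occ_add(occ, gB$chrom, gB$start, gB$end)
    }
    mm5 <- if (viol == "identity") as.integer(ceiling(len5 * 0.05)) else 0L
    r5 <- .gene_psl_row(gA, seq_len(jA), 0L, row$id, tx_len, chrom_lens, mm5)
    r3 <- .gene_psl_row(gB, 2:3, q3_off, row$id, tx_len, chrom_lens)
    psl[[row$id]] <- rbind(r5, r3)
    transcripts[[row$id]] <- core
    # genomic context flanking the junction (transcribed orientation):
    # continuation into A's following intron / B's preceding intron
    segA_int <- segsA[[ex_i[jA] + 1L]]$seq
    segB_int <- segsB[[ex_iB[2] - 1L]]$seq
    records[[row$id]] <- list(geneA = gA, geneB = gB,
                              after5 = segA_int, before3 = segB_int)
    truth[[row$id]] <- data.frame(
      id = row$id, class = row$class, order = row$order, violation = viol,
      junction_q = len5, g = if (viol == "gap") 11L else 0L,
      tx_len = tx_len, len5 = len5, len3 = len3,
      canonical = viol != "splice",
      chrom5 = gA$chrom, strand5 = gA$strand,
      start5 = min(gA$g_ex_start[seq_len(jA)]),
      end5 = max(gA$g_ex_start[seq_len(jA)] + gA$ex_len[seq_len(jA)]),
      chrom3 = gB$chrom, strand3 = gB$strand,
      start3 = min(gB$g_ex_start[2:3]),
      end3 = max(gB$g_ex_start[2:3] + gB$ex_len[2:3]),
      stringsAsFactors = FALSE)
  }
  ids <- classes_spec$id
  list(genome = genome, chimeras = do.call(rbind, truth[ids]),
       transcripts = unlist(transcripts)[ids], psl = do.call(rbind, psl[ids]),
       records = records[ids], occupied = occ)
}

#' Simulate single-end reads from transcripts
#'
#' Uniform fragment starts, random strand, substitution errors at
#' `error_rate`, high Phred qualities. When `junctions` (0-based fusion
#' points) are supplied the truth table records every read overlapping a
#' fusion point by at least `k` nt on both sides after trimming to
#' `target_len`; reads whose error-free sequence still admits a contiguous
#' genomic alignment (<= `max_mm` mismatches against the partner-locus
#' continuation supplied in `contexts`) are flagged `masked`, since no
#' genome-unmapped-read strategy can see them.
#'
#' @param transcripts Named character vector.
#' @param abundances Integer matrix transcripts x samples: reads to draw.
#' @param read_len Sequenced read length.
#' @param target_len Length after right-end trimming (default `read_len`).
#' @param error_rate Per-base substitution probability.
#' @param seed RNG seed.
#' @param junctions Named 0-based fusion points (chimeras only).
#' @param k Overhang for junction-read truth.
#' @param contexts Named list per chimera: `after5`, `before3` genomic
#'   continuation sequences in transcribed orientation.
#' @param max_mm Mismatch cap used for the `masked` flag.
#' @param qual_mean Mean Phred quality of simulated bases.
#' @return List with `reads` (data.frame read_id/sample_id/seq/qual) and
#'   `truth` (junction-read truth table).
#' @export
simulate_reads <- function(transcripts, abundances, read_len,
                           target_len = read_len, error_rate = 0,
                           seed = 1L, junctions = NULL, k = 5L,
                           contexts = NULL, max_mm = 2L, qual_mean = 36) {
  set.seed(seed)
  L <- as.integer(read_len)
  stopifnot(all(rownames(abundances) %in% names(transcripts)))
  bases <- c("A", "C", "G", "T")
  reads <- list(); truth <- list()
  for (s in colnames(abundances)) {
    for (tx in rownames(abundances)) {
      n <- abundances[tx, s]
      if (n <= 0) next
      tl <- nchar(transcripts[[tx]])
      if (tl < L) next
      starts <- sample.int(tl - L + 1L, n, replace = TRUE) - 1L
      strands <- sample(c("+", "-"), n, replace = TRUE)
      frag <- substring(transcripts[[tx]], starts + 1L, starts + L)
      seqs <- ifelse(strands == "-", revcomp(frag), frag)
      if (error_rate > 0) {
        seqs <- vapply(seqs, function(sq) {
          err <- which(runif(L) < error_rate)
          if (!length(err)) return(sq)
          v <- strsplit(sq, "", fixed = TRUE)[[1]]
          v[err] <- vapply(v[err],
                           function(b) sample(setdiff(bases, b), 1L), "")
          paste(v, collapse = "")
        }, "", USE.NAMES = FALSE)
      }
      quals <- vapply(seq_len(n), function(i) {
        encode_phred(pmin(40L, pmax(25L, round(rnorm(L, qual_mean, 2)))))
      }, "")
      ids <- sprintf("%s_%s_%05d", s, tx, seq_len(n))
      reads[[length(reads) + 1L]] <-
        data.frame(read_id = ids, sample_id = s, seq = seqs, qual = quals,
                   stringsAsFactors = FALSE)
      jq <- if (tx %in% names(junctions)) junctions[[tx]] else NULL
      if (!is.null(jq)) {
        # post-trim covered transcript interval: right-end trimming removes
        # the transcript-left end for '-' reads
        cov_s <- ifelse(strands == "+", starts, starts + L - target_len)
        cov_e <- ifelse(strands == "+", starts + target_len, starts + L)
        span <- cov_s <= jq - k & cov_e >= jq + k
        if (any(span)) {
          w <- which(span)
          masked <- rep(FALSE, length(w))
          if (!is.null(contexts[[tx]])) {
            ctx <- contexts[[tx]]
            for (j in seq_along(w)) {
              i <- w[j]
              ov3 <- cov_e[i] - jq
              ov5 <- jq - cov_s[i]
              mmA <- if (nchar(ctx$after5) >= ov3)
                sum(utf8ToInt(subseq0(transcripts[[tx]], jq, cov_e[i])) !=
                      utf8ToInt(subseq0(ctx$after5, 0L, ov3))) else Inf
              mmB <- if (nchar(ctx$before3) >= ov5)
                sum(utf8ToInt(subseq0(transcripts[[tx]], cov_s[i], jq)) !=
                      utf8ToInt(subseq0(ctx$before3,
                                        nchar(ctx$before3) - ov5,
                                        nchar(ctx$before3)))) else Inf
              masked[j] <- mmA <= max_mm || mmB <= max_mm
            }
          }
          truth[[length(truth) + 1L]] <- data.frame(
            read_id = ids[w], sample_id = s, event_id = tx,
            tstart0 = cov_s[w],
            ref_start_1based = cov_s[w] - (jq - (target_len - k)) + 1L,
            masked = masked, stringsAsFactors = FALSE)
        }
      }
    }
  }
  list(reads = if (length(reads)) do.call(rbind, reads)
       else data.frame(read_id = character(0), sample_id = character(0),
                       seq = character(0), qual = character(0)),
       truth = if (length(truth)) do.call(rbind, truth)
       else data.frame(read_id = character(0), sample_id = character(0),
                       event_id = character(0), tstart0 = integer(0),
                       ref_start_1based = integer(0), masked = logical(0)))
}

#' Simulate EST fragments for chimeras
#'
#' Spanning ESTs cover at least `min_flank` nt on both sides of the fusion
#' point; non-spanning ESTs end within `min_flank - 1` nt past it. About half
#' the ESTs are emitted reverse-complemented (ESTs are unstranded).
#'
#' @param chimeras Named character vector of chimera sequences.
#' @param junctions Named 0-based fusion points.
#' @param n_spanning Named (or scalar) count of spanning ESTs per chimera.
#' @param n_non_spanning Count of non-spanning ESTs per chimera.
#' @param min_flank Spanning flank in nt.
#' @param seed RNG seed.
#' @return List with `ests` (named character vector) and `truth`
#'   (data.frame est_id/chimera_id/spanning).
#' @export
simulate_ests <- function(chimeras, junctions, n_spanning = 3L,
                          n_non_spanning = 2L, min_flank = 20L, seed = 1L) {
  set.seed(seed)
  if (length(n_spanning) == 1L && is.null(names(n_spanning)))
    n_spanning <- setNames(rep(n_spanning, length(chimeras)), names(chimeras))
  ests <- character(0); truth <- list()
  for (id in names(chimeras)) {
    s <- chimeras[[id]]; jq <- junctions[[id]]; n <- nchar(s)
    stopifnot(jq >= min_flank, n - jq >= min_flank)
    for (e in seq_len(n_spanning[[id]])) {
      a <- sample(min_flank:min(160L, jq), 1L)
      b <- sample(min_flank:min(160L, n - jq), 1L)
      piece <- subseq0(s, jq - a, jq + b)
      if (runif(1) < 0.5) piece <- revcomp(piece)
      eid <- sprintf("EST_%s_S%02d", id, e)
      ests[[eid]] <- piece
      truth[[eid]] <- data.frame(est_id = eid, chimera_id = id,
                                 spanning = TRUE, stringsAsFactors = FALSE)
    }
    for (e in seq_len(n_non_spanning)) {
      end <- jq + sample(0:(min_flank - 1L), 1L)
      start <- max(0L, end - sample(120:200, 1L))
      piece <- subseq0(s, start, end)
      if (runif(1) < 0.5) piece <- revcomp(piece)
      eid <- sprintf("EST_%s_N%02d", id, e)
      ests[[eid]] <- piece
      truth[[eid]] <- data.frame(est_id = eid, chimera_id = id,
                                 spanning = FALSE, stringsAsFactors = FALSE)
    }
  }
  list(ests = unlist(ests), truth = do.call(rbind, truth))
}

#' Random parental-region pairs
#'
#' With a finite `max_shared_score`, a pair whose members already share
#' sites as strong as a deliberately planted motif (best seed-extension
#' score above the cap) has its second member resampled: sequences destined
#' to be decoys must actually lack a shared motif, otherwise the truth label
#' is wrong by construction.
#'
#' @param n Number of pairs.
#' @param len Sequence length per member.
#' @param gc GC content.
#' @param seed RNG seed.
#' @param max_shared_score Maximum tolerated chance shared-site score
#'   (default Inf: no screening).
#' @return data.frame pair_id, seq5, seq3.
#' @export
make_region_pairs <- function(n, len = 1000L, gc = 0.42, seed = 1L,
                              max_shared_score = Inf) {
  set.seed(seed)
  s5 <- vapply(seq_len(n), function(i) random_dna(len, gc), "")
  s3 <- vapply(seq_len(n), function(i) random_dna(len, gc), "")
  if (is.finite(max_shared_score)) {
    for (i in seq_len(n)) {
      for (try in 1:50) {
        b <- .best_shared_site(s5[i], s3[i])
        if (is.null(b) || b$score <= max_shared_score) break
        s3[i] <- random_dna(len, gc)
      }
    }
  }
  data.frame(pair_id = sprintf("PAIR%03d", seq_len(n)),
             seq5 = s5, seq3 = s3, stringsAsFactors = FALSE)
}

#' Plant a shared motif into region pairs
#'
#' For the chosen fraction of pairs the consensus (with at most one planted
#' mismatch per site) overwrites both members at recorded random offsets.
#'
#' @param region_pairs data.frame with pair_id, seq5, seq3.
#' @param motif_consensus Consensus sequence, width in `[10, 30]`.
#' @param fraction Fraction of pairs receiving the motif (taken from the top
#'   of the data.frame).
#' @param seed RNG seed.
#' @param max_mismatches Maximum planted mismatches per site (0 or 1).
#' @return List with `pairs` (mutated data.frame) and `truth`
#'   (pair_id/planted/off5/off3).
#' @export
plant_region_motifs <- function(region_pairs, motif_consensus, fraction = 1,
                                seed = 1L, max_mismatches = 1L) {
  w <- nchar(motif_consensus)
  stopifnot(w >= 10L, w <= 30L)
  set.seed(seed)
  n <- nrow(region_pairs)
  n_plant <- round(fraction * n)
  bases <- c("A", "C", "G", "T")
  # mismatches are planted near the site edges so that an exact seed window
  # (10-mer) always survives in both sites; below width 18 no interior-safe
  # window exists and sites are planted exact
  mm_pos <- if (w >= 18L) c(1:4, (w - 3L):w) else integer(0)
  site <- function() {
    s <- motif_consensus
    if (length(mm_pos) && sample(0:max_mismatches, 1L) == 1L) {
      p <- mm_pos[sample.int(length(mm_pos), 1L)]
      b <- substr(s, p, p)
      s <- overwrite_seq(s, p - 1L, sample(setdiff(bases, b), 1L))
    }
    s
  }
  truth <- data.frame(pair_id = region_pairs$pair_id, planted = FALSE,
                      off5 = NA_integer_, off3 = NA_integer_)
  for (i in seq_len(n_plant)) {
    o5 <- sample.int(nchar(region_pairs$seq5[i]) - w + 1L, 1L) - 1L
    o3 <- sample.int(nchar(region_pairs$seq3[i]) - w + 1L, 1L) - 1L
    region_pairs$seq5[i] <- overwrite_seq(region_pairs$seq5[i], o5, site())
    region_pairs$seq3[i] <- overwrite_seq(region_pairs$seq3[i], o3, site())
    truth$planted[i] <- TRUE
    truth$off5[i] <- o5
    truth$off3[i] <- o3
  }
  list(pairs = region_pairs, truth = truth)
}
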