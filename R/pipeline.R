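# Orchestration: the default synthetic study (cohort mirroring the original
# design: 11 liver samples, five males and six females, read lengths 76/101
# nt, plus three 49-nt muscle pools), and the full pipeline
# discover -> verify -> est-support -> quantify -> stats -> motifs with a
# deterministic report bundle.

#' Default study configuration
#'
#' The synthetic study conditions: a 4-chromosome genome (180/150/120/90 kb),
#' six background cis genes, the planted chimera set of
#' [default_classes_spec()], an 11-sample liver cohort (5 male / 6 female;
#' read length 76 nt, three samples sequenced at 101 nt and trimmed) plus
#' three 49-nt muscle pools, per-event read depth with mean 80 and
#' coefficient of variation 0.57, 1% substitution error, 3-6 spanning ESTs
#' per clean chimera, and a motif study of 20 planted + 20 decoy region
#' pairs with a CTCF-like 19-mer consensus.
#'
#' @return Nested list of parameters.
#' @export
study_config <- function() {
  list(
    genome = list(n_chrom = 4L,
                  lengths = c(chr1 = 180000L, chr2 = 150000L,
                              chr3 = 120000L, chr4 = 90000L),
                  gc = 0.42),
    n_background_genes = 6L,
    readthrough_gap = 60000L,
    discovery = discovery_params(max_intron = 50000L),
    flank = 500L,
    junction_liver = junction_params(L = 76L, k = 5L),
    junction_muscle = junction_params(L = 49L, k = 5L),
    qc_min_q = 20,
    reads = list(depth_mean = 80, depth_cv = 0.57, depth_min = 10L,
                 error_rate = 0.01, qual_mean = 36),
    est = list(n_spanning_range = c(3L, 6L), n_non_spanning = 2L,
               min_flank = 20L, min_ests = 3L, min_identity = 0.96),
    motifs = list(up_window = 2000L, down_window = 2000L, n_shuffles = 200L,
                  pfm_shuffles = 400L, p_threshold = 0.05),
    motif_study = list(n_planted = 20L, n_decoy = 20L, region_len = 1000L,
                       consensus = "TGGCCACCAGGGGGCGCTA"),
    samples = data.frame(
      sample_id = c(sprintf("L%02d", 1:11), sprintf("M%02d", 1:3)),
      tissue = c(rep("liver", 11), rep("muscle", 3)),
      sex = c(rep("male", 5), rep("female", 6), rep(NA, 3)),
      read_len = c(rep(76L, 8), rep(101L, 3), rep(49L, 3)),
      stringsAsFactors = FALSE)
  )
}

# derived sub-seed, kept within 32-bit integer range
.subseed <- function(seed, i) {
  as.integer((as.numeric(seed) * 131 + i) %% 2147483647)
}

#' Simulate the full synthetic study
#'
#' Generates every pipeline input with truth annotation: genome, background
#' genes (BED12 + single-locus alignments), planted chimeras and decoys with
#' exact PSL records, per-sample FASTQ-style reads, ESTs, and the
#' motif-study region pairs. Fully deterministic per seed.
#'
#' @param seed Integer seed driving all randomness.
#' @param config A [study_config()] list.
#' @return List with genome, genes, bed, psl, mrna_seqs, junctions, ests,
#'   reads, samples, motif_pairs and `truth` (chimeras, junction_reads,
#'   ests, motifs).
#' @export
simulate_study <- function(seed = 1L, config = study_config()) {
  genome <- make_genome(config$genome$n_chrom, config$genome$lengths,
                        config$genome$gc, seed = .subseed(seed, 1))
  bg <- plant_genes(genome, config$n_background_genes,
                    seed = .subseed(seed, 2), gc = config$genome$gc)
  ch <- plant_chimeras(bg$genome, default_classes_spec(),
                       seed = .subseed(seed, 3), occupied = bg$occupied,
                       gc = config$genome$gc,
                       readthrough_gap = config$readthrough_gap)
  chrom_lens <- nchar(ch$genome)
  bg_psl <- do.call(rbind, lapply(bg$genes, function(g) {
    .gene_psl_row(g, seq_along(g$ex_len), 0L, g$id,
                  sum(g$ex_len), chrom_lens)
  }))
  psl <- rbind(ch$psl, bg_psl)
  mrna_seqs <- c(ch$transcripts, bg$transcripts)
  junctions <- setNames(ch$chimeras$junction_q, ch$chimeras$id)
  contexts <- lapply(ch$records, function(r) r[c("after5", "before3")])

  # per-sample read depths: Gamma with the programmed dispersion
  samples <- config$samples
  set.seed(.subseed(seed, 4))
  txs <- names(mrna_seqs)
  shape <- 1 / config$reads$depth_cv^2
  base <- runif(length(txs), 0.6, 1.4) * config$reads$depth_mean
  ab <- matrix(0L, length(txs), nrow(samples),
               dimnames = list(txs, samples$sample_id))
  for (j in seq_len(nrow(samples)))
    ab[, j] <- pmax(config$reads$depth_min,
                    as.integer(round(rgamma(length(txs), shape = shape,
                                            scale = base / shape))))
  # the "starts" decoy is excluded from random simulation: it only ever gets
  # junction reads from two start positions in two samples
  ab["DECOY_starts", ] <- 0L

  reads <- list(); truth_reads <- list()
  for (j in seq_len(nrow(samples))) {
    sm <- samples[j, ]
    sr <- simulate_reads(mrna_seqs, ab[, sm$sample_id, drop = FALSE],
                         read_len = sm$read_len,
                         target_len = if (sm$tissue == "liver") 76L else 49L,
                         error_rate = config$reads$error_rate,
                         seed = .subseed(seed, 100 + j),
                         junctions = junctions, k = 5L, contexts = contexts,
                         qual_mean = config$reads$qual_mean)
    reads[[sm$sample_id]] <- sr$reads
    truth_reads[[sm$sample_id]] <- sr$truth
  }
  # hand-built junction reads for the "starts" decoy: 2 starts x 2 samples
  dst <- ch$chimeras[ch$chimeras$id == "DECOY_starts", ]
  dseq <- mrna_seqs[["DECOY_starts"]]
  for (sm in c("L01", "L02")) {
    for (s0 in c(dst$junction_q - 30L, dst$junction_q - 40L)) {
      rid <- sprintf("%s_DECOY_starts_fix%02d", sm, s0 %% 100L)
      reads[[sm]] <- rbind(reads[[sm]], data.frame(
        read_id = rid, sample_id = sm, seq = subseq0(dseq, s0, s0 + 76L),
        qual = strrep("I", 76L), stringsAsFactors = FALSE))
      truth_reads[[sm]] <- rbind(truth_reads[[sm]], data.frame(
        read_id = rid, sample_id = sm, event_id = "DECOY_starts",
        tstart0 = s0, ref_start_1based = s0 - (dst$junction_q - 71L) + 1L,
        masked = FALSE, stringsAsFactors = FALSE))
    }
  }

  # ESTs: clean chimeras (and splice/frame decoys, whose single violation is
  # elsewhere) get 3-6 spanning ESTs; the "est" decoy gets exactly 2
  set.seed(.subseed(seed, 5))
  nsp <- setNames(sample(config$est$n_spanning_range[1]:
                           config$est$n_spanning_range[2],
                         nrow(ch$chimeras), replace = TRUE),
                  ch$chimeras$id)
  nsp[["DECOY_est"]] <- 2L
  est <- simulate_ests(ch$transcripts, junctions, n_spanning = nsp,
                       n_non_spanning = config$est$n_non_spanning,
                       min_flank = config$est$min_flank,
                       seed = .subseed(seed, 6))

  # decoy labels must be true: resample pairs that by chance already share
  # sites as strong as the weakest planted motif (19-mer, <=1 mismatch per
  # site, i.e. score >= 15)
  mp0 <- make_region_pairs(config$motif_study$n_planted +
                             config$motif_study$n_decoy,
                           config$motif_study$region_len,
                           config$genome$gc, seed = .subseed(seed, 7),
                           max_shared_score = 14)
  mp <- plant_region_motifs(mp0, config$motif_study$consensus,
                            fraction = config$motif_study$n_planted /
                              nrow(mp0),
                            seed = .subseed(seed, 8))

  list(genome = ch$genome, genes = bg$genes, bed = bg$bed, psl = psl,
       mrna_seqs = mrna_seqs, junctions = junctions, ests = est$ests,
       reads = do.call(rbind, unname(reads)), samples = samples,
       motif_pairs = mp$pairs, records = ch$records,
       truth = list(chimeras = ch$chimeras,
                    junction_reads = do.call(rbind, unname(truth_reads)),
                    ests = est$truth, motifs = mp$truth))
}

# per-decoy verdict: which pipeline stage rejected it, mapped to the
# violation vocabulary {identity,length,gap,splice,frame,est,starts}
.decoy_reason <- function(id, disc_log, verified, est_support, validation) {
  lg <- disc_log[disc_log$mrna_id == id, ]
  if (nrow(lg)) {
    r <- lg$reason[1]
    if (grepl("identity", r)) return("identity")
    if (grepl("length", r)) return("length")
    if (r == "gap") return("gap")
    return(r)
  }
  v <- verified[verified$mrna_id == id, ]
  if (nrow(v)) {
    if (v$status != "ok" || !v$aligned_precisely || !v$canonical)
      return("splice")
    if (!v$frame_ok) return("frame")
  }
  e <- est_support[est_support$chimera_id == id, ]
  if (nrow(e) && !e$supported) return("est")
  va <- validation[validation$event_id == id, ]
  if (!nrow(va) || !va$validated) return("starts")
  "passed"
}

#' Run the full chimera pipeline on a study input bundle
#'
#' Stages: discovery, splice verification, EST support, read QC + genome
#' mapping + junction-read calling + event validation (per tissue),
#' unique-event expression statistics, and shared-motif analysis of the
#' verified candidates' parental regions (per-chimera best category pair)
#' with PFM-library comparison. Emits a Venn-style intersection table of the
#' evidence sets and a run manifest. Deterministic given the config seed.
#'
#' @param sim Input bundle as produced by [simulate_study()] (or assembled
#'   from files with the formats readers).
#' @param config A [study_config()] list.
#' @param pfm_library PFM list for motif matching; defaults to the synthetic
#'   library shipped with the package.
#' @param seed Seed for the motif-analysis nulls.
#' @param run_motifs Set FALSE to skip the (slowest) motif stage.
#' @return List with candidates, log, verified, est_support, hits, counts,
#'   validation (per tissue), unique_events, expression, motifs, venn,
#'   manifest.
#' @export
run_pipeline <- function(sim, config = study_config(), pfm_library = NULL,
                         seed = 1L, run_motifs = TRUE) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  disc <- stage("discover", discover_chimeras(sim$psl, config$discovery))
  verified <- stage("verify",
                    verify_candidates(disc$candidates, sim$genome,
                                      sim$mrna_seqs, flank = config$flank))
  ver_ok <- verified$mrna_id[verified$status == "ok" &
                               verified$aligned_precisely &
                               verified$canonical & verified$frame_ok]
  cand_ids <- names(disc$candidates)
  cjq <- setNames(vapply(disc$candidates, `[[`, 0L, "junction_q"), cand_ids)
  est <- stage("est-support",
               compute_est_support(sim$mrna_seqs[cand_ids], cjq, sim$ests,
                                   min_identity = config$est$min_identity,
                                   min_flank = config$est$min_flank,
                                   min_ests = config$est$min_ests))
  # read QC, genome mapping and junction calling per tissue group
  quant <- stage("quantify", {
    out <- list()
    for (tis in unique(sim$samples$tissue)) {
      jp <- if (tis == "liver") config$junction_liver
            else config$junction_muscle
      sm <- sim$samples$sample_id[sim$samples$tissue == tis]
      rd <- sim$reads[sim$reads$sample_id %in% sm, , drop = FALSE]
      rd <- qc_trim(rd, target_len = jp$L, min_q = config$qc_min_q)
      mp <- map_genome(rd, sim$genome, jp$max_mismatches)
      un <- mp$assignments[mp$assignments$status == "unmapped", , drop = FALSE]
      refs <- build_junction_refs(sim$mrna_seqs[intersect(ver_ok, cand_ids)],
                                  cjq[intersect(ver_ok, cand_ids)], jp)
      hits <- call_junction_reads(un, refs, jp)
      val <- validate_events(hits, jp, all_events = refs$event_id)
      out[[tis]] <- list(params = jp, assignments = mp$assignments,
                         hits = hits, validation = val,
                         counts = junction_count_matrix(hits, samples = sm))
    }
    out
  })
  expr_sum <- stage("stats", {
    lv <- quant[["liver"]]
    if (is.null(lv)) NULL else {
      uniq <- filter_unique_events(lv$validation,
                                   disc$candidates[intersect(ver_ok, cand_ids)],
                                   lv$counts)
      groups <- setNames(sim$samples$sex, sim$samples$sample_id)
      if (length(uniq) >= 2L)
        c(expression_summary(lv$counts[uniq, , drop = FALSE], groups),
          list(unique_events = uniq))
      else list(unique_events = uniq)
    }
  })
  motifs <- NULL
  if (run_motifs) motifs <- stage("motifs", {
    if (is.null(pfm_library))
      pfm_library <- read_jaspar(system.file("extdata",
                                             "jaspar_synthetic_core.pfm",
                                             package = "chimfuse"))
    shared <- list(); matches <- list()
    for (id in intersect(ver_ok, cand_ids)) {
      rp <- extract_region_pairs(disc$candidates[[id]], sim$genome,
                                 config$motifs$up_window,
                                 config$motifs$down_window)
      if (is.null(rp) || !nrow(rp)) next
      sc <- vapply(seq_len(nrow(rp)), function(i) {
        b <- .best_shared_site(rp$seq5[i], rp$seq3[i])
        if (is.null(b)) -Inf else b$score
      }, 0)
      if (!any(is.finite(sc))) next
      bi <- which.max(sc)
      sm <- find_shared_motif(rp$seq5[bi], rp$seq3[bi],
                              n_shuffles = config$motifs$n_shuffles,
                              seed = .subseed(seed, 300 + match(id, cand_ids)))
      if (is.null(sm)) next
      shared[[id]] <- data.frame(chimera_id = id, category5 = rp$category5[bi],
                                 category3 = rp$category3[bi],
                                 width = sm$width, site5 = sm$site5,
                                 site3 = sm$site3, score = sm$score,
                                 empirical_p = sm$empirical_p,
                                 stringsAsFactors = FALSE)
      mm <- match_pfm(sm, pfm_library,
                      n_shuffles = config$motifs$pfm_shuffles,
                      seed = .subseed(seed, 600 + match(id, cand_ids)),
                      p_threshold = config$motifs$p_threshold)
      if (nrow(mm)) {
        mm$chimera_id <- id
        matches[[id]] <- mm
      }
    }
    shared_df <- if (length(shared)) do.call(rbind, unname(shared)) else NULL
    matched_ids <- names(matches)[vapply(matches, function(m)
      any(m$q < 0.05), TRUE)]
    list(shared = shared_df,
         matches = if (length(matches)) do.call(rbind, unname(matches)) else NULL,
         table1 = tabulate_categories(shared_df, matched_ids))
  })
  # Venn-style intersection of the evidence sets over discovered candidates
  sets <- list(
    est = est$support$chimera_id[est$support$supported],
    liver = if (!is.null(quant[["liver"]]))
      quant[["liver"]]$validation$event_id[quant[["liver"]]$validation$validated]
      else character(0),
    muscle = if (!is.null(quant[["muscle"]]))
      quant[["muscle"]]$validation$event_id[quant[["muscle"]]$validation$validated]
      else character(0),
    motif = if (!is.null(motifs$shared)) motifs$shared$chimera_id
      else character(0))
  memb <- sapply(sets, function(s) cand_ids %in% s)
  venn <- as.data.frame(table(as.data.frame(memb)))
  venn <- venn[venn$Freq > 0, , drop = FALSE]
  manifest <- list(package = "chimfuse",
                   version = as.character(utils::packageVersion("chimfuse")),
                   seed = seed,
                   params = list(discovery = unclass(config$discovery),
                                 junction_liver = unclass(config$junction_liver),
                                 junction_muscle = unclass(config$junction_muscle),
                                 flank = config$flank, est = config$est,
                                 motifs = config$motifs))
  list(candidates = disc$candidates, log = disc$log, verified = verified,
       est_support = est$support, quant = quant, expression = expr_sum,
       motifs = motifs, venn = venn, manifest = manifest)
}

#' Stage-by-stage verdict for each planted chimera and decoy
#'
#' Maps every truth id to either "passed" (survived discovery, verification,
#' EST support and read validation) or the name of the violated filter.
#'
#' @param truth Truth chimera table from [simulate_study()].
#' @param res A [run_pipeline()] result.
#' @param tissue Tissue whose validation table to use.
#' @return data.frame id, violation, verdict.
#' @export
decoy_verdicts <- function(truth, res, tissue = "liver") {
  val <- res$quant[[tissue]]$validation
  verdict <- vapply(truth$id, function(id)
    .decoy_reason(id, res$log, res$verified, res$est_support, val), "")
  data.frame(id = truth$id, violation = truth$violation, verdict = verdict,
             stringsAsFactors = FALSE)
}
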