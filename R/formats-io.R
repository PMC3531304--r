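# Readers/writers for the external formats the pipeline touches: FASTA, FASTQ
# (Sanger Phred+33), PSL (BLAT 21-column), BED12, JASPAR PFM text and TSV
# reports. Parsers validate strictly and reject, never silently repair,
# invariant-violating input.

#' Read a FASTA file into a genome store
#'
#' Sequences are case-folded to upper case; record names are the first
#' whitespace-delimited token of the header. Used for genomes, transcripts and
#' ESTs alike.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences (a "genome store").
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readBStringSet(path)
  nm <- vapply(strsplit(names(ss), "\\s+"), `[`, "", 1L)
  if (anyDuplicated(nm)) stop("duplicate FASTA header: ", nm[duplicated(nm)][1])
  out <- toupper(as.character(ss))
  names(out) <- nm
  bad <- grepl("[^ACGTN]", out)
  if (any(bad)) stop("non-ACGTN character in record ", nm[bad][1])
  out
}

#' Write a genome store to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  check_genome(seqs)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read single-end reads from a FASTQ file (Sanger Phred+33)
#'
#' Quality encoding is fixed to Phred+33; no autodetection is attempted.
#'
#' @param path Path to an uncompressed or gzipped FASTQ file.
#' @param sample_id Sample label attached to every read.
#' @return data.frame with columns read_id, sample_id, seq, qual (the raw
#'   quality string; decode with [decode_phred()]).
#' @export
read_fastq <- function(path, sample_id) {
  if (!file.exists(path)) stop("no such file: ", path)
  ln <- readLines(path)
  if (length(ln) %% 4L != 0L) stop("truncated FASTQ record in ", path)
  i <- seq(1L, length(ln), by = 4L)
  hdr <- ln[i]
  seqs <- toupper(ln[i + 1L])
  plus <- ln[i + 2L]
  qual <- ln[i + 3L]
  if (any(!startsWith(hdr, "@"))) stop("FASTQ header line must start with '@'")
  if (any(!startsWith(plus, "+"))) stop("FASTQ separator line must start with '+'")
  if (any(nchar(seqs) != nchar(qual)))
    stop("FASTQ sequence/quality length mismatch at record ",
         which(nchar(seqs) != nchar(qual))[1])
  ph <- decode_phred(qual)
  rng <- range(unlist(ph, use.names = FALSE))
  if (length(qual) && (rng[1] < 0 || rng[2] > 60))
    stop("Phred score outside [0, 60]; not Sanger Phred+33?")
  data.frame(read_id = sub("^@", "", vapply(strsplit(hdr, "\\s+"), `[`, "", 1L)),
             sample_id = sample_id, seq = seqs, qual = qual,
             stringsAsFactors = FALSE)
}

#' Write reads to FASTQ (Sanger Phred+33)
#' @param reads data.frame as returned by [read_fastq()].
#' @param path Output path.
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", reads$read_id, "\n", reads$seq, "\n+\n", reads$qual), con)
  invisible(path)
}

#' Decode Phred+33 quality strings to integer scores
#' @param qual Character vector of quality strings.
#' @return List of integer vectors.
#' @export
decode_phred <- function(qual) {
  lapply(qual, function(q) utf8ToInt(q) - 33L)
}

#' Encode integer Phred scores as a Phred+33 string
#' @param scores Integer vector of Phred scores.
#' @export
encode_phred <- function(scores) {
  intToUtf8(as.integer(scores) + 33L)
}

.psl_cols <- c("matches", "misMatches", "repMatches", "nCount", "qNumInsert",
               "qBaseInsert", "tNumInsert", "tBaseInsert", "strand", "qName",
               "qSize", "qStart", "qEnd", "tName", "tSize", "tStart", "tEnd",
               "blockCount", "blockSizes", "qStarts", "tStarts")

# validate one parsed PSL row; returns NULL or an error message
.psl_check_row <- function(r) {
  num <- function(f) r[[f]]
  if (!(r$strand %in% c("+", "-"))) return("strand must be '+' or '-'")
  if (!(num("qStart") < num("qEnd") && num("qEnd") <= num("qSize")))
    return("requires qStart < qEnd <= qSize")
  if (!(num("tStart") < num("tEnd") && num("tEnd") <= num("tSize")))
    return("requires tStart < tEnd <= tSize")
  bs <- parse_commas(r$blockSizes)
  qs <- parse_commas(r$qStarts)
  ts <- parse_commas(r$tStarts)
  if (length(bs) != r$blockCount || length(qs) != r$blockCount ||
      length(ts) != r$blockCount)
    return("block list lengths disagree with blockCount")
  if (any(bs <= 0)) return("non-positive block size")
  if (is.unsorted(qs, strictly = TRUE) || any(qs[-1] < (qs + bs)[-length(bs)]))
    return("query blocks must be sorted and non-overlapping")
  if (qs[1] != r$qStart || qs[length(qs)] + bs[length(bs)] != r$qEnd)
    return("query blocks inconsistent with qStart/qEnd")
  # tStarts are plus-strand coordinates, blocks ordered by qStart: ascending in
  # t for '+' records, descending for '-' records
  tlo <- min(ts)
  thi <- max(ts + bs)
  if (tlo != r$tStart || thi != r$tEnd)
    return("target blocks inconsistent with tStart/tEnd")
  ord <- if (r$strand == "+") ts else rev(ts)
  if (is.unsorted(ord, strictly = TRUE))
    return("target blocks out of order for strand")
  if (r$matches + r$misMatches != sum(bs))
    return("matches + misMatches must equal total block length")
  NULL
}

#' Read a BLAT PSL alignment file
#'
#' Parses the 21-column PSL format. An optional `psLayout` header is tolerated.
#' Coordinates are 0-based half-open. One convention difference from BLAT is
#' documented: `qStarts` are always in the query's forward (transcript)
#' orientation and `tStarts` on the plus strand of the target, with blocks
#' ordered by query start (so `tStarts` descend for minus-strand records).
#'
#' @param path Path to a PSL file.
#' @return data.frame with one row per alignment record (columns as in the PSL
#'   spec; block lists are comma-separated strings, see [psl_blocks()]).
#' @export
read_psl <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ln <- readLines(path)
  keep <- !grepl("^(psLayout|match\\b|-{5,}|\\s*$)", ln)
  ln_no <- which(keep)
  ln <- ln[keep]
  if (!length(ln)) return(empty_psl())
  parts <- strsplit(ln, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 21L))
    stop("PSL line ", ln_no[nf != 21L][1], ": expected 21 fields, got ",
         nf[nf != 21L][1])
  m <- do.call(rbind, parts)
  df <- as.data.frame(m, stringsAsFactors = FALSE)
  names(df) <- .psl_cols
  int_cols <- setdiff(.psl_cols, c("strand", "qName", "tName",
                                   "blockSizes", "qStarts", "tStarts"))
  for (cc in int_cols) {
    v <- suppressWarnings(as.integer(df[[cc]]))
    if (anyNA(v)) stop("PSL line ", ln_no[which(is.na(v))[1]],
                       ": non-integer value in column ", cc)
    df[[cc]] <- v
  }
  for (i in seq_len(nrow(df))) {
    msg <- .psl_check_row(df[i, ])
    if (!is.null(msg)) stop("PSL line ", ln_no[i], ": ", msg)
  }
  df
}

empty_psl <- function() {
  df <- as.data.frame(setNames(rep(list(character(0)), 21), .psl_cols),
                      stringsAsFactors = FALSE)
  int_cols <- setdiff(.psl_cols, c("strand", "qName", "tName",
                                   "blockSizes", "qStarts", "tStarts"))
  for (cc in int_cols) df[[cc]] <- integer(0)
  df
}

#' Write alignment records to PSL
#' @param aln data.frame of alignment records (see [read_psl()]).
#' @param path Output path.
#' @export
write_psl <- function(aln, path) {
  stopifnot(all(.psl_cols %in% names(aln)))
  writeLines(do.call(paste, c(unname(aln[.psl_cols]), sep = "\t")), path)
  invisible(path)
}

#' Extract the block table of one alignment record
#' @param rec One-row data.frame (a row of [read_psl()] output).
#' @return data.frame with columns size, qStart, tStart (0-based).
#' @export
psl_blocks <- function(rec) {
  data.frame(size = parse_commas(rec$blockSizes),
             qStart = parse_commas(rec$qStarts),
             tStart = parse_commas(rec$tStarts))
}

#' Alignment identity of PSL records
#' @param aln data.frame of alignment records.
#' @return Numeric vector, matches / (matches + misMatches).
#' @export
alignment_identity <- function(aln) {
  aln$matches / (aln$matches + aln$misMatches)
}

#' Read a BED12 annotation file
#'
#' BED12 carries no query coordinates, which the junction gap/overlap rule
#' needs; records imported this way are flagged (`has_query = FALSE`) and
#' excluded from chimera discovery.
#'
#' @param path Path to a BED12 file.
#' @return data.frame with columns chrom, start, end, name, score, strand,
#'   blockSizes, blockStarts (0-based, half-open), has_query.
#' @export
read_bed12 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ln <- readLines(path)
  ln <- ln[!grepl("^(track|browser|#|\\s*$)", ln)]
  if (!length(ln))
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      name = character(0), score = integer(0), strand = character(0),
                      blockSizes = character(0), blockStarts = character(0),
                      has_query = logical(0)))
  parts <- strsplit(ln, "\t", fixed = TRUE)
  if (any(lengths(parts) != 12L))
    stop("BED12 line ", which(lengths(parts) != 12L)[1], ": expected 12 fields")
  m <- do.call(rbind, parts)
  df <- data.frame(chrom = m[, 1], start = as.integer(m[, 2]),
                   end = as.integer(m[, 3]), name = m[, 4],
                   score = as.integer(m[, 5]), strand = m[, 6],
                   blockSizes = m[, 11], blockStarts = m[, 12],
                   has_query = FALSE, stringsAsFactors = FALSE)
  if (any(df$start >= df$end)) stop("BED12: start must be < end")
  df
}

#' Write gene models to BED12
#' @param genes data.frame with columns chrom, start, end, name, strand,
#'   blockSizes, blockStarts (comma strings, starts relative to `start`).
#' @param path Output path.
#' @export
write_bed12 <- function(genes, path) {
  n <- nrow(genes)
  nblk <- vapply(strsplit(sub(",$", "", genes$blockSizes), ","), length, 1L)
  out <- paste(genes$chrom, genes$start, genes$end, genes$name,
               genes$score %||% 0L, genes$strand, genes$start, genes$end,
               "0", nblk, genes$blockSizes, genes$blockStarts, sep = "\t")
  writeLines(out, path)
  invisible(path)
}

#' Read a JASPAR-format PFM library
#'
#' Accepts the JASPAR text format: a `>motif_id` header followed by four count
#' rows, either labelled (`A [ 1 2 3 ]`) or plain numbers. Rows are reordered
#' to A, C, G, T regardless of label order in the file.
#'
#' @param path Path to a JASPAR PFM text file.
#' @return List of PFMs, each a list with `motif_id` and `counts` (4 x W
#'   matrix, rows A/C/G/T).
#' @export
read_jaspar <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ln <- trimws(readLines(path))
  ln <- ln[nzchar(ln)]
  hd <- which(startsWith(ln, ">"))
  if (!length(hd)) return(list())
  ends <- c(hd[-1] - 1L, length(ln))
  out <- vector("list", length(hd))
  for (i in seq_along(hd)) {
    id <- sub("^>\\s*", "", ln[hd[i]])
    id <- strsplit(id, "\\s+")[[1]][1]
    body <- ln[(hd[i] + 1L):ends[i]]
    if (length(body) != 4L) stop("PFM ", id, ": expected 4 count rows")
    labels <- toupper(sub("^([A-Za-z]).*$", "\\1", body))
    labelled <- all(labels %in% c("A", "C", "G", "T")) && !anyDuplicated(labels)
    rows <- lapply(body, function(b) {
      b <- gsub("[][]", " ", b)
      b <- sub("^\\s*[A-Za-z]\\s", " ", b)
      v <- suppressWarnings(as.numeric(strsplit(trimws(b), "\\s+")[[1]]))
      if (anyNA(v)) stop("PFM ", id, ": non-numeric count")
      v
    })
    if (length(unique(lengths(rows))) != 1L)
      stop("PFM ", id, ": ragged count rows")
    counts <- do.call(rbind, rows)
    rownames(counts) <- if (labelled) labels else c("A", "C", "G", "T")
    counts <- counts[c("A", "C", "G", "T"), , drop = FALSE]
    if (any(counts < 0)) stop("PFM ", id, ": negative count")
    if (any(colSums(counts) <= 0)) stop("PFM ", id, ": zero column sum")
    out[[i]] <- list(motif_id = id, counts = counts)
  }
  out
}

.report_schemas <- list(
  candidates = list(key = "mrna_id",
    cols = c("mrna_id", "fusion_class", "order_type", "gap_overlap",
             "junction_q", "chrom5", "strand5", "start5", "end5",
             "chrom3", "strand3", "start3", "end3")),
  verified = list(key = "mrna_id",
    cols = c("mrna_id", "status", "aligned_precisely", "donor", "acceptor",
             "canonical", "frame_ok")),
  est_support = list(key = "chimera_id",
    cols = c("chimera_id", "n_spanning", "supported")),
  junction_counts = list(key = c("event_id", "sample_id"),
    cols = c("event_id", "sample_id", "n_reads")),
  validation = list(key = "event_id",
    cols = c("event_id", "n_reads", "n_start_positions", "n_samples",
             "validated")),
  expression_stats = list(key = "event_id",
    cols = c("event_id", "mean", "sd", "cv_percent")),
  motifs = list(key = "chimera_id",
    cols = c("chimera_id", "category5", "category3", "width", "site5",
             "site3", "score", "empirical_p"))
)

#' Write a tab-separated report with a fixed schema
#'
#' Emits a header line and rows sorted deterministically by the schema's
#' primary key.
#'
#' @param records data.frame conforming to the named schema.
#' @param path Output path.
#' @param schema One of `names(chimfuse:::.report_schemas)`.
#' @export
write_report <- function(records, path, schema) {
  sc <- .report_schemas[[schema]]
  if (is.null(sc)) stop("unknown report schema: ", schema)
  miss <- setdiff(sc$cols, names(records))
  if (length(miss)) stop("records missing columns: ", paste(miss, collapse = ", "))
  records <- records[, sc$cols, drop = FALSE]
  if (nrow(records))
    records <- records[do.call(order, unname(records[sc$key])), , drop = FALSE]
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a report written by [write_report()]
#' @param path Path to the TSV file.
#' @param schema Schema name used when writing.
#' @export
read_report <- function(path, schema) {
  sc <- .report_schemas[[schema]]
  if (is.null(sc)) stop("unknown report schema: ", schema)
  df <- read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(sc$cols, names(df))
  if (length(miss)) stop("file missing columns: ", paste(miss, collapse = ", "))
  df
}
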