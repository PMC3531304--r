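# Internal helpers shared across modules. All genomic/transcript coordinates in
# this package are 0-based half-open; R's 1-based substring arithmetic is
# confined to these helpers.

#' @import data.table
#' @importFrom stats cor ks.test na.omit p.adjust pnorm rbinom rgamma rnorm
#'   runif sd setNames
#' @importFrom utils combn head read.delim write.table packageVersion
NULL

# 0-based half-open substring
subseq0 <- function(x, start, end) {
  substring(x, start + 1L, end)
}

# reverse complement of plain character DNA (vectorised)
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# random DNA string of length n at a given GC content (uses current RNG state)
random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p), collapse = "")
}

# overwrite bases of `seq` at 0-based position `at` with `piece`
overwrite_seq <- function(seq, at, piece) {
  w <- nchar(piece)
  stopifnot(at >= 0, at + w <= nchar(seq))
  paste0(subseq0(seq, 0L, at), piece, subseq0(seq, at + w, nchar(seq)))
}

# do 0-based half-open intervals [s1,e1) and [s2,e2) overlap?
ivl_overlap <- function(s1, e1, s2, e2) {
  s1 < e2 & s2 < e1
}

# parse a PSL comma-separated list ("12,34,") into an integer vector
parse_commas <- function(x) {
  as.integer(strsplit(sub(",$", "", x), ",", fixed = TRUE)[[1]])
}

fmt_commas <- function(v) {
  paste0(paste(v, collapse = ","), ",")
}

# validate a genome store: named character vector, unique names, A/C/G/T/N only
check_genome <- function(genome) {
  if (is.null(names(genome)) || anyDuplicated(names(genome)))
    stop("genome must be a character vector with unique names")
  bad <- grepl("[^ACGTN]", genome)
  if (any(bad))
    stop("genome sequence contains non-ACGTN characters: ", names(genome)[bad][1])
  invisible(genome)
}

# per-string mismatch counts between equal-length string vectors
hamming_vec <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (!length(a)) return(integer(0))
  mapply(function(x, y) sum(utf8ToInt(x) != utf8ToInt(y)), a, b, USE.NAMES = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
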