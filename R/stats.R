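# Expression-variability statistics for validated events: unique-event
# filtering, coefficient of variation, a normality check, and an exact
# two-sided rank-sum test.

#' Filter validated events down to unique events
#'
#' An event is kept iff it has a nonzero junction-read count in every sample
#' and neither of its partner locus intervals overlaps any partner interval
#' of any other candidate (overlapping pairs are all excluded).
#'
#' @param validated data.frame from [validate_events()] (only rows with
#'   `validated == TRUE` are considered).
#' @param candidates List of chimera candidates (ids matching event ids).
#' @param counts Events x samples count matrix ([junction_count_matrix()]).
#' @return Character vector of unique event ids.
#' @export
filter_unique_events <- function(validated, candidates, counts) {
  ids <- validated$event_id[validated$validated]
  ids <- intersect(ids, rownames(counts))
  ids <- ids[apply(counts[ids, , drop = FALSE] > 0, 1, all)]
  # partner-interval overlap against every other candidate
  loci <- do.call(rbind, lapply(candidates, function(cd) {
    data.frame(id = cd$mrna_id,
               chrom = c(cd$p5$tName, cd$p3$tName),
               start = c(cd$p5$tStart, cd$p3$tStart),
               end = c(cd$p5$tEnd, cd$p3$tEnd), stringsAsFactors = FALSE)
  }))
  overlapped <- vapply(ids, function(id) {
    mine <- loci[loci$id == id, , drop = FALSE]
    other <- loci[loci$id != id, , drop = FALSE]
    any(vapply(seq_len(nrow(mine)), function(i) {
      any(other$chrom == mine$chrom[i] &
            ivl_overlap(other$start, other$end, mine$start[i], mine$end[i]))
    }, TRUE))
  }, TRUE)
  ids[!overlapped]
}

#' Coefficient of variation of junction-read counts
#'
#' CV is the percentage ratio of the sample standard deviation (n-1
#' denominator) to the sample mean.
#'
#' @param values Numeric vector (n >= 2).
#' @return List with `mean`, `sd`, `cv_percent` (NA, flagged `undefined`,
#'   when the mean is zero).
#' @export
cv_stat <- function(values) {
  stopifnot(length(values) >= 2L)
  m <- mean(values)
  s <- sd(values)
  if (m == 0) return(list(mean = m, sd = s, cv_percent = NA_real_,
                          undefined = TRUE))
  list(mean = m, sd = s, cv_percent = 100 * s / m, undefined = FALSE)
}

#' Kolmogorov-Smirnov check of normality
#'
#' One-sample KS test of the values against Normal(mean, sd) with both
#' parameters estimated from the data (no Lilliefors correction, matching
#' the plain use of the test); D = sup |F_n - Phi|, p from the asymptotic KS
#' distribution.
#'
#' @param cv_list Numeric vector (n >= 5, nonzero variance).
#' @return List with `D` and `p`.
#' @export
ks_normality <- function(cv_list) {
  stopifnot(length(cv_list) >= 5L)
  if (sd(cv_list) == 0) stop("zero variance: KS normality check undefined")
  kt <- suppressWarnings(ks.test(cv_list, "pnorm", mean(cv_list), sd(cv_list)))
  list(D = unname(kt$statistic), p = kt$p.value)
}

#' Exact two-sided rank-sum test
#'
#' W is the rank sum of group A (midranks for ties). When
#' `choose(nA+nB, nA)` does not exceed `max_enum` the two-sided p is computed
#' by full enumeration of all label assignments, p = 2*min(P(W<=w), P(W>=w))
#' capped at 1; otherwise the normal approximation with tie correction and
#' continuity correction is used.
#'
#' @param groupA,groupB Numeric vectors (both nonempty).
#' @param max_enum Enumeration limit on the number of label assignments.
#' @return List with `W`, `p` and `method` ("exact" or "normal").
#' @export
ranksum_exact <- function(groupA, groupB, max_enum = 1e6) {
  na <- length(groupA); nb <- length(groupB)
  stopifnot(na >= 1L, nb >= 1L)
  n <- na + nb
  r <- rank(c(groupA, groupB))
  W <- sum(r[seq_len(na)])
  eps <- 1e-8
  if (choose(n, na) <= max_enum) {
    cmb <- combn(n, na)
    null <- colSums(matrix(r[cmb], nrow = na))
    p <- 2 * min(mean(null <= W + eps), mean(null >= W - eps))
    return(list(W = W, p = min(1, p), method = "exact"))
  }
  mu <- na * (n + 1) / 2
  ties <- table(r)
  sig2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  dev <- abs(W - mu)
  z <- max(0, dev - 0.5) / sqrt(sig2)
  list(W = W, p = min(1, 2 * pnorm(-z)), method = "normal")
}

#' Summarise expression variability of unique events
#'
#' Computes the per-event CV across samples, the KS normality check of the CV
#' distribution, and (when a two-level grouping is supplied) the exact
#' rank-sum p per event between the groups.
#'
#' @param counts Events x samples count matrix restricted to unique events.
#' @param groups Optional named character/factor: group label per sample.
#' @return List with `per_event` (data.frame: event_id, mean, sd, cv_percent,
#'   and ranksum_p when groups are given), `cv_mean`, `cv_sd`, `ks` (or NULL
#'   when fewer than 5 defined CVs).
#' @export
expression_summary <- function(counts, groups = NULL) {
  rows <- lapply(rownames(counts), function(ev) {
    st <- cv_stat(as.numeric(counts[ev, ]))
    data.frame(event_id = ev, mean = st$mean, sd = st$sd,
               cv_percent = st$cv_percent, stringsAsFactors = FALSE)
  })
  per_event <- do.call(rbind, rows)
  if (!is.null(groups)) {
    groups <- groups[colnames(counts)]
    lv <- unique(na.omit(as.character(groups)))
    stopifnot(length(lv) == 2L)
    per_event$ranksum_p <- vapply(rownames(counts), function(ev) {
      ranksum_exact(as.numeric(counts[ev, groups == lv[1]]),
                    as.numeric(counts[ev, groups == lv[2]]))$p
    }, 0)
  }
  cvs <- per_event$cv_percent[!is.na(per_event$cv_percent)]
  ks <- if (length(cvs) >= 5L && sd(cvs) > 0) ks_normality(cvs) else NULL
  list(per_event = per_event, cv_mean = mean(cvs), cv_sd = sd(cvs), ks = ks)
}
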