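---
title: "chimfuse: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chimfuse: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the models, conventions and design decisions behind
the package: what each stage assumes, why the defaults are what they are,
and what the synthetic study does and does not demonstrate.

# The model

A chimeric (trans-spliced) mRNA is a transcript whose 5′ and 3′ parts derive
from two non-contiguous genomic loci. The spliceosomal model predicts three
observable signatures, and the pipeline tests all three:

* the transcript splits into exactly two high-identity partial alignments
  whose junction on the transcript is sharp (gap/overlap within alignment
  noise);
* the fusion point mimics a cis splice site: when the two genomic regions
  are artificially joined, the transcript spliced-aligns with a precise
  junction flanked by a GT donor and an AG acceptor on the transcribed
  strand, and the message retains an intact reading frame across the
  junction;
* the junction sequence is private to the chimera, so sequencing reads that
  span it cannot map contiguously to the genome but do map to an artificial
  junction reference, from multiple start positions and samples if the
  molecule is really expressed.

The shared-motif analysis addresses the *origin* question: if parental genes
are co-recruited to a shared transcription site by a common DNA-binding
factor (CTCF being the canonical candidate), their genomic neighbourhoods
should share binding-site-like sequence.

# Coordinates and formats

All intervals are 0-based half-open internally; 1-based coordinates appear
only in human-readable report columns. PSL is the canonical alignment input
because BED12 lacks the query coordinates that the junction gap rule needs;
`read_bed12()` imports such records but flags them `has_query = FALSE` and
discovery excludes them. One PSL convention is deliberate: `qStarts` are
stored in the query's forward (transcript) orientation and `tStarts` on the
target plus strand, blocks ordered by query start — BLAT's reversed-query
convention for minus-strand records is not used, which keeps the junction
arithmetic `g = qStart(3′) − qEnd(5′)` orientation-free. FASTQ quality is
fixed to Sanger Phred+33 with no autodetection, for determinism. Parsers
reject invariant-violating input with the offending line; nothing is
silently repaired.

# Discovery

`discovery_params()` defaults: minimum identity 0.96, minimum aligned
length 100 nt, junction |g| ≤ 10 nt, all boundaries inclusive.

**Non-contiguity.** Two loci count as non-contiguous when they lie on
different chromosomes or strands; on the same chromosome and strand, when
their order in transcription direction is inconsistent with a single cis
transcript (the 3′ part upstream of, or inside, the 5′ part), or when they
are colinear but separated by more than `max_intron` (default 1,000,000 nt —
far beyond plausible intron sizes, so a readthrough-style candidate must be
an extreme outlier). The package-default synthetic study uses
`max_intron = 50,000` with its readthrough pair planted 60 kb apart — the
same geometry at study scale.

**Exactly two loci.** Transcripts with three or more surviving alignments
are excluded as ambiguous rather than pairwise-enumerated, and two records
with equal `qStart` are excluded because the 5′/3′ assignment is undefined.
When the identity/length filter removes a record and leaves fewer than two
loci, the discovery log names that filter — this is what makes the
single-violation decoys diagnosable.

# Trans-splice verification

`build_fused_reference()` joins each partner's genomic region plus
`flank = 500` nt of context per side (clipped at chromosome edges),
reverse-complementing minus-strand segments so the fused sequence reads
5′→3′ in transcript orientation. The flank matters: the donor/acceptor
dinucleotides live just outside the aligned exons, so without context the
signals are unreadable (`splice_signals()` then reports `NN`/`no-context`).

`spliced_align()` is a simplified seed-and-chain spliced aligner, not a
SIM4 reimplementation: exact 12-mer seeds are collapsed along diagonals into
ungapped blocks, merged across mismatch runs while the per-block mismatch
rate stays within 4% (mirroring the 96%-identity regime), and chained
colinearly; target gaps between chained blocks are introns (minimum 30 nt).
Two numerical points:

* **Boundary ambiguity.** When transcript bases adjacent to an exon
  boundary coincidentally match the intron side, the optimal split can
  slide by a few bases without changing the match count. Like splice-aware
  aligners, the chain is post-processed to prefer, among score-equivalent
  splits, the one whose intron boundaries read GT..AG. Chaining also
  tolerates a small query overlap between segments (trimmed at
  reconstruction) for the same reason.
* **Failure is a status.** If less than half the query aligns the candidate
  is marked unverifiable, not an exception.

`check_junction()` demands a block ending exactly at the fusion coordinate
and the next beginning exactly there, on opposite sides of the artificial
join — no query gap or overlap.

**Reading frame.** "Structural integrity" is operationalised as: the
longest open reading frame (ATG..stop, standard code, sense strand only —
an mRNA is stranded; an ORF running to the transcript end without a stop is
allowed; ties go to the leftmost) must span the fusion coordinate. This is
a deliberate, simple reading of an under-specified rule; it is monotone,
deterministic and testable against an exhaustive ORF scan.

Only the trans-junction is checked for GT/AG; cis-introns of the partners
are the generator's responsibility and are reported informationally.

# EST support

`local_align()` is a seeded local aligner: shared 11-mers define diagonals
and each diagonal's maximal-scoring ungapped segment (match +1, mismatch −1)
containing a seed is computed exactly; the best segment across diagonals is
reported, with a 0.96 identity floor and a 22 nt minimum length. Gapped
refinement is omitted: the package's error model (and the regime the
identity floor implies) is substitution-only, where the ungapped optimum
equals the Smith–Waterman optimum — the test suite checks exactly this
equivalence. ESTs are unstranded, so both orientations are aligned.
`spanning_support()` counts distinct ESTs covering at least 20 nt on both
sides of the fusion point; 3 are required.

# Junction-read quantification

`junction_params()` encodes the geometry: read length L, overhang k = 5,
junction reference of length 2·(L−k) (L−k per side of the fusion point),
valid start window 1 … L−2k+1. With L = 76: 142 nt, 71 per side, last start
67; with the 49-nt pools, 88 nt and last start 40. Reads longer than L are
trimmed from the right (the low-quality end); the read-level quality rule is
mean Phred ≥ 20 by default (`mode = "min"` is available) — "quality below
20" is ambiguous at read level and the mean is the common reading.

`map_genome()` is an exact ungapped mapper: pigeonhole seeding with
`max_mismatches + 1` disjoint segments guarantees that every alignment with
at most 2 mismatches is found, so the unique/multi/unmapped classification
provably equals a brute-force Hamming scan (and is tested against one).
Mismatch counting is plain Hamming with no quality weighting. Only
genome-*unmapped* reads proceed to junction calling; multi-mapped reads do
not. A read matching several junction references is assigned to the
fewest-mismatch reference; ties are flagged `shared` and excluded from
unique-event analysis. Validation requires junction reads from ≥ 3 distinct
start positions or ≥ 3 samples, and is monotone in added evidence.

Coverage profiles pool genome-unique reads (mapped back to transcript
coordinates through the candidate's alignment blocks; a read must lie
entirely inside one block) with junction reads; when the chimera is less
abundant than its parents this produces the characteristic trough at the
fusion point, which the test suite checks against a binomial expectation.

# Expression statistics

Unique events must be validated, nonzero in every sample, and their partner
intervals must not overlap any other candidate's partners (both members of
an overlapping pair are excluded). CV is 100·sd/mean with the n−1 standard
deviation, undefined (flagged, excluded from summaries) at mean zero.
The KS normality check estimates mean and sd from the data and uses the
asymptotic one-sample KS distribution — no Lilliefors correction, matching
the plain use of the test; this makes the p conservative, which is
acceptable for a descriptive normality statement. Counts are compared raw,
with no library-size normalisation, since junction-read counts at a fixed
read length are directly comparable across the cohort's equal-depth samples.

`ranksum_exact()` enumerates all C(nA+nB, nA) label assignments (up to 10⁶;
beyond that a tie-corrected normal approximation with continuity correction)
and uses midranks for ties; the two-sided p is 2·min(P(W≤w), P(W≥w)) capped
at 1. A discreteness caveat: at the cohort's 5-vs-6 design the exact test's
achievable level nearest 0.05 is 14/462 ≈ 0.030, so a type-I-error estimate
under a continuous null concentrates near 0.030, not 0.050.

# Shared-motif analysis

Parental regions are taken in transcription direction with
`up_window = down_window = 2000` nt (clipped windows flagged): upstream,
concatenated exons, concatenated introns, downstream; all nonempty category
pairings are formed. `find_shared_motif()` enumerates shared exact 10-mers,
extends each seed pair in both directions at +1/−1 with width clamped to
10–30 nt, and keeps the single best pair of sites (zero or one site per
sequence, one motif per pair). Significance is the fraction of 200
dinucleotide-shuffled (Altschul–Erickson) replicates of the second sequence
whose best score reaches the observed one; results with p > 0.05 are
discarded. For the category table each chimera contributes its single
best-scoring pairing — the table reports one cell per chimera — and the
shuffle test is run on that best pairing.

`match_pfm()` compares a shared motif's 4×W count matrix against a PFM
library by mean per-column Pearson correlation of frequency columns over
both orientations and all offsets with ≥ 4 overlapping columns;
zero-variance columns contribute 0. The null column-shuffles each library
motif (p = (1+k)/(1+n), keeping p in (0, 1]), with Benjamini–Hochberg FDR
across the library. Two known limitations of this TOMTOM-style comparison:
short overlaps can reach high mean correlations by chance (the empirical
null absorbs most but not all of this), and for motifs with many similar
columns (e.g. G-runs) the column-shuffle null is heavy, making true matches
conservative under FDR. The shipped library
(`inst/extdata/jaspar_synthetic_core.pfm`) is synthetic — twelve invented
motifs including a CTCF-like 19-mer — and is not derived from any real
database.

# The synthetic study

`simulate_study()` generates the full truth-annotated study from one seed;
identical seeds give identical bytes. Defaults (all in `study_config()`)
were chosen once as study conditions:

* **Genome**: 4 chromosomes of 180/150/120/90 kb at GC 0.42 — large enough
  to place a 60 kb readthrough separation and 27 chimera pairs, small
  enough that a full run maps tens of thousands of reads in seconds.
* **Chimeras**: 20 clean ones covering every class and ordering type with
  the intra-strand orders weighted like a real screen (downstream-dominant),
  plus 7 decoys, each violating exactly one filter: alignment identity
  0.95, part length 99 nt, junction gap 11 nt, GC donor, longest ORF
  confined to the 3′ part, only 2 spanning ESTs, junction reads from only 2
  starts in 2 samples. Junctions sit at exon boundaries so the trans
  junction inherits a genuine GT donor (from the 5′ partner's next intron)
  and AG acceptor (from the 3′ partner's previous intron). Nested ordering
  types are built by writing one partner gene inside the other's intron.
* **Reading frames**: background ORF runs are capped (a stop is written
  into any stop-free run beyond 40 codons) and a long ORF is planted across
  the junction — or, for the frame decoy, entirely inside the 3′ part
  behind a stop wall in all three frames — so the frame rule's truth value
  is guaranteed by construction rather than left to chance.
* **Cohort**: 11 liver samples (5 male, 6 female; eight at 76 nt, three at
  101 nt to exercise trimming) and three 49-nt muscle pools; per-event
  per-sample read counts are Gamma-distributed with mean 80 and CV 0.57
  (the dispersion regime of a real cohort), substitution errors at 1%, no
  indels (every aligner in the package is ungapped by design).
* **Junction-read truth**: a read overlapping the fusion point by ≥ 5 nt on
  both sides (after trimming) is a truth junction read, except that reads
  whose error-free sequence still admits a contiguous genomic alignment
  with ≤ 2 mismatches (possible at 5–7 nt overhangs when the intron
  continuation happens to match) are flagged `masked` — no
  unmapped-read strategy can see them, so they are excluded from recall
  denominators. The flag is computed against the partner-locus
  continuations recorded at generation time.
* **Motif study**: 20 planted + 20 decoy 1-kb pairs with a CTCF-like
  19-mer consensus, at most one mismatch per site planted in the outer four
  positions so an exact 10-mer seed window always survives both sites (an
  interior mismatch can make a planted motif invisible to a seed-based
  search, which would falsify the truth label, and for widths below 18
  sites are planted exact); decoy pairs are rejection-sampled until their
  best chance shared-site score is ≤ 14, strictly below the weakest
  plantable site (a 19-mer with one mismatch per site scores ≥ 15) — a
  "decoy" that genuinely contains a planted-strength shared site would be
  a mislabelled positive, not a false positive.

**What passing tests do and do not show.** The generator produces clean
exon structures, substitution-only errors, uniform read starts and
independent samples. Real data add indels, positional and GC bias, quality-
correlated errors, paralogy, incomplete genomes and spliced ESTs; the
pipeline's behaviour under those is untested here. The study demonstrates
that the implementation applies its stated rules exactly (filter fidelity,
oracle equivalence, recall at the binomial expectation under the mismatch
cap), not that those rules are optimal for any particular organism.

# Pipeline scale and determinism

`run_pipeline()` executes discovery → verification → EST support → QC /
genome mapping / junction calling / validation (per tissue) → unique-event
statistics → shared-motif analysis, and emits a Venn-style intersection
table of the evidence sets plus a manifest of parameters and seeds. Every
stochastic step takes an explicit seed; a rerun with the same configuration
is identical. The default test-suite and acceptance runs use the study sizes
above (a full run is a few minutes on one CPU); the mini configuration in
the README shows how to scale the same study down.
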