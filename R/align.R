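# Gapped short-read alignment: scoring, affine-gap local alignment, k-mer
# seed index and seed-and-extend mapping, mapping quality.

#' Alignment scoring scheme
#'
#' Defaults (match 1, mismatch 3, gap open 5, gap extend 2) make a single
#' 1 bp indel (cost 7) preferable to three mismatches (cost 9 + lost
#' matches) in a 33 bp read — the regime in which short-read gapped aligners
#' report indels.  A gap of length L costs `gap_open + L * gap_extend`.
#'
#' @param match positive match reward.
#' @param mismatch non-negative mismatch penalty.
#' @param gap_open,gap_extend non-negative gap penalties, open >= extend.
#' @export
scoring_scheme <- function(match = 1L, mismatch = 3L, gap_open = 5L,
                           gap_extend = 2L) {
  stopifnot(match > 0, mismatch >= 0, gap_open >= 0, gap_extend >= 0,
            gap_open >= gap_extend)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend)),
            class = "ScoringScheme")
}

#' Optimal local (or global) alignment under affine gap scoring
#'
#' 'N' never matches.  Co-optimal alignments resolve deterministically: the
#' traceback prefers the diagonal state (fewer gaps) and the end cell with
#' the leftmost target coordinate.
#'
#' @param query,target non-empty A/C/G/T/N strings.
#' @param scoring a [scoring_scheme()].
#' @param global if TRUE, end-to-end (Needleman-Wunsch) alignment.
#' @return list: score, cigar (M/I/D, query-centric), qstart/qend,
#'   tstart/tend (0-based half-open spans), n_gaps, n_mismatch.
#' @export
smith_waterman_affine <- function(query, target, scoring = scoring_scheme(),
                                  global = FALSE) {
  if (!nzchar(query) || !nzchar(target)) stop("empty sequence")
  sw_affine_cpp(query, target, scoring$match, scoring$mismatch,
                scoring$gap_open, scoring$gap_extend, global)
}

#' Build a k-mer seed index over a genome
#'
#' Exact-match lookups return every genomic position of a seed; seeds
#' occurring at more than `max_hits` (K, default 8) locations are flagged
#' repetitive and contribute no candidate locations during mapping.
#'
#' @param genome named character vector of contigs (or a `GenomeSet` slot).
#' @param seed_length k-mer length.
#' @param max_hits repetitive-lookup threshold K.
#' @return a `SeedIndex` handle.
#' @export
build_index <- function(genome, seed_length = 14, max_hits = 8) {
  ptr <- seed_index_build_cpp(names(genome), unname(genome),
                              as.integer(seed_length), as.integer(max_hits))
  structure(list(ptr = ptr, seed_length = as.integer(seed_length),
                 max_hits = as.integer(max_hits),
                 contigs = setNames(nchar(genome), names(genome)),
                 genome = genome),
            class = "SeedIndex")
}

#' @export
print.SeedIndex <- function(x, ...) {
  cat("SeedIndex: k =", x$seed_length, ", K =", x$max_hits, ",",
      length(x$contigs), "contig(s)\n")
  invisible(x)
}

#' Look up a seed in the index
#' @param index a `SeedIndex`.
#' @param seed a string of length `seed_length`.
#' @return list with a positions data.frame (contig, pos 0-based) and a
#'   `repetitive` flag; repetitive lookups return no positions.
#' @export
index_lookup <- function(index, seed) {
  r <- seed_index_lookup_cpp(index$ptr, seed)
  data_frame <- data.frame(
    contig = names(index$contigs)[r$contig], pos = r$pos,
    stringsAsFactors = FALSE)
  list(positions = data_frame, repetitive = r$repetitive)
}

#' Map reads to a genome by seed-and-extend gapped alignment
#'
#' Both strands are searched; candidate locations come from non-repetitive
#' seed lookups, capped at `max_candidates` (M) per read; every candidate is
#' aligned locally.  The highest-scoring alignment is reported only when it
#' covers the read end-to-end: a best alignment that soft-clips any base
#' leaves the read unmapped, so that only reads mapped over their entire
#' length enter calling.  MAPQ is 0 on a score tie, 60 with no full-length
#' runner-up, otherwise proportional to the score margin.
#'
#' @param reads data.frame with read_id, seq, qual (Phred+33).
#' @param index a `SeedIndex`.
#' @param scoring a [scoring_scheme()].
#' @param max_candidates CAL cap per read (default 1280).
#' @param mapq_score_range score margin that saturates one mismatch-worth of
#'   MAPQ; see [compute_mapq()].
#' @return alignment data.frame (SAM-convention fields; pos is 1-based;
#'   unmapped reads carry flag 4).
#' @export
map_reads <- function(reads, index, scoring = scoring_scheme(),
                      max_candidates = 1280, mapq_score_range = 4) {
  slope <- max(1L, as.integer(round(24 / mapq_score_range)))
  out <- map_reads_cpp(index$ptr, reads$read_id, reads$seq, reads$qual,
                       as.integer(max_candidates), scoring$match,
                       scoring$mismatch, scoring$gap_open,
                       scoring$gap_extend, 8L, slope)
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Map a single read
#' @inheritParams map_reads
#' @param read_id,seq,qual one read.
#' @return one-row alignment data.frame (flag 4 when unmapped).
#' @export
map_read <- function(seq, index, qual = NULL, read_id = "read1",
                     scoring = scoring_scheme(), max_candidates = 1280) {
  if (is.null(qual)) qual <- strrep(rawToChar(as.raw(37 + 33)), nchar(seq))
  map_reads(data.frame(read_id = read_id, seq = seq, qual = qual,
                       stringsAsFactors = FALSE),
            index, scoring, max_candidates)
}

#' Mapping quality from best and second-best alignment scores
#'
#' A contract, not a reproduction of any particular aligner's formula:
#' 0 when the best score is tied, 60 when no second candidate exists, and
#' otherwise monotone non-decreasing in the score margin —
#' `min(60, round(24/score_range) * (best - second))`.
#'
#' @param best_score best full-length alignment score.
#' @param second_score runner-up score, or NULL/NA if none.
#' @param score_range score difference corresponding to one mismatch under
#'   the scoring in use (match + mismatch; 4 for the defaults).
#' @return integer MAPQ between 0 and 60.
#' @export
compute_mapq <- function(best_score, second_score = NULL, score_range = 4) {
  if (is.null(second_score) || is.na(second_score)) return(60L)
  if (second_score > best_score) stop("best_score must be >= second_score")
  if (second_score == best_score) return(0L)
  slope <- max(1L, as.integer(round(24 / score_range)))
  min(60L, slope * as.integer(best_score - second_score))
}
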