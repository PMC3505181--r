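# False-positive elimination cascade.  Each passing candidate receives
# exactly one label, tested in this order: paternal_allele (genuine
# haplotype difference), splice_junction (read forced across an exon-exon
# boundary), paralog (gapless match elsewhere in the reference), or
# known_variant (database-annotated genomic indel); whatever survives is
# residual — the putative editing signal.

#' Classification cascade parameters
#'
#' @param flank bases of context on each side of the anchor (32).
#' @param partial_max a splice hit requires the unedited window to align to
#'   the transcript over at most this fraction of its length.
#' @param min_anchor minimum gapless segment length for the partial match.
#' @param junction_tol maximum distance (bp) between the partial-alignment
#'   breakpoint and an annotated junction; generous enough that a gapless
#'   segment which overshoots the boundary through a short repeat or a
#'   chance match still counts as breaking at the junction.
#' @param mm_max_splice mismatches allowed in the full edited-window match
#'   (the artifact typically carries one or more mismatches).
#' @param mm_max_paralog mismatches allowed in a gapless paralog match.
#' @param mm_max_paternal mismatches allowed when realigning a supporting
#'   read to the paternal locus.
#' @param full_min fraction of the edited window that must align gaplessly
#'   for a paralog hit.
#' @export
classify_params <- function(flank = 32L, partial_max = 0.9, min_anchor = 15L,
                            junction_tol = 15L, mm_max_splice = 3L,
                            mm_max_paralog = 6L, mm_max_paternal = 3L,
                            full_min = 0.95) {
  list(flank = flank, partial_max = partial_max, min_anchor = min_anchor,
       junction_tol = junction_tol, mm_max_splice = mm_max_splice,
       mm_max_paralog = mm_max_paralog, mm_max_paternal = mm_max_paternal,
       full_min = full_min)
}

#' Extract the flanking windows of a candidate
#'
#' The genomic window runs from `flank` bp upstream through `flank` bp
#' downstream of the anchor base, without the indel; the edited window is
#' the same window with the candidate indel applied (one base longer for
#' insertions, shorter for deletions).  Windows truncate at contig ends,
#' with the actual upstream extent recorded.
#'
#' @param candidate one candidate row.
#' @param genome the genome the candidate was called against.
#' @param flank window half-width.
#' @return list with genomic_window, edited_window, up (actual upstream
#'   extent), anchor_offset (0-based anchor position within the window).
#' @export
extract_flanks <- function(candidate, genome, flank = 32L) {
  s <- genome[[candidate$contig]]
  n <- nchar(s)
  a <- candidate$pos
  w0 <- max(0L, a - flank)
  w1 <- min(n, a + flank + 1L)
  win <- substr0(s, w0, w1)
  off <- a - w0
  if (candidate$kind == "insertion") {
    edited <- paste0(substr(win, 1, off + 1), candidate$seq,
                     substr(win, off + 2, nchar(win)))
  } else {
    L <- nchar(candidate$seq)
    edited <- paste0(substr(win, 1, off + 1),
                     substr(win, off + 2 + L, nchar(win)))
  }
  list(genomic_window = win, edited_window = edited, up = off,
       anchor_offset = off)
}

# candidate anchor in reference coordinates (NA when not liftable)
candidate_ref_anchor <- function(candidate, gs, calling_hap = "maternal") {
  if (calling_hap == "reference") return(candidate$pos)
  hap_to_ref(gs, calling_hap, candidate$contig, candidate$pos)
}

#' Test whether a candidate reflects the paternal allele
#'
#' Realigns every indel-supporting read to the homologous locus of the other
#' haplotype; the candidate is a genuine diploid difference when each one
#' aligns there full-length without indels (allowing a few mismatches).
#' Covers both patterns: all reads paternal, or a maternal/paternal mixture
#' — non-supporting reads match the calling haplotype by construction.
#'
#' @param candidate one candidate row.
#' @param alignments alignment table holding the supporting reads.
#' @param gs the diploid `GenomeSet`.
#' @param params see [classify_params()].
#' @param calling_hap haplotype the candidates were called against.
#' @return list(matched, unresolved, evidence).
#' @export
check_paternal_allele <- function(candidate, alignments, gs,
                                  params = classify_params(),
                                  calling_hap = "maternal") {
  other <- if (calling_hap == "maternal") "paternal" else "maternal"
  ra <- candidate_ref_anchor(candidate, gs, calling_hap)
  if (is.na(ra))
    return(list(matched = FALSE, unresolved = TRUE, evidence = NULL))
  pa <- ref_to_hap(gs, other, candidate$contig, ra)
  if (is.na(pa))
    return(list(matched = FALSE, unresolved = TRUE, evidence = NULL))
  ids <- strsplit(candidate$support_reads, ";", fixed = TRUE)[[1]]
  sup <- alignments[match(ids, alignments$qname), , drop = FALSE]
  rl <- max(nchar(sup$seq))
  oseq <- gs[[other]][[candidate$contig]]
  w0 <- max(0L, pa - rl - 8L)
  w1 <- min(nchar(oseq), pa + rl + 9L)
  window <- substr0(oseq, w0, w1)
  ok <- vapply(sup$seq, function(s)
    nrow(ungapped_full_hits_cpp(s, window, params$mm_max_paternal)) > 0,
    logical(1))
  if (all(ok) && length(ok) > 0) {
    list(matched = TRUE, unresolved = FALSE,
         evidence = sprintf("%s:%s:%d", other, candidate$contig, pa + 1L))
  } else {
    list(matched = FALSE, unresolved = FALSE, evidence = NULL)
  }
}

#' Test whether a candidate is a splice-junction misalignment
#'
#' Requires the published three-part signature against a single transcript:
#' (1) the unedited window aligns gaplessly at its expected reference locus;
#' (2) the unedited window aligns gaplessly to the transcript only in part,
#' with the breakpoint at an annotated exon-exon junction of a transcript
#' overlapping the locus; (3) the edited window aligns gaplessly to the same
#' transcript over its whole length, mismatches allowed.
#'
#' Criterion (3) accepts either route: the edited window aligns gaplessly
#' over its full length, or at least `read_support_min` of the supporting
#' reads themselves align to the transcript full-length without gaps (the
#' read-based form also catches artifacts whose alignment carries more than
#' one small gap).
#'
#' @param candidate one candidate row.
#' @param flanks output of [extract_flanks()].
#' @param junction_db annotation `JunctionDB` (reference-derived).
#' @param gs the `GenomeSet` (for reference lookup and liftover).
#' @param params see [classify_params()].
#' @param calling_hap haplotype the candidates were called against.
#' @param support_seqs sequences of the indel-supporting reads (as aligned,
#'   genome-forward); NULL disables the read-based route.
#' @param read_support_min fraction of supporting reads that must match the
#'   transcript gaplessly for the read-based route.
#' @return list(matched, evidence).
#' @export
check_splice_junction <- function(candidate, flanks, junction_db, gs,
                                  params = classify_params(),
                                  calling_hap = "maternal",
                                  support_seqs = NULL,
                                  read_support_min = 0.9) {
  ra <- candidate_ref_anchor(candidate, gs, calling_hap)
  if (is.na(ra)) return(list(matched = FALSE, evidence = NULL))
  # (1) unedited window sits gaplessly at the expected reference locus
  refseq <- gs$reference[[candidate$contig]]
  win <- flanks$genomic_window
  r0 <- max(0L, ra - flanks$anchor_offset - 5L)
  r1 <- min(nchar(refseq), r0 + nchar(win) + 10L)
  c1 <- nrow(ungapped_full_hits_cpp(win, substr0(refseq, r0, r1),
                                    params$mm_max_splice)) > 0
  if (!c1) return(list(matched = FALSE, evidence = NULL))
  wlen <- nchar(win)
  for (tx_id in names(junction_db$transcripts)) {
    em <- junction_db$exon_map[junction_db$exon_map$tx_id == tx_id, ,
                               drop = FALSE]
    if (em$contig[1] != candidate$contig) next
    if (ra < min(em$ref_start) - 50 || ra >= max(em$ref_end) + 50) next
    tx <- junction_db$transcripts[[tx_id]]
    jx <- junction_offsets(junction_db, tx_id)
    if (length(jx) == 0) next
    for (q in c(win, revcomp(win))) {
      seg <- ungapped_best_segment_cpp(q, tx)
      alen <- seg$qend - seg$qstart
      if (alen < params$min_anchor || alen > params$partial_max * wlen) next
      bp_dist <- min(abs(jx - seg$tstart), abs(jx - seg$tend))
      if (bp_dist > params$junction_tol) next
      # (3) the indel-carrying sequence fully aligns, gapless, to the same
      # transcript: either the edited window, or the supporting reads
      ew <- if (identical(q, win)) flanks$edited_window
            else revcomp(flanks$edited_window)
      hit <- ungapped_full_hits_cpp(ew, tx, params$mm_max_splice)
      if (nrow(hit) > 0) {
        return(list(matched = TRUE,
                    evidence = sprintf("%s@%d(mm=%d)", tx_id,
                                       hit$offset[1], hit$mismatches[1])))
      }
      if (!is.null(support_seqs) && length(support_seqs) > 0) {
        ok <- vapply(support_seqs, function(s) {
          nrow(ungapped_full_hits_cpp(s, tx, params$mm_max_splice)) > 0 ||
            nrow(ungapped_full_hits_cpp(revcomp(s), tx,
                                        params$mm_max_splice)) > 0
        }, logical(1))
        if (mean(ok) >= read_support_min) {
          return(list(matched = TRUE,
                      evidence = sprintf("%s:reads(%d/%d gapless)", tx_id,
                                         sum(ok), length(ok))))
        }
      }
    }
  }
  list(matched = FALSE, evidence = NULL)
}

#' Test whether a candidate arises from a paralog sequence
#'
#' Searches the whole reference (both strands) for a gapless, near
#' full-length alignment of the edited window away from the candidate's own
#' locus; such a match means the supporting reads originate from a diverged
#' genomic copy.
#'
#' @inheritParams check_splice_junction
#' @export
check_paralog <- function(candidate, flanks, gs,
                          params = classify_params(),
                          calling_hap = "maternal") {
  ra <- candidate_ref_anchor(candidate, gs, calling_hap)
  q <- flanks$edited_window
  qlen <- nchar(q)
  trim <- floor(qlen * (1 - params$full_min) / 2)
  queries <- list(fwd = q, rev = revcomp(q))
  for (ori in names(queries)) {
    qq <- queries[[ori]]
    if (trim > 0) qq <- substr(qq, trim + 1, qlen - trim)
    for (contig in names(gs$reference)) {
      hits <- ungapped_full_hits_cpp(qq, gs$reference[[contig]],
                                     params$mm_max_paralog)
      if (nrow(hits) == 0) next
      for (i in seq_len(nrow(hits))) {
        h0 <- hits$offset[i]; h1 <- h0 + nchar(qq)
        own <- !is.na(ra) && contig == candidate$contig &&
          h1 > ra - 100 && h0 < ra + 100
        if (!own) {
          return(list(matched = TRUE,
                      evidence = sprintf("%s:%d-%d:%s(mm=%d)", contig,
                                         h0 + 1L, h1, ori,
                                         hits$mismatches[i])))
        }
      }
    }
  }
  list(matched = FALSE, evidence = NULL)
}

#' Test whether a candidate is a known genomic indel variant
#'
#' Matches the candidate (lifted to reference coordinates and left-aligned)
#' against database indels of identical kind and sequence, allowing the
#' anchor to shift within the homopolymer run that makes the two
#' representations equivalent.
#'
#' @param candidate one candidate row.
#' @param known data.frame of database variants: contig, pos (0-based
#'   anchor), kind, seq, id.
#' @param gs the `GenomeSet`.
#' @param calling_hap haplotype the candidates were called against.
#' @export
check_known_variant <- function(candidate, known, gs,
                                calling_hap = "maternal") {
  if (nrow(known) == 0) return(list(matched = FALSE, evidence = NULL))
  ra <- candidate_ref_anchor(candidate, gs, calling_hap)
  if (is.na(ra)) return(list(matched = FALSE, evidence = NULL))
  same <- known[known$contig == candidate$contig &
                  known$kind == candidate$kind &
                  known$seq == candidate$seq, , drop = FALSE]
  if (nrow(same) == 0) return(list(matched = FALSE, evidence = NULL))
  refseq <- gs$reference[[candidate$contig]]
  rn <- run_at(refseq, min(ra + 1L, nchar(refseq) - 1L))
  ok <- same$pos == ra |
    (same$pos >= rn["start"] - 1L & same$pos <= rn["end"])
  if (any(ok)) {
    hit <- same[which(ok)[1], ]
    list(matched = TRUE, evidence = sprintf("%s@%s:%d", hit$id, hit$contig,
                                            hit$pos + 1L))
  } else {
    list(matched = FALSE, evidence = NULL)
  }
}

#' Parse database indels from a known-variants VCF table
#' @param vcf data.frame from [read_vcf()].
#' @return data.frame with contig, pos, kind, seq, id.
#' @export
known_variants_from_vcf <- function(vcf) {
  indel <- nchar(vcf$ref) != nchar(vcf$alt)
  v <- vcf[indel, , drop = FALSE]
  kind <- ifelse(nchar(v$alt) > nchar(v$ref), "insertion", "deletion")
  seqv <- ifelse(kind == "insertion", substring(v$alt, 2), substring(v$ref, 2))
  data.frame(contig = v$contig, pos = v$pos, kind = kind, seq = seqv,
             id = v$id, stringsAsFactors = FALSE)
}

#' Run the false-positive classification cascade
#'
#' Filters apply in the published order — paternal allele, splice junction,
#' paralog, known variant — and the first matching filter assigns the label;
#' unmatched candidates are residual.  The counts always partition the
#' input.
#'
#' @param candidates passing candidates (from [apply_site_filters()]).
#' @param resources list with `gs` (GenomeSet), `alignments` (table holding
#'   the supporting reads), `junction_db` (annotation `JunctionDB`), and
#'   `known` (database indels, see [known_variants_from_vcf()]).
#' @param params see [classify_params()].
#' @param calling_hap haplotype the candidates were called against.
#' @return list: `results` (one labelled row per candidate) and `counts`.
#' @export
classify_cascade <- function(candidates, resources,
                             params = classify_params(),
                             calling_hap = "maternal") {
  candidates <- candidates[, setdiff(names(candidates),
                                     c("label", "evidence")), drop = FALSE]
  labels <- character(nrow(candidates))
  evid <- character(nrow(candidates))
  gs <- resources$gs
  genome <- gs[[if (calling_hap == "reference") "reference" else calling_hap]]
  for (i in seq_len(nrow(candidates))) {
    cand <- candidates[i, , drop = FALSE]
    flanks <- extract_flanks(cand, genome, params$flank)
    pat <- check_paternal_allele(cand, resources$alignments, gs, params,
                                 calling_hap)
    if (pat$matched) {
      labels[i] <- "paternal_allele"; evid[i] <- pat$evidence; next
    }
    ids <- strsplit(cand$support_reads, ";", fixed = TRUE)[[1]]
    sup_seqs <- resources$alignments$seq[
      match(ids, resources$alignments$qname)]
    spl <- check_splice_junction(cand, flanks, resources$junction_db, gs,
                                 params, calling_hap,
                                 support_seqs = sup_seqs)
    if (spl$matched) {
      labels[i] <- "splice_junction"; evid[i] <- spl$evidence; next
    }
    par <- check_paralog(cand, flanks, gs, params, calling_hap)
    if (par$matched) {
      labels[i] <- "paralog"; evid[i] <- par$evidence; next
    }
    kn <- check_known_variant(cand, resources$known, gs, calling_hap)
    if (kn$matched) {
      labels[i] <- "known_variant"; evid[i] <- kn$evidence; next
    }
    labels[i] <- "residual"; evid[i] <- ""
  }
  results <- cbind(candidates,
                   data.frame(label = labels, evidence = evid,
                              stringsAsFactors = FALSE))
  counts <- c(initial_candidates = nrow(candidates),
              paternal_alleles = sum(labels == "paternal_allele"),
              splice_junctions = sum(labels == "splice_junction"),
              paralog_sequences = sum(labels == "paralog"),
              known_genomic_variations = sum(labels == "known_variant"),
              residual = sum(labels == "residual"))
  stopifnot(counts[["initial_candidates"]] == sum(counts[-1]))
  list(results = results, counts = counts)
}
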