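# Pileup construction and indel candidate calling with the initial filter
# set: read-level rules (base quality, mapping quality, end proximity,
# mismatch count) and site-level rules (support, coverage, fraction, variant
# quality, allele count, uncertain bases, indel size, homopolymer runs).

#' Read-level filter parameters
#' @param min_base_quality minimum base quality at the indel site (Q20).
#' @param min_mapq minimum read mapping quality (20).
#' @param max_end_proximity indel-containing reads are discarded when the
#'   indel lies within this many bases of either read end (2).
#' @param max_mismatches indel-containing reads are discarded when carrying
#'   more than this many mismatches (3).
#' @export
read_filters <- function(min_base_quality = 20, min_mapq = 20,
                         max_end_proximity = 2, max_mismatches = 3) {
  list(min_base_quality = min_base_quality, min_mapq = min_mapq,
       max_end_proximity = max_end_proximity,
       max_mismatches = max_mismatches)
}

#' Site-level filter thresholds
#'
#' Defaults follow the published criteria: at least 2 indel-containing
#' non-duplicated reads, at least 5 covering reads, at least 5% supporting
#' fraction, variant QUAL at least 0.01, exactly one non-reference allele,
#' no uncertain bases, indel size exactly 1, homopolymer run at most 5.
#'
#' The variant-quality rule is stated in the source criteria as a Phred
#' score below 0.01, which is effectively permissive (Phred values are
#' non-negative); `variant_quality_units = "probability"` instead reads the
#' threshold as a maximum error probability (0.01 becomes Phred 20).
#'
#' @param min_support,min_coverage,min_fraction,variant_quality,
#'   max_alleles,max_indel_size,max_homopolymer thresholds.
#' @param variant_quality_units `"phred"` or `"probability"`.
#' @export
call_thresholds <- function(min_support = 2, min_coverage = 5,
                            min_fraction = 0.05, variant_quality = 0.01,
                            variant_quality_units = c("phred", "probability"),
                            max_alleles = 1, max_indel_size = 1,
                            max_homopolymer = 5) {
  list(min_support = min_support, min_coverage = min_coverage,
       min_fraction = min_fraction, variant_quality = variant_quality,
       variant_quality_units = match.arg(variant_quality_units),
       max_alleles = max_alleles, max_indel_size = max_indel_size,
       max_homopolymer = max_homopolymer)
}

# split alignments into mapped records and check coordinate sorting
mapped_alignments <- function(alignments, require_sorted = TRUE) {
  m <- alignments[bitwAnd(alignments$flag, 4L) == 0L, , drop = FALSE]
  if (require_sorted && nrow(m) > 1) {
    o <- order(m$rname, m$pos)
    if (any(o != seq_len(nrow(m))))
      stop("alignments must be coordinate-sorted (contig, pos)")
  }
  m
}

#' Sort alignment records by coordinate
#' @param alignments alignment data.frame.
#' @export
sort_alignments <- function(alignments) {
  mapped <- bitwAnd(alignments$flag, 4L) == 0L
  rbind(alignments[mapped, , drop = FALSE][
    order(alignments$rname[mapped], alignments$pos[mapped]), , drop = FALSE],
    alignments[!mapped, , drop = FALSE])
}

# long entry table for the given sites: one row per (site, covering read);
# indel-supporting reads are represented by their (left-aligned) event
assemble_entries <- function(alignments, genome, at = NULL) {
  m <- mapped_alignments(alignments)
  if (nrow(m) == 0) {
    return(list(entries = empty_entries(), sites = at))
  }
  strand <- ifelse(bitwAnd(m$flag, 16L) > 0L, "-", "+")
  dupkey <- paste(m$rname, m$pos, strand, m$cigar)
  dup <- duplicated(dupkey)
  ev <- indel_events_cpp(m$rname, m$pos - 1L, m$cigar, m$seq, m$qual,
                         names(genome), unname(genome))
  if (is.null(at)) {
    at <- unique(data.frame(contig = ev$contig, pos = ev$anchor,
                            stringsAsFactors = FALSE))
    at <- at[order(at$contig, at$pos), , drop = FALSE]
  }
  if (nrow(at) == 0) return(list(entries = empty_entries(), sites = at))
  en <- pileup_entries_cpp(m$rname, m$pos - 1L, m$cigar, m$seq, m$qual,
                           at$contig, at$pos)
  en <- as.data.frame(en, stringsAsFactors = FALSE)
  # attach read-level fields
  en$read_id <- m$qname[en$row]
  en$mapq <- m$mapq[en$row]
  en$n_mismatches <- m$nm[en$row]
  en$duplicate_flag <- dup[en$row]
  en$contig <- at$contig[en$site]
  en$pos <- at$pos[en$site]
  # overlay indel events anchored at these sites
  en$is_indel <- FALSE
  en$kind <- NA_character_
  en$allele <- NA_character_
  en$event <- en$base
  en$event[en$op == "D"] <- "*"
  en$base_quality <- en$base_qual
  en$distance_to_read_end <- NA_integer_
  if (nrow(ev) > 0) {
    ekey <- paste(ev$row, ev$contig, ev$anchor)
    nkey <- paste(en$row, en$contig, en$pos)
    hit <- match(nkey, ekey)
    has <- !is.na(hit)
    en$is_indel[has] <- TRUE
    en$kind[has] <- ev$kind[hit[has]]
    en$allele[has] <- ev$alt[hit[has]]
    en$event[has] <- ifelse(ev$kind[hit[has]] == "insertion",
                            paste0("+", ev$alt[hit[has]]),
                            paste0("-", ev$alt[hit[has]]))
    en$base_quality[has] <- ev$event_qual[hit[has]]
    en$distance_to_read_end[has] <-
      pmin(ev$left_bases[hit[has]], ev$right_bases[hit[has]])
  }
  list(entries = en[, c("site", "contig", "pos", "row", "read_id", "event",
                        "base_quality", "mapq", "n_mismatches",
                        "distance_to_read_end", "duplicate_flag", "is_indel",
                        "kind", "allele")],
       sites = at)
}

empty_entries <- function() {
  data.frame(site = integer(), contig = character(), pos = integer(),
             row = integer(), read_id = character(), event = character(),
             base_quality = integer(), mapq = integer(),
             n_mismatches = integer(), distance_to_read_end = integer(),
             duplicate_flag = logical(), is_indel = logical(),
             kind = character(), allele = character(),
             stringsAsFactors = FALSE)
}

#' Build a pileup over alignment records
#'
#' Columns are materialized at the requested positions, or by default at
#' every (left-aligned) indel anchor observed in the alignments.  Insertion
#' events attach to the column of their anchor base (the base before the
#' event); deletions likewise, with the deleted span as the event sequence.
#' Reads identical in (contig, start, strand, CIGAR) are flagged duplicates
#' after the first.
#'
#' @param alignments coordinate-sorted alignment data.frame.
#' @param genome named character vector of contigs.
#' @param at optional data.frame (contig, pos 0-based) of columns to build.
#' @return a `Pileup`: list of columns, each with contig, pos, ref_base and
#'   an entries data.frame.
#' @export
build_pileup <- function(alignments, genome, at = NULL) {
  ae <- assemble_entries(alignments, genome, at)
  cols <- lapply(seq_len(nrow(ae$sites)), function(i) {
    list(contig = ae$sites$contig[i], pos = ae$sites$pos[i],
         ref_base = substr0(genome[[ae$sites$contig[i]]], ae$sites$pos[i],
                            ae$sites$pos[i] + 1L),
         entries = ae$entries[ae$entries$site == i, , drop = FALSE])
  })
  structure(list(columns = cols, genome_contigs = names(genome)),
            class = "Pileup")
}

#' @export
print.Pileup <- function(x, ...) {
  cat("Pileup:", length(x$columns), "column(s)\n")
  invisible(x)
}

# entry-level filtering shared by the column path and the fast path
filter_entry_table <- function(entries, params = read_filters()) {
  keep <- entries$base_quality >= params$min_base_quality &
    entries$mapq >= params$min_mapq
  ind <- entries$is_indel
  keep[ind] <- keep[ind] &
    entries$distance_to_read_end[ind] > params$max_end_proximity &
    (is.na(entries$n_mismatches[ind]) |
       entries$n_mismatches[ind] <= params$max_mismatches)
  entries[keep, , drop = FALSE]
}

#' Apply read-level filters to a pileup column
#'
#' Removes entries with base quality below Q20 at the site or mapping
#' quality below 20, and indel-containing entries whose event lies within
#' 2 bp of a read end or whose read carries more than 3 mismatches.
#'
#' @param column one column of a [build_pileup()] result.
#' @param params see [read_filters()].
#' @export
apply_read_level_filters <- function(column, params = read_filters()) {
  column$entries <- filter_entry_table(column$entries, params)
  column
}

# candidate statistics from a (filtered) entry table
candidates_from_entries <- function(entries, genome) {
  if (nrow(entries) == 0) return(empty_candidates())
  keys <- unique(entries[entries$is_indel, c("contig", "pos"), drop = FALSE])
  if (nrow(keys) == 0) return(empty_candidates())
  keys <- keys[order(keys$contig, keys$pos), , drop = FALSE]
  out <- lapply(seq_len(nrow(keys)), function(i) {
    e <- entries[entries$contig == keys$contig[i] &
                   entries$pos == keys$pos[i], , drop = FALSE]
    sup <- e[e$is_indel, , drop = FALSE]
    supn <- sup[!sup$duplicate_flag, , drop = FALSE]
    alleles <- unique(paste0(substr(sup$kind, 1, 1), ":", sup$allele))
    tab <- sort(table(paste0(substr(supn$kind, 1, 1), ":", supn$allele)),
                decreasing = TRUE)
    if (length(tab) == 0)
      tab <- sort(table(paste0(substr(sup$kind, 1, 1), ":", sup$allele)),
                  decreasing = TRUE)
    top <- names(tab)[1]
    kind <- if (substr(top, 1, 1) == "i") "insertion" else "deletion"
    seqv <- sub("^[id]:", "", top)
    vq <- min(255, sum(supn$base_quality))
    data.frame(
      contig = keys$contig[i], pos = keys$pos[i], kind = kind, seq = seqv,
      n_support = nrow(supn), n_total = nrow(e),
      support_fraction = nrow(supn) / nrow(e),
      variant_qual = vq,
      allele_count = length(alleles),
      has_n = any(grepl("N", sup$allele, fixed = TRUE)),
      indel_size = nchar(seqv),
      homopolymer_run = homopolymer_run(
        genome, keys$contig[i], keys$pos[i],
        if (kind == "insertion") seqv else NULL),
      support_reads = paste(sup$read_id, collapse = ";"),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

empty_candidates <- function() {
  data.frame(contig = character(), pos = integer(), kind = character(),
             seq = character(), n_support = integer(), n_total = integer(),
             support_fraction = numeric(), variant_qual = numeric(),
             allele_count = integer(), has_n = logical(),
             indel_size = integer(), homopolymer_run = integer(),
             support_reads = character(), stringsAsFactors = FALSE)
}

#' Call indel candidates from a pileup
#'
#' Emits one candidate per column carrying at least one indel event,
#' regardless of supporting fraction (fraction is a later, site-level rule,
#' because editing may occur well below 50%).  The variant quality is the
#' Phred-scaled probability that all supporting events are errors: the sum
#' of supporting event qualities, capped at 255.
#'
#' @param pileup a `Pileup` (apply [apply_read_level_filters()] first).
#' @param genome named character vector of contigs.
#' @return candidate data.frame.
#' @export
call_indels <- function(pileup, genome) {
  entries <- do.call(rbind, lapply(pileup$columns, `[[`, "entries"))
  if (is.null(entries)) return(empty_candidates())
  candidates_from_entries(entries, genome)
}

#' Call and filter indel candidates directly from alignments
#'
#' Fast path equivalent to building pileup columns at every indel anchor,
#' applying [apply_read_level_filters()], [call_indels()] and
#' [apply_site_filters()].
#'
#' @param alignments coordinate-sorted alignment data.frame.
#' @param genome named character vector of contigs.
#' @param rparams read-level filters ([read_filters()]).
#' @param thresholds site-level thresholds ([call_thresholds()]).
#' @return list: `candidates` (all called) and `decisions` (one
#'   `FilterDecision` row per candidate).
#' @export
call_candidates <- function(alignments, genome, rparams = read_filters(),
                            thresholds = call_thresholds()) {
  ae <- assemble_entries(alignments, genome)
  entries <- filter_entry_table(ae$entries, rparams)
  cands <- candidates_from_entries(entries, genome)
  list(candidates = cands,
       decisions = apply_site_filters(cands, thresholds))
}

#' Apply site-level filters to candidates
#'
#' Every rule is evaluated (no short-circuiting) so `failed_rules` is a
#' complete audit of why a candidate fails.
#'
#' @param candidates candidate data.frame from [call_indels()].
#' @param thresholds see [call_thresholds()].
#' @return the candidates with `passed` and `failed_rules` columns.
#' @export
apply_site_filters <- function(candidates, thresholds = call_thresholds()) {
  if (nrow(candidates) == 0) {
    candidates$passed <- logical(0)
    candidates$failed_rules <- character(0)
    return(candidates)
  }
  vq_min <- if (thresholds$variant_quality_units == "phred")
    thresholds$variant_quality
  else -10 * log10(thresholds$variant_quality)
  rules <- list(
    min_support = candidates$n_support < thresholds$min_support,
    min_coverage = candidates$n_total < thresholds$min_coverage,
    min_fraction = candidates$support_fraction < thresholds$min_fraction,
    variant_quality = candidates$variant_qual < vq_min,
    multiallelic = candidates$allele_count > thresholds$max_alleles,
    uncertain_base = candidates$has_n,
    indel_size = candidates$indel_size > thresholds$max_indel_size,
    homopolymer = candidates$homopolymer_run > thresholds$max_homopolymer)
  failmat <- do.call(cbind, rules)
  candidates$passed <- rowSums(failmat) == 0
  candidates$failed_rules <- apply(failmat, 1, function(f)
    paste(names(rules)[f], collapse = ","))
  candidates
}

#' Length of the homopolymer run at an indel site
#'
#' For a deletion (no `inserted_seq`), the maximal run of identical
#' reference bases containing the deleted base (the base after the anchor).
#' For an insertion, the run of the inserted base including flanking
#' identical reference bases.
#'
#' @param genome named character vector of contigs.
#' @param contig contig name.
#' @param pos 0-based anchor position (base before the event).
#' @param inserted_seq inserted sequence, or NULL for deletions.
#' @return integer run length.
#' @export
homopolymer_run <- function(genome, contig, pos, inserted_seq = NULL) {
  s <- genome[[contig]]
  if (is.null(inserted_seq)) {
    rn <- run_at(s, pos + 1L)
    return(as.integer(rn["end"] - rn["start"]))
  }
  b <- substr(inserted_seq, 1, 1)
  if (nchar(inserted_seq) > 1 &&
      !all(strsplit(inserted_seq, "")[[1]] == b)) return(1L)
  run <- nchar(inserted_seq)
  p <- pos
  while (p >= 0 && substr0(s, p, p + 1L) == b) { run <- run + 1L; p <- p - 1L }
  p <- pos + 1L
  n <- nchar(s)
  while (p < n && substr0(s, p, p + 1L) == b) { run <- run + 1L; p <- p + 1L }
  as.integer(run)
}

#' Write candidates to VCF
#'
#' @param candidates candidate data.frame (optionally with filter columns).
#' @param genome the genome the candidates were called against.
#' @param path output file.
#' @export
write_candidates_vcf <- function(candidates, genome, path) {
  if (nrow(candidates) == 0) {
    return(write_vcf(empty_vcf_df(), path,
                     contig_lengths = nchar(genome)))
  }
  anchor <- vapply(seq_len(nrow(candidates)), function(i)
    substr0(genome[[candidates$contig[i]]], candidates$pos[i],
            candidates$pos[i] + 1L), character(1))
  ref <- ifelse(candidates$kind == "insertion", anchor,
                paste0(anchor, candidates$seq))
  alt <- ifelse(candidates$kind == "insertion",
                paste0(anchor, candidates$seq), anchor)
  info <- sprintf("NS=%d;NT=%d;AF=%.4f;HP=%d", candidates$n_support,
                  candidates$n_total, candidates$support_fraction,
                  candidates$homopolymer_run)
  write_vcf(data.frame(contig = candidates$contig, pos = candidates$pos,
                       id = ".", ref = ref, alt = alt,
                       qual = candidates$variant_qual, info = info,
                       stringsAsFactors = FALSE),
            path, contig_lengths = nchar(genome))
}

empty_vcf_df <- function() {
  data.frame(contig = character(), pos = integer(), id = character(),
             ref = character(), alt = character(), qual = numeric(),
             info = character(), stringsAsFactors = FALSE)
}
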