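# Synthetic diploid genome: reference forging, haplotype derivation with
# truth variants and liftover tables, and paralog planting.

#' Forge a random reference genome
#'
#' @param n_contigs number of contigs.
#' @param contig_length length of each contig (>= 1000).
#' @param gc_fraction target GC content in (0, 1).
#' @param seed integer seed; the result is a pure function of the arguments.
#' @return a `GenomeSet` with only the reference slot populated.
#' @export
build_reference <- function(n_contigs = 1, contig_length = 100000,
                            gc_fraction = 0.41, seed = 1) {
  if (n_contigs < 1 || contig_length < 1000)
    stop("n_contigs must be >= 1 and contig_length >= 1000")
  if (gc_fraction <= 0 || gc_fraction >= 1)
    stop("gc_fraction must be strictly between 0 and 1")
  set.seed(seed)
  ref <- setNames(
    vapply(seq_len(n_contigs), function(i) random_dna(contig_length, gc_fraction),
           character(1)),
    sprintf("contig%02d", seq_len(n_contigs)))
  new_genomeset(reference = ref)
}

new_genomeset <- function(reference, maternal = NULL, paternal = NULL,
                          liftover = NULL, variants = NULL, paralogs = NULL) {
  if (is.null(variants)) variants <- empty_variants()
  structure(list(reference = reference, maternal = maternal,
                 paternal = paternal, liftover = liftover,
                 variants = variants, paralogs = paralogs),
            class = "GenomeSet")
}

empty_variants <- function() {
  data.frame(contig = character(), ref_pos = integer(), kind = character(),
             ref_allele = character(), alt_allele = character(),
             haplotype = character(), in_database = logical(),
             stringsAsFactors = FALSE)
}

#' @export
print.GenomeSet <- function(x, ...) {
  cat("GenomeSet:", length(x$reference), "contig(s),",
      sum(nchar(x$reference)), "bp reference\n")
  if (!is.null(x$maternal))
    cat("  diploid: ", nrow(x$variants), "truth variants\n")
  if (!is.null(x$paralogs) && nrow(x$paralogs) > 0)
    cat("  paralog pairs:", nrow(x$paralogs), "\n")
  invisible(x)
}

# left-align a single indel against the reference string; returns the
# normalized anchor (0-based base before the event) and event sequence
left_align_indel <- function(refseq, kind, anchor, eseq) {
  if (kind == "insertion") {
    p <- anchor + 1L  # insertion point
    L <- nchar(eseq)
    while (p > 0 && substr0(refseq, p - 1L, p) == substr(eseq, L, L)) {
      eseq <- paste0(substr0(refseq, p - 1L, p), substr(eseq, 1L, L - 1L))
      p <- p - 1L
    }
    list(anchor = p - 1L, seq = eseq)
  } else {
    d <- anchor + 1L  # first deleted base
    L <- nchar(eseq)
    while (d > 0 && substr0(refseq, d - 1L, d) ==
           substr0(refseq, d + L - 1L, d + L)) {
      d <- d - 1L
    }
    list(anchor = d - 1L, seq = substr0(refseq, d, d + L))
  }
}

# apply SNPs + single-base indels (one contig) to a reference string;
# returns the haplotype sequence and the liftover block table
apply_variants_to_contig <- function(refseq, vars) {
  seq2 <- refseq
  snps <- vars[vars$kind == "snp", , drop = FALSE]
  for (i in seq_len(nrow(snps))) {
    substr0(seq2, snps$ref_pos[i]) <- snps$alt_allele[i]
  }
  indels <- vars[vars$kind != "snp", , drop = FALSE]
  indels <- indels[order(indels$ref_pos), , drop = FALSE]
  n <- nchar(refseq)
  parts <- character(0)
  hs <- integer(0); he <- integer(0); rs <- integer(0); re <- integer(0)
  r <- 0L; h <- 0L
  for (i in seq_len(nrow(indels))) {
    a <- indels$ref_pos[i]
    piece <- substr0(seq2, r, a + 1L)
    L <- nchar(piece)
    parts <- c(parts, piece)
    hs <- c(hs, h); he <- c(he, h + L); rs <- c(rs, r); re <- c(re, a + 1L)
    h <- h + L
    if (indels$kind[i] == "insertion") {
      ins <- substr(indels$alt_allele[i], 2L, nchar(indels$alt_allele[i]))
      parts <- c(parts, ins)
      hs <- c(hs, h); he <- c(he, h + nchar(ins))
      rs <- c(rs, a + 1L); re <- c(re, a + 1L)
      h <- h + nchar(ins)
      r <- a + 1L
    } else {
      ndel <- nchar(indels$ref_allele[i]) - 1L
      r <- a + 1L + ndel
    }
  }
  piece <- substr0(seq2, r, n)
  parts <- c(parts, piece)
  hs <- c(hs, h); he <- c(he, h + nchar(piece)); rs <- c(rs, r); re <- c(re, n)
  list(seq = paste(parts, collapse = ""),
       blocks = data.frame(hap_start = hs, hap_end = he,
                           ref_start = rs, ref_end = re))
}

#' Derive maternal and paternal haplotypes from a reference
#'
#' Each haplotype receives an independent draw of SNPs and single-base indels.
#' A fraction of the indels is flagged `in_database` (present in the known
#' genomic variant database).  `n_misassembly` additional indels model
#' assembly errors: real homozygous indels (haplotype `"both"`, always
#' `in_database`) that are carried by the transcribed molecules but missing
#' from both assembled haplotype sequences — the mechanism behind
#' database-annotated false positives.
#'
#' @param gs a `GenomeSet` (or named character vector of contigs).
#' @param snp_rate,indel_rate per-base rates (each <= 0.01); ignored when the
#'   corresponding count argument is given.
#' @param database_fraction fraction of haplotype indels flagged as known.
#' @param seed integer seed.
#' @param n_snps,n_indels optional fixed counts instead of rates; indels are
#'   then assigned to maternal/paternal at random.
#' @param n_misassembly number of misassembly ("both"-haplotype) indels.
#' @param target_intervals optional data.frame (contig, start, end; 0-based
#'   half-open) restricting count-based placement, e.g. to exons.
#' @param min_gap minimum distance between planted variants.
#' @return a `GenomeSet` with maternal/paternal sequences, liftover tables,
#'   and the truth variant table.
#' @export
derive_diploid <- function(gs, snp_rate = 0, indel_rate = 0,
                           database_fraction = 0, seed = 1,
                           n_snps = NULL, n_indels = NULL,
                           n_misassembly = 0, target_intervals = NULL,
                           min_gap = 8L) {
  ref <- if (inherits(gs, "GenomeSet")) gs$reference else gs
  for (rate in c(snp_rate, indel_rate)) {
    if (rate < 0 || rate > 1) stop("rates must lie in [0, 1]")
    if (rate > 0.01) stop("per-base variant rates above 0.01 are not supported")
  }
  if (database_fraction < 0 || database_fraction > 1)
    stop("database_fraction must lie in [0, 1]")
  set.seed(seed)

  draw_variants <- function(contig, hap) {
    refseq <- ref[[contig]]
    n <- nchar(refseq)
    ti <- if (!is.null(target_intervals))
      target_intervals[target_intervals$contig == contig, c("start", "end")]
    else NULL
    pos_snp <- if (!is.null(n_snps)) {
      if (n_snps > 0) sample_positions(n, count = n_snps, intervals = ti)
      else integer(0)
    } else sample_positions(n, rate = snp_rate)
    pos_ind <- if (!is.null(n_indels)) {
      if (n_indels > 0) sample_positions(n, count = n_indels, intervals = ti)
      else integer(0)
    } else sample_positions(n, rate = indel_rate)
    make_variant_rows(refseq, contig, pos_snp, pos_ind, hap)
  }

  make_variant_rows <- function(refseq, contig, pos_snp, pos_ind, hap) {
    rows <- list()
    for (p in pos_snp) {
      rb <- substr0(refseq, p, p + 1L)
      ab <- sample(setdiff(BASES, rb), 1)
      rows[[length(rows) + 1]] <- data.frame(
        contig = contig, ref_pos = p, kind = "snp", ref_allele = rb,
        alt_allele = ab, haplotype = hap, in_database = FALSE,
        stringsAsFactors = FALSE)
    }
    for (p in pos_ind) {
      kind <- sample(c("insertion", "deletion"), 1)
      if (kind == "insertion") {
        x <- sample(BASES, 1)
        la <- left_align_indel(refseq, "insertion", p - 1L, x)
        anchor <- la$anchor
        if (anchor < 1) next
        ab <- substr0(refseq, anchor, anchor + 1L)
        rows[[length(rows) + 1]] <- data.frame(
          contig = contig, ref_pos = anchor, kind = "insertion",
          ref_allele = ab, alt_allele = paste0(ab, la$seq), haplotype = hap,
          in_database = FALSE, stringsAsFactors = FALSE)
      } else {
        la <- left_align_indel(refseq, "deletion", p - 1L, substr0(refseq, p, p + 1L))
        anchor <- la$anchor
        if (anchor < 1) next
        ab <- substr0(refseq, anchor, anchor + 1L)
        rows[[length(rows) + 1]] <- data.frame(
          contig = contig, ref_pos = anchor, kind = "deletion",
          ref_allele = paste0(ab, la$seq), alt_allele = ab, haplotype = hap,
          in_database = FALSE, stringsAsFactors = FALSE)
      }
    }
    if (length(rows) == 0) return(empty_variants())
    do.call(rbind, rows)
  }

  vars <- list()
  if (!is.null(n_indels) || !is.null(n_snps)) {
    # count-based planting: one pooled draw, haplotype assigned per variant
    for (contig in names(ref)) {
      v <- draw_variants(contig, "pooled")
      if (nrow(v)) v$haplotype <- sample(c("maternal", "paternal"), nrow(v),
                                         replace = TRUE)
      vars[[length(vars) + 1]] <- v
    }
  } else {
    for (hap in c("maternal", "paternal")) {
      for (contig in names(ref)) {
        vars[[length(vars) + 1]] <- draw_variants(contig, hap)
      }
    }
  }
  vars <- do.call(rbind, c(vars, list(empty_variants())))

  # misassembly indels (haplotype "both"; carried by transcripts, absent from
  # the assembled FASTA)
  if (n_misassembly > 0) {
    for (contig in names(ref)) {
      refseq <- ref[[contig]]
      ti <- if (!is.null(target_intervals))
        target_intervals[target_intervals$contig == contig, c("start", "end")]
      else NULL
      pos <- sample_positions(nchar(refseq), count = n_misassembly,
                              intervals = ti)
      v <- make_variant_rows(refseq, contig, integer(0), pos, "both")
      if (nrow(v)) v$in_database <- TRUE
      vars <- rbind(vars, v)
    }
  }

  # resolve collisions: keep well-separated variants only
  if (nrow(vars) > 0) {
    vars <- vars[order(vars$contig, vars$ref_pos), ]
    keep <- unlist(lapply(split(seq_len(nrow(vars)), vars$contig), function(ix) {
      p <- vars$ref_pos[ix]
      ix[!duplicated(p) & c(TRUE, diff(p) >= min_gap)]
    }), use.names = FALSE)
    vars <- vars[sort(keep), , drop = FALSE]
    rownames(vars) <- NULL
    is_hap_indel <- vars$kind != "snp" & vars$haplotype != "both"
    if (any(is_hap_indel)) {
      vars$in_database[is_hap_indel] <-
        runif(sum(is_hap_indel)) < database_fraction
    }
  }

  maternal <- ref; paternal <- ref
  lift <- list(maternal = NULL, paternal = NULL)
  for (hap in c("maternal", "paternal")) {
    blocks <- list()
    for (contig in names(ref)) {
      v <- vars[vars$contig == contig & vars$haplotype == hap, , drop = FALSE]
      ap <- apply_variants_to_contig(ref[[contig]], v)
      if (hap == "maternal") maternal[[contig]] <- ap$seq
      else paternal[[contig]] <- ap$seq
      b <- ap$blocks
      b$contig <- contig
      blocks[[contig]] <- b
    }
    lift[[hap]] <- do.call(rbind, blocks)
    rownames(lift[[hap]]) <- NULL
  }

  new_genomeset(reference = ref, maternal = maternal, paternal = paternal,
                liftover = lift, variants = vars,
                paralogs = if (inherits(gs, "GenomeSet")) gs$paralogs else NULL)
}

#' Map haplotype coordinates to reference coordinates
#'
#' @param gs a diploid `GenomeSet`.
#' @param hap `"maternal"` or `"paternal"`.
#' @param contig contig name.
#' @param pos 0-based positions in haplotype coordinates.
#' @return 0-based reference positions (NA for inserted bases).
#' @export
hap_to_ref <- function(gs, hap, contig, pos) {
  b <- gs$liftover[[hap]]
  b <- b[b$contig == contig, , drop = FALSE]
  if (nrow(b) == 0) stop(sprintf("no liftover for contig '%s'", contig))
  i <- findInterval(pos, b$hap_start)
  out <- rep(NA_integer_, length(pos))
  ok <- i >= 1 & pos < b$hap_end[pmax(i, 1)] &
    (b$ref_end[pmax(i, 1)] > b$ref_start[pmax(i, 1)])
  out[ok] <- b$ref_start[i[ok]] + (pos[ok] - b$hap_start[i[ok]])
  out
}

#' Map reference coordinates to haplotype coordinates
#' @inheritParams hap_to_ref
#' @param pos 0-based reference positions.
#' @return 0-based haplotype positions (NA for deleted bases).
#' @export
ref_to_hap <- function(gs, hap, contig, pos) {
  b <- gs$liftover[[hap]]
  b <- b[b$contig == contig & b$ref_end > b$ref_start, , drop = FALSE]
  if (nrow(b) == 0) stop(sprintf("no liftover for contig '%s'", contig))
  i <- findInterval(pos, b$ref_start)
  out <- rep(NA_integer_, length(pos))
  ok <- i >= 1 & pos < b$ref_end[pmax(i, 1)]
  out[ok] <- b$hap_start[i[ok]] + (pos[ok] - b$ref_start[i[ok]])
  out
}

# haplotype sequence of a reference interval, including inserted haplotype
# bases whose insertion point falls strictly inside the interval
extract_hap_interval <- function(gs, hap, contig, ref_start, ref_end) {
  if (hap == "reference")
    return(substr0(gs$reference[[contig]], ref_start, ref_end))
  b <- gs$liftover[[hap]]
  b <- b[b$contig == contig, , drop = FALSE]
  hapseq <- gs[[hap]][[contig]]
  parts <- character(0)
  for (i in seq_len(nrow(b))) {
    if (b$ref_end[i] > b$ref_start[i]) {
      ov0 <- max(b$ref_start[i], ref_start)
      ov1 <- min(b$ref_end[i], ref_end)
      if (ov1 > ov0) {
        h0 <- b$hap_start[i] + (ov0 - b$ref_start[i])
        parts <- c(parts, substr0(hapseq, h0, h0 + (ov1 - ov0)))
      }
    } else {
      # insertion block at ref point
      p <- b$ref_start[i]
      if (p > ref_start && p < ref_end) {
        parts <- c(parts, substr0(hapseq, b$hap_start[i], b$hap_end[i]))
      }
    }
  }
  paste(parts, collapse = "")
}

#' Plant diverged paralog copies in the reference
#'
#' Models the assembly-gap mechanism behind paralog false positives: a copy
#' of a source interval — mutated with substitutions at `divergence` and, when
#' `divergence > 0`, exactly one single-base indel — overwrites a distant
#' interval of the *reference* contig, while both assembled haplotypes keep
#' their original sequence there.  Reads transcribed from the copy region
#' (off the reference) can then only map to the source locus, where they
#' exhibit the copy's indel.
#'
#' Call after [derive_diploid()]; haplotype coordinates are unaffected
#' because the overwrite preserves length.
#'
#' @param gs a diploid `GenomeSet`.
#' @param n_pairs number of paralog pairs.
#' @param length source length (>= 200).
#' @param divergence substitution rate between copy and source, between 0 and 0.05.
#' @param seed integer seed.
#' @param avoid optional data.frame (contig, start, end) of intervals the
#'   source and copy must not overlap (e.g. genes).
#' @param min_separation minimum distance between source and copy (default
#'   10 kb).
#' @return the `GenomeSet` with `$paralogs` describing each pair.
#' @export
plant_paralogs <- function(gs, n_pairs, length = 500, divergence = 0.02,
                           seed = 1, avoid = NULL, min_separation = 10000L) {
  if (n_pairs == 0) return(gs)
  if (length < 200) stop("paralog length must be >= 200")
  if (divergence < 0 || divergence > 0.05)
    stop("divergence must lie in [0, 0.05]")
  set.seed(seed)
  taken <- if (is.null(avoid)) {
    data.frame(contig = character(), start = integer(), end = integer(),
               stringsAsFactors = FALSE)
  } else avoid[, c("contig", "start", "end")]
  pairs <- list()
  pick_interval <- function(len) {
    for (attempt in 1:2000) {
      contig <- sample(names(gs$reference), 1)
      n <- nchar(gs$reference[[contig]])
      if (n < len + 200) next
      s <- sample.int(n - len - 100L, 1) + 50L
      t <- taken[taken$contig == contig, , drop = FALSE]
      if (nrow(t) == 0 || all(t$end <= s - 200L | t$start >= s + len + 200L))
        return(list(contig = contig, start = s, end = s + len))
    }
    stop("insufficient genome space to place paralog interval")
  }
  for (i in seq_len(n_pairs)) {
    src <- pick_interval(length)
    src_seq <- substr0(gs$reference[[src$contig]], src$start, src$end)
    copy_seq <- src_seq
    indel <- list(kind = NA_character_, offset = NA_integer_,
                  base = NA_character_)
    if (divergence > 0) {
      # substitutions
      nsub <- rbinom(1, length, divergence)
      if (nsub > 0) {
        at <- sample.int(length, nsub)
        for (p in at) {
          orig <- substr(copy_seq, p, p)
          substr(copy_seq, p, p) <- sample(setdiff(BASES, orig), 1)
        }
      }
      # exactly one single-base indel, mid-interval, not extending a run
      off <- sample(seq.int(50L, length - 50L), 1)
      kind <- sample(c("insertion", "deletion"), 1)
      left_b <- substr(copy_seq, off, off)
      right_b <- substr(copy_seq, off + 1, off + 1)
      if (kind == "insertion") {
        x <- sample(setdiff(BASES, c(left_b, right_b)), 1)
        copy_seq <- paste0(substr(copy_seq, 1, off), x,
                           substr(copy_seq, off + 1, nchar(copy_seq)))
        indel <- list(kind = "insertion", offset = off, base = x)
      } else {
        copy_seq <- paste0(substr(copy_seq, 1, off),
                           substr(copy_seq, off + 2, nchar(copy_seq)))
        indel <- list(kind = "deletion", offset = off, base = right_b)
      }
    }
    clen <- nchar(copy_seq)
    # find a copy location far from the source
    cp <- NULL
    for (attempt in 1:2000) {
      cand <- pick_interval(clen)
      if (cand$contig != src$contig ||
          abs(cand$start - src$start) >= min_separation) { cp <- cand; break }
    }
    if (is.null(cp)) stop("insufficient genome space for a distant paralog copy")
    # overwrite the reference only; haplotypes keep their original sequence
    substr0(gs$reference[[cp$contig]], cp$start) <- copy_seq
    taken <- rbind(taken,
                   data.frame(contig = c(src$contig, cp$contig),
                              start = c(src$start, cp$start),
                              end = c(src$end, cp$start + clen),
                              stringsAsFactors = FALSE))
    nmm <- sum(strsplit(src_seq, "")[[1]][seq_len(min(length, clen))] !=
               strsplit(copy_seq, "")[[1]][seq_len(min(length, clen))])
    pairs[[i]] <- data.frame(
      pair_id = sprintf("par%02d", i),
      src_contig = src$contig, src_start = src$start, src_end = src$end,
      copy_contig = cp$contig, copy_start = cp$start,
      copy_end = cp$start + clen,
      indel_kind = indel$kind, indel_offset = indel$offset,
      indel_base = indel$base,
      percent_identity = 100 * (1 - nmm / length),
      stringsAsFactors = FALSE)
  }
  gs$paralogs <- do.call(rbind, pairs)
  gs
}
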