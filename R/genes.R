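# Gene models with canonical GT/AG introns, transcription to a splice
# junction database, and injection of single-base RNA editing events.

#' Build multi-exon gene models and write their splice signals
#'
#' Places non-overlapping genes on the reference, writes canonical GT/AG
#' dinucleotides at every intron boundary, and (optionally) turns a fraction
#' of first introns into splice-junction "decoys": the intron prefix becomes
#' a copy of the downstream exon prefix with one extra base.  Reads spanning
#' such a junction align full-length to the genome with a one-base deletion
#' — the classic indel artifact that splice-junction filtering must catch.
#' Decoy genes are forced to the plus strand.
#'
#' @param gs a `GenomeSet` (reference is modified; derive haplotypes after).
#' @param n_genes number of genes.
#' @param exon_count_range,exon_len_range,intron_len_range inclusive ranges;
#'   introns must be at least 60 bp so a short read cannot span one.
#' @param seed integer seed.
#' @param decoy_fraction fraction of genes given a decoy first intron.
#' @param avoid optional data.frame (contig, start, end) to keep clear of.
#' @return list with the modified `GenomeSet` (`gs`) and a `GeneModels`
#'   object (`models`): genes, exons and decoys tables, 0-based half-open.
#' @export
build_gene_models <- function(gs, n_genes = 20,
                              exon_count_range = c(2, 6),
                              exon_len_range = c(120, 300),
                              intron_len_range = c(70, 140),
                              seed = 1, decoy_fraction = 0, avoid = NULL) {
  if (intron_len_range[1] < 60) stop("introns must be at least 60 bp")
  set.seed(seed)
  taken <- if (is.null(avoid)) {
    data.frame(contig = character(), start = integer(), end = integer(),
               stringsAsFactors = FALSE)
  } else avoid[, c("contig", "start", "end")]
  n_decoy <- round(decoy_fraction * n_genes)
  genes <- list(); exons <- list(); decoys <- list()
  for (g in seq_len(n_genes)) {
    gene_id <- sprintf("gene%03d", g)
    is_decoy <- g <= n_decoy
    ne <- sample_range(exon_count_range)
    if (is_decoy) ne <- max(ne, 2L)
    elens <- sample_range(exon_len_range, ne)
    ilens <- if (ne > 1) sample_range(intron_len_range, ne - 1)
             else integer(0)
    span <- sum(elens) + sum(ilens)
    placed <- FALSE
    for (attempt in 1:2000) {
      contig <- sample(names(gs$reference), 1)
      n <- nchar(gs$reference[[contig]])
      if (n < span + 300) next
      s <- sample.int(n - span - 200L, 1) + 100L
      t <- taken[taken$contig == contig, , drop = FALSE]
      if (nrow(t) == 0 || all(t$end <= s - 150L | t$start >= s + span + 150L)) {
        placed <- TRUE; break
      }
    }
    if (!placed) stop("genome too small to place all requested genes")
    strand <- if (is_decoy) "+" else sample(c("+", "-"), 1)
    starts <- s + cumsum(c(0L, head(elens, -1) + ilens))
    ends <- starts + elens
    taken <- rbind(taken, data.frame(contig = contig, start = s,
                                     end = s + span,
                                     stringsAsFactors = FALSE))
    # intron boundary signals (coding == plus strand here; minus-strand genes
    # carry the complements so the transcript sees GT..AG)
    for (i in seq_len(ne - 1)) {
      istart <- ends[i]; iend <- starts[i + 1]
      if (strand == "+") {
        substr0(gs$reference[[contig]], istart) <- "GT"
        substr0(gs$reference[[contig]], iend - 2L) <- "AG"
      } else {
        substr0(gs$reference[[contig]], istart) <- "CT"
        substr0(gs$reference[[contig]], iend - 2L) <- "AC"
      }
    }
    if (is_decoy) {
      # decoy first intron: copy of downstream exon prefix with one extra base
      istart <- ends[1]; iend <- starts[2]
      j <- 5L; plen <- 40L
      substr0(gs$reference[[contig]], starts[2]) <- "GT"  # exon2 starts GT
      p <- substr0(gs$reference[[contig]], starts[2], starts[2] + plen)
      left_b <- substr(p, j, j); right_b <- substr(p, j + 1, j + 1)
      x <- sample(setdiff(BASES, c(left_b, right_b)), 1)
      dec_prefix <- paste0(substr(p, 1, j), x, substr(p, j + 1, plen))
      filler_len <- (iend - istart) - nchar(dec_prefix) - 2L
      filler <- random_dna(filler_len, 0.5)
      substr0(gs$reference[[contig]], istart) <-
        paste0(dec_prefix, filler, "AG")
      decoys[[length(decoys) + 1]] <- data.frame(
        gene_id = gene_id, contig = contig, intron_index = 1L,
        intron_start = istart, intron_end = iend, ins_offset = j,
        base = x, expected_anchor = istart + j - 1L,
        expected_kind = "deletion", stringsAsFactors = FALSE)
    }
    genes[[g]] <- data.frame(gene_id = gene_id, contig = contig,
                             strand = strand, start = s, end = s + span,
                             n_exons = ne, source = "haplotype",
                             stringsAsFactors = FALSE)
    exons[[g]] <- data.frame(gene_id = gene_id, contig = contig,
                             strand = strand, exon_rank = seq_len(ne),
                             start = starts, end = ends,
                             stringsAsFactors = FALSE)
  }
  models <- structure(
    list(genes = do.call(rbind, genes), exons = do.call(rbind, exons),
         decoys = if (length(decoys)) do.call(rbind, decoys)
                  else data.frame()),
    class = "GeneModels")
  list(gs = gs, models = models)
}

#' @export
print.GeneModels <- function(x, ...) {
  cat("GeneModels:", nrow(x$genes), "genes,", nrow(x$exons), "exons,",
      nrow(x$decoys), "decoy junctions\n")
  invisible(x)
}

#' Add single-exon genes over planted paralog copies
#'
#' The copy exists only in the reference (assembly-gap model), so these genes
#' carry `source = "reference"` and are transcribed off the reference.
#'
#' @param models a `GeneModels` object.
#' @param gs the `GenomeSet` holding `$paralogs`.
#' @export
add_paralog_genes <- function(models, gs) {
  pp <- gs$paralogs
  if (is.null(pp) || nrow(pp) == 0) return(models)
  for (i in seq_len(nrow(pp))) {
    gid <- paste0("pargene_", pp$pair_id[i])
    models$genes <- rbind(models$genes, data.frame(
      gene_id = gid, contig = pp$copy_contig[i], strand = "+",
      start = pp$copy_start[i], end = pp$copy_end[i], n_exons = 1L,
      source = "reference", stringsAsFactors = FALSE))
    models$exons <- rbind(models$exons, data.frame(
      gene_id = gid, contig = pp$copy_contig[i], strand = "+",
      exon_rank = 1L, start = pp$copy_start[i], end = pp$copy_end[i],
      stringsAsFactors = FALSE))
  }
  models
}

#' Transcribe gene models against a haplotype
#'
#' Concatenates exon sequences (reverse-complemented for minus-strand genes)
#' after lifting reference exon coordinates onto the chosen haplotype, so
#' haplotype variants are carried into the transcripts.
#'
#' @param gs a diploid `GenomeSet`.
#' @param models a `GeneModels` object (or subset).
#' @param haplotype `"maternal"`, `"paternal"`, or `"reference"`.
#' @return a `JunctionDB`: transcripts plus a per-exon transcript/genome map.
#' @export
transcribe <- function(gs, models, haplotype = "maternal") {
  stopifnot(haplotype %in% c("maternal", "paternal", "reference"))
  tx <- character(0)
  maps <- list()
  for (gid in models$genes$gene_id) {
    ex <- models$exons[models$exons$gene_id == gid, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    contig <- ex$contig[1]; strand <- ex$strand[1]
    clen <- nchar(gs$reference[[contig]])
    if (any(ex$start < 0 | ex$end > clen))
      stop(sprintf("exon of gene '%s' outside contig '%s'", gid, contig))
    pieces <- vapply(seq_len(nrow(ex)), function(i)
      extract_hap_interval(gs, haplotype, contig, ex$start[i], ex$end[i]),
      character(1))
    lens <- nchar(pieces)
    concat <- paste(pieces, collapse = "")
    L <- nchar(concat)
    txs <- if (strand == "+") concat else revcomp(concat)
    tx_id <- paste0(gid, "|", haplotype)
    tx[tx_id] <- txs
    cum <- cumsum(c(0L, lens))
    if (strand == "+") {
      t0 <- cum[-length(cum)]; t1 <- cum[-1]
    } else {
      t0 <- L - cum[-1]; t1 <- L - cum[-length(cum)]
    }
    maps[[tx_id]] <- data.frame(
      tx_id = tx_id, gene_id = gid, haplotype = haplotype, contig = contig,
      strand = strand, exon_rank = ex$exon_rank,
      ref_start = ex$start, ref_end = ex$end,
      tx_start = t0, tx_end = t1, stringsAsFactors = FALSE)
  }
  structure(list(transcripts = tx,
                 exon_map = if (length(maps)) do.call(rbind, maps)
                            else data.frame(),
                 editing = empty_editing()),
            class = "JunctionDB")
}

empty_editing <- function() {
  data.frame(site_id = character(), gene_id = character(),
             tx_id = character(), tx_pos = integer(), kind = character(),
             base = character(), editing_fraction = numeric(),
             ref_contig = character(), ref_anchor = integer(),
             genome_base = character(), stringsAsFactors = FALSE)
}

#' @export
print.JunctionDB <- function(x, ...) {
  cat("JunctionDB:", length(x$transcripts), "transcripts,",
      nrow(x$editing), "editing sites\n")
  invisible(x)
}

#' Merge junction databases
#' @param ... `JunctionDB` objects.
#' @export
combine_junctiondb <- function(...) {
  dbs <- list(...)
  structure(list(
    transcripts = do.call(c, lapply(dbs, `[[`, "transcripts")),
    exon_map = do.call(rbind, lapply(dbs, `[[`, "exon_map")),
    editing = do.call(rbind, lapply(dbs, `[[`, "editing"))),
    class = "JunctionDB")
}

# transcript coordinate of a reference position on one transcript (NA if the
# position falls in an intron or outside the gene); approximate within +-1
# around haplotype indels
ref_to_tx <- function(db, tx_id, refpos) {
  em <- db$exon_map[db$exon_map$tx_id == tx_id, , drop = FALSE]
  hit <- which(refpos >= em$ref_start & refpos < em$ref_end)
  if (length(hit) == 0) return(NA_integer_)
  e <- em[hit[1], ]
  p <- if (e$strand == "+") e$tx_start + (refpos - e$ref_start)
       else e$tx_start + (e$ref_end - 1L - refpos)
  min(max(p, e$tx_start), e$tx_end - 1L)
}

# reference coordinate of a transcript position (approximate near indels)
tx_to_ref <- function(db, tx_id, txpos) {
  em <- db$exon_map[db$exon_map$tx_id == tx_id, , drop = FALSE]
  hit <- which(txpos >= em$tx_start & txpos < em$tx_end)
  if (length(hit) == 0) return(NA_integer_)
  e <- em[hit[1], ]
  if (e$strand == "+") min(e$ref_start + (txpos - e$tx_start), e$ref_end - 1L)
  else max(e$ref_end - 1L - (txpos - e$tx_start), e$ref_start)
}

# internal exon-exon boundaries in transcript coordinates
junction_offsets <- function(db, tx_id) {
  em <- db$exon_map[db$exon_map$tx_id == tx_id, , drop = FALSE]
  L <- max(em$tx_end)
  sort(setdiff(unique(c(em$tx_start, em$tx_end)), c(0L, L)))
}

# exact transcript coordinate of a reference position: the coordinate route
# (ref_to_tx) drifts by one around upstream haplotype indels in the same
# exon, so the position is located by matching the local haplotype context
# inside the transcript, falling back to the coordinate estimate
exact_tx_pos <- function(gs, db, tx_id, contig, refpos, width = 10L) {
  em <- db$exon_map[db$exon_map$tx_id == tx_id, , drop = FALSE]
  hap <- em$haplotype[1]; strand <- em$strand[1]
  approx <- ref_to_tx(db, tx_id, refpos)
  if (hap == "reference") return(approx)
  hpos <- ref_to_hap(gs, hap, contig, refpos)
  if (is.na(hpos)) return(approx)
  hseq <- gs[[hap]][[contig]]
  w0 <- max(0L, hpos - width); w1 <- min(nchar(hseq), hpos + width + 1L)
  ctx <- substr0(hseq, w0, w1)
  txs <- db$transcripts[[tx_id]]
  if (strand == "-") {
    m <- gregexpr(revcomp(ctx), txs, fixed = TRUE)[[1]]
    off_in_ctx <- (w1 - 1L) - hpos
  } else {
    m <- gregexpr(ctx, txs, fixed = TRUE)[[1]]
    off_in_ctx <- hpos - w0
  }
  if (m[1] == -1) return(approx)
  hits <- as.integer(m) - 1L + off_in_ctx
  if (length(hits) > 1 && !is.na(approx))
    hits <- hits[which.min(abs(hits - approx))]
  hits[1]
}

# splice misassembly ("both"-haplotype) indels into the transcripts of a
# simulation database: the transcribed molecules carry them even though the
# assembled haplotypes do not
apply_misassembly_to_db <- function(db, gs, variants) {
  v <- variants[variants$haplotype == "both" & variants$kind != "snp", ,
                drop = FALSE]
  if (nrow(v) == 0) return(db)
  edits <- list()
  for (i in seq_len(nrow(v))) {
    a <- v$ref_pos[i]
    for (tx_id in names(db$transcripts)) {
      em <- db$exon_map[db$exon_map$tx_id == tx_id, , drop = FALSE]
      if (em$contig[1] != v$contig[i]) next
      if (!any(a >= em$ref_start + 2 & a < em$ref_end - 2)) next
      strand <- em$strand[1]
      if (v$kind[i] == "insertion") {
        x <- substr(v$alt_allele[i], 2, 2)
        at <- if (strand == "+") exact_tx_pos(gs, db, tx_id, v$contig[i], a)
              else exact_tx_pos(gs, db, tx_id, v$contig[i], a + 1L)
        if (is.na(at)) next
        ins <- if (strand == "+") x else revcomp(x)
        edits[[length(edits) + 1]] <- list(tx = tx_id, pos = at,
                                           kind = "insertion", base = ins)
      } else {
        d <- a + 1L
        at <- exact_tx_pos(gs, db, tx_id, v$contig[i], d)
        if (is.na(at)) next
        edits[[length(edits) + 1]] <- list(tx = tx_id, pos = at,
                                           kind = "deletion", base = NA)
      }
    }
  }
  # apply per transcript in descending position so coordinates stay valid
  if (length(edits)) {
    byt <- split(edits, vapply(edits, `[[`, "", "tx"))
    for (tx_id in names(byt)) {
      es <- byt[[tx_id]]
      ord <- order(-vapply(es, function(e) e$pos, 0))
      s <- db$transcripts[[tx_id]]
      for (e in es[ord]) {
        if (e$kind == "insertion") {
          s <- paste0(substr(s, 1, e$pos + 1), e$base,
                      substr(s, e$pos + 2, nchar(s)))
        } else {
          s <- paste0(substr(s, 1, e$pos), substr(s, e$pos + 2, nchar(s)))
        }
      }
      db$transcripts[[tx_id]] <- s
    }
  }
  db
}

#' Plant single-base RNA editing events in transcripts
#'
#' Sites are chosen at least `margin` bp from transcript ends and annotated
#' junctions, outside homopolymer runs that would trip the homopolymer
#' filter, and are propagated to every haplotype transcript of the chosen
#' gene.  A fraction `editing_fraction` of simulated molecules carries each
#' event.
#'
#' @param db simulation `JunctionDB`.
#' @param n_sites number of editing sites.
#' @param editing_fraction fraction of molecules edited, in (0, 1].
#' @param seed integer seed.
#' @param base inserted base (insertions); NULL draws one per site.
#' @param margin minimum distance from transcript ends and junctions.
#' @param max_homopolymer maximum allowed identical-base run at the site.
#' @param min_site_gap minimum spacing between sites on one gene.
#' @return the `JunctionDB` with `$editing` filled in.
#' @export
inject_editing <- function(db, n_sites, editing_fraction = 0.5, seed = 1,
                           base = NULL, margin = 40L, max_homopolymer = 5L,
                           min_site_gap = 60L) {
  if (n_sites == 0) return(db)
  if (editing_fraction <= 0 || editing_fraction > 1)
    stop("editing_fraction must lie in (0, 1]")
  set.seed(seed)
  em <- db$exon_map
  genes <- unique(em$gene_id[em$haplotype == "maternal"])
  if (length(genes) == 0) stop("no haplotype transcripts to edit")
  placed <- 0L
  rows <- list()
  used <- list()  # per gene: tx positions already used
  tries <- 0L
  while (placed < n_sites) {
    tries <- tries + 1L
    if (tries > 200L * n_sites)
      stop("n_sites exceeds the number of eligible editing positions")
    gid <- sample(genes, 1)
    mat_tx <- paste0(gid, "|maternal")
    s <- db$transcripts[[mat_tx]]
    L <- nchar(s)
    if (L < 2 * margin + 10) next
    p <- sample.int(L - 2L * margin, 1) + margin - 1L  # 0-based tx position
    jx <- junction_offsets(db, mat_tx)
    if (length(jx) && min(abs(jx - p)) < margin) next
    if (length(used[[gid]]) && min(abs(used[[gid]] - p)) < min_site_gap) next
    kind <- sample(c("insertion", "deletion"), 1)
    if (kind == "insertion") {
      x <- if (is.null(base)) sample(BASES, 1) else base
      rn <- run_at(paste0(substr(s, 1, p + 1), x, substr(s, p + 2, L)), p + 1L)
      if ((rn["end"] - rn["start"]) > max_homopolymer) next
    } else {
      x <- substr(s, p + 2, p + 2)  # deleted base (tx 0-based p+1)
      rn <- run_at(s, p + 1L)
      if ((rn["end"] - rn["start"]) > max_homopolymer) next
    }
    ref_anchor <- tx_to_ref(db, mat_tx, p)
    strand <- em$strand[em$tx_id == mat_tx][1]
    contig <- em$contig[em$tx_id == mat_tx][1]
    if (is.na(ref_anchor)) next
    placed <- placed + 1L
    site_id <- sprintf("edit%03d", placed)
    used[[gid]] <- c(used[[gid]], p)
    # genome-forward representation for truth bookkeeping
    if (kind == "insertion") {
      ganchor <- if (strand == "+") ref_anchor else ref_anchor - 1L
      gbase <- if (strand == "+") x else revcomp(x)
    } else {
      gpos <- tx_to_ref(db, mat_tx, p + 1L)  # deleted base, genome coords
      ganchor <- gpos - 1L
      gbase <- if (strand == "+") x else revcomp(x)
    }
    for (tx_id in names(db$transcripts)) {
      if (!startsWith(tx_id, paste0(gid, "|"))) next
      tp <- if (tx_id == mat_tx) p else {
        # locate the homologous position by context (haplotype transcripts
        # of one gene share orientation); coordinates alone drift around
        # upstream haplotype indels
        ctx <- substr(s, p - 9L, p + 11L)
        m <- gregexpr(ctx, db$transcripts[[tx_id]], fixed = TRUE)[[1]]
        fallback <- ref_to_tx(db, tx_id, ref_anchor)
        if (m[1] == -1) fallback else {
          hits <- as.integer(m) - 1L + 10L
          if (length(hits) > 1 && !is.na(fallback))
            hits <- hits[which.min(abs(hits - fallback))]
          hits[1]
        }
      }
      if (is.na(tp)) next
      rows[[length(rows) + 1]] <- data.frame(
        site_id = site_id, gene_id = gid, tx_id = tx_id, tx_pos = tp,
        kind = kind, base = x, editing_fraction = editing_fraction,
        ref_contig = contig, ref_anchor = ganchor, genome_base = gbase,
        stringsAsFactors = FALSE)
    }
  }
  db$editing <- rbind(db$editing, do.call(rbind, rows))
  db
}
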