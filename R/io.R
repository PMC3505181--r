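# File-format interfaces.  FASTA/FASTQ go through Biostrings and GFF3 through
# rtracklayer; SAM and VCF records are produced and parsed here because the
# pipeline's records carry custom fields and the reader must give precise,
# line-addressed parse errors.

#' Write sequences to FASTA
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#' @param path FASTA file.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write reads to FASTQ (Phred+33)
#' @param reads data.frame with read_id, seq, qual (Phred+33 strings).
#' @param path output file.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(nchar(reads$seq) == nchar(reads$qual)))
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(setNames(reads$seq, reads$read_id)),
    Biostrings::PhredQuality(reads$qual))
  suppressWarnings(Biostrings::writeQualityScaledXStringSet(x, path))
  invisible(path)
}

#' Read a FASTQ file
#' @param path FASTQ file.
#' @return data.frame with read_id, seq, qual.
#' @export
read_fastq <- function(path) {
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  data.frame(read_id = names(x), seq = as.character(x),
             qual = as.character(Biostrings::quality(x)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write gene models to GFF3
#'
#' One `gene` feature plus `exon` children per gene; coordinates convert from
#' the internal 0-based half-open representation to 1-based closed GFF3.
#'
#' @param models a `GeneModels` object (see [build_gene_models()]).
#' @param path output file.
#' @export
write_gff3 <- function(models, path) {
  ex <- models$exons
  g <- models$genes
  gene_gr <- GenomicRanges::GRanges(
    g$contig, IRanges::IRanges(g$start + 1L, g$end), strand = g$strand,
    type = "gene", ID = g$gene_id)
  exon_gr <- GenomicRanges::GRanges(
    ex$contig, IRanges::IRanges(ex$start + 1L, ex$end), strand = ex$strand,
    type = "exon", ID = paste0(ex$gene_id, ".e", ex$exon_rank),
    Parent = ex$gene_id)
  gr <- c(gene_gr, exon_gr)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models from GFF3
#' @param path GFF3 file.
#' @return a `GeneModels` object (genes + exons tables, 0-based half-open).
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  ex <- gr[gr$type == "exon"]
  parent <- as.character(unlist(ex$Parent))
  exons <- data.frame(
    gene_id = parent,
    contig = as.character(GenomicRanges::seqnames(ex)),
    strand = as.character(GenomicRanges::strand(ex)),
    start = GenomicRanges::start(ex) - 1L,
    end = GenomicRanges::end(ex),
    stringsAsFactors = FALSE)
  exons <- exons[order(exons$gene_id, exons$start), ]
  exons$exon_rank <- stats::ave(exons$start, exons$gene_id,
                                FUN = seq_along)
  genes <- do.call(rbind, lapply(split(exons, exons$gene_id), function(d) {
    data.frame(gene_id = d$gene_id[1], contig = d$contig[1],
               strand = d$strand[1], start = min(d$start), end = max(d$end),
               n_exons = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(genes) <- NULL
  structure(list(genes = genes, exons = exons,
                 decoys = data.frame()), class = "GeneModels")
}

# ---------------------------------------------------------------------------
# VCF
# ---------------------------------------------------------------------------

#' Write indel/SNP records to a minimal VCF
#'
#' @param vars data.frame with contig, pos (0-based anchor), id, ref, alt,
#'   qual (numeric or NA) and an optional `info` character column.
#' @param path output file.
#' @param contig_lengths named integer vector for `##contig` headers.
#' @export
write_vcf <- function(vars, path, contig_lengths = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           if (!is.null(contig_lengths))
             sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
                     as.integer(contig_lengths)),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  if (nrow(vars) == 0) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  qual <- ifelse(is.na(vars$qual), ".", format(vars$qual, trim = TRUE))
  info <- if (!is.null(vars$info)) vars$info else "."
  id <- if (!is.null(vars$id)) vars$id else "."
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t%s\tPASS\t%s",
                  vars$contig, vars$pos + 1L, id, vars$ref, vars$alt,
                  qual, info)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a (plain-text) VCF
#' @param path VCF file.
#' @return data.frame with contig, pos (0-based), id, ref, alt, qual, info.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0) {
    return(data.frame(contig = character(), pos = integer(), id = character(),
                      ref = character(), alt = character(), qual = numeric(),
                      info = character(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  n <- lengths(fields)
  if (any(n < 8)) {
    bad <- which(n < 8)[1] + sum(startsWith(lines, "#"))
    stop(sprintf("malformed VCF record at line %d: fewer than 8 fields", bad))
  }
  m <- do.call(rbind, fields)
  pos <- suppressWarnings(as.integer(m[, 2]))
  if (any(is.na(pos))) stop("malformed VCF: non-numeric POS")
  data.frame(contig = m[, 1], pos = pos - 1L, id = m[, 3], ref = m[, 4],
             alt = m[, 5],
             qual = suppressWarnings(as.numeric(ifelse(m[, 6] == ".", NA,
                                                       m[, 6]))),
             info = m[, 8], stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# SAM
# ---------------------------------------------------------------------------

#' Write alignment records to SAM
#'
#' @param records alignment data.frame (qname, flag, rname, pos 1-based,
#'   mapq, cigar, seq, qual, and optionally nm, score).
#' @param contig_lengths named integer vector for `@SQ` headers.
#' @param path output file.
#' @export
write_sam <- function(records, contig_lengths, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
                   as.integer(contig_lengths)))
  tags <- character(nrow(records))
  if (!is.null(records$nm)) {
    has <- !is.na(records$nm)
    tags[has] <- sprintf("\tNM:i:%d", records$nm[has])
  }
  if (!is.null(records$score)) {
    has <- !is.na(records$score)
    tags[has] <- paste0(tags[has], sprintf("\tAS:i:%d", records$score[has]))
  }
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s%s",
                  records$qname, records$flag, records$rname, records$pos,
                  records$mapq, records$cigar, records$seq, records$qual,
                  tags)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a SAM file
#'
#' Validates each record: CIGAR ops must be among M/I/D/S and their query
#' length must equal the sequence length; malformed records raise an error
#' naming the line.  Tags other than NM/AS are ignored, so output from
#' external aligners can be ingested.
#'
#' @param path SAM file.
#' @return alignment data.frame.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "@")
  body_idx <- which(!is_hdr)
  if (length(body_idx) == 0) {
    return(data.frame(qname = character(), flag = integer(),
                      rname = character(), pos = integer(), mapq = integer(),
                      cigar = character(), seq = character(),
                      qual = character(), nm = integer(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11)) {
    bad <- body_idx[which(nf < 11)[1]]
    stop(sprintf("malformed SAM record at line %d: fewer than 11 fields", bad))
  }
  qname <- vapply(fields, `[`, "", 1)
  flag <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2)))
  rname <- vapply(fields, `[`, "", 3)
  pos <- suppressWarnings(as.integer(vapply(fields, `[`, "", 4)))
  mapq <- suppressWarnings(as.integer(vapply(fields, `[`, "", 5)))
  cigar <- vapply(fields, `[`, "", 6)
  seq <- vapply(fields, `[`, "", 10)
  qual <- vapply(fields, `[`, "", 11)
  if (any(is.na(flag))) {
    bad <- body_idx[which(is.na(flag))[1]]
    stop(sprintf("malformed SAM record at line %d: non-numeric FLAG", bad))
  }
  nm <- rep(NA_integer_, length(qname))
  score <- rep(NA_integer_, length(qname))
  for (i in which(nf > 11)) {
    extra <- fields[[i]][12:nf[i]]
    nmv <- extra[startsWith(extra, "NM:i:")]
    if (length(nmv)) nm[i] <- as.integer(sub("NM:i:", "", nmv[1]))
    asv <- extra[startsWith(extra, "AS:i:")]
    if (length(asv)) score[i] <- as.integer(sub("AS:i:", "", asv[1]))
  }
  mapped <- !bitwAnd(flag, 4L)
  sp <- cigar_span_cpp(cigar)
  bad_cigar <- mapped & (!sp$ok | sp$qlen != nchar(seq))
  if (any(bad_cigar)) {
    bad <- body_idx[which(bad_cigar)[1]]
    stop(sprintf(
      "malformed SAM record at line %d: CIGAR invalid or inconsistent with sequence length",
      bad))
  }
  data.frame(qname = qname, flag = flag, rname = rname, pos = pos,
             mapq = mapq, cigar = cigar, seq = seq, qual = qual, nm = nm,
             score = score, stringsAsFactors = FALSE)
}
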