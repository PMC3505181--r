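# Shared fixture builders: everything is generated in code at test time.

# one-row alignment record in SAM conventions
aln_record <- function(qname, rname, pos1, cigar, seq,
                       qual = strrep(rawToChar(as.raw(37 + 33)), nchar(seq)),
                       flag = 0L, mapq = 60L, nm = 0L, score = NA_integer_) {
  data.frame(qname = qname, flag = flag, rname = rname, pos = pos1,
             mapq = mapq, cigar = cigar, seq = seq, qual = qual, nm = nm,
             score = score, stringsAsFactors = FALSE)
}

phred_chr <- function(q) rawToChar(as.raw(q + 33))

# a pileup column built directly (bypassing alignment), for filter fixtures
fixture_column <- function(contig = "c", pos = 50L, ref_base = "A",
                           entries) {
  list(contig = contig, pos = pos, ref_base = ref_base, entries = entries)
}

fixture_entry <- function(read_id, event = "A", base_quality = 37L,
                          mapq = 60L, n_mismatches = 0L,
                          distance_to_read_end = NA_integer_,
                          duplicate_flag = FALSE, contig = "c", pos = 50L) {
  is_indel <- grepl("^[+-]", event)
  data.frame(site = 1L, contig = contig, pos = pos, row = NA_integer_,
             read_id = read_id, event = event,
             base_quality = base_quality, mapq = mapq,
             n_mismatches = n_mismatches,
             distance_to_read_end = distance_to_read_end,
             duplicate_flag = duplicate_flag, is_indel = is_indel,
             kind = ifelse(is_indel,
                           ifelse(startsWith(event, "+"), "insertion",
                                  "deletion"), NA_character_),
             allele = ifelse(is_indel, substring(event, 2), NA_character_),
             stringsAsFactors = FALSE)
}

# small full pipeline configuration used across tests
small_config <- function(seed = 3, n_reads = 40000, editing = 0,
                         sensitivity = FALSE) {
  cfg <- default_config(seed = seed)
  cfg$genome$contig_length <- 60000
  cfg$genes$n_genes <- 8
  cfg$diploid$n_hap_indels <- 4
  cfg$diploid$n_snps <- 20
  cfg$diploid$n_misassembly <- 4
  cfg$paralogs$n_pairs <- 2
  cfg$reads$n_reads <- n_reads
  cfg$editing$n_sites <- editing
  cfg$stages$sensitivity <- sensitivity
  cfg
}
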