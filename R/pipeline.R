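# End-to-end orchestration: forge -> align -> call -> classify ->
# sensitivity, driven by a single config with one master seed, plus the
# summary report writer and truth-based label expectations.

#' Default pipeline configuration
#'
#' The defaults define the standard synthetic study conditions: a 200 kb
#' diploid genome carrying 20 spliced genes (a quarter with decoy first
#' introns), 5 paralog pairs at 2% divergence, 10 haplotype indels and 10
#' database (misassembly) indels planted in transcribed regions, and 200k
#' 33 bp single-end reads at 1% substitution error.  Editing is off by
#' default; switch it on to measure signal retention.
#'
#' @param seed master integer seed; every stage derives its own sub-seed.
#' @param out_dir optional output directory; when set, all stage outputs are
#'   written there.
#' @return a `RunConfig` list.
#' @export
default_config <- function(seed = 1, out_dir = NULL) {
  structure(list(
    seed = as.integer(seed),
    out_dir = out_dir,
    genome = list(n_contigs = 1, contig_length = 200000, gc_fraction = 0.41),
    genes = list(n_genes = 20, exon_count_range = c(2, 6),
                 exon_len_range = c(150, 300), intron_len_range = c(70, 140),
                 decoy_fraction = 0.25),
    diploid = list(n_hap_indels = 10, n_snps = 60, database_fraction = 0.5,
                   n_misassembly = 10, min_gap = 40L),
    paralogs = list(n_pairs = 5, length = 500, divergence = 0.02),
    editing = list(n_sites = 0, fraction = 0.5, base = NULL),
    reads = list(n_reads = 200000, read_length = 33, error_rate = 0.01),
    quality = quality_profile(),
    align = list(seed_length = 14, max_hits = 8, max_candidates = 1280),
    scoring = scoring_scheme(),
    read_filters = read_filters(),
    thresholds = call_thresholds(),
    classify = classify_params(),
    sensitivity = list(top_n = 100, min_coverage = 5, max_homopolymer = 5),
    stages = list(classify = TRUE, sensitivity = TRUE)),
    class = "RunConfig")
}

#' Load a pipeline configuration from YAML or JSON
#'
#' Values in the file override the corresponding [default_config()] entries
#' (nested lists merge; anything not mentioned keeps its default).  The file
#' should carry a top-level integer `seed`.
#'
#' @param path YAML (.yml/.yaml) or JSON file.
#' @return a `RunConfig`.
#' @export
read_config <- function(path) {
  user <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
          else jsonlite::read_json(path, simplifyVector = TRUE)
  merge_cfg <- function(base, over) {
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]]))
        merge_cfg(base[[nm]], over[[nm]]) else over[[nm]]
    }
    base
  }
  cfg <- merge_cfg(default_config(seed = if (!is.null(user$seed)) user$seed
                                         else 1),
                   user)
  class(cfg) <- "RunConfig"
  cfg
}

#' Run the full pipeline
#'
#' Deterministic for a fixed config: two runs with the same config produce
#' identical outputs.  Returns all stage products; when `config$out_dir` is
#' set, also writes FASTA/GFF3/VCF/FASTQ/SAM/TSV outputs and the summary
#' report there.
#'
#' @param config a `RunConfig` (see [default_config()]).
#' @return list with gs, models, db_sim, db_annot, reads, alignments,
#'   candidates, decisions, classification (results + counts), sensitivity,
#'   and the config.
#' @export
run_pipeline <- function(config = default_config()) {
  seed <- config$seed

  ## forge: reference, genes, haplotypes, paralogs
  gs <- build_reference(config$genome$n_contigs, config$genome$contig_length,
                        config$genome$gc_fraction,
                        seed = stage_seed(seed, "forge"))
  bg <- build_gene_models(gs, config$genes$n_genes,
                          config$genes$exon_count_range,
                          config$genes$exon_len_range,
                          config$genes$intron_len_range,
                          seed = stage_seed(seed, "genes"),
                          decoy_fraction = config$genes$decoy_fraction)
  gs <- bg$gs
  models <- bg$models
  # plant variants in exon cores, clear of decoy junctions: one planted
  # mechanism per read-length window, mirroring both the editing-placement
  # rule and the sparsity of real heterozygous indels (random placement at
  # desk scale would superimpose distinct mechanisms at rates real genomes
  # do not show)
  exon_targets <- data.frame(contig = models$exons$contig,
                             start = models$exons$start + 10L,
                             end = models$exons$end - 10L,
                             stringsAsFactors = FALSE)
  ex <- models$exons
  internal <- ex[order(ex$gene_id, ex$start), ]
  nexon <- ave(internal$exon_rank, internal$gene_id, FUN = length)
  bounds <- c(internal$end[internal$exon_rank < nexon],
              internal$start[internal$exon_rank > 1])
  bcontig <- c(internal$contig[internal$exon_rank < nexon],
               internal$contig[internal$exon_rank > 1])
  if (length(bounds) > 0) {
    zones <- data.frame(contig = bcontig, start = bounds - 45L,
                        end = bounds + 45L, stringsAsFactors = FALSE)
    exon_targets <- subtract_intervals(exon_targets, zones)
  }
  gs <- derive_diploid(gs, database_fraction = config$diploid$database_fraction,
                       seed = stage_seed(seed, "diploid"),
                       n_snps = config$diploid$n_snps,
                       n_indels = config$diploid$n_hap_indels,
                       n_misassembly = config$diploid$n_misassembly,
                       target_intervals = exon_targets,
                       min_gap = config$diploid$min_gap)
  if (config$paralogs$n_pairs > 0) {
    gs <- plant_paralogs(gs, config$paralogs$n_pairs, config$paralogs$length,
                         config$paralogs$divergence,
                         seed = stage_seed(seed, "paralogs"),
                         avoid = models$genes[, c("contig", "start", "end")])
    models <- add_paralog_genes(models, gs)
  }

  ## transcripts: simulation set (true molecules) and annotation set
  hap_models <- subset_models(models, models$genes$source == "haplotype")
  ref_models <- subset_models(models, models$genes$source == "reference")
  db_sim <- combine_junctiondb(transcribe(gs, hap_models, "maternal"),
                               transcribe(gs, hap_models, "paternal"))
  if (nrow(ref_models$genes) > 0)
    db_sim <- combine_junctiondb(db_sim, transcribe(gs, ref_models,
                                                    "reference"))
  db_sim <- apply_misassembly_to_db(db_sim, gs, gs$variants)
  if (config$editing$n_sites > 0) {
    db_sim <- inject_editing(db_sim, config$editing$n_sites,
                             config$editing$fraction,
                             seed = stage_seed(seed, "editing"),
                             base = config$editing$base)
  }
  db_annot <- transcribe(gs, models, "reference")

  ## reads
  reads <- simulate_reads(db_sim, n_reads = config$reads$n_reads,
                          read_length = config$reads$read_length,
                          error_rate = config$reads$error_rate,
                          profile = config$quality,
                          seed = stage_seed(seed, "reads"))

  ## align to the maternal haplotype
  index <- build_index(gs$maternal, config$align$seed_length,
                       config$align$max_hits)
  aln <- map_reads(reads, index, config$scoring,
                   config$align$max_candidates)
  aln <- sort_alignments(aln)

  ## call
  cc <- call_candidates(aln, gs$maternal, config$read_filters,
                        config$thresholds)
  passing <- cc$decisions[cc$decisions$passed, , drop = FALSE]

  ## classify
  classification <- NULL
  if (isTRUE(config$stages$classify)) {
    known <- known_variants_table(gs)
    resources <- list(gs = gs, alignments = aln, junction_db = db_annot,
                      known = known)
    classification <- classify_cascade(passing, resources, config$classify,
                                       calling_hap = "maternal")
  }

  ## sensitivity (needs a paternal-side run of the same pipeline)
  sens <- NULL
  if (isTRUE(config$stages$sensitivity)) {
    index_p <- build_index(gs$paternal, config$align$seed_length,
                           config$align$max_hits)
    aln_p <- sort_alignments(map_reads(reads, index_p, config$scoring,
                                       config$align$max_candidates))
    cc_p <- call_candidates(aln_p, gs$paternal, config$read_filters,
                            config$thresholds)
    passing_p <- cc_p$decisions[cc_p$decisions$passed, , drop = FALSE]
    sites <- locate_haplotype_indels(gs, method = "liftover")
    sel <- rank_and_select(sites, aln, gs$maternal,
                           config$sensitivity$top_n,
                           config$sensitivity$min_coverage,
                           config$sensitivity$max_homopolymer,
                           config$read_filters)
    rec <- recovery_fraction(sel, passing, passing_p)
    covered_all <- rank_and_select(sites, aln, gs$maternal,
                                   top_n = nrow(sites),
                                   config$sensitivity$min_coverage,
                                   config$sensitivity$max_homopolymer,
                                   config$read_filters)
    rec_all <- recovery_fraction(covered_all, passing, passing_p)
    sens <- list(sites = sites, selected = sel, recovery_top = rec,
                 covered_all = covered_all, recovery_all = rec_all,
                 candidates_paternal = passing_p)
  }

  run <- list(gs = gs, models = models, db_sim = db_sim, db_annot = db_annot,
              reads = reads, alignments = aln, candidates = cc$candidates,
              decisions = cc$decisions, passing = passing,
              classification = classification, sensitivity = sens,
              config = config)
  if (!is.null(config$out_dir)) write_run_outputs(run, config$out_dir)
  invisible(run)
}

# remove `zones` from `intervals` (both data.frames contig/start/end)
subtract_intervals <- function(intervals, zones) {
  out <- list()
  for (i in seq_len(nrow(intervals))) {
    segs <- data.frame(start = intervals$start[i], end = intervals$end[i])
    z <- zones[zones$contig == intervals$contig[i], , drop = FALSE]
    for (j in seq_len(nrow(z))) {
      nxt <- list()
      for (k in seq_len(nrow(segs))) {
        s <- segs$start[k]; e <- segs$end[k]
        if (z$end[j] <= s || z$start[j] >= e) {
          nxt[[length(nxt) + 1]] <- data.frame(start = s, end = e)
        } else {
          if (z$start[j] > s)
            nxt[[length(nxt) + 1]] <- data.frame(start = s, end = z$start[j])
          if (z$end[j] < e)
            nxt[[length(nxt) + 1]] <- data.frame(start = z$end[j], end = e)
        }
      }
      segs <- if (length(nxt)) do.call(rbind, nxt)
              else data.frame(start = integer(0), end = integer(0))
    }
    if (nrow(segs))
      out[[length(out) + 1]] <- data.frame(contig = intervals$contig[i],
                                           start = segs$start,
                                           end = segs$end,
                                           stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(data.frame(contig = character(),
                                        start = integer(), end = integer(),
                                        stringsAsFactors = FALSE))))
}

subset_models <- function(models, keep) {
  g <- models$genes[keep, , drop = FALSE]
  structure(list(genes = g,
                 exons = models$exons[models$exons$gene_id %in% g$gene_id, ,
                                      drop = FALSE],
                 decoys = models$decoys),
            class = "GeneModels")
}

# database indels in normalized (contig, anchor, kind, seq) form
known_variants_table <- function(gs) {
  v <- gs$variants
  v <- v[v$in_database & v$kind != "snp", , drop = FALSE]
  if (nrow(v) == 0) {
    return(data.frame(contig = character(), pos = integer(),
                      kind = character(), seq = character(),
                      id = character(), stringsAsFactors = FALSE))
  }
  data.frame(contig = v$contig, pos = v$ref_pos, kind = v$kind,
             seq = ifelse(v$kind == "insertion", substring(v$alt_allele, 2),
                          substring(v$ref_allele, 2)),
             id = sprintf("dbv%04d", seq_len(nrow(v))),
             stringsAsFactors = FALSE)
}

# paternal-coordinate anchors for haplotype indel sites (used when matching
# candidates from paternal-side calling)
hap_sites_paternal_anchor <- function(gs, sites) {
  vapply(seq_len(nrow(sites)), function(i) {
    p <- ref_to_hap(gs, "paternal", sites$contig[i], sites$ref_pos[i])
    if (is.na(p)) NA_integer_ else p
  }, integer(1))
}

#' Write the category summary report
#'
#' Renders the classification counts in the standard five-category layout
#' (initial candidates, paternal alleles, splice junctions, paralog
#' sequences, known genomic variations) plus the residual row.  Refuses to
#' write when the partition invariant (categories sum to the initial count)
#' is violated.
#'
#' @param counts named counts from [classify_cascade()].
#' @param path output file.
#' @param format `"tsv"` or `"markdown"`.
#' @export
write_report <- function(counts, path, format = c("tsv", "markdown")) {
  format <- match.arg(format)
  need <- c("initial_candidates", "paternal_alleles", "splice_junctions",
            "paralog_sequences", "known_genomic_variations", "residual")
  if (!all(need %in% names(counts)))
    stop("summary counts are missing required categories")
  if (counts[["initial_candidates"]] != sum(counts[need[-1]]))
    stop("report partition invariant violated: categories must sum to the initial count")
  labels <- c("Initial candidates", "Paternal alleles", "Splice junctions",
              "Paralog sequences", "Known genomic variations", "Residual")
  vals <- as.integer(counts[need])
  if (format == "tsv") {
    writeLines(c("category\tcount", paste(labels, vals, sep = "\t")), path)
  } else {
    writeLines(c("| Category | Count |", "| --- | --- |",
                 sprintf("| %s | %d |", labels, vals)), path)
  }
  invisible(path)
}

#' Truth-based expected label for each classified candidate
#'
#' Attributes each candidate to the planted mechanism nearest its reference
#' anchor: haplotype indels -> paternal_allele, decoy junctions ->
#' splice_junction, paralog source intervals -> paralog, misassembly
#' database indels -> known_variant, editing sites -> residual.  Candidates
#' matching no mechanism get NA.
#'
#' @param results classification results from [classify_cascade()].
#' @param run a [run_pipeline()] result (for the truth tables).
#' @param tol anchor matching tolerance (bp).
#' @return character vector of expected labels.
#' @export
expected_labels <- function(results, run, tol = 6) {
  gs <- run$gs
  n <- nrow(results)
  out <- rep(NA_character_, n)
  if (n == 0) return(out)
  ra <- vapply(seq_len(n), function(i)
    hap_to_ref(gs, "maternal", results$contig[i], results$pos[i]),
    integer(1))
  v <- gs$variants
  hap_ind <- v[v$kind != "snp" & v$haplotype %in% c("maternal", "paternal"), ]
  mis <- v[v$kind != "snp" & v$haplotype == "both", ]
  dec <- run$models$decoys
  par <- gs$paralogs
  ed <- run$db_sim$editing
  # internal exon boundaries of multi-exon genes (junction artifacts can
  # arise at any junction, engineered decoy or not)
  ex <- run$models$exons
  ex <- ex[ave(ex$exon_rank, ex$gene_id, FUN = length) > 1, , drop = FALSE]
  jbound <- data.frame(
    contig = c(ex$contig, ex$contig),
    pos = c(ex$start, ex$end),
    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    if (is.na(ra[i])) next
    hit <- function(pos, contig) {
      length(pos) > 0 && any(contig == results$contig[i] &
                               abs(pos - ra[i]) <= tol)
    }
    if (nrow(hap_ind) && hit(hap_ind$ref_pos, hap_ind$contig)) {
      out[i] <- "paternal_allele"
    } else if (nrow(dec) && hit(dec$expected_anchor, dec$contig)) {
      out[i] <- "splice_junction"
    } else if (!is.null(par) && nrow(par) &&
               any(par$src_contig == results$contig[i] &
                     ra[i] >= par$src_start - tol &
                     ra[i] < par$src_end + tol)) {
      out[i] <- "paralog"
    } else if (nrow(mis) && hit(mis$ref_pos, mis$contig)) {
      out[i] <- "known_variant"
    } else if (nrow(ed) && hit(ed$ref_anchor, ed$ref_contig)) {
      out[i] <- "residual"
    } else if (nrow(jbound) &&
               any(jbound$contig == results$contig[i] &
                     abs(jbound$pos - ra[i]) <= 35)) {
      out[i] <- "splice_junction"
    }
  }
  out
}

# ---------------------------------------------------------------------------
# run outputs
# ---------------------------------------------------------------------------

write_run_outputs <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gs <- run$gs
  p <- function(f) file.path(out_dir, f)
  write_fasta(gs$reference, p("reference.fa"))
  write_fasta(gs$maternal, p("maternal.fa"))
  write_fasta(gs$paternal, p("paternal.fa"))
  write_gff3(run$models, p("genes.gff3"))
  write_fasta(run$db_sim$transcripts, p("transcripts.fa"))
  truth_variants_vcf(gs, p("truth_variants.vcf"), known_only = FALSE)
  truth_variants_vcf(gs, p("known_variants.vcf"), known_only = TRUE)
  write_fastq(run$reads, p("reads.fastq"))
  write.table(run$reads[, c("read_id", "truth_transcript", "truth_offset",
                            "truth_strand", "truth_haplotype", "edits")],
              p("truth_reads.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_sam(run$alignments, nchar(gs$maternal), p("alignments.sam"))
  write_candidates_vcf(run$passing, gs$maternal, p("candidates.vcf"))
  write.table(run$decisions[, setdiff(names(run$decisions), "support_reads")],
              p("filter_audit.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(run$classification)) {
    write.table(run$classification$results[,
      setdiff(names(run$classification$results), "support_reads")],
      p("classification.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    write_report(run$classification$counts, p("summary.tsv"), "tsv")
    write_report(run$classification$counts, p("summary.md"), "markdown")
  }
  if (!is.null(run$sensitivity)) {
    write.table(run$sensitivity$selected, p("sensitivity_sites.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(
      fraction_maternal_top = run$sensitivity$recovery_top$fraction_maternal,
      fraction_combined_top = run$sensitivity$recovery_top$fraction_combined,
      fraction_maternal_covered = run$sensitivity$recovery_all$fraction_maternal,
      fraction_combined_covered = run$sensitivity$recovery_all$fraction_combined),
      p("sensitivity.json"), auto_unbox = TRUE, digits = NA)
  }
  manifest <- list(config = run$config[setdiff(names(run$config), "out_dir")],
                   counts = if (!is.null(run$classification))
                     as.list(run$classification$counts) else NULL,
                   n_reads_mapped = sum(bitwAnd(run$alignments$flag, 4L) == 0),
                   n_candidates = nrow(run$candidates),
                   n_passing = nrow(run$passing))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(out_dir)
}

truth_variants_vcf <- function(gs, path, known_only = FALSE) {
  v <- gs$variants
  if (known_only) v <- v[v$in_database, , drop = FALSE]
  if (nrow(v) == 0) return(write_vcf(empty_vcf_df(), path,
                                     nchar(gs$reference)))
  info <- sprintf("HAP=%s;DB=%d", v$haplotype, as.integer(v$in_database))
  write_vcf(data.frame(contig = v$contig, pos = v$ref_pos,
                       id = sprintf("tv%04d", seq_len(nrow(v))),
                       ref = v$ref_allele, alt = v$alt_allele,
                       qual = NA_real_, info = info,
                       stringsAsFactors = FALSE),
            path, contig_lengths = nchar(gs$reference))
}
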