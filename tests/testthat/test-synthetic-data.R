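# Synthetic diploid genome, gene models, paralogs, editing and reads.

test_that("reference forging is deterministic and honours GC targets", {
  a <- build_reference(1, 10000, 0.5, seed = 7)
  b <- build_reference(1, 10000, 0.5, seed = 7)
  expect_identical(a$reference, b$reference)
  # degenerate composition
  g <- build_reference(1, 10000, 1 - 1e-9, seed = 1)
  expect_false(grepl("[AT]", g$reference[[1]]))
  # GC within 3 points at realistic size
  g2 <- build_reference(2, 50000, 0.41, seed = 1)
  gc <- mean(strsplit(paste(g2$reference, collapse = ""), "")[[1]] %in%
               c("G", "C"))
  expect_gte(gc, 0.38); expect_lte(gc, 0.44)
  expect_error(build_reference(1, 500, 0.5), "contig_length")
  expect_error(build_reference(1, 10000, 1.2), "gc_fraction")
})

test_that("null variation yields identical haplotypes and empty truth", {
  gs <- derive_diploid(build_reference(1, 5000, 0.5, seed = 1),
                       snp_rate = 0, indel_rate = 0, seed = 2)
  expect_identical(gs$maternal, gs$reference)
  expect_identical(gs$paternal, gs$reference)
  expect_equal(nrow(gs$variants), 0)
  expect_error(derive_diploid(gs, snp_rate = -0.1), "rates")
  expect_error(derive_diploid(gs, indel_rate = 0.05), "0.01")
})

test_that("indel counts are Poisson around rate * length", {
  ref <- build_reference(1, 50000, 0.5, seed = 3)
  counts <- vapply(1:60, function(s) {
    gs <- derive_diploid(ref, indel_rate = 2e-4, seed = s)
    sum(gs$variants$kind != "snp" & gs$variants$haplotype == "maternal")
  }, numeric(1))
  lambda <- 2e-4 * 50000  # expected indels per haplotype draw
  se <- sqrt(lambda / length(counts))
  expect_lt(abs(mean(counts) - lambda), 3 * se + 0.5)
})

test_that("truth variants reproduce the haplotypes and length bookkeeping", {
  ref <- build_reference(1, 20000, 0.45, seed = 4)
  gs <- derive_diploid(ref, snp_rate = 1e-3, indel_rate = 5e-4, seed = 9)
  for (hap in c("maternal", "paternal")) {
    v <- gs$variants[gs$variants$haplotype == hap, ]
    ap <- indelrdd:::apply_variants_to_contig(ref$reference[[1]], v)
    expect_identical(ap$seq, gs[[hap]][[1]])
    dlen <- sum(nchar(v$alt_allele) - nchar(v$ref_allele))
    expect_equal(nchar(gs[[hap]][[1]]), 20000 + dlen)
  }
  # a single planted insertion lengthens the haplotype by exactly 1
  v1 <- data.frame(contig = "contig01", ref_pos = 1000L, kind = "insertion",
                   ref_allele = substr(ref$reference[[1]], 1001, 1001),
                   alt_allele = paste0(substr(ref$reference[[1]], 1001, 1001),
                                       "A"),
                   haplotype = "maternal", in_database = FALSE,
                   stringsAsFactors = FALSE)
  ap <- indelrdd:::apply_variants_to_contig(ref$reference[[1]], v1)
  expect_equal(nchar(ap$seq), 20001)
  ins_block <- ap$blocks[ap$blocks$ref_start == ap$blocks$ref_end, ]
  expect_equal(ins_block$ref_start, 1001)
})

test_that("liftover round-trips identity away from indel loci", {
  gs <- derive_diploid(build_reference(1, 30000, 0.5, seed = 5),
                       snp_rate = 1e-3, indel_rate = 5e-4, seed = 6)
  for (hap in c("maternal", "paternal")) {
    pos <- seq(0, 29000, by = 97)
    r <- hap_to_ref(gs, hap, "contig01", pos)
    keep <- !is.na(r)
    back <- ref_to_hap(gs, hap, "contig01", r[keep])
    expect_equal(back, pos[keep])
    # liftover blocks jointly cover the haplotype contig
    b <- gs$liftover[[hap]]
    expect_equal(min(b$hap_start), 0)
    expect_equal(max(b$hap_end), nchar(gs[[hap]][[1]]))
    expect_true(all(b$hap_start[-1] == head(b$hap_end, -1)))
  }
})

test_that("paralog copies carry the requested divergence and one indel", {
  gs <- derive_diploid(build_reference(1, 60000, 0.5, seed = 6), seed = 1)
  gs0 <- gs
  gs <- plant_paralogs(gs, n_pairs = 1, length = 500, divergence = 0.02,
                       seed = 2)
  pp <- gs$paralogs
  src <- substr0(gs$reference[[pp$src_contig]], pp$src_start, pp$src_end)
  cpy <- substr0(gs$reference[[pp$copy_contig]], pp$copy_start, pp$copy_end)
  al <- smith_waterman_affine(src, cpy, scoring_scheme(), global = TRUE)
  expect_equal(al$n_gaps, 1)
  ident <- 1 - al$n_mismatch / 500
  expect_gte(ident, 0.97); expect_lte(ident, 0.99)
  # haplotypes unchanged (assembly-gap model) and >= 10 kb separation
  expect_identical(gs$maternal, gs0$maternal)
  expect_gte(abs(pp$copy_start - pp$src_start), 10000)
  # divergence 0: identical copy; n_pairs 0: untouched genome
  gsd <- plant_paralogs(gs0, 1, 500, 0, seed = 3)
  p2 <- gsd$paralogs
  expect_identical(substr0(gsd$reference[[1]], p2$src_start, p2$src_end),
                   substr0(gsd$reference[[1]], p2$copy_start, p2$copy_end))
  expect_identical(plant_paralogs(gs0, 0)$reference, gs0$reference)
  expect_error(plant_paralogs(gs0, 1, length = 100), ">= 200")
  expect_error(plant_paralogs(gs0, 1, divergence = 0.2), "divergence")
})

test_that("gene models are disjoint with canonical GT/AG intron signals", {
  gs <- build_reference(1, 200000, 0.45, seed = 8)
  bg <- build_gene_models(gs, n_genes = 20, seed = 8, decoy_fraction = 0.25)
  ex <- bg$models$exons
  # pairwise disjoint exons (interval sweep)
  ex <- ex[order(ex$contig, ex$start), ]
  expect_true(all(ex$start[-1] >= head(ex$end, -1) |
                    ex$contig[-1] != head(ex$contig, -1)))
  # GT/AG at every intron boundary on the coding strand
  g <- bg$gs$reference
  for (gid in unique(ex$gene_id)) {
    e <- ex[ex$gene_id == gid, ]
    if (nrow(e) < 2) next
    strand <- bg$models$genes$strand[bg$models$genes$gene_id == gid]
    for (i in seq_len(nrow(e) - 1)) {
      intron <- substr0(g[[e$contig[1]]], e$end[i], e$start[i + 1])
      if (strand == "-") intron <- indelrdd::revcomp(intron)
      expect_equal(substr(intron, 1, 2), "GT")
      expect_equal(substr(intron, nchar(intron) - 1, nchar(intron)), "AG")
    }
  }
  # single-exon gene: no introns, genome untouched beyond placement
  gs2 <- build_reference(1, 50000, 0.5, seed = 9)
  bg2 <- build_gene_models(gs2, n_genes = 2, exon_count_range = c(1, 1),
                           seed = 9)
  expect_identical(bg2$gs$reference, gs2$reference)
  expect_error(build_gene_models(build_reference(1, 1000, 0.5, seed = 1),
                                 n_genes = 50, seed = 1), "too small")
  expect_error(build_gene_models(gs2, 2, intron_len_range = c(30, 40),
                                 seed = 1), "60")
})

test_that("transcription concatenates exons with strand handling", {
  gs <- build_reference(1, 30000, 0.5, seed = 10)
  bg <- build_gene_models(gs, n_genes = 1, exon_count_range = c(2, 2),
                          exon_len_range = c(100, 100),
                          intron_len_range = c(80, 80), seed = 12)
  gs2 <- derive_diploid(bg$gs, seed = 1)
  db <- transcribe(gs2, bg$models, "maternal")
  tx <- db$transcripts[[1]]
  expect_equal(nchar(tx), 200)
  e <- bg$models$exons
  concat <- paste0(substr0(gs2$maternal[[1]], e$start[1], e$end[1]),
                   substr0(gs2$maternal[[1]], e$start[2], e$end[2]))
  if (bg$models$genes$strand == "+") {
    expect_identical(tx, concat)
  } else {
    expect_identical(tx, indelrdd::revcomp(concat))
  }
  # single-exon transcript equals the genomic substring
  bg3 <- build_gene_models(build_reference(1, 20000, 0.5, seed = 13),
                           n_genes = 1, exon_count_range = c(1, 1), seed = 2)
  gs3 <- derive_diploid(bg3$gs, seed = 1)
  db3 <- transcribe(gs3, bg3$models, "maternal")
  e3 <- bg3$models$exons
  sub <- substr0(gs3$maternal[[1]], e3$start, e3$end)
  expect_true(identical(db3$transcripts[[1]], sub) ||
                identical(db3$transcripts[[1]], indelrdd::revcomp(sub)))
  # exon outside the contig is an explicit error
  bad <- bg3$models
  bad$exons$end <- 10^6
  expect_error(transcribe(gs3, bad, "maternal"), "outside contig")
})

test_that("editing injection respects margins and fraction semantics", {
  gs <- build_reference(1, 60000, 0.5, seed = 14)
  bg <- build_gene_models(gs, n_genes = 4, seed = 14)
  gs2 <- derive_diploid(bg$gs, seed = 1)
  db <- transcribe(gs2, bg$models, "maternal")
  db0 <- inject_editing(db, 0, 0.5, seed = 1)
  expect_identical(db0$transcripts, db$transcripts)
  db1 <- inject_editing(db, 5, 1.0, seed = 2)
  ed <- db1$editing
  expect_equal(length(unique(ed$site_id)), 5)
  for (i in seq_len(nrow(ed))) {
    L <- nchar(db$transcripts[[ed$tx_id[i]]])
    expect_gte(ed$tx_pos[i], 40)
    expect_lte(ed$tx_pos[i], L - 40)
  }
  expect_error(inject_editing(db, 10000, 0.5, seed = 1), "eligible")
  expect_error(inject_editing(db, 1, 0, seed = 1), "editing_fraction")
  # fraction 1.0: every read covering a site carries the indel
  reads <- simulate_reads(db1, n_reads = 3000, error_rate = 0, seed = 3)
  sid <- ed$site_id[1]
  tx1 <- ed$tx_id[1]; p1 <- ed$tx_pos[1]
  on_tx <- reads[reads$truth_transcript == tx1, ]
  margin <- 2
  covering <- on_tx$truth_offset + margin <= p1 &
    on_tx$truth_offset + 33 - margin > p1
  expect_gt(sum(covering), 10)
  expect_true(all(grepl(sid, on_tx$edits[covering], fixed = TRUE)))
  # and the read sequence is not a substring of the unedited transcript
  sub <- on_tx[covering, ][1:5, ]
  for (i in 1:5) {
    s <- sub$seq[i]
    if (sub$truth_strand[i] == "-") s <- indelrdd::revcomp(s)
    expect_false(grepl(s, db$transcripts[[tx1]], fixed = TRUE))
  }
})

test_that("editing support follows the binomial at the configured fraction", {
  gs <- build_reference(1, 40000, 0.5, seed = 15)
  bg <- build_gene_models(gs, n_genes = 3, seed = 15)
  gs2 <- derive_diploid(bg$gs, seed = 1)
  db <- transcribe(gs2, bg$models, "maternal")
  fr <- vapply(1:30, function(s) {
    dbe <- inject_editing(db, 1, 0.5, seed = 99)
    reads <- simulate_reads(dbe, n_reads = 1500, error_rate = 0, seed = s)
    ed <- dbe$editing[1, ]
    on_tx <- reads[reads$truth_transcript == ed$tx_id, ]
    covering <- on_tx$truth_offset + 2 <= ed$tx_pos &
      on_tx$truth_offset + 31 > ed$tx_pos
    mean(grepl(ed$site_id, on_tx$edits[covering], fixed = TRUE))
  }, numeric(1))
  # mean carried fraction within 3 s.e. of 0.5
  se <- sd(fr) / sqrt(length(fr))
  expect_lt(abs(mean(fr) - 0.5), 3 * se + 0.02)
})

test_that("read simulation honours error rate, length and determinism", {
  gs <- build_reference(1, 50000, 0.5, seed = 16)
  bg <- build_gene_models(gs, n_genes = 5, seed = 16)
  gs2 <- derive_diploid(bg$gs, seed = 1)
  db <- transcribe(gs2, bg$models, "maternal")
  r0 <- simulate_reads(db, n_reads = 2000, error_rate = 0, seed = 4)
  expect_true(all(nchar(r0$seq) == 33))
  expect_true(all(nchar(r0$qual) == 33))
  # error-free reads are exact substrings of their transcripts
  for (i in sample.int(2000, 50)) {
    s <- r0$seq[i]
    if (r0$truth_strand[i] == "-") s <- indelrdd::revcomp(s)
    expect_true(grepl(s, db$transcripts[[r0$truth_transcript[i]]],
                      fixed = TRUE))
  }
  # observed mismatch rate near the configured 1%
  r1 <- simulate_reads(db, n_reads = 10000, error_rate = 0.01, seed = 5)
  rate <- sum(r1$n_errors) / (10000 * 33)
  expect_gte(rate, 0.008); expect_lte(rate, 0.012)
  # and n_errors agrees with a direct comparison to the truth transcript
  mm <- vapply(sample.int(10000, 100), function(i) {
    s <- r1$seq[i]
    if (r1$truth_strand[i] == "-") s <- indelrdd::revcomp(s)
    truth <- substr(db$transcripts[[r1$truth_transcript[i]]],
                    r1$truth_offset[i] + 1, r1$truth_offset[i] + 33)
    sum(strsplit(s, "")[[1]] != strsplit(truth, "")[[1]]) - r1$n_errors[i]
  }, numeric(1))
  expect_true(all(mm == 0))
  # error bases are usually low-quality (>= 50% by contract)
  err_reads <- which(r1$n_errors == 1)[1:200]
  lowq_frac <- mean(vapply(err_reads, function(i) {
    s <- r1$seq[i]
    if (r1$truth_strand[i] == "-") s <- indelrdd::revcomp(s)
    truth <- substr(db$transcripts[[r1$truth_transcript[i]]],
                    r1$truth_offset[i] + 1, r1$truth_offset[i] + 33)
    pos <- which(strsplit(s, "")[[1]] != strsplit(truth, "")[[1]])
    q <- utf8ToInt(substr(r1$qual[i],
                          if (r1$truth_strand[i] == "-") 34 - pos else pos,
                          if (r1$truth_strand[i] == "-") 34 - pos else pos)) - 33
    q <= 10
  }, logical(1)))
  expect_gte(lowq_frac, 0.5)
  # determinism: identical FASTQ bytes for a fixed seed
  fa <- tempfile(fileext = ".fastq"); fb <- tempfile(fileext = ".fastq")
  write_fastq(simulate_reads(db, n_reads = 500, error_rate = 0.01, seed = 6),
              fa)
  write_fastq(simulate_reads(db, n_reads = 500, error_rate = 0.01, seed = 6),
              fb)
  expect_identical(readLines(fa), readLines(fb))
  expect_error(simulate_reads(db, n_reads = 10, read_length = 10000,
                              seed = 1), "shortest")
  expect_error(simulate_reads(db, n_reads = 10, error_rate = 0.5, seed = 1),
               "error_rate")
})
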