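# Gapped aligner: scoring examples, oracle equivalence, seed index
# contracts, mapping behaviour, MAPQ.

test_that("local alignment handles identity and non-homology", {
  sc <- scoring_scheme(1, 3, 5, 2)
  al <- smith_waterman_affine("ACGT", "ACGT", sc)
  expect_equal(al$score, 4)
  expect_equal(al$cigar, "4M")
  al2 <- smith_waterman_affine("AAAA", "CCCC", sc)
  expect_lte(al2$score, 1)
  expect_lte(al2$qend - al2$qstart, 1)
  expect_error(smith_waterman_affine("", "ACGT", sc), "empty")
})

test_that("enumeration validates the R scoring oracle on tiny strings", {
  strs <- all_strings(c("A", "C"), 3)
  for (q in strs) for (t in strs) {
    expect_equal(oracle_local_affine(q, t), enum_local_affine(q, t),
                 info = paste(q, t))
  }
})

test_that("local alignment scores match the oracle for all short {A,C} pairs", {
  sc <- scoring_scheme(1, 3, 5, 2)
  strs <- all_strings(c("A", "C"), 6)
  mism <- 0L
  for (q in strs) {
    for (t in strs) {
      got <- sw_affine_cpp(q, t, 1, 3, 5, 2, FALSE)$score
      want <- oracle_local_affine(q, t)
      if (got != want) mism <- mism + 1L
    }
  }
  expect_equal(mism, 0L)
})

test_that("alignment is deterministic and ties prefer fewer gaps", {
  sc <- scoring_scheme()
  a <- smith_waterman_affine("ACGTACGTACGT", "ACGTACGGACGT", sc)
  b <- smith_waterman_affine("ACGTACGTACGT", "ACGTACGGACGT", sc)
  expect_identical(a, b)
  # one mismatch beats opening two gaps under the default scheme
  expect_equal(a$n_gaps, 0)
})

test_that("seed index lookups return positions and flag repetitive seeds", {
  idx <- build_index(c(g = "ACGTACGT"), seed_length = 4)
  hit <- index_lookup(idx, "ACGT")
  expect_equal(sort(hit$positions$pos), c(0, 4))
  expect_false(hit$repetitive)
  expect_equal(nrow(index_lookup(idx, "GGGG")$positions), 0)
  # a seed at 9 locations with K=8 is repetitive and yields no positions
  idx2 <- build_index(c(g = strrep("ACGTT", 9)), seed_length = 5, max_hits = 8)
  hit2 <- index_lookup(idx2, "ACGTT")
  expect_true(hit2$repetitive)
  expect_equal(nrow(hit2$positions), 0)
  idx3 <- build_index(c(g = strrep("ACGTT", 8)), seed_length = 5, max_hits = 8)
  expect_false(index_lookup(idx3, "ACGTT")$repetitive)
})

test_that("error-free unique reads map exactly with mapq 60", {
  set.seed(42)
  genome <- c(chr = paste(sample(c("A", "C", "G", "T"), 5000, TRUE),
                          collapse = ""))
  idx <- build_index(genome, 14)
  read <- substr(genome[[1]], 1001, 1033)
  al <- map_read(read, idx)
  expect_equal(al$flag, 0L)
  expect_equal(al$pos, 1001L)
  expect_equal(al$cigar, "33M")
  expect_equal(al$mapq, 60L)
  expect_equal(al$nm, 0L)
  # reverse-complement read maps to the same place on the minus strand
  al2 <- map_read(indelrdd::revcomp(read), idx)
  expect_equal(al2$pos, 1001L)
  expect_equal(al2$flag, 16L)
})

test_that("reads from identical duplicated regions get mapq 0", {
  set.seed(7)
  block <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  pad <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                           collapse = "")
  genome <- c(chr = paste0(pad(500), block, pad(11000), block, pad(500)))
  idx <- build_index(genome, 14)
  read <- substr(block, 100, 132)
  al <- map_read(read, idx)
  expect_equal(al$mapq, 0L)
  expect_equal(bitwAnd(al$flag, 4L), 0L)
})

test_that("junction-spanning reads are unmapped or end-artifact alignments", {
  set.seed(11)
  ex1 <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  ex2 <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  intron <- paste0("GT", paste(sample(c("A", "C", "G", "T"), 96, TRUE),
                               collapse = ""), "AG")
  genome <- c(chr = paste0(ex1, intron, ex2))
  idx <- build_index(genome, 14)
  # read spans the junction: 20 bp of exon1 + 13 bp of exon2
  read <- paste0(substr(ex1, 181, 200), substr(ex2, 1, 13))
  al <- map_read(read, idx)
  unmapped <- bitwAnd(al$flag, 4L) > 0
  if (!unmapped) {
    # must be an artifact: gap or mismatches, not a clean 33M match
    expect_true(grepl("[ID]", al$cigar) || al$nm > 0)
  }
  expect_true(unmapped || grepl("[ID]", al$cigar) || al$nm > 0)
})

test_that("mapq contract: tie 0, sole candidate 60, monotone in margin", {
  expect_equal(compute_mapq(40, 40), 0L)
  expect_equal(compute_mapq(40, NULL), 60L)
  expect_gte(compute_mapq(40, 30), compute_mapq(40, 35))
  expect_gt(compute_mapq(40, 35), 0L)
  expect_error(compute_mapq(30, 40), "best_score")
})

test_that("error-free single-exon reads map to truth at >= 99%", {
  gs <- build_reference(1, 30000, 0.5, seed = 5)
  bg <- build_gene_models(gs, n_genes = 6, exon_count_range = c(1, 1),
                          exon_len_range = c(400, 600), seed = 5)
  gs <- derive_diploid(bg$gs, seed = 5)  # no variants: haploid equivalent
  db <- transcribe(gs, bg$models, "maternal")
  reads <- simulate_reads(db, n_reads = 4000, error_rate = 0,
                          seed = 5)
  idx <- build_index(gs$maternal, 14)
  aln <- map_reads(reads, idx)
  mapped <- bitwAnd(aln$flag, 4L) == 0
  expect_gte(mean(mapped), 0.99)
  expect_gte(mean(aln$cigar[mapped] == "33M"), 0.99)
  # check placement against truth (single-exon transcripts, either strand)
  em <- db$exon_map
  ex_start <- setNames(em$ref_start, em$tx_id)
  ex_end <- setNames(em$ref_end, em$tx_id)
  gstrand <- setNames(em$strand, em$tx_id)
  plus <- gstrand[reads$truth_transcript] == "+"
  want_pos <- ifelse(plus,
                     ex_start[reads$truth_transcript] + reads$truth_offset + 1L,
                     ex_end[reads$truth_transcript] - reads$truth_offset - 33L + 1L)
  ok <- aln$pos[mapped] == want_pos[mapped]
  expect_gte(mean(ok), 0.99)
})
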