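# False-positive cascade: flank extraction, the four checks, ordering and
# the partition invariant.  Mechanism fixtures come from the synthetic
# generator so every check is exercised against planted truth.

run_once <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- small_config(seed = 31, n_reads = 40000, editing = 4)
      cache <<- run_pipeline(cfg)
    }
    cache
  }
})

test_that("flank windows have the stated lengths and edits", {
  set.seed(1)
  g <- c(chr = paste(sample(c("A", "C", "G", "T"), 300, TRUE),
                     collapse = ""))
  cand <- data.frame(contig = "chr", pos = 150L, kind = "insertion",
                     seq = "T", stringsAsFactors = FALSE)
  fl <- extract_flanks(cand, g)
  expect_equal(nchar(fl$genomic_window), 65)
  expect_equal(nchar(fl$edited_window), 66)
  expect_equal(substr(fl$edited_window, 34, 34), "T")
  cand$kind <- "deletion"
  cand$seq <- substr(g[[1]], 152, 152)
  fl2 <- extract_flanks(cand, g)
  expect_equal(nchar(fl2$edited_window), 64)
  # truncation at the contig end is recorded
  cand$pos <- 10L
  fl3 <- extract_flanks(cand, g)
  expect_equal(fl3$up, 10)
  expect_equal(nchar(fl3$genomic_window), 10 + 1 + 32)
})

test_that("cascade labels every planted mechanism correctly on truth", {
  run <- run_once()
  res <- run$classification$results
  expect_gt(nrow(res), 5)
  want <- expected_labels(res, run)
  expect_true(all(!is.na(want)))
  expect_equal(res$label, want)
  counts <- run$classification$counts
  expect_equal(counts[["initial_candidates"]], sum(counts[-1]))
  expect_gt(counts[["paternal_alleles"]], 0)
  expect_gt(counts[["splice_junctions"]], 0)
  expect_gt(counts[["paralog_sequences"]], 0)
  expect_gt(counts[["known_genomic_variations"]], 0)
  expect_equal(counts[["residual"]],
               sum(want == "residual"))
})

test_that("paternal check matches gapless paternal support, both patterns", {
  run <- run_once()
  res <- run$classification$results
  pat <- res[res$label == "paternal_allele", ][1, ]
  chk <- check_paternal_allele(pat, run$alignments, run$gs)
  expect_true(chk$matched)
  expect_match(chk$evidence, "paternal")
  # the mixed pattern holds: non-supporting reads cover the same column
  expect_lt(pat$support_fraction, 1)
  # residual (editing) candidates must NOT match the paternal genome
  resid <- res[res$label == "residual", ][1, ]
  chk2 <- check_paternal_allele(resid, run$alignments, run$gs)
  expect_false(chk2$matched)
})

test_that("splice check requires all three signature criteria", {
  run <- run_once()
  res <- run$classification$results
  params <- run$config$classify
  spl <- res[res$label == "splice_junction", ][1, ]
  fl <- extract_flanks(spl, run$gs$maternal)
  chk <- check_splice_junction(spl, fl, run$db_annot, run$gs, params)
  expect_true(chk$matched)
  # candidate well inside an exon: unedited window fully aligns to the
  # transcript, so the partial-alignment criterion fails
  resid <- res[res$label == "residual", ][1, ]
  fl2 <- extract_flanks(resid, run$gs$maternal)
  chk2 <- check_splice_junction(resid, fl2, run$db_annot, run$gs, params)
  expect_false(chk2$matched)
  # empty junction database: criteria 2-3 vacuously fail
  empty_db <- structure(list(transcripts = character(0),
                             exon_map = data.frame(), editing = data.frame()),
                        class = "JunctionDB")
  expect_false(check_splice_junction(spl, fl, empty_db, run$gs,
                                     params)$matched)
})

test_that("paralog check needs a gapless off-locus match", {
  run <- run_once()
  res <- run$classification$results
  params <- run$config$classify
  par <- res[res$label == "paralog", ][1, ]
  fl <- extract_flanks(par, run$gs$maternal)
  chk <- check_paralog(par, fl, run$gs, params)
  expect_true(chk$matched)
  # the match must be at the planted copy locus
  pp <- run$gs$paralogs
  expect_true(any(vapply(seq_len(nrow(pp)), function(i)
    grepl(sprintf("%s:", pp$copy_contig[i]), chk$evidence), logical(1))))
  # unique-region candidates have no second gapless home
  resid <- res[res$label == "residual", ][1, ]
  fl2 <- extract_flanks(resid, run$gs$maternal)
  expect_false(check_paralog(resid, fl2, run$gs, params)$matched)
})

test_that("known-variant check honours left-alignment equivalence", {
  run <- run_once()
  res <- run$classification$results
  kn <- res[res$label == "known_variant", ][1, ]
  known <- indelrdd:::known_variants_table(run$gs)
  chk <- check_known_variant(kn, known, run$gs)
  expect_true(chk$matched)
  # same indel shifted inside its homopolymer run still matches
  ra <- hap_to_ref(run$gs, "maternal", kn$contig, kn$pos)
  shifted <- known
  hit <- which(shifted$contig == kn$contig & abs(shifted$pos - ra) <= 6)[1]
  rn <- indelrdd:::run_at(run$gs$reference[[kn$contig]], shifted$pos[hit] + 1L)
  if (rn["end"] - rn["start"] > 1) {
    shifted$pos[hit] <- shifted$pos[hit] + 1L
    expect_true(check_known_variant(kn, shifted, run$gs)$matched)
  }
  # a SNP-only database does not match
  snps <- data.frame(contig = kn$contig, pos = ra, kind = "snp", seq = "A",
                     id = "rsX", stringsAsFactors = FALSE)
  expect_false(check_known_variant(kn, snps, run$gs)$matched)
  # different sequence does not match
  other <- known[hit, ]; other$seq <- setdiff(c("A", "C", "G", "T"),
                                              other$seq)[1]
  expect_false(check_known_variant(kn, other, run$gs)$matched)
})

test_that("cascade order resolves multi-mechanism candidates to the earliest", {
  run <- run_once()
  res <- run$classification$results
  spl <- res[res$label == "splice_junction", ][1, ]
  # plant the splice candidate into the known-variant database too: the
  # cascade must still label it splice_junction (order contract)
  ra <- hap_to_ref(run$gs, "maternal", spl$contig, spl$pos)
  known2 <- rbind(indelrdd:::known_variants_table(run$gs),
                  data.frame(contig = spl$contig, pos = ra, kind = spl$kind,
                             seq = spl$seq, id = "planted",
                             stringsAsFactors = FALSE))
  resources <- list(gs = run$gs, alignments = run$alignments,
                    junction_db = run$db_annot, known = known2)
  out <- classify_cascade(spl, resources, run$config$classify)
  expect_equal(out$results$label, "splice_junction")
  # sanity: with the splice database removed it falls through to the DB hit
  resources$junction_db <- structure(
    list(transcripts = character(0), exon_map = data.frame(),
         editing = data.frame()), class = "JunctionDB")
  out2 <- classify_cascade(spl, resources, run$config$classify)
  expect_equal(out2$results$label, "known_variant")
})

test_that("editing placed away from junctions and paralogs stays residual", {
  run <- run_once()
  res <- run$classification$results
  want <- expected_labels(res, run)
  planted <- which(want == "residual")
  expect_gt(length(planted), 0)
  expect_true(all(res$label[planted] == "residual"))
})
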