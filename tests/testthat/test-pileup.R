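# Pileup construction, indel candidate calling, and the initial filters.

make_genome <- function(seq) c(chr = seq)

test_that("pileup columns attach events to anchors and flag duplicates", {
  set.seed(1)
  g <- make_genome(paste(sample(c("A", "C", "G", "T"), 200, TRUE),
                         collapse = ""))
  r33 <- function(pos1) substr(g[[1]], pos1, pos1 + 32)
  aln <- rbind(
    aln_record("r1", "chr", 10, "33M", r33(10)),
    aln_record("r2", "chr", 12, "33M", r33(12)),
    aln_record("r3", "chr", 14, "33M", r33(14)),
    aln_record("r4", "chr", 16, "33M", r33(16)),
    aln_record("r5", "chr", 18, "33M", r33(18)))
  p <- build_pileup(aln, g, at = data.frame(contig = "chr", pos = 30L))
  expect_equal(length(p$columns), 1)
  col <- p$columns[[1]]
  expect_equal(nrow(col$entries), 5)
  expect_false(any(col$entries$is_indel))
  expect_equal(col$ref_base, substr(g[[1]], 31, 31))

  # one read with an insertion: exactly one column carries the event
  ins_read <- paste0(substr(g[[1]], 50, 65), "A", substr(g[[1]], 66, 81))
  aln2 <- sort_alignments(rbind(
    aln_record("a", "chr", 50, "16M1I16M", ins_read),
    aln_record("b", "chr", 50, "33M", r33(50))))
  p2 <- build_pileup(aln2, g)
  stopifnot(length(p2$columns) == 1)
  ev <- p2$columns[[1]]$entries
  expect_equal(sum(ev$is_indel), 1)
  expect_equal(sum(startsWith(ev$event, "+")), 1)

  # duplicates: identical (contig, pos, strand, cigar) flagged after first
  aln3 <- rbind(aln_record("d1", "chr", 60, "33M", r33(60)),
                aln_record("d2", "chr", 60, "33M", r33(60)),
                aln_record("d3", "chr", 60, "33M", r33(60), flag = 16L))
  p3 <- build_pileup(aln3, g, at = data.frame(contig = "chr", pos = 70L))
  e3 <- p3$columns[[1]]$entries
  expect_equal(e3$duplicate_flag[match(c("d1", "d2", "d3"), e3$read_id)],
               c(FALSE, TRUE, FALSE))

  # unsorted input is an explicit error
  bad <- rbind(aln_record("x", "chr", 50, "33M", r33(50)),
               aln_record("y", "chr", 10, "33M", r33(10)))
  expect_error(build_pileup(bad, g), "sorted")
})

test_that("left-alignment normalizes indels into homopolymer runs", {
  g <- make_genome(paste0(strrep("ACGT", 10), "CT", strrep("A", 4), "G",
                          strrep("TGCA", 10)))
  # read deletes one A from the A4 run; aligner may anchor it anywhere
  del_read <- paste0(substr(g[[1]], 23, 43), substr(g[[1]], 45, 56))
  aln <- aln_record("d", "chr", 23, "21M1D12M", del_read)
  p <- build_pileup(aln, g)
  ev <- p$columns[[1]]$entries
  # anchor must be the T before the run (leftmost representation)
  expect_equal(p$columns[[1]]$pos, 41L)
  expect_equal(ev$event[ev$is_indel], "-A")
})

test_that("variant quality is the sum of supporting event qualities", {
  set.seed(2)
  g <- make_genome(paste(sample(c("A", "C", "G", "T"), 200, TRUE),
                         collapse = ""))
  ins_read <- paste0(substr(g[[1]], 50, 65), "A", substr(g[[1]], 66, 81))
  qual <- paste0(strrep(phred_chr(37), 16), phred_chr(37),
                 strrep(phred_chr(37), 16))
  aln <- aln_record("a", "chr", 50, "16M1I16M", ins_read, qual = qual)
  p <- build_pileup(aln, g)
  cand <- call_indels(p, g)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$n_support, 1)
  expect_equal(cand$variant_qual, 37)
  # no indel events -> no candidate
  aln0 <- aln_record("b", "chr", 10, "33M", substr(g[[1]], 10, 42))
  expect_equal(nrow(call_indels(build_pileup(
    aln0, g, at = data.frame(contig = "chr", pos = 20L)), g)), 0)
})

test_that("two insertion alleles at one column give one multiallelic candidate", {
  set.seed(3)
  g <- make_genome(paste(sample(c("A", "C", "G", "T"), 200, TRUE),
                         collapse = ""))
  mk <- function(id, base) {
    aln_record(id, "chr", 50,  "16M1I16M",
               paste0(substr(g[[1]], 50, 65), base, substr(g[[1]], 66, 81)))
  }
  b1 <- substr(g[[1]], 65, 65)
  alts <- setdiff(c("A", "C", "G", "T"), b1)[1:2]
  aln <- rbind(mk("x", alts[1]), mk("y", alts[2]))
  cand <- call_indels(build_pileup(aln, g), g)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$allele_count, 2)
  dec <- apply_site_filters(cand)
  expect_match(dec$failed_rules, "multiallelic")
})

test_that("read-level filters implement the four published rules exactly", {
  entries <- rbind(
    fixture_entry("q19", event = "+A", base_quality = 19),
    fixture_entry("q20", event = "+A", base_quality = 20),
    fixture_entry("m19", event = "+A", mapq = 19),
    fixture_entry("m20", event = "+A", mapq = 20),
    fixture_entry("end2", event = "+A", distance_to_read_end = 2),
    fixture_entry("end3", event = "+A", distance_to_read_end = 3),
    fixture_entry("mm4", event = "+A", n_mismatches = 4),
    fixture_entry("mm3", event = "+A", n_mismatches = 3),
    fixture_entry("plain19", event = "C", base_quality = 19),
    fixture_entry("plain20", event = "C", base_quality = 20))
  entries$distance_to_read_end[is.na(entries$distance_to_read_end) &
                                 entries$is_indel] <- 10L
  col <- fixture_column(entries = entries)
  kept <- apply_read_level_filters(col)$entries$read_id
  expect_setequal(kept, c("q20", "m20", "end3", "mm3", "plain20"))
})

test_that("site filters reproduce every published threshold boundary", {
  base <- data.frame(contig = "c", pos = 50L, kind = "insertion", seq = "A",
                     n_support = 5L, n_total = 20L, support_fraction = 0.25,
                     variant_qual = 100, allele_count = 1L, has_n = FALSE,
                     indel_size = 1L, homopolymer_run = 2L,
                     support_reads = "", stringsAsFactors = FALSE)
  tweak <- function(...) { b <- base; b[names(list(...))] <- list(...); b }
  cases <- list(
    list(cand = tweak(n_support = 1L), fail = "min_support"),
    list(cand = tweak(n_support = 2L), fail = NA),
    list(cand = tweak(n_total = 4L, support_fraction = 5 / 4), fail = "min_coverage"),
    list(cand = tweak(n_total = 5L, support_fraction = 1), fail = NA),
    list(cand = tweak(n_support = 2L, n_total = 50L,
                      support_fraction = 0.04), fail = "min_fraction"),
    list(cand = tweak(n_support = 3L, n_total = 60L,
                      support_fraction = 0.05), fail = NA),
    list(cand = tweak(indel_size = 2L, seq = "AA"), fail = "indel_size"),
    list(cand = tweak(allele_count = 2L), fail = "multiallelic"),
    list(cand = tweak(has_n = TRUE, seq = "N"), fail = "uncertain_base"),
    list(cand = tweak(homopolymer_run = 6L), fail = "homopolymer"),
    list(cand = tweak(homopolymer_run = 5L), fail = NA))
  for (cs in cases) {
    dec <- apply_site_filters(cs$cand)
    if (is.na(cs$fail)) {
      expect_true(dec$passed, info = paste("expected pass"))
    } else {
      expect_false(dec$passed)
      expect_match(dec$failed_rules, cs$fail)
    }
  }
  # failed_rules is complete (no short-circuit) and passed <=> empty
  multi <- tweak(n_support = 1L, n_total = 4L, support_fraction = 0.25,
                 homopolymer_run = 7L)
  dec <- apply_site_filters(multi)
  expect_false(dec$passed)
  for (r in c("min_support", "min_coverage", "homopolymer"))
    expect_match(dec$failed_rules, r)
  # variant-quality interpretations
  lowq <- tweak(variant_qual = 0.005)
  expect_match(apply_site_filters(lowq)$failed_rules, "variant_quality")
  probq <- tweak(variant_qual = 19)
  th <- call_thresholds(variant_quality = 0.01,
                        variant_quality_units = "probability")
  expect_match(apply_site_filters(probq, th)$failed_rules, "variant_quality")
  expect_true(apply_site_filters(tweak(variant_qual = 21), th)$passed)
})

test_that("homopolymer runs follow the insertion/deletion definitions", {
  g <- make_genome("CCCCCTAAAAAAGTTTT")
  # deletion of one A from the A6 run (anchor = T at index 5)
  expect_equal(homopolymer_run(g, "chr", 5L), 6L)
  g2 <- make_genome("GGCTAGGG")
  # insertion of T after the T: run 2 (inserted T + reference T)
  expect_equal(homopolymer_run(g2, "chr", 3L, "T"), 2L)
  # insertion of G between C and T: run 1 (no identical neighbours)
  expect_equal(homopolymer_run(g2, "chr", 2L, "G"), 1L)
  g3 <- make_genome("ACGTACGT")
  expect_equal(homopolymer_run(g3, "chr", 0L, "T"), 1L)
})

test_that("fast-path calling equals the column-by-column path", {
  cfg <- small_config(seed = 21, n_reads = 8000, editing = 3)
  run <- run_pipeline(cfg)
  aln <- run$alignments
  g <- run$gs$maternal
  fast <- call_candidates(aln, g)
  p <- build_pileup(aln, g)
  cols <- lapply(p$columns, apply_read_level_filters)
  slow <- call_indels(structure(list(columns = cols), class = "Pileup"), g)
  slow <- apply_site_filters(slow)
  expect_equal(fast$decisions[order(fast$decisions$contig, fast$decisions$pos),
                              c("contig", "pos", "kind", "seq", "n_support",
                                "n_total", "passed", "failed_rules")],
               slow[order(slow$contig, slow$pos),
                    c("contig", "pos", "kind", "seq", "n_support",
                      "n_total", "passed", "failed_rules")],
               ignore_attr = TRUE)
})

test_that("relaxing any single threshold never reduces passing candidates", {
  cfg <- small_config(seed = 22, n_reads = 12000, editing = 3)
  run <- run_pipeline(cfg)
  base_n <- sum(run$decisions$passed)
  relaxed <- list(
    call_thresholds(min_support = 1),
    call_thresholds(min_coverage = 1),
    call_thresholds(min_fraction = 0),
    call_thresholds(max_alleles = 10),
    call_thresholds(max_indel_size = 10),
    call_thresholds(max_homopolymer = 100))
  for (th in relaxed) {
    n <- sum(apply_site_filters(run$candidates, th)$passed)
    expect_gte(n, base_n)
  }
})

test_that("support fraction bookkeeping is binomial over repeated draws", {
  set.seed(9)
  g <- make_genome(paste(sample(c("A", "C", "G", "T"), 300, TRUE),
                         collapse = ""))
  anchor <- 60L
  x <- setdiff(c("A", "C", "G", "T"),
               c(substr(g[[1]], 61, 61), substr(g[[1]], 62, 62)))[1]
  slots <- expand.grid(start0 = 32:58, minus = c(FALSE, TRUE))
  f <- 0.5
  fr <- vapply(1:40, function(s) {
    set.seed(400 + s)
    pick <- slots[sample.int(nrow(slots), 40), ]
    carry <- runif(40) < f
    recs <- lapply(seq_len(40), function(i) {
      s0 <- pick$start0[i]
      a <- 61L - s0  # M bases before the insertion point
      if (carry[i]) {
        seqv <- paste0(substr(g[[1]], s0 + 1L, s0 + a), x,
                       substr(g[[1]], s0 + a + 1L, s0 + 32L))
        aln_record(sprintf("r%02d", i), "chr", s0 + 1L,
                   sprintf("%dM1I%dM", a, 32L - a), seqv,
                   flag = if (pick$minus[i]) 16L else 0L)
      } else {
        aln_record(sprintf("r%02d", i), "chr", s0 + 1L, "33M",
                   substr(g[[1]], s0 + 1L, s0 + 33L),
                   flag = if (pick$minus[i]) 16L else 0L)
      }
    })
    aln <- sort_alignments(do.call(rbind, recs))
    cand <- call_candidates(aln, g)$candidates
    cand <- cand[cand$pos == anchor, ]
    if (nrow(cand) == 0) return(0)
    cand$n_support / cand$n_total
  }, numeric(1))
  se <- sd(fr) / sqrt(length(fr))
  expect_lt(abs(mean(fr) - f), 3 * se + 0.01)
})
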