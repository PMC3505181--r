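# Pipeline sensitivity: locate maternal/paternal indel differences, rank by
# read coverage, and measure how many the caller recovers before the
# false-positive cascade.

#' Locate single-base indel differences between the haplotypes
#'
#' With `method = "liftover"` the truth variant table is used directly
#' (haplotype-specific indels are exactly the maternal/paternal sequence
#' differences).  With `method = "alignment"` each contig pair is globally
#' aligned (affine gaps) and indels are read off the alignment — feasible
#' for desk-scale contigs and used to cross-check the liftover route.
#'
#' @param gs a diploid `GenomeSet`.
#' @param method `"liftover"` or `"alignment"`.
#' @param scoring scoring for the alignment route.
#' @return data.frame: contig, ref_pos, maternal_pos, paternal_pos, kind
#'   (relative to the haplotype carrying the extra/missing base), seq.
#' @export
locate_haplotype_indels <- function(gs, method = c("liftover", "alignment"),
                                    scoring = scoring_scheme()) {
  method <- match.arg(method)
  if (!identical(sort(names(gs$maternal)), sort(names(gs$paternal))))
    stop("maternal and paternal contig names differ")
  if (method == "liftover") {
    v <- gs$variants
    v <- v[v$kind != "snp" & v$haplotype %in% c("maternal", "paternal"), ,
           drop = FALSE]
    if (nrow(v) == 0) return(empty_hap_sites())
    out <- lapply(seq_len(nrow(v)), function(i) {
      a <- v$ref_pos[i]
      extra_in <- if (v$kind[i] == "insertion") v$haplotype[i]
                  else setdiff(c("maternal", "paternal"), v$haplotype[i])
      data.frame(contig = v$contig[i], ref_pos = a,
                 maternal_pos = ref_to_hap(gs, "maternal", v$contig[i], a),
                 paternal_pos = ref_to_hap(gs, "paternal", v$contig[i], a),
                 kind = v$kind[i], haplotype = v$haplotype[i],
                 extra_in = extra_in,
                 seq = if (v$kind[i] == "insertion")
                   substring(v$alt_allele[i], 2)
                 else substring(v$ref_allele[i], 2),
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, out)
    df[order(df$contig, df$ref_pos), , drop = FALSE]
  } else {
    out <- list()
    for (contig in names(gs$maternal)) {
      m <- gs$maternal[[contig]]; p <- gs$paternal[[contig]]
      al <- sw_affine_cpp(m, p, scoring$match, scoring$mismatch,
                          scoring$gap_open, scoring$gap_extend, TRUE)
      ops <- regmatches(al$cigar, gregexpr("[0-9]+[MID]", al$cigar))[[1]]
      mp <- 0L; pp <- 0L
      for (op in ops) {
        L <- as.integer(sub("[MID]", "", op))
        tp <- substr(op, nchar(op), nchar(op))
        if (tp == "M") { mp <- mp + L; pp <- pp + L }
        else if (tp == "I") {
          # maternal carries extra bases
          out[[length(out) + 1]] <- data.frame(
            contig = contig, ref_pos = NA_integer_,
            maternal_pos = mp - 1L,
            paternal_pos = pp - 1L, kind = "insertion",
            haplotype = "maternal", extra_in = "maternal",
            seq = substr0(m, mp, mp + L), stringsAsFactors = FALSE)
          mp <- mp + L
        } else {
          # paternal carries extra bases
          out[[length(out) + 1]] <- data.frame(
            contig = contig, ref_pos = NA_integer_,
            maternal_pos = mp - 1L, paternal_pos = pp - 1L,
            kind = "insertion", haplotype = "paternal",
            extra_in = "paternal",
            seq = substr0(p, pp, pp + L), stringsAsFactors = FALSE)
          pp <- pp + L
        }
      }
    }
    if (length(out) == 0) return(empty_hap_sites())
    df <- do.call(rbind, out)
    # normalize anchors: shift the extra-base block left against the
    # haplotype that lacks it (insertion-style left alignment)
    for (i in seq_len(nrow(df))) {
      m <- gs$maternal[[df$contig[i]]]
      la <- left_align_indel(m, "insertion", df$maternal_pos[i], df$seq[i])
      df$maternal_pos[i] <- la$anchor
      df$seq[i] <- la$seq
    }
    df[order(df$contig, df$maternal_pos), , drop = FALSE]
  }
}

empty_hap_sites <- function() {
  data.frame(contig = character(), ref_pos = integer(),
             maternal_pos = integer(), paternal_pos = integer(),
             kind = character(), haplotype = character(),
             extra_in = character(), seq = character(),
             stringsAsFactors = FALSE)
}

#' Rank haplotype indel sites by read coverage and select the top set
#'
#' Coverage uses the same read-level filters as calling (mapping quality,
#' base quality at the column).  Sites inside homopolymer runs longer than
#' `max_homopolymer` are excluded; remaining sites are sorted by descending
#' coverage (ties by coordinate) and the top `top_n` with coverage at least
#' `min_coverage` are kept.
#'
#' @param sites output of [locate_haplotype_indels()].
#' @param alignments maternal-genome alignment table.
#' @param genome the maternal genome.
#' @param top_n number of sites kept (default 100).
#' @param min_coverage minimum covering reads (default 5).
#' @param max_homopolymer maximum homopolymer run (default 5).
#' @param rparams read-level filters.
#' @return the selected sites with a `coverage` column.
#' @export
rank_and_select <- function(sites, alignments, genome, top_n = 100,
                            min_coverage = 5, max_homopolymer = 5,
                            rparams = read_filters()) {
  if (nrow(sites) == 0) return(cbind(sites, coverage = integer(0)))
  at <- data.frame(contig = sites$contig, pos = sites$maternal_pos,
                   stringsAsFactors = FALSE)
  ae <- assemble_entries(alignments, genome, at)
  en <- ae$entries
  en <- en[en$base_quality >= rparams$min_base_quality &
             en$mapq >= rparams$min_mapq, , drop = FALSE]
  cov <- tabulate(en$site, nbins = nrow(sites))
  sites$coverage <- cov
  sites$homopolymer_run <- vapply(seq_len(nrow(sites)), function(i)
    homopolymer_run(genome, sites$contig[i], sites$maternal_pos[i],
                    if (sites$extra_in[i] == "paternal") sites$seq[i]
                    else NULL),
    integer(1))
  keep <- sites$homopolymer_run <= max_homopolymer &
    sites$coverage >= min_coverage
  sel <- sites[keep, , drop = FALSE]
  sel <- sel[order(-sel$coverage, sel$contig, sel$maternal_pos), ,
             drop = FALSE]
  head(sel, top_n)
}

#' Fraction of selected haplotype indel sites recovered by the caller
#'
#' A site counts as found when a called candidate (after initial filtering)
#' matches it, on either haplotype's coordinates, within a small
#' normalization tolerance.  Both the maternal-only and the combined
#' maternal+paternal fractions are returned; combined recovery can never be
#' lower.
#'
#' @param selected output of [rank_and_select()].
#' @param candidates_maternal passing candidates from maternal-genome
#'   calling.
#' @param candidates_paternal optional passing candidates from
#'   paternal-genome calling.
#' @param tol anchor matching tolerance in bp.
#' @return list: fraction_maternal, fraction_combined, per-site flags.
#' @export
recovery_fraction <- function(selected, candidates_maternal,
                              candidates_paternal = NULL, tol = 5) {
  n <- nrow(selected)
  if (n == 0) {
    return(list(fraction_maternal = NA_real_, fraction_combined = NA_real_,
                found_maternal = logical(0), found_combined = logical(0)))
  }
  match_sites <- function(pos_col, cands) {
    if (is.null(cands) || nrow(cands) == 0) return(rep(FALSE, n))
    vapply(seq_len(n), function(i) {
      any(cands$contig == selected$contig[i] &
            abs(cands$pos - selected[[pos_col]][i]) <= tol &
            cands$seq == selected$seq[i])
    }, logical(1))
  }
  fm <- match_sites("maternal_pos", candidates_maternal)
  fp <- match_sites("paternal_pos", candidates_paternal)
  fc <- fm | fp
  list(fraction_maternal = mean(fm), fraction_combined = mean(fc),
       found_maternal = fm, found_combined = fc)
}
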