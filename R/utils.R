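# Internal sequence and coordinate helpers.  All internal coordinates are
# 0-based half-open; emitted SAM/VCF/GFF3 are 1-based per their conventions.

BASES <- c("A", "C", "G", "T")

#' Reverse-complement DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  revcomp_cpp(x)
}

random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(BASES, n, replace = TRUE, prob = p), collapse = "")
}

substr0 <- function(x, start, end) {
  # 0-based half-open substring
  substr(x, start + 1L, end)
}

`substr0<-` <- function(x, start, value) {
  substr(x, start + 1L, start + nchar(value)) <- value
  x
}

#' Derive a stage seed from a master seed
#'
#' Stage seeds are a fixed affine function of the master seed so individual
#' pipeline stages can be re-run in isolation and still reproduce the full
#' run.  Kept below 2^31 - 1.
#'
#' @param seed master integer seed.
#' @param stage stage name.
#' @return integer seed.
#' @export
stage_seed <- function(seed, stage) {
  stages <- c(forge = 1L, diploid = 2L, paralogs = 3L, genes = 4L,
              editing = 5L, reads = 6L, align = 7L, call = 8L,
              classify = 9L, sensitivity = 10L)
  off <- stages[[stage]]
  as.integer((as.numeric(seed) * 127L + off * 9973) %% 2147483647)
}

# sample n integers uniformly from [lo, hi] (safe when lo == hi)
sample_range <- function(range, n = 1) {
  lo <- range[1]; hi <- range[2]
  if (lo == hi) rep(as.integer(lo), n)
  else sample(seq.int(lo, hi), n, replace = TRUE)
}

# maximal run of identical bases containing 0-based position pos
run_at <- function(seq, pos) {
  b <- substr0(seq, pos, pos + 1L)
  n <- nchar(seq)
  l <- pos
  while (l > 0 && substr0(seq, l - 1L, l) == b) l <- l - 1L
  r <- pos + 1L
  while (r < n && substr0(seq, r, r + 1L) == b) r <- r + 1L
  c(start = l, end = r)
}

# sample distinct positions at a per-base rate, or a fixed count, within
# intervals (data.frame start/end, 0-based half-open) of one contig
sample_positions <- function(contig_len, rate = NULL, count = NULL,
                             intervals = NULL, margin = 50L) {
  if (is.null(intervals)) {
    intervals <- data.frame(start = margin, end = contig_len - margin)
  }
  intervals <- intervals[intervals$end > intervals$start, , drop = FALSE]
  pool_sizes <- intervals$end - intervals$start
  if (!is.null(count)) {
    if (sum(pool_sizes) < count) stop("not enough eligible positions")
    pool <- unlist(mapply(function(s, e) seq.int(s, e - 1L), intervals$start,
                          intervals$end, SIMPLIFY = FALSE))
    sort(sample(pool, count))
  } else {
    pool <- unlist(mapply(function(s, e) seq.int(s, e - 1L), intervals$start,
                          intervals$end, SIMPLIFY = FALSE))
    keep <- runif(length(pool)) < rate
    sort(pool[keep])
  }
}

# drop positions closer than min_gap to a previous kept position
thin_positions <- function(pos, min_gap = 3L) {
  if (length(pos) < 2) return(pos)
  keep <- c(TRUE, diff(pos) >= min_gap)
  # iterate once more in case consecutive drops re-expose close pairs
  pos <- pos[keep]
  if (length(pos) < 2) return(pos)
  pos[c(TRUE, diff(pos) >= min_gap)]
}
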