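# Independent scoring oracles for local affine-gap alignment.
#
# oracle_local_affine: iterative three-state dynamic program written in R
# directly from the scoring definition (gap of length L costs
# open + L*extend; local alignments may start/end anywhere).
#
# enum_local_affine: exhaustive enumeration of every gapped alignment of
# every substring pair -- exponential, used on tiny strings to validate the
# R oracle itself.

oracle_local_affine <- function(q, t, match = 1, mismatch = 3,
                                gap_open = 5, gap_extend = 2) {
  m <- nchar(q); n <- nchar(t)
  qv <- strsplit(q, "")[[1]]; tv <- strsplit(t, "")[[1]]
  NEG <- -1e9
  M <- matrix(NEG, m + 1, n + 1)
  E <- matrix(NEG, m + 1, n + 1)
  F <- matrix(NEG, m + 1, n + 1)
  M[1, ] <- 0; M[, 1] <- 0
  best <- 0
  for (i in seq_len(m) + 1) {
    for (j in seq_len(n) + 1) {
      s <- if (qv[i - 1] == tv[j - 1]) match else -mismatch
      M[i, j] <- max(0, M[i - 1, j - 1], E[i - 1, j - 1], F[i - 1, j - 1]) + s
      E[i, j] <- max(M[i, j - 1] - gap_open - gap_extend,
                     E[i, j - 1] - gap_extend)
      F[i, j] <- max(M[i - 1, j] - gap_open - gap_extend,
                     F[i - 1, j] - gap_extend)
      if (M[i, j] > best) best <- M[i, j]
    }
  }
  best
}

enum_local_affine <- function(q, t, match = 1, mismatch = 3,
                              gap_open = 5, gap_extend = 2) {
  m <- nchar(q); n <- nchar(t)
  qv <- strsplit(q, "")[[1]]; tv <- strsplit(t, "")[[1]]
  best <- 0
  rec <- function(i, j, iend, jend, score, last) {
    if (i > iend && j > jend) { best <<- max(best, score); return(invisible()) }
    if (i <= iend && j <= jend) {
      s <- if (qv[i] == tv[j]) match else -mismatch
      rec(i + 1, j + 1, iend, jend, score + s, "M")
    }
    if (i <= iend) {
      cost <- if (last == "I") gap_extend else gap_open + gap_extend
      rec(i + 1, j, iend, jend, score - cost, "I")
    }
    if (j <= jend) {
      cost <- if (last == "D") gap_extend else gap_open + gap_extend
      rec(i, j + 1, iend, jend, score - cost, "D")
    }
  }
  for (a in seq_len(m)) for (b in a:m) {
    for (c in seq_len(n)) for (d in c:n) {
      rec(a, c, b, d, 0, "")
    }
  }
  best
}

all_strings <- function(alphabet, max_len) {
  out <- character(0)
  for (L in seq_len(max_len)) {
    g <- do.call(expand.grid, rep(list(alphabet), L))
    out <- c(out, apply(g, 1, paste, collapse = ""))
  }
  out
}
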