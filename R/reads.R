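# Short single-end RNA-seq read simulation with per-molecule editing,
# substitution errors and a two-state Phred quality profile.

#' Default two-state base-quality profile
#'
#' High-quality bases get `q_high`, low-quality ones `q_low`.  A base hit by
#' a sequencing error is assigned the low quality with probability
#' `p_low_on_error` (so error bases are usually, but not always, flagged by
#' their quality); other bases with probability `p_low`.
#'
#' @param q_high,q_low Phred scores of the two states (each between 2 and 41).
#' @param p_low background probability of a low-quality base.
#' @param p_low_on_error probability that an error base is low-quality.
#' @export
quality_profile <- function(q_high = 37, q_low = 10, p_low = 0.02,
                            p_low_on_error = 0.9) {
  stopifnot(q_high >= 2, q_high <= 41, q_low >= 2, q_low <= 41,
            p_low_on_error >= 0.5)
  list(q_high = q_high, q_low = q_low, p_low = p_low,
       p_low_on_error = p_low_on_error)
}

#' Simulate RNA-seq reads from a junction database
#'
#' Each read picks a transcript (probability proportional to
#' `expression_weights`, default transcript length), a molecule (each editing
#' site on the transcript is carried with its `editing_fraction`,
#' independently per molecule), a uniform start within the molecule, and a
#' random strand.  Substitution errors are then drawn per base at
#' `error_rate` and qualities assigned from `profile`.
#'
#' @param db a `JunctionDB` (with `$editing` possibly non-empty).
#' @param expression_weights named numeric vector per transcript or NULL.
#' @param n_reads number of reads.
#' @param read_length read length (default 33; must not exceed the shortest
#'   transcript).
#' @param error_rate per-base substitution error rate between 0 and 0.05.
#' @param profile see [quality_profile()].
#' @param seed integer seed.
#' @return data.frame with read_id, seq, qual, truth_transcript,
#'   truth_offset (0-based molecule offset), truth_strand, truth_haplotype,
#'   n_errors, and edits (semicolon-joined site ids carried AND covered).
#' @export
simulate_reads <- function(db, expression_weights = NULL, n_reads = 10000,
                           read_length = 33, error_rate = 0.01,
                           profile = quality_profile(), seed = 1) {
  txs <- db$transcripts
  if (length(txs) == 0) stop("empty transcript set")
  if (error_rate < 0 || error_rate > 0.05)
    stop("error_rate must lie in [0, 0.05]")
  lens <- nchar(txs)
  if (read_length > min(lens))
    stop("read_length exceeds the shortest transcript")
  set.seed(seed)
  w <- if (is.null(expression_weights)) lens - read_length + 1
       else expression_weights[names(txs)]
  tx_idx <- sample.int(length(txs), n_reads, replace = TRUE, prob = w)

  seqs <- character(n_reads)
  offs <- integer(n_reads)
  edits <- character(n_reads)
  ed <- db$editing
  for (ti in unique(tx_idx)) {
    rows <- which(tx_idx == ti)
    tx_id <- names(txs)[ti]
    sites <- ed[ed$tx_id == tx_id, , drop = FALSE]
    sites <- sites[order(sites$tx_pos), , drop = FALSE]
    k <- nrow(sites)
    if (k == 0) {
      off <- sample.int(lens[ti] - read_length + 1L, length(rows),
                        replace = TRUE) - 1L
      seqs[rows] <- substr(rep(txs[ti], length(rows)), off + 1L,
                           off + read_length)
      offs[rows] <- off
      edits[rows] <- ""
      next
    }
    # per-molecule carry pattern for each read
    carry <- matrix(runif(length(rows) * k) < rep(sites$editing_fraction,
                                                  each = length(rows)),
                    nrow = length(rows))
    pat <- as.integer(carry %*% (2^(seq_len(k) - 1)))
    for (pt in unique(pat)) {
      sel <- rows[pat == pt]
      on <- which(bitwAnd(pt, 2^(seq_len(k) - 1)) > 0)
      mol <- txs[[ti]]
      sh <- 0L
      site_mol_pos <- integer(0)
      for (si in on) {  # ascending tx_pos; shifts accumulate
        p <- sites$tx_pos[si] + sh
        if (sites$kind[si] == "insertion") {
          mol <- paste0(substr(mol, 1, p + 1), sites$base[si],
                        substr(mol, p + 2, nchar(mol)))
          site_mol_pos <- c(site_mol_pos, p + 1L)
          sh <- sh + 1L
        } else {
          mol <- paste0(substr(mol, 1, p + 1), substr(mol, p + 3, nchar(mol)))
          site_mol_pos <- c(site_mol_pos, p)
          sh <- sh - 1L
        }
      }
      mlen <- nchar(mol)
      off <- sample.int(mlen - read_length + 1L, length(sel),
                        replace = TRUE) - 1L
      seqs[sel] <- substr(rep(mol, length(sel)), off + 1L, off + read_length)
      offs[sel] <- off
      if (length(on)) {
        ids <- sites$site_id[on]
        edits[sel] <- vapply(off, function(o) {
          cov <- site_mol_pos >= o & site_mol_pos < o + read_length
          paste(ids[cov], collapse = ";")
        }, character(1))
      } else edits[sel] <- ""
    }
  }

  minus <- runif(n_reads) < 0.5
  seqs[minus] <- revcomp(seqs[minus])
  err <- apply_errors_cpp(seqs, error_rate, profile$q_high, profile$q_low,
                          profile$p_low, profile$p_low_on_error)
  tx_id <- names(txs)[tx_idx]
  hap <- sub("^.*\\|", "", tx_id)
  data.frame(
    read_id = sprintf("read%07d", seq_len(n_reads)),
    seq = err$seq, qual = err$qual,
    truth_transcript = tx_id, truth_offset = offs,
    truth_strand = ifelse(minus, "-", "+"),
    truth_haplotype = hap, n_errors = err$n_errors,
    edits = edits, stringsAsFactors = FALSE)
}
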