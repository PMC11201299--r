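#' Read quality-control thresholds
#'
#' Thresholds for the three discard rules applied to whole-genome reads:
#' a read is discarded when N bases make up more than `max_n_fraction` of
#' its sequence, when more than `max_lowq_fraction` of its bases are below
#' `lowq_cutoff`, or when its mean Phred quality is below
#' `min_mean_quality`. All comparisons are strict, so boundary reads
#' (exactly 10% N, exactly Q20 mean) pass.
#'
#' @param max_n_fraction maximum tolerated N fraction (default 0.10).
#' @param max_lowq_fraction maximum tolerated fraction of bases below the
#'   low-quality cutoff (default 0.40).
#' @param lowq_cutoff Phred score under which a base counts as low-quality
#'   (default 20).
#' @param min_mean_quality minimum mean Phred score (default 20).
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(max_n_fraction = 0.10, max_lowq_fraction = 0.40,
                          lowq_cutoff = 20L, min_mean_quality = 20) {
  stopifnot(max_n_fraction >= 0, max_n_fraction <= 1,
            max_lowq_fraction >= 0, max_lowq_fraction <= 1,
            lowq_cutoff >= 0, min_mean_quality >= 0)
  structure(list(max_n_fraction = max_n_fraction,
                 max_lowq_fraction = max_lowq_fraction,
                 lowq_cutoff = as.integer(lowq_cutoff),
                 min_mean_quality = min_mean_quality),
            class = "qc_thresholds")
}

#' Test a single read against the QC rules
#'
#' Rules are evaluated in a fixed order -- N fraction, low-quality fraction,
#' mean quality -- and the reported reason is the first rule violated.
#' N bases contribute their stored quality score (never negative) to the
#' quality-based rules.
#'
#' @param seq read sequence (may contain N).
#' @param qual per-base qualities: either a Phred+33 string or an integer
#'   vector of Phred scores; must match the sequence length.
#' @param thresholds a [qc_thresholds()].
#' @return list with `pass` (logical) and `reason` (`NA` when passing, else
#'   one of `"n_fraction"`, `"lowq_fraction"`, `"mean_quality"`).
#' @examples
#' read_passes(strrep("A", 100), rep(30L, 100))
#' @export
read_passes <- function(seq, qual, thresholds = qc_thresholds()) {
  if (!nzchar(seq)) stop("empty read")
  q <- if (is.character(qual)) phred_ints(qual) else as.integer(qual)
  if (length(q) != nchar(seq))
    stop("sequence and quality lengths differ")
  if (any(q < 0)) stop("negative Phred scores")
  reason <- qc_reason(seq, q, thresholds)
  list(pass = is.na(reason), reason = reason)
}

# internal: first failing rule for one read, NA if none
qc_reason <- function(seq, q, t) {
  L <- length(q)
  n_frac <- (L - nchar(gsub("N", "", seq, fixed = TRUE))) / L
  if (n_frac > t$max_n_fraction) return("n_fraction")
  if (sum(q < t$lowq_cutoff) / L > t$max_lowq_fraction) return("lowq_fraction")
  if (mean(q) < t$min_mean_quality) return("mean_quality")
  NA_character_
}

#' Filter paired-end reads, keeping mates synchronized
#'
#' The default policy discards the whole pair when either mate fails any
#' rule (conservative for junction calling, where orphan mates carry no
#' pairing information). `"drop_single"` keeps the surviving mate of a
#' broken pair in an `orphans` data.frame. Order of surviving pairs is
#' preserved.
#'
#' @param pairs data.frame `id, seq1, qual1, seq2, qual2` (as produced by
#'   [simulate_paired_reads()] or [read_paired_fastq()]).
#' @param thresholds a [qc_thresholds()].
#' @param policy `"drop_pair"` (default) or `"drop_single"`.
#' @return list with `pairs` (survivors), `orphans` (only for
#'   `"drop_single"`), and `report`: total/kept/dropped pair counts plus
#'   per-rule read-failure counts.
#' @export
qc_filter_pairs <- function(pairs, thresholds = qc_thresholds(),
                            policy = c("drop_pair", "drop_single")) {
  policy <- match.arg(policy)
  stopifnot(all(c("id", "seq1", "qual1", "seq2", "qual2") %in% names(pairs)))
  if (anyDuplicated(pairs$id)) stop("duplicate pair ids")
  n <- nrow(pairs)
  r1 <- qc_reasons_vec(pairs$seq1, pairs$qual1, thresholds)
  r2 <- qc_reasons_vec(pairs$seq2, pairs$qual2, thresholds)
  ok1 <- is.na(r1); ok2 <- is.na(r2)
  keep <- ok1 & ok2
  rule_counts <- table(factor(c(r1, r2),
                              levels = c("n_fraction", "lowq_fraction", "mean_quality")))
  out <- list(pairs = pairs[keep, , drop = FALSE],
              report = list(total_pairs = n,
                            kept_pairs = sum(keep),
                            dropped_pairs = n - sum(keep),
                            reads_failed = as.list(rule_counts),
                            thresholds = unclass(thresholds),
                            policy = policy))
  rownames(out$pairs) <- NULL
  if (policy == "drop_single") {
    orphan1 <- ok1 & !ok2
    orphan2 <- ok2 & !ok1
    out$orphans <- data.frame(
      id = c(pairs$id[orphan1], pairs$id[orphan2]),
      mate = c(rep(1L, sum(orphan1)), rep(2L, sum(orphan2))),
      seq = c(pairs$seq1[orphan1], pairs$seq2[orphan2]),
      qual = c(pairs$qual1[orphan1], pairs$qual2[orphan2]),
      stringsAsFactors = FALSE)
  }
  out
}

# internal: vectorised first-failing-rule over reads with Phred+33 strings
qc_reasons_vec <- function(seqs, quals, t) {
  if (any(!nzchar(seqs))) stop("empty read in stream")
  mapply(function(s, qstr) qc_reason(s, phred_ints(qstr), t),
         seqs, quals, USE.NAMES = FALSE)
}
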