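#' Parameters for the paired-end read simulator
#'
#' Defaults mirror a standard short-insert whole-genome library: 350 bp
#' fragments sequenced as 150 bp paired-end reads, with a low uniform
#' substitution error rate and a linearly decaying Phred quality profile.
#'
#' @param read_length read length in bp.
#' @param fragment_mean,fragment_sd Gaussian fragment-length model, bp.
#' @param coverage requested mean sequence coverage (x).
#' @param error_rate per-base substitution error probability in `[0, 1)`.
#' @param quality_model `"decay"` (linear from `q_start` at cycle 1 to
#'   `q_end` at the last cycle) or `"constant"` (`q_start` everywhere).
#' @param q_start,q_end Phred scores for the quality model.
#' @param seed optional integer seed; identical seeds give byte-identical
#'   reads.
#' @return A `read_sim_params` list.
#' @export
read_sim_params <- function(read_length = 150L, fragment_mean = 350L,
                            fragment_sd = 30L, coverage = 20,
                            error_rate = 0.001,
                            quality_model = c("decay", "constant"),
                            q_start = 38L, q_end = 28L, seed = NULL) {
  quality_model <- match.arg(quality_model)
  stopifnot(read_length >= 1, read_length <= fragment_mean,
            fragment_sd >= 0, coverage > 0,
            error_rate >= 0, error_rate < 1)
  structure(list(read_length = as.integer(read_length),
                 fragment_mean = as.integer(fragment_mean),
                 fragment_sd = as.integer(fragment_sd),
                 coverage = coverage, error_rate = error_rate,
                 quality_model = quality_model,
                 q_start = as.integer(q_start), q_end = as.integer(q_end),
                 seed = seed),
            class = "read_sim_params")
}

#' Simulate paired-end reads from a genome
#'
#' Fragments are drawn uniformly over positions and strands (chromosomes
#' weighted by length); mate 1 is read from the fragment 5' end and mate 2
#' reverse-complemented from the 3' end. Substitution errors are applied
#' independently per base. The truth table records each fragment's origin so
#' downstream results can be checked against ground truth.
#'
#' @param genome a [make_toy_genome()] object (possibly carrying an
#'   insertion).
#' @param params a [read_sim_params()].
#' @return list with
#'   * `pairs`: data.frame `id, seq1, qual1, seq2, qual2` (qualities are
#'     Phred+33 strings),
#'   * `truth`: data.frame `id, chrom, frag_start, frag_end, strand`
#'     (1-based inclusive fragment interval on the forward strand).
#' @export
simulate_paired_reads <- function(genome, params = read_sim_params()) {
  stopifnot(inherits(genome, "toy_genome"), inherits(params, "read_sim_params"))
  chroms <- genome$chromosomes
  lens <- nchar(chroms)
  min_len <- params$fragment_mean + 4L * params$fragment_sd
  if (any(lens < min_len))
    stop("every chromosome must be >= fragment_mean + 4*fragment_sd (",
         min_len, " bp)")
  rl <- params$read_length
  with_seed_or_not(params$seed, {
    n_pairs <- max(1L, round(params$coverage * sum(lens) / (2 * rl)))
    ci <- sample.int(length(chroms), n_pairs, replace = TRUE, prob = lens)
    fl <- pmax(rl, round(rnorm(n_pairs, params$fragment_mean, params$fragment_sd)))
    fl <- pmin(fl, lens[ci])
    fs <- floor(runif(n_pairs) * (lens[ci] - fl + 1)) + 1L
    fe <- fs + fl - 1L
    strand <- ifelse(runif(n_pairs) < 0.5, "+", "-")

    left <- substring(chroms[ci], fs, fs + rl - 1L)
    right <- substring(chroms[ci], fe - rl + 1L, fe)
    # mate 1 = fragment 5' end on the sequenced strand; mate 2 = the 3' end,
    # delivered reverse-complemented (standard FR library geometry)
    fwd <- strand == "+"
    rc_right <- revcomp(right)
    seq1 <- ifelse(fwd, left, rc_right)
    seq2 <- ifelse(fwd, rc_right, left)

    seq1 <- add_seq_errors(seq1, params$error_rate)
    seq2 <- add_seq_errors(seq2, params$error_rate)

    q <- if (params$quality_model == "decay")
      as.integer(round(seq(params$q_start, params$q_end, length.out = rl)))
    else rep(params$q_start, rl)
    qual <- phred_string(q)

    id <- sprintf("frag%06d", seq_len(n_pairs))
    list(pairs = data.frame(id = id, seq1 = seq1, qual1 = qual,
                            seq2 = seq2, qual2 = qual,
                            stringsAsFactors = FALSE),
         truth = data.frame(id = id, chrom = names(chroms)[ci],
                            frag_start = fs, frag_end = fe, strand = strand,
                            stringsAsFactors = FALSE))
  })
}

# internal: apply uniform substitution errors to a character vector of reads
add_seq_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  n_err <- rbinom(length(seqs), nchar(seqs), rate)
  idx <- which(n_err > 0)
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    at <- sample.int(nchar(seqs[i]), n_err[i])
    for (p in at) {
      old <- substr(seqs[i], p, p)
      substr(seqs[i], p, p) <- sample(setdiff(bases, old), 1L)
    }
  }
  seqs
}

#' Write paired reads as two FASTQ files
#'
#' @param pairs the `pairs` data.frame from [simulate_paired_reads()].
#' @param path1,path2 output FASTQ paths for mates 1 and 2.
#' @param mate_suffix `c("/1", "/2")` for classic mate naming, or
#'   `c("", "")` to rely on file separation only.
#' @return invisible `c(path1, path2)`.
#' @export
write_paired_fastq <- function(pairs, path1, path2, mate_suffix = c("/1", "/2")) {
  stopifnot(length(mate_suffix) == 2)
  w <- function(seqs, quals, ids, path) {
    x <- Biostrings::DNAStringSet(setNames(seqs, ids))
    Biostrings::writeXStringSet(x, filepath = path, format = "fastq",
                                qualities = Biostrings::BStringSet(quals))
  }
  w(pairs$seq1, pairs$qual1, paste0(pairs$id, mate_suffix[1]), path1)
  w(pairs$seq2, pairs$qual2, paste0(pairs$id, mate_suffix[2]), path2)
  invisible(c(path1, path2))
}

#' Read two synchronized FASTQ files into a pairs data.frame
#'
#' @param path1,path2 FASTQ files for mates 1 and 2, in matching order.
#' @return data.frame `id, seq1, qual1, seq2, qual2` (any trailing `/1`,
#'   `/2` mate suffix is stripped from ids).
#' @export
read_paired_fastq <- function(path1, path2) {
  rd <- function(path) {
    x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
    list(id = sub("/[12]$", "", sub("\\s.*$", "", names(x))),
         seq = as.character(x),
         qual = as.character(S4Vectors::mcols(x)$qualities))
  }
  a <- rd(path1); b <- rd(path2)
  if (length(a$id) != length(b$id) || any(a$id != b$id))
    stop("mate FASTQ files are not id-synchronized")
  data.frame(id = unname(a$id), seq1 = unname(a$seq), qual1 = unname(a$qual),
             seq2 = unname(b$seq), qual2 = unname(b$qual),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a truth table as tab-separated text
#'
#' @param truth a data.frame (e.g. the `truth` element of
#'   [simulate_paired_reads()] or [insert_transgene()]).
#' @param path output file; a `#`-prefixed header line names the columns.
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(truth, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(truth), collapse = "\t")), con)
  utils::write.table(truth, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
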