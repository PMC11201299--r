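#' Generate a toy multi-chromosome genome
#'
#' Draws i.i.d. bases at a given GC fraction and guarantees that every
#' chromosome contains at least one TTAA tetranucleotide (the PiggyBac
#' target motif) by planting one at a random interior position when none
#' arose by chance. Stands in for a real reference genome so that the
#' downstream aligner and junction caller can be exercised end to end with
#' known truth.
#'
#' @param n_chrom number of chromosomes.
#' @param lengths integer vector of chromosome lengths in bp (recycled to
#'   `n_chrom`); each must be >= 1000.
#' @param gc_fraction genome GC content, strictly between 0 and 1.
#' @param seed optional integer seed; the same seed yields byte-identical
#'   sequences.
#' @return A `toy_genome` object: a list with element `chromosomes`, a named
#'   character vector of uppercase DNA sequences (`chr1`, `chr2`, ...).
#' @examples
#' g <- make_toy_genome(2, c(5000, 8000), seed = 1)
#' nchar(g$chromosomes)
#' @export
make_toy_genome <- function(n_chrom = 1L, lengths = 10000L, gc_fraction = 0.42,
                            seed = NULL) {
  stopifnot(n_chrom >= 1, gc_fraction > 0, gc_fraction < 1)
  lengths <- as.integer(rep_len(lengths, n_chrom))
  if (any(!is.finite(lengths)) || any(lengths < 1000L))
    stop("chromosome lengths must be >= 1000 bp")
  with_seed_or_not(seed, {
    p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
           G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
    chroms <- vapply(lengths, function(L) {
      s <- paste(sample(names(p), L, replace = TRUE, prob = p), collapse = "")
      if (!grepl("TTAA", s, fixed = TRUE)) {
        at <- sample.int(L - 200L, 1L) + 100L   # interior, away from the ends
        substr(s, at, at + 3L) <- "TTAA"
      }
      s
    }, character(1))
    names(chroms) <- paste0("chr", seq_len(n_chrom))
    structure(list(chromosomes = chroms), class = "toy_genome")
  })
}

#' @export
print.toy_genome <- function(x, ...) {
  cat("toy_genome with", length(x$chromosomes), "chromosome(s):\n")
  for (nm in names(x$chromosomes))
    cat(sprintf("  %s  %s bp\n", nm, format(nchar(x$chromosomes[[nm]]), big.mark = ",")))
  invisible(x)
}

#' Define a transgene construct
#'
#' A transposon cargo: an insert flanked by inverted terminal repeats (ITRs),
#' the boundary sequences recognised by the transposase. Coordinates of the
#' ITR intervals are 0-based half-open on the construct sequence.
#'
#' @param name construct name (used as its reference name in alignment).
#' @param sequence DNA string, length >= 100.
#' @param itr_left,itr_right integer length-2 vectors `c(start, end)`,
#'   0-based half-open, within bounds and non-overlapping.
#' @param payload free-text label for the cargo (e.g. `"Ef1a-GFP"`).
#' @return A `transgene_construct` object.
#' @export
transgene_construct <- function(name, sequence, itr_left, itr_right,
                                payload = "") {
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  stopifnot(L >= 100, grepl("^[ACGTN]+$", sequence))
  itr_left <- as.integer(itr_left); itr_right <- as.integer(itr_right)
  ok_iv <- function(iv) length(iv) == 2 && iv[1] >= 0 && iv[2] <= L && iv[1] < iv[2]
  if (!ok_iv(itr_left) || !ok_iv(itr_right))
    stop("ITR intervals must be 0-based half-open and within the sequence")
  if (max(itr_left[1], itr_right[1]) < min(itr_left[2], itr_right[2]))
    stop("ITR intervals must not overlap")
  structure(list(name = name, sequence = sequence, itr_left = itr_left,
                 itr_right = itr_right, payload = payload),
            class = "transgene_construct")
}

#' Example ITR-flanked transgene construct
#'
#' Builds a random construct whose right ITR is the reverse complement of the
#' left ITR (a true inverted repeat), with a random payload in between.
#' Useful as a stand-in for an Ef1a-promoter/GFP cargo in simulations.
#'
#' @param length total construct length in bp (>= 200).
#' @param itr_length length of each ITR in bp.
#' @param seed optional integer seed.
#' @param name,payload labels.
#' @return A [transgene_construct()].
#' @export
example_transgene <- function(length = 2000L, itr_length = 35L, seed = NULL,
                              name = "PB-Ef1a-GFP", payload = "Ef1a-GFP") {
  stopifnot(length >= 200, itr_length >= 10, 2 * itr_length < length)
  with_seed_or_not(seed, {
    itr <- paste(sample(c("A", "C", "G", "T"), itr_length, replace = TRUE), collapse = "")
    mid <- paste(sample(c("A", "C", "G", "T"), length - 2L * itr_length,
                        replace = TRUE), collapse = "")
    seqn <- paste0(itr, mid, revcomp(itr))
    transgene_construct(name, seqn,
                        itr_left = c(0L, itr_length),
                        itr_right = c(length - itr_length, length),
                        payload = payload)
  })
}

#' Write sequences as FASTA
#'
#' @param x a `toy_genome`, `transgene_construct`, or named character vector.
#' @param path output file.
#' @param width line wrap width (default 60 columns).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 60L) {
  seqs <- as_ref_vector(x)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), filepath = path,
                              width = width)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#' @param path FASTA file.
#' @return named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), sub("\\s.*$", "", names(x)))
}

# internal: coerce the various sequence containers to a named character vector
as_ref_vector <- function(x) {
  if (inherits(x, "toy_genome")) return(x$chromosomes)
  if (inherits(x, "transgene_construct")) return(setNames(x$sequence, x$name))
  if (is.character(x)) {
    if (length(x) == 0L) return(x)
    if (is.null(names(x)) || anyNA(names(x)) || any(names(x) == ""))
      stop("character references must be named")
    return(toupper(x))
  }
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as reference sequences")
}
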