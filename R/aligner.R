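# Seeded ungapped aligner with soft-clipping.
#
# Reads are anchored by exact k-mer seeds (k = 45 by default) looked up in a
# hash of both reference strands, then extended without gaps; bases beyond
# the maximal-scoring extension are reported as soft clips. This keeps the
# junction signal of chimeric genome/transgene reads entirely in the clips,
# which is what the integration caller consumes. Substitution errors are
# tolerated by the scoring; indels are out of scope (external aligners can
# substitute via read_sam()).

#' Build an exact k-mer seed index over reference sequences
#'
#' Indexes every k-mer of both strands of every reference; k-mers containing
#' N are skipped. Duplicate k-mers keep all their positions.
#'
#' @param references a `toy_genome`, `transgene_construct`, or named
#'   character vector of sequences (multiple inputs can be combined with
#'   `c(as_references(...))`, see [as_references()]).
#' @param k seed length in bp (default 45, the minimum seed used for
#'   whole-genome mapping of this kind of data); must be >= 11 and no longer
#'   than the shortest reference.
#' @return A `seed_index` object (k, lookup table, reference sequences).
#' @export
build_index <- function(references, k = 45L) {
  refs <- as_ref_vector(references)
  k <- as.integer(k)
  if (k < 11L) stop("seed length k must be >= 11")
  if (k > min(nchar(refs)))
    stop("seed length k exceeds the shortest reference (",
         min(nchar(refs)), " bp)")
  tabs <- lapply(names(refs), function(nm) {
    s <- refs[[nm]]
    L <- nchar(s)
    n <- L - k + 1L
    fwd <- substring(s, seq_len(n), seq_len(n) + k - 1L)
    rcs <- revcomp(s)
    # rc of the fwd k-mer at i is the k-mer at L-k+2-i of the rc sequence
    rev <- substring(rcs, seq_len(n), seq_len(n) + k - 1L)
    dt <- data.table::data.table(
      kmer = c(fwd, rev),
      ref = nm,
      pos = c(seq_len(n), (L - k + 2L) - seq_len(n)),
      strand = rep(c("+", "-"), each = n))
    dt[!grepl("N", dt$kmer, fixed = TRUE)]
  })
  dt <- data.table::rbindlist(tabs)
  data.table::setkey(dt, kmer)
  structure(list(k = k, table = dt, refs = refs), class = "seed_index")
}

#' @export
print.seed_index <- function(x, ...) {
  cat(sprintf("seed_index: k=%d, %d reference(s), %s entries\n",
              x$k, length(x$refs), format(nrow(x$table), big.mark = ",")))
  invisible(x)
}

#' Coerce sequence containers to a named reference vector
#'
#' Convenience for combining a genome and a transgene into one reference set:
#' `c(as_references(genome), as_references(construct))`.
#' @param x a `toy_genome`, `transgene_construct`, or named character vector.
#' @return named character vector of sequences.
#' @export
as_references <- function(x) as_ref_vector(x)

#' Alignment scoring and clipping parameters
#'
#' @param match,mismatch per-base scores (match >= 1, mismatch <= -1).
#' @param min_score minimum alignment score to report a mapping (default 40,
#'   about 40 matching bases).
#' @param xdrop extension stops once the running score falls more than this
#'   many units below its running maximum; the alignment ends at the maximum.
#' @return An `align_scoring` list.
#' @export
align_scoring <- function(match = 1L, mismatch = -2L, min_score = 40L,
                          xdrop = 20L) {
  stopifnot(match >= 1, mismatch <= -1, min_score > 0, xdrop > 0)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 min_score = as.integer(min_score), xdrop = as.integer(xdrop)),
            class = "align_scoring")
}

#' Align reads against a seed index
#'
#' For each read, exact seeds are taken at the start, middle and end of the
#' read and looked up on both strands; each candidate diagonal is extended
#' without gaps around the seed, and the maximal-scoring segment containing
#' the seed is reported, with the remainder of the read soft-clipped. The
#' best-scoring candidate wins; ties break deterministically by reference
#' name, then position, then forward strand first. Reads with no seed hit or
#' best score below `min_score` are returned unmapped.
#'
#' @param reads data.frame with columns `id`, `seq` and optionally `qual`
#'   (Phred+33 string) and `mate` (1/2).
#' @param index a [build_index()] object.
#' @param scoring an [align_scoring()].
#' @return data.frame of alignment records: `qname, mate, mapped, rname,
#'   pos, strand, cigar, score, nm, seq, qual`. `seq`/`qual` are stored in
#'   aligned orientation (reverse-complemented for minus-strand hits), as in
#'   SAM. `nm` counts mismatches within the matched segment.
#' @export
align_reads <- function(reads, index, scoring = align_scoring()) {
  stopifnot(inherits(index, "seed_index"),
            all(c("id", "seq") %in% names(reads)))
  n <- nrow(reads)
  out <- data.frame(qname = reads$id,
                    mate = if ("mate" %in% names(reads)) reads$mate else NA_integer_,
                    mapped = logical(n), rname = NA_character_,
                    pos = NA_integer_, strand = NA_character_,
                    cigar = NA_character_, score = NA_integer_,
                    nm = NA_integer_,
                    seq = reads$seq,
                    qual = if ("qual" %in% names(reads)) reads$qual else NA_character_,
                    stringsAsFactors = FALSE)
  if (n == 0L) return(out)
  k <- index$k
  qlen <- nchar(reads$seq)
  if (any(qlen < k))
    stop("all reads must be at least as long as the seed length k = ", k)

  # seed offsets (0-based within the read): start, middle, end
  offs <- cbind(0L, pmax(0L, (qlen - k) %/% 2L), qlen - k)
  seed_dt <- data.table::data.table(
    qidx = rep(seq_len(n), 3L),
    off = as.integer(offs),
    kmer = substring(rep(reads$seq, 3L), as.integer(offs) + 1L,
                     as.integer(offs) + k))
  seed_dt <- unique(seed_dt, by = c("qidx", "off"))
  hits <- index$table[seed_dt, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  if (nrow(hits) == 0L) return(out)

  # map each hit to a candidate (query orientation, diagonal)
  hit_qlen <- qlen[hits$qidx]
  hits$off_eff <- ifelse(hits$strand == "+", hits$off, hit_qlen - k - hits$off)
  hits$qstart_ref <- hits$pos - hits$off_eff
  hits$qlen <- hit_qlen
  cand <- unique(hits[, c("qidx", "ref", "strand", "qstart_ref", "off_eff", "qlen")],
                 by = c("qidx", "ref", "strand", "qstart_ref"))

  # query sequence in candidate orientation
  need_rc <- any(cand$strand == "-")
  rcseq <- if (need_rc) revcomp(reads$seq) else character(0)
  cand$query <- ifelse(cand$strand == "+", reads$seq[cand$qidx], rcseq[cand$qidx])

  reflen <- nchar(index$refs)
  cand$rlen <- reflen[cand$ref]

  # fast path: fully contained, exact full-length match
  contained <- cand$qstart_ref >= 1L & cand$qstart_ref + cand$qlen - 1L <= cand$rlen
  win <- rep(NA_character_, nrow(cand))
  if (any(contained)) {
    idx <- which(contained)
    win[idx] <- substring(index$refs[cand$ref[idx]], cand$qstart_ref[idx],
                          cand$qstart_ref[idx] + cand$qlen[idx] - 1L)
  }
  perfect <- contained & !is.na(win) & win == cand$query
  m <- scoring$match
  cand$a_pos <- NA_integer_
  cand$a_score <- NA_integer_
  cand$a_cigar <- NA_character_
  cand$a_nm <- NA_integer_
  if (any(perfect)) {
    idx <- which(perfect)
    data.table::set(cand, idx, "a_pos", cand$qstart_ref[idx])
    data.table::set(cand, idx, "a_score", m * cand$qlen[idx])
    data.table::set(cand, idx, "a_cigar", paste0(cand$qlen[idx], "M"))
    data.table::set(cand, idx, "a_nm", 0L)
  }
  slow <- which(!perfect)
  for (i in slow) {
    e <- extend_seed(cand$query[i], index$refs[[cand$ref[i]]],
                     cand$qstart_ref[i], cand$off_eff[i], k, scoring)
    data.table::set(cand, i, "a_pos", e$pos)
    data.table::set(cand, i, "a_score", e$score)
    data.table::set(cand, i, "a_cigar", e$cigar)
    data.table::set(cand, i, "a_nm", e$nm)
  }

  # best candidate per read; deterministic tie-break
  data.table::setorder(cand, qidx, -a_score, ref, a_pos, strand)
  best <- cand[!duplicated(cand$qidx)]
  best <- best[best$a_score >= scoring$min_score]
  if (nrow(best) == 0L) return(out)

  bi <- best$qidx
  out$mapped[bi] <- TRUE
  out$rname[bi] <- best$ref
  out$pos[bi] <- best$a_pos
  out$strand[bi] <- best$strand
  out$cigar[bi] <- best$a_cigar
  out$score[bi] <- best$a_score
  out$nm[bi] <- best$a_nm
  minus <- bi[best$strand == "-"]
  if (length(minus)) {
    out$seq[minus] <- revcomp(out$seq[minus])
    if (!all(is.na(out$qual[minus]))) out$qual[minus] <- str_rev(out$qual[minus])
  }
  out
}

#' Align a single read
#'
#' Convenience wrapper around [align_reads()] for one sequence.
#' @param seq read sequence.
#' @param index a [build_index()] object.
#' @param scoring an [align_scoring()].
#' @param id read id.
#' @return one-row alignment record data.frame (see [align_reads()]).
#' @export
align_read <- function(seq, index, scoring = align_scoring(), id = "read1") {
  align_reads(data.frame(id = id, seq = seq, stringsAsFactors = FALSE),
              index, scoring)
}

# internal: ungapped X-drop extension around an exact seed.
# query is in reference orientation; qstart_ref is the reference position of
# query base 1 (may fall outside the reference; such bases are clipped);
# off is the 0-based seed offset within the query.
extend_seed <- function(query, refseq, qstart_ref, off, k, scoring) {
  qlen <- nchar(query)
  L <- nchar(refseq)
  lo <- max(1L, qstart_ref)                  # reference window
  hi <- min(L, qstart_ref + qlen - 1L)
  q_lo <- lo - qstart_ref + 1L               # query indices inside the reference
  q_hi <- hi - qstart_ref + 1L
  qi <- utf8ToInt(query)
  wi <- utf8ToInt(substr(refseq, lo, hi))
  mvec <- rep(FALSE, qlen)
  mvec[q_lo:q_hi] <- qi[q_lo:q_hi] == wi
  s <- ifelse(mvec, scoring$match, scoring$mismatch)

  seed_a <- off + 1L
  seed_b <- off + k
  best_dir <- function(sc) {
    # maximal prefix score with X-drop early stop; 0 if nothing positive
    if (!length(sc)) return(0L)
    cs <- cumsum(sc)
    drop <- cummax(cs) - cs > scoring$xdrop
    if (any(drop)) cs <- cs[seq_len(which(drop)[1] - 1L)]
    if (!length(cs) || max(cs) <= 0L) 0L else which.max(cs)
  }
  # right of the seed, bounded by the reference edge
  r_ext <- if (seed_b < q_hi) best_dir(s[(seed_b + 1L):q_hi]) else 0L
  l_ext <- if (seed_a > q_lo) best_dir(rev(s[q_lo:(seed_a - 1L)])) else 0L
  qa <- seed_a - l_ext
  qb <- seed_b + r_ext
  sc_total <- sum(s[qa:qb])
  lead <- qa - 1L
  trail <- qlen - qb
  cigar <- paste0(if (lead) paste0(lead, "S") else "",
                  qb - qa + 1L, "M",
                  if (trail) paste0(trail, "S") else "")
  list(pos = qstart_ref + qa - 1L, score = sc_total, cigar = cigar,
       nm = sum(!mvec[qa:qb]))
}

# internal: parse a CIGAR with M/=/X/S/H/D/I/N ops into summary lengths
cigar_summary <- function(cigar) {
  ops <- gregexpr("\\d+[MIDNSHP=X]", cigar)
  lapply(regmatches(cigar, ops), function(toks) {
    len <- as.integer(sub("[A-Z=]", "", toks))
    op <- sub("\\d+", "", toks)
    op[op %in% c("=", "X")] <- "M"
    lead_s <- if (length(op) && op[1] == "S") len[1] else 0L
    trail_s <- if (length(op) > 1 && op[length(op)] == "S") len[length(op)] else 0L
    list(lead_s = lead_s, trail_s = trail_s,
         ref_span = sum(len[op %in% c("M", "D", "N")]),
         read_len = sum(len[op %in% c("M", "I", "S")]))
  })
}

# internal: unclipped 5'-most position of a record (used as the duplicate key)
unclipped_pos5 <- function(pos, strand, cigar) {
  cs <- cigar_summary(cigar)
  lead <- vapply(cs, `[[`, integer(1), "lead_s")
  trail <- vapply(cs, `[[`, integer(1), "trail_s")
  span <- vapply(cs, `[[`, integer(1), "ref_span")
  ifelse(strand == "+", pos - lead, pos + span - 1L + trail)
}

#' Remove PCR/optical duplicates by coordinate
#'
#' Pairs whose two mates share both (reference, unclipped 5' position,
#' strand) keys are collapsed to the representative with the highest summed
#' base quality (ties by read id); records whose mate is unmapped or absent
#' are deduplicated by their own coordinates. Unmapped records pass through
#' untouched. Idempotent.
#'
#' @param records alignment records from [align_reads()] (both mates of each
#'   pair identified by a shared `qname`).
#' @return the surviving records, original order preserved.
#' @export
remove_duplicates <- function(records) {
  if (nrow(records) == 0L) return(records)
  mp <- records[records$mapped, , drop = FALSE]
  if (nrow(mp) == 0L) return(records)
  key1 <- paste(mp$rname, unclipped_pos5(mp$pos, mp$strand, mp$cigar),
                mp$strand, sep = ":")
  qsum <- vapply(seq_len(nrow(mp)), function(i) {
    if (is.na(mp$qual[i])) 0 else sum(phred_ints(mp$qual[i]))
  }, numeric(1))
  d <- data.frame(qname = mp$qname, key1 = key1, qsum = qsum,
                  stringsAsFactors = FALSE)
  # per read (pair), combine both mates' keys order-independently
  agg <- stats::aggregate(cbind(q = d$qsum) ~ qname, data = d, FUN = sum)
  keys <- vapply(split(d$key1, d$qname), function(ks)
    paste(sort(ks), collapse = "|"), character(1))
  agg$key <- keys[agg$qname]
  agg <- agg[order(-agg$q, agg$qname), ]
  keep_qnames <- agg$qname[!duplicated(agg$key)]
  dropped <- setdiff(unique(mp$qname), keep_qnames)
  records[!(records$qname %in% dropped), , drop = FALSE]
}

#' Write alignment records as SAM text
#'
#' Emits a minimal valid SAM: `@HD`/`@SQ` header and one line per record,
#' soft clips as `S` operations, FLAG bits for strand (0x10), unmapped (0x4)
#' and mate number (0x1|0x40/0x80 when `mate` is present).
#'
#' @param records alignment records from [align_reads()].
#' @param references the reference set the records were aligned to (for
#'   `@SQ` lines).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sam <- function(records, references, path) {
  refs <- as_ref_vector(references)
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(refs), nchar(refs)))
  flag <- ifelse(records$mapped, 0L, 4L) +
    ifelse(!is.na(records$strand) & records$strand == "-", 16L, 0L)
  if (!all(is.na(records$mate)))
    flag <- flag + 1L + ifelse(records$mate == 1L, 64L, 128L)
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                   records$qname, flag,
                   ifelse(records$mapped, records$rname, "*"),
                   ifelse(records$mapped, records$pos, 0L),
                   ifelse(records$mapped, 60L, 0L),
                   ifelse(records$mapped, records$cigar, "*"),
                   records$seq,
                   ifelse(is.na(records$qual), "*", records$qual))
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read a SAM text file into alignment records
#'
#' Accepts output of any aligner provided soft clips and sequences are
#' present; secondary/supplementary records (FLAG 0x100/0x800) are skipped
#' so each read contributes one record.
#'
#' @param path SAM file.
#' @return alignment-records data.frame compatible with the junction caller
#'   (`qname, mate, mapped, rname, pos, strand, cigar, seq, qual`).
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines))
    return(data.frame(qname = character(0), mate = integer(0),
                      mapped = logical(0), rname = character(0),
                      pos = integer(0), strand = character(0),
                      cigar = character(0), seq = character(0),
                      qual = character(0), stringsAsFactors = FALSE))
  f <- strsplit(lines, "\t", fixed = TRUE)
  flag <- vapply(f, function(x) as.integer(x[2]), integer(1))
  keep <- bitwAnd(flag, 0x100L) == 0L & bitwAnd(flag, 0x800L) == 0L
  f <- f[keep]; flag <- flag[keep]
  mate <- ifelse(bitwAnd(flag, 0x1L) == 0L, NA_integer_,
                 ifelse(bitwAnd(flag, 0x40L) != 0L, 1L, 2L))
  data.frame(
    qname = vapply(f, `[`, character(1), 1),
    mate = mate,
    mapped = bitwAnd(flag, 0x4L) == 0L,
    rname = vapply(f, `[`, character(1), 3),
    pos = vapply(f, function(x) as.integer(x[4]), integer(1)),
    strand = ifelse(bitwAnd(flag, 0x10L) != 0L, "-", "+"),
    cigar = vapply(f, `[`, character(1), 6),
    seq = vapply(f, `[`, character(1), 10),
    qual = vapply(f, `[`, character(1), 11),
    stringsAsFactors = FALSE)
}
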