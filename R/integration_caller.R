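# Junction discovery from soft-clipped reads.
#
# A read that straddles a genome/transgene boundary aligns partly, and the
# aligner soft-clips the remainder. Re-aligning each clip against the other
# sequence links a genome breakpoint to a transgene end; clustered links on
# the two sides of the insertion are paired into an integration call, the
# target-site duplication (TSD) is read off the genome, and the call is
# confirmed by clip-free read alignment on a hybrid reference.

#' Configuration for the integration caller
#'
#' @param min_clip_len minimum soft-clip length (bp) to use as junction
#'   evidence.
#' @param min_identity minimum percent identity for a clip re-alignment hit.
#' @param min_hit_len minimum aligned length (bp) of a clip hit.
#' @param cluster_tol breakpoints within this many bp merge into one
#'   junction cluster.
#' @param end_tol a clip hit must reach within this many bp of a transgene
#'   terminus to count as a junction (interior hits are discarded).
#' @param min_support minimum supporting reads per junction for a PASS call.
#' @param tsd_motif expected target-site duplication motif (TTAA for
#'   PiggyBac). Its absence downgrades confidence but does not veto a call.
#' @param flank genome flank length (bp) on each side of the hybrid
#'   reference; must be at least the read length.
#' @param min_span a validating read must cover at least this many bases on
#'   each side of a hybrid junction, without clips.
#' @param k seed length for alignment.
#' @param scoring an [align_scoring()].
#' @param qc a [qc_thresholds()] applied before alignment (or `NULL` to
#'   skip filtering).
#' @return A `caller_config` list.
#' @export
caller_config <- function(min_clip_len = 20L, min_identity = 95,
                          min_hit_len = 20L, cluster_tol = 5L, end_tol = 10L,
                          min_support = 3L, tsd_motif = "TTAA", flank = 500L,
                          min_span = 20L, k = 45L, scoring = align_scoring(),
                          qc = qc_thresholds()) {
  structure(list(min_clip_len = as.integer(min_clip_len),
                 min_identity = min_identity,
                 min_hit_len = as.integer(min_hit_len),
                 cluster_tol = as.integer(cluster_tol),
                 end_tol = as.integer(end_tol),
                 min_support = as.integer(min_support),
                 tsd_motif = toupper(tsd_motif),
                 flank = as.integer(flank),
                 min_span = as.integer(min_span),
                 k = as.integer(k), scoring = scoring, qc = qc),
            class = "caller_config")
}

#' Extract soft-clip evidence from alignment records
#'
#' One evidence item per clip of at least `min_clip_len` bases; a read
#' clipped on both sides yields two items. The anchor position is the
#' aligned reference base adjacent to the clip (the first aligned base for
#' left clips, the last for right clips).
#'
#' @param records deduplicated alignment records ([align_reads()] or
#'   [read_sam()]).
#' @param min_clip_len minimum clip length in bp.
#' @return data.frame `eid, qname, ref, anchor_pos, side, clip_seq, strand`.
#' @export
extract_softclipped <- function(records, min_clip_len = 20L) {
  empty <- data.frame(eid = character(0), qname = character(0),
                      ref = character(0), anchor_pos = integer(0),
                      side = character(0), clip_seq = character(0),
                      strand = character(0), stringsAsFactors = FALSE)
  mp <- records[records$mapped, , drop = FALSE]
  if (nrow(mp) == 0L) return(empty)
  if (any(is.na(mp$seq) | mp$seq == "*"))
    stop("alignment records lack sequence data")
  cs <- cigar_summary(mp$cigar)
  lead <- vapply(cs, `[[`, integer(1), "lead_s")
  trail <- vapply(cs, `[[`, integer(1), "trail_s")
  span <- vapply(cs, `[[`, integer(1), "ref_span")
  rl <- vapply(cs, `[[`, integer(1), "read_len")
  li <- which(lead >= min_clip_len)
  ri <- which(trail >= min_clip_len)
  ev <- rbind(
    data.frame(qname = mp$qname[li], ref = mp$rname[li],
               anchor_pos = mp$pos[li], side = rep("left", length(li)),
               clip_seq = substr(mp$seq[li], 1L, lead[li]),
               strand = mp$strand[li], stringsAsFactors = FALSE),
    data.frame(qname = mp$qname[ri], ref = mp$rname[ri],
               anchor_pos = mp$pos[ri] + span[ri] - 1L,
               side = rep("right", length(ri)),
               clip_seq = substr(mp$seq[ri], rl[ri] - trail[ri] + 1L, rl[ri]),
               strand = mp$strand[ri], stringsAsFactors = FALSE))
  if (nrow(ev) == 0L) return(empty)
  ev <- cbind(data.frame(eid = sprintf("ev%05d", seq_len(nrow(ev))),
                         stringsAsFactors = FALSE), ev)
  rownames(ev) <- NULL
  ev
}

#' Re-align clipped sequences against target references
#'
#' Affine-gap local (Smith-Waterman) alignment of each clip against every
#' target on both strands; the best hit per clip is kept if it reaches
#' `min_identity` percent identity over at least `min_len` aligned bases.
#' Ties break by target name, then position, then forward strand.
#'
#' @param evidence output of [extract_softclipped()].
#' @param targets named character vector of target sequences (typically the
#'   genome chromosomes plus the transgene).
#' @param min_identity minimum percent identity (default 95).
#' @param min_len minimum aligned length in bp (default 20).
#' @return data.frame `eid, target, t_start, t_end, t_strand, identity,
#'   score, aln_len` (1-based inclusive target interval).
#' @export
realign_clips <- function(evidence, targets, min_identity = 95, min_len = 20L) {
  targets <- as_ref_vector(targets)
  if (length(targets) == 0L) stop("empty target set")
  empty <- data.frame(eid = character(0), target = character(0),
                      t_start = integer(0), t_end = integer(0),
                      t_strand = character(0), identity = numeric(0),
                      score = numeric(0), aln_len = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(evidence) == 0L) return(empty)
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                     baseOnly = FALSE)
  clips <- Biostrings::DNAStringSet(setNames(evidence$clip_seq, evidence$eid))
  rc_clips <- Biostrings::reverseComplement(clips)
  res <- list()
  for (nm in names(targets)) {
    subj <- Biostrings::DNAString(targets[[nm]])
    for (st in c("+", "-")) {
      pats <- if (st == "+") clips else rc_clips
      aln <- Biostrings::pairwiseAlignment(pats, subj, type = "local",
                                           substitutionMatrix = submat,
                                           gapOpening = 5, gapExtension = 2)
      sub_rng <- Biostrings::subject(aln)
      res[[paste(nm, st)]] <- data.frame(
        eid = evidence$eid,
        target = nm,
        t_start = BiocGenerics::start(sub_rng),
        t_end = BiocGenerics::end(sub_rng),
        t_strand = st,
        identity = Biostrings::pid(aln),
        score = Biostrings::score(aln),
        aln_len = Biostrings::nchar(aln),
        stringsAsFactors = FALSE)
    }
  }
  hits <- do.call(rbind, res)
  hits <- hits[hits$identity >= min_identity & hits$aln_len >= min_len, ,
               drop = FALSE]
  if (nrow(hits) == 0L) return(empty)
  hits <- hits[order(hits$eid, -hits$score, hits$target, hits$t_start,
                     hits$t_strand), , drop = FALSE]
  hits <- hits[!duplicated(hits$eid), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

# internal: classify evidence/hit pairs into genome breakpoints.
# Returns one row per informative pair: chrom, bp, genome_side (which side of
# the insertion the genome flank is on), tg_end (transgene terminus joined),
# orientation, plus provenance. Interior transgene hits are dropped.
classify_junction_links <- function(hits, evidence, tg_name, tg_len, end_tol) {
  m <- merge(hits, evidence, by = "eid")
  if (nrow(m) == 0L) return(m[0, ])
  rows <- list()
  for (i in seq_len(nrow(m))) {
    r <- m[i, ]
    if (r$ref != tg_name && r$target == tg_name) {
      # genome-anchored read, clip matches the transgene
      chrom <- r$ref
      bp <- r$anchor_pos
      genome_side <- if (r$side == "right") "left" else "right"
      # transgene base adjacent to the junction = clip end nearest the anchor
      jpos <- if ((r$side == "right") == (r$t_strand == "+")) r$t_start else r$t_end
      h <- r$t_strand
    } else if (r$ref == tg_name && r$target != tg_name) {
      # transgene-anchored read, clip matches the genome
      chrom <- r$target
      genome_side <- if ((r$side == "left") == (r$t_strand == "+")) "left" else "right"
      bp <- if (genome_side == "left") r$t_end else r$t_start
      jpos <- r$anchor_pos
      h <- r$t_strand
    } else next
    tg_end <- if (jpos <= end_tol) "5p"
              else if (jpos >= tg_len - end_tol + 1L) "3p"
              else next
    orientation <- if (h == "+" && (genome_side == "left") == (tg_end == "5p"))
      "forward"
    else if (h == "-" && (genome_side == "left") == (tg_end == "3p"))
      "reverse"
    else NA_character_
    rows[[length(rows) + 1L]] <- data.frame(
      eid = r$eid, qname = r$qname, chrom = chrom, bp = as.integer(bp),
      genome_side = genome_side, tg_end = tg_end, orientation = orientation,
      clip_seq = r$clip_seq, anchored_on = r$ref, stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(m[0, ])
  do.call(rbind, rows)
}

#' Cluster junction evidence into breakpoint clusters
#'
#' Links between genome breakpoints and transgene ends (from
#' [realign_clips()] hits) are grouped by chromosome and by which side of
#' the insertion the genome flank is on; breakpoints within `tolerance` bp
#' merge. Each cluster reports its modal breakpoint (ties to the smallest),
#' spread, distinct-read support, majority orientation, and a per-column
#' majority consensus of the transgene-derived clips.
#'
#' @param hits output of [realign_clips()].
#' @param evidence output of [extract_softclipped()].
#' @param transgene the transgene as a [transgene_construct()] or named
#'   character vector of length 1.
#' @param tolerance clustering tolerance in bp (default 5).
#' @param end_tol see [caller_config()].
#' @return data.frame `chrom, genome_side, bp, spread, support, tg_end,
#'   orientation, n_forward, n_reverse, consensus_clip`.
#' @export
cluster_junctions <- function(hits, evidence, transgene, tolerance = 5L,
                              end_tol = 10L) {
  tg <- as_ref_vector(transgene)
  stopifnot(length(tg) == 1L)
  tg_name <- names(tg)
  tg_len <- nchar(tg[[1]])
  empty <- data.frame(chrom = character(0), genome_side = character(0),
                      bp = integer(0), spread = integer(0),
                      support = integer(0), tg_end = character(0),
                      orientation = character(0), n_forward = integer(0),
                      n_reverse = integer(0), consensus_clip = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(hits) == 0L || nrow(evidence) == 0L) return(empty)
  links <- classify_junction_links(hits, evidence, tg_name, tg_len, end_tol)
  if (nrow(links) == 0L) return(empty)
  out <- list()
  for (key in unique(paste(links$chrom, links$genome_side))) {
    g <- links[paste(links$chrom, links$genome_side) == key, , drop = FALSE]
    g <- g[order(g$bp), , drop = FALSE]
    grp <- cumsum(c(1L, diff(g$bp) > tolerance))
    for (cl in split(g, grp)) {
      tab <- table(cl$bp)
      modal <- as.integer(names(tab)[which.max(tab)])  # ties -> smallest
      nf <- sum(cl$orientation == "forward", na.rm = TRUE)
      nr <- sum(cl$orientation == "reverse", na.rm = TRUE)
      ori <- if (nf > nr) "forward" else if (nr > nf) "reverse" else NA_character_
      tge <- names(sort(table(cl$tg_end), decreasing = TRUE))[1]
      cons <- consensus_clip(cl$clip_seq[cl$anchored_on != tg_name],
                             align_end = if (cl$genome_side[1] == "left") "left" else "right")
      out[[length(out) + 1L]] <- data.frame(
        chrom = cl$chrom[1], genome_side = cl$genome_side[1], bp = modal,
        spread = max(cl$bp) - min(cl$bp),
        support = length(unique(cl$qname)),
        tg_end = tge, orientation = ori, n_forward = nf, n_reverse = nr,
        consensus_clip = cons, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(-res$support, res$chrom, res$bp), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# internal: per-column majority consensus of clips aligned at one end.
# align_end "left": clips share their left end (clips extending rightwards
# from the junction); "right": share their right end.
consensus_clip <- function(clips, align_end = c("left", "right")) {
  align_end <- match.arg(align_end)
  clips <- clips[nzchar(clips)]
  if (!length(clips)) return(NA_character_)
  w <- stats::median(nchar(clips))
  if (align_end == "right")
    clips <- str_rev(clips)
  mat <- vapply(clips, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    length(ch) <- w                      # pad with NA
    ch
  }, character(w))
  cons <- apply(matrix(mat, nrow = w), 1L, function(col) {
    col <- col[!is.na(col)]
    if (!length(col)) return("N")
    tb <- sort(table(col), decreasing = TRUE)
    names(tb)[1]
  })
  s <- paste(cons, collapse = "")
  if (align_end == "right") str_rev(s) else s
}

#' Pair junction clusters into integration calls
#'
#' A left-flank and a right-flank cluster on the same chromosome whose
#' breakpoints lie within `|TSD| + tolerance` bp of each other are paired
#' into one call. The junction interval is reported as the two 1-based
#' genome bases flanking the insertion point (pre-insertion coordinates).
#' When the genome bases between the paired breakpoints equal the expected
#' motif, the TSD is reported; its absence downgrades confidence but does
#' not veto the call. Contradictory orientations between the paired clusters
#' flag the call AMBIGUOUS; unpaired or under-supported junctions are
#' reported as CANDIDATE.
#'
#' @param clusters output of [cluster_junctions()].
#' @param genome the reference `toy_genome` (or named character vector).
#' @param tsd_motif expected TSD motif (default `"TTAA"`).
#' @param min_support minimum support on both sides for PASS (default 3).
#' @param tolerance breakpoint pairing slack in bp (default 5).
#' @return data.frame `chrom, start, end, orientation, tsd, support_left,
#'   support_right, support_total, status`, sorted by total support.
#' @export
call_integration <- function(clusters, genome, tsd_motif = "TTAA",
                             min_support = 3L, tolerance = 5L) {
  refs <- as_ref_vector(genome)
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), orientation = character(0),
                      tsd = character(0), support_left = integer(0),
                      support_right = integer(0), support_total = integer(0),
                      status = character(0), stringsAsFactors = FALSE)
  if (is.null(clusters) || nrow(clusters) == 0L) return(empty)
  w <- nchar(tsd_motif)
  left <- clusters[clusters$genome_side == "left", , drop = FALSE]
  right <- clusters[clusters$genome_side == "right", , drop = FALSE]
  used_l <- rep(FALSE, nrow(left)); used_r <- rep(FALSE, nrow(right))
  pairs <- list()
  if (nrow(left) && nrow(right)) {
    combos <- expand.grid(li = seq_len(nrow(left)), ri = seq_len(nrow(right)))
    combos$chrom_ok <- left$chrom[combos$li] == right$chrom[combos$ri]
    combos$dist <- abs(left$bp[combos$li] - right$bp[combos$ri])
    combos <- combos[combos$chrom_ok & combos$dist <= w + tolerance, , drop = FALSE]
    combos$total <- left$support[combos$li] + right$support[combos$ri]
    combos <- combos[order(-combos$total, combos$dist), , drop = FALSE]
    for (j in seq_len(nrow(combos))) {
      li <- combos$li[j]; ri <- combos$ri[j]
      if (used_l[li] || used_r[ri]) next
      used_l[li] <- TRUE; used_r[ri] <- TRUE
      pairs[[length(pairs) + 1L]] <- list(L = left[li, ], R = right[ri, ])
    }
  }
  calls <- list()
  for (p in pairs) {
    bpL <- p$L$bp; bpR <- p$R$bp
    chrom <- p$L$chrom
    # TSD detection with microhomology tolerance: when a cargo end happens to
    # match the genome beyond the junction, every read's alignment extends
    # past the true breakpoint and the cluster mode shifts by a base or two.
    # Search the motif at positions implied by either breakpoint, nearest
    # shift first, and re-anchor the call on the motif when found.
    tsd <- NA_character_
    anchor <- bpL
    L_chr <- nchar(refs[[chrom]])
    motif_at <- function(cs) {
      cs >= 1L && cs + w - 1L <= L_chr &&
        substr(refs[[chrom]], cs, cs + w - 1L) == tsd_motif
    }
    for (s in 0:tolerance) {
      cs1 <- bpL - w + 1L - s          # motif ending s bases left of bpL
      cs2 <- bpR + s                   # motif starting s bases right of bpR
      if (motif_at(cs1)) { tsd <- tsd_motif; anchor <- cs1 + w - 1L; break }
      if (motif_at(cs2)) { tsd <- tsd_motif; anchor <- cs2 + w - 1L; break }
    }
    bpL <- anchor
    oris <- c(p$L$orientation, p$R$orientation)
    oris <- oris[!is.na(oris)]
    conflict <- length(unique(oris)) > 1
    ori <- if (conflict || !length(oris)) NA_character_ else oris[1]
    status <- if (conflict) "AMBIGUOUS"
      else if (p$L$support >= min_support && p$R$support >= min_support) "PASS"
      else "CANDIDATE"
    calls[[length(calls) + 1L]] <- data.frame(
      chrom = chrom, start = bpL, end = bpL + 1L, orientation = ori,
      tsd = tsd, support_left = p$L$support, support_right = p$R$support,
      support_total = p$L$support + p$R$support, status = status,
      stringsAsFactors = FALSE)
  }
  singles <- rbind(left[!used_l, , drop = FALSE], right[!used_r, , drop = FALSE])
  for (i in seq_len(nrow(singles))) {
    s <- singles[i, ]
    st <- if (s$genome_side == "left") s$bp else s$bp - 1L
    calls[[length(calls) + 1L]] <- data.frame(
      chrom = s$chrom, start = st, end = st + 1L, orientation = s$orientation,
      tsd = NA_character_,
      support_left = if (s$genome_side == "left") s$support else 0L,
      support_right = if (s$genome_side == "right") s$support else 0L,
      support_total = s$support, status = "CANDIDATE",
      stringsAsFactors = FALSE)
  }
  if (!length(calls)) return(empty)
  res <- do.call(rbind, calls)
  res <- res[order(-res$support_total, res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Build a hybrid reference around an integration call
#'
#' Assembles `upstream flank + TSD + oriented transgene + TSD + downstream
#' flank` (TSD segments only when the call carries one), recreating the
#' post-insertion haplotype so junction-spanning reads align without clips.
#' Flanks that would extend past a chromosome end are truncated with a
#' warning.
#'
#' @param call one row of the [call_integration()] output.
#' @param genome the reference genome.
#' @param transgene the transgene construct (or named character vector).
#' @param flank flank length in bp; should be at least the read length.
#' @return list: `name`, `seq`, `junction_left`, `junction_right` (1-based
#'   positions of the last base before each junction boundary), `flank_left`,
#'   `flank_right`, `tsd`, and `map`, a data.frame mapping every hybrid
#'   segment back to its source coordinates.
#' @export
build_hybrid_reference <- function(call, genome, transgene, flank = 500L) {
  refs <- as_ref_vector(genome)
  tg <- as_ref_vector(transgene)
  stopifnot(length(tg) == 1L, nrow(call) == 1L)
  chrom <- call$chrom
  if (!chrom %in% names(refs)) stop("unknown chromosome: ", chrom)
  s <- refs[[chrom]]
  L <- nchar(s)
  tsd <- if (is.na(call$tsd)) "" else call$tsd
  w <- nchar(tsd)
  bpL <- call$start                     # last genome base left of the insert
  up_to <- bpL - w                      # flank excludes the TSD copy
  up_from <- up_to - flank + 1L
  if (up_from < 1L) {
    warning("left flank truncated at chromosome start")
    up_from <- 1L
  }
  dn_from <- bpL + 1L
  dn_to <- bpL + flank
  if (dn_to > L) {
    warning("right flank truncated at chromosome end")
    dn_to <- L
  }
  ori <- if (is.na(call$orientation)) "forward" else call$orientation
  cargo <- if (ori == "reverse") revcomp(tg[[1]]) else tg[[1]]
  fl_l <- up_to - up_from + 1L
  fl_r <- dn_to - dn_from + 1L
  seqh <- paste0(substr(s, up_from, up_to), tsd, cargo, tsd,
                 substr(s, dn_from, dn_to))
  tglen <- nchar(cargo)
  j1 <- fl_l + w                        # boundary: genome+TSD | transgene
  j2 <- j1 + tglen                      # boundary: transgene | TSD+genome
  seg <- function(h1, h2, src, s1, s2, strand)
    data.frame(hybrid_start = h1, hybrid_end = h2, source = src,
               src_start = s1, src_end = s2, strand = strand,
               stringsAsFactors = FALSE)
  map <- rbind(
    seg(1L, fl_l, chrom, up_from, up_to, "+"),
    if (w) seg(fl_l + 1L, j1, chrom, bpL - w + 1L, bpL, "+"),
    seg(j1 + 1L, j2, names(tg), if (ori == "reverse") tglen else 1L,
        if (ori == "reverse") 1L else tglen, if (ori == "reverse") "-" else "+"),
    if (w) seg(j2 + 1L, j2 + w, chrom, bpL - w + 1L, bpL, "+"),
    seg(j2 + w + 1L, nchar(seqh), chrom, dn_from, dn_to, "+"))
  list(name = sprintf("hybrid_%s_%d", chrom, bpL), seq = seqh,
       junction_left = j1, junction_right = j2,
       flank_left = fl_l, flank_right = fl_r, tsd = tsd, map = map)
}

#' Validate an integration call with a hybrid reference
#'
#' Aligns reads to the hybrid reference and counts, for each of the two
#' junctions, the reads that align without soft clips and cover at least
#' `min_span` bases on each side of the boundary. The call validates (PASS)
#' when both junctions reach `min_support` spanning reads.
#'
#' @param hybrid output of [build_hybrid_reference()].
#' @param pairs QC-passed read pairs (data.frame `id, seq1, qual1, seq2,
#'   qual2`) or a long-format reads data.frame (`id, seq`).
#' @param min_span minimum bases covered on each side of a junction.
#' @param min_support minimum spanning reads per junction for PASS.
#' @param k,scoring alignment parameters.
#' @return list `span_left, span_right, pass`.
#' @export
validate_with_hybrid <- function(hybrid, pairs, min_span = 20L,
                                 min_support = 3L, k = 45L,
                                 scoring = align_scoring()) {
  reads <- pairs_to_reads(pairs)
  if (nchar(hybrid$seq) < max(nchar(reads$seq)))
    stop("hybrid reference shorter than the read length")
  idx <- build_index(setNames(hybrid$seq, hybrid$name), k = k)
  rec <- align_reads(reads, idx, scoring)
  mp <- rec[rec$mapped & grepl("^\\d+M$", rec$cigar), , drop = FALSE]
  span_count <- function(j) {
    len <- nchar(mp$seq)
    sum(mp$pos <= j - min_span + 1L & mp$pos + len - 1L >= j + min_span)
  }
  sl <- span_count(hybrid$junction_left)
  sr <- span_count(hybrid$junction_right)
  list(span_left = sl, span_right = sr,
       pass = sl >= min_support && sr >= min_support)
}

# internal: accept either a pairs data.frame or long-format reads
pairs_to_reads <- function(pairs) {
  if (all(c("seq1", "seq2") %in% names(pairs))) {
    data.frame(id = rep(pairs$id, 2L),
               mate = rep(1:2, each = nrow(pairs)),
               seq = c(pairs$seq1, pairs$seq2),
               qual = if (all(c("qual1", "qual2") %in% names(pairs)))
                 c(pairs$qual1, pairs$qual2) else NA_character_,
               stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("id", "seq") %in% names(pairs)))
    pairs
  }
}

#' Full integration-site discovery pipeline
#'
#' Runs quality filtering, seeded alignment against genome + transgene,
#' duplicate removal, soft-clip extraction, clip re-alignment, junction
#' clustering, call pairing, and hybrid-reference validation of every call.
#'
#' @param genome a `toy_genome` (or named character vector of chromosomes).
#' @param transgene a [transgene_construct()] (or named character vector of
#'   length 1).
#' @param pairs read pairs data.frame (`id, seq1, qual1, seq2, qual2`).
#' @param config a [caller_config()].
#' @param genes optional data.frame `chrom, start, end, name` of gene
#'   intervals for annotating calls.
#' @return list with `calls` (including `span_left`, `span_right`,
#'   `validation` columns), `clusters`, `evidence`, and `report` (QC counts,
#'   record counts, thresholds used).
#' @examples
#' \donttest{
#' g <- make_toy_genome(1, 20000, seed = 11)
#' tg <- example_transgene(1500, seed = 12)
#' at <- as.integer(regexpr("TTAA", g$chromosomes[["chr1"]])) - 1L
#' ins <- insert_transgene(g, tg, planted_insertion("chr1", at))
#' sim <- simulate_paired_reads(ins$genome, read_sim_params(coverage = 20, seed = 13))
#' res <- find_integration_sites(g, tg, sim$pairs)
#' res$calls
#' }
#' @export
find_integration_sites <- function(genome, transgene, pairs,
                                   config = caller_config(), genes = NULL) {
  refs <- c(as_ref_vector(genome), as_ref_vector(transgene))
  tg <- as_ref_vector(transgene)
  qc_report <- NULL
  if (!is.null(config$qc)) {
    f <- qc_filter_pairs(pairs, config$qc)
    pairs <- f$pairs
    qc_report <- f$report
  }
  reads <- pairs_to_reads(pairs)
  idx <- build_index(refs, k = config$k)
  rec <- align_reads(reads, idx, config$scoring)
  rec <- remove_duplicates(rec)
  ev <- extract_softclipped(rec, config$min_clip_len)
  hits <- realign_clips(ev, refs, config$min_identity, config$min_hit_len)
  clus <- cluster_junctions(hits, ev, tg, config$cluster_tol, config$end_tol)
  calls <- call_integration(clus, genome, config$tsd_motif,
                            config$min_support, config$cluster_tol)
  calls$span_left <- rep(NA_integer_, nrow(calls))
  calls$span_right <- rep(NA_integer_, nrow(calls))
  calls$validation <- rep(NA_character_, nrow(calls))
  for (i in seq_len(nrow(calls))) {
    hyb <- build_hybrid_reference(calls[i, ], genome, transgene, config$flank)
    v <- validate_with_hybrid(hyb, pairs, config$min_span, config$min_support,
                              config$k, config$scoring)
    calls$span_left[i] <- v$span_left
    calls$span_right[i] <- v$span_right
    calls$validation[i] <- if (v$pass) "PASS" else "FAIL"
  }
  if (!is.null(genes)) calls <- annotate_calls(calls, genes)
  list(calls = calls, clusters = clus, evidence = ev,
       report = list(qc = qc_report,
                     n_records = nrow(rec),
                     n_mapped = sum(rec$mapped),
                     n_evidence = nrow(ev),
                     config = unclass(config)))
}

#' Screen reads for integration of a second vector
#'
#' Runs the junction-discovery chain (align, extract clips, re-align,
#' cluster) with the given vector sequence in the role of the transgene and
#' returns the number of genome-linked vector junction clusters. Zero means
#' no detectable vector integration; free episomal vector produces vector
#' reads but no genome-linked clusters.
#'
#' @param genome the reference genome.
#' @param vector_seq the vector sequence (named character vector of length 1
#'   or `transgene_construct`), e.g. a transposase plasmid backbone.
#' @param pairs read pairs data.frame.
#' @param config a [caller_config()].
#' @return integer: number of genome-linked vector junction clusters.
#' @export
screen_vector_integration <- function(genome, vector_seq, pairs,
                                      config = caller_config()) {
  v <- as_ref_vector(vector_seq)
  stopifnot(length(v) == 1L)
  if (!nzchar(v[[1]])) stop("empty vector sequence")
  refs <- c(as_ref_vector(genome), v)
  if (!is.null(config$qc)) pairs <- qc_filter_pairs(pairs, config$qc)$pairs
  reads <- pairs_to_reads(pairs)
  idx <- build_index(refs, k = config$k)
  rec <- remove_duplicates(align_reads(reads, idx, config$scoring))
  ev <- extract_softclipped(rec, config$min_clip_len)
  hits <- realign_clips(ev, refs, config$min_identity, config$min_hit_len)
  clus <- cluster_junctions(hits, ev, v, config$cluster_tol, config$end_tol)
  nrow(clus)
}

#' Annotate calls with overlapping gene intervals
#'
#' @param calls output of [call_integration()] / [find_integration_sites()].
#' @param genes data.frame `chrom, start, end, name` (1-based inclusive).
#' @return `calls` with an `overlapping_gene` column (comma-separated names,
#'   `NA` when none).
#' @export
annotate_calls <- function(calls, genes) {
  stopifnot(all(c("chrom", "start", "end", "name") %in% names(genes)))
  calls$overlapping_gene <- vapply(seq_len(nrow(calls)), function(i) {
    hit <- genes$chrom == calls$chrom[i] &
      genes$start <= calls$end[i] & genes$end >= calls$start[i]
    if (any(hit)) paste(genes$name[hit], collapse = ",") else NA_character_
  }, character(1))
  calls
}

#' Format calls as a report table
#'
#' Renders calls in the conventional reporting style for transgene
#' integration sites: chromosome, a two-base insert-site interval with
#' thousands separators, capitalised orientation, overlapping gene, support
#' and validation.
#'
#' @param calls annotated calls.
#' @param sample_id optional sample label column.
#' @return data.frame with columns `ID, Chromosome, Insert.Site,
#'   Orientation, Overlapping.gene, Support, Validation`.
#' @export
format_calls_table <- function(calls, sample_id = "sample") {
  data.frame(
    ID = sample_id,
    Chromosome = calls$chrom,
    Insert.Site = sprintf("%s-%s",
                          format(calls$start, big.mark = ",", trim = TRUE),
                          format(calls$end, big.mark = ",", trim = TRUE)),
    Orientation = ifelse(is.na(calls$orientation), "Ambiguous",
                         paste0(toupper(substr(calls$orientation, 1, 1)),
                                substring(calls$orientation, 2))),
    Overlapping.gene = if ("overlapping_gene" %in% names(calls))
      calls$overlapping_gene else NA_character_,
    Support = calls$support_total,
    Validation = if ("validation" %in% names(calls)) calls$validation
      else NA_character_,
    stringsAsFactors = FALSE)
}

#' Export calls as BED6
#'
#' 0-based half-open interval covering the two flanking bases; name is the
#' construct, score the total support (capped at 1000), strand the
#' orientation.
#'
#' @param calls calls data.frame.
#' @param construct_name name for the BED name field.
#' @param path optional output file; when given, writes tab-separated BED.
#' @return the BED data.frame, invisibly when `path` is given.
#' @export
calls_to_bed <- function(calls, construct_name = "transgene", path = NULL) {
  bed <- data.frame(chrom = calls$chrom,
                    start = calls$start - 1L,
                    end = calls$end,
                    name = construct_name,
                    score = pmin(calls$support_total, 1000L),
                    strand = ifelse(is.na(calls$orientation), ".",
                                    ifelse(calls$orientation == "forward", "+", "-")),
                    stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    return(invisible(bed))
  }
  bed
}
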