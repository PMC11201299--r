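# Shared fixture builders. Everything is generated in code under fixed seeds.

rc1 <- function(x) pbsite:::revcomp(x)

# 0-based position of a TTAA motif well inside chr1 (>= margin from both ends)
ttaa_interior <- function(seq, margin = 2000L) {
  hits <- gregexpr("TTAA", seq, fixed = TRUE)[[1]]
  hits <- hits[hits > margin & hits < nchar(seq) - margin]
  if (!length(hits)) stop("no interior TTAA in fixture genome")
  hits[ceiling(length(hits) / 2)] - 1L
}

# genome + planted insertion + simulated reads, with truth
make_insertion_fixture <- function(genome_len = 20000L, tg_len = 1500L,
                                   orientation = "forward", coverage = 20,
                                   error_rate = 0.001, seed = 1L) {
  g <- make_toy_genome(1, genome_len, seed = seed)
  tg <- example_transgene(tg_len, seed = seed + 1000L)
  at <- ttaa_interior(g$chromosomes[["chr1"]])
  site <- planted_insertion("chr1", at, orientation)
  ins <- insert_transgene(g, tg, site)
  sim <- simulate_paired_reads(
    ins$genome,
    read_sim_params(coverage = coverage, error_rate = error_rate,
                    seed = seed + 2000L))
  list(genome = g, tg = tg, site = site, truth = ins$truth,
       modified = ins$genome, sim = sim)
}

# exhaustive per-diagonal ungapped scan: the independent alignment oracle.
# For every reference, strand and diagonal it takes the maximal-scoring
# contiguous segment (ties: latest start, earliest end) and then applies the
# aligner's deterministic tie-break across diagonals.
oracle_align <- function(seq, refs, scoring = align_scoring(), k = 11L) {
  qlen <- nchar(seq)
  best <- NULL
  better <- function(cand, best) {
    if (is.null(best)) return(TRUE)
    if (cand$score != best$score) return(cand$score > best$score)
    if (cand$ref != best$ref) return(cand$ref < best$ref)
    if (cand$pos != best$pos) return(cand$pos < best$pos)
    cand$strand < best$strand
  }
  for (nm in names(refs)) {
    s <- refs[[nm]]
    L <- nchar(s)
    si <- utf8ToInt(s)
    for (st in c("+", "-")) {
      q <- if (st == "+") seq else rc1(seq)
      qi <- utf8ToInt(q)
      for (d in (1L - qlen + k):(L - k + 1L)) {
        lo <- max(1L, d); hi <- min(L, d + qlen - 1L)
        if (hi - lo + 1L < k) next
        qlo <- lo - d + 1L; qhi <- hi - d + 1L
        m <- qi[qlo:qhi] == si[lo:hi]
        sc <- ifelse(m, scoring$match, scoring$mismatch)
        cs <- cumsum(sc)
        pre <- c(0L, cs[-length(cs)])
        cm <- cummin(pre)
        val <- cs - cm
        bsc <- max(val)
        if (bsc < scoring$min_score) next
        e <- which.max(val)                            # earliest best end
        a <- max(which(pre[seq_len(e)] == cm[e]))      # latest best start
        cand <- list(score = bsc, ref = nm, pos = d + (qlo + a - 1L) - 1L,
                     strand = st, qa = qlo + a - 1L, qb = qlo + e - 1L)
        if (better(cand, best)) best <- cand
      }
    }
  }
  best
}
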