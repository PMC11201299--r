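test_that("soft-clip extraction does the anchor arithmetic", {
  rec <- data.frame(
    qname = c("a", "b", "c", "d"),
    mate = 1L, mapped = TRUE, rname = "chr1",
    pos = c(2000L, 100L, 500L, 700L), strand = "+",
    cigar = c("80M70S", "150M", "10S140M", "30S90M30S"),
    seq = c(paste0(strrep("G", 80), strrep("T", 70)),
            strrep("A", 150),
            paste0(strrep("C", 10), strrep("A", 140)),
            paste0(strrep("T", 30), strrep("A", 90), strrep("G", 30))),
    qual = NA_character_, stringsAsFactors = FALSE)
  ev <- extract_softclipped(rec, min_clip_len = 20)
  # a: right clip anchored at 2000+80-1; d: clips on both sides
  expect_equal(nrow(ev), 3)
  a <- ev[ev$qname == "a", ]
  expect_equal(a$side, "right")
  expect_equal(a$anchor_pos, 2079L)
  expect_equal(a$clip_seq, strrep("T", 70))
  d <- ev[ev$qname == "d", ]
  expect_setequal(d$side, c("left", "right"))
  expect_equal(d$anchor_pos[d$side == "left"], 700L)
  expect_equal(d$anchor_pos[d$side == "right"], 789L)
  # 150M yields nothing; 10S is under the threshold
  expect_false(any(ev$qname %in% c("b", "c")))
  expect_equal(nrow(extract_softclipped(rec[0, ], 20)), 0)
})

test_that("clip re-alignment finds exact hits, strands, and rejects noise", {
  g <- make_toy_genome(1, 10000, seed = 11)
  tg <- example_transgene(1000, seed = 12)
  targets <- c(as_references(g), as_references(tg))
  withr::with_seed(13, {
    rand <- paste(sample(c("A", "C", "G", "T"), 70, TRUE), collapse = "")
  })
  ev <- data.frame(
    eid = c("e1", "e2", "e3"),
    qname = c("r1", "r2", "r3"), ref = "chr1",
    anchor_pos = c(100L, 200L, 300L),
    side = "right",
    clip_seq = c(substr(tg$sequence, 1, 70),           # transgene 5' prefix
                 rand,                                   # random 70-mer
                 rc1(substr(g$chromosomes[["chr1"]], 5001, 5070))),
    strand = "+", stringsAsFactors = FALSE)
  hits <- realign_clips(ev, targets)
  h1 <- hits[hits$eid == "e1", ]
  expect_equal(h1$target, tg$name)
  expect_equal(h1$identity, 100)
  expect_equal(c(h1$t_start, h1$t_end), c(1L, 70L))
  expect_equal(h1$t_strand, "+")
  expect_false("e2" %in% hits$eid)                      # no 95% hit for noise
  h3 <- hits[hits$eid == "e3", ]
  expect_equal(h3$target, "chr1")
  expect_equal(h3$t_strand, "-")
  expect_equal(c(h3$t_start, h3$t_end), c(5001L, 5070L))
  expect_error(realign_clips(ev, character(0)), "empty target")
})

test_that("breakpoint clustering merges within tolerance and takes the mode", {
  tg <- setNames(strrep("A", 1000), "tgx")   # name/length only
  mk_ev <- function(eids, pos) data.frame(
    eid = eids, qname = paste0("q", seq_along(eids)), ref = "chr1",
    anchor_pos = pos, side = "right",
    clip_seq = strrep("C", 30), strand = "+", stringsAsFactors = FALSE)
  mk_hit <- function(eids) data.frame(
    eid = eids, target = "tgx", t_start = 1L, t_end = 30L, t_strand = "+",
    identity = 100, score = 60, aln_len = 30L, stringsAsFactors = FALSE)
  # 12 breakpoints at one position: one cluster, support 12
  ev <- mk_ev(sprintf("e%02d", 1:12), rep(4000L, 12))
  cl <- cluster_junctions(mk_hit(ev$eid), ev, tg)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$bp, 4000L)
  expect_equal(cl$support, 12)
  expect_equal(cl$orientation, "forward")   # right clip + 5' hit + plus strand
  # positions P and P+200 stay apart
  ev2 <- mk_ev(c("f1", "f2"), c(4000L, 4200L))
  cl2 <- cluster_junctions(mk_hit(c("f1", "f2")), ev2, tg)
  expect_equal(nrow(cl2), 2)
  # jitter within the tolerance merges; mode breaks ties to the smaller pos
  ev3 <- mk_ev(sprintf("g%d", 1:5), c(4000L, 4000L, 4001L, 4001L, 4003L))
  cl3 <- cluster_junctions(mk_hit(ev3$eid), ev3, tg)
  expect_equal(nrow(cl3), 1)
  expect_equal(cl3$bp, 4000L)
  expect_equal(cl3$spread, 3L)
  # empty inputs give empty clusters
  expect_equal(nrow(cluster_junctions(mk_hit("x")[0, ], ev[0, ], tg)), 0)
})

test_that("full simulated run recovers the planted site, both orientations", {
  for (ori in c("forward", "reverse")) {
    fx <- make_insertion_fixture(genome_len = 20000, orientation = ori,
                                 coverage = 20, seed = if (ori == "forward") 20 else 21)
    res <- find_integration_sites(fx$genome, fx$tg, fx$sim$pairs)
    calls <- res$calls[res$calls$status == "PASS", ]
    expect_equal(nrow(calls), 1)
    expect_equal(calls$chrom, fx$truth$chrom)
    expect_equal(calls$start, fx$truth$insert_start)
    expect_equal(calls$end, fx$truth$insert_end)
    expect_equal(calls$orientation, ori)
    expect_equal(calls$tsd, "TTAA")
    expect_gte(calls$support_left, 3)
    expect_gte(calls$support_right, 3)
    expect_equal(calls$validation, "PASS")
  }
})

test_that("microhomology-shifted breakpoints still recover the TSD and interval", {
  g <- make_toy_genome(1, 10000, seed = 90)
  at <- ttaa_interior(g$chromosomes[["chr1"]])   # 0-based; motif at at+1..at+4
  t1 <- at + 1L
  mk_cluster <- function(side, bp) data.frame(
    chrom = "chr1", genome_side = side, bp = bp, spread = 0L, support = 10L,
    tg_end = if (side == "left") "5p" else "3p", orientation = "forward",
    n_forward = 10L, n_reverse = 0L, consensus_clip = NA_character_,
    stringsAsFactors = FALSE)
  # right breakpoint shifted 1 bp left by chance microhomology
  cl <- rbind(mk_cluster("left", t1 + 3L), mk_cluster("right", t1 - 1L))
  call <- call_integration(cl, g)
  expect_equal(call$start, t1 + 3L)
  expect_equal(call$end, t1 + 4L)
  expect_equal(call$tsd, "TTAA")
  # left breakpoint shifted 2 bp right: interval re-anchors on the motif
  cl2 <- rbind(mk_cluster("left", t1 + 5L), mk_cluster("right", t1))
  call2 <- call_integration(cl2, g)
  expect_equal(call2$start, t1 + 3L)
  expect_equal(call2$tsd, "TTAA")
  # both shifted: still re-anchored via the nearer implied motif position
  cl3 <- rbind(mk_cluster("left", t1 + 4L), mk_cluster("right", t1 - 1L))
  call3 <- call_integration(cl3, g)
  expect_equal(call3$start, t1 + 3L)
  expect_equal(call3$tsd, "TTAA")
})

test_that("no soft-clip evidence yields an empty call list", {
  g <- make_toy_genome(1, 8000, seed = 22)
  tg <- example_transgene(800, seed = 23)
  sim <- simulate_paired_reads(g, read_sim_params(coverage = 10, seed = 24))
  res <- find_integration_sites(g, tg, sim$pairs)
  expect_equal(nrow(res$calls), 0)
})

test_that("hybrid reference has the stated geometry and embeds orientation", {
  g <- make_toy_genome(1, 10000, seed = 25)
  tg <- example_transgene(2000, seed = 26)
  at <- ttaa_interior(g$chromosomes[["chr1"]])
  call <- data.frame(chrom = "chr1", start = at + 4L, end = at + 5L,
                     orientation = "forward", tsd = "TTAA",
                     stringsAsFactors = FALSE)
  hyb <- build_hybrid_reference(call, g, tg, flank = 500)
  expect_equal(nchar(hyb$seq), 2 * 500 + 2000 + 2 * 4)
  expect_equal(hyb$junction_left, 504L)
  expect_equal(hyb$junction_right, 2504L)
  # embedded cargo matches the orientation
  expect_identical(substr(hyb$seq, 505, 2504), tg$sequence)
  call$orientation <- "reverse"
  hyb_r <- build_hybrid_reference(call, g, tg, flank = 500)
  expect_identical(substr(hyb_r$seq, 505, 2504), rc1(tg$sequence))
  # no TSD: plain flank + transgene + flank
  call$tsd <- NA_character_
  hyb_n <- build_hybrid_reference(call, g, tg, flank = 500)
  expect_equal(nchar(hyb_n$seq), 2 * 500 + 2000)
  # the hybrid with TSD reproduces the true post-insertion haplotype
  site <- planted_insertion("chr1", at, "forward")
  mod <- insert_transgene(g, tg, site)$genome$chromosomes[["chr1"]]
  region <- substr(mod, at + 4L - 4L - 500L + 1L, at + 4L + 2000L + 4L + 500L)
  expect_identical(hyb$seq, region)
  # truncation warns
  call2 <- data.frame(chrom = "chr1", start = 30L, end = 31L,
                      orientation = "forward", tsd = NA_character_,
                      stringsAsFactors = FALSE)
  expect_warning(build_hybrid_reference(call2, g, tg, flank = 500), "truncated")
})

test_that("hybrid validation passes at truth and fails a fabricated call", {
  fx <- make_insertion_fixture(genome_len = 15000, coverage = 30, seed = 27)
  call <- data.frame(chrom = "chr1", start = fx$truth$insert_start,
                     end = fx$truth$insert_end, orientation = "forward",
                     tsd = "TTAA", stringsAsFactors = FALSE)
  hyb <- build_hybrid_reference(call, fx$genome, fx$tg, flank = 500)
  v <- validate_with_hybrid(hyb, fx$sim$pairs, min_support = 5)
  expect_gte(v$span_left, 5)
  expect_gte(v$span_right, 5)
  expect_true(v$pass)
  # reads from an insertion-free genome cannot validate the same call
  clean <- simulate_paired_reads(fx$genome,
                                 read_sim_params(coverage = 20, seed = 28))
  v0 <- validate_with_hybrid(hyb, clean$pairs)
  expect_equal(v0$span_left, 0)
  expect_equal(v0$span_right, 0)
  expect_false(v0$pass)
})

test_that("junction reads clipped on the linear reference go clip-free on the hybrid", {
  fx <- make_insertion_fixture(genome_len = 12000, coverage = 20, seed = 29,
                               error_rate = 0)
  refs <- c(as_references(fx$genome), as_references(fx$tg))
  idx <- build_index(refs)
  reads <- pbsite:::pairs_to_reads(fx$sim$pairs)
  rec <- align_reads(reads, idx)
  ev <- extract_softclipped(rec, 20)
  expect_gt(nrow(ev), 0)
  call <- data.frame(chrom = "chr1", start = fx$truth$insert_start,
                     end = fx$truth$insert_end,
                     orientation = fx$truth$orientation,
                     tsd = "TTAA", stringsAsFactors = FALSE)
  hyb <- build_hybrid_reference(call, fx$genome, fx$tg, flank = 500)
  hidx <- build_index(setNames(hyb$seq, "hyb"), k = 45)
  # exactly the mates that carried the >= 20 bp clip on the linear references
  cs <- pbsite:::cigar_summary(rec$cigar[rec$mapped])
  clip_len <- vapply(cs, function(x) max(x$lead_s, x$trail_s), integer(1))
  clipped_keys <- paste(rec$qname[rec$mapped], rec$mate[rec$mapped])[clip_len >= 20]
  junction_reads <- reads[paste(reads$id, reads$mate) %in% clipped_keys, ]
  rec2 <- align_reads(junction_reads, hidx)
  near <- rec2[rec2$mapped, ]
  expect_gt(nrow(near), 0)
  expect_true(all(grepl("^\\d+M$", near$cigar)))
})

test_that("vector screening counts genome-linked junctions only", {
  g <- make_toy_genome(1, 15000, seed = 30)
  tg <- example_transgene(1200, seed = 31)
  vec <- example_transgene(1000, seed = 32, name = "TASE-vector",
                           payload = "Ef1a-Transposase")
  at <- ttaa_interior(g$chromosomes[["chr1"]])
  ins <- insert_transgene(g, tg, planted_insertion("chr1", at))
  sim <- simulate_paired_reads(ins$genome, read_sim_params(coverage = 20, seed = 33))
  # only the transgene planted: no vector junctions
  expect_equal(screen_vector_integration(g, vec, sim$pairs), 0)
  # vector also planted: junctions found
  s2 <- ins$genome$chromosomes[["chr1"]]
  hits <- gregexpr("TTAA", s2, fixed = TRUE)[[1]]
  at2 <- hits[hits > at + 3000][1] - 1L
  ins2 <- insert_transgene(ins$genome, vec, planted_insertion("chr1", at2))
  sim2 <- simulate_paired_reads(ins2$genome, read_sim_params(coverage = 20, seed = 34))
  expect_gte(screen_vector_integration(g, vec, sim2$pairs), 1)
  # free episomal vector: vector reads but no genome links
  vg <- structure(list(chromosomes = setNames(
    paste0(strrep(vec$sequence, 3), strrep(vec$sequence, 2)), "episome")),
    class = "toy_genome")
  free <- simulate_paired_reads(vg, read_sim_params(coverage = 10, seed = 35))
  mixed <- rbind(sim$pairs, within(free$pairs, id <- paste0("v_", id)))
  expect_equal(screen_vector_integration(g, vec, mixed), 0)
})

test_that("calls render as a report table and as BED6", {
  call <- data.frame(chrom = "NC_051345.1", start = 73640204L, end = 73640205L,
                     orientation = "reverse", tsd = "TTAA",
                     support_left = 10L, support_right = 12L,
                     support_total = 22L, status = "PASS",
                     validation = "PASS", stringsAsFactors = FALSE)
  genes <- data.frame(chrom = "NC_051345.1", start = 73600000L,
                      end = 73700000L, name = "Akap1",
                      stringsAsFactors = FALSE)
  ann <- annotate_calls(call, genes)
  tab <- format_calls_table(ann, sample_id = "GFP F6 #201")
  expect_equal(tab$Chromosome, "NC_051345.1")
  expect_equal(tab$Insert.Site, "73,640,204-73,640,205")
  expect_equal(tab$Orientation, "Reverse")
  expect_equal(tab$Overlapping.gene, "Akap1")
  bed <- calls_to_bed(ann, construct_name = "PB-Ef1a-GFP")
  expect_equal(bed$start, 73640203L)   # 0-based half-open
  expect_equal(bed$end, 73640205L)
  expect_equal(bed$strand, "-")
})
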