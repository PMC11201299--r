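test_that("index construction bounds, errors and duplicate k-mers", {
  g <- make_toy_genome(1, 10000, seed = 1)
  idx <- build_index(g, k = 45)
  expect_lte(nrow(idx$table), 2 * (10000 - 44))
  expect_error(build_index(setNames("ACGTACGTACGT", "tiny"), k = 45),
               "shortest reference")
  expect_error(build_index(g, k = 9), ">= 11")
  # the same k-mer at two loci keeps both positions
  s <- paste0(strrep("C", 30), "ACGTTGCAACGTTGG", strrep("A", 30),
              "ACGTTGCAACGTTGG", strrep("G", 30))
  idx2 <- build_index(setNames(s, "r"), k = 15)
  dup <- idx2$table[idx2$table$kmer == "ACGTTGCAACGTTGG" &
                      idx2$table$strand == "+", ]
  expect_equal(sort(dup$pos), c(31L, 76L))
})

test_that("perfect, chimeric and alien reads align as expected", {
  g <- make_toy_genome(1, 10000, seed = 2)
  tg <- example_transgene(1000, seed = 3)
  s <- g$chromosomes[["chr1"]]
  idx <- build_index(c(as_references(g), as_references(tg)))
  # exact read from position 1001: full-length match, no clips
  rec <- align_read(substr(s, 1001, 1150), idx)
  expect_true(rec$mapped)
  expect_equal(rec$pos, 1001L)
  expect_equal(rec$cigar, "150M")
  expect_equal(rec$strand, "+")
  # chimera 80 bp genome + 70 bp transgene: trailing 70 bp soft clip.
  # Pick a junction where the first transgene base differs from the genome
  # continuation, so the clip boundary is unambiguous.
  st <- 2001L
  while (substr(s, st + 80L, st + 80L) == substr(tg$sequence, 1, 1)) st <- st + 1L
  chim <- paste0(substr(s, st, st + 79L), substr(tg$sequence, 1, 70))
  rec <- align_read(chim, idx)
  expect_true(rec$mapped)
  expect_equal(rec$rname, "chr1")
  expect_equal(rec$pos, st)
  expect_equal(rec$cigar, "80M70S")
  # reverse-complemented read maps to the minus strand at the same locus
  rec <- align_read(rc1(substr(s, 3001, 3150)), idx)
  expect_equal(rec$pos, 3001L)
  expect_equal(rec$strand, "-")
  expect_identical(rec$seq, substr(s, 3001, 3150))   # stored as aligned
  # random sequence absent from the references stays unmapped
  withr::with_seed(4, {
    alien <- paste(sample(c("A", "C", "G", "T"), 150, TRUE), collapse = "")
  })
  rec <- align_read(alien, idx)
  expect_false(rec$mapped)
})

test_that("soft-clip lengths and matched length always sum to read length", {
  fx <- make_insertion_fixture(genome_len = 10000, seed = 5, coverage = 10)
  refs <- c(as_references(fx$genome), as_references(fx$tg))
  idx <- build_index(refs)
  reads <- pbsite:::pairs_to_reads(fx$sim$pairs)
  rec <- align_reads(reads, idx)
  mp <- rec[rec$mapped, ]
  cs <- pbsite:::cigar_summary(mp$cigar)
  total <- vapply(cs, function(x) x$lead_s + x$ref_span + x$trail_s, integer(1))
  expect_identical(total, nchar(mp$seq))
})

test_that("error-free contained reads all map at their truth coordinates", {
  g <- make_toy_genome(1, 6000, seed = 6)
  sim <- simulate_paired_reads(
    g, read_sim_params(coverage = 10, error_rate = 0, seed = 7))
  idx <- build_index(g, k = 45)
  reads <- pbsite:::pairs_to_reads(sim$pairs)
  rec <- align_reads(reads, idx)
  expect_true(all(rec$mapped))
  m <- merge(rec, sim$truth, by.x = "qname", by.y = "id")
  # mate 1 sits at the fragment 5' end, mate 2 at the 3' end;
  # record strand follows the sequenced strand of that mate
  exp_pos <- ifelse((m$mate == 1) == (m$strand.y == "+"),
                    m$frag_start, m$frag_end - 149L)
  exp_strand <- ifelse(m$mate == 1, m$strand.y,
                       ifelse(m$strand.y == "+", "-", "+"))
  expect_identical(m$pos, as.integer(exp_pos))
  expect_identical(m$strand.x, exp_strand)
  expect_true(all(m$cigar == "150M"))
})

test_that("seeded alignment equals the exhaustive-scan oracle on small refs", {
  withr::with_seed(8, {
    refs <- setNames(
      vapply(1:2, function(i)
        paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = ""),
        character(1)),
      c("refA", "refB"))
    sc <- align_scoring()
    idx <- build_index(refs, k = 11)
    n_checked <- 0
    for (i in 1:60) {
      type <- sample(c("exact", "one_error", "random", "revcomp"), 1)
      src <- sample(names(refs), 1)
      start <- sample(1:141, 1)
      read <- substr(refs[[src]], start, start + 59)
      if (type == "one_error") {
        p <- sample(60, 1)
        old <- substr(read, p, p)
        substr(read, p, p) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
      } else if (type == "random") {
        read <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
      } else if (type == "revcomp") {
        read <- rc1(read)
      }
      got <- align_read(read, idx, sc)
      want <- oracle_align(read, refs, sc, k = 11)
      if (is.null(want)) {
        expect_false(got$mapped)
      } else {
        expect_true(got$mapped)
        expect_equal(got$score, want$score)
        expect_equal(got$pos, want$pos)
        expect_equal(got$rname, want$ref)
        expect_equal(got$strand, want$strand)
      }
      n_checked <- n_checked + 1
    }
    expect_equal(n_checked, 60)
  })
})

test_that("duplicate removal collapses same-coordinate pairs and is idempotent", {
  g <- make_toy_genome(1, 6000, seed = 9)
  s <- g$chromosomes[["chr1"]]
  idx <- build_index(g)
  # two pairs from the identical fragment, one from a shifted fragment
  frag <- function(a, b) list(m1 = substring(s, a, a + 149),
                              m2 = rc1(substring(s, b - 149, b)))
  f1 <- frag(1000, 1349); f2 <- frag(1000, 1349); f3 <- frag(1010, 1359)
  reads <- data.frame(
    id = rep(c("p1", "p2", "p3"), each = 2),
    mate = rep(1:2, 3),
    seq = c(f1$m1, f1$m2, f2$m1, f2$m2, f3$m1, f3$m2),
    qual = c(rep(pbsite:::phred_string(rep(30L, 150)), 2),
             rep(pbsite:::phred_string(rep(35L, 150)), 2),
             rep(pbsite:::phred_string(rep(30L, 150)), 2)),
    stringsAsFactors = FALSE)
  rec <- align_reads(reads, idx)
  dd <- remove_duplicates(rec)
  expect_setequal(unique(dd$qname), c("p2", "p3"))   # p2 wins on quality
  expect_identical(remove_duplicates(dd), dd)
  # distinct coordinates all survive
  expect_equal(nrow(dd[dd$qname == "p3", ]), 2)
  expect_identical(remove_duplicates(rec[0, ]), rec[0, ])
})

test_that("SAM round trip preserves records and flags", {
  fx <- make_insertion_fixture(genome_len = 8000, seed = 10, coverage = 5)
  refs <- c(as_references(fx$genome), as_references(fx$tg))
  idx <- build_index(refs)
  reads <- pbsite:::pairs_to_reads(fx$sim$pairs)
  rec <- align_reads(head(reads, 200), idx)
  f <- tempfile(fileext = ".sam")
  write_sam(rec, refs, f)
  lines <- readLines(f)
  expect_true(any(startsWith(lines, "@SQ")))
  back <- read_sam(f)
  expect_equal(nrow(back), nrow(rec))
  expect_identical(back$qname, rec$qname)
  expect_identical(back$mapped, rec$mapped)
  keep <- rec$mapped
  expect_identical(back$rname[keep], rec$rname[keep])
  expect_identical(back$pos[keep], rec$pos[keep])
  expect_identical(back$cigar[keep], rec$cigar[keep])
  expect_identical(back$strand[keep], rec$strand[keep])
  expect_identical(back$seq, rec$seq)
})
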