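#' Describe a planted transposon insertion site
#'
#' PiggyBac integrates at a TTAA tetranucleotide and duplicates it, so that
#' the cargo ends up flanked by one full TTAA copy on each side (the
#' target-site duplication, TSD). `ttaa_start` is the 0-based position of
#' the motif in the pre-insertion chromosome.
#'
#' @param chrom chromosome name.
#' @param ttaa_start 0-based position of the TSD motif in the pre-insertion
#'   genome.
#' @param orientation `"forward"` (construct plus strand colinear with the
#'   genome plus strand) or `"reverse"`.
#' @param tsd the duplicated motif; `"TTAA"` for PiggyBac, configurable so
#'   other transposon chemistries can be simulated.
#' @return A `planted_insertion` object.
#' @export
planted_insertion <- function(chrom, ttaa_start,
                              orientation = c("forward", "reverse"),
                              tsd = "TTAA") {
  orientation <- match.arg(orientation)
  stopifnot(is.character(chrom), length(chrom) == 1,
            ttaa_start >= 0, nchar(tsd) >= 1, grepl("^[ACGT]+$", tsd))
  structure(list(chrom = chrom, ttaa_start = as.integer(ttaa_start),
                 orientation = orientation, tsd = toupper(tsd)),
            class = "planted_insertion")
}

#' Insert a transgene into a toy genome with target-site duplication
#'
#' Rewrites the named chromosome as
#' `prefix(..TSD) + oriented transgene + TSD + suffix`, i.e. the target
#' motif is duplicated so one full copy flanks each end of the cargo.
#' Reverse orientation inserts the reverse complement of the construct.
#' The returned truth record carries the 1-based two-base junction interval
#' (the genome bases flanking the insertion point, in pre-insertion
#' coordinates) against which integration calls can be compared.
#'
#' @param genome a [make_toy_genome()] object.
#' @param construct a [transgene_construct()].
#' @param site a [planted_insertion()]; the TSD motif must be present at
#'   `site$ttaa_start` on the named chromosome.
#' @return A list with `genome` (modified `toy_genome`) and `truth`, a
#'   one-row data.frame: `chrom`, `insert_start`, `insert_end` (the two
#'   1-based flanking bases), `orientation`, `tsd`, `transgene`.
#' @examples
#' g <- make_toy_genome(1, 5000, seed = 2)
#' tg <- example_transgene(500, seed = 3)
#' at <- as.integer(regexpr("TTAA", g$chromosomes[["chr1"]])) - 1L
#' ins <- insert_transgene(g, tg, planted_insertion("chr1", at))
#' ins$truth
#' @export
insert_transgene <- function(genome, construct, site) {
  stopifnot(inherits(genome, "toy_genome"),
            inherits(construct, "transgene_construct"),
            inherits(site, "planted_insertion"))
  chroms <- genome$chromosomes
  if (!site$chrom %in% names(chroms))
    stop("unknown chromosome: ", site$chrom)
  s <- chroms[[site$chrom]]
  w <- nchar(site$tsd)
  t1 <- site$ttaa_start + 1L                       # 1-based motif start
  if (substr(s, t1, t1 + w - 1L) != site$tsd)
    stop("TSD motif ", site$tsd, " not present at position ", site$ttaa_start,
         " (0-based) on ", site$chrom)
  cargo <- if (site$orientation == "forward") construct$sequence
           else revcomp(construct$sequence)
  chroms[[site$chrom]] <- paste0(substr(s, 1L, t1 + w - 1L),     # ends in TSD
                                 cargo, site$tsd,
                                 substr(s, t1 + w, nchar(s)))
  truth <- data.frame(chrom = site$chrom,
                      insert_start = t1 + w - 1L,   # last base of the TSD
                      insert_end = t1 + w,
                      orientation = site$orientation,
                      tsd = site$tsd,
                      transgene = construct$name,
                      stringsAsFactors = FALSE)
  list(genome = structure(list(chromosomes = chroms), class = "toy_genome"),
       truth = truth)
}

#' Excise a planted transgene, restoring the original chromosome
#'
#' Inverse of [insert_transgene()]: removes the oriented cargo plus exactly
#' one TSD copy. For any valid site, `excise_transgene(insert_transgene(...))`
#' restores the input genome byte for byte.
#'
#' @inheritParams insert_transgene
#' @return The restored `toy_genome`.
#' @export
excise_transgene <- function(genome, construct, site) {
  stopifnot(inherits(genome, "toy_genome"),
            inherits(construct, "transgene_construct"),
            inherits(site, "planted_insertion"))
  chroms <- genome$chromosomes
  if (!site$chrom %in% names(chroms))
    stop("unknown chromosome: ", site$chrom)
  s <- chroms[[site$chrom]]
  w <- nchar(site$tsd)
  Lc <- nchar(construct$sequence)
  keep_to <- site$ttaa_start + w                    # last 1-based base kept
  cut_len <- Lc + w                                 # cargo + one TSD copy
  cargo <- if (site$orientation == "forward") construct$sequence
           else revcomp(construct$sequence)
  if (substr(s, keep_to + 1L, keep_to + cut_len) != paste0(cargo, site$tsd))
    stop("chromosome does not carry the stated insertion at this site")
  chroms[[site$chrom]] <- paste0(substr(s, 1L, keep_to),
                                 substr(s, keep_to + cut_len + 1L, nchar(s)))
  structure(list(chromosomes = chroms), class = "toy_genome")
}
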