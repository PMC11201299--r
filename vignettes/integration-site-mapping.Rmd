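---
title: "Mapping a PiggyBac transgene integration site from soft-clipped reads"
author: "pbsite"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a PiggyBac transgene integration site from soft-clipped reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A PiggyBac (PB) transposon delivers an ITR-flanked cargo (here: a
constitutive promoter driving GFP) into a host genome at TTAA
tetranucleotides, duplicating the motif so that one full TTAA copy flanks
each end of the insertion (the target-site duplication, TSD). A founder
animal made by cytoplasmic injection typically carries several independent
hemizygous insertions; repeated backcrossing to wild type with selection of
expressing offspring reduces the locus count until litters segregate at the
single-locus Mendelian ratio of 50%. Whole-genome paired-end sequencing of
such an animal then localises the remaining insertion: reads that straddle a
genome/transgene boundary cannot align end-to-end to either sequence, and a
soft-clipping aligner anchors one part and leaves the other as a clip. The
clipped part, re-aligned against the other sequence, pins the junction to a
base.

`pbsite` implements that analysis as a reusable, fully testable pipeline:

1. a synthetic-data module that generates every input with known ground
   truth (toy genomes, TSD-correct insertions, paired reads, offspring
   genotypes, qPCR Ct panels);
2. the read quality-control filters used for this kind of data;
3. a seeded soft-clipping aligner with coordinate duplicate removal and SAM
   import/export;
4. the junction caller: clip extraction, local re-alignment, breakpoint
   clustering, call pairing with TSD detection, and hybrid-reference
   validation;
5. a Mendelian transmission model of the breeding programme;
6. comparative-CT relative expression and summary-statistics t-tests.

## Coordinates and the insertion-point convention

Internally the simulator works with 0-based motif positions; every
user-facing report is 1-based inclusive. With the TSD motif occupying
1-based positions `t..t+3` of the pre-insertion chromosome, the cargo is
inserted immediately after the motif, and the modified chromosome reads
`...TTAA | cargo | TTAA...`. Calls (and simulator truth records) report the
junction as the two-base interval `(t+3, t+4)`: the genome bases flanking
the insertion point. The two junction clusters overlap by `|TSD| - 1` bases
— the left-junction clips anchor at `t+3`, the right-junction clips at `t` —
which is itself the TSD signature the caller exploits when pairing clusters.
Because the relationship between a published two-base insert-site interval
and the TTAA is convention-dependent, the TSD is reported in its own column
rather than folded into the interval.

## The aligner

The aligner is deliberately minimal: exact k-mer seeds (default `k = 45`,
the minimum seed length used for mapping this data type) looked up in a
table built over both strands of genome + transgene, followed by ungapped
extension. Scoring is match +1, mismatch −2; a read maps when its best
extension reaches `min_score = 40` (about 40 matching bases); ties break
deterministically by reference name, position, then forward strand. Seeds
are taken at the start, middle and end of each read so that a junction read
always has at least one seed clear of the breakpoint. Extension takes the
maximal-scoring segment containing the seed — the running-score argmax in
each direction — with an X-drop bound (default 20) as an early stop; on
150 bp reads this is equivalent to an exhaustive per-diagonal best-segment
scan whenever an exact seed lies inside the optimal segment, a property the
test suite checks against an independently coded exhaustive oracle. Bases
outside the chosen segment become soft clips, so the junction signal is
carried entirely in clips, never in gaps. Indels are out of scope: the
simulator introduces substitution errors only, and external indel-aware
aligners can substitute through `read_sam()` as long as clips and sequences
are present.

Duplicate removal collapses read pairs sharing both mates' (reference,
unclipped 5′ position, strand) keys, keeping the highest summed base
quality, mirroring standard coordinate-based duplicate marking.

## Junction calling

Soft clips of at least `min_clip_len = 20` bases are re-aligned with
affine-gap local (Smith–Waterman) alignment against all references, both
strands; hits must reach 95% identity over at least 20 aligned bases.
Evidence links a genome breakpoint to a transgene terminus in one of two
symmetric ways (genome-anchored read with a transgene clip, or
transgene-anchored read with a genome clip); both contribute to the same
clusters. Breakpoints within `cluster_tol = 5` bp on the same chromosome
and flank merge; a cluster reports its modal breakpoint (ties to the
smallest), spread, distinct-read support and majority orientation.
Orientation is defined as *forward* when the construct plus strand is
colinear with the genome plus strand.

A left-flank and a right-flank cluster within `|TSD| + cluster_tol` bp pair
into one call. PASS requires at least `min_support = 3` reads on **both**
junctions (single-sided evidence is reported as CANDIDATE, orientation
conflicts as AMBIGUOUS — flagged, never silently dropped). These defaults
let 20× simulated coverage pass with a wide margin (typically 10–25 reads
per junction) while keeping insertion-free data at zero PASS calls.

**Microhomology.** When a cargo terminus happens to match the genome just
beyond the junction, every read's alignment extends past the true
breakpoint and the cluster mode shifts by a base or two — in random
sequence this happens on roughly a quarter of insertions per side. The
caller therefore searches for the TSD motif over a window of up to
`cluster_tol` bases implied by either breakpoint (nearest shift first) and,
when found, re-anchors the reported interval on the motif. The TSD remains
advisory: its absence downgrades confidence but does not veto a call, since
transposons occasionally integrate atypically. The motif search can match
spurious TTAAs within the small window on genuinely atypical junctions
(~order 1-in-10 for a 4-base motif over a ~20-position window); with a
detected TSD this risk is negligible because the motif position must agree
with a cluster breakpoint.

**Validation.** For each call a hybrid reference is assembled — `flank` bp
of upstream genome + TSD + oriented cargo + TSD + `flank` bp of downstream
genome (TSD segments only when detected) — recreating the post-insertion
haplotype. Reads are re-aligned to it; a read validates a junction when it
aligns with no soft clips and covers at least `min_span = 20` bases on each
side of the boundary. Both junctions need `min_support` such reads for the
call to validate. The same machinery, run with a second vector sequence in
the transgene's role, screens for unintended vector integration
(`screen_vector_integration()`): free episomal vector yields vector-mapping
reads but no genome-linked junction clusters.

## What the simulator does and does not emulate

`simulate_paired_reads()` draws ~350 bp fragments (SD 30) uniformly over
positions and strands and reads 150 bp from each end, applying uniform
per-base substitution errors (default 0.001) and a linearly decaying Phred
profile (Q38 at cycle 1 to Q28 at cycle 150, chosen to produce realistic
sub-read-end quality without violating the Q20 filters on clean data).
Offspring genotypes transmit each hemizygous locus independently with
probability 1/2 (unlinked, autosomal, never homozygous — the backcross
design guarantees hemizygosity). Ct panels place the generating fold change
in the target gene's Ct offset so the comparative-CT estimator is exactly
invertible at zero noise.

It does **not** emulate: indel sequencing errors, adapter read-through,
PCR-duplicate enrichment beyond exact fragment repetition, GC-coverage
bias, or — most importantly — repetitive genome sequence. Toy genomes are
i.i.d. random, so 45-mers are effectively unique; a real genome's repeats
create multi-mapping reads and spurious clip hits that the identity and
support gates mitigate but which these tests cannot probe. Passing the
simulated suites therefore demonstrates the correctness of the logic under
the stated read model, not performance on repeat-rich real data.

## Transmission genetics

The expected transgene-positive fraction of a `k`-locus hemizygous carrier
× wild-type litter is `1 − (1/2)^k`; at `k = 1` the familiar 50%.
`segregation_test()` is the exact binomial test (two-sided by summing
outcome probabilities no larger than the observation's). Note that exact
tests on small discrete samples are *conservative*: the null distribution
of their p-values is super-uniform, so the meaningful correctness property
— checked in the tests — is `P(p ≤ α) ≤ α`, not exact uniformity.

`infer_locus_count()` profiles the binomial likelihood over `k = 1..k_max`
(default 10). Because `1 − (1/2)^k` saturates geometrically, neighbouring
`k` become statistically close as `k` grows: at litter size 200, `k = 3`
(expected 0.875) and `k = 4` (expected 0.9375) differ by under three
binomial standard errors, so even the exact ML rule misclassifies a
non-negligible fraction of `k = 3` litters, and all-positive litters drive
the estimate to `k_max` (flagged as saturated). The estimator reports the
full log-likelihood profile so flatness is visible rather than hidden.

`simulate_breeding()` implements the selection loop. "Strongly expressing"
selection is modelled as `max_locus_carrier` (expression proportional to
copy number); `random_carrier` is the neutral alternative — the data give
no quantitative expression model, so both are exposed, with
`random_carrier` the default used in the trajectory tests. The founder
locus count is a free parameter (default 4): it is not derivable from the
observed endpoint, only the single-locus end state is.

## Expression statistics

`delta_delta_ct()` averages replicate wells arithmetically per
sample/gene, normalises the target Ct by the reference gene, subtracts the
calibrator-group mean ΔCt and exponentiates: fold `= 2^−ΔΔCt`. No
amplification-efficiency correction is applied (the plain comparative-CT
model). `t_test_from_summary()` computes Student (pooled, default) or
Welch t-tests from group means, dispersions and sizes; SEM dispersions are
converted via `sd = sem·√n`. Published summary tables often leave the
dispersion kind (SD vs SEM) and tail convention unstated; where printed
p-values match neither standard reading, the honest treatment — taken here
— is to compute and document both interpretations rather than assert
agreement, and to verify only reproducible qualitative conclusions (e.g.
non-significance at α = 0.05).

## Numerical and testing choices

* Strict inequalities throughout QC ("more than 10% N", "below Q20"):
  boundary reads pass. N bases contribute their stored (never negative)
  quality to the mean- and fraction-based rules; mean quality is the
  arithmetic mean of Phred scores, documented because some tools average
  error probabilities instead.
* Pair filtering drops the whole pair by default (an orphan mate carries no
  pairing information for junction work); `drop_single` with an orphan
  stream is available.
* All stochastic functions take a seed and are byte-reproducible;
  `withr::with_seed` keeps the caller's RNG state untouched.
* Validation suites run at deliberately modest problem sizes chosen as the
  package's own test design: 20 seeded end-to-end recoveries on 50–200 kb
  single-chromosome genomes at 20× coverage (error rate 0.001, both
  orientations), 10 insertion-free specificity runs at 50 kb/20×, a
  1,000-read aligner/oracle equivalence sweep on 200 bp references with
  `k = 11`, and 10,000-offspring segregation checks. At 5× coverage calls
  are not guaranteed; when made they localise within a couple of bases
  (breakpoint precision degrades before sensitivity does).

## Known limitations

Single-call deconvolution only (multiple insertions are reported as
multiple independent calls, with no attempt to phase shared read support);
no discordant-pair-only calling — clip evidence is required by design; no
gapped read alignment; no mapping-quality model; annotation overlap is
computed only from a user-supplied gene interval table. The aligner and
caller are sized for toy genomes (tens to hundreds of kb); applying the
module surface to a full mammalian genome is expected to go through an
external aligner via `read_sam()`.
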