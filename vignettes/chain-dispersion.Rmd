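---
title: "Chain-based window projection and dispersion statistics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chain-based window projection and dispersion statistics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chaindisp)
```

## The procedure

`chaindisp` measures how widely the sequence content of a fixed
reference-genome window is scattered across a target genome, using UCSC
pairwise chain alignments as the only evidence. A chain is an ordered run
of gapless aligned blocks separated by gaps on the reference (`dt`) and/or
query (`dq`) side, with a header giving the spans on both sequences. For a
window *W*:

1. every chain is clipped to *W* by walking its blocks with parallel
   reference/query cursors; a block contributes the length of its
   intersection with *W*, and offsets inside a gapless block map 1:1 to
   query positions;
2. each chain with at least one overlapping block becomes one *segment*
   (its per-block detail is kept as a block count); segments are never
   merged, and multiple chains onto the same query chromosome all count —
   multi-mapping is the phenomenon of interest, not an artefact;
3. segments whose query chromosome (`qName`) is not listed in the target
   chrom.sizes table are removed *after* overlap detection and reported
   with a reason, so the assembled-chromosome filter is auditable;
4. per (species, window) the package reports accumulated coverage
   `sum(L_chain) / L_window`, the distinct-`qName` count, the
   largest-block fraction, the Top1/Top2-3/Top4-5/others burden
   decomposition, and the per-segment aligned-length distribution.

No orthology, reciprocity, or synteny filtering is applied anywhere: the
statistics deliberately describe raw chain-mapped homology.

## Coordinate conventions

Chain and BED coordinates are 0-based half-open; genome-browser strings
(`chr7:56524206-56610877`) are 1-based inclusive. A
`genomic_window` carries its convention explicitly and all internal
arithmetic converts to half-open first; under the inclusive convention the
length is `end - start + 1` (86,672 bp for the window above), and the two
conventions always agree on length. Chain query coordinates are
strand-local; reverse-strand intervals are reflected to the forward strand
(`[L - e, L - s)`) before any chromosome-level aggregation, because
dispersion is defined per chromosome, not per strand.

## Accounting choices

* **`L_chain` counts gapless-block bases** overlapping the window, not the
  chain's reference-span overlap: gaps carry no alignment evidence. A
  `mode = "span"` option exposes span-based accounting for sensitivity
  analysis; a chain still only contributes when at least one gapless block
  overlaps the window.
* **Burdens aggregate per `qName`** ("chromosomal blocks"); a chain-level
  view remains available through the segment table. Ties in the burden
  ranking are broken by `qName` lexicographic order so Top-K group
  membership is deterministic even when tied values straddle a group
  boundary.
* **Hit threshold**: a chain counts toward dispersion with as little as
  1 aligned bp by default (`min_aligned`), configurable where a stricter
  definition is wanted.
* **No score filter** is applied to chains by default; `min_score` exposes
  one, since public "all" chain files include low-scoring chains whose
  relevance is analysis-dependent.
* **Empty projections yield zero-valued summaries**, not missing records,
  so species without detectable homology stay in comparative tables.

## Genome-context classification

Loci are classified against SD and centromeric-satellite (censat) interval
tracks with strand ignored and strict half-open overlap (abutting
intervals do not overlap but have distance 0). *Pericentromeric* means
distance-to-censat `<=` `peri_threshold`; *subtelomeric* means
distance-to-the-nearer-chromosome-end `<=` `telo_threshold`; both/interior
follow. There is no canonical numeric definition of either term, so the
thresholds are explicit, mandatory, reportable parameters defaulting to
5 Mb — a scale that comfortably covers satellite-adjacent SD aprons on
Mb-sized chromosomes while keeping mid-arm loci interior. GRCh38
centromere gaps and T2T censat annotations are both ingested as generic
censat-role BED tracks; the semantic difference is metadata. Overlap and
distance queries run through IRanges; the test suite checks them against
quadratic brute-force scans.

## Expression concordance

For a locus pair measured across tissues the module reports Spearman rho
(Pearson correlation of average ranks; average ranks for ties — the
standard convention), Pearson r, the OLS slope, and the minimum Spearman
over all leave-one-tissue-out subsamples. The slope is
orientation-dependent, so the predictor is fixed as the first-named locus
and the CLI prints the orientation. Zero-variance inputs are reported as
undefined rather than coerced. No expression-level filtering is applied by
default; the module is unit-agnostic.

## The synthetic-data generators

The simulator emulates the *structure* of the study inputs, not their
sequence content: chains are coordinate-level objects and no FASTA or
divergence model is involved.

`simulate_dispersal()` places `F` fragments per target chromosome wholly
inside the reference window, each a chain with seeded aligned length,
optional internal `dt`/`dq` gaps (at most one of each pair zero, so blocks
never merge), seeded strand, plus decoy chains strictly outside the
window. Because every fragment block lies inside the window, the
per-chain aligned-base truth is known by construction, giving an exact
end-to-end oracle: projection plus summary must reproduce the ledger
integer-for-integer. Fragments on the reference may overlap each other
freely (multi-mapping). `simulate_random_chains()` drops the
inside-the-window constraint for property tests where chains must straddle
window boundaries; there the independent check is a per-base brute-force
liftover.

Six presets cross target count (few = 4, many = 12) with fragmentation
(low: 2 fragments of 3-8 kb; medium: 5 of 0.8-2.5 kb; high: 10 of
150-700 bp) on a 20 kb window, chosen so the low/few corner mimics
near-intact transfer dominated by one large block and the high/many corner
mimics pronounced dispersal with coverage well above 1 spread over many
chromosomes — the qualitative contrast between lineages with reduced and
with pronounced SD fragmentation.

`simulate_context_fixture()` plants loci at constructed distances from
censat intervals and chromosome ends, including distances exactly at and
one bp beyond the thresholds and an SD interval abutting a locus (the
half-open edge case), with the expected classification recorded from the
construction arithmetic. `simulate_expression_pair()` draws a shared
log-normal factor `x` and sets `y = slope * x * exp(N(0, noise))`; at zero
noise the pair is perfectly concordant and the OLS slope equals the
configured slope exactly. The default of 54 tissues matches the size of a
tissue-median expression panel.

All generators use one explicitly seeded local RNG stream, restore the
caller's random state, and produce byte-identical files for identical
seeds. What the simulator does **not** emulate: sequence divergence and
alignment noise, chain fragmentation produced by assembly errors,
non-uniform chromosome sizes, and correlated placement of copies within
SD blocks. Passing the recovery suites therefore demonstrates that the
*accounting* is exact, not that real chain files are clean.

## Numerical choices

Coordinates are carried as doubles (chromosome lengths exceed 32-bit
integers); values that are conceptually integers are validated as such and
written without scientific notation. Top-K fractions are checked to sum to
1 within 1e-12. Chain validation enforces the run-sum identities
`sum(size + dt) = tEnd - tStart` and `sum(size + dq) = qEnd - qStart`
strictly; a tolerant mode skips invalid records with a warning, since
public chain downloads occasionally contain truncated records. The CLI
writes a JSON run record (config echo, input checksums, package version;
no timestamp, so identical runs are byte-identical) and maps failure
classes to exit codes 2/3/4.

## Validation problem sizes

The shipped suites validate clipping against the per-base oracle on 100
random instances (windows up to 10 kb, up to 50 chains each, gaps and
reverse strands included), exact truth recovery on 100 random dispersal
configurations (up to 8 targets x 6 fragments), 50 tied concordance
fixtures of 4-60 tissues against hand-rolled rank arithmetic, and planted
context fixtures of 15 loci over three chromosomes. These sizes keep the
full suite under a minute per module while exercising every code path the
statistics depend on.

## Known limitations

* Span-mode accounting reports the reference-span overlap but still keys
  segment existence on gapless blocks; a window falling entirely inside a
  chain gap yields no segment in either mode.
* A set of aligned (reference, forward-query) position pairs is
  representable in chain format on exactly one query strand once it has
  more than one block, so strand-representation invariance is only
  testable directly on gap-free chains; multi-block reverse-strand
  correctness is covered by the per-base oracle instead.
* The pairing of co-mobilized loci (which pseudogene travels with which)
  is accepted as input, never inferred.
* Boundary-class thresholds are global per run; chromosome-specific
  thresholds (e.g. acrocentric arms) are out of scope.
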