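---
title: "Targeted virophage discovery: models, parameters and design notes"
author: "vmine maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted virophage discovery: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the workflow

Virophages — small dsDNA viruses that parasitize giant viruses inside
unicellular eukaryotes — are typically far too rare in an aquatic metagenome
for whole-metagenome assembly to recover their genomes.  The workflow this
package implements instead *baits* them out: reads are quality-filtered,
recruited by six-frame translated homology against known virophage genomes,
assembled de novo, and the resulting contigs are extended iteratively
against the complete read set until they stop growing.  A circular genome
announces itself as a terminal direct repeat on the final contig.  The
finished genome is then annotated (ORFs, protein homologs, G+C statistics,
in-silico PCR against published primer sets) and placed on a phylogeny
built from the three conserved marker proteins (packaging ATPase, cysteine
protease PRO, and major capsid protein MCP).

`runDiscovery()` chains these stages in that order; every stage is also an
exported, independently usable function.

# Stage models and their tunables

## Read quality control (`qcDataset`)

A read is truncated immediately before the first position where the mean
Phred score of the `window` bases starting there falls below `minMeanQ`,
and discarded when fewer than `minLength` bases remain.  Defaults are the
study rule: a 5-nt window against Q20 with a 50-bp length floor.  Windows
are evaluated 5'→3' only and "more than 50 bp" is interpreted inclusively
(both documented knobs).  The rule is idempotent — every full window of a
retained read passes — and monotone in `minMeanQ`.

## Translated homology search (`recruitReads`, `translatedAlign`)

Both recruitment stages are tblastx-style: all 36 (query frame, subject
frame) pairs are scanned for gapped local alignments in amino-acid space
under BLOSUM62 with affine gaps (open 11, extend 1).  Raw scores become
E-values through the Karlin–Altschul form \(E = Kmn\,e^{-\lambda S}\) with
the published gapped-BLOSUM62 constants \(\lambda = 0.267\), \(K = 0.041\)
as defaults; because the original analysis ran inside an external tool
whose internal constants are unknowable, the *cutoffs* — 1e-5 for the
permissive multi-genome scan, 1e-10 with one hit per read for the strict
bait stage, 1e-3 for protein annotation — are what define the method, and
the constants are configurable.  The effective search space uses the
frame-summed lengths (6 query frames times the summed subject frame
lengths).

Large frame pairs are searched by two-hit word seeding (3-aa exact words;
stops and ambiguity codes never seed) followed by banded Smith–Waterman
around the seed diagonals; small pairs (and protein annotation) use
exhaustive dynamic programming.  `mode = "full"` forces the exhaustive
path everywhere.  Ties for the single best hit per read break by E-value,
then score, then lexicographic subject id, so recruitment is
deterministic.

## Assembly (`denovoAssemble`, `referenceExtend`, `detectTerminalRepeat`)

De novo assembly is greedy overlap-layout-consensus: repeatedly merge the
pair with the longest qualifying overlap (>= 25 bp at >= 80% identity, the
study thresholds), ties broken by identity then lexicographic id;
consensus is the per-column majority with ties kept at the earlier-merged
base, and depth is recorded per column.  Iterative extension maps every
read (both orientations) to the current contig at >= 25 bp / >= 90%,
recomputes the consensus, and accepts overhang columns with >= 2
supporting reads (single-read overhangs only when no deeper support
exists) until the length reaches a fixed point.

Overlaps and mappings are located by exact 12-mer seeds (query k-mers
sampled every 4 positions; a shared word is still guaranteed for any
error-free overlap >= 15 bp) and scored *gapless*.  This is a deliberate
design choice: the read simulator injects substitution errors only —
matching the dominant MiSeq error mode — so a gapless overlap computation
is exact for every input the assembler ever sees, and it keeps the
per-column consensus bookkeeping exact, which is what makes "collapsed
circular length equals the truth exactly" a testable property rather than
an approximation.  Reads with indel-scale artifacts would require a banded
aligner in the overlap step; that extension is out of scope here.

Extension over a circular genome would otherwise wrap forever, so the loop
also stops as soon as the contig's ends carry an exact terminal direct
repeat of at least `minTerminalRepeat` bp (default = `minOverlap`) — the
same signal targeted organelle/plasmid assemblers use.
`detectTerminalRepeat()` then finds the longest exact prefix/suffix match
(KMP border computation; a mismatch-tolerant scan is available behind
`repeatMaxMismatch`), collapses one copy, folds its depth onto the
retained prefix, and reports the circular length as original minus repeat.
Circular contigs are rotated so position 1 is the start codon of the
longest forward ORF, giving a canonical origin.

## Annotation (`predictOrfs`, `annotateProteins`, `insilicoPcr`)

ORF calling is the study rule: in each of six frames, each stop-to-stop
interval contributes one ORF from its *first* ATG through the stop,
reported when the span is >= 150 nt.  Cross-frame overlaps are all kept;
same-frame nested ORFs only exist under the `firstAtgOnly = FALSE` knob
and are suppressed by default there.  On circular sequences the scan runs
over the doubled sequence, keeps ORFs starting in the first copy with span
<= genome length, and de-duplicates the origin-crossing locus in favor of
the ORF with full upstream context.  Coordinates are strand-aware and
1-based inclusive: start is the first base of ATG on the ORF's own strand,
end the last base of the stop codon, so start > end on the reverse strand
and every record satisfies `nt_len %% 3 == 0` and
`aa = nt_len/3 - 1`.

Protein annotation takes each ORF against the local database with
exhaustive Smith–Waterman and reports the best hit at E <= 1e-3; ORFs
without a qualifying hit are flagged ORFans.  In-silico PCR finds
forward-primer sites on either strand and reverse-complement
reverse-primer sites downstream on the amplifiable orientation, allowing
`maxMismatch` substitutions and no indels; circular templates are scanned
across the origin and a `maxProduct` cap (default 10 kb) excludes
"long-way-around" products that every circular site pair would otherwise
imply.  The G+C skew track uses 500-bp windows stepped by 100 bp — window
sizes the original tooling does not state, chosen to resolve ~29-kb
genomes and documented as defaults.

## Phylogeny (`concatMarkers`, `alignProteins`, `njTree`, `bootstrapTree`)

The phylogenetic claim the workflow supports is topological (which known
virophage the discovery clusters with, and whether the new MCPs are
monophyletic), so the likelihood machinery of the original analysis is
replaced by a self-contained distance pipeline: per-marker center-star
progressive alignment (the center maximizes summed pairwise global BLOSUM62
scores; merges follow "once a gap, always a gap"), concatenation in the
fixed order ATPase–PRO–MCP with gap-fill for missing markers and recorded
block boundaries, pairwise-deletion p-distances (optionally
Poisson-corrected, \(-\ln(1-p)\)), canonical neighbor joining with
deterministic tie-breaking by taxon order and negative branch lengths
clamped to zero with the deficit moved to the sibling, and bootstrap
supports from `n` column resamples (100 by default, matching the study)
attached to bipartitions so they survive rerooting.  Gap treatment before
tree building is pairwise deletion, the documented default.  NJ is
consistent on additive matrices, which the tests verify exhaustively for
4–6 taxa.

# The synthetic study (`SimulationConfig`, `makeDemo`)

Because the original sequencing data were never deposited, a seeded
generator stands in for them, and its defaults *are* the study conditions:
a 28,788-bp circular genome at 43.2% G+C bearing 28 ORFs, 2 × 251 bp read
pairs from a 430-bp insert library, and a bait relative at 0.35
substitutions per site, which lands recovered amino-acid identities in the
33–70% band reported for the closest known relative.  Values the study
does not state were fixed once on field-typical grounds: insert-size SD 43
bp (~10%), per-base substitution error 0.5% (MiSeq era), single-base bait
indels at 0.001/site (indels are strongly selected against in coding-dense
viral genomes), 2,000 read pairs and 25% unrelated background as free
depth parameters.

Mechanics worth knowing when interpreting test results:

* **ORF planting.**  Each planted cassette is an in-frame guard stop, ATG,
  a stop-free codon body, and a stop.  The guard makes the planted ATG
  provably the first ATG of its stop-to-stop interval, so the ORF caller
  recovers every planted ORF at its exact coordinates (a closure property
  the annotation tests rely on).  Cassettes are placed disjoint, longest
  first, by rejection sampling: overlapping cassettes would overwrite each
  other and break that closure.  Cross-frame overlapping ORFs still arise
  spontaneously in the genomic background, as they do in real genomes.
* **Composition control.**  The intergenic background is drawn with exact
  base counts, and the codon-body letter rate is root-found so that, after
  stop-codon rejection (stops are AT-rich) and accounting for the fixed
  AT-rich cassette codons, the whole-genome expectation equals
  `gcTarget`.  Realized G+C at study scale stays within about half a
  percentage point of the target.
* **Reads.**  Fragments follow a truncated normal insert distribution,
  wrap the origin of circular genomes, and receive per-cycle Gaussian
  Phred scores (profile declining 38→28, SD 3, clipped to [2, 41]) —
  enough structure to exercise the windowed trimmer.  Errors are
  substitutions drawn per base; each read's truth row records its source,
  fragment coordinates, strand and injected error count.  Background pairs
  come from an i.i.d. sequence at the same G+C so recruitment specificity
  is measurable against truth labels.
* **What the simulator does not model** — platform-specific error
  structure (quality-by-dinucleotide, optical duplicates), chimeric reads,
  indel sequencing errors, and real genomes' codon usage or repeat
  families.  Passing tests therefore demonstrate that the machinery is
  correct under an idealized but parameterically faithful model, not that
  recruitment sensitivity on real lake water would match the study's.

`makeDemo()` freezes a complete miniature study (20-kb genome, 20 ORFs,
bait at 0.30 substitutions/site, ~40× coverage plus background, a
`taxon|marker` protein database of diverged pseudo-relatives at
0.35–0.7/residue) and `runDiscovery()` on it recovers the planted circular
genome exactly — length, rotation and all planted ORFs — and places the
assembly next to its closest pseudo-relative with full bootstrap support.
The scale was chosen so a full run fits comfortably in a few minutes on
one CPU; the study-scale defaults run the same code, only longer.

# Numerical and degenerate-input choices

* Alignment scores are integers; E-value comparisons and sorts are exact,
  and all tie-breaks (subject id, taxon order, earlier-merged consensus
  base, ACGT order) are lexicographic, making every stage
  seed-deterministic end to end.
* Reads shorter than one codon translate to empty frames and are silently
  unmatchable rather than errors; all-N sequences are rejected by
  `gcContent()` with a clear message.
* A terminal repeat equal to the whole contig is degenerate and raises an
  error; a repeat equal to half the contig legitimately collapses a
  doubly-traversed circle.
* `referenceExtend()` is guaranteed to terminate: length is
  non-decreasing, bounded by the total read bases, and capped by
  `maxIterations`.
* Triangle-inequality violations in a distance matrix produce a warning,
  never a failure — p-distances from gappy alignments can mildly violate
  it without invalidating NJ.

# Known limitations

* The gapless overlap scorer makes the assembler blind to indel sequencing
  errors; inputs from indel-prone platforms would need the overlap stage
  swapped for a banded aligner.
* The seeded translated search can in principle miss a homology with no
  two clustered exact 3-aa words; the exhaustive mode exists for audits
  and small inputs, and the tests verify agreement on clear homologies.
* Center-star alignment carries the classical 2-approximation guarantee
  rather than MUSCLE-quality refinement; for the conserved markers this
  workflow uses, the induced pairwise identities track the optimal
  pairwise alignments closely (tested).
* The greedy assembler is exact on unique-layout instances (tested against
  exhaustive layout search) but, like all greedy OLC, can collapse exact
  repeats longer than the read length; the study genome and the simulator
  avoid that regime.
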