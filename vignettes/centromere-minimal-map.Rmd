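---
title: "Building a minimal molecular map of a repetitive centromere"
author: "CenCoreMap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building a minimal molecular map of a repetitive centromere}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CenCoreMap)
```

## The problem

Centromeres of plants are built from megabase-scale tandem satellite
arrays (in maize, the 156-bp CentC repeat) interleaved with centromeric
retrotransposons (the CRM families) and, on the supernumerary B
chromosome, a B-specific repeat. The functional centromere is defined
epigenetically, by occupancy of the centromeric histone H3 variant CENH3,
and the standard assay is CENH3 ChIP-seq. But ChIP-seq needs a reference
on which short reads map uniquely, and for a chromosome absent from the
genome assembly no such reference exists.

The strategy this package implements exploits a simple fact: when a
retrotransposon inserts into other repeats, the insertion *junction* is
unique even though both sides of it are repetitive. Junction tags are
harvested by transposon display (TD) -- an AFLP-style assay in which a
primer anchored in the conserved LTR of a retroelement family is paired
with an adapter primer ligated at a restriction site, with three selective
bases on the adapter reducing band complexity (64 selective-triplet lanes
cover all possibilities). Tags specific to the chromosome of interest are
mapped by *deletion mapping* across a pedigree of centromere-misdivision
derivatives (chromosomes that lost one side of the centromere through
erroneous fission), ordered by their loss pattern, and concatenated into
an N-spaced pseudocontig -- a "minimal map" -- that serves as the ChIP-seq
alignment reference. A multi-library classification rule then identifies
the markers that interact with CENH3, and in-silico junction-junction PCR
converts a subset into simple presence/absence assays for genotyping
further derivatives.

All stages run on synthetic data generated by the package itself, so the
entire pipeline is testable without downloads.

## The synthetic world

`buildRepeatLibrary()` draws the repeat units: a 156-bp CentC-like tandem
monomer, a CRM2-like element (LTR -- internal -- LTR, 620 bp by default),
a B-repeat-like unit and filler retroelements, audited so that distinct
units share no exact 20-mers. The selective primer annealing segment sits
112 bp from the LTR end, so every amplified band carries 112 bp of LTR --
the tail -- plus flanking DNA up to the nearest BfaI site (C^TAG; the
recognition site and cut offset are configurable through `enzymeSpec()`).

`simulateCentromere()` assembles a backbone of CentC arrays interleaved
with B-repeat blocks and performs nested element insertions at random
positions and orientations, recording every junction. Three modeling
choices matter and are deliberate:

* **Repeat copies diverge.** Each placed copy is independently mutated
  (defaults: CentC 15%, B repeat 10%, CRM2 10% per base). Real satellite
  monomers and old retroelement families diverge at this scale, and this
  acquired polymorphism is precisely what makes junction flanks
  effectively unique at read length -- the premise of the whole method.
  Without it, no read interior to a marker flank can map uniquely and the
  full-coverage classification criterion is unattainable. Intermediate
  divergence (5--8%) is the worst regime: copies are similar enough to
  share exact 40-mer seeds yet different enough that one copy near the
  consensus becomes an "attractor" that soaks up reads from all the
  others; the defaults sit above that regime.
* **The 112-bp LTR tail is held at consensus.** This is the
  primer-bearing end of the element; its conservation is why a single
  primer pair amplifies every copy. It also means every marker's LTR
  portion is identical, so reads wholly within a tail tie across markers
  and are discarded by the unique mapper -- a marker's mappable
  uniqueness resides entirely in its flank, as for real junction tags.
* **Only the outward-pointing tail amplifies.** Both edges of an
  insertion are recorded as junctions, but the display primer extends
  outward across only one of them (the right edge of plus-orientation
  copies, the left edge of minus copies), so each insertion contributes
  one flank band; bands primed off the interior-facing tail terminate at
  a restriction site placed inside the element and cancel between
  genotypes.

Default scale is a ~180-kb centromere (five arrays of 150 monomers, 100
insertions) and a 36-kb background genome carrying filler elements and a
few CRM2 copies -- scaled down from the real 700-kb core so that
everything runs in seconds, with all sizes configurable.

`derivePedigree()` models misdivision as a single one-sided terminal
excision per event, so retained intervals are nested down the pedigree;
ring derivatives are out of scope. The default specification mirrors the
published pedigree topology: progenitor to pseudoisochromosome (PI), two
second-generation telocentrics from PI, an isochromosome and a core-less
telocentric from Telo2-1, and a fourth-generation telocentric whose cut
coincides exactly with Telo2-2's retained interval. The core-less
derivative retains a sub-marker-sized remnant (fraction 0.999), modeling
a line with no canonical centromere sequence left. Published transmission
rates (0.53 for Iso3, 0.43 for Telo2-2 and its look-alike) ride along as
metadata; they are biological observations used as inputs, never computed.

`simulateChipReads()` draws 150-nt single-end read start positions with
density proportional to 1 outside enriched intervals and to the requested
fold inside them, from both strands, error-free by default. For
`fragmented_control` libraries density is uniform; for `inactive_chip`
libraries the enrichment map is suppressed entirely. The specification of
an inactive library might be read as forcing fold 1 only within the
annotated CENH3 domain, but the fold map models CENH3 occupancy and an
epigenetically inactivated centromere has none anywhere; suppressing only
part of it would leave fictitious CENH3 signal wherever occupancy was
planted outside the default central sub-interval.

## Transposon display and marker screening

`runDisplay()` scans both genotype genomes once for outward-oriented
annealing sites, extends each to the nearest downstream cut boundary, and
distributes bands over the 64 lanes; `callBSpecific()` keeps bands whose
size bin is present in the B-plus lane and absent from the B-minus lane;
`collapseAndName()` merges identical sequences, unioning selective
triplets into names of the form `CRM2-<triplets>-<size>`, and
`parseMarkerName()` inverts the naming. Weak selectivity of real adapter
primers is modeled by `mismatchTolerance` (0 by default for
reproducibility; 1 reproduces multi-triplet names).

The real study sequenced 250 bands, collapsed them to 61 unique markers
and discarded 21 that fell outside the centromere. `selectMarkerPanel()`
plays the same curatorial role on synthetic bands. A panel marker must

1. originate from the centromere and carry a recorded junction,
2. have at least 21 bp of LTR before the junction (a primer anchor) and
   at least 40 bp of flank beyond it,
3. derive from a single genomic locus,
4. have an *effectively unique* flank: no 40-mer of the flank (the
   mapper's seed length) occurs more than once in the centromere on
   either strand -- this rejects, for example, bands from elements that
   inserted into another copy's conserved tail, whose "flank" is exactly
   repeated text, and
5. not overlap another band's source interval (of two overlapping bands
   only the shorter is kept, since duplicated text in the reference can
   never be covered uniquely).

Markers are then ordered by loss pattern (`partitionMarkers()`, groups
ordered by the generation of first loss along the main pedigree chain,
ties broken by discovery id, matching the layout of the published marker
table) and concatenated by `buildPseudocontig()` with 200-N spacers.

## Mapping and enrichment

`mapReads()` is a desk-scale stand-in for the aligner / MAPQ-filter /
pileup chain used on real data: exact 40-mer seeds at three read offsets
in both orientations, ungapped extension, and retention only when a
single best placement beats the runner-up by at least 5 matching bases
*and* matches its in-reference span to within 2 mismatches. The identity
requirement is not in the original filter's letter but is in its spirit:
in a genome of diverged repeat copies whose true loci are absent from the
reference, a read can have a single, mediocre (~80% identity) best
placement with a large margin -- an alignment no production aligner would
report confidently -- and the margin alone cannot reject it. Overhang
into N spacers or past a reference end counts as neither match nor
mismatch, so reads overlapping marker edges still anchor coverage there.

`computeEnrichment()` scales coverage per million mapped reads and
divides each marker's mean per-base unique coverage by the genome-wide
mean over the background references; `junctionCoverage()` flags a marker
only when every base has depth and every recorded junction is spanned by
a read with ten bases on both sides. Peak calling is deliberately not
reimplemented: fold over predefined marker intervals is the quantity the
analysis interprets.

Because only junction-spanning fragments map uniquely over the shared
tail, a marker's mean fold under-reports its planted fold by a factor
that shrinks as the flank grows (roughly `(0.58 * 112 + flank) /
(112 + flank)`). The experiment driver therefore plants the weakest
occupancy signal (threefold, the published value of the weakest CENH3
marker) on the eligible marker with the longest flank, and plants only on
markers with at least one read length of genomic clearance from every
other panel marker, since occupancy spills over fragment-length distances
and would otherwise confound a neighbour's call. Both rules are
deterministic measurement-design choices, fixed before any classification
is run.

## Classification and the core span

`classifyCore()` applies the multi-library rule: a marker is core iff its
fold exceeds `tActive` in every active replicate, stays at or below
`tInactive` (twofold) in every inactive-centromere replicate, has no
unique coverage in any negative or fragmented control (the strictest
reading of "no enrichment", configurable through `controlCeiling`), and
passes junction coverage in every active replicate. The active threshold
default of 2 is the largest round value below the published threefold
enrichment of the weakest genuine core marker; the original analysis
never states its cutoff, so it is exposed as a parameter. Classification
is monotone: raising `tActive` or lowering `tInactive` can only remove
calls.

`inferCoreSpan()` implements the reproducible part of combining ChIP
calls with derivative biology: the core domain is the set of minimal-map
markers retained in the *smallest functional derivative* -- the
derivative with the fewest retained markers whose transmission rate is
still at least 0.5. On the packaged fixture that derivative is Iso3
(transmission 0.53), giving the 33-marker span TD8--TD40. Note the span
may exclude a CENH3-positive marker (TD7) whose loss was tolerated: core
status and span membership are related but not identical, which is why
the function only requires the span to contain at least one core call.

`designJunctionPrimers()` converts markers into simple PCR assays. The
forward primer straddles the LTR/flank insertion junction itself (a
primer wholly within the LTR occurs at every element copy and can never
give a single product in a world with a conserved tail); the reverse
primer sits downstream in the flank, preferring windows that straddle a
second junction. A pair is accepted only if it amplifies exactly one
product from the B-plus genome and none from the B-minus genome;
`insilicoPCR()` scans primer sites in convergent orientation within a
size bound, with exact matching and no thermodynamics.

## What a green test establishes -- and what it does not

The synthetic world reproduces the *structure* of the real experiment:
nested repeats with unique junctions, nested terminal deletions, library
roles, the published per-marker enrichment values used as simulation
parameters, and the published presence/absence table shipped verbatim as
a fixture. It does not emulate sequencing error profiles, PCR bias,
chromatin accessibility, fragment-length distributions (reads are fixed
length and single-end), gapped alignment (no indels are simulated), or
the real genome's full repeat census. Numbers that depend on the real
sequencing libraries -- such as the measured 36-fold enrichment of the
strongest marker -- are not reproduced, only used as planted parameters;
a green end-to-end test establishes that the pipeline recovers what was
planted, at desk scale, under the stated noise model.

## Numerical choices and degenerate inputs

Coordinates are 1-based and closed throughout (IRanges convention). Band
sizes are exact integers (gels resolve integers), equal to the genomic
band length plus a configurable adapter constant (default 0). A genome
with no annealing sites amplifies nothing (not an error); a digest with
no restriction sites returns one fragment; an empty marker list refuses
to build a pseudocontig; a library with zero genome coverage is rejected
as degenerate. Every operation is a pure function of its inputs and a
seed: one master seed fans out to per-operation child seeds through a
fixed polynomial hash, and the RNG state of the caller is always
restored.

## Known limitations

The mapper is ungapped and single-end; the display model has no
thermodynamics (annealing is exact string matching, selectivity is a
Hamming-distance tolerance); misdivision is strictly one-sided terminal
deletion, so rings and centromere-gain events are out of scope; and the
minimal map's within-group marker order is arbitrary (fixed to discovery
order for determinism), exactly as the relative arrangement of real
never-lost markers is unknown.
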