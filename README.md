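# CenCoreMap

Tools for building a minimal molecular map of a highly repetitive
centromere from retroelement junction markers, and for locating the
functional centromere core on that map with CENH3 ChIP-seq.

Centromeres like that of the maize B chromosome are built from tandem
satellite arrays (the 156-bp CentC repeat), centromeric retrotransposons
(CRM families) and a B-specific repeat; no single-copy sequence exists to
anchor short reads. The method implemented here exploits the uniqueness
of transposon *insertion junctions*:

1. **In-silico transposon display (TD).** A primer in the conserved CRM2
   LTR is paired with an adapter at BfaI (C^TAG) restriction sites, with
   3 selective bases per lane (all 64 lanes). Bands present in a
   B-carrying genotype and absent from the B-less control are junction
   tags of the B centromere.
2. **Deletion mapping.** Tags are scored (+/−) across a pedigree of
   centromere-misdivision derivatives — chromosomes that lost one side of
   the centromere — partitioned by loss pattern, and ordered into a
   minimal map. The published 40-marker presence/absence table ships as a
   fixture (`table1Fixture()`).
3. **Pseudocontig assembly.** Marker sequences are concatenated with
   200-N spacers (`buildPseudocontig()`); the result is the ChIP-seq
   alignment reference.
4. **Unique-read mapping and enrichment.** A seed-and-extend mapper
   (40-mer seeds, uniqueness margin, near-perfect identity) stands in for
   the aligner/MAPQ/pileup chain; fold enrichment is mean marker coverage
   over the genome-wide average, per million mapped reads.
5. **Core classification.** A marker is functional-core iff it is
   enriched (> 2-fold) in *every* active-centromere replicate, at most
   2-fold in every inactive-centromere replicate, has *zero* unique
   coverage in negative/fragmented controls, and shows full junction
   coverage. The core *span* is the set of markers retained in the
   smallest derivative whose transmission is still normal
   (`inferCoreSpan()`), and junction-junction PCR primers
   (`designJunctionPrimers()`, `insilicoPCR()`) genotype further
   derivatives.

A synthetic-data module (`buildRepeatLibrary()`, `simulateCentromere()`,
`derivePedigree()`, `simulateChipReads()`) generates a scaled-down
centromere with nested, diverged repeat copies, a misdivision pedigree
and ChIP/control read sets, so the entire pipeline runs and is tested
without any downloads.

## Worked example

```r
library(CenCoreMap)
ex <- runCentromereExperiment(42)
ex
#> CentromereExperiment (seed 42)
#>   centromere: 181400 bp; markers: 148 discovered, panel of 40
#>   core markers called: TD7, TD9, TD16, TD18, TD21, TD28, TD35
#>   core span: 31 markers from derivative Iso3

round(foldEnrichment(ex$enrichment)[ex$corePositions, 1:5], 2)
#>      active_1 active_2 active_3 inactive_1 inactive_2
#> TD7     29.54    29.53    30.78       0.70       0.95
#> TD35     2.92     2.81     2.91       0.97       0.87
#> TD9     13.54    12.72    12.69       0.70       0.69
#> TD16    10.97    10.58    10.91       1.01       0.91
#> TD18    18.37    17.54    18.51       0.69       0.89
#> TD21     5.76     4.99     5.39       0.86       0.86
#> TD28    24.60    25.18    26.93       0.86       0.73

ex$genotypes["TD7", ]
#>    TB9Sb       PI  Telo2_1  Telo2_2     Iso3  Telo3_3 Telo4_11
#>     TRUE     TRUE    FALSE    FALSE    FALSE    FALSE    FALSE
```

The seven active/inactive/control folds above are the planted values 36,
3, 18, 12, 23, 6, 31 as recovered by unique-read mapping: enrichment on a
marker under-reports its planted fold by a flank-dependent factor because
only junction-spanning fragments map uniquely over the shared LTR tail
(see the vignette). On the published fixture the deletion-mapping results
reproduce exactly:

```r
fx <- table1Fixture()
lengths(markerGroups(partitionMarkers(fx$matrix)))
#> +---- ++--- +++-- ++++- +++++
#>     5     1     1     2    31
sum(!presenceValues(fx$matrix)[, "Telo2_2"])
#> [1] 9
```

The experiment simulates the seven-library design (three active
replicates, two inactive, a negative ChIP and a fragmented control) with
CENH3 occupancy planted on seven panel markers at the published
enrichment values; the classifier recovers exactly the planted set, the
core span follows the smallest functional derivative, and the seven
junction-junction primer pairs amplify nothing from the core-less
derivative while the fourth-generation derivative matches Telo2-2.

See the vignette (`vignettes/centromere-minimal-map.Rmd`) for the model,
its assumptions and the design decisions.

## Acceptance script

`scripts/acceptance.R` re-runs the full end-to-end experiment from
scratch at a given seed — simulation, display, deletion mapping, map
assembly, read mapping, classification and PCR genotyping — and writes a
JSON results file:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
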