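## End-to-end orchestration of the synthetic experiment: simulate genomes,
## run the display, build the minimal map, simulate the seven-library ChIP
## design, map, score enrichment and classify core markers.

#' Select the marker panel used for the minimal map
#'
#' Mirrors the screening applied to real display bands before they became
#' mapped markers: a panel marker must originate from the centromere, carry
#' a recorded junction preceded by an LTR segment long enough to anchor a
#' primer, derive from a single genomic locus, retain at least `minFlank`
#' bases of flanking sequence beyond its first junction (a junction marker
#' with almost no flank is uninformative at read scale), have an
#' effectively unique flank -- no `kUnique`-mer of the flank may occur more
#' than once in the centromere on either strand, since a flank made of
#' exactly repeated text (for instance an element inserted into another
#' copy's conserved LTR tail) can never be covered by uniquely mapping
#' reads -- and must not overlap another band's source interval
#' (overlapping bands share sequence and cannot be scored independently).
#'
#' @param markers Marker table from [collapseAndName()] (with junction
#'   annotations).
#' @param layout The source [CentromereLayout-class].
#' @param minFlank Minimum flank length beyond the first junction.
#' @param minLtr Minimum LTR segment length before the first junction.
#' @param kUnique Word size of the flank-uniqueness screen (the mapper's
#'   seed length).
#' @return The admissible subset of `markers` (discovery order).
#' @export
selectMarkerPanel <- function(markers, layout, minFlank = 40L, minLtr = 21L,
                              kUnique = 40L) {
  label <- layout@seqnameLabel
  keep <- markers$seqname == label & lengths(markers$junctions) > 0L
  j1 <- vapply(seq_len(nrow(markers)), function(i) {
    js <- markers$junctions[[i]]
    if (length(js)) js[1L] else NA_integer_
  }, integer(1))
  flank <- nchar(markers$sequence) - j1 + 1L
  keep <- keep & !is.na(j1) & j1 >= minLtr + 1L & flank >= minFlank &
    markers$nSources == 1L
  ## multi-copy words of the centromere (both strands)
  g <- as.character(layoutSequence(layout))
  n <- nchar(g) - kUnique + 1L
  kms <- c(substring(g, 1:n, kUnique:nchar(g)),
           substring(revComp(g), 1:n, kUnique:nchar(g)))
  multi <- unique(kms[duplicated(kms)])
  flankUnique <- function(i) {
    fl <- substr(markers$sequence[i], j1[i], nchar(markers$sequence[i]))
    m <- nchar(fl) - kUnique + 1L
    if (m < 1L) return(FALSE)
    !any(substring(fl, 1:m, kUnique:nchar(fl)) %in% multi)
  }
  keep[keep] <- vapply(which(keep), flankUnique, logical(1))
  sub <- markers[keep, ]
  if (nrow(sub) > 1L) {
    ## keep a non-overlapping subset, preferring shorter bands: of two
    ## bands sharing genomic sequence only one may enter the minimal map,
    ## otherwise the shared segment is duplicated in the reference and no
    ## read over it maps uniquely
    o <- order(nchar(sub$sequence), sub$start)
    kept <- IRanges::IRanges()
    take <- logical(nrow(sub))
    for (i in o) {
      r <- IRanges::IRanges(sub$start[i], sub$end[i])
      if (!length(kept) ||
          !any(IRanges::overlapsAny(r, kept))) {
        take[i] <- TRUE
        kept <- c(kept, r)
      }
    }
    sub <- sub[take, ]
  }
  sub
}

#' Run the full synthetic centromere-mapping experiment
#'
#' Simulates a repeat library, a centromere with nested CRM2-like
#' insertions, a background genome and the misdivision pedigree; runs the
#' 64-lane transposon display of the B-plus versus B-minus genotypes; calls
#' B-specific bands, collapses them to named markers, screens and orders a
#' marker panel by loss pattern, and assembles the minimal-map pseudocontig.
#' Optionally simulates the multi-library ChIP design (active replicates
#' with CENH3 occupancy planted over the markers at `corePositions` with
#' the given fold enrichments, inactive-centromere replicates, a negative
#' ChIP and a fragmented-genome control), maps all libraries and classifies
#' core markers; and optionally designs junction-junction primer pairs for
#' the planted core markers and genotypes every derivative in silico.
#'
#' @param seed Integer master seed (all randomness derives from it).
#' @param nCrmInsertions CRM2-like insertions in the centromere (default 100,
#'   enough that the screened panel reliably reaches `panelSize`).
#' @param panelSize Number of markers in the minimal map (default 40).
#' @param corePositions Minimal-map positions (1-based) where CENH3
#'   occupancy is planted.  The default (`NULL`) selects, for each of the
#'   published CENH3-marker positions (7, 9, 10, 15, 18, 21, 29), the
#'   nearest panel marker whose genomic locus has at least one read length
#'   of clearance to every other panel marker: occupancy spills over
#'   fragment-length distances, so planting hard against a neighbouring
#'   marker would confound that neighbour's call.
#' @param coreFolds Planted fold enrichments (default: the published
#'   per-marker enrichment values 36, 3, 18, 12, 23, 6, 31).
#' @param nActive,nInactive Replicate counts (default 3 active, 2 inactive,
#'   matching the seven-library design with one negative ChIP and one
#'   fragmented control).
#' @param readLength Read length (default 150 nt single-end).
#' @param depth Expected background unique coverage per library (default 20).
#' @param k Seed length for mapping (default 40).
#' @param minMargin Uniqueness margin for mapping (default 5).
#' @param spacerLength Pseudocontig spacer (default 200 Ns).
#' @param doChip,doPcr Stage switches.
#' @return List of class `CentromereExperiment` with the simulated objects,
#'   marker panel, presence matrix, partition, pseudocontig, enrichment
#'   table, core call and (optionally) primer pairs and PCR genotypes.
#' @export
runCentromereExperiment <- function(seed,
                                    nCrmInsertions = 100L,
                                    panelSize = 40L,
                                    corePositions = NULL,
                                    coreFolds = c(36, 3, 18, 12, 23, 6, 31),
                                    nActive = 3L, nInactive = 2L,
                                    readLength = 150L, depth = 20,
                                    k = 40L, minMargin = 5L,
                                    spacerLength = 200L,
                                    doChip = TRUE, doPcr = TRUE) {
  stopifnot(is.null(corePositions) ||
              (length(corePositions) == length(coreFolds) &&
                 all(corePositions >= 1L) &&
                 all(corePositions <= panelSize)))
  lib <- buildRepeatLibrary(seed)
  primers <- tdPrimers(lib)
  chain <- c("TB9Sb", "PI", "Telo2_1", "Iso3", "Telo2_2")
  ## the number of admissible markers is stochastic; if the screened panel
  ## comes up short, rebuild the centromere with proportionally more
  ## insertions (deterministic in the seed)
  nIns <- nCrmInsertions
  for (attempt in 1:4) {
    layout <- simulateCentromere(lib, nCrmInsertions = nIns, seed = seed)
    background <- simulateBackground(lib, seed = seed)
    bPlus <- setNames(Biostrings::DNAStringSet(list(
      background@sequence, layout@sequence)),
      c(background@seqnameLabel, layout@seqnameLabel))
    bMinus <- bPlus[background@seqnameLabel]

    profiles <- runDisplay(bPlus, bMinus, primers = primers)
    specific <- callBSpecific(profiles)
    if (nrow(specific) == 0L) stop("display produced no B-specific bands")
    specific <- annotateBandJunctions(specific, layout)
    markersAll <- collapseAndName(specific)
    admissible <- selectMarkerPanel(markersAll, layout)
    if (nrow(admissible) >= panelSize) break
    if (attempt == 4L)
      stop("only ", nrow(admissible), " admissible markers; panelSize = ",
           panelSize)
    nIns <- as.integer(round(nIns * 1.25))
  }
  derivatives <- derivePedigree(layout)
  mAll <- scorePresence(admissible, derivatives)
  partAll <- partitionMarkers(mAll, chain = chain)
  ordered <- orderMarkers(admissible, partAll)
  panel <- utils::head(ordered, panelSize)
  rownames(panel) <- panel$id <- paste0("TD", seq_len(nrow(panel)))

  ## rebuild the presence matrix on the panel (rows renamed to map order)
  vAll <- presenceValues(mAll)
  vPanel <- vAll[match(panel$discoveryId, rownames(vAll)), , drop = FALSE]
  rownames(vPanel) <- panel$id
  matrix <- presenceMatrix(vPanel, mAll@pedigree, mAll@transmission)
  partition <- partitionMarkers(matrix, chain = chain)
  pseudocontig <- buildPseudocontig(panel, spacerLength = spacerLength)

  if (is.null(corePositions)) {
    ## occupancy is planted on markers whose genomic locus has at least one
    ## read length of clearance to every other panel marker (occupancy
    ## spills over fragment-length distances) and whose flank is long
    ## enough that the marker-mean fold is not dominated by the shared LTR
    ## tail, where only junction-spanning fragments map uniquely; for each
    ## target position take the nearest eligible marker
    gaps <- vapply(seq_len(nrow(panel)), function(i) {
      d <- pmax(panel$start[i] - panel$end[-i], panel$start[-i] - panel$end[i])
      min(d)
    }, numeric(1))
    j1 <- vapply(seq_len(nrow(panel)), function(i)
      panel$junctions[[i]][1L], integer(1))
    flankLen <- nchar(panel$sequence) - j1 + 1L
    eligible <- which(gaps >= readLength & flankLen >= 100L)
    if (length(eligible) < length(coreFolds))
      stop("too few panel markers with genomic clearance for planting")
    ## the weakest occupancy signal goes on the eligible marker with the
    ## longest flank: only junction-spanning fragments map uniquely over
    ## the shared LTR tail, so a marker's mean fold under-reports its
    ## planted fold by a factor that shrinks with flank length, and the
    ## fold closest to the twofold decision boundary needs the most
    ## uniquely mappable sequence to be resolved
    corePositions <- integer(length(coreFolds))
    weakest <- which.min(coreFolds)
    corePositions[weakest] <- eligible[which.max(flankLen[eligible])]
    target <- c(7L, 9L, 10L, 15L, 18L, 21L, 29L)[seq_along(coreFolds)]
    for (s in setdiff(seq_along(coreFolds), weakest)) {
      free <- setdiff(eligible, corePositions)
      corePositions[s] <- free[which.min(abs(free - target[s]))]
    }
  }

  out <- list(seed = seed, library = lib, layout = layout,
              background = background, derivatives = derivatives,
              markersAll = markersAll, panel = panel, matrix = matrix,
              partition = partition, pseudocontig = pseudocontig,
              corePositions = corePositions, coreFolds = coreFolds)
  class(out) <- "CentromereExperiment"

  if (doChip) {
    ## occupancy covers the marker locus plus one read length on each side,
    ## so every fragment overlapping any marker base is enriched; the
    ## flanking repeat and element-interior reads this generates have no
    ## unique home in the reference and are discarded by the mapper
    cs <- panel$start[corePositions]; ce <- panel$end[corePositions]
    enriched <- GenomicRanges::GRanges(
      layout@seqnameLabel,
      IRanges::IRanges(pmax(1L, cs - readLength + 1L),
                       pmin(length(layout@sequence), ce + readLength - 1L)),
      fold = coreFolds)
    roles <- c(setNames(rep("active_chip", nActive),
                        paste0("active_", seq_len(nActive))),
               setNames(rep("inactive_chip", nInactive),
                        paste0("inactive_", seq_len(nInactive))),
               negative_chip = "negative_chip",
               fragmented_control = "fragmented_control")
    nPosB <- sum(Biostrings::width(bPlus) - readLength + 1L)
    nPosBg <- sum(Biostrings::width(bMinus) - readLength + 1L)
    wEnriched <- nPosB + sum((coreFolds - 1) *
                               GenomicRanges::width(enriched))
    readsets <- list()
    for (nm in names(roles)) {
      role <- roles[[nm]]
      genome <- if (role %in% c("negative_chip", "fragmented_control"))
        bMinus else bPlus
      w <- switch(role, active_chip = wEnriched,
                  inactive_chip = nPosB, nPosBg)
      n <- max(1L, round(depth * w / readLength))
      readsets[[nm]] <- simulateChipReads(
        genome, enriched = if (role == "active_chip") enriched else NULL,
        role = role, nReads = n, readLength = readLength,
        seed = seed, libraryName = nm)
    }
    index <- buildIndex(
      setNames(Biostrings::DNAStringSet(list(background@sequence,
                                             pseudocontig@sequence)),
               c(background@seqnameLabel, pseudocontig@seqnameLabel)),
      k = k, genomeRefs = background@seqnameLabel)
    placements <- lapply(readsets, mapReads, index = index,
                         minMargin = minMargin)
    enrichment <- computeEnrichment(placements, roles, index, pseudocontig)
    coreCall <- classifyCore(enrichment)
    coreSpan <- tryCatch(
      inferCoreSpan(coreCall, partition, matrix),
      error = function(e) NULL)
    out$readsets <- readsets
    out$index <- index
    out$placements <- placements
    out$enrichment <- enrichment
    out$coreCall <- coreCall
    out$coreSpan <- coreSpan
  }

  if (doPcr) {
    coreMarkersTab <- panel[corePositions, ]
    pairs <- do.call(rbind, lapply(seq_len(nrow(coreMarkersTab)), function(i)
      designJunctionPrimers(coreMarkersTab[i, ], bPlus, bMinus)))
    out$primerPairs <- pairs
    out$genotypes <- genotypeDerivatives(pairs, derivatives)
  }
  out
}

#' @export
print.CentromereExperiment <- function(x, ...) {
  cat("CentromereExperiment (seed ", x$seed, ")\n", sep = "")
  cat("  centromere: ", length(x$layout@sequence), " bp; markers: ",
      nrow(x$markersAll), " discovered, panel of ", nrow(x$panel), "\n",
      sep = "")
  if (!is.null(x$coreCall))
    cat("  core markers called: ",
        paste(coreMarkers(x$coreCall), collapse = ", "), "\n", sep = "")
  if (!is.null(x$coreSpan))
    cat("  core span: ", x$coreSpan$n, " markers from derivative ",
        x$coreSpan$derivative, "\n", sep = "")
  invisible(x)
}
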