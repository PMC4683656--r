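## Functional-core classification: the multi-library rule identifying
## markers that interact with CENH3, core-span inference over the minimal
## map, and in-silico junction-junction PCR genotyping of derivatives.

#' Declare the sequencing-library design
#'
#' @param names Library names (must match the enrichment-table columns).
#' @param roles Role per library (see [ReadSet-class]).
#' @return Named character vector of roles.
#' @export
libraryDesign <- function(names, roles) {
  stopifnot(length(names) == length(roles), all(roles %in% READSET_ROLES))
  if (!any(roles == "active_chip"))
    stop("design requires at least one active replicate")
  if (!any(roles %in% c("negative_chip", "fragmented_control")))
    stop("design requires at least one control library")
  setNames(roles, names)
}

#' Classify functional-core markers from a multi-library enrichment table
#'
#' A marker is called core iff (i) its fold enrichment exceeds `tActive` in
#' EVERY active replicate, (ii) it shows no more than `tInactive`-fold
#' enrichment in every inactive-centromere replicate, (iii) it has no unique
#' coverage above `controlCeiling` in any negative-ChIP or fragmented
#' control library (the strictest reading of "no enrichment" in controls),
#' and (iv) its junction coverage holds in every active replicate.
#' Raising `tActive` or lowering `tInactive` can only remove calls.
#'
#' @param table An [EnrichmentTable-class] with the `junctionOk` assay
#'   computed for active libraries.
#' @param design Optional named role vector from [libraryDesign()]; default
#'   is taken from the table's column data.  Any designed library missing
#'   from the table is an error naming it.
#' @param tActive Active enrichment threshold (default 2: exceeded by the
#'   threefold enrichment of the weakest published core marker while
#'   rejecting unenriched markers).
#' @param tInactive Maximum tolerated fold in inactive replicates
#'   (default 2).
#' @param controlCeiling Maximum tolerated scaled coverage in controls
#'   (default 0: strictly no uniquely mapped reads).
#' @return A [CoreCall-class].
#' @export
classifyCore <- function(table, design = NULL, tActive = 2.0,
                         tInactive = 2.0, controlCeiling = 0) {
  cd <- SummarizedExperiment::colData(table)
  if (is.null(design))
    design <- setNames(cd$role, rownames(cd))
  missing <- setdiff(names(design), rownames(cd))
  if (length(missing))
    stop("library missing from enrichment table: ",
         paste(missing, collapse = ", "))
  design <- design[names(design) %in% rownames(cd)]
  act <- names(design)[design == "active_chip"]
  ina <- names(design)[design == "inactive_chip"]
  ctl <- names(design)[design %in% c("negative_chip", "fragmented_control")]
  if (!length(act)) stop("design requires at least one active replicate")
  if (!length(ctl)) stop("design requires at least one control library")
  fold <- foldEnrichment(table)
  cov <- markerCoverage(table)
  jok <- junctionOk(table)
  if (any(is.na(jok[, act])))
    stop("junctionOk has not been computed for the active libraries")
  activeEnriched <- apply(fold[, act, drop = FALSE] > tActive, 1L, all)
  inactiveQuiet <- if (length(ina))
    apply(fold[, ina, drop = FALSE] <= tInactive, 1L, all)
  else rep(TRUE, nrow(fold))
  controlsClean <- apply(cov[, ctl, drop = FALSE] <= controlCeiling, 1L, all)
  junctionsCovered <- apply(jok[, act, drop = FALSE], 1L, all)
  calls <- S4Vectors::DataFrame(
    activeEnriched = activeEnriched,
    inactiveQuiet = inactiveQuiet,
    controlsClean = controlsClean,
    junctionsCovered = junctionsCovered,
    isCore = activeEnriched & inactiveQuiet & controlsClean &
      junctionsCovered,
    row.names = rownames(fold))
  new("CoreCall", calls = calls,
      thresholds = c(tActive = tActive, tInactive = tInactive,
                     controlCeiling = controlCeiling))
}

#' Infer the centromere core-domain span on the minimal map
#'
#' The reproducible part of combining ChIP calls with derivative biology:
#' the core span is the set of minimal-map markers retained in the smallest
#' functional derivative -- the derivative with the fewest retained markers
#' whose transmission is still at least `minTransmission` (functionality is
#' a biological attribute of the lines, carried as transmission-rate
#' metadata; it can be overridden with `functional`).  The span runs
#' contiguously from that derivative's first retained marker to the end of
#' the map.  A core marker lost in the smallest functional derivative falls
#' outside the span (its loss was tolerated), so the span need not contain
#' every core call, but it must contain at least one.
#'
#' @param call A [CoreCall-class].
#' @param partition A [MarkerPartition-class] (loss-pattern grouping of the
#'   same markers).
#' @param matrix The [PresenceMatrix-class] (rows in minimal-map order).
#' @param minTransmission Functional-transmission threshold (default 0.5).
#' @param functional Optional character vector of derivative names to treat
#'   as functional, overriding the transmission rule.
#' @return List with `derivative`, `span` (marker ids in map order) and
#'   `n` (span size).
#' @export
inferCoreSpan <- function(call, partition, matrix, minTransmission = 0.5,
                          functional = NULL) {
  core <- coreMarkers(call)
  if (!length(core)) stop("no core markers called")
  v <- presenceValues(matrix)
  if (is.null(functional)) {
    tr <- matrix@transmission[colnames(v)]
    functional <- colnames(v)[!is.na(tr) & tr >= minTransmission]
  }
  functional <- intersect(functional, colnames(v))
  if (!length(functional))
    stop("no functional derivative available to set the span boundary")
  retained <- colSums(v[, functional, drop = FALSE])
  smallest <- functional[which.min(retained)]
  span <- rownames(v)[v[, smallest]]
  if (!length(intersect(span, core)))
    stop("span of derivative '", smallest,
         "' contains no CENH3-positive marker")
  list(derivative = smallest, span = span, n = length(span))
}

#' Predict PCR amplification from primer-site positions
#'
#' An amplicon is present iff the forward primer site and the reverse
#' primer site occur in convergent orientation within `maxSize` bp.  Both
#' genomic orientations of the pair are scanned; primer matching is exact
#' (no mismatches, no thermodynamics).
#'
#' @param forward,reverse Primer sequences (5' to 3').
#' @param genome DNA (character, `DNAString(Set)`, layout or derivative).
#' @param maxSize Maximum amplicon size.
#' @return data.frame of amplicons (`seqname`, `start`, `end`, `size`);
#'   zero rows when nothing amplifies.
#' @export
insilicoPCR <- function(forward, reverse, genome, maxSize = 2000L) {
  g <- .asNamedChar(genome)
  out <- list()
  scanPair <- function(seqChr, nm, p1, p2) {
    ## p1 annealing on the plus strand, p2 (reverse-complemented) downstream
    subject <- Biostrings::DNAString(seqChr)
    f <- Biostrings::start(Biostrings::matchPattern(
      Biostrings::DNAString(p1), subject))
    if (!length(f)) return(NULL)
    r <- Biostrings::start(Biostrings::matchPattern(
      Biostrings::reverseComplement(Biostrings::DNAString(p2)), subject))
    if (!length(r)) return(NULL)
    rEnd <- r + nchar(p2) - 1L
    rows <- list()
    for (a in f) {
      hits <- rEnd[r >= a & rEnd - a + 1L <= maxSize]
      for (b in hits)
        rows[[length(rows) + 1L]] <- data.frame(
          seqname = nm, start = a, end = b, size = b - a + 1L)
    }
    if (length(rows)) do.call(rbind, rows) else NULL
  }
  for (nm in names(g)) {
    if (!nchar(g[[nm]])) next
    out[[length(out) + 1L]] <- scanPair(g[[nm]], nm, forward, reverse)
    out[[length(out) + 1L]] <- scanPair(g[[nm]], nm, reverse, forward)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(seqname = character(), start = integer(),
                      end = integer(), size = integer()))
  res <- unique(do.call(rbind, out))
  rownames(res) <- NULL
  res
}

#' Design a junction-junction PCR primer pair for a marker
#'
#' The forward primer straddles the marker's LTR/flank insertion junction
#' (at least `minFlank` bases on each side), anchoring it to the unique
#' insertion point: primers lying wholly within the LTR occur at every
#' element copy and can never give a single product.  The reverse primer
#' sits downstream in the flank, preferring windows that straddle a second
#' recorded junction.  The pair is accepted only if it amplifies exactly
#' one product from the B-plus genome and none from the B-minus genome;
#' candidate windows are scanned until a unique pair is found.
#'
#' @param marker One row of a marker table (with a `junctions` column).
#' @param bPlus,bMinus The genotype genomes screened for uniqueness.
#' @param primerLength Primer length (default 20).
#' @param minFlank Minimum bases of a straddling primer on each side of
#'   the junction (default 5).
#' @param maxSize Maximum amplicon size screened.
#' @return data.frame row: `markerId`, `forward`, `reverse`,
#'   `expectedSize`, `junctionOffset`.  Errors if no unique pair exists
#'   (the marker is reported un-convertible).
#' @export
designJunctionPrimers <- function(marker, bPlus, bMinus, primerLength = 20L,
                                  minFlank = 5L, maxSize = 2000L) {
  stopifnot(nrow(marker) == 1L)
  seq <- marker$sequence[1L]
  len <- nchar(seq)
  juncs <- marker$junctions[[1L]]
  if (!length(juncs)) stop("marker '", marker$id[1L],
                           "' has no recorded junction")
  j1 <- juncs[1L]
  straddling <- function(j) {
    lo <- max(1L, j - primerLength + minFlank)
    hi <- min(len - primerLength + 1L, j - minFlank)
    if (lo > hi) integer() else lo:hi
  }
  fwdStarts <- straddling(j1)
  if (!length(fwdStarts)) stop("marker '", marker$id[1L],
                               "' too short to straddle its junction")
  ## reverse candidates: windows straddling a later junction first, then a
  ## right-to-left sweep of the flank
  later <- unlist(lapply(juncs[-1L], straddling))
  sweep <- rev(seq(j1 + 1L, len - primerLength + 1L))
  rStartsAll <- unique(c(later, sweep))
  for (fs in fwdStarts) {
    fwd <- substr(seq, fs, fs + primerLength - 1L)
    for (rs in rStartsAll) {
      if (rs <= fs + primerLength - 1L) next  # primers must not overlap
      rev <- revComp(substr(seq, rs, rs + primerLength - 1L))
      plusHits <- insilicoPCR(fwd, rev, bPlus, maxSize)
      if (nrow(plusHits) != 1L) next
      if (nrow(insilicoPCR(fwd, rev, bMinus, maxSize)) != 0L) next
      return(data.frame(markerId = marker$id[1L], forward = fwd,
                        reverse = rev,
                        expectedSize = rs + primerLength - fs,
                        junctionOffset = j1,
                        stringsAsFactors = FALSE))
    }
  }
  stop("marker '", marker$id[1L],
       "' is un-convertible: no unique junction-junction pair found")
}

#' Genotype derivatives with junction-junction primer pairs
#'
#' @param pairs data.frame of primer pairs (rows from
#'   [designJunctionPrimers()]).
#' @param derivatives Named list of [DerivativeGenome-class].
#' @param maxSize Maximum amplicon size.
#' @return Logical matrix, pairs (by marker id) x derivatives: TRUE where a
#'   product amplifies.
#' @export
genotypeDerivatives <- function(pairs, derivatives, maxSize = 2000L) {
  out <- matrix(FALSE, nrow(pairs), length(derivatives),
                dimnames = list(pairs$markerId,
                                vapply(derivatives, function(d) d@name,
                                       character(1))))
  for (i in seq_len(nrow(pairs))) for (j in seq_along(derivatives)) {
    out[i, j] <- nrow(insilicoPCR(pairs$forward[i], pairs$reverse[i],
                                  derivatives[[j]], maxSize)) > 0L
  }
  out
}
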