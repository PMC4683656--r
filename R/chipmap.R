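## Desk-scale unique read mapping and CENH3 fold-enrichment scoring: an
## in-repo replacement for the aligner / MAPQ-filter / pileup chain used on
## real data.  Reads are seeded with exact k-mers (default k = 40, the seed
## length used for the real alignments), extended by ungapped match
## counting, and retained only when a single best placement beats the
## runner-up by a margin -- the analogue of "only unique hits" above a MAPQ
## floor.

#' Build a k-mer seed index over a reference set
#'
#' @param refs Named [Biostrings::DNAStringSet] (typically the background
#'   genome plus the minimal-map pseudocontig).
#' @param k Seed length; windows containing N (the pseudocontig spacers)
#'   are never indexed.
#' @param genomeRefs Names of the references forming the background genome
#'   (fold enrichment is computed relative to their mean coverage).
#' @return A [ReferenceIndex-class].
#' @export
buildIndex <- function(refs, k = 40L, genomeRefs = names(refs)[1L]) {
  if (is(refs, "Pseudocontig"))
    refs <- setNames(Biostrings::DNAStringSet(list(refs@sequence)),
                     refs@seqnameLabel)
  if (is.character(refs)) refs <- Biostrings::DNAStringSet(refs)
  stopifnot(is(refs, "DNAStringSet"), !is.null(names(refs)))
  out <- new("ReferenceIndex", refs = refs, k = as.integer(k),
             genomeRefs = genomeRefs)
  validObject(out)
  out
}

#' Look up all exact placements of one seed
#'
#' Returns every exact placement of a length-`k` seed in the indexed
#' references (plus strand).  Seeds containing non-ACGT letters never match,
#' and reference N positions never match any seed.
#'
#' @param index A [ReferenceIndex-class].
#' @param seed Character seed of length `index@k`.
#' @return data.frame with columns `ref`, `start`.
#' @export
lookupSeed <- function(index, seed) {
  stopifnot(nchar(seed) == index@k)
  empty <- data.frame(ref = character(), start = integer())
  if (grepl("[^ACGT]", seed)) return(empty)
  rows <- lapply(names(index@refs), function(nm) {
    m <- Biostrings::matchPattern(Biostrings::DNAString(seed),
                                  index@refs[[nm]], fixed = TRUE)
    if (length(m)) data.frame(ref = nm, start = Biostrings::start(m))
    else NULL
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

#' Map reads uniquely against an indexed reference
#'
#' Each read is seeded at three fixed offsets in both orientations and every
#' candidate placement is scored by ungapped match counting (N never
#' matches).  A read is retained iff a single best placement exists whose
#' score exceeds the second best by at least `minMargin` matching bases and
#' whose in-reference span is matched to within `maxMismatches` bases;
#' ties and marginal placements are discarded (and counted), which removes
#' reads from multi-copy repeat interiors, while the identity requirement
#' rejects reads from diverged repeat copies that happen to have a single,
#' mediocre best placement (the margin alone cannot catch those).
#'
#' @param reads A [ReadSet-class] or [Biostrings::DNAStringSet].
#' @param index A [ReferenceIndex-class].
#' @param minMargin Minimum best-minus-second-best score margin (default 5).
#' @param maxMismatches Maximum mismatches over the placement's in-reference
#'   span (default 2; raise it for read sets simulated with substitution
#'   errors).  Overhang into N spacers or past a reference end does not
#'   count as mismatch.
#' @param minReadLength Reads shorter than this are dropped before mapping
#'   (the desk-scale stand-in for quality/length trimming).
#' @return [S4Vectors::DataFrame] of placements: `readId`, `ref`, `start`
#'   (1-based; may extend past reference ends for overhanging alignments),
#'   `strand`, `width`, `score`, `margin`.  Attributes `nDiscarded` and
#'   `nUnseeded` count the dropped reads.
#' @export
mapReads <- function(reads, index, minMargin = 5L, maxMismatches = 2L,
                     minReadLength = 0L) {
  rs <- if (is(reads, "ReadSet")) reads@reads else reads
  stopifnot(is(rs, "DNAStringSet"))
  keep <- Biostrings::width(rs) >= minReadLength
  rs <- rs[keep]
  if (any(Biostrings::width(rs) < index@k))
    stop("read length must be at least the seed length k")
  ids <- names(rs)
  if (is.null(ids)) ids <- as.character(seq_along(rs))
  fwd <- as.character(rs)
  rc <- as.character(Biostrings::reverseComplement(rs))
  res <- cpp_map_reads(as.character(index@refs), fwd, rc,
                       index@k, as.integer(minMargin),
                       as.integer(maxMismatches))
  out <- S4Vectors::DataFrame(
    readId = ids[res$read],
    ref = names(index@refs)[res$ref],
    start = res$start,
    strand = ifelse(res$strand == 1L, "-", "+"),
    width = Biostrings::width(rs)[res$read],
    score = res$score,
    margin = res$margin)
  attr(out, "nDiscarded") <- res$nDiscarded
  attr(out, "nUnseeded") <- res$nUnseeded
  attr(out, "nInput") <- length(rs)
  out
}

## Per-base coverage (Rle per reference) from a placement table, with
## alignments clamped to the reference bounds.
.placementCoverage <- function(placements, index) {
  lens <- setNames(Biostrings::width(index@refs), names(index@refs))
  out <- list()
  for (nm in names(index@refs)) {
    sel <- placements$ref == nm
    if (!any(sel)) {
      out[[nm]] <- S4Vectors::Rle(0L, lens[[nm]])
      next
    }
    s <- pmax(1L, placements$start[sel])
    e <- pmin(lens[[nm]], placements$start[sel] + placements$width[sel] - 1L)
    ok <- s <= e
    out[[nm]] <- IRanges::coverage(IRanges::IRanges(s[ok], e[ok]),
                                   width = lens[[nm]])
  }
  out
}

#' Compute fold enrichment of minimal-map markers over the genome average
#'
#' Per library, coverage is scaled per million mapped reads; each marker's
#' fold enrichment is its scaled mean per-base unique coverage over the
#' marker interval divided by the scaled genome-wide mean coverage (over
#' the background-genome references of the index).  When the pseudocontig
#' is supplied, per-marker junction-coverage flags are computed as well
#' (see [junctionCoverage()]).
#'
#' @param placements Named list of placement tables (one per library, from
#'   [mapReads()]).
#' @param roles Named character vector: role of each library.
#' @param index The [ReferenceIndex-class] used for mapping.
#' @param pseudocontig A [Pseudocontig-class] (marker intervals and junction
#'   positions).
#' @param minOverhang,minDepth Passed to [junctionCoverage()].
#' @return An [EnrichmentTable-class] (markers x libraries) with assays
#'   `fold`, `coverage` and `junctionOk`.
#' @export
computeEnrichment <- function(placements, roles, index, pseudocontig,
                              minOverhang = 10L, minDepth = 1L) {
  stopifnot(is.list(placements), !is.null(names(placements)),
            all(names(placements) %in% names(roles)) ||
              all(names(placements) == names(roles)))
  libs <- names(placements)
  mi <- markerIntervals(pseudocontig)
  markers <- names(mi)
  pcName <- pseudocontig@seqnameLabel
  genomeRefs <- setdiff(index@genomeRefs, pcName)
  stopifnot(length(genomeRefs) > 0L)
  glen <- sum(Biostrings::width(index@refs)[names(index@refs) %in% genomeRefs])
  fold <- cov <- matrix(NA_real_, length(markers), length(libs),
                        dimnames = list(markers, libs))
  jok <- matrix(NA, length(markers), length(libs),
                dimnames = list(markers, libs))
  mapped <- genomeMean <- setNames(numeric(length(libs)), libs)
  for (lb in libs) {
    pl <- placements[[lb]]
    if (nrow(pl) == 0L) stop("no mapped reads in library '", lb, "'")
    mapped[lb] <- nrow(pl)
    scale <- 1e6 / nrow(pl)
    cv <- .placementCoverage(pl, index)
    gsum <- sum(vapply(genomeRefs, function(nm)
      sum(as.numeric(S4Vectors::runValue(cv[[nm]])) *
            S4Vectors::runLength(cv[[nm]])), numeric(1)))
    if (gsum == 0) stop("zero genome coverage in library '", lb,
                        "' (degenerate library)")
    genomeMean[lb] <- gsum / glen * scale
    pcCov <- as.numeric(cv[[pcName]])
    s <- GenomicRanges::start(mi); e <- GenomicRanges::end(mi)
    mcov <- vapply(seq_along(mi), function(i) mean(pcCov[s[i]:e[i]]),
                   numeric(1))
    cov[, lb] <- mcov * scale
    fold[, lb] <- (mcov * scale) / genomeMean[lb]
    jok[, lb] <- junctionCoverage(pl, pseudocontig, minOverhang, minDepth,
                                  .coverage = pcCov)
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(fold = fold, coverage = cov, junctionOk = jok),
    rowRanges = mi,
    colData = S4Vectors::DataFrame(role = unname(roles[libs]),
                                   mappedReads = mapped,
                                   genomeMean = genomeMean,
                                   row.names = libs))
  new("EnrichmentTable", se)
}

#' Assess marker junction coverage in one library
#'
#' A marker's junction coverage is satisfied iff every base of the marker
#' interval has unique-read depth of at least `minDepth` AND every recorded
#' junction within the marker is spanned by at least one read with at least
#' `minOverhang` bases of aligned extent on both sides of the junction --
#' the criterion that ChIP reads must cover the entire marker and flank its
#' unique insertion point.
#'
#' @param placements Placement table for one library ([mapReads()]).
#' @param pseudocontig A [Pseudocontig-class].
#' @param minOverhang Minimum read extent on each side of a junction.
#' @param minDepth Minimum per-base depth over the marker.
#' @param .coverage Optional precomputed per-base coverage vector.
#' @return Named logical vector, one flag per marker.
#' @export
junctionCoverage <- function(placements, pseudocontig, minOverhang = 10L,
                             minDepth = 1L, .coverage = NULL) {
  mi <- markerIntervals(pseudocontig)
  pcName <- pseudocontig@seqnameLabel
  pl <- placements[placements$ref == pcName, , drop = FALSE]
  if (is.null(.coverage)) {
    len <- sum(GenomicRanges::width(mi)) +
      pseudocontig@spacerLength * (length(mi) - 1L)
    s <- pmax(1L, pl$start)
    e <- pmin(len, pl$start + pl$width - 1L)
    ok <- s <= e
    .coverage <- as.numeric(IRanges::coverage(IRanges::IRanges(s[ok], e[ok]),
                                              width = len))
  }
  rs <- pl$start
  re <- pl$start + pl$width - 1L
  jx <- pseudocontig@junctions
  out <- setNames(logical(length(mi)), names(mi))
  for (i in seq_along(mi)) {
    a <- GenomicRanges::start(mi)[i]; b <- GenomicRanges::end(mi)[i]
    if (any(.coverage[a:b] < minDepth)) { out[i] <- FALSE; next }
    jpos <- GenomicRanges::start(jx)[S4Vectors::mcols(jx)$marker ==
                                       names(mi)[i]]
    spanned <- vapply(jpos, function(j)
      any(rs <= j - minOverhang & re >= j + minOverhang - 1L), logical(1))
    out[i] <- all(spanned)
  }
  out
}

#' Assay accessors for an enrichment table
#'
#' @param x An [EnrichmentTable-class].
#' @return Numeric (or logical) marker-by-library matrix.
#' @export
foldEnrichment <- function(x) SummarizedExperiment::assay(x, "fold")

#' @rdname foldEnrichment
#' @export
markerCoverage <- function(x) SummarizedExperiment::assay(x, "coverage")

#' @rdname foldEnrichment
#' @export
junctionOk <- function(x) SummarizedExperiment::assay(x, "junctionOk")
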