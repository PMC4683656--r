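## Shared in-code fixtures: everything is generated at test time from fixed
## seeds; nothing binary ships with the package.

tinyLib <- function(seed = 11) buildRepeatLibrary(seed)

## A small centromere that still exercises nesting and both orientations.
tinyCentromere <- function(lib, n = 8, seed = 11) {
  simulateCentromere(lib, nCrmInsertions = n, seed = seed,
                     nArrays = 2, monomersPerArray = 10)
}

tinyDisplay <- function(lib, layout, background, ...) {
  bPlus <- stats::setNames(
    Biostrings::DNAStringSet(list(background@sequence, layout@sequence)),
    c(background@seqnameLabel, layout@seqnameLabel))
  runDisplay(bPlus, bPlus[background@seqnameLabel],
             primers = tdPrimers(lib), ...)
}

randomSeq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## Marker-table row(s) built directly from sequences (for operations that
## only need sequences, sizes and junction offsets).
syntheticMarkers <- function(seqs, junctions = NULL, ids = NULL) {
  n <- length(seqs)
  if (is.null(ids)) ids <- paste0("TD", seq_len(n))
  if (is.null(junctions)) junctions <- rep(list(integer()), n)
  if (n == 0L) {
    out <- S4Vectors::DataFrame(
      id = character(), name = character(), size = integer(),
      sequence = character(),
      triplets = IRanges::CharacterList(),
      seqname = character(), start = integer(), end = integer(),
      strand = character(), nSources = integer(),
      junctions = IRanges::IntegerList())
    return(out)
  }
  out <- S4Vectors::DataFrame(
    id = ids,
    name = paste0("CRM2-AAA-", nchar(seqs)),
    size = nchar(seqs),
    sequence = unname(seqs),
    triplets = IRanges::CharacterList(as.list(rep("AAA", n))),
    seqname = "B_centromere",
    start = NA_integer_, end = NA_integer_, strand = "+",
    nSources = 1L,
    junctions = IRanges::IntegerList(junctions))
  rownames(out) <- ids
  out
}

## Memoised full experiment for the acceptance blocks that share one run.
.acceptanceCache <- new.env(parent = emptyenv())
acceptanceExperiment <- function(seed = 101) {
  key <- as.character(seed)
  if (is.null(.acceptanceCache[[key]]))
    .acceptanceCache[[key]] <- runCentromereExperiment(seed)
  .acceptanceCache[[key]]
}

## An EnrichmentTable built directly from assay matrices (classifier tests).
makeEnrichmentTable <- function(fold, coverage = fold, junctionOk = NULL,
                                roles) {
  if (is.null(junctionOk)) {
    junctionOk <- fold
    junctionOk[] <- TRUE
    mode(junctionOk) <- "logical"
  }
  mi <- GenomicRanges::GRanges(
    "minimal_map",
    IRanges::IRanges(seq_len(nrow(fold)) * 500L, width = 300L))
  names(mi) <- rownames(fold)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(fold = fold, coverage = coverage, junctionOk = junctionOk),
    rowRanges = mi,
    colData = S4Vectors::DataFrame(role = unname(roles),
                                   mappedReads = rep(1e6, ncol(fold)),
                                   genomeMean = rep(1, ncol(fold)),
                                   row.names = colnames(fold)))
  new("EnrichmentTable", se)
}
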