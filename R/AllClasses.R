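#' @import methods
#' @importClassesFrom Biostrings DNAString DNAStringSet
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom IRanges IRanges
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
NULL

.validDNA <- function(x) {
  af <- Biostrings::alphabetFrequency(x)
  sum(af[c("A", "C", "G", "T")]) == length(x)
}

#' Repeat library for synthetic centromere construction
#'
#' Named repeat units (a CentC-like 156-bp tandem monomer, a CRM2-like LTR
#' retroelement, a B-repeat-like unit and filler retroelements) from which
#' synthetic centromeres and background genomes are composed.  The CRM2-like
#' LTR carries two fixed primer-annealing subsequences used by the
#' transposon-display module; the selective primer sits `ltrTail` bases from
#' the LTR end so every amplified band carries that much LTR sequence.
#'
#' @slot units Named [Biostrings::DNAStringSet] of repeat units; must contain
#'   `centc`, `crm2`, `crm2_ltr` plus a `b_repeat` and filler elements.
#' @slot primarySite,selectiveSite Character; primer-annealing subsequences
#'   of the LTR (primary outer primer, nested selective primer).
#' @slot ltrTail Integer; LTR bases carried by each band (selective primer
#'   annealing start to LTR end), default 112.
#' @slot params List of generation parameters (lengths, GC, divergence).
#' @export
setClass("RepeatLibrary", representation(
  units = "DNAStringSet",
  primarySite = "character",
  selectiveSite = "character",
  ltrTail = "integer",
  params = "list"
))

setValidity("RepeatLibrary", function(object) {
  msg <- character()
  need <- c("centc", "crm2", "crm2_ltr", "b_repeat")
  if (!all(need %in% names(object@units)))
    msg <- c(msg, paste("units must include", paste(need, collapse = ", ")))
  for (nm in names(object@units)) {
    if (!.validDNA(object@units[[nm]]))
      msg <- c(msg, paste0("unit '", nm, "' contains non-ACGT letters"))
  }
  cl <- object@params$centcLen %||% 156L
  if ("centc" %in% names(object@units) &&
      length(object@units[["centc"]]) != cl)
    msg <- c(msg, sprintf("centc monomer must be %d bp", cl))
  if ("crm2_ltr" %in% names(object@units)) {
    ltr <- as.character(object@units[["crm2_ltr"]])
    if (!grepl(object@primarySite, ltr, fixed = TRUE) ||
        !grepl(object@selectiveSite, ltr, fixed = TRUE))
      msg <- c(msg, "LTR must contain both primer-annealing subsequences")
  }
  if (object@ltrTail < nchar(object@selectiveSite))
    msg <- c(msg, "ltrTail shorter than the selective annealing segment")
  if (length(msg)) msg else TRUE
})

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Annotated layout of a simulated centromere
#'
#' The assembled centromere sequence together with the tiling of repeat-unit
#' features (with nesting depth), the CENH3 occupancy domain, and the planted
#' junction positions.  A junction at position `p` is the boundary between
#' bases `p - 1` and `p` (1-based); `kind` distinguishes LTR-flank junctions
#' created by retroelement insertion from backbone block boundaries.
#'
#' @slot sequence [Biostrings::DNAString] of the centromere (or background).
#' @slot features [GenomicRanges::GRanges] tiling the sequence without gaps,
#'   with metadata columns `unit` and `depth`.
#' @slot cenh3Domain [IRanges::IRanges] (possibly empty) occupancy domain.
#' @slot junctions data.frame with columns `pos`, `kind`.
#' @slot seqnameLabel Character scalar naming the sequence.
#' @export
setClass("CentromereLayout", representation(
  sequence = "DNAString",
  features = "GRanges",
  cenh3Domain = "IRanges",
  junctions = "data.frame",
  seqnameLabel = "character"
))

setValidity("CentromereLayout", function(object) {
  msg <- character()
  len <- length(object@sequence)
  f <- object@features
  if (length(f)) {
    o <- order(GenomicRanges::start(f))
    s <- GenomicRanges::start(f)[o]; e <- GenomicRanges::end(f)[o]
    if (s[1] != 1L || e[length(e)] != len ||
        (length(s) > 1 && any(s[-1] != e[-length(e)] + 1L)))
      msg <- c(msg, "features must tile the sequence without gaps or overlaps")
  }
  if (length(object@cenh3Domain) &&
      (IRanges::start(object@cenh3Domain) < 1 ||
       IRanges::end(object@cenh3Domain) > len))
    msg <- c(msg, "cenh3Domain must lie within the sequence")
  j <- object@junctions
  if (nrow(j) && (!all(c("pos", "kind") %in% names(j)) ||
                  any(j$pos < 1) || any(j$pos > len + 1L)))
    msg <- c(msg, "junction positions out of range")
  if (length(msg)) msg else TRUE
})

#' A genome derived by centromere misdivision
#'
#' A derivative in a misdivision pedigree: the parent's sequence with one
#' terminal-side interval excised.  `retainedRoot` tracks the derivative's
#' retained interval in root (progenitor) coordinates, which is contiguous
#' because every misdivision event removes one side.
#'
#' @slot name,parent Character; `parent` is `NA` for the root.
#' @slot deletions [IRanges::IRanges] in the parent's coordinates.
#' @slot sequence [Biostrings::DNAString].
#' @slot retainedRoot [IRanges::IRanges] retained interval in root coordinates.
#' @slot transmission Numeric transmission rate (NA when unknown); used by
#'   [inferCoreSpan()] to decide which derivatives are functional.
#' @export
setClass("DerivativeGenome", representation(
  name = "character",
  parent = "character",
  deletions = "IRanges",
  sequence = "DNAString",
  retainedRoot = "IRanges",
  transmission = "numeric"
))

setValidity("DerivativeGenome", function(object) {
  msg <- character()
  if (length(object@retainedRoot) != 1L)
    msg <- c(msg, "retainedRoot must be a single interval")
  if (length(object@deletions) > 1L)
    msg <- c(msg, "at most one (terminal) deletion per misdivision event")
  if (length(msg)) msg else TRUE
})

#' Simulated sequencing library
#'
#' @slot libraryName Character label.
#' @slot role One of `active_chip`, `inactive_chip`, `negative_chip`,
#'   `fragmented_control`.
#' @slot reads [Biostrings::DNAStringSet] (fixed length).
#' @slot readLength,seed Integers.
#' @slot truth [S4Vectors::DataFrame] with the true source `ref`, `start`
#'   and `strand` of every read (used by calibration tests).
#' @export
setClass("ReadSet", representation(
  libraryName = "character",
  role = "character",
  reads = "DNAStringSet",
  readLength = "integer",
  seed = "integer",
  truth = "DataFrame"
))

READSET_ROLES <- c("active_chip", "inactive_chip", "negative_chip",
                   "fragmented_control")

setValidity("ReadSet", function(object) {
  msg <- character()
  if (!object@role %in% READSET_ROLES)
    msg <- c(msg, paste("role must be one of:",
                        paste(READSET_ROLES, collapse = ", ")))
  if (length(object@reads) &&
      any(Biostrings::width(object@reads) != object@readLength))
    msg <- c(msg, "all reads must have the declared read length")
  if (length(msg)) msg else TRUE
})

#' Marker presence/absence across a derivative pedigree
#'
#' @slot values Logical matrix, markers (rows, in minimal-map order) by
#'   derivatives (columns, in main-chain order).
#' @slot pedigree Named character vector mapping each derivative to its
#'   parent (`NA` for the root or externally derived lines).
#' @slot transmission Named numeric vector of transmission rates (NA allowed).
#' @export
setClass("PresenceMatrix", representation(
  values = "matrix",
  pedigree = "character",
  transmission = "numeric"
))

setValidity("PresenceMatrix", function(object) {
  msg <- character()
  v <- object@values
  if (!is.logical(v)) msg <- c(msg, "values must be a logical matrix")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "values must have marker row names and derivative column names")
  ped <- object@pedigree
  if (!is.null(colnames(v))) {
    known <- colnames(v)
    bad <- setdiff(names(ped), known)
    if (length(bad))
      msg <- c(msg, paste("pedigree names not in matrix:", paste(bad, collapse = ",")))
    for (d in known) {
      p <- ped[[d]] %||% NA_character_
      if (!is.na(p) && !p %in% known)
        msg <- c(msg, paste0("parent of '", d, "' absent from matrix"))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Partition of markers by loss pattern
#'
#' Markers grouped by identical presence pattern, ordered by the generation
#' at which they were first lost along the main pedigree chain (markers never
#' lost form the terminal group).
#'
#' @slot groups Named list of character vectors of marker ids.
#' @slot patterns Logical matrix, one row per group.
#' @slot firstLoss Integer vector: 1-based column index of first loss per
#'   group (`NA` for the never-lost group).
#' @slot violations data.frame of non-nested (marker, derivative) pairs.
#' @export
setClass("MarkerPartition", representation(
  groups = "list",
  patterns = "matrix",
  firstLoss = "integer",
  violations = "data.frame"
))

#' Minimal-map pseudocontig
#'
#' Ordered concatenation of marker sequences separated by runs of N, used as
#' the alignment reference for ChIP-seq interpretation.
#'
#' @slot sequence [Biostrings::DNAString] over ACGT plus N spacers.
#' @slot markerIntervals [GenomicRanges::GRanges] named by marker id.
#' @slot junctions [GenomicRanges::GRanges] of junction positions in map
#'   coordinates, with a `marker` metadata column.
#' @slot spacerLength Integer.
#' @slot seqnameLabel Character scalar (reference sequence name).
#' @export
setClass("Pseudocontig", representation(
  sequence = "DNAString",
  markerIntervals = "GRanges",
  junctions = "GRanges",
  spacerLength = "integer",
  seqnameLabel = "character"
))

setValidity("Pseudocontig", function(object) {
  msg <- character()
  mi <- object@markerIntervals
  n <- length(mi)
  if (n == 0L) msg <- c(msg, "at least one marker required")
  else {
    tot <- sum(GenomicRanges::width(mi)) + object@spacerLength * (n - 1L)
    if (tot != length(object@sequence))
      msg <- c(msg, "length law violated: sum(markers) + spacer * (n - 1)")
    if (is.null(names(mi))) msg <- c(msg, "marker intervals must be named")
  }
  if (length(msg)) msg else TRUE
})

#' k-mer seed index over a reference set
#'
#' Thin container for the reference sequences and seed length used by the
#' desk-scale unique-read mapper.  Seed lookup never matches across N
#' positions (spacer runs in the pseudocontig are unseedable).
#'
#' @slot refs Named [Biostrings::DNAStringSet].
#' @slot k Integer seed length (the paper-scale default is 40).
#' @slot genomeRefs Character: names of the references that constitute the
#'   background genome (fold enrichment is computed relative to their mean
#'   coverage); the remaining references are minimal-map pseudocontigs.
#' @export
setClass("ReferenceIndex", representation(
  refs = "DNAStringSet",
  k = "integer",
  genomeRefs = "character"
))

setValidity("ReferenceIndex", function(object) {
  msg <- character()
  if (length(object@refs) == 0L) msg <- c(msg, "references must be non-empty")
  if (is.null(names(object@refs))) msg <- c(msg, "references must be named")
  if (object@k < 1L) msg <- c(msg, "k must be >= 1")
  if (length(object@refs) && object@k > min(Biostrings::width(object@refs)))
    msg <- c(msg, "k exceeds the shortest reference")
  if (length(msg)) msg else TRUE
})

#' Marker-by-library enrichment table
#'
#' A [SummarizedExperiment::RangedSummarizedExperiment] with assays `fold`
#' (scaled marker coverage over scaled genome-average coverage), `coverage`
#' (mean per-base unique coverage per million mapped reads) and `junctionOk`
#' (logical; NA until [junctionCoverage()] has been applied).  Column data
#' carry `role`, `mappedReads` and `genomeMean`.
#'
#' @export
setClass("EnrichmentTable", contains = "RangedSummarizedExperiment")

#' Core-marker classification result
#'
#' @slot calls [S4Vectors::DataFrame] per marker: `isCore` plus one logical
#'   column per criterion (`activeEnriched`, `inactiveQuiet`, `controlsClean`,
#'   `junctionsCovered`).
#' @slot thresholds Named numeric (`tActive`, `tInactive`, `controlCeiling`).
#' @export
setClass("CoreCall", representation(
  calls = "DataFrame",
  thresholds = "numeric"
))

## ---- show methods -----------------------------------------------------

setMethod("show", "RepeatLibrary", function(object) {
  cat("RepeatLibrary with", length(object@units), "units:",
      paste(sprintf("%s(%d)", names(object@units),
                    Biostrings::width(object@units)), collapse = ", "), "\n")
  cat("  LTR tail carried by bands:", object@ltrTail, "bp\n")
})

setMethod("show", "CentromereLayout", function(object) {
  cat("CentromereLayout '", object@seqnameLabel, "': ",
      length(object@sequence), " bp, ", length(object@features),
      " features, ", sum(object@junctions$kind == "ltr_flank"),
      " LTR-flank junctions\n", sep = "")
  if (length(object@cenh3Domain))
    cat("  CENH3 domain: [", IRanges::start(object@cenh3Domain), ", ",
        IRanges::end(object@cenh3Domain), "]\n", sep = "")
})

setMethod("show", "DerivativeGenome", function(object) {
  cat("DerivativeGenome '", object@name, "' (parent: ",
      ifelse(is.na(object@parent), "none", object@parent), "): ",
      length(object@sequence), " bp retained\n", sep = "")
})

setMethod("show", "ReadSet", function(object) {
  cat("ReadSet '", object@libraryName, "' [", object@role, "]: ",
      length(object@reads), " reads x ", object@readLength, " nt\n", sep = "")
})

setMethod("show", "PresenceMatrix", function(object) {
  cat("PresenceMatrix:", nrow(object@values), "markers x",
      ncol(object@values), "derivatives\n")
  cat("  retained per derivative:",
      paste(sprintf("%s=%d", colnames(object@values),
                    colSums(object@values)), collapse = ", "), "\n")
})

setMethod("show", "MarkerPartition", function(object) {
  cat("MarkerPartition:", length(object@groups), "groups, sizes [",
      paste(lengths(object@groups), collapse = ", "), "]\n")
  if (nrow(object@violations))
    cat("  ", nrow(object@violations), "nestedness violations\n")
})

setMethod("show", "Pseudocontig", function(object) {
  cat("Pseudocontig '", object@seqnameLabel, "': ",
      length(object@markerIntervals), " markers, ",
      length(object@sequence), " bp total (",
      object@spacerLength, "-N spacers)\n", sep = "")
})

setMethod("show", "CoreCall", function(object) {
  cat("CoreCall:", sum(object@calls$isCore), "of", nrow(object@calls),
      "markers classified as functional core\n")
})

## ---- accessors --------------------------------------------------------

#' Accessors for package classes
#'
#' Small accessor generics for the central S4 containers: repeat units,
#' layout sequence/features/junctions, derivative sequences, presence
#' values, marker intervals.
#'
#' @param x An object of the documented class.
#' @param name For `repeatUnit`, the unit name.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("repeatUnit", function(x, name) standardGeneric("repeatUnit"))
#' @rdname accessors
#' @export
setMethod("repeatUnit", "RepeatLibrary", function(x, name) x@units[[name]])

#' @rdname accessors
#' @export
setGeneric("centcMonomer", function(x) standardGeneric("centcMonomer"))
#' @rdname accessors
#' @export
setMethod("centcMonomer", "RepeatLibrary", function(x) x@units[["centc"]])

#' @rdname accessors
#' @export
setGeneric("ltrSequence", function(x) standardGeneric("ltrSequence"))
#' @rdname accessors
#' @export
setMethod("ltrSequence", "RepeatLibrary", function(x) x@units[["crm2_ltr"]])

#' @rdname accessors
#' @export
setGeneric("layoutSequence", function(x) standardGeneric("layoutSequence"))
#' @rdname accessors
#' @export
setMethod("layoutSequence", "CentromereLayout", function(x) x@sequence)
#' @rdname accessors
#' @export
setMethod("layoutSequence", "DerivativeGenome", function(x) x@sequence)

#' @rdname accessors
#' @export
setGeneric("layoutFeatures", function(x) standardGeneric("layoutFeatures"))
#' @rdname accessors
#' @export
setMethod("layoutFeatures", "CentromereLayout", function(x) x@features)

#' @rdname accessors
#' @export
setGeneric("plantedJunctions", function(x) standardGeneric("plantedJunctions"))
#' @rdname accessors
#' @export
setMethod("plantedJunctions", "CentromereLayout", function(x) x@junctions)

#' @rdname accessors
#' @export
setGeneric("cenh3Domain", function(x) standardGeneric("cenh3Domain"))
#' @rdname accessors
#' @export
setMethod("cenh3Domain", "CentromereLayout", function(x) x@cenh3Domain)

#' @rdname accessors
#' @export
setGeneric("presenceValues", function(x) standardGeneric("presenceValues"))
#' @rdname accessors
#' @export
setMethod("presenceValues", "PresenceMatrix", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("markerIntervals", function(x) standardGeneric("markerIntervals"))
#' @rdname accessors
#' @export
setMethod("markerIntervals", "Pseudocontig", function(x) x@markerIntervals)

#' @rdname accessors
#' @export
setGeneric("markerGroups", function(x) standardGeneric("markerGroups"))
#' @rdname accessors
#' @export
setMethod("markerGroups", "MarkerPartition", function(x) x@groups)

#' @rdname accessors
#' @export
setGeneric("coreCalls", function(x) standardGeneric("coreCalls"))
#' @rdname accessors
#' @export
setMethod("coreCalls", "CoreCall", function(x) x@calls)

#' @rdname accessors
#' @export
setGeneric("coreMarkers", function(x) standardGeneric("coreMarkers"))
#' @rdname accessors
#' @export
setMethod("coreMarkers", "CoreCall", function(x)
  rownames(x@calls)[x@calls$isCore])
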