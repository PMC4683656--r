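## In-silico CRM2 transposon display: restriction digestion, LTR-anchored
## selective amplification, genotype band comparison, duplicate collapse and
## marker naming.

#' Restriction enzyme specification
#'
#' @slot name Label.
#' @slot recognition Recognition sequence over ACGT.
#' @slot cutOffset Cut position within the recognition site (cut falls after
#'   `cutOffset` bases; BfaI is C^TAG, offset 1).
#' @export
setClass("EnzymeSpec", representation(
  name = "character", recognition = "character", cutOffset = "integer"))

setValidity("EnzymeSpec", function(object) {
  msg <- character()
  if (nchar(object@recognition) == 0 ||
      grepl("[^ACGT]", object@recognition))
    msg <- c(msg, "recognition must be non-empty over ACGT")
  if (object@cutOffset < 0 || object@cutOffset > nchar(object@recognition))
    msg <- c(msg, "cutOffset must lie within the recognition site")
  if (length(msg)) msg else TRUE
})

#' @param name,recognition,cutOffset See slots.
#' @rdname EnzymeSpec-class
#' @export
enzymeSpec <- function(name = "BfaI", recognition = "CTAG", cutOffset = 1L) {
  out <- new("EnzymeSpec", name = name, recognition = recognition,
             cutOffset = as.integer(cutOffset))
  validObject(out)
  out
}

#' Transposon-display primer set
#'
#' The primary LTR primer and nested selective LTR primer (annealing
#' segments within the CRM2-like LTR), the adapter-core primer ligated at
#' the restriction site, and zero or three selective bases appended to the
#' adapter primer.
#'
#' @slot primaryLtr,selectiveLtr,adapterCore Character DNA segments.
#' @slot selectiveBases Character of length 0 or 3 over ACGT.
#' @export
setClass("PrimerSet", representation(
  primaryLtr = "character", selectiveLtr = "character",
  adapterCore = "character", selectiveBases = "character"))

setValidity("PrimerSet", function(object) {
  msg <- character()
  if (!nchar(object@selectiveBases) %in% c(0L, 3L) ||
      grepl("[^ACGT]", object@selectiveBases))
    msg <- c(msg, "selectiveBases must be empty or a DNA triplet")
  if (length(msg)) msg else TRUE
})

#' @param lib A [RepeatLibrary-class] supplying the LTR annealing segments.
#' @param selectiveBases Selective triplet ("" for unselective).
#' @param adapterCore Adapter primer core sequence.
#' @rdname PrimerSet-class
#' @export
tdPrimers <- function(lib, selectiveBases = "",
                      adapterCore = "GACGATGAGTCCTGAGTAG") {
  out <- new("PrimerSet", primaryLtr = lib@primarySite,
             selectiveLtr = lib@selectiveSite,
             adapterCore = adapterCore, selectiveBases = selectiveBases)
  validObject(out)
  out
}

.asNamedChar <- function(genome) {
  if (is(genome, "CentromereLayout"))
    return(setNames(as.character(genome@sequence), genome@seqnameLabel))
  if (is(genome, "DerivativeGenome"))
    return(setNames(as.character(genome@sequence), genome@name))
  if (is(genome, "DNAString")) return(c(genome = as.character(genome)))
  if (is(genome, "DNAStringSet")) {
    stopifnot(!is.null(names(genome)))
    return(setNames(as.character(genome), names(genome)))
  }
  if (is.character(genome)) {
    if (is.null(names(genome))) names(genome) <- paste0("seq", seq_along(genome))
    return(genome)
  }
  stop("unsupported genome representation")
}

## Cut boundaries of one sequence: 1-based positions b such that the enzyme
## cuts between b and b + 1.  Occurrences of the recognition site and of its
## reverse complement are both scanned (identical for palindromic sites);
## the cut offset is applied from the occurrence start in plus-strand
## coordinates, one double-strand break per site.
.cutBoundaries <- function(seqChr, enzyme) {
  subject <- Biostrings::DNAString(seqChr)
  rec <- Biostrings::DNAString(enzyme@recognition)
  starts <- Biostrings::start(Biostrings::matchPattern(rec, subject))
  rcRec <- Biostrings::reverseComplement(rec)
  if (as.character(rcRec) != as.character(rec))
    starts <- union(starts,
                    Biostrings::start(Biostrings::matchPattern(rcRec, subject)))
  sort(unique(starts + enzyme@cutOffset - 1L))
}

#' Digest a sequence into restriction fragments
#'
#' Fragments partition the sequence, with boundaries at every occurrence of
#' the recognition site (both strands scanned; BfaI's CTAG is its own
#' reverse complement) cut after `cutOffset` bases.  A sequence with no
#' sites yields a single fragment.
#'
#' @param sequence DNA (character, [Biostrings::DNAString] or layout).
#' @param enzyme An [EnzymeSpec-class].
#' @return [IRanges::IRanges] of fragments (1-based, closed).
#' @export
digestFragments <- function(sequence, enzyme = enzymeSpec()) {
  g <- .asNamedChar(sequence)
  stopifnot(length(g) == 1L)
  len <- nchar(g)
  b <- .cutBoundaries(g, enzyme)
  b <- b[b >= 1L & b < len]
  starts <- c(1L, b + 1L)
  ends <- c(b, len)
  IRanges::IRanges(starts, ends)
}

## Scan one genome for all potential TD bands (no selectivity applied).
## A band starts at a selective-primer annealing occurrence oriented outward
## and ends at the nearest downstream cut boundary; its primer-side
## selective triplet is the reverse complement of its final three bases.
.scanBands <- function(genomes, enzyme, primers, maxSize = 1000L,
                       adapterConstant = 0L) {
  genomes <- .asNamedChar(genomes)
  sel <- primers@selectiveLtr
  selLen <- nchar(sel)
  rows <- list()
  for (nm in names(genomes)) {
    g <- genomes[[nm]]
    if (nchar(g) < selLen) next
    subject <- Biostrings::DNAString(g)
    cuts <- .cutBoundaries(g, enzyme)
    plus <- Biostrings::start(
      Biostrings::matchPattern(Biostrings::DNAString(sel), subject))
    minus <- Biostrings::start(Biostrings::matchPattern(
      Biostrings::reverseComplement(Biostrings::DNAString(sel)), subject))
    if (length(plus) && length(cuts)) {
      ## nearest boundary at or beyond the annealing segment end
      idx <- findInterval(plus + selLen - 1L, cuts) + 1L
      ok <- idx <= length(cuts)
      for (i in which(ok)) {
        s <- plus[i]; e <- cuts[idx[i]]
        len <- e - s + 1L
        if (len < selLen + 3L || len + adapterConstant > maxSize) next
        bseq <- substr(g, s, e)
        rows[[length(rows) + 1L]] <- data.frame(
          seqname = nm, start = s, end = e, strand = "+",
          size = len + adapterConstant, sequence = bseq,
          triplet = revComp(substr(bseq, len - 2L, len)),
          stringsAsFactors = FALSE)
      }
    }
    if (length(minus) && length(cuts)) {
      ## band extends leftward from the annealing site to the nearest
      ## upstream boundary; the cut on the opposite strand falls after
      ## `cutOffset` bases from that strand's site start, so the fragment
      ## begins (in plus coordinates) at boundary + m - 2*cutOffset + 1;
      ## stored in amplified (reverse-complement) orientation so it begins
      ## with the annealing segment and ends at its strand's cut
      shiftRC <- nchar(enzyme@recognition) - 2L * enzyme@cutOffset
      idx <- findInterval(minus - 1L - shiftRC, cuts)
      ok <- idx >= 1L
      for (i in which(ok)) {
        e <- minus[i] + selLen - 1L; s <- cuts[idx[i]] + 1L + shiftRC
        len <- e - s + 1L
        if (len < selLen + 3L || len + adapterConstant > maxSize) next
        bseq <- revComp(substr(g, s, e))
        rows[[length(rows) + 1L]] <- data.frame(
          seqname = nm, start = s, end = e, strand = "-",
          size = len + adapterConstant, sequence = bseq,
          triplet = revComp(substr(bseq, len - 2L, len)),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(S4Vectors::DataFrame(seqname = character(), start = integer(),
                                end = integer(), strand = character(),
                                size = integer(), sequence = character(),
                                triplet = character()))
  df <- do.call(rbind, rows)
  df <- df[order(df$seqname, df$start, df$strand), ]
  rownames(df) <- NULL
  S4Vectors::DataFrame(df)
}

#' Amplify transposon-display bands from a genome
#'
#' Emits one band for every occurrence of the selective LTR annealing
#' segment oriented outward into flanking DNA, ending at the nearest
#' downstream cut boundary.  A band is retained only if the three genomic
#' bases immediately interior to the cut site match the primer's selective
#' triplet with at most `mismatchTolerance` mismatches (all bands are
#' retained when the primer carries no selective bases); bands longer than
#' `maxSize` fall outside the gel-resolvable range and are dropped.
#'
#' @param genome Named genome (character vector, `DNAStringSet`, or layout).
#' @param enzyme An [EnzymeSpec-class].
#' @param primers A [PrimerSet-class].
#' @param mismatchTolerance Allowed mismatches against the selective triplet
#'   (0 = fully selective; 1 emulates the weak selectivity seen on real
#'   adapter primers).
#' @param maxSize Maximum band size (bp).
#' @param adapterConstant Constant added to the genomic band length to give
#'   the gel size (primer/adapter tails), default 0.
#' @return [S4Vectors::DataFrame] of bands with source coordinates, size,
#'   sequence (amplified orientation) and genomic selective triplet.
#' @export
amplifyBands <- function(genome, enzyme = enzymeSpec(), primers,
                         mismatchTolerance = 0L, maxSize = 1000L,
                         adapterConstant = 0L) {
  stopifnot(mismatchTolerance >= 0L)
  bands <- .scanBands(genome, enzyme, primers, maxSize, adapterConstant)
  sb <- primers@selectiveBases
  if (nchar(sb) == 0L || nrow(bands) == 0L) return(bands)
  keep <- vapply(bands$triplet, function(t) hammingDistance(t, sb),
                 integer(1)) <= mismatchTolerance
  bands[keep, ]
}

#' Run a full transposon display on two genotypes
#'
#' Amplifies all bands from a B-plus and a B-minus genome and distributes
#' them over the 64 selective-triplet lanes: a band appears in every lane
#' whose triplet matches its genomic triplet within `mismatchTolerance`
#' mismatches (so each lane is the band profile of one selective adapter
#' primer, and all 64 triplet combinations are always present).
#'
#' @param bPlus,bMinus Genomes of the B-carrying and B-lacking genotypes.
#' @param enzyme,primers,mismatchTolerance,maxSize,adapterConstant As in
#'   [amplifyBands()].
#' @return List with elements `lanes` (the 64 triplets), `bPlus` and
#'   `bMinus` (band tables with a `lane` column) and `tolerance`.
#' @export
runDisplay <- function(bPlus, bMinus, enzyme = enzymeSpec(), primers,
                       mismatchTolerance = 0L, maxSize = 1000L,
                       adapterConstant = 0L) {
  lanes <- allKmers(3)
  assign <- function(bands) {
    if (nrow(bands) == 0L) {
      bands$lane <- character(0)
      return(bands)
    }
    hits <- if (mismatchTolerance == 0L) as.list(bands$triplet) else
      lapply(seq_len(nrow(bands)), function(i) {
        d <- vapply(lanes, function(l) hammingDistance(l, bands$triplet[i]),
                    integer(1))
        lanes[d <= mismatchTolerance]
      })
    idx <- rep(seq_len(nrow(bands)), lengths(hits))
    out <- bands[idx, ]
    out$lane <- unlist(hits)
    out <- out[order(out$lane, out$seqname, out$start, out$strand), ]
    rownames(out) <- NULL
    out
  }
  list(lanes = lanes,
       bPlus = assign(.scanBands(bPlus, enzyme, primers, maxSize,
                                 adapterConstant)),
       bMinus = assign(.scanBands(bMinus, enzyme, primers, maxSize,
                                  adapterConstant)),
       tolerance = as.integer(mismatchTolerance))
}

#' Call genotype-specific bands from display profiles
#'
#' A band is B-specific iff its size bin (plus or minus
#' `sizeBinTolerance` bp) is present in the B-plus lane and absent from the
#' B-minus lane for the same selective triplet.
#'
#' @param profiles Output of [runDisplay()].
#' @param sizeBinTolerance Size-bin half-width in bp (gels resolve
#'   integers; default 0).
#' @return [S4Vectors::DataFrame] of B-specific bands (with `lane`).
#' @export
callBSpecific <- function(profiles, sizeBinTolerance = 0L) {
  bp <- profiles$bPlus; bm <- profiles$bMinus
  if (nrow(bp) == 0L) return(bp)
  keep <- vapply(seq_len(nrow(bp)), function(i) {
    inLane <- bm$lane == bp$lane[i]
    !any(inLane & abs(bm$size - bp$size[i]) <= sizeBinTolerance)
  }, logical(1))
  bp[keep, ]
}

#' Annotate bands with planted junction offsets
#'
#' Records, for each band, the positions (1-based, band-local: a junction at
#' offset `k` separates band bases `k - 1` and `k`) of every planted layout
#' junction the band spans.  Flank bands always carry the LTR/flank junction
#' immediately after the LTR tail.
#'
#' @param bands Band table from [amplifyBands()] or [callBSpecific()].
#' @param layout The [CentromereLayout-class] the bands derive from.
#' @return The band table with an added `junctions` [IRanges::IntegerList]
#'   column.
#' @export
annotateBandJunctions <- function(bands, layout) {
  jpos <- layout@junctions$pos
  label <- layout@seqnameLabel
  offs <- lapply(seq_len(nrow(bands)), function(i) {
    if (bands$seqname[i] != label) return(integer())
    s <- bands$start[i]; e <- bands$end[i]
    j <- jpos[jpos > s & jpos <= e]
    if (bands$strand[i] == "+") sort(j - s + 1L) else sort(e - j + 2L)
  })
  bands$junctions <- IRanges::IntegerList(offs)
  bands
}

#' Collapse duplicate bands into named markers
#'
#' Bands with identical sequence merge into one marker whose selective
#' triplet set is the union of the lanes that amplified it (in discovery
#' order: lexicographic lane order, then genomic position).  Marker names
#' follow the convention `CRM2-<triplets joined by ->-<size>`; ids are
#' assigned TD1..TDn in discovery order and are reassigned to minimal-map
#' order by [orderMarkers()].  Collapsing is idempotent.
#'
#' @param bands Band table with a `lane` column (from [callBSpecific()]),
#'   optionally annotated with junction offsets.
#' @return [S4Vectors::DataFrame] of markers: `id`, `name`, `size`,
#'   `sequence`, `triplets` (CharacterList), first source coordinates,
#'   `nSources` and `junctions` (IntegerList).
#' @export
collapseAndName <- function(bands) {
  if (nrow(bands) == 0L) stop("no bands to collapse")
  if (is.null(bands$lane)) bands$lane <- bands$triplet
  if (is.null(bands$junctions))
    bands$junctions <- IRanges::IntegerList(rep(list(integer()), nrow(bands)))
  o <- order(bands$lane, bands$seqname, bands$start)
  bands <- bands[o, ]
  seqs <- bands$sequence
  first <- !duplicated(seqs)
  keyOrder <- seqs[first]
  idx <- split(seq_len(nrow(bands)), match(seqs, keyOrder))
  rows <- lapply(seq_along(keyOrder), function(k) {
    rs <- idx[[k]]
    trip <- unique(bands$lane[rs])
    i0 <- rs[1L]
    S4Vectors::DataFrame(
      id = NA_character_,
      name = paste0("CRM2-", paste(trip, collapse = "-"), "-",
                    bands$size[i0]),
      size = bands$size[i0],
      sequence = bands$sequence[i0],
      triplets = IRanges::CharacterList(list(trip)),
      seqname = bands$seqname[i0],
      start = bands$start[i0],
      end = bands$end[i0],
      strand = bands$strand[i0],
      nSources = length(unique(paste(bands$seqname[rs], bands$start[rs],
                                     bands$strand[rs]))),
      junctions = bands$junctions[i0])
  })
  out <- do.call(rbind, rows)
  out$id <- paste0("TD", seq_len(nrow(out)))
  rownames(out) <- out$id
  out
}

#' Parse a marker name back into its selective triplets and size
#'
#' @param name Marker name(s) of the form `CRM2-<t1>-...-<tk>-<size>`.
#' @return List (one element per name) with `triplets` and `size`.
#' @export
parseMarkerName <- function(name) {
  lapply(name, function(x) {
    parts <- strsplit(x, "-", fixed = TRUE)[[1]]
    stopifnot(length(parts) >= 3L, parts[1] == "CRM2")
    list(triplets = parts[2:(length(parts) - 1L)],
         size = as.integer(parts[length(parts)]))
  })
}

#' Filter markers by presence in a retained genome
#'
#' A marker is retained iff its full band sequence occurs (on either
#' strand) in the retained genome, emulating the screen against a miniB
#' chromosome that removed markers lying outside the centromere region.
#'
#' @param markers Marker table from [collapseAndName()].
#' @param retainedGenome DNA (character, `DNAString(Set)`, layout or
#'   derivative).
#' @return The subset of `markers` present in the retained genome.
#' @export
filterByGenome <- function(markers, retainedGenome) {
  g <- .asNamedChar(retainedGenome)
  combined <- paste(g, collapse = strrep("N", 50L))
  keep <- vapply(markers$sequence, occursIn, logical(1), subject = combined,
                 USE.NAMES = FALSE)
  markers[keep, ]
}
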