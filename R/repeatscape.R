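## Synthetic centromere world: repeat library, nested-insertion layouts,
## misdivision pedigree, ChIP/control read sets.  Everything is a pure
## function of (inputs, seed); one master seed fans out to per-operation
## child seeds via childSeed().

#' Build the repeat library used to compose synthetic genomes
#'
#' Generates a named set of repeat units: a CentC-like tandem monomer
#' (156 bp by default), a CRM2-like LTR retroelement (LTR + internal + LTR)
#' whose LTR carries the two transposon-display primer annealing segments, a
#' B-repeat-like unit, and filler retroelements.  The selective primer
#' segment sits `ltrTail` bases from the LTR end, so every amplified band
#' carries `ltrTail` bp of LTR sequence (112 by default, mirroring the
#' roughly 112 bp of CRM2 LTR present on every real marker).  The LTR tail is
#' kept free of the restriction site so bands always reach the LTR/flank
#' junction, and distinct units are re-drawn until they share no exact
#' `kmerCheck`-mers, so junctions between units are resolvable.
#'
#' @param seed Integer master seed.
#' @param centcLen Monomer length of the CentC-like tandem repeat.
#' @param ltrLen,internalLen CRM2-like element dimensions (element length is
#'   `2 * ltrLen + internalLen`).
#' @param bRepeatLen B-repeat-like unit length.
#' @param fillerLens Named integer vector of filler retroelement lengths.
#' @param gc GC content of generated sequence.
#' @param primerLen Length of the primer annealing segments.
#' @param ltrTail LTR bases between the selective annealing start and the
#'   LTR end.
#' @param kmerCheck Word size for the cross-unit uniqueness audit.
#' @return A [RepeatLibrary-class] object.
#' @export
buildRepeatLibrary <- function(seed,
                               centcLen = 156L,
                               ltrLen = 160L,
                               internalLen = 300L,
                               bRepeatLen = 600L,
                               fillerLens = c(sela = 700L, huck = 800L,
                                              doke = 500L),
                               gc = 0.45,
                               primerLen = 20L,
                               ltrTail = 112L,
                               kmerCheck = 20L) {
  lens <- c(centc = centcLen, ltr = ltrLen, internal = internalLen,
            b_repeat = bRepeatLen, fillerLens)
  if (any(lens <= 0)) stop("unit lengths must be positive")
  if (any(lens < primerLen))
    stop("unit lengths must not be shorter than the TD primer subsequences")
  if (ltrLen < ltrTail + primerLen + 4L)
    stop("ltrLen too short to host the primer annealing segments")
  withSeed(childSeed(seed, "repeat_library"), {
    site <- "CTAG"   # BfaI recognition; tails are kept free of it
    drawLtr <- function() {
      for (i in 1:200) {
        x <- randomDNA(ltrLen, gc)
        tail <- substr(x, ltrLen - ltrTail + 1L, ltrLen)
        if (grepl(site, tail, fixed = TRUE)) next
        sel <- substr(x, ltrLen - ltrTail + 1L, ltrLen - ltrTail + primerLen)
        if (length(gregexpr(sel, x, fixed = TRUE)[[1]]) != 1L) next
        if (grepl(sel, revComp(x), fixed = TRUE)) next
        return(x)
      }
      stop("failed to generate an LTR satisfying the primer constraints")
    }
    ltr <- drawLtr()
    selective <- substr(ltr, ltrLen - ltrTail + 1L, ltrLen - ltrTail + primerLen)
    primary <- substr(ltr, ltrLen - ltrTail - primerLen - 3L,
                      ltrLen - ltrTail - 4L)
    units <- list(
      centc = randomDNA(centcLen, gc),
      b_repeat = randomDNA(bRepeatLen, gc)
    )
    for (nm in names(fillerLens)) units[[nm]] <- randomDNA(fillerLens[[nm]], gc)
    ## re-draw any non-LTR unit sharing long words with another unit
    audit <- function(units) {
      nms <- names(units)
      for (i in seq_along(nms)) for (j in seq_along(nms)) {
        if (i < j && sharedKmerCount(units[[i]], units[[j]], kmerCheck) > 0)
          return(nms[j])
      }
      NULL
    }
    for (round in 1:50) {
      all <- c(units, list(crm2_ltr = ltr))
      bad <- audit(all)
      if (is.null(bad)) break
      if (bad == "crm2_ltr") ltr <- drawLtr() else
        units[[bad]] <- randomDNA(nchar(units[[bad]]), gc)
    }
    ## the internal region always carries a restriction site, so bands
    ## primed off the interior-facing LTR tail terminate inside the element
    ## (they are common to every copy and cancel between genotypes) instead
    ## of running through it into flanking DNA
    internal <- randomDNA(internalLen, gc)
    mid <- max(1L, internalLen %/% 2L)
    substr(internal, mid, mid + 3L) <- "CTAG"
    crm2 <- paste0(ltr, internal, ltr)
    out <- new("RepeatLibrary",
               units = Biostrings::DNAStringSet(
                 unlist(c(units, list(crm2_ltr = ltr, crm2 = crm2)))),
               primarySite = primary,
               selectiveSite = selective,
               ltrTail = as.integer(ltrTail),
               params = list(centcLen = as.integer(centcLen),
                             ltrLen = as.integer(ltrLen),
                             internalLen = as.integer(internalLen),
                             gc = gc, primerLen = as.integer(primerLen),
                             seed = as.integer(seed)))
    validObject(out)
    out
  })
}

## ---- internal layout machinery ----------------------------------------

## Insert `elem` immediately before position p of a layout state
## (list: seq, features df, junctions df), updating coordinates.
.insertAt <- function(state, p, elem, unit, junctionKinds, amplifiableSide) {
  w <- nchar(elem)
  len <- nchar(state$seq)
  stopifnot(p >= 2L, p <= len)
  f <- state$features
  containing <- which(f$start <= p - 1L & f$end >= p)
  newDepth <- if (length(containing)) f$depth[containing] + 1L else 1L
  shift <- function(x) ifelse(x >= p, x + w, x)
  extra <- NULL
  if (length(containing)) {
    cf <- f[containing, ]
    extra <- rbind(
      data.frame(start = cf$start, end = p - 1L,
                 unit = cf$unit, depth = cf$depth),
      data.frame(start = p + w, end = cf$end + w,
                 unit = cf$unit, depth = cf$depth))
    f <- f[-containing, ]
  }
  f$start <- shift(f$start); f$end <- shift(f$end)
  f <- rbind(f, extra,
             data.frame(start = p, end = p + w - 1L,
                        unit = unit, depth = newDepth))
  f <- f[order(f$start), ]
  j <- state$junctions
  if (nrow(j)) j$pos <- shift(j$pos)
  j <- rbind(j, data.frame(
    pos = c(p, p + w),
    kind = junctionKinds,
    amplifiable = c(amplifiableSide == "left", amplifiableSide == "right")))
  state$seq <- paste0(substr(state$seq, 1L, p - 1L), elem,
                      substr(state$seq, p, len))
  state$features <- f
  state$junctions <- j
  state
}

## A CRM2-like element copy with per-copy divergence.  The terminal
## `ltrTail` bases of each LTR -- the primer-bearing end adjacent to the
## insertion junction -- are kept at consensus: this is the conserved
## segment that lets one primer pair amplify every copy, and it makes every
## marker's LTR portion identical, so tail-interior reads tie across
## markers and are discarded by the unique mapper (a marker's mappable
## uniqueness resides wholly in its flank, as for real junction tags).
.crm2Copy <- function(lib, rate) {
  crm2 <- as.character(lib@units[["crm2"]])
  if (rate <= 0) return(crm2)
  L <- nchar(as.character(lib@units[["crm2_ltr"]]))
  tailLen <- lib@ltrTail
  ltr <- as.character(lib@units[["crm2_ltr"]])
  tailCons <- substr(ltr, L - tailLen + 1L, L)
  x <- mutateSequence(crm2, rate)
  substr(x, L - tailLen + 1L, L) <- tailCons
  substr(x, nchar(x) - tailLen + 1L, nchar(x)) <- tailCons
  x
}

.stateToLayout <- function(state, cenh3Domain, label) {
  gr <- GenomicRanges::GRanges(
    seqnames = label,
    ranges = IRanges::IRanges(state$features$start, state$features$end),
    unit = state$features$unit, depth = state$features$depth)
  out <- new("CentromereLayout",
             sequence = Biostrings::DNAString(state$seq),
             features = gr,
             cenh3Domain = cenh3Domain,
             junctions = state$junctions,
             seqnameLabel = label)
  validObject(out)
  out
}

#' Simulate a repetitive centromere with nested retroelement insertions
#'
#' Builds a backbone of CentC-like tandem arrays interspersed with B-repeat
#' blocks, then inserts `nCrmInsertions` CRM2-like element copies at random
#' positions (possibly inside earlier insertions, creating nested
#' arrangements).  Each insertion creates two LTR-flank junctions, recorded
#' in the planted-junction table; the junction adjacent to the outward-
#' pointing LTR tail (right edge for plus-orientation copies, left edge for
#' minus) is flagged `amplifiable`, since the transposon-display primer
#' amplifies across only that edge.  Tandem-repeat copies diverge at
#' per-copy substitution rates, emulating the acquired polymorphism that
#' makes real junction flanks effectively unique at read scale.
#'
#' @param lib A [RepeatLibrary-class].
#' @param nCrmInsertions Number of CRM2-like insertions (>= 0).
#' @param seed Integer master seed.
#' @param nArrays Number of CentC-like tandem arrays in the backbone.
#' @param monomersPerArray CentC monomer copies per array.
#' @param bRepeatCopies B-repeat copies per inter-array block.
#' @param divergence Named per-copy substitution rates for `centc`,
#'   `b_repeat` and `crm2` copies.  Element copies diverge (10% for CRM2,
#'   with the primer annealing segments kept intact so one primer pair
#'   still amplifies every copy): it is this acquired polymorphism that
#'   makes junction markers effectively unique at read scale.
#' @param cenh3Fraction Fraction of the final sequence covered by the
#'   central CENH3 occupancy domain.
#' @param maxLength Guard: error if the layout would exceed this size.
#' @return A [CentromereLayout-class].
#' @export
simulateCentromere <- function(lib, nCrmInsertions = 40L, seed,
                               nArrays = 5L, monomersPerArray = 150L,
                               bRepeatCopies = 1L,
                               divergence = c(centc = 0.15, b_repeat = 0.10,
                                              crm2 = 0.10),
                               cenh3Fraction = 0.4,
                               maxLength = 2e6) {
  stopifnot(nCrmInsertions >= 0L, nArrays >= 1L, monomersPerArray >= 1L)
  withSeed(childSeed(seed, "centromere"), {
    centc <- as.character(lib@units[["centc"]])
    brep <- as.character(lib@units[["b_repeat"]])
    div <- function(nm) if (nm %in% names(divergence)) divergence[[nm]] else 0
    blocks <- list()
    for (i in seq_len(nArrays)) {
      arr <- paste(vapply(seq_len(monomersPerArray),
                          function(k) mutateSequence(centc, div("centc")),
                          character(1)), collapse = "")
      blocks[[length(blocks) + 1L]] <- list(seq = arr, unit = "centc_array")
      if (i < nArrays && bRepeatCopies > 0) {
        bb <- paste(vapply(seq_len(bRepeatCopies),
                           function(k) mutateSequence(brep, div("b_repeat")),
                           character(1)), collapse = "")
        blocks[[length(blocks) + 1L]] <- list(seq = bb, unit = "b_repeat")
      }
    }
    seqs <- vapply(blocks, `[[`, character(1), "seq")
    lens <- nchar(seqs)
    ends <- cumsum(lens)
    starts <- c(1L, head(ends, -1L) + 1L)
    state <- list(
      seq = paste(seqs, collapse = ""),
      features = data.frame(start = starts, end = ends,
                            unit = vapply(blocks, `[[`, character(1), "unit"),
                            depth = 0L),
      junctions = if (length(starts) > 1L)
        data.frame(pos = starts[-1L], kind = "backbone", amplifiable = FALSE)
      else data.frame(pos = integer(), kind = character(),
                      amplifiable = logical()))
    elemLen <- nchar(as.character(lib@units[["crm2"]]))
    if (nchar(state$seq) + nCrmInsertions * elemLen > maxLength)
      stop("layout cannot host the requested insertions within maxLength")
    for (i in seq_len(nCrmInsertions)) {
      p <- sample(2:nchar(state$seq), 1L)
      copy <- .crm2Copy(lib, div("crm2"))
      ori <- sample(c("+", "-"), 1L)
      if (ori == "-") copy <- revComp(copy)
      state <- .insertAt(state, p, copy, "crm2",
                         junctionKinds = c("ltr_flank", "ltr_flank"),
                         amplifiableSide = ifelse(ori == "+", "right", "left"))
    }
    len <- nchar(state$seq)
    pad <- floor(len * (1 - cenh3Fraction) / 2)
    domain <- if (cenh3Fraction > 0)
      IRanges::IRanges(pad + 1L, len - pad) else IRanges::IRanges()
    .stateToLayout(state, domain, "B_centromere")
  })
}

#' Simulate a background (B-minus) genome
#'
#' A mostly unique random genome carrying a few filler-element and
#' CRM2-like copies, standing in for the reference genome of a line without
#' the supernumerary chromosome.  Shared CRM2 copies make the display's
#' genotype comparison meaningful: bands amplified from background copies
#' appear in both lanes and are removed by B-specific calling.
#'
#' @param lib A [RepeatLibrary-class].
#' @param seed Integer master seed.
#' @param length Backbone length (unique sequence).
#' @param nCrm CRM2-like insertions in the background.
#' @param nFiller Copies of each filler unit to insert.
#' @param divergence Per-copy substitution rates (as in
#'   [simulateCentromere()]).
#' @return A [CentromereLayout-class] with an empty CENH3 domain, labelled
#'   `background`.
#' @export
simulateBackground <- function(lib, seed, length = 30000L, nCrm = 4L,
                               nFiller = 2L,
                               divergence = c(filler = 0.05, crm2 = 0.10)) {
  stopifnot(length > 100L, nCrm >= 0L)
  withSeed(childSeed(seed, "background"), {
    state <- list(
      seq = randomDNA(length, lib@params$gc),
      features = data.frame(start = 1L, end = as.integer(length),
                            unit = "unique", depth = 0L),
      junctions = data.frame(pos = integer(), kind = character(),
                             amplifiable = logical()))
    fillers <- setdiff(names(lib@units),
                       c("centc", "b_repeat", "crm2", "crm2_ltr"))
    for (nm in fillers) for (i in seq_len(nFiller)) {
      copy <- mutateSequence(as.character(lib@units[[nm]]),
                             divergence[["filler"]])
      state <- .insertAt(state, sample(2:nchar(state$seq), 1L), copy, nm,
                         c("backbone", "backbone"), amplifiableSide = "none")
    }
    for (i in seq_len(nCrm)) {
      copy <- .crm2Copy(lib, divergence[["crm2"]])
      ori <- sample(c("+", "-"), 1L)
      if (ori == "-") copy <- revComp(copy)
      state <- .insertAt(state, sample(2:nchar(state$seq), 1L), copy, "crm2",
                         c("ltr_flank", "ltr_flank"),
                         amplifiableSide = ifelse(ori == "+", "right", "left"))
    }
    .stateToLayout(state, IRanges::IRanges(), "background")
  })
}

#' Default misdivision pedigree specification
#'
#' Mirrors the published pedigree topology: the progenitor gives rise to a
#' pseudoisochromosome (PI); two second-generation telocentrics derive from
#' PI; an isochromosome and a core-less telocentric derive from Telo2-1; and
#' a fourth-generation telocentric derives from Iso3 with its cut placed so
#' that its retained interval coincides exactly with Telo2-2's (the two
#' lines have the same basic makeup).  The core-less telocentric retains
#' only a sub-marker-sized terminal remnant (fraction 0.999), emulating a
#' derivative with no canonical centromere sequences left beyond small
#' repeat arrays.  Deletion fractions are of the parent's retained length,
#' from the left end; transmission rates are attached where the
#' corresponding real derivatives have published values (0.53 for Iso3,
#' 0.43 for Telo2-2 and its look-alike), and a nominal 0.10 for the
#' unstable core-less derivative.
#'
#' @param rootLength Length of the root centromere (used to place the
#'   Telo4-11 cut exactly on Telo2-2's boundary).
#' @return data.frame with columns `name`, `parent`, `fraction`, `side`,
#'   `transmission`.
#' @export
defaultPedigreeSpec <- function(rootLength) {
  L <- as.integer(rootLength)
  cPI <- round(0.12 * L)
  L1 <- L - cPI
  cT21 <- round(0.04 * L1)
  L2 <- L1 - cT21
  cIso <- round(0.03 * L2)
  L3 <- L2 - cIso
  cT22 <- round(0.10 * L1)
  c411 <- cT22 - cT21 - cIso
  stopifnot(c411 > 0L)
  data.frame(
    name = c("PI", "Telo2_1", "Telo2_2", "Iso3", "Telo3_3", "Telo4_11"),
    parent = c("TB9Sb", "PI", "PI", "Telo2_1", "Telo2_1", "Iso3"),
    fraction = c(0.12, 0.04, 0.10, 0.03, 0.999, c411 / L3),
    side = "left",
    transmission = c(NA, NA, 0.43, 0.53, 0.10, 0.43),
    stringsAsFactors = FALSE)
}

#' Derive a pedigree of misdivision genomes by nested terminal deletions
#'
#' Each derivative's sequence is its parent's with a single terminal-side
#' interval excised (misdivision removes one side of the centromere), so
#' retained intervals are nested down the pedigree and each derivative's
#' retained interval is contiguous in root coordinates.
#'
#' @param root A [CentromereLayout-class] (the progenitor centromere).
#' @param spec data.frame as returned by [defaultPedigreeSpec()]; parents
#'   must precede children.  `NULL` uses the default.
#' @param rootName Name of the progenitor derivative.
#' @param rootTransmission Transmission rate attached to the root (NA).
#' @return Named list of [DerivativeGenome-class], root first.
#' @export
derivePedigree <- function(root, spec = NULL, rootName = "TB9Sb",
                           rootTransmission = NA_real_) {
  L <- length(root@sequence)
  if (is.null(spec)) spec <- defaultPedigreeSpec(L)
  stopifnot(all(c("name", "parent", "fraction") %in% names(spec)))
  if (anyDuplicated(c(rootName, spec$name)))
    stop("pedigree spec is not a tree: duplicated names")
  if (any(spec$fraction < 0 | spec$fraction > 1))
    stop("deletion fractions must lie in [0, 1]")
  if (!"side" %in% names(spec)) spec$side <- "left"
  if (!"transmission" %in% names(spec)) spec$transmission <- NA_real_
  out <- list()
  out[[rootName]] <- new("DerivativeGenome",
                         name = rootName, parent = NA_character_,
                         deletions = IRanges::IRanges(),
                         sequence = root@sequence,
                         retainedRoot = IRanges::IRanges(1L, L),
                         transmission = rootTransmission)
  for (i in seq_len(nrow(spec))) {
    nm <- spec$name[i]; pa <- spec$parent[i]
    if (!pa %in% names(out))
      stop("pedigree spec is not a tree: unknown parent '", pa, "'")
    parent <- out[[pa]]
    plen <- length(parent@sequence)
    cut <- as.integer(round(spec$fraction[i] * plen))
    if (cut > plen) stop("deletion outside parent bounds")
    ra <- IRanges::start(parent@retainedRoot)
    rb <- IRanges::end(parent@retainedRoot)
    if (cut == 0L) {
      del <- IRanges::IRanges()
      keep <- IRanges::IRanges(1L, plen)
      retained <- IRanges::IRanges(ra, rb)
    } else if (identical(spec$side[i], "right")) {
      del <- IRanges::IRanges(plen - cut + 1L, plen)
      keep <- IRanges::IRanges(1L, plen - cut)
      retained <- IRanges::IRanges(ra, rb - cut)
    } else {
      del <- IRanges::IRanges(1L, cut)
      keep <- IRanges::IRanges(cut + 1L, plen)
      retained <- IRanges::IRanges(ra + cut, rb)
    }
    seq <- if (IRanges::width(keep) > 0)
      Biostrings::subseq(parent@sequence, IRanges::start(keep),
                         IRanges::end(keep))
    else Biostrings::DNAString("")
    out[[nm]] <- new("DerivativeGenome",
                     name = nm, parent = pa, deletions = del,
                     sequence = seq, retainedRoot = retained,
                     transmission = spec$transmission[i])
  }
  out
}

#' Simulate a ChIP or control sequencing library
#'
#' Read start positions are drawn with density proportional to 1 outside
#' enriched intervals and to the requested fold inside them.  For
#' `fragmented_control` libraries the density is uniform, and for
#' `inactive_chip` libraries the enrichment map is suppressed entirely: the
#' fold map models CENH3 occupancy and an epigenetically inactivated
#' centromere has none (see the methods vignette for why suppression is not
#' restricted to the annotated domain).  Reads are sampled from both strands
#' with probability one half and are error-free unless a substitution rate
#' is given.
#'
#' @param genome Named [Biostrings::DNAStringSet] (or a single
#'   [DerivativeGenome-class] / [CentromereLayout-class]).
#' @param enriched [GenomicRanges::GRanges] with a numeric `fold` metadata
#'   column, on the genome's sequence names; `NULL` for a flat library.
#' @param role Library role (see [ReadSet-class]).
#' @param nReads Number of reads (> 0).
#' @param readLength Read length in nt (default 150, a NextSeq-style
#'   single-end length).
#' @param errorRate Per-base substitution rate.
#' @param seed Integer master seed.
#' @param libraryName Label for the library.
#' @return A [ReadSet-class]; the `truth` slot records each read's source.
#' @export
simulateChipReads <- function(genome, enriched = NULL,
                              role = "active_chip", nReads,
                              readLength = 150L, errorRate = 0,
                              seed, libraryName = role) {
  if (is(genome, "DerivativeGenome") || is(genome, "CentromereLayout")) {
    label <- if (is(genome, "CentromereLayout")) genome@seqnameLabel
             else genome@name
    genome <- setNames(Biostrings::DNAStringSet(list(layoutSequence(genome))),
                       label)
  }
  stopifnot(is(genome, "DNAStringSet"), !is.null(names(genome)))
  if (nReads <= 0) stop("nReads must be positive")
  if (!role %in% READSET_ROLES)
    stop("invalid role '", role, "'")
  if (!is.null(enriched) && length(enriched) &&
      any(S4Vectors::mcols(enriched)$fold < 0))
    stop("fold values must be >= 0")
  if (role %in% c("inactive_chip", "fragmented_control")) enriched <- NULL
  withSeed(childSeed(seed, paste0("reads_", libraryName)), {
    lens <- Biostrings::width(genome)
    if (any(lens < readLength)) stop("read length exceeds a source sequence")
    nPos <- lens - readLength + 1L
    weights <- lapply(seq_along(genome), function(i) rep(1, nPos[i]))
    names(weights) <- names(genome)
    if (!is.null(enriched) && length(enriched)) {
      for (k in seq_along(enriched)) {
        sn <- as.character(GenomicRanges::seqnames(enriched)[k])
        if (!sn %in% names(genome)) next
        i <- match(sn, names(genome))
        s <- max(1L, GenomicRanges::start(enriched)[k])
        e <- min(nPos[i], GenomicRanges::end(enriched)[k])
        if (s <= e)
          weights[[i]][s:e] <- S4Vectors::mcols(enriched)$fold[k]
      }
    }
    w <- unlist(weights, use.names = FALSE)
    seqIdx <- rep(seq_along(genome), nPos)
    posIdx <- unlist(lapply(nPos, seq_len), use.names = FALSE)
    pick <- sample.int(length(w), nReads, replace = TRUE, prob = w)
    refs <- names(genome)[seqIdx[pick]]
    starts <- posIdx[pick]
    strands <- sample(c("+", "-"), nReads, replace = TRUE)
    chr <- setNames(as.character(genome), names(genome))
    readStr <- character(nReads)
    for (nm in unique(refs)) {
      sel <- refs == nm
      readStr[sel] <- substring(chr[[nm]], starts[sel],
                                starts[sel] + readLength - 1L)
    }
    reads <- Biostrings::DNAStringSet(readStr)
    minus <- strands == "-"
    if (any(minus))
      reads[minus] <- Biostrings::reverseComplement(reads[minus])
    if (errorRate > 0) {
      reads <- Biostrings::DNAStringSet(vapply(as.character(reads),
        mutateSequence, character(1), rate = errorRate, USE.NAMES = FALSE))
    }
    names(reads) <- sprintf("r%06d", seq_len(nReads))
    out <- new("ReadSet",
               libraryName = libraryName, role = role, reads = reads,
               readLength = as.integer(readLength), seed = as.integer(seed),
               truth = S4Vectors::DataFrame(ref = refs, start = starts,
                                            strand = strands))
    validObject(out)
    out
  })
}
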