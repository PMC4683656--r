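test_that("digestion partitions sequences at every recognition site", {
  bfa <- enzymeSpec()
  expect_identical(as.character(digestFragments("AAAA", bfa)),
                   as.character(IRanges::IRanges(1, 4)))
  ## cut after the C of CTAG
  expect_identical(as.character(digestFragments("AACTAGAA", bfa)),
                   as.character(IRanges::IRanges(c(1, 4), c(3, 8))))
  ## partition property on random sequences with planted sites
  set.seed(42)
  for (i in 1:10) {
    g <- paste0(randomSeq(80, i), "CTAG", randomSeq(60, i + 100), "CTAG",
                randomSeq(40, i + 200))
    fr <- digestFragments(g, bfa)
    expect_identical(IRanges::start(fr)[1], 1L)
    expect_identical(IRanges::end(fr)[length(fr)], nchar(g))
    expect_true(all(diff(IRanges::start(fr)) ==
                      IRanges::width(fr)[-length(fr)]))
    pieces <- substring(g, IRanges::start(fr), IRanges::end(fr))
    expect_identical(paste(pieces, collapse = ""), g)
  }
  expect_error(enzymeSpec(recognition = "CTXG"), "ACGT")
})

test_that("amplification is selective, oriented and bounded", {
  lib <- tinyLib(1)
  ltr <- as.character(ltrSequence(lib))
  flank <- gsub("CTAG", "ATAG", randomSeq(120, 77), fixed = TRUE)
  genome <- c(g = paste0(randomSeq(50, 1), ltr, flank, "CTAG",
                         randomSeq(50, 2)))
  bands <- amplifyBands(genome, primers = tdPrimers(lib))
  expect_identical(nrow(bands), 1L)
  ## band carries the LTR tail plus flank up to the cut after C
  expect_identical(bands$size[1], 112L + 120L + 1L)
  expect_true(startsWith(bands$sequence[1], lib@selectiveSite))
  trip <- bands$triplet[1]

  ## exact selectivity: matching triplet amplifies, any other does not,
  ## and full tolerance recovers the band (monotone in tolerance)
  hit <- amplifyBands(genome, primers = tdPrimers(lib, trip))
  expect_identical(nrow(hit), 1L)
  other <- setdiff(allKmers(3), trip)[1]
  expect_identical(nrow(amplifyBands(genome,
                                     primers = tdPrimers(lib, other))), 0L)
  counts <- vapply(0:3, function(tol)
    nrow(amplifyBands(genome, primers = tdPrimers(lib, other),
                      mismatchTolerance = tol)), integer(1))
  expect_true(all(diff(counts) >= 0))
  expect_identical(counts[4], 1L)

  ## a genome without the annealing site yields no bands, not an error
  expect_identical(nrow(amplifyBands(c(g = randomSeq(300, 9)),
                                     primers = tdPrimers(lib))), 0L)

  ## outward orientation on the minus strand: reverse-complemented context
  genomeRC <- c(g = revComp(genome[[1]]))
  bandsRC <- amplifyBands(genomeRC, primers = tdPrimers(lib))
  expect_identical(nrow(bandsRC), 1L)
  expect_identical(bandsRC$strand[1], "-")
  expect_identical(bandsRC$sequence[1], bands$sequence[1])

  ## bands beyond the gel-resolvable range are dropped
  expect_identical(nrow(amplifyBands(genome, primers = tdPrimers(lib),
                                     maxSize = 100)), 0L)
})

test_that("amplification agrees with exhaustive junction enumeration", {
  lib <- tinyLib(1)
  lay <- tinyCentromere(lib, n = 8, seed = 5)
  g <- as.character(layoutSequence(lay))
  bands <- amplifyBands(c(B_centromere = g), primers = tdPrimers(lib),
                        maxSize = 1000)
  ## true double-strand cut boundaries (the final fragment end is the
  ## sequence end, not a cut)
  cuts <- setdiff(IRanges::end(digestFragments(g)), nchar(g))
  tailCons <- substr(as.character(ltrSequence(lib)), 49, 160)
  j <- plantedJunctions(lay)
  amp <- j[j$amplifiable, ]
  for (k in seq_len(nrow(amp))) {
    pos <- amp$pos[k]
    ## the outward tail must still be intact (a later nested insertion can
    ## disrupt it, in which case no primer can anneal)
    tailPlus <- pos > 112L && substr(g, pos - 112L, pos - 1L) == tailCons
    tailMinus <- pos + 111L <= nchar(g) &&
      substr(g, pos, pos + 111L) == revComp(tailCons)
    ## an amplifiable junction with an intact tail yields a junction-
    ## spanning band iff a real cut lies within gel range on the outward
    ## strand, far enough from the junction for the band to span it
    spanningPlus <- any(bands$strand == "+" & bands$start < pos &
                          bands$end >= pos)
    spanningMinus <- any(bands$strand == "-" & bands$start <= pos - 1L &
                           bands$end >= pos - 1L)
    nextCut <- cuts[cuts >= pos][1]
    prevCuts <- cuts[cuts <= pos - 4L]       # minus fragment starts at cut+3
    prevCut <- if (length(prevCuts)) max(prevCuts) else NA_integer_
    reachablePlus <- tailPlus && !is.na(nextCut) &&
      (nextCut - pos + 113L) <= 1000L
    reachableMinus <- tailMinus && !is.na(prevCut) &&
      (pos + 111L - (prevCut + 3L) + 1L) <= 1000L
    expect_true(spanningPlus || spanningMinus ||
                  !(reachablePlus || reachableMinus),
                info = paste("junction", pos))
  }
})

test_that("display produces 64 lanes and genotype comparison is sound", {
  lib <- tinyLib(1)
  lay <- tinyCentromere(lib, n = 4, seed = 2)
  bg <- simulateBackground(lib, seed = 2, length = 5000, nCrm = 1,
                           nFiller = 1)
  prof <- tinyDisplay(lib, lay, bg)
  expect_identical(length(prof$lanes), 64L)
  expect_identical(sort(unique(nchar(prof$lanes))), 3L)
  ## identical genotypes produce no B-specific bands
  g <- c(x = as.character(layoutSequence(lay)))
  same <- runDisplay(g, g, primers = tdPrimers(lib))
  expect_identical(nrow(callBSpecific(same)), 0L)
  ## B-specific calls occur in B-plus and have no size match in B-minus
  spec <- callBSpecific(prof)
  expect_gt(nrow(spec), 0L)
  for (i in seq_len(nrow(spec))) {
    inLane <- prof$bMinus$lane == spec$lane[i]
    expect_false(any(inLane & prof$bMinus$size == spec$size[i]))
  }
  ## determinism / order-independence of lane contents
  prof2 <- tinyDisplay(lib, lay, bg)
  expect_identical(as.data.frame(prof2$bPlus), as.data.frame(prof$bPlus))
})

test_that("duplicate collapse, naming and round-trip parsing", {
  seqA <- randomSeq(196, 3)
  seqB <- randomSeq(250, 4)
  bands <- S4Vectors::DataFrame(
    seqname = "B_centromere",
    start = c(10L, 10L, 10L, 10L, 500L),
    end = c(205L, 205L, 205L, 205L, 749L),
    strand = "+",
    size = c(196L, 196L, 196L, 196L, 250L),
    sequence = c(seqA, seqA, seqA, seqA, seqB),
    triplet = c("ACC", "CCA", "AGA", "ATA", "GGT"),
    lane = c("ACC", "CCA", "AGA", "ATA", "GGT"))
  mk <- collapseAndName(bands)
  expect_identical(nrow(mk), 2L)
  expect_identical(mk$name[1], "CRM2-ACC-AGA-ATA-CCA-196")
  expect_identical(mk$name[2], "CRM2-GGT-250")
  expect_identical(mk$id, c("TD1", "TD2"))
  ## single-triplet naming
  one <- collapseAndName(bands[1, ])
  expect_identical(one$name, "CRM2-ACC-196")
  ## idempotence: collapsing the collapsed bands changes nothing
  again <- collapseAndName(bands)
  expect_identical(as.data.frame(again[, c("id", "name", "size")]),
                   as.data.frame(mk[, c("id", "name", "size")]))
  ## names parse back to their triplets and size
  parsed <- parseMarkerName(mk$name)
  expect_identical(parsed[[1]]$size, 196L)
  expect_identical(sort(parsed[[1]]$triplets),
                   sort(c("ACC", "CCA", "AGA", "ATA")))
  expect_identical(parsed[[2]]$triplets, "GGT")
})

test_that("genome retention filter keeps exactly the present markers", {
  seqs <- vapply(1:8, function(i) randomSeq(150, i + 50), character(1))
  mk <- syntheticMarkers(seqs)
  keepIdx <- c(1, 3, 5, 6, 8)
  retained <- paste(c(seqs[keepIdx], randomSeq(500, 99)), collapse = "NNNN")
  out <- filterByGenome(mk, retained)
  expect_identical(out$id, paste0("TD", keepIdx))
  ## identity and empty-genome edge cases
  expect_identical(nrow(filterByGenome(mk, paste(seqs, collapse = ""))), 8L)
  expect_identical(nrow(filterByGenome(mk, "")), 0L)
  ## occurrence on the reverse strand still counts as present
  expect_identical(nrow(filterByGenome(mk[1, ], revComp(seqs[1]))), 1L)
})
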