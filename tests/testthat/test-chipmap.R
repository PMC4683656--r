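## An R-side brute-force aligner used as the independent oracle: scores a
## read by ungapped match counting at every in-bounds position of every
## reference, both orientations, and applies the same retention rule
## (unique best placement, margin over the runner-up, near-perfect
## identity over the aligned span).
bruteMap <- function(readChr, refs, minMargin = 5L, maxMismatches = 2L) {
  L <- nchar(readChr)
  best <- -1L; second <- 0L; bestCount <- 0L; bestHit <- NULL
  for (ori in c("+", "-")) {
    r <- if (ori == "+") readChr else revComp(readChr)
    rv <- strsplit(r, "")[[1]]
    for (nm in names(refs)) {
      sv <- strsplit(refs[[nm]], "")[[1]]
      n <- length(sv)
      if (n < L) next
      for (p in 1:(n - L + 1)) {
        sc <- sum(sv[p:(p + L - 1)] == rv & rv %in% c("A", "C", "G", "T"))
        if (sc > best) {
          second <- max(second, best, 0L); best <- sc; bestCount <- 1L
          bestHit <- list(ref = nm, start = p, strand = ori)
        } else if (sc == best) {
          bestCount <- bestCount + 1L; second <- best
        } else if (sc > second) second <- sc
      }
    }
  }
  if (bestCount == 1L && best - second >= minMargin &&
      nchar(readChr) - best <= maxMismatches)  # fully in-bounds placements
    c(bestHit, list(score = best, margin = best - second))
  else NULL
}

test_that("seed index lookup matches brute-force substring scanning", {
  idx <- buildIndex(Biostrings::DNAStringSet(c(a = "ACGTACGT")), k = 4)
  hits <- lookupSeed(idx, "ACGT")
  expect_identical(hits$start, c(1L, 5L))
  ## N-containing seeds never match; N reference positions are unseedable
  idx2 <- buildIndex(Biostrings::DNAStringSet(c(a = "ACGTNNNACGTACGT")),
                     k = 4, genomeRefs = "a")
  expect_identical(nrow(lookupSeed(idx2, "GTNN")), 0L)
  ## exhaustive oracle on a random reference
  ref <- randomSeq(300, 31)
  idx3 <- buildIndex(Biostrings::DNAStringSet(c(r = ref)), k = 8)
  for (p in c(1, 50, 200, 293)) {
    seed <- substr(ref, p, p + 7)
    want <- which(vapply(1:293, function(q)
      substr(ref, q, q + 7) == seed, logical(1)))
    expect_identical(lookupSeed(idx3, seed)$start, as.integer(want))
  }
  expect_error(buildIndex(Biostrings::DNAStringSet(c(a = "ACG")), k = 10),
               "shortest reference")
})

test_that("unique mapping agrees with brute-force placement scoring", {
  set.seed(17)
  uniquePart <- randomSeq(700, 171)
  repeatUnitSeq <- randomSeq(60, 172)
  refs <- c(genome = paste0(uniquePart, strrep(repeatUnitSeq, 5),
                            randomSeq(200, 173)))
  idx <- buildIndex(Biostrings::DNAStringSet(refs), k = 20,
                    genomeRefs = "genome")
  L <- 60
  reads <- character(0)
  ## unique-region reads, repeat-interior reads, reverse-strand reads and
  ## one read with substitutions
  for (s in c(1, 100, 300, 600)) reads <- c(reads, substr(refs, s, s + L - 1))
  reads <- c(reads, substr(refs, 701, 760), substr(refs, 761, 820))
  reads <- c(reads, revComp(substr(refs, 200, 259)))
  mutated <- substr(refs, 400, 459)
  substr(mutated, 10, 10) <- "A"; substr(mutated, 30, 30) <- "C"
  reads <- c(reads, mutated)
  rs <- Biostrings::DNAStringSet(setNames(reads, paste0("r", seq_along(reads))))
  got <- mapReads(rs, idx, minMargin = 5)
  for (i in seq_along(reads)) {
    want <- bruteMap(reads[i], refs, 5L)
    hit <- got[got$readId == paste0("r", i), ]
    if (is.null(want)) {
      expect_identical(nrow(hit), 0L, info = paste("read", i))
    } else {
      expect_identical(nrow(hit), 1L, info = paste("read", i))
      expect_identical(hit$start, as.integer(want$start))
      expect_identical(hit$strand, want$strand)
      expect_identical(hit$score, as.integer(want$score))
      ## the mapper's margin is over seeded candidates: it can only miss
      ## (noise-level) competitors the exhaustive scan sees, never invent
      ## them, so its margin is bounded below by the exhaustive margin
      expect_gte(hit$margin, as.integer(want$margin))
    }
  }
  ## a read occurring exactly once is retained with margin = read length
  one <- got[got$readId == "r1", ]
  expect_identical(one$margin, 60L)
  ## repeat-interior reads are discarded as ambiguous
  expect_identical(nrow(got[got$readId == "r5", ]), 0L)
  expect_gt(attr(got, "nDiscarded"), 0)
})

test_that("fold enrichment is flat for uniform libraries and scale-free", {
  set.seed(23)
  bg <- randomSeq(20000, 231)
  markerSeqs <- vapply(1:4, function(i) randomSeq(800, 232 + i), character(1))
  mk <- syntheticMarkers(markerSeqs, junctions = as.list(rep(113L, 4)))
  pc <- buildPseudocontig(mk)
  genome <- Biostrings::DNAStringSet(
    c(background = paste0(substr(bg, 1, 10000),
                          paste(markerSeqs, collapse = ""),
                          substr(bg, 10001, 20000))))
  idx <- buildIndex(
    Biostrings::DNAStringSet(c(background = substr(bg, 1, 20000),
                               minimal_map = as.character(pc@sequence))),
    k = 40, genomeRefs = "background")
  rsU <- simulateChipReads(genome, role = "fragmented_control",
                           nReads = 25000, seed = 77)
  plU <- mapReads(rsU, idx)
  et <- computeEnrichment(list(lib = plU), c(lib = "fragmented_control"),
                          idx, pc)
  foldsU <- foldEnrichment(et)[, 1]
  ## uniform library: all marker folds near 1 (binomial noise only)
  expect_true(all(abs(foldsU - 1) < 0.25))
  ## doubling every read leaves folds unchanged (per-million scaling)
  plU2 <- rbind(plU, plU)
  et2 <- computeEnrichment(list(lib = plU2), c(lib = "fragmented_control"),
                           idx, pc)
  expect_equal(foldEnrichment(et2)[, 1], foldsU, tolerance = 1e-12)
})

test_that("computed fold enrichment recovers planted folds within 15%", {
  set.seed(29)
  bg <- randomSeq(20000, 291)
  markerSeqs <- vapply(1:3, function(i) randomSeq(1000, 292 + i),
                       character(1))
  mk <- syntheticMarkers(markerSeqs, junctions = as.list(rep(113L, 3)))
  pc <- buildPseudocontig(mk)
  genome <- Biostrings::DNAStringSet(
    c(background = substr(bg, 1, 20000),
      B_centromere = paste0(randomSeq(400, 299),
                            paste(markerSeqs, collapse = randomSeq(400, 300)),
                            randomSeq(400, 301))))
  idx <- buildIndex(
    Biostrings::DNAStringSet(c(background = substr(bg, 1, 20000),
                               minimal_map = as.character(pc@sequence))),
    k = 40, genomeRefs = "background")
  starts <- 401 + (0:2) * 1400
  folds <- c(1, 6, 36)
  enr <- GenomicRanges::GRanges(
    "B_centromere",
    IRanges::IRanges(starts - 149, starts + 999 + 149), fold = folds)
  W <- sum(Biostrings::width(genome) - 149) + sum((folds - 1) * 1299)
  n <- round(40 * W / 150)
  rs <- simulateChipReads(genome, enriched = enr, role = "active_chip",
                          nReads = n, seed = 31)
  pl <- mapReads(rs, idx)
  et <- computeEnrichment(list(lib = pl), c(lib = "active_chip"), idx, pc)
  got <- foldEnrichment(et)[, 1]
  for (i in 1:3) {
    expect_gt(got[i], folds[i] * 0.85)
    expect_lt(got[i], folds[i] * 1.15)
  }
})

test_that("junction coverage demands full depth and spanning reads", {
  mk <- syntheticMarkers(randomSeq(300, 41), junctions = list(113L))
  pc <- buildPseudocontig(mk)
  mkPlacements <- function(starts, width = 100L) {
    S4Vectors::DataFrame(readId = paste0("r", seq_along(starts)),
                         ref = "minimal_map", start = starts,
                         strand = "+", width = width,
                         score = width, margin = width)
  }
  ## reads covering only the LTR half never span the junction
  ltrOnly <- mkPlacements(seq(1L, 13L, by = 1L))
  expect_false(junctionCoverage(ltrOnly, pc)[["TD1"]])
  ## saturated coverage passes
  dense <- mkPlacements(seq(1L, 201L, by = 5L))
  expect_true(junctionCoverage(dense, pc)[["TD1"]])
  ## spanning reads without full marker depth still fail
  gap <- mkPlacements(c(60L, 150L))
  expect_false(junctionCoverage(gap, pc)[["TD1"]])
  ## brute-force oracle for the depth criterion
  cov <- integer(300)
  for (s in seq(1L, 201L, by = 5L)) cov[s:(s + 99L)] <- cov[s:(s + 99L)] + 1L
  expect_true(all(cov >= 1L))
  ## overhang rule: spanning read must extend minOverhang past the junction
  skimpy <- mkPlacements(c(1L, 105L, 113L, 200L), width = 13L)
  expect_false(junctionCoverage(skimpy, pc, minOverhang = 10)[["TD1"]])
})
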