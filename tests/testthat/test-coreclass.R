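## A marker-by-library fold matrix matching the seven-library design, with
## CENH3 occupancy planted on seven markers at the published enrichment
## values; everything else idles near fold 1.
plantedFoldTable <- function(planted = c(7, 9, 10, 15, 18, 21, 29),
                             folds = c(36, 3, 18, 12, 23, 6, 31),
                             n = 40) {
  libs <- c("active_1", "active_2", "active_3", "inactive_1", "inactive_2",
            "negative_chip", "fragmented_control")
  roles <- c(rep("active_chip", 3), rep("inactive_chip", 2),
             "negative_chip", "fragmented_control")
  names(roles) <- libs
  fold <- matrix(1, n, 7, dimnames = list(paste0("TD", 1:n), libs))
  fold[planted, 1:3] <- rep(folds, 3)
  fold[, 4:5] <- 0.9
  fold[, 6:7] <- 0
  cov <- fold
  makeEnrichmentTable(fold, cov, roles = roles)
}

test_that("multi-library rule calls exactly the CENH3-occupied markers", {
  et <- plantedFoldTable()
  call <- classifyCore(et)
  expect_identical(coreMarkers(call),
                   paste0("TD", c(7, 9, 10, 15, 18, 21, 29)))
  ## the threefold marker passes only because tActive < 3
  strict <- classifyCore(et, tActive = 3)
  expect_false("TD9" %in% coreMarkers(strict))
  ## coverage in a fragmented control vetoes an enriched marker
  et2 <- plantedFoldTable()
  SummarizedExperiment::assay(et2, "coverage")["TD7", 7] <- 5
  expect_false("TD7" %in% coreMarkers(classifyCore(et2)))
  ## more-than-twofold enrichment in an inactive replicate vetoes too
  et3 <- plantedFoldTable()
  SummarizedExperiment::assay(et3, "fold")["TD10", 4] <- 2.5
  expect_false("TD10" %in% coreMarkers(classifyCore(et3)))
  ## junction coverage is required in every active replicate
  et4 <- plantedFoldTable()
  SummarizedExperiment::assay(et4, "junctionOk")["TD15", 2] <- FALSE
  expect_false("TD15" %in% coreMarkers(classifyCore(et4)))
  ## a flat table yields no calls
  flat <- plantedFoldTable(planted = integer(), folds = numeric())
  expect_identical(length(coreMarkers(classifyCore(flat))), 0L)
  ## a designed library missing from the table is an error naming it
  design <- libraryDesign(c(colnames(et), "active_9"),
                          c(unname(SummarizedExperiment::colData(et)$role),
                            "active_chip"))
  expect_error(classifyCore(et, design = design), "active_9")
})

test_that("classification is monotone in its thresholds", {
  set.seed(5)
  for (trial in 1:5) {
    et <- plantedFoldTable()
    f <- SummarizedExperiment::assay(et, "fold")
    f[] <- f * exp(rnorm(length(f), 0, 0.2))
    SummarizedExperiment::assay(et, "fold") <- f
    base <- coreMarkers(classifyCore(et, tActive = 2, tInactive = 2))
    ## raising the active threshold can only remove calls
    expect_true(all(coreMarkers(classifyCore(et, tActive = 4)) %in% base))
    ## lowering the inactive tolerance can only remove calls
    expect_true(all(coreMarkers(classifyCore(et, tInactive = 0.5)) %in% base))
  }
})

test_that("core span follows the smallest functional derivative", {
  fx <- table1Fixture()
  calls <- S4Vectors::DataFrame(
    activeEnriched = fx$markers$td %in% fx$cenh3Markers,
    inactiveQuiet = TRUE, controlsClean = TRUE, junctionsCovered = TRUE,
    isCore = fx$markers$td %in% fx$cenh3Markers,
    row.names = fx$markers$td)
  call <- new("CoreCall", calls = calls,
              thresholds = c(tActive = 2, tInactive = 2, controlCeiling = 0))
  part <- partitionMarkers(fx$matrix)
  span <- inferCoreSpan(call, part, fx$matrix)
  expect_identical(span$derivative, "Iso3")   # 53% transmission, smallest
  expect_identical(span$n, 33L)
  expect_identical(span$span, paste0("TD", 8:40))
  ## a core marker lost in the smallest functional derivative (the marker
  ## differentiating it from its parent's sibling) falls outside the span
  expect_false("TD7" %in% span$span)
  expect_true(all(setdiff(fx$cenh3Markers, "TD7") %in% span$span))
  ## saturation: everything core, root declared functional -> whole map
  callAll <- new("CoreCall",
                 calls = S4Vectors::DataFrame(
                   activeEnriched = TRUE, inactiveQuiet = TRUE,
                   controlsClean = TRUE, junctionsCovered = TRUE,
                   isCore = rep(TRUE, 40), row.names = fx$markers$td),
                 thresholds = c(tActive = 2, tInactive = 2,
                                controlCeiling = 0))
  spanAll <- inferCoreSpan(callAll, part, fx$matrix, functional = "TB9Sb")
  expect_identical(spanAll$n, 40L)
  ## no core markers is an error
  none <- new("CoreCall",
              calls = S4Vectors::DataFrame(
                activeEnriched = FALSE, inactiveQuiet = TRUE,
                controlsClean = TRUE, junctionsCovered = TRUE,
                isCore = rep(FALSE, 40), row.names = fx$markers$td),
              thresholds = c(tActive = 2, tInactive = 2, controlCeiling = 0))
  expect_error(inferCoreSpan(none, part, fx$matrix), "no core markers")
})

test_that("in-silico PCR is convergent-orientation and size-bounded", {
  g <- randomSeq(2000, 61)
  fwd <- substr(g, 501, 520)
  rev <- revComp(substr(g, 781, 800))
  hits <- insilicoPCR(fwd, rev, g)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$size, 300L)
  ## the same pair amplifies from the reverse-complemented genome
  hitsRC <- insilicoPCR(fwd, rev, revComp(g))
  expect_identical(hitsRC$size, 300L)
  ## divergent orientation or excessive span does not amplify
  expect_identical(nrow(insilicoPCR(fwd, substr(g, 781, 800), g)), 0L)
  expect_identical(nrow(insilicoPCR(fwd, rev, g, maxSize = 200)), 0L)
  expect_identical(nrow(insilicoPCR(fwd, rev, randomSeq(2000, 62))), 0L)
})

test_that("junction primer design yields unique genotype-discriminating pairs", {
  lib <- tinyLib(1)
  tail112 <- substr(as.character(ltrSequence(lib)), 49, 160)
  flank <- gsub("CTAG", "CAAG", randomSeq(200, 63), fixed = TRUE)
  markerSeq <- paste0(tail112, flank)
  mk <- syntheticMarkers(markerSeq, junctions = list(113L))
  bPlus <- c(bg = paste0(randomSeq(300, 64), markerSeq, randomSeq(300, 65)))
  bMinus <- c(bg = randomSeq(800, 66))
  pair <- designJunctionPrimers(mk[1, ], bPlus, bMinus)
  expect_identical(nrow(insilicoPCR(pair$forward, pair$reverse, bPlus)), 1L)
  expect_identical(nrow(insilicoPCR(pair$forward, pair$reverse, bMinus)), 0L)
  ## the straddling primer spans the junction with flank on both sides
  amp <- insilicoPCR(pair$forward, pair$reverse, markerSeq)
  expect_identical(amp$size, pair$expectedSize)
  ## a marker whose locus also exists in the B-minus genome cannot be
  ## converted (no genotype-discriminating pair exists)
  bMinusDup <- c(bg = paste0(randomSeq(100, 67), markerSeq,
                             randomSeq(100, 68)))
  expect_error(designJunctionPrimers(mk[1, ], bPlus, bMinusDup),
               "un-convertible")
  ## a marker without junctions is rejected
  noj <- syntheticMarkers(markerSeq)
  expect_error(designJunctionPrimers(noj[1, ], bPlus, bMinus),
               "no recorded junction")
})
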