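## Deletion mapping: marker presence across the misdivision pedigree,
## loss-pattern partition, nestedness validation and minimal-map assembly.

#' Score marker presence across derivative genomes
#'
#' A cell is TRUE iff the marker's full band sequence occurs (on either
#' strand) in the derivative's sequence — the in-silico equivalent of
#' re-running the display on each misdivision line.
#'
#' @param markers Marker table from [collapseAndName()].
#' @param derivatives Named list of [DerivativeGenome-class] (e.g. from
#'   [derivePedigree()]).
#' @return A [PresenceMatrix-class] with pedigree and transmission metadata
#'   taken from the derivatives.
#' @export
scorePresence <- function(markers, derivatives) {
  stopifnot(length(derivatives) > 0L, nrow(markers) > 0L)
  nms <- vapply(derivatives, function(d) d@name, character(1))
  seqs <- lapply(derivatives, function(d) as.character(d@sequence))
  v <- matrix(FALSE, nrow(markers), length(derivatives),
              dimnames = list(markers$id, nms))
  for (j in seq_along(derivatives)) {
    subj <- Biostrings::DNAString(seqs[[j]])
    for (i in seq_len(nrow(markers)))
      v[i, j] <- occursIn(markers$sequence[i], subj)
  }
  ped <- setNames(vapply(derivatives, function(d) d@parent, character(1)), nms)
  tr <- setNames(vapply(derivatives, function(d) d@transmission, numeric(1)),
                 nms)
  out <- new("PresenceMatrix", values = v, pedigree = ped, transmission = tr)
  validObject(out)
  out
}

#' Construct a presence matrix directly
#'
#' @param values Logical matrix (markers x derivatives, dimnames required).
#' @param pedigree Named character vector mapping derivatives to parents
#'   (`NA` for the root / externally derived lines).
#' @param transmission Named numeric vector of transmission rates.
#' @return A [PresenceMatrix-class].
#' @export
presenceMatrix <- function(values, pedigree,
                           transmission = setNames(rep(NA_real_,
                                                       ncol(values)),
                                                   colnames(values))) {
  out <- new("PresenceMatrix", values = values, pedigree = pedigree,
             transmission = transmission)
  validObject(out)
  out
}

#' Validate pedigree nestedness of a presence matrix
#'
#' Deletion mapping relies on descendant marker sets being subsets of their
#' ancestors': a marker present in a child but absent in its pedigree parent
#' violates nestedness.  The report is driven by the pedigree, not by
#' column order.
#'
#' @param matrix A [PresenceMatrix-class].
#' @return data.frame of violations with columns `marker`, `derivative`,
#'   `parent` (zero rows when fully nested).
#' @export
validateNestedness <- function(matrix) {
  v <- presenceValues(matrix)
  ped <- matrix@pedigree
  out <- data.frame(marker = character(), derivative = character(),
                    parent = character(), stringsAsFactors = FALSE)
  for (d in colnames(v)) {
    p <- if (d %in% names(ped)) ped[[d]] else NA_character_
    if (is.na(p) || !p %in% colnames(v)) next
    bad <- which(v[, d] & !v[, p])
    if (length(bad))
      out <- rbind(out, data.frame(marker = rownames(v)[bad],
                                   derivative = d, parent = p,
                                   stringsAsFactors = FALSE))
  }
  out
}

#' Partition markers by loss pattern across the pedigree
#'
#' Markers with identical presence pattern form one group; groups are
#' ordered by the generation at which the markers were first lost along the
#' main pedigree chain (the matrix column order, which follows the
#' root-to-smallest-derivative chain), markers lost earliest first.  Markers
#' never lost form the terminal group.  A non-nested matrix still yields a
#' partition, with the pedigree violations annotated.
#'
#' @param matrix A [PresenceMatrix-class].
#' @param chain Derivative names defining the main chain (default: matrix
#'   column order).
#' @return A [MarkerPartition-class].
#' @export
partitionMarkers <- function(matrix, chain = colnames(presenceValues(matrix))) {
  v <- presenceValues(matrix)
  stopifnot(all(chain %in% colnames(v)))
  vc <- v[, chain, drop = FALSE]
  pat <- apply(vc, 1L, function(r) paste(ifelse(r, "+", "-"), collapse = ""))
  firstLoss <- apply(vc, 1L, function(r) {
    w <- which(!r)
    if (length(w)) w[1L] else NA_integer_
  })
  keys <- unique(pat)
  groups <- lapply(keys, function(k) rownames(v)[pat == k])
  names(groups) <- keys
  fl <- vapply(keys, function(k) firstLoss[match(k, pat)], integer(1))
  o <- order(ifelse(is.na(fl), ncol(vc) + 1L, fl), keys)
  groups <- groups[o]
  patterns <- do.call(rbind, lapply(names(groups), function(k)
    strsplit(k, "")[[1]] == "+"))
  dimnames(patterns) <- list(names(groups), chain)
  new("MarkerPartition",
      groups = groups,
      patterns = patterns,
      firstLoss = fl[o],
      violations = validateNestedness(matrix))
}

#' Reorder markers into minimal-map order
#'
#' Minimal-map order is partition order (markers lost earliest first, the
#' never-lost group last) with ties broken by discovery id, matching the
#' layout of the published marker table.  Ids are reassigned TD1..TDn in the
#' new order; the original discovery id is kept in `discoveryId`.
#'
#' @param markers Marker table from [collapseAndName()].
#' @param partition A [MarkerPartition-class] computed on these markers.
#' @return The reordered marker table with reassigned ids.
#' @export
orderMarkers <- function(markers, partition) {
  ids <- unlist(markerGroups(partition), use.names = FALSE)
  stopifnot(setequal(ids, markers$id))
  ord <- markers[match(ids, markers$id), ]
  ord$discoveryId <- ord$id
  ord$id <- paste0("TD", seq_len(nrow(ord)))
  rownames(ord) <- ord$id
  ord
}

#' Assemble markers into an N-spaced pseudocontig (minimal map)
#'
#' Joins marker sequences in the given order with `spacerLength` Ns between
#' consecutive markers, the reference used to interpret ChIP-seq in
#' repetitive centromeres.  Marker junction offsets, when present, are
#' lifted to map coordinates.
#'
#' @param markers Marker table (ordered; see [orderMarkers()]).
#' @param spacerLength Number of Ns between markers (default 200).
#' @param label Reference sequence name.
#' @return A [Pseudocontig-class].
#' @export
buildPseudocontig <- function(markers, spacerLength = 200L,
                              label = "minimal_map") {
  if (is.null(nrow(markers)) || nrow(markers) == 0L)
    stop("at least one marker is required")
  lens <- nchar(markers$sequence)
  n <- nrow(markers)
  starts <- cumsum(c(1L, head(lens, -1L) + spacerLength))
  ends <- starts + lens - 1L
  seq <- paste(markers$sequence, collapse = strrep("N", spacerLength))
  mi <- GenomicRanges::GRanges(label, IRanges::IRanges(starts, ends))
  names(mi) <- markers$id
  jrows <- list()
  if (!is.null(markers$junctions)) {
    for (i in seq_len(n)) {
      offs <- markers$junctions[[i]]
      if (length(offs))
        jrows[[length(jrows) + 1L]] <- data.frame(
          pos = starts[i] + offs - 1L, marker = markers$id[i])
    }
  }
  jd <- if (length(jrows)) do.call(rbind, jrows)
        else data.frame(pos = integer(), marker = character())
  jx <- GenomicRanges::GRanges(rep(label, nrow(jd)),
                               IRanges::IRanges(jd$pos, jd$pos),
                               marker = jd$marker)
  out <- new("Pseudocontig",
             sequence = Biostrings::DNAString(seq),
             markerIntervals = mi, junctions = jx,
             spacerLength = as.integer(spacerLength),
             seqnameLabel = label)
  validObject(out)
  out
}

#' Extract one marker's sequence back out of a pseudocontig
#'
#' @param pseudocontig A [Pseudocontig-class].
#' @param id Marker id.
#' @return Character sequence of the marker interval.
#' @export
markerSlice <- function(pseudocontig, id) {
  mi <- markerIntervals(pseudocontig)
  stopifnot(id %in% names(mi))
  r <- mi[id]
  as.character(Biostrings::subseq(pseudocontig@sequence,
                                  GenomicRanges::start(r),
                                  GenomicRanges::end(r)))
}

#' The packaged marker-by-derivative presence fixture
#'
#' Loads the transcribed 40-marker presence/absence table scored on the
#' misdivision progenitor and four early descendants, together with which
#' markers interact with CENH3 by ChIP-seq and which were converted to
#' simple PCR markers, the pedigree of the scored lines, and the published
#' transmission rates of the two smallest derivatives.
#'
#' @return List with `matrix` (a [PresenceMatrix-class]), `markers`
#'   (data.frame with `name`, `td`, `cenh3`, `pcr`), `cenh3Markers` and
#'   `pcrMarkers` (character id vectors).
#' @export
table1Fixture <- function() {
  path <- system.file("extdata", "table1_presence.tsv",
                      package = "CenCoreMap", mustWork = TRUE)
  df <- read.delim(path, stringsAsFactors = FALSE)
  derivs <- c("TB9Sb", "PI", "Telo2_1", "Iso3", "Telo2_2")
  v <- as.matrix(df[, derivs]) == "+"
  rownames(v) <- df$td
  ped <- c(TB9Sb = NA_character_, PI = "TB9Sb", Telo2_1 = "PI",
           Iso3 = "Telo2_1", Telo2_2 = "PI")
  tr <- c(TB9Sb = NA_real_, PI = NA_real_, Telo2_1 = NA_real_,
          Iso3 = 0.53, Telo2_2 = 0.43)
  list(matrix = presenceMatrix(v, ped, tr),
       markers = df[, c("name", "td", "cenh3", "pcr")],
       cenh3Markers = df$td[df$cenh3 == 1],
       pcrMarkers = df$td[df$pcr == 1])
}
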