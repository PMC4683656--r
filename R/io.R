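## Plain-text export/import: FASTA/FASTQ via Biostrings, BED-style feature
## tables, TSV result tables, JSON pedigree specifications.

#' Write genomes to FASTA
#'
#' @param x A named [Biostrings::DNAStringSet], a layout/derivative, or a
#'   list of them.
#' @param file Output path.
#' @export
writeGenomeFasta <- function(x, file) {
  if (is(x, "CentromereLayout") || is(x, "DerivativeGenome"))
    x <- list(x)
  if (is.list(x)) {
    chr <- unlist(lapply(x, .asNamedChar))
    x <- Biostrings::DNAStringSet(chr)
  }
  Biostrings::writeXStringSet(x, file)
  invisible(file)
}

#' Write a read set to FASTQ (uniform qualities)
#'
#' @param readset A [ReadSet-class].
#' @param file Output path.
#' @export
writeReadsFastq <- function(readset, file) {
  q <- Biostrings::BStringSet(rep(strrep("I", readset@readLength),
                                  length(readset@reads)))
  Biostrings::writeXStringSet(readset@reads, file, format = "fastq",
                              qualities = q)
  invisible(file)
}

#' Write layout features (or marker intervals) as BED
#'
#' Four-column BED (0-based half-open, as the format requires), with the
#' feature unit or marker id as the name.
#'
#' @param x A [CentromereLayout-class] or [Pseudocontig-class].
#' @param file Output path.
#' @export
writeBedFeatures <- function(x, file) {
  if (is(x, "CentromereLayout")) {
    gr <- x@features
    nm <- S4Vectors::mcols(gr)$unit
  } else if (is(x, "Pseudocontig")) {
    gr <- markerIntervals(x)
    nm <- names(gr)
  } else stop("unsupported object")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   name = nm)
  utils::write.table(df, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Write a presence matrix as TSV
#'
#' @param matrix A [PresenceMatrix-class].
#' @param file Output path.
#' @export
writePresenceTsv <- function(matrix, file) {
  v <- presenceValues(matrix)
  df <- data.frame(marker = rownames(v),
                   ifelse(v, "+", "-"), check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write an enrichment table (folds and junction flags) as TSV
#'
#' @param table An [EnrichmentTable-class].
#' @param file Output path.
#' @export
writeEnrichmentTsv <- function(table, file) {
  fold <- foldEnrichment(table)
  jok <- junctionOk(table)
  colnames(jok) <- paste0("junctionOk_", colnames(jok))
  df <- data.frame(marker = rownames(fold), round(fold, 3), jok,
                   check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read / write a pedigree specification as JSON
#'
#' @param file Path to a JSON file with fields `name`, `parent`,
#'   `fraction`, and optionally `side` and `transmission`.
#' @return data.frame usable as the `spec` of [derivePedigree()].
#' @export
readPedigreeSpec <- function(file) {
  df <- jsonlite::fromJSON(file)
  stopifnot(all(c("name", "parent", "fraction") %in% names(df)))
  df
}

#' @param spec data.frame (as from [defaultPedigreeSpec()]).
#' @rdname readPedigreeSpec
#' @export
writePedigreeSpec <- function(spec, file) {
  jsonlite::write_json(spec, file, digits = NA, na = "null")
  invisible(file)
}
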