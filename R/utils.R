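#' @importFrom methods new validObject is slot setValidity show
#' @importFrom stats rbinom runif setNames
#' @importFrom utils head tail read.delim
#' @importFrom Rcpp evalCpp
#' @useDynLib CenCoreMap, .registration = TRUE
NULL

DNA_BASES <- c("A", "C", "G", "T")

## Deterministic child-seed derivation: one master seed fans out to
## per-operation seeds via a fixed polynomial hash of the operation tag.
## All values stay below 2^31 - 1 so they are valid R integer seeds.
childSeed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  m <- 2147483399
  h <- seed %% m
  for (b in utf8ToInt(tag)) h <- (h * 31 + b) %% m
  as.integer(h) + 1L
}

## Evaluate `code` under a fixed seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## Random DNA of length n as a plain character scalar.
randomDNA <- function(n, gc = 0.5) {
  if (n <= 0) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

## Substitute bases at a fixed per-base rate; substitutions always change
## the base (no silent hits), matching how repeat-copy divergence is scored.
mutateSequence <- function(x, rate) {
  if (rate <= 0 || nchar(x) == 0) return(x)
  n <- nchar(x)
  hit <- which(runif(n) < rate)
  if (!length(hit)) return(x)
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  for (i in hit) {
    chars[i] <- sample(setdiff(DNA_BASES, chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## Occurrence on either strand (exact), used for presence scoring and the
## miniB-style retention filter.
occursIn <- function(pattern, subject) {
  subj <- if (is(subject, "DNAString")) subject else Biostrings::DNAString(subject)
  if (nchar(as.character(pattern)) == 0L || length(subj) == 0L) return(FALSE)
  p <- Biostrings::DNAString(pattern)
  Biostrings::countPattern(p, subj) > 0L ||
    Biostrings::countPattern(Biostrings::reverseComplement(p), subj) > 0L
}

hammingDistance <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

## All 4^k DNA k-mers in lexicographic order (the 64 selective triplets).
allKmers <- function(k = 3) {
  grid <- expand.grid(rep(list(DNA_BASES), k), stringsAsFactors = FALSE)
  ## expand.grid varies the first factor fastest; flip for lexicographic order
  apply(grid[, k:1, drop = FALSE], 1, paste, collapse = "")
}

## Number of distinct k-mers shared between two sequences (uniqueness audit
## for the repeat library: distinct units must not share long exact words).
sharedKmerCount <- function(a, b, k = 20) {
  ka <- substring(a, seq_len(max(0, nchar(a) - k + 1)),
                  seq_len(max(0, nchar(a) - k + 1)) + k - 1)
  kb <- substring(b, seq_len(max(0, nchar(b) - k + 1)),
                  seq_len(max(0, nchar(b) - k + 1)) + k - 1)
  length(intersect(ka, kb))
}
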