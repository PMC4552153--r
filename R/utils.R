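## Internal helpers shared across modules.

.BASES <- c("A", "C", "G", "T")

.REPEAT_CLASSES <- c("retrotransposon", "dna_transposon")
.JUNCTION_CLASSES <- c(.REPEAT_CLASSES, "unknown")
.LINE_KINDS <- c("control", "nulli_tetrasomic", "deletion", "alt_genome")

#' Generate a uniform-random DNA string
#'
#' Draws from the current RNG stream; callers are responsible for seeding.
#'
#' @param n Sequence length in bases.
#' @return A single character string over A/C/G/T.
#' @keywords internal
.randomDNA <- function(n) {
  paste(sample(.BASES, n, replace = TRUE), collapse = "")
}

#' @keywords internal
.revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Strict ACGT check on a character vector of sequences.
.assertDNA <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    stop(sprintf("%s contains non-ACGT characters (first offender: element %d)",
                 what, which(bad)[1]), call. = FALSE)
  }
  invisible(TRUE)
}

## Schema validation for TSV readers: explicit, names the missing column.
.checkColumns <- function(df, required, what = "table") {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

## Seeded evaluation without disturbing the caller's RNG state.
.withSeed <- function(seed, code) {
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be a single integer", call. = FALSE)
  withr::with_seed(seed, code)
}

## Substitution-error injection: mutates `k` uniformly chosen positions of a
## character string to a different base each.
.injectSubstitutions <- function(seq, k) {
  if (k <= 0L) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- sample.int(length(chars), min(k, length(chars)))
  for (p in pos) {
    chars[p] <- sample(setdiff(.BASES, chars[p]), 1L)
  }
  paste(chars, collapse = "")
}
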