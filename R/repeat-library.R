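#' Build a synthetic repeat element library
#'
#' Generates uniform-random element sequences of the two repeat classes used
#' throughout the package. Element ids are `retro_<i>` / `dnat_<i>`.
#'
#' @param nRetro Number of retrotransposon elements (>= 0).
#' @param nDna Number of DNA-transposon elements (>= 0).
#' @param lengthRange Integer interval `c(min, max)` of element lengths;
#'   minimum must be at least 50 bp.
#' @param seed Integer seed; the same seed yields a byte-identical library.
#' @return A [RepeatLibrary-class] with `nRetro + nDna` elements.
#' @examples
#' lib <- buildRepeatLibrary(3, 2, c(100, 200), seed = 7)
#' table(repeatClass(lib))
#' @export
buildRepeatLibrary <- function(nRetro, nDna, lengthRange = c(1000L, 3000L), seed = 1L) {
  if (nRetro < 0 || nDna < 0) stop("element counts must be >= 0", call. = FALSE)
  lengthRange <- as.integer(lengthRange)
  if (length(lengthRange) != 2 || any(lengthRange <= 0))
    stop("lengthRange must be two positive integers", call. = FALSE)
  if (lengthRange[1] < 50L)
    stop("lengthRange minimum must be at least 50 bp", call. = FALSE)
  if (lengthRange[1] > lengthRange[2])
    stop("lengthRange must be non-decreasing", call. = FALSE)

  n <- nRetro + nDna
  cls <- c(rep("retrotransposon", nRetro), rep("dna_transposon", nDna))
  ids <- c(sprintf("retro_%03d", seq_len(nRetro)),
           sprintf("dnat_%03d", seq_len(nDna)))
  seqs <- .withSeed(seed, {
    lens <- lengthRange[1] +
      sample.int(lengthRange[2] - lengthRange[1] + 1L, n, replace = TRUE) - 1L
    vapply(lens, .randomDNA, character(1))
  })
  dss <- Biostrings::DNAStringSet(seqs)
  names(dss) <- ids
  new("RepeatLibrary", sequences = dss, repeatClass = cls)
}

#' Assemble a RepeatLibrary from raw sequences
#'
#' @param sequences Named character vector or `DNAStringSet`.
#' @param repeatClass Character vector of classes, parallel to `sequences`.
#' @return A [RepeatLibrary-class].
#' @export
RepeatLibrary <- function(sequences, repeatClass) {
  if (!is(sequences, "DNAStringSet")) {
    seqs <- toupper(as.character(sequences))
    .assertDNA(seqs, "library")
    sequences <- Biostrings::DNAStringSet(stats::setNames(seqs, names(sequences)))
  }
  new("RepeatLibrary", sequences = sequences, repeatClass = as.character(repeatClass))
}
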