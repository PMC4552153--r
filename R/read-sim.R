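#' Simulate single-end shotgun reads
#'
#' Draws `round(coverage * genomeLength / readLength)` fixed-length reads with
#' uniform origins across the genome (chromosomes weighted by length), random
#' strand, and independent substitution errors at the requested per-base rate.
#' Indels are not modelled; the optional homopolymer-lengthening error mode of
#' pyrosequencing-style reads can be emulated downstream by substitution-dense
#' discovery reads.
#'
#' @param genome A [GenomeModel-class].
#' @param coverage Nominal fold coverage (> 0).
#' @param readLength Read length; must be shorter than the shortest chromosome.
#' @param substitutionRate Per-base substitution probability in `[0, 1)`.
#' @param seed Integer seed; identical seeds give byte-identical read sets.
#' @return A [ReadSet-class].
#' @examples
#' lib <- buildRepeatLibrary(1, 1, c(300, 400), seed = 1)
#' gm <- simulateGenome(lib, data.frame(name = "1D", length = 2e4,
#'                                      arm_fraction = 0.5), teCount = 2, seed = 2)
#' rs <- simulateReads(gm, coverage = 1, readLength = 500, seed = 3)
#' length(rs)
#' @export
simulateReads <- function(genome, coverage, readLength = 150L,
                          substitutionRate = 0, seed = 1L) {
  stopifnot(is(genome, "GenomeModel"))
  if (coverage <= 0) stop("coverage must be positive", call. = FALSE)
  readLength <- as.integer(readLength)
  lens <- chromLengths(genome)
  if (readLength >= min(lens))
    stop("readLength must be shorter than the shortest chromosome", call. = FALSE)
  if (substitutionRate < 0 || substitutionRate >= 1)
    stop("substitutionRate must be in [0, 1)", call. = FALSE)

  total <- sum(lens)
  n <- as.integer(round(coverage * total / readLength))
  .withSeed(seed, {
    chrom <- sample(names(lens), n, replace = TRUE, prob = lens)
    start <- vapply(lens[chrom] - readLength,
                    function(m) sample.int(m + 1L, 1L) - 1L, integer(1))
    strand <- sample(c("+", "-"), n, replace = TRUE)
    chromStr <- stats::setNames(as.character(chromSequences(genome)), names(lens))
    seqs <- substring(chromStr[chrom], start + 1L, start + readLength)
    rev <- strand == "-"
    if (any(rev)) seqs[rev] <- .revComp(seqs[rev])
    if (substitutionRate > 0) {
      nerr <- stats::rbinom(n, readLength, substitutionRate)
      for (i in which(nerr > 0L)) seqs[i] <- .injectSubstitutions(seqs[i], nerr[i])
    }
    dss <- Biostrings::DNAStringSet(seqs)
    names(dss) <- sprintf("read_%06d", seq_len(n))
    new("ReadSet", sequences = dss,
        origins = data.frame(read_id = names(dss), chrom = chrom,
                             start = as.integer(start), strand = strand,
                             stringsAsFactors = FALSE),
        nominalCoverage = as.numeric(coverage), readLength = readLength)
  })
}
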