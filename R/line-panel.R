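#' Build an aneuploid line panel for a genome
#'
#' Creates one control line, one nullisomic-tetrasomic line per chromosome
#' (missing that chromosome), one terminal-deletion line per requested
#' breakpoint, and optionally an alternative-genome line that lacks the whole
#' target genome (the tetraploid genome-specificity screen). A deletion line
#' with breakpoint `b` on arm `A` retains the proximal fraction `[0, b]` of
#' that arm (fraction length measured centromere to telomere) and all other
#' chromatin.
#'
#' @param genome A [GenomeModel-class].
#' @param deletionFLs Named list: `chromosome -> list(S = breakpoints, L =
#'   breakpoints)`, breakpoints strictly inside (0,1) and strictly increasing.
#' @param altGenome If `TRUE`, append an `alt_genome` line named `"AABB"`.
#' @return A [LinePanel-class]. Line names are `control`, `N<chrom>`, and
#'   `<chrom><arm>_b<percent>` for deletion lines (no dots, so names survive
#'   the TSV signal-matrix column encoding).
#' @examples
#' lib <- buildRepeatLibrary(1, 1, c(300, 400), seed = 1)
#' gm <- simulateGenome(lib, data.frame(name = c("1D", "2D"),
#'   length = c(2e4, 2e4), arm_fraction = 0.4), teCount = 0, seed = 2)
#' buildLinePanel(gm, list(`1D` = list(L = c(0.18, 0.41))))
#' @export
buildLinePanel <- function(genome, deletionFLs = list(), altGenome = FALSE) {
  stopifnot(is(genome, "GenomeModel"))
  chroms <- names(chromSequences(genome))
  rows <- list(data.frame(name = "control", kind = "control", chromosome = "",
                          arm = "", breakpoint_fl = NA_real_,
                          stringsAsFactors = FALSE))
  for (ch in chroms) {
    rows[[length(rows) + 1L]] <- data.frame(
      name = paste0("N", ch), kind = "nulli_tetrasomic", chromosome = ch,
      arm = "", breakpoint_fl = NA_real_, stringsAsFactors = FALSE)
  }
  for (ch in names(deletionFLs)) {
    if (!ch %in% chroms)
      stop(sprintf("deletion breakpoints given for unknown chromosome '%s'", ch),
           call. = FALSE)
    for (arm in names(deletionFLs[[ch]])) {
      bps <- deletionFLs[[ch]][[arm]]
      if (length(bps) == 0) next
      if (!arm %in% c("S", "L"))
        stop("deletion arms must be 'S' or 'L'", call. = FALSE)
      if (any(bps <= 0 | bps >= 1))
        stop("breakpoints must be strictly inside (0,1)", call. = FALSE)
      if (anyDuplicated(bps))
        stop("duplicate breakpoints on the same arm", call. = FALSE)
      if (is.unsorted(bps, strictly = TRUE))
        stop("breakpoints must be strictly increasing per arm", call. = FALSE)
      for (b in bps) {
        rows[[length(rows) + 1L]] <- data.frame(
          name = sprintf("%s%s_b%02d", ch, arm, round(100 * b)),
          kind = "deletion", chromosome = ch, arm = arm, breakpoint_fl = b,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (altGenome) {
    rows[[length(rows) + 1L]] <- data.frame(
      name = "AABB", kind = "alt_genome", chromosome = "", arm = "",
      breakpoint_fl = NA_real_, stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  new("LinePanel", lines = df)
}

#' Copy number of genomic loci in a panel line
#'
#' Per-locus dosage used by the hybridization model: the control carries one
#' copy of every locus; a nullisomic-tetrasomic line zeroes the loci of its
#' missing chromosome; a deletion line zeroes the loci distal to its
#' breakpoint (`fl > b`) on the deleted arm; an alt-genome line carries zero
#' copies of every target-genome locus.
#'
#' @param genome A [GenomeModel-class].
#' @param panel A [LinePanel-class].
#' @param lineName Name of one line in the panel.
#' @param chrom,position Vectors of loci (0-based positions).
#' @return Integer vector of copy numbers (0 or 1).
#' @export
locusCopyNumber <- function(genome, panel, lineName, chrom, position) {
  stopifnot(is(genome, "GenomeModel"), is(panel, "LinePanel"))
  ln <- panelLines(panel)
  row <- ln[ln$name == lineName, , drop = FALSE]
  if (nrow(row) != 1) stop(sprintf("unknown line '%s'", lineName), call. = FALSE)
  n <- max(length(chrom), length(position))
  chrom <- rep_len(chrom, n); position <- rep_len(position, n)
  copies <- rep(1L, n)
  if (row$kind == "alt_genome") return(rep(0L, n))
  if (row$kind == "nulli_tetrasomic") {
    copies[chrom == row$chromosome] <- 0L
  } else if (row$kind == "deletion") {
    sel <- chrom == row$chromosome
    if (any(sel)) {
      fl <- locusFL(genome, chrom[sel], position[sel])
      lost <- fl$arm == row$arm & fl$fl > row$breakpoint_fl
      copies[sel][lost] <- 0L
    }
  }
  copies
}
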