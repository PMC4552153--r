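#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' RepeatLibrary: a classed set of repeat element sequences
#'
#' Container for transposable-element consensus sequences used both to build
#' synthetic genomes and to detect repeat junctions. Each element carries a
#' repeat class, either `"retrotransposon"` or `"dna_transposon"`.
#'
#' @slot sequences A [Biostrings::DNAStringSet] of element sequences; names are
#'   the element ids and must be unique.
#' @slot repeatClass Character vector parallel to `sequences`.
#'
#' @seealso [buildRepeatLibrary()]
#' @exportClass RepeatLibrary
setClass("RepeatLibrary",
         slots = c(sequences = "DNAStringSet", repeatClass = "character"))

setValidity("RepeatLibrary", function(object) {
  msgs <- character()
  n <- length(object@sequences)
  if (length(object@repeatClass) != n)
    msgs <- c(msgs, "repeatClass length must match number of sequences")
  if (n > 0) {
    ids <- names(object@sequences)
    if (is.null(ids) || anyNA(ids) || any(ids == ""))
      msgs <- c(msgs, "every element must have a non-empty id")
    else if (anyDuplicated(ids))
      msgs <- c(msgs, "element ids must be unique within a library")
    if (!all(object@repeatClass %in% .REPEAT_CLASSES))
      msgs <- c(msgs, sprintf("repeatClass values must be one of: %s",
                              paste(.REPEAT_CLASSES, collapse = ", ")))
    if (any(Biostrings::width(object@sequences) == 0))
      msgs <- c(msgs, "element sequences must be non-empty")
    letters <- Biostrings::uniqueLetters(object@sequences)
    if (!all(letters %in% .BASES))
      msgs <- c(msgs, "element sequences must use only A/C/G/T")
  }
  if (length(msgs)) msgs else TRUE
})

#' GenomeModel: a simulated multi-chromosome genome with junction truth
#'
#' Holds chromosome sequences, the short-arm fraction of each chromosome
#' (the centromere splits a chromosome of length L at `round(armFraction * L)`;
#' positions below the split belong to the S arm, the rest to the L arm), the
#' placed transposable-element insertions, gene intervals, and the exhaustive
#' list of true repeat-junction boundaries. All coordinates are 0-based,
#' half-open; a junction position is the index of the first base to the right
#' of the boundary.
#'
#' @slot sequences Named [Biostrings::DNAStringSet] of chromosomes.
#' @slot armFraction Named numeric in (0,1), short-arm fraction per chromosome.
#' @slot teInsertions data.frame: chrom, start, end, element_id, element_class,
#'   strand (final genome coordinates spanning the inserted copy, including any
#'   elements later nested inside it).
#' @slot genes data.frame: chrom, start, end, gene_id.
#' @slot junctionTruth data.frame: chrom, position, left_class, right_class.
#'
#' @seealso [simulateGenome()]
#' @exportClass GenomeModel
setClass("GenomeModel",
         slots = c(sequences = "DNAStringSet", armFraction = "numeric",
                   teInsertions = "data.frame", genes = "data.frame",
                   junctionTruth = "data.frame"))

setValidity("GenomeModel", function(object) {
  msgs <- character()
  nm <- names(object@sequences)
  if (is.null(nm) || anyDuplicated(nm))
    msgs <- c(msgs, "chromosomes must have unique names")
  if (!all(names(object@armFraction) %in% nm) ||
      length(object@armFraction) != length(object@sequences))
    msgs <- c(msgs, "armFraction must be named after the chromosomes")
  if (length(object@armFraction) &&
      (any(object@armFraction <= 0) || any(object@armFraction >= 1)))
    msgs <- c(msgs, "armFraction values must be strictly inside (0,1)")
  lens <- stats::setNames(Biostrings::width(object@sequences), nm)
  te <- object@teInsertions
  if (nrow(te)) {
    if (!all(te$chrom %in% nm))
      msgs <- c(msgs, "teInsertions reference unknown chromosomes")
    else if (any(te$start < 0) || any(te$end > lens[te$chrom]))
      msgs <- c(msgs, "every te insertion interval must lie within its chromosome")
  }
  jt <- object@junctionTruth
  if (nrow(jt)) {
    if (!all(jt$chrom %in% nm))
      msgs <- c(msgs, "junctionTruth references unknown chromosomes")
    else if (any(jt$position <= 0) || any(jt$position >= lens[jt$chrom]))
      msgs <- c(msgs, "junction positions must be strictly inside (0, chromosome length)")
    if (!all(c(jt$left_class, jt$right_class) %in% .JUNCTION_CLASSES))
      msgs <- c(msgs, "junction classes must be retrotransposon/dna_transposon/unknown")
  }
  if (length(msgs)) msgs else TRUE
})

#' ReadSet: simulated single-end shotgun reads with origin bookkeeping
#'
#' @slot sequences Named [Biostrings::DNAStringSet] of reads.
#' @slot origins data.frame: chrom, start (0-based), strand, one row per read.
#'   Origins describe the genomic substring a read was drawn from before error
#'   injection.
#' @slot nominalCoverage The coverage the set was generated at.
#' @slot readLength Fixed read length.
#'
#' @seealso [simulateReads()]
#' @exportClass ReadSet
setClass("ReadSet",
         slots = c(sequences = "DNAStringSet", origins = "data.frame",
                   nominalCoverage = "numeric", readLength = "integer"))

setValidity("ReadSet", function(object) {
  msgs <- character()
  if (nrow(object@origins) != length(object@sequences))
    msgs <- c(msgs, "origins must have one row per read")
  if (length(object@nominalCoverage) != 1 || object@nominalCoverage <= 0)
    msgs <- c(msgs, "nominalCoverage must be a single positive number")
  if (nrow(object@origins) &&
      !all(object@origins$strand %in% c("+", "-")))
    msgs <- c(msgs, "strand must be '+' or '-'")
  if (length(msgs)) msgs else TRUE
})

#' LinePanel: aneuploid stock definitions
#'
#' One control line, nullisomic-tetrasomic lines (one missing chromosome
#' each), terminal-deletion lines defined by an arm and a fraction-length
#' breakpoint, and optionally an alternative-genome line lacking the whole
#' target genome (the tetraploid screen).
#'
#' @slot lines data.frame with columns name, kind, chromosome, arm,
#'   breakpoint_fl. Deletion lines retain the proximal fraction `[0, b]` of
#'   their arm, measured centromere (0) to telomere (1).
#'
#' @seealso [buildLinePanel()]
#' @exportClass LinePanel
setClass("LinePanel", slots = c(lines = "data.frame"))

setValidity("LinePanel", function(object) {
  df <- object@lines
  msgs <- character()
  req <- c("name", "kind", "chromosome", "arm", "breakpoint_fl")
  missing <- setdiff(req, names(df))
  if (length(missing))
    return(sprintf("lines is missing column(s): %s", paste(missing, collapse = ", ")))
  if (!all(df$kind %in% .LINE_KINDS))
    msgs <- c(msgs, sprintf("kind must be one of: %s", paste(.LINE_KINDS, collapse = ", ")))
  if (sum(df$kind == "control") != 1)
    msgs <- c(msgs, "a panel must contain exactly one control line")
  if (anyDuplicated(df$name))
    msgs <- c(msgs, "line names must be unique")
  del <- df[df$kind == "deletion", , drop = FALSE]
  if (nrow(del)) {
    if (anyNA(del$breakpoint_fl) || any(del$breakpoint_fl <= 0) ||
        any(del$breakpoint_fl >= 1))
      msgs <- c(msgs, "deletion lines need a breakpoint strictly inside (0,1)")
    if (!all(del$arm %in% c("S", "L")) || any(del$chromosome == ""))
      msgs <- c(msgs, "deletion lines need a chromosome and an arm (S or L)")
  }
  nulli <- df[df$kind == "nulli_tetrasomic", , drop = FALSE]
  if (nrow(nulli) && any(nulli$chromosome == ""))
    msgs <- c(msgs, "nulli-tetrasomic lines need a target chromosome")
  if (length(msgs)) msgs else TRUE
})

#' SignalModel: parameters of the hybridization dosage response
#'
#' Intensity for a probe at locus copy number c is
#' `baseIntensity * copyGain^(c-1)` for `c >= 1`, zero for repeat-junction
#' probes at `c = 0`, and `crossHyb * baseIntensity` for gene probes at
#' `c = 0` (homoeologous background). Multiplicative lognormal noise with
#' log-sd `lognormalSd` is applied per spot; with probability `dropoutRate` a
#' spot measurement is replaced with a near-background value.
#'
#' @slot baseIntensity Positive real, single-copy expected intensity.
#' @slot copyGain Per-additional-copy multiplicative factor.
#' @slot lognormalSd Log-scale standard deviation of spot noise.
#' @slot dropoutRate Fraction in `[0,1]`.
#' @slot crossHyb Fraction in `[0,1]`, gene-probe homoeologous background.
#' @slot seed Integer RNG seed.
#'
#' @seealso [signalModel()], [simulateHybridization()]
#' @exportClass SignalModel
setClass("SignalModel",
         slots = c(baseIntensity = "numeric", copyGain = "numeric",
                   lognormalSd = "numeric", dropoutRate = "numeric",
                   crossHyb = "numeric", seed = "integer"))

setValidity("SignalModel", function(object) {
  msgs <- character()
  if (object@baseIntensity <= 0) msgs <- c(msgs, "baseIntensity must be positive")
  if (object@copyGain <= 0) msgs <- c(msgs, "copyGain must be positive")
  if (object@lognormalSd < 0) msgs <- c(msgs, "lognormalSd must be non-negative")
  for (s in c("dropoutRate", "crossHyb")) {
    v <- slot(object, s)
    if (v < 0 || v > 1) msgs <- c(msgs, sprintf("%s must be in [0,1]", s))
  }
  if (length(msgs)) msgs else TRUE
})

#' SignalMatrix: replicated two-channel hybridization intensities
#'
#' A [SummarizedExperiment::SummarizedExperiment] with a single `"intensity"`
#' assay (probes x array columns). `colData` carries `line`, `array_rep`,
#' `spot_rep` and `channel` (`"test"` or `"reference"`); every
#' (line, array, spot) combination must be present in both channels.
#'
#' @seealso [simulateHybridization()], [quantileNormalize()]
#' @exportClass SignalMatrix
setClass("SignalMatrix", contains = "SummarizedExperiment")

setValidity("SignalMatrix", function(object) {
  cd <- SummarizedExperiment::colData(object)
  req <- c("line", "array_rep", "spot_rep", "channel")
  missing <- setdiff(req, names(cd))
  if (length(missing))
    return(sprintf("colData is missing column(s): %s", paste(missing, collapse = ", ")))
  msgs <- character()
  if (!all(cd$channel %in% c("test", "reference")))
    msgs <- c(msgs, "channel must be 'test' or 'reference'")
  if (!"intensity" %in% SummarizedExperiment::assayNames(object))
    msgs <- c(msgs, "assay 'intensity' is required")
  else if (any(SummarizedExperiment::assay(object, "intensity") < 0, na.rm = TRUE))
    msgs <- c(msgs, "intensities must be non-negative")
  key <- paste(cd$line, cd$array_rep, cd$spot_rep)
  tst <- unique(key[cd$channel == "test"])
  ref <- unique(key[cd$channel == "reference"])
  if (!setequal(tst, ref))
    msgs <- c(msgs, "every (line, array, spot) must be measured in both channels")
  if (length(msgs)) msgs else TRUE
})

#' ProbeSet: designed probes with per-filter verdicts and accounting
#'
#' @slot probes data.frame, one row per extracted probe candidate: probe_id,
#'   probe_type ("rjm" or "gene"), sequence (52 nt), source_id, source_start,
#'   chrom, position (genome truth coordinate of the junction midpoint, NA when
#'   unknown), gc_percent, tm_celsius, verdict_homopolymer,
#'   verdict_read_validation, verdict_copy_number, verdict_thermo
#'   ("pass"/"fail"/"not_run"), selected (logical).
#' @slot accounting Named integer vector: candidates, rejected_edge,
#'   rejected_homopolymer, rejected_read_validation, rejected_copy_number,
#'   rejected_thermo, selected. Each probe is charged to its first failing
#'   filter; candidates = selected + sum of rejections.
#'
#' @seealso [runDesignPipeline()]
#' @exportClass ProbeSet
setClass("ProbeSet", slots = c(probes = "data.frame", accounting = "integer"))

setValidity("ProbeSet", function(object) {
  acc <- object@accounting
  req <- c("candidates", "rejected_edge", "rejected_homopolymer",
           "rejected_read_validation", "rejected_copy_number",
           "rejected_thermo", "selected")
  missing <- setdiff(req, names(acc))
  if (length(missing))
    return(sprintf("accounting is missing: %s", paste(missing, collapse = ", ")))
  if (acc[["candidates"]] !=
      acc[["selected"]] + sum(acc[setdiff(req, c("candidates", "selected"))]))
    return("accounting must satisfy candidates = selected + sum(rejections)")
  TRUE
})

## ---- show methods ----

setMethod("show", "RepeatLibrary", function(object) {
  tab <- table(factor(object@repeatClass, levels = .REPEAT_CLASSES))
  cat(sprintf("RepeatLibrary with %d elements (%d retrotransposon, %d dna_transposon)\n",
              length(object@sequences), tab[["retrotransposon"]], tab[["dna_transposon"]]))
})

setMethod("show", "GenomeModel", function(object) {
  cat(sprintf("GenomeModel: %d chromosome(s), %s bp total\n",
              length(object@sequences),
              format(sum(Biostrings::width(object@sequences)), big.mark = ",")))
  cat(sprintf("  %d TE insertion(s), %d gene(s), %d truth junction(s)\n",
              nrow(object@teInsertions), nrow(object@genes),
              nrow(object@junctionTruth)))
})

setMethod("show", "ReadSet", function(object) {
  cat(sprintf("ReadSet: %s reads of length %d (nominal coverage %.2gx)\n",
              format(length(object@sequences), big.mark = ","),
              object@readLength, object@nominalCoverage))
})

setMethod("show", "LinePanel", function(object) {
  tab <- table(factor(object@lines$kind, levels = .LINE_KINDS))
  cat(sprintf("LinePanel with %d lines (%s)\n", nrow(object@lines),
              paste(sprintf("%d %s", tab, names(tab)), collapse = ", ")))
})

setMethod("show", "SignalModel", function(object) {
  cat(sprintf(paste0("SignalModel: base %.3g, copyGain %.3g, lognormalSd %.3g, ",
                     "dropout %.3g, crossHyb %.3g, seed %d\n"),
              object@baseIntensity, object@copyGain, object@lognormalSd,
              object@dropoutRate, object@crossHyb, object@seed))
})

setMethod("show", "ProbeSet", function(object) {
  acc <- object@accounting
  cat(sprintf("ProbeSet: %d candidates, %d selected\n",
              acc[["candidates"]], acc[["selected"]]))
  rej <- acc[grep("^rejected_", names(acc))]
  cat("  rejections:", paste(sprintf("%s=%d", sub("rejected_", "", names(rej)), rej),
                             collapse = ", "), "\n")
})
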