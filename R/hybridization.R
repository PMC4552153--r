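#' Construct a SignalModel
#'
#' Defaults describe a well-behaved two-channel array: single-copy intensity
#' 1000, per-extra-copy gain 1.8, 15% multiplicative (log-sd) spot noise, 2%
#' spot dropout, and 30% homoeologous cross-hybridization background for gene
#' probes. Set `lognormalSd = 0` and `dropoutRate = 0` for a noise-free model.
#'
#' @param baseIntensity Expected single-copy intensity.
#' @param copyGain Multiplicative gain per additional copy.
#' @param lognormalSd Log-scale sd of spot noise.
#' @param dropoutRate Per-spot dropout probability.
#' @param crossHyb Gene-probe background fraction at copy number 0.
#' @param seed Integer seed.
#' @return A [SignalModel-class].
#' @export
signalModel <- function(baseIntensity = 1000, copyGain = 1.8, lognormalSd = 0.15,
                        dropoutRate = 0.02, crossHyb = 0.3, seed = 1L) {
  new("SignalModel", baseIntensity = as.numeric(baseIntensity),
      copyGain = as.numeric(copyGain), lognormalSd = as.numeric(lognormalSd),
      dropoutRate = as.numeric(dropoutRate), crossHyb = as.numeric(crossHyb),
      seed = as.integer(seed))
}

#' Assemble a SignalMatrix from an intensity matrix and column metadata
#'
#' @param intensity Numeric matrix, probes x array columns.
#' @param info data.frame with columns line, array_rep, spot_rep, channel.
#' @return A [SignalMatrix-class].
#' @export
SignalMatrix <- function(intensity, info) {
  .checkColumns(info, c("line", "array_rep", "spot_rep", "channel"), "column info")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = intensity), colData = S4Vectors::DataFrame(info))
  new("SignalMatrix", se)
}

#' Normalize probe loci input
#'
#' Accepts either a ProbeSet (selected probes with genome coordinates) or a
#' data.frame with columns probe_id, chrom, position, probe_type (optionally
#' multi_copy).
#' @noRd
.probeLoci <- function(probes) {
  if (is(probes, "ProbeSet")) {
    df <- probeTable(probes)
    df <- df[df$selected, c("probe_id", "chrom", "position", "probe_type")]
  } else {
    df <- as.data.frame(probes)
    .checkColumns(df, c("probe_id", "chrom", "position", "probe_type"), "probes")
  }
  if (!"multi_copy" %in% names(df)) df$multi_copy <- FALSE
  bad <- is.na(df$position) & !df$multi_copy
  if (any(bad))
    stop("probe without a truth coordinate and not flagged multi-copy: ",
         df$probe_id[which(bad)[1]], call. = FALSE)
  df
}

#' Simulate replicated two-channel hybridization signals
#'
#' For every panel line, every array replicate and every spot replicate, a
#' test-channel (aneuploid line) and reference-channel (control genome)
#' intensity is drawn per probe under the dosage model of
#' [SignalModel-class]: the reference channel is centred on the control copy
#' number's intensity, the test channel on the line's copy number at the
#' probe's locus; gene probes retain `crossHyb * baseIntensity` even at copy
#' number 0 while repeat-junction probes drop to zero. Probes flagged
#' `multi_copy` are given two copies in every line. Deterministic given
#' `model@seed`.
#'
#' @param panel A [LinePanel-class].
#' @param probes A [ProbeSet-class] (selected probes) or a data.frame with
#'   columns probe_id, chrom, position, probe_type and optionally multi_copy.
#' @param genome The [GenomeModel-class] the loci refer to.
#' @param model A [SignalModel-class].
#' @param nArrays,nSpots Array and spot replicate counts (defaults 2 and 3).
#' @return A [SignalMatrix-class] with rowData carrying the probe loci.
#' @export
simulateHybridization <- function(panel, probes, genome, model,
                                  nArrays = 2L, nSpots = 3L) {
  stopifnot(is(panel, "LinePanel"), is(genome, "GenomeModel"),
            is(model, "SignalModel"))
  loci <- .probeLoci(probes)
  ln <- panelLines(panel)
  np <- nrow(loci)

  ## copy number matrix: probes x lines
  copies <- vapply(ln$name, function(nm)
    locusCopyNumber(genome, panel, nm, loci$chrom, loci$position), integer(np))
  copies <- matrix(copies, nrow = np,
                   dimnames = list(loci$probe_id, ln$name))
  copies[loci$multi_copy, ] <- 2L
  ctrlCopies <- copies[, ln$name[ln$kind == "control"], drop = TRUE]

  base <- model@baseIntensity
  gain <- model@copyGain
  Etest <- base * gain^(pmax(copies, 1L) - 1L)
  zero <- copies == 0L
  geneRow <- matrix(loci$probe_type == "gene", nrow = np, ncol = ncol(copies))
  Etest[zero] <- ifelse(geneRow[zero], model@crossHyb * base, 0)
  Eref <- base * gain^(pmax(ctrlCopies, 1L) - 1L)  # control has no zero loci

  info <- expand.grid(channel = c("test", "reference"),
                      spot_rep = seq_len(nSpots), array_rep = seq_len(nArrays),
                      line = ln$name, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  info <- info[, c("line", "array_rep", "spot_rep", "channel")]
  M <- matrix(0, nrow = np, ncol = nrow(info),
              dimnames = list(loci$probe_id,
                              paste(info$line, paste0("a", info$array_rep),
                                    paste0("s", info$spot_rep), info$channel,
                                    sep = ".")))
  isTest <- info$channel == "test"
  M[, isTest] <- Etest[, info$line[isTest]]
  M[, !isTest] <- matrix(Eref, nrow = np, ncol = sum(!isTest))

  M <- .withSeed(model@seed, {
    if (model@lognormalSd > 0)
      M <- M * exp(matrix(stats::rnorm(length(M), 0, model@lognormalSd),
                          nrow = np))
    if (model@dropoutRate > 0) {
      drop <- matrix(stats::runif(length(M)) < model@dropoutRate, nrow = np)
      nd <- sum(drop)
      if (nd > 0)
        M[drop] <- 0.01 * base *
          exp(stats::rnorm(nd, 0, max(model@lognormalSd, 0.1)))
    }
    M
  })

  se <- SignalMatrix(M, info)
  SummarizedExperiment::rowData(se) <- S4Vectors::DataFrame(loci)
  se
}
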