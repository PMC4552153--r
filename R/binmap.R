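## Deletion-bin bookkeeping: bin physical sizes, pericentromeric subtraction,
## marker densities, coverage, genetic-map integration and within-bin ordering.

#' Physical length of a deletion bin
#'
#' The fragment between two breakpoints at fraction lengths `a < b` on an arm
#' of physical length `armLengthMb` spans `(b - a) * armLengthMb` megabases.
#'
#' @param armLengthMb Arm physical length in Mb (> 0).
#' @param flInterval Numeric `c(a, b)` with `0 <= a < b <= 1`.
#' @return Bin length in Mb.
#' @examples
#' estimateBinLength(381.0, c(0.41, 1.00))  # 224.79, a terminal bin
#' @export
estimateBinLength <- function(armLengthMb, flInterval) {
  if (armLengthMb <= 0) stop("arm length must be positive", call. = FALSE)
  a <- flInterval[1]; b <- flInterval[2]
  if (a >= b) stop("fl interval must satisfy a < b", call. = FALSE)
  if (a < 0 || b > 1) stop("fl interval must lie within [0, 1]", call. = FALSE)
  (b - a) * armLengthMb
}

#' Pericentromeric marker count by subtraction
#'
#' The proximal composite bin is not assayed by any deletion line; its marker
#' count is the chromosome's nulli-tetrasomic total minus the markers placed
#' in the assayed bins.
#'
#' @param chromosomeTotal Markers assigned to the chromosome.
#' @param binCounts Marker counts of the chromosome's assayed bins.
#' @return `chromosomeTotal - sum(binCounts)`.
#' @examples
#' pericentromericBySubtraction(3921, c(67, 113, 273, 247))  # 3221
#' @export
pericentromericBySubtraction <- function(chromosomeTotal, binCounts) {
  s <- sum(binCounts)
  if (s > chromosomeTotal)
    stop(sprintf(paste0("bin counts (%d) exceed the chromosome total (%d): ",
                        "inconsistent accounting"), s, chromosomeTotal),
         call. = FALSE)
  as.integer(chromosomeTotal - s)
}

#' Marker density of a mapped region
#'
#' @param nMarkers Number of markers (> 0).
#' @param spanMb Physical span in Mb (> 0).
#' @return list(markers_per_mb, kb_per_marker).
#' @examples
#' markerDensity(35118, 4900)  # ~7 markers/Mb, ~140 kb/marker
#' @export
markerDensity <- function(nMarkers, spanMb) {
  if (nMarkers <= 0 || spanMb <= 0)
    stop("marker count and span must be positive", call. = FALSE)
  list(markers_per_mb = nMarkers / spanMb,
       kb_per_marker = 1000 * spanMb / nMarkers)
}

#' Fraction of the genome covered by the assayed bins
#'
#' With a genome size known only as a range, coverage is itself a range:
#' dividing by the high estimate gives the low percentage and vice versa.
#'
#' @param assayedMb Total assayed length in Mb.
#' @param genomeSizeRange `c(low, high)` genome size in Mb.
#' @return Numeric `c(low_percent, high_percent)`.
#' @examples
#' coverageFraction(2500, c(4020, 4950))  # c(50.5, 62.2)
#' @export
coverageFraction <- function(assayedMb, genomeSizeRange) {
  if (assayedMb <= 0 || any(genomeSizeRange <= 0))
    stop("sizes must be positive", call. = FALSE)
  c(100 * assayedMb / genomeSizeRange[2], 100 * assayedMb / genomeSizeRange[1])
}

#' Summarize per-bin marker counts
#'
#' @param binCounts Named integer vector (or data.frame with `bin` and
#'   `count`) of unique markers per bin.
#' @return list(n_bins, total, mean, min, max).
#' @export
summarizeBins <- function(binCounts) {
  if (is.data.frame(binCounts)) binCounts <- stats::setNames(binCounts$count,
                                                             binCounts$bin)
  if (length(binCounts) < 1) stop("need at least one bin", call. = FALSE)
  list(n_bins = length(binCounts), total = sum(binCounts),
       mean = sum(binCounts) / length(binCounts),
       min = min(binCounts), max = max(binCounts))
}

#' Deletion-bin definitions implied by a line panel
#'
#' Enumerates, per chromosome, the assayed bins between consecutive
#' breakpoints (including the terminal bin of each arm with deletion lines)
#' and the proximal pericentromeric composite, with physical lengths taken
#' from per-arm lengths.
#'
#' @param panel A [LinePanel-class].
#' @param armLengthsMb Named numeric: `"<chrom><arm>"` (e.g. `"1DS"`) -> Mb.
#'   When `NULL`, physical lengths are `NA`.
#' @return data.frame: chromosome, arm, fl_low, fl_high, label, kind,
#'   length_mb.
#' @export
binDefinitionsFromPanel <- function(panel, armLengthsMb = NULL) {
  ln <- panelLines(panel)
  del <- ln[ln$kind == "deletion", , drop = FALSE]
  out <- list()
  for (ch in unique(del$chromosome)) {
    assayed <- 0
    for (a in c("S", "L")) {
      bps <- sort(del$breakpoint_fl[del$chromosome == ch & del$arm == a])
      if (!length(bps)) next
      armLen <- if (is.null(armLengthsMb)) NA_real_ else
        armLengthsMb[[paste0(ch, a)]]
      edges <- c(bps, 1)
      for (i in seq_len(length(edges) - 1L)) {
        lenMb <- if (is.na(armLen)) NA_real_ else
          estimateBinLength(armLen, c(edges[i], edges[i + 1L]))
        out[[length(out) + 1L]] <- data.frame(
          chromosome = ch, arm = a, fl_low = edges[i], fl_high = edges[i + 1L],
          label = sprintf("%s%s-%.2f-%.2f", ch, a, edges[i], edges[i + 1L]),
          kind = if (edges[i + 1L] == 1) "terminal" else "interstitial",
          length_mb = lenMb, stringsAsFactors = FALSE)
        if (!is.na(lenMb)) assayed <- assayed + lenMb
      }
    }
    ## proximal composite: both arms' unassayed residue plus the centromere
    periLen <- NA_real_
    if (!is.null(armLengthsMb)) {
      tot <- sum(armLengthsMb[paste0(ch, c("S", "L"))], na.rm = TRUE)
      periLen <- tot - assayed
    }
    out[[length(out) + 1L]] <- data.frame(
      chromosome = ch, arm = "C", fl_low = 0, fl_high = NA_real_,
      label = sprintf("%sC", ch), kind = "pericentromeric",
      length_mb = periLen, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Truth bin label of a genomic locus
#'
#' The label [assignBin()] should recover for a locus, given the panel's
#' breakpoints: the bin whose half-open FL interval `(a, b]` contains the
#' locus, or `"pericentromeric-inferred"` when no deletion line assays it.
#'
#' @param genome A [GenomeModel-class].
#' @param panel A [LinePanel-class].
#' @param chrom,position Locus vectors.
#' @return Character vector of bin labels.
#' @export
truthBinLabel <- function(genome, panel, chrom, position) {
  ln <- panelLines(panel)
  del <- ln[ln$kind == "deletion", , drop = FALSE]
  fl <- locusFL(genome, chrom, position)
  n <- nrow(fl)
  chrom <- rep_len(chrom, n)
  out <- character(n)
  for (i in seq_len(n)) {
    ch <- chrom[i]
    bps <- sort(del$breakpoint_fl[del$chromosome == ch & del$arm == fl$arm[i]])
    if (!length(bps) || fl$fl[i] <= bps[1]) {
      out[i] <- "pericentromeric-inferred"
    } else {
      ## left-open intervals (a, b]: a locus exactly at a breakpoint is
      ## retained by that deletion line, hence proximal to it
      k <- findInterval(fl$fl[i], bps, left.open = TRUE)
      lower <- bps[k]
      upper <- if (k < length(bps)) bps[k + 1L] else 1
      out[i] <- sprintf("%s%s-%.2f-%.2f", ch, fl$arm[i], lower, upper)
    }
  }
  out
}

#' Order markers within a bin against a genetic map
#'
#' Markers with genetic-map entries are sorted by their centiMorgan position.
#' A marker is flagged discordant — and excluded from the ordered list — when
#' its position falls outside the consensus cM span of the bin's remaining
#' markers while lying inside an adjacent bin's span (a bin-level conflict
#' between the physical and genetic maps).
#'
#' @param markerIds Markers assigned to the bin.
#' @param geneticMap data.frame: marker_id, chromosome, position_cm.
#' @param neighborIds Optional list of character vectors of the adjacent
#'   bins' markers (used to confirm discordance).
#' @return list(ordered = data.frame(marker_id, position_cm),
#'   discordant = character vector).
#' @export
orderMarkersInBin <- function(markerIds, geneticMap, neighborIds = list()) {
  .checkColumns(geneticMap, c("marker_id", "chromosome", "position_cm"),
                "genetic map")
  pos <- geneticMap$position_cm[match(markerIds, geneticMap$marker_id)]
  mapped <- !is.na(pos)
  ids <- markerIds[mapped]; cm <- pos[mapped]
  if (!length(ids))
    return(list(ordered = data.frame(marker_id = character(),
                                     position_cm = numeric(),
                                     stringsAsFactors = FALSE),
                discordant = character()))
  neighborSpans <- lapply(neighborIds, function(nb) {
    p <- geneticMap$position_cm[match(nb, geneticMap$marker_id)]
    p <- p[!is.na(p)]
    if (length(p)) range(p) else NULL
  })
  discordant <- logical(length(ids))
  if (length(ids) >= 2) {
    for (i in seq_along(ids)) {
      rest <- cm[-i]
      inOwn <- cm[i] >= min(rest) && cm[i] <= max(rest)
      if (inOwn) next
      inNeighbor <- any(vapply(neighborSpans, function(sp)
        !is.null(sp) && cm[i] >= sp[1] && cm[i] <= sp[2], logical(1)))
      discordant[i] <- inNeighbor
    }
  }
  keep <- !discordant
  o <- order(cm[keep])
  list(ordered = data.frame(marker_id = ids[keep][o],
                            position_cm = cm[keep][o],
                            stringsAsFactors = FALSE),
       discordant = ids[discordant])
}

#' Genetic length of a bin
#'
#' @param positionsCm cM positions of the bin's concordant markers (>= 1).
#' @return `max - min` (0 for a single marker).
#' @export
binGeneticLength <- function(positionsCm) {
  positionsCm <- positionsCm[!is.na(positionsCm)]
  if (!length(positionsCm)) stop("need at least one mapped marker", call. = FALSE)
  max(positionsCm) - min(positionsCm)
}

#' Correlation between bin physical and genetic lengths
#'
#' @param physicalMb,geneticCm Parallel numeric vectors (>= 3 bins).
#' @return list(pearson_r, pearson_p, spearman_rho, spearman_p); all `NA`
#'   when either vector is constant.
#' @export
lengthCorrelation <- function(physicalMb, geneticCm) {
  ok <- stats::complete.cases(physicalMb, geneticCm)
  x <- physicalMb[ok]; y <- geneticCm[ok]
  if (length(x) < 3) stop("need at least three bins", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(pearson_r = NA_real_, pearson_p = NA_real_,
                spearman_rho = NA_real_, spearman_p = NA_real_))
  pe <- stats::cor.test(x, y, method = "pearson")
  sp <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
       spearman_rho = unname(sp$estimate), spearman_p = sp$p.value)
}

#' Assemble a bin map from assignments and bin definitions
#'
#' Tabulates markers per bin split by probe type, adds the inferred
#' pericentromeric counts by subtraction from the chromosome totals, and
#' checks the accounting identity chromosome total = assayed bins +
#' pericentromeric + bin-unassigned.
#'
#' @param assignments data.frame from [stringencyLadder()] (probe_id,
#'   chromosome, bin) plus a `probe_type` column.
#' @param binDefs data.frame from [binDefinitionsFromPanel()].
#' @return data.frame: one row per bin (label, chromosome, kind, length_mb,
#'   n_rjm, n_gene, n_total), pericentromeric rows filled by subtraction.
#' @export
buildBinMap <- function(assignments, binDefs) {
  .checkColumns(assignments, c("probe_id", "chromosome", "bin", "probe_type"),
                "assignments")
  asg <- assignments[assignments$chromosome != "unassigned", , drop = FALSE]
  res <- binDefs
  res$n_rjm <- 0L; res$n_gene <- 0L
  for (i in seq_len(nrow(res))) {
    if (res$kind[i] == "pericentromeric") next
    sel <- asg$bin == res$label[i]
    res$n_rjm[i] <- sum(sel & asg$probe_type == "rjm")
    res$n_gene[i] <- sum(sel & asg$probe_type == "gene")
  }
  for (ch in unique(res$chromosome)) {
    chRows <- res$chromosome == ch & res$kind != "pericentromeric"
    peri <- which(res$chromosome == ch & res$kind == "pericentromeric")
    chAsg <- asg[asg$chromosome == ch, , drop = FALSE]
    for (type in c("rjm", "gene")) {
      ## footnote rule: composite = chromosome total minus the assayed bins,
      ## so probes confidently on the chromosome but not placed in any assayed
      ## bin are inferred to sit in the proximal composite
      total <- sum(chAsg$probe_type == type)
      col <- paste0("n_", type)
      res[[col]][peri] <- pericentromericBySubtraction(total, res[[col]][chRows])
    }
  }
  res$n_total <- res$n_rjm + res$n_gene
  res
}
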