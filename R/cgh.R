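## Comparative-hybridization analysis: normalization, replicate handling,
## signal-loss testing, the decreasing stringency ladder, and chromosome /
## deletion-bin assignment.

#' Quantile normalization of a signal matrix
#'
#' Full quantile (rank-mean) normalization: after normalization every column
#' shares the identical sorted value vector, the per-rank mean of the input
#' columns; tied entries within a column receive the mean of their tied rank
#' values. A simpler median-scaling alternative is available via
#' `method = "median"` (columns rescaled to a common median).
#'
#' @param x Numeric matrix (probes x columns) or [SignalMatrix-class].
#' @param method `"quantile"` (default) or `"median"`.
#' @return Same shape as the input, normalized.
#' @examples
#' quantileNormalize(cbind(a = c(1, 2, 3), b = c(2, 4, 6)))
#' @export
quantileNormalize <- function(x, method = c("quantile", "median")) {
  method <- match.arg(method)
  if (is(x, "SignalMatrix")) {
    m <- SummarizedExperiment::assay(x, "intensity")
    SummarizedExperiment::assay(x, "intensity") <-
      quantileNormalize(m, method = method)
    return(x)
  }
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("need at least two columns to normalize", call. = FALSE)
  if (any(x < 0, na.rm = TRUE)) stop("negative intensities", call. = FALSE)
  dn <- dimnames(x)
  out <- if (method == "quantile") {
    limma::normalizeQuantiles(x, ties = TRUE)
  } else {
    med <- apply(x, 2, stats::median, na.rm = TRUE)
    sweep(x, 2, med, "/") * mean(med)
  }
  dimnames(out) <- dn
  out
}

#' Average spot replicates within arrays
#'
#' Means over spot replicates within each (line, array replicate, channel),
#' with `NA` spots (masked dropouts) excluded, keeping the array-level values
#' available as the test sample for the loss t-test.
#'
#' @param x A [SignalMatrix-class] or a matrix plus `info` data.frame
#'   (columns line, array_rep, spot_rep, channel).
#' @param info Column metadata when `x` is a bare matrix.
#' @return data.frame: probe_id, line, array_rep, channel, mean_intensity.
#' @export
averageReplicates <- function(x, info = NULL) {
  if (is(x, "SignalMatrix")) {
    info <- as.data.frame(SummarizedExperiment::colData(x))
    x <- SummarizedExperiment::assay(x, "intensity")
  }
  .checkColumns(info, c("line", "array_rep", "spot_rep", "channel"), "info")
  if (nrow(info) != ncol(x)) stop("info must describe every column", call. = FALSE)
  key <- paste(info$line, info$array_rep, info$channel, sep = "\r")
  groups <- split(seq_len(ncol(x)), key)
  out <- lapply(names(groups), function(kk) {
    cols <- groups[[kk]]
    parts <- strsplit(kk, "\r", fixed = TRUE)[[1]]
    data.frame(probe_id = rownames(x) %||% as.character(seq_len(nrow(x))),
               line = parts[1], array_rep = as.integer(parts[2]),
               channel = parts[3],
               mean_intensity = rowMeans(x[, cols, drop = FALSE], na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Vectorized pooled-variance two-sided Student t-test between row groups.
## A, B: matrices with the same rows. Degenerate rows (zero pooled variance)
## get p = 0 when the means differ and p = 1 when they agree.
.rowPooledT <- function(A, B) {
  n1 <- rowSums(!is.na(A)); n2 <- rowSums(!is.na(B))
  m1 <- rowMeans(A, na.rm = TRUE); m2 <- rowMeans(B, na.rm = TRUE)
  ss1 <- rowSums((A - m1)^2, na.rm = TRUE)
  ss2 <- rowSums((B - m2)^2, na.rm = TRUE)
  df <- n1 + n2 - 2
  sp2 <- (ss1 + ss2) / pmax(df, 1)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(t), df)
  scale <- pmax(abs(m1), abs(m2), 1e-300)
  degenerate <- se == 0 | !is.finite(se)
  p[degenerate] <- ifelse(abs(m1 - m2)[degenerate] / scale[degenerate] < 1e-9, 1, 0)
  p[n1 < 2 | n2 < 2] <- NA_real_
  p
}

#' Signal-loss test for one probe
#'
#' `loss = 1 - mean(test)/mean(ref)`, with a two-sided pooled-variance
#' Student t-test on the replicate values. A probe is flagged when the loss
#' reaches the threshold and the p-value is below `alpha`.
#'
#' @param testValues,refValues Numeric replicate vectors (>= 2 values each).
#' @param threshold Minimum loss fraction to flag.
#' @param alpha Significance level.
#' @return A list: loss_fraction, p_value, flagged.
#' @export
lossTest <- function(testValues, refValues, threshold = 0.2, alpha = 0.05) {
  testValues <- testValues[!is.na(testValues)]
  refValues <- refValues[!is.na(refValues)]
  if (length(testValues) < 2 || length(refValues) < 2)
    stop("need at least two replicate values per side", call. = FALSE)
  mr <- mean(refValues)
  if (mr == 0) stop("zero reference mean: loss ratio undefined", call. = FALSE)
  loss <- 1 - mean(testValues) / mr
  p <- .rowPooledT(matrix(testValues, nrow = 1), matrix(refValues, nrow = 1))
  list(loss_fraction = loss, p_value = as.numeric(p),
       flagged = !is.na(p) && loss >= threshold && p < alpha)
}

#' Per-probe, per-line signal-loss table
#'
#' Computes, for every probe and every non-control line, the normalized
#' test/reference ratio statistics the assignment ladder consumes. Each spot's
#' test value is divided by its same-spot reference value; ratios are
#' normalized per probe by the control line's median ratio; reference-channel
#' measurements below `maskRefFrac` of their column median are treated as
#' technical dropouts and masked. Loss is `1 - mean(line ratios)/mean(control
#' ratios)` with a pooled t-test between the two ratio sets.
#'
#' @param x A (typically normalized) [SignalMatrix-class], or matrix + `info`.
#' @param panel The [LinePanel-class] describing the lines.
#' @param info Column metadata when `x` is a bare matrix.
#' @param control Name of the control line.
#' @param maskRefFrac Reference-channel dropout mask threshold (fraction of
#'   the column median; 0 disables masking).
#' @return data.frame: probe_id, line, loss_fraction, p_value.
#' @export
lossTable <- function(x, panel, info = NULL, control = "control",
                      maskRefFrac = 0.1) {
  if (is(x, "SignalMatrix")) {
    info <- as.data.frame(SummarizedExperiment::colData(x))
    x <- SummarizedExperiment::assay(x, "intensity")
  }
  .checkColumns(info, c("line", "array_rep", "spot_rep", "channel"), "info")
  ln <- panelLines(panel)
  if (!control %in% info$line)
    stop(sprintf("control line '%s' not present in the signal matrix", control),
         call. = FALSE)
  key <- paste(info$line, info$array_rep, info$spot_rep, sep = "\r")
  tIdx <- which(info$channel == "test")
  rIdx <- match(key[tIdx], key[info$channel == "reference"])
  rIdx <- which(info$channel == "reference")[rIdx]
  if (anyNA(rIdx)) stop("missing reference channel for some spots", call. = FALSE)

  Tm <- x[, tIdx, drop = FALSE]
  Rm <- x[, rIdx, drop = FALSE]
  if (maskRefFrac > 0) {
    med <- apply(Rm, 2, stats::median, na.rm = TRUE)
    bad <- sweep(Rm, 2, maskRefFrac * med, "<")
    Rm[bad] <- NA
  }
  ratio <- Tm / Rm
  spotLine <- info$line[tIdx]
  ctl <- ratio[, spotLine == control, drop = FALSE]
  ctlMed <- apply(ctl, 1, stats::median, na.rm = TRUE)
  if (any(!is.finite(ctlMed)) || any(ctlMed == 0))
    stop("control ratios undefined for some probes", call. = FALSE)
  ratio <- ratio / ctlMed
  ctl <- ratio[, spotLine == control, drop = FALSE]
  ctlMean <- rowMeans(ctl, na.rm = TRUE)

  lines <- setdiff(unique(spotLine), control)
  ids <- rownames(x) %||% as.character(seq_len(nrow(x)))
  out <- lapply(lines, function(l) {
    R <- ratio[, spotLine == l, drop = FALSE]
    data.frame(probe_id = ids, line = l,
               loss_fraction = 1 - rowMeans(R, na.rm = TRUE) / ctlMean,
               p_value = .rowPooledT(R, ctl), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Assign a chromosome from nulli-tetrasomic flags
#'
#' Assigned iff exactly one nullisomic-tetrasomic line is flagged.
#'
#' @param flags Named logical vector, one entry per nulli line; names are the
#'   lines' missing chromosomes.
#' @return The chromosome name, or `"unassigned"`.
#' @export
assignChromosome <- function(flags) {
  if (sum(flags) == 1L) names(flags)[which(flags)] else "unassigned"
}

#' Assign a deletion bin from deletion-line flags
#'
#' A deletion line with breakpoint `b` flags a probe iff the probe lies
#' distal to `b` on the deleted arm, so a real locus produces a prefix of
#' flags over the ascending breakpoints of one arm. Valid patterns map to the
#' bin bounded by the largest flagged and smallest unflagged breakpoints;
#' all lines of an arm flagged gives the terminal bin `(b_max, 1]`; no
#' deletion line flagged on either arm means the probe sits in the proximal
#' region assayed by no line (`"pericentromeric-inferred"`); any non-monotone
#' or cross-arm pattern is `"unassigned"`.
#'
#' @param flags Logical vector over the chromosome's deletion lines.
#' @param arm Character vector ("S"/"L") parallel to `flags`.
#' @param breakpoint Numeric breakpoints parallel to `flags`.
#' @param chromosome Chromosome name used in the bin label.
#' @return A bin label `"<chrom><arm>-<a>-<b>"`, `"pericentromeric-inferred"`
#'   or `"unassigned"`.
#' @examples
#' assignBin(c(TRUE, TRUE), c("L", "L"), c(0.18, 0.41), "1D")  # terminal bin
#' @export
assignBin <- function(flags, arm, breakpoint, chromosome) {
  stopifnot(length(flags) == length(arm), length(flags) == length(breakpoint))
  if (!any(flags)) return("pericentromeric-inferred")
  armsFlagged <- unique(arm[flags])
  if (length(armsFlagged) > 1) return("unassigned")
  a <- armsFlagged
  sel <- arm == a
  b <- breakpoint[sel]; f <- flags[sel]
  o <- order(b)
  b <- b[o]; f <- f[o]
  k <- sum(f)
  if (!all(f[seq_len(k)]) || any(f[-seq_len(k)])) return("unassigned")
  lower <- b[k]
  upper <- if (k < length(b)) b[k + 1L] else 1
  sprintf("%s%s-%.2f-%.2f", chromosome, a, lower, upper)
}

#' Decreasing stringency ladder over loss thresholds
#'
#' Evaluates the chromosome-assignment rule at the strictest loss threshold
#' first (default ladder 0.5, 0.4, 0.3, 0.2, p < alpha throughout); the first
#' threshold at which exactly one nulli-tetrasomic line is flagged fixes the
#' probe's chromosome and stringency level, and the deletion-line flag
#' pattern at that same level fixes its bin. Probes never clean at any level
#' stay unassigned.
#'
#' @param lossTab data.frame from [lossTable()].
#' @param panel The [LinePanel-class].
#' @param thresholds Strictly decreasing loss thresholds.
#' @param alpha Significance level of the loss test.
#' @return data.frame: probe_id, chromosome, bin, stringency_level.
#' @export
stringencyLadder <- function(lossTab, panel, thresholds = c(0.5, 0.4, 0.3, 0.2),
                             alpha = 0.05) {
  if (is.unsorted(rev(thresholds), strictly = TRUE))
    stop("thresholds must be strictly decreasing", call. = FALSE)
  ln <- panelLines(panel)
  ids <- unique(lossTab$probe_id)
  lineNames <- unique(lossTab$line)
  L <- matrix(NA_real_, length(ids), length(lineNames),
              dimnames = list(ids, lineNames))
  P <- L
  idx <- cbind(match(lossTab$probe_id, ids), match(lossTab$line, lineNames))
  L[idx] <- lossTab$loss_fraction
  P[idx] <- lossTab$p_value

  nulli <- ln[ln$kind == "nulli_tetrasomic" & ln$name %in% lineNames, ]
  del <- ln[ln$kind == "deletion" & ln$name %in% lineNames, ]
  delByChrom <- split(del, del$chromosome)

  res <- data.frame(probe_id = ids, chromosome = "unassigned",
                    bin = "unassigned", stringency_level = NA_real_,
                    stringsAsFactors = FALSE)
  for (t in thresholds) {
    F <- !is.na(L) & !is.na(P) & L >= t & P < alpha
    todo <- which(res$chromosome == "unassigned")
    if (!length(todo)) break
    nf <- F[todo, nulli$name, drop = FALSE]
    hit <- rowSums(nf) == 1L
    for (i in todo[hit]) {
      ch <- nulli$chromosome[which(F[i, nulli$name])]
      res$chromosome[i] <- ch
      res$stringency_level[i] <- t
      del <- delByChrom[[ch]]
      res$bin[i] <- if (is.null(del) || nrow(del) == 0) "unassigned" else
        assignBin(F[i, del$name], del$arm, del$breakpoint_fl, ch)
    }
  }
  res
}

#' Genome-specificity screen against an alternative-genome line
#'
#' A probe is kept (judged target-genome specific) iff its signal in the
#' alternative-genome hybridization drops by at least `threshold` relative to
#' the control, with `p < alpha`; probes with substantial homoeologous
#' cross-hybridization fail to lose signal and are dropped.
#'
#' @param lossTab data.frame from [lossTable()] including the alt-genome line.
#' @param altLine Name of the alternative-genome line.
#' @param threshold Minimum loss fraction.
#' @param alpha Significance level.
#' @return Named logical vector (`TRUE` = keep), one entry per probe.
#' @export
screenGenomeSpecific <- function(lossTab, altLine = "AABB", threshold = 0.2,
                                 alpha = 0.05) {
  sel <- lossTab[lossTab$line == altLine, , drop = FALSE]
  if (nrow(sel) == 0) stop(sprintf("line '%s' absent from the loss table", altLine),
                           call. = FALSE)
  keep <- !is.na(sel$p_value) & sel$loss_fraction >= threshold &
    sel$p_value < alpha
  stats::setNames(keep, sel$probe_id)
}

#' Concordance between two assignment tables
#'
#' Compares assignments at chromosome or bin level over the probes assigned
#' in both tables.
#'
#' @param a,b data.frames with probe_id plus chromosome / bin columns.
#' @param level `"chromosome"` or `"bin"`.
#' @return list(n_compared, n_agree, percent); percent is `NA` when the
#'   comparison set is empty.
#' @export
concordance <- function(a, b, level = c("chromosome", "bin")) {
  level <- match.arg(level)
  col <- level
  ka <- a[a[[col]] != "unassigned", c("probe_id", col)]
  kb <- b[b[[col]] != "unassigned", c("probe_id", col)]
  m <- merge(ka, kb, by = "probe_id")
  n <- nrow(m)
  agree <- sum(m[[paste0(col, ".x")]] == m[[paste0(col, ".y")]])
  list(n_compared = n, n_agree = agree,
       percent = if (n > 0) 100 * agree / n else NA_real_)
}

#' End-to-end assignment from a raw signal matrix
#'
#' Normalizes the intensities within groups of columns sharing an expected
#' distribution (same line and channel, i.e. spot and array replicates of one
#' sample), computes the loss table and runs the stringency ladder.
#'
#' @param se A raw [SignalMatrix-class].
#' @param panel The [LinePanel-class].
#' @param thresholds,alpha Ladder parameters (see [stringencyLadder()]).
#' @param control Control line name.
#' @param normalize `"quantile"`, `"median"` or `"none"`.
#' @param maskRefFrac See [lossTable()].
#' @return list(assignments, lossTab) — the ladder output and the loss table.
#' @export
cghAssign <- function(se, panel, thresholds = c(0.5, 0.4, 0.3, 0.2),
                      alpha = 0.05, control = "control",
                      normalize = c("quantile", "median", "none"),
                      maskRefFrac = 0.1) {
  normalize <- match.arg(normalize)
  info <- as.data.frame(SummarizedExperiment::colData(se))
  M <- SummarizedExperiment::assay(se, "intensity")
  if (normalize != "none") {
    groups <- split(seq_len(ncol(M)), paste(info$line, info$channel))
    for (cols in groups) {
      if (length(cols) >= 2)
        M[, cols] <- quantileNormalize(M[, cols, drop = FALSE],
                                       method = normalize)
    }
  }
  lt <- lossTable(M, panel, info = info, control = control,
                  maskRefFrac = maskRefFrac)
  list(assignments = stringencyLadder(lt, panel, thresholds, alpha),
       lossTab = lt)
}
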