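#' Simulate a genome with nested transposable-element insertions
#'
#' Builds a multi-chromosome genome by inserting repeat elements into random
#' backbone ("flank") sequence. With probability `nestingProb` an insertion
#' lands inside a previously inserted element, splitting the host and creating
#' element-element junctions; otherwise it lands in flank sequence. Every
#' boundary between an inserted element and its neighbour (flank or another
#' element) is recorded in the junction truth table, so each non-abutting
#' insertion contributes exactly two truth junctions. Genes are placed in
#' TE-free (flank) intervals after all insertions.
#'
#' Coordinates are 0-based half-open; a junction position is the index of the
#' first base right of the boundary.
#'
#' @param library A [RepeatLibrary-class]; must be non-empty when `teCount > 0`.
#' @param chromSpecs data.frame with columns `name`, `length` (backbone length
#'   in bp, >= 10 kb), `arm_fraction` (short-arm fraction in (0,1)).
#' @param teCount Number of insertions to place.
#' @param nestingProb Probability that an insertion nests inside an existing
#'   element.
#' @param geneCount Number of genes to place in TE-free intervals.
#' @param geneLength Gene length in bp.
#' @param seed Integer seed; identical seeds give byte-identical genomes.
#' @return A [GenomeModel-class].
#' @examples
#' lib <- buildRepeatLibrary(2, 1, c(300, 500), seed = 1)
#' gm <- simulateGenome(lib,
#'   data.frame(name = "1D", length = 2e4, arm_fraction = 0.45),
#'   teCount = 4, nestingProb = 0, geneCount = 2, seed = 5)
#' nrow(junctionTruth(gm))  # 8: two boundaries per insertion
#' @export
simulateGenome <- function(library, chromSpecs, teCount, nestingProb = 0.1,
                           geneCount = 0L, geneLength = 900L, seed = 1L) {
  stopifnot(is(library, "RepeatLibrary"))
  .checkColumns(chromSpecs, c("name", "length", "arm_fraction"), "chromSpecs")
  if (any(chromSpecs$length < 10000))
    stop("chromosome backbone lengths must be at least 10 kb", call. = FALSE)
  if (nestingProb < 0 || nestingProb > 1)
    stop("nestingProb must be in [0,1]", call. = FALSE)
  if (teCount > 0 && length(library) == 0)
    stop("cannot place insertions from an empty library", call. = FALSE)

  eltSeq <- as.character(sequencesOf(library))
  eltRev <- if (length(eltSeq)) .revComp(eltSeq) else character()
  eltClass <- repeatClass(library)
  orientedSeq <- function(id, strand) {
    if (id == "flank") stop("internal: flank has no element sequence")
    if (strand == "+") eltSeq[[id]] else eltRev[[id]]
  }

  .withSeed(seed, {
    ## One backbone string per chromosome; segments reference oriented sources.
    backbone <- stats::setNames(
      vapply(chromSpecs$length, .randomDNA, character(1)), chromSpecs$name)
    segs <- stats::setNames(lapply(chromSpecs$length, function(L) {
      data.frame(source = "flank", class = "unknown", strand = "+",
                 src_start = 0L, src_end = as.integer(L), ins_id = NA_integer_,
                 stringsAsFactors = FALSE)
    }), chromSpecs$name)

    insRecords <- vector("list", teCount)
    for (i in seq_len(teCount)) {
      flat <- do.call(rbind, lapply(names(segs), function(ch) {
        s <- segs[[ch]]
        s$chrom <- ch
        s$idx <- seq_len(nrow(s))
        s
      }))
      flat$len <- flat$src_end - flat$src_start
      isElt <- flat$source != "flank" & flat$len >= 2L
      isFlank <- flat$source == "flank" & flat$len >= 2L
      nest <- any(isElt) && stats::runif(1) < nestingProb
      pool <- flat[if (nest) isElt else isFlank, , drop = FALSE]
      if (nrow(pool) == 0)
        stop("genome too small to host the requested insertions", call. = FALSE)
      tgt <- pool[sample.int(nrow(pool), 1L, prob = pool$len - 1L), ]
      cut <- sample.int(tgt$len - 1L, 1L)  # split point, relative, in 1..len-1

      eid <- sample(names(eltSeq), 1L)
      estrand <- sample(c("+", "-"), 1L)
      ch <- tgt$chrom
      s <- segs[[ch]]
      row <- s[tgt$idx, ]
      left <- row; right <- row
      left$src_end <- row$src_start + cut
      right$src_start <- row$src_start + cut
      newSeg <- data.frame(source = eid, class = eltClass[[eid]], strand = estrand,
                           src_start = 0L,
                           src_end = as.integer(nchar(eltSeq[[eid]])),
                           ins_id = i, stringsAsFactors = FALSE)
      segs[[ch]] <- rbind(
        if (tgt$idx > 1) s[seq_len(tgt$idx - 1L), ] else NULL,
        left, newSeg, right,
        if (tgt$idx < nrow(s)) s[seq(tgt$idx + 1L, nrow(s)), ] else NULL)
      rownames(segs[[ch]]) <- NULL
      insRecords[[i]] <- list(chrom = ch, element_id = eid, strand = estrand,
                              nested = nest)
    }

    ## Materialize sequences and enumerate truth junctions.
    chromStr <- character(length(segs))
    names(chromStr) <- names(segs)
    jt <- list(); te <- list()
    for (ch in names(segs)) {
      s <- segs[[ch]]
      pieces <- vapply(seq_len(nrow(s)), function(j) {
        if (s$source[j] == "flank") {
          substring(backbone[[ch]], s$src_start[j] + 1L, s$src_end[j])
        } else {
          substring(orientedSeq(s$source[j], s$strand[j]),
                    s$src_start[j] + 1L, s$src_end[j])
        }
      }, character(1))
      chromStr[[ch]] <- paste(pieces, collapse = "")
      lens <- s$src_end - s$src_start
      starts <- cumsum(c(0L, lens[-length(lens)]))
      ends <- starts + lens
      if (nrow(s) > 1) {
        for (j in seq_len(nrow(s) - 1L)) {
          lc <- s$class[j]; rc <- s$class[j + 1L]
          if (lc == "unknown" && rc == "unknown") next
          jt[[length(jt) + 1L]] <- data.frame(
            chrom = ch, position = ends[j], left_class = lc, right_class = rc,
            stringsAsFactors = FALSE)
        }
      }
      for (i in which(!vapply(insRecords, is.null, logical(1)))) {
        if (insRecords[[i]]$chrom != ch) next
        rows <- which(!is.na(s$ins_id) & s$ins_id == i)
        te[[length(te) + 1L]] <- data.frame(
          chrom = ch, start = starts[min(rows)], end = ends[max(rows)],
          element_id = insRecords[[i]]$element_id,
          element_class = eltClass[[insRecords[[i]]$element_id]],
          strand = insRecords[[i]]$strand, stringsAsFactors = FALSE)
      }
    }

    ## Genes: one per chosen TE-free segment.
    genes <- data.frame(chrom = character(), start = integer(), end = integer(),
                        gene_id = character(), stringsAsFactors = FALSE)
    if (geneCount > 0) {
      flat <- do.call(rbind, lapply(names(segs), function(ch) {
        s <- segs[[ch]]
        lens <- s$src_end - s$src_start
        starts <- cumsum(c(0L, lens[-length(lens)]))
        data.frame(chrom = ch, gstart = starts, len = lens,
                   flank = s$source == "flank", stringsAsFactors = FALSE)
      }))
      pool <- flat[flat$flank & flat$len >= geneLength, , drop = FALSE]
      if (nrow(pool) < geneCount)
        stop("not enough TE-free interval space to place the requested genes",
             call. = FALSE)
      pick <- pool[sample.int(nrow(pool), geneCount, prob = pool$len), , drop = FALSE]
      off <- vapply(pick$len - geneLength, function(m)
        if (m == 0) 0L else sample.int(m + 1L, 1L) - 1L, integer(1))
      genes <- data.frame(chrom = pick$chrom,
                          start = as.integer(pick$gstart + off),
                          end = as.integer(pick$gstart + off + geneLength),
                          gene_id = sprintf("gene_%04d", seq_len(geneCount)),
                          stringsAsFactors = FALSE)
      rownames(genes) <- NULL
    }

    dss <- Biostrings::DNAStringSet(chromStr)
    jtd <- if (length(jt)) do.call(rbind, jt) else
      data.frame(chrom = character(), position = integer(),
                 left_class = character(), right_class = character(),
                 stringsAsFactors = FALSE)
    ted <- if (length(te)) do.call(rbind, te) else
      data.frame(chrom = character(), start = integer(), end = integer(),
                 element_id = character(), element_class = character(),
                 strand = character(), stringsAsFactors = FALSE)
    new("GenomeModel", sequences = dss,
        armFraction = stats::setNames(chromSpecs$arm_fraction, chromSpecs$name),
        teInsertions = ted, genes = genes, junctionTruth = jtd)
  })
}

#' Arm and fraction-length coordinates of genomic loci
#'
#' Converts 0-based positions to (arm, fraction length) coordinates. The
#' centromere of a chromosome of length L with short-arm fraction f sits at
#' `round(f * L)`; positions below it are on the S arm, the rest on the L arm.
#' Fraction length runs from 0 at the centromere to 1 at the telomere.
#'
#' @param genome A [GenomeModel-class].
#' @param chrom Character vector of chromosome names.
#' @param position Integer vector of 0-based positions (recycled with `chrom`).
#' @return data.frame with columns `arm` ("S"/"L") and `fl` in `[0, 1]`.
#' @export
locusFL <- function(genome, chrom, position) {
  stopifnot(is(genome, "GenomeModel"))
  n <- max(length(chrom), length(position))
  chrom <- rep_len(chrom, n); position <- rep_len(position, n)
  L <- chromLengths(genome)[chrom]
  cent <- round(armFraction(genome)[chrom] * L)
  if (any(position < 0 | position >= L))
    stop("position outside chromosome", call. = FALSE)
  onS <- position < cent
  fl <- ifelse(onS, (cent - position) / cent, (position - cent) / (L - cent))
  data.frame(arm = ifelse(onS, "S", "L"), fl = as.numeric(fl),
             stringsAsFactors = FALSE)
}

#' Extract gene sequences from a genome model
#'
#' @param genome A [GenomeModel-class].
#' @return A named [Biostrings::DNAStringSet], one sequence per annotated gene.
#' @export
geneSequences <- function(genome) {
  stopifnot(is(genome, "GenomeModel"))
  g <- geneAnnotation(genome)
  if (nrow(g) == 0) return(Biostrings::DNAStringSet())
  out <- Biostrings::DNAStringSet(vapply(seq_len(nrow(g)), function(i) {
    substring(as.character(chromSequences(genome)[[g$chrom[i]]]),
              g$start[i] + 1L, g$end[i])
  }, character(1)))
  names(out) <- g$gene_id
  out
}
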