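## 52-mer probe extraction and the four-step filter cascade:
## homopolymer runs -> deep-read validation -> copy-number screen -> GC/Tm.

#' Default probe-design configuration
#'
#' @param probe_length Probe length (even; 52 by default).
#' @param max_run Maximum tolerated homopolymer run.
#' @param min_support Minimum validation-read occurrences of the exact probe.
#' @param max_hits Maximum exact hits against the target-genome read set
#'   before a probe is called multi-copy.
#' @param gc_range,tm_range Inclusive GC% and melting-temperature windows.
#' @param na_molar Sodium concentration for the Tm formula (mol/L).
#' @param max_gene_probes Maximum probes per gene.
#' @param gene_spacing Minimum separation between probes of one gene (bp).
#' @param gene_skip_copy_number Gene probes skip the copy-number screen
#'   (genes are expected in homoeologous copies).
#' @return Named list of parameters.
#' @export
designConfig <- function(probe_length = 52L, max_run = 3L, min_support = 2L,
                         max_hits = 5L, gc_range = c(50, 65),
                         tm_range = c(76, 83), na_molar = 0.165,
                         max_gene_probes = 3L, gene_spacing = 10L,
                         gene_skip_copy_number = TRUE) {
  if (probe_length %% 2L != 0L) stop("probe_length must be even", call. = FALSE)
  list(probe_length = as.integer(probe_length), max_run = as.integer(max_run),
       min_support = as.integer(min_support), max_hits = as.integer(max_hits),
       gc_range = gc_range, tm_range = tm_range, na_molar = na_molar,
       max_gene_probes = as.integer(max_gene_probes),
       gene_spacing = as.integer(gene_spacing),
       gene_skip_copy_number = isTRUE(gene_skip_copy_number))
}

#' Extract a fixed-length probe window around a junction midpoint
#'
#' The window is `[midpoint - length/2, midpoint + length/2)`, so the junction
#' sits exactly at the probe midpoint. Windows that would run off either end
#' of the sequence are rejected with reason `"edge"`.
#'
#' @param sequence A nucleotide string.
#' @param midpoint 0-based boundary coordinate inside the sequence.
#' @param length Even probe length (default 52).
#' @return A list with `sequence` (the probe) and `start` (0-based window
#'   start), or `NULL` with attribute-free `NA` handling: on rejection the
#'   function returns `list(sequence = NA_character_, start = NA_integer_,
#'   reason = "edge")`.
#' @examples
#' extractProbe(strrep("ACGT", 26), 52)$start  # 26
#' @export
extractProbe <- function(sequence, midpoint, length = 52L) {
  length <- as.integer(length)
  if (length %% 2L != 0L) stop("probe length must be even", call. = FALSE)
  half <- length %/% 2L
  start <- as.integer(midpoint) - half
  end <- start + length
  if (start < 0L || end > nchar(sequence))
    return(list(sequence = NA_character_, start = NA_integer_, reason = "edge"))
  list(sequence = substring(sequence, start + 1L, end), start = start,
       reason = NA_character_)
}

#' Homopolymer filter
#'
#' Fails any sequence containing a single-nucleotide run longer than
#' `maxRun` (default: runs of 4 or more fail).
#'
#' @param sequence Nucleotide string (or vector of strings).
#' @param maxRun Longest tolerated run.
#' @return Logical vector: `TRUE` = pass.
#' @export
homopolymerFilter <- function(sequence, maxRun = 3L) {
  pat <- sprintf("A{%d}|C{%d}|G{%d}|T{%d}", maxRun + 1L, maxRun + 1L,
                 maxRun + 1L, maxRun + 1L)
  !grepl(pat, sequence)
}

#' GC content of a sequence, in percent
#'
#' @param sequence Nucleotide string (vectorized).
#' @return `100 * (#G + #C) / length`.
#' @export
gcContent <- function(sequence) {
  if (any(nchar(sequence) == 0)) stop("empty sequence", call. = FALSE)
  gc <- nchar(gsub("[^GC]", "", sequence))
  100 * gc / nchar(sequence)
}

#' Salt-adjusted melting temperature for long oligonucleotides
#'
#' `Tm = 81.5 + 16.6 log10(Na) + 0.41 GC% - 600/N` (Na in mol/L) (degrees Celsius), the
#' standard long-probe approximation; monotone increasing in GC%. At the
#' default sodium concentration of 0.165 M the GC window 50-65% maps onto roughly 77.5-83.6 C
#' for 52-mers, which makes the default GC and Tm selection windows mutually
#' consistent.
#'
#' @param sequence Nucleotide string (vectorized), at least 14 nt.
#' @param naMolar Sodium concentration in mol/L (> 0).
#' @return Melting temperature in degrees Celsius.
#' @examples
#' meltingTemp(strrep("AG", 26))  # 52-mer, GC 50% -> 77.47
#' @export
meltingTemp <- function(sequence, naMolar = 0.165) {
  if (naMolar <= 0) stop("naMolar must be positive", call. = FALSE)
  n <- nchar(sequence)
  if (any(n < 14)) stop("sequences must be at least 14 nt", call. = FALSE)
  81.5 + 16.6 * log10(naMolar) + 0.41 * gcContent(sequence) - 600 / n
}

#' GC / melting-temperature window filter
#'
#' Passes iff GC% and Tm both fall inside their inclusive windows.
#'
#' @param sequence Nucleotide string (vectorized).
#' @param gcRange,tmRange Inclusive windows.
#' @param naMolar Sodium concentration for [meltingTemp()].
#' @return Logical vector: `TRUE` = pass.
#' @export
thermoFilter <- function(sequence, gcRange = c(50, 65), tmRange = c(76, 83),
                         naMolar = 0.165) {
  if (gcRange[1] > gcRange[2] || tmRange[1] > tmRange[2])
    stop("filter ranges must be non-empty", call. = FALSE)
  gc <- gcContent(sequence)
  tm <- meltingTemp(sequence, naMolar)
  gc >= gcRange[1] & gc <= gcRange[2] & tm >= tmRange[1] & tm <= tmRange[2]
}

#' Count exact full-length occurrences of probes in a read set
#'
#' Both strands, no mismatches. Uses a constant-width dictionary match over
#' the read sequences.
#'
#' @param sequences Character vector of equal-length probe sequences.
#' @param reads A [ReadSet-class] or `DNAStringSet`.
#' @return Integer vector of occurrence counts, parallel to `sequences`.
#' @export
countProbeHits <- function(sequences, reads) {
  if (length(sequences) == 0) return(integer())
  seqs <- if (is(reads, "ReadSet")) sequencesOf(reads) else reads
  probes <- Biostrings::DNAStringSet(sequences)
  pd <- Biostrings::PDict(probes)
  fwd <- Biostrings::vcountPDict(pd, seqs, collapse = 1L)
  rev <- Biostrings::vcountPDict(pd, Biostrings::reverseComplement(seqs),
                                 collapse = 1L)
  as.integer(fwd + rev)
}

#' Deep-read validation filter
#'
#' A probe passes iff its exact sequence occurs in at least `minSupport`
#' validation reads (either strand, full length). Probes carrying sequencing
#' errors from the error-prone discovery reads are absent from an independent
#' deep read set and fail here.
#'
#' @param sequence Probe sequence(s).
#' @param validationReads Deep-coverage [ReadSet-class].
#' @param minSupport Minimum occurrence count (0 always passes).
#' @return Logical vector: `TRUE` = pass.
#' @export
validateWithDeepReads <- function(sequence, validationReads, minSupport = 2L) {
  if (minSupport <= 0L) return(rep(TRUE, length(sequence)))
  countProbeHits(sequence, validationReads) >= minSupport
}

#' Copy-number filter against target-genome reads
#'
#' A probe fails when its exact sequence occurs more than `maxHits` times
#' across the target-genome reads (multi-copy), and also when it occurs zero
#' times (absent from the target genome, so not usable as a shared marker).
#'
#' @param sequence Probe sequence(s).
#' @param targetReads [ReadSet-class] of target-genome shotgun reads.
#' @param maxHits Hit count above which a probe is called multi-copy.
#' @return Logical vector: `TRUE` = pass.
#' @export
copyNumberFilter <- function(sequence, targetReads, maxHits = 5L) {
  hits <- countProbeHits(sequence, targetReads)
  hits > 0L & hits <= maxHits
}

#' Design probes over a gene sequence
#'
#' Chooses up to `maxProbes` non-overlapping windows left to right, separated
#' by at least `spacing` bp, each passing the homopolymer and GC/Tm filters.
#'
#' @param geneSequence A nucleotide string of length >= probe length.
#' @param maxProbes Maximum number of probes.
#' @param spacing Minimum separation between chosen windows (bp).
#' @param config A [designConfig()] list.
#' @return data.frame with columns start (0-based) and sequence; zero rows
#'   when no window qualifies.
#' @export
designGeneProbes <- function(geneSequence, maxProbes = 3L, spacing = 10L,
                             config = designConfig()) {
  len <- config$probe_length
  L <- nchar(geneSequence)
  if (L < len) stop("gene shorter than the probe length", call. = FALSE)
  starts <- 0L; seqs <- character(); chosen <- integer()
  pos <- 0L
  while (pos + len <= L && length(chosen) < maxProbes) {
    win <- substring(geneSequence, pos + 1L, pos + len)
    ok <- homopolymerFilter(win, config$max_run) &&
      thermoFilter(win, config$gc_range, config$tm_range, config$na_molar)
    if (ok) {
      chosen <- c(chosen, pos)
      seqs <- c(seqs, win)
      pos <- pos + len + spacing
    } else {
      pos <- pos + 1L
    }
  }
  data.frame(start = chosen, sequence = seqs, stringsAsFactors = FALSE)
}

#' Run the full probe-design cascade
#'
#' Turns detected junctions into candidate 52-mers (junction at the window
#' midpoint), designs gene probes, and applies the filter cascade in the
#' order extraction -> homopolymer -> deep-read validation -> copy-number ->
#' GC/Tm. All filters are evaluated for every candidate (so the selected set
#' is order-independent); for accounting each rejected probe is charged to
#' its first failing filter in cascade order. Gene probes skip deep-read
#' validation (they are taken from assembled gene models, not error-prone
#' reads) and, by default, the copy-number screen.
#'
#' @param junctions data.frame from [scanReadsForJunctions()]; may have
#'   genome coordinates attached by [junctionGenomeCoords()] (carried through
#'   to the probe table for downstream truth checks).
#' @param discoveryReads [ReadSet-class] the junctions were detected in.
#' @param validationReads Deep-coverage [ReadSet-class] (may be `NULL` to
#'   skip validation).
#' @param targetReads Target-genome [ReadSet-class] (may be `NULL` to skip
#'   the copy-number screen).
#' @param genes Named `DNAStringSet` of gene sequences (or `NULL`).
#' @param config A [designConfig()] list.
#' @return A [ProbeSet-class].
#' @export
runDesignPipeline <- function(junctions, discoveryReads,
                              validationReads = NULL, targetReads = NULL,
                              genes = NULL, config = designConfig()) {
  len <- config$probe_length
  rows <- list()
  acc <- c(candidates = 0L, rejected_edge = 0L, rejected_homopolymer = 0L,
           rejected_read_validation = 0L, rejected_copy_number = 0L,
           rejected_thermo = 0L, selected = 0L)

  hasCoords <- !is.null(junctions) && nrow(junctions) > 0 &&
    all(c("chrom", "genome_position") %in% names(junctions))
  if (!is.null(junctions) && nrow(junctions) > 0) {
    readSeqs <- as.character(sequencesOf(discoveryReads))
    org <- readOrigins(discoveryReads)
    for (i in seq_len(nrow(junctions))) {
      acc[["candidates"]] <- acc[["candidates"]] + 1L
      rid <- junctions$query_id[i]
      ext <- extractProbe(readSeqs[[rid]], junctions$midpoint[i], len)
      if (is.na(ext$sequence)) {
        acc[["rejected_edge"]] <- acc[["rejected_edge"]] + 1L
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        probe_id = sprintf("rjm_%05d", length(rows) + 1L),
        probe_type = "rjm", sequence = ext$sequence, source_id = rid,
        source_start = ext$start,
        chrom = if (hasCoords) junctions$chrom[i] else NA_character_,
        position = if (hasCoords) junctions$genome_position[i] else NA_integer_,
        stringsAsFactors = FALSE)
    }
  }
  if (!is.null(genes) && length(genes) > 0) {
    gseq <- as.character(genes)
    for (g in names(gseq)) {
      des <- designGeneProbes(gseq[[g]], config$max_gene_probes,
                              config$gene_spacing, config)
      ## gene windows that reached the candidate pool already passed
      ## homopolymer+thermo by construction; still run the shared cascade
      if (nrow(des) == 0) next
      for (j in seq_len(nrow(des))) {
        acc[["candidates"]] <- acc[["candidates"]] + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          probe_id = sprintf("gene_%s_p%d", g, j), probe_type = "gene",
          sequence = des$sequence[j], source_id = g, source_start = des$start[j],
          chrom = NA_character_, position = NA_integer_,
          stringsAsFactors = FALSE)
      }
    }
  }

  if (!length(rows)) {
    probes <- data.frame(probe_id = character(), probe_type = character(),
                         sequence = character(), source_id = character(),
                         source_start = integer(), chrom = character(),
                         position = integer(), gc_percent = numeric(),
                         tm_celsius = numeric(),
                         verdict_homopolymer = character(),
                         verdict_read_validation = character(),
                         verdict_copy_number = character(),
                         verdict_thermo = character(), selected = logical(),
                         stringsAsFactors = FALSE)
    return(new("ProbeSet", probes = probes, accounting = acc))
  }

  probes <- do.call(rbind, rows)
  probes$gc_percent <- gcContent(probes$sequence)
  probes$tm_celsius <- meltingTemp(probes$sequence, config$na_molar)

  verdict <- function(x) ifelse(x, "pass", "fail")
  probes$verdict_homopolymer <-
    verdict(homopolymerFilter(probes$sequence, config$max_run))

  isGene <- probes$probe_type == "gene"
  probes$verdict_read_validation <- "not_run"
  if (!is.null(validationReads) && any(!isGene)) {
    probes$verdict_read_validation[!isGene] <- verdict(
      validateWithDeepReads(probes$sequence[!isGene], validationReads,
                            config$min_support))
  }
  probes$verdict_copy_number <- "not_run"
  runCN <- if (config$gene_skip_copy_number) !isGene else rep(TRUE, nrow(probes))
  if (!is.null(targetReads) && any(runCN)) {
    probes$verdict_copy_number[runCN] <- verdict(
      copyNumberFilter(probes$sequence[runCN], targetReads, config$max_hits))
  }
  probes$verdict_thermo <- verdict(
    thermoFilter(probes$sequence, config$gc_range, config$tm_range,
                 config$na_molar))

  vm <- cbind(probes$verdict_homopolymer, probes$verdict_read_validation,
              probes$verdict_copy_number, probes$verdict_thermo)
  probes$selected <- apply(vm, 1, function(v) all(v != "fail"))

  ## first-failing-filter attribution, cascade order
  firstFail <- apply(vm, 1, function(v) {
    w <- which(v == "fail")
    if (length(w)) w[1] else 0L
  })
  counts <- tabulate(firstFail, nbins = 4L)
  acc[["rejected_homopolymer"]] <- counts[1]
  acc[["rejected_read_validation"]] <- counts[2]
  acc[["rejected_copy_number"]] <- counts[3]
  acc[["rejected_thermo"]] <- counts[4]
  acc[["selected"]] <- sum(probes$selected)
  rownames(probes) <- NULL
  new("ProbeSet", probes = probes, accounting = acc)
}
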