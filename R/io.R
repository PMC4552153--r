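## Readers and writers for the package's interchange formats: FASTA/FASTQ
## (Biostrings), TSV tables with explicit schemas, and BED exports
## (rtracklayer). All genomic coordinates in TSVs are 0-based half-open;
## BED files follow the BED convention.

#' Read a FASTA file of nucleotide sequences
#'
#' Lowercase bases are normalized to uppercase on read.
#'
#' @param path FASTA file.
#' @return Named [Biostrings::DNAStringSet].
#' @export
readFastaFile <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  ids <- sub("\\s.*$", "", names(x))
  out <- Biostrings::DNAStringSet(toupper(as.character(x)))
  names(out) <- ids
  out
}

#' Write sequences to FASTA (80-column wrapped)
#'
#' @param x Named `DNAStringSet` or character vector.
#' @param path Output path.
#' @export
writeFastaFile <- function(x, path) {
  if (!is(x, "DNAStringSet")) x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(x, path, format = "fasta", width = 80L)
  invisible(path)
}

#' Read / write a repeat library FASTA
#'
#' The element class is carried in the description line as
#' `class=retrotransposon` or `class=dna_transposon`.
#'
#' @param path FASTA path.
#' @return A [RepeatLibrary-class].
#' @export
readRepeatLibraryFasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  desc <- names(x)
  ids <- sub("\\s.*$", "", desc)
  m <- regmatches(desc, regexpr("class=[A-Za-z_]+", desc))
  if (length(m) != length(desc))
    stop("every repeat library record needs a 'class=' tag", call. = FALSE)
  cls <- sub("class=", "", m)
  seqs <- Biostrings::DNAStringSet(toupper(as.character(x)))
  names(seqs) <- ids
  new("RepeatLibrary", sequences = seqs, repeatClass = cls)
}

#' @rdname readRepeatLibraryFasta
#' @param library A [RepeatLibrary-class].
#' @export
writeRepeatLibraryFasta <- function(library, path) {
  seqs <- sequencesOf(library)
  out <- seqs
  names(out) <- paste0(names(seqs), " class=", repeatClass(library))
  Biostrings::writeXStringSet(out, path, format = "fasta", width = 80L)
  invisible(path)
}

#' Write simulated reads as FASTQ with uniform dummy qualities
#'
#' @param reads A [ReadSet-class].
#' @param path Output path.
#' @export
writeReadsFastq <- function(reads, path) {
  seqs <- sequencesOf(reads)
  quals <- Biostrings::BStringSet(strrep("I", Biostrings::width(seqs)))
  Biostrings::writeXStringSet(seqs, path, format = "fastq", qualities = quals)
  invisible(path)
}

## ---- TSV tables ----

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a line panel TSV
#'
#' Columns: name, kind, chromosome, arm, breakpoint_fl.
#'
#' @param path TSV path.
#' @return A [LinePanel-class].
#' @export
readLinePanelTsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  .checkColumns(df, c("name", "kind", "chromosome", "arm", "breakpoint_fl"),
                "line panel")
  for (col in c("chromosome", "arm")) df[[col]][is.na(df[[col]])] <- ""
  new("LinePanel", lines = df)
}

#' @rdname readLinePanelTsv
#' @param panel A [LinePanel-class].
#' @export
writeLinePanelTsv <- function(panel, path) .writeTsv(panelLines(panel), path)

#' Read / write a signal matrix TSV
#'
#' First column `probe_id`; remaining columns are named
#' `<line>.a<arrayRep>.s<spotRep>.<channel>` (line names must not contain
#' dots).
#'
#' @param path TSV path.
#' @return A [SignalMatrix-class].
#' @export
readSignalMatrixTsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  .checkColumns(df, "probe_id", "signal matrix")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$probe_id
  parts <- strsplit(colnames(m), ".", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) != 4L
  if (any(bad))
    stop(sprintf("malformed signal column name '%s'", colnames(m)[bad][1]),
         call. = FALSE)
  info <- data.frame(
    line = vapply(parts, `[`, "", 1L),
    array_rep = as.integer(sub("^a", "", vapply(parts, `[`, "", 2L))),
    spot_rep = as.integer(sub("^s", "", vapply(parts, `[`, "", 3L))),
    channel = vapply(parts, `[`, "", 4L), stringsAsFactors = FALSE)
  SignalMatrix(m, info)
}

#' @rdname readSignalMatrixTsv
#' @param se A [SignalMatrix-class].
#' @export
writeSignalMatrixTsv <- function(se, path) {
  info <- as.data.frame(SummarizedExperiment::colData(se))
  if (any(grepl(".", info$line, fixed = TRUE)))
    stop("line names must not contain '.' in the TSV encoding", call. = FALSE)
  m <- SummarizedExperiment::assay(se, "intensity")
  df <- data.frame(probe_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[-1] <- paste(info$line, paste0("a", info$array_rep),
                            paste0("s", info$spot_rep), info$channel, sep = ".")
  .writeTsv(df, path)
}

#' Read / write probe tables, assignments and genetic maps
#'
#' Thin schema-validated TSV round-trips for the pipeline's tabular outputs.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
readGeneticMapTsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  .checkColumns(df, c("marker_id", "chromosome", "position_cm"), "genetic map")
  df
}

#' @rdname readGeneticMapTsv
#' @param geneticMap data.frame: marker_id, chromosome, position_cm.
#' @export
writeGeneticMapTsv <- function(geneticMap, path) {
  .checkColumns(geneticMap, c("marker_id", "chromosome", "position_cm"),
                "genetic map")
  .writeTsv(geneticMap, path)
}

#' @rdname readGeneticMapTsv
#' @export
readAssignmentsTsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  .checkColumns(df, c("probe_id", "chromosome", "bin", "stringency_level"),
                "assignments")
  df
}

#' @rdname readGeneticMapTsv
#' @param assignments data.frame from [stringencyLadder()].
#' @export
writeAssignmentsTsv <- function(assignments, path) {
  .checkColumns(assignments, c("probe_id", "chromosome", "bin",
                               "stringency_level"), "assignments")
  .writeTsv(assignments, path)
}

#' @rdname readGeneticMapTsv
#' @param probeSet A [ProbeSet-class].
#' @export
writeProbeTableTsv <- function(probeSet, path) {
  .writeTsv(probeTable(probeSet), path)
}

#' @rdname readGeneticMapTsv
#' @export
readProbeTableTsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  .checkColumns(df, c("probe_id", "probe_type", "sequence", "selected"),
                "probe table")
  df
}

## ---- BED exports ----

#' Export truth junctions as BED
#'
#' A junction at 0-based boundary position p is written as the 2-bp interval
#' `[p-1, p+1)` flanking the boundary.
#'
#' @param genome A [GenomeModel-class].
#' @param path Output BED path.
#' @export
exportJunctionsBed <- function(genome, path) {
  jt <- junctionTruth(genome)
  gr <- GenomicRanges::GRanges(
    seqnames = jt$chrom,
    ranges = IRanges::IRanges(start = jt$position, end = jt$position + 1L),
    name = paste(jt$left_class, jt$right_class, sep = "|"))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Export TE insertions as BED
#'
#' @param genome A [GenomeModel-class].
#' @param path Output BED path.
#' @export
exportInsertionsBed <- function(genome, path) {
  te <- teInsertions(genome)
  gr <- GenomicRanges::GRanges(
    seqnames = te$chrom,
    ranges = IRanges::IRanges(start = te$start + 1L, end = te$end),
    name = te$element_id, strand = te$strand)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
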