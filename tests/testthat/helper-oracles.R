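## Independent oracles and shared fixtures. Oracles deliberately avoid the
## code paths they check: plain-R scanning instead of the k-mer index, base-R
## string matching instead of Biostrings dictionaries.

revcomp <- function(x) {
  vapply(x, function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))),
    character(1), USE.NAMES = FALSE)
}

randomSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = "")

## Brute-force exact-match oracle: every maximal identical run of length
## >= minMatchLen on every (element, strand, diagonal), by direct scan.
bruteMatches <- function(query, library, minMatchLen) {
  q <- strsplit(query, "", fixed = TRUE)[[1]]
  seqs <- as.character(sequencesOf(library))
  out <- list()
  for (id in names(seqs)) {
    for (strand in c("+", "-")) {
      s <- if (strand == "+") seqs[[id]] else revcomp(seqs[[id]])
      e <- strsplit(s, "", fixed = TRUE)[[1]]
      for (d in seq(-(length(e) - minMatchLen), length(q) - minMatchLen)) {
        qs <- max(0L, d); qe <- min(length(q), d + length(e))
        if (qe - qs < minMatchLen) next
        qi <- (qs + 1L):qe
        m <- q[qi] == e[qi - d]
        r <- rle(m)
        ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
        for (i in which(r$values & r$lengths >= minMatchLen)) {
          out[[length(out) + 1L]] <- data.frame(
            query_start = qs + starts[i] - 1L, query_end = qs + ends[i],
            element_id = id, strand = strand, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out))
    return(data.frame(query_start = integer(), query_end = integer(),
                      element_id = character(), strand = character(),
                      stringsAsFactors = FALSE))
  res <- unique(do.call(rbind, out))
  res <- res[order(res$query_start, res$query_end, res$element_id, res$strand), ]
  rownames(res) <- NULL
  res
}

## Base-R occurrence counting of an exact pattern across reads, both strands.
bruteOccurrences <- function(pattern, readStrings) {
  countIn <- function(pat, s) {
    n <- 0L; from <- 1L
    repeat {
      i <- regexpr(pat, substring(s, from), fixed = TRUE)
      if (i < 0) break
      n <- n + 1L
      from <- from + i
    }
    n
  }
  pats <- c(pattern, revcomp(pattern))
  if (pats[2] == pats[1]) pats <- pats[1]
  sum(vapply(readStrings, function(s)
    sum(vapply(pats, countIn, integer(1), s = s)), integer(1)))
}

## Genome copy count of a 52-mer (both strands), via Biostrings pattern
## matching on the chromosome sequences (not the read-based filter path).
genomeCopies <- function(sequence, genome) {
  gseq <- chromSequences(genome)
  fwd <- sum(Biostrings::vcountPattern(sequence, gseq))
  rc <- revcomp(sequence)
  bwd <- if (rc == sequence) 0L else sum(Biostrings::vcountPattern(rc, gseq))
  fwd + bwd
}

## A bare GenomeModel around hand-built chromosome strings (no insertions).
manualGenome <- function(seqs, armFraction = 0.5) {
  dss <- Biostrings::DNAStringSet(seqs)
  af <- rep_len(armFraction, length(dss))
  names(af) <- names(dss)
  new("GenomeModel", sequences = dss, armFraction = af,
      teInsertions = data.frame(), genes = data.frame(),
      junctionTruth = data.frame())
}

## A LinePanel straight from a definition data.frame.
manualPanel <- function(df) new("LinePanel", lines = df)

## ---- shared small end-to-end fixture (built once per test run) ----
.fixtureCache <- new.env(parent = emptyenv())

designFixture <- function() {
  if (!is.null(.fixtureCache$design)) return(.fixtureCache$design)
  lib <- buildRepeatLibrary(3, 2, c(800, 1500), seed = 7)
  gm <- simulateGenome(
    lib, data.frame(name = c("1D", "2D"), length = c(8e4, 8e4),
                    arm_fraction = c(0.4, 0.5)),
    teCount = 16, nestingProb = 0.15, geneCount = 6, geneLength = 1000,
    seed = 11)
  disc <- simulateReads(gm, coverage = 1, readLength = 400,
                        substitutionRate = 0.005, seed = 3)
  valid <- simulateReads(gm, coverage = 30, readLength = 150, seed = 4)
  targ <- simulateReads(gm, coverage = 5, readLength = 150, seed = 5)
  js <- junctionGenomeCoords(scanReadsForJunctions(disc, lib), disc)
  ps <- runDesignPipeline(js, disc, valid, targ, geneSequences(gm))
  .fixtureCache$design <- list(lib = lib, genome = gm, discovery = disc,
                               validation = valid, target = targ,
                               junctions = js, probes = ps)
  .fixtureCache$design
}

## The recovery fixture at the documented study scale: 5 chromosomes x 1 Mb,
## 300 insertions, 2000 probe loci, nulli panel + 12 deletion lines.
recoveryFixture <- function() {
  if (!is.null(.fixtureCache$recovery)) return(.fixtureCache$recovery)
  lib <- buildRepeatLibrary(6, 3, c(1000, 3000), seed = 7)
  gm <- simulateGenome(
    lib, data.frame(name = paste0(1:5, "D"), length = 1e6,
                    arm_fraction = c(0.45, 0.4, 0.5, 0.35, 0.45)),
    teCount = 300, nestingProb = 0.1, geneCount = 40, seed = 11)
  dels <- list(`1D` = list(L = c(0.3, 0.6), S = 0.5),
               `2D` = list(L = c(0.4, 0.7)),
               `3D` = list(S = 0.4, L = 0.5),
               `4D` = list(L = c(0.25, 0.55, 0.8)),
               `5D` = list(S = 0.6, L = 0.45))
  panel <- buildLinePanel(gm, dels)
  loci <- withr::with_seed(42, {
    lens <- chromLengths(gm)
    ch <- sample(names(lens), 2000, replace = TRUE, prob = lens)
    pos <- vapply(lens[ch], function(L) sample.int(L, 1) - 1L, integer(1))
    data.frame(probe_id = sprintf("p%04d", 1:2000), chrom = ch,
               position = pos, probe_type = "rjm", stringsAsFactors = FALSE)
  })
  .fixtureCache$recovery <- list(
    lib = lib, genome = gm, panel = panel, loci = loci,
    truthBin = truthBinLabel(gm, panel, loci$chrom, loci$position))
  .fixtureCache$recovery
}
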