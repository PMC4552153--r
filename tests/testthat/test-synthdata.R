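test_that("repeat library respects counts, classes and determinism", {
  expect_equal(length(buildRepeatLibrary(0, 0, c(100, 200), seed = 1)), 0L)

  lib <- buildRepeatLibrary(3, 2, c(100, 200), seed = 7)
  expect_equal(length(lib), 5L)
  expect_equal(as.vector(table(repeatClass(lib))[c("retrotransposon", "dna_transposon")]),
               c(3L, 2L))
  w <- Biostrings::width(sequencesOf(lib))
  expect_true(all(w >= 100 & w <= 200))

  lib2 <- buildRepeatLibrary(3, 2, c(100, 200), seed = 7)
  expect_identical(as.character(sequencesOf(lib)), as.character(sequencesOf(lib2)))

  expect_error(buildRepeatLibrary(1, 1, c(-5, 10)), "positive")
  expect_error(buildRepeatLibrary(1, 1, c(10, 20)), "at least 50")
})

test_that("genome simulation enumerates junction truth by construction", {
  lib <- buildRepeatLibrary(1, 1, c(300, 400), seed = 2)
  spec1 <- data.frame(name = "1D", length = 2e4, arm_fraction = 0.5)

  gm0 <- simulateGenome(lib, spec1, teCount = 0, seed = 3)
  expect_equal(nrow(junctionTruth(gm0)), 0L)

  gm1 <- simulateGenome(lib, spec1, teCount = 1, nestingProb = 0, seed = 3)
  jt1 <- junctionTruth(gm1)
  expect_equal(nrow(jt1), 2L)
  expect_true(all(apply(jt1[, c("left_class", "right_class")], 1,
                        function(r) sum(r == "unknown") == 1L)))

  ## nesting with probability 1: the second insertion splits the first, so a
  ## pair of insertions yields 4 junctions, 2 of them element-element; with
  ## one element per class the pair is a dna/retro (or retro/dna) boundary
  found <- FALSE
  for (s in 1:20) {
    g2 <- simulateGenome(lib, spec1, teCount = 2, nestingProb = 1, seed = s)
    jt <- junctionTruth(g2)
    ee <- jt[jt$left_class != "unknown" & jt$right_class != "unknown", ]
    expect_equal(nrow(jt), 4L)
    expect_equal(nrow(ee), 2L)
    mixed <- apply(ee[, c("left_class", "right_class")], 1,
                   function(r) setequal(r, c("dna_transposon", "retrotransposon")))
    if (all(mixed)) { found <- TRUE; break }
  }
  expect_true(found)  # a cross-class nested pair occurs within 20 seeds

  ## every insertion adds exactly two boundaries
  gm <- simulateGenome(lib, spec1, teCount = 8, nestingProb = 0.3, seed = 9)
  expect_equal(nrow(junctionTruth(gm)), 16L)
  ## truth positions strictly inside the chromosome, and validity holds
  expect_true(validObject(gm))
})

test_that("genome simulation places genes in TE-free intervals", {
  lib <- buildRepeatLibrary(2, 1, c(300, 500), seed = 1)
  gm <- simulateGenome(lib, data.frame(name = "1D", length = 3e4,
                                       arm_fraction = 0.5),
                       teCount = 10, nestingProb = 0.2, geneCount = 4,
                       geneLength = 800, seed = 6)
  g <- geneAnnotation(gm)
  te <- teInsertions(gm)
  expect_equal(nrow(g), 4L)
  for (i in seq_len(nrow(g))) {
    overl <- te$chrom == g$chrom[i] & te$start < g$end[i] & te$end > g$start[i]
    expect_false(any(overl))
  }
  expect_equal(unname(Biostrings::width(geneSequences(gm))), rep(800L, 4))
})

test_that("read simulation respects the coverage arithmetic and error model", {
  lib <- buildRepeatLibrary(1, 0, c(300, 400), seed = 1)
  gm <- simulateGenome(lib, data.frame(name = c("a", "b"),
                                       length = c(6e4, 4e4),
                                       arm_fraction = 0.5),
                       teCount = 0, seed = 2)
  rs <- simulateReads(gm, coverage = 1, readLength = 500, seed = 4)
  expect_equal(length(rs), 200L)  # 1 x 100 kb / 500

  ## error-free reads equal their origin substring (or its reverse complement)
  org <- readOrigins(rs)
  chromStr <- as.character(chromSequences(gm))
  for (i in sample.int(length(rs), 20)) {
    ref <- substring(chromStr[[org$chrom[i]]], org$start[i] + 1L,
                     org$start[i] + 500L)
    got <- as.character(sequencesOf(rs)[[i]])
    expect_identical(got, if (org$strand[i] == "+") ref else revcomp(ref))
  }

  ## coverage ratio 30 : 5 = 6 : 1 up to rounding
  n30 <- length(simulateReads(gm, 30, 500, seed = 5))
  n5 <- length(simulateReads(gm, 5, 500, seed = 5))
  expect_equal(n30 / n5, 6, tolerance = 0.01)

  ## substitutions hit roughly the requested rate
  rsE <- simulateReads(gm, coverage = 2, readLength = 500,
                       substitutionRate = 0.01, seed = 6)
  orgE <- readOrigins(rsE)
  mm <- vapply(seq_len(50), function(i) {
    ref <- substring(chromStr[[orgE$chrom[i]]], orgE$start[i] + 1L,
                     orgE$start[i] + 500L)
    if (orgE$strand[i] == "-") ref <- revcomp(ref)
    got <- as.character(sequencesOf(rsE)[[i]])
    sum(strsplit(ref, "")[[1]] != strsplit(got, "")[[1]])
  }, numeric(1))
  expect_gt(mean(mm) / 500, 0.005)
  expect_lt(mean(mm) / 500, 0.02)

  expect_error(simulateReads(gm, coverage = 0, readLength = 100), "positive")
  expect_error(simulateReads(gm, coverage = 1, readLength = 50000), "shorter")

  ## determinism
  r1 <- simulateReads(gm, 1, 500, 0.01, seed = 8)
  r2 <- simulateReads(gm, 1, 500, 0.01, seed = 8)
  expect_identical(as.character(sequencesOf(r1)), as.character(sequencesOf(r2)))
})

test_that("line panels enumerate control, nulli and deletion lines", {
  lib <- buildRepeatLibrary(1, 0, c(300, 400), seed = 1)
  gm <- simulateGenome(lib, data.frame(name = c("1D", "2D"),
                                       length = c(2e4, 2e4),
                                       arm_fraction = c(0.45, 0.5)),
                       teCount = 0, seed = 2)
  expect_equal(nrow(panelLines(buildLinePanel(gm))), 3L)  # control + 2 nulli

  panel <- buildLinePanel(gm, list(`1D` = list(L = c(0.18, 0.41))))
  expect_equal(nrow(panelLines(panel)), 5L)

  expect_error(buildLinePanel(gm, list(`1D` = list(L = c(0.3, 0.3)))),
               "duplicate")
  expect_error(buildLinePanel(gm, list(`1D` = list(L = c(0.5, 0.2)))),
               "increasing")

  ## copy number: locus at 1DL FL 0.30 is lost in the 0.18 line (distal to
  ## its breakpoint) and retained in the 0.41 line
  L <- chromLengths(gm)[["1D"]]
  cent <- round(0.45 * L)
  pos <- cent + round(0.30 * (L - cent))  # FL ~0.30 on 1DL
  expect_equal(locusCopyNumber(gm, panel, "1DL_b18", "1D", pos), 0L)
  expect_equal(locusCopyNumber(gm, panel, "1DL_b41", "1D", pos), 1L)
  expect_equal(locusCopyNumber(gm, panel, "control", "1D", pos), 1L)
  ## nulli zeroes exactly its own chromosome
  expect_equal(locusCopyNumber(gm, panel, "N1D", "1D", pos), 0L)
  expect_equal(locusCopyNumber(gm, panel, "N2D", "1D", pos), 1L)
})

test_that("copy numbers stay within one of the control for every line", {
  fx <- recoveryFixture()
  ln <- panelLines(fx$panel)
  sub <- fx$loci[1:200, ]
  for (nm in ln$name) {
    cp <- locusCopyNumber(fx$genome, fx$panel, nm, sub$chrom, sub$position)
    expect_true(all(cp %in% c(0L, 1L)))
  }
  ## a nulli line zeroes exactly the loci of its chromosome
  cp <- locusCopyNumber(fx$genome, fx$panel, "N3D", sub$chrom, sub$position)
  expect_identical(cp == 0L, sub$chrom == "3D")
})

test_that("hybridization signals follow the dosage model exactly at zero noise", {
  lib <- buildRepeatLibrary(1, 0, c(300, 400), seed = 1)
  gm <- simulateGenome(lib, data.frame(name = c("1D", "3D"),
                                       length = c(2e4, 2e4),
                                       arm_fraction = 0.5),
                       teCount = 0, seed = 2)
  panel <- buildLinePanel(gm)
  loci <- data.frame(probe_id = c("r1", "g1"), chrom = "3D",
                     position = c(5000L, 15000L),
                     probe_type = c("rjm", "gene"), stringsAsFactors = FALSE)
  model <- signalModel(lognormalSd = 0, dropoutRate = 0, crossHyb = 0.25,
                       seed = 5)
  se <- simulateHybridization(panel, loci, gm, model)
  m <- SummarizedExperiment::assay(se, "intensity")
  info <- as.data.frame(SummarizedExperiment::colData(se))

  ratio <- function(probe, line) {
    t <- m[probe, info$line == line & info$channel == "test"]
    r <- m[probe, info$line == line & info$channel == "reference"]
    mean(t) / mean(r)
  }
  ## control line: ratio exactly 1 for every probe
  expect_equal(ratio("r1", "control"), 1)
  expect_equal(ratio("g1", "control"), 1)
  ## rjm probe on 3D: full loss in nulli-3D, none in nulli-1D
  expect_equal(1 - ratio("r1", "N3D"), 1)
  expect_equal(1 - ratio("r1", "N1D"), 0)
  ## gene probe retains the homoeologous background at copy 0
  expect_equal(1 - ratio("g1", "N3D"), 0.75)

  ## determinism of the full matrix
  se2 <- simulateHybridization(panel, loci, gm, model)
  expect_identical(m, SummarizedExperiment::assay(se2, "intensity"))

  ## replication structure: both channels for every (line, array, spot)
  expect_true(validObject(se))
  expect_equal(sum(info$channel == "test"), sum(info$channel == "reference"))

  ## consistency error for coordinate-free probes
  bad <- data.frame(probe_id = "x", chrom = "3D", position = NA_integer_,
                    probe_type = "rjm")
  expect_error(simulateHybridization(panel, bad, gm, model), "truth coordinate")
})
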