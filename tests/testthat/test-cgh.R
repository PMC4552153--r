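## A minimal panel for the assignment-rule tests: control, 2 nulli lines,
## deletion lines on 1DL (0.18, 0.41) and 1DS (0.5).
toyPanelDF <- function() data.frame(
  name = c("control", "N1D", "N2D", "1DL_b18", "1DL_b41", "1DS_b50"),
  kind = c("control", "nulli_tetrasomic", "nulli_tetrasomic",
           "deletion", "deletion", "deletion"),
  chromosome = c("", "1D", "2D", "1D", "1D", "1D"),
  arm = c("", "", "", "L", "L", "S"),
  breakpoint_fl = c(NA, NA, NA, 0.18, 0.41, 0.5),
  stringsAsFactors = FALSE)

## Hand-built loss table: one row per (probe, line).
toyLossTab <- function(losses, p = 1e-6) {
  do.call(rbind, lapply(names(losses), function(pid) {
    data.frame(probe_id = pid, line = names(losses[[pid]]),
               loss_fraction = unlist(losses[[pid]]), p_value = p,
               stringsAsFactors = FALSE)
  }))
}

test_that("quantile normalization equalizes column distributions", {
  ## identical columns are left untouched
  x <- cbind(a = c(3, 1, 2), b = c(3, 1, 2))
  expect_equal(quantileNormalize(x), x)

  ## hand-computed rank means
  expect_equal(unname(quantileNormalize(cbind(c(1, 2, 3), c(2, 4, 6)))),
               cbind(c(1.5, 3, 4.5), c(1.5, 3, 4.5)))

  ## ties receive the mean of their tied rank values
  got <- quantileNormalize(cbind(A = c(1, 1, 2), B = c(1, 2, 3)))
  expect_equal(unname(got), cbind(c(1.25, 1.25, 2.5), c(1, 1.5, 2.5)))

  ## property: all sorted columns identical after normalization
  withr::with_seed(41, {
    m <- matrix(rexp(600), ncol = 6)
    qn <- quantileNormalize(m)
    s <- apply(qn, 2, sort)
    expect_true(all(abs(s - s[, 1]) < 1e-9))
  })

  expect_error(quantileNormalize(matrix(1:3, ncol = 1)), "two columns")
  expect_error(quantileNormalize(cbind(c(-1, 2), c(1, 2))), "negative")

  ## median scaling alternative equalizes column medians
  ms <- quantileNormalize(cbind(c(1, 2, 3), c(2, 4, 6)), method = "median")
  expect_equal(apply(ms, 2, median), rep(mean(c(2, 4)), 2))
})

test_that("replicate averaging masks missing spots", {
  info <- data.frame(line = "l", array_rep = rep(1:2, each = 3),
                     spot_rep = rep(1:3, 2), channel = "test")
  m <- matrix(5, nrow = 2, ncol = 6,
              dimnames = list(c("p1", "p2"), NULL))
  av <- averageReplicates(m, info)
  expect_true(all(av$mean_intensity == 5))

  m2 <- rbind(p1 = c(1, 2, 3, 4, 5, 6), p2 = c(2, NA, 4, 1, 1, 1))
  av2 <- averageReplicates(m2, info)
  a1 <- av2[av2$array_rep == 1, ]
  expect_equal(a1$mean_intensity[a1$probe_id == "p1"], 2)
  expect_equal(a1$mean_intensity[a1$probe_id == "p2"], 3)  # NA masked
  a2 <- av2[av2$array_rep == 2, ]
  expect_equal(a2$mean_intensity[a2$probe_id == "p1"], 5)
  expect_equal(a2$mean_intensity[a2$probe_id == "p2"], 1)
})

test_that("the loss test matches a pooled-variance Student t-test", {
  ## equal samples: loss 0, not flagged
  r <- lossTest(c(1, 1.1, 0.9), c(1, 1.1, 0.9))
  expect_equal(r$loss_fraction, 0)
  expect_false(r$flagged)

  ## halved signal with negligible variance: loss 0.5, p ~ 0
  r <- lossTest(c(0.5, 0.501, 0.499, 0.5), c(1, 1.001, 0.999, 1),
                threshold = 0.5)
  expect_equal(r$loss_fraction, 0.5, tolerance = 1e-3)
  expect_lt(r$p_value, 1e-6)
  expect_true(r$flagged)

  ## degenerate zero-variance case: p = 0 when means differ, 1 when equal
  expect_equal(lossTest(c(1, 1), c(2, 2))$p_value, 0)
  expect_equal(lossTest(c(2, 2), c(2, 2))$p_value, 1)

  ## high-variance toy: loss over threshold but insignificant
  r <- lossTest(c(0.2, 1.3), c(1, 1))
  expect_equal(r$loss_fraction, 0.25)
  expect_gt(r$p_value, 0.3)
  expect_false(r$flagged)

  ## cross-check p-values against stats::t.test on random toys
  withr::with_seed(42, {
    for (i in 1:10) {
      x <- rnorm(6, 1, 0.2); y <- rnorm(6, 0.8, 0.2)
      expect_equal(lossTest(x, y)$p_value,
                   t.test(x, y, var.equal = TRUE)$p.value, tolerance = 1e-12)
    }
  })

  expect_error(lossTest(c(1, 1), c(0, 0)), "zero reference")
  expect_error(lossTest(1, c(1, 2)), "two replicate")
})

test_that("chromosome assignment needs exactly one flagged nulli line", {
  flags <- c(`1D` = FALSE, `2D` = FALSE, `3D` = TRUE, `4D` = FALSE,
             `5D` = FALSE, `6D` = FALSE, `7D` = FALSE)
  expect_identical(assignChromosome(flags), "3D")
  flags["5D"] <- TRUE
  expect_identical(assignChromosome(flags), "unassigned")
  expect_identical(assignChromosome(flags & FALSE), "unassigned")
})

test_that("bin assignment decodes prefix flag patterns", {
  arm <- c("L", "L"); bp <- c(0.18, 0.41)
  expect_identical(assignBin(c(TRUE, TRUE), arm, bp, "1D"), "1DL-0.41-1.00")
  expect_identical(assignBin(c(TRUE, FALSE), arm, bp, "1D"), "1DL-0.18-0.41")
  expect_identical(assignBin(c(FALSE, TRUE), arm, bp, "1D"), "unassigned")
  expect_identical(assignBin(c(FALSE, FALSE), arm, bp, "1D"),
                   "pericentromeric-inferred")
  ## cross-arm flags are impossible for a single locus
  expect_identical(assignBin(c(TRUE, TRUE, TRUE), c("L", "L", "S"),
                             c(0.18, 0.41, 0.5), "1D"), "unassigned")
})

test_that("the stringency ladder fixes the first clean level", {
  panel <- manualPanel(toyPanelDF())

  ## 60% loss in exactly one nulli line: assigned at the strictest level
  lt <- toyLossTab(list(p1 = c(N1D = 0.6, N2D = 0.0, `1DL_b18` = 0.6,
                               `1DL_b41` = 0.6, `1DS_b50` = 0.0)))
  a <- stringencyLadder(lt, panel)
  expect_identical(a$chromosome, "1D")
  expect_equal(a$stringency_level, 0.5)
  expect_identical(a$bin, "1DL-0.41-1.00")

  ## 25% loss: only the final level catches it
  lt <- toyLossTab(list(p1 = c(N1D = 0.25, N2D = 0.0, `1DL_b18` = 0.25,
                               `1DL_b41` = 0.0, `1DS_b50` = 0.0)))
  a <- stringencyLadder(lt, panel)
  expect_equal(a$stringency_level, 0.2)
  expect_identical(a$bin, "1DL-0.18-0.41")

  ## ambiguous at every level: unassigned
  lt <- toyLossTab(list(p1 = c(N1D = 0.25, N2D = 0.25, `1DL_b18` = 0,
                               `1DL_b41` = 0, `1DS_b50` = 0)))
  a <- stringencyLadder(lt, panel)
  expect_identical(a$chromosome, "unassigned")
  expect_true(is.na(a$stringency_level))

  ## flagged in no nulli line but some deletion line: unassigned
  lt <- toyLossTab(list(p1 = c(N1D = 0.0, N2D = 0.0, `1DL_b18` = 0.6,
                               `1DL_b41` = 0, `1DS_b50` = 0)))
  expect_identical(stringencyLadder(lt, panel)$chromosome, "unassigned")

  expect_error(stringencyLadder(lt, panel, thresholds = c(0.2, 0.5)),
               "decreasing")
})

test_that("flagged sets are nested across the threshold ladder", {
  fx <- recoveryFixture()
  se <- simulateHybridization(fx$panel, fx$loci[1:300, ], fx$genome,
                              signalModel(seed = 77))
  lt <- cghAssign(se, fx$panel)$lossTab
  flagsAt <- function(t) which(!is.na(lt$p_value) & lt$loss_fraction >= t &
                                 lt$p_value < 0.05)
  f5 <- flagsAt(0.5); f4 <- flagsAt(0.4); f3 <- flagsAt(0.3); f2 <- flagsAt(0.2)
  expect_true(all(f5 %in% f4))
  expect_true(all(f4 %in% f3))
  expect_true(all(f3 %in% f2))
  ## raising stringency never gains assignments
  aStrict <- stringencyLadder(lt, fx$panel, thresholds = 0.5)
  aLoose <- stringencyLadder(lt, fx$panel, thresholds = c(0.5, 0.4, 0.3, 0.2))
  gained <- aStrict$chromosome != "unassigned"
  expect_true(all(aLoose$chromosome[gained] != "unassigned"))
})

test_that("the genome-specificity screen keeps only strong-loss probes", {
  lib <- buildRepeatLibrary(1, 0, c(300, 400), seed = 1)
  gm <- simulateGenome(lib, data.frame(name = "1D", length = 2e4,
                                       arm_fraction = 0.5),
                       teCount = 0, seed = 2)
  panel <- buildLinePanel(gm, altGenome = TRUE)
  loci <- data.frame(probe_id = c("rjm1", "gene1"), chrom = "1D",
                     position = c(4000L, 12000L),
                     probe_type = c("rjm", "gene"), stringsAsFactors = FALSE)
  ## strong homoeologous background: the gene probe loses only ~10%
  se <- simulateHybridization(panel, loci, gm,
                              signalModel(lognormalSd = 0.02, dropoutRate = 0,
                                          crossHyb = 0.9, seed = 3))
  out <- cghAssign(se, panel)
  keep <- screenGenomeSpecific(out$lossTab)
  expect_true(keep[["rjm1"]])    # loss ~1.0
  expect_false(keep[["gene1"]])  # loss ~0.1 < 0.2

  ## identical signals are never kept
  lt <- data.frame(probe_id = "p", line = "AABB", loss_fraction = 0,
                   p_value = 1)
  expect_false(screenGenomeSpecific(lt)[["p"]])
  expect_error(screenGenomeSpecific(lt, altLine = "missing"), "absent")
})

test_that("concordance compares jointly assigned probes", {
  a <- data.frame(probe_id = c("p1", "p2", "p3", "p4"),
                  chromosome = c("1D", "2D", "3D", "unassigned"))
  b <- data.frame(probe_id = c("p1", "p2", "p3", "p4"),
                  chromosome = c("1D", "3D", "3D", "1D"))
  r <- concordance(a, b, "chromosome")
  expect_equal(r$n_compared, 3L)
  expect_equal(r$n_agree, 2L)
  expect_equal(r$percent, 100 * 2 / 3)

  r <- concordance(a, a, "chromosome")
  expect_equal(r$percent, 100)

  empty <- data.frame(probe_id = "q", chromosome = "unassigned")
  expect_true(is.na(concordance(a, empty, "chromosome")$percent))
})

test_that("zero-noise assignment recovers truth on a small end-to-end run", {
  fx <- recoveryFixture()
  sub <- fx$loci[1:250, ]
  se <- simulateHybridization(fx$panel, sub, fx$genome,
                              signalModel(lognormalSd = 0, dropoutRate = 0,
                                          seed = 9))
  a <- cghAssign(se, fx$panel)$assignments
  expect_identical(a$chromosome, sub$chrom)
  expect_identical(a$bin, fx$truthBin[1:250])
})
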