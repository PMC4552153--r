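test_that("probe extraction centres the junction and rejects edge windows", {
  seq104 <- strrep("ACGT", 26)
  p <- extractProbe(seq104, 52)
  expect_equal(p$start, 26L)
  expect_equal(nchar(p$sequence), 52L)
  expect_identical(p$sequence, substring(seq104, 27, 78))

  expect_identical(extractProbe(seq104, 20)$reason, "edge")  # window start -6
  expect_equal(extractProbe(seq104, 26)$start, 0L)           # exact fit
  expect_identical(extractProbe(seq104, 79)$reason, "edge")
  expect_error(extractProbe(seq104, 52, length = 51), "even")
})

test_that("homopolymer filter fails runs longer than the limit only", {
  expect_false(homopolymerFilter(paste0(strrep("AC", 10), "AAAA", strrep("GT", 14))))
  expect_true(homopolymerFilter(strrep("ACGT", 13)))
  expect_true(homopolymerFilter(paste0("AAAT", strrep("CG", 11), "AAA",
                                       strrep("TC", 11), "A")))  # runs of 3 pass
  expect_false(homopolymerFilter("ACCCCGT", maxRun = 3))
  expect_true(homopolymerFilter("ACCCCGT", maxRun = 4))
})

test_that("GC content and melting temperature follow the stated formulas", {
  expect_equal(gcContent(strrep("AG", 26)), 50)    # 26 G/C of 52
  expect_equal(gcContent(strrep("A", 52)), 0)
  expect_equal(gcContent(paste0(strrep("G", 34), strrep("A", 18))), 65.38,
               tolerance = 1e-3)

  ## Tm = 81.5 + 16.6 log10(Na) + 0.41 GC - 600/N
  expect_equal(meltingTemp(strrep("AG", 26)), 77.47, tolerance = 1e-2)

  ## closed-form check at GC 65 (no 52-mer has exactly 65% GC):
  tm <- function(gc, n = 52, na = 0.165) 81.5 + 16.6 * log10(na) + 0.41 * gc - 600 / n
  expect_equal(tm(50), 77.47, tolerance = 1e-2)
  expect_equal(tm(65), 83.62, tolerance = 1e-2)

  ## salt term vanishes at 1 M
  expect_equal(meltingTemp(strrep("AG", 26), naMolar = 1),
               81.5 + 0.41 * 50 - 600 / 52)
  expect_error(meltingTemp(strrep("AG", 26), naMolar = 0), "positive")

  ## monotone increasing in GC at fixed length and salt
  gcs <- vapply(0:26, function(k)
    paste0(strrep("G", 2 * k), strrep("A", 52 - 2 * k)), character(1))
  tms <- meltingTemp(gcs)
  expect_true(all(diff(tms) > 0))
})

test_that("the GC/Tm window filter binds on both conditions", {
  expect_true(thermoFilter(strrep("AG", 26)))                 # GC 50, Tm 77.47
  expect_false(thermoFilter(paste0(strrep("G", 25), strrep("A", 27))))  # GC 48
  ## at the default salt both windows bind near the top: GC 63.46 (33/52,
  ## Tm 82.99) still passes, while the Tm cap alone would reject GC > 63.5
  s33 <- paste0(strrep("GA", 19), strrep("GC", 7))  # 19+14 = 33 G/C
  expect_equal(gcContent(s33), 100 * 33 / 52)
  expect_true(thermoFilter(s33))
  expect_false(thermoFilter(s33, tmRange = c(76, 82.9)))  # Tm condition binds
  expect_false(thermoFilter(s33, gcRange = c(50, 63)))    # GC condition binds
  expect_error(thermoFilter("ACGT", gcRange = c(60, 50)), "non-empty")
})

test_that("deep-read validation counts exact occurrences on both strands", {
  fx <- designFixture()
  gseq <- as.character(chromSequences(fx$genome))[["1D"]]
  probe <- substring(gseq, 10001, 10052)
  expect_true(validateWithDeepReads(probe, fx$validation, minSupport = 2))
  ## an error-bearing variant is absent from the deep reads
  broken <- probe
  substring(broken, 26, 26) <- setdiff(c("A", "C", "G", "T"),
                                       substring(probe, 26, 26))[1]
  expect_false(validateWithDeepReads(broken, fx$validation, minSupport = 2))
  expect_true(validateWithDeepReads(broken, fx$validation, minSupport = 0))

  ## the dictionary counter agrees with a base-R occurrence oracle
  reads <- as.character(sequencesOf(fx$validation))[1:2000]
  got <- countProbeHits(c(probe, broken), Biostrings::DNAStringSet(reads))
  expect_equal(got, c(bruteOccurrences(probe, reads),
                      bruteOccurrences(broken, reads)))
})

test_that("copy-number decisions match genome copy counts at 20x coverage", {
  withr::with_seed(31, {
    seg <- randomSeq(300)  # triplicated segment
    chr <- paste0(randomSeq(9000), seg, randomSeq(8000), seg,
                  randomSeq(9000), seg, randomSeq(14700))
    gm <- manualGenome(c(chr1 = chr))
  })
  reads <- simulateReads(gm, coverage = 20, readLength = 115, seed = 32)
  uniq <- vapply(c(2000, 12000, 25000), function(at)
    substring(as.character(chromSequences(gm))[[1]], at, at + 51), character(1))
  multi <- substring(seg, 100, 151)
  absent <- withr::with_seed(33, randomSeq(52))

  probes <- c(uniq, multi, absent)
  copies <- vapply(probes, genomeCopies, integer(1), genome = gm)
  expect_equal(unname(copies), c(1L, 1L, 1L, 3L, 0L))

  verdict <- copyNumberFilter(probes, reads, maxHits = 20)
  expect_identical(unname(verdict), unname(copies == 1L))
})

test_that("gene probe design picks disjoint qualifying windows left to right", {
  ## a clean 52-mer gene gives exactly one probe
  g52 <- paste0(strrep("AG", 13), strrep("TC", 13))
  expect_equal(nrow(designGeneProbes(g52, maxProbes = 3)), 1L)

  ## 60 bp cannot host two non-overlapping probes
  g60 <- paste0(g52, "ACGTACGT")
  expect_lte(nrow(designGeneProbes(g60, maxProbes = 3)), 1L)

  ## a 1-kb gene at GC ~57% yields 3 pairwise-disjoint probes
  g1k <- withr::with_seed(34, paste(
    sample(c("A", "C", "G", "T"), 1000, replace = TRUE,
           prob = c(0.215, 0.285, 0.285, 0.215)), collapse = ""))
  des <- designGeneProbes(g1k, maxProbes = 3, spacing = 10)
  expect_equal(nrow(des), 3L)
  expect_true(all(diff(des$start) >= 62))
  expect_true(all(thermoFilter(des$sequence)))
  expect_true(all(homopolymerFilter(des$sequence)))

  expect_error(designGeneProbes("ACGT"), "shorter")
})

test_that("the design pipeline conserves accounting and selects clean probes", {
  ## empty inputs give an empty, zeroed ProbeSet
  empty <- runDesignPipeline(NULL, NULL, NULL, NULL, NULL)
  expect_equal(nrow(probeTable(empty)), 0L)
  expect_true(all(accounting(empty) == 0L))

  fx <- designFixture()
  ps <- fx$probes
  acc <- accounting(ps)
  expect_equal(acc[["candidates"]],
               acc[["selected"]] + sum(acc[grep("^rejected_", names(acc))]))
  expect_gt(acc[["selected"]], 0L)

  pt <- probeTable(ps)
  sel <- pt[pt$selected, ]
  expect_true(all(nchar(sel$sequence) == 52L))
  expect_true(all(homopolymerFilter(sel$sequence)))
  expect_true(all(thermoFilter(sel$sequence)))
  ## every selected RJM 52-mer occurs exactly once in the target genome
  rjm <- sel[sel$probe_type == "rjm", ]
  copies <- vapply(rjm$sequence, genomeCopies, integer(1), genome = fx$genome)
  expect_true(all(copies == 1L))
  ## junction probes keep the boundary at the window midpoint
  jt <- junctionTruth(fx$genome)
  offs <- vapply(seq_len(nrow(rjm)), function(i) {
    tt <- jt[jt$chrom == rjm$chrom[i], ]
    min(abs(tt$position - rjm$position[i]))
  }, numeric(1))
  expect_true(all(offs <= 2))
})

test_that("the selected set is invariant to filter application order", {
  fx <- designFixture()
  pt <- probeTable(fx$probes)
  ## recompute each filter independently and intersect in a different order
  keepThermo <- thermoFilter(pt$sequence)
  keepHomo <- homopolymerFilter(pt$sequence)
  keepVal <- rep(TRUE, nrow(pt))
  isR <- pt$probe_type == "rjm"
  keepVal[isR] <- validateWithDeepReads(pt$sequence[isR], fx$validation, 2)
  keepCN <- rep(TRUE, nrow(pt))
  keepCN[isR] <- copyNumberFilter(pt$sequence[isR], fx$target, 5)
  expect_identical(pt$selected, keepThermo & keepCN & keepVal & keepHomo)
})
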