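# rjmap — repeat junction markers and deletion-bin mapping

`rjmap` builds genome-specific molecular markers from transposable-element
insertion sites and maps them to chromosome deletion bins by comparative
genomic hybridization (CGH) against aneuploid stocks, in the style of the
wheat D-genome physical mapping arrays.

**Who it is for.** Researchers working with large, repeat-rich plant genomes
(wheat and its relatives being the motivating case) who need physical markers
outside the gene space: gene-based markers cross-hybridize between
homoeologous subgenomes and cluster in distal recombining regions, whereas a
*repeat junction* — the boundary between a transposable-element insertion and
its flanking sequence — is effectively unique in a genome, so a 52-mer
spanning it (an ISBP / repeat junction marker, RJM) is genome-specific and
distributed genome-wide.

## What it computes

* **Junction discovery** — a self-contained k-mer-seeded ungapped matcher
  (`findRepeatMatches`, defaults k = 16, 30 bp, 90% identity) scans shotgun
  reads against a classed repeat library; `detectJunctions` calls a junction
  at every match boundary with ≥ 30 bp support on both sides and classifies
  it (retrotransposon/dna_transposon/unknown pairs).
* **Probe design** — `runDesignPipeline` extracts 52-mers with the junction
  at the midpoint and applies the four-step cascade: homopolymer runs (> 3
  fail), deep-read validation (exact 52-mer in ≥ 2 of the 30× reads),
  copy-number screen (> 5 exact hits in the 5× target-genome reads, or 0
  hits, fail), and GC/Tm windows (GC ∈ [50, 65]%, Tm ∈ [76, 83] °C with
  `Tm = 81.5 + 16.6·log10(Na) + 0.41·GC% − 600/N` at 0.165 M Na⁺). Gene
  probes (1–3 disjoint windows per gene) are designed alongside.
* **CGH analysis** — `cghAssign` quantile-normalizes replicate intensities,
  computes per-line signal loss (`1 − test/reference` ratio-of-means, pooled
  Student t-test on 2 arrays × 3 spots against the control), and walks a
  decreasing stringency ladder (50 → 20% loss in 10% steps, p < 0.05): a
  probe flagged in exactly one nullisomic-tetrasomic line gets that
  chromosome; the deletion-line flag prefix decodes its fraction-length bin,
  with the proximal composite reported as `pericentromeric-inferred`.
* **Bin-map bookkeeping** — bin physical sizes (`(b − a) ×` arm length),
  pericentromeric counts by subtraction, marker densities and coverage,
  within-bin ordering against a genetic map, and bin genetic lengths.
* **Synthetic data** — `simulateGenome`/`simulateReads`/`buildLinePanel`/
  `simulateHybridization` generate genomes with nested TE insertions and
  exhaustive junction truth, aneuploid panels, error-prone reads and
  replicated two-channel signals, so the whole pipeline is testable end to
  end with known ground truth.

## Worked example

```r
library(rjmap)

lib <- buildRepeatLibrary(nRetro = 3, nDna = 2, lengthRange = c(800, 1500), seed = 7)
genome <- simulateGenome(lib,
  data.frame(name = c("1D", "2D"), length = c(8e4, 8e4), arm_fraction = c(0.4, 0.5)),
  teCount = 16, nestingProb = 0.15, geneCount = 6, geneLength = 1000, seed = 11)
genome
#> GenomeModel: 2 chromosome(s), 179,816 bp total
#>   16 TE insertion(s), 6 gene(s), 32 truth junction(s)

discovery  <- simulateReads(genome, coverage = 1,  readLength = 400,
                            substitutionRate = 0.005, seed = 3)   # error-prone
validation <- simulateReads(genome, coverage = 30, readLength = 150, seed = 4)
target     <- simulateReads(genome, coverage = 5,  readLength = 150, seed = 5)

junctions <- junctionGenomeCoords(scanReadsForJunctions(discovery, lib), discovery)
tabulateCategories(junctions)
#>         retrotransposon-unknown          dna_transposon-unknown
#>                              17                               7
#> retrotransposon-retrotransposon   dna_transposon-dna_transposon
#>                               2                               0
#>  dna_transposon-retrotransposon
#>                               0

probes <- runDesignPipeline(junctions, discovery, validation, target,
                            geneSequences(genome))
probes
#> ProbeSet: 44 candidates, 21 selected
#>   rejections: edge=0, homopolymer=17, read_validation=3, copy_number=2, thermo=1
```

44 candidate 52-mers were extracted (26 junction windows + 18 gene windows);
17 carried homopolymer runs, 3 contained discovery-read sequencing errors
absent from the 30× validation reads, 2 were multi-copy or absent in the
target-genome reads, 1 fell outside the GC/Tm windows, leaving 21 selected
probes (accounting always satisfies candidates = selected + rejections).

```r
panel <- buildLinePanel(genome, list(`1D` = list(L = c(0.3, 0.6), S = 0.5),
                                     `2D` = list(L = 0.4)))
sel  <- subset(probeTable(probes), selected & probe_type == "rjm")
se   <- simulateHybridization(panel, sel[, c("probe_id", "chrom", "position",
                                             "probe_type")],
                              genome, signalModel(seed = 2))
cghAssign(se, panel)$assignments
#>    probe_id chromosome                      bin stringency_level
#> 1 rjm_00017         1D pericentromeric-inferred              0.5
#> 2 rjm_00022         2D            2DL-0.40-1.00              0.5
#> 3 rjm_00024         1D            1DL-0.60-1.00              0.5
```

Each selected RJM is assigned to its true chromosome at the strictest (50%
loss) stringency; `2DL-0.40-1.00` is the terminal bin distal to the 2DL
breakpoint, and the 1D probe proximal to every breakpoint lands in the
pericentromeric composite. The bookkeeping operations work on printed counts
directly:

```r
estimateBinLength(381.0, c(0.41, 1.00))               # terminal 1DL bin, Mb
#> [1] 224.79
pericentromericBySubtraction(3921, c(67, 113, 273, 247))  # 1D RJM composite
#> [1] 3221
unlist(markerDensity(35118, 4900))
#> markers_per_mb  kb_per_marker
#>       7.166939     139.529586
```

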