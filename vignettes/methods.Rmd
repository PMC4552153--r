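---
title: "Repeat junction markers and deletion-bin mapping: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Repeat junction markers and deletion-bin mapping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rjmap)
```

# The problem

Large *Triticeae* genomes are mostly transposable elements, and their genes
are concentrated in distal, recombining regions. Gene-based markers therefore
leave most of the physical genome unmarked, and in a polyploid the three
homoeologous gene copies cross-hybridize, blurring chromosome assignment. A
repeat *junction* — the boundary between a transposable-element insertion and
whatever it inserted into — behaves very differently: the insertion site is
effectively unique, so a short oligonucleotide spanning the boundary (an
insertion-site-based polymorphism, ISBP, or repeat junction marker, RJM) is
genome-specific and distributed wherever repeats are, i.e. everywhere.

`rjmap` implements the full route from shotgun reads to a physical bin map:

1. **Junction discovery** — find repeat-library matches in reads and call a
   junction at every match boundary with adequate support.
2. **Probe design** — cut a 52-mer with the junction at its midpoint and pass
   it through a four-step filter cascade (homopolymer runs, deep-read
   validation, copy-number screen, GC/Tm windows); design 1–3 probes per gene
   the same way.
3. **Comparative hybridization analysis** — normalize two-channel array
   intensities, test for signal loss per aneuploid line, and assign each
   probe to a chromosome (nullisomic-tetrasomic panel) and a deletion bin
   (fraction-length deletion panel) through a decreasing stringency ladder.
4. **Bin-map bookkeeping** — bin physical sizes, pericentromeric counts by
   subtraction, marker densities, and within-bin ordering against a genetic
   map.

Because the original array data and the donor genome are far beyond desk
scale, the package ships a first-class synthetic-data module whose ground
truth exercises every stage; the acceptance checks measure how well each
stage recovers that truth.

# The synthetic model

## Genome and junction truth

`simulateGenome()` inserts repeat elements into uniform-random backbone
sequence. With probability `nestingProb` an insertion splits an existing
element (creating element–element junctions), otherwise it splits flank. An
insertion always splits one segment into two, so each insertion adds exactly
two boundaries; the junction truth table enumerates every boundary whose
sides differ, with 0-based positions (a junction position is the first base
right of the boundary). Genes are placed only in TE-free intervals.

Chromosome arm coordinates follow the cytogenetic convention: the centromere
sits at `round(armFraction * length)`; fraction length (FL) runs from 0 at
the centromere to 1 at the telomere of each arm, matching bin labels of the
form `1DL-0.18-0.41`.

## Reads

`simulateReads()` draws `round(coverage x genomeLength / readLength)`
fixed-length single-end reads with uniform origins and independent
substitution errors. Indels and base qualities are deliberately out of scope:
every filter under test is a substring or occupancy filter, so substitution
errors are the failure mode that matters. Error-prone "discovery" reads
(default 0.5% substitutions, mimicking pyrosequencing-era data) supply the
junction candidates; error-free deep read sets play the validation (30x) and
target-genome (5x) roles.

## Hybridization dosage model

Ploidy is represented as per-locus copy numbers, not duplicated sequences —
the hybridization model needs dosage only. For copy number `c >= 1` the
expected intensity is `base x copyGain^(c-1)`; at `c = 0` an RJM probe drops
to zero while a gene probe retains `crossHyb x base` of homoeologous
background. A single `crossHyb` factor stands in for explicit A/B subgenomes:
it is sufficient to reproduce the behaviour that matters downstream (gene
probes retain partial signal, RJMs go to background). Each spot measurement
gets multiplicative lognormal noise; with probability `dropoutRate` a spot is
replaced by a near-background value (a scratched or failed feature). The
noise law is a modelling choice — the hybridization literature does not fix
one — and lognormal multiplicative noise is the conventional default for
intensity data.

Defaults (`signalModel()`): base 1000, copyGain 1.8, lognormalSd 0.15,
dropoutRate 0.02, crossHyb 0.3, with 2 array replicates x 3 spot replicates
per line, matching the replication structure of the array design the package
emulates.

# Junction discovery

`findRepeatMatches()` replaces external BLAST-style machinery with a
self-contained k-mer-seeded ungapped extender: exact 16-mer seeds locate
candidate (element, strand, diagonal) triples; each seed run is extended
while the identity *of the extension itself* stays at or above
`minIdentity`, and the endpoint only ever advances onto a matching base.
Judging the extension, rather than the whole segment, prevents a long perfect
prefix from buying its way across an element boundary into unrelated
sequence — an effect that would otherwise merge abutting matches and erase
exactly the element–element junctions the pipeline exists to find. Matches on
the same diagonal are merged; defaults are k = 16, minimum length 30, minimum
identity 0.9, playing the role of a stringent e-value cutoff. At identity 1.0
the algorithm provably reduces to maximal exact runs per diagonal, which the
test suite checks against an exhaustive brute-force scan.

`detectJunctions()` calls a junction at every match edge with at least
`minFlank` supporting bases on both sides; two matches whose facing edges lie
within `gapTol = 5` bp (sequencing-error slack) fuse into a single
element–element junction at the floor of the mean of the two edges. Both
query strands are scanned through the reverse-complemented element index, and
coordinates are reported on the read's forward strand. Junction categories
are order-insensitive over {retrotransposon, dna_transposon, unknown}; a
junction with two unknown sides is rejected. The 'unknown' class deliberately
conflates "genic/low-copy" with "absent from the repeat library" — the two
are not distinguishable at this stage.

# Probe design

`extractProbe()` takes the window `[midpoint - 26, midpoint + 26)`, so the
junction sits exactly at the probe midpoint; windows running off the read are
rejected with reason `"edge"`. The cascade then applies, in order:

* **homopolymer** — fail on any single-base run longer than 3;
* **deep-read validation** — the exact 52-mer must occur in at least 2
  validation reads (either strand), which removes probes built on discovery
  sequencing errors;
* **copy-number** — fail when the 52-mer occurs more than `maxHits = 5`
  times in the 5x target-genome reads (multi-copy), and also when it occurs
  zero times, which encodes the requirement that a usable marker be shared
  between the donor and target genomes;
* **GC/Tm** — GC in [50, 65]% and Tm in [76, 83] degrees C, inclusive.

Tm uses the salt-adjusted long-oligo formula
`Tm = 81.5 + 16.6 log10(Na) + 0.41 GC% - 600/N` at `Na = 0.165` M. That salt
concentration was chosen because it maps GC 50–65% onto roughly 77.5–83.6
degrees for 52-mers, making the two published selection windows mutually
consistent; it is configurable. Note the windows genuinely interact: at the
default salt, 52-mers above GC 63.5% pass the GC window but fail the Tm cap.

All filters are evaluated for every candidate, so the *selected set* is
provably order-independent; for the rejection report each probe is charged to
its first failing filter in cascade order, which makes the accounting
reproducible (`candidates = selected + sum of rejections` always holds).
Gene probes are chosen left-to-right along each gene (up to 3 disjoint
windows at least 10 bp apart, homopolymer- and thermo-clean) and skip the
read-validation step (they derive from assembled gene models, not error-prone
reads) and, by default, the copy-number screen (genes are expected in
homoeologous copies). The per-gene maximum is configurable; the source
material reports both "1 to 3" and "1–6" probes per gene, and the package
defaults to 3 without deciding which is authoritative.

## Calibration of the copy-number screen

With uniform random reads the number of full-length hits of a single-copy
52-mer is approximately Poisson with mean `coverage x (L - 51)/L`. At 5x
coverage and a threshold of 5 the single-copy mean sits essentially at the
threshold, so individual decisions are noisy by construction — the screen is
a population-level filter at that operating point. The package's fixtures
therefore verify exact agreement with genome copy counts at the 20x /
max-hits-20 operating point, using 115-bp reads so that the expected hit
count is ~11 per copy: single-copy loci sit far below the threshold, and the
multi-copy fixture uses three copies (~33 expected hits) to sit far above it.
These are design choices of the fixture geometry, made so that the check
tests the decision rule rather than Poisson sampling luck.

# Hybridization analysis

## Normalization

"Quantile normalization" here is full rank-mean normalization (after it,
every column shares the identical sorted vector; ties receive the mean of
their tied rank values), delegated to `limma::normalizeQuantiles`. A
median-scaling alternative sits behind `method = "median"` for users who read
the original "quartile" wording as quartile scaling; quantile is the default.

Which columns to normalize *together* is a modelling decision with teeth.
Quantile normalization assumes the grouped columns share an underlying
intensity distribution. Replicate spots/arrays of one line and channel do;
test channels of *different* aneuploid lines do not — a nullisomic line
genuinely lacks ~1/7 of loci, and forcing its test channel onto a shared
distribution with the euploid reference would drag its zero block up to the
shared lower tail and attenuate true losses from ~100% toward ~50%.
`cghAssign()` therefore normalizes within (line, channel) groups, i.e.
across the 6 replicate measurements of each sample.

## Loss testing

Each spot's test value is divided by its same-spot reference value; ratios
are normalized per probe by the control line's median ratio, which makes "20%
signal reduction relative to the reference" operational for a two-channel
design. Reference-channel values below 10% of their column median are masked
as technical dropouts (the reference genome is euploid, so a near-zero
reference is always technical; a near-zero *test* value is confounded with
real loss and is never masked). Loss is `1 - mean(line ratios)/mean(control
ratios)`; the p-value is a two-sided pooled-variance Student t-test between
the line's 6 spot-level ratios and the control's 6, implemented as a
vectorized closed form and cross-checked against `stats::t.test` in the
tests. Degenerate zero-variance cases (exact noise-free fixtures) get p = 0
when the means differ and p = 1 when they agree. No multiple-testing
correction is applied across probes, matching the published analysis.

## The stringency ladder and assignment rules

Flags are `loss >= threshold & p < 0.05`, evaluated at thresholds 0.5, 0.4,
0.3, 0.2 from strict to lenient. The first threshold at which *exactly one*
nulli-tetrasomic line is flagged fixes the probe's chromosome and stringency
level; the deletion-line flag pattern at that same level fixes the bin. Since
the flag sets are nested across thresholds (a 50% loss is also a 20% loss),
raising stringency can never gain assignments, and evaluating the bin at the
chromosome's own level keeps the two calls mutually consistent.

Deletion-line patterns decode as follows: a line with breakpoint `b` on arm
`A` flags a probe iff the probe is distal to `b`, so a real locus flags a
prefix of the ascending breakpoints of one arm. A full prefix maps to the bin
between the largest flagged and smallest unflagged breakpoints; all lines
flagged gives the terminal bin `(b_max, 1]`; no deletion flags on either arm
means the locus sits proximal of every breakpoint — the pericentromeric
composite assayed by no line — and is reported `pericentromeric-inferred`;
any non-monotone or cross-arm pattern is left unassigned, as are probes
flagged in deletion lines but no nulli line. Bin intervals are half-open
`(a, b]`: a locus exactly at a breakpoint is retained by that deletion line
and belongs to the proximal side.

The genome-specificity screen is the same loss test against an
alternative-genome line lacking the whole target genome: probes that fail to
lose at least 20% of signal there (e.g. gene probes with strong homoeologous
cross-hybridization) are dropped as not genome-specific.

# Bin-map bookkeeping

Bin physical length is `(b - a) x arm length` in Mb; arm lengths are supplied
per arm (the published 1D sizes reproduce under 1DS = 224 Mb, 1DL = 381 Mb).
The pericentromeric composite is not assayed by any deletion line, so its
marker count is the chromosome's nulli-tetrasomic total minus the assayed-bin
counts — `pericentromericBySubtraction()` reports a consistency error rather
than clamping when bins exceed the total, which is how the internally
inconsistent cells of the published table surface in the tests.

Within-bin marker order is inferred from a genetic map. The discordance rule
had to be made concrete where the source only says inconsistent markers were
excluded: a marker is flagged iff its cM position falls outside the span
(min–max) of the bin's remaining markers *and* inside an adjacent bin's span.
This satisfies the two properties that define the intent — a monotone map
yields zero flags, and swapping k markers across bins flags exactly those k —
while staying robust for small bins, where quantile-based intervals are
unstable. `lengthCorrelation()` reports Pearson (with Spearman as secondary)
between bin physical and genetic lengths without interpreting it; on
realistic synthetic maps with distally concentrated recombination the two are
essentially uncorrelated, as expected.

# Problem sizes, tolerances and degenerate inputs

The packaged study conditions are: recovery fixture of 5 chromosomes x 1 Mb
backbone, 300 insertions, 2,000 probe loci, a nulli line per chromosome plus
12 deletion lines, 2 arrays x 3 spots; probe-design fixture of 2 x 80 kb with
1x/30x/5x read sets. These sizes were chosen so that every property of
interest is measurable with comfortable margins (noise-free recovery is
exactly 100%; noisy recovery runs ~97–99.7% against acceptance floors of
95%/90%) while a full test run stays in tens of seconds. Floating-point
tolerances: quantile-normalized column distributions agree to 1e-9; bin
tilings to 1e-6; t-test p-values match `stats::t.test` to 1e-12.

Degenerate inputs are defined rather than accidental: empty libraries yield
empty match sets; zero insertions yield empty truth; a zero reference mean is
an explicit error; constant vectors make the length correlation `NA`;
zero-variance loss tests get exact 0/1 p-values; and every generator is
byte-reproducible from its integer seed.

# What the synthetic results do and do not show

Passing recovery at these settings shows the *pipeline logic* is correct:
normalization preserves dosage contrasts, the ladder and bin decoder invert
the deletion geometry exactly, and the filter cascade selects probes that are
unique in the target genome. It does not show field performance on real
arrays, where dye bias, spatial artefacts, segmental duplications, diverged
repeat families and partial homoeologous hybridization all exist and are not
modelled. The synthetic noise model is multiplicative and independent across
spots; real array noise is neither, and the dropout mask (10% of column
median) is a simple stand-in for real quality control. The concordance
operation is provided for comparing assignment sources, but no external map
is bundled, so cross-platform agreement is exercised only against synthetic
truth.
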