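---
title: "Modelling germ-granule-dependent 22G siRNA production"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling germ-granule-dependent 22G siRNA production}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eGranuleSeq)
```

# Scope

`eGranuleSeq` is a simulation-plus-analysis package for the small-RNA biology
of the *C. elegans* germ granule. Germline mRNAs are targeted by 22G RNAs —
22-nucleotide, 5′-guanine siRNAs synthesized antisense to their templates by
RNA-dependent RNA polymerases. Distinct germ-granule subcompartments make
distinct siRNA pools: loss of E-granule factors (here called *egc1* and
*elli1*) removes siRNAs from the 5′ region of one gene set (E-class), loss of
Mutator foci (*mut16*) removes siRNAs gene-wide from another (M-class), and a
third, small gene set (UP-class) *gains* siRNAs when E granules are lost.
Loss of the RdRP itself (*ego1*) removes E-class siRNAs along the whole gene
body.

The package ships every stage of a desk-scale study of this system:

1. **Synthetic data** — annotated toy genomes, genotype-specific sequencing
   libraries with per-read ground truth, mRNA count tables, qPCR Ct tables
   and rendered condensate images with a known contact graph.
2. **Quantification** — adapter trimming, a bespoke exact-match read mapper,
   weighted antisense 22G counting and the two field-standard RPM
   normalizations.
3. **Classification** — two-fold-change contrasts with abundance floors,
   allele-consensus target sets and the E/M/UP class assembly.
4. **Metagene profiling** — fixed-bin coverage profiles and per-gene
   positional-bias labels that distinguish 5′-restricted from uniform
   depletion.
5. **Imaging** — ROI-restricted Pearson colocalization, foci segmentation,
   pixel-distance contact calls and the three-condensate arrangement
   taxonomy.
6. **Pipeline** — a seeded end-to-end run tying 1–4 together with recovery
   metrics against the generator's own answer key.

Everything is deterministic given a single master seed, which is fanned out
to per-stage streams with `deriveSeed()`.

# The generative model

## Genome

`makeGenome()` lays out non-overlapping, single-exon genes on one random
chromosome. Defaults (see `genomeConfig()`): 120 germline coding genes split
into hidden truth classes (30 E, 30 M, 15 UP, 45 NEUTRAL), 6 soma-specific
genes, 7 structural loci (rRNA, tRNA, snRNA, snoRNA, ncRNA), 2 miRNA and 2
21U-RNA loci, gene bodies of 500–1500 nt on a 400 kb chromosome with at
least 50 nt between neighbours. Each coding gene draws a log-normal
wild-type siRNA production rate (`rateSdLog = 0.5`).

Two numerical choices deserve comment:

* **Minimum gene length 100 nt** (enforced: default minimum 500) keeps the
  100-bin metagene profiles meaningful — every bin covers at least one base.
* **`upRateScale = 0.1`**: UP-class genes start from one-tenth the usual
  wild-type rate. Genes that gain siRNAs upon E-granule loss are near-silent in
  wild type; besides realism, this keeps the gained reads from dominating
  the library and compositionally depressing the RPM of unchanged genes,
  which would otherwise masquerade as weak global depletion under
  total-mapper normalization.

## Genotype models

A `GenotypeModel` rescales per-region production rates relative to wild
type. E-class genes have a 5′ window (the first `fivePrimeFraction = 0.8`
of the gene body, a proxy for "all but the last exon") and a 3′-terminal
window; their rates are multiplied by `delta5` and `delta3`. M- and
UP-class genes are scaled gene-wide by `deltaM` and `deltaUp`.

| genotype      | delta5 | delta3 | deltaM | deltaUp | reading                          |
|---------------|-------:|-------:|-------:|--------:|----------------------------------|
| `WT`          | 1      | 1      | 1      | 1       | reference                        |
| `egc1`,`elli1`| 0.1    | 1      | 1      | 10      | 5′ loss, 3′ persistence, UP gain |
| `ego1`        | 0.1    | 0.1    | 1      | 1       | gene-wide loss (RdRP itself)     |
| `mut16`       | 1      | 1      | 0.05   | 0.05    | M-class ablation; UP-class too   |
| doubles       | 0.1    | 1      | 0.05   | 0.5     | product of the parents           |

`deltaUp = 10` encodes "more than tenfold" siRNA gains at genes like the
RNAi-pathway genes that lose their mRNAs when over-targeted. `mut16` also
ablates UP-class genes because the gained siRNAs are Mutator-derived —
which is why the generator's answer key for a `mut16` contrast
(`truthContrastSet()`) is the union of M- and UP-class genes. Double
mutants are the elementwise product of their parents (`composeModels()`),
the usual independence assumption for lesions in different compartments.

## Sequencing libraries

`simulateSirnaLibrary()` draws reads by multinomial sampling over
(gene, window) rate cells, so expected read shares follow
`base_rate × (0.8·mult5 + 0.2·mult3)` exactly (`expectedReadShare()`
exposes the law for testing). Within a window, read start positions are
uniform. Read lengths follow a discrete distribution peaked at 22 nt
(support 18–26). A read starts with G with probability `pG = 0.9`,
realised by conditioning the template position on a template cytosine —
this keeps every read an exact reverse-complement substring of its
transcript, which the exact-match mapper requires and the test oracles
exploit. Sense rRNA degradation fragments (5%), miRNA and 21U-RNA reads
(1% each) are mixed in to exercise the normalization subtractions and
biotype filters. `writeFastq()` appends the 3′ adapter so that
`cleanReads()` has real work to do.

## What the generator does *not* emulate

Sequencing error, quality-score variation, PCR duplication bias, ligation
bias, multi-exon gene structure, genomic repeats (so multi-mapping is rare
and only arises from chance k-mer duplication), partial adapters shorter
than 8 nt, and biological replicate variance beyond resampling noise. These
omissions are deliberate: each would blur the sharp oracle properties
(exact substring mapping, exact read-share laws) that make the analysis
code testable, without changing the statistics under study.

# The analysis machinery

## Quantification and normalization

`cleanReads()` trims the 3′ adapter (longest prefix of at least 8 nt found
in the read), strips 5′-adapter carryover and keeps 17–30 nt inserts
(18–26 for the metagene preset). `mapReads()` finds full-length exact
matches on either strand of every annotated transcript; a read matching
*n* loci contributes weight 1/*n* to each, so weighted counts conserve
mapped reads exactly. Antisense hits from reads of 21–23 nt starting with
G (a deliberately relaxed 22G definition tolerating length heterogeneity)
are summed per gene by `countGenes()`.

Two RPM denominators are carried side by side, matching field practice:

* **quantification RPM** — total mapped reads minus sense rRNA reads;
* **metagene RPM** — 18–26 nt mapped reads with no structural-locus hit
  (rRNA, tRNA, snRNA, snoRNA, ncRNA).

## Classification

`depletedGenes()` implements the two-fold criterion: candidate genes must
not be structural/miRNA/21U loci nor soma-specific, must clear a 10 RPM
floor (in wild type for depletion calls; in the mutant for gain calls,
since gaining genes can start near zero), and must change at least two-fold
(pseudocount 0.1 RPM). Allele-specific calls are intersected by
`consensusTargets()`; the E-class is the union of the two factors' target
sets (`defineClasses()`).

## Metagene profiles and positional bias

`geneProfile()` rescales per-base antisense coverage to 100 bins (remainder
bases go one per leading bin — deterministic and reversal-symmetric).
`positionalBias()` compares mutant and wild-type profiles within the 5′
(80%) and 3′ (20%) windows: a gene is `five_prime_depleted` when the 5′
ratio falls to ≤ 0.5 while the 3′ ratio stays ≥ 0.75, `uniform_depleted`
when both fall, `unchanged` when both persist. The 0.5 threshold echoes
the two-fold criterion; 0.75 (rather than 1) absorbs sampling noise in the
small 3′ window and is a package choice, as is the 0.1 wild-type coverage
floor below which genes are `not_callable`.

## Imaging

Foci are rendered as isotropic Gaussians whose half-maximum radius equals
the nominal focus radius, so thresholding at half the peak recovers discs
of roughly nominal size; segmentation is 4-connected with a 5-pixel
minimum area. Two foci are "in contact" when their minimum pixel-to-pixel
distance is ≤ 1 px — the operational reading of "no empty space between
them". `classifyArrangement()` anchors the taxonomy on the P granule:
`EP_only` (one E on P, no Z on that E), `EPZ` (one E bridging P and Z) and
`multiE_P` (two or more E on one P, at least one touching a Z).
`generateArrangementCohort()` draws cohorts with configurable category
weights (defaults 0.32 / 0.48 / 0.20) and geometry chosen so that the
analytic truth graph and the re-segmented images agree: touching pairs are
placed at centre distance r₁ + r₂ − 2, non-touching pairs at least
r₁ + r₂ + 5 apart.

# Problem sizes and runtime

The default study — 120 genes, nine libraries (wild type, two alleles each
of the two E-granule factors, the RdRP mutant, the Mutator mutant, two
doubles) at 10⁵ reads each — runs in roughly one to two minutes on one
CPU, and class recovery against the model-implied answer key is expected
to be essentially perfect; these sizes were chosen as the smallest at
which the two-fold contrasts, the RPM floors and the positional labels
operate away from their decision boundaries with comfortable sampling
margins.

# A compact end-to-end run

```{r pipeline, eval = FALSE}
library(eGranuleSeq)
res <- runPipeline(runConfig(seed = 1L), verbose = TRUE)
res$report$set_sizes
res$report$recovery
res$report$positional$egc1_E
```

# Limitations

* The mapper is exact-match only and quadratic-free by construction; it is
  a stand-in at toy scale, not a replacement for a genome aligner.
* Fold-change calling has no dispersion model or multiple-testing control —
  it mirrors threshold-based custom scripts, and the simulation depths are
  chosen so thresholds sit far from the noise floor.
* Truth classes are gene-level and mutually exclusive; real target sets
  overlap partially between pathways.
* Images are 2-D with additive Gaussian noise; no point-spread anisotropy,
  z-stacks or chromatic shift.
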