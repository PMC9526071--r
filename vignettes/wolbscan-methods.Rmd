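---
title: "Detecting endosymbionts and grouping strains from host resequencing reads"
author: "wolbscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting endosymbionts and grouping strains from host resequencing reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wolbscan)
```

## The problem

Reduced-representation sequencing of insects — here genotyping-by-sequencing
(GBS) of *Lycaeides* butterflies — incidentally sequences DNA of maternally
transmitted endosymbionts such as *Wolbachia*. Those by-catch reads, mapped
to a *Wolbachia* reference, carry two kinds of information: their mere
*presence* indicates infection, and the *alleles* they cover at variable
sites identify the infecting haplotype. wolbscan implements the full chain
from per-read alignment summaries to locality- and lineage-level infection
and strain tables, together with a synthetic-data generator that emulates the
statistical structure of such a survey so that every stage can be tested
without raw sequencing data.

## Infection detection and threshold calibration

An individual is called infected when at least `min_reads` endosymbiont-
mapped reads pass three filters: SAM flag clear of the exclusion mask
(default 2432: secondary, QC-fail and supplementary alignments), mapping
quality strictly greater than `mapq_min = 20` (≈1% misplacement
probability), and read length at least `min_len = 80` bp. Length is compared
inclusively (`>= 80`) while MAPQ is strict (`> 20`); both conventions are
exposed as parameters. The default `min_reads = 5` is the operating point at
which concordance with PCR assays of a calibration subset is maximal in
surveys of this design; `threshold_sweep()` recomputes the full
accuracy/FNR/FPR curves over a log-spaced grid of read thresholds so the
operating point can be re-derived for any data set. Exact integer
concordance counts are compared (never floating-point accuracies), and ties
are broken toward the smallest threshold — when several thresholds classify
equally well, the least stringent one loses fewer true infections as
sequencing effort varies. Gold-labeled individuals absent from the alignment
summaries are treated as having zero mapped reads (called uninfected), which
is what their absence means bioinformatically.

Calibration against a single cohort of ~2,000 individuals separates
neighbouring thresholds by only a handful of discordant individuals, so the
single-cohort argmax is intrinsically noisy; where we assess the calibrated
operating point on simulated data we therefore pool confusion counts across
replicate cohorts before locating the maximum, and check the monotone
properties (false-negative rate non-decreasing, infected count
non-increasing in the threshold) on every cohort individually.

## Haploid haplotype calling

Variant data are modeled as haploid: one *Wolbachia* lineage per host. At
each biallelic site the call is the allele with the larger quality-passing
depth; zero total depth is missing, and equal nonzero depths are missing
under the default tie policy (a flag switches to summed base-quality
tie-breaking when qualities are available). Sites with a third observed
allele are dropped before calling. Haploidy buys phased haplotypes at the
cost of misrepresenting multiply-infected individuals — such individuals
tend to be removed by the filters below, and no diploid mode is provided.

Filtering is fixed in order and idempotent: first sites with more than
`max_missing = 25%` missing calls are dropped, then individuals with any
remaining missing call are dropped (complete cases). The missingness
denominator is the *infected* individuals only: uninfected hosts carry no
endosymbiont reads, so counting them would discard every site. Complete
haplotypes are exported as haploid VCF 4.2 (GT 0/1/`.`), NEXUS (standard
datatype, symbols 0/1, for coalescent demographic tools) and FASTA (0→A,
1→C, a fixed coding chosen for sequence-tool compatibility).

## Statistical-parsimony strain networks

Strains are operationally defined as connected components of a
statistical-parsimony network: haplotype pairs are joined when their Hamming
distance is at most a *connection limit* chosen so that, with 95%
confidence, the observed differences arose without superimposed changes
(Templeton, Crandall & Sing 1992). Because no implementation of the
published estimator was available as a dependency, wolbscan authors the
probability model itself, as a stepwise recursion under a finite-sites
Jukes–Cantor pair model. At observed per-site divergence $q$ the implied
substitution load is $\mu(q) = -\tfrac34\log(1 - \tfrac43 q)$, and the
probability that a visible difference reflects exactly one substitution is

$$ s(q) \;=\; \frac{\mu(q)\,e^{-\mu(q)}}{q}, $$

the Poisson single-hit mass over the Jukes–Cantor visible-difference mass.
The parsimony probability after $j$ accumulated differences on $m$ sites is
the recursion $P_j = P_{j-1}\, s(j/m)$, and the connection limit is the
largest $j$ with $P_j \geq 0.95$. For $m = 115$ variant sites this gives a
limit of 5 steps, which joins within-strain pairs (p-distance ≈ 0.03–0.04)
while leaving the between-strain divergences of 11–38% (14+ steps) in
separate networks; at common mitochondrial-marker lengths the same recursion
gives limits of 9 (360 bp) and 13 (658 bp) steps, in line with values
reported by the classic TCS software. Two numerical details: beyond the
Jukes–Cantor saturation point ($q \ge 3/4$) the per-step factor is held at
its saturation value so $P_j$ stays positive (vanishing confidence then
connects everything, as it should); and the limit can be overridden manually
(`connection_limit`) for sensitivity analysis — e.g. for the question of
whether the limit should be computed on variant sites only (our choice, 115)
or on a longer locus, which would raise it.

Within components the rendered edges form a minimum spanning structure
(Kruskal), with ties broken deterministically by higher joint haplotype
multiplicity and then lexical label order, so outputs are bit-reproducible.
Edges spanning $s \ge 2$ steps contribute $s-1$ inferred intermediate nodes
for rendering parity with published network figures; inferred nodes never
affect components or statistics. Components are labeled A, B, C, … by
decreasing number of carrying individuals; components with fewer than
`min_major = 11` individuals are flagged rare — the default is chosen so
that, on the packaged survey table, the three major strains are major and
every singleton is rare, and it is a flag, not a semantic constant.

## Ordination and divergence

`pcoa()` implements classical metric scaling (double-centering of squared
distances, eigendecomposition). Hamming distance matrices need not be
Euclidean-embeddable; negative eigenvalues are reported and excluded from
variance proportions, with a message. `divergence_table()` reports
uncorrected percent divergence (p × 100) within and between strains, by
default weighting each *distinct haplotype pair* once — published divergence
tables of this kind read as haplotype-level — with per-individual weighting
behind a flag (`weight = "individual"`). The standard deviation is the
population SD over the same pairs; a strain with a single haplotype has a
missing within-strain cell.

## What the generator emulates — and what it does not

`simulation_config()` defaults are the survey-like conditions: 115 biallelic
sites; 3 strain founders placed at exact Hamming distances 43/14/37
(p ≈ 0.374/0.122/0.322, mirroring observed between-strain divergence; the
smallest was raised from 13 to 14 steps because the three pairwise distances
of binary strings must have an even sum); per-strain haplotype pools of
19/44/3 built by mutating the founder at Poisson(1.5) uniformly chosen
sites; right-skewed pool frequencies (1–6 dominant haplotypes carrying 93%
of the mass); per-locality lineage structure with 90% dominant-strain
fidelity; infected read counts negative binomial with mean 3,500 and
dispersion 1 (the observed per-individual median mapped-read count motivates
the mean); uninfected contamination Poisson(0.2) — the real contamination
distribution is unobservable, this is a modeling choice; read lengths 30–87
bp with ≥ 90% above 80 bp; per-site depths Poisson with mean 5.5, which
yields roughly 60% complete-case retention among infected individuals, the
retention seen in real data; and PCR labels with sensitivity 0.96 and
specificity 0.98 (assay error rates are not published; these are realistic
choices, and tests of calibration behavior set both to 1).

Deliberately not emulated: the wet-lab GBS protocol (digestion, barcodes,
size selection), base-level sequencing error (per-site depths support the
true allele only, so calling fidelity tests isolate the calling logic),
linkage between read counts and depths beyond infection status, and
demographic history within strains (the star-like cloud is a phenomenological
stand-in, not a coalescent simulation). Consequently, passing tests show the
*pipeline logic* is correct under the planted statistical structure; they do
not validate robustness to sequencing error, index hopping, uneven coverage
or reference bias in real data.

One emergent property of the generative model is worth naming: Poisson
mutation tails occasionally place a pool haplotype beyond the connection
limit from every other haplotype. Such haplotypes fragment into singleton
components — exactly the phenomenology of rare strains in real surveys — so
strain-recovery checks in the test suite compare planted and inferred
assignments over individuals in *major* components and treat fragments as
rare strains, rather than demanding that the partition match on every
individual.

## Problem sizes and reproducibility

All randomness flows from one integer seed per generator call; substreams
(founders, truth, read counts, depths, PCR) are derived deterministically
from it, and every seeded artifact is byte-reproducible, including pipeline
output checksums (`run_pipeline()` writes an md5 manifest; no timestamps
appear in any output). The test suite exercises cohorts of 2,000 individuals
for detection calibration (20 replicates), the same scale for strain
recovery, and 300 individuals for calling fidelity — sizes chosen to match
the survey's locality structure while keeping the whole suite under a
minute of compute.

## Known limitations

* The connection-limit estimator is this package's own transcription of the
  statistical-parsimony idea; it matches an independently coded oracle and
  reported TCS-era limits at common sequence lengths, but it is not the
  original program's code path. The manual override exists for exactly this
  reason.
* The haploid model cannot represent multiple infections; individuals
  carrying two strains are usually lost at complete-case filtering, which
  biases haplotype counts toward singly-infected hosts.
* Divergence summaries and the PCoA operate on distinct haplotypes; highly
  uneven multiplicities can make haplotype-level and individual-level
  pictures differ (the weighting flag exposes this).
* The packaged survey table is a verbatim transcription, quirks included
  (one locality lists more haplotyped than infected individuals; the loader
  warns and keeps it). Aggregates computed from it are reproduced exactly
  rather than "corrected".
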