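---
title: "Methods: miRNA gene variability, target-site scanning and kinship mixed-model association"
author: "mirvar package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA gene variability, target-site scanning and kinship mixed-model association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirvar)
```

## The problem this package addresses

Mature microRNAs repress mRNA expression by binding, through their
seed (nucleotides 2-8 from the 5' end), to complementary sites in
3'UTRs. Because the seed determines target recognition, polymorphisms
inside it are expected to be selected against more strongly than
polymorphisms elsewhere in the hairpin, and the resulting SNP-density
gradient (*precursor* > *mature* > *seed*) is a signature of purifying
selection on miRNA genes. `mirvar` implements the full desk-side
analysis around that question for a population of sequenced genomes:

1. canonical seed-match prediction (7mer-m8 and 8mer sites) in spliced
   3'UTRs, with strand-aware projection of sites onto the genome and
   intersection with SNPs;
2. classification of every miRNA-overlapping SNP into hairpin
   sub-regions and summaries of cross-population sharing and
   allele-frequency spectra;
3. region-wise SNP-density statistics, per-mature-position profiles,
   flanking-bin comparisons and a Mann-Whitney rank-sum test;
4. univariate kinship mixed-model association between miRNA SNP
   genotypes and expression or quantitative phenotypes, with
   likelihood-ratio testing, Benjamini-Hochberg FDR, hypergeometric
   pathway enrichment, Welch tests and 2^-ddCt qPCR quantification;
5. seeded synthetic-data generators that emulate all of the above with
   known ground truth, so every stage is testable without external
   data.

## Representation and coordinate conventions

All intervals are held in `GRanges`/`IRanges` containers, i.e. 1-based
and closed on both ends, the native Bioconductor convention; GFF3 and
VCF coordinates therefore pass through unchanged, and BED's 0-based
half-open coordinates are converted at the boundary. Mature-arm
sequences are stored 5'->3' in miRNA orientation, so the *mature
position* p of a genomic coordinate is `g - start + 1` on the plus
strand and `end - g + 1` on the minus strand; p = 1 is the anchor
nucleotide held by the Argonaute MID domain. RNA input (U) is
normalised to the DNA alphabet on read and the original alphabet
recorded.

## The site scanner

A 7mer-m8 site is an exact, Watson-Crick match of the reverse
complement of the 7-nt seed in the spliced 3'UTR. An occurrence is
promoted to 8mer when the base immediately 3' of the match on the mRNA
(target position t1) is an adenine, in which case the reported site is
extended by that base. Decisions worth making explicit:

* classification is strictly by the t1 base; both labels are always
  emitted so either counting convention can be reproduced downstream;
* an occurrence flush with the UTR end (no t1 base) stays 7mer-m8;
* overlapping occurrences are all reported and per-pair counts count
  occurrences, not merged intervals;
* matching is case-insensitive and any window containing an ambiguous
  base never matches (`matchPattern` with `fixed = TRUE`);
* UTRs are scanned as **spliced** sequence and sites are then projected
  through the transcript blocks onto the genome (a site spanning a
  block junction yields two or more genomic blocks). Whether a
  genomic or spliced search is more faithful to upstream tools is not
  decidable in general; spliced sequence is the biologically coherent
  choice and the projection makes the result usable either way.

The scanner is validated against a brute-force sliding-window oracle
on hundreds of random (seed, UTR) pairs and against generator truth
(planted motifs are recovered exactly; see below).

## Region classification and density statistics

Every position of a hairpin belongs to exactly one of five classes:
`ANCHOR` (p = 1), `SEED` (p in 2..8), `SUPPLEMENTARY` (p in 13..18),
`MATURE_OTHER` (any other arm position), `PRECURSOR` (hairpin outside
the arms). The coarse three-way labels collapse the three non-seed arm
classes into *mature*. The supplementary-pairing window is defined as
positions 13-18; 13-16 is sometimes quoted for 3'-compensatory
pairing, but the wider window is used consistently here. The annotated
hairpin interval is treated as the whole precursor universe; flanking
pri-miRNA sequence beyond the annotation is "flank".

The density statistic is D = Nr x 100 / Lr, SNPs per 100 bp of region
universe, where the seed universe is 7 bp per arm, the mature universe
the arm length minus the seed, and the precursor universe the hairpin
minus the arms; the three always partition the hairpin total.
Flanking-bin profiles pool ten 100-bp bins on each side of every
hairpin; *upstream* is by default the 5' flank in the hairpin's
transcriptional orientation (bin -1 abuts the 5' end on both strands),
with a `"genomic"` switch for left/right orientation instead. Bins
overlapping a neighbouring hairpin are kept. For the seed-vs-mature
rank-sum comparison the sampling unit is the per-arm density (one seed
and one mature density per arm, compared unpaired); this construction
is a package choice, as such comparisons can also be built per locus
or per position. The rank-sum test itself uses mid-ranks for ties,
exact enumeration when n1 + n2 <= 20 without ties, and otherwise a
normal approximation with tie and continuity correction; the exact
branch is validated against full permutation enumeration.

Published percentage summaries mix rounding conventions, so
`percentValue()` offers both `round` and `truncate` modes (e.g.
139/370 renders as 37.56 only under truncation, while 43/285 renders
as 15.09 under rounding).

## The kinship mixed model

Association uses the univariate model

$$\mathbf{y} = \mathbf{W}\boldsymbol\alpha + \mathbf{x}\delta +
\mathbf{u} + \boldsymbol\varepsilon,\qquad
\mathbf{u} \sim \mathrm{MVN}_n(0,\ \lambda\tau^{-1}\mathbf{K}),\qquad
\boldsymbol\varepsilon \sim \mathrm{MVN}_n(0,\ \tau^{-1}\mathbf{I}),$$

where W holds the intercept and fixed covariates, x the SNP dosage,
delta the allele substitution effect, K the genomic kinship and lambda
the ratio of genetic to residual variance. Choices:

* **Kinship** is the centered construction K = Xc Xc' / p over the
  genome-wide dosage matrix, with per-SNP mean imputation of missing
  genotypes. For the tested SNP itself, individuals with missing
  dosage are excluded from that test.
* **Estimation** is maximum likelihood (not REML) so that nested fits
  are comparable by a likelihood-ratio test: the statistic
  2(logL1 - logL0), floored at zero, is referred to chi-square with
  1 df.
* **Numerics**: K is eigendecomposed once per kinship (small negative
  eigenvalues within tolerance are clamped to zero; anything worse is
  an error); data are rotated so the covariance is diagonal and each
  trial lambda reduces to weighted least squares with weights
  1/(lambda d_i + 1). The profile likelihood is maximised over
  log10(lambda) in [-5, 5] by a 0.1-step grid followed by
  `optimize()` refinement to ~1e-6; the grid keeps the refinement out
  of local optima, and a fit at the lower edge is effectively
  lambda = 0 (no genetic variance). With K = I the estimates coincide
  with ordinary least squares, and the reported log-likelihood is
  tested to equal the direct multivariate-normal density at the
  returned parameters.
* **FDR family**: q-values are Benjamini-Hochberg within one scan
  (all phenotypes tested for one SNP in one tissue), matching how
  per-SNP q-value blocks are usually reported; a global family can be
  formed by pooling scans before adjustment.
* **Fixed effects** are reference-coded with the first observed level
  as baseline; rank-deficient designs are an error rather than a
  silent drop.

Candidate-target filtering admits a probe to a SNP's test list only if
(1) its gene carries at least one canonical site for an arm of the
SNP's miRNA, (2) the (miRNA, gene) pair appears in the supplied
experimentally-validated interaction table, and (3) the probe was
called present in at least 50% of samples. A probe present in exactly
half the samples is retained: only probes below threshold in *more*
than half are discarded. Both filters can be switched off for a
condition-free scan of the whole expressed transcriptome.

## qPCR quantification

`ddctQuantify()` averages technical triplicates per (sample, gene),
takes dCt as target minus the arithmetic mean of the control-gene mean
Cts (equivalent to normalising expression by the geometric mean of the
controls — a deliberate choice, since multi-control combination is
convention-dependent), references ddCt to the mean dCt of the
calibrator genotype group, and compares groups by Welch's t-test on
log2 Rq = -ddCt.

## What the synthetic generators emulate

`simConfig()` defaults encode the study conditions the package is
exercised against:

* 370 miRNA loci with 409 mature arms (39 two-arm loci), arms of
  20-24 nt inside hairpins of 60-110 bp, on both strands;
* per-bp SNP rates set to the observed per-region densities
  (12/2863 for seed, 52/6053 for mature, 221/22229 for precursor) and
  a flank rate of 0.0238/bp, reproducing the roughly 2.6-fold excess
  of flanking over miRNA-body density;
* four populations with an all-population sharing probability of
  0.15 and rare-skewed Beta allele frequencies (mean 0.12 for
  mature/seed, 0.15 for precursor SNPs);
* 3'UTRs carrying planted seed-match sites (one third 8mer) for a
  small set of target arms. UTR backgrounds are **rejection-sampled**
  so those arms' motifs occur nowhere except the planted positions:
  site recovery is then exact, which removes stochastic flakiness
  from scanner tests (masking would only make collisions rare, not
  impossible);
* a five-sire half-sib cohort of 345 individuals, gene-dropped from
  sire haplotypes and unrelated dams, heritability 0.3, allele
  substitution effect 0.4508 (the scale of reported expression
  effects), an expression fold of 1.9 between homozygous genotype
  groups in the repressive direction, and triplicate Ct tables with
  technical SD 0.15.

The generators do **not** model linkage disequilibrium beyond family
structure, demographic history, hairpin secondary structure, probe
cross-hybridisation, or genotyping error. Passing tests therefore
demonstrate correctness of the arithmetic and calibration of the
statistics under the stated generating model, not robustness to every
artefact of real data.

## Problem sizes used in validation

The test suite runs the scanner oracle on 500 random (seed, UTR)
pairs; the exact rank-sum branch against full enumeration for
n1 + n2 <= 12; the null calibration of the LRT on 1000 replicate
phenotypes of a 300-individual cohort (observed type-I error within
0.05 +/- 0.02); parameter recovery over 200 replicates at delta =
0.4508 (estimate within 2 se of truth in at least 95% of replicates);
and the full simulate-scan-annotate-density loop at 60-80 loci. These
sizes were chosen to make the checks statistically meaningful while
keeping the default suite comfortably fast on one core.

## Known limitations

* The density ordering *precursor* > *mature* is a small effect at the
  published rates; single synthetic replicates at 370 loci reproduce
  it only in a clear majority of runs, which the tests assert, rather
  than in every run.
* The mixed model is univariate; no multi-trait or permutation-based
  FDR machinery is provided.
* The scanner is restricted to canonical 7mer-m8/8mer geometry — no
  6mer, 7mer-A1, 3'-compensatory or context-score modelling.
* Pathway enrichment consumes user-supplied gene sets; no live
  database retrieval is performed, and probe-to-gene mapping is an
  input table.
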