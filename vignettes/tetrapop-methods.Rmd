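---
title: "Methods: tetraploid genotyping, inheritance-mode tests, and sweep scans"
author: "tetrapop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tetraploid genotyping, inheritance-mode tests, and sweep scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetrapop)
```

# Scope

`tetrapop` implements a population-genomic workflow for an autotetraploid
plant population sequenced as 12 individuals (48 chromosomes): likelihood
genotyping of tetraploid dosages from read pileups, an alignment-based
error-rate estimator, tetraploid diversity statistics and site frequency
spectra (SFS), coalescent machinery to discriminate tetrasomic from
disomic inheritance, and a selective-sweep scan combining an SFS composite
likelihood ratio with diversity outliers. A synthetic-data generator
reproduces the statistical structure of such a study so every stage is
testable without sequencing data.

# The genotyping model

At a biallelic site with alleles $A_1, A_2$, a tetraploid genotype carries
$i$ copies of $A_1$ and $j = 4 - i$ of $A_2$. Given the pileup $D$ of read
bases $b$ for one individual,

$$P(D \mid G) = \prod_b P(b \mid G), \qquad
  P(b \mid G) = \frac{i}{4} P(b \mid A_1) + \frac{j}{4} P(b \mid A_2),$$

with $P(b \mid a) = 1 - e$ when $b = a$ and $e/3$ otherwise, $e$ being the
individual's combined sequencing-plus-mapping error rate. Splitting the
error uniformly over the three wrong bases is the simplest completion
consistent with a single scalar $e$, and makes $\sum_b P(b\mid G) = 1$ for
every genotype. The maximum-likelihood genotype among the five dosages is
accepted when its log-odds over the runner-up reaches 2; we use base-10
logs, the common genotyping convention, which makes the threshold
stringent (a 100:1 likelihood ratio). Sites enter genotyping only when
every individual has coverage strictly above 4x and at most two variant
bases are seen across the sample; a pooled binomial test at rate $e/3$
separates real variants from error noise. Sites where any individual
fails the log-odds threshold are excluded from frequency-based analyses,
keeping the sample size fixed at 48 chromosomes.

The error rate is estimated per individual from three-way alignments:
divergence of the focal reads from a distant outgroup includes both
evolutionary divergence and error, while divergence of the error-free
sister reference from the same outgroup over the same columns includes
divergence only; the difference estimates $e$, clamped at zero with a
warning when negative.

# Diversity statistics

Watterson's estimator is $\hat\theta_W = S / (a_{n-1} L)$ with
$a_{47} \approx 4.438$ for $n = 48$. Nucleotide diversity is expected
gametic heterozygosity,
$\pi = \tfrac{1}{L}\sum_\text{sites} \tfrac{n}{n-1}\,(1 - \sum_a p_a^2)$,
computed from chromosome-level allele frequencies; the $n/(n-1)$ factor is
the standard unbiased sample correction and makes $\pi$ equal the mean
pairwise Hamming distance between chromosomes. $F_{ST}$ uses the
Weir–Cockerham variance components with each tetraploid individual
contributing four independent gametes (no within-individual correlation
term) — consistent with tetrasomic inheritance — and multi-site estimates
are ratios of summed components. Note the estimator's known small-sample
behaviour: for identical allele frequencies it sits at $-1/(n_c - 1)$,
just below zero, rather than exactly zero.

Sites are polarized by requiring the two reference species to agree; the
shared base is taken as ancestral. Sites where the outgroups disagree, or
where the shared base is absent from the sample, stay unpolarized: they
are excluded from the unfolded SFS but retained in the folded SFS.
CDS sites are classified synonymous or non-synonymous by swapping the two
alleles in the reference codon and comparing translations.

# Coalescent simulation and inheritance mode

Time is measured in units of $4N$ generations (the `ms` convention): with
$k$ lineages the total coalescence rate is $k(k-1)$ and mutations fall at
rate $\theta$ per lineage per unit time, so $E[S] = \theta\,a_{n-1}$ and
$E[\pi] = \theta$ for a locus-wide $\theta = 4N\mu$. Tetrasomic
inheritance draws 48 chromosomes from one pool and partitions them
randomly into 12 individuals. Disomic inheritance simulates two isolated
pools of 24 that merge into the ancestral population at $t_d$ (time since
genetic diploidization), and gives each individual two chromosomes from
each pool. The default $t_d$ grid is 0.2 to 1.0 in steps of 0.2. Genotype
dosage expectations under tetrasomy with bivalent pairing are
binomial$(4, p)$; double reduction is not modelled.

Old disomic inheritance leaves two fingerprints: SNPs fixed between
homeolog pools appear at frequency 24/48, and every individual is duplex
(AAaa) at them. `compareSFS()` contrasts per-SNP folded frequency classes
by a two-sided Mann–Whitney U test with tie correction, and
`compareGenotypeClasses()` compares dosage-class proportions with a
chi-square and flags duplex excess.

A caveat we document rather than hide: SNPs pooled across replicate runs
of one locus share genealogies within runs, so they are not independent
observations. The resulting inflation of the Mann–Whitney statistic grows
with the per-run SNP count and does not vanish with more runs. Desk-scale
analyses here therefore use small per-locus $\theta$ (0.2–1), where pooled
SNPs are quasi-independent and the test is close to nominally calibrated;
direction and power checks (duplex excess, rejection of disomic models)
are insensitive to this choice. When observed data at study-scale
$\theta$ are compared against pooled-run expectations (as the pipeline
does), the pool must contain many more runs than the observed data has
genes, so that pool-side Monte-Carlo noise is negligible; this is the
same reason a study-scale analysis needs pools of hundreds of thousands
of runs. The pipeline default is 3,000 runs per model for 60 genes.

# The sweep scan

Each gene's polarized SNPs are split into consecutive 100-SNP windows
(a trailing partial window is scored but flagged). A window with unfolded
class counts $m_c$ (total $m$) is scored against the genome-wide spectrum
proportions $q_c$ with the multinomial composite likelihood ratio

$$\mathrm{CLR} = 2 \sum_c m_c \ln\frac{m_c / m}{q_c},$$

a G statistic: zero when the window matches the background and large when
window mass sits in classes rare genome-wide, notably the high-frequency
derived classes a sweep inflates. Background classes with zero mass that
a window occupies receive a 0.5 pseudo-count before normalization. The
parametric spatial sweep model of SweepFinder-style scans (sweep location
and strength) is deliberately out of scope. A gene is a sweep candidate
when at least one window reaches the top 5% of the genome-wide window CLR
distribution *and* its $\pi$/bp falls in the bottom 5%; quantiles are
empirical order statistics, inclusive of ties. Because the G statistic is
linear in the window SNP count, gene-level maximum CLR retains a mild
structural association with $S$ (and hence $\pi$) in fixed-length
synthetic genes; `checkIndependence()` reports the observed $R^2$
alongside the scan. Gene-set enrichment among candidates uses a one-sided
Fisher's exact test on the 2x2 membership-by-candidacy table, whose
p-value equals the hypergeometric tail.

# The synthetic study generator

`simConfig()` defaults define the emulated study: 12 tetraploid
individuals, per-silent-site $\theta = 0.043$, focal-vs-sister divergence
$8.7\times10^{-4}$ / $2.7\times10^{-4}$ / $9.6\times10^{-4}$ for
synonymous, non-synonymous and intronic sites, mean depth 25x (Poisson
per site and individual), and base error 0.15%, the midpoint of the
0.1–0.2% range the error estimator recovers. The outgroup carries
10-fold larger divergence, a realistic contrast between a close sister
species and a distant congener. Three-species alignments are gap-free by
construction (no indels), so alignment columns map 1:1 to gene positions.

Within-gene recombination matters for the sweep scan: with a single
genealogy per gene, neutral 100-SNP windows are so correlated that their
CLR noise swamps any sweep signal. The generator therefore defaults to a
population recombination rate $\rho$ per bp equal to the silent-site
$\theta$ ($\rho/\theta = 1$, the order of magnitude estimated for
outcrossing *Arabidopsis*), implemented by the independent-segments
approximation: Poisson$(\rho L)$ uniform breakpoints cut the gene into
segments with independent genealogies, free recombination between
segments and none within. Deme labels and individual assignment are
shared across segments. `coalescentSample()` itself remains
recombination-free, matching the single-locus `ms` usage that the
inheritance simulations mirror.

Sweeps are emulated by a star-like replacement: the chromosome carrying
the most derived alleles is copied over $\lceil 0.9 \times 48 \rceil$
chromosomes. This produces exactly the two signals the scan intersects —
reduced $\pi$ and excess high-frequency derived alleles — without
modelling the forward selection dynamics, which the analysis never uses.
What passing tests show is therefore that the scan detects this
footprint; they do not validate power against structured sweep histories,
background selection, or demography.

# Numerical choices and degenerate inputs

* Zero-depth pileups, monomorphic SFS inputs, zero-length genes, all-gap
  alignments, and fewer than two models or 20 genes are errors, not
  silent results.
* Error estimates below zero are clamped with a flag; identity at the
  80% filter boundary is kept (the filter excludes only identities
  strictly below 80%).
* A fully degenerate scan (all genes identical) is refused rather than
  returning an all-candidate list.
* All generators take explicit seeds; the pipeline derives per-stage
  seeds from one master seed so stages are individually reproducible.

# Problem sizes used in tests

The shipped test-suite and acceptance analyses are scaled for a desk run:
coalescent expectations use 1,200–3,000 replicates; the diversity-doubling
comparison 2,000 replicates per ploidy; inheritance pools 1,500–5,000
runs per model (the study-scale equivalent would be 500,000); and the
sweep-recovery experiment 1,000 genes with 20 injected sweeps at 2%
incidence. Oracles include closed-form coalescent expectations,
hypergeometric dosage sampling, brute-force pairwise-difference and
variance-component implementations, and an independent msprime run on a
small configuration.

# Limitations

* No indels, multi-allelic sites, read mapping, base-quality weighting or
  phasing; pileups are the entry point.
* No migration between homeolog pools and no mixed-pairing inheritance
  models beyond the $t_d$ grid; no double reduction.
* The sweep emulation is a haplotype replacement, not a structured
  coalescent; the scan's false-negative behaviour under partial or soft
  sweeps is untested.
* Mann–Whitney comparisons of pooled-run SNP collections are
  anti-conservative at large per-locus $\theta$ (see above).
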