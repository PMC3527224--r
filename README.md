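# tetrapop

Population genomics for autotetraploids: tetraploid genotype calling from
read pileups, diversity statistics and site frequency spectra (SFS),
coalescent tests of tetrasomic vs. disomic inheritance, and a
selective-sweep scan — with a synthetic-data generator that emulates a
full resequencing study of 12 tetraploid individuals (48 chromosomes) so
the whole pipeline runs and is testable without external data.

## Who this is for

Population geneticists working with autopolyploid resequencing data face
three problems that diploid toolchains do not solve: genotypes are
dosages (AAAA, AAAa, AAaa, Aaaa, aaaa), the mode of inheritance
(tetrasomic vs. disomic) must be established before any inference, and
genome scans need tetraploid-aware diversity statistics. `tetrapop`
implements that stack for the canonical design of an outcrossing
autotetraploid population sample aligned to a diploid sister reference
with a second, more distant outgroup.

## The models at the core

**Genotyping.** At a biallelic site the likelihood of a pileup `D` for a
genotype with `i` copies of allele A1 (`i + j = 4`) is

    P(D|G) = prod_b P(b|G),   P(b|G) = (i/4) P(b|A1) + (j/4) P(b|A2)

with `P(b|a) = 1 - e` for a match and `e/3` otherwise; the ML genotype is
accepted at log10-odds >= 2 over the runner-up. The error rate `e` is
estimated per individual as the excess divergence of its reads, relative
to the sister reference, from a shared outgroup.

**Diversity.** Watterson's `theta_W = S/(a_{n-1} L)`; `pi` as expected
gametic heterozygosity `(n/(n-1)) (1 - sum p_a^2)` per site; pairwise
`F_ST` by Weir–Cockerham variance components with each tetraploid
contributing four gametes.

**Inheritance mode.** A seedable Kingman coalescent (ms time scale)
simulates one panmictic pool of 48 chromosomes (tetrasomic) or two
isolated homeolog pools of 24 merging at time `t_d` (disomic), assembles
12 tetraploid individuals per model, and compares observed folded SFS and
dosage classes against the pooled expectations (Mann–Whitney U;
chi-square with a duplex-excess flag).

**Sweep scan.** Genes are cut into 100-SNP windows scored against the
genome-wide unfolded SFS with the composite likelihood ratio
`CLR = 2 sum_c m_c ln((m_c/m)/q_c)` (a G statistic); candidates are genes
with a top-5% window CLR *and* bottom-5% pi/bp, and gene-set enrichment
among candidates uses one-sided Fisher's exact tests.

## Worked example

Simulate a 40-gene study (5% of genes carry injected sweeps), test the
mode of inheritance, and run the sweep scan:

```r
library(tetrapop)
cfg <- pipelineConfig(nGenes = 40, seed = 7, sweepFraction = 0.05,
                      tdGrid = c(0.2, 1.0))
out <- runPipeline(cfg, outDir = "demo_run")
out$inheritance
#>          model           U             p    verdict
#>     tetrasomic  6611793275  5.646327e-01 consistent
#>  disomic_td0.2 10648299756 3.036561e-122   rejected
#>    disomic_td1 12214904523  6.399456e-23   rejected
subset(out$scan, candidate)[, c("gene_id", "maxClr", "pi", "swept")]
#>   gene_id   maxClr          pi swept
#>  gene0031 248.7159 0.005993881  TRUE
#>  gene0038 275.4937 0.006777598  TRUE
```

The tetrasomic model is the only one consistent with the simulated data
(the two disomic pools are rejected at p << 0.01), and both flagged sweep
candidates are genes that truly carry injected sweeps: their maximum
window CLR (~250–275) sits in the top 5% genome-wide while their pi
(~0.006/bp) sits in the bottom 5%, an order of magnitude below the
neutral mean (`mean(out$summaries$pi)` ≈ 0.041, matching the generator's
silent theta = 0.043). All stage outputs (gene models, alignments, site
frequencies, per-gene summaries, verdicts, scan table) are written to
`demo_run/` with a seed-stamped manifest and checksums.

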