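Package: tetrapop
Title: Population Genomics of Autotetraploids: Genotyping, Diversity,
    Inheritance Mode, and Selective-Sweep Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for population-genomic analysis of autotetraploid
    resequencing data. Implements a likelihood-based tetraploid genotype
    caller for per-site read pileups with an alignment-based estimator of
    the combined sequencing and mapping error rate; tetraploid diversity
    statistics (Watterson's theta, nucleotide diversity as gametic
    heterozygosity, Weir-Cockerham F_ST) and site-frequency spectra with
    outgroup polarization; coalescent simulation of tetrasomic and disomic
    (homeolog-split) inheritance with statistical tests that discriminate
    the two from observed spectra and genotype classes; a selective-sweep
    scan scoring SNP windows with a composite likelihood ratio against the
    genome-wide spectrum combined with diversity outliers; and a synthetic
    data generator that emulates the full study design (tetraploid
    population samples, three-species alignments, error-bearing pileups)
    so every stage is testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
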