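# Independent oracle implementations used to cross-check the package's
# estimators. These deliberately share no code with the implementations
# they verify.

# mean pairwise Hamming distance over all chromosome pairs, per bp
oraclePiPairwise <- function(hapmat, L) {
  n <- nrow(hapmat)
  tot <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      tot <- tot + sum(hapmat[i, ] != hapmat[j, ])
    }
  }
  tot / choose(n, 2) / L
}

# Weir-Cockerham two-population estimator for gametic data, written as a
# direct transcription of the mean-squares definitions
oracleFst <- function(c1, c2, n1, n2) {
  S <- length(c1)
  n1 <- rep_len(n1, S); n2 <- rep_len(n2, S)
  sumA <- 0; sumT <- 0; perSite <- numeric(S)
  for (s in seq_len(S)) {
    freqs <- c(c1[s] / n1[s], c2[s] / n2[s])
    sizes <- c(n1[s], n2[s])
    nTot <- sum(sizes)
    pBar <- sum(sizes * freqs) / nTot
    MSP <- sum(sizes * (freqs - pBar)^2) / (2 - 1)
    MSG <- sum(sizes * freqs * (1 - freqs)) / (nTot - 2)
    nC <- (nTot - sum(sizes^2) / nTot) / (2 - 1)
    a <- (MSP - MSG) / nC
    tot <- a + MSG
    perSite[s] <- if (tot > 0) a / tot else NA_real_
    sumA <- sumA + a
    sumT <- sumT + tot
  }
  list(fst = sumA / sumT, perSite = perSite)
}

# log10 multinomial-free genotype likelihood by direct per-read product
oracleGenotypeLL <- function(counts, alleles, e) {
  bases <- c("A", "C", "G", "T")
  pOf <- function(b, allele) if (b == allele) 1 - e else e / 3
  sapply(4:0, function(i) {
    tot <- 0
    for (b in bases) {
      pb <- (i / 4) * pOf(b, alleles[1]) + ((4 - i) / 4) * pOf(b, alleles[2])
      tot <- tot + counts[b] * log10(pb)
    }
    tot
  })
}

# G statistic of window counts vs background proportions, contingency form
oracleGStat <- function(windowCounts, bgCounts, pseudo = 0.5) {
  m <- tabulate(windowCounts, nbins = length(bgCounts))
  bg <- as.numeric(bgCounts)
  bg[m > 0 & bg == 0] <- pseudo
  q <- bg / sum(bg)
  expected <- sum(m) * q
  keep <- m > 0
  2 * sum(m[keep] * log(m[keep] / expected[keep]))
}

# run a small msprime simulation (same time scale: coalescence rate
# k(k-1) per 4N generations, locus mutation rate theta) and return mean S
# and mean pairwise diversity over replicates
msprimeOracle <- function(n, theta, reps, seed) {
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys, json, msprime",
    "n, theta, reps, seed = int(sys.argv[1]), float(sys.argv[2]), int(sys.argv[3]), int(sys.argv[4])",
    "S = 0; pi = 0.0",
    "for r in range(reps):",
    "    ts = msprime.sim_ancestry(samples=n, ploidy=1, population_size=0.5, random_seed=seed + 2*r + 1)",
    "    mts = msprime.sim_mutations(ts, rate=theta, random_seed=seed + 2*r + 2, discrete_genome=False)",
    "    S += mts.num_sites",
    "    pi += mts.diversity(span_normalise=False)",
    "print(json.dumps({'meanS': S / reps, 'meanPi': pi / reps}))"
  ), script)
  out <- suppressWarnings(system2("python",
    c(script, n, theta, reps, seed), stdout = TRUE, stderr = FALSE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) return(NULL)
  jsonlite::fromJSON(out[length(out)])
}

# quick gene + config fixtures
fixtureGene <- function(L = 900L, id = "geneX") {
  L <- as.integer(3 * ceiling(L / 3))   # keep the single CDS in frame
  new("GeneModel", geneId = id, length = as.integer(L),
      features = data.frame(start = 0L, end = as.integer(L),
                            kind = "CDS", frame = 0L),
      chrom = "scaffold_1", strand = "+")
}

fixtureConfig <- function(...) simConfig(nGenes = 1L, seed = 42L, ...)
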