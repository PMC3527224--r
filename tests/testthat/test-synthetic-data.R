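test_that("zero divergence yields three identical sequences", {
  gene <- fixtureGene(300)
  cfg <- fixtureConfig(divSyn = 0, divNonsyn = 0, divIntron = 0)
  tr <- simulateTriple(gene, cfg, seed = 1)
  sq <- as.character(tr@alignment)
  expect_identical(sq[["focal"]], sq[["sister"]])
  expect_identical(sq[["focal"]], sq[["outgroup"]])
  badGene <- gene
  badGene@length <- 0L
  expect_error(simulateTriple(badGene, cfg), "zero-length")
})

test_that("sister divergence tracks class-specific rates", {
  # elevated rate at a known count of synonymous sites: binomial check
  gene <- fixtureGene(9000)        # single CDS: 3000 third positions
  cfg <- fixtureConfig(divSyn = 0.05, divNonsyn = 0, divIntron = 0)
  tr <- simulateTriple(gene, cfg, seed = 7)
  cls <- siteClassMap(gene)
  f <- strsplit(as.character(tr@alignment[["focal"]]), "")[[1]]
  s <- strsplit(as.character(tr@alignment[["sister"]]), "")[[1]]
  synDiff <- sum(f[cls == "synonymous"] != s[cls == "synonymous"])
  expect_equal(sum(cls == "synonymous"), 3000)
  expect_lt(abs(synDiff - 150), 3 * sqrt(3000 * 0.05 * 0.95))
  expect_equal(sum(f[cls == "nonsynonymous"] != s[cls == "nonsynonymous"]), 0)

  # default synonymous rate recovered over replicates within binomial CI
  cfg2 <- fixtureConfig()
  gene2 <- fixtureGene(10002)
  set.seed(11)
  nSyn <- 0; nDiff <- 0
  cls2 <- siteClassMap(gene2)
  syn <- cls2 == "synonymous"
  for (r in 1:150) {
    tr2 <- simulateTriple(gene2, cfg2)
    f2 <- strsplit(as.character(tr2@alignment[["focal"]]), "")[[1]]
    s2 <- strsplit(as.character(tr2@alignment[["sister"]]), "")[[1]]
    nSyn <- nSyn + sum(syn)
    nDiff <- nDiff + sum(f2[syn] != s2[syn])
  }
  expect_lt(abs(nDiff - nSyn * 8.7e-4), 3 * sqrt(nSyn * 8.7e-4))
})

test_that("population samples follow coalescent and assembly expectations", {
  gene <- fixtureGene(1000)
  cfg0 <- fixtureConfig(thetaSite = 0)
  s0 <- simulatePopulation(gene, cfg0, seed = 2)
  expect_equal(ncol(haplotypes(s0)), 0)

  # mean S near theta * L * a47 (theta_site 0.005 -> locus theta 5.01)
  cfg <- fixtureConfig(thetaSite = 0.005)
  a47 <- sum(1 / (1:47))
  set.seed(3)
  S <- replicate(300, ncol(haplotypes(simulatePopulation(gene, cfg))))
  expect_lt(abs(mean(S) - 0.005 * 1002 * a47),
            3 * stats::sd(S) / sqrt(length(S)))

  # disomic assembly: two chromosomes from each homeolog pool
  sd1 <- simulatePopulation(gene, cfg, inheritanceModel("disomic", 1.0),
                            seed = 4)
  comp <- table(sd1@individual, sd1@deme)
  expect_true(all(comp == 2L))
})

test_that("sweep injection lowers pi and raises high-frequency mass", {
  gene <- fixtureGene(2000)
  cfg <- fixtureConfig(thetaSite = 0.02)
  s <- simulatePopulation(gene, cfg, seed = 5)
  k0 <- colSums(haplotypes(s))
  piBefore <- nucleotideDiversity(k0[k0 > 0 & k0 < 48], L = 2001)

  sw <- injectSweep(s, 0.9, seed = 6)
  k1 <- colSums(haplotypes(sw))
  piAfter <- nucleotideDiversity(k1[k1 > 0 & k1 < 48], L = 2001)
  expect_lt(piAfter, piBefore)
  expect_gt(sum(k1 >= 40 & k1 < 48), sum(k0 >= 40 & k0 < 48))

  # full replacement: monomorphic, pi = 0
  sw1 <- injectSweep(s, 1, seed = 7)
  kf <- colSums(haplotypes(sw1))
  expect_true(all(kf %in% c(0L, 48L)))
  expect_equal(nucleotideDiversity(kf[kf > 0 & kf < 48], L = 2001), 0)

  # single carrier (fraction -> 0+): sample unchanged
  swEps <- injectSweep(s, 1e-6, seed = 8)
  expect_identical(haplotypes(swEps), haplotypes(s))
  expect_error(injectSweep(s, 0), "carrierFraction")
})

test_that("pileups follow the genotype + uniform-error read model", {
  gene <- fixtureGene(60)
  cfg <- fixtureConfig(thetaSite = 0.05, meanDepth = 25, errorRate = 0)
  s <- simulatePopulation(gene, cfg, seed = 9)
  pu <- simulatePileups(s, cfg, seed = 10)
  # error-free: bases restricted to the two segregating alleles
  for (r in sample(nrow(pu), min(20, nrow(pu)))) {
    site <- which(s@positions == pu$pos[r])
    present <- c("A", "C", "G", "T")[
      which(c(pu$countA[r], pu$countC[r], pu$countG[r], pu$countT[r]) > 0)]
    expect_true(all(present %in% c(s@ancestralBase[site],
                                   s@derivedBase[site])))
  }

  # homozygous ancestral individuals at e = 0.0015: non-ancestral
  # fraction matches the error rate within a binomial CI
  cfgE <- fixtureConfig(thetaSite = 0.05, meanDepth = 80,
                        errorRate = 0.0015)
  s2 <- simulatePopulation(fixtureGene(600), cfgE, seed = 11)
  dos <- trueDosage(s2)
  pu2 <- simulatePileups(s2, cfgE, seed = 12)
  tot <- 0L; bad <- 0L
  for (r in seq_len(nrow(pu2))) {
    site <- which(s2@positions == pu2$pos[r])
    if (dos[pu2$individual[r], site] != 0L) next
    counts <- c(A = pu2$countA[r], C = pu2$countC[r],
                G = pu2$countG[r], T = pu2$countT[r])
    tot <- tot + sum(counts)
    bad <- bad + sum(counts[names(counts) != s2@ancestralBase[site]])
  }
  expect_gt(tot, 1e4)
  expect_lt(abs(bad - tot * 0.0015), 4 * sqrt(tot * 0.0015))

  # balanced duplex at high depth, no error: allele fraction near 1/2
  dup <- which(dos == 2L, arr.ind = TRUE)[1, ]
  cfgD <- fixtureConfig(thetaSite = 0.05, meanDepth = 4000, errorRate = 0)
  pu3 <- simulatePileups(s2, cfgD, seed = 13)
  row <- pu3[pu3$individual == dup[1] &
             pu3$pos == s2@positions[dup[2]], ]
  derCount <- row[[paste0("count", s2@derivedBase[dup[2]])]]
  depth <- row$countA + row$countC + row$countG + row$countT
  expect_lt(abs(derCount / depth - 0.5), 3 * sqrt(0.25 / depth))
})

test_that("generator output is identical under a fixed seed", {
  gene <- fixtureGene(500)
  cfg <- fixtureConfig(thetaSite = 0.02)
  s1 <- simulatePopulation(gene, cfg, seed = 99)
  s2 <- simulatePopulation(gene, cfg, seed = 99)
  expect_identical(haplotypes(s1), haplotypes(s2))
  expect_identical(s1@positions, s2@positions)
  t1 <- simulateTriple(gene, cfg, seed = 99)
  t2 <- simulateTriple(gene, cfg, seed = 99)
  expect_identical(as.character(t1@alignment), as.character(t2@alignment))
  p1 <- simulatePileups(s1, cfg, seed = 99)
  p2 <- simulatePileups(s2, cfg, seed = 99)
  expect_identical(p1, p2)
})

test_that("neutral folded spectrum matches the 1/i + 1/(n-i) shape", {
  pool <- simulateModel(inheritanceModel("tetrasomic"),
                        thetaSource = 10, runs = 2500, seed = 17)
  sfs <- buildSFS(pool@foldedCounts, n = 48, flavor = "folded")
  i <- 1:24
  expProp <- (1 / i + 1 / (48 - i))
  expProp[24] <- 1 / 24            # class n/2 counted once
  expProp <- expProp / sum(expProp)
  # large pooled sample: shape agreement rather than exact fit
  obs <- sfsCounts(sfs) / sum(sfsCounts(sfs))
  expect_gt(cor(obs, expProp), 0.999)
  expect_lt(max(abs(obs - expProp)), 0.01)
})
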