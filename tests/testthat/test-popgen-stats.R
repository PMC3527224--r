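test_that("outgroup agreement polarizes sites", {
  hit <- polarizeSite(c("A", "G"), "A", "A")
  expect_true(hit$polarized)
  expect_equal(hit$ancestral, "A")
  expect_equal(hit$derived, "G")

  expect_false(polarizeSite(c("A", "G"), "A", "G")$polarized)
  # outgroups agree on a base absent from the sample: unpolarized
  expect_false(polarizeSite(c("A", "G"), "C", "C")$polarized)
  expect_false(polarizeSite(c("A", "G"), "-", "A")$polarized)
})

test_that("codon swapping classifies CDS and intron sites", {
  gene <- new("GeneModel", geneId = "g", length = 12L,
              features = data.frame(start = c(0L, 6L), end = c(6L, 12L),
                                    kind = c("CDS", "intron"),
                                    frame = c(0L, NA)),
              chrom = "c", strand = "+")
  refSeq <- strsplit("GGAAAATTTTTT", "")[[1]]
  # third position GGA <-> GGG: Gly/Gly
  expect_equal(classifySite(gene, 2L, c("A", "G"), refSeq), "synonymous")
  # first position AAA <-> GAA: Lys/Glu
  expect_equal(classifySite(gene, 3L, c("A", "G"), refSeq),
               "nonsynonymous")
  expect_equal(classifySite(gene, 8L, c("A", "G"), refSeq), "intron")
})

test_that("SFS construction, folding and degenerate input behave", {
  one <- buildSFS(3L, n = 48, flavor = "unfolded")
  expect_equal(unname(sfsCounts(one)[3]), 1)
  expect_equal(sum(sfsCounts(one)), 1)

  folded45 <- buildSFS(45L, n = 48, flavor = "folded")
  expect_equal(unname(sfsCounts(folded45)[3]), 1)

  expect_error(buildSFS(c(3L, 48L), n = 48, flavor = "unfolded"),
               "monomorphic")

  # folding an unfolded SFS equals building folded directly
  set.seed(8)
  k <- sample(1:47, 500, replace = TRUE)
  viaFold <- foldSFS(buildSFS(k, 48, "unfolded"))
  direct <- buildSFS(k, 48, "folded")
  expect_equal(sfsCounts(viaFold), sfsCounts(direct))
})

test_that("Watterson's theta follows S / (a_{n-1} L)", {
  expect_equal(wattersonTheta(0, 48, 1000), 0)
  a47 <- sum(1 / (1:47))
  expect_equal(wattersonTheta(10, 48, 1000), 10 / (a47 * 1000))
  expect_equal(a47, 4.438, tolerance = 1e-3)
  expect_equal(wattersonTheta(10, 48, 2000),
               wattersonTheta(10, 48, 1000) / 2)
  expect_error(wattersonTheta(10, 48, 0), "L")
})

test_that("pi equals mean pairwise difference (gametic heterozygosity)", {
  expect_equal(nucleotideDiversity(integer(), L = 1000), 0)
  expect_equal(nucleotideDiversity(24, n = 48, L = 1000),
               2 * 24 * 24 / (48 * 47) / 1000, tolerance = 1e-12)
  expect_equal(nucleotideDiversity(24, n = 48, L = 1000), 5.106e-4,
               tolerance = 1e-4)

  # brute-force Hamming oracle on a random small sample
  set.seed(9)
  H <- matrix(rbinom(48 * 15, 1, 0.3), nrow = 48)
  k <- colSums(H)
  k <- k[k > 0 & k < 48]
  expect_equal(nucleotideDiversity(k, 48, 100),
               oraclePiPairwise(H[, colSums(H) %% 48 != 0, drop = FALSE],
                                100),
               tolerance = 1e-12)

  # allele-label swap invariance
  expect_equal(nucleotideDiversity(k, 48, 100),
               nucleotideDiversity(48 - k, 48, 100))
})

test_that("fixed differences require monomorphism and outgroup agreement", {
  expect_equal(countFixedDifferences(48L, "G", "A", "A"), 1)
  expect_equal(countFixedDifferences(47L, "G", "A", "A"), 0)
  expect_equal(countFixedDifferences(48L, "G", "A", "C"), 0)
  expect_equal(countFixedDifferences(c(48L, 48L, 47L), c("G", "T", "G"),
                                     c("A", "T", "A"), c("A", "T", "A")),
               1)
})

test_that("F_ST matches the variance-components oracle", {
  # fixed differences: F_ST = 1
  expect_equal(pairwiseFst(48, 0, 48, 48)$fst, 1)
  # identical frequencies: the W&C estimator sits just below zero
  # (exactly -1/(nc - 1) when MSP = 0), i.e. ~0 at this sample size
  near0 <- pairwiseFst(c(24, 10), c(24, 10), 48, 48)
  expect_lt(abs(near0$fst), 0.05)
  expect_lte(near0$fst, 0)

  set.seed(10)
  c1 <- rbinom(200, 48, runif(200, 0.05, 0.95))
  c2 <- rbinom(200, 48, runif(200, 0.05, 0.95))
  ours <- pairwiseFst(c1, c2, 48, 48)
  theirs <- oracleFst(c1, c2, 48, 48)
  expect_equal(ours$fst, theirs$fst, tolerance = 1e-12)
  expect_equal(ours$perSite, theirs$perSite, tolerance = 1e-12)

  # unequal sample sizes too
  ours2 <- pairwiseFst(c1, c2, 48, 36)
  theirs2 <- oracleFst(c1, c2, 48, 36)
  expect_equal(ours2$fst, theirs2$fst, tolerance = 1e-12)

  # a population against itself: estimate hovers at/below zero
  self <- pairwiseFst(c1, c1, 48, 48)
  expect_lte(self$fst, 0)
  expect_gt(self$fst, -0.05)
})

test_that("identity filter keeps >= 80% and drops below", {
  mkTriple <- function(nDiff, L = 100) {
    f <- paste(rep("A", L), collapse = "")
    s <- paste(c(rep("C", nDiff), rep("A", L - nDiff)), collapse = "")
    new("SpeciesTriple", geneId = "g",
        alignment = Biostrings::DNAStringSet(
          c(focal = f, sister = s, outgroup = f)),
        siteClass = rep("other", L))
  }
  expect_true(identityFilter(mkTriple(0))$keep)
  expect_false(identityFilter(mkTriple(25))$keep)   # 75% identity
  expect_true(identityFilter(mkTriple(20))$keep)    # exactly 80%
  gapped <- new("SpeciesTriple", geneId = "g",
                alignment = Biostrings::DNAStringSet(
                  c(focal = "---", sister = "---", outgroup = "---")),
                siteClass = rep("other", 3))
  expect_error(identityFilter(gapped), "non-gap")
})

test_that("theta_W and pi are unbiased on neutral simulations", {
  # locus theta 8: E[theta_W] = E[pi] = theta
  theta <- 8
  set.seed(12)
  reps <- 250
  tw <- numeric(reps); pw <- numeric(reps)
  a47 <- sum(1 / (1:47))
  for (r in seq_len(reps)) {
    H <- coalescentSample(48, theta)
    k <- colSums(H)
    k <- k[k > 0 & k < 48]
    tw[r] <- length(k) / a47
    pw[r] <- nucleotideDiversity(k, 48, 1)
  }
  expect_lt(abs(mean(tw) - theta), 2 * stats::sd(tw) / sqrt(reps))
  expect_lt(abs(mean(pw) - theta), 2 * stats::sd(pw) / sqrt(reps))
})

test_that("per-gene summaries agree with direct statistics", {
  gene <- fixtureGene(1500)
  cfg <- fixtureConfig(thetaSite = 0.02)
  s <- simulatePopulation(gene, cfg, seed = 13)
  sm <- geneSummary(s, L = gene@length)
  k <- colSums(haplotypes(s))
  k <- k[k > 0 & k < 48]
  expect_equal(sm$S[sm$class == "all"], length(k))
  expect_equal(sm$pi[sm$class == "all"],
               nucleotideDiversity(k, 48, gene@length))
  expect_equal(sm$thetaW[sm$class == "all"],
               wattersonTheta(length(k), 48, gene@length))
})
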