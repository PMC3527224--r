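test_that("genotype likelihoods normalize and match direct enumeration", {
  e <- 0.002
  # single-read pileups: 10^ll over the four bases must sum to 1 per G
  for (g in 1:5) {
    tot <- sum(vapply(c("A", "C", "G", "T"), function(b) {
      counts <- setNames(as.integer(c("A", "C", "G", "T") == b),
                         c("A", "C", "G", "T"))
      10^genotypeLikelihoods(counts, c("A", "C"), e)[g]
    }, numeric(1)))
    expect_equal(tot, 1, tolerance = 1e-12)
  }

  # independent per-read product oracle on random pileups
  set.seed(1)
  for (r in 1:20) {
    counts <- setNames(as.integer(rmultinom(1, 30, c(5, 4, 1, 1))),
                       c("A", "C", "G", "T"))
    if (sum(counts) == 0) next
    ll <- genotypeLikelihoods(counts, c("A", "C"), e)
    expect_equal(unname(ll), unname(oracleGenotypeLL(counts, c("A", "C"), e)),
                 tolerance = 1e-12)
  }

  # pure pileup: homozygote wins
  ll <- genotypeLikelihoods(c(A = 20, C = 0, G = 0, T = 0), c("A", "C"),
                            0.001)
  expect_equal(names(which.max(ll)), "AAAA")
  expect_gt(ll["AAAA"], ll["AAAC"])

  # balanced pileup: duplex is the ML genotype
  llBal <- genotypeLikelihoods(c(A = 13, C = 12, G = 0, T = 0),
                               c("A", "C"), 0.002)
  expect_equal(names(which.max(llBal)), "AACC")

  expect_error(genotypeLikelihoods(c(A = 0, C = 0, G = 0, T = 0),
                                   c("A", "C"), e), "zero-depth")
  expect_error(genotypeLikelihoods(c(A = 5, C = 0, G = 0, T = 0),
                                   c("A", "A"), e), "distinct")
  expect_error(genotypeLikelihoods(c(A = 5, C = 0, G = 0, T = 0),
                                   c("A", "C"), 0), "error rate")
})

test_that("log-odds threshold separates calls from no-calls", {
  clear <- callGenotype(c(A = 25, C = 0, G = 0, T = 0), c("A", "C"), 0.002)
  expect_equal(clear$status, "called")
  expect_equal(clear$dosage, 0)

  # 4 A / 1 C: AAAa leads AAaa by ~0.40 log10-odds, below the threshold;
  # expected lod frozen from the per-read product oracle
  marginal <- callGenotype(c(A = 4, C = 1, G = 0, T = 0), c("A", "C"),
                           0.002)
  llOracle <- sort(oracleGenotypeLL(c(A = 4, C = 1, G = 0, T = 0),
                                    c("A", "C"), 0.002), decreasing = TRUE)
  expect_equal(marginal$lod, unname(llOracle[1] - llOracle[2]),
               tolerance = 1e-10)
  expect_equal(marginal$lod, 0.403, tolerance = 1e-3)
  expect_equal(marginal$status, "no_call")

  # mirrored pileups give mirrored dosages
  a <- callGenotype(c(A = 13, C = 12, G = 0, T = 0), c("A", "C"), 0.002)
  b <- callGenotype(c(A = 12, C = 13, G = 0, T = 0), c("A", "C"), 0.002)
  expect_equal(a$dosage + b$dosage, 4)
  expect_equal(a$lod, b$lod, tolerance = 1e-10)
})

test_that("site filter enforces coverage and the two-variant rule", {
  mkSite <- function(depths, altDepth = 0) {
    data.frame(gene_id = "g", pos = 1L, individual = 1:12,
               countA = depths - altDepth, countC = altDepth,
               countG = 0L, countT = 0L)
  }
  # depth exactly 4 in one individual: dropped (rule is strictly > 4)
  low <- mkSite(c(4L, rep(30L, 11)))
  expect_false(siteFilter(low, e = 0.002)$keep)
  expect_equal(siteFilter(low, e = 0.002)$reason, "low_coverage")

  ok <- mkSite(rep(5L, 12), altDepth = 2L)
  flt <- siteFilter(ok, e = 0.002)
  expect_true(flt$keep)
  expect_setequal(flt$alleles, c("A", "C"))

  # three bases well above error expectation: dropped
  tri <- data.frame(gene_id = "g", pos = 1L, individual = 1:12,
                    countA = 10L, countC = 10L, countG = 10L, countT = 0L)
  res <- siteFilter(tri, e = 0.002)
  expect_false(res$keep)
  expect_equal(res$reason, "too_many_variants")

  expect_error(siteFilter(ok[1:5, ], e = 0.002), "individuals")
})

test_that("error-rate estimator recovers an injected flip rate", {
  set.seed(4)
  n <- 2e5
  eps <- 0.0015
  d <- 0.005                      # equal reads/reference divergence
  outg <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  flip <- function(x, rate) {
    hit <- runif(length(x)) < rate
    x[hit] <- vapply(x[hit], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    x
  }
  reference <- flip(outg, d)
  truth <- flip(outg, d)
  reads <- flip(truth, eps)
  est <- estimateErrorRate(reads, reference, outg, individual = "ind1")
  expect_false(est$clamped)
  expect_lt(abs(est$e - eps) / eps, 0.2)

  # reads identical to reference: zero error
  expect_equal(estimateErrorRate(reference, reference, outg)$e, 0)

  # reference more diverged than reads: clamped at zero with a warning
  refFar <- flip(outg, 0.05)
  expect_warning(
    clamped <- estimateErrorRate(outg, refFar, outg),
    "clamped")
  expect_equal(clamped$e, 0)
  expect_true(clamped$clamped)

  expect_error(estimateErrorRate(reads[1:10], reference[1:10], outg[1:10]),
               "columns")
})

test_that("calls converge to the generating genotype at high depth", {
  set.seed(5)
  nSites <- 2000
  e <- 0.002
  dosages <- sample(0:4, nSites, replace = TRUE)
  correct <- 0L
  for (s in seq_len(nSites)) {
    depth <- 100L
    nAlt <- rbinom(1, depth, dosages[s] / 4 * (1 - e) +
                     (1 - dosages[s] / 4) * e / 3)
    call <- callGenotype(c(A = depth - nAlt, C = nAlt, G = 0L, T = 0L),
                         c("A", "C"), e)
    if (call$dosage == dosages[s]) correct <- correct + 1L
  }
  expect_gt(correct / nSites, 0.99)
})

test_that("allele frequencies from synthetic pileups track the truth", {
  gene <- fixtureGene(4500)
  cfg <- fixtureConfig(thetaSite = 0.043, meanDepth = 25,
                       errorRate = 0.0015)
  s <- simulatePopulation(gene, cfg, seed = 6)
  pu <- simulatePileups(s, cfg, seed = 7)
  calls <- genotypePileup(pu, e = 0.0015)
  af <- alleleFrequencies(calls)
  expect_gt(nrow(af), 20)

  idx <- match(af$pos, s@positions)
  trueK <- colSums(haplotypes(s))[idx]
  # orient the called alternate count to the derived allele
  calledK <- ifelse(af$allele2 == s@derivedBase[idx], af$altCount,
                    af$total - af$altCount)
  expect_gt(cor(calledK, trueK), 0.99)

  # dosage sums equal a brute-force per-individual summation
  sp <- split(calls, calls$pos)
  some <- sp[[which.max(vapply(sp, nrow, 0L))]]
  expect_equal(sum(some$dosage),
               Reduce(`+`, lapply(seq_len(nrow(some)),
                                  function(i) some$dosage[i])))
})

test_that("allele counting is plain dosage arithmetic", {
  mkCalls <- function(dosages) {
    data.frame(gene_id = "g", pos = 10L, individual = seq_along(dosages),
               allele1 = "A", allele2 = "C", dosage = dosages,
               lod = 5, status = "called")
  }
  expect_equal(alleleFrequencies(mkCalls(rep(0L, 12)))$altCount, 0)
  expect_equal(alleleFrequencies(mkCalls(c(rep(0L, 11), 1L)))$altCount, 1)
  expect_equal(alleleFrequencies(mkCalls(c(rep(4L, 11), 3L)))$altCount, 47)
  # a no_call individual removes the whole site
  nc <- mkCalls(rep(1L, 12))
  nc$status[3] <- "no_call"
  expect_equal(nrow(alleleFrequencies(nc)), 0)
})
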