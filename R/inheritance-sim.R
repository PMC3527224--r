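## Coalescent machinery for neutral expectations under tetrasomic and
## disomic inheritance. Time is measured in units of 4N generations (the ms
## convention used throughout): with k lineages the total coalescence rate
## is k(k-1), and mutations fall on branches at rate theta per lineage per
## unit time, so E[S] = theta * a_{n-1} and E[pi] = theta for a locus-wide
## theta = 4N * mu_locus.

#' Construct an inheritance model
#'
#' @param kind `"tetrasomic"` (one panmictic pool of 48 chromosomes) or
#'   `"disomic"` (two isolated homeolog pools of 24).
#' @param td time since the evolution of disomic inheritance, in units of
#'   4N generations; required when `kind = "disomic"`.
#' @return An [InheritanceModel-class] object.
#' @examples
#' inheritanceModel("tetrasomic")
#' inheritanceModel("disomic", td = 1)
#' @export
inheritanceModel <- function(kind = c("tetrasomic", "disomic"), td = NA_real_) {
  kind <- match.arg(kind)
  new("InheritanceModel", kind = kind, td = as.numeric(td))
}

#' Default grid of diploidization times for disomic models
#'
#' @return Numeric vector `c(0.2, 0.4, 0.6, 0.8, 1.0)` of t_d values (4N
#'   generations) spanning recent to old genetic diploidization.
#' @export
tdGrid <- function() seq(0.2, 1.0, by = 0.2)

## simulate one deme's coalescent from `n` lineages down to (at most) one,
## stopping the clock at `tmax` (Inf = run to the MRCA). Lineages are sets
## of tip indices. Returns the surviving lineages plus the exposure table
## used for mutation placement.
.coalesceDeme <- function(lineages, tmax) {
  t <- 0
  segs <- list()     # each: list(dt, lineages at that epoch)
  while (length(lineages) > 1L) {
    k <- length(lineages)
    dt <- rexp(1L, rate = k * (k - 1))
    if (t + dt > tmax) {
      segs[[length(segs) + 1L]] <- list(dt = tmax - t, lineages = lineages)
      return(list(lineages = lineages, segs = segs, t = tmax))
    }
    segs[[length(segs) + 1L]] <- list(dt = dt, lineages = lineages)
    t <- t + dt
    pair <- sample.int(k, 2L)
    merged <- c(lineages[[pair[1L]]], lineages[[pair[2L]]])
    lineages <- c(lineages[-pair], list(merged))
  }
  if (is.finite(tmax) && t < tmax)
    segs[[length(segs) + 1L]] <- list(dt = tmax - t,
                                      lineages = lineages)
  list(lineages = lineages, segs = segs, t = t)
}

## drop mutations on the exposure table: each (epoch, lineage) pair carries
## Poisson(theta * dt) mutations; a mutation marks the lineage's tip set as
## derived. Lineages spanning the whole sample are excluded (monomorphic).
.mutateSegs <- function(segs, theta, n) {
  carriers <- list()
  if (theta <= 0) return(carriers)
  for (s in segs) {
    if (s$dt <= 0) next
    k <- length(s$lineages)
    nm <- rpois(1L, lambda = theta * s$dt * k)
    if (nm == 0L) next
    which.lin <- sample.int(k, nm, replace = TRUE)
    for (w in which.lin) {
      tips <- s$lineages[[w]]
      if (length(tips) < n)
        carriers[[length(carriers) + 1L]] <- tips
    }
  }
  carriers
}

#' Sample haplotypes from a neutral coalescent
#'
#' Kingman coalescent with infinite-sites mutation for `n` chromosomes, in
#' one panmictic deme or in two isolated demes of `n/2` that merge into a
#' single ancestral population at time `tMerge` in the past (no migration).
#' Mutations fall on branches at rate `theta` per lineage per unit of 4N
#' generations (locus-wide theta = 4N mu), so over replicates
#' `E[S] = theta * sum(1/(1:(n-1)))`.
#'
#' @param n number of chromosomes (even when `demes = 2`).
#' @param theta locus-wide population mutation rate 4N mu.
#' @param demes 1 or 2.
#' @param tMerge time of the deme merge, units of 4N generations
#'   (`demes = 2` only).
#' @param seed optional integer seed.
#' @return Integer 0/1 matrix `n` x S (S = segregating sites; site order is
#'   arbitrary), with attribute `deme` giving each chromosome's deme.
#' @examples
#' h <- coalescentSample(48, theta = 5, seed = 1)
#' dim(h)
#' @export
coalescentSample <- function(n = 48L, theta, demes = 1L, tMerge = NA_real_,
                             seed = NULL) {
  if (theta < 0) stop("theta must be non-negative")
  n <- as.integer(n)
  if (demes == 2L) {
    if (n %% 2L != 0L) stop("n must be even for two demes")
    if (!is.finite(tMerge) || tMerge <= 0)
      stop("tMerge must be positive for two demes")
  }
  .setSeed(seed)
  if (demes == 1L) {
    res <- .coalesceDeme(as.list(seq_len(n)), Inf)
    segs <- res$segs
    deme <- rep(1L, n)
  } else {
    half <- n %/% 2L
    d1 <- .coalesceDeme(as.list(seq_len(half)), tMerge)
    d2 <- .coalesceDeme(as.list(half + seq_len(half)), tMerge)
    anc <- .coalesceDeme(c(d1$lineages, d2$lineages), Inf)
    segs <- c(d1$segs, d2$segs, anc$segs)
    deme <- rep(c(1L, 2L), each = half)
  }
  carriers <- .mutateSegs(segs, theta, n)
  H <- matrix(0L, nrow = n, ncol = length(carriers))
  for (j in seq_along(carriers)) H[carriers[[j]], j] <- 1L
  attr(H, "deme") <- deme
  H
}

#' Assemble tetraploid individuals from 48 chromosomes
#'
#' Tetrasomic inheritance: the 48 chromosomes are partitioned at random
#' into 12 groups of 4. Disomic inheritance: each individual receives two
#' chromosomes from each homeolog pool, representing its two homeologous
#' chromosome pairs.
#'
#' @param haplotypes 48 x S matrix from [coalescentSample()] (attribute
#'   `deme` required for disomic models).
#' @param model an [InheritanceModel-class].
#' @param seed optional integer seed.
#' @return Integer vector of length 48 mapping each chromosome to an
#'   individual 1..12.
#' @export
assembleIndividuals <- function(haplotypes, model, seed = NULL) {
  n <- nrow(haplotypes)
  if (n != 48L) stop("individual assembly requires exactly 48 chromosomes")
  .setSeed(seed)
  ind <- integer(n)
  if (model@kind == "tetrasomic") {
    ind[sample.int(n)] <- rep(1:12, each = 4L)
  } else {
    deme <- attr(haplotypes, "deme")
    if (is.null(deme)) deme <- rep(c(1L, 2L), each = 24L)
    for (d in 1:2) {
      idx <- which(deme == d)
      if (length(idx) != 24L)
        stop("disomic assembly requires 24 chromosomes per homeolog pool")
      ind[idx[sample.int(24L)]] <- rep(1:12, each = 2L)
    }
  }
  ind
}

#' Pool SNPs and genotype classes over replicate coalescent runs
#'
#' Per run, draws a locus theta from `thetaSource` (sampling with
#' replacement), simulates the coalescent under `model` (one deme for
#' tetrasomic; two demes of 24 merging at `td` for disomic), assembles 12
#' tetraploid individuals, and accumulates every segregating site's derived
#' and folded minor count (out of 48) together with the individuals'
#' dosage-class counts.
#'
#' @param model an [InheritanceModel-class].
#' @param thetaSource numeric vector of empirical locus theta values to
#'   resample.
#' @param runs number of replicate runs.
#' @param seed optional integer seed.
#' @return A [SimulatedPool-class].
#' @examples
#' pool <- simulateModel(inheritanceModel("tetrasomic"),
#'                       thetaSource = 5, runs = 50, seed = 1)
#' pool
#' @export
simulateModel <- function(model, thetaSource, runs, seed = NULL) {
  if (!length(thetaSource)) stop("thetaSource must be non-empty")
  if (runs < 1L) stop("runs must be >= 1")
  .setSeed(seed)
  derived <- vector("list", runs)
  gclass <- numeric(5L)
  for (r in seq_len(runs)) {
    th <- thetaSource[[sample.int(length(thetaSource), 1L)]]
    H <- if (model@kind == "tetrasomic") {
      coalescentSample(48L, th, demes = 1L)
    } else {
      coalescentSample(48L, th, demes = 2L, tMerge = model@td)
    }
    if (!ncol(H)) next
    ind <- assembleIndividuals(H, model)
    k <- colSums(H)
    keep <- k > 0L & k < 48L
    if (!any(keep)) next
    H <- H[, keep, drop = FALSE]
    derived[[r]] <- k[keep]
    dos <- rowsum(H, group = ind)          # 12 x S dosages
    gclass <- gclass + tabulate(as.vector(dos) + 1L, nbins = 5L)
  }
  dc <- as.integer(unlist(derived))
  new("SimulatedPool",
      model = model,
      derivedCounts = dc,
      foldedCounts = as.integer(pmin(dc, 48L - dc)),
      genotypeClasses = setNames(gclass, paste0("dosage", 0:4)),
      runs = as.integer(runs))
}

#' Expected tetrasomic genotype frequencies at allele frequency p
#'
#' Under tetrasomic inheritance with bivalent pairing (no double
#' reduction), a tetraploid genotype is four independent draws from the
#' allele pool, so the dosage g of an allele at population frequency `p` is
#' binomial(4, p).
#'
#' @param p allele frequency in `[0, 1]`.
#' @return Named numeric vector of length 5: frequencies of dosage 0..4.
#' @examples
#' expectedTetrasomicGenotypeFreqs(0.5)
#' @export
expectedTetrasomicGenotypeFreqs <- function(p) {
  if (p < 0 || p > 1) stop("p must be in [0, 1]")
  setNames(dbinom(0:4, size = 4L, prob = p), paste0("dosage", 0:4))
}
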