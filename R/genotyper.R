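## Likelihood-based tetraploid genotype calling from per-site read pileups.
## For genotype G with i copies of allele A1 and j = 4 - i copies of A2,
## P(D|G) = prod_b P(b|G) with P(b|G) = (i/4) P(b|A1) + (j/4) P(b|A2) and
## P(b|a) = 1 - e if b == a, e/3 otherwise. The most probable genotype is
## accepted when its log10-odds over the runner-up reaches `lodMin`.

GENOTYPE_DOSAGES <- 4:0   # copies of A1 for the five tetraploid genotypes

#' Log-likelihoods of the five tetraploid genotypes at one site
#'
#' @param counts named base counts (`A`, `C`, `G`, `T`) for one individual
#'   at one site, or a [data.frame] row with `countA`..`countT`.
#' @param alleles length-2 character vector `(A1, A2)`; the five genotypes
#'   carry i = 4, 3, 2, 1, 0 copies of `A1`.
#' @param e per-base error rate in (0, 1).
#' @return Numeric length-5 vector of log10 P(D|G) for i = 4..0, named by
#'   genotype string (e.g. `"AAAC"`).
#' @examples
#' genotypeLikelihoods(c(A = 13, C = 12, G = 0, T = 0), c("A", "C"), 0.002)
#' @export
genotypeLikelihoods <- function(counts, alleles, e) {
  counts <- .asCounts(counts)
  if (sum(counts) == 0L) stop("zero-depth pileup")
  if (length(alleles) != 2L || alleles[1] == alleles[2])
    stop("two distinct alleles required")
  if (e <= 0 || e >= 1) stop("error rate must lie in (0, 1)")
  pBase <- function(allele)
    ifelse(BASES == allele, 1 - e, e / 3)    # sums to 1 over the 4 bases
  p1 <- pBase(alleles[1])
  p2 <- pBase(alleles[2])
  ll <- vapply(GENOTYPE_DOSAGES, function(i) {
    pb <- (i / 4) * p1 + ((4 - i) / 4) * p2
    sum(counts * log10(pb))
  }, numeric(1))
  names(ll) <- vapply(GENOTYPE_DOSAGES, function(i)
    paste(c(rep(alleles[1], i), rep(alleles[2], 4L - i)), collapse = ""),
    "")
  ll
}

.asCounts <- function(x) {
  if (is.data.frame(x))
    x <- c(A = x$countA, C = x$countC, G = x$countG, T = x$countT)
  stopifnot(all(BASES %in% names(x)))
  v <- as.integer(x[BASES])
  names(v) <- BASES
  v
}

#' Call the tetraploid genotype at one site for one individual
#'
#' The maximum-likelihood genotype is accepted when its log10-odds over the
#' second-best genotype is at least `lodMin` (default 2); otherwise the
#' site is a no-call for that individual.
#'
#' @inheritParams genotypeLikelihoods
#' @param lodMin minimum log10-odds of best over second-best genotype.
#' @return `data.frame` row: `allele1`, `allele2`, `dosage` (copies of
#'   `allele2`, 0..4), `lod`, `status` (`"called"` / `"no_call"`), plus the
#'   five log10-likelihoods `llA1x4`..`llA2x4`.
#' @examples
#' callGenotype(c(A = 25, C = 0, G = 0, T = 0), c("A", "C"), 0.002)
#' @export
callGenotype <- function(counts, alleles, e, lodMin = 2) {
  ll <- genotypeLikelihoods(counts, alleles, e)
  o <- order(ll, decreasing = TRUE)
  lod <- ll[o[1]] - ll[o[2]]
  best <- o[1]                                 # index into GENOTYPE_DOSAGES
  data.frame(
    allele1 = alleles[1], allele2 = alleles[2],
    dosage = 4L - GENOTYPE_DOSAGES[best],      # copies of allele2
    lod = unname(lod),
    status = if (lod >= lodMin) "called" else "no_call",
    llA1x4 = unname(ll[1]), llA1x3 = unname(ll[2]), llA1x2 = unname(ll[3]),
    llA1x1 = unname(ll[4]), llA1x0 = unname(ll[5]))
}

#' Site-level coverage and variant-count filter
#'
#' A site enters genotyping only if (a) per-individual coverage exceeds 4x
#' for all 12 individuals (strictly greater than 4) and (b) no more than
#' two variants are observed among all individuals. Variants are bases
#' whose pooled count exceeds what the error rate explains
#' (> `errorQuantile` of binomial(total depth, e)).
#'
#' @param siteCounts `data.frame` of the 12 individuals' rows at one site
#'   with columns `individual`, `countA`..`countT`.
#' @param e per-base error rate used to separate real variants from error
#'   noise.
#' @param minIndividuals expected number of individuals (default 12).
#' @param errorQuantile binomial quantile above which a pooled base count
#'   is deemed a real variant.
#' @return `list(keep =, reason =, alleles =)`; `alleles` holds the (at
#'   most two) variant bases, most abundant first.
#' @export
siteFilter <- function(siteCounts, e, minIndividuals = 12L,
                       errorQuantile = 0.999) {
  if (nrow(siteCounts) < minIndividuals ||
      length(unique(siteCounts$individual)) < minIndividuals)
    stop("all individuals must be present at the site")
  depths <- with(siteCounts, countA + countC + countG + countT)
  if (any(depths <= 4L))
    return(list(keep = FALSE, reason = "low_coverage", alleles = character()))
  pooled <- c(A = sum(siteCounts$countA), C = sum(siteCounts$countC),
              G = sum(siteCounts$countG), T = sum(siteCounts$countT))
  tot <- sum(pooled)
  cut <- stats::qbinom(errorQuantile, tot, e / 3)
  variants <- names(pooled)[pooled > cut]
  if (length(variants) > 2L)
    return(list(keep = FALSE, reason = "too_many_variants",
                alleles = variants))
  list(keep = TRUE, reason = "pass",
       alleles = names(sort(pooled[variants], decreasing = TRUE)))
}

#' Genotype a whole pileup table
#'
#' Applies [siteFilter()] then [callGenotype()] per individual at every
#' site of a pileup table (as produced by [simulatePileups()] or read from
#' TSV). Monomorphic passing sites (one variant) are called dosage 0 for
#' every individual without a likelihood contest.
#'
#' @param pileup pileup `data.frame` (`gene_id`, `pos`, `individual`,
#'   `countA`..`countT`).
#' @param e scalar error rate or named vector of per-individual rates.
#' @param lodMin log10-odds acceptance threshold.
#' @return `data.frame` with one row per individual x kept polymorphic
#'   site: `gene_id`, `pos`, `individual`, `allele1`, `allele2`, `dosage`,
#'   `lod`, `status`; attribute `"siteLog"` records per-site keep/drop
#'   reasons.
#' @export
genotypePileup <- function(pileup, e, lodMin = 2) {
  keyed <- split(pileup, list(pileup$gene_id, pileup$pos), drop = TRUE)
  calls <- vector("list", length(keyed))
  log <- vector("list", length(keyed))
  for (ii in seq_along(keyed)) {
    sc <- keyed[[ii]]
    flt <- siteFilter(sc, e = mean(e))
    log[[ii]] <- data.frame(gene_id = sc$gene_id[1], pos = sc$pos[1],
                            keep = flt$keep, reason = flt$reason)
    if (!flt$keep || length(flt$alleles) < 2L) next
    al <- flt$alleles[1:2]
    rows <- lapply(seq_len(nrow(sc)), function(r) {
      ei <- if (length(e) > 1L) e[[as.character(sc$individual[r])]] else e
      cbind(gene_id = sc$gene_id[r], pos = sc$pos[r],
            individual = sc$individual[r],
            callGenotype(sc[r, ], al, ei, lodMin))
    })
    calls[[ii]] <- do.call(rbind, rows)
  }
  out <- do.call(rbind, calls)
  if (is.null(out))
    out <- data.frame(gene_id = character(), pos = integer(),
                      individual = integer(), allele1 = character(),
                      allele2 = character(), dosage = integer(),
                      lod = numeric(), status = character())
  rownames(out) <- NULL
  attr(out, "siteLog") <- do.call(rbind, log)
  out
}

#' Per-site allele counts out of 48 from genotype calls
#'
#' Sums the called dosages of the alternate allele across individuals.
#' Sites where any individual is not `called` are excluded so the sample
#' size stays fixed at 4 x 12 = 48 chromosomes.
#'
#' @param calls output of [genotypePileup()].
#' @param nIndividuals number of individuals required per site.
#' @return `data.frame`: `gene_id`, `pos`, `allele1`, `allele2`,
#'   `altCount` (0..48), `total` (48).
#' @export
alleleFrequencies <- function(calls, nIndividuals = 12L) {
  if (!nrow(calls))
    return(data.frame(gene_id = character(), pos = integer(),
                      allele1 = character(), allele2 = character(),
                      altCount = integer(), total = integer()))
  sp <- split(calls, list(calls$gene_id, calls$pos), drop = TRUE)
  rows <- lapply(sp, function(sc) {
    if (nrow(sc) < nIndividuals || any(sc$status != "called")) return(NULL)
    data.frame(gene_id = sc$gene_id[1], pos = sc$pos[1],
               allele1 = sc$allele1[1], allele2 = sc$allele2[1],
               altCount = sum(sc$dosage), total = 4L * nrow(sc))
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(out))
    out <- data.frame(gene_id = character(), pos = integer(),
                      allele1 = character(), allele2 = character(),
                      altCount = integer(), total = integer())
  out <- out[order(out$gene_id, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Estimate the combined sequencing + mapping error rate
#'
#' Divergence of focal-species reads from the outgroup reflects both true
#' evolutionary divergence and error; divergence of the (error-free)
#' sister reference from the same outgroup reflects divergence alone.
#' Their difference over the same alignment columns estimates the error
#' rate. Negative excess is clamped to 0 with a warning flag.
#'
#' @param reads character vector of read bases (focal) per column.
#' @param reference sister-reference base per column.
#' @param outgroup outgroup base per column.
#' @param individual identifier carried into the result.
#' @param minColumns minimum usable (non-gap) aligned columns.
#' @return `list(individual, e, columns, mismatchReads, mismatchRef,
#'   clamped)`.
#' @export
estimateErrorRate <- function(reads, reference, outgroup,
                              individual = NA, minColumns = 1000L) {
  ok <- reads %in% BASES & reference %in% BASES & outgroup %in% BASES
  reads <- reads[ok]; reference <- reference[ok]; outgroup <- outgroup[ok]
  n <- length(reads)
  if (n < minColumns)
    stop(sprintf("only %d aligned columns; %d required", n, minColumns))
  mr <- sum(reads != outgroup)
  ms <- sum(reference != outgroup)
  e <- (mr - ms) / n
  clamped <- e < 0
  if (clamped) {
    warning("reference more diverged than reads; error estimate clamped at 0")
    e <- 0
  }
  list(individual = individual, e = e, columns = n,
       mismatchReads = mr, mismatchRef = ms, clamped = clamped)
}
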