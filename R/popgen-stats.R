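## Diversity statistics for tetraploid population samples: outgroup
## polarization, codon-based site classification, site frequency spectra,
## Watterson's theta, nucleotide diversity as expected gametic
## heterozygosity, fixed differences, and Weir-Cockerham F_ST treating each
## tetraploid individual as four independent gametes.

#' Polarize a SNP against two outgroup sequences
#'
#' Sites where the two outgroups (sister reference and distant outgroup)
#' carry the same base are assigned that base as the ancestral state; sites
#' where they disagree, or where the shared outgroup base is absent from
#' the sampled alleles, remain unpolarized (excluded from the unfolded SFS
#' but kept in the folded one).
#'
#' @param alleles length-2 character vector of the sampled alleles.
#' @param referenceBase sister-species base at the site.
#' @param outgroupBase outgroup base at the site.
#' @return `list(ancestral =, derived =, polarized =)`; `ancestral` is
#'   `NA` when unpolarized.
#' @examples
#' polarizeSite(c("A", "G"), "A", "A")   # ancestral A, derived G
#' polarizeSite(c("A", "G"), "A", "G")   # unpolarized
#' @export
polarizeSite <- function(alleles, referenceBase, outgroupBase) {
  unpol <- list(ancestral = NA_character_, derived = NA_character_,
                polarized = FALSE)
  if (!referenceBase %in% BASES || !outgroupBase %in% BASES) return(unpol)
  if (referenceBase != outgroupBase) return(unpol)
  if (!referenceBase %in% alleles) return(unpol)
  list(ancestral = referenceBase,
       derived = setdiff(alleles, referenceBase)[1],
       polarized = TRUE)
}

#' Classify a polymorphic site as synonymous, non-synonymous or intronic
#'
#' CDS sites are classified by swapping the two alleles within the
#' reference codon context: if both codons translate to the same amino
#' acid the site is synonymous, otherwise non-synonymous. Intron-annotated
#' positions are `"intron"`; positions outside any feature are `"other"`.
#'
#' @param gene a [GeneModel-class].
#' @param position 0-based position within the gene.
#' @param alleles length-2 character vector.
#' @param refSeq character vector: the gene's reference sequence (one base
#'   per position), used for codon context.
#' @return One of `"synonymous"`, `"nonsynonymous"`, `"intron"`, `"other"`.
#' @export
classifySite <- function(gene, position, alleles, refSeq) {
  f <- gene@features
  hit <- which(f$start <= position & position < f$end)
  if (!length(hit)) return("other")
  if (f$kind[hit] == "intron") return("intron")
  frame <- f$frame[hit]
  if (is.na(frame)) stop("CDS feature without reading frame")
  offInExon <- position - f$start[hit]
  codonPos <- (offInExon + frame) %% 3L          # 0,1,2 within codon
  codonStart <- position - codonPos
  idx <- codonStart + 0:2
  if (any(idx < f$start[hit] | idx >= f$end[hit]))
    stop("codon spans a feature boundary; frame violation")
  codon <- refSeq[idx + 1L]
  aa <- function(cd) as.character(Biostrings::translate(
    Biostrings::DNAString(paste(cd, collapse = ""))))
  cd1 <- codon; cd1[codonPos + 1L] <- alleles[1]
  cd2 <- codon; cd2[codonPos + 1L] <- alleles[2]
  if (aa(cd1) == aa(cd2)) "synonymous" else "nonsynonymous"
}

#' Build a site frequency spectrum
#'
#' @param counts integer vector of per-SNP allele counts: derived counts
#'   (1..n-1) for `flavor = "unfolded"`, or any counts which are folded to
#'   minor counts for `flavor = "folded"`.
#' @param n sample size in chromosomes.
#' @param flavor `"unfolded"` or `"folded"`.
#' @return An [SFS-class].
#' @examples
#' buildSFS(c(3, 45, 3), n = 48, flavor = "folded")
#' @export
buildSFS <- function(counts, n = 48L, flavor = c("unfolded", "folded")) {
  flavor <- match.arg(flavor)
  n <- as.integer(n)
  if (any(counts <= 0L | counts >= n))
    stop("monomorphic site in SFS input (counts must be in 1..n-1)")
  if (flavor == "folded") {
    counts <- pmin(counts, n - counts)
    tab <- tabulate(counts, nbins = n %/% 2L)
  } else {
    tab <- tabulate(counts, nbins = n - 1L)
  }
  new("SFS", n = n, flavor = flavor,
      counts = setNames(as.integer(tab), seq_along(tab)))
}

#' Fold an unfolded SFS
#'
#' @param sfs an unfolded [SFS-class].
#' @return The folded [SFS-class] obtained by pooling classes i and n-i.
#' @export
foldSFS <- function(sfs) {
  if (sfs@flavor != "unfolded") stop("sfs is already folded")
  n <- sfs@n
  half <- n %/% 2L
  folded <- integer(half)
  for (i in seq_len(half)) {
    folded[i] <- sfs@counts[i] +
      if (n - i != i) sfs@counts[n - i] else 0L
  }
  new("SFS", n = n, flavor = "folded",
      counts = setNames(as.integer(folded), seq_len(half)))
}

#' Watterson's theta per site
#'
#' theta_W = S / (a_{n-1} L) with a_{n-1} = sum_{i=1}^{n-1} 1/i.
#'
#' @param S number of segregating sites.
#' @param n sample size in chromosomes.
#' @param L sequence length in bp.
#' @return Per-site Watterson estimate.
#' @examples
#' wattersonTheta(S = 10, n = 48, L = 1000)
#' @export
wattersonTheta <- function(S, n = 48L, L) {
  if (L <= 0) stop("L must be positive")
  S / (sum(1 / seq_len(n - 1L)) * L)
}

#' Nucleotide diversity per site (expected gametic heterozygosity)
#'
#' pi = (1/L) sum_sites (n/(n-1)) (1 - sum_a p_a^2) over gametic
#' (chromosome-level) allele frequencies, equal to the mean pairwise
#' difference between sampled chromosomes divided by L.
#'
#' @param counts per-SNP counts of one allele out of `n` chromosomes.
#' @param n sample size in chromosomes.
#' @param L sequence length in bp.
#' @return Per-site pi.
#' @examples
#' nucleotideDiversity(24, n = 48, L = 1000)
#' @export
nucleotideDiversity <- function(counts, n = 48L, L) {
  if (L <= 0) stop("L must be positive")
  if (!length(counts)) return(0)
  p <- counts / n
  sum((n / (n - 1)) * (1 - p^2 - (1 - p)^2)) / L
}

#' Count fixed differences against the two outgroups
#'
#' A site is a fixed difference when the sample is monomorphic (all 48
#' chromosomes) for an allele that differs from the base shared by both
#' outgroup sequences.
#'
#' @param sampleCounts per-site derived counts out of `n`.
#' @param sampleAllele per-site allele fixed or segregating in the sample
#'   (the derived base).
#' @param referenceBase,outgroupBase per-site outgroup bases.
#' @param n sample size.
#' @return Number of fixed-difference sites.
#' @export
countFixedDifferences <- function(sampleCounts, sampleAllele,
                                  referenceBase, outgroupBase, n = 48L) {
  agree <- referenceBase == outgroupBase &
    referenceBase %in% BASES & outgroupBase %in% BASES
  sum(sampleCounts == n & agree & sampleAllele != referenceBase)
}

#' Weir-Cockerham F_ST from gametic allele counts
#'
#' Variance-components estimator for haploid-style (gametic) data: each
#' tetraploid individual contributes its four chromosomes as independent
#' gametes, with no within-individual correlation term. The multi-site
#' estimate is the ratio of summed among-population components to summed
#' total components (ratio of sums, not mean of ratios).
#'
#' @param counts1,counts2 per-site counts of the same allele in each
#'   population.
#' @param n1,n2 per-site sample sizes in gametes (scalars or vectors).
#' @return `list(fst =, perSite =, a =, b =)`: the genome estimate, the
#'   per-site ratios, and the summed variance components. `fst` is `NA`
#'   when no site has variation.
#' @export
pairwiseFst <- function(counts1, counts2, n1, n2) {
  S <- length(counts1)
  n1 <- rep_len(n1, S); n2 <- rep_len(n2, S)
  if (any(n1 < 2 | n2 < 2)) stop("need >= 2 gametes per population")
  p1 <- counts1 / n1
  p2 <- counts2 / n2
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  msp <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / (r - 1)
  msg <- (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) / (n1 + n2 - r)
  a <- (msp - msg) / nc           # among-population component
  b <- msg                        # within-population component
  tot <- a + b
  perSite <- ifelse(tot > 0, a / tot, NA_real_)
  fst <- if (sum(tot) > 0) sum(a) / sum(tot) else NA_real_
  list(fst = fst, perSite = perSite, a = sum(a), b = sum(b))
}

#' Three-species identity filter
#'
#' Keeps a gene only if all three pairwise sequence identities over
#' non-gap columns are at least 80% (inclusive at the boundary).
#'
#' @param triple a [SpeciesTriple-class].
#' @param minIdentity minimum pairwise identity.
#' @return `list(keep =, identities =)` with the three pairwise identities
#'   (focal-sister, focal-outgroup, sister-outgroup).
#' @export
identityFilter <- function(triple, minIdentity = 0.80) {
  m <- do.call(rbind, strsplit(as.character(triple@alignment), ""))
  ident <- function(i, j) {
    ok <- m[i, ] %in% BASES & m[j, ] %in% BASES
    if (!any(ok)) stop("alignment has no comparable (non-gap) columns")
    mean(m[i, ok] == m[j, ok])
  }
  ids <- c(focal_sister = ident(1, 2), focal_outgroup = ident(1, 3),
           sister_outgroup = ident(2, 3))
  list(keep = all(ids >= minIdentity), identities = ids)
}

#' Per-gene diversity summary from a population sample
#'
#' Computes S, Watterson's theta/site and pi/site for one gene directly
#' from a [PopulationSample-class]'s haplotypes (monomorphic columns are
#' ignored), optionally stratified by site class.
#'
#' @param sample a [PopulationSample-class].
#' @param L aligned gene length in bp.
#' @param siteClass optional per-site class vector parallel to the
#'   sample's positions.
#' @return `data.frame`: `gene_id`, `class` (`"all"` plus any strata),
#'   `L`, `S`, `thetaW`, `pi`.
#' @export
geneSummary <- function(sample, L, siteClass = NULL) {
  k <- colSums(sample@haplotypes)
  n <- nrow(sample@haplotypes)
  seg <- k > 0L & k < n
  one <- function(cls, sel, Lc) {
    kk <- k[seg & sel]
    data.frame(gene_id = sample@geneId, class = cls, L = Lc,
               S = length(kk),
               thetaW = wattersonTheta(length(kk), n, Lc),
               pi = nucleotideDiversity(kk, n, Lc))
  }
  out <- one("all", rep(TRUE, length(k)), L)
  if (!is.null(siteClass)) {
    for (cls in unique(siteClass)) {
      Lc <- attr(siteClass, "classLength")[[cls]] %||% L
      out <- rbind(out, one(cls, siteClass == cls, Lc))
    }
  }
  out
}
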