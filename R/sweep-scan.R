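## Selective-sweep scan: 100-SNP windows scored with a composite
## likelihood ratio (multinomial G-statistic) of the window's unfolded
## spectrum against the genome-wide background, intersected with per-gene
## diversity outliers, plus gene-set enrichment by Fisher's exact test.

#' Split a gene's polarized SNPs into fixed-size windows
#'
#' Consecutive non-overlapping blocks of `windowSnps` SNPs in positional
#' order; a trailing block with fewer SNPs (or a gene with fewer than
#' `windowSnps` SNPs altogether) forms a single window flagged partial.
#'
#' @param derivedCounts per-SNP derived counts (1..n-1), in position order.
#' @param windowSnps SNPs per window (default 100).
#' @return `data.frame`: `window`, `from`, `to` (SNP indices), `nSnps`,
#'   `partial`; zero rows when the gene has no polarized SNPs.
#' @examples
#' makeWindows(rep(1, 250))   # windows of 100, 100, 50 (partial)
#' @export
makeWindows <- function(derivedCounts, windowSnps = 100L) {
  S <- length(derivedCounts)
  if (!S)
    return(data.frame(window = integer(), from = integer(),
                      to = integer(), nSnps = integer(),
                      partial = logical()))
  starts <- seq(1L, S, by = windowSnps)
  ends <- pmin(starts + windowSnps - 1L, S)
  data.frame(window = seq_along(starts), from = starts, to = ends,
             nSnps = ends - starts + 1L,
             partial = (ends - starts + 1L) < windowSnps)
}

#' Composite likelihood ratio of a window's spectrum vs. the background
#'
#' CLR = 2 * sum_c m_c log((m_c/m) / q_c), the multinomial composite
#' likelihood ratio (a G-statistic) of the window's unfolded class counts
#' m_c against the genome-wide background proportions q_c. Zero when the
#' window matches the background; large when window mass sits in classes
#' rare genome-wide -- in particular high-frequency derived classes after
#' a sweep.
#'
#' @param windowCounts per-SNP derived counts in the window.
#' @param background an unfolded [SFS-class] built from all polarized SNPs
#'   genome-wide, or a vector of background class counts.
#' @param pseudo pseudo-count added to empty background classes before
#'   normalization.
#' @return Non-negative CLR value.
#' @export
clrScore <- function(windowCounts, background, pseudo = 0.5) {
  bg <- if (is(background, "SFS")) {
    if (background@flavor != "unfolded")
      stop("background must be an unfolded SFS")
    as.numeric(background@counts)
  } else as.numeric(background)
  m <- length(windowCounts)
  if (!m) stop("empty window")
  if (any(windowCounts < 1L | windowCounts > length(bg)))
    stop("window class outside background support")
  mc <- tabulate(windowCounts, nbins = length(bg))
  occupiedEmpty <- mc > 0 & bg == 0
  if (any(occupiedEmpty)) bg[occupiedEmpty] <- pseudo
  q <- bg / sum(bg)
  nz <- mc > 0
  max(0, 2 * sum(mc[nz] * log((mc[nz] / m) / q[nz])))
}

#' Per-gene pi per basepair
#'
#' Convenience wrapper around [nucleotideDiversity()] over the gene's
#' aligned length.
#'
#' @param counts per-SNP allele counts out of `n`.
#' @param n sample size in chromosomes.
#' @param L aligned gene length.
#' @return pi per bp.
#' @export
genePiPerBp <- function(counts, n = 48L, L) nucleotideDiversity(counts, n, L)

#' Nominate sweep-candidate genes from CLR and diversity tails
#'
#' A gene is a candidate when (a) at least one of its windows scores in
#' the top `clrTail` of the genome-wide window CLR distribution and (b)
#' its pi/bp lies in the bottom `piTail` genome-wide. Quantiles are
#' empirical order statistics, inclusive of ties; degenerate inputs where
#' every gene would pass both tails are refused.
#'
#' @param genes `data.frame` with columns `gene_id`, `pi` and `maxClr`
#'   (the gene's maximum window CLR).
#' @param windowClr numeric vector of all window CLR values genome-wide
#'   (defaults to `genes$maxClr` when windows are not kept separately).
#' @param clrTail,piTail tail fractions (default 0.05 each).
#' @return `genes` with added logical columns `clrTop`, `piLow`,
#'   `candidate`, plus attributes `clrCutoff` and `piCutoff`.
#' @export
selectCandidates <- function(genes, windowClr = genes$maxClr,
                             clrTail = 0.05, piTail = 0.05) {
  if (nrow(genes) < 20L)
    stop("need >= 20 genes for meaningful tail quantiles")
  if (length(unique(genes$pi)) == 1L && length(unique(genes$maxClr)) == 1L)
    stop("degenerate input: all genes identical; no scan possible")
  clrCut <- quantile(windowClr, probs = 1 - clrTail, type = 1, names = FALSE)
  piCut <- quantile(genes$pi, probs = piTail, type = 1, names = FALSE)
  genes$clrTop <- if (clrTail > 0) genes$maxClr >= clrCut else FALSE
  genes$piLow <- if (piTail > 0) genes$pi <= piCut else FALSE
  genes$candidate <- genes$clrTop & genes$piLow
  attr(genes, "clrCutoff") <- clrCut
  attr(genes, "piCutoff") <- piCut
  genes
}

#' Squared correlation between per-gene CLR and diversity
#'
#' @param clr,pi paired per-gene values.
#' @return R^2 (squared Pearson correlation); `NA` for constant input.
#' @export
checkIndependence <- function(clr, pi) {
  if (length(unique(clr)) == 1L || length(unique(pi)) == 1L)
    return(NA_real_)
  cor(clr, pi)^2
}

#' Gene-set enrichment among sweep candidates (Fisher's exact test)
#'
#' Builds the 2x2 table of gene-set membership vs. candidate status over
#' the gene universe and tests for over-representation with a one-sided
#' (greater) Fisher's exact test; the p-value equals the hypergeometric
#' tail probability.
#'
#' @param candidates character vector of candidate gene ids.
#' @param geneSet character vector of gene ids in the functional set.
#' @param universe character vector of all analysed gene ids.
#' @return `list(table =, inSetCandidates =, inSetFractionPct =, odds =,
#'   fold =, p =)`; `fold` is the candidate rate inside the set over the
#'   universe-wide candidate rate.
#' @examples
#' enrichmentTest(paste0("g", 1:20), paste0("g", c(1:5, 100:110)),
#'                paste0("g", 1:1000))
#' @export
enrichmentTest <- function(candidates, geneSet, universe) {
  if (!length(geneSet)) stop("empty gene set")
  if (!all(geneSet %in% universe)) stop("gene set must lie in the universe")
  if (!all(candidates %in% universe))
    stop("candidates must lie in the universe")
  inSet <- universe %in% geneSet
  isCand <- universe %in% candidates
  tab <- matrix(c(sum(inSet & isCand), sum(inSet & !isCand),
                  sum(!inSet & isCand), sum(!inSet & !isCand)),
                nrow = 2,
                dimnames = list(c("candidate", "not"),
                                c("inSet", "outSet")))
  ft <- fisher.test(tab, alternative = "greater")
  inSetRate <- tab[1, 1] / sum(inSet)
  uniRate <- sum(isCand) / length(universe)
  list(table = tab,
       inSetCandidates = tab[1, 1],
       inSetFractionPct = 100 * inSetRate,
       odds = unname(ft$estimate),
       fold = if (uniRate > 0) inSetRate / uniRate else NA_real_,
       p = ft$p.value)
}
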