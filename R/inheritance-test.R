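## Tests of the mode of inheritance: compare an observed dataset's folded
## SFS and genotype-class distribution against pooled coalescent
## expectations under tetrasomic and disomic models, and report which
## models are rejected.

#' Compare observed and simulated folded spectra (Mann-Whitney U)
#'
#' Two-sided Mann-Whitney U test, with tie correction, on the two multisets
#' of per-SNP folded minor-allele counts.
#'
#' @param observed integer vector of per-SNP folded minor counts, or an
#'   object with folded counts ([SimulatedPool-class]).
#' @param simulated a [SimulatedPool-class] (or integer vector).
#' @return `list(U =, p =)`.
#' @export
compareSFS <- function(observed, simulated) {
  x <- .foldedVector(observed)
  y <- .foldedVector(simulated)
  if (!length(x) || !length(y)) stop("empty SNP pool")
  wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value)
}

.foldedVector <- function(x) {
  if (is(x, "SimulatedPool")) return(x@foldedCounts)
  as.integer(x)
}

#' Compare observed genotype-class counts with model expectations
#'
#' Chi-square comparison of the five dosage-class proportions
#' (nulliplex..quadruplex over segregating sites) against the proportions
#' pooled from a simulated model, flagging an excess of duplex (dosage 2)
#' genotypes -- the hallmark of long-standing disomic inheritance.
#'
#' @param observed named length-5 vector of dosage-class counts
#'   (`dosage0`..`dosage4`).
#' @param expected a [SimulatedPool-class] or length-5 count/proportion
#'   vector.
#' @param duplexTol relative excess of duplex proportion that raises the
#'   flag.
#' @return `list(table =, chisq =, p =, duplexExcess =)`; `table` holds
#'   observed and expected proportions per class.
#' @export
compareGenotypeClasses <- function(observed, expected, duplexTol = 0.05) {
  if (is(expected, "SimulatedPool")) expected <- expected@genotypeClasses
  if (sum(observed) == 0) stop("no segregating genotypes in observed data")
  if (length(observed) != 5L || length(expected) != 5L)
    stop("dosage classes 0..4 required on both sides")
  pObs <- observed / sum(observed)
  pExp <- expected / sum(expected)
  keep <- pExp > 0
  cs <- suppressWarnings(
    chisq.test(observed[keep], p = pExp[keep] / sum(pExp[keep])))
  duplexExcess <- pObs[3] > pExp[3] * (1 + duplexTol)
  list(table = data.frame(class = paste0("dosage", 0:4),
                          observed = as.numeric(pObs),
                          expected = as.numeric(pExp)),
       chisq = unname(cs$statistic), p = cs$p.value,
       duplexExcess = unname(duplexExcess))
}

#' Classify the mode of inheritance of an observed dataset
#'
#' Runs [compareSFS()] of the observed folded spectrum against each
#' model's simulated pool and reports, per model, whether it is rejected
#' at level `alpha` or consistent with the data.
#'
#' @param observed per-SNP folded minor counts of the observed data.
#' @param pools named list of [SimulatedPool-class] objects (one per
#'   model).
#' @param alpha rejection level (default 0.01, the level used for the
#'   disomic rejections).
#' @return `data.frame` with one row per model: `model`, `U`, `p`,
#'   `verdict`; attribute `"consistent"` names the non-rejected models.
#' @export
classifyInheritance <- function(observed, pools, alpha = 0.01) {
  if (length(pools) < 2L) stop("at least two models required")
  rows <- lapply(names(pools), function(nm) {
    cmp <- compareSFS(observed, pools[[nm]])
    data.frame(model = nm, U = cmp$U, p = cmp$p,
               verdict = if (cmp$p < alpha) "rejected" else "consistent")
  })
  out <- do.call(rbind, rows)
  attr(out, "consistent") <- out$model[out$verdict == "consistent"]
  out
}
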