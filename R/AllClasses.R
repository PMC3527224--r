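#' @import methods
#' @importFrom stats rpois rbinom runif rexp setNames quantile cor chisq.test
#'   wilcox.test fisher.test rmultinom phyper dbinom
#' @importFrom utils head tail
#' @importClassesFrom Biostrings DNAStringSet
NULL

setClassUnion("integerOrNumeric", c("integer", "numeric"))

#' GeneModel: a gene with CDS/intron feature annotation
#'
#' Represents one protein-coding gene on a chromosome as a set of
#' non-overlapping, sorted features (CDS segments with reading frame, and
#' introns) in 0-based half-open coordinates local to the gene.
#'
#' @slot geneId single gene identifier.
#' @slot length gene length in bases.
#' @slot features `data.frame` with columns `start`, `end` (0-based,
#'   half-open), `kind` (`"CDS"` or `"intron"`) and `frame` (0, 1 or 2 for
#'   CDS; `NA` for introns). Frame is the offset of the first base of the
#'   feature within its codon.
#' @slot chrom chromosome label.
#' @slot strand `"+"` or `"-"`.
#'
#' @seealso [makeGeneModels()], [classifySite()]
#' @export
setClass("GeneModel",
  representation(
    geneId   = "character",
    length   = "integer",
    features = "data.frame",
    chrom    = "character",
    strand   = "character"
  )
)

setValidity("GeneModel", function(object) {
  msg <- character()
  f <- object@features
  need <- c("start", "end", "kind", "frame")
  if (!all(need %in% names(f))) {
    return(paste("features must have columns", paste(need, collapse = ", ")))
  }
  if (length(object@length) != 1L || object@length < 1L)
    msg <- c(msg, "length must be a single positive integer")
  if (nrow(f)) {
    if (any(f$start < 0L) || any(f$end > object@length))
      msg <- c(msg, "features must lie within [0, length)")
    if (any(f$end <= f$start))
      msg <- c(msg, "features must have end > start")
    if (is.unsorted(f$start, strictly = TRUE))
      msg <- c(msg, "features must be sorted by start")
    if (nrow(f) > 1L && any(f$start[-1L] < f$end[-nrow(f)]))
      msg <- c(msg, "features must not overlap")
    if (!all(f$kind %in% c("CDS", "intron")))
      msg <- c(msg, "feature kind must be CDS or intron")
    cds <- f$kind == "CDS"
    if (any(cds) && sum(f$end[cds] - f$start[cds]) %% 3L != 0L)
      msg <- c(msg, "total CDS length must be divisible by 3")
    if (any(cds & (is.na(f$frame) | !(f$frame %in% 0:2))))
      msg <- c(msg, "CDS features must carry frame 0, 1 or 2")
  }
  if (length(msg)) msg else TRUE
})

#' SpeciesTriple: aligned focal / sister / outgroup sequences for one gene
#'
#' Holds the three-way alignment used for polarization, divergence and
#' error-rate estimation: the focal-species consensus, the reference sister
#' species, and a more distant outgroup, all of equal aligned length, with a
#' per-column site-class annotation.
#'
#' @slot geneId gene identifier.
#' @slot alignment [Biostrings::DNAStringSet] of length 3, names
#'   `focal`, `sister`, `outgroup`; gaps allowed.
#' @slot siteClass character vector, one of `"synonymous"`,
#'   `"nonsynonymous"`, `"intron"`, `"other"` per alignment column.
#'
#' @seealso [simulateTriple()], [polarizeSite()], [identityFilter()]
#' @export
setClass("SpeciesTriple",
  representation(
    geneId    = "character",
    alignment = "DNAStringSet",
    siteClass = "character"
  )
)

setValidity("SpeciesTriple", function(object) {
  msg <- character()
  al <- object@alignment
  if (length(al) != 3L)
    msg <- c(msg, "alignment must contain exactly 3 sequences")
  w <- unique(Biostrings::width(al))
  if (length(w) > 1L)
    msg <- c(msg, "aligned sequences must have equal length")
  if (length(al) == 3L &&
      !identical(names(al), c("focal", "sister", "outgroup")))
    msg <- c(msg, "alignment names must be focal, sister, outgroup")
  if (length(w) == 1L && length(object@siteClass) != w)
    msg <- c(msg, "siteClass must have one entry per alignment column")
  if (length(msg)) msg else TRUE
})

#' PopulationSample: phased tetraploid population sample at one gene
#'
#' The 48 sampled chromosomes (12 tetraploid individuals, 4 haplotypes each)
#' of one gene, reduced to its segregating sites under an infinite-sites
#' model. Row `h` of `haplotypes` is one chromosome; entry 1 means the
#' derived allele.
#'
#' @slot geneId gene identifier.
#' @slot haplotypes integer matrix (chromosomes x segregating sites) of 0/1.
#' @slot positions 0-based site positions within the gene, sorted.
#' @slot ancestralBase,derivedBase one base per site.
#' @slot individual integer vector mapping each chromosome to its
#'   individual (1..12).
#' @slot deme integer vector, homeolog pool of origin per chromosome (1 for
#'   tetrasomic samples; 1/2 for disomic).
#'
#' @seealso [simulatePopulation()], [injectSweep()], [trueDosage()]
#' @export
setClass("PopulationSample",
  representation(
    geneId        = "character",
    haplotypes    = "matrix",
    positions     = "integer",
    ancestralBase = "character",
    derivedBase   = "character",
    individual    = "integer",
    deme          = "integer"
  )
)

setValidity("PopulationSample", function(object) {
  msg <- character()
  H <- object@haplotypes
  if (nrow(H) != 48L)
    msg <- c(msg, "a population sample holds exactly 48 chromosomes")
  if (!all(H %in% c(0L, 1L)))
    msg <- c(msg, "haplotypes must be 0/1 (infinite-sites biallelic)")
  if (ncol(H) != length(object@positions))
    msg <- c(msg, "positions must match haplotype columns")
  if (ncol(H) && is.unsorted(object@positions))
    msg <- c(msg, "positions must be sorted")
  if (length(object@individual) != nrow(H) ||
      !all(sort(unique(object@individual)) %in% 1:12))
    msg <- c(msg, "individual assignment must map 48 chromosomes to 1..12")
  if (length(msg)) msg else TRUE
})

#' SimConfig: parameters of the synthetic study design
#'
#' Bundles the generator parameters that define the emulated study: 12
#' tetraploid individuals (48 chromosomes), mean sequencing depth 25x with
#' per-base error 0.15%, per-silent-site diversity theta = 0.043, and
#' class-specific focal-vs-sister divergence rates (synonymous 8.7e-4,
#' non-synonymous 2.7e-4, intronic 9.6e-4).
#'
#' @slot nGenes number of genes to simulate.
#' @slot meanGeneLength mean gene length in bp (exponential-ish spread).
#' @slot thetaSite per-site population mutation rate at silent sites.
#' @slot divSyn,divNonsyn,divIntron focal-vs-sister per-site divergence by
#'   site class.
#' @slot outgroupScale multiplier giving the extra outgroup divergence
#'   relative to the focal-sister rates.
#' @slot meanDepth mean per-individual per-site read depth (Poisson).
#' @slot errorRate per-read-base error probability `e`.
#' @slot sweepFraction fraction of genes carrying an injected sweep.
#' @slot sweepCarrierFraction fraction of chromosomes replaced by the sweep
#'   haplotype in swept genes.
#' @slot recombRate within-gene recombination rate (0 = none; reserved).
#' @slot seed integer seed; mandatory for reproducibility.
#'
#' @seealso [simConfig()]
#' @export
setClass("SimConfig",
  representation(
    nGenes               = "integer",
    meanGeneLength       = "integer",
    thetaSite            = "numeric",
    divSyn               = "numeric",
    divNonsyn            = "numeric",
    divIntron            = "numeric",
    outgroupScale        = "numeric",
    meanDepth            = "numeric",
    errorRate            = "numeric",
    sweepFraction        = "numeric",
    sweepCarrierFraction = "numeric",
    recombRate           = "numeric",
    seed                 = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  rates <- c(
    thetaSite = object@thetaSite, divSyn = object@divSyn,
    divNonsyn = object@divNonsyn, divIntron = object@divIntron,
    errorRate = object@errorRate, sweepFraction = object@sweepFraction,
    sweepCarrierFraction = object@sweepCarrierFraction
  )
  bad <- rates < 0 | rates > 1
  if (any(bad))
    msg <- c(msg, paste("rates must lie in [0,1]:",
                        paste(names(rates)[bad], collapse = ", ")))
  if (object@meanDepth <= 0)
    msg <- c(msg, "meanDepth must be positive")
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "seed is mandatory")
  if (length(msg)) msg else TRUE
})

#' SFS: a site frequency spectrum
#'
#' Histogram of SNP counts by allele-frequency class for a sample of `n`
#' chromosomes: unfolded (derived counts 1..n-1, outgroup-polarized) or
#' folded (minor counts 1..n/2).
#'
#' @slot n sample size in chromosomes.
#' @slot flavor `"folded"` or `"unfolded"`.
#' @slot counts integer vector of class counts (length n-1 unfolded,
#'   floor(n/2) folded), named by class.
#'
#' @seealso [buildSFS()], [foldSFS()]
#' @export
setClass("SFS",
  representation(n = "integer", flavor = "character", counts = "integerOrNumeric")
)

setValidity("SFS", function(object) {
  msg <- character()
  if (!object@flavor %in% c("folded", "unfolded"))
    msg <- c(msg, "flavor must be folded or unfolded")
  want <- if (identical(object@flavor, "unfolded")) object@n - 1L
          else object@n %/% 2L
  if (length(object@counts) != want)
    msg <- c(msg, sprintf("counts must have length %d", want))
  if (any(object@counts < 0))
    msg <- c(msg, "counts must be non-negative")
  if (length(msg)) msg else TRUE
})

#' InheritanceModel: tetrasomic or disomic inheritance scenario
#'
#' Tetrasomic inheritance draws all 48 chromosomes from one panmictic pool;
#' disomic inheritance splits them into two homeolog pools of 24 that have
#' been isolated since `td` (time since genetic diploidization, in units of
#' 4N generations), with each individual receiving two chromosomes from
#' each pool.
#'
#' @slot kind `"tetrasomic"` or `"disomic"`.
#' @slot td time since diploidization in 4N generations (disomic only).
#'
#' @seealso [inheritanceModel()], [coalescentSample()]
#' @export
setClass("InheritanceModel",
  representation(kind = "character", td = "numeric")
)

setValidity("InheritanceModel", function(object) {
  if (!object@kind %in% c("tetrasomic", "disomic"))
    return("kind must be tetrasomic or disomic")
  if (object@kind == "disomic" && (length(object@td) != 1L || object@td <= 0))
    return("td must be a single positive number for disomic models")
  TRUE
})

#' SimulatedPool: pooled SNPs from replicate coalescent runs
#'
#' Accumulates, across replicate simulations of one inheritance model, the
#' per-SNP derived and folded-minor counts (out of 48) and the inferred
#' genotype-class totals over the 12 assembled individuals
#' (nulliplex..quadruplex).
#'
#' @slot model the generating [InheritanceModel-class].
#' @slot derivedCounts integer vector, derived count per pooled SNP.
#' @slot foldedCounts integer vector, minor count per pooled SNP.
#' @slot genotypeClasses named numeric vector of length 5 with pooled
#'   dosage-class counts (`dosage0`..`dosage4`) over segregating sites.
#' @slot runs number of simulation runs pooled.
#'
#' @seealso [simulateModel()], [compareSFS()]
#' @export
setClass("SimulatedPool",
  representation(
    model           = "InheritanceModel",
    derivedCounts   = "integer",
    foldedCounts    = "integer",
    genotypeClasses = "numeric",
    runs            = "integer"
  )
)

setValidity("SimulatedPool", function(object) {
  msg <- character()
  if (length(object@genotypeClasses) != 5L)
    msg <- c(msg, "genotypeClasses must have 5 entries (dosage 0..4)")
  if (length(object@derivedCounts) != length(object@foldedCounts))
    msg <- c(msg, "derived and folded counts must be parallel")
  if (length(msg)) msg else TRUE
})

## ---- show methods -------------------------------------------------------

setMethod("show", "GeneModel", function(object) {
  f <- object@features
  cat("GeneModel", object@geneId, "on", object@chrom, object@strand,
      sprintf("(%d bp)\n", object@length))
  cat(sprintf("  %d features: %d CDS (%d bp), %d intron (%d bp)\n",
      nrow(f), sum(f$kind == "CDS"),
      sum((f$end - f$start)[f$kind == "CDS"]),
      sum(f$kind == "intron"),
      sum((f$end - f$start)[f$kind == "intron"])))
})

setMethod("show", "SpeciesTriple", function(object) {
  cat("SpeciesTriple", object@geneId,
      sprintf("(%d aligned columns)\n", Biostrings::width(object@alignment)[1]))
  cat("  site classes:",
      paste(sprintf("%s=%d", names(table(object@siteClass)),
                    table(object@siteClass)), collapse = " "), "\n")
})

setMethod("show", "PopulationSample", function(object) {
  cat("PopulationSample", object@geneId, ":",
      nrow(object@haplotypes), "chromosomes,",
      ncol(object@haplotypes), "segregating sites\n")
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nGenes, "genes, theta/site", object@thetaSite,
      ", depth", object@meanDepth, ", error", object@errorRate,
      ", seed", object@seed, "\n")
})

setMethod("show", "SFS", function(object) {
  cat(object@flavor, "SFS, n =", object@n, ",",
      sum(object@counts), "SNPs\n")
})

setMethod("show", "InheritanceModel", function(object) {
  if (object@kind == "disomic")
    cat("InheritanceModel: disomic, t_d =", object@td, "\n")
  else cat("InheritanceModel: tetrasomic\n")
})

setMethod("show", "SimulatedPool", function(object) {
  cat("SimulatedPool (", object@model@kind,
      if (object@model@kind == "disomic") paste0(", t_d=", object@model@td),
      "): ", length(object@derivedCounts), " SNPs pooled over ",
      object@runs, " runs\n", sep = "")
})

## ---- accessors ----------------------------------------------------------

#' @rdname accessors
#' @export
setGeneric("geneId", function(x) standardGeneric("geneId"))

#' Accessors for tetrapop classes
#'
#' `geneId()` returns the gene identifier; `haplotypes()` the 0/1 chromosome
#' matrix of a [PopulationSample-class]; `sfsCounts()` the class counts of an
#' [SFS-class]; `trueDosage()` the true per-individual derived-allele dosage
#' matrix (12 x sites) implied by a sample's haplotypes and individual
#' assignment.
#'
#' @param x a tetrapop object.
#' @return See details per accessor.
#' @name accessors
#' @aliases geneId haplotypes sfsCounts trueDosage
#' @export
setMethod("geneId", "GeneModel", function(x) x@geneId)

#' @rdname accessors
#' @export
setMethod("geneId", "SpeciesTriple", function(x) x@geneId)

#' @rdname accessors
#' @export
setMethod("geneId", "PopulationSample", function(x) x@geneId)

#' @rdname accessors
#' @export
setGeneric("haplotypes", function(x) standardGeneric("haplotypes"))

#' @rdname accessors
#' @export
setMethod("haplotypes", "PopulationSample", function(x) x@haplotypes)

#' @rdname accessors
#' @export
setGeneric("sfsCounts", function(x) standardGeneric("sfsCounts"))

#' @rdname accessors
#' @export
setMethod("sfsCounts", "SFS", function(x) x@counts)

#' @rdname accessors
#' @export
setGeneric("trueDosage", function(x) standardGeneric("trueDosage"))

#' @rdname accessors
#' @export
setMethod("trueDosage", "PopulationSample", function(x) {
  H <- x@haplotypes
  if (!ncol(H)) return(matrix(0L, nrow = 12L, ncol = 0L))
  d <- rowsum(H, group = x@individual, reorder = TRUE)
  storage.mode(d) <- "integer"
  d
})
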