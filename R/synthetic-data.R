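## Synthetic study generator: gene models, three-species alignments,
## tetraploid population samples (optionally carrying injected sweeps) and
## error-bearing read pileups with the statistical structure the analysis
## assumes: 12 tetraploid individuals (48 chromosomes), ~25x mean coverage
## with ~0.15% base error, silent diversity near theta = 0.043 per site,
## and class-specific divergence to the sister and outgroup species.

#' Construct a synthetic study configuration
#'
#' Defaults are the emulated study conditions: per-silent-site theta 0.043,
#' focal-vs-sister divergence 8.7e-4 / 2.7e-4 / 9.6e-4 for synonymous,
#' non-synonymous and intronic sites, mean depth 25x, base error 0.15%
#' (mid-point of the 0.1-0.2% range).
#'
#' @param nGenes number of genes.
#' @param meanGeneLength mean gene length (bp).
#' @param thetaSite per-silent-site population mutation rate.
#' @param divSyn,divNonsyn,divIntron focal-vs-sister divergence per site by
#'   class.
#' @param outgroupScale extra outgroup divergence as a multiple of the
#'   sister rates (the outgroup is the more distant of the two references).
#' @param meanDepth mean per-individual sequencing depth.
#' @param errorRate per-base error probability.
#' @param sweepFraction fraction of genes with an injected sweep.
#' @param sweepCarrierFraction chromosomes carrying the sweep haplotype in
#'   swept genes.
#' @param recombRate within-gene population recombination rate rho per bp
#'   (4Nr). The default equals the silent-site theta (rho/theta = 1, the
#'   usual order of magnitude for outcrossing Arabidopsis), so window
#'   spectra within a gene reflect several quasi-independent genealogies
#'   as they do in real genomes; set 0 for a single genealogy per gene.
#' @param seed mandatory integer seed.
#' @return A [SimConfig-class].
#' @examples
#' simConfig(nGenes = 5, seed = 1)
#' @export
simConfig <- function(nGenes = 100L, meanGeneLength = 2000L,
                      thetaSite = 0.043,
                      divSyn = 8.7e-4, divNonsyn = 2.7e-4,
                      divIntron = 9.6e-4, outgroupScale = 10,
                      meanDepth = 25, errorRate = 0.0015,
                      sweepFraction = 0, sweepCarrierFraction = 0.9,
                      recombRate = thetaSite, seed) {
  if (missing(seed)) stop("seed is mandatory")
  new("SimConfig",
      nGenes = as.integer(nGenes),
      meanGeneLength = as.integer(meanGeneLength),
      thetaSite = thetaSite, divSyn = divSyn, divNonsyn = divNonsyn,
      divIntron = divIntron, outgroupScale = outgroupScale,
      meanDepth = meanDepth, errorRate = errorRate,
      sweepFraction = sweepFraction,
      sweepCarrierFraction = sweepCarrierFraction,
      recombRate = recombRate, seed = as.integer(seed))
}

#' Generate random gene models
#'
#' Builds `n` exon/intron gene structures: alternating CDS segments (total
#' length a multiple of 3, frames tracked across exons) and introns, in
#' 0-based half-open gene-local coordinates.
#'
#' @param n number of genes.
#' @param meanLength mean gene length in bp (lengths vary around it).
#' @param seed optional integer seed.
#' @return List of [GeneModel-class] objects named by gene id.
#' @export
makeGeneModels <- function(n, meanLength = 2000L, seed = NULL) {
  .setSeed(seed)
  lapply(seq_len(n), function(i) {
    nExon <- sample(1:4, 1L)
    exonLens <- 3L * pmax(10L, rpois(nExon, lambda = meanLength * 0.6 /
                                       (3 * nExon)))
    intronLens <- if (nExon > 1L)
      pmax(30L, rpois(nExon - 1L, lambda = meanLength * 0.4 / (nExon - 1L)))
    else integer()
    feats <- list()
    pos <- 0L
    cdsSoFar <- 0L
    for (ex in seq_len(nExon)) {
      feats[[length(feats) + 1L]] <- data.frame(
        start = pos, end = pos + exonLens[ex], kind = "CDS",
        frame = cdsSoFar %% 3L)
      cdsSoFar <- cdsSoFar + exonLens[ex]
      pos <- pos + exonLens[ex]
      if (ex < nExon) {
        feats[[length(feats) + 1L]] <- data.frame(
          start = pos, end = pos + intronLens[ex], kind = "intron",
          frame = NA_integer_)
        pos <- pos + intronLens[ex]
      }
    }
    new("GeneModel",
        geneId = sprintf("gene%04d", i),
        length = pos,
        features = do.call(rbind, feats),
        chrom = sprintf("scaffold_%d", 1L + (i - 1L) %% 8L),
        strand = "+")
  }) -> genes
  names(genes) <- vapply(genes, geneId, "")
  genes
}

#' Per-position site class implied by a gene model
#'
#' @param gene a [GeneModel-class].
#' @return Character vector of length `gene@length` with values
#'   `"synonymous"`, `"nonsynonymous"`, `"intron"` or `"other"`. CDS third
#'   codon positions are labelled synonymous and first/second positions
#'   non-synonymous; this coarse map is used by the generator to assign
#'   divergence rates (the analysis itself re-classifies sites from codons
#'   via [classifySite()]).
#' @export
siteClassMap <- function(gene) {
  cls <- rep("other", gene@length)
  f <- gene@features
  for (r in seq_len(nrow(f))) {
    idx <- (f$start[r] + 1L):f$end[r]
    if (f$kind[r] == "intron") {
      cls[idx] <- "intron"
    } else {
      codonPos <- (seq_along(idx) - 1L + f$frame[r]) %% 3L
      cls[idx] <- ifelse(codonPos == 2L, "synonymous", "nonsynonymous")
    }
  }
  cls
}

.classRate <- function(cls, cfg) {
  r <- c(synonymous = cfg@divSyn, nonsynonymous = cfg@divNonsyn,
         intron = cfg@divIntron, other = cfg@divIntron)
  unname(r[cls])
}

.randomSeq <- function(L) sample(BASES, L, replace = TRUE)

.mutateSeq <- function(seq, rate) {
  hit <- which(runif(length(seq)) < rate)
  if (length(hit))
    seq[hit] <- vapply(seq[hit],
                       function(b) sample(.otherBases(b), 1L), "")
  seq
}

#' Simulate a three-species alignment for one gene
#'
#' Draws a random ancestral sequence for the gene, sets the focal consensus
#' equal to it, derives the sister sequence by substituting each site with
#' its class-specific divergence probability, and the outgroup by an
#' independent, `outgroupScale`-fold larger divergence from the ancestor.
#' No indels are introduced, so the alignment is gap-free and columns map
#' 1:1 to gene positions.
#'
#' @param gene a [GeneModel-class].
#' @param cfg a [SimConfig-class] carrying the divergence rates.
#' @param seed optional integer seed.
#' @return A [SpeciesTriple-class].
#' @export
simulateTriple <- function(gene, cfg, seed = NULL) {
  if (gene@length < 1L) stop("zero-length gene")
  .setSeed(seed)
  cls <- siteClassMap(gene)
  rate <- .classRate(cls, cfg)
  anc <- .randomSeq(gene@length)
  focal <- anc
  sister <- .mutateSeq(anc, rate)
  outg <- .mutateSeq(anc, pmin(1, rate * cfg@outgroupScale))
  al <- Biostrings::DNAStringSet(c(
    focal = paste(focal, collapse = ""),
    sister = paste(sister, collapse = ""),
    outgroup = paste(outg, collapse = "")))
  new("SpeciesTriple", geneId = gene@geneId, alignment = al,
      siteClass = cls)
}

#' Simulate a tetraploid population sample for one gene
#'
#' Delegates haplotype generation to [coalescentSample()] with locus theta
#' = `cfg@thetaSite * gene length`, places the segregating sites uniformly
#' along the gene (infinite sites), assigns derived bases relative to the
#' focal sequence of `triple` (or a random ancestral base when no triple is
#' given), and assembles 12 tetraploid individuals under `model`.
#'
#' Within-gene recombination (`cfg@recombRate`, rho per bp) is modelled by
#' the independent-segments approximation: the gene is cut at
#' Poisson(rho L) uniform breakpoints and each segment receives its own
#' genealogy (free recombination between segments, none within). Deme
#' labels and the individual assignment are shared across segments, so
#' disomic structure and sweep injection act on whole chromosomes.
#'
#' @param gene a [GeneModel-class].
#' @param cfg a [SimConfig-class].
#' @param model an [InheritanceModel-class] (default tetrasomic).
#' @param triple optional [SpeciesTriple-class] supplying ancestral bases.
#' @param seed optional integer seed.
#' @return A [PopulationSample-class].
#' @export
simulatePopulation <- function(gene, cfg,
                               model = inheritanceModel("tetrasomic"),
                               triple = NULL, seed = NULL) {
  .setSeed(seed)
  L <- gene@length
  nBreaks <- if (cfg@recombRate > 0) rpois(1L, cfg@recombRate * L) else 0L
  bounds <- sort(unique(c(0, runif(nBreaks), 1)))
  segLen <- diff(bounds) * L
  segLen <- segLen[segLen > 0]
  segs <- lapply(segLen, function(l) {
    th <- cfg@thetaSite * l
    if (model@kind == "tetrasomic") coalescentSample(48L, th, demes = 1L)
    else coalescentSample(48L, th, demes = 2L, tMerge = model@td)
  })
  H <- do.call(cbind, segs)
  if (ncol(H) > L)                               # finite length caps the
    H <- H[, seq_len(L), drop = FALSE]           # infinite-sites ideal
  attr(H, "deme") <- if (model@kind == "disomic")
    rep(c(1L, 2L), each = 24L) else rep(1L, 48L)
  S <- ncol(H)
  pos <- sort(sample.int(L, S)) - 1L             # distinct positions
  anc <- if (!is.null(triple)) {
    strsplit(as.character(triple@alignment[["focal"]]), "")[[1]][pos + 1L]
  } else .randomSeq(max(S, 1L))[seq_len(S)]
  der <- vapply(anc, function(b) sample(.otherBases(b), 1L), "",
                USE.NAMES = FALSE)
  ind <- assembleIndividuals(H, model)
  new("PopulationSample",
      geneId = gene@geneId,
      haplotypes = H,
      positions = pos,
      ancestralBase = as.character(anc),
      derivedBase = der,
      individual = ind,
      deme = attr(H, "deme") %||% rep(1L, 48L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Inject a star-like selective sweep into a population sample
#'
#' Emulates the footprint of a recent sweep by replacing
#' `ceiling(carrierFraction * 48)` chromosomes with one designated sweep
#' haplotype (the chromosome carrying the most derived alleles). The
#' result has reduced diversity and an excess of high-frequency derived
#' alleles -- the two signals the sweep scan looks for. The sweep
#' haplotype's own slot is replaced first, so `carrierFraction` small
#' enough to give one carrier leaves the sample unchanged.
#'
#' @param sample a [PopulationSample-class].
#' @param carrierFraction fraction of chromosomes carrying the sweep, in
#'   (0, 1].
#' @param seed optional integer seed.
#' @return A [PopulationSample-class] with the same sites (columns that
#'   become monomorphic are retained; downstream SFS construction drops
#'   them).
#' @export
injectSweep <- function(sample, carrierFraction, seed = NULL) {
  if (carrierFraction <= 0 || carrierFraction > 1)
    stop("carrierFraction must be in (0, 1]")
  .setSeed(seed)
  H <- sample@haplotypes
  if (!ncol(H)) return(sample)
  k <- as.integer(ceiling(carrierFraction * nrow(H)))
  sweepIdx <- which.max(rowSums(H))
  others <- setdiff(seq_len(nrow(H)), sweepIdx)
  slots <- c(sweepIdx, sample(others, k - 1L))
  H[slots, ] <- rep(H[sweepIdx, ], each = length(slots))
  out <- sample
  out@haplotypes <- H
  out
}

#' Simulate read pileups for a population sample
#'
#' Per individual and site, draws depth ~ Poisson(`cfg@meanDepth`); each
#' read base is sampled uniformly from the individual's four alleles and
#' then, with probability `cfg@errorRate`, flipped to a uniformly chosen
#' different base.
#'
#' @param sample a [PopulationSample-class].
#' @param cfg a [SimConfig-class].
#' @param seed optional integer seed.
#' @return `data.frame` with columns `gene_id`, `pos`, `individual`,
#'   `countA`, `countC`, `countG`, `countT` (one row per individual-site).
#' @export
simulatePileups <- function(sample, cfg, seed = NULL) {
  .setSeed(seed)
  S <- ncol(sample@haplotypes)
  if (!S) {
    return(data.frame(gene_id = character(), pos = integer(),
                      individual = integer(), countA = integer(),
                      countC = integer(), countG = integer(),
                      countT = integer()))
  }
  dos <- trueDosage(sample)                     # 12 x S derived dosage
  e <- cfg@errorRate
  rows <- vector("list", 12L * S)
  ri <- 0L
  for (i in 1:12) {
    depth <- rpois(S, cfg@meanDepth)
    for (s in seq_len(S)) {
      d <- depth[s]
      counts <- c(A = 0L, C = 0L, G = 0L, T = 0L)
      if (d > 0L) {
        pDer <- dos[i, s] / 4
        nDer <- rbinom(1L, d, pDer)
        reads <- c(rep(sample@derivedBase[s], nDer),
                   rep(sample@ancestralBase[s], d - nDer))
        err <- runif(d) < e
        if (any(err))
          reads[err] <- vapply(reads[err],
                               function(b) sample(.otherBases(b), 1L), "")
        tb <- table(factor(reads, levels = BASES))
        counts <- setNames(as.integer(tb), BASES)
      }
      ri <- ri + 1L
      rows[[ri]] <- c(i, sample@positions[s], counts)
    }
  }
  m <- do.call(rbind, rows)
  data.frame(gene_id = sample@geneId,
             pos = as.integer(m[, 2]),
             individual = as.integer(m[, 1]),
             countA = as.integer(m[, 3]), countC = as.integer(m[, 4]),
             countG = as.integer(m[, 5]), countT = as.integer(m[, 6]))
}
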