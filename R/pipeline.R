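## End-to-end orchestration: simulate -> genotype -> diversity statistics
## -> inheritance test -> sweep scan, from one config with a single master
## seed that deterministically derives per-stage seeds.

#' Default pipeline configuration
#'
#' @param nGenes number of genes to simulate.
#' @param seed master seed; per-stage seeds are derived from it.
#' @param sweepFraction fraction of genes given an injected sweep.
#' @param runsPerModel coalescent runs per inheritance model. Keep this
#'   well above the number of simulated genes: the Mann-Whitney verdicts
#'   are anti-conservative when the pools' own Monte-Carlo noise is
#'   comparable to the observed data's (runs within a pool share
#'   genealogies).
#' @param tdGrid diploidization-time grid for disomic models.
#' @param windowSnps SNPs per scan window.
#' @param clrTail,piTail scan tail fractions.
#' @param alpha rejection level for inheritance tests.
#' @param lodMin genotype log10-odds threshold.
#' @param genotype logical: run the pileup-and-genotype stage (exact but
#'   the slowest stage) rather than using the simulated haplotypes
#'   directly.
#' @return Named list understood by [runPipeline()].
#' @export
pipelineConfig <- function(nGenes = 60L, seed, sweepFraction = 0.05,
                           runsPerModel = 3000L, tdGrid = c(0.2, 1.0),
                           windowSnps = 100L, clrTail = 0.05,
                           piTail = 0.05, alpha = 0.01, lodMin = 2,
                           genotype = FALSE) {
  if (missing(seed)) stop("seed is mandatory")
  cfg <- list(nGenes = as.integer(nGenes), seed = as.integer(seed),
              sweepFraction = sweepFraction,
              runsPerModel = as.integer(runsPerModel), tdGrid = tdGrid,
              windowSnps = as.integer(windowSnps), clrTail = clrTail,
              piTail = piTail, alpha = alpha, lodMin = lodMin,
              genotype = isTRUE(genotype))
  cfg
}

.validateConfig <- function(config) {
  known <- names(formals(pipelineConfig))
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  required <- setdiff(known, "seed")
  miss <- setdiff(c(required, "seed"), names(config))
  if (length(miss))
    stop("missing config keys: ", paste(miss, collapse = ", "))
  invisible(config)
}

#' Run the full synthetic analysis pipeline
#'
#' Simulates the study (gene models, triples, tetraploid samples with a
#' configurable fraction of injected sweeps, pileups if requested),
#' derives per-site allele frequencies (via the likelihood genotyper when
#' `config$genotype` is TRUE, else from the true haplotypes), computes
#' per-gene diversity summaries and the genome-wide SFS, tests the mode of
#' inheritance against tetrasomic and disomic pools, runs the sweep scan,
#' and writes every stage's tables plus a manifest with parameters, seed
#' and md5 checksums into `outDir`.
#'
#' @param config list from [pipelineConfig()].
#' @param outDir output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results
#'   (`genes`, `summaries`, `inheritance`, `scan`, `manifest`).
#' @export
runPipeline <- function(config, outDir = tempfile("tetrapop_run_")) {
  .validateConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  stage <- function(k) .deriveSeed(seed, k)

  ## stage 1: simulate
  cfg <- simConfig(nGenes = config$nGenes,
                   sweepFraction = config$sweepFraction, seed = seed)
  genes <- makeGeneModels(config$nGenes, seed = stage(1))
  set.seed(stage(2))
  triples <- lapply(genes, function(g) simulateTriple(g, cfg))
  set.seed(stage(3))
  samples <- lapply(genes, function(g) simulatePopulation(g, cfg))
  nSweep <- round(config$sweepFraction * config$nGenes)
  sweptIds <- character()
  if (nSweep > 0) {
    set.seed(stage(4))
    sweptIds <- sample(names(samples), nSweep)
    for (id in sweptIds)
      samples[[id]] <- injectSweep(samples[[id]],
                                   cfg@sweepCarrierFraction)
  }
  writeTriplesFasta(triples, file.path(outDir, "triples.fasta"))
  writeGeneBed(genes, file.path(outDir, "genes.bed.tsv"), seed = seed)

  ## stage 2: per-site allele counts (genotyper or truth)
  set.seed(stage(5))
  freqs <- lapply(names(samples), function(id) {
    s <- samples[[id]]
    k <- colSums(s@haplotypes)
    seg <- k > 0L & k < 48L
    if (config$genotype && any(seg)) {
      pu <- simulatePileups(s, cfg)
      calls <- genotypePileup(pu, e = cfg@errorRate,
                              lodMin = config$lodMin)
      af <- alleleFrequencies(calls)
      ## orient counts to the derived allele
      derBase <- s@derivedBase[match(af$pos, s@positions)]
      alt <- ifelse(af$allele2 == derBase, af$altCount,
                    af$total - af$altCount)
      data.frame(gene_id = id, pos = af$pos, k = alt)
    } else {
      data.frame(gene_id = id, pos = s@positions[seg], k = k[seg])
    }
  })
  freqs <- do.call(rbind, freqs)
  freqs <- freqs[freqs$k > 0L & freqs$k < 48L, , drop = FALSE]
  .writeTsv(freqs, file.path(outDir, "site_frequencies.tsv"),
            header = c(stage = "frequencies", seed = seed))

  ## stage 3: diversity summaries + genome SFS
  summaries <- do.call(rbind, lapply(names(samples), function(id) {
    k <- freqs$k[freqs$gene_id == id]
    L <- genes[[id]]@length
    data.frame(gene_id = id, L = L, S = length(k),
               thetaW = wattersonTheta(length(k), 48L, L),
               pi = nucleotideDiversity(k, 48L, L),
               swept = id %in% sweptIds)
  }))
  .writeTsv(summaries, file.path(outDir, "gene_summaries.tsv"),
            header = c(stage = "summaries", seed = seed))
  background <- buildSFS(freqs$k, n = 48L, flavor = "unfolded")

  ## stage 4: inheritance test
  thetaSource <- pmax(summaries$thetaW * summaries$L, 0.5)
  models <- c(list(tetrasomic = inheritanceModel("tetrasomic")),
              setNames(lapply(config$tdGrid, function(td)
                inheritanceModel("disomic", td)),
                paste0("disomic_td", config$tdGrid)))
  pools <- lapply(seq_along(models), function(i)
    simulateModel(models[[i]], thetaSource, runs = config$runsPerModel,
                  seed = stage(10 + i)))
  names(pools) <- names(models)
  observedFolded <- pmin(freqs$k, 48L - freqs$k)
  inheritance <- classifyInheritance(observedFolded, pools,
                                     alpha = config$alpha)
  .writeTsv(inheritance, file.path(outDir, "inheritance.tsv"),
            header = c(stage = "inheritance", seed = seed))

  ## stage 5: sweep scan
  perGene <- do.call(rbind, lapply(names(samples), function(id) {
    k <- freqs$k[freqs$gene_id == id]
    if (!length(k)) return(NULL)
    w <- makeWindows(k, config$windowSnps)
    clr <- vapply(seq_len(nrow(w)), function(j)
      clrScore(k[w$from[j]:w$to[j]], background), numeric(1))
    data.frame(gene_id = id, maxClr = max(clr),
               pi = summaries$pi[summaries$gene_id == id],
               swept = id %in% sweptIds)
  }))
  scan <- selectCandidates(perGene, clrTail = config$clrTail,
                           piTail = config$piTail)
  .writeTsv(scan, file.path(outDir, "scan.tsv"),
            header = c(stage = "scan", seed = seed))

  ## manifest
  outputs <- list.files(outDir, full.names = TRUE)
  manifest <- list(
    package = "tetrapop",
    version = as.character(utils::packageVersion("tetrapop")),
    seed = seed,
    parameters = config[setdiff(names(config), "seed")],
    r2_clr_pi = checkIndependence(perGene$maxClr, perGene$pi),
    consistentModels = attr(inheritance, "consistent"),
    checksums = as.list(tools::md5sum(sort(outputs))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(genes = genes, summaries = summaries,
                 inheritance = inheritance, scan = scan,
                 manifest = manifest, outDir = outDir))
}
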