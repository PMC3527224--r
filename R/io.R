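## File interchange: FASTA triples (Biostrings), BED-like gene features,
## pileup TSV, genotype VCF, and small TSV writers with seed-provenance
## header comments.

#' Write three-species alignments to FASTA
#'
#' Three records per gene, named `<gene>|focal`, `<gene>|sister`,
#' `<gene>|outgroup`.
#'
#' @param triples list of [SpeciesTriple-class].
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
writeTriplesFasta <- function(triples, path) {
  seqs <- do.call(c, unname(lapply(triples, function(tr) {
    al <- tr@alignment
    names(al) <- paste(tr@geneId, names(al), sep = "|")
    al
  })))
  Biostrings::writeXStringSet(seqs, filepath = path)
  invisible(path)
}

#' Read three-species alignments from FASTA
#'
#' Inverse of [writeTriplesFasta()]. Site classes are not stored in FASTA
#' and come back as `"other"`.
#'
#' @param path FASTA file with `gene|role` record names.
#' @return Named list of [SpeciesTriple-class].
#' @export
readTriplesFasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  gene <- vapply(parts, `[`, "", 1L)
  role <- vapply(parts, `[`, "", 2L)
  out <- lapply(unique(gene), function(g) {
    al <- seqs[gene == g][match(c("focal", "sister", "outgroup"),
                                role[gene == g])]
    names(al) <- c("focal", "sister", "outgroup")
    new("SpeciesTriple", geneId = g, alignment = al,
        siteClass = rep("other", Biostrings::width(al)[1]))
  })
  names(out) <- unique(gene)
  out
}

#' Write gene models as a BED-like feature table
#'
#' 0-based half-open coordinates; columns chrom, start, end, gene_id,
#' kind, frame, strand.
#'
#' @param genes list of [GeneModel-class].
#' @param path output path.
#' @param seed seed recorded in the header comment.
#' @return `path`, invisibly.
#' @export
writeGeneBed <- function(genes, path, seed = NA) {
  rows <- do.call(rbind, lapply(genes, function(g) {
    f <- g@features
    data.frame(chrom = g@chrom, start = f$start, end = f$end,
               gene_id = g@geneId, kind = f$kind, frame = f$frame,
               strand = g@strand)
  }))
  .writeTsv(rows, path, header = c(format = "bed-like features", seed = seed))
}

#' Write a pileup table to TSV
#'
#' @param pileup pileup `data.frame` ([simulatePileups()] layout).
#' @param path output path.
#' @param seed seed recorded in the header comment.
#' @return `path`, invisibly.
#' @export
writePileupTsv <- function(pileup, path, seed = NA) {
  .writeTsv(pileup, path, header = c(format = "pileup", seed = seed))
}

#' Read a pileup TSV
#' @param path pileup TSV path.
#' @return pileup `data.frame`.
#' @export
readPileupTsv <- function(path) .readTsv(path)

#' Write genotype calls as a minimal VCF 4.2
#'
#' One record per kept polymorphic site; tetraploid genotypes as
#' slash-separated GT (`0/0/0/1` = one alternate copy), per-genotype log10
#' likelihoods in the GL field (dosage order 0..4), FILTER from the site
#' log where available.
#'
#' @param calls output of [genotypePileup()].
#' @param path output VCF path.
#' @param chrom chromosome label used for all records.
#' @return `path`, invisibly.
#' @export
writeGenotypeVcf <- function(calls, path, chrom = "gene") {
  con <- file(path, "w")
  on.exit(close(con))
  inds <- sort(unique(calls$individual))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=tetrapop",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Tetraploid genotype\">",
    "##FORMAT=<ID=GL,Number=5,Type=Float,Description=\"log10 likelihoods, alt dosage 0..4\">",
    "##FILTER=<ID=no_call,Description=\"log-odds below threshold in some individual\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "FORMAT", paste0("ind", inds)), collapse = "\t")), con)
  sp <- split(calls, list(calls$gene_id, calls$pos), drop = TRUE)
  for (sc in sp) {
    gt <- vapply(inds, function(i) {
      row <- sc[sc$individual == i, , drop = FALSE]
      if (!nrow(row) || row$status != "called") return("./././.")
      d <- row$dosage
      paste(c(rep("0", 4L - d), rep("1", d)), collapse = "/")
    }, "")
    gl <- vapply(inds, function(i) {
      row <- sc[sc$individual == i, , drop = FALSE]
      if (!nrow(row)) return(".")
      paste(sprintf("%.4f",
                    as.numeric(row[c("llA1x4", "llA1x3", "llA1x2",
                                     "llA1x1", "llA1x0")])),
            collapse = ",")
    }, "")
    filt <- if (all(sc$status == "called")) "PASS" else "no_call"
    writeLines(paste(c(sc$gene_id[1], sc$pos[1] + 1L, ".",
                       sc$allele1[1], sc$allele2[1], ".", filt, "GT:GL",
                       paste(gt, gl, sep = ":")), collapse = "\t"), con)
  }
  invisible(path)
}
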