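## internal helpers

BASES <- c("A", "C", "G", "T")

.setSeed <- function(seed) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
      stop("seed must be a single integer")
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}

## deterministic derived seed for stage `k` of a run seeded with `seed`;
## kept below 2^31 - 1
.deriveSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483629)
}

.otherBases <- function(b) BASES[BASES != b]

## writes a TSV with `# key: value` header comments (seed provenance etc.)
.writeTsv <- function(x, path, header = character()) {
  writeLines(vapply(names(header), function(h)
    sprintf("# %s: %s", h, header[[h]]), ""), path)
  data.table::fwrite(x, path, sep = "\t", col.names = TRUE, append = TRUE)
  invisible(path)
}

.readTsv <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#")]
  as.data.frame(data.table::fread(text = paste(ln, collapse = "\n"),
                                  sep = "\t", header = TRUE))
}
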