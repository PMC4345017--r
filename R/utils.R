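# Shared helpers: seeded RNG splitting, sequence utilities, coordinate
# conversion and plain-text table I/O.

BASES <- c("A", "C", "G", "T")

#' Derive a deterministic sub-seed from a parent seed
#'
#' All randomness in the package flows from one integer seed; components that
#' need independent streams (per-sample libraries, per-feature sequences)
#' derive a child seed from the parent seed and a string key. The derivation
#' hashes the key so that streams are stable under reordering of components.
#'
#' @param seed parent integer seed.
#' @param key character scalar naming the child stream.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(key))
  h <- 0
  for (ch in utf8ToInt(paste0(key, collapse = ""))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer((abs(seed) %% 2147483647 + h) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

random_dna <- function(n, base_comp = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  paste(sample(BASES, n, replace = TRUE, prob = base_comp[BASES]), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' @noRd
check_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) stop(sprintf("%s contains non-ACGT characters", what))
  invisible(x)
}

# 0-based half-open internal intervals <-> GRanges (1-based inclusive)
intervals_to_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = if ("strand" %in% names(df)) df$strand else "*"
  )
}

granges_to_intervals <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}
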