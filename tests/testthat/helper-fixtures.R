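# Shared fixtures, built once per test run and cached.

.fx <- new.env(parent = emptyenv())

# full-scale study: default blueprint and recipe (the conditions the
# synthetic module is specified to emulate), processed end to end
study_fixture <- function() {
  if (is.null(.fx$study)) {
    bp <- blueprint_germline(seed = 101)
    rec <- read_recipe(seed = 101)
    sim <- simulate_study(bp, rec)
    proc <- process_libraries(sim$libs, sim$genome, rec$adapter)
    .fx$study <- list(bp = bp, rec = rec, genome = sim$genome,
                      libs = sim$libs, proc = proc)
  }
  .fx$study
}

# small genome for fast unit tests: a handful of features, light libraries
small_blueprint <- function(seed = 11) {
  blueprint_germline(
    n_known = 2, n_novel = 4, n_decoy = 2, n_mirtron = 1,
    te_families = c("LTR1", "IR1"), copies_per_family = 2,
    n_cisnat = 1, n_trna = 2, n_mrna_utr = 1,
    n_cluster = 3, n_decoy_cluster = 2,
    chrom_lengths = c(chr2 = 40000L, chr3 = 40000L, chrX = 30000L),
    seed = seed)
}

small_recipe <- function(seed = 11, samples = c("s1", "s2", "s3")) {
  read_recipe(
    samples = samples,
    class_counts = c(mirna = 800, mirtron = 100, te_pirna = 900,
                     cluster_pirna = 700, utr_pirna = 250,
                     cisnat_sirna = 150, half_trna = 100, background = 500),
    sample_factors = matrix(1, nrow = 8, ncol = length(samples),
                            dimnames = list(c("mirna", "mirtron", "te_pirna",
                                              "cluster_pirna", "utr_pirna",
                                              "cisnat_sirna", "half_trna",
                                              "background"), samples)),
    seed = seed)
}

small_study_fixture <- function() {
  if (is.null(.fx$small)) {
    bp <- small_blueprint()
    rec <- small_recipe()
    sim <- simulate_study(bp, rec)
    proc <- process_libraries(sim$libs, sim$genome, rec$adapter)
    .fx$small <- list(bp = bp, rec = rec, genome = sim$genome,
                      libs = sim$libs, proc = proc)
  }
  .fx$small
}

# bias-recovery fixture: one deep TE piRNA library with flat planted
# fractions and no ping-pong amplification, mapped
bias_fixture <- function() {
  if (is.null(.fx$bias)) {
    fix <- study_fixture()
    rec <- read_recipe(
      samples = "s1",
      class_counts = c(te_pirna = 20000),
      sample_factors = matrix(1, 1, 1, dimnames = list("te_pirna", "s1")),
      u1_antisense = 0.85,
      a10_sense_by_len = setNames(rep(0.8, 7), 24:30),
      u1_sense_by_len = setNames(rep(0.6, 7), 24:30),
      pingpong_fraction = 0, sense_fraction_te = 0.5,
      seed = 202)
    lib <- simulate_library(fix$genome, rec, "s1")
    proc <- process_libraries(list(s1 = lib), fix$genome, rec$adapter)
    .fx$bias <- list(rec = rec, lib = lib, proc = proc,
                     genome = fix$genome)
  }
  .fx$bias
}

# ping-pong null fixture: no planted pairing and neutral (background)
# U1/A10 composition, so offset-10 coincidences are not compositionally
# enriched
ppnull_fixture <- function() {
  if (is.null(.fx$ppnull)) {
    fix <- study_fixture()
    rec <- read_recipe(
      samples = "s1",
      class_counts = c(te_pirna = 12000),
      sample_factors = matrix(1, 1, 1, dimnames = list("te_pirna", "s1")),
      u1_antisense = 0.25,
      a10_sense_by_len = setNames(rep(0.25, 7), 24:30),
      u1_sense_by_len = setNames(rep(0.25, 7), 24:30),
      pingpong_fraction = 0, sense_fraction_te = 0.5,
      seed = 303)
    lib <- simulate_library(fix$genome, rec, "s1")
    proc <- process_libraries(list(s1 = lib), fix$genome, rec$adapter)
    .fx$ppnull <- list(rec = rec, proc = proc, genome = fix$genome)
  }
  .fx$ppnull
}

# log-sum-exp, for exact binomial tails beyond double underflow
lse <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# signed -log10 exact binomial tail computed in log space (oracle form)
oracle_binom_score <- function(k, n, p0) {
  if (k / n > p0) -lse(dbinom(k:n, n, p0, log = TRUE)) / log(10)
  else lse(dbinom(0:k, n, p0, log = TRUE)) / log(10)
}

# per-read TE orientation for an alignment set (relative to the TE strand)
te_read_orientation <- function(aln, te) {
  gr <- srnapipe:::intervals_to_granges(aln)
  hits <- GenomicRanges::findOverlaps(gr, te, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  data.frame(row = qi,
             sense = aln$strand[qi] ==
               as.character(GenomicRanges::strand(te))[si])
}

# miRNA discovery over the full study (known precursors masked), cached
study_discovered <- function() {
  if (is.null(.fx$discovered)) {
    fix <- study_fixture()
    type <- S4Vectors::mcols(fix$genome$annotation)$type
    known <- fix$genome$annotation[type == "pre_miRNA"]
    .fx$discovered <- list(
      known = known,
      novel = discover_novel_mirnas(fix$proc, fix$genome, known))
  }
  .fx$discovered
}

# truth intervals as GRanges
truth_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start + 1L, df$end),
                         strand = df$strand)
}

# span Jaccard between a truth row and a called interval
span_jaccard <- function(ts, te, cs, ce) {
  inter <- max(0, min(te, ce) - max(ts, cs))
  union <- max(te, ce) - min(ts, cs)
  inter / union
}

# brute-force maximum nested pairing by explicit enumeration of all
# non-crossing pair sets (independent oracle for the fold)
oracle_max_pairs <- function(seq, min_loop = 3L) {
  bases <- strsplit(chartr("TU", "UU", toupper(seq)), "")[[1]]
  ok <- function(a, b) {
    paste0(bases[a], bases[b]) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  }
  n <- length(bases)
  best <- function(i, j) {
    if (j - i < min_loop + 1L) return(0L)
    m <- best(i + 1L, j)
    for (k in (i + min_loop + 1L):j) {
      if (ok(i, k)) {
        m <- max(m, 1L + best(i + 1L, k - 1L) + if (k < j) best(k + 1L, j) else 0L)
      }
    }
    m
  }
  if (n < min_loop + 2L) return(0L)
  best(1L, n)
}

# naive full-scan perfect mapper (independent oracle)
oracle_map <- function(read, genome) {
  hits <- list()
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
  for (chr in names(genome)) {
    s <- genome[[chr]]
    L <- nchar(s); w <- nchar(read)
    if (w > L) next
    for (i in seq_len(L - w + 1L)) {
      sub <- substr(s, i, i + w - 1L)
      if (sub == read) {
        hits[[length(hits) + 1L]] <- data.frame(chrom = chr, start = i - 1L,
                                                end = i - 1L + w, strand = "+")
      }
      if (sub == rc) {
        hits[[length(hits) + 1L]] <- data.frame(chrom = chr, start = i - 1L,
                                                end = i - 1L + w, strand = "-")
      }
    }
  }
  if (!length(hits)) return(NULL)
  do.call(rbind, hits)
}
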