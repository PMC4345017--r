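# Read categorization, size profiles, miRNA-fraction removal, peak calls,
# UTR bias and cis-NAT overlap profiles.

make_index <- function() {
  ann <- GenomicRanges::GRanges(
    c("c1", "c1", "c1", "c1"),
    IRanges::IRanges(c(101, 301, 501, 501), c(200, 400, 700, 600)),
    strand = "+")
  S4Vectors::mcols(ann)$type <- c("rRNA", "intron", "exon", "three_prime_UTR")
  S4Vectors::mcols(ann)$ID <- c("r1", "i1", "e1", "u1")
  S4Vectors::mcols(ann)$Parent <- NA_character_
  te <- GenomicRanges::GRanges("c1", IRanges::IRanges(301, 350), strand = "+")
  S4Vectors::mcols(te)$family <- "LTR1"
  feature_index(ann, te)
}

test_that("categorization uses precedence over all placements", {
  idx <- make_index()
  aln <- data.frame(
    read = c(1L, 1L, 2L, 3L),
    chrom = "c1",
    start = c(310L, 390L, 520L, 10L),
    end = c(332L, 412L, 542L, 32L),
    strand = "+", hit_count = c(2L, 2L, 1L, 1L),
    stringsAsFactors = FALSE)
  cats <- categorize_reads(aln, idx)
  # read 1: one placement in TE (and intron), one in intron -> TE wins
  expect_equal(as.character(cats[["1"]]), "TE")
  # read 2 inside exon + 3UTR -> 3UTR outranks exon
  expect_equal(as.character(cats[["2"]]), "3UTR")
  expect_equal(as.character(cats[["3"]]), "unannotated")
  # multi-placement rRNA vs intron -> rRNA
  aln2 <- data.frame(read = 1L, chrom = "c1", start = c(110L, 310L),
                     end = c(132L, 332L), strand = "+", hit_count = 2L)
  expect_equal(as.character(categorize_reads(aln2, idx)[["1"]]), "rRNA")
})

test_that("size histogram conserves weighted totals", {
  lens <- c(22L, 22L, 29L, 40L)
  cats <- factor(c("miRNA", "miRNA", "TE", "TE"),
                 levels = c(CATEGORY_PRECEDENCE, "unannotated"))
  w <- c(5, 5, 3, 7)
  m <- size_histogram(lens, cats, w)
  expect_equal(m["22", "miRNA"], 10)
  expect_equal(m["29", "TE"], 3)
  expect_equal(sum(m), 13)  # the 40-nt read is outside the window
  expect_equal(sum(size_histogram(integer(0), cats[0], numeric(0))), 0)
})

test_that("miRNA-fraction removal drops all reads touching a precursor", {
  prec <- GenomicRanges::GRanges("c1", IRanges::IRanges(101, 156))
  aln <- data.frame(read = 1:3, chrom = "c1",
                    start = c(110L, 156L, 90L),
                    end = c(132L, 178L, 100L),
                    strand = "+", hit_count = 1L)
  out <- remove_mirna_fraction(aln, prec)
  expect_equal(out$removed_reads, 1L)         # read 2 starts at end (half-open)
  expect_setequal(out$keep_reads, c(2L, 3L))  # read 3 ends 1 nt before
  expect_equal(sort(c(out$keep_reads, out$removed_reads)), 1:3)
})

test_that("peak calling follows the dominance and mass rules", {
  h <- setNames(rep(0, 20), 17:36)
  h["21"] <- 100
  expect_equal(detect_size_peak(h), 21L)
  flat <- setNames(rep(5, 20), 17:36)
  expect_equal(length(detect_size_peak(flat)), 0L)
  # 1.4x neighbour dominance is not enough at the default ratio
  h2 <- setNames(rep(10, 20), 17:36)
  h2["21"] <- 14
  expect_equal(length(detect_size_peak(h2)), 0L)
})

test_that("siRNA peak emerges after removing the miRNA fraction", {
  fix <- study_fixture()
  proc <- fix$proc
  g <- fix$genome
  lens <- nchar(proc$collapsed$seq)
  disc <- study_discovered()
  known <- disc$known
  novel <- disc$novel
  prec <- c(GenomicRanges::granges(known),
            GenomicRanges::granges(srnapipe:::intervals_to_granges(
              novel[, c("chrom", "start", "end", "strand")])))
  before <- proc$aln
  after <- remove_mirna_fraction(before, prec)
  w <- rowSums(proc$collapsed$counts)
  mass <- function(aln, lo, hi) {
    ids <- unique(aln$read[lens[aln$read] >= lo & lens[aln$read] <= hi])
    sum(w[ids])
  }
  # the 20-23 nt mass shrinks when precursor reads are removed
  expect_lt(mass(after$aln, 20, 23), mass(before, 20, 23))
})

test_that("UTR mapping bias follows planted uniform expectation", {
  # transcript of 1000 nt with a 100-nt 3'UTR; uniform sense reads
  g <- c(c1 = srnapipe:::random_dna(2000))
  mrna <- GenomicRanges::GRanges("c1", IRanges::IRanges(501, 1500),
                                 strand = "+")
  S4Vectors::mcols(mrna)$ID <- "m1"
  utr3 <- GenomicRanges::GRanges("c1", IRanges::IRanges(1401, 1500),
                                 strand = "+")
  S4Vectors::mcols(utr3)$Parent <- "m1"
  set.seed(5)
  n <- 2000
  starts <- 500L + sample.int(1000L - 25L, n, replace = TRUE) - 1L
  aln <- data.frame(read = seq_len(n), chrom = "c1", start = starts,
                    end = starts + 25L, strand = "+", hit_count = 1L)
  lens <- rep(25L, n); wts <- rep(1, n)
  out <- utr_fraction_by_size(aln, lens, wts, mrna, utr3)
  row <- out[out$length == 25, ]
  expect_equal(row$mrna_pct, 100)
  # fully-inside-UTR fraction: (100 - 25 + 1)/976 of placements, +-3 sigma
  p <- (100 - 25 + 1) / 976
  sigma <- 100 * sqrt(p * (1 - p) / n)
  expect_lt(abs(row$utr3_pct - 100 * p), 3 * sigma)
  # lengths with no reads are reported missing
  expect_true(is.na(out$mrna_pct[out$length == 30]))
})

test_that("transcripts without a 3'UTR are excluded with a message", {
  mrna <- GenomicRanges::GRanges("c1", IRanges::IRanges(c(1, 600), c(500, 900)),
                                 strand = "+")
  S4Vectors::mcols(mrna)$ID <- c("m1", "m2")
  utr3 <- GenomicRanges::GRanges("c1", IRanges::IRanges(401, 500), strand = "+")
  S4Vectors::mcols(utr3)$Parent <- "m1"
  aln <- data.frame(read = 1L, chrom = "c1", start = 10L, end = 35L,
                    strand = "+", hit_count = 1L)
  expect_message(utr_fraction_by_size(aln, c(25L), c(1), mrna, utr3),
                 "lacking")
})

test_that("overlap profile counts only reads fully inside the overlap", {
  a <- GenomicRanges::GRanges("c1", IRanges::IRanges(1, 300), strand = "+")
  b <- GenomicRanges::GRanges("c1", IRanges::IRanges(201, 500), strand = "-")
  aln <- data.frame(read = 1:3, chrom = "c1",
                    start = c(210L, 190L, 240L),
                    end = c(231L, 211L, 261L),
                    strand = c("+", "+", "-"), hit_count = 1L)
  lens <- c(21L, 21L, 21L); wts <- c(1, 1, 1)
  m <- overlap_region_profile(a, b, aln, lens, wts)
  expect_equal(m["21", "+"], 1)  # read 2 straddles the boundary: excluded
  expect_equal(m["21", "-"], 1)
  # non-overlapping pair is skipped with a message
  b2 <- GenomicRanges::GRanges("c1", IRanges::IRanges(400, 500), strand = "-")
  expect_message(overlap_region_profile(a, b2, aln, lens, wts), "skipping")
})

test_that("planted cis-NAT siRNAs spike at 21 nt inside the overlap", {
  fix <- small_study_fixture()
  g <- fix$genome
  truth <- g$truth[g$truth$class == "cisnat_pair", ]
  proc <- fix$proc
  lens <- nchar(proc$collapsed$seq)
  w <- rowSums(proc$collapsed$counts)
  a <- GenomicRanges::GRanges(truth$chrom,
                              IRanges::IRanges(truth$start + 1L,
                                               truth$overlap_end),
                              strand = "+")
  b <- GenomicRanges::GRanges(truth$chrom,
                              IRanges::IRanges(truth$overlap_start + 1L,
                                               truth$end),
                              strand = "-")
  m <- overlap_region_profile(a, b, proc$aln, lens, w)
  expect_equal(names(which.max(m[, "+"])), "21")
  expect_equal(names(which.max(m[, "-"])), "21")
})
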