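# piRNA characterization: signature selection, cluster gates, TE profiles,
# bias scores, ping-pong, dominant reads, half-tRNAs.

test_that("U1/A10 selection follows first and tenth base rules", {
  seqs <- c("TAAAAAAAAAAAAAAAAAAAAAAAAA",   # U1
            "GGGGGGGGGCGGGGGGGGGGGGGGGG",   # neither
            "GGGGGGGGGAGGGGGGGGGGGGGGGG")   # A10
  keep <- select_u1_a10(seqs)
  expect_equal(keep, c(TRUE, FALSE, TRUE))
  # idempotent partition
  expect_equal(sum(keep) + sum(!keep), length(seqs))
  expect_equal(select_u1_a10(seqs[keep]), rep(TRUE, 2))
  expect_error(select_u1_a10("ACGT"), ">= 10")
})

test_that("cluster gates reject short, siRNA-like and sparse loci", {
  # construct alignments directly: one good cluster, one 21-nt locus,
  # one low-abundance locus
  mk <- function(n, start0, len, chrom = "c1") {
    st <- as.integer(start0 + round(seq(0, 1500, length.out = n)))
    data.frame(read = seq_len(n), chrom = chrom, start = st,
               end = st + len, strand = "+", hit_count = 1L)
  }
  good <- mk(120, 1000, 26L)
  good$end <- good$start + rep(c(26L, 27L), 60)
  sir <- mk(120, 10000, 21L); sir$read <- sir$read + 200L
  sparse <- mk(30, 20000, 26L); sparse$read <- sparse$read + 400L
  aln <- rbind(good, sir, sparse)
  lens <- integer(500)
  lens[good$read] <- good$end - good$start
  lens[sir$read] <- 21L
  lens[sparse$read] <- 26L
  counts <- matrix(0L, 500, 2, dimnames = list(NULL, c("s1", "s2")))
  counts[good$read, ] <- 2L   # recurrent across both samples
  counts[sir$read, ] <- 2L
  counts[sparse$read, "s1"] <- 2L  # 30 reads in one sample: below 50 mean
  norm <- rpm_normalize(counts, c(1000, 1000))
  cl <- call_pirna_clusters(aln, lens, counts, norm)
  expect_equal(nrow(cl), 1L)
  expect_gte(cl$start, 999L)
  expect_true(cl$mean_len >= 26 & cl$mean_len <= 27)
  expect_gt(cl$mean_count, 50)
  # multi-hit reads are ignored
  aln_multi <- good; aln_multi$hit_count <- 2L
  expect_equal(nrow(call_pirna_clusters(aln_multi, lens, counts, norm)), 0L)
})

test_that("planted clusters are recovered with tight spans, decoys are
          not called", {
  fix <- study_fixture()
  proc <- fix$proc
  truth <- fix$genome$truth
  lens <- nchar(proc$collapsed$seq)
  sel <- which(srnapipe:::select_u1_a10_safe(proc$collapsed$seq))
  pal <- proc$aln[proc$aln$read %in% sel, , drop = FALSE]
  cl <- call_pirna_clusters(pal, lens, proc$collapsed$counts, proc$norm)
  real <- truth[truth$class == "pirna_cluster_region" & !truth$decoy, ]
  dec <- truth[truth$class == "pirna_cluster_region" & truth$decoy, ]
  jac <- vapply(seq_len(nrow(real)), function(i) {
    same <- cl[cl$chrom == real$chrom[i], , drop = FALSE]
    if (!nrow(same)) return(0)
    max(vapply(seq_len(nrow(same)), function(j)
      span_jaccard(real$start[i], real$end[i], same$start[j], same$end[j]),
      numeric(1)))
  }, numeric(1))
  expect_true(all(jac >= 0.8))
  dgr <- truth_granges(dec)
  cgr <- GenomicRanges::GRanges(cl$chrom, IRanges::IRanges(cl$start + 1L,
                                                           cl$end))
  expect_equal(sum(IRanges::overlapsAny(dgr, cgr)), 0L)
  # every reported cluster re-passes its gates
  expect_true(all(cl$end - cl$start > 100))
  expect_true(all(cl$mean_len >= 26 & cl$mean_len <= 27))
  expect_true(all(cl$mean_count > 50))
})

test_that("TE strand profile recovers planted orientation fractions", {
  fix <- study_fixture()
  proc <- fix$proc
  lens <- nchar(proc$collapsed$seq)
  tot <- rowSums(proc$collapsed$counts)
  tep <- te_strand_profile(proc$aln, lens, tot, fix$genome$te)
  s <- tep$summary
  expect_true(all(s$antisense_frac > 0.5))  # antisense-dominant by recipe
  # sense fraction ~0.3 planted: antisense fraction within 3 sigma
  for (i in seq_len(nrow(s))) {
    n <- s$sense[i] + s$antisense[i]
    sigma <- sqrt(0.3 * 0.7 / n)
    expect_lt(abs(s$antisense_frac[i] - 0.7), 3 * sigma + 0.05,
              label = s$family[i])
  }
  # the 29-dominant family stands out in the 29:27 ratio
  expect_gt(s$ratio_29_27[s$family == "LTR1"], 1)
  expect_gt(s$ratio_29_27[s$family == "LTR1"],
            max(s$ratio_29_27[s$family != "LTR1"]))
})

test_that("29:27 ratio handles pseudocounts and zero families", {
  expect_equal(ratio_29_27(c(`29` = 30, `27` = 10), pseudocount = 0), 3)
  expect_equal(ratio_29_27(c(`29` = 0, `27` = 0)), 1)
  expect_equal(ratio_29_27(numeric(0)), 1)
})

test_that("positional bias scores equal exact binomial tail sums", {
  # worked example: k = 70 of n = 100 at p0 = 0.25
  seqs <- c(rep("TAAA", 70), rep("GAAA", 30))
  b <- positional_bias(seqs)
  k <- 70; n <- 100
  oracle <- -log10(sum(dbinom(k:n, n, 0.25)))
  expect_equal(b$score[1, "U"], oracle, tolerance = 1e-6)
  # k = 0: large negative score equal to the lower tail 0.75^100
  expect_equal(b$score[2, "U"], log10(0.75^100), tolerance = 1e-6)
  # at the median the magnitude is bounded by log10(2)
  seqs2 <- c(rep("A", 25), rep("C", 25), rep("G", 25), rep("T", 25))
  b2 <- positional_bias(seqs2)
  expect_lte(abs(b2$score[1, "A"]), -log10(0.5) + 1e-9)
  # frequencies sum to one per position
  expect_equal(unname(rowSums(b$freq)), rep(1, 4))
  expect_error(positional_bias(c("AA", "ACA")), "one length")
  expect_error(positional_bias("ACGT", background = c(A = .5, C = .5,
                                                      G = .5, U = .5)),
               "sum to 1")
})

test_that("bias scores agree with exact tails to 6 significant figures", {
  set.seed(13)
  for (trial in 1:200) {
    n <- sample(1:500, 1)
    p0 <- runif(1, 0.05, 0.9)
    k <- sample(0:n, 1)
    got <- srnapipe:::.binom_bias_score(k, n, p0)
    expect_equal(got, oracle_binom_score(k, n, p0), tolerance = 5e-7,
                 label = sprintf("k=%d n=%d p0=%.3f", k, n, p0))
  }
})

test_that("A10/U1 ratio by size recovers planted trends", {
  # constant planted fractions give flat ratios
  set.seed(21)
  mk <- function(len, n, fa, fu) {
    sapply(seq_len(n), function(i) {
      b <- sample(c("A", "C", "G"), len, replace = TRUE)
      b[1] <- if (runif(1) < fu) "T" else "G"
      b[10] <- if (runif(1) < fa) "A" else "C"
      paste(b, collapse = "")
    })
  }
  seqs <- unlist(lapply(24:30, function(l) mk(l, 400, 0.6, 0.6)))
  r <- a10_u1_ratio_by_size(seqs)
  expect_true(all(abs(r$ratio - 1) < 0.25))
  # below the read floor lengths are missing
  few <- mk(24, 10, 0.6, 0.6)
  r2 <- a10_u1_ratio_by_size(few)
  expect_true(is.na(r2$ratio[r2$length == 24]))
})

test_that("joint A10+U1 bias and terminal cytosines compute fractions", {
  seqs <- c(rep("TAAAAAAAAACC", 6), rep("GAAAAAAAAACC", 4))
  jb <- joint_bias_a10_u1(seqs)
  expect_equal(jb$fraction, 0.6)
  # all A10 reads starting with G give zero
  expect_equal(joint_bias_a10_u1(rep("GAAAAAAAAA", 5))$fraction, 0)
  # one qualifying U1 read gives one
  expect_equal(joint_bias_a10_u1("TAAAAAAAAA")$fraction, 1)
  # no qualifying reads: missing
  expect_true(is.na(joint_bias_a10_u1("TAAAAAAAAG")$fraction))
  tc <- terminal_c_fraction(seqs)
  expect_equal(tc$freq_c, c(1, 1))
  # mixed lengths use each read's own terminal positions
  tc2 <- terminal_c_fraction(c("AAC", "AAAACA"))
  expect_equal(tc2$freq_c[tc2$position == "last"], 0.5)
  expect_equal(tc2$freq_c[tc2$position == "last-1"], 0.5)
})

test_that("ping-pong offsets follow the worked coordinate example", {
  # sense 5' at 100 (+); antisense spanning [85,110) has 5' end 109
  sense <- data.frame(chrom = "c1", start = 100L, end = 126L, strand = "+",
                      weight = 2)
  anti <- data.frame(chrom = "c1", start = 85L, end = 110L, strand = "-",
                     weight = 3)
  pp <- pingpong_overlap_histogram(sense, anti)
  expect_equal(unname(pp$histogram[10]), 6)   # product of weights
  expect_equal(sum(pp$histogram), 6)
  expect_true(is.na(pp$z10))                  # a single informative offset
  # no antisense reads: empty histogram
  pp0 <- pingpong_overlap_histogram(sense, sense[0, ])
  expect_equal(sum(pp0$histogram), 0)
  expect_true(is.na(pp0$z10))
})

test_that("ping-pong z-score is high at planted pairing and low without", {
  fix <- study_fixture()
  proc <- fix$proc
  lens <- nchar(proc$collapsed$seq)
  gr <- srnapipe:::intervals_to_granges(proc$aln)
  pir <- lens[proc$aln$read] >= 24 & lens[proc$aln$read] <= 30
  teov <- IRanges::overlapsAny(gr, fix$genome$te, ignore.strand = TRUE)
  ta <- proc$aln[teov & pir, , drop = FALSE]
  ta$weight <- rowSums(proc$norm)[ta$read]
  z <- pingpong_overlap_histogram(ta, ta)$z10
  expect_gt(z, 5)
})

test_that("dominant-read scan applies the two-orders rule", {
  locus <- c("a", "a", "b", "b")
  seqs <- c("TACGTACGTACGTACGTACGTACGTACGT",
            "GGCGTACGTACGTACGTACGTACGTACGT",
            "TTCGTACGTACGTACGTACGTACGTACGT",
            "CCCGTACGTACGTACGTACGTACGTACGT")
  dom <- dominant_read_scan(locus, seqs, c(10000, 50, 500, 50))
  expect_equal(dom$locus, "a")
  expect_equal(dom$first_base, "U")
  expect_equal(dom$length, 29L)
})

test_that("half-tRNA counting respects the 5' anchor tolerance and
          recovers the planted fold change", {
  fix <- study_fixture()
  g <- fix$genome
  proc <- fix$proc
  lens <- nchar(proc$collapsed$seq)
  type <- S4Vectors::mcols(g$annotation)$type
  trna <- g$annotation[type == "tRNA"]
  S4Vectors::mcols(trna)$ID <- S4Vectors::mcols(g$annotation)$ID[type == "tRNA"]
  ht <- half_trna_profile(proc$aln, lens, proc$norm, trna, "ov_bf", "ov_nbf")
  expect_gte(ht$total_fold, 24)
  expect_lte(ht$total_fold, 36)
  # a 32-nt read starting 5 nt inside the tRNA is not counted
  t1 <- trna[as.character(GenomicRanges::strand(trna)) == "+"][1]
  st <- GenomicRanges::start(t1) - 1L
  aln <- data.frame(read = 1:2, chrom = as.character(
    GenomicRanges::seqnames(t1)),
    start = c(st, st + 5L), end = c(st + 32L, st + 37L),
    strand = as.character(GenomicRanges::strand(t1)), hit_count = 1L)
  lens2 <- c(32L, 32L)
  norm2 <- matrix(c(10, 10, 10, 10), 2,
                  dimnames = list(NULL, c("ov_bf", "ov_nbf")))
  ht2 <- half_trna_profile(aln, lens2, norm2, t1, "ov_bf", "ov_nbf")
  expect_equal(sum(ht2$per_trna$ov_bf), 10)
})
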