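# miRNA discovery criteria, star finding, mirtrons, clusters, repeats,
# catalog comparison.

test_that("5' homogeneity arithmetic and boundaries", {
  # 9 reads at one start, 1 shifted -> 0.9, passes when 3' is no tighter
  h <- five_prime_homogeneity(c(rep(100, 9), 101), c(rep(121, 6), 120:123),
                              tau5 = 0.9)
  expect_equal(h$frac5, 0.9)
  expect_true(h$pass)
  # uniform starts over 4 positions fail
  h2 <- five_prime_homogeneity(c(100, 101, 102, 103), rep(121, 4))
  expect_equal(h2$frac5, 0.25)
  expect_false(h2$pass)
  # single read trivially passes
  h3 <- five_prime_homogeneity(100, 121)
  expect_equal(h3$frac5, 1)
  expect_true(h3$pass)
  # counts weight the modal fraction
  h4 <- five_prime_homogeneity(c(100, 101), c(121, 122), counts = c(95, 5))
  expect_equal(h4$frac5, 0.95)
})

test_that("multi-sample support thresholds", {
  expect_true(multi_sample_support(c(a = 3, b = 0, c = 1, d = 0, e = 0,
                                     f = 2, g = 0)))
  expect_false(multi_sample_support(c(a = 9, b = 0, c = 0)))
  expect_true(multi_sample_support(c(a = 1, b = 1), min_samples = 2))
  expect_error(multi_sample_support(c(a = 5)), "two libraries")
})

test_that("find_star prefers abundance then the 5'-most candidate", {
  hp <- synthesize_hairpin(24, 8, seed = 9)
  f <- fold_maxpair(hp$seq)
  good <- data.frame(start = hp$star[1], end = hp$star[2], count = 10)
  bad <- data.frame(start = hp$star[1] - 1L, end = hp$star[2] - 1L,
                    count = 99)
  # geometry beats abundance: the shifted high-count candidate fails
  pick <- find_star(f, hp$mature, rbind(bad, good))
  expect_equal(pick$start, hp$star[1])
  # no opposite-arm reads -> NULL
  expect_null(find_star(f, hp$mature,
                        data.frame(start = hp$mature[1], end = hp$mature[2],
                                   count = 5)))
})

test_that("planted hairpins are discovered and decoys rejected", {
  fix <- study_fixture()
  disc <- study_discovered()
  truth <- fix$genome$truth
  novel <- disc$novel
  ngr <- truth_granges(novel[, c("chrom", "start", "end", "strand")])
  hp <- truth[truth$class == "mirna_hairpin" & !truth$known, ]
  dec <- truth[truth$class == "decoy_hairpin", ]
  hit <- IRanges::overlapsAny(truth_granges(hp), ngr)
  expect_gte(mean(hit), 0.9)
  expect_equal(sum(IRanges::overlapsAny(truth_granges(dec), ngr)), 0L)
  # known precursors are excluded from the novel set
  known_t <- truth[truth$class == "mirna_hairpin" & truth$known, ]
  expect_equal(sum(IRanges::overlapsAny(truth_granges(known_t), ngr)), 0L)
})

test_that("discovered loci re-pass their criteria independently", {
  fix <- study_fixture()
  disc <- study_discovered()
  novel <- disc$novel
  proc <- fix$proc
  lens <- nchar(proc$collapsed$seq)
  tot <- rowSums(proc$collapsed$counts)
  for (i in sample.int(nrow(novel), min(8, nrow(novel)))) {
    l <- novel[i, ]
    # duplex geometry re-validates on the padded read-stack window fold
    # (the window the discovery criteria are defined on)
    ws <- max(0L, l$mature_start - 70L)
    we <- min(nchar(fix$genome$seqs[[l$chrom]]), l$mature_end + 70L)
    f <- fold_maxpair(srnapipe:::genome_subseq(fix$genome$seqs, l$chrom,
                                               ws, we, l$strand))
    mloc <- srnapipe:::.local_coords(l$mature_start, l$mature_end,
                                     ws, we, l$strand)
    sloc <- srnapipe:::.local_coords(l$star_start, l$star_end,
                                     ws, we, l$strand)
    expect_true(duplex_overhang_check(f, mloc, sloc)$pass, info = l$id)
    # homogeneity and support re-validate
    expect_gte(l$frac5, 0.9)
    sc <- unlist(l[grep("^count_", names(l))])
    expect_true(multi_sample_support(sc))
  }
})

test_that("raising the homogeneity threshold never reports more loci", {
  fix <- small_study_fixture()
  n_loose <- nrow(discover_novel_mirnas(fix$proc, fix$genome, tau5 = 0.7))
  n_mid <- nrow(discover_novel_mirnas(fix$proc, fix$genome, tau5 = 0.9))
  n_tight <- nrow(discover_novel_mirnas(fix$proc, fix$genome, tau5 = 0.99))
  expect_gte(n_loose, n_mid)
  expect_gte(n_mid, n_tight)
})

test_that("mirtrons are discovered, with uridylation excusing a lost star", {
  fix <- study_fixture()
  g <- fix$genome
  type <- S4Vectors::mcols(g$annotation)$type
  introns <- g$annotation[type == "intron"]
  mt <- discover_mirtrons(fix$proc, g, introns)
  truth <- g$truth[g$truth$class == "mirtron_host", ]
  expect_equal(nrow(mt), 2L)
  # the star-less locus is reported on uridylation evidence
  starless <- truth[!truth$has_star, ]
  row <- mt[mt$chrom == starless$chrom &
              mt$start >= starless$start & mt$end <= starless$end, ]
  expect_equal(nrow(row), 1L)
  expect_true(is.na(row$star_start))
  expect_gte(row$urid_frac, 0.5)
})

test_that("long introns are excluded from mirtron discovery", {
  fix <- study_fixture()
  g <- fix$genome
  type <- S4Vectors::mcols(g$annotation)$type
  introns <- g$annotation[type == "intron"]
  mt <- discover_mirtrons(fix$proc, g, introns, max_intron = 50L)
  expect_equal(nrow(mt), 0L)  # planted introns are 60 nt
})

test_that("locus clustering chains by gap and transitivity", {
  loci <- data.frame(
    chrom = c("c1", "c1", "c1", "c2"),
    start = c(1000L, 4100L, 60000L, 1000L),
    end = c(1100L, 4200L, 60100L, 1100L))
  ids <- cluster_loci(loci, max_gap = 10000L)
  expect_equal(ids[1], ids[2])       # 3 kb apart
  expect_true(is.na(ids[3]))         # > 10 kb away: singleton
  expect_true(is.na(ids[4]))         # other chromosome
  ids2 <- cluster_loci(loci, max_gap = 1000L)
  expect_true(all(is.na(ids2)))      # 50 kb apart under a 1 kb gap
  # chain of 9 loci 2 kb apart collapses into one cluster
  chain <- data.frame(chrom = "c1",
                      start = seq(0L, by = 2100L, length.out = 9),
                      end = seq(100L, by = 2100L, length.out = 9))
  expect_equal(length(unique(cluster_loci(chain, 10000L))), 1L)
})

test_that("repeat overlap flags use half-open boundaries", {
  loci <- data.frame(chrom = "c1", start = c(100L, 300L), end = c(200L, 400L))
  reps <- GenomicRanges::GRanges("c1", IRanges::IRanges(150, 170))
  out <- flag_repeat_overlap(loci, reps)
  expect_equal(out$flag, c(TRUE, FALSE))
  expect_equal(out$fraction, 0.5)
  # adjacent but non-overlapping repeat does not flag
  adj <- GenomicRanges::GRanges("c1", IRanges::IRanges(201, 299))
  expect_equal(flag_repeat_overlap(loci, adj)$flag, c(FALSE, FALSE))
  expect_equal(flag_repeat_overlap(loci, NULL)$fraction, 0)
})

test_that("catalog comparison reproduces the 63 minus 18 arithmetic", {
  set.seed(8)
  loci <- data.frame(chrom = "c1",
                     start = seq(0L, by = 1000L, length.out = 63),
                     end = seq(200L, by = 1000L, length.out = 63),
                     strand = "+")
  prior_idx <- sample.int(63, 18)
  prior <- GenomicRanges::GRanges("c1",
    IRanges::IRanges(loci$start[prior_idx] + 50L, loci$end[prior_idx] - 50L),
    strand = "+")
  out <- compare_catalog(loci, prior)
  expect_equal(out$n_reported, 18L)
  expect_equal(out$n_novel, 45L)
  # same interval on the opposite strand does not match
  opp <- GenomicRanges::GRanges("c1", IRanges::IRanges(loci$start + 50L,
                                                       loci$end - 50L),
                                strand = "-")
  expect_equal(compare_catalog(loci, opp)$n_novel, 63L)
  # exact mature sequence match flags a locus
  loci$mature_seq <- replicate(63, srnapipe:::random_dna(22))
  out2 <- compare_catalog(loci, NULL, prior_matures = loci$mature_seq[1])
  expect_equal(out2$n_reported, 1L)
})
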