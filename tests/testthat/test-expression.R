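# Size factors, NB exact-style test, BH, heatmap classes, sex bias,
# Fisher enrichment.

test_that("median-of-ratios size factors on stated examples and a formula
          oracle", {
  m <- matrix(rep(c(10, 20, 30), 3), ncol = 3)
  expect_equal(unname(size_factors_median_ratio(m)), rep(1, 3))
  m2 <- cbind(a = c(10, 20, 30), b = c(20, 40, 60))
  sf <- size_factors_median_ratio(m2)
  expect_equal(unname(sf["b"] / sf["a"]), 2)
  # random matrix vs direct re-computation of the formula
  set.seed(12)
  m3 <- matrix(rpois(200, 50) + 1L, nrow = 50, ncol = 4)
  sf3 <- size_factors_median_ratio(m3)
  gm <- exp(rowMeans(log(m3)))
  oracle <- apply(sweep(m3, 1, gm, "/"), 2, median)
  expect_equal(unname(sf3), unname(oracle))
  # all-zero-containing rows fall back to library size with a message
  m4 <- matrix(c(0, 5, 3, 0), 2)
  expect_message(size_factors_median_ratio(m4), "library-size")
})

test_that("NB test is near 1 for symmetric counts and label-swap
          invariant", {
  m <- matrix(c(10, 12, 11, 10), nrow = 1,
              dimnames = list("l", c("a1", "a2", "b1", "b2")))
  sf <- setNames(rep(1, 4), colnames(m))
  p <- nb_test(m, c("a1", "a2"), c("b1", "b2"), sf)$pval
  expect_gte(p, 0.8)
  expect_lte(p, 1)
  set.seed(3)
  mm <- matrix(rnbinom(300, mu = 80, size = 5), ncol = 6)
  colnames(mm) <- c(paste0("a", 1:3), paste0("b", 1:3))
  r1 <- nb_test(mm, paste0("a", 1:3), paste0("b", 1:3))
  r2 <- nb_test(mm, paste0("b", 1:3), paste0("a", 1:3))
  expect_equal(r1$pval, r2$pval)
  expect_equal(r1$log2fc, -r2$log2fc)
})

test_that("dispersion floor reduces to the exact binomial split test", {
  sf <- setNames(c(1, 1), c("a", "b"))
  for (k in c(5L, 20L, 60L)) {
    m <- matrix(c(k, 0L), nrow = 1, dimnames = list("l", c("a", "b")))
    p <- nb_test(m, "a", "b", sf)$pval
    oracle <- binom.test(k, k, 0.5)$p.value
    expect_lt(abs(p - oracle) / oracle, 0.1, label = paste("k =", k))
  }
  # all-zero locus gets p = 1
  m0 <- matrix(c(0L, 0L), nrow = 1, dimnames = list("l", c("a", "b")))
  expect_equal(nb_test(m0, "a", "b", sf)$pval, 1)
})

test_that("BH adjustment matches a hand-run step-up and validates input", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  p <- c(0.01, 0.02, 0.03, 0.5)
  # step-up by hand: p_(i) * n / i with monotonicity from the top
  hand <- c(0.01 * 4 / 1, 0.02 * 4 / 2, 0.03 * 4 / 3, 0.5)
  hand <- rev(cummin(rev(hand)))
  expect_equal(bh_adjust(p), hand)
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  pp <- sort(runif(30))
  adj <- bh_adjust(pp)
  expect_true(all(adj >= pp))
  expect_true(all(diff(adj) >= 0))
})

test_that("planted differential loci are recovered with controlled false
          discoveries", {
  set.seed(7)
  mu <- exp(rnorm(500, log(100), 0.8))
  fc <- rep(1, 500); fc[1:50] <- 10
  m <- cbind(sapply(1:10, function(j) rnbinom(500, mu = mu, size = 10)),
             sapply(1:10, function(j) rnbinom(500, mu = mu * fc, size = 10)))
  colnames(m) <- c(paste0("a", 1:10), paste0("b", 1:10))
  # the generator has no library-size variation: unit size factors are the
  # ground truth (median-of-ratios estimation is exercised separately)
  res <- nb_test(m, paste0("a", 1:10), paste0("b", 1:10),
                 size_factors = setNames(rep(1, 20), colnames(m)))
  padj <- bh_adjust(res$pval)
  expect_gte(mean(padj[1:50] < 0.01), 0.9)
  n_false <- sum(padj[-(1:50)] < 0.01)
  expect_lte(n_false / max(1, sum(padj < 0.01)), 0.05)
})

test_that("heatmap classes filter at count > 20 and separate archetypes", {
  set.seed(9)
  base <- rbind(
    matrix(rpois(40, 2000), 10, 4),   # ubiquitous high
    matrix(rpois(40, 60), 10, 4),     # low
    cbind(matrix(rpois(20, 5), 10, 2), matrix(rpois(20, 2000), 10, 2)))
  colnames(base) <- paste0("s", 1:4)
  rownames(base) <- paste0("l", 1:30)
  out <- expression_heatmap_classes(base, k = 3)
  cls <- out$classes
  expect_equal(length(unique(cls[1:10])), 1L)
  expect_equal(length(unique(cls[11:20])), 1L)
  expect_equal(length(unique(cls[21:30])), 1L)
  expect_equal(length(unique(cls)), 3L)
  # strict > 20 filter
  m <- rbind(rep(20L, 4), rep(21L, 4), base)
  out2 <- expression_heatmap_classes(m, k = 3)
  expect_false(out2$keep[1])
  expect_true(out2$keep[2])
  # duplicated rows share a class
  dup <- rbind(base, base[1, , drop = FALSE])
  out3 <- expression_heatmap_classes(dup, k = 3)
  expect_equal(out3$classes[[1]], out3$classes[[31]])
  expect_error(expression_heatmap_classes(matrix(100L, 2, 3), k = 3),
               "fewer than k")
})

test_that("sex-bias calls gate on adjusted p and fold", {
  res <- data.frame(log2fc = c(3, 1, 3, -3), padj = c(0.005, 0.005, 0.02,
                                                      0.001))
  calls <- sex_bias_call(res)
  expect_equal(calls, c("testes-biased", "unbiased", "unbiased",
                        "ovary-biased"))
})

test_that("Fisher enumeration equals fisher.test over all small tables", {
  # exhaustive over margins <= 12 here (the acceptance suite pushes to 30)
  for (r1 in 0:12) {
    for (c1 in 0:12) {
      tot <- 12L
      for (k in max(0, r1 + c1 - tot):min(r1, c1)) {
        m <- matrix(c(k, r1 - k, c1 - k, tot - r1 - c1 + k), 2, byrow = TRUE)
        if (any(m < 0)) next
        expect_equal(fisher_exact_2x2(m),
                     stats::fisher.test(m)$p.value, tolerance = 1e-9,
                     label = paste(m, collapse = ","))
      }
    }
  }
})

test_that("X-enrichment reproduces the printed worked example", {
  enr <- chromosome_enrichment(20, 31, 23, 99)
  expect_equal(enr$pct_x, 64.5)
  expect_lt(enr$pvalue, 1e-3)
  # stated 2x2 example equals brute-force tail enumeration via dhyper
  m <- matrix(c(20, 11, 23, 76), 2, byrow = TRUE)
  support <- 0:31
  probs <- dhyper(support, 43, 130 - 43, 31)
  brute <- sum(probs[probs <= dhyper(20, 43, 87, 31) * (1 + 1e-7)])
  expect_equal(fisher_exact_2x2(m), brute)
  # null case: biased X proportion equals background
  null <- chromosome_enrichment(5, 20, 25, 100)
  expect_gt(null$pvalue, 0.5)
  # zero biased loci
  z <- chromosome_enrichment(0, 0, 25, 100)
  expect_true(is.na(z$pct_x))
  expect_equal(z$pvalue, 1)
})
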