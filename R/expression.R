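# Expression profiling: median-of-ratios size factors, a negative-binomial
# exact-style two-group test with pooled method-of-moments dispersion,
# Benjamini-Hochberg adjustment, heatmap expression classes, sex-bias calls
# and chromosomal (X) enrichment by a two-sided Fisher exact test computed
# from hypergeometric enumeration.

#' Median-of-ratios size factors
#'
#' For each sample, the factor is the median over loci with all-positive
#' counts of the ratio of the sample's count to the locus geometric mean.
#' When no locus has all-positive counts, falls back to library-size ratios
#' with a message.
#'
#' @param mat integer count matrix (loci x samples).
#' @return named numeric vector of size factors.
#' @export
size_factors_median_ratio <- function(mat) {
  stopifnot(is.matrix(mat), all(mat >= 0))
  allpos <- rowSums(mat > 0) == ncol(mat)
  if (!any(allpos)) {
    message("size_factors_median_ratio: no all-positive locus; ",
            "falling back to library-size ratios")
    tot <- colSums(mat)
    return(tot / exp(mean(log(tot))))
  }
  m <- mat[allpos, , drop = FALSE]
  gm <- exp(rowMeans(log(m)))
  apply(m / gm, 2L, median)
}

#' Negative-binomial exact-style test for a two-group contrast
#'
#' Per locus, a pooled dispersion is estimated by method of moments on
#' size-factor-normalized counts (floored at 1e-8) and the condition totals
#' are modelled as negative binomial with moment-matched means and
#' variances. The two-sided p-value sums the probabilities of all splits
#' (a, b) of the observed total whose joint probability does not exceed
#' that of the observed split, normalized by the total probability over
#' splits. All-zero loci get p = 1. The log2 fold change is taken between
#' the normalized condition means (B over A).
#'
#' @param mat count matrix (loci x samples).
#' @param cond_a,cond_b column names or indices of the two conditions.
#' @param size_factors per-sample size factors (default: median-of-ratios).
#' @return data.frame `locus`, `mean_a`, `mean_b`, `log2fc`, `pval`.
#' @export
nb_test <- function(mat, cond_a, cond_b, size_factors = NULL) {
  stopifnot(is.matrix(mat))
  if (is.null(size_factors)) size_factors <- size_factors_median_ratio(mat)
  a <- mat[, cond_a, drop = FALSE]
  b <- mat[, cond_b, drop = FALSE]
  sf_a <- size_factors[cond_a]; sf_b <- size_factors[cond_b]
  xn <- cbind(sweep(a, 2L, sf_a, "/"), sweep(b, 2L, sf_b, "/"))
  zf <- mean(1 / c(sf_a, sf_b))
  n <- nrow(mat)
  pval <- numeric(n)
  l2fc <- numeric(n)
  mean_a <- rowMeans(sweep(a, 2L, sf_a, "/"))
  mean_b <- rowMeans(sweep(b, 2L, sf_b, "/"))
  na <- ncol(a); nb <- ncol(b)
  for (i in seq_len(n)) {
    ka <- sum(a[i, ]); kb <- sum(b[i, ])
    tot <- ka + kb
    if (tot == 0) { pval[i] <- 1; l2fc[i] <- 0; next }
    m <- mean(xn[i, ])
    # pooled within-condition variance so that a real between-condition
    # difference does not inflate its own dispersion estimate; the chi-square
    # median correction guards the extreme tail against downward-noisy
    # per-locus variance estimates (no information is shared across loci)
    xa <- xn[i, seq_len(na)]; xb <- xn[i, na + seq_len(nb)]
    df <- (na - 1L) + (nb - 1L)
    v <- if (df > 0) {
      (sum((xa - mean(xa))^2) + sum((xb - mean(xb))^2)) / qchisq(0.5, df)
    } else 0
    alpha <- max((v - m * zf) / m^2, 1e-8)
    q <- tot / (sum(sf_a) + sum(sf_b))
    p_split <- .nb_split_probs(tot, q, sf_a, sf_b, alpha)
    p_obs <- p_split[ka + 1L]
    pval[i] <- min(1, sum(p_split[p_split <= p_obs * (1 + 1e-7)]) /
                     sum(p_split))
    l2fc[i] <- log2(mean_b[i] / mean_a[i])
  }
  data.frame(locus = if (!is.null(rownames(mat))) rownames(mat)
                     else seq_len(n),
             mean_a = mean_a, mean_b = mean_b, log2fc = l2fc, pval = pval,
             stringsAsFactors = FALSE)
}

# probabilities of splitting total `tot` into condition sums (a, tot - a)
# under moment-matched NB marginals (Poisson in the small-dispersion limit)
.nb_split_probs <- function(tot, q, sf_a, sf_b, alpha) {
  aa <- 0:tot
  dens <- function(k, sfs) {
    mu_s <- q * sfs
    mu <- sum(mu_s)
    v <- sum(mu_s + alpha * mu_s^2)
    if (v <= mu * (1 + 1e-12)) dpois(k, mu)
    else dnbinom(k, mu = mu, size = mu^2 / (v - mu))
  }
  dens(aa, sf_a) * dens(tot - aa, sf_b)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement, capped at 1.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("bh_adjust: p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Expression classes from log-scale hierarchical clustering
#'
#' Loci with maximum raw count > `min_count` in at least one sample are
#' kept; values are log10(normalized + 1); average-linkage hierarchical
#' clustering on Euclidean distances is cut into `k` classes.
#'
#' @param mat raw count matrix (loci x samples).
#' @param norm normalized matrix, same shape (default: RPM over column
#'   totals of `mat`).
#' @param min_count strict minimum of the per-locus maximum raw count.
#' @param k number of classes.
#' @return list `logmat` (filtered log matrix), `classes` (integer labels),
#'   `keep` (logical row filter).
#' @export
expression_heatmap_classes <- function(mat, norm = NULL, min_count = 20L,
                                       k = 3L) {
  stopifnot(is.matrix(mat))
  if (is.null(norm)) norm <- rpm_normalize(mat, colSums(mat))
  keep <- apply(mat, 1L, max) > min_count
  if (sum(keep) < k) {
    stop("expression_heatmap_classes: fewer than k loci pass the filter")
  }
  lm <- log10(norm[keep, , drop = FALSE] + 1)
  hc <- hclust(dist(lm), method = "average")
  classes <- cutree(hc, k = k)
  list(logmat = lm, classes = classes, keep = keep)
}

#' Call sex-biased loci from a differential contrast
#'
#' Biased iff the adjusted p-value is below `alpha` and the absolute log2
#' fold change reaches log2(`min_fold`); direction follows the sign (the
#' contrast's B condition is the first label).
#'
#' @param results data.frame with `log2fc` and `padj`.
#' @param alpha adjusted-p threshold (default 0.01).
#' @param min_fold minimum fold change (default 4).
#' @param labels category names for positive, negative and unbiased calls.
#' @return character vector of calls.
#' @export
sex_bias_call <- function(results, alpha = 0.01, min_fold = 4,
                          labels = c("testes-biased", "ovary-biased",
                                     "unbiased")) {
  lfc <- results$log2fc
  biased <- results$padj < alpha & !is.na(lfc) & abs(lfc) >= log2(min_fold)
  out <- rep(labels[3], nrow(results))
  out[biased & lfc > 0] <- labels[1]
  out[biased & lfc < 0] <- labels[2]
  out
}

#' Two-sided Fisher exact test on a 2x2 table by enumeration
#'
#' Enumerates all tables with the observed margins, summing the
#' hypergeometric probabilities of tables no more probable than the
#' observed one (with the customary (1 + 1e-7) tolerance).
#'
#' @param m 2x2 integer matrix.
#' @return two-sided p-value.
#' @export
fisher_exact_2x2 <- function(m) {
  stopifnot(all(dim(m) == c(2L, 2L)), all(m >= 0))
  k <- m[1, 1]
  row1 <- sum(m[1, ]); col1 <- sum(m[, 1]); tot <- sum(m)
  lo <- max(0L, col1 - (tot - row1))
  hi <- min(row1, col1)
  support <- lo:hi
  probs <- dhyper(support, col1, tot - col1, row1)
  p_obs <- dhyper(k, col1, tot - col1, row1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

#' Chromosomal enrichment of biased loci
#'
#' Builds the 2x2 table (biased/unbiased x target-chromosome/other), tests
#' it with the two-sided Fisher exact test and reports the percentage of
#' biased loci on the target chromosome (one decimal).
#'
#' @param biased_x,biased_total counts of biased loci on the target
#'   chromosome and in total.
#' @param unbiased_x,unbiased_total same for unbiased loci.
#' @return list of class `enrichment_table`: `table`, `pvalue`,
#'   `pct_x` (NA when no biased loci, with p = 1).
#' @export
chromosome_enrichment <- function(biased_x, biased_total,
                                  unbiased_x, unbiased_total) {
  stopifnot(biased_x <= biased_total, unbiased_x <= unbiased_total)
  tab <- matrix(c(biased_x, biased_total - biased_x,
                  unbiased_x, unbiased_total - unbiased_x),
                nrow = 2L, byrow = TRUE,
                dimnames = list(c("biased", "unbiased"), c("X", "non-X")))
  if (biased_total == 0) {
    return(structure(list(table = tab, pvalue = 1, pct_x = NA_real_),
                     class = "enrichment_table"))
  }
  structure(list(table = tab,
                 pvalue = fisher_exact_2x2(tab),
                 pct_x = round(100 * biased_x / biased_total, 1)),
            class = "enrichment_table")
}

#' @export
print.enrichment_table <- function(x, ...) {
  print(x$table)
  cat(sprintf("X-linked among biased: %.1f%%; Fisher two-sided p = %.3g\n",
              x$pct_x, x$pvalue))
  invisible(x)
}
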