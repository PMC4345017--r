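# piRNA and endo-siRNA characterization: U1/A10 enrichment filtering,
# cluster calling on unique-mapping reads, TE strand/size profiling, 29:27
# ratios, positional nucleotide-bias scoring against a background model,
# ping-pong overlap diagnostics, dominant-read and 5' half-tRNA detection.

#' Select reads carrying the piRNA U1 or A10 signature
#'
#' Keeps reads whose first base is U or whose tenth base is A (read
#' sequence space; T is read as U).
#'
#' @param seqs character vector of read sequences (>= 10 nt).
#' @return logical keep vector.
#' @export
select_u1_a10 <- function(seqs) {
  if (any(nchar(seqs) < 10L)) stop("select_u1_a10: reads must be >= 10 nt")
  substr(seqs, 1L, 1L) %in% c("T", "U") | substr(seqs, 10L, 10L) == "A"
}

# strand-aware 5' coordinate of 0-based half-open alignments
.five_prime0 <- function(aln) {
  ifelse(aln$strand == "+", aln$start, aln$end - 1L)
}

#' Call piRNA clusters from unique-mapping signature-selected reads
#'
#' Chains are seeded at 5' positions supported by at least `min_pos_reads`
#' reads (recurrent 5' ends; singleton positions are treated as degradation
#' noise) and extended while consecutive seed positions lie within
#' `max_gap`. Each chained locus collects every unique-mapping read whose
#' 5' end falls inside the seed span and is reported iff the genomic span
#' exceeds `min_span`, the mean length of the distinct supporting sequences
#' lies in `len_range`, and the mean across samples of the summed raw read
#' counts exceeds `min_mean_count` (the abundance gate operates on read
#' counts; normalized abundance is reported alongside). Only alignments
#' with `hit_count == 1` are used.
#'
#' @param aln alignment data.frame (filtered internally to unique hits).
#' @param lengths per-read lengths indexed by read id.
#' @param counts raw count matrix (reads x samples), for seed support and
#'   the abundance gate.
#' @param norm normalized count matrix (reads x samples), reported.
#' @param max_gap chaining gap (default 500 nt).
#' @param min_span minimum locus span, exclusive (default 100 bp).
#' @param len_range admissible mean read length (default [26, 27]).
#' @param min_mean_count minimum mean per-sample read count (default 50).
#' @param min_pos_reads minimum summed reads at a seed position (default 2).
#' @return data.frame of clusters: `chrom`, `start`, `end`, `n_seqs`,
#'   `mean_len`, `mean_count`, `mean_norm`, `plus_frac`.
#' @export
call_pirna_clusters <- function(aln, lengths, counts, norm, max_gap = 500L,
                                min_span = 100L, len_range = c(26, 27),
                                min_mean_count = 50, min_pos_reads = 2L) {
  uni <- aln[aln$hit_count == 1L, , drop = FALSE]
  if (!nrow(uni)) return(.empty_clusters())
  support <- rowSums(counts)
  uni$five <- .five_prime0(uni)
  out <- list()
  for (chr in unique(uni$chrom)) {
    sub <- uni[uni$chrom == chr, , drop = FALSE]
    pos_support <- tapply(support[sub$read], sub$five, sum)
    seeds <- sort(as.integer(names(pos_support)[pos_support >= min_pos_reads]))
    if (!length(seeds)) next
    grp <- cumsum(c(1L, diff(seeds) > max_gap))
    for (g in unique(grp)) {
      span_pos <- seeds[grp == g]
      # boundary refinement: drop terminal seeds separated from the chain
      # body by far more than the typical intra-chain seed spacing
      while (length(span_pos) > 2L) {
        gaps <- diff(span_pos)
        cut <- max(50, 10 * median(gaps))
        if (gaps[1] > cut) span_pos <- span_pos[-1]
        else if (gaps[length(gaps)] > cut) span_pos <- span_pos[-length(span_pos)]
        else break
      }
      cl <- sub[sub$five >= span_pos[1] & sub$five <= span_pos[length(span_pos)], ,
                drop = FALSE]
      span <- max(cl$end) - min(cl$start)
      if (span <= min_span) next
      rids <- unique(cl$read)
      mean_len <- mean(lengths[rids])
      if (mean_len < len_range[1] || mean_len > len_range[2]) next
      mean_count <- mean(colSums(counts[rids, , drop = FALSE]))
      if (mean_count <= min_mean_count) next
      mean_norm <- mean(colSums(norm[rids, , drop = FALSE]))
      out[[length(out) + 1L]] <- data.frame(
        chrom = chr, start = min(cl$start), end = max(cl$end),
        n_seqs = length(rids), mean_len = mean_len,
        mean_count = mean_count, mean_norm = mean_norm,
        plus_frac = mean(cl$strand == "+"), stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(.empty_clusters())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.empty_clusters <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             n_seqs = integer(), mean_len = numeric(), mean_count = numeric(),
             mean_norm = numeric(), plus_frac = numeric(),
             stringsAsFactors = FALSE)
}

#' Per-family TE strand and size profile
#'
#' Counts reads per TE family, per length and per orientation relative to
#' the TE strand, weighting each placement by `count / hit_count`.
#' Families with no reads are omitted with a message.
#'
#' @param aln alignment data.frame.
#' @param lengths per-read lengths indexed by read id.
#' @param weights per-read counts (raw or normalized) indexed by read id.
#' @param te GRanges of TE copies with a `family` metadata column.
#' @param len_range profiled lengths (default 17-36).
#' @return list of class `te_profile`: `by_length` (data.frame family x
#'   length with `sense`/`antisense` weights) and `summary` (per family:
#'   totals, `antisense_frac`, `ratio_29_27`).
#' @export
te_strand_profile <- function(aln, lengths, weights, te,
                              len_range = c(17L, 36L)) {
  fam <- S4Vectors::mcols(te)$family
  gr <- intervals_to_granges(aln)
  hits <- GenomicRanges::findOverlaps(gr, te, minoverlap = 1L,
                                      ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  if (!length(qi)) {
    message("te_strand_profile: no TE-mapped reads")
    return(structure(list(by_length = NULL, summary = NULL),
                     class = "te_profile"))
  }
  d <- data.frame(
    family = fam[si],
    len = lengths[aln$read[qi]],
    sense = aln$strand[qi] == as.character(GenomicRanges::strand(te))[si],
    w = weights[aln$read[qi]] / aln$hit_count[qi])
  d <- d[d$len >= len_range[1] & d$len <= len_range[2], , drop = FALSE]
  missing <- setdiff(unique(fam), unique(d$family))
  if (length(missing)) {
    message("te_strand_profile: omitting family(ies) with zero reads: ",
            paste(missing, collapse = ", "))
  }
  lens <- len_range[1]:len_range[2]
  agg <- function(sel) {
    t0 <- tapply(d$w[sel], list(d$family[sel], factor(d$len[sel], levels = lens)),
                 sum)
    t0[is.na(t0)] <- 0
    t0
  }
  sm <- agg(d$sense); am <- agg(!d$sense)
  by_len <- do.call(rbind, lapply(sort(unique(d$family)), function(f) {
    data.frame(family = f, length = lens,
               sense = if (f %in% rownames(sm)) as.numeric(sm[f, ]) else 0,
               antisense = if (f %in% rownames(am)) as.numeric(am[f, ]) else 0,
               stringsAsFactors = FALSE)
  }))
  summ <- do.call(rbind, lapply(split(by_len, by_len$family), function(x) {
    data.frame(family = x$family[1],
               sense = sum(x$sense), antisense = sum(x$antisense),
               antisense_frac = sum(x$antisense) /
                 (sum(x$sense) + sum(x$antisense)),
               ratio_29_27 = ratio_29_27(
                 setNames(x$sense + x$antisense, x$length)),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  structure(list(by_length = by_len, summary = summ), class = "te_profile")
}

#' 29 vs 27 nt abundance ratio
#'
#' `(count_29 + c) / (count_27 + c)` with pseudocount `c` (default 1) to
#' keep zero-count families finite.
#'
#' @param counts named numeric vector of per-length counts.
#' @param pseudocount added to both terms.
#' @return the ratio.
#' @export
ratio_29_27 <- function(counts, pseudocount = 1) {
  c29 <- if ("29" %in% names(counts)) counts[["29"]] else 0
  c27 <- if ("27" %in% names(counts)) counts[["27"]] else 0
  (c29 + pseudocount) / (c27 + pseudocount)
}

#' Positional nucleotide-bias matrix with binomial scores
#'
#' For reads of one length (and strand class), computes per position and
#' base the observed frequency and a signed score against a background
#' probability: over-represented cells (freq > background) score
#' `-log10 P(X >= k)` (positive), under-represented cells score
#' `log10 P(X <= k)` (negative), with X ~ Binomial(n, p0) and exact tails.
#'
#' @param seqs character read sequences, all the same length.
#' @param counts per-read abundances (default 1; rounded to integers for
#'   the binomial model).
#' @param background named probabilities for A, C, G, U (sum 1 within
#'   1e-6); default uniform.
#' @return list of class `bias_matrix`: `freq`, `score` (position x base
#'   matrices), `n`, `background`.
#' @export
positional_bias <- function(seqs, counts = NULL,
                            background = c(A = .25, C = .25, G = .25, U = .25)) {
  stopifnot(length(seqs) >= 1L)
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("positional_bias: reads must share one length")
  if (abs(sum(background) - 1) > 1e-6) {
    stop("positional_bias: background probabilities must sum to 1")
  }
  if (is.null(counts)) counts <- rep(1L, length(seqs))
  counts <- round(counts)
  bases <- c("A", "C", "G", "U")
  chars <- do.call(rbind, strsplit(chartr("T", "U", seqs), ""))
  n <- sum(counts)
  freq <- matrix(0, nrow = L, ncol = 4, dimnames = list(1:L, bases))
  score <- freq
  for (pos in 1:L) {
    for (b in bases) {
      k <- sum(counts[chars[, pos] == b])
      p0 <- background[[b]]
      freq[pos, b] <- k / n
      score[pos, b] <- .binom_bias_score(k, n, p0)
    }
  }
  structure(list(freq = freq, score = score, n = n, background = background),
            class = "bias_matrix")
}

# signed -log10 exact binomial tail; log-space for numeric range
.binom_bias_score <- function(k, n, p0) {
  if (k / n > p0) {
    -pbinom(k - 1, n, p0, lower.tail = FALSE, log.p = TRUE) / log(10)
  } else {
    pbinom(k, n, p0, lower.tail = TRUE, log.p = TRUE) / log(10)
  }
}

#' A10 over U1 frequency ratio by read length
#'
#' For sense-strand piRNA reads: per length, the ratio of the weighted
#' frequency of A at position 10 to U at position 1. Lengths supported by
#' fewer than `floor` reads are reported missing.
#'
#' @param seqs read sequences.
#' @param weights per-read counts (default 1).
#' @param len_range evaluated lengths (default 24-30).
#' @param floor minimum summed weight per length (default 20).
#' @return data.frame `length`, `freq_a10`, `freq_u1`, `ratio`, `n`.
#' @export
a10_u1_ratio_by_size <- function(seqs, weights = NULL,
                                 len_range = c(24L, 30L), floor = 20) {
  if (is.null(weights)) weights <- rep(1, length(seqs))
  lens <- len_range[1]:len_range[2]
  rl <- nchar(seqs)
  out <- data.frame(length = lens, freq_a10 = NA_real_, freq_u1 = NA_real_,
                    ratio = NA_real_, n = 0)
  for (i in seq_along(lens)) {
    sel <- rl == lens[i]
    n <- sum(weights[sel])
    out$n[i] <- n
    if (n < floor) next
    s <- seqs[sel]; w <- weights[sel]
    fa <- sum(w[substr(s, 10L, 10L) == "A"]) / n
    fu <- sum(w[substr(s, 1L, 1L) %in% c("T", "U")]) / n
    out$freq_a10[i] <- fa
    out$freq_u1[i] <- fu
    out$ratio[i] <- if (fu > 0) fa / fu else NA_real_
  }
  out
}

#' U1 frequency among A10-carrying reads
#'
#' Fraction of reads with A at position 10 that also start with U, plus the
#' binomial bias score against the background U probability.
#'
#' @param seqs read sequences (>= 10 nt).
#' @param weights per-read counts.
#' @param background_u background probability of U at a position.
#' @return list `fraction`, `n`, `score`; fraction NA when no read
#'   qualifies.
#' @export
joint_bias_a10_u1 <- function(seqs, weights = NULL, background_u = 0.25) {
  if (is.null(weights)) weights <- rep(1, length(seqs))
  a10 <- substr(seqs, 10L, 10L) == "A"
  n <- round(sum(weights[a10]))
  if (n == 0) return(list(fraction = NA_real_, n = 0, score = NA_real_))
  k <- round(sum(weights[a10 & substr(seqs, 1L, 1L) %in% c("T", "U")]))
  list(fraction = k / n, n = n,
       score = .binom_bias_score(k, n, background_u))
}

#' Cytosine enrichment at the last two read positions
#'
#' Per-read terminal positions (L-1, L) are evaluated for each read's own
#' length; reports C frequencies and binomial scores against the background
#' C probability.
#'
#' @param seqs read sequences (>= 2 nt).
#' @param weights per-read counts.
#' @param background_c background probability of C.
#' @return data.frame for positions `last-1` and `last`: `freq_c`, `score`.
#' @export
terminal_c_fraction <- function(seqs, weights = NULL, background_c = 0.25) {
  if (any(nchar(seqs) < 2L)) stop("terminal_c_fraction: reads must be >= 2 nt")
  if (is.null(weights)) weights <- rep(1, length(seqs))
  L <- nchar(seqs)
  n <- round(sum(weights))
  k2 <- round(sum(weights[substr(seqs, L - 1L, L - 1L) == "C"]))
  k1 <- round(sum(weights[substr(seqs, L, L) == "C"]))
  data.frame(position = c("last-1", "last"),
             freq_c = c(k2, k1) / n,
             score = c(.binom_bias_score(k2, n, background_c),
                       .binom_bias_score(k1, n, background_c)),
             stringsAsFactors = FALSE)
}

#' Ping-pong 5' overlap histogram
#'
#' For every opposite-strand alignment pair on the same chromosome, the
#' overlap offset is `five_minus - five_plus + 1` in 1-based units (the 5'
#' end of a minus-strand alignment is its rightmost coordinate), so a
#' perfect ping-pong pair scores 10. Pairs are weighted by the product of
#' the two reads' normalized counts. The z-score at offset 10 compares
#' h[10] with the mean and sd of the other offsets.
#'
#' @param sense,antisense alignment data.frames with per-row `weight`
#'   column (normalized counts).
#' @param max_offset largest offset tabulated (default 20).
#' @return list `histogram` (named vector 1..max_offset), `z10` (NA when
#'   fewer than 2 informative offsets).
#' @export
pingpong_overlap_histogram <- function(sense, antisense, max_offset = 20L) {
  h <- setNames(numeric(max_offset), 1:max_offset)
  plus1 <- sense[sense$strand == "+", , drop = FALSE]
  minus1 <- sense[sense$strand == "-", , drop = FALSE]
  plus2 <- antisense[antisense$strand == "+", , drop = FALSE]
  minus2 <- antisense[antisense$strand == "-", , drop = FALSE]
  h <- h + .pp_accumulate(plus1, minus2, max_offset)
  h <- h + .pp_accumulate(plus2, minus1, max_offset)
  informative <- sum(h > 0)
  z10 <- NA_real_
  if (informative >= 2L && max_offset >= 10L) {
    rest <- h[-10L]
    if (sd(rest) > 0) z10 <- (h[[10L]] - mean(rest)) / sd(rest)
  }
  list(histogram = h, z10 = z10)
}

.pp_accumulate <- function(plus, minus, max_offset) {
  h <- numeric(max_offset)
  if (!nrow(plus) || !nrow(minus)) return(h)
  pw <- tapply(plus$weight, paste(plus$chrom, plus$start), sum)
  mw <- tapply(minus$weight, paste(minus$chrom, minus$end - 1L), sum)
  pk <- names(pw)
  psp <- strsplit(pk, " ", fixed = TRUE)
  pchr <- vapply(psp, `[[`, "", 1L)
  ppos <- as.integer(vapply(psp, `[[`, "", 2L))
  for (d in seq_len(max_offset)) {
    key <- paste(pchr, ppos + d - 1L)
    mh <- mw[key]
    ok <- !is.na(mh)
    if (any(ok)) h[d] <- sum(pw[ok] * mh[ok])
  }
  h
}

#' Scan loci for dominant sequences
#'
#' A sequence dominates its locus when its normalized count is at least
#' `ratio` times that of the next most abundant distinct sequence there
#' (two orders of magnitude by default).
#'
#' @param locus per-read locus labels.
#' @param seqs read sequences.
#' @param norm_counts per-read normalized abundances.
#' @param ratio dominance ratio (default 100).
#' @return data.frame of dominant sequences with `locus`, `seq`, `length`,
#'   `first_base`, `top`, `second`.
#' @export
dominant_read_scan <- function(locus, seqs, norm_counts, ratio = 100) {
  out <- list()
  for (l in unique(locus)) {
    sel <- locus == l
    o <- order(-norm_counts[sel])
    s <- seqs[sel][o]; w <- norm_counts[sel][o]
    second <- if (length(w) > 1L) w[2] else 0
    if (w[1] >= ratio * second && w[1] > 0) {
      out[[length(out) + 1L]] <- data.frame(
        locus = l, seq = s[1], length = nchar(s[1]),
        first_base = chartr("T", "U", substr(s[1], 1L, 1L)),
        top = w[1], second = second, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(locus = character(), seq = character(),
                      length = integer(), first_base = character(),
                      top = numeric(), second = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' 5' half-tRNA profile and condition contrast
#'
#' Counts reads of length `half_len` whose 5' end coincides (within
#' `tol` nt) with a tRNA 5' end on the tRNA strand; reports per-tRNA
#' normalized counts per sample and the fold change between two named
#' conditions.
#'
#' @param aln alignment data.frame.
#' @param lengths per-read lengths indexed by read id.
#' @param norm normalized count matrix (reads x samples).
#' @param trna GRanges of tRNA genes (stranded) with an `ID` column.
#' @param cond_a,cond_b sample names contrasted as `cond_a / cond_b`.
#' @param half_len half-tRNA length (default 32 nt).
#' @param tol 5'-end tolerance (default 1 nt).
#' @return list `per_trna` (data.frame with per-sample columns and
#'   `fold_change`), `total_fold` (summed-count fold change).
#' @export
half_trna_profile <- function(aln, lengths, norm, trna, cond_a, cond_b,
                              half_len = 32L, tol = 1L) {
  ids <- S4Vectors::mcols(trna)$ID
  tchrom <- as.character(GenomicRanges::seqnames(trna))
  tstrand <- as.character(GenomicRanges::strand(trna))
  tfive <- ifelse(tstrand == "+", GenomicRanges::start(trna) - 1L,
                  GenomicRanges::end(trna) - 1L)
  sel <- lengths[aln$read] == half_len
  sub <- aln[sel, , drop = FALSE]
  sub$five <- .five_prime0(sub)
  rows <- list()
  for (i in seq_along(trna)) {
    m <- sub$chrom == tchrom[i] & sub$strand == tstrand[i] &
      abs(sub$five - tfive[i]) <= tol
    rids <- unique(sub$read[m])
    cnt <- if (length(rids)) colSums(norm[rids, , drop = FALSE])
           else setNames(numeric(ncol(norm)), colnames(norm))
    fc <- if (cnt[[cond_b]] > 0) cnt[[cond_a]] / cnt[[cond_b]] else NA_real_
    rows[[i]] <- data.frame(trna = ids[i], t(cnt), fold_change = fc,
                            stringsAsFactors = FALSE, check.names = FALSE)
  }
  per <- do.call(rbind, rows)
  tot_a <- sum(per[[cond_a]]); tot_b <- sum(per[[cond_b]])
  list(per_trna = per,
       total_fold = if (tot_b > 0) tot_a / tot_b else NA_real_)
}
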