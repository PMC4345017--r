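# De novo miRNA discovery: hairpin candidates from read stacks, duplex
# 2-nt overhang validation against the fold, 5'-end homogeneity,
# multi-sample support, star finding, mirtron discovery from short introns,
# genomic clustering, repeat overlap and prior-catalog comparison.

#' 5'-end homogeneity of a read stack
#'
#' Mature miRNAs have a uniform 5' terminus compared with the 3' terminus.
#' Passing requires the modal-5' fraction to reach `tau5` and to be at
#' least the modal-3' fraction.
#'
#' @param five,three per-read 5' and 3' end coordinates.
#' @param counts per-read abundances (default 1 each).
#' @param tau5 required modal-5' fraction (default 0.9).
#' @return list `frac5`, `frac3`, `pass`.
#' @export
five_prime_homogeneity <- function(five, three, counts = NULL, tau5 = 0.9) {
  stopifnot(length(five) >= 1L, length(five) == length(three))
  if (is.null(counts)) counts <- rep(1, length(five))
  frac <- function(x) max(tapply(counts, x, sum)) / sum(counts)
  f5 <- frac(five); f3 <- frac(three)
  list(frac5 = f5, frac3 = f3, pass = f5 >= tau5 && f5 >= f3)
}

#' Multi-sample expression support
#'
#' @param sample_counts named per-library read counts at a locus.
#' @param min_samples minimum number of libraries with evidence (default 2).
#' @param min_reads minimum reads per supporting library (default 1).
#' @return logical.
#' @export
multi_sample_support <- function(sample_counts, min_samples = 2L,
                                 min_reads = 1L) {
  if (length(sample_counts) < 2L) {
    stop("multi_sample_support: at least two libraries are required")
  }
  sum(sample_counts >= min_reads) >= min_samples
}

# local 1-based coordinates of a genomic 0-based half-open interval within
# a window [wstart, wend), respecting strand (local runs 5'->3' on strand)
.local_coords <- function(gstart, gend, wstart, wend, strand) {
  if (strand == "+") c(gstart - wstart + 1L, gend - wstart)
  else c(wend - gend + 1L, wend - gstart)
}

#' Find the star read for a mature miRNA
#'
#' Among reads on the opposite arm, returns the most abundant one whose
#' duplex with the mature satisfies the 2-nt 3' overhang geometry in the
#' fold; ties break to the 5'-most candidate.
#'
#' @param fold fold of the candidate window (local coordinates).
#' @param mature local 1-based `c(start, end)` of the mature read.
#' @param reads data.frame of candidate reads with local `start`, `end`
#'   (1-based inclusive) and `count`.
#' @return the chosen row of `reads`, or NULL.
#' @export
find_star <- function(fold, mature, reads) {
  if (!nrow(reads)) return(NULL)
  # opposite arm = disjoint from mature
  disjoint <- reads$end < mature[1] | reads$start > mature[2]
  cand <- reads[disjoint, , drop = FALSE]
  if (!nrow(cand)) return(NULL)
  cand <- cand[order(-cand$count, cand$start), , drop = FALSE]
  for (i in seq_len(nrow(cand))) {
    chk <- duplex_overhang_check(fold, mature,
                                 c(cand$start[i], cand$end[i]))
    if (chk$pass) return(cand[i, , drop = FALSE])
  }
  NULL
}

# duplex validation: 2-nt 3' overhang geometry plus the requirement that
# most of the mature actually pairs with the star interval on the stem
.duplex_ok <- function(fold, mature, star, min_pairing = 0.6) {
  duplex_overhang_check(fold, mature, star)$pass &&
    duplex_pairing_fraction(fold, mature, star) >= min_pairing
}

# aggregate alignments of miRNA-sized reads into 5'-position stacks
.read_stacks <- function(aln, lengths, totals) {
  len <- lengths[aln$read]
  five <- ifelse(aln$strand == "+", aln$start, aln$end - 1L)
  data.frame(read = aln$read, chrom = aln$chrom, strand = aln$strand,
             start = aln$start, end = aln$end, five = five, len = len,
             count = totals[aln$read], stringsAsFactors = FALSE)
}

#' Discover novel miRNA loci
#'
#' Candidate windows are built around read stacks (>= `min_stack` summed
#' reads across libraries) extended by `pad` nt and folded once by maximum
#' base pairing. A locus is reported iff (i) some same-strand read in the
#' window — disjoint from the mature, supported by `min_star_reads` and the
#' dominant product of its own arm — forms a duplex with the mature showing
#' exactly 2-nt 3' overhangs on both strands and substantial mature-star
#' stem pairing, (ii) the read stacks pass 5'-end homogeneity at `tau5`
#' (the star arm is held to this only when deep enough to judge), and
#' (iii) at least `min_samples` libraries support the locus. Windows
#' overlapping known precursors are excluded and one locus is reported per
#' precursor span.
#'
#' @param processed `srna_processed` from [process_libraries()].
#' @param genome `srna_genome` or named chromosome sequence vector.
#' @param known GRanges of known precursors (may be NULL).
#' @param min_stack minimum summed stack count (default 5).
#' @param pad window extension around the mature stack (default 70 nt).
#' @param tau5 5'-homogeneity threshold (default 0.9).
#' @param min_samples,min_reads multi-sample support parameters.
#' @param min_star_reads minimum summed reads supporting a star candidate
#'   (default 2; a single stray read is not star evidence).
#' @param hom_min_reads minimum star-arm depth at which the star-side
#'   homogeneity check applies (default 25).
#' @param mature_len mature-sized read window (default 18-26 nt).
#' @param max_window maximum folded window (default 200 nt).
#' @return data.frame of discovered loci (0-based half-open coordinates)
#'   with per-sample count columns `count_<sample>`.
#' @export
discover_novel_mirnas <- function(processed, genome, known = NULL,
                                  min_stack = 5, pad = 70L, tau5 = 0.9,
                                  min_samples = 2L, min_reads = 1L,
                                  min_star_reads = 2L, hom_min_reads = 25L,
                                  mature_len = c(18L, 26L),
                                  max_window = 200L) {
  seqs <- if (inherits(genome, "srna_genome")) genome$seqs else genome
  lengths <- nchar(processed$collapsed$seq)
  totals <- rowSums(processed$collapsed$counts)
  aln <- processed$aln
  small <- aln[lengths[aln$read] >= mature_len[1] &
                 lengths[aln$read] <= mature_len[2], , drop = FALSE]
  if (!nrow(small)) return(.empty_mirna_loci(colnames(processed$collapsed$counts)))
  st <- .read_stacks(small, lengths, totals)
  # stack anchors: distinct (chrom, strand, five) with enough summed reads
  key <- paste(st$chrom, st$strand, st$five)
  stack_sum <- tapply(st$count, key, sum)
  anchors <- names(stack_sum)[stack_sum >= min_stack]
  if (!length(anchors)) return(.empty_mirna_loci(colnames(processed$collapsed$counts)))
  anchors <- anchors[order(-stack_sum[anchors])]

  samples <- colnames(processed$collapsed$counts)
  accepted <- list()
  occupied <- data.frame(chrom = character(), strand = character(),
                         start = integer(), end = integer())
  for (a in anchors) {
    parts <- strsplit(a, " ", fixed = TRUE)[[1]]
    chrom <- parts[1]; strand <- parts[2]; five <- as.integer(parts[3])
    sub <- st[st$chrom == chrom & st$strand == strand & st$five == five, ,
              drop = FALSE]
    # modal mature read of the stack
    ml <- sub$len[which.max(sub$count)]
    mstart <- if (strand == "+") five else five - ml + 1L
    mend <- mstart + ml
    if (any(occupied$chrom == chrom & occupied$strand == strand &
              occupied$start < mend & occupied$end > mstart))
      next
    wstart <- max(0L, mstart - pad)
    wend <- min(nchar(seqs[[chrom]]), mend + pad)
    # reads on the same strand within the window, as star candidates
    win <- st[st$chrom == chrom & st$strand == strand &
                st$start >= wstart & st$end <= wend, , drop = FALSE]
    win <- win[!duplicated(win[, c("start", "end")]), , drop = FALSE]
    cand <- win[win$end < mstart | win$start > mend, , drop = FALSE]
    cand <- cand[cand$count >= min_star_reads, , drop = FALSE]
    if (!nrow(cand)) next
    # the star must be the dominant product of its arm: a duplex explaining
    # only a rare length variant of an otherwise differently-processed arm
    # is not accepted
    arm_modal <- vapply(seq_len(nrow(cand)), function(i) {
      ov <- win$start < cand$end[i] & win$end > cand$start[i]
      max(win$count[ov])
    }, numeric(1))
    cand <- cand[cand$count >= 0.5 * arm_modal, , drop = FALSE]
    if (!nrow(cand)) next
    cand <- cand[order(-cand$count, cand$five), , drop = FALSE]
    cand <- cand[seq_len(min(nrow(cand), 10L)), , drop = FALSE]
    # one fold of the padded read-stack window; every star candidate is
    # checked against it for overhang geometry and stem pairing
    wfold <- fold_maxpair(genome_subseq(seqs, chrom, wstart, wend, strand))
    star <- NULL; pre <- NULL
    for (i in seq_len(nrow(cand))) {
      pstart <- min(mstart, cand$start[i])
      pend <- max(mend, cand$end[i])
      if (pend - pstart > max_window) next
      if (.duplex_ok(wfold, .local_coords(mstart, mend, wstart, wend, strand),
                     .local_coords(cand$start[i], cand$end[i], wstart, wend,
                                   strand))) {
        star <- cand[i, , drop = FALSE]
        pre <- c(pstart, pend)
        break
      }
    }
    if (is.null(star)) next
    # criterion ii: 5' homogeneity on both duplex strands (each arm is a
    # defined Dicer product; a ragged arm rejects the locus whichever arm
    # the anchor came from)
    arm_reads <- function(a, b) {
      st[st$chrom == chrom & st$strand == strand &
           st$start < b & st$end > a, , drop = FALSE]
    }
    mreads <- arm_reads(mstart, mend)
    sreads <- arm_reads(star$start[1], star$end[1])
    hom <- five_prime_homogeneity(mreads$five,
                                  ifelse(mreads$strand == "+",
                                         mreads$end - 1L, mreads$start),
                                  mreads$count, tau5 = tau5)
    if (!hom$pass) next
    # the star arm is held to the same standard only when covered deeply
    # enough to judge (a stray read next to a 10-read star is not evidence
    # of ragged processing)
    if (sum(sreads$count) >= hom_min_reads) {
      hom_s <- five_prime_homogeneity(sreads$five,
                                      ifelse(sreads$strand == "+",
                                             sreads$end - 1L, sreads$start),
                                      sreads$count, tau5 = tau5)
      if (!hom_s$pass) next
    }
    # criterion iii: multi-sample support
    rsel <- unique(mreads$read)
    sc <- colSums(processed$collapsed$counts[rsel, , drop = FALSE])
    if (!multi_sample_support(sc, min_samples, min_reads)) next
    # known-precursor exclusion
    # dedup: one locus per precursor span (the opposite-arm anchor of an
    # accepted locus resolves to the same precursor)
    if (any(occupied$chrom == chrom & occupied$strand == strand &
              occupied$start < pre[2] & occupied$end > pre[1]))
      next
    pre_gr <- GenomicRanges::GRanges(chrom,
                                     IRanges::IRanges(pre[1] + 1L, pre[2]),
                                     strand = strand)
    if (!is.null(known) && length(known) &&
        any(IRanges::overlapsAny(pre_gr, known))) next
    occupied <- rbind(occupied,
                      data.frame(chrom = chrom, strand = strand,
                                 start = pre[1], end = pre[2]))
    arm <- if (strand == "+") {
      if (mstart <= star$start[1]) "5p" else "3p"
    } else {
      if (mstart >= star$start[1]) "5p" else "3p"
    }
    accepted[[length(accepted) + 1L]] <- data.frame(
      id = sprintf("novel_mir_%03d", length(accepted) + 1L),
      chrom = chrom, start = pre[1], end = pre[2], strand = strand,
      mature_start = mstart, mature_end = mend,
      star_start = star$start[1], star_end = star$end[1],
      arm = arm, frac5 = hom$frac5, frac3 = hom$frac3,
      novel = TRUE, mirtron = FALSE,
      as.list(setNames(as.integer(sc), paste0("count_", samples))),
      stringsAsFactors = FALSE)
  }
  out <- if (length(accepted)) do.call(rbind, accepted)
         else .empty_mirna_loci(samples)
  rownames(out) <- NULL
  out
}

.empty_mirna_loci <- function(samples) {
  base <- data.frame(id = character(), chrom = character(), start = integer(),
                     end = integer(), strand = character(),
                     mature_start = integer(), mature_end = integer(),
                     star_start = integer(), star_end = integer(),
                     arm = character(), frac5 = numeric(), frac3 = numeric(),
                     novel = logical(), mirtron = logical(),
                     stringsAsFactors = FALSE)
  for (s in samples) base[[paste0("count_", s)]] <- integer()
  base
}

#' Discover mirtrons in short introns
#'
#' Evaluates introns shorter than `max_intron` nt whose span folds to a
#' hairpin supporting a 5'-arm mature read stack that passes 5' homogeneity
#' and multi-sample support. A star read with valid 2-nt overhang geometry
#' completes the locus; a missing star is tolerated iff at least `tau_u` of
#' the mature reads carry an untemplated 3' U (a terminal read U where the
#' genomic base on the read strand is not T).
#'
#' @param processed `srna_processed`.
#' @param genome `srna_genome` or named sequence vector.
#' @param introns GRanges of intron features.
#' @param max_intron maximum intron length (default 100 nt, exclusive).
#' @param tau_u minimum untemplated-U fraction when no star is found.
#' @param tau5,min_samples,min_reads as in [discover_novel_mirnas()].
#' @return data.frame of mirtron loci (mirtron flag set; star columns NA
#'   when the locus is star-less).
#' @export
discover_mirtrons <- function(processed, genome, introns, max_intron = 100L,
                              tau_u = 0.5, tau5 = 0.9, min_samples = 2L,
                              min_reads = 1L) {
  seqs <- if (inherits(genome, "srna_genome")) genome$seqs else genome
  samples <- colnames(processed$collapsed$counts)
  short <- introns[GenomicRanges::width(introns) < max_intron]
  out <- list()
  cs <- processed$collapsed
  totals <- rowSums(cs$counts)
  for (i in seq_along(short)) {
    chrom <- as.character(GenomicRanges::seqnames(short[i]))
    istart <- GenomicRanges::start(short[i]) - 1L
    iend <- GenomicRanges::end(short[i])
    strand <- as.character(GenomicRanges::strand(short[i]))
    iseq <- genome_subseq(seqs, chrom, istart, iend, strand)
    ilen <- nchar(iseq)
    # reads matching inside the intron, by sequence: exact matches and
    # matches after stripping one terminal U (untemplated test)
    m <- .intron_read_matches(cs$seq, totals, iseq)
    if (is.null(m) || !nrow(m)) next
    # mature stack on the 5' arm: modal 5' position among arm-1 reads
    arm5 <- m[m$start <= ilen / 2, , drop = FALSE]
    if (!nrow(arm5)) next
    five_tab <- tapply(arm5$count, arm5$start, sum)
    m5 <- as.integer(names(five_tab)[which.max(five_tab)])
    stack <- m[m$start == m5, , drop = FALSE]
    mlen <- stack$end[which.max(stack$count)] - m5 + 1L
    mend <- m5 + mlen - 1L
    mat_reads <- m[m$start < mend & m$end >= m5, , drop = FALSE]
    hom <- five_prime_homogeneity(mat_reads$start, mat_reads$end,
                                  mat_reads$count, tau5 = tau5)
    if (!hom$pass) next
    rsel <- unique(mat_reads$read)
    sc <- colSums(cs$counts[rsel, , drop = FALSE])
    if (!multi_sample_support(sc, min_samples, min_reads)) next
    fold <- fold_maxpair(iseq)
    star <- find_star(fold, c(m5, mend),
                      m[, c("start", "end", "count")])
    urid_frac <- sum(mat_reads$count[mat_reads$uridylated]) /
      sum(mat_reads$count)
    if (is.null(star) && !(urid_frac >= tau_u)) next
    # genomic coordinates of the mature (local 1-based on the intron strand)
    gmat <- if (strand == "+") c(istart + m5 - 1L, istart + mend)
            else c(iend - mend, iend - m5 + 1L)
    gstar <- if (!is.null(star)) {
      if (strand == "+") c(istart + star$start[1] - 1L, istart + star$end[1])
      else c(iend - star$end[1], iend - star$start[1] + 1L)
    } else c(NA_integer_, NA_integer_)
    out[[length(out) + 1L]] <- data.frame(
      id = sprintf("mirtron_%03d", length(out) + 1L),
      chrom = chrom, start = istart, end = iend, strand = strand,
      mature_start = gmat[1], mature_end = gmat[2],
      star_start = gstar[1], star_end = gstar[2],
      arm = "5p", frac5 = hom$frac5, frac3 = hom$frac3,
      novel = TRUE, mirtron = TRUE, urid_frac = urid_frac,
      as.list(setNames(as.integer(sc), paste0("count_", samples))),
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    e <- .empty_mirna_loci(samples)
    e$urid_frac <- numeric()
    return(e)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# locate collapsed reads inside an intron sequence; returns local 1-based
# inclusive coordinates plus an `uridylated` flag for reads that only match
# after stripping one trailing T (with the genomic continuation not T)
.intron_read_matches <- function(seqs, counts, iseq) {
  cand <- which(nchar(seqs) <= nchar(iseq))
  if (!length(cand)) return(NULL)
  rows <- list()
  for (j in cand) {
    s <- seqs[j]
    p <- regexpr(s, iseq, fixed = TRUE)
    if (p > 0) {
      rows[[length(rows) + 1L]] <- data.frame(
        read = j, start = as.integer(p), end = as.integer(p) + nchar(s) - 1L,
        count = counts[j], uridylated = FALSE)
      next
    }
    if (substr(s, nchar(s), nchar(s)) == "T") {
      s2 <- substr(s, 1L, nchar(s) - 1L)
      p2 <- regexpr(s2, iseq, fixed = TRUE)
      if (p2 > 0) {
        nxt <- p2 + nchar(s2)
        templated <- nxt <= nchar(iseq) &&
          substr(iseq, nxt, nxt) == "T"
        if (!templated) {
          rows[[length(rows) + 1L]] <- data.frame(
            read = j, start = as.integer(p2),
            end = as.integer(p2) + nchar(s2) - 1L,
            count = counts[j], uridylated = TRUE)
        }
      }
    }
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

#' Group miRNA loci into genomic clusters
#'
#' Single-linkage chaining: loci whose precursor intervals lie within
#' `max_gap` on the same chromosome share a cluster id; singletons stay
#' unclustered (NA).
#'
#' @param loci data.frame with `chrom`, `start`, `end`.
#' @param max_gap chaining distance (default 10 kb).
#' @return integer cluster ids (NA for singletons), parallel to `loci`.
#' @export
cluster_loci <- function(loci, max_gap = 10000L) {
  n <- nrow(loci)
  ids <- rep(NA_integer_, n)
  if (!n) return(ids)
  nxt <- 0L
  for (chr in unique(loci$chrom)) {
    w <- which(loci$chrom == chr)
    o <- w[order(loci$start[w])]
    grp <- integer(length(o))
    g <- 1L
    grp[1] <- g
    for (i in seq_along(o)[-1]) {
      gap <- loci$start[o[i]] - max(loci$end[o[seq_len(i - 1)][grp == g]])
      if (gap <= max_gap) grp[i] <- g else { g <- g + 1L; grp[i] <- g }
    }
    for (g0 in unique(grp)) {
      members <- o[grp == g0]
      if (length(members) >= 2L) {
        nxt <- nxt + 1L
        ids[members] <- nxt
      }
    }
  }
  ids
}

#' Flag precursor overlap with a repeat track
#'
#' @param loci data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @param repeats GRanges of repeat intervals (may be empty).
#' @return list `flag` (logical per locus) and `fraction` flagged.
#' @export
flag_repeat_overlap <- function(loci, repeats) {
  if (!nrow(loci)) return(list(flag = logical(0), fraction = 0))
  if (is.null(repeats) || !length(repeats)) {
    return(list(flag = rep(FALSE, nrow(loci)), fraction = 0))
  }
  gr <- intervals_to_granges(loci[, c("chrom", "start", "end")])
  flag <- IRanges::overlapsAny(gr, repeats, minoverlap = 1L,
                               ignore.strand = TRUE)
  list(flag = flag, fraction = mean(flag))
}

#' Partition discovered loci against a prior catalog
#'
#' A locus is previously reported iff its precursor overlaps a prior
#' precursor on the same strand, or its mature sequence exactly matches a
#' prior mature sequence.
#'
#' @param loci data.frame with `chrom`, `start`, `end`, `strand` and
#'   optionally `mature_seq`.
#' @param prior_precursors GRanges of prior precursors (or NULL).
#' @param prior_matures character vector of prior mature sequences (or NULL).
#' @return list `truly_novel`, `previously_reported` (row subsets),
#'   `n_novel`, `n_reported`.
#' @export
compare_catalog <- function(loci, prior_precursors = NULL,
                            prior_matures = NULL) {
  reported <- rep(FALSE, nrow(loci))
  if (!is.null(prior_precursors) && length(prior_precursors) && nrow(loci)) {
    gr <- intervals_to_granges(loci[, c("chrom", "start", "end", "strand")])
    reported <- reported | IRanges::overlapsAny(gr, prior_precursors,
                                                minoverlap = 1L)
  }
  if (!is.null(prior_matures) && "mature_seq" %in% names(loci)) {
    reported <- reported | loci$mature_seq %in% prior_matures
  }
  list(truly_novel = loci[!reported, , drop = FALSE],
       previously_reported = loci[reported, , drop = FALSE],
       n_novel = sum(!reported), n_reported = sum(reported))
}
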