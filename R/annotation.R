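# Annotation-category profiling: read categorization under a fixed
# precedence, size distributions, miRNA-fraction removal, size-peak calls,
# 3'UTR mapping bias and cis-NAT overlap profiles.

CATEGORY_PRECEDENCE <- c("miRNA", "rRNA", "tRNA", "TE", "3UTR", "5UTR",
                         "exon", "intron")

#' Build a category-indexed feature set
#'
#' Collects, from a GFF3-derived annotation and a TE track, one interval
#' set per annotation category. Precedence (highest first) is
#' miRNA > rRNA > tRNA > TE > 3UTR > 5UTR > exon > intron: specific small
#' RNA sources outrank generic gene structure.
#'
#' @param annotation GRanges with a `type` metadata column using GFF3/SO
#'   terms (`pre_miRNA` or `miRNA_precursor`, `rRNA`, `tRNA`,
#'   `three_prime_UTR`, `five_prime_UTR`, `exon`, `intron`).
#' @param te GRanges of transposable-element copies (optional).
#' @param extra_mirna GRanges of additional miRNA precursors (e.g. newly
#'   discovered loci) to include in the miRNA category.
#' @param precedence category order, highest precedence first.
#' @return list of class `feature_index`: `categories` (named list of
#'   GRanges) and `precedence`.
#' @export
feature_index <- function(annotation, te = NULL, extra_mirna = NULL,
                          precedence = CATEGORY_PRECEDENCE) {
  if (!all(precedence %in% CATEGORY_PRECEDENCE)) {
    stop("feature_index: unknown category in precedence: ",
         paste(setdiff(precedence, CATEGORY_PRECEDENCE), collapse = ", "))
  }
  type <- S4Vectors::mcols(annotation)$type
  pick <- function(types) annotation[type %in% types]
  cats <- list(
    miRNA = pick(c("pre_miRNA", "miRNA_precursor", "miRNA_primary_transcript")),
    rRNA = pick("rRNA"),
    tRNA = pick("tRNA"),
    TE = if (is.null(te)) GenomicRanges::GRanges() else te,
    `3UTR` = pick("three_prime_UTR"),
    `5UTR` = pick("five_prime_UTR"),
    exon = pick("exon"),
    intron = pick("intron"))
  if (!is.null(extra_mirna) && length(extra_mirna)) {
    cats$miRNA <- c(GenomicRanges::granges(cats$miRNA),
                    GenomicRanges::granges(extra_mirna))
  }
  structure(list(categories = cats[precedence], precedence = precedence),
            class = "feature_index")
}

#' Assign one annotation category per read
#'
#' Each read receives the highest-precedence category overlapped (>= 1 nt,
#' either strand) by any of its genomic placements; reads overlapping
#' nothing are "unannotated". Each read is counted once regardless of its
#' number of placements.
#'
#' @param aln alignment data.frame from [map_perfect()].
#' @param index a [feature_index()].
#' @return factor of categories, one per row of `unique(aln$read)`, named
#'   by read index; levels are the precedence order plus "unannotated".
#' @export
categorize_reads <- function(aln, index) {
  stopifnot(inherits(index, "feature_index"))
  reads <- sort(unique(aln$read))
  # rank per placement: smallest = highest precedence; NA if no overlap
  gr <- intervals_to_granges(aln)
  rank <- rep(NA_integer_, nrow(aln))
  for (i in rev(seq_along(index$precedence))) {
    cat_gr <- index$categories[[index$precedence[i]]]
    if (!length(cat_gr)) next
    hit <- IRanges::overlapsAny(gr, cat_gr, minoverlap = 1L,
                                ignore.strand = TRUE)
    rank[hit] <- i
  }
  best <- tapply(rank, factor(aln$read, levels = reads),
                 function(r) if (all(is.na(r))) NA_integer_ else min(r, na.rm = TRUE))
  lv <- c(index$precedence, "unannotated")
  out <- factor(ifelse(is.na(best), "unannotated", index$precedence[best]),
                levels = lv)
  names(out) <- reads
  out
}

#' Size-by-category profile
#'
#' @param lengths integer read lengths, parallel to `categories`.
#' @param categories factor from [categorize_reads()].
#' @param weights per-read weights (raw or normalized counts).
#' @param len_range histogram window, default 17-36 nt.
#' @return matrix lengths x categories; marginal totals equal the summed
#'   weights of in-window reads.
#' @export
size_histogram <- function(lengths, categories, weights = NULL,
                           len_range = c(17L, 36L)) {
  if (is.null(weights)) weights <- rep(1, length(lengths))
  stopifnot(length(lengths) == length(categories),
            length(weights) == length(lengths))
  lens <- len_range[1]:len_range[2]
  lv <- levels(categories)
  m <- matrix(0, nrow = length(lens), ncol = length(lv),
              dimnames = list(lens, lv))
  keep <- lengths >= len_range[1] & lengths <= len_range[2]
  if (any(keep)) {
    agg <- tapply(weights[keep],
                  list(factor(lengths[keep], levels = lens),
                       categories[keep]), sum)
    agg[is.na(agg)] <- 0
    m[rownames(agg), colnames(agg)] <- agg
  }
  m
}

#' Remove reads mapping to miRNA precursors
#'
#' Drops every read with at least one placement overlapping a known or
#' discovered miRNA precursor, mirroring the removal of the miRNA fraction
#' before endo-siRNA analysis.
#'
#' @param aln alignment data.frame.
#' @param precursors GRanges of precursor intervals.
#' @return list with `keep_reads` (read indices retained), `removed_reads`,
#'   and `aln` (alignments of retained reads).
#' @export
remove_mirna_fraction <- function(aln, precursors) {
  gr <- intervals_to_granges(aln)
  hit <- IRanges::overlapsAny(gr, precursors, minoverlap = 1L,
                              ignore.strand = TRUE)
  removed <- unique(aln$read[hit])
  keep <- setdiff(unique(aln$read), removed)
  list(keep_reads = keep, removed_reads = removed,
       aln = aln[!aln$read %in% removed, , drop = FALSE])
}

#' Call peaks in a read-length histogram
#'
#' Length l is a peak iff its count is at least `ratio` times each
#' neighbouring length's count and at least `min_frac` of the histogram
#' total. Missing neighbours (window edges) count as zero.
#'
#' @param hist named numeric vector, names = lengths.
#' @param ratio neighbour dominance ratio (default 1.5).
#' @param min_frac minimum fraction of the total (default 0.05).
#' @return integer vector of peak lengths.
#' @export
detect_size_peak <- function(hist, ratio = 1.5, min_frac = 0.05) {
  lens <- as.integer(names(hist))
  tot <- sum(hist)
  if (tot == 0) return(integer(0))
  up <- c(hist[-1], 0)       # count at l + 1
  down <- c(0, hist[-length(hist)])
  ok <- hist >= ratio * up & hist >= ratio * down & hist >= min_frac * tot &
    hist > 0
  lens[ok]
}

#' Fraction of reads mapping to mRNAs and to 3'UTRs, by read length
#'
#' For each length: mRNA% is the weighted fraction of all mapped reads of
#' that length with a sense placement on an annotated mRNA; 3'UTR% is
#' computed identically for reads with a sense placement fully inside a
#' 3'UTR. Transcripts lacking a 3'UTR annotation are excluded with a
#' message.
#'
#' @param aln alignment data.frame.
#' @param lengths per-read lengths (indexed by read id).
#' @param weights per-read weights (indexed by read id).
#' @param mrna GRanges of mRNA spans with an `ID` metadata column.
#' @param utr3 GRanges of 3'UTRs with a `Parent` metadata column naming the
#'   mRNA.
#' @param len_range evaluated lengths.
#' @return data.frame `length`, `mrna_pct`, `utr3_pct`, `n_total`; rows
#'   with no mapped reads of that length carry NA percentages.
#' @export
utr_fraction_by_size <- function(aln, lengths, weights, mrna, utr3,
                                 len_range = c(17L, 36L)) {
  ids <- S4Vectors::mcols(mrna)$ID
  with_utr <- ids %in% S4Vectors::mcols(utr3)$Parent
  if (any(!with_utr)) {
    message("utr_fraction_by_size: excluding ", sum(!with_utr),
            " transcript(s) lacking a 3'UTR annotation")
  }
  mrna <- mrna[with_utr]
  gr <- intervals_to_granges(aln)
  sense_mrna <- IRanges::overlapsAny(gr, mrna, minoverlap = 1L)  # same strand
  inside_utr <- IRanges::overlapsAny(gr, utr3, type = "within")
  reads <- sort(unique(aln$read))
  f <- factor(aln$read, levels = reads)
  read_mrna <- tapply(sense_mrna, f, any)
  read_utr <- tapply(inside_utr, f, any)
  rl <- lengths[reads]
  rw <- weights[reads]
  lens <- len_range[1]:len_range[2]
  out <- data.frame(length = lens, mrna_pct = NA_real_, utr3_pct = NA_real_,
                    n_total = 0)
  for (i in seq_along(lens)) {
    sel <- rl == lens[i]
    tot <- sum(rw[sel])
    out$n_total[i] <- tot
    if (tot > 0) {
      out$mrna_pct[i] <- 100 * sum(rw[sel & read_mrna]) / tot
      out$utr3_pct[i] <- 100 * sum(rw[sel & read_utr]) / tot
    }
  }
  out
}

#' Size profile of reads inside convergent-transcript overlaps
#'
#' Restricts to reads fully inside the overlap interval of a convergently
#' transcribed pair; non-overlapping or non-convergent pairs are skipped
#' with a message.
#'
#' @param pair_a,pair_b GRanges of the two transcripts of each pair
#'   (parallel vectors).
#' @param aln alignment data.frame.
#' @param lengths,weights per-read lengths and weights (indexed by read id).
#' @param len_range histogram window.
#' @return matrix lengths x strands (`+`, `-`) of summed weights.
#' @export
overlap_region_profile <- function(pair_a, pair_b, aln, lengths, weights,
                                   len_range = c(17L, 36L)) {
  stopifnot(length(pair_a) == length(pair_b))
  lens <- len_range[1]:len_range[2]
  m <- matrix(0, nrow = length(lens), ncol = 2,
              dimnames = list(lens, c("+", "-")))
  for (i in seq_along(pair_a)) {
    a <- pair_a[i]; b <- pair_b[i]
    convergent <- as.character(GenomicRanges::strand(a)) !=
      as.character(GenomicRanges::strand(b))
    same_chrom <- as.character(GenomicRanges::seqnames(a)) ==
      as.character(GenomicRanges::seqnames(b))
    ov_start <- max(GenomicRanges::start(a), GenomicRanges::start(b))
    ov_end <- min(GenomicRanges::end(a), GenomicRanges::end(b))
    if (!convergent || !same_chrom || ov_end < ov_start) {
      message("overlap_region_profile: skipping non-convergent or ",
              "non-overlapping pair ", i)
      next
    }
    ov <- GenomicRanges::GRanges(GenomicRanges::seqnames(a),
                                 IRanges::IRanges(ov_start, ov_end))
    gr <- intervals_to_granges(aln)
    inside <- IRanges::overlapsAny(gr, ov, type = "within",
                                   ignore.strand = TRUE)
    sub <- aln[inside, , drop = FALSE]
    if (!nrow(sub)) next
    # one contribution per (read, strand) inside the overlap
    key <- !duplicated(sub[, c("read", "strand")])
    sub <- sub[key, , drop = FALSE]
    rl <- lengths[sub$read]
    rw <- weights[sub$read]
    keep <- rl >= len_range[1] & rl <= len_range[2]
    if (any(keep)) {
      agg <- tapply(rw[keep], list(factor(rl[keep], levels = lens),
                                   factor(sub$strand[keep],
                                          levels = c("+", "-"))), sum)
      agg[is.na(agg)] <- 0
      m <- m + agg
    }
  }
  m
}
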