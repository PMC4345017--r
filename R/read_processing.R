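# Read preprocessing and mapping: 3' adapter clipping, length filtering,
# collapsing to unique sequences, perfect-match (0 mismatch) genome mapping
# and reads-per-million normalization.

#' Clip the 3' adapter from raw reads
#'
#' The insert is everything before the leftmost exact occurrence of an
#' adapter prefix of length >= `min_overlap`. Reads with no such occurrence
#' are rejected (returned as `NA`): over a short-insert library the
#' sequencing run must read into the adapter, so its absence marks an
#' artifact.
#'
#' @param reads character vector of raw read sequences.
#' @param adapter 3' adapter sequence (length >= `min_overlap`).
#' @param min_overlap minimum matched adapter prefix, default 8 nt.
#' @return character vector of inserts, `NA` where rejected; possibly empty
#'   strings (removed later by the length filter).
#' @export
clip_3p_adapter <- function(reads, adapter, min_overlap = 8L) {
  if (nchar(adapter) < min_overlap) {
    stop("clip_3p_adapter: adapter shorter than min_overlap")
  }
  if (any(!nzchar(reads))) stop("clip_3p_adapter: empty read")
  key <- substr(adapter, 1L, min_overlap)
  pos <- regexpr(key, reads, fixed = TRUE)
  out <- ifelse(pos > 0L, substr(reads, 1L, pos - 1L), NA_character_)
  out
}

#' Filter reads by insert length
#'
#' @param reads character vector.
#' @param min,max inclusive length bounds (defaults 17 and 36 nt).
#' @return the retained reads, input order preserved.
#' @export
length_filter <- function(reads, min = 17L, max = 36L) {
  n <- nchar(reads)
  reads[!is.na(reads) & n >= min & n <= max]
}

#' Collapse reads to unique sequences with counts
#'
#' @param reads character vector of clipped, filtered reads.
#' @return data.frame with `seq` and `count`, ordered by decreasing count
#'   then sequence.
#' @export
collapse_reads <- function(reads) {
  if (!length(reads)) {
    return(data.frame(seq = character(), count = integer(),
                      stringsAsFactors = FALSE))
  }
  tab <- table(reads)
  df <- data.frame(seq = names(tab), count = as.integer(tab),
                   stringsAsFactors = FALSE)
  df[order(-df$count, df$seq), , drop = FALSE] -> df
  rownames(df) <- NULL
  df
}

#' Build a multi-sample collapsed read set
#'
#' Collapses each sample's clipped/filtered reads and joins them on
#' sequence into one raw count matrix.
#'
#' @param read_lists named list (per sample) of character vectors of reads.
#' @return list of class `collapsed_set`: `seq` (character vector) and
#'   `counts` (integer matrix, sequences x samples).
#' @export
collapse_samples <- function(read_lists) {
  stopifnot(is.list(read_lists), !is.null(names(read_lists)))
  per <- lapply(read_lists, collapse_reads)
  seqs <- sort(unique(unlist(lapply(per, `[[`, "seq"), use.names = FALSE)))
  counts <- matrix(0L, nrow = length(seqs), ncol = length(per),
                   dimnames = list(NULL, names(per)))
  for (s in names(per)) {
    counts[match(per[[s]]$seq, seqs), s] <- per[[s]]$count
  }
  structure(list(seq = seqs, counts = counts), class = "collapsed_set")
}

#' @export
print.collapsed_set <- function(x, ...) {
  cat("collapsed_set:", length(x$seq), "unique sequences,",
      ncol(x$counts), "sample(s); total reads",
      sum(x$counts), "\n")
  invisible(x)
}

#' Map sequences to a genome with zero mismatches
#'
#' Reports all exact occurrences of each sequence on both strands. Minus
#' strand hits are positions where the reverse complement of the read
#' matches the forward genome; coordinates are 0-based half-open on the
#' forward strand. Sequences containing N are dropped (counted in the
#' `n_with_N` attribute); sequences with no hit yield no records and are
#' listed in the `unmapped` attribute.
#'
#' @param seqs character vector of read sequences (ACGT).
#' @param genome named character vector of chromosome sequences, or an
#'   `srna_genome`.
#' @return data.frame `read` (index into `seqs`), `chrom`, `start`, `end`,
#'   `strand`, `hit_count` (total genomic placements of that sequence),
#'   with attributes `unmapped` (integer indices) and `n_with_N`.
#' @export
map_perfect <- function(seqs, genome) {
  if (inherits(genome, "srna_genome")) genome <- genome$seqs
  keep <- !grepl("N", seqs, fixed = TRUE)
  n_with_n <- sum(!keep)
  idx <- which(keep)
  subject <- Biostrings::DNAStringSet(genome)
  hits <- list()
  if (length(idx)) {
    widths <- nchar(seqs[idx])
    for (w in sort(unique(widths))) {
      ids <- idx[widths == w]
      fwd <- Biostrings::DNAStringSet(seqs[ids])
      rev <- Biostrings::reverseComplement(fwd)
      pd_f <- Biostrings::PDict(fwd)
      pd_r <- Biostrings::PDict(rev)
      for (chr in names(genome)) {
        for (side in c("+", "-")) {
          pd <- if (side == "+") pd_f else pd_r
          m <- Biostrings::matchPDict(pd, subject[[chr]])
          cnt <- S4Vectors::elementNROWS(m)
          if (!sum(cnt)) next
          which_pat <- rep(seq_along(cnt), cnt)
          starts <- unlist(IRanges::start(m), use.names = FALSE)
          hits[[length(hits) + 1L]] <- data.frame(
            read = ids[which_pat], chrom = chr,
            start = starts - 1L, end = starts - 1L + w,
            strand = side, stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(read = integer(), chrom = character(), start = integer(),
               end = integer(), strand = character(), stringsAsFactors = FALSE)
  hc <- table(out$read)
  out$hit_count <- as.integer(hc[as.character(out$read)])
  out <- out[order(out$read, out$chrom, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unmapped") <- setdiff(idx, unique(out$read))
  attr(out, "n_with_N") <- n_with_n
  out
}

#' Reads-per-million normalization
#'
#' @param counts raw count vector or matrix (sequences x samples).
#' @param totals total mapped reads per sample (recycled for a vector).
#' @return normalized abundances: `counts * 1e6 / totals`.
#' @export
rpm_normalize <- function(counts, totals) {
  if (any(totals <= 0)) stop("rpm_normalize: totals must be > 0")
  if (is.matrix(counts)) {
    stopifnot(length(totals) == ncol(counts))
    sweep(counts, 2L, totals, function(x, t) x * 1e6 / t)
  } else {
    counts * 1e6 / totals[1]
  }
}

#' Run preprocessing and mapping over a set of libraries
#'
#' Clips, filters, collapses, maps and normalizes. Totals for RPM are the
#' per-sample counts of mapped reads.
#'
#' @param libs named list of raw read character vectors (or data.frames with
#'   a `read` column, as produced by [simulate_library()]).
#' @param genome named character vector of chromosome sequences or an
#'   `srna_genome`.
#' @param adapter 3' adapter sequence.
#' @param min_len,max_len insert length window.
#' @param min_overlap adapter clip overlap.
#' @return list of class `srna_processed`: `collapsed` (collapsed_set),
#'   `aln` (alignment data.frame), `norm` (RPM matrix), `totals`
#'   (mapped reads per sample), `stats` (per-sample data.frame).
#' @export
process_libraries <- function(libs, genome, adapter,
                              min_len = 17L, max_len = 36L, min_overlap = 8L) {
  raw <- lapply(libs, function(x) if (is.data.frame(x)) x$read else x)
  clipped <- lapply(raw, clip_3p_adapter, adapter = adapter,
                    min_overlap = min_overlap)
  kept <- lapply(clipped, length_filter, min = min_len, max = max_len)
  collapsed <- collapse_samples(kept)
  aln <- map_perfect(collapsed$seq, genome)
  mapped <- logical(length(collapsed$seq))
  mapped[unique(aln$read)] <- TRUE
  totals <- colSums(collapsed$counts[mapped, , drop = FALSE])
  norm <- rpm_normalize(collapsed$counts, totals)
  stats <- data.frame(
    sample = names(raw),
    n_raw = vapply(raw, length, integer(1)),
    n_clipped = vapply(clipped, function(x) sum(!is.na(x)), integer(1)),
    n_kept = vapply(kept, length, integer(1)),
    n_mapped = as.integer(totals),
    stringsAsFactors = FALSE)
  rownames(stats) <- NULL
  structure(list(collapsed = collapsed, aln = aln, norm = norm,
                 totals = totals, mapped = mapped, stats = stats),
            class = "srna_processed")
}

#' @export
print.srna_processed <- function(x, ...) {
  cat("srna_processed:", length(x$collapsed$seq), "unique sequences;",
      nrow(x$aln), "alignments\n")
  print(x$stats)
  invisible(x)
}

#' Write collapsed reads as FASTA with `>id-count` headers
#'
#' @param collapsed a `collapsed_set`.
#' @param path output path.
#' @param sample sample whose counts to use (default: row sums).
#' @export
write_collapsed_fasta <- function(collapsed, path, sample = NULL) {
  cnt <- if (is.null(sample)) rowSums(collapsed$counts)
         else collapsed$counts[, sample]
  keep <- cnt > 0
  dna <- Biostrings::DNAStringSet(collapsed$seq[keep])
  names(dna) <- sprintf("%d-%d", which(keep), as.integer(cnt[keep]))
  Biostrings::writeXStringSet(dna, path)
  invisible(path)
}

#' Write alignments as BED6 plus hit-count column
#'
#' @param aln alignment data.frame from [map_perfect()].
#' @param path output TSV path.
#' @export
write_alignments_bed <- function(aln, path) {
  bed <- data.frame(chrom = aln$chrom, start = aln$start, end = aln$end,
                    name = paste0("read", aln$read), score = 0L,
                    strand = aln$strand, hit_count = aln$hit_count)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a FASTQ file (gz-transparent) into a character vector of reads
#' @param path FASTQ path.
#' @export
read_fastq_seqs <- function(path) {
  as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
}
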