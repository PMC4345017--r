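# Synthetic-data module: hairpin synthesis, genome blueprints, and
# construction of a genome + annotation + truth table in which every small
# RNA class the pipeline characterizes is planted with known coordinates.

#' Synthesize a miRNA-like hairpin precursor
#'
#' Builds a precursor of layout 5' arm + loop + 3' arm, where the 3' arm is
#' the reverse complement of the 5' arm with a configurable mismatch rate so
#' that the maximum-base-pair fold recovers the intended duplex register.
#' Mature and star strands are placed so that each 3' end overhangs the
#' duplex by exactly 2 nt: mature occupies arm positions 3..arm_len and the
#' star the mirrored window on the 3' arm. Loop bases are drawn from {A, C}
#' so the loop cannot extend the stem and the base following the mature 3'
#' end is never a T (which keeps appended 3' U tails untemplated for mirtron
#' simulation). Mismatches are restricted to the interior of the arm (4 nt
#' protected at each end) and always to a non-pairing base.
#'
#' @param arm_len arm length in nt (>= 18); the mature strand is
#'   `arm_len - 2` nt.
#' @param loop_len loop length in nt (>= 3).
#' @param seed integer seed; identical parameters and seed give an identical
#'   sequence.
#' @param mismatch_rate per-position probability of a planted arm mismatch.
#' @return list with `seq`, `mature` and `star` (1-based inclusive intervals
#'   within the precursor), `arm_len`, `loop_len`.
#' @export
synthesize_hairpin <- function(arm_len, loop_len, seed, mismatch_rate = 0.1) {
  if (arm_len < 18) stop("synthesize_hairpin: arm_len must be >= 18")
  if (loop_len < 3) stop("synthesize_hairpin: loop_len must be >= 3")
  L <- 2L * arm_len + loop_len
  mature <- c(3L, arm_len)
  star <- c(L + 3L - arm_len, L)
  pairs_with <- list(A = "T", C = "G", G = c("C", "T"), T = c("A", "G"))
  for (attempt in 0:24) {
    hp <- with_seed(derive_seed(seed, paste0("hairpin-", attempt)), {
      arm5 <- sample(BASES, arm_len, replace = TRUE)
      loop <- sample(c("A", "C"), loop_len, replace = TRUE)
      arm3 <- rev(chartr("ACGT", "TGCA", arm5))
      mutable <- seq_len(arm_len) >= 5 & seq_len(arm_len) <= arm_len - 4
      mut <- mutable & runif(arm_len) < mismatch_rate
      # real stems always carry internal mismatches; at least two keep the
      # two arms from being exact reverse complements (which would make arm
      # reads map to both strands of the precursor)
      while (sum(mut) < 2L) mut[sample(which(mutable & !mut), 1L)] <- TRUE
      for (t in which(mut)) {
        partner <- arm5[arm_len + 1L - t]
        forbidden <- c(pairs_with[[partner]], arm3[t])
        cand <- setdiff(BASES, forbidden)
        arm3[t] <- sample(cand, 1L)
      }
      paste(c(arm5, loop, arm3), collapse = "")
    })
    fold <- fold_maxpair(hp)
    if (duplex_overhang_check(fold, mature, star)$pass) {
      return(list(seq = hp, mature = mature, star = star,
                  arm_len = arm_len, loop_len = loop_len))
    }
  }
  stop("synthesize_hairpin: could not realize duplex geometry (unexpected)")
}

FEATURE_KINDS <- c("mirna_hairpin", "mirtron_host", "te_copy", "cisnat_pair",
                   "trna", "mrna_with_utr", "pirna_cluster_region",
                   "decoy_hairpin")

#' Construct a genome blueprint
#'
#' A blueprint lists chromosome lengths and planned features (0-based
#' half-open intervals). Features may not overlap each other except where
#' the plan requires it: the two transcripts of a `cisnat_pair` overlap by
#' construction inside one feature row, and `te_copy` features may sit
#' inside `pirna_cluster_region` features.
#'
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param features data.frame with columns `kind`, `chrom`, `start`, `end`,
#'   `strand`, `id` and a list column `params` of kind-specific parameters.
#' @param base_comp named base composition (A/C/G/T), default uniform.
#' @param seed integer seed controlling all sequence content.
#' @export
genome_blueprint <- function(chrom_lengths, features,
                             base_comp = c(A = .25, C = .25, G = .25, T = .25),
                             seed = 1L) {
  stopifnot(!is.null(names(chrom_lengths)), is.data.frame(features))
  need <- c("kind", "chrom", "start", "end", "strand", "id")
  if (!all(need %in% names(features))) {
    stop("blueprint features need columns: ", paste(need, collapse = ", "))
  }
  if (!"params" %in% names(features)) {
    features$params <- replicate(nrow(features), list(), simplify = FALSE)
  }
  bad_kind <- setdiff(unique(features$kind), FEATURE_KINDS)
  if (length(bad_kind)) stop("unknown feature kind(s): ",
                             paste(bad_kind, collapse = ", "))
  if (any(!features$chrom %in% names(chrom_lengths))) {
    stop("feature on unknown chromosome")
  }
  if (any(features$start < 0) ||
      any(features$end > chrom_lengths[features$chrom]) ||
      any(features$end <= features$start)) {
    stop("feature interval outside its chromosome")
  }
  .check_blueprint_overlaps(features)
  structure(list(chrom_lengths = chrom_lengths, features = features,
                 base_comp = base_comp, seed = as.integer(seed)),
            class = "genome_blueprint")
}

.check_blueprint_overlaps <- function(features) {
  for (chr in unique(features$chrom)) {
    f <- features[features$chrom == chr, ]
    if (nrow(f) < 2) next
    o <- order(f$start)
    f <- f[o, ]
    for (i in seq_len(nrow(f) - 1)) {
      for (j in (i + 1):nrow(f)) {
        if (f$start[j] >= f$end[i]) break
        sanctioned <- f$kind[j] == "te_copy" && f$kind[i] == "pirna_cluster_region" &&
          f$start[j] >= f$start[i] && f$end[j] <= f$end[i]
        if (!sanctioned) {
          stop(sprintf("unsanctioned overlap between features %s and %s",
                       f$id[i], f$id[j]))
        }
      }
    }
  }
  invisible(TRUE)
}

#' Standard germline small-RNA study blueprint
#'
#' Lays out, on a three-chromosome genome (two autosomes and an X), the
#' feature complement the pipeline expects: known and novel miRNA hairpins
#' (a subset X-linked), decoy hairpins (non-miRNA hairpin loci that violate
#' either 5' homogeneity or duplex geometry at read time), mirtron host
#' genes with sub-100-nt hairpin introns, transposon families with two
#' copies each, convergently transcribed cis-NAT pairs, tRNA genes, mRNAs
#' with annotated 3' UTRs and piRNA cluster regions plus sub-threshold decoy
#' regions. Features are placed left to right with randomized spacing.
#'
#' @param n_known,n_novel,n_decoy miRNA hairpin counts (known = annotated in
#'   the GFF3/prior catalog; novel = unannotated, to be discovered; decoy =
#'   unannotated loci whose reads violate the discovery criteria).
#' @param n_mirtron mirtron host genes.
#' @param te_families character vector of family names (first is the
#'   29-nt-dominant family).
#' @param copies_per_family TE copies per family.
#' @param n_cisnat convergent gene pairs.
#' @param n_trna tRNA genes.
#' @param n_mrna_utr mRNAs with 3' UTRs.
#' @param n_cluster,n_decoy_cluster piRNA cluster regions meeting / failing
#'   the calling gates at read time.
#' @param chrom_lengths named chromosome lengths.
#' @param seed integer seed.
#' @return a `genome_blueprint`.
#' @export
blueprint_germline <- function(n_known = 10, n_novel = 30, n_decoy = 10,
                               n_mirtron = 2,
                               te_families = c("LTR1", "LTR2", "LINE1",
                                               "LINE2", "IR1", "RC1"),
                               copies_per_family = 2,
                               n_cisnat = 2, n_trna = 4, n_mrna_utr = 3,
                               n_cluster = 20, n_decoy_cluster = 5,
                               chrom_lengths = c(chr2 = 140000L,
                                                 chr3 = 140000L,
                                                 chrX = 110000L),
                               seed = 1L) {
  arm_len <- 24L; loop_len <- 8L
  hp_len <- 2L * arm_len + loop_len
  rows <- list()
  add <- function(kind, id, len, strand, chrom = NA, params = list()) {
    rows[[length(rows) + 1L]] <<- list(kind = kind, id = id, len = len,
                                       strand = strand, chrom = chrom,
                                       params = params)
  }
  x_novel <- max(0L, round(n_novel * 0.25))
  for (i in seq_len(n_known)) {
    add("mirna_hairpin", sprintf("mir_known_%02d", i), hp_len,
        if (i %% 2) "+" else "-",
        params = list(known = TRUE, arm_len = arm_len, loop_len = loop_len))
  }
  for (i in seq_len(n_novel)) {
    add("mirna_hairpin", sprintf("mir_novel_%02d", i), hp_len,
        if (i %% 2) "+" else "-",
        chrom = if (i <= x_novel) "chrX" else NA,
        params = list(known = FALSE, arm_len = arm_len, loop_len = loop_len,
                      testes_biased = i <= x_novel))
  }
  for (i in seq_len(n_decoy)) {
    add("decoy_hairpin", sprintf("decoy_%02d", i), hp_len,
        if (i %% 2) "+" else "-",
        params = list(arm_len = arm_len, loop_len = loop_len,
                      decoy_mode = if (i %% 2) "ragged5p" else "bad_overhang"))
  }
  for (i in seq_len(n_mirtron)) {
    intron_len <- 60L  # < 100 nt, itself a hairpin: arm 26 + loop 8 + arm 26
    add("mirtron_host", sprintf("mirtron_%d", i), 100L + intron_len + 100L, "+",
        params = list(intron_len = intron_len, exon_len = 100L,
                      has_star = i == 1L,
                      u_rate = if (i == 1L) 0.5 else 0.8))
  }
  for (fam in te_families) {
    for (cp in seq_len(copies_per_family)) {
      add("te_copy", sprintf("te_%s_%d", fam, cp), 1500L,
          if (cp %% 2) "+" else "-",
          params = list(family = fam, divergence = 0.05))
    }
  }
  for (i in seq_len(n_cisnat)) {
    add("cisnat_pair", sprintf("cisnat_%d", i), 2L * 800L - 120L, "+",
        params = list(gene_len = 800L, overlap_len = 120L))
  }
  for (i in seq_len(n_trna)) {
    add("trna", sprintf("trna_%d", i), 72L, if (i %% 2) "+" else "-")
  }
  for (i in seq_len(n_mrna_utr)) {
    add("mrna_with_utr", sprintf("mrna_%d", i), 900L, if (i %% 2) "+" else "-",
        params = list(utr5_len = 100L, utr3_len = 200L,
                      dominant29 = i == 1L))
  }
  for (i in seq_len(n_cluster)) {
    add("pirna_cluster_region", sprintf("picl_%02d", i), 2000L,
        if (i %% 2) "+" else "-",
        params = list(decoy = FALSE, dominant29 = i == 1L))
  }
  for (i in seq_len(n_decoy_cluster)) {
    # decoys fail the calling gates at read time: siRNA-like 21-nt reads
    # (mean-length gate) or reads in a single sample (abundance gate)
    add("pirna_cluster_region", sprintf("picl_decoy_%02d", i), 2000L,
        if (i %% 2) "+" else "-",
        params = list(decoy = TRUE,
                      decoy_mode = if (i %% 2) "sirna_like" else "sparse"))
  }

  # left-to-right placement with randomized gaps, honouring forced chromosomes
  feats <- with_seed(derive_seed(seed, "placement"), {
    cursors <- setNames(rep(1000L, length(chrom_lengths)), names(chrom_lengths))
    out <- vector("list", length(rows))
    auto <- names(chrom_lengths)
    k <- 0L
    for (i in seq_along(rows)) {
      r <- rows[[i]]
      chrom <- r$chrom
      if (is.na(chrom)) {
        k <- k + 1L
        chrom <- auto[(k %% length(auto)) + 1L]
      }
      gap <- sample(1200:2000, 1L)  # keeps features beyond the piRNA chaining gap
      start <- cursors[[chrom]] + gap
      end <- start + r$len
      if (end > chrom_lengths[[chrom]] - 1000L) {
        stop("blueprint_germline: chromosome ", chrom, " too short for plan")
      }
      cursors[[chrom]] <- end
      out[[i]] <- data.frame(
        kind = r$kind, chrom = chrom, start = start, end = end,
        strand = r$strand, id = r$id, stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
  feats$params <- lapply(rows, `[[`, "params")
  genome_blueprint(chrom_lengths, feats, seed = seed)
}
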