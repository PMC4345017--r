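# Realization of a genome blueprint: chromosome sequences with planted
# feature content, annotation, TE track and the machine-readable truth table.

# Map a 1-based inclusive interval [a, b] inside a feature to genomic 0-based
# half-open coordinates, honouring the feature strand.
plant_interval <- function(fstart, fend, strand, a, b) {
  if (strand == "+") c(fstart + a - 1L, fstart + b)
  else c(fend - b, fend - a + 1L)
}

# local 1-based strand-oriented coordinates of interval `iv` in window
# [wstart, wend)
.ctx_local <- function(iv, wstart, wend, strand) {
  if (strand == "+") c(iv[1] - wstart + 1L, iv[2] - wstart)
  else c(wend - iv[2] + 1L, wend - iv[1])
}

# Strand-aware sequence of a genomic 0-based half-open interval.
genome_subseq <- function(seqs, chrom, start, end, strand) {
  s <- substring(seqs[[chrom]], start + 1L, end)
  if (strand == "-") revcomp(s) else s
}

#' Build a genome from a blueprint
#'
#' Generates random chromosome sequences at the blueprint base composition,
#' substitutes synthesized content at planted features (miRNA/decoy hairpins,
#' mirtron intron hairpins, diverged TE family copies), and assembles the
#' annotation, TE track and truth table. Identical blueprints give
#' byte-identical output.
#'
#' @param blueprint a [genome_blueprint()].
#' @return an object of class `srna_genome`: list with `seqs` (named
#'   character vector of chromosome sequences), `annotation` (GRanges with
#'   `type`/`ID`/`Parent`), `te` (GRanges with `family`), `truth`
#'   (data.frame, 0-based half-open coordinates) and `blueprint`.
#' @export
build_genome <- function(blueprint) {
  stopifnot(inherits(blueprint, "genome_blueprint"))
  seed <- blueprint$seed
  seqs <- vapply(names(blueprint$chrom_lengths), function(chr) {
    with_seed(derive_seed(seed, paste0("chrom-", chr)),
              random_dna(blueprint$chrom_lengths[[chr]], blueprint$base_comp))
  }, character(1))

  feats <- blueprint$features
  ann <- list()   # annotation rows: chrom,start,end,strand,type,ID,Parent
  te <- list()
  truth <- list()
  add_ann <- function(chrom, start, end, strand, type, id, parent = NA_character_) {
    ann[[length(ann) + 1L]] <<- data.frame(
      chrom = chrom, start = start, end = end, strand = strand, type = type,
      ID = id, Parent = parent, stringsAsFactors = FALSE)
  }
  add_truth <- function(row) {
    base <- list(id = NA, class = NA, chrom = NA, start = NA, end = NA,
                 strand = NA, known = NA, decoy_mode = NA, family = NA,
                 mature_start = NA, mature_end = NA, star_start = NA,
                 star_end = NA, intron_start = NA, intron_end = NA,
                 overlap_start = NA, overlap_end = NA, utr3_start = NA,
                 utr3_end = NA, dominant29 = FALSE, decoy = FALSE,
                 has_star = NA, u_rate = NA, testes_biased = FALSE)
    truth[[length(truth) + 1L]] <<- as.data.frame(
      modifyList(base, row), stringsAsFactors = FALSE)
  }
  substitute_seq <- function(chrom, start, end, strand, content) {
    if (strand == "-") content <- revcomp(content)
    stopifnot(nchar(content) == end - start)
    s <- seqs[[chrom]]
    seqs[[chrom]] <<- paste0(substring(s, 1L, start), content,
                             substring(s, end + 1L, nchar(s)))
  }

  te_consensus <- new.env()
  for (i in seq_len(nrow(feats))) {
    f <- feats[i, ]
    p <- feats$params[[i]]
    kind <- f$kind
    if (kind %in% c("mirna_hairpin", "decoy_hairpin")) {
      # plant and verify in genomic context: the duplex geometry must hold in
      # the fold of the read-stack window discovery will examine (mature
      # +/- 70 nt), not just in the isolated precursor; flanking genomic
      # sequence can otherwise tie-break the stem into a shifted register
      for (attempt in 0:49) {
        hp <- synthesize_hairpin(p$arm_len, p$loop_len,
                                 derive_seed(seed,
                                             paste0("hp-", f$id, "-", attempt)))
        substitute_seq(f$chrom, f$start, f$end, f$strand, hp$seq)
        mg <- plant_interval(f$start, f$end, f$strand, hp$mature[1], hp$mature[2])
        sg0 <- plant_interval(f$start, f$end, f$strand, hp$star[1], hp$star[2])
        wstart <- max(0L, mg[1] - 70L)
        wend <- min(nchar(seqs[[f$chrom]]), mg[2] + 70L)
        wfold <- fold_maxpair(genome_subseq(seqs, f$chrom, wstart, wend, f$strand))
        mloc <- .ctx_local(mg, wstart, wend, f$strand)
        sloc <- .ctx_local(sg0, wstart, wend, f$strand)
        ok <- duplex_overhang_check(wfold, mloc, sloc)$pass &&
          duplex_pairing_fraction(wfold, mloc, sloc) >= 0.6
        if (ok) break
      }
      star <- hp$star
      mode <- if (kind == "decoy_hairpin") p$decoy_mode else NA
      if (identical(mode, "bad_overhang")) star <- star - 1L  # breaks 2-nt geometry
      sg <- plant_interval(f$start, f$end, f$strand, star[1], star[2])
      known <- isTRUE(p$known)
      if (known) add_ann(f$chrom, f$start, f$end, f$strand, "pre_miRNA", f$id)
      add_truth(list(id = f$id, class = kind, chrom = f$chrom, start = f$start,
                     end = f$end, strand = f$strand, known = known,
                     decoy_mode = mode,
                     mature_start = mg[1], mature_end = mg[2],
                     star_start = sg[1], star_end = sg[2],
                     testes_biased = isTRUE(p$testes_biased)))
    } else if (kind == "mirtron_host") {
      arm <- (p$intron_len - 8L) %/% 2L
      hp <- synthesize_hairpin(arm, p$intron_len - 2L * arm,
                               derive_seed(seed, paste0("hp-", f$id)))
      intron <- c(f$start + p$exon_len, f$start + p$exon_len + p$intron_len)
      substitute_seq(f$chrom, intron[1], intron[2], f$strand, hp$seq)
      mg <- plant_interval(intron[1], intron[2], f$strand, hp$mature[1], hp$mature[2])
      sg <- plant_interval(intron[1], intron[2], f$strand, hp$star[1], hp$star[2])
      gid <- paste0(f$id, "_gene"); mid <- paste0(f$id, "_mRNA")
      add_ann(f$chrom, f$start, f$end, f$strand, "gene", gid)
      add_ann(f$chrom, f$start, f$end, f$strand, "mRNA", mid, gid)
      add_ann(f$chrom, f$start, intron[1], f$strand, "exon",
              paste0(f$id, "_exon1"), mid)
      add_ann(f$chrom, intron[1], intron[2], f$strand, "intron",
              paste0(f$id, "_intron"), mid)
      add_ann(f$chrom, intron[2], f$end, f$strand, "exon",
              paste0(f$id, "_exon2"), mid)
      add_truth(list(id = f$id, class = kind, chrom = f$chrom, start = f$start,
                     end = f$end, strand = f$strand,
                     intron_start = intron[1], intron_end = intron[2],
                     mature_start = mg[1], mature_end = mg[2],
                     star_start = sg[1], star_end = sg[2],
                     has_star = isTRUE(p$has_star), u_rate = p$u_rate))
    } else if (kind == "te_copy") {
      fam <- p$family
      if (is.null(te_consensus[[fam]])) {
        te_consensus[[fam]] <- with_seed(derive_seed(seed, paste0("te-", fam)),
                                         random_dna(f$end - f$start))
      }
      copy <- with_seed(derive_seed(seed, paste0("te-", f$id)), {
        x <- strsplit(te_consensus[[fam]], "")[[1]]
        mut <- which(runif(length(x)) < p$divergence)
        for (m in mut) x[m] <- sample(setdiff(BASES, x[m]), 1L)
        paste(x, collapse = "")
      })
      substitute_seq(f$chrom, f$start, f$end, f$strand, copy)
      te[[length(te) + 1L]] <- data.frame(
        chrom = f$chrom, start = f$start, end = f$end, strand = f$strand,
        family = fam, id = f$id, stringsAsFactors = FALSE)
      add_truth(list(id = f$id, class = kind, chrom = f$chrom, start = f$start,
                     end = f$end, strand = f$strand, family = fam))
    } else if (kind == "cisnat_pair") {
      glen <- p$gene_len; ov <- p$overlap_len
      a <- c(f$start, f$start + glen)            # + strand transcript
      b <- c(f$end - glen, f$end)                # - strand transcript
      ovl <- c(b[1], a[2])                       # shared 3' overlap
      stopifnot(ovl[2] - ovl[1] == ov)
      for (g in list(list(iv = a, str = "+", tag = "A"),
                     list(iv = b, str = "-", tag = "B"))) {
        gid <- paste0(f$id, "_", g$tag, "_gene")
        mid <- paste0(f$id, "_", g$tag, "_mRNA")
        add_ann(f$chrom, g$iv[1], g$iv[2], g$str, "gene", gid)
        add_ann(f$chrom, g$iv[1], g$iv[2], g$str, "mRNA", mid, gid)
        add_ann(f$chrom, g$iv[1], g$iv[2], g$str, "exon",
                paste0(mid, "_exon"), mid)
        add_ann(f$chrom, ovl[1], ovl[2], g$str, "three_prime_UTR",
                paste0(mid, "_3utr"), mid)
      }
      add_truth(list(id = f$id, class = kind, chrom = f$chrom, start = f$start,
                     end = f$end, strand = "+",
                     overlap_start = ovl[1], overlap_end = ovl[2]))
    } else if (kind == "trna") {
      add_ann(f$chrom, f$start, f$end, f$strand, "tRNA", f$id)
      add_truth(list(id = f$id, class = kind, chrom = f$chrom, start = f$start,
                     end = f$end, strand = f$strand))
    } else if (kind == "mrna_with_utr") {
      u5 <- p$utr5_len; u3 <- p$utr3_len
      gid <- paste0(f$id, "_gene"); mid <- paste0(f$id, "_mRNA")
      utr3 <- if (f$strand == "+") c(f$end - u3, f$end) else c(f$start, f$start + u3)
      utr5 <- if (f$strand == "+") c(f$start, f$start + u5) else c(f$end - u5, f$end)
      add_ann(f$chrom, f$start, f$end, f$strand, "gene", gid)
      add_ann(f$chrom, f$start, f$end, f$strand, "mRNA", mid, gid)
      add_ann(f$chrom, f$start, f$end, f$strand, "exon", paste0(mid, "_exon"), mid)
      add_ann(f$chrom, utr5[1], utr5[2], f$strand, "five_prime_UTR",
              paste0(mid, "_5utr"), mid)
      add_ann(f$chrom, utr3[1], utr3[2], f$strand, "three_prime_UTR",
              paste0(mid, "_3utr"), mid)
      add_truth(list(id = f$id, class = kind, chrom = f$chrom, start = f$start,
                     end = f$end, strand = f$strand,
                     utr3_start = utr3[1], utr3_end = utr3[2],
                     dominant29 = isTRUE(p$dominant29)))
    } else if (kind == "pirna_cluster_region") {
      add_truth(list(id = f$id, class = kind, chrom = f$chrom, start = f$start,
                     end = f$end, strand = f$strand,
                     decoy = isTRUE(p$decoy), dominant29 = isTRUE(p$dominant29),
                     decoy_mode = if (is.null(p$decoy_mode)) NA else p$decoy_mode))
    }
  }

  ann_df <- if (length(ann)) do.call(rbind, ann) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               strand = character(), type = character(), ID = character(),
               Parent = character(), stringsAsFactors = FALSE)
  te_df <- if (length(te)) do.call(rbind, te) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               strand = character(), family = character(), id = character(),
               stringsAsFactors = FALSE)
  truth_df <- do.call(rbind, truth)

  ann_gr <- intervals_to_granges(ann_df)
  S4Vectors::mcols(ann_gr)$type <- ann_df$type
  S4Vectors::mcols(ann_gr)$ID <- ann_df$ID
  S4Vectors::mcols(ann_gr)$Parent <- ann_df$Parent
  te_gr <- intervals_to_granges(te_df)
  if (nrow(te_df)) {
    S4Vectors::mcols(te_gr)$family <- te_df$family
    S4Vectors::mcols(te_gr)$id <- te_df$id
  }

  structure(list(seqs = seqs, annotation = ann_gr, te = te_gr,
                 truth = truth_df, blueprint = blueprint),
            class = "srna_genome")
}

#' @export
print.srna_genome <- function(x, ...) {
  cat("srna_genome:", length(x$seqs), "chromosome(s),",
      sum(nchar(x$seqs)), "bp;", nrow(x$truth), "planted features\n")
  print(table(x$truth$class))
  invisible(x)
}

#' Write a genome bundle to disk
#'
#' Emits the genome FASTA, annotation GFF3 (1-based inclusive, `ID=`
#' attributes), TE BED (0-based half-open, name = family) and the truth
#' table TSV.
#'
#' @param genome an `srna_genome`.
#' @param dir output directory (created if missing).
#' @return invisibly, the named vector of written paths.
#' @export
write_genome_bundle <- function(genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(dir, "genome.fa"),
             gff = file.path(dir, "annotation.gff3"),
             te = file.path(dir, "te.bed"),
             truth = file.path(dir, "truth.tsv"))
  dna <- Biostrings::DNAStringSet(genome$seqs)
  Biostrings::writeXStringSet(dna, paths["fasta"])
  ann <- genome$annotation
  rtracklayer::export(ann, paths["gff"], format = "gff3")
  te <- genome$te
  if (length(te)) {
    bed <- te
    S4Vectors::mcols(bed) <- S4Vectors::DataFrame(
      name = S4Vectors::mcols(te)$family, score = 0L)
    rtracklayer::export(bed, paths["te"], format = "bed")
  } else {
    file.create(paths["te"])
  }
  write_tsv(genome$truth, paths["truth"])
  invisible(paths)
}
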