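# Simulation of per-sample small RNA FASTQ libraries from a built genome:
# every read class the analysis characterizes is planted according to a
# ReadRecipe, with U1/A10 and ping-pong structure realized by selecting
# genomic 5' positions whose sequence carries the required bases (so that
# every non-background, non-uridylated read still maps perfectly).

#' Study sample identifiers
#'
#' The seven library conditions emulated by the default recipe: larval
#' testes fragment, larval ovary fragment, whole male larvae, whole female
#' larvae, non-bloodfed ovaries, bloodfed (vitellogenic) ovaries and adult
#' testes.
#' @export
STUDY_SAMPLES <- c("lt_frag", "lo_frag", "wml", "wfl",
                   "ov_nbf", "ov_bf", "testes")

#' Construct a read recipe
#'
#' Per-class read counts per sample, per-class length distributions and the
#' sequence-bias knobs of the simulation. Defaults reflect the library
#' structure the pipeline is designed for: miRNA duplex reads peaked at
#' 22 nt, TE piRNAs 24-30 nt with a 27-nt mode (one family 29-dominant),
#' exactly-21-nt cis-NAT siRNAs, 32-nt 5' half-tRNAs (30-fold reduced in
#' pre-vitellogenic ovaries), piRNA cluster reads averaging 26-27 nt,
#' dominant single 29-mers, and uniform 17-36 nt degradation background.
#'
#' @param samples sample identifiers.
#' @param class_counts named per-sample base read counts per class.
#' @param sample_factors optional class x sample multiplier matrix.
#' @param u1_antisense fraction of antisense TE piRNAs with 5' U.
#' @param a10_sense_by_len,u1_sense_by_len per-length (24-30) fractions of
#'   sense TE piRNAs carrying A at position 10 / U at position 1; the
#'   default A10 profile falls and the U1 profile rises with length.
#' @param pingpong_fraction fraction of sense TE piRNAs generated as
#'   ping-pong partners (5' end exactly 10 nt inside an antisense 5' end).
#' @param sense_fraction_te fraction of TE piRNAs on the TE sense strand.
#' @param cluster_u1 5' U fraction in piRNA cluster reads.
#' @param dominant29_multiplier abundance multiplier of the planted dominant
#'   29-mers relative to a typical distinct sequence.
#' @param mirna_homogeneity probability that a miRNA read starts at the
#'   canonical mature 5' end; decoy "ragged" loci use `decoy_homogeneity`.
#' @param decoy_homogeneity see above.
#' @param mirna_star_fraction fraction of hairpin reads from the star strand.
#' @param pirna_len_probs,pirna29_len_probs,cluster_len_probs,utr_len_probs
#'   named length distributions for TE piRNAs, 29-dominant-family antisense
#'   TE piRNAs, cluster piRNAs and 3'UTR piRNAs.
#' @param dominant29_families TE families whose antisense reads use the
#'   29-dominant length distribution.
#' @param adapter 3' adapter sequence appended to every read.
#' @param seed integer seed; per-sample sub-seeds are derived from it.
#' @return a list of class `read_recipe`.
#' @export
read_recipe <- function(samples = STUDY_SAMPLES,
                        class_counts = c(mirna = 6000, mirtron = 300,
                                         te_pirna = 8000, cluster_pirna = 6000,
                                         utr_pirna = 1500, cisnat_sirna = 800,
                                         half_trna = 600, background = 4000),
                        sample_factors = NULL,
                        u1_antisense = 0.85,
                        a10_sense_by_len = c(`24` = 0.92, `25` = 0.87, `26` = 0.82,
                                             `27` = 0.77, `28` = 0.72, `29` = 0.67,
                                             `30` = 0.62),
                        u1_sense_by_len = c(`24` = 0.50, `25` = 0.56, `26` = 0.62,
                                            `27` = 0.68, `28` = 0.74, `29` = 0.80,
                                            `30` = 0.86),
                        pingpong_fraction = 0.3,
                        sense_fraction_te = 0.3,
                        cluster_u1 = 0.85,
                        dominant29_multiplier = 100,
                        mirna_homogeneity = 0.97,
                        decoy_homogeneity = 0.4,
                        mirna_star_fraction = 0.15,
                        pirna_len_probs = c(`24` = 0.06, `25` = 0.10, `26` = 0.18,
                                            `27` = 0.30, `28` = 0.18, `29` = 0.12,
                                            `30` = 0.06),
                        pirna29_len_probs = c(`24` = 0.03, `25` = 0.05, `26` = 0.08,
                                              `27` = 0.12, `28` = 0.10, `29` = 0.55,
                                              `30` = 0.07),
                        cluster_len_probs = c(`25` = 0.05, `26` = 0.35, `27` = 0.40,
                                              `28` = 0.15, `29` = 0.05),
                        utr_len_probs = c(`24` = 0.05, `25` = 0.07, `26` = 0.13,
                                          `27` = 0.25, `28` = 0.12, `29` = 0.33,
                                          `30` = 0.05),
                        dominant29_families = "LTR1",
                        adapter = "TGGAATTCTCGGGTGCCAAGG",
                        seed = 1L) {
  fr <- c(u1_antisense, a10_sense_by_len, u1_sense_by_len, pingpong_fraction,
          sense_fraction_te, cluster_u1, mirna_homogeneity, decoy_homogeneity,
          mirna_star_fraction)
  if (any(fr < 0 | fr > 1)) stop("read_recipe: fractions must lie in [0, 1]")
  if (any(class_counts < 0)) stop("read_recipe: counts must be non-negative")
  if (is.null(sample_factors)) {
    sample_factors <- matrix(1, nrow = length(class_counts),
                             ncol = length(samples),
                             dimnames = list(names(class_counts), samples))
    # half-tRNAs 30-fold down in pre-vitellogenic ovaries
    if ("half_trna" %in% rownames(sample_factors) && "ov_nbf" %in% samples) {
      sample_factors["half_trna", "ov_nbf"] <- 1 / 30
    }
  }
  structure(list(samples = samples, class_counts = class_counts,
                 sample_factors = sample_factors,
                 u1_antisense = u1_antisense,
                 a10_sense_by_len = a10_sense_by_len,
                 u1_sense_by_len = u1_sense_by_len,
                 pingpong_fraction = pingpong_fraction,
                 sense_fraction_te = sense_fraction_te,
                 cluster_u1 = cluster_u1,
                 dominant29_multiplier = dominant29_multiplier,
                 mirna_homogeneity = mirna_homogeneity,
                 decoy_homogeneity = decoy_homogeneity,
                 mirna_star_fraction = mirna_star_fraction,
                 pirna_len_probs = pirna_len_probs,
                 pirna29_len_probs = pirna29_len_probs,
                 cluster_len_probs = cluster_len_probs,
                 utr_len_probs = utr_len_probs,
                 dominant29_families = dominant29_families,
                 adapter = adapter, seed = as.integer(seed)),
            class = "read_recipe")
}

# sample n lengths from a named prob vector
.draw_len <- function(n, probs) {
  as.integer(sample(as.integer(names(probs)), n, replace = TRUE, prob = probs))
}

# convert (5' position, length, genomic strand) to 0-based half-open interval
.five_to_interval <- function(five, len, gstrand) {
  gstrand <- rep_len(gstrand, length(five))
  start <- ifelse(gstrand == "+", five, five - len + 1L)
  data.frame(start = start, end = start + len)
}

#' Simulate one sample's small RNA library
#'
#' Emits the reads of every planted class for one sample according to the
#' recipe. Each read is the strand-aware genomic subsequence at its source
#' locus plus the 3' adapter; mirtron reads flagged for terminal uridylation
#' carry one additional non-genomic 3' U before the adapter; ping-pong sense
#' piRNAs have 5' ends exactly 10 nt inside a partner antisense 5' end.
#'
#' @param genome an `srna_genome` from [build_genome()].
#' @param recipe a [read_recipe()].
#' @param sample_id one of `recipe$samples`.
#' @param seed optional integer; defaults to a sub-seed derived from the
#'   recipe seed and the sample id.
#' @return data.frame with columns `id`, `class`, `locus`, `chrom`, `start`,
#'   `end`, `gstrand`, `uridylated`, `insert`, `read`.
#' @export
simulate_library <- function(genome, recipe, sample_id, seed = NULL) {
  stopifnot(inherits(genome, "srna_genome"), inherits(recipe, "read_recipe"))
  if (!sample_id %in% recipe$samples) {
    stop("simulate_library: unknown sample ", sample_id)
  }
  if (is.null(seed)) seed <- derive_seed(recipe$seed, paste0("lib-", sample_id))
  truth <- genome$truth
  counts <- round(recipe$class_counts *
                    recipe$sample_factors[names(recipe$class_counts), sample_id])
  for (cls in names(counts)[counts > 0]) {
    ok <- switch(cls,
      mirna = any(truth$class %in% c("mirna_hairpin", "decoy_hairpin")),
      mirtron = any(truth$class == "mirtron_host"),
      te_pirna = any(truth$class == "te_copy"),
      cluster_pirna = any(truth$class == "pirna_cluster_region"),
      utr_pirna = any(truth$class == "mrna_with_utr"),
      cisnat_sirna = any(truth$class == "cisnat_pair"),
      half_trna = any(truth$class == "trna"),
      background = TRUE,
      stop("simulate_library: unknown read class in recipe: ", cls))
    if (!ok) stop("simulate_library: recipe requests class '", cls,
                  "' but no matching feature is planted")
  }

  cnt <- function(cls) if (cls %in% names(counts)) counts[[cls]] else 0L
  chars <- lapply(genome$seqs, function(s) strsplit(s, "")[[1]])
  plan <- with_seed(seed, {
    parts <- list(
      .sim_mirna(truth, cnt("mirna"), recipe, sample_id),
      .sim_mirtron(truth, cnt("mirtron"), recipe),
      .sim_te_pirna(truth, chars, cnt("te_pirna"), recipe),
      .sim_cluster_pirna(truth, chars, cnt("cluster_pirna"), recipe,
                         sample_id),
      .sim_utr_pirna(truth, chars, cnt("utr_pirna"), recipe),
      .sim_cisnat(truth, cnt("cisnat_sirna")),
      .sim_half_trna(truth, cnt("half_trna")),
      .sim_background(genome$blueprint$chrom_lengths, cnt("background"))
    )
    do.call(rbind, Filter(Negate(is.null), parts))
  })
  if (is.null(plan) || !nrow(plan)) {
    return(data.frame(id = character(), class = character(),
                      locus = character(), chrom = character(),
                      start = integer(), end = integer(),
                      gstrand = character(), uridylated = logical(),
                      insert = character(), read = character(),
                      stringsAsFactors = FALSE))
  }

  # strand-aware insert extraction, vectorized per chromosome/strand
  plan$insert <- NA_character_
  for (chr in unique(plan$chrom)) {
    for (str in c("+", "-")) {
      sel <- plan$chrom == chr & plan$gstrand == str
      if (!any(sel)) next
      s <- substring(genome$seqs[[chr]], plan$start[sel] + 1L, plan$end[sel])
      if (str == "-") {
        s <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAStringSet(s)))
      }
      plan$insert[sel] <- s
    }
  }
  plan$insert[plan$uridylated] <- paste0(plan$insert[plan$uridylated], "T")
  plan$read <- paste0(plan$insert, recipe$adapter)
  plan$id <- sprintf("%s_%07d class=%s locus=%s", sample_id,
                     seq_len(nrow(plan)), plan$class, plan$locus)
  rownames(plan) <- NULL
  plan
}

# ---- per-class planners (run inside one seeded block) ---------------------

.mk_plan <- function(class, locus, chrom, start, end, gstrand,
                     uridylated = FALSE) {
  if (!length(locus)) return(NULL)
  data.frame(class = class, locus = locus, chrom = chrom,
             start = as.integer(start), end = as.integer(end),
             gstrand = gstrand,
             uridylated = rep_len(uridylated, length(locus)),
             stringsAsFactors = FALSE)
}

.locus_weights <- function(seed, ids, sdlog) {
  with_seed(seed, setNames(exp(rnorm(length(ids), 0, sdlog)), ids))
}

.sim_mirna <- function(truth, n, recipe, sample_id) {
  hp <- truth[truth$class %in% c("mirna_hairpin", "decoy_hairpin"), ]
  if (!nrow(hp) || n == 0) return(NULL)
  w <- .locus_weights(derive_seed(recipe$seed, "mirna-abund"), hp$id, 1.2)
  # testes-biased loci up in testes-like, down in ovary-like samples
  bias <- ifelse(hp$testes_biased,
                 if (sample_id %in% c("testes", "lt_frag")) 6
                 else if (sample_id %in% c("ov_nbf", "ov_bf", "lo_frag")) 1 / 6
                 else 1, 1)
  alloc <- as.vector(rmultinom(1, n, w * bias))
  out <- vector("list", nrow(hp))
  for (i in seq_len(nrow(hp))) {
    ni <- alloc[i]
    if (ni == 0) next
    h <- hp[i, ]
    is_star <- runif(ni) < recipe$mirna_star_fraction
    n_m <- sum(!is_star)
    homog <- if (identical(h$decoy_mode, "ragged5p")) recipe$decoy_homogeneity
             else recipe$mirna_homogeneity
    mlen <- h$mature_end - h$mature_start
    five_modal <- if (h$strand == "+") h$mature_start else h$mature_end - 1L
    r5 <- ifelse(runif(n_m) < homog, 0L,
                 sample(c(-2L, -1L, 1L, 2L), n_m, replace = TRUE))
    r3 <- sample(c(0L, -1L, 1L), n_m, replace = TRUE, prob = c(0.7, 0.15, 0.15))
    len <- pmax(17L, mlen - r5 + r3)
    five <- five_modal + r5 * (if (h$strand == "+") 1L else -1L)
    iv_m <- .five_to_interval(five, len, h$strand)
    # star reads: exact planted star interval
    iv_s <- if (ni - n_m > 0) {
      data.frame(start = rep(h$star_start, ni - n_m),
                 end = rep(h$star_end, ni - n_m))
    } else NULL
    iv <- rbind(iv_m, iv_s)
    out[[i]] <- .mk_plan("mirna", h$id, h$chrom, iv$start, iv$end, h$strand)
  }
  do.call(rbind, Filter(Negate(is.null), out))
}

.sim_mirtron <- function(truth, n, recipe) {
  mt <- truth[truth$class == "mirtron_host", ]
  if (!nrow(mt) || n == 0) return(NULL)
  alloc <- as.vector(rmultinom(1, n, rep(1, nrow(mt))))
  out <- vector("list", nrow(mt))
  for (i in seq_len(nrow(mt))) {
    ni <- alloc[i]
    if (ni == 0) next
    h <- mt[i, ]
    star_ok <- isTRUE(h$has_star)
    is_star <- star_ok & runif(ni) < 0.2
    n_m <- sum(!is_star)
    urid <- runif(ni) < h$u_rate
    urid[is_star] <- FALSE
    st <- ifelse(is_star, h$star_start, h$mature_start)
    en <- ifelse(is_star, h$star_end, h$mature_end)
    out[[i]] <- .mk_plan("mirtron", h$id, h$chrom, st, en, h$strand, urid)
  }
  do.call(rbind, Filter(Negate(is.null), out))
}

# per-position U1/A10 eligibility for reads on genomic strand `gstrand`
# whose 5' position lies in [s, e): read-space U1 requires genomic T (+) /
# A (-) at the 5' position; A10 requires A at genomic offset +9 (+) / T at
# offset -9 (-). Returns 0-based candidate position sets per flag combo so
# planted bias fractions are exact.
.bias_pos_sets <- function(v, s, e, gstrand) {
  p <- s:(e - 1L)
  base5 <- v[p + 1L]
  u1 <- if (gstrand == "+") base5 == "T" else base5 == "A"
  p10 <- if (gstrand == "+") p + 9L else p - 9L
  ok10 <- p10 >= 0L & p10 < length(v)
  base10 <- rep(NA_character_, length(p))
  base10[ok10] <- v[p10[ok10] + 1L]
  a10 <- if (gstrand == "+") !is.na(base10) & base10 == "A"
         else !is.na(base10) & base10 == "T"
  list(both = p[u1 & a10], u1_only = p[u1 & !a10],
       a10_only = p[!u1 & a10], neither = p[!u1 & !a10],
       u1 = p[u1], not_u1 = p[!u1])
}

# draw n positions from a candidate set restricted to [lo, hi]; empty sets
# fall back to the full range
.draw_from <- function(n, set, lo, hi) {
  cand <- set[set >= lo & set <= hi]
  if (!length(cand)) cand <- lo:hi
  cand[sample.int(length(cand), n, replace = TRUE)]
}

.sim_te_pirna <- function(truth, chars, n, recipe) {
  te <- truth[truth$class == "te_copy", ]
  if (!nrow(te) || n == 0) return(NULL)
  w <- .locus_weights(derive_seed(recipe$seed, "te-abund"), te$id, 0.8)
  alloc <- as.vector(rmultinom(1, n, w))
  out <- list()
  for (i in seq_len(nrow(te))) {
    ni <- alloc[i]
    if (ni == 0) next
    f <- te[i, ]
    v <- chars[[f$chrom]]
    anti_g <- if (f$strand == "+") "-" else "+"
    sense_g <- f$strand
    n_sense <- rbinom(1, ni, recipe$sense_fraction_te)
    n_anti <- ni - n_sense
    dom29 <- f$family %in% recipe$dominant29_families
    lp_anti <- if (dom29) recipe$pirna29_len_probs else recipe$pirna_len_probs
    aset <- .bias_pos_sets(v, f$start, f$end, anti_g)
    sset <- .bias_pos_sets(v, f$start, f$end, sense_g)

    # --- antisense (primary) reads at an exact U1 fraction ---
    a_len <- .draw_len(n_anti, lp_anti)
    a_u1 <- runif(n_anti) < recipe$u1_antisense
    a_five <- integer(n_anti)
    for (l in unique(a_len)) {
      rng <- if (anti_g == "+") c(f$start, f$end - l) else c(f$start + l - 1L, f$end - 1L)
      s1 <- which(a_len == l & a_u1)
      s0 <- which(a_len == l & !a_u1)
      if (length(s1)) a_five[s1] <- .draw_from(length(s1), aset$u1, rng[1], rng[2])
      if (length(s0)) a_five[s0] <- .draw_from(length(s0), aset$not_u1, rng[1], rng[2])
    }
    iv_a <- .five_to_interval(a_five, a_len, anti_g)
    out[[length(out) + 1L]] <- .mk_plan("te_pirna", f$id, f$chrom,
                                        iv_a$start, iv_a$end, anti_g)

    # --- sense reads: ping-pong partners plus primary at exact per-length
    # A10/U1 fractions ---
    if (n_sense > 0) {
      n_pp <- rbinom(1, n_sense, recipe$pingpong_fraction)
      pp_partners <- a_five[a_u1]
      s_len <- .draw_len(n_sense, recipe$pirna_len_probs)
      s_five <- integer(n_sense)
      is_pp <- seq_len(n_sense) <= n_pp & length(pp_partners) > 0
      if (any(is_pp)) {
        part <- pp_partners[sample.int(length(pp_partners), sum(is_pp),
                                       replace = TRUE)]
        s_five[is_pp] <- if (sense_g == "+") part - 9L else part + 9L
      }
      pri <- which(!is_pp)
      if (length(pri)) {
        a10 <- runif(length(pri)) <
          recipe$a10_sense_by_len[as.character(s_len[pri])]
        u1 <- runif(length(pri)) <
          recipe$u1_sense_by_len[as.character(s_len[pri])]
        for (l in unique(s_len[pri])) {
          rng <- if (sense_g == "+") c(f$start, f$end - l) else c(f$start + l - 1L, f$end - 1L)
          for (cmb in 1:4) {
            sel <- pri[s_len[pri] == l &
                         a10 == (cmb %in% c(1, 2)) & u1 == (cmb %in% c(1, 3))]
            if (!length(sel)) next
            set <- switch(cmb, sset$both, sset$a10_only, sset$u1_only,
                          sset$neither)
            s_five[sel] <- .draw_from(length(sel), set, rng[1], rng[2])
          }
        }
      }
      keep <- if (sense_g == "+") {
        s_five >= f$start & s_five + s_len <= f$end
      } else {
        s_five - s_len + 1L >= f$start & s_five < f$end
      }
      if (any(keep)) {
        iv_s <- .five_to_interval(s_five[keep], s_len[keep], sense_g)
        out[[length(out) + 1L]] <- .mk_plan("te_pirna", f$id, f$chrom,
                                            iv_s$start, iv_s$end, sense_g)
      }
    }
  }
  do.call(rbind, out)
}

.sim_cluster_pirna <- function(truth, chars, n, recipe, sample_id) {
  cl <- truth[truth$class == "pirna_cluster_region", ]
  if (!nrow(cl) || n == 0) return(NULL)
  real <- cl[!cl$decoy, ]
  out <- list()
  alloc <- as.vector(rmultinom(1, n, rep(1, nrow(real))))
  for (i in seq_len(nrow(real))) {
    f <- real[i, ]
    ni <- alloc[i]
    if (ni == 0) next
    v <- chars[[f$chrom]]
    len <- .draw_len(ni, recipe$cluster_len_probs)
    u1 <- runif(ni) < recipe$cluster_u1
    pset <- .bias_pos_sets(v, f$start, f$end, f$strand)
    five <- integer(ni)
    for (l in unique(len)) {
      rng <- if (f$strand == "+") c(f$start, f$end - l) else c(f$start + l - 1L, f$end - 1L)
      s1 <- which(len == l & u1); s0 <- which(len == l & !u1)
      if (length(s1)) five[s1] <- .draw_from(length(s1), pset$u1, rng[1], rng[2])
      if (length(s0)) five[s0] <- .draw_from(length(s0), pset$not_u1, rng[1], rng[2])
    }
    iv <- .five_to_interval(five, len, f$strand)
    out[[length(out) + 1L]] <- .mk_plan("cluster_pirna", f$id, f$chrom,
                                        iv$start, iv$end, f$strand)
    if (isTRUE(f$dominant29)) {
      dom <- .dominant29_read(v, f)
      if (!is.null(dom)) {
        nd <- as.integer(round(recipe$dominant29_multiplier * 7))
        out[[length(out) + 1L]] <- .mk_plan("cluster_pirna", f$id, f$chrom,
                                            rep(dom[1], nd), rep(dom[2], nd),
                                            f$strand)
      }
    }
  }
  # decoy regions: siRNA-like 21-nt reads, or reads in one sample only
  dec <- cl[cl$decoy, ]
  for (i in seq_len(nrow(dec))) {
    f <- dec[i, ]
    if (identical(f$decoy_mode, "sirna_like")) {
      ni <- 150L
      five <- if (f$strand == "+") {
        f$start + sample.int(f$end - f$start - 21L, ni, replace = TRUE) - 1L
      } else {
        f$start + 20L + sample.int(f$end - f$start - 21L, ni, replace = TRUE) - 1L
      }
      iv <- .five_to_interval(five, 21L, f$strand)
      out[[length(out) + 1L]] <- .mk_plan("cluster_pirna", f$id, f$chrom,
                                          iv$start, iv$end, f$strand)
    } else if (identical(f$decoy_mode, "sparse") && sample_id == recipe$samples[1]) {
      # few reads, single sample: passes the span and length gates but
      # stays below the mean normalized abundance gate
      step <- (f$end - f$start - 60L) %/% 4L
      five <- rep(f$start + (0:3) * step + (if (f$strand == "-") 26L else 0L),
                  each = 2L)
      len <- rep(c(26L, 26L, 27L, 27L), each = 2L)
      iv <- .five_to_interval(five, len, f$strand)
      out[[length(out) + 1L]] <- .mk_plan("cluster_pirna", f$id, f$chrom,
                                          iv$start, iv$end, f$strand)
    }
  }
  do.call(rbind, out)
}

# deterministic dominant 29-mer 5' position: first U1-compatible position in
# the middle 1000 bp of the region; returns c(start, end) or NULL
.dominant29_read <- function(v, f) {
  mid <- f$start + (f$end - f$start) %/% 4L
  if (f$strand == "+") {
    p <- which(v[(mid + 1L):(f$end - 29L)] == "T")
    if (!length(p)) return(NULL)
    st <- mid + p[1] - 1L
    c(st, st + 29L)
  } else {
    p <- which(v[(mid + 1L):(f$end - 1L)] == "A")
    if (!length(p)) return(NULL)
    five <- mid + p[1] - 1L
    if (five - 28L < f$start) return(NULL)
    c(five - 28L, five + 1L)
  }
}

.sim_utr_pirna <- function(truth, chars, n, recipe) {
  mr <- truth[truth$class == "mrna_with_utr", ]
  if (!nrow(mr) || n == 0) return(NULL)
  alloc <- as.vector(rmultinom(1, n, rep(1, nrow(mr))))
  out <- list()
  for (i in seq_len(nrow(mr))) {
    f <- mr[i, ]
    ni <- alloc[i]
    if (ni == 0) next
    v <- chars[[f$chrom]]
    len <- .draw_len(ni, recipe$utr_len_probs)
    # 29-mers derive almost exclusively from the 3' UTR; others mostly do
    in_utr <- runif(ni) < ifelse(len == 29L, 0.97, 0.75)
    u1 <- runif(ni) < 0.7
    pset <- .bias_pos_sets(v, f$start, f$end, f$strand)
    five <- integer(ni)
    for (l in unique(len)) {
      rng_utr <- if (f$strand == "+") c(f$utr3_start, f$utr3_end - l)
                 else c(f$utr3_start + l - 1L, f$utr3_end - 1L)
      rng_all <- if (f$strand == "+") c(f$start, f$end - l)
                 else c(f$start + l - 1L, f$end - 1L)
      for (u in c(TRUE, FALSE)) {
        rng <- if (u) rng_utr else rng_all
        s1 <- which(len == l & in_utr == u & u1)
        s0 <- which(len == l & in_utr == u & !u1)
        if (length(s1)) five[s1] <- .draw_from(length(s1), pset$u1, rng[1], rng[2])
        if (length(s0)) five[s0] <- .draw_from(length(s0), pset$not_u1, rng[1], rng[2])
      }
    }
    iv <- .five_to_interval(five, len, f$strand)
    out[[length(out) + 1L]] <- .mk_plan("utr_pirna", f$id, f$chrom,
                                        iv$start, iv$end, f$strand)
    if (isTRUE(f$dominant29)) {
      dom <- .dominant29_read(v, data.frame(start = f$utr3_start,
                                            end = f$utr3_end,
                                            strand = f$strand))
      if (!is.null(dom)) {
        nd <- as.integer(round(recipe$dominant29_multiplier * 7))
        out[[length(out) + 1L]] <- .mk_plan("utr_pirna", f$id, f$chrom,
                                            rep(dom[1], nd), rep(dom[2], nd),
                                            f$strand)
      }
    }
  }
  do.call(rbind, out)
}

.sim_cisnat <- function(truth, n) {
  cn <- truth[truth$class == "cisnat_pair", ]
  if (!nrow(cn) || n == 0) return(NULL)
  alloc <- as.vector(rmultinom(1, n, rep(1, nrow(cn))))
  out <- list()
  for (i in seq_len(nrow(cn))) {
    f <- cn[i, ]
    ni <- alloc[i]
    if (ni == 0) next
    gstr <- sample(c("+", "-"), ni, replace = TRUE)
    start <- f$overlap_start +
      sample.int(f$overlap_end - f$overlap_start - 21L + 1L, ni,
                 replace = TRUE) - 1L
    out[[length(out) + 1L]] <- .mk_plan("cisnat_sirna", f$id, f$chrom,
                                        start, start + 21L, gstr)
  }
  do.call(rbind, out)
}

.sim_half_trna <- function(truth, n) {
  tr <- truth[truth$class == "trna", ]
  if (!nrow(tr) || n == 0) return(NULL)
  alloc <- as.vector(rmultinom(1, n, rep(1, nrow(tr))))
  out <- list()
  for (i in seq_len(nrow(tr))) {
    f <- tr[i, ]
    ni <- alloc[i]
    if (ni == 0) next
    # 32-nt fragment anchored at the tRNA 5' end
    iv <- if (f$strand == "+") c(f$start, f$start + 32L)
          else c(f$end - 32L, f$end)
    out[[length(out) + 1L]] <- .mk_plan("half_trna", f$id, f$chrom,
                                        rep(iv[1], ni), rep(iv[2], ni),
                                        f$strand)
  }
  do.call(rbind, out)
}

.sim_background <- function(chrom_lengths, n) {
  if (n == 0) return(NULL)
  chrom <- sample(names(chrom_lengths), n, replace = TRUE,
                  prob = chrom_lengths / sum(chrom_lengths))
  len <- sample(17:36, n, replace = TRUE)
  start <- vapply(seq_len(n), function(i) {
    sample.int(chrom_lengths[[chrom[i]]] - len[i], 1L) - 1L
  }, integer(1))
  .mk_plan("background", "background", chrom, start, start + len,
           sample(c("+", "-"), n, replace = TRUE))
}

#' Write a simulated library as FASTQ
#'
#' Constant quality "I" per base.
#'
#' @param lib data.frame from [simulate_library()].
#' @param path output FASTQ path.
#' @export
write_fastq <- function(lib, path) {
  dna <- Biostrings::DNAStringSet(lib$read)
  names(dna) <- lib$id
  qual <- Biostrings::BStringSet(vapply(nchar(lib$read), function(n)
    paste(rep("I", n), collapse = ""), character(1)))
  Biostrings::writeXStringSet(dna, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Simulate the full multi-sample study
#'
#' Builds the genome from a blueprint and simulates one FASTQ library per
#' recipe sample.
#'
#' @param blueprint a [genome_blueprint()]; default [blueprint_germline()].
#' @param recipe a [read_recipe()].
#' @param dir optional directory; when given, genome bundle and per-sample
#'   FASTQ files are written there.
#' @return list with `genome`, `libs` (named list of per-sample read
#'   data.frames) and, when written, `paths`.
#' @export
simulate_study <- function(blueprint = blueprint_germline(),
                           recipe = read_recipe(), dir = NULL) {
  genome <- build_genome(blueprint)
  libs <- lapply(setNames(recipe$samples, recipe$samples), function(s)
    simulate_library(genome, recipe, s))
  paths <- NULL
  if (!is.null(dir)) {
    paths <- write_genome_bundle(genome, dir)
    fq <- vapply(recipe$samples, function(s) {
      p <- file.path(dir, paste0(s, ".fastq"))
      write_fastq(libs[[s]], p)
      p
    }, character(1))
    paths <- c(paths, setNames(fq, paste0("fastq_", recipe$samples)))
  }
  list(genome = genome, libs = libs, paths = paths)
}
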