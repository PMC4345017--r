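# Pipeline orchestration: YAML configuration with validated defaults, and
# staged execution (simulate -> process -> profile -> mirna -> expression ->
# pirna) with per-stage tables, a parameter/log record and deterministic
# reruns.

.config_defaults <- function() {
  list(
    genome_fasta = NULL, annotation_gff = NULL, te_bed = NULL,
    repeats_bed = NULL, fastq = NULL,
    outdir = NULL, seed = 1L,
    simulate = FALSE,
    sim_blueprint = list(),   # argument overrides for blueprint_germline()
    sim_recipe = list(),      # argument overrides for read_recipe()
    adapter = "TGGAATTCTCGGGTGCCAAGG",
    min_len = 17L, max_len = 36L, min_overlap = 8L,
    tau5 = 0.9, min_stack = 5, pad = 70L,
    min_samples = 2L, min_reads = 1L, max_intron = 100L, tau_u = 0.5,
    mirna_cluster_gap = 10000L,
    peak_ratio = 1.5, peak_min_frac = 0.05,
    pirna_max_gap = 500L, pirna_min_span = 100L,
    pirna_len_low = 26, pirna_len_high = 27, pirna_min_count = 50,
    pirna_window = c(24L, 30L),
    alpha = 0.01, min_fold = 4, heatmap_min_count = 20L, heatmap_k = 3L,
    contrast = c("testes", "ov_nbf"),
    halftrna_contrast = c("ov_bf", "ov_nbf"),
    x_chrom = "chrX")
}

.config_ranges <- list(
  tau5 = c(0, 1), tau_u = c(0, 1), peak_min_frac = c(0, 1),
  alpha = c(0, 1), min_len = c(1, Inf), max_len = c(1, Inf),
  min_overlap = c(1, Inf), min_fold = c(1, Inf), peak_ratio = c(1, Inf),
  pirna_min_span = c(0, Inf), pirna_min_count = c(0, Inf))

#' Validate and normalize a pipeline configuration
#'
#' Reads a YAML file (or takes a list), fills documented defaults, rejects
#' unknown keys, checks threshold ranges and file existence, and (when an
#' output directory is set) writes the effective configuration there.
#'
#' @param config path to a YAML file or a named list.
#' @param check_files verify referenced input files exist (default TRUE).
#' @return normalized configuration list of class `pipeline_config`.
#' @export
validate_config <- function(config, check_files = TRUE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  defaults <- .config_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stop("validate_config: unknown configuration key(s): ",
         paste(unknown, collapse = ", "))
  }
  cfg <- modifyList(defaults, config)
  for (key in names(.config_ranges)) {
    v <- cfg[[key]]
    r <- .config_ranges[[key]]
    if (!is.null(v) && (v < r[1] || v > r[2])) {
      stop(sprintf("validate_config: %s = %s outside [%s, %s]",
                   key, v, r[1], r[2]))
    }
  }
  if (cfg$min_len > cfg$max_len) {
    stop("validate_config: min_len exceeds max_len")
  }
  if (check_files && !isTRUE(cfg$simulate)) {
    paths <- c(cfg$genome_fasta, cfg$annotation_gff, cfg$te_bed,
               cfg$repeats_bed, unlist(cfg$fastq))
    missing <- paths[!file.exists(paths)]
    if (length(missing)) {
      stop("validate_config: missing input file(s): ",
           paste(missing, collapse = ", "))
    }
  }
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "pipeline_config"
  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
    yaml::write_yaml(unclass(cfg), file.path(cfg$outdir, "config_used.yaml"))
  }
  cfg
}

PIPELINE_STAGES <- c("simulate", "process", "profile", "mirna",
                     "expression", "pirna")

.stage_deps <- list(simulate = character(), process = "simulate",
                    profile = "process", mirna = "process",
                    expression = "mirna", pirna = "mirna")

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order, writing each stage's
#' tables under the configured output directory plus a run log with the
#' parameters, input checksums and seed used. State is cached on disk so
#' stage subsets can resume earlier runs; requesting a stage whose inputs
#' were never computed is an error.
#'
#' @param config a `pipeline_config` (or path / list accepted by
#'   [validate_config()]).
#' @param stages character subset of
#'   simulate/process/profile/mirna/expression/pirna, or "all".
#' @return invisibly, the pipeline state (list of stage results).
#' @export
run_pipeline <- function(config, stages = "all") {
  cfg <- if (inherits(config, "pipeline_config")) config
         else validate_config(config)
  if (is.null(cfg$outdir)) stop("run_pipeline: outdir must be set")
  if (identical(stages, "all")) {
    stages <- if (isTRUE(cfg$simulate)) PIPELINE_STAGES
              else setdiff(PIPELINE_STAGES, "simulate")
  }
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad)) stop("run_pipeline: unknown stage(s): ",
                        paste(bad, collapse = ", "))
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  state_path <- file.path(cfg$outdir, "state.rds")
  state <- if (file.exists(state_path)) readRDS(state_path) else list()
  log <- list(seed = cfg$seed, stages = stages,
              parameters = unclass(cfg)[setdiff(names(cfg),
                                                c("fastq", "outdir"))])
  for (st in stages) {
    dep <- .stage_deps[[st]]
    dep <- setdiff(dep, "simulate")  # external inputs may replace simulation
    if (st %in% c("process") && !isTRUE(cfg$simulate) &&
        (is.null(cfg$genome_fasta) || is.null(cfg$fastq))) {
      stop("run_pipeline: stage 'process' needs genome_fasta and fastq ",
           "inputs (or simulate: true)")
    }
    for (d in dep) {
      if (is.null(state[[d]])) {
        stop(sprintf("run_pipeline: stage '%s' requires outputs of '%s'",
                     st, d))
      }
    }
    state[[st]] <- switch(st,
      simulate = .stage_simulate(cfg),
      process = .stage_process(cfg, state),
      profile = .stage_profile(cfg, state),
      mirna = .stage_mirna(cfg, state),
      expression = .stage_expression(cfg, state),
      pirna = .stage_pirna(cfg, state))
    saveRDS(state, state_path)
  }
  inputs <- c(cfg$genome_fasta, cfg$annotation_gff, cfg$te_bed,
              unlist(cfg$fastq))
  if (!is.null(state$simulate)) inputs <- c(inputs, state$simulate$fastq)
  inputs <- unique(inputs[file.exists(inputs)])
  if (length(inputs)) log$input_md5 <- as.list(tools::md5sum(inputs))
  yaml::write_yaml(log, file.path(cfg$outdir, "run_log.yaml"))
  invisible(state)
}

.stage_simulate <- function(cfg) {
  dir <- file.path(cfg$outdir, "sim")
  bp <- do.call(blueprint_germline,
                modifyList(list(seed = cfg$seed), cfg$sim_blueprint))
  rec <- do.call(read_recipe,
                 modifyList(list(seed = cfg$seed, adapter = cfg$adapter),
                            cfg$sim_recipe))
  sim <- simulate_study(bp, rec, dir = dir)
  list(genome = sim$genome, recipe = rec,
       fastq = setNames(file.path(dir, paste0(rec$samples, ".fastq")),
                        rec$samples))
}

.load_inputs <- function(cfg, state) {
  if (!is.null(state$simulate)) {
    g <- state$simulate$genome
    return(list(seqs = g$seqs, annotation = g$annotation, te = g$te,
                fastq = state$simulate$fastq))
  }
  seqs <- as.character(Biostrings::readDNAStringSet(cfg$genome_fasta))
  names(seqs) <- sub("\\s.*", "", names(seqs))
  ann <- rtracklayer::import(cfg$annotation_gff, format = "gff3")
  te <- if (!is.null(cfg$te_bed)) {
    b <- rtracklayer::import(cfg$te_bed, format = "bed")
    S4Vectors::mcols(b)$family <- S4Vectors::mcols(b)$name
    b
  } else GenomicRanges::GRanges()
  list(seqs = seqs, annotation = ann, te = te, fastq = unlist(cfg$fastq))
}

.stage_process <- function(cfg, state) {
  inp <- .load_inputs(cfg, state)
  libs <- lapply(inp$fastq, read_fastq_seqs)
  proc <- process_libraries(libs, inp$seqs, cfg$adapter,
                            cfg$min_len, cfg$max_len, cfg$min_overlap)
  write_tsv(proc$stats, file.path(cfg$outdir, "processing_stats.tsv"))
  write_alignments_bed(proc$aln, file.path(cfg$outdir, "alignments.bed"))
  write_collapsed_fasta(proc$collapsed,
                        file.path(cfg$outdir, "collapsed.fa"))
  list(proc = proc, inputs = inp)
}

.stage_profile <- function(cfg, state) {
  proc <- state$process$proc
  inp <- state$process$inputs
  idx <- feature_index(inp$annotation, inp$te)
  cats <- categorize_reads(proc$aln, idx)
  reads <- as.integer(names(cats))
  lens <- nchar(proc$collapsed$seq)
  profiles <- lapply(colnames(proc$collapsed$counts), function(s) {
    w <- proc$collapsed$counts[reads, s]
    size_histogram(lens[reads], cats, w,
                   len_range = c(cfg$min_len, cfg$max_len))
  })
  names(profiles) <- colnames(proc$collapsed$counts)
  for (s in names(profiles)) {
    write_tsv(data.frame(length = rownames(profiles[[s]]), profiles[[s]],
                         check.names = FALSE),
              file.path(cfg$outdir, paste0("size_profile_", s, ".tsv")))
  }
  peaks <- lapply(profiles, function(p)
    detect_size_peak(rowSums(p), cfg$peak_ratio, cfg$peak_min_frac))
  list(index = idx, categories = cats, profiles = profiles, peaks = peaks)
}

.stage_mirna <- function(cfg, state) {
  proc <- state$process$proc
  inp <- state$process$inputs
  type <- S4Vectors::mcols(inp$annotation)$type
  known <- inp$annotation[type %in% c("pre_miRNA", "miRNA_precursor")]
  introns <- inp$annotation[type == "intron"]
  novel <- discover_novel_mirnas(proc, inp$seqs, known,
                                 min_stack = cfg$min_stack, pad = cfg$pad,
                                 tau5 = cfg$tau5,
                                 min_samples = cfg$min_samples,
                                 min_reads = cfg$min_reads)
  mirtrons <- discover_mirtrons(proc, inp$seqs, introns,
                                max_intron = cfg$max_intron,
                                tau_u = cfg$tau_u, tau5 = cfg$tau5,
                                min_samples = cfg$min_samples,
                                min_reads = cfg$min_reads)
  novel$cluster <- cluster_loci(novel, max_gap = cfg$mirna_cluster_gap)
  repeats <- if (!is.null(cfg$repeats_bed)) {
    rtracklayer::import(cfg$repeats_bed, format = "bed")
  } else NULL
  rep_flag <- flag_repeat_overlap(novel, repeats)
  novel$repeat_overlap <- rep_flag$flag
  write_tsv(novel, file.path(cfg$outdir, "novel_mirnas.tsv"))
  if (nrow(mirtrons)) {
    write_tsv(mirtrons, file.path(cfg$outdir, "mirtrons.tsv"))
  }
  write_mirna_gff(novel, file.path(cfg$outdir, "novel_mirnas.gff3"))
  list(novel = novel, mirtrons = mirtrons, known = known,
       repeat_fraction = rep_flag$fraction)
}

.stage_expression <- function(cfg, state) {
  proc <- state$process$proc
  inp <- state$process$inputs
  novel <- state$mirna$novel
  known <- state$mirna$known
  loci <- rbind(
    if (length(known)) data.frame(
      id = S4Vectors::mcols(known)$ID,
      granges_to_intervals(known)[, c("chrom", "start", "end", "strand")],
      stringsAsFactors = FALSE) else NULL,
    if (nrow(novel)) data.frame(
      id = novel$id, chrom = novel$chrom, start = novel$start,
      end = novel$end, strand = novel$strand, stringsAsFactors = FALSE)
    else NULL)
  if (is.null(loci) || !nrow(loci)) {
    return(list(counts = NULL, results = NULL))
  }
  gr <- intervals_to_granges(loci)
  agr <- intervals_to_granges(proc$aln)
  hits <- GenomicRanges::findOverlaps(agr, gr, minoverlap = 1L,
                                      ignore.strand = TRUE)
  counts <- matrix(0L, nrow = nrow(loci), ncol = ncol(proc$collapsed$counts),
                   dimnames = list(loci$id, colnames(proc$collapsed$counts)))
  if (length(hits)) {
    ri <- proc$aln$read[S4Vectors::queryHits(hits)]
    li <- S4Vectors::subjectHits(hits)
    dedup <- !duplicated(paste(ri, li))
    for (s in colnames(counts)) {
      counts[, s] <- as.integer(tapply(
        proc$collapsed$counts[ri[dedup], s],
        factor(li[dedup], levels = seq_len(nrow(loci))), sum, default = 0))
    }
  }
  sf <- size_factors_median_ratio(counts)
  res <- nb_test(counts, cond_a = cfg$contrast[2], cond_b = cfg$contrast[1],
                 size_factors = sf)
  res$padj <- bh_adjust(res$pval)
  res$call <- sex_bias_call(res, alpha = cfg$alpha, min_fold = cfg$min_fold)
  res$chrom <- loci$chrom
  cls <- tryCatch(
    expression_heatmap_classes(counts, min_count = cfg$heatmap_min_count,
                               k = cfg$heatmap_k),
    error = function(e) NULL)
  biased <- res$call != "unbiased" & grepl("testes", res$call)
  onx <- loci$chrom == cfg$x_chrom
  enr <- chromosome_enrichment(sum(biased & onx), sum(biased),
                               sum(!biased & onx), sum(!biased))
  write_tsv(res, file.path(cfg$outdir, "differential_expression.tsv"))
  enr_df <- data.frame(biased_x = enr$table[1, 1],
                       biased = sum(enr$table[1, ]),
                       unbiased_x = enr$table[2, 1],
                       unbiased = sum(enr$table[2, ]),
                       pct_x = enr$pct_x, pvalue = enr$pvalue)
  write_tsv(enr_df, file.path(cfg$outdir, "x_enrichment.tsv"))
  if (!is.null(cls)) {
    write_tsv(data.frame(locus = rownames(cls$logmat), class = cls$classes),
              file.path(cfg$outdir, "expression_classes.tsv"))
  }
  list(counts = counts, size_factors = sf, results = res,
       classes = cls, enrichment = enr)
}

.stage_pirna <- function(cfg, state) {
  proc <- state$process$proc
  inp <- state$process$inputs
  novel <- state$mirna$novel
  known <- state$mirna$known
  lens <- nchar(proc$collapsed$seq)
  # remove known + discovered miRNA precursors, then restrict to the piRNA
  # window and U1/A10-selected reads
  prec <- c(GenomicRanges::granges(known),
            if (nrow(novel)) intervals_to_granges(
              novel[, c("chrom", "start", "end", "strand")])
            else GenomicRanges::GRanges())
  nomir <- remove_mirna_fraction(proc$aln, prec)
  window <- cfg$pirna_window
  selected <- which(select_u1_a10_safe(proc$collapsed$seq))
  pal <- nomir$aln[nomir$aln$read %in% selected, , drop = FALSE]
  clusters <- call_pirna_clusters(pal, lens, proc$collapsed$counts, proc$norm,
                                  max_gap = cfg$pirna_max_gap,
                                  min_span = cfg$pirna_min_span,
                                  len_range = c(cfg$pirna_len_low,
                                                cfg$pirna_len_high),
                                  min_mean_count = cfg$pirna_min_count)
  write_tsv(clusters, file.path(cfg$outdir, "pirna_clusters.tsv"))
  totals_w <- rowSums(proc$collapsed$counts)
  tep <- te_strand_profile(nomir$aln, lens, totals_w, inp$te)
  if (!is.null(tep$summary)) {
    write_tsv(tep$summary, file.path(cfg$outdir, "te_profile.tsv"))
  }
  # ping-pong over TE-overlapping alignments in the piRNA window
  te_aln <- nomir$aln[IRanges::overlapsAny(intervals_to_granges(nomir$aln),
                                           inp$te, ignore.strand = TRUE) &
                        lens[nomir$aln$read] >= window[1] &
                        lens[nomir$aln$read] <= window[2], , drop = FALSE]
  te_aln$weight <- rowSums(proc$norm)[te_aln$read]
  pp <- pingpong_overlap_histogram(te_aln, te_aln)
  list(clusters = clusters, te_profile = tep, pingpong = pp)
}

# select_u1_a10 over mixed-length sequences (short reads never qualify)
select_u1_a10_safe <- function(seqs) {
  ok <- nchar(seqs) >= 10L
  out <- logical(length(seqs))
  out[ok] <- select_u1_a10(seqs[ok])
  out
}

#' Write discovered miRNA loci as GFF3
#'
#' Precursor / mature / star hierarchy via `Parent=` attributes.
#'
#' @param loci data.frame from [discover_novel_mirnas()].
#' @param path output path.
#' @export
write_mirna_gff <- function(loci, path) {
  rows <- list()
  for (i in seq_len(nrow(loci))) {
    l <- loci[i, ]
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = l$chrom, start = l$start, end = l$end, strand = l$strand,
      type = "pre_miRNA", ID = l$id, Parent = NA_character_)
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = l$chrom, start = l$mature_start, end = l$mature_end,
      strand = l$strand, type = "miRNA", ID = paste0(l$id, "_mature"),
      Parent = l$id)
    if (!is.na(l$star_start)) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = l$chrom, start = l$star_start, end = l$star_end,
        strand = l$strand, type = "miRNA_star", ID = paste0(l$id, "_star"),
        Parent = l$id)
    }
  }
  if (!length(rows)) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  df <- do.call(rbind, rows)
  gr <- intervals_to_granges(df)
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$ID <- df$ID
  S4Vectors::mcols(gr)$Parent <- df$Parent
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
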