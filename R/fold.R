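# Secondary-structure primitives used by hairpin synthesis and miRNA
# discovery: maximum base-pair folding and the duplex 2-nt overhang geometry.

#' Fold a sequence by maximum base pairing
#'
#' Computes a pseudoknot-free secondary structure maximizing the number of
#' Watson-Crick plus G-U wobble base pairs, with a minimum hairpin loop of
#' `min_loop` unpaired bases, by interval dynamic programming. Ties are
#' resolved deterministically during traceback: the 5'-most base is paired
#' first and, among equally optimal partners, the 3'-most partner is taken.
#' This base-pair-maximization fold deliberately replaces thermodynamic
#' folding so that results are exactly reproducible and testable against
#' exhaustive enumeration; `fold_fun` arguments elsewhere in the package
#' allow an external folder to be plugged in.
#'
#' @param seq character scalar over A/C/G/U (T accepted as U).
#' @param min_loop minimum number of unpaired bases in a hairpin loop.
#' @return a list with `structure` (dot-bracket string), `pairs` (optimal
#'   pair count) and `pairing` (1-based partner index per position, NA if
#'   unpaired).
#' @export
fold_maxpair <- function(seq, min_loop = 3L) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) > 400L) stop("fold_maxpair: sequence longer than 400 nt")
  s <- toupper(seq)
  if (grepl("[^ACGUT]", s)) stop("fold_maxpair: non-ACGU characters in input")
  .fold_maxpair_cpp(s, as.integer(min_loop))
}

#' Check the miRNA/miRNA* duplex 2-nt 3' overhang geometry
#'
#' A mature/star duplex produced by Drosha/Dicer processing leaves each
#' strand's 3' end protruding 2 nt beyond the paired region. In fold
#' coordinates this means: the base pairing the mature 5' end sits exactly
#' 2 nt inside the star 3' end, and the base pairing the star 5' end sits
#' exactly 2 nt inside the mature 3' end.
#'
#' @param fold result of [fold_maxpair()] (or any list with a `pairing`
#'   vector of 1-based partners).
#' @param mature integer vector `c(start, end)`, 1-based inclusive positions
#'   of the mature strand within the folded window.
#' @param star same for the star strand.
#' @return list with `pass` (logical) and `reason` (character).
#' @export
duplex_overhang_check <- function(fold, mature, star) {
  p <- fold$pairing
  n <- length(p)
  stopifnot(length(mature) == 2L, length(star) == 2L)
  if (any(c(mature, star) < 1L) || any(c(mature, star) > n)) {
    stop("duplex_overhang_check: intervals outside the folded window")
  }
  # opposite arms: one interval strictly before the other
  if (!(mature[2] < star[1] || star[2] < mature[1])) {
    return(list(pass = FALSE, reason = "mature and star on the same arm"))
  }
  m5 <- mature[1]; m3 <- mature[2]; s5 <- star[1]; s3 <- star[2]
  if (is.na(p[m5])) {
    return(list(pass = FALSE, reason = "mature 5' end unpaired"))
  }
  if (is.na(p[s5])) {
    return(list(pass = FALSE, reason = "star 5' end unpaired"))
  }
  ok1 <- p[m5] == s3 - 2L
  ok2 <- p[s5] == m3 - 2L
  if (ok1 && ok2) list(pass = TRUE, reason = "2-nt 3' overhangs on both strands")
  else list(pass = FALSE,
            reason = sprintf("overhang geometry violated (pair(m5)=%d vs star3-2=%d; pair(s5)=%d vs mature3-2=%d)",
                             p[m5], s3 - 2L, p[s5], m3 - 2L))
}

#' Fraction of mature bases paired with the star interval
#'
#' The duplex criterion requires the mature to pair with the star on the
#' precursor stem; this measures how much of the mature actually does.
#'
#' @inheritParams duplex_overhang_check
#' @return fraction in `[0, 1]`.
#' @export
duplex_pairing_fraction <- function(fold, mature, star) {
  p <- fold$pairing
  idx <- mature[1]:mature[2]
  partners <- p[idx]
  mean(!is.na(partners) & partners >= star[1] & partners <= star[2])
}
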