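# Pairwise alignment wrappers around Biostrings::pairwiseAlignment, plus
# substitution-type bookkeeping used by both the dating and family modules.
# Scoring convention: a gap of length L costs gap_open + L * gap_extend.

default_scoring <- function() {
  list(match = 2, mismatch = -2, gap_open = 6, gap_extend = 1)
}

sub_matrix <- function(scoring) {
  Biostrings::nucleotideSubstitutionMatrix(
    match = scoring$match, mismatch = scoring$mismatch, baseOnly = TRUE)
}

#' Globally align the two LTRs of an element
#'
#' Needleman-Wunsch global alignment with affine gaps (defaults: match +2,
#' mismatch -2, gap open -6, gap extend -1 per residue). Gap columns and
#' columns containing ambiguous bases are excluded from the compared-site
#' count; the remainder is partitioned into matches, transitions and
#' transversions for downstream Kimura-style distances.
#'
#' @param ltr5_seq,ltr3_seq the two LTR sequences (>= 1 nt; dating expects
#'   >= 50).
#' @param scoring list(match, mismatch, gap_open, gap_extend).
#' @return list of class `pair_alignment`: `aligned_a`, `aligned_b`,
#'   `n_sites`, `matches`, `transitions`, `transversions`, `identity`,
#'   `score`.
#' @export
align_ltr_pair <- function(ltr5_seq, ltr3_seq, scoring = default_scoring()) {
  if (!nzchar(ltr5_seq) || !nzchar(ltr3_seq)) stop("empty LTR sequence")
  aln <- Biostrings::pairwiseAlignment(
    ltr5_seq, ltr3_seq, type = "global",
    substitutionMatrix = sub_matrix(scoring),
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
  a <- as.character(Biostrings::pattern(aln))
  b <- as.character(Biostrings::subject(aln))
  st <- alignment_stats(a, b)
  st$score <- Biostrings::score(aln)
  structure(st, class = "pair_alignment")
}

# substitution-type counts over ungapped, unambiguous columns
alignment_stats <- function(aligned_a, aligned_b) {
  ca <- s2c(aligned_a); cb <- s2c(aligned_b)
  stopifnot(length(ca) == length(cb))
  ok <- ca %in% DNA_BASES & cb %in% DNA_BASES
  ca <- ca[ok]; cb <- cb[ok]
  n <- length(ca)
  match <- sum(ca == cb)
  diff <- ca != cb
  ts <- sum(diff & is_transition_pair(ca, cb))
  tv <- sum(diff) - ts
  list(aligned_a = aligned_a, aligned_b = aligned_b,
       n_sites = n, matches = match,
       transitions = ts, transversions = tv,
       identity = if (n > 0) match / n else NA_real_)
}

# Local alignment returning aligned region coordinates (1-based within the
# input sequences), used by the 80-80-80 rule and LTR-pair detection.
align_local <- function(a, b, scoring = default_scoring()) {
  aln <- Biostrings::pairwiseAlignment(
    a, b, type = "local",
    substitutionMatrix = sub_matrix(scoring),
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
  pa <- as.character(Biostrings::pattern(aln))
  pb <- as.character(Biostrings::subject(aln))
  st <- alignment_stats(pa, pb)
  st$n_columns <- nchar(pa)
  st$score <- Biostrings::score(aln)
  st$start_a <- Biostrings::start(Biostrings::pattern(aln))
  st$end_a <- Biostrings::end(Biostrings::pattern(aln))
  st$start_b <- Biostrings::start(Biostrings::subject(aln))
  st$end_b <- Biostrings::end(Biostrings::subject(aln))
  # identity over all aligned columns (gaps count as mismatch), the usual
  # convention for the 80-80-80 rule
  st$identity_columns <- if (st$n_columns > 0) st$matches / st$n_columns else NA_real_
  st
}
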