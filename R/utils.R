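`%||%` <- function(a, b) if (is.null(a)) b else a

DNA_BASES <- c("A", "C", "G", "T")

#' Random DNA string
#'
#' @param n length in nucleotides.
#' @param gc target GC fraction (A/T and G/C split evenly).
#' @return a single character string over A, C, G, T.
#' @export
random_dna <- function(n, gc = 0.5) {
  stopifnot(n >= 0, gc >= 0, gc <= 1)
  if (n == 0) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

#' Reverse complement of a DNA string
#' @param x DNA character string.
#' @return the reverse complement string.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

s2c <- function(x) strsplit(x, "", fixed = TRUE)[[1]]
c2s <- function(x) paste(x, collapse = "")

#' GC fraction over concatenated sequences, ignoring N
#' @param seqs character vector of DNA strings.
#' @return GC fraction in [0, 1].
#' @export
gc_fraction <- function(seqs) {
  af <- Biostrings::alphabetFrequency(Biostrings::DNAStringSet(seqs))
  tot <- colSums(af[, DNA_BASES, drop = FALSE])
  sum(tot[c("G", "C")]) / sum(tot)
}

n_fraction <- function(seq) {
  af <- Biostrings::alphabetFrequency(Biostrings::DNAString(seq))
  af[["N"]] / nchar(seq)
}

# transition partner for each base
TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")
TRANSVERSION <- list(A = c("C", "T"), G = c("C", "T"),
                     C = c("A", "G"), T = c("A", "G"))

is_transition_pair <- function(a, b) {
  (a %in% c("A", "G") & b %in% c("A", "G")) |
    (a %in% c("C", "T") & b %in% c("C", "T"))
}
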