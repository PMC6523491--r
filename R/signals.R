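# Structural signals of LTR elements: LTR-pair detection, TG...CA boundary
# flags, PBS detection against a tRNA database with usage statistics, PPT
# and TSD detection, and boundary position matrices (base counts plus
# information content, a text replacement for sequence logos).

#' Detect the LTR pair of an unannotated element sequence
#'
#' Locally aligns a 5'-terminal window against a 3'-terminal window and
#' accepts the best hit as the LTR pair when it is long and similar enough.
#' Candidates starting TG and ending CA are preferred on score ties.
#'
#' @param sequence element DNA string (>= 2 * `min_ltr_len`).
#' @param min_ltr_len minimum aligned LTR length (default 100 bp).
#' @param min_identity minimum alignment identity (default 0.80).
#' @param scoring alignment scoring.
#' @return list(ltr5, ltr3) of 0-based half-open intervals, or `NULL`.
#' @export
detect_ltr_pair <- function(sequence, min_ltr_len = 100L, min_identity = 0.80,
                            scoring = default_scoring()) {
  n <- nchar(sequence)
  if (n < 2 * min_ltr_len) return(NULL)
  half <- n %/% 2L
  head_seq <- substring(sequence, 1L, half)
  tail_seq <- substring(sequence, half + 1L, n)
  st <- align_local(head_seq, tail_seq, scoring)
  if (st$n_columns < min_ltr_len) return(NULL)
  if (is.na(st$identity_columns) || st$identity_columns < min_identity) return(NULL)
  ltr5 <- c(st$start_a - 1L, st$end_a)
  ltr3 <- c(half + st$start_b - 1L, half + st$end_b)
  list(ltr5 = as.integer(ltr5), ltr3 = as.integer(ltr3),
       identity = st$identity_columns, span = st$n_columns)
}

#' TG...CA boundary flags
#'
#' @param element an `ltr_element` with LTR coordinates set.
#' @return list(starts_TG, ends_CA) logical flags from the first 2 nt of
#'   the 5'LTR and the last 2 nt of the 3'LTR.
#' @export
check_boundaries <- function(element) {
  s5 <- substring(element$seq, element$ltr5[1] + 1L, element$ltr5[1] + 2L)
  e3 <- substring(element$seq, element$ltr3[2] - 1L, element$ltr3[2])
  list(starts_TG = identical(s5, "TG"), ends_CA = identical(e3, "CA"))
}

#' Find the primer-binding site of an element
#'
#' Searches the window immediately 3' of the 5'LTR for the best match to
#' the reverse complement of each tRNA's 3'-terminal segment (CCA appended
#' when the gene sequence lacks it). Best call = longest match, then fewest
#' mismatches, then smallest offset; tRNAs sharing an identical acceptor
#' end are reported together by amino acid.
#'
#' @param element an `ltr_element`.
#' @param trna_db data.frame from [read_trna_db()] / [make_trna_db()].
#' @param window search window size 3' of the 5'LTR.
#' @param max_match,min_match probe lengths tried (3'-terminal nt of the
#'   tRNA), longest first.
#' @param max_mismatch maximum mismatches tolerated.
#' @return list (class `pbs_call`): `element_id`, `trna_id`, `amino_acid`,
#'   `amino_acids` (all candidates on acceptor-end ties), `match_length`,
#'   `mismatches`, `offset` (0-based from the 5'LTR end); or `NULL`.
#' @export
find_pbs <- function(element, trna_db, window = 30L, max_match = 12L,
                     min_match = 10L, max_mismatch = 1L) {
  if (nrow(trna_db) == 0) stop("empty tRNA database")
  win <- substring(element$seq, element$ltr5[2] + 1L,
                   min(element$ltr5[2] + window, nchar(element$seq)))
  wc <- s2c(win)
  best <- NULL
  for (m in seq.int(max_match, min_match)) {
    probes <- vapply(trna_db$sequence,
                     function(s) revcomp(substring(trna_acceptor_end(s, m), 1L, m)),
                     "", USE.NAMES = FALSE)
    for (ti in seq_len(nrow(trna_db))) {
      pc <- s2c(probes[ti])
      if (length(wc) < m) next
      for (off in 0:(length(wc) - m)) {
        mm <- sum(pc != wc[(off + 1):(off + m)])
        if (mm > max_mismatch) next
        cand <- list(element_id = element$element_id,
                     trna_id = trna_db$trna_id[ti],
                     amino_acid = trna_db$amino_acid[ti],
                     amino_acids = trna_db$amino_acid[ti],
                     match_length = m, mismatches = mm, offset = off)
        if (is.null(best)) { best <- cand; next }
        if (cand$match_length > best$match_length ||
            (cand$match_length == best$match_length && cand$mismatches < best$mismatches) ||
            (cand$match_length == best$match_length && cand$mismatches == best$mismatches &&
             cand$offset < best$offset)) {
          best <- cand
        } else if (cand$match_length == best$match_length &&
                   cand$mismatches == best$mismatches &&
                   cand$offset == best$offset &&
                   !cand$amino_acid %in% best$amino_acids) {
          # distinct tRNAs with identical acceptor ends: ambiguous call
          best$amino_acids <- c(best$amino_acids, cand$amino_acid)
        }
      }
    }
    if (!is.null(best)) break  # longest match wins outright
  }
  if (!is.null(best)) class(best) <- "pbs_call"
  best
}

#' tRNA usage table from PBS calls
#'
#' @param pbs_calls list of `pbs_call` (NULL entries allowed, counted as
#'   unassigned).
#' @param superfamilies character vector parallel to `pbs_calls`.
#' @return data.frame: superfamily, amino_acid, count, proportion
#'   (proportions over assigned, unambiguous elements sum to 1 within each
#'   superfamily); unassigned/ambiguous tracked under `"none"` /
#'   `"ambiguous"` with NA proportion.
#' @export
trna_usage <- function(pbs_calls, superfamilies) {
  if (length(pbs_calls) == 0) stop("no PBS calls")
  stopifnot(length(pbs_calls) == length(superfamilies))
  aa <- vapply(pbs_calls, function(p) {
    if (is.null(p)) "none"
    else if (length(p$amino_acids) > 1) "ambiguous"
    else p$amino_acid
  }, "")
  out <- list()
  for (s in unique(superfamilies)) {
    a <- aa[superfamilies == s]
    tab <- table(a)
    assigned <- sum(tab[!names(tab) %in% c("none", "ambiguous")])
    df <- data.frame(superfamily = s, amino_acid = names(tab),
                     count = as.integer(tab), stringsAsFactors = FALSE)
    df$proportion <- ifelse(df$amino_acid %in% c("none", "ambiguous"),
                            NA_real_, df$count / assigned)
    out[[s]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$superfamily, -res$count), , drop = FALSE]
}

#' Find the polypurine tract
#'
#' Longest run of >= 90% purines (A/G) of at least `min_len` nt ending
#' within `max_offset` of the 3'LTR start.
#'
#' @param element an `ltr_element`.
#' @param min_len minimum PPT length.
#' @param max_offset how far 5' of the 3'LTR the tract may end.
#' @return 0-based half-open interval `c(start, end)` or `NULL`.
#' @export
find_ppt <- function(element, min_len = 10L, max_offset = 30L) {
  lo <- max(element$ltr5[2], element$ltr3[1] - max_offset - 50L)
  region <- substring(element$seq, lo + 1L, element$ltr3[1])
  rc <- s2c(region)
  pur <- rc %in% c("A", "G")
  n <- length(pur)
  best <- NULL
  # scan candidate runs ending within max_offset of the 3'LTR start
  for (e in seq.int(n, max(min_len, n - max_offset))) {
    for (s in seq.int(1L, e - min_len + 1L)) {
      len <- e - s + 1L
      if (!is.null(best) && len <= best[2] - best[1]) next
      if (mean(pur[s:e]) >= 0.9) best <- c(lo + s - 1L, lo + e)
    }
  }
  if (is.null(best)) return(NULL)
  as.integer(best)
}

#' Find the target-site duplication flanking an element locus
#'
#' @param genome genome DNA string.
#' @param locus 1-based closed `c(start, end)` of the element in the
#'   genome.
#' @param len_range inclusive range of TSD lengths to test.
#' @return the longest exactly duplicated flanking string, or `NULL` (with
#'   a warning when the element abuts a contig edge).
#' @export
find_tsd <- function(genome, locus, len_range = c(4L, 6L)) {
  s <- locus[1]; e <- locus[2]
  n <- nchar(genome)
  if (s - len_range[1] < 1 || e + len_range[1] > n) {
    warning("element at contig edge; TSD not assessable")
    return(NULL)
  }
  for (k in seq.int(min(len_range[2], s - 1L, n - e), len_range[1])) {
    left <- substring(genome, s - k, s - 1L)
    right <- substring(genome, e + 1L, e + k)
    if (identical(left, right)) return(left)
  }
  NULL
}

#' Boundary position matrices around the 5'LTR start
#'
#' Extracts `flank` bp upstream and downstream of each element's 5'
#' boundary in the genome and tabulates per-position base counts with
#' information content (2 - Shannon entropy, log2; no small-sample
#' correction by default), ready for any logo renderer.
#'
#' @param loci data.frame(element_id, start, end) 1-based closed genome
#'   coordinates of the elements (5' boundary = `start`).
#' @param genome genome DNA string.
#' @param flank flank width in bp.
#' @return list with `upstream` and `downstream`, each a list of `counts`
#'   (4 x flank matrix) and `ic` (bits per position).
#' @export
boundary_matrix <- function(loci, genome, flank = 30L) {
  n <- nchar(genome)
  ok <- loci$start - flank >= 1 & loci$start + flank - 1 <= n
  loci <- loci[ok, , drop = FALSE]
  if (nrow(loci) == 0) stop("no element with full flanks")
  up <- substring(genome, loci$start - flank, loci$start - 1L)
  down <- substring(genome, loci$start, loci$start + flank - 1L)
  pm <- function(seqs) {
    m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
    counts <- vapply(seq_len(ncol(m)), function(j) {
      tabulate(factor(m[, j], levels = DNA_BASES), nbins = 4L)
    }, integer(4))
    rownames(counts) <- DNA_BASES
    freq <- counts / colSums(counts)[col(counts)]
    ent <- apply(freq, 2, function(p) {
      p <- p[p > 0]; -sum(p * log2(p))
    })
    list(counts = counts, ic = 2 - ent)
  }
  list(upstream = pm(up), downstream = pm(down), n = nrow(loci))
}

#' Write a position matrix as TSV
#' @param pm one component (`upstream`/`downstream`) of [boundary_matrix()].
#' @param path output TSV.
#' @export
write_position_matrix <- function(pm, path) {
  df <- as.data.frame(t(pm$counts))
  df$position <- seq_len(nrow(df))
  df$ic_bits <- pm$ic
  write.table(df[, c("position", DNA_BASES, "ic_bits")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
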