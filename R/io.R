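# Domain types and readers/writers.
#
# Internal coordinate convention: 0-based half-open intervals, stored as
# integer c(start, end). External annotation tables are 1-based inclusive
# (GFF3 dialect) unless the reader is told otherwise; BED stays 0-based
# half-open. Genome-scale features use GRanges (1-based closed), the
# Bioconductor standard.

#' Construct an LTR element
#'
#' The unit record every pipeline stage consumes: a full-length element
#' sequence with 5'/3' LTR coordinates and optional PBS/PPT/RT annotations.
#' All within-element coordinates are 0-based half-open.
#'
#' @param element_id nonempty identifier; `RLC_`/`RLG_` prefixes imply the
#'   Copia/Gypsy superfamily.
#' @param seq element DNA string (uppercase A/C/G/T/N).
#' @param ltr5,ltr3 integer `c(start, end)` of the two LTRs, 0-based half-open.
#' @param superfamily one of `"COPIA"`, `"GYPSY"`, `"UNKNOWN"`; inferred
#'   from the id prefix when `NULL`.
#' @param family_id optional family label.
#' @param rt optional RT-domain interval `c(start, end)` within the element.
#' @param pbs optional list(offset, trna_id).
#' @param ppt optional interval.
#' @param tsd optional duplicated target-site string.
#' @param source optional genome locus `list(seq_id, start, end, strand)`.
#' @return an object of class `ltr_element`.
#' @export
ltr_element <- function(element_id, seq, ltr5, ltr3, superfamily = NULL,
                        family_id = NA_character_, rt = NULL, pbs = NULL,
                        ppt = NULL, tsd = NULL, source = NULL) {
  seq <- toupper(seq)
  el <- structure(list(
    element_id = as.character(element_id),
    superfamily = superfamily %||% superfamily_from_id(element_id),
    family_id = family_id,
    seq = seq,
    ltr5 = as.integer(ltr5),
    ltr3 = as.integer(ltr3),
    rt = if (!is.null(rt)) as.integer(rt) else NULL,
    pbs = pbs, ppt = ppt, tsd = tsd, source = source
  ), class = "ltr_element")
  el
}

#' @export
print.ltr_element <- function(x, ...) {
  cat(sprintf("<ltr_element> %s [%s] %d bp; 5'LTR [%d,%d) 3'LTR [%d,%d)%s\n",
              x$element_id, x$superfamily, nchar(x$seq),
              x$ltr5[1], x$ltr5[2], x$ltr3[1], x$ltr3[2],
              if (!is.null(x$rt)) sprintf("; RT [%d,%d)", x$rt[1], x$rt[2]) else ""))
  invisible(x)
}

superfamily_from_id <- function(id) {
  if (startsWith(id, "RLC_")) "COPIA"
  else if (startsWith(id, "RLG_")) "GYPSY"
  else "UNKNOWN"
}

#' Validate an LTR element
#'
#' @param el an `ltr_element`.
#' @param max_n_fraction elements with a larger fraction of N are rejected.
#' @return character vector of violated invariants (empty when valid).
#' @export
validate_element <- function(el, max_n_fraction = 0.10) {
  bad <- character(0)
  n <- nchar(el$seq)
  if (!nzchar(el$element_id)) bad <- c(bad, "empty element_id")
  if (n < 1) bad <- c(bad, "empty sequence")
  if (grepl("[^ACGTN]", el$seq)) bad <- c(bad, "non-ACGTN residues")
  ok_iv <- function(iv) length(iv) == 2 && !anyNA(iv) && iv[1] >= 0 && iv[1] < iv[2] && iv[2] <= n
  if (!ok_iv(el$ltr5)) bad <- c(bad, "ltr5 interval out of bounds")
  if (!ok_iv(el$ltr3)) bad <- c(bad, "ltr3 interval out of bounds")
  if (length(bad) == 0 && el$ltr5[2] > el$ltr3[1])
    bad <- c(bad, "5'LTR overlaps or follows 3'LTR")
  if (!is.null(el$rt) && !ok_iv(el$rt)) bad <- c(bad, "rt interval out of bounds")
  if (n >= 1 && n_fraction(el$seq) > max_n_fraction)
    bad <- c(bad, sprintf("N fraction > %g", max_n_fraction))
  bad
}

element_seq <- function(el, iv) substring(el$seq, iv[1] + 1L, iv[2])
ltr5_seq <- function(el) element_seq(el, el$ltr5)
ltr3_seq <- function(el) element_seq(el, el$ltr3)
rt_seq <- function(el) if (is.null(el$rt)) NULL else element_seq(el, el$rt)

#' Read elements from FASTA plus an annotation table
#'
#' The table is tab-separated with a header and columns `element_id`,
#' `ltr5_start`, `ltr5_end`, `ltr3_start`, `ltr3_end` and optionally
#' `rt_start`, `rt_end`, `superfamily`, `family_id`. Coordinates are
#' 1-based inclusive by default (`coords = "1-based"`); pass
#' `coords = "0-based"` for 0-based half-open input.
#'
#' Elements violating invariants (or exceeding the N-fraction cutoff) are
#' reported via a warning and skipped; an id present in the table but not
#' the FASTA (or vice versa with `strict = TRUE`) is a hard error.
#'
#' @param fasta_path element FASTA.
#' @param annotation_path annotation TSV.
#' @param coords coordinate convention of the table.
#' @param max_n_fraction see [validate_element()].
#' @param strict error when FASTA contains ids absent from the table.
#' @return list of `ltr_element` objects.
#' @export
read_elements <- function(fasta_path, annotation_path,
                          coords = c("1-based", "0-based"),
                          max_n_fraction = 0.10, strict = FALSE) {
  coords <- match.arg(coords)
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  ann <- read.delim(annotation_path, stringsAsFactors = FALSE)
  req <- c("element_id", "ltr5_start", "ltr5_end", "ltr3_start", "ltr3_end")
  if (!all(req %in% names(ann)))
    stop("annotation table must contain columns: ", paste(req, collapse = ", "))
  for (col in setdiff(req, "element_id")) {
    if (!is.numeric(ann[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(ann[[col]]))))[1]
      stop(sprintf("malformed coordinate in column '%s' at table line %d",
                   col, bad + 1L))
    }
  }
  missing_ids <- setdiff(ann$element_id, names(seqs))
  if (length(missing_ids))
    stop("annotation ids missing from FASTA: ",
         paste(head(missing_ids, 5), collapse = ", "))
  if (strict) {
    extra <- setdiff(names(seqs), ann$element_id)
    if (length(extra))
      stop("FASTA ids missing from annotation: ",
           paste(head(extra, 5), collapse = ", "))
  }
  off <- if (coords == "1-based") 1L else 0L  # start shift to 0-based
  out <- list()
  skipped <- character(0)
  for (i in seq_len(nrow(ann))) {
    row <- ann[i, ]
    to_iv <- function(s, e) {
      if (coords == "1-based") c(as.integer(s) - 1L, as.integer(e))
      else c(as.integer(s), as.integer(e))
    }
    rt <- NULL
    if (all(c("rt_start", "rt_end") %in% names(ann)) &&
        !is.na(row$rt_start) && !is.na(row$rt_end))
      rt <- to_iv(row$rt_start, row$rt_end)
    el <- ltr_element(
      element_id = row$element_id,
      seq = as.character(seqs[[row$element_id]]),
      ltr5 = to_iv(row$ltr5_start, row$ltr5_end),
      ltr3 = to_iv(row$ltr3_start, row$ltr3_end),
      superfamily = if ("superfamily" %in% names(ann) && nzchar(row$superfamily %||% ""))
        row$superfamily else NULL,
      family_id = if ("family_id" %in% names(ann))
        as.character(row$family_id) else NA_character_,
      rt = rt
    )
    bad <- validate_element(el, max_n_fraction)
    if (length(bad)) {
      skipped <- c(skipped, sprintf("%s (%s)", row$element_id, bad[1]))
    } else {
      out[[row$element_id]] <- el
    }
  }
  if (length(skipped))
    warning("skipped ", length(skipped), " element(s) failing invariants: ",
            paste(head(skipped, 10), collapse = "; "))
  out
}

#' Write elements to FASTA plus annotation table
#'
#' Inverse of [read_elements()]: coordinates are emitted 1-based inclusive
#' in canonical column order, so read/write round-trips are byte-identical
#' on canonical tables.
#'
#' @param elements list of `ltr_element`.
#' @param fasta_path,annotation_path output paths.
#' @return invisibly, the annotation data.frame written.
#' @export
write_elements <- function(elements, fasta_path, annotation_path) {
  seqs <- Biostrings::DNAStringSet(vapply(elements, `[[`, "", "seq"))
  names(seqs) <- vapply(elements, `[[`, "", "element_id")
  Biostrings::writeXStringSet(seqs, fasta_path, width = 70L)
  ann <- data.frame(
    element_id = names(seqs),
    superfamily = vapply(elements, `[[`, "", "superfamily"),
    family_id = vapply(elements,
                       function(e) as.character(e$family_id %||% NA), ""),
    ltr5_start = vapply(elements, function(e) e$ltr5[1] + 1L, 1L),
    ltr5_end = vapply(elements, function(e) e$ltr5[2], 1L),
    ltr3_start = vapply(elements, function(e) e$ltr3[1] + 1L, 1L),
    ltr3_end = vapply(elements, function(e) e$ltr3[2], 1L),
    rt_start = vapply(elements, function(e) if (is.null(e$rt)) NA_integer_ else e$rt[1] + 1L, 1L),
    rt_end = vapply(elements, function(e) if (is.null(e$rt)) NA_integer_ else e$rt[2], 1L),
    stringsAsFactors = FALSE
  )
  rownames(ann) <- NULL
  write.table(ann, annotation_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(ann)
}

#' Per-superfamily summary of an element set
#'
#' Reports, for each superfamily, the element and family counts and the
#' mean (min-max) of full length and LTR lengths, plus GC content computed
#' over the concatenated element sequences (N ignored), rounded to 2
#' decimals.
#'
#' @param elements list of `ltr_element` (at least one).
#' @return data.frame with one row per superfamily.
#' @export
summarize_elements <- function(elements) {
  if (length(elements) == 0) stop("no elements to summarize")
  sf <- vapply(elements, `[[`, "", "superfamily")
  out <- lapply(split(elements, sf), function(els) {
    len <- vapply(els, function(e) nchar(e$seq), 1)
    l5 <- vapply(els, function(e) diff(e$ltr5), 1L)
    l3 <- vapply(els, function(e) diff(e$ltr3), 1L)
    fam <- vapply(els, function(e) e$family_id %||% NA_character_, "")
    data.frame(
      superfamily = els[[1]]$superfamily,
      n_elements = length(els),
      n_families = length(unique(fam[!is.na(fam)])),
      full_length_mean = round(mean(len)),
      full_length_min = min(len), full_length_max = max(len),
      ltr5_mean = round(mean(l5)), ltr5_min = min(l5), ltr5_max = max(l5),
      ltr3_mean = round(mean(l3)), ltr3_min = min(l3), ltr3_max = max(l3),
      gc = round(gc_fraction(vapply(els, `[[`, "", "seq")), 2),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read a tRNA database
#'
#' Accepts either a FASTA whose headers are `id amino_acid anticodon`
#' (whitespace-separated) or a TSV with columns `trna_id`, `amino_acid`,
#' `anticodon`, `sequence`.
#'
#' @param path input file.
#' @return data.frame(trna_id, amino_acid, anticodon, sequence).
#' @export
read_trna_db <- function(path) {
  first <- readLines(path, n = 1)
  if (startsWith(first, ">")) {
    seqs <- Biostrings::readDNAStringSet(path)
    parts <- strsplit(names(seqs), "\\s+")
    db <- data.frame(
      trna_id = vapply(parts, `[[`, "", 1),
      amino_acid = vapply(parts, function(p) if (length(p) >= 2) p[2] else NA_character_, ""),
      anticodon = vapply(parts, function(p) if (length(p) >= 3) p[3] else NA_character_, ""),
      sequence = as.character(seqs),
      stringsAsFactors = FALSE
    )
  } else {
    db <- read.delim(path, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("trna_id", "amino_acid", "anticodon", "sequence") %in% names(db)))
  if (nrow(db) == 0) stop("empty tRNA database")
  db$sequence <- toupper(db$sequence)
  if (any(nchar(db$sequence) < 20)) stop("tRNA sequences must be >= 20 nt")
  db
}

#' Write a tRNA database as FASTA
#' @param db data.frame as returned by [read_trna_db()].
#' @param path output FASTA path.
#' @export
write_trna_db <- function(db, path) {
  seqs <- Biostrings::DNAStringSet(db$sequence)
  names(seqs) <- paste(db$trna_id, db$amino_acid, db$anticodon)
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}
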