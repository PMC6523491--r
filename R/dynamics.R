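# Deletion dynamics and genomic context.
#
# Under a constant per-element deletion rate, the ages of surviving
# full-length elements are exponentially distributed and the half-life
# ln(2)/lambda summarizes the removal process. The fit is descriptive: a
# clearly non-exponential age distribution (flagged by the KS statistic)
# means the constant-rate model does not hold and the half-life is only a
# bound.

#' Fit an exponential deletion model to insertion ages
#'
#' Maximum-likelihood rate lambda = 1/mean(age), half-life ln(2)/lambda,
#' and a one-sample Kolmogorov-Smirnov statistic against Exp(lambda). The
#' KS p-value is approximate (anticonservative) because lambda is estimated
#' from the same data; use the statistic for comparisons between
#' distributions.
#'
#' @param ages_MY nonnegative ages in MY (n >= 10).
#' @return list (class `decay_fit`): `lambda_per_MY`, `half_life_MY`, `n`,
#'   `log_likelihood`, `ks_statistic`, `ks_pvalue`.
#' @export
fit_exponential <- function(ages_MY) {
  ages <- ages_MY[!is.na(ages_MY)]
  if (length(ages) < 10) stop("need at least 10 ages")
  if (any(ages < 0)) stop("ages must be nonnegative")
  m <- mean(ages)
  if (m <= 0) stop("mean age is zero; cannot fit an exponential")
  lambda <- 1 / m
  ks <- suppressWarnings(ks.test(ages, "pexp", rate = lambda))
  structure(list(
    lambda_per_MY = lambda,
    half_life_MY = log(2) / lambda,
    n = length(ages),
    log_likelihood = sum(dexp(ages, rate = lambda, log = TRUE)),
    ks_statistic = unname(ks$statistic),
    ks_pvalue = ks$p.value
  ), class = "decay_fit")
}

#' Classify the genomic context of element insertions
#'
#' Precedence exon > intron > promoter > intergenic. Exon/intron calls use
#' the element midpoint within a gene span (so an element spanning a
#' junction gets exactly one call); the promoter call, by default, fires
#' when the element span overlaps the window upstream of a gene's
#' transcription start on the gene strand (`mode = "midpoint"` restricts
#' it to the midpoint, which misses insertions longer than the window).
#' Intron calls report the intron ordinal in transcription order.
#'
#' @param loci data.frame(element_id, seq_id, start, end), 1-based closed.
#' @param gm a `gene_models` object.
#' @param promoter_window bp upstream of the TSS regarded as promoter.
#' @param mode `"overlap"` (default) or `"midpoint"` for the promoter rule.
#' @param known_contigs optional contig names; loci on other contigs error.
#' @return data.frame: element_id, context, gene_id, intron_ordinal.
#' @export
genomic_context <- function(loci, gm, promoter_window = 2000L,
                            mode = c("overlap", "midpoint"),
                            known_contigs = NULL) {
  mode <- match.arg(mode)
  if (!is.null(known_contigs) && any(!loci$seq_id %in% known_contigs))
    stop("element on unknown contig: ",
         paste(unique(setdiff(loci$seq_id, known_contigs)), collapse = ", "))
  genes <- gm$genes
  rows <- lapply(seq_len(nrow(loci)), function(i) {
    el <- loci[i, ]
    mid <- (el$start + el$end) %/% 2L
    call <- list(context = "intergenic", gene_id = NA_character_,
                 intron_ordinal = NA_integer_)
    g_here <- genes[genes$seq_id == el$seq_id & genes$start <= mid &
                      genes$end >= mid, ]
    if (nrow(g_here) > 0) {
      g <- g_here[1, ]
      ex <- gm$exons[gm$exons$gene_id == g$gene_id, ]
      in_exon <- any(ex$start <= mid & ex$end >= mid)
      if (in_exon) {
        call <- list(context = "exon", gene_id = g$gene_id,
                     intron_ordinal = NA_integer_)
      } else {
        intr <- gene_introns(gm, g$gene_id)
        hit <- which(intr$start <= mid & intr$end >= mid)
        call <- list(context = "intron", gene_id = g$gene_id,
                     intron_ordinal = if (length(hit)) intr$ordinal[hit[1]] else NA_integer_)
      }
    } else {
      # promoter: window upstream of the gene-strand 5' end
      cand <- genes[genes$seq_id == el$seq_id, , drop = FALSE]
      if (nrow(cand) > 0) {
        pstart <- ifelse(cand$strand == "+", cand$start - promoter_window, cand$end + 1L)
        pend <- ifelse(cand$strand == "+", cand$start - 1L, cand$end + promoter_window)
        hit <- if (mode == "overlap") {
          which(el$start <= pend & el$end >= pstart)
        } else {
          which(pstart <= mid & pend >= mid)
        }
        if (length(hit)) {
          # nearest TSS on ties
          tss <- ifelse(cand$strand == "+", cand$start, cand$end)
          h <- hit[which.min(abs(tss[hit] - mid))]
          call <- list(context = "promoter", gene_id = cand$gene_id[h],
                       intron_ordinal = NA_integer_)
        }
      }
    }
    data.frame(element_id = el$element_id, context = call$context,
               gene_id = call$gene_id, intron_ordinal = call$intron_ordinal,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
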