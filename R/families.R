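# Family classification under the 80-80-80 rule: two elements belong to
# the same family when they share >= 80% identity over an aligned region of
# >= 80 bp covering >= 80% of the (by default) shorter sequence. Families
# are the single-linkage transitive closure of that relation, computed per
# superfamily, and named RLC_k / RLG_k by descending size.

#' Pairwise 80-80-80 comparison
#'
#' Best local alignment between two element sequences with identity taken
#' over all aligned columns (gaps count against identity) and coverage as
#' the aligned span over each sequence length.
#'
#' @param seq_a,seq_b element sequences (>= 80 bp to be classifiable).
#' @param scoring alignment scoring (see [align_ltr_pair()]).
#' @param min_identity,min_span,min_coverage the three 80s of the rule.
#' @param coverage_of denominator convention: coverage of the `"shorter"`
#'   sequence (the common reading of the rule) or of `"both"`.
#' @return list: `identity`, `span`, `coverage_a`, `coverage_b`, `linked`.
#' @export
pairwise_8080 <- function(seq_a, seq_b, scoring = default_scoring(),
                          min_identity = 0.80, min_span = 80L,
                          min_coverage = 0.80,
                          coverage_of = c("shorter", "both")) {
  coverage_of <- match.arg(coverage_of)
  if (nchar(seq_a) < 80 || nchar(seq_b) < 80)
    stop("sequences shorter than 80 bp are not classifiable under the 80-80-80 rule")
  st <- align_local(seq_a, seq_b, scoring)
  cov_a <- (st$end_a - st$start_a + 1) / nchar(seq_a)
  cov_b <- (st$end_b - st$start_b + 1) / nchar(seq_b)
  cov <- if (coverage_of == "shorter") {
    if (nchar(seq_a) <= nchar(seq_b)) cov_a else cov_b
  } else min(cov_a, cov_b)
  linked <- !is.na(st$identity_columns) &&
    st$identity_columns >= min_identity &&
    st$n_columns >= min_span && cov >= min_coverage
  list(identity = st$identity_columns, span = st$n_columns,
       coverage_a = cov_a, coverage_b = cov_b, linked = linked)
}

# count of shared distinct k-mers between two sequences
shared_kmers <- function(a, b, k = 13L) {
  ka <- unique(substring(a, seq_len(nchar(a) - k + 1L),
                         seq_len(nchar(a) - k + 1L) + k - 1L))
  kb <- unique(substring(b, seq_len(nchar(b) - k + 1L),
                         seq_len(nchar(b) - k + 1L) + k - 1L))
  length(intersect(ka, kb))
}

#' Cluster elements into families (80-80-80 rule)
#'
#' Single-linkage transitive closure of the pairwise linkage relation,
#' computed separately within each superfamily. Families are named
#' `RLC_k`/`RLG_k` by descending member count (ties broken by the
#' lexicographically smallest member id). A shared-13-mer prefilter prunes
#' hopeless pairs; disable it (`prefilter = FALSE`) for exhaustive
#' all-pairs alignment.
#'
#' @param elements list of `ltr_element`.
#' @param linkage `"single"` (standard) or `"complete"`.
#' @param prefilter skip pairs sharing no 13-mer.
#' @param ... thresholds passed to [pairwise_8080()].
#' @return data.frame: element_id, superfamily, family_id, member_no; with
#'   a `families` attribute (list of member-id vectors named by family).
#' @export
cluster_families <- function(elements, linkage = c("single", "complete"),
                             prefilter = TRUE, ...) {
  linkage <- match.arg(linkage)
  sf <- vapply(elements, `[[`, "", "superfamily")
  ids <- vapply(elements, `[[`, "", "element_id")
  out <- list()
  fam_list <- list()
  for (s in unique(sf)) {
    idx <- which(sf == s)
    n <- length(idx)
    seqs <- vapply(elements[idx], `[[`, "", "seq")
    # union-find over linked pairs
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    adj <- matrix(FALSE, n, n)
    if (n > 1) {
      for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
        if (prefilter && shared_kmers(seqs[i], seqs[j]) < 1L) next
        pr <- pairwise_8080(seqs[i], seqs[j], ...)
        if (pr$linked) {
          adj[i, j] <- adj[j, i] <- TRUE
          if (linkage == "single") {
            ri <- find(i); rj <- find(j)
            if (ri != rj) parent[ri] <- rj
          }
        }
      }
    }
    comp <- if (linkage == "single") {
      vapply(seq_len(n), find, 1L)
    } else {
      complete_linkage_components(adj)
    }
    groups <- split(seq_len(n), comp)
    # order families: descending size, then smallest member id
    key <- vapply(groups, function(g) min(ids[idx[g]]), "")
    ord <- order(-vapply(groups, length, 1L), key)
    prefix <- switch(s, COPIA = "RLC_", GYPSY = "RLG_", "RLX_")
    for (k in seq_along(ord)) {
      g <- groups[[ord[k]]]
      fam <- paste0(prefix, k)
      member_ids <- sort(ids[idx[g]])
      fam_list[[fam]] <- member_ids
      out[[length(out) + 1L]] <- data.frame(
        element_id = member_ids, superfamily = s, family_id = fam,
        member_no = seq_along(member_ids), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "families") <- fam_list
  res
}

# greedy complete-linkage: grow each cluster only while every member pair
# is linked (used behind a flag; single linkage is the standard reading)
complete_linkage_components <- function(adj) {
  n <- nrow(adj)
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    comp[i] <- cid
    members <- i
    for (j in seq_len(n)) {
      if (!is.na(comp[j])) next
      if (all(adj[members, j])) {
        comp[j] <- cid
        members <- c(members, j)
      }
    }
  }
  comp
}

#' Genome proportion occupied by each family
#'
#' Hit intervals are merged (overlapping or bookended runs collapsed) per
#' family before summing, so nested RepeatMasker-style hits are not double
#' counted.
#'
#' @param hits data.frame(seq_id, start, end, family_id), 1-based closed
#'   coordinates (e.g. imported from BED via [read_hits()]).
#' @param genome_size genome size in bp.
#' @return data.frame: family_id, bases, proportion.
#' @export
genome_proportion <- function(hits, genome_size) {
  stopifnot(genome_size > 0)
  if (any(hits$start < 1) || any(hits$end > genome_size))
    stop("hit interval outside genome bounds")
  gr <- GenomicRanges::GRanges(hits$seq_id, IRanges::IRanges(hits$start, hits$end))
  out <- lapply(split(gr, hits$family_id), function(g) {
    sum(GenomicRanges::width(GenomicRanges::reduce(g)))
  })
  res <- data.frame(family_id = names(out),
                    bases = unlist(out, use.names = FALSE),
                    stringsAsFactors = FALSE)
  res$proportion <- res$bases / genome_size
  res[order(-res$proportion), , drop = FALSE]
}

#' Read family-labeled hit intervals from BED or GFF3
#'
#' BED `name` (or GFF3 `ID`) is taken as the family label; coordinates are
#' returned 1-based closed.
#'
#' @param path BED or GFF3 file.
#' @return data.frame(seq_id, start, end, family_id).
#' @export
read_hits <- function(path) {
  gr <- rtracklayer::import(path)
  fam <- if (!is.null(gr$name)) gr$name else as.character(gr$ID)
  data.frame(seq_id = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             family_id = fam, stringsAsFactors = FALSE)
}

#' Rank correlation between family mean age and genome proportion
#'
#' @param family_ages data.frame(family_id, mean_age_MY).
#' @param proportions data.frame(family_id, proportion) from
#'   [genome_proportion()].
#' @return list: `rho` (Spearman), `p_value`, `n`.
#' @export
age_proportion_correlation <- function(family_ages, proportions) {
  m <- merge(family_ages, proportions, by = "family_id")
  if (nrow(m) < 3) stop("need at least 3 families")
  ct <- suppressWarnings(cor.test(m$mean_age_MY, m$proportion,
                                  method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = nrow(m))
}
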