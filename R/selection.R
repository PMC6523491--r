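# Nei-Gojobori (1986) dN/dS on reverse-transcriptase domains.
#
# Synonymous/nonsynonymous site counts use the 1/3-per-position rule with
# changes to stop codons excluded and the position weight renormalized over
# non-stop changes, so S + N = 3 x codons exactly. Observed differences
# average over all orderings of mutational pathways between two codons,
# excluding pathways through stop codons. Proportions are Jukes-Cantor
# corrected: d = -3/4 ln(1 - 4p/3).

translate_codon <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  aa <- gc[codon]
  ifelse(is.na(aa), "X", aa)
}

# per-codon synonymous site count (S; N = 3 - S)
codon_syn_sites <- function() {
  if (!is.null(.ltrdyn_cache$syn_sites)) return(.ltrdyn_cache$syn_sites)
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)[gc != "*"]
  s <- vapply(codons, function(cod) {
    ch <- s2c(cod)
    tot <- 0
    for (pos in 1:3) {
      alts <- setdiff(DNA_BASES, ch[pos])
      newc <- vapply(alts, function(b) { x <- ch; x[pos] <- b; c2s(x) }, "")
      aa <- gc[newc]
      nonstop <- aa != "*"
      if (sum(nonstop) > 0)
        tot <- tot + sum(aa[nonstop] == gc[[cod]]) / sum(nonstop)
    }
    tot
  }, 1)
  names(s) <- codons
  .ltrdyn_cache$syn_sites <- s
  s
}

# average (syn, nonsyn) differences between two sense codons over all
# mutational pathways, excluding pathways through stop codons
ng86_path_counts <- function(c1, c2) {
  key <- paste0(c1, c2)
  if (is.null(.ltrdyn_cache$paths)) .ltrdyn_cache$paths <- new.env(parent = emptyenv())
  hit <- .ltrdyn_cache$paths[[key]]
  if (!is.null(hit)) return(hit)
  gc <- Biostrings::GENETIC_CODE
  a <- s2c(c1); b <- s2c(c2)
  pos <- which(a != b)
  d <- length(pos)
  res <- if (d == 0) {
    c(syn = 0, nonsyn = 0)
  } else {
    perms <- list(1L)
    if (d >= 2) perms <- permutations_of(pos)
    else perms <- list(pos)
    walk <- function(order_pos, count_stops_as_nonsyn) {
      cur <- a
      syn <- 0; nonsyn <- 0
      for (p in order_pos) {
        nxt <- cur
        nxt[p] <- b[p]
        aa1 <- gc[[c2s(cur)]] %||% "*"
        aa2 <- gc[[c2s(nxt)]] %||% "*"
        if (aa2 == "*" && !count_stops_as_nonsyn) return(NULL)
        if (aa1 == aa2 && aa1 != "*") syn <- syn + 1 else nonsyn <- nonsyn + 1
        cur <- nxt
      }
      c(syn = syn, nonsyn = nonsyn)
    }
    counts <- Filter(Negate(is.null), lapply(perms, walk, count_stops_as_nonsyn = FALSE))
    if (length(counts) == 0)  # all pathways blocked by stops: count them anyway
      counts <- lapply(perms, walk, count_stops_as_nonsyn = TRUE)
    Reduce(`+`, counts) / length(counts)
  }
  .ltrdyn_cache$paths[[key]] <- res
  res
}

permutations_of <- function(x) {
  if (length(x) == 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in permutations_of(x[-i])) out[[length(out) + 1L]] <- c(x[i], rest)
  }
  out
}

split_codons <- function(cds) {
  n <- nchar(cds) %/% 3L
  substring(cds, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

#' Pairwise Nei-Gojobori dN/dS
#'
#' @param cds_a,cds_b equal-length coding sequences (gapped allowed;
#'   columns whose codon in either sequence contains a gap, ambiguity or
#'   stop are dropped pairwise).
#' @return list (class `ng86_stats`): `n_codons` compared, `S`, `N`, `Sd`,
#'   `Nd`, `pS`, `pN`, `dS`, `dN`, `omega`, `flag` (`"ok"`, `"identical"`,
#'   or `"saturated"`).
#' @export
ng86_pair <- function(cds_a, cds_b) {
  if (nchar(cds_a) != nchar(cds_b)) stop("sequences must be equal length")
  ca <- split_codons(cds_a)
  cb <- split_codons(cds_b)
  syn_sites <- codon_syn_sites()
  ok <- ca %in% names(syn_sites) & cb %in% names(syn_sites)
  ca <- ca[ok]; cb <- cb[ok]
  nc <- length(ca)
  if (nc == 0) stop("no comparable codons")
  S <- sum((syn_sites[ca] + syn_sites[cb]) / 2)
  N <- 3 * nc - S
  Sd <- 0; Nd <- 0
  for (i in seq_len(nc)) {
    if (ca[i] == cb[i]) next
    cnt <- ng86_path_counts(ca[i], cb[i])
    Sd <- Sd + cnt[["syn"]]
    Nd <- Nd + cnt[["nonsyn"]]
  }
  pS <- Sd / S; pN <- Nd / N
  flag <- "ok"
  if (Sd + Nd == 0) flag <- "identical"
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  dS <- jc(pS); dN <- jc(pN)
  if (flag == "ok" && (is.na(dS) || is.na(dN))) flag <- "saturated"
  omega <- if (flag == "ok" && dS > 0) dN / dS else NA_real_
  structure(list(n_codons = nc, S = S, N = N, Sd = Sd, Nd = Nd,
                 pS = pS, pN = pN, dS = dS, dN = dN, omega = omega,
                 flag = flag), class = "ng86_stats")
}

#' Family-level dN/dS with selection classification
#'
#' Aggregates all valid pairwise comparisons as
#' omega = mean(dN) / mean(dS) and classifies the family against 1:
#' purifying (omega < 1 - band), neutral (within the band), positive
#' (omega > 1 + band). The default band of 0 reproduces the strict
#' threshold-at-1 reading.
#'
#' @param cds named character vector of equal-length coding rows (a codon
#'   alignment).
#' @param min_members minimum rows.
#' @param neutral_band half-width of the neutrality band around 1.
#' @return list: `n_members`, `n_pairs`, `S`, `N`, `Sd`, `Nd`, `dS`, `dN`,
#'   `omega`, `classification` (`"purifying"`, `"neutral"`, `"positive"`, or
#'   `"unestimable"`), `pairs` (data.frame of pairwise stats).
#' @export
family_dnds <- function(cds, min_members = 2L, neutral_band = 0) {
  if (length(cds) < min_members)
    stop("need at least ", min_members, " members")
  prs <- combn(seq_along(cds), 2)
  rows <- lapply(seq_len(ncol(prs)), function(k) {
    i <- prs[1, k]; j <- prs[2, k]
    st <- ng86_pair(cds[[i]], cds[[j]])
    data.frame(a = names(cds)[i] %||% i, b = names(cds)[j] %||% j,
               S = st$S, N = st$N, Sd = st$Sd, Nd = st$Nd,
               dS = st$dS, dN = st$dN, omega = st$omega, flag = st$flag,
               stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, rows)
  valid <- pairs$flag == "ok" & !is.na(pairs$dS) & pairs$dS > 0
  if (!any(valid)) {
    return(list(n_members = length(cds), n_pairs = nrow(pairs),
                S = NA, N = NA, Sd = NA, Nd = NA, dS = NA, dN = NA,
                omega = NA_real_, classification = "unestimable",
                pairs = pairs))
  }
  dS <- mean(pairs$dS[valid]); dN <- mean(pairs$dN[valid])
  omega <- dN / dS
  cls <- if (omega < 1 - neutral_band) "purifying"
  else if (omega > 1 + neutral_band) "positive"
  else "neutral"
  list(n_members = length(cds), n_pairs = sum(valid),
       S = mean(pairs$S[valid]), N = mean(pairs$N[valid]),
       Sd = mean(pairs$Sd[valid]), Nd = mean(pairs$Nd[valid]),
       dS = dS, dN = dN, omega = omega, classification = cls, pairs = pairs)
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Each amino-acid column becomes its source codon; protein gaps become
#' 3-nt gaps. Every row is checked against its CDS: the ungapped protein
#' length times 3 must equal the CDS length and the CDS must translate to
#' the row (standard code), otherwise a hard error names the sequence and
#' residue.
#'
#' @param protein_msa named character vector of gapped protein rows.
#' @param cds_map named character vector of in-frame CDS (same names).
#' @return named character vector: the codon alignment rows.
#' @export
back_translate_alignment <- function(protein_msa, cds_map) {
  miss <- setdiff(names(protein_msa), names(cds_map))
  if (length(miss)) stop("no CDS for: ", paste(miss, collapse = ", "))
  out <- vapply(names(protein_msa), function(id) {
    prot <- s2c(protein_msa[[id]])
    aas <- prot[prot != "-"]
    cds <- cds_map[[id]]
    if (length(aas) * 3L != nchar(cds))
      stop(sprintf("CDS length mismatch for %s: %d residues vs %d nt",
                   id, length(aas), nchar(cds)))
    codons <- split_codons(cds)
    trans <- translate_codon(codons)
    bad <- which(trans != aas)
    if (length(bad))
      stop(sprintf("CDS of %s does not translate to protein row at residue %d (%s vs %s)",
                   id, bad[1], trans[bad[1]], aas[bad[1]]))
    k <- 0L
    row <- vapply(prot, function(a) {
      if (a == "-") return("---")
      k <<- k + 1L
      codons[k]
    }, "")
    paste(row, collapse = "")
  }, "")
  names(out) <- names(protein_msa)
  out
}

#' Trim an RT domain to its longest stop-free reading frame
#'
#' Tries all three frames and returns the longest run of sense codons;
#' domains without a run of at least `min_codons` are rejected (NULL),
#' mirroring the rule that only intact RT genes enter selection analysis.
#'
#' @param seq RT-domain nucleotide string.
#' @param min_codons minimum intact length in codons.
#' @return list(`seq` trimmed in-frame CDS, `frame` 0-2, `n_codons`) or
#'   `NULL`.
#' @export
rt_trim <- function(seq, min_codons = 150L) {
  best <- NULL
  for (f in 0:2) {
    n_cod <- (nchar(seq) - f) %/% 3L
    if (n_cod < 1) next
    codons <- substring(seq, f + 3L * seq_len(n_cod) - 2L, f + 3L * seq_len(n_cod))
    is_stop <- translate_codon(codons) %in% c("*", "X")
    # longest FALSE run
    r <- rle(is_stop)
    if (!any(!r$values)) next
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(!r$values)
    k <- runs[which.max(r$lengths[runs])]
    len <- r$lengths[k]
    if (is.null(best) || len > best$n_codons) {
      s0 <- f + 3L * (starts[k] - 1L) + 1L
      best <- list(seq = substring(seq, s0, s0 + 3L * len - 1L),
                   frame = f, n_codons = len)
    }
  }
  if (is.null(best) || best$n_codons < min_codons) return(NULL)
  best
}
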