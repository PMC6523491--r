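# Synthetic LTR-element generator.
#
# Produces elements with known ground truth (insertion age, priming tRNA,
# omega, family membership, genomic context) so that every pipeline stage
# can be validated offline. Elements carry two initially identical LTRs
# bounded by TG...CA, a PBS complementary to the chosen tRNA's 3' end, a
# polypurine tract abutting the 3'LTR, and an internal open reading frame
# housing the RT domain. After insertion the two LTRs evolve independently
# (no gene conversion) under a Kimura two-parameter substitution process;
# the RT region evolves under a codon process in which nonsynonymous
# changes are accepted with relative probability omega.

STANDARD_AA <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly",
                 "His", "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser",
                 "Thr", "Trp", "Tyr", "Val")

#' Simulation configuration
#'
#' Defaults mirror the element anatomy and study conditions the pipeline is
#' built around: 400 bp LTRs, a 0.41 GC background, a substitution rate of
#' r = 1.3e-8 per site per year with transition/transversion ratio
#' kappa = 2, insertion ages uniform on 0-3 MY, and 5 bp target-site
#' duplications.
#'
#' @param seed integer seed (applied by [simulate_ltr_dataset()]).
#' @param n_families number of families to simulate.
#' @param copies_per_family copies per family (recycled).
#' @param frac_copia fraction of families labeled Copia (rest Gypsy).
#' @param ltr_length LTR length in bp (>= 100).
#' @param internal_length internal-region length in bp.
#' @param rt_codons RT open-reading-frame length in codons (incl. start).
#' @param r substitution rate per site per year.
#' @param kappa transition/transversion rate ratio.
#' @param age_min_MY,age_max_MY uniform insertion-age range in MY.
#' @param omega_per_family optional numeric vector of dN/dS per family;
#'   sampled from a purifying-dominated set when NULL.
#' @param trna_per_family optional character vector of tRNA ids per family;
#'   sampled Met-biased when NULL (mirroring the Met dominance seen in
#'   plant LTR elements).
#' @param tsd_length target-site duplication length.
#' @param gc background GC fraction.
#' @return list of class `sim_config`.
#' @export
simulation_config <- function(seed = 1L, n_families = 6L, copies_per_family = 5L,
                              frac_copia = 0.5, ltr_length = 400L,
                              internal_length = 3000L, rt_codons = 300L,
                              r = 1.3e-8, kappa = 2, age_min_MY = 0,
                              age_max_MY = 3, omega_per_family = NULL,
                              trna_per_family = NULL, tsd_length = 5L,
                              gc = 0.41) {
  stopifnot(r > 0, ltr_length >= 100, kappa > 0, tsd_length >= 0,
            n_families >= 1, age_max_MY >= age_min_MY, age_min_MY >= 0)
  if (!is.null(omega_per_family) && any(omega_per_family <= 0))
    stop("all omega must be > 0")
  structure(as.list(environment()), class = "sim_config")
}

#' Generate a synthetic tRNA database
#'
#' Random tRNA gene sequences (no 3' CCA, as for genomic tRNA genes) with
#' distinct 3' ends, labeled with amino acids and anticodons.
#'
#' @param n number of tRNAs (<= 20; one per amino acid).
#' @param length tRNA length in nt.
#' @return data.frame(trna_id, amino_acid, anticodon, sequence).
#' @export
make_trna_db <- function(n = 15L, length = 72L) {
  stopifnot(n >= 1, n <= length(STANDARD_AA) || n <= 20)
  aa <- STANDARD_AA[seq_len(n)]
  if (!"Met" %in% aa) aa[1] <- "Met"
  repeat {
    seqs <- vapply(seq_len(n), function(i) random_dna(length, gc = 0.5), "")
    ends <- substring(seqs, nchar(seqs) - 8, nchar(seqs))
    if (!anyDuplicated(ends)) break
  }
  data.frame(
    trna_id = paste0("trna_", aa),
    amino_acid = aa,
    anticodon = vapply(seq_len(n), function(i) random_dna(3), ""),
    sequence = seqs,
    stringsAsFactors = FALSE
  )
}

# 3'-terminal `len` nt of a tRNA with CCA appended when absent
trna_acceptor_end <- function(trna_seq, len = 12L) {
  s <- if (endsWith(trna_seq, "CCA")) trna_seq else paste0(trna_seq, "CCA")
  substring(s, nchar(s) - len + 1L, nchar(s))
}

sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

#' Simulate an ancestral (age-zero) element
#'
#' Layout: LTR | PBS | spacer | RT ORF | spacer | PPT | LTR, with the two
#' LTRs identical, starting TG and ending CA; the PBS is the reverse
#' complement of the chosen tRNA's 3'-terminal 12 nt (CCA included); the
#' PPT is a 15 nt purine run ending at the 3'LTR; the RT ORF is stop-free.
#'
#' @param config a `sim_config`.
#' @param family_index family number (used in the element id).
#' @param trna_db tRNA database ([make_trna_db()] format).
#' @param trna_id priming tRNA id (must exist in `trna_db`).
#' @param superfamily `"COPIA"` or `"GYPSY"` (drives the RLC_/RLG_ id).
#' @param rt_cds optional stop-free CDS of length `3 * rt_codons` to use as
#'   the RT open reading frame (random when NULL); lets families inherit a
#'   shared ancestral RT so deep phylogenetic structure is simulable.
#' @return an `ltr_element` with `pbs`, `ppt` and `rt` annotated.
#' @export
simulate_ancestor <- function(config, family_index, trna_db,
                              trna_id = trna_db$trna_id[1],
                              superfamily = "COPIA", rt_cds = NULL) {
  L <- config$ltr_length
  pbs_len <- 12L
  ppt_len <- 15L
  rt_len <- 3L * config$rt_codons
  inner <- config$internal_length
  if (inner < pbs_len + ppt_len + rt_len + 20L)
    stop("internal_length too small for PBS + RT + PPT")
  ltr <- paste0("TG", random_dna(L - 4L, config$gc), "CA")
  tr <- trna_db[trna_db$trna_id == trna_id, ]
  if (nrow(tr) != 1) stop("unknown tRNA id: ", trna_id)
  pbs <- revcomp(trna_acceptor_end(tr$sequence, pbs_len))
  spacer_total <- inner - pbs_len - ppt_len - rt_len
  s1 <- spacer_total %/% 2L
  s2 <- spacer_total - s1
  rt <- rt_cds %||% {
    codons <- sample(setdiff(sense_codons(), "ATG"), config$rt_codons - 1L,
                     replace = TRUE)
    paste0("ATG", paste(codons, collapse = ""))
  }
  if (nchar(rt) != rt_len) stop("rt_cds must have length 3 * rt_codons")
  ppt <- random_dna(ppt_len, gc = 0.5)
  ppt <- chartr("CT", "GA", ppt)  # force purines
  seq <- paste0(ltr, pbs, random_dna(s1, config$gc), rt,
                random_dna(s2, config$gc), ppt, ltr)
  prefix <- if (superfamily == "COPIA") "RLC_" else "RLG_"
  rt_start <- L + pbs_len + s1
  ltr_element(
    element_id = paste0(prefix, family_index, "_0"),
    seq = seq,
    ltr5 = c(0L, L),
    ltr3 = c(L + inner, L + inner + L),
    superfamily = superfamily,
    rt = c(rt_start, rt_start + rt_len),
    pbs = list(offset = 0L, trna_id = trna_id),
    ppt = c(L + inner - ppt_len, L + inner)
  )
}

# apply n_events K2P substitutions (sites drawn with replacement, so
# multiple hits occur as in the continuous-time process)
mutate_neutral_chars <- function(chars, n_events, kappa) {
  if (n_events == 0L) return(chars)
  sites <- sample.int(length(chars), n_events, replace = TRUE)
  ts <- runif(n_events) < kappa / (kappa + 2)
  for (i in seq_len(n_events)) {
    b <- chars[sites[i]]
    if (!b %in% DNA_BASES) next
    chars[sites[i]] <- if (ts[i]) TRANSITION[[b]]
    else sample(TRANSVERSION[[b]], 1L)
  }
  chars
}

# codon-level process: proposals as above, but a proposal creating a stop
# is rejected and a nonsynonymous proposal is accepted with relative
# probability omega (synonymous changes with relative probability 1)
evolve_codon_chars <- function(chars, n_proposals, kappa, omega) {
  if (n_proposals == 0L) return(chars)
  code <- Biostrings::GENETIC_CODE
  wmax <- max(1, omega)
  sites <- sample.int(length(chars), n_proposals, replace = TRUE)
  ts <- runif(n_proposals) < kappa / (kappa + 2)
  acc <- runif(n_proposals)
  for (i in seq_len(n_proposals)) {
    s <- sites[i]
    b <- chars[s]
    nb <- if (ts[i]) TRANSITION[[b]] else sample(TRANSVERSION[[b]], 1L)
    ci <- (s - 1L) %/% 3L
    cod <- chars[(ci * 3L + 1L):(ci * 3L + 3L)]
    newcod <- cod
    newcod[(s - 1L) %% 3L + 1L] <- nb
    aa_old <- code[[c2s(cod)]]
    aa_new <- code[[c2s(newcod)]]
    if (aa_new == "*") next
    p <- if (aa_new == aa_old) 1 / wmax else omega / wmax
    if (acc[i] <= p) chars[s] <- nb
  }
  chars
}

#' Age an element
#'
#' Each LTR independently accumulates a Poisson(r * age * L) number of
#' substitutions under the K2P process; the RT region evolves under the
#' omega-thinned codon process scaled to the same clock; remaining internal
#' sites evolve neutrally.
#'
#' @param element an age-zero `ltr_element` (e.g. from [simulate_ancestor()]).
#' @param age_years insertion age in years (>= 0).
#' @param config a `sim_config` (supplies r, kappa).
#' @param omega dN/dS for the RT codon process.
#' @param new_id id for the aged copy.
#' @return list: `element` (aged copy), `truth` (one-row data.frame of
#'   class TruthRecord fields).
#' @export
age_element <- function(element, age_years, config, omega = 0.5,
                        new_id = element$element_id) {
  stopifnot(age_years >= 0)
  chars <- s2c(element$seq)
  r <- config$r; kappa <- config$kappa
  idx_iv <- function(iv) if (is.null(iv)) integer(0) else seq.int(iv[1] + 1L, iv[2])
  i5 <- idx_iv(element$ltr5); i3 <- idx_iv(element$ltr3)
  irt <- idx_iv(element$rt)
  iother <- setdiff(seq_along(chars), c(i5, i3, irt))
  mut_region <- function(idx) {
    n <- rpois(1L, r * age_years * length(idx))
    if (n > 0L) chars[idx] <<- mutate_neutral_chars(chars[idx], n, kappa)
  }
  mut_region(i5)
  mut_region(i3)
  if (length(iother)) mut_region(iother)
  if (length(irt)) {
    # Jukes-Cantor-style codon clock: uniform proposals, omega acceptance
    n <- rpois(1L, r * age_years * length(irt))
    if (n > 0L) chars[irt] <- evolve_codon_chars(chars[irt], n, 1, omega)
  }
  el <- element
  el$seq <- c2s(chars)
  el$element_id <- new_id
  truth <- data.frame(
    element_id = new_id,
    true_age_years = age_years,
    true_family = NA_character_,
    true_trna = element$pbs$trna_id %||% NA_character_,
    true_omega = omega,
    ltr5_start = element$ltr5[1], ltr5_end = element$ltr5[2],
    ltr3_start = element$ltr3[1], ltr3_end = element$ltr3[2],
    true_context = NA_character_,
    stringsAsFactors = FALSE
  )
  list(element = el, truth = truth)
}

#' Simulate a dataset of families with full ground truth
#'
#' Families are seeded from independent random ancestors (so between-family
#' identity is background-level) and copies radiate from each ancestor with
#' independent uniform ages, giving within-family identity >= ~92% over the
#' default 0-3 MY age range.
#'
#' @param config a `sim_config`; `config$seed` is applied first.
#' @return list: `elements` (named list of `ltr_element`), `truth`
#'   (data.frame), `trna_db`, `config`.
#' @export
simulate_ltr_dataset <- function(config = simulation_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  trna_db <- make_trna_db()
  nf <- config$n_families
  copies <- rep_len(config$copies_per_family, nf)
  n_copia <- round(config$frac_copia * nf)
  superfams <- c(rep("COPIA", n_copia), rep("GYPSY", nf - n_copia))
  omegas <- config$omega_per_family %||%
    sample(c(0.2, 0.5, 1.0, 2.0), nf, replace = TRUE, prob = c(.4, .3, .2, .1))
  omegas <- rep_len(omegas, nf)
  trnas <- config$trna_per_family %||% {
    met <- trna_db$trna_id[trna_db$amino_acid == "Met"]
    others <- setdiff(trna_db$trna_id, met)
    sample(c(met, others), nf, replace = TRUE,
           prob = c(0.5, rep(0.5 / length(others), length(others))))
  }
  trnas <- rep_len(trnas, nf)
  # per-superfamily family numbering so ids follow the RLC_#/RLG_# scheme
  fam_no <- stats::ave(seq_len(nf), superfams, FUN = seq_along)
  # each superfamily carries one ancestral RT pool; family RTs diverge from
  # it (~8% of sites per lineage), so RT similarity encodes the deep
  # superfamily split while LTRs and internal regions stay family-specific
  pool_rt <- lapply(unique(superfams), function(s) {
    s2c(paste0("ATG", paste(sample(setdiff(sense_codons(), "ATG"),
                                   config$rt_codons - 1L, replace = TRUE),
                            collapse = "")))
  })
  names(pool_rt) <- unique(superfams)
  elements <- list()
  truth <- list()
  for (f in seq_len(nf)) {
    fam_rt <- c2s(evolve_codon_chars(pool_rt[[superfams[f]]],
                                     rpois(1L, 0.08 * 3L * config$rt_codons),
                                     kappa = 1, omega = 1))
    anc <- simulate_ancestor(config, fam_no[f], trna_db,
                             trna_id = trnas[f], superfamily = superfams[f],
                             rt_cds = fam_rt)
    prefix <- sub("_0$", "", anc$element_id)
    for (j in seq_len(copies[f])) {
      age <- runif(1, config$age_min_MY, config$age_max_MY) * 1e6
      res <- age_element(anc, age, config, omega = omegas[f],
                         new_id = paste0(prefix, "_", j))
      res$truth$true_family <- prefix
      elements[[res$element$element_id]] <- res$element
      truth[[length(truth) + 1L]] <- res$truth
    }
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(elements = elements, truth = truth, trna_db = trna_db, config = config)
}

#' Simulate one diverged LTR pair
#'
#' Fast path for dating validation: a single ancestral LTR copied into two
#' descendants, each accumulating Poisson(r * age * L) K2P substitutions.
#'
#' @param age_years true insertion age in years.
#' @param L LTR length.
#' @param r rate per site per year.
#' @param kappa transition/transversion ratio.
#' @param gc ancestral GC fraction.
#' @return list(ltr5, ltr3) character strings.
#' @export
simulate_ltr_pair <- function(age_years, L = 1000L, r = 1.3e-8, kappa = 2,
                              gc = 0.5) {
  anc <- s2c(random_dna(L, gc))
  mk <- function() {
    n <- rpois(1L, r * age_years * L)
    c2s(mutate_neutral_chars(anc, n, kappa))
  }
  list(ltr5 = mk(), ltr3 = mk())
}

#' Simulate a family of RT coding sequences at a chosen omega
#'
#' Members radiate from a random stop-free ancestor; each lineage receives
#' Poisson(depth * 3 * n_codons) substitution proposals thinned by the
#' omega acceptance rule, giving pairwise divergence with a known dN/dS.
#' The default depth of 0.1 proposals per nucleotide site yields pairwise
#' divergences comparable to within-family RT divergence while leaving
#' Nei-Gojobori counting well away from saturation.
#'
#' @param n_members family size.
#' @param n_codons coding length in codons.
#' @param omega true dN/dS.
#' @param depth expected substitution proposals per nucleotide site per
#'   lineage.
#' @param kappa transition/transversion ratio of the proposal process
#'   (default 1: the Jukes-Cantor-style codon clock matching unweighted
#'   Nei-Gojobori path counting).
#' @return named character vector of equal-length, gap-free CDS strings.
#' @export
simulate_family_rt <- function(n_members = 6L, n_codons = 300L, omega = 0.5,
                               depth = 0.1, kappa = 1) {
  anc <- s2c(paste(sample(sense_codons(), n_codons, replace = TRUE),
                   collapse = ""))
  out <- vapply(seq_len(n_members), function(i) {
    n <- rpois(1L, depth * length(anc))
    c2s(evolve_codon_chars(anc, n, kappa, omega))
  }, "")
  names(out) <- paste0("m", seq_len(n_members))
  out
}
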