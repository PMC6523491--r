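# End-to-end orchestration: summarize -> signals -> classify -> date ->
# proportion -> selection -> phylo -> dynamics/context, with a
# machine-readable JSON report of per-stage counts, exclusions and
# headline statistics.

#' Run the full characterization pipeline
#'
#' @param elements list of `ltr_element` (e.g. from [read_elements()] or
#'   [simulate_ltr_dataset()]).
#' @param trna_db tRNA database (PBS stage skipped when NULL).
#' @param genome genome DNA string (TSD/boundary stages skipped when NULL).
#' @param loci element genome loci data.frame (element_id, seq_id, start,
#'   end) for TSD and context stages.
#' @param gm `gene_models` for context classification.
#' @param hits family-labeled hit intervals for genome proportions.
#' @param genome_size genome size in bp (defaults to `nchar(genome)`).
#' @param r substitution rate per site per year.
#' @param model divergence model, `"K2P"` or `"JC69"`.
#' @param min_identity dating exclusion threshold.
#' @param promoter_window promoter window in bp.
#' @param boot bootstrap replicates for the RT tree (0 = no bootstrap).
#' @param seed seed recorded in the report and used for the bootstrap.
#' @param neutral_band neutrality band for selection classification.
#' @param out_dir when given, per-stage TSVs and `report.json` are written
#'   there.
#' @return the report, invisibly a list; see `$headline` for the summary
#'   statistics (fractions younger than 2/3 MY, modal age bin per
#'   superfamily, top families by proportion, families under positive
#'   selection).
#' @export
run_pipeline <- function(elements, trna_db = NULL, genome = NULL, loci = NULL,
                         gm = NULL, hits = NULL, genome_size = NULL,
                         r = 1.3e-8, model = "K2P", min_identity = 0.6,
                         promoter_window = 2000L, boot = 0L, seed = 1L,
                         neutral_band = 0) {
  if (length(elements) == 0) stop("stage validate: no elements")
  set.seed(seed)
  report <- list(schema = "ltrdyn-report/1",
                 seed = seed,
                 parameters = list(r = r, model = model,
                                   min_identity = min_identity,
                                   promoter_window = promoter_window,
                                   boot = boot, neutral_band = neutral_band))

  report$summary <- summarize_elements(elements)

  # signals
  sfs <- vapply(elements, `[[`, "", "superfamily")
  bounds <- lapply(elements, check_boundaries)
  report$signals <- list(
    tg_ca_fraction = mean(vapply(bounds, function(b) b$starts_TG && b$ends_CA, TRUE)))
  if (!is.null(trna_db)) {
    pbs <- lapply(elements, find_pbs, trna_db = trna_db)
    report$signals$pbs_assigned <- sum(!vapply(pbs, is.null, TRUE))
    report$signals$trna_usage <- trna_usage(pbs, sfs)
  }

  # families
  fam <- cluster_families(elements)
  for (i in seq_len(nrow(fam)))
    elements[[fam$element_id[i]]]$family_id <- fam$family_id[i]
  report$families <- list(
    n_families = length(attr(fam, "families")),
    per_superfamily = table(fam$superfamily[!duplicated(fam$family_id)]))

  # dating
  ages <- date_elements(elements, r = r, model = model,
                        min_identity = min_identity)
  dated <- ages[ages$flag == "ok", ]
  report$dating <- list(
    n_dated = nrow(dated),
    n_excluded = nrow(ages) - nrow(dated),
    exclusions = table(ages$flag[ages$flag != "ok"]))
  headline <- list()
  if (nrow(dated) > 0) {
    headline$fraction_within_2MY <- mean(dated$T_MY <= 2)
    headline$fraction_within_3MY <- mean(dated$T_MY <= 3)
    headline$peak_MY <- lapply(split(dated$T_MY, dated$superfamily),
                               function(a) age_histogram(a)$peak_MY)
  }

  # proportions
  if (!is.null(hits)) {
    gs <- genome_size %||% nchar(genome)
    prop <- genome_proportion(hits, gs)
    report$proportion <- prop
    headline$top_families_by_proportion <- head(prop$family_id, 3)
  }

  # selection: per family, intact RT rows of equal length
  fam_ids <- unique(fam$family_id)
  sel <- list()
  for (f in fam_ids) {
    members <- fam$element_id[fam$family_id == f]
    cds <- list()
    for (m in members) {
      rts <- rt_seq(elements[[m]])
      if (is.null(rts)) next
      tr <- rt_trim(rts)
      if (is.null(tr)) next
      cds[[m]] <- tr$seq
    }
    if (length(cds) < 2) next
    lens <- nchar(unlist(cds))
    cds <- cds[lens == max(lens)]  # rows must be alignable codon-wise
    if (length(cds) < 2) next
    st <- family_dnds(unlist(cds), neutral_band = neutral_band)
    sel[[f]] <- data.frame(family_id = f, n_members = st$n_members,
                           dS = st$dS, dN = st$dN, omega = st$omega,
                           classification = st$classification,
                           stringsAsFactors = FALSE)
  }
  if (length(sel)) {
    seldf <- do.call(rbind, sel)
    rownames(seldf) <- NULL
    report$selection <- seldf
    headline$positive_families <-
      seldf$family_id[seldf$classification == "positive"]
  }

  # phylogeny on family-representative RTs (longest intact RT per family)
  reps <- list()
  for (f in fam_ids) {
    members <- fam$element_id[fam$family_id == f]
    best <- NULL
    for (m in members) {
      rts <- rt_seq(elements[[m]])
      if (is.null(rts)) next
      tr <- rt_trim(rts)
      if (!is.null(tr) && (is.null(best) || tr$n_codons > best$n))
        best <- list(seq = tr$seq, n = tr$n_codons, id = f)
    }
    if (!is.null(best)) reps[[f]] <- best$seq
  }
  if (length(reps) >= 3 && length(unique(nchar(unlist(reps)))) == 1) {
    msa <- unlist(reps)
    tree <- if (boot > 0) bootstrap_support(msa, n_reps = boot, seed = seed)$tree
    else neighbor_joining(rt_distance_matrix(msa))
    report$phylo <- list(newick = ape::write.tree(tree))
    rep_sf <- vapply(reps, function(x) NA_character_, "")
    rep_sf <- setNames(fam$superfamily[match(names(reps), fam$family_id)],
                       names(reps))
    if (length(unique(rep_sf)) == 2) {
      sp <- superfamily_split(tree, rep_sf)
      report$phylo$superfamily_split <- sp$split
      report$phylo$misplaced <- sp$misplaced
    }
  }

  # dynamics & context
  if (nrow(dated) >= 10) {
    fit <- fit_exponential(dated$T_MY)
    report$dynamics <- list(lambda_per_MY = fit$lambda_per_MY,
                            half_life_MY = fit$half_life_MY,
                            ks_statistic = fit$ks_statistic,
                            note = "half-life is descriptive; check ks_statistic for exponentiality")
  }
  if (!is.null(loci) && !is.null(gm)) {
    ctx <- genomic_context(loci, gm, promoter_window = promoter_window)
    report$context <- list(counts = table(ctx$context), calls = ctx)
  }

  report$headline <- headline
  report$ages <- ages
  report$family_table <- fam
  invisible(structure(report, class = "ltrdyn_report"))
}

#' Write a pipeline report to disk
#'
#' Emits `report.json` plus `ages.tsv` and `families.tsv` under `out_dir`.
#'
#' @param report result of [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.table(report$ages, file.path(out_dir, "ages.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  fam <- report$family_table
  attr(fam, "families") <- NULL
  write.table(fam, file.path(out_dir, "families.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  slim <- report[setdiff(names(report), c("ages", "family_table"))]
  if (!is.null(slim$context)) slim$context$calls <- NULL
  jsonlite::write_json(slim, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       pretty = TRUE)
  invisible(out_dir)
}
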