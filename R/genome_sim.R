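# Planting simulated elements into a background genome with exact TSDs,
# generated gene models, and recorded insertion contexts.

# random gene structure layout on a gap-separated backbone
generate_gene_layout <- function(n_genes, gap = 6000L, seq_id = "chr1") {
  genes <- list(); exons <- list()
  pos <- gap
  for (g in seq_len(n_genes)) {
    k <- sample(3:5, 1)
    exon_len <- sample(150:400, k, replace = TRUE)
    intron_len <- sample(400:900, k - 1, replace = TRUE)
    gstart <- pos + 1L
    cur <- gstart
    ex <- list()
    for (i in seq_len(k)) {
      ex[[i]] <- c(cur, cur + exon_len[i] - 1L)
      cur <- cur + exon_len[i]
      if (i < k) cur <- cur + intron_len[i]
    }
    gend <- ex[[k]][2]
    gid <- paste0("gene", g)
    genes[[g]] <- data.frame(gene_id = gid, seq_id = seq_id,
                             start = gstart, end = gend,
                             strand = sample(c("+", "-"), 1),
                             stringsAsFactors = FALSE)
    exons[[g]] <- data.frame(gene_id = gid, seq_id = seq_id,
                             start = vapply(ex, `[`, 1L, 1),
                             end = vapply(ex, `[`, 1L, 2),
                             stringsAsFactors = FALSE)
    pos <- gend + gap
  }
  gene_models(do.call(rbind, genes), do.call(rbind, exons))
}

#' Plant elements into a synthetic background genome
#'
#' Each element is inserted at a point chosen to realize a configured mix
#' of genomic contexts (gene promoters, introns, intergenic space) and is
#' flanked by an exact target-site duplication. Gene-model coordinates are
#' shifted to the post-insertion genome, so the emitted GFF3 and element
#' loci are mutually consistent and [genomic_context()] can be validated
#' against the recorded truth.
#'
#' @param elements list of `ltr_element` to insert.
#' @param config a `sim_config` (supplies `tsd_length`, `gc`).
#' @param context_fractions named fractions over
#'   `c("promoter", "intron", "intergenic")` (summing to 1).
#' @param n_genes number of genes to generate (default: enough to host the
#'   promoter and intron insertions).
#' @param genome_length optional total background length; an error if too
#'   small for the layout.
#' @param seq_id contig name.
#' @return list: `genome` (string), `gene_models`, `loci` (data.frame
#'   element_id, seq_id, start, end, strand; 1-based closed), `truth`
#'   (element_id, true_context, gene_id, intron_ordinal, tsd).
#' @export
plant_insertions <- function(elements, config,
                             context_fractions = c(promoter = 0.25,
                                                   intron = 0.25,
                                                   intergenic = 0.5),
                             n_genes = NULL, genome_length = NULL,
                             seq_id = "chr1") {
  n <- length(elements)
  stopifnot(n >= 1)
  stopifnot(abs(sum(context_fractions) - 1) < 1e-9)
  tsd_len <- config$tsd_length
  cts <- c("promoter", "intron", "intergenic")
  counts <- setNames(floor(context_fractions[cts] * n), cts)
  counts[is.na(counts)] <- 0L
  while (sum(counts) < n) counts["intergenic"] <- counts["intergenic"] + 1L
  n_genes <- n_genes %||% max(3L, counts[["promoter"]], counts[["intron"]],
                              counts[["intergenic"]] - 1L)
  gap <- 6000L
  gm <- generate_gene_layout(n_genes, gap = gap, seq_id = seq_id)
  base_len <- max(gm$genes$end) + gap
  if (!is.null(genome_length)) {
    if (genome_length < base_len)
      stop("genome too small: need at least ", base_len, " bp")
    base_len <- genome_length
  }
  base <- random_dna(base_len, config$gc)

  # one insertion point per promoter / intron / inter-gene gap
  promoter_genes <- sample(gm$genes$gene_id, counts[["promoter"]])
  intron_slots <- do.call(rbind, lapply(gm$genes$gene_id, function(g) {
    intr <- gene_introns(gm, g)
    if (nrow(intr) == 0) return(NULL)
    cbind(data.frame(gene_id = g, stringsAsFactors = FALSE), intr)
  }))
  if (counts[["intron"]] > nrow(intron_slots))
    stop("not enough introns for requested intron insertions")
  intron_pick <- intron_slots[sample(nrow(intron_slots), counts[["intron"]]), ,
                              drop = FALSE]
  gap_starts <- c(1L, gm$genes$end + 1L)
  gap_ends <- c(gm$genes$start - 1L, base_len)
  ok_gap <- which((gap_ends - gap_starts) >= 5200L)
  if (counts[["intergenic"]] > length(ok_gap))
    stop("not enough inter-gene gaps for requested intergenic insertions")
  gap_idx <- ok_gap[sample.int(length(ok_gap), counts[["intergenic"]])]

  plan <- list()
  k <- 0L
  for (g in promoter_genes) {
    gi <- gm$genes[gm$genes$gene_id == g, ]
    d <- sample(60:600, 1)
    p <- if (gi$strand == "+") gi$start - 1L - d else gi$end + d
    k <- k + 1L
    plan[[k]] <- data.frame(point = p, context = "promoter", gene_id = g,
                            intron_ordinal = NA_integer_, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(intron_pick))) {
    s <- intron_pick[i, ]
    p <- sample(seq.int(s$start + 20L, s$end - 20L), 1)
    k <- k + 1L
    plan[[k]] <- data.frame(point = p, context = "intron", gene_id = s$gene_id,
                            intron_ordinal = s$ordinal, stringsAsFactors = FALSE)
  }
  for (gi in gap_idx) {
    p <- sample(seq.int(gap_starts[gi] + 2500L, gap_ends[gi] - 2500L), 1)
    k <- k + 1L
    plan[[k]] <- data.frame(point = p, context = "intergenic",
                            gene_id = NA_character_,
                            intron_ordinal = NA_integer_, stringsAsFactors = FALSE)
  }
  plan <- do.call(rbind, plan)
  plan$element_id <- vapply(elements, `[[`, "", "element_id")
  plan <- plan[order(plan$point), ]
  if (anyDuplicated(plan$point)) stop("insertion points collide; regenerate")

  elens <- vapply(elements, function(e) nchar(e$seq), 1L)[plan$element_id]
  ins_len <- elens + tsd_len
  shift_before <- cumsum(c(0L, ins_len[-length(ins_len)]))

  pieces <- character(0)
  prev <- 0L
  loci <- list(); tsds <- character(nrow(plan))
  for (i in seq_len(nrow(plan))) {
    p <- plan$point[i]
    if (p <= tsd_len) stop("insertion point too close to contig edge")
    el_seq <- elements[[plan$element_id[i]]]$seq
    tsds[i] <- substring(base, p - tsd_len + 1L, p)
    pieces <- c(pieces, substring(base, prev + 1L, p), el_seq, tsds[i])
    prev <- p
    start_final <- p + shift_before[i] + 1L
    loci[[i]] <- data.frame(element_id = plan$element_id[i], seq_id = seq_id,
                            start = start_final,
                            end = start_final + nchar(el_seq) - 1L,
                            strand = "+", stringsAsFactors = FALSE)
  }
  pieces <- c(pieces, substring(base, prev + 1L, base_len))
  genome <- paste(pieces, collapse = "")
  loci <- do.call(rbind, loci)

  # shift gene coordinates past each insertion point
  shift_coord <- function(x) {
    x + vapply(x, function(xi) sum(ins_len[plan$point < xi]), 1L)
  }
  gm$genes$start <- shift_coord(gm$genes$start)
  gm$genes$end <- shift_coord(gm$genes$end)
  gm$exons$start <- shift_coord(gm$exons$start)
  gm$exons$end <- shift_coord(gm$exons$end)

  truth <- data.frame(element_id = plan$element_id,
                      true_context = plan$context,
                      gene_id = plan$gene_id,
                      intron_ordinal = plan$intron_ordinal,
                      tsd = tsds, stringsAsFactors = FALSE)
  list(genome = genome, gene_models = gm, loci = loci, truth = truth)
}

#' Write a simulated dataset to disk
#'
#' Emits `elements.fa` + `elements.tsv` (annotation table), `truth.tsv`,
#' `trnas.fa`, and — when the dataset has been planted into a genome —
#' `genome.fa`, `genes.gff3` and `loci.tsv`.
#'
#' @param sim result of [simulate_ltr_dataset()].
#' @param out_dir output directory (created if needed).
#' @param planted optional result of [plant_insertions()].
#' @return invisibly, the output directory.
#' @export
write_simulation <- function(sim, out_dir, planted = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_elements(sim$elements, file.path(out_dir, "elements.fa"),
                 file.path(out_dir, "elements.tsv"))
  write_trna_db(sim$trna_db, file.path(out_dir, "trnas.fa"))
  truth <- sim$truth
  if (!is.null(planted)) {
    truth <- merge(truth, planted$truth, by = "element_id", all.x = TRUE,
                   suffixes = c("", ".planted"))
    g <- Biostrings::DNAStringSet(planted$genome)
    names(g) <- planted$loci$seq_id[1]
    Biostrings::writeXStringSet(g, file.path(out_dir, "genome.fa"), width = 70L)
    write_gene_models(planted$gene_models, file.path(out_dir, "genes.gff3"))
    write.table(planted$loci, file.path(out_dir, "loci.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}
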