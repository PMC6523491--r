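# Gene models: a light container (two data.frames, 1-based closed
# coordinates as in GFF3) with rtracklayer-backed GFF3 I/O.

#' Construct a gene-model set
#'
#' @param genes data.frame(gene_id, seq_id, start, end, strand).
#' @param exons data.frame(gene_id, seq_id, start, end); exons of one gene
#'   must be non-overlapping and within the gene span.
#' @return list of class `gene_models`.
#' @export
gene_models <- function(genes, exons) {
  stopifnot(all(c("gene_id", "seq_id", "start", "end", "strand") %in% names(genes)),
            all(c("gene_id", "seq_id", "start", "end") %in% names(exons)))
  for (g in genes$gene_id) {
    ex <- exons[exons$gene_id == g, ]
    ex <- ex[order(ex$start), ]
    gi <- genes[genes$gene_id == g, ]
    if (nrow(ex)) {
      if (any(ex$start < gi$start) || any(ex$end > gi$end))
        stop("exons outside gene span for ", g)
      if (nrow(ex) > 1 && any(ex$start[-1] <= ex$end[-nrow(ex)]))
        stop("overlapping exons for ", g)
    }
  }
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

#' Write gene models to GFF3
#' @param gm a `gene_models` object.
#' @param path output GFF3 path.
#' @export
write_gene_models <- function(gm, path) {
  g <- gm$genes; e <- gm$exons
  gr_g <- GenomicRanges::GRanges(g$seq_id,
                                 IRanges::IRanges(g$start, g$end),
                                 strand = g$strand,
                                 type = "gene", ID = g$gene_id)
  estr <- g$strand[match(e$gene_id, g$gene_id)]
  gr_e <- GenomicRanges::GRanges(e$seq_id,
                                 IRanges::IRanges(e$start, e$end),
                                 strand = estr,
                                 type = "exon",
                                 ID = paste0(e$gene_id, ".e", seq_len(nrow(e))))
  gr_e$Parent <- e$gene_id
  gr_g$Parent <- NA_character_
  gr <- c(gr_g, gr_e)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models from GFF3
#' @param path GFF3 with `gene` and `exon` features (`exon` rows carrying a
#'   `Parent` attribute naming the gene).
#' @return a `gene_models` object.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gg <- gr[gr$type == "gene"]
  ee <- gr[gr$type == "exon"]
  genes <- data.frame(
    gene_id = as.character(gg$ID),
    seq_id = as.character(GenomicRanges::seqnames(gg)),
    start = GenomicRanges::start(gg), end = GenomicRanges::end(gg),
    strand = as.character(GenomicRanges::strand(gg)),
    stringsAsFactors = FALSE)
  parent <- vapply(ee$Parent, function(p) as.character(p)[1], "")
  exons <- data.frame(
    gene_id = parent,
    seq_id = as.character(GenomicRanges::seqnames(ee)),
    start = GenomicRanges::start(ee), end = GenomicRanges::end(ee),
    stringsAsFactors = FALSE)
  gene_models(genes, exons)
}

# introns of one gene in genomic order: data.frame(start, end, ordinal)
# with ordinal counted in transcription order (reversed for minus strand)
gene_introns <- function(gm, gene_id) {
  ex <- gm$exons[gm$exons$gene_id == gene_id, ]
  ex <- ex[order(ex$start), ]
  if (nrow(ex) < 2) return(data.frame(start = integer(0), end = integer(0),
                                      ordinal = integer(0)))
  introns <- data.frame(start = ex$end[-nrow(ex)] + 1L,
                        end = ex$start[-1] - 1L)
  strand <- gm$genes$strand[gm$genes$gene_id == gene_id]
  introns$ordinal <- if (strand == "-") rev(seq_len(nrow(introns))) else seq_len(nrow(introns))
  introns
}
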