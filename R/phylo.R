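# RT-based phylogeny: K2P distance matrices, neighbor-joining trees with
# bootstrap support, the superfamily-split check, and nearest-reference
# lineage assignment. Tree manipulation is delegated to ape; distances
# share the Kimura machinery of the dating module.

COPIA_LINEAGES <- c("TAR", "Maximus", "Ivana", "COP21", "TOS17", "Ale",
                    "TNT1", "Angela")
GYPSY_LINEAGES <- c("CRM", "Reina", "Athila", "Tat", "Galadriel", "Tekay")

#' K2P distance matrix from an RT multiple alignment
#'
#' Pairwise gap deletion: columns where either row carries a gap or
#' ambiguity are dropped for that pair. Saturated pairs are set to
#' `ceiling` and flagged.
#'
#' @param msa named character vector of equal-length (gapped) rows.
#' @param model `"K2P"` or `"JC69"`.
#' @param min_sites minimum comparable sites per pair.
#' @param ceiling distance assigned to saturated pairs.
#' @return symmetric matrix with zero diagonal; attribute `"saturated"`
#'   holds flagged pairs, attribute `"model"` the model tag.
#' @export
rt_distance_matrix <- function(msa, model = "K2P", min_sites = 50L,
                               ceiling = 3) {
  n <- length(msa)
  stopifnot(n >= 2, length(unique(nchar(msa))) == 1)
  chars <- do.call(rbind, strsplit(unname(msa), "", fixed = TRUE))
  dm <- matrix(0, n, n, dimnames = list(names(msa), names(msa)))
  saturated <- character(0)
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    a <- chars[i, ]; b <- chars[j, ]
    ok <- a %in% DNA_BASES & b %in% DNA_BASES
    aln <- alignment_stats(c2s(a[ok]), c2s(b[ok]))
    if (aln$n_sites < min_sites)
      stop("fewer than ", min_sites, " comparable sites for pair ",
           names(msa)[i], " / ", names(msa)[j])
    dv <- k2p_distance(aln, model, min_sites = min_sites)
    d <- dv$K
    if (dv$flag == "saturated") {
      d <- ceiling
      saturated <- c(saturated, paste(names(msa)[i], names(msa)[j], sep = "|"))
    }
    dm[i, j] <- dm[j, i] <- d
  }
  attr(dm, "saturated") <- saturated
  attr(dm, "model") <- model
  dm
}

#' Neighbor-joining tree
#'
#' Saitou-Nei NJ (via ape) with negative branch lengths clamped to zero and
#' the deficit transferred to the adjacent (parent) edge, the usual
#' post-processing.
#'
#' @param dm symmetric distance matrix with row/col names.
#' @return an `ape::phylo` tree (n = 2 gives a single-edge two-tip tree).
#' @export
neighbor_joining <- function(dm) {
  n <- nrow(dm)
  if (n < 2) stop("need at least 2 taxa")
  if (n == 2) {
    tr <- list(edge = matrix(c(3L, 1L, 3L, 2L), 2, 2, byrow = TRUE),
               edge.length = rep(dm[1, 2] / 2, 2),
               tip.label = rownames(dm), Nnode = 1L)
    class(tr) <- "phylo"
    return(tr)
  }
  tr <- ape::nj(dm)
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    parent_node <- tr$edge[e, 1]
    up <- which(tr$edge[, 2] == parent_node)
    if (length(up) == 1)
      tr$edge.length[up] <- tr$edge.length[up] + tr$edge.length[e]
    tr$edge.length[e] <- 0
  }
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

# canonical bipartition keys of all non-trivial splits; each key is the
# sorted tip set on the side NOT containing the alphabetically first tip
tree_bipartitions <- function(tree) {
  tips <- tree$tip.label
  anchor <- min(tips)
  pp <- ape::prop.part(tree)
  keys <- vapply(pp, function(idx) {
    side <- tips[idx]
    if (anchor %in% side) side <- setdiff(tips, side)
    if (length(side) < 2 || length(side) > length(tips) - 2) return(NA_character_)
    paste(sort(side), collapse = "|")
  }, "")
  keys
}

#' Bootstrap support for an NJ tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree, and
#' reports the fraction of replicates containing each internal bipartition
#' of the full-data tree. Supports are stored as node labels.
#'
#' @param msa named character vector of aligned rows.
#' @param n_reps replicates (desk default 100; 1000 mirrors full-scale use).
#' @param seed RNG seed for column draws.
#' @param model distance model.
#' @return list: `tree` (node labels = support), `support` (named numeric
#'   per bipartition key).
#' @export
bootstrap_support <- function(msa, n_reps = 100L, seed = 1L, model = "K2P") {
  msa <- msa[order(names(msa))]  # leaf input order must not affect draws
  dm <- rt_distance_matrix(msa, model)
  ref <- neighbor_joining(dm)
  ref_keys <- tree_bipartitions(ref)
  hit <- setNames(numeric(length(ref_keys)), ref_keys)
  chars <- do.call(rbind, strsplit(unname(msa), "", fixed = TRUE))
  set.seed(seed)
  L <- ncol(chars)
  for (b in seq_len(n_reps)) {
    cols <- sample.int(L, L, replace = TRUE)
    rep_msa <- setNames(apply(chars[, cols, drop = FALSE], 1, paste, collapse = ""),
                        names(msa))
    rep_tree <- neighbor_joining(rt_distance_matrix(rep_msa, model))
    rep_keys <- tree_bipartitions(rep_tree)
    hit[ref_keys %in% rep_keys] <- hit[ref_keys %in% rep_keys] + 1
  }
  support <- hit / n_reps
  ref$node.label <- vapply(seq_along(ref_keys), function(i) {
    if (is.na(ref_keys[i])) "" else format(support[[i]], digits = 3)
  }, "")
  list(tree = ref, support = support[!is.na(names(support))])
}

#' Does the tree split cleanly into the two superfamilies?
#'
#' TRUE iff some edge bipartitions the leaves exactly into the Copia and
#' Gypsy label sets; otherwise the tips breaking the best available split
#' are reported.
#'
#' @param tree an `ape::phylo`.
#' @param labels named character vector (tip -> `"COPIA"`/`"GYPSY"`).
#' @return list: `split` (logical), `misplaced` (character ids).
#' @export
superfamily_split <- function(tree, labels) {
  tips <- tree$tip.label
  labels <- labels[tips]
  if (length(unique(labels)) < 2) stop("need both superfamilies on the tree")
  anchor <- min(tips)
  target <- sort(tips[labels != labels[[anchor]]])  # side without anchor
  key <- paste(target, collapse = "|")
  keys <- tree_bipartitions(tree)
  if (key %in% keys) return(list(split = TRUE, misplaced = character(0)))
  # best available split: the edge (and orientation) whose sides disagree
  # with the superfamily labels for the fewest tips
  best <- NULL
  sf <- sort(unique(labels))
  for (k in keys[!is.na(keys)]) {
    side <- strsplit(k, "|", fixed = TRUE)[[1]]
    other <- setdiff(tips, side)
    for (ori in list(c(sf[1], sf[2]), c(sf[2], sf[1]))) {
      bad <- c(side[labels[side] != ori[1]], other[labels[other] != ori[2]])
      if (is.null(best) || length(bad) < length(best)) best <- bad
    }
  }
  list(split = FALSE, misplaced = sort(best %||% character(0)))
}

#' Assign families to lineages by nearest reference RT
#'
#' Each family representative is compared with every labeled reference RT
#' (global alignment, then the configured distance) and labeled with the
#' lineage of the nearest reference; representatives farther than
#' `max_distance` from every reference are `"unassigned"`. Distance ties
#' are broken toward the alphabetically first reference id.
#'
#' @param family_rts named character vector of representative RT sequences.
#' @param reference_rts named character vector of reference RT sequences.
#' @param reference_lineages named character vector (reference id ->
#'   lineage label).
#' @param model distance model.
#' @param max_distance assignment ceiling.
#' @return data.frame: family_id, lineage, nearest_ref, distance.
#' @export
assign_lineages <- function(family_rts, reference_rts, reference_lineages,
                            model = "K2P", max_distance = 1.5) {
  stopifnot(all(names(reference_rts) %in% names(reference_lineages)))
  refs <- names(reference_rts)[order(names(reference_rts))]
  rows <- lapply(names(family_rts), function(fid) {
    d <- vapply(refs, function(rid) {
      aln <- align_ltr_pair(family_rts[[fid]], reference_rts[[rid]])
      dv <- k2p_distance(aln, model)
      if (dv$flag == "saturated") Inf else dv$K
    }, 1)
    i <- which.min(d)
    assigned <- is.finite(d[i]) && d[i] <= max_distance
    data.frame(family_id = fid,
               lineage = if (assigned) reference_lineages[[refs[i]]] else "unassigned",
               nearest_ref = refs[i], distance = d[[i]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a tree with supports as Newick
#' @param tree an `ape::phylo`.
#' @param path output path.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, path)
  invisible(path)
}
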