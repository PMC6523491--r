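# Independent oracles used by the tests. These deliberately re-derive
# results by brute force (dynamic programming, exhaustive enumeration,
# least-squares topology search) and stay independent of the package's
# implementation paths.

oracle_s2c <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Gotoh affine-gap alignment score; gap of length L costs go + L * ge
oracle_align_score <- function(a, b, match = 2, mis = -2, go = 6, ge = 1,
                               type = "global") {
  A <- oracle_s2c(a); B <- oracle_s2c(b)
  n <- length(A); m <- length(B); NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  if (type == "local") {
    M[, 1] <- 0; M[1, ] <- 0
  } else {
    for (i in 2:(n + 1)) X[i, 1] <- -(go + (i - 1) * ge)
    for (j in 2:(m + 1)) Y[1, j] <- -(go + (j - 1) * ge)
  }
  best <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    s <- if (A[i - 1] == B[j - 1]) match else mis
    M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
    if (type == "local") M[i, j] <- max(M[i, j], s)
    X[i, j] <- max(M[i - 1, j] - go - ge, X[i - 1, j] - ge, Y[i - 1, j] - go - ge)
    Y[i, j] <- max(M[i, j - 1] - go - ge, Y[i, j - 1] - ge, X[i, j - 1] - go - ge)
    best <- max(best, M[i, j])
  }
  if (type == "local") best
  else max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# all permutations of a vector, generated by filtering the full product
oracle_permutations <- function(x) {
  k <- length(x)
  if (k == 1) return(list(x))
  grid <- do.call(expand.grid, rep(list(seq_len(k)), k))
  keep <- apply(grid, 1, function(r) length(unique(r)) == k)
  lapply(which(keep), function(i) x[as.integer(grid[i, ])])
}

# average synonymous/nonsynonymous step counts over all mutational
# pathways between two sense codons, pathways through stops excluded;
# translation via seqinr, independent of the package's genetic-code path
oracle_ng86_diffs <- function(c1, c2) {
  a <- oracle_s2c(c1); b <- oracle_s2c(c2)
  pos <- which(a != b)
  if (length(pos) == 0) return(c(syn = 0, nonsyn = 0))
  tr <- function(ch) seqinr::translate(ch)
  counts <- list()
  for (ord in oracle_permutations(pos)) {
    cur <- a; syn <- 0; nonsyn <- 0; blocked <- FALSE
    for (p in ord) {
      nxt <- cur; nxt[p] <- b[p]
      if (tr(nxt) == "*") { blocked <- TRUE; break }
      if (tr(nxt) == tr(cur)) syn <- syn + 1 else nonsyn <- nonsyn + 1
      cur <- nxt
    }
    if (!blocked) counts[[length(counts) + 1]] <- c(syn = syn, nonsyn = nonsyn)
  }
  if (length(counts) == 0) return(NULL)  # all pathways blocked
  Reduce(`+`, counts) / length(counts)
}

# least-squares residual of fitting branch lengths of a fixed topology to
# a distance matrix (unconstrained LS on the edge-path indicator matrix)
oracle_topology_rss <- function(topology, dm) {
  tips <- topology$tip.label
  n <- length(tips)
  prs <- combn(n, 2)
  E <- matrix(0, ncol(prs), nrow(topology$edge))
  d <- numeric(ncol(prs))
  for (k in seq_len(ncol(prs))) {
    i <- prs[1, k]; j <- prs[2, k]
    np <- ape::nodepath(topology, i, j)
    for (s in seq_len(length(np) - 1)) {
      e <- which((topology$edge[, 1] == np[s] & topology$edge[, 2] == np[s + 1]) |
                 (topology$edge[, 2] == np[s] & topology$edge[, 1] == np[s + 1]))
      E[k, e] <- 1
    }
    d[k] <- dm[tips[i], tips[j]]
  }
  fit <- lm.fit(E, d)
  sum(fit$residuals^2)
}

# a tiny hand-built gene-model set for context tests
make_test_genes <- function() {
  genes <- data.frame(gene_id = c("gA", "gB"), seq_id = "chr1",
                      start = c(10001L, 30001L), end = c(14000L, 33000L),
                      strand = c("+", "-"), stringsAsFactors = FALSE)
  exons <- data.frame(
    gene_id = c("gA", "gA", "gA", "gA", "gB", "gB"),
    seq_id = "chr1",
    start = c(10001L, 11001L, 12001L, 13501L, 30001L, 32001L),
    end = c(10300L, 11300L, 12300L, 14000L, 30500L, 33000L),
    stringsAsFactors = FALSE)
  gene_models(genes, exons)
}
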