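# Distance matrices, neighbor joining, bootstrap, superfamily split, and
# lineage assignment.

random_msa <- function(n, L, mut = 0.1) {
  anc <- ltrdyn:::s2c(random_dna(L))
  out <- vapply(seq_len(n), function(i) {
    x <- anc
    k <- rbinom(1, L, mut)
    if (k > 0) {
      sites <- sample.int(L, k)
      x[sites] <- vapply(x[sites], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    }
    paste(x, collapse = "")
  }, "")
  names(out) <- paste0("t", seq_len(n))
  out
}

test_that("a two-row matrix agrees with the pairwise K2P distance", {
  set.seed(70)
  msa <- random_msa(2, 300)
  dm <- rt_distance_matrix(msa)
  aln <- align_ltr_pair(msa[1], msa[2])
  expect_equal(dm[1, 2], k2p_distance(aln)$K, tolerance = 1e-12)
  expect_equal(diag(dm), c(t1 = 0, t2 = 0))
})

test_that("K2P matrices match ape::dist.dna with pairwise deletion", {
  set.seed(71)
  msa <- random_msa(6, 400, mut = 0.08)
  dm <- rt_distance_matrix(msa)
  bin <- ape::as.DNAbin(do.call(rbind, strsplit(tolower(msa), "")))
  ref <- as.matrix(ape::dist.dna(bin, model = "K80", pairwise.deletion = TRUE))
  expect_equal(as.vector(dm), as.vector(ref[names(msa), names(msa)]),
               tolerance = 1e-9)
})

test_that("NJ reconstructs additive matrices exactly", {
  set.seed(72)
  for (n in 5:8) {
    tr <- ape::rtree(n, br = function(k) runif(k, 0.1, 1))
    dm <- cophenetic(tr)
    nj <- neighbor_joining(dm)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), nj)), 0)
  }
})

test_that("NJ attains the least-squares optimum over all 5-taxon topologies", {
  set.seed(73)
  tr <- ape::rtree(5, br = function(k) runif(k, 0.2, 1))
  dm <- cophenetic(tr)
  nj <- neighbor_joining(dm)
  nj_rss <- oracle_topology_rss(nj, dm)
  all_rss <- vapply(phangorn::allTrees(5, rooted = FALSE,
                                  tip.label = rownames(dm)),
                    oracle_topology_rss, 1, dm = dm)
  expect_lte(nj_rss, min(all_rss) + 1e-9)
  expect_equal(nj_rss, 0, tolerance = 1e-9)
})

test_that("degenerate inputs give the documented degenerate trees", {
  dm2 <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  tr2 <- neighbor_joining(dm2)
  expect_equal(sort(tr2$tip.label), c("a", "b"))
  expect_equal(tr2$edge.length, c(0.2, 0.2))
  # three taxa: closed-form branch lengths
  d <- matrix(c(0, .3, .5, .3, 0, .4, .5, .4, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr3 <- neighbor_joining(d)
  bl <- setNames(tr3$edge.length, tr3$tip.label[tr3$edge[, 2]])
  expect_equal(bl[["a"]], (.3 + .5 - .4) / 2)
  expect_equal(bl[["b"]], (.3 + .4 - .5) / 2)
  expect_equal(bl[["c"]], (.5 + .4 - .3) / 2)
  expect_error(neighbor_joining(matrix(0, 1, 1)), "at least 2")
  # clamped negatives never survive
  set.seed(74)
  noisy <- cophenetic(ape::rtree(6)) + matrix(runif(36, 0, .05), 6)
  noisy <- (noisy + t(noisy)) / 2; diag(noisy) <- 0
  expect_true(all(neighbor_joining(noisy)$edge.length >= 0))
})

test_that("bootstrap supports are reproducible and bounded", {
  set.seed(75)
  # two clearly separated clades
  cl1 <- random_msa(3, 300, mut = 0.02)
  set.seed(76)
  cl2 <- random_msa(3, 300, mut = 0.02)
  msa <- c(cl1, setNames(cl2, paste0("u", 1:3)))
  bs <- bootstrap_support(msa, n_reps = 50, seed = 7)
  bs2 <- bootstrap_support(msa, n_reps = 50, seed = 7)
  expect_identical(bs$support, bs2$support)
  expect_true(all(bs$support >= 0 & bs$support <= 1))
  # the clade split is near-certain
  key <- paste(sort(c("u1", "u2", "u3")), collapse = "|")
  expect_gte(bs$support[[key]], 0.95)
  # input order does not change supports
  bs3 <- bootstrap_support(msa[sample(6)], n_reps = 50, seed = 7)
  expect_identical(bs$support, bs3$support)
  one <- bootstrap_support(msa, n_reps = 1, seed = 1)
  expect_true(all(one$support %in% c(0, 1)))
})

test_that("the superfamily split is recognized and misplacements named", {
  set.seed(77)
  cl1 <- random_msa(4, 300, mut = 0.03)
  set.seed(78)
  cl2 <- random_msa(4, 300, mut = 0.03)
  msa <- c(setNames(cl1, paste0("c", 1:4)), setNames(cl2, paste0("g", 1:4)))
  tree <- neighbor_joining(rt_distance_matrix(msa))
  labels <- setNames(rep(c("COPIA", "GYPSY"), each = 4), names(msa))
  sp <- superfamily_split(tree, labels)
  expect_true(sp$split)
  expect_length(sp$misplaced, 0)
  # on a fixed topology, one mislabeled leaf breaks the split and is named
  fixed <- ape::read.tree(text = "((c1,c2),(c3,c4),((g1,g2),(g3,g4)));")
  expect_true(superfamily_split(fixed, labels)$split)
  wrong <- labels
  wrong["c1"] <- "GYPSY"
  sp2 <- superfamily_split(fixed, wrong)
  expect_false(sp2$split)
  expect_length(sp2$misplaced, 1)  # the single label/topology conflict
  expect_error(superfamily_split(tree, setNames(rep("COPIA", 8), names(msa))),
               "both superfamilies")
})

test_that("families are assigned to the lineage of the nearest reference", {
  set.seed(79)
  refs <- setNames(vapply(1:3, function(i) random_dna(300), ""),
                   c("refAle", "refTat", "refTar"))
  lin <- c(refAle = "Ale", refTat = "Tat", refTar = "TAR")
  # a reference assigned to itself
  self <- assign_lineages(refs["refAle"], refs, lin)
  expect_equal(self$lineage, "Ale")
  expect_equal(self$distance, 0)
  # ~5% diverged copy of a reference
  mut <- ltrdyn:::s2c(refs[["refTat"]])
  sites <- sample(300, 15)
  mut[sites] <- vapply(mut[sites], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  fam <- assign_lineages(c(fam1 = paste(mut, collapse = "")), refs, lin)
  expect_equal(fam$lineage, "Tat")
  # something unrelated to every reference is unassigned
  far <- assign_lineages(c(famX = random_dna(300)), refs, lin,
                         max_distance = 0.5)
  expect_equal(far$lineage, "unassigned")
})

test_that("Newick output round-trips topology and branch lengths", {
  set.seed(80)
  msa <- random_msa(6, 300, mut = 0.08)
  tree <- neighbor_joining(rt_distance_matrix(msa))
  path <- withr::local_tempfile(fileext = ".nwk")
  write_tree(tree, path)
  back <- ape::read.tree(path)
  expect_equal(as.numeric(ape::dist.topo(tree, back)), 0)
  expect_equal(sort(back$edge.length), sort(tree$edge.length),
               tolerance = 1e-9)
})
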