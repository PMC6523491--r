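# The 80-80-80 rule, single-linkage families, and genome proportions.

test_that("identical sequences are linked; partial overlap fails coverage", {
  set.seed(30)
  s <- random_dna(1000)
  pr <- pairwise_8080(s, s)
  expect_equal(pr$identity, 1.0)
  expect_equal(pr$coverage_a, 1.0)
  expect_true(pr$linked)
  # 300 bp shared block between otherwise random 1000-mers: coverage ~0.3
  block <- random_dna(300)
  a <- paste0(random_dna(350), block, random_dna(350))
  b <- paste0(random_dna(350), block, random_dna(350))
  pr2 <- pairwise_8080(a, b)
  expect_lt(pr2$coverage_a, 0.5)
  expect_false(pr2$linked)
  expect_error(pairwise_8080(random_dna(50), random_dna(1000)),
               "not classifiable")
})

test_that("local identities match the brute-force DP oracle on short strings", {
  set.seed(31)
  for (k in 1:25) {
    a <- random_dna(sample(6:12, 1))
    b <- random_dna(sample(6:12, 1))
    st <- ltrdyn:::align_local(a, b)
    expect_equal(st$score, oracle_align_score(a, b, type = "local"),
                 info = paste(a, b))
  }
})

test_that("single linkage takes the transitive closure of pairwise links", {
  set.seed(32)
  A <- random_dna(1000)
  mk <- function(id, seq) ltr_element(id, seq, c(0L, 100L),
                                      c(nchar(seq) - 100L, nchar(seq)))
  # B and C each overlap A well but share only 200 bp with each other
  els <- list(mk("RLC_x_A", A),
              mk("RLC_x_B", substring(A, 1, 600)),
              mk("RLC_x_C", substring(A, 401, 1000)))
  names(els) <- vapply(els, `[[`, "", "element_id")
  expect_false(pairwise_8080(els[[2]]$seq, els[[3]]$seq)$linked)
  expect_true(pairwise_8080(els[[1]]$seq, els[[2]]$seq)$linked)
  fam <- cluster_families(els)
  expect_equal(length(unique(fam$family_id)), 1)
  expect_equal(sort(fam$element_id), sort(names(els)))
})

test_that("clustering is a partition and invariant to input order", {
  sim <- simulate_ltr_dataset(simulation_config(seed = 33, n_families = 3,
                                                copies_per_family = 3,
                                                internal_length = 1200L,
                                                rt_codons = 150L))
  fam1 <- cluster_families(sim$elements)
  expect_setequal(fam1$element_id, names(sim$elements))
  expect_equal(anyDuplicated(fam1$element_id), 0)
  set.seed(1)
  shuffled <- sim$elements[sample(length(sim$elements))]
  fam2 <- cluster_families(shuffled)
  m1 <- fam1[order(fam1$element_id), c("element_id", "family_id")]
  m2 <- fam2[order(fam2$element_id), c("element_id", "family_id")]
  expect_equal(m1, m2, ignore_attr = TRUE)
  # naming: descending size within superfamily, numbered from 1
  sizes <- table(fam1$family_id)
  for (s in unique(fam1$superfamily)) {
    fams <- unique(fam1$family_id[fam1$superfamily == s])
    nums <- as.integer(sub("^RL[CGX]_", "", fams))
    expect_setequal(nums, seq_along(fams))
    ord <- fams[order(nums)]
    expect_true(all(diff(as.integer(sizes[ord])) <= 0))
  }
})

test_that("the prefilter never changes the partition on diverged families", {
  sim <- simulate_ltr_dataset(simulation_config(seed = 34, n_families = 2,
                                                copies_per_family = 3,
                                                internal_length = 1200L,
                                                rt_codons = 150L))
  f_pre <- cluster_families(sim$elements, prefilter = TRUE)
  f_all <- cluster_families(sim$elements, prefilter = FALSE)
  expect_equal(f_pre[order(f_pre$element_id), ],
               f_all[order(f_all$element_id), ], ignore_attr = TRUE)
})

test_that("genome proportions merge overlapping hits before summing", {
  hits <- data.frame(seq_id = "chr1", start = c(1L), end = c(1000L),
                     family_id = "RLC_1")
  expect_equal(genome_proportion(hits, 10000)$proportion, 0.10)
  hits2 <- data.frame(seq_id = "chr1", start = c(1L, 401L), end = c(600L, 1000L),
                      family_id = "RLC_1")
  expect_equal(genome_proportion(hits2, 10000)$bases, 1000)
  expect_error(genome_proportion(data.frame(seq_id = "chr1", start = 1L,
                                            end = 20000L, family_id = "x"),
                                 10000), "outside genome")
  # merged proportions over disjoint family territories cannot exceed 1
  set.seed(35)
  sa <- sample(1:400, 25, TRUE)
  sb <- sample(501:900, 25, TRUE)
  many <- data.frame(seq_id = "chr1", start = c(sa, sb),
                     end = c(pmin(sa + sample(20:100, 25, TRUE), 500L),
                             pmin(sb + sample(20:100, 25, TRUE), 1000L)),
                     family_id = rep(c("A", "B"), each = 25))
  gp <- genome_proportion(many, 1000)
  expect_lte(sum(gp$proportion), 1 + 1e-12)
})

test_that("family mean age and proportion correlate via Spearman rank", {
  fa <- data.frame(family_id = c("A", "B", "C", "D"),
                   mean_age_MY = c(0.5, 1.0, 1.5, 2.0))
  pr <- data.frame(family_id = c("A", "B", "C", "D"),
                   proportion = c(0.01, 0.02, 0.03, 0.04))
  out <- age_proportion_correlation(fa, pr)
  expect_equal(out$rho, 1)
  expect_error(age_proportion_correlation(fa[1:2, ], pr), "at least 3")
})
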