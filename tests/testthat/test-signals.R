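# Structural signals: LTR-pair detection, boundary flags, PBS/tRNA usage,
# PPT, TSD, and boundary position matrices.

fresh_element <- function(seed = 40, trna = NULL, cfg = simulation_config()) {
  set.seed(seed)
  db <- make_trna_db()
  anc <- simulate_ancestor(cfg, 1, db, trna_id = trna %||% db$trna_id[1])
  list(el = anc, db = db)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("exact terminal repeats are detected at their true coordinates", {
  fx <- fresh_element(41)
  det <- detect_ltr_pair(fx$el$seq)
  expect_equal(det$ltr5, fx$el$ltr5)
  expect_equal(det$ltr3, fx$el$ltr3)
  expect_equal(det$identity, 1.0)
})

test_that("aged elements are still detected; random sequence is not", {
  set.seed(42)
  cfg <- simulation_config()
  db <- make_trna_db()
  anc <- simulate_ancestor(cfg, 1, db)
  aged <- age_element(anc, 1e6, cfg)$element  # expected identity ~0.974
  det <- detect_ltr_pair(aged$seq)
  expect_false(is.null(det))
  expect_gte(det$identity, 0.95)
  expect_null(detect_ltr_pair(random_dna(2000)))
})

test_that("boundary flags read exactly the terminal dinucleotides", {
  fx <- fresh_element(43)
  expect_equal(check_boundaries(fx$el), list(starts_TG = TRUE, ends_CA = TRUE))
  mut <- fx$el
  substring(mut$seq, 1, 2) <- "AA"
  expect_equal(check_boundaries(mut), list(starts_TG = FALSE, ends_CA = TRUE))
})

test_that("PBS detection recovers the constructed tRNA and rejects noise", {
  fx <- fresh_element(44)
  met <- fx$db$trna_id[fx$db$amino_acid == "Met"]
  cfg <- simulation_config()
  el <- simulate_ancestor(cfg, 2, fx$db, trna_id = met)
  call <- find_pbs(el, fx$db)
  expect_s3_class(call, "pbs_call")
  expect_equal(call$trna_id, met)
  expect_equal(call$mismatches, 0)
  expect_equal(call$match_length, 12)
  # deterministic: repeated calls identical
  expect_identical(find_pbs(el, fx$db), call)
  # a random internal region yields no call
  set.seed(45)
  rnd <- ltr_element("RLC_7_1", random_dna(2000), c(0L, 300L), c(1700L, 2000L))
  expect_null(find_pbs(rnd, fx$db))
})

test_that("tRNAs sharing an acceptor end are reported as ambiguous", {
  set.seed(46)
  db <- make_trna_db(4)
  db$sequence[2] <- paste0(random_dna(60), substring(db$sequence[1], 61, 72))
  cfg <- simulation_config()
  el <- simulate_ancestor(cfg, 1, db, trna_id = db$trna_id[1])
  call <- find_pbs(el, db)
  expect_setequal(call$amino_acids, db$amino_acid[1:2])
})

test_that("usage tables are proportions over assigned elements", {
  calls <- list(list(amino_acids = "Met", amino_acid = "Met"),
                list(amino_acids = "Met", amino_acid = "Met"),
                list(amino_acids = "Lys", amino_acid = "Lys"),
                NULL)
  u <- trna_usage(calls, rep("COPIA", 4))
  met <- u[u$amino_acid == "Met", ]
  expect_equal(met$proportion, 2 / 3)
  assigned <- u[!u$amino_acid %in% c("none", "ambiguous"), ]
  expect_equal(sum(assigned$proportion), 1)
  expect_error(trna_usage(list(), character(0)), "no PBS")
})

test_that("PPT detection finds the purine run and ignores pyrimidine tracts", {
  fx <- fresh_element(47)
  ppt <- find_ppt(fx$el)
  expect_false(is.null(ppt))
  expect_equal(ppt[2], fx$el$ltr3[1])  # abuts the 3'LTR
  expect_gte(ppt[2] - ppt[1], 10)
  pyr <- ltr_element("RLC_8_1",
                     paste0("TG", random_dna(296), "CA", strrep("CT", 200),
                            "TG", random_dna(296), "CA"),
                     c(0L, 300L), c(700L, 1000L))
  expect_null(find_ppt(pyr))
})

test_that("planted TSDs are recovered and contig edges warn", {
  cfg <- simulation_config(seed = 48, n_families = 2, copies_per_family = 2)
  sim <- simulate_ltr_dataset(cfg)
  pl <- plant_insertions(sim$elements, cfg)
  for (i in seq_len(nrow(pl$loci))) {
    tsd <- find_tsd(pl$genome, c(pl$loci$start[i], pl$loci$end[i]))
    expect_false(is.null(tsd))
    expect_gte(nchar(tsd), cfg$tsd_length)
  }
  expect_warning(out <- find_tsd("ACGTACGTAC", c(1, 6)), "contig edge")
  expect_null(out)
})

test_that("information content spans its 0-2 bit range as expected", {
  # identical flanks: IC 2 at every position
  loci <- data.frame(element_id = paste0("e", 1:5),
                     start = rep(31L, 5), end = rep(100L, 5))
  genome <- random_dna(200)
  bm <- boundary_matrix(loci, genome, flank = 10)
  expect_true(all(abs(bm$upstream$ic - 2) < 1e-12))
  expect_true(all(colSums(bm$upstream$counts) == 5))
  # many uniform random flanks: IC near 0
  set.seed(49)
  genome2 <- random_dna(30000)
  loci2 <- data.frame(element_id = paste0("r", 1:200),
                      start = seq(100L, by = 140L, length.out = 200))
  loci2$end <- loci2$start + 50L
  bm2 <- boundary_matrix(loci2, genome2, flank = 10)
  expect_lt(mean(bm2$upstream$ic), 0.1)
  # fresh planted elements: the TG start gives IC 2 downstream at position 1
  cfg <- simulation_config(seed = 50, n_families = 2, copies_per_family = 2,
                           age_max_MY = 0)
  sim <- simulate_ltr_dataset(cfg)
  pl <- plant_insertions(sim$elements, cfg)
  bm3 <- boundary_matrix(pl$loci, pl$genome)
  expect_equal(bm3$downstream$ic[1], 2)
  expect_equal(bm3$downstream$ic[2], 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_position_matrix(bm3$downstream, path)
  expect_equal(nrow(read.delim(path)), 30)
})
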