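# Codon alignments and Nei-Gojobori dN/dS.

test_that("back-translation maps amino-acid columns to source codons", {
  out <- back_translate_alignment(c(x = "M-K"), c(x = "ATGAAA"))
  expect_equal(unname(out), "ATG---AAA")
  expect_error(back_translate_alignment(c(x = "M-K"), c(x = "ATGCCC")),
               "residue 2")
  expect_error(back_translate_alignment(c(x = "MKK"), c(x = "ATGAAA")),
               "length mismatch")
})

test_that("back-translation round-trips: strip gaps and translate", {
  set.seed(60)
  cds <- vapply(1:4, function(i) ltrdyn:::c2s(
    sample(setdiff(ltrdyn:::sense_codons(), "ATG"), 20, replace = TRUE)), "")
  names(cds) <- paste0("s", 1:4)
  prot <- vapply(cds, function(x)
    paste(ltrdyn:::translate_codon(ltrdyn:::split_codons(x)), collapse = ""), "")
  # introduce a shared gap column to make it a real alignment
  msa <- paste0(substring(prot, 1, 10), "-", substring(prot, 11, 20))
  names(msa) <- names(cds)
  codon_aln <- back_translate_alignment(msa, cds)
  stripped <- gsub("-", "", codon_aln)
  expect_equal(unname(stripped), unname(cds))
})

test_that("NG86 difference counts match hand-derived single-codon cases", {
  # TTT (Phe) -> TTA (Leu): nonsynonymous
  st <- ng86_pair("TTT", "TTA")
  expect_equal(st$Nd, 1)
  expect_equal(st$Sd, 0)
  # GCC (Ala) -> GCA (Ala): synonymous
  st2 <- ng86_pair("GCC", "GCA")
  expect_equal(st2$Sd, 1)
  expect_equal(st2$Nd, 0)
  # identical rows: no differences, omega undefined
  st3 <- ng86_pair("ATGAAA", "ATGAAA")
  expect_equal(st3$flag, "identical")
  expect_true(is.na(st3$omega))
})

test_that("site counts are conserved: S + N = 3 x compared codons", {
  set.seed(61)
  for (k in 1:10) {
    a <- ltrdyn:::c2s(sample(ltrdyn:::sense_codons(), 30, replace = TRUE))
    b <- ltrdyn:::c2s(sample(ltrdyn:::sense_codons(), 30, replace = TRUE))
    st <- ng86_pair(a, b)
    expect_equal(st$S + st$N, 3 * st$n_codons, tolerance = 1e-9)
    # symmetry
    st_rev <- ng86_pair(b, a)
    expect_equal(st$Sd, st_rev$Sd, tolerance = 1e-12)
    expect_equal(st$Nd, st_rev$Nd, tolerance = 1e-12)
  }
})

test_that("pathway counts equal exhaustive enumeration on random codon pairs", {
  set.seed(62)
  codons <- ltrdyn:::sense_codons()
  tested <- 0
  while (tested < 60) {
    c1 <- sample(codons, 1); c2 <- sample(codons, 1)
    oracle <- oracle_ng86_diffs(c1, c2)
    if (is.null(oracle)) next  # all pathways stop-blocked; fallback rule applies
    st <- ng86_pair(c1, c2)
    expect_equal(st$Sd, unname(oracle["syn"]), tolerance = 1e-12,
                 info = paste(c1, c2))
    expect_equal(st$Nd, unname(oracle["nonsyn"]), tolerance = 1e-12,
                 info = paste(c1, c2))
    tested <- tested + 1
  }
  # multi-codon rows: sums of per-codon pathway counts
  for (k in 1:10) {
    a <- sample(codons, 3); b <- sample(codons, 3)
    oracles <- lapply(1:3, function(i) oracle_ng86_diffs(a[i], b[i]))
    if (any(vapply(oracles, is.null, TRUE))) next
    st <- ng86_pair(paste(a, collapse = ""), paste(b, collapse = ""))
    tot <- Reduce(`+`, oracles)
    expect_equal(st$Sd, unname(tot["syn"]), tolerance = 1e-12)
    expect_equal(st$Nd, unname(tot["nonsyn"]), tolerance = 1e-12)
  }
})

test_that("gap-containing codon columns are dropped pairwise", {
  st <- ng86_pair("ATG---AAA", "ATGCCCAAA")
  expect_equal(st$n_codons, 2)
})

test_that("family omega classifies simulated selection regimes", {
  set.seed(63)
  pos <- family_dnds(simulate_family_rt(6, 300, omega = 2.0))
  expect_equal(pos$classification, "positive")
  pur <- family_dnds(simulate_family_rt(6, 300, omega = 0.2))
  expect_equal(pur$classification, "purifying")
  ident <- family_dnds(c(a = "ATGAAACCC", b = "ATGAAACCC"))
  expect_equal(ident$classification, "unestimable")
  expect_error(family_dnds(c(a = "ATG")), "at least 2")
})

test_that("RT trimming finds the longest stop-free frame", {
  set.seed(64)
  clean <- ltrdyn:::c2s(sample(ltrdyn:::sense_codons(), 200, replace = TRUE))
  tr <- rt_trim(clean)
  expect_equal(tr$n_codons, 200)
  expect_equal(tr$seq, clean)
  # a stop splits the frame; the longer side is kept
  broken <- paste0(ltrdyn:::c2s(sample(ltrdyn:::sense_codons(), 60, replace = TRUE)),
                   "TAA",
                   ltrdyn:::c2s(sample(ltrdyn:::sense_codons(), 170, replace = TRUE)))
  tr2 <- rt_trim(broken)
  expect_equal(tr2$n_codons, 170)
  # frame shift by one nucleotide is recovered
  shifted <- paste0("G", clean)
  tr3 <- rt_trim(shifted)
  expect_gte(tr3$n_codons, 199)
  expect_equal(tr3$frame, 1)
  # too short after trimming
  expect_null(rt_trim(paste0(ltrdyn:::c2s(sample(ltrdyn:::sense_codons(), 40,
                                                 replace = TRUE)))))
})
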