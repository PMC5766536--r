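sc <- scoring_scheme()

test_that("labelled libraries round-trip through family-tagged FASTA", {
  lib <- rt_library(c(a = random_protein(30), b = random_protein(40)),
                    c("caulimovirid", "gypsy_decoy"))
  tmp <- withr::local_tempfile(fileext = ".faa")
  write_rt_library(lib, tmp)
  expect_true(any(grepl("^>a family=caulimovirid$", readLines(tmp))))
  lib2 <- read_rt_library(tmp)
  expect_identical(lib2, lib)
})

test_that("stop-free segment enumeration respects frames, stops and the
           length filter", {
  set.seed(41)
  p <- random_protein(240)
  cds <- reverse_translate(p, seed = 42)
  cand <- best_translation(cds, min_len = 200)
  expect_gte(nrow(cand), 1)
  expect_equal(cand$frame[1], 1)
  expect_equal(cand$aa_len[1], 240)
  expect_identical(cand$aa_seq[1], p)

  # a locus whose only long segment is 190 aa fails at min_len = 200
  p190 <- random_protein(190)
  cds190 <- reverse_translate(p190, seed = 43)
  short <- paste0(cds190, "TAA", reverse_translate(random_protein(10),
                                                   seed = 44))
  expect_equal(nrow(best_translation(short, min_len = 200)), 0)
  expect_gte(nrow(best_translation(short, min_len = 150)), 1)

  # internal stop splits a frame; only the long side is returned
  p210 <- random_protein(210)
  p30 <- random_protein(30)
  spl <- paste0(reverse_translate(p210, seed = 45), "TAA",
                reverse_translate(p30, seed = 46))
  cand2 <- best_translation(spl, min_len = 200)
  in_frame1 <- cand2[cand2$frame == 1, ]
  expect_equal(nrow(in_frame1), 1)
  expect_equal(in_frame1$aa_len, 210)
  expect_identical(in_frame1$aa_seq, p210)
})

test_that("protein aligner reproduces published scores and the DP
           oracle", {
  r <- align_protein("MKWV", "MKWV", sc)
  expect_equal(r$score, 25)
  expect_equal(r$aln_len, 4)
  expect_equal(r$identity, 1.0)

  set.seed(47)
  for (i in 1:30) {
    a <- random_protein(sample(20:100, 1))
    b <- if (i %% 2) random_protein(sample(20:100, 1)) else
      mutate_protein(a, 0.3)
    mine <- align_protein(a, b, sc)
    expect_equal(mine$score, oracle_sw_score(a, b))
    full <- oracle_sw_full(a, b)
    expect_equal(mine$aln_len, full$aln_len)
    expect_equal(mine$identity, full$identity)
  }
})

test_that("reciprocal classification separates planted families and
           enforces the alignment-length rule", {
  toy <- toy_reference_package(seed = 77)
  gy <- make_protein_family(3, 240, 0.25, seed = 78, prefix = "gypsy")
  lib <- rt_library(c(toy$proteins, gy),
                    c(rep("caulimovirid", 8), rep("gypsy_decoy", 3)))

  # a decayed caulimovirid copy is accepted
  dm <- decay_model(sub_rate = 0.05, indel_rate = 0, stop_rate = 0,
                    seed = 79)
  dec <- decay(toy$cds[[3]], dm)$seq
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(
    substr(dec, 1, 3 * (nchar(dec) %/% 3))), no.init.codon = TRUE))
  aa <- strsplit(aa, "*", fixed = TRUE)[[1]]
  aa <- aa[which.max(nchar(aa))]
  cl <- reciprocal_classify(aa, lib, sc)
  expect_identical(cl$status, "accepted")
  expect_identical(cl$best_family, "caulimovirid")

  # a decayed decoy is rejected by family
  gy_cds <- reverse_translate(gy[[1]], seed = 80)
  decg <- decay(gy_cds, dm)$seq
  aag <- as.character(Biostrings::translate(Biostrings::DNAString(
    substr(decg, 1, 3 * (nchar(decg) %/% 3))), no.init.codon = TRUE))
  aag <- strsplit(aag, "*", fixed = TRUE)[[1]]
  aag <- aag[which.max(nchar(aag))]
  clg <- reciprocal_classify(aag, lib, sc)
  expect_identical(clg$status, "rejected_family")

  # a short caulimovirid fragment fails the 170-residue rule
  frag <- substr(toy$proteins[[1]], 1, 150)
  clf <- reciprocal_classify(frag, lib, sc)
  expect_identical(clf$best_family, "caulimovirid")
  expect_identical(clf$status, "rejected_length")

  # raising min_aln never grows the accepted set (monotonicity)
  for (m1 in c(100, 170, 220)) {
    c1 <- reciprocal_classify(aa, lib, sc, min_aln = m1)
    c2 <- reciprocal_classify(aa, lib, sc, min_aln = m1 + 30)
    expect_false(c1$status != "accepted" && c2$status == "accepted")
  }

  expect_error(reciprocal_classify(aa, NULL, sc), "empty")
})

test_that("pass-2 eligibility applies the 80%-of-subject rule in base
           pairs", {
  toy <- toy_reference_package(seed = 81)
  lib <- rt_library(toy$proteins, "caulimovirid")
  # the generic threshold for a 240-aa subject is 576 bp
  flank <- generate_background(120, 0.4, seed = 82)
  locus <- paste0(flank, toy$cds[[2]], flank)
  sel <- select_for_placement(locus, lib, sc)
  expect_equal(sel$threshold_nt, 576)
  expect_true(sel$pass2_eligible)
  expect_gte(sel$pass2_aln_len_nt, 576)

  # a fragment spanning only 500 nt of the subject is not eligible
  frag_locus <- paste0(flank, substr(toy$cds[[2]], 1, 500), flank)
  self <- select_for_placement(frag_locus, lib, sc)
  expect_false(self$pass2_eligible)

  # per-subject scaling: a 300-aa subject needs 720 nt
  lib300 <- rt_library(
    setNames(paste0(toy$proteins[[2]], random_protein(60)), "big"),
    "caulimovirid")
  sel300 <- select_for_placement(locus, lib300, sc)
  expect_equal(sel300$threshold_nt, 720)
})

test_that("every locus gets exactly one status and accepted loci are
           caulimovirid with long alignments", {
  b <- local_small_bundle()
  g <- names(b$genomes)[1]
  ts <- translated_search(b$genomes[[g]],
                          setNames(b$library$seq, b$library$id), sc,
                          genome_id = g)
  cl <- classify_loci(ts$loci, b$genomes[[g]], b$library, sc)
  expect_equal(nrow(cl), nrow(ts$loci))
  expect_true(all(cl$status %in% c("accepted", "rejected_family",
                                   "rejected_length", "rejected_no_orf")))
  acc <- cl[cl$status == "accepted", ]
  if (nrow(acc)) {
    expect_true(all(acc$best_family == "caulimovirid"))
    expect_true(all(acc$aln_len_aa >= 170))
  }
})
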