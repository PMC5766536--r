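test_that("background generation honours length, composition and GC", {
  expect_identical(generate_background(0), "")
  expect_error(generate_background(-1), "non-negative")

  g <- generate_background(100, gc = 1.0, seed = 3)
  expect_true(grepl("^[GC]+$", g))

  g <- generate_background(10000, gc = 0.5, seed = 7)
  expect_equal(nchar(g), 10000)
  gc_obs <- mean(strsplit(g, "")[[1]] %in% c("G", "C"))
  # 3 sigma binomial bound at n = 10,000
  expect_lt(abs(gc_obs - 0.5), 0.015)

  # determinism
  expect_identical(g, generate_background(10000, gc = 0.5, seed = 7))
})

test_that("reverse translation round-trips through the standard code", {
  expect_identical(reverse_translate("M"), "ATG")
  expect_identical(reverse_translate("MW"), "ATGTGG")
  expect_error(reverse_translate("MB"), "unknown residue")

  set.seed(11)
  for (i in 1:5) {
    p <- random_protein(50)
    cds <- reverse_translate(p, seed = i)
    expect_equal(nchar(cds), 150)
    back <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                               no.init.codon = TRUE))
    expect_identical(back, p)
  }
})

test_that("decay matches its stated distributions and replays exactly", {
  seq0 <- generate_background(10000, 0.5, seed = 1)

  # identity at zero rates
  d0 <- decay(seq0, decay_model(0, 0, 1, 0, seed = 2))
  expect_identical(d0$seq, seq0)
  expect_equal(nrow(d0$log), 0)

  # substitution fraction within 3 sigma of 0.1 at n = 10,000
  ds <- decay(seq0, decay_model(sub_rate = 0.1, indel_rate = 0,
                                stop_rate = 0, seed = 3))
  expect_equal(nchar(ds$seq), nchar(seq0))
  ham <- mean(strsplit(ds$seq, "")[[1]] != strsplit(seq0, "")[[1]])
  expect_lt(abs(ham - 0.1), 0.01)

  # indel event count inside the Poisson(100) central 99.7% interval
  di <- decay(seq0, decay_model(sub_rate = 0, indel_rate = 0.01,
                                stop_rate = 0, seed = 4))
  n_events <- sum(di$log$kind %in% c("ins", "del"))
  expect_gte(n_events, qpois(0.0015, 100))
  expect_lte(n_events, qpois(0.9985, 100))

  # edit log replays to the output, with all edit kinds active
  dm <- decay_model(sub_rate = 0.05, indel_rate = 0.005, stop_rate = 2,
                    seed = 5)
  dd <- decay(seq0, dm)
  expect_identical(apply_edits(seq0, dd$log), dd$seq)

  # determinism
  expect_identical(decay(seq0, dm)$seq, dd$seq)
})

test_that("forced stops land on the original reading frame", {
  p <- random_protein(200)
  cds <- reverse_translate(p, seed = 6)
  d <- decay(cds, decay_model(sub_rate = 0, indel_rate = 0,
                              stop_rate = 10, seed = 7))
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(d$seq),
                                           no.init.codon = TRUE))
  n_stops <- lengths(regmatches(aa, gregexpr("\\*", aa)))
  expect_equal(n_stops, sum(d$log$kind == "stop"))
})

test_that("planting conserves length and truth intervals round-trip", {
  bg <- generate_background(10000, 0.4, seed = 8)
  none <- plant_insertions(bg, NULL, decay_model(seed = 9), seed = 10)
  expect_identical(none$genome, bg)
  expect_equal(nrow(none$truth), 0)

  p <- random_protein(240)
  cds <- reverse_translate(p, seed = 11)
  donors <- data.frame(id = c("a", "b", "c"),
                       family = c("caulimovirid", "caulimovirid",
                                  "gypsy_decoy"),
                       seq = cds)
  mod <- decay_model(sub_rate = 0.08, indel_rate = 0.002, stop_rate = 1,
                     seed = 12)
  pl <- plant_insertions(bg, donors, mod, seed = 13, genome_id = "g1")
  expect_equal(nchar(pl$genome),
               nchar(bg) + sum(nchar(pl$truth$decayed_seq)))
  # intervals within bounds, pairwise disjoint
  expect_true(all(pl$truth$start >= 0))
  expect_true(all(pl$truth$end <= nchar(pl$genome)))
  tr <- pl$truth[order(pl$truth$start), ]
  expect_true(all(utils::head(tr$end, -1) <= tr$start[-1]))
  # slicing (with strand) reproduces the decayed donor and its edit log
  for (i in seq_len(nrow(tr))) {
    sl <- substr(pl$genome, tr$start[i] + 1, tr$end[i])
    if (tr$strand[i] == "-")
      sl <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(sl)))
    expect_identical(sl, tr$decayed_seq[i])
    donor <- donors$seq[donors$id == tr$donor_id[i]]
    expect_identical(apply_edits(donor, tr$edits[[i]]), sl)
  }

  # 3 donors need 3 distinct cut points; a 1-base background has 2
  expect_error(
    plant_insertions("A", donors, mod, seed = 1),
    "too short")
})

test_that("bundle FASTA/BED outputs are byte-identical across runs", {
  b1 <- make_benchmark_bundle(n_genomes = 1L, genome_length = 2e4,
                              n_caulimo = 2L, n_decoy = 1L, seed = 5L)
  b2 <- make_benchmark_bundle(n_genomes = 1L, genome_length = 2e4,
                              n_caulimo = 2L, n_decoy = 1L, seed = 5L)
  d1 <- withr::local_tempdir()
  f1 <- write_fasta(b1$genomes, file.path(d1, "g1.fa"))
  f2 <- write_fasta(b2$genomes, file.path(d1, "g2.fa"))
  expect_identical(readLines(f1), readLines(f2))
  t1 <- write_bed(b1$truth, file.path(d1, "t1.bed"))
  t2 <- write_bed(b2$truth, file.path(d1, "t2.bed"))
  expect_identical(readLines(t1), readLines(t2))
  expect_equal(sort(unique(b1$library$family)),
               c("caulimovirid", "gypsy_decoy"))
})

test_that("gap runs are inserted without changing length and are found", {
  g <- generate_background(5000, 0.5, seed = 20)
  gg <- insert_gap_runs(g, n_runs = 3, run_len = 100, seed = 21)
  expect_equal(nchar(gg), 5000)
  gr <- gap_ranges(gg)
  expect_equal(sum(gr$end - gr$start), 300)
  expect_true(all(gr$end - gr$start >= 100))
})
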