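sc <- scoring_scheme()

test_that("six-frame translation handles strand, stops and arithmetic", {
  f <- six_frame_translate("ATGAAATGA")
  expect_identical(f[[1]]$aa, "MK*")
  expect_identical(six_frame_translate("CAT")[[4]]$aa, "M")
  # frame +f has floor((n - f + 1) / 3) residues
  s <- generate_background(100, 0.5, seed = 1)
  fr <- six_frame_translate(s)
  for (fobj in fr) {
    f_ <- abs(fobj$frame)
    expect_equal(nchar(fobj$aa), floor((100 - f_ + 1) / 3))
  }
  # N codons become X
  fx <- six_frame_translate("ATGNNNAAA")
  expect_identical(fx[[1]]$aa, "MXK")
})

test_that("frame coordinates map back to the forward strand", {
  s <- "ATGAAATGA"
  # frame -1: reverse complement is TCATTTCAT; residue 0 covers forward
  # bases [6, 9)
  expect_equal(frame_to_forward(-1, 0, 1, 9), c(6L, 9L))
  expect_equal(frame_to_forward(1, 1, 3, 9), c(3L, 9L))
})

test_that("Karlin-Altschul E-values follow the closed form and are
           monotone in score", {
  e <- karlin_evalue(100, 240, 1e6, sc)
  expect_equal(e, 0.041 * 240 * 1e6 * exp(-0.267 * 100))
  s <- seq(50, 150, by = 10)
  ev <- karlin_evalue(s, 240, 1e6, sc)
  expect_true(all(diff(ev) < 0))
})

test_that("a verbatim planted query is recovered as one full-coverage
           HSP matching the Smith-Waterman oracle", {
  set.seed(21)
  prot <- random_protein(240)
  cds <- reverse_translate(prot, seed = 22)
  bg <- generate_background(10000, 0.45, seed = 23)
  pl <- plant_insertions(bg, data.frame(id = "d", family = "caulimovirid",
                                        seq = cds),
                         decay_model(0, 0, 1, 0, seed = 24), seed = 25)
  h <- seeded_search(prot, pl$genome, sc)
  expect_gte(nrow(h), 1)
  top <- h[1, ]
  expect_gte((top$q_end - top$q_start) / 240, 0.95)
  # footprint covers the planted interval
  expect_lte(top$g_start, pl$truth$start + 10)
  expect_gte(top$g_end, pl$truth$end - 10)
  # score equals the full Smith-Waterman score on the right frame
  frames <- six_frame_translate(pl$genome)
  best_sw <- max(vapply(frames, function(fr)
    oracle_sw_score(prot, fr$aa), numeric(1)))
  expect_gte(top$score, best_sw - 1)
})

test_that("no shared seed words means no hits", {
  # tryptophan-rich query vs poly-A genome (translates to poly-K)
  q <- paste(rep("W", 50), collapse = "")
  g <- paste(rep("A", 3000), collapse = "")
  expect_equal(nrow(seeded_search(q, g, sc)), 0)
  expect_equal(nrow(seeded_search(q, "", sc)), 0)
})

test_that("assembly gaps reduce the effective search length", {
  set.seed(26)
  prot <- random_protein(240)
  cds <- reverse_translate(prot, seed = 27)
  bg <- generate_background(20000, 0.45, seed = 28)
  pl <- plant_insertions(bg, data.frame(id = "d", family = "caulimovirid",
                                        seq = cds),
                         decay_model(0, 0, 1, 0, seed = 29), seed = 30)
  gapped <- insert_gap_runs(pl$genome, 1, 5000,
                            seed = 31)
  h <- seeded_search(prot, pl$genome, sc)
  h2 <- seeded_search(prot, gapped, sc)
  if (nrow(h) && nrow(h2) && h$score[1] == h2$score[1]) {
    # same score, smaller effective n, hence smaller E
    expect_lt(h2$evalue[1], h$evalue[1])
  } else {
    succeed("gap overlapped the planted copy; E comparison skipped")
  }
})

test_that("locus merging unions overlaps, keeps touching intervals
           apart, and is idempotent", {
  h <- data.frame(query_id = "q", genome_id = "g",
                  frame = c(1L, -2L, 3L),
                  g_start = c(100L, 350L, 600L),
                  g_end = c(400L, 600L, 800L),
                  q_start = 0L, q_end = 10L, score = c(50, 60, 40),
                  evalue = 1e-10)
  lo <- merge_hit_loci(h[1:2, ])
  expect_equal(nrow(lo), 1)
  expect_equal(c(lo$start, lo$end), c(100L, 600L))
  expect_equal(lo$best_score, 60)
  expect_equal(lo$n_hsps, 2L)

  # half-open touching intervals are not merged
  lo2 <- merge_hit_loci(h[c(2, 3), ])
  expect_equal(nrow(lo2), 2)

  # idempotence against a brute-force union oracle on random sets
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(3:20, 1)
    st <- sample(0:5000, n)
    en <- st + sample(10:500, n, replace = TRUE)
    hh <- data.frame(query_id = "q", genome_id = "g", frame = 1L,
                     g_start = st, g_end = en, q_start = 0L, q_end = 1L,
                     score = runif(n), evalue = 1e-9)
    lo <- merge_hit_loci(hh)
    # brute force: sweep over start-sorted intervals, merging only
    # strict overlaps (touching half-open intervals stay apart)
    o <- order(st)
    m_st <- st[o][1]; m_en <- en[o][1]
    starts <- integer(0); ends <- integer(0)
    for (i in seq_len(n)[-1]) {
      if (st[o][i] < m_en) {
        m_en <- max(m_en, en[o][i])
      } else {
        starts <- c(starts, m_st); ends <- c(ends, m_en)
        m_st <- st[o][i]; m_en <- en[o][i]
      }
    }
    starts <- c(starts, m_st); ends <- c(ends, m_en)
    expect_equal(lo$start, starts)
    expect_equal(lo$end, ends)
    # idempotence: re-merging the loci changes nothing
    hh2 <- data.frame(query_id = "q", genome_id = "g", frame = 1L,
                      g_start = lo$start, g_end = lo$end, q_start = 0L,
                      q_end = 1L, score = lo$best_score, evalue = 1e-9)
    lo3 <- merge_hit_loci(hh2)
    expect_equal(lo3$start, lo$start)
    expect_equal(lo3$end, lo$end)
    # disjoint and sorted
    expect_true(all(diff(lo$start) > 0))
    expect_true(all(utils::head(lo$end, -1) <= lo$start[-1]))
  }
})

test_that("flank extension widens, clamps and re-merges", {
  lo <- data.frame(locus_id = "g:1000-1600", genome_id = "g",
                   start = 1000L, end = 1600L, best_score = 10,
                   n_hsps = 1L, extended = FALSE)
  ex <- extend_loci(lo, flank = 120L, genome_length = 10000L)
  expect_equal(c(ex$start, ex$end), c(880L, 1720L))
  lo2 <- data.frame(locus_id = "g:50-200", genome_id = "g", start = 50L,
                    end = 200L, best_score = 5, n_hsps = 1L,
                    extended = FALSE)
  ex2 <- extend_loci(lo2, flank = 120L, genome_length = 10000L)
  expect_equal(c(ex2$start, ex2$end), c(0L, 320L))
  ex3 <- extend_loci(lo, flank = 0L, genome_length = 10000L)
  expect_equal(c(ex3$start, ex3$end), c(1000L, 1600L))
  # extension-induced overlap re-merges
  both <- rbind(lo, data.frame(locus_id = "g:1700-1900", genome_id = "g",
                               start = 1700L, end = 1900L,
                               best_score = 20, n_hsps = 2L,
                               extended = FALSE))
  ex4 <- extend_loci(both, flank = 120L, genome_length = 10000L)
  expect_equal(nrow(ex4), 1)
  expect_equal(c(ex4$start, ex4$end), c(880L, 2020L))
  expect_equal(ex4$best_score, 20)
  expect_equal(ex4$n_hsps, 3L)
})
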