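sc <- scoring_scheme()

test_that("pairwise identity matches trivial cases and the DP oracle", {
  expect_equal(pairwise_identity("AAAA", "AAAA", sc), 1.0)
  expect_equal(pairwise_identity("AAAA", "AATA", sc), 0.75)

  set.seed(51)
  for (i in 1:25) {
    a <- random_protein(sample(10:50, 1))
    b <- if (i %% 2) random_protein(sample(10:50, 1)) else
      mutate_protein(a, 0.25)
    mine <- pairwise_identity(a, b, sc)
    expect_equal(mine, oracle_overlap(a, b)$identity)
    # symmetry
    expect_equal(mine, pairwise_identity(b, a, sc))
  }
})

test_that("greedy clustering separates families, is deterministic and
           covers every sequence once", {
  set.seed(52)
  famA <- make_protein_family(6, 200, divergence = 0.15, seed = 53,
                              prefix = "A")
  famB <- make_protein_family(5, 220, divergence = 0.15, seed = 54,
                              prefix = "B")
  # verify the construction: families are mutually <= 40% identical
  # over full-length alignments (the core-column metric can spike on
  # accidental short overlaps between unrelated pairs)
  cross <- outer(names(famA), names(famB), Vectorize(function(i, j)
    pairwise_identity(famA[[i]], famB[[j]], sc, mode = "full")))
  expect_lte(max(cross), 0.40)

  cl <- greedy_cluster(c(famA, famB), 0.55, sc)
  expect_equal(length(cl$clusters), 2)
  # exhaustive pairwise-identity check of the partition
  for (clu in cl$clusters) {
    pre <- substr(clu$members, 1, 1)
    expect_equal(length(unique(pre)), 1)
    expect_true(clu$representative %in% clu$members)
  }
  # every sequence in exactly one cluster
  all_members <- unlist(lapply(cl$clusters, `[[`, "members"))
  expect_setequal(all_members, names(c(famA, famB)))
  expect_equal(anyDuplicated(all_members), 0)
  # representative is the longest member
  for (clu in cl$clusters) {
    lens <- nchar(c(famA, famB)[clu$members])
    expect_equal(nchar(c(famA, famB)[[clu$representative]]), max(lens))
  }
  # determinism
  cl2 <- greedy_cluster(c(famA, famB), 0.55, sc)
  expect_identical(cl$membership, cl2$membership)

  # trivial cases
  same <- setNames(rep(random_protein(50), 3), c("x", "y", "z"))
  expect_equal(length(greedy_cluster(same, 0.8, sc)$clusters), 1)
  # distinct sequences whose pairwise identity is verifiably below 1
  # (free-end-gap identity can hit 1.0 on accidental short overlaps)
  repeat {
    distinct <- setNames(replicate(4, random_protein(40)), letters[1:4])
    pid <- utils::combn(4, 2, function(ij)
      pairwise_identity(distinct[[ij[1]]], distinct[[ij[2]]], sc))
    if (max(pid) < 1) break
  }
  expect_equal(length(greedy_cluster(distinct, 1.0, sc)$clusters), 4)
})

test_that("alignment overlap filtering drops sparse rows then gappy
           columns, and is idempotent", {
  set.seed(55)
  core <- random_protein(100)
  msa <- setNames(rep(core, 10), sprintf("s%02d", 1:10))
  expect_identical(unname(unclass(filter_alignment(msa))[1:10]),
                   unname(msa))

  # a row covering only 10% of columns is removed (0.10 < 0.50)
  sparse <- paste0(substr(core, 1, 10),
                   paste(rep("-", 90), collapse = ""))
  msa2 <- c(msa, sparse = sparse)
  f2 <- filter_alignment(msa2)
  expect_true("sparse" %in% attr(f2, "dropped_seqs"))
  expect_false("sparse" %in% names(f2))

  # a column that is gap in 6 of 10 rows is removed (0.4 < 0.5)
  ch <- strsplit(msa, "")
  for (i in 1:6) ch[[i]][50] <- "-"
  msa3 <- setNames(vapply(ch, paste, character(1), collapse = ""),
                   names(msa))
  f3 <- filter_alignment(msa3)
  expect_equal(attr(f3, "dropped_cols"), 50L)
  expect_equal(unique(nchar(f3)), 99L)

  # idempotence
  f3b <- filter_alignment(f3)
  expect_identical(unclass(f3b)[names(f3b)], unclass(f3)[names(f3)])

  # an emptied alignment is flagged, not an error
  allgap <- setNames(rep(paste(rep("-", 20), collapse = ""), 3),
                     c("a", "b", "c"))
  fe <- filter_alignment(allgap)
  expect_true(attr(fe, "emptied"))
})

test_that("similarity network components equal a union-find oracle and
           respect threshold monotonicity", {
  set.seed(56)
  famA <- make_protein_family(4, 150, divergence = 0.12, seed = 57,
                              prefix = "A")
  famB <- make_protein_family(3, 150, divergence = 0.12, seed = 58,
                              prefix = "B")
  net <- build_network(c(famA, famB), 0.55, sc)
  expect_equal(net$n_otus, 2)
  # membership equals brute-force union-find over the same edges
  uf <- oracle_components(names(c(famA, famB)), net$edges)
  for (i in names(uf)) for (j in names(uf)) {
    expect_equal(uf[[i]] == uf[[j]],
                 net$membership[[i]] == net$membership[[j]])
  }
  # no self edges, undirected semantics
  expect_false(any(net$edges$from == net$edges$to))

  # chain a-b, b-c above threshold with a-c below is one component
  p <- random_protein(100)
  a <- p
  b <- mutate_protein(p, 0.25)
  c_ <- mutate_protein(b, 0.25)
  iab <- pairwise_identity(a, b, sc, mode = "full")
  ibc <- pairwise_identity(b, c_, sc, mode = "full")
  iac <- pairwise_identity(a, c_, sc, mode = "full")
  thr <- min(iab, ibc) - 0.01
  if (iac < thr) {
    net2 <- build_network(c(A = a, B = b, C = c_), thr, sc)
    expect_equal(net2$n_otus, 1)
  } else {
    succeed("mutational chain did not produce the a-c dip; skipped")
  }

  # OTU count is non-increasing as the threshold decreases
  thrs <- c(0.9, 0.7, 0.5, 0.3, 0.1)
  counts <- vapply(thrs, function(t)
    build_network(c(famA, famB), t, sc)$n_otus, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("iterated OTU delineation is stable and labels every input", {
  set.seed(59)
  famA <- make_protein_family(5, 160, divergence = 0.15, seed = 60,
                              prefix = "A")
  famB <- make_protein_family(4, 160, divergence = 0.15, seed = 61,
                              prefix = "B")
  del <- delineate_otus(c(famA, famB), cluster_id = 0.55,
                        network_id = 0.35, sc)
  expect_equal(length(unique(del$otus)), 2)
  expect_setequal(names(del$otus), names(c(famA, famB)))
  expect_false(any(is.na(del$otus)))
  # family members share an OTU
  expect_equal(length(unique(del$otus[names(famA)])), 1)
  expect_equal(length(unique(del$otus[names(famB)])), 1)
})
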