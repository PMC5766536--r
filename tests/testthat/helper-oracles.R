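# Independent oracles used across the suite.

aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_protein <- function(len) paste(sample(aa20, len, TRUE), collapse = "")

mutate_protein <- function(p, rate) {
  ch <- strsplit(p, "")[[1]]
  idx <- which(runif(length(ch)) < rate)
  if (length(idx))
    ch[idx] <- vapply(idx, function(j) sample(setdiff(aa20, ch[j]), 1),
                      character(1))
  paste(ch, collapse = "")
}

# Smith-Waterman score via Biostrings (fully independent implementation)
oracle_sw_score <- function(a, b) {
  m <- get_blosum()
  Biostrings::score(Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = m, gapOpening = 11, gapExtension = 1))
}

get_blosum <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

# quadratic-space affine-gap local DP with traceback, plain R: the
# brute-force oracle for alignment length / identity (same tie-break
# convention as the package kernel: zero, then diagonal, then
# horizontal gap, then vertical gap; gap of length g costs open + g*ext)
oracle_sw_full <- function(a, b, gap_open = 11, gap_extend = 1) {
  m <- get_blosum()
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); mm <- length(bv)
  go <- gap_open + gap_extend; ge <- gap_extend
  NEG <- -1e18
  H <- matrix(0, n + 1, mm + 1); E <- matrix(NEG, n + 1, mm + 1)
  F_ <- matrix(NEG, n + 1, mm + 1)
  TB <- matrix(0L, n + 1, mm + 1); TE <- matrix(0L, n + 1, mm + 1)
  TF <- matrix(0L, n + 1, mm + 1)
  best <- 0; bi <- 0; bj <- 0
  for (i in 2:(n + 1)) for (j in 2:(mm + 1)) {
    eo <- H[i, j - 1] - go; ee <- E[i, j - 1] - ge
    E[i, j] <- max(eo, ee); TE[i, j] <- as.integer(ee > eo)
    fo <- H[i - 1, j] - go; fe <- F_[i - 1, j] - ge
    F_[i, j] <- max(fo, fe); TF[i, j] <- as.integer(fe > fo)
    d <- H[i - 1, j - 1] + m[av[i - 1], bv[j - 1]]
    h <- 0; tb <- 0L
    if (d > h) { h <- d; tb <- 1L }
    if (E[i, j] > h) { h <- E[i, j]; tb <- 2L }
    if (F_[i, j] > h) { h <- F_[i, j]; tb <- 3L }
    H[i, j] <- h; TB[i, j] <- tb
    if (h > best) { best <- h; bi <- i; bj <- j }
  }
  i <- bi; j <- bj; cols <- 0; ident <- 0; state <- 0L
  while (i > 1 && j > 1) {
    if (state == 0L) {
      tb <- TB[i, j]
      if (tb == 0L) break
      if (tb == 1L) {
        cols <- cols + 1
        if (av[i - 1] == bv[j - 1]) ident <- ident + 1
        i <- i - 1; j <- j - 1
      } else if (tb == 2L) state <- 2L else state <- 3L
    } else if (state == 2L) {
      cols <- cols + 1
      if (TE[i, j] == 0L) state <- 0L
      j <- j - 1
    } else {
      cols <- cols + 1
      if (TF[i, j] == 0L) state <- 0L
      i <- i - 1
    }
  }
  list(score = best, aln_len = cols,
       identity = if (cols > 0) ident / cols else NA_real_)
}

# overlap (free-end-gap global) DP oracle, same conventions
oracle_overlap <- function(a, b, gap_open = 11, gap_extend = 1) {
  m <- get_blosum()
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); mm <- length(bv)
  go <- gap_open + gap_extend; ge <- gap_extend
  NEG <- -1e18
  H <- matrix(0, n + 1, mm + 1); E <- matrix(NEG, n + 1, mm + 1)
  F_ <- matrix(NEG, n + 1, mm + 1)
  TB <- matrix(0L, n + 1, mm + 1); TE <- matrix(0L, n + 1, mm + 1)
  TF <- matrix(0L, n + 1, mm + 1)
  for (i in 2:(n + 1)) for (j in 2:(mm + 1)) {
    eo <- H[i, j - 1] - go; ee <- E[i, j - 1] - ge
    E[i, j] <- max(eo, ee); TE[i, j] <- as.integer(ee > eo)
    fo <- H[i - 1, j] - go; fe <- F_[i - 1, j] - ge
    F_[i, j] <- max(fo, fe); TF[i, j] <- as.integer(fe > fo)
    d <- H[i - 1, j - 1] + m[av[i - 1], bv[j - 1]]
    h <- d; tb <- 1L
    if (E[i, j] > h) { h <- E[i, j]; tb <- 2L }
    if (F_[i, j] > h) { h <- F_[i, j]; tb <- 3L }
    H[i, j] <- h; TB[i, j] <- tb
  }
  best <- -Inf; bi <- n + 1; bj <- mm + 1
  for (j in 1:(mm + 1)) if (H[n + 1, j] > best) {
    best <- H[n + 1, j]; bi <- n + 1; bj <- j
  }
  for (i in 1:(n + 1)) if (H[i, mm + 1] > best) {
    best <- H[i, mm + 1]; bi <- i; bj <- mm + 1
  }
  i <- bi; j <- bj; cols <- 0; ident <- 0; state <- 0L
  while (i > 1 && j > 1) {
    if (state == 0L) {
      tb <- TB[i, j]
      if (tb == 1L) {
        cols <- cols + 1
        if (av[i - 1] == bv[j - 1]) ident <- ident + 1
        i <- i - 1; j <- j - 1
      } else if (tb == 2L) state <- 2L else state <- 3L
    } else if (state == 2L) {
      cols <- cols + 1
      if (TE[i, j] == 0L) state <- 0L
      j <- j - 1
    } else {
      cols <- cols + 1
      if (TF[i, j] == 0L) state <- 0L
      i <- i - 1
    }
  }
  list(score = best,
       identity = if (cols > 0) ident / cols else 0)
}

# exhaustive ancestral-state enumeration likelihood (GTR+Gamma),
# independent of the pruning implementation
oracle_exhaustive_loglik <- function(tree, model, rows) {
  po <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(po$tip.label)
  nnode <- ntip + po$Nnode
  internals <- (ntip + 1L):nnode
  S <- nchar(rows[[1]])
  enc <- lapply(rows[po$tip.label], function(s)
    match(strsplit(s, "")[[1]], c("A", "C", "G", "T")))
  k <- model$ncat
  nI <- length(internals)
  assign_mat <- as.matrix(expand.grid(rep(list(1:4), nI)))
  colnames(assign_mat) <- as.character(internals)
  total <- 0
  Ps <- lapply(seq_len(k), function(c)
    lapply(seq_len(nrow(po$edge)), function(e)
      gtr_prob(model, po$edge.length[e], model$cat_rates[c])))
  root <- po$edge[nrow(po$edge), 1]
  int_edges <- which(po$edge[, 2] > ntip)
  tip_edges <- which(po$edge[, 2] <= ntip)
  # internal-edge factors are site-independent: precompute per category
  f_int <- lapply(seq_len(k), function(c) {
    f <- model$freq[assign_mat[, as.character(root)]]
    for (e in int_edges) {
      pa <- assign_mat[, as.character(po$edge[e, 1])]
      ch <- assign_mat[, as.character(po$edge[e, 2])]
      f <- f * Ps[[c]][[e]][cbind(pa, ch)]
    }
    f
  })
  tip_pa <- lapply(tip_edges, function(e)
    assign_mat[, as.character(po$edge[e, 1])])
  for (s in seq_len(S)) {
    site_lik <- 0
    for (c in seq_len(k)) {
      f <- f_int[[c]]
      for (ti in seq_along(tip_edges)) {
        e <- tip_edges[ti]
        st <- enc[[po$edge[e, 2]]][s]
        if (is.na(st)) next # gap: sums to 1 over states
        f <- f * Ps[[c]][[e]][tip_pa[[ti]] + 4L * (st - 1L)]
      }
      site_lik <- site_lik + sum(f) / k
    }
    total <- total + log(site_lik)
  }
  total
}

# brute-force best placement edge: graft the query on every edge at a
# grid of pendant lengths and evaluate the full augmented tree with
# tree_loglik
oracle_best_edge <- function(query_row, ref, engine,
                             pendants = seq(0.001, 0.5, length.out = 10)) {
  po <- engine$tree
  best_ll <- -Inf; best_edge <- NA_integer_
  for (e in seq_len(nrow(po$edge))) {
    chi <- po$edge[e, 2]; t <- po$edge.length[e]
    for (pd in pendants) {
      tip <- structure(list(edge = matrix(c(2L, 1L), 1, 2),
                            tip.label = "QUERY__", edge.length = pd,
                            Nnode = 1L), class = "phylo")
      aug <- ape::bind.tree(po, tip, where = chi, position = t / 2)
      ll <- tree_loglik(aug, ref$model, c(ref$msa, QUERY__ = query_row))
      if (ll > best_ll) { best_ll <- ll; best_edge <- e }
    }
  }
  list(edge = best_edge, ll = best_ll)
}

# union-find connected components oracle
oracle_components <- function(nodes, edges) {
  parent <- setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  for (i in seq_len(nrow(edges)))
    parent[[find(edges$from[i])]] <- find(edges$to[i])
  vapply(nodes, find, character(1))
}

# small cached bundle shared by integration tests
local_small_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- make_benchmark_bundle(n_genomes = 2L, genome_length = 6e4,
                                      n_caulimo = 5L, n_decoy = 3L,
                                      seed = 42L)
    cache
  }
})
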