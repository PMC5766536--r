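#' Pairwise protein identity (global alignment, free terminal gaps)
#'
#' Aligns two sequences globally with free end gaps and returns the
#' fraction of identical columns. By default the denominator counts
#' alignment columns excluding terminal-gap columns (`mode = "core"`,
#' closest to centroid-clustering defaults); `mode = "full"` divides by
#' all columns including terminal gaps.
#'
#' @param a,b non-empty amino-acid sequences.
#' @param scoring a [scoring_scheme()].
#' @param mode identity denominator, `"core"` or `"full"`.
#' @return identity fraction in `[0, 1]`; symmetric in its arguments.
#' @export
pairwise_identity <- function(a, b, scoring = scoring_scheme(),
                              mode = c("core", "full")) {
  mode <- match.arg(mode)
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  r <- cpp_overlap_align(encode_seq(a, scoring$lookup),
                         encode_seq(b, scoring$lookup),
                         scoring$matrix, scoring$gap_open, scoring$gap_extend)
  den <- if (mode == "core") r$cols_core else r$cols_core + r$lead + r$trail
  if (den == 0) return(0)
  r$n_ident / den
}

#' Greedy centroid clustering at an identity threshold
#'
#' Sequences are processed in order of decreasing length (ties broken
#' by lexicographic id). Each sequence joins the first existing
#' centroid with [pairwise_identity()] at or above the threshold,
#' otherwise it founds a new cluster. The representative of each
#' cluster is its longest member. The procedure is deterministic.
#'
#' @param seqs named character vector of amino-acid sequences.
#' @param threshold identity threshold in `(0, 1]` (0.80 for
#'   within-species clustering, 0.55 for the global round).
#' @param scoring a [scoring_scheme()].
#' @param mode identity mode passed to [pairwise_identity()].
#' @return list of class `otu_clusters`: `clusters` (list of
#'   `members`, `representative`, `level`), `membership` (data.frame
#'   `id`, `cluster`, `representative`), `level`.
#' @export
greedy_cluster <- function(seqs, threshold, scoring = scoring_scheme(),
                           mode = "core") {
  stopifnot(threshold > 0, threshold <= 1, !is.null(names(seqs)))
  ids <- names(seqs)[order(-nchar(seqs), names(seqs))]
  centroids <- character(0)
  members <- list()
  for (id in ids) {
    joined <- FALSE
    for (ci in seq_along(centroids)) {
      if (pairwise_identity(seqs[[id]], seqs[[centroids[ci]]], scoring,
                            mode) >= threshold) {
        members[[ci]] <- c(members[[ci]], id)
        joined <- TRUE
        break
      }
    }
    if (!joined) {
      centroids <- c(centroids, id)
      members[[length(centroids)]] <- id
    }
  }
  clusters <- lapply(seq_along(centroids), function(ci) {
    mem <- members[[ci]]
    rep <- mem[order(-nchar(seqs[mem]), mem)][1]
    list(members = mem, representative = rep, level = threshold)
  })
  membership <- do.call(rbind, lapply(seq_along(clusters), function(ci)
    data.frame(id = clusters[[ci]]$members, cluster = ci,
               representative = clusters[[ci]]$representative)))
  structure(list(clusters = clusters, membership = membership,
                 level = threshold), class = "otu_clusters")
}

#' @export
print.otu_clusters <- function(x, ...) {
  cat("otu_clusters:", length(x$clusters), "clusters at identity >=",
      x$level, "\n")
  invisible(x)
}

#' Two-round overlap filtering of an alignment (trimAl-style)
#'
#' Round 1 drops sequences whose fraction of well-supported residues is
#' below `seq_overlap`, where a residue is well supported if at least
#' `res_overlap` of the other sequences are non-gap in its column.
#' Round 2 drops columns whose non-gap fraction is below
#' `gap_threshold`. Round 3 repeats round 1 on the reduced alignment.
#'
#' @param msa named character vector of aligned sequences (equal
#'   length, `-` for gaps), at least 2 sequences.
#' @param res_overlap column-support fraction for a residue (default
#'   0.75).
#' @param seq_overlap minimum fraction of supported residues per
#'   sequence (default 0.50).
#' @param gap_threshold minimum non-gap fraction per column (default
#'   0.50).
#' @return filtered alignment (named character vector) with attributes
#'   `dropped_seqs`, `dropped_cols` and `emptied` (TRUE if nothing
#'   survived; never an error).
#' @export
filter_alignment <- function(msa, res_overlap = 0.75, seq_overlap = 0.50,
                             gap_threshold = 0.50) {
  stopifnot(length(msa) >= 2L, length(unique(nchar(msa))) == 1L,
            !is.null(names(msa)))
  M <- do.call(rbind, strsplit(msa, ""))
  rownames(M) <- names(msa)
  dropped_seqs <- character(0)

  drop_round <- function(M) {
    if (nrow(M) < 2L) return(rep(TRUE, nrow(M)))
    nongap <- M != "-"
    colcov <- colSums(nongap)
    keep <- logical(nrow(M))
    for (i in seq_len(nrow(M))) {
      res <- which(nongap[i, ])
      if (!length(res)) { keep[i] <- FALSE; next }
      support <- (colcov[res] - 1) / (nrow(M) - 1)
      # fraction of alignment columns holding a well-supported residue
      keep[i] <- sum(support >= res_overlap) / ncol(M) >= seq_overlap
    }
    keep
  }

  k1 <- drop_round(M)
  dropped_seqs <- c(dropped_seqs, rownames(M)[!k1])
  M <- M[k1, , drop = FALSE]
  dropped_cols <- integer(0)
  if (nrow(M) > 0L) {
    nongap_frac <- colMeans(M != "-")
    dropped_cols <- which(nongap_frac < gap_threshold)
    if (length(dropped_cols)) M <- M[, -dropped_cols, drop = FALSE]
  }
  if (nrow(M) >= 2L && ncol(M) > 0L) {
    k3 <- drop_round(M)
    dropped_seqs <- c(dropped_seqs, rownames(M)[!k3])
    M <- M[k3, , drop = FALSE]
  }
  emptied <- nrow(M) == 0L || ncol(M) == 0L
  out <- if (emptied) setNames(character(0), character(0)) else
    setNames(apply(M, 1, paste, collapse = ""), rownames(M))
  structure(out, dropped_seqs = dropped_seqs,
            dropped_cols = dropped_cols, emptied = emptied)
}

#' Similarity network over representative sequences
#'
#' Adds an undirected edge between every pair of representatives whose
#' [pairwise_identity()] reaches the threshold; operational taxonomic
#' units are the connected components. Component labels are stable:
#' components are numbered by their lexicographically smallest member.
#'
#' The default identity mode is `"full"` (denominator includes
#' terminal-gap columns): network nodes may be entirely unrelated
#' families, and the core-column identity can reach 1.0 on accidental
#' short overlaps between unrelated pairs, which would wire spurious
#' edges. Cluster membership, by contrast, compares homologous
#' fragments and keeps the length-tolerant `"core"` mode.
#'
#' @param reps named character vector of representative sequences.
#' @param threshold edge identity threshold.
#' @param scoring a [scoring_scheme()].
#' @param mode identity mode passed to [pairwise_identity()].
#' @return list of class `similarity_network`: `edges` (data.frame
#'   `from`, `to`, `identity`), `membership` (named character vector of
#'   OTU labels), `n_otus`, `graph` (igraph object).
#' @export
build_network <- function(reps, threshold, scoring = scoring_scheme(),
                          mode = "full") {
  stopifnot(length(reps) >= 1L, !is.null(names(reps)))
  ids <- names(reps)
  pairs <- if (length(ids) > 1L) utils::combn(ids, 2L) else
    matrix(character(0), 2, 0)
  from <- character(0); to <- character(0); idn <- numeric(0)
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    pid <- pairwise_identity(reps[[i]], reps[[j]], scoring, mode)
    if (pid >= threshold) {
      from <- c(from, i); to <- c(to, j); idn <- c(idn, pid)
    }
  }
  edges <- data.frame(from = from, to = to, identity = idn)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = ids))
  comp <- igraph::components(g)
  # stable labels: order components by smallest member id
  mins <- tapply(names(comp$membership), comp$membership, min)
  lab <- setNames(sprintf("OTU_%02d", order(order(mins))), names(mins))
  membership <- setNames(unname(lab[as.character(comp$membership)]),
                         names(comp$membership))
  structure(list(edges = edges, membership = membership,
                 n_otus = comp$no, graph = g),
            class = "similarity_network")
}

#' @export
print.similarity_network <- function(x, ...) {
  cat("similarity_network:", length(x$membership), "nodes,",
      nrow(x$edges), "edges,", x$n_otus, "OTUs\n")
  invisible(x)
}

#' Delineate OTUs by iterated clustering and network components
#'
#' Clusters the input at `cluster_id`, takes cluster representatives,
#' and re-clusters until the representative set is stable; the final
#' representatives are joined into a similarity network whose connected
#' components are the OTUs.
#'
#' @param seqs named character vector of amino-acid sequences.
#' @param cluster_id greedy-clustering identity threshold (default
#'   0.55).
#' @param network_id network edge threshold (default 0.35).
#' @param scoring a [scoring_scheme()].
#' @return list with `clusters` (final [greedy_cluster()] result),
#'   `network` ([build_network()] result) and `otus` (named character
#'   vector: input id -> OTU label, via its representative).
#' @export
delineate_otus <- function(seqs, cluster_id = 0.55, network_id = 0.35,
                           scoring = scoring_scheme()) {
  rep_map <- setNames(names(seqs), names(seqs))
  current <- seqs
  repeat {
    cl <- greedy_cluster(current, cluster_id, scoring)
    rep_of <- setNames(cl$membership$representative, cl$membership$id)
    rep_map <- setNames(unname(rep_of[rep_map]), names(rep_map))
    reps <- unique(unname(rep_of))
    if (setequal(reps, names(current))) break
    current <- seqs[reps]
  }
  net <- build_network(seqs[reps], network_id, scoring)
  otus <- setNames(unname(net$membership[rep_map]), names(seqs))
  list(clusters = cl, network = net, otus = otus)
}
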