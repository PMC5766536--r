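#' Precomputed placement engine for a reference package
#'
#' Computes, once per reference, the per-edge conditional likelihood
#' messages needed to attach a query at the midpoint of any edge:
#' the clade-side partial and the rest-of-tree partial, both propagated
#' half an edge length towards the attachment point, combined with the
#' stationary frequencies. Placing a query then only requires the
#' query-side message as a function of the pendant branch length.
#'
#' @param ref a [reference_package()].
#' @return an object of class `placement_engine`.
#' @export
placement_engine <- function(ref) {
  stopifnot(inherits(ref, "reference_package"))
  model <- ref$model
  k <- model$ncat
  S <- ref$width
  po <- ape::reorder.phylo(ref$tree, "postorder")
  ntip <- length(po$tip.label)
  nnode <- ntip + po$Nnode
  enc <- encode_nt_rows(ref$msa[po$tip.label])
  tip_partial <- function(i) {
    v <- enc[[i]]
    M <- matrix(0, 4, S)
    ok <- !is.na(v)
    M[cbind(v[ok], which(ok))] <- 1
    M[, !ok] <- 1
    M
  }
  down <- vector("list", nnode)
  for (i in seq_len(ntip)) down[[i]] <- rep(list(tip_partial(i)), k)
  edge <- po$edge
  elen <- po$edge.length
  nE <- nrow(edge)
  Pm <- vector("list", nE) # P(t) per category per edge
  msg <- vector("list", nE) # P(t) %*% down[child]
  for (e in seq_len(nE)) {
    chi <- edge[e, 2]
    Pm[[e]] <- lapply(seq_len(k), function(c)
      gtr_prob(model, elen[e], model$cat_rates[c]))
    if (!is.null(down[[chi]])) {
      msg[[e]] <- lapply(seq_len(k), function(c)
        Pm[[e]][[c]] %*% down[[chi]][[c]])
      par <- edge[e, 1]
      down[[par]] <- if (is.null(down[[par]])) msg[[e]] else
        lapply(seq_len(k), function(c) down[[par]][[c]] * msg[[e]][[c]])
    }
  }
  # postorder guarantees children edges precede parents, but the msg for
  # an edge may have been skipped if down[child] was not ready (cannot
  # happen in postorder); recompute defensively
  for (e in seq_len(nE)) if (is.null(msg[[e]])) {
    chi <- edge[e, 2]
    msg[[e]] <- lapply(seq_len(k), function(c)
      Pm[[e]][[c]] %*% down[[chi]][[c]])
  }
  root <- edge[nE, 1]
  # rest-of-tree partials by preorder
  up <- vector("list", nnode)
  up[[root]] <- rep(list(matrix(1, 4, S)), k)
  for (e in rev(seq_len(nE))) {
    par <- edge[e, 1]; chi <- edge[e, 2]
    sibs <- which(edge[, 1] == par & edge[, 2] != chi)
    A <- up[[par]]
    for (s in sibs)
      A <- lapply(seq_len(k), function(c) A[[c]] * msg[[s]][[c]])
    up[[chi]] <- lapply(seq_len(k), function(c) Pm[[e]][[c]] %*% A[[c]])
    # store the un-propagated rest message for midpoint attachment
    attr(up[[chi]], "at_parent") <- A
  }
  # per-edge midpoint weights W_e = freq * P(t/2) rest * P(t/2) clade
  W <- vector("list", nE)
  for (e in seq_len(nE)) {
    chi <- edge[e, 2]
    A <- attr(up[[chi]], "at_parent")
    W[[e]] <- lapply(seq_len(k), function(c) {
      Ph <- gtr_prob(model, elen[e] / 2, model$cat_rates[c])
      (model$freq * (Ph %*% A[[c]])) * (Ph %*% down[[chi]][[c]])
    })
  }
  # reference-tree site likelihoods (for gap-site contributions)
  site_ref <- Reduce(`+`, lapply(seq_len(k), function(c)
    colSums(model$freq * down[[root]][[c]]))) / k
  edge_label <- vapply(seq_len(nE), function(e) {
    chi <- edge[e, 2]
    if (chi <= ntip) po$tip.label[chi] else sprintf("node%d", chi)
  }, character(1))
  structure(list(ref = ref, tree = po, edge = edge, elen = elen,
                 W = W, ncat = k, S = S, model = model,
                 edge_label = edge_label, site_ref = site_ref,
                 ntip = ntip),
            class = "placement_engine")
}

#' Align a query fragment into the reference column space
#'
#' Pairwise overlap alignment (global with free end gaps) of the query
#' against its best-matching ungapped reference row, on the better of
#' the two strands, then projection onto reference alignment columns.
#' Query residues falling in insertions relative to the reference are
#' dropped (keep-length semantics), so the output row has exactly the
#' reference alignment length. A query sharing no `seed_k`-mer with any
#' reference row is flagged unalignable.
#'
#' @param query nucleotide sequence (character).
#' @param ref a [reference_package()].
#' @param seed_k exact nucleotide k-mer required to attempt alignment
#'   (default 8).
#' @return list with `row` (character, reference width), `ref_row`,
#'   `strand`, `score`; or `NULL` if unalignable.
#' @export
add_fragment <- function(query, ref, seed_k = 8L) {
  stopifnot(nchar(query) > 0)
  ungapped <- gsub("-", "", ref$msa)
  q_fwd <- toupper(query)
  q_rev <- revcomp(q_fwd)
  kmers <- function(s) {
    n <- nchar(s)
    if (n < seed_k) return(character(0))
    unique(substring(s, 1:(n - seed_k + 1L), seed_k:n))
  }
  qk <- list(`+` = kmers(q_fwd), `-` = kmers(q_rev))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = FALSE)
  best <- NULL
  for (nm in names(ungapped)) {
    rk <- kmers(ungapped[[nm]])
    for (strand in c("+", "-")) {
      if (!length(intersect(qk[[strand]], rk))) next
      q <- if (strand == "+") q_fwd else q_rev
      al <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(q), Biostrings::DNAString(ungapped[[nm]]),
        type = "overlap", substitutionMatrix = mat,
        gapOpening = 5, gapExtension = 2)
      sc <- Biostrings::score(al)
      if (is.null(best) || sc > best$score)
        best <- list(score = sc, ref_row = nm, strand = strand, aln = al)
    }
  }
  if (is.null(best)) return(NULL)
  # projection: walk alignment columns; ref-row positions map to
  # reference alignment columns
  refrow_chars <- strsplit(ref$msa[[best$ref_row]], "")[[1]]
  col_of <- which(refrow_chars != "-")
  ap <- strsplit(as.character(Biostrings::alignedPattern(best$aln)), "")[[1]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(best$aln)), "")[[1]]
  s_off <- Biostrings::start(Biostrings::subject(best$aln)) - 1L
  out <- rep("-", ref$width)
  r <- s_off
  for (i in seq_along(ap)) {
    if (as_[i] != "-") {
      r <- r + 1L
      if (ap[i] != "-") out[col_of[r]] <- ap[i]
    }
    # query char over a subject gap = insertion relative to reference:
    # dropped (keep-length)
  }
  list(row = paste(out, collapse = ""), ref_row = best$ref_row,
       strand = best$strand, score = best$score)
}

#' Maximum-likelihood placement of an aligned query on the reference
#' tree
#'
#' Attaches the query at the midpoint of every reference edge by a
#' pendant branch whose length is optimized by golden-section search
#' (tolerance 1e-4), keeps the single best edge, and reports the
#' like-weight ratio (LWR): the exp-normalized likelihood of the best
#' edge over all evaluated edges.
#'
#' @param aligned_query character row in reference column space (from
#'   [add_fragment()]).
#' @param ref a [reference_package()] (ignored when `engine` is given).
#' @param engine optional [placement_engine()], reused across queries.
#' @return one-row data.frame: `edge_id` (index in the engine's
#'   postorder edge table), `edge_label`, `pendant_length`,
#'   `attach_position` (fixed at 0.5), `log_likelihood`, `lwr`.
#' @export
place_query <- function(aligned_query, ref = NULL, engine = NULL) {
  if (is.null(engine)) engine <- placement_engine(ref)
  v <- encode_nt_rows(list(aligned_query))[[1]]
  stopifnot(length(v) == engine$S)
  nE <- nrow(engine$edge)
  lls <- numeric(nE)
  pend <- numeric(nE)
  for (e in seq_len(nE)) {
    op <- place_query_edge(aligned_query, engine, e)
    lls[e] <- op$ll
    pend[e] <- op$pendant
  }
  best <- which.max(lls)
  lwr <- exp(lls - max(lls))
  lwr <- lwr / sum(lwr)
  data.frame(edge_id = best, edge_label = engine$edge_label[best],
             pendant_length = pend[best], attach_position = 0.5,
             log_likelihood = lls[best], lwr = lwr[best])
}

#' Like-weight ratios across all edges for one query
#'
#' Same computation as [place_query()] but returning the full
#' normalized vector (sums to 1 before keep-at-most truncation).
#'
#' @inheritParams place_query
#' @return numeric vector of LWRs, one per edge.
#' @export
placement_lwr_profile <- function(aligned_query, ref = NULL, engine = NULL) {
  if (is.null(engine)) engine <- placement_engine(ref)
  res <- place_query_all(aligned_query, engine)
  lwr <- exp(res$ll - max(res$ll))
  lwr / sum(lwr)
}

# internal: per-edge optimized log-likelihoods
place_query_all <- function(aligned_query, engine) {
  nE <- nrow(engine$edge)
  ll <- vapply(seq_len(nE), function(e) {
    r <- place_query_edge(aligned_query, engine, e)
    r$ll
  }, numeric(1))
  list(ll = ll)
}

# internal: optimize the pendant on one edge
place_query_edge <- function(aligned_query, engine, e) {
  model <- engine$model
  k <- engine$ncat
  S <- engine$S
  v <- encode_nt_rows(list(aligned_query))[[1]]
  Lq <- matrix(0, 4, S)
  ok <- !is.na(v)
  Lq[cbind(v[ok], which(ok))] <- 1
  Lq[, !ok] <- 1
  f <- function(p) {
    acc <- numeric(S)
    for (c in seq_len(k)) {
      C <- gtr_prob(model, p, model$cat_rates[c]) %*% Lq
      acc <- acc + colSums(engine$W[[e]][[c]] * C)
    }
    sl <- acc / k
    if (any(sl <= 0)) return(-Inf)
    sum(log(sl))
  }
  gr <- (sqrt(5) - 1) / 2
  a <- 1e-9; b <- 4
  c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
  f1 <- f(c1); f2 <- f(c2)
  while (b - a > 1e-4) {
    if (f1 < f2) {
      a <- c1; c1 <- c2; f1 <- f2; c2 <- a + gr * (b - a); f2 <- f(c2)
    } else {
      b <- c2; c2 <- c1; f2 <- f1; c1 <- b - gr * (b - a); f1 <- f(c1)
    }
  }
  x <- (a + b) / 2
  list(ll = f(x), pendant = x)
}

#' OTU label for a placement
#'
#' If every leaf on the leafward side of the attachment edge maps to a
#' single OTU, that OTU is returned; otherwise the placement is on an
#' inner edge and labelled `"inner"`.
#'
#' @param result one-row data.frame from [place_query()].
#' @param ref a [reference_package()].
#' @param engine the [placement_engine()] that produced `result`.
#' @return character: OTU label or `"inner"`.
#' @export
classify_placement <- function(result, ref, engine = NULL) {
  if (is.null(engine)) engine <- placement_engine(ref)
  chi <- engine$edge[result$edge_id, 2]
  tips <- descendant_tips(engine$tree, chi)
  map <- setNames(ref$otu_map$otu, ref$otu_map$leaf)
  otus <- unique(unname(map[tips]))
  if (length(otus) == 1L) otus else "inner"
}

#' Place a set of query fragments and assign OTU labels
#'
#' Runs [add_fragment()], [place_query()] and [classify_placement()]
#' for every query; unalignable queries are reported with status
#' `"unalignable"` and no placement. Exactly one placement is kept per
#' query (keep-at-most 1).
#'
#' @param queries named character vector of nucleotide fragments.
#' @param ref a [reference_package()].
#' @return data.frame: `query_id`, `status` (`placed`/`unalignable`),
#'   `edge_id`, `edge_label`, `pendant_length`, `log_likelihood`,
#'   `lwr`, `otu_label`.
#' @export
place_queries <- function(queries, ref) {
  engine <- placement_engine(ref)
  rows <- lapply(names(queries), function(qid) {
    fr <- add_fragment(queries[[qid]], ref)
    if (is.null(fr))
      return(data.frame(query_id = qid, status = "unalignable",
                        edge_id = NA_integer_, edge_label = NA_character_,
                        pendant_length = NA_real_,
                        log_likelihood = NA_real_, lwr = NA_real_,
                        otu_label = NA_character_))
    res <- place_query(fr$row, engine = engine)
    data.frame(query_id = qid, status = "placed", edge_id = res$edge_id,
               edge_label = res$edge_label,
               pendant_length = res$pendant_length,
               log_likelihood = res$log_likelihood, lwr = res$lwr,
               otu_label = classify_placement(res, ref, engine))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write placements as jplace-style JSON
#'
#' @param placements data.frame from [place_queries()].
#' @param ref a [reference_package()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_jplace <- function(placements, ref, path) {
  placed <- placements[placements$status == "placed", , drop = FALSE]
  obj <- list(
    version = 3,
    tree = ape::write.tree(ref$tree),
    fields = c("edge_num", "likelihood", "like_weight_ratio",
               "pendant_length"),
    placements = lapply(seq_len(nrow(placed)), function(i) list(
      p = list(list(placed$edge_id[i], placed$log_likelihood[i],
                    placed$lwr[i], placed$pendant_length[i])),
      n = list(placed$query_id[i]))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
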