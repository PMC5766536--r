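#' General time-reversible substitution model with discrete-gamma rates
#'
#' Builds a GTR rate matrix from exchangeabilities and base frequencies,
#' normalized to one expected substitution per site per unit branch
#' length, with gamma rate heterogeneity discretized into `ncat`
#' equal-probability categories (category means, Yang 1994).
#'
#' @param rates six exchangeabilities in the order AC, AG, AT, CG, CT, GT.
#' @param freq base frequencies (A, C, G, T), summing to 1.
#' @param alpha gamma shape; rate variation vanishes as `alpha` grows.
#' @param ncat number of discrete gamma categories.
#' @return an object of class `gtr_model` with the eigendecomposition
#'   needed for transition probabilities.
#' @export
gtr_model <- function(rates = c(1, 1, 1, 1, 1, 1),
                      freq = c(0.25, 0.25, 0.25, 0.25),
                      alpha = 1, ncat = 4L) {
  stopifnot(length(rates) == 6L, all(rates > 0), length(freq) == 4L,
            all(freq > 0), abs(sum(freq) - 1) < 1e-8, alpha > 0, ncat >= 1L)
  R <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                       c("A", "C", "G", "T")))
  R[1, 2] <- R[2, 1] <- rates[1]
  R[1, 3] <- R[3, 1] <- rates[2]
  R[1, 4] <- R[4, 1] <- rates[3]
  R[2, 3] <- R[3, 2] <- rates[4]
  R[2, 4] <- R[4, 2] <- rates[5]
  R[3, 4] <- R[4, 3] <- rates[6]
  Q <- R %*% diag(freq)
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freq * diag(Q))
  Q <- Q / mu
  # symmetrize for a stable eigendecomposition
  sp <- sqrt(freq)
  B <- diag(sp) %*% Q %*% diag(1 / sp)
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  U <- diag(1 / sp) %*% eig$vectors
  Uinv <- t(eig$vectors) %*% diag(sp)
  cr <- discrete_gamma_rates(alpha, ncat)
  structure(list(Q = Q, freq = freq, rates = rates, alpha = alpha,
                 ncat = as.integer(ncat), cat_rates = cr,
                 U = U, Uinv = Uinv, eigval = eig$values),
            class = "gtr_model")
}

#' Discrete gamma category rates (mean of equal-probability bins)
#'
#' @param alpha gamma shape (mean fixed at 1).
#' @param ncat number of categories.
#' @return numeric vector of category rates with mean 1.
#' @export
discrete_gamma_rates <- function(alpha, ncat) {
  if (ncat == 1L) return(1)
  b <- qgamma(seq(0, 1, length.out = ncat + 1), shape = alpha, rate = alpha)
  ncat * diff(pgamma(b, shape = alpha + 1, rate = alpha))
}

#' Transition probability matrix P(t) under a GTR model
#'
#' @param model a [gtr_model()].
#' @param t branch length in expected substitutions per site.
#' @param rate rate multiplier (gamma category rate).
#' @return 4x4 matrix of transition probabilities.
#' @export
gtr_prob <- function(model, t, rate = 1) {
  P <- model$U %*% (exp(model$eigval * t * rate) * model$Uinv)
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Simulate nucleotide sequences along a tree under GTR+Gamma
#'
#' Sites evolve independently; each site draws one gamma category for
#' the whole tree. Produces gap-free aligned sequences, one per tip.
#'
#' @param tree an [ape::phylo] with branch lengths.
#' @param model a [gtr_model()].
#' @param nsites number of alignment columns.
#' @param seed integer RNG seed.
#' @param root_seq optional root sequence (character string of A/C/G/T)
#'   instead of a stationary draw.
#' @return named character vector of tip sequences.
#' @export
simulate_gtr <- function(tree, model, nsites, seed = 1L, root_seq = NULL) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  tree <- ape::reorder.phylo(tree, "cladewise")
  cat_of <- sample.int(model$ncat, nsites, replace = TRUE)
  states <- matrix(NA_integer_, nnode, nsites)
  root <- ntip + 1L
  if (is.null(root_seq)) {
    states[root, ] <- sample.int(4L, nsites, replace = TRUE, prob = model$freq)
  } else {
    stopifnot(nchar(root_seq) == nsites)
    states[root, ] <- match(strsplit(root_seq, "")[[1]], bases)
  }
  Ps <- lapply(seq_len(model$ncat), function(c) model$cat_rates[c])
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1]; chi <- tree$edge[e, 2]
    t <- tree$edge.length[e]
    for (c in seq_len(model$ncat)) {
      P <- gtr_prob(model, t, model$cat_rates[c])
      for (s in 1:4) {
        idx <- which(cat_of == c & states[par, ] == s)
        if (length(idx))
          states[chi, idx] <- sample.int(4L, length(idx), replace = TRUE,
                                         prob = P[s, ])
      }
    }
  }
  out <- apply(states[seq_len(ntip), , drop = FALSE], 1,
               function(r) paste(bases[r], collapse = ""))
  names(out) <- tree$tip.label
  out
}

# encode aligned nucleotide rows as 1..4 integers, NA for gaps/ambiguity
encode_nt_rows <- function(rows) {
  lapply(rows, function(s) {
    v <- match(strsplit(toupper(s), "")[[1]], c("A", "C", "G", "T"))
    v
  })
}

#' Log-likelihood of an alignment on a tree (Felsenstein pruning)
#'
#' Computes the phylogenetic log-likelihood of aligned nucleotide rows
#' under GTR+Gamma by the pruning algorithm with per-node rescaling.
#' Gaps and ambiguity codes are treated as missing data. The value is
#' invariant to the rooting of the tree.
#'
#' @param tree an [ape::phylo] with branch lengths; tip labels must name
#'   rows of `rows`.
#' @param model a [gtr_model()].
#' @param rows named character vector of aligned sequences (equal
#'   length), covering all tips.
#' @return total log-likelihood (numeric scalar).
#' @export
tree_loglik <- function(tree, model, rows) {
  stopifnot(all(tree$tip.label %in% names(rows)))
  S <- unique(nchar(rows[tree$tip.label]))
  stopifnot(length(S) == 1L)
  if (S == 0L) stop("zero-length alignment")
  enc <- encode_nt_rows(rows[tree$tip.label])
  po <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(po$tip.label)
  nnode <- ntip + po$Nnode
  k <- model$ncat
  # partials[[node]][[cat]] : 4 x S
  partials <- vector("list", nnode)
  scaler <- numeric(S) # accumulated log-scalers (shared across nodes)
  tip_partial <- function(i) {
    v <- enc[[i]]
    M <- matrix(0, 4, S)
    ok <- !is.na(v)
    M[cbind(v[ok], which(ok))] <- 1
    M[, !ok] <- 1
    M
  }
  for (i in seq_len(ntip))
    partials[[i]] <- rep(list(tip_partial(i)), k)
  done <- logical(nnode)
  done[seq_len(ntip)] <- TRUE
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1]; chi <- po$edge[e, 2]; t <- po$edge.length[e]
    msg <- vector("list", k)
    for (c in seq_len(k))
      msg[[c]] <- gtr_prob(model, t, model$cat_rates[c]) %*% partials[[chi]][[c]]
    if (is.null(partials[[par]])) {
      partials[[par]] <- msg
    } else {
      for (c in seq_len(k)) partials[[par]][[c]] <- partials[[par]][[c]] * msg[[c]]
    }
    # rescale parent when all children so far folded in (safe to do always)
    mx <- do.call(pmax, lapply(partials[[par]], function(M) apply(M, 2, max)))
    mx[mx <= 0] <- 1
    for (c in seq_len(k))
      partials[[par]][[c]] <- sweep(partials[[par]][[c]], 2, mx, "/")
    scaler <- scaler + log(mx)
  }
  root <- po$edge[nrow(po$edge), 1]
  site_lik <- Reduce(`+`, lapply(partials[[root]],
                                 function(M) colSums(model$freq * M))) / k
  sum(log(site_lik) + scaler)
}
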