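#' Protein scoring scheme for translated search and classification
#'
#' Bundles a substitution matrix with BLAST-style affine gap penalties
#' (a gap of length g costs `gap_open + g * gap_extend`) and the
#' Karlin-Altschul parameters used to convert raw scores into E-values.
#' Defaults follow the published gapped BLOSUM62 / 11,1 statistics
#' (lambda = 0.267, K = 0.041) and an E-value cutoff of 1e-5.
#'
#' @param matrix substitution matrix with dimnames over the amino-acid
#'   alphabet (default: BLOSUM62 as shipped with Biostrings).
#' @param gap_open gap opening penalty (> 0).
#' @param gap_extend per-residue gap extension penalty (> 0).
#' @param lambda,K Karlin-Altschul scale and constant (> 0).
#' @param e_max E-value cutoff for retained HSPs.
#' @param seed_k exact-match seed length in residues.
#' @return an object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(matrix = NULL, gap_open = 11, gap_extend = 1,
                           lambda = 0.267, K = 0.041, e_max = 1e-5,
                           seed_k = 4L) {
  if (is.null(matrix)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    matrix <- e$BLOSUM62
  }
  stopifnot(is.matrix(matrix), identical(rownames(matrix), colnames(matrix)),
            isTRUE(all(matrix == t(matrix))),
            gap_open > 0, gap_extend > 0, lambda > 0, K > 0)
  structure(list(
    matrix = matrix, alphabet = rownames(matrix),
    lookup = make_lookup(rownames(matrix)),
    gap_open = gap_open, gap_extend = gap_extend,
    lambda = lambda, K = K, e_max = e_max, seed_k = as.integer(seed_k)),
    class = "scoring_scheme")
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat("scoring_scheme:", nrow(x$matrix), "letter matrix, gap", x$gap_open,
      "/", x$gap_extend, ", lambda", x$lambda, ", K", x$K,
      ", E-max", x$e_max, "\n")
  invisible(x)
}

#' Karlin-Altschul E-value
#'
#' `E = K * m * n * exp(-lambda * S)` for a raw score `S`, query length
#' `m` (residues) and effective search-space length `n` (bases, assembly
#' gaps excluded).
#'
#' @param score raw alignment score.
#' @param m query length in residues.
#' @param n effective subject length in bases.
#' @param scoring a [scoring_scheme()].
#' @return E-value(s).
#' @export
karlin_evalue <- function(score, m, n, scoring) {
  scoring$K * m * n * exp(-scoring$lambda * score)
}
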