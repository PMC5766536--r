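#' Six-frame translation with coordinate bookkeeping
#'
#' Translates a nucleotide sequence in all six reading frames. Frames
#' +1..+3 read the forward strand, -1..-3 the reverse complement. Stop
#' codons are rendered `*`; codons containing an ambiguity (e.g. `N`)
#' are rendered `X`.
#'
#' @param seq nucleotide sequence (character or [Biostrings::DNAString]).
#' @return a list with one element per frame: `frame` (signed integer),
#'   `aa` (protein as a character string). Use [frame_to_forward()] to
#'   map amino-acid coordinates back to forward-strand nucleotides.
#' @export
six_frame_translate <- function(seq) {
  d <- if (is(seq, "DNAString")) seq else Biostrings::DNAString(as.character(seq))
  rc <- Biostrings::reverseComplement(d)
  out <- vector("list", 6L)
  n <- length(d)
  for (i in 1:3) {
    for (strand in c(1L, -1L)) {
      src <- if (strand > 0) d else rc
      len <- max(0L, n - (i - 1L))
      len <- len - (len %% 3L)
      aa <- if (len == 0L) "" else as.character(Biostrings::translate(
        Biostrings::subseq(src, start = i, width = len),
        if.fuzzy.codon = "X", no.init.codon = TRUE))
      slot <- if (strand > 0) i else i + 3L
      out[[slot]] <- list(frame = strand * i, aa = aa)
    }
  }
  out
}

#' Map amino-acid coordinates of a frame back to the forward strand
#'
#' @param frame signed frame in `{+1,+2,+3,-1,-2,-3}`.
#' @param aa_start,aa_end 0-based half-open residue interval in the
#'   frame's translation.
#' @param n nucleotide sequence length.
#' @return integer `c(start, end)`, 0-based half-open on the forward
#'   strand.
#' @export
frame_to_forward <- function(frame, aa_start, aa_end, n) {
  f <- abs(frame)
  out <- if (frame > 0) {
    c((f - 1) + 3 * aa_start, (f - 1) + 3 * aa_end)
  } else {
    c(n - (f - 1) - 3 * aa_end, n - (f - 1) - 3 * aa_start)
  }
  as.integer(out)
}

#' Assembly-gap annotation
#'
#' Finds runs of `N` of at least `min_run` bases; these are treated as
#' assembly gaps and excluded from effective search-space and density
#' denominators.
#'
#' @param seq nucleotide sequence (character).
#' @param min_run minimum run length to count as a gap.
#' @return data.frame with 0-based half-open `start`, `end`.
#' @export
gap_ranges <- function(seq, min_run = 1L) {
  m <- gregexpr("N+", as.character(seq))[[1]]
  if (m[1] == -1L) return(data.frame(start = integer(), end = integer()))
  len <- attr(m, "match.length")
  keep <- len >= min_run
  data.frame(start = as.integer(m[keep]) - 1L,
             end = as.integer(m[keep]) - 1L + len[keep])
}

#' Translated seed-and-extend homology search (tBLASTn-like)
#'
#' Searches a protein query against the six translation frames of a
#' genome. Exact `seed_k`-mer seeds (standard residues only) trigger an
#' ungapped X-drop extension along the diagonal, and promising segments
#' are refined by a windowed gapped Smith-Waterman. E-values follow
#' Karlin-Altschul statistics with the effective subject length equal to
#' the genome length minus assembly gaps (`N` runs). HSPs with
#' `E <= e_max` are returned sorted by decreasing score.
#'
#' @param query protein sequence (character).
#' @param genome nucleotide sequence (character).
#' @param scoring a [scoring_scheme()].
#' @param query_id,genome_id identifiers carried into the result.
#' @param xdrop score drop-off terminating ungapped extension.
#' @param gap_trigger minimum ungapped segment score to enter the gapped
#'   stage.
#' @param frames optional pre-computed [six_frame_translate()] result for
#'   `genome` (saves recomputation when searching many queries).
#' @return data.frame of HSPs: `query_id`, `genome_id`, `frame`,
#'   `g_start`, `g_end` (0-based half-open, forward strand), `q_start`,
#'   `q_end` (0-based half-open, residues), `score`, `evalue`.
#' @export
seeded_search <- function(query, genome, scoring = scoring_scheme(),
                          query_id = "query", genome_id = "genome",
                          xdrop = 20, gap_trigger = 30, frames = NULL) {
  n <- nchar(genome)
  empty <- data.frame(query_id = character(), genome_id = character(),
                      frame = integer(), g_start = integer(),
                      g_end = integer(), q_start = integer(),
                      q_end = integer(), score = numeric(),
                      evalue = numeric())
  if (n == 0L) return(empty)
  if (is.null(frames)) frames <- six_frame_translate(genome)
  qv <- encode_seq(as.character(query), scoring$lookup)
  if (length(qv) < scoring$seed_k) return(empty)
  n_eff <- n - sum(utf8ToInt(as.character(genome)) == utf8ToInt("N"))
  res <- list()
  for (fr in frames) {
    if (nchar(fr$aa) < scoring$seed_k) next
    sv <- encode_seq(fr$aa, scoring$lookup)
    hits <- cpp_seed_extend(qv, sv, scoring$matrix, scoring$gap_open,
                            scoring$gap_extend, scoring$seed_k,
                            xdrop, gap_trigger, 60L)
    if (nrow(hits) == 0L) next
    hits$evalue <- karlin_evalue(hits$score, length(qv), n_eff, scoring)
    hits <- hits[hits$evalue <= scoring$e_max, , drop = FALSE]
    if (nrow(hits) == 0L) next
    hits <- dedupe_hsps(hits)
    gc <- t(vapply(seq_len(nrow(hits)), function(i)
      frame_to_forward(fr$frame, hits$s_start[i], hits$s_end[i], n),
      integer(2)))
    res[[length(res) + 1L]] <- data.frame(
      query_id = query_id, genome_id = genome_id, frame = fr$frame,
      g_start = gc[, 1], g_end = gc[, 2],
      q_start = as.integer(hits$q_start), q_end = as.integer(hits$q_end),
      score = hits$score, evalue = hits$evalue)
  }
  if (length(res) == 0L) return(empty)
  out <- do.call(rbind, res)
  out <- out[order(-out$score, out$g_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# drop same-frame HSPs whose footprint duplicates a better-scoring one
# (window Smith-Waterman re-finds the same optimum from multiple seeds)
dedupe_hsps <- function(h) {
  o <- order(-h$score, h$s_start, h$q_start)
  h <- h[o, , drop = FALSE]
  keep <- logical(nrow(h))
  for (i in seq_len(nrow(h))) {
    dup <- FALSE
    if (any(keep)) {
      k <- which(keep)
      ov <- pmin(h$s_end[k], h$s_end[i]) - pmax(h$s_start[k], h$s_start[i])
      len <- h$s_end[i] - h$s_start[i]
      dup <- any(ov >= 0.9 * len)
    }
    keep[i] <- !dup
  }
  h[keep, , drop = FALSE]
}

#' Merge overlapping HSP footprints into hit loci
#'
#' Forward-strand nucleotide footprints from one genome are merged
#' transitively whenever they overlap, irrespective of strand or frame.
#' Touching half-open intervals (`end == start`) are not merged. The
#' operation is idempotent and returns loci sorted by start.
#'
#' @param hsps data.frame as returned by [seeded_search()] (one genome).
#' @return data.frame of loci: `locus_id`, `genome_id`, `start`, `end`
#'   (0-based half-open), `best_score`, `n_hsps`, `extended`.
#' @export
merge_hit_loci <- function(hsps) {
  if (nrow(hsps) == 0L)
    return(data.frame(locus_id = character(), genome_id = character(),
                      start = integer(), end = integer(),
                      best_score = numeric(), n_hsps = integer(),
                      extended = logical()))
  stopifnot(length(unique(hsps$genome_id)) == 1L)
  ir <- IRanges::IRanges(start = hsps$g_start + 1L, end = hsps$g_end)
  red <- IRanges::reduce(ir, min.gapwidth = 0L)
  ov <- IRanges::findOverlaps(ir, red)
  best <- tapply(hsps$score[S4Vectors::queryHits(ov)],
                 S4Vectors::subjectHits(ov), max)
  cnt <- tabulate(S4Vectors::subjectHits(ov), nbins = length(red))
  gid <- hsps$genome_id[1]
  st <- IRanges::start(red) - 1L
  en <- IRanges::end(red)
  data.frame(
    locus_id = sprintf("%s:%d-%d", gid, st, en), genome_id = gid,
    start = st, end = en,
    best_score = as.numeric(best[as.character(seq_along(red))]),
    n_hsps = cnt, extended = FALSE)
}

#' Extend hit loci by a fixed flank
#'
#' Widens each locus by `flank` bases on both sides, clamps to the
#' sequence bounds, and re-merges overlaps created by the extension.
#'
#' @param loci data.frame from [merge_hit_loci()].
#' @param flank bases added upstream and downstream (default 120).
#' @param genome_length sequence length for clamping.
#' @return data.frame with the same columns, `extended = TRUE`.
#' @export
extend_loci <- function(loci, flank = 120L, genome_length) {
  if (nrow(loci) == 0L) return(loci)
  st <- pmax(0L, loci$start - as.integer(flank))
  en <- pmin(as.integer(genome_length), loci$end + as.integer(flank))
  ir <- IRanges::IRanges(start = st + 1L, end = en)
  red <- IRanges::reduce(ir, min.gapwidth = 0L)
  ov <- IRanges::findOverlaps(ir, red)
  best <- tapply(loci$best_score[S4Vectors::queryHits(ov)],
                 S4Vectors::subjectHits(ov), max)
  cnt <- tapply(loci$n_hsps[S4Vectors::queryHits(ov)],
                S4Vectors::subjectHits(ov), sum)
  gid <- loci$genome_id[1]
  st2 <- IRanges::start(red) - 1L
  en2 <- IRanges::end(red)
  key <- as.character(seq_along(red))
  data.frame(
    locus_id = sprintf("%s:%d-%d", gid, st2, en2), genome_id = gid,
    start = st2, end = en2,
    best_score = as.numeric(best[key]),
    n_hsps = as.integer(cnt[key]), extended = TRUE)
}

#' First-pass mining of one genome against a protein library
#'
#' Runs [seeded_search()] for every library protein, pools the HSPs,
#' merges overlapping footprints and applies the fixed flank extension.
#'
#' @param genome nucleotide sequence (character).
#' @param library named character vector of protein sequences (or an
#'   [Biostrings::AAStringSet]).
#' @param scoring a [scoring_scheme()].
#' @param genome_id identifier for the genome.
#' @param flank extension in bases (default 120).
#' @return list with `hsps` and `loci` data.frames.
#' @export
translated_search <- function(genome, library, scoring = scoring_scheme(),
                              genome_id = "genome", flank = 120L) {
  if (is(library, "AAStringSet")) {
    nm <- names(library)
    library <- setNames(as.character(library), nm)
  }
  stopifnot(!is.null(names(library)))
  frames <- six_frame_translate(genome)
  hs <- lapply(names(library), function(qid)
    seeded_search(library[[qid]], genome, scoring, query_id = qid,
                  genome_id = genome_id, frames = frames))
  hsps <- do.call(rbind, hs)
  if (is.null(hsps)) hsps <- seeded_search("", "", scoring)
  loci <- merge_hit_loci(hsps)
  loci <- extend_loci(loci, flank = flank, genome_length = nchar(genome))
  list(hsps = hsps, loci = loci)
}
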