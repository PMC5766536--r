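#' Labelled reverse-transcriptase protein library
#'
#' @param proteins named character vector of protein sequences.
#' @param families character vector of family labels (e.g.
#'   `"caulimovirid"`, `"gypsy_decoy"`), recycled against `proteins`.
#' @return data.frame with columns `id`, `family`, `seq`.
#' @export
rt_library <- function(proteins, families) {
  stopifnot(!is.null(names(proteins)), length(families) %in%
              c(1L, length(proteins)))
  data.frame(id = names(proteins), family = rep(families,
             length.out = length(proteins)), seq = unname(proteins))
}

#' Write a labelled RT library as FASTA with `family=` headers
#'
#' Records are written as `>id family=<label>`, the conventional
#' header for the dual-family library files.
#'
#' @param library an [rt_library()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_rt_library <- function(library, path) {
  seqs <- setNames(library$seq,
                   paste0(library$id, " family=", library$family))
  write_fasta(seqs, path)
}

#' Read a labelled RT library from FASTA with `family=` headers
#'
#' @param path FASTA file written by [write_rt_library()].
#' @return an [rt_library()] data.frame.
#' @export
read_rt_library <- function(path) {
  seqs <- read_fasta(path)
  ids <- sub(" .*", "", names(seqs))
  fam <- sub(".*family=([^ ]+).*", "\\1", names(seqs))
  rt_library(setNames(unname(seqs), ids), fam)
}

#' Enumerate long stop-free translations of a locus
#'
#' Translates the locus in all six frames, splits each frame at stop
#' codons, and returns the maximal stop-free segments of at least
#' `min_len` residues, longest first.
#'
#' @param locus_seq nucleotide sequence of the (extended) locus.
#' @param min_len minimum segment length in residues (default 200).
#' @return data.frame with `frame`, `aa_start` (0-based offset in the
#'   frame translation), `aa_len`, `aa_seq`; zero rows if nothing
#'   qualifies.
#' @export
best_translation <- function(locus_seq, min_len = 200L) {
  frames <- six_frame_translate(locus_seq)
  out <- list()
  for (fr in frames) {
    if (nchar(fr$aa) < min_len) next
    m <- gregexpr("[^*]+", fr$aa)[[1]]
    if (m[1] == -1L) next
    len <- attr(m, "match.length")
    keep <- which(len >= min_len)
    for (i in keep) {
      out[[length(out) + 1L]] <- data.frame(
        frame = fr$frame, aa_start = as.integer(m[i]) - 1L,
        aa_len = len[i],
        aa_seq = substr(fr$aa, m[i], m[i] + len[i] - 1L))
    }
  }
  if (!length(out))
    return(data.frame(frame = integer(), aa_start = integer(),
                      aa_len = integer(), aa_seq = character()))
  res <- do.call(rbind, out)
  res <- res[order(-res$aa_len, res$frame), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Local protein alignment (Smith-Waterman)
#'
#' Affine-gap local alignment under the scoring scheme. `aln_len`
#' counts alignment columns including gaps; `identity` is identical
#' columns divided by `aln_len`.
#'
#' @param query,subject non-empty amino-acid sequences.
#' @param scoring a [scoring_scheme()].
#' @return list with `score`, `aln_len`, `identity`, and the 0-based
#'   half-open aligned intervals `q_start`, `q_end`, `s_start`, `s_end`.
#' @export
align_protein <- function(query, subject, scoring = scoring_scheme()) {
  stopifnot(nchar(query) > 0, nchar(subject) > 0)
  r <- cpp_sw_align(encode_seq(query, scoring$lookup),
                    encode_seq(subject, scoring$lookup),
                    scoring$matrix, scoring$gap_open, scoring$gap_extend)
  list(score = r$score, aln_len = r$aln_len,
       identity = if (r$aln_len > 0) r$n_ident / r$aln_len else NA_real_,
       q_start = r$a_start, q_end = r$a_end,
       s_start = r$b_start, s_end = r$b_end)
}

#' First-pass reciprocal classification of a protein candidate
#'
#' Aligns the candidate against every record of the dual-family library
#' and assigns the family of the best-scoring hit (ties broken by
#' higher identity, then lexicographic subject id). The candidate is
#' accepted only if the best family is `caulimovirid` and the best-hit
#' alignment spans at least `min_aln` residues.
#'
#' @param candidate amino-acid sequence.
#' @param library an [rt_library()] with at least one caulimovirid and
#'   one outgroup record.
#' @param scoring a [scoring_scheme()].
#' @param min_aln minimum best-hit alignment length in residues
#'   (default 170).
#' @return one-row data.frame: `best_subject_id`, `best_family`,
#'   `best_score`, `aln_len_aa`, `identity`, `status` in
#'   `{accepted, rejected_family, rejected_length}`.
#' @export
reciprocal_classify <- function(candidate, library,
                                scoring = scoring_scheme(),
                                min_aln = 170L) {
  if (is.null(library) || nrow(library) == 0L)
    stop("empty RT library")
  hits <- lapply(seq_len(nrow(library)), function(i)
    align_protein(candidate, library$seq[i], scoring))
  score <- vapply(hits, `[[`, numeric(1), "score")
  ident <- vapply(hits, `[[`, numeric(1), "identity")
  alen <- vapply(hits, `[[`, numeric(1), "aln_len")
  o <- order(-score, -ident, library$id)
  b <- o[1]
  fam <- library$family[b]
  status <- if (fam != "caulimovirid") "rejected_family"
    else if (alen[b] < min_aln) "rejected_length"
    else "accepted"
  data.frame(best_subject_id = library$id[b], best_family = fam,
             best_score = score[b], aln_len_aa = alen[b],
             identity = ident[b], status = status)
}

#' Second-pass eligibility of a locus for phylogenetic placement
#'
#' Frame-aware translated alignment of the extended locus against each
#' library protein (the nucleotide-level rule of the second mining
#' pass). The locus is eligible when the best family is caulimovirid
#' and the nucleotide span of the best alignment (3 bases per alignment
#' column) reaches `frac` of the subject length in base pairs; for the
#' generic 240-residue RT domain this threshold is
#' `0.8 * 3 * 240 = 576` bp.
#'
#' @param locus_seq nucleotide sequence of the extended locus.
#' @param library an [rt_library()] (the "diverse" library in the
#'   second pass).
#' @param scoring a [scoring_scheme()].
#' @param frac required fraction of the subject length (default 0.8).
#' @return one-row data.frame: `best_subject_id`, `best_family`,
#'   `best_score`, `frame`, `pass2_aln_len_nt`, `threshold_nt`,
#'   `pass2_eligible`.
#' @export
select_for_placement <- function(locus_seq, library,
                                 scoring = scoring_scheme(), frac = 0.8) {
  frames <- six_frame_translate(locus_seq)
  best <- NULL
  for (i in seq_len(nrow(library))) {
    sv <- encode_seq(library$seq[i], scoring$lookup)
    for (fr in frames) {
      if (nchar(fr$aa) == 0L) next
      r <- cpp_sw_align(encode_seq(fr$aa, scoring$lookup), sv,
                        scoring$matrix, scoring$gap_open, scoring$gap_extend)
      cand <- list(id = library$id[i], family = library$family[i],
                   score = r$score, aln_len = r$aln_len, frame = fr$frame,
                   n_ident = r$n_ident,
                   subject_len = nchar(library$seq[i]))
      if (is.null(best) || cand$score > best$score ||
          (cand$score == best$score &&
           (cand$n_ident > best$n_ident ||
            (cand$n_ident == best$n_ident && cand$id < best$id))))
        best <- cand
    }
  }
  span_nt <- 3L * best$aln_len
  # guard against binary representation of frac pushing ceiling() up
  # (0.8 * 720 must give the generic 576, not 577)
  thr <- ceiling(frac * 3 * best$subject_len - 1e-9)
  data.frame(best_subject_id = best$id, best_family = best$family,
             best_score = best$score, frame = best$frame,
             pass2_aln_len_nt = span_nt, threshold_nt = thr,
             pass2_eligible = best$family == "caulimovirid" &&
               span_nt >= thr)
}

#' Classify extended hit loci against the RT library (pass 1)
#'
#' For each locus, enumerates stop-free translations of at least
#' `min_aa` residues and classifies the longest candidate with
#' [reciprocal_classify()]. Loci with no qualifying translation get
#' status `rejected_no_orf`. Every locus receives exactly one status.
#'
#' @param loci data.frame from [extend_loci()].
#' @param genome nucleotide sequence the loci index into.
#' @param library an [rt_library()].
#' @param scoring a [scoring_scheme()].
#' @param min_aa minimum translated length in residues (default 200).
#' @param min_aln minimum best-hit alignment length (default 170).
#' @return data.frame: locus columns plus `protein`, `frame`,
#'   `best_subject_id`, `best_family`, `best_score`, `aln_len_aa`,
#'   `status`.
#' @export
classify_loci <- function(loci, genome, library,
                          scoring = scoring_scheme(), min_aa = 200L,
                          min_aln = 170L) {
  rows <- lapply(seq_len(nrow(loci)), function(i) {
    seq <- substr(genome, loci$start[i] + 1L, loci$end[i])
    cand <- best_translation(seq, min_len = min_aa)
    if (nrow(cand) == 0L)
      return(data.frame(locus_id = loci$locus_id[i], protein = NA_character_,
                        frame = NA_integer_, best_subject_id = NA_character_,
                        best_family = NA_character_, best_score = NA_real_,
                        aln_len_aa = NA_real_, status = "rejected_no_orf"))
    cl <- reciprocal_classify(cand$aa_seq[1], library, scoring, min_aln)
    data.frame(locus_id = loci$locus_id[i], protein = cand$aa_seq[1],
               frame = cand$frame[1], best_subject_id = cl$best_subject_id,
               best_family = cl$best_family, best_score = cl$best_score,
               aln_len_aa = cl$aln_len_aa, status = cl$status)
  })
  out <- do.call(rbind, rows)
  merge(loci, out, by = "locus_id", sort = FALSE)
}
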