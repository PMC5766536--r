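#' Mutational decay model for planted viral insertions
#'
#' Parameters of the sequence-decay process applied to donor sequences
#' before planting, emulating the pseudogenization of endogenous viral
#' elements: point substitutions, indels with geometric lengths, and
#' forced premature stop codons in the donor's original reading frame.
#'
#' @param sub_rate expected substitutions per site, in `[0, 1]`.
#' @param indel_rate expected indel events per site, in `[0, 1]`.
#' @param indel_len_mean mean of the geometric indel-length
#'   distribution, in bases (>= 1).
#' @param stop_rate expected premature stop codons per 100 codons.
#' @param seed integer RNG seed; identical seed and inputs give
#'   identical output.
#' @return an object of class `decay_model`.
#' @export
decay_model <- function(sub_rate = 0.1, indel_rate = 0.001,
                        indel_len_mean = 3, stop_rate = 0.5, seed = 1L) {
  stopifnot(sub_rate >= 0, sub_rate <= 1, indel_rate >= 0, indel_rate <= 1,
            indel_len_mean >= 1, stop_rate >= 0)
  structure(list(sub_rate = sub_rate, indel_rate = indel_rate,
                 indel_len_mean = indel_len_mean, stop_rate = stop_rate,
                 seed = as.integer(seed)),
            class = "decay_model")
}

#' Generate a random background genome sequence
#'
#' I.i.d. draws over `{A,C,G,T}` with `P(G) + P(C) = gc`, split evenly
#' within each pair.
#'
#' @param length sequence length in bases (>= 0).
#' @param gc GC fraction in `[0, 1]`.
#' @param seed integer RNG seed.
#' @return a character string of exactly `length` bases.
#' @export
generate_background <- function(length, gc = 0.5, seed = 1L) {
  if (length < 0) stop("length must be non-negative")
  stopifnot(gc >= 0, gc <= 1)
  if (length == 0) return("")
  set.seed(seed)
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE, prob = p),
        collapse = "")
}

#' Reverse-translate a protein into a coding sequence
#'
#' Chooses, per residue, a codon uniformly at random among that
#' residue's standard-code codons, so that translating the result in
#' frame +1 recovers the input protein.
#'
#' @param protein amino-acid sequence over the 20 standard residues.
#' @param seed integer RNG seed.
#' @return nucleotide string of length `3 * nchar(protein)`.
#' @export
reverse_translate <- function(protein, seed = 1L) {
  gc_tab <- Biostrings::GENETIC_CODE
  by_aa <- split(names(gc_tab), gc_tab)
  aa <- strsplit(toupper(protein), "")[[1]]
  if (!all(aa %in% names(by_aa)) || any(aa == "*"))
    stop("unknown residue in protein: ",
         paste(unique(aa[!aa %in% setdiff(names(by_aa), "*")]), collapse = ","))
  set.seed(seed)
  codons <- vapply(aa, function(r) {
    cs <- by_aa[[r]]
    if (length(cs) == 1L) cs else cs[sample.int(length(cs), 1L)]
  }, character(1))
  paste(codons, collapse = "")
}

#' Apply an edit log to a sequence
#'
#' Replays the edits recorded by [decay()]: stage-1 substitutions (point
#' substitutions and forced stop codons, positions on the original
#' sequence) followed by stage-2 indels (applied right-to-left, so
#' original coordinates stay valid).
#'
#' @param seq nucleotide string.
#' @param log data.frame with columns `stage`, `pos` (0-based), `kind`
#'   (`sub`, `stop`, `ins`, `del`), `payload`.
#' @return the edited sequence (character string).
#' @export
apply_edits <- function(seq, log) {
  ch <- strsplit(seq, "")[[1]]
  s1 <- log[log$stage == 1L, , drop = FALSE]
  for (i in seq_len(nrow(s1))) {
    pl <- strsplit(s1$payload[i], "")[[1]]
    ch[s1$pos[i] + seq_along(pl)] <- pl
  }
  s2 <- log[log$stage == 2L, , drop = FALSE]
  if (nrow(s2)) {
    s2 <- s2[order(-s2$pos), , drop = FALSE]
    for (i in seq_len(nrow(s2))) {
      if (s2$kind[i] == "ins") {
        ch <- append(ch, strsplit(s2$payload[i], "")[[1]], after = s2$pos[i])
      } else {
        len <- as.integer(s2$payload[i])
        idx <- (s2$pos[i] + 1L):min(s2$pos[i] + len, length(ch))
        if (s2$pos[i] < length(ch)) ch <- ch[-idx]
      }
    }
  }
  paste(ch, collapse = "")
}

#' Apply mutational decay to a sequence
#'
#' Draws substitutions per site with probability `sub_rate` (always to a
#' different base), forces premature stop codons at `stop_rate` per 100
#' codons of the original reading frame, and applies indel events per
#' site with probability `indel_rate` and geometric lengths with mean
#' `indel_len_mean`. The returned edit log replays exactly to the
#' output via [apply_edits()].
#'
#' @param seq non-empty nucleotide string.
#' @param model a [decay_model()].
#' @return list with `seq` (decayed sequence) and `log` (edit log).
#' @export
decay <- function(seq, model) {
  stopifnot(inherits(model, "decay_model"), nchar(seq) > 0)
  set.seed(model$seed)
  n <- nchar(seq)
  ch <- strsplit(seq, "")[[1]]
  logs <- list()
  # forced premature stops, on the original reading frame
  ncod <- n %/% 3L
  if (model$stop_rate > 0 && ncod > 0) {
    k <- rbinom(1L, ncod, min(1, model$stop_rate / 100))
    if (k > 0) {
      cods <- sort(sample.int(ncod, k))
      stops <- sample(c("TAA", "TAG", "TGA"), k, replace = TRUE)
      logs[[length(logs) + 1L]] <- data.frame(
        stage = 1L, pos = 3L * (cods - 1L), kind = "stop", payload = stops)
    }
  }
  # point substitutions, always to a different base
  if (model$sub_rate > 0) {
    sites <- which(runif(n) < model$sub_rate)
    if (length(sites)) {
      bases <- c("A", "C", "G", "T")
      newb <- vapply(sites, function(i)
        sample(setdiff(bases, ch[i]), 1L), character(1))
      logs[[length(logs) + 1L]] <- data.frame(
        stage = 1L, pos = sites - 1L, kind = "sub", payload = newb)
    }
  }
  # indel events with geometric lengths
  if (model$indel_rate > 0) {
    sites <- which(runif(n) < model$indel_rate)
    if (length(sites)) {
      lens <- rgeom(length(sites), 1 / model$indel_len_mean) + 1L
      ins <- runif(length(sites)) < 0.5
      payload <- character(length(sites))
      for (i in seq_along(sites)) {
        payload[i] <- if (ins[i])
          paste(sample(c("A", "C", "G", "T"), lens[i], replace = TRUE),
                collapse = "")
        else as.character(lens[i])
      }
      logs[[length(logs) + 1L]] <- data.frame(
        stage = 2L, pos = sites - 1L,
        kind = ifelse(ins, "ins", "del"), payload = payload)
    }
  }
  log <- if (length(logs)) do.call(rbind, logs) else
    data.frame(stage = integer(), pos = integer(), kind = character(),
               payload = character())
  list(seq = apply_edits(seq, log), log = log)
}

revcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

#' Plant decayed donor sequences into a background genome
#'
#' Each donor is decayed under `model` (with a donor-specific seed
#' derived from `model$seed`) and inserted at a uniformly chosen,
#' distinct cut point of the background, on a random strand. Insertions
#' never overlap or nest, and the genome length equals the background
#' length plus the total decayed donor length.
#'
#' @param background nucleotide string.
#' @param donors data.frame with columns `id`, `family`, `seq` (may
#'   have zero rows).
#' @param model a [decay_model()].
#' @param seed integer RNG seed for positions and strands.
#' @param genome_id identifier recorded in the truth table.
#' @return list with `genome` (character) and `truth` (data.frame:
#'   `genome_id`, `start`, `end` 0-based half-open, `strand`,
#'   `donor_id`, `family`, `decayed_seq`, list column `edits`).
#' @export
plant_insertions <- function(background, donors, model, seed = 1L,
                             genome_id = "genome") {
  empty_truth <- data.frame(genome_id = character(), start = integer(),
                            end = integer(), strand = character(),
                            donor_id = character(), family = character(),
                            decayed_seq = character())
  empty_truth$edits <- list()
  if (is.null(donors) || nrow(donors) == 0L)
    return(list(genome = background, truth = empty_truth))
  L <- nchar(background)
  n <- nrow(donors)
  if (n > L + 1L)
    stop("background too short to host all insertions disjointly")
  set.seed(seed)
  cuts <- sample.int(L + 1L, n) - 1L          # distinct cut points in 0..L
  strands <- sample(c("+", "-"), n, replace = TRUE)
  dec <- vector("list", n)
  for (i in seq_len(n)) {
    mi <- model
    mi$seed <- (model$seed + 7919L * i) %% .Machine$integer.max
    dec[[i]] <- decay(donors$seq[i], mi)
  }
  o <- order(cuts)
  pieces <- character(0)
  prev <- 0L
  starts <- integer(n); ends <- integer(n)
  offset <- 0L
  for (j in seq_len(n)) {
    i <- o[j]
    cut <- cuts[i]
    pieces <- c(pieces, substr(background, prev + 1L, cut))
    dseq <- dec[[i]]$seq
    ins <- if (strands[i] == "+") dseq else revcomp(dseq)
    starts[i] <- cut + offset
    ends[i] <- starts[i] + nchar(dseq)
    pieces <- c(pieces, ins)
    offset <- offset + nchar(dseq)
    prev <- cut
  }
  pieces <- c(pieces, substr(background, prev + 1L, L))
  truth <- data.frame(genome_id = genome_id, start = starts, end = ends,
                      strand = strands, donor_id = donors$id,
                      family = donors$family,
                      decayed_seq = vapply(dec, `[[`, character(1), "seq"))
  truth$edits <- lapply(dec, `[[`, "log")
  truth <- truth[order(truth$start), , drop = FALSE]
  rownames(truth) <- NULL
  list(genome = paste(pieces, collapse = ""), truth = truth)
}

#' Generate a synthetic protein family around a random ancestor
#'
#' Members are derived from a common random ancestor by substituting
#' each residue with probability `divergence` (to a different residue).
#'
#' @param n number of members.
#' @param len protein length in residues.
#' @param divergence per-residue substitution probability from the
#'   ancestor.
#' @param seed integer RNG seed.
#' @param prefix member name prefix.
#' @return named character vector of protein sequences.
#' @export
make_protein_family <- function(n, len = 240L, divergence = 0.25,
                                seed = 1L, prefix = "fam") {
  set.seed(seed)
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  anc <- sample(aa20, len, replace = TRUE)
  out <- character(n)
  for (i in seq_len(n)) {
    m <- anc
    hit <- which(runif(len) < divergence)
    if (length(hit))
      m[hit] <- vapply(hit, function(j) sample(setdiff(aa20, anc[j]), 1L),
                       character(1))
    out[i] <- paste(m, collapse = "")
  }
  names(out) <- sprintf("%s%02d", prefix, seq_len(n))
  out
}

#' Insert assembly-gap runs (N) into a sequence
#'
#' Overwrites `n_runs` non-overlapping stretches of `run_len` bases with
#' `N`, emulating assembly gaps. Sequence length is unchanged.
#'
#' @param seq nucleotide string.
#' @param n_runs number of gap runs.
#' @param run_len length of each run in bases.
#' @param seed integer RNG seed.
#' @return the gapped sequence (character string).
#' @export
insert_gap_runs <- function(seq, n_runs, run_len, seed = 1L) {
  n <- nchar(seq)
  stopifnot(n_runs * run_len <= n)
  set.seed(seed)
  slots <- n - n_runs * run_len
  offs <- sort(sample.int(slots + 1L, n_runs) - 1L)
  starts <- offs + (seq_len(n_runs) - 1L) * run_len
  ch <- strsplit(seq, "")[[1]]
  for (s in starts) ch[(s + 1L):(s + run_len)] <- "N"
  paste(ch, collapse = "")
}
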