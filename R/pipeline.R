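#' Run the full ECRT mining pipeline on a benchmark bundle
#'
#' Orchestrates the stages end to end: translated search of every
#' genome against the protein library, merging and flank extension of
#' hit loci, first-pass reciprocal classification, per-genome greedy
#' clustering of accepted proteins (within-species identity level)
#' followed by a global clustering round whose representatives augment
#' the library ("diverse library"), similarity-network OTU
#' delineation over the global representatives, second-pass
#' nucleotide-level eligibility against the diverse library,
#' phylogenetic placement of eligible loci on the reference tree, and
#' the summary surfaces. All stages are deterministic given the
#' bundle.
#'
#' @param bundle a [make_benchmark_bundle()] result (or a compatible
#'   list with `genomes`, `library`, `refpkg`).
#' @param scoring a [scoring_scheme()].
#' @param flank locus extension in bases (default 120).
#' @param min_aa pass-1 minimum translation length (default 200).
#' @param min_aln pass-1 minimum best-hit alignment length (default
#'   170).
#' @param cluster_within within-species clustering identity (default
#'   0.80).
#' @param cluster_global global clustering identity (default 0.55).
#' @param network_id similarity-network edge threshold (default 0.35).
#' @param frac pass-2 fraction of subject length (default 0.8).
#' @param outdir optional directory for TSV/BED/jplace outputs.
#' @return list with `hsps`, `loci`, `classified`, `within_clusters`,
#'   `global_clusters`, `network`, `diverse_library`, `pass2`,
#'   `placements`, `stats`, `distribution`, `trend`, `conservation`.
#' @export
run_pipeline <- function(bundle, scoring = scoring_scheme(),
                         flank = 120L, min_aa = 200L, min_aln = 170L,
                         cluster_within = 0.80, cluster_global = 0.55,
                         network_id = 0.35, frac = 0.8, outdir = NULL) {
  lib <- bundle$library
  genomes <- bundle$genomes
  hsps <- list(); loci <- list(); classified <- list()
  within <- list()
  for (g in names(genomes)) {
    ts <- translated_search(genomes[[g]], setNames(lib$seq, lib$id),
                            scoring, genome_id = g, flank = flank)
    hsps[[g]] <- ts$hsps
    loci[[g]] <- ts$loci
    cl <- classify_loci(ts$loci, genomes[[g]], lib, scoring,
                        min_aa = min_aa, min_aln = min_aln)
    classified[[g]] <- cl
    acc <- cl[cl$status == "accepted", , drop = FALSE]
    if (nrow(acc))
      within[[g]] <- greedy_cluster(setNames(acc$protein, acc$locus_id),
                                    cluster_within, scoring)
  }
  hsps <- do.call(rbind, hsps)
  all_loci <- do.call(rbind, loci)
  classified_all <- do.call(rbind, classified)
  rownames(hsps) <- rownames(all_loci) <- rownames(classified_all) <- NULL

  # within-species representatives join the caulimovirid library core
  # for the global clustering round
  reps <- unlist(lapply(within, function(w)
    vapply(w$clusters, `[[`, character(1), "representative")))
  rep_seqs <- setNames(
    classified_all$protein[match(reps, classified_all$locus_id)], reps)
  core <- setNames(lib$seq[lib$family == "caulimovirid"],
                   lib$id[lib$family == "caulimovirid"])
  global_cl <- greedy_cluster(c(core, rep_seqs), cluster_global, scoring)
  greps <- vapply(global_cl$clusters, `[[`, character(1),
                  "representative")
  net <- build_network(c(core, rep_seqs)[greps], network_id, scoring)

  diverse <- rbind(lib, if (length(rep_seqs))
    rt_library(rep_seqs, "caulimovirid"))

  # pass 2: nucleotide-level eligibility of every extended locus
  pass2 <- lapply(seq_len(nrow(all_loci)), function(i) {
    g <- all_loci$genome_id[i]
    s <- substr(genomes[[g]], all_loci$start[i] + 1L, all_loci$end[i])
    cbind(data.frame(locus_id = all_loci$locus_id[i], genome_id = g),
          select_for_placement(s, diverse, scoring, frac))
  })
  pass2 <- do.call(rbind, pass2)

  elig <- pass2[pass2$pass2_eligible, , drop = FALSE]
  queries <- setNames(vapply(seq_len(nrow(elig)), function(i) {
    g <- elig$genome_id[i]
    li <- all_loci[all_loci$locus_id == elig$locus_id[i], ]
    s <- substr(genomes[[g]], li$start + 1L, li$end)
    if (elig$frame[i] < 0) revcomp(s) else s
  }, character(1)), elig$locus_id)
  placements <- if (length(queries))
    place_queries(queries, bundle$refpkg)
  else data.frame(query_id = character(), status = character(),
                  edge_id = integer(), edge_label = character(),
                  pendant_length = numeric(), log_likelihood = numeric(),
                  lwr = numeric(), otu_label = character())

  counts <- table(elig$genome_id)
  stats <- genome_stats(genomes, setNames(as.integer(counts),
                                          names(counts)))
  trend <- if (nrow(stats) >= 3 &&
               length(unique(stats$ungapped_mb)) > 1)
    log_trend_fit(stats$ecrt_count, stats$ungapped_mb) else
    list(slope = NA_real_, intercept = NA_real_, r_squared = NA_real_)
  placed <- placements[placements$status == "placed", , drop = FALSE]
  species_map <- setNames(elig$genome_id, elig$locus_id)
  distribution <- if (nrow(placed))
    build_distribution(placed, species_map) else
    list(matrix = matrix(integer(), 0, 0), otu_totals = integer(),
         species_presence = integer())
  conservation <- list(
    n_eligible = nrow(elig),
    n_otu = sum(placed$otu_label != "inner"),
    n_inner = sum(placed$otu_label == "inner"),
    n_rejected = sum(placements$status == "unalignable"))

  out <- list(hsps = hsps, loci = all_loci, classified = classified_all,
              within_clusters = within, global_clusters = global_cl,
              network = net, diverse_library = diverse, pass2 = pass2,
              placements = placements, stats = stats,
              distribution = distribution, trend = trend,
              conservation = conservation)
  if (!is.null(outdir)) write_pipeline_outputs(out, bundle, outdir)
  out
}

# write the pipeline's tabular outputs; deterministic, byte-stable
write_pipeline_outputs <- function(out, bundle, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, name) write.table(
    x, file.path(outdir, name), sep = "\t", quote = FALSE,
    row.names = FALSE)
  tsv(out$hsps, "hsps.tsv")
  write_bed(out$loci, file.path(outdir, "loci.bed"))
  tsv(out$classified[, setdiff(names(out$classified), "protein")],
      "classified.tsv")
  tsv(out$global_clusters$membership, "clusters.tsv")
  tsv(out$network$edges, "network_edges.tsv")
  tsv(out$pass2, "pass2.tsv")
  tsv(out$placements, "placements.tsv")
  tsv(out$stats, "genome_stats.tsv")
  if (length(out$distribution$matrix)) {
    dm <- data.frame(species = rownames(out$distribution$matrix),
                     out$distribution$matrix, check.names = FALSE)
    tsv(dm, "distribution_matrix.tsv")
  }
  if (nrow(out$placements))
    write_jplace(out$placements, bundle$refpkg,
                 file.path(outdir, "placements.jplace"))
  invisible(outdir)
}

#' Benchmark recovery metrics against planted ground truth
#'
#' `recall`: fraction of planted caulimovirid insertions intersecting a
#' retained (extended) locus. `decoy_false_acceptance`: fraction of
#' planted decoy insertions whose overlapping locus was accepted as
#' caulimovirid in pass 1.
#'
#' @param bundle the [make_benchmark_bundle()] used for the run.
#' @param result the [run_pipeline()] output (or a list with `loci` and
#'   `classified`).
#' @return list with `recall`, `decoy_false_acceptance`,
#'   `n_caulimo_truth`, `n_decoy_truth`.
#' @export
evaluate_recovery <- function(bundle, result) {
  truth <- bundle$truth
  loci <- result$loci
  cls <- result$classified
  overlaps <- function(tr, lo)
    lo$genome_id == tr$genome_id & lo$start < tr$end & lo$end > tr$start
  cau <- truth[truth$family == "caulimovirid", , drop = FALSE]
  dec <- truth[truth$family == "gypsy_decoy", , drop = FALSE]
  hit <- vapply(seq_len(nrow(cau)), function(i)
    any(overlaps(cau[i, ], loci)), logical(1))
  dec_acc <- vapply(seq_len(nrow(dec)), function(i) {
    ov <- overlaps(dec[i, ], cls)
    any(ov & cls$status == "accepted")
  }, logical(1))
  list(recall = mean(hit),
       decoy_false_acceptance = if (nrow(dec)) mean(dec_acc) else 0,
       n_caulimo_truth = nrow(cau), n_decoy_truth = nrow(dec))
}
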