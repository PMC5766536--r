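#' Reference package for phylogenetic placement
#'
#' Bundles a reference tree (with branch lengths), the reference
#' nucleotide alignment whose rows are the tree's leaves, the
#' substitution model, and a leaf-to-OTU map.
#'
#' @param tree an [ape::phylo] with non-negative branch lengths.
#' @param msa named character vector of aligned nucleotide rows
#'   covering exactly the tree's leaves.
#' @param model a [gtr_model()].
#' @param otu_map data.frame with columns `leaf`, `otu` covering all
#'   leaves.
#' @return an object of class `reference_package`.
#' @export
reference_package <- function(tree, msa, model, otu_map) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length),
            all(tree$edge.length >= 0),
            setequal(tree$tip.label, names(msa)),
            length(unique(nchar(msa))) == 1L,
            inherits(model, "gtr_model"),
            all(c("leaf", "otu") %in% names(otu_map)),
            all(tree$tip.label %in% otu_map$leaf))
  structure(list(tree = tree, msa = msa, model = model,
                 otu_map = otu_map, width = nchar(msa[[1]])),
            class = "reference_package")
}

#' @export
print.reference_package <- function(x, ...) {
  cat("reference_package:", length(x$tree$tip.label), "leaves,",
      x$width, "columns,", length(unique(x$otu_map$otu)), "OTUs\n")
  invisible(x)
}

#' Write a reference package to a directory
#'
#' Plain-text layout: `tree.nwk` (Newick), `refmsa.fasta`,
#' `otu_map.tsv`, `model.json`.
#'
#' @param ref a [reference_package()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_reference_package <- function(ref, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ape::write.tree(ref$tree, file.path(dir, "tree.nwk"))
  write_fasta(ref$msa, file.path(dir, "refmsa.fasta"))
  write.table(ref$otu_map, file.path(dir, "otu_map.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  m <- ref$model
  jsonlite::write_json(list(rates = m$rates, freq = m$freq,
                            alpha = m$alpha, ncat = m$ncat),
                       file.path(dir, "model.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a reference package from a directory
#'
#' @param dir directory written by [write_reference_package()].
#' @return a [reference_package()].
#' @export
read_reference_package <- function(dir) {
  tree <- ape::read.tree(file.path(dir, "tree.nwk"))
  msa <- read_fasta(file.path(dir, "refmsa.fasta"))
  otu_map <- read.table(file.path(dir, "otu_map.tsv"), sep = "\t",
                        header = TRUE, stringsAsFactors = FALSE)
  mj <- jsonlite::read_json(file.path(dir, "model.json"),
                            simplifyVector = TRUE)
  model <- gtr_model(mj$rates, mj$freq, mj$alpha, mj$ncat)
  reference_package(tree, msa, model, otu_map)
}

#' Toy reference package and matching caulimovirid library
#'
#' Builds, deterministically from a seed, an 8-leaf reference tree with
#' two OTUs (the two clades under the root), a gapless 720-column
#' nucleotide reference alignment simulated along the tree under
#' GTR+Gamma from a stop-free ancestral coding sequence, and the
#' corresponding leaf proteins. In-frame stop codons arising in the
#' simulation are repaired (first base swapped to C) so every leaf
#' translates cleanly; the leaf coding sequences double as planting
#' donors in benchmark bundles, keeping classification and placement
#' mutually consistent.
#'
#' @param seed integer RNG seed.
#' @param n_leaves number of reference leaves.
#' @param len_codons reference length in codons (default 240, the
#'   canonical RT-domain size used for the generic placement
#'   threshold).
#' @param alpha gamma shape of the model.
#' @return list with `ref` (a [reference_package()]), `proteins`
#'   (named character vector) and `cds` (named character vector, the
#'   ungapped reference rows).
#' @export
toy_reference_package <- function(seed = 101L, n_leaves = 8L,
                                  len_codons = 240L, alpha = 1) {
  set.seed(seed)
  tree <- ape::rtree(n_leaves, rooted = TRUE,
                     br = function(n) runif(n, 0.05, 0.22))
  tree$tip.label <- sprintf("caulimo%02d", seq_len(n_leaves))
  model <- gtr_model(rates = c(1, 2, 1, 1, 2, 1),
                     freq = c(0.3, 0.2, 0.2, 0.3), alpha = alpha, ncat = 4L)
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  anc_prot <- paste(sample(aa20, len_codons, replace = TRUE), collapse = "")
  anc_cds <- reverse_translate(anc_prot, seed = seed + 1L)
  leaves <- simulate_gtr(tree, model, nsites = 3L * len_codons,
                         seed = seed + 2L, root_seq = anc_cds)
  leaves <- vapply(leaves, repair_stops, character(1))
  prots <- vapply(leaves, function(s)
    as.character(Biostrings::translate(Biostrings::DNAString(s),
                                       no.init.codon = TRUE)),
    character(1))
  # two OTUs: the clades under the root
  root <- length(tree$tip.label) + 1L
  kids <- tree$edge[tree$edge[, 1] == root, 2]
  cl1 <- descendant_tips(tree, kids[1])
  otu_map <- data.frame(
    leaf = tree$tip.label,
    otu = ifelse(tree$tip.label %in% cl1, "OTU_A", "OTU_B"))
  ref <- reference_package(tree, leaves, model, otu_map)
  list(ref = ref, proteins = prots, cds = leaves)
}

# replace in-frame stop codons (TAA/TAG/TGA -> CAA/CAG/CGA)
repair_stops <- function(cds) {
  ch <- strsplit(cds, "")[[1]]
  starts <- seq(1L, length(ch) - 2L, by = 3L)
  cod <- paste0(ch[starts], ch[starts + 1L], ch[starts + 2L])
  bad <- which(cod %in% c("TAA", "TAG", "TGA"))
  if (length(bad)) ch[starts[bad]] <- "C"
  paste(ch, collapse = "")
}

# tip labels below a node (the node itself if it is a tip)
descendant_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  out <- character(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[1]; stack <- stack[-1]
    kids <- tree$edge[tree$edge[, 1] == nd, 2]
    tips <- kids[kids <= ntip]
    out <- c(out, tree$tip.label[tips])
    stack <- c(stack, kids[kids > ntip])
  }
  out
}

#' Assemble a synthetic benchmark bundle
#'
#' Generates background genomes, plants decayed caulimovirid insertions
#' (copies of the toy reference leaves) and Ty3/Gypsy-like decoy
#' insertions with ground-truth intervals, and returns the labelled
#' protein library and the placement reference package.
#'
#' @param n_genomes number of genomes.
#' @param genome_length background length per genome in bases.
#' @param n_caulimo caulimovirid insertions per genome.
#' @param n_decoy decoy insertions per genome.
#' @param model a [decay_model()] applied to every donor.
#' @param gc background GC fraction.
#' @param seed master integer RNG seed.
#' @return list of class `benchmark_bundle`: `genomes` (named
#'   character), `truth` (data.frame), `library` (an [rt_library()]),
#'   `refpkg` (a [reference_package()]), `donors`.
#' @export
make_benchmark_bundle <- function(n_genomes = 5L, genome_length = 1e6,
                                  n_caulimo = 20L, n_decoy = 10L,
                                  model = decay_model(sub_rate = 0.10,
                                                      indel_rate = 0.001,
                                                      indel_len_mean = 3,
                                                      stop_rate = 0.5,
                                                      seed = 1L),
                                  gc = 0.38, seed = 1L) {
  toy <- toy_reference_package(seed = seed + 1000L)
  gypsy_prot <- make_protein_family(4L, len = 240L, divergence = 0.25,
                                    seed = seed + 2000L, prefix = "gypsy")
  gypsy_cds <- setNames(vapply(seq_along(gypsy_prot), function(i)
    reverse_translate(gypsy_prot[[i]], seed = seed + 2000L + i),
    character(1)), names(gypsy_prot))
  lib <- rt_library(c(toy$proteins, gypsy_prot),
                    c(rep("caulimovirid", length(toy$proteins)),
                      rep("gypsy_decoy", length(gypsy_prot))))
  donor_pool <- data.frame(
    id = c(names(toy$cds), names(gypsy_cds)),
    family = c(rep("caulimovirid", length(toy$cds)),
               rep("gypsy_decoy", length(gypsy_cds))),
    seq = c(unname(toy$cds), unname(gypsy_cds)))
  genomes <- character(n_genomes)
  names(genomes) <- sprintf("genome%02d", seq_len(n_genomes))
  truths <- vector("list", n_genomes)
  for (g in seq_len(n_genomes)) {
    gs <- seed + 100L * g
    bg <- generate_background(genome_length, gc = gc, seed = gs)
    set.seed(gs + 1L)
    pick_c <- sample(which(donor_pool$family == "caulimovirid"),
                     n_caulimo, replace = TRUE)
    pick_d <- sample(which(donor_pool$family == "gypsy_decoy"),
                     n_decoy, replace = TRUE)
    donors <- donor_pool[c(pick_c, pick_d), , drop = FALSE]
    donors$id <- sprintf("%s_ins%02d", donors$id, seq_len(nrow(donors)))
    mi <- model
    mi$seed <- (model$seed + 13L * g) %% .Machine$integer.max
    pl <- plant_insertions(bg, donors, mi, seed = gs + 2L,
                           genome_id = names(genomes)[g])
    genomes[g] <- pl$genome
    truths[[g]] <- pl$truth
  }
  structure(list(genomes = genomes, truth = do.call(rbind, truths),
                 library = lib, refpkg = toy$ref, donors = donor_pool),
            class = "benchmark_bundle")
}

#' @export
print.benchmark_bundle <- function(x, ...) {
  cat("benchmark_bundle:", length(x$genomes), "genomes,",
      nrow(x$truth), "planted insertions,",
      nrow(x$library), "library proteins\n")
  invisible(x)
}

#' Write a named set of sequences as FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @param width line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    n <- nchar(s)
    starts <- seq(1L, max(n, 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}

#' Read a FASTA file into a named character vector
#'
#' @param path FASTA file.
#' @return named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write planted-insertion truth (or loci) as 6-column BED
#'
#' Columns: chrom, start, end, name (`donor_id:family` for truth
#' tables, the locus id otherwise), score 0, strand.
#'
#' @param x truth data.frame from [plant_insertions()] or a loci
#'   data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  if (all(c("donor_id", "family") %in% names(x))) {
    name <- paste0(x$donor_id, ":", x$family)
    strand <- x$strand
    chrom <- x$genome_id
  } else {
    name <- x$locus_id
    strand <- rep(".", nrow(x))
    chrom <- x$genome_id
  }
  df <- data.frame(chrom = chrom, start = x$start, end = x$end,
                   name = name, score = 0L, strand = strand)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
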