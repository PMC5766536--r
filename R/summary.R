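#' ECRT density per ungapped megabase
#'
#' Locus count divided by the assembly length with assembly gaps
#' (N runs) excluded, expressed per megabase.
#'
#' @param count number of loci (>= 0).
#' @param assembly_length total assembly length in bases.
#' @param gap_length total bases in assembly gaps
#'   (`assembly_length > gap_length >= 0`).
#' @return loci per ungapped megabase; `NA` if the ungapped length is
#'   zero.
#' @export
compute_density <- function(count, assembly_length, gap_length = 0) {
  stopifnot(count >= 0, gap_length >= 0, assembly_length >= gap_length)
  ungapped <- assembly_length - gap_length
  if (ungapped == 0) return(NA_real_)
  count / (ungapped / 1e6)
}

#' Logarithmic trendline of locus count against genome size
#'
#' Ordinary least squares of per-genome counts on `log10` of the
#' ungapped genome size in megabases, with the coefficient of
#' determination.
#'
#' @param counts integer vector of per-genome locus counts (>= 3
#'   genomes).
#' @param sizes ungapped genome sizes in megabases (> 0).
#' @return list with `slope`, `intercept`, `r_squared`; `r_squared` is
#'   `NA` (with a warning) when the sizes are constant.
#' @export
log_trend_fit <- function(counts, sizes) {
  stopifnot(length(counts) == length(sizes), length(counts) >= 3,
            all(sizes > 0))
  x <- log10(sizes)
  if (length(unique(x)) == 1L) {
    warning("constant genome sizes: trend fit undefined")
    return(list(slope = NA_real_, intercept = NA_real_,
                r_squared = NA_real_))
  }
  fit <- lm(counts ~ x)
  ss_res <- sum(residuals(fit)^2)
  ss_tot <- sum((counts - mean(counts))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - ss_res / ss_tot
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = r2)
}

#' Per-genome assembly statistics and ECRT density
#'
#' @param genomes named character vector of genome sequences.
#' @param counts named integer vector of per-genome locus counts
#'   (missing genomes count 0).
#' @param min_gap_run minimum N-run length counted as an assembly gap.
#' @return data.frame: `genome_id`, `assembly_length`, `gap_length`,
#'   `ecrt_count`, `ungapped_mb`, `density`.
#' @export
genome_stats <- function(genomes, counts, min_gap_run = 1L) {
  rows <- lapply(names(genomes), function(g) {
    gl <- sum(gap_ranges(genomes[[g]], min_gap_run)$end -
                gap_ranges(genomes[[g]], min_gap_run)$start)
    al <- nchar(genomes[[g]])
    cnt <- if (g %in% names(counts)) counts[[g]] else 0L
    data.frame(genome_id = g, assembly_length = al, gap_length = gl,
               ecrt_count = cnt, ungapped_mb = (al - gl) / 1e6,
               density = compute_density(cnt, al, gl))
  })
  do.call(rbind, rows)
}

#' OTU-by-species distribution matrix
#'
#' One row per species, one column per OTU label plus `"inner"`; cells
#' count placed loci. Column sums give per-OTU totals and the number
#' of species with a non-zero cell gives per-OTU species presence.
#'
#' @param placements data.frame with `query_id`, `otu_label` (placed
#'   queries only, e.g. from [place_queries()] filtered to
#'   `status == "placed"`).
#' @param species_map named character vector: query/locus id ->
#'   species.
#' @return list with `matrix` (integer matrix), `otu_totals`,
#'   `species_presence`.
#' @export
build_distribution <- function(placements, species_map) {
  unmapped <- setdiff(placements$query_id, names(species_map))
  if (length(unmapped))
    stop("loci without a species mapping: ",
         paste(head(unmapped, 5), collapse = ", "))
  sp <- unname(species_map[placements$query_id])
  otu <- placements$otu_label
  otus <- sort(unique(otu))
  otus <- c(setdiff(otus, "inner"), intersect("inner", otus))
  M <- table(factor(sp, levels = sort(unique(sp))),
             factor(otu, levels = otus))
  M <- unclass(as.matrix(M))
  list(matrix = M, otu_totals = colSums(M),
       species_presence = colSums(M > 0))
}
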