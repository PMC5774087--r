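#' Genome layout for simulation and mapping
#'
#' Describes the physical and genetic coordinate frame the simulator and the
#' pipeline operate on: chromosome sizes in bp and cM, the physical positions
#' of the segregating SNPs, and an optional relative crossover-intensity track
#' in 1-Mb windows (uniform when absent).
#'
#' @param chromosomes data.frame with columns `name`, `length_bp`,
#'   `length_cM`; one row per chromosome.
#' @param snp_positions named list (one element per chromosome, matching
#'   `chromosomes$name`) of strictly increasing 1-based SNP positions.
#' @param crossover_intensity optional named list of non-negative per-1-Mb
#'   relative weights per chromosome; `NULL` means uniform.
#' @return object of class `genome_layout`.
#' @export
genome_layout <- function(chromosomes, snp_positions,
                          crossover_intensity = NULL) {
  stopifnot(is.data.frame(chromosomes),
            all(c("name", "length_bp", "length_cM") %in% names(chromosomes)))
  chromosomes$name <- as.character(chromosomes$name)
  if (any(chromosomes$length_bp <= 0) || any(chromosomes$length_cM <= 0))
    stop("chromosome lengths must be positive")
  if (anyDuplicated(chromosomes$name))
    stop("duplicated chromosome names")
  if (!all(chromosomes$name %in% names(snp_positions)))
    stop("snp_positions must have an entry for every chromosome")
  for (ch in chromosomes$name) {
    p <- snp_positions[[ch]]
    if (length(p) == 0) stop("empty snp_positions for chromosome ", ch)
    if (is.unsorted(p, strictly = TRUE))
      stop("snp positions must be strictly increasing on chromosome ", ch)
    L <- chromosomes$length_bp[chromosomes$name == ch]
    if (p[1] < 1 || p[length(p)] > L)
      stop("snp positions outside chromosome ", ch)
  }
  if (!is.null(crossover_intensity)) {
    for (ch in chromosomes$name) {
      w <- crossover_intensity[[ch]]
      if (is.null(w)) stop("missing crossover intensity for ", ch)
      if (any(w < 0) || all(w == 0))
        stop("intensity weights must be non-negative and not all zero")
    }
  }
  structure(list(chromosomes = chromosomes,
                 snp_positions = lapply(snp_positions[chromosomes$name],
                                        as.numeric),
                 crossover_intensity = crossover_intensity),
            class = "genome_layout")
}

#' Convenience layout with evenly spaced SNPs
#'
#' Builds a `genome_layout` with `n_chrom` equally sized chromosomes and
#' evenly spaced SNPs, a miniature of the maize coordinate frame the method
#' was developed on. Defaults give the ~1 SNP / 50 kb marker density of a
#' low-coverage GBS SNP set.
#'
#' @param n_chrom number of chromosomes.
#' @param length_bp physical length per chromosome (bp).
#' @param length_cM genetic length per chromosome (cM).
#' @param n_snps number of SNPs per chromosome; the default, one SNP per
#'   4 kb, reproduces a dense parental SNP set whose 0.08 site-sampling
#'   leaves ~1 observed SNP per 50 kb per line.
#' @param crossover_intensity optional list as in [genome_layout()].
#' @return a `genome_layout`.
#' @export
uniform_layout <- function(n_chrom = 2, length_bp = 1e8, length_cM = 120,
                           n_snps = round(length_bp / 4e3),
                           crossover_intensity = NULL) {
  nm <- paste0("chr", seq_len(n_chrom))
  chr <- data.frame(name = nm, length_bp = length_bp, length_cM = length_cM)
  pos <- round(seq(1, length_bp, length.out = n_snps))
  pos <- unique(pos)
  snps <- stats::setNames(rep(list(pos), n_chrom), nm)
  genome_layout(chr, snps, crossover_intensity)
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("genome_layout:", nrow(x$chromosomes), "chromosome(s)\n")
  n <- vapply(x$snp_positions, length, integer(1))
  df <- cbind(x$chromosomes, n_snps = n)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Simulation parameters for the GBS RIL generator
#'
#' Defaults are the study conditions of the population the pipeline targets:
#' six generations of selfing by single-seed descent, each SNP observed in a
#' line with probability 0.08 (the site-sampling consequence of ~0.08x
#' sequencing depth), and parent-specific allele miscall rates of 0.6%
#' (parent 1) and 0.9% (parent 2).
#'
#' @param n_lines number of RILs to simulate.
#' @param n_selfing_generations selfing generations after the F1 (>= 1).
#' @param site_sampling_rate probability a SNP site is observed in a line.
#' @param error_rate_p1,error_rate_p2 probability an emitted parent-1 /
#'   parent-2 allele is miscalled as the other parent's allele.
#' @param seed integer RNG seed.
#' @return object of class `sim_params`.
#' @export
sim_params <- function(n_lines = 200, n_selfing_generations = 6,
                       site_sampling_rate = 0.08,
                       error_rate_p1 = 0.006, error_rate_p2 = 0.009,
                       seed = 1L) {
  rates <- c(site_sampling_rate, error_rate_p1, error_rate_p2)
  if (any(rates < 0) || any(rates > 1)) stop("rates must be in [0, 1]")
  if (site_sampling_rate == 0) stop("site_sampling_rate must be > 0")
  if (n_selfing_generations < 1) stop("n_selfing_generations must be >= 1")
  if (n_lines < 1) stop("n_lines must be >= 1")
  structure(list(n_lines = as.integer(n_lines),
                 n_selfing_generations = as.integer(n_selfing_generations),
                 site_sampling_rate = site_sampling_rate,
                 error_rate_p1 = error_rate_p1,
                 error_rate_p2 = error_rate_p2,
                 seed = as.integer(seed)),
            class = "sim_params")
}
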