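# Meiosis-level RIL population simulator.
#
# A haplotype is a list(ends, founder): `ends` are increasing segment end
# positions (bp, last == chromosome length), `founder` in {1, 2} labels the
# parental origin of each segment. Crossovers per meiosis are Poisson with
# mean genetic_length_cM / 100 (no interference), positions drawn from the
# layout's crossover-intensity track (uniform by default).

.hap_founder_at <- function(hap, x) {
  hap$founder[findInterval(x, hap$ends, left.open = TRUE) + 1L]
}

# extract founder segments of `hap` over the half-open physical range (a, b]
.hap_slice <- function(hap, a, b) {
  starts <- c(0, hap$ends[-length(hap$ends)])
  keep <- which(hap$ends > a & starts < b)
  ends <- pmin(hap$ends[keep], b)
  list(ends = ends, founder = hap$founder[keep])
}

.hap_compact <- function(ends, founder) {
  if (length(ends) > 1L) {
    same <- c(founder[-1] == founder[-length(founder)], FALSE)
    ends <- ends[!same]
    founder <- founder[!same]
  }
  list(ends = ends, founder = founder)
}

.draw_crossovers <- function(k, length_bp, intensity) {
  if (k == 0L) return(numeric(0))
  if (is.null(intensity)) return(sort(stats::runif(k, 0, length_bp)))
  n_win <- length(intensity)
  win_bp <- length_bp / n_win
  w <- sample.int(n_win, k, replace = TRUE, prob = intensity)
  sort((w - 1) * win_bp + stats::runif(k, 0, win_bp))
}

# one meiosis: recombine two homologs into a gamete haplotype
.meiosis <- function(h1, h2, length_bp, length_cM, intensity = NULL) {
  k <- stats::rpois(1L, length_cM / 100)
  phase <- if (stats::runif(1) < 0.5) 1L else 2L
  if (k == 0L) {
    g <- if (phase == 1L) h1 else h2
    return(list(hap = g, n_xo = 0L, xo_pos = numeric(0)))
  }
  pos <- .draw_crossovers(k, length_bp, intensity)
  cuts <- c(0, pos, length_bp)
  ends <- numeric(0); founder <- integer(0)
  cur <- phase
  for (i in seq_len(length(cuts) - 1L)) {
    h <- if (cur == 1L) h1 else h2
    s <- .hap_slice(h, cuts[i], cuts[i + 1L])
    ends <- c(ends, s$ends); founder <- c(founder, s$founder)
    cur <- 3L - cur
  }
  list(hap = .hap_compact(ends, founder), n_xo = as.integer(k), xo_pos = pos)
}

# diploid genotype mosaic from two haplotypes; integer bp, 1-based inclusive
.diploid_mosaic <- function(h1, h2, length_bp) {
  ends <- sort(unique(c(h1$ends, h2$ends)))
  starts <- c(0, ends[-length(ends)])
  mid <- (starts + ends) / 2
  f1 <- .hap_founder_at(h1, mid)
  f2 <- .hap_founder_at(h2, mid)
  g <- ifelse(f1 == f2, ifelse(f1 == 1L, "P1", "P2"), "HET")
  keep <- c(g[-1] != g[-length(g)], TRUE)
  ends <- ends[keep]; g <- g[keep]
  iend <- pmin(floor(ends), length_bp)
  istart <- c(1, iend[-length(iend)] + 1)
  ok <- istart <= iend           # drop sub-bp slivers created by flooring
  data.frame(start = istart[ok], end = iend[ok], genotype = g[ok],
             stringsAsFactors = FALSE)
}

#' Simulate a selfed RIL population with GBS-like sparse observations
#'
#' Starts every line as an F1 (one chromosome from each parent), then applies
#' `n_selfing_generations` rounds of self-pollination by single-seed descent:
#' each generation two independent meioses produce the two gametes of the
#' single selected seed. Crossover counts per meiosis are Poisson with mean
#' `length_cM / 100`; positions follow the layout's crossover-intensity track
#' (uniform by default; no interference). Sparse observations mimic
#' low-coverage GBS: each SNP site is observed in a line independently with
#' probability `site_sampling_rate`; at a heterozygous site a single
#' observation emits one of the two parental alleles with probability 1/2;
#' the emitted allele is miscalled as the other parent's allele with the
#' parent-appropriate error rate.
#'
#' @param layout a [genome_layout()].
#' @param params a [sim_params()].
#' @return list of class `ril_sim` with elements
#'   `mosaics` (data.frame line, chrom, start, end, genotype — the true
#'   genotype mosaic, tiling each chromosome),
#'   `observations` (data.frame chrom, pos, line, allele in \{"P1","P2"\}),
#'   `meioses` (data.frame line, chrom, generation, gamete, n_crossovers),
#'   `layout`, `params`.
#' @export
simulate_population <- function(layout, params) {
  stopifnot(inherits(layout, "genome_layout"), inherits(params, "sim_params"))
  set.seed(params$seed)
  chrs <- layout$chromosomes
  lines_id <- sprintf("L%04d", seq_len(params$n_lines))

  mos_list <- vector("list", params$n_lines * nrow(chrs))
  mei_list <- vector("list", params$n_lines * nrow(chrs))
  obs_list <- vector("list", params$n_lines * nrow(chrs))
  k <- 0L
  for (li in seq_len(params$n_lines)) {
    for (ci in seq_len(nrow(chrs))) {
      L <- chrs$length_bp[ci]; cm <- chrs$length_cM[ci]
      ch <- chrs$name[ci]
      intensity <- if (is.null(layout$crossover_intensity)) NULL
                   else layout$crossover_intensity[[ch]]
      h1 <- list(ends = L, founder = 1L)
      h2 <- list(ends = L, founder = 2L)
      nxo <- integer(2L * params$n_selfing_generations)
      for (g in seq_len(params$n_selfing_generations)) {
        m1 <- .meiosis(h1, h2, L, cm, intensity)
        m2 <- .meiosis(h1, h2, L, cm, intensity)
        h1 <- m1$hap; h2 <- m2$hap
        nxo[2L * g - 1L] <- m1$n_xo; nxo[2L * g] <- m2$n_xo
      }
      mos <- .diploid_mosaic(h1, h2, L)
      k <- k + 1L
      mos_list[[k]] <- data.frame(line = lines_id[li], chrom = ch,
                                  mos, stringsAsFactors = FALSE)
      mei_list[[k]] <- data.frame(
        line = lines_id[li], chrom = ch,
        generation = rep(seq_len(params$n_selfing_generations), each = 2L),
        gamete = rep(1:2, params$n_selfing_generations),
        n_crossovers = nxo, stringsAsFactors = FALSE)
      obs_list[[k]] <- .sample_observations(mos, layout$snp_positions[[ch]],
                                            ch, lines_id[li], params)
    }
  }
  structure(list(mosaics = do.call(rbind, mos_list),
                 observations = do.call(rbind, obs_list),
                 meioses = do.call(rbind, mei_list),
                 layout = layout, params = params),
            class = "ril_sim")
}

.sample_observations <- function(mos, snps, chrom, line, params) {
  seen <- which(stats::runif(length(snps)) < params$site_sampling_rate)
  if (length(seen) == 0L)
    return(data.frame(chrom = character(0), pos = numeric(0),
                      line = character(0), allele = character(0),
                      stringsAsFactors = FALSE))
  pos <- snps[seen]
  g <- mos$genotype[findInterval(pos, mos$end, left.open = TRUE) + 1L]
  allele <- ifelse(g == "HET",
                   ifelse(stats::runif(length(g)) < 0.5, "P1", "P2"),
                   g)
  u <- stats::runif(length(allele))
  flip <- (allele == "P1" & u < params$error_rate_p1) |
          (allele == "P2" & u < params$error_rate_p2)
  allele[flip] <- ifelse(allele[flip] == "P1", "P2", "P1")
  data.frame(chrom = chrom, pos = pos, line = line, allele = allele,
             stringsAsFactors = FALSE)
}

#' True genotypes of simulated lines at arbitrary positions
#'
#' Looks up each line's true mosaic genotype at the requested physical
#' positions, returning the numeric QTL coding -1 (P1 homozygote),
#' 0 (heterozygote), +1 (P2 homozygote).
#'
#' @param sim a `ril_sim` (or its `mosaics` data.frame).
#' @param positions named list per chromosome of bp positions.
#' @return numeric matrix lines x loci; columns named `chrom:pos`.
#' @export
truth_genotypes <- function(sim, positions) {
  mos <- if (inherits(sim, "ril_sim")) sim$mosaics else sim
  lines_id <- unique(mos$line)
  cols <- unlist(lapply(names(positions), function(ch)
    paste0(ch, ":", positions[[ch]])))
  out <- matrix(NA_real_, length(lines_id), length(cols),
                dimnames = list(lines_id, cols))
  code <- c(P1 = -1, HET = 0, P2 = 1)
  for (li in lines_id) {
    j <- 0L
    for (ch in names(positions)) {
      m <- mos[mos$line == li & mos$chrom == ch, ]
      p <- positions[[ch]]
      g <- m$genotype[findInterval(p, m$end, left.open = TRUE) + 1L]
      out[li, j + seq_along(p)] <- code[g]
      j <- j + length(p)
    }
  }
  out
}

#' Residual heterozygosity of true mosaics
#'
#' Fraction of each line's physical genome that is heterozygous in the true
#' simulated mosaic; after g selfing generations the expectation is (1/2)^g.
#'
#' @param sim a `ril_sim` or mosaic data.frame.
#' @return named numeric vector, one fraction per line.
#' @export
het_fraction_true <- function(sim) {
  mos <- if (inherits(sim, "ril_sim")) sim$mosaics else sim
  len <- mos$end - mos$start + 1
  tot <- tapply(len, mos$line, sum)
  het <- tapply(len * (mos$genotype == "HET"), mos$line, sum)
  stats::setNames(as.vector(het / tot), names(tot))
}

#' Simulate multi-environment phenotypes with planted additive QTLs
#'
#' Generates `y = mu + env_j + sum_k a_k x_k + e`, with the RIL genotype at
#' each planted locus coded x in \{-1, 0, +1\} for \{P1, HET, P2\} and
#' residuals N(0, residual_sd^2). The realized per-locus percentage of
#' variance explained is attached as attribute `realized_pve`.
#'
#' @param sim a `ril_sim`.
#' @param qtl data.frame with columns `chrom`, `pos`, `effect` (trait units);
#'   may have zero rows for a null trait.
#' @param env_effects numeric vector of per-environment shifts (length =
#'   number of environments).
#' @param residual_sd residual standard deviation (> 0).
#' @param mu grand mean.
#' @param trait trait name recorded in the output.
#' @param seed RNG seed.
#' @return data.frame (line, environment, trait, value) with attribute
#'   `realized_pve`.
#' @export
simulate_phenotypes <- function(sim, qtl, env_effects = 0, residual_sd = 1,
                                mu = 0, trait = "trait1", seed = 1L) {
  stopifnot(residual_sd > 0)
  set.seed(seed)
  chrs <- sim$layout$chromosomes
  if (nrow(qtl) > 0) {
    for (i in seq_len(nrow(qtl))) {
      ci <- match(qtl$chrom[i], chrs$name)
      if (is.na(ci) || qtl$pos[i] < 1 || qtl$pos[i] > chrs$length_bp[ci])
        stop("QTL locus outside layout: ", qtl$chrom[i], ":", qtl$pos[i])
    }
    positions <- split(qtl$pos, qtl$chrom)
    X <- truth_genotypes(sim, positions)
    # columns of X follow split() order; realign to qtl rows
    want <- paste0(qtl$chrom, ":", qtl$pos)
    X <- X[, want, drop = FALSE]
    gvalue <- as.vector(X %*% qtl$effect)
  } else {
    lines_id <- unique(sim$mosaics$line)
    X <- NULL
    gvalue <- stats::setNames(rep(0, length(lines_id)), lines_id)
  }
  lines_id <- names(gvalue) %||% rownames(X)
  if (is.null(lines_id)) lines_id <- rownames(X)
  n_env <- length(env_effects)
  out <- do.call(rbind, lapply(seq_len(n_env), function(j) {
    data.frame(line = lines_id, environment = paste0("env", j),
               trait = trait,
               value = mu + env_effects[j] + gvalue +
                 stats::rnorm(length(gvalue), 0, residual_sd),
               stringsAsFactors = FALSE)
  }))
  if (nrow(qtl) > 0) {
    vy <- stats::var(out$value - env_effects[match(out$environment,
                                                   paste0("env", seq_len(n_env)))])
    pve <- vapply(seq_len(nrow(qtl)), function(k)
      100 * qtl$effect[k]^2 * stats::var(X[, k]) / vy, numeric(1))
    attr(out, "realized_pve") <- stats::setNames(
      pve, paste0(qtl$chrom, ":", qtl$pos))
  } else attr(out, "realized_pve") <- numeric(0)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate backcross progeny of a recombinant introgression line
#'
#' Models the progeny test used to verify a QTL carried on a heterozygous
#' donor segment: each progeny inherits the donor segment (becoming HET) with
#' probability 1/2, optionally with recombination inside the segment, and
#' carriers of the donor allele at the QTL position are shifted by
#' `effect / 2` (one dose).
#'
#' @param segment c(start_bp, end_bp) of the heterozygous donor segment.
#' @param markers numeric vector of marker positions (bp) within or near the
#'   segment.
#' @param n_progeny number of progeny (>= 2).
#' @param effect additive (homozygote-difference / 2) effect in trait units;
#'   heterozygous carriers shift by `effect / 2`.
#' @param qtl_pos QTL position (bp); defaults to the segment midpoint.
#' @param residual_sd phenotype residual SD.
#' @param base_mean non-carrier phenotype mean.
#' @param recomb_cM genetic length of the segment used to draw within-segment
#'   crossovers (0 disables recombination: markers co-segregate perfectly).
#' @param seed RNG seed.
#' @return data.frame (progeny, one `H`/`A` genotype column per marker,
#'   carrier, phenotype). `H` = heterozygous (donor present), `A` =
#'   homozygous recurrent parent.
#' @export
simulate_backcross_progeny <- function(segment, markers, n_progeny, effect,
                                       qtl_pos = mean(segment),
                                       residual_sd = 1, base_mean = 0,
                                       recomb_cM = 0, seed = 1L) {
  if (n_progeny < 2) stop("n_progeny must be >= 2")
  stopifnot(length(segment) == 2, segment[2] > segment[1])
  set.seed(seed)
  m <- length(markers)
  geno <- matrix("A", n_progeny, m)
  carrier <- logical(n_progeny)
  for (i in seq_len(n_progeny)) {
    phase <- stats::runif(1) < 0.5          # donor-leading gamete?
    if (recomb_cM > 0) {
      k <- stats::rpois(1, recomb_cM / 100)
      cuts <- sort(stats::runif(k, segment[1], segment[2]))
    } else cuts <- numeric(0)
    donor_at <- function(p) {
      n_before <- findInterval(p, cuts)
      (n_before %% 2 == 0) == phase           # phase TRUE: donor-leading
    }
    don <- vapply(markers, donor_at, logical(1))
    geno[i, don] <- "H"
    carrier[i] <- donor_at(qtl_pos)
  }
  phen <- base_mean + ifelse(carrier, effect / 2, 0) +
    stats::rnorm(n_progeny, 0, residual_sd)
  out <- data.frame(progeny = sprintf("bc%03d", seq_len(n_progeny)),
                    geno, carrier = carrier, phenotype = phen,
                    stringsAsFactors = FALSE)
  names(out)[1 + seq_len(m)] <- paste0("m", seq_len(m))
  out
}
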