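# Sliding-window genotype caller for sparse low-coverage SNP observations.
#
# Thresholds follow the modified sliding-window method: 15-SNP windows called
# homozygous when > 11/15 sites match one parent, heterozygous runs shorter
# than 7 windows treated as breakpoints and split at the midpoint, block
# filters (< 5 SNPs or < 300 kb; heterozygous < 15 SNPs or < 1 Mb), and line
# filters (> 15% residual heterozygosity or > 360 breakpoints). All
# comparisons are strict inequalities; ties keep the item.

#' Configuration of the sliding-window genotype caller
#'
#' @param window_size SNPs per window.
#' @param hom_threshold minimum same-parent site count for a homozygous call,
#'   exclusive: homozygous when count > `hom_threshold`.
#' @param het_run_breakpoint_max exclusive upper bound on a heterozygous
#'   window-run length treated as a crossover breakpoint (runs of 1 to
#'   `het_run_breakpoint_max - 1` windows are split at their midpoint).
#' @param block_min_snps,block_min_bp exclusive lower bounds below which any
#'   block is set missing.
#' @param het_block_min_snps,het_block_min_bp exclusive lower bounds below
#'   which a heterozygous block is set missing.
#' @param line_max_het_fraction,line_max_breakpoints exclusive upper bounds
#'   above which a line is excluded.
#' @param transient_window_blocks,transient_min_switches operational
#'   definition of "frequently transient genotypes": at least
#'   `transient_min_switches` genotype switches within any
#'   `transient_window_blocks` consecutive non-missing blocks consolidates
#'   the stretch into one heterozygous block.
#' @return object of class `caller_config`.
#' @export
caller_config <- function(window_size = 15L, hom_threshold = 11L,
                          het_run_breakpoint_max = 7L,
                          block_min_snps = 5L, block_min_bp = 3e5,
                          het_block_min_snps = 15L, het_block_min_bp = 1e6,
                          line_max_het_fraction = 0.15,
                          line_max_breakpoints = 360L,
                          transient_window_blocks = 10L,
                          transient_min_switches = 3L) {
  if (!(hom_threshold > 0 && hom_threshold < window_size))
    stop("need 0 < hom_threshold < window_size")
  if (any(c(block_min_snps, block_min_bp, het_block_min_snps,
            het_block_min_bp) <= 0)) stop("block minima must be positive")
  structure(list(window_size = as.integer(window_size),
                 hom_threshold = as.integer(hom_threshold),
                 het_run_breakpoint_max = as.integer(het_run_breakpoint_max),
                 block_min_snps = as.integer(block_min_snps),
                 block_min_bp = block_min_bp,
                 het_block_min_snps = as.integer(het_block_min_snps),
                 het_block_min_bp = het_block_min_bp,
                 line_max_het_fraction = line_max_het_fraction,
                 line_max_breakpoints = as.integer(line_max_breakpoints),
                 transient_window_blocks = as.integer(transient_window_blocks),
                 transient_min_switches = as.integer(transient_min_switches)),
            class = "caller_config")
}

#' Call sliding windows over one line's observed SNPs
#'
#' Slides a `window_size`-SNP window by one SNP over the line's observed
#' alleles in position order and calls each window P1 or P2 when more than
#' `hom_threshold` sites match that parent, HET otherwise.
#'
#' @param pos SNP positions (sorted increasing).
#' @param allele parental allele per SNP, `"P1"` or `"P2"`.
#' @param cfg a [caller_config()].
#' @return data.frame (first_snp, last_snp, genotype, p1_count, p2_count);
#'   zero rows when fewer than `window_size` SNPs are observed.
#' @export
call_windows <- function(pos, allele, cfg = caller_config()) {
  bad <- !(allele %in% c("P1", "P2"))
  if (any(bad))
    stop("unknown allele code at position ", pos[which(bad)[1]],
         ": '", allele[which(bad)[1]], "'")
  if (is.unsorted(pos)) {
    o <- order(pos); pos <- pos[o]; allele <- allele[o]
  }
  n <- length(pos); w <- cfg$window_size
  if (n < w)
    return(data.frame(first_snp = integer(0), last_snp = integer(0),
                      genotype = character(0), p1_count = integer(0),
                      p2_count = integer(0), stringsAsFactors = FALSE))
  cs <- c(0L, cumsum(allele == "P1"))
  first <- seq_len(n - w + 1L)
  p1 <- cs[first + w] - cs[first]
  p2 <- w - p1
  g <- ifelse(p1 > cfg$hom_threshold, "P1",
              ifelse(p2 > cfg$hom_threshold, "P2", "HET"))
  data.frame(first_snp = first, last_snp = first + w - 1L, genotype = g,
             p1_count = p1, p2_count = p2, stringsAsFactors = FALSE)
}

#' Resolve short heterozygous window runs into breakpoints
#'
#' A maximal HET run shorter than `het_run_breakpoint_max` windows flanked by
#' two different homozygous genotypes marks a crossover: the run is split at
#' its midpoint, the left half taking the left flank's genotype and the right
#' half the right flank's (odd runs give the extra window to the left). Runs
#' flanked by the same genotype adopt it; short runs at a chromosome end
#' adopt the single flanking genotype. Runs of `het_run_breakpoint_max` or
#' more windows are retained as heterozygous.
#'
#' @param genotypes character vector of window genotypes (from
#'   [call_windows()]).
#' @param cfg a [caller_config()].
#' @return character vector of resolved window genotypes.
#' @export
resolve_breakpoints <- function(genotypes, cfg = caller_config()) {
  g <- as.character(genotypes)
  r <- rle(g)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in seq_along(r$values)) {
    if (r$values[i] != "HET" || r$lengths[i] >= cfg$het_run_breakpoint_max)
      next
    left <- if (i > 1L) r$values[i - 1L] else NA_character_
    right <- if (i < length(r$values)) r$values[i + 1L] else NA_character_
    len <- r$lengths[i]
    if (is.na(left) && is.na(right)) next          # all-HET chromosome
    if (is.na(left)) { g[starts[i]:ends[i]] <- right; next }
    if (is.na(right)) { g[starts[i]:ends[i]] <- left; next }
    if (left == right) { g[starts[i]:ends[i]] <- left; next }
    n_left <- ceiling(len / 2)                      # extra window to the left
    g[starts[i]:(starts[i] + n_left - 1L)] <- left
    if (n_left < len) g[(starts[i] + n_left):ends[i]] <- right
  }
  g
}

#' Merge resolved window calls into genotype blocks
#'
#' Assigns each observed SNP the genotype of the window centered on it (SNPs
#' within half a window of a chromosome end take the terminal window's call),
#' merges runs of identical per-SNP genotype into blocks, and places the
#' physical boundary between adjacent blocks at the midpoint between their
#' flanking observed SNPs. Coordinates are 1-based inclusive and blocks tile
#' `[1, chrom_length]`.
#'
#' @param resolved character vector of resolved window genotypes.
#' @param pos observed SNP positions the windows were called over.
#' @param chrom_length chromosome physical length (bp).
#' @param cfg a [caller_config()].
#' @return data.frame (start, end, genotype, snp_count). A single MISSING
#'   block when no windows could be called.
#' @export
merge_to_blocks <- function(resolved, pos, chrom_length,
                            cfg = caller_config()) {
  n <- length(pos)
  if (length(resolved) == 0L)
    return(data.frame(start = 1, end = chrom_length, genotype = "MISSING",
                      snp_count = n, stringsAsFactors = FALSE))
  offset <- (cfg$window_size - 1L) %/% 2L
  idx <- pmin(pmax(seq_len(n) - offset, 1L), length(resolved))
  snp_g <- resolved[idx]
  r <- rle(snp_g)
  ends_i <- cumsum(r$lengths)
  starts_i <- ends_i - r$lengths + 1L
  nb <- length(r$values)
  start_bp <- numeric(nb); end_bp <- numeric(nb)
  for (i in seq_len(nb)) {
    start_bp[i] <- if (i == 1L) 1
      else floor((pos[starts_i[i] - 1L] + pos[starts_i[i]]) / 2) + 1
    end_bp[i] <- if (i == nb) chrom_length
      else floor((pos[ends_i[i]] + pos[ends_i[i] + 1L]) / 2)
  }
  data.frame(start = start_bp, end = end_bp, genotype = r$values,
             snp_count = r$lengths, stringsAsFactors = FALSE)
}

# consolidate "frequently transient" stretches into one HET block: only
# *small* non-missing blocks (under the heterozygous-block minima) are
# considered; a run of consecutive small blocks is consolidated when at
# least `min_switches` genotype switches occur within any `win` of them
.consolidate_transient <- function(blocks, win, min_switches,
                                   small_min_snps, small_min_bp) {
  len <- blocks$end - blocks$start + 1
  small <- blocks$genotype != "MISSING" &
    (blocks$snp_count < small_min_snps | len < small_min_bp)
  nm <- which(small)
  if (length(nm) < 2L) return(blocks)
  # runs of small blocks: consecutive in block order, allowing interleaved
  # MISSING but broken by any large non-missing block
  brk <- vapply(seq_len(length(nm) - 1L), function(k) {
    if (nm[k + 1L] - nm[k] < 2L) return(FALSE)
    any(blocks$genotype[(nm[k] + 1L):(nm[k + 1L] - 1L)] != "MISSING")
  }, logical(1))
  run_id <- cumsum(c(TRUE, brk))
  gn <- blocks$genotype[nm]
  mark <- rep(FALSE, length(nm))
  for (rid in unique(run_id)) {
    ii <- which(run_id == rid)
    if (length(ii) < 2L) next
    sw <- gn[ii][-1] != gn[ii][-length(ii)]
    for (s in seq_len(length(ii) - 1L)) {
      e <- min(length(ii), s + win - 1L)
      if (sum(sw[s:(e - 1L)]) >= min_switches) mark[ii[s:e]] <- TRUE
    }
  }
  if (!any(mark)) return(blocks)
  # merge each maximal marked stretch (including interleaved MISSING) to HET
  mr <- rle(mark)
  me <- cumsum(mr$lengths); ms <- me - mr$lengths + 1L
  drop <- logical(nrow(blocks))
  for (i in seq_along(mr$values)) {
    if (!mr$values[i]) next
    b1 <- nm[ms[i]]; b2 <- nm[me[i]]
    blocks$genotype[b1] <- "HET"
    blocks$end[b1] <- blocks$end[b2]
    blocks$snp_count[b1] <- sum(blocks$snp_count[b1:b2])
    if (b2 > b1) drop[(b1 + 1L):b2] <- TRUE
  }
  blocks[!drop, , drop = FALSE]
}

#' Apply block-level filters to a raw block mosaic
#'
#' Sets blocks with too few sequenced SNPs or too short a physical span to
#' missing, consolidates stretches of frequently switching genotypes into a
#' single heterozygous block, applies the stricter heterozygous-block minima,
#' and merges same-genotype blocks separated only by missing regions (the gap
#' is absorbed into the merged block). Breakpoints are genotype transitions
#' between consecutive non-missing blocks.
#'
#' @param blocks data.frame from [merge_to_blocks()].
#' @param cfg a [caller_config()].
#' @return filtered block data.frame with attributes `n_breakpoints` and
#'   `het_fraction` (heterozygous share of the non-missing physical length).
#' @export
filter_blocks <- function(blocks, cfg = caller_config()) {
  b <- blocks
  len <- b$end - b$start + 1
  small <- b$genotype != "MISSING" &
    (b$snp_count < cfg$block_min_snps | len < cfg$block_min_bp)
  b$genotype[small] <- "MISSING"
  b <- .consolidate_transient(b, cfg$transient_window_blocks,
                              cfg$transient_min_switches,
                              cfg$het_block_min_snps, cfg$het_block_min_bp)
  len <- b$end - b$start + 1
  het_small <- b$genotype == "HET" &
    (b$snp_count < cfg$het_block_min_snps | len < cfg$het_block_min_bp)
  b$genotype[het_small] <- "MISSING"

  # group consecutive non-missing blocks of equal genotype, absorbing gaps
  nm <- which(b$genotype != "MISSING")
  chrom_start <- b$start[1]; chrom_end <- b$end[nrow(b)]
  if (length(nm) == 0L) {
    out <- data.frame(start = chrom_start, end = chrom_end,
                      genotype = "MISSING",
                      snp_count = sum(b$snp_count), stringsAsFactors = FALSE)
    attr(out, "n_breakpoints") <- 0L
    attr(out, "het_fraction") <- NA_real_
    return(out)
  }
  gn <- b$genotype[nm]
  grp <- cumsum(c(TRUE, gn[-1] != gn[-length(gn)]))
  gs <- tapply(b$start[nm], grp, min)
  ge <- tapply(b$end[nm], grp, max)
  gg <- tapply(gn, grp, function(x) x[1])
  gc <- tapply(b$snp_count[nm], grp, sum)
  k <- length(gs)
  rows <- list()
  if (gs[1] > chrom_start)
    rows[[length(rows) + 1L]] <- c(chrom_start, gs[1] - 1, NA, 0)
  for (i in seq_len(k)) {
    rows[[length(rows) + 1L]] <- c(gs[i], ge[i], i, gc[i])
    if (i < k && ge[i] + 1 < gs[i + 1])
      rows[[length(rows) + 1L]] <- c(ge[i] + 1, gs[i + 1] - 1, NA, 0)
  }
  if (ge[k] < chrom_end)
    rows[[length(rows) + 1L]] <- c(ge[k] + 1, chrom_end, NA, 0)
  m <- do.call(rbind, rows)
  out <- data.frame(start = m[, 1], end = m[, 2],
                    genotype = ifelse(is.na(m[, 3]), "MISSING",
                                      as.character(gg[m[, 3]])),
                    snp_count = as.integer(m[, 4]), stringsAsFactors = FALSE)
  covered <- sum((out$end - out$start + 1)[out$genotype != "MISSING"])
  het_len <- sum((out$end - out$start + 1)[out$genotype == "HET"])
  attr(out, "n_breakpoints") <- as.integer(k - 1L)
  attr(out, "het_fraction") <- if (covered > 0) het_len / covered else NA_real_
  out
}

#' Call genotype-block mosaics for a whole population
#'
#' Runs the window caller, breakpoint resolution, block merging and block
#' filters for every line x chromosome of a sparse observation table.
#' Chromosomes with fewer observed SNPs than one window are entirely missing
#' for that line.
#'
#' @param observations data.frame (chrom, pos, line, allele).
#' @param layout a [genome_layout()].
#' @param cfg a [caller_config()].
#' @return list of class `mosaic_set`: `blocks` (line, chrom, start, end,
#'   genotype, snp_count) and `line_stats` (line, het_fraction,
#'   n_breakpoints).
#' @export
call_mosaics <- function(observations, layout, cfg = caller_config()) {
  lines_id <- sort(unique(observations$line))
  chrs <- layout$chromosomes
  res <- vector("list", length(lines_id) * nrow(chrs))
  hetlen <- stats::setNames(numeric(length(lines_id)), lines_id)
  covlen <- stats::setNames(numeric(length(lines_id)), lines_id)
  nbp <- stats::setNames(integer(length(lines_id)), lines_id)
  k <- 0L
  obs_split <- split(observations, list(observations$line,
                                        observations$chrom), drop = FALSE)
  for (li in lines_id) {
    for (ci in seq_len(nrow(chrs))) {
      ch <- chrs$name[ci]; L <- chrs$length_bp[ci]
      o <- obs_split[[paste(li, ch, sep = ".")]]
      if (is.null(o) || nrow(o) < cfg$window_size) {
        fb <- data.frame(start = 1, end = L, genotype = "MISSING",
                         snp_count = if (is.null(o)) 0L else nrow(o),
                         stringsAsFactors = FALSE)
        attr(fb, "n_breakpoints") <- 0L
        attr(fb, "het_fraction") <- NA_real_
      } else {
        o <- o[order(o$pos), ]
        wc <- call_windows(o$pos, o$allele, cfg)
        rg <- resolve_breakpoints(wc$genotype, cfg)
        bl <- merge_to_blocks(rg, o$pos, L, cfg)
        fb <- filter_blocks(bl, cfg)
      }
      k <- k + 1L
      res[[k]] <- data.frame(line = li, chrom = ch, fb,
                             stringsAsFactors = FALSE)
      nonmiss <- fb$genotype != "MISSING"
      covlen[li] <- covlen[li] + sum((fb$end - fb$start + 1)[nonmiss])
      hetlen[li] <- hetlen[li] +
        sum((fb$end - fb$start + 1)[fb$genotype == "HET"])
      nbp[li] <- nbp[li] + attr(fb, "n_breakpoints")
    }
  }
  stats_df <- data.frame(line = lines_id,
                         het_fraction = ifelse(covlen > 0, hetlen / covlen,
                                               NA_real_),
                         n_breakpoints = nbp, stringsAsFactors = FALSE,
                         row.names = NULL)
  structure(list(blocks = do.call(rbind, res), line_stats = stats_df,
                 layout = layout, config = cfg),
            class = "mosaic_set")
}

#' Exclude lines with excess heterozygosity or breakpoints
#'
#' Removes lines whose residual heterozygous fraction exceeds
#' `line_max_het_fraction` or whose breakpoint count exceeds
#' `line_max_breakpoints` (both strict), reporting each exclusion with its
#' reason.
#'
#' @param mosaics a `mosaic_set` from [call_mosaics()].
#' @param cfg a [caller_config()].
#' @return list: `mosaics` (filtered `mosaic_set`), `retained` (line ids),
#'   `excluded` (data.frame line, het_fraction, n_breakpoints, reason).
#' @export
filter_lines <- function(mosaics, cfg = caller_config()) {
  st <- mosaics$line_stats
  too_het <- !is.na(st$het_fraction) &
    st$het_fraction > cfg$line_max_het_fraction
  too_bp <- st$n_breakpoints > cfg$line_max_breakpoints
  excl <- too_het | too_bp
  reason <- ifelse(too_het & too_bp, "het_fraction;breakpoints",
                   ifelse(too_het, "het_fraction", "breakpoints"))
  excluded <- data.frame(st[excl, , drop = FALSE],
                         reason = reason[excl], stringsAsFactors = FALSE,
                         row.names = NULL)
  keep <- st$line[!excl]
  out <- mosaics
  out$blocks <- mosaics$blocks[mosaics$blocks$line %in% keep, , drop = FALSE]
  out$line_stats <- st[!excl, , drop = FALSE]
  list(mosaics = out, retained = keep, excluded = excluded)
}
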