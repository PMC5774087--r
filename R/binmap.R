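# Population-wide bin map: bins are maximal intervals carrying no breakpoint
# in any retained line. Genotypes are stored as an integer matrix with the
# on-disk coding 0 = P1, 2 = P2, 1 = HET, NA = missing.

GENO_CODE <- c(P1 = 0L, HET = 1L, P2 = 2L)

#' Construct the bin map from line mosaics
#'
#' Bin boundaries on each chromosome are the sorted union of all retained
#' lines' block boundaries; bins shorter than `min_bin_bp` are merged into
#' their right neighbour (left neighbour at the chromosome end), the merged
#' bin taking, per line, the genotype of the larger constituent. The
#' genotype matrix is filled from each line's covering block.
#'
#' @param mosaics a `mosaic_set` (after line filtering) or its `blocks`
#'   data.frame.
#' @param layout a [genome_layout()].
#' @param min_bin_bp merge floor for bin physical length (default 5 kb,
#'   strict: bins of exactly `min_bin_bp` are kept).
#' @return object of class `bin_map`: `bins` (chrom, start, end),
#'   `geno` (lines x bins integer matrix, 0/1/2/NA), `layout`.
#' @export
construct_bins <- function(mosaics, layout, min_bin_bp = 5000) {
  blocks <- if (inherits(mosaics, "mosaic_set")) mosaics$blocks else mosaics
  lines_id <- sort(unique(blocks$line))
  if (length(lines_id) < 2) stop("need >= 2 retained lines")
  chrs <- layout$chromosomes
  bin_list <- list(); geno_list <- list()
  for (ci in seq_len(nrow(chrs))) {
    ch <- chrs$name[ci]; L <- chrs$length_bp[ci]
    bc <- blocks[blocks$chrom == ch, , drop = FALSE]
    if (any(bc$start < 1 | bc$end > L))
      stop("block boundary outside chromosome ", ch)
    cuts <- sort(unique(c(1, bc$start, bc$end + 1, L + 1)))
    cuts <- cuts[cuts >= 1 & cuts <= L + 1]
    start <- cuts[-length(cuts)]; end <- cuts[-1] - 1
    nb <- length(start)
    G <- matrix(NA_integer_, length(lines_id), nb,
                dimnames = list(lines_id, NULL))
    for (li in lines_id) {
      bl <- bc[bc$line == li, , drop = FALSE]
      if (nrow(bl) == 0L) next
      bl <- bl[order(bl$start), ]
      idx <- findInterval(start, bl$start)
      ok <- idx >= 1 & end <= bl$end[pmax(idx, 1L)]
      g <- rep(NA_character_, nb)
      g[ok] <- bl$genotype[idx[ok]]
      gi <- GENO_CODE[g]
      gi[is.na(g) | g == "MISSING"] <- NA_integer_
      G[li, ] <- gi
    }
    m <- .merge_small_bins(start, end, G, min_bin_bp)
    bin_list[[ci]] <- data.frame(chrom = ch, start = m$start, end = m$end,
                                 stringsAsFactors = FALSE)
    geno_list[[ci]] <- m$G
  }
  bins <- do.call(rbind, bin_list)
  geno <- do.call(cbind, geno_list)
  colnames(geno) <- paste0(bins$chrom, ":", bins$start, "-", bins$end)
  structure(list(bins = bins, geno = geno, layout = layout),
            class = "bin_map")
}

# merge bins shorter than the floor into the right neighbour (left at the
# chromosome end); merged genotype per line = genotype of the larger
# constituent
.merge_small_bins <- function(start, end, G, min_bp) {
  repeat {
    len <- end - start + 1
    small <- which(len < min_bp)
    if (length(small) == 0L) break
    i <- small[1]
    j <- if (i < length(start)) i + 1L else i - 1L
    a <- min(i, j); b <- max(i, j)
    dominant <- if (len[i] >= len[j]) i else j
    g_new <- ifelse(is.na(G[, a]) | is.na(G[, b]),
                    ifelse(is.na(G[, dominant]),
                           ifelse(is.na(G[, a]), G[, b], G[, a]),
                           G[, dominant]),
                    ifelse(G[, a] == G[, b], G[, a], G[, dominant]))
    G[, a] <- as.integer(g_new)
    end[a] <- end[b]
    start <- start[-b]; end <- end[-b]
    G <- G[, -b, drop = FALSE]
    if (length(start) == 1L) break
  }
  list(start = start, end = end, G = G)
}

#' Per-bin allele frequencies
#'
#' @param binmap a `bin_map`.
#' @return data.frame (chrom, start, end, n_informative, f_p1, f_p2, f_het);
#'   frequencies are over non-missing lines.
#' @export
allele_frequencies <- function(binmap) {
  G <- binmap$geno
  n_obs <- colSums(!is.na(G))
  f1 <- colSums(G == 0L, na.rm = TRUE) / pmax(n_obs, 1L)
  f2 <- colSums(G == 2L, na.rm = TRUE) / pmax(n_obs, 1L)
  fh <- colSums(G == 1L, na.rm = TRUE) / pmax(n_obs, 1L)
  data.frame(binmap$bins, n_informative = n_obs, f_p1 = f1, f_p2 = f2,
             f_het = fh, row.names = NULL, stringsAsFactors = FALSE)
}

#' Chi-square test of segregation distortion per bin
#'
#' Goodness-of-fit of the homozygote counts (heterozygous and missing lines
#' ignored) against the Mendelian 1:1 expectation, df = 1, with Bonferroni
#' correction over the tested bins. Bins with fewer than two informative
#' lines are excluded from testing and from the correction denominator.
#'
#' @param binmap a `bin_map`.
#' @param alpha significance level applied to the Bonferroni-adjusted p.
#' @return data.frame (chrom, start, end, n_p1, n_p2, chisq, p, p_adj,
#'   distorted).
#' @export
test_segregation_distortion <- function(binmap, alpha = 0.01) {
  G <- binmap$geno
  n1 <- colSums(G == 0L, na.rm = TRUE)
  n2 <- colSums(G == 2L, na.rm = TRUE)
  n <- n1 + n2
  testable <- n >= 2L
  E <- n / 2
  stat <- ifelse(testable, (n1 - E)^2 / E + (n2 - E)^2 / E, NA_real_)
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  m <- sum(testable)
  p_adj <- pmin(1, p * m)
  data.frame(binmap$bins, n_p1 = n1, n_p2 = n2, chisq = stat, p = p,
             p_adj = p_adj,
             distorted = !is.na(p_adj) & p_adj < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Discard bins with distorted segregation ratios or excess heterozygosity
#'
#' Removes bins whose parental allele-frequency ratio exceeds `max_ratio`
#' (strict; a ratio of exactly 2 is retained) or whose heterozygous
#' frequency exceeds `max_het` (strict). A zero minor-allele frequency gives
#' an infinite ratio and the bin is discarded.
#'
#' @param binmap a `bin_map`.
#' @param max_ratio maximum allowed major/minor parental frequency ratio.
#' @param max_het maximum allowed heterozygous frequency.
#' @return filtered `bin_map` with attribute `discarded_fraction`.
#' @export
filter_distorted_bins <- function(binmap, max_ratio = 2, max_het = 0.15) {
  af <- allele_frequencies(binmap)
  hi <- pmax(af$f_p1, af$f_p2); lo <- pmin(af$f_p1, af$f_p2)
  ratio <- ifelse(lo > 0, hi / lo, Inf)
  drop <- ratio > max_ratio | af$f_het > max_het
  out <- binmap
  out$bins <- binmap$bins[!drop, , drop = FALSE]
  out$geno <- binmap$geno[, !drop, drop = FALSE]
  attr(out, "discarded_fraction") <- mean(drop)
  out
}

#' Kosambi map function and its inverse
#'
#' Converts a per-meiosis recombination fraction to additive map distance,
#' d = 25 ln((1+2r)/(1-2r)) cM, and back (r = tanh(d/50)/2).
#'
#' @param r recombination fraction(s) in [0, 0.5).
#' @param d map distance(s) in cM.
#' @return numeric vector of cM (or r for the inverse).
#' @export
kosambi_cm <- function(r) {
  if (any(r < 0 | r >= 0.5)) stop("r must be in [0, 0.5)")
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' @rdname kosambi_cm
#' @export
kosambi_r <- function(d) {
  if (any(d < 0)) stop("d must be non-negative")
  tanh(d / 50) / 2
}

#' Selfed-RIL recombination correction
#'
#' In a RIL produced by repeated selfing the observed recombinant fraction R
#' between two loci relates to the per-meiosis fraction r by
#' R = 2r / (1 + 2r); `ril_r` inverts this (r = R / (2(1 - R))), clamping
#' the result to [0, 0.5).
#'
#' @param R observed RIL recombinant fraction(s).
#' @param r per-meiosis recombination fraction(s).
#' @return numeric vector.
#' @export
ril_r <- function(R) {
  pmin(pmax(R / (2 * (1 - R)), 0), 0.5 - 1e-9)
}

#' @rdname ril_r
#' @export
ril_R <- function(r) 2 * r / (1 + 2 * r)

#' Recombination fractions between bins
#'
#' Observed recombinant fraction R = discordant / doubly informative lines
#' (homozygous calls only), and the per-meiosis r through the selfed-RIL
#' correction. `pairs = "adjacent"` gives the map-building estimates for
#' consecutive bins within chromosomes; `pairs = "all"` returns the full
#' pairwise R matrix (small maps only).
#'
#' @param binmap a `bin_map` (ideally after imputation).
#' @param pairs `"adjacent"` or `"all"`.
#' @param min_informative pairs with fewer doubly informative lines are
#'   flagged `low_conf`.
#' @return for `"adjacent"`, data.frame (chrom, bin1, bin2, n_informative,
#'   R, r, low_conf); for `"all"`, a list with matrices `R` and `n`.
#' @export
estimate_rf <- function(binmap, pairs = c("adjacent", "all"),
                        min_informative = 10L) {
  pairs <- match.arg(pairs)
  G <- binmap$geno
  H <- G
  H[H == 1L] <- NA_integer_          # heterozygotes are uninformative here
  if (pairs == "all") {
    m <- ncol(H)
    Rm <- matrix(NA_real_, m, m); Nm <- matrix(0L, m, m)
    for (i in seq_len(m)) for (j in seq_len(m)) {
      ok <- !is.na(H[, i]) & !is.na(H[, j])
      Nm[i, j] <- sum(ok)
      if (Nm[i, j] > 0) Rm[i, j] <- mean(H[ok, i] != H[ok, j])
    }
    return(list(R = Rm, n = Nm))
  }
  bins <- binmap$bins
  out <- list()
  for (ch in unique(bins$chrom)) {
    idx <- which(bins$chrom == ch)
    if (length(idx) < 2L) next
    for (k in seq_len(length(idx) - 1L)) {
      i <- idx[k]; j <- idx[k + 1L]
      ok <- !is.na(H[, i]) & !is.na(H[, j])
      n <- sum(ok)
      R <- if (n > 0) mean(H[ok, i] != H[ok, j]) else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, bin1 = i, bin2 = j, n_informative = n,
        R = R, r = if (!is.na(R) && R < 1) ril_r(min(R, 0.9999)) else NA_real_,
        low_conf = n < min_informative, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Impute heterozygous and missing bin genotypes
#'
#' Heterozygous calls are first set missing (downstream QTL models are
#' two-state), then each line x chromosome is decoded with a two-state
#' Viterbi pass over \{P1, P2\}: transition probability between adjacent
#' bins is the RIL recombinant fraction implied by the current genetic-map
#' interval, emissions allow a small genotyping-error probability `epsilon`.
#' Missing bins take the most probable state path; observed homozygous calls
#' are kept.
#'
#' @param binmap a `bin_map`.
#' @param rf optional adjacent recombination fractions (from
#'   [estimate_rf()]); computed from the raw matrix when `NULL`.
#' @param epsilon emission error probability.
#' @return `bin_map` with an imputed genotype matrix (attribute
#'   `n_imputed` = number of cells filled).
#' @export
impute_genotypes <- function(binmap, rf = NULL, epsilon = 1e-4) {
  G <- binmap$geno
  G[G == 1L] <- NA_integer_
  if (is.null(rf)) {
    tmp <- binmap; tmp$geno <- G
    rf <- estimate_rf(tmp, "adjacent")
  }
  bins <- binmap$bins
  n_filled <- 0L
  for (ch in unique(bins$chrom)) {
    idx <- which(bins$chrom == ch)
    if (length(idx) < 2L) next
    rch <- rf[rf$chrom == ch, , drop = FALSE]
    Rstep <- pmin(pmax(ifelse(is.na(rch$R), 0.25, rch$R), 1e-6), 0.499)
    sub <- G[, idx, drop = FALSE]
    for (li in seq_len(nrow(sub))) {
      o <- sub[li, ]
      if (!anyNA(o)) next
      if (all(is.na(o))) next                    # nothing to anchor on
      dec <- .viterbi2(o, Rstep, epsilon)
      fill <- is.na(o)
      sub[li, fill] <- dec[fill]
      n_filled <- n_filled + sum(fill)
    }
    G[, idx] <- sub
  }
  out <- binmap
  out$geno <- G
  attr(out, "n_imputed") <- n_filled
  out
}

# two-state Viterbi over codes {0, 2}; obs has NA for missing
.viterbi2 <- function(obs, Rstep, eps) {
  m <- length(obs)
  le <- function(o) {
    if (is.na(o)) c(0, 0)
    else if (o == 0L) log(c(1 - eps, eps))
    else log(c(eps, 1 - eps))
  }
  delta <- matrix(-Inf, 2, m)
  psi <- matrix(1L, 2, m)
  delta[, 1] <- log(c(0.5, 0.5)) + le(obs[1])
  for (t in 2:m) {
    R <- Rstep[t - 1L]
    lt <- log(matrix(c(1 - R, R, R, 1 - R), 2, 2))  # [from, to]
    e <- le(obs[t])
    for (s in 1:2) {
      cand <- delta[, t - 1L] + lt[, s]
      psi[s, t] <- which.max(cand)
      delta[s, t] <- max(cand) + e[s]
    }
  }
  path <- integer(m)
  path[m] <- which.max(delta[, m])
  for (t in (m - 1L):1L) path[t] <- psi[path[t + 1L], t + 1L]
  c(0L, 2L)[path]
}

#' Build the genetic map from adjacent recombination fractions
#'
#' Converts each adjacent-bin interval's per-meiosis r to cM through the
#' Kosambi function and accumulates positions along each chromosome
#' (first bin at 0 cM). The summary table mirrors the conventional bin-map
#' summary: per chromosome the bin count, mean and maximal physical interval
#' between adjacent bin midpoints (Mb), total map length, mean and maximal
#' adjacent linkage interval (cM), cM/Mb ratio, and mean crossovers per line.
#'
#' @param binmap a `bin_map` (imputed).
#' @param rf optional adjacent rf table; computed when `NULL`.
#' @return object of class `genetic_map`: `map` (chrom, start, end, mid_bp,
#'   cM), `intervals` (adds interval_cM per adjacent pair), `summary`.
#' @export
build_genetic_map <- function(binmap, rf = NULL) {
  if (is.null(rf)) rf <- estimate_rf(binmap, "adjacent")
  bins <- binmap$bins
  mid <- (bins$start + bins$end) / 2
  cM <- numeric(nrow(bins))
  interval_cM <- rep(NA_real_, max(0L, nrow(rf)))
  if (!is.null(rf) && nrow(rf) > 0)
    interval_cM <- kosambi_cm(ifelse(is.na(rf$r), 0, rf$r))
  for (ch in unique(bins$chrom)) {
    idx <- which(bins$chrom == ch)
    if (length(idx) < 2L) { cM[idx] <- 0; next }
    rows <- which(rf$chrom == ch)
    cM[idx] <- c(0, cumsum(interval_cM[rows]))
  }
  xo <- count_crossovers(binmap)
  summ <- do.call(rbind, lapply(unique(bins$chrom), function(ch) {
    idx <- which(bins$chrom == ch)
    rows <- which(rf$chrom == ch)
    dmid <- if (length(idx) > 1) diff(mid[idx]) / 1e6 else NA_real_
    ic <- interval_cM[rows]
    total <- if (length(rows)) sum(ic) else 0
    span_mb <- (max(bins$end[idx]) - min(bins$start[idx]) + 1) / 1e6
    data.frame(chrom = ch, n_bins = length(idx),
               mean_interval_mb = mean(dmid), max_interval_mb = max(dmid),
               total_cM = total,
               mean_interval_cM = if (length(rows)) mean(ic) else NA_real_,
               max_interval_cM = if (length(rows)) max(ic) else NA_real_,
               cM_per_Mb = total / span_mb,
               mean_crossovers_per_line = xo$per_chrom_mean[ch],
               stringsAsFactors = FALSE)
  }))
  map <- data.frame(bins, mid_bp = mid, cM = cM, stringsAsFactors = FALSE)
  structure(list(map = map,
                 intervals = if (nrow(rf)) cbind(rf, interval_cM = interval_cM)
                             else rf,
                 summary = summ, method = "kosambi"),
            class = "genetic_map")
}

#' Count crossovers in the bin genotype matrix
#'
#' A crossover is a genotype transition between consecutive non-missing bins
#' (or blocks) within one line and chromosome. Means are reported to one
#' decimal in the printed summary.
#'
#' @param x a `bin_map`, or a mosaic `blocks` data.frame (line, chrom,
#'   start, end, genotype).
#' @return list: `total`, `per_line` (named vector), `per_chrom_mean`
#'   (mean per line for each chromosome), `mean_per_chrom_line` (grand mean
#'   crossovers per chromosome per line).
#' @export
count_crossovers <- function(x) {
  if (inherits(x, "bin_map")) {
    G <- x$geno; bins <- x$bins
    lines_id <- rownames(G)
    chroms <- unique(bins$chrom)
    per_line <- stats::setNames(numeric(length(lines_id)), lines_id)
    per_chrom <- stats::setNames(numeric(length(chroms)), chroms)
    for (ch in chroms) {
      idx <- which(bins$chrom == ch)
      cnt <- apply(G[, idx, drop = FALSE], 1, function(g) {
        g <- g[!is.na(g)]
        if (length(g) < 2) 0L else sum(g[-1] != g[-length(g)])
      })
      per_line <- per_line + cnt
      per_chrom[ch] <- mean(cnt)
    }
  } else {
    blocks <- x
    lines_id <- unique(blocks$line)
    chroms <- unique(blocks$chrom)
    per_line <- stats::setNames(numeric(length(lines_id)), lines_id)
    per_chrom <- stats::setNames(numeric(length(chroms)), chroms)
    for (ch in chroms) {
      cnt <- vapply(lines_id, function(li) {
        g <- blocks$genotype[blocks$line == li & blocks$chrom == ch]
        g <- g[g != "MISSING"]
        if (length(g) < 2) 0L else sum(g[-1] != g[-length(g)])
      }, numeric(1))
      per_line <- per_line + cnt
      per_chrom[ch] <- mean(cnt)
    }
  }
  total <- sum(per_line)
  list(total = total, per_line = per_line, per_chrom_mean = per_chrom,
       mean_per_chrom_line = total / (length(per_line) * length(per_chrom)))
}

#' Recombination-rate profile in fixed physical windows
#'
#' Apportions each adjacent-bin interval's linkage distance to 1-Mb (by
#' default) windows proportionally to physical overlap (the interval spans
#' the midpoints of its two bins) and reports cM/Mb per window, plus Pearson
#' correlations against any supplied per-window annotation tracks.
#'
#' @param genmap a `genetic_map`.
#' @param layout a [genome_layout()].
#' @param window_bp window size (bp).
#' @param tracks optional data.frame with columns `chrom`, `start` and one
#'   or more numeric track columns on the same windows.
#' @return list of class `recomb_profile`: `profile` (chrom, start, end,
#'   cM, cM_per_Mb), `correlations` (track, r, p) when tracks given.
#' @export
recombination_profile <- function(genmap, layout, window_bp = 1e6,
                                  tracks = NULL) {
  map <- genmap$map
  prof <- list()
  for (ci in seq_len(nrow(layout$chromosomes))) {
    ch <- layout$chromosomes$name[ci]
    L <- layout$chromosomes$length_bp[ci]
    ws <- seq(1, L, by = window_bp)
    we <- pmin(ws + window_bp - 1, L)
    cm <- numeric(length(ws))
    idx <- which(map$chrom == ch)
    if (length(idx) >= 2) {
      a <- map$mid_bp[idx[-length(idx)]]
      b <- map$mid_bp[idx[-1]]
      dcm <- diff(map$cM[idx])
      for (k in seq_along(a)) {
        if (b[k] <= a[k]) next
        # windows treated half-open [ws, we+1) so overlaps sum exactly
        ov <- pmax(0, pmin(we + 1, b[k]) - pmax(ws, a[k]))
        cm <- cm + dcm[k] * ov / (b[k] - a[k])
      }
    }
    prof[[ci]] <- data.frame(chrom = ch, start = ws, end = we, cM = cm,
                             cM_per_Mb = cm / ((we - ws + 1) / 1e6),
                             stringsAsFactors = FALSE)
  }
  profile <- do.call(rbind, prof)
  cors <- NULL
  if (!is.null(tracks)) {
    key_p <- paste(profile$chrom, profile$start)
    key_t <- paste(tracks$chrom, tracks$start)
    if (!all(key_p %in% key_t))
      stop("annotation track is on a different window layout")
    t2 <- tracks[match(key_p, key_t), , drop = FALSE]
    tcols <- setdiff(names(t2), c("chrom", "start", "end"))
    cors <- do.call(rbind, lapply(tcols, function(cn) {
      ct <- stats::cor.test(profile$cM_per_Mb, t2[[cn]])
      data.frame(track = cn, r = unname(ct$estimate), p = ct$p.value,
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(profile = profile, correlations = cors),
            class = "recomb_profile")
}
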