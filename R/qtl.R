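# Genome scan for QTL against the bin genotype matrix: marker regression at
# bins with stepwise-selected background cofactors and a cM exclusion window
# around the tested bin (the dense-map analog of composite interval mapping),
# permutation-based genome-wide thresholds, 1.5-LOD support intervals, and
# single-locus additive effects / variance explained.

#' Configuration of the QTL genome scan
#'
#' @param n_permutations permutations for the genome-wide threshold.
#' @param alpha genome-wide significance level.
#' @param lod_drop LOD drop defining support intervals (and the minimum
#'   valley depth separating twin peaks).
#' @param n_cofactors_max maximum background cofactors.
#' @param cofactor_exclusion_cM cofactors within this distance of the tested
#'   bin are dropped from its model; also the minimum spacing between
#'   selected cofactors.
#' @param entry_pvalue partial-F entry p-value for stepwise cofactor
#'   selection.
#' @param min_informative bins with fewer informative lines get LOD NA.
#' @param seed RNG seed for permutations.
#' @return object of class `scan_config`.
#' @export
scan_config <- function(n_permutations = 1000L, alpha = 0.05,
                        lod_drop = 1.5, n_cofactors_max = 5L,
                        cofactor_exclusion_cM = 10,
                        entry_pvalue = 0.001, min_informative = 20L,
                        seed = 1L) {
  if (lod_drop <= 0) stop("lod_drop must be > 0")
  structure(list(n_permutations = as.integer(n_permutations), alpha = alpha,
                 lod_drop = lod_drop,
                 n_cofactors_max = as.integer(n_cofactors_max),
                 cofactor_exclusion_cM = cofactor_exclusion_cM,
                 entry_pvalue = entry_pvalue,
                 min_informative = as.integer(min_informative),
                 seed = as.integer(seed)),
            class = "scan_config")
}

#' Numeric QTL coding of a bin genotype matrix
#'
#' Codes P1 homozygotes -1, P2 homozygotes +1, residual heterozygotes 0.
#'
#' @param geno integer matrix with codes 0/1/2/NA (as in a `bin_map`).
#' @return numeric matrix, same shape.
#' @export
code_genotypes <- function(geno) {
  X <- matrix(NA_real_, nrow(geno), ncol(geno), dimnames = dimnames(geno))
  X[geno == 0L] <- -1
  X[geno == 2L] <- 1
  X[geno == 1L] <- 0
  X
}

# residualize y and the columns of X on design [1, C]; returns the squared
# partial correlation of each column of X with y
.partial_r2 <- function(X, y, C = NULL) {
  D <- cbind(rep(1, length(y)), C)
  qd <- qr(D)
  Q <- qr.Q(qd)[, seq_len(qd$rank), drop = FALSE]
  ry <- as.vector(y - Q %*% crossprod(Q, y))
  RX <- X - Q %*% crossprod(Q, X)
  rss_y <- sum(ry^2)
  b <- as.vector(crossprod(RX, ry))
  sxx <- colSums(RX^2)
  r2 <- ifelse(sxx > 1e-12 & rss_y > 1e-12, b^2 / (sxx * rss_y), 0)
  pmin(pmax(r2, 0), 1)
}

#' Genome scan with background cofactors
#'
#' At each bin, regresses the phenotype on the bin's coded genotype plus the
#' cofactor bins, dropping any cofactor within `cofactor_exclusion_cM` of
#' the tested bin (same chromosome). LOD = (n/2) log10(RSS_reduced /
#' RSS_full) with the reduced model holding the surviving cofactors only;
#' with no cofactors this is -(n/2) log10(1 - R^2) of the single-bin fit.
#'
#' @param X coded genotype matrix (lines x bins, values -1/0/+1, NA allowed).
#' @param y phenotype vector (one value per line).
#' @param cofactors integer indices of cofactor bins (possibly empty).
#' @param bin_cM genetic position of each bin (cM within chromosome).
#' @param bin_chrom chromosome of each bin.
#' @param cfg a [scan_config()].
#' @return numeric LOD vector (NA for bins with too few informative lines).
#' @export
cim_scan <- function(X, y, cofactors = integer(0), bin_cM = NULL,
                     bin_chrom = NULL, cfg = scan_config()) {
  stopifnot(nrow(X) == length(y))
  n <- length(y)
  m <- ncol(X)
  lod <- rep(NA_real_, m)
  informative <- colSums(!is.na(X))
  scanable <- informative >= cfg$min_informative
  if (stats::var(y) < 1e-12) { lod[scanable] <- 0; return(lod) }
  Xi <- X
  # mean-impute residual NAs so the fast path applies; bins failing the
  # informative-lines floor stay NA
  if (anyNA(Xi)) {
    mu <- colMeans(Xi, na.rm = TRUE)
    for (j in which(colSums(is.na(Xi)) > 0)) Xi[is.na(Xi[, j]), j] <- mu[j]
  }
  if (length(cofactors) == 0L) {
    r2 <- .partial_r2(Xi, y, NULL)
    lod[scanable] <- -(n / 2) * log10(1 - r2[scanable])
    return(lod)
  }
  if (is.null(bin_cM) || is.null(bin_chrom))
    stop("bin_cM and bin_chrom are required when cofactors are used")
  active <- lapply(seq_len(m), function(j) {
    keep <- bin_chrom[cofactors] != bin_chrom[j] |
      abs(bin_cM[cofactors] - bin_cM[j]) > cfg$cofactor_exclusion_cM
    cofactors[keep]
  })
  key <- vapply(active, function(a) paste(a, collapse = ","), character(1))
  for (kk in unique(key)) {
    cols <- which(key == kk)
    a <- active[[cols[1]]]
    C <- if (length(a)) Xi[, a, drop = FALSE] else NULL
    r2 <- .partial_r2(Xi[, cols, drop = FALSE], y, C)
    lod[cols] <- -(n / 2) * log10(1 - r2)
  }
  lod[!scanable] <- NA_real_
  lod
}

#' Forward stepwise cofactor selection
#'
#' Adds, at each step, the bin giving the largest reduction in residual sum
#' of squares, while its partial F statistic exceeds the entry threshold
#' implied by `entry_pvalue`; candidates within `cofactor_exclusion_cM` of
#' an already-selected cofactor are ineligible. Stops at
#' `n_cofactors_max` or when no candidate passes.
#'
#' @inheritParams cim_scan
#' @return integer vector of selected bin indices (possibly empty).
#' @export
select_cofactors <- function(X, y, bin_cM, bin_chrom, cfg = scan_config()) {
  n <- length(y)
  if (stats::var(y) < 1e-12) return(integer(0))
  Xi <- X
  if (anyNA(Xi)) {
    mu <- colMeans(Xi, na.rm = TRUE)
    for (j in which(colSums(is.na(Xi)) > 0)) Xi[is.na(Xi[, j]), j] <- mu[j]
  }
  chosen <- integer(0)
  eligible <- rep(TRUE, ncol(Xi))
  repeat {
    if (length(chosen) >= cfg$n_cofactors_max) break
    C <- if (length(chosen)) Xi[, chosen, drop = FALSE] else NULL
    r2 <- .partial_r2(Xi, y, C)
    r2[!eligible] <- 0
    j <- which.max(r2)
    df_err <- n - length(chosen) - 2L          # intercept + cofactors + bin
    if (df_err < 1L) break
    Fj <- r2[j] / (1 - r2[j]) * df_err
    if (Fj < stats::qf(1 - cfg$entry_pvalue, 1, df_err)) break
    chosen <- c(chosen, j)
    near <- bin_chrom == bin_chrom[j] &
      abs(bin_cM - bin_cM[j]) <= cfg$cofactor_exclusion_cM
    eligible[near] <- FALSE
  }
  chosen
}

#' Permutation-based genome-wide LOD threshold
#'
#' Shuffles the phenotype across lines, reselects cofactors inside each
#' permutation, re-runs the scan and records the genome-wide maximum LOD;
#' the threshold is the empirical (1 - alpha) quantile of that null
#' distribution. Permutation i uses RNG seed `seed + i`, so results are
#' independent of evaluation order.
#'
#' @inheritParams cim_scan
#' @return numeric threshold, with the max-LOD draws as attribute
#'   `max_lods`.
#' @export
permutation_threshold <- function(X, y, bin_cM, bin_chrom,
                                  cfg = scan_config()) {
  if (cfg$n_permutations < 100L)
    warning("fewer than 100 permutations: threshold will be unstable")
  maxs <- numeric(cfg$n_permutations)
  for (i in seq_len(cfg$n_permutations)) {
    set.seed(cfg$seed + i)
    yp <- sample(y)
    cof <- select_cofactors(X, yp, bin_cM, bin_chrom, cfg)
    lod <- cim_scan(X, yp, cof, bin_cM, bin_chrom, cfg)
    maxs[i] <- if (all(is.na(lod))) 0 else max(lod, na.rm = TRUE)
  }
  thr <- stats::quantile(maxs, 1 - cfg$alpha, names = FALSE)
  attr(thr, "max_lods") <- maxs
  thr
}

#' Find LOD peaks and 1.5-LOD support intervals
#'
#' Peaks are local maxima at or above the threshold. Two maxima on one
#' chromosome are distinct QTLs only if the profile between them drops at
#' least `lod_drop` below the lesser peak; otherwise they merge into one
#' peak at the higher LOD. Each peak's support interval is the contiguous
#' run of bins around it with LOD >= peak - `lod_drop`, extended one bin
#' outward on each side where available.
#'
#' @param lod numeric LOD vector over bins.
#' @param threshold genome-wide threshold.
#' @param bins data.frame (chrom, start, end) matching `lod`.
#' @param bin_cM genetic positions (optional, reported when given).
#' @param lod_drop LOD drop (default 1.5).
#' @return data.frame (chrom, peak_bin, peak_bp, peak_cM, lod,
#'   interval_start_bp, interval_end_bp); zero rows when nothing exceeds
#'   the threshold.
#' @export
find_peaks_and_intervals <- function(lod, threshold, bins, bin_cM = NULL,
                                     lod_drop = 1.5) {
  empty <- data.frame(chrom = character(0), peak_bin = integer(0),
                      peak_bp = numeric(0), peak_cM = numeric(0),
                      lod = numeric(0), interval_start_bp = numeric(0),
                      interval_end_bp = numeric(0), stringsAsFactors = FALSE)
  if (length(lod) == 0L || all(is.na(lod))) return(empty)
  out <- list()
  for (ch in unique(bins$chrom)) {
    idx <- which(bins$chrom == ch)
    v <- lod[idx]
    v[is.na(v)] <- -Inf
    n <- length(v)
    is_max <- vapply(seq_len(n), function(i) {
      left <- if (i > 1) v[i - 1] else -Inf
      right <- if (i < n) v[i + 1] else -Inf
      v[i] >= left && v[i] >= right && v[i] >= threshold
    }, logical(1))
    peaks <- which(is_max)
    if (length(peaks) == 0L) next
    # drop plateau duplicates: keep first index of equal-value neighbours
    if (length(peaks) > 1L)
      peaks <- peaks[c(TRUE, !(diff(peaks) == 1 &
                               v[peaks[-1]] == v[peaks[-length(peaks)]]))]
    # merge peaks not separated by a deep enough valley
    repeat {
      if (length(peaks) < 2L) break
      merged <- FALSE
      for (k in seq_len(length(peaks) - 1L)) {
        a <- peaks[k]; b <- peaks[k + 1L]
        valley <- min(v[a:b])
        lesser <- min(v[a], v[b])
        if (lesser - valley < lod_drop) {
          peaks <- peaks[-(if (v[a] >= v[b]) k + 1L else k)]
          merged <- TRUE
          break
        }
      }
      if (!merged) break
    }
    for (p in peaks) {
      lo <- p; hi <- p
      cut <- v[p] - lod_drop
      while (lo > 1 && v[lo - 1] >= cut) lo <- lo - 1
      while (hi < n && v[hi + 1] >= cut) hi <- hi + 1
      lo <- max(1, lo - 1); hi <- min(n, hi + 1)     # one bin outward
      gi <- idx[p]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, peak_bin = gi,
        peak_bp = (bins$start[gi] + bins$end[gi]) / 2,
        peak_cM = if (is.null(bin_cM)) NA_real_ else bin_cM[gi],
        lod = v[p],
        interval_start_bp = bins$start[idx[lo]],
        interval_end_bp = bins$end[idx[hi]],
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(empty)
  do.call(rbind, out)
}

#' Additive effect and variance explained at a peak bin
#'
#' Single-locus linear fit y = mu + a x with x coded -1 (P1) / +1 (P2);
#' the additive effect a is positive when the P2 allele increases the
#' trait, and PVE = 100 R^2 of this fit.
#'
#' @param x coded genotypes at the peak bin (-1/0/+1, NA allowed).
#' @param y phenotype vector.
#' @return list (additive_effect, pve); both NA when one homozygote class
#'   is absent.
#' @export
qtl_effects <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (!any(x == -1) || !any(x == 1)) {
    warning("one genotype class absent: effect undefined")
    return(list(additive_effect = NA_real_, pve = NA_real_))
  }
  fit <- stats::lm.fit(cbind(1, x), y)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  list(additive_effect = unname(fit$coefficients[2]),
       pve = 100 * (1 - rss / tss))
}

#' Physical interval length
#'
#' @param start_mb,end_mb interval ends in Mb (`end_mb >= start_mb`).
#' @return length in Mb.
#' @export
interval_length <- function(start_mb, end_mb) {
  if (any(end_mb < start_mb)) stop("end must be >= start")
  end_mb - start_mb
}

#' Full QTL scan for one trait
#'
#' Selects cofactors, scans all bins, derives the permutation threshold
#' (cofactors reselected inside each permutation), extracts peaks with
#' 1.5-LOD support intervals, and computes additive effects and PVE at each
#' peak.
#'
#' @param binmap a `bin_map` (imputed).
#' @param genmap the matching `genetic_map`.
#' @param phenotype named numeric vector (names = line ids) or data.frame
#'   (line, value).
#' @param trait trait label for the output.
#' @param cfg a [scan_config()].
#' @return object of class `qtl_result`: `trait`, `lod` (per-bin profile
#'   data.frame), `threshold`, `peaks` (with additive_effect and pve
#'   columns), `cofactors`, `config`.
#' @export
scan_qtl <- function(binmap, genmap, phenotype, trait = "trait",
                     cfg = scan_config()) {
  if (is.data.frame(phenotype))
    phenotype <- stats::setNames(phenotype$value, phenotype$line)
  lines_id <- rownames(binmap$geno)
  y <- phenotype[lines_id]
  ok <- !is.na(y)
  X <- code_genotypes(binmap$geno[ok, , drop = FALSE])
  y <- as.numeric(y[ok])
  bin_cM <- genmap$map$cM
  bin_chrom <- binmap$bins$chrom
  cof <- select_cofactors(X, y, bin_cM, bin_chrom, cfg)
  lod <- cim_scan(X, y, cof, bin_cM, bin_chrom, cfg)
  thr <- permutation_threshold(X, y, bin_cM, bin_chrom, cfg)
  peaks <- find_peaks_and_intervals(lod, as.numeric(thr), binmap$bins,
                                    bin_cM, cfg$lod_drop)
  if (nrow(peaks) > 0) {
    eff <- lapply(peaks$peak_bin, function(j) qtl_effects(X[, j], y))
    peaks$additive_effect <- vapply(eff, `[[`, numeric(1), "additive_effect")
    peaks$pve <- vapply(eff, `[[`, numeric(1), "pve")
  } else {
    peaks$additive_effect <- numeric(0)
    peaks$pve <- numeric(0)
  }
  structure(list(trait = trait,
                 lod = data.frame(binmap$bins, cM = bin_cM, lod = lod,
                                  stringsAsFactors = FALSE),
                 threshold = as.numeric(thr),
                 max_lods = attr(thr, "max_lods"),
                 peaks = peaks, cofactors = cof, config = cfg),
            class = "qtl_result")
}

#' @export
print.qtl_result <- function(x, ...) {
  cat("QTL scan:", x$trait, "\n")
  cat("  threshold (", 100 * (1 - x$config$alpha), "th pct of ",
      x$config$n_permutations, " permutations): ",
      round(x$threshold, 2), "\n", sep = "")
  cat("  peaks:", nrow(x$peaks), "\n")
  if (nrow(x$peaks)) print(x$peaks, row.names = FALSE)
  invisible(x)
}
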