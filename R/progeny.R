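# Recombinant-derived progeny testing: a backcross family segregates the
# parental recombinant's heterozygous segment into heterozygous and
# homozygous-recurrent progeny; a two-sample t-test on the phenotype decides
# whether the QTL lies inside (significant) or outside (non-significant) the
# segregating segment, and set algebra over the family verdicts refines the
# QTL interval.

#' Test one progeny family for segregation of the QTL
#'
#' Classic equal-variance two-sample t-test between heterozygous-segment
#' carriers and homozygous recurrent-parent progeny. A significant
#' difference localizes the QTL inside the family's heterozygous region;
#' otherwise it is inferred to lie in the homozygous region.
#'
#' @param genotype character vector per progeny, `"HET"`/`"H"` for carriers
#'   of the heterozygous donor segment, `"HOM"`/`"A"` for homozygous
#'   recurrent parent.
#' @param phenotype numeric vector per progeny.
#' @param alpha significance level.
#' @param family optional family label carried into the output.
#' @return data.frame (family, n_het, n_hom, mean_het, mean_hom,
#'   t_statistic, p, verdict); verdict is NA with a warning when either
#'   class has fewer than two progeny.
#' @export
test_family <- function(genotype, phenotype, alpha = 0.05, family = NA) {
  g <- toupper(as.character(genotype))
  g[g == "H"] <- "HET"; g[g == "A"] <- "HOM"
  if (!all(g %in% c("HET", "HOM")))
    stop("genotypes must be HET/H or HOM/A")
  het <- phenotype[g == "HET"]; hom <- phenotype[g == "HOM"]
  if (length(het) < 2 || length(hom) < 2) {
    warning("family ", family, ": fewer than 2 progeny in a class; ",
            "verdict undefined")
    return(data.frame(family = family, n_het = length(het),
                      n_hom = length(hom), mean_het = mean(het),
                      mean_hom = mean(hom), t_statistic = NA_real_,
                      p = NA_real_, verdict = NA_character_,
                      stringsAsFactors = FALSE))
  }
  tt <- stats::t.test(het, hom, var.equal = TRUE)
  data.frame(family = family, n_het = length(het), n_hom = length(hom),
             mean_het = mean(het), mean_hom = mean(hom),
             t_statistic = unname(tt$statistic), p = tt$p.value,
             verdict = if (tt$p.value < alpha) "QTL-in-het-region"
                       else "QTL-in-hom-region",
             stringsAsFactors = FALSE)
}

# set difference of a union of intervals minus one interval
.interval_subtract <- function(ivals, cut) {
  out <- list()
  for (k in seq_len(nrow(ivals))) {
    a <- ivals$start[k]; b <- ivals$end[k]
    if (cut[2] <= a || cut[1] >= b) {
      out[[length(out) + 1L]] <- c(a, b)
    } else {
      if (cut[1] > a) out[[length(out) + 1L]] <- c(a, cut[1])
      if (cut[2] < b) out[[length(out) + 1L]] <- c(cut[2], b)
    }
  }
  if (length(out) == 0L)
    return(data.frame(start = numeric(0), end = numeric(0)))
  m <- do.call(rbind, out)
  data.frame(start = m[, 1], end = m[, 2])
}

#' Refine a QTL interval from family verdicts
#'
#' The QTL must lie in the intersection of the heterozygous segments of all
#' significant families, minus the heterozygous segments of non-significant
#' families, clipped to the prior QTL interval. Exclusions from families
#' whose smaller genotype class has fewer than `weak_min_n` progeny are
#' reported as weak evidence and not subtracted. An empty result flags a
#' contradiction.
#'
#' @param families data.frame with columns `family`, `het_start`, `het_end`
#'   (bp of the heterozygous segment), `significant` (logical), and
#'   `min_class_n` (smaller genotype-class size; used for the weak-evidence
#'   rule, defaulting to large when absent).
#' @param prior numeric c(start, end): the prior QTL interval (bp).
#' @param weak_min_n minimum class size for a non-significant family to
#'   contribute a hard exclusion.
#' @return list of class `segment_verdict`: `intervals` (data.frame start,
#'   end; possibly several disjoint pieces), `contradiction` (logical),
#'   `weak_exclusions` (family ids whose exclusions were not applied).
#' @export
refine_interval <- function(families, prior, weak_min_n = 20L) {
  stopifnot(all(c("family", "het_start", "het_end", "significant") %in%
                  names(families)),
            length(prior) == 2, prior[2] > prior[1])
  if (!"min_class_n" %in% names(families))
    families$min_class_n <- Inf
  cur <- data.frame(start = prior[1], end = prior[2])
  sig <- families[families$significant, , drop = FALSE]
  for (k in seq_len(nrow(sig))) {
    cur <- do.call(rbind, lapply(seq_len(nrow(cur)), function(i) {
      s <- max(cur$start[i], sig$het_start[k])
      e <- min(cur$end[i], sig$het_end[k])
      if (s < e) data.frame(start = s, end = e) else NULL
    }))
    if (is.null(cur) || nrow(cur) == 0)
      return(structure(list(intervals = data.frame(start = numeric(0),
                                                   end = numeric(0)),
                            contradiction = TRUE,
                            weak_exclusions = character(0)),
                       class = "segment_verdict"))
  }
  ns <- families[!families$significant, , drop = FALSE]
  weak <- character(0)
  for (k in seq_len(nrow(ns))) {
    if (ns$min_class_n[k] < weak_min_n) {
      weak <- c(weak, as.character(ns$family[k]))
      next
    }
    cur <- .interval_subtract(cur, c(ns$het_start[k], ns$het_end[k]))
  }
  structure(list(intervals = cur,
                 contradiction = nrow(cur) == 0,
                 weak_exclusions = weak),
            class = "segment_verdict")
}
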