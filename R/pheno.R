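# Multi-environment phenotype handling: BLUP line values through a
# random-line / fixed-environment mixed model (lme4), entry-mean
# heritability, and trait correlations.

#' BLUP line values across environments
#'
#' Fits y_ij = mu + env_j + g_i + e_ij with environments fixed and lines
#' random (REML through lme4) and returns each line's predicted genotypic
#' value (the random-effect BLUP), together with the variance components.
#' With a single environment the model reduces to an intercept plus the
#' line effect. An optional replicate term nests replicates within
#' environments.
#'
#' @param table long-format data.frame with columns `line`, `environment`,
#'   `trait`, `value` (and optionally `replicate`).
#' @param traits traits to process (default: all in the table).
#' @param include_replicate add a fixed environment:replicate term.
#' @return list of class `blup_result`: `blups` (data.frame line, trait,
#'   blup), `components` (data.frame trait, sigma2_g, sigma2_e, n_env, h2).
#' @export
blup_line_values <- function(table, traits = NULL,
                             include_replicate = FALSE) {
  stopifnot(all(c("line", "environment", "trait", "value") %in% names(table)))
  if (length(unique(table$line)) < 2) stop("need >= 2 lines")
  if (nrow(table) < 2) stop("need more than one observation")
  if (is.null(traits)) traits <- unique(table$trait)
  blups <- list(); comps <- list()
  for (tr in traits) {
    d <- table[table$trait == tr & !is.na(table$value), , drop = FALSE]
    n_env <- length(unique(d$environment))
    fixed <- if (n_env > 1) "environment" else "1"
    if (include_replicate && "replicate" %in% names(d) &&
        length(unique(d$replicate)) > 1)
      fixed <- paste(fixed, "+ environment:factor(replicate)")
    fml <- stats::as.formula(paste("value ~", fixed, "+ (1 | line)"))
    fit <- lme4::lmer(fml, data = d,
                      control = lme4::lmerControl(check.conv.singular =
                        lme4::.makeCC(action = "ignore", tol = 1e-4)))
    vc <- as.data.frame(lme4::VarCorr(fit))
    s2g <- vc$vcov[vc$grp == "line"]
    s2e <- vc$vcov[vc$grp == "Residual"]
    re <- lme4::ranef(fit)$line
    blups[[tr]] <- data.frame(line = rownames(re), trait = tr,
                              blup = re[, 1], stringsAsFactors = FALSE)
    comps[[tr]] <- data.frame(trait = tr, sigma2_g = s2g, sigma2_e = s2e,
                              n_env = n_env,
                              h2 = heritability(s2g, s2e, n_env),
                              stringsAsFactors = FALSE)
  }
  structure(list(blups = do.call(rbind, c(blups, make.row.names = FALSE)),
                 components = do.call(rbind, c(comps,
                                               make.row.names = FALSE))),
            class = "blup_result")
}

#' Entry-mean heritability
#'
#' h2 = sigma2_g / (sigma2_g + sigma2_e / n_env): the repeatability of a
#' line mean over `n_env` environments.
#'
#' @param sigma2_g genotypic variance component.
#' @param sigma2_e residual variance component.
#' @param n_env number of environments the line mean averages over.
#' @return heritability in [0, 1]; NA when both components are zero.
#' @export
heritability <- function(sigma2_g, sigma2_e, n_env) {
  if (sigma2_g < 0 || sigma2_e < 0) stop("variance components must be >= 0")
  denom <- sigma2_g + sigma2_e / n_env
  if (denom == 0) return(NA_real_)
  sigma2_g / denom
}

#' Pairwise trait correlations
#'
#' Pearson correlations (pairwise-complete) with two-sided p-values among
#' per-line trait values.
#'
#' @param values data.frame or matrix, one row per line, one column per
#'   trait.
#' @return list of class `trait_cor`: matrices `r` and `p`.
#' @export
trait_correlations <- function(values) {
  v <- as.data.frame(values)
  v <- v[vapply(v, is.numeric, logical(1))]
  k <- ncol(v)
  if (k < 2) stop("need at least two traits")
  r <- matrix(NA_real_, k, k, dimnames = list(names(v), names(v)))
  p <- r
  diag(r) <- 1; diag(p) <- 0
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    ok <- stats::complete.cases(v[[i]], v[[j]])
    if (sum(ok) < 3) next
    ct <- stats::cor.test(v[[i]][ok], v[[j]][ok])
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  structure(list(r = r, p = p), class = "trait_cor")
}
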