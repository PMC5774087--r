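# Independent oracles used to freeze expected values. These deliberately
# avoid the package's own code paths.

# single-locus selfing: genotype distribution after g generations starting
# from a heterozygote, by matrix power (states AA, Aa, aa)
selfing_het_oracle <- function(generations) {
  P <- rbind(c(1, 0, 0),
             c(0.25, 0.5, 0.25),
             c(0, 0, 1))
  v <- c(0, 1, 0)
  for (g in seq_len(generations)) v <- as.vector(v %*% P)
  v[2]
}

# two-locus selfing to (near) fixation: probability the two loci are
# discordant given both homozygous, as a function of the per-meiosis
# recombination fraction r. Brute force over the 16 ordered diplotype
# states; independent derivation of the selfed-RIL relation R = 2r/(1+2r).
selfing_R_oracle <- function(r, generations = 60) {
  haps <- rbind(c(1, 1), c(1, 0), c(0, 1), c(0, 0))
  hap_idx <- function(h) which(haps[, 1] == h[1] & haps[, 2] == h[2])
  gamete_dist <- function(i, j) {
    p <- numeric(4)
    h1 <- haps[i, ]; h2 <- haps[j, ]
    p[i] <- p[i] + (1 - r) / 2
    p[j] <- p[j] + (1 - r) / 2
    p[hap_idx(c(h1[1], h2[2]))] <- p[hap_idx(c(h1[1], h2[2]))] + r / 2
    p[hap_idx(c(h2[1], h1[2]))] <- p[hap_idx(c(h2[1], h1[2]))] + r / 2
    p
  }
  P <- matrix(0, 16, 16)
  for (s in 1:16) {
    i <- (s - 1) %/% 4 + 1; j <- (s - 1) %% 4 + 1
    g <- gamete_dist(i, j)
    for (a in 1:4) for (b in 1:4) P[s, (a - 1) * 4 + b] <- g[a] * g[b]
  }
  v <- numeric(16); v[(1 - 1) * 4 + 4] <- 1      # start AB / ab
  for (g in seq_len(generations)) v <- as.vector(v %*% P)
  i_of <- (seq_len(16) - 1) %/% 4 + 1
  j_of <- (seq_len(16) - 1) %% 4 + 1
  hom <- i_of == j_of
  disc <- xor(haps[i_of, 1] == 1, haps[i_of, 2] == 1)
  sum(v[hom & disc]) / sum(v[hom])
}

# direct least-squares LOD for a single predictor (oracle for the LOD-R^2
# identity)
lod_lm_oracle <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  fit <- stats::lm(y[ok] ~ x[ok])
  r2 <- summary(fit)$r.squared
  -(sum(ok) / 2) * log10(1 - r2)
}

# brute-force pairwise recombinant-fraction matrix on a small coded matrix
rf_bruteforce_oracle <- function(H) {
  m <- ncol(H)
  R <- matrix(NA_real_, m, m)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    n <- 0L; d <- 0L
    for (l in seq_len(nrow(H))) {
      a <- H[l, i]; b <- H[l, j]
      if (is.na(a) || is.na(b) || a == 1L || b == 1L) next
      n <- n + 1L
      if (a != b) d <- d + 1L
    }
    if (n > 0) R[i, j] <- d / n
  }
  R
}

# hand-rolled two-state Viterbi on a short chain (oracle for imputation)
viterbi_oracle <- function(obs, Rstep, eps = 1e-4) {
  states <- c(0L, 2L)
  m <- length(obs)
  paths <- as.matrix(expand.grid(rep(list(1:2), m)))
  best <- NULL; best_lp <- -Inf
  for (k in seq_len(nrow(paths))) {
    p <- paths[k, ]
    lp <- log(0.5)
    for (t in seq_len(m)) {
      if (t > 1) {
        R <- Rstep[t - 1]
        lp <- lp + log(if (p[t] == p[t - 1]) 1 - R else R)
      }
      if (!is.na(obs[t]))
        lp <- lp + log(if (states[p[t]] == obs[t]) 1 - eps else eps)
    }
    if (lp > best_lp) { best_lp <- lp; best <- p }
  }
  states[best]
}

# build a bin_map object directly (for unit tests of bin-map operations)
make_binmap <- function(bins, geno, layout = NULL) {
  rownames(geno) <- rownames(geno) %||% sprintf("L%03d", seq_len(nrow(geno)))
  structure(list(bins = bins, geno = geno, layout = layout),
            class = "bin_map")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
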