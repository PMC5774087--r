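# Bin construction, segregation distortion, distorted-bin discard,
# imputation, recombination fractions, Kosambi map, crossover counting,
# recombination profile.

.toy_layout <- function(n_chrom = 1, length_bp = 3e7, length_cM = 50) {
  uniform_layout(n_chrom = n_chrom, length_bp = length_bp,
                 length_cM = length_cM, n_snps = 30)
}

.blocks_from_breaks <- function(line, breaks, L, genos = NULL,
                                chrom = "chr1") {
  edges <- c(1, breaks + 1, L + 1)
  n <- length(edges) - 1
  if (is.null(genos)) genos <- rep(c("P1", "P2"), length.out = n)
  data.frame(line = line, chrom = chrom, start = edges[-length(edges)],
             end = edges[-1] - 1, genotype = genos, snp_count = 100,
             stringsAsFactors = FALSE)
}

test_that("bin boundaries are the union of line breakpoints", {
  lay <- .toy_layout()
  blocks <- rbind(.blocks_from_breaks("A", 1e7, 3e7),
                  .blocks_from_breaks("B", c(1e7, 2e7), 3e7,
                                      c("P2", "P1", "P2")),
                  .blocks_from_breaks("C", numeric(0), 3e7, "P1"))
  bm <- construct_bins(blocks, lay)
  expect_equal(bm$bins$start, c(1, 1e7 + 1, 2e7 + 1))
  expect_equal(bm$bins$end, c(1e7, 2e7, 3e7))
  # per-line genotypes come from the covering block
  expect_equal(unname(bm$geno["A", ]), c(0L, 2L, 2L))
  expect_equal(unname(bm$geno["B", ]), c(2L, 0L, 2L))
  expect_equal(unname(bm$geno["C", ]), c(0L, 0L, 0L))
  # bins tile the chromosome
  expect_equal(sum(bm$bins$end - bm$bins$start + 1), 3e7)
})

test_that("bins shorter than 5 kb are merged with dominant genotype", {
  lay <- .toy_layout()
  blocks <- rbind(.blocks_from_breaks("A", 1e7, 3e7),
                  .blocks_from_breaks("B", 1e7 + 3000, 3e7))
  bm <- construct_bins(blocks, lay)
  # the 3 kb sliver between the two breakpoints is merged away
  expect_true(all(bm$bins$end - bm$bins$start + 1 >= 5000))
  expect_equal(nrow(bm$bins), 2)
  # two lines with no breakpoints give a single bin
  b2 <- rbind(.blocks_from_breaks("A", numeric(0), 3e7, "P1"),
              .blocks_from_breaks("B", numeric(0), 3e7, "P2"))
  bm2 <- construct_bins(b2, lay)
  expect_equal(nrow(bm2$bins), 1)
  expect_error(construct_bins(.blocks_from_breaks("A", 1e7, 3e7), lay),
               ">= 2")
})

test_that("segregation chi-square matches the direct (O-E)^2/E formula", {
  lay <- .toy_layout()
  g <- matrix(0L, 1021, 1)
  g[511:1021, 1] <- 2L                    # 510 vs 511
  bm <- make_binmap(data.frame(chrom = "chr1", start = 1, end = 3e7), g, lay)
  sd1 <- test_segregation_distortion(bm)
  expect_gt(sd1$p, 0.9)
  expect_false(sd1$distorted)
  g2 <- matrix(c(rep(0L, 700), rep(2L, 321)), ncol = 1)
  bm2 <- make_binmap(data.frame(chrom = "chr1", start = 1, end = 3e7), g2,
                     lay)
  sd2 <- test_segregation_distortion(bm2)
  expect_equal(sd2$chisq,
               (700 - 510.5)^2 / 510.5 + (321 - 510.5)^2 / 510.5)
  expect_true(sd2$distorted)
  # counts at expectation give statistic zero
  g3 <- matrix(rep(c(0L, 2L), 50), ncol = 1)
  bm3 <- make_binmap(data.frame(chrom = "chr1", start = 1, end = 3e7), g3,
                     lay)
  expect_equal(test_segregation_distortion(bm3)$chisq, 0)
})

test_that("distorted-bin discard applies the strict 2/1 and 15% rules", {
  lay <- .toy_layout()
  mk_col <- function(n1, n2, nh, nn = 0)
    c(rep(0L, n1), rep(2L, n2), rep(1L, nh), rep(NA_integer_, nn))
  g <- cbind(mk_col(60, 25, 15),    # ratio 2.4 -> discard
             mk_col(50, 25, 25),    # het 0.25 -> discard
             mk_col(50, 25, 0, 25), # ratio exactly 2.0, het 0 -> keep
             mk_col(100, 0, 0))     # minor frequency 0 -> discard
  bins <- data.frame(chrom = "chr1", start = c(1, 11, 21, 31) * 1e5 - 1e5 + 1,
                     end = c(10, 20, 30, 40) * 1e5)
  bm <- make_binmap(bins, g, lay)
  out <- filter_distorted_bins(bm)
  expect_equal(ncol(out$geno), 1)
  expect_equal(out$bins$start, 21e5 - 1e5 + 1)
  expect_equal(attr(out, "discarded_fraction"), 0.75)
})

test_that("Kosambi function matches closed forms and round-trips", {
  expect_equal(kosambi_cm(0), 0)
  expect_equal(kosambi_cm(0.25), 25 * log(3))
  expect_equal(kosambi_cm(0.1), 25 * log(1.5))
  expect_lt(abs(kosambi_cm(0.25) - 27.465), 0.001)
  r <- seq(0, 0.49, by = 0.005)
  expect_true(all(abs(r - kosambi_r(kosambi_cm(r))) < 1e-12))
  expect_error(kosambi_cm(0.5), "r must be")
  expect_error(kosambi_r(-1), "non-negative")
})

test_that("selfed-RIL correction matches the two-locus brute-force oracle", {
  for (r in c(0.01, 0.05, 0.1, 0.2, 0.3)) {
    R_oracle <- selfing_R_oracle(r)
    expect_lt(abs(R_oracle - ril_R(r)), 1e-8)
    expect_lt(abs(ril_r(R_oracle) - r), 1e-8)
  }
  expect_equal(ril_r(0.4), 0.4 / 1.2)
  expect_lt(ril_r(0.9999), 0.5)          # clamped at the asymptote
})

test_that("recombination fractions match a brute-force pairwise count", {
  set.seed(8)
  H <- matrix(sample(c(0L, 2L), 200, replace = TRUE), 20, 10)
  H[sample(length(H), 15)] <- NA_integer_
  H[sample(length(H), 5)] <- 1L
  bins <- data.frame(chrom = "chr1",
                     start = seq(1, by = 1e6, length.out = 10),
                     end = seq(1e6, by = 1e6, length.out = 10))
  bm <- make_binmap(bins, H)
  oracle <- rf_bruteforce_oracle(H)
  est <- estimate_rf(bm, "all")
  expect_equal(est$R, oracle)
  adj <- estimate_rf(bm, "adjacent")
  expect_equal(adj$R, oracle[cbind(1:9, 2:10)])
  # identical columns give R = r = 0; discordance 0.4 gives r = 1/3
  c1 <- rep(c(0L, 2L), 50)
  c3 <- c1
  c3[1:40] <- 2L - c3[1:40]                 # 40% discordant
  H2 <- cbind(c1, c1, c3)
  bm2 <- make_binmap(data.frame(chrom = "chr1",
                                start = c(1, 1e6 + 1, 2e6 + 1),
                                end = c(1e6, 2e6, 3e6)), H2)
  adj2 <- estimate_rf(bm2, "adjacent")
  expect_equal(adj2$R, c(0, 0.4))
  expect_equal(adj2$r, c(0, 0.4 / 1.2))
})

test_that("Viterbi imputation fills missing bins like the exhaustive oracle", {
  bins <- data.frame(chrom = "chr1", start = c(1, 1e6 + 1, 2e6 + 1),
                     end = c(1e6, 2e6, 3e6))
  rf <- data.frame(chrom = "chr1", bin1 = 1:2, bin2 = 2:3,
                   n_informative = 100, R = c(0.01, 0.3),
                   r = ril_r(c(0.01, 0.3)), low_conf = FALSE)
  # missing middle flanked by P1/P1: imputed P1
  g <- rbind(c(0L, NA, 0L), c(0L, 0L, 0L))
  bm <- make_binmap(bins, g)
  out <- impute_genotypes(bm, rf)
  expect_equal(unname(out$geno[1, 2]), 0L)
  # P1 .. P2 with unequal intervals: middle goes to the genetically closer
  # flank (smaller R on the left)
  g2 <- rbind(c(0L, NA, 2L), c(0L, 0L, 2L))
  bm2 <- make_binmap(bins, g2)
  out2 <- impute_genotypes(bm2, rf)
  expect_equal(unname(out2$geno[1, 2]), 0L)
  expect_equal(unname(out2$geno[1, 2]),
               viterbi_oracle(c(0L, NA, 2L), rf$R)[2])
  # random chains agree with the exhaustive-path oracle
  set.seed(5)
  for (k in 1:20) {
    obs <- sample(c(0L, 2L, NA), 5, replace = TRUE)
    if (all(is.na(obs))) next
    Rstep <- runif(4, 0.02, 0.45)
    rf5 <- data.frame(chrom = "chr1", bin1 = 1:4, bin2 = 2:5,
                      n_informative = 100, R = Rstep, r = ril_r(Rstep),
                      low_conf = FALSE)
    bins5 <- data.frame(chrom = "chr1",
                        start = seq(1, by = 1e6, length.out = 5),
                        end = seq(1e6, by = 1e6, length.out = 5))
    bm5 <- make_binmap(bins5, rbind(obs, obs))
    got <- unname(impute_genotypes(bm5, rf5)$geno[1, ])
    want <- viterbi_oracle(obs, Rstep)
    want[!is.na(obs)] <- obs[!is.na(obs)]
    expect_equal(got, want)
  }
  # heterozygous calls are first set missing, then filled
  g3 <- rbind(c(0L, 1L, 0L), c(0L, 0L, 0L))
  out3 <- impute_genotypes(make_binmap(bins, g3), rf)
  expect_equal(unname(out3$geno[1, 2]), 0L)
  # nothing missing: matrix unchanged
  g4 <- rbind(c(0L, 2L, 0L), c(2L, 0L, 2L))
  out4 <- impute_genotypes(make_binmap(bins, g4), rf)
  expect_equal(out4$geno, make_binmap(bins, g4)$geno)
})

test_that("genetic map accumulates Kosambi distances per chromosome", {
  bins <- data.frame(chrom = rep(c("chr1", "chr2"), c(3, 1)),
                     start = c(1, 1e6 + 1, 2e6 + 1, 1),
                     end = c(1e6, 2e6, 3e6, 3e6))
  set.seed(3)
  # deterministic toy: columns with known discordance
  g <- cbind(rep(c(0L, 2L), 100),
             c(rep(c(2L, 0L), 10), rep(c(0L, 2L), 90)),
             c(rep(c(2L, 0L), 30), rep(c(0L, 2L), 70)),
             sample(c(0L, 2L), 200, TRUE))
  bm <- make_binmap(bins, g)
  gm <- build_genetic_map(bm)
  expect_equal(gm$map$cM[1], 0)
  expect_true(all(diff(gm$map$cM[1:3]) >= 0))
  expect_equal(gm$map$cM[4], 0)           # single-bin chromosome: 0 cM
  # total equals the sum of interval distances
  expect_equal(gm$summary$total_cM[1], sum(gm$intervals$interval_cM[1:2]))
  # mean interval convention on a toy: mean of adjacent interval cM
  expect_equal(gm$summary$mean_interval_cM[1],
               mean(gm$intervals$interval_cM[1:2]))
})

test_that("crossover counting matches hand totals", {
  bins <- data.frame(chrom = "chr1",
                     start = seq(1, by = 1e6, length.out = 4),
                     end = seq(1e6, by = 1e6, length.out = 4))
  g <- rbind(c(0L, 2L, 0L, 0L),      # 2 transitions
             c(0L, 0L, NA, 2L),      # 1 (missing skipped)
             c(2L, 2L, 2L, 2L))      # 0
  bm <- make_binmap(bins, g)
  xo <- count_crossovers(bm)
  expect_equal(xo$total, 3)
  expect_equal(unname(xo$per_line), c(2, 1, 0))
  expect_equal(unname(xo$mean_per_chrom_line), 1)
  # the headline arithmetic: totals over lines x chromosomes
  expect_equal(round(50040 / (1021 * 10), 1), 4.9)
})

test_that("map recovery on simulated data carries the known F7 deficit", {
  # the fixation-based RIL correction applied to F7 (6 selfing generations)
  # data under-scales R by ~9% (two-locus oracle: R_F7/R_inf ~ 0.91 at
  # small r), so recovered length sits below truth but within 20%
  expect_lt(selfing_R_oracle(0.01, 6) / ril_R(0.01), 0.93)
  expect_gt(selfing_R_oracle(0.01, 6) / ril_R(0.01), 0.88)
  lay <- uniform_layout(n_chrom = 1, length_bp = 1e8, length_cM = 100)
  sim <- simulate_population(lay, sim_params(n_lines = 250, seed = 60))
  fl <- filter_lines(call_mosaics(sim$observations, lay))
  bm <- construct_bins(fl$mosaics, lay)
  imp <- impute_genotypes(filter_distorted_bins(bm))
  gm <- build_genetic_map(imp)
  expect_lt(abs(sum(gm$summary$total_cM) - 100) / 100, 0.2)
  expect_true(all(diff(gm$map$cM) >= -1e-9))
})

test_that("recombination profile apportions interval cM by overlap", {
  lay <- uniform_layout(n_chrom = 1, length_bp = 1e7, length_cM = 20,
                        n_snps = 50)
  bins <- data.frame(chrom = "chr1", start = c(1, 5e6 + 1),
                     end = c(5e6, 1e7))
  g <- rbind(c(0L, 0L), c(0L, 2L), c(2L, 2L), c(2L, 0L),
             c(0L, 0L), c(2L, 2L), c(0L, 0L), c(2L, 2L),
             c(0L, 0L), c(2L, 2L))
  bm <- make_binmap(bins, g, lay)
  gm <- build_genetic_map(bm)
  pr <- recombination_profile(gm, lay)
  expect_equal(nrow(pr$profile), 10)
  # all interval cM lands between the bin midpoints (2.5 and 7.5 Mb)
  expect_equal(sum(pr$profile$cM), sum(gm$intervals$interval_cM))
  expect_equal(pr$profile$cM[1], 0)
  expect_equal(pr$profile$cM[10], 0)
  # windows fully inside the interval share one local rate
  inner <- pr$profile$cM_per_Mb[4:7]
  expect_true(all(abs(inner - inner[1]) < 1e-9))
  # mismatched track layout is rejected
  bad <- data.frame(chrom = "chr1", start = c(1, 2), x = 1:2)
  expect_error(recombination_profile(gm, lay, tracks = bad), "layout")
})

test_that("profile correlates with a planted crossover-intensity track", {
  intensity <- rep(c(0.2, 2), each = 50)     # cold left arm, hot right arm
  lay <- uniform_layout(n_chrom = 1, length_bp = 1e8, length_cM = 100,
                        crossover_intensity = list(chr1 = intensity))
  sim <- simulate_population(lay, sim_params(n_lines = 250, seed = 61))
  fl <- filter_lines(call_mosaics(sim$observations, lay))
  imp <- impute_genotypes(filter_distorted_bins(
    construct_bins(fl$mosaics, lay)))
  gm <- build_genetic_map(imp)
  track <- data.frame(chrom = "chr1",
                      start = seq(1, 1e8, by = 1e6), density = intensity)
  pr <- recombination_profile(gm, lay, tracks = track)
  expect_gt(pr$correlations$r, 0.5)
  expect_lt(pr$correlations$p, 1e-6)
})
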