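# Sliding-window caller: window rule, breakpoint resolution, block merging,
# block and line filters.

test_that("window genotype rule applies the strict >11/15 threshold", {
  cfg <- caller_config()
  mk <- function(n1, n2) c(rep("P1", n1), rep("P2", n2))
  pos <- seq_len(15) * 1000
  expect_equal(call_windows(pos, mk(15, 0), cfg)$genotype, "P1")
  expect_equal(call_windows(pos, mk(12, 3), cfg)$genotype, "P1")   # 12 > 11
  expect_equal(call_windows(pos, mk(11, 4), cfg)$genotype, "HET")  # 11 is not
  expect_equal(call_windows(pos, mk(3, 12), cfg)$genotype, "P2")
  expect_error(call_windows(pos, c(mk(14, 0), "XX")), "unknown allele")
})

test_that("windows slide by one SNP with complementary counts", {
  set.seed(1)
  allele <- sample(c("P1", "P2"), 60, replace = TRUE)
  wc <- call_windows(seq_len(60) * 500, allele)
  expect_equal(nrow(wc), 60 - 15 + 1)
  expect_equal(wc$first_snp, 1:46)
  expect_true(all(wc$p1_count + wc$p2_count == 15))
  # oracle: recount windows directly
  expect_equal(wc$p1_count,
               vapply(1:46, function(i) sum(allele[i:(i + 14)] == "P1"),
                      integer(1)))
})

test_that("short HET runs are resolved by the midpoint rule", {
  cfg <- caller_config()
  g <- c(rep("P1", 20), rep("HET", 4), rep("P2", 20))
  expect_equal(resolve_breakpoints(g, cfg),
               c(rep("P1", 22), rep("P2", 22)))
  # runs of 7+ windows are retained as heterozygous
  g8 <- c(rep("P1", 20), rep("HET", 8), rep("P2", 20))
  expect_equal(resolve_breakpoints(g8, cfg), g8)
  # same flanks absorb the run
  gs <- c(rep("P1", 10), rep("HET", 2), rep("P1", 10))
  expect_equal(resolve_breakpoints(gs, cfg), rep("P1", 22))
  # odd run length: extra window goes left
  g5 <- c(rep("P1", 10), rep("HET", 5), rep("P2", 10))
  expect_equal(resolve_breakpoints(g5, cfg),
               c(rep("P1", 13), rep("P2", 12)))
  # run at a chromosome end adopts the single flank
  ge <- c(rep("HET", 3), rep("P2", 20))
  expect_equal(resolve_breakpoints(ge, cfg), rep("P2", 23))
})

test_that("blocks get midpoint boundaries and tile the chromosome", {
  cfg <- caller_config()
  # homogeneous calls: one block spanning the chromosome
  pos <- seq(1e4, 2e6, length.out = 40)
  bl <- merge_to_blocks(rep("P1", 40 - 14), pos, 2e6, cfg)
  expect_equal(nrow(bl), 1)
  expect_equal(bl$start, 1); expect_equal(bl$end, 2e6)
  expect_equal(bl$snp_count, 40)
  # boundary at the midpoint between flanking assigned SNPs
  pos2 <- c(seq(2e4, 1e6, length.out = 50), seq(1000400, 2e6,
                                                length.out = 50))
  calls <- c(rep("P1", 50 - 7), rep("P2", 100 - 14 - 43))
  bl2 <- merge_to_blocks(calls, pos2, 2e6, cfg)
  expect_equal(nrow(bl2), 2)
  expect_equal(bl2$end[1], floor((1e6 + 1000400) / 2))
  expect_equal(bl2$start[2], floor((1e6 + 1000400) / 2) + 1)
  expect_equal(sum(bl2$end - bl2$start + 1), 2e6)
})

test_that("block filters enforce the strict SNP and length minima", {
  cfg <- caller_config()
  base <- function(snps, len, g) {
    # a candidate block surrounded by two large anchor blocks
    data.frame(start = c(1, 1e7 + 1, 1e7 + len + 1),
               end = c(1e7, 1e7 + len, 3e7),
               genotype = c("P1", g, "P2"),
               snp_count = c(300, snps, 300), stringsAsFactors = FALSE)
  }
  g1 <- filter_blocks(base(4, 5e5, "P2"), cfg)     # 4 SNPs < 5
  expect_false("P2" %in% g1$genotype[g1$end <= 1e7 + 5e5])
  g2 <- filter_blocks(base(20, 2.5e5, "P2"), cfg)  # 250 kb < 300 kb
  expect_true(any(g2$genotype == "MISSING"))
  g3 <- filter_blocks(base(14, 2e6, "HET"), cfg)   # HET with 14 SNPs < 15
  expect_false("HET" %in% g3$genotype)
  g4 <- filter_blocks(base(5, 3e5, "P2"), cfg)     # exactly at both minima
  expect_true("P2" %in% g4$genotype)
  # breakpoints counted across missing gaps
  expect_equal(attr(g1, "n_breakpoints"), 1L)
})

test_that("frequently switching small blocks consolidate to heterozygous", {
  cfg <- caller_config()
  # alternating small blocks (each passes the basic filter but is 'small')
  n <- 8
  st <- seq(1, by = 5e5, length.out = n)
  b <- data.frame(start = c(st, 4e6 + 1), end = c(st + 5e5 - 1, 3e7),
                  genotype = c(rep(c("P1", "P2"), n / 2), "P1"),
                  snp_count = c(rep(10, n), 500), stringsAsFactors = FALSE)
  f <- filter_blocks(b, cfg)
  # the switching stretch became one HET block, then fell to the HET minima
  expect_false(any(f$genotype == "P2"))
  # large alternating blocks (true crossovers) are NOT consolidated
  b2 <- data.frame(start = c(1, 1e7 + 1, 2e7 + 1, 3e7 + 1),
                   end = c(1e7, 2e7, 3e7, 4e7),
                   genotype = c("P1", "P2", "P1", "P2"),
                   snp_count = rep(200, 4), stringsAsFactors = FALSE)
  f2 <- filter_blocks(b2, cfg)
  expect_equal(f2$genotype, c("P1", "P2", "P1", "P2"))
  expect_equal(attr(f2, "n_breakpoints"), 3L)
})

test_that("line filter applies the strict 15% het / 360 breakpoint rules", {
  cfg <- caller_config()
  fake <- structure(list(
    blocks = data.frame(),
    line_stats = data.frame(
      line = c("A", "B", "C", "D"),
      het_fraction = c(0.16, 0.10, 0.15, 0),
      n_breakpoints = c(10L, 361L, 360L, 30L))), class = "mosaic_set")
  fl <- filter_lines(fake, cfg)
  expect_setequal(fl$retained, c("C", "D"))
  expect_equal(sort(fl$excluded$line), c("A", "B"))
  expect_equal(fl$excluded$reason[fl$excluded$line == "A"], "het_fraction")
  expect_equal(fl$excluded$reason[fl$excluded$line == "B"], "breakpoints")
})

test_that("opposite-homozygote window miscalls are essentially impossible at GBS error rates", {
  # 10^4 independent windows inside a true P1 tract at 0.9% per-site error
  set.seed(2024)
  flips <- matrix(stats::runif(1e4 * 15) < 0.009, ncol = 15)
  p2_count <- rowSums(flips)
  expect_equal(sum(p2_count > 11), 0L)
  expect_lt(stats::pbinom(11, 15, 0.009, lower.tail = FALSE), 1e-18)
  # the direct count agrees with the caller on a sample of windows
  for (i in sample.int(1e4, 20)) {
    allele <- ifelse(flips[i, ], "P2", "P1")
    expect_equal(call_windows(seq_len(15) * 100, allele)$p2_count,
                 sum(flips[i, ]))
  }
})

test_that("caller recovers simulated crossovers and genotypes", {
  lay <- uniform_layout(n_chrom = 1, length_bp = 1e8, length_cM = 100)
  sim <- simulate_population(lay, sim_params(n_lines = 120, seed = 42))
  called <- call_mosaics(sim$observations, lay)
  fl <- filter_lines(called)
  expect_gt(length(fl$retained), 100)
  blocks <- fl$mosaics$blocks
  mos <- sim$mosaics
  # genotype concordance over covered length >= 99%
  conc <- vapply(fl$retained, function(li) {
    b <- blocks[blocks$line == li & blocks$genotype != "MISSING", ]
    m <- mos[mos$line == li, ]
    match_len <- 0; tot <- 0
    for (i in seq_len(nrow(b))) {
      idx <- which(m$end >= b$start[i] & m$start <= b$end[i])
      for (j in idx) {
        ov <- min(m$end[j], b$end[i]) - max(m$start[j], b$start[i]) + 1
        tot <- tot + ov
        if (m$genotype[j] == b$genotype[i]) match_len <- match_len + ov
      }
    }
    match_len / tot
  }, numeric(1))
  expect_gt(mean(conc), 0.99)
  # crossover recovery: clean homozygous-homozygous transitions flanked by
  # large segments should have a called breakpoint nearby (half the local
  # observed SNP spacing times the window size)
  tol <- 0.5 * (1e8 / (0.08 * length(lay$snp_positions$chr1))) * 15
  n_true <- 0; n_found <- 0
  for (li in fl$retained) {
    m <- mos[mos$line == li, ]
    b <- blocks[blocks$line == li & blocks$genotype != "MISSING", ]
    if (nrow(b) < 2) bks <- numeric(0)
    else bks <- (b$end[-nrow(b)] + b$start[-1]) / 2
    if (nrow(m) < 2) next
    seg_len <- m$end - m$start + 1
    for (k in seq_len(nrow(m) - 1)) {
      if (m$genotype[k] == "HET" || m$genotype[k + 1] == "HET") next
      if (seg_len[k] < 2e6 || seg_len[k + 1] < 2e6) next
      n_true <- n_true + 1
      if (length(bks) && min(abs(bks - m$end[k])) <= tol)
        n_found <- n_found + 1
    }
  }
  expect_gt(n_true, 50)
  expect_gte(n_found / n_true, 0.95)
})

test_that("chromosomes with fewer SNPs than one window are entirely missing", {
  lay <- uniform_layout(n_chrom = 1, length_bp = 1e7, length_cM = 10,
                        n_snps = 100)
  obs <- data.frame(chrom = "chr1", pos = seq(1e5, 1e6, length.out = 10),
                    line = "L1", allele = rep("P1", 10))
  obs2 <- rbind(obs, data.frame(chrom = "chr1",
                                pos = seq(1e5, 9e6, length.out = 40),
                                line = "L2", allele = rep("P2", 40)))
  cm <- call_mosaics(obs2, lay)
  b1 <- cm$blocks[cm$blocks$line == "L1", ]
  expect_equal(b1$genotype, "MISSING")
  expect_equal(b1$start, 1); expect_equal(b1$end, 1e7)
})
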