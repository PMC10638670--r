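test_that("polarisation flips against a fixed-alt outgroup and drops the rest", {
  # 5 hand-made sites: outgroup fixed ref, fixed alt, polymorphic, missing
  geno <- rbind(c(2L, 0L, 0L),   # derived in P1
                c(0L, 2L, 2L),   # outgroup fixed alt: flips
                c(2L, 2L, 1L),   # outgroup polymorphic: dropped
                c(0L, 2L, NA),   # outgroup missing: dropped
                c(2L, 2L, 0L))
  colnames(geno) <- c("p1", "p2", "og")
  gm <- genotype_matrix(
    data.frame(chrom = "chr1", pos = 0:4, ref = "A", alt = "T"),
    geno, setNames(c("P1", "P2", "O"), c("p1", "p2", "og")), outgroup = "O")
  fr <- polarize(gm)
  expect_equal(nrow(fr$freq), 3)
  expect_equal(fr$n_dropped, 2L)
  expect_equal(unname(fr$freq[, "P1"]), c(1, 1, 1))    # site 2 flipped
  expect_equal(unname(fr$freq[, "P2"]), c(0, 0, 1))
  expect_equal(unname(fr$freq[, "O"]), c(0, 0, 0))
  # all dropped -> warning
  gm2 <- subset_genotypes(gm, 3:4)
  expect_warning(polarize(gm2), "all sites dropped")
})

test_that("Patterson's D reproduces exact pattern arithmetic", {
  # 30 pure-ABBA sites and 10 pure-BABA sites -> D = 0.5
  f <- rbind(matrix(rep(c(0, 1, 1), 30), ncol = 3, byrow = TRUE),
             matrix(rep(c(1, 0, 1), 10), ncol = 3, byrow = TRUE))
  colnames(f) <- c("P1", "P2", "P3")
  d <- patterson_d(freqs_fixture(f), "P1", "P2", "P3", block_size = 5000,
                   min_blocks_z = 2)
  expect_equal(d$D, 0.5)
  expect_equal(d$abba, 30); expect_equal(d$baba, 10)
  # p1 == p2 everywhere -> D = 0 exactly
  set.seed(9)
  p <- runif(50); q <- runif(50)
  f2 <- cbind(P1 = p, P2 = p, P3 = q)
  expect_equal(patterson_d(freqs_fixture(f2), "P1", "P2", "P3",
                           block_size = 5000, min_blocks_z = 2)$D, 0)
  # no informative weight -> undefined flag
  f3 <- cbind(P1 = rep(0, 5), P2 = rep(0, 5), P3 = rep(0, 5))
  expect_equal(patterson_d(freqs_fixture(f3), "P1", "P2", "P3")$flag,
               "undefined")
})

test_that("D is antisymmetric under swapping P1 and P2", {
  set.seed(10)
  f <- cbind(P1 = runif(200), P2 = runif(200), P3 = runif(200))
  fr <- freqs_fixture(f)
  d12 <- patterson_d(fr, "P1", "P2", "P3", block_size = 1e4,
                     min_blocks_z = 2)
  d21 <- patterson_d(fr, "P2", "P1", "P3", block_size = 1e4,
                     min_blocks_z = 2)
  expect_equal(d12$D, -d21$D)
  expect_equal(d12$se, d21$se)
})

test_that("block-jackknife SE agrees with the analytic iid value", {
  # iid 0/1 pattern sites: ABBA with prob pa, BABA with prob pb
  set.seed(11)
  n <- 1e5; pa <- 0.012; pb <- 0.008
  r <- runif(n)
  f <- matrix(0, n, 3, dimnames = list(NULL, c("P1", "P2", "P3")))
  f[r < pa, ] <- rep(c(0, 1, 1), each = sum(r < pa))
  f[r >= pa & r < pa + pb, ] <- rep(c(1, 0, 1),
                                    each = sum(r >= pa & r < pa + pb))
  fr <- freqs_fixture(f)
  d <- patterson_d(fr, "P1", "P2", "P3", block_size = 1e6)  # 100 blocks
  nA <- d$abba; nB <- d$baba
  se_analytic <- 2 * sqrt(nA * nB / (nA + nB)^3)
  expect_gt(d$se / se_analytic, 0.8)
  expect_lt(d$se / se_analytic, 1.25)
})

test_that("trios are ordered by the reference topology", {
  st <- ape::read.tree(text = "((((A,B),C),D),O);")
  tr <- enumerate_trios(st, c("A", "B", "C", "D"))
  expect_equal(nrow(tr), 4)
  expect_true(all(tr$resolved))
  key <- function(m1, m2, m3)
    any(tr$M1 == m1 & tr$M2 == m2 & tr$M3 == m3)
  expect_true(key("A", "B", "C") && key("A", "B", "D") &&
                key("A", "C", "D") && key("B", "C", "D"))
  # triple spanning the root: the lone-side taxon is M3
  st2 <- ape::read.tree(text = "(((A,B),C),(D,E));")
  tr2 <- enumerate_trios(st2, c("A", "C", "D"))
  expect_equal(tr2$M3[1], "D")
  # combinatorial count at 16 taxa
  big <- ape::read.tree(text = paste0("(", paste0("t", 1:16, collapse = ","),
                                      ");"))
  big <- ape::as.phylo(stats::hclust(stats::dist(1:16), "single"))
  big$tip.label <- paste0("t", 1:16)
  expect_equal(nrow(enumerate_trios(big, paste0("t", 1:16))), choose(16, 3))
})

test_that("f4 ratio equals hand arithmetic and its boundary cases", {
  # donor identical to recipient -> ratio 1
  set.seed(12)
  p <- runif(30, 0.2, 0.8)
  f <- cbind(A = runif(30, 0, 0.2), B = p, C = p)
  expect_equal(f4_ratio(freqs_fixture(f), "A", "B", "C")$ratio, 1)
  # hand-computed 6-site table
  fa <- c(0, 0, 0.5, 1, 0.2, 0); fb <- c(1, 0.5, 0.5, 1, 0.4, 0)
  fc <- c(1, 1, 0.5, 0, 0.8, 0.3)
  f6 <- cbind(A = fa, B = fb, C = fc)
  num <- sum((fb - fa) * fc)
  den <- sum((pmax(fb, fc) - fa) * pmax(fb, fc))
  r <- f4_ratio(freqs_fixture(f6), "A", "B", "C")
  expect_equal(r$raw, num / den)
  # zero denominator flagged
  fz <- cbind(A = rep(0.5, 4), B = rep(0.5, 4), C = rep(0.5, 4)) * 0
  expect_equal(f4_ratio(freqs_fixture(fz), "A", "B", "C")$flag, "undefined")
})

test_that("f-branch is a min of medians and order-invariant", {
  st <- ape::read.tree(text = "(((A,B),(C,D)),O);")
  f4 <- expand.grid(A = c("A", "B"), B = c("C", "D"), C = "O",
                    stringsAsFactors = FALSE)[0, ]
  # hand-built table: branch of {C,D}; donors outside
  f4 <- data.frame(A = c("A", "B", "A", "B"), B = c("C", "C", "D", "D"),
                   C = "X", ratio = c(0.1, 0.3, 0.4, 0.6))
  st2 <- ape::read.tree(text = "((((A,B),(C,D)),X),O);")
  fb <- f_branch(st2, f4, outgroup = "O")
  # for branch {C,D}: median over A in {A,B} per B, then min over B
  expect_equal(unname(fb["C,D", "X"]), min(median(c(0.1, 0.3)),
                                           median(c(0.4, 0.6))))
  # invariant to the row order of the f4 table
  fb2 <- f_branch(st2, f4[sample(nrow(f4)), ], outgroup = "O")
  expect_equal(fb, fb2)
})

test_that("windowed Fd handles boundary conventions and enrichment", {
  # p1 == p2 in a window -> fd = 0; full donor haplotype -> fd = 1
  f <- cbind(P1 = c(0.3, 0.3, 0, 0), P2 = c(0.3, 0.3, 1, 1),
             P3 = c(0.8, 0.6, 1, 1))
  fr <- freqs_fixture(f)   # positions 0, 1000, 2000, 3000
  wins <- data.frame(chrom = "chr1", start = c(0, 2000),
                     end = c(2000, 4000))
  fd <- fd_windows(fr, "P1", "P2", "P3", wins)
  expect_equal(fd$value, c(0, 1))
  # negative numerator -> undefined, not zero
  fneg <- cbind(P1 = c(1, 1), P2 = c(0, 0), P3 = c(1, 1))
  fdneg <- fd_windows(freqs_fixture(fneg), "P1", "P2", "P3",
                      data.frame(chrom = "chr1", start = 0, end = 4000))
  expect_true(is.na(fdneg$value))
})

test_that("top-fraction selection sizes and tie-breaks are deterministic", {
  ws <- data.frame(chrom = "chr1", start = (0:999) * 1e4,
                   end = (1:1000) * 1e4, statistic = "fd",
                   value = rep(1, 1000))
  class(ws) <- c("window_stat", "data.frame")
  expect_equal(nrow(top_fraction(ws, 0.05)), 50)
  expect_equal(nrow(top_fraction(ws, 0.01)), 10)
  # all equal -> first windows in genomic order
  expect_equal(top_fraction(ws, 0.01)$start, (0:9) * 1e4)
  # undefined windows are excluded from the denominator
  ws$value[1:500] <- NA
  expect_equal(nrow(top_fraction(ws, 0.05)), 25)
})

test_that("Hudson FST matches a site-by-site oracle and its limits", {
  mk <- function(geno, pops) {
    colnames(geno) <- names(pops)
    genotype_matrix(data.frame(chrom = "chr1", pos = seq_len(nrow(geno)) - 1,
                               ref = "A", alt = "T"), geno, pops)
  }
  # identical allele frequencies -> 0 up to the finite-sample correction
  # (the unbiased Hudson estimator is slightly negative at equal sample
  # frequencies; negative estimates are retained by design)
  g <- matrix(rep(c(rep(c(0L, 2L), 50), rep(c(0L, 2L), 50)), 25), 25, 200,
              byrow = TRUE)
  gm <- mk(g, setNames(rep(c("A", "B"), each = 100), paste0("i", 1:200)))
  expect_lt(abs(hudson_fst(gm, "A", "B")), 0.01)
  expect_lte(hudson_fst(gm, "A", "B"), 0)
  # fixed differences with decent samples -> near 1
  g2 <- matrix(rep(c(rep(0L, 10), rep(2L, 10)), 25), 25, 20, byrow = TRUE)
  gm2 <- mk(g2, setNames(rep(c("A", "B"), each = 10), paste0("i", 1:20)))
  expect_gt(hudson_fst(gm2, "A", "B"), 0.99)
  # two-island simulation vs an independent per-site implementation
  set.seed(14)
  n <- 400; na <- 12; nb <- 16
  pa <- rbeta(n, 2, 2); pb <- pmin(1, pmax(0, pa + rnorm(n, 0, 0.25)))
  ga <- matrix(rbinom(n * na, 2, rep(pa, na)), n, na)
  gb <- matrix(rbinom(n * nb, 2, rep(pb, nb)), n, nb)
  gm3 <- mk(cbind(ga, gb) |> `storage.mode<-`("integer"),
            setNames(rep(c("A", "B"), c(na, nb)), paste0("i", 1:(na + nb))))
  est <- hudson_fst(gm3, "A", "B")
  num <- den <- 0
  for (s in seq_len(n)) {
    p1 <- mean(ga[s, ]) / 2; p2 <- mean(gb[s, ]) / 2
    num <- num + (p1 - p2)^2 - p1 * (1 - p1) / (2 * na - 1) -
      p2 * (1 - p2) / (2 * nb - 1)
    den <- den + p1 * (1 - p2) + p2 * (1 - p1)
  }
  expect_equal(est, num / den)
})

test_that("heterozygosity windows count het calls per callable length", {
  n <- 60
  geno <- matrix(0L, n, 2, dimnames = list(NULL, c("i1", "i2")))
  geno[1:50, 2] <- 1L   # 50 het calls for i2 in the first window
  gm <- genotype_matrix(
    data.frame(chrom = "chr1", pos = c(seq_len(50) * 100, 1e5 + 1:10),
               ref = "A", alt = "T"),
    geno, setNames(c("P1", "P2"), c("i1", "i2")))
  hw <- heterozygosity_windows(gm, 1e5, chrom_lengths = c(chr1 = 2e5))
  expect_equal(hw$value[hw$individual == "i1"], c(0, 0))
  expect_equal(hw$value[hw$individual == "i2" & hw$start == 0], 5e-4)
})
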