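test_that("gamma boundary cases follow the pattern algebra", {
  # pure pattern sites: a BBAA, b ABBA, c BABA (P1, H, P2 order)
  mkf <- function(bbaa, abba, baba) {
    rbind(matrix(rep(c(1, 1, 0), bbaa), ncol = 3, byrow = TRUE),
          matrix(rep(c(0, 1, 1), abba), ncol = 3, byrow = TRUE),
          matrix(rep(c(1, 0, 1), baba), ncol = 3, byrow = TRUE)) |>
      (\(m) { colnames(m) <- c("P1", "H", "P2"); m })()
  }
  # ABBA == BABA: H purely sister to P1 -> gamma 0
  g0 <- gamma_estimate(freqs_fixture(mkf(40, 10, 10)), "P1", "H", "P2",
                       block_size = 5e3, n_boot = 50, seed = 1)
  expect_equal(g0$gamma, 0)
  # BBAA == BABA: H purely sister to P2 -> gamma 1
  g1 <- gamma_estimate(freqs_fixture(mkf(10, 40, 10)), "P1", "H", "P2",
                       block_size = 5e3, n_boot = 50, seed = 1)
  expect_equal(g1$gamma, 1)
  # non-positive denominator -> no-hybridisation verdict with flag
  gu <- gamma_estimate(freqs_fixture(mkf(5, 5, 30)), "P1", "H", "P2")
  expect_equal(gu$flag, "undefined")
  expect_equal(gu$verdict, "no_hybridization")
})

test_that("swapping the parents maps gamma to 1 - gamma exactly", {
  set.seed(2)
  f <- cbind(P1 = runif(300), H = runif(300), P2 = runif(300))
  fr <- freqs_fixture(f)
  a <- gamma_estimate(fr, "P1", "H", "P2", n_boot = 10, seed = 3)
  b <- gamma_estimate(fr, "P2", "H", "P1", n_boot = 10, seed = 3)
  expect_equal(a$raw, 1 - b$raw, tolerance = 1e-12)
})

test_that("expected gamma is linear in the true mixing proportion", {
  # regression of gamma_hat on true gamma across a grid, equal parental
  # divergences; slope must sit in [0.9, 1.1]
  grid <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  reps <- 8
  est <- vapply(seq_along(grid), function(i) {
    mean(vapply(seq_len(reps), function(r) {
      s <- 1000 * i + 10 * r
      trees <- simulate_gene_trees(hyde_net(grid[i]), 1200, seed = s)
      gm <- simulate_genotypes(trees, 25, 0.05, seed = s + 1,
                               locus_bp = 1000)
      gamma_estimate(polarize(gm), "P1", "H", "P2", block_size = 5e4,
                     n_boot = 2, seed = s + 2)$raw
    }, 1))
  }, 1)
  slope <- coef(stats::lm(est ~ grid))[2]
  expect_gt(slope, 0.9); expect_lt(slope, 1.1)
})

test_that("the triplet scan tests every ordered triplet and calibrates", {
  trees <- simulate_gene_trees(
    species_network("((((A:0.6,B:0.6):0.4,C:1.0):0.5,D:1.5):4,O:5.5);",
                    outgroup = "O"), 800, seed = 7)
  gm <- simulate_genotypes(trees, 25, 0.05, seed = 8, locus_bp = 1000)
  sc <- scan_triplets(gm, outgroup = "O", block_size = 5e4, n_boot = 100,
                      seed = 9)
  expect_equal(nrow(sc), choose(4, 3) * 3)
  # parents are lexicographic, each 3-subset contributes 3 hybrids
  expect_true(all(sc$P1 < sc$P2))
  # no gene flow: nothing significant after Bonferroni
  expect_false(any(sc$significant))
})

test_that("individual-level estimates reduce to the population estimate", {
  trees <- simulate_gene_trees(hyde_net(0.55), 800, seed = 11,
                               samples = c(P1 = 2, H = 1, P2 = 2, O = 1))
  gm <- simulate_genotypes(trees, 25, 0.05, seed = 12, locus_bp = 1000)
  pops <- split(names(gm$pop), gm$pop)
  ind <- individual_level(gm, c("P1", "H", "P2"), outgroup = "O",
                          block_size = 5e4, n_boot = 20, seed = 13)
  expect_equal(nrow(ind), 1)     # single-individual hybrid population
  pop_est <- gamma_estimate(polarize(gm), "P1", "H", "P2",
                            block_size = 5e4, n_boot = 20, seed = 13)
  expect_equal(ind$raw, pop_est$raw)
})

test_that("the individual bootstrap has the right shape and degeneracies", {
  trees <- simulate_gene_trees(hyde_net(0.5), 600, seed = 21,
                               samples = c(P1 = 2, H = 4, P2 = 2, O = 1))
  gm <- simulate_genotypes(trees, 25, 0.05, seed = 22, locus_bp = 1000)
  bs <- bootstrap_individuals(gm, c("P1", "H", "P2"), n_reps = 500,
                              seed = 23, outgroup = "O")
  expect_length(bs$boot, 500)
  expect_false(bs$degenerate)
  expect_true(bs$ci[1] <= bs$mean && bs$mean <= bs$ci[2])
  # seed reproducibility
  bs2 <- bootstrap_individuals(gm, c("P1", "H", "P2"), n_reps = 500,
                               seed = 23, outgroup = "O")
  expect_identical(bs$boot, bs2$boot)
  # identical individuals -> zero-width distribution
  gm2 <- gm
  h_ind <- names(gm$pop)[gm$pop == "H"]
  for (i in h_ind[-1]) gm2$geno[, i] <- gm2$geno[, h_ind[1]]
  bs3 <- bootstrap_individuals(gm2, c("P1", "H", "P2"), n_reps = 50,
                               seed = 24, outgroup = "O")
  expect_equal(stats::var(bs3$boot), 0)
})
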