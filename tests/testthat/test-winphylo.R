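test_that("window tiling follows the stride and drops partial windows", {
  expect_equal(nrow(make_windows(c(chr1 = 1e6), 2e5)), 5)
  w <- make_windows(c(chr1 = 1.26e6), 2e4, 4e5)
  expect_equal(w$start, c(0, 420000, 840000))
  expect_equal(w$end - w$start, rep(20000, 3))
  expect_equal(nrow(make_windows(c(chr1 = 1.5e5), 2e5)), 0)
  # multi-chromosome, sorted, non-overlapping, within bounds
  w2 <- make_windows(c(chr2 = 5.5e5, chr1 = 3.2e5), 1e5, 5e4)
  for (ch in unique(w2$chrom)) {
    s <- w2[w2$chrom == ch, ]
    expect_true(all(diff(s$start) >= 1e5))
    expect_true(all(s$end <= c(chr2 = 5.5e5, chr1 = 3.2e5)[ch]))
  }
})

test_that("informative-site counting matches per-site brute force", {
  set.seed(5)
  n <- 20
  cons <- matrix(sample(c(0L, 1L, NA), n * 4, replace = TRUE,
                        prob = c(.45, .45, .1)), n, 4,
                 dimnames = list(NULL, paste0("sp", 1:4)))
  geno <- 2L * cons  # one haploid-style individual per species
  colnames(geno) <- paste0("sp", 1:4)
  gm <- genotype_matrix(
    data.frame(chrom = "chr1", pos = seq_len(n) - 1L, ref = "A", alt = "T"),
    geno, setNames(paste0("sp", 1:4), paste0("sp", 1:4)))
  win <- data.frame(chrom = "chr1", start = 0, end = n)
  brute <- sum(apply(cons, 1, function(r) {
    sum(r == 0, na.rm = TRUE) >= 2 && sum(r == 1, na.rm = TRUE) >= 2
  }))
  expect_equal(count_informative_sites(gm, win), brute)
  # all-invariant window
  gm0 <- genotype_matrix(gm$variants,
                         matrix(0L, n, 4, dimnames = dimnames(geno)), gm$pop)
  expect_equal(count_informative_sites(gm0, win), 0L)
})

test_that("window trees recover a well-separated topology deterministically", {
  net <- species_network("(((P1:1,P2:1):2,P3:3):4,O:7);", outgroup = "O")
  trees <- simulate_gene_trees(net, 1, seed = 41)
  gm <- simulate_genotypes(trees, 5000, 0.02, seed = 42, locus_bp = 5e4)
  win <- data.frame(chrom = "chr1", start = 0, end = 5e4)
  phy <- infer_window_tree(gm, win)
  expect_s3_class(phy, "phylo")
  expect_equal(canonical_topology(phy, "O"), "(((P1,P2),P3),O)")
  expect_equal(attr(phy, "units"), "subs_per_site")
  # permutation invariance to individual order
  gm_shuf <- subset_genotypes(gm, individuals = rev(colnames(gm$geno)))
  phy2 <- infer_window_tree(gm_shuf, win)
  expect_equal(canonical_topology(phy2, "O"), canonical_topology(phy, "O"))
})

test_that("the informative-site filter flags sparse windows", {
  net <- species_network("(((P1:1,P2:1):2,P3:3):4,O:7);", outgroup = "O")
  trees <- simulate_gene_trees(net, 1, seed = 43)
  gm <- simulate_genotypes(trees, 6, 0.001, seed = 44, locus_bp = 5e4)
  win <- data.frame(chrom = "chr1", start = 0, end = 5e4)
  out <- infer_window_tree(gm, win, min_informative = 10)
  expect_s3_class(out, "filtered_window")
  expect_lt(out$n_informative, 10)
})

test_that("identical sequences give a star-like tree with zero lengths", {
  n <- 30
  geno <- matrix(2L, n, 4, dimnames = list(NULL, paste0("sp", 1:4)))
  gm <- genotype_matrix(
    data.frame(chrom = "chr1", pos = seq_len(n) - 1L, ref = "A", alt = "T"),
    geno, setNames(paste0("sp", 1:4), paste0("sp", 1:4)))
  phy <- infer_window_tree(gm, data.frame(chrom = "chr1", start = 0, end = n),
                           outgroup = "sp4", min_informative = 0)
  expect_true(all(phy$edge.length == 0))
})

test_that("saturated distances are capped with a warning", {
  n <- 30
  geno <- matrix(rep(c(0L, 2L), each = n * 2), n, 4,
                 dimnames = list(NULL, paste0("sp", 1:4)))
  gm <- genotype_matrix(
    data.frame(chrom = "chr1", pos = seq_len(n) - 1L, ref = "A", alt = "T"),
    geno, setNames(paste0("sp", 1:4), paste0("sp", 1:4)))
  expect_warning(
    infer_window_tree(gm, data.frame(chrom = "chr1", start = 0, end = n),
                      outgroup = "sp4", min_informative = 1),
    "saturated")
})

test_that("topology tabulation ranks, normalises and rejects odd leaf sets", {
  t1 <- ape::read.tree(text = "(((A:1,B:1):1,C:2):1,O:3);")
  t2 <- ape::read.tree(text = "(((A:1,C:1):1,B:2):1,O:3);")
  tt <- tabulate_topologies(c(rep(list(t1), 6), rep(list(t2), 4)),
                            outgroup = "O")
  expect_equal(tt$freq, c(0.6, 0.4))
  expect_equal(tt$rank, 1:2)
  expect_equal(tt$topology[1], canonical_topology(t1, "O"))
  # single topology
  tt1 <- tabulate_topologies(rep(list(t1), 10), outgroup = "O")
  expect_equal(tt1$freq, 1)
  # differing leaf set rejected per-tree, not fatal
  t3 <- ape::read.tree(text = "(((A:1,B:1):1,D:2):1,O:3);")
  expect_message(tt2 <- tabulate_topologies(list(t1, t1, t3), outgroup = "O"),
                 "rejected")
  expect_equal(sum(tt2$count), 2)
})

test_that("simulated topology frequencies flow through tabulation", {
  n <- 4000
  trees <- simulate_gene_trees(triplet_net(tau = 0.5), n, seed = 51)
  tt <- tabulate_topologies(trees, outgroup = "O")
  conc <- tt$freq[tt$topology == "(((A,B),C),O)"]
  expect_lt(abs(conc - (1 - 2 / 3 * exp(-0.5))), 0.02)
})
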