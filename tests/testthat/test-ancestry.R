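test_that("dosage tracks are bounded, near-truth on diverged panels", {
  sim <- simulate_admixed_panel(Inf, 0.25, 10, 1e-7, seed = 61,
                                n_admixed = 3, n_sites = 1500)
  track <- infer_dosage(sim$genotypes, g = 10, recomb_rate = 1e-7)
  expect_true(all(track$dosage >= 0 & track$dosage <= 2))
  # pure source-1 individual: dosage approximately 0 everywhere
  gm <- sim$genotypes
  adm <- names(gm$pop)[gm$pop == "adm"]
  gm$geno[, adm[1]] <- gm$geno[, names(gm$pop)[gm$pop == "src1"][1]]
  t2 <- infer_dosage(gm, g = 10, recomb_rate = 1e-7)
  expect_lt(mean(t2$dosage[, adm[1]]), 0.05)
})

test_that("averaging runs with identical g equals a single run", {
  sim <- simulate_admixed_panel(2, 0.3, 8, 1e-7, seed = 62,
                                n_admixed = 2, n_sites = 800)
  one <- infer_dosage(sim$genotypes, g = 10, recomb_rate = 1e-7)
  three <- infer_dosage(sim$genotypes, g = c(10, 10, 10),
                        recomb_rate = 1e-7)
  expect_equal(one$dosage, three$dosage)
})

test_that("monomorphic panels are flagged uninformative", {
  geno <- matrix(0L, 10, 6,
                 dimnames = list(NULL, paste0("i", 1:6)))
  gm <- genotype_matrix(
    data.frame(chrom = "chr1", pos = 0:9, ref = "A", alt = "T"), geno,
    setNames(c("src1", "src1", "src2", "src2", "adm", "adm"),
             paste0("i", 1:6)))
  expect_warning(tr <- infer_dosage(gm, g = 5, recomb_rate = 1e-8),
                 "uninformative")
  expect_true(tr$uninformative)
})

test_that("site calling uses a strict threshold and is monotone", {
  track <- structure(list(
    dosage = matrix(c(1.6, 1.5, 0.2, 1.9), 4, 1,
                    dimnames = list(NULL, "adm_1")),
    chrom = rep("chr1", 4), pos = c(0, 10, 20, 30), runs = 10,
    uninformative = FALSE), class = "ancestry_track")
  s <- call_sites(track, 1.5)
  expect_equal(s$pos, c(0, 30))          # 1.5 itself is not a site
  expect_equal(nrow(call_sites(track, 1.95)), 0)
  # raising the threshold never adds sites
  for (thr in seq(0, 2, by = 0.25)) {
    lo <- call_sites(track, thr)
    hi <- call_sites(track, thr + 0.25)
    expect_true(all(hi$pos %in% lo$pos))
  }
  # empty track
  track$dosage <- track$dosage[0, , drop = FALSE]
  track$chrom <- character(0); track$pos <- numeric(0)
  expect_equal(nrow(call_sites(track)), 0)
})

test_that("tract selection takes the top fraction with degeneracy flag", {
  wins <- make_windows(c(chr1 = 1e7), 1e4)          # 1000 windows
  dosage <- matrix(0, 500, 1, dimnames = list(NULL, "adm_1"))
  dosage[1:40, 1] <- 2
  track <- structure(list(dosage = dosage, chrom = rep("chr1", 500),
                          pos = seq(0, by = 2.1e4, length.out = 500),
                          runs = 10, uninformative = FALSE),
                     class = "ancestry_track")
  sel <- call_tracts(track, wins, fraction = 0.01)
  expect_equal(nrow(sel), 10)
  expect_false(attr(sel, "degenerate"))
  # all-zero sums: still ceil(f n) windows, flagged degenerate
  track$dosage[] <- 0
  expect_warning(sel0 <- call_tracts(track, wins, fraction = 0.01),
                 "degenerate")
  expect_equal(nrow(sel0), 10)
  expect_equal(sel0$start, wins$start[1:10])
  expect_true(attr(sel0, "degenerate"))
})

test_that("candidate intersection is window-wise and grid-checked", {
  wins <- make_windows(c(chr1 = 1e6), 1e4)
  a <- wins[1:10, ]; attr(a, "all_windows") <- wins
  b <- wins[6:15, ]
  out <- intersect_candidates(a, b)
  expect_equal(out$start, wins$start[6:10])
  expect_equal(nrow(intersect_candidates(a, wins[90:95, ])), 0)
  expect_equal(intersect_candidates(a, a[, c("chrom", "start", "end")])$start,
               a$start)
  off_grid <- data.frame(chrom = "chr1", start = 5, end = 10005)
  expect_error(intersect_candidates(a, off_grid), "window grids")
})

test_that("partitioned trees detect the donor attachment of a hybrid clade", {
  net <- species_network(
    "((((H:0.5,P1:0.5):0.5,P2:1.0):0.5,X:1.5):4,O:5.5);", outgroup = "O",
    hybrid = list(recipient = "H", donor = "P2", time = 0.6, gamma = 0.3))
  trees <- simulate_gene_trees(net, 300, seed = 71)
  gm <- simulate_genotypes(trees, 60, 0.05, seed = 72, locus_bp = 1000)
  lw <- attr(gm, "locus_windows")
  donor_loci <- lw[attr(trees, "paths") == "donor", ]
  pt <- partition_trees(gm, donor_loci, outgroup = "O", focal = "H")
  expect_true(pt$different_attachment)
  expect_equal(attachment_partners(pt$introgressed, "H"), "P2")
  expect_equal(attachment_partners(pt$non_introgressed, "H"), "P1")
  # no-introgression partition: both trees identical in topology
  net0 <- species_network(
    "((((H:0.5,P1:0.5):0.5,P2:1.0):0.5,X:1.5):4,O:5.5);", outgroup = "O")
  trees0 <- simulate_gene_trees(net0, 300, seed = 73)
  gm0 <- simulate_genotypes(trees0, 60, 0.05, seed = 74, locus_bp = 1000)
  pt0 <- partition_trees(gm0, lw[1:150, ], outgroup = "O", focal = "H")
  expect_false(pt0$different_attachment)
  expect_equal(canonical_topology(pt0$introgressed),
               canonical_topology(pt0$non_introgressed))
  # partitions below the variant minimum are refused
  expect_error(partition_trees(gm, lw[1, ], outgroup = "O",
                               min_sites = 1e5), "partition")
})
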