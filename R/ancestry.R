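#' Local-ancestry dosage by a two-source hidden Markov model
#'
#' Infers, for each admixed individual, the expected number of haplotypes
#' (0-2) inherited from source population 2 at every site. Each haplotype is
#' modelled as a two-state Markov chain along the chromosome whose switch
#' probability between adjacent sites at distance `d` bp is
#' `1 - exp(-g * recomb_rate * d)` toward the stationary mix; the diploid
#' chain is the convolution of two independent haplotype chains (states
#' 0/1/2 source-2 copies). Emissions use panel allele frequencies with a
#' 0.5 pseudocount. The forward-backward posterior mean dosage is averaged
#' over `length(g)` runs that differ only in the generations-since-admixture
#' parameter, mirroring the practice of averaging several runs with
#' different mixture generation settings.
#'
#' @param gm A [genotype_matrix()] containing the admixed individuals and
#'   both source panels.
#' @param admixed,source1,source2 Population labels (or named lists via
#'   `pops`).
#' @param g Generations since admixture: a single value or one per run
#'   (default one run).
#' @param recomb_rate Recombination rate per bp per generation.
#' @param admix_prior Stationary source-2 haplotype proportion (default
#'   0.5; emissions dominate when panels are informative).
#' @param pops Optional named list group -> individuals.
#' @return Object of class `ancestry_track`: `dosage` (sites x admixed
#'   individuals posterior mean source-2 dosage), `chrom`, `pos`,
#'   `runs` (g values), `uninformative` flag (monomorphic panels at every
#'   site).
#' @export
infer_dosage <- function(gm, admixed = "adm", source1 = "src1",
                         source2 = "src2", g = 10, recomb_rate = 1e-8,
                         admix_prior = 0.5, pops = NULL) {
  stop_if_not(all(g > 0), "g must be > 0")
  if (is.null(pops)) pops <- split(names(gm$pop), gm$pop)
  stop_if_not(all(c(admixed, source1, source2) %in% names(pops)),
              "unknown population label")
  panel_freq <- function(pp) {
    sub <- gm$geno[, pops[[pp]], drop = FALSE]
    n <- 2 * rowSums(!is.na(sub))
    (rowSums(sub, na.rm = TRUE) + 0.5) / (n + 1)   # pseudocount
  }
  f1 <- panel_freq(source1)
  f2 <- panel_freq(source2)
  uninformative <- all(abs(f1 - f2) < 1e-12)
  if (uninformative)
    warning("source panels are monomorphic/identical at every site; ",
            "dosages are uninformative")
  n_sites <- nrow(gm$geno)
  inds <- pops[[admixed]]
  dosage <- matrix(0, n_sites, length(inds), dimnames = list(NULL, inds))
  d_bp <- c(0, diff(gm$variants$pos))
  d_bp[d_bp < 0] <- Inf                     # chromosome change: reset
  # emissions: P(genotype | a source-2 haplotypes) = Bin(a, f2) + Bin(2-a, f1)
  emis <- function(geno) {
    e <- matrix(1, n_sites, 3)
    ok <- !is.na(geno)
    pick <- function(p_by_k) {   # select P(g) per site from the 3 columns
      out <- rep(1, n_sites)
      out[ok] <- p_by_k[cbind(which(ok), geno[ok] + 1L)]
      out
    }
    e[, 1] <- pick(cbind((1 - f1)^2, 2 * f1 * (1 - f1), f1^2))
    e[, 2] <- pick(cbind((1 - f1) * (1 - f2),
                         f1 * (1 - f2) + f2 * (1 - f1), f1 * f2))
    e[, 3] <- pick(cbind((1 - f2)^2, 2 * f2 * (1 - f2), f2^2))
    e
  }
  # emissions for all admixed individuals: array [individual, state, site]
  E <- array(1, c(length(inds), 3, n_sites))
  for (i in seq_along(inds)) E[i, , ] <- t(emis(gm$geno[, inds[i]]))
  for (gi in seq_along(g)) {
    q <- 1 - exp(-g[gi] * recomb_rate * d_bp)   # per-hap switch prob
    q[!is.finite(q)] <- 1
    dosage <- dosage + fb_dosage(E, q, admix_prior) / length(g)
  }
  structure(list(dosage = dosage, chrom = gm$variants$chrom,
                 pos = gm$variants$pos, runs = g,
                 uninformative = uninformative),
            class = "ancestry_track")
}

#' @export
print.ancestry_track <- function(x, ...) {
  cat("Ancestry track:", nrow(x$dosage), "sites,", ncol(x$dosage),
      "individuals; mean source-2 dosage",
      format(mean(x$dosage), digits = 3), "\n")
  invisible(x)
}

# Forward-backward posterior mean dosage for the 3-state diploid chain
# built from two independent 2-state haplotype chains; runs all admixed
# individuals simultaneously. E is an [individual, state, site] array.
fb_dosage <- function(E, q, alpha) {
  n <- dim(E)[3]; I <- dim(E)[1]
  prior <- c((1 - alpha)^2, 2 * alpha * (1 - alpha), alpha^2)
  # diploid transition = convolution of two independent haplotype chains;
  # per-hap chain: stay, or redraw from the stationary mix with prob q
  dip_T <- function(qi) {
    h11 <- 1 - qi + qi * (1 - alpha); h12 <- qi * alpha
    h21 <- qi * (1 - alpha);          h22 <- 1 - qi + qi * alpha
    rbind(c(h11^2, 2 * h11 * h12, h12^2),
          c(h11 * h21, h11 * h22 + h12 * h21, h12 * h22),
          c(h21^2, 2 * h21 * h22, h22^2))
  }
  renorm <- function(m, fallback) {
    s <- rowSums(m)
    bad <- !is.finite(s) | s <= 0
    if (any(bad)) { m[bad, ] <- rep(fallback, each = sum(bad)); s[bad] <- sum(fallback) }
    m / s
  }
  fwd <- array(0, c(I, 3, n))
  f <- renorm(matrix(rep(prior, each = I) * E[, , 1], I), prior)
  fwd[, , 1] <- f
  for (t in 2:n) {
    Td <- dip_T(q[t])
    f <- renorm((f %*% Td) * matrix(E[, , t], I), prior)
    fwd[, , t] <- f
  }
  dosage <- matrix(0, n, I)
  b <- matrix(1, I, 3)
  post <- renorm(matrix(fwd[, , n], I) * b, prior)
  dosage[n, ] <- post %*% (0:2)
  for (t in (n - 1):1) {
    Td <- dip_T(q[t + 1])
    b <- renorm((matrix(E[, , t + 1], I) * b) %*% t(Td), rep(1 / 3, 3))
    post <- renorm(matrix(fwd[, , t], I) * b, prior)
    dosage[t, ] <- post %*% (0:2)
  }
  dosage
}

#' Call introgression sites from a dosage track
#'
#' Sites with a source-2 dosage strictly greater than `threshold` (default
#' 1.5) are called introgression sites; `source = 1` calls the complement
#' scale (source-1 dosage `2 - dosage`). Raising the threshold never adds
#' sites.
#'
#' @param track An [infer_dosage()] result.
#' @param threshold Dosage threshold (strict inequality; default 1.5).
#' @param source Which source ancestry to call (default 2).
#' @return `data.frame`: `individual`, `chrom`, `pos`, `dosage` for every
#'   called site.
#' @export
call_sites <- function(track, threshold = 1.5, source = 2) {
  d <- if (source == 2) track$dosage else 2 - track$dosage
  out <- lapply(colnames(d), function(ind) {
    idx <- which(d[, ind] > threshold)
    if (!length(idx)) return(NULL)
    data.frame(individual = ind, chrom = track$chrom[idx],
               pos = track$pos[idx], dosage = d[idx, ind],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out) %||%
    data.frame(individual = character(0), chrom = character(0),
               pos = numeric(0), dosage = numeric(0))
  rownames(out) <- NULL
  out
}

#' Call putative introgression tracts as top windows of dosage sums
#'
#' Sums the above-threshold dosages within tiled windows (pooled over
#' admixed individuals) and selects the top fraction of windows (default
#' top 1%) as putative introgression tracts. When every window sum is zero
#' the selection is degenerate and flagged.
#'
#' @param track An [infer_dosage()] result.
#' @param windows Tiled windows from [make_windows()] (10-kb standard).
#' @param fraction Fraction of windows to select (default 0.01).
#' @param threshold Site dosage threshold (default 1.5).
#' @return Selected windows (`window_stat` rows with `statistic =
#'   "dosage_sum"`), attributes `k`, `degenerate`, and `all_windows` (the
#'   full scored table).
#' @export
call_tracts <- function(track, windows, fraction = 0.01, threshold = 1.5) {
  sites <- call_sites(track, threshold)
  widx <- assign_windows(sites$chrom, sites$pos, windows)
  value <- window_sums(sites$dosage, widx, nrow(windows))
  stats <- data.frame(chrom = windows$chrom, start = windows$start,
                      end = windows$end, statistic = "dosage_sum",
                      value = value, stringsAsFactors = FALSE)
  class(stats) <- c("window_stat", "data.frame")
  sel <- top_fraction(stats, fraction)
  attr(sel, "degenerate") <- all(value == 0)
  if (all(value == 0))
    warning("all window dosage sums are zero; tract selection is degenerate")
  attr(sel, "all_windows") <- stats
  sel
}

#' Intersect tract calls with an Fd selection
#'
#' Window-wise intersection of the local-ancestry tract selection and the
#' top-Fd selection; both must come from the same window grid.
#'
#' @param tracts Selected windows from [call_tracts()].
#' @param fd_top Selected windows from [top_fraction()] on an Fd scan.
#' @return The common windows (possibly zero rows), in genomic order.
#' @export
intersect_candidates <- function(tracts, fd_top) {
  key <- function(x) paste(x$chrom, x$start, x$end)
  grid_a <- attr(tracts, "all_windows")
  if (!is.null(grid_a)) {
    stop_if_not(all(key(fd_top) %in% key(grid_a)),
                "selections come from different window grids")
  }
  out <- tracts[key(tracts) %in% key(fd_top),
                c("chrom", "start", "end"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Trees from introgressed versus non-introgressed regions
#'
#' Splits the variants into those inside and outside the candidate
#' introgression regions and infers a neighbour-joining tree from each
#' partition (consensus alleles, Jukes-Cantor distances over the included
#' sites). Reports whether the focal clade attaches differently in the two
#' trees.
#'
#' @param gm A [genotype_matrix()].
#' @param regions `data.frame` with `chrom`, `start`, `end` of candidate
#'   introgressed windows.
#' @param outgroup Population used for rooting (defaults to the matrix's).
#' @param focal Optional character vector of populations whose attachment
#'   is compared between the two trees.
#' @param min_sites Minimum variants required in each partition
#'   (default 25).
#' @param pops Optional grouping for consensus alleles.
#' @return List of class `partition_trees`: `introgressed`,
#'   `non_introgressed` (rooted `phylo`), `n_sites` (2-vector),
#'   `different_attachment` (logical or `NA` when no focal set given).
#' @export
partition_trees <- function(gm, regions, outgroup = gm$outgroup,
                            focal = NULL, min_sites = 25, pops = NULL) {
  stop_if_not(nrow(regions) >= 1, "no candidate regions supplied")
  inreg <- rep(FALSE, nrow(gm$geno))
  for (i in seq_len(nrow(regions))) {
    inreg <- inreg | (gm$variants$chrom == regions$chrom[i] &
                        gm$variants$pos >= regions$start[i] &
                        gm$variants$pos < regions$end[i])
  }
  n_in <- sum(inreg); n_out <- sum(!inreg)
  stop_if_not(n_in >= min_sites,
              sprintf("introgressed partition has %d < %d variants", n_in,
                      min_sites))
  stop_if_not(n_out >= min_sites,
              sprintf("non-introgressed partition has %d < %d variants",
                      n_out, min_sites))
  # JC denominators are the genomic extent of each partition, so distances
  # stay per base pair (variant-only proportions would saturate)
  total_bp <- sum(vapply(split(gm$variants$pos, gm$variants$chrom),
                         function(p) max(p) + 1, 1))
  in_bp <- sum(regions$end - regions$start)
  tree_of <- function(mask, denom_bp) {
    cons <- consensus_alleles(subset_genotypes(gm, which(mask)), pops)
    d <- jc_distance(cons, denom_bp)
    phy <- ape::nj(d)
    phy$edge.length[phy$edge.length < 0] <- 0
    ape::root(phy, outgroup = outgroup, resolve.root = TRUE)
  }
  t_in <- tree_of(inreg, in_bp)
  t_out <- tree_of(!inreg, max(total_bp - in_bp, n_out))
  diff_att <- NA
  if (!is.null(focal)) {
    diff_att <- !identical(attachment_partners(t_in, focal),
                           attachment_partners(t_out, focal))
  }
  structure(list(introgressed = t_in, non_introgressed = t_out,
                 n_sites = c(introgressed = n_in, non_introgressed = n_out),
                 focal = focal, different_attachment = diff_att),
            class = "partition_trees")
}

#' @export
print.partition_trees <- function(x, ...) {
  cat("Partitioned trees:", x$n_sites[1], "introgressed-region variants vs",
      x$n_sites[2], "non-introgressed\n")
  cat("  introgressed    :", canonical_topology(x$introgressed), "\n")
  cat("  non-introgressed:", canonical_topology(x$non_introgressed), "\n")
  if (!is.na(x$different_attachment))
    cat("  focal clade attaches differently:", x$different_attachment, "\n")
  invisible(x)
}

#' Attachment partners of a set of tips
#'
#' The taxa a (possibly non-monophyletic) group attaches to: the other tips
#' inside the smallest clade containing `tips` or, when the group is
#' monophyletic, its sister group. This is the natural way to ask "which
#' lineage does the focal clade group with" even when the focal tips do not
#' form a clade in the tree at hand.
#'
#' @param phy Rooted `phylo`.
#' @param tips Character vector of tip labels.
#' @return Sorted character vector of partner tips.
#' @export
attachment_partners <- function(phy, tips) {
  stop_if_not(all(tips %in% phy$tip.label), "unknown tips")
  if (length(tips) == 1) return(sister_clade(phy, tips))
  node <- ape::getMRCA(phy, tips)
  inside <- setdiff(phy$tip.label[node_tip_sets(phy)[[node]]], tips)
  if (length(inside)) sort(inside) else sister_clade(phy, tips)
}

#' Sister group of a clade
#'
#' Tip labels of the sister group of the smallest clade containing `tips`.
#'
#' @param phy Rooted `phylo`.
#' @param tips Character vector of tip labels.
#' @return Sorted character vector of sister-group tips.
#' @export
sister_clade <- function(phy, tips) {
  stop_if_not(all(tips %in% phy$tip.label), "unknown tips")
  ntip <- ape::Ntip(phy)
  node <- if (length(tips) == 1) which(phy$tip.label == tips)
  else ape::getMRCA(phy, tips)
  parent <- phy$edge[phy$edge[, 2] == node, 1]
  if (!length(parent)) return(character(0))   # clade is the whole tree
  sets <- node_tip_sets(phy)
  sibs <- setdiff(node_children(phy)[[parent]], node)
  sort(phy$tip.label[unlist(sets[sibs])])
}
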