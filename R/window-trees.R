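#' Infer a per-window gene tree by neighbour joining
#'
#' Builds per-population consensus sequences for the window, computes
#' Jukes-Cantor-corrected pairwise distances (treating all positions of the
#' window that carry no variant as identical, so distances are per base
#' pair), and runs neighbour joining, rooting the result on the outgroup.
#' Windows with fewer parsimony-informative sites than `min_informative` are
#' not inferred and come back flagged as filtered. The procedure is fully
#' deterministic and invariant to taxon input order up to topology.
#'
#' @param gm A [genotype_matrix()].
#' @param window One-row window (`chrom`, `start`, `end`).
#' @param outgroup Population used to root the tree (defaults to the
#'   matrix's outgroup).
#' @param min_informative Minimum parsimony-informative sites (default 10).
#' @param pops Optional grouping passed to [consensus_alleles()].
#' @return A rooted `phylo` with branch lengths in substitutions/site
#'   (attribute `units = "subs_per_site"`, attribute `window` the window),
#'   or an object of class `filtered_window` when the informative-site
#'   filter fails.
#' @export
infer_window_tree <- function(gm, window, outgroup = gm$outgroup,
                              min_informative = 10, pops = NULL) {
  stop_if_not(!is.na(outgroup), "an outgroup population is required")
  idx <- sites_in_window(gm, window)
  sub <- subset_genotypes(gm, idx)
  cons <- consensus_alleles(sub, pops)
  stop_if_not(ncol(cons) >= 4, "need at least 4 populations")
  n_inf <- sum(informative_mask(cons))
  if (n_inf < min_informative) {
    return(structure(list(window = window, n_informative = n_inf,
                          reason = "informative sites below minimum"),
                     class = "filtered_window"))
  }
  win_bp <- window$end - window$start
  d <- jc_distance(cons, win_bp)
  phy <- ape::nj(d)
  phy$edge.length[phy$edge.length < 0] <- 0
  phy <- ape::root(phy, outgroup = outgroup, resolve.root = TRUE)
  attr(phy, "units") <- "subs_per_site"
  attr(phy, "window") <- window
  attr(phy, "n_informative") <- n_inf
  phy
}

#' @export
print.filtered_window <- function(x, ...) {
  cat(sprintf("Filtered window %s:%d-%d (%d informative sites): %s\n",
              x$window$chrom, x$window$start, x$window$end,
              x$n_informative, x$reason))
  invisible(x)
}

# JC69 distance on consensus allele columns; `denom_bp` positions are
# compared of which the non-listed ones are identical by construction.
# Saturated proportions (>= 0.75) are capped just below the JC pole, with a
# warning.
jc_distance <- function(cons, denom_bp) {
  k <- ncol(cons)
  d <- matrix(0, k, k, dimnames = list(colnames(cons), colnames(cons)))
  capped <- FALSE
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    ok <- !is.na(cons[, i]) & !is.na(cons[, j])
    mm <- sum(cons[ok, i] != cons[ok, j])
    denom <- denom_bp - sum(!ok)
    p <- if (denom > 0) mm / denom else 0
    if (p >= 0.75) { p <- 0.7499; capped <- TRUE }
    d[i, j] <- d[j, i] <- -0.75 * log(1 - 4 * p / 3)
  }
  if (capped) warning("saturated distance(s) capped at the JC limit")
  stats::as.dist(d)
}

#' Tabulate gene-tree topologies
#'
#' Canonicalises every tree (rooted on the outgroup, branch lengths ignored,
#' children sorted) and tabulates topology frequencies. Trees whose leaf set
#' differs from the first tree's are rejected individually and excluded from
#' the frequency denominator.
#'
#' @param trees List of `phylo` trees (filtered windows are skipped).
#' @param outgroup Tip used for rooting before canonicalisation; defaults to
#'   the `outgroup` attribute of `trees`.
#' @return A `data.frame` of class `topology_table` with columns `topology`,
#'   `count`, `freq`, `rank`; rejected tree indices are in the attribute
#'   `rejected`.
#' @export
tabulate_topologies <- function(trees, outgroup = attr(trees, "outgroup")) {
  stop_if_not(!is.null(outgroup), "an outgroup label is required")
  keep <- !vapply(trees, inherits, logical(1), "filtered_window")
  trees <- trees[keep]
  stop_if_not(length(trees) > 0, "no trees to tabulate")
  ref <- sort(trees[[1]]$tip.label)
  rejected <- integer(0)
  labs <- character(length(trees))
  for (i in seq_along(trees)) {
    if (!identical(sort(trees[[i]]$tip.label), ref)) {
      rejected <- c(rejected, i)
      labs[i] <- NA_character_
      next
    }
    labs[i] <- canonical_topology(trees[[i]], outgroup = outgroup)
  }
  if (length(rejected))
    message(length(rejected), " tree(s) rejected: differing leaf sets")
  tb <- sort(table(labs[!is.na(labs)]), decreasing = TRUE)
  out <- data.frame(topology = names(tb), count = as.integer(tb),
                    freq = as.integer(tb) / sum(tb),
                    rank = seq_along(tb), stringsAsFactors = FALSE)
  attr(out, "rejected") <- rejected
  class(out) <- c("topology_table", "data.frame")
  out
}
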