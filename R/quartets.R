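#' Quartet support (q1, q2, q3) for every internal branch
#'
#' For each internal branch of the rooted species tree the four surrounding
#' clades are formed (the two child clades below the branch, the sibling
#' clade, and everything else). Every quartet with one leaf per clade is
#' classified, in every gene tree containing the four leaves, into the
#' species-tree arrangement (q1) or the two alternatives (q2, q3), by exact
#' enumeration. Proportions are normalised so q1 + q2 + q3 = 1 per branch.
#' Under the multispecies coalescent a branch of length tau in coalescent
#' units expects q2 = q3 = (1/3) exp(-tau).
#'
#' @param species_tree Rooted `phylo` (topology; lengths ignored).
#' @param gene_trees List of `phylo` gene trees (leaf sets may be subsets of
#'   the species tree's).
#' @param quartet_budget Maximum number of quartets enumerated per branch;
#'   above it a uniform random sample of quartets (seeded, reproducible) is
#'   scored instead (default 1e5, far above desk-scale needs).
#' @return `data.frame` of class `quartet_support`: `branch` (child node
#'   number), `clade` (tips below the branch), `q1`, `q2`, `q3`, `n`
#'   (quartet-tree observations). Branches adjacent to fewer than four
#'   non-empty clades are skipped.
#' @export
quartet_scores <- function(species_tree, gene_trees, quartet_budget = 1e5) {
  st <- species_tree
  ntip <- ape::Ntip(st)
  stop_if_not(ntip >= 4, "need at least 4 taxa")
  ch <- node_children(st)
  sets <- node_tip_sets(st)
  root <- ntip + 1L
  metrics <- lapply(gene_trees, pairwise_tree_metric)

  rows <- list()
  for (v in (ntip + 1L):(ntip + st$Nnode)) {
    if (v == root) next
    u <- st$edge[st$edge[, 2] == v, 1]
    kids <- ch[[v]]
    if (length(kids) != 2) next
    A1 <- st$tip.label[sets[[kids[1]]]]
    A2 <- st$tip.label[sets[[kids[2]]]]
    B1 <- st$tip.label[setdiff(sets[[u]], sets[[v]])]
    B2 <- setdiff(st$tip.label, st$tip.label[sets[[u]]])
    if (!length(B1) || !length(B2)) {
      message("branch above node ", v, " skipped: fewer than 4 adjacent clades")
      next
    }
    cnt <- count_branch_quartets(metrics, A1, A2, B1, B2, quartet_budget)
    tot <- sum(cnt)
    if (tot == 0) next
    rows[[length(rows) + 1L]] <- data.frame(
      branch = v,
      clade = paste(sort(c(A1, A2)), collapse = ","),
      q1 = cnt[1] / tot, q2 = cnt[2] / tot, q3 = cnt[3] / tot, n = tot,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows) %||%
    data.frame(branch = integer(0), clade = character(0), q1 = numeric(0),
               q2 = numeric(0), q3 = numeric(0), n = numeric(0))
  class(out) <- c("quartet_support", "data.frame")
  out
}

count_branch_quartets <- function(metrics, A1, A2, B1, B2,
                                  quartet_budget = Inf) {
  cnt <- c(0, 0, 0)
  for (m in metrics) {
    labs <- rownames(m)
    a1 <- intersect(A1, labs); a2 <- intersect(A2, labs)
    b1 <- intersect(B1, labs); b2 <- intersect(B2, labs)
    if (!length(a1) || !length(a2) || !length(b1) || !length(b2)) next
    n_q <- length(a1) * length(a2) * length(b1) * length(b2)
    if (n_q <= quartet_budget) {
      for (x in a1) for (y in a2) for (z in b1) for (w in b2) {
        arr <- quartet_arrangement(m, x, y, z, w)
        if (!is.na(arr)) cnt[arr] <- cnt[arr] + 1
      }
    } else {
      # reproducible uniform sample of quartets, rescaled to the full count
      smp <- with_seed(quartet_budget + n_q, {
        cbind(sample(a1, quartet_budget, TRUE),
              sample(a2, quartet_budget, TRUE),
              sample(b1, quartet_budget, TRUE),
              sample(b2, quartet_budget, TRUE))
      })
      sub <- c(0, 0, 0)
      for (r in seq_len(nrow(smp))) {
        arr <- quartet_arrangement(m, smp[r, 1], smp[r, 2], smp[r, 3],
                                   smp[r, 4])
        if (!is.na(arr)) sub[arr] <- sub[arr] + 1
      }
      cnt <- cnt + sub / sum(sub) * n_q
    }
  }
  cnt
}

node_tip_sets <- function(phy) {
  ntip <- ape::Ntip(phy)
  ch <- node_children(phy)
  below <- vector("list", ntip + phy$Nnode)
  fill <- function(node) {
    if (node <= ntip) { below[[node]] <<- node; return(invisible()) }
    for (k in ch[[node]]) fill(k)
    below[[node]] <<- unlist(below[ch[[node]]])
    invisible()
  }
  fill(ntip + 1L)
  below
}

# Tally of gene-tree arrangements for every 4-subset of `taxa`.
# Returns list(quartets = 4 x Q matrix of labels, counts = 3 x Q matrix).
quartet_count_table <- function(gene_trees, taxa) {
  quartets <- combn(sort(taxa), 4)
  counts <- matrix(0, 3, ncol(quartets))
  for (m in lapply(gene_trees, pairwise_tree_metric)) {
    labs <- rownames(m)
    for (q in seq_len(ncol(quartets))) {
      tq <- quartets[, q]
      if (!all(tq %in% labs)) next
      arr <- quartet_arrangement(m, tq[1], tq[2], tq[3], tq[4])
      if (!is.na(arr)) counts[arr, q] <- counts[arr, q] + 1
    }
  }
  list(quartets = quartets, counts = counts)
}

# Summed quartet concordance of one candidate unrooted topology.
score_topology <- function(cand, tab) {
  cand$edge.length <- rep(1, nrow(cand$edge))
  d <- ape::cophenetic.phylo(cand)
  s <- 0
  labs <- rownames(d)
  for (q in seq_len(ncol(tab$quartets))) {
    tq <- tab$quartets[, q]
    if (!all(tq %in% labs)) next   # partial trees during greedy insertion
    arr <- quartet_arrangement(d, tq[1], tq[2], tq[3], tq[4])
    if (!is.na(arr)) s <- s + tab$counts[arr, q]
  }
  s
}

#' Estimate the species tree by maximum quartet concordance
#'
#' Scores topologies by the total number of gene-tree quartets they agree
#' with (the criterion ASTRAL maximises). Up to 8 taxa the search is
#' exhaustive over all unrooted topologies; beyond that a greedy taxon-
#' insertion order with nearest-neighbour-interchange refinement is used.
#' Ties are broken lexicographically on the canonical topology string, so
#' the result is deterministic.
#'
#' @param gene_trees List of `phylo` gene trees (at least 3).
#' @param outgroup Optional tip to root the returned tree on.
#' @return A `phylo` species-tree estimate with attributes `score` (summed
#'   quartet concordance) and `quartet_support` (the [quartet_scores()]
#'   table, when the tree is rooted).
#' @export
infer_species_tree <- function(gene_trees, outgroup = attr(gene_trees, "outgroup")) {
  stop_if_not(length(gene_trees) >= 3, "need at least 3 gene trees")
  taxa <- sort(unique(unlist(lapply(gene_trees, function(t) t$tip.label))))
  stop_if_not(length(taxa) >= 4, "need at least 4 taxa")
  tab <- quartet_count_table(gene_trees, taxa)
  if (length(taxa) <= 8) {
    cands <- phangorn::allTrees(length(taxa), rooted = FALSE,
                                tip.label = taxa)
    best <- NULL; best_s <- -Inf; best_key <- ""
    for (i in seq_along(cands)) {
      cand <- cands[[i]]   # [[ restores compressed multiPhylo tip labels
      s <- score_topology(cand, tab)
      key <- canonical_topology(cand, outgroup = taxa[1])
      if (s > best_s || (s == best_s && key < best_key)) {
        best <- cand; best_s <- s; best_key <- key
      }
    }
  } else {
    res <- greedy_quartet_tree(taxa, tab)
    best <- res$tree; best_s <- res$score
  }
  if (!is.null(outgroup) && outgroup %in% taxa) {
    best <- ape::root(ape::unroot(best), outgroup = outgroup,
                      resolve.root = TRUE)
    attr(best, "quartet_support") <- quartet_scores(best, gene_trees)
  }
  attr(best, "score") <- best_s
  best
}

greedy_quartet_tree <- function(taxa, tab) {
  # seed with the best arrangement of the first four taxa, insert the rest
  # one by one on the best edge, then NNI to a local optimum
  first4 <- taxa[1:4]
  seeds <- phangorn::allTrees(4, rooted = FALSE, tip.label = first4)
  cur <- NULL; cur_s <- -Inf
  for (i in seq_along(seeds)) {
    s4 <- seeds[[i]]
    s <- score_topology(s4, tab)
    if (s > cur_s) { cur <- s4; cur_s <- s }
  }
  tip_tree <- function(tx) structure(
    list(edge = matrix(c(2L, 1L), 1, 2), tip.label = tx,
         edge.length = 1, Nnode = 1L, root.edge = 1), class = "phylo")
  for (tx in taxa[-(1:4)]) {
    best <- NULL; best_s <- -Inf
    cur$edge.length <- rep(1, nrow(cur$edge))
    for (e in seq_len(nrow(cur$edge))) {
      cand <- ape::bind.tree(cur, tip_tree(tx),
                             where = cur$edge[e, 2], position = 0.5)
      cand <- ape::collapse.singles(ape::unroot(cand))
      s <- score_topology(cand, tab)
      if (s > best_s) { best <- cand; best_s <- s }
    }
    cur <- best; cur_s <- best_s
  }
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    nbs <- phangorn::nni(cur)
    for (i in seq_along(nbs)) {
      nb <- nbs[[i]]   # [[ restores compressed multiPhylo tip labels
      s <- score_topology(nb, tab)
      if (s > cur_s) { cur <- nb; cur_s <- s; improved <- TRUE }
    }
  }
  list(tree = cur, score = cur_s)
}

#' Consensus splits of a set of gene trees
#'
#' Tabulates all non-trivial bipartitions of the common taxon set and keeps
#' those whose gene-tree frequency reaches `threshold`. Mutually
#' incompatible splits are all retained (consensus-network semantics), so
#' lowering the threshold never removes a split.
#'
#' @param gene_trees List of `phylo` trees on a common leaf set.
#' @param threshold Minimum split frequency in (0, 1].
#' @return `data.frame` of class `split_set`: `split` (comma-separated tips
#'   of the side not containing the reference taxon), `support`; attribute
#'   `threshold`.
#' @export
consensus_splits <- function(gene_trees, threshold) {
  stop_if_not(threshold > 0 && threshold <= 1, "threshold must be in (0, 1]")
  keep <- !vapply(gene_trees, inherits, logical(1), "filtered_window")
  gene_trees <- gene_trees[keep]
  taxa <- sort(gene_trees[[1]]$tip.label)
  ref <- taxa[1]
  tally <- new.env(parent = emptyenv())
  for (tr in gene_trees) {
    stop_if_not(identical(sort(tr$tip.label), taxa),
                "consensus_splits needs a common leaf set")
    sets <- node_tip_sets(tr)
    ntip <- ape::Ntip(tr)
    keys <- unique(unlist(lapply((ntip + 2L):(ntip + tr$Nnode), function(v) {
      side <- tr$tip.label[sets[[v]]]
      if (length(side) < 2 || length(side) > ntip - 2) return(NULL)
      if (ref %in% side) side <- setdiff(taxa, side)
      paste(sort(side), collapse = ",")
    })))
    for (k in keys) assign(k, (tally[[k]] %||% 0) + 1, envir = tally)
  }
  keys <- ls(tally)
  support <- vapply(keys, function(k) tally[[k]] / length(gene_trees), 1)
  keep <- support >= threshold
  out <- data.frame(split = keys[keep], support = unname(support[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$support, out$split), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  class(out) <- c("split_set", "data.frame")
  out
}
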