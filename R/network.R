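#' Species network for coalescent simulation
#'
#' A rooted species tree with branch lengths in coalescent units (one unit =
#' 2N generations of the reference population), per-branch relative effective
#' population sizes, and at most one hybrid edge. The hybrid edge gives a
#' recipient clade a second possible attachment point: at each locus the
#' recipient lineage follows the donor path with probability `gamma`
#' (hybrid-speciation semantics; the locus-level path choice is recorded on
#' every simulated gene tree). Removing the hybrid edge always leaves a tree.
#'
#' @param tree A rooted `phylo` object or Newick string. Branch lengths are
#'   coalescent units; the tree need not be ultrametric but all lengths must
#'   be non-negative.
#' @param outgroup Tip label of the outgroup; it must attach basally (be a
#'   child of the root).
#' @param pop_size Relative effective size of the branch *above* each node:
#'   either a single number used everywhere, or a named vector keyed by node
#'   label (tips, and internal nodes via their `node.label`). Unnamed
#'   branches default to 1.
#' @param root_pop Relative effective size above the root (the ancestral
#'   population in which the last lineages coalesce). Default 1.
#' @param hybrid Optional list describing one hybrid edge:
#'   `list(recipient =, donor =, time =, gamma =)`. `recipient` and `donor`
#'   are tip labels or character vectors of tips (the clade MRCA is used);
#'   `time` is the attachment age (coalescent units before present) on the
#'   donor branch; `gamma` in \[0, 1\] is the probability that a locus of the
#'   recipient follows the donor path.
#' @return An object of class `species_network`.
#' @examples
#' net <- species_network("(((A:1,B:1):1,C:2):4,O:6);", outgroup = "O")
#' net
#' @export
species_network <- function(tree, outgroup, pop_size = 1, root_pop = 1,
                            hybrid = NULL) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  stop_if_not(inherits(tree, "phylo"), "'tree' must be a phylo or Newick string")
  stop_if_not(!is.null(tree$edge.length), "species tree needs branch lengths")
  stop_if_not(all(tree$edge.length >= 0), "branch lengths must be >= 0")
  stop_if_not(ape::is.rooted(tree), "species tree must be rooted")
  stop_if_not(is.character(outgroup) && length(outgroup) == 1 &&
                outgroup %in% tree$tip.label, "invalid outgroup label")
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  og_edge <- tree$edge[tree$edge[, 2] == which(tree$tip.label == outgroup), 1]
  stop_if_not(og_edge == root, "outgroup must attach basal (child of the root)")

  tab <- build_node_table(tree, pop_size, root_pop)
  major <- tab
  minor <- NULL
  if (!is.null(hybrid)) {
    stop_if_not(is.list(hybrid) &&
                  all(c("recipient", "donor", "time", "gamma") %in% names(hybrid)),
                "hybrid must be list(recipient=, donor=, time=, gamma=)")
    g <- hybrid$gamma
    stop_if_not(is.numeric(g) && length(g) == 1 && g >= 0 && g <= 1,
                "gamma must be in [0, 1]")
    r <- clade_node(tab, hybrid$recipient)
    d <- clade_node(tab, hybrid$donor)
    minor <- attach_hybrid(tab, r, d, hybrid$time)
    hybrid$recipient_node <- r
    hybrid$donor_node <- d
  }
  structure(list(tree = tree, tab = major, minor_tab = minor,
                 hybrid = hybrid, outgroup = outgroup),
            class = "species_network")
}

# Flat node table used by the simulator: parent, age (time before present),
# pop (size of the branch above the node), children, label, tip flag.
build_node_table <- function(tree, pop_size, root_pop) {
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  depth <- ape::node.depth.edgelength(tree)
  age <- max(depth[seq_len(ntip)]) - depth
  parent <- rep(NA_integer_, nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  labels <- c(tree$tip.label,
              if (!is.null(tree$node.label)) tree$node.label
              else rep(NA_character_, tree$Nnode))
  labels[is.na(labels) | labels == ""] <-
    paste0(".n", which(is.na(labels) | labels == ""))
  pop <- rep(if (length(pop_size) == 1 && is.null(names(pop_size)))
    pop_size else 1, nnode)
  if (!is.null(names(pop_size))) {
    hit <- match(names(pop_size), labels)
    stop_if_not(!anyNA(hit), "pop_size names must match tip/node labels")
    pop[hit] <- unname(pop_size)
  }
  root <- ntip + 1L
  pop[root] <- root_pop
  stop_if_not(all(pop > 0), "population sizes must be > 0")
  list(parent = parent, age = age, pop = pop,
       children = node_children(tree), label = labels,
       tip = seq_len(nnode) <= ntip, root = root, ntip = ntip)
}

# Node number of the MRCA of a set of tip labels (a single label names the
# tip itself).
clade_node <- function(tab, tips) {
  idx <- match(tips, tab$label[seq_len(tab$ntip)])
  stop_if_not(!anyNA(idx), sprintf("unknown tip(s): %s",
                                   paste(tips[is.na(idx)], collapse = ", ")))
  if (length(idx) == 1) return(idx)
  anc <- function(i) {
    out <- i
    while (!is.na(tab$parent[i])) { i <- tab$parent[i]; out <- c(out, i) }
    out
  }
  common <- Reduce(intersect, lapply(idx, anc))
  common[1]
}

# SPR-style construction of the minor path: detach the recipient clade and
# hang it from a new unary-splitting anchor node on the donor branch at age
# t_h. Unary nodes left behind are kept (the simulator walks through them),
# which preserves per-segment population sizes exactly.
attach_hybrid <- function(tab, recipient, donor, t_h) {
  stop_if_not(recipient != donor, "recipient and donor must differ")
  stop_if_not(!is.na(tab$parent[donor]), "donor branch cannot be above the root")
  # recipient must not be an ancestor of the donor or vice versa
  i <- donor
  while (!is.na(tab$parent[i])) {
    i <- tab$parent[i]
    stop_if_not(i != recipient, "donor lies inside the recipient clade")
  }
  i <- recipient
  while (!is.na(tab$parent[i])) {
    i <- tab$parent[i]
    stop_if_not(i != donor, "recipient lies inside the donor clade")
  }
  pd <- tab$parent[donor]
  stop_if_not(t_h >= tab$age[donor] && t_h <= tab$age[pd],
              "hybrid time must lie on the donor branch")
  stop_if_not(t_h >= tab$age[recipient],
              "hybrid time predates the recipient clade")
  n <- length(tab$parent)
  anchor <- n + 1L
  tab$parent <- c(tab$parent, pd)
  tab$age <- c(tab$age, t_h)
  tab$pop <- c(tab$pop, tab$pop[donor])
  tab$children <- c(tab$children, list(c(donor, recipient)))
  tab$label <- c(tab$label, ".hyb_anchor")
  tab$tip <- c(tab$tip, FALSE)
  tab$children[[pd]] <- setdiff(tab$children[[pd]], donor)
  tab$children[[pd]] <- c(tab$children[[pd]], anchor)
  pr <- tab$parent[recipient]
  tab$children[[pr]] <- setdiff(tab$children[[pr]], recipient)
  tab$parent[donor] <- anchor
  tab$parent[recipient] <- anchor
  # sanity: structure must remain a tree (acyclic, single root)
  seen <- integer(0)
  for (j in seq_along(tab$parent)) {
    i <- j; steps <- 0
    while (!is.na(tab$parent[i])) {
      i <- tab$parent[i]; steps <- steps + 1
      stop_if_not(steps <= length(tab$parent),
                  "cycle detected after attaching the hybrid edge")
    }
    seen <- c(seen, i)
  }
  stop_if_not(length(unique(seen)) == 1, "hybrid attachment split the tree")
  tab
}

#' @export
print.species_network <- function(x, ...) {
  cat("Species network:", ape::Ntip(x$tree), "tips, outgroup", x$outgroup, "\n")
  cat("  topology:", canonical_topology(x$tree), "\n")
  if (is.null(x$hybrid)) {
    cat("  no hybrid edge\n")
  } else {
    cat(sprintf("  hybrid edge: recipient node %d <- donor node %d at age %.3g, gamma = %.3g\n",
                x$hybrid$recipient_node, x$hybrid$donor_node,
                x$hybrid$time, x$hybrid$gamma))
  }
  invisible(x)
}
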