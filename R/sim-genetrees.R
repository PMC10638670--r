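#' Simulate gene trees under the multispecies coalescent on a network
#'
#' Each locus evolves independently. If the network carries a hybrid edge,
#' the locus first chooses the donor path with probability `gamma` (and the
#' major, species-tree path otherwise); lineages then coalesce within each
#' branch of the chosen tree at the standard rate `choose(k, 2) / N` given
#' that branch's relative population size. Branch lengths of the returned
#' trees are in coalescent units (2N generations of the reference
#' population).
#'
#' @param network A [species_network()].
#' @param n_loci Number of independent loci (>= 1).
#' @param seed Optional integer seed; fixing it reproduces the trees exactly.
#' @param samples Optional named integer vector giving the number of sampled
#'   lineages per species (default one per species). With `k > 1` lineages
#'   the tips are labelled `species_1 ... species_k`.
#' @return A list of `phylo` gene trees (class `gene_tree_list`). Each tree
#'   carries attributes: `coal_times` (pairwise coalescence ages),
#'   `path` (`"major"` or `"donor"`), `locus`, and `units = "coalescent"`.
#'   The list itself carries `species_map` (tip -> species) and `outgroup`.
#' @examples
#' net <- species_network("(((A:1,B:1):1,C:2):4,O:6);", outgroup = "O")
#' trees <- simulate_gene_trees(net, 5, seed = 1)
#' trees[[1]]
#' @export
simulate_gene_trees <- function(network, n_loci, seed = NULL, samples = NULL) {
  stop_if_not(inherits(network, "species_network"), "need a species_network")
  stop_if_not(n_loci >= 1, "n_loci must be >= 1")
  tab <- network$tab
  species <- tab$label[seq_len(tab$ntip)]
  if (is.null(samples)) samples <- setNames(rep(1L, length(species)), species)
  stop_if_not(all(names(samples) %in% species), "unknown species in 'samples'")
  miss <- setdiff(species, names(samples))
  if (length(miss)) samples <- c(samples, setNames(rep(1L, length(miss)), miss))
  samples <- samples[species]

  tip_names <- unlist(lapply(species, function(s) {
    if (samples[[s]] == 1) s else paste0(s, "_", seq_len(samples[[s]]))
  }))
  species_map <- setNames(rep(species, samples), tip_names)
  gamma <- if (is.null(network$hybrid)) 0 else network$hybrid$gamma

  with_seed(seed, {
    paths <- if (gamma > 0) ifelse(runif(n_loci) < gamma, "donor", "major")
    else rep("major", n_loci)
    trees <- vector("list", n_loci)
    ord_major <- order(tab$age, !tab$tip)
    ord_minor <- if (!is.null(network$minor_tab))
      order(network$minor_tab$age, !network$minor_tab$tip)
    for (l in seq_len(n_loci)) {
      donor <- paths[l] == "donor"
      use_tab <- if (donor) network$minor_tab else tab
      trees[[l]] <- sim_one_gene_tree(use_tab, samples, tip_names, species_map,
                                      if (donor) ord_minor else ord_major)
      attr(trees[[l]], "path") <- paths[l]
      attr(trees[[l]], "locus") <- l
    }
    structure(trees, class = "gene_tree_list",
              species_map = species_map, outgroup = network$outgroup,
              paths = paths)
  })
}

#' @export
print.gene_tree_list <- function(x, ...) {
  paths <- attr(x, "paths")
  cat(length(x), "simulated gene trees,",
      length(attr(x, "species_map")), "lineages each;",
      sum(paths == "donor"), "donor-path loci\n")
  invisible(x)
}

# One coalescent genealogy on a node table. Lineage ids: 1..S are samples,
# S+1 .. 2S-1 are coalescences in chronological order.
sim_one_gene_tree <- function(tab, samples, tip_names, species_map,
                              ord = order(tab$age, !tab$tip)) {
  S <- length(tip_names)
  n_nodes <- length(tab$parent)
  # sample lineages start at their species tip
  pending <- vector("list", n_nodes)
  offs <- cumsum(c(0, unname(samples)))
  for (i in seq_len(tab$ntip)) {
    k <- samples[[tab$label[i]]]
    pending[[i]] <- seq.int(offs[i] + 1L, offs[i] + k)
  }
  lin_age <- numeric(2L * S - 1L)
  lin_age[seq_len(tab$ntip)] <- 0  # overwritten below for non-zero tip ages
  desc <- vector("list", 2L * S - 1L)
  for (i in seq_len(S)) desc[[i]] <- i
  ev_time <- numeric(S - 1L)
  ev_kids <- matrix(0L, S - 1L, 2)
  n_ev <- 0L
  coal <- matrix(0, S, S)
  next_id <- S + 1L

  for (i in seq_len(S)) lin_age[i] <- 0
  # tips may sit at positive ages in non-ultrametric species trees
  for (i in seq_len(tab$ntip)) lin_age[pending[[i]]] <- tab$age[i]

  run_edge <- function(lins, t0, t1, N) {
    k <- length(lins)
    while (k >= 2) {
      t0 <- t0 + rexp(1, rate = k * (k - 1) / 2 / N)
      if (t0 >= t1) break
      pair <- sample.int(k, 2L)
      a <- lins[pair[1]]; b <- lins[pair[2]]
      n_ev <<- n_ev + 1L
      ev_time[n_ev] <<- t0
      ev_kids[n_ev, ] <<- c(a, b)
      id <- next_id; next_id <<- next_id + 1L
      lin_age[id] <<- t0
      da <- desc[[a]]; db <- desc[[b]]
      coal[da, db] <<- t0
      coal[db, da] <<- t0
      desc[[id]] <<- c(da, db)
      lins <- c(lins[-pair], id)
      k <- k - 1L
    }
    lins
  }

  for (n in ord) {
    if (tab$tip[n]) next
    pool <- integer(0)
    for (ch in tab$children[[n]]) {
      pool <- c(pool, run_edge(pending[[ch]], tab$age[ch], tab$age[n],
                               tab$pop[ch]))
    }
    pending[[n]] <- pool
  }
  root_l <- run_edge(pending[[tab$root]], tab$age[tab$root], Inf,
                     tab$pop[tab$root])
  stop_if_not(length(root_l) == 1, "coalescent did not finish (internal error)")

  # assemble the phylo object; ape wants the root numbered S + 1
  ape_id <- function(id) if (id <= S) id else 2L * S - (id - S)
  edge <- matrix(0L, 2L * (S - 1L), 2)
  elen <- numeric(2L * (S - 1L))
  r <- 0L
  for (j in seq_len(S - 1L)) {
    m <- S + j
    for (kid in ev_kids[j, ]) {
      r <- r + 1L
      edge[r, ] <- c(ape_id(m), ape_id(kid))
      elen[r] <- ev_time[j] - lin_age[kid]
    }
  }
  phy <- structure(list(edge = edge, edge.length = elen,
                        tip.label = tip_names, Nnode = S - 1L),
                   class = "phylo")
  phy <- ape::reorder.phylo(phy, "cladewise")
  dimnames(coal) <- list(tip_names, tip_names)
  attr(phy, "coal_times") <- coal
  attr(phy, "units") <- "coalescent"
  attr(phy, "species_map") <- species_map
  phy
}
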