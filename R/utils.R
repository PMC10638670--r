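#' @importFrom stats rexp runif rbinom rpois median optimize pnorm quantile
#'   setNames sd coef dexp p.adjust complete.cases
#' @importFrom utils combn head read.table write.table modifyList
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `code` with `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded simulation calls do not perturb the global stream.
#' A `NULL` seed evaluates the code in the current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Counter-based fan-out of one user seed into independent per-stage seeds.
# Multiplicative hashing keeps results in [1, 2^31 - 2] (valid R seeds).
stage_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  x <- (as.double(seed) %% 2147483647) + 1
  for (k in seq_len(stage)) x <- (x * 48271) %% 2147483647
  as.integer(x)
}

# Polynomial rolling hash of a character scalar, reported as 8 hex digits;
# used to stamp output files with a configuration fingerprint.
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 216613626
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

stop_if_not <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

## ---- tree helpers ---------------------------------------------------------

# Children lists indexed by node number.
node_children <- function(phy) {
  n <- ape::Ntip(phy) + phy$Nnode
  ch <- vector("list", n)
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1]
    ch[[p]] <- c(ch[[p]], phy$edge[i, 2])
  }
  ch
}

#' Canonical topology string of a rooted tree
#'
#' Branch lengths are ignored; at every internal node the child subtrees are
#' sorted by their own canonical string, so two trees share a canonical string
#' exactly when their rooted topologies are identical. When `outgroup` is
#' given the tree is (re)rooted on it first, which makes the string a
#' canonical form of the unrooted topology.
#'
#' @param phy A `phylo` tree.
#' @param outgroup Optional tip label to root on before canonicalising.
#' @return A single Newick-like topology string.
#' @export
canonical_topology <- function(phy, outgroup = NULL) {
  if (!is.null(outgroup)) {
    stop_if_not(outgroup %in% phy$tip.label,
                sprintf("outgroup '%s' is not a tip of the tree", outgroup))
    phy <- ape::root(ape::unroot(phy), outgroup = outgroup,
                     resolve.root = TRUE)
  }
  ch <- node_children(phy)
  ntip <- ape::Ntip(phy)
  build <- function(node) {
    if (node <= ntip) return(phy$tip.label[node])
    parts <- sort(vapply(ch[[node]], build, character(1)))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  build(ntip + 1L)
}

# Pairwise tip "metric" used for topology queries: the recorded coalescence
# times for simulated trees, otherwise cophenetic path distances.
pairwise_tree_metric <- function(phy) {
  ct <- attr(phy, "coal_times")
  if (!is.null(ct)) return(ct)
  ape::cophenetic.phylo(phy)
}

# Quartet arrangement by the four-point condition on any additive tip metric.
# Returns 1 for ab|cd, 2 for ac|bd, 3 for ad|bc, NA for an exact tie
# (unresolved quartet).
quartet_arrangement <- function(d, a, b, c, e) {
  s <- c(d[a, b] + d[c, e], d[a, c] + d[b, e], d[a, e] + d[b, c])
  m <- min(s)
  w <- which(s == m)
  if (length(w) > 1L) return(NA_integer_)
  w
}

# Depths (distance from root) of pairwise MRCAs, as a tip x tip matrix.
# Sister structure of any triplet {x,y,z} follows: the pair with the largest
# pair-MRCA depth is the sister pair, and the triplet internal branch length
# is max(depth) - min(depth) over the three pairs.
pair_mrca_depth <- function(phy) {
  ct <- attr(phy, "coal_times")
  if (!is.null(ct)) {
    # coalescence times are ages; convert to depths by negation (only
    # differences and orderings are ever used)
    return(-ct)
  }
  depth <- ape::node.depth.edgelength(phy)
  m <- ape::mrca(phy)
  d <- matrix(depth[m], nrow = nrow(m), dimnames = dimnames(m))
  d
}
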