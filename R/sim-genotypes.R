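#' Biallelic genotype matrix
#'
#' Container for biallelic variants: a variant table (chromosome, 0-based
#' position, ref/alt codes), an integer matrix of alt-allele dosages (0/1/2,
#' `NA` for missing) with one column per individual, an individual-to-
#' population map, and a designated outgroup population.
#'
#' @param variants `data.frame` with columns `chrom`, `pos` (0-based), `ref`,
#'   `alt`; positions must be strictly increasing within each chromosome.
#' @param geno Integer matrix, `nrow(variants)` x individuals, entries in
#'   `{0, 1, 2, NA}`; column names are individual ids.
#' @param pop Named character vector mapping individual -> population.
#' @param outgroup Outgroup population label (or `NA` if none).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(variants, geno, pop, outgroup = NA_character_) {
  stop_if_not(is.data.frame(variants) &&
                all(c("chrom", "pos", "ref", "alt") %in% names(variants)),
              "variants needs columns chrom, pos, ref, alt")
  stop_if_not(is.matrix(geno) && nrow(geno) == nrow(variants),
              "geno must be a matrix with one row per variant")
  stop_if_not(!is.null(colnames(geno)), "geno needs individual column names")
  stop_if_not(all(geno %in% c(0L, 1L, 2L, NA)), "dosages must be 0/1/2/NA")
  stop_if_not(all(colnames(geno) %in% names(pop)),
              "every individual needs a population")
  pop <- pop[colnames(geno)]
  for (ch in unique(variants$chrom)) {
    p <- variants$pos[variants$chrom == ch]
    stop_if_not(!is.unsorted(p, strictly = TRUE),
                sprintf("positions not strictly increasing on %s", ch))
  }
  if (!is.na(outgroup))
    stop_if_not(outgroup %in% pop, "outgroup population has no individuals")
  stop_if_not(all(table(pop) >= 1), "every population must be non-empty")
  structure(list(variants = variants, geno = geno, pop = pop,
                 outgroup = outgroup),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("Genotype matrix:", nrow(x$geno), "biallelic variants,",
      ncol(x$geno), "individuals,", length(unique(x$pop)), "populations\n")
  if (!is.na(x$outgroup)) cat("  outgroup population:", x$outgroup, "\n")
  invisible(x)
}

#' Drop mutations on simulated gene trees (infinite-sites model)
#'
#' Each locus contributes `sites_per_locus` candidate positions laid out on a
#' synthetic coordinate system (`locus_bp` base pairs per locus, optional
#' inter-locus gaps, so downstream window machinery is exercised). A
#' candidate site becomes a variant with probability
#' `1 - exp(-mut_rate * L)` where `L` is the total branch length of the
#' locus tree; the single mutation is then placed on a branch with
#' probability proportional to its length and all tips below carry the
#' derived allele. There is no back-mutation, so polarisation against the
#' outgroup-rooted ancestral state is exact.
#'
#' @param trees Gene trees from [simulate_gene_trees()].
#' @param sites_per_locus Candidate sites per locus.
#' @param mut_rate Mutations per site per coalescent unit (>= 0).
#' @param seed Optional seed.
#' @param locus_bp Synthetic length of each locus in bp
#'   (default `10 * sites_per_locus`).
#' @param gap_bp Gap between consecutive loci (default 0).
#' @param chrom Chromosome name for the synthetic coordinates.
#' @param diploid If `TRUE`, consecutive pairs of lineages of a species are
#'   combined into diploid individuals (every species then needs an even
#'   number of sampled lineages); otherwise each lineage is reported as a
#'   doubled-haploid individual with dosages 0/2.
#' @return A [genotype_matrix()]; the attribute `locus_windows` maps loci to
#'   their coordinate ranges and `locus_of_site` gives each variant's locus.
#' @export
simulate_genotypes <- function(trees, sites_per_locus, mut_rate, seed = NULL,
                               locus_bp = 10L * sites_per_locus, gap_bp = 0L,
                               chrom = "chr1", diploid = FALSE) {
  stop_if_not(mut_rate >= 0, "mut_rate must be >= 0")
  stop_if_not(locus_bp >= sites_per_locus,
              "locus_bp must be >= sites_per_locus")
  species_map <- attr(trees, "species_map")
  outgroup_sp <- attr(trees, "outgroup")
  haps <- names(species_map)
  if (diploid) {
    per_sp <- split(haps, species_map[haps])[unique(species_map)]
    bad <- names(per_sp)[vapply(per_sp, length, 1L) %% 2 != 0]
    stop_if_not(length(bad) == 0,
                paste("diploid pairing needs an even number of lineages for:",
                      paste(bad, collapse = ", ")))
    ind_of_hap <- unlist(unname(lapply(per_sp, function(h) {
      k <- length(h) / 2
      ids <- if (k == 1) unique(species_map[h]) else
        paste0(unique(species_map[h]), "_", seq_len(k))
      setNames(rep(ids, each = 2), h)
    })))
    ind_of_hap <- ind_of_hap[haps]
  } else {
    ind_of_hap <- setNames(haps, haps)
  }
  inds <- unique(unname(ind_of_hap))
  pop <- setNames(species_map[haps][match(inds, unname(ind_of_hap))], inds)

  stride <- locus_bp + gap_bp
  n_loci <- length(trees)
  res_pos <- vector("list", n_loci)
  res_geno <- vector("list", n_loci)
  res_locus <- vector("list", n_loci)

  with_seed(seed, {
    for (l in seq_len(n_loci)) {
      phy <- trees[[l]]
      L <- sum(phy$edge.length)
      if (L <= 0 || mut_rate == 0) next
      p_var <- 1 - exp(-mut_rate * L)
      n_var <- rbinom(1, sites_per_locus, p_var)
      if (n_var == 0) next
      pos <- sort(sample.int(locus_bp, n_var)) - 1L + (l - 1L) * stride
      sets <- edge_tip_sets(phy)
      br <- sample.int(nrow(phy$edge), n_var, replace = TRUE,
                       prob = phy$edge.length)
      ind_idx <- match(ind_of_hap[phy$tip.label], inds)  # tip -> column
      g <- matrix(0L, n_var, length(inds), dimnames = list(NULL, inds))
      for (v in seq_len(n_var)) {
        cols <- ind_idx[sets[[br[v]]]]
        if (diploid) {
          g[v, ] <- tabulate(cols, nbins = length(inds))
        } else {
          g[v, cols] <- 2L
        }
      }
      res_pos[[l]] <- pos
      res_geno[[l]] <- g
      res_locus[[l]] <- rep(l, n_var)
    }
  })

  pos <- unlist(res_pos) %||% integer(0)
  geno <- do.call(rbind, res_geno)
  if (is.null(geno)) geno <- matrix(integer(0), 0, length(inds),
                                    dimnames = list(NULL, inds))
  variants <- data.frame(chrom = rep(chrom, length(pos)), pos = pos,
                         ref = rep("A", length(pos)),
                         alt = rep("T", length(pos)),
                         stringsAsFactors = FALSE)
  gm <- genotype_matrix(variants, geno, pop, outgroup = outgroup_sp)
  attr(gm, "locus_windows") <- data.frame(
    chrom = chrom, start = (seq_len(n_loci) - 1L) * stride,
    end = (seq_len(n_loci) - 1L) * stride + locus_bp)
  attr(gm, "locus_of_site") <- unlist(res_locus) %||% integer(0)
  gm
}

# Tip index sets below each edge, aligned with the rows of phy$edge.
edge_tip_sets <- function(phy) {
  ntip <- ape::Ntip(phy)
  ch <- node_children(phy)
  below <- vector("list", ntip + phy$Nnode)
  fill <- function(node) {
    if (node <= ntip) { below[[node]] <<- node; return(invisible()) }
    kids <- ch[[node]]
    for (k in kids) fill(k)
    below[[node]] <<- unlist(below[kids])
    invisible()
  }
  fill(ntip + 1L)
  lapply(phy$edge[, 2], function(n) below[[n]])
}

#' Subset a genotype matrix
#'
#' @param gm A [genotype_matrix()].
#' @param sites Logical or integer index over variant rows.
#' @param individuals Optional character vector of individuals to keep.
#' @return A [genotype_matrix()].
#' @export
subset_genotypes <- function(gm, sites = NULL, individuals = NULL) {
  stop_if_not(inherits(gm, "genotype_matrix"), "need a genotype_matrix")
  if (is.null(sites)) sites <- seq_len(nrow(gm$geno))
  keep_ind <- individuals %||% colnames(gm$geno)
  og <- gm$outgroup
  if (!is.na(og) && !og %in% gm$pop[keep_ind]) og <- NA_character_
  genotype_matrix(gm$variants[sites, , drop = FALSE],
                  gm$geno[sites, keep_ind, drop = FALSE],
                  gm$pop[keep_ind], og)
}
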