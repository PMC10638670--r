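#' Simulate two source panels and admixed mosaic individuals
#'
#' Generates biallelic genotypes for two diverged source populations and a
#' set of admixed diploids whose chromosomes are ancestry mosaics. Tract
#' lengths along each admixed haplotype are exponential with mean
#' `1 / (n_generations * recomb_rate)` base pairs and each tract draws its
#' source independently with probability `admix_fraction` for source 2
#' (the classic pulse-admixture approximation). The true tracts are returned
#' for recall/precision scoring of downstream local-ancestry calls.
#'
#' Source allele frequencies follow a Balding-Nichols model at divergence
#' `F = 1 - exp(-source_divergence)`; `source_divergence = Inf` gives fixed
#' differences (source 1 ancestral, source 2 derived at every site).
#'
#' @param source_divergence Divergence between the sources in coalescent
#'   units (`Inf` for fully fixed differences).
#' @param admix_fraction Genome-wide source-2 proportion, strictly in (0, 1).
#' @param n_generations Generations since admixture (> 0).
#' @param recomb_rate Recombination rate per bp per generation.
#' @param seed Optional seed.
#' @param n_source Diploid individuals per source panel.
#' @param n_admixed Admixed diploid individuals.
#' @param n_sites Number of biallelic sites.
#' @param chrom_bp Chromosome length in bp.
#' @return A list with `genotypes` (a [genotype_matrix()] with populations
#'   `src1`, `src2`, `adm`), `tracts` (true ancestry tracts per admixed
#'   haplotype: individual, hap, chrom, start, end, source), and
#'   `true_dosage` (sites x admixed-individuals matrix of true source-2
#'   dosages).
#' @export
simulate_admixed_panel <- function(source_divergence, admix_fraction,
                                   n_generations, recomb_rate, seed = NULL,
                                   n_source = 8, n_admixed = 6,
                                   n_sites = 4000, chrom_bp = 5e6) {
  stop_if_not(admix_fraction > 0 && admix_fraction < 1,
              "admix_fraction must be strictly inside (0, 1)")
  stop_if_not(n_generations > 0, "n_generations must be > 0")
  stop_if_not(recomb_rate >= 0, "recomb_rate must be >= 0")
  with_seed(seed, {
    pos <- sort(sample.int(chrom_bp, n_sites)) - 1L
    if (is.infinite(source_divergence)) {
      p1 <- rep(0, n_sites); p2 <- rep(1, n_sites)
    } else {
      Fst <- 1 - exp(-source_divergence)
      pa <- runif(n_sites, 0.05, 0.95)
      if (Fst <= 0) { p1 <- p2 <- pa } else {
        a <- pa * (1 - Fst) / Fst
        b <- (1 - pa) * (1 - Fst) / Fst
        p1 <- stats::rbeta(n_sites, a, b)
        p2 <- stats::rbeta(n_sites, a, b)
      }
    }
    draw_panel <- function(p, n, prefix) {
      g <- matrix(rbinom(n_sites * n, 2, rep(p, n)), n_sites, n)
      colnames(g) <- paste0(prefix, "_", seq_len(n))
      g
    }
    g1 <- draw_panel(p1, n_source, "src1")
    g2 <- draw_panel(p2, n_source, "src2")

    rate <- n_generations * recomb_rate           # breakpoints per bp
    tracts <- list(); k <- 0
    gadm <- matrix(0L, n_sites, n_admixed,
                   dimnames = list(NULL, paste0("adm_", seq_len(n_admixed))))
    true_dose <- matrix(0L, n_sites, n_admixed,
                        dimnames = list(NULL, colnames(gadm)))
    for (i in seq_len(n_admixed)) {
      for (h in 1:2) {
        bk <- 0
        while (TRUE) {
          nxt <- if (rate > 0) bk[length(bk)] + rexp(1, rate) else Inf
          if (nxt >= chrom_bp) break
          bk <- c(bk, nxt)
        }
        starts <- floor(bk); ends <- c(floor(bk[-1]), chrom_bp)
        src <- 1L + (runif(length(starts)) < admix_fraction)
        # merge runs of equal source so tract lengths are well defined
        keep <- c(TRUE, src[-1] != src[-length(src)])
        starts <- starts[keep]; src <- src[keep]
        ends <- c(starts[-1], chrom_bp)
        k <- k + 1
        tracts[[k]] <- data.frame(individual = colnames(gadm)[i], hap = h,
                                  chrom = "chr1", start = starts, end = ends,
                                  source = src)
        src_of_site <- src[findInterval(pos, starts)]
        p_hap <- ifelse(src_of_site == 2L, p2, p1)
        hap <- rbinom(n_sites, 1, p_hap)
        gadm[, i] <- gadm[, i] + hap
        true_dose[, i] <- true_dose[, i] + (src_of_site == 2L)
      }
    }
    geno <- cbind(g1, g2, gadm)
    storage.mode(geno) <- "integer"
    pop <- setNames(c(rep("src1", n_source), rep("src2", n_source),
                      rep("adm", n_admixed)), colnames(geno))
    variants <- data.frame(chrom = "chr1", pos = pos, ref = "A", alt = "T",
                           stringsAsFactors = FALSE)
    list(genotypes = genotype_matrix(variants, geno, pop),
         tracts = do.call(rbind, tracts),
         true_dosage = true_dose)
  })
}
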