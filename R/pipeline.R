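#' Pipeline configuration
#'
#' Assembles the configuration for [run_pipeline()] with every analysis
#' threshold at its standard value: 200-kb gene-fragment windows, the
#' 20-kb/400-kb-gap window scheme for the branch-length mixture stage,
#' 10-kb Fd windows, 100-kb heterozygosity windows, an informative-site
#' minimum of 10, the +/-10 delta-BIC band, a 30% consensus-network
#' threshold, a top-5% Fd tail, a top-1% tract tail, the 1.5 dosage
#' threshold, and 500 individual-bootstrap replicates. The default
#' simulation emulates a radiation with three rapidly splitting in-group
#' clades, a basal in-group lineage, an outgroup, and one ancestral hybrid
#' node (recipient clade `fm`, major parent `as`, donor `sn`) with
#' inheritance probability `gamma`. Every entry can be overridden via
#' `...` (nested lists are merged).
#'
#' @param seed Global seed fanned out to per-stage seeds.
#' @param gamma Inheritance probability of the simulated hybrid edge
#'   (0 disables the hybrid edge entirely).
#' @param ... Named overrides of `sim`, `windows`, `thresholds`, `clades`,
#'   `ancestry` sub-lists.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, gamma = 0.5, ...) {
  cfg <- list(
    seed = seed,
    sim = list(
      newick = paste0("(((((fm1:0.5,fm2:0.5):0.5,(as1:0.5,as2:0.5):0.5)",
                      ":0.2,(sn1:0.5,sn2:0.5):0.7):1.8,syl:3.0):3.0,",
                      "Out:6.0);"),
      outgroup = "Out",
      gamma = gamma,
      hybrid_recipient = c("fm1", "fm2"),
      hybrid_donor = c("sn1", "sn2"),
      hybrid_time = 1.0,
      n_loci = 600,
      sites_per_locus = 875,
      mut_rate = 0.02,
      locus_bp = 7e4,
      gap_bp = 0,
      lineages_per_species = 4,   # two diploid individuals per species
      outgroup_lineages = 2),
    # one gene-fragment window per 70-kb locus; the mixture-stage scheme
    # keeps the 20-kb window and strides one window per locus, so both
    # schemes sample independent genealogies at this genome scale
    windows = list(gf = 7e4, quibl_size = 2e4, quibl_gap = 5e4, fd = 1e4,
                   het = 1e5),
    # resampling blocks equal the simulated recombination unit (one locus),
    # the smallest size that respects the correlation structure while
    # maximising the number of independent blocks at this genome size
    thresholds = list(min_informative = 10, delta_bic = 10, consensus = 0.30,
                      fd_top = 0.05, tract_top = 0.01, dosage = 1.5,
                      boot_reps = 500, alpha = 0.05, block_size = 7e4,
                      quibl_min_n = 30, n_boot_gamma = 200),
    clades = list(fm = c("fm1", "fm2"), as = c("as1", "as2"),
                  sn = c("sn1", "sn2"), syl = "syl"),
    ancestry = list(admixed = "fm", source1 = "as", source2 = "sn",
                    g = c(8, 10, 12), recomb_rate = 2e-7),
    fd_trio = c("as1", "fm1", "sn1"))
  dots <- list(...)
  for (nm in names(dots)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(dots[[nm]]))
      modifyList(cfg[[nm]], dots[[nm]]) else dots[[nm]]
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Pipeline configuration (seed", x$seed, "):\n")
  cat("  simulation:", x$sim$n_loci, "loci x", x$sim$locus_bp, "bp, gamma =",
      x$sim$gamma, "\n")
  cat("  config hash:", config_hash(x), "\n")
  invisible(x)
}

config_hash <- function(config) {
  fnv1a_hash(paste(deparse(unclass(config)), collapse = ""))
}

#' Run the full discordance-attribution pipeline on synthetic data
#'
#' Executes, in order: coalescent simulation on the configured species
#' network; genotype simulation; per-window gene-tree inference (gene
#' fragments, plus the gapped scheme for the mixture stage); topology
#' tabulation; quartet-support species-tree estimation and consensus
#' splits; D statistics over all species trios with f-branch assignment;
#' the gamma scan over clades with individual-level estimates and
#' individual bootstrap; the triplet branch-length mixture classification;
#' the windowed Fd scan with top-5% selection; local-ancestry dosage with
#' introgression-site and top-1% tract calling and intersection with the
#' Fd tail; partitioned tree re-estimation from introgressed versus
#' non-introgressed regions; and FST / heterozygosity summaries. A stage
#' failure halts the run naming the stage, with completed stages preserved
#' in the error condition.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage progress messages?
#' @return Object of class `pipeline_report`; see the package vignette for
#'   the meaning of every component.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  stop_if_not(inherits(config, "pipeline_config"), "need a pipeline_config")
  report <- list(config = config)
  t_all <- Sys.time()
  note <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    t0 <- Sys.time()
    val <- tryCatch(expr, error = function(e) {
      cond <- simpleError(sprintf("pipeline stage '%s' failed: %s", name,
                                  conditionMessage(e)))
      cond$partial_report <- report
      stop(cond)
    })
    note("stage %-16s %6.1f s", name,
         as.numeric(Sys.time() - t0, units = "secs"))
    val
  }
  sd <- function(k) stage_seed(config$seed, k)
  thr <- config$thresholds

  ## simulate -----------------------------------------------------------
  sim <- config$sim
  net <- stage("network", {
    hyb <- if (sim$gamma > 0)
      list(recipient = sim$hybrid_recipient, donor = sim$hybrid_donor,
           time = sim$hybrid_time, gamma = sim$gamma)
    species_network(sim$newick, outgroup = sim$outgroup, hybrid = hyb)
  })
  report$network <- net
  trees <- stage("gene_trees", {
    sp <- ape::read.tree(text = sim$newick)$tip.label
    smp <- setNames(rep(sim$lineages_per_species, length(sp)), sp)
    smp[sim$outgroup] <- sim$outgroup_lineages
    simulate_gene_trees(net, sim$n_loci, seed = sd(1), samples = smp)
  })
  report$paths <- attr(trees, "paths")
  gm <- stage("genotypes", simulate_genotypes(
    trees, sim$sites_per_locus, sim$mut_rate, seed = sd(2),
    locus_bp = sim$locus_bp, gap_bp = sim$gap_bp, diploid = TRUE))
  report$genotypes <- gm
  genome_bp <- sim$n_loci * (sim$locus_bp + sim$gap_bp)
  chrom_lengths <- c(chr1 = genome_bp)

  ## window trees -------------------------------------------------------
  species_pops <- split(names(gm$pop), gm$pop)
  gf_windows <- make_windows(chrom_lengths, config$windows$gf)
  gf_trees <- stage("window_trees", lapply(seq_len(nrow(gf_windows)),
    function(i) infer_window_tree(gm, gf_windows[i, ],
                                  outgroup = sim$outgroup,
                                  min_informative = thr$min_informative)))
  report$n_gf_windows <- nrow(gf_windows)
  report$n_gf_trees <- sum(!vapply(gf_trees, inherits, TRUE,
                                   "filtered_window"))
  qb_windows <- make_windows(chrom_lengths, config$windows$quibl_size,
                             config$windows$quibl_gap)
  qb_trees <- stage("quibl_trees", lapply(seq_len(nrow(qb_windows)),
    function(i) infer_window_tree(gm, qb_windows[i, ],
                                  outgroup = sim$outgroup,
                                  min_informative = thr$min_informative)))
  report$n_quibl_trees <- sum(!vapply(qb_trees, inherits, TRUE,
                                      "filtered_window"))

  ## species tree, topologies, splits -----------------------------------
  report$topologies <- stage("topologies",
                             tabulate_topologies(gf_trees,
                                                 outgroup = sim$outgroup))
  sp_tree <- stage("species_tree", {
    keep <- !vapply(gf_trees, inherits, TRUE, "filtered_window")
    infer_species_tree(gf_trees[keep], outgroup = sim$outgroup)
  })
  report$species_tree <- sp_tree
  report$splits <- stage("consensus_splits", {
    keep <- !vapply(gf_trees, inherits, TRUE, "filtered_window")
    consensus_splits(gf_trees[keep], thr$consensus)
  })

  ## D statistics and f-branch ------------------------------------------
  freqs_sp <- polarize(gm, outgroup = sim$outgroup)
  report$dstats <- stage("dstats", {
    trios <- enumerate_trios(sp_tree,
                             setdiff(sp_tree$tip.label, sim$outgroup))
    do.call(rbind, lapply(seq_len(nrow(trios)), function(i) {
      d <- patterson_d(freqs_sp, trios$M1[i], trios$M2[i], trios$M3[i],
                       block_size = thr$block_size)
      data.frame(P1 = trios$M1[i], P2 = trios$M2[i], P3 = trios$M3[i],
                 D = d$D, Z = d$Z, n_blocks = d$n_blocks, flag = d$flag,
                 stringsAsFactors = FALSE)
    }))
  })
  report$fbranch <- stage("fbranch", {
    f4 <- f4_all(freqs_sp)
    f_branch(sp_tree, f4, outgroup = sim$outgroup)
  })

  ## gamma scan ----------------------------------------------------------
  clade_units <- lapply(config$clades, function(spp)
    unlist(species_pops[spp], use.names = FALSE))
  report$gamma_scan <- stage("gamma_scan", scan_triplets(
    gm, units = clade_units, outgroup = sim$outgroup, alpha = thr$alpha,
    block_size = thr$block_size, n_boot = thr$n_boot_gamma, seed = sd(3)))
  top <- report$gamma_scan[1, ]
  hyb_trip <- c(top$P1, top$H, top$P2)
  report$gamma_individual <- stage("gamma_individual", individual_level(
    gm, hyb_trip, units = clade_units, outgroup = sim$outgroup,
    block_size = thr$block_size, n_boot = thr$n_boot_gamma, seed = sd(4)))
  report$gamma_bootstrap <- stage("gamma_bootstrap", bootstrap_individuals(
    gm, hyb_trip, n_reps = thr$boot_reps, seed = sd(5), units = clade_units,
    outgroup = sim$outgroup))

  ## mixture classification ---------------------------------------------
  report$quibl <- stage("quibl", run_quibl(
    qb_trees, sp_tree, outgroup = sim$outgroup, min_n = thr$quibl_min_n,
    seed = sd(6)))

  ## Fd scan -------------------------------------------------------------
  fd_windows_tab <- make_windows(chrom_lengths, config$windows$fd)
  report$fd <- stage("fd", fd_windows(
    freqs_sp, config$fd_trio[1], config$fd_trio[2], config$fd_trio[3],
    fd_windows_tab))
  report$fd_top <- top_fraction(report$fd, thr$fd_top)

  ## local ancestry ------------------------------------------------------
  anc <- config$ancestry
  track <- stage("ancestry", infer_dosage(
    gm, admixed = anc$admixed, source1 = anc$source1, source2 = anc$source2,
    g = anc$g, recomb_rate = anc$recomb_rate,
    pops = clade_units[c(anc$admixed, anc$source1, anc$source2)]))
  report$ancestry <- track
  report$tracts <- stage("tracts", call_tracts(
    track, fd_windows_tab, fraction = thr$tract_top,
    threshold = thr$dosage))
  report$candidates <- stage("intersection",
                             intersect_candidates(report$tracts,
                                                  report$fd_top))

  ## partitioned trees ---------------------------------------------------
  report$partition <- stage("partition_trees", {
    regions <- unique(rbind(report$fd_top[, c("chrom", "start", "end")],
                            report$tracts[, c("chrom", "start", "end")]))
    regions <- regions[order(regions$chrom, regions$start), ]
    partition_trees(gm, regions, outgroup = sim$outgroup,
                    focal = config$clades[[anc$admixed]])
  })

  ## population summaries ------------------------------------------------
  report$fst <- stage("fst", {
    species <- setdiff(names(species_pops), sim$outgroup)
    clade_of <- setNames(rep(names(config$clades),
                             lengths(config$clades)),
                         unlist(config$clades))
    prs <- combn(species, 2)
    vals <- vapply(seq_len(ncol(prs)), function(i)
      hudson_fst(gm, prs[1, i], prs[2, i]), 1)
    within <- clade_of[prs[1, ]] == clade_of[prs[2, ]]
    data.frame(pop_a = prs[1, ], pop_b = prs[2, ], fst = vals,
               comparison = ifelse(within, "within_group", "between_group"),
               stringsAsFactors = FALSE)
  })
  report$heterozygosity <- stage("heterozygosity", {
    hw <- heterozygosity_windows(gm, config$windows$het,
                                 chrom_lengths = chrom_lengths)
    stats::aggregate(value ~ individual, hw, mean)
  })

  report$manifest <- list(
    config_hash = config_hash(config), seed = config$seed,
    stage_seeds = vapply(1:6, sd, 1L),
    package_version = tryCatch(
      as.character(utils::packageVersion("mscdiscord")),
      error = function(e) "dev"),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  note("pipeline finished in %.1f s",
       as.numeric(Sys.time() - t_all, units = "secs"))
  class(report) <- "pipeline_report"
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("== Discordance-attribution pipeline report ==\n")
  cat(sprintf("config %s | seed %d | gamma = %s\n",
              x$manifest$config_hash, x$manifest$seed,
              format(x$config$sim$gamma)))
  cat(sprintf("gene trees: %d GF windows (%d passed filter), %d mixture-scheme trees\n",
              x$n_gf_windows, x$n_gf_trees, x$n_quibl_trees))
  cat("top topologies:\n")
  print(utils::head(data.frame(x$topologies), 3))
  cat("species tree:", canonical_topology(x$species_tree), "\n")
  qs <- attr(x$species_tree, "quartet_support")
  if (!is.null(qs) && nrow(qs)) {
    con <- qs[which.min(qs$q1), ]
    cat(sprintf("most conflicted branch: {%s} q1 = %.3f, q2 = %.3f, q3 = %.3f\n",
                con$clade, con$q1, con$q2, con$q3))
  }
  sig <- x$gamma_scan[x$gamma_scan$significant, ]
  if (nrow(sig)) {
    cat(sprintf("gamma scan: %d significant triplet(s); top: H = %s (parents %s, %s), gamma = %.3f\n",
                nrow(sig), sig$H[1], sig$P1[1], sig$P2[1], sig$gamma[1]))
  } else {
    cat("gamma scan: no significant hybridization\n")
  }
  s <- attr(x$quibl, "summary")
  cat(sprintf("mixture decisions (discordant classes): %d ILS-only, %d ILS+introgression, %d indistinguishable\n",
              s[1], s[2], s[3]))
  cat(sprintf("Fd top-%d%%: %d windows; tracts: %d; intersection: %d\n",
              round(100 * x$config$thresholds$fd_top), nrow(x$fd_top),
              nrow(x$tracts), nrow(x$candidates)))
  cat(sprintf("partitioned trees attach the focal clade differently: %s\n",
              x$partition$different_attachment))
  fst_m <- stats::aggregate(fst ~ comparison, x$fst, median)
  cat("median FST:",
      paste(sprintf("%s %.3f", fst_m$comparison, fst_m$fst), collapse = ", "),
      "\n")
  invisible(x)
}
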