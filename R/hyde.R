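#' Estimate the hybrid inheritance probability gamma from site patterns
#'
#' For a triplet (P1, putative hybrid H, P2) with a polarised outgroup, the
#' frequency-weighted rooted site-pattern counts are
#' `n_BBAA` (P1 and H share the derived allele), `n_ABBA` (H and P2 share)
#' and `n_BABA` (P1 and P2 share). Under a hybrid origin of H with
#' inheritance probability `gamma` from the P2-side parent, and assuming the
#' two parental attachment points are equally diverged, the expected excess
#' of each sharing pattern over the ILS baseline (`n_BABA`) is linear in
#' `gamma`, giving the estimator
#' `gamma_hat = (n_ABBA - n_BABA) / ((n_ABBA - n_BABA) + (n_BBAA - n_BABA))`.
#' Values near 0.5 indicate a balanced hybrid origin; values near 0 or 1
#' indicate H is simply sister to P1 or P2. Unequal parental divergences
#' bias the estimate (see the package vignette); swapping P1 and P2 maps
#' `gamma_hat` to `1 - gamma_hat` exactly.
#'
#' Significance is assessed with a site-block bootstrap: `gamma_hat` is
#' recomputed over resampled genomic blocks and compared, on the bootstrap
#' scale, with the nearer of the no-hybridisation values {0, 1}.
#'
#' @param freqs A [polarize()] result.
#' @param p1,hyb,p2 Population (or individual) labels: the two putative
#'   parents and the candidate hybrid.
#' @param block_size Bootstrap block size in bp (default 1e6).
#' @param n_boot Bootstrap replicates for the Z score (default 200).
#' @param seed Optional seed for the bootstrap.
#' @param keep_boot Keep the bootstrap distribution in the result?
#' @param level `"population"` or `"individual"` (annotation only).
#' @return Object of class `gamma_estimate`: `gamma` (clamped to \[0, 1\]),
#'   `raw`, `se`, `Z`, `p`, `counts`, `verdict` (`"hybridization"` /
#'   `"no_hybridization"`), `flag`.
#' @export
gamma_estimate <- function(freqs, p1, hyb, p2, block_size = 1e6,
                           n_boot = 200, seed = NULL, keep_boot = FALSE,
                           level = "population") {
  w <- pattern_weights(freqs, p1, hyb, p2)
  est <- gamma_from_weights(w$abba, w$baba, w$bbaa)
  out <- list(triplet = c(P1 = p1, H = hyb, P2 = p2), level = level,
              counts = c(abba = sum(w$abba), baba = sum(w$baba),
                         bbaa = sum(w$bbaa)),
              raw = est$raw, gamma = est$gamma, flag = est$flag)
  if (est$flag == "undefined") {
    out <- c(out, list(se = NA_real_, Z = NA_real_, p = NA_real_,
                       verdict = "no_hybridization"))
    class(out) <- "gamma_estimate"
    return(out)
  }
  blocks <- site_blocks(w$chrom, w$pos, block_size)
  ub <- unique(blocks)
  idx <- match(blocks, ub)
  A <- vapply(split(w$abba, idx), sum, 1)
  B <- vapply(split(w$baba, idx), sum, 1)
  C <- vapply(split(w$bbaa, idx), sum, 1)
  nb <- length(ub)
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(r) {
      s <- sample.int(nb, nb, replace = TRUE)
      gamma_from_weights(A[s], B[s], C[s])$raw
    }, 1)
  })
  # gamma is a ratio, so bootstrap replicates can be heavy-tailed when a
  # resample nearly zeroes the denominator; use a percentile-based spread
  # (half the central 68% interval) rather than the raw standard deviation
  qb <- quantile(boot, c(0.1587, 0.8413), na.rm = TRUE, names = FALSE)
  se <- (qb[2] - qb[1]) / 2
  nearer <- if (est$gamma < 0.5) 0 else 1
  Z <- if (is.finite(se) && se > 0) abs(est$raw - nearer) / se else NA_real_
  p <- if (is.na(Z)) NA_real_ else 2 * pnorm(-Z)
  out$se <- se; out$Z <- Z; out$p <- p
  out$verdict <- if (!is.na(p) && p < 0.05) "hybridization" else "no_hybridization"
  if (keep_boot) out$boot <- boot
  class(out) <- "gamma_estimate"
  out
}

gamma_from_weights <- function(abba, baba, bbaa) {
  num <- sum(abba) - sum(baba)
  den <- num + (sum(bbaa) - sum(baba))
  if (den <= 0) return(list(raw = NA_real_, gamma = NA_real_,
                            flag = "undefined"))
  raw <- num / den
  list(raw = raw, gamma = min(1, max(0, raw)), flag = "ok")
}

#' @export
print.gamma_estimate <- function(x, ...) {
  cat(sprintf("gamma estimate (P1=%s, H=%s, P2=%s; %s level): gamma = %s, Z = %s, p = %s -> %s\n",
              x$triplet[1], x$triplet[2], x$triplet[3], x$level,
              format(x$gamma, digits = 3), format(x$Z, digits = 3),
              format(x$p, digits = 3), x$verdict))
  invisible(x)
}

#' Scan all ordered triplets for hybridisation
#'
#' Tests every ordered triplet (P1, H, P2) of the supplied units (each
#' unordered 3-subset contributes three candidate hybrids; the parent pair
#' is taken in lexicographic order since swapping parents only reflects
#' gamma). P values are Bonferroni-corrected across the tests; significant
#' triplets are sorted by `|gamma - 0.5|` so balanced hybrid origins rank
#' first.
#'
#' @param gm A [genotype_matrix()].
#' @param units Named list unit -> individuals (e.g. clades); defaults to
#'   the population map minus the outgroup.
#' @param outgroup Outgroup population label.
#' @param alpha Family-wise significance level (default 0.05).
#' @param block_size,n_boot,seed Passed to [gamma_estimate()].
#' @return `data.frame` of class `gamma_scan`: one row per ordered triplet
#'   with `gamma`, `Z`, `p`, `p_adj`, `significant`, `verdict`.
#' @export
scan_triplets <- function(gm, units = NULL, outgroup = gm$outgroup,
                          alpha = 0.05, block_size = 1e6, n_boot = 200,
                          seed = NULL) {
  pops <- split(names(gm$pop), gm$pop)
  if (is.null(units)) units <- pops[setdiff(names(pops), outgroup)]
  stop_if_not(length(units) >= 3, "need at least 3 in-group units")
  grouping <- c(units, pops[outgroup])
  freqs <- polarize(gm, pops = grouping, outgroup = outgroup)
  subsets <- combn(sort(names(units)), 3)
  rows <- list()
  for (i in seq_len(ncol(subsets))) {
    s3 <- subsets[, i]
    for (h in s3) {
      par <- sort(setdiff(s3, h))
      est <- gamma_estimate(freqs, par[1], h, par[2], block_size = block_size,
                            n_boot = n_boot,
                            seed = stage_seed(seed, length(rows) + 1L))
      rows[[length(rows) + 1L]] <- data.frame(
        P1 = par[1], H = h, P2 = par[2], gamma = est$gamma, raw = est$raw,
        Z = est$Z, p = est$p, flag = est$flag, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- pmin(1, out$p * nrow(out))      # Bonferroni
  out$significant <- !is.na(out$p_adj) & out$p_adj < alpha
  out$verdict <- ifelse(out$significant, "hybridization", "no_hybridization")
  out <- out[order(!out$significant, abs(out$gamma - 0.5)), ]
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  class(out) <- c("gamma_scan", "data.frame")
  out
}

#' Individual-level gamma estimates within a putative hybrid population
#'
#' Re-estimates gamma with each individual of the hybrid unit standing in
#' for the whole unit, parents kept at population level.
#'
#' @param gm A [genotype_matrix()].
#' @param triplet Character vector `c(P1, H, P2)` of unit names.
#' @param units Named list unit -> individuals (defaults to populations).
#' @param outgroup,block_size,n_boot,seed As in [gamma_estimate()].
#' @return `data.frame`: one row per individual with `gamma`, `Z`, `p`.
#' @export
individual_level <- function(gm, triplet, units = NULL,
                             outgroup = gm$outgroup, block_size = 1e6,
                             n_boot = 200, seed = NULL) {
  pops <- split(names(gm$pop), gm$pop)
  if (is.null(units)) units <- pops[setdiff(names(pops), outgroup)]
  h_inds <- units[[triplet[2]]]
  stop_if_not(length(h_inds) >= 1, "hybrid unit has no individuals")
  grouping <- c(units[triplet[c(1, 3)]], pops[outgroup],
                setNames(as.list(h_inds), h_inds))
  freqs <- polarize(gm, pops = grouping, outgroup = outgroup)
  rows <- lapply(seq_along(h_inds), function(i) {
    ind <- h_inds[i]
    if (all(is.na(freqs$freq[, ind]))) return(NULL)  # fully missing: skip
    est <- gamma_estimate(freqs, triplet[1], ind, triplet[3],
                          block_size = block_size, n_boot = n_boot,
                          seed = stage_seed(seed, i), level = "individual")
    data.frame(individual = ind, gamma = est$gamma, raw = est$raw,
               Z = est$Z, p = est$p, flag = est$flag,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bootstrap gamma over individuals of the hybrid unit
#'
#' Resamples the individuals of the putative hybrid population with
#' replacement (500 replicates by default, following the usual practice for
#' assessing heterogeneity of introgression levels) and re-estimates gamma
#' for each replicate.
#'
#' @inheritParams individual_level
#' @param n_reps Bootstrap replicates (default 500).
#' @return Object of class `gamma_bootstrap`: `boot` (replicate gammas),
#'   `mean`, `ci` (2.5/97.5 percentiles), `point` (all-individual
#'   estimate), `degenerate` flag when the unit has a single individual.
#' @export
bootstrap_individuals <- function(gm, triplet, n_reps = 500, seed = NULL,
                                  units = NULL, outgroup = gm$outgroup) {
  pops <- split(names(gm$pop), gm$pop)
  if (is.null(units)) units <- pops[setdiff(names(pops), outgroup)]
  h_inds <- units[[triplet[2]]]
  stop_if_not(length(h_inds) >= 1, "hybrid unit has no individuals")
  grouping <- c(units[triplet[c(1, 3)]], pops[outgroup],
                setNames(as.list(h_inds), h_inds))
  freqs <- polarize(gm, pops = grouping, outgroup = outgroup)
  f <- freqs$freq
  p1 <- f[, triplet[1]]; p2f <- f[, triplet[3]]
  q4 <- 1 - f[, freqs$outgroup]
  hmat <- f[, h_inds, drop = FALSE]
  g_of_ph <- function(ph) {
    ok <- stats::complete.cases(cbind(p1, ph, p2f, q4))
    gamma_from_weights(((1 - p1) * ph * p2f * q4)[ok],
                       (p1 * (1 - ph) * p2f * q4)[ok],
                       (p1 * ph * (1 - p2f) * q4)[ok])$raw
  }
  point <- g_of_ph(rowMeans(hmat, na.rm = TRUE))
  boot <- with_seed(seed, vapply(seq_len(n_reps), function(r) {
    s <- sample.int(length(h_inds), length(h_inds), replace = TRUE)
    g_of_ph(rowMeans(hmat[, s, drop = FALSE], na.rm = TRUE))
  }, 1))
  structure(list(boot = boot, mean = mean(boot, na.rm = TRUE),
                 ci = quantile(boot, c(0.025, 0.975), na.rm = TRUE,
                               names = FALSE),
                 point = point, n_reps = n_reps,
                 degenerate = length(h_inds) < 2,
                 triplet = triplet),
            class = "gamma_bootstrap")
}

#' @export
print.gamma_bootstrap <- function(x, ...) {
  cat(sprintf("Individual bootstrap of gamma (P1=%s, H=%s, P2=%s): point %s, mean %s, 95%% CI [%s, %s], %d replicates%s\n",
              x$triplet[1], x$triplet[2], x$triplet[3],
              format(x$point, digits = 3), format(x$mean, digits = 3),
              format(x$ci[1], digits = 3), format(x$ci[2], digits = 3),
              x$n_reps,
              if (x$degenerate) " (single individual: degenerate)" else ""))
  invisible(x)
}
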