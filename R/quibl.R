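#' Triplet topology classes and internal branch lengths
#'
#' Restricts every rooted gene tree to a species triplet and extracts the
#' triplet topology (which pair is sister) and the internal branch length
#' C2 (distance between the triplet MRCA and the sister-pair MRCA, in the
#' tree's own length units). The species tree orders the triplet: the
#' concordant class has the species-tree sister pair, the other two classes
#' are discordant. A triplet polytomy in a gene tree yields C2 = 0 and is
#' assigned to the concordant class by tie-break (flagged via `resolved`).
#'
#' @param trees List of rooted `phylo` gene trees.
#' @param triplet Character vector of 3 species.
#' @param species_tree Rooted `phylo` used to order the triplet.
#' @return `data.frame`: one row per usable tree with `tree` (index),
#'   `class` (`"concordant"`, `"discordant1"`, `"discordant2"`), `sister`
#'   (the sister pair), `c2`, `resolved`.
#' @export
triplet_branch_lengths <- function(trees, triplet, species_tree) {
  stop_if_not(length(triplet) == 3, "need exactly 3 species")
  ord <- enumerate_trios(species_tree, triplet)
  m1 <- ord$M1[1]; m2 <- ord$M2[1]; m3 <- ord$M3[1]
  sisters <- rbind(c(m1, m2), c(m1, m3), c(m2, m3))
  class_of <- c(paste(sort(c(m1, m2)), collapse = ","),
                paste(sort(c(m1, m3)), collapse = ","),
                paste(sort(c(m2, m3)), collapse = ","))
  names_of <- setNames(c("concordant", "discordant1", "discordant2"),
                       class_of)
  rows <- vector("list", length(trees))
  for (i in seq_along(trees)) {
    tr <- trees[[i]]
    if (inherits(tr, "filtered_window")) next
    if (!all(triplet %in% tr$tip.label)) next
    dep <- pair_mrca_depth(tr)
    d3 <- c(dep[m1, m2], dep[m1, m3], dep[m2, m3])
    mx <- max(d3)
    resolved <- sum(d3 == mx) == 1
    if (resolved) {
      sis <- sisters[which.max(d3), ]
      c2 <- mx - min(d3)
    } else {
      sis <- c(m1, m2)   # polytomy: concordant by tie-break
      c2 <- 0
    }
    key <- paste(sort(sis), collapse = ",")
    rows[[i]] <- data.frame(tree = i, class = unname(names_of[key]),
                            sister = key, c2 = c2, resolved = resolved,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows) %||%
    data.frame(tree = integer(0), class = character(0), sister = character(0),
               c2 = numeric(0), resolved = logical(0))
  rownames(out) <- NULL
  attr(out, "triplet") <- c(M1 = m1, M2 = m2, M3 = m3)
  out
}

#' Fit the ILS-only and ILS+introgression branch-length models
#'
#' Model M1 (ILS only) is an exponential density `Exp(lambda)` for the
#' internal branch lengths of one triplet topology class; under the
#' multispecies coalescent, discordant internal branches are exponential
#' excursions starting at zero. Model M2 adds a second component shifted to
#' a positive offset `c` (non-ILS branches concentrate at the species or
#' introgression divergence): `pi * Exp(lambda) + (1 - pi) * (c + Exp(lambda))`
#' with a shared scale `lambda` (mean of the exponential). M2 is fitted by
#' EM with the offset profiled on a data-quantile grid and refined
#' numerically; multiple random starts make the fit robust and a fixed seed
#' makes it reproducible. Models are compared by
#' `BIC = k ln(n) - 2 logL` with k = 1 (M1) and k = 3 (M2).
#'
#' @param lengths Numeric vector of internal branch lengths (>= 0).
#' @param n_starts Random EM starts (default 10).
#' @param seed Optional seed.
#' @param min_n Minimum sample size to attempt the fit (default 30).
#' @param tol Convergence tolerance on the log-likelihood (default 1e-8).
#' @param max_iter Maximum EM iterations per start (default 500).
#' @return Object of class `triplet_mixture`: `n`, `m1` (list `lambda`,
#'   `logL`, `bic`), `m2` (list `lambda`, `c`, `pi`, `logL`, `bic`,
#'   `converged`), `delta_bic` (BIC_M2 - BIC_M1), `decision`, `flag`.
#' @export
fit_mixture <- function(lengths, n_starts = 10, seed = NULL, min_n = 30,
                        tol = 1e-8, max_iter = 500) {
  x <- lengths[!is.na(lengths)]
  stop_if_not(all(x >= 0), "branch lengths must be >= 0")
  n <- length(x)
  if (n < min_n) {
    out <- list(n = n, m1 = NULL, m2 = NULL, delta_bic = NA_real_,
                decision = "indistinguishable", flag = "insufficient_data")
    class(out) <- "triplet_mixture"
    return(out)
  }
  lam1 <- max(mean(x), 1e-8)
  logL1 <- sum(dexp(x, rate = 1 / lam1, log = TRUE))
  bic1 <- 1 * log(n) - 2 * logL1

  fit <- with_seed(seed, {
    cgrid <- unique(c(0, quantile(x, seq(0.05, 0.95, by = 0.1), names = FALSE)))
    best <- NULL
    # coarse profile of the offset: short EM runs over starts x grid
    for (s in seq_len(n_starts)) {
      pi0 <- runif(1, 0.1, 0.9)
      lam0 <- lam1 * runif(1, 0.5, 1.5)
      for (cc in cgrid) {
        f <- em_shifted_mix(x, pi0, lam0, cc, 1e-6, 100L)
        if (is.null(best) || f$logL > best$logL) best <- f
      }
    }
    # refine the offset around the best grid value, then polish at full
    # tolerance
    lo <- max(0, best$c - diff(range(cgrid)) / 10)
    hi <- min(max(x), best$c + diff(range(cgrid)) / 10)
    if (hi > lo) {
      opt <- optimize(function(cc)
        em_shifted_mix(x, best$pi, best$lambda, cc, 1e-6, 100L)$logL,
        c(lo, hi), maximum = TRUE)
      f <- em_shifted_mix(x, best$pi, best$lambda, opt$maximum, 1e-6, 100L)
      if (f$logL > best$logL) best <- f
    }
    em_shifted_mix(x, best$pi, best$lambda, best$c, tol, max_iter)
  })
  bic2 <- 3 * log(n) - 2 * fit$logL
  delta <- bic2 - bic1
  out <- list(n = n,
              m1 = list(lambda = lam1, logL = logL1, bic = bic1),
              m2 = list(lambda = fit$lambda, c = fit$c, pi = fit$pi,
                        logL = fit$logL, bic = bic2,
                        converged = fit$converged),
              delta_bic = delta,
              decision = classify(bic1, bic2),
              flag = if (fit$converged) "ok" else "em_not_converged")
  class(out) <- "triplet_mixture"
  out
}

# EM for pi * Exp(lambda) + (1 - pi) * (c + Exp(lambda)) at fixed offset c.
# lambda is the exponential mean (scale).
em_shifted_mix <- function(x, pi0, lam0, cc, tol, max_iter) {
  n <- length(x)
  pi_ <- min(max(pi0, 1e-3), 1 - 1e-3)
  lam <- max(lam0, 1e-8)
  shifted <- x >= cc
  xs <- numeric(n); xs[shifted] <- x[shifted] - cc
  ll_old <- -Inf
  converged <- FALSE
  dens <- function(lam) {
    d1 <- exp(-x / lam) / lam
    d2 <- numeric(n)
    d2[shifted] <- exp(-xs[shifted] / lam) / lam
    list(d1 = d1, d2 = d2)
  }
  for (it in seq_len(max_iter)) {
    d <- dens(lam)
    mix <- pi_ * d$d1 + (1 - pi_) * d$d2
    mix[mix <= 0] <- .Machine$double.xmin
    r <- pi_ * d$d1 / mix
    pi_ <- mean(r)
    lam <- max(sum(r * x + (1 - r) * xs) / n, 1e-8)
    ll <- sum(log(mix))
    if (is.finite(ll) && abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
  }
  d <- dens(lam)
  mix <- pi_ * d$d1 + (1 - pi_) * d$d2
  mix[mix <= 0] <- .Machine$double.xmin
  list(pi = pi_, lambda = lam, c = cc, logL = sum(log(mix)),
       converged = converged)
}

#' @export
print.triplet_mixture <- function(x, ...) {
  if (is.null(x$m1)) {
    cat("Triplet mixture: insufficient data (n =", x$n, ")\n")
    return(invisible(x))
  }
  cat(sprintf("Triplet mixture (n = %d): M1 lambda = %.4g (BIC %.1f); M2 pi = %.3f, c = %.4g, lambda = %.4g (BIC %.1f)\n",
              x$n, x$m1$lambda, x$m1$bic, x$m2$pi, x$m2$c, x$m2$lambda,
              x$m2$bic))
  cat(sprintf("  delta BIC (M2 - M1) = %.2f -> %s\n", x$delta_bic, x$decision))
  invisible(x)
}

#' BIC decision rule for ILS-only versus ILS+introgression
#'
#' With `delta = BIC_M2 - BIC_M1`: `delta > 10` prefers the ILS-only model,
#' `delta < -10` prefers ILS plus introgression, and the band \[-10, 10\]
#' is indistinguishable.
#'
#' @param bic_m1,bic_m2 Finite BIC values of the two models.
#' @return `"ILS-only"`, `"ILS+introgression"`, or `"indistinguishable"`.
#' @export
classify <- function(bic_m1, bic_m2) {
  stop_if_not(is.finite(bic_m1) && is.finite(bic_m2),
              "both BIC values must be finite")
  delta <- bic_m2 - bic_m1
  if (delta > 10) "ILS-only"
  else if (delta < -10) "ILS+introgression"
  else "indistinguishable"
}

#' Introgressed-locus fraction for one topology class
#'
#' The non-ILS mixture weight multiplied by the genomic frequency of the
#' topology class: `(1 - pi) * topology_frequency`. Triplets where the
#' ILS-only model is preferred contribute 0 by convention.
#'
#' @param mixture A [fit_mixture()] result.
#' @param topology_frequency Genomic frequency of the topology class.
#' @return Proportion of loci attributed to introgression.
#' @export
introgressed_fraction <- function(mixture, topology_frequency) {
  stop_if_not(topology_frequency >= 0 && topology_frequency <= 1,
              "topology_frequency must be in [0, 1]")
  if (is.null(mixture$m2) || mixture$decision != "ILS+introgression") return(0)
  (1 - mixture$m2$pi) * topology_frequency
}

#' Run the triplet mixture classification over many triplets
#'
#' For every species triplet, gene trees are restricted, internal branch
#' lengths are pooled per topology class, both models are fitted per class,
#' and the BIC rule is applied. The introgressed-locus fraction of a class
#' is `(1 - pi)` times its genomic frequency.
#'
#' @param trees List of rooted gene trees.
#' @param species_tree Rooted species tree (orders each triplet).
#' @param triplets Optional 3-column matrix / data.frame of triplets;
#'   default all 3-subsets of the non-outgroup species.
#' @param outgroup Tip excluded from default triplets.
#' @param min_n,n_starts,seed Passed to [fit_mixture()].
#' @return `data.frame` of class `quibl_table`: one row per
#'   (triplet, topology class) with counts, fits, `delta_bic`, `decision`
#'   and `introgressed_fraction`; attribute `summary` tabulates decisions
#'   over discordant classes.
#' @export
run_quibl <- function(trees, species_tree, triplets = NULL,
                      outgroup = attr(trees, "outgroup"), min_n = 30,
                      n_starts = 10, seed = NULL) {
  taxa <- setdiff(species_tree$tip.label, outgroup)
  if (is.null(triplets)) {
    stop_if_not(length(taxa) >= 3, "need at least 3 in-group taxa")
    triplets <- t(combn(sort(taxa), 3))
  }
  triplets <- as.matrix(triplets)
  rows <- list()
  for (i in seq_len(nrow(triplets))) {
    tb <- triplet_branch_lengths(trees, triplets[i, ], species_tree)
    if (!nrow(tb)) next
    trip_id <- paste(attr(tb, "triplet")[1:2], collapse = ",")
    trip_id <- paste0("((", trip_id, "),", attr(tb, "triplet")[3], ")")
    ntot <- nrow(tb)
    for (cl in c("concordant", "discordant1", "discordant2")) {
      sub <- tb[tb$class == cl, ]
      freq <- nrow(sub) / ntot
      fit <- fit_mixture(sub$c2, n_starts = n_starts,
                         seed = stage_seed(seed, length(rows) + 1L),
                         min_n = min_n)
      rows[[length(rows) + 1L]] <- data.frame(
        triplet = trip_id, class = cl,
        sister = if (nrow(sub)) sub$sister[1] else NA_character_,
        n = nrow(sub), freq = freq,
        lambda1 = if (!is.null(fit$m1)) fit$m1$lambda else NA_real_,
        lambda2 = if (!is.null(fit$m2)) fit$m2$lambda else NA_real_,
        c = if (!is.null(fit$m2)) fit$m2$c else NA_real_,
        pi = if (!is.null(fit$m2)) fit$m2$pi else NA_real_,
        bic1 = if (!is.null(fit$m1)) fit$m1$bic else NA_real_,
        bic2 = if (!is.null(fit$m2)) fit$m2$bic else NA_real_,
        delta_bic = fit$delta_bic,
        decision = fit$decision,
        introgressed_fraction = introgressed_fraction(fit, freq),
        flag = fit$flag, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows) %||% empty_quibl_table()
  rownames(out) <- NULL
  disc <- out[out$class != "concordant" & out$n > 0, ]
  attr(out, "summary") <- c(
    `ILS-only` = sum(disc$decision == "ILS-only"),
    `ILS+introgression` = sum(disc$decision == "ILS+introgression"),
    indistinguishable = sum(disc$decision == "indistinguishable"))
  class(out) <- c("quibl_table", "data.frame")
  out
}

empty_quibl_table <- function() {
  data.frame(triplet = character(0), class = character(0),
             sister = character(0), n = integer(0), freq = numeric(0),
             lambda1 = numeric(0), lambda2 = numeric(0), c = numeric(0),
             pi = numeric(0), bic1 = numeric(0), bic2 = numeric(0),
             delta_bic = numeric(0), decision = character(0),
             introgressed_fraction = numeric(0), flag = character(0),
             stringsAsFactors = FALSE)
}
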