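#' Patterson's D with block-jackknife standard error
#'
#' Computes the frequency-weighted ABBA-BABA imbalance
#' `D = sum(ABBA - BABA) / sum(ABBA + BABA)` for an ordered trio
#' `(P1, P2, P3)` with the polarised outgroup, and its standard error by a
#' delete-one block jackknife over contiguous genomic blocks. Under
#' incomplete lineage sorting alone E\[D\] = 0; an excess of ABBA (derived
#' sharing between P2 and P3) indicates gene flow.
#'
#' @param freqs A [polarize()] result.
#' @param p1,p2,p3 Population labels for the ordered trio `((P1, P2), P3)`.
#' @param block_size Jackknife block size in bp (default 1e6).
#' @param min_blocks_z Minimum number of blocks required to report a Z score
#'   (default 20).
#' @return Object of class `d_stat`: `D`, `se`, `Z`, `n_blocks`, `abba`,
#'   `baba`, `n_sites`, `trio`, and `flag` (`"ok"`, `"undefined"` when
#'   sum(ABBA + BABA) is 0, or `"too_few_blocks"`).
#' @export
patterson_d <- function(freqs, p1, p2, p3, block_size = 1e6,
                        min_blocks_z = 20) {
  w <- pattern_weights(freqs, p1, p2, p3)
  num <- w$abba - w$baba
  den <- w$abba + w$baba
  out <- list(trio = c(P1 = p1, P2 = p2, P3 = p3),
              abba = sum(w$abba), baba = sum(w$baba),
              n_sites = length(num), block_size = block_size)
  if (sum(den) <= 0) {
    out <- c(out, list(D = NA_real_, se = NA_real_, Z = NA_real_,
                       n_blocks = 0L, flag = "undefined"))
    class(out) <- "d_stat"
    return(out)
  }
  out$D <- sum(num) / sum(den)
  blocks <- site_blocks(w$chrom, w$pos, block_size)
  ub <- unique(blocks)
  B <- length(ub)
  stop_if_not(B >= 2, "need at least 2 jackknife blocks for a standard error")
  bn <- vapply(split(num, blocks), sum, 1)[ub]
  bd <- vapply(split(den, blocks), sum, 1)[ub]
  loo <- (sum(num) - bn) / (sum(den) - bd)
  loo[!is.finite(loo)] <- out$D
  se <- sqrt((B - 1) / B * sum((loo - mean(loo))^2))
  out$se <- se
  out$n_blocks <- B
  if (B < min_blocks_z) {
    out$Z <- NA_real_
    out$flag <- "too_few_blocks"
  } else {
    out$Z <- if (se > 0) out$D / se else NA_real_
    out$flag <- "ok"
  }
  class(out) <- "d_stat"
  out
}

#' @export
print.d_stat <- function(x, ...) {
  cat(sprintf("D statistic ((%s,%s),%s): D = %s, SE = %s, Z = %s [%d blocks, %d sites]%s\n",
              x$trio[1], x$trio[2], x$trio[3],
              format(x$D, digits = 4), format(x$se, digits = 3),
              format(x$Z, digits = 4), x$n_blocks, x$n_sites,
              if (x$flag != "ok") paste0(" (", x$flag, ")") else ""))
  invisible(x)
}

#' Order all species trios by a reference topology
#'
#' For every 3-subset of `taxa` the ordering `((M1, M2), M3)` is induced by
#' the reference species tree: the cladistically closest pair becomes
#' (M1, M2). Unresolved triples are ordered lexicographically and flagged.
#'
#' @param species_tree Rooted `phylo`.
#' @param taxa Taxa to enumerate (default: all tips except the outgroup
#'   attribute, when present).
#' @return `data.frame` with columns `M1`, `M2`, `M3`, `resolved`; the
#'   number of trios equals `choose(length(taxa), 3)`.
#' @export
enumerate_trios <- function(species_tree, taxa = NULL) {
  if (is.null(taxa)) taxa <- species_tree$tip.label
  stop_if_not(all(taxa %in% species_tree$tip.label), "unknown taxa")
  stop_if_not(length(taxa) >= 3, "need at least 3 taxa")
  dep <- pair_mrca_depth(species_tree)
  trios <- combn(sort(taxa), 3)
  out <- data.frame(M1 = character(ncol(trios)), M2 = "", M3 = "",
                    resolved = TRUE, stringsAsFactors = FALSE)
  for (i in seq_len(ncol(trios))) {
    t3 <- trios[, i]
    d3 <- c(dep[t3[1], t3[2]], dep[t3[1], t3[3]], dep[t3[2], t3[3]])
    mx <- max(d3)
    if (sum(d3 == mx) > 1) {          # polytomy: lexicographic, flagged
      out[i, ] <- list(t3[1], t3[2], t3[3], FALSE)
    } else {
      pair <- list(t3[c(1, 2)], t3[c(1, 3)], t3[c(2, 3)])[[which.max(d3)]]
      out[i, ] <- list(pair[1], pair[2], setdiff(t3, pair), TRUE)
    }
  }
  out
}

#' f4-admixture ratio
#'
#' Estimates the admixture fraction for the hypothesis of gene flow from
#' donor `C` into `B`, relative to complete replacement: the numerator is
#' `sum((pB - pA) pC (1 - pO))` and the denominator repeats the sum with the
#' donor frequency `pD = max(pB, pC)` substituted at each site for both `B`
#' and `C` (the "dynamic donor" convention). The ratio is clamped to
#' \[0, 1\] for reporting; the raw value is retained.
#'
#' @param freqs A [polarize()] result.
#' @param a,b,c Population labels: `a` the sister unaffected by gene flow,
#'   `b` the candidate recipient, `c` the candidate donor.
#' @return Object of class `f4_ratio`: `ratio` (clamped), `raw`, `num`,
#'   `den`, `flag`.
#' @export
f4_ratio <- function(freqs, a, b, c) {
  w <- pattern_weights(freqs, a, b, c)
  num <- sum((w$p2 - w$p1) * w$p3 * w$q4)
  pd <- pmax(w$p2, w$p3)
  den <- sum((pd - w$p1) * pd * w$q4)
  if (den <= 0) {
    out <- list(ratio = NA_real_, raw = NA_real_, num = num, den = den,
                pops = c(A = a, B = b, C = c), flag = "undefined")
  } else {
    raw <- num / den
    out <- list(ratio = min(1, max(0, raw)), raw = raw, num = num, den = den,
                pops = c(A = a, B = b, C = c), flag = "ok")
  }
  class(out) <- "f4_ratio"
  out
}

#' @export
print.f4_ratio <- function(x, ...) {
  cat(sprintf("f4 admixture ratio (A=%s, B=%s; C=%s): %s%s\n",
              x$pops[1], x$pops[2], x$pops[3], format(x$ratio, digits = 4),
              if (x$flag != "ok") paste0(" (", x$flag, ")") else ""))
  invisible(x)
}

#' f-branch matrix: assign admixture signal to branches
#'
#' Summarises a table of f4-admixture ratios into one value per (species-tree
#' branch, donor taxon): `f_b(C)` is the minimum over recipient descendants
#' `B` of branch `b` of the median over valid sisters `A` (descendants of
#' `b`'s sibling) of the f4 ratio `f(A, B; C)`. Large values on an internal
#' branch indicate gene flow into that (possibly ancestral) lineage.
#'
#' @param species_tree Rooted `phylo`; the outgroup is excluded from donors.
#' @param f4_results `data.frame` with columns `A`, `B`, `C`, `ratio` (as
#'   assembled from [f4_ratio()] calls), in any row order.
#' @param outgroup Outgroup tip label (excluded from the matrix).
#' @return Matrix of class `f_branch` (branches x donors); `NA` cells had no
#'   valid (A, B) combination. Row names are the branch's descendant clade.
#' @export
f_branch <- function(species_tree, f4_results, outgroup = NULL) {
  st <- species_tree
  ntip <- ape::Ntip(st)
  sets <- node_tip_sets(st)
  root <- ntip + 1L
  tips_all <- st$tip.label
  donors <- setdiff(tips_all, outgroup)
  branch_nodes <- setdiff(seq_len(ntip + st$Nnode), root)
  og_node <- if (!is.null(outgroup)) which(tips_all == outgroup) else -1L

  key <- paste(f4_results$A, f4_results$B, f4_results$C, sep = "\r")
  lookup <- setNames(f4_results$ratio, key)
  ch <- node_children(st)
  rows <- list()
  for (v in branch_nodes) {
    if (v == og_node) next
    u <- st$edge[st$edge[, 2] == v, 1]
    sib <- setdiff(ch[[u]], v)
    if (!length(sib)) next
    Bset <- tips_all[sets[[v]]]
    Aset <- tips_all[unlist(sets[sib])]
    if (!is.null(outgroup)) {
      Bset <- setdiff(Bset, outgroup); Aset <- setdiff(Aset, outgroup)
    }
    if (!length(Aset) || !length(Bset)) next
    vals <- vapply(donors, function(cc) {
      if (cc %in% Bset || cc %in% Aset) return(NA_real_)
      per_b <- vapply(Bset, function(bb) {
        r <- lookup[paste(Aset, bb, cc, sep = "\r")]
        if (all(is.na(r))) NA_real_ else median(r, na.rm = TRUE)
      }, 1)
      if (all(is.na(per_b))) NA_real_ else min(per_b, na.rm = TRUE)
    }, 1)
    rows[[paste(sort(Bset), collapse = ",")]] <- vals
  }
  m <- do.call(rbind, rows)
  class(m) <- c("f_branch", class(m))
  m
}

#' All f4 ratios needed by [f_branch()]
#'
#' Convenience wrapper running [f4_ratio()] for every combination
#' `(A, B, C)` of distinct ingroup populations.
#'
#' @param freqs A [polarize()] result.
#' @param pops Populations to use (default all non-outgroup columns).
#' @return `data.frame` with columns `A`, `B`, `C`, `ratio`, `raw`.
#' @export
f4_all <- function(freqs, pops = NULL) {
  pops <- pops %||% setdiff(colnames(freqs$freq), freqs$outgroup)
  grid <- expand.grid(A = pops, B = pops, C = pops,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$A != grid$B & grid$A != grid$C & grid$B != grid$C, ]
  res <- lapply(seq_len(nrow(grid)), function(i)
    f4_ratio(freqs, grid$A[i], grid$B[i], grid$C[i]))
  grid$ratio <- vapply(res, function(r) r$ratio, 1)
  grid$raw <- vapply(res, function(r) r$raw, 1)
  rownames(grid) <- NULL
  grid
}
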