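#' Derived-allele frequencies per population
#'
#' Polarises biallelic sites against the outgroup: sites where the outgroup
#' consensus is missing or polymorphic are dropped; where the outgroup is
#' fixed for the alternate allele the site is flipped, so the outgroup's
#' derived-allele frequency is 0 everywhere. All ABBA-BABA style arithmetic
#' in the package consumes this representation (frequency-weighted site
#' patterns from diploid dosages).
#'
#' @param gm A [genotype_matrix()] with a designated outgroup population.
#' @param pops Optional named list group -> individual ids to override the
#'   population map (e.g. to pool species into clades).
#' @param outgroup Outgroup population label (defaults to the matrix's).
#' @return An object of class `derived_freqs`: list with `freq` (sites x
#'   populations matrix of derived-allele frequencies), `chrom`, `pos`,
#'   `outgroup`, `n_dropped`.
#' @export
polarize <- function(gm, pops = NULL, outgroup = gm$outgroup) {
  stop_if_not(!is.na(outgroup), "an outgroup population is required")
  if (is.null(pops)) pops <- split(names(gm$pop), gm$pop)
  stop_if_not(outgroup %in% names(pops), "outgroup missing from grouping")
  freq <- matrix(NA_real_, nrow(gm$geno), length(pops),
                 dimnames = list(NULL, names(pops)))
  for (j in seq_along(pops)) {
    sub <- gm$geno[, pops[[j]], drop = FALSE]
    freq[, j] <- rowMeans(sub, na.rm = TRUE) / 2
  }
  fo <- freq[, outgroup]
  keep <- !is.nan(fo) & (fo == 0 | fo == 1)
  if (!any(keep)) warning("all sites dropped during polarisation")
  flip <- keep & fo == 1
  freq[flip, ] <- 1 - freq[flip, ]
  freq[is.nan(freq)] <- NA_real_
  structure(list(freq = freq[keep, , drop = FALSE],
                 chrom = gm$variants$chrom[keep],
                 pos = gm$variants$pos[keep],
                 outgroup = outgroup,
                 n_dropped = sum(!keep)),
            class = "derived_freqs")
}

#' @export
print.derived_freqs <- function(x, ...) {
  cat("Derived-allele frequencies:", nrow(x$freq), "sites,",
      ncol(x$freq), "populations (outgroup", paste0(x$outgroup, ");"),
      x$n_dropped, "sites dropped\n")
  invisible(x)
}

# Site-pattern weights for an ordered trio (P1, P2, P3) against the
# (polarised) outgroup: ABBA = (1-p1) p2 p3, BABA = p1 (1-p2) p3,
# BBAA = p1 p2 (1-p3), each times (1 - p_outgroup).
pattern_weights <- function(freqs, p1, p2, p3) {
  f <- freqs$freq
  stop_if_not(all(c(p1, p2, p3) %in% colnames(f)),
              "unknown population in trio")
  q4 <- 1 - f[, freqs$outgroup]
  a1 <- f[, p1]; a2 <- f[, p2]; a3 <- f[, p3]
  ok <- stats::complete.cases(cbind(a1, a2, a3, q4))
  list(abba = ((1 - a1) * a2 * a3 * q4)[ok],
       baba = (a1 * (1 - a2) * a3 * q4)[ok],
       bbaa = (a1 * a2 * (1 - a3) * q4)[ok],
       chrom = freqs$chrom[ok], pos = freqs$pos[ok],
       p1 = a1[ok], p2 = a2[ok], p3 = a3[ok], q4 = q4[ok])
}

# Block labels for jackknife/bootstrap resampling of sites.
site_blocks <- function(chrom, pos, block_size) {
  paste(chrom, pos %/% block_size, sep = ":")
}
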