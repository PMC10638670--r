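#' Hudson's FST (ratio of averages)
#'
#' Estimates FST between two populations with Hudson's estimator, summing
#' numerator and denominator over sites before taking the ratio (the
#' recommended "ratio of averages"). Per site,
#' `N = (p1 - p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)` and
#' `D = p1(1-p2) + p2(1-p1)`, with `n` the allele sample size. Negative
#' estimates are retained. A Weir-Cockerham variant is available behind
#' `method = "wc"`.
#'
#' @param gm A [genotype_matrix()].
#' @param pop_a,pop_b Population labels (or named lists of individuals via
#'   `pops`).
#' @param windows Optional window table; when given, one estimate per
#'   window is returned as a `window_stat` `data.frame`.
#' @param pops Optional named list group -> individuals overriding the
#'   population map.
#' @param method `"hudson"` (default) or `"wc"`.
#' @return A single FST value, or a `window_stat` `data.frame` when
#'   `windows` is supplied. `NA` when no usable polymorphic site exists.
#' @export
hudson_fst <- function(gm, pop_a, pop_b, windows = NULL, pops = NULL,
                       method = c("hudson", "wc")) {
  method <- match.arg(method)
  if (is.null(pops)) pops <- split(names(gm$pop), gm$pop)
  stop_if_not(all(c(pop_a, pop_b) %in% names(pops)), "unknown population")
  ga <- gm$geno[, pops[[pop_a]], drop = FALSE]
  gb <- gm$geno[, pops[[pop_b]], drop = FALSE]
  na <- 2 * rowSums(!is.na(ga)); nb <- 2 * rowSums(!is.na(gb))
  pa <- rowSums(ga, na.rm = TRUE) / na
  pb <- rowSums(gb, na.rm = TRUE) / nb
  ok <- na >= 2 & nb >= 2 & is.finite(pa) & is.finite(pb)
  if (method == "hudson") {
    num <- (pa - pb)^2 - pa * (1 - pa) / (na - 1) - pb * (1 - pb) / (nb - 1)
    den <- pa * (1 - pb) + pb * (1 - pa)
  } else {
    # two-population Weir-Cockerham theta components
    nbar <- (na + nb) / 2
    pbar <- (na * pa + nb * pb) / (na + nb)
    s2 <- (na * (pa - pbar)^2 + nb * (pb - pbar)^2) / nbar
    hbar <- 0  # dosage data: within-individual heterozygosity term omitted
    nc <- (na + nb - (na^2 + nb^2) / (na + nb))
    num <- s2 - 1 / (nbar - 1) * (pbar * (1 - pbar) - s2 / 2 - hbar / 4)
    den <- pbar * (1 - pbar) + s2 / (2 * 2)
  }
  num[!ok] <- 0; den[!ok] <- 0
  if (is.null(windows)) {
    if (sum(den) <= 0) return(NA_real_)
    return(sum(num) / sum(den))
  }
  widx <- assign_windows(gm$variants$chrom, gm$variants$pos, windows)
  nw <- window_sums(num, widx, nrow(windows))
  dw <- window_sums(den, widx, nrow(windows))
  value <- ifelse(dw > 0, nw / dw, NA_real_)
  out <- data.frame(chrom = windows$chrom, start = windows$start,
                    end = windows$end, statistic = "fst", value = value,
                    stringsAsFactors = FALSE)
  class(out) <- c("window_stat", "data.frame")
  out
}

#' Per-individual heterozygosity in non-overlapping windows
#'
#' Counts heterozygous calls (dosage 1) per individual in tiled windows and
#' divides by the window length in bp. Positions without a variant record
#' are treated as callable homozygous reference, so the denominator is the
#' full window length.
#'
#' @param gm A [genotype_matrix()].
#' @param window_size Window size in bp (default 1e5).
#' @param chrom_lengths Named chromosome lengths; defaults to the largest
#'   position + 1 per chromosome present in the data.
#' @return `data.frame` of class `window_stat` with one row per
#'   (individual, window): `individual`, `chrom`, `start`, `end`,
#'   `statistic = "heterozygosity"`, `value`.
#' @export
heterozygosity_windows <- function(gm, window_size = 1e5,
                                   chrom_lengths = NULL) {
  if (is.null(chrom_lengths)) {
    chrom_lengths <- vapply(split(gm$variants$pos, gm$variants$chrom),
                            function(p) max(p) + 1, 1)
  }
  wins <- make_windows(chrom_lengths, window_size)
  stop_if_not(nrow(wins) > 0, "no complete window fits the data")
  inds <- colnames(gm$geno)
  widx <- assign_windows(gm$variants$chrom, gm$variants$pos, wins)
  out <- vector("list", length(inds))
  for (j in seq_along(inds)) {
    het <- window_sums(as.numeric(gm$geno[, j] == 1L), widx, nrow(wins))
    out[[j]] <- data.frame(individual = inds[j], chrom = wins$chrom,
                           start = wins$start, end = wins$end,
                           statistic = "heterozygosity",
                           value = het / window_size,
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("window_stat", "data.frame")
  out
}
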