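#' Tile half-open genomic windows
#'
#' Windows start at 0 and advance with stride `size + gap`; trailing partial
#' windows are dropped. With `gap = 0` this is the plain non-overlapping
#' tiling used for window trees, Fd scans and heterozygosity; a positive
#' `gap` gives the spaced scheme used to keep windows approximately free of
#' recombination breakpoints.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @param size Window size in bp (>= 1).
#' @param gap Gap between consecutive windows in bp (>= 0).
#' @return `data.frame` with columns `chrom`, `start`, `end`
#'   (0-based, half-open), sorted by chromosome then start.
#' @examples
#' make_windows(c(chr1 = 1e6), size = 2e5)           # five 200-kb windows
#' make_windows(c(chr1 = 1.26e6), size = 2e4, gap = 4e5)
#' @export
make_windows <- function(chrom_lengths, size, gap = 0) {
  stop_if_not(size >= 1, "size must be >= 1")
  stop_if_not(gap >= 0, "gap must be >= 0")
  stop_if_not(!is.null(names(chrom_lengths)), "chrom_lengths must be named")
  out <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    n <- if (len < size) 0L else (len - size) %/% (size + gap) + 1L
    if (n == 0L) return(NULL)
    start <- (seq_len(n) - 1) * (size + gap)
    data.frame(chrom = ch, start = start, end = start + size,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- data.frame(chrom = character(0), start = numeric(0),
                                      end = numeric(0))
  out
}

# Row indices of variants falling in a half-open window.
sites_in_window <- function(gm, window) {
  which(gm$variants$chrom == window$chrom &
          gm$variants$pos >= window$start & gm$variants$pos < window$end)
}

# Window row index for each (chrom, pos), NA outside all windows. Windows
# must be sorted and non-overlapping (as produced by make_windows).
assign_windows <- function(chrom, pos, windows) {
  out <- rep(NA_integer_, length(pos))
  for (ch in unique(windows$chrom)) {
    rows <- which(windows$chrom == ch)
    in_ch <- which(chrom == ch)
    if (!length(in_ch)) next
    i <- findInterval(pos[in_ch], windows$start[rows])
    ok <- i >= 1 & pos[in_ch] < windows$end[rows][pmax(i, 1)]
    out[in_ch[ok]] <- rows[i[ok]]
  }
  out
}

# Sum `x` per window (0 for empty windows).
window_sums <- function(x, widx, n_windows) {
  out <- numeric(n_windows)
  ok <- !is.na(widx) & !is.na(x)
  if (any(ok)) {
    s <- rowsum(x[ok], widx[ok])
    out[as.integer(rownames(s))] <- s[, 1]
  }
  out
}

#' Per-population consensus alleles
#'
#' Collapses individual dosages to one consensus allele per population per
#' site: the majority allele by mean alt-dosage; exact ties and all-missing
#' entries give `NA` (such sites are excluded from informative-site counts,
#' keeping the procedure deterministic).
#'
#' @param gm A [genotype_matrix()].
#' @param pops Optional named list group -> individual ids; defaults to the
#'   matrix's population map.
#' @return Integer matrix (sites x populations) with entries 0, 1, `NA`.
#' @export
consensus_alleles <- function(gm, pops = NULL) {
  if (is.null(pops)) pops <- split(names(gm$pop), gm$pop)
  out <- matrix(NA_integer_, nrow(gm$geno), length(pops),
                dimnames = list(NULL, names(pops)))
  for (j in seq_along(pops)) {
    sub <- gm$geno[, pops[[j]], drop = FALSE]
    f <- rowMeans(sub, na.rm = TRUE) / 2
    out[, j] <- ifelse(is.nan(f) | f == 0.5, NA_integer_,
                       as.integer(f > 0.5))
  }
  out
}

#' Count parsimony-informative sites in a window
#'
#' A site is parsimony-informative when at least two distinct consensus
#' alleles are each carried by at least two populations.
#'
#' @param gm A [genotype_matrix()].
#' @param window One-row window (`chrom`, `start`, `end`) as produced by
#'   [make_windows()].
#' @param pops Optional grouping passed to [consensus_alleles()].
#' @return Integer count.
#' @export
count_informative_sites <- function(gm, window, pops = NULL) {
  idx <- sites_in_window(gm, window)
  if (!length(idx)) return(0L)
  cons <- consensus_alleles(subset_genotypes(gm, idx), pops)
  sum(informative_mask(cons))
}

informative_mask <- function(cons) {
  n1 <- rowSums(cons == 1L, na.rm = TRUE)
  n0 <- rowSums(cons == 0L, na.rm = TRUE)
  n1 >= 2 & n0 >= 2
}
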