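#' Windowed Fd introgression scan
#'
#' Computes the Fd statistic of each genomic window for the trio
#' `((P1, P2), P3)` with a polarised outgroup: the ABBA-BABA imbalance
#' normalised by the value it would take if the donor haplotype had
#' replaced P2 entirely, with the donor frequency taken per site as
#' `max(p2, p3)`. Fd is bounded and remains stable in small windows with
#' few informative sites. Windows with a non-positive denominator or a
#' negative numerator are reported as undefined (`NA`) rather than 0, the
#' usual convention for Fd (this affects which windows can enter the
#' selected tail).
#'
#' @param freqs A [polarize()] result.
#' @param p1,p2,p3 Ordered trio labels (P2 the candidate recipient, P3 the
#'   donor).
#' @param windows Window table from [make_windows()] (10-kb tiles in the
#'   standard scan).
#' @return `data.frame` of class `window_stat`: `chrom`, `start`, `end`,
#'   `statistic = "fd"`, `value`, `n_informative`.
#' @export
fd_windows <- function(freqs, p1, p2, p3, windows) {
  w <- pattern_weights(freqs, p1, p2, p3)
  num_s <- (w$p2 - w$p1) * w$p3 * w$q4
  pd <- pmax(w$p2, w$p3)
  den_s <- (pd - w$p1) * pd * w$q4
  inf_s <- num_s != 0 | den_s != 0
  widx <- assign_windows(w$chrom, w$pos, windows)
  num <- window_sums(num_s, widx, nrow(windows))
  den <- window_sums(den_s, widx, nrow(windows))
  n_inf <- as.integer(window_sums(as.numeric(inf_s), widx, nrow(windows)))
  value <- ifelse(den > 0 & num >= 0, num / den, NA_real_)
  out <- data.frame(chrom = windows$chrom, start = windows$start,
                    end = windows$end, statistic = "fd", value = value,
                    n_informative = n_inf, stringsAsFactors = FALSE)
  class(out) <- c("window_stat", "data.frame")
  out
}

#' Select the top fraction of windows by statistic value
#'
#' Keeps the `ceiling(fraction * n_defined)` windows with the highest
#' values among windows whose statistic is defined. Ties are broken by
#' genomic order (earlier windows kept), making the selection deterministic.
#'
#' @param stats A `window_stat` `data.frame` (any statistic).
#' @param fraction Fraction in (0, 1), e.g. 0.05 for a top-5% scan or 0.01
#'   for top-1% tract calling.
#' @return The selected rows, in genomic order; attributes `k` (number
#'   selected) and `cutoff` (smallest selected value).
#' @export
top_fraction <- function(stats, fraction) {
  stop_if_not(fraction > 0 && fraction < 1, "fraction must be in (0, 1)")
  def <- which(!is.na(stats$value))
  k <- ceiling(fraction * length(def))
  if (k == 0) {
    out <- stats[integer(0), ]
  } else {
    ord <- def[order(-stats$value[def], stats$chrom[def], stats$start[def])]
    sel <- sort(ord[seq_len(k)])
    out <- stats[sel, ]
  }
  rownames(out) <- NULL
  attr(out, "k") <- k
  attr(out, "cutoff") <- if (k > 0) min(out$value) else NA_real_
  out
}
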