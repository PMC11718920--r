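#' Aggregate iHS scores into non-overlapping windows
#'
#' Tiles each chromosome from position 1 in steps of `window_size` and
#' averages standardized iHS over the valid scored sites in each window. A
#' site at position P belongs to window `floor((P - 1) / window_size)`.
#' Windows are labelled 1-based with `end = start + window_size`, the
#' convention used for regions such as `chr5:58800001-58850001`; internal
#' assignment is half-open. Windows without any valid site are omitted.
#'
#' Both the mean of `|iHS|` (`mean_abs_ihs`, used for ranking) and the
#' absolute mean (`abs_mean_ihs`) are reported.
#'
#' @param scores an [ihs_scan()] object or its `scores` data frame.
#' @param window_size window span in bp (default 50,000).
#' @return Data frame with `chrom`, `start`, `end`, `n_snps`,
#'   `mean_abs_ihs`, `abs_mean_ihs`, ordered by `start`.
#' @export
bin_scores <- function(scores, window_size = 50000) {
  chrom <- "1"
  if (inherits(scores, "ihs_scan")) {
    chrom <- scores$chrom
    scores <- scores$scores
  }
  s <- scores[scores$valid & !is.na(scores$ihs_std), ]
  if (!nrow(s))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_snps = integer(0),
                      mean_abs_ihs = numeric(0), abs_mean_ihs = numeric(0)))
  chrom <- if ("chrom" %in% names(s)) s$chrom else rep_len(chrom, nrow(s))
  idx <- floor((s$position - 1) / window_size)
  key <- paste(chrom, idx, sep = "\r")
  agg <- data.frame(key = unique(key))
  first <- match(agg$key, key)
  agg$chrom <- chrom[first]
  agg$idx <- idx[first]
  agg$n_snps <- as.integer(tapply(s$position, key, length)[agg$key])
  agg$mean_abs_ihs <- as.numeric(tapply(abs(s$ihs_std), key, mean)[agg$key])
  agg$abs_mean_ihs <- abs(as.numeric(tapply(s$ihs_std, key, mean)[agg$key]))
  out <- data.frame(chrom = agg$chrom, start = agg$idx * window_size + 1,
                    end = agg$idx * window_size + window_size + 1,
                    n_snps = agg$n_snps, mean_abs_ihs = agg$mean_abs_ihs,
                    abs_mean_ihs = agg$abs_mean_ihs)
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Drop sparsely covered windows
#'
#' Keeps windows supported by at least `min_snps` valid scored sites; a scan
#' statistic averaged over very few SNPs is noise-dominated.
#'
#' @param windows data frame from [bin_scores()].
#' @param min_snps minimum SNP count (default 10; a window with exactly 10 is
#'   kept).
#' @return The surviving windows, with attribute `n_dropped`.
#' @export
filter_windows <- function(windows, min_snps = 10L) {
  keep <- windows$n_snps >= min_snps
  out <- windows[keep, , drop = FALSE]
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Call the top-fraction candidate selection regions
#'
#' Ranks SNP-count-filtered windows by `mean_abs_ihs` and returns the top
#' `floor(fraction * n)` as candidate selection regions, together with the
#' realized |iHS| threshold (the smallest selected window statistic). Ties at
#' the selection boundary are broken by (chrom, start) order with a warning.
#'
#' @param windows data frame from [filter_windows()].
#' @param fraction fraction of windows to select (default 0.01, the top 1%).
#' @return A data frame of selected windows with `rank` and `threshold`
#'   columns added, ordered by decreasing `mean_abs_ihs`; attribute
#'   `threshold` also carries the realized cutoff. Zero selectable windows
#'   give an empty result with a warning.
#' @examples
#' w <- data.frame(chrom = "1", start = (0:199) * 50000 + 1,
#'                 end = (0:199) * 50000 + 50001, n_snps = 20,
#'                 mean_abs_ihs = seq(0, 2, length.out = 200),
#'                 abs_mean_ihs = 0)
#' select_top(w)   # floor(0.01 * 200) = 2 windows
#' @export
select_top <- function(windows, fraction = 0.01) {
  n <- nrow(windows)
  k <- floor(fraction * n)
  if (k < 1L) {
    warning(sprintf("top fraction %.3g of %d windows selects none", fraction, n))
    out <- windows[integer(0), , drop = FALSE]
    out$rank <- integer(0)
    out$threshold <- numeric(0)
    attr(out, "threshold") <- NA_real_
    return(out)
  }
  o <- order(-windows$mean_abs_ihs, windows$chrom, windows$start)
  ranked <- windows[o, , drop = FALSE]
  cut_stat <- ranked$mean_abs_ihs[k]
  if (k < n && isTRUE(all.equal(ranked$mean_abs_ihs[k + 1L], cut_stat)))
    warning("ties at the selection boundary broken by (chrom, start) order")
  out <- ranked[seq_len(k), , drop = FALSE]
  out$rank <- seq_len(k)
  out$threshold <- cut_stat
  rownames(out) <- NULL
  attr(out, "threshold") <- cut_stat
  out
}
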