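#' Standardize iHS scores within derived-allele-frequency bins
#'
#' Unstandardized `ln(iHH_A/iHH_D)` depends strongly on the derived allele
#' frequency. Scores are therefore binned by derived frequency into `n_bins`
#' equal-width bins on (0, 1) and centred and scaled within bins:
#' `ihs_std = (uihs - E_p) / SD_p`, with the sample mean and the `n - 1`
#' standard deviation of each bin. Bins holding fewer than two valid scores
#' (or with zero spread) are merged with their nearest occupied
#' lower-frequency neighbour, or the next higher one at the low end.
#'
#' @param scores data frame from [unstandardized_ihs()] rows (needs columns
#'   `derived_freq`, `uihs`, `valid`).
#' @param n_bins number of equal-width frequency bins (default 100).
#' @return A list: `scores` (input plus `bin_index` and `ihs_std`; invalid
#'   rows keep `NA`) and `bins` (per retained bin: frequency range, count,
#'   `E_p`, `SD_p`).
#' @export
standardize_ihs <- function(scores, n_bins = 100L) {
  stopifnot(is.data.frame(scores),
            all(c("derived_freq", "uihs", "valid") %in% names(scores)))
  ok <- which(scores$valid)
  if (!length(ok))
    stop("no valid scores to standardize")
  raw_bin <- pmin(n_bins, pmax(1L, ceiling(scores$derived_freq * n_bins)))

  ## merge underpopulated/degenerate bins into a neighbour until stable
  binmap <- seq_len(n_bins)
  repeat {
    b <- binmap[raw_bin[ok]]
    tab <- table(b)
    ids <- as.integer(names(tab))
    sds <- vapply(ids, function(i) stats::sd(scores$uihs[ok][b == i]), numeric(1))
    bad <- ids[tab < 2L | (!is.na(sds) & sds == 0)]
    if (!length(bad)) break
    if (length(ids) == 1L)
      stop("cannot standardize: a single degenerate frequency bin remains")
    b0 <- bad[1L]
    lower <- ids[ids < b0]
    target <- if (length(lower)) max(lower) else min(ids[ids > b0])
    binmap[binmap == b0] <- target
  }

  fin <- binmap[raw_bin]
  scores$bin_index <- NA_integer_
  scores$bin_index[ok] <- fin[ok]
  scores$ihs_std <- NA_real_
  ids <- sort(unique(fin[ok]))
  bins <- data.frame(bin = ids, freq_lo = NA_real_, freq_hi = NA_real_,
                     n = NA_integer_, E_p = NA_real_, SD_p = NA_real_)
  for (r in seq_along(ids)) {
    i <- ids[r]
    members <- which(binmap == i)           # original bins folded into i
    sel <- ok[fin[ok] == i]
    mu <- mean(scores$uihs[sel])
    sg <- stats::sd(scores$uihs[sel])
    scores$ihs_std[sel] <- (scores$uihs[sel] - mu) / sg
    bins[r, c("freq_lo", "freq_hi")] <- c((min(members) - 1) / n_bins,
                                          max(members) / n_bins)
    bins$n[r] <- length(sel)
    bins$E_p[r] <- mu
    bins$SD_p[r] <- sg
  }
  list(scores = scores, bins = bins)
}

#' Genome-wide iHS scan
#'
#' Fits the integrated haplotype score over every site of a QC-clean phased
#' haplotype matrix: per-site EHH curves in both directions for both alleles,
#' trapezoidal iHH integrals, the log-ratio `ln(iHH_A/iHH_D)`, and
#' frequency-bin standardization. Sites where either allele has fewer than
#' two called carriers, an inter-site gap exceeds `max_gap_bp`, or an EHH
#' curve runs off the chromosome before decaying below `ehh_cutoff` are
#' flagged invalid with a reason and excluded from standardization.
#'
#' Standardization is genome-wide: with a multi-chromosome input the
#' log-ratios of all chromosomes are pooled before frequency-bin
#' standardization, as the frequency bins must be anchored by genome-wide
#' (predominantly neutral) variation.
#'
#' @param hm a [haplo_matrix()], normally the output of [apply_qc()], or a
#'   list of them (one per chromosome, distinct chromosome names).
#' @param ehh_cutoff EHH truncation level (default 0.05).
#' @param max_gap_bp maximum tolerated spacing between consecutive sites
#'   (default 800,000 bp).
#' @param max_extend_bp maximum EHH extension distance from a core site
#'   (default 1 Mb); see [ehh()].
#' @param n_bins derived-frequency standardization bins (default 100).
#' @return An object of class `ihs_scan`: list with `scores` (one row per
#'   site: `chrom`, `position`, `derived_freq`, `ihh_a`, `ihh_d`, `uihs`,
#'   `bin_index`, `ihs_std`, `valid`, `reason`), `bins`, `chrom`,
#'   `n_haplotypes`, `params` and `call`. Methods: `print`, `summary`,
#'   `plot`, `as.data.frame`.
#' @examples
#' sim <- simulate_population(sim_params(n_diploids = 40, n_generations = 60,
#'                                       seq_length = 2e5, mu = 5e-6,
#'                                       rho = 5e-6, sample_n = 20,
#'                                       missing_rate = 0, seed = 2))
#' fit <- ihs_scan(sim$hm)
#' fit
#' @export
ihs_scan <- function(hm, ehh_cutoff = 0.05, max_gap_bp = 800000,
                     max_extend_bp = 1e6, n_bins = 100L) {
  hml <- if (inherits(hm, "haplo_matrix")) list(hm) else hm
  stopifnot(all(vapply(hml, inherits, logical(1), "haplo_matrix")))
  chroms <- vapply(hml, `[[`, "", "chrom")
  if (anyDuplicated(chroms))
    stop("chromosome names must be distinct across matrices")
  scores <- do.call(rbind, lapply(hml, function(h) {
    m <- ncol(h$alleles)
    if (m < 2L)
      stop("need at least two sites per chromosome to scan")
    out <- do.call(rbind, lapply(seq_len(m), function(j)
      unstandardized_ihs(h, j, ehh_cutoff = ehh_cutoff,
                         max_gap_bp = max_gap_bp,
                         max_extend_bp = max_extend_bp)))
    cbind(chrom = h$chrom, out)
  }))
  std <- standardize_ihs(scores, n_bins = n_bins)
  structure(list(scores = std$scores, bins = std$bins,
                 chrom = paste(chroms, collapse = ","),
                 n_haplotypes = nrow(hml[[1L]]$alleles),
                 params = list(ehh_cutoff = ehh_cutoff,
                               max_gap_bp = max_gap_bp,
                               max_extend_bp = max_extend_bp,
                               n_bins = n_bins),
                 call = match.call()),
            class = "ihs_scan")
}

#' @export
print.ihs_scan <- function(x, ...) {
  s <- x$scores
  cat(sprintf("iHS scan of chromosome %s: %d sites, %d haplotypes\n",
              x$chrom, nrow(s), x$n_haplotypes))
  cat(sprintf("  %d valid scores in %d frequency bins; EHH cutoff %.2g, max gap %s bp\n",
              sum(s$valid), nrow(x$bins), x$params$ehh_cutoff,
              format(x$params$max_gap_bp, big.mark = ",")))
  if (any(s$valid)) {
    i <- which.max(abs(s$ihs_std))
    cat(sprintf("  largest |iHS| = %.2f at %s bp\n", abs(s$ihs_std[i]),
                format(s$position[i], big.mark = ",")))
  }
  invisible(x)
}

#' @export
summary.ihs_scan <- function(object, ...) {
  s <- object$scores
  reasons <- table(s$reason[!s$valid], useNA = "no")
  out <- list(n_sites = nrow(s), n_valid = sum(s$valid),
              invalid_reasons = reasons,
              ihs_quantiles = stats::quantile(s$ihs_std[s$valid],
                                              c(0, .05, .25, .5, .75, .95, 1)),
              frac_extreme = mean(abs(s$ihs_std[s$valid]) > 2),
              bins = object$bins, chrom = object$chrom)
  class(out) <- "summary.ihs_scan"
  out
}

#' @export
print.summary.ihs_scan <- function(x, ...) {
  cat(sprintf("iHS scan summary (chromosome %s)\n", x$chrom))
  cat(sprintf("  sites: %d scored, %d valid (%.1f%%)\n", x$n_sites, x$n_valid,
              100 * x$n_valid / x$n_sites))
  if (length(x$invalid_reasons)) {
    cat("  invalid by reason:",
        paste(sprintf("%s=%d", names(x$invalid_reasons), x$invalid_reasons),
              collapse = ", "), "\n")
  }
  cat("  standardized iHS quantiles:\n")
  print(round(x$ihs_quantiles, 3))
  cat(sprintf("  fraction with |iHS| > 2: %.3f (about 0.046 under normality)\n",
              x$frac_extreme))
  invisible(x)
}

#' @export
as.data.frame.ihs_scan <- function(x, ...) x$scores

#' Manhattan-style plot of an iHS scan
#'
#' @param x an [ihs_scan()] object.
#' @param windows optional window data frame from [bin_scores()] /
#'   [select_top()]; selected windows are shaded.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ihs_scan <- function(x, windows = NULL, ...) {
  s <- x$scores[x$scores$valid, ]
  graphics::plot(s$position / 1e6, abs(s$ihs_std), pch = 16, cex = 0.4,
                 col = "grey30", xlab = sprintf("position on %s (Mb)", x$chrom),
                 ylab = "|iHS|", ...)
  if (!is.null(windows) && nrow(windows)) {
    sel <- if ("selected" %in% names(windows)) windows[windows$selected, ] else windows
    if (nrow(sel))
      graphics::rect(sel$start / 1e6, 0, sel$end / 1e6,
                     max(abs(s$ihs_std)), col = grDevices::adjustcolor("firebrick", 0.2),
                     border = NA)
  }
  invisible(x)
}
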