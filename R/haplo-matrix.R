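#' Phased haplotype matrix
#'
#' Container for phased, biallelic, ancestrally polarized haplotypes on a
#' single chromosome: an `n_haplotypes x n_sites` integer matrix with values
#' 0 (ancestral), 1 (derived) or `NA` (missing call), plus strictly
#' increasing 1-based physical positions. Two consecutive rows form one
#' phased diploid individual, so the number of rows must be even.
#'
#' @param alleles integer matrix, haplotypes in rows, sites in columns;
#'   entries 0, 1 or `NA`.
#' @param positions integer vector of strictly increasing 1-based bp
#'   coordinates, one per column of `alleles`.
#' @param chrom single chromosome name.
#' @param sample_ids optional character vector of diploid sample names,
#'   length `nrow(alleles)/2`; generated as `ind1, ind2, ...` when omitted.
#'
#' @return An object of class `haplo_matrix`: a list with elements
#'   `alleles`, `positions`, `chrom`, `sample_ids`.
#' @examples
#' hm <- haplo_matrix(rbind(c(0, 1), c(1, 1), c(0, 0), c(0, 1)),
#'                    positions = c(100L, 250L), chrom = "1")
#' hm
#' @export
haplo_matrix <- function(alleles, positions, chrom = "1", sample_ids = NULL) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (ncol(alleles) != length(positions))
    stop("number of columns of 'alleles' must equal length(positions)")
  if (nrow(alleles) %% 2L != 0L)
    stop("number of haplotypes must be even (phased diploids)")
  positions <- as.integer(positions)
  if (length(positions) > 1L && any(diff(positions) <= 0L))
    stop("'positions' must be strictly increasing")
  bad <- alleles[!is.na(alleles)]
  if (length(bad) && !all(bad %in% c(0L, 1L)))
    stop("allele values must be 0, 1 or NA")
  if (is.null(sample_ids))
    sample_ids <- paste0("ind", seq_len(nrow(alleles) / 2L))
  if (length(sample_ids) != nrow(alleles) / 2L)
    stop("'sample_ids' must have one entry per diploid individual")
  structure(list(alleles = alleles, positions = positions,
                 chrom = as.character(chrom)[1L],
                 sample_ids = as.character(sample_ids)),
            class = "haplo_matrix")
}

#' @export
dim.haplo_matrix <- function(x) dim(x$alleles)

#' @export
print.haplo_matrix <- function(x, ...) {
  d <- dim(x$alleles)
  miss <- mean(is.na(x$alleles))
  cat(sprintf("haplo_matrix: %d haplotypes (%d diploids) x %d sites on chromosome %s\n",
              d[1L], d[1L] / 2L, d[2L], x$chrom))
  if (d[2L] > 0L)
    cat(sprintf("  positions %s..%s bp, %.2f%% missing calls\n",
                format(min(x$positions), big.mark = ","),
                format(max(x$positions), big.mark = ","), 100 * miss))
  invisible(x)
}

#' Subset sites of a haplotype matrix
#'
#' @param hm a [haplo_matrix()].
#' @param keep logical or integer index over sites (columns).
#' @return A `haplo_matrix` restricted to the selected sites.
#' @export
subset_sites <- function(hm, keep) {
  stopifnot(inherits(hm, "haplo_matrix"))
  haplo_matrix(hm$alleles[, keep, drop = FALSE], hm$positions[keep],
               hm$chrom, hm$sample_ids)
}

## derived-allele frequency per site, ignoring missing calls
derived_freq <- function(hm) {
  colMeans(hm$alleles, na.rm = TRUE)
}

## minor allele frequency per site
site_maf <- function(hm) {
  f <- derived_freq(hm)
  pmin(f, 1 - f)
}
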