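#' Exact two-sided Hardy-Weinberg test
#'
#' Exact test of Hardy-Weinberg proportions for a biallelic site. Conditional
#' on the observed allele counts, the number of heterozygotes follows a known
#' exact distribution; the two-sided p-value sums the probabilities of all
#' heterozygote counts no more probable than the observed one. Probabilities
#' are computed by the standard ratio recurrence in the heterozygote count,
#' which is numerically stable for large samples.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative, at least one
#'   individual in total).
#' @return The exact p-value. Monomorphic samples give 1. The test is
#'   symmetric in `n_AA` and `n_aa`.
#' @examples
#' hwe_exact_test(20, 10, 20)   # heterozygote deficit
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("at least one genotype required")
  nA <- 2 * n_AA + n_Aa          # minor/major labelling is irrelevant
  na <- 2 * n_aa + n_Aa
  if (nA == 0 || na == 0) return(1)
  rare <- min(nA, na)
  het <- seq.int(rare %% 2, rare, by = 2)  # feasible heterozygote counts

  ## P(k+2)/P(k) = 4 * nAA(k) * naa(k) / ((k+2)*(k+1)) with
  ## nAA(k) = (nA - k)/2, naa(k) = (na - k)/2 (homozygotes at het count k)
  logp <- numeric(length(het))
  for (i in seq_along(het)[-1L]) {
    k <- het[i - 1L]
    logp[i] <- logp[i - 1L] +
      log(4 * ((nA - k) / 2) * ((na - k) / 2)) - log((k + 2) * (k + 1))
  }
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_Aa, het)]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

#' GATK-style INFO threshold filter
#'
#' Evaluates hard thresholds on variant-level INFO annotations: a site fails
#' when QD < 2.0, FS > 60.0, MQ < 40.0, MQRankSum < -12.5 or
#' ReadPosRankSum < -8.0. Boundary values pass (the inequalities are strict).
#' Absent annotations pass by default; with `strict = TRUE` an absent
#' annotation fails.
#'
#' @param info a named numeric vector / list of INFO values, or a single raw
#'   INFO string such as `"QD=1.2;MQ=60"`.
#' @param strict fail fields that are absent.
#' @return Named logical vector of per-field passes, with attribute `pass`
#'   giving the overall verdict (all fields pass).
#' @export
filter_info_thresholds <- function(info, strict = FALSE) {
  rules <- list(QD = c(-1, 2.0), FS = c(1, 60.0), MQ = c(-1, 40.0),
                MQRankSum = c(-1, -12.5), ReadPosRankSum = c(-1, -8.0))
  if (is.character(info) && length(info) == 1L && is.null(names(info))) {
    fields <- strsplit(info, ";", fixed = TRUE)[[1L]]
    kv <- strsplit(fields, "=", fixed = TRUE)
    info <- stats::setNames(lapply(kv, function(x) if (length(x) > 1L) x[2L] else NA),
                            vapply(kv, `[`, "", 1L))
  }
  if (!is.list(info)) info <- as.list(info)
  out <- stats::setNames(logical(length(rules)), names(rules))
  for (f in names(rules)) {
    if (is.null(info[[f]]) || is.na(info[[f]])) {
      out[f] <- !strict
      next
    }
    val <- suppressWarnings(as.numeric(info[[f]]))
    if (is.na(val))
      stop(sprintf("non-numeric INFO value for %s: '%s'", f, info[[f]]))
    sgn <- rules[[f]][1L]
    out[f] <- !(sgn * val > sgn * rules[[f]][2L])  # fail iff beyond threshold
  }
  attr(out, "pass") <- all(out)
  out
}

#' Site-level quality control
#'
#' Applies the site filters of a resequencing scan to a haplotype matrix, in
#' this order: GATK INFO thresholds (when INFO is available on the matrix),
#' missing rate, minor allele frequency, exact Hardy-Weinberg test. A site is
#' removed when its missing rate exceeds `max_missing` (strictly), its MAF is
#' below `maf` (strictly), or its HWE p-value is below `hwe_p`. Each filter is
#' a per-site predicate, so the retained set does not depend on filter order;
#' the report attributes each removed site to the first failed filter.
#'
#' @param hm a [haplo_matrix()]; biallelic enforcement happens at read time
#'   in [read_phased_vcf()].
#' @param max_missing maximum tolerated per-site missing call fraction
#'   (default 0.10; exactly 0.10 is kept).
#' @param maf minimum minor allele frequency (default 0.05; exactly 0.05 is
#'   kept).
#' @param hwe_p minimum exact HWE p-value (default 1e-6).
#' @param info_strict passed to [filter_info_thresholds()].
#' @return A list with `hm` (the filtered matrix) and `report`, a data frame
#'   with one row per input site: `position`, `missing_rate`, `maf`, `hwe_p`,
#'   `info_pass`, `kept` and `fail_reason` (`NA` for kept sites).
#' @export
apply_qc <- function(hm, max_missing = 0.10, maf = 0.05, hwe_p = 1e-6,
                     info_strict = FALSE) {
  stopifnot(inherits(hm, "haplo_matrix"))
  m <- ncol(hm$alleles)
  if (m == 0L) {
    rep0 <- data.frame(position = integer(0), missing_rate = numeric(0),
                       maf = numeric(0), hwe_p = numeric(0),
                       info_pass = logical(0), kept = logical(0),
                       fail_reason = character(0))
    return(list(hm = hm, report = rep0))
  }
  miss <- colMeans(is.na(hm$alleles))
  mafv <- site_maf(hm)

  info <- attr(hm, "site_info")
  info_pass <- rep(TRUE, m)
  if (!is.null(info))
    info_pass <- vapply(info, function(s)
      attr(filter_info_thresholds(s, strict = info_strict), "pass"),
      logical(1), USE.NAMES = FALSE)

  odd <- seq(1L, nrow(hm$alleles), 2L)
  hwe <- vapply(seq_len(m), function(j) {
    a1 <- hm$alleles[odd, j]
    a2 <- hm$alleles[odd + 1L, j]
    ok <- !is.na(a1) & !is.na(a2)       # HWE uses fully called genotypes
    g <- a1[ok] + a2[ok]
    if (!length(g)) return(1)
    hwe_exact_test(sum(g == 0L), sum(g == 1L), sum(g == 2L))
  }, numeric(1))

  fail_reason <- rep(NA_character_, m)
  fail_reason[is.na(fail_reason) & !info_pass] <- "info"
  fail_reason[is.na(fail_reason) & miss > max_missing] <- "missing_rate"
  fail_reason[is.na(fail_reason) & mafv < maf] <- "maf"
  fail_reason[is.na(fail_reason) & hwe < hwe_p] <- "hwe"
  kept <- is.na(fail_reason)

  report <- data.frame(position = hm$positions, missing_rate = miss,
                       maf = mafv, hwe_p = hwe, info_pass = info_pass,
                       kept = kept, fail_reason = fail_reason)
  if (!any(kept))
    warning("no sites survive QC")
  out <- subset_sites(hm, kept)
  if (!is.null(info)) attr(out, "site_info") <- info[kept]
  list(hm = out, report = report)
}
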