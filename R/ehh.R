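#' Extended haplotype homozygosity from a core allele
#'
#' Walks outward from a core site among the carriers of one core allele and,
#' at each successive site, partitions carriers by their extended haplotype
#' (all alleles from the core through that site). EHH at distance x is the
#' probability that two distinct carriers drawn at random are identical over
#' the whole stretch: `sum_h C(n_h, 2) / C(n_c, 2)` over haplotype groups h.
#' The walk stops when EHH drops below `ehh_cutoff` (the sub-cutoff point is
#' recorded), at the last site of the chromosome, or when the physical gap to
#' the next site exceeds `max_gap_bp`.
#'
#' A missing call places its haplotype in a singleton group from that site
#' on: sharing is broken conservatively, biasing EHH downward. Haplotypes
#' with a missing call at the core are not carriers.
#'
#' @param hm a [haplo_matrix()], ideally QC-filtered.
#' @param core_index column index of the core site.
#' @param core_allele `0` (ancestral) or `1` (derived).
#' @param direction `"downstream"` (increasing position) or `"upstream"`.
#' @param ehh_cutoff stop once EHH falls below this value (default 0.05).
#' @param max_gap_bp maximum tolerated spacing between consecutive sites
#'   during extension (default 800,000 bp); a larger gap truncates the curve
#'   and invalidates the core site.
#' @param max_extend_bp maximum extension distance from the core (default
#'   1 Mb, the conventional scan limit); a curve still above the cutoff at
#'   this distance is treated like one that ran off the chromosome.
#' @return A list of class `ehh_curve`: `points` (data frame with
#'   `distance_bp`, `ehh`, first row `(0, 1)`), `status` (`"cutoff"`,
#'   `"chrom_end"`, `"gap"` or `"max_extend"`), `core_position`,
#'   `core_allele`, `direction`, `n_carriers`.
#' @export
ehh <- function(hm, core_index, core_allele, direction = c("downstream", "upstream"),
                ehh_cutoff = 0.05, max_gap_bp = 800000, max_extend_bp = 1e6) {
  stopifnot(inherits(hm, "haplo_matrix"), core_allele %in% c(0L, 1L))
  direction <- match.arg(direction)
  A <- hm$alleles
  pos <- hm$positions
  carriers <- which(!is.na(A[, core_index]) & A[, core_index] == core_allele)
  n_c <- length(carriers)
  if (n_c < 2L)
    stop(sprintf("fewer than 2 carriers of allele %d at site %d", core_allele,
                 core_index))
  step <- if (direction == "downstream") 1L else -1L
  w <- ehh_walk(A, carriers, core_index, step, as.numeric(pos),
                ehh_cutoff, max_gap_bp, max_extend_bp)
  structure(list(points = data.frame(distance_bp = w$distance_bp,
                                     ehh = w$ehh),
                 status = c("chrom_end", "cutoff", "gap",
                            "max_extend")[w$status + 1L],
                 core_position = pos[core_index],
                 core_allele = core_allele, direction = direction,
                 n_carriers = n_c),
            class = "ehh_curve")
}

#' @export
print.ehh_curve <- function(x, ...) {
  cat(sprintf("EHH curve: %s allele at %s bp, %s, %d carriers, %d points (%s)\n",
              if (x$core_allele == 0L) "ancestral" else "derived",
              format(x$core_position, big.mark = ","), x$direction,
              x$n_carriers, nrow(x$points), x$status))
  invisible(x)
}

## trapezoidal area under one EHH curve against physical distance
trapezoid_area <- function(points) {
  n <- nrow(points)
  if (n < 2L) return(0)
  d <- diff(points$distance_bp)
  sum(d * (points$ehh[-n] + points$ehh[-1L]) / 2)
}

#' Integrated haplotype homozygosity
#'
#' Integrates EHH against physical distance (trapezoidal rule) over both
#' directions from the core. Each curve is truncated at the first recorded
#' point below the EHH cutoff; the final trapezoid ending at that point is
#' included. Curves truncated by a large inter-site gap or by the chromosome
#' end before reaching the cutoff do not yield a usable integral.
#'
#' @param curve_up,curve_down [ehh()] curves for the two directions from the
#'   same core site and allele.
#' @return A list: `value` (bp-weighted homozygosity; `NA` when invalid),
#'   `valid`, `reason` (`NA`, `"gap"` or `"edge"`).
#' @export
ihh <- function(curve_up, curve_down) {
  stopifnot(inherits(curve_up, "ehh_curve"), inherits(curve_down, "ehh_curve"))
  for (cv in list(curve_up, curve_down)) {
    if (cv$status == "gap")
      return(list(value = NA_real_, valid = FALSE, reason = "gap"))
    if (cv$status %in% c("chrom_end", "max_extend"))
      return(list(value = NA_real_, valid = FALSE, reason = "edge"))
  }
  list(value = trapezoid_area(curve_up$points) +
         trapezoid_area(curve_down$points),
       valid = TRUE, reason = NA_character_)
}

#' Unstandardized iHS at one site
#'
#' Computes `ln(iHH_A / iHH_D)`, the log-ratio of the integrated haplotype
#' homozygosity of the ancestral and derived alleles at a core site. The
#' score is invalid when either allele has fewer than 2 called carriers, any
#' of the four EHH curves is gap- or edge-truncated, or either integral is
#' zero.
#'
#' @inheritParams ehh
#' @return A one-row data frame: `position`, `derived_freq`, `ihh_a`,
#'   `ihh_d`, `uihs`, `valid`, `reason`.
#' @export
unstandardized_ihs <- function(hm, core_index, ehh_cutoff = 0.05,
                               max_gap_bp = 800000, max_extend_bp = 1e6) {
  a <- hm$alleles[, core_index]
  called <- !is.na(a)
  n_der <- sum(a[called] == 1L)
  n_anc <- sum(called) - n_der
  out <- data.frame(position = hm$positions[core_index],
                    derived_freq = if (sum(called)) n_der / sum(called) else NA_real_,
                    ihh_a = NA_real_, ihh_d = NA_real_, uihs = NA_real_,
                    valid = FALSE, reason = NA_character_)
  if (n_anc < 2L || n_der < 2L) {
    out$reason <- "carriers"
    return(out)
  }
  for (allele in c(0L, 1L)) {
    up <- ehh(hm, core_index, allele, "upstream", ehh_cutoff, max_gap_bp,
              max_extend_bp)
    dn <- ehh(hm, core_index, allele, "downstream", ehh_cutoff, max_gap_bp,
              max_extend_bp)
    ih <- ihh(up, dn)
    if (!ih$valid) {
      out$reason <- ih$reason
      return(out)
    }
    if (allele == 0L) out$ihh_a <- ih$value else out$ihh_d <- ih$value
  }
  if (out$ihh_a <= 0 || out$ihh_d <= 0) {
    out$reason <- "zero_ihh"
    return(out)
  }
  out$uihs <- log(out$ihh_a) - log(out$ihh_d)   # exactly antisymmetric
  out$valid <- TRUE
  out
}
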