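## the six trait classes of the cattle QTL database
qtl_trait_classes <- c("Exterior", "Health", "Meat and Carcass", "Milk",
                       "Production", "Reproduction")

#' Read a QTL annotation table
#'
#' Reads a tab-separated QTL table with columns `chrom`, `start_1based`,
#' `end_1based`, `trait_name`, `trait_class` (the layout produced by
#' flattening the animal QTL database GFF dialect: one row per QTL interval,
#' with the trait name and its class). Trait classes must come from the six
#' canonical categories.
#'
#' @param path TSV file.
#' @return Data frame with `chrom`, `start`, `end` (1-based inclusive),
#'   `trait_name`, `trait_class`.
#' @export
read_qtl_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start_1based", "end_1based", "trait_name", "trait_class")
  if (!all(need %in% names(df)))
    stop("QTL table must have columns: ", paste(need, collapse = ", "))
  bad <- which(!(df$trait_class %in% qtl_trait_classes))
  if (length(bad))
    stop(sprintf("unknown trait_class '%s' in QTL table row %d",
                 df$trait_class[bad[1L]], bad[1L]))
  data.frame(chrom = as.character(df$chrom), start = df$start_1based,
             end = df$end_1based, trait_name = df$trait_name,
             trait_class = df$trait_class)
}

#' Overlap candidate regions with QTL intervals
#'
#' Finds the QTL records overlapping candidate selection regions by at least
#' one base (each QTL counted once however many regions it touches) and
#' summarizes the overlapping set as per-class and per-trait percentages.
#'
#' @param regions data frame with `chrom`, `start`, `end`.
#' @param qtls data frame from [read_qtl_table()].
#' @param label_end_exclusive treat `regions$end` as exclusive (window-label
#'   convention; see [intersect_regions()]).
#' @return A list: `overlap` (the overlapping QTL rows), `n_overlap`,
#'   `class_percent` (named percentages over the overlapping QTLs),
#'   `trait_percent`.
#' @export
annotate_qtls <- function(regions, qtls, label_end_exclusive = TRUE) {
  bad <- which(!(qtls$trait_class %in% qtl_trait_classes))
  if (length(bad))
    stop(sprintf("unknown trait_class '%s' in QTL row %d",
                 qtls$trait_class[bad[1L]], bad[1L]))
  reg <- regions
  if (label_end_exclusive) reg$end <- reg$end - 1
  hit <- rep(FALSE, nrow(qtls))
  if (nrow(regions) && nrow(qtls)) {
    ov <- GenomicRanges::findOverlaps(as_granges(qtls), as_granges(reg),
                                      minoverlap = 1L)
    hit[unique(S4Vectors::queryHits(ov))] <- TRUE
  }
  overlap <- qtls[hit, , drop = FALSE]
  pct <- function(x) {
    if (!nrow(overlap)) return(numeric(0))
    100 * sort(table(x), decreasing = TRUE) / nrow(overlap)
  }
  list(overlap = overlap, n_overlap = nrow(overlap),
       class_percent = pct(overlap$trait_class),
       trait_percent = pct(overlap$trait_name))
}

#' Per-trait QTL enrichment of candidate regions
#'
#' Tests every trait represented in the QTL database for over-representation
#' among the QTLs overlapping candidate regions, with the one-sided
#' hypergeometric (Fisher) upper-tail test:
#' `p = P(X >= x)` with `X ~ Hypergeom(N = n_db, K = n_trait_db,
#' n = n_overlap_total)`. The richness factor is the trait's share among
#' overlapping QTLs divided by its share in the whole database. P-values are
#' Benjamini-Hochberg adjusted across all tested traits; traits with
#' `fdr < fdr_cutoff` are flagged significant.
#'
#' @param overlap data frame of overlapping QTLs (element `overlap` of
#'   [annotate_qtls()]).
#' @param qtl_db the full QTL table ([read_qtl_table()]).
#' @param by group by `"trait_name"` (default) or `"trait_class"`.
#' @param fdr_cutoff significance threshold on the adjusted p-value
#'   (default 0.05).
#' @return Data frame, one row per trait, ordered by p-value: `trait`,
#'   `trait_class`, `n_overlap`, `n_overlap_total`, `n_trait_db`, `n_db`,
#'   `richness_factor`, `p_value`, `fdr`, `significant`.
#' @export
qtl_enrich <- function(overlap, qtl_db, by = c("trait_name", "trait_class"),
                       fdr_cutoff = 0.05) {
  by <- match.arg(by)
  if (!nrow(overlap))
    stop("no overlapping QTLs; enrichment is undefined")
  if (!all(overlap[[by]] %in% qtl_db[[by]]))
    stop("overlapping QTL trait absent from the database table")
  N <- nrow(qtl_db)
  n_tot <- nrow(overlap)
  traits <- sort(unique(qtl_db[[by]]))
  K <- vapply(traits, function(t) sum(qtl_db[[by]] == t), numeric(1))
  x <- vapply(traits, function(t) sum(overlap[[by]] == t), numeric(1))
  p <- stats::phyper(x - 1, K, N - K, n_tot, lower.tail = FALSE)
  rf <- (x / n_tot) / (K / N)
  cls <- if (by == "trait_class") traits else
    qtl_db$trait_class[match(traits, qtl_db$trait_name)]
  out <- data.frame(trait = traits, trait_class = cls, n_overlap = x,
                    n_overlap_total = n_tot, n_trait_db = K, n_db = N,
                    richness_factor = rf, p_value = p,
                    fdr = stats::p.adjust(p, method = "BH"))
  out$significant <- out$fdr < fdr_cutoff
  out <- out[order(out$p_value, out$trait), , drop = FALSE]
  rownames(out) <- NULL
  out
}
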