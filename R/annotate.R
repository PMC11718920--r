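#' Read gene annotations from BED or GTF
#'
#' Imports gene intervals with `rtracklayer`. BED input is interpreted as
#' 0-based half-open and GTF as 1-based inclusive, both normalized to the
#' 1-based inclusive convention used internally (so BED `chr1 100 200` and a
#' GTF gene at 101..200 become the same interval). GTF rows are restricted to
#' feature type `gene`; `gene_name` falls back to `gene_id` when absent.
#'
#' @param path annotation file.
#' @param format `"BED"` or `"GTF"`; guessed from the file extension when
#'   omitted.
#' @return Data frame with `chrom`, `start`, `end` (1-based inclusive),
#'   `gene_id`, `gene_name`.
#' @export
read_gene_annotation <- function(path, format = c("auto", "BED", "GTF")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(gtf|gff2?)(\\.gz)?$", path, ignore.case = TRUE))
      "GTF" else "BED"
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = tolower(format)),
    error = function(e) stop(sprintf("failed to parse %s file '%s': %s",
                                     format, path, conditionMessage(e))))
  if (format == "GTF") {
    ty <- as.character(gr$type)
    gr <- gr[!is.na(ty) & ty == "gene"]
    if (!length(gr))
      warning("no 'gene' feature rows in GTF; returning an empty gene list")
  }
  md <- S4Vectors::mcols(gr)
  gene_id <- if ("gene_id" %in% names(md)) as.character(md$gene_id)
    else if ("name" %in% names(md)) as.character(md$name)
    else paste0("feature", seq_along(gr))
  gene_name <- if ("gene_name" %in% names(md)) as.character(md$gene_name)
    else rep(NA_character_, length(gr))
  gene_name <- ifelse(is.na(gene_name) | !nzchar(gene_name), gene_id, gene_name)
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             gene_id = gene_id, gene_name = gene_name)
}

## 1-based inclusive data frame -> GRanges
as_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start, end = df$end))
}

#' Intersect candidate regions with gene annotations
#'
#' Reports, for every candidate region, the genes overlapping it by at least
#' one base (the `bedtools intersect` default). Window labels produced by
#' [bin_scores()] use `end = start + window_size`, i.e. the labelled end base
#' is exclusive; set `label_end_exclusive = TRUE` (default) to intersect on
#' the true 50,000 bp span so that a gene merely abutting a region does not
#' count as overlapping.
#'
#' @param regions data frame with `chrom`, `start`, `end` (e.g. from
#'   [select_top()]).
#' @param genes data frame from [read_gene_annotation()].
#' @param label_end_exclusive treat `regions$end` as exclusive.
#' @return A list: `table` (one row per region x overlapping gene, regions
#'   without genes keep one row with `NA` gene), `n_regions`,
#'   `n_regions_with_genes`, `n_distinct_genes`, `genes` (sorted distinct
#'   gene names).
#' @export
intersect_regions <- function(regions, genes, label_end_exclusive = TRUE) {
  stopifnot(all(c("chrom", "start", "end") %in% names(regions)),
            all(c("chrom", "start", "end") %in% names(genes)))
  reg <- regions
  if (label_end_exclusive) reg$end <- reg$end - 1
  if (nrow(genes)) {
    hits <- GenomicRanges::findOverlaps(as_granges(reg), as_granges(genes),
                                        minoverlap = 1L)
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
  } else {
    qh <- sh <- integer(0)
  }
  rows <- lapply(seq_len(nrow(regions)), function(i) {
    g <- sh[qh == i]
    if (!length(g))
      return(data.frame(chrom = regions$chrom[i], start = regions$start[i],
                        end = regions$end[i], gene_id = NA_character_,
                        gene_name = NA_character_))
    data.frame(chrom = regions$chrom[i], start = regions$start[i],
               end = regions$end[i], gene_id = genes$gene_id[g],
               gene_name = genes$gene_name[g])
  })
  tab <- do.call(rbind, rows)
  with_gene <- tapply(!is.na(tab$gene_id), paste(tab$chrom, tab$start), any)
  distinct <- sort(unique(tab$gene_name[!is.na(tab$gene_name)]))
  list(table = tab, n_regions = nrow(regions),
       n_regions_with_genes = sum(with_gene),
       n_distinct_genes = length(distinct), genes = distinct)
}

#' Write toy gene and QTL annotation files
#'
#' Emits a BED file of named gene intervals (0-based half-open, converted
#' from the 1-based inclusive input) and a TSV of QTL records, as small
#' fixtures matching the simulated chromosome. The QTL TSV has columns
#' `chrom`, `start_1based`, `end_1based`, `trait_name`, `trait_class`.
#'
#' @param genes data frame with `chrom`, `start`, `end` (1-based inclusive),
#'   `gene_name`; may have zero rows.
#' @param qtls data frame with `chrom`, `start`, `end`, `trait_name`,
#'   `trait_class`; may have zero rows.
#' @param path_genes,path_qtls output paths.
#' @return Invisibly, `c(path_genes, path_qtls)`.
#' @export
write_toy_annotations <- function(genes, qtls, path_genes, path_qtls) {
  bed <- character(0)
  if (nrow(genes))
    bed <- paste(genes$chrom, genes$start - 1L, genes$end, genes$gene_name,
                 sep = "\t")
  writeLines(bed, path_genes)

  hdr <- paste("chrom", "start_1based", "end_1based", "trait_name",
               "trait_class", sep = "\t")
  body <- character(0)
  if (nrow(qtls))
    body <- paste(qtls$chrom, qtls$start, qtls$end, qtls$trait_name,
                  qtls$trait_class, sep = "\t")
  writeLines(c(hdr, body), path_qtls)
  invisible(c(path_genes, path_qtls))
}
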