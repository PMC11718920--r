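#' Configuration for an end-to-end selection scan
#'
#' Collects every stage threshold with its conventional default: site QC at
#' missing rate <= 0.10, MAF >= 0.05 and exact HWE p >= 1e-6; EHH truncation
#' at 0.05 with an 800,000 bp maximum inter-site spacing; 100 standardization
#' bins; 50 kb non-overlapping windows kept at >= 10 SNPs; top 1% region
#' calling; QTL enrichment at FDR < 0.05.
#'
#' @param vcf path to a phased input VCF, or `NULL` to simulate.
#' @param sim a [sim_params()] object used when `vcf` is `NULL`.
#' @param genes optional gene annotation path (BED/GTF).
#' @param qtls optional QTL table path (TSV).
#' @param ancestral_source `"AA"` or `"REF"` (see [read_phased_vcf()]).
#' @param maf,max_missing,hwe_p site QC thresholds.
#' @param ehh_cutoff,max_gap_bp,n_bins iHS parameters.
#' @param window_size,min_snps,top_fraction window-scan parameters.
#' @param fdr enrichment significance threshold.
#' @param out_dir optional directory for per-stage TSV outputs.
#' @param seed seed for any stage randomness (simulation).
#' @return A list of class `sweep_config`.
#' @export
sweep_config <- function(vcf = NULL, sim = sim_params(), genes = NULL,
                         qtls = NULL, ancestral_source = "AA",
                         maf = 0.05, max_missing = 0.10, hwe_p = 1e-6,
                         ehh_cutoff = 0.05, max_gap_bp = 800000,
                         n_bins = 100L, window_size = 50000,
                         min_snps = 10L, top_fraction = 0.01, fdr = 0.05,
                         out_dir = NULL, seed = 1L) {
  cfg <- list(vcf = vcf, sim = sim, genes = genes, qtls = qtls,
              ancestral_source = ancestral_source, maf = maf,
              max_missing = max_missing, hwe_p = hwe_p,
              ehh_cutoff = ehh_cutoff, max_gap_bp = max_gap_bp,
              n_bins = as.integer(n_bins), window_size = window_size,
              min_snps = as.integer(min_snps), top_fraction = top_fraction,
              fdr = fdr, out_dir = out_dir, seed = as.integer(seed))
  class(cfg) <- "sweep_config"
  cfg
}

#' Serialize / parse a scan configuration as YAML
#'
#' @param cfg a [sweep_config()] object.
#' @param path file to write to / read from.
#' @return `write_sweep_config()` returns `path` invisibly;
#'   `read_sweep_config()` returns a `sweep_config`.
#' @export
write_sweep_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sweep_config"))
  flat <- unclass(cfg)
  flat$sim <- unclass(flat$sim)
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' @rdname write_sweep_config
#' @export
read_sweep_config <- function(path) {
  flat <- yaml::read_yaml(path)
  sim <- flat$sim
  flat$sim <- NULL
  cfg <- do.call(sweep_config, c(flat, list(sim = do.call(sim_params, sim))))
  cfg
}

#' Run the full selection-signature scan
#'
#' Executes every stage in order: input (simulation or phased VCF) -> site
#' QC -> iHS scan -> 50 kb window aggregation and top-fraction region
#' calling -> gene annotation of the selected regions (when a gene file is
#' configured) -> QTL overlap and per-trait enrichment (when a QTL table is
#' configured). Per-stage tables are written to `out_dir` when set. The run
#' is deterministic given the configuration.
#'
#' @param cfg a [sweep_config()].
#' @return An object of class `sweepscan_run`: list with `config`, `truth`
#'   (simulation truth or `NULL`), `qc_report`, `scan` (the [ihs_scan()]
#'   fit), `windows`, `regions`, `annotation`, `enrichment`, and `summary`
#'   (named counts: sites in, sites after QC, valid scores, windows,
#'   retained windows, selected regions, realized threshold, genes,
#'   significant traits).
#' @export
run_sweepscan <- function(cfg) {
  stopifnot(inherits(cfg, "sweep_config"))
  truth <- NULL
  if (is.null(cfg$vcf)) {
    sim <- cfg$sim
    sim$seed <- cfg$seed
    res <- simulate_population(sim)
    hm <- res$hm
    truth <- res$truth
  } else {
    hm <- read_phased_vcf(cfg$vcf, ancestral_source = cfg$ancestral_source)
  }
  n_in <- ncol(hm$alleles)

  qc <- apply_qc(hm, max_missing = cfg$max_missing, maf = cfg$maf,
                 hwe_p = cfg$hwe_p)
  scan <- ihs_scan(qc$hm, ehh_cutoff = cfg$ehh_cutoff,
                   max_gap_bp = cfg$max_gap_bp, n_bins = cfg$n_bins)
  windows <- bin_scores(scan, window_size = cfg$window_size)
  retained <- filter_windows(windows, min_snps = cfg$min_snps)
  regions <- select_top(retained, fraction = cfg$top_fraction)

  annotation <- NULL
  if (!is.null(cfg$genes) && nrow(regions)) {
    genes <- read_gene_annotation(cfg$genes)
    annotation <- intersect_regions(regions, genes)
  }
  enrichment <- NULL
  if (!is.null(cfg$qtls) && nrow(regions)) {
    qtl_db <- read_qtl_table(cfg$qtls)
    ov <- annotate_qtls(regions, qtl_db)
    enrichment <- list(overlap = ov,
                       table = if (ov$n_overlap)
                         qtl_enrich(ov$overlap, qtl_db, fdr_cutoff = cfg$fdr)
                       else NULL)
  }

  summary <- list(
    sites_in = n_in, sites_after_qc = ncol(qc$hm$alleles),
    valid_scores = sum(scan$scores$valid), windows = nrow(windows),
    retained_windows = nrow(retained), selected_regions = nrow(regions),
    realized_threshold = attr(regions, "threshold"),
    n_regions_with_genes = if (is.null(annotation)) NA_integer_
      else annotation$n_regions_with_genes,
    n_genes = if (is.null(annotation)) NA_integer_
      else annotation$n_distinct_genes,
    n_significant_traits = if (is.null(enrichment) || is.null(enrichment$table))
      NA_integer_ else sum(enrichment$table$significant))

  out <- structure(list(config = cfg, truth = truth, qc_report = qc$report,
                        scan = scan, windows = windows, retained = retained,
                        regions = regions, annotation = annotation,
                        enrichment = enrichment, summary = summary),
                   class = "sweepscan_run")
  if (!is.null(cfg$out_dir)) write_run_tables(out, cfg$out_dir)
  out
}

write_run_tables <- function(run, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wt <- function(df, name)
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  wt(run$qc_report, "site_qc.tsv")
  wt(run$scan$scores, "ihs.tsv")
  w <- run$windows
  w$selected <- paste(w$chrom, w$start) %in%
    paste(run$regions$chrom, run$regions$start)
  wt(w, "windows.tsv")
  wt(run$regions, "regions.tsv")
  if (!is.null(run$annotation)) wt(run$annotation$table, "region_genes.tsv")
  if (!is.null(run$enrichment) && !is.null(run$enrichment$table))
    wt(run$enrichment$table, "qtl_enrichment.tsv")
  smr <- run$summary
  smr[vapply(smr, is.null, logical(1))] <- NA
  wt(data.frame(quantity = names(smr), value = unlist(smr)), "summary.tsv")
  invisible(dir)
}

#' @export
print.sweepscan_run <- function(x, ...) {
  s <- x$summary
  cat("sweepscan run\n")
  cat(sprintf("  sites: %d in, %d after QC, %d valid iHS scores\n",
              s$sites_in, s$sites_after_qc, s$valid_scores))
  cat(sprintf("  windows: %d covered, %d with >= %d SNPs, %d selected (top %.2g%%)\n",
              s$windows, s$retained_windows, x$config$min_snps,
              s$selected_regions, 100 * x$config$top_fraction))
  if (!is.null(s$realized_threshold) && !is.na(s$realized_threshold))
    cat(sprintf("  realized |iHS| threshold: %.3f\n", s$realized_threshold))
  if (!is.na(s$n_genes))
    cat(sprintf("  genes: %d distinct in %d of the selected regions\n",
                s$n_genes, s$n_regions_with_genes))
  if (!is.na(s$n_significant_traits))
    cat(sprintf("  QTL enrichment: %d traits significant at FDR < %.2g\n",
                s$n_significant_traits, x$config$fdr))
  invisible(x)
}
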