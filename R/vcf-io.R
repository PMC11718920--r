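#' Write a haplotype matrix as a phased VCF
#'
#' Emits VCFv4.2 with phased `GT` (`0|1` style), REF set to the ancestral
#' allele and ALT to the derived allele, and the ancestral base recorded in
#' the `AA` INFO tag. Missing calls become `.|.` (or `0|.` etc. when only one
#' haplotype is masked). Positions are written 1-based, strictly increasing.
#' REF/ALT bases are a deterministic function of position, so output is
#' byte-identical for identical input.
#'
#' @param hm a nonempty [haplo_matrix()].
#' @param path output file path (plain text).
#' @param info optional character vector of pre-formatted INFO strings, one
#'   per site, appended after the `AA` tag (used to plant GATK-style INFO
#'   annotations in fixtures).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(hm, path, info = NULL) {
  stopifnot(inherits(hm, "haplo_matrix"))
  m <- ncol(hm$alleles)
  if (m == 0L)
    stop("cannot write a VCF from a haplotype matrix with no sites")
  if (m > 1L && any(diff(hm$positions) <= 0L))
    stop("sites must be sorted by strictly increasing position")
  if (!is.null(info) && length(info) != m)
    stop("'info' must have one entry per site")

  bases <- c("A", "C", "G", "T")
  ref <- bases[hm$positions %% 4L + 1L]
  alt <- bases[(hm$positions + 1L) %% 4L + 1L]

  gt <- hm$alleles
  gtc <- matrix(as.character(gt), nrow = nrow(gt))
  gtc[is.na(gt)] <- "."
  odd <- seq(1L, nrow(gt), by = 2L)
  cols <- matrix("", nrow = length(odd), ncol = m)
  for (k in seq_along(odd))
    cols[k, ] <- paste0(gtc[odd[k], ], "|", gtc[odd[k] + 1L, ])

  info_str <- paste0("AA=", ref)
  if (!is.null(info)) {
    extra <- !is.na(info) & nzchar(info)
    info_str[extra] <- paste0(info_str[extra], ";", info[extra])
  }

  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", hm$chrom,
                   max(hm$positions)),
           "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
           "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
           "##INFO=<ID=FS,Number=1,Type=Float,Description=\"FisherStrand\">",
           "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mapping quality\">",
           "##INFO=<ID=MQRankSum,Number=1,Type=Float,Description=\"MQ rank sum\">",
           "##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description=\"Read pos rank sum\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", hm$sample_ids), collapse = "\t"))
  body <- paste(hm$chrom, hm$positions, ".", ref, alt, ".", "PASS",
                info_str, "GT",
                apply(cols, 2L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a phased VCF into a haplotype matrix
#'
#' Parses a VCF (plain or bgzipped) with `vcfR`, keeps biallelic SNPs on
#' autosomes, requires phased genotypes, and recodes alleles so that 0 is the
#' ancestral state. With `ancestral_source = "AA"` the ancestral base is taken
#' from the `AA` INFO tag (sites whose tag is absent or matches neither
#' allele are dropped and counted); with `"REF"` the reference allele is
#' assumed ancestral.
#'
#' @param path VCF file.
#' @param ancestral_source `"AA"` (INFO tag, the default) or `"REF"`.
#' @param sex_chroms chromosome names excluded as sex chromosomes.
#' @return A [haplo_matrix()] with attributes `read_report` (named counts of
#'   sites dropped at read time) and `site_info` (per retained site, the raw
#'   INFO string, for [filter_info_thresholds()]).
#' @export
read_phased_vcf <- function(path, ancestral_source = c("AA", "REF"),
                            sex_chroms = c("X", "Y", "chrX", "chrY")) {
  ancestral_source <- match.arg(ancestral_source)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L,
                                       dimnames = list(NULL, names(fix)))
  gt_raw <- v@gt[, -1L, drop = FALSE]
  if (is.null(dim(gt_raw))) gt_raw <- matrix(gt_raw, nrow = 1L)
  sample_ids <- colnames(v@gt)[-1L]

  chrom <- fix[, "CHROM"]
  keep_chrom <- !(chrom %in% sex_chroms)
  n_sex <- sum(!keep_chrom)
  biallelic <- !grepl(",", fix[, "ALT"], fixed = TRUE) &
    nchar(fix[, "REF"]) == 1L & nchar(fix[, "ALT"]) == 1L &
    fix[, "ALT"] != "."
  n_multi <- sum(keep_chrom & !biallelic)
  keep <- keep_chrom & biallelic
  if (!any(keep))
    stop("no biallelic autosomal SNPs left after read-time filtering")
  if (length(unique(chrom[keep])) > 1L)
    stop("multiple chromosomes in one VCF are not supported; split the file")

  fix <- fix[keep, , drop = FALSE]
  gt_raw <- gt_raw[keep, , drop = FALSE]

  gt_field <- sub(":.*$", "", gt_raw)
  gt_field[is.na(gt_field)] <- ".|."   # vcfR reads fully missing calls as NA
  dim(gt_field) <- dim(gt_raw)
  unphased <- grepl("/", gt_field, fixed = TRUE)
  dim(unphased) <- dim(gt_field)
  if (any(unphased)) {
    i <- which(unphased, arr.ind = TRUE)[1L, ]
    stop(sprintf("unphased genotype '%s' at %s:%s (sample %s); input must be fully phased",
                 gt_field[i[1L], i[2L]], fix[i[1L], "CHROM"],
                 fix[i[1L], "POS"], sample_ids[i[2L]]))
  }

  a1 <- substr(gt_field, 1L, 1L)
  a2 <- substr(gt_field, 3L, 3L)
  code <- function(x) {
    out <- suppressWarnings(as.integer(x))
    out[x == "."] <- NA_integer_
    if (any(is.na(out) & x != "."))
      stop("malformed GT allele in VCF")
    out
  }
  m1 <- matrix(code(a1), nrow = nrow(gt_field))
  m2 <- matrix(code(a2), nrow = nrow(gt_field))
  if (any(c(m1, m2) > 1L, na.rm = TRUE))
    stop("allele index >1 found; input must be biallelic")

  ## rows = sites here; interleave into haplotype rows (2 per sample)
  n_samp <- length(sample_ids)
  alle <- matrix(NA_integer_, nrow = 2L * n_samp, ncol = nrow(fix))
  alle[seq(1L, 2L * n_samp, 2L), ] <- t(m1)
  alle[seq(2L, 2L * n_samp, 2L), ] <- t(m2)

  info <- fix[, "INFO"]
  n_noaa <- 0L
  if (ancestral_source == "AA") {
    aa <- rep(NA_character_, length(info))
    has_info <- !is.na(info)
    hit <- regexpr("(^|;)AA=[^;]*", info[has_info])
    aa[has_info][hit > 0L] <- sub("^;?AA=", "", regmatches(info[has_info], hit))
    flip <- !is.na(aa) & aa == fix[, "ALT"]
    known <- !is.na(aa) & (aa == fix[, "REF"] | aa == fix[, "ALT"])
    n_noaa <- sum(!known)
    alle[, flip] <- 1L - alle[, flip]
    alle <- alle[, known, drop = FALSE]
    fix <- fix[known, , drop = FALSE]
    info <- info[known]
  }
  if (nrow(fix) == 0L)
    stop("no sites with a usable ancestral state")

  pos <- as.integer(fix[, "POS"])
  o <- order(pos)
  hm <- haplo_matrix(alle[, o, drop = FALSE], pos[o],
                     chrom = fix[1L, "CHROM"], sample_ids = sample_ids)
  attr(hm, "read_report") <- c(sex_chrom = n_sex, not_biallelic = n_multi,
                               no_ancestral_state = n_noaa)
  attr(hm, "site_info") <- info[o]
  hm
}
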