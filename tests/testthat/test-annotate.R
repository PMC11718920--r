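write_gtf <- function(rows, path) {
  writeLines(c("#!genome-build test", rows), path)
  path
}

test_that("BED and GTF conventions normalize to the same interval", {
  fb <- tempfile(fileext = ".bed")
  writeLines("chr1\t100\t200\tgeneA", fb)
  fg <- tempfile(fileext = ".gtf")
  write_gtf(paste("chr1", "src", "gene", "101", "200", ".", "+", ".",
                  'gene_id "geneA"; gene_name "GENEA";', sep = "\t"), fg)
  bed <- read_gene_annotation(fb)
  gtf <- read_gene_annotation(fg)
  expect_equal(bed$start, gtf$start)
  expect_equal(bed$end, gtf$end)
  expect_equal(bed$start, 101)
  expect_equal(bed$end, 200)
  expect_equal(gtf$gene_name, "GENEA")
})

test_that("a GTF without gene rows yields an empty list with a warning", {
  fg <- tempfile(fileext = ".gtf")
  write_gtf(paste("chr1", "src", "exon", "101", "200", ".", "+", ".",
                  'gene_id "geneA";', sep = "\t"), fg)
  expect_warning(out <- read_gene_annotation(fg), "no 'gene' feature")
  expect_equal(nrow(out), 0L)
})

test_that("gene_id is the fallback when gene_name is absent", {
  fg <- tempfile(fileext = ".gtf")
  write_gtf(paste("chr1", "src", "gene", "50", "80", ".", "-", ".",
                  'gene_id "ENSBTAG1";', sep = "\t"), fg)
  out <- read_gene_annotation(fg)
  expect_equal(out$gene_name, "ENSBTAG1")
})

test_that("region-gene intersection uses >= 1 bp overlap, not touching", {
  regions <- data.frame(chrom = "1", start = 50001, end = 100001)  # spans 50001..100000
  genes <- data.frame(chrom = "1",
                      start = c(60000, 100000, 100001, 49000, 1000),
                      end = c(60100, 100300, 100200, 50001, 2000),
                      gene_id = paste0("g", 1:5), gene_name = paste0("g", 1:5))
  out <- intersect_regions(regions, genes)
  hit <- out$table$gene_name[!is.na(out$table$gene_name)]
  expect_setequal(hit, c("g1", "g2", "g4"))   # g3 only touches the label end
  expect_equal(out$n_regions_with_genes, 1L)
  expect_equal(out$n_distinct_genes, 3L)
})

test_that("intersection matches an all-pairs brute-force oracle", {
  set.seed(12)
  n_r <- 40; n_g <- 60
  regions <- data.frame(chrom = sample(c("1", "2"), n_r, TRUE),
                        start = sample.int(5e5, n_r))
  regions$end <- regions$start + 50000
  genes <- data.frame(chrom = sample(c("1", "2"), n_g, TRUE),
                      start = sample.int(55e4, n_g))
  genes$end <- genes$start + sample.int(3e4, n_g)
  genes$gene_id <- genes$gene_name <- paste0("g", seq_len(n_g))
  out <- intersect_regions(regions, genes)
  for (i in seq_len(n_r)) {
    ov <- mapply(function(gs, ge)
      oracle_overlaps(regions$start[i], regions$end[i] - 1, gs, ge),
      genes$start, genes$end)
    expected <- genes$gene_name[genes$chrom == regions$chrom[i] & ov]
    got <- out$table$gene_name[out$table$start == regions$start[i] &
                               out$table$chrom == regions$chrom[i]]
    got <- got[!is.na(got)]
    expect_setequal(got, expected)
  }
})

test_that("toy annotation files have the advertised line counts", {
  genes <- data.frame(chrom = "1", start = c(1000, 5000, 9000),
                      end = c(2000, 6000, 9500),
                      gene_name = c("gA", "gB", "gC"))
  qtls <- data.frame(chrom = "1",
                     start = rep(seq(1000, 10000, length.out = 10), 2),
                     end = rep(seq(2000, 11000, length.out = 10), 2),
                     trait_name = rep(c("milk yield", "carcass weight"), each = 10),
                     trait_class = rep(c("Milk", "Meat and Carcass"), each = 10))
  fg <- tempfile(fileext = ".bed"); fq <- tempfile(fileext = ".tsv")
  write_toy_annotations(genes, qtls, fg, fq)
  expect_length(readLines(fg), 3L)
  expect_length(readLines(fq), 21L)        # header + 20 records

  ## empty inputs: BED empty, TSV header only
  write_toy_annotations(genes[0, ], qtls[0, ], fg, fq)
  expect_length(readLines(fg), 0L)
  expect_length(readLines(fq), 1L)
})

test_that("a gene planted in a region is recovered through file round-trip", {
  regions <- data.frame(chrom = "1", start = 450001, end = 500001)
  genes <- data.frame(chrom = "1", start = 470000, end = 480000,
                      gene_name = "planted")
  fg <- tempfile(fileext = ".bed"); fq <- tempfile(fileext = ".tsv")
  write_toy_annotations(genes, data.frame(chrom = character(0),
                                          start = numeric(0), end = numeric(0),
                                          trait_name = character(0),
                                          trait_class = character(0)), fg, fq)
  back <- read_gene_annotation(fg)
  expect_equal(back$start, 470000)
  expect_equal(back$end, 480000)
  out <- intersect_regions(regions, back)
  expect_equal(out$genes, "planted")
})
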