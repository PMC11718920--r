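mk_qtls <- function(n_per_trait, traits, classes, chrom = "1",
                    start = NULL, width = 10000) {
  total <- sum(n_per_trait)
  if (is.null(start)) start <- sample.int(9e5, total)
  data.frame(chrom = chrom, start = start, end = start + width,
             trait_name = rep(traits, n_per_trait),
             trait_class = rep(classes, n_per_trait))
}

test_that("QTL tables are read and validated against the six classes", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tstart_1based\tend_1based\ttrait_name\ttrait_class",
               "1\t100\t200\tMilk yield\tMilk",
               "1\t300\t400\tCalving ease\tReproduction"), f)
  db <- read_qtl_table(f)
  expect_equal(nrow(db), 2L)
  expect_equal(db$start, c(100, 300))
  writeLines(c("chrom\tstart_1based\tend_1based\ttrait_name\ttrait_class",
               "1\t100\t200\tShininess\tCoat"), f)
  expect_error(read_qtl_table(f), "unknown trait_class 'Coat'.*row 1")
})

test_that("class percentages among overlapping QTLs are exact", {
  regions <- data.frame(chrom = "1", start = 1, end = 1e6 + 1)
  qtls <- mk_qtls(c(10, 30), c("Milk fat", "Carcass weight"),
                  c("Milk", "Meat and Carcass"))
  out <- annotate_qtls(regions, qtls)
  expect_equal(out$n_overlap, 40L)
  expect_equal(unname(out$class_percent["Milk"]), 25)
  expect_equal(unname(out$class_percent["Meat and Carcass"]), 75)

  ## all overlapping QTLs in one class -> 100%
  out1 <- annotate_qtls(regions, mk_qtls(5, "Milk fat", "Milk"))
  expect_equal(unname(out1$class_percent), 100)
})

test_that("each QTL is counted once however many regions it spans", {
  regions <- data.frame(chrom = "1", start = c(1, 50001), end = c(50001, 100001))
  qtl <- data.frame(chrom = "1", start = 40000, end = 60000,
                    trait_name = "t", trait_class = "Health")
  out <- annotate_qtls(regions, qtl)
  expect_equal(out$n_overlap, 1L)
})

test_that("overlap percentages match a brute-force recount", {
  set.seed(4)
  regions <- data.frame(chrom = "1", start = (0:9) * 1e5 + 1)
  regions$end <- regions$start + 50000
  qtls <- mk_qtls(c(25, 25, 25), c("a", "b", "c"),
                  c("Milk", "Production", "Health"))
  out <- annotate_qtls(regions, qtls)
  inside <- vapply(seq_len(nrow(qtls)), function(i)
    any(mapply(function(rs, re) oracle_overlaps(qtls$start[i], qtls$end[i], rs, re),
               regions$start, regions$end - 1)), logical(1))
  expect_equal(out$n_overlap, sum(inside))
  recount <- 100 * table(qtls$trait_class[inside]) / sum(inside)
  for (cl in names(recount))
    expect_equal(unname(out$class_percent[cl]), unname(recount[cl]))
})

test_that("hypergeometric enrichment reproduces the closed-form example", {
  ## N = 20 QTLs, K = 5 of trait T, n = 4 overlapping, x = 3 of them trait T
  db <- mk_qtls(c(5, 15), c("T", "other"), c("Milk", "Production"))
  overlap <- rbind(db[1:3, ], db[6, ])
  out <- qtl_enrich(overlap, db)
  row <- out[out$trait == "T", ]
  expect_equal(row$p_value, 155 / 4845, tolerance = 1e-12)
  expect_equal(row$p_value, oracle_hyper_upper(20, 5, 4, 3), tolerance = 1e-12)
  expect_equal(row$richness_factor, (3 / 4) / (5 / 20))
})

test_that("a single-trait database is degenerate: richness 1, p 1", {
  db <- mk_qtls(12, "only", "Exterior")
  out <- qtl_enrich(db[1:5, ], db)
  expect_equal(out$richness_factor, 1)
  expect_equal(out$p_value, 1)
})

test_that("enrichment p-values equal enumeration on random small tables", {
  set.seed(90)
  for (rep in 1:40) {
    N <- sample(5:30, 1)
    K <- sample.int(N, 1)
    db <- mk_qtls(c(K, N - K)[c(K, N - K) > 0],
                  c("T", "other")[c(K, N - K) > 0],
                  c("Milk", "Production")[c(K, N - K) > 0])
    n <- sample.int(N, 1)
    overlap <- db[sample.int(N, n), ]
    out <- qtl_enrich(overlap, db)
    x <- sum(overlap$trait_name == "T")
    if (K > 0 && K < N) {
      expect_equal(out$p_value[out$trait == "T"],
                   oracle_hyper_upper(N, K, n, x), tolerance = 1e-12)
    }
  }
})

test_that("BH adjustment matches the reference step-up and stays ordered", {
  set.seed(33)
  traits <- paste0("t", 1:12)
  classes6 <- c("Exterior", "Health", "Meat and Carcass", "Milk",
                "Production", "Reproduction")
  db <- mk_qtls(rep(8, 12), traits, rep(classes6, 2))
  overlap <- db[sample.int(nrow(db), 30), ]
  out <- qtl_enrich(overlap, db)
  expect_equal(out$fdr, oracle_bh(out$p_value))
  expect_true(all(out$fdr >= out$p_value - 1e-15))
  expect_true(all(out$fdr <= 1))
  expect_true(all(diff(out$fdr) >= -1e-15))   # sorted by p: BH non-decreasing
})

test_that("richness factor is 1 when overlap shares equal database shares", {
  db <- mk_qtls(c(10, 30), c("A", "B"), c("Milk", "Health"))
  overlap <- rbind(db[1:2, ], db[11:16, ])   # 2/8 vs 10/40, 6/8 vs 30/40
  out <- qtl_enrich(overlap, db)
  expect_equal(out$richness_factor, c(1, 1))
})

test_that("a trait concentrated in the regions tops the ranking almost always", {
  hits <- 0L
  for (seed in 1:20) {
    set.seed(seed * 13)
    regions <- data.frame(chrom = "1", start = c(100001, 400001, 700001))
    regions$end <- regions$start + 50000
    inside <- sample(regions$start + 10, 15, replace = TRUE) +
      sample.int(30000, 15)
    planted <- data.frame(chrom = "1", start = inside, end = inside + 5000,
                          trait_name = "planted", trait_class = "Health")
    noise_start <- sample.int(9.5e5, 120)
    noise <- data.frame(chrom = "1", start = noise_start,
                        end = noise_start + 5000,
                        trait_name = sample(paste0("t", 1:6), 120, TRUE),
                        trait_class = "Production")
    db <- rbind(planted, noise)
    ov <- annotate_qtls(regions, db)
    out <- qtl_enrich(ov$overlap, db)
    if (out$trait[1] == "planted") hits <- hits + 1L
  }
  expect_gte(hits, 19L)   # >= 95% of 20 seeds
})

test_that("unknown or missing traits raise errors", {
  db <- mk_qtls(4, "A", "Milk")
  bad <- db; bad$trait_class <- "Fluff"
  expect_error(annotate_qtls(data.frame(chrom = "1", start = 1, end = 10), bad),
               "unknown trait_class")
  stray <- db[1, ]; stray$trait_name <- "notindb"
  expect_error(qtl_enrich(stray, db), "absent from the database")
})
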