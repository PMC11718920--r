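test_that("identical carriers keep EHH at 1 along the whole extension", {
  m <- rbind(matrix(1L, 4, 10),
             matrix(rbinom(40, 1, 0.5), 4, 10))
  m[5:8, 5] <- 0L   # carriers of allele 1 at the core are rows 1:4 only
  hm <- haplo_matrix(m, positions = (1:10) * 100L)
  cv <- ehh(hm, 5, core_allele = 1L, direction = "downstream")
  expect_true(all(cv$points$ehh == 1))
  expect_equal(cv$status, "chrom_end")
})

test_that("a 2/2 split of four carriers gives EHH = 2/6 at the split site", {
  ## carriers of allele 1 at the core split into two haplotype groups
  m <- rbind(c(1L, 0L), c(1L, 0L), c(1L, 1L), c(1L, 1L),
             c(0L, 0L), c(0L, 1L))
  hm <- haplo_matrix(m, positions = c(100L, 200L))
  cv <- ehh(hm, 1, core_allele = 1L, direction = "downstream", ehh_cutoff = 0)
  expect_equal(cv$points$ehh, c(1, 2 / 6))
  expect_equal(cv$points$distance_bp, c(0, 100))
})

test_that("EHH equals brute-force pairwise homozygosity on random matrices", {
  set.seed(2024)
  for (rep in 1:60) {
    hm <- rand_hm(16, 30, miss = ifelse(rep %% 3 == 0, 0.06, 0))
    core <- sample(2:29, 1)
    for (allele in 0:1) {
      carriers <- sum(!is.na(hm$alleles[, core]) & hm$alleles[, core] == allele)
      if (carriers < 2) next
      for (dir in c("upstream", "downstream")) {
        cv <- ehh(hm, core, allele, dir, ehh_cutoff = 0, max_gap_bp = Inf)
        orc <- oracle_ehh(hm$alleles, core, allele, dir)
        expect_equal(cv$points$ehh[-1], orc, tolerance = 1e-12)
      }
    }
  }
})

test_that("EHH is monotone non-increasing and invariant to haplotype order", {
  set.seed(5)
  hm <- rand_hm(20, 40)
  cv <- ehh(hm, 10, 1L, "downstream", ehh_cutoff = 0, max_gap_bp = Inf)
  expect_true(all(diff(cv$points$ehh) <= 1e-15))
  perm <- sample(nrow(hm$alleles))
  ## permute within diploid structure constraints (pairs stay pairs is not
  ## required by ehh itself, so any row permutation must give the same curve)
  hm2 <- hm
  hm2$alleles <- hm$alleles[perm, ]
  cv2 <- ehh(hm2, 10, 1L, "downstream", ehh_cutoff = 0, max_gap_bp = Inf)
  expect_equal(cv$points$ehh, cv2$points$ehh)
})

test_that("a large inter-site gap truncates the curve and voids the score", {
  m <- matrix(rbinom(6 * 6, 1, 0.5), 6, 6)
  m[, 3] <- c(1L, 1L, 1L, 0L, 0L, 0L)
  m[, 2] <- c(0L, 1L, 0L, 0L, 0L, 0L)   # upstream splits carriers ...
  m[, 1] <- c(0L, 0L, 1L, 0L, 0L, 0L)   # ... down to singletons (EHH 0)
  hm <- haplo_matrix(m, positions = c(1e5, 2e5, 3e5, 4e5, 13e5, 14e5))
  cv <- ehh(hm, 3, 1L, "downstream", ehh_cutoff = 0.05, max_gap_bp = 8e5)
  expect_equal(cv$status, "gap")               # 4e5 -> 13e5 exceeds 800 kb
  up <- ehh(hm, 3, 1L, "upstream", ehh_cutoff = 0.05, max_gap_bp = 8e5)
  expect_equal(up$status, "cutoff")
  res <- ihh(up, cv)
  expect_false(res$valid)
  expect_equal(res$reason, "gap")
})

test_that("iHH is the trapezoidal integral truncated at the cutoff crossing", {
  mk_curve <- function(d, e, status = "cutoff")
    structure(list(points = data.frame(distance_bp = d, ehh = e),
                   status = status, core_position = 0, core_allele = 1L,
                   direction = "downstream", n_carriers = 4L),
              class = "ehh_curve")
  cv <- mk_curve(c(0, 100, 200), c(1, 0.5, 0))
  res <- ihh(cv, cv)
  expect_true(res$valid)
  expect_equal(res$value, 200)   # 2 x (100*(1+.5)/2 + 100*(.5+0)/2) = 2 x 100

  ## doubling all distances doubles the integral
  cv2 <- mk_curve(c(0, 200, 400), c(1, 0.5, 0))
  expect_equal(ihh(cv2, cv2)$value, 400)

  ## a curve that ran off the chromosome never reached the cutoff
  res_edge <- ihh(cv, mk_curve(c(0, 100), c(1, 0.8), status = "chrom_end"))
  expect_false(res_edge$valid)
  expect_equal(res_edge$reason, "edge")
})

test_that("mirror-symmetric allele classes give uihs of exactly zero", {
  set.seed(9)
  block <- matrix(rbinom(4 * 11, 1, 0.5), 4, 11)
  m <- rbind(block, block)           # derived carriers mirror the ancestral
  m[1:4, 6] <- 0L
  m[5:8, 6] <- 1L
  hm <- haplo_matrix(m, positions = (1:11) * 500L)
  r <- unstandardized_ihs(hm, 6)
  expect_true(r$valid)
  expect_equal(r$uihs, 0)
  expect_equal(r$ihh_a, r$ihh_d)
})

test_that("swapping ancestral/derived labels negates every uihs exactly", {
  set.seed(31)
  hm <- rand_hm(24, 50)
  flipped <- hm
  flipped$alleles <- 1L - hm$alleles
  for (core in c(10, 25, 40)) {
    a <- unstandardized_ihs(hm, core)
    b <- unstandardized_ihs(flipped, core)
    expect_identical(a$valid, b$valid)
    if (a$valid) {
      expect_identical(b$uihs, -a$uihs)
      expect_identical(b$ihh_a, a$ihh_d)
    }
  }
})

test_that("a planted hard sweep drives uihs negative at the swept site", {
  fx <- fx_sim("sweep")
  hm <- fx$qc$hm
  j <- match(fx$sim$truth$sweep_pos, hm$positions)
  expect_false(is.na(j))
  r <- unstandardized_ihs(hm, j)
  expect_true(r$valid)
  expect_lt(r$uihs, 0)   # derived allele rides the long swept haplotype
})

test_that("sites with fewer than two carriers of either allele are flagged", {
  m <- cbind(c(1L, rep(0L, 9)), matrix(rbinom(50, 1, 0.5), 10, 5))
  hm <- haplo_matrix(m, positions = (1:6) * 100L)
  r <- unstandardized_ihs(hm, 1)
  expect_false(r$valid)
  expect_equal(r$reason, "carriers")
  expect_error(ehh(hm, 1, 1L, "downstream"), "fewer than 2 carriers")
})
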