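## Independent brute-force oracles used to cross-check the implementation.

## EHH by explicit pair counting: for every pair of carriers, cumulative
## identity (both called and equal) over all sites from the core out to each
## extension site, via cumprod. Returns the EHH value at every extension
## site in the given direction.
oracle_ehh <- function(A, core, allele, direction) {
  carriers <- which(!is.na(A[, core]) & A[, core] == allele)
  n_c <- length(carriers)
  idx <- if (direction == "downstream") {
    if (core < ncol(A)) (core + 1L):ncol(A) else integer(0)
  } else {
    if (core > 1L) (core - 1L):1L else integer(0)
  }
  if (!length(idx)) return(numeric(0))
  total <- numeric(length(idx))
  for (i in seq_len(n_c - 1L)) {
    for (j in (i + 1L):n_c) {
      ai <- A[carriers[i], idx]
      aj <- A[carriers[j], idx]
      same <- !is.na(ai) & !is.na(aj) & ai == aj
      total <- total + cumprod(same)
    }
  }
  total / (n_c * (n_c - 1) / 2)
}

## Exact HWE p-value by direct factorial enumeration over heterozygote
## counts (valid for totals <= 50; plain double-precision factorials).
oracle_hwe <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  if (nA == 0 || na == 0) return(1)
  ks <- seq(min(nA, na) %% 2, min(nA, na), by = 2)
  pk <- vapply(ks, function(k) {
    nAAk <- (nA - k) / 2
    naak <- (na - k) / 2
    factorial(n) / (factorial(nAAk) * factorial(k) * factorial(naak)) *
      2^k / choose(2 * n, nA)
  }, numeric(1))
  obs <- pk[ks == n_Aa]
  sum(pk[pk <= obs * (1 + 1e-12)])
}

## Upper-tail hypergeometric by explicit enumeration with choose().
oracle_hyper_upper <- function(N, K, n, x) {
  js <- x:min(K, n)
  js <- js[n - js <= N - K]
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

## Benjamini-Hochberg step-up, written out directly.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

## 1-based inclusive interval overlap (>= 1 shared base).
oracle_overlaps <- function(s1, e1, s2, e2) {
  max(s1, s2) <= min(e1, e2)
}

## Random haplotype matrix with optional missingness; even haplotype count.
rand_hm <- function(n_hap, n_sites, miss = 0, chrom = "1", max_pos = NULL) {
  if (is.null(max_pos)) max_pos <- n_sites * 1000L
  pos <- sort(sample.int(max_pos, n_sites))
  m <- matrix(rbinom(n_hap * n_sites, 1L, runif(1, 0.2, 0.8)), nrow = n_hap)
  if (miss > 0) m[runif(length(m)) < miss] <- NA_integer_
  haplo_matrix(m, pos, chrom = chrom)
}

## Session-level cache for the expensive simulation fixtures.
.fixture_cache <- new.env(parent = emptyenv())

fx_sim <- function(name) {
  if (!is.null(.fixture_cache[[name]])) return(.fixture_cache[[name]])
  val <- switch(name,
    neutral = {
      sim <- simulate_population(sim_params(seed = 11L))
      qc <- apply_qc(sim$hm)
      list(sim = sim, qc = qc, scan = ihs_scan(qc$hm))
    },
    sweep = {
      ## 1 Mb version of the canonical ongoing-sweep study condition
      sim <- simulate_population(sim_params(s = 2, sweep_pos = 475000L,
                                            sweep_start = 990L,
                                            min_final_freq = 0.6,
                                            max_final_freq = 0.85,
                                            missing_rate = 0, seed = 7L,
                                            max_retries = 400L))
      qc <- apply_qc(sim$hm)
      list(sim = sim, qc = qc, scan = ihs_scan(qc$hm))
    },
    stop("unknown fixture ", name))
  .fixture_cache[[name]] <- val
  val
}
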