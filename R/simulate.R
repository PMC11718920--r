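#' Parameters for the forward Wright-Fisher simulator
#'
#' Bundles and validates the knobs of [simulate_population()]. The defaults
#' describe the desk-scale study condition used throughout the package's
#' tests: 100 diploids evolving for 1000 discrete generations (five times the
#' haploid population size, enough to approach mutation-drift-recombination
#' equilibrium) on a 1 Mb chromosome with per-generation, per-haplotype
#' mutation and recombination intensities of about one event
#' (`mu * seq_length = rho * seq_length = 1`, so the scaled diversity
#' `4*N*mu` is 4e-4 per bp), with 60 haplotypes (30 diploids) sampled at the
#' end.
#'
#' @param n_diploids number of diploid individuals (constant population size).
#' @param n_generations number of discrete generations simulated.
#' @param seq_length chromosome length in bp.
#' @param mu per-bp, per-generation mutation rate (infinite-sites; a position
#'   is never hit twice, so every site stays biallelic).
#' @param rho per-bp, per-generation crossover rate.
#' @param s selection coefficient of the derived allele at `sweep_pos`;
#'   `s = 0` gives a neutral simulation. Genotype fitnesses are `1`,
#'   `1 + h*s`, `1 + s` for 0, 1, 2 copies of the derived allele.
#' @param h dominance coefficient in `[0, 1]`.
#' @param sweep_pos bp coordinate of the selected site; defaults to the
#'   chromosome midpoint when `s > 0`, and must be `NULL` when `s = 0`.
#' @param sweep_start generation (1-based) at which the beneficial mutation
#'   arises as a single new copy; default leaves 30 generations of selection
#'   before sampling (an ongoing, recent hard sweep).
#' @param sample_n haplotypes sampled at the end; must be even (whole phased
#'   diploids are sampled) and at most `2 * n_diploids`.
#' @param missing_rate fraction of genotype calls masked i.i.d. after
#'   sampling; must be below 0.1 so default fixtures survive the missingness
#'   QC filter.
#' @param min_final_freq,max_final_freq condition the sweep on a present
#'   population frequency inside `[min_final_freq, max_final_freq]` at
#'   sampling time (defaults 0 and 1: only survival is required).
#'   Conditioning on the present frequency of the selected allele is the
#'   conventional way to simulate detectable ongoing sweeps, since
#'   conditional trajectories vary widely in how far they have risen.
#' @param seed RNG seed; a fixed seed gives bit-identical output.
#' @param max_retries number of selection-phase restarts allowed when the
#'   beneficial mutation is lost by drift or ends outside the configured
#'   frequency window. The neutral burn-in (generations before
#'   `sweep_start`) is computed once and reused; each retry re-runs the
#'   selection phase with a fresh RNG substream derived from `seed` plus the
#'   attempt number.
#'
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_diploids = 100L, n_generations = 1000L,
                       seq_length = 1e6, mu = 1e-6, rho = 1e-6,
                       s = 0, h = 0.5, sweep_pos = NULL, sweep_start = NULL,
                       sample_n = 60L, missing_rate = 0.02,
                       min_final_freq = 0, max_final_freq = 1, seed = 1L,
                       max_retries = 100L) {
  p <- list(n_diploids = as.integer(n_diploids),
            n_generations = as.integer(n_generations),
            seq_length = as.integer(seq_length), mu = mu, rho = rho,
            s = s, h = h, sweep_pos = sweep_pos, sweep_start = sweep_start,
            sample_n = as.integer(sample_n), missing_rate = missing_rate,
            min_final_freq = min_final_freq, max_final_freq = max_final_freq,
            seed = as.integer(seed), max_retries = as.integer(max_retries))
  stopifnot(p$n_diploids >= 2L, p$n_generations >= 1L, p$seq_length >= 1L,
            p$mu >= 0, p$rho >= 0, p$s >= 0, p$h >= 0, p$h <= 1,
            p$missing_rate >= 0, p$missing_rate < 0.1,
            p$min_final_freq >= 0, p$min_final_freq < 1,
            p$max_final_freq > p$min_final_freq, p$max_final_freq <= 1,
            p$sample_n >= 2L, p$sample_n <= 2L * p$n_diploids,
            p$sample_n %% 2L == 0L)
  if (p$s > 0) {
    if (is.null(p$sweep_pos)) p$sweep_pos <- as.integer(round(p$seq_length / 2))
    p$sweep_pos <- as.integer(p$sweep_pos)
    stopifnot(p$sweep_pos >= 1L, p$sweep_pos <= p$seq_length)
    if (is.null(p$sweep_start)) p$sweep_start <- max(1L, p$n_generations - 30L)
    p$sweep_start <- as.integer(p$sweep_start)
    stopifnot(p$sweep_start >= 1L, p$sweep_start <= p$n_generations)
  } else {
    if (!is.null(p$sweep_pos))
      stop("'sweep_pos' must be NULL when s = 0")
    p$sweep_start <- NULL
  }
  class(p) <- "sim_params"
  p
}

## Evolve a population state over a block of absolute generation indices.
## `state` holds `pop` (2N haplotypes as integer position vectors) and
## `occupied` (infinite-sites bookkeeping). The hot loop is compiled
## (wf_evolve_cpp); all randomness flows through R's RNG so set.seed()
## governs reproducibility. Returns NULL if the beneficial allele is lost.
wf_evolve <- function(state, gens, p, select = FALSE) {
  wf_evolve_cpp(state$pop, state$occupied, gens[1L], length(gens),
                p$n_diploids, p$seq_length, p$mu, p$rho, p$s, p$h,
                if (is.null(p$sweep_pos)) -1L else p$sweep_pos,
                if (is.null(p$sweep_start)) -1L else p$sweep_start,
                select)
}

wf_init <- function(p) {
  occupied <- logical(p$seq_length)
  if (p$s > 0) occupied[p$sweep_pos] <- TRUE   # reserved for the sweep allele
  list(pop = rep(list(integer(0)), 2L * p$n_diploids), occupied = occupied)
}

#' Simulate a phased population sample under drift or a hard sweep
#'
#' Forward Wright-Fisher simulation with discrete generations, Poisson
#' infinite-sites mutation at uniform positions, Poisson crossover
#' recombination and, when `s > 0`, viability selection at `sweep_pos` with
#' genotype fitnesses `1`, `1 + h*s`, `1 + s`. The beneficial mutation enters
#' as a single new copy at generation `sweep_start`; if it is lost before
#' sampling (or its final frequency falls outside the configured window) the
#' selection phase is re-run on the cached burn-in state with an incremented
#' RNG substream, up to `max_retries` times. At the end, `sample_n/2`
#' diploids are drawn, sites still segregating in the sample are retained,
#' and calls are masked i.i.d. at `missing_rate`.
#'
#' @param params a [sim_params()] object.
#' @return A list with elements `hm` (a [haplo_matrix()], alleles coded
#'   0 = ancestral, 1 = derived) and `truth` (a list with `sweep_pos`,
#'   `s`, `final_derived_freq` -- the population frequency of the selected
#'   allele at sampling, `NULL`s for neutral runs -- and `attempts`).
#' @examples
#' sim <- simulate_population(sim_params(n_diploids = 30, n_generations = 40,
#'                                       seq_length = 1e5, mu = 1e-5,
#'                                       rho = 1e-5, sample_n = 10, seed = 42))
#' sim$hm
#' @export
simulate_population <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  pop <- NULL
  attempts <- 0L
  n_hap <- 2L * p$n_diploids
  final_freq <- NULL
  if (p$s == 0) {
    set.seed(p$seed)
    pop <- wf_evolve(wf_init(p), seq_len(p$n_generations), p)$pop
    attempts <- 1L
  } else {
    ## neutral burn-in once; each retry re-runs only the selection phase on
    ## the cached burn-in state, with its own RNG substream
    set.seed(p$seed)
    burn <- if (p$sweep_start > 1L)
      wf_evolve(wf_init(p), seq_len(p$sweep_start - 1L), p)
    else wf_init(p)
    repeat {
      attempts <- attempts + 1L
      if (attempts > p$max_retries + 1L)
        stop(sprintf(paste0("beneficial allele at %d lost by drift (or its ",
                            "final frequency outside [%g, %g]) in all %d ",
                            "attempts; increase s, selection time or ",
                            "max_retries"), p$sweep_pos, p$min_final_freq,
                     p$max_final_freq, attempts - 1L))
      set.seed(p$seed + attempts)
      st <- wf_evolve(burn, p$sweep_start:p$n_generations, p, select = TRUE)
      if (is.null(st)) next
      final_freq <- sum(vapply(st$pop, function(h)
        match(p$sweep_pos, h, nomatch = 0L) > 0L, logical(1))) / n_hap
      if (final_freq < p$min_final_freq || final_freq > p$max_final_freq) next
      pop <- st$pop
      break
    }
  }

  ind <- sort(sample.int(p$n_diploids, p$sample_n / 2L))
  hap_idx <- as.vector(rbind(2L * ind - 1L, 2L * ind))
  sampled <- pop[hap_idx]

  pos <- sort(unique(unlist(sampled, use.names = FALSE)))
  if (length(pos)) {
    m <- matrix(0L, nrow = p$sample_n, ncol = length(pos))
    for (i in seq_len(p$sample_n))
      m[i, match(sampled[[i]], pos)] <- 1L
    seg <- colSums(m) > 0L & colSums(m) < p$sample_n
    m <- m[, seg, drop = FALSE]
    pos <- pos[seg]
  } else {
    m <- matrix(integer(0), nrow = p$sample_n, ncol = 0L)
  }

  if (p$missing_rate > 0 && length(pos)) {
    mask <- matrix(runif(length(m)) < p$missing_rate, nrow = nrow(m))
    m[mask] <- NA_integer_
  }

  truth <- list(sweep_pos = p$sweep_pos, s = if (p$s > 0) p$s else NULL,
                final_derived_freq = final_freq, attempts = attempts)
  if (p$s == 0) truth$sweep_pos <- NULL
  list(hm = haplo_matrix(m, pos, chrom = "1"), truth = truth)
}

#' Simulate a multi-chromosome genome
#'
#' Builds a genome as independent single-chromosome simulations with
#' distinct chromosome names (chromosomes are unlinked, so independent runs
#' concatenate exactly). Each element of `params_list` is simulated with its
#' own parameters; names of the list become chromosome names.
#'
#' @param params_list named list of [sim_params()] objects; unnamed entries
#'   get chromosome names `chr1, chr2, ...`.
#' @return A list with `hms` (list of [haplo_matrix()]) and `truths` (per
#'   chromosome simulation truth).
#' @export
simulate_genome <- function(params_list) {
  stopifnot(length(params_list) >= 1L,
            all(vapply(params_list, inherits, logical(1), "sim_params")))
  nm <- names(params_list)
  if (is.null(nm)) nm <- rep("", length(params_list))
  nm[!nzchar(nm)] <- paste0("chr", which(!nzchar(nm)))
  if (anyDuplicated(nm)) stop("chromosome names must be distinct")
  hms <- vector("list", length(params_list))
  truths <- vector("list", length(params_list))
  for (i in seq_along(params_list)) {
    res <- simulate_population(params_list[[i]])
    res$hm$chrom <- nm[i]
    hms[[i]] <- res$hm
    truths[[i]] <- res$truth
  }
  names(hms) <- names(truths) <- nm
  list(hms = hms, truths = truths)
}

#' Canonical desk-scale study conditions for sweep-recovery experiments
#'
#' Returns the fixed simulation conditions used by the package's
#' sweep-recovery experiments: a rescaled equilibrium population
#' (100 diploids, 1000 generations, `mu = rho = 1e-6` per bp so scaled
#' diversity is 4e-4/bp) on 3 Mb chromosomes, sampled at 60 haplotypes
#' with no missing calls (the statistic operates on phased, imputed data).
#' The `"sweep"` role adds a hard sweep with `s = 2` (`2Ns = 400`, the
#' conventional strong-selection regime once rescaled to N = 100) arising
#' 10 generations before sampling at a window-center position, conditioned
#' on a present population frequency in `[0.6, 0.85]` -- the ongoing-sweep
#' band where the integrated haplotype score has documented power.
#'
#' @param seed RNG seed for the run.
#' @param role `"sweep"` or `"background"` (neutral chromosome).
#' @return A [sim_params()] object.
#' @export
sweep_study_params <- function(seed = 1L, role = c("sweep", "background")) {
  role <- match.arg(role)
  if (role == "sweep")
    sim_params(seq_length = 3e6, s = 2, sweep_pos = 1475000L,
               sweep_start = 990L, min_final_freq = 0.6,
               max_final_freq = 0.85, missing_rate = 0, seed = seed,
               max_retries = 400L)
  else
    sim_params(seq_length = 3e6, missing_rate = 0, seed = seed)
}
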