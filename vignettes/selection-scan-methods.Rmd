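---
title: "Detecting recent positive selection with iHS: models, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting recent positive selection with iHS: models, parameters, design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the statistic

A beneficial mutation rising quickly through a population drags its linked
neighbourhood along: carriers of the favoured (derived) allele share an
unusually long stretch of identical haplotype, because recombination and new
mutation have had little time to break it up. Extended haplotype
homozygosity (EHH) quantifies this: among the `n_c` carriers of a core
allele, EHH at distance `x` is the probability that two carriers drawn at
random are identical at every site from the core out to `x`,

    EHH(x) = sum_h C(n_h, 2) / C(n_c, 2),

where the `n_h` are the sizes of the distinct extended-haplotype groups.
EHH starts at 1 and is non-increasing, since groups only ever split.

Integrating EHH against physical distance (trapezoidal rule, both
directions, truncated where EHH first drops below a cutoff) gives the
integrated haplotype homozygosity iHH, once for the ancestral allele
(iHH_A) and once for the derived allele (iHH_D). The unstandardized score
is `ln(iHH_A / iHH_D)`. Because young (low-frequency) derived alleles sit
on long haplotypes even under neutrality, the log-ratio is strongly
frequency-dependent; it is therefore standardized within derived-allele
frequency bins,

    iHS = ( ln(iHH_A/iHH_D) - E_p ) / SD_p,

with `E_p` and `SD_p` the within-bin sample mean and standard deviation
(`n - 1` denominator — this fixes the worked example in
`?standardize_ihs`). After standardization, |iHS| > 2 flags roughly the
5% tail whatever the allele frequency, and sweeps appear as clusters of
extreme scores.

## Assumptions and validity rules

* **Phased, polarized input.** Haplotypes must be phased; alleles are coded
  0 = ancestral, 1 = derived. Polarization comes from the `AA` INFO tag by
  default, with reference-as-ancestral as a fallback
  (`read_phased_vcf(..., ancestral_source = "REF")`) — how a study
  polarizes its data is a genuine degree of freedom, so it is explicit and
  configurable here.
* **Missing calls break sharing.** During extension a missing call places
  its haplotype in a singleton group, biasing EHH downward; haplotypes
  missing at the core are not carriers. This conservative rule matters:
  at even 2% missingness the chance that a carrier pair survives, say, 35
  sites with no missing call is only about one half, so EHH decay becomes
  missingness-dominated and the long-range signal a sweep relies on is
  destroyed. The statistic is meant for phased, imputed data with
  essentially no missing calls — which is what phasing pipelines emit —
  and the packaged study conditions therefore simulate the iHS stage
  without missingness, while QC fixtures keep a 2% rate to exercise the
  missing-rate filter.
* **Validity flags instead of silent numbers.** A site's score is invalid,
  with a recorded reason, when either allele has fewer than two called
  carriers, when an inter-site gap exceeds 800 kb (the maximum-spacing
  rule; the alternative of capping the gap's area contribution is not the
  default), when an EHH curve is still above the cutoff at the chromosome
  end, or when it is still above the cutoff at the maximum extension
  distance (1 Mb, the conventional scan limit). Invalid scores are
  excluded from standardization and from windows.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `maf` | 0.05 | minimum minor allele frequency (site QC; exactly 0.05 kept) |
| `max_missing` | 0.10 | maximum per-site missing fraction (exactly 0.10 kept) |
| `hwe_p` | 1e-6 | minimum exact Hardy–Weinberg p-value |
| `ehh_cutoff` | 0.05 | EHH truncation level for the iHH integral |
| `max_gap_bp` | 800,000 | maximum tolerated spacing between consecutive sites |
| `max_extend_bp` | 1e6 | maximum EHH extension distance from the core |
| `n_bins` | 100 | derived-frequency standardization bins (merged when < 2 scores) |
| `window_size` | 50,000 | non-overlapping window span (bp) |
| `min_snps` | 10 | minimum valid scores per retained window (exactly 10 kept) |
| `top_fraction` | 0.01 | fraction of retained windows called as regions |
| `fdr` | 0.05 | BH-adjusted significance threshold for QTL enrichment |

Boundary semantics follow the quoted filter inequalities literally: a
missing rate *greater than* 10% excludes, MAF *less than* 5% excludes, and
the GATK INFO thresholds are strict inequalities, so boundary values pass.
The SNP-count rule keeps windows with exactly 10 SNPs (the two natural
readings conflict at exactly 10; the keep-at-10 reading is adopted and the
threshold is configurable). Windows are ranked by the mean of |iHS|; the
absolute mean is also emitted, since "average iHS" is ambiguous between the
two and mean-of-absolute is the standard scan statistic. Window labels are
printed 1-based with `end = start + 50000` (the `chr5:58800001-58850001`
style); internal arithmetic is half-open, and annotation treats the label
end as exclusive so that a gene merely abutting a region does not count.

## The synthetic-data generator

`simulate_population()` is a discrete-generation forward Wright–Fisher
simulator: per-generation Poisson mutation at uniform, never-reused
positions (infinite sites, so every site stays biallelic), Poisson
crossover recombination, and viability selection at one site with genotype
fitnesses 1, 1+hs, 1+s. It is deliberately a forward simulator rather than
a coalescent one: at desk scale it is simpler to verify, and selection,
conditioning and truth extraction are direct.

The default conditions are a *rescaled* population: N = 100 diploids
evolved for 1000 generations (five times the haploid size, so about 95% of
lineage pairs have coalesced and the background sits near
mutation–drift–recombination equilibrium) on chromosomes with
`mu = rho = 1e-6` per bp per generation, giving a scaled diversity of
`4*N*mu = 4e-4` per bp — cattle-like marker density at 1/2500 of a real
population size. Two findings from building this generator shaped the
defaults and are worth recording:

* **Equilibrium matters more than size.** A population founded monomorphic
  and run for only one or two N generations is one giant bottleneck: every
  allele sits on a long shared haplotype, and iHS has no contrast. The
  background must be old relative to 2N.
* **Time scales must be rescaled together.** With mutation and
  recombination rates scaled up by ~2500x, a sweep lasting many tens of
  generations is eroded by mutation as fast as by recombination and loses
  its haplotype signature. The canonical strong-selection regime
  `2Ns = 400` at N = 100 means s = 2 and a sweep lasting ~10 generations
  — which is the faithful rescaling of a strong sweep, not an exaggeration.

`sweep_study_params()` packages the canonical sweep scenario: a 3 Mb
chromosome, the beneficial mutation arising 10 generations before sampling
at a window-center position, conditioned on a present population frequency
in [0.6, 0.85] — the ongoing-sweep band in which iHS has documented power
(a sweep observed near fixation leaves only a handful of ancestral
carriers, themselves recently coalesced, and the contrast collapses).
Conditioning works by re-running the selection phase on a cached neutral
burn-in with a fresh RNG substream per attempt; a fixed seed still gives
bit-identical output, and neutral runs are single-pass.

What the generator does **not** emulate: realistic demography (the real
population is admixed with unknown history), gene conversion, background
selection, variable recombination maps, genotyping error. Passing tests
show the statistic and the plumbing behave as specified on a clean
equilibrium background with hard sweeps; they do not certify power on real
livestock data.

## Window selection at desk scale

Sweep-recovery experiments use a replicate genome of one sweep chromosome
plus two neutral chromosomes (9 Mb, ~170 retained windows). Standardization
is pooled across chromosomes — frequency bins must be anchored by
predominantly neutral variation, which is also why the neutral chromosomes
are there: on a lone sweep chromosome the high-frequency bins are dominated
by the sweep's own sites and standardization subtracts the signal away.

Top-1% selection of ~170 windows yields exactly one region
(`floor(0.01 * n)`), while an ongoing sweep's footprint spans several
adjacent windows and the |iHS| peak frequently sits one window off the
core. At full scale this is immaterial — a 495-window selected set swallows
a whole footprint — but a one-window selected set demands sub-footprint
localization. The recovery criterion therefore counts a replicate as
recovered when the selected region is the core window or immediately
adjacent to it (within one 50 kb window). The realized localization of the
method at these conditions, and its failure modes (occasionally a shoulder
window two or three windows out carries the maximum, rarely a neutral
excursion wins outright), are visible in the acceptance test.

## Numerical choices and degenerate inputs

* The HWE exact test computes the conditional distribution of the
  heterozygote count by the standard ratio recurrence (stable for large
  samples) and sums all outcomes no more probable than the observed one,
  with a `1 + 1e-12` relative guard against ties lost to floating point.
  Monomorphic tables give p = 1.
* The iHH trapezoid includes the final segment ending at the first
  sub-cutoff EHH point.
* Standardization merges any bin with fewer than two valid scores, or zero
  spread, into its nearest occupied lower-frequency neighbour (the next
  higher one at the low end); an all-degenerate input is an error, not a
  NaN.
* Ties at the top-1% selection boundary are broken by (chrom, start) order
  with a warning; `floor` semantics make the full-scale arithmetic exact
  (1% of 49,562 retained windows is 495 regions).
* Empty results degrade gracefully: QC may return an empty matrix with a
  warning, `select_top` warns and returns nothing when the fraction selects
  zero windows, and regions without genes keep a row with `NA` gene.

## Known limitations

* Integration is over physical distance only; no genetic-map option.
* The enrichment test is a plain one-sided hypergeometric with BH-FDR.
  Dedicated livestock-QTL enrichment tools differ in their exact statistic,
  so enrichment output is comparable in structure (richness factor, FDR,
  trait class) but not numerically interchangeable.
* A gene overlapping two selected windows is counted once in the distinct
  gene count.
* The simulator is single-chromosome per run; multi-chromosome genomes are
  built by concatenating independent runs (`simulate_genome()`), which is
  exact for unlinked chromosomes but cannot create inter-chromosome LD.
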