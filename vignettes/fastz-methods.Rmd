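---
title: "Methods and design choices in fastz"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design choices in fastz}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`fastz` implements a pipeline for separating drift-driven from
adaptation-driven evolution of the Z chromosome in ZW systems: sex-aware
filtering, ancestral-allele polarization, diversity-based and
trajectory-based Z:A effective-population-size ratios, coding-sequence
selection summaries on GC-conservative sites, windowed differentiation and
sweep post-processing, and frequency-based introgression statistics with
block-jackknife inference. This vignette records the statistical model
behind each stage, the tunable parameters and their defaults, and the design
decisions taken where the methodology was genuinely open.

## The synthetic-data generator

Every stage of the pipeline is exercised against data with known truth from
a structured-coalescent simulator (`sim_config()`, `simulate_dataset()`).

**Model.** Five populations — two sister pairs ((P1, P2), (P3, P4)) and an
outgroup — exchange ancestry backward in time through population splits at
`split_times` (generations) and, optionally, migration that moves P2
lineages into P3 at rate `migration_rate` per generation (forward-time
P3→P2 gene flow), active until the first pair split. Each locus is an
independent neutral genealogy: waiting times are exponential with
coalescence rate k(k−1)/2 per 2N within each population and mutations fall
on branches as a Poisson process under infinite sites. There is no
recombination within loci; loci are fully unlinked, and the physical
coordinates assigned to them (`locus_spacing`) matter only for windowed
statistics and jackknife blocks.

**ZW structure.** Z-linked loci coalesce in populations of size
`z_a_ratio * ne` and mutate at `male_bias * mu`; female samples contribute
a single Z lineage and are emitted as haploid genotypes, which is what makes
the sex-aware filters and the hemizygosity accounting testable. Defaults
mirror the structure of flycatcher-style resequencing studies: `rho = 0.75`
(the neutral expectation at equal breeding sex numbers), `male_bias = 1.1`
(the conventional correction for male-biased mutation in passerines),
`mu = 4.6e-9` per site per generation (the pedigree-based flycatcher rate),
`ne = 2e5` per population, and split times of 0.3/0.6/1/2 Myr-scale
generations, giving per-site diversity near 0.004 — the magnitude seen in
real flycatcher data. A generation time of 2 years is used only when
trajectories are rescaled to years (`rescale_psmc()`); the simulator itself
works in generations.

**What is not emulated.** Linked selection, background selection, gene
conversion (including its GC bias), recombination within loci, mutation-rate
heterogeneity, and genotyping error beyond the synthetic depth/GQ
annotations. Tests that pass on this generator therefore validate the
estimators' algebra and calibration under neutrality, not robustness to
those confounders; on real data the GC-conservative and
linked-selection-masked variants of the diversity ratios exist precisely
because the confounders do.

## Filtering and the callable-site ledger

Genotype filters remove calls with depth outside (5, 200) exclusive or with
GQ not strictly above the threshold — 30 for autosomal and male-Z calls, 15
for hemizygous female-Z calls. Strict inequality ("GQ > 30 keeps 31") was
adopted because the thresholds are conventionally quoted as "GQ > x"; a GQ
of exactly 30 is removed. Site filters then drop (a) Z sites where any
female call is still heterozygous — a female cannot be heterozygous on Z,
so the whole site is treated as unreliable rather than just the offending
genotype, (b) sites with more than 10% missing calls in any species, where
a hemizygous female Z call counts as one observation, and (c) sites
overlapping the repeat mask. The callable-site ledger `L` (variant plus
monomorphic callable sites per chromosome class) is maintained through
filtering because it is the denominator of every per-site statistic;
`filter_sites()` also emits a per-rule removal report.

## Diversity and the Z:A ratio of Ne

Diversity is the uncorrected per-site heterozygosity
`pi = sum_i 2 p_i q_i / L` over variable sites — deliberately without the
n/(n−1) sample-size correction, matching how the quantity is conventionally
reported in this literature. Three site filters are offered: all SNPs,
GC-conservative SNPs only (both alleles strong or both weak, immune to
GC-biased gene conversion), and linked-selection masking, which excludes
sites inside exons and CNEs of at least 100 bp extended by 1-kb flanks
(`build_linked_selection_mask()`) and shrinks `L` by the masked callable
footprint. The Z:A ratio divides the Z estimate by `alpha = 1.1` before the
ratio, converting a diversity ratio into an Ne ratio under male-biased
mutation. The trajectory-based analog (`harmonic_mean_ne_ratio()`)
resamples two Ne trajectories piecewise-constant onto a 1000-year grid from
the present to 1 Mya and takes the ratio of harmonic means, again dividing
the Z side by `alpha`.

**Bootstrap universes.** `bootstrap_ci()` implements the percentile
bootstrap over sites in two variants, and the distinction matters at small
scale. Resampling the observed variable sites with their count held fixed
(`universe = "variable"`) reproduces the procedure as conventionally
described, and at genome scale (millions of SNPs) it is accurate because
the segregating-site count carries negligible relative variance. On
desk-scale datasets, however, the count itself is Poisson-variable and
carries most of the sampling variance of `pi`; fixed-count resampling then
understates uncertainty by a factor of roughly `CV^2 / (1 + CV^2)` in
variance, where CV is the coefficient of variation of the per-site `2pq`
contributions. `universe = "callable"` therefore resamples the full
callable universe of `L` sites — monomorphic sites contributing zero —
implemented via the exact equivalence of drawing a Binomial(L, s/L)
variable-site count first. `compute_pi()` defaults to the literal variant;
`z_a_ratio()` defaults to the callable variant so that its CI is calibrated
at any scale (the two coincide asymptotically). Resampling is independent
between the Z and autosomal classes, as the ratio's two inputs come from
disjoint site sets.

**Parameter recovery design.** The recovery suite in the tests simulates
`rho` in {0.6, 0.75, 1.0} with 1000 autosomal and 800 Z loci of 50 bp,
sampling males only. Two deliberate choices: male-only sampling equalizes
allele counts between the classes so the (n−1)/n finite-sample factor of
the uncorrected estimator cancels exactly in the ratio (with mixed-sex
sampling at these sizes it biases the ratio several percent downward,
while at a study scale of ~190 genomes the bias is negligible); and short
loci keep the expected number of SNPs per locus below about one so that
per-site resampling is a good approximation to per-locus resampling. Under
these conditions the 95% callable-universe CIs cover the true `rho` in
roughly 9 of 10 replicates, which is what the acceptance suite asserts
across 60 seeded runs.

**Breeding-sex expressions.** `za_breeding_ratio()` evaluates
`Ne_A = 4 Nm Nf / (Nm + Nf)` and `Ne_Z = 9 Nm Nf / (4 Nm + 2 Nf)`; the
ratio is 3/4 at parity and tends to 9/16 when breeding females are scarce
and 9/8 when breeding males are scarce.

## Polarization and the ancestral sequence

An allele is ancestral when at least two of three groups — the outgroup and
the two ingroup species pairs — are fixed for it; "fixed" requires at least
`min_calls` non-missing allele observations (default 1, appropriate for a
single outgroup individual) and no alternative allele. Groups that are
polymorphic or entirely missing do not veto: a site fixed for the same
allele in the two informative groups is polarized. A two-versus-one split
of fixed groups resolves to the majority allele. `build_ancestral_sequence()`
rewrites a reference: non-genotyped positions and unpolarized variable
positions become `N`; polarized positions take the ancestral allele.

## Coding-sequence selection summaries

Degeneracy is classified per CDS base from the standard nuclear code:
zero-fold if all three substitutions change the amino acid, four-fold if
none does. Genes with frame violations or internal stops are skipped with a
warning. `pi_n_pi_s()` is the ratio of per-site diversity at zero-fold over
four-fold sites with class-specific `L` from the degeneracy table,
restricted by default to GC-conservative polymorphisms; CIs resample genes
with replacement (100 replicates), since sites within a gene share history.

The `dN/dS` aggregation normalizes each GC-conservative substitution class
by the fraction of sites able to undergo it — S-to-S counts divided by
`f_GC`, W-to-W counts by `f_AT = 1 - f_GC` (length-weighted pooled
fractions) — and sums the two, separately for nonsynonymous and synonymous
counts. The alternative reading that multiplies counts by the proportions
instead of dividing is available as `weighting = "multiply"`; the divide
form is the default because it is the one under which each class is scaled
to a per-opportunity rate before summation. `build_sfs()` tallies unfolded
derived-allele counts per degeneracy class (unpolarized sites excluded;
population-monomorphic sites retained regardless of the GC filter, which
applies to polymorphisms) and `write_sfs()` emits the spectra in a
DFE-style text layout. DFE model fitting itself is out of scope.

## Windowed differentiation

`window_fst()` computes per-site Weir–Cockerham (1984) variance components
a, b, c — sample sizes in individuals, heterozygote frequencies from
diploid calls, hemizygous calls contributing half an individual — and the
weighted window estimator `sum(a)/sum(a+b+c)` over 200-kb windows tiled
from position 0 on each chromosome; trailing partial windows are kept and
flagged, negative estimates are reported as computed, and empty windows are
`NA`.

Peak and outlier calling share one engine (`call_window_outliers()`) with
two orderings. F_ST peaks: z-transform per chromosome (that chromosome's
mean and SD), then Savitzky–Golay smoothing, then flag smoothed values
above 2. f_d outliers: smooth per chromosome first, then z-transform the
smoothed values with the genome-wide mean and SD, and flag values at or
below −2. The filter defaults to window length 5 and polynomial order 3 —
values not dictated by the methodology and therefore exposed as arguments;
edge windows are handled by the truncated-window polynomial refit that
`signal::sgolayfilt` performs. Chromosomes with fewer usable windows than
the filter length are skipped with a warning, and a numerically constant
series z-transforms to zero rather than to noise.

PBS uses `T = -ln(1 - F_ST)` with pairwise values at or above 1 either
dropped (default) or capped, and outliers are flagged with the same
smoothed z > 2 procedure as F_ST peaks.

**Sweep post-processing.** Significant CLR positions (strictly above the
threshold, default 46.25 — a value calibrated elsewhere against
background-selection simulations, accepted here as input) are merged when
adjacent on the test grid; an intervening non-significant grid position
breaks a region. Regions with a single position, or spanning fewer than 1
significant site per kb (count divided by span in kb; exactly 1 is kept),
are removed, and presence/absence is marked in 200-kb windows.

## Introgression

`patterson_d()` evaluates the frequency form of the ABBA-BABA statistic
with sums taken before the ratio. `block_jackknife_d()` deletes physical
200-kb blocks (blocks without informative sites are dropped from n) and
uses `SE = sqrt(((n-1)/n) * sum((theta_i - mean(theta))^2))` over the
delete-one estimates, `z = D/SE`, two-sided normal p. `fd_windows()`
normalizes the window D-numerator by its value with the donor frequency set
to `max(p2, p3)` per site; windows with a negative numerator, a zero
denominator, or fewer than `min_sites` informative sites (default 10, a
guard against the noisy microchromosome-like windows) are reported missing.
Sites with a missing frequency in any of P1/P2/P3 are excluded listwise.
The recombination regression is ordinary least squares of window f_d on
the local recombination rate, reporting R², slope and the slope's p-value.

## Overlap and enrichment

Fixed differences require each species fixed for different alleles among
non-missing calls (no additional minimum-count rule beyond the upstream
missingness filter); shared polymorphisms segregate within both species of
the pair. Functional categories resolve overlapping annotations with the
fixed precedence zero-fold > four-fold > UTR > CNE > intron > intergenic —
coding degeneracy beats regulatory annotation; the choice is recorded here
because annotations do overlap and the literature leaves the precedence
implicit. Enrichment tables report the sample cross-product odds ratio
`(a d)/(b c)` — the quantity conventionally printed alongside such tables,
not the conditional MLE that `fisher.test()` estimates — with the
two-sided Fisher exact p-value (sum of hypergeometric probabilities at most
as likely as observed); a zero cell yields an infinite OR with the
one-sided p.

## Problem sizes, tolerances and limitations

The test and acceptance suites run at desk scale: oracle-equivalence checks
use toys of at most 1000 sites at 1e-10 relative tolerance; the
D-statistic checks use 250 loci of 1 kb; the recovery suite 1800 loci of
50 bp across 60 seeded replicates. These sizes make the suites complete in
a few minutes on one CPU while keeping every assertion statistically
meaningful; they are choices of this package, and all of them scale up
through `sim_config()`.

Known limitations: the generator's neutrality (above); the VCF writer
records monomorphic reference bases as `N` because the container does not
carry a reference sequence; multi-allelic sites are not represented
(biallelic retention is assumed upstream); and PSMC-style trajectory
inference is not reimplemented — trajectories enter as tables, with
`rescale_psmc()` provided for the conventional rescaling with generation
time 2 years and the pedigree mutation rate.
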