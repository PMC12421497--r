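#' Classify a biallelic site as GC-conservative
#'
#' GC-conservative variants are immune to GC-biased gene conversion: both
#' alleles strong (G/C, "S-to-S") or both weak (A/T, "W-to-W").
#'
#' @param ref,alt Character vectors of alleles.
#' @return Logical vector.
#' @export
classify_gc_conservative <- function(ref, alt) {
  ok <- c("A", "C", "G", "T")
  if (!all(ref %in% ok) || !all(alt %in% ok)) {
    abort("non-ACGT allele in GC-conservative classification")
  }
  strong <- c("G", "C")
  (ref %in% strong & alt %in% strong) | (!ref %in% strong & !alt %in% strong)
}

#' Linked-selection mask from exons and conserved noncoding elements
#'
#' Builds the union of exons and CNEs (CNEs shorter than `min_cne_bp` are
#' dropped), each extended by `flank` bp on both sides, merged per
#' chromosome. Intervals are 1-based inclusive.
#'
#' @param exons,cnes Tibbles with `chrom`, `start`, `end`.
#' @param flank Flanking extension in bp (default 1000).
#' @param min_cne_bp Minimum CNE length retained (default 100).
#' @return Tibble of merged intervals `chrom`, `start`, `end`.
#' @export
build_linked_selection_mask <- function(exons, cnes, flank = 1000,
                                        min_cne_bp = 100) {
  if (flank < 0) abort("flank must be non-negative")
  cnes <- dplyr::filter(cnes, .data$end - .data$start + 1 >= min_cne_bp)
  iv <- bind_rows(exons, cnes) |>
    mutate(start = pmax(1, .data$start - flank), end = .data$end + flank)
  if (nrow(iv) == 0) return(tibble(chrom = character(), start = integer(),
                                   end = integer()))
  iv |>
    group_by(.data$chrom) |>
    dplyr::reframe({
      r <- IRanges::reduce(IRanges::IRanges(start, end))
      tibble(start = IRanges::start(r), end = IRanges::end(r))
    }) |>
    ungroup()
}

# bp of mask overlapping the callable loci of one class
masked_bp <- function(loci, mask) {
  tot <- 0
  for (ch in unique(loci$chrom)) {
    l <- loci[loci$chrom == ch, ]
    m <- mask[mask$chrom == ch, , drop = FALSE]
    if (nrow(m) == 0) next
    ir_l <- IRanges::IRanges(l$start, l$end)
    ir_m <- IRanges::reduce(IRanges::IRanges(m$start, m$end))
    tot <- tot + sum(IRanges::width(IRanges::intersect(ir_l, ir_m)))
  }
  tot
}

# logical: site inside mask
in_mask <- function(chrom, pos, mask) {
  hit <- rep(FALSE, length(pos))
  for (ch in unique(chrom)) {
    m <- mask[mask$chrom == ch, , drop = FALSE]
    if (nrow(m) == 0) next
    i <- chrom == ch
    hit[i] <- IRanges::overlapsAny(
      IRanges::IRanges(pos[i], width = 1),
      IRanges::IRanges(m$start, m$end))
  }
  hit
}

#' Percentile bootstrap over sites
#'
#' Returns the percentile 95% confidence interval of `sum(contrib)/L` under
#' site resampling with replacement. Two resampling universes are offered:
#'
#' * `"variable"`: resample the observed variable sites, holding their
#'   number fixed (the resampling scheme conventionally reported with
#'   genome-scale diversity estimates). With millions of SNPs the
#'   segregating-site count carries negligible relative variance and this CI
#'   is accurate; on small datasets it understates uncertainty because the
#'   count itself is random.
#' * `"callable"`: resample the full callable-site universe of L sites, of
#'   which the variable ones carry the observed contributions and the rest
#'   contribute zero. Computed via the exact binomial equivalence (draw the
#'   resampled variable-site count, then values). This CI also propagates
#'   the count variance and is calibrated at any scale.
#'
#' @param contrib Numeric vector of per-site contributions (e.g. `2 p q`).
#' @param L Callable-site denominator.
#' @param n_reps Number of bootstrap replicates (default 1000).
#' @param seed Integer seed (reproducible).
#' @param probs CI quantiles, default `c(0.025, 0.975)`.
#' @param universe `"variable"` (default) or `"callable"`.
#' @return Named numeric `c(lo, hi)`.
#' @export
bootstrap_ci <- function(contrib, L, n_reps = 1000, seed = 1,
                         probs = c(0.025, 0.975),
                         universe = c("variable", "callable")) {
  universe <- match.arg(universe)
  if (n_reps < 2) abort("n_reps must be >= 2")
  if (length(contrib) < 1) abort("need at least one variable site")
  set.seed(seed)
  reps <- boot_reps(contrib, L, n_reps, universe)
  q <- unname(quantile(reps, probs, type = 7))
  c(lo = q[1], hi = q[2])
}

# bootstrap replicate sums/L (no seed handling; caller sets the seed)
boot_reps <- function(contrib, L, n_reps, universe) {
  s <- length(contrib)
  if (universe == "variable") {
    draws <- matrix(sample(contrib, s * n_reps, replace = TRUE), nrow = n_reps)
    rowSums(draws) / L
  } else {
    counts <- stats::rbinom(n_reps, L, s / L)
    vals <- sample(contrib, sum(counts), replace = TRUE)
    grp <- rep.int(seq_len(n_reps), counts)
    out <- numeric(n_reps)
    if (length(vals) > 0) {
      agg <- tapply(vals, factor(grp, levels = seq_len(n_reps)), sum)
      out <- ifelse(is.na(agg), 0, as.numeric(agg))
    }
    out / L
  }
}

#' Nucleotide diversity from allele frequencies
#'
#' Computes pi = sum over variable sites of `2 p q`, divided by the number
#' of callable sites L (variant + monomorphic) — no sample-size correction.
#' Frequencies are taken from non-missing alleles of the focal population;
#' hemizygous female Z calls contribute one allele.
#'
#' @param x A [geno_data] object.
#' @param pop Population label whose diversity is estimated.
#' @param class Chromosome class, `"A"` or `"Z"`.
#' @param site_filter `"all"`, `"gc"` (GC-conservative SNPs only) or
#'   `"masked"` (exclude sites inside `mask` and shrink L by the masked
#'   callable footprint).
#' @param mask Interval tibble (`chrom`, `start`, `end`) required for
#'   `site_filter = "masked"`; see [build_linked_selection_mask()].
#' @param n_boot Bootstrap replicates for the CI (0 to skip).
#' @param seed Bootstrap seed.
#' @param universe Bootstrap resampling universe (see [bootstrap_ci()]).
#' @return One-row tibble: `pop`, `class`, `site_filter`, `s`, `L`, `pi`,
#'   `ci_lo`, `ci_hi`; per-site contributions are attached as attribute
#'   `"contrib"` for downstream ratio bootstraps.
#' @export
compute_pi <- function(x, pop, class = "A",
                       site_filter = c("all", "gc", "masked"), mask = NULL,
                       n_boot = 1000, seed = 1,
                       universe = c("variable", "callable")) {
  universe <- match.arg(universe)
  site_filter <- match.arg(site_filter)
  L <- x$ledger$L[x$ledger$class == class]
  if (length(L) != 1 || L <= 0) abort("undefined estimate: L = 0 for class")
  sel <- x$sites$class == class
  if (site_filter == "gc") {
    sel <- sel & classify_gc_conservative(x$sites$ref, x$sites$alt)
  }
  if (site_filter == "masked") {
    if (is.null(mask)) abort("site_filter = \"masked\" needs a mask")
    sel <- sel & !in_mask(x$sites$chrom, x$sites$pos, mask)
    L <- L - masked_bp(x$loci[x$loci$class == class, ], mask)
    if (L <= 0) abort("undefined estimate: masked L = 0")
  }
  sm <- x$samples$sample[x$samples$pop == pop]
  if (length(sm) == 0) abort(paste0("population not found: ", pop))
  ac <- allele_counts(x, sm)
  p <- ac$alt[sel] / ac$tot[sel]
  p <- p[!is.na(p)]
  variable <- p > 0 & p < 1
  contrib <- 2 * p[variable] * (1 - p[variable])
  pi <- sum(contrib) / L
  ci <- c(lo = NA_real_, hi = NA_real_)
  if (n_boot > 0 && length(contrib) >= 1) {
    ci <- bootstrap_ci(contrib, L, n_reps = n_boot, seed = seed,
                       universe = universe)
  }
  out <- tibble(pop = pop, class = class, site_filter = site_filter,
                s = sum(variable), L = L, pi = pi,
                ci_lo = ci["lo"], ci_hi = ci["hi"])
  attr(out, "contrib") <- contrib
  out
}

#' Z:A effective-population-size ratio from diversity
#'
#' Computes `(pi_Z / alpha) / pi_A`: the Z-linked diversity is first divided
#' by the male-bias mutation factor `alpha` so that the ratio reflects Ne
#' rather than mutation rate. When both inputs are [compute_pi()] results
#' carrying per-site contributions, a percentile bootstrap CI of the ratio is
#' computed by resampling variable sites independently within each
#' chromosome class.
#'
#' @param pi_z,pi_a Numbers, or one-row tibbles from [compute_pi()].
#' @param alpha Male-bias correction factor (default 1.1).
#' @param n_boot Bootstrap replicates (used only with [compute_pi()] inputs).
#' @param seed Bootstrap seed.
#' @param universe Bootstrap resampling universe (see [bootstrap_ci()]);
#'   defaults to `"callable"` so that the ratio CI also propagates the
#'   stochasticity of the segregating-site counts, which fixed-count
#'   resampling omits (the two coincide at genome scale).
#' @return One-row tibble: `ratio`, `alpha`, `method`, `ci_lo`, `ci_hi`.
#' @export
z_a_ratio <- function(pi_z, pi_a, alpha = 1.1, n_boot = 1000, seed = 1,
                      universe = c("callable", "variable")) {
  universe <- match.arg(universe)
  val <- function(p) if (is.data.frame(p)) p$pi else p
  vz <- val(pi_z)
  va <- val(pi_a)
  if (va == 0) abort("undefined ratio: pi_A = 0")
  ratio <- (vz / alpha) / va
  method <- if (is.data.frame(pi_z)) {
    switch(pi_z$site_filter[1], all = "All sites", gc = "GC cons",
           masked = "No LS")
  } else "All sites"
  ci_lo <- ci_hi <- NA_real_
  cz <- attr(pi_z, "contrib")
  ca <- attr(pi_a, "contrib")
  if (!is.null(cz) && !is.null(ca) && n_boot > 0 &&
      length(cz) >= 1 && length(ca) >= 1) {
    set.seed(seed)
    reps_z <- boot_reps(cz, pi_z$L, n_boot, universe)
    reps_a <- boot_reps(ca, pi_a$L, n_boot, universe)
    r <- (reps_z / alpha) / reps_a
    q <- unname(quantile(r[is.finite(r)], c(0.025, 0.975)))
    ci_lo <- q[1]
    ci_hi <- q[2]
  }
  tibble(ratio = ratio, alpha = alpha, method = method,
         ci_lo = ci_lo, ci_hi = ci_hi)
}

#' Rescale PSMC output to years and effective size
#'
#' Applies the conventional rescaling of scaled PSMC estimates: `N0 =
#' theta0 / (4 mu s)` with bin size `s`, times `t_k` converted to years via
#' `2 N0 t_k g`, and sizes `lambda_k N0`.
#'
#' @param tbl Tibble with columns `t_k`, `lambda_k` and `theta0` (scaled
#'   PSMC output).
#' @param mu Mutation rate per site per generation (default 4.6e-9).
#' @param s Bin size in bp used when generating the PSMC input (default 100).
#' @param gen_years Generation time in years (default 2).
#' @return Tibble `time_years`, `ne`, ascending in time.
#' @export
rescale_psmc <- function(tbl, mu = 4.6e-9, s = 100, gen_years = 2) {
  n0 <- tbl$theta0 / (4 * mu * s)
  tibble(time_years = 2 * n0 * tbl$t_k * gen_years, ne = tbl$lambda_k * n0) |>
    arrange(.data$time_years)
}

# piecewise-constant resampling of a trajectory onto a fixed grid
resample_trajectory <- function(traj, t_max = 1e6, step = 1000) {
  if (any(traj$ne <= 0)) abort("Ne must be strictly positive")
  traj <- arrange(traj, .data$time_years)
  grid <- seq(step, t_max, by = step)
  ne <- stats::approx(traj$time_years, traj$ne, xout = grid,
                      method = "constant", f = 0, rule = 2)$y
  tibble(time_years = grid, ne = ne)
}

#' Harmonic-mean Ne ratio from demographic trajectories
#'
#' Resamples both trajectories piecewise-constant onto a common 1000-year
#' grid from the present back to `t_max` (default 1 Mya), takes the harmonic
#' mean `n / sum(1/Ne_t)` of each, and returns `(H_Z / alpha) / H_A`.
#'
#' @param traj_z,traj_a Tibbles with `time_years`, `ne` (see
#'   [rescale_psmc()]).
#' @param alpha Male-bias correction factor (default 1.1).
#' @param t_max Oldest time used, in years (default 1e6).
#' @param step Grid step in years (default 1000).
#' @return One-row tibble: `ratio`, `alpha`, `method = "PSMC"`, `h_z`, `h_a`.
#' @export
harmonic_mean_ne_ratio <- function(traj_z, traj_a, alpha = 1.1,
                                   t_max = 1e6, step = 1000) {
  hz <- resample_trajectory(traj_z, t_max, step)
  ha <- resample_trajectory(traj_a, t_max, step)
  hmean <- function(v) length(v) / sum(1 / v)
  h_z <- hmean(hz$ne)
  h_a <- hmean(ha$ne)
  tibble(ratio = (h_z / alpha) / h_a, alpha = alpha, method = "PSMC",
         h_z = h_z, h_a = h_a)
}

#' Z:A Ne ratio under unequal breeding sex numbers
#'
#' Standard breeding-sex expressions for a ZW system: `Ne_A = 4 Nm Nf /
#' (Nm + Nf)` and `Ne_Z = 9 Nm Nf / (4 Nm + 2 Nf)`, giving a ratio of 3/4
#' at equal numbers and analytic limits of 9/16 (breeding females scarce)
#' and 9/8 (breeding males scarce).
#'
#' @param n_males,n_females Numbers of breeding males and females (> 0).
#' @return Numeric ratio `Ne_Z / Ne_A`.
#' @export
za_breeding_ratio <- function(n_males, n_females) {
  if (any(n_males <= 0) || any(n_females <= 0)) {
    abort("breeding numbers must be positive")
  }
  ne_a <- 4 * n_males * n_females / (n_males + n_females)
  ne_z <- 9 * n_males * n_females / (4 * n_males + 2 * n_females)
  ne_z / ne_a
}
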