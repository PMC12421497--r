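#' Simulation configuration for the ZW-aware data generator
#'
#' Describes the demography and mutational model of the synthetic dataset:
#' two sister-species pairs ((P1, P2), (P3, P4)) plus an outgroup (OUT),
#' autosomal and Z-linked loci, a Z:A effective-population-size ratio `rho`,
#' male-biased mutation on the Z (`alpha`), and optional unidirectional gene
#' flow from P3 into P2 after their split (matching a four-taxon ABBA-BABA
#' design that tests P2-P3 gene flow).
#'
#' @param n_autosomal_loci,n_z_loci Number of independent loci per class.
#' @param locus_length Locus length in bp.
#' @param ne Diploid effective population size of every population (autosomal).
#' @param z_a_ratio Z:A ratio of Ne (`rho`), in (0, 9/8]. Z loci coalesce in a
#'   population of size `rho * ne`.
#' @param male_bias Z-to-autosome mutation-rate multiplier `alpha` (>= 1);
#'   default 1.1, the correction conventionally applied for male-biased
#'   mutation in birds.
#' @param mu Mutation rate per site per generation; default 4.6e-9, the
#'   flycatcher pedigree-based rate.
#' @param split_times Named numeric vector of split times in generations:
#'   `pair1` (P1/P2), `pair2` (P3/P4), `root` (cross-pair), `outgroup`.
#'   Must satisfy `pair1, pair2 <= root <= outgroup`.
#' @param migration_rate Backward per-generation probability that a P2
#'   lineage traces to P3 (forward P3 -> P2 gene flow), active between the
#'   present and `min(pair1, pair2)`.
#' @param z_migration_scale Multiplier applied to `migration_rate` for
#'   Z-linked loci (default 1). Values below 1 emulate a large-Z effect:
#'   reduced effective gene flow on the Z relative to the autosomes.
#' @param samples_per_pop Diploid individuals per ingroup population (single
#'   number, or named vector over `P1, P2, P3, P4, OUT`).
#' @param sex_pattern `"alternating"` (M, F, M, ... within each population;
#'   the default, emulating mixed-sex resequencing panels) or `"male_only"`.
#'   Male-only sampling equalizes the allele count between autosomes and the
#'   Z (males are ZZ), so that the finite-sample factor (n-1)/n of the
#'   uncorrected diversity estimator cancels exactly in Z:A ratios — the
#'   appropriate design for parameter-recovery studies. The outgroup
#'   individual is always male.
#' @param n_autosomes Autosomal loci are tiled across this many chromosomes
#'   (`chr1`, `chr2`, ...); Z loci all lie on `chrZ`.
#' @param locus_spacing Distance between locus start positions in bp; loci do
#'   not recombine internally and are fully independent, spacing only sets
#'   physical coordinates used by windowed statistics and jackknife blocks.
#' @param ref_flip_prob Probability that the derived allele is used as the
#'   VCF REF allele at a variant site (the reference individual may carry the
#'   derived state); genotypes are recoded accordingly.
#' @param miss_rate Per-genotype missingness probability.
#' @param attach_qc Attach synthetic per-genotype depth (Poisson, mean 30)
#'   and genotype quality (uniform 60-99) matrices so that the genotype
#'   filters can be exercised.
#' @param seed Integer seed; the full dataset is reproducible bit-for-bit
#'   from the configuration.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_autosomal_loci = 150,
                       n_z_loci = 100,
                       locus_length = 2000,
                       ne = 2e5,
                       z_a_ratio = 0.75,
                       male_bias = 1.1,
                       mu = 4.6e-9,
                       split_times = c(pair1 = 3e5, pair2 = 6e5,
                                       root = 1e6, outgroup = 2e6),
                       migration_rate = 0,
                       z_migration_scale = 1,
                       samples_per_pop = 4,
                       sex_pattern = c("alternating", "male_only"),
                       n_autosomes = 4,
                       locus_spacing = 50000,
                       ref_flip_prob = 0.2,
                       miss_rate = 0,
                       attach_qc = TRUE,
                       seed = 1L) {
  pops <- c("P1", "P2", "P3", "P4", "OUT")
  if (length(samples_per_pop) == 1) {
    samples_per_pop <- c(P1 = samples_per_pop, P2 = samples_per_pop,
                         P3 = samples_per_pop, P4 = samples_per_pop, OUT = 1)
  }
  samples_per_pop <- samples_per_pop[pops]
  sex_pattern <- match.arg(sex_pattern)
  cfg <- list(
    sex_pattern = sex_pattern,
    n_autosomal_loci = n_autosomal_loci, n_z_loci = n_z_loci,
    locus_length = locus_length, ne = ne, z_a_ratio = z_a_ratio,
    male_bias = male_bias, mu = mu, split_times = split_times,
    migration_rate = migration_rate, z_migration_scale = z_migration_scale,
    samples_per_pop = samples_per_pop,
    n_autosomes = n_autosomes, locus_spacing = locus_spacing,
    ref_flip_prob = ref_flip_prob, miss_rate = miss_rate,
    attach_qc = attach_qc, seed = as.integer(seed)
  )
  bad <- function(msg) abort(paste0("invalid sim_config: ", msg),
                             class = "fastz_config_error")
  if (anyNA(samples_per_pop) || any(samples_per_pop < 1)) bad("samples_per_pop")
  if (n_autosomal_loci < 0 || n_z_loci < 0) bad("negative locus counts")
  if (locus_length <= 0) bad("locus_length must be positive")
  if (ne <= 0) bad("ne must be positive")
  if (z_a_ratio <= 0 || z_a_ratio > 9 / 8) bad("z_a_ratio must be in (0, 9/8]")
  if (male_bias < 1) bad("male_bias must be >= 1")
  if (mu <= 0) bad("mu must be positive")
  st <- split_times
  if (!all(c("pair1", "pair2", "root", "outgroup") %in% names(st))) {
    bad("split_times needs pair1, pair2, root, outgroup")
  }
  if (any(st <= 0)) bad("split times must be positive")
  if (st["pair1"] > st["root"] || st["pair2"] > st["root"] ||
      st["root"] > st["outgroup"]) bad("split times must be nested")
  if (migration_rate < 0 || migration_rate >= 1) bad("migration_rate in [0,1)")
  if (z_migration_scale < 0) bad("z_migration_scale must be non-negative")
  if (miss_rate < 0 || miss_rate >= 1) bad("miss_rate in [0,1)")
  if (locus_spacing < locus_length) bad("locus_spacing < locus_length")
  structure(cfg, class = "sim_config")
}

# sample table implied by a sim_config
sim_samples <- function(cfg) {
  purrr::imap(as.list(cfg$samples_per_pop), function(n, pop) {
    sex <- if (pop == "OUT" || cfg$sex_pattern == "male_only") rep("M", n)
      else rep(c("M", "F"), length.out = n)
    tibble(sample = paste0(pop, "_", seq_len(n)), pop = pop, sex = sex)
  }) |> list_rbind()
}

# one structured-coalescent genealogy; lineage_pop: integer pop index per
# starting lineage (1=P1..5=OUT); N: per-population size (constant, shared by
# ancestral populations); returns parent pointers, node times
sim_genealogy <- function(lineage_pop, N, split_times, mig_rate) {
  n_tips <- length(lineage_pop)
  n_nodes <- 2L * n_tips - 1L
  parent <- integer(n_nodes)
  node_time <- numeric(n_nodes)
  # demographic events, backward in time: (time, from-pop, to-pop)
  ev <- list(
    list(t = split_times[["pair1"]], from = 2L, to = 1L),
    list(t = split_times[["pair2"]], from = 4L, to = 3L),
    list(t = split_times[["root"]], from = 3L, to = 1L),
    list(t = split_times[["outgroup"]], from = 5L, to = 1L)
  )
  ev <- ev[order(map_dbl(ev, "t"))]
  mig_until <- min(split_times[["pair1"]], split_times[["pair2"]])

  active <- seq_len(n_tips)
  pop <- lineage_pop
  t <- 0
  next_id <- n_tips + 1L
  ei <- 1L
  while (length(active) > 1L) {
    k <- tabulate(pop, nbins = 5L)
    coal_rate <- k * (k - 1) / 2 / (2 * N)
    mig <- if (mig_rate > 0 && t < mig_until) k[2L] * mig_rate else 0
    total <- sum(coal_rate) + mig
    t_event <- if (ei <= length(ev)) ev[[ei]]$t else Inf
    dt <- if (total > 0) rexp(1L, total) else Inf
    if (t + dt >= t_event) {
      t <- t_event
      pop[pop == ev[[ei]]$from] <- ev[[ei]]$to
      ei <- ei + 1L
      next
    }
    t <- t + dt
    which_ev <- sample.int(6L, 1L, prob = c(coal_rate, mig))
    if (which_ev <= 5L) {
      in_pop <- active[pop == which_ev]
      pair <- if (length(in_pop) == 2L) in_pop else sample(in_pop, 2L)
      parent[pair] <- next_id
      node_time[next_id] <- t
      keep <- !(active %in% pair)
      active <- c(active[keep], next_id)
      pop <- c(pop[keep], which_ev)
      next_id <- next_id + 1L
    } else {
      in_p2 <- which(pop == 2L)
      mover <- if (length(in_p2) == 1L) in_p2 else sample(in_p2, 1L)
      pop[mover] <- 3L
    }
  }
  list(parent = parent, time = node_time, n_tips = n_tips)
}

# tip descendants of every node (children created before parents)
node_descendants <- function(tree) {
  n_nodes <- length(tree$parent)
  desc <- vector("list", n_nodes)
  for (i in seq_len(tree$n_tips)) desc[[i]] <- i
  for (i in seq_len(n_nodes)) {
    p <- tree$parent[i]
    if (p > 0L) desc[[p]] <- c(desc[[p]], desc[[i]])
  }
  desc
}

# drop infinite-sites mutations on a genealogy; returns per-mutation carrier
# tip sets and positions within the locus
drop_mutations <- function(tree, mu_site, locus_length) {
  brlen <- numeric(length(tree$parent))
  nonroot <- tree$parent > 0L
  brlen[nonroot] <- tree$time[tree$parent[nonroot]] - tree$time[nonroot]
  total <- sum(brlen)
  m <- rpois(1L, total * mu_site * locus_length)
  m <- min(m, locus_length)  # infinite-sites cap: one mutation per position
  if (m == 0L) return(list(pos = integer(), carriers = list()))
  pos <- sort(sample.int(locus_length, m))
  branch <- sample.int(length(brlen), m, replace = TRUE, prob = brlen)
  desc <- node_descendants(tree)
  list(pos = pos, carriers = lapply(branch, function(b) desc[[b]]))
}

#' Simulate a ZW-aware multi-population genotype dataset
#'
#' Runs a neutral structured coalescent per independent locus under the
#' demography in `config`, drops infinite-sites mutations, and assembles a
#' [geno_data] object. Autosomal loci coalesce in populations of size `ne`
#' with mutation rate `mu`; Z-linked loci in populations of size
#' `z_a_ratio * ne` with rate `male_bias * mu`, and female samples contribute
#' a single Z lineage (hemizygosity). The callable-site ledger records
#' `locus_length` callable positions per locus, so per-site denominators are
#' known exactly.
#'
#' @param config A [sim_config()].
#' @return A list with elements `data` (a [geno_data]) and `truth` (a tibble
#'   of expected per-class diversity, `4 Ne mu` per chromosome class, and the
#'   expected sign of Patterson's D given the configured migration).
#' @examples
#' sim <- simulate_dataset(sim_config(n_autosomal_loci = 5, n_z_loci = 3,
#'                                    samples_per_pop = 2, seed = 7))
#' sim$data
#' @export
simulate_dataset <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  cfg <- config
  set.seed(cfg$seed)
  samples <- sim_samples(cfg)
  n_smp <- nrow(samples)

  # locus layout
  layout_a <- if (cfg$n_autosomal_loci > 0) {
    chrom <- paste0("chr", rep_len(seq_len(cfg$n_autosomes), cfg$n_autosomal_loci))
    idx_on_chr <- stats::ave(seq_along(chrom), chrom, FUN = seq_along)
    tibble(locus = paste0("A", seq_len(cfg$n_autosomal_loci)), chrom = chrom,
           start = (idx_on_chr - 1L) * cfg$locus_spacing + 1L, class = "A")
  } else tibble(locus = character(), chrom = character(),
                start = integer(), class = character())
  layout_z <- if (cfg$n_z_loci > 0) {
    tibble(locus = paste0("Z", seq_len(cfg$n_z_loci)), chrom = "chrZ",
           start = (seq_len(cfg$n_z_loci) - 1L) * cfg$locus_spacing + 1L,
           class = "Z")
  } else tibble(locus = character(), chrom = character(),
                start = integer(), class = character())
  loci <- bind_rows(layout_a, layout_z) |>
    mutate(end = .data$start + cfg$locus_length - 1L)

  pop_idx <- match(samples$pop, c("P1", "P2", "P3", "P4", "OUT"))
  # lineage-to-sample maps per class
  lin_a_sample <- rep(seq_len(n_smp), each = 2L)
  n_z_lin <- ifelse(samples$sex == "F", 1L, 2L)
  lin_z_sample <- rep(seq_len(n_smp), times = n_z_lin)

  sim_class <- function(class) {
    if (class == "A") {
      lin_sample <- lin_a_sample
      N <- cfg$ne
      mu <- cfg$mu
      mig <- cfg$migration_rate
    } else {
      lin_sample <- lin_z_sample
      N <- cfg$z_a_ratio * cfg$ne
      mu <- cfg$male_bias * cfg$mu
      mig <- cfg$migration_rate * cfg$z_migration_scale
    }
    lin_pop <- pop_idx[lin_sample]
    lay <- loci[loci$class == class, ]
    res <- vector("list", nrow(lay))
    for (i in seq_len(nrow(lay))) {
      tree <- sim_genealogy(lin_pop, N, cfg$split_times, mig)
      mut <- drop_mutations(tree, mu, cfg$locus_length)
      if (length(mut$pos) == 0L) {
        res[[i]] <- NULL
        next
      }
      g <- matrix(0L, nrow = length(mut$pos), ncol = n_smp)
      for (j in seq_along(mut$pos)) {
        carriers <- tabulate(lin_sample[mut$carriers[[j]]], nbins = n_smp)
        g[j, ] <- carriers
      }
      res[[i]] <- list(locus = lay$locus[i], chrom = lay$chrom[i],
                       pos = lay$start[i] + mut$pos - 1L, geno = g)
    }
    res[!map_lgl(res, is.null)]
  }

  parts <- c(sim_class("A"), sim_class("Z"))
  if (length(parts) > 0) {
    sites <- purrr::map(parts, function(p) {
      tibble(chrom = p$chrom, pos = p$pos, locus = p$locus)
    }) |> list_rbind()
    geno <- do.call(rbind, purrr::map(parts, "geno"))
  } else {
    sites <- tibble(chrom = character(), pos = integer(), locus = character())
    geno <- matrix(integer(), 0, n_smp)
  }
  sites <- left_join(sites, loci[, c("locus", "class")], by = "locus")

  n_sites <- nrow(sites)
  # allele labels: ancestral base uniform, derived uniform among the rest
  bases <- c("A", "C", "G", "T")
  anc <- sample(bases, n_sites, replace = TRUE)
  der <- vapply(anc, function(a) sample(setdiff(bases, a), 1L), character(1))
  sites$ref <- anc
  sites$alt <- unname(der)
  sites$anc <- anc
  colnames(geno) <- samples$sample

  data <- geno_data(
    sites = sites, geno = geno, samples = samples, loci = loci,
    ledger = tibble(class = c("A", "Z"),
                    L = c(cfg$n_autosomal_loci, cfg$n_z_loci) *
                      as.numeric(cfg$locus_length))
  )

  # reference allele may carry the derived state: swap REF/ALT and recode
  if (cfg$ref_flip_prob > 0 && n_sites > 0) {
    flip <- runif(n_sites) < cfg$ref_flip_prob
    if (any(flip)) {
      pl <- ploidy_matrix(data)
      g <- data$geno
      g[flip, ] <- pl[flip, , drop = FALSE] - g[flip, , drop = FALSE]
      data$geno <- g
      r <- data$sites$ref[flip]
      data$sites$ref[flip] <- data$sites$alt[flip]
      data$sites$alt[flip] <- r
    }
  }

  if (cfg$miss_rate > 0 && n_sites > 0) {
    miss <- matrix(runif(n_sites * n_smp) < cfg$miss_rate, n_sites, n_smp)
    data$geno[miss] <- NA_integer_
  }

  if (cfg$attach_qc) {
    dp <- matrix(rpois(n_sites * n_smp, 30), n_sites, n_smp,
                 dimnames = dimnames(data$geno))
    gq <- matrix(sample(60:99, n_sites * n_smp, replace = TRUE), n_sites,
                 n_smp, dimnames = dimnames(data$geno))
    data$qc <- list(dp = dp, gq = gq)
  }

  truth <- tibble(
    class = c("A", "Z"),
    expected_pi = c(4 * cfg$ne * cfg$mu,
                    4 * cfg$z_a_ratio * cfg$ne * cfg$male_bias * cfg$mu),
    expected_d_sign = ifelse(cfg$migration_rate > 0, 1, 0)
  )
  list(data = data, truth = truth, config = cfg)
}
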