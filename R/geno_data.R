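#' Genotype dataset container
#'
#' `geno_data()` bundles the pieces the pipeline operates on: a table of
#' variant sites, a sites-by-samples matrix of ALT allele counts, per-sample
#' metadata (population and sex), the locus layout, and the callable-site
#' ledger that supplies the denominators (L) for per-site statistics.
#' Monomorphic callable positions are not stored row-by-row; they are carried
#' by the ledger and the locus layout, from which an all-sites VCF can be
#' reconstructed by [write_vcf()].
#'
#' Genotypes are coded as the number of ALT alleles: 0/1/2 for diploid calls,
#' 0/1 for hemizygous calls (females on the Z carry a single allele), and
#' `NA` for missing. Chromosome class is `"A"` (autosome) or `"Z"`.
#'
#' @param sites Tibble with columns `chrom`, `pos` (1-based), `locus`,
#'   `class` (`"A"`/`"Z"`), `ref`, `alt`, and optionally `anc` (the true or
#'   inferred ancestral allele).
#' @param geno Integer matrix, `nrow(sites)` x `nrow(samples)`, ALT allele
#'   counts with `NA` for missing calls. Column names must match
#'   `samples$sample`.
#' @param samples Tibble with columns `sample`, `pop`, `sex` (`"M"`/`"F"`).
#' @param loci Tibble with columns `locus`, `chrom`, `start`, `end`
#'   (1-based, inclusive), `class` describing the callable locus layout.
#' @param ledger Tibble with columns `class`, `L`: callable sites (variant +
#'   monomorphic) per chromosome class.
#' @param qc Optional list with matrices `dp` and `gq` of per-genotype depth
#'   and genotype quality, same dimensions as `geno`.
#'
#' @return An object of class `geno_data`.
#' @export
geno_data <- function(sites, geno, samples, loci, ledger, qc = NULL) {
  sites <- as_tibble(sites)
  samples <- as_tibble(samples)
  loci <- as_tibble(loci)
  ledger <- as_tibble(ledger)
  stopifnot(
    all(c("chrom", "pos", "locus", "class", "ref", "alt") %in% names(sites)),
    all(c("sample", "pop", "sex") %in% names(samples)),
    all(c("locus", "chrom", "start", "end", "class") %in% names(loci)),
    all(c("class", "L") %in% names(ledger)),
    is.matrix(geno), nrow(geno) == nrow(sites), ncol(geno) == nrow(samples)
  )
  if (!"anc" %in% names(sites)) sites$anc <- NA_character_
  if (is.null(colnames(geno))) colnames(geno) <- samples$sample
  if (!identical(colnames(geno), samples$sample)) {
    abort("column names of `geno` must match `samples$sample`")
  }
  if (!all(samples$sex %in% c("M", "F"))) {
    abort("`samples$sex` must be \"M\" or \"F\"")
  }
  if (!all(sites$class %in% c("A", "Z"))) abort("site class must be \"A\" or \"Z\"")
  if (!is.null(qc)) {
    stopifnot(is.list(qc), all(c("dp", "gq") %in% names(qc)))
    stopifnot(identical(dim(qc$dp), dim(geno)), identical(dim(qc$gq), dim(geno)))
  }
  structure(
    list(sites = sites, geno = geno, samples = samples, loci = loci,
         ledger = ledger, qc = qc),
    class = "geno_data"
  )
}

#' @export
print.geno_data <- function(x, ...) {
  cat("<geno_data> ", nrow(x$sites), " variant sites x ", nrow(x$samples),
      " samples\n", sep = "")
  lg <- paste0(x$ledger$class, "=", x$ledger$L, collapse = ", ")
  cat("  callable sites: ", lg, "\n", sep = "")
  pops <- dplyr::count(x$samples, .data$pop, .data$sex)
  cat("  samples: ",
      paste0(pops$pop, "/", pops$sex, ":", pops$n, collapse = " "), "\n",
      sep = "")
  invisible(x)
}

#' Per-genotype ploidy matrix
#'
#' Ploidy is 2 everywhere except for female samples at Z-linked sites, where
#' it is 1 (hemizygosity).
#'
#' @param x A [geno_data] object.
#' @return Integer matrix with the dimensions of `x$geno`.
#' @export
ploidy_matrix <- function(x) {
  p <- matrix(2L, nrow = nrow(x$sites), ncol = nrow(x$samples),
              dimnames = dimnames(x$geno))
  if (nrow(x$sites) > 0) {
    z <- x$sites$class == "Z"
    fem <- x$samples$sex == "F"
    if (any(z) && any(fem)) p[z, fem] <- 1L
  }
  p
}

#' ALT allele counts and totals for a set of samples
#'
#' @param x A [geno_data] object.
#' @param samples Character vector of sample names (defaults to all).
#' @return Tibble with one row per site: `alt` (ALT allele count) and `tot`
#'   (non-missing allele total).
#' @export
allele_counts <- function(x, samples = NULL) {
  samples <- samples %||% x$samples$sample
  idx <- match(samples, x$samples$sample)
  if (anyNA(idx)) abort("unknown sample name(s)")
  g <- x$geno[, idx, drop = FALSE]
  pl <- ploidy_matrix(x)[, idx, drop = FALSE]
  pl[is.na(g)] <- 0L
  g0 <- g
  g0[is.na(g0)] <- 0L
  tibble(alt = as.numeric(rowSums(g0)), tot = as.numeric(rowSums(pl)))
}

#' Per-population ALT allele frequencies
#'
#' @param x A [geno_data] object.
#' @param pops Character vector of population labels (defaults to all).
#' @return Tibble: `chrom`, `pos`, `class`, then `freq_<pop>` and `n_<pop>`
#'   (non-missing allele totals) per population. Frequencies are `NaN` where
#'   no alleles were observed.
#' @export
pop_freqs <- function(x, pops = NULL) {
  pops <- pops %||% unique(x$samples$pop)
  out <- x$sites[, c("chrom", "pos", "class")]
  for (p in pops) {
    sm <- x$samples$sample[x$samples$pop == p]
    if (length(sm) == 0) abort(paste0("population not found: ", p))
    ac <- allele_counts(x, sm)
    out[[paste0("freq_", p)]] <- ac$alt / ac$tot
    out[[paste0("n_", p)]] <- ac$tot
  }
  out
}

#' Derived-allele frequencies given ancestral calls
#'
#' Converts ALT frequencies into derived-allele frequencies using per-site
#' ancestral alleles: where the ancestral allele equals REF the derived
#' frequency is the ALT frequency; where it equals ALT it is 1 minus the ALT
#' frequency; sites with no (or third-allele) ancestral call get `NA`.
#'
#' @param x A [geno_data] object.
#' @param pops Character vector of population labels.
#' @param ancestral Character vector of ancestral alleles per site; defaults
#'   to `x$sites$anc`.
#' @return Tibble `chrom`, `pos`, `class`, plus `p_<pop>` derived frequencies.
#' @export
derived_freqs <- function(x, pops, ancestral = NULL) {
  anc <- ancestral %||% x$sites$anc
  if (length(anc) != nrow(x$sites)) abort("`ancestral` must have one entry per site")
  fr <- pop_freqs(x, pops)
  flip <- ifelse(anc == x$sites$ref, FALSE,
                 ifelse(anc == x$sites$alt, TRUE, NA))
  out <- x$sites[, c("chrom", "pos", "class")]
  for (p in pops) {
    f <- fr[[paste0("freq_", p)]]
    out[[paste0("p_", p)]] <- ifelse(is.na(flip), NA_real_,
                                     ifelse(flip, 1 - f, f))
  }
  out
}

# internal: subset a geno_data to a logical/integer site index
subset_sites <- function(x, keep) {
  qc <- x$qc
  if (!is.null(qc)) {
    qc <- list(dp = qc$dp[keep, , drop = FALSE], gq = qc$gq[keep, , drop = FALSE])
  }
  geno_data(x$sites[keep, , drop = FALSE], x$geno[keep, , drop = FALSE],
            x$samples, x$loci, x$ledger, qc)
}
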