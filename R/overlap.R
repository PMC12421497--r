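#' Classify sites as fixed differences or shared polymorphisms
#'
#' For a pair of species/populations: a fixed difference is a site at which
#' each species is fixed (no alternative allele among its non-missing
#' calls) for different alleles; a shared polymorphism segregates within
#' both; `private` segregates in exactly one; everything else (including
#' sites fixed for the same allele) is `other`. Sites untyped in either
#' species are excluded with a reason.
#'
#' @param x A [geno_data] object.
#' @param pop1,pop2 The two species/population labels.
#' @return Tibble: `chrom`, `pos`, `class`, `status` (`fixed_difference`,
#'   `shared_polymorphism`, `private`, `other`, `untyped`).
#' @export
classify_sites <- function(x, pop1, pop2) {
  st <- function(p) {
    ac <- allele_counts(x, x$samples$sample[x$samples$pop == p])
    ifelse(ac$tot == 0, NA_integer_,
           ifelse(ac$alt == 0, 0L, ifelse(ac$alt == ac$tot, 2L, 1L)))
  }
  s1 <- st(pop1)
  s2 <- st(pop2)
  status <- dplyr::case_when(
    is.na(s1) | is.na(s2) ~ "untyped",
    s1 == 1L & s2 == 1L ~ "shared_polymorphism",
    s1 != 1L & s2 != 1L & s1 != s2 ~ "fixed_difference",
    xor(s1 == 1L, s2 == 1L) ~ "private",
    TRUE ~ "other"
  )
  tibble(chrom = x$sites$chrom, pos = x$sites$pos, class = x$sites$class,
         status = status)
}

#' Assign one functional category per site
#'
#' Resolves overlapping annotations with a fixed precedence: zero-fold >
#' four-fold > UTR > CNE > intron > intergenic (coding degeneracy beats
#' regulatory annotation; anything unannotated is intergenic).
#'
#' @param sites Tibble with `chrom`, `pos`.
#' @param annotations Named list of interval tibbles (`chrom`, `start`,
#'   `end`, 1-based inclusive); recognized names: `zero_fold`, `four_fold`,
#'   `utr`, `cne`, `intron`. Positions matching nothing are `intergenic`.
#'   `zero_fold`/`four_fold` may also be site tables with `pos` only
#'   (width-1 intervals are then implied).
#' @return `sites` with a `category` column.
#' @export
assign_functional_category <- function(sites, annotations) {
  precedence <- c("zero_fold", "four_fold", "utr", "cne", "intron")
  sites <- as_tibble(sites)
  sites$category <- "intergenic"
  for (cat in rev(precedence)) {
    iv <- annotations[[cat]]
    if (is.null(iv) || nrow(iv) == 0) next
    iv <- as_tibble(iv)
    if (!"start" %in% names(iv)) iv <- mutate(iv, start = .data$pos, end = .data$pos)
    hit <- in_mask(sites$chrom, sites$pos, iv)
    sites$category[hit] <- cat
  }
  sites
}

#' Densities of fixed differences per functional category
#'
#' Fixed differences per callable site, per functional category and
#' chromosome class, plus the proportion of all fixed differences falling
#' in each category (the pie-chart analog). Categories with zero callable
#' sites get `NA` density.
#'
#' @param classified Output of [classify_sites()] with a `category` column
#'   (see [assign_functional_category()]).
#' @param callable Tibble `class`, `category`, `L`: callable sites per
#'   category and chromosome class.
#' @return Tibble: `class`, `category`, `n_fixed`, `L`, `density`,
#'   `proportion`.
#' @export
functional_density <- function(classified, callable) {
  fd <- classified |>
    dplyr::filter(.data$status == "fixed_difference") |>
    dplyr::count(.data$class, .data$category, name = "n_fixed")
  out <- as_tibble(callable) |>
    left_join(fd, by = c("class", "category")) |>
    mutate(n_fixed = dplyr::coalesce(.data$n_fixed, 0L),
           density = if_else(.data$L > 0, .data$n_fixed / .data$L, NA_real_)) |>
    group_by(.data$class) |>
    mutate(proportion = if (sum(.data$n_fixed) > 0)
      .data$n_fixed / sum(.data$n_fixed) else NA_real_) |>
    ungroup()
  out
}

#' Overlap of sweep regions with nonsynonymous fixed differences
#'
#' For each chromosome class: the fraction of sweep regions containing at
#' least one nonsynonymous (zero-fold) fixed difference, with per-sweep
#' counts.
#'
#' @param nonsyn_fixed Tibble of nonsynonymous fixed-difference sites
#'   (`chrom`, `pos`, `class`).
#' @param sweeps Sweep-region tibble (`chrom`, `start`, `end`), e.g. from
#'   [postprocess_sweeps()], with a `class` column (added from the
#'   chromosome naming if absent: `chrZ` is Z).
#' @return List with `per_sweep` (regions + `n_nonsyn`) and `summary`
#'   (per class: `n_sweeps`, `n_overlapping`, `fraction`).
#' @export
sweep_overlap <- function(nonsyn_fixed, sweeps) {
  sweeps <- as_tibble(sweeps)
  if (nrow(sweeps) == 0) {
    return(list(per_sweep = sweeps,
                summary = tibble(class = character(), n_sweeps = integer(),
                                 n_overlapping = integer(),
                                 fraction = numeric())))
  }
  if (!"class" %in% names(sweeps)) {
    sweeps$class <- ifelse(sweeps$chrom == "chrZ", "Z", "A")
  }
  sweeps$n_nonsyn <- purrr::pmap_int(
    sweeps[, c("chrom", "start", "end")],
    function(chrom, start, end) {
      sum(nonsyn_fixed$chrom == chrom & nonsyn_fixed$pos >= start &
            nonsyn_fixed$pos <= end)
    })
  summary <- sweeps |>
    group_by(.data$class) |>
    summarise(n_sweeps = dplyr::n(),
              n_overlapping = sum(.data$n_nonsyn > 0),
              fraction = mean(.data$n_nonsyn > 0), .groups = "drop")
  list(per_sweep = sweeps, summary = summary)
}

#' Fisher exact Z-versus-autosome enrichment
#'
#' For a 2x2 table of 200-kb window counts (rows: autosome, Z; columns:
#' flagged, unflagged), returns the sample cross-product odds ratio
#' `(a d) / (b c)` — the quantity conventionally reported alongside such
#' tables — and the two-sided Fisher exact p-value (sum of hypergeometric
#' probabilities of tables at most as probable as the observed one). A zero
#' off-diagonal cell gives an infinite odds ratio, reported with the
#' one-sided p-value.
#'
#' @param auto_flagged,auto_unflagged,z_flagged,z_unflagged Cell counts; or
#'   pass a 2x2 matrix as the single first argument.
#' @return One-row tibble: `odds_ratio`, `p_value`, plus the four counts.
#' @export
fisher_enrichment <- function(auto_flagged, auto_unflagged = NULL,
                              z_flagged = NULL, z_unflagged = NULL) {
  if (is.matrix(auto_flagged)) {
    m <- auto_flagged
  } else {
    m <- matrix(c(auto_flagged, z_flagged, auto_unflagged, z_unflagged), 2)
  }
  if (any(m < 0)) abort("counts must be non-negative")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("margins must be positive")
  }
  or <- (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
  if (is.finite(or)) {
    p <- fisher.test(m)$p.value
  } else {
    p <- fisher.test(m, alternative = "greater")$p.value
  }
  tibble(odds_ratio = or, p_value = p,
         auto_flagged = m[1, 1], auto_unflagged = m[1, 2],
         z_flagged = m[2, 1], z_unflagged = m[2, 2])
}
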