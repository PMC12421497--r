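#' Filter configuration
#'
#' Thresholds for the genotype- and site-level filters. Depth and GQ bounds
#' are exclusive as is conventional for these filters: a genotype is removed
#' when depth is strictly below `min_depth` or strictly above `max_depth`,
#' and kept only when GQ is strictly above the sex/chromosome-appropriate
#' threshold (GQ exactly at the threshold is removed). On the Z chromosome,
#' female (hemizygous) calls use a relaxed GQ threshold.
#'
#' @param min_depth,max_depth Depth bounds (defaults 5 and 200).
#' @param gq_autosome GQ threshold for autosomal genotypes (default 30).
#' @param gq_z_male,gq_z_female GQ thresholds on the Z for males (30) and
#'   females (15).
#' @param max_missing Maximum tolerated missing-data fraction per species at
#'   a site (default 0.10); sites exceeding it in any species are removed.
#' @param repeat_mask Optional tibble of repeat intervals (`chrom`, `start`,
#'   `end`, 1-based inclusive); overlapping sites are removed.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_depth = 5, max_depth = 200, gq_autosome = 30,
                          gq_z_male = 30, gq_z_female = 15,
                          max_missing = 0.10, repeat_mask = NULL) {
  if (min_depth >= max_depth) abort("min_depth must be < max_depth")
  if (max_missing < 0 || max_missing > 1) abort("max_missing must be in [0,1]")
  structure(list(min_depth = min_depth, max_depth = max_depth,
                 gq_autosome = gq_autosome, gq_z_male = gq_z_male,
                 gq_z_female = gq_z_female, max_missing = max_missing,
                 repeat_mask = repeat_mask),
            class = "filter_config")
}

#' Apply genotype-level depth and GQ filters
#'
#' Sets to missing every genotype whose depth lies outside
#' `(min_depth, max_depth)` exclusive-of-bounds as configured, or whose GQ is
#' not strictly above the applicable threshold: `gq_autosome` for autosomal
#' calls, `gq_z_male` / `gq_z_female` for Z-linked calls by sample sex.
#' All other genotypes are untouched.
#'
#' @param x A [geno_data] with attached `qc` matrices (`dp`, `gq`).
#' @param cfg A [filter_config()].
#' @return The filtered [geno_data].
#' @export
filter_genotypes <- function(x, cfg = filter_config()) {
  if (is.null(x$qc)) abort("no per-genotype depth/GQ attached (x$qc is NULL)")
  if (any(x$sites$class == "Z") && anyNA(x$samples$sex)) {
    abort("samples must carry a sex label when Z sites are present")
  }
  dp <- x$qc$dp
  gq <- x$qc$gq
  z <- x$sites$class == "Z"
  fem <- x$samples$sex == "F"
  gq_thr <- matrix(cfg$gq_autosome, nrow(x$sites), nrow(x$samples))
  if (any(z)) {
    gq_thr[z, ] <- rep(ifelse(fem, cfg$gq_z_female, cfg$gq_z_male),
                       each = sum(z))
  }
  bad <- dp < cfg$min_depth | dp > cfg$max_depth | !(gq > gq_thr)
  x$geno[bad] <- NA_integer_
  x
}

#' Apply site-level filters and update the callable-site ledger
#'
#' Removes, in order: (a) Z-linked sites at which any female genotype is
#' still heterozygous after genotype filtering (hemizygous females cannot be
#' heterozygous, so the whole site is treated as unreliable), (b) sites with
#' more than `max_missing` missing genotype calls in any species
#' (hemizygous female Z calls count as one observation), and (c) sites
#' overlapping the repeat mask. The ledger is decremented by the number of
#' sites each class loses, and a per-rule report is attached.
#'
#' @param x A [geno_data], typically after [filter_genotypes()].
#' @param cfg A [filter_config()].
#' @return A list with `data` (filtered [geno_data] with updated ledger) and
#'   `report` (tibble: rule, sites removed).
#' @export
filter_sites <- function(x, cfg = filter_config()) {
  n0 <- nrow(x$sites)
  removed <- logical(n0)
  reason <- character(0)

  # (a) heterozygous females on Z
  fem <- x$samples$sex == "F"
  het_fem <- rep(FALSE, n0)
  if (any(fem) && n0 > 0) {
    g <- x$geno[, fem, drop = FALSE]
    het_fem <- x$sites$class == "Z" &
      rowSums(g == 1L, na.rm = TRUE) > 0
  }
  n_het <- sum(het_fem & !removed)
  removed <- removed | het_fem
  reason <- c(reason, het_female_z = n_het)

  # (b) per-species missingness
  miss_fail <- rep(FALSE, n0)
  for (p in unique(x$samples$pop)) {
    cols <- x$samples$pop == p
    frac <- rowMeans(is.na(x$geno[, cols, drop = FALSE]))
    miss_fail <- miss_fail | frac > cfg$max_missing
  }
  n_miss <- sum(miss_fail & !removed)
  removed <- removed | miss_fail
  reason <- c(reason, missingness = n_miss)

  # (c) repeat overlap
  rep_fail <- rep(FALSE, n0)
  if (!is.null(cfg$repeat_mask) && nrow(cfg$repeat_mask) > 0 && n0 > 0) {
    rm_tbl <- as_tibble(cfg$repeat_mask)
    unknown <- setdiff(unique(rm_tbl$chrom), unique(x$loci$chrom))
    if (length(unknown) > 0) {
      warn(paste0("repeat intervals on unknown contig(s) ignored: ",
                  paste(unknown, collapse = ", ")))
      rm_tbl <- rm_tbl[!rm_tbl$chrom %in% unknown, ]
    }
    for (ch in unique(rm_tbl$chrom)) {
      iv <- rm_tbl[rm_tbl$chrom == ch, ]
      ir <- IRanges::IRanges(start = iv$start, end = iv$end)
      on_ch <- which(x$sites$chrom == ch)
      if (length(on_ch) > 0) {
        hits <- IRanges::overlapsAny(
          IRanges::IRanges(start = x$sites$pos[on_ch], width = 1), ir)
        rep_fail[on_ch[hits]] <- TRUE
      }
    }
  }
  n_rep <- sum(rep_fail & !removed)
  removed <- removed | rep_fail
  reason <- c(reason, repeat_overlap = n_rep)

  out <- subset_sites(x, !removed)
  # repeat-masked and failed positions are no longer callable; the ledger is
  # reduced by removed variant sites (monomorphic repeat content is handled
  # when the mask is applied to the locus layout at import)
  lost <- tibble(class = x$sites$class[removed]) |> dplyr::count(.data$class)
  out$ledger <- out$ledger |>
    left_join(lost, by = "class") |>
    mutate(L = .data$L - dplyr::coalesce(.data$n, 0L)) |>
    select("class", "L")
  report <- tibble(rule = names(reason), sites_removed = as.integer(reason))
  list(data = out, report = report)
}
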