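#' Derived-allele frequency quartets for ABBA-BABA tests
#'
#' Builds the per-site table of derived-allele frequencies (p1, p2, p3) in
#' the three ingroup populations of a four-taxon comparison
#' ((P1, P2), P3, outgroup). The derived state is defined by the ancestral
#' calls in `x$sites$anc` (e.g. from [polarize()] with the outgroup);
#' unpolarized sites and sites with a missing frequency in any population
#' are excluded listwise.
#'
#' @param x A [geno_data] with ancestral calls.
#' @param p1,p2,p3 Population labels.
#' @return Tibble: `chrom`, `pos`, `class`, `p1`, `p2`, `p3`.
#' @export
site_freq_quartet <- function(x, p1, p2, p3) {
  fr <- derived_freqs(x, c(p1, p2, p3))
  out <- tibble(chrom = fr$chrom, pos = fr$pos, class = fr$class,
                p1 = fr[[paste0("p_", p1)]], p2 = fr[[paste0("p_", p2)]],
                p3 = fr[[paste0("p_", p3)]])
  out[complete.cases(out[, c("p1", "p2", "p3")]), ]
}

#' Patterson's D from derived-allele frequencies
#'
#' `D = (sum (1-p1) p2 p3 - sum p1 (1-p2) p3) /
#'      (sum (1-p1) p2 p3 + sum p1 (1-p2) p3)`,
#' the frequency-based ABBA-BABA asymmetry; sums are taken across sites
#' before the ratio. Positive D indicates an excess of shared derived
#' alleles between P2 and P3.
#'
#' @param quartets Tibble with `p1`, `p2`, `p3` (see [site_freq_quartet()]).
#' @return Numeric D.
#' @export
patterson_d <- function(quartets) {
  abba <- sum((1 - quartets$p1) * quartets$p2 * quartets$p3)
  baba <- sum(quartets$p1 * (1 - quartets$p2) * quartets$p3)
  if (abba + baba == 0) abort("undefined D: zero denominator")
  (abba - baba) / (abba + baba)
}

#' Block-jackknife inference for Patterson's D
#'
#' Delete-one jackknife over physical blocks (default 200 kb tiles): for n
#' non-empty blocks, `SE = sqrt(((n - 1) / n) * sum((theta_i - mean)^2))`
#' over the delete-one estimates, `z = D / SE`, and a two-sided normal
#' p-value. Blocks with no informative site are dropped from n.
#'
#' @param quartets Tibble from [site_freq_quartet()] with `chrom`, `pos`.
#' @param block Block span in bp (default 200,000).
#' @param class_label Annotation stored in the result (e.g. `"A"`, `"Z"`).
#' @return Object of class `d_stat`: list with `d`, `se`, `z`, `p`,
#'   `n_blocks`, `block`, `class`.
#' @export
block_jackknife_d <- function(quartets, block = 200000, class_label = NA) {
  blk <- paste0(quartets$chrom, ":", floor((quartets$pos - 1) / block))
  ids <- unique(blk)
  if (length(ids) < 2) abort("jackknife undefined: fewer than 2 blocks")
  d_hat <- patterson_d(quartets)
  theta <- vapply(ids, function(b) patterson_d(quartets[blk != b, ]),
                  numeric(1))
  n <- length(ids)
  se <- sqrt((n - 1) / n * sum((theta - mean(theta))^2))
  z <- if (se > 0) d_hat / se else NA_real_
  p <- if (is.na(z)) NA_real_ else 2 * pnorm(-abs(z))
  structure(list(d = d_hat, se = se, z = z, p = p, n_blocks = n,
                 block = block, class = class_label),
            class = "d_stat")
}

#' @export
print.d_stat <- function(x, ...) {
  cat(sprintf("Patterson's D = %.4g (+/- %.3g), z = %.3g, p = %.3g [%d blocks of %g kb]\n",
              x$d, x$se, x$z, x$p, x$n_blocks, x$block / 1000))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname block_jackknife_d
#' @param x A `d_stat` object.
#' @param ... Unused.
#' @export
tidy.d_stat <- function(x, ...) {
  tibble(term = "D", estimate = x$d, std.error = x$se, statistic = x$z,
         p.value = x$p, class = x$class)
}

#' @rdname block_jackknife_d
#' @export
glance.d_stat <- function(x, ...) {
  tibble(n_blocks = x$n_blocks, block_bp = x$block, class = x$class)
}

#' Windowed f_d introgression estimator
#'
#' The f_d statistic normalizes the ABBA-BABA numerator by its value when
#' the donor frequency is maximal: per window, `f_d = S(p1, p2, p3) /
#' S(p1, pD, pD)` where `S` is the D numerator and `pD` is, per site, the
#' larger of p2 and p3. Windows with a negative numerator are reported as
#' missing (f_d is not biologically meaningful when negative); windows with
#' fewer than `min_sites` informative sites are also missing.
#'
#' @param quartets Tibble from [site_freq_quartet()].
#' @param window Window width in bp (default 200,000).
#' @param min_sites Minimum informative sites per window (default 10).
#' @return A `win_stat_tbl`: `chrom`, `class`, `start`, `end`, `n_sites`,
#'   `fd`.
#' @export
fd_windows <- function(quartets, window = 200000, min_sites = 10) {
  q <- quartets |>
    mutate(start = floor((.data$pos - 1) / window) * window + 1,
           num = (1 - .data$p1) * .data$p2 * .data$p3 -
             .data$p1 * (1 - .data$p2) * .data$p3,
           pd = pmax(.data$p2, .data$p3),
           den = (1 - .data$p1) * .data$pd * .data$pd -
             .data$p1 * (1 - .data$pd) * .data$pd)
  out <- q |>
    group_by(.data$chrom, .data$class, .data$start) |>
    summarise(n_sites = dplyr::n(), num = sum(.data$num),
              den = sum(.data$den), .groups = "drop") |>
    mutate(end = .data$start + window - 1,
           fd = dplyr::case_when(
             n_sites < min_sites ~ NA_real_,
             den == 0 ~ NA_real_,
             num < 0 ~ NA_real_,
             TRUE ~ num / den)) |>
    select("chrom", "class", "start", "end", "n_sites", "fd")
  new_win_stat(out, "fd")
}

#' Flag windows with significantly reduced f_d
#'
#' Smooths window f_d per chromosome (Savitzky-Golay), z-transforms the
#' smoothed values using the genome-wide mean and standard deviation, and
#' flags windows with z at or below `z_threshold` (default -2) as reduced
#' gene-flow outliers.
#'
#' @param tbl Output of [fd_windows()].
#' @param z_threshold Outlier threshold (default -2).
#' @inheritParams call_window_outliers
#' @return The table with `processed` (smoothed, z-transformed f_d) and
#'   `flag` columns.
#' @export
call_fd_outliers <- function(tbl, z_threshold = -2, sg_window = 5,
                             sg_order = 3) {
  call_window_outliers(tbl, attr(tbl, "stat") %||% "fd", z_threshold,
                       sg_window, sg_order,
                       order = "smooth_then_z", moments = "genome",
                       side = "below")
}

#' Regression of window f_d on recombination rate
#'
#' Ordinary least squares of f_d against the local recombination rate,
#' pairing windows on `chrom` and `start`. A positive slope indicates lower
#' introgression in low-recombination regions, as expected when selection
#' against introgressed ancestry extends further at low recombination.
#'
#' @param fd_tbl Output of [fd_windows()].
#' @param recomb Tibble with `chrom`, `start`, `rate` (e.g. cM/Mb per
#'   window).
#' @return One-row tibble: `r_squared`, `slope`, `p_value`, `n`.
#' @export
fd_recombination_regression <- function(fd_tbl, recomb) {
  d <- fd_tbl |>
    inner_join(as_tibble(recomb), by = c("chrom", "start")) |>
    dplyr::filter(!is.na(.data$fd), !is.na(.data$rate))
  if (nrow(d) < 3) abort("need at least 3 paired windows")
  if (sd(d$rate) == 0) abort("undefined fit: zero variance in predictor")
  fit <- lm(fd ~ rate, data = d)
  sm <- summary(fit)
  tibble(r_squared = sm$r.squared, slope = coef(fit)[["rate"]],
         p_value = sm$coefficients["rate", "Pr(>|t|)"], n = nrow(d))
}
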