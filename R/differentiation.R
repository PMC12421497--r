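# per-site Weir & Cockerham (1984) variance components for two populations;
# n_i in individuals (non-missing alleles / 2), h_i the heterozygote
# frequency among diploid calls
wc84_components <- function(p1, n1, h1, p2, n2, h2) {
  r <- 2
  n_bar <- (n1 + n2) / r
  n_c <- (r * n_bar - (n1^2 + n2^2) / (r * n_bar)) / (r - 1)
  p_bar <- (n1 * p1 + n2 * p2) / (r * n_bar)
  s2 <- (n1 * (p1 - p_bar)^2 + n2 * (p2 - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- (n1 * h1 + n2 * h2) / (r * n_bar)
  a <- n_bar / n_c *
    (s2 - (p_bar * (1 - p_bar) - s2 * (r - 1) / r - h_bar / 4) / (n_bar - 1))
  b <- n_bar / (n_bar - 1) *
    (p_bar * (1 - p_bar) - s2 * (r - 1) / r -
       h_bar * (2 * n_bar - 1) / (4 * n_bar))
  c <- h_bar / 2
  tibble(a = a, b = b, c = c)
}

# tile fixed-width windows over the locus layout; 0-based tiling, reported
# 1-based inclusive
tile_windows <- function(loci, window) {
  ends <- loci |>
    group_by(.data$chrom, .data$class) |>
    summarise(chrom_end = max(.data$end), .groups = "drop")
  purrr::pmap(ends, function(chrom, class, chrom_end) {
    start <- seq(1, chrom_end, by = window)
    tibble(chrom = chrom, class = class, start = start,
           end = pmin(start + window - 1, chrom_end))
  }) |>
    list_rbind() |>
    mutate(partial = .data$end - .data$start + 1 < window)
}

#' Windowed Weir-Cockerham F_ST between two populations
#'
#' Computes per-site Weir & Cockerham (1984) variance components a, b, c and
#' the weighted window estimator `sum(a) / sum(a + b + c)` over fixed-width
#' windows tiled from position 0 on every chromosome of the locus layout.
#' Sites monomorphic across the two populations contribute zero to both
#' sums; sites untyped in either population are skipped. Negative window
#' estimates are reported as computed (no clamping). Windows with no usable
#' site have `fst = NA`.
#'
#' @param x A [geno_data] object.
#' @param pop1,pop2 Population labels.
#' @param window Window width in bp (default 200,000).
#' @return A `win_stat_tbl` tibble: `chrom`, `class`, `start`, `end`,
#'   `partial`, `n_sites`, `fst`.
#' @export
window_fst <- function(x, pop1, pop2, window = 200000) {
  for (p in c(pop1, pop2)) {
    if (sum(x$samples$pop == p) == 0) abort(paste0("empty population: ", p))
  }
  comp <- fst_site_components(x, pop1, pop2)
  win <- tile_windows(x$loci, window)
  comp$start <- (floor((comp$pos - 1) / window)) * window + 1
  agg <- comp |>
    group_by(.data$chrom, .data$start) |>
    summarise(n_sites = sum(.data$usable),
              sum_a = sum(.data$a[.data$usable]),
              sum_abc = sum((.data$a + .data$b + .data$c)[.data$usable]),
              .groups = "drop")
  out <- win |>
    left_join(agg, by = c("chrom", "start")) |>
    mutate(n_sites = dplyr::coalesce(.data$n_sites, 0L),
           fst = if_else(.data$n_sites > 0 & .data$sum_abc != 0,
                         .data$sum_a / .data$sum_abc, NA_real_)) |>
    select("chrom", "class", "start", "end", "partial", "n_sites", "fst")
  new_win_stat(out, "fst")
}

# per-site WC84 component table for two populations
fst_site_components <- function(x, pop1, pop2) {
  stat_pop <- function(p) {
    sm <- x$samples$sample[x$samples$pop == p]
    idx <- match(sm, x$samples$sample)
    g <- x$geno[, idx, drop = FALSE]
    pl <- ploidy_matrix(x)[, idx, drop = FALSE]
    pl[is.na(g)] <- 0L
    tot <- rowSums(pl)
    g0 <- g
    g0[is.na(g0)] <- 0L
    alt <- rowSums(g0)
    het <- rowSums(g == 1L & pl == 2L, na.rm = TRUE)
    n_ind <- tot / 2
    list(p = alt / tot, n = n_ind, h = ifelse(n_ind > 0, het / n_ind, 0))
  }
  s1 <- stat_pop(pop1)
  s2 <- stat_pop(pop2)
  comp <- wc84_components(s1$p, s1$n, s1$h, s2$p, s2$n, s2$h)
  comp$chrom <- x$sites$chrom
  comp$pos <- x$sites$pos
  comp$class <- x$sites$class
  comp$usable <- s1$n > 0 & s2$n > 0 & (s1$n + s2$n) > 1 &
    is.finite(comp$a)
  comp
}

new_win_stat <- function(tbl, stat) {
  attr(tbl, "stat") <- stat
  class(tbl) <- c("win_stat_tbl", class(tbl))
  tbl
}

#' Smooth, z-transform and flag windowed statistics
#'
#' The generic peak/outlier engine: z-transformation and Savitzky-Golay
#' smoothing applied per chromosome, in either order, with moments taken per
#' chromosome or genome-wide, then thresholding of the processed value.
#' Chromosomes with fewer non-missing windows than the filter length are
#' skipped with a warning. Used by [call_fst_peaks()] (z-transform per
#' chromosome, then smooth, flag `> threshold`) and [call_fd_outliers()]
#' (smooth per chromosome, then z-transform with genome-wide moments, flag
#' `<= threshold`).
#'
#' @param tbl A `win_stat_tbl` (or tibble with `chrom` and the value column).
#' @param value_col Name of the statistic column.
#' @param z_threshold Threshold on the processed value.
#' @param sg_window Savitzky-Golay filter length in windows (odd, default 5).
#' @param sg_order Polynomial order (default 3).
#' @param order `"z_then_smooth"` or `"smooth_then_z"`.
#' @param moments `"chromosome"` or `"genome"`: moments of the z-transform.
#' @param side `"above"` flags `processed > z_threshold`; `"below"` flags
#'   `processed <= z_threshold`.
#' @return The table with `processed` and `flag` columns added.
#' @export
call_window_outliers <- function(tbl, value_col, z_threshold,
                                 sg_window = 5, sg_order = 3,
                                 order = c("z_then_smooth", "smooth_then_z"),
                                 moments = c("chromosome", "genome"),
                                 side = c("above", "below")) {
  order <- match.arg(order)
  moments <- match.arg(moments)
  side <- match.arg(side)
  if (sg_window %% 2 != 1 || sg_window <= sg_order) {
    abort("sg_window must be odd and greater than sg_order")
  }
  v_all <- tbl[[value_col]]
  g_mean <- mean(v_all, na.rm = TRUE)
  g_sd <- sd(v_all, na.rm = TRUE)
  tbl$processed <- NA_real_
  for (ch in unique(tbl$chrom)) {
    i <- which(tbl$chrom == ch)
    i <- i[base::order(tbl$start[i])]
    ok <- i[!is.na(tbl[[value_col]][i])]
    if (length(ok) < sg_window) {
      warn(paste0("chromosome ", ch, " has fewer than ", sg_window,
                  " usable windows; skipped"))
      next
    }
    v <- tbl[[value_col]][ok]
    if (order == "z_then_smooth") {
      m <- if (moments == "chromosome") mean(v) else g_mean
      s <- if (moments == "chromosome") sd(v) else g_sd
      z <- if (s > 0) (v - m) / s else rep(0, length(v))
      sm <- signal::sgolayfilt(z, p = sg_order, n = sg_window)
      tbl$processed[ok] <- sm
    } else {
      sm <- signal::sgolayfilt(v, p = sg_order, n = sg_window)
      tbl$processed[ok] <- sm
    }
  }
  if (order == "smooth_then_z") {
    # a numerically constant vector must z-transform to zero, not to noise
    ztrans <- function(v) {
      m <- mean(v, na.rm = TRUE)
      s <- sd(v, na.rm = TRUE)
      if (is.na(s) || s <= 1e-10 * (abs(m) + 1)) {
        ifelse(is.na(v), NA_real_, 0)
      } else (v - m) / s
    }
    if (moments == "chromosome") {
      for (ch in unique(tbl$chrom)) {
        i <- tbl$chrom == ch
        tbl$processed[i] <- ztrans(tbl$processed[i])
      }
    } else {
      tbl$processed <- ztrans(tbl$processed)
    }
  }
  tbl$flag <- !is.na(tbl$processed) &
    (if (side == "above") tbl$processed > z_threshold
     else tbl$processed <= z_threshold)
  tbl
}

#' Call F_ST peaks from a windowed table
#'
#' Per chromosome, F_ST values are z-transformed (chromosome mean and SD),
#' smoothed with a Savitzky-Golay filter, and windows with a smoothed
#' Z-F_ST above `z_threshold` (default 2) are flagged as peaks.
#'
#' @inheritParams call_window_outliers
#' @param tbl Output of [window_fst()].
#' @param z_threshold Peak threshold (default 2).
#' @return The table with `processed` (smoothed Z-F_ST) and `flag` columns.
#' @export
call_fst_peaks <- function(tbl, z_threshold = 2, sg_window = 5, sg_order = 3) {
  call_window_outliers(tbl, attr(tbl, "stat") %||% "fst", z_threshold,
                       sg_window, sg_order,
                       order = "z_then_smooth", moments = "chromosome",
                       side = "above")
}

#' Population branch statistic
#'
#' `PBS_A = (T_AB + T_AC - T_BC) / 2` with `T = -log(1 - F_ST)`: the
#' branch-specific differentiation of focal population A against references
#' B and C. Pairwise `F_ST >= 1` is handled per `on_unit`: dropped (`NA`)
#' or capped just below 1.
#'
#' @param fst_ab,fst_ac,fst_bc Numeric vectors of pairwise window F_ST.
#' @param on_unit `"drop"` (default) or `"cap"`.
#' @param cap Cap value used when `on_unit = "cap"` (default 0.99999).
#' @return Numeric vector of PBS values for the focal population.
#' @export
pbs <- function(fst_ab, fst_ac, fst_bc, on_unit = c("drop", "cap"),
                cap = 0.99999) {
  on_unit <- match.arg(on_unit)
  fix <- function(f) {
    if (on_unit == "cap") pmin(f, cap) else
      replace(f, !is.na(f) & f >= 1, NA_real_)
  }
  t_ab <- -log(1 - fix(fst_ab))
  t_ac <- -log(1 - fix(fst_ac))
  t_bc <- -log(1 - fix(fst_bc))
  (t_ab + t_ac - t_bc) / 2
}

#' Windowed PBS with outlier flagging
#'
#' Joins three pairwise windowed F_ST tables (focal-B, focal-C, B-C) on
#' window coordinates, computes PBS for the focal population, and flags
#' outliers with the same smoothed z-score procedure as F_ST peaks.
#'
#' @param tbl_ab,tbl_ac,tbl_bc Outputs of [window_fst()] on identical
#'   window grids.
#' @inheritParams call_fst_peaks
#' @inheritParams pbs
#' @return A `win_stat_tbl` with `pbs`, `processed` and `flag` columns.
#' @export
pbs_windows <- function(tbl_ab, tbl_ac, tbl_bc, z_threshold = 2,
                        sg_window = 5, sg_order = 3,
                        on_unit = c("drop", "cap"), cap = 0.99999) {
  key <- c("chrom", "class", "start", "end", "partial")
  j <- tbl_ab |>
    select(dplyr::all_of(key), fst_ab = "fst") |>
    inner_join(select(tbl_ac, dplyr::all_of(key), fst_ac = "fst"), by = key) |>
    inner_join(select(tbl_bc, dplyr::all_of(key), fst_bc = "fst"), by = key) |>
    mutate(pbs = pbs(.data$fst_ab, .data$fst_ac, .data$fst_bc,
                     on_unit = on_unit, cap = cap))
  out <- call_window_outliers(j, "pbs", z_threshold, sg_window, sg_order,
                              order = "z_then_smooth",
                              moments = "chromosome", side = "above")
  new_win_stat(out, "pbs")
}

#' Post-process composite-likelihood sweep scans
#'
#' Takes per-position CLR values on a test grid (e.g. a SweepFinder2 output
#' grid), keeps positions with `CLR > threshold`, merges runs of adjacent
#' significant grid positions into candidate sweep regions, and removes
#' regions with a single position or with fewer than one significant site
#' per kb of span. Presence/absence is then marked in fixed-width windows
#' tiled from position 0.
#'
#' @param clr Tibble with `chrom`, `pos`, `clr`; sorted internally (with a
#'   warning) if needed. "Adjacent" means consecutive positions on the test
#'   grid: an intervening non-significant grid position breaks a region.
#' @param threshold Significance threshold (default 46.25, a
#'   background-selection-calibrated cutoff).
#' @param window Window width for presence/absence (default 200,000).
#' @param min_density Minimum significant sites per kb of region span
#'   (default 1).
#' @return List with `regions` (tibble `chrom`, `start`, `end`, `n_sites`,
#'   `max_clr`, `density`) and `windows` (tibble `chrom`, `start`, `end`,
#'   `present`).
#' @export
postprocess_sweeps <- function(clr, threshold = 46.25, window = 200000,
                               min_density = 1) {
  clr <- as_tibble(clr)
  resorted <- clr |> arrange(.data$chrom, .data$pos)
  if (!identical(resorted$pos, clr$pos) ||
      !identical(resorted$chrom, clr$chrom)) {
    warn("CLR grid was unsorted; sorted internally")
  }
  clr <- resorted
  regions <- clr |>
    group_by(.data$chrom) |>
    dplyr::group_modify(function(d, key) {
      sig <- d$clr > threshold
      r <- rle(sig)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      runs <- which(r$values & r$lengths >= 2)
      if (length(runs) == 0) {
        return(tibble(start = integer(), end = integer(),
                      n_sites = integer(), max_clr = numeric(),
                      density = numeric()))
      }
      purrr::map(runs, function(k) {
        i <- seq(starts[k], ends[k])
        span <- max(d$pos[i]) - min(d$pos[i])
        tibble(start = min(d$pos[i]), end = max(d$pos[i]),
               n_sites = length(i), max_clr = max(d$clr[i]),
               density = length(i) / (span / 1000))
      }) |> list_rbind()
    }) |>
    ungroup() |>
    dplyr::filter(.data$density >= min_density)
  wins <- clr |>
    group_by(.data$chrom) |>
    summarise(chrom_end = max(.data$pos), .groups = "drop") |>
    purrr::pmap(function(chrom, chrom_end) {
      start <- seq(1, chrom_end, by = window)
      tibble(chrom = chrom, start = start, end = start + window - 1)
    }) |>
    list_rbind()
  wins$present <- purrr::pmap_lgl(wins, function(chrom, start, end) {
    any(regions$chrom == chrom & regions$start <= end & regions$end >= start)
  })
  list(regions = regions, windows = wins)
}
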