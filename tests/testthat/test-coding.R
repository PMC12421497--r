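test_that("degeneracy classes follow the codon table", {
  deg <- classify_degeneracy(c(g1 = "GGAGGC"))  # two glycine codons
  expect_equal(deg$degeneracy[deg$codon_pos == 3], rep("four-fold", 2))
  # second codon position is always zero-fold
  set.seed(3)
  gc_map <- Biostrings::GENETIC_CODE
  stop_free <- names(gc_map)[gc_map != "*"]
  rand_cds <- paste(sample(stop_free, 30, TRUE), collapse = "")
  deg2 <- classify_degeneracy(stats::setNames(rand_cds, "g"))
  expect_true(all(deg2$degeneracy[deg2$codon_pos == 2] == "zero-fold"))
  # frame violation and internal stop are skipped with a warning
  expect_warning(out <- classify_degeneracy(c(bad = "AAAA")), "skipped")
  expect_equal(nrow(out), 0)
  expect_warning(classify_degeneracy(c(stopgene = "ATGTAAAAA")), "skipped")
})

test_that("a random toy gene matches brute-force substitution enumeration", {
  set.seed(41)
  bases <- c("A", "C", "G", "T")
  gc_map <- Biostrings::GENETIC_CODE
  repeat {
    codons <- replicate(30, paste(sample(bases, 3, TRUE), collapse = ""))
    if (!any(gc_map[codons[-30]] == "*")) break
  }
  cds <- paste(codons, collapse = "")
  deg <- classify_degeneracy(stats::setNames(cds, "toy"))
  for (i in seq_len(90)) {
    codon_i <- (i - 1) %/% 3 + 1
    pos_in <- (i - 1) %% 3 + 1
    cod <- codons[codon_i]
    aa0 <- gc_map[[cod]]
    n_nonsyn <- 0
    for (b in setdiff(bases, substr(cod, pos_in, pos_in))) {
      mut <- cod
      substr(mut, pos_in, pos_in) <- b
      if (gc_map[[mut]] != aa0) n_nonsyn <- n_nonsyn + 1
    }
    expected <- if (n_nonsyn == 3) "zero-fold"
      else if (n_nonsyn == 0) "four-fold" else "other"
    expect_identical(deg$degeneracy[i], expected)
  }
})

# a 5-gene toy: degeneracy table with genomic coordinates plus a matched
# genotype matrix, for piN/piS and SFS checks
toy_coding <- function() {
  deg <- tibble::tibble(
    gene = rep(paste0("g", 1:5), each = 6),
    chrom = "chr1",
    pos = seq_len(30),
    cds_pos = rep(1:6, 5),
    codon_pos = rep(c(1:3, 1:3), 5),
    degeneracy = rep(c("zero-fold", "zero-fold", "four-fold"), 10))
  # variants at selected positions; all W-to-W so GC-conservative
  pos_var <- c(1L, 3L, 7L, 9L, 15L, 21L, 27L)
  g <- matrix(0L, length(pos_var), 6)
  g[1, ] <- c(1L, 0L, 0L, 0L, 0L, 0L)   # zero-fold, p = 1/12
  g[2, ] <- c(2L, 2L, 0L, 0L, 0L, 0L)   # four-fold, p = 4/12
  g[3, ] <- c(1L, 1L, 0L, 0L, 0L, 0L)   # zero-fold, p = 2/12
  g[4, ] <- c(2L, 2L, 2L, 1L, 0L, 0L)   # four-fold, p = 7/12
  g[5, ] <- c(0L, 0L, 0L, 0L, 0L, 2L)   # four-fold (pos 15), p = 2/12
  g[6, ] <- c(1L, 0L, 1L, 0L, 1L, 0L)   # four-fold (pos 21), p = 3/12
  g[7, ] <- c(0L, 2L, 0L, 0L, 0L, 0L)   # four-fold (pos 27), p = 2/12
  x <- toy_geno(g, pops = rep("P1", 6), pos = pos_var, L = 30,
                anc = rep("A", length(pos_var)))
  list(x = x, deg = deg)
}

test_that("piN/piS matches a hand-built two-pass computation on 5 toy genes", {
  tc <- toy_coding()
  est <- pi_n_pi_s(tc$x, tc$deg, "P1", gc_conservative_only = TRUE,
                   n_boot = 0)
  # hand computation: zero-fold sites are cds_pos 1,2,4,5 (20 sites);
  # four-fold are cds_pos 3,6 (10 sites)
  two_pq <- function(p) 2 * p * (1 - p)
  pi_n <- (two_pq(1 / 12) + two_pq(2 / 12)) / 20
  pi_s <- (two_pq(4 / 12) + two_pq(7 / 12) + two_pq(2 / 12) +
             two_pq(3 / 12) + two_pq(2 / 12)) / 10
  expect_equal(est$pi_n, pi_n, tolerance = 1e-12)
  expect_equal(est$pi_s, pi_s, tolerance = 1e-12)
  expect_equal(est$ratio, pi_n / pi_s, tolerance = 1e-12)
  expect_equal(c(est$l_n, est$l_s), c(20, 10))
  # no zero-fold SNPs -> ratio 0
  tc0 <- tc
  keep <- tc0$x$sites$pos %in% c(9, 15, 21, 27, 3)
  x0 <- tc0$x
  x0$sites <- x0$sites[keep, ]
  x0$geno <- x0$geno[keep, , drop = FALSE]
  expect_equal(pi_n_pi_s(x0, tc0$deg, "P1", n_boot = 0)$ratio, 0)
})

test_that("GC-weighted dN/dS aggregation follows the stated algebra", {
  # all substitutions W-to-W with f_AT = 0.5: weighting doubles raw counts
  one <- tibble::tibble(gene = "g1", n_ss = 0, n_ww = 3, s_ss = 0, s_ww = 6,
                        l_n = 300, l_s = 100, f_gc = 0.5)
  est <- aggregate_dn_ds(one, n_boot = 0)
  expect_equal(est$d_n, 3 / (300 * 0.5))
  expect_equal(est$d_s, 6 / (100 * 0.5))
  # symmetric counts and f_gc = 0.5: ratio equals the unweighted ratio
  sym <- tibble::tibble(gene = "g1", n_ss = 4, n_ww = 4, s_ss = 5, s_ww = 5,
                        l_n = 200, l_s = 80, f_gc = 0.5)
  expect_equal(aggregate_dn_ds(sym, n_boot = 0)$ratio,
               (8 / 200) / (10 / 80))
  # 3-gene manual (spreadsheet-style) computation
  tb <- tibble::tibble(gene = c("a", "b", "c"),
                       n_ss = c(1, 0, 2), n_ww = c(2, 1, 0),
                       s_ss = c(3, 2, 2), s_ww = c(4, 1, 3),
                       l_n = c(300, 150, 250), l_s = c(100, 60, 90),
                       f_gc = c(0.4, 0.5, 0.6))
  l_tot <- tb$l_n + tb$l_s
  f <- sum(l_tot * tb$f_gc) / sum(l_tot)
  d_n <- 3 / (700 * f) + 3 / (700 * (1 - f))
  d_s <- 7 / (250 * f) + 8 / (250 * (1 - f))
  got <- aggregate_dn_ds(tb, n_boot = 0)
  expect_equal(got$d_n, d_n, tolerance = 1e-12)
  expect_equal(got$ratio, d_n / d_s, tolerance = 1e-12)
  # invariance under uniform scaling of all counts
  tb2 <- dplyr::mutate(tb, dplyr::across(c(n_ss, n_ww, s_ss, s_ww), ~ .x * 7))
  expect_equal(aggregate_dn_ds(tb2, n_boot = 0)$ratio, got$ratio)
  # degenerate weights
  bad <- dplyr::mutate(tb, f_gc = 1)
  expect_error(aggregate_dn_ds(bad, n_boot = 0), "degenerate")
  # multiply variant: weights multiply instead of divide
  m <- aggregate_dn_ds(sym, weighting = "multiply", n_boot = 0)
  expect_equal(m$d_n, (4 * 0.5 + 4 * 0.5) / 200)
})

test_that("the unfolded SFS is a per-site tally with mass conservation", {
  tc <- toy_coding()
  sfs <- build_sfs(tc$x, tc$deg, "P1", gc_conservative_only = TRUE)
  # total mass = classified polarized sites (30; none unpolarized here)
  expect_equal(sum(sfs$n_sites), 30)
  # derived counts: anc = A = ref everywhere, so derived = ALT count
  z <- sfs[sfs$degeneracy == "zero-fold", ]
  expect_equal(z$n_sites[z$derived_count == 0], 18)  # 20 - 2 variants
  expect_equal(z$n_sites[z$derived_count == 1], 1)
  expect_equal(z$n_sites[z$derived_count == 2], 1)
  f <- sfs[sfs$degeneracy == "four-fold", ]
  expect_equal(f$n_sites[f$derived_count == 0], 5)
  expect_equal(f$n_sites[f$derived_count == 4], 1)
  expect_equal(f$n_sites[f$derived_count == 7], 1)
  expect_equal(sum(f$n_sites * (f$derived_count >= 1)), 5)
  # an unpolarized variable site is excluded from the mass
  tc$x$sites$anc[1] <- NA_character_
  sfs2 <- build_sfs(tc$x, tc$deg, "P1")
  expect_equal(sum(sfs2$n_sites), 29)
  # writer emits one spectrum line per class
  path <- withr::local_tempfile()
  write_sfs(sfs, path)
  lines <- readLines(path)
  expect_equal(length(lines), 4)
  expect_equal(length(strsplit(lines[3], " ")[[1]]), 13)  # 0..12 bins
})
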