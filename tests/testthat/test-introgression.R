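rand_quartets <- function(n, seed = 1, chrom = "chr1", spacing = 5000L) {
  set.seed(seed)
  tibble::tibble(chrom = chrom, pos = seq_len(n) * spacing, class = "A",
                 p1 = round(runif(n), 2), p2 = round(runif(n), 2),
                 p3 = round(runif(n), 2))
}

test_that("Patterson's D follows the frequency formula", {
  # p1 = p2 everywhere: terms cancel sitewise
  q <- rand_quartets(50)
  q$p2 <- q$p1
  q$p3 <- pmax(q$p3, 0.01)
  expect_equal(patterson_d(q), 0)
  # single site (0, 1, 1): pure ABBA
  expect_equal(patterson_d(tibble::tibble(p1 = 0, p2 = 1, p3 = 1)), 1)
  # 100 random sites against the explicit per-site loop oracle
  q2 <- rand_quartets(100, seed = 2)
  expect_equal(patterson_d(q2), oracle_d(q2$p1, q2$p2, q2$p3),
               tolerance = 1e-10)
  expect_true(abs(patterson_d(q2)) <= 1)
  # swapping P1 and P2 flips the sign
  q_sw <- q2
  q_sw[, c("p1", "p2")] <- q2[, c("p2", "p1")]
  expect_equal(patterson_d(q_sw), -patterson_d(q2), tolerance = 1e-12)
  expect_error(patterson_d(tibble::tibble(p1 = 0, p2 = 0, p3 = 0)),
               "denominator")
})

test_that("the 200-kb block jackknife matches an explicit leave-one-out oracle", {
  q <- rand_quartets(200, seed = 3, spacing = 10000L)  # 10 blocks of 200 kb
  res <- block_jackknife_d(q, block = 200000)
  blocks <- floor((q$pos - 1) / 200000)
  se <- oracle_jackknife_se(function(d) oracle_d(d$p1, d$p2, d$p3), q, blocks)
  expect_equal(res$se, se, tolerance = 1e-10)
  expect_equal(res$n_blocks, 10)
  expect_equal(res$d, oracle_d(q$p1, q$p2, q$p3), tolerance = 1e-10)
  expect_equal(res$z, res$d / res$se)
  expect_equal(res$p, 2 * stats::pnorm(-abs(res$z)))
  # duplicating every block leaves D unchanged
  q_dup <- dplyr::bind_rows(q, dplyr::mutate(q, chrom = "chr2"))
  expect_equal(patterson_d(q_dup), patterson_d(q), tolerance = 1e-12)
  # degenerate: identical block compositions give SE = 0, z undefined
  q_id <- dplyr::bind_rows(
    tibble::tibble(chrom = "chr1", pos = c(1L, 200001L), class = "A",
                   p1 = c(0.2, 0.2), p2 = c(0.8, 0.8), p3 = c(0.9, 0.9)))
  deg <- block_jackknife_d(q_id, block = 200000)
  expect_equal(deg$se, 0)
  expect_true(is.na(deg$z))
  expect_error(block_jackknife_d(q_id[1, ]), "fewer than 2")
  # jackknife SE shrinks roughly as 1/sqrt(blocks) on homogeneous data
  q_big <- rand_quartets(800, seed = 4, spacing = 10000L)  # 40 blocks
  res_big <- block_jackknife_d(q_big, block = 200000)
  expect_lt(res_big$se, res$se)
})

test_that("tidy and glance expose the D inference as tibbles", {
  q <- rand_quartets(100, seed = 9, spacing = 10000L)
  res <- block_jackknife_d(q, block = 200000, class_label = "A")
  td <- tidy(res)
  expect_equal(td$estimate, res$d)
  expect_equal(td$std.error, res$se)
  expect_equal(glance(res)$n_blocks, res$n_blocks)
})

test_that("window f_d follows the max-donor normalization", {
  # p2 = p3 everywhere with positive numerator: f_d = 1
  q <- rand_quartets(30, seed = 5)
  q$p1 <- 0
  q$p3 <- q$p2 <- pmax(q$p2, 0.05)
  fd <- fd_windows(q, window = 200000, min_sites = 5)
  expect_equal(fd$fd[1], 1)
  # numerator exactly 0 (site terms cancel) with a nonzero denominator
  q0 <- tibble::tibble(chrom = "chr1", pos = (1:12) * 100L, class = "A",
                       p1 = rep(c(0.8, 0.2), 6), p2 = rep(c(0.2, 0.8), 6),
                       p3 = 0.5)
  expect_equal(fd_windows(q0, min_sites = 5)$fd[1], 0)
  # negative numerator -> missing
  qn <- tibble::tibble(chrom = "chr1", pos = (1:12) * 100L, class = "A",
                       p1 = 1, p2 = 0, p3 = 0.8)
  expect_true(is.na(fd_windows(qn, min_sites = 5)$fd[1]))
  # windows below min_sites are missing
  expect_true(is.na(fd_windows(q0, min_sites = 50)$fd[1]))
  # random windows match the per-site oracle
  q2 <- rand_quartets(300, seed = 6, spacing = 2000L)
  fd2 <- fd_windows(q2, window = 200000, min_sites = 1)
  for (w in seq_len(nrow(fd2))) {
    i <- q2$pos > fd2$start[w] - 1 & q2$pos <= fd2$end[w]
    o <- oracle_fd(q2$p1[i], q2$p2[i], q2$p3[i])
    if (is.na(fd2$fd[w])) expect_lt(o, 0) else {
      expect_equal(fd2$fd[w], o, tolerance = 1e-10)
    }
  }
  # sign linkage with D's numerator per window
  num_sign <- sapply(seq_len(nrow(fd2)), function(w) {
    i <- q2$pos > fd2$start[w] - 1 & q2$pos <= fd2$end[w]
    sign(sum((1 - q2$p1[i]) * q2$p2[i] * q2$p3[i] -
               q2$p1[i] * (1 - q2$p2[i]) * q2$p3[i]))
  })
  expect_true(all(is.na(fd2$fd) | sign(fd2$fd) == num_sign |
                    (fd2$fd == 0 & num_sign == 0)))
})

test_that("f_d outlier calling uses genome-wide moments after smoothing", {
  set.seed(10)
  mk <- function(chrom, mu) tibble::tibble(
    chrom = chrom, class = "A",
    start = seq(1, by = 200000, length.out = 40),
    end = seq(200000, by = 200000, length.out = 40),
    n_sites = 100L, fd = pmax(0, rnorm(40, mu, 0.01)))
  tbl <- fastz:::new_win_stat(
    dplyr::bind_rows(mk("chr1", 0.4), mk("chr2", 0.4), mk("chr3", 0.4),
                     mk("chr4", 0.4), mk("chr5", 0.4), mk("chrZ", 0.1)),
    "fd")
  out <- call_fd_outliers(tbl)
  # the uniformly depressed chromosome is flagged, the others are not
  expect_true(all(out$flag[out$chrom == "chrZ"]))
  expect_false(any(out$flag[out$chrom != "chrZ"]))
  # constant f_d genome-wide: no outliers
  flat <- fastz:::new_win_stat(dplyr::mutate(tbl, fd = 0.3), "fd")
  expect_equal(sum(call_fd_outliers(flat)$flag), 0)
  # -Inf threshold flags nothing
  expect_equal(sum(call_fd_outliers(tbl, z_threshold = -Inf)$flag), 0)
})

test_that("the recombination regression reproduces closed-form OLS", {
  mkfd <- function(vals) fastz:::new_win_stat(tibble::tibble(
    chrom = "chr1", class = "A",
    start = seq(1, by = 200000, length.out = length(vals)),
    end = seq(200000, by = 200000, length.out = length(vals)),
    n_sites = 10L, fd = vals), "fd")
  rec <- function(vals) tibble::tibble(
    chrom = "chr1", start = seq(1, by = 200000, length.out = length(vals)),
    rate = vals)
  # perfectly linear: R^2 = 1
  r <- suppressWarnings(
    fd_recombination_regression(mkfd(0.1 + 0.02 * (1:10)), rec(1:10)))
  expect_equal(r$r_squared, 1)
  expect_equal(r$slope, 0.02, tolerance = 1e-10)
  # 20-point toy against the normal equations
  set.seed(11)
  xv <- runif(20)
  yv <- 0.2 + 0.5 * xv + rnorm(20, 0, 0.05)
  got <- fd_recombination_regression(mkfd(yv), rec(xv))
  beta <- cov(xv, yv) / var(xv)
  alpha <- mean(yv) - beta * mean(xv)
  ss_res <- sum((yv - alpha - beta * xv)^2)
  ss_tot <- sum((yv - mean(yv))^2)
  expect_equal(got$slope, beta, tolerance = 1e-10)
  expect_equal(got$r_squared, 1 - ss_res / ss_tot, tolerance = 1e-10)
  expect_error(fd_recombination_regression(mkfd(yv), rec(rep(1, 20))),
               "zero variance")
})
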