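# Toy dataset builder: a geno_data from an explicit site x sample matrix.
# One locus per chromosome spanning 1..L; defaults give a single autosomal
# contig with W-to-W (GC-conservative) alleles.
toy_geno <- function(geno, pops, sexes = rep("M", length(pops)),
                     class = "A", chrom = NULL, pos = NULL, L = NULL,
                     ref = NULL, alt = NULL, anc = NULL, qc = NULL) {
  geno <- as.matrix(geno)
  n_sites <- nrow(geno)
  if (is.null(pos)) pos <- seq_len(n_sites)
  if (is.null(chrom)) chrom <- rep(if (class[1] == "Z") "chrZ" else "chr1",
                                   n_sites)
  class <- rep(class, length.out = n_sites)
  if (is.null(L)) L <- max(pos)
  if (is.null(ref)) ref <- rep("A", n_sites)
  if (is.null(alt)) alt <- rep("T", n_sites)
  samples <- tibble::tibble(
    sample = paste0("s", seq_along(pops)), pop = pops, sex = sexes)
  colnames(geno) <- samples$sample
  sites <- tibble::tibble(chrom = chrom, pos = pos, locus = chrom,
                          class = class, ref = ref, alt = alt,
                          anc = if (is.null(anc)) NA_character_ else anc)
  loci <- dplyr::distinct(sites[, c("locus", "chrom", "class")]) |>
    dplyr::mutate(start = 1L, end = as.integer(L))
  ledger <- dplyr::count(loci, class, wt = end, name = "L")
  geno_data(sites, geno, samples, loci, ledger, qc = qc)
}

# ---- independent oracles (plain loops, no shared code with the package) ----

oracle_pi <- function(p_vec, L) {
  tot <- 0
  for (p in p_vec) if (p > 0 && p < 1) tot <- tot + 2 * p * (1 - p)
  tot / L
}

# per-site Weir & Cockerham (1984) two-population estimator, summed manually
oracle_wc_fst <- function(p1, n1, h1, p2, n2, h2) {
  num <- den <- 0
  for (i in seq_along(p1)) {
    nb <- (n1[i] + n2[i]) / 2
    nc <- (2 * nb - (n1[i]^2 + n2[i]^2) / (2 * nb))
    pb <- (n1[i] * p1[i] + n2[i] * p2[i]) / (2 * nb)
    s2 <- (n1[i] * (p1[i] - pb)^2 + n2[i] * (p2[i] - pb)^2) / nb
    hb <- (n1[i] * h1[i] + n2[i] * h2[i]) / (2 * nb)
    a <- nb / nc * (s2 - (pb * (1 - pb) - s2 / 2 - hb / 4) / (nb - 1))
    b <- nb / (nb - 1) * (pb * (1 - pb) - s2 / 2 - hb * (2 * nb - 1) / (4 * nb))
    cc <- hb / 2
    num <- num + a
    den <- den + a + b + cc
  }
  num / den
}

oracle_d <- function(p1, p2, p3) {
  abba <- baba <- 0
  for (i in seq_along(p1)) {
    abba <- abba + (1 - p1[i]) * p2[i] * p3[i]
    baba <- baba + p1[i] * (1 - p2[i]) * p3[i]
  }
  (abba - baba) / (abba + baba)
}

oracle_fd <- function(p1, p2, p3) {
  num <- den <- 0
  for (i in seq_along(p1)) {
    num <- num + (1 - p1[i]) * p2[i] * p3[i] - p1[i] * (1 - p2[i]) * p3[i]
    pd <- max(p2[i], p3[i])
    den <- den + (1 - p1[i]) * pd * pd - p1[i] * (1 - pd) * pd
  }
  num / den
}

# delete-one-block jackknife SE of a statistic over a list of block indices
oracle_jackknife_se <- function(stat_fn, data, block_ids) {
  ids <- unique(block_ids)
  n <- length(ids)
  theta <- numeric(n)
  for (k in seq_len(n)) theta[k] <- stat_fn(data[block_ids != ids[k], ])
  m <- mean(theta)
  sqrt((n - 1) / n * sum((theta - m)^2))
}

# two-sided Fisher exact p by full hypergeometric enumeration
oracle_fisher_p <- function(m) {
  a <- m[1, 1]
  r1 <- sum(m[1, ])
  c1 <- sum(m[, 1])
  n <- sum(m)
  lo <- max(0, c1 - (n - r1))
  hi <- min(r1, c1)
  probs <- stats::dhyper(lo:hi, r1, n - r1, c1)
  p_obs <- stats::dhyper(a, r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Savitzky-Golay smoothing by direct local polynomial least squares, with
# truncated-window refits at the edges (fit on the first/last n points and
# evaluate at the off-centre position)
oracle_sgolay <- function(x, p, n) {
  h <- (n - 1) / 2
  len <- length(x)
  out <- numeric(len)
  for (i in seq_len(len)) {
    if (i <= h) {
      idx <- 1:n
      at <- i
    } else if (i > len - h) {
      idx <- (len - n + 1):len
      at <- i - (len - n)
    } else {
      idx <- (i - h):(i + h)
      at <- h + 1
    }
    t <- seq_along(idx) - at
    fit <- stats::lm(y ~ stats::poly(t, p, raw = TRUE),
                     data = data.frame(y = x[idx], t = t))
    out[i] <- unname(stats::predict(fit, newdata = data.frame(t = 0)))
  }
  out
}

oracle_pbs <- function(fab, fac, fbc) {
  (-log(1 - fab) - log(1 - fac) + log(1 - fbc)) / 2
}
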