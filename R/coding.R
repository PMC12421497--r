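# degeneracy lookup: for each codon and codon position, how many of the
# three possible substitutions are nonsynonymous
degeneracy_table <- local({
  gc <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  codons <- names(gc)
  tab <- matrix(NA_character_, length(codons), 3,
                dimnames = list(codons, NULL))
  for (cod in codons) {
    for (p in 1:3) {
      alt_aa <- vapply(setdiff(bases, substr(cod, p, p)), function(b) {
        mut <- cod
        substr(mut, p, p) <- b
        gc[[mut]]
      }, character(1))
      n_nonsyn <- sum(alt_aa != gc[[cod]])
      tab[cod, p] <- if (n_nonsyn == 3) "zero-fold"
        else if (n_nonsyn == 0) "four-fold" else "other"
    }
  }
  tab
})

#' Classify coding positions by degeneracy
#'
#' Labels every base of each coding sequence as zero-fold (every change is
#' nonsynonymous), four-fold (no change is nonsynonymous) or other, from the
#' standard nuclear genetic code. Genes whose length is not a multiple of 3
#' or that contain an internal stop codon are flagged and skipped with a
#' warning.
#'
#' @param cds A named [Biostrings::DNAStringSet] (or named character vector)
#'   of in-frame coding sequences, one per gene.
#' @param gene_coords Optional tibble `gene`, `chrom`, `start` mapping each
#'   CDS base to genomic coordinates (`pos = start + cds_pos - 1`; ungapped,
#'   forward-strand CDS).
#' @return Tibble: `gene`, `cds_pos`, `codon`, `codon_pos`, `degeneracy`,
#'   plus `chrom`/`pos` when `gene_coords` is given. Skipped genes are
#'   recorded in attribute `"skipped"`.
#' @export
classify_degeneracy <- function(cds, gene_coords = NULL) {
  if (methods::is(cds, "DNAStringSet")) cds <- as.character(cds)
  if (is.null(names(cds))) abort("`cds` must be named by gene")
  gc_map <- Biostrings::GENETIC_CODE
  skipped <- character(0)
  rows <- purrr::imap(as.list(cds), function(seq, gene) {
    n <- nchar(seq)
    if (n %% 3 != 0) {
      skipped <<- c(skipped, gene)
      return(NULL)
    }
    codons <- substring(seq, seq(1, n, 3), seq(3, n, 3))
    aa <- unname(gc_map[codons])
    if (any(aa[-length(aa)] == "*", na.rm = TRUE) || anyNA(aa)) {
      skipped <<- c(skipped, gene)
      return(NULL)
    }
    tibble(gene = gene, cds_pos = seq_len(n),
           codon = rep(codons, each = 3),
           codon_pos = rep(1:3, length(codons)),
           degeneracy = as.vector(t(degeneracy_table[codons, ])))
  })
  if (length(skipped) > 0) {
    warn(paste0("skipped gene(s) with frame/stop problems: ",
                paste(skipped, collapse = ", ")))
  }
  out <- list_rbind(rows[!map_lgl(rows, is.null)])
  if (!is.null(gene_coords)) {
    out <- out |>
      inner_join(as_tibble(gene_coords), by = "gene") |>
      mutate(pos = .data$start + .data$cds_pos - 1L) |>
      select(-"start")
  }
  attr(out, "skipped") <- skipped
  out
}

#' piN/piS from zero-fold and four-fold degenerate sites
#'
#' Nucleotide diversity at zero-fold sites (nonsynonymous proxy) over
#' diversity at four-fold sites (synonymous proxy), each computed as
#' `sum(2 p q) / L_class` with class-specific callable totals taken from the
#' degeneracy table. By default only GC-conservative polymorphisms enter the
#' sums, to shield the ratio from GC-biased gene conversion. The CI
#' resamples genes with replacement (100 replicates).
#'
#' @param x A [geno_data] object.
#' @param degeneracy Output of [classify_degeneracy()] carrying `chrom`,
#'   `pos`, `gene`, `degeneracy`.
#' @param pop Population label.
#' @param gc_conservative_only Restrict polymorphisms to GC-conservative
#'   ones (default `TRUE`).
#' @param n_boot Gene-bootstrap replicates (default 100).
#' @param seed Bootstrap seed.
#' @return One-row tibble: `pop`, `pi_n`, `pi_s`, `ratio`, `l_n`, `l_s`,
#'   `ci_lo`, `ci_hi`.
#' @export
pi_n_pi_s <- function(x, degeneracy, pop, gc_conservative_only = TRUE,
                      n_boot = 100, seed = 1) {
  deg <- dplyr::filter(degeneracy, .data$degeneracy %in%
                         c("zero-fold", "four-fold"))
  sm <- x$samples$sample[x$samples$pop == pop]
  ac <- allele_counts(x, sm)
  sites <- x$sites |>
    mutate(p = ac$alt / ac$tot,
           contrib = 2 * .data$p * (1 - .data$p),
           gc_cons = classify_gc_conservative(.data$ref, .data$alt)) |>
    dplyr::filter(!is.na(.data$p), .data$p > 0, .data$p < 1)
  if (gc_conservative_only) sites <- dplyr::filter(sites, .data$gc_cons)
  hit <- deg |>
    left_join(sites[, c("chrom", "pos", "contrib")], by = c("chrom", "pos")) |>
    mutate(contrib = dplyr::coalesce(.data$contrib, 0))
  per_gene <- hit |>
    group_by(.data$gene, .data$degeneracy) |>
    summarise(contrib = sum(.data$contrib), l = dplyr::n(), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "degeneracy",
                       values_from = c("contrib", "l"), values_fill = 0)
  for (col in c("contrib_zero-fold", "contrib_four-fold", "l_zero-fold",
                "l_four-fold")) {
    if (!col %in% names(per_gene)) per_gene[[col]] <- 0
  }
  ratio_from <- function(tb) {
    l_n <- sum(tb[["l_zero-fold"]])
    l_s <- sum(tb[["l_four-fold"]])
    pi_n <- sum(tb[["contrib_zero-fold"]]) / l_n
    pi_s <- sum(tb[["contrib_four-fold"]]) / l_s
    c(pi_n = pi_n, pi_s = pi_s, ratio = pi_n / pi_s, l_n = l_n, l_s = l_s)
  }
  est <- ratio_from(per_gene)
  if (!is.finite(est["pi_s"]) || est["pi_s"] == 0) {
    if (est["pi_n"] > 0) abort("undefined ratio: zero four-fold diversity")
  }
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0 && nrow(per_gene) > 1) {
    set.seed(seed)
    reps <- vapply(seq_len(n_boot), function(i) {
      ratio_from(per_gene[sample.int(nrow(per_gene), replace = TRUE), ])["ratio"]
    }, numeric(1))
    ci <- unname(quantile(reps[is.finite(reps)], c(0.025, 0.975)))
  }
  tibble(pop = pop, pi_n = est[["pi_n"]], pi_s = est[["pi_s"]],
         ratio = est[["ratio"]], l_n = est[["l_n"]], l_s = est[["l_s"]],
         ci_lo = ci[1], ci_hi = ci[2])
}

#' Aggregate per-gene substitution counts into dN/dS
#'
#' Pools GC-conservative substitution counts across genes, normalizing each
#' substitution class by the fraction of sites able to undergo it: with the
#' default `weighting = "divide"`, `d_N = sum(cN_SS) / (L_N f_GC) +
#' sum(cN_WW) / (L_N f_AT)` (f_GC pooled across genes, length-weighted), and
#' analogously `d_S`. The alternative reading that multiplies counts by the
#' proportions is available as `weighting = "multiply"`. The CI resamples
#' genes with replacement (100 replicates).
#'
#' @param counts Tibble with one row per gene: `gene`, nonsynonymous counts
#'   `n_ss`, `n_ww`, synonymous counts `s_ss`, `s_ww`, site totals `l_n`,
#'   `l_s`, and GC fraction `f_gc`.
#' @param weighting `"divide"` (default) or `"multiply"`.
#' @param n_boot Gene-bootstrap replicates (default 100).
#' @param seed Bootstrap seed.
#' @return One-row tibble: `d_n`, `d_s`, `ratio`, `ci_lo`, `ci_hi`.
#' @export
aggregate_dn_ds <- function(counts, weighting = c("divide", "multiply"),
                            n_boot = 100, seed = 1) {
  weighting <- match.arg(weighting)
  counts <- as_tibble(counts)
  est_from <- function(tb) {
    l_tot <- tb$l_n + tb$l_s
    f_gc <- sum(l_tot * tb$f_gc) / sum(l_tot)
    f_at <- 1 - f_gc
    l_n <- sum(tb$l_n)
    l_s <- sum(tb$l_s)
    if (weighting == "divide") {
      if ((f_gc == 0 && sum(tb$n_ss + tb$s_ss) > 0) ||
          (f_at == 0 && sum(tb$n_ww + tb$s_ww) > 0)) {
        abort("degenerate GC weight: f in {0,1} with nonzero opposite counts")
      }
      d_n <- sum(tb$n_ss) / (l_n * f_gc) + sum(tb$n_ww) / (l_n * f_at)
      d_s <- sum(tb$s_ss) / (l_s * f_gc) + sum(tb$s_ww) / (l_s * f_at)
    } else {
      d_n <- (sum(tb$n_ss) * f_gc + sum(tb$n_ww) * f_at) / l_n
      d_s <- (sum(tb$s_ss) * f_gc + sum(tb$s_ww) * f_at) / l_s
    }
    c(d_n = d_n, d_s = d_s, ratio = d_n / d_s)
  }
  est <- est_from(counts)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0 && nrow(counts) > 1) {
    set.seed(seed)
    reps <- vapply(seq_len(n_boot), function(i) {
      est_from(counts[sample.int(nrow(counts), replace = TRUE), ])["ratio"]
    }, numeric(1))
    ci <- unname(quantile(reps[is.finite(reps)], c(0.025, 0.975)))
  }
  tibble(d_n = est[["d_n"]], d_s = est[["d_s"]], ratio = est[["ratio"]],
         ci_lo = ci[1], ci_hi = ci[2])
}

#' Unfolded site frequency spectrum per degeneracy class
#'
#' Tallies derived-allele counts (0..2n alleles) at zero-fold and four-fold
#' degenerate sites of a population, using the per-site ancestral calls in
#' `x$sites$anc`. Unpolarized variable sites are excluded (and do not count
#' toward the monomorphic bin); classified sites with no variant record are
#' ancestral-monomorphic and fill bin 0. Sites whose non-missing allele
#' total differs from the modal sample size are dropped (no projection).
#'
#' @param x A [geno_data] with ancestral calls.
#' @param degeneracy Output of [classify_degeneracy()] with `chrom`, `pos`.
#' @param pop Population label.
#' @param gc_conservative_only Restrict variable sites to GC-conservative
#'   polymorphisms (default `TRUE`).
#' @return Tibble: `degeneracy`, `derived_count` (0..2n), `n_sites`.
#' @export
build_sfs <- function(x, degeneracy, pop, gc_conservative_only = TRUE) {
  deg <- dplyr::filter(degeneracy, .data$degeneracy %in%
                         c("zero-fold", "four-fold"))
  sm <- x$samples$sample[x$samples$pop == pop]
  ac <- allele_counts(x, sm)
  der <- ifelse(is.na(x$sites$anc), NA_real_,
                ifelse(x$sites$anc == x$sites$ref, ac$alt,
                       ifelse(x$sites$anc == x$sites$alt, ac$tot - ac$alt,
                              NA_real_)))
  sites <- x$sites |>
    mutate(derived = der, tot = ac$tot,
           gc_cons = classify_gc_conservative(.data$ref, .data$alt))
  if (gc_conservative_only) {
    # the GC restriction applies to polymorphisms; sites monomorphic within
    # the population (derived count 0 or 2n) are retained either way
    sites <- dplyr::filter(sites, .data$gc_cons | .data$derived == 0 |
                             .data$derived == .data$tot)
  }
  n_hap <- as.integer(names(sort(table(ac$tot), decreasing = TRUE))[1])
  hit <- deg |>
    left_join(sites[, c("chrom", "pos", "derived", "tot")],
              by = c("chrom", "pos"))
  # classified positions without a variant record are ancestral-monomorphic
  hit$derived[is.na(hit$tot)] <- 0
  hit$tot[is.na(hit$tot)] <- n_hap
  hit <- dplyr::filter(hit, .data$tot == n_hap, !is.na(.data$derived))
  tidyr::crossing(degeneracy = c("zero-fold", "four-fold"),
                  derived_count = 0:n_hap) |>
    left_join(
      hit |> dplyr::count(.data$degeneracy, derived_count = .data$derived),
      by = c("degeneracy", "derived_count")) |>
    mutate(n_sites = dplyr::coalesce(.data$n, 0L)) |>
    select("degeneracy", "derived_count", "n_sites")
}

#' Write site frequency spectra in a DFE-alpha-style text layout
#'
#' One block per degeneracy class: a header line with the number of
#' chromosomes sampled, then the whitespace-separated spectrum from derived
#' count 0 to 2n. Neutral (four-fold) spectrum is written before the
#' selected (zero-fold) one.
#'
#' @param sfs Output of [build_sfs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sfs <- function(sfs, path) {
  n_hap <- max(sfs$derived_count)
  lines <- c("1", as.character(n_hap))
  for (cls in c("four-fold", "zero-fold")) {
    v <- sfs |>
      dplyr::filter(.data$degeneracy == cls) |>
      arrange(.data$derived_count) |>
      pull("n_sites")
    lines <- c(lines, paste(v, collapse = " "))
  }
  writeLines(lines, path)
  invisible(path)
}
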