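#' Polarization groups
#'
#' The two-of-three rule assigns an ancestral allele when at least two of
#' three sample groups — an outgroup and two ingroup species pairs — are
#' fixed for the same allele.
#'
#' @param outgroup,group2,group3 Character vectors of sample names; disjoint
#'   and non-empty.
#' @param min_calls Minimum number of non-missing allele observations for a
#'   group to count as "fixed" (default 1, appropriate when the outgroup is
#'   a single individual).
#' @return A list of class `polarization_groups`.
#' @export
polarization_groups <- function(outgroup, group2, group3, min_calls = 1) {
  gs <- list(outgroup = outgroup, group2 = group2, group3 = group3)
  if (any(lengths(gs) == 0)) abort("polarization groups must be non-empty")
  if (anyDuplicated(unlist(gs))) abort("polarization groups must be disjoint")
  structure(c(gs, list(min_calls = min_calls)), class = "polarization_groups")
}

#' Assign ancestral alleles by the two-of-three fixed-group rule
#'
#' A group is "fixed" for an allele at a site when it has at least
#' `min_calls` non-missing allele observations and no alternative allele
#' among them. The ancestral allele is the allele for which at least two of
#' the three groups are fixed; sites where no allele reaches two fixed
#' groups are labelled `unpolarized`. Sites monomorphic across all groups
#' are trivially polarized to the only observed allele.
#'
#' @param x A [geno_data] object (biallelic or monomorphic sites).
#' @param groups A [polarization_groups()].
#' @return Tibble: `chrom`, `pos`, `class`, `ancestral` (allele or `NA`),
#'   `status` (`"polarized"`/`"unpolarized"`), `n_supporting` (number of
#'   groups fixed for the ancestral allele).
#' @export
polarize_sites <- function(x, groups) {
  grp_counts <- function(members) {
    ac <- allele_counts(x, members)
    list(alt = ac$alt, tot = ac$tot)
  }
  g1 <- grp_counts(groups$outgroup)
  g2 <- grp_counts(groups$group2)
  g3 <- grp_counts(groups$group3)
  mc <- groups$min_calls

  # per group: +1 fixed ALT, -1 fixed REF, 0 not fixed
  fixed_state <- function(g) {
    ifelse(g$tot < mc, 0L,
           ifelse(g$alt == 0, -1L, ifelse(g$alt == g$tot, 1L, 0L)))
  }
  s <- cbind(fixed_state(g1), fixed_state(g2), fixed_state(g3))
  n_ref <- rowSums(s == -1L)
  n_alt <- rowSums(s == 1L)
  anc <- ifelse(n_ref >= 2, x$sites$ref,
                ifelse(n_alt >= 2, x$sites$alt, NA_character_))
  tibble(
    chrom = x$sites$chrom, pos = x$sites$pos, class = x$sites$class,
    ancestral = anc,
    status = ifelse(is.na(anc), "unpolarized", "polarized"),
    n_supporting = ifelse(n_ref >= 2, n_ref, ifelse(n_alt >= 2, n_alt, 0L))
  )
}

#' Attach ancestral calls to a dataset
#'
#' Convenience wrapper storing the result of [polarize_sites()] in the
#' `anc` column of the site table (unpolarized sites get `NA`).
#'
#' @param x A [geno_data] object.
#' @param groups A [polarization_groups()].
#' @return `x` with `sites$anc` filled in.
#' @export
polarize <- function(x, groups) {
  calls <- polarize_sites(x, groups)
  x$sites$anc <- calls$ancestral
  x
}

#' Build a masked ancestralized reference sequence
#'
#' Starting from a reference sequence set, masks (with `N`) every position
#' that was not genotyped and every variable position that could not be
#' polarized, and substitutes the ancestral allele where it differs from the
#' reference base.
#'
#' @param reference A [Biostrings::DNAStringSet] (names = chromosomes) or a
#'   named character vector of sequences.
#' @param calls Tibble as returned by [polarize_sites()].
#' @param genotyped A tibble of genotyped (callable) intervals with columns
#'   `chrom`, `start`, `end` (1-based inclusive); positions outside these
#'   intervals are masked.
#' @return A [Biostrings::DNAStringSet] of the same lengths as `reference`.
#' @export
build_ancestral_sequence <- function(reference, calls, genotyped) {
  if (!methods::is(reference, "DNAStringSet")) {
    reference <- Biostrings::DNAStringSet(reference)
  }
  out <- vector("list", length(reference))
  names(out) <- names(reference)
  for (ch in names(reference)) {
    s <- strsplit(as.character(reference[[ch]]), "")[[1]]
    len <- length(s)
    callable <- rep(FALSE, len)
    gi <- genotyped[genotyped$chrom == ch, , drop = FALSE]
    for (k in seq_len(nrow(gi))) {
      callable[seq.int(max(1L, gi$start[k]), min(len, gi$end[k]))] <- TRUE
    }
    s[!callable] <- "N"
    cc <- calls[calls$chrom == ch, , drop = FALSE]
    if (any(cc$pos > len)) abort("ancestral call beyond reference length")
    unpol <- cc$pos[cc$status == "unpolarized"]
    s[unpol] <- "N"
    pol <- cc[cc$status == "polarized", , drop = FALSE]
    s[pol$pos[callable[pol$pos]]] <- pol$ancestral[callable[pol$pos]]
    out[[ch]] <- paste(s, collapse = "")
  }
  Biostrings::DNAStringSet(unlist(out))
}
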