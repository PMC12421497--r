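#' Write a genotype dataset as an all-sites VCF
#'
#' Emits a VCF 4.2 file containing both the variant sites of `x` and the
#' monomorphic callable positions implied by its locus layout, so that
#' per-site denominators (L) can be recovered from the file alone. Female
#' genotypes at Z-linked sites are written haploid (`0`, `1` or `.`); all
#' other genotypes diploid (`0/1`, `./.`). If ancestral alleles are present
#' they are recorded as `AA=` in INFO. Monomorphic positions, whose base
#' identity the container does not track, are written with REF `N`.
#'
#' @param x A [geno_data] object.
#' @param path Output path.
#' @param all_sites Write monomorphic records too (default `TRUE`).
#' @param seed Optional integer recorded in the header as `##fastz_seed`,
#'   so a simulated file carries its provenance.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path, all_sites = TRUE, seed = NULL) {
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) abort(paste0("cannot write: ", path)))
  on.exit(close(con))
  chroms <- unique(x$loci$chrom)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=fastz",
    if (!is.null(seed)) paste0("##fastz_seed=", as.integer(seed)),
    '##INFO=<ID=AA,Number=1,Type=String,Description="Ancestral allele">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    vapply(chroms, function(ch) {
      len <- max(x$loci$end[x$loci$chrom == ch])
      paste0("##contig=<ID=", ch, ",length=", len, ">")
    }, character(1)),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", x$samples$sample), collapse = "\t")
  )
  writeLines(hdr, con)

  hap <- function(g) ifelse(is.na(g), ".", as.character(g))
  dip <- function(g) dplyr::case_when(
    is.na(g) ~ "./.", g == 0L ~ "0/0", g == 1L ~ "0/1", g == 2L ~ "1/1"
  )
  fem <- x$samples$sex == "F"

  emit <- function(chrom, pos, ref, alt, info, gt) {
    paste(c(chrom, pos, ".", ref, alt, ".", "PASS", info, "GT", gt),
          collapse = "\t")
  }

  # interleave variant and monomorphic records locus by locus, in order
  for (i in seq_len(nrow(x$loci))) {
    lc <- x$loci[i, ]
    on_locus <- which(x$sites$locus == lc$locus)
    var_pos <- x$sites$pos[on_locus]
    lines <- character(0)
    if (all_sites) {
      mono <- setdiff(seq.int(lc$start, lc$end), var_pos)
      gt0 <- if (lc$class == "Z") ifelse(fem, "0", "0/0") else rep("0/0", nrow(x$samples))
      gt0 <- paste(gt0, collapse = "\t")
      lines <- vapply(mono, function(p) emit(lc$chrom, p, "N", ".", ".", gt0),
                      character(1))
      all_pos <- c(mono, var_pos)
    } else all_pos <- var_pos
    for (k in seq_along(on_locus)) {
      j <- on_locus[k]
      g <- x$geno[j, ]
      gt <- if (x$sites$class[j] == "Z") ifelse(fem, hap(g), dip(g)) else dip(g)
      info <- if (!is.na(x$sites$anc[j])) paste0("AA=", x$sites$anc[j]) else "."
      lines <- c(lines, emit(x$sites$chrom[j], x$sites$pos[j], x$sites$ref[j],
                             x$sites$alt[j], info,
                             paste(gt, collapse = "\t")))
    }
    if (length(lines)) writeLines(lines[order(all_pos)], con)
  }
  invisible(path)
}

#' Read a VCF into a genotype dataset
#'
#' Parses a (possibly all-sites) VCF with `vcfR` and rebuilds a [geno_data]
#' object. Chromosome class is assigned from `z_chroms`; the callable-site
#' ledger counts every record (variant + monomorphic) per class, and the
#' locus layout is taken as one interval per chromosome spanning the observed
#' positions. Haploid genotype strings (`0`, `1`, `.`) are accepted at
#' Z-linked sites; `AA=` INFO entries populate the ancestral-allele column.
#'
#' @param path VCF path (plain or bgzipped).
#' @param samples Tibble with `sample`, `pop`, `sex` covering the VCF samples.
#' @param z_chroms Character vector of chromosome names treated as Z-linked.
#' @return A [geno_data] object (variant sites only, ledger from all records).
#' @export
read_vcf <- function(path, samples, z_chroms = "chrZ") {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as_tibble(as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE))
  fix$POS <- as.integer(fix$POS)
  chrom_class <- ifelse(fix$CHROM %in% z_chroms, "Z", "A")
  info <- vcfR::extract.info(v, element = "AA")

  is_var <- !is.na(fix$ALT) & fix$ALT != "." & fix$ALT != ""
  ledger <- tibble(class = c("A", "Z"),
                   L = c(sum(chrom_class == "A"), sum(chrom_class == "Z")))

  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- as_tibble(samples)
  if (!all(colnames(gt) %in% samples$sample)) {
    abort("`samples` does not cover all VCF sample columns")
  }
  samples <- samples[match(colnames(gt), samples$sample), ]

  parse_gt <- function(s) {
    a <- strsplit(s, "[/|]")
    vapply(a, function(al) {
      al <- al[al != "."]
      if (length(al) == 0) NA_integer_ else sum(as.integer(al))
    }, integer(1))
  }
  gt_var <- gt[is_var, , drop = FALSE]
  geno <- matrix(NA_integer_, nrow(gt_var), ncol(gt))
  for (j in seq_len(ncol(gt))) geno[, j] <- parse_gt(gt_var[, j])
  colnames(geno) <- colnames(gt)

  loci <- fix |>
    mutate(class = chrom_class) |>
    group_by(.data$CHROM, .data$class) |>
    summarise(start = min(.data$POS), end = max(.data$POS), .groups = "drop") |>
    mutate(locus = .data$CHROM) |>
    select(locus, chrom = "CHROM", "start", "end", "class")

  sites <- tibble(
    chrom = fix$CHROM[is_var], pos = fix$POS[is_var],
    locus = fix$CHROM[is_var], class = chrom_class[is_var],
    ref = fix$REF[is_var], alt = fix$ALT[is_var],
    anc = if (is.null(info)) NA_character_ else unname(info[is_var])
  )
  geno_data(sites, geno, samples, loci, ledger)
}
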