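#' Write genotypes as a PLINK bed/bim/fam fileset
#'
#' SNP-major .bed with the standard magic bytes; two-bit codes map homozygous
#' A1 (two minor alleles) to 00, missing to 01, heterozygous to 10 and
#' homozygous A2 to 11. The .bim carries chromosome, SNP id, zero genetic
#' distance, position and the A1/A2 alleles; the .fam uses the sample id as
#' both family and individual id unless a design table supplies pedigree
#' columns.
#'
#' @param G a [genotype_matrix()].
#' @param prefix path prefix (writes `prefix.bed/.bim/.fam`).
#' @param fam optional data frame with columns `fid`, `iid`, `pat`, `mat`,
#'   `sex`, `pheno` aligned with the samples.
#' @return The prefix, invisibly.
#' @export
write_plink <- function(G, prefix, fam = NULL) {
  D <- G$dosage
  n <- nrow(D)
  m <- ncol(D)
  # two-bit codes per sample, SNP-major
  code <- matrix(3L, n, m) # hom A2 (dosage 0)
  code[D == 1] <- 2L # het
  code[D == 2] <- 0L # hom A1
  code[is.na(D)] <- 1L # missing
  bytes_per_snp <- ceiling(n / 4)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  pad <- 4 * bytes_per_snp - n
  for (j in seq_len(m)) {
    cc <- c(code[, j], rep(0L, pad))
    quads <- matrix(cc, nrow = 4)
    byte_vals <- quads[1, ] + quads[2, ] * 4L + quads[3, ] * 16L + quads[4, ] * 64L
    writeBin(as.raw(byte_vals), con)
  }
  utils::write.table(
    data.frame(
      G$snps$chrom, G$snps$snp_id, 0, G$snps$pos, G$snps$a1, G$snps$a2
    ),
    paste0(prefix, ".bim"),
    quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t"
  )
  if (is.null(fam)) {
    ids <- rownames(D)
    fam <- data.frame(fid = ids, iid = ids, pat = 0, mat = 0, sex = 0, pheno = -9)
  }
  utils::write.table(fam, paste0(prefix, ".fam"),
    quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t"
  )
  invisible(prefix)
}

#' Read a PLINK bed/bim/fam fileset
#'
#' Dosages are recoded onto the cohort's minor allele: if the A1 allele's
#' sample frequency exceeds 0.5 the SNP's coding is flipped (`dosage = 2 -
#' dosage`, alleles swapped) and the flip is reported via a warning and the
#' `coding_flips` attribute. Strand-ambiguous A/T and G/C SNPs are listed in
#' the `ambiguous` attribute.
#'
#' @param prefix path prefix of the fileset.
#' @param recode `"minor"` (default) folds the coding onto the cohort minor
#'   allele; `"none"` keeps the stored A1 coding, making write-then-read an
#'   exact round trip.
#' @return A [genotype_matrix()]; attribute `fam` holds the .fam table.
#' @export
read_plink <- function(prefix, recode = c("minor", "none")) {
  recode <- match.arg(recode)
  bim <- utils::read.table(paste0(prefix, ".bim"),
    col.names = c("chrom", "snp_id", "cm", "pos", "a1", "a2"),
    colClasses = c("character", "character", "numeric", "integer", "character", "character")
  )
  fam <- utils::read.table(paste0(prefix, ".fam"),
    col.names = c("fid", "iid", "pat", "mat", "sex", "pheno"),
    colClasses = c("character", "character", "character", "character", "integer", "numeric")
  )
  n <- nrow(fam)
  m <- nrow(bim)
  bytes_per_snp <- ceiling(n / 4)
  raw <- readBin(paste0(prefix, ".bed"), "raw", n = 3 + m * bytes_per_snp)
  if (!identical(raw[1:3], as.raw(c(0x6c, 0x1b, 0x01)))) {
    stop("not a SNP-major PLINK .bed file")
  }
  body <- as.integer(raw[-(1:3)])
  # unpack two-bit codes
  codes <- rbind(
    body %% 4L,
    (body %/% 4L) %% 4L,
    (body %/% 16L) %% 4L,
    (body %/% 64L) %% 4L
  )
  D <- matrix(NA_integer_, n, m)
  for (j in seq_len(m)) {
    cc <- codes[, ((j - 1) * bytes_per_snp + 1):(j * bytes_per_snp)]
    cc <- as.integer(cc)[seq_len(n)]
    D[, j] <- c(2L, NA_integer_, 1L, 0L)[cc + 1L]
  }
  rownames(D) <- fam$iid
  colnames(D) <- bim$snp_id
  snps <- data.frame(
    snp_id = bim$snp_id, chrom = bim$chrom, pos = bim$pos,
    gene = NA_character_, a1 = bim$a1, a2 = bim$a2,
    stringsAsFactors = FALSE
  )
  G <- genotype_matrix(D, snps)
  if (recode == "minor") G <- .recode_to_minor(G)
  attr(G, "fam") <- fam
  G
}

# fold coded allele onto the cohort minor allele; warn about flips and
# strand-ambiguous SNPs
.recode_to_minor <- function(G) {
  af <- observed_maf(G, fold = FALSE)
  flip <- which(!is.na(af) & af > 0.5)
  if (length(flip)) {
    G$dosage[, flip] <- 2L - G$dosage[, flip]
    a1 <- G$snps$a1[flip]
    G$snps$a1[flip] <- G$snps$a2[flip]
    G$snps$a2[flip] <- a1
    warning(sprintf(
      "allele coding flipped to the cohort minor allele for %d SNP(s): %s",
      length(flip), paste(utils::head(G$snps$snp_id[flip], 5), collapse = ", ")
    ))
  }
  amb <- with(G$snps, (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "G" & a2 == "C") | (a1 == "C" & a2 == "G"))
  if (any(amb)) {
    warning(sprintf(
      "%d strand-ambiguous (A/T or G/C) SNP(s); check strand alignment",
      sum(amb)
    ))
  }
  attr(G, "coding_flips") <- G$snps$snp_id[flip]
  attr(G, "ambiguous") <- G$snps$snp_id[which(amb)]
  G
}

#' Write genotypes as an uncompressed VCF (GT field)
#'
#' REF is the major (A2) allele and ALT the minor (A1) allele, so GT allele
#' counts equal the minor-allele dosage. Missing calls are written `./.`.
#'
#' @param G a [genotype_matrix()].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_vcf <- function(G, path) {
  D <- G$dosage
  gt <- matrix("./.", nrow(D), ncol(D))
  gt[!is.na(D) & D == 0] <- "0/0"
  gt[!is.na(D) & D == 1] <- "0/1"
  gt[!is.na(D) & D == 2] <- "1/1"
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=sctassoc",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c(
      "#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
      rownames(D)
    ), collapse = "\t")
  )
  body <- vapply(seq_len(ncol(D)), function(j) {
    paste(c(
      G$snps$chrom[j], G$snps$pos[j], G$snps$snp_id[j],
      G$snps$a2[j], G$snps$a1[j], ".", "PASS", ".", "GT",
      gt[, j]
    ), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read genotypes from a VCF (GT field)
#'
#' Parses hard GT calls into ALT-allele dosages, then recodes onto the
#' cohort minor allele (flips reported as in [read_plink()]).
#'
#' @param path VCF file path.
#' @param recode `"minor"` (default) folds the coding onto the cohort minor
#'   allele; `"none"` keeps the ALT coding.
#' @return A [genotype_matrix()].
#' @export
read_vcf_genotypes <- function(path, recode = c("minor", "none")) {
  recode <- match.arg(recode)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  count_alt <- function(s) {
    out <- rep(NA_integer_, length(s))
    ok <- !is.na(s) & !s %in% c("./.", ".|.", ".")
    out[ok] <- vapply(strsplit(gsub("\\|", "/", s[ok]), "/"), function(al) {
      sum(al == "1")
    }, integer(1))
    out
  }
  # gt is variants x samples; dosage wants samples x variants
  D <- t(matrix(count_alt(as.vector(gt)), nrow = nrow(gt), ncol = ncol(gt)))
  rownames(D) <- colnames(gt)
  colnames(D) <- fix$ID
  snps <- data.frame(
    snp_id = fix$ID, chrom = fix$CHROM, pos = as.integer(fix$POS),
    gene = NA_character_, a1 = fix$ALT, a2 = fix$REF,
    stringsAsFactors = FALSE
  )
  G <- genotype_matrix(D, snps)
  if (recode == "minor") G <- .recode_to_minor(G)
  G
}

#' Read genotypes from PLINK or VCF
#'
#' @param path file path (`.vcf`) or PLINK prefix (or any of the three
#'   fileset member paths).
#' @param format `"auto"` (by extension), `"plink"` or `"vcf"`.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "plink", "vcf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "plink"
  }
  if (format == "vcf") {
    read_vcf_genotypes(path)
  } else {
    prefix <- sub("\\.(bed|bim|fam)$", "", path)
    read_plink(prefix)
  }
}

#' Select the SNPs of a gene region
#'
#' A SNP belongs to a region when its position lies inside the 1-based
#' inclusive interval on the region's chromosome, or when its id appears in
#' the region's explicit id list (which overrides the interval).
#'
#' @param G a [genotype_matrix()].
#' @param region list or one-row data frame with `gene`, `chrom`, `start`,
#'   `end` and optionally `snp_ids`.
#' @return A [genotype_matrix()] restricted to the region's SNPs, with the
#'   `gene` column set to the region label.
#' @export
select_region_snps <- function(G, region) {
  region <- as.list(region)
  if (!is.null(region$snp_ids) && length(region$snp_ids[[1]])) {
    ids <- unlist(region$snp_ids)
    keep <- G$snps$snp_id %in% ids
  } else {
    stopifnot(region$start <= region$end)
    keep <- G$snps$chrom == as.character(region$chrom) &
      G$snps$pos >= region$start & G$snps$pos <= region$end
  }
  if (!any(keep)) stop("no SNPs in region ", region$gene)
  sub <- subset_genotypes(G, snps = keep)
  sub$snps$gene <- region$gene
  sub
}
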