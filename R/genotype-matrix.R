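#' Genotype dosage matrix with SNP metadata
#'
#' Container pairing an `n x m` minor-allele dosage matrix (values 0, 1, 2 or
#' `NA` for a missing call) with a SNP metadata table. Dosages always count
#' copies of the minor allele (`a1`); the major allele is `a2`.
#'
#' @param dosage numeric or integer matrix, samples in rows, SNPs in columns.
#'   Row names are sample ids, column names SNP ids.
#' @param snps data frame with one row per SNP and at least the columns
#'   `snp_id`, `chrom`, `pos`, `gene`. Optional columns `maf` (design allele
#'   frequency), `a1` (minor allele), `a2` (major allele).
#' @return An object of class `genotype_matrix` with elements `dosage` and
#'   `snps`.
#' @export
genotype_matrix <- function(dosage, snps) {
  dosage <- as.matrix(dosage)
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  stopifnot(ncol(dosage) == nrow(snps))
  required <- c("snp_id", "chrom", "pos", "gene")
  missing_cols <- setdiff(required, names(snps))
  if (length(missing_cols)) {
    stop("snps table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(snps$snp_id)) {
    stop("snp_id must be unique within a panel")
  }
  if (is.null(colnames(dosage))) colnames(dosage) <- snps$snp_id
  if (!identical(colnames(dosage), as.character(snps$snp_id))) {
    stop("dosage column names do not match snps$snp_id")
  }
  if (is.null(rownames(dosage))) {
    rownames(dosage) <- sprintf("S%04d", seq_len(nrow(dosage)))
  }
  vals <- dosage[!is.na(dosage)]
  if (length(vals) && !all(vals %in% c(0, 1, 2))) {
    stop("dosage values must be 0, 1, 2 or NA (hard calls only)")
  }
  if (is.null(snps$a1)) snps$a1 <- "A"
  if (is.null(snps$a2)) snps$a2 <- "G"
  structure(list(dosage = dosage, snps = snps), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "<genotype_matrix> %d samples x %d SNPs (%d gene region%s), %.2f%% missing\n",
    nrow(x$dosage), ncol(x$dosage), length(unique(x$snps$gene)),
    if (length(unique(x$snps$gene)) == 1) "" else "s",
    100 * mean(is.na(x$dosage))
  ))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix by samples and/or SNPs
#'
#' @param G a [genotype_matrix()].
#' @param samples sample ids, logical mask or integer indices (default: all).
#' @param snps SNP ids, logical mask or integer indices (default: all).
#' @return A `genotype_matrix` restricted to the requested rows/columns.
#' @export
subset_genotypes <- function(G, samples = NULL, snps = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  ri <- if (is.null(samples)) seq_len(nrow(G$dosage)) else samples
  ci <- if (is.null(snps)) seq_len(ncol(G$dosage)) else snps
  if (is.character(ci)) ci <- match(ci, G$snps$snp_id)
  if (anyNA(ci)) stop("unknown snp_id in subset request")
  genotype_matrix(G$dosage[ri, ci, drop = FALSE], G$snps[ci, , drop = FALSE])
}

#' Observed minor allele frequency per SNP
#'
#' Frequency of the coded (a1) allele among non-missing calls, folded onto the
#' minor side so the result is always at most 0.5.
#'
#' @param G a [genotype_matrix()].
#' @param fold fold frequencies above 0.5 back onto the minor allele
#'   (default `TRUE`). With `fold = FALSE` the raw coded-allele frequency is
#'   returned, which is what coding-flip detection needs.
#' @return Named numeric vector of allele frequencies.
#' @export
observed_maf <- function(G, fold = TRUE) {
  af <- colMeans(G$dosage, na.rm = TRUE) / 2
  if (fold) af <- pmin(af, 1 - af)
  stats::setNames(af, G$snps$snp_id)
}
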