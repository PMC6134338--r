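#' Quality-control thresholds
#'
#' The per-sample and per-SNP thresholds of the QC cascade. Defaults follow
#' standard candidate-gene practice: samples with a genotype call rate below
#' 95% or a heterozygosity rate more than 2 SD from the sample mean are
#' removed, as are SNPs with an exact Hardy-Weinberg p below 1e-6, a minor
#' allele frequency below 1%, or a Mendelian (trio inheritance) error rate
#' above 1%. Call-rate and MAF thresholds are inclusive (values equal to the
#' threshold pass); the heterozygosity bound is exclusive (strictly outside
#' the band is removed).
#'
#' @param min_sample_call_rate minimum per-sample non-missing fraction.
#' @param het_sd_bound allowed heterozygosity deviation in SD multiples.
#' @param hwe_p_min minimum exact Hardy-Weinberg p-value.
#' @param maf_min minimum minor allele frequency.
#' @param mendel_error_max maximum per-SNP Mendelian error rate.
#' @param ld_report_r2 r-squared above which SNP pairs are counted in the LD
#'   report.
#' @return List of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_sample_call_rate = 0.95,
                          het_sd_bound = 2,
                          hwe_p_min = 1e-6,
                          maf_min = 0.01,
                          mendel_error_max = 0.01,
                          ld_report_r2 = 0.8) {
  th <- list(
    min_sample_call_rate = min_sample_call_rate,
    het_sd_bound = het_sd_bound,
    hwe_p_min = hwe_p_min,
    maf_min = maf_min,
    mendel_error_max = mendel_error_max,
    ld_report_r2 = ld_report_r2
  )
  stopifnot(
    th$min_sample_call_rate >= 0, th$min_sample_call_rate <= 1,
    th$het_sd_bound > 0, th$hwe_p_min >= 0, th$hwe_p_min <= 1,
    th$maf_min >= 0, th$maf_min <= 0.5,
    th$mendel_error_max >= 0, th$mendel_error_max <= 1,
    th$ld_report_r2 >= 0, th$ld_report_r2 <= 1
  )
  class(th) <- "qc_thresholds"
  th
}

.qc_entry <- function(filter, axis, n_removed, n_remaining, detail = "") {
  data.frame(
    filter = filter, axis = axis, n_removed = n_removed,
    n_remaining = n_remaining, detail = detail, stringsAsFactors = FALSE
  )
}

#' Remove samples with low genotype call rate
#'
#' @param G a [genotype_matrix()].
#' @param thresholds a [qc_thresholds()].
#' @return List with the filtered `geno` and a one-row `report` entry.
#' @export
sample_call_rate_filter <- function(G, thresholds = qc_thresholds()) {
  stopifnot(nrow(G$dosage) > 0)
  call_rate <- rowMeans(!is.na(G$dosage))
  keep <- call_rate >= thresholds$min_sample_call_rate
  if (!any(keep)) stop("sample call-rate filter removed every sample")
  list(
    geno = subset_genotypes(G, samples = keep),
    report = .qc_entry(
      "sample_call_rate", "samples", sum(!keep), sum(keep),
      sprintf("threshold >= %.3f", thresholds$min_sample_call_rate)
    ),
    removed = rownames(G$dosage)[!keep]
  )
}

#' Remove heterozygosity-rate outlier samples
#'
#' Per-sample heterozygous-call fraction compared against the mean +/- `k` SD
#' band computed on the input set (not iterated). Samples strictly outside
#' the band are removed.
#'
#' @inheritParams sample_call_rate_filter
#' @return List with filtered `geno` and a `report` entry.
#' @export
heterozygosity_filter <- function(G, thresholds = qc_thresholds()) {
  stopifnot(nrow(G$dosage) >= 3)
  het <- rowMeans(G$dosage == 1, na.rm = TRUE)
  mu <- mean(het)
  s <- stats::sd(het)
  if (!is.finite(s) || s == 0) {
    warning("zero variance in heterozygosity rates; no samples removed")
    keep <- rep(TRUE, length(het))
  } else {
    keep <- abs(het - mu) <= thresholds$het_sd_bound * s
  }
  if (!any(keep)) stop("heterozygosity filter removed every sample")
  list(
    geno = subset_genotypes(G, samples = keep),
    report = .qc_entry(
      "heterozygosity", "samples", sum(!keep), sum(keep),
      sprintf("band mean +/- %g SD on input set", thresholds$het_sd_bound)
    ),
    removed = rownames(G$dosage)[!keep]
  )
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test on genotype counts: given the observed allele
#' counts, the p-value is the sum of the conditional probabilities of all
#' heterozygote counts whose probability does not exceed that of the
#' observed count (no mid-p adjustment). Monomorphic SNPs return p = 1. The
#' conditional probabilities are computed by the standard stable recurrence
#' over heterozygote counts.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (minor homozygote, heterozygote,
#'   major homozygote; order does not matter).
#' @return Exact p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  stopifnot(n >= 1)
  n_minor <- 2 * min(n_AA, n_aa) + n_Aa
  if (n_minor == 0 || n_minor == 2 * n) return(1)

  # possible heterozygote counts share the parity of the minor-allele count
  h_obs <- n_Aa
  h_vals <- seq(n_minor %% 2, min(n_minor, 2 * n - n_minor), by = 2)
  # recurrence over heterozygote counts, in log space for stability:
  # P(h+2)/P(h) = 4 * nAA(h) * naa(h) / ((h+2)(h+1))
  logp <- numeric(length(h_vals))
  for (i in seq_len(length(h_vals) - 1)) {
    h <- h_vals[i]
    nAA <- (n_minor - h) / 2
    naa <- n - nAA - h
    logp[i + 1] <- logp[i] + log(4 * nAA * naa) - log((h + 2) * (h + 1))
  }
  probs <- exp(logp - max(logp))
  probs <- probs / sum(probs)
  p_obs <- probs[match(h_obs, h_vals)]
  if (is.na(p_obs)) stop("observed heterozygote count incompatible with allele counts")
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}

#' Remove SNPs failing the exact Hardy-Weinberg test
#'
#' @inheritParams sample_call_rate_filter
#' @param samples optional sample ids on which the HWE genotype counts are
#'   computed (e.g. unrelated individuals only); the filter still drops the
#'   SNP for all samples.
#' @return List with filtered `geno`, `report` entry and the per-SNP p-values.
#' @export
hwe_filter <- function(G, thresholds = qc_thresholds(), samples = NULL) {
  D <- G$dosage
  if (!is.null(samples)) D <- D[rownames(D) %in% samples, , drop = FALSE]
  p <- apply(D, 2, function(g) {
    g <- g[!is.na(g)]
    if (!length(g)) return(1)
    hwe_exact_test(sum(g == 2), sum(g == 1), sum(g == 0))
  })
  keep <- p >= thresholds$hwe_p_min
  list(
    geno = subset_genotypes(G, snps = keep),
    report = .qc_entry(
      "hwe_exact", "snps", sum(!keep), sum(keep),
      sprintf("exact p >= %g", thresholds$hwe_p_min)
    ),
    p_values = p,
    removed = G$snps$snp_id[!keep]
  )
}

#' Remove SNPs with low minor allele frequency
#'
#' MAF computed on non-missing calls of the current sample set and always
#' folded to the minor allele; SNPs with MAF greater than or equal to the
#' threshold are retained.
#'
#' @inheritParams sample_call_rate_filter
#' @return List with filtered `geno` and a `report` entry.
#' @export
maf_filter <- function(G, thresholds = qc_thresholds()) {
  maf <- observed_maf(G)
  keep <- !is.na(maf) & maf >= thresholds$maf_min
  list(
    geno = subset_genotypes(G, snps = keep),
    report = .qc_entry(
      "maf", "snps", sum(!keep), sum(keep),
      sprintf("MAF >= %g (inclusive)", thresholds$maf_min)
    ),
    removed = G$snps$snp_id[!keep]
  )
}

# is a (child, mother, father) dosage triple Mendelian-consistent?
.trio_consistent <- function(child, mother, father) {
  tm <- switch(as.character(mother), "0" = 0, "1" = c(0, 1), "2" = 1)
  tf <- switch(as.character(father), "0" = 0, "1" = c(0, 1), "2" = 1)
  child %in% outer(tm, tf, "+")
}

#' Remove SNPs with excess Mendelian errors and blank inconsistent calls
#'
#' For each SNP the error rate is the fraction of informative trios (child
#' and both parents called) whose genotypes are impossible under Mendelian
#' transmission. SNPs above the threshold are dropped; for surviving SNPs
#' the child genotype of each remaining inconsistent trio is set missing.
#'
#' @inheritParams sample_call_rate_filter
#' @param pedigree data frame with columns `child`, `mother`, `father`
#'   holding sample ids present in `G` (rows with parents absent from the
#'   matrix are ignored).
#' @return List with filtered `geno` and a `report` entry.
#' @export
mendelian_error_filter <- function(G, pedigree, thresholds = qc_thresholds()) {
  ids <- rownames(G$dosage)
  if (is.null(pedigree) || !nrow(pedigree)) {
    warning("no trios available; Mendelian filter skipped")
    return(list(
      geno = G,
      report = .qc_entry("mendelian", "snps", 0, ncol(G$dosage), "skipped: no trios"),
      removed = character()
    ))
  }
  trios <- pedigree[
    pedigree$child %in% ids & pedigree$mother %in% ids & pedigree$father %in% ids,
    , drop = FALSE
  ]
  if (!nrow(trios)) {
    warning("no complete trios in genotype matrix; Mendelian filter skipped")
    return(list(
      geno = G,
      report = .qc_entry("mendelian", "snps", 0, ncol(G$dosage), "skipped: no trios"),
      removed = character()
    ))
  }
  m <- ncol(G$dosage)
  err <- matrix(FALSE, nrow(trios), m)
  inform <- matrix(FALSE, nrow(trios), m)
  for (t in seq_len(nrow(trios))) {
    cg <- G$dosage[trios$child[t], ]
    mg <- G$dosage[trios$mother[t], ]
    fg <- G$dosage[trios$father[t], ]
    ok <- !is.na(cg) & !is.na(mg) & !is.na(fg)
    inform[t, ok] <- TRUE
    for (j in which(ok)) {
      err[t, j] <- !.trio_consistent(cg[j], mg[j], fg[j])
    }
  }
  n_inform <- colSums(inform)
  rate <- ifelse(n_inform > 0, colSums(err) / n_inform, 0)
  keep <- rate <= thresholds$mendel_error_max
  G2 <- subset_genotypes(G, snps = keep)
  # blank remaining inconsistent child genotypes
  keep_idx <- which(keep)
  for (t in seq_len(nrow(trios))) {
    bad <- which(err[t, keep_idx])
    if (length(bad)) G2$dosage[trios$child[t], bad] <- NA
  }
  list(
    geno = G2,
    report = .qc_entry(
      "mendelian", "snps", sum(!keep), sum(keep),
      sprintf(
        "error rate <= %g over %d trios; inconsistent calls blanked",
        thresholds$mendel_error_max, nrow(trios)
      )
    ),
    removed = G$snps$snp_id[!keep]
  )
}

#' Pairwise linkage disequilibrium (r-squared) within a region
#'
#' Squared Pearson correlation of dosages over pairwise-complete samples.
#' Zero-variance SNPs give `NA` for their pairs.
#'
#' @param G a [genotype_matrix()].
#' @param gene optional gene label restricting the SNP set.
#' @param ld_report_r2 threshold for the high-LD pair count.
#' @return List with the symmetric `r2` matrix and `n_pairs_above`, the
#'   number of distinct off-diagonal pairs exceeding the threshold.
#' @export
pairwise_r2 <- function(G, gene = NULL, ld_report_r2 = 0.8) {
  if (!is.null(gene)) G <- subset_genotypes(G, snps = G$snps$gene == gene)
  if (ncol(G$dosage) < 2) stop("need at least two SNPs for pairwise r2")
  r2 <- suppressWarnings(
    stats::cor(G$dosage, use = "pairwise.complete.obs")^2
  )
  diag(r2) <- 1
  up <- r2[upper.tri(r2)]
  list(r2 = r2, n_pairs_above = sum(up > ld_report_r2, na.rm = TRUE))
}

#' Run the full QC cascade
#'
#' Filters applied in order: sample call rate, heterozygosity outliers,
#' exact Hardy-Weinberg, minor allele frequency, Mendelian errors. The
#' report records per-filter removal counts and the surviving dimensions.
#' Re-running the cascade on its own output removes nothing further when the
#' input has no borderline mass inside the recomputed heterozygosity band.
#'
#' @param G a [genotype_matrix()].
#' @param pedigree optional trio pedigree for the Mendelian filter
#'   (`NULL` skips it silently when no trios exist).
#' @param thresholds a [qc_thresholds()].
#' @param hwe_samples optional ids of the (unrelated) samples on which HWE
#'   genotype counts are computed.
#' @return List of class `qc_result` with `geno` and `report`.
#' @export
run_qc <- function(G, pedigree = NULL, thresholds = qc_thresholds(),
                   hwe_samples = NULL) {
  steps <- list()
  s1 <- sample_call_rate_filter(G, thresholds)
  steps$call_rate <- s1$report
  s2 <- heterozygosity_filter(s1$geno, thresholds)
  steps$het <- s2$report
  s3 <- hwe_filter(s2$geno, thresholds, samples = hwe_samples)
  steps$hwe <- s3$report
  s4 <- maf_filter(s3$geno, thresholds)
  steps$maf <- s4$report
  if (!is.null(pedigree)) {
    s5 <- mendelian_error_filter(s4$geno, pedigree, thresholds)
  } else {
    s5 <- list(
      geno = s4$geno,
      report = .qc_entry("mendelian", "snps", 0, ncol(s4$geno$dosage),
                         "skipped: no pedigree supplied")
    )
  }
  steps$mendel <- s5$report
  report <- do.call(rbind, steps)
  rownames(report) <- NULL
  structure(
    list(
      geno = s5$geno,
      report = report,
      input_dim = dim(G$dosage),
      output_dim = dim(s5$geno$dosage),
      thresholds = thresholds,
      hwe_population = if (is.null(hwe_samples)) "all samples" else
        sprintf("%d specified (unrelated) samples", length(hwe_samples))
    ),
    class = "qc_result"
  )
}

#' @export
print.qc_result <- function(x, ...) {
  cat(sprintf(
    "<qc_result> %d x %d -> %d x %d (samples x SNPs); HWE population: %s\n",
    x$input_dim[1], x$input_dim[2], x$output_dim[1], x$output_dim[2],
    x$hwe_population
  ))
  print(x$report, row.names = FALSE)
  invisible(x)
}
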