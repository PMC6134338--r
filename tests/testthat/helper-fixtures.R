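# Deterministic fixtures used across the suite. Everything is built in code;
# no files are read.

# small SNP spec table for generator tests
tiny_panel <- function(m, maf = 0.3, gene = "GENE", prefix = "s") {
  data.frame(
    snp_id = sprintf("%s%02d", prefix, seq_len(m)),
    chrom = "1",
    pos = seq_len(m) * 1000L,
    maf = rep_len(maf, m),
    gene = gene,
    stringsAsFactors = FALSE
  )
}

make_G <- function(dosage, maf = NULL, gene = "GENE") {
  dosage <- as.matrix(dosage)
  if (is.null(colnames(dosage))) {
    colnames(dosage) <- sprintf("c%02d", seq_len(ncol(dosage)))
  }
  snps <- data.frame(
    snp_id = colnames(dosage), chrom = "1",
    pos = seq_len(ncol(dosage)) * 100L,
    gene = gene, stringsAsFactors = FALSE
  )
  if (!is.null(maf)) snps$maf <- maf
  genotype_matrix(dosage, snps)
}

# Arithmetic QC fixture with tightly controlled per-sample heterozygosity
# (counts 11/12/13 out of 60 clean SNPs), so the cascade's heterozygosity
# band is stable under re-running. `dirty = TRUE` appends one engineered
# violation per filter:
#   sample "lowcall"  - 24/64 calls missing           (call-rate filter)
#   sample "hihet"    - heterozygous at 40 clean SNPs (heterozygosity filter)
#   SNP "hwe_bad"     - every sample heterozygous     (HWE filter)
#   SNP "rare_mono"   - monomorphic (MAF 0)           (MAF filter)
#   SNP "mendel_bad"  - child 2 with 0/0 parents      (Mendelian filter)
qc_fixture <- function(dirty = FALSE) {
  n <- 60L
  m <- 60L
  D <- matrix(0L, n, m)
  for (i in seq_len(n)) {
    h <- 11L + (i %% 3L) # het count 11/12/13
    het_pos <- ((i * 7L + 0:(h - 1L)) %% m) + 1L
    hom_pos <- ((i * 7L + h + c(5L, 25L)) %% m) + 1L
    D[i, het_pos] <- 1L
    D[i, hom_pos] <- 2L
  }
  # rows 10-12 form a Mendelian-consistent trio (child S10 of S11 x S12)
  # with het counts of 12 each, inside the fixture's het band
  D[11, ] <- 0L; D[11, 1:12] <- 1L; D[11, 13:14] <- 2L # mother
  D[12, ] <- 0L; D[12, 7:18] <- 1L; D[12, 19:20] <- 2L # father
  D[10, ] <- 0L; D[10, 9:20] <- 1L # child
  ids <- sprintf("S%02d", seq_len(n))
  rownames(D) <- ids
  colnames(D) <- sprintf("c%02d", seq_len(m))
  pedigree <- data.frame(
    child = "S10", mother = "S11", father = "S12",
    stringsAsFactors = FALSE
  )
  if (!dirty) {
    return(list(geno = make_G(D), pedigree = pedigree))
  }
  lowcall <- D[1, ]
  hihet <- integer(m)
  hihet[1:40] <- 1L
  D <- rbind(D, lowcall = lowcall, hihet = hihet)
  hwe_bad <- rep(1L, nrow(D))
  rare_mono <- rep(0L, nrow(D))
  mendel_bad <- rep(0L, nrow(D))
  mendel_bad[match("S10", rownames(D))] <- 2L # child 2, parents 0/0
  D <- cbind(D, hwe_bad = hwe_bad, rare_mono = rare_mono, mendel_bad = mendel_bad)
  D["lowcall", 1:24] <- NA_integer_
  list(geno = make_G(D), pedigree = pedigree)
}

# direct log-multinomial HWE enumeration oracle, independent of the
# package's recurrence implementation
hwe_enumeration_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_minor <- 2 * min(n_AA, n_aa) + n_Aa
  if (n_minor == 0 || n_minor == 2 * n) {
    return(1)
  }
  hs <- seq(n_minor %% 2, min(n_minor, 2 * n - n_minor), by = 2)
  lp <- vapply(hs, function(h) {
    a <- (n_minor - h) / 2
    b <- n - a - h
    lfactorial(n) - lfactorial(a) - lfactorial(h) - lfactorial(b) +
      h * log(2) +
      lfactorial(n_minor) + lfactorial(2 * n - n_minor) - lfactorial(2 * n)
  }, numeric(1))
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  sum(pr[pr <= pr[match(n_Aa, hs)] * (1 + 1e-12)])
}

# one-gene null cohort (unrelated samples) for permutation calibration
null_cohort_designs <- function(n, panel, ld, spec, seed) {
  G <- generate_genotypes(panel, ld, n = n, seed = seed)
  ph <- generate_phenotypes(G, cohort_scenario(), seed = seed + 1L)
  standardize_blocks(G, ph, spec)
}
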