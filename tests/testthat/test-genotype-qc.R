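test_that("sample call-rate filter removes exactly the engineered samples", {
  D <- matrix(0L, 10, 20)
  D[, 1] <- 1L # keep a SNP polymorphic
  D[1, 2:3] <- NA_integer_ # 90% call rate
  D[2, 2:4] <- NA_integer_ # 85%
  G <- make_G(D)
  out <- sample_call_rate_filter(G)
  expect_equal(out$report$n_removed, 2)
  expect_setequal(out$removed, rownames(G$dosage)[1:2])

  clean <- sample_call_rate_filter(make_G(matrix(1L, 5, 4)))
  expect_equal(clean$report$n_removed, 0)
})

test_that("heterozygosity filter flags extreme outliers and tolerates zero variance", {
  fx <- qc_fixture()
  # add an extreme outlier: heterozygous everywhere
  D <- rbind(fx$geno$dosage, outlier = rep(1L, ncol(fx$geno$dosage)))
  out <- heterozygosity_filter(make_G(D))
  expect_equal(out$report$n_removed, 1)
  expect_equal(out$removed, "outlier")

  same <- matrix(rep(c(0L, 1L, 2L, 1L), each = 5), 5, 4)
  expect_warning(res <- heterozygosity_filter(make_G(same)), "zero variance")
  expect_equal(res$report$n_removed, 0)

  # Gaussian heterozygosity: a 2 SD band removes ~4.6% of samples
  G <- generate_genotypes(tiny_panel(200, maf = 0.5), NULL, n = 2000, seed = 7)
  res2 <- heterozygosity_filter(G)
  expect_gt(res2$report$n_removed / 2000, 0.02)
  expect_lt(res2$report$n_removed / 2000, 0.08)
})

test_that("exact HWE test matches the enumeration oracle and known cases", {
  expect_equal(hwe_exact_test(25, 50, 25), 1, tolerance = 1e-12)
  expect_lt(hwe_exact_test(0, 100, 0), 1e-6)
  expect_equal(hwe_exact_test(10, 0, 0), 1) # monomorphic

  set.seed(99)
  for (i in 1:300) {
    n <- sample(1:50, 1)
    x <- as.numeric(rmultinom(1, n, c(0.3, 0.4, 0.3)))
    expect_equal(
      hwe_exact_test(x[1], x[2], x[3]),
      hwe_enumeration_oracle(x[1], x[2], x[3]),
      tolerance = 1e-12
    )
  }
})

test_that("MAF filter uses inclusive boundary on the minor allele", {
  # 1 minor allele in 200 samples: MAF 0.0025, removed
  D <- matrix(0L, 200, 3)
  D[, 1] <- rep(c(0L, 1L, 2L, 1L), 50) # common
  D[1, 2] <- 1L # MAF 1/400
  D[1:4, 3] <- 1L # MAF 4/400 = 0.01 exactly
  out <- maf_filter(make_G(D))
  expect_equal(out$removed, "c02")
  expect_true(all(c("c01", "c03") %in% out$geno$snps$snp_id))

  # 5 engineered-rare SNPs out of 47 leave 42
  panel <- default_snp_panel()
  G <- generate_genotypes(panel, NULL, n = 400, seed = 8)
  G$dosage[, 1:5] <- 0L
  G$dosage[1, 1:5] <- 1L
  out2 <- maf_filter(G)
  expect_equal(ncol(out2$geno$dosage), 42L)
})

test_that("Mendelian filter drops bad SNPs and blanks inconsistent calls", {
  expect_false(sctassoc:::.trio_consistent(2, 0, 0))
  expect_true(sctassoc:::.trio_consistent(1, 0, 2))
  expect_false(sctassoc:::.trio_consistent(0, 2, 2))
  expect_true(sctassoc:::.trio_consistent(2, 1, 1))

  fx <- qc_fixture(dirty = TRUE)
  out <- mendelian_error_filter(fx$geno, fx$pedigree)
  expect_true("mendel_bad" %in% out$removed)

  expect_warning(
    res <- mendelian_error_filter(fx$geno, fx$pedigree[0, ]),
    "skipped"
  )
  expect_equal(res$report$n_removed, 0)
})

test_that("QC cascade removes exactly the engineered violations and is idempotent", {
  clean <- qc_fixture()
  res0 <- suppressWarnings(run_qc(clean$geno, clean$pedigree))
  expect_equal(sum(res0$report$n_removed), 0)
  expect_equal(res0$output_dim, dim(clean$geno$dosage))

  dirty <- qc_fixture(dirty = TRUE)
  res1 <- run_qc(dirty$geno, dirty$pedigree)
  counts <- setNames(res1$report$n_removed, res1$report$filter)
  expect_equal(unname(counts[c(
    "sample_call_rate", "heterozygosity", "hwe_exact", "maf", "mendelian"
  )]), c(1, 1, 1, 1, 1))
  expect_equal(res1$output_dim, c(60L, 60L))

  res2 <- run_qc(res1$geno, dirty$pedigree)
  expect_equal(sum(res2$report$n_removed), 0)
  expect_identical(res2$geno$dosage, res1$geno$dosage)
})

test_that("pairwise r2 is symmetric, permutation-invariant and matches direct computation", {
  G <- generate_genotypes(tiny_panel(4, maf = 0.4), NULL, n = 500, seed = 9)
  G$dosage[, 4] <- G$dosage[, 3] # duplicated SNP
  out <- pairwise_r2(G)
  expect_equal(out$r2[3, 4], 1, tolerance = 1e-12)
  expect_equal(out$r2, t(out$r2))

  direct <- cor(G$dosage)^2
  expect_equal(out$r2, direct, tolerance = 1e-12)

  perm <- sample(nrow(G$dosage))
  Gp <- subset_genotypes(G, samples = perm)
  expect_equal(pairwise_r2(Gp)$r2, out$r2, tolerance = 1e-12)

  # independent SNPs: off-diagonal r2 near zero
  G0 <- generate_genotypes(tiny_panel(5, maf = 0.3), NULL, n = 10000, seed = 10)
  r2 <- pairwise_r2(G0)$r2
  expect_lt(max(r2[upper.tri(r2)]), 0.01)

  # zero-variance SNP yields NA pairs
  G$dosage[, 1] <- 0L
  rz <- pairwise_r2(G)
  expect_true(all(is.na(rz$r2[1, -1])))
})
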