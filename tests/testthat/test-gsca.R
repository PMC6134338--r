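# helper: one-gene-block spec over given ids
one_block_spec <- function(ids, pheno = "y1", alpha = c(G1 = 0.05)) {
  gsca_spec(
    gene_blocks = list(G1 = ids), phenotype_block = pheno,
    alpha_sequence = alpha
  )
}

test_that("single-indicator GSCA collapses to the Pearson correlation", {
  set.seed(1)
  n <- 300
  g <- rbinom(n, 2, 0.3)
  y <- 0.4 * scale(g) + rnorm(n)
  G <- make_G(matrix(g, ncol = 1, dimnames = list(NULL, "s01")))
  ph <- data.frame(sample_id = rownames(G$dosage), y1 = as.numeric(y))
  spec <- one_block_spec("s01")
  d <- standardize_blocks(G, ph, spec)
  m <- fit_gsca(spec, d)
  expect_equal(unname(m$a_g), cor(g, as.numeric(y)), tolerance = 1e-10)
})

test_that("two single-SNP components reproduce the OLS coefficients", {
  set.seed(2)
  n <- 1000
  g1 <- rbinom(n, 2, 0.4)
  g2 <- rbinom(n, 2, 0.25)
  y <- 0.3 * scale(g1) - 0.2 * scale(g2) + rnorm(n)
  G <- make_G(cbind(s01 = g1, s02 = g2))
  G$snps$gene <- c("A", "B")
  ph <- data.frame(sample_id = rownames(G$dosage), y1 = as.numeric(y))
  spec <- gsca_spec(
    gene_blocks = list(A = "s01", B = "s02"), phenotype_block = "y1",
    alpha_sequence = c(A = 0.05, B = 0.025)
  )
  d <- standardize_blocks(G, ph, spec)
  m <- fit_gsca(spec, d)
  oracle <- coef(lm(scale(y) ~ 0 + scale(g1) + scale(g2)))
  # lm standardizes with the same n-1 convention, so coefficients match
  expect_equal(unname(m$a_g), unname(oracle), tolerance = 1e-6)
})

test_that("an injected gene-to-factor path of 0.3 is recovered at n = 2000", {
  set.seed(3)
  n <- 2000
  panel <- tiny_panel(10, maf = 0.3)
  G <- generate_genotypes(panel, NULL, n = n, seed = 30)
  comp <- as.numeric(scale(rowSums(scale(G$dosage))))
  latent <- 0.3 * comp + sqrt(1 - 0.09) * rnorm(n)
  lam <- default_phenotype_loadings()
  P <- sapply(lam, function(l) l * latent + sqrt(1 - l^2) * rnorm(n))
  ph <- data.frame(sample_id = rownames(G$dosage), P)
  spec <- gsca_spec(
    gene_blocks = list(GENE = panel$snp_id),
    phenotype_block = names(lam),
    alpha_sequence = c(GENE = 0.05)
  )
  m <- fit_gsca(spec, standardize_blocks(G, ph, spec))
  expect_lt(abs(unname(m$a_g) - 0.3), 0.05)
})

test_that("the ALS criterion is monotone non-increasing and components have unit variance", {
  panel <- default_snp_panel()
  for (seed in 1:3) {
    G <- generate_genotypes(panel, default_ld(panel), n = 150, seed = seed)
    ph <- generate_phenotypes(G, cohort_scenario(), seed = seed + 50)
    spec <- gsca_spec_from_panel(panel)
    d <- standardize_blocks(G, ph, spec)
    m <- fit_gsca(spec, d)
    expect_true(all(diff(m$criterion_trace) <= 1e-10))
    # unit variance of each fitted component
    for (g in names(m$W_g)) {
      comp <- d$Z[[g]] %*% m$W_g[[g]]
      expect_equal(as.numeric(var(comp)), 1, tolerance = 1e-8)
    }
    f <- d$P %*% m$v
    expect_equal(as.numeric(var(f)), 1, tolerance = 1e-8)
  }
})

test_that("standardize_blocks imputes, standardizes and drops degenerate columns", {
  set.seed(4)
  D <- cbind(
    s01 = rbinom(100, 2, 0.4),
    s02 = rep(1L, 100), # constant: dropped
    s03 = rbinom(100, 2, 0.3)
  )
  D[1:10, 3] <- NA_integer_
  G <- make_G(D)
  ph <- data.frame(
    sample_id = rownames(G$dosage),
    y1 = rnorm(100), y2 = rnorm(100), y3 = rnorm(100)
  )
  ph$y1[5] <- NA # complete-case exclusion
  spec <- gsca_spec(
    gene_blocks = list(G1 = c("s01", "s02", "s03")),
    phenotype_block = c("y1", "y2", "y3"),
    alpha_sequence = c(G1 = 0.05)
  )
  expect_warning(d <- standardize_blocks(G, ph, spec), "zero-variance")
  expect_equal(d$n, 99L)
  expect_equal(colnames(d$Z$G1), c("s01", "s03"))
  expect_equal(as.numeric(apply(d$Z$G1, 2, sd)), c(1, 1), tolerance = 1e-12)
  expect_equal(as.numeric(colMeans(d$Z$G1)), c(0, 0), tolerance = 1e-12)
})

test_that("permutation p-values are deterministic, valid at the extreme, and flag-stable", {
  set.seed(5)
  n <- 120
  g <- rbinom(n, 2, 0.3)
  G <- make_G(matrix(g, ncol = 1, dimnames = list(NULL, "s01")))
  # phenotype duplicated from the gene component: perfect association
  ph <- data.frame(sample_id = rownames(G$dosage), y1 = as.numeric(scale(g)))
  spec <- one_block_spec("s01")
  d <- standardize_blocks(G, ph, spec)
  res <- permutation_test(spec, d, B = 4999, seed = 6)
  expect_equal(unname(res$p_value), 1 / 5000)

  res2 <- permutation_test(spec, d, B = 499, seed = 7)
  res3 <- permutation_test(spec, d, B = 499, seed = 7)
  expect_identical(res2$null_draws, res3$null_draws)
  expect_warning(permutation_test(spec, d, B = 50, seed = 1), "unstable")
})

test_that("results are invariant to SNP relabeling and indicator sign flips", {
  panel <- tiny_panel(6, maf = 0.3)
  G <- generate_genotypes(panel, NULL, n = 200, seed = 8)
  ph <- generate_phenotypes(G, cohort_scenario(), seed = 9)
  spec <- gsca_spec(
    gene_blocks = list(GENE = panel$snp_id),
    alpha_sequence = c(GENE = 0.05)
  )
  d <- standardize_blocks(G, ph, spec)
  res <- permutation_test(spec, d, B = 199, seed = 10)

  # relabel (reorder) SNPs within the block
  perm_ids <- rev(panel$snp_id)
  spec_r <- gsca_spec(
    gene_blocks = list(GENE = perm_ids),
    alpha_sequence = c(GENE = 0.05)
  )
  d_r <- standardize_blocks(G, ph, spec_r)
  res_r <- permutation_test(spec_r, d_r, B = 199, seed = 10)
  expect_equal(res$p_value, res_r$p_value, tolerance = 1e-10)
  expect_equal(abs(unname(res$a_obs)), abs(unname(res_r$a_obs)), tolerance = 1e-8)

  # flip the allele coding of one indicator
  G2 <- G
  G2$dosage[, 3] <- 2L - G2$dosage[, 3]
  d_f <- standardize_blocks(G2, ph, spec)
  res_f <- permutation_test(spec, d_f, B = 199, seed = 10)
  expect_equal(res$p_value, res_f$p_value, tolerance = 1e-10)
  expect_equal(
    abs(unname(res$model$W_g$GENE[3])),
    abs(unname(res_f$model$W_g$GENE[3])),
    tolerance = 1e-8
  )
})

test_that("sequential alpha rule reproduces the registered decisions", {
  fake <- function(p) {
    structure(list(p_value = p), class = "gsca_permutation")
  }
  seqd <- function(p) {
    sequential_alpha_decision(fake(p), c(CNTNAP2 = 0.05, NRXN1 = 0.025))
  }
  # the reported SCT pattern: both non-significant
  d1 <- seqd(c(CNTNAP2 = 0.268, NRXN1 = 0.703))
  expect_false(any(d1$significant))
  d2 <- seqd(c(CNTNAP2 = 0.04, NRXN1 = 0.02))
  expect_true(all(d2$significant))
  d3 <- seqd(c(CNTNAP2 = 0.04, NRXN1 = 0.03))
  expect_equal(d3$significant, c(TRUE, FALSE))
  expect_error(
    sequential_alpha_decision(fake(c(CNTNAP2 = 0.5)), c(CNTNAP2 = 0.05, NRXN1 = 0.025)),
    "no p-value"
  )
})

test_that("group analyses respect the subgroup filter arithmetic", {
  co <- simulate_cohort(cohort_scenario(), seed = 11)
  spec <- gsca_spec_from_panel(co$panel)
  tab <- suppressWarnings(run_group_analyses(
    co, spec,
    B = 99, seed = 12, min_n = 20
  ))
  expect_setequal(
    unique(tab$group[!grepl("^SCT_", tab$group)]),
    c("SCT", "Twin1", "Twin2")
  )
  # karyotype subgroup sizes = prenatally identified cases per karyotype
  pre <- co$design[co$design$group == "SCT" & co$design$ascertainment == "prenatal", ]
  for (k in unique(pre$karyotype)) {
    nk <- sum(pre$karyotype == k)
    if (nk >= 20) {
      rows <- tab[tab$group == paste0("SCT_", k, "_prenatal"), ]
      expect_equal(unique(rows$n), nk)
    }
  }
  expect_true(all(tab$p_value >= 1 / 100 & tab$p_value <= 1))
})
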