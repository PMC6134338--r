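test_that("per-SNP regression matches the closed-form OLS oracle", {
  # small fixture, printed in full
  dosage <- c(0, 1, 2, 0, 1, 2, 0, 1, 2, 0, 1, 2)
  pheno <- c(9.8, 10.5, 12.1, 8.9, 10.2, 11.0, 9.5, 10.9, 12.5, 9.1, 9.9, 11.8)
  res <- snp_regression(dosage, pheno, snp_id = "rs_test")

  # independent oracle: closed-form least squares on z-scores
  zx <- (dosage - mean(dosage)) / sd(dosage)
  zy <- (pheno - mean(pheno)) / sd(pheno)
  b <- sum(zx * zy) / sum(zx^2)
  rss <- sum((zy - b * zx)^2)
  se <- sqrt(rss / 10 / sum(zx^2))
  expect_equal(res$slope, b, tolerance = 1e-12)
  expect_equal(res$se, se, tolerance = 1e-12)
  expect_equal(res$p_value, 2 * pt(-abs(b / se), 10), tolerance = 1e-12)
  means <- attr(res, "dosage_means")
  expect_equal(means$n, c(4, 4, 4))

  # phenotype identical to dosage: unit slope, p at the floor
  res2 <- snp_regression(rep(0:2, 20), rep(0:2, 20))
  expect_equal(res2$slope, 1, tolerance = 1e-12)
  expect_lt(res2$p_value, 1e-100)

  # null at scale
  set.seed(1)
  res3 <- snp_regression(rbinom(10000, 2, 0.3), rnorm(10000))
  expect_lt(abs(res3$slope), 0.05)

  # monomorphic SNP untestable
  res4 <- snp_regression(rep(0, 50), rnorm(50))
  expect_true(res4$untestable)

  # allele-coding flip: slope negates, p unchanged
  set.seed(2)
  g <- rbinom(500, 2, 0.4)
  y <- 0.2 * g + rnorm(500)
  a <- snp_regression(g, y)
  bflip <- snp_regression(2 - g, y)
  expect_equal(a$slope, -bflip$slope, tolerance = 1e-12)
  expect_equal(a$p_value, bflip$p_value, tolerance = 1e-12)
})

test_that("p-value uniformity diagnostic reports deciles and departures", {
  even <- seq(0.05, 0.95, by = 0.1)
  out <- pvalue_uniformity_check(even)
  expect_equal(out$decile_counts, rep(1L, 10))
  expect_false(out$departure)

  skew <- runif(100, 0, 0.01)
  out2 <- pvalue_uniformity_check(skew)
  expect_true(out2$departure)

  expect_error(pvalue_uniformity_check(c(0.5, 0.6)), "at least 10")
})

test_that("burden score follows its carrier-proportion definition", {
  # 5 rare sites; the first sample carries minor alleles at 2 of them
  D <- matrix(0L, 200, 5)
  D[1, 1:2] <- 1L
  D[2, 3] <- 1L
  D[3, 4] <- 1L
  D[4, 5] <- 1L
  G <- make_G(D)
  maf <- observed_maf(G)
  expect_true(all(maf < 0.01 & maf > 0))
  carrier <- rowMeans(D >= 1)
  expect_equal(carrier[1], 0.4)

  set.seed(3)
  y <- rnorm(200)
  res <- burden_test_zeggini(G, y)
  expect_equal(res$n_variants, 5L)
  expect_false(res$untestable)

  # constant burden: untestable
  res0 <- burden_test_zeggini(make_G(matrix(0L, 50, 3)), rnorm(50))
  expect_true(res0$untestable)
})

test_that("a causal rare variant gives the burden test real power", {
  reps <- 30
  p_eff <- p_null <- numeric(reps)
  for (r in seq_len(reps)) {
    set.seed(100 + r)
    n <- 2000
    D <- matrix(rbinom(n * 6, 2, 0.004), n, 6)
    G <- make_G(D)
    carrier <- D[, 1] >= 1
    y_eff <- 0.5 * carrier + rnorm(n)
    y_null <- rnorm(n)
    p_eff[r] <- burden_test_zeggini(G, y_eff)$p_value
    p_null[r] <- burden_test_zeggini(G, y_null)$p_value
  }
  expect_gt(mean(p_eff < 0.05, na.rm = TRUE), mean(p_null < 0.05, na.rm = TRUE))
  expect_lt(median(p_eff, na.rm = TRUE), median(p_null, na.rm = TRUE))
})

test_that("single-variant SKAT equals the closed-form score test", {
  set.seed(4)
  for (r in 1:5) {
    n <- 200 + 50 * r
    g <- rbinom(n, 2, 0.3)
    y <- 0.1 * g + rnorm(n)
    G <- make_G(matrix(g, ncol = 1))
    res <- skat_test(G, y, weights_scheme = "flat")
    gc <- g - mean(g)
    rr <- y - mean(y)
    chi <- sum(gc * rr)^2 / ((sum(rr^2) / (n - 1)) * sum(gc^2))
    expect_equal(res$p_value, pchisq(chi, 1, lower.tail = FALSE), tolerance = 1e-12)
  }
})

test_that("moment-matching and Imhof inversion agree on chi-square mixtures", {
  set.seed(5)
  for (r in 1:5) {
    D <- matrix(rbinom(400 * 15, 2, runif(15, 0.05, 0.45)), 400, 15, byrow = TRUE)
    y <- rnorm(400)
    G <- make_G(D)
    p_liu <- skat_test(G, y, method = "liu")$p_value
    p_imhof <- skat_test(G, y, method = "imhof")$p_value
    # moment matching is tightest in the tails; mid-distribution agreement
    # with the exact inversion is looser
    expect_lt(abs(p_liu - p_imhof), 0.05)
  }
})

test_that("variance-component test beats burden under mixed-sign effects", {
  reps <- 25
  wins <- 0
  for (r in seq_len(reps)) {
    set.seed(200 + r)
    n <- 800
    m <- 10
    D <- matrix(rbinom(n * m, 2, 0.05), n, m)
    beta <- rep(c(0.25, -0.25), length.out = m)
    y <- as.numeric(D %*% beta) + rnorm(n)
    G <- make_G(D)
    p_skat <- skat_test(G, y, weights_scheme = "flat")$p_value
    p_burden <- burden_test_zeggini(G, y, maf_max = 0.5)$p_value
    if (!is.na(p_skat) && !is.na(p_burden) && p_skat < p_burden) wins <- wins + 1
  }
  expect_gt(wins / reps, 0.6)
})

test_that("Bonferroni threshold reproduces the registered value", {
  bt <- bonferroni_threshold(0.05, 47, 3)
  expect_equal(bt$threshold, 0.05 / 141, tolerance = 1e-15)
  expect_equal(bt$display, 0.00035)
  expect_equal(bonferroni_threshold(0.05, 1, 1)$threshold, 0.05)
  expect_equal(bonferroni_threshold(0.01, 10, 1)$threshold, 0.001)
})
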