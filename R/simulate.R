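#' Cohort simulation scenario
#'
#' Bundles every knob of the synthetic-cohort generator. Defaults reproduce
#' the design of the study the pipeline targets: 130 sex-chromosome-trisomy
#' (SCT) children of whom 59 came to attention because of developmental
#' problems (phenotype-ascertained, mean shift -0.9 SD on the language
#' measure), a comparison sample of 185 twin pairs (about one third MZ), and
#' three observed outcome measures loading on one latent neurodevelopmental
#' factor so that their pairwise correlations are 0.76, 0.60 and 0.69.
#'
#' @param n_sct number of SCT cases.
#' @param n_twin_pairs number of twin pairs in the comparison sample.
#' @param frac_postnatal proportion of SCT cases ascertained via phenotype
#'   (the "postnatal" route). Default 59/130.
#' @param ascertainment_shift target mean shift (SD units, positive number)
#'   of the ascertained subgroup below the unascertained subgroup.
#' @param karyotype_mix named proportions for XXX/XXY/XYY; default 42:43:45.
#' @param zygosity_mix named proportions for MZ/DZ twin pairs.
#' @param phenotype_loadings loadings of the three observed measures
#'   (nonword repetition, language factor, global burden) on the latent
#'   factor. The default is the exact solution of
#'   `l1*l2 = 0.76, l1*l3 = 0.60, l2*l3 = 0.69`, so the generated measures
#'   reproduce that correlation pattern in expectation.
#' @param battery_loadings loadings of the four language subtests on the
#'   language measure's true score.
#' @param gene_effect standardized path from the causal gene component to the
#'   latent factor; 0 under the null.
#' @param sct_multiplier factor amplifying `gene_effect` in the SCT group
#'   (the double-hit injection); 1 leaves SCT and twins identical.
#' @param causal_gene gene label whose SNP block carries the effect.
#' @param ascertain_on phenotype column used for truncation ascertainment;
#'   the study shifted the language factor, so that is the default.
#' @param missing_geno_rate,missing_pheno_rate optional missing-data rates
#'   injected completely at random; default 0.
#' @return A validated list of class `cohort_scenario`.
#' @export
cohort_scenario <- function(n_sct = 130L,
                            n_twin_pairs = 185L,
                            frac_postnatal = 59 / 130,
                            ascertainment_shift = 0.9,
                            karyotype_mix = c(XXX = 42, XXY = 43, XYY = 45) / 130,
                            zygosity_mix = c(MZ = 1 / 3, DZ = 2 / 3),
                            phenotype_loadings = default_phenotype_loadings(),
                            battery_loadings = c(
                              verbal_comprehension = 0.85,
                              oromotor_sequences = 0.75,
                              sentence_repetition = 0.80,
                              vocabulary = 0.80
                            ),
                            gene_effect = 0,
                            sct_multiplier = 1,
                            causal_gene = "CNTNAP2",
                            ascertain_on = "language_factor",
                            missing_geno_rate = 0,
                            missing_pheno_rate = 0) {
  sc <- list(
    n_sct = as.integer(n_sct), n_twin_pairs = as.integer(n_twin_pairs),
    frac_postnatal = frac_postnatal,
    ascertainment_shift = ascertainment_shift,
    karyotype_mix = karyotype_mix, zygosity_mix = zygosity_mix,
    phenotype_loadings = phenotype_loadings,
    battery_loadings = battery_loadings,
    gene_effect = gene_effect, sct_multiplier = sct_multiplier,
    causal_gene = causal_gene, ascertain_on = ascertain_on,
    missing_geno_rate = missing_geno_rate,
    missing_pheno_rate = missing_pheno_rate
  )
  stopifnot(
    sc$n_sct >= 0, sc$n_twin_pairs >= 0,
    sc$frac_postnatal >= 0, sc$frac_postnatal <= 1,
    sc$ascertainment_shift >= 0,
    all(sc$karyotype_mix >= 0), all(sc$zygosity_mix >= 0),
    sc$missing_geno_rate >= 0, sc$missing_geno_rate < 1,
    sc$missing_pheno_rate >= 0, sc$missing_pheno_rate < 1
  )
  if (abs(sum(sc$karyotype_mix) - 1) > 1e-8) stop("karyotype_mix must sum to 1")
  if (abs(sum(sc$zygosity_mix) - 1) > 1e-8) stop("zygosity_mix must sum to 1")
  if (any(abs(sc$phenotype_loadings) >= 1)) {
    stop("phenotype loadings must lie in (-1, 1)")
  }
  if (any(abs(sc$battery_loadings) >= 1)) {
    stop("battery loadings must lie in (-1, 1)")
  }
  if (abs(sc$gene_effect) >= 1) stop("gene_effect must lie in (-1, 1)")
  if (abs(sc$gene_effect * sc$sct_multiplier) >= 1) {
    stop("gene_effect * sct_multiplier must lie in (-1, 1)")
  }
  class(sc) <- "cohort_scenario"
  sc
}

#' Default loadings reproducing the observed phenotype correlations
#'
#' Closed-form one-factor loadings for three indicators with target pairwise
#' correlations r12 = 0.76 (nonword repetition vs language factor), r13 =
#' 0.60 (nonword repetition vs global burden) and r23 = 0.69 (language
#' factor vs global burden): `l1 = sqrt(r12 * r13 / r23)` etc.
#'
#' @param r12,r13,r23 target correlations.
#' @return Named numeric vector of three loadings.
#' @export
default_phenotype_loadings <- function(r12 = 0.76, r13 = 0.60, r23 = 0.69) {
  l1 <- sqrt(r12 * r13 / r23)
  c(
    nonword_repetition = l1,
    language_factor = r12 / l1,
    global_burden = r13 / l1
  )
}

# cache of calibrated latent correlations, keyed on (r, p1, p2)
.latent_rho_cache <- new.env(parent = emptyenv())

# P(Z1 < t1, Z2 < t2) for standard bivariate normal with correlation rho
.binorm_lower <- function(t1, t2, rho) {
  if (abs(rho) < 1e-12) return(stats::pnorm(t1) * stats::pnorm(t2))
  s <- sqrt(1 - rho^2)
  stats::integrate(
    function(z) stats::dnorm(z) * stats::pnorm((t2 - rho * z) / s),
    -Inf, t1, rel.tol = 1e-10
  )$value
}

# correlation between two binary allele indicators induced by latent rho
.allele_corr <- function(rho, p1, p2) {
  t1 <- stats::qnorm(p1)
  t2 <- stats::qnorm(p2)
  (.binorm_lower(t1, t2, rho) - p1 * p2) /
    sqrt(p1 * (1 - p1) * p2 * (1 - p2))
}

# latent Gaussian correlation giving allele (and hence dosage) correlation r
.calibrate_latent_rho <- function(r, p1, p2) {
  if (r == 0) return(0)
  key <- sprintf("%.6f|%.6f|%.6f", r, min(p1, p2), max(p1, p2))
  hit <- .latent_rho_cache[[key]]
  if (!is.null(hit)) return(hit)
  upper <- 0.99995
  if (.allele_corr(upper, p1, p2) < r) {
    warning(sprintf(
      "target r = %.3f unattainable for allele frequencies %.3f / %.3f; clamping",
      r, p1, p2
    ))
    rho <- upper
  } else {
    rho <- stats::uniroot(
      function(x) .allele_corr(x, p1, p2) - r,
      lower = max(r - 0.2, 0), upper = upper, tol = 1e-8
    )$root
  }
  .latent_rho_cache[[key]] <- rho
  rho
}

# latent correlation matrix for a panel + target r2 matrix; errors if the
# calibrated matrix is materially non-PSD, clips numerically tiny negatives
.latent_corr_matrix <- function(specs, ld) {
  m <- nrow(specs)
  if (is.null(ld)) return(list(R = diag(m), factor = diag(m)))
  ld <- as.matrix(ld)
  stopifnot(nrow(ld) == m, ncol(ld) == m)
  if (max(abs(ld - t(ld))) > 1e-8) stop("target r2 matrix must be symmetric")
  if (any(ld < 0 | ld > 1)) stop("target r2 values must lie in [0, 1]")
  R <- diag(m)
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      if (ld[i, j] > 0) {
        R[i, j] <- R[j, i] <- .calibrate_latent_rho(
          sqrt(ld[i, j]), specs$maf[i], specs$maf[j]
        )
      }
    }
  }
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) < -1e-6) {
    stop(sprintf(
      "target LD matrix is infeasible: latent correlation matrix is not positive semi-definite (min eigenvalue %.3g)",
      min(e$values)
    ))
  }
  list(R = R, factor = e$vectors %*% diag(sqrt(pmax(e$values, 0)), m))
}

# draw n_hap binary haplotypes under the Gaussian-copula LD model
.draw_haplotypes <- function(n_hap, specs, factor_mat) {
  m <- nrow(specs)
  Z <- matrix(stats::rnorm(n_hap * m), n_hap, m) %*% t(factor_mat)
  H <- matrix(0L, n_hap, m)
  thr <- stats::qnorm(specs$maf)
  for (j in seq_len(m)) H[, j] <- as.integer(Z[, j] < thr[j])
  H
}

.check_specs <- function(specs) {
  specs <- as.data.frame(specs, stringsAsFactors = FALSE)
  stopifnot(nrow(specs) >= 1)
  if (is.null(specs$maf)) stop("SNP specs need a maf column")
  if (any(specs$maf <= 0 | specs$maf > 0.5)) stop("maf must lie in (0, 0.5]")
  if (anyDuplicated(specs$snp_id)) stop("snp_id must be unique")
  specs
}

#' Simulate unrelated genotypes with block LD
#'
#' Haplotype-level Gaussian copula generator: each haplotype is a vector of
#' allele indicators obtained by thresholding a latent multivariate normal at
#' the allele-frequency quantile, and a genotype is the sum of two
#' independent haplotypes. Hardy-Weinberg equilibrium therefore holds exactly
#' at generation, and the dosage correlation between two SNPs equals their
#' allele-indicator correlation, which is calibrated numerically so the
#' realized r-squared matches `ld` without thresholding attenuation.
#'
#' @param specs SNP spec table (`snp_id`, `maf`, plus metadata columns).
#' @param ld target r-squared matrix (`NULL` for linkage equilibrium).
#' @param n number of individuals (`>= 2`).
#' @param seed RNG seed; the draw is exactly reproducible given
#'   `(specs, ld, n, seed)`.
#' @return A [genotype_matrix()].
#' @export
generate_genotypes <- function(specs, ld = NULL, n, seed = 1L) {
  specs <- .check_specs(specs)
  stopifnot(n >= 2)
  lat <- .latent_corr_matrix(specs, ld)
  set.seed(seed)
  H <- .draw_haplotypes(2L * n, specs, lat$factor)
  dosage <- H[seq(1, 2 * n, by = 2), , drop = FALSE] +
    H[seq(2, 2 * n, by = 2), , drop = FALSE]
  rownames(dosage) <- sprintf("S%05d", seq_len(n))
  colnames(dosage) <- specs$snp_id
  if (is.null(specs$chrom)) specs$chrom <- "1"
  if (is.null(specs$pos)) specs$pos <- seq_len(nrow(specs))
  if (is.null(specs$gene)) specs$gene <- "GENE"
  genotype_matrix(dosage, specs)
}

#' Simulate phenotypes from a latent-factor generative model
#'
#' The latent neurodevelopmental factor is
#' `latent = effect * gene_component + sqrt(1 - effect^2) * e`, where the
#' gene component is the standardized equal-weight sum of the standardized
#' dosages in the causal gene's block and
#' `effect = gene_effect * effect_multiplier`. Each observed measure is
#' `loading * latent + sqrt(1 - loading^2) * noise`; all three measures
#' (including the global burden index) are emitted already oriented so that a
#' low score means impairment. Nonword repetition is reported on the
#' scaled-score metric (mean 10, SD 3); the other measures are z-scores.
#' Four language subtests are additionally generated from the language
#' measure's value, for use by the factor-construction stage.
#'
#' @param G a [genotype_matrix()] for the cohort.
#' @param scenario a [cohort_scenario()].
#' @param seed RNG seed.
#' @param effect_multiplier multiplier applied to `gene_effect` (used by the
#'   cohort builder to amplify the effect in the SCT group).
#' @return Data frame with the three outcome measures, the four subtests and
#'   the simulation-truth columns `latent_neurodev` and `gene_component`.
#' @export
generate_phenotypes <- function(G, scenario, seed = 1L, effect_multiplier = 1) {
  stopifnot(inherits(G, "genotype_matrix"), inherits(scenario, "cohort_scenario"))
  n <- nrow(G$dosage)
  effect <- scenario$gene_effect * effect_multiplier
  if (abs(effect) >= 1) stop("effective gene effect must lie in (-1, 1)")
  lam <- scenario$phenotype_loadings
  if (any(abs(lam) >= 1)) stop("phenotype loadings must lie in (-1, 1)")

  set.seed(seed)
  cols <- which(G$snps$gene == scenario$causal_gene)
  comp <- rep(0, n)
  if (length(cols)) {
    X <- G$dosage[, cols, drop = FALSE]
    sds <- apply(X, 2, stats::sd, na.rm = TRUE)
    keep <- which(is.finite(sds) & sds > 0)
    if (length(keep)) {
      Xs <- scale(X[, keep, drop = FALSE])
      Xs[is.na(Xs)] <- 0
      raw <- rowSums(Xs)
      if (stats::sd(raw) > 0) comp <- as.numeric(scale(raw))
    }
  }
  latent <- effect * comp + sqrt(1 - effect^2) * stats::rnorm(n)

  measure <- sapply(names(lam), function(nm) {
    lam[[nm]] * latent + sqrt(1 - lam[[nm]]^2) * stats::rnorm(n)
  })
  gam <- scenario$battery_loadings
  battery <- sapply(names(gam), function(nm) {
    gam[[nm]] * measure[, "language_factor"] +
      sqrt(1 - gam[[nm]]^2) * stats::rnorm(n)
  })

  pheno <- data.frame(
    sample_id = rownames(G$dosage),
    nonword_repetition = 10 + 3 * measure[, "nonword_repetition"],
    language_factor = measure[, "language_factor"],
    global_burden = measure[, "global_burden"],
    battery,
    latent_neurodev = latent,
    gene_component = comp,
    stringsAsFactors = FALSE
  )
  if (scenario$missing_pheno_rate > 0) {
    mcols <- c(
      "nonword_repetition", "language_factor", "global_burden",
      names(gam)
    )
    for (cc in mcols) {
      drop <- stats::runif(n) < scenario$missing_pheno_rate
      pheno[[cc]][drop] <- NA
    }
  }
  rownames(pheno) <- NULL
  pheno
}

# truncation threshold c with E[Z | Z < c] = -shift for Z ~ N(0,1)
.truncation_threshold <- function(shift) {
  if (shift <= 0) return(Inf)
  stats::uniroot(
    function(c) stats::dnorm(c) / stats::pnorm(c) - shift,
    lower = -8, upper = 8, tol = 1e-10
  )$root
}

# deterministic integer quotas for a proportion vector
.quota_counts <- function(n, mix) {
  counts <- diff(c(0, round(cumsum(mix) * n)))
  stats::setNames(as.integer(counts), names(mix))
}

#' Select an SCT cohort from a candidate pool under phenotype ascertainment
#'
#' Treats the rows of `pheno` as a pool of exchangeable SCT candidates and
#' selects `scenario$n_sct` of them: a fraction `frac_postnatal` by
#' truncation sampling (uniformly among candidates whose standardized
#' ascertainment measure falls below the threshold `c` at which the
#' truncated-normal mean equals `-ascertainment_shift`), the rest uniformly
#' from the remaining pool. Karyotypes are assigned by quota from
#' `karyotype_mix`.
#'
#' @param pheno candidate phenotype table (as from [generate_phenotypes()]);
#'   must have at least `n_sct` rows, and comfortably more when
#'   `frac_postnatal > 0` so enough low-phenotype candidates exist.
#' @param scenario a [cohort_scenario()].
#' @param seed RNG seed.
#' @return List with `pheno` (selected rows), `design` (sample_id, group,
#'   karyotype, ascertainment) and `index` (selected pool rows, so callers
#'   can subset the matching genotypes).
#' @export
apply_ascertainment <- function(pheno, scenario, seed = 1L) {
  stopifnot(inherits(scenario, "cohort_scenario"))
  n_pool <- nrow(pheno)
  n_sct <- scenario$n_sct
  if (n_pool < n_sct) stop("candidate pool smaller than n_sct")
  measure <- pheno[[scenario$ascertain_on]]
  if (is.null(measure)) stop("ascertainment measure not found: ", scenario$ascertain_on)
  z <- as.numeric(scale(measure))

  set.seed(seed)
  n_post <- round(scenario$frac_postnatal * n_sct)
  # draw the representative (prenatal) subgroup first so the truncation
  # sample comes from an undepleted pool and both subgroup means hit their
  # targets (prenatal ~ 0, postnatal ~ -shift)
  pre_idx <- sample.int(n_pool, n_sct - n_post)
  remaining <- setdiff(seq_len(n_pool), pre_idx)
  if (n_post > 0 && scenario$ascertainment_shift > 0) {
    cthr <- .truncation_threshold(scenario$ascertainment_shift)
    eligible <- remaining[z[remaining] < cthr]
    if (length(eligible) < n_post) {
      stop(sprintf(
        "candidate pool has only %d candidates below the truncation threshold (%d needed); enlarge the pool",
        length(eligible), n_post
      ))
    }
    post_idx <- sample(eligible, n_post)
  } else {
    post_idx <- sample(remaining, n_post)
  }
  idx <- c(post_idx, pre_idx)

  karyo <- sample(rep(names(scenario$karyotype_mix),
                      times = .quota_counts(n_sct, scenario$karyotype_mix)))
  design <- data.frame(
    sample_id = pheno$sample_id[idx],
    group = "SCT",
    karyotype = karyo,
    ascertainment = rep(c("postnatal", "prenatal"), c(n_post, n_sct - n_post)),
    pair_id = NA_character_,
    zygosity = NA_character_,
    stringsAsFactors = FALSE
  )
  list(pheno = pheno[idx, , drop = FALSE], design = design, index = idx)
}

#' Simulate a twin comparison sample with MZ/DZ genotype sharing
#'
#' For each pair, four parental haplotypes are drawn from the copula LD
#' model; each twin receives one maternal and one paternal haplotype. MZ
#' co-twins copy the same transmissions (identical genotypes); DZ co-twins
#' draw transmissions independently (expected IBD 0.5, so the within-pair
#' dosage correlation is 0.5). Phenotypes are generated from the shared
#' genetic model with independent residuals (no shared-environment term).
#'
#' @param specs SNP spec table.
#' @param ld target r-squared matrix or `NULL`.
#' @param scenario a [cohort_scenario()].
#' @param seed RNG seed.
#' @return List with `geno`, `pheno` and `design` (pair_id, zygosity,
#'   twin_order) for the `2 * n_twin_pairs` twins.
#' @export
generate_twin_pairs <- function(specs, ld = NULL, scenario, seed = 1L) {
  specs <- .check_specs(specs)
  stopifnot(inherits(scenario, "cohort_scenario"), scenario$n_twin_pairs >= 1)
  n_pairs <- scenario$n_twin_pairs
  lat <- .latent_corr_matrix(specs, ld)

  set.seed(seed)
  zyg <- sample(rep(names(scenario$zygosity_mix),
                    times = .quota_counts(n_pairs, scenario$zygosity_mix)))
  # 4 parental haplotypes per pair: mother 1,2 then father 3,4
  H <- .draw_haplotypes(4L * n_pairs, specs, lat$factor)
  m <- nrow(specs)
  dosage <- matrix(0L, 2L * n_pairs, m)
  for (p in seq_len(n_pairs)) {
    hap <- H[(4 * p - 3):(4 * p), , drop = FALSE]
    m1 <- sample(1:2, 1)
    f1 <- sample(3:4, 1)
    if (zyg[p] == "MZ") {
      m2 <- m1
      f2 <- f1
    } else {
      m2 <- sample(1:2, 1)
      f2 <- sample(3:4, 1)
    }
    dosage[2 * p - 1, ] <- hap[m1, ] + hap[f1, ]
    dosage[2 * p, ] <- hap[m2, ] + hap[f2, ]
  }
  pair_id <- sprintf("P%04d", rep(seq_len(n_pairs), each = 2))
  ids <- paste0("TW_", pair_id, rep(c("A", "B"), n_pairs))
  rownames(dosage) <- ids
  colnames(dosage) <- specs$snp_id
  geno <- genotype_matrix(dosage, specs)

  pheno <- generate_phenotypes(geno, scenario,
    seed = seed + 104729L, effect_multiplier = 1
  )
  design <- data.frame(
    sample_id = ids,
    group = NA_character_,
    karyotype = NA_character_,
    ascertainment = NA_character_,
    pair_id = pair_id,
    zygosity = rep(zyg, each = 2),
    twin_order = rep(c("A", "B"), n_pairs),
    stringsAsFactors = FALSE
  )
  list(geno = geno, pheno = pheno, design = design)
}

#' Split twins into two subsamples, one co-twin per pair
#'
#' Each complete pair contributes exactly one member to each subsample, at
#' random. Pairs reduced to a single member (for example after removing
#' samples with missing DNA) are assigned to one subsample at random, which
#' can make the two subsamples unequal in size. Pairs with more than two
#' members are an error.
#'
#' @param design twin design table with `sample_id` and `pair_id`.
#' @param seed RNG seed; the split is deterministic given the seed.
#' @param labels subsample labels (default `c("Twin1", "Twin2")`).
#' @return `design` with a `group` column set to the subsample label.
#' @export
split_one_per_pair <- function(design, seed = 1L, labels = c("Twin1", "Twin2")) {
  stopifnot(!is.null(design$pair_id), !anyNA(design$pair_id))
  sizes <- table(design$pair_id)
  if (any(sizes > 2)) stop("pairs with more than two members cannot be split")
  set.seed(seed)
  design$group <- NA_character_
  for (p in names(sizes)) {
    rows <- which(design$pair_id == p)
    if (length(rows) == 2) {
      first <- sample(1:2, 1)
      design$group[rows[first]] <- labels[1]
      design$group[rows[-first]] <- labels[2]
    } else {
      design$group[rows] <- labels[sample(1:2, 1)]
    }
  }
  design
}

# inject missing dosage calls completely at random
.inject_missing_geno <- function(G, rate, seed) {
  if (rate <= 0) return(G)
  set.seed(seed)
  drop <- matrix(stats::runif(length(G$dosage)) < rate, nrow(G$dosage))
  G$dosage[drop] <- NA
  G
}

#' Simulate the full study cohort
#'
#' Builds the complete synthetic dataset: an SCT group selected from a
#' candidate pool under phenotype ascertainment (with the double-hit
#' multiplier applied to its gene effect), plus a twin comparison sample
#' split into two one-per-pair subsamples. All stages derive their seeds from
#' `seed`, so the cohort is exactly reproducible.
#'
#' @param scenario a [cohort_scenario()].
#' @param panel SNP spec table; default [default_snp_panel()].
#' @param ld target r-squared matrix; default [default_ld()] for the panel.
#' @param seed master RNG seed.
#' @param pool_factor size of the SCT candidate pool relative to `n_sct`.
#' @return List of class `sct_cohort` with `geno`, `pheno`, `design`,
#'   `scenario`, `panel` and `seed`. `design$group` is one of `SCT`,
#'   `Twin1`, `Twin2`.
#' @export
simulate_cohort <- function(scenario = cohort_scenario(),
                            panel = default_snp_panel(),
                            ld = default_ld(panel),
                            seed = 1L, pool_factor = 6) {
  stopifnot(inherits(scenario, "cohort_scenario"))
  seed <- as.integer(seed)

  pool_n <- max(ceiling(pool_factor * scenario$n_sct), 500L)
  G_pool <- generate_genotypes(panel, ld, n = pool_n, seed = seed + 11L)
  rownames(G_pool$dosage) <- sprintf("SCT_pool%05d", seq_len(pool_n))
  pheno_pool <- generate_phenotypes(G_pool, scenario,
    seed = seed + 13L, effect_multiplier = scenario$sct_multiplier
  )
  asc <- apply_ascertainment(pheno_pool, scenario, seed = seed + 17L)
  G_sct <- subset_genotypes(G_pool, samples = asc$index)
  sct_ids <- sprintf("SCT%04d", seq_len(scenario$n_sct))
  rownames(G_sct$dosage) <- sct_ids
  pheno_sct <- asc$pheno
  pheno_sct$sample_id <- sct_ids
  design_sct <- asc$design
  design_sct$sample_id <- sct_ids
  design_sct$twin_order <- NA_character_

  tw <- generate_twin_pairs(panel, ld, scenario, seed = seed + 19L)
  tw$design <- split_one_per_pair(tw$design, seed = seed + 23L)

  dosage <- rbind(G_sct$dosage, tw$geno$dosage)
  geno <- genotype_matrix(dosage, G_sct$snps)
  pheno <- rbind(pheno_sct, tw$pheno)
  design <- rbind(design_sct, tw$design[, names(design_sct)])
  rownames(pheno) <- rownames(design) <- NULL

  geno <- .inject_missing_geno(geno, scenario$missing_geno_rate, seed + 29L)
  structure(
    list(
      geno = geno, pheno = pheno, design = design,
      scenario = scenario, panel = panel, seed = seed
    ),
    class = "sct_cohort"
  )
}

#' @export
print.sct_cohort <- function(x, ...) {
  cat(sprintf(
    "<sct_cohort> %d samples (%s), %d SNPs, seed %d\n",
    nrow(x$geno$dosage),
    paste(sprintf("%s=%d", names(table(x$design$group)), table(x$design$group)),
      collapse = ", "
    ),
    ncol(x$geno$dosage), x$seed
  ))
  invisible(x)
}
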