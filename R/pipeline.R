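#' Pipeline configuration
#'
#' A single configuration object drives the end-to-end analysis. Components:
#' `scenario` (overrides for [cohort_scenario()]), `qc` (overrides for
#' [qc_thresholds()]), `gsca` (`B` permutations, `alternative`, `min_n`
#' subgroup floor), `tests` (gene-based test settings) and `power`
#' (`n_reps` Monte-Carlo replicates). Every stage derives its RNG stream
#' from `seed`, so a configuration pins down every number the pipeline
#' writes.
#'
#' @param seed master seed.
#' @param scenario,qc,gsca,tests,power named lists of stage settings.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            scenario = list(),
                            qc = list(),
                            gsca = list(B = 500L, alternative = "two.sided", min_n = 20L),
                            tests = list(
                              burden_maf_max = 0.01,
                              skat_maf_max = 0.5,
                              skat_weights = "beta"
                            ),
                            power = list(n_reps = 5000L)) {
  cfg <- list(
    seed = as.integer(seed), scenario = scenario, qc = qc,
    gsca = utils::modifyList(
      list(B = 500L, alternative = "two.sided", min_n = 20L), gsca
    ),
    tests = utils::modifyList(
      list(burden_maf_max = 0.01, skat_maf_max = 0.5, skat_weights = "beta"),
      tests
    ),
    power = utils::modifyList(list(n_reps = 5000L), power)
  )
  class(cfg) <- "pipeline_config"
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys match [pipeline_config()]'s
#'   arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

.write_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  path
}

#' Run the full registered analysis on a synthetic cohort
#'
#' Simulate, QC, construct phenotypes, fit the GSCA model with permutation
#' inference per group and karyotype subgroup, run the exploratory per-SNP
#' and gene-based tests, and compute the power appendix. All results are
#' written as plain CSV/JSON under `out_dir`, together with a run manifest
#' (configuration echo, seeds, package version and MD5 digests of every
#' output file). Re-running with the same configuration and seed reproduces
#' every output byte for byte.
#'
#' @param config a [pipeline_config()] (or YAML path).
#' @param out_dir output directory (created if needed).
#' @param write_genotype_files also export the cohort as PLINK and VCF.
#' @return Invisibly, a list with the in-memory results of every stage.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         write_genotype_files = TRUE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  seed <- config$seed

  # 1. simulate ------------------------------------------------------------
  scenario <- do.call(cohort_scenario, config$scenario)
  cohort <- simulate_cohort(scenario, seed = seed)
  files <- c(files, .write_csv(cohort$design, file.path(out_dir, "design.csv")))
  files <- c(files, .write_csv(cohort$pheno, file.path(out_dir, "phenotypes_raw.csv")))
  yaml::write_yaml(
    config$scenario[lengths(config$scenario) > 0],
    file.path(out_dir, "scenario.yaml")
  )
  files <- c(files, file.path(out_dir, "scenario.yaml"))
  if (write_genotype_files) {
    write_plink(cohort$geno, file.path(out_dir, "cohort"))
    write_vcf(cohort$geno, file.path(out_dir, "cohort.vcf"))
    files <- c(files, file.path(out_dir, c("cohort.bed", "cohort.bim", "cohort.fam", "cohort.vcf")))
  }

  # 2. genotype QC ----------------------------------------------------------
  thresholds <- do.call(qc_thresholds, config$qc)
  unrelated <- cohort$design$sample_id[cohort$design$group %in% "Twin1"]
  qc <- run_qc(cohort$geno, pedigree = NULL, thresholds = thresholds,
               hwe_samples = unrelated)
  ld <- lapply(unique(qc$geno$snps$gene), function(g) {
    data.frame(
      gene = g,
      n_pairs_r2_above = pairwise_r2(qc$geno, gene = g,
        ld_report_r2 = thresholds$ld_report_r2)$n_pairs_above
    )
  })
  ld <- do.call(rbind, ld)
  files <- c(files, .write_csv(qc$report, file.path(out_dir, "qc_report.csv")))
  files <- c(files, .write_csv(ld, file.path(out_dir, "ld_report.csv")))
  jsonlite::write_json(
    list(
      input_dim = qc$input_dim, output_dim = qc$output_dim,
      hwe_population = qc$hwe_population,
      thresholds = unclass(thresholds)
    ),
    file.path(out_dir, "qc_summary.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  files <- c(files, file.path(out_dir, "qc_summary.json"))

  # 3. phenotype construction ----------------------------------------------
  battery <- cohort$pheno[, c(
    "verbal_comprehension", "oromotor_sequences",
    "sentence_repetition", "vocabulary"
  )]
  lf <- fit_language_factor(battery)
  pheno <- cohort$pheno
  pheno$language_factor <- lf$scores
  twin_ids <- cohort$design$sample_id[cohort$design$group %in% c("Twin1", "Twin2")]
  pheno <- orient_and_standardize(pheno, reference_ids = twin_ids)
  files <- c(files, .write_csv(
    pheno[, c(
      "sample_id", "nonword_repetition", "language_factor", "global_burden"
    )],
    file.path(out_dir, "phenotypes_analysis.csv")
  ))
  jsonlite::write_json(
    list(loadings = as.list(round(lf$loadings, 6)), method = lf$method,
         n_complete = lf$n_complete),
    file.path(out_dir, "language_factor.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  files <- c(files, file.path(out_dir, "language_factor.json"))

  # 4. GSCA + permutations ---------------------------------------------------
  spec <- gsca_spec_from_panel(qc$geno$snps)
  analysis_cohort <- list(geno = qc$geno, pheno = pheno, design = cohort$design)
  gsca_tab <- run_group_analyses(
    analysis_cohort, spec,
    B = config$gsca$B, seed = seed + 100L,
    karyotype_subgroups = TRUE, min_n = config$gsca$min_n,
    alternative = config$gsca$alternative
  )
  main <- gsca_tab[!grepl("^SCT_", gsca_tab$group), , drop = FALSE]
  sub <- gsca_tab[grepl("^SCT_", gsca_tab$group), , drop = FALSE]
  files <- c(files, .write_csv(main, file.path(out_dir, "gsca_groups.csv")))
  files <- c(files, .write_csv(sub, file.path(out_dir, "gsca_karyotype_subgroups.csv")))

  # 5. exploratory SNP and gene tests ---------------------------------------
  snp_tab <- do.call(rbind, lapply(
    unique(stats::na.omit(cohort$design$group)),
    function(g) {
      ids <- cohort$design$sample_id[cohort$design$group %in% g]
      snp_assoc_scan(
        subset_genotypes(qc$geno, samples = rownames(qc$geno$dosage) %in% ids),
        pheno[pheno$sample_id %in% ids, , drop = FALSE],
        group = g
      )
    }
  ))
  files <- c(files, .write_csv(snp_tab, file.path(out_dir, "snp_assoc.csv")))
  unif <- pvalue_uniformity_check(snp_tab$p_value[!snp_tab$untestable])
  jsonlite::write_json(unif, file.path(out_dir, "pvalue_uniformity.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  files <- c(files, file.path(out_dir, "pvalue_uniformity.json"))

  gene_rows <- list()
  for (g in unique(stats::na.omit(cohort$design$group))) {
    ids <- cohort$design$sample_id[cohort$design$group %in% g]
    Gg <- subset_genotypes(qc$geno, samples = rownames(qc$geno$dosage) %in% ids)
    phg <- pheno[match(rownames(Gg$dosage), pheno$sample_id), , drop = FALSE]
    for (gene in unique(Gg$snps$gene)) {
      Ggene <- subset_genotypes(Gg, snps = Gg$snps$gene == gene)
      for (p in c("nonword_repetition", "language_factor", "global_burden")) {
        b <- burden_test_zeggini(Ggene, phg[[p]],
          maf_max = config$tests$burden_maf_max,
          gene = gene, phenotype_name = p
        )
        s <- skat_test(Ggene, phg[[p]],
          weights_scheme = config$tests$skat_weights,
          maf_max = config$tests$skat_maf_max,
          gene = gene, phenotype_name = p
        )
        b$group <- s$group <- g
        gene_rows[[length(gene_rows) + 1L]] <- b
        gene_rows[[length(gene_rows) + 1L]] <- s
      }
    }
  }
  gene_tab <- do.call(rbind, gene_rows)
  files <- c(files, .write_csv(gene_tab, file.path(out_dir, "gene_tests.csv")))
  bonf <- bonferroni_threshold(0.05, ncol(qc$geno$dosage), 3)
  jsonlite::write_json(bonf, file.path(out_dir, "bonferroni.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  files <- c(files, file.path(out_dir, "bonferroni.json"))

  # 6. power appendix --------------------------------------------------------
  reps <- config$power$n_reps
  p_unbiased <- simulate_power(
    power_scenario(n = 150L, slope = 0.25, tails = "one", n_reps = reps),
    seed = seed + 200L
  )
  p_biased <- simulate_power(
    power_scenario(
      n = 130L, slope = 0.25, tails = "one",
      frac_ascertained = 0.5, ascertainment_shift = 0.9, n_reps = reps
    ),
    seed = seed + 201L
  )
  power_tab <- data.frame(
    design = c("unbiased_n150", "ascertained_n130"),
    power = c(p_unbiased$power, p_biased$power),
    ci_lower = c(p_unbiased$ci[1], p_biased$ci[1]),
    ci_upper = c(p_unbiased$ci[2], p_biased$ci[2]),
    analytic = c(p_unbiased$analytic, NA),
    n_reps = reps
  )
  files <- c(files, .write_csv(power_tab, file.path(out_dir, "power.csv")))

  # 7. manifest ---------------------------------------------------------------
  manifest <- list(
    package_version = as.character(utils::packageVersion("sctassoc")),
    seed = seed,
    config = unclass(config),
    file_md5 = {
      md5 <- tools::md5sum(sort(files))
      stats::setNames(as.list(md5), basename(names(md5)))
    }
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )

  invisible(list(
    cohort = cohort, qc = qc, language_factor = lf, pheno = pheno,
    gsca = gsca_tab, snp_assoc = snp_tab, uniformity = unif,
    gene_tests = gene_tab, bonferroni = bonf,
    power = power_tab, files = files, out_dir = out_dir
  ))
}
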